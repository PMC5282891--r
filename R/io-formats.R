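#' @importFrom methods as is
#' @importFrom stats cor dist median p.adjust phyper rbinom rlnorm rnorm runif sd setNames t.test
#' @importFrom utils read.delim write.table head tail
NULL

# Internal coordinate convention: 0-based, half-open [start, end).
# GTF converts at the boundary (1-based inclusive); BED/bedGraph pass through.
# Strand is one of "+", "-", "*" ("*" = unknown).

.STRANDS <- c("+", "-", "*")

#' Build a transcript model table
#'
#' The package represents a set of transcript models as a plain data frame
#' with one row per exon and columns `transcript_id`, `gene_id`, `chrom`,
#' `start`, `end`, `strand`, `biotype`. Coordinates are 0-based, half-open;
#' strand is `"+"`, `"-"` or `"*"` (unknown). This constructor validates the
#' invariants every other function assumes: exons sorted by start within
#' transcript, non-overlapping, on a single chromosome and strand, and
#' `end > start` for every exon.
#'
#' @param df data frame with the columns above (`gene_id` and `biotype`
#'   optional; they default to the transcript id and `"unannotated"`).
#' @return validated transcript table (rows ordered by transcript then start).
#' @export
transcript_models <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("transcript_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("transcript table is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$gene_id)) df$gene_id <- df$transcript_id
  if (is.null(df$biotype)) df$biotype <- "unannotated"
  df <- df[, c("transcript_id", "gene_id", "chrom", "start", "end",
               "strand", "biotype")]
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (any(!df$strand %in% .STRANDS))
    stop("strand must be one of '+', '-', '*'")
  bad <- which(df$end <= df$start)
  if (length(bad) > 0L)
    stop("exon with end <= start for transcript ",
         df$transcript_id[bad[1L]])
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (tid in unique(df$transcript_id)) {
    ex <- df[df$transcript_id == tid, , drop = FALSE]
    if (length(unique(ex$chrom)) != 1L)
      stop("transcript ", tid, " has exons on multiple chromosomes")
    if (length(unique(ex$strand)) != 1L)
      stop("transcript ", tid, " has exons on multiple strands")
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)]))
      stop("transcript ", tid, " has overlapping exons")
  }
  df
}

#' Per-transcript summary of a transcript table
#'
#' @param tx transcript table (see [transcript_models()]).
#' @return data frame with one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `biotype`, `n_exons`, `length` (mature
#'   length, the sum of exon lengths), `span_start`, `span_end`.
#' @export
transcript_summary <- function(tx) {
  sp <- split(seq_len(nrow(tx)), tx$transcript_id)
  ids <- names(sp)
  first <- vapply(sp, `[`, integer(1L), 1L)
  data.frame(
    transcript_id = ids,
    gene_id = tx$gene_id[first],
    chrom = tx$chrom[first],
    strand = tx$strand[first],
    biotype = tx$biotype[first],
    n_exons = lengths(sp),
    length = vapply(sp, function(i) sum(tx$end[i] - tx$start[i]), numeric(1L)),
    span_start = vapply(sp, function(i) min(tx$start[i]), numeric(1L)),
    span_end = vapply(sp, function(i) max(tx$end[i]), numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# exon table -> GRanges (1-based internally to GRanges); strand kept in a
# metadata column so "*" never gets GRanges' match-anything semantics.
.exons_gr <- function(tx) {
  GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(start = tx$start + 1L, end = tx$end),
    strand = "*",
    transcript_id = tx$transcript_id,
    exon_strand = tx$strand
  )
}

# Pairs of (query row, subject row) whose exons share >= 1 bp, with strand
# mode "same", "opposite" or "any". Unknown-strand exons never satisfy
# "same" or "opposite".
.overlap_pairs <- function(tx_q, tx_s, mode = c("same", "opposite", "any")) {
  mode <- match.arg(mode)
  gq <- .exons_gr(tx_q)
  gs <- .exons_gr(tx_s)
  hits <- GenomicRanges::findOverlaps(gq, gs, minoverlap = 1L,
                                      ignore.strand = TRUE)
  qs <- tx_q$strand[S4Vectors::queryHits(hits)]
  ss <- tx_s$strand[S4Vectors::subjectHits(hits)]
  keep <- switch(mode,
    same = qs == ss & qs != "*",
    opposite = (qs == "+" & ss == "-") | (qs == "-" & ss == "+"),
    any = rep(TRUE, length(qs))
  )
  data.frame(q = S4Vectors::queryHits(hits)[keep],
             s = S4Vectors::subjectHits(hits)[keep])
}

# transcript ids in tx_q with >= 1 bp exonic overlap with tx_s under mode
.overlapping_ids <- function(tx_q, tx_s, mode) {
  if (nrow(tx_q) == 0L || nrow(tx_s) == 0L) return(character(0L))
  p <- .overlap_pairs(tx_q, tx_s, mode)
  unique(tx_q$transcript_id[p$q])
}

.gtf_attr <- function(attrs, key) {
  pat <- paste0(key, ' "([^"]*)"')
  m <- regexpr(pat, attrs)
  out <- rep(NA_character_, length(attrs))
  hit <- m != -1L
  out[hit] <- sub(pat, "\\1", regmatches(attrs, m))
  out
}

#' Read transcript models from a GTF file
#'
#' Reads `exon` features from an Ensembl-dialect GTF (attributes `gene_id`
#' and `transcript_id`; optional `biotype`), converting 1-based inclusive
#' coordinates to the internal 0-based half-open convention. Strand `"."`
#' becomes the first-class unknown value `"*"` rather than being coerced to
#' `"+"`. A transcript id appearing on more than one chromosome is an error:
#' the pipeline assumes unique ids.
#'
#' @param path path to a GTF file.
#' @return transcript table (see [transcript_models()]).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(transcript_models(data.frame(transcript_id = character(0L),
                                        chrom = character(0L), start = numeric(0L),
                                        end = numeric(0L), strand = character(0L))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop("malformed GTF line ", lineno[which(nf < 9L)[1L]],
         ": expected 9 tab-separated fields, got ", nf[which(nf < 9L)[1L]])
  feat <- vapply(fields, `[`, character(1L), 3L)
  exon <- feat == "exon"
  fields <- fields[exon]
  lineno <- lineno[exon]
  if (length(fields) == 0L)
    stop("GTF file contains no exon features: ", path)
  start1 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1L), 4L)))
  end1 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1L), 5L)))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad) > 0L)
    stop("malformed GTF line ", lineno[bad[1L]], ": non-numeric coordinates")
  bad <- which(end1 < start1)
  if (length(bad) > 0L)
    stop("invalid GTF line ", lineno[bad[1L]], ": end < start")
  strand <- vapply(fields, `[`, character(1L), 7L)
  bad <- which(!strand %in% c("+", "-", "."))
  if (length(bad) > 0L)
    stop("malformed GTF line ", lineno[bad[1L]], ": bad strand '",
         strand[bad[1L]], "'")
  strand[strand == "."] <- "*"
  attrs <- vapply(fields, `[`, character(1L), 9L)
  tid <- .gtf_attr(attrs, "transcript_id")
  gid <- .gtf_attr(attrs, "gene_id")
  bad <- which(is.na(tid))
  if (length(bad) > 0L)
    stop("malformed GTF line ", lineno[bad[1L]], ": missing transcript_id")
  bt <- .gtf_attr(attrs, "biotype")
  bt[is.na(bt)] <- "unannotated"
  df <- data.frame(
    transcript_id = tid,
    gene_id = ifelse(is.na(gid), tid, gid),
    chrom = vapply(fields, `[`, character(1L), 1L),
    start = start1 - 1,
    end = end1,
    strand = strand,
    biotype = bt,
    stringsAsFactors = FALSE
  )
  # duplicate transcript id across chromosomes is a hard error
  byid <- split(df$chrom, df$transcript_id)
  dup <- names(byid)[vapply(byid, function(x) length(unique(x)) > 1L, logical(1L))]
  if (length(dup) > 0L)
    stop("transcript id on multiple chromosomes: ", paste(dup, collapse = ", "))
  transcript_models(df)
}

#' Write transcript models to a GTF file
#'
#' Inverse of [read_gtf()]: internal 0-based half-open exons are written as
#' 1-based inclusive GTF exon lines; unknown strand is written as `"."`.
#' A read/write round trip is bit-identical on coordinates and strand.
#'
#' @param tx transcript table.
#' @param path output path.
#' @param source value of the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(tx, path, source = "lncfeather") {
  strand <- ifelse(tx$strand == "*", ".", tx$strand)
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; biotype "%s";',
    tx$chrom, source, as.integer(tx$start) + 1L, as.integer(tx$end),
    strand, tx$gene_id, tx$transcript_id, tx$biotype)
  writeLines(lines, path)
  invisible(path)
}

#' Library metadata for the six-library embryonic skin design
#'
#' @param library_ids library names; defaults to the anterior/posterior
#'   dorsal design at incubation days E8, E9 and E12.
#' @return data frame with `library_id`, `region` (`AD`/`PD`), `stage`.
#' @export
library_metadata <- function(library_ids = c("E8A", "E8P", "E9A", "E9P",
                                             "E12A", "E12P")) {
  region <- ifelse(grepl("A$", library_ids), "AD", "PD")
  stage <- sub("[AP]$", "", library_ids)
  data.frame(library_id = library_ids, region = region, stage = stage,
             stringsAsFactors = FALSE)
}

#' Build an expression table
#'
#' @param values numeric matrix of FPKM, rows = transcripts, columns =
#'   libraries (dimnames required).
#' @param library_meta data frame with `library_id`, `region`, `stage`
#'   covering every column of `values`.
#' @return an `expression_table` object (list with `values`, `meta`).
#' @export
expression_table <- function(values, library_meta = library_metadata(colnames(values))) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (is.null(rownames(values))) {
    if (nrow(values) > 0L) stop("expression matrix needs transcript rownames")
    rownames(values) <- character(0L)
  }
  if (anyNA(values)) stop("expression table contains missing values")
  if (any(values < 0)) stop("negative FPKM values are not allowed")
  if (anyDuplicated(rownames(values)))
    stop("duplicate transcript ids in expression table")
  missing_meta <- setdiff(colnames(values), library_meta$library_id)
  if (length(missing_meta) > 0L)
    stop("libraries absent from metadata: ", paste(missing_meta, collapse = ", "))
  meta <- library_meta[match(colnames(values), library_meta$library_id), ,
                       drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", nrow(x$values), "transcripts x",
      ncol(x$values), "libraries\n")
  cat("libraries:", paste0(x$meta$library_id, " (", x$meta$region, "/",
                           x$meta$stage, ")", collapse = ", "), "\n")
  invisible(x)
}

#' Read an FPKM expression table from TSV
#'
#' Expects a header of library ids with a leading `transcript_id` column and
#' a numeric body. Negative or missing values are rejected; every library in
#' the file must be declared in `library_meta`.
#'
#' @param path TSV path.
#' @param library_meta see [library_metadata()].
#' @return an `expression_table`.
#' @export
read_expression <- function(path, library_meta = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "transcript_id")
    stop("expression TSV must have a leading transcript_id column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("expression TSV body must be numeric")
  rownames(m) <- df$transcript_id
  if (is.null(library_meta)) library_meta <- library_metadata(colnames(m))
  expression_table(m, library_meta)
}

#' Write an expression table to TSV
#'
#' @param expr an `expression_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(transcript_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tab_lines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

#' Read labeled intervals from a BED file
#'
#' BED3 or longer; coordinates pass through unchanged (BED is already
#' 0-based, half-open). Column 4, if present, is kept as `name` (used for
#' repeat classes and known-ncRNA catalogs); column 6, if present, as
#' `strand` (`"."` mapped to `"*"`).
#'
#' @param path BED path.
#' @return data frame with `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  tl <- .read_tab_lines(path)
  if (length(tl$fields) == 0L)
    return(data.frame(chrom = character(0L), start = numeric(0L),
                      end = numeric(0L), name = character(0L),
                      strand = character(0L), stringsAsFactors = FALSE))
  nf <- lengths(tl$fields)
  bad <- which(nf < 3L)
  if (length(bad) > 0L)
    stop("malformed BED line ", tl$lineno[bad[1L]],
         ": expected >= 3 tab-separated fields")
  start <- suppressWarnings(as.numeric(vapply(tl$fields, `[`, character(1L), 2L)))
  end <- suppressWarnings(as.numeric(vapply(tl$fields, `[`, character(1L), 3L)))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad) > 0L)
    stop("malformed BED line ", tl$lineno[bad[1L]], ": bad coordinates")
  name <- vapply(tl$fields, function(f) if (length(f) >= 4L) f[4L] else ".",
                 character(1L))
  strand <- vapply(tl$fields, function(f) if (length(f) >= 6L) f[6L] else ".",
                   character(1L))
  strand[!strand %in% c("+", "-")] <- "*"
  data.frame(chrom = vapply(tl$fields, `[`, character(1L), 1L),
             start = start, end = end, name = name, strand = strand,
             stringsAsFactors = FALSE)
}

#' Write intervals to a BED file
#'
#' @param bed data frame with `chrom`, `start`, `end` and optional `name`,
#'   `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  name <- if (is.null(bed$name)) rep(".", nrow(bed)) else bed$name
  strand <- if (is.null(bed$strand)) rep(".", nrow(bed)) else
    ifelse(bed$strand == "*", ".", bed$strand)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", bed$chrom,
                   as.integer(bed$start), as.integer(bed$end), name, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-base score track from a bedGraph file
#'
#' Four columns, 0-based half-open. Bases not covered by any interval are
#' missing, never zero. Overlapping intervals with conflicting scores are
#' rejected.
#'
#' @param path bedGraph path.
#' @return a `score_track`: data frame with `chrom`, `start`, `end`, `score`.
#' @export
read_track <- function(path) {
  tl <- .read_tab_lines(path)
  nf <- lengths(tl$fields)
  bad <- which(nf < 4L)
  if (length(bad) > 0L)
    stop("malformed bedGraph line ", tl$lineno[bad[1L]],
         ": expected 4 tab-separated fields")
  tr <- data.frame(
    chrom = vapply(tl$fields, `[`, character(1L), 1L),
    start = as.numeric(vapply(tl$fields, `[`, character(1L), 2L)),
    end = as.numeric(vapply(tl$fields, `[`, character(1L), 3L)),
    score = as.numeric(vapply(tl$fields, `[`, character(1L), 4L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(tr$start) || anyNA(tr$end) || anyNA(tr$score))
    stop("malformed bedGraph file: non-numeric fields in ", path)
  score_track(tr)
}

#' Validate a score track
#'
#' @param tr data frame with `chrom`, `start`, `end`, `score`.
#' @return validated track, intervals sorted by chrom and start.
#' @export
score_track <- function(tr) {
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(tr)))
  if (any(tr$end <= tr$start)) stop("track interval with end <= start")
  tr <- tr[order(tr$chrom, tr$start), , drop = FALSE]
  rownames(tr) <- NULL
  for (ch in unique(tr$chrom)) {
    x <- tr[tr$chrom == ch, , drop = FALSE]
    if (nrow(x) > 1L) {
      ov <- which(x$start[-1L] < x$end[-nrow(x)])
      if (length(ov) > 0L) {
        i <- ov[1L]
        if (x$score[i] != x$score[i + 1L])
          stop("overlapping track intervals with conflicting scores on ", ch,
               " near base ", x$start[i + 1L])
      }
    }
  }
  tr
}

#' Per-base scores of a genomic window
#'
#' @param track a score track (see [read_track()]).
#' @param chrom chromosome.
#' @param start,end window, 0-based half-open.
#' @return numeric vector of length `end - start`; `NA` where no score.
#' @export
track_scores <- function(track, chrom, start, end) {
  out <- rep(NA_real_, end - start)
  x <- track[track$chrom == chrom & track$end > start & track$start < end, ,
             drop = FALSE]
  for (i in seq_len(nrow(x))) {
    a <- max(x$start[i], start) - start
    b <- min(x$end[i], end) - start
    out[(a + 1L):b] <- x$score[i]
  }
  out
}

#' Read chromosome sizes from a two-column TSV
#'
#' @param path TSV path (chromosome, size in bp).
#' @return named numeric vector of sizes.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("chrom.sizes file must have two columns")
  setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' Read a coding potential score table
#'
#' TSV with columns `transcript_id`, `cpc_score`, `plek_score`,
#' `min_domain_evalue` (`NA` = no domain hit). Negative scores lean
#' noncoding; E-values must be non-negative.
#'
#' @param path TSV path.
#' @return validated data frame (see [coding_scores()]).
#' @export
read_coding_scores <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  coding_scores(df)
}

#' Validate a coding potential score table
#'
#' @param df data frame with `transcript_id`, `cpc_score`, `plek_score`,
#'   `min_domain_evalue`.
#' @return the validated table.
#' @export
coding_scores <- function(df) {
  need <- c("transcript_id", "cpc_score", "plek_score", "min_domain_evalue")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("coding score table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$transcript_id))
    stop("duplicate transcript ids in coding score table")
  ev <- df$min_domain_evalue
  if (any(!is.na(ev) & ev < 0)) stop("negative domain E-value")
  df[, need]
}

#' Read/write FASTA sequences
#'
#' Thin wrappers over Biostrings for the package's sequence IO.
#'
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param seqs a named [Biostrings::DNAStringSet] (or named character vector).
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
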