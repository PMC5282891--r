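# Filtering cascade from raw assembled isotigs to the unannotated
# transcript set: strand filter, annotation partition, isotig merging,
# length/expression filters and known-ncRNA novelty labeling.

.split_tx <- function(tx, ids) {
  keep <- tx$transcript_id %in% ids
  list(kept = tx[keep, , drop = FALSE], removed = tx[!keep, , drop = FALSE])
}

.n_tx <- function(tx) length(unique(tx$transcript_id))

#' Remove isotigs without strand information
#'
#' Keeps exactly the models on `"+"` or `"-"`; unknown-strand (`"*"`)
#' isotigs are removed. Strand-specific library preparation determines the
#' strand of real transcripts, so strandless models are assembly artifacts.
#'
#' @param isotigs transcript table.
#' @return list with `kept` and `removed` transcript tables.
#' @export
filter_stranded <- function(isotigs) {
  stranded <- unique(isotigs$transcript_id[isotigs$strand %in% c("+", "-")])
  .split_tx(isotigs, stranded)
}

#' Partition isotigs by annotation overlap
#'
#' An isotig is *annotated* iff at least one base of its exons overlaps at
#' least one base of a reference exon on the same strand; all others
#' (including antisense and purely intronic isotigs) are *unannotated*.
#' Overlap is exon-level and strand-aware, which is what allows antisense
#' and intronic lncRNAs to survive to the downstream classes.
#'
#' @param isotigs stranded transcript table.
#' @param reference_annotation reference transcript table (exon features).
#' @return list with `annotated` and `unannotated` transcript tables.
#' @export
partition_by_annotation <- function(isotigs, reference_annotation) {
  if (.n_tx(reference_annotation) == 0L)
    stop("reference annotation has no exon features")
  ann_ids <- .overlapping_ids(isotigs, reference_annotation, "same")
  s <- .split_tx(isotigs, ann_ids)
  list(annotated = s$kept, unannotated = s$removed)
}

#' Merge overlapping isotigs into raw transcripts
#'
#' Single-linkage merge of isotigs whose exons share at least one base on
#' the same chromosome and strand. The merged exon structure is the base
#' union of the member exon sets; member ids are recorded. A merged
#' transcript keeps its member's id when it has a single member, and gets a
#' sequential `RAW.n` id otherwise.
#'
#' @param isotigs stranded, unannotated transcript table.
#' @return list with `transcripts` (merged transcript table) and `members`
#'   (named list: merged id -> member isotig ids).
#' @export
merge_isotigs <- function(isotigs) {
  ids <- unique(isotigs$transcript_id)
  if (length(ids) == 0L)
    return(list(transcripts = isotigs, members = setNames(list(), character(0L))))
  p <- .overlap_pairs(isotigs, isotigs, "same")
  e_from <- isotigs$transcript_id[p$q]
  e_to <- isotigs$transcript_id[p$s]
  g <- igraph::graph_from_data_frame(
    data.frame(from = e_from, to = e_to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership[ids]
  groups <- split(ids, comp)
  # deterministic ordering by leftmost exon of each group
  sm <- transcript_summary(isotigs)
  ord <- order(vapply(groups, function(m) {
    sm2 <- sm[sm$transcript_id %in% m, , drop = FALSE]
    min(sm2$span_start)
  }, numeric(1L)),
  vapply(groups, function(m) sm$chrom[sm$transcript_id == m[1L]][1L],
         character(1L)))
  groups <- groups[ord]
  out <- list(); members <- list()
  n_multi <- 0L
  for (m in groups) {
    ex <- isotigs[isotigs$transcript_id %in% m, , drop = FALSE]
    if (length(m) == 1L) {
      mid <- m
      merged <- ex
      merged$gene_id <- mid
    } else {
      n_multi <- n_multi + 1L
      mid <- sprintf("RAW.%04d", n_multi)
      red <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
      merged <- data.frame(transcript_id = mid, gene_id = mid,
                           chrom = ex$chrom[1L],
                           start = IRanges::start(red) - 1L,
                           end = IRanges::end(red),
                           strand = ex$strand[1L], biotype = "unannotated",
                           stringsAsFactors = FALSE)
    }
    merged$transcript_id <- mid
    out[[mid]] <- merged
    members[[mid]] <- sort(m)
  }
  list(transcripts = transcript_models(do.call(rbind, out)),
       members = members)
}

#' Aggregate member expression onto merged transcripts
#'
#' Per-library expression of a merged raw transcript is the maximum over its
#' member isotigs (the strongest evidence of locus expression in that
#' library).
#'
#' @param expr an `expression_table` keyed by member isotig ids.
#' @param members named list from [merge_isotigs()].
#' @return an `expression_table` keyed by merged ids.
#' @export
aggregate_member_expression <- function(expr, members) {
  miss <- setdiff(unlist(members), rownames(expr$values))
  if (length(miss) > 0L)
    stop("member isotigs missing from expression table: ",
         paste(head(miss, 5L), collapse = ", "))
  m <- t(vapply(members, function(ids) {
    apply(expr$values[ids, , drop = FALSE], 2L, max)
  }, numeric(ncol(expr$values))))
  rownames(m) <- names(members)
  expression_table(m, expr$meta)
}

#' Remove short and unexpressed transcripts
#'
#' Removes transcripts with mature length (sum of exon lengths) below
#' `min_length`, and transcripts whose FPKM is below `min_max_fpkm` in every
#' library (i.e. kept iff the maximum over libraries reaches the cutoff).
#' Boundaries: length `>= min_length` keeps; max FPKM `>= min_max_fpkm`
#' keeps.
#'
#' @param transcripts transcript table.
#' @param expr an `expression_table` containing every transcript.
#' @param min_length minimum mature length in bp (default 200).
#' @param min_max_fpkm minimum of the per-transcript max-library FPKM
#'   (default 1).
#' @return list with `kept` (transcript table), `removed_short` and
#'   `removed_lowexpr` (id vectors; short removal takes precedence).
#' @export
filter_length_expression <- function(transcripts, expr, min_length = 200,
                                     min_max_fpkm = 1) {
  sm <- transcript_summary(transcripts)
  miss <- setdiff(sm$transcript_id, rownames(expr$values))
  if (length(miss) > 0L)
    stop("transcripts missing from expression table: ",
         paste(head(miss, 5L), collapse = ", "))
  maxf <- apply(expr$values[sm$transcript_id, , drop = FALSE], 1L, max)
  short <- sm$length < min_length
  lowexpr <- !short & maxf < min_max_fpkm
  kept_ids <- sm$transcript_id[!short & !lowexpr]
  list(kept = transcripts[transcripts$transcript_id %in% kept_ids, ,
                          drop = FALSE],
       removed_short = sm$transcript_id[short],
       removed_lowexpr = sm$transcript_id[lowexpr])
}

#' Label transcripts as known or novel against a non-coding catalog
#'
#' A transcript is *known* iff at least one base of its exons overlaps a
#' catalog entry on the same strand; all transcripts are retained either
#' way — catalog membership is a label, not a filter.
#'
#' @param transcripts transcript table.
#' @param catalog BED-style data frame of known non-coding intervals
#'   (`chrom`, `start`, `end`, `strand`).
#' @return named logical vector, `TRUE` = known, indexed by transcript id.
#' @export
label_novelty <- function(transcripts, catalog) {
  ids <- unique(transcripts$transcript_id)
  if (is.null(catalog) || nrow(catalog) == 0L)
    return(setNames(rep(FALSE, length(ids)), ids))
  cat_tx <- transcript_models(data.frame(
    transcript_id = paste0("CAT.", seq_len(nrow(catalog))),
    chrom = catalog$chrom, start = catalog$start, end = catalog$end,
    strand = catalog$strand, stringsAsFactors = FALSE))
  known <- .overlapping_ids(transcripts, cat_tx, "same")
  setNames(ids %in% known, ids)
}

#' Run the discovery cascade
#'
#' Applies, in order: strand filter, annotation partition, single-linkage
#' isotig merging, length/expression filter, and novelty labeling. Returns
#' the retained transcript models together with a stage-by-stage accounting
#' report whose counts satisfy
#' `input = removed_unstranded + annotated + unannotated_isotigs` and
#' `retained = merged_raw_transcripts - removed_short - removed_lowexpr`.
#'
#' @param isotigs raw isotig transcript table.
#' @param reference_annotation reference annotation transcript table.
#' @param expr `expression_table` keyed by isotig ids.
#' @param known_catalog BED-style catalog for novelty labeling (may be
#'   `NULL`).
#' @param min_length,min_max_fpkm see [filter_length_expression()].
#' @return list with `transcripts` (retained), `expr` (merged-id
#'   expression), `members`, `novelty` (named logical), and `report` (named
#'   integer vector of stage counts).
#' @export
discover_transcripts <- function(isotigs, reference_annotation, expr,
                                 known_catalog = NULL, min_length = 200,
                                 min_max_fpkm = 1) {
  st <- filter_stranded(isotigs)
  part <- partition_by_annotation(st$kept, reference_annotation)
  merged <- merge_isotigs(part$unannotated)
  mexpr <- aggregate_member_expression(expr, merged$members)
  fl <- filter_length_expression(merged$transcripts, mexpr, min_length,
                                 min_max_fpkm)
  novelty <- label_novelty(fl$kept, known_catalog)
  report <- c(
    input = .n_tx(isotigs),
    removed_unstranded = .n_tx(st$removed),
    annotated = .n_tx(part$annotated),
    unannotated_isotigs = .n_tx(part$unannotated),
    merged_raw_transcripts = .n_tx(merged$transcripts),
    removed_short = length(fl$removed_short),
    removed_lowexpr = length(fl$removed_lowexpr),
    retained = .n_tx(fl$kept),
    known = sum(novelty),
    novel = sum(!novelty)
  )
  kept_ids <- unique(fl$kept$transcript_id)
  list(transcripts = fl$kept,
       expr = expression_table(mexpr$values[kept_ids, , drop = FALSE],
                               mexpr$meta),
       members = merged$members[kept_ids],
       novelty = novelty,
       report = report)
}
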