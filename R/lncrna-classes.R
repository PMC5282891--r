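# Positional classification of consensus lncRNAs relative to the
# protein-coding annotation: lincRNA / intronic / lncNAT.

.gene_spans <- function(annotation) {
  sm <- transcript_summary(annotation)
  sp <- split(seq_len(nrow(sm)), sm$gene_id)
  data.frame(
    gene_id = names(sp),
    chrom = vapply(sp, function(i) sm$chrom[i[1L]], character(1L)),
    strand = vapply(sp, function(i) sm$strand[i[1L]], character(1L)),
    start = vapply(sp, function(i) min(sm$span_start[i]), numeric(1L)),
    end = vapply(sp, function(i) max(sm$span_end[i]), numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# introns of every annotated transcript: gaps between adjacent exons
.introns <- function(annotation) {
  out <- list()
  for (tid in unique(annotation$transcript_id)) {
    ex <- annotation[annotation$transcript_id == tid, , drop = FALSE]
    if (nrow(ex) < 2L) next
    out[[tid]] <- data.frame(chrom = ex$chrom[1L],
                             start = ex$end[-nrow(ex)],
                             end = ex$start[-1L],
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0L), start = numeric(0L),
                      end = numeric(0L), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Classify lncRNAs by position relative to coding genes
#'
#' Assigns each transcript exactly one positional class with precedence
#' lncNAT > intronic > lincRNA:
#'
#' * **lncNAT** — at least one base of exonic overlap with a coding exon on
#'   the opposite strand;
#' * **intronic** — the full exon set lies within a single intron of some
#'   coding transcript, with no coding-exon overlap on either strand
#'   (containment is accepted on either strand);
#' * **lincRNA** — no overlap with any coding gene span.
#'
#' Transcripts matching none of the definitions (straddling a gene boundary
#' without exonic overlap) fall back to intronic when the majority of their
#' exonic bases lie inside a gene span, else lincRNA.
#'
#' @param lncrnas transcript table of putative lncRNAs.
#' @param coding_annotation transcript table of protein-coding genes.
#' @return named character vector of classes (`lincRNA`, `intronic`,
#'   `lncNAT`) indexed by transcript id.
#' @export
classify_positional <- function(lncrnas, coding_annotation) {
  ids <- unique(lncrnas$transcript_id)
  if (.n_tx(coding_annotation) == 0L) {
    warning("empty coding annotation: all transcripts classified lincRNA")
    return(setNames(rep("lincRNA", length(ids)), ids))
  }
  out <- setNames(rep(NA_character_, length(ids)), ids)

  nat <- .overlapping_ids(lncrnas, coding_annotation, "opposite")
  out[nat] <- "lncNAT"

  exonic_any <- .overlapping_ids(lncrnas, coding_annotation, "any")
  introns <- .introns(coding_annotation)
  spans <- .gene_spans(coding_annotation)
  sm <- transcript_summary(lncrnas)

  for (tid in ids) {
    if (!is.na(out[tid])) next
    s <- sm[sm$transcript_id == tid, ]
    # intronic: inside one intron, no exonic overlap on either strand
    if (!(tid %in% exonic_any)) {
      inside <- introns$chrom == s$chrom & introns$start <= s$span_start &
        introns$end >= s$span_end
      if (any(inside)) {
        out[tid] <- "intronic"
        next
      }
    }
    sp_ov <- spans$chrom == s$chrom & spans$start < s$span_end &
      spans$end > s$span_start
    if (!any(sp_ov)) {
      out[tid] <- "lincRNA"
      next
    }
    # fallback: majority of exonic bases inside a gene span
    ex <- lncrnas[lncrnas$transcript_id == tid, , drop = FALSE]
    total <- sum(ex$end - ex$start)
    inbase <- 0
    for (j in which(sp_ov)) {
      ov <- pmin(ex$end, spans$end[j]) - pmax(ex$start, spans$start[j])
      inbase <- max(inbase, sum(pmax(ov, 0)))
    }
    out[tid] <- if (inbase > total / 2) "intronic" else "lincRNA"
  }
  out
}

#' Count transcripts per positional class
#'
#' @param classes named class vector from [classify_positional()].
#' @return named integer vector with entries `lincRNA`, `intronic`,
#'   `lncNAT`; sums to `length(classes)`.
#' @export
class_counts <- function(classes) {
  lv <- c("lincRNA", "intronic", "lncNAT")
  tab <- table(factor(classes, levels = lv))
  setNames(as.integer(tab), lv)
}

#' Transcripts per megabase of chromosome
#'
#' @param transcripts transcript table (one location per transcript).
#' @param chrom_sizes named vector of chromosome sizes in bp.
#' @return named numeric vector: transcripts per Mb for every chromosome in
#'   `chrom_sizes` (0 where no transcripts).
#' @export
chromosome_density <- function(transcripts, chrom_sizes) {
  sm <- transcript_summary(transcripts)
  unknown <- setdiff(sm$chrom, names(chrom_sizes))
  if (length(unknown) > 0L)
    stop("chromosomes absent from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  counts <- table(factor(sm$chrom, levels = names(chrom_sizes)))
  setNames(as.numeric(counts) / (chrom_sizes / 1e6), names(chrom_sizes))
}
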