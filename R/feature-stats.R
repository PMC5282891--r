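# Genomic and expression features: transcript length, exon count, mean
# conservation over exonic bases, transposable-element overlap, expression
# summaries and Jensen-Shannon tissue specificity, with mRNA-vs-lncRNA
# group comparisons.

#' Length and exon-count summary of a transcript group
#'
#' Lengths are mature lengths (sum of exon lengths, not genomic span). The
#' median uses the standard mean-of-central-pair convention for even group
#' sizes.
#'
#' @param transcripts non-empty transcript table.
#' @return list with `median_len`, `mean_len`, `mean_exons`, `n`.
#' @export
length_exon_summary <- function(transcripts) {
  sm <- transcript_summary(transcripts)
  if (nrow(sm) == 0L) stop("empty transcript group")
  list(median_len = median(sm$length), mean_len = mean(sm$length),
       mean_exons = mean(sm$n_exons), n = nrow(sm))
}

#' Mean conservation score of a transcript
#'
#' Mean of per-base scores over the transcript's exonic bases that carry a
#' score; bases with no score are ignored, and the result is `NA` when no
#' exonic base is scored (such transcripts are excluded from group means
#' rather than counted as zero).
#'
#' @param transcript exon rows of one transcript.
#' @param track score track (see [read_track()]).
#' @return mean score in `[0, 1]`, or `NA`.
#' @export
mean_conservation <- function(transcript, track) {
  tot_base <- 0
  tot_score <- 0
  for (i in seq_len(nrow(transcript))) {
    x <- track[track$chrom == transcript$chrom[i] &
                 track$end > transcript$start[i] &
                 track$start < transcript$end[i], , drop = FALSE]
    if (nrow(x) == 0L) next
    bases <- pmin(x$end, transcript$end[i]) - pmax(x$start, transcript$start[i])
    tot_base <- tot_base + sum(bases)
    tot_score <- tot_score + sum(bases * x$score)
  }
  if (tot_base == 0) NA_real_ else tot_score / tot_base
}

#' Fraction of transcripts overlapping a transposable element
#'
#' Fraction of the group whose exons share at least one base with any
#' repeat interval, strand-blind (repeat annotations are unstranded).
#'
#' @param transcripts transcript table.
#' @param repeats BED-style data frame of repeat intervals (TE class in
#'   `name`).
#' @return fraction in `[0, 1]` (0 for an empty repeat set).
#' @export
te_overlap_fraction <- function(transcripts, repeats) {
  ids <- unique(transcripts$transcript_id)
  if (length(ids) == 0L) return(0)
  if (is.null(repeats) || nrow(repeats) == 0L) return(0)
  rep_tx <- transcript_models(data.frame(
    transcript_id = paste0("REP.", seq_len(nrow(repeats))),
    chrom = repeats$chrom, start = repeats$start, end = repeats$end,
    strand = "*", stringsAsFactors = FALSE))
  hit <- .overlapping_ids(transcripts, rep_tx, "any")
  length(intersect(ids, hit)) / length(ids)
}

#' Per-transcript expression statistic and its group summary
#'
#' The per-transcript statistic is the maximum FPKM over libraries by
#' default (consistent with the expression filter of discovery); the mean
#' over libraries is available as an alternative.
#'
#' @param transcripts transcript table (or character vector of ids).
#' @param expr an `expression_table`.
#' @param statistic `"max"` (default) or `"mean"`.
#' @return list with `median_fpkm`, `mean_fpkm`, `per_transcript` (named
#'   vector), `n`.
#' @export
expression_summary <- function(transcripts, expr, statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  ids <- if (is.character(transcripts)) transcripts
         else unique(transcripts$transcript_id)
  miss <- setdiff(ids, rownames(expr$values))
  if (length(miss) > 0L)
    stop("transcripts missing from expression table: ",
         paste(head(miss, 5L), collapse = ", "))
  v <- apply(expr$values[ids, , drop = FALSE], 1L,
             if (statistic == "max") max else mean)
  list(median_fpkm = median(v), mean_fpkm = mean(v),
       per_transcript = v, n = length(v))
}

.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# base-2 Jensen-Shannon divergence between probability vectors
.jsd2 <- function(p, q) {
  m <- (p + q) / 2
  .entropy2(m) - (.entropy2(p) + .entropy2(q)) / 2
}

#' Jensen-Shannon specificity score of an expression profile
#'
#' Measures how confined a transcript's expression is to one condition.
#' The per-condition mean FPKM vector is normalized to sum 1 to give the
#' expression pattern `p`; for condition `t` with unit pattern `e_t`, the
#' condition score is `1 - sqrt(JSD(p, e_t))` with base-2 Jensen-Shannon
#' divergence, and the transcript score is the maximum over conditions.
#' The score lies in `[0, 1]` and reaches 1 iff expression is confined to a
#' single condition. All-zero profiles give `NA` (excluded, not zero).
#'
#' @param expr_vector named non-negative FPKM vector over libraries.
#' @param condition_partition named list: condition -> library ids, jointly
#'   covering `names(expr_vector)`.
#' @param per_library use per-library values directly instead of condition
#'   means (each library its own pattern column).
#' @return specificity score in `[0, 1]`, or `NA` for an all-zero profile.
#' @export
js_specificity <- function(expr_vector, condition_partition,
                           per_library = FALSE) {
  if (any(expr_vector < 0)) stop("negative expression values")
  libs <- unlist(condition_partition)
  miss <- setdiff(libs, names(expr_vector))
  if (length(miss) > 0L)
    stop("libraries absent from expression vector: ",
         paste(miss, collapse = ", "))
  p <- if (per_library) expr_vector[libs]
       else vapply(condition_partition,
                   function(l) mean(expr_vector[l]), numeric(1L))
  if (sum(p) == 0) return(NA_real_)
  p <- p / sum(p)
  scores <- vapply(seq_along(p), function(t) {
    e <- rep(0, length(p)); e[t] <- 1
    1 - sqrt(.jsd2(p, e))
  }, numeric(1L))
  max(scores)
}

#' Group comparison by two-sample t-test
#'
#' Student's t-test (equal variances) by default; Welch available.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param welch use the Welch unequal-variance variant.
#' @return two-sided p-value.
#' @export
group_compare <- function(values_a, values_b, welch = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  t.test(values_a, values_b, var.equal = !welch)$p.value
}

#' Condition partition of the libraries
#'
#' @param meta library metadata (see [library_metadata()]).
#' @param by `"region"` or `"stage"`.
#' @return named list: condition -> library ids.
#' @export
condition_partition <- function(meta, by = c("region", "stage")) {
  by <- match.arg(by)
  split(meta$library_id, meta[[by]])
}

#' Per-transcript feature table
#'
#' Computes, for every transcript: mature length, exon count, mean
#' conservation (`NA` when no exonic base is scored), TE overlap flag,
#' max- and mean-library FPKM, and the regional and stage Jensen-Shannon
#' specificity scores.
#'
#' @param transcripts transcript table.
#' @param expr an `expression_table` covering the transcripts.
#' @param track conservation score track (or `NULL`).
#' @param repeats repeat intervals (or `NULL`).
#' @return data frame with one row per transcript.
#' @export
feature_table <- function(transcripts, expr, track = NULL, repeats = NULL) {
  sm <- transcript_summary(transcripts)
  ids <- sm$transcript_id
  miss <- setdiff(ids, rownames(expr$values))
  if (length(miss) > 0L)
    stop("transcripts missing from expression table: ",
         paste(head(miss, 5L), collapse = ", "))
  cons <- if (is.null(track)) rep(NA_real_, length(ids)) else
    vapply(ids, function(tid)
      mean_conservation(transcripts[transcripts$transcript_id == tid, ,
                                    drop = FALSE], track), numeric(1L))
  te <- if (is.null(repeats) || nrow(repeats) == 0L)
    rep(FALSE, length(ids))
  else {
    rep_tx <- transcript_models(data.frame(
      transcript_id = paste0("REP.", seq_len(nrow(repeats))),
      chrom = repeats$chrom, start = repeats$start, end = repeats$end,
      strand = "*", stringsAsFactors = FALSE))
    ids %in% .overlapping_ids(transcripts, rep_tx, "any")
  }
  v <- expr$values[ids, , drop = FALSE]
  region <- condition_partition(expr$meta, "region")
  stage <- condition_partition(expr$meta, "stage")
  js_r <- apply(v, 1L, js_specificity, condition_partition = region)
  js_s <- apply(v, 1L, js_specificity, condition_partition = stage)
  data.frame(transcript_id = ids,
             length = sm$length,
             n_exons = sm$n_exons,
             mean_conservation = unname(cons),
             te_overlap = te,
             max_fpkm = apply(v, 1L, max),
             mean_fpkm = apply(v, 1L, mean),
             js_region = unname(js_r),
             js_stage = unname(js_s),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-group feature summary
#'
#' Summarizes a [feature_table()] by group (e.g. mRNA / lincRNA / intronic /
#' lncNAT): median and mean length, mean exon count, mean of per-transcript
#' mean conservation (scored transcripts only), TE-overlap fraction, median
#' and mean max-library FPKM, and mean regional/stage specificity.
#'
#' @param features a [feature_table()].
#' @param groups named group label vector indexed by transcript id (or a
#'   vector aligned with `features` rows).
#' @return data frame with one row per group.
#' @export
feature_group_summary <- function(features, groups) {
  g <- if (!is.null(names(groups))) groups[features$transcript_id]
       else groups
  parts <- split(features, g)
  do.call(rbind, lapply(names(parts), function(grp) {
    f <- parts[[grp]]
    data.frame(group = grp,
               n = nrow(f),
               median_len = median(f$length),
               mean_len = mean(f$length),
               mean_exons = mean(f$n_exons),
               mean_conservation = if (all(is.na(f$mean_conservation)))
                 NA_real_ else mean(f$mean_conservation, na.rm = TRUE),
               te_fraction = mean(f$te_overlap),
               median_max_fpkm = median(f$max_fpkm),
               mean_max_fpkm = mean(f$max_fpkm),
               mean_js_region = mean(f$js_region, na.rm = TRUE),
               mean_js_stage = mean(f$js_stage, na.rm = TRUE),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
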