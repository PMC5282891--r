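# Differential expression between pooled library groups with an empirical
# noise-distribution probability: the signal (M, D) of each transcript is
# compared against the cloud of (M, D) values observed between replicate
# libraries of the same condition, and q is the fraction of the noise cloud
# the signal strictly dominates. Transcripts with q > 0.7 are called
# differentially expressed. An externally computed q table can be plugged
# in instead.

#' Define a pooled comparison scheme
#'
#' @param name scheme name.
#' @param group_a,group_b disjoint, non-empty library id vectors.
#' @return a `comparison_scheme` list.
#' @export
comparison_scheme <- function(name, group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("comparison groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0L)
    stop("comparison groups must be disjoint")
  structure(list(name = name, group_a = group_a, group_b = group_b),
            class = "comparison_scheme")
}

#' Build the standard comparison schemes from library metadata
#'
#' Regional schemes pool consecutive-stage libraries of each region and
#' compare AD against PD (for the six-library design: `E8A + E9A` vs
#' `E8P + E9P` and `E9A + E12A` vs `E9P + E12P`). Temporal schemes compare
#' stages pairwise within each region. Regions or stages missing from the
#' metadata simply yield fewer schemes.
#'
#' @param meta library metadata (see [library_metadata()]).
#' @return named list of `comparison_scheme` objects, regional first.
#' @export
build_schemes <- function(meta) {
  schemes <- list()
  stages <- unique(meta$stage)
  regions <- unique(meta$region)
  lib <- function(region, stage)
    meta$library_id[meta$region == region & meta$stage == stage]
  if (all(c("AD", "PD") %in% regions) && length(stages) >= 2L) {
    for (i in seq_len(length(stages) - 1L)) {
      st <- stages[c(i, i + 1L)]
      a <- unlist(lapply(st, lib, region = "AD"))
      b <- unlist(lapply(st, lib, region = "PD"))
      nm <- paste0("regional_", paste(st, collapse = "_"))
      schemes[[nm]] <- comparison_scheme(nm, a, b)
    }
  }
  for (r in regions) {
    for (i in seq_len(max(length(stages) - 1L, 0L))) {
      for (j in seq.int(i + 1L, length(stages))) {
        a <- lib(r, stages[i]); b <- lib(r, stages[j])
        if (length(a) == 0L || length(b) == 0L) next
        nm <- paste0("temporal_", r, "_", stages[i], "_", stages[j])
        schemes[[nm]] <- comparison_scheme(nm, a, b)
      }
    }
  }
  schemes
}

#' Signal statistic (M, D) of a pooled comparison
#'
#' `M = log2((mean_a + c) / (mean_b + c))` and `D = |mean_a - mean_b|`,
#' where the means are over the scheme's library groups and `c` is a
#' pseudocount guarding the ratio (default 0.5).
#'
#' @param expr an `expression_table`.
#' @param scheme a `comparison_scheme`.
#' @param pseudocount ratio pseudocount.
#' @return data frame `transcript_id`, `M`, `D`.
#' @export
md_statistic <- function(expr, scheme, pseudocount = 0.5) {
  miss <- setdiff(c(scheme$group_a, scheme$group_b), colnames(expr$values))
  if (length(miss) > 0L)
    stop("scheme libraries absent from expression table: ",
         paste(miss, collapse = ", "))
  ma <- rowMeans(expr$values[, scheme$group_a, drop = FALSE])
  mb <- rowMeans(expr$values[, scheme$group_b, drop = FALSE])
  data.frame(transcript_id = rownames(expr$values),
             M = log2((ma + pseudocount) / (mb + pseudocount)),
             D = abs(ma - mb), row.names = NULL, stringsAsFactors = FALSE)
}

#' Within-condition library pairs for the noise distribution
#'
#' All unordered library pairs sharing the same condition (region by
#' default), i.e. the pairs treated as replicates when computing the noise
#' cloud.
#'
#' @param meta library metadata.
#' @param by condition column (`"region"` or `"stage"`).
#' @return data frame `lib_a`, `lib_b`.
#' @export
replicate_pairs <- function(meta, by = "region") {
  out <- list()
  for (cond in unique(meta[[by]])) {
    libs <- meta$library_id[meta[[by]] == cond]
    if (length(libs) < 2L) next
    for (i in seq_len(length(libs) - 1L))
      for (j in seq.int(i + 1L, length(libs)))
        out[[length(out) + 1L]] <- data.frame(lib_a = libs[i],
                                              lib_b = libs[j],
                                              stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(lib_a = character(0L), lib_b = character(0L),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Empirical noise distribution of (M, D)
#'
#' Computes one `(M0, D0)` point per transcript per within-condition
#' library pair, pooled over pairs: the spread of (M, D) attributable to
#' replicate-level noise alone.
#'
#' @param expr an `expression_table`.
#' @param pairs data frame `lib_a`, `lib_b` (see [replicate_pairs()]).
#' @param pseudocount ratio pseudocount.
#' @return data frame `M0`, `D0` with `nrow(expr) * nrow(pairs)` rows.
#' @export
noise_null <- function(expr, pairs, pseudocount = 0.5) {
  if (nrow(pairs) == 0L)
    stop("no within-condition library pairs available")
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- expr$values[, pairs$lib_a[i]]
    b <- expr$values[, pairs$lib_b[i]]
    data.frame(M0 = log2((a + pseudocount) / (b + pseudocount)),
               D0 = abs(a - b), row.names = NULL)
  })
  do.call(rbind, out)
}

#' Probability of differential expression from strict dominance
#'
#' `q` is the fraction of noise points `(M0, D0)` strictly dominated by the
#' signal: `|M0| < |M|` and `D0 < D`. It is 0 for a null-like signal, 1 for
#' a signal beyond every noise point, and monotone non-decreasing in `|M|`
#' and `D`.
#'
#' @param M,D signal statistics (vectors of equal length).
#' @param null noise cloud from [noise_null()].
#' @return numeric vector of q values in `[0, 1]`.
#' @export
q_probability <- function(M, D, null) {
  if (nrow(null) == 0L) stop("empty noise cloud")
  absM0 <- abs(null$M0)
  vapply(seq_along(M), function(i) {
    mean(absM0 < abs(M[i]) & null$D0 < D[i])
  }, numeric(1L))
}

#' Call differentially expressed transcripts for one scheme
#'
#' Computes (M, D) for the scheme, the noise cloud from within-condition
#' pairs, the dominance probability q, and the call `q > q_threshold`.
#' Alternatively, a pre-computed `external_q` table (columns
#' `transcript_id`, `q`) replaces the internal probability, so output from
#' a dedicated differential-expression engine can be substituted.
#'
#' @param expr an `expression_table`.
#' @param scheme a `comparison_scheme`.
#' @param pairs within-condition pairs (default [replicate_pairs()] on the
#'   region condition).
#' @param q_threshold call threshold (strict, default 0.7).
#' @param pseudocount ratio pseudocount.
#' @param external_q optional data frame `transcript_id`, `q`.
#' @return data frame `transcript_id`, `M`, `D`, `q`, `call`.
#' @export
deg_call <- function(expr, scheme, pairs = replicate_pairs(expr$meta),
                     q_threshold = 0.7, pseudocount = 0.5,
                     external_q = NULL) {
  md <- md_statistic(expr, scheme, pseudocount)
  if (is.null(external_q)) {
    null <- noise_null(expr, pairs, pseudocount)
    md$q <- q_probability(md$M, md$D, null)
  } else {
    i <- match(md$transcript_id, external_q$transcript_id)
    if (anyNA(i))
      stop("external q table is missing transcripts: ",
           paste(head(md$transcript_id[is.na(i)], 5L), collapse = ", "))
    md$q <- external_q$q[i]
  }
  md$call <- md$q > q_threshold
  md
}
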