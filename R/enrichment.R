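# Per-cluster term enrichment (one-sided Fisher/hypergeometric test with
# Benjamini-Hochberg correction) and three-criterion candidate selection:
# cluster membership, regional differential expression, and cross-species
# same-chromosome sequence similarity.

#' Term enrichment of a cluster by Fisher's exact test
#'
#' For every term with at least one gene in the cluster, tests
#' over-representation with the one-sided hypergeometric tail
#' (`P[X >= k]` for `k` term genes among `n` cluster genes, `K` term genes
#' in a background of `N`), then adjusts across the cluster's terms by
#' Benjamini-Hochberg. `significant = (p < p_cutoff) & (fdr < fdr_cutoff)`
#' with the conventional cutoffs 0.01 and 0.05.
#'
#' @param cluster_genes character vector, subset of `background_genes`.
#' @param background_genes character vector of all genes considered.
#' @param term_map data frame `gene_id`, `term_id` (optionally `term_name`).
#' @param p_cutoff,fdr_cutoff significance cutoffs (strict).
#' @return data frame `term_id`, `k`, `n`, `K`, `N`, `p`, `fdr`,
#'   `significant`, ordered by p.
#' @export
fisher_enrichment <- function(cluster_genes, background_genes, term_map,
                              p_cutoff = 0.01, fdr_cutoff = 0.05) {
  if (length(background_genes) == 0L) stop("empty background")
  extra <- setdiff(cluster_genes, background_genes)
  if (length(extra) > 0L)
    stop("cluster genes outside the background: ",
         paste(head(extra, 5L), collapse = ", "))
  tm <- term_map[term_map$gene_id %in% background_genes, , drop = FALSE]
  tm <- unique(tm[, c("gene_id", "term_id")])
  N <- length(unique(background_genes))
  n <- length(unique(cluster_genes))
  by_term <- split(tm$gene_id, tm$term_id)
  rows <- lapply(names(by_term), function(term) {
    genes <- by_term[[term]]
    k <- length(intersect(genes, cluster_genes))
    if (k == 0L) return(NULL)
    K <- length(genes)
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L)
    return(data.frame(term_id = character(0L), k = integer(0L),
                      n = integer(0L), K = integer(0L), N = integer(0L),
                      p = numeric(0L), fdr = numeric(0L),
                      significant = logical(0L), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$fdr <- p.adjust(res$p, method = "BH")
  res$significant <- res$p < p_cutoff & res$fdr < fdr_cutoff
  res[order(res$p, res$term_id), , drop = FALSE]
}

#' Enrichment across all clusters
#'
#' Runs [fisher_enrichment()] for each cluster label, adjusting within each
#' cluster across its terms.
#'
#' @param clusters named cluster label vector (gene id -> label).
#' @param term_map data frame `gene_id`, `term_id`.
#' @param background_genes background (default: all clustered genes).
#' @param ... passed to [fisher_enrichment()].
#' @return data frame with a leading `cluster` column.
#' @export
cluster_enrichment <- function(clusters, term_map,
                               background_genes = names(clusters), ...) {
  out <- lapply(sort(unique(clusters)), function(lab) {
    res <- fisher_enrichment(names(clusters)[clusters == lab],
                             background_genes, term_map, ...)
    if (nrow(res) == 0L) return(NULL)
    cbind(cluster = lab, res, stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0L)
    return(data.frame(cluster = character(0L), term_id = character(0L),
                      k = integer(0L), n = integer(0L), K = integer(0L),
                      N = integer(0L), p = numeric(0L), fdr = numeric(0L),
                      significant = logical(0L), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.check_dna <- function(s) {
  if (grepl("[^ACGTN]", s)) stop("sequence has non-ACGTN symbols")
  s
}

.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# best ungapped similarity between two sequences: for every diagonal
# holding an exact k-mer seed, slide a window of win_len and keep windows
# with identity >= min_identity; the best window is extended greedily while
# identity stays above the threshold.
.ungapped_hit <- function(q, t, k, win_len, min_identity) {
  nq <- nchar(q); nt <- nchar(t)
  if (nq < win_len || nt < win_len) return(NULL)
  qk <- substring(q, seq_len(nq - k + 1L), seq_len(nq - k + 1L) + k - 1L)
  tk <- substring(t, seq_len(nt - k + 1L), seq_len(nt - k + 1L) + k - 1L)
  tpos <- split(seq_along(tk), tk)
  diags <- unique(unlist(lapply(seq_along(qk), function(i) {
    j <- tpos[[qk[i]]]
    if (is.null(j)) return(NULL)
    j - i
  })))
  if (length(diags) == 0L) return(NULL)
  qc <- strsplit(q, "")[[1L]]
  tc <- strsplit(t, "")[[1L]]
  best <- NULL
  for (dg in sort(diags)) {
    lo_q <- max(1L, 1L - dg); hi_q <- min(nq, nt - dg)
    len <- hi_q - lo_q + 1L
    if (len < win_len) next
    match_vec <- qc[lo_q:hi_q] == tc[(lo_q + dg):(hi_q + dg)] &
      qc[lo_q:hi_q] != "N"
    cs <- c(0L, cumsum(match_vec))
    wins <- seq_len(len - win_len + 1L)
    ident <- (cs[wins + win_len] - cs[wins]) / win_len
    ok <- which(ident >= min_identity)
    if (length(ok) == 0L) next
    w <- ok[which.max(ident[ok])]
    a <- w; b <- w + win_len - 1L
    matches <- cs[b + 1L] - cs[a]
    repeat {
      grown <- FALSE
      if (a > 1L && (matches + match_vec[a - 1L]) / (b - a + 2L) >= min_identity) {
        a <- a - 1L; matches <- matches + match_vec[a]; grown <- TRUE
      }
      if (b < len && (matches + match_vec[b + 1L]) / (b - a + 2L) >= min_identity) {
        b <- b + 1L; matches <- matches + match_vec[b]; grown <- TRUE
      }
      if (!grown) break
    }
    cand <- list(length = b - a + 1L, identity = matches / (b - a + 1L),
                 q_start = lo_q + a - 1L, t_start = lo_q + a - 1L + dg)
    if (is.null(best) || cand$identity > best$identity ||
        (cand$identity == best$identity && cand$length > best$length))
      best <- cand
  }
  best
}

#' Cross-species sequence similarity hits
#'
#' Finds, for every query lncRNA, target catalog sequences sharing an
#' ungapped similar region: an exact k-mer seed (default k = 11) must
#' extend ungapped to at least `min_length` bases (default 50) at identity
#' at least `min_identity` (default 0.8). The chromosome-match flag records
#' whether the query chromosome maps to the target's chromosome under the
#' supplied homology table.
#'
#' @param query_seqs named [Biostrings::DNAStringSet] (or character vector)
#'   of query lncRNA sequences.
#' @param query_chroms named chromosome vector for the queries.
#' @param target_seqs named sequences of the second-species catalog.
#' @param target_catalog data frame `target_id`, `chrom`.
#' @param homology_map data frame `query_chrom`, `target_chrom`.
#' @param k seed length.
#' @param min_length minimum hit length (nt).
#' @param min_identity minimum hit identity.
#' @param both_strands also search the reverse complement of each query.
#' @return data frame `query_id`, `target_id`, `strand`, `length`,
#'   `identity`, `chrom_match`.
#' @export
cross_species_hits <- function(query_seqs, query_chroms, target_seqs,
                               target_catalog, homology_map,
                               k = 11L, min_length = 50L, min_identity = 0.8,
                               both_strands = TRUE) {
  qs <- if (is.character(query_seqs)) query_seqs
        else setNames(as.character(query_seqs), names(query_seqs))
  ts <- if (is.character(target_seqs)) target_seqs
        else setNames(as.character(target_seqs), names(target_seqs))
  lapply(c(qs, ts), .check_dna)
  out <- list()
  for (qid in names(qs)) {
    variants <- list(`+` = qs[[qid]])
    if (both_strands) variants$`-` <- .revcomp(qs[[qid]])
    for (tid in names(ts)) {
      for (strand in names(variants)) {
        hit <- .ungapped_hit(variants[[strand]], ts[[tid]], k, min_length,
                             min_identity)
        if (is.null(hit)) next
        t_chrom <- target_catalog$chrom[target_catalog$target_id == tid]
        exp_chrom <- homology_map$target_chrom[
          homology_map$query_chrom == query_chroms[[qid]]]
        out[[length(out) + 1L]] <- data.frame(
          query_id = qid, target_id = tid, strand = strand,
          length = hit$length, identity = hit$identity,
          chrom_match = length(t_chrom) > 0L && length(exp_chrom) > 0L &&
            t_chrom[1L] %in% exp_chrom,
          stringsAsFactors = FALSE)
        break  # one hit per (query, target) suffices; prefer plus strand
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(query_id = character(0L), target_id = character(0L),
                      strand = character(0L), length = integer(0L),
                      identity = numeric(0L), chrom_match = logical(0L),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Select candidate lncRNAs by the three-criterion rule
#'
#' A lncRNA is a candidate iff (1) its co-expression cluster is one of the
#' selected clusters, (2) it is called differentially expressed in at least
#' one regional comparison, and (3) it has at least one cross-species hit
#' on the homologous chromosome. All three flags are reported per lncRNA.
#'
#' @param ids lncRNA transcript ids.
#' @param cluster_assignment named cluster label vector covering `ids`.
#' @param selected_clusters cluster labels satisfying criterion 1.
#' @param deg_results data frame (or list of data frames) with
#'   `transcript_id` and `call` from regional [deg_call()]s.
#' @param hits data frame from [cross_species_hits()].
#' @return data frame `transcript_id`, `cluster`, `in_selected_cluster`,
#'   `regional_de`, `cross_species`, `candidate`.
#' @export
select_candidates <- function(ids, cluster_assignment, selected_clusters,
                              deg_results, hits) {
  if (is.data.frame(deg_results)) deg_results <- list(deg_results)
  miss <- setdiff(ids, names(cluster_assignment))
  if (length(miss) > 0L)
    stop("ids missing from cluster assignment: ",
         paste(head(miss, 5L), collapse = ", "))
  for (dr in deg_results) {
    miss <- setdiff(ids, dr$transcript_id)
    if (length(miss) > 0L)
      stop("ids missing from differential-expression results: ",
           paste(head(miss, 5L), collapse = ", "))
  }
  de_any <- Reduce(`|`, lapply(deg_results, function(dr)
    setNames(dr$call, dr$transcript_id)[ids]))
  cl <- cluster_assignment[ids]
  in_cl <- cl %in% selected_clusters
  xs <- ids %in% hits$query_id[hits$chrom_match]
  data.frame(transcript_id = ids,
             cluster = unname(cl),
             in_selected_cluster = in_cl,
             regional_de = unname(de_any),
             cross_species = xs,
             candidate = in_cl & unname(de_any) & xs,
             row.names = NULL, stringsAsFactors = FALSE)
}
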