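# Independent brute-force oracles used to cross-check the implementation,
# plus small fixture builders. Oracles deliberately use per-base
# enumeration and naive algorithms, never the code paths they check.

# exonic bases of one transcript as a set of "chrom:strand:base" keys
oracle_base_set <- function(tx, id, strand_blind = FALSE) {
  ex <- tx[tx$transcript_id == id, , drop = FALSE]
  unlist(lapply(seq_len(nrow(ex)), function(i) {
    b <- seq.int(ex$start[i], ex$end[i] - 1L)
    st <- if (strand_blind) "." else ex$strand[i]
    paste(ex$chrom[i], st, b)
  }))
}

# number of shared exonic bases between two transcripts under a strand mode
oracle_overlap_bases <- function(tx_a, id_a, tx_b, id_b,
                                 mode = c("same", "opposite", "any")) {
  mode <- match.arg(mode)
  a <- tx_a[tx_a$transcript_id == id_a, , drop = FALSE]
  b <- tx_b[tx_b$transcript_id == id_b, , drop = FALSE]
  sa <- a$strand[1L]; sb <- b$strand[1L]
  ok <- switch(mode,
    same = sa == sb && sa != "*",
    opposite = (sa == "+" && sb == "-") || (sa == "-" && sb == "+"),
    any = TRUE)
  if (!ok) return(0L)
  ka <- oracle_base_set(a, id_a, strand_blind = TRUE)
  kb <- oracle_base_set(b, id_b, strand_blind = TRUE)
  length(intersect(ka, kb))
}

# single-linkage merge groups by union-find over pairwise exon-base overlap
oracle_merge_groups <- function(tx) {
  ids <- unique(tx$transcript_id)
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  n <- length(ids)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (oracle_overlap_bases(tx, ids[i], tx, ids[j], "same") > 0L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  unname(lapply(split(ids, roots), sort))
}

# hypergeometric upper tail P[X >= k] by direct summation
oracle_hyper_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg by the textbook sort / scale / cummin recipe
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# strict-dominance q by double loop
oracle_q <- function(M, D, null) {
  vapply(seq_along(M), function(i) {
    cnt <- 0L
    for (j in seq_len(nrow(null)))
      if (abs(null$M0[j]) < abs(M[i]) && null$D0[j] < D[i]) cnt <- cnt + 1L
    cnt / nrow(null)
  }, numeric(1L))
}

# JS specificity by direct base-2 entropy computation
oracle_js <- function(v, partition) {
  p <- vapply(partition, function(l) mean(v[l]), numeric(1L))
  if (sum(p) == 0) return(NA_real_)
  p <- p / sum(p)
  H <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  max(vapply(seq_along(p), function(t) {
    e <- rep(0, length(p)); e[t] <- 1
    m <- (p + e) / 2
    1 - sqrt(H(m) - (H(p) + H(e)) / 2)
  }, numeric(1L)))
}

# mean conservation by per-base lookup over exonic bases
oracle_mean_conservation <- function(tx, id, track) {
  ex <- tx[tx$transcript_id == id, , drop = FALSE]
  scores <- unlist(lapply(seq_len(nrow(ex)), function(i)
    track_scores(track, ex$chrom[i], ex$start[i], ex$end[i])))
  if (all(is.na(scores))) NA_real_ else mean(scores, na.rm = TRUE)
}

# TE fraction by per-base membership
oracle_te_fraction <- function(tx, repeats) {
  ids <- unique(tx$transcript_id)
  rep_bases <- unlist(lapply(seq_len(nrow(repeats)), function(i)
    paste(repeats$chrom[i], seq.int(repeats$start[i], repeats$end[i] - 1L))))
  hit <- vapply(ids, function(id) {
    ex <- tx[tx$transcript_id == id, , drop = FALSE]
    bases <- unlist(lapply(seq_len(nrow(ex)), function(i)
      paste(ex$chrom[i], seq.int(ex$start[i], ex$end[i] - 1L))))
    any(bases %in% rep_bases)
  }, logical(1L))
  mean(hit)
}

# naive ORF score by exhaustive scan over all ATG positions
oracle_orf_score <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  best <- 0L
  for (start in seq_len(max(n - 5L, 0L))) {
    if (substr(s, start, start + 2L) != "ATG") next
    pos <- start + 3L
    while (pos + 2L <= n) {
      codon <- substr(s, pos, pos + 2L)
      if (codon %in% c("TAA", "TAG", "TGA")) {
        len <- pos + 2L - start + 1L
        # only the first in-frame stop terminates this ORF
        best <- max(best, len)
        break
      }
      pos <- pos + 3L
    }
  }
  if (best == 0L) -1 else 2 * best / n - 1
}

# cross-species hit decision by all-diagonal, all-window enumeration
oracle_has_hit <- function(q, t, k, win_len, min_identity) {
  qc <- strsplit(toupper(q), "")[[1L]]
  tc <- strsplit(toupper(t), "")[[1L]]
  nq <- length(qc); nt <- length(tc)
  for (dg in seq.int(-(nq - 1L), nt - 1L)) {
    lo <- max(1L, 1L - dg); hi <- min(nq, nt - dg)
    if (hi - lo + 1L < win_len) next
    mv <- qc[lo:hi] == tc[(lo + dg):(hi + dg)] & qc[lo:hi] != "N"
    len <- length(mv)
    for (a in seq_len(len - win_len + 1L)) {
      w <- mv[a:(a + win_len - 1L)]
      if (mean(w) < min_identity) next
      # window must contain an exact k-mer seed
      runs <- rle(w)
      if (any(runs$values & runs$lengths >= k)) return(TRUE)
    }
  }
  FALSE
}

# small random multi-exon transcript on one chromosome
random_transcript <- function(id, chrom = "chr1", max_pos = 2000L,
                              strand = sample(c("+", "-"), 1L)) {
  n_ex <- sample(1:3, 1L)
  starts <- sort(sample(seq.int(0L, max_pos - 60L, by = 10L), n_ex))
  lens <- sample(10:50, n_ex, replace = TRUE)
  ends <- starts + lens
  # enforce non-overlap of adjacent exons
  if (n_ex > 1L) for (i in 2:n_ex) {
    if (starts[i] < ends[i - 1L]) starts[i] <- ends[i - 1L] + 5L
    ends[i] <- starts[i] + lens[i]
  }
  data.frame(transcript_id = id, gene_id = id, chrom = chrom,
             start = starts, end = ends, strand = strand,
             biotype = "unannotated", stringsAsFactors = FALSE)
}

random_transcript_set <- function(n, chrom = "chr1", max_pos = 2000L) {
  transcript_models(do.call(rbind, lapply(seq_len(n), function(i)
    random_transcript(sprintf("T%02d", i), chrom, max_pos))))
}

# tiny deterministic synthetic study shared across test files
tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_synthetic_study(synthetic_config(
        seed = 42L, n_chromosomes = 2L, chrom_length_bp = 300000L,
        n_coding_genes = 16L,
        planted_counts = c(lincRNA = 10L, intronic = 4L, lncNAT = 4L,
                           coding_fragment = 5L, unstranded = 3L,
                           short_decoy = 3L, lowexpr_decoy = 3L),
        fpkm_noise_cv = 0, de_fraction = 0.2))
    cache
  }
})
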