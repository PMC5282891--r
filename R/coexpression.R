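# Co-expression clustering: expressed filter, z-scaling, WPGMA
# agglomeration on correlation distance, tree cut.

#' Expressed-transcript filter
#'
#' An expressed transcript has FPKM strictly greater than `threshold`
#' (default 1) in at least one library.
#'
#' @param expr an `expression_table`.
#' @param threshold strict FPKM threshold.
#' @return character vector of expressed transcript ids.
#' @export
expressed_filter <- function(expr, threshold = 1) {
  rownames(expr$values)[apply(expr$values, 1L, max) > threshold]
}

#' Z-scale expression profiles across libraries
#'
#' Centers and scales each transcript's profile to mean 0 and standard
#' deviation 1 across libraries. The population convention (divisor `n`) is
#' the default; the sample convention (`n - 1`) is available. Zero-variance
#' profiles are mapped to all-zeros with a warning.
#'
#' @param expr an `expression_table`.
#' @param ids transcripts to scale (default all).
#' @param sample_sd use divisor `n - 1`.
#' @return numeric matrix of scaled profiles (rows = transcripts).
#' @export
zscale <- function(expr, ids = rownames(expr$values), sample_sd = FALSE) {
  m <- expr$values[ids, , drop = FALSE]
  if (ncol(m) < 2L) stop("z-scaling needs at least 2 libraries")
  mu <- rowMeans(m)
  cent <- m - mu
  div <- if (sample_sd) ncol(m) - 1L else ncol(m)
  s <- sqrt(rowSums(cent^2) / div)
  flat <- s == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance profile(s) mapped to all-zeros")
    s[flat] <- 1
  }
  out <- cent / s
  out[flat, ] <- 0
  out
}

# pairwise distances between profile rows
.profile_dist <- function(m, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  if (metric == "correlation") {
    # zero-variance rows (all-zero after scaling) are maximally distant
    # from everything except each other
    s <- apply(m, 1L, sd)
    d <- matrix(1, nrow(m), nrow(m))
    ok <- s > 0
    if (sum(ok) >= 2L)
      d[ok, ok] <- 1 - cor(t(m[ok, , drop = FALSE]))
    if (any(!ok)) d[!ok, !ok] <- 0
    diag(d) <- 0
    d
  } else {
    as.matrix(dist(m))
  }
}

#' WPGMA hierarchical clustering with tree cut
#'
#' Agglomerates expression profiles by WPGMA (weighted pair-group method
#' with arithmetic mean: the distance from a new node to any other node is
#' the plain average of its two children's distances) on correlation
#' distance `1 - Pearson(r)` between profiles (Euclidean available).
#' Minimum-distance ties are broken by the first minimal pair in node
#' creation order (input order, then merge order), making the merge order
#' deterministic. Clusters are
#' the connected components obtained by discarding merges at height
#' strictly greater than `cut`; labels are assigned in order of each
#' cluster's first member in the input.
#'
#' @param m numeric matrix of (typically z-scaled) profiles with rownames.
#' @param cut tree cut height (default 0.69, on the correlation-distance
#'   scale).
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @return a `cluster_assignment` list: `clusters` (named label vector),
#'   `merges` (data frame `step`, `left`, `right`, `height`), `cut`,
#'   `n_clusters`.
#' @export
wpgma_cluster <- function(m, cut = 0.69, metric = "correlation") {
  ids <- rownames(m)
  if (is.null(ids)) stop("profile matrix needs rownames")
  n <- length(ids)
  if (n < 2L) {
    cl <- setNames(rep("C1", n), ids)
    return(structure(list(clusters = cl,
                          merges = data.frame(step = integer(0L),
                                              left = character(0L),
                                              right = character(0L),
                                              height = numeric(0L)),
                          cut = cut, n_clusters = as.integer(n > 0L)),
                     class = "cluster_assignment"))
  }
  d <- .profile_dist(m, metric)
  dimnames(d) <- list(ids, ids)
  active <- ids
  node_members <- setNames(as.list(ids), ids)
  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    sub <- d[active, active, drop = FALSE]
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      # strict < keeps the lexicographically first minimal pair
      if (sub[i, j] < bestd) { bestd <- sub[i, j]; best <- c(i, j) }
    }
    a <- active[best[1L]]; b <- active[best[2L]]
    new_id <- paste0("N", step)
    # WPGMA merge rule: d(k, a+b) = (d(k, a) + d(k, b)) / 2
    others <- setdiff(active, c(a, b))
    newd <- (d[a, others] + d[b, others]) / 2
    d <- rbind(cbind(d, 0), 0)
    rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- new_id
    d[new_id, others] <- newd
    d[others, new_id] <- newd
    node_members[[new_id]] <- c(node_members[[a]], node_members[[b]])
    merges[[step]] <- data.frame(step = step, left = a, right = b,
                                 height = bestd, stringsAsFactors = FALSE)
    active <- c(others, new_id)
  }
  merges <- do.call(rbind, merges)

  # cut: union the leaves of merges with height <= cut
  parent <- setNames(seq_len(n), ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  idx <- setNames(seq_len(n), ids)
  memb <- merges[merges$height <= cut, , drop = FALSE]
  for (s in seq_len(nrow(memb))) {
    la <- node_members[[memb$left[s]]]
    lb <- node_members[[memb$right[s]]]
    ra <- find(idx[la[1L]]); rb <- find(idx[lb[1L]])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), find, numeric(1L))
  labels <- setNames(match(roots, unique(roots)), ids)
  structure(list(clusters = setNames(paste0("C", labels), ids),
                 merges = merges, cut = cut,
                 n_clusters = length(unique(labels))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", length(x$clusters), "items in", x$n_clusters,
      "clusters (cut =", x$cut, ")\n")
  print(table(x$clusters))
  invisible(x)
}

#' Cluster expressed transcripts end to end
#'
#' Convenience wrapper: expressed filter, z-scaling, WPGMA, cut.
#'
#' @param expr an `expression_table`.
#' @param threshold expressed-filter threshold (strict, default 1).
#' @param cut tree cut height (default 0.69).
#' @param metric distance metric for [wpgma_cluster()].
#' @return a `cluster_assignment` (over the expressed transcripts only).
#' @export
cluster_expression <- function(expr, threshold = 1, cut = 0.69,
                               metric = "correlation") {
  ids <- expressed_filter(expr, threshold)
  if (length(ids) == 0L)
    return(structure(list(clusters = setNames(character(0L), character(0L)),
                          merges = data.frame(step = integer(0L),
                                              left = character(0L),
                                              right = character(0L),
                                              height = numeric(0L)),
                          cut = cut, n_clusters = 0L),
                     class = "cluster_assignment"))
  wpgma_cluster(zscale(expr, ids), cut = cut, metric = metric)
}
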