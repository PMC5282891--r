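test_that("Fisher enrichment equals the hypergeometric tail oracle", {
  bg <- paste0("g", 1:100)
  cl <- paste0("g", 1:10)
  tm <- data.frame(gene_id = paste0("g", 1:10), term_id = "T1",
                   stringsAsFactors = FALSE)
  res <- fisher_enrichment(cl, bg, tm)
  # k = 5? no: all 10 term genes in the cluster of 10
  expect_equal(res$k, 10L)
  expect_equal(res$p, oracle_hyper_tail(10, 10, 10, 100), tolerance = 1e-12)

  # textbook table: k=5, n=10, K=10, N=100 via direct summation
  tm2 <- data.frame(gene_id = c(paste0("g", 1:5), paste0("g", 51:55)),
                    term_id = "T2", stringsAsFactors = FALSE)
  res2 <- fisher_enrichment(cl, bg, tm2)
  expect_equal(res2$k, 5L)
  expect_equal(res2$p, oracle_hyper_tail(5, 10, 10, 100), tolerance = 1e-12)
  # and against fisher.test's one-sided p
  ft <- fisher.test(matrix(c(5, 5, 5, 85), nrow = 2), alternative = "greater")
  expect_equal(res2$p, ft$p.value, tolerance = 1e-9)

  # a term covering the whole background has p = 1
  tm3 <- data.frame(gene_id = bg, term_id = "ALL", stringsAsFactors = FALSE)
  expect_equal(fisher_enrichment(cl, bg, tm3)$p, 1)
  expect_error(fisher_enrichment(cl, character(0L), tm), "empty background")
  expect_error(fisher_enrichment(c(cl, "outsider"), bg, tm), "outside")
})

test_that("Fisher p equals direct summation on random small tables", {
  withr::local_seed(701)
  for (trial in 1:60) {
    N <- sample(20:200, 1L)
    bg <- paste0("g", seq_len(N))
    n <- sample(3:(N %/% 2), 1L)
    K <- sample(2:(N %/% 2), 1L)
    cl <- sample(bg, n)
    term_genes <- sample(bg, K)
    tm <- data.frame(gene_id = term_genes, term_id = "T",
                     stringsAsFactors = FALSE)
    res <- fisher_enrichment(cl, bg, tm)
    k <- length(intersect(cl, term_genes))
    if (k == 0L) {
      expect_equal(nrow(res), 0L)
    } else {
      expect_equal(res$p, oracle_hyper_tail(k, n, K, N), tolerance = 1e-10)
    }
  }
})

test_that("BH adjustment matches the closed form and its monotonicity", {
  tm <- NULL
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               c(0.03, 0.03, 0.03))
  withr::local_seed(702)
  for (trial in 1:40) {
    p <- runif(sample(3:15, 1L))
    adj <- p.adjust(p, method = "BH")
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("enrichment significance combines raw p and FDR cutoffs", {
  withr::local_seed(703)
  bg <- paste0("g", 1:60)
  clusters <- setNames(rep(c("A", "B"), each = 30), bg)
  tm <- data.frame(
    gene_id = c(paste0("g", 1:12), sample(bg, 30)),
    term_id = rep(c("T1", "T2"), c(12, 30)), stringsAsFactors = FALSE)
  res <- cluster_enrichment(clusters, tm)
  expect_true(all(res$fdr >= res$p - 1e-15))
  expect_equal(res$significant, res$p < 0.01 & res$fdr < 0.05)
  expect_true(all(res$k <= pmin(res$n, res$K)))
})

test_that("cross-species search finds planted similarity and respects strand", {
  withr::local_seed(704)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
             collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  qmap <- data.frame(query_chrom = "chr1", target_chrom = "gga_chr1",
                     stringsAsFactors = FALSE)
  cat1 <- data.frame(target_id = c("h1", "h2"),
                     chrom = c("gga_chr1", "gga_chr9"),
                     stringsAsFactors = FALSE)
  hits <- cross_species_hits(setNames(s, "q1"), c(q1 = "chr1"),
                             setNames(c(s, rc), c("h1", "h2")), cat1, qmap)
  h1 <- hits[hits$target_id == "h1", ]
  expect_equal(h1$identity, 1.0)
  expect_equal(h1$length, 200L)
  expect_true(h1$chrom_match)
  h2 <- hits[hits$target_id == "h2", ]
  expect_equal(h2$strand, "-")
  expect_false(h2$chrom_match)  # wrong chromosome
  # unrelated random sequence: no hit
  u <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  none <- cross_species_hits(setNames(u, "q2"), c(q2 = "chr1"),
                             setNames(s, "h1"), cat1, qmap)
  expect_equal(nrow(none), 0L)
  expect_error(cross_species_hits(setNames("ACGU", "q"), c(q = "chr1"),
                                  setNames(s, "h1"), cat1, qmap), "ACGTN")
})

test_that("hit decisions equal the all-substring oracle on short sequences", {
  withr::local_seed(705)
  k <- 5L; win <- 20L; ident <- 0.8
  for (trial in 1:60) {
    q <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    t <- if (runif(1) < 0.5) {
      # embed a mutated copy of a query chunk
      chunk <- substr(q, 11, 40)
      cc <- strsplit(chunk, "")[[1L]]
      nmut <- sample(0:4, 1L)
      if (nmut > 0) {
        pos <- sample(length(cc), nmut)
        cc[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
      }
      paste0(paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE),
                   collapse = ""), paste(cc, collapse = ""),
             paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE),
                   collapse = ""))
    } else {
      paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    }
    got <- nrow(cross_species_hits(
      setNames(q, "q"), c(q = "chr1"), setNames(t, "t"),
      data.frame(target_id = "t", chrom = "gga_chr1"),
      data.frame(query_chrom = "chr1", target_chrom = "gga_chr1"),
      k = k, min_length = win, min_identity = ident,
      both_strands = FALSE)) > 0L
    expect_equal(got, oracle_has_hit(q, t, k, win, ident))
  }
})

test_that("candidate selection is the exact three-way conjunction", {
  ids <- paste0("L", 1:6)
  cl <- setNames(c("F", "F", "G", "H", "L", "H"), ids)
  deg <- data.frame(transcript_id = ids,
                    call = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))
  hits <- data.frame(query_id = c("L1", "L2", "L3", "L5", "L6"),
                     chrom_match = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                     stringsAsFactors = FALSE)
  rep <- select_candidates(ids, cl, c("F", "G", "L"), deg, hits)
  expect_equal(rep$candidate, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  # L2 fails only the DE criterion
  l2 <- rep[rep$transcript_id == "L2", ]
  expect_true(l2$in_selected_cluster && l2$cross_species && !l2$regional_de)
  # set-algebra oracle
  want <- ids[cl %in% c("F", "G", "L") &
                deg$call[match(ids, deg$transcript_id)] &
                ids %in% hits$query_id[hits$chrom_match]]
  expect_setequal(rep$transcript_id[rep$candidate], want)
  # empty selected clusters: no candidates
  expect_equal(sum(select_candidates(ids, cl, character(0L), deg,
                                     hits)$candidate), 0L)
  expect_error(select_candidates(c(ids, "Lx"), cl, "F", deg, hits),
               "missing")
})
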