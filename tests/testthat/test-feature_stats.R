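test_that("length and exon summaries use mature length and exact medians", {
  tx <- transcript_models(data.frame(
    transcript_id = c("a", "b", "c", "c"),
    chrom = "chr1", start = c(0, 1000, 2000, 2500),
    end = c(100, 1200, 2100, 2700), strand = "+",
    stringsAsFactors = FALSE))
  s <- length_exon_summary(tx)
  expect_equal(s$median_len, 200)           # lengths 100, 200, 300
  expect_equal(s$mean_len, 200)
  expect_equal(s$mean_exons, 4 / 3)
  expect_error(length_exon_summary(tx[0, ]), "empty")
  # even group size: mean of the central pair
  s2 <- length_exon_summary(tx[tx$transcript_id %in% c("a", "b"), ])
  expect_equal(s2$median_len, 150)
})

test_that("mean conservation averages scored exonic bases and skips the rest", {
  tx <- transcript_models(data.frame(
    transcript_id = "t", chrom = "chr1", start = c(0, 100),
    end = c(10, 120), strand = "+", stringsAsFactors = FALSE))
  # constant track over everything
  tr <- score_track(data.frame(chrom = "chr1", start = 0, end = 200,
                               score = 0.5))
  expect_equal(mean_conservation(tx, tr), 0.5)
  # scores 0.2 over 5 bases and 0.4 over 5 bases, 20 bases unscored -> 0.3
  tr2 <- score_track(data.frame(chrom = "chr1", start = c(0, 5),
                                end = c(5, 10), score = c(0.2, 0.4)))
  expect_equal(mean_conservation(tx, tr2), 0.3)
  # nothing scored -> missing
  tr3 <- score_track(data.frame(chrom = "chr2", start = 0, end = 100,
                                score = 1))
  expect_true(is.na(mean_conservation(tx, tr3)))
})

test_that("mean conservation equals the per-base oracle on random cases", {
  withr::local_seed(404)
  for (trial in 1:40) {
    tx <- random_transcript_set(1L, max_pos = 300L)
    k <- sample(1:5, 1L)
    starts <- sort(sample(seq(0, 280, by = 20), k))
    tr <- score_track(data.frame(chrom = "chr1", start = starts,
                                 end = starts + sample(5:20, k, replace = TRUE),
                                 score = round(runif(k), 3)))
    id <- tx$transcript_id[1L]
    got <- mean_conservation(tx[tx$transcript_id == id, ], tr)
    want <- oracle_mean_conservation(tx, id, tr)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
  }
})

test_that("TE overlap fraction counts >= 1 shared base, strand-blind", {
  tx <- transcript_models(data.frame(
    transcript_id = paste0("t", 1:5), chrom = "chr1",
    start = c(0, 100, 200, 300, 400), end = c(50, 150, 250, 350, 450),
    strand = c("+", "-", "+", "-", "+"), stringsAsFactors = FALSE))
  expect_equal(te_overlap_fraction(tx, NULL), 0)
  reps_all <- data.frame(chrom = "chr1", start = 0, end = 500,
                         name = "LINE", stringsAsFactors = FALSE)
  expect_equal(te_overlap_fraction(tx, reps_all), 1)
  # exactly 1 bp overlaps for t1 and t3
  reps <- data.frame(chrom = "chr1", start = c(49, 249), end = c(60, 260),
                     name = c("SINE", "LTR"), stringsAsFactors = FALSE)
  expect_equal(te_overlap_fraction(tx, reps), 0.4)
})

test_that("TE fraction equals the per-base membership oracle", {
  withr::local_seed(405)
  for (trial in 1:30) {
    tx <- random_transcript_set(sample(3:6, 1L), max_pos = 400L)
    k <- sample(1:4, 1L)
    starts <- sample(seq(0, 380, by = 20), k)
    reps <- data.frame(chrom = "chr1", start = starts,
                       end = starts + sample(5:30, k, replace = TRUE),
                       name = "SINE", stringsAsFactors = FALSE)
    expect_equal(te_overlap_fraction(tx, reps), oracle_te_fraction(tx, reps))
  }
})

test_that("expression summary uses the max-library statistic by default", {
  m <- matrix(c(0, 0, 0, 0, 0, 2,
                1, 1, 1, 1, 1, 1,
                3, 0, 0, 0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"),
                              library_metadata()$library_id))
  expr <- expression_table(m)
  s <- expression_summary(c("a", "c"), expr)
  expect_equal(unname(s$per_transcript), c(2, 3))
  expect_equal(s$median_fpkm, 2.5)
  expect_equal(s$mean_fpkm, 2.5)
  s2 <- expression_summary("b", expr, statistic = "mean")
  expect_equal(unname(s2$per_transcript), 1)
  expect_error(expression_summary("zzz", expr), "missing")
})

test_that("JS specificity matches its closed form and bounds", {
  meta <- library_metadata()
  region <- condition_partition(meta, "region")
  v_ad <- setNames(c(5, 0, 3, 0, 1, 0), meta$library_id)   # AD only
  expect_equal(js_specificity(v_ad, region), 1.0)
  # uniform across both regions: 1 - sqrt(H(0.75, 0.25) - 0.5)
  v_uni <- setNames(rep(2, 6), meta$library_id)
  want <- 1 - sqrt((-0.75 * log2(0.75) - 0.25 * log2(0.25)) - 0.5)
  expect_equal(js_specificity(v_uni, region), want, tolerance = 1e-9)
  # permutation of conditions leaves the max unchanged
  expect_equal(js_specificity(v_ad, region[c(2, 1)]),
               js_specificity(v_ad, region))
  expect_true(is.na(js_specificity(setNames(rep(0, 6), meta$library_id),
                                   region)))
  expect_error(js_specificity(setNames(c(-1, rep(1, 5)), meta$library_id),
                              region), "negative")
})

test_that("JS specificity equals the entropy oracle on random profiles", {
  withr::local_seed(406)
  meta <- library_metadata()
  for (partition in list(condition_partition(meta, "region"),
                         condition_partition(meta, "stage"))) {
    for (trial in 1:50) {
      v <- setNames(round(runif(6, 0, 20), 2), meta$library_id)
      got <- js_specificity(v, partition)
      expect_equal(got, oracle_js(v, partition), tolerance = 1e-12)
      expect_gte(got, 0); expect_lte(got, 1)
    }
  }
})

test_that("concentrating mass on one condition never lowers its score", {
  meta <- library_metadata()
  region <- condition_partition(meta, "region")
  v <- setNames(c(4, 4, 4, 4, 4, 4), meta$library_id)
  prev <- js_specificity(v, region)
  for (boost in c(2, 4, 8, 16)) {
    v2 <- v; v2[meta$region == "AD"] <- 4 * boost
    cur <- js_specificity(v2, region)
    expect_gte(cur, prev - 1e-12)
    prev <- cur
  }
})

test_that("group comparison reproduces the t-test and its edge cases", {
  withr::local_seed(407)
  expect_equal(group_compare(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_lt(group_compare(c(0, 0, 0, 0.001), c(1, 1, 1, 1.001)), 1e-6)
  a <- rnorm(8); b <- rnorm(6, mean = 1)
  # closed-form pooled-variance Student's t
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  want <- 2 * pt(-abs(tstat), df = length(a) + length(b) - 2)
  expect_equal(group_compare(a, b), want, tolerance = 1e-12)
  expect_error(group_compare(1, c(1, 2)), "at least 2")
})

test_that("feature table and group summary agree with recomputation", {
  st <- tiny_study()
  disc <- discover_transcripts(st$isotigs, st$annotation, st$expr,
                               st$known_catalog)
  ft <- feature_table(disc$transcripts, disc$expr, st$conservation,
                      st$repeats)
  expect_equal(nrow(ft), length(unique(disc$transcripts$transcript_id)))
  sm <- transcript_summary(disc$transcripts)
  expect_equal(ft$length, sm$length[match(ft$transcript_id, sm$transcript_id)])
  expect_equal(unname(ft$max_fpkm),
               unname(apply(disc$expr$values[ft$transcript_id, ], 1, max)))
  cls <- classify_positional(disc$transcripts, st$annotation)
  gs <- feature_group_summary(ft, cls)
  expect_setequal(gs$group, unique(unname(cls)))
  expect_equal(sum(gs$n), nrow(ft))
  expect_true(all(gs$te_fraction >= 0 & gs$te_fraction <= 1))
})
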