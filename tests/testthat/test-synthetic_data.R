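test_that("the generator is fully deterministic under its seed", {
  cfg <- synthetic_config(seed = 5L, n_chromosomes = 2L,
                          chrom_length_bp = 200000L, n_coding_genes = 10L,
                          planted_counts = c(lincRNA = 6L, intronic = 2L,
                                             lncNAT = 2L, coding_fragment = 2L,
                                             unstranded = 2L, short_decoy = 2L,
                                             lowexpr_decoy = 2L))
  a <- generate_synthetic_study(cfg)
  b <- generate_synthetic_study(cfg)
  expect_identical(a$isotigs, b$isotigs)
  expect_identical(a$truth, b$truth)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(a$repeats, b$repeats)
  da <- withr::local_tempdir(); db <- withr::local_tempdir()
  fa <- write_synthetic_study(a, da)
  fb <- write_synthetic_study(b, db)
  for (i in seq_along(fa))
    expect_identical(readLines(fa[[i]]), readLines(fb[[i]]))
  # a different seed preserves all count-level invariants
  c2 <- generate_synthetic_study(synthetic_config(seed = 6L,
    n_chromosomes = 2L, chrom_length_bp = 200000L, n_coding_genes = 10L,
    planted_counts = cfg$planted_counts))
  expect_equal(table(c2$truth$class)[names(table(a$truth$class))],
               table(a$truth$class))
})

test_that("an empty gene count still yields a valid genome", {
  cfg <- synthetic_config(seed = 3L, n_coding_genes = 0L,
                          chrom_length_bp = 150000L,
                          planted_counts = c(lincRNA = 5L))
  g <- generate_genome(cfg)
  expect_equal(nrow(g$annotation), 0L)
  expect_equal(length(g$sequences), cfg$n_chromosomes)
  iso <- generate_isotigs(cfg, g)
  expect_equal(nrow(transcript_summary(iso$isotigs)), 5L)
})

test_that("repeat and conservation coverage honor the configured fractions", {
  cfg <- synthetic_config(seed = 9L, n_chromosomes = 1L,
                          chrom_length_bp = 1000000L, n_coding_genes = 5L,
                          repeat_fraction = 0.25, conservation_fraction = 0.5)
  g <- generate_genome(cfg)
  # brute-force interval-union base count (grid windows never overlap)
  rep_bases <- sum(g$repeats$end - g$repeats$start)
  expect_lt(abs(rep_bases - 0.25 * 1e6), 300)  # one window of granularity
  cons_bases <- sum(g$conservation$end - g$conservation$start)
  expect_lt(abs(cons_bases - 0.5 * 1e6), 200)
  expect_true(all(g$conservation$score >= 0 & g$conservation$score <= 1))
})

test_that("planted classes satisfy their defining geometry", {
  st <- tiny_study()
  tr <- st$truth
  iso <- st$isotigs
  ann <- st$annotation
  sm <- transcript_summary(iso)

  for (id in tr$transcript_id[tr$class == "short_decoy"])
    expect_lt(sm$length[sm$transcript_id == id], 200)
  for (id in tr$transcript_id[tr$class == "unstranded"])
    expect_equal(sm$strand[sm$transcript_id == id], "*")

  # lncNAT: >= 1 shared base with a coding exon antisense, 0 same-strand
  ann_ids <- unique(ann$transcript_id)
  for (id in tr$transcript_id[tr$class == "lncNAT"]) {
    anti <- sum(vapply(ann_ids, function(aid)
      oracle_overlap_bases(iso, id, ann, aid, "opposite"), integer(1L)))
    same <- sum(vapply(ann_ids, function(aid)
      oracle_overlap_bases(iso, id, ann, aid, "same"), integer(1L)))
    expect_gte(anti, 1L)
    expect_equal(same, 0L)
  }
  # lincRNA: no exonic overlap with any coding gene on either strand,
  # and no gene-span overlap
  spans <- transcript_summary(ann)
  for (id in tr$transcript_id[tr$class == "lincRNA"]) {
    s <- sm[sm$transcript_id == id, ]
    expect_false(any(spans$chrom == s$chrom &
                       spans$span_start < s$span_end &
                       spans$span_end > s$span_start))
  }
  # intronic: inside a gene span but overlapping no coding exon
  for (id in tr$transcript_id[tr$class == "intronic"]) {
    s <- sm[sm$transcript_id == id, ]
    expect_true(any(spans$chrom == s$chrom &
                      spans$span_start <= s$span_start &
                      spans$span_end >= s$span_end))
    ov <- sum(vapply(ann_ids, function(aid)
      oracle_overlap_bases(iso, id, ann, aid, "any"), integer(1L)))
    expect_equal(ov, 0L)
  }
})

test_that("planted expression honors decoys, fold changes and clusters", {
  st <- tiny_study()  # noise-free
  v <- st$expr$values
  tr <- st$truth
  low <- tr$transcript_id[tr$class == "lowexpr_decoy"]
  expect_true(all(v[low, ] < 1))
  expect_true(all(v >= 0))

  meta <- st$expr$meta
  ad <- meta$library_id[meta$region == "AD"]
  pd <- meta$library_id[meta$region == "PD"]
  for (id in tr$transcript_id[tr$de])
    expect_equal(mean(v[id, ad]) / mean(v[id, pd]), 4, tolerance = 1e-12)

  # noise 0: within-cluster profiles exactly proportional to the template
  for (k in unique(na.omit(tr$cluster))) {
    ids <- tr$transcript_id[!is.na(tr$cluster) & tr$cluster == k & !tr$de &
                              tr$class != "lowexpr_decoy"]
    if (length(ids) < 2L) next
    prof <- v[ids, , drop = FALSE] / rowSums(v[ids, , drop = FALSE])
    for (i in seq_len(nrow(prof)))
      expect_equal(unname(prof[i, ]), unname(prof[1L, ]), tolerance = 1e-12)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(de_fraction = 1.5), "de_fraction")
  expect_error(synthetic_config(planted_counts = c(lincRNA = -1L)), ">= 0")
  expect_error(synthetic_config(n_clusters = 9L), "n_clusters")
  # placement failure advises a larger chromosome
  cfg <- synthetic_config(seed = 1L, chrom_length_bp = 30000L,
                          n_coding_genes = 40L)
  expect_error(generate_genome(cfg), "chrom_length_bp")
})

test_that("homolog catalog carries mutated copies with chromosome mapping", {
  st <- tiny_study()
  hom <- st$homologs
  expect_true(all(grepl("^gga_", hom$homology_map$target_chrom)))
  expect_true(all(hom$catalog$source_id %in%
                    st$truth$transcript_id[st$truth$class %in%
                                             c("lincRNA", "intronic", "lncNAT")]))
  # mutated copies stay close to the source sequence
  src <- transcript_sequences(
    st$isotigs[st$isotigs$transcript_id %in% hom$catalog$source_id, ],
    st$sequences)
  for (i in seq_len(min(3L, nrow(hom$catalog)))) {
    a <- as.character(src[[hom$catalog$source_id[i]]])
    b <- as.character(hom$sequences[[hom$catalog$target_id[i]]])
    expect_equal(nchar(a), nchar(b))
    ident <- mean(strsplit(a, "")[[1L]] == strsplit(b, "")[[1L]])
    expect_gt(ident, 0.9)
  }
})
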