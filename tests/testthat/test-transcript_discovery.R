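make_tx <- function(...) transcript_models(rbind(...))
exon <- function(id, start, end, strand = "+", chrom = "chr1",
                 biotype = "unannotated")
  data.frame(transcript_id = id, gene_id = id, chrom = chrom, start = start,
             end = end, strand = strand, biotype = biotype,
             stringsAsFactors = FALSE)

test_that("strand filter removes exactly the unknown-strand isotigs", {
  tx <- make_tx(exon("a", 0, 100, "+"), exon("b", 200, 300, "-"),
                exon("c", 400, 500, "*"), exon("d", 600, 700, "+"),
                exon("e", 800, 900, "*"))
  s <- filter_stranded(tx)
  expect_setequal(unique(s$kept$transcript_id), c("a", "b", "d"))
  expect_setequal(unique(s$removed$transcript_id), c("c", "e"))
  empty <- tx[0, ]
  s0 <- filter_stranded(empty)
  expect_equal(nrow(s0$kept), 0L)
  expect_equal(nrow(s0$removed), 0L)
})

test_that("annotation partition is same-strand and exon-level", {
  ann <- make_tx(exon("g1", 1000, 1200, "+", biotype = "protein_coding"),
                 exon("g1", 2000, 2200, "+", biotype = "protein_coding"))
  iso <- make_tx(
    exon("sense1bp", 1199, 1400, "+"),    # 1 bp same-strand exon overlap
    exon("antisense", 1000, 1100, "-"),   # antisense to an exon
    exon("inintron", 1300, 1500, "+"),    # wholly inside the intron
    exon("faraway", 9000, 9200, "+"))
  p <- partition_by_annotation(iso, ann)
  expect_setequal(unique(p$annotated$transcript_id), "sense1bp")
  expect_setequal(unique(p$unannotated$transcript_id),
                  c("antisense", "inintron", "faraway"))
  expect_error(partition_by_annotation(iso, ann[0, ]), "no exon")
})

test_that("isotig merging is single-linkage over same-strand exon bases", {
  # chain: A overlaps B, B overlaps C, A and C disjoint
  tx <- make_tx(exon("A", 0, 100, "+"), exon("B", 90, 200, "+"),
                exon("C", 190, 300, "+"),
                exon("D", 1000, 1100, "+"), exon("E", 1000, 1100, "-"))
  m <- merge_isotigs(tx)
  groups <- unname(lapply(m$members, sort))
  has_group <- function(g)
    any(vapply(groups, identical, logical(1L), y = g))
  expect_true(has_group(c("A", "B", "C")))
  expect_true(has_group("D"))
  expect_true(has_group("E"))  # opposite strand never merges
  # merged exon structure is the base union
  merged_id <- names(m$members)[vapply(m$members, length, integer(1L)) == 3L]
  ex <- m$transcripts[m$transcripts$transcript_id == merged_id, ]
  expect_equal(ex$start, 0)
  expect_equal(ex$end, 300)
  # singletons keep their ids
  expect_true(all(c("D", "E") %in% names(m$members)))
})

test_that("merging equals the union-find oracle on random isotig sets", {
  withr::local_seed(202)
  for (trial in 1:30) {
    tx <- random_transcript_set(sample(3:8, 1L), max_pos = 500L)
    got <- sort(vapply(unname(lapply(merge_isotigs(tx)$members, sort)),
                       paste, character(1L), collapse = ","))
    want <- sort(vapply(oracle_merge_groups(tx), paste, character(1L),
                        collapse = ","))
    expect_identical(got, want)
  }
})

test_that("length and expression filters apply the documented boundaries", {
  tx <- make_tx(exon("len199", 0, 199, "+"), exon("len200", 300, 500, "+"),
                exon("silent", 600, 5600, "+"))
  m <- matrix(c(10, 10, 10, 10, 10, 10,
                0.9, 0.9, 0.9, 0.9, 0.9, 1.0,
                0, 0, 0, 0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("len199", "len200", "silent"),
                              library_metadata()$library_id))
  fl <- filter_length_expression(tx, expression_table(m))
  expect_setequal(unique(fl$kept$transcript_id), "len200")
  expect_equal(fl$removed_short, "len199")
  expect_equal(fl$removed_lowexpr, "silent")
  expect_error(filter_length_expression(tx, expression_table(m[1:2, ])),
               "missing from expression")
})

test_that("novelty labeling partitions known and novel exactly", {
  withr::local_seed(77)
  tx <- random_transcript_set(10L)
  sm <- transcript_summary(tx)
  known_ids <- sm$transcript_id[c(2, 5, 9)]
  catalog <- do.call(rbind, lapply(known_ids, function(id) {
    ex <- tx[tx$transcript_id == id, ][1L, ]
    data.frame(chrom = ex$chrom, start = ex$start, end = ex$end,
               name = paste0("NONC.", id), strand = ex$strand,
               stringsAsFactors = FALSE)
  }))
  nov <- label_novelty(tx, catalog)
  expect_setequal(names(nov)[nov], known_ids)
  expect_equal(sum(!nov), 7L)
  # empty catalog: everything novel
  expect_false(any(label_novelty(tx, NULL)))
  # antisense catalog entry does not mark known
  cat2 <- catalog[1L, ]
  cat2$strand <- setdiff(c("+", "-"), cat2$strand)
  nov2 <- label_novelty(tx, cat2)
  expect_false(any(nov2))
})

test_that("discovery accounting is conserved and idempotent", {
  st <- tiny_study()
  disc <- discover_transcripts(st$isotigs, st$annotation, st$expr,
                               st$known_catalog)
  r <- disc$report
  expect_equal(r[["input"]],
               r[["removed_unstranded"]] + r[["annotated"]] +
                 r[["unannotated_isotigs"]])
  expect_equal(r[["retained"]],
               r[["merged_raw_transcripts"]] - r[["removed_short"]] -
                 r[["removed_lowexpr"]])
  expect_equal(r[["retained"]], r[["known"]] + r[["novel"]])

  # re-running discovery on its own retained output changes nothing
  disc2 <- discover_transcripts(disc$transcripts, st$annotation, disc$expr,
                                st$known_catalog)
  expect_equal(sort(unique(disc2$transcripts$transcript_id)),
               sort(unique(disc$transcripts$transcript_id)))
  expect_equal(disc2$report[["retained"]], r[["retained"]])
  expect_equal(disc2$report[["removed_unstranded"]], 0L)
  expect_equal(disc2$report[["annotated"]], 0L)
})

test_that("discovery retains exactly the planted lncRNAs at noise zero", {
  st <- tiny_study()
  disc <- discover_transcripts(st$isotigs, st$annotation, st$expr,
                               st$known_catalog)
  planted <- st$truth$transcript_id[st$truth$class %in%
                                      c("lincRNA", "intronic", "lncNAT")]
  expect_setequal(unique(disc$transcripts$transcript_id), planted)
  expect_setequal(names(disc$novelty)[disc$novelty],
                  st$truth$transcript_id[st$truth$known])
})
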