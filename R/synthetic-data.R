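# Deterministic synthetic study generator with planted ground truth.
# Every generator seeds R's RNG locally from config$seed plus a fixed
# per-stage offset, so each stage is reproducible on its own and the full
# study is byte-identical under the same config.

.STAGE_SEED <- c(genome = 0L, isotigs = 1L, expression = 2L, scores = 3L,
                 homologs = 4L)

# seed the RNG for one generator stage, restoring the caller's RNG state
# when the calling function exits
.local_seed <- function(seed, envir = parent.frame()) {
  withr::local_seed(seed, .local_envir = envir)
}

#' Configuration of the synthetic study
#'
#' Parameters of the planted-truth generator. Defaults describe a desk-scale
#' emulation of a six-library stranded RNA-seq study of two skin regions
#' (anterior/posterior dorsal, AD/PD) at three embryonic stages: a small
#' multi-chromosome genome with non-overlapping multi-exon coding genes,
#' planted lncRNAs of each positional class, decoys exercising every
#' discovery filter, cluster-structured expression and a planted
#' regional (AD vs PD) differential-expression effect.
#'
#' @param seed integer seed; fully determines every output.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp length of each chromosome (bp).
#' @param n_coding_genes coding genes placed across chromosomes.
#' @param planted_counts named counts for classes `lincRNA`, `intronic`,
#'   `lncNAT`, `coding_fragment`, `unstranded`, `short_decoy`,
#'   `lowexpr_decoy`.
#' @param n_clusters planted co-expression clusters (1..3, one per stage;
#'   cluster k is high at stage k in both regions, so templates are
#'   region-balanced and mutually far apart in correlation distance).
#' @param de_fraction fraction of planted lncRNAs carrying the regional
#'   effect.
#' @param de_log2fc planted AD-vs-PD log2 fold change (applied to AD
#'   libraries before noise).
#' @param fpkm_noise_cv coefficient of variation of multiplicative
#'   log-normal FPKM noise (0 = noise free).
#' @param repeat_fraction fraction of each chromosome covered by
#'   transposable-element intervals.
#' @param conservation_fraction fraction of each chromosome covered by the
#'   conservation track.
#' @param known_fraction fraction of planted lncRNAs present in the
#'   known-ncRNA catalog (novelty labeling).
#' @param intronic_same_strand place intronic lncRNAs on the host gene
#'   strand (default) or the opposite strand.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 3L,
                             chrom_length_bp = 500000L,
                             n_coding_genes = 45L,
                             planted_counts = c(lincRNA = 40L, intronic = 10L,
                                                lncNAT = 10L,
                                                coding_fragment = 12L,
                                                unstranded = 8L,
                                                short_decoy = 8L,
                                                lowexpr_decoy = 8L),
                             n_clusters = 3L,
                             de_fraction = 0.15,
                             de_log2fc = 2,
                             fpkm_noise_cv = 0.3,
                             repeat_fraction = 0.10,
                             conservation_fraction = 0.60,
                             known_fraction = 0.20,
                             intronic_same_strand = TRUE) {
  classes <- c("lincRNA", "intronic", "lncNAT", "coding_fragment",
               "unstranded", "short_decoy", "lowexpr_decoy")
  pc <- setNames(rep(0L, length(classes)), classes)
  pc[names(planted_counts)] <- as.integer(planted_counts)
  if (any(pc < 0)) stop("planted counts must be >= 0")
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must be in [0, 1]")
  if (n_clusters < 1L || n_clusters > 3L)
    stop("n_clusters must be between 1 and 3")
  if (fpkm_noise_cv < 0) stop("fpkm_noise_cv must be >= 0")
  structure(list(seed = as.integer(seed),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = as.integer(chrom_length_bp),
                 n_coding_genes = as.integer(n_coding_genes),
                 planted_counts = pc,
                 n_clusters = as.integer(n_clusters),
                 de_fraction = de_fraction,
                 de_log2fc = de_log2fc,
                 fpkm_noise_cv = fpkm_noise_cv,
                 repeat_fraction = repeat_fraction,
                 conservation_fraction = conservation_fraction,
                 known_fraction = known_fraction,
                 intronic_same_strand = isTRUE(intronic_same_strand)),
            class = "synthetic_config")
}

#' Generate the synthetic genome, annotation and tracks
#'
#' Places non-overlapping, stranded, multi-exon coding genes along each
#' chromosome, draws random chromosome sequences, and lays down
#' transposable-element intervals and a conservation track as
#' non-overlapping windows covering the configured fractions.
#'
#' @param config a [synthetic_config()].
#' @return list with `annotation` (transcript table), `sequences`
#'   (chromosome [Biostrings::DNAStringSet]), `repeats` (BED-style data
#'   frame with TE class in `name`), `conservation` (score track),
#'   `chrom_sizes` (named vector), and `gene_structures` (internal layout
#'   reused by [generate_isotigs()]).
#' @export
generate_genome <- function(config) {
  .local_seed(config$seed + .STAGE_SEED[["genome"]])
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  L <- config$chrom_length_bp
  chrom_sizes <- setNames(rep(L, length(chroms)), chroms)

  # gene placement: cursor walks each chromosome; genes assigned round-robin
  genes <- list()
  cursor <- setNames(rep(3000, length(chroms)), chroms)
  for (g in seq_len(config$n_coding_genes)) {
    ch <- chroms[((g - 1L) %% length(chroms)) + 1L]
    n_ex <- sample(3:5, 1L)
    ex_len <- sample(150:400, n_ex, replace = TRUE)
    in_len <- sample(1500:3000, n_ex - 1L, replace = TRUE)
    span <- sum(ex_len) + sum(in_len)
    gap <- sample(2500:6000, 1L)
    start <- cursor[ch] + gap
    if (start + span > L - 3000)
      stop("gene placement failed on ", ch,
           "; increase chrom_length_bp or reduce n_coding_genes")
    starts <- start + c(0, cumsum(ex_len[-n_ex] + in_len))
    gid <- sprintf("GENE.%03d", g)
    genes[[gid]] <- list(gene_id = gid, chrom = ch,
                         strand = sample(c("+", "-"), 1L),
                         exon_start = starts, exon_end = starts + ex_len,
                         span = c(start, start + span))
    cursor[ch] <- start + span
  }

  ann <- do.call(rbind, lapply(genes, function(g) {
    data.frame(transcript_id = paste0(g$gene_id, ".t1"), gene_id = g$gene_id,
               chrom = g$chrom, start = g$exon_start, end = g$exon_end,
               strand = g$strand, biotype = "protein_coding",
               stringsAsFactors = FALSE)
  }))
  if (is.null(ann))
    ann <- data.frame(transcript_id = character(0L), gene_id = character(0L),
                      chrom = character(0L), start = numeric(0L),
                      end = numeric(0L), strand = character(0L),
                      biotype = character(0L), stringsAsFactors = FALSE)
  annotation <- transcript_models(ann)

  sequences <- Biostrings::DNAStringSet(setNames(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1L)), chroms))

  # non-overlapping windows on a fixed grid cover the requested fractions
  grid_cover <- function(frac, w) {
    do.call(rbind, lapply(chroms, function(ch) {
      ncell <- L %/% w
      k <- floor(frac * ncell)
      if (k == 0L) return(NULL)
      cells <- sort(sample(seq_len(ncell) - 1L, k))
      data.frame(chrom = ch, start = cells * w, end = cells * w + w,
                 stringsAsFactors = FALSE)
    }))
  }
  rep_iv <- grid_cover(config$repeat_fraction, 300L)
  if (is.null(rep_iv))
    rep_iv <- data.frame(chrom = character(0L), start = numeric(0L),
                         end = numeric(0L), stringsAsFactors = FALSE)
  rep_iv$name <- if (nrow(rep_iv)) sample(c("SINE", "LINE", "LTR", "DNA"),
                                          nrow(rep_iv), replace = TRUE)
                 else character(0L)
  rep_iv$strand <- rep("*", nrow(rep_iv))

  cons <- grid_cover(config$conservation_fraction, 200L)
  if (is.null(cons))
    cons <- data.frame(chrom = character(0L), start = numeric(0L),
                       end = numeric(0L), stringsAsFactors = FALSE)
  # coding exons conserved, elsewhere low: mRNA > lncRNA conservation
  if (nrow(cons)) {
    in_exon <- rep(FALSE, nrow(cons))
    if (nrow(annotation)) {
      gcons <- GenomicRanges::GRanges(cons$chrom,
                                      IRanges::IRanges(cons$start + 1L, cons$end))
      gex <- .exons_gr(annotation)
      in_exon <- IRanges::overlapsAny(gcons, gex, minoverlap = 1L)
    }
    cons$score <- round(ifelse(in_exon, runif(nrow(cons), 0.6, 1),
                               runif(nrow(cons), 0.02, 0.45)), 3)
  } else cons$score <- numeric(0L)

  list(annotation = annotation, sequences = sequences, repeats = rep_iv,
       conservation = score_track(cons), chrom_sizes = chrom_sizes,
       gene_structures = genes)
}

# Allocator over intergenic space: consumes [start, start+len) slices out of
# the gaps between gene spans, leaving a 60 bp buffer between allocations so
# intergenic features never share a base.
.gap_allocator <- function(genome) {
  gaps <- list()
  for (ch in names(genome$chrom_sizes)) {
    spans <- do.call(rbind, lapply(genome$gene_structures, function(g)
      if (g$chrom == ch) g$span else NULL))
    L <- genome$chrom_sizes[[ch]]
    if (is.null(spans)) {
      gaps[[length(gaps) + 1L]] <- list(chrom = ch, start = 500, end = L - 500)
    } else {
      spans <- spans[order(spans[, 1L]), , drop = FALSE]
      edges <- c(500, t(spans), L - 500)
      for (i in seq(1L, length(edges) - 1L, by = 2L)) {
        lo <- edges[i] + 150; hi <- edges[i + 1L] - 150
        if (hi - lo > 400)
          gaps[[length(gaps) + 1L]] <- list(chrom = ch, start = lo, end = hi)
      }
    }
  }
  gaps <- Filter(Negate(is.null), gaps)
  env <- new.env()
  env$gaps <- gaps
  env$take <- function(len) {
    for (i in seq_along(env$gaps)) {
      g <- env$gaps[[i]]
      if (g$end - g$start >= len + 60) {
        out <- list(chrom = g$chrom, start = g$start, end = g$start + len)
        env$gaps[[i]]$start <- g$start + len + 60
        return(out)
      }
    }
    stop("could not place an intergenic feature; increase chrom_length_bp")
  }
  env
}

#' Generate planted isotigs and their ground truth
#'
#' Plants one isotig per requested class with geometry that satisfies the
#' exact predicates the discovery and classification stages test:
#' lincRNAs overlap no gene span; intronic isotigs lie strictly inside one
#' intron with no exonic overlap; lncNATs share bases with a coding exon on
#' the opposite strand only; coding fragments overlap coding exons on the
#' same strand; unstranded decoys carry strand `"*"`; short decoys have
#' mature length < 200; low-expression decoys are geometrically valid
#' lncRNAs flagged for sub-1 FPKM in every library.
#'
#' @param config a [synthetic_config()].
#' @param genome output of [generate_genome()].
#' @return list with `isotigs` (transcript table) and `truth` (data frame
#'   `transcript_id`, `class`, `cluster`, `de`, `known`).
#' @export
generate_isotigs <- function(config, genome) {
  .local_seed(config$seed + .STAGE_SEED[["isotigs"]])
  pc <- config$planted_counts
  alloc <- .gap_allocator(genome)
  genes <- genome$gene_structures
  rows <- list(); truth <- list()
  k <- 0L
  add <- function(cls, chrom, starts, ends, strand) {
    k <<- k + 1L
    tid <- sprintf("ISO.%04d", k)
    rows[[tid]] <<- data.frame(transcript_id = tid, gene_id = tid,
                               chrom = chrom, start = starts, end = ends,
                               strand = strand, biotype = "unannotated",
                               stringsAsFactors = FALSE)
    truth[[tid]] <<- data.frame(transcript_id = tid, class = cls,
                                stringsAsFactors = FALSE)
    tid
  }
  intergenic_single <- function(cls, len, strand = sample(c("+", "-"), 1L)) {
    slot <- alloc$take(len)
    add(cls, slot$chrom, slot$start, slot$start + len, strand)
  }

  # lincRNA: 1-3 exons in intergenic space (exons carved out of one slice)
  for (i in seq_len(pc[["lincRNA"]])) {
    n_ex <- sample(1:3, 1L)
    ex_len <- sample(200:600, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1L) sample(100:300, n_ex - 1L, replace = TRUE)
              else integer(0L)
    slot <- alloc$take(sum(ex_len) + sum(in_len))
    starts <- slot$start + c(0, cumsum(ex_len[-n_ex] + in_len))
    add("lincRNA", slot$chrom, starts, starts + ex_len,
        sample(c("+", "-"), 1L))
  }

  # intronic: strictly inside one intron, margin 100 bp from flanking exons
  multi <- Filter(function(g) length(g$exon_start) >= 2L, genes)
  if (pc[["intronic"]] > 0L && length(multi) == 0L)
    stop("intronic isotigs require coding genes with introns")
  used_intron <- character(0L)
  for (i in seq_len(pc[["intronic"]])) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      g <- multi[[sample(length(multi), 1L)]]
      j <- sample(length(g$exon_start) - 1L, 1L)
      key <- paste(g$gene_id, j)
      if (key %in% used_intron) next
      ilo <- g$exon_end[j] + 100; ihi <- g$exon_start[j + 1L] - 100
      if (ihi - ilo < 260) next
      len <- sample(220:min(600, ihi - ilo - 20), 1L)
      start <- ilo + sample.int(max(1, ihi - ilo - len), 1L) - 1L
      strand <- if (config$intronic_same_strand) g$strand
                else setdiff(c("+", "-"), g$strand)
      add("intronic", g$chrom, start, start + len, strand)
      used_intron <- c(used_intron, key)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place an intronic isotig; ",
                      "increase chrom_length_bp or gene count")
  }

  # lncNAT: antisense to one coding exon, extending at most 150 bp past it
  all_exons <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene = g$gene_id, chrom = g$chrom, strand = g$strand,
               start = g$exon_start, end = g$exon_end,
               stringsAsFactors = FALSE)))
  if (pc[["lncNAT"]] > 0L && (is.null(all_exons) || nrow(all_exons) == 0L))
    stop("lncNAT isotigs require coding genes")
  used_exon <- integer(0L)
  for (i in seq_len(pc[["lncNAT"]])) {
    cand <- setdiff(seq_len(nrow(all_exons)), used_exon)
    if (length(cand) == 0L) stop("not enough coding exons for lncNATs")
    e <- cand[sample(length(cand), 1L)]
    used_exon <- c(used_exon, e)
    lo <- max(all_exons$start[e] - 150, 0)
    hi <- all_exons$end[e] + 150
    len <- max(220, hi - lo - sample(0:100, 1L))
    start <- lo
    add("lncNAT", all_exons$chrom[e], start, min(start + len, hi),
        setdiff(c("+", "-"), all_exons$strand[e]))
  }

  # coding_fragment: same-strand sub-interval of a coding exon (+ margin)
  for (i in seq_len(pc[["coding_fragment"]])) {
    cand <- setdiff(seq_len(nrow(all_exons)), used_exon)
    if (length(cand) == 0L) stop("not enough coding exons for coding fragments")
    e <- cand[sample(length(cand), 1L)]
    used_exon <- c(used_exon, e)
    start <- all_exons$start[e] + 10
    end <- max(start + 210, all_exons$end[e] + sample(0:120, 1L))
    add("coding_fragment", all_exons$chrom[e], start, end,
        all_exons$strand[e])
  }

  for (i in seq_len(pc[["unstranded"]]))
    intergenic_single("unstranded", sample(250:600, 1L), "*")
  for (i in seq_len(pc[["short_decoy"]]))
    intergenic_single("short_decoy", sample(120:199, 1L))
  for (i in seq_len(pc[["lowexpr_decoy"]]))
    intergenic_single("lowexpr_decoy", sample(250:600, 1L))

  isotigs <- transcript_models(do.call(rbind, rows))
  tr <- do.call(rbind, truth)
  rownames(tr) <- NULL

  # cluster labels for everything that will be expressed; DE and catalog
  # membership planted among the lncRNA classes only
  lnc <- tr$transcript_id[tr$class %in% c("lincRNA", "intronic", "lncNAT")]
  expressed <- tr$transcript_id[!tr$class %in% c("lowexpr_decoy")]
  tr$cluster <- NA_integer_
  tr$cluster[tr$transcript_id %in% expressed] <-
    sample(seq_len(config$n_clusters), length(expressed), replace = TRUE)
  n_de <- round(config$de_fraction * length(lnc))
  de_ids <- if (n_de > 0L) sample(lnc, n_de) else character(0L)
  tr$de <- tr$transcript_id %in% de_ids
  n_known <- round(config$known_fraction * length(lnc))
  known_ids <- if (n_known > 0L) sample(lnc, n_known) else character(0L)
  tr$known <- tr$transcript_id %in% known_ids

  list(isotigs = isotigs, truth = tr)
}

#' Known-ncRNA catalog matching the planted truth
#'
#' Builds a BED-style catalog containing the exon spans of the planted
#' lncRNAs flagged `known` in the ground truth, so novelty labeling can be
#' validated exactly.
#'
#' @param isotigs,truth output of [generate_isotigs()].
#' @return BED-style data frame (`chrom`, `start`, `end`, `name`, `strand`).
#' @export
generate_known_catalog <- function(isotigs, truth) {
  ids <- truth$transcript_id[truth$known]
  ex <- isotigs[isotigs$transcript_id %in% ids, , drop = FALSE]
  if (nrow(ex) == 0L)
    return(data.frame(chrom = character(0L), start = numeric(0L),
                      end = numeric(0L), name = character(0L),
                      strand = character(0L), stringsAsFactors = FALSE))
  data.frame(chrom = ex$chrom, start = ex$start, end = ex$end,
             name = paste0("NONC.", ex$transcript_id), strand = ex$strand,
             stringsAsFactors = FALSE)
}

# cluster template over the six libraries: cluster k is high in both
# regions of stage k and low elsewhere. Templates are region-balanced, so
# the planted AD-vs-PD effect is exactly 2^de_log2fc on top of any
# template, and pairwise correlation between distinct templates is -0.5
# (distance 1.5), so any cut in (0, 1.5) separates planted clusters at
# noise 0.
.cluster_template <- function(cluster, n_clusters, meta) {
  n_lib <- nrow(meta)
  if (n_clusters == 1L) return(rep(1, n_lib))
  stages <- unique(meta$stage)
  t <- rep(0.05, n_lib)
  t[meta$stage == stages[((cluster - 1L) %% length(stages)) + 1L]] <- 1
  t
}

#' Generate the synthetic FPKM table
#'
#' Every expressed transcript (annotation plus planted isotigs except
#' low-expression decoys) gets FPKM = scale x cluster template, with the
#' planted AD-vs-PD effect applied by multiplying AD libraries by
#' `2^de_log2fc` before noise, and multiplicative log-normal noise of the
#' configured coefficient of variation applied last (unit mean). mRNA scales
#' are drawn higher than lncRNA scales, mirroring the expression gap between
#' coding and non-coding transcripts.
#'
#' @param config a [synthetic_config()].
#' @param isotigs,truth output of [generate_isotigs()].
#' @param annotation coding annotation from [generate_genome()].
#' @return list with `expr` (an `expression_table`) and `truth` (the input
#'   truth with mRNA rows appended for cluster bookkeeping).
#' @export
generate_expression <- function(config, isotigs, truth, annotation) {
  .local_seed(config$seed + .STAGE_SEED[["expression"]])
  meta <- library_metadata()
  n_lib <- nrow(meta)
  mrna <- unique(annotation$transcript_id)
  mrna_truth <- if (length(mrna)) {
    data.frame(transcript_id = mrna, class = "mRNA",
               cluster = sample(seq_len(config$n_clusters), length(mrna),
                                replace = TRUE),
               de = FALSE, known = FALSE, stringsAsFactors = FALSE)
  } else NULL
  all_truth <- rbind(truth, mrna_truth)
  ids <- all_truth$transcript_id
  m <- matrix(0, nrow = length(ids), ncol = n_lib,
              dimnames = list(ids, meta$library_id))
  sigma <- sqrt(log(1 + config$fpkm_noise_cv^2))
  ad <- meta$region == "AD"
  for (i in seq_along(ids)) {
    cls <- all_truth$class[i]
    if (cls == "lowexpr_decoy") {
      base <- runif(n_lib, 0.05, 0.6)
    } else {
      scale <- if (cls == "mRNA") 2^runif(1L, 3, 8) else 2^runif(1L, 1.2, 5)
      base <- scale * .cluster_template(all_truth$cluster[i],
                                        config$n_clusters, meta)
      if (all_truth$de[i]) base[ad] <- base[ad] * 2^config$de_log2fc
    }
    noisy <- if (sigma > 0)
      base * rlnorm(n_lib, meanlog = -sigma^2 / 2, sdlog = sigma)
    else base
    if (cls == "lowexpr_decoy") noisy <- pmin(noisy, 0.95)
    m[i, ] <- noisy
  }
  list(expr = expression_table(m, meta), truth = all_truth)
}

#' Generate a coding potential score table for the planted isotigs
#'
#' Planted lncRNA classes and decoys receive noncoding-leaning scores
#' (CPC/PLEK well below -0.5, no domain hit); coding fragments and mRNAs
#' receive coding-leaning scores and strong domain hits, so the three-filter
#' consensus recovers exactly the planted lncRNAs among retained
#' transcripts.
#'
#' @param config a [synthetic_config()].
#' @param truth ground-truth table covering the scored transcripts.
#' @return a coding score table (see [coding_scores()]).
#' @export
generate_coding_scores <- function(config, truth) {
  .local_seed(config$seed + .STAGE_SEED[["scores"]])
  n <- nrow(truth)
  codingish <- truth$class %in% c("coding_fragment", "mRNA")
  cpc <- ifelse(codingish, runif(n, 0.5, 3), runif(n, -2.5, -0.8))
  plek <- ifelse(codingish, runif(n, 0.5, 2), runif(n, -2.5, -0.8))
  ev <- ifelse(codingish, 10^runif(n, -12, -6), NA_real_)
  coding_scores(data.frame(transcript_id = truth$transcript_id,
                           cpc_score = round(cpc, 4),
                           plek_score = round(plek, 4),
                           min_domain_evalue = signif(ev, 4),
                           stringsAsFactors = FALSE))
}

.mutate_seq <- function(s, rate) {
  x <- strsplit(s, "")[[1L]]
  n <- length(x)
  k <- rbinom(1L, n, rate)
  if (k > 0L) {
    pos <- sample(n, k)
    x[pos] <- vapply(x[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
  }
  paste(x, collapse = "")
}

#' Spliced transcript sequences from the synthetic genome
#'
#' @param isotigs transcript table.
#' @param sequences chromosome [Biostrings::DNAStringSet].
#' @return named [Biostrings::DNAStringSet] of spliced (exon-concatenated)
#'   sequences; minus-strand transcripts are reverse complemented.
#' @export
transcript_sequences <- function(isotigs, sequences) {
  ids <- unique(isotigs$transcript_id)
  out <- vapply(ids, function(tid) {
    ex <- isotigs[isotigs$transcript_id == tid, , drop = FALSE]
    s <- paste(vapply(seq_len(nrow(ex)), function(i)
      as.character(Biostrings::subseq(sequences[[ex$chrom[i]]],
                                      ex$start[i] + 1L, ex$end[i])),
      character(1L)), collapse = "")
    if (ex$strand[1L] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1L))
  Biostrings::DNAStringSet(setNames(out, ids))
}

#' Generate a homologous second-species lncRNA catalog
#'
#' For a subset of planted lncRNAs, emits a lightly mutated copy of the
#' spliced sequence assigned to a second-species chromosome. By default the
#' homolog sits on the chromosome homologous to the source chromosome
#' (prefix `gga_`); a configurable fraction is displaced to a different
#' chromosome so the chromosome-match flag of candidate selection is
#' exercised in both directions.
#'
#' @param config a [synthetic_config()].
#' @param isotigs,truth output of [generate_isotigs()].
#' @param sequences chromosome sequences from [generate_genome()].
#' @param homolog_fraction fraction of planted lncRNAs with a homolog.
#' @param mismatch_fraction fraction of homologs placed on a non-homologous
#'   chromosome.
#' @param mutation_rate per-base substitution rate of the homolog copy.
#' @return list with `sequences` ([Biostrings::DNAStringSet]), `catalog`
#'   (data frame `target_id`, `chrom`, `source_id`), and `homology_map`
#'   (data frame `query_chrom`, `target_chrom`).
#' @export
generate_homologs <- function(config, isotigs, truth, sequences,
                              homolog_fraction = 0.5,
                              mismatch_fraction = 0.2,
                              mutation_rate = 0.03) {
  .local_seed(config$seed + .STAGE_SEED[["homologs"]])
  chroms <- unique(isotigs$chrom)
  map <- data.frame(query_chrom = chroms,
                    target_chrom = paste0("gga_", chroms),
                    stringsAsFactors = FALSE)
  lnc <- truth$transcript_id[truth$class %in% c("lincRNA", "intronic", "lncNAT")]
  n_hom <- round(homolog_fraction * length(lnc))
  if (n_hom == 0L)
    return(list(sequences = Biostrings::DNAStringSet(),
                catalog = data.frame(target_id = character(0L),
                                     chrom = character(0L),
                                     source_id = character(0L),
                                     stringsAsFactors = FALSE),
                homology_map = map))
  picked <- sort(sample(lnc, n_hom))
  seqs <- transcript_sequences(isotigs[isotigs$transcript_id %in% picked, ,
                                       drop = FALSE], sequences)
  src_chrom <- vapply(picked, function(tid)
    isotigs$chrom[isotigs$transcript_id == tid][1L], character(1L))
  target <- map$target_chrom[match(src_chrom, map$query_chrom)]
  n_mis <- round(mismatch_fraction * n_hom)
  if (n_mis > 0L) {
    mis <- sample(n_hom, n_mis)
    target[mis] <- vapply(target[mis], function(tc) {
      alt <- setdiff(map$target_chrom, tc)
      if (length(alt) == 0L) tc else sample(alt, 1L)
    }, character(1L))
  }
  hom <- vapply(picked, function(tid)
    .mutate_seq(as.character(seqs[[tid]]), mutation_rate), character(1L))
  tids <- sprintf("GGA.%04d", seq_len(n_hom))
  list(sequences = Biostrings::DNAStringSet(setNames(hom, tids)),
       catalog = data.frame(target_id = tids, chrom = target,
                            source_id = picked, stringsAsFactors = FALSE),
       homology_map = map)
}

#' Generate the full synthetic study
#'
#' Runs every generator in order under the configured seed and returns the
#' complete planted-truth study: genome, annotation, tracks, isotigs,
#' expression, coding scores, known-ncRNA catalog and a second-species
#' homolog catalog.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_study` list.
#' @export
generate_synthetic_study <- function(config = synthetic_config()) {
  genome <- generate_genome(config)
  iso <- generate_isotigs(config, genome)
  ex <- generate_expression(config, iso$isotigs, iso$truth, genome$annotation)
  scores <- generate_coding_scores(config, ex$truth)
  hom <- generate_homologs(config, iso$isotigs, iso$truth, genome$sequences)
  structure(list(config = config,
                 annotation = genome$annotation,
                 sequences = genome$sequences,
                 repeats = genome$repeats,
                 conservation = genome$conservation,
                 chrom_sizes = genome$chrom_sizes,
                 isotigs = iso$isotigs,
                 truth = ex$truth,
                 expr = ex$expr,
                 scores = scores,
                 known_catalog = generate_known_catalog(iso$isotigs, iso$truth),
                 homologs = hom),
            class = "synthetic_study")
}

#' Write a synthetic study as standard files
#'
#' Emits the complete fixture set (GTF annotation and isotigs, FASTA genome,
#' BED repeats and known catalog, bedGraph conservation, TSV expression,
#' scores, chromosome sizes and ground truth, FASTA + TSV homolog catalog)
#' so the pipeline can be exercised purely through its file interfaces.
#'
#' @param study output of [generate_synthetic_study()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_gtf(study$annotation, p("annotation.gtf"))
  write_gtf(study$isotigs, p("isotigs.gtf"))
  write_fasta(study$sequences, p("genome.fa"))
  write_bed(study$repeats, p("repeats.bed"))
  write_bed(study$known_catalog, p("known_ncrna.bed"))
  tr <- study$conservation
  writeLines(sprintf("%s\t%d\t%d\t%g", tr$chrom, as.integer(tr$start),
                     as.integer(tr$end), tr$score), p("conservation.bedGraph"))
  write_expression(study$expr, p("expression.tsv"))
  write.table(data.frame(chrom = names(study$chrom_sizes),
                         size = as.integer(study$chrom_sizes)),
              p("chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(study$scores, p("coding_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(study$truth, p("ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(study$homologs$sequences, p("homolog_seqs.fa"))
  write.table(study$homologs$catalog, p("homolog_catalog.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(study$homologs$homology_map, p("homology_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c("annotation.gtf", "isotigs.gtf", "genome.fa", "repeats.bed",
             "known_ncrna.bed", "conservation.bedGraph", "expression.tsv",
             "chrom.sizes", "coding_scores.tsv", "ground_truth.tsv",
             "homolog_seqs.fa", "homolog_catalog.tsv", "homology_map.tsv")
  invisible(setNames(file.path(dir, files), files))
}
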