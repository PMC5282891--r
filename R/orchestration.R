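# Single-call pipeline runner: discovery -> coding consensus -> positional
# classification -> characterization -> clustering -> differential
# expression -> enrichment -> candidate selection, with a stage-by-stage
# accounting manifest.

#' Pipeline configuration
#'
#' Collects all input paths and thresholds. Every threshold default is the
#' value used throughout the package: minimum length 200 bp, minimum max
#' FPKM 1, CPC/PLEK cutoffs -0.5, domain E-value 1e-4, expressed filter
#' > 1 FPKM, cluster cut 0.69, q threshold 0.7, enrichment p < 0.01 and
#' FDR < 0.05.
#'
#' @param isotigs,annotation GTF paths.
#' @param expression expression TSV path (isotig-level FPKM).
#' @param coding_scores coding score TSV path.
#' @param known_catalog BED path of known non-coding RNAs (optional).
#' @param repeats BED path of transposable elements (optional).
#' @param conservation bedGraph path (optional).
#' @param chrom_sizes two-column TSV path (optional).
#' @param term_map TSV path `gene_id`, `term_id` (optional).
#' @param homolog_seqs,homolog_catalog,homology_map cross-species catalog
#'   paths (optional, all three required together).
#' @param genome_fasta genome FASTA (needed for cross-species search).
#' @param selected_clusters cluster labels for candidate selection.
#' @param out_dir output directory.
#' @param min_length,min_max_fpkm,cpc_cutoff,plek_cutoff,evalue_threshold,
#'   expressed_threshold,cluster_cut,q_threshold,enrich_p,enrich_fdr
#'   thresholds (defaults above).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(isotigs, annotation, expression, coding_scores,
                            known_catalog = NULL, repeats = NULL,
                            conservation = NULL, chrom_sizes = NULL,
                            term_map = NULL, homolog_seqs = NULL,
                            homolog_catalog = NULL, homology_map = NULL,
                            genome_fasta = NULL,
                            selected_clusters = character(0L),
                            out_dir = NULL,
                            min_length = 200, min_max_fpkm = 1,
                            cpc_cutoff = -0.5, plek_cutoff = -0.5,
                            evalue_threshold = 1e-4,
                            expressed_threshold = 1,
                            cluster_cut = 0.69, q_threshold = 0.7,
                            enrich_p = 0.01, enrich_fdr = 0.05) {
  cfg <- as.list(environment())
  required <- c("isotigs", "annotation", "expression", "coding_scores")
  for (f in required)
    if (!file.exists(cfg[[f]])) stop("input file not found: ", cfg[[f]])
  for (f in c("known_catalog", "repeats", "conservation", "chrom_sizes",
              "term_map", "homolog_seqs", "homolog_catalog", "homology_map",
              "genome_fasta"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("input file not found: ", cfg[[f]])
  structure(cfg, class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full lncRNA pipeline
#'
#' Executes every stage on the configured inputs and returns (and
#' optionally writes) all stage outputs plus a manifest of stage counts and
#' the thresholds used. Optional stages (enrichment, cross-species search,
#' candidate selection) run only when their inputs are configured. Any
#' stage error aborts with the stage name and cause.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list with `discovery`, `consensus_ids`,
#'   `classes`, `features`, `clusters`, `deg` (per scheme), `enrichment`,
#'   `hits`, `candidates`, `manifest`.
#' @export
run_pipeline <- function(config) {
  iso <- .stage("read_isotigs", read_gtf(config$isotigs))
  ann <- .stage("read_annotation", read_gtf(config$annotation))
  expr <- .stage("read_expression", read_expression(config$expression))
  scores <- .stage("read_scores", read_coding_scores(config$coding_scores))
  catalog <- if (!is.null(config$known_catalog))
    .stage("read_catalog", read_bed(config$known_catalog)) else NULL
  repeats <- if (!is.null(config$repeats))
    .stage("read_repeats", read_bed(config$repeats)) else NULL
  track <- if (!is.null(config$conservation))
    .stage("read_conservation", read_track(config$conservation)) else NULL

  disc <- .stage("discovery",
                 discover_transcripts(iso, ann, expr, catalog,
                                      config$min_length, config$min_max_fpkm))
  retained_ids <- unique(disc$transcripts$transcript_id)

  consensus <- .stage("coding_consensus", {
    if (length(retained_ids) == 0L) character(0L) else
      consensus_lncrnas(
        call_noncoding_cpc(scores, retained_ids, config$cpc_cutoff),
        call_noncoding_plek(scores, retained_ids, config$plek_cutoff),
        call_domain_free(scores, retained_ids, config$evalue_threshold))
  })
  lnc <- disc$transcripts[disc$transcripts$transcript_id %in% consensus, ,
                          drop = FALSE]

  classes <- .stage("positional_classes", {
    if (length(consensus) == 0L) setNames(character(0L), character(0L))
    else classify_positional(lnc, ann)
  })

  features <- .stage("characterization", {
    if (length(consensus) == 0L) NULL
    else feature_table(lnc, disc$expr, track, repeats)
  })

  # cluster lncRNAs together with the expressed annotated genes
  cl_expr <- .stage("clustering_input", {
    keep <- union(rownames(expr$values)[rownames(expr$values) %in%
                                          unique(ann$transcript_id)],
                  character(0L))
    m <- rbind(expr$values[keep, , drop = FALSE],
               disc$expr$values[retained_ids, , drop = FALSE])
    expression_table(m, expr$meta)
  })
  clusters <- .stage("clustering",
                     cluster_expression(cl_expr, config$expressed_threshold,
                                        config$cluster_cut))

  schemes <- .stage("deg_schemes", build_schemes(expr$meta))
  regional <- schemes[grep("^regional", names(schemes))]
  deg <- .stage("deg", lapply(schemes, function(sc)
    deg_call(cl_expr, sc, replicate_pairs(cl_expr$meta),
             config$q_threshold)))

  enrichment <- if (!is.null(config$term_map)) .stage("enrichment", {
    tm <- read.delim(config$term_map, stringsAsFactors = FALSE)
    cluster_enrichment(clusters$clusters, tm,
                       p_cutoff = config$enrich_p,
                       fdr_cutoff = config$enrich_fdr)
  }) else NULL

  hits <- NULL
  candidates <- NULL
  have_xs <- !is.null(config$homolog_seqs) &&
    !is.null(config$homolog_catalog) && !is.null(config$homology_map) &&
    !is.null(config$genome_fasta)
  if (have_xs && length(consensus) > 0L) {
    hits <- .stage("cross_species", {
      genome <- read_fasta(config$genome_fasta)
      qseqs <- transcript_sequences(lnc, genome)
      qchrom <- setNames(transcript_summary(lnc)$chrom,
                         transcript_summary(lnc)$transcript_id)
      cross_species_hits(qseqs, qchrom,
                         read_fasta(config$homolog_seqs),
                         read.delim(config$homolog_catalog,
                                    stringsAsFactors = FALSE),
                         read.delim(config$homology_map,
                                    stringsAsFactors = FALSE))
    })
    candidates <- .stage("candidate_selection", {
      lnc_clustered <- intersect(consensus, names(clusters$clusters))
      if (length(lnc_clustered) == 0L || length(regional) == 0L) NULL
      else select_candidates(lnc_clustered, clusters$clusters,
                             config$selected_clusters,
                             unname(deg[names(regional)]), hits)
    })
  }

  manifest <- c(disc$report,
                noncoding_cpc = length(call_noncoding_cpc(
                  scores, retained_ids, config$cpc_cutoff)),
                noncoding_plek = length(call_noncoding_plek(
                  scores, retained_ids, config$plek_cutoff)),
                domain_free = length(call_domain_free(
                  scores, retained_ids, config$evalue_threshold)),
                consensus_lncrnas = length(consensus),
                class_counts(classes),
                expressed = length(expressed_filter(
                  cl_expr, config$expressed_threshold)),
                n_clusters = clusters$n_clusters,
                setNames(vapply(deg, function(d) sum(d$call), integer(1L)),
                         paste0("deg_", names(deg))),
                candidates = if (is.null(candidates)) 0L
                             else sum(candidates$candidate))

  result <- structure(list(discovery = disc, consensus_ids = consensus,
                           lncrnas = lnc, classes = classes,
                           features = features, clusters = clusters,
                           deg = deg, enrichment = enrichment, hits = hits,
                           candidates = candidates, manifest = manifest,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

#' Write pipeline stage outputs
#'
#' Emits the retained transcripts (GTF), per-transcript class/novelty TSV,
#' feature TSV, cluster assignment TSV, per-scheme differential-expression
#' TSVs, enrichment and candidate TSVs where available, and the manifest
#' TSV (`stage`, `count`) plus a thresholds TSV.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_gtf(result$discovery$transcripts, p("retained.gtf"))
  if (length(result$consensus_ids) > 0L) {
    write_gtf(result$lncrnas, p("lncrnas.gtf"))
    write.table(data.frame(
      transcript_id = names(result$classes),
      class = unname(result$classes),
      novelty = ifelse(result$discovery$novelty[names(result$classes)],
                       "known", "novel")),
      p("lncrna_classes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$features))
    write.table(result$features, p("features.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write.table(data.frame(transcript_id = names(result$clusters$clusters),
                         cluster = unname(result$clusters$clusters)),
              p("clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$clusters$merges, p("merge_tree.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in names(result$deg))
    write.table(result$deg[[nm]], p(paste0("deg_", nm, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(result$enrichment))
    write.table(result$enrichment, p("enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(result$hits))
    write.table(result$hits, p("cross_species_hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(result$candidates))
    write.table(result$candidates, p("candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write.table(data.frame(stage = names(result$manifest),
                         count = unname(result$manifest)),
              p("manifest.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  th <- result$config[c("min_length", "min_max_fpkm", "cpc_cutoff",
                        "plek_cutoff", "evalue_threshold",
                        "expressed_threshold", "cluster_cut", "q_threshold",
                        "enrich_p", "enrich_fdr")]
  write.table(data.frame(parameter = names(th),
                         value = unlist(th, use.names = FALSE)),
              p("thresholds.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("lncfeather pipeline result\n")
  m <- x$manifest
  for (nm in names(m)) cat(sprintf("  %-24s %s\n", nm, m[[nm]]))
  invisible(x)
}
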