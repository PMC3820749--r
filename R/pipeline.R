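# Configuration-driven orchestration of the full analysis:
# synthesis (optional) -> expression classification -> peak-gene
# association -> signature enrichment -> coverage/DRB response ->
# qPCR/phenotype summaries, with a manifest recording digests of every
# input and output for provenance.

PIPELINE_KEYS <- c("output_dir", "seed", "synth", "inputs", "thresholds",
                   "association", "coverage", "conditions")

#' Load and validate a pipeline configuration
#'
#' YAML (or list) with keys: `output_dir`; `seed`; either `synth`
#' (arguments for [synth_config()]) or `inputs` (paths: genes, fpkm,
#' peaks_ash1l, peaks_rar, coverage per mark/condition, signatures,
#' genome); optional `thresholds` ([response_thresholds()] arguments),
#' `association` (flank, upstream), `coverage` (bin_width,
#' total_mapped_reads, drb_edges, pseudocount) and `conditions` (column
#' names: wt, wt_ra, mut, mut_ra).  Unknown top-level keys are rejected.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_validation("config file not found: ",
                                              config)
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop_validation("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$output_dir))
    stop_validation("config needs an output_dir")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$synth) && is.null(config$inputs))
    stop_validation("config needs either 'synth' or 'inputs'")
  if (!is.null(config$inputs)) {
    missing <- Filter(function(p) !file.exists(p),
                      unlist(config$inputs, use.names = FALSE))
    if (length(missing))
      stop_validation("missing input file(s): ",
                      paste(missing, collapse = ", "))
  }
  defaults <- list(
    thresholds = list(), association = list(flank = 4000, upstream = 20000),
    coverage = list(drb_edges = c(-0.6, 0.6), pseudocount = 0.1),
    conditions = list(wt = "WT", wt_ra = "WT_RA", mut = "dSET",
                      mut_ra = "dSET_RA"))
  for (k in names(defaults))
    config[[k]] <- utils::modifyList(defaults[[k]],
                                     as.list(config[[k]]))
  class(config) <- "pipeline_config"
  config
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full pipeline
#'
#' Executes all stages on synthetic or file inputs, writes result tables
#' under `output_dir`, and returns (and writes) a run manifest with
#' per-file MD5 digests; identical config + seed reproduce identical
#' digests.
#'
#' @param config a [pipeline_config()] (or path/list coercible to one).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, path)
    path
  }

  # stage: inputs --------------------------------------------------------
  if (!is.null(config$synth)) {
    .stage_log("synth", "generating synthetic inputs")
    sc <- do.call(synth_config,
                  utils::modifyList(as.list(config$synth),
                                    list(seed = config$seed)))
    syn <- synth_generate(sc, out_dir = file.path(out_dir, "synth"))
    written <- c(written, unname(syn$files))
    genome <- syn$genome; genes <- syn$genes
    fpkm <- syn$expression; peaks <- syn$peaks
    coverage <- syn$coverage; signatures <- syn$signatures
  } else {
    ip <- config$inputs
    .stage_log("input", "reading ", length(unlist(ip)), " input file(s)")
    gtab <- utils::read.delim(ip$genome, stringsAsFactors = FALSE)
    genome <- genome_info(stats::setNames(gtab$size, gtab$chrom))
    genes <- read_gene_models(ip$genes, genome = genome)
    fpkm <- read_expression_table(ip$fpkm)
    peaks <- list(
      ash1l = read_bed(ip$peaks_ash1l, factor = "Ash1l", genome = genome),
      rar = read_bed(ip$peaks_rar, factor = "RAR", genome = genome))
    coverage <- NULL
    if (!is.null(ip$coverage)) {
      cc <- config$coverage
      coverage <- lapply(ip$coverage, function(conds)
        lapply(conds, function(path)
          read_bedgraph(path, cc$bin_width, cc$total_mapped_reads,
                        genome = genome)))
    }
    signatures <- if (!is.null(ip$signatures))
      read_signature_labels(ip$signatures)
  }

  thr <- do.call(response_thresholds, as.list(config$thresholds))
  cond <- config$conditions

  # stage: expression ----------------------------------------------------
  resp <- classify_ra_responsive(fpkm, cond$wt_ra, cond$wt, thr)
  imp <- classify_impaired(fpkm, cond$mut_ra, cond$wt_ra, resp, thr)
  dys <- classify_dysregulated(fpkm, cond$mut, cond$wt, thr)
  .stage_log("expression", sum(resp$eligible), " eligible genes; ",
             sum(resp$responsive), " RA-responsive; ",
             sum(imp$impaired), " impaired; ",
             length(dys$down), " down / ", length(dys$up),
             " up dysregulated")
  labels <- merge(resp, imp[c("gene_id", "dlog2_genotype", "impaired")],
                  by = "gene_id", sort = FALSE)
  labels$down_dysregulated <- labels$gene_id %in% dys$down
  labels$up_dysregulated <- labels$gene_id %in% dys$up
  emit(labels, "expression_labels.tsv")

  # stage: association ---------------------------------------------------
  assoc <- config$association
  ash_assoc <- associate_peaks(genes, peaks$ash1l,
                               association_rule("tss_window",
                                                flank = assoc$flank),
                               genome = genome)
  rar_assoc <- associate_peaks(genes, peaks$rar,
                               association_rule("upstream_and_body",
                                                upstream = assoc$upstream),
                               genome = genome)
  cooc <- co_occupancy(peaks$rar, peaks$ash1l)
  .stage_log("association", sum(ash_assoc$associated), " Ash1l-target and ",
             sum(rar_assoc$associated), " RAR-associated genes; ",
             "RAR/Ash1l peak co-occupancy ",
             round_half_up(100 * cooc, 1), "%")
  gene_flags <- data.frame(
    gene_id = genes$gene_id,
    ash1l_target = ash_assoc$associated,
    rar_associated = rar_assoc$associated, stringsAsFactors = FALSE)
  emit(gene_flags, "gene_flags.tsv")
  impaired_ids <- labels$gene_id[labels$impaired]
  venn <- cross_tabulate(gene_flags$gene_id[gene_flags$ash1l_target],
                         impaired_ids, genes$gene_id)
  .stage_log("association", "Ash1l-target x impaired: ",
             paste(names(venn), venn, sep = "=", collapse = ", "))

  # stage: enrichment -----------------------------------------------------
  enrich <- NULL
  if (!is.null(signatures) && length(impaired_ids)) {
    enrich <- enrichment_vs_background(impaired_ids, signatures,
                                       universe = genes$gene_id)
    emit(as.data.frame(enrich), "signature_enrichment.tsv")
    .stage_log("enrichment", "impaired-gene signature enrichment written")
  }

  # stage: coverage -------------------------------------------------------
  drb <- NULL
  if (!is.null(coverage)) {
    cc <- config$coverage
    for (mark in names(coverage)) {
      norm <- lapply(coverage[[mark]], function(tr)
        percentile75_normalize(gene_rpkm_table(tr, genes)))
      d <- drb_dlog2(norm[["DRB+"]], norm[["DRB-"]],
                     pseudocount = cc$pseudocount)
      grp <- group_by_response(d, edges = cc$drb_edges)
      rep_tab <- underrepresentation_test(
        grp, data.frame(gene_id = gene_flags$gene_id,
                        flag = gene_flags$rar_associated))
      emit(grp, sprintf("drb_response_%s.tsv", mark))
      emit(as.data.frame(rep_tab),
           sprintf("rar_representation_%s.tsv", mark))
      .stage_log("coverage", mark, ": ",
                 paste(levels(grp$group), tabulate(grp$group),
                       sep = "=", collapse = ", "))
      if (mark == "K36me3") drb <- list(groups = grp, report = rep_tab)
    }
  }

  # manifest --------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("ash36")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config = unclass(config),
    outputs = as.list(tools::md5sum(sort(unique(written)))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  .stage_log("done", length(manifest$outputs), " files written to ",
             out_dir)
  invisible(manifest)
}
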