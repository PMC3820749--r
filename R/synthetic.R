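# Seeded synthetic-data generator.  It emulates the statistical structure
# the analysis assumes: four-condition FPKM tables with RA-responsive and
# impaired genes, Ash1l/RAR peak sets with controllable co-occupancy,
# K36me2/3 coverage tracks whose DRB response is attenuated at
# RAR-associated genes, and chromatin-signature labels correlated with
# responsiveness.  Genes are placed far apart so that the ground-truth
# labels map one-to-one onto what the association rules recover.

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the study conditions the pipeline targets: ~3.8% of
#' genes RA-responsive, 28% of those impaired in the mutant, ~30% Ash1l
#' targets, 60% RAR/Ash1l peak co-occupancy, a mean RA induction of 3 log2
#' units, mutant impairment of -1.5, and a DRB-induced K36me3 loss of -1.0
#' log2 that is attenuated to -0.1 at RAR-associated genes (K36me2 instead
#' gains +0.3).  See the package vignette for the calibration rationale.
#'
#' @param seed RNG seed; identical seed + config gives byte-identical
#'   outputs.
#' @param n_genes,n_chroms number of genes / chromosomes.
#' @param gene_length_range bp bounds for transcription-unit lengths; the
#'   minimum must exceed 5100 bp so RAR peaks fit in the gene body clear of
#'   the TSS window.
#' @param gene_spacing bp between consecutive gene starts (default 50 kb),
#'   chosen so the +/-4 kb and -20 kb windows of distinct genes never
#'   collide.
#' @param frac_ra_responsive fraction of genes induced by RA.
#' @param frac_impaired_given_responsive fraction of responsive genes
#'   impaired in the mutant.
#' @param frac_ash1l_target fraction of genes with an Ash1l TSS peak.
#' @param frac_rar_associated fraction of genes with a RAR peak in the
#'   upstream/body window.
#' @param co_occupancy probability that a RAR peak is accompanied by an
#'   overlapping Ash1l peak (independently per peak).
#' @param signature_probs list with numeric vectors `base` and
#'   `responsive`, each giving probabilities over the four signature
#'   states (Lys4me alone, Bivalent, Lys27me alone, None).
#' @param baseline_fpkm_log_mean,baseline_fpkm_log_sd log2-scale mean/sd of
#'   baseline FPKM (lognormal).
#' @param ra_effect_log2 mean log2 induction of responsive genes.
#' @param impair_effect_log2 mean log2 reduction in the mutant under RA.
#' @param drb_me3_loss_log2,drb_me3_loss_rar_log2 mean log2 change of
#'   K36me3 body coverage under DRB for non-RAR / RAR-associated genes.
#' @param drb_me2_gain_log2 mean log2 change of K36me2 under DRB.
#' @param noise_sd_log2 sd of multiplicative lognormal measurement noise.
#' @param coverage_baseline_density mean ChIP read density over gene bodies
#'   (reads/bp).
#' @param coverage_density_log_sd log2-scale sd of per-gene baseline
#'   density.
#' @param bin_width coverage bin width (bp).
#' @param total_reads_per_track nominal library size per track.
#' @param marks ChIP marks to simulate coverage for.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_genes = 2000L,
                         n_chroms = 4L,
                         gene_length_range = c(6000, 20000),
                         gene_spacing = 50000,
                         frac_ra_responsive = 0.038,
                         frac_impaired_given_responsive = 0.28,
                         frac_ash1l_target = 0.30,
                         frac_rar_associated = 0.40,
                         co_occupancy = 0.60,
                         signature_probs = list(
                           base = c("Lys4me alone" = 0.35, Bivalent = 0.15,
                                    "Lys27me alone" = 0.05, None = 0.45),
                           responsive = c("Lys4me alone" = 0.15,
                                          Bivalent = 0.55,
                                          "Lys27me alone" = 0.10,
                                          None = 0.20)),
                         baseline_fpkm_log_mean = 3.3,
                         baseline_fpkm_log_sd = 1.5,
                         ra_effect_log2 = 3.0,
                         impair_effect_log2 = -1.5,
                         drb_me3_loss_log2 = -1.0,
                         drb_me3_loss_rar_log2 = -0.1,
                         drb_me2_gain_log2 = 0.3,
                         noise_sd_log2 = 0.15,
                         coverage_baseline_density = 0.5,
                         coverage_density_log_sd = 0.10,
                         bin_width = 200,
                         total_reads_per_track = 1e6,
                         marks = c("K36me2", "K36me3")) {
  cfg <- as.list(environment())
  check_positive(n_genes, "n_genes")
  check_positive(n_chroms, "n_chroms")
  for (f in c("frac_ra_responsive", "frac_impaired_given_responsive",
              "frac_ash1l_target", "frac_rar_associated", "co_occupancy"))
    check_fraction(cfg[[f]], f)
  for (p in signature_probs) {
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop_validation("signature_probs entries must be 4 probabilities summing to 1")
  }
  if (length(gene_length_range) != 2L || gene_length_range[1] < 5100 ||
      diff(gene_length_range) < 0)
    stop_validation("gene_length_range must be increasing with minimum >= 5100")
  if (gene_length_range[2] > gene_spacing - 30000)
    stop_validation("gene_spacing too small for gene_length_range")
  check_positive(noise_sd_log2, "noise_sd_log2", strict = FALSE)
  check_positive(bin_width, "bin_width")
  check_positive(total_reads_per_track, "total_reads_per_track")
  check_positive(coverage_baseline_density, "coverage_baseline_density")
  structure(cfg, class = "synth_config")
}

.synth_margin <- 25000

#' Generate a synthetic data set
#'
#' Draws gene models, truth labels, FPKM tables for
#' {WT, dSET} x {undifferentiated, +RA}, Ash1l/RAR peak sets, K36me2/3
#' coverage tracks with and without DRB, and signature labels, all from a
#' single seed.  Each component uses its own derived sub-seed, so
#' restricting `what` does not change the components that are generated.
#'
#' Ash1l TSS peaks are placed so that exactly the genes labeled
#' `ash1l_target` carry a peak in the +/-4 kb TSS window, and RAR body
#' peaks so that exactly the `rar_associated` genes satisfy the
#' upstream/body rule; each RAR peak gains an overlapping Ash1l partner
#' peak with probability `co_occupancy`.
#'
#' @param config a [synth_config()].
#' @param out_dir optional directory; when given, all components are also
#'   written as GTF/BED12/TSV/BED/bedGraph files.
#' @param what components to generate besides gene models and truth
#'   labels.
#' @return list with genome, genes, truth, and the requested components
#'   (expression, peaks, coverage, signatures); `files` lists written
#'   paths when `out_dir` is used.
#' @export
synth_generate <- function(config,
                           out_dir = NULL,
                           what = c("expression", "peaks", "coverage",
                                    "signatures")) {
  stopifnot(inherits(config, "synth_config"))
  what <- match.arg(what, several.ok = TRUE)
  seeds <- with_seed(config$seed, sample.int(2^31 - 2, 6L))

  n <- config$n_genes
  # --- placement -------------------------------------------------------------
  pl <- with_seed(seeds[1], {
    chrom_idx <- sort(rep_len(seq_len(config$n_chroms), n))
    ordinal <- stats::ave(seq_len(n), chrom_idx, FUN = seq_along)
    jitter <- sample.int(1000L, n, replace = TRUE) - 1L
    len <- sample.int(diff(config$gene_length_range) + 1L, n,
                      replace = TRUE) + config$gene_length_range[1] - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    list(chrom_idx = chrom_idx, ordinal = ordinal, jitter = jitter,
         len = len, strand = strand)
  })
  chrom <- sprintf("chr%d", pl$chrom_idx)
  start <- .synth_margin + (pl$ordinal - 1) * config$gene_spacing + pl$jitter
  genes_per_chrom <- tabulate(pl$chrom_idx, config$n_chroms)
  sizes <- genes_per_chrom * config$gene_spacing + 2 * .synth_margin
  genome <- genome_info(stats::setNames(sizes,
                                        sprintf("chr%d",
                                                seq_len(config$n_chroms))))
  genes <- gene_models(sprintf("gene_%05d", seq_len(n)), chrom, start,
                       start + pl$len, pl$strand, genome = genome)

  # --- truth labels ----------------------------------------------------------
  truth <- with_seed(seeds[2], {
    responsive <- stats::runif(n) < config$frac_ra_responsive
    impaired <- responsive &
      stats::runif(n) < config$frac_impaired_given_responsive
    ash1l_target <- stats::runif(n) < config$frac_ash1l_target
    rar_associated <- stats::runif(n) < config$frac_rar_associated
    sig <- character(n)
    pr_base <- config$signature_probs$base
    pr_resp <- config$signature_probs$responsive
    for (i in seq_len(n))
      sig[i] <- sample(SIGNATURE_LEVELS, 1L,
                       prob = if (responsive[i]) pr_resp else pr_base)
    data.frame(gene_id = genes$gene_id, responsive = responsive,
               impaired = impaired, ash1l_target = ash1l_target,
               rar_associated = rar_associated,
               rar_cooccupied = FALSE, signature = sig,
               dlog2_ra_true = ifelse(responsive, config$ra_effect_log2, 0),
               dlog2_genotype_true = ifelse(impaired,
                                            config$impair_effect_log2, 0),
               stringsAsFactors = FALSE)
  })

  out <- list(config = config, genome = genome, genes = genes)

  # --- expression ------------------------------------------------------------
  if ("expression" %in% what) {
    out$expression <- with_seed(seeds[3], {
      baseline <- 2^stats::rnorm(n, config$baseline_fpkm_log_mean,
                                 config$baseline_fpkm_log_sd)
      noise <- function() 2^stats::rnorm(n, 0, config$noise_sd_log2)
      data.frame(
        gene_id = genes$gene_id,
        WT = baseline * noise(),
        WT_RA = baseline * 2^truth$dlog2_ra_true * noise(),
        dSET = baseline * noise(),
        dSET_RA = baseline *
          2^(truth$dlog2_ra_true + truth$dlog2_genotype_true) * noise(),
        stringsAsFactors = FALSE)
    })
  }

  # --- peaks -----------------------------------------------------------------
  if ("peaks" %in% what || "coverage" %in% what) {
    pk <- with_seed(seeds[4], {
      tgt <- which(truth$ash1l_target)
      ash <- data.frame(chrom = genes$chrom[tgt],
                        start = genes$tss[tgt] - 250,
                        end = genes$tss[tgt] + 250,
                        stringsAsFactors = FALSE)
      rar_ix <- which(truth$rar_associated)
      # body position clear of the TSS window: offsets in
      # [4750, len - 300] keep the 500-bp peak > 4 kb from the TSS and
      # inside the transcription unit
      off <- numeric(length(rar_ix))
      if (length(rar_ix)) {
        lo <- 4750
        hi <- pl$len[rar_ix] - 300
        off <- lo + floor(stats::runif(length(rar_ix)) * (hi - lo + 1))
      }
      plus <- genes$strand[rar_ix] == "+"
      centers <- ifelse(plus, genes$tss[rar_ix] + off,
                        genes$tss[rar_ix] - off)
      rar <- data.frame(chrom = genes$chrom[rar_ix],
                        start = centers - 250, end = centers + 250,
                        stringsAsFactors = FALSE)
      cooc <- stats::runif(length(rar_ix)) < config$co_occupancy
      partner <- data.frame(chrom = rar$chrom[cooc],
                            start = centers[cooc] - 200,
                            end = centers[cooc] + 300,
                            stringsAsFactors = FALSE)
      list(ash = ash, rar = rar, partner = partner,
           rar_ix = rar_ix, cooc = cooc)
    })
    truth$rar_cooccupied[pk$rar_ix] <- pk$cooc
    ash_all <- rbind(pk$ash, pk$partner)
    out$peaks <- list(
      ash1l = peak_set(ash_all$chrom, ash_all$start, ash_all$end,
                       name = sprintf("ash1l_%05d", seq_len(nrow(ash_all))),
                       factor = "Ash1l", genome = genome),
      rar = peak_set(pk$rar$chrom, pk$rar$start, pk$rar$end,
                     name = sprintf("rar_%05d", seq_len(nrow(pk$rar))),
                     factor = "RAR", genome = genome))
  }

  # --- coverage --------------------------------------------------------------
  if ("coverage" %in% what) {
    bw <- config$bin_width
    flank <- 5000
    block_start <- pmax(floor((genes$start - flank) / bw) * bw, 0)
    block_end <- pmin(ceiling((genes$end + flank) / bw) * bw,
                      unname(genome[genes$chrom]))
    nb <- as.integer((block_end - block_start) / bw +
                       ((block_end - block_start) %% bw > 0))
    bin_chrom <- rep(genes$chrom, nb)
    bin_start <- rep(block_start, nb) + bw * (sequence(nb) - 1)
    bin_w <- pmin(bw, rep(block_end, nb) - bin_start)
    out$coverage <- with_seed(seeds[5], {
      cov <- list()
      for (mark in config$marks) {
        base <- config$coverage_baseline_density *
          2^stats::rnorm(n, 0, config$coverage_density_log_sd)
        delta <- if (mark == "K36me3")
          ifelse(truth$rar_associated, config$drb_me3_loss_rar_log2,
                 config$drb_me3_loss_log2)
        else rep(config$drb_me2_gain_log2, n)
        truth[[paste0("drb_", tolower(mark), "_dlog2_true")]] <- delta
        dens_minus <- base * 2^stats::rnorm(n, 0, config$noise_sd_log2)
        dens_plus <- base * 2^(delta + stats::rnorm(n, 0,
                                                    config$noise_sd_log2))
        cov[[mark]] <- list(
          `DRB-` = coverage_track(bin_chrom, bin_start,
                                  stats::rpois(length(bin_start),
                                               rep(dens_minus, nb) * bin_w),
                                  bw, config$total_reads_per_track,
                                  mark = mark, condition = "DRB-",
                                  genome = genome),
          `DRB+` = coverage_track(bin_chrom, bin_start,
                                  stats::rpois(length(bin_start),
                                               rep(dens_plus, nb) * bin_w),
                                  bw, config$total_reads_per_track,
                                  mark = mark, condition = "DRB+",
                                  genome = genome))
      }
      cov
    })
  }

  # --- signatures ------------------------------------------------------------
  if ("signatures" %in% what) {
    sig <- factor(truth$signature, levels = SIGNATURE_LEVELS)
    out$signatures <- data.frame(
      gene_id = genes$gene_id,
      k4me3 = sig %in% c("Lys4me alone", "Bivalent"),
      k27me3 = sig %in% c("Lys27me alone", "Bivalent"),
      signature = sig, stringsAsFactors = FALSE)
  }

  out$truth <- truth

  if (!is.null(out_dir)) out$files <- .synth_write(out, out_dir)
  invisible(out)
}

.synth_write <- function(x, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_validation("cannot create output directory: ", out_dir)
  p <- function(f) file.path(out_dir, f)
  files <- c(genes_gtf = p("genes.gtf"), genes_bed12 = p("genes.bed12"),
             genome = p("genome.tsv"), truth = p("truth.tsv"))
  write_gene_models_gtf(x$genes, files["genes_gtf"])
  write_gene_models_bed12(x$genes, files["genes_bed12"])
  utils::write.table(
    data.frame(chrom = names(x$genome), size = as.numeric(x$genome)),
    files["genome"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$truth, files["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(x$expression)) {
    files["fpkm"] <- p("fpkm.tsv")
    write_expression_table(x$expression, files["fpkm"])
  }
  if (!is.null(x$peaks)) {
    files["peaks_ash1l"] <- p("peaks_ash1l.bed")
    files["peaks_rar"] <- p("peaks_rar.bed")
    write_bed(x$peaks$ash1l, files["peaks_ash1l"])
    write_bed(x$peaks$rar, files["peaks_rar"])
  }
  for (mark in names(x$coverage)) {
    for (cond in names(x$coverage[[mark]])) {
      tag <- paste0(mark, "_", if (cond == "DRB+") "DRBplus" else "DRBminus")
      files[tag] <- p(paste0("coverage_", tag, ".bedgraph"))
      write_bedgraph(x$coverage[[mark]][[cond]], files[tag])
    }
  }
  if (!is.null(x$signatures)) {
    files["signatures"] <- p("signatures.tsv")
    utils::write.table(x$signatures, files["signatures"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  files
}

#' Generate a synthetic ChIP-qPCR percent-input table
#'
#' Triplicate percent-input values drawn around configured means with
#' Gaussian noise, in the long format the qPCR summaries consume.
#'
#' @param means data.frame with columns region, antibody, genotype,
#'   condition, mean_percent_input; one row per assayed combination.
#' @param noise_sd sd of the per-replicate noise (percent-input units);
#'   0 gives replicates equal to the configured means.
#' @param n_reps replicates per combination (default 3).
#' @param seed RNG seed.
#' @return long data.frame: region, antibody, genotype, condition,
#'   replicate, percent_input.
#' @export
synth_qpcr_table <- function(means, noise_sd = 0.05, n_reps = 3L,
                             seed = 1L) {
  need <- c("region", "antibody", "genotype", "condition",
            "mean_percent_input")
  if (!all(need %in% names(means)))
    stop_validation("means needs columns: ", paste(need, collapse = ", "))
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  with_seed(seed, {
    idx <- rep(seq_len(nrow(means)), each = n_reps)
    out <- means[idx, c("region", "antibody", "genotype", "condition")]
    out$replicate <- rep(seq_len(n_reps), nrow(means))
    out$percent_input <- pmax(
      means$mean_percent_input[idx] +
        stats::rnorm(length(idx), 0, noise_sd), 0)
    rownames(out) <- NULL
    out
  })
}

#' Generate synthetic phenotype penetrance counts
#'
#' Affected animals are binomial draws per genotype; when phenotype
#' probabilities are given, the affected animals are split multinomially
#' across phenotypes.
#'
#' @param penetrance named vector of per-genotype penetrance (probability
#'   an animal is affected).
#' @param n_analyzed named vector of animals per genotype.
#' @param phenotype_probs optional named probability vector over phenotypes
#'   (conditional on being affected).
#' @param seed RNG seed.
#' @return list with `n_analyzed`, `n_affected` and, when phenotype
#'   probabilities are supplied, a phenotype x genotype count matrix.
#' @export
synth_phenotype_counts <- function(penetrance, n_analyzed,
                                   phenotype_probs = NULL, seed = 1L) {
  if (!identical(names(penetrance), names(n_analyzed)))
    stop_validation("penetrance and n_analyzed must share genotype names")
  for (pp in penetrance) check_fraction(pp, "penetrance")
  with_seed(seed, {
    affected <- stats::rbinom(length(penetrance), n_analyzed, penetrance)
    names(affected) <- names(penetrance)
    out <- list(n_analyzed = n_analyzed, n_affected = affected)
    if (!is.null(phenotype_probs)) {
      m <- vapply(seq_along(affected), function(i)
        stats::rmultinom(1, affected[i], phenotype_probs)[, 1],
        numeric(length(phenotype_probs)))
      dimnames(m) <- list(names(phenotype_probs), names(penetrance))
      out$phenotype_counts <- m
    }
    out
  })
}
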