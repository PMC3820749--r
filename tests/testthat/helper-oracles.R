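# Brute-force per-base oracles and small fixture builders used across the
# suite.  The oracles deliberately share no code with the implementation:
# membership and coverage are computed by enumerating bases.

# bases covered by [start, end) as a plain integer set
oracle_bases <- function(start, end) {
  if (end <= start) integer() else seq.int(start, end - 1L)
}

oracle_overlaps <- function(s1, e1, s2, e2) {
  length(intersect(oracle_bases(s1, e1), oracle_bases(s2, e2))) > 0L
}

# per-base window membership for the association rules
oracle_tss_window_bases <- function(tss, flank, chrom_size = Inf) {
  b <- (tss - flank):(tss + flank)
  b[b >= 0 & b < chrom_size]
}

oracle_upstream_body_bases <- function(tss, tes, upstream,
                                       chrom_size = Inf) {
  b <- if (tss <= tes) (tss - upstream):tes else tes:(tss + upstream)
  b[b >= 0 & b < chrom_size]
}

# expand a coverage track on a small genome into per-base read density,
# then sum over a region (reads are uniform within a nominal-width bin)
oracle_track_density <- function(bins, bin_width, chrom_size) {
  dens <- numeric(chrom_size)
  for (i in seq_len(nrow(bins))) {
    b <- oracle_bases(bins$start[i], min(bins$start[i] + bin_width,
                                         chrom_size))
    dens[b + 1L] <- bins$count[i] / bin_width
  }
  dens
}

oracle_region_reads <- function(dens, start, end) {
  sum(dens[oracle_bases(start, end) + 1L])
}

# random small-genome fixture: genes and peaks on one chromosome
random_genome_fixture <- function(chrom_size = 1e5, n_genes = 20,
                                  n_peaks = 30) {
  genome <- genome_info(c(chrT = chrom_size))
  start <- sort(sample.int(chrom_size - 6000L, n_genes))
  len <- sample(500:5000, n_genes, replace = TRUE)
  genes <- gene_models(sprintf("g%03d", seq_len(n_genes)), "chrT", start,
                       pmin(start + len, chrom_size),
                       sample(c("+", "-"), n_genes, TRUE), genome = genome)
  ps <- sample.int(chrom_size - 500L, n_peaks)
  peaks <- peak_set("chrT", ps, ps + sample(50:400, n_peaks, TRUE),
                    factor = "X", genome = genome)
  list(genome = genome, genes = genes, peaks = peaks)
}

# a small deterministic synthetic config for fast end-to-end tests
small_synth_config <- function(seed = 11L, n_genes = 400L, ...) {
  synth_config(seed = seed, n_genes = n_genes, n_chroms = 2L, ...)
}
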