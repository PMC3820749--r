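# Peak-to-gene association under the two window rules used to define
# Ash1l-target genes (peak within +/- 4 kb of the TSS) and RAR-associated
# genes (peak between 20 kb upstream of the TSS and the TES).

#' Peak-to-gene association rule
#'
#' @param mode "tss_window" (peak overlaps `[tss - flank, tss + flank]`) or
#'   "upstream_and_body" (peak overlaps `[tss - upstream, tes]`,
#'   strand-aware).
#' @param flank bp for the TSS window (default 4000).
#' @param upstream bp for the upstream window (default 20000).
#' @return an `association_rule` list.
#' @export
association_rule <- function(mode = c("tss_window", "upstream_and_body"),
                             flank = 4000, upstream = 20000) {
  mode <- match.arg(mode)
  check_positive(flank, "flank")
  check_positive(upstream, "upstream")
  structure(list(mode = mode, flank = flank, upstream = upstream),
            class = "association_rule")
}

gene_windows <- function(genes, rule, genome = NULL) {
  switch(rule$mode,
         tss_window = tss_window(genes, rule$flank, genome),
         upstream_and_body = upstream_body_window(genes, rule$upstream,
                                                  genome))
}

#' Associate peaks with genes
#'
#' A gene is flagged when at least one peak overlaps its rule window (any
#' overlap of the peak interval, half-open semantics).  A peak may associate
#' with several genes and the result does not depend on input order.
#'
#' @param genes a [gene_models()] object.
#' @param peaks a [peak_set()].
#' @param rule an [association_rule()].
#' @param genome optional [genome_info()]; peaks on chromosomes absent from
#'   it raise a validation error, and windows are clipped to bounds.
#' @return data.frame gene_id, associated (logical), n_peaks, and a list
#'   column `peak_names`.
#' @export
associate_peaks <- function(genes, peaks, rule = association_rule(),
                            genome = NULL) {
  if (!is.null(genome)) {
    unknown <- setdiff(unique(peaks$chrom), names(genome))
    if (length(unknown))
      stop_validation("peaks on unknown chromosome(s): ",
                      paste(unknown, collapse = ", "))
  }
  win <- gene_windows(genes, rule, genome)
  hits <- vector("list", nrow(win))
  by_chrom <- split(seq_len(nrow(peaks)), peaks$chrom)
  for (i in seq_len(nrow(win))) {
    ix <- by_chrom[[win$chrom[i]]]
    if (is.null(ix)) { hits[[i]] <- character(); next }
    sel <- peaks$start[ix] < win$end[i] & peaks$end[ix] > win$start[i]
    hits[[i]] <- peaks$name[ix[sel]]
  }
  out <- data.frame(gene_id = win$gene_id,
                    associated = lengths(hits) > 0L,
                    n_peaks = lengths(hits), stringsAsFactors = FALSE)
  out$peak_names <- hits
  out
}

#' Fraction of peaks co-occupied by a second factor
#'
#' The fraction of `primary` peaks having at least one `secondary` peak
#' within `max_gap` bp (0 = direct overlap).
#'
#' @param primary,secondary [peak_set()] objects (e.g. RAR and Ash1l).
#' @param max_gap maximum allowed gap in bp between peak edges (default 0).
#' @return fraction in [0, 1].
#' @export
co_occupancy <- function(primary, secondary, max_gap = 0) {
  if (nrow(primary) == 0L) stop_validation("primary peak set is empty")
  if (nrow(secondary) == 0L) stop_validation("secondary peak set is empty")
  check_positive(max_gap, "max_gap", strict = FALSE)
  by_chrom <- split(seq_len(nrow(secondary)), secondary$chrom)
  hit <- logical(nrow(primary))
  for (i in seq_len(nrow(primary))) {
    ix <- by_chrom[[primary$chrom[i]]]
    if (is.null(ix)) next
    hit[i] <- any(secondary$start[ix] < primary$end[i] + max_gap &
                    primary$start[i] < secondary$end[ix] + max_gap)
  }
  mean(hit)
}

#' Cross-tabulate two gene sets against a universe
#'
#' @param set_a,set_b character vectors of gene ids, subsets of `universe`.
#' @param universe character vector of all genes under consideration.
#' @return named integer vector: both, a_only, b_only, neither (sums to the
#'   universe size).
#' @export
cross_tabulate <- function(set_a, set_b, universe) {
  if (anyDuplicated(universe)) stop_validation("universe has duplicates")
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop_validation("set members outside the universe")
  a <- universe %in% set_a
  b <- universe %in% set_b
  c(both = sum(a & b), a_only = sum(a & !b),
    b_only = sum(!a & b), neither = sum(!a & !b))
}
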