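# Region RPKM, 75th-percentile normalization, DRB-response grouping with
# RAR under-representation testing, and metagene / anchor-centered
# coverage profiles.

#' RPKM of regions from a coverage track
#'
#' reads overlapping the region (partial bins pro-rated) divided by region
#' length in kb and library size in millions.
#'
#' @param track a [coverage_track()].
#' @param chrom,start,end region(s), 0-based half-open.
#' @return numeric RPKM vector.
#' @examples
#' tr <- coverage_track("chr1", c(0, 1000), c(500, 500), 1000, 1e7)
#' region_rpkm(tr, "chr1", 0, 2000)  # 1000 reads / 2 kb / 10 M = 50
#' @export
region_rpkm <- function(track, chrom, start, end) {
  if (any(end <= start)) stop_validation("zero-length region")
  reads <- track_region_reads(track, chrom, start, end)
  len_kb <- (end - start) / 1000
  reads / (len_kb * track$total_mapped_reads / 1e6)
}

#' Per-gene-body RPKM table for one track
#'
#' @param track a [coverage_track()].
#' @param genes a [gene_models()] object; RPKM is computed over each
#'   transcription unit ("coding region" in the gene-body sense).
#' @return data.frame gene_id, rpkm with attributes `mark`, `condition`,
#'   `normalized` (FALSE) and `normalizer` (NA).
#' @export
gene_rpkm_table <- function(track, genes) {
  out <- data.frame(gene_id = genes$gene_id,
                    rpkm = region_rpkm(track, genes$chrom, genes$start,
                                       genes$end),
                    stringsAsFactors = FALSE)
  attr(out, "mark") <- track$mark
  attr(out, "condition") <- track$condition
  attr(out, "normalized") <- FALSE
  attr(out, "normalizer") <- NA_real_
  out
}

#' Normalize an RPKM table to its 75th percentile
#'
#' Every value is divided by the 75th percentile of the input distribution
#' (linear interpolation between order statistics, [stats::quantile()]
#' type 7).  After normalization the table's 75th percentile is exactly 1,
#' so the operation is idempotent.
#'
#' @param table output of [gene_rpkm_table()] (or any data.frame with an
#'   `rpkm` column).
#' @return the table rescaled, with `normalized = TRUE` and the
#'   `normalizer` (in raw RPKM units) recorded as attributes.
#' @examples
#' t <- data.frame(gene_id = letters[1:4], rpkm = c(1, 2, 3, 4))
#' attr(percentile75_normalize(t), "normalizer")  # 3.25
#' @export
percentile75_normalize <- function(table) {
  x <- table$rpkm
  if (anyNA(x) || any(x < 0)) stop_validation("RPKM must be non-negative")
  if (sum(x > 0) < 4L)
    stop_validation("need at least 4 genes with RPKM > 0 to normalize")
  q <- unname(stats::quantile(x, 0.75, type = 7))
  if (q <= 0)
    stop_validation("degenerate normalizer: 75th percentile is 0")
  prev <- attr(table, "normalizer")
  table$rpkm <- x / q
  attr(table, "normalized") <- TRUE
  attr(table, "normalizer") <- if (is.null(prev) || is.na(prev)) q
                               else prev * q
  table
}

#' DRB-response delta-log2 per gene
#'
#' `log2((plus + pc) / (minus + pc))` of 75th-percentile-normalized RPKM,
#' DRB-treated over untreated.  The pseudocount (default 0.1 on the
#' normalized scale) keeps genes with zero coverage finite.
#'
#' @param plus,minus normalized RPKM tables ([percentile75_normalize()])
#'   over the same gene universe.
#' @param pseudocount added to both normalized values.
#' @return data.frame gene_id, dlog2.
#' @export
drb_dlog2 <- function(plus, minus, pseudocount = 0.1) {
  check_positive(pseudocount, "pseudocount")
  for (t in list(plus, minus))
    if (!isTRUE(attr(t, "normalized")))
      stop_validation("tables must be 75th-percentile normalized first")
  if (!identical(sort(plus$gene_id), sort(minus$gene_id)))
    stop_validation("gene universes differ between tracks")
  m <- minus$rpkm[match(plus$gene_id, minus$gene_id)]
  data.frame(gene_id = plus$gene_id,
             dlog2 = log2((plus$rpkm + pseudocount) / (m + pseudocount)),
             stringsAsFactors = FALSE)
}

#' Group genes by DRB-response fold change
#'
#' Default scheme: "decreased" (dlog2 strictly < -0.6), "unchanged"
#' (-0.6 <= dlog2 <= 0.6), "increased" (strictly > 0.6).  With more edges,
#' outer bins remain strict and internal boundaries belong to the lower
#' bin.
#'
#' @param response data.frame with gene_id and dlog2 (from [drb_dlog2()]).
#' @param edges sorted numeric bin boundaries (default c(-0.6, 0.6)).
#' @param labels group names, length `length(edges) + 1`.
#' @return data.frame gene_id, dlog2, group (factor); an exhaustive,
#'   disjoint partition.
#' @export
group_by_response <- function(response, edges = c(-0.6, 0.6),
                              labels = NULL) {
  if (is.unsorted(edges, strictly = TRUE))
    stop_validation("edges must be strictly increasing")
  if (anyNA(response$dlog2) || any(!is.finite(response$dlog2)))
    stop_validation("dlog2 values must be finite")
  k <- length(edges)
  if (is.null(labels))
    labels <- if (k == 2L) c("decreased", "unchanged", "increased")
              else sprintf("group_%d", seq_len(k + 1L))
  if (length(labels) != k + 1L)
    stop_validation("need length(edges) + 1 labels")
  d <- response$dlog2
  idx <- rep(NA_integer_, length(d))
  idx[d < edges[1L]] <- 1L
  idx[d > edges[k]] <- k + 1L
  mid <- is.na(idx)
  if (any(mid))  # middle bins are 2..k; internal boundaries go to the lower bin
    idx[mid] <- pmax(pmin(findInterval(d[mid], edges, left.open = TRUE) + 1L,
                          k), 2L)
  data.frame(gene_id = response$gene_id, dlog2 = d,
             group = factor(labels[idx], levels = labels),
             stringsAsFactors = FALSE)
}

#' Test gene groups for over/under-representation of a flag
#'
#' For each response group, a 2x2 chi-square (in group vs rest) x (flagged
#' vs not) against the total gene set, as used to show that RAR-associated
#' genes are under-represented among genes losing K36me3 under DRB.
#'
#' @param groups output of [group_by_response()].
#' @param flags logical vector (or data.frame gene_id, flag) marking e.g.
#'   RAR-associated genes, aligned with `groups$gene_id`.
#' @return `enrichment_report` data.frame: one row per group with counts,
#'   relative ratio, chi-square statistic, p-value, direction.  Empty
#'   groups are skipped with a warning.
#' @export
underrepresentation_test <- function(groups, flags) {
  if (is.data.frame(flags)) {
    if (!all(groups$gene_id %in% flags$gene_id))
      stop_validation("every grouped gene needs a flag")
    flags <- flags$flag[match(groups$gene_id, flags$gene_id)]
  }
  if (length(flags) != nrow(groups) || anyNA(flags))
    stop_validation("flags must align with groups and contain no NA")
  empty <- setdiff(levels(groups$group), unique(as.character(groups$group)))
  if (length(empty))
    warning("skipping empty group(s): ", paste(empty, collapse = ", "))
  uni_frac <- mean(flags)
  rows <- lapply(setdiff(levels(groups$group), empty), function(g) {
    ing <- groups$group == g
    tab <- matrix(c(sum(ing & flags), sum(!ing & flags),
                    sum(ing & !flags), sum(!ing & !flags)), 2L)
    res <- tryCatch(chi_square_2x2(tab),
                    error = function(e) list(statistic = NA_real_,
                                             df = NA_real_,
                                             p_value = NA_real_))
    data.frame(category = g, n_group = sum(ing),
               n_universe = nrow(groups),
               relative_ratio = mean(flags[ing]) / uni_frac,
               statistic = res$statistic, df = res$df,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$direction <- ifelse(out$relative_ratio > 1, "enriched",
                          ifelse(out$relative_ratio < 1, "depleted", "none"))
  class(out) <- c("enrichment_report", "data.frame")
  out
}

# profiles --------------------------------------------------------------------

.profile_matrix <- function(values, widths, bin_scheme, base_density) {
  dens <- values / widths
  mean_density <- colMeans(dens)
  structure(list(counts = values, widths = widths,
                 mean_density = mean_density,
                 log2_ratio = log2(mean_density / base_density),
                 base_density = base_density, bin_scheme = bin_scheme),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("<profile_matrix> ", nrow(x$counts), " regions x ",
      ncol(x$counts), " bins (", x$bin_scheme$type, "); base density ",
      signif(x$base_density, 4), " reads/bp\n", sep = "")
  invisible(x)
}

#' Metagene coverage profile
#'
#' Gene bodies are rescaled TSS to TES into `n_body_bins` position bins
#' (strand-flipped for minus-strand genes) and flanked by fixed-width bins;
#' the column-mean read density and its log2 ratio to a base density are
#' reported, as in metagene plots of K36me2/3 distributions.
#'
#' @param track a [coverage_track()].
#' @param genes a [gene_models()] object; genes shorter than `n_body_bins`
#'   bp are skipped with a warning.
#' @param n_body_bins bins across the gene body (default 100).
#' @param flank_bp flank width on each side in bp (default 2000).
#' @param flank_bins bins per flank (default 20).
#' @param base_density density (reads/bp) used as the log2-ratio baseline;
#'   default is the track's mean density over its covered bases.
#' @param genome optional [genome_info()] used to clip flanks.
#' @return a `profile_matrix`: counts matrix, per-cell widths, mean density
#'   per column, log2 ratio to base, and the bin scheme.
#' @export
metagene_profile <- function(track, genes, n_body_bins = 100,
                             flank_bp = 2000, flank_bins = 20,
                             base_density = NULL, genome = NULL) {
  check_positive(n_body_bins, "n_body_bins")
  check_positive(flank_bp, "flank_bp")
  check_positive(flank_bins, "flank_bins")
  keep <- (genes$end - genes$start) >= n_body_bins
  if (any(!keep))
    warning(sum(!keep), " gene(s) shorter than n_body_bins bp skipped")
  genes <- genes[keep, , drop = FALSE]
  if (!nrow(genes)) stop_validation("no genes long enough to profile")
  nc <- 2L * flank_bins + n_body_bins
  fw <- flank_bp / flank_bins
  counts <- matrix(0, nrow(genes), nc)
  widths <- matrix(0, nrow(genes), nc)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    body <- seq(g$start, g$end, length.out = n_body_bins + 1L)
    up <- seq(g$start - flank_bp, g$start, length.out = flank_bins + 1L)
    dn <- seq(g$end, g$end + flank_bp, length.out = flank_bins + 1L)
    edges <- c(up[-length(up)], body, dn[-1L])
    lo <- pmax(edges[-length(edges)], 0)
    hi <- edges[-1L]
    if (!is.null(genome)) hi <- pmin(hi, unname(genome[g$chrom]))
    hi <- pmax(hi, lo)
    w <- hi - lo
    v <- numeric(nc)
    ok <- w > 0
    if (any(ok))
      v[ok] <- track_region_reads(track, g$chrom, lo[ok], hi[ok])
    if (g$strand == "-") { v <- rev(v); w <- rev(w) }
    counts[i, ] <- v
    widths[i, ] <- ifelse(w > 0, w, NA)
  }
  if (is.null(base_density)) base_density <- track_mean_density(track)
  widths[is.na(widths)] <- Inf  # zero-width (clipped) cells contribute 0 density
  scheme <- list(type = "metagene", n_body_bins = n_body_bins,
                 flank_bp = flank_bp, flank_bins = flank_bins)
  .profile_matrix(counts, widths, scheme, base_density)
}

#' Anchor-centered coverage profile
#'
#' Fixed-width bins centered on peak anchors (the narrowPeak summit when
#' present, else the interval midpoint), e.g. K36me3 read density around
#' RAR binding sites.
#'
#' @param track a [coverage_track()].
#' @param anchors a [peak_set()].
#' @param half_width_bp distance covered on each side of the anchor.
#' @param n_bins total number of bins (even; default 50).
#' @param base_density,genome as in [metagene_profile()].
#' @return a `profile_matrix`.
#' @export
anchor_profile <- function(track, anchors, half_width_bp = 5000,
                           n_bins = 50, base_density = NULL,
                           genome = NULL) {
  check_positive(half_width_bp, "half_width_bp")
  check_positive(n_bins, "n_bins")
  centers <- if ("summit" %in% names(anchors) && !anyNA(anchors$summit))
    anchors$summit else floor((anchors$start + anchors$end) / 2)
  counts <- matrix(0, nrow(anchors), n_bins)
  widths <- matrix(0, nrow(anchors), n_bins)
  for (i in seq_len(nrow(anchors))) {
    edges <- seq(centers[i] - half_width_bp, centers[i] + half_width_bp,
                 length.out = n_bins + 1L)
    lo <- pmax(edges[-length(edges)], 0)
    hi <- edges[-1L]
    if (!is.null(genome)) hi <- pmin(hi, unname(genome[anchors$chrom[i]]))
    hi <- pmax(hi, lo)
    w <- hi - lo
    v <- numeric(n_bins)
    ok <- w > 0
    if (any(ok))
      v[ok] <- track_region_reads(track, anchors$chrom[i], lo[ok], hi[ok])
    counts[i, ] <- v
    widths[i, ] <- ifelse(w > 0, w, Inf)
  }
  if (is.null(base_density)) base_density <- track_mean_density(track)
  scheme <- list(type = "anchor", half_width_bp = half_width_bp,
                 n_bins = n_bins)
  .profile_matrix(counts, widths, scheme, base_density)
}

#' Plot a profile matrix
#'
#' Line plot of the mean log2 ratio to the base density.
#'
#' @param x a `profile_matrix`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.profile_matrix <- function(x, ...) {
  graphics::plot(seq_along(x$log2_ratio), x$log2_ratio, type = "l",
                 xlab = "position bin",
                 ylab = "log2(read density / base)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Write a profile matrix as TSV plus a JSON sidecar
#'
#' The sidecar records the bin scheme and base density so the profile can
#' be re-plotted without the track.
#'
#' @param profile a `profile_matrix`.
#' @param path TSV output; the sidecar is written to `<path>.json`.
#' @export
write_profile_matrix <- function(profile, path) {
  utils::write.table(profile$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- c(profile$bin_scheme,
            list(base_density = profile$base_density,
                 mean_density = profile$mean_density,
                 log2_ratio = profile$log2_ratio))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
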