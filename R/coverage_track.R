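# Binned coverage container.  Bins are fixed-width, aligned to the genome
# grid (start %% bin_width == 0, except a final bin clipped at a chromosome
# end), and stored as runs of consecutive bins so that sparse tracks
# covering only gene neighborhoods stay small.  Reads are assumed uniform
# within a bin, so partial overlaps pro-rate linearly.

#' Construct a binned coverage track
#'
#' @param chrom,start chromosome and 0-based start of each bin; starts must
#'   be multiples of `bin_width` and unique per chromosome.
#' @param count reads in each bin (non-negative).
#' @param bin_width bin width in bp.
#' @param total_mapped_reads library size used for RPKM; must be > 0.  The
#'   binned counts may cover only a subset of the genome, so they need not
#'   sum to this value.
#' @param mark,condition free-text labels (e.g. "K36me3", "DRB+").
#' @param genome optional [genome_info()]; bins are validated against it and
#'   the final bin of a chromosome may be shorter than `bin_width`.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, start, count, bin_width,
                           total_mapped_reads, mark = "", condition = "",
                           genome = NULL) {
  check_positive(bin_width, "bin_width")
  check_positive(total_mapped_reads, "total_mapped_reads")
  check_positive(count, "bin counts", strict = FALSE)
  n <- max(length(chrom), length(start), length(count))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n)
  count <- rep_len(count, n)
  if (any(start %% bin_width != 0))
    stop_validation("bin starts must be multiples of bin_width")
  ord <- order(chrom, start, method = "radix")
  chrom <- chrom[ord]; start <- start[ord]; count <- count[ord]
  if (!is.null(genome))
    validate_intervals(chrom, start, start + 1, genome, what = "coverage bin")
  runs <- lapply(split(seq_along(start), chrom), function(ix) {
    s <- start[ix]; v <- count[ix]
    if (anyDuplicated(s)) stop_validation("duplicated bin on a chromosome")
    brk <- c(0, which(diff(s) != bin_width), length(s))
    rr <- lapply(seq_len(length(brk) - 1L), function(j) {
      sel <- (brk[j] + 1L):brk[j + 1L]
      list(start = s[sel[1L]], counts = v[sel],
           cum = c(0, cumsum(v[sel])))
    })
    attr(rr, "run_start") <- vapply(rr, function(u) u$start, 0)
    attr(rr, "run_end") <- vapply(rr, function(u)
      u$start + bin_width * length(u$counts), 0)
    rr
  })
  structure(list(runs = runs, bin_width = bin_width,
                 total_mapped_reads = total_mapped_reads,
                 mark = mark, condition = condition, genome = genome),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  nb <- sum(vapply(x$runs, function(r)
    sum(vapply(r, function(u) length(u$counts), 0)), 0))
  cat("<coverage_track> ", x$mark,
      if (nzchar(x$condition)) paste0(" (", x$condition, ")"),
      ": ", nb, " bins of ", x$bin_width, " bp on ",
      length(x$runs), " chromosome(s); ",
      format(x$total_mapped_reads, big.mark = ","), " mapped reads\n",
      sep = "")
  invisible(x)
}

track_covered_bp <- function(track) {
  track$bin_width * sum(vapply(track$runs, function(r)
    sum(vapply(r, function(u) length(u$counts), 0)), 0))
}

track_total_counts <- function(track) {
  sum(vapply(track$runs, function(r)
    sum(vapply(r, function(u) sum(u$counts), 0)), 0))
}

#' Mean read density of a track over its covered bases
#'
#' @param track a [coverage_track()].
#' @return reads per bp, averaged over all covered bins.
#' @export
track_mean_density <- function(track) {
  track_total_counts(track) / track_covered_bp(track)
}

# reads overlapping one region within one run, pro-rated at partial bins
.run_region_reads <- function(run, bw, s, e) {
  run_end <- run$start + bw * length(run$counts)
  s <- max(s, run$start); e <- min(e, run_end)
  if (e <= s) return(0)
  # fractional bin index relative to the run, then interpolate the cumsum
  fi <- (s - run$start) / bw
  fj <- (e - run$start) / bw
  interp <- function(f) {
    i <- floor(f)
    base <- run$cum[i + 1L]
    if (f > i) base <- base + (f - i) * run$counts[i + 1L]
    base
  }
  interp(fj) - interp(fi)
}

#' Reads overlapping regions, pro-rated at partial bins
#'
#' Reads in a bin are treated as uniformly distributed over the bin, so a
#' region covering a fraction of a bin receives that fraction of its count.
#'
#' @param track a [coverage_track()].
#' @param chrom,start,end regions (vectors recycled to common length).
#' @return numeric vector of (possibly fractional) read counts.
#' @export
track_region_reads <- function(track, chrom, start, end) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n)
  end <- rep_len(end, n)
  validate_intervals(chrom, start, end, what = "query region")
  bw <- track$bin_width
  out <- numeric(n)
  for (k in seq_len(n)) {
    runs <- track$runs[[chrom[k]]]
    if (is.null(runs)) next
    rs <- attr(runs, "run_start"); re <- attr(runs, "run_end")
    # runs are sorted and disjoint: candidates are those with
    # run_start < end and run_end > start
    lo <- findInterval(start[k], re) + 1L
    hi <- findInterval(end[k], rs, left.open = TRUE)
    if (hi < lo) next
    tot <- 0
    for (j in lo:hi)
      tot <- tot + .run_region_reads(runs[[j]], bw, start[k], end[k])
    out[k] <- tot
  }
  out
}
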