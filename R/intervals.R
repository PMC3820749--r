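# Coordinate conventions: every interval in this package is 0-based,
# half-open [start, end) on a named chromosome -- the BED convention.
# GTF input (1-based, closed) is converted at the file boundary.

#' Genome description
#'
#' A genome is a named vector of chromosome lengths in bp.  It is used to
#' validate intervals on ingest and to clip windows at chromosome bounds.
#'
#' @param chrom_sizes named numeric vector, chromosome name -> length (bp).
#' @return object of class `genome_info` (a named numeric vector).
#' @examples
#' gen <- genome_info(c(chr1 = 1e5, chr2 = 5e4))
#' @export
genome_info <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop_validation("chrom_sizes must be a named vector")
  if (anyDuplicated(names(chrom_sizes)))
    stop_validation("duplicated chromosome names")
  check_positive(chrom_sizes, "chromosome lengths")
  structure(stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes)),
            class = "genome_info")
}

validate_intervals <- function(chrom, start, end, genome = NULL,
                               what = "interval") {
  if (any(!nzchar(chrom)) || anyNA(chrom))
    stop_validation(what, ": empty chromosome name")
  if (anyNA(start) || anyNA(end))
    stop_validation(what, ": NA coordinates")
  if (any(start < 0)) stop_validation(what, ": start must be >= 0")
  if (any(end <= start)) stop_validation(what, ": end must be > start")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(chrom), names(genome))
    if (length(unknown))
      stop_validation(what, ": unknown chromosome(s): ",
                      paste(unknown, collapse = ", "))
    if (any(end > genome[chrom]))
      stop_validation(what, ": interval extends beyond chromosome bounds")
  }
  invisible(TRUE)
}

#' Interval overlap under half-open semantics
#'
#' Two intervals overlap iff they are on the same chromosome and share at
#' least one base: `a.start < b.end && b.start < a.end`.  Touching intervals
#' (`a.end == b.start`) do not overlap.  All arguments are recycled to a
#' common length.
#'
#' @param chrom_a,start_a,end_a first interval(s), 0-based half-open.
#' @param chrom_b,start_b,end_b second interval(s).
#' @return logical vector.
#' @examples
#' interval_overlaps("chr1", 100, 200, "chr1", 199, 300)  # TRUE
#' interval_overlaps("chr1", 100, 200, "chr1", 200, 300)  # FALSE
#' @export
interval_overlaps <- function(chrom_a, start_a, end_a,
                              chrom_b, start_b, end_b) {
  validate_intervals(chrom_a, start_a, end_a)
  validate_intervals(chrom_b, start_b, end_b)
  chrom_a == chrom_b & start_a < end_b & start_b < end_a
}

# gene models -----------------------------------------------------------------

#' Construct a set of gene models
#'
#' A gene model is a stranded transcription unit.  The transcription start
#' site (TSS) is the first transcribed base: `start` on the + strand,
#' `end - 1` on the - strand; the transcription end site (TES) is the
#' strand-aware opposite.
#'
#' @param gene_id character vector of unique identifiers.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open span of the transcription unit.
#' @param strand "+" or "-".
#' @param genome optional [genome_info()] used to validate bounds.
#' @return a `gene_models` data.frame with columns gene_id, chrom, start,
#'   end, strand, tss, tes.
#' @examples
#' g <- gene_models("g1", "chr1", 10000, 15000, "+")
#' g$tss  # 10000
#' @export
gene_models <- function(gene_id, chrom, start, end, strand, genome = NULL) {
  if (anyDuplicated(gene_id)) stop_validation("gene_id values must be unique")
  if (!all(strand %in% c("+", "-")))
    stop_validation("strand must be '+' or '-'")
  validate_intervals(chrom, start, end, genome, what = "gene model")
  plus <- strand == "+"
  df <- data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    start = as.numeric(start), end = as.numeric(end),
    strand = as.character(strand),
    tss = ifelse(plus, start, end - 1),
    tes = ifelse(plus, end - 1, start),
    stringsAsFactors = FALSE
  )
  class(df) <- c("gene_models", "data.frame")
  df
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x), " genes on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more)\n", sep = "")
  invisible(x)
}

clip_to_genome <- function(chrom, start, end, genome) {
  start <- pmax(start, 0)
  if (!is.null(genome)) {
    unknown <- setdiff(unique(chrom), names(genome))
    if (length(unknown))
      stop_validation("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    end <- pmin(end, unname(genome[chrom]))
  }
  list(start = start, end = end)
}

#' TSS-centered window
#'
#' The window spans `flank` bp on each side of the strand-aware TSS,
#' inclusive of the TSS base itself: `[tss - flank, tss + flank + 1)`,
#' clipped to chromosome bounds.  The default flank of 4 kb is the window
#' used to call Ash1l-target genes.
#'
#' @param genes a [gene_models()] object.
#' @param flank bp on each side of the TSS (default 4000).
#' @param genome optional [genome_info()]; when supplied, windows are clipped
#'   to chromosome ends.
#' @return data.frame gene_id, chrom, start, end.
#' @examples
#' g <- gene_models("g1", "chr1", 10000, 15000, "+")
#' tss_window(g, 4000)  # [6000, 14001)
#' @export
tss_window <- function(genes, flank = 4000, genome = NULL) {
  check_positive(flank, "flank")
  s <- genes$tss - flank
  e <- genes$tss + flank + 1
  cl <- clip_to_genome(genes$chrom, s, e, genome)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = cl$start, end = cl$end, stringsAsFactors = FALSE)
}

#' Upstream-plus-gene-body window
#'
#' The window runs from `upstream` bp 5' of the TSS through the TES, in
#' strand-aware orientation, clipped to chromosome bounds.  The default
#' 20 kb upstream extent is the window used to call RAR-associated genes
#' ("from -20 kb to TSS" plus the transcription unit).
#'
#' @inheritParams tss_window
#' @param upstream bp upstream of the TSS (default 20000).
#' @return data.frame gene_id, chrom, start, end.
#' @export
upstream_body_window <- function(genes, upstream = 20000, genome = NULL) {
  check_positive(upstream, "upstream")
  plus <- genes$strand == "+"
  s <- ifelse(plus, genes$tss - upstream, genes$start)
  e <- ifelse(plus, genes$end, genes$tss + upstream + 1)
  cl <- clip_to_genome(genes$chrom, s, e, genome)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = cl$start, end = cl$end, stringsAsFactors = FALSE)
}

# peak sets -------------------------------------------------------------------

#' Construct a peak set
#'
#' Named genomic intervals from one ChIP experiment, kept sorted by
#' (chrom, start) so downstream operations are order-independent.
#'
#' @param chrom,start,end peak intervals, 0-based half-open.
#' @param name optional peak labels (auto-generated when NULL).
#' @param score optional non-negative scores.
#' @param summit optional absolute summit positions (from narrowPeak).
#' @param factor label of the ChIP'd factor, e.g. "Ash1l" or "RAR".
#' @param genome optional [genome_info()] for bounds validation.
#' @return a `peak_set` data.frame with attribute `factor`.
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = NULL,
                     summit = NULL, factor = "", genome = NULL) {
  validate_intervals(chrom, start, end, genome, what = "peak")
  n <- length(chrom)
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  if (is.null(score)) score <- rep(0, n)
  if (any(score < 0, na.rm = TRUE)) stop_validation("peak scores must be >= 0")
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), name = as.character(name),
                   score = as.numeric(score), stringsAsFactors = FALSE)
  if (!is.null(summit)) df$summit <- as.numeric(summit)
  ord <- order(df$chrom, df$start, df$end, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "factor") <- factor
  class(df) <- c("peak_set", "data.frame")
  df
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> ", nrow(x), " peaks",
      if (nzchar(attr(x, "factor"))) paste0(" [", attr(x, "factor"), "]"),
      "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more)\n", sep = "")
  invisible(x)
}
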