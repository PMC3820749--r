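# Readers and writers for the standard formats the pipeline touches.
# BED-family formats are parsed with a validating base reader so that
# malformed lines can be reported by line number; GTF goes through
# rtracklayer and is converted from 1-based closed to 0-based half-open
# coordinates on ingest.

.read_tab_lines <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)|^\\s*$", lines)
  list(lines = lines[keep], lineno = which(keep))
}

.split_fields <- function(parsed, min_fields, format) {
  fields <- strsplit(parsed$lines, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad))
    stop_validation(format, " parse error at line ", parsed$lineno[bad[1L]],
                    ": expected >= ", min_fields, " fields, found ",
                    nf[bad[1L]])
  fields
}

.num_field <- function(fields, i, parsed, format) {
  v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
  bad <- which(is.na(v))
  if (length(bad))
    stop_validation(format, " parse error at line ", parsed$lineno[bad[1L]],
                    ": field ", i, " is not numeric")
  v
}

#' Read peaks from a BED3/BED6 file
#'
#' @param path BED file (0-based half-open; columns chrom, start, end and
#'   optionally name, score, strand).
#' @param factor label for the ChIP'd factor.
#' @param genome optional [genome_info()]; intervals outside chromosome
#'   bounds raise a validation error.
#' @return a [peak_set()].
#' @export
read_bed <- function(path, factor = "", genome = NULL) {
  p <- .read_tab_lines(path)
  if (!length(p$lines))
    return(peak_set(character(), numeric(), numeric(), factor = factor))
  f <- .split_fields(p, 3L, "BED")
  chrom <- vapply(f, `[[`, "", 1L)
  start <- .num_field(f, 2L, p, "BED")
  end <- .num_field(f, 3L, p, "BED")
  has4 <- all(lengths(f) >= 4L)
  has5 <- all(lengths(f) >= 5L)
  peak_set(chrom, start, end,
           name = if (has4) vapply(f, `[[`, "", 4L),
           score = if (has5) .num_field(f, 5L, p, "BED"),
           factor = factor, genome = genome)
}

#' Write a peak set as BED6
#'
#' @param peaks a [peak_set()].
#' @param path output file.
#' @export
write_bed <- function(peaks, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t.", peaks$chrom,
                     as.integer(peaks$start), as.integer(peaks$end),
                     peaks$name, peaks$score), path)
  invisible(path)
}

#' Read peaks from an ENCODE narrowPeak file
#'
#' The 10th column (summit offset from start, or -1 when absent) is stored
#' as an absolute `summit` position.
#'
#' @inheritParams read_bed
#' @return a [peak_set()] with a `summit` column.
#' @export
read_narrowpeak <- function(path, factor = "", genome = NULL) {
  p <- .read_tab_lines(path)
  if (!length(p$lines))
    return(peak_set(character(), numeric(), numeric(), factor = factor))
  f <- .split_fields(p, 10L, "narrowPeak")
  start <- .num_field(f, 2L, p, "narrowPeak")
  offs <- .num_field(f, 10L, p, "narrowPeak")
  peak_set(vapply(f, `[[`, "", 1L), start, .num_field(f, 3L, p, "narrowPeak"),
           name = vapply(f, `[[`, "", 4L),
           score = .num_field(f, 5L, p, "narrowPeak"),
           summit = ifelse(offs >= 0, start + offs, NA_real_),
           factor = factor, genome = genome)
}

#' @rdname read_narrowpeak
#' @param peaks a [peak_set()]; a missing summit is written as -1.
#' @export
write_narrowpeak <- function(peaks, path) {
  summit <- if ("summit" %in% names(peaks)) peaks$summit else NA_real_
  offs <- ifelse(is.na(summit), -1, summit - peaks$start)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t.\t0\t-1\t-1\t%d", peaks$chrom,
                     as.integer(peaks$start), as.integer(peaks$end),
                     peaks$name, peaks$score, as.integer(offs)), path)
  invisible(path)
}

#' Read gene models from GTF or BED12
#'
#' GTF coordinates (1-based, closed) are converted to the internal 0-based
#' half-open convention; `gene` feature lines are used when present,
#' otherwise the span of each `gene_id`'s features.  When a `gene_id`
#' carries several transcripts/rows, one canonical model is kept: the
#' longest span (association rules anchor on a single TSS per gene).
#'
#' @param path GTF/GFF file (`.gtf`, `.gff`, `.gff3`) or BED12/BED6
#'   (`.bed`); format inferred from the extension unless given.
#' @param format "auto", "gtf" or "bed".
#' @param genome optional [genome_info()] for validation.
#' @return a [gene_models()] object.
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "bed"),
                             genome = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE))
      "gtf" else "bed"
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    df <- as.data.frame(gr)
    if ("type" %in% names(df) && any(df$type == "gene"))
      df <- df[df$type == "gene", , drop = FALSE]
    if (!"gene_id" %in% names(df))
      stop_validation("GTF has no gene_id attribute")
    # 1-based closed -> 0-based half-open
    df$start0 <- df$start - 1
    df$end0 <- df$end
  } else {
    p <- .read_tab_lines(path)
    f <- .split_fields(p, 6L, "BED")
    df <- data.frame(
      seqnames = vapply(f, `[[`, "", 1L),
      start0 = .num_field(f, 2L, p, "BED"),
      end0 = .num_field(f, 3L, p, "BED"),
      gene_id = vapply(f, `[[`, "", 4L),
      strand = vapply(f, `[[`, "", 6L),
      stringsAsFactors = FALSE)
  }
  df$len <- df$end0 - df$start0
  df <- df[order(-df$len), , drop = FALSE]
  df <- df[!duplicated(df$gene_id), , drop = FALSE]
  df <- df[order(df$seqnames, df$start0, method = "radix"), , drop = FALSE]
  gene_models(df$gene_id, as.character(df$seqnames), df$start0, df$end0,
              as.character(df$strand), genome = genome)
}

#' Write gene models as GTF gene lines
#'
#' @param genes a [gene_models()] object.
#' @param path output file.
#' @param source value for the GTF source column.
#' @export
write_gene_models_gtf <- function(genes, path, source = "ash36") {
  writeLines(sprintf(
    "%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    genes$chrom, source, as.integer(genes$start + 1), as.integer(genes$end),
    genes$strand, genes$gene_id), path)
  invisible(path)
}

#' Write gene models as BED12
#'
#' The transcription unit is emitted as a single block.
#'
#' @inheritParams write_gene_models_gtf
#' @export
write_gene_models_bed12 <- function(genes, path) {
  s <- as.integer(genes$start); e <- as.integer(genes$end)
  writeLines(sprintf(
    "%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t1\t%d,\t0,",
    genes$chrom, s, e, genes$gene_id, genes$strand, s, e, e - s), path)
  invisible(path)
}

#' Read a binned coverage track from bedGraph
#'
#' Lines must describe fixed-width bins aligned to the `bin_width` grid
#' (a final bin clipped at a chromosome end is allowed when `genome` is
#' supplied); values are read counts per bin.
#'
#' @param path bedGraph file.
#' @param bin_width expected bin width in bp.
#' @param total_mapped_reads library size for RPKM computations.
#' @param mark,condition labels stored on the track.
#' @param genome optional [genome_info()].
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, bin_width, total_mapped_reads,
                          mark = "", condition = "", genome = NULL) {
  p <- .read_tab_lines(path)
  if (!length(p$lines))
    stop_validation("bedGraph is empty: ", path)
  f <- .split_fields(p, 4L, "bedGraph")
  chrom <- vapply(f, `[[`, "", 1L)
  start <- .num_field(f, 2L, p, "bedGraph")
  end <- .num_field(f, 3L, p, "bedGraph")
  value <- .num_field(f, 4L, p, "bedGraph")
  w <- end - start
  chrom_end <- if (is.null(genome)) rep(Inf, length(chrom))
               else unname(genome[chrom])
  bad <- which(w != bin_width & !(end == chrom_end & w < bin_width & w > 0))
  if (length(bad))
    stop_validation("bedGraph parse error at line ", p$lineno[bad[1L]],
                    ": bin is not ", bin_width, " bp wide")
  coverage_track(chrom, start, value, bin_width, total_mapped_reads,
                 mark = mark, condition = condition, genome = genome)
}

#' Write a coverage track as bedGraph
#'
#' @param track a [coverage_track()].
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  bw <- track$bin_width
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track$runs)) {
    size <- if (!is.null(track$genome)) unname(track$genome[chrom]) else Inf
    for (run in track$runs[[chrom]]) {
      s <- run$start + bw * (seq_along(run$counts) - 1L)
      e <- pmin(s + bw, size)
      writeLines(sprintf("%s\t%d\t%d\t%g", chrom, as.integer(s),
                         as.integer(e), run$counts), con)
    }
  }
  invisible(path)
}

#' Read / write a genes-by-conditions FPKM table
#'
#' Plain TSV with a header row: a `gene_id` column plus one numeric column
#' per condition.  Negative or missing FPKM values are a validation error.
#'
#' @param path TSV file.
#' @return data.frame with `gene_id` plus condition columns.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_expression_table(df)
}

#' @rdname read_expression_table
#' @param table expression data.frame.
#' @export
write_expression_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_expression_table <- function(df) {
  if (!"gene_id" %in% names(df))
    stop_validation("expression table needs a gene_id column")
  if (anyDuplicated(df$gene_id))
    stop_validation("duplicated gene_id in expression table")
  conds <- setdiff(names(df), "gene_id")
  if (!length(conds)) stop_validation("expression table has no conditions")
  for (cc in conds) {
    if (!is.numeric(df[[cc]]) || anyNA(df[[cc]]))
      stop_validation("condition '", cc, "' has non-numeric or missing FPKM")
    if (any(df[[cc]] < 0))
      stop_validation("condition '", cc, "' has negative FPKM")
  }
  df
}
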