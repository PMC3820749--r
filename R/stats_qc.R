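# Small-statistics layer: ChIP-qPCR percent-input quantification with
# background subtraction, triplicate summaries with Student's t-test, and
# phenotype penetrance tabulation.

#' ChIP-qPCR percent input
#'
#' `100 * ip / (input / input_fraction)`: the immunoprecipitated quantity
#' as a percentage of the dilution-corrected input chromatin.
#'
#' @param ip_quantity,input_quantity positive qPCR-derived quantities.
#' @param input_fraction fraction of chromatin the input aliquot represents
#'   (0 < f <= 1; default 1 for precorrected inputs).
#' @return percent-input values.
#' @examples
#' percent_input(1, 1)            # 100
#' percent_input(0.001, 1, 0.1)   # 0.01
#' @export
percent_input <- function(ip_quantity, input_quantity, input_fraction = 1) {
  check_positive(ip_quantity, "ip_quantity")
  check_positive(input_quantity, "input_quantity")
  if (any(input_fraction <= 0) || any(input_fraction > 1))
    stop_validation("input_fraction must be in (0, 1]")
  100 * ip_quantity / (input_quantity / input_fraction)
}

#' Subtract a background percent-input level
#'
#' Background ChIP signal (typically around 0.01% input) is subtracted and
#' results are clipped at 0; the number of clipped values is reported as an
#' attribute.
#'
#' @param values percent-input values.
#' @param background background percent-input level (>= 0).
#' @return values minus background, floored at 0, with attribute
#'   `n_clipped`.
#' @examples
#' subtract_background(0.05, 0.01)  # 0.04
#' @export
subtract_background <- function(values, background) {
  check_positive(values, "values", strict = FALSE)
  check_positive(background, "background", strict = FALSE)
  out <- values - background
  n_clipped <- sum(out < 0)
  structure(pmax(out, 0), n_clipped = n_clipped)
}

#' Mean and standard deviation of replicate measurements
#'
#' @param values numeric replicate values (>= 2).
#' @return list(mean, sd, n); sd uses the n - 1 denominator.
#' @export
summarize_replicates <- function(values) {
  if (length(values) < 2L || anyNA(values))
    stop_validation("need >= 2 non-missing replicates")
  list(mean = mean(values), sd = stats::sd(values), n = length(values))
}

#' Two-sample Student's t-test
#'
#' Classical pooled-variance Student's t by default (`var_equal = TRUE`),
#' two-sided; Welch's form available as an option.  When both groups have
#' zero variance, equal means give t = 0, p = 1 and unequal means give an
#' infinite statistic with p = 0.
#'
#' @param values_a,values_b numeric vectors (>= 2 values each).
#' @param var_equal pool variances (default TRUE).
#' @return list(t, df, p_value).
#' @export
two_sample_t <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L ||
      anyNA(values_a) || anyNA(values_b))
    stop_validation("need >= 2 non-missing replicates per group")
  df0 <- length(values_a) + length(values_b) - 2L
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b))
      return(list(t = 0, df = df0, p_value = 1))
    return(list(t = sign(mean(values_a) - mean(values_b)) * Inf,
                df = df0, p_value = 0))
  }
  ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Phenotype penetrance table
#'
#' Converts per-genotype affected counts into percentages of the number of
#' animals analyzed, rounded half-up to the nearest integer (the precision
#' at which such tables are printed).  The totals rows must be supplied
#' separately because one animal can show several phenotypes.
#'
#' @param affected phenotype x genotype matrix (or data.frame) of affected
#'   counts; rownames are phenotype labels, colnames genotypes.
#' @param n_analyzed named vector: animals analyzed per genotype.
#' @param n_affected optional named vector: total animals affected per
#'   genotype (for the summary rows).
#' @return list with `counts`, `percent` (phenotype x genotype, integer),
#'   and when `n_affected` is given, `total_affected_percent` and
#'   `total_unaffected_percent`.
#' @examples
#' penetrance_table(matrix(15, 1, 1, dimnames = list("arch", "het")),
#'                  c(het = 36))$percent  # 42
#' @export
penetrance_table <- function(affected, n_analyzed, n_affected = NULL) {
  affected <- as.matrix(affected)
  if (is.null(colnames(affected)) || is.null(names(n_analyzed)))
    stop_validation("genotype names required on counts and totals")
  if (!all(colnames(affected) %in% names(n_analyzed)))
    stop_validation("missing n_analyzed for some genotype")
  n <- n_analyzed[colnames(affected)]
  check_positive(n, "n_analyzed")
  if (any(affected < 0) || any(sweep(affected, 2, n, `>`)))
    stop_validation("affected counts must be in [0, n_analyzed]")
  pct <- round_half_up(sweep(100 * affected, 2, as.numeric(n), `/`))
  out <- list(counts = affected, percent = pct, n_analyzed = n)
  if (!is.null(n_affected)) {
    na <- n_affected[colnames(affected)]
    if (any(na < 0 | na > n))
      stop_validation("n_affected must be in [0, n_analyzed]")
    out$total_affected_percent <- round_half_up(100 * na / n)
    out$total_unaffected_percent <- round_half_up(100 * (n - na) / n)
  }
  out
}
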