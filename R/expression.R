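# RNA-Seq response classification.  All fold changes are taken on the
# "modified" log2 scale log2(FPKM + 0.1): the pseudocount damps the
# dispersion of near-zero FPKM values so that ratios between lowly
# expressed genes do not explode.

#' Modified log2 transform of FPKM
#'
#' `log2(fpkm + pseudocount)`, the transform under which all fold-change
#' classifications are made.
#'
#' @param fpkm non-negative FPKM values.
#' @param pseudocount added before taking log2 (default 0.1 FPKM).
#' @return numeric vector.
#' @examples
#' modified_log2(0)    # log2(0.1) = -3.3219...
#' modified_log2(7.9)  # 3
#' @export
modified_log2 <- function(fpkm, pseudocount = 0.1) {
  check_positive(pseudocount, "pseudocount")
  if (anyNA(fpkm)) stop_validation("FPKM contains NA/NaN")
  check_positive(fpkm, "FPKM", strict = FALSE)
  log2(fpkm + pseudocount)
}

#' Delta-log2 fold change between two FPKM vectors
#'
#' `modified_log2(a) - modified_log2(b)`; a value of 1 corresponds to a
#' 2-fold increase of `a` over `b` on the modified scale.
#'
#' @param a_fpkm,b_fpkm non-negative FPKM values.
#' @inheritParams modified_log2
#' @export
dlog2 <- function(a_fpkm, b_fpkm, pseudocount = 0.1) {
  modified_log2(a_fpkm, pseudocount) - modified_log2(b_fpkm, pseudocount)
}

#' Classification thresholds for expression responses
#'
#' All thresholds are strict inequalities.  `ra_responsive_dlog2 = 2.5`
#' encodes "more than 5-fold induction" on the modified scale;
#' `impaired_dlog2 = -1` encodes "greater than 2-fold decrease";
#' `dysregulated_dlog2 = 1` encodes 2-fold change in either direction.
#' Genes enter the analysis ("eligible") when FPKM reaches
#' `eligibility_min_fpkm` in at least one of the compared conditions.
#'
#' @param pseudocount FPKM pseudocount for the modified log2 transform.
#' @param ra_responsive_dlog2 strict lower bound for RA responsiveness.
#' @param impaired_dlog2 strict upper bound for impairment (negative).
#' @param dysregulated_dlog2 strict magnitude bound for dysregulation.
#' @param eligibility_min_fpkm FPKM floor defining eligible genes.
#' @return a `response_thresholds` list.
#' @export
response_thresholds <- function(pseudocount = 0.1,
                                ra_responsive_dlog2 = 2.5,
                                impaired_dlog2 = -1,
                                dysregulated_dlog2 = 1,
                                eligibility_min_fpkm = 0.1) {
  check_positive(pseudocount, "pseudocount")
  stopifnot(is.finite(ra_responsive_dlog2), is.finite(impaired_dlog2),
            is.finite(dysregulated_dlog2), is.finite(eligibility_min_fpkm))
  structure(list(pseudocount = pseudocount,
                 ra_responsive_dlog2 = ra_responsive_dlog2,
                 impaired_dlog2 = impaired_dlog2,
                 dysregulated_dlog2 = dysregulated_dlog2,
                 eligibility_min_fpkm = eligibility_min_fpkm),
            class = "response_thresholds")
}

.get_cond <- function(table, cond) {
  if (!cond %in% names(table))
    stop_validation("condition '", cond, "' not in expression table")
  table[[cond]]
}

#' Call RA-responsive genes
#'
#' A gene is RA-responsive when its modified-log2 fold change of the
#' RA-treated over the undifferentiated condition strictly exceeds
#' `ra_responsive_dlog2` (default > 2.5, i.e. more than ~5-fold), among
#' eligible genes.
#'
#' @param table expression data.frame (`gene_id` + condition columns).
#' @param cond_ra,cond_undiff condition column names.
#' @param thresholds a [response_thresholds()].
#' @return data.frame gene_id, dlog2_ra, eligible, responsive.
#' @export
classify_ra_responsive <- function(table, cond_ra, cond_undiff,
                                   thresholds = response_thresholds()) {
  table <- validate_expression_table(table)
  ra <- .get_cond(table, cond_ra)
  un <- .get_cond(table, cond_undiff)
  d <- dlog2(ra, un, thresholds$pseudocount)
  eligible <- ra >= thresholds$eligibility_min_fpkm |
    un >= thresholds$eligibility_min_fpkm
  data.frame(gene_id = table$gene_id, dlog2_ra = d, eligible = eligible,
             responsive = eligible & d > thresholds$ra_responsive_dlog2,
             stringsAsFactors = FALSE)
}

#' Call genes with impaired RA response in a mutant
#'
#' Among RA-responsive genes, a gene is impaired when its mutant-over-wild-type
#' fold change under RA falls strictly below `impaired_dlog2` (default < -1,
#' i.e. a greater-than-2-fold decrease).
#'
#' @inheritParams classify_ra_responsive
#' @param cond_mut_ra,cond_wt_ra RA-treated mutant and wild-type columns.
#' @param responsive_labels output of [classify_ra_responsive()].
#' @return data.frame gene_id, dlog2_genotype, responsive, impaired.
#' @export
classify_impaired <- function(table, cond_mut_ra, cond_wt_ra,
                              responsive_labels,
                              thresholds = response_thresholds()) {
  table <- validate_expression_table(table)
  if (!identical(responsive_labels$gene_id, table$gene_id))
    stop_validation("responsive labels do not match the table's genes")
  d <- dlog2(.get_cond(table, cond_mut_ra), .get_cond(table, cond_wt_ra),
             thresholds$pseudocount)
  data.frame(gene_id = table$gene_id, dlog2_genotype = d,
             responsive = responsive_labels$responsive,
             impaired = responsive_labels$responsive &
               d < thresholds$impaired_dlog2,
             stringsAsFactors = FALSE)
}

#' Call dysregulated genes between genotypes
#'
#' Down-regulated: dlog2 strictly below -`dysregulated_dlog2`;
#' up-regulated: strictly above +`dysregulated_dlog2`.  Only eligible genes
#' are called.
#'
#' @inheritParams classify_ra_responsive
#' @param cond_mut,cond_wt condition columns to compare (mutant over wild type).
#' @return list with character vectors `down` and `up` (disjoint).
#' @export
classify_dysregulated <- function(table, cond_mut, cond_wt,
                                  thresholds = response_thresholds()) {
  table <- validate_expression_table(table)
  mut <- .get_cond(table, cond_mut)
  wt <- .get_cond(table, cond_wt)
  d <- dlog2(mut, wt, thresholds$pseudocount)
  eligible <- mut >= thresholds$eligibility_min_fpkm |
    wt >= thresholds$eligibility_min_fpkm
  thr <- thresholds$dysregulated_dlog2
  list(down = table$gene_id[eligible & d < -thr],
       up = table$gene_id[eligible & d > thr])
}

#' Percentage of a subset within a superset
#'
#' Reported half-up at one decimal, the precision at which such fractions
#' are conventionally printed (e.g. 152 of 543 -> 28.0).
#'
#' @param subset either a count or a character vector of members.
#' @param superset either a count or a character vector containing `subset`.
#' @return percentage rounded to 1 decimal.
#' @export
summarize_fraction <- function(subset, superset) {
  if (is.character(subset) && is.character(superset)) {
    if (!all(subset %in% superset))
      stop_validation("subset is not contained in superset")
    k <- length(unique(subset)); n <- length(unique(superset))
  } else {
    k <- as.numeric(subset); n <- as.numeric(superset)
    if (length(k) != 1L || length(n) != 1L || k < 0 || k > n)
      stop_validation("need counts with 0 <= subset <= superset")
  }
  if (n == 0) stop_validation("superset is empty")
  round_half_up(100 * k / n, 1)
}
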