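# Chromatin-signature classification (promoter H3K4me3/H3K27me3 status in
# ES cells, after the published reference calls) and chi-square enrichment
# of gene groups against the total gene set.

SIGNATURE_LEVELS <- c("Lys4me alone", "Bivalent", "Lys27me alone", "None")

#' Classify the four-state promoter chromatin signature
#'
#' (K4me3, K27me3) map to: (T,F) "Lys4me alone"; (T,T) "Bivalent";
#' (F,T) "Lys27me alone"; (F,F) "None".
#'
#' @param k4me3,k27me3 logical vectors.
#' @return factor with levels Lys4me alone, Bivalent, Lys27me alone, None.
#' @examples
#' classify_signature(TRUE, TRUE)  # Bivalent
#' @export
classify_signature <- function(k4me3, k27me3) {
  if (anyNA(k4me3) || anyNA(k27me3))
    stop_validation("mark status must be TRUE/FALSE")
  lab <- ifelse(k4me3 & k27me3, "Bivalent",
         ifelse(k4me3, "Lys4me alone",
         ifelse(k27me3, "Lys27me alone", "None")))
  factor(lab, levels = SIGNATURE_LEVELS)
}

#' Read a per-gene signature reference table
#'
#' TSV with columns gene_id, k4me3, k27me3 (logical or 0/1); the four-state
#' signature is recomputed from the two marks.
#'
#' @param path TSV file.
#' @return data.frame gene_id, k4me3, k27me3, signature.
#' @export
read_signature_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "k4me3", "k27me3")
  if (!all(need %in% names(df)))
    stop_validation("signature table needs columns: ",
                    paste(need, collapse = ", "))
  df$k4me3 <- as.logical(df$k4me3)
  df$k27me3 <- as.logical(df$k27me3)
  df$signature <- classify_signature(df$k4me3, df$k27me3)
  df[c("gene_id", "k4me3", "k27me3", "signature")]
}

#' Pearson chi-square test on a 2x2 table
#'
#' Plain Pearson statistic (sum (O-E)^2/E with expectations from the
#' marginals), df = 1, upper-tail p-value; continuity correction off by
#' default.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param continuity apply Yates' correction (default FALSE).
#' @return list(statistic, df, p_value).
#' @examples
#' chi_square_2x2(matrix(c(10, 30, 90, 70), 2))  # statistic 12.5
#' @export
chi_square_2x2 <- function(table, continuity = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop_validation("need a 2x2 table")
  if (any(table < 0) || anyNA(table))
    stop_validation("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_validation("chi-square undefined: zero marginal")
  ht <- suppressWarnings(stats::chisq.test(table, correct = continuity))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Chi-square goodness-of-fit of a category vector against universe
#' proportions
#'
#' Alternative reading of "chi-square against the total gene set": the
#' observed category counts of a gene group are compared with expectations
#' from the universe's category proportions (df = k - 1).
#'
#' @param observed named vector of category counts in the group.
#' @param universe_counts named vector of category counts in the universe.
#' @return list(statistic, df, p_value).
#' @export
chi_square_gof <- function(observed, universe_counts) {
  if (!identical(names(observed), names(universe_counts)))
    stop_validation("category names must match")
  if (any(universe_counts <= 0))
    stop_validation("every category needs universe members")
  ht <- suppressWarnings(
    stats::chisq.test(observed, p = universe_counts / sum(universe_counts)))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Enrichment of a gene group across signature categories
#'
#' For each category, a 2x2 table (in group vs rest of universe) x (in
#' category vs not) is tested by [chi_square_2x2()]; the relative ratio
#' (category fraction in the group over its fraction in the universe, the
#' quantity shown in bar/radar charts) and the direction are reported.
#' `test = "goodness_of_fit"` instead performs one k-category test of the
#' group's category vector against universe proportions.
#'
#' @param group character vector of gene ids (subset of the universe).
#' @param labels data.frame gene_id, signature (or any category column
#'   named by `category_col`).
#' @param universe gene ids forming the background (default: all labeled
#'   genes).
#' @param category_col name of the category column in `labels`.
#' @param test "two_by_two" (default) or "goodness_of_fit".
#' @param continuity passed to [chi_square_2x2()].
#' @param bonferroni multiply p-values by the number of categories
#'   (default FALSE: raw chi-square p-values).
#' @return for "two_by_two", a data.frame (class `enrichment_report`) with
#'   one row per category: n_group, n_universe, relative_ratio, statistic,
#'   df, p_value, direction; for "goodness_of_fit", a list with the single
#'   test plus the relative-ratio vector.
#' @export
enrichment_vs_background <- function(group, labels,
                                     universe = labels$gene_id,
                                     category_col = "signature",
                                     test = c("two_by_two",
                                              "goodness_of_fit"),
                                     continuity = FALSE,
                                     bonferroni = FALSE) {
  test <- match.arg(test)
  if (!length(group)) stop_validation("group is empty")
  if (!all(universe %in% labels$gene_id))
    stop_validation("universe contains unlabeled genes")
  if (!all(group %in% universe))
    stop_validation("group is not a subset of the universe")
  lab <- labels[match(universe, labels$gene_id), category_col]
  lab <- factor(lab, levels = if (is.factor(lab)) levels(lab)
                else sort(unique(as.character(lab))))
  in_group <- universe %in% group
  n_grp_cat <- table(lab[in_group])
  n_uni_cat <- table(lab)
  rel <- (as.numeric(n_grp_cat) / sum(in_group)) /
    (as.numeric(n_uni_cat) / length(universe))
  if (test == "goodness_of_fit") {
    keep <- n_uni_cat > 0
    gof <- chi_square_gof(as.vector(n_grp_cat[keep]),
                          as.vector(n_uni_cat[keep]))
    return(c(gof, list(relative_ratio =
                         stats::setNames(rel, levels(lab)))))
  }
  rows <- lapply(levels(lab), function(cat) {
    inc <- lab == cat
    tab <- matrix(c(sum(in_group & inc), sum(!in_group & inc),
                    sum(in_group & !inc), sum(!in_group & !inc)), 2L)
    res <- tryCatch(chi_square_2x2(tab, continuity),
                    error = function(e) list(statistic = NA_real_,
                                             df = NA_real_,
                                             p_value = NA_real_))
    data.frame(category = cat, n_group = sum(in_group & inc),
               n_universe = sum(inc),
               relative_ratio = rel[match(cat, levels(lab))],
               statistic = res$statistic, df = res$df,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni)
    out$p_value <- pmin(out$p_value * nrow(out), 1)
  out$direction <- ifelse(out$relative_ratio > 1, "enriched",
                          ifelse(out$relative_ratio < 1, "depleted", "none"))
  rownames(out) <- NULL
  class(out) <- c("enrichment_report", "data.frame")
  out
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("<enrichment_report> group of ", sum(x$n_group), " genes vs universe of ",
      sum(x$n_universe), "\n", sep = "")
  df <- as.data.frame(x)
  df$relative_ratio <- signif(df$relative_ratio, 3)
  df$statistic <- signif(df$statistic, 4)
  df$p_value <- signif(df$p_value, 3)
  print.data.frame(df, ...)
  invisible(x)
}
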