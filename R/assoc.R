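#' Genotype counts helper
#'
#' @param hom,het,wt non-negative counts of marker-mutation homozygotes,
#'   heterozygotes and wild types
#' @return named numeric vector of class `genotype_counts`
#' @export
genotype_counts <- function(hom, het, wt) {
  stopifnot(hom >= 0, het >= 0, wt >= 0)
  structure(c(HOM = hom, HET = het, WT = wt), class = "genotype_counts")
}

new_test_result <- function(statistic, df, p_value, method, warning = NULL) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, warning = warning),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %d, p = %.4g\n",
              x$method, x$statistic, x$df, signif(x$p_value, 4)))
  if (!is.null(x$warning)) cat("  note:", x$warning, "\n")
  invisible(x)
}

#' Pearson chi-square test of genotype frequencies between groups
#'
#' Uncorrected Pearson chi-square on an r x 3 (HOM/HET/WT) contingency
#' table; expected counts come from the margins. Genotype columns with zero
#' margin are dropped before computing degrees of freedom (needed when a
#' group lacks a genotype entirely, as line 1 lacks wild-type cases). No
#' Yates continuity correction is applied.
#'
#' @param groups list of [genotype_counts()] (or length-3 numeric vectors),
#'   at least two
#' @return a `test_result` with `statistic`, `df`, `p_value`
#' @export
chi2_genotype_test <- function(groups) {
  m <- do.call(rbind, lapply(groups, as.numeric))
  if (nrow(m) < 2) stop("need at least 2 groups")
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) < 2) stop("fewer than 2 non-empty groups")
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2 || sum(m) == 0) stop("table is degenerate after dropping zero margins")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  new_test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
                  "Pearson chi-square (genotype frequencies)")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Estimates the marker-mutation allele frequency from the observed counts,
#' forms the expected Hardy-Weinberg genotype numbers, and computes the
#' uncorrected Pearson chi-square with one degree of freedom (three classes,
#' one estimated allele frequency). A monomorphic sample returns statistic 0
#' and p = 1 with a warning note rather than an error.
#'
#' @param counts a [genotype_counts()] (HOM, HET, WT)
#' @return a `test_result`; the expected counts are attached as
#'   `attr(, "expected")` and always sum to the observed total
#' @export
hwe_chi2_test <- function(counts) {
  o <- as.numeric(counts)
  stopifnot(length(o) == 3, all(o >= 0))
  n <- sum(o)
  if (n == 0) stop("empty sample")
  p <- (2 * o[1] + o[2]) / (2 * n)
  if (p %in% c(0, 1)) {
    res <- new_test_result(0, 1L, 1,
                           "Hardy-Weinberg chi-square",
                           warning = "monomorphic sample; test undefined")
    attr(res, "expected") <- o
    return(res)
  }
  e <- c(p^2, 2 * p * (1 - p), (1 - p)^2) * n
  stat <- sum((o - e)^2 / e)
  res <- new_test_result(stat, 1L, stats::pchisq(stat, 1, lower.tail = FALSE),
                         "Hardy-Weinberg chi-square")
  attr(res, "expected") <- e
  res
}

#' Unpaired Student t test on age at diagnosis
#'
#' Two-sample pooled-variance (Student, not Welch) t statistic with a
#' two-sided p-value, as used to compare ages of diagnosis between dogs and
#' bitches. When both groups have zero variance and equal means the result
#' is statistic 0, p = 1.
#'
#' @param group_a,group_b numeric vectors of ages (each n >= 2)
#' @return a `test_result` (df = n_a + n_b - 2)
#' @export
onset_age_ttest <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 == 0) {
    if (mean(a) == mean(b))
      return(new_test_result(0, df, 1, "Student t (pooled variance)",
                             warning = "zero variance in both groups"))
    return(new_test_result(Inf, df, 0, "Student t (pooled variance)",
                           warning = "zero variance, unequal means"))
  }
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  new_test_result(tstat, df, p, "Student t (pooled variance)")
}

#' Combined genotype-table and test report
#'
#' Assembles a publication-shaped report: the genotype count table (groups as
#' rows, HOM/HET/WT/Total columns) followed by footnote-style lines for the
#' supplied tests. p-values are formatted to 4 significant figures.
#'
#' @param tables a [genotype_tables_by_group()] result (or any data frame
#'   with HOM/HET/WT/Total columns); may be `NULL`/empty
#' @param tests named list of `test_result` objects; names become footnote
#'   labels
#' @return list of class `assoc_report` with `table`, `footnotes`
#' @export
summary_report <- function(tables, tests = list()) {
  footnotes <- character(0)
  if (length(tests)) {
    footnotes <- vapply(names(tests), function(nm) {
      t <- tests[[nm]]
      sprintf("%s: chi2/t = %.4g, df = %d, P = %.4g", nm, t$statistic, t$df,
              signif(t$p_value, 4))
    }, character(1))
  }
  structure(list(table = tables, footnotes = footnotes),
            class = "assoc_report")
}

#' @export
print.assoc_report <- function(x, ...) {
  if (!is.null(x$table) && nrow(x$table)) print(as.data.frame(x$table))
  else cat("(empty table)\n")
  for (f in x$footnotes) cat(" *", f, "\n")
  invisible(x)
}
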