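#' Round half away from zero
#'
#' Table-style rounding (0.125 -> 0.13 at 2 dp), as opposed to R's
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson statistic `sum((O - E)^2 / E)` with
#' `df = (r - 1)(c - 1)`, as used for the omnibus blood-type x subtype
#' comparison. A Yates continuity correction can be requested for 2x2
#' tables but is off by default.
#'
#' @param counts Non-negative integer matrix.
#' @param yates Apply the continuity correction (2x2 only). Default FALSE.
#' @return List: `chi2`, `df`, `p_value`.
#' @export
chi_square_test <- function(counts, yates = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column marginal", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(counts, correct = yates))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Blood-type x category contingency table with test
#'
#' Cross-tabulates called blood types against a per-sample category (e.g.
#' the five CCS stroke subtypes LAA/CE/SAO/OE/UE), computes within-row
#' percentages (rounded half-up to 2 dp, the table convention), and the
#' uncorrected chi-square test of independence. Samples with a missing
#' blood-type call are excluded and their number reported.
#'
#' @param calls Data.frame with `sample_id` and `blood_type` (from
#'   [call_blood_types()]), or a character vector of blood types.
#' @param labels Category per sample, aligned with `calls`.
#' @return List of class `contingency_table`: `counts`, `row_percents`,
#'   `chi2`, `df`, `p_value`, `n_missing`.
#' @export
build_contingency <- function(calls, labels) {
  bt <- if (is.data.frame(calls)) calls$blood_type else as.character(calls)
  stopifnot(length(bt) == length(labels))
  keep <- bt != "missing" & !is.na(bt) & !is.na(labels)
  n_missing <- sum(!keep)
  if (n_missing > 0)
    message(n_missing, " sample(s) with missing blood type excluded")
  counts <- table(blood_type = bt[keep], category = labels[keep])
  counts <- unclass(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0))
    stop("expected cell count of zero; collapse sparse categories before testing",
         call. = FALSE)
  ht <- chi_square_test(counts)
  structure(list(counts = counts,
                 row_percents = round_half_up(100 * counts / rowSums(counts), 2),
                 chi2 = ht$chi2, df = ht$df, p_value = ht$p_value,
                 n_missing = n_missing),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Contingency table (", nrow(x$counts), "x", ncol(x$counts), ")\n", sep = "")
  print(x$counts)
  cat("Row percents:\n")
  print(x$row_percents)
  cat(sprintf("chi2 = %.4g, df = %d, p = %.3g\n", x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = ad / bc` for a 2x2 table `[[a, b], [c, d]]`, with a 95% CI from the
#' log-OR normal approximation. Any zero cell triggers the
#' Haldane-Anscombe correction (+0.5 to every cell).
#'
#' @param table2x2 2x2 numeric matrix of non-negative counts.
#' @param conf_level Confidence level. Default 0.95.
#' @return List: `or`, `ci_low`, `ci_high`, `corrected` (logical).
#' @export
odds_ratio <- function(table2x2, conf_level = 0.95) {
  t <- as.matrix(table2x2)
  stopifnot(all(dim(t) == c(2, 2)))
  if (any(t < 0)) stop("negative counts", call. = FALSE)
  corrected <- any(t == 0)
  if (corrected) t <- t + 0.5
  or <- (t[1, 1] * t[2, 2]) / (t[1, 2] * t[2, 1])
  se <- sqrt(sum(1 / t))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se),
       corrected = corrected)
}

#' Study-population exclusion arithmetic
#'
#' From the genotyped total, removes samples that failed ABO locus
#' sequencing and TIA diagnoses to get the ischaemic-stroke count, then
#' removes patients with a prior stroke to get the first-ever count.
#'
#' @param n_total Genotyped samples passing genomic QC.
#' @param n_failed_abo Samples failing ABO locus sequencing.
#' @param n_tia Transient-ischaemic-attack diagnoses.
#' @param n_prior_stroke IS patients with a stroke history.
#' @return List: `n_is`, `n_first_ever`.
#' @export
cohort_filter <- function(n_total, n_failed_abo, n_tia, n_prior_stroke) {
  counts <- c(n_total, n_failed_abo, n_tia, n_prior_stroke)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n_is <- n_total - n_failed_abo - n_tia
  if (n_is < 0) stop("exclusions exceed the running total", call. = FALSE)
  n_first_ever <- n_is - n_prior_stroke
  if (n_first_ever < 0) stop("exclusions exceed the running total", call. = FALSE)
  list(n_is = n_is, n_first_ever = n_first_ever)
}

#' Compare a variable between blood types
#'
#' Continuous variables get medians/IQRs and the Wilcoxon rank-sum test;
#' categorical variables get counts/percents and the chi-square test.
#' Missing values are dropped pairwise per variable.
#'
#' @param x Variable values per sample.
#' @param blood_type `"O"`/`"non_O"` per sample.
#' @param type `"continuous"` or `"categorical"`.
#' @return List with `variable_type`, per-group `summaries`, `test`,
#'   `p_value`.
#' @export
group_comparison <- function(x, blood_type, type = c("continuous", "categorical")) {
  type <- match.arg(type)
  keep <- !is.na(x) & blood_type %in% c("O", "non_O")
  x <- x[keep]; g <- blood_type[keep]
  if (type == "continuous") {
    summ <- lapply(split(x, g), function(v)
      c(median = stats::median(v), q1 = unname(stats::quantile(v, 0.25)),
        q3 = unname(stats::quantile(v, 0.75))))
    wt <- wilcoxon_rank_sum(x[g == "O"], x[g == "non_O"])
    list(variable_type = type, summaries = summ, test = "wilcoxon",
         p_value = wt$p_value)
  } else {
    tab <- table(g, x)
    summ <- lapply(rownames(tab), function(r)
      stats::setNames(as.vector(tab[r, ]), colnames(tab)))
    names(summ) <- rownames(tab)
    ht <- chi_square_test(unclass(tab))
    list(variable_type = type, summaries = summ, test = "chi_square",
         p_value = ht$p_value)
  }
}

#' Printed CCS subtype counts by blood type
#'
#' The published blood-type x CCS-subtype counts for the 9,542-patient
#' ischaemic-stroke cohort, shipped so the association stage can be
#' exercised with zero inputs. Rows: O, non-O; columns: LAA, CE, SAO, OE,
#' UE.
#'
#' @return 2x5 integer matrix with dimnames.
#' @export
ccs_table1_counts <- function() {
  matrix(c(708, 193, 806, 21, 1091,
           2030, 475, 1770, 55, 2393),
         nrow = 2, byrow = TRUE,
         dimnames = list(blood_type = c("O", "non_O"),
                         subtype = c("LAA", "CE", "SAO", "OE", "UE")))
}
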