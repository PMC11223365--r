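#' Cholesterol efflux percentage
#'
#' Fraction of labelled cholesterol released to the medium:
#' `100 * FI(medium) / (FI(medium) + FI(cell lysate))`, from fluorescence
#' read at 469 nm excitation / 537 nm emission. An optional blank is
#' subtracted from both readings first (values floored at 0).
#'
#' @param fi_medium,fi_lysate Fluorescence of medium and cell lysate
#'   (arbitrary units, >= 0). Vectorised.
#' @param blank Background fluorescence to subtract. Default 0.
#' @return Efflux percentage in `[0, 100]`.
#' @export
efflux_percent <- function(fi_medium, fi_lysate, blank = 0) {
  if (any(fi_medium < 0 | fi_lysate < 0)) stop("fluorescence must be >= 0", call. = FALSE)
  m <- pmax(fi_medium - blank, 0)
  l <- pmax(fi_lysate - blank, 0)
  if (any(m + l == 0)) stop("total fluorescence is zero", call. = FALSE)
  100 * m / (m + l)
}

#' Summarise efflux readings per condition
#'
#' Mean of per-replicate efflux percentages (not the efflux of summed
#' fluorescence) for each condition.
#'
#' @param readings Data.frame with columns `condition`, `replicate`,
#'   `fi_medium`, `fi_lysate`.
#' @param blank Passed to [efflux_percent()].
#' @return Data.frame: `condition`, `n`, `mean_efflux`, `sd_efflux`.
#' @export
efflux_summary <- function(readings, blank = 0) {
  eff <- efflux_percent(readings$fi_medium, readings$fi_lysate, blank)
  agg <- split(eff, readings$condition)
  data.frame(condition = names(agg),
             n = vapply(agg, length, integer(1)),
             mean_efflux = vapply(agg, mean, numeric(1)),
             sd_efflux = vapply(agg, stats::sd, numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Relative expression by the 2^-ddCt method
#'
#' Normalises target Ct to the reference gene (GAPDH) within each
#' measurement, averages delta-Ct per group, and reports
#' `2^-(mean dCt knockdown - mean dCt control)`. Invariant to adding a
#' constant to every Ct.
#'
#' @param kd,ctrl Data.frames with columns `ct_target`, `ct_reference`
#'   (cycles, in (0, 45)); knockdown and control groups.
#' @return Fold change relative to control (1 = no change).
#' @export
relative_expression <- function(kd, ctrl) {
  check_ct <- function(d) {
    ct <- c(d$ct_target, d$ct_reference)
    if (length(ct) == 0) stop("empty measurement group", call. = FALSE)
    if (any(ct <= 0 | ct >= 45)) stop("Ct values must lie in (0, 45)", call. = FALSE)
  }
  check_ct(kd); check_ct(ctrl)
  ddct <- mean(kd$ct_target - kd$ct_reference) -
    mean(ctrl$ct_target - ctrl$ct_reference)
  2^(-ddct)
}

#' Percent reduction relative to a control mean
#'
#' `100 * (control - treated) / control`; an increase comes out negative.
#'
#' @param control_mean,treated_mean Group means; `control_mean` non-zero.
#' @return Percent reduction.
#' @export
percent_change <- function(control_mean, treated_mean) {
  if (any(control_mean == 0)) stop("control mean must be non-zero", call. = FALSE)
  100 * (control_mean - treated_mean) / control_mean
}
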