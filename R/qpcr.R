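#' Fit a qPCR standard curve
#'
#' Least squares of ct on log10(human fraction):
#' `ct = slope * log10(fraction) + intercept`. Amplification efficiency is
#' `10^(-1/slope) - 1` (a perfect 10-fold series with delta-ct 3.321928
#' gives slope -3.321928 and 100% efficiency).
#'
#' @param standards data.frame with log10_human_fraction and ct (>= 3 rows)
#' @return list: slope, intercept, efficiency, r_squared
#' @export
fit_standard_curve <- function(standards) {
  x <- standards$log10_human_fraction; y <- standards$ct
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_nb("need >= 3 standards")
  if (sd(x) == 0) stop_nb("singular fit: standards at a single dilution")
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  if (!is.finite(slope) || slope >= 0 || sd(y) == 0)
    stop_nb("degenerate standard curve (non-negative or undefined slope)")
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = unname(fit$coefficients[1]),
       efficiency = 10^(-1 / slope) - 1, r_squared = r2)
}

#' Estimate human-cell fractions and call chimera-positive embryos
#'
#' Per embryo: fraction = 10^((ct - intercept)/slope); positive when the
#' fraction reaches the detection-limit threshold (one human cell in 10,000
#' mouse cells by default) and the well is not a non-detect (non-detects are
#' never positive regardless of extrapolation). Wells below the lowest
#' standard's ct are flagged above the calibration range but still
#' estimated.
#'
#' @param plate list from [gen_qpcr_plate()] or with `standards` and
#'   `unknowns` (embryo_id, condition, ct, non_detect)
#' @param curve optional pre-fitted [fit_standard_curve()] result
#' @param threshold detection-limit human:mouse fraction
#' @return list with `per_embryo` (estimated fraction, positive,
#'   above_range) and `summary` per condition (n_tested, n_positive,
#'   pct_positive, half-up 1 decimal)
#' @export
call_embryos <- function(plate, curve = NULL, threshold = 1e-4) {
  if (is.null(curve)) curve <- fit_standard_curve(plate$standards)
  u <- plate$unknowns
  nd <- if (!is.null(u$non_detect)) u$non_detect else is.na(u$ct)
  nd <- nd | is.na(u$ct) |
    (!is.null(plate$ct_ceiling) & !is.na(u$ct) & u$ct >= plate$ct_ceiling)
  frac <- ifelse(nd, NA_real_,
                 10^((u$ct - curve$intercept) / curve$slope))
  min_ct <- min(plate$standards$ct, na.rm = TRUE)
  per_embryo <- data.frame(
    embryo_id = u$embryo_id, condition = u$condition, ct = u$ct,
    non_detect = nd, est_fraction = frac,
    above_range = !nd & u$ct < min_ct,
    positive = !nd & frac >= threshold,
    stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(split(per_embryo, per_embryo$condition),
    function(d) data.frame(
      condition = d$condition[1], n_tested = nrow(d),
      n_positive = sum(d$positive),
      pct_positive = round_half_up(100 * sum(d$positive) / nrow(d), 1),
      stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(per_embryo = per_embryo, summary = summary, curve = curve,
       threshold = threshold)
}
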