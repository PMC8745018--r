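# Label-free isoD7 quantification from CID fragment-ion intensity ratios.
#
# Isomerization of D7 to isoAsp is mass-silent, but it increases the cleavage
# efficiency of the backbone bonds flanking the residue, so the intensities of
# the fragments b6, b7 and y10 of Abeta(1-16) rise with isoD7 content while
# b11 and y11 are insensitive. The ratio marker/base is therefore calibrated
# against designed binary norm/iso mixtures and inverted to estimate the
# isoD7 percentage of an unknown sample.

MARKER_FRAGMENTS <- c("b6", "b7", "y10")
BASE_FRAGMENTS <- c("b11", "y11")

#' Marker/base fragment intensity ratio
#'
#' @param matches An `ab_matchset` from [match_fragments()].
#' @param marker Marker fragment label (`"b6"` default; `"b7"`, `"y10"`
#'   allowed).
#' @param base Base fragment label (`"b11"` default; `"y11"` allowed).
#' @return `intensity(marker) / intensity(base)`. A missing marker yields 0
#'   with a warning; a missing or zero-intensity base is an error, since the
#'   ratio is then undefined.
#' @export
marker_ratio <- function(matches, marker = "b6", base = "b11") {
  if (!marker %in% MARKER_FRAGMENTS)
    stop("marker must be one of ", paste(MARKER_FRAGMENTS, collapse = ", "))
  if (!base %in% BASE_FRAGMENTS)
    stop("base must be one of ", paste(BASE_FRAGMENTS, collapse = ", "))
  row_m <- matches[matches$label == marker, , drop = FALSE]
  row_b <- matches[matches$label == base, , drop = FALSE]
  if (nrow(row_b) != 1L || !row_b$matched || row_b$intensity <= 0)
    stop("base fragment missing: ", base)
  if (nrow(row_m) != 1L || !row_m$matched) {
    warning("marker fragment ", marker, " unmatched; ratio set to 0")
    return(0)
  }
  row_m$intensity / row_b$intensity
}

#' Fit a calibration curve from designed binary mixtures
#'
#' Fits `ratio = slope * fraction + intercept` by least squares to
#' (fraction %, observed ratio) pairs from a binary norm/isoD7 mixing design
#' (canonically 0-100% in 10% steps). Binary mixing of two pure species with
#' a species-insensitive base fragment makes the expected ratio exactly
#' linear in the mixing fraction, which is why the linear form is the
#' default; if the replicate-mean ratios are non-monotone beyond what the
#' linear residual scatter explains, a shape-constrained monotone (isotonic)
#' interpolant through the replicate means is used instead.
#'
#' @param fraction_pct Design fractions in percent, `[0, 100]`; replicates
#'   share a fraction value.
#' @param ratio Observed marker/base ratios, same length.
#' @return An object of class `ab_calibration` with elements
#'   `design_fractions`, `mean_ratios`, `slope`, `intercept`, `slope_se`,
#'   `intercept_se`, `residual_sd`, `fit_kind` (`"linear"` or `"monotone"`),
#'   `n` and, for the monotone fallback, `mono_fractions`/`mono_ratios`.
#' @export
fit_calibration <- function(fraction_pct, ratio) {
  if (length(fraction_pct) != length(ratio)) stop("length mismatch")
  ok <- is.finite(fraction_pct) & is.finite(ratio)
  fraction_pct <- fraction_pct[ok]; ratio <- ratio[ok]
  fr <- sort(unique(fraction_pct))
  if (length(fr) < 3L) stop("need at least 3 distinct design fractions")
  if (max(fr) - min(fr) < 50)
    stop("design must cover at least 50 percentage points of range")
  if (any(fr < 0 | fr > 100)) stop("fractions must lie in [0, 100]")
  fit <- stats::lm(ratio ~ fraction_pct)
  # noise-free designs (exact lines) are legitimate here; summary.lm warns
  # about them, so that warning is muffled
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  co <- sm$coefficients
  slope <- co["fraction_pct", "Estimate"]
  intercept <- co["(Intercept)", "Estimate"]
  residual_sd <- sm$sigma
  means <- as.numeric(tapply(ratio, fraction_pct, mean))
  # monotone fallback: replicate means decreasing by more than twice the
  # linear fit's residual SD indicate curvature the line cannot represent
  nonmono <- any(diff(means) < -2 * max(residual_sd, .Machine$double.eps))
  fit_kind <- "linear"
  mono_fractions <- mono_ratios <- NULL
  if (nonmono) {
    iso <- stats::isoreg(fr, means)
    mono_fractions <- fr
    mono_ratios <- iso$yf
    fit_kind <- "monotone"
    if (max(mono_ratios) - min(mono_ratios) <= 0)
      stop("non-monotone calibration: no increasing fit possible")
  }
  if (fit_kind == "linear" && slope <= 0)
    stop("non-monotone calibration: fitted slope is not positive")
  structure(list(design_fractions = fr, mean_ratios = means,
                 slope = slope, intercept = intercept,
                 slope_se = co["fraction_pct", "Std. Error"],
                 intercept_se = co["(Intercept)", "Std. Error"],
                 residual_sd = residual_sd, fit_kind = fit_kind,
                 mono_fractions = mono_fractions, mono_ratios = mono_ratios,
                 n = length(ratio)),
            class = "ab_calibration")
}

#' @export
print.ab_calibration <- function(x, ...) {
  cat(sprintf("ab_calibration (%s): ratio = %.5f * f%% + %.4f, residual sd %.4f, n = %d\n",
              x$fit_kind, x$slope, x$intercept, x$residual_sd, x$n))
  invisible(x)
}

#' Inverse-predict the isoD7 fraction from an observed ratio
#'
#' Inverts the fitted calibration relation. Predictions outside the physical
#' range are clamped to `[0, 100]` and flagged; the uncertainty is the
#' first-order propagation of the calibration residual SD through the
#' inverse slope.
#'
#' @param curve An `ab_calibration`.
#' @param ratio Observed marker/base ratio (single value).
#' @return A list of class `ab_iso_estimate`: `fraction_pct`, `sd_pct`,
#'   `clamped`.
#' @export
predict_fraction <- function(curve, ratio) {
  if (!inherits(curve, "ab_calibration")) stop("curve must be an ab_calibration")
  if (!is.finite(ratio)) stop("ratio must be finite")
  if (curve$fit_kind == "linear") {
    f <- (ratio - curve$intercept) / curve$slope
    sd_pct <- curve$residual_sd / curve$slope
  } else {
    yr <- curve$mono_ratios; xr <- curve$mono_fractions
    f <- stats::approx(yr, xr, xout = ratio, ties = mean, rule = 2)$y
    # local inverse slope at the prediction point
    seg <- findInterval(ratio, yr, all.inside = TRUE)
    dy <- yr[seg + 1L] - yr[seg]
    dx <- xr[seg + 1L] - xr[seg]
    sd_pct <- if (dy > 0) curve$residual_sd * dx / dy else Inf
  }
  clamped <- f < 0 || f > 100
  structure(list(fraction_pct = min(max(f, 0), 100),
                 sd_pct = abs(sd_pct), clamped = clamped),
            class = "ab_iso_estimate")
}

#' @export
print.ab_iso_estimate <- function(x, ...) {
  cat(sprintf("isoD7 fraction: %.1f%% (sd %.1f)%s%s\n", x$fraction_pct,
              x$sd_pct, if (isTRUE(x$clamped)) " [clamped]" else "",
              if (!is.null(x$n_spectra)) sprintf(", n = %d spectra", x$n_spectra) else ""))
  invisible(x)
}

#' Estimate a sample's isoD7 fraction from replicate MS/MS spectra
#'
#' Computes the marker/base ratio in every spectrum, averages the ratios
#' (mean of per-spectrum ratios; the alternative of ratioing accumulated
#' intensities is available via `average = "accumulated"`), and inverse
#' predicts the mean ratio through the calibration curve.
#'
#' @param spectra List of `ab_spectrum` of the Abeta(1-16) precursor
#'   (typically the 20 replicate acquisitions of one sample).
#' @param curve An `ab_calibration`.
#' @param marker,base Fragment channels (defaults `b6`/`b11`).
#' @param tolerance_da Fragment match tolerance (Da), default 0.05.
#' @param ladder Theoretical ladder to match against; defaults to human
#'   Abeta(1-16).
#' @param average `"ratios"` (default: mean of per-spectrum ratios) or
#'   `"accumulated"` (single ratio on the accumulated spectrum).
#' @return An `ab_iso_estimate` with `fraction_pct`, `sd_pct` (between-
#'   spectrum ratio SD mapped through the inverse slope), `n_spectra`,
#'   `marker_used`, `ratio_mean`, `ratio_sd`, `clamped`.
#' @export
estimate_sample <- function(spectra, curve, marker = "b6", base = "b11",
                            tolerance_da = 0.05,
                            ladder = theoretical_ladder(get_sequence("human", 1, 16)),
                            average = c("ratios", "accumulated")) {
  average <- match.arg(average)
  if (inherits(spectra, "ab_spectrum")) spectra <- list(spectra)
  if (length(spectra) < 1L) stop("need at least one spectrum")
  if (average == "accumulated") {
    acc <- accumulate(spectra)
    ratios <- marker_ratio(match_fragments(acc, ladder, tolerance_da),
                           marker, base)
  } else {
    ratios <- vapply(spectra, function(s) {
      m <- match_fragments(s, ladder, tolerance_da)
      tryCatch(marker_ratio(m, marker, base), error = function(e) NA_real_)
    }, 0)
    ratios <- ratios[!is.na(ratios)]
    if (length(ratios) == 0L)
      stop("base fragment missing in every spectrum")
  }
  mean_ratio <- mean(ratios)
  sd_ratio <- if (length(ratios) > 1L) stats::sd(ratios) else 0
  est <- predict_fraction(curve, mean_ratio)
  slope_local <- if (curve$fit_kind == "linear") curve$slope else {
    yr <- curve$mono_ratios; xr <- curve$mono_fractions
    seg <- findInterval(mean_ratio, yr, all.inside = TRUE)
    max((yr[seg + 1L] - yr[seg]) / (xr[seg + 1L] - xr[seg]), .Machine$double.eps)
  }
  est$sd_pct <- sd_ratio / slope_local
  est$n_spectra <- length(ratios)
  est$marker_used <- marker
  est$ratio_mean <- mean_ratio
  est$ratio_sd <- sd_ratio
  est
}

#' Compare calibration curves for matrix effects
#'
#' Tests whether calibration curves measured under different backgrounds
#' (e.g. neat standards vs standards spiked into brain extract) share slope
#' and intercept, using pairwise Welch-type t-tests on the least-squares
#' coefficients at alpha = 0.05.
#'
#' @param curves List of at least two `ab_calibration` objects fitted on the
#'   same design fractions.
#' @return A list of class `ab_matrix_check`: `comparisons` (data.frame of
#'   pairwise slope/intercept differences and p-values) and `verdict`
#'   (`"comparable"` when no test is significant, else `"different"`).
#' @export
matrix_effect_check <- function(curves) {
  if (length(curves) < 2L) stop("need at least two curves")
  for (cv in curves) if (!inherits(cv, "ab_calibration"))
    stop("all elements must be ab_calibration objects")
  d0 <- curves[[1]]$design_fractions
  for (cv in curves[-1]) if (!isTRUE(all.equal(cv$design_fractions, d0)))
    stop("mismatched calibration designs")
  pairs <- utils::combn(length(curves), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- curves[[pairs[1, k]]]; b <- curves[[pairs[2, k]]]
    p_for <- function(da, se, df) {
      if (da == 0) return(1)
      if (se == 0) return(0)
      2 * stats::pt(-abs(da / se), df)
    }
    df <- a$n + b$n - 4
    data.frame(curve_a = pairs[1, k], curve_b = pairs[2, k],
               slope_diff = a$slope - b$slope,
               p_slope = p_for(a$slope - b$slope,
                               sqrt(a$slope_se^2 + b$slope_se^2), df),
               intercept_diff = a$intercept - b$intercept,
               p_intercept = p_for(a$intercept - b$intercept,
                                   sqrt(a$intercept_se^2 + b$intercept_se^2), df))
  })
  comparisons <- do.call(rbind, rows)
  sig <- with(comparisons, p_slope < 0.05 | p_intercept < 0.05)
  structure(list(comparisons = comparisons,
                 verdict = if (any(sig)) "different" else "comparable"),
            class = "ab_matrix_check")
}

#' @export
print.ab_matrix_check <- function(x, ...) {
  cat("matrix-effect check:", x$verdict, "\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
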