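# Cohort-level statistics: Kendall tau-b trend testing, Mann-Whitney U
# group comparison, z-score outlier flagging, and age-phase grouping.

#' Kendall rank trend of a value against age
#'
#' Computes Kendall's tau-b (tie-corrected: ages in an ageing cohort are
#' heavily tied because several animals share an age) between age and value.
#' The two-sided p-value is exact (distribution of the concordant-pair
#' count) for tie-free data with `n <= 10`, and otherwise uses the normal
#' approximation with the standard tie-corrected variance of the S
#' statistic.
#'
#' @param age,value Paired numeric vectors, `n >= 3`.
#' @return A list of class `ab_trend`: `tau`, `p_value`, `n`, `method`.
#' @export
kendall_trend <- function(age, value) {
  ok <- is.finite(age) & is.finite(value)
  age <- age[ok]; value <- value[ok]
  n <- length(age)
  if (n < 3L) stop("need at least 3 observations")
  if (length(unique(value)) < 2L)
    stop("tau undefined: values are constant")
  if (length(unique(age)) < 2L)
    stop("tau undefined: ages are constant")
  S <- 0
  for (i in seq_len(n - 1L)) {
    dx <- age[(i + 1L):n] - age[i]
    dy <- value[(i + 1L):n] - value[i]
    S <- S + sum(sign(dx) * sign(dy))
  }
  n0 <- n * (n - 1) / 2
  tx <- table(age); ty <- table(value)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  has_ties <- n1 > 0 || n2 > 0
  if (!has_ties && n <= 10L) {
    # exact null distribution of S via the classical recursion over
    # inversion counts of a random permutation
    counts <- 1
    for (k in 2:n) {
      new <- numeric(length(counts) + k - 1L)
      for (j in 0:(k - 1L)) new[(j + 1):(j + length(counts))] <-
          new[(j + 1):(j + length(counts))] + counts
      counts <- new
    }
    probs <- counts / sum(counts)            # P(#discordant pairs = d)
    s_values <- n0 - 2 * (seq_along(probs) - 1L)  # S for d discordant pairs
    p <- sum(probs[abs(s_values) >= abs(S)])
    method <- "exact"
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(var_s)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(tau = tau, p_value = min(p, 1), n = n, method = method),
            class = "ab_trend")
}

#' @export
print.ab_trend <- function(x, ...) {
  cat(sprintf("Kendall tau-b = %.3f, p = %.3g (%s, n = %d)\n",
              x$tau, x$p_value, x$method, x$n))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided U test comparing two independent groups. U is the number of
#' (a, b) pairs with `a < b` plus half the ties; the p-value uses the normal
#' approximation with tie correction and continuity correction (the same
#' approximation standard implementations apply under ties).
#'
#' @param groupA,groupB Non-empty numeric vectors.
#' @return A list of class `ab_mw`: `U` (for group A), `p_value`,
#'   `significant` (at alpha = 0.05).
#' @export
mann_whitney <- function(groupA, groupB) {
  groupA <- groupA[is.finite(groupA)]; groupB <- groupB[is.finite(groupB)]
  n1 <- length(groupA); n2 <- length(groupB)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  cmp <- outer(groupA, groupB, "<")
  ties <- outer(groupA, groupB, "==")
  U <- sum(cmp) + 0.5 * sum(ties)
  N <- n1 + n2
  t_counts <- table(c(groupA, groupB))
  tie_term <- sum(t_counts^3 - t_counts) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    p <- 1  # all observations identical
  } else {
    z <- (abs(U - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(2 * stats::pnorm(-z), 1)
  }
  structure(list(U = U, p_value = p, significant = p < 0.05,
                 n = c(n1, n2)), class = "ab_mw")
}

#' @export
print.ab_mw <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, p = %.3g%s\n", x$U, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Flag outliers by z-score
#'
#' Flags values whose absolute z-score, `|x - mean| / sd`, exceeds the
#' threshold (default 3). Note the algebraic bound: the largest attainable
#' z-score in a sample of size n is `(n - 1) / sqrt(n)`, so no flag is
#' possible for n < 11 at threshold 3 regardless of the data.
#'
#' @param values Numeric vector, `n >= 3`.
#' @param threshold z-score cutoff; default 3.
#' @return Logical vector of flags (all `FALSE`, with a warning, when the SD
#'   is zero).
#' @export
detect_outliers <- function(values, threshold = 3) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    warning("zero standard deviation; no outliers can be flagged")
    return(rep(FALSE, length(values)))
  }
  abs(values - mean(values)) / s > threshold
}

#' Group cohort ages into accumulation phases
#'
#' Maps ages (months) to phase labels by right-closed bin edges. The default
#' bins mirror the accumulation phases of an amyloidosis mouse cohort:
#' slow early accumulation up to 6 months, an intermediate plateau at 7-9,
#' rapid accumulation at 10-14, and the late phase beyond.
#'
#' @param ages Positive numeric vector of ages in months.
#' @param edges Increasing internal bin edges; age a falls in the first bin
#'   with `a <= edge`, and beyond the last edge into the final bin.
#' @param labels One label per bin (`length(edges) + 1`).
#' @return Factor of phase labels, one per age.
#' @export
group_by_phase <- function(ages, edges = c(6, 9, 14),
                           labels = c("early", "plateau", "rapid", "late")) {
  if (any(!is.finite(ages) | ages <= 0)) stop("ages must be positive")
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be increasing")
  if (length(labels) != length(edges) + 1L)
    stop("need one label per bin (", length(edges) + 1L, ")")
  idx <- vapply(ages, function(a) sum(a > edges) + 1L, 1L)  # right-closed bins
  factor(labels[idx], levels = labels)
}
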