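# Independent oracles used to check the package's fragment-mass and
# rank-statistic implementations. These deliberately re-derive everything
# from first principles (their own constants, direct enumeration) and share
# no code with the package internals.

ORACLE_AA <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)
ORACLE_PROTON <- 1.007276467
ORACLE_WATER <- 18.010565
ORACLE_MOD_DELTA <- c(deamidation = 0.984016, oxidation = 15.994915,
                      phosphorylation = 79.966331,
                      pyroglutamate_E = -18.010565,
                      pyroglutamate_Q = -17.026549, iso_asp = 0)
ORACLE_MOD_TARGETS <- list(deamidation = c("N", "Q"), oxidation = "M",
                           phosphorylation = c("S", "T", "Y"),
                           pyroglutamate_E = "E", pyroglutamate_Q = "Q",
                           iso_asp = "D")

# brute-force fragment m/z: residues is a plain string, deltas a per-residue
# numeric vector of modification mass shifts
oracle_fragment_mz <- function(residues, series, index, deltas = NULL) {
  aa <- strsplit(residues, "")[[1]]
  if (is.null(deltas)) deltas <- numeric(length(aa))
  masses <- ORACLE_AA[aa] + deltas
  if (series == "b") sum(masses[1:index]) + ORACLE_PROTON
  else sum(masses[(length(aa) - index + 1):length(aa)]) +
    ORACLE_WATER + ORACLE_PROTON
}

oracle_mh <- function(residues, deltas = NULL) {
  aa <- strsplit(residues, "")[[1]]
  if (is.null(deltas)) deltas <- numeric(length(aa))
  sum(ORACLE_AA[aa] + deltas) + ORACLE_WATER + ORACLE_PROTON
}

random_peptide <- function(len) {
  paste(sample(names(ORACLE_AA), len, replace = TRUE), collapse = "")
}

# draw a random legal modification set for a peptide; returns list(mods =
# data.frame(position, name), deltas = per-residue vector)
random_legal_mods <- function(residues, max_mods = 3) {
  aa <- strsplit(residues, "")[[1]]
  deltas <- numeric(length(aa))
  mods <- data.frame(position = integer(), name = character())
  n_mods <- sample(0:max_mods, 1)
  avail <- seq_along(aa)
  for (k in seq_len(n_mods)) {
    if (!length(avail)) break
    i <- if (length(avail) == 1L) avail else sample(avail, 1)
    legal <- names(ORACLE_MOD_TARGETS)[vapply(ORACLE_MOD_TARGETS, function(t)
      aa[i] %in% t, TRUE)]
    if (i != 1L)
      legal <- setdiff(legal, c("pyroglutamate_E", "pyroglutamate_Q"))
    if (!length(legal)) { avail <- setdiff(avail, i); next }
    name <- if (length(legal) == 1L) legal else sample(legal, 1)
    mods <- rbind(mods, data.frame(position = i, name = name))
    deltas[i] <- deltas[i] + ORACLE_MOD_DELTA[[name]]
    avail <- setdiff(avail, i)
  }
  list(mods = mods, deltas = deltas)
}

# exhaustive-pair Kendall tau-b
oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0 && sy == 0) next
    if (sx == 0) tx <- tx + 1
    else if (sy == 0) ty <- ty + 1
    else if (sx == sy) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - sum(table(x) * (table(x) - 1) / 2)) *
                 (n0 - sum(table(y) * (table(y) - 1) / 2)))
}

# exhaustive-pair Mann-Whitney U for group A
oracle_mw_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x < y) + 0.5 * (x == y)
  u
}

# quick noise-free spectrum config for deterministic tests
noise_free_config <- function(...) {
  spectrum_sim_config(noise_cv = 0, n_background_peaks = 0L,
                      mz_jitter_da = 0, ...)
}

HUMAN_1_16_LADDER <- theoretical_ladder(get_sequence("human", 1, 16))
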