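# Synthetic-data generator: simulated CID MS/MS spectra of norm/isoD7
# Abeta(1-16) mixtures and a simulated 5xFAD-like ageing cohort, with the
# generating parameters returned as ground truth so every estimator in the
# package can be exercised against a known answer without any raw data.

#' Spectrum simulation configuration
#'
#' Describes the generative model for a CID spectrum of the Abeta(1-16)
#' precursor: pure-species fragment-intensity profiles, a multiplicative
#' log-normal intensity noise, small m/z jitter, and uniform background
#' peaks. The marker fragments (b6, b7, y10) are enhanced in the pure-iso
#' profile; the base fragments (b11, y11) are identical between profiles by
#' construction, so the marker/base ratio is exactly linear in the mixing
#' fraction at zero noise.
#'
#' The absolute intensities and the factor-2 marker enhancement are free
#' parameters of the simulation (no reference spectra are available to fit
#' them); they are chosen so the b6/b11 ratio doubles from 0% to 100% iso.
#'
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   intensity noise (default 0.10).
#' @param n_background_peaks Number of uniform background peaks (default 15).
#' @param mz_jitter_da SD of Gaussian m/z jitter on fragment peaks (Da).
#' @param marker_enhancement Intensity multiplier of b6/b7/y10 in the pure
#'   iso profile (default 2; must exceed 1).
#' @return A list of class `ab_spectrum_sim_config` with `pure_norm_profile`
#'   and `pure_iso_profile` (named intensity vectors over the full b/y
#'   ladder), the theoretical `ladder`, `precursor_mz` and the noise
#'   parameters.
#' @export
spectrum_sim_config <- function(noise_cv = 0.10, n_background_peaks = 15L,
                                mz_jitter_da = 0.002,
                                marker_enhancement = 2) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (marker_enhancement <= 1) stop("marker enhancement factors must exceed 1")
  seq16 <- get_sequence("human", 1, 16)
  ladder <- theoretical_ladder(seq16)
  norm <- stats::setNames(rep(20, nrow(ladder)), ladder$label)
  norm[c("b6", "b7", "y10")] <- c(40, 30, 35)
  norm[c("b11", "y11")] <- c(100, 80)
  iso <- norm
  iso[c("b6", "b7", "y10")] <- norm[c("b6", "b7", "y10")] * marker_enhancement
  structure(list(pure_norm_profile = norm, pure_iso_profile = iso,
                 ladder = ladder, precursor_mz = peptide_mh(seq16),
                 noise_cv = noise_cv,
                 n_background_peaks = as.integer(n_background_peaks),
                 mz_jitter_da = mz_jitter_da),
            class = "ab_spectrum_sim_config")
}

#' Simulate one CID spectrum of a norm/isoD7 mixture
#'
#' Fragment intensity means are the linear mixture
#' `(1 - f/100) * norm + (f/100) * iso`; each is multiplied by log-normal
#' noise with the configured CV (mean preserved), fragment m/z receives
#' Gaussian jitter, and background peaks are placed uniformly at random,
#' avoiding a 0.1 Da guard band around every theoretical fragment.
#'
#' @param iso_fraction_pct True isoD7 percentage in `[0, 100]`.
#' @param config An [spectrum_sim_config()].
#' @param seed Optional integer; when given, the spectrum is a pure function
#'   of `(config, iso_fraction_pct, seed)`.
#' @param sample_id,replicate Identity stamped on the spectrum.
#' @return An `ab_spectrum`.
#' @export
simulate_spectrum <- function(iso_fraction_pct, config = spectrum_sim_config(),
                              seed = NULL, sample_id = "sim", replicate = 1L) {
  if (!is.finite(iso_fraction_pct) || iso_fraction_pct < 0 ||
      iso_fraction_pct > 100)
    stop("iso_fraction_pct must lie in [0, 100]")
  if (!is.null(seed)) set.seed(seed)
  f <- iso_fraction_pct / 100
  mu <- (1 - f) * config$pure_norm_profile + f * config$pure_iso_profile
  cv <- config$noise_cv
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    noise <- stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    intensity <- mu * noise
  } else intensity <- mu
  mz <- config$ladder$mz
  if (config$mz_jitter_da > 0)
    mz <- mz + stats::rnorm(length(mz), 0, config$mz_jitter_da)
  nbg <- config$n_background_peaks
  if (nbg > 0) {
    guard <- 0.1
    theo <- sort(config$ladder$mz)
    bg_mz <- numeric(0)
    lo <- 100; hi <- config$precursor_mz - 20
    while (length(bg_mz) < nbg) {
      cand <- stats::runif(nbg * 2, lo, hi)
      j <- findInterval(cand, theo)
      d_lo <- ifelse(j >= 1L, cand - theo[pmax(j, 1L)], Inf)
      d_hi <- ifelse(j < length(theo), theo[pmin(j + 1L, length(theo))] - cand, Inf)
      bg_mz <- c(bg_mz, cand[pmin(d_lo, d_hi) > guard])
    }
    bg_mz <- bg_mz[seq_len(nbg)]
    bg_int <- stats::runif(nbg, 0.5, 8)
    mz <- c(mz, bg_mz); intensity <- c(intensity, bg_int)
  }
  new_spectrum(mz, unname(intensity), config$precursor_mz,
               sample_id = sample_id, replicate = replicate,
               metadata = list(true_iso_fraction_pct = iso_fraction_pct))
}

#' Simulate a binary-mixture calibration series
#'
#' Replicate spectra at every design fraction `0, step, ..., 100` percent,
#' mirroring the canonical 0-100% in 10% increments mixing design.
#'
#' @param step_pct Design step in percent; must divide 100 (default 10).
#' @param reps Replicate spectra per fraction (default 3).
#' @param config An [spectrum_sim_config()].
#' @param seed Optional integer seed for the whole series.
#' @return A data.frame with columns `fraction_pct`, `replicate`, and a
#'   list-column `spectrum`.
#' @export
simulate_calibration_series <- function(step_pct = 10, reps = 3,
                                        config = spectrum_sim_config(),
                                        seed = NULL) {
  if (step_pct <= 0) stop("step_pct must be positive")
  if (100 %% step_pct != 0) stop("step_pct must divide 100")
  if (reps < 1) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  fractions <- seq(0, 100, by = step_pct)
  grid <- expand.grid(replicate = seq_len(reps), fraction_pct = fractions)
  grid <- grid[, c("fraction_pct", "replicate")]
  grid$spectrum <- lapply(seq_len(nrow(grid)), function(i)
    simulate_spectrum(grid$fraction_pct[i], config,
                      sample_id = sprintf("cal%03d", grid$fraction_pct[i]),
                      replicate = grid$replicate[i]))
  grid
}

#' Fit a calibration curve from a simulated (or measured) series
#'
#' Convenience wrapper: computes the marker/base ratio of every spectrum in
#' a calibration series and fits [fit_calibration()].
#'
#' @param series Data frame as returned by [simulate_calibration_series()]
#'   (columns `fraction_pct`, `spectrum`).
#' @param marker,base Fragment channels.
#' @param tolerance_da Fragment match tolerance (Da).
#' @param ladder Theoretical ladder; defaults to human Abeta(1-16).
#' @return An `ab_calibration`.
#' @export
calibrate_from_series <- function(series, marker = "b6", base = "b11",
                                  tolerance_da = 0.05,
                                  ladder = theoretical_ladder(get_sequence("human", 1, 16))) {
  ratios <- vapply(series$spectrum, function(s)
    marker_ratio(match_fragments(s, ladder, tolerance_da), marker, base), 0)
  fit_calibration(series$fraction_pct, ratios)
}

#' Cohort simulation configuration
#'
#' The stated world of the simulated ageing cohort: the default animal table
#' is 24 animals (two each at 2, 8, 9, 10, 12, 14 and 16 months, three each
#' at 3 and 7 months, one each at 4, 17, 18 and 23 months). Total Abeta
#' follows a logistic accumulation per species, plateauing near 10 ng per mg
#' of tissue for the overexpressed human peptide; the murine peptide
#' plateaus earlier (by ~12 months) and about 50-fold lower. The true isoD7
#' fraction rises linearly from 8% at 7 months to 30% at 23 months with a
#' 5-percentage-point between-animal SD; Met35 oxidation sits at 13%,
#' pyroglutamate on E3-truncated peptides at 7%, deamidation peaks near 12
#' months, and the missed-cleavage probability rises after 16 months.
#'
#' @param animals Data frame `age_months`/`count`.
#' @param n_psms_per_sample PSMs generated per animal (default 500).
#' @param n_spectra_per_sample Replicate MS/MS spectra per animal (default
#'   20).
#' @param iso_anchor_low,iso_anchor_high `(age, pct)` anchors of the linear
#'   isoD7 trajectory.
#' @param iso_animal_sd Between-animal SD of the true isoD7 fraction
#'   (percentage points).
#' @param human_trajectory,murine_trajectory Logistic parameters
#'   `(plateau, midpoint_months, rate)` of total-Abeta accumulation.
#' @param oxidation_m35,pyroglu_e3 Occupancy probabilities.
#' @param deamidation_peak Named vector `Q15`/`N27`: peak occupancies of the
#'   Gaussian-in-age deamidation schedule centred at `deamidation_peak_month`.
#' @param deamidation_peak_month,deamidation_width Centre and SD (months).
#' @param truncation_start_probs Named probabilities of N-terminal start
#'   positions (normalized internally; `-1` is the Met-extended form).
#' @param cterm_end_probs Named probabilities of C-terminal end positions.
#' @param missed_cleavage_base,missed_cleavage_rise Baseline missed-cleavage
#'   probability and the amplitude of its logistic rise centred at 17
#'   months.
#' @param intensity_sdlog Log-scale SD of per-PSM intensity noise.
#' @param spectrum_config An [spectrum_sim_config()] used for the per-animal
#'   MS/MS spectra.
#' @return A list of class `ab_cohort_config`.
#' @export
cohort_config <- function(
    animals = data.frame(
      age_months = c(2, 2, 3, 3, 3, 4, 7, 7, 7, 8, 8, 9, 9, 10, 10,
                     12, 12, 14, 14, 16, 16, 17, 18, 23),
      count = 1L),
    n_psms_per_sample = 500L,
    n_spectra_per_sample = 20L,
    iso_anchor_low = c(age = 7, pct = 8),
    iso_anchor_high = c(age = 23, pct = 30),
    iso_animal_sd = 5,
    human_trajectory = c(plateau = 10, midpoint = 10.5, rate = 0.7),
    murine_trajectory = c(plateau = 0.2, midpoint = 8, rate = 0.8),
    oxidation_m35 = 0.13,
    pyroglu_e3 = 0.07,
    deamidation_peak = c(Q15 = 0.05, N27 = 0.03),
    deamidation_peak_month = 12,
    deamidation_width = 4,
    truncation_start_probs = c("-1" = 0.01, "1" = 0.78, "2" = 0.02,
                               "3" = 0.06, "4" = 0.01, "5" = 0.04,
                               "6" = 0.01, "7" = 0.01, "8" = 0.03,
                               "9" = 0.02, "10" = 0.005, "11" = 0.005),
    cterm_end_probs = c("40" = 0.04, "41" = 0.01, "42" = 0.94, "43" = 0.01),
    missed_cleavage_base = 0.05,
    missed_cleavage_rise = 0.25,
    intensity_sdlog = 0.35,
    spectrum_config = spectrum_sim_config()) {
  if (any(animals$count < 1L)) stop("animal counts must be >= 1")
  if (any(animals$age_months <= 0)) stop("ages must be positive")
  probs <- c(truncation_start_probs, cterm_end_probs,
             oxidation_m35, pyroglu_e3, deamidation_peak,
             missed_cleavage_base, missed_cleavage_base + missed_cleavage_rise)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  cfg <- structure(list(
    animals = animals, n_psms_per_sample = as.integer(n_psms_per_sample),
    n_spectra_per_sample = as.integer(n_spectra_per_sample),
    iso_anchor_low = iso_anchor_low, iso_anchor_high = iso_anchor_high,
    iso_animal_sd = iso_animal_sd,
    human_trajectory = human_trajectory, murine_trajectory = murine_trajectory,
    oxidation_m35 = oxidation_m35, pyroglu_e3 = pyroglu_e3,
    deamidation_peak = deamidation_peak,
    deamidation_peak_month = deamidation_peak_month,
    deamidation_width = deamidation_width,
    truncation_start_probs = truncation_start_probs / sum(truncation_start_probs),
    cterm_end_probs = cterm_end_probs / sum(cterm_end_probs),
    missed_cleavage_base = missed_cleavage_base,
    missed_cleavage_rise = missed_cleavage_rise,
    intensity_sdlog = intensity_sdlog,
    spectrum_config = spectrum_config), class = "ab_cohort_config")
  ages <- rep(animals$age_months, animals$count)
  iso <- vapply(ages, function(a) iso_trajectory(cfg, a), 0)
  bad <- iso < 0 | iso > 100
  if (any(bad))
    stop("isoD7 trajectory leaves [0, 100] at age ", ages[bad][1], " months")
  cfg
}

#' True isoD7 trajectory (percent) at an age
#' @param config An `ab_cohort_config`.
#' @param age_months Age in months.
#' @export
iso_trajectory <- function(config, age_months) {
  a0 <- config$iso_anchor_low; a1 <- config$iso_anchor_high
  slope <- (a1[["pct"]] - a0[["pct"]]) / (a1[["age"]] - a0[["age"]])
  a0[["pct"]] + slope * (age_months - a0[["age"]])
}

#' Total-Abeta logistic trajectory at an age
#' @param config An `ab_cohort_config`.
#' @param age_months Age in months.
#' @param species `"human"` or `"murine"`.
#' @export
abeta_trajectory <- function(config, age_months, species = c("human", "murine")) {
  species <- match.arg(species)
  p <- if (species == "human") config$human_trajectory else config$murine_trajectory
  p[["plateau"]] / (1 + exp(-p[["rate"]] * (age_months - p[["midpoint"]])))
}

.deamidation_level <- function(config, age_months, site = c("Q15", "N27")) {
  site <- match.arg(site)
  config$deamidation_peak[[site]] *
    exp(-(age_months - config$deamidation_peak_month)^2 /
          (2 * config$deamidation_width^2))
}

.missed_cleavage_prob <- function(config, age_months) {
  config$missed_cleavage_base +
    config$missed_cleavage_rise / (1 + exp(-(age_months - 17)))
}

#' Simulate the PSM table of a single sample
#'
#' Draws `n_psms_per_sample` peptide-spectrum matches for one animal:
#' species by the relative human/murine trajectory intensity at that age,
#' peptide family (N-terminal X-16, mid 17-28, C-terminal 29-X, or a
#' missed-cleavage span), truncation positions from the configured
#' probabilities, and PTMs from the age-evaluated schedules; intensities are
#' log-normal around the species trajectory value.
#'
#' @param config An [cohort_config()].
#' @param age_months Animal age.
#' @param sample_id Sample label.
#' @param seed Optional integer seed.
#' @return A data.frame of PSM rows (unvalidated; feed through
#'   [validate_psm_records()] for analysis).
#' @export
simulate_psm_sample <- function(config, age_months, sample_id = "sim",
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_psms_per_sample
  h <- abeta_trajectory(config, age_months, "human")
  m <- abeta_trajectory(config, age_months, "murine")
  species <- ifelse(stats::runif(n) < h / (h + m), "human", "murine")
  mc <- stats::runif(n) < .missed_cleavage_prob(config, age_months)
  family <- ifelse(mc, ifelse(stats::runif(n) < 0.5, "mc_n", "mc_c"),
                   sample(c("nterm", "mid", "cterm"), n, replace = TRUE,
                          prob = c(0.5, 0.2, 0.3)))
  starts <- integer(n); ends <- integer(n)
  sp <- as.integer(names(config$truncation_start_probs))
  ep <- as.integer(names(config$cterm_end_probs))
  idx_n <- family == "nterm"
  starts[idx_n] <- sample(sp, sum(idx_n), replace = TRUE,
                          prob = config$truncation_start_probs)
  ends[idx_n] <- 16L
  starts[family == "mid"] <- 17L; ends[family == "mid"] <- 28L
  idx_c <- family == "cterm"
  starts[idx_c] <- 29L
  ends[idx_c] <- sample(ep, sum(idx_c), replace = TRUE,
                        prob = config$cterm_end_probs)
  starts[family == "mc_n"] <- 1L; ends[family == "mc_n"] <- 28L
  starts[family == "mc_c"] <- 17L; ends[family == "mc_c"] <- 42L
  peptides <- vapply(seq_len(n), function(i)
    get_sequence(if (starts[i] >= 17L) "human" else species[i],
                 starts[i], ends[i])$residues, "")
  dQ15 <- .deamidation_level(config, age_months, "Q15")
  dN27 <- .deamidation_level(config, age_months, "N27")
  mods <- vapply(seq_len(n), function(i) {
    md <- character(0)
    covers <- function(p) starts[i] <= p && ends[i] >= p
    if (covers(35L) && stats::runif(1) < config$oxidation_m35)
      md <- c(md, "35:oxidation")
    if (starts[i] == 3L && stats::runif(1) < config$pyroglu_e3)
      md <- c(md, "3:pyroglutamate_E")
    if (covers(15L) && stats::runif(1) < dQ15)
      md <- c(md, "15:deamidation")
    if (covers(27L) && stats::runif(1) < dN27)
      md <- c(md, "27:deamidation")
    paste(md, collapse = ";")
  }, "")
  base_int <- ifelse(species == "human", h, m)
  intensity <- stats::rlnorm(n, meanlog = log(base_int), sdlog = config$intensity_sdlog)
  data.frame(sample_id = sample_id, age_months = age_months,
             peptide = peptides, start = starts, end = ends,
             mods = mods, intensity = intensity,
             stringsAsFactors = FALSE)
}

#' Simulate a full ageing cohort
#'
#' Expands the configured animal table, draws each animal's true isoD7
#' fraction (linear trajectory plus between-animal noise), generates its PSM
#' table and its replicate MS/MS spectra, and returns the generating ground
#' truth alongside.
#'
#' @param config An [cohort_config()].
#' @param seed Integer seed; the whole cohort is a pure function of
#'   `(config, seed)`.
#' @param spectra Set `FALSE` to skip spectrum generation (PSM-only studies
#'   run much faster).
#' @return A list of class `ab_cohort`: `psm` (combined validated-format PSM
#'   table), `spectra` (per-animal list of `ab_spectrum`, or `NULL`),
#'   `truth` (data.frame of per-animal age and true isoD7 plus trajectory
#'   values) and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L,
                            spectra = TRUE) {
  set.seed(seed)
  ages <- rep(config$animals$age_months, config$animals$count)
  n_animal <- length(ages)
  ids <- sprintf("m%02d_age%02d", seq_len(n_animal), ages)
  true_iso <- vapply(ages, function(a) iso_trajectory(config, a), 0) +
    stats::rnorm(n_animal, 0, config$iso_animal_sd)
  true_iso <- pmin(pmax(true_iso, 0), 100)
  psm <- do.call(rbind, lapply(seq_len(n_animal), function(i)
    simulate_psm_sample(config, ages[i], ids[i])))
  spec_list <- NULL
  if (isTRUE(spectra)) {
    spec_list <- lapply(seq_len(n_animal), function(i)
      lapply(seq_len(config$n_spectra_per_sample), function(r)
        simulate_spectrum(true_iso[i], config$spectrum_config,
                          sample_id = ids[i], replicate = r)))
    names(spec_list) <- ids
  }
  truth <- data.frame(
    sample_id = ids, age_months = ages, true_iso_pct = true_iso,
    human_total = vapply(ages, function(a) abeta_trajectory(config, a, "human"), 0),
    murine_total = vapply(ages, function(a) abeta_trajectory(config, a, "murine"), 0),
    stringsAsFactors = FALSE)
  structure(list(psm = psm, spectra = spec_list, truth = truth,
                 config = config, seed = seed), class = "ab_cohort")
}

#' @export
print.ab_cohort <- function(x, ...) {
  cat(sprintf("ab_cohort: %d animals, %d PSMs%s (seed %d)\n",
              nrow(x$truth), nrow(x$psm),
              if (is.null(x$spectra)) "" else
                sprintf(", %d spectra/animal", x$config$n_spectra_per_sample),
              x$seed))
  invisible(x)
}

#' Write a complete offline fixture bundle
#'
#' Simulates a cohort plus a calibration series and writes everything a
#' pipeline run needs: one MGF per animal, the calibration MGF and design
#' CSV, the PSM CSV, the ground-truth JSON and the serialized configuration.
#' Re-running with the same seed reproduces the files byte for byte.
#'
#' @param outdir Output directory (created if needed).
#' @param config An [cohort_config()].
#' @param seed Integer seed.
#' @param calibration_reps Replicates per calibration fraction.
#' @return Data frame manifest (`file`, `kind`), invisibly the paths exist.
#' @export
write_fixture_bundle <- function(outdir, config = cohort_config(), seed = 1L,
                                 calibration_reps = 3L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config, seed)
  manifest <- list()
  add <- function(file, kind) manifest[[length(manifest) + 1L]] <<-
    data.frame(file = file, kind = kind)
  for (id in names(cohort$spectra)) {
    f <- file.path(outdir, paste0(id, ".mgf"))
    write_mgf(cohort$spectra[[id]], f)
    add(basename(f), "sample_mgf")
  }
  series <- simulate_calibration_series(10, calibration_reps,
                                        config$spectrum_config,
                                        seed = seed + 1L)
  cal_spectra <- series$spectrum
  f <- file.path(outdir, "calibration.mgf")
  write_mgf(cal_spectra, f); add("calibration.mgf", "calibration_mgf")
  utils::write.csv(series[, c("fraction_pct", "replicate")],
                   file.path(outdir, "design.csv"), row.names = FALSE)
  add("design.csv", "design_csv")
  utils::write.csv(cohort$psm, file.path(outdir, "psm.csv"), row.names = FALSE)
  add("psm.csv", "psm_csv")
  jsonlite::write_json(cohort$truth, file.path(outdir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  add("truth.json", "truth_json")
  cfg <- cohort$config
  cfg$spectrum_config$ladder <- NULL  # derivable; keep the JSON small
  jsonlite::write_json(lapply(unclass(cfg), unclass),
                       file.path(outdir, "config.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  add("config.json", "config_json")
  do.call(rbind, manifest)
}
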