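psm_row <- function(peptide, start, end, mods = "", intensity = 1,
                    sample_id = "s1", age = 12) {
  data.frame(sample_id = sample_id, age_months = age, peptide = peptide,
             start = start, end = end, mods = mods, intensity = intensity,
             stringsAsFactors = FALSE)
}

human_pep <- function(start, end) get_sequence("human", start, end)$residues

test_that("read_psm_table parses, validates and reports rejects", {
  tab <- rbind(
    psm_row(human_pep(1, 16), 1, 16, "", 90),
    psm_row(human_pep(3, 16), 3, 16, "3:pyroglutamate_E", 10),
    psm_row(human_pep(29, 42), 29, 42, "35:oxidation", 5),
    psm_row("DAEF", 9, 5, "", 1),               # start > end
    psm_row("DAEF", 1, 16, "", 1),              # length mismatch
    psm_row(human_pep(1, 16), 1, 16, "xx", 1))  # bad mods
  path <- tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  rec <- read_psm_table(path)
  expect_equal(nrow(rec), 3)
  rejects <- attr(rec, "rejects")
  expect_equal(nrow(rejects), 3)
  expect_match(rejects$reason[1], "start > end")
  expect_equal(rec$species, c("human", "human", "shared"))

  # TSV autodetection
  path2 <- tempfile(fileext = ".tsv")
  write.table(tab[1:2, ], path2, sep = "\t", row.names = FALSE)
  expect_equal(nrow(read_psm_table(path2)), 2)

  # missing column
  path3 <- tempfile(fileext = ".csv")
  write.csv(tab[, -3], path3, row.names = FALSE)
  expect_error(read_psm_table(path3), "peptide")
})

test_that("M(-1)-extended records validate with the off-by-one coordinate", {
  rec <- validate_psm_records(psm_row(paste0("M", human_pep(1, 16)), -1, 16))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$species, "human")
})

test_that("terminal_distribution computes normalized intensity fractions", {
  recs <- validate_psm_records(rbind(
    psm_row(human_pep(1, 16), 1, 16, "", 90),
    psm_row(human_pep(3, 16), 3, 16, "", 10)))
  d <- terminal_distribution(recs, "N")
  expect_equal(d, c("1" = 0.9, "3" = 0.1))
  expect_equal(sum(d), 1, tolerance = 1e-9)

  only1 <- validate_psm_records(psm_row(human_pep(1, 16), 1, 16, "", 5))
  expect_equal(terminal_distribution(only1, "N"), c("1" = 1.0))

  cterm <- validate_psm_records(rbind(
    psm_row(human_pep(29, 42), 29, 42, "", 94),
    psm_row(human_pep(29, 40), 29, 40, "", 4),
    psm_row(human_pep(29, 43), 29, 43, "", 2)))
  dc <- terminal_distribution(cterm, "C")
  expect_equal(unname(dc["42"]), 0.94)
  expect_equal(sum(dc), 1, tolerance = 1e-9)

  # invariant to uniform intensity rescaling
  recs2 <- recs; recs2$intensity <- recs2$intensity * 137
  expect_equal(terminal_distribution(recs2, "N"), d)

  expect_error(terminal_distribution(recs, "C"), "no records")
})

test_that("ptm_occupancy: worked example and contracts", {
  recs <- validate_psm_records(rbind(
    psm_row(human_pep(29, 42), 29, 42, "", 87),
    psm_row(human_pep(29, 42), 29, 42, "35:oxidation", 13)))
  expect_equal(ptm_occupancy(recs, 35, "oxidation"), 0.13)

  unmod <- validate_psm_records(psm_row(human_pep(29, 42), 29, 42, "", 10))
  expect_equal(ptm_occupancy(unmod, 35, "oxidation"), 0)
  expect_error(ptm_occupancy(unmod, 15, "deamidation"), "site not covered")
  expect_error(ptm_occupancy(unmod, 35, "hydroxylation"), "unknown modification")
})

test_that("N-terminus-restricted occupancy counts only peptides starting at the site", {
  recs <- validate_psm_records(rbind(
    psm_row(human_pep(1, 16), 1, 16, "", 100),        # covers E3, cannot be pyroGlu
    psm_row(human_pep(3, 16), 3, 16, "3:pyroglutamate_E", 6),
    psm_row(human_pep(3, 16), 3, 16, "", 94)))
  expect_equal(ptm_occupancy(recs, 3, "pyroglutamate_E"), 0.06)
})

test_that("occupancy recovery against the generator", {
  set.seed(61)
  cfg <- cohort_config(pyroglu_e3 = 0.06)
  ok <- replicate(20, {
    tab <- validate_psm_records(simulate_psm_sample(cfg, 12, "s"))
    e3 <- tab[tab$start == 3, ]
    phat <- ptm_occupancy(tab, 3, "pyroglutamate_E")
    se <- sqrt(0.06 * 0.94 / nrow(e3))
    abs(phat - 0.06) <= 3 * se
  })
  expect_gte(mean(ok), 0.9)
})

test_that("missed_cleavage_fraction identifies K16/K28-spanning peptides", {
  full <- validate_psm_records(rbind(
    psm_row(human_pep(1, 16), 1, 16),
    psm_row(human_pep(17, 28), 17, 28),
    psm_row(human_pep(29, 42), 29, 42)))
  expect_equal(missed_cleavage_fraction(full), 0)

  missed <- validate_psm_records(psm_row(human_pep(1, 28), 1, 28))
  expect_equal(missed_cleavage_fraction(missed), 1)

  mixed <- validate_psm_records(rbind(
    psm_row(human_pep(1, 16), 1, 16, "", 3),
    psm_row(human_pep(17, 42), 17, 42, "", 1)))
  expect_equal(missed_cleavage_fraction(mixed), 0.25)
})

test_that("missed-cleavage schedule rises with age in generator data", {
  set.seed(71)
  cfg <- cohort_config(n_psms_per_sample = 1000L)
  mc <- vapply(c(6, 12, 18, 23), function(a)
    missed_cleavage_fraction(validate_psm_records(
      simulate_psm_sample(cfg, a, "s"))), 0)
  expect_true(all(diff(mc) > 0))
})

test_that("abundance_timeseries families are nested and errors are raised", {
  recs <- validate_psm_records(rbind(
    psm_row(human_pep(1, 16), 1, 16, "", 5, sample_id = "a", age = 6)))
  for (ser in c("Ab1_16", "AbX_16", "total_Nterm"))
    expect_equal(abundance_timeseries(recs, ser)$intensity, 5)

  recs2 <- validate_psm_records(rbind(
    psm_row(human_pep(1, 16), 1, 16, "", 5, sample_id = "a", age = 6),
    psm_row(human_pep(2, 16), 2, 16, "", 2, sample_id = "a", age = 6)))
  expect_gt(abundance_timeseries(recs2, "AbX_16")$intensity,
            abundance_timeseries(recs2, "Ab1_16")$intensity)

  expect_error(abundance_timeseries(recs, "Ab1_42"), "unknown series")
})

test_that("simulated cohort reproduces the trajectory shapes", {
  cohort <- simulate_cohort(cohort_config(n_psms_per_sample = 300L),
                            seed = 5, spectra = FALSE)
  recs <- validate_psm_records(cohort$psm)
  expect_equal(nrow(attr(recs, "rejects")), 0)
  hum <- abundance_timeseries(recs, "AbX_16", species_filter = "human")
  mur <- abundance_timeseries(recs, "AbX_16", species_filter = "murine")
  # human series keeps growing after month 9; murine has plateaued by 12
  h_early <- mean(hum$intensity[hum$age_months <= 8])
  h_late <- mean(hum$intensity[hum$age_months >= 14])
  expect_gt(h_late, 5 * h_early)
  # murine is sparse in the table (human dominates the intensity after 10
  # months), so the plateau check pools age bins and allows a factor 2
  m_mid <- mean(mur$intensity[mur$age_months %in% c(12, 14)])
  m_late <- mean(mur$intensity[mur$age_months >= 16])
  expect_lt(abs(log(m_late / m_mid)), log(2))
  # nesting invariant across all three series
  tot <- abundance_timeseries(recs, "total_Nterm", species_filter = "human")
  one <- abundance_timeseries(recs, "Ab1_16", species_filter = "human")
  expect_true(all(one$intensity <= hum$intensity + 1e-9))
  expect_true(all(hum$intensity <= tot$intensity + 1e-9))
})

test_that("proteoform_profile aggregates per-sample summaries", {
  set.seed(81)
  tab <- validate_psm_records(simulate_psm_sample(cohort_config(), 14, "s14"))
  prof <- proteoform_profile(tab)
  expect_equal(sum(prof$n_term_fractions), 1, tolerance = 1e-9)
  expect_equal(sum(prof$c_term_fractions), 1, tolerance = 1e-9)
  expect_true(prof$ptm_occupancy[["oxidation_M35"]] >= 0 &&
              prof$ptm_occupancy[["oxidation_M35"]] <= 1)
  expect_true(all(c("phospho_S8", "phospho_Y10") %in% prof$low_confidence))
  expect_true(prof$missed_cleavage_fraction >= 0 &&
              prof$missed_cleavage_fraction <= 1)
})
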