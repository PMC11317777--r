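test_that("most severe outcome follows the fixed ranking", {
  expect_equal(most_severe_outcome(c("HO", "DE")), "DE")
  expect_equal(most_severe_outcome(c("OT")), "OT")
  expect_equal(most_severe_outcome(character(0)), "Unknown")
  # order-invariant and idempotent under duplication
  expect_equal(most_severe_outcome(c("OT", "LT", "HO")),
               most_severe_outcome(c("HO", "OT", "LT")))
  expect_equal(most_severe_outcome(c("HO", "HO", "DS")),
               most_severe_outcome(c("DS", "HO")))
  expect_error(most_severe_outcome(c("HO", "ZZ")), "unknown outcome code")
  # list interface vectorizes
  expect_equal(most_severe_outcome(list(c("HO", "DE"), character(0))),
               c("DE", "Unknown"))
})

test_that("median and quartiles use inclusive linear interpolation", {
  expect_equal(median_iqr(c(7, 9, 12, 13)),
               c(median = 10.5, q1 = 8.5, q3 = 12.25))
  # degenerate single observation
  expect_equal(median_iqr(5), c(median = 5, q1 = 5, q3 = 5))
  expect_true(all(is.na(median_iqr(NA_real_))))
  # property: matches a hand-rolled order-statistic oracle
  set.seed(12)
  for (i in 1:20) {
    x <- sample(0:400, sample(2:60, 1), replace = TRUE)
    expect_equal(median_iqr(x), oracle_quartiles(x))
  }
})

test_that("baseline blocks are internally consistent", {
  b <- summarize_baseline(fixture_cohort())
  for (g in names(b)) {
    blk <- b[[g]]
    expect_equal(sum(blk$age_bands$n), blk$n_cases)
    expect_equal(sum(blk$sex$n), blk$n_cases)
    expect_equal(sum(blk$outcomes$n), blk$n_cases)
    expect_equal(sum(blk$received_years$n), blk$n_cases)
    # every percentage is the display-rounded count share
    for (block in list(blk$age_bands, blk$sex, blk$outcomes)) {
      expect_equal(block$pct, round_half_up(100 * block$n / blk$n_cases, 2))
    }
    expect_lte(nrow(blk$countries), 5)
    expect_lte(nrow(blk$indications), 5)
  }
})

test_that("receipt-year bins span the window with a quarter-labelled partial bin", {
  b <- summarize_baseline(fixture_cohort())
  expect_equal(b$DOXYCYCLINE$received_years$period,
               c("2005-2007", "2008-2010", "2011-2013", "2014-2016",
                 "2017-2019", "2020-2022", "2023 (Q1-Q3)"))
  expect_equal(b$DOXYCYCLINE$received_years$n,
               c(39L, 45L, 52L, 152L, 177L, 250L, 67L))
  expect_equal(b$MINOCYCLINE$received_years$n,
               c(60L, 117L, 123L, 174L, 257L, 206L, 44L))
  expect_equal(b$TIGECYCLINE$received_years$n,
               c(2L, 8L, 6L, 12L, 42L, 58L, 12L))
})

test_that("fatal drill-down reports ineffectiveness share and top-3 lists", {
  co <- fixture_cohort()
  fd <- fatal_case_drilldown(co, "TIGECYCLINE")
  expect_equal(fd$n_fatal, 33L)
  expect_equal(fd$n_ineffectiveness, 27L)
  expect_equal(fd$pct_ineffectiveness, 81.82)
  expect_equal(fd$top_countries$level, c("CN", "GR", "GB"))
  expect_equal(fd$top_countries$n, c(13L, 7L, 4L))
  expect_equal(fd$top_indications$indication,
               c("mastoiditis", "sepsis", "pneumonia"))
  expect_equal(fd$top_indications$n, c(16L, 8L, 5L))
})

test_that("fatal drill-down edge cases: none fatal and all flagged", {
  co <- fixture_cohort()
  # synthetic mini-check through compute path: a drug with no DE outcome
  mini <- co
  mini$cases$outcome_codes <- rep(list("OT"), nrow(mini$cases))
  fd0 <- fatal_case_drilldown(mini, "DOXYCYCLINE")
  expect_equal(fd0$n_fatal, 0L)
  expect_match(fd0$note, "no fatal cases")
  # all fatal cases flagged -> 100%
  mini2 <- co
  keep <- mini2$case_targets$caseid[mini2$case_targets$drug == "TIGECYCLINE"]
  fatal <- mini2$cases$caseid[vapply(mini2$cases$outcome_codes,
                                     function(x) "DE" %in% x, logical(1))]
  fatal <- intersect(fatal, keep)
  extra <- tibble::tibble(caseid = fatal, pt = "drug ineffective")
  mini2$case_pts <- dplyr::distinct(dplyr::bind_rows(mini2$case_pts, extra))
  expect_equal(fatal_case_drilldown(mini2, "TIGECYCLINE")$pct_ineffectiveness, 100)
})

test_that("subgroup tables count combined-drug cases once, in their own row", {
  co <- fixture_cohort()
  sg <- subgroup_table(co, subgroup_presets()$suicidality)
  expect_equal(sg$n_total, 44L)
  counts <- setNames(sg$counts$n, sg$counts$row)
  expect_equal(unname(counts["DOXYCYCLINE"]), 35L)
  expect_equal(unname(counts["MINOCYCLINE"]), 8L)
  expect_equal(unname(counts["DOXYCYCLINE + MINOCYCLINE"]), 1L)
  # single-drug rows plus combined rows equal the subgroup total
  expect_equal(sum(sg$counts$n), sg$n_total)
  # a case with several index PTs counts once
  thyroid <- subgroup_table(co, subgroup_presets()$thyroid)
  expect_equal(thyroid$n_total, 77L)
  # empty subgroup
  empty <- subgroup_table(co, subgroup_spec("none", "jarisch-herxheimer reaction"))
  expect_equal(empty$n_total, 0L)
  expect_match(empty$note, "no cases")
})

test_that("subgroup onset medians use day-precision therapy gaps", {
  co <- fixture_cohort()
  iih <- subgroup_table(co, subgroup_presets()$iih_icp)
  on <- iih$onset
  expect_equal(on$median[on$drug == "DOXYCYCLINE"], 151)
  expect_equal(unname(unlist(on[on$drug == "MINOCYCLINE", c("median", "q1", "q3")])),
               c(31, 16, 122))
  dress <- subgroup_table(co, subgroup_presets()$dress)
  expect_equal(unname(unlist(dress$onset[dress$onset$drug == "MINOCYCLINE",
                                         c("median", "q1", "q3")])),
               c(36, 20, 49))
  sui <- subgroup_table(co, subgroup_presets()$suicidality)
  expect_equal(unname(unlist(sui$onset[sui$onset$drug == "MINOCYCLINE",
                                       c("median", "q1", "q3")])),
               c(9, 7.5, 12))
})

test_that("co-occurrence share is 100 exactly when the co-PT never occurs alone", {
  co <- fixture_cohort()
  prof <- cooccurrence_profile(
    co, "MINOCYCLINE", "drug reaction with eosinophilia and systemic symptoms")
  expect_true(all(diff(prof$n_co) <= 0))
  mods <- prof[prof$co_pt == "multiple organ dysfunction syndrome", ]
  expect_equal(mods$n_co, 34L)
  expect_equal(mods$pct, 100)
  expect_equal(mods$n_co, mods$n_total_pt)
  t1dm <- prof[prof$co_pt == "type 1 diabetes mellitus", ]
  expect_equal(c(t1dm$n_co, t1dm$n_total_pt, t1dm$pct), c(23, 24, 95.83))
  # PTs never co-occurring with the index PT are absent
  expect_false("suicidal ideation" %in% prof$co_pt)
  expect_true(all(prof$n_co <= prof$n_total_pt))
  expect_error(cooccurrence_profile(co, "TIGECYCLINE", "headache"),
               "does not occur")
})

test_that("under-8 analysis filters age before computing the staining signal", {
  co <- fixture_cohort()
  u8 <- under8_analysis(co)
  counts <- setNames(u8$counts$n_cases, u8$counts$drug)
  expect_equal(unname(counts["DOXYCYCLINE"]), 103L)
  expect_equal(unname(counts["MINOCYCLINE"]), 15L)
  expect_equal(unname(counts["TIGECYCLINE"]), 71L)
  sig <- u8$signals
  expect_equal(sig$drug, "DOXYCYCLINE")  # no staining rows for the others
  expect_equal(sig$n, 7L)
  expect_true(sig$significant)
  # cells partition the under-8 stratum only
  young <- co$background_cases$caseid[co$background_cases$age_years < 8]
  n_units <- sum(co$background_units$caseid %in% young)
  expect_equal(sig$a + sig$b + sig$c + sig$d, n_units)
})

test_that("the American staining spelling is folded into the MedDRA PT", {
  expect_equal(normalize_pt("Tooth Discoloration"), "tooth discolouration")
  expect_equal(normalize_pt("oesophagitis"), "oesophagitis")
  expect_equal(normalize_pt("esophagitis"), "oesophagitis")
})
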