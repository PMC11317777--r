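test_that("contingency cells partition a toy background exactly", {
  units <- tibble::tibble(caseid = c("1", "1", "2", "2"),
                          pt = c("ptQ", "ptR", "ptQ", "ptR"))
  targets <- tibble::tibble(caseid = c("1", "2"),
                            drug = c("drugX", "drugY"))
  tab <- build_contingency(units, targets, "drugX", "ptQ")
  expect_equal(tab, c(a = 1L, b = 1L, c = 1L, d = 1L))
  expect_equal(sum(tab), nrow(units))
  # PT reported only for the target drug: comparator cell is zero
  tab2 <- build_contingency(units, targets, "drugX", "ptZ")
  expect_equal(unname(tab2[c("a", "c")]), c(0L, 0L))
})

test_that("contingency matches exhaustive enumeration and conserves units", {
  gen <- generate_database(synthetic_config(seed = 31, n_cases = 300))
  db <- gen$db
  db$demo <- deduplicate_reports(db$demo)
  co <- build_cohort(db)
  units <- co$background_units
  targets <- co$case_targets
  for (g in c("DOXYCYCLINE", "MINOCYCLINE")) {
    for (pt in c("vomiting", "headache", "oesophagitis")) {
      tab <- build_contingency(units, targets, g, pt)
      expect_equal(tab, oracle_2x2(units, targets$caseid[targets$drug == g], pt))
      expect_equal(sum(tab), nrow(units))
    }
  }
  # every screened pair conserves the unit total
  sig <- suppressWarnings(detect_signals(co))
  expect_true(all(sig$a + sig$b + sig$c + sig$d == nrow(units)))
  expect_true(all(sig$a >= 1))
})

test_that("ROR equals the cross-product ratio for all-positive cells", {
  set.seed(77)
  for (i in 1:50) {
    cells <- sample(1:500, 4, replace = TRUE)
    r <- compute_ror(cells[1], cells[2], cells[3], cells[4])
    oracle <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    expect_equal(r$ror, oracle, tolerance = 1e-12)
    expect_true(r$ci_low <= r$ror && r$ror <= r$ci_high)
  }
})

test_that("a balanced table gives ROR 1 with a log-symmetric interval", {
  r <- compute_ror(5, 5, 5, 5)
  expect_equal(r$ror, 1)
  expect_equal(log(r$ci_low), -log(r$ci_high))
})

test_that("degenerate cells follow the stated conventions", {
  r0 <- compute_ror(0, 50, 7, 5000)
  expect_equal(r0$ror, 0)
  expect_true(is.na(r0$ci_low))
  expect_false(r0$significant)

  rInf <- compute_ror(c(5, 3), c(0, 3), c(5, 0), c(5, 9))
  expect_true(all(is.infinite(rInf$ror)))
  expect_true(all(is.na(rInf$ci_low)))

  # Haldane correction produces finite estimates and intervals
  rh <- compute_ror(3, 3, 0, 9, signal_criteria(haldane = TRUE))
  expect_true(is.finite(rh$ror))
  expect_true(is.finite(rh$ci_low))
})

test_that("significance requires both the report-count and CI-bound criteria", {
  # n = 2 with a CI excluding 1 still fails the count rule
  r2 <- compute_ror(2, 38, 4, 5000)
  expect_gt(r2$ci_low, 1)
  expect_false(r2$significant)
  # n >= 3 with ci_low > 1 passes
  r3 <- compute_ror(10, 90, 100, 9900)
  expect_true(r3$significant)
  # ci_low below 1 fails regardless of n
  r4 <- compute_ror(5, 95, 50, 950)
  expect_lt(r4$ci_low, 1)
  expect_false(r4$significant)
  # thresholds are configurable
  expect_true(compute_ror(2, 38, 4, 5000,
                          signal_criteria(min_reports = 2))$significant)
})

test_that("ROR increases strictly in the interest cell", {
  a <- 1:30
  r <- compute_ror(a, 100, 50, 5000)
  expect_true(all(diff(r$ror) > 0))
})

test_that("signal results are sorted and flag stop-listed PTs without dropping them", {
  co <- fixture_cohort()
  sig <- suppressWarnings(detect_signals(co))
  expect_true("drug ineffective" %in% sig$pt[sig$drug == "TIGECYCLINE"])
  expect_true(all(sig$stoplisted[sig$pt == "drug ineffective"]))
  # within drug: significant block first, then n descending
  for (g in unique(sig$drug)) {
    s <- sig[sig$drug == g, ]
    expect_true(all(diff(as.integer(!s$significant)) >= 0))
    sTrue <- s[s$significant, ]
    expect_true(all(diff(sTrue$n) <= 0))
  }
})

test_that("top-k tables truncate, tie-break by ROR, and exclude stop-listed PTs", {
  sig <- tibble::tibble(
    drug = "D",
    soc = "S",
    pt = sprintf("pt%02d", 1:25),
    a = 25:1, b = 100, c = 10, d = 1000,
    n = 25:1,
    ror = seq(2, 26, length.out = 25),
    ci_low = 1.5, ci_high = 30,
    significant = TRUE, stoplisted = FALSE)
  sig$n[1:2] <- 30
  sig$ror[1] <- 3; sig$ror[2] <- 5
  sig$stoplisted[3] <- TRUE
  top <- top_k_signals(sig, "D", k = 20)
  expect_equal(nrow(top), 20)
  expect_false("pt03" %in% top$pt)          # stop-listed despite high n
  expect_equal(top$pt[1:2], c("pt02", "pt01"))  # equal n -> larger ROR first
  # fewer than k significant rows: return all, no padding
  expect_equal(nrow(top_k_signals(sig[1:4, ], "D", k = 20)), 3)
})

test_that("SOC summary keeps only organ classes with a significant PT somewhere", {
  co <- fixture_cohort()
  sig <- suppressWarnings(detect_signals(co))
  soc <- soc_summary(sig, co)
  expect_true(all(soc$soc %in% sig$soc[sig$significant]))
  # counts are drug-event units of the drug in that SOC
  gi <- soc[soc$soc == "Gastrointestinal disorders" & soc$drug == "DOXYCYCLINE", ]
  units <- dplyr::inner_join(co$background_units, co$case_targets,
                             by = "caseid", relationship = "many-to-many")
  map <- read_pt_soc_map()
  units$soc <- map$soc[match(units$pt, map$pt)]
  manual <- sum(units$drug == "DOXYCYCLINE" &
                  units$soc %in% "Gastrointestinal disorders")
  expect_equal(gi$n, manual)
})

test_that("signal table carries side-by-side columns for every drug", {
  co <- fixture_cohort()
  sig <- suppressWarnings(detect_signals(co))
  top <- top_k_signals(sig, "MINOCYCLINE", k = 5)
  expect_true(all(c("n_MINOCYCLINE", "ror_MINOCYCLINE") %in% names(top)))
  dress <- "drug reaction with eosinophilia and systemic symptoms"
  if (dress %in% top$pt) {
    row <- top[top$pt == dress, ]
    expect_equal(row$n_MINOCYCLINE, 136)
    expect_equal(row$n_DOXYCYCLINE, 13)
    expect_equal(row$n_TIGECYCLINE, 1)
  }
})
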