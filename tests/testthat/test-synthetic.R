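test_that("identical configurations yield byte-identical databases", {
  cfg <- synthetic_config(seed = 13, n_cases = 200)
  g1 <- generate_database(cfg)
  g2 <- generate_database(cfg)
  expect_identical(g1, g2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_faers_db(g1$db, d1)
  write_faers_db(g2$db, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # a different seed changes the data
  g3 <- generate_database(synthetic_config(seed = 14, n_cases = 200))
  expect_false(identical(g1$db$demo, g3$db$demo))
})

test_that("generated databases have full referential integrity", {
  for (s in c(1, 8, 23)) {
    v <- validate_faers_db(generate_database(
      synthetic_config(seed = s, n_cases = 150))$db)
    expect_true(v$ok)
    expect_equal(sum(v$orphans), 0L)
    expect_equal(v$ther_unlinked_drug_seq, 0L)
  }
})

test_that("duplicate clusters share a caseid with non-decreasing receipt dates", {
  gen <- generate_database(synthetic_config(seed = 4, n_cases = 400,
                                            duplicate_rate = 0.4))
  demo <- gen$db$demo
  clusters <- split(seq_len(nrow(demo)), demo$caseid)
  multi <- clusters[lengths(clusters) > 1]
  expect_gt(length(multi), 50)
  for (idx in multi[1:30]) {
    d <- demo[idx, ]
    ord <- order(as.numeric(d$primaryid))
    expect_true(all(diff(d$fda_dt[ord]) >= 0))
    expect_equal(length(unique(d$primaryid)), nrow(d))
  }
})

test_that("deduplication recovers the ledger's planted survivors", {
  gen <- generate_database(synthetic_config(seed = 6, n_cases = 500,
                                            duplicate_rate = 0.3))
  demo <- deduplicate_reports(gen$db$demo)
  led <- gen$ledger$duplicates
  expect_equal(demo$primaryid[match(led$caseid, demo$caseid)],
               led$survivor_primaryid)
  # and matches the brute-force argmax
  expect_equal(demo$primaryid, oracle_dedup(gen$db$demo)$primaryid)
})

test_that("with no duplicates, deduplication is the identity", {
  gen <- generate_database(synthetic_config(seed = 3, n_cases = 250,
                                            duplicate_rate = 0))
  expect_identical(deduplicate_reports(gen$db$demo), gen$db$demo)
  expect_true(all(gen$ledger$duplicates$n_versions == 1))
})

test_that("injected signals use odds inversion with a closed-form hit probability", {
  vocab <- tibble::tibble(pt = c("target pt", "filler a", "filler b"),
                          freq = c(0.01, 0.3, 0.3))
  inj <- data.frame(drug = "DOXYCYCLINE", pt = "target pt", odds_ratio = 10)
  cfg <- synthetic_config(seed = 1, n_cases = 1000,
                          drug_mix = c(DOXYCYCLINE = 1),
                          pt_vocabulary = vocab, injected_signals = inj,
                          duplicate_rate = 0, dual_target_rate = 0,
                          concomitant_rate = 0)
  # pi1 solves pi1/(1-pi1) = 10 * 0.01/0.99
  expect_equal(cfg$injected_signals$pi1, (10 * 0.01 / 0.99) / (1 + 10 * 0.01 / 0.99),
               tolerance = 1e-12)
  expect_equal(cfg$injected_signals$pi1, 0.0917, tolerance = 1e-3)
  # simulated mean count of target-PT cases approximates n * pi1 (about 92)
  hits <- vapply(1:6, function(s) {
    cfg_s <- synthetic_config(seed = s, n_cases = 1000,
                              drug_mix = c(DOXYCYCLINE = 1),
                              pt_vocabulary = vocab, injected_signals = inj,
                              duplicate_rate = 0, dual_target_rate = 0,
                              concomitant_rate = 0)
    g <- generate_database(cfg_s)
    length(unique(g$db$reac$primaryid[g$db$reac$pt == "target pt"]))
  }, numeric(1))
  expect_equal(mean(hits), 1000 * cfg$injected_signals$pi1, tolerance = 0.15)
})

test_that("invalid signal configurations fail with informative errors", {
  vocab <- tibble::tibble(pt = "a", freq = 0.1)
  expect_error(synthetic_config(
    pt_vocabulary = vocab,
    injected_signals = data.frame(drug = "X", pt = "missing", odds_ratio = 2)),
    "not in the vocabulary")
  expect_error(synthetic_config(
    pt_vocabulary = vocab,
    injected_signals = data.frame(drug = "X", pt = "a", odds_ratio = -1)),
    "must be > 0")
  expect_error(synthetic_config(n_cases = 0), "n_cases")
})

test_that("the reference fixture regenerates byte-identically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_reference_fixture(dir = d1)
  make_reference_fixture(dir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  v <- validate_faers_db(make_reference_fixture())
  expect_true(v$ok)
  expect_equal(sum(v$orphans), 0L)
})
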