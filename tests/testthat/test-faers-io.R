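test_that("DEMO lines parse into typed report fields", {
  path <- write_faers_lines(c(
    "primaryid$caseid$fda_dt$event_dt$rept_dt$age$age_cod$sex$occr_country",
    "100$1$20200315$20200301$20200320$14$YR$F$US",
    "101$2$20200316$202003$$$$M$",
    "102$3$20200317$$$5$YR$$GB"))
  demo <- read_faers_table(path, "DEMO")
  expect_equal(nrow(demo), 3)
  r <- demo[1, ]
  expect_equal(r$primaryid, "100")
  expect_equal(r$caseid, "1")
  expect_equal(r$fda_dt, 20200315L)
  expect_equal(r$event_dt, 20200301L)
  expect_equal(r$event_dt_prec, "day")
  expect_equal(r$age, 14)
  expect_equal(r$age_cod, "YR")
  expect_equal(r$sex, "F")
  expect_equal(r$occr_country, "US")
  # partial event date keeps month precision; empty fields are missing
  expect_equal(demo$event_dt[2], 202003L)
  expect_equal(demo$event_dt_prec[2], "month")
  expect_true(is.na(demo$age[2]))
  expect_true(is.na(demo$sex[3]))
  # missing age does not drop the record
  expect_equal(attr(demo, "n_skipped"), 0L)
})

test_that("header matching is case-insensitive and extra columns survive", {
  path <- write_faers_lines(c(
    "PRIMARYID$CASEID$FDA_DT$EVENT_DT$REPT_DT$AGE$AGE_COD$SEX$OCCR_COUNTRY$I_F_COD",
    "100$1$20200315$$$14$YR$F$US$I"))
  demo <- read_faers_table(path, "DEMO")
  expect_equal(demo$primaryid, "100")
  expect_equal(demo$i_f_cod, "I")
})

test_that("malformed dates are skipped and line counts reconcile", {
  path <- write_faers_lines(c(
    "primaryid$caseid$fda_dt$event_dt$rept_dt$age$age_cod$sex$occr_country",
    "100$1$20200315$$$14$YR$F$US",
    "101$2$20201315$$$14$YR$F$US",   # month 13 in fda_dt
    "102$3$20200230$$$14$YR$F$US",   # Feb 30
    "103$4$202003$$$14$YR$F$US",     # fda_dt must be full precision
    "104$5$20200316$20209901$$14$YR$F$US")) # bad event month
  demo <- read_faers_table(path, "DEMO")
  expect_equal(nrow(demo), 1)
  expect_equal(attr(demo, "n_lines"), 5L)
  expect_equal(attr(demo, "n_skipped"), 4L)
  expect_equal(nrow(demo) + attr(demo, "n_skipped"), attr(demo, "n_lines"))
  expect_equal(sort(attr(demo, "problems")$line), 3:6)
})

test_that("missing required columns and unknown kinds are usage errors", {
  path <- write_faers_lines(c("primaryid$caseid", "1$1"))
  expect_error(read_faers_table(path, "DEMO"), "missing required column")
  expect_error(read_faers_table(path, "BOGUS"), "unknown table kind")
  expect_error(read_faers_table(file.path(tempdir(), "nope.txt"), "DEMO"),
               "not found")
})

test_that("OUTC rows merge into order-independent outcome sets", {
  path <- write_faers_lines(c("primaryid$outc_cod",
                              "100$HO", "100$DE", "101$OT", "100$HO"))
  outc <- read_faers_table(path, "OUTC")
  sets <- outcome_sets(outc)
  expect_equal(sets$outcome_codes[[which(sets$primaryid == "100")]],
               c("DE", "HO"))
  # shuffled input yields identical sets
  shuffled <- outc[c(3, 1, 2), ]
  expect_equal(outcome_sets(shuffled), sets)
  # unknown outcome codes are skipped, not kept
  bad <- write_faers_lines(c("primaryid$outc_cod", "100$XX", "100$DE"))
  outc2 <- read_faers_table(bad, "OUTC")
  expect_equal(outc2$outc_cod, "DE")
  expect_equal(attr(outc2, "n_skipped"), 1L)
})

test_that("write/read round-trips are field-identical for all six tables", {
  gen <- generate_database(synthetic_config(seed = 5, n_cases = 150))
  dir <- withr::local_tempdir()
  write_faers_db(gen$db, dir)
  back <- load_faers_db(dir)
  for (t in names(gen$db)) {
    got <- back[[t]]
    attributes(got)[c("n_lines", "n_skipped", "problems")] <- NULL
    expect_equal(as.data.frame(got), as.data.frame(gen$db[[t]]))
  }
})

test_that("an empty table writes a header-only file that reads back empty", {
  dir <- withr::local_tempdir()
  empty <- tibble::tibble(primaryid = character(), pt = character())
  p <- file.path(dir, "REAC.txt")
  write_faers_table(empty, p, "REAC")
  expect_equal(length(readLines(p)), 1L)
  back <- read_faers_table(p, "REAC")
  expect_equal(nrow(back), 0)
})

test_that("reports without outcomes produce no OUTC rows", {
  gen <- generate_database(synthetic_config(seed = 9, n_cases = 100))
  with_out <- unique(gen$db$outc$primaryid)
  expect_lt(length(with_out), nrow(gen$db$demo))
  sets <- outcome_sets(gen$db$outc)
  expect_true(all(lengths(sets$outcome_codes) >= 1))
})

test_that("validation counts orphans and duplicate primaryids", {
  gen <- generate_database(synthetic_config(seed = 2, n_cases = 60))
  db <- gen$db
  expect_true(validate_faers_db(db)$ok)
  expect_equal(sum(validate_faers_db(db)$orphans), 0L)

  db$reac <- dplyr::bind_rows(db$reac,
                              tibble::tibble(primaryid = "999999999", pt = "nausea"))
  v <- validate_faers_db(db)
  expect_equal(unname(v$orphans["reac"]), 1L)

  db$demo <- dplyr::bind_rows(db$demo, db$demo[1, ])
  v2 <- validate_faers_db(db)
  expect_equal(v2$n_duplicate_primaryid, 1L)
  expect_false(v2$ok)
})

test_that("partial date parser classifies precision and rejects impossible dates", {
  p <- parse_partial_date(c("2020", "202006", "20200615", "20201301",
                            "20200230", "notadate", "", NA))
  expect_equal(p$prec,
               c("year", "month", "day", "invalid", "invalid", "invalid", NA, NA))
  expect_equal(p$value[1:3], c(2020L, 202006L, 20200615L))
  expect_true(all(is.na(p$value[4:8])))
})
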