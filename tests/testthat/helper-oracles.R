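# Independent oracles and small builders shared across the suite.

# brute-force deduplication: per case, scan every report and keep the
# argmax of (fda_dt, numeric primaryid)
oracle_dedup <- function(demo) {
  keep <- vapply(split(seq_len(nrow(demo)), demo$caseid), function(idx) {
    best <- idx[1]
    for (i in idx[-1]) {
      if (demo$fda_dt[i] > demo$fda_dt[best] ||
          (demo$fda_dt[i] == demo$fda_dt[best] &&
           as.numeric(demo$primaryid[i]) > as.numeric(demo$primaryid[best]))) {
        best <- i
      }
    }
    best
  }, integer(1))
  out <- demo[unname(keep), , drop = FALSE]
  out[order(out$caseid), , drop = FALSE]
}

# hand-rolled inclusive linear interpolation between order statistics
oracle_quartiles <- function(x) {
  s <- sort(x[!is.na(x)])
  n <- length(s)
  qq <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  c(median = qq(0.5), q1 = qq(0.25), q3 = qq(0.75))
}

# exhaustive 2x2 cell enumeration over unit rows
oracle_2x2 <- function(units, target_cases, pt) {
  a <- b <- cc <- d <- 0L
  for (i in seq_len(nrow(units))) {
    tgt <- units$caseid[i] %in% target_cases
    hit <- units$pt[i] == pt
    if (tgt && hit) a <- a + 1L
    else if (tgt) b <- b + 1L
    else if (hit) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# minimal DEMO builder
tiny_demo <- function(primaryid, caseid, fda_dt) {
  tibble::tibble(primaryid = as.character(primaryid),
                 caseid = as.character(caseid),
                 fda_dt = as.integer(fda_dt),
                 event_dt = NA_integer_, event_dt_prec = NA_character_,
                 rept_dt = NA_integer_, age = 10, age_cod = "YR",
                 sex = "F", occr_country = "US")
}

write_faers_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# deduplicated cohort from the reference fixture, built once per test run
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      db <- make_reference_fixture()
      db$demo <- deduplicate_reports(db$demo)
      cache <<- build_cohort(db)
    }
    cache
  }
})

# identity dictionary for synthetic drug names
identity_dictionary <- function(drugs) {
  tibble::tibble(canonical = drugs, synonym = drugs)
}
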