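# Deterministic reference fixture. A fully constructed (RNG-free) database
# whose cohort reproduces, after deduplication, a set of published-style
# count identities: per-drug case totals, sex splits, age bands and
# quartiles, most-severe-outcome distributions, receipt-year bins, top
# indications, subgroup counts with combined-drug rows, co-occurrence
# percentages, and an under-8 dental-staining association. Regeneration is
# byte-identical by construction.

# expand one single-suspect-drug block of cases into the six tables
.fx_block <- function(caseid, fda_dt, age, age_cod, sex, country,
                      drugname, role, pts, outcomes, indication, onset) {
  n <- length(caseid)
  stopifnot(length(fda_dt) == n, length(age) == n, length(pts) == n,
            length(outcomes) == n, length(indication) == n,
            length(onset) == n)
  primaryid <- paste0(caseid, "1")
  has_onset <- !is.na(onset)
  event_dt <- ifelse(has_onset, fda_dt, NA_integer_)
  event_prec <- ifelse(has_onset, "day", NA_character_)

  demo <- tibble::tibble(
    primaryid = primaryid, caseid = caseid, fda_dt = as.integer(fda_dt),
    event_dt = as.integer(event_dt), event_dt_prec = event_prec,
    rept_dt = as.integer(fda_dt), age = as.numeric(age), age_cod = age_cod,
    sex = sex, occr_country = country)
  drug <- tibble::tibble(primaryid = primaryid, drug_seq = 1L,
                         role_cod = role, drugname = drugname)
  reac <- tibble::tibble(primaryid = rep(primaryid, lengths(pts)),
                         pt = unlist(pts))
  n_out <- lengths(outcomes)
  outc <- tibble::tibble(primaryid = rep(primaryid, n_out),
                         outc_cod = unlist(outcomes))
  has_ind <- !is.na(indication)
  indi <- tibble::tibble(primaryid = primaryid[has_ind],
                         indi_drug_seq = 1L, indi_pt = indication[has_ind])
  start_dt <- as.integer(format(faers_date(fda_dt[has_onset]) - onset[has_onset],
                                "%Y%m%d"))
  ther <- tibble::tibble(primaryid = primaryid[has_onset], dsg_drug_seq = 1L,
                         start_dt = start_dt,
                         start_dt_prec = rep("day", sum(has_onset)))
  list(demo = demo, drug = drug, reac = reac, outc = outc, indi = indi,
       ther = ther)
}

# receipt dates filling 3-year bins with given per-bin counts
.fx_dates <- function(bin_counts,
                      bin_starts = c(2005, 2008, 2011, 2014, 2017, 2020, 2023)) {
  unlist(lapply(seq_along(bin_counts), function(b) {
    k <- bin_counts[b]
    if (k == 0) return(integer(0))
    j <- seq_len(k) - 1L
    yr <- bin_starts[b] + if (bin_starts[b] == 2023) 0L else j %% 3L
    mo <- (j %% 9L) + 1L
    as.integer(yr * 10000L + mo * 100L + 15L)
  }))
}

.fx_fill <- function(n, assignments, default = NA_character_) {
  out <- rep(default, n)
  for (k in seq_along(assignments)) out[assignments[[k]]] <- names(assignments)[k]
  out
}

.fx_outcomes <- function(n, assignments) {
  # assignments: named list label -> indices; labels are the most severe
  # code; sets include extra codes to exercise most-severe selection
  sets <- list(DE = c("HO", "DE"), LT = c("LT", "OT"), HO = "HO",
               DS = c("DS", "OT"), RI = "RI", OT = "OT",
               Unknown = character(0))
  out <- rep(list(character(0)), n)
  for (lab in names(assignments)) {
    out[assignments[[lab]]] <- list(sets[[lab]])
  }
  out
}

.fx_doxy <- function() {
  n <- 781L
  caseid <- as.character(1000000L + seq_len(n))
  age <- c(2, 3, 4, 4, 5, 6, 7, rep(5, 96), rep(10, 92), rep(12, 2),
           rep(13, 193), rep(15, 195), rep(16, 196))
  age_cod <- rep("YR", n)
  # represent two toddler ages in months to exercise unit conversion
  age[1] <- 24; age_cod[1] <- "MON"
  age[3] <- 48; age_cod[3] <- "MON"

  sex <- .fx_fill(n, list(F = c(1:5, 8:411), M = c(6:7, 412:770)))
  country <- .fx_fill(n, list(US = 1:410, GB = 411:492, CA = 493:547,
                              CN = 548, NL = 549:550, FR = 551:630,
                              DE = 631:710, AU = 711:781))
  outcomes <- .fx_outcomes(n, list(Unknown = c(1:100, 739:781), DE = 101:121,
                                   LT = 122:178, HO = 179:415, DS = 416:429,
                                   RI = 430:431, OT = 432:738))
  fda_dt <- .fx_dates(c(39, 45, 52, 152, 177, 249, 67))
  indication <- .fx_fill(n, list(
    "acne" = 1:281, "lyme disease" = 282:319, "acne conglobata" = 320:345,
    "relapsing fever" = 346:360, "sclerotherapy" = 361:373))

  generic <- c("vomiting", "nausea", "headache", "pyrexia", "fatigue",
               "rash", "diarrhoea", "abdominal pain upper")
  pts <- lapply(seq_len(n), function(i) generic[(i - 1L) %% 8L + 1L])
  for (i in 1:7) pts[[i]] <- c("tooth discoloration", "vomiting")
  for (i in 8:21) pts[[i]] <- "idiopathic intracranial hypertension"
  for (i in 22:35) pts[[i]] <- "intracranial pressure increased"
  for (i in 8:14) pts[[i]] <- c(pts[[i]], "headache")
  for (i in 36:55) pts[[i]] <- "suicidal ideation"
  for (i in 56:70) pts[[i]] <- "suicide attempt"
  for (i in 71:83) pts[[i]] <- "hyperthyroidism"
  pts[[84]] <- "hypothyroidism"
  for (i in 85:97) pts[[i]] <- "drug reaction with eosinophilia and systemic symptoms"

  onset <- rep(NA_real_, n)
  onset[8:35] <- c(rep(50, 6), rep(72, 2), rep(100, 5), rep(151, 2),
                   rep(170, 5), rep(196, 2), rep(300, 6))

  drugname <- c("DOXYCYCLINE HYCLATE", "Vibramycin", "doxycycline",
                "DORYX")[(seq_len(n) - 1L) %% 4L + 1L]
  role <- ifelse(seq_len(n) %% 5L == 0L, "SS", "PS")

  blk <- .fx_block(caseid, fda_dt, age, age_cod, sex, country, drugname,
                   role, pts, outcomes, indication, onset)
  # therapy-date edge cases: case 99 start after event (negative onset ->
  # missing); case 100 month-precision event date (-> missing onset)
  p99 <- paste0(caseid[99], "1"); p100 <- paste0(caseid[100], "1")
  blk$demo$event_dt[99] <- fda_dt[99]; blk$demo$event_dt_prec[99] <- "day"
  blk$demo$event_dt[100] <- fda_dt[100] %/% 100L
  blk$demo$event_dt_prec[100] <- "month"
  extra_ther <- tibble::tibble(
    primaryid = c(p99, p100), dsg_drug_seq = 1L,
    start_dt = c(as.integer(format(faers_date(fda_dt[99]) + 50, "%Y%m%d")),
                 as.integer(format(faers_date(fda_dt[100]) - 60, "%Y%m%d"))),
    start_dt_prec = "day")
  blk$ther <- dplyr::bind_rows(blk$ther, extra_ther)
  blk
}

.fx_mino <- function() {
  n <- 980L
  caseid <- as.character(2000000L + seq_len(n))
  age <- c(rep(5, 15), rep(13, 230), rep(14, 245), rep(16, 244), rep(17, 246))
  age_cod <- rep("YR", n)
  sex <- .fx_fill(n, list(F = 1:567, M = 568:965))
  country <- .fx_fill(n, list(US = 1:698, GB = 699:739, CA = 740:790,
                              CN = 791:792, FR = 793:852, DE = 853:912,
                              JP = 913:980))
  outcomes <- .fx_outcomes(n, list(
    DE = c(1:42, 301:336), LT = c(43:56, 577:622), HO = c(57:106, 337:576),
    OT = c(107:300, 650:864), DS = 623:637, RI = 638:649,
    Unknown = 865:980))
  fda_dt <- .fx_dates(c(60, 117, 123, 174, 257, 205, 44))
  indication <- .fx_fill(n, list(
    "acne" = 1:691, "confluent and reticulate papillomatosis" = 692:703,
    "folliculitis" = 704:714,
    "infective pulmonary exacerbation of cystic fibrosis" = 715:722,
    "mycobacterium abscessus infection" = 723:729))

  generic <- c("nausea", "headache", "pyrexia", "fatigue", "urticaria",
               "arthralgia", "dizziness", "rash")
  pts <- lapply(seq_len(n), function(i) generic[(i - 1L) %% 8L + 1L])
  dress <- "drug reaction with eosinophilia and systemic symptoms"
  for (i in 1:136) pts[[i]] <- dress
  for (i in 1:34) pts[[i]] <- c(pts[[i]], "multiple organ dysfunction syndrome")
  for (i in 35:57) pts[[i]] <- c(pts[[i]], "type 1 diabetes mellitus")
  for (i in 58:78) pts[[i]] <- c(pts[[i]], "autoimmune thyroiditis")
  for (i in 79:96) pts[[i]] <- c(pts[[i]], "acute kidney injury")
  for (i in 97:112) pts[[i]] <- c(pts[[i]], "erythema multiforme")
  for (i in 137:181) pts[[i]] <- "idiopathic intracranial hypertension"
  for (i in 182:225) pts[[i]] <- "intracranial pressure increased"
  for (i in 137:168) pts[[i]] <- c(pts[[i]], "headache")
  for (i in 226:229) pts[[i]] <- "suicidal ideation"
  for (i in 230:233) pts[[i]] <- "suicide attempt"
  for (i in 234:282) pts[[i]] <- "hyperthyroidism"
  for (i in 283:287) pts[[i]] <- "hypothyroidism"
  for (i in 288:296) pts[[i]] <- c("hyperthyroidism", "hypothyroidism")
  pts[[297]] <- c("type 1 diabetes mellitus", "nausea")
  for (i in 298:300) pts[[i]] <- c("autoimmune thyroiditis", "rash")
  for (i in 301:304) pts[[i]] <- c(pts[[i]], "acute kidney injury")

  onset <- rep(NA_real_, n)
  onset[1:136] <- c(rep(15, 33), rep(20, 2), rep(30, 32), rep(36, 2),
                    rep(45, 32), rep(49, 2), rep(60, 33))
  onset[137:225] <- c(rep(10, 22), 16, rep(20, 21), 31, rep(60, 21), 122,
                      rep(150, 22))
  onset[226:233] <- c(5, 6, 8, 8, 10, 12, 12, 14)

  drugname <- c("MINOCYCLINE", "Minocin", "SOLODYN",
                "minocycline hydrochloride")[(seq_len(n) - 1L) %% 4L + 1L]
  role <- ifelse(seq_len(n) %% 6L == 0L, "SS", "PS")
  .fx_block(caseid, fda_dt, age, age_cod, sex, country, drugname, role,
            pts, outcomes, indication, onset)
}

.fx_tige <- function() {
  n <- 140L
  caseid <- as.character(2500000L + seq_len(n))
  age <- c(rep(3, 34), rep(5, 2), rep(6, 33), rep(7, 2), rep(12, 33),
           rep(14, 2), rep(16, 34))
  age_cod <- rep("YR", n)
  sex <- .fx_fill(n, list(M = 1:76, F = 77:138))
  country <- .fx_fill(n, list(
    CN = c(1:13, 34:47), GR = 14:20, GB = c(21:24, 89:93),
    NL = c(25:27, 48:67), US = c(28:30, 68:88), FR = c(31:33, 101:103),
    CA = 94:100, DE = 104:109, JP = 110:115, AU = 116:121, BR = 122:127,
    IN = 128:133, IT = 134:139, ES = 140))
  outcomes <- .fx_outcomes(n, list(DE = 1:33, LT = 34:48, HO = 49:80,
                                   OT = 81:105, Unknown = 106:140))
  fda_dt <- .fx_dates(c(2, 8, 6, 12, 42, 58, 12))
  indication <- .fx_fill(n, list(
    "sepsis" = c(1:8, 93:94), "pneumonia" = c(9:13, 95:98),
    "acinetobacter infection" = c(14:17, 99:100),
    "mastoiditis" = c(18:33, 72:92),
    "mycobacterium abscessus infection" = 34:71))

  generic <- c("vomiting", "nausea", "pancreatitis", "hepatotoxicity",
               "rash", "diarrhoea")
  pts <- lapply(seq_len(n), function(i) generic[(i - 1L) %% 6L + 1L])
  for (i in 1:20) pts[[i]] <- c("drug ineffective", "pyrexia")
  for (i in 21:24) pts[[i]] <- c("treatment failure", "vomiting")
  for (i in 25:27) pts[[i]] <- "drug resistance"
  for (i in 28:33) pts[[i]] <- "pyrexia"
  pts[[50]] <- c(pts[[50]], "drug reaction with eosinophilia and systemic symptoms")

  drugname <- c("TYGACIL", "TIGECYCLINE", "tigecycline")[(seq_len(n) - 1L) %% 3L + 1L]
  .fx_block(caseid, fda_dt, age, age_cod, sex, country, drugname,
            rep("PS", n), pts, outcomes, indication, rep(NA_real_, n))
}

.fx_background <- function() {
  n <- 1000L
  i <- seq_len(n)
  caseid <- as.character(4000000L + i)
  age <- ((i - 1L) %% 17L) + 1L
  drugs <- c("IBUPROFEN", "AMOXICILLIN", "AZITHROMYCIN", "PARACETAMOL",
             "CEFTRIAXONE", "VANCOMYCIN", "OSELTAMIVIR", "PREDNISONE")
  drugname <- drugs[(i - 1L) %% 8L + 1L]
  sex <- ifelse(i %% 2L == 0L, "F", "M")
  country <- c("US", "GB", "FR", "DE", "CA")[(i - 1L) %% 5L + 1L]
  yr <- 2006L + ((i - 1L) %% 17L)
  fda_dt <- yr * 10000L + (((i - 1L) %% 12L) + 1L) * 100L + 10L
  p1 <- c("vomiting", "nausea", "headache", "pyrexia", "fatigue", "rash",
          "diarrhoea", "urticaria", "dizziness", "arthralgia",
          "abdominal pain", "insomnia")
  p2 <- c("pruritus", "dyspnoea", "somnolence", "myalgia", "anxiety",
          "decreased appetite", "alopecia", "dermatitis", "anaemia",
          "depression", "weight decreased")
  pts <- lapply(i, function(k) {
    unique(c(p1[(k - 1L) %% 12L + 1L], p2[(k - 1L) %% 11L + 1L]))
  })
  # two under-8 comparator cases with dental staining so the under-8
  # contingency has a nonzero comparator cell
  pts[[18]] <- c(pts[[18]], "tooth discoloration")
  pts[[35]] <- c(pts[[35]], "tooth discoloration")
  out_cycle <- list("HO", "OT", character(0), c("LT", "OT"), "OT", character(0))
  outcomes <- out_cycle[((i - 1L) %% 6L) + 1L]
  .fx_block(caseid, fda_dt, age, rep("YR", n), sex, country, drugname,
            rep("PS", n), pts, outcomes, rep(NA_character_, n),
            rep(NA_real_, n))
}

# dual-suspect case appearing in both doxycycline's and minocycline's
# tallies and in the combined subgroup row
.fx_dual <- function() {
  blk <- .fx_block("3000001", 20210615L, 16, "YR", "M", "US",
                   "DOXYCYCLINE", "PS", list("suicidal ideation"),
                   list("OT"), NA_character_, NA_real_)
  blk$drug <- dplyr::bind_rows(
    blk$drug,
    tibble::tibble(primaryid = "30000011", drug_seq = 2L, role_cod = "SS",
                   drugname = "Minocin"))
  blk
}

# reports excluded by the funnel: adult, out-of-window, concomitant-only,
# missing age
.fx_decoys <- function() {
  blk <- .fx_block(
    caseid = as.character(5000000L + 1:4),
    fda_dt = c(20210315L, 20040101L, 20210315L, 20210315L),
    age = c(19, 12, 10, NA), age_cod = c("YR", "YR", "YR", NA),
    sex = c("F", "F", "M", "F"), country = rep("US", 4),
    drugname = c("DOXYCYCLINE", "DOXYCYCLINE", "DOXYCYCLINE", "Vibramycin"),
    role = c("PS", "PS", "C", "PS"),
    pts = list("nausea", "nausea", "nausea", "nausea"),
    outcomes = list("OT", "OT", "OT", "OT"),
    indication = rep(NA_character_, 4), onset = rep(NA_real_, 4))
  blk
}

# planted duplicate clusters: earlier report versions with adult age and a
# disease-course PT; if deduplication failed, cohort counts and receipt-year
# bins would shift visibly
.fx_duplicates <- function(doxy, tige) {
  mk_old <- function(demo_row, tie) {
    old_fda <- if (tie) demo_row$fda_dt else
      as.integer(format(faers_date(demo_row$fda_dt) - 90, "%Y%m%d"))
    pid <- paste0(demo_row$caseid, "0")
    list(demo = tibble::tibble(
      primaryid = pid, caseid = demo_row$caseid, fda_dt = old_fda,
      event_dt = NA_integer_, event_dt_prec = NA_character_,
      rept_dt = old_fda, age = 45, age_cod = "YR", sex = "M",
      occr_country = "US"),
      drug = tibble::tibble(primaryid = pid, drug_seq = 1L, role_cod = "PS",
                            drugname = "DOXYCYCLINE"),
      reac = tibble::tibble(primaryid = pid, pt = "condition aggravated"),
      outc = tibble::tibble(primaryid = pid, outc_cod = "DE"))
  }
  rows <- c(lapply(200:204, function(i) mk_old(doxy$demo[i, ], tie = FALSE)),
            lapply(205:206, function(i) mk_old(doxy$demo[i, ], tie = TRUE)),
            list(mk_old(tige$demo[100, ], tie = FALSE)))
  list(demo = dplyr::bind_rows(lapply(rows, `[[`, "demo")),
       drug = dplyr::bind_rows(lapply(rows, `[[`, "drug")),
       reac = dplyr::bind_rows(lapply(rows, `[[`, "reac")),
       outc = dplyr::bind_rows(lapply(rows, `[[`, "outc")))
}

#' Deterministic reference database
#'
#' Builds, without any random number generation, a complete six-table
#' database whose deduplicated pediatric cohort hits a fixed set of count
#' identities used throughout the test-suite: 782/981/140 cases for the
#' three tetracyclines (one case suspect for both doxycycline and
#' minocycline), a 409/782 female share, 33/140 deaths with 27/33 fatal
#' cases carrying ineffectiveness PTs, a 136-case DRESS subgroup with
#' 42 deaths and co-occurrence shares of 100% and 95.83%, 7 under-8
#' dental-staining cases, published-style receipt-year bins, and planted
#' duplicate clusters (including receipt-date ties) whose earlier versions
#' carry adult ages and disease-course PTs.
#'
#' @param dir Optional directory; when given, the six tables are also
#'   written as "$"-delimited files via [write_faers_db()].
#' @return A `faers_db`.
#' @export
make_reference_fixture <- function(dir = NULL) {
  doxy <- .fx_doxy()
  mino <- .fx_mino()
  tige <- .fx_tige()
  bg <- .fx_background()
  dual <- .fx_dual()
  decoys <- .fx_decoys()
  dups <- .fx_duplicates(doxy, tige)

  bind_part <- function(part) {
    dplyr::bind_rows(doxy[[part]], mino[[part]], tige[[part]], bg[[part]],
                     dual[[part]], decoys[[part]], dups[[part]])
  }
  db <- structure(list(demo = bind_part("demo"), drug = bind_part("drug"),
                       reac = bind_part("reac"), outc = bind_part("outc"),
                       indi = bind_part("indi"), ther = bind_part("ther")),
                  class = "faers_db")
  if (!is.null(dir)) write_faers_db(db, dir)
  db
}
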