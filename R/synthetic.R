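# Synthetic FAERS-like database generator. Emulates the relational
# structure of spontaneous-report data - duplicate report versions sharing a
# case id, demographic fields with age-unit codes, multi-drug multi-PT
# reports, therapy dates with partial precision - with controlled
# statistical structure: background PT frequencies and injected drug-event
# associations at specified odds ratios.
#
# Signals are injected by odds inversion: for a planted (drug g, PT p,
# odds ratio w), cases on g receive p with probability pi1 such that
# pi1/(1-pi1) = w * pi0/(1-pi0), pi0 being the background frequency. The
# planted quantity is therefore the same estimand the reporting odds ratio
# estimates, making parameter recovery well-posed.

#' Default PT vocabulary for the generator
#'
#' A background reaction vocabulary drawn from the package PT-to-SOC map,
#' with frequencies scaled so the expected number of distinct PTs per case
#' is `mean_pts` (PTs are included independently per case). Includes
#' ineffectiveness/stop-list terms at realistic rates.
#'
#' @param mean_pts Target expected PTs per case (default 3.4, typical of
#'   spontaneous reports).
#' @return A tibble with columns `pt`, `freq`.
#' @export
default_pt_vocabulary <- function(mean_pts = 3.4) {
  base <- c(
    vomiting = 8, nausea = 7, headache = 7, pyrexia = 6, fatigue = 5,
    diarrhoea = 5, rash = 5, pruritus = 4, dizziness = 4, urticaria = 3,
    "abdominal pain" = 3, dyspnoea = 3, "drug ineffective" = 5,
    "condition aggravated" = 2, "off label use" = 3, depression = 2.5,
    insomnia = 2.5, anxiety = 2.5, "vision blurred" = 1.5, arthralgia = 2.5,
    myalgia = 2, "alanine aminotransferase increased" = 2,
    "aspartate aminotransferase increased" = 2, "weight decreased" = 2,
    "decreased appetite" = 2.5, somnolence = 2, seizure = 1, alopecia = 1.5,
    dermatitis = 1.5, hepatotoxicity = 0.8, thrombocytopenia = 1.2,
    neutropenia = 1.2, anaemia = 1.6, pancreatitis = 0.7, oesophagitis = 0.5,
    "oesophageal ulcer" = 0.3, "photosensitivity reaction" = 0.7,
    "idiopathic intracranial hypertension" = 0.3,
    "intracranial pressure increased" = 0.3, "suicidal ideation" = 0.9,
    "suicide attempt" = 0.7,
    "drug reaction with eosinophilia and systemic symptoms" = 0.5,
    hyperthyroidism = 0.35, hypothyroidism = 0.35, thyroiditis = 0.2,
    "tooth discolouration" = 0.3,
    "multiple organ dysfunction syndrome" = 0.5, "cardiac arrest" = 0.4,
    "acute kidney injury" = 0.7, hepatitis = 0.5)
  freq <- base / sum(base) * mean_pts
  tibble::tibble(pt = names(base), freq = pmin(unname(freq), 0.5))
}

#' Default drug mix for the generator
#'
#' Probabilities over the suspect drug of each case: the three tetracyclines
#' at shares echoing their report volumes, the rest spread over common
#' background drugs.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_drug_mix <- function() {
  mix <- c(DOXYCYCLINE = 0.12, MINOCYCLINE = 0.15, TIGECYCLINE = 0.02,
           IBUPROFEN = 0.11, AMOXICILLIN = 0.10, AZITHROMYCIN = 0.09,
           PARACETAMOL = 0.09, CEFTRIAXONE = 0.08, VANCOMYCIN = 0.07,
           OSELTAMIVIR = 0.07, PREDNISONE = 0.06, METHOTREXATE = 0.04)
  mix / sum(mix)
}

#' Configuration for the synthetic database generator
#'
#' Defaults emulate the pediatric tetracycline study conditions: receipt
#' window January 2005 to September 2023, pediatric-heavy age mixtures with
#' drug-specific medians (adolescent-heavy for doxycycline/minocycline,
#' young children for tigecycline), drug-specific sex ratios, about 3.4 PTs
#' per case, and a realistic share of duplicate report versions.
#'
#' @param seed Master RNG seed; one sub-stream per generation component is
#'   derived from it, so identical configs give byte-identical databases.
#' @param n_cases Number of distinct cases (before duplicate versions).
#' @param duplicate_rate Fraction of cases receiving extra report versions.
#' @param max_versions Maximum report versions per case (>= 2 when
#'   duplicates are enabled).
#' @param window Integer `c(start, end)` YYYYMMDD receipt-date range.
#' @param drug_mix Named probabilities over the suspect drug per case.
#' @param target_drugs Drugs treated as study targets (get synonym-varied
#'   verbatim names and injected signals).
#' @param dual_target_rate Probability a target-drug case carries a second
#'   target drug as co-suspect.
#' @param adult_rate Fraction of reports with adult (18-60y) patients.
#' @param age_centers Named vector of pediatric age medians per drug
#'   (years); drugs not named use `age_default`.
#' @param age_default,age_sd Center/spread for unnamed drugs and the
#'   pediatric normal spread.
#' @param missing_age_rate,missing_sex_rate Missingness rates.
#' @param sex_female Named per-drug probability that a report is female.
#' @param countries Named country weights.
#' @param pt_vocabulary Tibble `pt`, `freq` of background PT inclusion
#'   probabilities (independent per case).
#' @param injected_signals `NULL` or a tibble/data.frame with columns
#'   `drug`, `pt`, `odds_ratio` of associations to plant by odds inversion.
#' @param outcome_none_rate Probability a report has no outcome codes.
#' @param outcome_weights Named weights over outcome codes.
#' @param onset_meanlog,onset_sdlog Log-normal parameters of the
#'   therapy-to-event gap in days.
#' @param partial_date_rate Fraction of event dates degraded to month
#'   precision.
#' @param concomitant_rate Probability of one additional concomitant
#'   (role C) background drug per case.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_cases = 2000,
                             duplicate_rate = 0.15,
                             max_versions = 3,
                             window = c(20050101, 20230930),
                             drug_mix = default_drug_mix(),
                             target_drugs = c("DOXYCYCLINE", "MINOCYCLINE", "TIGECYCLINE"),
                             dual_target_rate = 0.002,
                             adult_rate = 0.2,
                             age_centers = c(DOXYCYCLINE = 14, MINOCYCLINE = 15.5,
                                             TIGECYCLINE = 7),
                             age_default = 10,
                             age_sd = 3.5,
                             missing_age_rate = 0.015,
                             missing_sex_rate = 0.014,
                             sex_female = c(DOXYCYCLINE = 0.523, MINOCYCLINE = 0.578,
                                            TIGECYCLINE = 0.443),
                             countries = c(US = 0.52, GB = 0.08, CA = 0.06, CN = 0.04,
                                           NL = 0.03, FR = 0.07, DE = 0.07, JP = 0.05,
                                           AU = 0.05, BR = 0.03),
                             pt_vocabulary = default_pt_vocabulary(),
                             injected_signals = NULL,
                             outcome_none_rate = 0.25,
                             outcome_weights = c(OT = 0.40, HO = 0.30, LT = 0.09,
                                                 DE = 0.10, DS = 0.04, CA = 0.02,
                                                 RI = 0.05),
                             onset_meanlog = log(30),
                             onset_sdlog = 0.9,
                             partial_date_rate = 0.3,
                             concomitant_rate = 0.5) {
  stopifnot(n_cases >= 1, duplicate_rate >= 0, duplicate_rate <= 1,
            max_versions >= 2, window[1] <= window[2],
            abs(sum(drug_mix) - 1) < 1e-8,
            all(pt_vocabulary$freq > 0), all(pt_vocabulary$freq < 1))
  if (!is.null(injected_signals)) {
    injected_signals <- tibble::as_tibble(injected_signals)
    stopifnot(all(c("drug", "pt", "odds_ratio") %in% names(injected_signals)))
    if (any(injected_signals$odds_ratio <= 0)) {
      stop("injected odds ratios must be > 0", call. = FALSE)
    }
    miss <- setdiff(injected_signals$pt, pt_vocabulary$pt)
    if (length(miss) > 0) {
      stop("injected signal PT(s) not in the vocabulary: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    pi0 <- pt_vocabulary$freq[match(injected_signals$pt, pt_vocabulary$pt)]
    odds1 <- injected_signals$odds_ratio * pi0 / (1 - pi0)
    pi1 <- odds1 / (1 + odds1)
    if (any(pi1 >= 1)) {
      bad <- which(pi1 >= 1)[1]
      stop("infeasible injected signal (pi1 >= 1): ",
           injected_signals$drug[bad], " / ", injected_signals$pt[bad],
           call. = FALSE)
    }
    injected_signals$pi0 <- pi0
    injected_signals$pi1 <- pi1
  }
  cfg <- list(seed = seed, n_cases = n_cases, duplicate_rate = duplicate_rate,
              max_versions = max_versions, window = as.integer(window),
              drug_mix = drug_mix, target_drugs = toupper(target_drugs),
              dual_target_rate = dual_target_rate, adult_rate = adult_rate,
              age_centers = age_centers, age_default = age_default,
              age_sd = age_sd, missing_age_rate = missing_age_rate,
              missing_sex_rate = missing_sex_rate, sex_female = sex_female,
              countries = countries, pt_vocabulary = pt_vocabulary,
              injected_signals = injected_signals,
              outcome_none_rate = outcome_none_rate,
              outcome_weights = outcome_weights,
              onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
              partial_date_rate = partial_date_rate,
              concomitant_rate = concomitant_rate)
  class(cfg) <- "synthetic_config"
  cfg
}

# verbatim-name pools for target drugs (exercise the synonym dictionary)
.target_verbatims <- list(
  DOXYCYCLINE = c("DOXYCYCLINE", "DOXYCYCLINE HYCLATE", "VIBRAMYCIN", "DORYX"),
  MINOCYCLINE = c("MINOCYCLINE", "MINOCYCLINE HYDROCHLORIDE", "MINOCIN", "SOLODYN"),
  TIGECYCLINE = c("TIGECYCLINE", "TYGACIL"))

.indication_pools <- list(
  DOXYCYCLINE = c("acne", "lyme disease", "acne conglobata", "relapsing fever"),
  MINOCYCLINE = c("acne", "confluent and reticulate papillomatosis", "folliculitis"),
  TIGECYCLINE = c("mycobacterium abscessus infection", "mastoiditis", "sepsis",
                  "pneumonia", "acinetobacter infection"),
  other = c("infection", "pain", "pyrexia", "bronchitis", "sinusitis"))

#' Generate a synthetic FAERS-like database
#'
#' Produces the six quarterly tables plus a ground-truth ledger of planted
#' duplicate survivors and injected signals. The same configuration always
#' yields the identical database; each generation component (demographics,
#' reactions, outcomes, therapy dates, duplicates) draws from its own
#' RNG sub-stream so extending one component does not perturb the others.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with elements `db` (a `faers_db`) and `ledger` (a list
#'   with `signals` - drug, pt, odds_ratio, pi0, pi1 - and `duplicates` -
#'   caseid, survivor primaryid, n_versions).
#' @export
generate_database <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  streams <- sample.int(.Machine$integer.max - 1L, 8)
  n <- cfg$n_cases
  caseid <- as.character(10000000 + seq_len(n))

  # -- demographics stream -------------------------------------------------
  set.seed(streams[1])
  drug1 <- sample(names(cfg$drug_mix), n, replace = TRUE, prob = cfg$drug_mix)
  is_target <- drug1 %in% cfg$target_drugs
  dual <- is_target & stats::runif(n) < cfg$dual_target_rate &
    length(cfg$target_drugs) > 1
  drug2 <- rep(NA_character_, n)
  if (any(dual)) {
    drug2[dual] <- vapply(drug1[dual], function(g) {
      sample(setdiff(cfg$target_drugs, g), 1)
    }, character(1))
  }

  adult <- stats::runif(n) < cfg$adult_rate
  centers <- ifelse(drug1 %in% names(cfg$age_centers),
                    cfg$age_centers[drug1], cfg$age_default)
  age_y <- ifelse(adult, stats::runif(n, 18, 60),
                  pmin(pmax(stats::rnorm(n, centers, cfg$age_sd), 0.05), 17.9))
  use_months <- !adult & age_y < 2
  age <- ifelse(use_months, round(age_y * 12), round(age_y))
  age_cod <- ifelse(use_months, "MON", "YR")
  age_missing <- stats::runif(n) < cfg$missing_age_rate
  age[age_missing] <- NA_real_
  age_cod[age_missing] <- NA_character_

  p_female <- ifelse(drug1 %in% names(cfg$sex_female),
                     cfg$sex_female[drug1], 0.5)
  sex <- ifelse(stats::runif(n) < p_female, "F", "M")
  sex[stats::runif(n) < cfg$missing_sex_rate] <- NA_character_
  country <- sample(names(cfg$countries), n, replace = TRUE,
                    prob = cfg$countries)
  d0 <- faers_date(cfg$window[1])
  d1 <- faers_date(cfg$window[2])
  fda_date <- d0 + floor(stats::runif(n) * (as.numeric(d1 - d0) + 1))
  fda_dt <- as.integer(format(fda_date, "%Y%m%d"))

  # -- reactions stream (background Bernoulli + injected odds) -------------
  set.seed(streams[2])
  vocab <- cfg$pt_vocabulary
  m <- nrow(vocab)
  prob <- matrix(vocab$freq, nrow = n, ncol = m, byrow = TRUE)
  if (!is.null(cfg$injected_signals)) {
    for (k in seq_len(nrow(cfg$injected_signals))) {
      g <- cfg$injected_signals$drug[k]
      j <- match(cfg$injected_signals$pt[k], vocab$pt)
      rows <- drug1 == g | (!is.na(drug2) & drug2 == g)
      prob[rows, j] <- cfg$injected_signals$pi1[k]
    }
  }
  hits <- matrix(stats::runif(n * m), n, m) < prob
  none <- rowSums(hits) == 0
  if (any(none)) {
    fallback <- sample.int(m, sum(none), replace = TRUE, prob = vocab$freq)
    hits[cbind(which(none), fallback)] <- TRUE
  }
  idx <- which(hits, arr.ind = TRUE)
  reac_case <- tibble::tibble(i = idx[, 1], pt = vocab$pt[idx[, 2]]) %>%
    dplyr::arrange(.data$i, .data$pt)

  # -- outcomes stream -----------------------------------------------------
  set.seed(streams[3])
  has_out <- stats::runif(n) >= cfg$outcome_none_rate
  code1 <- sample(names(cfg$outcome_weights), n, replace = TRUE,
                  prob = cfg$outcome_weights)
  second <- has_out & stats::runif(n) < 0.25
  code2 <- sample(names(cfg$outcome_weights), n, replace = TRUE,
                  prob = cfg$outcome_weights)
  outc_case <- dplyr::bind_rows(
    tibble::tibble(i = which(has_out), outc_cod = code1[has_out]),
    tibble::tibble(i = which(second), outc_cod = code2[second])) %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$i, .data$outc_cod)

  # -- therapy / event dates stream ----------------------------------------
  set.seed(streams[4])
  start_date <- fda_date - round(stats::runif(n, 30, 400))
  gap <- pmax(0, round(stats::rlnorm(n, cfg$onset_meanlog, cfg$onset_sdlog)))
  event_date <- start_date + gap
  event_dt <- as.integer(format(event_date, "%Y%m%d"))
  event_prec <- rep("day", n)
  part <- stats::runif(n) < cfg$partial_date_rate
  event_dt[part] <- event_dt[part] %/% 100L
  event_prec[part] <- "month"
  start_dt <- as.integer(format(start_date, "%Y%m%d"))
  start_prec <- rep("day", n)
  part_s <- stats::runif(n) < cfg$partial_date_rate / 2
  start_dt[part_s] <- start_dt[part_s] %/% 100L
  start_prec[part_s] <- "month"
  no_event <- stats::runif(n) < 0.2
  event_dt[no_event] <- NA_integer_
  event_prec[no_event] <- NA_character_

  # -- drug rows stream ----------------------------------------------------
  set.seed(streams[5])
  verbatim1 <- vapply(drug1, function(g) {
    pool <- .target_verbatims[[g]] %||% g
    pool[sample.int(length(pool), 1)]
  }, character(1))
  role1 <- sample(c("PS", "SS"), n, replace = TRUE, prob = c(0.8, 0.2))
  conc_pool <- setdiff(names(cfg$drug_mix), cfg$target_drugs)
  conc <- if (length(conc_pool) > 0) stats::runif(n) < cfg$concomitant_rate
          else rep(FALSE, n)
  conc_name <- if (length(conc_pool) > 0) sample(conc_pool, n, replace = TRUE)
               else rep(NA_character_, n)
  drug_case <- dplyr::bind_rows(
    tibble::tibble(i = seq_len(n), drug_seq = 1L, role_cod = role1,
                   drugname = verbatim1, canon = drug1),
    tibble::tibble(i = which(dual), drug_seq = 2L, role_cod = "SS",
                   drugname = drug2[dual], canon = drug2[dual]),
    tibble::tibble(i = which(conc), drug_seq = 3L, role_cod = "C",
                   drugname = conc_name[conc], canon = conc_name[conc])) %>%
    dplyr::arrange(.data$i, .data$drug_seq)

  # -- indications stream --------------------------------------------------
  set.seed(streams[6])
  pool_of <- function(g) .indication_pools[[g]] %||% .indication_pools$other
  has_indi <- stats::runif(nrow(drug_case)) < 0.7
  indi_case <- drug_case[has_indi, c("i", "drug_seq", "canon")]
  indi_case$indi_pt <- vapply(indi_case$canon, function(g) {
    pool <- pool_of(g)
    pool[sample.int(length(pool), 1)]
  }, character(1))

  # -- duplicate versions stream -------------------------------------------
  set.seed(streams[7])
  dup <- stats::runif(n) < cfg$duplicate_rate
  n_versions <- rep(1L, n)
  n_versions[dup] <- 1L + sample.int(cfg$max_versions - 1L, sum(dup),
                                     replace = TRUE)
  versions <- tibble::tibble(i = rep(seq_len(n), n_versions)) %>%
    dplyr::mutate(version = dplyr::row_number(), .by = "i")
  jit <- ifelse(stats::runif(nrow(versions)) < 0.25, 0L,
                sample.int(180, nrow(versions), replace = TRUE))
  jit[versions$version == 1L] <- 0L
  cum_jit <- stats::ave(jit, versions$i, FUN = cumsum)
  versions$primaryid <- paste0(caseid[versions$i], versions$version)
  versions$fda_dt <- as.integer(format(fda_date[versions$i] + cum_jit,
                                       "%Y%m%d"))

  # -- materialize tables ---------------------------------------------------
  demo <- tibble::tibble(
    primaryid = versions$primaryid, caseid = caseid[versions$i],
    fda_dt = versions$fda_dt, event_dt = event_dt[versions$i],
    event_dt_prec = event_prec[versions$i], rept_dt = versions$fda_dt,
    age = age[versions$i], age_cod = age_cod[versions$i],
    sex = sex[versions$i], occr_country = country[versions$i]) %>%
    dplyr::arrange(.data$primaryid)

  expand <- function(per_case, cols) {
    out <- dplyr::inner_join(versions[, c("i", "primaryid")], per_case,
                             by = "i", relationship = "many-to-many")
    out[, c("primaryid", cols)]
  }
  drug_tbl <- expand(drug_case, c("drug_seq", "role_cod", "drugname")) %>%
    dplyr::arrange(.data$primaryid, .data$drug_seq)
  reac_tbl <- expand(reac_case, "pt") %>%
    dplyr::arrange(.data$primaryid, .data$pt)
  outc_tbl <- expand(outc_case, "outc_cod") %>%
    dplyr::arrange(.data$primaryid, .data$outc_cod)
  indi_tbl <- expand(indi_case, c("drug_seq", "indi_pt")) %>%
    dplyr::rename(indi_drug_seq = "drug_seq") %>%
    dplyr::arrange(.data$primaryid, .data$indi_drug_seq)
  ther_case <- tibble::tibble(i = seq_len(n), dsg_drug_seq = 1L,
                              start_dt = start_dt, start_dt_prec = start_prec)
  ther_tbl <- expand(ther_case, c("dsg_drug_seq", "start_dt", "start_dt_prec")) %>%
    dplyr::arrange(.data$primaryid, .data$dsg_drug_seq)

  survivors <- versions %>%
    dplyr::arrange(.data$i, .data$fda_dt,
                   as.numeric(.data$primaryid)) %>%
    dplyr::slice_tail(n = 1, by = "i")
  ledger <- list(
    signals = if (is.null(cfg$injected_signals)) {
      tibble::tibble(drug = character(), pt = character(),
                     odds_ratio = numeric(), pi0 = numeric(), pi1 = numeric())
    } else cfg$injected_signals,
    duplicates = tibble::tibble(caseid = caseid[survivors$i],
                                survivor_primaryid = survivors$primaryid,
                                n_versions = n_versions[survivors$i]))

  db <- structure(list(demo = demo, drug = drug_tbl, reac = reac_tbl,
                       outc = outc_tbl, indi = indi_tbl, ther = ther_tbl),
                  class = "faers_db")
  list(db = db, ledger = ledger)
}
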