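#' Cohort configuration
#'
#' Defines the study funnel: receipt-date window, age bounds, drug roles
#' counted as exposure, and the target drugs.
#'
#' @param window_start,window_end Inclusive YYYYMMDD bounds on the FDA
#'   receipt date (`fda_dt`). Defaults cover January 2005 through
#'   September 2023.
#' @param age_min_years Inclusive lower age bound (years).
#' @param age_max_years Exclusive upper age bound; the default 18 keeps
#'   patients strictly under 18. Reports with missing age are excluded (the
#'   bound cannot be affirmed).
#' @param roles_included Drug role codes counted as exposure; default
#'   suspect roles `PS` (primary) and `SS` (secondary), excluding
#'   concomitant (`C`) and interacting (`I`).
#' @param target_drugs Canonical names of the drugs under study.
#' @param background_scope Comparator population for disproportionality:
#'   `"pediatric"` (default) restricts the background to in-window reports
#'   passing the same age filter; `"all"` uses all in-window reports.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(window_start = 20050101,
                          window_end = 20230930,
                          age_min_years = 0,
                          age_max_years = 18,
                          roles_included = c("PS", "SS"),
                          target_drugs = c("DOXYCYCLINE", "MINOCYCLINE", "TIGECYCLINE"),
                          background_scope = c("pediatric", "all")) {
  stopifnot(window_start <= window_end,
            age_min_years >= 0, age_min_years < age_max_years,
            all(roles_included %in% .role_codes),
            length(target_drugs) >= 1)
  structure(list(window_start = as.integer(window_start),
                 window_end = as.integer(window_end),
                 age_min_years = age_min_years,
                 age_max_years = age_max_years,
                 roles_included = roles_included,
                 target_drugs = toupper(target_drugs),
                 background_scope = match.arg(background_scope)),
            class = "cohort_config")
}

#' Deduplicate reports by the FDA case rule
#'
#' Within each case (CASEID), keeps the report with the latest FDA receipt
#' date; among ties on the date, the report with the numerically higher
#' PRIMARYID. One report survives per case. The operation is idempotent and
#' the survivor set does not depend on input row order; output is sorted by
#' `caseid`.
#'
#' @param demo DEMO tibble (needs `primaryid`, `caseid`, `fda_dt`).
#' @return The surviving rows of `demo`, one per `caseid`, sorted by
#'   `caseid`.
#' @export
deduplicate_reports <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  pid_num <- suppressWarnings(as.numeric(demo$primaryid))
  ord <- order(demo$caseid, -demo$fda_dt, -pid_num)
  out <- demo[ord, , drop = FALSE]
  out <- out[!duplicated(out$caseid), , drop = FALSE]
  out[order(out$caseid), , drop = FALSE]
}

#' Convert reported ages to years
#'
#' FAERS ages come with a unit code: decades (`DEC`), years (`YR`), months
#' (`MON`), weeks (`WK`), days (`DY`) or hours (`HR`). Conversion constants
#' are fixed (52.18 weeks, 365.25 days, 8766 hours per year) so results are
#' deterministic; the differences between year-length conventions are
#' immaterial at the age-18 boundary.
#'
#' @param age_value Numeric age values.
#' @param age_code Unit codes; missing code (with a present value) or an
#'   unknown code yields `NA` with a warning counting the affected records.
#' @return Numeric vector of ages in years.
#' @examples
#' age_in_years(c(14, 30, 2), c("YR", "MON", "DEC")) # 14, 2.5, 20
#' @export
age_in_years <- function(age_value, age_code) {
  factor_map <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.18,
                  DY = 1 / 365.25, HR = 1 / 8766)
  code <- toupper(age_code)
  f <- factor_map[code]
  unknown <- !is.na(age_value) & !is.na(code) & !code %in% names(factor_map)
  if (any(unknown)) {
    warning(sum(unknown), " record(s) with unknown age unit code treated as missing age",
            call. = FALSE)
  }
  out <- age_value * unname(f)
  out[is.na(age_value) | is.na(code) | unknown] <- NA_real_
  out
}

#' Normalize a verbatim drug name against the synonym dictionary
#'
#' Uppercases, trims and collapses internal whitespace, then looks the name
#' up among the dictionary's exact synonyms. Non-matching names map to
#' `"other"`; there is no fuzzy matching or spelling correction.
#'
#' @param verbatim Character vector of reported drug names.
#' @param dictionary Tibble from [read_drug_dictionary()].
#' @return Character vector of canonical drug names (or `"other"`).
#' @export
normalize_drug_name <- function(verbatim, dictionary = read_drug_dictionary()) {
  x <- toupper(stringr::str_squish(verbatim))
  i <- match(x, dictionary$synonym)
  out <- dictionary$canonical[i]
  out[is.na(i)] <- "other"
  out
}

#' Build the study cohort and inclusion funnel
#'
#' Applies the study funnel to a deduplicated database: receipt date within
#' the window, age within bounds, at least one target drug in an included
#' role, and at least one reported reaction. Emits the retained cases, the
#' per-stage funnel counts, per-drug tallies, and the background drug-event
#' units used downstream for disproportionality.
#'
#' A case suspect for two target drugs appears in both drugs' tallies (and
#' in neither drug's comparator). Onset days per (case, drug) are the
#' difference between the event date and the earliest therapy start date for
#' that drug, computed only when both dates have day precision; negative
#' differences are treated as missing.
#'
#' @param db A `faers_db` whose DEMO table is already deduplicated
#'   (see [deduplicate_reports()]); an error is raised otherwise.
#' @param cfg A [cohort_config()].
#' @param dictionary Drug synonym dictionary, [read_drug_dictionary()].
#' @param aliases PT spelling aliases, [read_pt_aliases()].
#' @return An object of class `faers_cohort`: a list with
#'   \describe{
#'     \item{cases}{tibble of retained cases: `caseid`, `primaryid`,
#'       `age_years`, `sex`, `country`, `fda_dt`, `outcome_codes`
#'       (list-column), `n_pts`.}
#'     \item{case_drugs}{tibble `caseid`, `drug`, `onset_days`.}
#'     \item{case_pts}{tibble `caseid`, `pt` (distinct, normalized).}
#'     \item{case_indications}{tibble `caseid`, `drug`, `indication` for
#'       indications attached to matched target-drug records.}
#'     \item{funnel}{tibble `stage`, `n`, `excluded`.}
#'     \item{per_drug}{tibble `drug`, `n_cases`, `n_drug_event`.}
#'     \item{background_units}{tibble `caseid`, `pt`: distinct case-PT
#'       pairs over the comparator-scope population (all drugs).}
#'     \item{background_cases}{tibble `caseid`, `age_years` for the
#'       background population.}
#'     \item{case_targets}{tibble `caseid`, `drug`: target-drug exposure
#'       over the background population.}
#'     \item{config}{the `cohort_config` used.}
#'   }
#' @export
build_cohort <- function(db, cfg = cohort_config(),
                         dictionary = read_drug_dictionary(),
                         aliases = read_pt_aliases()) {
  demo <- db$demo
  if (anyDuplicated(demo$caseid)) {
    stop("DEMO contains duplicate caseids; run deduplicate_reports() first",
         call. = FALSE)
  }

  n_total <- nrow(demo)
  in_window <- !is.na(demo$fda_dt) &
    demo$fda_dt >= cfg$window_start & demo$fda_dt <= cfg$window_end
  demo_w <- demo[in_window, , drop = FALSE]

  age_years <- age_in_years(demo_w$age, demo_w$age_cod)
  pediatric <- !is.na(age_years) &
    age_years >= cfg$age_min_years & age_years < cfg$age_max_years
  demo_a <- demo_w[pediatric, , drop = FALSE]
  age_a <- age_years[pediatric]

  # drug exposure for the whole in-scope background (needed for comparator)
  scope_demo <- if (cfg$background_scope == "pediatric") demo_a else demo_w
  scope_age <- if (cfg$background_scope == "pediatric") age_a else age_years
  drug_scope <- db$drug[db$drug$primaryid %in% scope_demo$primaryid, , drop = FALSE]
  drug_scope$drug <- normalize_drug_name(drug_scope$drugname, dictionary)
  matched <- drug_scope[drug_scope$drug %in% cfg$target_drugs &
                          drug_scope$role_cod %in% cfg$roles_included, , drop = FALSE]
  pid_case <- stats::setNames(scope_demo$caseid, scope_demo$primaryid)
  case_targets <- tibble::tibble(caseid = unname(pid_case[matched$primaryid]),
                                 drug = matched$drug) %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$caseid, .data$drug)

  # reactions for the background scope, normalized
  reac_scope <- db$reac[db$reac$primaryid %in% scope_demo$primaryid, , drop = FALSE]
  background_units <- tibble::tibble(
    caseid = unname(pid_case[reac_scope$primaryid]),
    pt = normalize_pt(reac_scope$pt, aliases)) %>%
    dplyr::filter(!is.na(.data$pt), nzchar(.data$pt)) %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$caseid, .data$pt)
  background_cases <- tibble::tibble(caseid = scope_demo$caseid,
                                     age_years = scope_age)

  # funnel: cases whose report names a target drug in an included role.
  # When the background is all-ages the pediatric filter still defines the
  # cohort; exposure is computed on the pediatric subset in either scope.
  ped_ids <- demo_a$primaryid
  suspect_case_ids <- unique(case_targets$caseid[
    case_targets$caseid %in% pid_case[ped_ids]])
  demo_s <- demo_a[demo_a$caseid %in% suspect_case_ids, , drop = FALSE]
  age_s <- age_a[demo_a$caseid %in% suspect_case_ids]

  pts_by_case <- background_units[background_units$caseid %in% demo_s$caseid, ,
                                  drop = FALSE]
  has_pt <- demo_s$caseid %in% pts_by_case$caseid
  demo_e <- demo_s[has_pt, , drop = FALSE]
  age_e <- age_s[has_pt]

  funnel <- tibble::tibble(
    stage = c("total reports (deduplicated)", "within study window",
              "age within bounds", "target drug as suspect",
              "with at least one reaction PT"),
    n = c(n_total, nrow(demo_w), nrow(demo_a), nrow(demo_s), nrow(demo_e)))
  funnel$excluded <- c(0L, funnel$n[-5] - funnel$n[-1])

  outc_sets <- outcome_sets(db$outc)
  oc <- outc_sets$outcome_codes[match(demo_e$primaryid, outc_sets$primaryid)]
  oc[vapply(oc, is.null, logical(1))] <- list(character(0))

  case_pts <- pts_by_case[pts_by_case$caseid %in% demo_e$caseid, , drop = FALSE]
  n_pts <- dplyr::count(case_pts, .data$caseid, name = "n_pts")

  cases <- tibble::tibble(
    caseid = demo_e$caseid, primaryid = demo_e$primaryid,
    age_years = age_e, sex = demo_e$sex, country = demo_e$occr_country,
    fda_dt = demo_e$fda_dt, outcome_codes = oc) %>%
    dplyr::left_join(n_pts, by = "caseid") %>%
    dplyr::arrange(.data$caseid)

  cohort_targets <- case_targets[case_targets$caseid %in% cases$caseid, , drop = FALSE]

  # onset per (case, drug): event date minus earliest day-precision therapy
  # start among that drug's records
  case_drugs <- .compute_onsets(db, demo_e, matched, cohort_targets)

  case_indications <- .collect_indications(db, demo_e, matched, aliases)

  n_de <- dplyr::count(
    dplyr::inner_join(cohort_targets, case_pts, by = "caseid",
                      relationship = "many-to-many"),
    .data$drug, name = "n_drug_event")
  per_drug <- cohort_targets %>%
    dplyr::count(.data$drug, name = "n_cases") %>%
    dplyr::left_join(n_de, by = "drug") %>%
    dplyr::arrange(.data$drug)

  structure(list(cases = cases, case_drugs = case_drugs, case_pts = case_pts,
                 case_indications = case_indications, funnel = funnel,
                 per_drug = per_drug, background_units = background_units,
                 background_cases = background_cases,
                 case_targets = case_targets, config = cfg),
            class = "faers_cohort")
}

.compute_onsets <- function(db, demo_e, matched, cohort_targets) {
  out <- dplyr::mutate(cohort_targets, onset_days = NA_real_)
  if (is.null(db$ther) || nrow(db$ther) == 0) return(out)
  m <- matched[matched$primaryid %in% demo_e$primaryid, , drop = FALSE]
  ther <- db$ther %>%
    dplyr::filter(.data$start_dt_prec %in% "day") %>%
    dplyr::inner_join(m, by = c("primaryid", "dsg_drug_seq" = "drug_seq"))
  if (nrow(ther) == 0) return(out)
  starts <- ther %>%
    dplyr::summarise(start_dt = min(.data$start_dt),
                     .by = c("primaryid", "drug"))
  ev <- demo_e[!is.na(demo_e$event_dt_prec) & demo_e$event_dt_prec == "day",
               c("primaryid", "caseid", "event_dt")]
  joined <- dplyr::inner_join(starts, ev, by = "primaryid")
  joined$onset_days <- as.numeric(faers_date(joined$event_dt) -
                                    faers_date(joined$start_dt))
  joined$onset_days[joined$onset_days < 0] <- NA_real_
  out %>%
    dplyr::rows_update(joined[, c("caseid", "drug", "onset_days")],
                       by = c("caseid", "drug"), unmatched = "ignore")
}

.collect_indications <- function(db, demo_e, matched, aliases) {
  empty <- tibble::tibble(caseid = character(), drug = character(),
                          indication = character())
  if (is.null(db$indi) || nrow(db$indi) == 0) return(empty)
  m <- matched[matched$primaryid %in% demo_e$primaryid, , drop = FALSE]
  ind <- dplyr::inner_join(db$indi, m,
                           by = c("primaryid", "indi_drug_seq" = "drug_seq"))
  if (nrow(ind) == 0) return(empty)
  tibble::tibble(
    caseid = demo_e$caseid[match(ind$primaryid, demo_e$primaryid)],
    drug = ind$drug,
    indication = normalize_pt(ind$indi_pt, aliases)) %>%
    dplyr::filter(!is.na(.data$indication)) %>%
    dplyr::distinct()
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat("<faers_cohort>", nrow(x$cases), "cases;",
      nrow(x$background_units), "background drug-event units\n")
  print(x$funnel)
  print(x$per_drug)
  invisible(x)
}
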