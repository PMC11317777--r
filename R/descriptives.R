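# Descriptive surfaces: baseline characteristics with most-severe-outcome
# selection, fatal-case drill-down, subgroup tables with time-to-onset,
# co-occurrence profiles, and the under-8 dental-staining analysis.

#' Outcome severity ranking
#'
#' Total order over the seven FAERS outcome codes, most severe first:
#' death (`DE`), life-threatening (`LT`), hospitalization (`HO`), disability
#' (`DS`), congenital anomaly (`CA`), required intervention (`RI`), other
#' serious (`OT`). Reports with an empty outcome set are labelled
#' `"Unknown"`.
#'
#' @return Character vector of codes in decreasing severity.
#' @export
severity_ranking <- function() {
  c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
}

#' Most severe outcome of a report
#'
#' A report may carry several outcome codes; baseline tables keep the most
#' severe one. Invariant to input order and to duplicated codes.
#'
#' @param codes Character vector of outcome codes (one report's set), or a
#'   list of such vectors.
#' @param ranking Severity order, most severe first.
#' @return A single label per report: the highest-ranked code present, or
#'   `"Unknown"` for an empty set. Unknown codes raise an error.
#' @examples
#' most_severe_outcome(c("HO", "DE")) # "DE"
#' @export
most_severe_outcome <- function(codes, ranking = severity_ranking()) {
  if (is.list(codes)) {
    return(vapply(codes, most_severe_outcome, character(1), ranking = ranking))
  }
  codes <- unique(codes[!is.na(codes)])
  if (length(codes) == 0) return("Unknown")
  bad <- setdiff(codes, ranking)
  if (length(bad) > 0) {
    stop("unknown outcome code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ranking[min(match(codes, ranking))]
}

.outcome_labels <- c(DE = "Death", LT = "Life Threatening", HO = "Hospitalization",
                     DS = "Disability", CA = "Congenital Anomaly",
                     RI = "Required Intervention", OT = "Other serious events",
                     Unknown = "Unknown")

# cases joined with exposure for one drug
.drug_cases <- function(cohort, drug) {
  ids <- cohort$case_targets$caseid[cohort$case_targets$drug == drug]
  cohort$cases[cohort$cases$caseid %in% ids, , drop = FALSE]
}

.count_block <- function(values, total, levels = NULL) {
  values[is.na(values)] <- "Missing"
  tab <- table(values)
  if (!is.null(levels)) {
    tab <- tab[match(levels, names(tab))]
    tab[is.na(tab)] <- 0
    names(tab) <- levels
  }
  tibble::tibble(level = names(tab), n = as.integer(tab),
                 pct = pct_of(as.integer(tab), total))
}

# 3-year receipt-year bins anchored at the window start; a final partial
# bin is labelled with the quarters it covers.
.year_bins <- function(years, window_start, window_end) {
  y0 <- window_start %/% 10000L
  y1 <- window_end %/% 10000L
  end_month <- (window_end %/% 100L) %% 100L
  bin_start <- y0 + 3L * ((years - y0) %/% 3L)
  bin_end <- pmin(bin_start + 2L, y1)
  lab <- ifelse(bin_start == bin_end,
                ifelse(bin_end == y1 & end_month < 12L,
                       sprintf("%d (Q1-Q%d)", bin_start, ceiling(end_month / 3)),
                       sprintf("%d", bin_start)),
                sprintf("%d-%d", bin_start, bin_end))
  ordered_labels <- unique(lab[order(bin_start)])
  factor(lab, levels = ordered_labels)
}

#' Baseline characteristics per drug
#'
#' Case counts, median age with quartiles, age-band counts, sex split,
#' top-5 countries, most-severe-outcome distribution, receipt-year counts in
#' 3-year bins, and top-5 indication PTs, for each target drug.
#' Percentages are per drug to two decimals (half-up). Age bands follow the
#' published convention: "0-7" is age < 8, "8-18" is 8 <= age < upper
#' bound, so the bands partition the cohort. Country ties at the top-5 cut
#' are broken alphabetically.
#'
#' @param cohort A `faers_cohort`.
#' @param age_band_break Age (years) splitting the two bands; default 8.
#' @return A list of class `faers_baseline` with one tibble per block:
#'   `n_cases`, `age`, `age_bands`, `sex`, `countries`, `outcomes`,
#'   `received_years`, `indications`.
#' @export
summarize_baseline <- function(cohort, age_band_break = 8) {
  cfg <- cohort$config
  drugs <- sort(unique(cohort$case_targets$drug))
  blocks <- lapply(drugs, function(g) {
    cc <- .drug_cases(cohort, g)
    total <- nrow(cc)
    ai <- median_iqr(cc$age_years)
    band_lab <- c(sprintf("0-%d", age_band_break - 1),
                  sprintf("%d-%d", age_band_break, cfg$age_max_years))
    bands <- .count_block(ifelse(cc$age_years < age_band_break,
                                 band_lab[1], band_lab[2]),
                          total, levels = band_lab)
    sex <- .count_block(dplyr::case_match(cc$sex, "M" ~ "Male", "F" ~ "Female",
                                          .default = "Missing"),
                        total, levels = c("Male", "Female", "Missing"))
    ctry <- .count_block(cc$country, total)
    ctry <- ctry[ctry$level != "Missing", , drop = FALSE]
    ctry <- ctry[order(-ctry$n, ctry$level), , drop = FALSE][
      seq_len(min(5, nrow(ctry))), , drop = FALSE]
    out_codes <- most_severe_outcome(cc$outcome_codes)
    outc <- .count_block(unname(.outcome_labels[out_codes]), total,
                         levels = unname(.outcome_labels))
    yrs <- .year_bins(cc$fda_dt %/% 10000L, cfg$window_start, cfg$window_end)
    ry <- tibble::tibble(period = levels(yrs),
                         n = as.integer(table(yrs)))
    ind <- cohort$case_indications %>%
      dplyr::filter(.data$drug == g) %>%
      dplyr::distinct(.data$caseid, .data$indication) %>%
      dplyr::count(.data$indication, name = "n", sort = TRUE)
    ind <- ind[order(-ind$n, ind$indication), , drop = FALSE][
      seq_len(min(5, nrow(ind))), , drop = FALSE]
    list(drug = g, n_cases = total,
         age = tibble::tibble(median = unname(ai["median"]),
                              q1 = unname(ai["q1"]), q3 = unname(ai["q3"])),
         age_bands = bands, sex = sex, countries = ctry, outcomes = outc,
         received_years = ry, indications = ind)
  })
  names(blocks) <- drugs
  structure(blocks, class = "faers_baseline")
}

#' @export
print.faers_baseline <- function(x, ...) {
  for (g in names(x)) {
    b <- x[[g]]
    cat(sprintf("== %s (N = %d) ==\n", g, b$n_cases))
    cat(sprintf("  age median %.1f [%.1f, %.1f]\n",
                b$age$median, b$age$q1, b$age$q3))
    cat("  sex:", paste(sprintf("%s %d (%.2f%%)", b$sex$level, b$sex$n, b$sex$pct),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Drill-down of fatal cases for one drug
#'
#' Fatal cases are those whose outcome set contains `DE`. Reports the count,
#' the count and share carrying at least one ineffectiveness/product-issue
#' PT, the median age with IQR, and the top-3 indications and countries.
#'
#' @param cohort A `faers_cohort`.
#' @param drug Canonical drug name.
#' @param ineffectiveness Character vector of PTs marking ineffectiveness or
#'   product-use issues; see [ineffectiveness_pts()].
#' @return A list: `n_fatal`, `n_ineffectiveness`, `pct_ineffectiveness`,
#'   `age` (median/q1/q3), `top_indications`, `top_countries`. When there
#'   are no fatal cases, `n_fatal = 0` and a `note` explains the empty
#'   summary.
#' @export
fatal_case_drilldown <- function(cohort, drug,
                                 ineffectiveness = ineffectiveness_pts()) {
  cc <- .drug_cases(cohort, drug)
  fatal <- cc[vapply(cc$outcome_codes, function(x) "DE" %in% x, logical(1)), ,
              drop = FALSE]
  if (nrow(fatal) == 0) {
    return(list(drug = drug, n_fatal = 0L, note = "no fatal cases"))
  }
  pts <- cohort$case_pts[cohort$case_pts$caseid %in% fatal$caseid, , drop = FALSE]
  flagged <- unique(pts$caseid[pts$pt %in% tolower(ineffectiveness)])
  ind <- cohort$case_indications %>%
    dplyr::filter(.data$drug == !!drug, .data$caseid %in% fatal$caseid) %>%
    dplyr::distinct(.data$caseid, .data$indication) %>%
    dplyr::count(.data$indication, name = "n")
  ind <- ind[order(-ind$n, ind$indication), , drop = FALSE][
    seq_len(min(3, nrow(ind))), , drop = FALSE]
  ctry <- .count_block(fatal$country, nrow(fatal))
  ctry <- ctry[ctry$level != "Missing", , drop = FALSE]
  ctry <- ctry[order(-ctry$n, ctry$level), , drop = FALSE][
    seq_len(min(3, nrow(ctry))), , drop = FALSE]
  ai <- median_iqr(fatal$age_years)
  list(drug = drug, n_fatal = nrow(fatal),
       n_ineffectiveness = length(flagged),
       pct_ineffectiveness = pct_of(length(flagged), nrow(fatal)),
       age = ai, top_indications = ind, top_countries = ctry)
}

#' Time to onset for one drug's cases
#'
#' Onset is the day difference between the event date and the earliest
#' therapy start for the drug, available only when both dates have day
#' precision; negative differences were discarded at cohort build.
#'
#' @param cohort A `faers_cohort`.
#' @param drug Canonical drug name.
#' @param caseids Optional restriction to a subset of cases (e.g. a
#'   subgroup).
#' @return Numeric vector of onset days (`NA` where unavailable).
#' @export
time_to_onset <- function(cohort, drug, caseids = NULL) {
  cd <- cohort$case_drugs[cohort$case_drugs$drug == drug, , drop = FALSE]
  if (!is.null(caseids)) cd <- cd[cd$caseid %in% caseids, , drop = FALSE]
  cd$onset_days
}

#' Define an adverse-event subgroup
#'
#' A subgroup is indexed by a set of PTs (e.g. IIH/ICP, suicidality, DRESS,
#' thyroid dysfunction) and optionally an age filter (e.g. dental staining
#' under 8 years).
#'
#' @param name Display name.
#' @param pts Character vector of index PTs (spelling aliases resolved).
#' @param age_max Optional exclusive upper age bound in years.
#' @return A list of class `subgroup_spec`.
#' @export
subgroup_spec <- function(name, pts, age_max = NULL) {
  stopifnot(length(pts) >= 1)
  structure(list(name = name, pts = normalize_pt(pts), age_max = age_max),
            class = "subgroup_spec")
}

#' Built-in subgroup definitions
#'
#' The five subgroups studied for tetracycline pediatric safety:
#' intracranial hypertension (IIH/ICP), suicidality, DRESS, thyroid
#' dysfunction, and dental staining in children under 8.
#'
#' @return Named list of [subgroup_spec()] objects.
#' @export
subgroup_presets <- function() {
  list(
    iih_icp = subgroup_spec("IIH/ICP",
                            c("idiopathic intracranial hypertension",
                              "intracranial pressure increased")),
    suicidality = subgroup_spec("Suicidal ideation/suicide attempts",
                                c("suicidal ideation", "suicide attempt")),
    dress = subgroup_spec("DRESS",
                          "drug reaction with eosinophilia and systemic symptoms"),
    thyroid = subgroup_spec("Thyroid dysfunction",
                            c("hyperthyroidism", "hypothyroidism")),
    dental_staining = subgroup_spec("Dental staining under 8 years old",
                                    "tooth discolouration", age_max = 8))
}

#' Subgroup characteristics table
#'
#' Counts subgroup cases by drug, with cases suspect for several target
#' drugs reported in a combined row only (e.g. "DOXYCYCLINE + MINOCYCLINE"),
#' so single-drug rows plus combined rows sum to the subgroup total. Adds
#' the sex split, median age, per-drug median onset among subgroup cases,
#' and the most-severe-outcome distribution.
#'
#' @param cohort A `faers_cohort`.
#' @param spec A [subgroup_spec()].
#' @return A list of class `faers_subgroup`: `name`, `n_total`, `counts`
#'   (tibble `row`, `n`), `sex`, `age` (median/q1/q3), `onset` (per-drug
#'   median/q1/q3 tibble), `outcomes`. Empty subgroups return `n_total = 0`
#'   with a `note`.
#' @export
subgroup_table <- function(cohort, spec) {
  hit_cases <- unique(cohort$case_pts$caseid[cohort$case_pts$pt %in% spec$pts])
  cc <- cohort$cases[cohort$cases$caseid %in% hit_cases, , drop = FALSE]
  if (!is.null(spec$age_max)) {
    cc <- cc[cc$age_years < spec$age_max, , drop = FALSE]
  }
  if (nrow(cc) == 0) {
    return(structure(list(name = spec$name, n_total = 0L,
                          note = "no cases in subgroup"),
                     class = "faers_subgroup"))
  }
  membership <- cohort$case_targets %>%
    dplyr::filter(.data$caseid %in% cc$caseid) %>%
    dplyr::summarise(row = paste(sort(.data$drug), collapse = " + "),
                     .by = "caseid")
  counts <- membership %>%
    dplyr::count(.data$row, name = "n") %>%
    dplyr::arrange(stringr::str_count(.data$row, stringr::fixed(" + ")), .data$row)
  sex <- .count_block(dplyr::case_match(cc$sex, "M" ~ "Male", "F" ~ "Female",
                                        .default = "Missing"),
                      nrow(cc), levels = c("Male", "Female", "Missing"))
  drugs <- sort(unique(cohort$case_targets$drug[
    cohort$case_targets$caseid %in% cc$caseid]))
  onset <- dplyr::bind_rows(lapply(drugs, function(g) {
    v <- time_to_onset(cohort, g, caseids = cc$caseid)
    mi <- median_iqr(v)
    tibble::tibble(drug = g, n_with_onset = sum(!is.na(v)),
                   median = unname(mi["median"]), q1 = unname(mi["q1"]),
                   q3 = unname(mi["q3"]))
  }))
  out_codes <- most_severe_outcome(cc$outcome_codes)
  outcomes <- .count_block(unname(.outcome_labels[out_codes]), nrow(cc),
                           levels = unname(.outcome_labels))
  structure(list(name = spec$name, n_total = nrow(cc), counts = counts,
                 sex = sex, age = median_iqr(cc$age_years), onset = onset,
                 outcomes = outcomes),
            class = "faers_subgroup")
}

#' @export
print.faers_subgroup <- function(x, ...) {
  cat(sprintf("<subgroup: %s> %d cases\n", x$name, x$n_total))
  if (x$n_total > 0) print(x$counts)
  invisible(x)
}

#' Co-occurrence profile of an index PT for one drug
#'
#' For each PT reported together with the index PT among one drug's cases,
#' gives the number of co-occurrences and the share this represents of all
#' the drug's cases reporting that PT: 100 means the PT occurs exclusively
#' alongside the index condition.
#'
#' @param cohort A `faers_cohort`.
#' @param drug Canonical drug name.
#' @param index_pt Index PT (aliases resolved).
#' @return A tibble `co_pt`, `n_co`, `n_total_pt`, `pct`, sorted by `n_co`
#'   descending (ties by PT).
#' @export
cooccurrence_profile <- function(cohort, drug, index_pt) {
  index_pt <- normalize_pt(index_pt)
  ids <- cohort$case_targets$caseid[cohort$case_targets$drug == drug]
  pts <- cohort$case_pts[cohort$case_pts$caseid %in% ids, , drop = FALSE]
  idx_cases <- unique(pts$caseid[pts$pt == index_pt])
  if (length(idx_cases) == 0) {
    stop("index PT '", index_pt, "' does not occur for ", drug, call. = FALSE)
  }
  totals <- dplyr::count(pts, .data$pt, name = "n_total_pt")
  co <- pts[pts$caseid %in% idx_cases & pts$pt != index_pt, , drop = FALSE] %>%
    dplyr::count(.data$pt, name = "n_co")
  co %>%
    dplyr::left_join(totals, by = "pt") %>%
    dplyr::mutate(pct = pct_of(.data$n_co, .data$n_total_pt)) %>%
    dplyr::rename(co_pt = "pt") %>%
    dplyr::arrange(dplyr::desc(.data$n_co), .data$co_pt)
}

#' Under-8 subcohort analysis with dental-staining signal
#'
#' Restricts both the target cohorts and the comparator to children under
#' the age cut (default 8 years) and, within that stratum, recomputes the
#' disproportionality signal for the dental-staining PT per drug.
#'
#' @param cohort A `faers_cohort`.
#' @param criteria A [signal_criteria()].
#' @param pt_soc_map PT-to-SOC map.
#' @param staining_pt Index PT; `"tooth discolouration"` (the American
#'   spelling is an alias).
#' @param age_cut Exclusive upper age bound (default 8).
#' @return A list: `counts` (per-drug under-8 case counts), `signals`
#'   (tibble of staining signal rows, one per drug with at least one
#'   report), `n_under_age`. Returns a `note` when the stratum is empty.
#' @export
under8_analysis <- function(cohort, criteria = signal_criteria(),
                            pt_soc_map = read_pt_soc_map(),
                            staining_pt = "tooth discolouration",
                            age_cut = 8) {
  staining_pt <- normalize_pt(staining_pt)
  young <- cohort$background_cases$caseid[
    !is.na(cohort$background_cases$age_years) &
      cohort$background_cases$age_years < age_cut]
  if (length(young) == 0) {
    return(list(n_under_age = 0L, note = "no cases under the age cut"))
  }
  units <- cohort$background_units[cohort$background_units$caseid %in% young, ,
                                   drop = FALSE]
  targets <- cohort$case_targets[cohort$case_targets$caseid %in% young, ,
                                 drop = FALSE]
  counts <- dplyr::count(targets, .data$drug, name = "n_cases")
  drugs_present <- intersect(cohort$config$target_drugs, targets$drug)
  sig <- .screen_units(units, targets, drugs_present, criteria,
                       pt_soc_map, stoplist = character(0))
  sig <- sig[sig$pt == staining_pt, , drop = FALSE]
  list(n_under_age = length(young), counts = counts, signals = sig)
}
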