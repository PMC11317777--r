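# Reporting odds ratio disproportionality on case-level drug-event units.
#
# The analysis unit is a distinct (case, PT) pair after deduplication. For a
# target drug g and preferred term p the 2x2 table partitions all units:
#   a = cases on g reporting p            b = g's remaining units
#   c = comparator cases reporting p      d = comparator's remaining units
# where the comparator is every background case not exposed to g. A case
# suspect for two target drugs contributes to both drugs' a/b and to
# neither drug's comparator.

#' Signal criteria for disproportionality screening
#'
#' @param min_reports Minimum number of reports (`a` cell) for a signal;
#'   default 3.
#' @param z Normal quantile for the Wald confidence interval; default 1.96
#'   (95% CI).
#' @param ci_lower_threshold The CI lower bound must exceed this value;
#'   default 1.
#' @param haldane If `TRUE`, apply the Haldane-Anscombe 0.5 continuity
#'   correction to every cell of tables containing a zero (for both the
#'   point estimate and the CI). Off by default: published ROR tables for
#'   single-report rows are consistent with the uncorrected formula.
#' @return A list of class `signal_criteria`.
#' @export
signal_criteria <- function(min_reports = 3, z = 1.96,
                            ci_lower_threshold = 1, haldane = FALSE) {
  stopifnot(min_reports >= 1, z > 0)
  structure(list(min_reports = min_reports, z = z,
                 ci_lower_threshold = ci_lower_threshold,
                 haldane = isTRUE(haldane)),
            class = "signal_criteria")
}

#' Build the 2x2 contingency table for one (drug, PT) pair
#'
#' @param units Tibble of distinct case-PT pairs (`caseid`, `pt`) for the
#'   whole background population, e.g. `cohort$background_units`.
#' @param case_targets Tibble (`caseid`, `drug`) of target-drug exposure,
#'   e.g. `cohort$case_targets`.
#' @param drug Canonical drug name.
#' @param pt Preferred term (lowercase).
#' @return Named integer vector `c(a, b, c, d)`; the four cells always sum
#'   to `nrow(units)`.
#' @export
build_contingency <- function(units, case_targets, drug, pt) {
  target_cases <- unique(case_targets$caseid[case_targets$drug == drug])
  is_target <- units$caseid %in% target_cases
  has_pt <- units$pt == pt
  a <- sum(is_target & has_pt)
  b <- sum(is_target & !has_pt)
  c_ <- sum(!is_target & has_pt)
  d <- sum(!is_target & !has_pt)
  c(a = a, b = b, c = c_, d = d)
}

#' Reporting odds ratio with Wald 95% confidence interval
#'
#' Computes `ROR = (a/c)/(b/d) = ad/bc` and
#' `CI = exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Degenerate cells follow fixed conventions: `a = 0` yields ROR 0;
#' `a > 0` with `b = 0` or `c = 0` yields `Inf`; the CI is undefined (`NA`)
#' whenever any cell is 0 (unless the Haldane correction is enabled). A pair
#' is a significant signal when `a >= min_reports` and the CI lower bound
#' exceeds the threshold.
#'
#' @param a,b,c,d Cell counts (vectors of equal length are recycled
#'   together).
#' @param criteria A [signal_criteria()].
#' @return A tibble with columns `a`, `b`, `c`, `d`, `n` (= `a`), `ror`,
#'   `ci_low`, `ci_high`, `significant`.
#' @examples
#' compute_ror(10, 90, 100, 9900) # ROR 11, CI approximately 5.56-21.76
#' @export
compute_ror <- function(a, b, c, d, criteria = signal_criteria()) {
  n <- vctrs::vec_size_common(a = a, b = b, c = c, d = d)
  a <- vctrs::vec_recycle(as.numeric(a), n)
  b <- vctrs::vec_recycle(as.numeric(b), n)
  c <- vctrs::vec_recycle(as.numeric(c), n)
  d <- vctrs::vec_recycle(as.numeric(d), n)
  stopifnot(all(c(a, b, c, d) >= 0))

  any_zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (criteria$haldane) {
    aa <- ifelse(any_zero, a + 0.5, a)
    bb <- ifelse(any_zero, b + 0.5, b)
    cc <- ifelse(any_zero, c + 0.5, c)
    dd <- ifelse(any_zero, d + 0.5, d)
  } else {
    aa <- a; bb <- b; cc <- c; dd <- d
  }

  ror <- (aa * dd) / (bb * cc)
  if (!criteria$haldane) {
    ror[a == 0] <- 0
    ror[a > 0 & (b == 0 | c == 0)] <- Inf
  }

  defined <- aa > 0 & bb > 0 & cc > 0 & dd > 0
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  ci_low <- ifelse(defined, exp(log(ror) - criteria$z * se), NA_real_)
  ci_high <- ifelse(defined, exp(log(ror) + criteria$z * se), NA_real_)

  significant <- a >= criteria$min_reports & !is.na(ci_low) &
    ci_low > criteria$ci_lower_threshold

  tibble::tibble(a = a, b = b, c = c, d = d, n = a, ror = ror,
                 ci_low = ci_low, ci_high = ci_high, significant = significant)
}

# Vectorized signal screen over arbitrary unit/exposure tables; shared by
# detect_signals() and under8_analysis().
.screen_units <- function(units, case_targets, drugs, criteria,
                          pt_soc_map, stoplist) {
  n_units <- nrow(units)
  pt_totals <- dplyr::count(units, .data$pt, name = "n_pt")
  res <- lapply(drugs, function(g) {
    target_cases <- unique(case_targets$caseid[case_targets$drug == g])
    if (length(target_cases) == 0) {
      warning("drug ", g, " has no cases; excluded from results", call. = FALSE)
      return(NULL)
    }
    tu <- units[units$caseid %in% target_cases, , drop = FALSE]
    n_target_units <- nrow(tu)
    tab <- dplyr::count(tu, .data$pt, name = "a") %>%
      dplyr::left_join(pt_totals, by = "pt") %>%
      dplyr::mutate(b = n_target_units - .data$a,
                    c = .data$n_pt - .data$a,
                    d = (n_units - n_target_units) - .data$c,
                    drug = g)
    dplyr::bind_cols(tab[, c("drug", "pt")],
                     compute_ror(tab$a, tab$b, tab$c, tab$d, criteria))
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) return(out)

  i <- match(out$pt, pt_soc_map$pt)
  out$soc <- pt_soc_map$soc[i]
  n_unmapped <- sum(is.na(i))
  if (n_unmapped > 0) {
    warning(n_unmapped, " (drug, PT) pair(s) with PT absent from the PT->SOC map; ",
            "SOC set to UNMAPPED", call. = FALSE)
    out$soc[is.na(i)] <- "UNMAPPED"
  }
  out$stoplisted <- out$pt %in% stoplist
  out %>%
    dplyr::select("drug", "soc", "pt", "a", "b", "c", "d", "n", "ror",
                  "ci_low", "ci_high", "significant", "stoplisted") %>%
    dplyr::arrange(.data$drug, dplyr::desc(.data$significant),
                   dplyr::desc(.data$n), dplyr::desc(.data$ror), .data$pt)
}

#' Screen all (drug, PT) pairs for disproportionality signals
#'
#' One result row per target drug and PT with at least one report
#' (`a > 0`). Stop-listed PTs are retained but flagged so ranked tables can
#' exclude them. No multiple-testing adjustment is applied; the screen
#' implements the stated criteria only (report count and CI bound), so the
#' output is a hypothesis-generating list, not a set of confirmed risks.
#'
#' @param cohort A `faers_cohort` from [build_cohort()].
#' @param criteria A [signal_criteria()].
#' @param pt_soc_map PT-to-SOC map from [read_pt_soc_map()]; unmapped PTs
#'   get SOC `"UNMAPPED"` with a warning.
#' @param stoplist Character vector of PTs to flag, [read_stoplist()].
#' @return A tibble with columns `drug`, `soc`, `pt`, `a`, `b`, `c`, `d`,
#'   `n`, `ror`, `ci_low`, `ci_high`, `significant`, `stoplisted`, sorted by
#'   drug, then significance, report count, ROR (descending) and PT.
#' @export
detect_signals <- function(cohort, criteria = signal_criteria(),
                           pt_soc_map = read_pt_soc_map(),
                           stoplist = read_stoplist()) {
  .screen_units(cohort$background_units, cohort$case_targets,
                cohort$config$target_drugs, criteria, pt_soc_map, stoplist)
}

#' Per-drug report counts by system organ class
#'
#' For each target drug, counts its drug-event units per SOC, restricted to
#' SOCs that contain at least one significant PT for at least one drug.
#'
#' @param signals Output of [detect_signals()].
#' @param cohort The `faers_cohort` the signals were computed from.
#' @param pt_soc_map PT-to-SOC map.
#' @return A tibble `soc`, `drug`, `n`, sorted by total SOC count
#'   (descending).
#' @export
soc_summary <- function(signals, cohort, pt_soc_map = read_pt_soc_map()) {
  keep_socs <- unique(signals$soc[signals$significant])
  if (length(keep_socs) == 0) {
    return(tibble::tibble(soc = character(), drug = character(), n = integer()))
  }
  units <- dplyr::inner_join(cohort$background_units, cohort$case_targets,
                             by = "caseid", relationship = "many-to-many")
  units$soc <- pt_soc_map$soc[match(units$pt, pt_soc_map$pt)]
  units$soc[is.na(units$soc)] <- "UNMAPPED"
  out <- units %>%
    dplyr::filter(.data$soc %in% keep_socs) %>%
    dplyr::count(.data$soc, .data$drug, name = "n")
  totals <- out %>% dplyr::summarise(total = sum(.data$n), .by = "soc")
  out %>%
    dplyr::left_join(totals, by = "soc") %>%
    dplyr::arrange(dplyr::desc(.data$total), .data$soc, .data$drug) %>%
    dplyr::select(-"total")
}

#' Top-k significant signals for one drug, side-by-side across drugs
#'
#' Ranks a drug's significant, non-stop-listed PTs by report count
#' (ties: larger ROR first, then PT alphabetically), truncates to `k`, and
#' attaches every other drug's `n`, `ror` and CI for the same PTs, mirroring
#' the usual side-by-side comparison layout.
#'
#' @param signals Output of [detect_signals()].
#' @param drug Canonical drug name to rank.
#' @param k Number of rows (default 20); fewer are returned without padding
#'   when the drug has fewer significant PTs.
#' @return A tibble with `soc`, `pt` and, per drug `<g>`, columns `n_<g>`,
#'   `ror_<g>`, `ci_low_<g>`, `ci_high_<g>`, `significant_<g>`.
#' @export
top_k_signals <- function(signals, drug, k = 20) {
  ranked <- signals %>%
    dplyr::filter(.data$drug == !!drug, .data$significant, !.data$stoplisted) %>%
    dplyr::arrange(dplyr::desc(.data$n), dplyr::desc(.data$ror), .data$pt) %>%
    utils::head(k)
  if (nrow(ranked) == 0) return(ranked)
  wide <- signals %>%
    dplyr::filter(.data$pt %in% ranked$pt) %>%
    dplyr::select("drug", "pt", "n", "ror", "ci_low", "ci_high", "significant") %>%
    tidyr::pivot_wider(names_from = "drug",
                       values_from = c("n", "ror", "ci_low", "ci_high", "significant"))
  ranked %>%
    dplyr::select("soc", "pt") %>%
    dplyr::left_join(wide, by = "pt")
}

#' Display-round an ROR value
#'
#' Published convention: two decimals, ties rounded up.
#'
#' @param x Numeric vector of RORs or CI bounds.
#' @return Rounded values.
#' @export
format_ror <- function(x) round_half_up(x, 2)
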