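# End-to-end pipeline: load -> validate -> deduplicate -> cohort ->
# signals -> descriptives, writing every artifact (funnel, baseline, signal
# tables, top-k tables, SOC summary, subgroups, co-occurrence, under-8) plus
# a manifest with content hashes. The funnel counts are a first-class
# output: every filter stage is logged and exported.

#' Pipeline run configuration
#'
#' Bundles paths and analysis settings for [run_pipeline()]. Reference
#' tables default to the dictionaries shipped with the package.
#'
#' @param data_dir Directory with the six "$"-delimited quarterly tables.
#' @param out_dir Output directory for artifacts (created if needed).
#' @param dictionary_path,pt_soc_path,alias_path,stoplist_path Optional
#'   paths overriding the packaged reference tables.
#' @param window_start,window_end,age_min_years,age_max_years,roles_included,target_drugs,background_scope
#'   Cohort settings, see [cohort_config()].
#' @param min_reports,z,ci_lower_threshold,haldane Signal criteria, see
#'   [signal_criteria()].
#' @param top_k Rows per ranked signal table (default 20).
#' @return A list of class `run_config`.
#' @export
run_config <- function(data_dir, out_dir,
                       dictionary_path = NULL, pt_soc_path = NULL,
                       alias_path = NULL, stoplist_path = NULL,
                       window_start = 20050101, window_end = 20230930,
                       age_min_years = 0, age_max_years = 18,
                       roles_included = c("PS", "SS"),
                       target_drugs = c("DOXYCYCLINE", "MINOCYCLINE", "TIGECYCLINE"),
                       background_scope = "pediatric",
                       min_reports = 3, z = 1.96, ci_lower_threshold = 1,
                       haldane = FALSE, top_k = 20) {
  for (p in c(dictionary_path, pt_soc_path, alias_path, stoplist_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured path does not exist: ", p, call. = FALSE)
    }
  }
  structure(list(
    data_dir = data_dir, out_dir = out_dir,
    dictionary_path = dictionary_path, pt_soc_path = pt_soc_path,
    alias_path = alias_path, stoplist_path = stoplist_path,
    cohort = cohort_config(window_start, window_end, age_min_years,
                           age_max_years, roles_included, target_drugs,
                           background_scope),
    criteria = signal_criteria(min_reports, z, ci_lower_threshold, haldane),
    top_k = top_k), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

.write_tsv <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ";")
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

.baseline_long <- function(baseline) {
  dplyr::bind_rows(lapply(names(baseline), function(g) {
    b <- baseline[[g]]
    dplyr::bind_rows(
      tibble::tibble(drug = g, block = "n_cases", level = "total",
                     n = b$n_cases, pct = NA_real_),
      tibble::tibble(drug = g, block = "age_median_q1_q3",
                     level = c("median", "q1", "q3"),
                     n = NA_integer_,
                     pct = c(b$age$median, b$age$q1, b$age$q3)),
      dplyr::mutate(b$age_bands, drug = g, block = "age_band"),
      dplyr::mutate(b$sex, drug = g, block = "sex"),
      dplyr::mutate(b$countries, drug = g, block = "country_top5"),
      dplyr::mutate(b$outcomes, drug = g, block = "outcome_most_severe"),
      dplyr::mutate(dplyr::rename(b$received_years, level = "period"),
                    drug = g, block = "received_year", pct = NA_real_),
      dplyr::mutate(dplyr::rename(b$indications, level = "indication"),
                    drug = g, block = "indication_top5", pct = NA_real_))
  }))
}

.subgroup_long <- function(sg) {
  if (sg$n_total == 0) {
    return(tibble::tibble(block = "note", level = sg$note, value = 0))
  }
  dplyr::bind_rows(
    tibble::tibble(block = "n_total", level = "total", value = sg$n_total),
    tibble::tibble(block = "count", level = sg$counts$row, value = sg$counts$n),
    tibble::tibble(block = "sex", level = sg$sex$level, value = sg$sex$n),
    tibble::tibble(block = "age", level = c("median", "q1", "q3"),
                   value = unname(sg$age)),
    tibble::tibble(block = "onset_median",
                   level = sg$onset$drug, value = sg$onset$median),
    tibble::tibble(block = "outcome", level = sg$outcomes$level,
                   value = sg$outcomes$n))
}

#' Run the full pipeline and write its artifact set
#'
#' Executes load, integrity validation, deduplication, cohort construction,
#' disproportionality screening and all descriptive analyses, writing each
#' artifact as a tab-delimited UTF-8 file plus a JSON manifest listing every
#' emitted file with its MD5 content hash. Identical inputs and
#' configuration produce identical artifact contents (the manifest timestamp
#' aside).
#'
#' @param cfg A [run_config()].
#' @param db Optional in-memory `faers_db`; when supplied, `cfg$data_dir`
#'   is not read.
#' @return The manifest (a list), invisibly. Artifacts:
#'   `validation.tsv`, `funnel.tsv`, `per_drug.tsv`, `baseline.tsv`,
#'   `signals.tsv`, `top<k>_<drug>.tsv`, `soc_summary.tsv`,
#'   `subgroup_<name>.tsv`, `cooccurrence_<drug>_dress.tsv`,
#'   `under8.tsv`, `manifest.json`.
#' @export
run_pipeline <- function(cfg, db = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(x, name) {
    written <<- c(written, .write_tsv(x, file.path(out, name)))
    invisible(NULL)
  }

  dictionary <- if (is.null(cfg$dictionary_path)) read_drug_dictionary()
                else read_drug_dictionary(cfg$dictionary_path)
  pt_soc <- if (is.null(cfg$pt_soc_path)) read_pt_soc_map()
            else read_pt_soc_map(cfg$pt_soc_path)
  aliases <- if (is.null(cfg$alias_path)) read_pt_aliases()
             else read_pt_aliases(cfg$alias_path)
  stoplist <- if (is.null(cfg$stoplist_path)) read_stoplist()
              else read_stoplist(cfg$stoplist_path)

  if (is.null(db)) db <- load_faers_db(cfg$data_dir)
  val <- validate_faers_db(db)
  emit(tibble::tibble(check = c(paste0("orphans_", names(val$orphans)),
                                "ther_unlinked_drug_seq",
                                "duplicate_primaryid"),
                      n = c(val$orphans, val$ther_unlinked_drug_seq,
                            val$n_duplicate_primaryid)),
       "validation.tsv")
  if (!val$ok) {
    stop("validation failed: DEMO contains duplicate primaryids", call. = FALSE)
  }

  db$demo <- deduplicate_reports(db$demo)
  cohort <- build_cohort(db, cfg$cohort, dictionary, aliases)
  emit(cohort$funnel, "funnel.tsv")
  emit(cohort$per_drug, "per_drug.tsv")

  baseline <- summarize_baseline(cohort)
  emit(.baseline_long(baseline), "baseline.tsv")

  signals <- detect_signals(cohort, cfg$criteria, pt_soc, stoplist)
  emit(signals, "signals.tsv")
  for (g in intersect(cfg$cohort$target_drugs, signals$drug)) {
    topk <- top_k_signals(signals, g, cfg$top_k)
    if (nrow(topk) > 0) {
      emit(topk, sprintf("top%d_%s.tsv", cfg$top_k, tolower(g)))
    }
  }
  emit(soc_summary(signals, cohort, pt_soc), "soc_summary.tsv")

  for (nm in names(subgroup_presets())) {
    sg <- subgroup_table(cohort, subgroup_presets()[[nm]])
    emit(.subgroup_long(sg), sprintf("subgroup_%s.tsv", nm))
  }

  dress_pt <- subgroup_presets()$dress$pts
  for (g in cfg$cohort$target_drugs) {
    ids <- cohort$case_targets$caseid[cohort$case_targets$drug == g]
    hit <- any(cohort$case_pts$pt[cohort$case_pts$caseid %in% ids] %in% dress_pt)
    if (hit) {
      emit(cooccurrence_profile(cohort, g, dress_pt),
           sprintf("cooccurrence_%s_dress.tsv", tolower(g)))
    }
  }

  u8 <- under8_analysis(cohort, cfg$criteria, pt_soc)
  if (!is.null(u8$signals) && nrow(u8$signals) > 0) {
    emit(dplyr::left_join(u8$counts, u8$signals, by = "drug"), "under8.tsv")
  } else {
    emit(u8$counts %||% tibble::tibble(drug = character(), n_cases = integer()),
         "under8.tsv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("faerspv")),
    generated_at = format(Sys.time(), tz = "UTC"),
    config = list(window = c(cfg$cohort$window_start, cfg$cohort$window_end),
                  age = c(cfg$cohort$age_min_years, cfg$cohort$age_max_years),
                  roles = cfg$cohort$roles_included,
                  target_drugs = cfg$cohort$target_drugs,
                  background_scope = cfg$cohort$background_scope,
                  min_reports = cfg$criteria$min_reports, z = cfg$criteria$z,
                  top_k = cfg$top_k),
    files = lapply(stats::setNames(written, basename(written)), function(f) {
      list(md5 = unname(tools::md5sum(f)), bytes = file.size(f))
    }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
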