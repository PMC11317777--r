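#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# Canonical column layout of the six quarterly tables ("$"-delimited ASCII,
# header row, UTF-8). Headers are matched case-insensitively; extra columns
# are preserved verbatim after the typed ones.
.faers_tables <- list(
  DEMO = c("primaryid", "caseid", "fda_dt", "event_dt", "rept_dt",
           "age", "age_cod", "sex", "occr_country"),
  DRUG = c("primaryid", "drug_seq", "role_cod", "drugname"),
  REAC = c("primaryid", "pt"),
  OUTC = c("primaryid", "outc_cod"),
  INDI = c("primaryid", "indi_drug_seq", "indi_pt"),
  THER = c("primaryid", "dsg_drug_seq", "start_dt")
)

.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
.role_codes <- c("PS", "SS", "C", "I")
.age_codes <- c("DEC", "YR", "MON", "WK", "DY", "HR")

.blank_to_na <- function(x) {
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  trimws(x)
}

#' Read one FAERS-style quarterly table
#'
#' Parses a "$"-delimited ASCII file with a header row into a typed tibble.
#' Records failing validation (malformed dates, unknown outcome/role codes,
#' missing identifiers) are skipped; the skip count and per-record problems
#' are attached as attributes so that `lines = records + skips` always
#' reconciles.
#'
#' @param path Path to the delimited file.
#' @param kind One of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`, `"INDI"`,
#'   `"THER"` (case-insensitive).
#' @return A tibble, one row per retained record, with attributes
#'   `n_lines` (data lines read), `n_skipped`, and `problems` (a tibble with
#'   columns `line`, `problem`). Partial dates (`event_dt`, `start_dt`) carry
#'   a companion `<col>_prec` column with values `"day"`, `"month"`,
#'   `"year"` or `NA`. Duplicate OUTC rows (same report and code) collapse to
#'   one, since outcome codes form a set.
#' @seealso [write_faers_table()] for the exact inverse, [load_faers_db()]
#'   to read a whole database directory.
#' @export
read_faers_table <- function(path, kind) {
  kind <- toupper(kind)
  if (!kind %in% names(.faers_tables)) {
    stop("unknown table kind '", kind, "'; expected one of ",
         paste(names(.faers_tables), collapse = ", "), call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) stop("empty file (no header): ", path, call. = FALSE)

  header <- tolower(strsplit(lines[[1]], "$", fixed = TRUE)[[1]])
  required <- .faers_tables[[kind]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0) {
    stop("format error in ", kind, " file '", path, "': missing required column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  body <- lines[-1]
  n_lines <- length(body)
  parts <- strsplit(body, "$", fixed = TRUE)
  ncols <- length(header)
  mat <- matrix(NA_character_, nrow = n_lines, ncol = ncols)
  for (j in seq_len(ncols)) {
    mat[, j] <- vapply(parts, function(p) if (length(p) >= j) p[[j]] else NA_character_,
                       character(1))
  }
  raw <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                           .name_repair = "minimal")
  names(raw) <- header
  raw <- dplyr::mutate(raw, dplyr::across(dplyr::everything(), .blank_to_na))
  extra_cols <- setdiff(header, required)

  typed <- .type_faers_table(raw, kind)
  problems <- typed$problems
  out <- typed$tbl
  if (length(extra_cols) > 0) out <- dplyr::bind_cols(out, typed$raw_kept[extra_cols])

  if (kind == "OUTC") out <- dplyr::distinct(out)

  attr(out, "n_lines") <- n_lines
  attr(out, "n_skipped") <- n_lines - typed$n_kept
  attr(out, "problems") <- problems
  out
}

# Type/validate one raw table; returns list(tbl, raw_kept, n_kept, problems).
.type_faers_table <- function(raw, kind) {
  n <- nrow(raw)
  bad <- rep(FALSE, n)
  problems <- list()
  note <- function(idx, what) {
    if (any(idx)) {
      problems[[length(problems) + 1]] <<- tibble::tibble(
        line = which(idx) + 1L, problem = what)
      bad <<- bad | idx
    }
  }

  if (kind == "DEMO") {
    fda <- parse_partial_date(raw$fda_dt)
    note(is.na(raw$primaryid) | is.na(raw$caseid), "missing primaryid/caseid")
    note(is.na(fda$prec) | fda$prec != "day", "malformed fda_dt (full date required)")
    ev <- parse_partial_date(raw$event_dt)
    note(!is.na(ev$prec) & ev$prec == "invalid", "malformed event_dt")
    rp <- parse_partial_date(raw$rept_dt)
    note(!is.na(rp$prec) & rp$prec == "invalid", "malformed rept_dt")
    age <- suppressWarnings(as.numeric(raw$age))
    note(!is.na(raw$age) & is.na(age), "non-numeric age")
    tbl <- tibble::tibble(
      primaryid = raw$primaryid, caseid = raw$caseid,
      fda_dt = fda$value, event_dt = ev$value, event_dt_prec = ev$prec,
      rept_dt = rp$value, age = age, age_cod = toupper(raw$age_cod),
      sex = toupper(raw$sex), occr_country = raw$occr_country)
  } else if (kind == "DRUG") {
    seq <- suppressWarnings(as.integer(raw$drug_seq))
    role <- toupper(raw$role_cod)
    note(is.na(raw$primaryid), "missing primaryid")
    note(is.na(seq), "missing/non-integer drug_seq")
    note(is.na(role) | !role %in% .role_codes, "unknown role_cod")
    note(is.na(raw$drugname), "missing drugname")
    tbl <- tibble::tibble(primaryid = raw$primaryid, drug_seq = seq,
                          role_cod = role, drugname = raw$drugname)
  } else if (kind == "REAC") {
    note(is.na(raw$primaryid), "missing primaryid")
    note(is.na(raw$pt), "empty pt")
    tbl <- tibble::tibble(primaryid = raw$primaryid, pt = raw$pt)
  } else if (kind == "OUTC") {
    code <- toupper(raw$outc_cod)
    note(is.na(raw$primaryid), "missing primaryid")
    note(is.na(code) | !code %in% .outcome_codes, "unknown outc_cod")
    tbl <- tibble::tibble(primaryid = raw$primaryid, outc_cod = code)
  } else if (kind == "INDI") {
    seq <- suppressWarnings(as.integer(raw$indi_drug_seq))
    note(is.na(raw$primaryid), "missing primaryid")
    note(is.na(seq), "missing/non-integer indi_drug_seq")
    tbl <- tibble::tibble(primaryid = raw$primaryid, indi_drug_seq = seq,
                          indi_pt = raw$indi_pt)
  } else { # THER
    seq <- suppressWarnings(as.integer(raw$dsg_drug_seq))
    st <- parse_partial_date(raw$start_dt)
    note(is.na(raw$primaryid), "missing primaryid")
    note(is.na(seq), "missing/non-integer dsg_drug_seq")
    note(!is.na(st$prec) & st$prec == "invalid", "malformed start_dt")
    tbl <- tibble::tibble(primaryid = raw$primaryid, dsg_drug_seq = seq,
                          start_dt = st$value, start_dt_prec = st$prec)
  }

  keep <- !bad
  list(tbl = tbl[keep, , drop = FALSE],
       raw_kept = raw[keep, , drop = FALSE],
       n_kept = sum(keep),
       problems = if (length(problems)) dplyr::bind_rows(problems)
                  else tibble::tibble(line = integer(), problem = character()))
}

#' Write one FAERS-style quarterly table
#'
#' Exact inverse of [read_faers_table()]: emits a "$"-delimited file with a
#' header row such that reading it back reproduces the input tibble
#' field-for-field. Missing values become empty fields; `<col>_prec`
#' companion columns are implicit in the digit width of the written date and
#' are not emitted.
#'
#' @param tbl A tibble as returned by [read_faers_table()] (an empty tibble
#'   yields a header-only file).
#' @param path Output path.
#' @param kind Table kind, as in [read_faers_table()].
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(tbl, path, kind) {
  kind <- toupper(kind)
  if (!kind %in% names(.faers_tables)) {
    stop("unknown table kind '", kind, "'", call. = FALSE)
  }
  required <- .faers_tables[[kind]]
  drop <- grep("_prec$", names(tbl), value = TRUE)
  cols <- c(required, setdiff(names(tbl), c(required, drop)))
  out <- tbl[intersect(cols, names(tbl))]
  chr <- lapply(out, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  lines <- c(paste(names(out), collapse = "$"),
             if (nrow(out) > 0) do.call(paste, c(chr, sep = "$")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Load a six-table FAERS-style database from a directory
#'
#' Expects files `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `OUTC.txt` and
#' optionally `INDI.txt`, `THER.txt` (names configurable via `files`).
#'
#' @param dir Directory containing the delimited files.
#' @param files Named character vector mapping table kinds to file names.
#' @return A `faers_db`: a named list of tibbles
#'   (`demo`, `drug`, `reac`, `outc`, `indi`, `ther`).
#' @export
load_faers_db <- function(dir,
                          files = c(DEMO = "DEMO.txt", DRUG = "DRUG.txt",
                                    REAC = "REAC.txt", OUTC = "OUTC.txt",
                                    INDI = "INDI.txt", THER = "THER.txt")) {
  read1 <- function(kind, optional = FALSE) {
    p <- file.path(dir, files[[kind]])
    if (!file.exists(p)) {
      if (optional) return(NULL)
      stop("missing ", kind, " file: ", p, call. = FALSE)
    }
    read_faers_table(p, kind)
  }
  db <- list(demo = read1("DEMO"), drug = read1("DRUG"), reac = read1("REAC"),
             outc = read1("OUTC"), indi = read1("INDI", optional = TRUE),
             ther = read1("THER", optional = TRUE))
  structure(db, class = "faers_db")
}

#' Write a database as six delimited files
#'
#' @param db A `faers_db` (see [load_faers_db()], [generate_database()]).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_faers_db <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kinds <- c(demo = "DEMO", drug = "DRUG", reac = "REAC",
             outc = "OUTC", indi = "INDI", ther = "THER")
  for (nm in names(kinds)) {
    if (!is.null(db[[nm]])) {
      write_faers_table(db[[nm]], file.path(dir, paste0(kinds[[nm]], ".txt")),
                        kinds[[nm]])
    }
  }
  invisible(dir)
}

#' Merge outcome rows into per-report outcome sets
#'
#' @param outc The OUTC tibble (`primaryid`, `outc_cod`).
#' @return A tibble with `primaryid` and a list-column `outcome_codes`
#'   holding the sorted, de-duplicated set of codes per report. The result is
#'   invariant to the order of the input rows.
#' @export
outcome_sets <- function(outc) {
  outc %>%
    dplyr::distinct(.data$primaryid, .data$outc_cod) %>%
    dplyr::arrange(.data$primaryid, .data$outc_cod) %>%
    dplyr::summarise(outcome_codes = list(.data$outc_cod), .by = "primaryid")
}

#' Referential-integrity report for a loaded database
#'
#' Counts child rows (DRUG/REAC/OUTC/INDI/THER) whose `primaryid` does not
#' appear in DEMO, THER rows whose (`primaryid`, `drug_seq`) pair has no DRUG
#' row, and duplicated `primaryid`s in DEMO. The pipeline refuses to proceed
#' on duplicated primaryids; orphans are reported but tolerated.
#'
#' @param db A `faers_db`.
#' @return A list with `orphans` (named integer vector per child table),
#'   `n_duplicate_primaryid`, and `ok` (`TRUE` iff no duplicate primaryids),
#'   of class `faers_validation`.
#' @export
validate_faers_db <- function(db) {
  ids <- db$demo$primaryid
  orphan <- function(tbl) {
    if (is.null(tbl)) return(0L)
    sum(!tbl$primaryid %in% ids)
  }
  orphans <- c(drug = orphan(db$drug), reac = orphan(db$reac),
               outc = orphan(db$outc), indi = orphan(db$indi),
               ther = orphan(db$ther))
  ther_unlinked <- 0L
  if (!is.null(db$ther) && nrow(db$ther) > 0) {
    key <- paste(db$ther$primaryid, db$ther$dsg_drug_seq)
    drug_key <- paste(db$drug$primaryid, db$drug$drug_seq)
    ther_unlinked <- sum(!key %in% drug_key)
  }
  res <- list(orphans = orphans,
              ther_unlinked_drug_seq = ther_unlinked,
              n_duplicate_primaryid = sum(duplicated(ids)),
              ok = !anyDuplicated(ids))
  class(res) <- "faers_validation"
  res
}

#' @export
print.faers_validation <- function(x, ...) {
  cat("FAERS database integrity report\n")
  cat("  orphan child rows:",
      paste(sprintf("%s=%d", names(x$orphans), x$orphans), collapse = " "), "\n")
  cat("  THER rows with no matching DRUG row:", x$ther_unlinked_drug_seq, "\n")
  cat("  duplicated primaryids in DEMO:", x$n_duplicate_primaryid, "\n")
  cat(if (x$ok) "  OK: primaryids unique\n" else "  NOT OK: duplicate primaryids\n")
  invisible(x)
}

#' @export
print.faers_db <- function(x, ...) {
  cat("<faers_db>\n")
  for (nm in names(x)) {
    if (!is.null(x[[nm]])) cat(sprintf("  %-5s %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
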