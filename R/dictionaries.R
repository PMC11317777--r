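# Flat reference tables: drug synonym dictionary, PT -> primary-SOC map,
# PT spelling aliases, and the stop-list of drug-unrelated PTs. All ship as
# plain delimited files under inst/extdata and can be replaced by the user.

.extdata <- function(file) {
  system.file("extdata", file, package = "faerspv", mustWork = TRUE)
}

#' Read a drug synonym dictionary
#'
#' Two-column delimited file mapping each canonical (generic) drug name to
#' the verbatim synonyms under which it appears in reports: generic names,
#' brand names, salts/formulations, research codes. Matching is exact after
#' whitespace/case normalization; no fuzzy matching.
#'
#' @param path Path to a tab-delimited file with columns `canonical_drug`
#'   and `synonym`; default is the tetracycline dictionary shipped with the
#'   package (doxycycline, minocycline, tigecycline).
#' @return A tibble with columns `canonical` and `synonym`, both uppercase.
#' @export
read_drug_dictionary <- function(path = .extdata("drug_synonyms.tsv")) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("canonical_drug", "synonym") %in% names(d))) {
    stop("drug dictionary must have columns canonical_drug, synonym", call. = FALSE)
  }
  tibble::tibble(canonical = toupper(trimws(d$canonical_drug)),
                 synonym = toupper(stringr::str_squish(d$synonym)))
}

#' Read a PT to primary-SOC mapping
#'
#' A flat two-column stand-in for the MedDRA hierarchy: each preferred term
#' maps to exactly one primary system organ class. Duplicate PT entries are
#' an error.
#'
#' @param path Tab-delimited file with columns `pt` and `soc`; default is the
#'   map shipped with the package covering the PT vocabulary used by the
#'   synthetic generator.
#' @return A tibble with columns `pt` (lowercase) and `soc`.
#' @export
read_pt_soc_map <- function(path = .extdata("pt_soc_map.tsv")) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pt", "soc") %in% names(d))) {
    stop("PT->SOC map must have columns pt, soc", call. = FALSE)
  }
  out <- tibble::tibble(pt = tolower(trimws(d$pt)), soc = trimws(d$soc))
  if (anyDuplicated(out$pt)) {
    stop("PT->SOC map assigns more than one SOC to: ",
         paste(unique(out$pt[duplicated(out$pt)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' PT spelling alias table
#'
#' MedDRA uses British spellings ("oesophagitis", "tooth discolouration");
#' source tables mix British and American forms. This table resolves each
#' alias to the canonical PT before any counting.
#'
#' @param path Tab-delimited file with columns `alias` and `pt`.
#' @return A tibble with columns `alias` and `pt`, lowercase.
#' @export
read_pt_aliases <- function(path = .extdata("pt_aliases.tsv")) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  tibble::tibble(alias = tolower(trimws(d$alias)), pt = tolower(trimws(d$pt)))
}

#' Normalize PT spellings
#'
#' Lowercases, squeezes whitespace, and resolves spelling aliases to the
#' canonical preferred term.
#'
#' @param pt Character vector of PT strings.
#' @param aliases Alias table from [read_pt_aliases()].
#' @return Character vector of canonical lowercase PTs.
#' @export
normalize_pt <- function(pt, aliases = read_pt_aliases()) {
  x <- tolower(stringr::str_squish(pt))
  i <- match(x, aliases$alias)
  x[!is.na(i)] <- aliases$pt[i[!is.na(i)]]
  x
}

#' Stop-list of PTs excluded from signal tables
#'
#' PTs that are clearly unrelated to drug causality in ranked signal tables
#' (ineffectiveness, disease-course and product-use terms). Stop-listed PTs
#' are still scored and retained in the full signal output, only flagged for
#' exclusion from top-k tables.
#'
#' @param path One-PT-per-line text file; default is the shipped list
#'   (death, drug ineffective, condition aggravated, treatment failure,
#'   drug resistance, sepsis, off label use).
#' @return Character vector of lowercase PTs.
#' @export
read_stoplist <- function(path = .extdata("stoplist.txt")) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- tolower(trimws(x))
  x[nzchar(x)]
}

#' Ineffectiveness / product-issue PT list for the fatal-case drill-down
#'
#' Default PTs whose presence in a fatal case marks it as involving drug
#' ineffectiveness or a product-use issue rather than a toxicity signal.
#'
#' @return Character vector of lowercase PTs.
#' @export
ineffectiveness_pts <- function() {
  c("drug ineffective", "drug ineffective for unapproved indication",
    "treatment failure", "drug resistance", "intentional product use issue",
    "multiple drug resistance", "product use issue")
}
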