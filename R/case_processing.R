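# Case-level processing: deduplication, primary-suspect drug selection via a
# synonym list, age conversion/banding, PT -> SOC mapping, and assembly of
# one analysis-ready record per report.

#' Deduplicate FAERS case versions
#'
#' FAERS carries multiple versions of the same case under one `caseid`. The
#' FDA-recommended rule keeps, within each `caseid`, the version with the
#' largest FDA receipt date (`fda_dt`), breaking ties by the largest
#' `primaryid`. Dates are compared on their numeric `yyyymmdd` form with
#' missing month/day padded with zeros, so a lower-precision date sorts
#' earlier; an unparsable `fda_dt` sorts before any parsable one.
#'
#' The operation is idempotent and retains exactly one `primaryid` per
#' distinct `caseid`.
#'
#' @param demo DEMO data frame with columns `primaryid`, `caseid`, `fda_dt`.
#' @return character vector of retained `primaryid`s.
#' @export
deduplicate <- function(demo) {
  if (nrow(demo) == 0) return(character())
  key_dt <- partial_date_key(demo$fda_dt)
  key_dt[is.na(key_dt)] <- -Inf
  pid_num <- suppressWarnings(as.numeric(demo$primaryid))
  # digit-string ids compare numerically; fall back to lexicographic rank
  if (anyNA(pid_num)) pid_num <- xtfrm(demo$primaryid)
  ord <- order(demo$caseid, key_dt, pid_num)
  sorted <- demo[ord, , drop = FALSE]
  keep <- !duplicated(sorted$caseid, fromLast = TRUE)
  sorted$primaryid[keep]
}

#' Load a drug synonym list
#'
#' One name per line; `#` starts a comment; blank lines ignored. Names are
#' stored accent-folded, upper-cased and trimmed for matching.
#'
#' @param path path to the synonym file.
#' @return character vector of match keys (class `"synonym_list"`).
#' @export
read_synonyms <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  synonym_list(lines[lines != ""])
}

#' @rdname read_synonyms
#' @param names character vector of verbatim drug names.
#' @export
synonym_list <- function(names) {
  keys <- unique(norm_text(names))
  keys <- keys[keys != ""]
  if (!length(keys)) stop("synonym list is empty", call. = FALSE)
  structure(keys, class = "synonym_list")
}

#' Bundled lorazepam screening keywords
#'
#' The verbatim trade and generic names used to screen free-text drug names
#' for lorazepam: lorazepam, ATIVAN, LORAZ, LOREEV XR, Temesta, Donix,
#' Duralozam, Laubeel.
#'
#' @return a `"synonym_list"`.
#' @export
lorazepam_synonyms <- function() {
  read_synonyms(system.file("extdata", "lorazepam_synonyms.txt",
                            package = "faerspv", mustWork = TRUE))
}

#' Match verbatim drug names against a synonym list
#'
#' True where any synonym occurs as a case-insensitive, accent-folded
#' substring of the verbatim drug name or (when given) the active-ingredient
#' string. This mirrors keyword screening of free-text FAERS drug names,
#' where "ATIVAN 1MG TAB" must hit the keyword "ATIVAN".
#'
#' @param name character vector of verbatim drug names.
#' @param syn a [synonym_list()].
#' @param prod_ai optional character vector of active-ingredient strings,
#'   recycled against `name`.
#' @return logical vector.
#' @export
match_drug_name <- function(name, syn, prod_ai = NULL) {
  stopifnot(inherits(syn, "synonym_list"))
  hay <- norm_text(name)
  if (!is.null(prod_ai)) hay <- paste(hay, norm_text(prod_ai), sep = " | ")
  hit <- rep(FALSE, length(hay))
  for (key in syn) hit <- hit | grepl(key, hay, fixed = TRUE)
  hit & !is.na(hay)
}

#' Select reports with a matching primary-suspect drug
#'
#' A report qualifies when at least one of its DRUG rows has role code `PS`
#' and a drug name (or active ingredient) matching the synonym list.
#' Restricting to the primary suspect keeps the drug-event attribution
#' specific: secondary suspects and concomitants do not qualify a report.
#'
#' @param drug DRUG data frame.
#' @param retained primaryids retained by [deduplicate()].
#' @param syn a [synonym_list()].
#' @return character vector of qualifying `primaryid`s (subset of `retained`).
#' @export
select_primary_suspect <- function(drug, retained, syn) {
  ps <- drug[drug$role_cod == "PS" &
               match_drug_name(drug$drugname, syn, drug$prod_ai), , drop = FALSE]
  intersect(retained, unique(ps$primaryid))
}

#' Convert reported ages to years
#'
#' FAERS ages carry a unit code: DEC (decades), YR, MON, WK, DY, HR. Weeks
#' use the mean Gregorian year of 365.25 days (52.1775 weeks, 8766 hours).
#' Unknown codes or negative values yield `NA`.
#'
#' @param value numeric vector of reported ages.
#' @param unit_code character vector of unit codes, recycled against `value`.
#' @return numeric vector of ages in years.
#' @export
#' @examples
#' convert_age(c(5, 24, 730.5), c("DEC", "MON", "DY"))
convert_age <- function(value, unit_code) {
  factor_map <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
                  DY = 1 / 365.25, HR = 1 / 8766)
  f <- factor_map[toupper(as.character(unit_code))]
  v <- suppressWarnings(as.numeric(value))
  out <- v * as.numeric(f)
  out[!is.na(v) & v < 0] <- NA_real_
  out
}

#' Assign the standard reporting age bands
#'
#' Bands partition age in years as half-open intervals: `<18` for ages below
#' 18, `18-65` for 18 up to (but excluding) 65, `>=65` from 65 up. A missing
#' age maps to `"unknown"`. Exactly 65.0 falls in `>=65` so the bands
#' partition.
#'
#' @param age_years numeric vector.
#' @return character vector over `c("<18", "18-65", ">=65", "unknown")`.
#' @export
assign_age_band <- function(age_years) {
  out <- rep("unknown", length(age_years))
  known <- !is.na(age_years)
  out[known & age_years < 18] <- "<18"
  out[known & age_years >= 18 & age_years < 65] <- "18-65"
  out[known & age_years >= 65] <- ">=65"
  out
}

#' @noRd
age_band_levels <- function() c("<18", "18-65", ">=65", "unknown")

#' Load a PT to SOC mapping table
#'
#' MedDRA itself is licensed and cannot ship with the package, so the map is
#' a user-supplied two-column delimited table (`pt`, `soc`). Lookup keys are
#' whitespace- and case-normalised.
#'
#' @param path path to the delimited file.
#' @param delim field delimiter (default tab).
#' @return a `"pt_soc_map"` object.
#' @export
read_pt_soc_map <- function(path, delim = "\t") {
  tab <- utils::read.table(path, sep = delim, header = TRUE, quote = "",
                           comment.char = "#", colClasses = "character",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  names(tab) <- tolower(names(tab))
  if (!all(c("pt", "soc") %in% names(tab))) {
    stop("PT->SOC map needs columns 'pt' and 'soc'", call. = FALSE)
  }
  pt_soc_map(tab$pt, tab$soc)
}

#' @rdname read_pt_soc_map
#' @param pt character vector of Preferred Terms.
#' @param soc character vector of System Organ Classes, parallel to `pt`.
#' @export
pt_soc_map <- function(pt, soc) {
  stopifnot(length(pt) == length(soc))
  key <- norm_text(pt)
  keep <- !duplicated(key)
  structure(list(key = key[keep], soc = trimws(soc[keep])),
            class = "pt_soc_map")
}

#' Map Preferred Terms to their System Organ Class
#'
#' Deterministic lookup after whitespace/case normalisation; a PT absent from
#' the map yields the value `"unmapped"` (not an error).
#'
#' @param pt character vector of PT strings.
#' @param map a `"pt_soc_map"`.
#' @return character vector of SOC names.
#' @export
map_pt_to_soc <- function(pt, map) {
  stopifnot(inherits(map, "pt_soc_map"))
  idx <- match(norm_text(pt), map$key)
  out <- map$soc[idx]
  out[is.na(idx)] <- "unmapped"
  out
}

#' Bundled synthetic PT to SOC map
#'
#' A small fixture covering the Preferred Terms emitted by the synthetic
#' generator plus a handful of common terms. It is not MedDRA; SOC
#' assignments follow common usage but the file is synthetic.
#'
#' @return a `"pt_soc_map"`.
#' @export
synthetic_pt_soc_map <- function() {
  read_pt_soc_map(system.file("extdata", "pt_soc_map_synthetic.tsv",
                              package = "faerspv", mustWork = TRUE))
}

#' Assemble analysis-ready case reports
#'
#' Collapses the five FAERS tables into one row per deduplicated report:
#' demographics, outcome codes, the set of distinct reaction PTs (a PT
#' reported twice in one report counts once), the primary-suspect drug names,
#' a target-drug flag from synonym screening, and the earliest full-precision
#' therapy start date among primary-suspect drugs.
#'
#' @param tables named list with elements `demo`, `drug`, `reac`, and
#'   optionally `ther`, `outc`, as from [read_faers_tables()] or
#'   [synth_faers()].
#' @param syn a [synonym_list()] defining the target drug.
#' @return a data frame of class `"faers_cases"`, one row per retained
#'   report, with list columns `reaction_pts`, `outcome_codes`,
#'   `suspect_drugs` and logical column `is_target`. Attribute `flow` records
#'   the raw-row, post-dedup and post-drug-filter counts.
#' @export
build_case_reports <- function(tables, syn) {
  demo <- tables$demo
  if (is.null(demo) || nrow(demo) == 0) stop("DEMO table is empty", call. = FALSE)
  retained <- deduplicate(demo)
  demo <- demo[match(retained, demo$primaryid), , drop = FALSE]

  target_ids <- if (!is.null(tables$drug)) {
    select_primary_suspect(tables$drug, retained, syn)
  } else character()

  cases <- data.frame(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    fda_dt = demo$fda_dt,
    event_dt = demo$event_dt %||% rep("", nrow(demo)),
    sex = {
      s <- toupper(demo$sex %||% rep("", nrow(demo)))
      s[!s %in% c("F", "M")] <- "UNK"
      s
    },
    country = demo$occr_country %||% rep("", nrow(demo)),
    occupation = demo$occp_cod %||% rep("", nrow(demo)),
    stringsAsFactors = FALSE
  )
  cases$age_years <- convert_age(demo$age, demo$age_cod)
  cases$age_band <- assign_age_band(cases$age_years)
  cases$is_target <- cases$primaryid %in% target_ids

  empty_split <- function(values, ids) {
    got <- split(values, ids)
    out <- got[match(cases$primaryid, names(got))]
    out[vapply(out, is.null, logical(1))] <- list(character())
    unname(out)
  }

  if (!is.null(tables$reac) && nrow(tables$reac)) {
    pairs <- unique(tables$reac[, c("primaryid", "pt")])
    cases$reaction_pts <- empty_split(pairs$pt, pairs$primaryid)
  } else {
    cases$reaction_pts <- rep(list(character()), nrow(cases))
  }

  if (!is.null(tables$outc) && nrow(tables$outc)) {
    cases$outcome_codes <- empty_split(tables$outc$outc_cod, tables$outc$primaryid)
  } else {
    cases$outcome_codes <- rep(list(character()), nrow(cases))
  }

  if (!is.null(tables$drug) && nrow(tables$drug)) {
    ps <- tables$drug[tables$drug$role_cod == "PS", , drop = FALSE]
    cases$suspect_drugs <- empty_split(ps$drugname, ps$primaryid)
  } else {
    ps <- NULL
    cases$suspect_drugs <- rep(list(character()), nrow(cases))
  }

  cases$therapy_start <- rep(NA_character_, nrow(cases))
  if (!is.null(tables$ther) && nrow(tables$ther) && !is.null(ps) && nrow(ps)) {
    ther <- tables$ther
    ps_key <- paste(ps$primaryid, ps$drug_seq)
    ther_ps <- ther[paste(ther$primaryid, ther$dsg_drug_seq) %in% ps_key, , drop = FALSE]
    pd <- parse_partial_date(ther_ps$start_dt, strict = FALSE)
    full <- !is.na(pd$precision) & pd$precision == "YMD"
    ther_ps <- ther_ps[full, , drop = FALSE]
    if (nrow(ther_ps)) {
      key <- partial_date_key(ther_ps$start_dt)
      agg <- tapply(key, ther_ps$primaryid, min)
      idx <- match(cases$primaryid, names(agg))
      starts <- sprintf("%08.0f", unname(agg[idx]))
      starts[is.na(idx)] <- NA_character_
      cases$therapy_start <- starts
    }
  }

  structure(cases,
            class = c("faers_cases", "data.frame"),
            flow = c(raw_demo_rows = nrow(tables$demo),
                     after_dedup = length(retained),
                     target_reports = length(target_ids)))
}

#' @export
print.faers_cases <- function(x, ...) {
  flow <- attr(x, "flow")
  cat(sprintf("<faers_cases> %d reports (%d target-drug)\n",
              nrow(x), sum(x$is_target)))
  if (!is.null(flow)) {
    cat(sprintf("  flow: %d raw DEMO rows -> %d after dedup -> %d target\n",
                flow[["raw_demo_rows"]], flow[["after_dedup"]],
                flow[["target_reports"]]))
  }
  invisible(x)
}
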