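# Demographic/outcome summary tables and end-to-end pipeline orchestration.

#' Demographic and outcome summary of a report universe
#'
#' Counts and percentages mirroring the usual "characteristics of reports"
#' table: sex, age bands, top reporting countries, reporter occupations and
#' outcome codes. Denominators differ by block and are reported alongside:
#' * sex and age percentages use the total number of reports (unknowns form
#'   their own row, so each block sums to 100);
#' * country percentages use reports with a known country;
#' * occupation percentages use reports with a known occupation code;
#' * outcome percentages use the total number of outcome *entries* - a
#'   report may carry several outcome codes, and published outcome
#'   percentages only reconcile against the entry total.
#'
#' @param cases a `"faers_cases"` data frame, typically already restricted
#'   to target-drug reports.
#' @param top_countries how many countries to list (default 5).
#' @param digits decimals for percentages (half-up rounding).
#' @return list of class `"faers_demographics"` with data-frame elements
#'   `sex`, `age`, `country`, `occupation`, `outcome`, each with columns
#'   `value`, `n`, `pct`, and attribute `denominator`.
#' @export
demographic_summary <- function(cases, top_countries = 5, digits = 2) {
  n_rep <- nrow(cases)
  block <- function(values, levels, denom) {
    counts <- table(factor(values, levels = levels))
    out <- data.frame(value = names(counts), n = as.integer(counts),
                      pct = if (denom > 0) percent(as.integer(counts), denom, digits)
                            else rep(0, length(counts)),
                      stringsAsFactors = FALSE)
    attr(out, "denominator") <- denom
    out
  }

  sex_vals <- ifelse(cases$sex %in% c("F", "M"), cases$sex, "UNK")
  sex <- block(sex_vals, c("F", "M", "UNK"), n_rep)

  age <- block(cases$age_band, age_band_levels(), n_rep)

  known_ctry <- cases$country[!is_blank(cases$country)]
  ctab <- sort(table(known_ctry), decreasing = TRUE)
  top <- utils::head(names(ctab), top_countries)
  country <- block(known_ctry[known_ctry %in% top], top, length(known_ctry))

  known_occ <- cases$occupation[!is_blank(cases$occupation)]
  occupation <- block(known_occ, names(sort(table(known_occ), decreasing = TRUE)),
                      length(known_occ))

  entries <- unlist(cases$outcome_codes, use.names = FALSE)
  if (is.null(entries)) entries <- character()
  otab <- table(factor(entries, levels = .outcome_codes))
  outcome <- block(entries, names(sort(otab, decreasing = TRUE)), length(entries))

  structure(list(sex = sex, age = age, country = country,
                 occupation = occupation, outcome = outcome),
            class = "faers_demographics", n_reports = n_rep)
}

#' @export
print.faers_demographics <- function(x, ...) {
  cat(sprintf("<faers_demographics> %d reports\n", attr(x, "n_reports")))
  for (nm in names(x)) {
    cat(sprintf("-- %s (denominator %d)\n", nm, attr(x[[nm]], "denominator")))
    print(x[[nm]], row.names = FALSE)
  }
  invisible(x)
}

#' Reports per calendar year
#'
#' @param cases a `"faers_cases"` data frame.
#' @return data frame `(year, n, pct)` over reports with a parsable
#'   `fda_dt`.
#' @export
yearly_counts <- function(cases) {
  yr <- parse_partial_date(cases$fda_dt, strict = FALSE)$year
  yr <- yr[!is.na(yr)]
  counts <- table(yr)
  data.frame(year = as.integer(names(counts)), n = as.integer(counts),
             pct = percent(as.integer(counts), length(yr)),
             stringsAsFactors = FALSE)
}

#' Configure a pipeline run
#'
#' @param input directory of FAERS ASCII tables, or a [synth_config()] to
#'   generate data on the fly.
#' @param synonyms a [synonym_list()], or path to a synonym file; defaults
#'   to the bundled lorazepam keywords.
#' @param pt_soc_map a `"pt_soc_map"`, or path to a two-column table;
#'   defaults to the bundled synthetic map.
#' @param level `"PT"`, `"SOC"` or `"both"`.
#' @param strata run sex- and age-stratified detection.
#' @param volcano build sex-contrast volcano data.
#' @param tto build the time-to-onset table.
#' @param out_dir optional output directory for delimited artifact files.
#' @param delim input-table delimiter.
#' @param zero_cell,volcano_base,volcano_test passed to [disprop()] /
#'   [volcano_data()].
#' @return list of class `"run_config"`.
#' @export
run_config <- function(input, synonyms = lorazepam_synonyms(),
                       pt_soc_map = synthetic_pt_soc_map(),
                       level = c("both", "PT", "SOC"),
                       strata = TRUE, volcano = TRUE, tto = TRUE,
                       out_dir = NULL, delim = "$",
                       zero_cell = "haldane", volcano_base = 3,
                       volcano_test = "fisher") {
  level <- match.arg(level)
  if (is.character(synonyms) && !inherits(synonyms, "synonym_list")) {
    synonyms <- read_synonyms(synonyms)
  }
  if (is.character(pt_soc_map)) pt_soc_map <- read_pt_soc_map(pt_soc_map)
  if (!inherits(input, "synth_config")) {
    if (!is.character(input) || !dir.exists(input)) {
      stop("input must be an existing directory or a synth_config", call. = FALSE)
    }
  }
  structure(list(input = input, synonyms = synonyms, pt_soc_map = pt_soc_map,
                 level = level, strata = strata, volcano = volcano, tto = tto,
                 out_dir = out_dir, delim = delim, zero_cell = zero_cell,
                 volcano_base = volcano_base, volcano_test = volcano_test),
            class = "run_config")
}

#' Run the full signal-detection pipeline
#'
#' Reads (or generates) the five tables, deduplicates, screens for the
#' target drug, and produces the demographic summary, PT/SOC signal tables,
#' sex- and age-stratified tables, the sex-contrast volcano data and the
#' time-to-onset distribution. Row counts at each stage (raw DEMO rows,
#' after deduplication, after the drug filter) are logged. Deterministic
#' given the inputs (and the seed inside a [synth_config()] input).
#'
#' When `cfg$out_dir` is set, every table is written there as delimited
#' text plus a `run.log`; on a stage failure the partial outputs are removed
#' and the error re-thrown with the stage name.
#'
#' @param cfg a [run_config()].
#' @return list of class `"faers_run"` with elements `cases`, `summary`,
#'   `yearly`, `signals` (per level), `strata` (per stratum, PT level),
#'   `volcano`, `tto`, `flow`, `log`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(cfg$out_dir)) unlink(cfg$out_dir, recursive = TRUE)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  tables <- stage("load", {
    if (inherits(cfg$input, "synth_config")) {
      say("generating synthetic data (seed %d)", cfg$input$seed)
      synth_faers(cfg$input)
    } else {
      say("reading FAERS tables from %s", cfg$input)
      read_faers_tables(cfg$input, delim = cfg$delim)
    }
  })

  cases <- stage("case_processing", build_case_reports(tables, cfg$synonyms))
  flow <- attr(cases, "flow")
  say("raw DEMO rows: %d", flow[["raw_demo_rows"]])
  say("after deduplication: %d", flow[["after_dedup"]])
  say("target-drug reports: %d", flow[["target_reports"]])

  target_cases <- cases[cases$is_target, , drop = FALSE]
  class(target_cases) <- class(cases)

  res <- list(cases = cases, flow = flow)
  res$summary <- stage("summary", demographic_summary(target_cases))
  res$yearly <- stage("summary", yearly_counts(target_cases))

  levels <- if (cfg$level == "both") c("PT", "SOC") else cfg$level
  res$signals <- stage("signals", {
    out <- lapply(levels, function(lv) {
      detect_signals(cases, level = lv, map = cfg$pt_soc_map,
                     zero_cell = cfg$zero_cell)
    })
    names(out) <- levels
    out
  })

  if (cfg$strata) {
    res$strata <- stage("strata", {
      specs <- c(lapply(c("F", "M"), function(v) stratum_spec("sex", v)),
                 lapply(setdiff(age_band_levels(), "unknown"),
                        function(v) stratum_spec("age", v)))
      out <- lapply(specs, function(sp) {
        suppressWarnings(stratify(cases, sp, level = "PT", map = cfg$pt_soc_map,
                                  zero_cell = cfg$zero_cell))
      })
      names(out) <- vapply(specs, function(sp) paste(sp$kind, sp$value, sep = "_"),
                           character(1))
      out
    })
    if (cfg$volcano) {
      res$volcano <- stage("volcano", {
        volcano_data(res$strata$sex_F, res$strata$sex_M,
                     base = cfg$volcano_base, test = cfg$volcano_test)
      })
    }
  }

  if (cfg$tto) {
    res$tto <- stage("tto", {
      days <- compute_onset_days(target_cases)
      say("reports with onset information: %d (negative differences: %d)",
          sum(!is.na(days)), attr(days, "negative_tto"))
      tto_distribution(days)
    })
  }

  res$log <- log_lines
  class(res) <- "faers_run"

  if (!is.null(cfg$out_dir)) {
    stage("write", {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      wtab <- function(x, name) {
        utils::write.table(as.data.frame(x), file.path(cfg$out_dir, name),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      for (nm in names(res$summary)) wtab(res$summary[[nm]],
                                          sprintf("summary_%s.tsv", nm))
      wtab(res$yearly, "yearly_counts.tsv")
      for (lv in names(res$signals)) wtab(res$signals[[lv]],
                                          sprintf("signals_%s.tsv", lv))
      for (st in names(res$strata %||% list())) {
        safe <- gsub(">=", "ge", gsub("<", "lt", st))
        wtab(res$strata[[st]], sprintf("signals_stratum_%s.tsv", safe))
      }
      if (!is.null(res$volcano)) wtab(res$volcano, "volcano.tsv")
      if (!is.null(res$tto)) wtab(res$tto, "tto.tsv")
      writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
    })
  }
  res
}

#' @export
print.faers_run <- function(x, ...) {
  cat("<faers_run>\n")
  cat(paste0("  ", x$log), sep = "\n")
  invisible(x)
}
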