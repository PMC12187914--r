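# Seeded synthetic FAERS-like data with planted disproportionality.
#
# Every report draws one primary-suspect drug from a marginal distribution
# and a set of reaction PTs, each present independently with its background
# probability; for a planted (drug, pt, rr) triple, reports whose suspect
# drug matches use min(1, rr * p) instead. Reports that would carry no PT
# are redrawn, so observed per-PT rates are conditioned on >= 1 event (a
# mild inflation shared by both margins). A configurable fraction of cases
# is emitted as two versions sharing a caseid - identical content, distinct
# primaryid, non-decreasing fda_dt - to exercise deduplication.

.default_background_pts <- function() {
  soc_psy <- "Psychiatric disorders"
  soc_ner <- "Nervous system disorders"
  soc_gen <- "General disorders and administration site conditions"
  soc_inj <- "Injury, poisoning and procedural complications"
  soc_gas <- "Gastrointestinal disorders"
  soc_car <- "Cardiac disorders"
  soc_res <- "Respiratory, thoracic and mediastinal disorders"
  soc_inv <- "Investigations"
  soc_mus <- "Musculoskeletal and connective tissue disorders"
  soc_ski <- "Skin and subcutaneous tissue disorders"
  pts <- rbind(
    data.frame(pt = c("Nausea", "Headache", "Fatigue", "Dizziness",
                      "Vomiting", "Diarrhoea", "Rash", "Pruritus"),
               soc = c(soc_gas, soc_ner, soc_gen, soc_ner,
                       soc_gas, soc_gas, soc_ski, soc_ski),
               p = c(0.12, 0.10, 0.08, 0.08, 0.06, 0.05, 0.05, 0.04)),
    data.frame(pt = c("Sopor", "Somnolence", "Tachycardia", "Drug abuse",
                      "Confusional state", "Agitation", "Sedation",
                      "Poisoning", "Tremor", "Insomnia", "Asthenia",
                      "Dyspnoea", "Arthralgia", "Myalgia", "Weight decreased",
                      "Blood pressure increased", "Cough", "Pyrexia",
                      "Malaise", "Anxiety", "Depression", "Syncope",
                      "Fall", "Overdose", "Hypotension", "Bradycardia",
                      "Constipation", "Dry mouth", "Hyperhidrosis",
                      "Palpitations", "Memory impairment", "Coma"),
               soc = c(soc_psy, soc_ner, soc_car, soc_psy,
                       soc_psy, soc_psy, soc_ner,
                       soc_inj, soc_ner, soc_psy, soc_gen,
                       soc_res, soc_mus, soc_mus, soc_inv,
                       soc_inv, soc_res, soc_gen,
                       soc_gen, soc_psy, soc_psy, soc_ner,
                       soc_inj, soc_inj, soc_car, soc_car,
                       soc_gas, soc_gas, soc_ski,
                       soc_car, soc_psy, soc_ner),
               p = 0.01)
  )
  pts
}

#' Configure the synthetic FAERS generator
#'
#' Defaults emulate the structure of a spontaneous-report extract at a scale
#' where planted reporting-rate ratios of 2-10 are comfortably recoverable:
#' 50,000 cases, a target drug holding 1% of reports (target drugs hold a
#' small share of a spontaneous-report database, and the EBGM observed/
#' expected ratio only approximates a planted rate ratio when the target
#' margin is a small fraction of the event margin), ~40 background PTs
#' (planted-pair PTs at background probability 0.01), three planted
#' drug-event pairs with rate ratios 10, 5 and 2, 10% duplicate case
#' versions, missingness patterned on published report-completeness figures
#' (about 8% missing sex, 26% missing age, 72% lacking usable onset dates),
#' a 63/37 female/male split among known-sex reports, and a time-to-onset
#' distribution concentrated in the first month.
#'
#' @param n_cases number of distinct cases.
#' @param drugs data frame `(name, prob)`: the primary-suspect drug marginal.
#' @param background_pts data frame `(pt, soc, p)`: background PT presence
#'   probabilities per report.
#' @param planted data frame `(drug, pt, rr)`: reporting-rate ratios planted
#'   on drug-event pairs; must reference declared drugs and PTs.
#' @param duplicate_rate fraction of cases emitted as two versions.
#' @param missing_sex_rate,missing_age_rate,missing_date_rate missingness
#'   fractions in \[0, 1\]; `missing_date_rate` is the fraction of reports
#'   without a usable (full-precision, ordered) start/event date pair.
#' @param sex_split probability a known-sex report is female.
#' @param age_distribution named probabilities over the bands
#'   `<18`, `18-65`, `>=65` (renormalised).
#' @param tto_distribution named probabilities over the onset bins of
#'   [bin_onset()] (renormalised).
#' @param outcome_probs named per-report probabilities for outcome codes.
#' @param seed integer root seed; all randomness derives from it.
#' @return a validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_cases = 50000,
                         drugs = data.frame(
                           name = c("LORAZEPAM", "ALPRAZOLAM", "DIAZEPAM",
                                    "SERTRALINE", "QUETIAPINE"),
                           prob = c(0.01, 0.29, 0.25, 0.25, 0.20)),
                         background_pts = .default_background_pts(),
                         planted = data.frame(
                           drug = "LORAZEPAM",
                           pt = c("Sopor", "Somnolence", "Tachycardia"),
                           rr = c(10, 5, 2)),
                         duplicate_rate = 0.10,
                         missing_sex_rate = 0.0786,
                         missing_age_rate = 0.2551,
                         missing_date_rate = 0.72,
                         sex_split = 0.628,
                         age_distribution = c("<18" = 0.060, "18-65" = 0.634,
                                              ">=65" = 0.306),
                         tto_distribution = c("0-30" = 0.8610, "31-60" = 0.0222,
                                              "61-90" = 0.0120, "91-120" = 0.0080,
                                              "121-150" = 0.0053, "151-180" = 0.0080,
                                              "181-360" = 0.0260, ">360" = 0.0575),
                         outcome_probs = c(OT = 0.40, HO = 0.37, DE = 0.13,
                                           LT = 0.065, DS = 0.022, RI = 0.011,
                                           CA = 0.004),
                         seed = 20240101) {
  cfg <- list(n_cases = as.integer(n_cases), drugs = drugs,
              background_pts = background_pts, planted = planted,
              duplicate_rate = duplicate_rate,
              missing_sex_rate = missing_sex_rate,
              missing_age_rate = missing_age_rate,
              missing_date_rate = missing_date_rate,
              sex_split = sex_split,
              age_distribution = age_distribution,
              tto_distribution = tto_distribution,
              outcome_probs = outcome_probs,
              seed = as.integer(seed))

  if (cfg$n_cases < 1) stop("n_cases must be >= 1", call. = FALSE)
  rates <- c(cfg$duplicate_rate, cfg$missing_sex_rate, cfg$missing_age_rate,
             cfg$missing_date_rate, cfg$sex_split)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (!all(c("name", "prob") %in% names(cfg$drugs)) || nrow(cfg$drugs) < 2) {
    stop("drugs needs columns (name, prob) and at least two drugs", call. = FALSE)
  }
  if (abs(sum(cfg$drugs$prob) - 1) > 1e-8) stop("drug probabilities must sum to 1", call. = FALSE)
  bp <- cfg$background_pts
  if (!all(c("pt", "soc", "p") %in% names(bp)) ||
      any(bp$p < 0 | bp$p > 1) || anyDuplicated(bp$pt)) {
    stop("background_pts needs unique pt with columns (pt, soc, p), p in [0, 1]",
         call. = FALSE)
  }
  pl <- cfg$planted
  if (nrow(pl)) {
    if (!all(c("drug", "pt", "rr") %in% names(pl)) || any(pl$rr <= 0)) {
      stop("planted needs columns (drug, pt, rr) with rr > 0", call. = FALSE)
    }
    if (!all(pl$drug %in% cfg$drugs$name) || !all(pl$pt %in% bp$pt)) {
      stop("planted pairs must reference declared drugs and PTs", call. = FALSE)
    }
    if (anyDuplicated(paste(pl$drug, pl$pt))) {
      stop("duplicate planted pair", call. = FALSE)
    }
  }
  if (!all(names(cfg$age_distribution) %in% age_band_levels()) ||
      any(cfg$age_distribution < 0) || sum(cfg$age_distribution) <= 0) {
    stop("invalid age_distribution", call. = FALSE)
  }
  if (!setequal(names(cfg$tto_distribution), .tto_labels) ||
      any(cfg$tto_distribution < 0) || sum(cfg$tto_distribution) <= 0) {
    stop("tto_distribution must cover the onset bins", call. = FALSE)
  }
  if (any(cfg$outcome_probs < 0 | cfg$outcome_probs > 1) ||
      !all(names(cfg$outcome_probs) %in% .outcome_codes)) {
    stop("invalid outcome_probs", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %d cases, %d drugs, %d background PTs, %d planted pairs, seed %d\n",
              x$n_cases, nrow(x$drugs), nrow(x$background_pts),
              nrow(x$planted), x$seed))
  invisible(x)
}

#' Generate synthetic FAERS-dialect tables
#'
#' Fully deterministic given `cfg$seed`. Duplicate case versions share a
#' `caseid` with distinct `primaryid`s and non-decreasing `fda_dt`, and have
#' identical content in the other tables, so they isolate the deduplication
#' rule. Therapy start dates of target-drug reports are placed so that
#' `event_dt - start_dt` follows `cfg$tto_distribution` for the reports that
#' carry full-precision dates.
#'
#' @param cfg a [synth_config()].
#' @param dir optional directory; when given, the five tables are written as
#'   `DEMO24Q2.txt` etc. in the FAERS ASCII dialect plus a `TRUTH.txt`
#'   delimited truth table.
#' @param delim delimiter used when writing.
#' @return named list `demo`, `drug`, `reac`, `ther`, `outc` (data frames in
#'   reader layout) plus `truth` (see [truth_table()]).
#' @export
synth_faers <- function(cfg = synth_config(), dir = NULL, delim = "$") {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cases

  caseid <- sprintf("%07d", seq_len(n))
  drug_idx <- sample.int(nrow(cfg$drugs), n, replace = TRUE, prob = cfg$drugs$prob)
  drug_name <- cfg$drugs$name[drug_idx]

  ## demographics ------------------------------------------------------
  sex <- ifelse(stats::runif(n) < cfg$sex_split, "F", "M")
  sex[stats::runif(n) < cfg$missing_sex_rate] <- ""

  age_p <- cfg$age_distribution / sum(cfg$age_distribution)
  band <- sample(names(age_p), n, replace = TRUE, prob = age_p)
  age <- round(stats::runif(n,
                            min = c("<18" = 1, "18-65" = 18, ">=65" = 65)[band],
                            max = c("<18" = 17.99, "18-65" = 64.99, ">=65" = 95)[band]), 1)
  age_cod <- rep("YR", n)
  miss_age <- stats::runif(n) < cfg$missing_age_rate
  age_chr <- ifelse(miss_age, "", as.character(age))
  age_cod[miss_age] <- ""

  countries <- c("US", "IT", "CA", "DE", "GB", "FR", "JP")
  country <- sample(countries, n, replace = TRUE,
                    prob = c(0.47, 0.22, 0.055, 0.05, 0.03, 0.1, 0.075))
  occp <- sample(c("MD", "CN", "PH", "OT"), n, replace = TRUE,
                 prob = c(0.29, 0.28, 0.20, 0.23))

  ## dates -------------------------------------------------------------
  fda_date <- as.Date("2004-01-01") + sample.int(7486, n, replace = TRUE) - 1
  onset_bin <- sample(.tto_labels, n, replace = TRUE,
                      prob = cfg$tto_distribution[.tto_labels] /
                        sum(cfg$tto_distribution))
  lo <- c("0-30" = 0, "31-60" = 31, "61-90" = 61, "91-120" = 91,
          "121-150" = 121, "151-180" = 151, "181-360" = 181, ">360" = 361)[onset_bin]
  hi <- c("0-30" = 30, "31-60" = 60, "61-90" = 90, "91-120" = 120,
          "121-150" = 150, "151-180" = 180, "181-360" = 360, ">360" = 1000)[onset_bin]
  onset_days <- floor(stats::runif(n, lo, hi + 1))
  report_lag <- sample.int(60, n, replace = TRUE)
  event_date <- fda_date - report_lag
  start_date <- event_date - onset_days
  start_dt <- format(start_date, "%Y%m%d")
  event_dt <- format(event_date, "%Y%m%d")
  # degrade onset information: blank the event date, blank the start date,
  # or truncate the start date to year-month precision
  no_onset <- stats::runif(n) < cfg$missing_date_rate
  how <- sample.int(3, n, replace = TRUE)
  event_dt[no_onset & how == 1] <- ""
  start_dt[no_onset & how == 2] <- ""
  start_dt[no_onset & how == 3] <- substr(start_dt[no_onset & how == 3], 1, 6)

  ## reactions ---------------------------------------------------------
  bp <- cfg$background_pts
  npt <- nrow(bp)
  prob_mat <- matrix(bp$p, nrow = n, ncol = npt, byrow = TRUE)
  if (nrow(cfg$planted)) {
    for (k in seq_len(nrow(cfg$planted))) {
      rows <- drug_name == cfg$planted$drug[k]
      col <- match(cfg$planted$pt[k], bp$pt)
      prob_mat[rows, col] <- pmin(1, cfg$planted$rr[k] * bp$p[col])
    }
  }
  present <- matrix(stats::runif(n * npt), n, npt) < prob_mat
  empty <- which(rowSums(present) == 0)
  while (length(empty)) {
    redraw <- matrix(stats::runif(length(empty) * npt), length(empty), npt) <
      prob_mat[empty, , drop = FALSE]
    present[empty, ] <- redraw
    empty <- empty[rowSums(redraw) == 0]
  }

  ## duplicate versions -------------------------------------------------
  dup <- stats::runif(n) < cfg$duplicate_rate
  versions <- 1L + dup
  pid_final <- paste0(caseid, "2")
  pid_first <- paste0(caseid, "1")
  fda_first <- fda_date - sample.int(90, n, replace = TRUE)

  rep_idx <- rep(seq_len(n), versions)
  is_first <- unlist(lapply(versions, function(v) if (v == 2L) c(TRUE, FALSE) else FALSE),
                     use.names = FALSE)
  primaryid <- ifelse(is_first, pid_first[rep_idx], pid_final[rep_idx])

  demo <- data.frame(
    primaryid = primaryid,
    caseid = caseid[rep_idx],
    fda_dt = format(as.Date(ifelse(is_first, fda_first[rep_idx], fda_date[rep_idx]),
                            origin = "1970-01-01"), "%Y%m%d"),
    event_dt = event_dt[rep_idx],
    sex = sex[rep_idx],
    age = age_chr[rep_idx],
    age_cod = age_cod[rep_idx],
    occr_country = country[rep_idx],
    occp_cod = occp[rep_idx],
    stringsAsFactors = FALSE
  )

  drug <- data.frame(
    primaryid = primaryid,
    drug_seq = 1L,
    role_cod = "PS",
    drugname = drug_name[rep_idx],
    prod_ai = drug_name[rep_idx],
    stringsAsFactors = FALSE
  )
  # a concomitant row for some reports, to exercise role filtering
  conc <- stats::runif(n) < 0.3
  conc_rows <- which(conc[rep_idx])
  if (length(conc_rows)) {
    other <- vapply(drug_name[rep_idx][conc_rows], function(dn) {
      pool <- setdiff(cfg$drugs$name, dn)
      pool[1 + (nchar(dn) %% length(pool))]  # deterministic pick
    }, character(1))
    drug <- rbind(drug, data.frame(
      primaryid = primaryid[conc_rows], drug_seq = 2L, role_cod = "C",
      drugname = other, prod_ai = other, stringsAsFactors = FALSE))
  }

  pt_rows <- which(present[rep_idx, , drop = FALSE], arr.ind = TRUE)
  reac <- data.frame(
    primaryid = primaryid[pt_rows[, 1]],
    pt = bp$pt[pt_rows[, 2]],
    stringsAsFactors = FALSE
  )

  ther <- data.frame(
    primaryid = primaryid,
    dsg_drug_seq = 1L,
    start_dt = start_dt[rep_idx],
    end_dt = "",
    stringsAsFactors = FALSE
  )
  ther <- ther[ther$start_dt != "", , drop = FALSE]

  outc_draw <- matrix(stats::runif(n * length(cfg$outcome_probs)), n) <
    matrix(cfg$outcome_probs, n, length(cfg$outcome_probs), byrow = TRUE)
  oc_rows <- which(outc_draw[rep_idx, , drop = FALSE], arr.ind = TRUE)
  outc <- data.frame(
    primaryid = primaryid[oc_rows[, 1]],
    outc_cod = names(cfg$outcome_probs)[oc_rows[, 2]],
    stringsAsFactors = FALSE
  )

  ord <- function(x) {
    x <- x[order(x$primaryid, method = "radix"), , drop = FALSE]
    rownames(x) <- NULL
    x
  }
  out <- list(demo = ord(demo), drug = ord(drug), reac = ord(reac),
              ther = ord(ther), outc = ord(outc),
              truth = truth_table(cfg))

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_faers_table(out$demo, file.path(dir, "DEMO24Q2.txt"), delim)
    write_faers_table(out$drug, file.path(dir, "DRUG24Q2.txt"), delim)
    write_faers_table(out$reac, file.path(dir, "REAC24Q2.txt"), delim)
    write_faers_table(out$ther, file.path(dir, "THER24Q2.txt"), delim)
    write_faers_table(out$outc, file.path(dir, "OUTC24Q2.txt"), delim)
    utils::write.table(out$truth, file.path(dir, "TRUTH.txt"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

#' Closed-form expectations for planted pairs
#'
#' For each planted `(drug, pt, rr)`, the expected contingency cells before
#' conditioning on non-empty reports: with `n_t = n_cases * P(drug)` target
#' reports and event probability `p_t = min(1, rr * p)` among them versus
#' `p` in the background, `E[a] = n_t * p_t`, `E[c] = (n - n_t) * p`, and
#' the margins follow. Used by parameter-recovery tests.
#'
#' @param cfg a [synth_config()].
#' @return data frame with one row per planted pair: `drug`, `pt`, `rr`,
#'   `p_background`, `p_target`, `exp_a`, `exp_b`, `exp_c`, `exp_d`.
#' @export
truth_table <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  pl <- cfg$planted
  if (!nrow(pl)) {
    return(data.frame(drug = character(), pt = character(), rr = numeric(),
                      p_background = numeric(), p_target = numeric(),
                      exp_a = numeric(), exp_b = numeric(),
                      exp_c = numeric(), exp_d = numeric()))
  }
  p_bg <- cfg$background_pts$p[match(pl$pt, cfg$background_pts$pt)]
  p_t <- pmin(1, pl$rr * p_bg)
  n_t <- cfg$n_cases * cfg$drugs$prob[match(pl$drug, cfg$drugs$name)]
  n_b <- cfg$n_cases - n_t
  data.frame(drug = pl$drug, pt = pl$pt, rr = pl$rr,
             p_background = p_bg, p_target = p_t,
             exp_a = n_t * p_t, exp_b = n_t * (1 - p_t),
             exp_c = n_b * p_bg, exp_d = n_b * (1 - p_bg),
             stringsAsFactors = FALSE)
}
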