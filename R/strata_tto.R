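# Subgroup (sex / age band) signal detection, volcano-plot data for the
# sex contrast, and time-to-onset binning.

#' Define a subgroup of the report universe
#'
#' @param kind `"sex"` or `"age"`.
#' @param value for `kind = "sex"`, `"F"` or `"M"`; for `kind = "age"` one of
#'   the bands of [assign_age_band()].
#' @return an object of class `"stratum_spec"`.
#' @export
stratum_spec <- function(kind = c("sex", "age"), value) {
  kind <- match.arg(kind)
  valid <- if (kind == "sex") c("F", "M") else age_band_levels()
  if (!value %in% valid) {
    stop(sprintf("invalid %s stratum '%s' (expected one of %s)",
                 kind, value, paste(valid, collapse = ", ")), call. = FALSE)
  }
  structure(list(kind = kind, value = value), class = "stratum_spec")
}

#' @export
print.stratum_spec <- function(x, ...) {
  cat(sprintf("<stratum_spec> %s = %s\n", x$kind, x$value))
  invisible(x)
}

#' Stratified signal detection
#'
#' Restricts the whole report universe - target and background alike - to a
#' subgroup and reruns [detect_signals()] inside it, so both margins of every
#' 2x2 table are recomputed within the stratum.
#'
#' @param cases a `"faers_cases"` universe.
#' @param spec a [stratum_spec()].
#' @inheritParams detect_signals
#' @param ... passed on to [detect_signals()].
#' @return a `"faers_signals"` object with attribute `stratum`.
#' @export
stratify <- function(cases, spec, level = c("PT", "SOC"), map = NULL,
                     target = cases$is_target, ...) {
  stopifnot(inherits(spec, "stratum_spec"))
  keep <- if (spec$kind == "sex") cases$sex == spec$value else
    cases$age_band == spec$value
  if (!any(keep)) {
    warning(sprintf("stratum %s = %s contains no reports", spec$kind, spec$value),
            call. = FALSE)
  }
  sub <- cases[keep, , drop = FALSE]
  class(sub) <- class(cases)
  out <- detect_signals(sub, level = level, map = map, target = target[keep], ...)
  attr(out, "stratum") <- spec
  out
}

#' Volcano-plot data for the sex contrast
#'
#' For every event detected in both sex strata among target-drug reports,
#' builds the male-versus-female 2x2 table
#' (`a` = male reports with the event, `b` = male without, `c` = female
#' with, `d` = female without), and returns `x = log_base(OR)` (base 3 by
#' default) and `y = -log10 p` from a two-sided test on that table. Events
#' with `x > epsilon` are male-leaning, `x < -epsilon` female-leaning,
#' otherwise neutral. Swapping the two strata flips the sign of `x`.
#'
#' Zero cells get the Haldane +0.5 correction for the odds ratio so `x`
#' stays finite; the p-value is computed on the uncorrected counts.
#'
#' @param results_f stratified `"faers_signals"` for the female stratum.
#' @param results_m stratified `"faers_signals"` for the male stratum.
#' @param base logarithm base for the x axis (default 3).
#' @param test `"fisher"` (two-sided exact, default) or `"chisq"`.
#' @param epsilon half-width of the neutral band on the x axis.
#' @return data frame of class `"faers_volcano"` with columns `event`, `x`,
#'   `y`, `side` and the four cells. Attribute `n_skipped` counts events
#'   present in only one stratum.
#' @export
volcano_data <- function(results_f, results_m, base = 3,
                         test = c("fisher", "chisq"), epsilon = 1e-8) {
  test <- match.arg(test)
  common <- intersect(results_f$event, results_m$event)
  n_skipped <- length(union(results_f$event, results_m$event)) - length(common)
  fi <- match(common, results_f$event)
  mi <- match(common, results_m$event)
  a <- results_m$a[mi]
  b <- attr(results_m, "n_target") - a
  cc <- results_f$a[fi]
  d <- attr(results_f, "n_target") - cc

  corr <- (a == 0 | b == 0 | cc == 0 | d == 0) * 0.5
  or <- (a + corr) * (d + corr) / ((b + corr) * (cc + corr))
  x <- log(or) / log(base)
  y <- vapply(seq_along(common), function(i) {
    tab <- matrix(c(a[i], b[i], cc[i], d[i]), nrow = 2, byrow = TRUE)
    p <- if (test == "fisher") stats::fisher.test(tab)$p.value else
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    -log10(max(p, .Machine$double.xmin))
  }, numeric(1))
  # fisher.test can return 1 + eps; a p of 1 is exactly y = 0
  y <- pmax(y, 0)

  side <- ifelse(x > epsilon, "male-leaning",
                 ifelse(x < -epsilon, "female-leaning", "neutral"))
  out <- data.frame(event = common, x = x, y = y, side = side,
                    a_male = a, b_male = b, a_female = cc, b_female = d,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$y, out$event), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("faers_volcano", "data.frame"),
            n_skipped = n_skipped, base = base, test = test)
}

#' @export
plot.faers_volcano <- function(x, ...) {
  col <- c("male-leaning" = "red3", "female-leaning" = "green4",
           "neutral" = "grey60")[x$side]
  plot(x$x, x$y, col = col, pch = 19,
       xlab = sprintf("log%s(ROR) male vs female", attr(x, "base")),
       ylab = "-log10 p", ...)
  graphics::abline(v = 0, lty = 2, col = "grey40")
  invisible(x)
}

#' Days from therapy start to event onset
#'
#' `event_dt - therapy_start` in whole days, defined only when both dates
#' have full calendar precision and the difference is non-negative. Partial
#' dates are excluded, never imputed; a negative difference is treated as
#' missing and tallied in the `negative_tto` attribute.
#'
#' @param cases a `"faers_cases"` data frame (needs columns `event_dt`,
#'   `therapy_start`).
#' @return integer vector of onset days (`NA` when unavailable) with
#'   attribute `negative_tto`.
#' @export
compute_onset_days <- function(cases) {
  ev <- partial_date_as_date(cases$event_dt)
  st <- partial_date_as_date(cases$therapy_start)
  days <- as.integer(ev - st)
  neg <- !is.na(days) & days < 0
  days[neg] <- NA_integer_
  attr(days, "negative_tto") <- sum(neg)
  days
}

.tto_breaks <- c(-1, 30, 60, 90, 120, 150, 180, 360, Inf)
.tto_labels <- c("0-30", "31-60", "61-90", "91-120", "121-150", "151-180",
                 "181-360", ">360")

#' Bin onset days into the standard reporting intervals
#'
#' 30-day bins up to 180 days, then 181-360, then beyond 360. Boundaries are
#' inclusive on the upper edge (30 falls in `0-30`, 360 in `181-360`).
#'
#' @param onset_days non-negative integer vector (`NA` allowed).
#' @return factor with levels `0-30`, `31-60`, ..., `181-360`, `>360`.
#' @export
bin_onset <- function(onset_days) {
  cut(onset_days, breaks = .tto_breaks, labels = .tto_labels, right = TRUE)
}

#' Time-to-onset distribution
#'
#' Per-bin counts and percentages over the reports that carry onset
#' information; counts sum to the number of non-missing inputs and
#' percentages to 100 up to rounding.
#'
#' @param onset_days integer vector as from [compute_onset_days()], or a
#'   `"faers_cases"` object (onset days are then computed from it).
#' @param digits decimals for the percentage column.
#' @return data frame of class `"faers_tto"` with columns `bin`, `n`, `pct`;
#'   attribute `n_with_onset` gives the denominator.
#' @export
tto_distribution <- function(onset_days, digits = 2) {
  if (inherits(onset_days, "faers_cases")) {
    onset_days <- compute_onset_days(onset_days)
  }
  days <- onset_days[!is.na(onset_days)]
  if (!length(days)) {
    out <- data.frame(bin = character(), n = integer(), pct = numeric())
    return(structure(out, class = c("faers_tto", "data.frame"), n_with_onset = 0L))
  }
  counts <- table(bin_onset(days))
  out <- data.frame(bin = names(counts), n = as.integer(counts),
                    pct = percent(as.integer(counts), length(days), digits),
                    stringsAsFactors = FALSE)
  structure(out, class = c("faers_tto", "data.frame"),
            n_with_onset = length(days))
}

#' @export
plot.faers_tto <- function(x, ...) {
  graphics::barplot(stats::setNames(x$n, x$bin), las = 2,
                    ylab = "reports", xlab = "days to onset", ...)
  invisible(x)
}
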