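# Disproportionality statistics on the 2x2 drug-event contingency table
#
#              event   no event
#   target       a        b
#   background   c        d        N = a + b + c + d
#
# Four algorithms with their positivity criteria:
#   ROR    a >= 3 and lower 95% CI bound > 1
#   PRR    a >= 3, PRR >= 2, chi-squared >= 4
#   BCPNN  a >= 3 and IC025 > 0
#   MGPS   a > 0 and EBGM05 > 2
# A pair is a positive signal when all four flags hold simultaneously.

#' Default BCPNN prior hyperparameters
#'
#' The canonical BCPNN prior: Dirichlet joint prior count `gamma11 = 1`,
#' Beta margin parameters `alpha1 = beta1 = 1` and `alpha = beta = 2`. The
#' joint denominator parameter `gamma` is never user-set: it is derived from
#' the cell counts as
#' `gamma11 * (N + alpha) * (N + beta) / ((a + b + alpha1) * (a + c + beta1))`,
#' which centres the prior IC at zero.
#'
#' @param gamma11,alpha1,alpha,beta1,beta strictly positive prior parameters.
#' @return a named list of class `"bcpnn_prior"`.
#' @export
bcpnn_prior <- function(gamma11 = 1, alpha1 = 1, alpha = 2, beta1 = 1, beta = 2) {
  p <- list(gamma11 = gamma11, alpha1 = alpha1, alpha = alpha,
            beta1 = beta1, beta = beta)
  if (any(unlist(p) <= 0)) stop("BCPNN prior parameters must be > 0", call. = FALSE)
  structure(p, class = "bcpnn_prior")
}

#' Build a 2x2 contingency table over a report universe
#'
#' Counting unit is the (report, event) pair: a report contributes once to
#' the event row if any of its distinct PTs satisfies the event, so `a + b`
#' equals the number of target reports in the universe. At SOC level a PT
#' satisfies the event when it maps to the SOC.
#'
#' @param cases a `"faers_cases"` universe (see [build_case_reports()]).
#' @param event a PT string (`level = "PT"`) or SOC string (`level = "SOC"`).
#' @param level `"PT"` or `"SOC"`.
#' @param map a `"pt_soc_map"`, required for SOC level.
#' @param target logical vector flagging target-drug reports; defaults to
#'   `cases$is_target`.
#' @return one-row data frame with columns `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(cases, event, level = c("PT", "SOC"), map = NULL,
                              target = cases$is_target) {
  level <- match.arg(level)
  if (nrow(cases) == 0) stop("empty report universe", call. = FALSE)
  stopifnot(length(target) == nrow(cases))
  pts <- cases$reaction_pts
  row <- rep(seq_len(nrow(cases)), lengths(pts))
  flat <- unlist(pts, use.names = FALSE)
  if (is.null(flat)) flat <- character()
  hit <- if (level == "PT") {
    norm_text(flat) == norm_text(event)
  } else {
    if (is.null(map)) stop("SOC level needs a pt_soc_map", call. = FALSE)
    map_pt_to_soc(flat, map) == event
  }
  has_event <- logical(nrow(cases))
  has_event[row[hit]] <- TRUE
  a <- sum(target & has_event)
  b <- sum(target & !has_event)
  cc <- sum(!target & has_event)
  d <- sum(!target & !has_event)
  data.frame(a = a, b = b, c = cc, d = d, n = a + b + cc + d)
}

#' Disproportionality statistics for 2x2 tables
#'
#' Vectorised over table cells. Computes, per table:
#' * `ror = ad/bc` with the Woolf log-normal 95% interval
#'   `exp(log(ror) -/+ 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`;
#' * `prr = (a/(a+b)) / (c/(c+d))` with the uncorrected chi-squared
#'   `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` (Yates' continuity correction
#'   available but off by default);
#' * the BCPNN information component `ic = log2(a N / ((a+b)(a+c)))`, its
#'   posterior expectation `e_ic` and variance `v_ic` under the prior of
#'   [bcpnn_prior()], and `ic025 = e_ic - 2 sqrt(v_ic)`;
#' * the closed-form empirical Bayes geometric mean
#'   `ebgm = a N / ((a+b)(a+c))` (the observed/expected ratio, identical to
#'   `2^ic`) with lower bound
#'   `ebgm05 = exp(log(ebgm) - 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' Zero-cell policy: when `a > 0` but `b`, `c` or `d` is zero, all four
#' statistics are computed on a Haldane-corrected table (+0.5 to every cell)
#' and the row is marked `corrected`. When `a = 0` the statistics are
#' undefined (`NA`) and every flag is `FALSE`. Eligibility thresholds
#' (`a >= 3`, `a > 0`) always use the uncorrected `a`.
#'
#' @param a,b,c,d non-negative integer vectors of cell counts (recycled).
#' @param prior a [bcpnn_prior()].
#' @param zero_cell `"haldane"` (default) or `"none"` (zero cells then
#'   propagate `Inf`/`NaN`).
#' @param yates apply Yates' continuity correction to the chi-squared
#'   statistic (default `FALSE`, matching the plain formula).
#' @return data frame of class `"faers_disprop"` with the cells, `n`, the
#'   statistics (`ror`, `ror_lo95`, `ror_hi95`, `prr`, `chi2`, `ic`, `e_ic`,
#'   `v_ic`, `ic025`, `ebgm`, `ebgm05`), `corrected`, the per-algorithm flags
#'   (`ror_pos`, `prr_pos`, `bcpnn_pos`, `mgps_pos`) and the combined
#'   `positive` verdict.
#' @export
#' @examples
#' disprop(30, 70, 300, 9700)
disprop <- function(a, b, c, d, prior = bcpnn_prior(),
                    zero_cell = c("haldane", "none"), yates = FALSE) {
  zero_cell <- match.arg(zero_cell)
  stopifnot(inherits(prior, "bcpnn_prior"))
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) {
    stop("contingency cells must be non-negative", call. = FALSE)
  }

  defined <- a > 0
  corrected <- defined & (b == 0 | c == 0 | d == 0) & zero_cell == "haldane"
  aa <- a + 0.5 * corrected; bb <- b + 0.5 * corrected
  cc <- c + 0.5 * corrected; dd <- d + 0.5 * corrected
  nn <- aa + bb + cc + dd

  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  ror <- aa * dd / (bb * cc)
  ror_lo95 <- exp(log(ror) - 1.96 * se)
  ror_hi95 <- exp(log(ror) + 1.96 * se)

  prr <- (aa / (aa + bb)) / (cc / (cc + dd))
  dev <- abs(aa * dd - bb * cc)
  if (yates) dev <- pmax(dev - nn / 2, 0)
  chi2 <- nn * dev^2 / ((aa + bb) * (cc + dd) * (aa + cc) * (bb + dd))

  ic <- log2(aa * nn / ((aa + bb) * (aa + cc)))
  g11 <- prior$gamma11; a1 <- prior$alpha1; al <- prior$alpha
  b1 <- prior$beta1; be <- prior$beta
  gam <- g11 * (nn + al) * (nn + be) / ((aa + bb + a1) * (aa + cc + b1))
  e_ic <- log2((aa + g11) * (nn + al) * (nn + be) /
                 ((nn + gam) * (aa + bb + a1) * (aa + cc + b1)))
  v_ic <- (1 / log(2)^2) *
    ((nn - aa + gam - g11) / ((aa + g11) * (1 + nn + gam)) +
       (nn - (aa + bb) + al - a1) / ((aa + bb + a1) * (1 + nn + al)) +
       (nn - (aa + cc) + be - b1) / ((aa + cc + b1) * (1 + nn + be)))
  ic025 <- e_ic - 2 * sqrt(v_ic)

  ebgm <- aa * nn / ((aa + bb) * (aa + cc))
  ebgm05 <- exp(log(ebgm) - 1.96 * se)

  out <- data.frame(a = a, b = b, c = c, d = d, n = a + b + c + d,
                    ror = ror, ror_lo95 = ror_lo95, ror_hi95 = ror_hi95,
                    prr = prr, chi2 = chi2,
                    ic = ic, e_ic = e_ic, v_ic = v_ic, ic025 = ic025,
                    ebgm = ebgm, ebgm05 = ebgm05,
                    corrected = corrected)
  stat_cols <- c("ror", "ror_lo95", "ror_hi95", "prr", "chi2",
                 "ic", "e_ic", "v_ic", "ic025", "ebgm", "ebgm05")
  out[!defined, stat_cols] <- NA_real_
  out <- apply_signal_criteria(out)
  class(out) <- c("faers_disprop", "data.frame")
  out
}

#' Apply the four positivity criteria
#'
#' Recomputes the per-algorithm flags and the combined verdict from the
#' statistic columns: `ror_pos = a >= 3 & ror_lo95 > 1`;
#' `prr_pos = a >= 3 & prr >= 2 & chi2 >= 4` (thresholds inclusive);
#' `bcpnn_pos = a >= 3 & ic025 > 0`; `mgps_pos = a > 0 & ebgm05 > 2`
#' (strict); `positive` is their conjunction. Undefined statistics never
#' flag.
#'
#' @param x data frame with columns `a`, `ror_lo95`, `prr`, `chi2`, `ic025`,
#'   `ebgm05`.
#' @return `x` with flag columns and `positive` replaced.
#' @export
apply_signal_criteria <- function(x) {
  flag <- function(cond) !is.na(cond) & cond
  x$ror_pos <- flag(x$a >= 3 & x$ror_lo95 > 1)
  x$prr_pos <- flag(x$a >= 3 & x$prr >= 2 & x$chi2 >= 4)
  x$bcpnn_pos <- flag(x$a >= 3 & x$ic025 > 0)
  x$mgps_pos <- flag(x$a > 0 & x$ebgm05 > 2)
  x$positive <- x$ror_pos & x$prr_pos & x$bcpnn_pos & x$mgps_pos
  x
}

# distinct (primaryid, event) pairs over the universe at PT or SOC level
#' @noRd
report_event_pairs <- function(cases, level, map) {
  pts <- cases$reaction_pts
  ids <- rep(cases$primaryid, lengths(pts))
  ev <- unlist(pts, use.names = FALSE)
  if (is.null(ev)) ev <- character()
  if (level == "SOC") ev <- map_pt_to_soc(ev, map)
  keep <- !duplicated(paste(ids, ev, sep = "\r"))
  data.frame(primaryid = ids[keep], event = ev[keep], stringsAsFactors = FALSE)
}

#' Detect disproportionality signals for a target drug
#'
#' Builds the 2x2 table of every event observed at least once with the
#' target drug (at PT or SOC level), computes all four statistics via
#' [disprop()], applies the positivity criteria and ranks the results.
#' Ranking is either by case count `a` ("signal frequency") or by `ror`;
#' ties break by event name ascending so output order is deterministic.
#'
#' @inheritParams build_contingency
#' @param rank_by `"a"` (default) or `"ror"`.
#' @param positive_only keep only pairs positive on all four algorithms.
#' @param ... passed to [disprop()] (`prior`, `zero_cell`, `yates`).
#' @return a data frame of class `"faers_signals"`: one row per event with
#'   `level`, `event`, (`soc` at PT level when a map is given), the cells and
#'   statistics of [disprop()]. Attributes `level`, `rank_by`, `n_universe`,
#'   `n_target`.
#' @export
detect_signals <- function(cases, level = c("PT", "SOC"), map = NULL,
                           target = cases$is_target,
                           rank_by = c("a", "ror"), positive_only = FALSE, ...) {
  level <- match.arg(level)
  rank_by <- match.arg(rank_by)
  if (level == "SOC" && is.null(map)) stop("SOC level needs a pt_soc_map", call. = FALSE)
  stopifnot(length(target) == nrow(cases))

  n_target <- sum(target)
  n_bg <- sum(!target)
  empty <- {
    st <- disprop(numeric(), numeric(), numeric(), numeric())
    cbind(data.frame(level = character(), event = character(),
                     stringsAsFactors = FALSE), st)
  }
  if (n_target == 0 || nrow(cases) == 0) {
    return(structure(empty, class = c("faers_signals", "data.frame"),
                     level = level, rank_by = rank_by,
                     n_universe = nrow(cases), n_target = n_target))
  }

  pairs <- report_event_pairs(cases, level, map)
  tgt <- cases$primaryid[target]
  in_target <- pairs$primaryid %in% tgt
  events <- unique(pairs$event[in_target])
  events <- events[order(events, method = "radix")]
  if (!length(events)) {
    return(structure(empty, class = c("faers_signals", "data.frame"),
                     level = level, rank_by = rank_by,
                     n_universe = nrow(cases), n_target = n_target))
  }

  a <- as.vector(table(factor(pairs$event[in_target], levels = events)))
  cc <- as.vector(table(factor(pairs$event[!in_target], levels = events)))
  st <- disprop(a, n_target - a, cc, n_bg - cc, ...)

  res <- cbind(data.frame(level = level, event = events, stringsAsFactors = FALSE), st)
  if (level == "PT" && !is.null(map)) {
    res$soc <- map_pt_to_soc(res$event, map)
    res <- res[, c("level", "event", "soc", setdiff(names(res), c("level", "event", "soc")))]
  }
  ord <- if (rank_by == "a") {
    order(-res$a, res$event, method = "radix")
  } else {
    r <- res$ror
    r[is.na(r)] <- -Inf
    order(-r, res$event, method = "radix")
  }
  res <- res[ord, , drop = FALSE]
  if (positive_only) res <- res[res$positive, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("faers_signals", "data.frame"),
            level = level, rank_by = rank_by,
            n_universe = nrow(cases), n_target = n_target)
}

#' @export
print.faers_signals <- function(x, n = 10, digits = 3, ...) {
  cat(sprintf("<faers_signals> level %s, %d events, %d positive (ranked by %s)\n",
              attr(x, "level"), nrow(x), sum(x$positive), attr(x, "rank_by")))
  cat(sprintf("  universe: %d reports, %d target-drug\n",
              attr(x, "n_universe"), attr(x, "n_target")))
  if (nrow(x)) {
    show <- utils::head(as.data.frame(x)[, intersect(
      c("event", "a", "ror", "ror_lo95", "prr", "chi2", "ic", "ic025",
        "ebgm", "ebgm05", "positive"), names(x))], n)
    num <- vapply(show, is.numeric, logical(1)) & names(show) != "a"
    show[num] <- lapply(show[num], signif, digits)
    print(show, row.names = FALSE)
    if (nrow(x) > n) cat(sprintf("  ... %d more events\n", nrow(x) - n))
  }
  invisible(x)
}

#' @export
summary.faers_signals <- function(object, ...) {
  out <- list(
    level = attr(object, "level"),
    n_events = nrow(object),
    n_universe = attr(object, "n_universe"),
    n_target = attr(object, "n_target"),
    positive_by = c(ror = sum(object$ror_pos), prr = sum(object$prr_pos),
                    bcpnn = sum(object$bcpnn_pos), mgps = sum(object$mgps_pos),
                    all_four = sum(object$positive))
  )
  class(out) <- "summary.faers_signals"
  out
}

#' @export
print.summary.faers_signals <- function(x, ...) {
  cat(sprintf("Signal detection at %s level: %d events over %d reports (%d target)\n",
              x$level, x$n_events, x$n_universe, x$n_target))
  cat("Events positive per algorithm:\n")
  print(x$positive_by)
  invisible(x)
}

#' Write a signal table to a delimited file
#'
#' Column layout mirrors published SOC/PT signal tables: event identity,
#' case count, the four statistics with their interval bounds, and the five
#' flags.
#'
#' @param x a `"faers_signals"` object.
#' @param path output path.
#' @param delim delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(x, path, delim = "\t") {
  utils::write.table(as.data.frame(x), path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
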