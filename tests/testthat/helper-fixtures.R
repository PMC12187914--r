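# Shared fixtures built in code.

# straight-line evaluation of the four algorithms' printed formulas,
# independent of the package implementation (kept as plain arithmetic)
oracle_stats <- function(a, b, c, d, g11 = 1, a1 = 1, al = 2, b1 = 1, be = 2) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- a * d / (b * c)
  prr <- (a / (a + b)) / (c / (c + d))
  chi2 <- N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  ic <- log2(a * N / ((a + b) * (a + c)))
  gam <- g11 * (N + al) * (N + be) / ((a + b + a1) * (a + c + b1))
  e_ic <- log2((a + g11) * (N + al) * (N + be) /
                 ((N + gam) * (a + b + a1) * (a + c + b1)))
  v_ic <- (1 / log(2)^2) *
    ((N - a + gam - g11) / ((a + g11) * (1 + N + gam)) +
       (N - (a + b) + al - a1) / ((a + b + a1) * (1 + N + al)) +
       (N - (a + c) + be - b1) / ((a + c + b1) * (1 + N + be)))
  ebgm <- a * N / ((a + b) * (a + c))
  list(ror = ror, ror_lo95 = exp(log(ror) - 1.96 * se),
       ror_hi95 = exp(log(ror) + 1.96 * se),
       prr = prr, chi2 = chi2, ic = ic, e_ic = e_ic, v_ic = v_ic,
       ic025 = e_ic - 2 * sqrt(v_ic),
       ebgm = ebgm, ebgm05 = exp(log(ebgm) - 1.96 * se))
}

# minimal case universe built directly (bypasses the readers):
# pts is a list of character vectors, one per report
toy_cases <- function(is_target, pts, sex = NULL, age_band = NULL,
                      event_dt = NULL, therapy_start = NULL,
                      outcomes = NULL, country = NULL, occupation = NULL) {
  n <- length(is_target)
  df <- data.frame(
    primaryid = sprintf("p%03d", seq_len(n)),
    caseid = sprintf("c%03d", seq_len(n)),
    fda_dt = rep("20230101", n),
    event_dt = event_dt %||% rep("", n),
    sex = sex %||% rep("UNK", n),
    country = country %||% rep("", n),
    occupation = occupation %||% rep("", n),
    stringsAsFactors = FALSE
  )
  df$age_years <- NA_real_
  df$age_band <- age_band %||% rep("unknown", n)
  df$is_target <- is_target
  df$reaction_pts <- pts
  df$outcome_codes <- outcomes %||% rep(list(character()), n)
  df$suspect_drugs <- rep(list(character()), n)
  df$therapy_start <- therapy_start %||% rep(NA_character_, n)
  structure(df, class = c("faers_cases", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fixture map used in unit tests
test_map <- function() {
  faerspv::pt_soc_map(
    pt = c("Sopor", "Somnolence", "Nausea", "Tachycardia"),
    soc = c("Psychiatric disorders", "Nervous system disorders",
            "Gastrointestinal disorders", "Cardiac disorders"))
}

write_faers_fixture <- function(dir, demo = NULL, drug = NULL, reac = NULL,
                                ther = NULL, outc = NULL, delim = "$") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    if (!is.null(x)) faerspv::write_faers_table(x, file.path(dir, name), delim)
  }
  w(demo, "DEMO24Q2.txt"); w(drug, "DRUG24Q2.txt"); w(reac, "REAC24Q2.txt")
  w(ther, "THER24Q2.txt"); w(outc, "OUTC24Q2.txt")
  dir
}

# universe with the marginal counts of a published lorazepam report series:
# sex 8173 F / 4843 M / 1110 unknown of 14,126 reports; ages 633 / 6673 /
# 3216 known plus 3604 unknown; 14,682 outcome entries
# (5884 OT / 5437 HO / 1862 DE / 950 LT / 325 DS / 166 RI / 58 CA)
fixture_counts_cases <- function() {
  sex <- c(rep("F", 8173), rep("M", 4843), rep("UNK", 1110))
  band <- c(rep("<18", 633), rep("18-65", 6673), rep(">=65", 3216),
            rep("unknown", 3604))
  flat <- c(rep("OT", 5884), rep("HO", 5437), rep("DE", 1862), rep("LT", 950),
            rep("DS", 325), rep("RI", 166), rep("CA", 58))
  idx <- rep(seq_len(14126), length.out = length(flat))
  outcomes <- unname(split(flat, factor(idx, levels = seq_len(14126))))
  toy_cases(is_target = rep(TRUE, 14126),
            pts = rep(list(character()), 14126),
            sex = sex, age_band = band, outcomes = outcomes)
}
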