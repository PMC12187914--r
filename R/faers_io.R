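# Reading and writing the FAERS quarterly ASCII dialect: "$"-separated,
# one header row with canonical column names, no quoting.

.faers_schema <- list(
  DEMO = list(
    columns = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age",
                "age_cod", "occr_country", "occp_cod"),
    mandatory = c("primaryid", "caseid", "fda_dt")
  ),
  DRUG = list(
    columns = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
    mandatory = c("primaryid", "drug_seq", "role_cod", "drugname")
  ),
  REAC = list(
    columns = c("primaryid", "pt"),
    mandatory = c("primaryid", "pt")
  ),
  THER = list(
    columns = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
    mandatory = c("primaryid", "dsg_drug_seq")
  ),
  OUTC = list(
    columns = c("primaryid", "outc_cod"),
    mandatory = c("primaryid", "outc_cod")
  )
)

.role_codes <- c("PS", "SS", "C", "I")
.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
.age_codes <- c("DEC", "YR", "MON", "WK", "DY", "HR")

#' Read one FAERS quarterly ASCII table
#'
#' Reads a `$`-delimited FAERS table (DEMO, DRUG, REAC, THER or OUTC) into a
#' typed data frame. Columns are resolved by header name, not position, and
#' unknown extra columns are dropped. Rows whose mandatory fields cannot be
#' parsed are removed, counted, and returned in a rejects table rather than
#' aborting the read: spontaneous-report extracts are dirty by nature and a
#' malformed record should never sink a run.
#'
#' Validation per table kind:
#' * DEMO: `primaryid` and `caseid` non-empty, `fda_dt` parses with at least
#'   year precision (else the row is rejected); an unparsable `event_dt` or a
#'   negative/unparsable `age` is blanked and noted, the row is kept.
#' * DRUG: `role_cod` must be one of PS/SS/C/I and `drugname` non-empty.
#' * REAC: `pt` non-empty after whitespace normalisation.
#' * THER: `start_dt > end_dt` at full precision is flagged, not fatal.
#' * OUTC: `outc_cod` must be one of DE/LT/HO/DS/CA/RI/OT.
#'
#' @param path path to the ASCII file.
#' @param table_kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"THER"`, `"OUTC"`.
#' @param delim field delimiter, `"$"` by FAERS convention; the synthetic
#'   generator can emit tab or comma if asked.
#' @return a data frame with the canonical columns for the table kind, one row
#'   per accepted record. Attributes: `table_kind`, and `rejects`, a data
#'   frame `(primaryid, reason)` with one row per dropped record or blanked
#'   field.
#' @seealso [write_faers_table()], [read_faers_tables()]
#' @export
read_faers_table <- function(path, table_kind = c("DEMO", "DRUG", "REAC", "THER", "OUTC"),
                             delim = "$") {
  table_kind <- match.arg(table_kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schema <- .faers_schema[[table_kind]]

  raw <- utils::read.table(path, sep = delim, header = TRUE, quote = "",
                           comment.char = "", colClasses = "character",
                           check.names = FALSE, fill = TRUE,
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  names(raw) <- tolower(trimws(names(raw)))
  missing_cols <- setdiff(schema$mandatory, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("%s table %s is missing mandatory column(s): %s",
                 table_kind, path, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  # resolve by header name; absent optional columns become empty
  out <- as.data.frame(
    lapply(stats::setNames(schema$columns, schema$columns), function(cn) {
      if (cn %in% names(raw)) trimws(raw[[cn]]) else rep("", nrow(raw))
    }),
    stringsAsFactors = FALSE
  )

  rejects <- data.frame(primaryid = character(), reason = character(),
                        stringsAsFactors = FALSE)
  note <- function(ids, reason) {
    if (length(ids)) {
      rejects <<- rbind(rejects, data.frame(primaryid = ids, reason = reason,
                                            stringsAsFactors = FALSE))
    }
  }

  drop <- rep(FALSE, nrow(out))
  bad_pid <- is_blank(out$primaryid)
  if (any(bad_pid)) {
    note(rep("<blank>", sum(bad_pid)), "empty primaryid")
    drop <- drop | bad_pid
  }

  if (table_kind == "DEMO") {
    bad_case <- !drop & is_blank(out$caseid)
    note(out$primaryid[bad_case], "empty caseid")
    fda <- parse_partial_date(out$fda_dt, strict = FALSE)
    bad_fda <- !drop & (is_blank(out$fda_dt) | is.na(fda$precision))
    note(out$primaryid[bad_fda], "unparsable fda_dt")
    drop <- drop | bad_case | bad_fda

    ev <- parse_partial_date(out$event_dt, strict = FALSE)
    bad_ev <- !drop & !is_blank(out$event_dt) & is.na(ev$precision)
    note(out$primaryid[bad_ev], "unparsable event_dt (field blanked)")
    out$event_dt[bad_ev] <- ""

    out$sex <- toupper(out$sex)
    out$sex[!out$sex %in% c("F", "M")] <- "UNK"
    out$age_cod <- toupper(out$age_cod)
    age_num <- suppressWarnings(as.numeric(out$age))
    bad_age <- !is_blank(out$age) & (is.na(age_num) | age_num < 0)
    note(out$primaryid[!drop & bad_age], "invalid age (field blanked)")
    age_num[bad_age] <- NA_real_
    out$age <- age_num
  } else if (table_kind == "DRUG") {
    out$role_cod <- toupper(out$role_cod)
    bad_role <- !drop & !out$role_cod %in% .role_codes
    note(out$primaryid[bad_role], "role_cod outside PS/SS/C/I")
    bad_name <- !drop & is_blank(out$drugname)
    note(out$primaryid[bad_name], "empty drugname")
    seq_num <- suppressWarnings(as.integer(out$drug_seq))
    bad_seq <- !drop & is.na(seq_num)
    note(out$primaryid[bad_seq], "unparsable drug_seq")
    drop <- drop | bad_role | bad_name | bad_seq
    out$drug_seq <- seq_num
  } else if (table_kind == "REAC") {
    out$pt <- gsub("\\s+", " ", trimws(out$pt))
    bad_pt <- !drop & is_blank(out$pt)
    note(out$primaryid[bad_pt], "empty pt")
    drop <- drop | bad_pt
  } else if (table_kind == "THER") {
    seq_num <- suppressWarnings(as.integer(out$dsg_drug_seq))
    bad_seq <- !drop & is.na(seq_num)
    note(out$primaryid[bad_seq], "unparsable dsg_drug_seq")
    drop <- drop | bad_seq
    out$dsg_drug_seq <- seq_num
    ks <- partial_date_key(out$start_dt)
    ke <- partial_date_key(out$end_dt)
    full <- nchar(out$start_dt) == 8 & nchar(out$end_dt) == 8
    rev_dates <- !drop & !is.na(ks) & !is.na(ke) & full & ks > ke
    note(out$primaryid[rev_dates], "start_dt after end_dt (kept)")
  } else if (table_kind == "OUTC") {
    out$outc_cod <- toupper(out$outc_cod)
    bad_outc <- !drop & !out$outc_cod %in% .outcome_codes
    note(out$primaryid[bad_outc], "unknown outc_cod")
    drop <- drop | bad_outc
  }

  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "table_kind") <- table_kind
  attr(out, "rejects") <- rejects
  out
}

#' Write a table back to the FAERS ASCII dialect
#'
#' @param x data frame as returned by [read_faers_table()] (or with the same
#'   columns).
#' @param path output path.
#' @param delim field delimiter; `"$"` by default.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(x, path, delim = "$") {
  y <- as.data.frame(lapply(x, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(y, path, sep = delim, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a directory of FAERS quarterly tables
#'
#' Locates files named like `DEMO24Q2.txt` (prefix DEMO/DRUG/REAC/THER/OUTC)
#' in `dir` and reads each with [read_faers_table()]. Several quarters of the
#' same table are row-bound; rejects are concatenated.
#'
#' @param dir directory containing the ASCII files.
#' @param delim field delimiter.
#' @return named list with elements `demo`, `drug`, `reac`, `ther`, `outc`
#'   (missing tables are `NULL`).
#' @export
read_faers_tables <- function(dir, delim = "$") {
  kinds <- names(.faers_schema)
  out <- stats::setNames(vector("list", length(kinds)), tolower(kinds))
  for (kind in kinds) {
    files <- sort(list.files(dir, pattern = paste0("^", kind, ".*\\.(txt|TXT)$"),
                             full.names = TRUE))
    if (!length(files)) next
    parts <- lapply(files, read_faers_table, table_kind = kind, delim = delim)
    tab <- do.call(rbind, parts)
    attr(tab, "table_kind") <- kind
    attr(tab, "rejects") <- do.call(rbind, lapply(parts, attr, "rejects"))
    out[[tolower(kind)]] <- tab
  }
  out
}
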