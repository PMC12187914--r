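# internal helpers shared across the package

#' Round half away from zero
#'
#' Fixed-point rounding with ties going up in absolute value, the convention
#' used for printed report percentages. Base `round()` rounds half to even,
#' which disagrees with published tables at ties such as 0.405.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @export
#' @examples
#' round_half_up(2.345, 2) # 2.35
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
percent <- function(n, denom, digits = 2) {
  if (denom == 0) return(rep(0, length(n)))
  round_half_up(100 * n / denom, digits)
}

# Strip diacritics so e.g. "Témesta" matches "TEMESTA".  iconv transliteration
# is locale-dependent, so a chartr fallback covers the Latin-1 range.
#' @noRd
fold_accents <- function(x) {
  out <- suppressWarnings(iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT"))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    from <- "áàâäãåéèêëíìîïóòôöõúùûüýçñÁÀÂÄÃÅÉÈÊËÍÌÎÏÓÒÔÖÕÚÙÛÜÝÇÑ"
    to   <- "aaaaaaeeeeiiiiooooouuuuycnAAAAAAEEEEIIIIOOOOOUUUUYCN"
    out[bad] <- chartr(from, to, x[bad])
  }
  out[is.na(out)] <- x[is.na(out)]
  # transliteration may leave accent marks as separate characters
  gsub("['`^\"~]", "", out)
}

# Canonical form for matching free text: fold accents, uppercase, squeeze
# whitespace.
#' @noRd
norm_text <- function(x) {
  toupper(gsub("\\s+", " ", trimws(fold_accents(as.character(x)))))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# blank-ish field values coming out of delimited FAERS files
#' @noRd
is_blank <- function(x) is.na(x) | trimws(x) == ""
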