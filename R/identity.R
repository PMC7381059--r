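# Canonicalization of raw patient identifiers. All matching tolerance
# (phonetics, name order, day/month transposition, nicknames) is realized
# here, BEFORE hashing: hashed keys can only be compared for equality, so two
# records can only match if their identifiers canonicalize identically.

#' Canonicalize a date of birth
#'
#' Validates the calendar combination and produces two canonical forms: the
#' ISO date (full when day, month and year are all valid; year-only when only
#' the year is usable; otherwise missing) and the transposition-canonical
#' form used by the name+date key. When both day and month are at most 12 and
#' differ, the smaller value is placed in the day slot, so `03/05/1990` and
#' `05/03/1990` canonicalize identically and a transposed birth date still
#' matches.
#'
#' An invalid calendar combination (e.g. 31 February) drops the day: the
#' record keeps its year-only ISO form and no transposition form.
#'
#' @param day,month,year Integer vectors (NA = missing).
#' @return A data.frame with columns `birth_year`, `birth_month`, `birth_day`
#'   (validated components), `dob_iso` (`"YYYY-MM-DD"`, `"YYYY"`, or `NA`),
#'   `dob_t3` (`"YYYY-MM-DD"` after transposition canonicalization, `NA`
#'   unless all three components are valid) and `dob_invalid` (logical flag
#'   for the validation log).
#' @examples
#' canonicalize_dob(3, 5, 1990)$dob_t3 == canonicalize_dob(5, 3, 1990)$dob_t3
#' @export
canonicalize_dob <- function(day, month, year) {
  n <- max(length(day), length(month), length(year))
  day <- rep_len(suppressWarnings(as.integer(day)), n)
  month <- rep_len(suppressWarnings(as.integer(month)), n)
  year <- rep_len(suppressWarnings(as.integer(year)), n)

  year[!is.na(year) & (year < 1000 | year > 9999)] <- NA_integer_
  month_ok <- !is.na(month) & month >= 1 & month <= 12
  month[!month_ok] <- NA_integer_
  day_in_range <- !is.na(day) & day >= 1 & day <= 31
  day[!day_in_range] <- NA_integer_

  # full calendar validation needs all three parts
  full <- !is.na(day) & !is.na(month) & !is.na(year)
  invalid <- rep(FALSE, n)
  if (any(full)) {
    probe <- as.Date(sprintf("%04d-%02d-%02d", year[full], month[full], day[full]),
                     format = "%Y-%m-%d")
    bad <- is.na(probe)
    invalid[full][bad] <- TRUE
    day[full][bad] <- NA_integer_
    full[full][bad] <- FALSE
  }

  dob_iso <- rep(NA_character_, n)
  dob_iso[!is.na(year)] <- sprintf("%04d", year[!is.na(year)])
  dob_iso[full] <- sprintf("%04d-%02d-%02d", year[full], month[full], day[full])

  # transposition-canonical form: smaller of (day, month) into the day slot
  t3_day <- day
  t3_mon <- month
  swap <- full & day <= 12 & month <= 12 & day != month & month < day
  t3_day[swap] <- month[swap]
  t3_mon[swap] <- day[swap]
  dob_t3 <- rep(NA_character_, n)
  dob_t3[full] <- sprintf("%04d-%02d-%02d", year[full], t3_mon[full], t3_day[full])

  data.frame(birth_year = year, birth_month = month, birth_day = day,
             dob_iso = dob_iso, dob_t3 = dob_t3, dob_invalid = invalid,
             stringsAsFactors = FALSE)
}

#' Normalize a raw sex field
#'
#' Case-insensitive mapping of common encodings: M/MALE to `"M"`, F/FEMALE to
#' `"F"`, any other non-empty value to `"X"`, empty to `NA`.
#'
#' @param raw Character vector.
#' @return Character vector over `{"M", "F", "X", NA}`.
#' @export
normalize_sex <- function(raw) {
  x <- toupper(trimws(blank_to_na(raw)))
  out <- rep(NA_character_, length(x))
  out[!is.na(x)] <- "X"
  out[x %in% c("M", "MALE")] <- "M"
  out[x %in% c("F", "FEMALE")] <- "F"
  out
}

#' Extract the 5 Medicare key digits
#'
#' Strips non-digits and, when at least 10 digits remain (a complete card
#' number, with or without the individual reference number), returns the 5
#' digits starting at `offset`. Shorter strings fail validation and yield
#' `NA`: a partial card number is never hashed.
#'
#' @param raw Character vector of raw Medicare numbers.
#' @param offset 0-based position of the first extracted digit (default 0,
#'   i.e. digits 1-5 of the card number).
#' @return Character vector of 5-digit strings or `NA`.
#' @examples
#' extract_medicare5("2123 45670 1")  # "21234"
#' @export
extract_medicare5 <- function(raw, offset = 0) {
  digits <- gsub("[^0-9]", "", blank_to_na(as.character(raw)))
  out <- rep(NA_character_, length(digits))
  ok <- !is.na(digits) & nchar(digits) >= 10 & nchar(digits) >= offset + 5
  out[ok] <- substr(digits[ok], offset + 1, offset + 5)
  out
}

#' Prepare raw identities for key generation
#'
#' Applies the whole canonicalization chain to a table of identified records:
#' name cleaning and nickname resolution, phonetic encoding, date-of-birth
#' validation and transposition canonicalization, sex normalization, and
#' Medicare digit extraction. Fully deterministic given the configuration
#' lists.
#'
#' @param raw A data.frame with columns `record_id`, `site_id`, `site_type`,
#'   `first_name`, `last_name`, `birth_day`, `birth_month`, `birth_year`,
#'   `sex`, `postcode`, `medicare_number` (missing values as `NA` or empty
#'   strings).
#' @param stop_words,nickname_table Configuration lists; see [clean_name()]
#'   and [resolve_nickname()].
#' @param medicare_offset Passed to [extract_medicare5()].
#' @return A data.frame of prepared identities: `record_id`, `site_id`,
#'   `site_type`, `first_canon`, `last_canon`, `first_phonetic`,
#'   `last_phonetic`, `birth_year`, `dob_iso`, `dob_t3`, `sex_norm`,
#'   `postcode_norm`, `medicare5`, `dob_invalid`.
#' @export
prepare_identities <- function(raw,
                               stop_words = default_stop_words(),
                               nickname_table = default_nickname_table(),
                               medicare_offset = 0) {
  required <- c("record_id", "first_name", "last_name", "birth_day",
                "birth_month", "birth_year", "sex", "postcode",
                "medicare_number")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("identified-records table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  first_canon <- resolve_nickname(clean_name(raw$first_name, stop_words),
                                  nickname_table)
  last_canon <- resolve_nickname(clean_name(raw$last_name, stop_words),
                                 nickname_table)
  dob <- canonicalize_dob(raw$birth_day, raw$birth_month, raw$birth_year)
  postcode_norm <- gsub("[^0-9]", "", blank_to_na(as.character(raw$postcode)))
  postcode_norm[!is.na(postcode_norm) & !nzchar(postcode_norm)] <- NA_character_

  data.frame(
    record_id = as.character(raw$record_id),
    site_id = if ("site_id" %in% names(raw)) as.character(raw$site_id) else NA_character_,
    site_type = if ("site_type" %in% names(raw)) as.character(raw$site_type) else NA_character_,
    first_canon = first_canon,
    last_canon = last_canon,
    first_phonetic = phonetic_encode(first_canon),
    last_phonetic = phonetic_encode(last_canon),
    birth_year = dob$birth_year,
    dob_iso = dob$dob_iso,
    dob_t3 = dob$dob_t3,
    sex_norm = normalize_sex(raw$sex),
    postcode_norm = postcode_norm,
    medicare5 = extract_medicare5(raw$medicare_number, medicare_offset),
    dob_invalid = dob$dob_invalid,
    stringsAsFactors = FALSE
  )
}
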