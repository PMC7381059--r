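# Irreversible hashed linkage keys. Each key is a keyed HMAC-SHA256 digest of
# a fixed, ordered combination of canonical identifier components. Without
# the secret seed the digests cannot be reversed or even re-generated, so
# records can be pooled across sites without exchanging identifiers.

#' Key-generation configuration
#'
#' @param secret_seed Non-empty character or raw secret. All sites in a
#'   linkage network must share it; it must never be written to outputs or
#'   logs (the print method masks it).
#' @param digest_len Length of the emitted keys in hex characters, between 8
#'   and 64 (HMAC-SHA256 digests are 64 hex characters; shorter keys are
#'   truncations).
#' @param medicare_offset 0-based offset of the extracted Medicare digits,
#'   see [extract_medicare5()].
#' @return An object of class `keygen_config`.
#' @export
keygen_config <- function(secret_seed, digest_len = 64, medicare_offset = 0) {
  if (is.raw(secret_seed)) secret_seed <- rawToChar(secret_seed)
  stopifnot(is.character(secret_seed), length(secret_seed) == 1L,
            nzchar(secret_seed))
  digest_len <- as.integer(digest_len)
  stopifnot(length(digest_len) == 1L, digest_len >= 8L, digest_len <= 64L)
  structure(list(secret_seed = secret_seed, digest_len = digest_len,
                 medicare_offset = as.integer(medicare_offset)),
            class = "keygen_config")
}

#' @export
print.keygen_config <- function(x, ...) {
  cat("<keygen_config> digest_len:", x$digest_len,
      " medicare_offset:", x$medicare_offset, " secret_seed: <hidden>\n")
  invisible(x)
}

# Components are joined with the ASCII unit separator, which cannot occur in
# canonical components, so ("A","B") and ("AB","") can never collide.
.component_sep <- "\x1f"

#' Keyed hash of a component combination
#'
#' Produces the hex HMAC-SHA256 digest of the components joined with an
#' unambiguous separator under the configured secret seed. Every component
#' must be present: a key is never a hash of partial identifying
#' information.
#'
#' @param components Character vector of canonical component strings; any
#'   `NA` yields `NA` (no key).
#' @param config A [keygen_config()].
#' @return A lowercase hex string of `config$digest_len` characters, or
#'   `NA_character_`.
#' @export
make_key <- function(components, config) {
  stopifnot(inherits(config, "keygen_config"))
  if (anyNA(components) || !length(components)) return(NA_character_)
  msg <- paste(components, collapse = .component_sep)
  digest <- openssl::sha256(msg, key = config$secret_seed)
  substr(as.character(digest), 1L, config$digest_len)
}

# vectorized internal: msgs may contain NA (no key)
.hmac_many <- function(msgs, config) {
  out <- rep(NA_character_, length(msgs))
  ok <- !is.na(msgs)
  if (any(ok)) {
    digests <- as.character(openssl::sha256(msgs[ok], key = config$secret_seed))
    out[ok] <- substr(digests, 1L, config$digest_len)
  }
  out
}

# join components rowwise; NA if any component NA
.join_components <- function(...) {
  parts <- list(...)
  any_na <- Reduce(`|`, lapply(parts, is.na))
  msg <- do.call(paste, c(parts, sep = .component_sep))
  msg[any_na] <- NA_character_
  msg
}

#' Generate the up-to-four linkage keys per record
#'
#' The four key types combine canonical components as follows:
#' * **key 1** — Medicare digits, full date of birth, sex.
#' * **key 2** — Medicare digits, postcode, first three characters of the
#'   cleaned first name, year of birth.
#' * **key 3** — the two name phonetic codes as a sorted pair (so first/last
#'   order is irrelevant) plus the transposition-canonical date of birth.
#' * **key 4** — the sorted phonetic pair plus the Medicare digits.
#'
#' A key is missing whenever any of its components is missing; keys 1, 2 and
#' 4 therefore all require the Medicare number, and a record without one can
#' carry at most key 3. The key-type number is itself hashed with the
#' components so equal component sets under different types cannot collide.
#'
#' @param prepared Prepared identities from [prepare_identities()].
#' @param config A [keygen_config()].
#' @return A deidentified data.frame: `record_id`, `site_id`, `site_type`,
#'   `key1`..`key4`, `sex`, `birth_year` (sex and year are retained for the
#'   match-acceptance filters).
#' @export
generate_keysets <- function(prepared, config) {
  stopifnot(inherits(config, "keygen_config"))
  p <- prepared
  dob_full <- ifelse(!is.na(p$dob_iso) & nchar(p$dob_iso) == 10L,
                     p$dob_iso, NA_character_)
  yob <- ifelse(is.na(p$birth_year), NA_character_,
                sprintf("%04d", p$birth_year))
  first3 <- ifelse(is.na(p$first_canon) | nchar(p$first_canon) < 3L,
                   NA_character_, substr(p$first_canon, 1L, 3L))
  ph_lo <- pmin(p$first_phonetic, p$last_phonetic)
  ph_hi <- pmax(p$first_phonetic, p$last_phonetic)

  msg1 <- .join_components("1", p$medicare5, dob_full, p$sex_norm)
  msg2 <- .join_components("2", p$medicare5, p$postcode_norm, first3, yob)
  msg3 <- .join_components("3", ph_lo, ph_hi, p$dob_t3)
  msg4 <- .join_components("4", ph_lo, ph_hi, p$medicare5)

  data.frame(
    record_id = p$record_id,
    site_id = p$site_id,
    site_type = p$site_type,
    key1 = .hmac_many(msg1, config),
    key2 = .hmac_many(msg2, config),
    key3 = .hmac_many(msg3, config),
    key4 = .hmac_many(msg4, config),
    sex = p$sex_norm,
    birth_year = p$birth_year,
    stringsAsFactors = FALSE
  )
}

#' Per-site availability of each linkage key type
#'
#' Counts, for each site and key type, how many records carry that key, plus
#' how many records carry no key at all, with percentages rounded half-up to
#' two decimals. An overall `Total` row is appended.
#'
#' @param keysets A data.frame of keysets (from [generate_keysets()] or read
#'   from a deidentified CSV), with columns `site_id`, `key1`..`key4`.
#' @return A data.frame with one row per site plus a total row: `site_id`,
#'   `n_records`, `n_no_keys`, `pct_no_keys`, and `n_key<t>` / `pct_key<t>`
#'   for each type.
#' @export
key_availability_summary <- function(keysets) {
  cols <- paste0("key", 1:4)
  stopifnot(all(cols %in% names(keysets)))
  if (!nrow(keysets)) {
    return(data.frame(site_id = character(0), n_records = integer(0)))
  }
  site <- as.character(keysets$site_id)
  site[is.na(site)] <- "(unknown)"
  has <- vapply(cols, function(k) !is.na(keysets[[k]]), logical(nrow(keysets)))
  none <- rowSums(has) == 0L

  summarise <- function(idx) {
    n <- length(idx)
    row <- data.frame(n_records = n,
                      n_no_keys = sum(none[idx]),
                      pct_no_keys = pct(sum(none[idx]), n))
    for (t in 1:4) {
      row[[paste0("n_key", t)]] <- sum(has[idx, t])
      row[[paste0("pct_key", t)]] <- pct(sum(has[idx, t]), n)
    }
    row
  }
  sites <- sort(unique(site))
  per_site <- do.call(rbind, lapply(sites, function(s) summarise(which(site == s))))
  out <- cbind(site_id = sites, per_site)
  total <- cbind(site_id = "Total", summarise(seq_along(site)))
  rbind(out, total)
}
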