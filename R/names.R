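# Name cleaning and nickname resolution. Both run before phonetic encoding
# and hashing, so the hashed keys already absorb titles, punctuation and
# alias spellings ("Bill" vs "William").

#' Default stop words removed from name fields
#'
#' Titles and honorifics that appear inside name fields in practice. The list
#' ships as an editable CSV (`extdata/titles.csv`) and is configuration, not
#' code: pass your own vector to [clean_name()] to override.
#'
#' @return Uppercase character vector of stop words.
#' @export
default_stop_words <- function() {
  cached <- get0("stop_words", envir = .hashlink_cache)
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "titles.csv", package = "hashlink")
  out <- toupper(utils::read.csv(path, stringsAsFactors = FALSE)$title)
  assign("stop_words", out, envir = .hashlink_cache)
  out
}

.hashlink_cache <- new.env(parent = emptyenv())

#' Default nickname table
#'
#' A bundled list of common English nickname-to-formal-name pairs (an
#' editable stand-in for national nickname registries, which are not
#' published). Keys and values are uppercase; no formal name appears as a
#' nickname key, so resolution is idempotent.
#'
#' @return Named character vector mapping `NICKNAME -> FORMALNAME`.
#' @export
default_nickname_table <- function() {
  cached <- get0("nicknames", envir = .hashlink_cache)
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "nicknames.csv", package = "hashlink")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- stats::setNames(toupper(tab$formal), toupper(tab$nickname))
  assign("nicknames", out, envir = .hashlink_cache)
  out
}

#' Clean a raw name field into a canonical token
#'
#' Uppercases, splits on whitespace, strips non-alphabetic characters within
#' each token, drops stop-word tokens (titles such as DR, MRS, JR), and keeps
#' the longest remaining token (ties broken by position, first wins) so that
#' middle names do not perturb the key. Total function: any input is
#' accepted; an empty result is `NA`.
#'
#' @param raw Character vector of raw name fields.
#' @param stop_words Uppercase tokens to drop; defaults to
#'   [default_stop_words()].
#' @return Character vector of canonical tokens (`NA` = missing).
#' @examples
#' clean_name("O'Brien-Smith ")   # "OBRIENSMITH"
#' clean_name("Dr William")       # "WILLIAM"
#' @export
clean_name <- function(raw, stop_words = default_stop_words()) {
  raw <- blank_to_na(as.character(raw))
  vapply(raw, function(x) {
    if (is.na(x)) return(NA_character_)
    tokens <- strsplit(toupper(x), "\\s+")[[1]]
    tokens <- gsub("[^A-Z]", "", tokens)
    tokens <- tokens[nzchar(tokens) & !(tokens %in% stop_words)]
    if (!length(tokens)) return(NA_character_)
    tokens[which.max(nchar(tokens))]
  }, character(1), USE.NAMES = FALSE)
}

#' Resolve a nickname to its formal form
#'
#' Looks the token up in a nickname table; unmapped tokens (including formal
#' names) pass through unchanged, so the mapping is idempotent.
#'
#' @param token Character vector of cleaned tokens (see [clean_name()]).
#' @param nickname_table Named character vector `NICKNAME -> FORMALNAME`;
#'   defaults to [default_nickname_table()].
#' @return Character vector of resolved tokens.
#' @examples
#' resolve_nickname("BILL")  # "WILLIAM"
#' @export
resolve_nickname <- function(token, nickname_table = default_nickname_table()) {
  hit <- match(token, names(nickname_table))
  out <- token
  out[!is.na(hit)] <- unname(nickname_table[hit[!is.na(hit)]])
  out
}
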