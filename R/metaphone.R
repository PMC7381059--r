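# Double Metaphone phonetic encoding (L. Philips, 2000), implemented from the
# published algorithm description. Names that are commonly misspelled or
# spelled differently across clinic databases (SMITH/SMYTH, JON/JOHN,
# STEPHEN/STEVEN) map to the same code, which is what makes hashed name keys
# tolerant to misspellings: all fuzziness is applied before hashing.

#' Double Metaphone codes for a word
#'
#' Computes the primary and alternate Double Metaphone codes of a single
#' word. Codes are at most `max_length` characters drawn from
#' `A E F H J K L M N P R S T X 0` (`X` is the "sh" sound, `0` the "th"
#' sound). The encoding is deterministic.
#'
#' @param word A single character string. Encoding is case-insensitive;
#'   non-alphabetic characters should already have been removed (see
#'   [clean_name()]).
#' @param max_length Maximum code length (default 4, the conventional value).
#' @return Character vector `c(primary, alternate)`. The alternate equals the
#'   primary when no alternate pronunciation rule fires.
#' @examples
#' double_metaphone("SMITH")  # c("SM0", "XMT")
#' double_metaphone("JON")[1] == double_metaphone("JOHN")[1]
#' @export
double_metaphone <- function(word, max_length = 4L) {
  stopifnot(is.character(word), length(word) == 1L)
  if (is.na(word) || !nzchar(word)) return(c("", ""))
  w <- toupper(word)
  len <- nchar(w)
  last <- len  # 1-based index of last character
  # pad so lookahead never walks off the end
  padded <- paste0(w, strrep(" ", 5))
  ch <- function(i) if (i < 1L) " " else substr(padded, i, i)
  str_at <- function(i, n, ...) {
    if (i < 1L) return(FALSE)
    substr(padded, i, i + n - 1L) %in% c(...)
  }
  vowels <- c("A", "E", "I", "O", "U", "Y")
  is_vowel <- function(i) ch(i) %in% vowels
  slavo <- grepl("W|K|CZ|WITZ", w)

  pri <- character(0)
  alt <- character(0)
  add <- function(p, a = p) {
    if (nzchar(p) && p != " ") pri <<- c(pri, p)
    if (nzchar(a) && a != " ") alt <<- c(alt, a)
  }

  cur <- 1L
  # skip silent initial letters
  if (str_at(1L, 2L, "GN", "KN", "PN", "WR", "PS")) cur <- 2L
  # initial X pronounced as Z -> S (e.g. Xavier)
  if (ch(1L) == "X") {
    add("S")
    cur <- 2L
  }

  repeat {
    if (cur > len) break
    if (sum(nchar(pri)) >= max_length && sum(nchar(alt)) >= max_length) break
    c0 <- ch(cur)

    if (c0 %in% vowels) {
      if (cur == 1L) add("A")
      cur <- cur + 1L

    } else if (c0 == "B") {
      add("P")
      cur <- cur + if (ch(cur + 1L) == "B") 2L else 1L

    } else if (c0 == "C") {
      if (cur > 2L && !is_vowel(cur - 2L) && str_at(cur - 1L, 3L, "ACH") &&
          ch(cur + 2L) != "I" &&
          (ch(cur + 2L) != "E" || str_at(cur - 2L, 6L, "BACHER", "MACHER"))) {
        add("K"); cur <- cur + 2L
      } else if (cur == 1L && str_at(cur, 6L, "CAESAR")) {
        add("S"); cur <- cur + 2L
      } else if (str_at(cur, 4L, "CHIA")) {
        add("K"); cur <- cur + 2L
      } else if (str_at(cur, 2L, "CH")) {
        if (cur > 1L && str_at(cur, 4L, "CHAE")) {
          add("K", "X"); cur <- cur + 2L
        } else if (cur == 1L &&
                   (str_at(cur + 1L, 5L, "HARAC", "HARIS") ||
                    str_at(cur + 1L, 3L, "HOR", "HYM", "HIA", "HEM")) &&
                   !str_at(1L, 5L, "CHORE")) {
          add("K"); cur <- cur + 2L
        } else {
          if (str_at(1L, 4L, "VAN ", "VON ") || str_at(1L, 3L, "SCH") ||
              str_at(cur - 2L, 6L, "ORCHES", "ARCHIT", "ORCHID") ||
              str_at(cur + 2L, 1L, "T", "S") ||
              ((str_at(cur - 1L, 1L, "A", "O", "U", "E") || cur == 1L) &&
               str_at(cur + 2L, 1L, "L", "R", "N", "M", "B", "H", "F", "V", "W", " "))) {
            add("K")
          } else if (cur > 1L) {
            if (str_at(1L, 2L, "MC")) add("K") else add("X", "K")
          } else {
            add("X")
          }
          cur <- cur + 2L
        }
      } else if (str_at(cur, 2L, "CZ") && !str_at(cur - 2L, 4L, "WICZ")) {
        add("S", "X"); cur <- cur + 2L
      } else if (str_at(cur + 1L, 3L, "CIA")) {
        add("X"); cur <- cur + 3L
      } else if (str_at(cur, 2L, "CC") && !(cur == 2L && ch(1L) == "M")) {
        if (str_at(cur + 2L, 1L, "I", "E", "H") && !str_at(cur + 2L, 2L, "HU")) {
          if ((cur == 2L && ch(cur - 1L) == "A") ||
              str_at(cur - 1L, 5L, "UCCEE", "UCCES")) add("KS") else add("X")
          cur <- cur + 3L
        } else {
          add("K"); cur <- cur + 2L
        }
      } else if (str_at(cur, 2L, "CK", "CG", "CQ")) {
        add("K"); cur <- cur + 2L
      } else if (str_at(cur, 2L, "CI", "CE", "CY")) {
        if (str_at(cur, 3L, "CIO", "CIE", "CIA")) add("S", "X") else add("S")
        cur <- cur + 2L
      } else {
        add("K")
        if (str_at(cur + 1L, 2L, " C", " Q", " G")) {
          cur <- cur + 3L
        } else if (str_at(cur + 1L, 1L, "C", "K", "Q") &&
                   !str_at(cur + 1L, 2L, "CE", "CI")) {
          cur <- cur + 2L
        } else {
          cur <- cur + 1L
        }
      }

    } else if (c0 == "D") {
      if (str_at(cur, 2L, "DG")) {
        if (str_at(cur + 2L, 1L, "I", "E", "Y")) {
          add("J"); cur <- cur + 3L
        } else {
          add("TK"); cur <- cur + 2L
        }
      } else if (str_at(cur, 2L, "DT", "DD")) {
        add("T"); cur <- cur + 2L
      } else {
        add("T"); cur <- cur + 1L
      }

    } else if (c0 == "F") {
      add("F")
      cur <- cur + if (ch(cur + 1L) == "F") 2L else 1L

    } else if (c0 == "G") {
      if (ch(cur + 1L) == "H") {
        if (cur > 1L && !is_vowel(cur - 1L)) {
          add("K"); cur <- cur + 2L
        } else if (cur == 1L) {
          if (ch(cur + 2L) == "I") add("J") else add("K")
          cur <- cur + 2L
        } else if ((cur > 2L && str_at(cur - 2L, 1L, "B", "H", "D")) ||
                   (cur > 3L && str_at(cur - 3L, 1L, "B", "H", "D")) ||
                   (cur > 4L && str_at(cur - 4L, 1L, "B", "H"))) {
          cur <- cur + 2L  # silent, e.g. 'hugh', 'bough'
        } else {
          if (cur > 3L && ch(cur - 1L) == "U" &&
              str_at(cur - 3L, 1L, "C", "G", "L", "R", "T")) {
            add("F")  # 'laugh', 'cough', 'rough'
          } else if (cur > 1L && ch(cur - 1L) != "I") {
            add("K")
          }
          cur <- cur + 2L
        }
      } else if (ch(cur + 1L) == "N") {
        if (cur == 2L && is_vowel(1L) && !slavo) {
          add("KN", "N")
        } else if (!str_at(cur + 2L, 2L, "EY") && ch(cur + 1L) != "Y" && !slavo) {
          add("N", "KN")
        } else {
          add("KN")
        }
        cur <- cur + 2L
      } else if (str_at(cur + 1L, 2L, "LI") && !slavo) {
        add("KL", "L"); cur <- cur + 2L
      } else if (cur == 1L &&
                 (ch(cur + 1L) == "Y" ||
                  str_at(cur + 1L, 2L, "ES", "EP", "EB", "EL", "EY", "IB",
                         "IL", "IN", "IE", "EI", "ER"))) {
        add("K", "J"); cur <- cur + 2L
      } else if ((str_at(cur + 1L, 2L, "ER") || ch(cur + 1L) == "Y") &&
                 !str_at(1L, 6L, "DANGER", "RANGER", "MANGER") &&
                 !str_at(cur - 1L, 1L, "E", "I") &&
                 !str_at(cur - 1L, 3L, "RGY", "OGY")) {
        add("K", "J"); cur <- cur + 2L
      } else if (str_at(cur + 1L, 1L, "E", "I", "Y") ||
                 str_at(cur - 1L, 4L, "AGGI", "OGGI")) {
        if (str_at(1L, 4L, "VAN ", "VON ") || str_at(1L, 3L, "SCH") ||
            str_at(cur + 1L, 2L, "ET")) {
          add("K")
        } else if (str_at(cur + 1L, 4L, "IER ")) {
          add("J")
        } else {
          add("J", "K")
        }
        cur <- cur + 2L
      } else {
        cur <- cur + if (ch(cur + 1L) == "G") 2L else 1L
        add("K")
      }

    } else if (c0 == "H") {
      if ((cur == 1L || is_vowel(cur - 1L)) && is_vowel(cur + 1L)) {
        add("H"); cur <- cur + 2L
      } else {
        cur <- cur + 1L
      }

    } else if (c0 == "J") {
      if (str_at(cur, 4L, "JOSE") || str_at(1L, 4L, "SAN ")) {
        if ((cur == 1L && ch(cur + 4L) == " ") || str_at(1L, 4L, "SAN ")) {
          add("H")
        } else {
          add("J", "H")
        }
        cur <- cur + 1L
      } else {
        if (cur == 1L) {
          add("J", "A")
        } else if (is_vowel(cur - 1L) && !slavo &&
                   (ch(cur + 1L) == "A" || ch(cur + 1L) == "O")) {
          add("J", "H")
        } else if (cur == last) {
          add("J", " ")
        } else if (!str_at(cur + 1L, 1L, "L", "T", "K", "S", "N", "M", "B", "Z") &&
                   !str_at(cur - 1L, 1L, "S", "K", "L")) {
          add("J")
        }
        cur <- cur + if (ch(cur + 1L) == "J") 2L else 1L
      }

    } else if (c0 == "K") {
      add("K")
      cur <- cur + if (ch(cur + 1L) == "K") 2L else 1L

    } else if (c0 == "L") {
      if (ch(cur + 1L) == "L") {
        if ((cur == len - 2L && str_at(cur - 1L, 4L, "ILLO", "ILLA", "ALLE")) ||
            ((str_at(last - 1L, 2L, "AS", "OS") || str_at(last, 1L, "A", "O")) &&
             str_at(cur - 1L, 4L, "ALLE"))) {
          add("L", " ")  # Spanish 'cabrillo', 'gallegos'
          cur <- cur + 2L
          next
        }
        cur <- cur + 2L
      } else {
        cur <- cur + 1L
      }
      add("L")

    } else if (c0 == "M") {
      if ((str_at(cur - 1L, 3L, "UMB") &&
           (cur + 1L == last || str_at(cur + 2L, 2L, "ER"))) ||
          ch(cur + 1L) == "M") {
        cur <- cur + 2L
      } else {
        cur <- cur + 1L
      }
      add("M")

    } else if (c0 == "N") {
      add("N")
      cur <- cur + if (ch(cur + 1L) == "N") 2L else 1L

    } else if (c0 == "P") {
      if (ch(cur + 1L) == "H") {
        add("F"); cur <- cur + 2L
      } else {
        cur <- cur + if (str_at(cur + 1L, 1L, "P", "B")) 2L else 1L
        add("P")
      }

    } else if (c0 == "Q") {
      add("K")
      cur <- cur + if (ch(cur + 1L) == "Q") 2L else 1L

    } else if (c0 == "R") {
      if (cur == last && !slavo && str_at(cur - 2L, 2L, "IE") &&
          !str_at(cur - 4L, 2L, "ME", "MA")) {
        add("", "R")  # French 'rogier'
      } else {
        add("R")
      }
      cur <- cur + if (ch(cur + 1L) == "R") 2L else 1L

    } else if (c0 == "S") {
      if (str_at(cur - 1L, 3L, "ISL", "YSL")) {
        cur <- cur + 1L  # silent, 'island', 'carlisle'
      } else if (cur == 1L && str_at(cur, 5L, "SUGAR")) {
        add("X", "S"); cur <- cur + 1L
      } else if (str_at(cur, 2L, "SH")) {
        if (str_at(cur + 1L, 4L, "HEIM", "HOEK", "HOLM", "HOLZ")) add("S") else add("X")
        cur <- cur + 2L
      } else if (str_at(cur, 3L, "SIO", "SIA") || str_at(cur, 4L, "SIAN")) {
        if (!slavo) add("S", "X") else add("S")
        cur <- cur + 3L
      } else if ((cur == 1L && str_at(cur + 1L, 1L, "M", "N", "L", "W")) ||
                 str_at(cur + 1L, 1L, "Z")) {
        add("S", "X")  # 'smith' matches 'schmidt', 'snider' matches 'schneider'
        cur <- cur + if (str_at(cur + 1L, 1L, "Z")) 2L else 1L
      } else if (str_at(cur, 2L, "SC")) {
        if (ch(cur + 2L) == "H") {
          if (str_at(cur + 3L, 2L, "OO", "ER", "EN", "UY", "ED", "EM")) {
            if (str_at(cur + 3L, 2L, "ER", "EN")) add("X", "SK") else add("SK")
            cur <- cur + 3L
          } else {
            if (cur == 1L && !is_vowel(4L) && ch(4L) != "W") add("X", "S") else add("X")
            cur <- cur + 3L
          }
        } else if (str_at(cur + 2L, 1L, "I", "E", "Y")) {
          add("S"); cur <- cur + 3L
        } else {
          add("SK"); cur <- cur + 3L
        }
      } else {
        if (cur == last && str_at(cur - 2L, 2L, "AI", "OI")) {
          add("", "S")  # French 'resnais', 'artois'
        } else {
          add("S")
        }
        cur <- cur + if (str_at(cur + 1L, 1L, "S", "Z")) 2L else 1L
      }

    } else if (c0 == "T") {
      if (str_at(cur, 4L, "TION")) {
        add("X"); cur <- cur + 3L
      } else if (str_at(cur, 3L, "TIA", "TCH")) {
        add("X"); cur <- cur + 3L
      } else if (str_at(cur, 2L, "TH") || str_at(cur, 3L, "TTH")) {
        if (str_at(cur + 2L, 2L, "OM", "AM") ||
            str_at(1L, 4L, "VAN ", "VON ") || str_at(1L, 3L, "SCH")) {
          add("T")  # 'thomas', 'thames', Germanic
        } else {
          add("0", "T")
        }
        cur <- cur + 2L
      } else {
        cur <- cur + if (str_at(cur + 1L, 1L, "T", "D")) 2L else 1L
        add("T")
      }

    } else if (c0 == "V") {
      add("F")
      cur <- cur + if (ch(cur + 1L) == "V") 2L else 1L

    } else if (c0 == "W") {
      if (str_at(cur, 2L, "WR")) {
        add("R"); cur <- cur + 2L
      } else {
        if (cur == 1L && (is_vowel(cur + 1L) || str_at(cur, 2L, "WH"))) {
          if (is_vowel(cur + 1L)) add("A", "F") else add("A")
        }
        if ((cur == last && is_vowel(cur - 1L)) ||
            str_at(cur - 1L, 5L, "EWSKI", "EWSKY", "OWSKI", "OWSKY") ||
            str_at(1L, 3L, "SCH")) {
          add("", "F")  # 'Arnow' matches 'Arnoff'
          cur <- cur + 1L
        } else if (str_at(cur, 4L, "WICZ", "WITZ")) {
          add("TS", "FX"); cur <- cur + 4L
        } else {
          cur <- cur + 1L
        }
      }

    } else if (c0 == "X") {
      if (!(cur == last &&
            (str_at(cur - 3L, 3L, "IAU", "EAU") || str_at(cur - 2L, 2L, "AU", "OU")))) {
        add("KS")
      }
      cur <- cur + if (str_at(cur + 1L, 1L, "C", "X")) 2L else 1L

    } else if (c0 == "Z") {
      if (ch(cur + 1L) == "H") {
        add("J"); cur <- cur + 2L
      } else {
        if (str_at(cur + 1L, 2L, "ZO", "ZI", "ZA") ||
            (slavo && cur > 1L && ch(cur - 1L) != "T")) {
          add("S", "TS")
        } else {
          add("S")
        }
        cur <- cur + if (ch(cur + 1L) == "Z") 2L else 1L
      }

    } else {
      cur <- cur + 1L  # digits, accents etc. contribute nothing
    }
  }

  p <- substr(paste(pri, collapse = ""), 1L, max_length)
  a <- substr(paste(alt, collapse = ""), 1L, max_length)
  if (!nzchar(a)) a <- p
  c(p, a)
}

#' Primary phonetic code of a canonical name token
#'
#' Vectorized wrapper around [double_metaphone()] returning the primary code
#' only. One code per record and key type keeps the keyset bounded; the
#' alternate pronunciation code is not used.
#'
#' @param token Character vector of cleaned, uppercase alphabetic tokens
#'   (see [clean_name()]). `NA` elements stay `NA`.
#' @return Character vector of primary codes; `NA` where the input is `NA` or
#'   yields an empty code.
#' @examples
#' phonetic_encode(c("SMITH", "SMYTH"))
#' @export
phonetic_encode <- function(token) {
  out <- rep(NA_character_, length(token))
  todo <- which(!is.na(token) & nzchar(token))
  if (length(todo)) {
    uniq <- unique(token[todo])
    codes <- vapply(uniq, function(t) double_metaphone(t)[1L], character(1))
    out[todo] <- codes[match(token[todo], uniq)]
  }
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}
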