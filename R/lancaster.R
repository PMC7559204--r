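# Paice/Husk ("Lancaster") suffix-stripping stemmer.
#
# Rules use the compact Paice encoding: reversed ending, optional "*" (apply
# only while the word is still intact), number of characters to remove,
# optional replacement text, and ">" (continue stemming) or "." (stop).
# The table below is the standard published Lancaster rule set, pinned here
# so stems are stable across environments.

.lancaster_default_rules <- c(
  "ai*2.", "a*1.", "bb1.", "city3s.", "ci2>", "cn1t>", "dd1.", "dei3y>",
  "deec2ss.", "dee1.", "de2>", "dooh4>", "e1>", "feil1v.", "fi2>", "gni3>",
  "gai3y.", "ga2>", "gg1.", "ht*2.", "hsiug5ct.", "hsi3>", "i*1.", "i1y>",
  "ji1d.", "juf1s.", "ju1d.", "jo1d.", "jeh1r.", "jrev1t.", "jsim2t.",
  "jn1d.", "j1s.", "lbaifi6.", "lbai4y.", "lba3>", "lbi3.", "lib2l>", "lc1.",
  "lufi4y.", "luf3>", "lu2.", "lai3>", "lau3>", "la2>", "ll1.", "mui3.",
  "mu*2.", "msi3>", "mm1.", "nois4j>", "noix4ct.", "noi3>", "nai3>", "na2>",
  "nee0.", "ne2>", "nn1.", "pihs4>", "pp1.", "re2>", "rae0.", "ra2.", "ro2>",
  "ru2>", "rr1.", "rt1>", "rei3y>", "sei3y>", "sis2.", "si2>", "ssen4>",
  "ss0.", "suo3>", "su*2.", "s*1>", "s0.", "tacilp4y.", "ta2>", "tnem4>",
  "tne3>", "tna3>", "tpir2b.", "tpro2b.", "tcud1.", "tpmus2.", "tpec2iv.",
  "tulo2v.", "tsis0.", "tsi3>", "tt1.", "uqi3.", "ugo1.", "vis3j>", "vie0.",
  "vi2>", "ylb1>", "yli3y>", "ylp0.", "yl2>", "ygo1.", "yhp1.", "ymo1.",
  "ypo1.", "yti3>", "yte3>", "ytl2.", "yrtsi5.", "yra3>", "yro3>", "yfi3.",
  "ycn2t>", "yca3>", "zi2>", "zy1s."
)

#' Stemming rule set for the Lancaster (Paice/Husk) stemmer
#'
#' Parses a vector of rules in the compact Paice encoding into the ordered
#' rule table used by [lancaster_stem()]. Each rule consists of a reversed
#' suffix to match, an optional `*` flag restricting the rule to intact
#' (not-yet-stemmed) words, a digit giving the number of trailing characters
#' to remove, optional replacement characters to append, and a final `>`
#' (keep stemming) or `.` (stop). Rules are grouped by the final letter of
#' the word and tried in table order.
#'
#' @param rules Character vector of encoded rules; defaults to the standard
#'   published Lancaster rule table pinned in the package.
#' @return An object of class `stem_rules`: a data frame with one row per
#'   rule (`ending`, `intact`, `remove`, `append`, `cont`, `section`).
#' @examples
#' rules <- lancaster_rules()
#' head(rules)
#' @export
lancaster_rules <- function(rules = .lancaster_default_rules) {
  stopifnot(is.character(rules), length(rules) > 0L)
  m <- regmatches(rules, regexec("^([a-z]+)(\\*?)([0-9])([a-z]*)([>.])$", rules))
  bad <- vapply(m, length, 1L) != 6L
  if (any(bad)) {
    stop("invalid stemming rule(s): ", paste(rules[bad], collapse = ", "),
         call. = FALSE)
  }
  tab <- data.frame(
    ending = vapply(m, `[`, "", 2L),       # reversed suffix as encoded
    intact = vapply(m, `[`, "", 3L) == "*",
    remove = as.integer(vapply(m, `[`, "", 4L)),
    append = vapply(m, `[`, "", 5L),
    cont = vapply(m, `[`, "", 6L) == ">",
    stringsAsFactors = FALSE
  )
  tab$section <- substr(tab$ending, 1L, 1L)  # last letter of the word
  # un-reverse the ending for suffix comparison
  tab$suffix <- vapply(strsplit(tab$ending, ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, "")
  class(tab) <- c("stem_rules", class(tab))
  tab
}

#' Read a stemming rule table from a text file
#'
#' One encoded rule per line; blank lines and lines starting with `#` are
#' ignored. See [lancaster_rules()] for the encoding.
#'
#' @param path Path to a rule file.
#' @return A `stem_rules` object.
#' @export
read_stem_rules <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lancaster_rules(lines)
}

# a stem may be stripped to `remove` fewer characters only if what remains
# is pronounceable: >= 2 chars starting with a vowel, or >= 3 chars starting
# with a consonant with a vowel (or y) in position 2 or 3
.stem_acceptable <- function(word, remove) {
  n <- nchar(word)
  first <- substr(word, 1L, 1L)
  vowels <- c("a", "e", "i", "o", "u", "y")
  if (first %in% vowels) {
    n - remove >= 2L
  } else {
    n - remove >= 3L &&
      (substr(word, 2L, 2L) %in% vowels || substr(word, 3L, 3L) %in% vowels)
  }
}

#' Stem a single word with the Lancaster (Paice/Husk) algorithm
#'
#' Iteratively strips or rewrites suffixes according to the rule table until
#' a terminating rule fires, no rule matches, or the acceptability condition
#' (minimum stem length / vowel requirement) blocks further stripping.
#' Input is lower-cased; apostrophes are removed first. Stemming only
#' proceeds while the word ends in an unbroken run of letters.
#'
#' @param word Character vector of single words.
#' @param rules A `stem_rules` table from [lancaster_rules()].
#' @return Character vector of stems, one per input word.
#' @examples
#' lancaster_stem(c("ulcerative", "colitis", "diabetes"))
#' @export
lancaster_stem <- function(word, rules = lancaster_rules()) {
  stopifnot(is.character(word), inherits(rules, "stem_rules"))
  vapply(word, .stem_one, "", rules = rules, USE.NAMES = FALSE)
}

.stem_one <- function(word, rules) {
  if (is.na(word)) return(NA_character_)
  word <- gsub("'", "", tolower(word), fixed = TRUE)
  intact <- word
  repeat {
    # position of the last letter of the leading alphabetic run
    last <- regmatches(word, regexpr("^[a-z]+", word))
    if (length(last) == 0L || !nzchar(last)) break
    section <- substr(last, nchar(last), nchar(last))
    sec_rules <- rules[rules$section == section, , drop = FALSE]
    if (nrow(sec_rules) == 0L) break
    applied <- FALSE
    stop_now <- FALSE
    for (k in seq_len(nrow(sec_rules))) {
      rl <- sec_rules[k, ]
      if (!endsWith(word, rl$suffix)) next
      if (rl$intact && !identical(word, intact)) next
      if (!.stem_acceptable(word, rl$remove)) next
      word <- substr(word, 1L, nchar(word) - rl$remove)
      if (nzchar(rl$append)) word <- paste0(word, rl$append)
      applied <- TRUE
      stop_now <- !rl$cont
      break
    }
    if (!applied || stop_now) break
  }
  word
}

#' Stem whitespace-delimited text token by token
#'
#' Tokenizes on whitespace, stems each token independently and rejoins the
#' stems with single spaces. This is the form used as lookup key into the
#' stem-to-category dictionary (multi-word keys such as `"ulc colit"` are
#' matched as whole strings).
#'
#' @param text Character vector of (possibly multi-word) strings.
#' @param rules A `stem_rules` table.
#' @return Character vector of space-joined stem strings.
#' @examples
#' stem_text("ulcerative colitis")  # "ulc colit"
#' @export
stem_text <- function(text, rules = lancaster_rules()) {
  stopifnot(is.character(text))
  if (any(is.na(text) | !nzchar(trimws(text)))) {
    stop("stem_text() requires non-empty input text", call. = FALSE)
  }
  vapply(text, function(s) {
    toks <- strsplit(trimws(s), "\\s+")[[1L]]
    paste(lancaster_stem(toks, rules), collapse = " ")
  }, "", USE.NAMES = FALSE)
}
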