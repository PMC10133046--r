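#' @title Text preprocessing for entity resolution
#' @description Cleaning operators applied to manufacturer and device name
#'   fields before any similarity computation: punctuation removal,
#'   whitespace/special-character cleanup, lowercasing, tokenization,
#'   part-of-speech tagging and legal-suffix stripping. Each operator is
#'   independently testable; [normalize_text()] is their composition.
#' @name textprep
NULL

# Default character sets. Punctuation = ASCII punctuation; "specials" are the
# symbols removed together with extra spaces (asterisks and similar marks that
# are neither letters, digits, punctuation we already strip, nor whitespace).
.default_punctuation <- "!\"#$%&'()*+,-./:;<=>?@[\\]^_`{|}~"

#' Default legal-form suffixes stripped from company names
#'
#' Lowercase tokens recognised as corporate legal forms (Italian, German,
#' French, Anglo-American and Benelux conventions). Used by
#' [strip_company_suffix()] and by the named-entity heuristic.
#'
#' @return Character vector of suffix tokens.
#' @export
default_company_suffixes <- function() {
  c("spa", "srl", "snc", "gmbh", "ag", "sa", "inc", "ltd", "llc",
    "co", "corp", "bv", "nv", "plc", "kg", "sarl")
}

#' Remove punctuation characters
#'
#' Deletes every character belonging to the punctuation set; all other
#' characters keep their order. Vectorised over `text`.
#'
#' @param text Character vector.
#' @param punctuation Single string listing the characters to remove.
#' @return Character vector of the same length.
#' @examples
#' remove_punctuation("My pen is red!")
#' @export
remove_punctuation <- function(text, punctuation = .default_punctuation) {
  if (!nzchar(punctuation)) return(text)
  pattern <- paste0("[", gsub("([][\\^-])", "\\\\\\1", punctuation), "]")
  gsub(pattern, "", text, perl = TRUE)
}

#' Collapse whitespace and drop special characters
#'
#' Removes characters in the special set (by default `*` and any symbol that
#' is neither alphanumeric, punctuation nor whitespace), collapses runs of
#' whitespace to a single space and trims leading/trailing whitespace.
#'
#' @param text Character vector.
#' @param specials Single string of extra characters to delete, or `NULL` to
#'   use the default rule.
#' @return Character vector of the same length.
#' @examples
#' clean_spaces_specials("a  *b ")
#' @export
clean_spaces_specials <- function(text, specials = NULL) {
  if (is.null(specials)) {
    # anything that is not word, space or ASCII punctuation (minus '*')
    out <- gsub("\\*", "", text)
    out <- gsub("[^[:alnum:][:punct:][:space:]]", "", out)
  } else {
    pattern <- paste0("[", gsub("([][\\^-])", "\\\\\\1", specials), "]")
    out <- gsub(pattern, "", text, perl = TRUE)
  }
  out <- gsub("[[:space:]]+", " ", out)
  trimws(out)
}

#' Lowercase text
#'
#' @param text Character vector.
#' @return Character vector of the same length.
#' @export
lowercase_text <- function(text) tolower(text)

#' Normalize a name field
#'
#' Composition of the cleaning operators: punctuation removal, special
#' character/whitespace cleanup and lowercasing. The result is
#' punctuation-free, space-collapsed and lowercase, and the operator is
#' idempotent.
#'
#' @param text Character vector.
#' @param punctuation,specials Passed to the component operators.
#' @return Character vector of the same length.
#' @examples
#' normalize_text("My pen is red!")
#' normalize_text("  ACME*  S.p.A. ")
#' @export
normalize_text <- function(text, punctuation = .default_punctuation,
                           specials = NULL) {
  lowercase_text(clean_spaces_specials(remove_punctuation(text, punctuation),
                                       specials))
}

#' Tokenize a sentence into words
#'
#' Splits on whitespace; on raw (non-normalized) text, trailing or isolated
#' punctuation marks become standalone tokens, so `"red!"` yields `"red"`
#' and `"!"`. On normalized text this reduces to whitespace splitting.
#'
#' @param text Single character string.
#' @return Character vector of tokens (length 0 for empty input).
#' @examples
#' tokenize_words("My pen is red!")
#' @export
tokenize_words <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  # put spaces around punctuation runs, then split on whitespace
  spaced <- gsub("([[:punct:]]+)", " \\1 ", text)
  toks <- strsplit(trimws(gsub("[[:space:]]+", " ", spaced)), " ",
                   fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

# Small bundled lexicon for the deterministic POS backend. Penn-style tags.
.pos_lexicon <- c(
  my = "PRP$", your = "PRP$", his = "PRP$", her = "PRP$", its = "PRP$",
  our = "PRP$", their = "PRP$",
  i = "PRP", you = "PRP", he = "PRP", she = "PRP", it = "PRP", we = "PRP",
  they = "PRP",
  the = "DT", a = "DT", an = "DT", this = "DT", that = "DT",
  is = "VBZ", are = "VBP", was = "VBD", were = "VBD", be = "VB",
  has = "VBZ", have = "VBP", had = "VBD",
  and = "CC", or = "CC", but = "CC",
  of = "IN", in.. = "IN", on = "IN", at = "IN", by = "IN", for.. = "IN",
  with = "IN", from = "IN", to = "TO",
  not = "RB", very = "RB",
  red = "JJ", blue = "JJ", green = "JJ", new = "JJ", old = "JJ",
  medical = "JJ", safe = "JJ", defective = "JJ",
  pen = "NN", device = "NN", notice = "NN", recall = "NN", company = "NN",
  manufacturer = "NN", scanner = "NN", catheter = "NN", prosthesis = "NN"
)
names(.pos_lexicon) <- sub("\\.\\.$", "", names(.pos_lexicon))

#' Default deterministic part-of-speech backend
#'
#' A small bundled lexicon plus suffix rules (`-ly` adverb, `-ing` gerund,
#' `-ed` past tense, plural `-s`), defaulting to singular noun. Punctuation
#' tokens are tagged as themselves. Intended as a reproducible stand-in for a
#' statistical tagger; users can supply their own backend to [pos_tag()].
#'
#' @param tokens Character vector of tokens.
#' @return Character vector of Penn-style tags, one per token.
#' @export
pos_backend_lexicon <- function(tokens) {
  vapply(tokens, function(tok) {
    low <- tolower(tok)
    if (grepl("^[[:punct:]]+$", tok)) return(tok)
    if (!is.na(.pos_lexicon[low])) return(unname(.pos_lexicon[low]))
    if (grepl("[0-9]", tok)) return("CD")
    if (nchar(low) > 3 && endsWith(low, "ly")) return("RB")
    if (nchar(low) > 4 && endsWith(low, "ing")) return("VBG")
    if (nchar(low) > 3 && endsWith(low, "ed")) return("VBD")
    if (nchar(low) > 3 && endsWith(low, "s") && !endsWith(low, "ss"))
      return("NNS")
    "NN"
  }, character(1), USE.NAMES = FALSE)
}

#' Part-of-speech tag a token sequence
#'
#' @param tokens Character vector of tokens.
#' @param backend Function mapping a token vector to a tag vector of the same
#'   length; defaults to the bundled deterministic lexicon backend.
#' @return A data.frame with columns `token` and `tag`; zero rows for empty
#'   input.
#' @examples
#' pos_tag(c("My", "pen", "is", "red"))
#' @export
pos_tag <- function(tokens, backend = pos_backend_lexicon) {
  if (!is.function(backend))
    stop("pos_tag: no tagger backend configured", call. = FALSE)
  if (length(tokens) == 0L)
    return(data.frame(token = character(0), tag = character(0),
                      stringsAsFactors = FALSE))
  tags <- backend(tokens)
  if (length(tags) != length(tokens))
    stop("pos_tag: backend returned ", length(tags), " tags for ",
         length(tokens), " tokens", call. = FALSE)
  data.frame(token = tokens, tag = tags, stringsAsFactors = FALSE)
}

#' Strip trailing corporate legal-form suffixes
#'
#' Removes trailing tokens found in the suffix list, repeatedly, until the
#' last token is not a suffix or a single token remains (a name is never
#' emptied). Input is expected to be normalized.
#'
#' @param name Character vector of normalized company names.
#' @param suffixes Character vector of lowercase suffix tokens.
#' @return Character vector of the same length.
#' @examples
#' strip_company_suffix("acme medical srl")
#' strip_company_suffix("acme gmbh co kg")
#' @export
strip_company_suffix <- function(name, suffixes = default_company_suffixes()) {
  vapply(name, function(nm) {
    if (is.na(nm) || !nzchar(nm)) return(nm)
    toks <- strsplit(nm, " ", fixed = TRUE)[[1]]
    while (length(toks) > 1L && toks[length(toks)] %in% suffixes)
      toks <- toks[-length(toks)]
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical form of a manufacturer name
#'
#' Normalization followed by legal-suffix stripping; the representation under
#' which manufacturer names are compared, deduplicated and vectorised.
#'
#' @param name Character vector of raw manufacturer names.
#' @param suffixes Suffix list for [strip_company_suffix()].
#' @return Character vector of canonical names.
#' @export
canonical_manufacturer <- function(name,
                                   suffixes = default_company_suffixes()) {
  strip_company_suffix(normalize_text(name), suffixes)
}

#' Read a one-entry-per-line configuration list
#'
#' Plain-text loader for suffix lists and character sets: one entry per line,
#' blank lines and lines starting with `#` ignored.
#'
#' @param path File path.
#' @return Character vector of entries.
#' @export
read_config_list <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
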