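#' @title EMDN/CND hierarchical nomenclature codes
#' @description The European Medical Device Nomenclature (derived from the
#'   Italian CND) identifies every device by an alphanumeric code: one letter
#'   for the anatomical/functional category, a two-digit pair for the group
#'   and further two-digit pairs for increasingly specific types, up to seven
#'   levels. Linkage quality is scored level-wise, so codes are compared by
#'   the depth to which their level prefixes agree rather than by full-string
#'   equality.
#' @name emdn
NULL

#' Parse an EMDN/CND code
#'
#' Accepts one category letter followed by zero to six two-digit pairs
#' (case-insensitive; surrounding whitespace ignored).
#'
#' @param code Single non-empty string.
#' @return An object of class `emdn_code`: a list with `raw` (canonical
#'   uppercased code), `category` (the level-1 letter), `level_prefixes`
#'   (character vector, one cumulative prefix per level) and `depth`
#'   (integer, 1..7).
#' @examples
#' parse_emdn("Z110401")
#' parse_emdn("P0908")$level_prefixes
#' @export
parse_emdn <- function(code) {
  if (length(code) != 1L || is.na(code) || !nzchar(trimws(code)))
    stop("parse_emdn: code must be a non-empty string", call. = FALSE)
  raw <- toupper(trimws(code))
  if (!grepl("^[A-Z]", raw))
    stop("parse_emdn: '", code, "' must start with a category letter",
         call. = FALSE)
  digits <- substring(raw, 2L)
  if (!grepl("^[0-9]*$", digits))
    stop("parse_emdn: '", code, "' contains non-digit characters after the ",
         "category letter", call. = FALSE)
  if (nchar(digits) %% 2L != 0L)
    stop("parse_emdn: '", code, "' has an odd number of digits; levels ",
         "below the category are two-digit pairs", call. = FALSE)
  depth <- 1L + nchar(digits) %/% 2L
  if (depth > 7L)
    stop("parse_emdn: '", code, "' exceeds the maximum of seven levels",
         call. = FALSE)
  prefixes <- vapply(seq_len(depth),
                     function(k) substr(raw, 1L, 1L + 2L * (k - 1L)),
                     character(1))
  structure(list(raw = raw, category = substr(raw, 1L, 1L),
                 level_prefixes = prefixes, depth = depth),
            class = "emdn_code")
}

#' @export
print.emdn_code <- function(x, ...) {
  cat("<EMDN ", x$raw, "> depth ", x$depth, ": ",
      paste(x$level_prefixes, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Hierarchical agreement depth between two codes
#'
#' The largest level `k` such that the two codes share all level prefixes
#' `1..k`; 0 when the categories already differ. "Correct at level k" in
#' validation means agreement depth at least `k`.
#'
#' @param a,b `emdn_code` objects (see [parse_emdn()]), or strings parsed on
#'   the fly.
#' @return Integer in 0..7.
#' @examples
#' emdn_agreement_depth("Z110401", "Z110401")  # 4
#' emdn_agreement_depth("P0908", "Z110401")    # 0
#' emdn_agreement_depth("P0908", "P09")        # 2
#' @export
emdn_agreement_depth <- function(a, b) {
  if (!inherits(a, "emdn_code")) a <- parse_emdn(a)
  if (!inherits(b, "emdn_code")) b <- parse_emdn(b)
  kmax <- min(a$depth, b$depth)
  k <- 0L
  while (k < kmax && a$level_prefixes[k + 1L] == b$level_prefixes[k + 1L])
    k <- k + 1L
  k
}

#' Truncate a code to a level
#'
#' @param x An `emdn_code` or string.
#' @param level Target depth (capped at the code's own depth).
#' @return An `emdn_code` of depth `min(level, depth(x))`.
#' @export
emdn_truncate <- function(x, level) {
  if (!inherits(x, "emdn_code")) x <- parse_emdn(x)
  level <- min(as.integer(level), x$depth)
  stopifnot(level >= 1L)
  parse_emdn(x$level_prefixes[level])
}

# Internal vectorised helper: depth-k prefix of raw code strings, NA where the
# code is missing/unparseable. Used by the aggregation and validation layers.
emdn_prefix_at <- function(codes, level) {
  vapply(codes, function(cd) {
    if (is.na(cd) || !nzchar(cd)) return(NA_character_)
    p <- tryCatch(parse_emdn(cd), error = function(e) NULL)
    if (is.null(p) || p$depth < level) return(NA_character_)
    p$level_prefixes[level]
  }, character(1), USE.NAMES = FALSE)
}
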