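#' @title Phase-2 entity resolution: fuzzy device matching
#' @description Within the candidate block produced by manufacturer
#'   blocking, the notice's device fields are compared against each
#'   candidate device with a Levenshtein-based token-set ratio (0..100).
#'   Two field pairs are scored — the notice's device name against the
#'   registry commercial name, and the notice's commercial-name field
#'   (which often embeds a catalogue code) against the registry catalogue
#'   code — and combined by taking the better of the two. Acceptance walks
#'   an iterative threshold schedule from 95 down to a floor of 60 in steps
#'   of 5: at the first threshold any candidate reaches, the
#'   highest-scoring candidate wins.
#' @name device_match
NULL

#' Levenshtein edit distance
#'
#' Minimal number of unit-cost insertions, deletions and substitutions
#' transforming `a` into `b`. Vectorised with recycling.
#'
#' @param a,b Character vectors.
#' @return Integer vector of distances.
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' @export
levenshtein <- function(a, b) {
  d <- utils::adist(a, b, costs = c(ins = 1, del = 1, sub = 1))
  if (length(a) == length(b)) as.integer(diag(as.matrix(d)))
  else as.integer(d)
}

# edit distance with substitution cost 2 (equivalently: indel-only distance)
.dist2 <- function(a, b) {
  as.integer(utils::adist(a, b, costs = c(ins = 1, del = 1, sub = 2)))
}

#' Normalized similarity ratio (0..100)
#'
#' With \eqn{d_2} the edit distance under substitution cost 2 and unit
#' insert/delete costs, the ratio is
#' \eqn{\mathrm{round}(100\,(|a|+|b|-d_2)/(|a|+|b|))}, and 100 when both
#' strings are empty. This is the standard normalization used by fuzzy
#' string-matching libraries.
#'
#' @param a,b Single strings.
#' @return Integer score in 0..100.
#' @examples
#' ratio_score("ab", "ac")  # 50
#' @export
ratio_score <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la + lb == 0L) return(100L)
  as.integer(round(100 * (la + lb - .dist2(a, b)) / (la + lb)))
}

#' Token-set similarity ratio (0..100)
#'
#' Both inputs (assumed normalized) are split on whitespace and de-duplicated
#' into token sets. With `I` the sorted common tokens, `Ra`/`Rb` the sorted
#' tokens unique to each side, three strings are formed — `join(I)`,
#' `join(I, Ra)`, `join(I, Rb)` — and the maximum pairwise [ratio_score()]
#' among them is returned. The construction is order- and
#' duplication-invariant and yields 100 whenever one token set contains the
#' other, which makes it robust to strings of very different lengths (a
#' short catalogue code embedded in a long commercial-name field).
#'
#' @param a,b Single normalized strings.
#' @return Integer score in 0..100.
#' @examples
#' token_set_ratio("alpha beta", "beta alpha")      # 100
#' token_set_ratio("probe x200", "probe x200 kit")  # 100 (subset)
#' @export
token_set_ratio <- function(a, b) {
  ta <- unique(strsplit(trimws(a), "[[:space:]]+")[[1]])
  tb <- unique(strsplit(trimws(b), "[[:space:]]+")[[1]])
  ta <- ta[nzchar(ta)]; tb <- tb[nzchar(tb)]
  common <- sort(intersect(ta, tb))
  ra <- sort(setdiff(ta, tb))
  rb <- sort(setdiff(tb, ta))
  s0 <- paste(common, collapse = " ")
  s1 <- paste(c(common, ra), collapse = " ")
  s2 <- paste(c(common, rb), collapse = " ")
  max(ratio_score(s0, s1), ratio_score(s0, s2), ratio_score(s1, s2))
}

#' Score one notice against one candidate device
#'
#' The maximum of the two field-pair token-set ratios:
#' `device_vs_commercial` (notice device name vs registry commercial name)
#' and `commercial_vs_catalogue` (notice commercial-name field vs registry
#' catalogue code). A pair with an empty side contributes 0.
#'
#' @param notice_device,notice_commercial Normalized notice fields.
#' @param device_commercial,device_catalogue Normalized registry fields.
#' @return List with `score` (integer 0..100) and `field_pair` (which pair
#'   achieved it; the device-name pair on ties).
#' @export
score_pair <- function(notice_device, notice_commercial,
                       device_commercial, device_catalogue) {
  nonempty <- function(x) !is.na(x) && nzchar(trimws(x))
  s1 <- if (nonempty(notice_device) && nonempty(device_commercial))
    token_set_ratio(notice_device, device_commercial) else 0L
  s2 <- if (nonempty(notice_commercial) && nonempty(device_catalogue))
    token_set_ratio(notice_commercial, device_catalogue) else 0L
  if (s1 >= s2) list(score = as.integer(s1), field_pair = "device_vs_commercial")
  else list(score = as.integer(s2), field_pair = "commercial_vs_catalogue")
}

#' Iterative threshold schedule
#'
#' @param start First threshold tried (default 95).
#' @param step Decrement between attempts (default 5).
#' @param floor Minimum acceptable threshold (default 60); candidates
#'   scoring below the floor never match.
#' @return List of class `threshold_schedule`.
#' @export
threshold_schedule <- function(start = 95L, step = 5L, floor = 60L) {
  start <- as.integer(start); step <- as.integer(step)
  floor <- as.integer(floor)
  stopifnot(start >= floor, step > 0L)
  structure(list(start = start, step = step, floor = floor),
            class = "threshold_schedule")
}

#' Find the best-matching device within a candidate block
#'
#' Scores each candidate once with [score_pair()], then walks the threshold
#' schedule downwards. At the first threshold reached by at least one
#' candidate, the highest-scoring candidate is selected (ties broken by the
#' smallest progressive identifier, numerically where possible). If no
#' candidate reaches the floor, no match is returned. Extensionally this
#' equals "take the argmax if its score reaches the floor", with the
#' accepted threshold recording where in the schedule the match fired.
#'
#' @param notice One-row slice (or list) with normalized fields
#'   `device_norm` and `commercial_norm`.
#' @param candidates Data frame of candidate devices with columns
#'   `progressive_id`, `commercial_norm`, `catalogue_norm`.
#' @param schedule A [threshold_schedule()].
#' @return `NULL` when unmatched, else a list with `device_id`, `score`,
#'   `accepted_threshold`, `field_pair`.
#' @export
find_best_device <- function(notice, candidates,
                             schedule = threshold_schedule()) {
  n <- nrow(candidates)
  if (is.null(n) || n == 0L) return(NULL)
  scored <- vector("list", n)
  scores <- integer(n)
  for (i in seq_len(n)) {
    scored[[i]] <- score_pair(notice$device_norm, notice$commercial_norm,
                              candidates$commercial_norm[i],
                              candidates$catalogue_norm[i])
    scores[i] <- scored[[i]]$score
  }
  sth <- schedule$start
  while (sth >= schedule$floor) {
    hit <- which(scores >= sth)
    if (length(hit)) {
      top <- hit[scores[hit] == max(scores[hit])]
      if (length(top) > 1L) {
        ids <- candidates$progressive_id[top]
        num <- suppressWarnings(as.numeric(ids))
        ord <- if (anyNA(num)) order(ids) else order(num)
        top <- top[ord[1L]]
      }
      return(list(device_id = candidates$progressive_id[top],
                  score = scores[top],
                  accepted_threshold = as.integer(sth),
                  field_pair = scored[[top]]$field_pair))
    }
    sth <- sth - schedule$step
  }
  NULL
}
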