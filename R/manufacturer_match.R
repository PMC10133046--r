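#' @title Phase-1 entity resolution: manufacturer blocking
#' @description Comparing every safety notice against every registry device
#'   is infeasible (a national registry holds on the order of 1.5 million
#'   devices), so candidate devices are first restricted to those whose
#'   manufacturer is "similar" to the notice's manufacturer. Two
#'   interchangeable blocking methods are provided: TF-IDF cosine similarity
#'   on suffix-stripped canonical names with an acceptance threshold
#'   (default 0.90), and named-entity equality where a pluggable extractor
#'   pulls the organisation name out of the raw string and blocks demand
#'   exact agreement. An empty named entity falls back to an un-blocked
#'   (global) search, mirroring how extraction failure behaves in practice.
#' @name manufacturer_match
NULL

#' Build a TF-IDF model over manufacturer names
#'
#' Each canonical (normalized, suffix-stripped, deduplicated) manufacturer
#' name is one document. Term frequency is the raw within-name count; the
#' inverse document frequency is smoothed,
#' \eqn{\mathrm{idf}(t) = \ln\frac{1+N}{1+\mathrm{df}(t)} + 1}, and document
#' vectors are L2-normalized. Vocabulary order is first occurrence.
#'
#' @param names Character vector of canonical manufacturer names (the
#'   document corpus); duplicates are collapsed.
#' @return An object of class `tfidf_model`: list with `vocabulary`,
#'   `doc_count`, `doc_freq`, `idf`.
#' @export
build_tfidf <- function(names) {
  names <- unique(names[!is.na(names) & nzchar(names)])
  if (length(names) == 0L)
    stop("build_tfidf: empty corpus", call. = FALSE)
  token_lists <- strsplit(names, " ", fixed = TRUE)
  vocabulary <- unique(unlist(token_lists))
  df <- integer(length(vocabulary))
  names(df) <- vocabulary
  for (toks in token_lists) {
    u <- unique(toks)
    df[u] <- df[u] + 1L
  }
  n <- length(names)
  idf <- log((1 + n) / (1 + df)) + 1
  structure(list(vocabulary = vocabulary, doc_count = n, doc_freq = df,
                 idf = idf),
            class = "tfidf_model")
}

#' TF-IDF vector of a name under a model
#'
#' Out-of-vocabulary terms get weight zero; the vector is L2-normalized
#' unless it is identically zero.
#'
#' @param model A `tfidf_model`.
#' @param name Single canonical name.
#' @return Numeric vector over `model$vocabulary`.
#' @export
tfidf_vector <- function(model, name) {
  v <- numeric(length(model$vocabulary))
  names(v) <- model$vocabulary
  if (is.na(name) || !nzchar(name)) return(v)
  tf <- table(strsplit(name, " ", fixed = TRUE)[[1]])
  keep <- intersect(names(tf), model$vocabulary)
  v[keep] <- as.numeric(tf[keep]) * model$idf[keep]
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

# dense doc-term weight matrix (rows = names), L2-normalized rows
tfidf_matrix <- function(model, names) {
  m <- matrix(0, nrow = length(names), ncol = length(model$vocabulary),
              dimnames = list(NULL, model$vocabulary))
  token_lists <- strsplit(names, " ", fixed = TRUE)
  for (i in seq_along(names)) {
    tf <- table(token_lists[[i]])
    keep <- intersect(names(tf), model$vocabulary)
    m[i, keep] <- as.numeric(tf[keep]) * model$idf[keep]
  }
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m
}

#' Cosine similarity between two weight vectors
#'
#' \eqn{u \cdot v / (|u||v|)}; defined as 0 when either vector is zero.
#'
#' @param u,v Nonnegative numeric vectors over a shared vocabulary.
#' @return Numeric scalar in `[0, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  min(1, sum(u * v) / (nu * nv))
}

#' Block registry manufacturers by TF-IDF cosine
#'
#' Returns every registry manufacturer whose cosine similarity with the
#' notice manufacturer reaches the threshold. An empty block is a valid
#' outcome and carries a reason: `"oov"` when the query has no in-vocabulary
#' term, `"below_threshold"` otherwise.
#'
#' @param notice_name Canonical notice manufacturer name (preprocessed the
#'   same way as the corpus).
#' @param model A `tfidf_model` whose corpus covers the registry names.
#' @param registry_names Character vector of canonical registry manufacturer
#'   names to score against.
#' @param threshold Acceptance threshold in `(0, 1]`, default 0.90.
#' @return An object of class `manufacturer_block`: list with
#'   `notice_manufacturer`, `matched` (character vector), `scores` (named
#'   numeric), `method = "cos"`, `reason` (`NA` unless the block is empty).
#' @export
block_by_cosine <- function(notice_name, model, registry_names,
                            threshold = 0.90) {
  stopifnot(threshold > 0, threshold <= 1)
  q <- tfidf_vector(model, notice_name)
  if (all(q == 0)) {
    return(structure(list(notice_manufacturer = notice_name,
                          matched = character(0), scores = numeric(0),
                          method = "cos", reason = "oov"),
                     class = "manufacturer_block"))
  }
  m <- tfidf_matrix(model, registry_names)
  sims <- as.numeric(m %*% q)          # rows already unit norm
  sims <- pmin(sims, 1)
  keep <- sims >= threshold
  scores <- sims[keep]
  names(scores) <- registry_names[keep]
  structure(list(notice_manufacturer = notice_name,
                 matched = registry_names[keep], scores = scores,
                 method = "cos",
                 reason = if (any(keep)) NA_character_ else "below_threshold"),
            class = "manufacturer_block")
}

#' Extract the organisation named entity from a raw manufacturer string
#'
#' Default deterministic heuristic: the longest run of capitalized tokens,
#' excluding tokens whose normalized form is a corporate legal suffix.
#' Suffixes are deliberately kept in the *input* (extraction operates on raw
#' names, where the legal form is informative context), but the extracted
#' entity itself excludes them. Returns the empty string when no capitalized
#' token exists — extraction failure, handled upstream by falling back to a
#' global search.
#'
#' @param name Raw (non-normalized) manufacturer string.
#' @param backend Extraction function taking and returning one string;
#'   defaults to the capitalized-run heuristic. Plug in a statistical NER
#'   model here if one is available.
#' @param suffixes Legal suffix list used by the default heuristic.
#' @return Single string, possibly empty.
#' @examples
#' extract_named_entity("Acme Medical S.p.A.")
#' extract_named_entity("unknown lowercase firm")  # ""
#' @export
extract_named_entity <- function(name, backend = NULL,
                                 suffixes = default_company_suffixes()) {
  if (!is.null(backend)) {
    if (!is.function(backend))
      stop("extract_named_entity: backend is not a function", call. = FALSE)
    return(backend(name))
  }
  if (is.na(name) || !nzchar(trimws(name))) return("")
  toks <- strsplit(trimws(gsub("[[:space:]]+", " ", name)), " ",
                   fixed = TRUE)[[1]]
  # a token is part of the entity if it starts with a capital and is not a
  # legal-form abbreviation ("S.p.A." normalizes to "spa")
  is_cap <- grepl("^[A-Z]", toks) &
    !(normalize_text(toks) %in% suffixes)
  if (!any(is_cap)) return("")
  # longest run of capitalized non-suffix tokens; first one on ties
  r <- rle(is_cap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cap_runs <- which(r$values)
  best <- cap_runs[which.max(r$lengths[cap_runs])]
  paste(toks[starts[best]:ends[best]], collapse = " ")
}

#' Block registry manufacturers by named-entity equality
#'
#' Registry manufacturers whose extracted entity equals the notice's
#' extracted entity (compared after normalization). When extraction on the
#' notice side fails (empty entity), the block is the whole registry — an
#' un-blocked search — with reason `"empty_ne_global"` recorded.
#'
#' @param notice_name Raw notice manufacturer string.
#' @param registry_names Character vector of raw registry manufacturer
#'   names.
#' @param backend Optional extraction backend, see
#'   [extract_named_entity()].
#' @return A `manufacturer_block` with `method = "ner"` (no scores).
#' @export
block_by_ner <- function(notice_name, registry_names, backend = NULL) {
  ne_notice <- normalize_text(extract_named_entity(notice_name, backend))
  if (!nzchar(ne_notice)) {
    return(structure(list(notice_manufacturer = notice_name,
                          matched = registry_names, scores = NULL,
                          method = "ner", reason = "empty_ne_global"),
                     class = "manufacturer_block"))
  }
  ne_reg <- vapply(registry_names, function(nm)
    normalize_text(extract_named_entity(nm, backend)), character(1),
    USE.NAMES = FALSE)
  keep <- ne_reg == ne_notice
  structure(list(notice_manufacturer = notice_name,
                 matched = registry_names[keep], scores = NULL,
                 method = "ner",
                 reason = if (any(keep)) NA_character_ else "no_ne_match"),
            class = "manufacturer_block")
}

#' @export
print.manufacturer_block <- function(x, ...) {
  cat("<manufacturer_block method=", x$method, "> '",
      x$notice_manufacturer, "' -> ", length(x$matched), " name(s)",
      if (!is.na(x$reason)) paste0(" [", x$reason, "]"), "\n", sep = "")
  invisible(x)
}
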