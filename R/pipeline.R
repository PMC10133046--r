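#' @title Linkage pipeline and surveillance aggregation
#' @description Orchestrates the resolution of each safety notice against
#'   the device registry. A notice carrying a BD/RMD identifier is linked
#'   directly by key lookup (Case 1); otherwise two-phase entity resolution
#'   runs: manufacturer blocking, then fuzzy device matching within the
#'   block (Case 2). The nomenclature code of the matched device is attached
#'   to the link, and linked notices can be aggregated into surveillance
#'   summaries (counts by year, by nomenclature prefix at a chosen level,
#'   and by manufacturer).
#' @name pipeline
NULL

#' Build a resolution index over a device registry
#'
#' Precomputes everything phase-1 and phase-2 need: canonical manufacturer
#' names, normalized device fields, the progressive-identifier lookup and
#' the per-manufacturer device blocks. Build it once, resolve many notices
#' against it.
#'
#' @param devices `device_registry` data.frame (see [read_devices()]).
#' @param extra_manufacturers Optional character vector of raw notice
#'   manufacturer names folded into the TF-IDF corpus, so query and corpus
#'   weights share one document universe.
#' @param suffixes Legal suffix list for canonicalisation.
#' @return An object of class `registry_index`.
#' @export
build_registry_index <- function(devices, extra_manufacturers = NULL,
                                 suffixes = default_company_suffixes()) {
  stopifnot(nrow(devices) > 0L)
  dev <- as.data.frame(devices)
  dev$manufacturer_canon <- canonical_manufacturer(dev$manufacturer, suffixes)
  dev$commercial_norm <- normalize_text(dev$commercial_name)
  dev$catalogue_norm <- normalize_text(dev$catalogue_code)
  canon_names <- unique(dev$manufacturer_canon)
  corpus <- canon_names
  if (!is.null(extra_manufacturers))
    corpus <- unique(c(corpus,
                       canonical_manufacturer(extra_manufacturers, suffixes)))
  model <- build_tfidf(corpus)
  structure(list(
    devices = dev,
    by_id = split(seq_len(nrow(dev)), dev$progressive_id),
    by_manufacturer = split(seq_len(nrow(dev)), dev$manufacturer_canon),
    canon_names = canon_names,
    canon_matrix = tfidf_matrix(model, canon_names),
    tfidf = model,
    suffixes = suffixes), class = "registry_index")
}

#' @export
print.registry_index <- function(x, ...) {
  cat("<registry_index> ", nrow(x$devices), " device row(s), ",
      length(x$canon_names), " canonical manufacturer(s), vocabulary ",
      length(x$tfidf$vocabulary), "\n", sep = "")
  invisible(x)
}

# phase-1 block for one canonical notice manufacturer name
.block_for <- function(index, raw_name, canon_name, method, cos_threshold,
                       ner_backend) {
  if (method == "cos") {
    q <- tfidf_vector(index$tfidf, canon_name)
    if (all(q == 0))
      return(list(matched = character(0), reason = "oov"))
    sims <- pmin(as.numeric(index$canon_matrix %*% q), 1)
    keep <- sims >= cos_threshold
    if (!any(keep)) return(list(matched = character(0), reason = "no_block"))
    list(matched = index$canon_names[keep], reason = NA_character_)
  } else {
    blk <- block_by_ner(raw_name, unique(index$devices$manufacturer),
                        backend = ner_backend)
    if (length(blk$matched) == 0L)
      return(list(matched = character(0), reason = "no_block"))
    list(matched = unique(canonical_manufacturer(blk$matched,
                                                 index$suffixes)),
         reason = NA_character_)
  }
}

empty_link <- function(ref) {
  n <- length(ref)
  data.frame(reference_number = ref,
             provenance = rep(NA_character_, n),
             device_id = rep(NA_character_, n),
             emdn_code = rep(NA_character_, n),
             score = rep(NA_integer_, n),
             accepted_threshold = rep(NA_integer_, n),
             failure_reason = rep(NA_character_, n),
             stringsAsFactors = FALSE)
}

#' Resolve a single notice against the registry
#'
#' Case 1: the notice carries a BD/RMD identifier — link directly to the
#' registry row with that progressive identifier (unmatched with reason
#' `no_bdrmd_in_registry` if absent). Case 2: manufacturer blocking followed
#' by [find_best_device()] within the block. The matched device's
#' nomenclature code is attached (possibly absent when the registry row has
#' none).
#'
#' @param notice One-row `notice_set` slice.
#' @param index A [build_registry_index()] result.
#' @param method `"cos"` (TF-IDF cosine blocking, default) or `"ner"`
#'   (named-entity equality).
#' @param cos_threshold Cosine acceptance threshold, default 0.90.
#' @param schedule Phase-2 [threshold_schedule()].
#' @param ner_backend Optional entity-extraction backend.
#' @return One-row `link_results` data.frame.
#' @export
resolve_notice <- function(notice, index, method = c("cos", "ner"),
                           cos_threshold = 0.90,
                           schedule = threshold_schedule(),
                           ner_backend = NULL) {
  method <- match.arg(method)
  out <- empty_link(notice$reference_number)
  # Case 1: direct identifier link
  if (!is.na(notice$bdrmd) && nzchar(notice$bdrmd)) {
    rows <- index$by_id[[notice$bdrmd]]
    if (is.null(rows)) {
      out$provenance <- "unmatched"
      out$failure_reason <- "no_bdrmd_in_registry"
      return(structure(out, class = c("link_results", "data.frame")))
    }
    row <- rows[1L]
    out$provenance <- "direct"
    out$device_id <- index$devices$progressive_id[row]
    code <- index$devices$emdn_code[row]
    out$emdn_code <- if (!is.na(code) && nzchar(code)) code else NA_character_
    return(structure(out, class = c("link_results", "data.frame")))
  }
  # Case 2: two-phase entity resolution
  canon <- canonical_manufacturer(notice$manufacturer, index$suffixes)
  blk <- .block_for(index, notice$manufacturer, canon, method,
                    cos_threshold, ner_backend)
  if (length(blk$matched) == 0L) {
    out$provenance <- "unmatched"
    out$failure_reason <- blk$reason
    return(structure(out, class = c("link_results", "data.frame")))
  }
  cand_rows <- unlist(index$by_manufacturer[blk$matched], use.names = FALSE)
  candidates <- index$devices[cand_rows, , drop = FALSE]
  nn <- list(device_norm = normalize_text(notice$device),
             commercial_norm = normalize_text(notice$commercial_name))
  best <- find_best_device(nn, candidates, schedule)
  if (is.null(best)) {
    out$provenance <- "unmatched"
    out$failure_reason <- "below_floor"
    return(structure(out, class = c("link_results", "data.frame")))
  }
  out$provenance <- "er"
  out$device_id <- best$device_id
  out$score <- best$score
  out$accepted_threshold <- best$accepted_threshold
  code <- index$devices$emdn_code[index$by_id[[best$device_id]][1L]]
  out$emdn_code <- if (!is.na(code) && nzchar(code)) code else NA_character_
  structure(out, class = c("link_results", "data.frame"))
}

#' Resolve a whole notice set
#'
#' Order-preserving batch wrapper around [resolve_notice()]. Deterministic
#' given identical inputs and configuration. Per-provenance tallies and
#' elapsed time are attached as the `"run_log"` attribute and reported via
#' `message()`.
#'
#' @param notices `notice_set` data.frame.
#' @param index A [build_registry_index()] result (build it with
#'   `extra_manufacturers = notices$manufacturer` so the TF-IDF document
#'   universe covers both sources).
#' @param ... Passed to [resolve_notice()].
#' @param quiet Suppress the tally message.
#' @return `link_results` data.frame, one row per notice in input order.
#' @export
resolve_all <- function(notices, index, ..., quiet = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  rows <- lapply(seq_len(nrow(notices)), function(i)
    resolve_notice(notices[i, , drop = FALSE], index, ...))
  links <- if (length(rows)) do.call(rbind, rows) else empty_link(character(0))
  rownames(links) <- NULL
  tally <- c(direct = sum(links$provenance == "direct"),
             er = sum(links$provenance == "er"),
             unmatched = sum(links$provenance == "unmatched"))
  log <- list(n = nrow(links), tally = tally,
              elapsed_s = proc.time()[["elapsed"]] - t0)
  if (!quiet)
    message("resolve_all: ", log$n, " notice(s): ", tally[["direct"]],
            " direct, ", tally[["er"]], " er, ", tally[["unmatched"]],
            " unmatched (", sprintf("%.2f", log$elapsed_s), " s)")
  attr(links, "run_log") <- log
  class(links) <- c("link_results", "data.frame")
  links
}

#' Aggregate linked notices into a surveillance summary
#'
#' Counts the notices passing the filters by calendar year, by nomenclature
#' prefix at the requested level, and by canonical manufacturer. Notices
#' without an assigned code fall into a reserved `"unassigned"` bucket of
#' the nomenclature map (and of the prefix filter, which they never pass).
#'
#' @param links `link_results` from [resolve_all()].
#' @param notices The `notice_set` the links were computed from.
#' @param emdn_level Aggregation depth for the nomenclature map, 1..4.
#' @param year_range Optional `c(from, to)` filter on notice year.
#' @param emdn_prefix Optional code-prefix filter (e.g. `"P09"`).
#' @param manufacturer Optional case-insensitive substring filter on the
#'   notice manufacturer.
#' @return List of class `surveillance_summary`: `total_notices`,
#'   `counts_by_year`, `counts_by_emdn_prefix`, `counts_by_manufacturer`.
#' @export
summarize_links <- function(links, notices, emdn_level = 1L,
                            year_range = NULL, emdn_prefix = NULL,
                            manufacturer = NULL) {
  emdn_level <- as.integer(emdn_level)
  if (is.na(emdn_level) || emdn_level < 1L || emdn_level > 4L)
    stop("summarize_links: emdn_level must be in 1..4", call. = FALSE)
  m <- match(notices$reference_number, links$reference_number)
  if (anyNA(m))
    stop("summarize_links: links and notices do not align", call. = FALSE)
  code <- links$emdn_code[m]
  prefix <- emdn_prefix_at(code, emdn_level)
  prefix[is.na(prefix)] <- "unassigned"
  year <- as.integer(format(notices$date, "%Y"))
  manu <- canonical_manufacturer(notices$manufacturer)

  keep <- rep(TRUE, nrow(notices))
  if (!is.null(year_range))
    keep <- keep & !is.na(year) & year >= year_range[1] & year <= year_range[2]
  if (!is.null(emdn_prefix)) {
    pfx <- toupper(trimws(emdn_prefix))
    keep <- keep & !is.na(code) & startsWith(toupper(code), pfx)
  }
  if (!is.null(manufacturer))
    keep <- keep & grepl(tolower(manufacturer), manu, fixed = TRUE)

  count_map <- function(x) {
    tab <- table(x[keep], useNA = "no")
    stats::setNames(as.integer(tab), names(tab))
  }
  structure(list(total_notices = sum(keep),
                 counts_by_year = count_map(year),
                 counts_by_emdn_prefix = count_map(prefix),
                 counts_by_manufacturer = count_map(manu)),
            class = "surveillance_summary")
}

#' @export
print.surveillance_summary <- function(x, ...) {
  cat("<surveillance_summary> ", x$total_notices, " notice(s)\n", sep = "")
  if (length(x$counts_by_year)) {
    cat("  by year: ")
    cat(paste0(names(x$counts_by_year), "=", x$counts_by_year),
        sep = ", ")
    cat("\n")
  }
  top <- utils::head(sort(x$counts_by_emdn_prefix, decreasing = TRUE), 5)
  if (length(top)) {
    cat("  top nomenclature buckets: ")
    cat(paste0(names(top), "=", top), sep = ", ")
    cat("\n")
  }
  invisible(x)
}

#' Write a surveillance summary to JSON
#'
#' Machine-readable stand-in for an interactive dashboard.
#'
#' @param summary A `surveillance_summary`.
#' @param path Output path.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(
    list(total_notices = summary$total_notices,
         counts_by_year = as.list(summary$counts_by_year),
         counts_by_emdn_prefix = as.list(summary$counts_by_emdn_prefix),
         counts_by_manufacturer = as.list(summary$counts_by_manufacturer)),
    path, auto_unbox = TRUE, pretty = TRUE)
}

#' Render a static HTML report of a summary
#'
#' Minimal self-contained HTML tables (total, per-year, per-bucket,
#' per-manufacturer) as a static replacement for a BI dashboard.
#'
#' @param summary A `surveillance_summary`.
#' @param path Output `.html` path.
#' @export
write_summary_html <- function(summary, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  tbl <- function(counts, title) {
    if (!length(counts)) return(sprintf("<h2>%s</h2><p>none</p>", title))
    rows <- paste0("<tr><td>", esc(names(counts)), "</td><td>",
                   counts, "</td></tr>", collapse = "\n")
    sprintf("<h2>%s</h2>\n<table border='1'>%s</table>", title, rows)
  }
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Safety-notice surveillance summary</title></head><body>",
    "<h1>Safety-notice surveillance summary</h1>",
    "<p>Total notices: ", summary$total_notices, "</p>",
    tbl(summary$counts_by_year, "Notices by year"),
    tbl(summary$counts_by_emdn_prefix, "Notices by nomenclature bucket"),
    tbl(summary$counts_by_manufacturer, "Notices by manufacturer"),
    "</body></html>")
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}
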