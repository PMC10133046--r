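#' @title Reading and writing device and notice tables
#' @description The pipeline consumes two CSV tables: a Dataset of Devices
#'   (DoD) — the market registry, keyed by a progressive registration number
#'   — and a Dataset of Notices (DoN) of scraped safety notices, where a
#'   minority of rows carry a BD/RMD identifier pointing directly into the
#'   registry. Column names are configurable because real sources are
#'   national-language exports; identifiers are canonicalised to bare digit
#'   strings at ingest (printed sources use thousands separators).
#' @name records_io
NULL

#' Default column mappings
#'
#' Named character vectors mapping internal field names to the CSV header
#' names expected by default. Override individual entries to ingest sources
#' with different headers.
#'
#' @return Named character vector.
#' @export
device_columns <- function() {
  c(device_type     = "Type",
    progressive_id  = "Progressive DM/ASS",
    manufacturer    = "Manufacturer/assembler",
    catalogue_code  = "Catalogue code",
    commercial_name = "Commercial name",
    emdn_code       = "Classification CND/EMDN")
}

#' @rdname device_columns
#' @export
notice_columns <- function() {
  c(manufacturer     = "Manufacturer",
    device           = "Device",
    commercial_name  = "Commercial name",
    notice_type      = "Type",
    action           = "Action",
    reference_number = "Reference number",
    date             = "Date",
    bdrmd            = "BD/RMD")
}

# strip "." and "," thousands separators (locale-independent) and whitespace
strip_separators <- function(x) gsub("[.,[:space:]]", "", x)

read_mapped_csv <- function(path, columns, what, sep = ",") {
  df <- utils::read.csv(path, sep = sep, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8",
                        na.strings = NULL)
  missing <- setdiff(unname(columns), names(df))
  if (length(missing))
    stop(what, ": required column(s) missing from '", path, "': ",
         paste0("'", missing, "'", collapse = ", "), call. = FALSE)
  out <- df[, unname(columns), drop = FALSE]
  names(out) <- names(columns)
  out
}

#' Read a device registry (DoD) from CSV
#'
#' One record per row. Thousands separators are stripped from the progressive
#' registration number. Duplicate progressive identifiers are retained —
#' the same physical device can legitimately be registered more than once —
#' but are reported via a message so runs are auditable.
#'
#' @param path CSV file path (UTF-8).
#' @param columns Column mapping, see [device_columns()].
#' @param sep Field delimiter.
#' @return A data.frame of class `device_registry` with columns
#'   `progressive_id`, `manufacturer`, `catalogue_code`, `commercial_name`,
#'   `device_type`, `emdn_code`.
#' @export
read_devices <- function(path, columns = device_columns(), sep = ",") {
  dod <- read_mapped_csv(path, columns, "read_devices", sep)
  dod$progressive_id <- strip_separators(dod$progressive_id)
  bad <- which(!nzchar(dod$progressive_id))
  if (length(bad))
    stop("read_devices: empty progressive identifier at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  dup <- unique(dod$progressive_id[duplicated(dod$progressive_id)])
  if (length(dup))
    message("read_devices: ", length(dup),
            " progressive identifier(s) appear on multiple rows (kept)")
  class(dod) <- c("device_registry", "data.frame")
  dod
}

#' Read a safety-notice table (DoN) from CSV
#'
#' Rows are returned in file order. Empty BD/RMD cells become `NA`; non-empty
#' cells are reduced to digit strings. Duplicate reference numbers trigger a
#' warning and a keep-first policy. Dates are parsed under `date_format`;
#' an unparseable date is a row-level error.
#'
#' @param path CSV file path (UTF-8).
#' @param columns Column mapping, see [notice_columns()].
#' @param date_format `strptime` format for the date column (default
#'   ISO-8601).
#' @param sep Field delimiter.
#' @return A data.frame of class `notice_set`; `date` is of class `Date`,
#'   `bdrmd` is a character column with `NA` for absent identifiers.
#' @export
read_notices <- function(path, columns = notice_columns(),
                         date_format = "%Y-%m-%d", sep = ",") {
  don <- read_mapped_csv(path, columns, "read_notices", sep)
  dupes <- duplicated(don$reference_number)
  if (any(dupes)) {
    warning("read_notices: ", sum(dupes),
            " duplicate reference number(s) dropped (keep-first): ",
            paste(unique(don$reference_number[dupes]), collapse = ", "),
            call. = FALSE)
    don <- don[!dupes, , drop = FALSE]
  }
  bdrmd <- strip_separators(don$bdrmd)
  bdrmd[!nzchar(bdrmd)] <- NA_character_
  nondigit <- which(!is.na(bdrmd) & !grepl("^[0-9]+$", bdrmd))
  if (length(nondigit))
    stop("read_notices: BD/RMD not a digit string at row(s) ",
         paste(nondigit, collapse = ", "), call. = FALSE)
  don$bdrmd <- bdrmd
  parsed <- as.Date(don$date, format = date_format)
  badrow <- which(is.na(parsed) & nzchar(don$date))
  if (length(badrow))
    stop("read_notices: unparseable date at row(s) ",
         paste(badrow, collapse = ", "), " (format '", date_format, "')",
         call. = FALSE)
  don$date <- parsed
  rownames(don) <- NULL
  class(don) <- c("notice_set", "data.frame")
  don
}

#' Write a device registry / notice set to CSV
#'
#' Inverse of the readers; round-trips all fields (identifiers are written in
#' their canonical separator-free form).
#'
#' @param x Data frame as returned by [read_devices()] / [read_notices()] or
#'   the synthetic generator.
#' @param path Output CSV path.
#' @param columns Column mapping giving the output header names.
#' @export
write_devices <- function(x, path, columns = device_columns()) {
  out <- as.data.frame(x)[, names(columns), drop = FALSE]
  names(out) <- unname(columns)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
}

#' @rdname write_devices
#' @export
write_notices <- function(x, path, columns = notice_columns()) {
  out <- as.data.frame(x)[, names(columns), drop = FALSE]
  out$date <- format(out$date, "%Y-%m-%d")
  out$bdrmd[is.na(out$bdrmd)] <- ""
  names(out) <- unname(columns)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
}

#' Write a link table to CSV
#'
#' Serialises the outcome of [resolve_all()] with a fixed column set, in
#' input order: `reference_number`, `matched_progressive_id`, `provenance`,
#' `score`, `accepted_threshold`, `emdn_code`. Direct links carry no
#' similarity score (empty cells); unmatched notices have empty identifier
#' and code cells.
#'
#' @param links `link_results` data.frame from [resolve_all()].
#' @param path Output CSV path.
#' @export
write_links <- function(links, path) {
  out <- data.frame(
    reference_number       = links$reference_number,
    matched_progressive_id = ifelse(is.na(links$device_id), "",
                                    links$device_id),
    provenance             = links$provenance,
    score                  = ifelse(is.na(links$score), "",
                                    as.character(links$score)),
    accepted_threshold     = ifelse(is.na(links$accepted_threshold), "",
                                    as.character(links$accepted_threshold)),
    emdn_code              = ifelse(is.na(links$emdn_code), "",
                                    links$emdn_code),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
}

#' Read a link table written by [write_links()]
#'
#' @param path CSV path.
#' @return A `link_results` data.frame (empty strings back to `NA`, numeric
#'   columns restored).
#' @export
read_links <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8", na.strings = NULL)
  need <- c("reference_number", "matched_progressive_id", "provenance",
            "score", "accepted_threshold", "emdn_code")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("read_links: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  blank_na <- function(x) { x[!nzchar(x)] <- NA_character_; x }
  out <- data.frame(
    reference_number   = df$reference_number,
    provenance         = df$provenance,
    device_id          = blank_na(df$matched_progressive_id),
    emdn_code          = blank_na(df$emdn_code),
    score              = as.integer(blank_na(df$score)),
    accepted_threshold = as.integer(blank_na(df$accepted_threshold)),
    failure_reason     = NA_character_,
    stringsAsFactors = FALSE)
  class(out) <- c("link_results", "data.frame")
  out
}
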