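#' @title Linkage-quality validation
#' @description Notices that carry a BD/RMD identifier give a free reference
#'   standard: hide the identifier, run entity resolution as if it were
#'   absent, and compare the predicted registry device with the one the
#'   identifier points to. Four criteria are scored: (1) manufacturer
#'   correctness, (2) exact identifier correctness, (3) nomenclature
#'   correctness at each level 1..4, and (4) nomenclature correctness at
#'   each level restricted to notices whose identifier was wrongly assigned
#'   — the quantity that matters for surveillance, since duplicate
#'   registrations of one physical device make the identifier itself
#'   ambiguous while its nomenclature code is not. Two matching methods are
#'   compared with the mid-P variant of McNemar's paired test.
#' @name validation
NULL

#' Score resolved links against a reference standard
#'
#' Unmatched notices count as incorrect under every criterion. Manufacturer
#' correctness is judged at the canonical-name level of the true device.
#' Nomenclature correctness at level `k` means agreement depth at least `k`
#' between the predicted and true codes.
#'
#' @param links `link_results` computed with the reference identifiers
#'   hidden (see [run_validation()], which arranges this).
#' @param reference Data frame with columns `reference_number` and
#'   `true_progressive_id`; every identifier must resolve in the registry.
#' @param index A [build_registry_index()] over the registry the links were
#'   computed against.
#' @return Object of class `validation_report`: `n_reference`,
#'   `manufacturer_accuracy`, `id_accuracy`, `emdn_accuracy_by_level`
#'   (levels 1..4), `conditional_emdn_accuracy_by_level` (same, on the
#'   wrong-identifier subset, with its size `n_wrong_id`), and `per_item`
#'   (per-notice logical flags).
#' @export
evaluate_links <- function(links, reference, index) {
  if (nrow(reference) == 0L)
    stop("evaluate_links: empty reference set", call. = FALSE)
  missing_id <- setdiff(reference$true_progressive_id,
                        names(index$by_id))
  if (length(missing_id))
    stop("evaluate_links: reference identifier(s) not in registry: ",
         paste(missing_id, collapse = ", "), call. = FALSE)
  m <- match(reference$reference_number, links$reference_number)
  if (anyNA(m))
    stop("evaluate_links: link table lacks reference notice(s): ",
         paste(reference$reference_number[is.na(m)], collapse = ", "),
         call. = FALSE)
  lk <- links[m, , drop = FALSE]

  true_row <- vapply(reference$true_progressive_id,
                     function(id) index$by_id[[id]][1L], integer(1))
  true_manu <- index$devices$manufacturer_canon[true_row]
  true_code <- index$devices$emdn_code[true_row]

  pred_manu <- rep(NA_character_, nrow(lk))
  has_dev <- !is.na(lk$device_id)
  pred_manu[has_dev] <- index$devices$manufacturer_canon[
    vapply(lk$device_id[has_dev], function(id) index$by_id[[id]][1L],
           integer(1))]

  manufacturer_ok <- !is.na(pred_manu) & pred_manu == true_manu
  id_ok <- has_dev & lk$device_id == reference$true_progressive_id

  depth <- mapply(function(p, t) {
    if (is.na(p) || is.na(t) || !nzchar(t)) return(0L)
    tryCatch(emdn_agreement_depth(p, t), error = function(e) 0L)
  }, lk$emdn_code, true_code, USE.NAMES = FALSE)
  level_ok <- vapply(1:4, function(k) depth >= k,
                     logical(nrow(lk)))
  if (is.null(dim(level_ok))) level_ok <- matrix(level_ok, nrow = 1L)
  colnames(level_ok) <- paste0("level", 1:4)

  wrong <- !id_ok
  cond <- if (any(wrong))
    colMeans(level_ok[wrong, , drop = FALSE]) else
      stats::setNames(rep(NA_real_, 4), paste0("level", 1:4))

  structure(list(
    n_reference = nrow(lk),
    manufacturer_accuracy = mean(manufacturer_ok),
    id_accuracy = mean(id_ok),
    emdn_accuracy_by_level = colMeans(level_ok),
    n_wrong_id = sum(wrong),
    conditional_emdn_accuracy_by_level = cond,
    per_item = data.frame(reference_number = reference$reference_number,
                          manufacturer_ok = manufacturer_ok,
                          id_ok = id_ok, level_ok,
                          stringsAsFactors = FALSE)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> n = ", x$n_reference, "\n",
      sprintf("  manufacturer accuracy: %.2f%%\n",
              100 * x$manufacturer_accuracy),
      sprintf("  identifier accuracy:   %.2f%%\n", 100 * x$id_accuracy),
      sep = "")
  for (k in 1:4)
    cat(sprintf("  nomenclature level %d:  %.2f%%%s\n", k,
                100 * x$emdn_accuracy_by_level[k],
                if (x$n_wrong_id > 0)
                  sprintf("  (wrong-id subset: %.2f%%)",
                          100 * x$conditional_emdn_accuracy_by_level[k])
                else ""))
  invisible(x)
}

#' End-to-end validation of a matching method
#'
#' Takes the notices that carry a BD/RMD identifier as the reference subset,
#' hides the identifier, resolves them by pure entity resolution and scores
#' the result with [evaluate_links()].
#'
#' @param devices `device_registry` data.frame.
#' @param notices `notice_set` data.frame; rows with an identifier form the
#'   reference subset.
#' @param method,... Passed to [resolve_all()].
#' @return A `validation_report` (with the resolved links attached as
#'   attribute `"links"`).
#' @export
run_validation <- function(devices, notices, method = "cos", ...) {
  ref_rows <- which(!is.na(notices$bdrmd))
  if (length(ref_rows) == 0L)
    stop("run_validation: no notice carries a BD/RMD identifier",
         call. = FALSE)
  ref <- data.frame(reference_number = notices$reference_number[ref_rows],
                    true_progressive_id = notices$bdrmd[ref_rows],
                    stringsAsFactors = FALSE)
  hidden <- notices[ref_rows, , drop = FALSE]
  hidden$bdrmd <- NA_character_
  index <- build_registry_index(devices,
                                extra_manufacturers = hidden$manufacturer)
  links <- resolve_all(hidden, index, method = method, ..., quiet = TRUE)
  report <- evaluate_links(links, ref, index)
  attr(report, "links") <- links
  report
}

#' Mid-P McNemar test on paired correctness flags
#'
#' For two methods scored on the same items, let `b` be the count of items
#' method A gets right and B wrong, `c` the reverse. Under the null the
#' discordant count `X ~ Binomial(n = b + c, 1/2)`; with `m = max(b, c)`
#' the mid-P value is `2 P(X >= m) - P(X = m)`, capped at 1, and 1 when
#' there are no discordant pairs. The mid-P variant keeps the power of the
#' exact conditional test while controlling the type-I error rate better.
#'
#' @param flags_a,flags_b Logical vectors of equal length, paired by item.
#' @return List of class `mcnemar_result` with `b`, `c`, `midp`.
#' @examples
#' midp_mcnemar(c(TRUE, TRUE, TRUE, TRUE, TRUE), rep(FALSE, 5))$midp
#' @export
midp_mcnemar <- function(flags_a, flags_b) {
  if (length(flags_a) != length(flags_b))
    stop("midp_mcnemar: flag vectors differ in length", call. = FALSE)
  stopifnot(is.logical(flags_a), is.logical(flags_b))
  b <- sum(flags_a & !flags_b)
  c_ <- sum(!flags_a & flags_b)
  n <- b + c_
  midp <- if (n == 0L) 1 else {
    m <- max(b, c_)
    min(1, 2 * stats::pbinom(m - 1L, n, 0.5, lower.tail = FALSE) -
          stats::dbinom(m, n, 0.5))
  }
  structure(list(b = b, c = c_, midp = midp), class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat("<mcnemar_result> b = ", x$b, ", c = ", x$c,
      sprintf(", mid-P = %.4g\n", x$midp), sep = "")
  invisible(x)
}

#' Compare two matching methods on one dataset
#'
#' Runs [run_validation()] under both methods and applies the mid-P McNemar
#' test to each correctness criterion.
#'
#' @param devices,notices As in [run_validation()].
#' @param methods Character vector of two method names.
#' @param ... Passed through to [resolve_all()].
#' @return List with both `validation_report`s and a named list of
#'   `mcnemar_result`s (criteria: `id`, `level1`..`level4`).
#' @export
compare_methods <- function(devices, notices, methods = c("cos", "ner"),
                            ...) {
  stopifnot(length(methods) == 2L)
  rep_a <- run_validation(devices, notices, method = methods[1], ...)
  rep_b <- run_validation(devices, notices, method = methods[2], ...)
  crit <- c("id_ok", paste0("level", 1:4))
  tests <- lapply(crit, function(cn)
    midp_mcnemar(rep_a$per_item[[cn]], rep_b$per_item[[cn]]))
  names(tests) <- sub("_ok$", "", crit)
  list(report_a = rep_a, report_b = rep_b, methods = methods,
       mcnemar = tests)
}

#' Write a validation report to JSON
#'
#' @param report A `validation_report`.
#' @param path Output path.
#' @export
write_validation_json <- function(report, path) {
  jsonlite::write_json(
    list(n_reference = report$n_reference,
         manufacturer_accuracy = report$manufacturer_accuracy,
         id_accuracy = report$id_accuracy,
         emdn_accuracy_by_level = as.list(report$emdn_accuracy_by_level),
         n_wrong_id = report$n_wrong_id,
         conditional_emdn_accuracy_by_level =
           as.list(report$conditional_emdn_accuracy_by_level)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
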