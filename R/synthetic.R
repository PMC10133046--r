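#' @title Synthetic registry and notice generator
#' @description No redistributable registry/notice data exist, so the
#'   package bundles a generator that emulates both schemas with known
#'   ground truth: a hierarchical nomenclature catalog, a device registry
#'   (manufacturer names with legal suffixes, commercial names with model
#'   tokens, catalogue codes, nomenclature codes, optional duplicate
#'   registrations of the same physical device under distinct progressive
#'   numbers), and safety notices derived from sampled devices with
#'   controllable corruption: token reordering, legal-suffix variants,
#'   casing changes and per-character typos. Roughly a third of notices
#'   carry the registry identifier, matching the fraction observed in
#'   national vigilance data; the rest must be recovered by entity
#'   resolution.
#' @name synthetic
NULL

# bundled wordlists (no external downloads)
.company_words_a <- c(
  "acme", "nova", "delta", "vertex", "prime", "astra", "helix", "orion",
  "zenith", "apex", "sigma", "vega", "lumen", "terra", "aria", "polar",
  "omega", "quanta", "stella", "aurora", "corona", "altus", "ferro",
  "hydra", "kappa", "lyra", "mira", "nexus", "pico", "rhea")
.company_words_b <- c(
  "medical", "biotech", "surgical", "diagnostics", "implants", "devices",
  "ortho", "cardio", "pharma", "health", "clinics", "instruments",
  "optics", "dental", "vascular", "imaging", "robotics", "systems",
  "therapeutics", "labs")
.device_words <- c(
  "catheter", "stent", "pump", "monitor", "valve", "probe", "scanner",
  "syringe", "implant", "lead", "sensor", "electrode", "cannula",
  "forceps", "scalpel", "retractor", "ventilator", "oximeter", "infusion",
  "dialysis", "pacemaker", "defibrillator", "endoscope", "prosthesis",
  "graft", "clamp", "drill", "plate", "screw", "nail", "cement", "mesh",
  "balloon", "guidewire", "introducer", "set", "kit", "system", "unit",
  "module", "array", "console", "adapter", "tube", "filter", "bag",
  "dressing", "suture", "staple", "tip")
.action_phrases <- c("recall", "update", "suspension of use",
                     "field safety corrective action")

#' Generator configuration
#'
#' Bundles every knob of the synthetic world. The default identifier
#' fraction (0.32) matches the share of real notices observed to carry a
#' registry identifier; corruption defaults are mild, representing routine
#' transcription noise between two administrative sources.
#'
#' @param n_manufacturers Number of distinct manufacturers.
#' @param devices_per_manufacturer Integer range `c(min, max)` of physical
#'   devices per manufacturer.
#' @param emdn_catalog_size Integer vector of per-level branching factors,
#'   e.g. `c(4, 3, 3, 2)` for 4 categories, 3 groups each, ...; length =
#'   catalog depth (max 7).
#' @param bdrmd_fraction Probability a notice carries the registry
#'   identifier of its true device.
#' @param typo_rate Per-character probability of a random edit
#'   (substitution, insertion or deletion) in notice name fields.
#' @param suffix_variant_prob Probability the legal suffix of the notice's
#'   manufacturer name is added, dropped or swapped.
#' @param token_shuffle_prob Probability the token order of a notice name
#'   field is randomly permuted.
#' @param case_variant_prob Probability the casing of a notice name field
#'   is changed wholesale (upper or title case).
#' @param duplicate_registration_prob Probability a physical device is
#'   registered twice under distinct progressive identifiers (identical
#'   names and code).
#' @param notice_count Number of notices to generate.
#' @param year_range Calendar years the notice dates are drawn from.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_manufacturers = 50,
                             devices_per_manufacturer = c(2, 8),
                             emdn_catalog_size = c(5, 4, 3, 2),
                             bdrmd_fraction = 0.32,
                             typo_rate = 0.02,
                             suffix_variant_prob = 0.2,
                             token_shuffle_prob = 0.2,
                             case_variant_prob = 0.3,
                             duplicate_registration_prob = 0.05,
                             notice_count = 200,
                             year_range = c(2009, 2021),
                             seed = 1L) {
  probs <- c(bdrmd_fraction, typo_rate, suffix_variant_prob,
             token_shuffle_prob, case_variant_prob,
             duplicate_registration_prob)
  stopifnot(all(probs >= 0 & probs <= 1),
            n_manufacturers > 0, notice_count >= 0,
            length(devices_per_manufacturer) == 2L,
            devices_per_manufacturer[1] >= 1,
            length(emdn_catalog_size) >= 1,
            length(emdn_catalog_size) <= 7,
            all(emdn_catalog_size >= 1))
  structure(list(n_manufacturers = as.integer(n_manufacturers),
                 devices_per_manufacturer =
                   as.integer(devices_per_manufacturer),
                 emdn_catalog_size = as.integer(emdn_catalog_size),
                 bdrmd_fraction = bdrmd_fraction,
                 typo_rate = typo_rate,
                 suffix_variant_prob = suffix_variant_prob,
                 token_shuffle_prob = token_shuffle_prob,
                 case_variant_prob = case_variant_prob,
                 duplicate_registration_prob = duplicate_registration_prob,
                 notice_count = as.integer(notice_count),
                 year_range = as.integer(year_range),
                 seed = as.integer(seed)),
            class = "generator_config")
}

two_digit_pool <- function() sprintf("%02d", 1:99)

#' Generate a synthetic nomenclature catalog
#'
#' Builds a full tree with the configured branching factors: category
#' letters at level 1, distinct two-digit pairs below, and returns the
#' deepest codes (the leaves), each valid under [parse_emdn()]. Uses the
#' current RNG state.
#'
#' @param sizes Per-level branching factors (see [generator_config()]).
#' @return Character vector of `prod(sizes)` codes at depth
#'   `length(sizes)`.
#' @export
generate_catalog <- function(sizes = c(5, 4, 3, 2)) {
  stopifnot(length(sizes) >= 1, length(sizes) <= 7, all(sizes >= 1),
            sizes[1] <= 26)
  codes <- sample(LETTERS, sizes[1])
  for (lvl in seq_along(sizes)[-1]) {
    codes <- unlist(lapply(codes, function(prefix)
      paste0(prefix, sample(two_digit_pool(), sizes[lvl]))))
  }
  codes
}

random_progressive_ids <- function(n) {
  # 7-digit registry keys, unique, no leading zero
  ids <- character(0)
  while (length(ids) < n)
    ids <- unique(c(ids, as.character(
      sample.int(9000000L, n - length(ids)) + 999999L)))
  ids
}

random_catalogue_code <- function(i) {
  paste0(paste(sample(LETTERS, sample(2:4, 1)), collapse = ""),
         sprintf("%04d", i))
}

#' Generate a synthetic device registry
#'
#' Manufacturer names are two wordlist tokens plus a random legal suffix;
#' commercial names are one to three device words plus a unique model token
#' (so distinct devices of one manufacturer are never token subsets of each
#' other); catalogue codes are unique alphanumeric strings; nomenclature
#' codes are drawn from the catalog. With probability
#' `duplicate_registration_prob` a physical device is registered a second
#' time under a fresh progressive identifier with identical names and code.
#' Uses the current RNG state.
#'
#' @param config A [generator_config()].
#' @param catalog Character vector of nomenclature codes.
#' @return List with `registry` (a `device_registry` data.frame) and
#'   `device_key` (integer vector identifying the physical device behind
#'   each registry row; duplicate registrations share a key).
#' @export
generate_registry <- function(config, catalog) {
  stopifnot(length(catalog) > 0)
  n_manu <- config$n_manufacturers
  pair_idx <- sample(length(.company_words_a) * length(.company_words_b),
                     n_manu)
  manu_names <- vapply(pair_idx, function(k) {
    i <- (k - 1) %% length(.company_words_a) + 1
    j <- (k - 1) %/% length(.company_words_a) + 1
    base <- paste(tools::toTitleCase(.company_words_a[i]),
                  tools::toTitleCase(.company_words_b[j]))
    paste(base, sample(c("SpA", "Srl", "GmbH", "Ltd", "Inc", "SA"), 1))
  }, character(1))

  dmin <- config$devices_per_manufacturer[1]
  dmax <- config$devices_per_manufacturer[2]
  n_dev <- if (dmin == dmax) rep(dmin, n_manu) else
    sample(dmin:dmax, n_manu, replace = TRUE)
  total <- sum(n_dev)
  manu_of_device <- rep(manu_names, n_dev)
  commercial <- vapply(seq_len(total), function(i) {
    words <- sample(.device_words, sample(1:3, 1))
    model <- paste0(paste(sample(LETTERS, 2), collapse = ""), 100 + i)
    tools::toTitleCase(paste(c(words, model), collapse = " "))
  }, character(1))
  catalogue <- vapply(seq_len(total), random_catalogue_code, character(1))
  emdn <- sample(catalog, total, replace = TRUE)
  dup <- stats::runif(total) < config$duplicate_registration_prob

  rows <- sum(dup) + total
  ids <- random_progressive_ids(rows)
  take <- c(seq_len(total), which(dup))       # duplicates appended
  registry <- data.frame(
    progressive_id  = ids,
    manufacturer    = manu_of_device[take],
    catalogue_code  = catalogue[take],
    commercial_name = commercial[take],
    device_type     = sample(c("MD", "IVD", "Assembled"), rows,
                             replace = TRUE),
    emdn_code       = emdn[take],
    stringsAsFactors = FALSE)
  class(registry) <- c("device_registry", "data.frame")
  list(registry = registry, device_key = take)
}

# one corruption pass over a name field; order fixed:
# token shuffle -> suffix ops -> casing -> per-character typos
corrupt_name <- function(text, config, is_manufacturer = FALSE) {
  ops <- character(0)
  toks <- strsplit(text, " ", fixed = TRUE)[[1]]
  if (length(toks) > 1 && stats::runif(1) < config$token_shuffle_prob) {
    # word-order variation affects the core name; a trailing legal suffix
    # stays trailing
    tail_suffix <- is_manufacturer &&
      tolower(gsub("[[:punct:]]", "", toks[length(toks)])) %in%
        default_company_suffixes()
    if (tail_suffix && length(toks) > 2) {
      head_toks <- toks[-length(toks)]
      toks <- c(sample(head_toks), toks[length(toks)])
    } else if (!tail_suffix) {
      toks <- sample(toks)
    }
    ops <- c(ops, "shuffle")
  }
  if (is_manufacturer && stats::runif(1) < config$suffix_variant_prob) {
    suffix_pool <- c("SpA", "Srl", "GmbH", "Ltd", "Inc", "SA", "Co")
    has_suffix <- tolower(gsub("[[:punct:]]", "", toks[length(toks)])) %in%
      default_company_suffixes()
    op <- sample(c("add", "drop", "swap"), 1)
    if (op == "drop" && has_suffix && length(toks) > 1) {
      toks <- toks[-length(toks)]
    } else if (op == "swap" && has_suffix) {
      toks[length(toks)] <- sample(suffix_pool, 1)
    } else {
      toks <- c(toks, sample(suffix_pool, 1))
    }
    ops <- c(ops, paste0("suffix_", op))
  }
  out <- paste(toks, collapse = " ")
  if (stats::runif(1) < config$case_variant_prob) {
    out <- if (stats::runif(1) < 0.5) toupper(out) else tolower(out)
    ops <- c(ops, "case")
  }
  if (config$typo_rate > 0) {
    chars <- strsplit(out, "")[[1]]
    res <- character(0)
    n_typos <- 0L
    alphabet <- c(letters, LETTERS, 0:9)
    for (ch in chars) {
      if (ch != " " && stats::runif(1) < config$typo_rate) {
        n_typos <- n_typos + 1L
        kind <- sample(c("sub", "ins", "del"), 1)
        res <- c(res, switch(kind,
                             sub = sample(alphabet, 1),
                             ins = c(ch, sample(alphabet, 1)),
                             del = character(0)))
      } else res <- c(res, ch)
    }
    out <- paste(res, collapse = "")
    if (n_typos > 0) ops <- c(ops, paste0("typos_", n_typos))
  }
  list(text = out, ops = ops)
}

#' Generate synthetic safety notices from a registry
#'
#' Each notice samples one registry row as its true device. The registry
#' identifier is carried with probability `bdrmd_fraction`; manufacturer
#' and name fields are corrupted per the configuration (the notice
#' commercial-name field concatenates the device's commercial name and
#' catalogue code, as scraped notices often embed the catalogue code
#' there). Uses the current RNG state.
#'
#' @param registry `device_registry` from [generate_registry()].
#' @param config A [generator_config()].
#' @return List with `notices` (a `notice_set` data.frame) and `truth`
#'   (data.frame: `reference_number`, `true_progressive_id`, `true_emdn`,
#'   `corruption_ops`).
#' @export
generate_notices <- function(registry, config) {
  stopifnot(nrow(registry) > 0)
  n <- config$notice_count
  rows <- if (n > 0) sample(nrow(registry), n, replace = TRUE) else integer(0)
  day0 <- as.Date(sprintf("%d-01-01", config$year_range[1]))
  day1 <- as.Date(sprintf("%d-12-31", config$year_range[2]))
  dates <- day0 + sample.int(as.integer(day1 - day0) + 1L, n,
                             replace = TRUE) - 1L
  manu <- character(n); dev <- character(n); comm <- character(n)
  ops <- character(n)
  for (i in seq_len(n)) {
    r <- rows[i]
    cm <- corrupt_name(registry$manufacturer[r], config,
                       is_manufacturer = TRUE)
    cd <- corrupt_name(registry$commercial_name[r], config)
    cc <- corrupt_name(paste(registry$commercial_name[r],
                             registry$catalogue_code[r]), config)
    manu[i] <- cm$text; dev[i] <- cd$text; comm[i] <- cc$text
    ops[i] <- paste(unique(c(cm$ops, cd$ops, cc$ops)), collapse = ";")
  }
  has_id <- stats::runif(n) < config$bdrmd_fraction
  bdrmd <- registry$progressive_id[rows]
  bdrmd[!has_id] <- NA_character_
  notices <- data.frame(
    manufacturer     = manu,
    device           = dev,
    commercial_name  = comm,
    notice_type      = if (n) sample(c("MD", "IVD", "AIMD"), n,
                                     replace = TRUE) else character(0),
    action           = if (n) sample(.action_phrases, n, replace = TRUE)
                       else character(0),
    reference_number = sprintf("SN-%06d", seq_len(n)),
    date             = dates,
    bdrmd            = bdrmd,
    stringsAsFactors = FALSE)
  class(notices) <- c("notice_set", "data.frame")
  truth <- data.frame(
    reference_number    = notices$reference_number,
    true_progressive_id = registry$progressive_id[rows],
    true_emdn           = registry$emdn_code[rows],
    corruption_ops      = ops,
    stringsAsFactors = FALSE)
  list(notices = notices, truth = truth)
}

#' Run a full simulation
#'
#' Seeds the RNG from the configuration and generates catalog, registry and
#' notices; optionally writes `dod.csv`, `don.csv` and `truth.csv` to a
#' directory. Identical configurations produce identical datasets.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return List with `catalog`, `registry`, `device_key`, `notices`,
#'   `truth`, `config`.
#' @export
simulate_pms <- function(config = generator_config(), out_dir = NULL) {
  set.seed(config$seed)
  catalog <- generate_catalog(config$emdn_catalog_size)
  reg <- generate_registry(config, catalog)
  nts <- generate_notices(reg$registry, config)
  out <- list(catalog = catalog, registry = reg$registry,
              device_key = reg$device_key, notices = nts$notices,
              truth = nts$truth, config = config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_devices(out$registry, file.path(out_dir, "dod.csv"))
    write_notices(out$notices, file.path(out_dir, "don.csv"))
    utils::write.csv(out$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  out
}
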