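# Six-item hand-computed fixture: a registry of six devices plus a link
# table with errors planted at known levels.
planted_fixture <- function() {
  reg <- data.frame(
    progressive_id  = c("1", "2", "3", "4", "5", "6"),
    manufacturer    = c("Acme SpA", "Acme SpA", "Beta Srl", "Beta Srl",
                        "Gamma GmbH", "Delta Ltd"),
    catalogue_code  = paste0("C", 1:6),
    commercial_name = paste("Device", 1:6),
    device_type     = "MD",
    emdn_code       = c("Z110401", "Z110402", "Z120101", "P0908",
                        "P0901", "A01"),
    stringsAsFactors = FALSE)
  class(reg) <- c("device_registry", "data.frame")
  reg
}

planted_links <- function() {
  # item 1: exact id            -> id ok, depth 4
  # item 2: sibling device of 1 -> id wrong, agreement Z1104   (depth 3)
  # item 3: cousin at level 2   -> id wrong, agreement Z1/Z12? (depth 1)
  # item 4: wrong category      -> id wrong, depth 0
  # item 5: unmatched           -> wrong everywhere
  # item 6: exact id            -> id ok, depth 2 (code depth 2)
  data.frame(
    reference_number = paste0("SN-", 1:6),
    provenance = c("er", "er", "er", "er", "unmatched", "er"),
    device_id = c("1", "2", "3", "4", NA, "6"),
    emdn_code = c("Z110401", "Z110402", "Z120101", "P0908", NA, "A01"),
    score = c(100, 96, 88, 75, NA, 100),
    accepted_threshold = c(95, 95, 85, 75, NA, 95),
    failure_reason = c(NA, NA, NA, NA, "below_floor", NA),
    stringsAsFactors = FALSE)
}

planted_reference <- function() {
  data.frame(reference_number = paste0("SN-", 1:6),
             true_progressive_id = c("1", "1", "1", "1", "1", "6"),
             stringsAsFactors = FALSE)
}

test_that("evaluation reproduces hand-computed accuracies on the fixture", {
  idx <- build_registry_index(planted_fixture())
  rep <- evaluate_links(planted_links(), planted_reference(), idx)
  expect_identical(rep$n_reference, 6L)
  # manufacturer: items 1,2 (acme), 6 (delta) correct; 3,4 wrong; 5 unmatched
  expect_equal(rep$manufacturer_accuracy, 3 / 6)
  expect_equal(rep$id_accuracy, 2 / 6)
  # agreement depths vs truth: 4, 3, 1, 0, 0(unmatched), 2
  expect_equal(unname(rep$emdn_accuracy_by_level),
               c(4 / 6, 3 / 6, 2 / 6, 1 / 6))
  # conditional: wrong-id items 2,3,4,5 with depths 3,1,0,0
  expect_identical(rep$n_wrong_id, 4L)
  expect_equal(unname(rep$conditional_emdn_accuracy_by_level),
               c(2 / 4, 1 / 4, 1 / 4, 0))
  expect_true(all(diff(rep$emdn_accuracy_by_level) <= 0))
})

test_that("evaluation errors are informative", {
  idx <- build_registry_index(planted_fixture())
  ref <- planted_reference()
  expect_error(evaluate_links(planted_links(), ref[0, ], idx), "empty")
  bad <- ref; bad$true_progressive_id[1] <- "404"
  expect_error(evaluate_links(planted_links(), bad, idx), "404")
  short <- planted_links()[1:3, ]
  expect_error(evaluate_links(short, ref, idx), "SN-4")
})

test_that("duplicate registrations break the identifier, not the code", {
  # same physical device registered twice; prediction hits the other row
  reg <- planted_fixture()
  reg <- rbind(reg, data.frame(progressive_id = "7",
                               manufacturer = "Acme SpA",
                               catalogue_code = "C1",
                               commercial_name = "Device 1",
                               device_type = "MD",
                               emdn_code = "Z110401"))
  class(reg) <- c("device_registry", "data.frame")
  idx <- build_registry_index(reg)
  links <- planted_links()[1, ]
  links$device_id <- "7"                 # the duplicate registration
  ref <- planted_reference()[1, ]        # truth says "1"
  rep <- evaluate_links(links, ref, idx)
  expect_equal(rep$id_accuracy, 0)
  expect_equal(unname(rep$emdn_accuracy_by_level), rep(1, 4))
  expect_equal(rep$manufacturer_accuracy, 1)
})

test_that("end-to-end validation hides the identifier before resolving", {
  cfg <- generator_config(n_manufacturers = 10, notice_count = 40,
                          seed = 23, bdrmd_fraction = 0.5, typo_rate = 0,
                          suffix_variant_prob = 0, token_shuffle_prob = 0,
                          case_variant_prob = 0,
                          duplicate_registration_prob = 0)
  sim <- simulate_pms(cfg)
  rep <- run_validation(sim$registry, sim$notices)
  expect_identical(rep$n_reference, sum(!is.na(sim$notices$bdrmd)))
  # clean copies must be recovered by pure entity resolution
  expect_equal(rep$id_accuracy, 1)
  links <- attr(rep, "links")
  expect_false(any(links$provenance == "direct"))
})

test_that("mid-P McNemar matches its exact formula and enumeration", {
  r <- midp_mcnemar(rep(TRUE, 5), rep(FALSE, 5))
  expect_identical(c(r$b, r$c), c(5L, 0L))
  expect_equal(r$midp, 0.03125)
  # equal discordance is capped at 1
  expect_equal(midp_mcnemar(c(TRUE, FALSE), c(FALSE, TRUE))$midp, 1)
  expect_equal(midp_mcnemar(logical(0), logical(0))$midp, 1)
  expect_error(midp_mcnemar(TRUE, c(TRUE, FALSE)), "length")
  # symmetry in the two methods, and strictly below the classical exact p
  set.seed(51)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    a <- sample(c(TRUE, FALSE), n, replace = TRUE)
    b <- sample(c(TRUE, FALSE), n, replace = TRUE)
    ra <- midp_mcnemar(a, b); rb <- midp_mcnemar(b, a)
    expect_equal(ra$midp, rb$midp)
    if (ra$b + ra$c > 0) {
      classical <- min(1, 2 * pbinom(max(ra$b, ra$c) - 1, ra$b + ra$c,
                                     0.5, lower.tail = FALSE))
      expect_lt(ra$midp, classical + 1e-12)
    }
  }
})

test_that("method comparison pairs the per-item flags", {
  cfg <- generator_config(n_manufacturers = 8, notice_count = 30,
                          seed = 29, bdrmd_fraction = 0.6)
  sim <- simulate_pms(cfg)
  cmp <- compare_methods(sim$registry, sim$notices)
  expect_named(cmp$mcnemar, c("id", paste0("level", 1:4)))
  for (t in cmp$mcnemar) {
    expect_gte(t$b, 0); expect_gte(t$c, 0)
    expect_lte(t$midp, 1); expect_gt(t$midp, 0)
  }
})
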