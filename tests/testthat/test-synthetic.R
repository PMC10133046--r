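test_that("catalog is the full product tree and every code parses", {
  set.seed(61)
  cat3 <- generate_catalog(c(2, 2, 2))
  expect_identical(length(cat3), 8L)
  expect_identical(length(unique(cat3)), 8L)
  for (code in cat3) {
    p <- parse_emdn(code)
    expect_identical(p$depth, 3L)
    expect_identical(p$raw, code)
  }
  expect_identical(length(generate_catalog(c(3))), 3L)
})

test_that("identical seed and configuration reproduce identical datasets", {
  cfg <- generator_config(n_manufacturers = 8, notice_count = 25, seed = 99)
  s1 <- simulate_pms(cfg)
  s2 <- simulate_pms(cfg)
  expect_identical(s1$registry, s2$registry)
  expect_identical(s1$notices, s2$notices)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_pms(generator_config(n_manufacturers = 8,
                                      notice_count = 25, seed = 100))
  expect_false(identical(s1$notices, s3$notices))
})

test_that("duplicate-registration probability 0 and 1 behave exactly", {
  set.seed(62)
  cfg0 <- generator_config(n_manufacturers = 6,
                           duplicate_registration_prob = 0, seed = 1)
  r0 <- generate_registry(cfg0, generate_catalog(c(2, 2)))
  expect_identical(anyDuplicated(r0$device_key), 0L)
  cfg1 <- generator_config(n_manufacturers = 6,
                           duplicate_registration_prob = 1, seed = 1)
  r1 <- generate_registry(cfg1, generate_catalog(c(2, 2)))
  expect_true(all(table(r1$device_key) == 2L))
  # duplicate rows share names and code but not the progressive identifier
  expect_identical(anyDuplicated(r1$registry$progressive_id), 0L)
  first <- !duplicated(r1$device_key)
  m <- match(r1$device_key[!first], r1$device_key[first])
  expect_identical(r1$registry$commercial_name[!first],
                   r1$registry$commercial_name[first][m])
  expect_identical(r1$registry$emdn_code[!first],
                   r1$registry$emdn_code[first][m])
})

test_that("every notice has exactly one true device and plausible fields", {
  sim <- simulate_pms(generator_config(n_manufacturers = 10,
                                       notice_count = 80, seed = 63))
  expect_identical(nrow(sim$truth), 80L)
  expect_true(all(sim$truth$true_progressive_id %in%
                    sim$registry$progressive_id))
  expect_identical(anyDuplicated(sim$notices$reference_number), 0L)
  expect_true(all(sim$notices$date >= as.Date("2009-01-01") &
                    sim$notices$date <= as.Date("2021-12-31")))
  # a carried identifier always points at the true device
  has <- !is.na(sim$notices$bdrmd)
  expect_identical(sim$notices$bdrmd[has],
                   sim$truth$true_progressive_id[has])
})

test_that("realized identifier fraction converges to its parameter", {
  frac <- vapply(1:3, function(s) {
    sim <- simulate_pms(generator_config(n_manufacturers = 20,
                                         notice_count = 400, seed = s))
    mean(!is.na(sim$notices$bdrmd))
  }, numeric(1))
  # binomial tolerance: 4 sd of a 0.32 proportion at n = 1200 pooled
  expect_lt(abs(mean(frac) - 0.32), 4 * sqrt(0.32 * 0.68 / 1200))
})

test_that("zero corruption produces verbatim copies", {
  cfg <- generator_config(n_manufacturers = 6, notice_count = 30,
                          seed = 64, typo_rate = 0,
                          suffix_variant_prob = 0, token_shuffle_prob = 0,
                          case_variant_prob = 0, bdrmd_fraction = 0)
  sim <- simulate_pms(cfg)
  r <- match(sim$truth$true_progressive_id, sim$registry$progressive_id)
  expect_identical(sim$notices$manufacturer, sim$registry$manufacturer[r])
  expect_identical(sim$notices$device, sim$registry$commercial_name[r])
  expect_identical(sim$truth$corruption_ops, rep("", 30))
})

test_that("corruption operators leave an audit trail and raise distance", {
  cfg <- generator_config(n_manufacturers = 6, notice_count = 50,
                          seed = 65, typo_rate = 0.08,
                          suffix_variant_prob = 0.5,
                          token_shuffle_prob = 0.5, case_variant_prob = 0)
  sim <- simulate_pms(cfg)
  expect_true(any(nzchar(sim$truth$corruption_ops)))
  r <- match(sim$truth$true_progressive_id, sim$registry$progressive_id)
  changed <- sim$notices$device != sim$registry$commercial_name[r]
  noted <- grepl("typo|shuffle", sim$truth$corruption_ops)
  expect_true(all(noted[changed]))   # a changed field always leaves a trace
  expect_gt(mean(changed), 0.2)
})

test_that("simulation writes the three CSV artefacts", {
  dir <- withr::local_tempdir()
  sim <- simulate_pms(generator_config(n_manufacturers = 5,
                                       notice_count = 10, seed = 66),
                      out_dir = dir)
  expect_true(all(file.exists(file.path(dir,
                                        c("dod.csv", "don.csv",
                                          "truth.csv")))))
  dod <- read_devices(file.path(dir, "dod.csv"))
  expect_identical(nrow(dod), nrow(sim$registry))
})
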