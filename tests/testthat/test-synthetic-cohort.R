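test_that("response probabilities invert the scoring formulas", {
  expect_equal(response_probability(0, 0, "true"), 0.5)
  expect_equal(response_probability(1.683242467, 0, "true"), 0.8,
               tolerance = 1e-8)
  expect_equal(response_probability(1.683242467, 0, "false"), 0.2,
               tolerance = 1e-8)
  p <- response_probability(c(-2, 0, 4), c(1, -1, 0), c("true", "false", "true"))
  expect_true(all(p > 0 & p < 1))
  expect_error(response_probability(NA, 0, "true"), "finite")
  expect_error(response_probability(1, 0, "yes"), "veracity")
})

test_that("item banks have exact cell counts and seeded fixed order", {
  bank <- generate_item_bank(20, seed = 4)
  expect_equal(nrow(bank), 80)
  expect_true(all(table(bank$veracity, bank$slant) == 20))
  expect_setequal(bank$order_index, 1:80)

  tiny <- generate_item_bank(1, seed = 4)
  expect_equal(nrow(tiny), 4)
  expect_true(all(table(tiny$veracity, tiny$slant) == 1))

  expect_identical(generate_item_bank(5, seed = 99),
                   generate_item_bank(5, seed = 99))
  expect_false(identical(generate_item_bank(5, seed = 1)$order_index,
                         generate_item_bank(5, seed = 2)$order_index))
  expect_error(generate_item_bank(0), "positive integer")
})

test_that("latent draws match configured marginals and correlations", {
  # degenerate: zero sds give every participant the mean parameters
  cfg0 <- cohort_config(
    n_per_group = 5, dprime_dist = c(1.2, 0), criterion_dist = c(0.3, 0),
    myside_dist = c(-0.4, 0), trait_spec = NULL, seed = 2
  )
  set.seed(2)
  lat0 <- sample_participant_params(cfg0, 10)
  expect_equal(lat0$d_true, rep(1.2, 10))
  expect_equal(lat0$c_base, rep(0.3, 10))
  expect_equal(lat0$m_true, rep(-0.4, 10))

  # perfect correlation: the trait is an affine map of the d' latent
  ts1 <- data.frame(trait = "proxy", mean = 10, sd = 2, r_dprime = 1,
                    r_criterion = 0, r_myside = 0, reliability = 1)
  cfg1 <- cohort_config(trait_spec = ts1, likert_items = FALSE, seed = 3)
  set.seed(3)
  lat1 <- sample_participant_params(cfg1, 50)
  z <- (lat1$d_true - 0.52) / 0.49
  expect_equal(lat1$proxy, 10 + 2 * z, tolerance = 1e-12)

  # Monte Carlo: configured correlation recovered within +/- 0.03
  ts2 <- data.frame(trait = "t1", mean = 0, sd = 1, r_dprime = 0.3,
                    r_criterion = -0.2, r_myside = 0.1, reliability = 1)
  cfg2 <- cohort_config(trait_spec = ts2, likert_items = FALSE, seed = 4)
  set.seed(4)
  lat2 <- sample_participant_params(cfg2, 10000)
  expect_lt(abs(stats::cor(lat2$t1, lat2$d_true) - 0.3), 0.03)
  expect_lt(abs(stats::cor(lat2$t1, lat2$c_base) + 0.2), 0.03)
  expect_lt(abs(stats::cor(lat2$t1, lat2$m_true) - 0.1), 0.03)
})

test_that("invalid generative configurations are rejected at construction", {
  bad <- data.frame(trait = "t", mean = 0, sd = 1, r_dprime = 0.8,
                    r_criterion = 0.7, r_myside = 0.5, reliability = 1)
  expect_error(cohort_config(trait_spec = bad), "non-positive-semi-definite")
  expect_error(cohort_config(dprime_dist = c(1, -0.1)), "sd >= 0")
  neg_sd <- default_trait_spec()
  neg_sd$sd[1] <- -1
  expect_error(cohort_config(trait_spec = neg_sd), "sds must be")
})

test_that("generated cohorts have the configured shape and chance behavior", {
  cfg <- cohort_config(n_per_group = 150, items_per_cell = 20,
                       trait_spec = NULL, seed = 10)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$participants), 300)
  expect_equal(nrow(coh$judgments), 300 * 80)
  expect_true(all(table(coh$judgments$participant_id) == 80))
  expect_equal(sum(coh$participants$group == "side_A"), 150)

  # pure guessing: pooled "true" proportion near one half
  cfg0 <- cohort_config(n_per_group = 50, dprime_dist = c(0, 0),
                        criterion_dist = c(0, 0), myside_dist = c(0, 0),
                        trait_spec = NULL, seed = 11)
  coh0 <- generate_cohort(cfg0)
  expect_equal(mean(coh0$judgments$response == "true"), 0.5, tolerance = 0.02)

  # high known sensitivity: per-participant hit rates near pnorm(d/2)
  cfgd <- cohort_config(n_per_group = 5, items_per_cell = 200,
                        dprime_dist = c(3, 0), criterion_dist = c(0, 0),
                        myside_dist = c(0, 0), trait_spec = NULL, seed = 12)
  cohd <- generate_cohort(cfgd)
  scd <- score_cohort(cohd$judgments, cohd$bank, cohd$participants,
                      splits = "all")
  expect_equal(mean(scd$hit_raw), 0.9331927987, tolerance = 0.02)
})

test_that("identical seeds give identical cohorts; files round-trip", {
  cfg <- cohort_config(n_per_group = 10, items_per_cell = 4, seed = 77)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$judgments, c2$judgments)
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$latents, c2$latents)

  dir <- withr::local_tempdir()
  write_cohort(c1, dir)
  back <- read_cohort(dir)
  s1 <- score_cohort(c1$judgments, c1$bank, c1$participants, splits = "all")
  s2 <- score_cohort(back$judgments, back$bank, back$participants,
                     splits = "all")
  expect_equal(s2$d_prime, s1$d_prime)
  expect_equal(back$config$seed, cfg$seed)

  # incomplete imported judgments are rejected
  trunc_dir <- withr::local_tempdir()
  c3 <- c1
  c3$judgments <- c1$judgments[-1, ]
  write_cohort(c3, trunc_dir)
  expect_error(read_cohort(trunc_dir), "exactly once")
})

test_that("estimation error shrinks as the item bank grows", {
  err <- vapply(c(100, 400), function(ipc) {
    cfg <- cohort_config(n_per_group = 15, items_per_cell = ipc,
                         dprime_dist = c(1, 0), criterion_dist = c(0.3, 0),
                         myside_dist = c(0.6, 0), trait_spec = NULL,
                         seed = 42)
    coh <- generate_cohort(cfg)
    sc <- score_cohort(coh$judgments, coh$bank, coh$participants,
                       splits = "all")
    mean(abs(sc$d_prime - 1)) + mean(abs(sc$c_overall - 0.3)) +
      mean(abs(sc$myside - 0.6))
  }, numeric(1))
  expect_lt(err[2], err[1])
})
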