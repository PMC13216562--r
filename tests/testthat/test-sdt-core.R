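test_that("probit, correction, and index formulas match inverse-CDF oracles", {
  expect_equal(z_transform(0.5), 0)
  expect_equal(z_transform(0.975), 1.959963985, tolerance = 1e-8)
  p <- seq(0.05, 0.95, by = 0.05)
  expect_equal(z_transform(p), -z_transform(1 - p))
  expect_error(z_transform(0), "strictly")
  expect_error(z_transform(1), "strictly")

  expect_equal(correct_extreme_rate(0, 20), 0.025)
  expect_equal(correct_extreme_rate(1, 20), 0.975)
  expect_equal(correct_extreme_rate(0.4, 20), 0.4)
  expect_equal(correct_extreme_rate(c(0, 1, 0.3), c(10, 10, 10)),
               c(0.05, 0.95, 0.3))
  expect_error(correct_extreme_rate(1.2, 20), "\\[0, 1\\]")

  expect_equal(d_prime(0.3, 0.3), 0)
  expect_equal(d_prime(0.8, 0.2), 1.683242467, tolerance = 1e-8)
  # printed mean hit/FA rates of the political study
  expect_equal(d_prime(0.46, 0.28), 0.4824077868, tolerance = 1e-8)
  expect_equal(criterion(0.46, 0.28), 0.3416376139, tolerance = 1e-8)
  expect_equal(criterion(0.5, 0.5), 0)
  expect_equal(criterion(0.8, 0.2), 0)

  expect_equal(myside_bias(0.1, 0.8), 0.7)
  expect_equal(myside_bias(0.3, 0.3), 0)
  # antisymmetry under swapping the congruence subsets
  expect_equal(myside_bias(0.2, 0.9), -myside_bias(0.9, 0.2))
  expect_error(myside_bias(Inf, 0), "finite")
})

test_that("congruence is group-slant match, invariant to relabeling", {
  expect_equal(congruence_of("side_A", "side_A"), "congruent")
  expect_equal(congruence_of("side_A", "side_B"), "incongruent")
  expect_equal(congruence_of("side_B", "side_B"), "congruent")
  grid <- expand.grid(g = c("side_A", "side_B"), s = c("side_A", "side_B"),
                      stringsAsFactors = FALSE)
  relabel <- function(x) ifelse(x == "side_A", "side_B", "side_A")
  expect_equal(congruence_of(grid$g, grid$s),
               congruence_of(relabel(grid$g), relabel(grid$s)))
  expect_error(congruence_of("left", "side_A"), "unknown group")
})

test_that("degenerate responders score as the formulas force", {
  bank <- generate_item_bank(10, seed = 3)  # 20 true / 20 false overall
  all_true <- rule_judgments(bank, function(it) TRUE)
  s <- score_participant(all_true, bank, "side_A")
  n <- 20
  expect_equal(s$hit, 1 - 1 / (2 * n))
  expect_equal(s$fa, 1 - 1 / (2 * n))
  expect_equal(s$d_prime, 0)
  expect_equal(s$c_overall, -stats::qnorm(1 - 1 / (2 * n)))
  expect_lt(s$c_overall, 0)

  perfect <- rule_judgments(bank, function(it) it$veracity == "true")
  s2 <- score_participant(perfect, bank, "side_B")
  expect_equal(s2$hit, 0.975)
  expect_equal(s2$fa, 0.025)
  expect_equal(s2$d_prime, 3.919927969, tolerance = 1e-8)
  expect_equal(s2$c_overall, 0)
  expect_equal(s2$myside, 0)
})

test_that("scoring the exact generative probabilities round-trips (d, c, m)", {
  # expected rates, not sampled ones: the estimators are exact inverses
  set.seed(11)
  for (i in 1:20) {
    d <- stats::runif(1, -2, 3); cb <- stats::runif(1, -1.5, 1.5)
    m <- stats::runif(1, -1, 1)
    H_c <- response_probability(d, cb - m / 2, "true")
    FA_c <- response_probability(d, cb - m / 2, "false")
    H_i <- response_probability(d, cb + m / 2, "true")
    FA_i <- response_probability(d, cb + m / 2, "false")
    expect_equal(myside_bias(criterion(H_c, FA_c), criterion(H_i, FA_i)), m,
                 tolerance = 1e-10)
    expect_equal(d_prime(H_c, FA_c), d, tolerance = 1e-10)
    expect_equal(criterion(H_c, FA_c) + m / 2, cb, tolerance = 1e-10)
  }
})

test_that("global true/false relabeling preserves d' and flips c", {
  bank <- generate_item_bank(10, seed = 9)
  set.seed(21)
  jv <- rule_judgments(bank, function(it) stats::runif(1) < 0.6)
  s <- score_participant(jv, bank, "side_A")
  flipped_bank <- bank
  flipped_bank$veracity <- ifelse(bank$veracity == "true", "false", "true")
  s_flip <- score_participant(!jv, flipped_bank, "side_A")
  expect_equal(s_flip$d_prime, s$d_prime, tolerance = 1e-12)
  expect_equal(s_flip$c_overall, -s$c_overall, tolerance = 1e-12)
})

test_that("odd/even splits partition items and agree for deterministic responders", {
  bank <- balanced_bank(4)
  odd <- score_participant(rule_judgments(bank, function(it) it$veracity == "true"),
                           bank, "side_A", "odd")
  even <- score_participant(rule_judgments(bank, function(it) it$veracity == "true"),
                            bank, "side_A", "even")
  expect_equal(odd$d_prime, even$d_prime)
  expect_equal(odd$c_overall, even$c_overall)
  expect_equal(odd$myside, even$myside)
  # correction uses the split's own trial count (4 true items per half here)
  expect_equal(odd$hit, 1 - 1 / 8)
})

test_that("vectorized cohort scoring matches the per-participant path", {
  cfg <- cohort_config(n_per_group = 8, items_per_cell = 6, trait_spec = NULL,
                       seed = 14)
  coh <- generate_cohort(cfg)
  fast <- score_cohort(coh$judgments, coh$bank, coh$participants)
  for (pid in sample(coh$participants$participant_id, 4)) {
    j <- coh$judgments[coh$judgments$participant_id == pid, ]
    jv <- stats::setNames(j$response == "true", j$item_id)
    g <- coh$participants$group[coh$participants$participant_id == pid]
    for (sp in c("all", "odd", "even")) {
      ref <- score_participant(jv, coh$bank, g, sp)
      got <- fast[fast$participant_id == pid & fast$split == sp, ]
      expect_equal(got$d_prime, ref$d_prime)
      expect_equal(got$c_congruent, ref$c_congruent)
      expect_equal(got$myside, ref$myside)
      expect_equal(got$fa_incongruent, ref$fa_incongruent)
    }
  }
})

test_that("cohort rate summary obeys the complement identities", {
  cfg <- cohort_config(n_per_group = 20, trait_spec = NULL, seed = 8)
  coh <- generate_cohort(cfg)
  sc <- score_cohort(coh$judgments, coh$bank, coh$participants, splits = "all")
  rs <- rate_summary(sc)
  m <- stats::setNames(rs$mean, rs$rate)
  s <- stats::setNames(rs$sd, rs$rate)
  expect_equal(m[["misses"]], 1 - m[["hits"]])
  expect_equal(m[["correct_rejections"]], 1 - m[["false_alarms"]])
  expect_equal(s[["misses"]], s[["hits"]])
  expect_equal(s[["correct_rejections"]], s[["false_alarms"]])
})
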