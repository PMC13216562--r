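random_bifactor_params <- function(spec, seed) {
  set.seed(seed)
  p_ind <- length(spec$indicators)
  nf <- length(spec$factors)
  list(
    general = stats::runif(p_ind, 0.4, 0.7),
    specific = stats::runif(p_ind, 0.3, 0.6),
    paths = matrix(stats::runif(length(spec$outcomes) * nf, -0.3, 0.5),
                   length(spec$outcomes), nf),
    resid = stats::runif(p_ind + length(spec$outcomes), 0.3, 0.6)
  )
}

std_true_loadings <- function(spec, params) {
  sigma <- implied_covariance(spec, params)
  sd_ <- sqrt(diag(sigma))
  p_ind <- length(spec$indicators)
  L <- matrix(0, p_ind + length(spec$outcomes), length(spec$factors),
              dimnames = list(c(spec$indicators, spec$outcomes), spec$factors))
  L[seq_len(p_ind), 1] <- params$general
  for (i in seq_len(p_ind)) {
    sf <- spec$specific_map[spec$indicators[i]]
    if (!is.na(sf)) L[i, sf] <- params$specific[i]
  }
  if (length(spec$outcomes)) {
    L[p_ind + seq_along(spec$outcomes), ] <- as.matrix(params$paths)
  }
  sweep(L, 1, sd_, "/")
}

test_that("implied covariance matches the path-tracing oracle", {
  spec <- default_bifactor_spec()
  params <- random_bifactor_params(spec, 101)

  # all loadings zero: diagonal residual matrix
  zero <- params
  zero$general[] <- 0; zero$specific[] <- 0; zero$paths[] <- 0
  expect_equal(implied_covariance(spec, zero), {
    d <- diag(zero$resid, 14)
    dimnames(d) <- dimnames(implied_covariance(spec, zero)); d
  })

  # scalar case: one indicator, general loading only -> lambda^2 + theta
  one <- bifactor_spec("x1", c(x1 = NA), outcomes = character(0))
  s1 <- implied_covariance(one, list(general = 0.7, specific = numeric(1),
                                     paths = NULL, resid = 0.4))
  expect_equal(unname(s1[1, 1]), 0.7^2 + 0.4)

  # full path-tracing oracle: sigma_ij = sum_k lambda_ik lambda_jk (+ theta_i)
  sigma <- implied_covariance(spec, params)
  expect_equal(sigma, t(sigma))
  Lfull <- std_true_loadings(spec, params) # standardized; rebuild unstd
  sd_ <- sqrt(diag(sigma))
  Lu <- sweep(Lfull, 1, sd_, "*")
  oracle <- matrix(0, 14, 14)
  for (i in 1:14) for (j in 1:14) {
    oracle[i, j] <- sum(Lu[i, ] * Lu[j, ]) + if (i == j) params$resid[i] else 0
  }
  expect_equal(unname(sigma), oracle, tolerance = 1e-10)

  expect_error(
    implied_covariance(spec, list(general = 1, specific = 1, paths = NULL,
                                  resid = rep(1, 14))),
    "dimensions"
  )
})

test_that("fitting the exact population covariance recovers the structure", {
  spec <- default_bifactor_spec()
  params <- random_bifactor_params(spec, 102)
  sigma <- implied_covariance(spec, params)
  fit <- fit_bifactor(sigma, 5000, spec, n_starts = 8, seed = 1)
  expect_true(attr(fit, "converged"))
  expect_lt(attr(fit, "discrepancy"), 1e-10)
  expect_false(attr(fit, "heywood"))
  expect_equal(standardized_loadings(fit), std_true_loadings(spec, params),
               tolerance = 1e-4)
})

test_that("discrepancy is zero iff the model reproduces S, positive otherwise", {
  spec <- default_bifactor_spec()
  params <- random_bifactor_params(spec, 103)
  sigma <- implied_covariance(spec, params)
  layout <- truthsdt:::bifactor_layout(spec)
  # evaluate F at the truth and at a perturbation via the internal objective
  L <- matrix(0, layout$p, layout$nf, dimnames = dimnames(layout$free))
  L[seq_len(12), 1] <- params$general
  for (i in 1:12) L[i, spec$specific_map[spec$indicators[i]]] <- params$specific[i]
  L[13:14, ] <- params$paths
  th <- c(L[layout$free], log(params$resid))
  ld_s <- 2 * sum(log(diag(chol(sigma))))
  F0 <- truthsdt:::ml_discrepancy(th, sigma, layout, ld_s)
  expect_equal(F0, 0, tolerance = 1e-10)
  th2 <- th + 0.1
  expect_gt(truthsdt:::ml_discrepancy(th2, sigma, layout, ld_s), 0)
})

test_that("one-factor reduction matches the closed-form three-indicator solution", {
  inds <- c("y1", "y2", "y3")
  spec1 <- bifactor_spec(inds, stats::setNames(rep(NA_character_, 3), inds),
                         outcomes = character(0))
  lam <- c(0.8, 0.6, 0.7)
  th <- c(0.36, 0.64, 0.51)
  sigma <- tcrossprod(lam) + diag(th)
  dimnames(sigma) <- list(inds, inds)
  fit <- fit_bifactor(sigma, 1000, spec1, n_starts = 5, seed = 2)
  # closed form from the three off-diagonal moments
  lam1 <- sqrt(sigma[1, 2] * sigma[1, 3] / sigma[2, 3])
  lam2 <- sigma[1, 2] / lam1
  lam3 <- sigma[1, 3] / lam1
  est <- fit$estimate[fit$parameter == "loading"]
  expect_equal(est, unname(c(lam1, lam2, lam3)), tolerance = 1e-6)
  expect_equal(est, lam, tolerance = 1e-6)
})

test_that("standardized solutions are invariant to observed-variable rescaling", {
  spec <- default_bifactor_spec()
  params <- random_bifactor_params(spec, 104)
  x <- simulate_bifactor(spec, params, 800)
  S <- stats::cov(x)
  fit1 <- fit_bifactor(S, 800, spec, n_starts = 6, seed = 3)
  D <- diag(stats::runif(14, 0.5, 3))
  S2 <- D %*% S %*% D
  dimnames(S2) <- dimnames(S)
  fit2 <- fit_bifactor(S2, 800, spec, n_starts = 6, seed = 3)
  expect_equal(standardized_loadings(fit2), standardized_loadings(fit1),
               tolerance = 1e-5)
  # correlation-matrix input is the standardization helper's fixed point
  expect_equal(cov_to_cor(cov_to_cor(S)), cov_to_cor(S))
  # doubling one variable's scale leaves its standardized loading unchanged
  expect_equal(attr(fit1, "discrepancy"), attr(fit2, "discrepancy"),
               tolerance = 1e-8)
})

test_that("a shared-cause cohort yields a dominant general factor", {
  # four indicator constructs and the outcome all driven by one latent
  inds <- paste0("v", 1:8)
  map <- stats::setNames(rep(c("F1", "F2", "F3", "F4"), each = 2), inds)
  spec <- bifactor_spec(inds, map, outcomes = "crit")
  nf <- length(spec$factors)
  params <- list(general = rep(0.75, 8), specific = rep(0.25, 8),
                 paths = matrix(c(0.6, rep(0.05, nf - 1)), 1, nf),
                 resid = c(rep(0.3, 8), 0.5))
  set.seed(105)
  x <- simulate_bifactor(spec, params, 100000)
  fit <- fit_bifactor(stats::cov(x), 100000, spec, n_starts = 8, seed = 4)
  L <- standardized_loadings(fit)
  expect_gt(abs(L["crit", spec$general_factor]),
            max(abs(L["crit", setdiff(spec$factors, spec$general_factor)])))
})

test_that("bifactor specs survive the JSON round trip", {
  spec <- default_bifactor_spec()
  path <- withr::local_tempfile(fileext = ".json")
  write_bifactor_spec(spec, path)
  back <- read_bifactor_spec(path)
  expect_equal(back$indicators, spec$indicators)
  expect_equal(back$specific_map, spec$specific_map)
  expect_equal(back$outcomes, spec$outcomes)
  expect_error(bifactor_spec(c("a", "b"), c(a = "F")), "every indicator")
})
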