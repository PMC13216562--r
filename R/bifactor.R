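#' Specify a bifactor structural model
#'
#' One general factor loads on every indicator; each indicator additionally
#' loads on exactly one specific factor; all latent factors are mutually
#' orthogonal with unit variance (the standard bifactor identification).
#' Outcome variables (by default the odd- and even-half truth-sensitivity
#' scores) are regressed on the general factor and every specific factor;
#' because the factors are orthogonal these structural paths enter the
#' implied covariance exactly like loadings, so the model is fitted as a
#' single constrained factor pattern.
#'
#' @param indicators character vector of indicator variable names.
#' @param specific_map named character vector mapping each indicator to its
#'   specific factor (e.g. `c(crt_1 = "CR", ...)`); an `NA` entry gives an
#'   indicator with no specific factor (mapping all indicators to `NA`
#'   reduces the model to a one-factor analysis).
#' @param outcomes character vector of outcome variable names (may be empty).
#' @param general_factor name of the general factor (default `"ROM"`,
#'   reflective open-mindedness).
#' @return object of class `bifactor_spec`.
#' @export
bifactor_spec <- function(indicators, specific_map,
                          outcomes = c("ts_odd", "ts_even"),
                          general_factor = "ROM") {
  if (!setequal(names(specific_map), indicators)) {
    stop("specific_map must name every indicator exactly once", call. = FALSE)
  }
  specific_map <- specific_map[indicators]
  factors <- c(general_factor,
               unique(unname(specific_map[!is.na(specific_map)])))
  structure(
    list(indicators = indicators, specific_map = specific_map,
         outcomes = outcomes, general_factor = general_factor,
         factors = factors),
    class = "bifactor_spec"
  )
}

#' @export
print.bifactor_spec <- function(x, ...) {
  cat(sprintf(
    "Bifactor spec: %d indicators, general factor '%s', specific factors %s\n",
    length(x$indicators), x$general_factor,
    paste(setdiff(x$factors, x$general_factor), collapse = ", ")))
  if (length(x$outcomes)) {
    cat("  outcomes regressed on all factors:",
        paste(x$outcomes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Default bifactor specification
#'
#' Three order-based item parcels per construct for cognitive reflection
#' (CR), bullshit receptivity (BS), conspiracy mentality (CM), and actively
#' open-minded thinking (AOT), with odd/even truth-sensitivity outcomes.
#' The parcel-level structure is a configurable default, not a fixed
#' published indicator set.
#'
#' @return a [bifactor_spec()].
#' @export
default_bifactor_spec <- function() {
  constructs <- c(crt = "CR", bs = "BS", cm = "CM", aot = "AOT")
  indicators <- as.vector(t(outer(names(constructs), 1:3, paste, sep = "_p")))
  map <- stats::setNames(rep(unname(constructs), each = 3), indicators)
  bifactor_spec(indicators, map)
}

# free-parameter bookkeeping ------------------------------------------------

# The fitted pattern matrix has one row per observed variable (indicators
# then outcomes) and one column per factor (general first). Indicator rows
# have two free entries (general + own specific); outcome rows are fully
# free (structural paths). Residual variances are log-parameterized.
bifactor_layout <- function(spec) {
  p_ind <- length(spec$indicators)
  p_out <- length(spec$outcomes)
  nf <- length(spec$factors)
  vars <- c(spec$indicators, spec$outcomes)
  free <- matrix(FALSE, p_ind + p_out, nf,
                 dimnames = list(vars, spec$factors))
  free[seq_len(p_ind), 1] <- TRUE
  for (i in seq_len(p_ind)) {
    sf <- spec$specific_map[spec$indicators[i]]
    if (!is.na(sf)) free[i, sf] <- TRUE
  }
  if (p_out) free[p_ind + seq_len(p_out), ] <- TRUE
  list(free = free, p = p_ind + p_out, nf = nf, vars = vars,
       n_load = sum(free))
}

theta_to_matrices <- function(theta, layout) {
  L <- matrix(0, layout$p, layout$nf,
              dimnames = dimnames(layout$free))
  L[layout$free] <- theta[seq_len(layout$n_load)]
  resid <- exp(theta[layout$n_load + seq_len(layout$p)])
  list(L = L, resid = resid)
}

#' Implied covariance matrix of a bifactor model
#'
#' `Sigma = Lambda Lambda' + Theta` with orthogonal unit-variance factors
#' (`Phi = I`); the outcome rows of `Lambda` hold the structural paths.
#'
#' @param spec a [bifactor_spec()].
#' @param params list with `general` (indicator loadings on the general
#'   factor), `specific` (each indicator's loading on its mapped factor),
#'   `paths` (outcomes x factors matrix, may be 0-row), and `resid`
#'   (nonnegative residual variances for indicators then outcomes).
#' @return symmetric implied covariance matrix.
#' @export
implied_covariance <- function(spec, params) {
  layout <- bifactor_layout(spec)
  p_ind <- length(spec$indicators)
  p_out <- length(spec$outcomes)
  if (length(params$general) != p_ind || length(params$specific) != p_ind ||
      length(params$resid) != layout$p) {
    stop("parameter dimensions do not match the spec", call. = FALSE)
  }
  if (p_out && (is.null(params$paths) ||
                !all(dim(as.matrix(params$paths)) == c(p_out, layout$nf)))) {
    stop("paths must be an outcomes x factors matrix", call. = FALSE)
  }
  L <- matrix(0, layout$p, layout$nf, dimnames = dimnames(layout$free))
  L[seq_len(p_ind), 1] <- params$general
  for (i in seq_len(p_ind)) {
    sf <- spec$specific_map[spec$indicators[i]]
    if (!is.na(sf)) L[i, sf] <- params$specific[i]
  }
  if (p_out) L[p_ind + seq_len(p_out), ] <- as.matrix(params$paths)
  sigma <- tcrossprod(L) + diag(params$resid, layout$p)
  dimnames(sigma) <- list(layout$vars, layout$vars)
  sigma
}

# ML discrepancy and its analytic gradient ----------------------------------

ml_discrepancy <- function(theta, S, layout, log_det_S) {
  mats <- theta_to_matrices(theta, layout)
  sigma <- tcrossprod(mats$L) + diag(mats$resid, layout$p)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  log_det <- 2 * sum(log(diag(ch)))
  inv <- chol2inv(ch)
  val <- log_det + sum(inv * S) - log_det_S - layout$p
  if (!is.finite(val)) 1e10 else val
}

ml_gradient <- function(theta, S, layout, log_det_S) {
  mats <- theta_to_matrices(theta, layout)
  sigma <- tcrossprod(mats$L) + diag(mats$resid, layout$p)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(rep(0, length(theta)))
  inv <- chol2inv(ch)
  M <- inv %*% (sigma - S) %*% inv   # dF/dSigma
  g_load <- (2 * (M %*% mats$L))[layout$free]
  g_resid <- diag(M) * mats$resid    # chain rule through log-variances
  c(g_load, g_resid)
}

#' Fit a bifactor model by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy
#' `F = log|Sigma(theta)| + tr(S Sigma^-1) - log|S| - p`
#' over loadings, structural paths, and (log-parameterized) residual
#' variances, from multiple seeded random starts, keeping the best
#' converged solution. Factor-sign indeterminacy is resolved by flipping
#' each factor so that the sum of its indicator loadings is positive.
#' Standard errors come from the inverse Hessian of the discrepancy
#' (`acov = 2/(n-1) H^-1`).
#'
#' @param sample_cov sample covariance matrix with variable names covering
#'   the spec's indicators and outcomes.
#' @param n sample size behind `sample_cov`.
#' @param spec a [bifactor_spec()].
#' @param n_starts number of random starts (default 20).
#' @param seed integer seed for the starts.
#' @param grad_tol gradient-norm convergence tolerance (default 1e-8).
#' @return object of class `bifactor_fit`: data frame of parameters
#'   (`parameter`, `variable`, `factor`, `estimate`, `se`, `std_estimate`,
#'   `std_se`) with attributes `discrepancy`, `df`, `converged`, `heywood`,
#'   `n`, `spec`, `implied_cov`.
#' @export
fit_bifactor <- function(sample_cov, n, spec, n_starts = 20, seed = 1,
                         grad_tol = 1e-8) {
  layout <- bifactor_layout(spec)
  vars <- layout$vars
  if (!all(vars %in% rownames(sample_cov))) {
    stop("sample_cov lacks variables named in the spec", call. = FALSE)
  }
  S <- as.matrix(sample_cov)[vars, vars]
  ch_S <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch_S)) stop("sample covariance is singular", call. = FALSE)
  log_det_S <- 2 * sum(log(diag(ch_S)))
  n_par <- layout$n_load + layout$p
  if (n <= n_par) stop("n must exceed the number of free parameters",
                       call. = FALSE)

  sds <- sqrt(diag(S))
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  best <- NULL
  for (s in seq_len(n_starts)) {
    start_load <- 0.5 * sds[row(layout$free)[layout$free]] *
      stats::runif(layout$n_load, 0.5, 1.5)
    start <- c(start_load, log(0.5 * diag(S)))
    opt <- tryCatch(
      stats::nlminb(start, ml_discrepancy, gradient = ml_gradient,
                    S = S, layout = layout, log_det_S = log_det_S,
                    control = list(iter.max = 2000, eval.max = 4000,
                                   rel.tol = 1e-14, x.tol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)

  gnorm <- max(abs(ml_gradient(best$par, S, layout, log_det_S)))
  converged <- is.finite(best$objective) && gnorm < max(grad_tol, 1e-6)

  mats <- theta_to_matrices(best$par, layout)
  # resolve factor sign: indicator-loading sums positive
  p_ind <- length(spec$indicators)
  for (j in seq_len(layout$nf)) {
    colsum <- sum(mats$L[seq_len(p_ind), j])
    if (colsum < 0) mats$L[, j] <- -mats$L[, j]
  }
  sigma <- tcrossprod(mats$L) + diag(mats$resid, layout$p)
  dimnames(sigma) <- list(vars, vars)

  # SEs on the free-parameter vector (signs re-applied afterwards)
  theta_hat <- c(mats$L[layout$free], log(mats$resid))
  H <- tryCatch(
    stats::optimHess(theta_hat, ml_discrepancy, gr = ml_gradient,
                     S = S, layout = layout, log_det_S = log_det_S),
    error = function(e) NULL
  )
  se_load <- rep(NA_real_, layout$n_load)
  if (!is.null(H)) {
    acov <- tryCatch(2 / (n - 1) * solve(H), error = function(e) NULL)
    if (!is.null(acov)) {
      d <- diag(acov)[seq_len(layout$n_load)]
      se_load <- ifelse(d > 0, sqrt(d), NA_real_)
    }
  }

  imp_sd <- sqrt(diag(sigma))
  idx <- which(layout$free, arr.ind = TRUE)
  params <- data.frame(
    parameter = ifelse(idx[, 1] <= p_ind, "loading", "path"),
    variable = vars[idx[, 1]],
    factor = spec$factors[idx[, 2]],
    estimate = mats$L[layout$free],
    se = se_load,
    stringsAsFactors = FALSE
  )
  params$std_estimate <- params$estimate / imp_sd[idx[, 1]]
  params$std_se <- params$se / imp_sd[idx[, 1]]
  resid_df <- data.frame(
    parameter = "residual_variance", variable = vars, factor = NA_character_,
    estimate = mats$resid, se = NA_real_,
    std_estimate = mats$resid / imp_sd^2, std_se = NA_real_,
    stringsAsFactors = FALSE
  )
  out <- rbind(params, resid_df)
  rownames(out) <- NULL
  structure(out, class = c("bifactor_fit", "data.frame"),
            discrepancy = best$objective,
            df = layout$p * (layout$p + 1) / 2 - n_par,
            converged = converged,
            heywood = any(mats$resid < 1e-6),
            gradient_norm = gnorm,
            n = n, spec = spec, implied_cov = sigma)
}

#' @export
print.bifactor_fit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Bifactor ML fit: F = %.6f, df = %d, converged = %s%s (n = %d)\n",
    attr(x, "discrepancy"), attr(x, "df"), attr(x, "converged"),
    if (attr(x, "heywood")) ", HEYWOOD case" else "", attr(x, "n")))
  show <- x[x$parameter != "residual_variance",
            c("parameter", "variable", "factor", "std_estimate", "std_se")]
  show$std_estimate <- round(show$std_estimate, digits)
  show$std_se <- round(show$std_se, digits)
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}

#' Standardized loadings of a fit as a matrix
#'
#' @param fit a `bifactor_fit`.
#' @return variables x factors matrix of standardized loadings/paths
#'   (zeros where the pattern is fixed).
#' @export
standardized_loadings <- function(fit) {
  spec <- attr(fit, "spec")
  layout <- bifactor_layout(spec)
  L <- matrix(0, layout$p, layout$nf, dimnames = dimnames(layout$free))
  rows <- fit[fit$parameter %in% c("loading", "path"), ]
  for (i in seq_len(nrow(rows))) {
    L[rows$variable[i], rows$factor[i]] <- rows$std_estimate[i]
  }
  L
}

#' Standardize a covariance matrix and re-express a solution on it
#'
#' Rescaling observed variables (e.g. fitting on a correlation instead of a
#' covariance matrix) leaves standardized estimates unchanged; this helper
#' standardizes an input covariance. Standardization of the fitted solution
#' itself happens inside [fit_bifactor()] (factors already have unit
#' variance; loadings are divided by implied observed SDs).
#'
#' @param sigma covariance matrix.
#' @return the corresponding correlation matrix.
#' @export
cov_to_cor <- function(sigma) {
  d <- sqrt(diag(sigma))
  if (any(d <= 0)) stop("zero observed variance", call. = FALSE)
  sigma / tcrossprod(d)
}

#' Simulate observations from a bifactor model
#'
#' Draws orthogonal standard-normal factor scores and Gaussian residuals.
#'
#' @param spec a [bifactor_spec()].
#' @param params parameter list as for [implied_covariance()].
#' @param n number of observations.
#' @return numeric matrix n x variables.
#' @export
simulate_bifactor <- function(spec, params, n) {
  layout <- bifactor_layout(spec)
  p_ind <- length(spec$indicators)
  L <- matrix(0, layout$p, layout$nf)
  L[seq_len(p_ind), 1] <- params$general
  for (i in seq_len(p_ind)) {
    sf <- spec$specific_map[spec$indicators[i]]
    if (!is.na(sf)) L[i, match(sf, spec$factors)] <- params$specific[i]
  }
  if (length(spec$outcomes)) {
    L[p_ind + seq_along(spec$outcomes), ] <- as.matrix(params$paths)
  }
  f <- matrix(stats::rnorm(n * layout$nf), n)
  e <- matrix(stats::rnorm(n * layout$p), n) %*%
    diag(sqrt(params$resid), layout$p)
  x <- f %*% t(L) + e
  colnames(x) <- layout$vars
  x
}

#' Build bifactor indicators from a scored cohort
#'
#' Forms three consecutive item parcels per construct for cognitive
#' reflection, bullshit receptivity, conspiracy mentality, and AOT (parcel
#' score = mean of keyed items; sum for the 0/1 CRT items), and attaches the
#' odd- and even-half truth-sensitivity scores.
#'
#' @param participants participants data frame with scale-item columns.
#' @param scores output of [score_cohort()] with `"odd"` and `"even"` rows.
#' @param registry scale registry (default [default_scale_registry()]).
#' @return data frame of indicator and outcome columns matching
#'   [default_bifactor_spec()].
#' @export
bifactor_indicators <- function(participants, scores,
                                registry = default_scale_registry()) {
  constructs <- c(crt = "cognitive_reflection", bs = "bullshit_receptivity",
                  cm = "conspiracy_mentality", aot = "aot")
  out <- data.frame(participant_id = participants$participant_id,
                    stringsAsFactors = FALSE)
  for (short in names(constructs)) {
    tr <- constructs[[short]]
    spec <- registry[[tr]]
    cols <- paste0(tr, "_", seq_len(spec$n_items))
    if (!all(cols %in% names(participants))) {
      stop("missing item columns for construct: ", tr, call. = FALSE)
    }
    m <- as.matrix(participants[cols])
    rev <- spec$reverse_items
    if (length(rev)) {
      m[, rev] <- reverse_code(m[, rev], spec$response_min, spec$response_max)
    }
    groups <- split(seq_len(spec$n_items),
                    ceiling(3 * seq_len(spec$n_items) / spec$n_items))
    for (j in 1:3) {
      sub <- m[, groups[[j]], drop = FALSE]
      out[[paste0(short, "_p", j)]] <-
        if (spec$aggregation == "sum") rowSums(sub) else rowMeans(sub)
    }
  }
  for (s in c("odd", "even")) {
    h <- scores[scores$split == s, c("participant_id", "d_prime")]
    names(h)[2] <- paste0("ts_", s)
    out <- merge(out, h, by = "participant_id", sort = TRUE)
  }
  out
}

#' Write / read a bifactor spec as JSON
#'
#' @param spec a [bifactor_spec()].
#' @param path JSON file path.
#' @return `path` (write) or the spec (read).
#' @export
write_bifactor_spec <- function(spec, path) {
  jsonlite::write_json(
    list(indicators = spec$indicators,
         specific_map = as.list(spec$specific_map),
         outcomes = spec$outcomes, general_factor = spec$general_factor),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_bifactor_spec
#' @export
read_bifactor_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  bifactor_spec(raw$indicators, unlist(raw$specific_map),
                outcomes = raw$outcomes %||% character(0),
                general_factor = raw$general_factor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
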