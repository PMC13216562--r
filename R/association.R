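#' Pearson correlation with two-sided p-value
#'
#' @param x,y equal-length numeric vectors (n >= 4, nonzero variance).
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must match in length", call. = FALSE)
  if (length(x) < 4) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' First-order partial correlation
#'
#' Correlation between `x` and `y` after partialling out a single covariate
#' (which may be a binary group dummy):
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' with a two-sided p from the t distribution on n - 3 df.
#'
#' @param x,y,covariate equal-length numeric vectors.
#' @return list with `r`, `p`, `n`.
#' @export
partial_r <- function(x, y, covariate) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n) {
    stop("all vectors must match in length", call. = FALSE)
  }
  r_xy <- stats::cor(x, y)
  r_xz <- stats::cor(x, covariate)
  r_yz <- stats::cor(y, covariate)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    stop("degenerate covariate: collinear with x or y", call. = FALSE)
  }
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  df <- n - 3
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), n = n)
}

#' Standardized multiple regression
#'
#' z-scores the outcome and every predictor, fits ordinary least squares,
#' and returns standardized betas with classical two-sided p-values and R^2.
#' With a single predictor the beta equals the Pearson correlation.
#'
#' @param y numeric outcome.
#' @param X numeric predictor matrix or data frame (named columns).
#' @param outcome_name,direction labels carried into the result (used by the
#'   split-half wrapper).
#' @return object of class `regression_result`: data frame of `predictor`,
#'   `beta`, `p`, with attributes `r_squared`, `n`, `outcome_name`,
#'   `direction`.
#' @export
standardized_ols <- function(y, X, outcome_name = "y", direction = NA_character_) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("y and X must match in rows", call. = FALSE)
  if (n <= ncol(X) + 1) stop("too few observations", call. = FALSE)
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    stop("collinear predictors: design matrix is rank deficient", call. = FALSE)
  }
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  Z <- apply(X, 2, zs)
  fit <- stats::lm(zs(y) ~ Z)
  sm <- summary(fit)
  coefs <- sm$coefficients[-1, , drop = FALSE]
  res <- data.frame(
    predictor = colnames(X),
    beta = unname(coefs[, "Estimate"]),
    p = unname(coefs[, "Pr(>|t|)"]),
    stringsAsFactors = FALSE
  )
  structure(res, class = c("regression_result", "data.frame"),
            r_squared = sm$r.squared, n = n,
            outcome_name = outcome_name, direction = direction)
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Standardized OLS: %s%s (n = %d, R^2 = %.3f)\n",
              attr(x, "outcome_name"),
              if (!is.na(attr(x, "direction")))
                paste0(" [", attr(x, "direction"), "]") else "",
              attr(x, "n"), attr(x, "r_squared")))
  print.data.frame(cbind(x["predictor"],
                         beta = round(x$beta, 3),
                         p = signif(x$p, 3)), row.names = FALSE)
  invisible(x)
}

#' Split-half regressions of misinformation acceptance on the SDT indices
#'
#' For each congruence-specific false-alarm outcome (acceptance of
#' belief-congruent and belief-incongruent misinformation) and each
#' direction (even-half predictors on odd-half outcome, and the reverse),
#' fits a standardized multiple regression of the corrected false-alarm rate
#' on the opposite half's truth sensitivity, acceptance threshold, and
#' myside bias. Computing predictors and outcome from disjoint item halves
#' makes them mathematically independent.
#'
#' @param scores output of [score_cohort()] containing both `"odd"` and
#'   `"even"` split rows.
#' @return named list of four `regression_result`s:
#'   `congruent.even_to_odd`, `congruent.odd_to_even`,
#'   `incongruent.even_to_odd`, `incongruent.odd_to_even`.
#' @export
split_half_fa_regression <- function(scores) {
  halves <- lapply(c(odd = "odd", even = "even"), function(s) {
    h <- scores[scores$split == s, , drop = FALSE]
    if (!nrow(h)) stop("scores lack the '", s, "' split", call. = FALSE)
    h[order(h$participant_id), , drop = FALSE]
  })
  if (!identical(halves$odd$participant_id, halves$even$participant_id)) {
    stop("odd and even splits cover different participants", call. = FALSE)
  }
  out <- list()
  for (outcome in c("congruent", "incongruent")) {
    fa_col <- paste0("fa_", outcome)
    for (dir in c("even_to_odd", "odd_to_even")) {
      pred <- halves[[if (dir == "even_to_odd") "even" else "odd"]]
      targ <- halves[[if (dir == "even_to_odd") "odd" else "even"]]
      X <- cbind(d_prime = pred$d_prime, c_overall = pred$c_overall,
                 myside = pred$myside)
      out[[paste(outcome, dir, sep = ".")]] <- standardized_ols(
        targ[[fa_col]], X,
        outcome_name = paste0("fa_", outcome), direction = dir
      )
    }
  }
  out
}

#' Adjust p-values for multiple testing
#'
#' Holm step-down (default) or Bonferroni over the supplied family.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"holm"` or `"bonferroni"`.
#' @return adjusted p-values (monotone, >= raw).
#' @export
adjust_pvalues <- function(p, method = c("holm", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Correlation screen of traits against misinformation outcomes
#'
#' Correlates every trait score with the corrected overall false-alarm rate
#' and the three SDT indices from the all-items split. Raw two-sided
#' p-values are adjusted within two families: the 3 x `n_traits` crossing of
#' the SDT indices (the family the robustness analyses correct), and the
#' false-alarm column as its own family. When `group` is supplied, partial
#' correlations controlling for a 0/1 group dummy are added.
#'
#' @param trait_scores output of [score_traits()] (or any data frame with
#'   `participant_id` + numeric trait columns).
#' @param scores output of [score_cohort()] including the `"all"` split.
#' @param group optional character/factor vector of group membership aligned
#'   with `trait_scores$participant_id`, or the name of a column in `scores`.
#' @param method multiplicity adjustment, `"holm"` (default) or
#'   `"bonferroni"`.
#' @return data frame with one row per trait x outcome: `trait`, `outcome`
#'   (`fa_rate`, `d_prime`, `c_overall`, `myside`), `r`, `p`, `p_adjusted`,
#'   and `partial_r`, `partial_p` when a group was given.
#' @export
correlation_screen <- function(trait_scores, scores, group = NULL,
                               method = c("holm", "bonferroni")) {
  method <- match.arg(method)
  s <- scores[scores$split == "all", , drop = FALSE]
  if (!nrow(s)) stop("scores lack the 'all' split", call. = FALSE)
  m <- merge(trait_scores, s, by = "participant_id", sort = TRUE)
  outcomes <- c(fa_rate = "fa", d_prime = "d_prime",
                c_overall = "c_overall", myside = "myside")
  traits <- setdiff(names(trait_scores), "participant_id")
  if (!is.null(group) && length(group) == 1 && is.character(group)) {
    group <- m[[group]]
  } else if (!is.null(group)) {
    group <- group[order(trait_scores$participant_id)]
  }
  gdum <- if (!is.null(group)) as.integer(group == sort(unique(group))[1])
  rows <- list()
  for (tr in traits) {
    for (oc in names(outcomes)) {
      pr <- pearson_r(m[[tr]], m[[outcomes[oc]]])
      row <- data.frame(trait = tr, outcome = oc, r = pr$r, p = pr$p,
                        stringsAsFactors = FALSE)
      if (!is.null(gdum)) {
        pp <- partial_r(m[[tr]], m[[outcomes[oc]]], gdum)
        row$partial_r <- pp$r
        row$partial_p <- pp$p
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)
  res$p_adjusted <- NA_real_
  sdt_fam <- res$outcome != "fa_rate"
  res$p_adjusted[sdt_fam] <- adjust_pvalues(res$p[sdt_fam], method)
  res$p_adjusted[!sdt_fam] <- adjust_pvalues(res$p[!sdt_fam], method)
  rownames(res) <- NULL
  res
}
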