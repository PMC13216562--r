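#' Congruence of an item for a participant
#'
#' An item is congruent when its slant matches the participant's group: a
#' pro-side_A claim is belief-congruent for side_A members and
#' belief-incongruent for side_B members, and vice versa.
#'
#' @param group character vector of participant group labels
#'   (`"side_A"`/`"side_B"`).
#' @param slant character vector of item slant labels, same labels, recycled
#'   against `group`.
#' @return character vector, `"congruent"` or `"incongruent"`.
#' @examples
#' congruence_of("side_A", "side_A")
#' congruence_of("side_A", "side_B")
#' @export
congruence_of <- function(group, slant) {
  sides <- c("side_A", "side_B")
  if (!all(group %in% sides)) stop("unknown group label", call. = FALSE)
  if (!all(slant %in% sides)) stop("unknown slant label", call. = FALSE)
  ifelse(group == slant, "congruent", "incongruent")
}

#' Correct extreme response proportions
#'
#' Rates of exactly 0 are replaced by 1/(2n) and rates of exactly 1 by
#' 1 - 1/(2n), where n is the number of trials the proportion was computed
#' from; interior values pass through unchanged. This keeps the probit
#' transform finite.
#'
#' @param p numeric vector of proportions in \[0, 1\].
#' @param n_trials positive integer vector of trial counts, recycled.
#' @return corrected proportions, strictly inside (0, 1).
#' @examples
#' correct_extreme_rate(c(0, 1, 0.4), 20)
#' @export
correct_extreme_rate <- function(p, n_trials) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  if (any(n_trials < 1)) stop("n_trials must be >= 1", call. = FALSE)
  half <- rep_len(1 / (2 * n_trials), length(p))
  ifelse(p == 0, half, ifelse(p == 1, 1 - half, p))
}

#' Probit transform
#'
#' Inverse standard-normal CDF of a proportion. Rates at exactly 0 or 1 must
#' be corrected first (see [correct_extreme_rate()]).
#'
#' @param p numeric vector strictly inside (0, 1).
#' @return z-scores.
#' @export
z_transform <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0 | p >= 1)) {
    stop("probit requires p strictly in (0, 1); correct extreme rates first",
         call. = FALSE)
  }
  stats::qnorm(p)
}

#' Truth sensitivity (d')
#'
#' d' = z(H) - z(FA) under the equal-variance Gaussian model. Higher values
#' mean better discrimination between true and false claims.
#'
#' @param hit_rate,fa_rate corrected hit and false-alarm rates in (0, 1).
#' @return numeric vector of sensitivities.
#' @examples
#' d_prime(0.8, 0.2)
#' @export
d_prime <- function(hit_rate, fa_rate) {
  z_transform(hit_rate) - z_transform(fa_rate)
}

#' Acceptance threshold (criterion c)
#'
#' c = -0.5 * (z(H) + z(FA)). Higher values mean a stronger tendency to
#' reject (vs. accept) claims regardless of veracity.
#'
#' @inheritParams d_prime
#' @return numeric vector of criteria.
#' @examples
#' criterion(0.46, 0.28)
#' @export
criterion <- function(hit_rate, fa_rate) {
  -0.5 * (z_transform(hit_rate) + z_transform(fa_rate))
}

#' Myside bias
#'
#' The criterion difference between belief-incongruent and belief-congruent
#' claims, `c_incongruent - c_congruent`. Positive values mean a lower
#' threshold for accepting congruent than incongruent claims.
#'
#' @param c_congruent,c_incongruent criteria computed on the two congruence
#'   subsets.
#' @return numeric vector of bias scores.
#' @export
myside_bias <- function(c_congruent, c_incongruent) {
  if (any(!is.finite(c_congruent)) || any(!is.finite(c_incongruent))) {
    stop("criteria must be finite", call. = FALSE)
  }
  c_incongruent - c_congruent
}

# Items retained by a split: "all", or parity of the 1-based order_index.
split_items <- function(bank, split = c("all", "odd", "even")) {
  split <- match.arg(split)
  switch(split,
    all  = bank,
    odd  = bank[bank$order_index %% 2 == 1, , drop = FALSE],
    even = bank[bank$order_index %% 2 == 0, , drop = FALSE]
  )
}

# corrected "true"-response rate of one cell; n is the cell's own trial count
cell_rate <- function(responses) {
  n <- length(responses)
  if (n == 0L) stop("empty item subset after split", call. = FALSE)
  correct_extreme_rate(mean(responses), n)
}

#' Score one participant's judgments
#'
#' Computes corrected hit and false-alarm rates overall and within each
#' congruence subset, then the three signal-detection indices: truth
#' sensitivity and the acceptance threshold from the all-items rates, and
#' myside bias as the criterion difference between the incongruent and
#' congruent subsets. Rates at exactly 0 or 1 are corrected with the trial
#' count of the subset they were computed from.
#'
#' @param judgments named logical vector (or "true"/"false" character vector),
#'   names are item ids; `TRUE`/"true" means the claim was judged true.
#' @param bank item bank data frame (see [generate_item_bank()]).
#' @param group participant group label (`"side_A"`/`"side_B"`).
#' @param split which items to score: `"all"` (default), or the `"odd"`/
#'   `"even"` half by presentation-order parity.
#' @return one-row data frame with raw and corrected rates, per-congruence
#'   false-alarm rates, `d_prime`, `c_overall`, `c_congruent`,
#'   `c_incongruent`, and `myside`.
#' @export
score_participant <- function(judgments, bank, group,
                              split = c("all", "odd", "even")) {
  split <- match.arg(split)
  if (is.character(judgments)) {
    bad <- !judgments %in% c("true", "false")
    if (any(bad)) stop("judgments must be 'true'/'false'", call. = FALSE)
    judgments <- stats::setNames(judgments == "true", names(judgments))
  }
  items <- split_items(bank, split)
  if (!all(items$item_id %in% names(judgments))) {
    stop("judgments do not cover the selected split's items", call. = FALSE)
  }
  resp <- judgments[items$item_id]
  cong <- congruence_of(group, items$slant)
  is_true <- items$veracity == "true"

  rate <- function(sel) cell_rate(resp[sel])
  raw  <- function(sel) mean(resp[sel])

  hit_all <- rate(is_true)
  fa_all  <- rate(!is_true)
  h_cong   <- rate(is_true & cong == "congruent")
  fa_cong  <- rate(!is_true & cong == "congruent")
  h_incong <- rate(is_true & cong == "incongruent")
  fa_incong <- rate(!is_true & cong == "incongruent")

  c_cong   <- criterion(h_cong, fa_cong)
  c_incong <- criterion(h_incong, fa_incong)

  data.frame(
    split = split,
    hit_raw = raw(is_true), fa_raw = raw(!is_true),
    hit = hit_all, fa = fa_all,
    fa_congruent = fa_cong, fa_incongruent = fa_incong,
    d_prime = d_prime(hit_all, fa_all),
    c_overall = criterion(hit_all, fa_all),
    c_congruent = c_cong, c_incongruent = c_incong,
    myside = myside_bias(c_cong, c_incong),
    stringsAsFactors = FALSE
  )
}

#' Score every participant in a cohort, per split
#'
#' Applies [score_participant()] to each participant for each requested
#' split and stacks the results.
#'
#' @param judgments long data frame with columns `participant_id`, `item_id`,
#'   `response` ("true"/"false" or logical).
#' @param bank item bank data frame.
#' @param participants data frame with columns `participant_id` and `group`.
#' @param splits character vector from `c("all", "odd", "even")`.
#' @return data frame, one row per participant per split, columns as in
#'   [score_participant()] plus `participant_id` and `group`.
#' @export
score_cohort <- function(judgments, bank, participants,
                         splits = c("all", "odd", "even")) {
  splits <- match.arg(splits, several.ok = TRUE)
  resp <- judgments$response
  if (is.character(resp)) resp <- resp == "true"
  pid <- factor(judgments$participant_id,
                levels = participants$participant_id)
  iid <- factor(judgments$item_id, levels = bank$item_id)
  keep <- !is.na(pid) & !is.na(iid)
  n <- nrow(participants)
  R <- matrix(NA, n, nrow(bank))
  R[cbind(as.integer(pid[keep]), as.integer(iid[keep]))] <- resp[keep]
  if (anyNA(R)) {
    stop("judgments do not cover every item for every participant",
         call. = FALSE)
  }
  side_A <- participants$group == "side_A"
  per_split <- lapply(splits, function(s) {
    items <- split_items(bank, s)
    Rs <- R[, match(items$item_id, bank$item_id), drop = FALSE]
    cong_A <- congruence_of("side_A", items$slant) == "congruent"
    is_cong <- outer(side_A, cong_A, "==")          # n x k logical
    is_true <- matrix(items$veracity == "true", n, ncol(Rs), byrow = TRUE)
    rate <- function(mask) {
      n_cell <- rowSums(mask)
      if (any(n_cell == 0)) stop("empty item subset after split", call. = FALSE)
      raw <- rowSums(Rs & mask) / n_cell
      list(raw = raw, corr = correct_extreme_rate(raw, n_cell))
    }
    h_all <- rate(is_true); f_all <- rate(!is_true)
    h_c <- rate(is_true & is_cong); f_c <- rate(!is_true & is_cong)
    h_i <- rate(is_true & !is_cong); f_i <- rate(!is_true & !is_cong)
    c_cong <- criterion(h_c$corr, f_c$corr)
    c_incong <- criterion(h_i$corr, f_i$corr)
    data.frame(
      participant_id = participants$participant_id,
      group = participants$group,
      split = s,
      hit_raw = h_all$raw, fa_raw = f_all$raw,
      hit = h_all$corr, fa = f_all$corr,
      fa_congruent = f_c$corr, fa_incongruent = f_i$corr,
      d_prime = d_prime(h_all$corr, f_all$corr),
      c_overall = criterion(h_all$corr, f_all$corr),
      c_congruent = c_cong, c_incongruent = c_incong,
      myside = myside_bias(c_cong, c_incong),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, per_split)
  rownames(res) <- NULL
  res
}

#' Cohort-level rate summary
#'
#' Means and SDs of raw hit, false-alarm, miss, and correct-rejection rates
#' across participants (all items). Miss and correct-rejection rates are the
#' complements of the hit and false-alarm rates.
#'
#' @param scores output of [score_cohort()]; only rows with `split == "all"`
#'   are used.
#' @return data frame with columns `rate`, `mean`, `sd`.
#' @export
rate_summary <- function(scores) {
  s <- scores[scores$split == "all", , drop = FALSE]
  if (!nrow(s)) stop("scores contain no 'all'-split rows", call. = FALSE)
  vals <- list(
    hits = s$hit_raw,
    false_alarms = s$fa_raw,
    misses = 1 - s$hit_raw,
    correct_rejections = 1 - s$fa_raw
  )
  data.frame(
    rate = names(vals),
    mean = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, stats::sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
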