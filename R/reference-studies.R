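#' Published sample-flow counts of the two reference studies
#'
#' The stage-by-stage participant counts reported by the two misinformation
#' studies this pipeline models: a political-headline study (two partisan
#' groups) and a COVID-19 vaccine study (pro- and anti-vaccine groups).
#' These serve as inputs for checking the exclusion arithmetic.
#'
#' @return data frame with one row per study: `study`, `n_started`,
#'   `n_completed`, `n_failed_attention`, `n_inconsistent_group`, `n_final`,
#'   `n_group_1`, `n_group_2`.
#' @export
reference_study_counts <- function() {
  data.frame(
    study = c("political", "vaccine"),
    n_started = c(314L, 309L),
    n_completed = c(300L, 301L),
    n_failed_attention = c(21L, 72L),
    n_inconsistent_group = c(5L, 7L),
    n_final = c(274L, 222L),
    n_group_1 = c(141L, 122L),
    n_group_2 = c(133L, 100L),
    stringsAsFactors = FALSE
  )
}

#' Published mean judgment rates of the two reference studies
#'
#' Mean and SD of hit, false-alarm, miss, and correct-rejection rates as
#' printed in the reference studies' rate table. Used to check the
#' definitional complement identities (miss = 1 - hit,
#' correct rejection = 1 - false alarm).
#'
#' @return data frame: `study`, `rate`, `mean`, `sd`.
#' @export
reference_study_rates <- function() {
  data.frame(
    study = rep(c("political", "vaccine"), each = 4),
    rate = rep(c("hits", "false_alarms", "misses", "correct_rejections"), 2),
    mean = c(0.46, 0.28, 0.54, 0.72,
             0.66, 0.24, 0.34, 0.76),
    sd = c(0.20, 0.15, 0.20, 0.15,
           0.14, 0.12, 0.14, 0.12),
    stringsAsFactors = FALSE
  )
}

#' Reconstruct a reference study's exclusion flow as participant records
#'
#' Builds a minimal participant table whose stage counts match a reference
#' study: the reported number of completers, attention-check failures among
#' them, and group-inconsistent respondents among the remainder, with final
#' per-group sizes as reported. Running [apply_exclusions()] on it must
#' reproduce the study's printed final sample size.
#'
#' @param study `"political"` or `"vaccine"`.
#' @return data frame of participant records (completers only, since the
#'   non-completers provided no analyzable data).
#' @export
reference_exclusion_records <- function(study = c("political", "vaccine")) {
  study <- match.arg(study)
  cts <- reference_study_counts()
  cts <- cts[cts$study == study, ]
  n_comp <- cts$n_completed
  groups <- c(rep("side_A", cts$n_group_1), rep("side_B", cts$n_group_2))
  n_kept <- length(groups)
  n_att <- cts$n_failed_attention
  n_inc <- cts$n_inconsistent_group
  # completers = kept + inconsistent + attention failures
  group <- c(groups,
             rep("side_A", n_inc),
             rep(c("side_A", "side_B"), length.out = n_att))
  prescreen <- c(groups,
                 rep("side_B", n_inc),  # inconsistent: flipped prescreen
                 rep(c("side_A", "side_B"), length.out = n_att))
  attention <- c(rep(TRUE, n_kept + n_inc), rep(FALSE, n_att))
  stopifnot(length(group) == n_comp)
  data.frame(
    participant_id = sprintf("p_%03d", seq_len(n_comp)),
    group = group,
    prescreen_group = prescreen,
    attention_passed = attention,
    stringsAsFactors = FALSE
  )
}
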