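#' Probability of a "true" response under the generative model
#'
#' Under equal-variance Gaussian signal detection with sensitivity `d` and
#' criterion `c`, the probability of judging an item "true" is
#' `pnorm(d/2 - c)` for true items and `pnorm(-d/2 - c)` for false items.
#' Scoring these exact probabilities with [d_prime()] and [criterion()]
#' returns `(d, c)`, which is what makes estimator consistency testable in
#' closed form.
#'
#' @param d,c finite numerics (recycled against each other).
#' @param veracity `"true"` or `"false"`, recycled.
#' @return probabilities strictly in (0, 1).
#' @export
response_probability <- function(d, c, veracity) {
  if (any(!is.finite(d)) || any(!is.finite(c))) {
    stop("d and c must be finite", call. = FALSE)
  }
  if (!all(veracity %in% c("true", "false"))) {
    stop("veracity must be 'true' or 'false'", call. = FALSE)
  }
  sign <- ifelse(veracity == "true", 1, -1)
  stats::pnorm(sign * d / 2 - c)
}

#' Generate an abstract item bank
#'
#' Builds a 2 x 2 bank of judgment items (true/false veracity crossed with
#' two slants), `items_per_cell` items per cell, and assigns a fixed
#' presentation order as a seeded permutation. Odd/even split-half scoring is
#' defined on the parity of this 1-based `order_index`.
#'
#' @param items_per_cell items in each veracity x slant cell (default 20, so
#'   80 items total).
#' @param seed integer seed fixing the presentation order.
#' @return data frame of class `item_bank` with columns `item_id`,
#'   `veracity`, `slant`, `order_index`.
#' @export
generate_item_bank <- function(items_per_cell = 20, seed = 1) {
  if (length(items_per_cell) != 1 || is.na(items_per_cell) ||
      items_per_cell < 1 || items_per_cell != round(items_per_cell)) {
    stop("items_per_cell must be a positive integer", call. = FALSE)
  }
  cells <- expand.grid(
    veracity = c("true", "false"), slant = c("side_A", "side_B"),
    stringsAsFactors = FALSE
  )
  bank <- cells[rep(seq_len(nrow(cells)), each = items_per_cell), ]
  n <- nrow(bank)
  bank$item_id <- sprintf("item_%03d", seq_len(n))
  rng <- local_rng(seed)
  bank$order_index <- sample.int(n)
  restore_rng(rng)
  bank <- bank[c("item_id", "veracity", "slant", "order_index")]
  rownames(bank) <- NULL
  class(bank) <- c("item_bank", "data.frame")
  validate_item_bank(bank)
  bank
}

validate_item_bank <- function(bank) {
  need <- c("item_id", "veracity", "slant", "order_index")
  if (!all(need %in% names(bank))) stop("item bank missing columns", call. = FALSE)
  if (!setequal(bank$order_index, seq_len(nrow(bank)))) {
    stop("order_index must be a permutation of 1..n_items", call. = FALSE)
  }
  counts <- table(bank$veracity, bank$slant)
  if (length(unique(as.vector(counts))) != 1) {
    stop("veracity x slant cells must have equal item counts", call. = FALSE)
  }
  invisible(bank)
}

# Seeded RNG scoping: save the caller's RNG state, seed, and restore on exit.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  old
}
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Default individual-difference generator targets
#'
#' One row per measure in the 15-measure battery: the marginal mean and SD of
#' the latent trait, its target correlations with latent truth sensitivity,
#' acceptance threshold, and myside bias, and the reliability used when
#' emitting noisy scale-item responses. The shipped values emulate the
#' published summary statistics of the political-misinformation study
#' (measure means/SDs, the trait-by-index correlation screen, and scale
#' reliabilities); they are configurable.
#'
#' @return data frame with columns `trait`, `mean`, `sd`, `r_dprime`,
#'   `r_criterion`, `r_myside`, `reliability`.
#' @export
default_trait_spec <- function() {
  spec <- utils::read.csv(text = trimws("
trait,mean,sd,r_dprime,r_criterion,r_myside,reliability
extraversion,2.86,0.91,-0.10,-0.01,-0.16,0.78
agreeableness,3.88,0.80,-0.03,0.16,0.00,0.80
conscientiousness,3.78,0.90,-0.05,0.12,-0.06,0.84
neuroticism,2.62,1.10,-0.02,-0.09,0.00,0.89
openness,3.89,0.82,0.03,0.02,0.19,0.81
cognitive_reflection,4.02,2.03,0.30,0.02,0.11,0.77
aot,4.63,0.73,0.28,0.15,0.13,0.84
intellectual_humility,3.95,0.73,0.10,0.11,-0.09,0.86
need_to_evaluate,3.05,0.67,-0.02,-0.17,0.09,0.86
bullshit_receptivity,2.61,0.87,-0.25,-0.14,-0.25,0.88
conspiracy_mentality,6.12,2.06,-0.14,-0.23,0.01,0.86
self_esteem,3.06,0.74,0.06,0.01,-0.02,0.94
grandiose_narcissism,3.42,3.16,-0.24,-0.07,-0.07,0.79
need_to_belong,2.83,0.81,-0.13,0.00,-0.13,0.86
likeminded_identification,0.35,0.65,0.00,-0.04,0.00,0.85
"), stringsAsFactors = FALSE)
  spec
}

#' Generative specification for a synthetic cohort
#'
#' Fixes everything needed to simulate a study: group sizes, the item bank
#' size, the marginal distributions of the three latent signal-detection
#' parameters, the trait battery with its correlation targets, and the seed.
#' Latent traits are built as linear combinations of the three (mutually
#' independent, standard-normal) SDT latents plus independent uniqueness, so
#' each trait's correlations with d', c, and myside hit their targets exactly
#' in population; this construction requires the squared targets of each
#' trait to sum to at most 1 (otherwise no joint Gaussian exists and
#' construction fails).
#'
#' @param n_per_group participants per group (two groups; default 150).
#' @param items_per_cell items per veracity x slant cell (default 20).
#' @param dprime_dist,criterion_dist,myside_dist length-2 numerics
#'   `c(mean, sd)` of the latent sensitivity, baseline criterion, and
#'   criterion shift. Defaults emulate the published index means/SDs of the
#'   political study (0.52/0.49, 0.38/0.50, 0.66/0.70).
#' @param trait_spec data frame as from [default_trait_spec()], or `NULL`
#'   for no traits.
#' @param scale_registry named list of scale specs used when emitting
#'   item-level scale responses; `NULL` (default [default_scale_registry()]).
#' @param likert_items logical; emit discretized Likert scale-item responses
#'   (`TRUE`, default) or exact continuous trait scores as single pseudo-items
#'   (`FALSE`, giving perfect-reliability traits).
#' @param seed integer seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 150, items_per_cell = 20,
                          dprime_dist = c(mean = 0.52, sd = 0.49),
                          criterion_dist = c(mean = 0.38, sd = 0.50),
                          myside_dist = c(mean = 0.66, sd = 0.70),
                          trait_spec = default_trait_spec(),
                          scale_registry = NULL,
                          likert_items = TRUE,
                          seed = 1) {
  stopifnot(n_per_group >= 1, items_per_cell >= 1)
  for (d in list(dprime_dist, criterion_dist, myside_dist)) {
    if (length(d) != 2 || any(!is.finite(d)) || d[2] < 0) {
      stop("latent distributions are c(mean, sd) with sd >= 0", call. = FALSE)
    }
  }
  if (!is.null(trait_spec)) {
    need <- c("trait", "mean", "sd", "r_dprime", "r_criterion", "r_myside")
    if (!all(need %in% names(trait_spec))) {
      stop("trait_spec missing required columns", call. = FALSE)
    }
    if (any(trait_spec$sd < 0)) stop("trait sds must be >= 0", call. = FALSE)
    load2 <- trait_spec$r_dprime^2 + trait_spec$r_criterion^2 +
      trait_spec$r_myside^2
    if (any(load2 > 1 + 1e-12)) {
      stop("trait correlation targets imply a non-positive-semi-definite ",
           "latent covariance (squared targets sum to > 1 for: ",
           paste(trait_spec$trait[load2 > 1 + 1e-12], collapse = ", "), ")",
           call. = FALSE)
    }
    if (is.null(scale_registry)) scale_registry <- default_scale_registry()
    unknown <- setdiff(trait_spec$trait, names(scale_registry))
    if (likert_items && length(unknown)) {
      stop("no scale spec in registry for trait(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group),
      items_per_cell = as.integer(items_per_cell),
      dprime_dist = unname(dprime_dist),
      criterion_dist = unname(criterion_dist),
      myside_dist = unname(myside_dist),
      trait_spec = trait_spec,
      scale_registry = scale_registry,
      likert_items = isTRUE(likert_items),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  participants: %d per group (2 groups)\n", x$n_per_group))
  cat(sprintf("  items: %d per veracity x slant cell (%d total)\n",
              x$items_per_cell, 4L * x$items_per_cell))
  cat(sprintf("  latent d':     mean %.2f, sd %.2f\n",
              x$dprime_dist[1], x$dprime_dist[2]))
  cat(sprintf("  latent c:      mean %.2f, sd %.2f\n",
              x$criterion_dist[1], x$criterion_dist[2]))
  cat(sprintf("  latent myside: mean %.2f, sd %.2f\n",
              x$myside_dist[1], x$myside_dist[2]))
  cat(sprintf("  traits: %d (%s item responses)\n",
              if (is.null(x$trait_spec)) 0L else nrow(x$trait_spec),
              if (x$likert_items) "Likert" else "continuous"))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Draw latent parameters for a block of participants
#'
#' Samples `(d_true, c_base, m_true)` independently from the configured
#' Gaussians and each latent trait as its target-correlation combination of
#' the standardized SDT latents plus independent uniqueness. When all SDs are
#' zero every participant receives exactly the mean parameters. The
#' congruence-specific criteria are `c_base -/+ m_true/2`, so the overall
#' criterion equals `c_base` and the incongruent-congruent difference equals
#' `m_true`.
#'
#' @param config a [cohort_config()].
#' @param n number of draws.
#' @return data frame: `d_true`, `c_base`, `m_true`, then one column per
#'   trait (latent trait values on the trait's own metric).
#' @export
sample_participant_params <- function(config, n) {
  zd <- stats::rnorm(n); zc <- stats::rnorm(n); zm <- stats::rnorm(n)
  out <- data.frame(
    d_true = config$dprime_dist[1] + config$dprime_dist[2] * zd,
    c_base = config$criterion_dist[1] + config$criterion_dist[2] * zc,
    m_true = config$myside_dist[1] + config$myside_dist[2] * zm
  )
  ts <- config$trait_spec
  if (!is.null(ts)) {
    for (i in seq_len(nrow(ts))) {
      r <- c(ts$r_dprime[i], ts$r_criterion[i], ts$r_myside[i])
      uniq <- sqrt(max(0, 1 - sum(r^2)))
      z <- r[1] * zd + r[2] * zc + r[3] * zm + uniq * stats::rnorm(n)
      out[[ts$trait[i]]] <- ts$mean[i] + ts$sd[i] * z
    }
  }
  out
}

#' Generate a full synthetic cohort
#'
#' Simulates a balanced two-group study: an item bank, per-participant latent
#' parameters, Bernoulli truth judgments for every item using the
#' participant's congruence-specific criterion, scale-item responses for the
#' trait battery, and the latent truth table for parameter-recovery testing.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list of class `sdt_cohort` with elements `bank`, `participants`
#'   (group, prescreen_group, attention_passed, scale-item columns),
#'   `judgments` (long: participant_id, item_id, response), `latents`, and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- local_rng(config$seed)
  on.exit(restore_rng(old))

  bank <- generate_item_bank_unseeded(config$items_per_cell)
  n <- 2L * config$n_per_group
  group <- rep(c("side_A", "side_B"), each = config$n_per_group)
  latents <- sample_participant_params(config, n)
  latents <- cbind(
    participant_id = sprintf("p_%04d", seq_len(n)),
    group = group, latents, stringsAsFactors = FALSE
  )

  # response probabilities: participants x items
  cong_A <- congruence_of("side_A", bank$slant)   # per item, for side_A
  is_cong <- outer(group == "side_A", cong_A == "congruent", "==")
  # criterion used for item j by participant i: c_base -/+ m/2
  crit <- latents$c_base + ifelse(is_cong, -1, 1) * latents$m_true / 2
  sgn <- ifelse(bank$veracity == "true", 1, -1)
  mu <- outer(latents$d_true / 2, sgn) - crit
  prob <- stats::pnorm(mu)
  resp <- matrix(stats::runif(length(prob)) < prob, nrow = n)

  judgments <- data.frame(
    participant_id = rep(latents$participant_id, times = nrow(bank)),
    item_id = rep(bank$item_id, each = n),
    response = ifelse(as.vector(resp), "true", "false"),
    stringsAsFactors = FALSE
  )
  judgments <- judgments[order(judgments$participant_id, judgments$item_id), ]
  rownames(judgments) <- NULL

  participants <- data.frame(
    participant_id = latents$participant_id,
    group = group,
    prescreen_group = group,
    attention_passed = TRUE,
    stringsAsFactors = FALSE
  )
  if (!is.null(config$trait_spec)) {
    participants <- cbind(
      participants,
      generate_scale_responses(latents, config),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(bank = bank, participants = participants, judgments = judgments,
         latents = latents, config = config),
    class = "sdt_cohort"
  )
}

# item bank drawn from the current RNG stream (generate_cohort scopes the seed)
generate_item_bank_unseeded <- function(items_per_cell) {
  cells <- expand.grid(
    veracity = c("true", "false"), slant = c("side_A", "side_B"),
    stringsAsFactors = FALSE
  )
  bank <- cells[rep(seq_len(nrow(cells)), each = items_per_cell), ]
  n <- nrow(bank)
  bank$item_id <- sprintf("item_%03d", seq_len(n))
  bank$order_index <- sample.int(n)
  bank <- bank[c("item_id", "veracity", "slant", "order_index")]
  rownames(bank) <- NULL
  class(bank) <- c("item_bank", "data.frame")
  bank
}

#' @export
print.sdt_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %d items, %d trait scales\n",
              nrow(x$participants), nrow(x$bank),
              if (is.null(x$config$trait_spec)) 0L else nrow(x$config$trait_spec)))
  invisible(x)
}

# Item-level scale responses whose scored values track the latent traits with
# the configured reliability. Mean scales get Gaussian item noise sized so the
# k-item mean has the target reliability, then Likert rounding; sum scales
# (0/1 items) get Bernoulli items with success probability T/k; the
# likeminded difference scale gets paired rating vectors whose item-wise
# difference tracks the latent. Reverse-keyed items are stored reverse-coded
# so that standard scoring recovers the construct.
generate_scale_responses <- function(latents, config) {
  ts <- config$trait_spec
  reg <- config$scale_registry
  n <- nrow(latents)
  cols <- list()
  for (i in seq_len(nrow(ts))) {
    trait <- ts$trait[i]
    tvals <- latents[[trait]]
    if (!config$likert_items) {
      cols[[paste0(trait, "_score")]] <- tvals
      next
    }
    spec <- reg[[trait]]
    rel <- ts$reliability[i]
    k <- spec$n_items
    if (spec$aggregation == "sum") {
      p <- pmin(pmax(tvals / k, 0.02), 0.98)
      for (j in seq_len(k)) {
        cols[[paste0(trait, "_", j)]] <- as.integer(stats::runif(n) < p)
      }
    } else if (spec$aggregation == "difference_of_means") {
      mid <- (spec$response_min + spec$response_max) / 2
      sd_item <- sqrt(k * (1 - rel) / rel) * max(ts$sd[i], 1e-8)
      for (j in seq_len(k)) {
        hum <- mid + stats::rnorm(n, sd = 0.8)
        lik <- hum + tvals + stats::rnorm(n, sd = sd_item)
        cols[[paste0(trait, "_hum_", j)]] <-
          likert_round(hum, spec$response_min, spec$response_max)
        cols[[paste0(trait, "_lm_", j)]] <-
          likert_round(lik, spec$response_min, spec$response_max)
      }
    } else {
      sd_item <- sqrt(k * (1 - rel) / rel) * max(ts$sd[i], 1e-8)
      for (j in seq_len(k)) {
        x <- tvals + stats::rnorm(n, sd = sd_item)
        x <- likert_round(x, spec$response_min, spec$response_max)
        if (j %in% spec$reverse_items) {
          x <- spec$response_min + spec$response_max - x
        }
        cols[[paste0(trait, "_", j)]] <- x
      }
    }
  }
  as.data.frame(cols, stringsAsFactors = FALSE)
}

likert_round <- function(x, lo, hi) {
  pmin(pmax(round(x), lo), hi)
}

#' Write a cohort to plain CSV/JSON files
#'
#' Emits `item_bank.csv`, `participants.csv`, `judgments.csv`,
#' `latents.csv`, and `config.json` into `dir`.
#'
#' @param cohort an `sdt_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sdt_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$bank, file.path(dir, "item_bank.csv"), row.names = FALSE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$judgments, file.path(dir, "judgments.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$latents, file.path(dir, "latents.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  cfg$scale_registry <- NULL # registry travels separately; defaults re-attach
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the cohort CSVs.
#' @return an `sdt_cohort` (with `latents`/`config` present when their files
#'   exist; imported real data need only the bank, participants, judgments).
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("item_bank.csv", "participants.csv",
                           "judgments.csv"))
  if (!all(file.exists(need))) {
    stop("no cohort found at ", dir, call. = FALSE)
  }
  bank <- utils::read.csv(file.path(dir, "item_bank.csv"),
                          stringsAsFactors = FALSE)
  class(bank) <- c("item_bank", "data.frame")
  validate_item_bank(bank)
  participants <- utils::read.csv(file.path(dir, "participants.csv"),
                                  stringsAsFactors = FALSE)
  judgments <- utils::read.csv(file.path(dir, "judgments.csv"),
                               stringsAsFactors = FALSE)
  check_complete_judgments(judgments, bank, participants)
  latents <- NULL
  lat_path <- file.path(dir, "latents.csv")
  if (file.exists(lat_path)) {
    latents <- utils::read.csv(lat_path, stringsAsFactors = FALSE)
  }
  config <- NULL
  cfg_path <- file.path(dir, "config.json")
  if (file.exists(cfg_path)) {
    cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    config <- cohort_config(
      n_per_group = cfg$n_per_group, items_per_cell = cfg$items_per_cell,
      dprime_dist = cfg$dprime_dist, criterion_dist = cfg$criterion_dist,
      myside_dist = cfg$myside_dist,
      trait_spec = if (is.null(cfg$trait_spec)) NULL else
        as.data.frame(cfg$trait_spec, stringsAsFactors = FALSE),
      likert_items = cfg$likert_items, seed = cfg$seed
    )
  }
  structure(
    list(bank = bank, participants = participants, judgments = judgments,
         latents = latents, config = config),
    class = "sdt_cohort"
  )
}

check_complete_judgments <- function(judgments, bank, participants) {
  tab <- table(judgments$participant_id)
  ids <- participants$participant_id
  if (!all(ids %in% names(tab)) || any(tab[ids] != nrow(bank))) {
    stop("imported judgments must cover every bank item exactly once per ",
         "participant", call. = FALSE)
  }
  if (anyDuplicated(judgments[c("participant_id", "item_id")])) {
    stop("duplicate participant x item judgments", call. = FALSE)
  }
  invisible(TRUE)
}
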