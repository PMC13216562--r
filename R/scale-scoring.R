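#' Define a scale specification
#'
#' @param scale_name name of the measure.
#' @param n_items number of items (for the difference scale, items per
#'   rating target).
#' @param response_min,response_max integer response bounds.
#' @param reverse_items integer indices of reverse-keyed items (subset of
#'   `1:n_items`).
#' @param aggregation `"mean"`, `"sum"`, or `"difference_of_means"` (the
#'   likeminded-identification difference score).
#' @return object of class `scale_spec`.
#' @export
scale_spec <- function(scale_name, n_items, response_min, response_max,
                       reverse_items = integer(0),
                       aggregation = c("mean", "sum", "difference_of_means")) {
  aggregation <- match.arg(aggregation)
  stopifnot(n_items >= 1, response_min < response_max)
  reverse_items <- as.integer(reverse_items)
  if (length(reverse_items) &&
      (any(reverse_items < 1) || any(reverse_items > n_items))) {
    stop("reverse_items must be within 1..n_items", call. = FALSE)
  }
  structure(
    list(scale_name = scale_name, n_items = as.integer(n_items),
         response_min = as.integer(response_min),
         response_max = as.integer(response_max),
         reverse_items = reverse_items, aggregation = aggregation),
    class = "scale_spec"
  )
}

#' @export
print.scale_spec <- function(x, ...) {
  cat(sprintf("Scale '%s': %d items, range %d-%d, %s%s\n",
              x$scale_name, x$n_items, x$response_min, x$response_max,
              x$aggregation,
              if (length(x$reverse_items))
                paste0(", reverse items {",
                       paste(x$reverse_items, collapse = ","), "}")
              else ""))
  invisible(x)
}

#' Bundled registry of the 15-measure battery
#'
#' Scale lengths, response ranges, and aggregation rules follow the cited
#' instruments of the battery (Big-5 domain subscales of the 30-item
#' inventory; 7-item cognitive reflection test summed 0/1; 10-item bullshit
#' receptivity; 5-item conspiracy mentality on 0-10; 10-item self-esteem on
#' 1-4; 16-item narcissism inventory summed 0/1; 6-item intellectual
#' humility; 13-item actively open-minded thinking on 1-6; 16-item need to
#' evaluate; 10-item need to belong; and the likeminded-identification
#' difference score over 10 paired ratings). Reverse-keyed item sets must
#' come from the source instruments' scoring keys; the sets shipped here are
#' plausible placeholders and the registry is intended to be edited when the
#' exact keys are in hand.
#'
#' @return named list of [scale_spec()] objects.
#' @export
default_scale_registry <- function() {
  reg <- list(
    scale_spec("extraversion", 6, 1, 5, c(2, 4, 6)),
    scale_spec("agreeableness", 6, 1, 5, c(2, 4, 6)),
    scale_spec("conscientiousness", 6, 1, 5, c(2, 4, 6)),
    scale_spec("neuroticism", 6, 1, 5, c(2, 4, 6)),
    scale_spec("openness", 6, 1, 5, c(2, 4, 6)),
    scale_spec("cognitive_reflection", 7, 0, 1, aggregation = "sum"),
    scale_spec("aot", 13, 1, 6, c(10, 11, 12, 13)),
    scale_spec("intellectual_humility", 6, 1, 5),
    scale_spec("need_to_evaluate", 16, 1, 5, c(2, 5, 8, 11, 14, 16)),
    scale_spec("bullshit_receptivity", 10, 1, 5),
    scale_spec("conspiracy_mentality", 5, 0, 10),
    scale_spec("self_esteem", 10, 1, 4, c(2, 5, 6, 8, 9)),
    scale_spec("grandiose_narcissism", 16, 0, 1, aggregation = "sum"),
    scale_spec("need_to_belong", 10, 1, 5, c(1, 3, 7)),
    scale_spec("likeminded_identification", 10, 1, 5,
               aggregation = "difference_of_means")
  )
  stats::setNames(reg, vapply(reg, `[[`, "", "scale_name"))
}

#' Write / read a scale registry as JSON
#'
#' @param registry named list of [scale_spec()] objects.
#' @param path JSON file path.
#' @return `path` (write) or the registry (read).
#' @export
write_scale_registry <- function(registry, path) {
  jsonlite::write_json(lapply(registry, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scale_registry
#' @export
read_scale_registry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg <- lapply(raw, function(s) {
    scale_spec(s$scale_name, s$n_items, s$response_min, s$response_max,
               if (is.null(s$reverse_items)) integer(0) else s$reverse_items,
               s$aggregation)
  })
  stats::setNames(reg, vapply(reg, `[[`, "", "scale_name"))
}

#' Reverse-code responses
#'
#' Maps a response r to `response_min + response_max - r`; applying the map
#' twice restores the input.
#'
#' @param r numeric responses.
#' @param response_min,response_max scale bounds.
#' @return recoded responses.
#' @export
reverse_code <- function(r, response_min, response_max) {
  response_min + response_max - r
}

#' Score a scale from item responses
#'
#' Reverse-keyed items are recoded, then the spec's aggregation (mean or sum)
#' is applied. Missing or out-of-range responses are rejected, not imputed.
#'
#' @param responses numeric vector of length `spec$n_items`.
#' @param spec a [scale_spec()] with aggregation `"mean"` or `"sum"`.
#' @return scalar score.
#' @examples
#' score_scale(c(1, 5), scale_spec("ex", 2, 1, 5, reverse_items = 2))
#' @export
score_scale <- function(responses, spec) {
  stopifnot(inherits(spec, "scale_spec"))
  if (spec$aggregation == "difference_of_means") {
    stop("use score_likeminded_identification() for the difference scale",
         call. = FALSE)
  }
  if (length(responses) != spec$n_items) {
    stop(sprintf("'%s' expects %d responses, got %d", spec$scale_name,
                 spec$n_items, length(responses)), call. = FALSE)
  }
  if (any(is.na(responses)) ||
      any(responses < spec$response_min | responses > spec$response_max)) {
    stop(sprintf("missing or out-of-range response for '%s'",
                 spec$scale_name), call. = FALSE)
  }
  rev <- spec$reverse_items
  responses[rev] <- reverse_code(responses[rev], spec$response_min,
                                 spec$response_max)
  switch(spec$aggregation, mean = mean(responses), sum = sum(responses))
}

#' Likeminded-identification difference score
#'
#' Mean of the item-wise differences between ratings of likeminded people
#' and ratings of all humanity on the same items.
#'
#' @param ratings_likeminded,ratings_humanity equal-length numeric vectors.
#' @return scalar score (positive = stronger identification with likeminded
#'   people than with humanity at large).
#' @export
score_likeminded_identification <- function(ratings_likeminded,
                                            ratings_humanity) {
  if (length(ratings_likeminded) != length(ratings_humanity)) {
    stop("rating vectors must have equal length", call. = FALSE)
  }
  if (any(is.na(ratings_likeminded)) || any(is.na(ratings_humanity))) {
    stop("missing ratings are rejected, not imputed", call. = FALSE)
  }
  mean(ratings_likeminded - ratings_humanity)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#' Can be negative for incoherent item sets.
#'
#' @param item_matrix numeric matrix or data frame, participants x items
#'   (>= 3 participants, >= 2 items).
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2) stop("alpha needs at least 2 items", call. = FALSE)
  if (nrow(m) < 3) stop("alpha needs at least 3 participants", call. = FALSE)
  if (any(is.na(m))) stop("missing responses are rejected", call. = FALSE)
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) {
    stop("undefined reliability: total-score variance is zero", call. = FALSE)
  }
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Parcel-based reliability of a signal-detection index
#'
#' The binary-judgment indices have no item-level scores, so reliability is
#' approximated by splitting each veracity x congruence cell into `k_parcels`
#' presentation-order-based parcels, computing the index within each parcel
#' for every participant, and taking Cronbach's alpha across parcel scores.
#' This is a stated stand-in for the (unreported) method behind published
#' index reliabilities, not a reproduction of it.
#'
#' @param judgments long judgments data frame (`participant_id`, `item_id`,
#'   `response`).
#' @param bank item bank.
#' @param participants data frame with `participant_id`, `group`.
#' @param index which index: `"d_prime"`, `"c_overall"`, or `"myside"`.
#' @param k_parcels number of parcels; must divide the per-cell item count.
#' @return scalar alpha across parcels.
#' @export
sdt_index_reliability <- function(judgments, bank, participants,
                                  index = c("d_prime", "c_overall", "myside"),
                                  k_parcels = 4) {
  index <- match.arg(index)
  items_per_cell <- nrow(bank) / 4L
  if (items_per_cell %% k_parcels != 0) {
    stop("k_parcels must divide the per-cell item count evenly", call. = FALSE)
  }
  # assign parcel by order rank within each veracity x slant cell
  bank2 <- bank
  cell <- interaction(bank2$veracity, bank2$slant, drop = TRUE)
  parcel <- integer(nrow(bank2))
  for (cl in levels(cell)) {
    idx <- which(cell == cl)
    rank_in_cell <- rank(bank2$order_index[idx])
    parcel[idx] <- ceiling(rank_in_cell / (items_per_cell / k_parcels))
  }
  scores <- sapply(seq_len(k_parcels), function(pk) {
    sub_bank <- bank2[parcel == pk, , drop = FALSE]
    sub_bank$order_index <- rank(sub_bank$order_index)
    class(sub_bank) <- c("item_bank", "data.frame")
    sub_j <- judgments[judgments$item_id %in% sub_bank$item_id, , drop = FALSE]
    sc <- score_cohort(sub_j, sub_bank, participants, splits = "all")
    sc[[index]]
  })
  cronbach_alpha(scores)
}

#' Score the full trait battery for a cohort
#'
#' Locates each scale's item columns in the participants table (named
#' `<trait>_<i>`, or `<trait>_lm_<i>` / `<trait>_hum_<i>` for the difference
#' scale, or `<trait>_score` for pre-scored continuous traits), scores every
#' participant, and attaches Cronbach's alpha per multi-item scale as the
#' `"alphas"` attribute.
#'
#' @param participants participants data frame with scale-item columns.
#' @param registry named list of [scale_spec()]s
#'   (default [default_scale_registry()]).
#' @param traits which traits to score (default: all in the registry that
#'   have columns present).
#' @return data frame `participant_id` + one column per trait, with an
#'   `"alphas"` attribute (named numeric; `NA` for pre-scored traits).
#' @export
score_traits <- function(participants, registry = default_scale_registry(),
                         traits = NULL) {
  if (is.null(traits)) {
    traits <- names(registry)[vapply(names(registry), function(tr) {
      any(startsWith(names(participants), paste0(tr, "_")))
    }, logical(1))]
  }
  out <- data.frame(participant_id = participants$participant_id,
                    stringsAsFactors = FALSE)
  alphas <- stats::setNames(rep(NA_real_, length(traits)), traits)
  for (tr in traits) {
    spec <- registry[[tr]]
    if (is.null(spec)) stop("no registry entry for trait: ", tr, call. = FALSE)
    score_col <- paste0(tr, "_score")
    if (score_col %in% names(participants)) {
      out[[tr]] <- participants[[score_col]]
      next
    }
    if (spec$aggregation == "difference_of_means") {
      lm_cols <- paste0(tr, "_lm_", seq_len(spec$n_items))
      hum_cols <- paste0(tr, "_hum_", seq_len(spec$n_items))
      if (!all(c(lm_cols, hum_cols) %in% names(participants))) {
        stop("missing item columns for trait: ", tr, call. = FALSE)
      }
      lm_m <- as.matrix(participants[lm_cols])
      hum_m <- as.matrix(participants[hum_cols])
      out[[tr]] <- vapply(seq_len(nrow(lm_m)), function(i) {
        score_likeminded_identification(lm_m[i, ], hum_m[i, ])
      }, numeric(1))
      diffs <- lm_m - hum_m
      alphas[tr] <- tryCatch(cronbach_alpha(diffs), error = function(e) NA_real_)
    } else {
      cols <- paste0(tr, "_", seq_len(spec$n_items))
      if (!all(cols %in% names(participants))) {
        stop("missing item columns for trait: ", tr, call. = FALSE)
      }
      m <- as.matrix(participants[cols])
      out[[tr]] <- vapply(seq_len(nrow(m)), function(i) {
        score_scale(m[i, ], spec)
      }, numeric(1))
      # alpha on the keyed (recoded) item matrix
      keyed <- m
      rev <- spec$reverse_items
      if (length(rev)) {
        keyed[, rev] <- reverse_code(keyed[, rev], spec$response_min,
                                     spec$response_max)
      }
      alphas[tr] <- tryCatch(cronbach_alpha(keyed), error = function(e) NA_real_)
    }
  }
  attr(out, "alphas") <- alphas
  out
}
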