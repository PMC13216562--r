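#' Apply the study exclusion rules
#'
#' Among participants who completed all measures, attention-check failures
#' are removed first; then, among the survivors, participants whose reported
#' group membership is inconsistent with their prescreen group are removed.
#' Record order is preserved. The staged order matters for the counts: a
#' participant failing both rules is counted as an attention failure only.
#'
#' @param participants data frame with columns `participant_id`, `group`,
#'   `prescreen_group`, `attention_passed`, and optionally `completed`
#'   (assumed `TRUE` when absent).
#' @return list with `kept` (the retained records) and `report` (an
#'   `exclusion_report`: n_started, n_completed, n_failed_attention,
#'   n_inconsistent_group, n_final, per-group final counts).
#' @examples
#' recs <- data.frame(
#'   participant_id = c("a", "b", "c"),
#'   group = c("side_A", "side_A", "side_B"),
#'   prescreen_group = c("side_A", "side_B", "side_B"),
#'   attention_passed = c(TRUE, TRUE, FALSE)
#' )
#' apply_exclusions(recs)$report
#' @export
apply_exclusions <- function(participants) {
  need <- c("participant_id", "group", "prescreen_group", "attention_passed")
  if (!all(need %in% names(participants))) {
    stop("participants must carry columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(participants$attention_passed))) {
    stop("attention_passed must not be missing", call. = FALSE)
  }
  n_started <- nrow(participants)
  completed <- if ("completed" %in% names(participants)) {
    as.logical(participants$completed)
  } else {
    rep(TRUE, n_started)
  }
  comp <- participants[completed, , drop = FALSE]
  att_ok <- comp[comp$attention_passed, , drop = FALSE]
  consistent <- att_ok$group == att_ok$prescreen_group
  kept <- att_ok[consistent, , drop = FALSE]
  per_group <- table(kept$group)
  report <- structure(
    list(
      n_started = n_started,
      n_completed = nrow(comp),
      n_failed_attention = nrow(comp) - nrow(att_ok),
      n_inconsistent_group = sum(!consistent),
      n_final = nrow(kept),
      per_group = stats::setNames(as.integer(per_group), names(per_group))
    ),
    class = "exclusion_report"
  )
  stopifnot(report$n_final ==
              report$n_completed - report$n_failed_attention -
              report$n_inconsistent_group)
  list(kept = kept, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report\n")
  cat(sprintf("  started:              %d\n", x$n_started))
  cat(sprintf("  completed:            %d\n", x$n_completed))
  cat(sprintf("  failed attention:     %d\n", x$n_failed_attention))
  cat(sprintf("  inconsistent group:   %d\n", x$n_inconsistent_group))
  cat(sprintf("  final:                %d (%s)\n", x$n_final,
              paste(sprintf("%s: %d", names(x$per_group), x$per_group),
                    collapse = ", ")))
  invisible(x)
}

#' Configure a full study run
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"import"`
#'   (read a cohort directory written by [write_cohort()] or assembled from
#'   real data in the same layout).
#' @param cohort a [cohort_config()] (simulate mode).
#' @param input_dir cohort directory (import mode).
#' @param output_dir where result tables are written.
#' @param seed integer seed for the run (simulate mode reseeds the cohort
#'   config with it so one seed fixes the whole run).
#' @param adjust_method multiplicity adjustment for the screen.
#' @param run_bifactor fit the bifactor model stage (default `TRUE` when the
#'   required scale columns exist).
#' @param bifactor_spec_path optional JSON path of a custom bifactor spec.
#' @param quiet suppress progress messages (default `TRUE`).
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "import"), cohort = NULL,
                       input_dir = NULL, output_dir = tempfile("sdt_run_"),
                       seed = 1, adjust_method = c("holm", "bonferroni"),
                       run_bifactor = TRUE, bifactor_spec_path = NULL,
                       quiet = TRUE) {
  mode <- match.arg(mode)
  adjust_method <- match.arg(adjust_method)
  if (mode == "simulate") {
    if (is.null(cohort)) cohort <- cohort_config(seed = seed)
    stopifnot(inherits(cohort, "cohort_config"))
    if (!is.null(input_dir)) {
      stop("exactly one input mode: simulate takes no input_dir", call. = FALSE)
    }
  } else {
    if (is.null(input_dir)) stop("import mode needs input_dir", call. = FALSE)
    if (!is.null(cohort)) {
      stop("exactly one input mode: import takes no cohort config",
           call. = FALSE)
    }
  }
  structure(
    list(mode = mode, cohort = cohort, input_dir = input_dir,
         output_dir = output_dir, seed = as.integer(seed),
         adjust_method = adjust_method, run_bifactor = isTRUE(run_bifactor),
         bifactor_spec_path = bifactor_spec_path, quiet = isTRUE(quiet)),
    class = "run_config"
  )
}

run_log <- function(config, stage, msg) {
  if (!config$quiet) message(sprintf("[%s] %s", stage, msg))
}

#' Run the full study analysis
#'
#' Orchestrates, deterministically given the seed: cohort input (simulated
#' or imported), exclusions, trait scoring, signal-detection scoring for the
#' all/odd/even splits, the cohort rate summary, the measures summary
#' (means, SDs, Cronbach's alpha), the four split-half regressions, the
#' correlation screen with partial correlations and adjusted p-values, and
#' (optionally) the bifactor model. All tables are written to
#' `config$output_dir` as full-precision CSVs plus 3-decimal `*_display.csv`
#' companions, with a machine-readable `manifest.json`. Any stage failure
#' removes partial outputs and aborts with a stage-labeled error.
#'
#' @param config a [run_config()].
#' @return invisible list with all result objects (`cohort`, `exclusions`,
#'   `scores`, `traits`, `rates`, `measures`, `regressions`, `screen`,
#'   `bifactor`, `manifest`).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  stage <- "input"
  res <- tryCatch({
    cohort <- if (config$mode == "simulate") {
      cfg <- config$cohort
      cfg$seed <- config$seed
      run_log(config, stage, "generating synthetic cohort")
      generate_cohort(cfg)
    } else {
      run_log(config, stage, paste("importing", config$input_dir))
      read_cohort(config$input_dir)
    }

    stage <- "exclusions"
    excl <- apply_exclusions(cohort$participants)
    kept <- excl$kept
    judgments <- cohort$judgments[
      cohort$judgments$participant_id %in% kept$participant_id, , drop = FALSE]

    stage <- "scoring"
    registry <- if (!is.null(cohort$config) &&
                    !is.null(cohort$config$scale_registry)) {
      cohort$config$scale_registry
    } else {
      default_scale_registry()
    }
    traits <- score_traits(kept, registry)
    scores <- score_cohort(judgments, cohort$bank, kept)

    stage <- "rates"
    rates <- rate_summary(scores)

    stage <- "measures"
    s_all <- scores[scores$split == "all", , drop = FALSE]
    idx <- data.frame(
      measure = c("truth_sensitivity", "acceptance_threshold", "myside_bias"),
      mean = c(mean(s_all$d_prime), mean(s_all$c_overall), mean(s_all$myside)),
      sd = c(stats::sd(s_all$d_prime), stats::sd(s_all$c_overall),
             stats::sd(s_all$myside)),
      alpha = vapply(c("d_prime", "c_overall", "myside"), function(ix) {
        tryCatch(
          sdt_index_reliability(judgments, cohort$bank, kept, index = ix,
                                k_parcels = best_parcel_count(cohort$bank)),
          error = function(e) NA_real_)
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
    alphas <- attr(traits, "alphas")
    trait_cols <- setdiff(names(traits), "participant_id")
    measures <- rbind(idx, data.frame(
      measure = trait_cols,
      mean = vapply(traits[trait_cols], mean, numeric(1)),
      sd = vapply(traits[trait_cols], stats::sd, numeric(1)),
      alpha = unname(alphas[trait_cols]),
      stringsAsFactors = FALSE
    ))
    rownames(measures) <- NULL

    stage <- "regressions"
    regs <- split_half_fa_regression(scores)
    reg_tab <- do.call(rbind, lapply(names(regs), function(nm) {
      r <- regs[[nm]]
      data.frame(outcome = attr(r, "outcome_name"),
                 direction = attr(r, "direction"),
                 predictor = r$predictor, beta = r$beta, p = r$p,
                 r_squared = attr(r, "r_squared"), n = attr(r, "n"),
                 stringsAsFactors = FALSE)
    }))

    stage <- "screen"
    screen <- correlation_screen(traits, scores, group = kept$group,
                                 method = config$adjust_method)

    stage <- "bifactor"
    bf <- NULL
    bf_summary <- NULL
    if (config$run_bifactor) {
      bspec <- if (!is.null(config$bifactor_spec_path)) {
        read_bifactor_spec(config$bifactor_spec_path)
      } else {
        default_bifactor_spec()
      }
      ind <- tryCatch(
        bifactor_indicators(kept, scores, registry),
        error = function(e) NULL
      )
      if (!is.null(ind)) {
        vars <- c(bspec$indicators, bspec$outcomes)
        S <- stats::cov(as.matrix(ind[vars]))
        bf <- fit_bifactor(S, nrow(ind), bspec, seed = config$seed)
        bf_summary <- list(
          discrepancy = attr(bf, "discrepancy"), df = attr(bf, "df"),
          converged = attr(bf, "converged"), heywood = attr(bf, "heywood"),
          n = attr(bf, "n")
        )
      }
    }

    stage <- "write"
    emit <- function(df, name) {
      path <- file.path(out_dir, paste0(name, ".csv"))
      utils::write.csv(df, path, row.names = FALSE)
      disp <- as.data.frame(lapply(df, function(col) {
        if (is.numeric(col)) round(col, 3) else col
      }))
      disp_path <- file.path(out_dir, paste0(name, "_display.csv"))
      utils::write.csv(disp, disp_path, row.names = FALSE)
      written <<- c(written, path, disp_path)
    }
    excl_df <- data.frame(
      stage = c("started", "completed", "failed_attention",
                "inconsistent_group", "final"),
      n = c(excl$report$n_started, excl$report$n_completed,
            excl$report$n_failed_attention, excl$report$n_inconsistent_group,
            excl$report$n_final),
      stringsAsFactors = FALSE
    )
    emit(excl_df, "exclusions")
    emit(rates, "rates_summary")
    emit(measures, "measures_summary")
    emit(reg_tab, "regressions")
    emit(screen, "screen")
    emit(scores, "sdt_scores")
    emit(traits, "trait_scores")
    if (!is.null(bf)) emit(as.data.frame(bf), "bifactor")

    manifest <- list(
      package = "truthsdt",
      package_version = as.character(utils::packageVersion("truthsdt")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      mode = config$mode,
      seed = config$seed,
      adjust_method = config$adjust_method,
      config_hash = config_hash(config),
      n_final = excl$report$n_final,
      bifactor = bf_summary,
      tables = basename(written)
    )
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    written <- c(written, manifest_path)
    run_log(config, "done", out_dir)
    list(cohort = cohort, exclusions = excl$report, scores = scores,
         traits = traits, rates = rates, measures = measures,
         regressions = regs, screen = screen, bifactor = bf,
         manifest = manifest, output_dir = out_dir)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("run_study failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

# largest parcel count <= 4 dividing the per-cell item count
best_parcel_count <- function(bank) {
  per_cell <- nrow(bank) / 4L
  for (k in 4:2) if (per_cell %% k == 0) return(k)
  2L
}

# stable hash of the run configuration (md5 of its serialized form)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  stripped <- config
  stripped$output_dir <- NULL
  saveRDS(stripped, tmp, version = 2)
  unname(tools::md5sum(tmp))
}
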