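#' Benchmark configuration
#'
#' Describes the full factorial experiment: cohorts x mechanisms x scales x
#' methods x repetitions. Cohorts are [cohort_config()] objects (generated on
#' the fly) or paths to matrix TSV files; each carries a cohort status
#' (healthy / disease). The default design mirrors the benchmark layout:
#' five mechanisms, both scales, all seven methods, 100 repetitions, 3%
#' simulated missing values.
#'
#' @param cohorts Named list of [cohort_config()] objects or file paths.
#' @param mechanisms Subset of `c("MCAR", "MAR", "MNAR_LOW", "MNAR_MID",
#'   "MNAR_HIGH")`.
#' @param scales Subset of `c("beta", "M")`.
#' @param methods Character vector of method names or list of
#'   [imputer_spec()]s.
#' @param repetitions Repetitions of the masking per mechanism (default 100).
#' @param fraction Simulated missing fraction (default 0.03).
#' @param alpha Significance level for the comparison report.
#' @param base_seed Integer; all task seeds are derived from it.
#' @param outdir Optional output directory for score/report files and the
#'   resumability cache.
#' @return A `benchmark_config`.
#' @export
benchmark_config <- function(cohorts,
                             mechanisms = c("MCAR", "MAR", "MNAR_LOW",
                                            "MNAR_MID", "MNAR_HIGH"),
                             scales = c("beta", "M"),
                             methods = c("mean", "knn", "svd_iter", "soft_svd",
                                         "iter_pca", "chained_reg",
                                         "methylimp"),
                             repetitions = 100L, fraction = 0.03,
                             alpha = 0.05, base_seed = 1L, outdir = NULL) {
  if (length(cohorts) == 0) abort_config("`cohorts` must be non-empty")
  if (is.null(names(cohorts)) || any(names(cohorts) == "")) {
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  }
  mechanisms <- match.arg(mechanisms, several.ok = TRUE)
  scales <- match.arg(scales, several.ok = TRUE)
  if (repetitions < 1) abort_config("`repetitions` must be >= 1")
  if (fraction <= 0 || fraction >= 1) abort_config("`fraction` must lie in (0, 1)")
  if (length(methods) == 0) abort_config("`methods` must be non-empty")
  specs <- lapply(methods, function(m) {
    if (inherits(m, "imputer_spec")) m else imputer_spec(m)
  })
  names(specs) <- vapply(specs, `[[`, character(1), "method")
  if (anyDuplicated(names(specs))) abort_config("duplicate method names")
  structure(list(cohorts = cohorts, mechanisms = mechanisms, scales = scales,
                 methods = specs, repetitions = as.integer(repetitions),
                 fraction = fraction, alpha = alpha,
                 base_seed = as.integer(base_seed), outdir = outdir),
            class = "benchmark_config")
}

#' Enumerate the benchmark task plan
#'
#' Deterministic enumeration of all (cohort, mechanism, scale, method,
#' repetition) tasks. The masking seed depends only on (cohort, mechanism,
#' repetition), so both scales and all methods of a repetition see identical
#' masked positions; imputer-internal randomness is seeded from the masking
#' seed plus the method. Under the default design this yields
#' `mechanisms x scales x repetitions` = 1000 imputation runs per dataset per
#' method, 500 per scale.
#'
#' @param cfg A [benchmark_config()].
#' @return A tibble with one row per task: `cohort`, `mechanism`, `scale`,
#'   `method`, `repetition`, `mask_seed`, `method_seed`.
#' @export
plan_tasks <- function(cfg) {
  stopifnot(inherits(cfg, "benchmark_config"))
  plan <- tidyr::expand_grid(
    cohort = names(cfg$cohorts),
    mechanism = cfg$mechanisms,
    repetition = seq_len(cfg$repetitions),
    scale = cfg$scales,
    method = names(cfg$methods)
  )
  plan$mask_seed <- purrr::pmap_int(
    plan[, c("cohort", "mechanism", "repetition")],
    function(cohort, mechanism, repetition) {
      hash_seed(cfg$base_seed, cohort, mechanism, repetition)
    }
  )
  plan$method_seed <- purrr::map2_int(plan$mask_seed, plan$method, hash_seed)
  plan[, c("cohort", "mechanism", "scale", "method", "repetition",
           "mask_seed", "method_seed")]
}

resolve_cohort <- function(spec, name) {
  if (inherits(spec, "cohort_config")) {
    coh <- generate_cohort(spec)
    list(data = coh$data, weights = coh$propensity$weight,
         status = spec$status)
  } else if (inherits(spec, "methyl_cohort")) {
    list(data = spec$data, weights = spec$propensity$weight,
         status = spec$config$status)
  } else if (is.character(spec)) {
    if (!file.exists(spec)) {
      stop(sprintf("cohort file not readable: %s", spec), call. = FALSE)
    }
    m <- read_methyl_matrix(spec, scale = "beta")
    # propensities re-estimated from whatever missingness the file carries
    list(data = m, weights = estimate_mar_weights(m)$weight,
         status = "healthy")
  } else {
    abort_config(sprintf("cohort `%s` is neither a config nor a path", name))
  }
}

#' Run the full imputation benchmark
#'
#' Executes the plan of [plan_tasks()]: for every cohort, mechanism and
#' repetition a mask is simulated once (shared across scales and methods),
#' the matrix is converted to each requested scale, every method is run
#' behind its guards, and the result is scored on the beta scale. Individual
#' task failures are logged and recorded as absent cells; they never abort
#' the run.
#'
#' With an `outdir`, score chunks are cached per (cohort, mechanism) under
#' `outdir/cache/` keyed by a checksum of the task signature, so re-running
#' the same configuration skips completed work; the final artifacts
#' (`scores.csv`, `per_bin.csv`, `range_profile.csv`, `report.json` and
#' plain-text summary tables) are written at the end.
#'
#' @param cfg A [benchmark_config()].
#' @param quiet Suppress progress messages.
#' @return A `benchmark_result`: list with `scores` (tibble of score
#'   records), `profile` (per-beta-range aggregate), `reports` (per-stratum
#'   `comparison_report`s) and `plan`.
#' @export
run_benchmark <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "benchmark_config"))
  if (!is.null(cfg$outdir)) {
    dir.create(file.path(cfg$outdir, "cache"), recursive = TRUE,
               showWarnings = FALSE)
    if (!dir.exists(cfg$outdir)) {
      stop(sprintf("output directory not writable: %s", cfg$outdir),
           call. = FALSE)
    }
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  chunks <- list()
  for (cname in names(cfg$cohorts)) {
    coh <- resolve_cohort(cfg$cohorts[[cname]], cname)
    for (mech in cfg$mechanisms) {
      sig <- paste(cname, mech, cfg$fraction, cfg$repetitions,
                   paste(cfg$scales, collapse = "+"),
                   paste(names(cfg$methods), collapse = "+"),
                   cfg$base_seed, sep = "|")
      cache_file <- if (!is.null(cfg$outdir)) {
        file.path(cfg$outdir, "cache",
                  sprintf("chunk_%d.rds.csv", hash_seed(sig)))
      }
      if (!is.null(cache_file) && file.exists(cache_file)) {
        cached <- readr::read_csv(cache_file, show_col_types = FALSE)
        if (nrow(cached) && identical(cached$signature[1], sig)) {
          say("reusing cached scores for %s / %s", cname, mech)
          cached$signature <- NULL
          cached$per_bin <- lapply(cached$per_bin_json, function(js) {
            tibble::as_tibble(jsonlite::fromJSON(js))
          })
          cached$per_bin_json <- NULL
          chunks[[length(chunks) + 1]] <- cached
          next
        }
      }
      say("benchmarking cohort %s under %s", cname, mech)
      rows <- list()
      for (r in seq_len(cfg$repetitions)) {
        mask_seed <- hash_seed(cfg$base_seed, cname, mech, r)
        masked <- tryCatch(
          simulate_missingness(coh$data, mech, cfg$fraction,
                               weights = coh$weights, seed = mask_seed),
          error = function(e) {
            say("masking failed (%s/%s rep %d): %s", cname, mech, r,
                conditionMessage(e))
            NULL
          })
        if (is.null(masked)) next
        for (sc in cfg$scales) {
          input <- masked$matrix
          if (sc == "M") input <- convert_matrix(input, "M")
          for (mt in names(cfg$methods)) {
            spec <- cfg$methods[[mt]]
            spec$seed <- hash_seed(mask_seed, mt)
            rec <- tryCatch({
              outcome <- impute(input, spec)
              score_imputation(masked, outcome, dataset = cname, method = mt,
                               scale = sc, mechanism = mech, repetition = r)
            }, error = function(e) {
              say("task failed (%s/%s/%s/%s rep %d): %s", cname, mech, sc,
                  mt, r, conditionMessage(e))
              NULL
            })
            if (!is.null(rec)) {
              rec$status <- coh$status
              rows[[length(rows) + 1]] <- rec
            }
          }
        }
      }
      chunk <- dplyr::bind_rows(rows)
      if (!is.null(cache_file) && nrow(chunk)) {
        flat <- chunk
        flat$per_bin_json <- vapply(flat$per_bin, function(pb) {
          as.character(jsonlite::toJSON(pb, digits = NA))
        }, character(1))
        flat$per_bin <- NULL
        flat$signature <- sig
        readr::write_csv(flat, cache_file)
      }
      chunks[[length(chunks) + 1]] <- chunk
    }
  }
  scores <- dplyr::bind_rows(chunks)
  if (nrow(scores) == 0) {
    stop("no task produced a score; see the log for failures", call. = FALSE)
  }
  profile <- profile_by_range(scores)
  reports <- summarize_table(scores, alpha = cfg$alpha)
  if (inherits(reports, "comparison_report")) {
    reports <- stats::setNames(list(reports), reports$stratum)
  }
  if (!is.null(cfg$outdir)) {
    flat <- scores
    flat$per_bin <- NULL
    readr::write_csv(flat, file.path(cfg$outdir, "scores.csv"))
    readr::write_csv(
      tidyr::unnest(scores[, c("dataset", "method", "scale", "mechanism",
                               "repetition", "per_bin")], "per_bin"),
      file.path(cfg$outdir, "per_bin.csv"))
    readr::write_csv(profile, file.path(cfg$outdir, "range_profile.csv"))
    writeLines(unlist(lapply(reports, format_comparison_table)),
               file.path(cfg$outdir, "summary_tables.txt"))
    jsonlite::write_json(
      lapply(reports, function(rep) {
        list(stratum = rep$stratum, best = rep$best,
             intra = rep$intra,
             summary = rep$summary,
             alpha = rep$alpha)
      }),
      file.path(cfg$outdir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  structure(list(scores = scores, profile = profile, reports = reports,
                 plan = plan_tasks(cfg)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d score records (%d cohorts, %d mechanisms, %d methods)\n",
              nrow(x$scores), length(unique(x$scores$dataset)),
              length(unique(x$scores$mechanism)),
              length(unique(x$scores$method))))
  for (rep in x$reports) print(rep)
  invisible(x)
}

#' @export
tidy.benchmark_result <- function(x, ...) {
  out <- x$scores
  out$per_bin <- NULL
  tibble::as_tibble(out)
}

#' @export
glance.benchmark_result <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$scores, .data$method, .data$scale),
    mae = mean(.data$mae), rmse = mean(.data$rmse), n = dplyr::n(),
    .groups = "drop"
  )
}
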