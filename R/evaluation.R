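#' Mean absolute error and root mean square error
#'
#' `mae(p, t) = mean(|p - t|)` and `rmse(p, t) = sqrt(mean((p - t)^2))`. When
#' truth and predictions are beta-values both metrics live in `[0, 1]`, 0
#' meaning perfect imputation, and Jensen's inequality gives `rmse >= mae`.
#'
#' @param pred,truth Numeric vectors of equal, positive length.
#' @return A single number.
#' @examples
#' mae(c(0, 0.3), c(0.2, 0.2))  # 0.15
#' rmse(c(0, 0.3), c(0.2, 0.2)) # sqrt(0.025)
#' @export
mae <- function(pred, truth) {
  check_score_args(pred, truth)
  mean(abs(pred - truth))
}

#' @rdname mae
#' @export
rmse <- function(pred, truth) {
  check_score_args(pred, truth)
  sqrt(mean((pred - truth)^2))
}

check_score_args <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    abort_config("`pred` and `truth` must have equal length")
  }
  if (length(pred) == 0) {
    stop(structure(class = c("methylmiss_undefined_score", "error", "condition"),
                   list(message = "undefined score: no positions to evaluate",
                        call = sys.call(-1))))
  }
}

beta_bin_index <- function(beta, bins = 10) {
  pmin(floor(beta * bins) + 1L, bins) # last bin right-closed
}

beta_bin_labels <- function(bins = 10) {
  lo <- (seq_len(bins) - 1) / bins
  hi <- seq_len(bins) / bins
  sprintf("[%.1f,%.1f%s", lo, hi, c(rep(")", bins - 1), "]"))
}

#' Score an imputation against the held-out truth
#'
#' Gathers the imputed values at the masked positions, converts them to the
#' beta scale when the imputation ran on M-values (truth is always stored and
#' compared on the beta scale), drops unimputable positions (counted in
#' `n_ignored`), and computes global plus per-beta-range MAE/RMSE. Ranges are
#' `bins` equal-width intervals of the TRUE beta-value on `[0, 1]`, the last
#' one right-closed.
#'
#' @param masked A `masked_dataset`.
#' @param outcome The `imputation_outcome` produced from `masked$matrix`
#'   (possibly after scale conversion).
#' @param bins Number of equal-width beta bins (default 10).
#' @param dataset,method,scale,mechanism,repetition Optional bookkeeping
#'   columns stored in the record; `scale` and `mechanism` default to the
#'   outcome's matrix scale and the masked dataset's mechanism.
#' @return A one-row tibble (`score_record`): bookkeeping columns, `n_scored`,
#'   `n_ignored`, `mae`, `rmse`, and a `per_bin` list-column holding a tibble
#'   with `bin`, `n`, `mae`, `rmse`.
#' @export
score_imputation <- function(masked, outcome, bins = 10, dataset = NA_character_,
                             method = NULL, scale = NULL, mechanism = NULL,
                             repetition = NA_integer_) {
  imp <- outcome$imputed
  if (!identical(dim(imp), dim(masked$matrix))) {
    abort_config("outcome does not match the masked dataset's dimensions")
  }
  scale <- scale %||% methyl_scale(imp)
  mechanism <- mechanism %||% masked$mechanism$kind
  method <- method %||% outcome$method
  pos <- masked$positions
  pred <- unclass(imp)[cbind(pos$row, pos$col)]
  if (methyl_scale(imp) == "M") {
    ok <- !is.na(pred)
    pred[ok] <- m_to_beta(pred[ok])
  }
  scored <- !is.na(pred)
  n_ignored <- sum(!scored)
  if (!any(scored)) {
    stop(structure(class = c("methylmiss_undefined_score", "error", "condition"),
                   list(message = "every masked position is unimputable; score undefined",
                        call = sys.call(-1))))
  }
  p <- pred[scored]
  t <- pos$truth_beta[scored]
  bin_idx <- beta_bin_index(t, bins)
  labels <- beta_bin_labels(bins)
  bin_mae <- as.numeric(tapply(abs(p - t), bin_idx, mean))
  bin_rmse <- sqrt(as.numeric(tapply((p - t)^2, bin_idx, mean)))
  per_bin <- tibble::tibble(bin = labels[sort(unique(bin_idx))],
                            n = as.integer(table(bin_idx)),
                            mae = bin_mae, rmse = bin_rmse)
  out <- tibble::tibble(
    dataset = dataset, method = method, scale = scale, mechanism = mechanism,
    repetition = repetition, n_scored = sum(scored),
    n_ignored = as.integer(n_ignored),
    mae = mae(p, t), rmse = rmse(p, t), per_bin = list(per_bin)
  )
  class(out) <- c("score_record", class(out))
  out
}

#' Aggregate per-beta-range error profiles over score records
#'
#' Per (method, scale, mechanism, bin): MAE/RMSE averaged over records with
#' weights equal to the per-record bin counts, i.e. the pooled per-position
#' mean absolute error and pooled root mean square error.
#'
#' @param records A tibble of score records (rows from [score_imputation()]).
#' @return A tibble with `method`, `scale`, `mechanism`, `bin`, `n`, `mae`,
#'   `rmse`.
#' @export
profile_by_range <- function(records) {
  if (nrow(records) == 0) abort_config("no records to aggregate")
  bins <- tidyr::unnest(
    records[, c("method", "scale", "mechanism", "per_bin")],
    "per_bin"
  )
  labs <- unique(bins$bin)
  width <- vapply(strsplit(gsub("[][)]", "", labs), ","),
                  function(x) diff(as.numeric(x)), numeric(1))
  if (length(unique(round(width, 10))) > 1) {
    abort_config("records do not share bin edges")
  }
  out <- dplyr::summarise(
    dplyr::group_by(bins, .data$method, .data$scale, .data$mechanism, .data$bin),
    mae = sum(.data$mae * .data$n) / sum(.data$n),
    rmse = sqrt(sum(.data$rmse^2 * .data$n) / sum(.data$n)),
    n = sum(.data$n),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$method, .data$scale, .data$mechanism, .data$bin)
}
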