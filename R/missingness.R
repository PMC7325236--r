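#' Number of entries to mask for a given missing fraction
#'
#' The masked count is `round(fraction * n_samples * n_cpgs)` (half away from
#' zero), counting every matrix entry — observed or already missing — as part
#' of the "size" of the dataset. Masking itself only ever draws from currently
#' observed entries; an error is raised when the target exceeds their number.
#'
#' @param x A `methyl_matrix`.
#' @param fraction Missing fraction in (0, 1); 0.03 is the benchmark default.
#' @return Integer target count.
#' @examples
#' x <- methyl_matrix(matrix(runif(1000), 10, 100), scale = "beta")
#' target_count(x, 0.03) # 30
#' @export
target_count <- function(x, fraction) {
  if (fraction <= 0 || fraction >= 1) {
    abort_config("`fraction` must lie in (0, 1)")
  }
  n <- floor(fraction * length(x) + 0.5)
  if (n > sum(!is.na(x))) {
    abort_infeasible("target count exceeds the number of observed entries")
  }
  as.integer(n)
}

new_masked_dataset <- function(x, idx, mechanism) {
  v <- unclass(x)
  scl <- methyl_scale(x)
  attr(v, "scale") <- NULL
  truth <- v[idx]
  rows <- ((idx - 1) %% nrow(v)) + 1L
  cols <- ((idx - 1) %/% nrow(v)) + 1L
  v[idx] <- NA_real_
  structure(list(
    matrix = methyl_matrix(v, scale = scl),
    positions = tibble::tibble(
      row = rows, col = cols,
      sample_id = rownames(v)[rows], cpg_id = colnames(v)[cols],
      truth_beta = truth
    ),
    mechanism = mechanism
  ), class = "masked_dataset")
}

#' @export
print.masked_dataset <- function(x, ...) {
  cat(sprintf("<masked_dataset> %s: %d simulated missing entries in a %d x %d matrix\n",
              x$mechanism$kind, nrow(x$positions), nrow(x$matrix),
              ncol(x$matrix)))
  invisible(x)
}

#' Restore the held-out truth into a masked dataset
#'
#' @param masked A `masked_dataset`.
#' @return The original `methyl_matrix`, bit-identical to the pre-masking one.
#' @export
restore_truth <- function(masked) {
  v <- unclass(masked$matrix)
  scl <- methyl_scale(masked$matrix)
  attr(v, "scale") <- NULL
  v[cbind(masked$positions$row, masked$positions$col)] <-
    masked$positions$truth_beta
  methyl_matrix(v, scale = scl)
}

check_maskable <- function(x, n_target) {
  if (n_target < 1) {
    abort_infeasible("target count rounds to zero entries; nothing to mask")
  }
}

check_beta_scale <- function(x) {
  if (methyl_scale(x) != "beta") {
    abort_config("masking operates on the beta scale (truth is stored as beta)")
  }
}

#' Simulate missing-completely-at-random values
#'
#' Uniformly samples `target_count(x, fraction)` positions without replacement
#' from the currently observed entries and sets them missing, recording the
#' held-out truth. The beta-value distribution of MCAR-masked entries
#' coincides with the overall distribution.
#'
#' @param x A beta-scale `methyl_matrix` (truth is stored on the beta scale).
#' @param fraction Missing fraction (default 0.03).
#' @param seed Integer seed; identical seeds give identical positions.
#' @return A `masked_dataset`.
#' @export
simulate_mcar <- function(x, fraction = 0.03, seed = 1L) {
  check_beta_scale(x)
  n_target <- target_count(x, fraction)
  check_maskable(x, n_target)
  observed <- which(!is.na(x))
  idx <- with_seed(seed, observed[sample.int(length(observed), n_target)])
  new_masked_dataset(x, idx, list(kind = "MCAR", fraction = fraction,
                                  seed = seed))
}

#' Estimate MAR propensity weights from an observed missingness mask
#'
#' CpG-level missingness propensities estimated from observed frequencies:
#' `weight_j` is proportional to the missing count in CpG `j` plus a
#' pseudocount, normalised to sum 1.
#'
#' @param mask Logical matrix (`TRUE` = missing) or a `methyl_matrix` whose
#'   `NA` pattern is used.
#' @param pseudocount Added to every CpG's missing count (default 0.5).
#' @return Tibble with `cpg_id` and `weight` columns summing to 1.
#' @export
estimate_mar_weights <- function(mask, pseudocount = 0.5) {
  if (inherits(mask, "methyl_matrix")) mask <- is.na(unclass(mask))
  stopifnot(is.matrix(mask), is.logical(mask))
  counts <- colSums(mask) + pseudocount
  tibble::tibble(
    cpg_id = colnames(mask) %||% sprintf("cg%05d", seq_len(ncol(mask))),
    weight = counts / sum(counts)
  )
}

#' Simulate missing-at-random values with CpG-level propensities
#'
#' Samples positions without replacement from the observed entries with
#' probability proportional to the weight of each position's CpG (uniform
#' across samples within a CpG — the missingness depends on the CpG identity,
#' never on the unobserved value). Implemented with exponential-key weighted
#' sampling, exactly equivalent in distribution to sequential weighted
#' sampling without replacement.
#'
#' @inheritParams simulate_mcar
#' @param weights Per-CpG weights: a numeric vector, or a tibble with a
#'   `weight` column (as returned by [estimate_mar_weights()] or carried by a
#'   `methyl_cohort`).
#' @return A `masked_dataset`.
#' @export
simulate_mar <- function(x, fraction = 0.03, weights, seed = 1L) {
  if (is.data.frame(weights)) weights <- weights$weight
  if (length(weights) != ncol(x)) abort_config("one weight per CpG required")
  if (any(weights < 0)) abort_config("weights must be nonnegative")
  if (sum(weights) <= 0) abort_config("weights must not be all zero")
  check_beta_scale(x)
  n_target <- target_count(x, fraction)
  check_maskable(x, n_target)
  observed <- which(!is.na(x))
  w_entry <- weights[((observed - 1) %/% nrow(x)) + 1L]
  eligible <- observed[w_entry > 0]
  w_pos <- w_entry[w_entry > 0]
  if (n_target > length(eligible)) {
    abort_infeasible("target count exceeds the observed entries with positive weight")
  }
  idx <- with_seed(seed, {
    keys <- stats::rexp(length(eligible)) / w_pos
    eligible[order(keys)[seq_len(n_target)]]
  })
  new_masked_dataset(x, idx, list(kind = "MAR", fraction = fraction,
                                  seed = seed))
}

#' Simulate missing-not-at-random values tied to a beta-value range
#'
#' Sequential draws without replacement: each draw comes from the pool of
#' observed entries whose beta-value lies inside `beta_range` with probability
#' `in_range_prob`, and from the complementary pool otherwise. When a pool
#' empties, every remaining draw is redirected to the other pool and counted
#' in the `n_redirected` warning counter, keeping the masked count exact.
#'
#' The three canonical ranges are `[0, 0.2]` (low), `[0.4, 0.6]` (mid) and
#' `[0.8, 1]` (high), each with 70% in-range probability.
#'
#' @inheritParams simulate_mcar
#' @param beta_range Closed interval `c(lo, hi)`.
#' @param in_range_prob Per-draw probability of sampling inside the range.
#' @return A `masked_dataset` whose `mechanism` records `n_redirected`.
#' @export
simulate_mnar <- function(x, fraction = 0.03, beta_range = c(0, 0.2),
                          in_range_prob = 0.70, seed = 1L) {
  if (length(beta_range) != 2 || beta_range[1] > beta_range[2]) {
    abort_config("`beta_range` must be a closed interval c(lo, hi)")
  }
  if (in_range_prob < 0 || in_range_prob > 1) {
    abort_config("`in_range_prob` must lie in [0, 1]")
  }
  check_beta_scale(x)
  n_target <- target_count(x, fraction)
  check_maskable(x, n_target)
  observed <- which(!is.na(x))
  vals <- unclass(x)[observed]
  inside <- vals >= beta_range[1] & vals <= beta_range[2]
  pool_in <- observed[inside]
  pool_out <- observed[!inside]
  if (n_target > length(pool_in) + length(pool_out)) {
    abort_infeasible("both pools exhausted before reaching the target count")
  }
  with_seed(seed, {
    flags <- stats::runif(n_target) < in_range_prob
    want_in <- cumsum(flags)
    want_out <- cumsum(!flags)
    n_redirected <- 0L
    if (want_in[n_target] <= length(pool_in) &&
        want_out[n_target] <= length(pool_out)) {
      take_in <- want_in[n_target]
    } else if (want_in[n_target] > length(pool_in)) {
      # in-range pool empties first: every draw after the one that used its
      # last element is redirected out-of-range
      t_exhaust <- if (length(pool_in) == 0) 0L else
        which(want_in == length(pool_in))[1]
      take_in <- length(pool_in)
      n_redirected <- n_target - t_exhaust
    } else {
      t_exhaust <- if (length(pool_out) == 0) 0L else
        which(want_out == length(pool_out))[1]
      take_in <- n_target - length(pool_out)
      n_redirected <- n_target - t_exhaust
    }
    take_out <- n_target - take_in
    idx <- c(
      if (take_in > 0) pool_in[sample.int(length(pool_in), take_in)],
      if (take_out > 0) pool_out[sample.int(length(pool_out), take_out)]
    )
    new_masked_dataset(x, idx, list(
      kind = sprintf("MNAR[%g,%g]", beta_range[1], beta_range[2]),
      fraction = fraction, beta_range = beta_range,
      in_range_prob = in_range_prob, n_redirected = as.integer(n_redirected),
      seed = seed
    ))
  })
}

#' Dispatch a missingness mechanism by name
#'
#' @param x A beta-scale `methyl_matrix`.
#' @param mechanism One of `"MCAR"`, `"MAR"`, `"MNAR_LOW"`, `"MNAR_MID"`,
#'   `"MNAR_HIGH"`.
#' @param fraction Missing fraction.
#' @param weights MAR propensity weights (required for `"MAR"`).
#' @param seed Integer seed.
#' @return A `masked_dataset`.
#' @export
simulate_missingness <- function(x, mechanism = c("MCAR", "MAR", "MNAR_LOW",
                                                  "MNAR_MID", "MNAR_HIGH"),
                                 fraction = 0.03, weights = NULL, seed = 1L) {
  mechanism <- match.arg(mechanism)
  out <- switch(mechanism,
    MCAR = simulate_mcar(x, fraction, seed),
    MAR = {
      if (is.null(weights)) abort_config("MAR requires propensity `weights`")
      simulate_mar(x, fraction, weights, seed)
    },
    MNAR_LOW = simulate_mnar(x, fraction, c(0, 0.2), 0.70, seed),
    MNAR_MID = simulate_mnar(x, fraction, c(0.4, 0.6), 0.70, seed),
    MNAR_HIGH = simulate_mnar(x, fraction, c(0.8, 1), 0.70, seed)
  )
  out$mechanism$kind <- mechanism
  out
}

#' Serialize / load a masked dataset
#'
#' Writes the masked matrix in the TSV dialect of [write_methyl_matrix()] plus
#' a positions CSV (`sample_id`, `cpg_id`, `truth_beta`, `mechanism`, `seed`).
#'
#' @param masked A `masked_dataset`.
#' @param prefix Path prefix; files `<prefix>_matrix.tsv` and
#'   `<prefix>_positions.csv` are created.
#' @return `write_masked_dataset()`: the prefix, invisibly;
#'   `read_masked_dataset()`: a `masked_dataset`.
#' @export
write_masked_dataset <- function(masked, prefix) {
  write_methyl_matrix(masked$matrix, paste0(prefix, "_matrix.tsv"),
                      header = sprintf("mechanism: %s", masked$mechanism$kind))
  pos <- dplyr::mutate(masked$positions,
                       mechanism = masked$mechanism$kind,
                       seed = masked$mechanism$seed)
  readr::write_csv(pos[, c("sample_id", "cpg_id", "truth_beta", "mechanism",
                           "seed")],
                   paste0(prefix, "_positions.csv"))
  invisible(prefix)
}

#' @rdname write_masked_dataset
#' @param scale Scale tag of the stored matrix.
#' @export
read_masked_dataset <- function(prefix, scale = "beta") {
  m <- read_methyl_matrix(paste0(prefix, "_matrix.tsv"), scale = scale)
  pos <- readr::read_csv(paste0(prefix, "_positions.csv"),
                         show_col_types = FALSE)
  rows <- match(pos$sample_id, rownames(m))
  cols <- match(pos$cpg_id, colnames(m))
  structure(list(
    matrix = m,
    positions = tibble::tibble(row = rows, col = cols,
                               sample_id = pos$sample_id, cpg_id = pos$cpg_id,
                               truth_beta = pos$truth_beta),
    mechanism = list(kind = pos$mechanism[1], seed = pos$seed[1])
  ), class = "masked_dataset")
}
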