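#' Configuration for a synthetic methylation cohort
#'
#' Describes a cohort generated by [generate_cohort()]. Each CpG belongs to an
#' unmethylated / intermediate / methylated class; its per-sample mean is a
#' logit-scale perturbation of the class mean through a low-rank sample-factor
#' model (the inter-sample correlation regression-based imputers exploit), and
#' observed beta-values are Beta-distributed around that mean with a single
#' concentration parameter `kappa`. Beta noise makes the standard deviation of
#' beta-values compressed near 0 and 1 and maximal mid-range, the
#' heteroscedasticity characteristic of methylation arrays.
#'
#' A fraction `high_missing_frac` of CpGs is designated high missingness
#' propensity: their class is re-drawn towards the intermediate class (so
#' their beta distribution is mid-range shifted) and they carry
#' `propensity_ratio` times the baseline missingness weight.
#'
#' @param n_samples,n_cpgs Cohort dimensions.
#' @param class_props Probabilities of the unmethylated / mid / methylated CpG
#'   classes; must sum to 1.
#' @param class_means Class mean beta-values, strictly inside (0, 1).
#' @param kappa Beta concentration; larger = less dispersion. Default 60
#'   (healthy); `status = "disease"` lowers it to 15, emulating the higher
#'   methylation heterogeneity of disease tissue.
#' @param latent_rank Number of sample factors inducing inter-sample
#'   correlation (0 = independent samples).
#' @param loading_sd Standard deviation of factor loadings on the logit scale.
#' @param mu_jitter_sd Logit-scale jitter of per-CpG baseline means around the
#'   class mean.
#' @param high_missing_frac Fraction of CpGs with elevated missingness
#'   propensity (default 0.11).
#' @param high_missing_mid_prob Probability that a high-propensity CpG is
#'   reassigned to the mid-range subpopulation.
#' @param high_missing_center,high_missing_spread Beta-scale center and
#'   logit-scale spread of the reassigned high-propensity CpGs; the defaults
#'   concentrate their beta distribution in the 0.4-0.8 interval, the range
#'   frequently-missing CpGs occupy on real arrays.
#' @param propensity_ratio Missingness weight of high- relative to
#'   normal-propensity CpGs.
#' @param status `"healthy"` or `"disease"`; only changes the default `kappa`.
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   configuration.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 50, n_cpgs = 5000,
                          class_props = c(0.40, 0.20, 0.40),
                          class_means = c(0.08, 0.50, 0.92),
                          kappa = NULL,
                          latent_rank = 3,
                          loading_sd = 0.12,
                          mu_jitter_sd = 0.5,
                          high_missing_frac = 0.11,
                          high_missing_mid_prob = 0.7,
                          high_missing_center = 0.65,
                          high_missing_spread = 0.50,
                          propensity_ratio = 30,
                          status = c("healthy", "disease"),
                          seed = 1L) {
  status <- match.arg(status)
  kappa <- kappa %||% if (status == "healthy") 60 else 15
  if (n_samples < 1 || n_cpgs < 1) {
    abort_config("`n_samples` and `n_cpgs` must be positive")
  }
  if (length(class_props) != 3 || abs(sum(class_props) - 1) > 1e-8) {
    abort_config("`class_props` must be three probabilities summing to 1")
  }
  if (any(class_means <= 0) || any(class_means >= 1)) {
    abort_config("`class_means` must lie strictly inside (0, 1)")
  }
  if (kappa <= 0) abort_config("`kappa` must be positive")
  if (latent_rank < 0) abort_config("`latent_rank` must be nonnegative")
  if (high_missing_frac < 0 || high_missing_frac > 1) {
    abort_config("`high_missing_frac` must lie in [0, 1]")
  }
  if (propensity_ratio <= 0) abort_config("`propensity_ratio` must be positive")
  structure(list(
    n_samples = as.integer(n_samples), n_cpgs = as.integer(n_cpgs),
    class_props = class_props, class_means = class_means, kappa = kappa,
    latent_rank = as.integer(latent_rank), loading_sd = loading_sd,
    mu_jitter_sd = mu_jitter_sd, high_missing_frac = high_missing_frac,
    high_missing_mid_prob = high_missing_mid_prob,
    high_missing_center = high_missing_center,
    high_missing_spread = high_missing_spread,
    propensity_ratio = propensity_ratio, status = status,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Generate a synthetic methylation cohort
#'
#' Draws a complete beta-scale `methyl_matrix` plus a per-CpG missingness
#' propensity profile according to a [cohort_config()]. The marginal beta
#' distribution is bimodal with mass near 0 and 1; high-propensity CpGs are
#' mid-range shifted; per-CpG noise is largest mid-range; samples are
#' correlated through the latent factors. Deterministic given the seed; no
#' entries are missing on return.
#'
#' @param cfg A [cohort_config()].
#' @return A `methyl_cohort`: list with elements `data` (beta-scale
#'   `methyl_matrix`), `propensity` (tibble: `cpg_id`, `weight` summing to 1,
#'   `high_propensity`, `class`), and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_samples = 10, n_cpgs = 200))
#' coh$data
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_samples
  p <- cfg$n_cpgs
  with_seed(cfg$seed, {
    classes <- sample.int(3, p, replace = TRUE, prob = cfg$class_props)
    n_high <- round(cfg$high_missing_frac * p)
    high <- rep(FALSE, p)
    mid_shift <- rep(FALSE, p)
    if (n_high > 0) {
      idx <- sample.int(p, n_high)
      high[idx] <- TRUE
      # mid-range shift of the high-propensity subpopulation
      to_mid <- stats::runif(n_high) < cfg$high_missing_mid_prob
      mid_shift[idx[to_mid]] <- TRUE
      classes[idx[to_mid]] <- 2L
      classes[idx[!to_mid]] <- sample.int(3, sum(!to_mid), replace = TRUE,
                                          prob = cfg$class_props)
    }
    mu_logit <- stats::qlogis(cfg$class_means[classes]) +
      stats::rnorm(p, 0, cfg$mu_jitter_sd)
    # mid-shifted high-propensity CpGs occupy the 0.4-0.8 band
    mu_logit[mid_shift] <- stats::rnorm(sum(mid_shift),
                                        stats::qlogis(cfg$high_missing_center),
                                        cfg$high_missing_spread)
    eta <- matrix(mu_logit, n, p, byrow = TRUE)
    if (cfg$latent_rank > 0) {
      loadings <- matrix(stats::rnorm(p * cfg$latent_rank, 0, cfg$loading_sd),
                         p, cfg$latent_rank)
      factors <- matrix(stats::rnorm(n * cfg$latent_rank), n, cfg$latent_rank)
      eta <- eta + factors %*% t(loadings)
    }
    mu <- stats::plogis(eta)
    values <- matrix(stats::rbeta(n * p, mu * cfg$kappa, (1 - mu) * cfg$kappa),
                     n, p)
    # rbeta can underflow to exactly 0/1 for extreme means; keep beta in (0,1)
    values <- pmin(pmax(values, 1e-9), 1 - 1e-9)
    w <- ifelse(high, cfg$propensity_ratio, 1)
    mm <- methyl_matrix(values, scale = "beta")
    structure(list(
      data = mm,
      propensity = tibble::tibble(
        cpg_id = colnames(mm),
        weight = w / sum(w),
        high_propensity = high,
        class = c("unmethylated", "mid", "methylated")[classes]
      ),
      config = cfg
    ), class = "methyl_cohort")
  })
}

#' @export
print.methyl_cohort <- function(x, ...) {
  cat(sprintf("<methyl_cohort> %s, %d samples x %d CpGs (kappa = %g, %d high-propensity CpGs)\n",
              x$config$status, nrow(x$data), ncol(x$data), x$config$kappa,
              sum(x$propensity$high_propensity)))
  invisible(x)
}

#' Apply baseline (real-data-like) missingness to a complete matrix
#'
#' Marks entries missing independently, with per-CpG probability proportional
#' to the propensity profile and scaled so the expected overall missing
#' fraction equals `overall_rate`. This emulates the missingness observed in
#' real array cohorts, from which MAR weights can be re-estimated with
#' [estimate_mar_weights()]. Per-CpG probabilities exceeding 1 after scaling
#' are capped with a warning.
#'
#' @param x A `methyl_matrix` (or a `methyl_cohort`, whose own profile is then
#'   the default `weights`).
#' @param weights Per-CpG propensity weights (any positive scale; normalised
#'   internally), or a propensity tibble with a `weight` column.
#' @param overall_rate Expected overall missing fraction (default 0.04, a
#'   rate representative of array cohorts with a high-missingness CpG
#'   subpopulation).
#' @param seed Integer seed.
#' @return A `methyl_matrix` with `NA`s introduced.
#' @export
apply_baseline_missingness <- function(x, weights = NULL, overall_rate = 0.04,
                                       seed = 1L) {
  if (inherits(x, "methyl_cohort")) {
    weights <- weights %||% x$propensity$weight
    x <- x$data
  }
  if (is.null(weights)) abort_config("`weights` must be supplied")
  if (is.data.frame(weights)) weights <- weights$weight
  if (overall_rate < 0 || overall_rate >= 1) {
    abort_config("`overall_rate` must lie in [0, 1)")
  }
  p <- ncol(x)
  if (length(weights) != p) abort_config("one weight per CpG required")
  if (any(weights < 0) || sum(weights) <= 0) {
    abort_config("weights must be nonnegative with positive sum")
  }
  if (overall_rate == 0) return(x)
  w <- weights / sum(weights)
  prob <- overall_rate * p * w
  if (any(prob > 1)) {
    warning(sprintf("%d per-CpG missing probabilities capped at 1; realised rate will fall below overall_rate",
                    sum(prob > 1)))
    prob <- pmin(prob, 1)
  }
  v <- unclass(x)
  scl <- methyl_scale(x)
  attr(v, "scale") <- NULL
  with_seed(seed, {
    miss <- matrix(stats::runif(length(v)), nrow(v), ncol(v)) <
      matrix(prob, nrow(v), ncol(v), byrow = TRUE)
    v[miss] <- NA_real_
  })
  methyl_matrix(v, scale = scl)
}
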