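#' Methylation level from probe intensities (beta scale)
#'
#' The beta-value is the methylated fraction of the total probe signal,
#' `max(meth, 0) / (max(meth, 0) + max(unmeth, 0) + alpha)`. Negative
#' fluorescence intensities are legal inputs (background subtraction can
#' produce them) and are clamped to zero; the offset `alpha` regularises the
#' ratio when both intensities are low.
#'
#' @param meth,unmeth Numeric vectors of methylated / unmethylated probe
#'   intensities (arbitrary units, recycled to a common length).
#' @param alpha Nonnegative offset, 100 by convention.
#' @return Beta-values in `[0, 1)`.
#' @examples
#' beta_from_intensities(300, 100) # 0.6
#' @export
beta_from_intensities <- function(meth, unmeth, alpha = 100) {
  if (any(alpha < 0)) abort_config("`alpha` must be nonnegative")
  m <- pmax(meth, 0)
  u <- pmax(unmeth, 0)
  denom <- m + u + alpha
  if (any(denom == 0)) {
    abort_config("undefined ratio: both intensities are <= 0 and alpha = 0")
  }
  m / denom
}

#' Methylation level from probe intensities (M scale)
#'
#' The M-value is the log2 ratio of the (clamped, offset) methylated to
#' unmethylated intensities, `log2((max(meth,0) + alpha) / (max(unmeth,0) +
#' alpha))`. The offset `alpha` (1 by convention) prevents large swings for
#' near-zero intensities.
#'
#' @inheritParams beta_from_intensities
#' @param alpha Positive offset, 1 by convention.
#' @return M-values (unbounded).
#' @examples
#' m_from_intensities(7, 3) # 1
#' @export
m_from_intensities <- function(meth, unmeth, alpha = 1) {
  if (any(alpha <= 0)) abort_config("`alpha` must be positive")
  log2((pmax(meth, 0) + alpha) / (pmax(unmeth, 0) + alpha))
}

#' Logit (base 2) conversions between beta- and M-values
#'
#' Ignoring the intensity offsets, the two representations are related by a
#' base-2 logit: `M = log2(beta / (1 - beta))` and `beta = 2^M / (2^M + 1)`.
#' Beta-values of exactly 0 or 1 have infinite M, so `beta_to_m()` first clips
#' its argument into `[eps, 1 - eps]`.
#'
#' @param beta Numeric vector in `[0, 1]`.
#' @param eps Small positive clipping bound (default `1e-6`).
#' @return `beta_to_m()`: finite M-values; `m_to_beta()`: beta-values in the
#'   open interval (0, 1).
#' @examples
#' beta_to_m(0.8) # 2
#' m_to_beta(2)   # 0.8
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(is.na(beta))) abort_config("beta values must be non-missing")
  if (any(beta < 0 | beta > 1)) abort_config("beta values must lie in [0, 1]")
  if (eps <= 0 || eps >= 0.5) abort_config("`eps` must lie in (0, 0.5)")
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b) - log2(1 - b)
}

#' @rdname beta_to_m
#' @param m Numeric vector of finite M-values.
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m))) abort_config("M-values must be finite")
  # overflow-safe logistic: 2^m/(2^m+1) = 1/(1+2^-m); branch on sign so the
  # exponent is always nonpositive.
  out <- numeric(length(m))
  pos <- m >= 0
  out[pos] <- 1 / (1 + 2^(-m[pos]))
  out[!pos] <- 2^(m[!pos]) / (2^(m[!pos]) + 1)
  # extreme |m| can saturate floating point to exactly 0 or 1; keep the
  # result in the open interval
  pmin(pmax(out, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}
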