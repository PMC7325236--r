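# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG state
#'
#' Sets the Mersenne-Twister seed for the duration of `expr` and restores the
#' caller's RNG state afterwards, so library code never perturbs user-level
#' randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

#' Deterministic 32-bit string hash for seed derivation
#'
#' FNV-1a over the UTF-8 bytes of the `...` components joined with "\x1f",
#' reduced modulo 2^31 - 1 (R seeds must stay below 2^31). Used to derive
#' masking and imputer seeds from a base seed plus task coordinates, so that
#' tasks sharing coordinates share randomness and all others are independent.
#'
#' @param ... Atomic components identifying the task.
#' @return A single integer in `[1, 2^31 - 1]`.
#' @keywords internal
#' @noRd
hash_seed <- function(...) {
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)),
               collapse = "\x1f")
  bytes <- utf8ToInt(key)
  # 32-bit FNV-1a on doubles, with split multiplication to stay inside the
  # exact-double range.
  prime <- 16777619
  h <- 2166136261
  for (b in bytes) {
    # xor of h (32-bit) with byte b: only the low 8 bits change
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    # (h * prime) mod 2^32 via 16-bit split
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((lo * prime) %% 4294967296 + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  as.integer(h %% 2147483646) + 1L
}

#' Moore-Penrose pseudoinverse via SVD
#' @param x Numeric matrix.
#' @param tol Relative tolerance on singular values.
#' @return The pseudoinverse of `x`.
#' @keywords internal
#' @noRd
pinv <- function(x, tol = .Machine$double.eps * max(dim(x))) {
  s <- svd(x)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) {
    return(matrix(0, ncol(x), nrow(x)))
  }
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

abort_config <- function(msg) {
  stop(structure(class = c("methylmiss_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_infeasible <- function(msg) {
  stop(structure(class = c("methylmiss_infeasible_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
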