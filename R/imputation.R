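#' Imputation method specification
#'
#' Bundles a method name with its hyperparameters. Available methods:
#'
#' * `mean` — column (CpG) mean imputation, the baseline for continuous data.
#' * `knn` — inverse-distance-weighted average over the `k` nearest CpGs,
#'   distances computed over jointly observed samples.
#' * `svd_iter` — iterative rank-`rank` truncated-SVD matrix completion.
#' * `soft_svd` — iterative SVD completion with soft-thresholded singular
#'   values, threshold `lambda_frac` times the leading singular value of the
#'   mean-initialised fill.
#' * `iter_pca` — EM-style regularised iterative PCA with `ncp` components and
#'   a noise-variance estimate from the trailing spectrum.
#' * `chained_reg` — iterate over CpGs in increasing order of missingness,
#'   regressing each on all others with a pluggable `learner` (`"linear"`
#'   minimum-norm least squares, or `"forest"` via the ranger package), with
#'   the classic stop-on-increase rule.
#' * `methylimp` — a multi-output linear model: the fully observed CpG columns
#'   predict, via Moore-Penrose pseudoinverse, the columns sharing each
#'   missingness pattern. Exploits the strong inter-sample correlation of
#'   methylation levels.
#'
#' @param method One of the seven method names.
#' @param k,fallback knn parameters: neighbourhood size and what to do when no
#'   neighbour qualifies (`"mean"`, `"zero"` — mirroring the classic tool's
#'   zero fill — or `"none"`, leaving the position unimputable).
#' @param rank Truncation rank for `svd_iter`.
#' @param lambda_frac Soft-threshold fraction for `soft_svd`, in `[0, 1)`.
#' @param ncp Number of components for `iter_pca`.
#' @param max_iter,tol Iteration cap and relative-change tolerance of the
#'   iterative methods (`chained_reg` defaults to 10 sweeps and uses the
#'   stop-on-increase rule instead of `tol`).
#' @param learner,num_trees `chained_reg` learner and forest size.
#' @param clip_beta Clip beta-scale imputations into `[0, 1]` (M-scale output
#'   is never clipped).
#' @param seed Seed for stochastic learners (forest).
#' @return An `imputer_spec`.
#' @export
imputer_spec <- function(method = c("mean", "knn", "svd_iter", "soft_svd",
                                    "iter_pca", "chained_reg", "methylimp"),
                         k = 10L, fallback = c("mean", "zero", "none"),
                         rank = 5L, lambda_frac = 0.1, ncp = 5L,
                         max_iter = NULL, tol = 1e-5,
                         learner = c("linear", "forest"), num_trees = 100L,
                         clip_beta = TRUE, seed = NULL) {
  method <- match.arg(method)
  fallback <- match.arg(fallback)
  learner <- match.arg(learner)
  max_iter <- max_iter %||% if (method == "chained_reg") 10L else 100L
  if (k < 1) abort_config("`k` must be >= 1")
  if (rank < 1) abort_config("`rank` must be >= 1")
  if (ncp < 1) abort_config("`ncp` must be >= 1")
  if (tol <= 0) abort_config("`tol` must be positive")
  if (lambda_frac < 0 || lambda_frac >= 1) {
    abort_config("`lambda_frac` must lie in [0, 1)")
  }
  structure(list(method = method, k = as.integer(k), fallback = fallback,
                 rank = as.integer(rank), lambda_frac = lambda_frac,
                 ncp = as.integer(ncp), max_iter = as.integer(max_iter),
                 tol = tol, learner = learner,
                 num_trees = as.integer(num_trees),
                 clip_beta = isTRUE(clip_beta), seed = seed),
            class = "imputer_spec")
}

#' Method-specific preprocessing guards
#'
#' Every method leaves the missing entries of completely missing CpG columns
#' unimputable (a CpG missing in all samples carries no information).
#' Additionally: `svd_iter` drops completely missing columns; `iter_pca` drops
#' zero-variance columns (constant or singly observed); `chained_reg` drops
#' single-observation columns; `methylimp` refuses matrices in which every
#' CpG has at least one missing entry ("no complete variables").
#'
#' @param x A `methyl_matrix`.
#' @param spec An [imputer_spec()] (or a method name).
#' @return List with `matrix` (the guarded `methyl_matrix`, dropped columns
#'   removed), `unimputable` (tibble of `row`, `col`, `sample_id`, `cpg_id` in
#'   the coordinates of `x`), and `dropped` (CpG identifiers removed).
#' @export
apply_method_guards <- function(x, spec) {
  if (is.character(spec)) spec <- imputer_spec(spec)
  v <- unclass(x)
  attr(v, "scale") <- NULL
  n_obs <- colSums(!is.na(v))
  drop <- n_obs == 0 # unimputable for every method
  if (spec$method == "iter_pca") {
    vars <- apply(v, 2, function(col) stats::var(col[!is.na(col)]))
    drop <- drop | n_obs < 2 | (!is.na(vars) & vars == 0)
  }
  if (spec$method == "chained_reg") {
    drop <- drop | n_obs == 1
  }
  if (spec$method == "methylimp" && !any(n_obs == nrow(v))) {
    stop(structure(class = c("methylmiss_no_complete_variables", "error",
                             "condition"),
                   list(message = "no complete variables: every CpG has at least one missing entry",
                        call = sys.call(-1))))
  }
  un <- which(is.na(v[, drop, drop = FALSE]), arr.ind = TRUE)
  drop_idx <- which(drop)
  unimputable <- tibble::tibble(
    row = as.integer(if (nrow(un)) un[, 1] else integer()),
    col = as.integer(if (nrow(un)) drop_idx[un[, 2]] else integer())
  )
  unimputable$sample_id <- rownames(v)[unimputable$row]
  unimputable$cpg_id <- colnames(v)[unimputable$col]
  list(
    matrix = methyl_matrix(v[, !drop, drop = FALSE], scale = methyl_scale(x)),
    unimputable = unimputable,
    dropped = colnames(v)[drop]
  )
}

#' Impute missing values in a methylation matrix
#'
#' Applies the method guards, runs the requested algorithm on the retained
#' columns, and reassembles a full-size matrix. Observed entries always pass
#' through unchanged; every originally missing position is either filled or
#' listed as unimputable. On the beta scale, imputed values are clipped into
#' `[0, 1]` when `spec$clip_beta` is set.
#'
#' @param x A `methyl_matrix` on either scale.
#' @param spec An [imputer_spec()] or a method name.
#' @return An `imputation_outcome`: list with `imputed` (`methyl_matrix`),
#'   `unimputable` (tibble of positions left missing), `diagnostics`
#'   (iterations, convergence flag, dropped variables, fallback counters) and
#'   `method`.
#' @examples
#' x <- methyl_matrix(matrix(c(0.2, NA, 0.4, 0.5, 0.6, 0.7), 3, 2),
#'                    scale = "beta")
#' impute(x, "mean")$imputed
#' @export
impute <- function(x, spec) {
  if (is.character(spec)) spec <- imputer_spec(spec)
  stopifnot(inherits(spec, "imputer_spec"))
  guard <- apply_method_guards(x, spec)
  sub <- unclass(guard$matrix)
  attr(sub, "scale") <- NULL
  res <- switch(spec$method,
    mean = impute_mean_work(sub),
    knn = impute_knn_work(sub, spec$k, spec$fallback),
    svd_iter = impute_svd_iter_work(sub, spec$rank, spec$tol, spec$max_iter),
    soft_svd = impute_soft_svd_work(sub, spec$lambda_frac, spec$tol,
                                    spec$max_iter),
    iter_pca = impute_iter_pca_work(sub, spec$ncp, spec$tol, spec$max_iter),
    chained_reg = impute_chained_work(sub, spec$learner, spec$max_iter,
                                      spec$num_trees, spec$seed),
    methylimp = impute_methylimp_work(sub)
  )
  out <- unclass(x)
  scl <- methyl_scale(x)
  attr(out, "scale") <- NULL
  kept <- which(!colnames(out) %in% guard$dropped)
  filled_cols <- out[, kept, drop = FALSE]
  was_missing <- is.na(filled_cols)
  filled <- res$filled
  if (scl == "beta" && spec$clip_beta) {
    filled[was_missing] <- pmin(pmax(filled[was_missing], 0), 1)
  }
  filled_cols[was_missing] <- filled[was_missing]
  out[, kept] <- filled_cols
  # positions the worker could not fill
  still <- which(is.na(filled) & was_missing, arr.ind = TRUE)
  worker_un <- tibble::tibble(
    row = as.integer(if (nrow(still)) still[, 1] else integer()),
    col = as.integer(if (nrow(still)) kept[still[, 2]] else integer())
  )
  worker_un$sample_id <- rownames(out)[worker_un$row]
  worker_un$cpg_id <- colnames(out)[worker_un$col]
  unimputable <- dplyr::bind_rows(guard$unimputable, worker_un)
  structure(list(
    imputed = methyl_matrix(out, scale = scl),
    unimputable = unimputable,
    diagnostics = c(res$diagnostics, list(dropped = guard$dropped)),
    method = spec$method
  ), class = "imputation_outcome")
}

#' @export
print.imputation_outcome <- function(x, ...) {
  cat(sprintf("<imputation_outcome> method %s: %d entries still missing, %d unimputable\n",
              x$method, sum(is.na(x$imputed)), nrow(x$unimputable)))
  invisible(x)
}

#' Convenience wrappers around [impute()]
#'
#' Each builds the corresponding [imputer_spec()] and calls [impute()]; see
#' there for the returned `imputation_outcome`.
#'
#' @param x A `methyl_matrix`.
#' @param ... Passed to [imputer_spec()].
#' @name imputers
NULL

#' @rdname imputers
#' @export
impute_mean <- function(x, ...) impute(x, imputer_spec("mean", ...))

#' @rdname imputers
#' @export
impute_knn <- function(x, ...) impute(x, imputer_spec("knn", ...))

#' @rdname imputers
#' @export
impute_svd_iter <- function(x, ...) impute(x, imputer_spec("svd_iter", ...))

#' @rdname imputers
#' @export
impute_soft_svd <- function(x, ...) impute(x, imputer_spec("soft_svd", ...))

#' @rdname imputers
#' @export
impute_iter_pca <- function(x, ...) impute(x, imputer_spec("iter_pca", ...))

#' @rdname imputers
#' @export
impute_chained_reg <- function(x, ...) impute(x, imputer_spec("chained_reg", ...))

#' @rdname imputers
#' @export
impute_methylimp <- function(x, ...) impute(x, imputer_spec("methylimp", ...))

# ---- workers (operate on plain matrices, NA = missing) ----------------------

col_means_fill <- function(m) {
  cm <- colMeans(m, na.rm = TRUE)
  miss <- is.na(m)
  m[miss] <- cm[((which(miss) - 1) %/% nrow(m)) + 1L]
  m
}

impute_mean_work <- function(m) {
  list(filled = col_means_fill(m), diagnostics = list())
}

impute_knn_work <- function(m, k, fallback) {
  miss <- is.na(m)
  if (!any(miss)) return(list(filled = m, diagnostics = list(fallbacks = 0L)))
  n <- nrow(m); p <- ncol(m)
  W <- !miss
  A <- m; A[miss] <- 0
  Wn <- W * 1
  S1 <- crossprod(A * A, Wn)       # sum over shared rows of x_j^2
  cross <- crossprod(A)            # sum over shared rows of x_j x_k
  nsh <- crossprod(Wn)             # number of shared rows
  msd <- (S1 + t(S1) - 2 * cross) / nsh
  msd[nsh == 0] <- NA
  dist <- sqrt(pmax(msd, 0))
  cm <- colMeans(m, na.rm = TRUE)
  fallbacks <- 0L
  cols <- which(colSums(miss) > 0)
  idx_all <- seq_len(p)
  for (j in cols) {
    dj <- dist[, j]
    valid <- idx_all[idx_all != j & !is.na(dj)]
    ord <- valid[order(dj[valid], valid)] # stable tie-break by CpG index
    for (i in which(miss[, j])) {
      cand <- ord[W[i, ord]]
      if (length(cand) == 0) {
        fallbacks <- fallbacks + 1L
        m[i, j] <- switch(fallback, mean = cm[j], zero = 0, none = NA_real_)
      } else {
        nb <- cand[seq_len(min(k, length(cand)))]
        w <- 1 / pmax(dj[nb], 1e-12)
        m[i, j] <- sum(w * m[i, nb]) / sum(w)
      }
    }
  }
  list(filled = m, diagnostics = list(fallbacks = fallbacks))
}

svd_like_iterate <- function(m, reconstruct, tol, max_iter) {
  miss <- is.na(m)
  if (!any(miss)) {
    return(list(filled = m, diagnostics = list(iterations = 0L,
                                               converged = TRUE)))
  }
  X <- col_means_fill(m)
  old <- X[miss]
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    newv <- reconstruct(X)[miss]
    change <- sqrt(sum((newv - old)^2)) /
      max(sqrt(sum(old^2)), .Machine$double.eps)
    X[miss] <- newv
    old <- newv
    if (change < tol) {
      converged <- TRUE
      break
    }
  }
  list(filled = X, diagnostics = list(iterations = it, converged = converged))
}

impute_svd_iter_work <- function(m, rank, tol, max_iter) {
  if (rank > min(dim(m))) {
    abort_config("`rank` must not exceed the smaller matrix dimension")
  }
  svd_like_iterate(m, function(X) {
    s <- svd(X, nu = rank, nv = rank)
    s$u %*% (s$d[seq_len(rank)] * t(s$v))
  }, tol, max_iter)
}

impute_soft_svd_work <- function(m, lambda_frac, tol, max_iter) {
  miss <- is.na(m)
  lambda <- if (any(miss)) {
    lambda_frac * svd(col_means_fill(m), nu = 0, nv = 0)$d[1]
  } else {
    0
  }
  res <- svd_like_iterate(m, function(X) {
    s <- svd(X)
    d <- pmax(s$d - lambda, 0)
    keep <- d > 0
    if (!any(keep)) return(matrix(0, nrow(X), ncol(X)))
    s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
  }, tol, max_iter)
  res$diagnostics$lambda <- lambda
  res
}

impute_iter_pca_work <- function(m, ncp, tol, max_iter) {
  if (ncp >= min(dim(m))) {
    abort_config("`ncp` must be smaller than the smaller matrix dimension")
  }
  svd_like_iterate(m, function(X) {
    mu <- colMeans(X)
    s <- svd(sweep(X, 2, mu), nu = ncp, nv = ncp)
    # noise variance from the trailing spectrum shrinks the leading values
    sigma2 <- mean(s$d[-seq_len(ncp)]^2)
    d <- pmax(s$d[seq_len(ncp)] -
                sigma2 / pmax(s$d[seq_len(ncp)], .Machine$double.eps), 0)
    sweep(s$u %*% (d * t(s$v)), 2, mu, "+")
  }, tol, max_iter)
}

# Symmetric PSD solve: Cholesky when well-conditioned, eigen-pseudoinverse
# otherwise (minimum-norm least squares in the dual).
solve_psd <- function(A, y) {
  out <- tryCatch(drop(chol2inv(chol(A)) %*% y), error = function(e) NULL)
  if (!is.null(out) && all(is.finite(out))) return(out)
  e <- eigen(A, symmetric = TRUE)
  keep <- e$values > max(e$values, 0) * length(y) * .Machine$double.eps
  if (!any(keep)) return(rep(0, length(y)))
  drop(e$vectors[, keep, drop = FALSE] %*%
         ((crossprod(e$vectors[, keep, drop = FALSE], y)) / e$values[keep]))
}

impute_chained_work <- function(m, learner, max_iter, num_trees, seed) {
  miss <- is.na(m)
  if (!any(miss)) {
    return(list(filled = m, diagnostics = list(sweeps = 0L,
                                               learner_failures = 0L)))
  }
  if (learner == "forest" && !requireNamespace("ranger", quietly = TRUE)) {
    abort_config("the forest learner requires the `ranger` package")
  }
  n <- nrow(m)
  cm <- colMeans(m, na.rm = TRUE)
  X <- col_means_fill(m)
  cols <- order(colSums(miss))
  cols <- cols[colSums(miss)[cols] > 0] # increasing missingness
  failures <- 0L
  prev_delta <- Inf
  prev_fill <- X[miss]
  X_accepted <- X
  sweeps <- 0L
  stopped_early <- FALSE
  if (learner == "linear") K <- tcrossprod(X)
  for (s in seq_len(max_iter)) {
    sweeps <- s
    for (j in cols) {
      Tr <- which(!miss[, j])
      R <- which(miss[, j])
      pred <- if (learner == "linear") {
        xj <- X[, j]
        Kj <- K - tcrossprod(xj)
        # minimum-norm least squares in the dual: predictions K[R,T] a with
        # (K[T,T] + intercept) a = y; identical to the primal pseudoinverse fit
        alpha <- solve_psd(Kj[Tr, Tr, drop = FALSE] + 1, X[Tr, j])
        drop((Kj[R, Tr, drop = FALSE] + 1) %*% alpha)
      } else {
        fit <- tryCatch({
          rf <- ranger::ranger(
            x = as.data.frame(X[Tr, -j, drop = FALSE]),
            y = X[Tr, j], num.trees = num_trees,
            seed = (seed %||% 1L) + j, num.threads = 1
          )
          stats::predict(rf,
                         data = as.data.frame(X[R, -j, drop = FALSE]),
                         num.threads = 1)$predictions
        }, error = function(e) NULL)
        fit
      }
      if (is.null(pred) || any(!is.finite(pred))) {
        failures <- failures + 1L
        pred <- rep(cm[j], length(R))
      }
      X[R, j] <- pred
      if (learner == "linear") K <- Kj + tcrossprod(X[, j])
    }
    new_fill <- X[miss]
    delta <- sum((new_fill - prev_fill)^2) / max(sum(new_fill^2),
                                                 .Machine$double.eps)
    if (delta > prev_delta) {
      # change increased: keep the previous sweep's fill (classic stopping)
      X <- X_accepted
      stopped_early <- TRUE
      break
    }
    X_accepted <- X
    prev_fill <- new_fill
    if (delta == 0) break
    prev_delta <- delta
  }
  list(filled = X,
       diagnostics = list(sweeps = sweeps, stopped_early = stopped_early,
                          learner_failures = failures))
}

impute_methylimp_work <- function(m) {
  miss <- is.na(m)
  complete <- which(colSums(miss) == 0)
  if (!any(miss)) {
    return(list(filled = m, diagnostics = list(n_complete = length(complete),
                                               n_patterns = 0L)))
  }
  n <- nrow(m)
  X <- m
  targets <- which(colSums(miss) > 0)
  keys <- vapply(targets, function(j) paste(which(miss[, j]), collapse = ","),
                 character(1))
  groups <- split(targets, keys)
  for (g in groups) {
    R <- which(miss[, g[1]])
    Tr <- setdiff(seq_len(n), R)
    if (length(Tr) == 0) next # missing in all samples: unimputable
    B <- pinv(X[Tr, complete, drop = FALSE]) %*% X[Tr, g, drop = FALSE]
    X[R, g] <- X[R, complete, drop = FALSE] %*% B
  }
  list(filled = X, diagnostics = list(n_complete = length(complete),
                                      n_patterns = length(groups)))
}
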