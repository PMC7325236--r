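#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on the paired differences `a - b`. Zero
#' differences are dropped (classical treatment); if every difference is zero
#' the test is degenerate and `p = 1` is returned with a flag. The exact null
#' distribution is used for up to 25 untied nonzero pairs, the normal
#' approximation with continuity correction otherwise — the switching built
#' into [stats::wilcox.test()], which performs the computation.
#'
#' @param a,b Numeric vectors of equal length (>= 5 pairs).
#' @return List with `p.value`, `statistic` (V, the positive-rank sum),
#'   `n_nonzero`, `degenerate` (all differences zero) and `zero_heavy` (more
#'   than half of the pairs tied at zero).
#' @examples
#' paired_wilcoxon(rnorm(20), rnorm(20))$p.value
#' @export
paired_wilcoxon <- function(a, b) {
  if (length(a) != length(b)) abort_config("`a` and `b` must be paired")
  if (length(a) < 5) abort_config("at least 5 pairs are required")
  keep <- !is.na(a) & !is.na(b) # incomplete pairs (absent cells) are dropped
  a <- a[keep]
  b <- b[keep]
  d <- a - b
  nz <- d != 0
  if (!any(nz)) {
    return(list(p.value = 1, statistic = NA_real_, n_nonzero = 0L,
                degenerate = TRUE, zero_heavy = TRUE))
  }
  n <- sum(nz)
  res <- suppressWarnings(
    stats::wilcox.test(a[nz], b[nz], paired = TRUE, exact = (n <= 25),
                       correct = TRUE, alternative = "two.sided")
  )
  list(p.value = unname(res$p.value), statistic = unname(res$statistic),
       n_nonzero = as.integer(n), degenerate = FALSE,
       zero_heavy = n < length(a) / 2)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (a thin wrapper over
#' [stats::p.adjust()] so the whole comparison machinery shares one entry
#' point).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, order-preserving and capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort_config("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Which scale wins for one method?
#'
#' Intra-method comparison: paired Wilcoxon test between the per-repetition
#' scores of the beta- and M-value runs of the same method. If the (BH-)
#' adjusted two-sided p-value falls below `alpha`, the winner is the scale
#' with the smaller mean score (scores are errors); otherwise `"none"`.
#'
#' @param beta_scores,m_scores Per-repetition average scores, paired by
#'   repetition.
#' @param alpha Significance level (default 0.05).
#' @param p_adjusted Optionally, an externally BH-adjusted p-value for this
#'   comparison (used by [summarize_table()], which adjusts across the whole
#'   method family); by default the raw p is used alone (a family of one).
#' @return `"beta"`, `"M"` or `"none"`.
#' @export
intra_method_winner <- function(beta_scores, m_scores, alpha = 0.05,
                                p_adjusted = NULL) {
  if (length(beta_scores) != length(m_scores)) {
    abort_config("score vectors must be paired by repetition")
  }
  p <- p_adjusted %||% paired_wilcoxon(beta_scores, m_scores)$p.value
  if (is.na(p) || p >= alpha) return("none")
  if (mean(beta_scores) < mean(m_scores)) "beta" else "M"
}

#' Relaxed best-performance set
#'
#' All pairwise paired Wilcoxon tests within the table family are BH-adjusted
#' together; a cell (method, scale) belongs to the best set iff no other cell
#' both beats it significantly (adjusted p < alpha) and has a smaller mean.
#' With this definition the set is never empty: the cell with the smallest
#' mean cannot be excluded.
#'
#' @param vectors Named list of per-repetition score vectors (equal lengths),
#'   one per (method, scale) cell.
#' @param alpha Significance level.
#' @return List with `best` (names of the cells never significantly beaten),
#'   `p_adjusted` (matrix of adjusted pairwise p-values) and `means`.
#' @export
best_method_set <- function(vectors, alpha = 0.05) {
  m <- length(vectors)
  if (m < 2) abort_config("at least two cells are required for comparison")
  if (length(unique(lengths(vectors))) != 1) {
    abort_config("all score vectors must have the same length")
  }
  nms <- names(vectors) %||% paste0("cell", seq_len(m))
  pairs <- utils::combn(m, 2)
  praw <- apply(pairs, 2, function(ij) {
    paired_wilcoxon(vectors[[ij[1]]], vectors[[ij[2]]])$p.value
  })
  padj <- bh_adjust(praw)
  P <- matrix(NA_real_, m, m, dimnames = list(nms, nms))
  for (q in seq_len(ncol(pairs))) {
    P[pairs[1, q], pairs[2, q]] <- padj[q]
    P[pairs[2, q], pairs[1, q]] <- padj[q]
  }
  mu <- vapply(vectors, mean, numeric(1), na.rm = TRUE)
  beaten <- vapply(seq_len(m), function(i) {
    any(P[i, ] < alpha & mu < mu[i], na.rm = TRUE)
  }, logical(1))
  list(best = nms[!beaten], p_adjusted = P, means = mu)
}

#' Summarise a benchmark table with the full testing procedure
#'
#' Reproduces the benchmark's reporting layout: per stratum (mechanism, and
#' cohort status when present) and per metric, the mean +- sd of the
#' per-repetition average scores for every (method, scale) cell; the
#' intra-method scale winners (BH-adjusted across methods); and the relaxed
#' best-method set over all cells (BH-adjusted across all pairs). Scores are
#' first averaged over datasets within each repetition, so the tests pair by
#' repetition.
#'
#' @param records Tibble of score records ([score_imputation()] rows),
#'   optionally with a `status` column.
#' @param alpha Significance level.
#' @param metrics Which metrics to report.
#' @return A `comparison_report` (or a named list of them, one per stratum,
#'   when several strata are present). Each has [generics::tidy()] /
#'   [generics::glance()] methods and a table-style print.
#' @export
summarize_table <- function(records, alpha = 0.05, metrics = c("mae", "rmse")) {
  stopifnot(all(c("method", "scale", "repetition") %in% names(records)))
  strata_keys <- intersect(c("mechanism", "status"), names(records))
  strata <- if (length(strata_keys)) {
    split(records, interaction(records[strata_keys], drop = TRUE, sep = " / "))
  } else {
    list(all = records)
  }
  reports <- lapply(names(strata), function(nm) {
    one_stratum_report(strata[[nm]], nm, alpha, metrics)
  })
  names(reports) <- names(strata)
  if (length(reports) == 1) reports[[1]] else reports
}

one_stratum_report <- function(records, stratum, alpha, metrics) {
  # per-repetition averages over datasets: the paired unit of the tests
  per_rep <- dplyr::summarise(
    dplyr::group_by(records, .data$method, .data$scale, .data$repetition),
    dplyr::across(dplyr::all_of(metrics), mean),
    .groups = "drop"
  )
  n_rep <- length(unique(per_rep$repetition))
  if (any(table(per_rep$method, per_rep$scale) > 0 &
          table(per_rep$method, per_rep$scale) < 2)) {
    abort_config("at least two repetitions per cell are required")
  }
  out <- lapply(metrics, function(metric) {
    wide <- tidyr::pivot_wider(per_rep[, c("method", "scale", "repetition",
                                           metric)],
                               names_from = "repetition",
                               values_from = dplyr::all_of(metric))
    cells <- paste(wide$method, wide$scale, sep = "/")
    vecs <- lapply(seq_len(nrow(wide)), function(i) {
      as.numeric(unlist(wide[i, -(1:2)]))
    })
    names(vecs) <- cells
    summary <- tibble::tibble(
      method = wide$method, scale = wide$scale, metric = metric,
      mean = unname(vapply(vecs, mean, numeric(1), na.rm = TRUE)),
      sd = unname(vapply(vecs, stats::sd, numeric(1), na.rm = TRUE))
    )
    # intra-method scale comparison, BH-adjusted across methods
    methods <- unique(wide$method)
    both <- methods[vapply(methods, function(mt) {
      all(c("beta", "M") %in% wide$scale[wide$method == mt])
    }, logical(1))]
    # significance tests need at least 5 paired repetitions; with fewer,
    # report summaries only and mark every cell as (trivially) best
    intra <- if (length(both) && n_rep >= 5) {
      praw <- vapply(both, function(mt) {
        paired_wilcoxon(vecs[[paste0(mt, "/beta")]],
                        vecs[[paste0(mt, "/M")]])$p.value
      }, numeric(1))
      padj <- bh_adjust(praw)
      tibble::tibble(
        method = both, metric = metric, p_adjusted = padj,
        winner = vapply(seq_along(both), function(i) {
          intra_method_winner(vecs[[paste0(both[i], "/beta")]],
                              vecs[[paste0(both[i], "/M")]],
                              alpha = alpha, p_adjusted = padj[i])
        }, character(1))
      )
    } else {
      tibble::tibble(method = character(), metric = character(),
                     p_adjusted = numeric(), winner = character())
    }
    best <- if (length(vecs) >= 2 && n_rep >= 5) best_method_set(vecs, alpha) else
      list(best = names(vecs), p_adjusted = NULL,
           means = vapply(vecs, mean, numeric(1)))
    summary$best <- cells %in% best$best
    list(summary = summary, intra = intra, best = best)
  })
  names(out) <- metrics
  structure(list(
    stratum = stratum,
    summary = dplyr::bind_rows(lapply(out, `[[`, "summary")),
    intra = dplyr::bind_rows(lapply(out, `[[`, "intra")),
    best = lapply(out, function(o) o$best$best),
    p_adjusted = lapply(out, function(o) o$best$p_adjusted),
    alpha = alpha, n_repetitions = n_rep
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  cat(format_comparison_table(x, digits = digits), sep = "\n")
  invisible(x)
}

#' Render a comparison report as a plain-text table
#'
#' One row per method, one column per (metric, scale) with `mean +- sd`;
#' a `*` marks the significantly better scale within a method, and the
#' relaxed best cells are wrapped in `**bold**` markers.
#'
#' @param x A `comparison_report`.
#' @param digits Digits for means and sds.
#' @return Character vector of lines.
#' @export
format_comparison_table <- function(x, digits = 3) {
  s <- x$summary
  metrics <- unique(s$metric)
  methods <- unique(s$method)
  scales <- unique(s$scale)
  fmt_cell <- function(mt, metric, sc) {
    row <- s[s$method == mt & s$metric == metric & s$scale == sc, ]
    if (nrow(row) == 0) return("-")
    star <- if (nrow(x$intra) &&
                any(x$intra$method == mt & x$intra$metric == metric &
                    x$intra$winner == sc)) "*" else ""
    cell <- sprintf("%.*f ±%.*f%s", digits, row$mean, digits, row$sd, star)
    if (row$best) paste0("**", cell, "**") else cell
  }
  header <- c("method",
              unlist(lapply(metrics, function(me) paste(toupper(me), scales))))
  rows <- lapply(methods, function(mt) {
    c(mt, unlist(lapply(metrics, function(me) {
      vapply(scales, function(sc) fmt_cell(mt, me, sc), character(1))
    })))
  })
  tab <- rbind(header, do.call(rbind, rows))
  widths <- apply(nchar(tab), 2, max)
  lines <- apply(tab, 1, function(r) {
    padded <- vapply(seq_along(r), function(i) {
      formatC(r[i], width = widths[i], flag = "-")
    }, character(1))
    paste(padded, collapse = "  ")
  })
  c(sprintf("Stratum: %s (alpha = %g, %d repetitions)", x$stratum, x$alpha,
            x$n_repetitions),
    lines)
}

#' @export
tidy.comparison_report <- function(x, ...) {
  s <- x$summary
  s$stratum <- x$stratum
  winners <- x$intra
  if (nrow(winners)) {
    s <- dplyr::left_join(s, winners[, c("method", "metric", "winner")],
                          by = c("method", "metric"))
    s$winner <- ifelse(is.na(s$winner), "none", s$winner)
  } else {
    s$winner <- "none"
  }
  tibble::as_tibble(s)
}

#' @export
glance.comparison_report <- function(x, ...) {
  tibble::tibble(
    stratum = x$stratum, alpha = x$alpha, n_repetitions = x$n_repetitions,
    n_methods = length(unique(x$summary$method)),
    n_best_mae = length(x$best$mae %||% character()),
    n_best_rmse = length(x$best$rmse %||% character())
  )
}
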