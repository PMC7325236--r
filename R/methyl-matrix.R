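#' Methylation matrix container
#'
#' A `methyl_matrix` is a plain numeric matrix with samples as rows and CpG
#' sites as columns, tagged with the scale its values live on: `"beta"`
#' (methylated fraction in \[0, 1\]) or `"M"` (log2 methylated/unmethylated
#' ratio, unbounded). Missing entries are `NA`. Row names are sample
#' identifiers and column names CpG identifiers; both must be unique.
#'
#' @param values Numeric matrix, rows = samples, columns = CpGs.
#' @param scale `"beta"` or `"M"`.
#' @param sample_ids,cpg_ids Optional identifier vectors; default to existing
#'   dimnames or generated `S1..Sn` / `cg00001..` labels.
#' @return A `methyl_matrix` object.
#' @examples
#' x <- methyl_matrix(matrix(c(0.5, NA, 0.8, 0.2), 2, 2), scale = "beta")
#' methyl_scale(x)
#' @export
methyl_matrix <- function(values, scale = c("beta", "M"),
                          sample_ids = NULL, cpg_ids = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_config("`values` must be a numeric matrix (samples x CpGs)")
  }
  sample_ids <- sample_ids %||% rownames(values) %||%
    paste0("S", seq_len(nrow(values)))
  cpg_ids <- cpg_ids %||% colnames(values) %||%
    sprintf("cg%05d", seq_len(ncol(values)))
  if (anyDuplicated(sample_ids) || anyDuplicated(cpg_ids)) {
    abort_config("sample and CpG identifiers must be unique")
  }
  dimnames(values) <- list(sample_ids, cpg_ids)
  obs <- values[!is.na(values)]
  if (any(!is.finite(obs))) {
    abort_config("observed entries must be finite")
  }
  if (scale == "beta" && length(obs) && (min(obs) < 0 || max(obs) > 1)) {
    abort_config("beta-scale values must lie in [0, 1]")
  }
  structure(values, scale = scale, class = c("methyl_matrix", class(values)))
}

#' @rdname methyl_matrix
#' @param x A `methyl_matrix`.
#' @export
methyl_scale <- function(x) {
  attr(x, "scale") %||% abort_config("matrix carries no scale tag")
}

#' @export
print.methyl_matrix <- function(x, ...) {
  cat(sprintf("<methyl_matrix> %d samples x %d CpGs on the %s scale, %d missing (%.2f%%)\n",
              nrow(x), ncol(x), methyl_scale(x), sum(is.na(x)),
              100 * mean(is.na(x))))
  invisible(x)
}

#' Tidy a methylation matrix into long format
#'
#' @param x A `methyl_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `cpg_id`, `value`, `missing`.
#' @export
tidy.methyl_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x), times = ncol(x)),
    cpg_id = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x)),
    missing = is.na(as.vector(unclass(x)))
  )
}

#' Convert a methylation matrix between scales
#'
#' Applies the logit (base 2) transformation elementwise to observed entries
#' only; `NA`s are preserved, so missingness is representation-invariant.
#' Converting to the current scale returns the input unchanged.
#'
#' @param x A `methyl_matrix`.
#' @param target `"beta"` or `"M"`.
#' @param eps Clipping bound applied to beta values before the logit (see
#'   [beta_to_m()]).
#' @return A `methyl_matrix` on the target scale with an identical mask.
#' @examples
#' x <- methyl_matrix(matrix(c(0.5, NA, 0.8, 0.2), 2, 2), scale = "beta")
#' convert_matrix(x, "M")
#' @export
convert_matrix <- function(x, target = c("beta", "M"), eps = 1e-6) {
  target <- match.arg(target)
  cur <- methyl_scale(x)
  if (cur == target) {
    return(x)
  }
  v <- unclass(x)
  attr(v, "scale") <- NULL
  obs <- !is.na(v)
  v[obs] <- if (target == "M") beta_to_m(v[obs], eps = eps) else m_to_beta(v[obs])
  methyl_matrix(v, scale = target)
}

#' Read / write the methylation matrix text format
#'
#' Tab-separated text: first column CpG identifiers, header row sample
#' identifiers, `na` marking missing entries (file convention: CpGs as rows).
#' Lines starting with `#` carry provenance and are skipped on read.
#'
#' @param path File path.
#' @param scale Scale tag of the stored values.
#' @param orientation `"cpgs"` (rows are CpGs, the file convention) or
#'   `"samples"` (rows are samples).
#' @param na String marking missing values.
#' @return `read_methyl_matrix()` returns a `methyl_matrix` (internally always
#'   samples x CpGs); `write_methyl_matrix()` returns `path` invisibly.
#' @export
read_methyl_matrix <- function(path, scale = c("beta", "M"),
                               orientation = c("cpgs", "samples"), na = "NA") {
  scale <- match.arg(scale)
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          na.strings = na, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (orientation == "cpgs") m <- t(m)
  methyl_matrix(m, scale = scale)
}

#' @rdname read_methyl_matrix
#' @param x A `methyl_matrix`.
#' @param header Optional character vector of provenance lines, written as
#'   `#`-prefixed comments.
#' @export
write_methyl_matrix <- function(x, path, orientation = c("cpgs", "samples"),
                                na = "NA", header = NULL) {
  orientation <- match.arg(orientation)
  m <- unclass(x)
  attr(m, "scale") <- NULL
  if (orientation == "cpgs") m <- t(m)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", header), con)
  }
  id_col <- if (orientation == "cpgs") "cpg_id" else "sample_id"
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", na = na, quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}
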