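#' Convert abundances to within-plot relative abundances
#'
#' Each plot row is divided by its total so rows sum to one; species
#' (columns) that are zero everywhere are preserved. A plot with zero total
#' abundance cannot be normalised and is an error naming the plot.
#'
#' @param m a [community_matrix] or plain plot-by-species matrix.
#' @return Matrix of the same shape and class with unit row sums.
#' @export
to_relative_abundance <- function(m) {
  tot <- rowSums(m)
  if (any(tot <= 0))
    stopf("plot(s) with zero total abundance: %s",
          paste(rownames(m)[tot <= 0], collapse = ", "))
  out <- unclass(m) / tot
  attributes(out) <- c(attributes(out),
                       attributes(m)[c("group_id", "trophic_level",
                                       "compartment", "producer")])
  class(out) <- class(m)
  out
}

new_score_set <- function(scores, varexp, total_axes, source_id) {
  structure(list(plot_ids = rownames(scores), scores = scores,
                 variance_explained = varexp, total_axes = total_axes,
                 source_id = source_id),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("score set '%s': %d plots x %d axes; variance explained %s\n",
              x$source_id, nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", ")))
  invisible(x)
}

## Shared PCA core. Columns are centered (and optionally standardised);
## site scores are projections onto the leading eigenvectors, scaled so the
## variance of axis i equals its eigenvalue. Sign convention: each axis is
## oriented so that its largest-magnitude variable loading is positive,
## which makes output reproducible across eigensolvers (congruence and the
## downstream path models are invariant to the flip in any case).
pca_core <- function(x, n_axes, source_id, scale. = FALSE) {
  if (nrow(x) < 3) stopf("'%s': need at least 3 plots for PCA", source_id)
  xc <- scale(x, center = TRUE, scale = scale.)
  sv <- svd(xc)
  ev <- sv$d^2 / (nrow(x) - 1)
  if (sum(ev) <= .Machine$double.eps * 100)
    stopf("'%s': matrix is constant across plots; PCA undefined", source_id)
  rank <- sum(sv$d > sv$d[1] * 1e-9)
  if (rank < n_axes) {
    warnf("'%s': rank %d < %d requested axes; returning %d",
          source_id, rank, n_axes, rank)
    n_axes <- rank
  }
  scores <- xc %*% sv$v[, seq_len(n_axes), drop = FALSE]
  for (j in seq_len(n_axes)) {
    ld <- sv$v[, j]
    if (ld[which.max(abs(ld))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(n_axes))
  rownames(scores) <- rownames(x)
  new_score_set(scores, varexp = ev[seq_len(n_axes)] / sum(ev),
                total_axes = rank, source_id = source_id)
}

#' PCA site scores of a community matrix
#'
#' Principal components analysis of species' relative abundances
#' (covariance PCA on the column-centered matrix, no per-species
#' standardisation), returning the per-plot site scores of the leading
#' axes. These two axes are the community-composition summary used for
#' congruence testing and path modelling.
#'
#' @param m plot-by-species relative-abundance matrix (see
#'   [to_relative_abundance()]); any plot-by-variable matrix is accepted.
#' @param n_axes number of axes to keep (default 2).
#' @param transform `"none"` (default) or `"hellinger"` (square-root of
#'   relative abundances before centering).
#' @return A `score_set`: plot ids, an `n_plots x n_axes` score matrix
#'   whose column variances equal the eigenvalues, and the fraction of
#'   total variance explained per axis.
#' @export
pca_site_scores <- function(m, n_axes = 2, transform = c("none", "hellinger")) {
  transform <- match.arg(transform)
  x <- unclass(m)
  if (transform == "hellinger") x <- sqrt(x)
  id <- attr(m, "group_id")
  pca_core(x, n_axes, source_id = if (is.null(id)) "community" else id)
}

#' PCA scores of an environment table
#'
#' Variables are standardised to zero mean and unit variance before the
#' analysis (correlation PCA), since environmental and spatial parameters
#' are on incommensurate scales. Zero-variance variables are dropped with a
#' warning.
#'
#' @param env plot-by-variable numeric matrix.
#' @param n_axes number of axes to keep (default 2).
#' @return A `score_set` with `source_id = "env"`.
#' @export
environment_scores <- function(env, n_axes = 2) {
  env <- as.matrix(env)
  v <- apply(env, 2, stats::var)
  if (any(v <= .Machine$double.eps * 100)) {
    warnf("dropping zero-variance environment variable(s): %s",
          paste(colnames(env)[v <= .Machine$double.eps * 100], collapse = ", "))
    env <- env[, v > .Machine$double.eps * 100, drop = FALSE]
  }
  pca_core(env, min(n_axes, ncol(env)), source_id = "env", scale. = TRUE)
}
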