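#' Per-plot species richness
#'
#' Number of species with abundance greater than zero in each plot.
#'
#' @param m a [community_matrix] (or plot-by-species matrix).
#' @return Named integer vector over plots; all-zero plots count 0 and are
#'   reported in the `empty_plots` attribute.
#' @export
richness <- function(m) {
  out <- as.integer(rowSums(unclass(m) > 0))
  names(out) <- rownames(m)
  attr(out, "empty_plots") <- rownames(m)[out == 0]
  out
}

#' Per-plot Shannon diversity
#'
#' `H = -sum p_i * ln(p_i)` over species present in the plot, with `p_i`
#' the within-plot relative abundance (natural log). Bounded by
#' `ln(richness)`; a plot with zero total abundance has undefined diversity
#' and is returned as `NA` with a flag.
#'
#' @inheritParams richness
#' @return Named numeric vector over plots.
#' @export
shannon <- function(m) {
  x <- unclass(m)
  tot <- rowSums(x)
  out <- rep(NA_real_, nrow(x))
  names(out) <- rownames(x)
  ok <- tot > 0
  for (i in which(ok)) {
    p <- x[i, ][x[i, ] > 0] / tot[i]
    out[i] <- -sum(p * log(p))
  }
  if (any(!ok))
    warnf("Shannon diversity undefined for empty plot(s): %s",
          paste(rownames(x)[!ok], collapse = ", "))
  attr(out, "empty_plots") <- rownames(x)[!ok]
  out
}

#' Diversity table across trophic groups
#'
#' @param matrices named list of [community_matrix] objects over aligned
#'   plots.
#' @return Object of class `diversity_table`: `plot_ids`, and plot-by-group
#'   matrices `richness` and `shannon`.
#' @export
diversity_table <- function(matrices) {
  plots <- rownames(matrices[[1]])
  for (m in matrices)
    if (!identical(rownames(m), plots))
      stopf("community matrices are not plot-aligned; see align_plots()")
  rich <- vapply(matrices, richness, integer(length(plots)))
  shan <- vapply(matrices, function(m) suppressWarnings(shannon(m)),
                 numeric(length(plots)))
  rownames(rich) <- rownames(shan) <- plots
  structure(list(plot_ids = plots, richness = rich, shannon = shan),
            class = "diversity_table")
}

#' Bottom-up vs top-down comparison on diversity metrics
#'
#' Runs the same search machinery as [compare_directions()] with one
#' variable per group (standardised richness or Shannon diversity) instead
#' of two composition axes, starting from the less conservative initial
#' model containing every cross-level path (oriented by the regime), every
#' within-level covariance, and every environment link; the model is then
#' expanded via modification indices and pruned by stepwise AIC.
#'
#' @param table a [diversity_table].
#' @param env_scores environment `score_set`.
#' @param structure a [trophic_structure] covering the table's groups.
#' @param metric `"richness"` or `"shannon"`.
#' @inheritParams expand_via_mi
#' @return A `direction_comparison` (see [compare_directions()]).
#' @export
diversity_web <- function(table, env_scores, structure,
                          metric = c("richness", "shannon"),
                          alpha_global = 0.05, mi_threshold = 3.84,
                          max_steps = 30) {
  metric <- match.arg(metric)
  vals <- table[[metric]]
  groups <- intersect(colnames(vals), names(structure$levels))
  if (length(groups) < 2) stopf("need at least 2 groups with declared levels")
  data <- as.data.frame(vals[, groups, drop = FALSE])
  for (j in seq_len(ncol(env_scores$scores)))
    data[[paste0("env.PC", j)]] <- env_scores$scores[table$plot_ids, j]
  lev <- structure$levels[groups]
  branch <- function(regime) {
    st <- set_regime(structure, regime)
    paths <- list(); covs <- list(list("env.PC1", "env.PC2"))
    for (a in groups) for (b in groups) {
      if (a >= b) next
      if (lev[a] == lev[b]) covs[[length(covs) + 1L]] <- c(a, b)
      else {
        lower_first <- lev[a] < lev[b]
        if (regime == "top_down") lower_first <- !lower_first
        paths[[length(paths) + 1L]] <- if (lower_first) c(a, b) else c(b, a)
      }
    }
    for (g in groups) for (e in c("env.PC1", "env.PC2"))
      paths[[length(paths) + 1L]] <- c(e, g)
    m0 <- websem_model(c(groups, "env.PC1", "env.PC2"),
                       paths = do.call(rbind, paths),
                       covariances = do.call(rbind, covs))
    run_search(m0, data, st, alpha_global, mi_threshold, max_steps)
  }
  finish_comparison(branch, structure)
}
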