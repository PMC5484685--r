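## Symmetric Procrustes congruence between ordination configurations and
## its permutation (protest) test, the all-pairs screen, multiple-testing
## adjustment and redundancy-based group screening.

as_score_matrix <- function(x) {
  if (inherits(x, "score_set")) x$scores else as.matrix(x)
}

## Center and scale a configuration to unit total sum of squares.
proc_prepare <- function(x, label) {
  x <- scale(x, center = TRUE, scale = FALSE)
  ss <- sum(x^2)
  if (ss <= .Machine$double.eps * 100)
    stopf("configuration '%s' has zero variance; Procrustes undefined", label)
  x / sqrt(ss)
}

#' Symmetric Procrustes goodness of fit
#'
#' Both configurations are column-centered and scaled to unit total sum of
#' squares; the rotation (reflections permitted) minimising the residual
#' sum of squares is obtained from the singular value decomposition of the
#' cross-product. The statistic is `m2 = 1 - (sum of singular values)^2`,
#' the minimised residual, and `t = sqrt(1 - m2)` is the Procrustes
#' correlation. The treatment is symmetric: swapping the arguments gives
#' the same value, and the statistic is invariant to translation, rotation,
#' reflection and uniform scaling of either configuration.
#'
#' @param x,y `n x k` score matrices (or `score_set` objects) over the same
#'   plots in the same order, `n >= 3`.
#' @return List with elements `m_squared` and `t_statistic`.
#' @export
procrustes_m2 <- function(x, y) {
  xs <- as_score_matrix(x); ys <- as_score_matrix(y)
  if (nrow(xs) != nrow(ys))
    stopf("configurations have %d and %d rows; plots must match", nrow(xs), nrow(ys))
  if (!is.null(rownames(xs)) && !is.null(rownames(ys)) &&
      !identical(rownames(xs), rownames(ys)))
    stopf("plot identifiers of the two configurations differ or are reordered")
  if (nrow(xs) < 3) stopf("need at least 3 plots")
  xs <- proc_prepare(xs, "x"); ys <- proc_prepare(ys, "y")
  d <- svd(crossprod(xs, ys))$d
  m2 <- max(0, min(1, 1 - sum(d)^2))
  list(m_squared = m2, t_statistic = sqrt(1 - m2))
}

#' Procrustes permutation (protest) test
#'
#' Significance of the Procrustes correlation is assessed by permuting the
#' rows of `y` uniformly at random and recomputing `t`; the p-value uses
#' the add-one rule, with ties counted as exceedances:
#' `p = (#\{t_perm >= t_obs\} + 1) / (n_permutations + 1)`.
#'
#' @inheritParams procrustes_m2
#' @param n_permutations number of row permutations (default 999).
#' @param seed integer seed for the permutation stream; the caller's RNG
#'   state is untouched.
#' @return A one-row data frame of class `congruence_record` with columns
#'   `source_a`, `source_b`, `m_squared`, `t_statistic`, `p_perm`,
#'   `n_permutations`, `p_adjusted` (NA until [adjust_pvalues()]),
#'   `significant`.
#' @export
protest <- function(x, y, n_permutations = 999, seed = 1) {
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  a <- if (inherits(x, "score_set")) x$source_id else "x"
  b <- if (inherits(y, "score_set")) y$source_id else "y"
  xs <- as_score_matrix(x); ys <- as_score_matrix(y)
  obs <- procrustes_m2(xs, ys)
  n <- nrow(xs)
  xp <- proc_prepare(xs, "x"); yp <- proc_prepare(ys, "y")
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_permutations)) {
      perm <- yp[sample.int(n), , drop = FALSE]
      ## permuted config must be re-centered (permutation preserves the
      ## column means, so centering/scale are unchanged; rotation only)
      tperm <- sum(svd(crossprod(xp, perm))$d)
      if (tperm >= obs$t_statistic - 1e-12) cnt <- cnt + 1L
    }
    cnt
  })
  p <- (exceed + 1) / (n_permutations + 1)
  structure(data.frame(source_a = a, source_b = b,
                       m_squared = obs$m_squared,
                       t_statistic = obs$t_statistic,
                       p_perm = p, n_permutations = n_permutations,
                       p_adjusted = NA_real_,
                       significant = NA,
                       stringsAsFactors = FALSE),
            class = c("congruence_record", "data.frame"))
}

#' All-pairs Procrustes congruence screen
#'
#' Runs [protest()] for every unordered pair of score sets (`choose(G, 2)`
#' records for `G` groups). Each pair draws its permutations from an
#' independent substream derived from the master seed and the canonical
#' (sorted) pair label, so results do not depend on the order score sets
#' are supplied in.
#'
#' @param scoresets list of `score_set` objects over aligned plots.
#' @param n_permutations permutations per pair (default 999).
#' @param seed master integer seed.
#' @return Data frame of class `congruence_table`, one row per pair, sorted
#'   by canonical pair key.
#' @export
pairwise_congruence <- function(scoresets, n_permutations = 999, seed = 1) {
  if (length(scoresets) < 2) stopf("need at least 2 score sets")
  ids <- vapply(scoresets, function(s) s$source_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate score-set ids")
  names(scoresets) <- ids
  pairs <- utils::combn(sort(ids), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    rec <- protest(scoresets[[a]], scoresets[[b]],
                   n_permutations = n_permutations,
                   seed = seed_for_label(seed, paste(a, b, sep = "|")))
    rec$source_a <- a; rec$source_b <- b
    rec
  })
  out <- do.call(rbind, rows)
  class(out) <- c("congruence_table", "data.frame")
  rownames(out) <- NULL
  out
}

#' Adjust congruence p-values for multiple testing
#'
#' Applies the Benjamini-Hochberg step-up adjustment and reports, alongside,
#' the expected number of false discoveries among the raw-significant tests
#' (`m * alpha`, attached as attribute `expected_false_discoveries`).
#'
#' @param records a `congruence_table` (or any data frame with `p_perm`).
#' @param method adjustment method passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @param alpha significance level for the `significant` flag (on the
#'   adjusted p) and the expected-false-discovery count.
#' @return `records` with `p_adjusted` and `significant` filled in.
#' @export
adjust_pvalues <- function(records, method = "BH", alpha = 0.05) {
  if (nrow(records) == 0) {
    attr(records, "expected_false_discoveries") <- 0
    return(records)
  }
  records$p_adjusted <- stats::p.adjust(records$p_perm, method = method)
  records$significant <- records$p_adjusted < alpha
  attr(records, "expected_false_discoveries") <- nrow(records) * alpha
  records
}

#' Screen candidate groups for congruence and redundancy
#'
#' Handles redundant taxon groupings such as highly correlated bacterial
#' phyla: among a designated candidate set (e.g. bacterial groups), a candidate
#' with no significant congruence (`p_perm < alpha_keep`) against any
#' non-candidate group is excluded outright; candidates that are mutually
#' redundant (linked by Procrustes `t > t_redundancy` at
#' `p_perm < alpha_redundancy`) are clustered (graph components of the
#' redundancy relation) and a single representative per cluster is
#' retained — the member with the highest mean `t` against the
#' non-candidates, ties broken lexicographically.
#'
#' @param records `congruence_table` covering all pairs among the groups.
#' @param candidates character vector of candidate group ids; all other
#'   groups in `records` are retained unconditionally.
#' @param t_redundancy,alpha_redundancy redundancy-link thresholds
#'   (defaults 0.8 and 0.001).
#' @param alpha_keep significance needed against at least one non-candidate
#'   to stay in the analysis (default 0.05).
#' @return List with `kept` (character vector of retained group ids) and
#'   `report` (data frame: candidate, status, cluster, representative).
#' @export
screen_groups <- function(records, candidates,
                          t_redundancy = 0.8, alpha_redundancy = 0.001,
                          alpha_keep = 0.05) {
  groups <- sort(unique(c(records$source_a, records$source_b)))
  candidates <- intersect(candidates, groups)
  others <- setdiff(groups, candidates)
  pair_rows <- function(g1, g2)
    records[(records$source_a == g1 & records$source_b == g2) |
            (records$source_a == g2 & records$source_b == g1), , drop = FALSE]
  ## exclusion: no significant link to any non-candidate
  status <- stats::setNames(rep("kept", length(candidates)), candidates)
  mean_t <- stats::setNames(numeric(length(candidates)), candidates)
  for (g in candidates) {
    rr <- do.call(rbind, lapply(others, pair_rows, g2 = g))
    if (is.null(rr) || nrow(rr) == 0 || all(rr$p_perm >= alpha_keep))
      status[g] <- "excluded_no_congruence"
    mean_t[g] <- if (is.null(rr) || nrow(rr) == 0) 0 else mean(rr$t_statistic)
  }
  surv <- names(status)[status == "kept"]
  ## redundancy clusters among surviving candidates
  cluster <- stats::setNames(rep(NA_integer_, length(candidates)), candidates)
  rep_of <- stats::setNames(rep(NA_character_, length(candidates)), candidates)
  if (length(surv) > 1) {
    edges <- character(0)
    for (j in seq_len(nrow(records))) {
      a <- records$source_a[j]; b <- records$source_b[j]
      ## <= on the p threshold: with 999 permutations the smallest
      ## achievable p equals 1/1000 and counts as passing P < 0.001
      if (a %in% surv && b %in% surv &&
          records$t_statistic[j] > t_redundancy &&
          records$p_perm[j] <= alpha_redundancy)
        edges <- c(edges, a, b)
    }
    g <- igraph::make_graph(edges = edges, isolates = setdiff(surv, edges),
                            directed = FALSE)
    comp <- igraph::components(g)
    memb <- comp$membership
    for (ci in seq_len(comp$no)) {
      members <- sort(names(memb)[memb == ci])
      cluster[members] <- ci
      best <- members[order(-mean_t[members], members)][1]
      rep_of[members] <- best
      drop <- setdiff(members, best)
      status[drop] <- "merged_redundant"
    }
  } else if (length(surv) == 1) {
    cluster[surv] <- 1L; rep_of[surv] <- surv
  }
  kept <- c(others, names(status)[status == "kept"])
  list(kept = sort(kept),
       report = data.frame(candidate = candidates,
                           status = unname(status[candidates]),
                           cluster = unname(cluster[candidates]),
                           representative = unname(rep_of[candidates]),
                           mean_t_to_noncandidates = unname(mean_t[candidates]),
                           stringsAsFactors = FALSE))
}
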