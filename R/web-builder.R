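## Model-search procedure: congruence-screened initial model, modification-
## index expansion to a non-significant global solution, stepwise AIC
## pruning to the minimum adequate model, and the bottom-up vs top-down
## direction comparison.

#' Declare the trophic structure and causal regime
#'
#' @param levels named integer vector mapping each analysed group to its
#'   trophic rank (1 = producers); ranks are totally ordered within a
#'   compartment.
#' @param regime `"bottom_up"` (paths point from lower to higher rank) or
#'   `"top_down"` (reversed).
#' @return Object of class `trophic_structure`.
#' @export
trophic_structure <- function(levels, regime = c("bottom_up", "top_down")) {
  regime <- match.arg(regime)
  stopifnot(is.numeric(levels), !is.null(names(levels)))
  structure(list(levels = stats::setNames(as.integer(levels), names(levels)),
                 regime = regime),
            class = "trophic_structure")
}

set_regime <- function(structure, regime)
  trophic_structure(structure$levels, regime)

## variable -> group: env axes map to "env", "<group>.PCk" to the group,
## bare group names (diversity variables) to themselves
var_group <- function(vars, structure) {
  out <- sub("\\.PC[0-9]+$", "", vars)
  out[grepl("^env($|\\.)", vars)] <- "env"
  unknown <- setdiff(out, c("env", names(structure$levels)))
  if (length(unknown))
    stopf("variable(s) belong to no declared group: %s",
          paste(unknown, collapse = ", "))
  out
}

#' Select the most significant axis pair between two score sets
#'
#' Pearson correlations of the four axis combinations between the first two
#' axes of each set; returns the pair with the smallest two-sided p-value
#' (t test on n-2 df), ties broken by larger absolute correlation, then by
#' pair order (1,1), (1,2), (2,1), (2,2). Zero-variance axes are skipped.
#'
#' @param scores_a,scores_b `score_set` objects (or score matrices) over
#'   aligned plots.
#' @return List with `axis_a`, `axis_b`, `r`, `p`.
#' @export
axis_pair_selection <- function(scores_a, scores_b) {
  xa <- as_score_matrix(scores_a); xb <- as_score_matrix(scores_b)
  stopifnot(nrow(xa) == nrow(xb))
  n <- nrow(xa)
  best <- NULL
  for (i in seq_len(min(2, ncol(xa)))) for (j in seq_len(min(2, ncol(xb)))) {
    if (stats::sd(xa[, i]) == 0 || stats::sd(xb[, j]) == 0) next
    r <- stats::cor(xa[, i], xb[, j])
    tt <- abs(r) * sqrt((n - 2) / max(1 - r^2, 1e-15))
    p <- 2 * stats::pt(tt, n - 2, lower.tail = FALSE)
    cand <- list(axis_a = i, axis_b = j, r = r, p = p)
    if (is.null(best) || p < best$p - 1e-15 ||
        (abs(p - best$p) <= 1e-15 && abs(r) > abs(best$r) + 1e-15))
      best <- cand
  }
  if (is.null(best)) stopf("all axis pairs degenerate")
  best
}

## assemble the observed-variable data matrix from score sets (+ env)
scores_data <- function(scoresets, env_scores = NULL) {
  cols <- list()
  for (s in scoresets)
    for (j in seq_len(ncol(s$scores)))
      cols[[paste0(s$source_id, ".PC", j)]] <- s$scores[, j]
  if (!is.null(env_scores))
    for (j in seq_len(ncol(env_scores$scores)))
      cols[[paste0("env.PC", j)]] <- env_scores$scores[, j]
  as.data.frame(cols, check.names = FALSE)
}

#' Assemble the initial path model from the congruence screen
#'
#' For every group pair with a significant Procrustes permutation p-value,
#' one link is added on the most significant axis pair: a directed path
#' (oriented by the regime) if the groups sit on different trophic levels,
#' a covariance if on the same level. Environment links (env axis to group
#' axis) are selected by the same axis-pair significance procedure; the two
#' environment axes are exogenous with a free covariance.
#'
#' @param congruence a `congruence_table` covering the group pairs.
#' @param scoresets named list of group `score_set`s.
#' @param env_scores `score_set` of the environment PCA.
#' @param structure a [trophic_structure].
#' @param alpha significance threshold on the raw permutation p (default
#'   0.05).
#' @return A [websem_model] over two axes per group plus `env.PC1`,
#'   `env.PC2`.
#' @export
initial_model <- function(congruence, scoresets, env_scores, structure,
                          alpha = 0.05) {
  ids <- vapply(scoresets, function(s) s$source_id, character(1))
  names(scoresets) <- ids
  ids <- intersect(ids, names(structure$levels))
  if (!length(ids)) stopf("no score sets match the trophic structure")
  paths <- list(); covs <- list(list("env.PC1", "env.PC2"))
  linked <- character(0)
  lev <- structure$levels
  sig <- congruence[congruence$p_perm < alpha &
                      congruence$source_a %in% ids &
                      congruence$source_b %in% ids, , drop = FALSE]
  for (j in seq_len(nrow(sig))) {
    a <- sig$source_a[j]; b <- sig$source_b[j]
    ap <- axis_pair_selection(scoresets[[a]], scoresets[[b]])
    va <- paste0(a, ".PC", ap$axis_a); vb <- paste0(b, ".PC", ap$axis_b)
    linked <- c(linked, a, b)
    if (lev[a] == lev[b]) {
      covs[[length(covs) + 1L]] <- c(va, vb)
    } else {
      lower_first <- lev[a] < lev[b]
      if (structure$regime == "top_down") lower_first <- !lower_first
      paths[[length(paths) + 1L]] <-
        if (lower_first) c(va, vb) else c(vb, va)
    }
  }
  for (g in ids) {
    ap <- axis_pair_selection(env_scores, scoresets[[g]])
    if (ap$p < alpha) {
      paths[[length(paths) + 1L]] <- c(paste0("env.PC", ap$axis_a),
                                       paste0(g, ".PC", ap$axis_b))
      linked <- c(linked, g)
    }
  }
  ## only groups with at least one link enter the model (both their axes);
  ## a fully unlinked screen leaves the environment block alone
  linked <- sort(unique(linked))
  vars <- c(if (length(linked)) paste0(rep(linked, each = 2), ".PC", 1:2),
            "env.PC1", "env.PC2")
  websem_model(vars,
               paths = if (length(paths)) do.call(rbind, paths),
               covariances = do.call(rbind, covs))
}

## All absent free-able parameters consistent with the path/covariance rule
## and the regime: directed paths from env to any group axis or between
## different trophic levels in the regime's direction; covariances within a
## level (including between the two axes of one group) or among the
## exogenous environment axes.
admissible_candidates <- function(model, structure) {
  v <- model$variables
  grp <- var_group(v, structure)
  lev <- ifelse(grp == "env", NA_integer_, structure$levels[grp])
  pk <- paste(model$paths$source, model$paths$target)
  ck <- paste(model$covariances$a, model$covariances$b)
  has_path <- function(a, b) (paste(a, b) %in% pk) || (paste(b, a) %in% pk)
  has_cov <- function(a, b) paste(min(a, b), max(a, b)) %in% ck
  cand <- list()
  for (i in seq_along(v)) for (j in seq_along(v)) {
    if (i == j) next
    a <- v[i]; b <- v[j]
    ## covariances once per unordered pair
    if (a < b && !has_cov(a, b) && !has_path(a, b)) {
      same_level <- grp[i] != "env" && grp[j] != "env" && lev[i] == lev[j]
      both_env <- grp[i] == "env" && grp[j] == "env"
      if (same_level || both_env)
        cand[[length(cand) + 1L]] <- c("covariance", a, b)
    }
    if (has_path(a, b) || has_cov(a, b)) next
    ok <- if (grp[i] == "env" && grp[j] != "env") TRUE
          else if (grp[i] == "env" || grp[j] == "env") FALSE
          else if (lev[i] == lev[j]) FALSE
          else if (structure$regime == "bottom_up") lev[i] < lev[j]
          else lev[i] > lev[j]
    if (ok) cand[[length(cand) + 1L]] <- c("path", a, b)
  }
  if (!length(cand))
    return(data.frame(type = character(0), source = character(0),
                      target = character(0), stringsAsFactors = FALSE))
  out <- as.data.frame(do.call(rbind, cand), stringsAsFactors = FALSE)
  names(out) <- c("type", "source", "target")
  out
}

add_parameter <- function(model, type, source, target) {
  if (type == "path")
    websem_model(model$variables,
                 paths = rbind(model$paths, data.frame(source = source, target = target)),
                 covariances = model$covariances)
  else
    websem_model(model$variables, paths = model$paths,
                 covariances = rbind(model$covariances,
                                     data.frame(a = source, b = target)))
}

#' Expand a model via modification indices
#'
#' While the global chi-square test rejects (`p < alpha_global`), the
#' admissible fixed parameter with the largest modification index at least
#' `mi_threshold` is freed (ties broken by larger absolute expected
#' change) and the model refitted, until a non-significant global solution
#' is reached, no admissible index passes the threshold, or `max_steps`
#' additions were made.
#'
#' @param model starting [websem_model].
#' @param data observed-variable data (plots in rows).
#' @param structure a [trophic_structure] defining admissibility (paths in
#'   the regime direction or from the environment; covariances within
#'   level).
#' @param alpha_global stop once the global p reaches this (default 0.05).
#' @param mi_threshold minimum modification index to free a parameter
#'   (default 3.84, the 0.05 critical value of chi-square on 1 df).
#' @param max_steps cap on additions.
#' @return List: `model`, `fit` (last converged fit, without standard
#'   errors), `added` (data frame of freed parameters), `status`
#'   (`"adequate"`, `"no_candidate"`, `"max_steps"` or
#'   `"nonconvergence"`).
#' @export
expand_via_mi <- function(model, data, structure, alpha_global = 0.05,
                          mi_threshold = 3.84, max_steps = 30) {
  fit <- websem(model, data, se = FALSE)
  added <- list()
  status <- "adequate"
  repeat {
    if (length(added) >= max_steps) { status <- "max_steps"; break }
    cand <- admissible_candidates(model, structure)
    if (nrow(cand) == 0) { status <- "no_candidate"; break }
    mi <- modification_indices(fit, cand)
    mi <- mi[is.finite(mi$mi), , drop = FALSE]
    ## a parameter with overwhelming single-df evidence (Bonferroni over
    ## the candidate pool) is freed even once the global test is passed:
    ## the low-powered global test alone would leave strong real pathways
    ## unmodelled
    mi_strong <- stats::qchisq(1 - alpha_global / nrow(cand), 1)
    inadequate <- fit$p_chi_corrected < alpha_global
    mi <- mi[mi$mi >= if (inadequate) mi_threshold else mi_strong, , drop = FALSE]
    if (nrow(mi) == 0) {
      if (inadequate) status <- "no_candidate"
      break
    }
    mi <- mi[order(-mi$mi, -abs(mi$expected_change)), , drop = FALSE]
    pick <- mi[1, ]
    model2 <- add_parameter(model, pick$type, pick$source, pick$target)
    fit2 <- tryCatch(websem(model2, data, se = FALSE, start = coef(fit)),
                     error = function(e) NULL)
    if (is.null(fit2)) { status <- "nonconvergence"; break }
    model <- model2; fit <- fit2
    added[[length(added) + 1L]] <- pick
  }
  list(model = model, fit = fit,
       added = if (length(added)) do.call(rbind, added)
               else data.frame(type = character(0), source = character(0),
                               target = character(0), mi = numeric(0),
                               expected_change = numeric(0)),
       status = status)
}

#' Prune a model by stepwise AIC removal
#'
#' Greedy backward elimination: at each step the single free path or
#' covariance whose removal most lowers the AIC is dropped; stops when no
#' removal lowers it. Residual variances are never removed. The returned
#' model's AIC never exceeds the input model's.
#'
#' @inheritParams expand_via_mi
#' @return List: `model` (minimum adequate model), `fit` (with standard
#'   errors), `removed` (character vector of dropped parameter labels).
#' @export
prune_by_aic <- function(model, data) {
  fit <- websem(model, data, se = FALSE)
  removed <- character(0)
  repeat {
    cand <- rbind(
      if (nrow(model$paths))
        data.frame(type = "path", source = model$paths$source,
                   target = model$paths$target, stringsAsFactors = FALSE),
      if (nrow(model$covariances))
        data.frame(type = "covariance", source = model$covariances$a,
                   target = model$covariances$b, stringsAsFactors = FALSE))
    if (is.null(cand) || nrow(cand) == 0) break
    best <- NULL
    for (j in seq_len(nrow(cand))) {
      m2 <- drop_parameter(model, cand$type[j], cand$source[j], cand$target[j])
      f2 <- tryCatch(websem(m2, data, se = FALSE, start = coef(fit)),
                     error = function(e) NULL)
      if (!is.null(f2) && f2$aic < fit$aic - 1e-9 &&
          (is.null(best) || f2$aic < best$fit$aic))
        best <- list(model = m2, fit = f2, label = cand[j, ])
    }
    if (is.null(best)) break
    model <- best$model; fit <- best$fit
    removed <- c(removed, with(best$label, if (type == "path")
      paste0(source, "->", target) else paste0(source, "<~>", target)))
  }
  list(model = model, fit = websem(model, data, se = TRUE), removed = removed)
}

drop_parameter <- function(model, type, source, target) {
  if (type == "path") {
    keep <- !(model$paths$source == source & model$paths$target == target)
    websem_model(model$variables, paths = model$paths[keep, , drop = FALSE],
                 covariances = model$covariances)
  } else {
    keep <- !(model$covariances$a == source & model$covariances$b == target)
    websem_model(model$variables, paths = model$paths,
                 covariances = model$covariances[keep, , drop = FALSE])
  }
}

run_search <- function(model, data, structure, alpha_global, mi_threshold,
                       max_steps) {
  ex <- expand_via_mi(model, data, structure, alpha_global = alpha_global,
                      mi_threshold = mi_threshold, max_steps = max_steps)
  pr <- prune_by_aic(ex$model, data)
  list(model = pr$model, fit = pr$fit, expansion = ex, removed = pr$removed)
}

direction_verdict <- function(fit_bu, fit_td) {
  delta <- fit_td$aic - fit_bu$aic
  list(delta_aic = delta,
       preferred = if (abs(delta) < 2) "equivocal"
                   else if (delta > 0) "bottom_up" else "top_down")
}

#' Compare bottom-up and top-down control by AIC
#'
#' Runs the full search (initial model, modification-index expansion,
#' stepwise AIC pruning) independently under both causal orientations,
#' sharing the same congruence screen and axis-pair selections, and
#' compares the final models' AIC values. `|delta AIC| < 2` is reported as
#' equivocal support.
#'
#' @inheritParams initial_model
#' @inheritParams expand_via_mi
#' @return Object of class `direction_comparison`: `fit_bottom_up`,
#'   `fit_top_down`, `model_bottom_up`, `model_top_down`,
#'   `delta_aic` (`AIC_top_down - AIC_bottom_up`), `preferred`
#'   (`"bottom_up"`, `"top_down"` or `"equivocal"`), `failed` (character
#'   vector of branches that errored, if any).
#' @export
compare_directions <- function(scoresets, env_scores, congruence, structure,
                               alpha = 0.05, alpha_global = 0.05,
                               mi_threshold = 3.84, max_steps = 30) {
  data <- scores_data(scoresets, env_scores)
  branch <- function(regime) {
    st <- set_regime(structure, regime)
    m0 <- initial_model(congruence, scoresets, env_scores, st, alpha = alpha)
    run_search(m0, data, st, alpha_global, mi_threshold, max_steps)
  }
  finish_comparison(branch, structure)
}

finish_comparison <- function(branch, structure) {
  res <- list(); failed <- character(0)
  for (regime in c("bottom_up", "top_down")) {
    res[[regime]] <- tryCatch(branch(regime), error = function(e) {
      failed <<- c(failed, regime)
      list(error = conditionMessage(e))
    })
  }
  out <- list(fit_bottom_up = res$bottom_up$fit,
              fit_top_down = res$top_down$fit,
              model_bottom_up = res$bottom_up$model,
              model_top_down = res$top_down$model,
              search_bottom_up = res$bottom_up,
              search_top_down = res$top_down,
              delta_aic = NA_real_, preferred = NA_character_,
              failed = failed)
  if (!length(failed)) {
    v <- direction_verdict(res$bottom_up$fit, res$top_down$fit)
    out$delta_aic <- v$delta_aic
    out$preferred <- v$preferred
  }
  class(out) <- "direction_comparison"
  out
}

#' @export
print.direction_comparison <- function(x, ...) {
  if (length(x$failed)) {
    cat("direction comparison: branch failure in", paste(x$failed, collapse = ", "), "\n")
    return(invisible(x))
  }
  cat(sprintf("direction comparison: AIC bottom-up %.1f vs top-down %.1f (delta = %.2f)\n",
              x$fit_bottom_up$aic, x$fit_top_down$aic, x$delta_aic))
  cat("preferred:", x$preferred, "\n")
  invisible(x)
}
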