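#' Chi-square upper-tail p-value of a covariance-structure fit
#'
#' @param chi_square likelihood-ratio statistic (`N * F_ML`).
#' @param df model degrees of freedom; `df = 0` (saturated model) returns 1
#'   with a warning.
#' @return Upper-tail probability of the central chi-square.
#' @export
chisq_pvalue <- function(chi_square, df) {
  if (df == 0) {
    warnf("df = 0 (saturated model); p defined as 1")
    return(1)
  }
  stats::pchisq(chi_square, df, lower.tail = FALSE)
}

#' Root mean square error of approximation
#'
#' `sqrt(max(chi_square - df, 0) / (df * n))`, zero whenever the statistic
#' does not exceed its degrees of freedom. Values below 0.1 indicate
#' adequate model fit; values close to 0 a good fit.
#'
#' @inheritParams chisq_pvalue
#' @param n sample size (number of plots).
#' @return RMSEA; `NA` with a warning when `df = 0`.
#' @export
rmsea <- function(chi_square, df, n) {
  if (df == 0) {
    warnf("RMSEA undefined at df = 0")
    return(NA_real_)
  }
  sqrt(max(chi_square - df, 0) / (df * n))
}

#' Close-fit test p-value for the RMSEA
#'
#' Tests H0: RMSEA <= `rmsea0` via the upper tail of a noncentral
#' chi-square with noncentrality `n * df * rmsea0^2` evaluated at the
#' observed statistic.
#'
#' @inheritParams rmsea
#' @param rmsea0 null RMSEA (default 0.05).
#' @return p-value; `NA` with a warning when `df = 0`.
#' @export
rmsea_close_fit_p <- function(chi_square, df, n, rmsea0 = 0.05) {
  if (df == 0) {
    warnf("close-fit p undefined at df = 0")
    return(NA_real_)
  }
  stats::pchisq(chi_square, df, ncp = n * df * rmsea0^2, lower.tail = FALSE)
}

## Default candidate set for modification indices: every absent directed
## path that keeps the graph acyclic and does not shadow a free covariance,
## and every absent covariance between variables not joined by a path.
default_mi_candidates <- function(model) {
  v <- model$variables
  pk <- paste(model$paths$source, model$paths$target)
  ck <- paste(model$covariances$a, model$covariances$b)
  g <- igraph::graph_from_data_frame(model$paths, directed = TRUE, vertices = v)
  reach <- igraph::distances(g, mode = "out")
  cand <- list()
  for (a in v) for (b in v) {
    if (a == b) next
    if (a < b && !(paste(a, b) %in% ck) &&
        !is.finite(reach[a, b]) && !is.finite(reach[b, a]))
      cand[[length(cand) + 1L]] <- c("covariance", a, b)
    if (paste(a, b) %in% pk || paste(min(a, b), max(a, b)) %in% ck) next
    if (is.finite(reach[b, a])) next   # adding a->b would close a cycle
    cand[[length(cand) + 1L]] <- c("path", a, b)
  }
  if (!length(cand))
    return(data.frame(type = character(0), source = character(0),
                      target = character(0), stringsAsFactors = FALSE))
  out <- as.data.frame(do.call(rbind, cand), stringsAsFactors = FALSE)
  names(out) <- c("type", "source", "target")
  out
}

#' Modification indices of a fitted path model
#'
#' For each admissible fixed-at-zero path or covariance, the score
#' (Lagrange-multiplier) statistic approximating the chi-square drop that
#' freeing the parameter would yield, together with the expected parameter
#' change. Computed from the fit-function gradient and the expected
#' (Fisher) information over the free parameters plus the candidate.
#'
#' @param fit a converged [websem] fit.
#' @param candidates optional data frame (`type` in `"path"`/`"covariance"`,
#'   `source`, `target`) restricting the admissible set; by default every
#'   acyclicity-preserving absent path and every absent covariance between
#'   path-unconnected variables is scored.
#' @return Data frame with columns `type`, `source`, `target`, `mi`,
#'   `expected_change`, sorted by decreasing `mi`. Candidates whose
#'   information is singular get `NA`.
#' @export
modification_indices <- function(fit, candidates = NULL) {
  stopifnot(inherits(fit, "websem"))
  model <- fit$model
  if (is.null(candidates)) candidates <- default_mi_candidates(model)
  if (nrow(candidates) == 0)
    return(data.frame(type = character(0), source = character(0),
                      target = character(0), mi = numeric(0),
                      expected_change = numeric(0)))
  v <- model$variables
  cp <- candidates[candidates$type == "path", , drop = FALSE]
  cc <- candidates[candidates$type != "path", , drop = FALSE]
  pat <- sem_pattern(model)
  ## extended packing: free paths + candidate paths, diag, free covs +
  ## candidate covs; candidates enter at zero
  ep <- list(p = pat$p,
             nb = pat$nb + nrow(cp), nc = pat$nc + nrow(cc),
             ti = c(pat$ti, match(cp$target, v)),
             si = c(pat$si, match(cp$source, v)),
             ai = c(pat$ai, match(cc$source, v)),
             bi = c(pat$bi, match(cc$target, v)))
  th <- fit$theta
  theta_ext <- c(th[seq_len(pat$nb)], rep(0, nrow(cp)),
                 th[pat$nb + seq_len(pat$p)],
                 th[pat$nb + pat$p + seq_len(pat$nc)], rep(0, nrow(cc)))
  free_ix <- c(seq_len(pat$nb),
               ep$nb + seq_len(pat$p),
               ep$nb + pat$p + seq_len(pat$nc))
  cand_ix <- c(pat$nb + seq_len(nrow(cp)),
               ep$nb + pat$p + pat$nc + seq_len(nrow(cc)))
  cand_tab <- rbind(cp, cc)
  ldetS <- determinant(fit$S)$modulus[1]
  r <- sem_fml(ep, theta_ext, fit$S, ldetS)
  H <- sem_expected_info(ep, theta_ext)
  mi <- epc <- rep(NA_real_, nrow(cand_tab))
  if (!is.null(H)) {
    Hff <- H[free_ix, free_ix, drop = FALSE]
    Hff_inv <- solve_ridged(Hff)
    if (!is.null(Hff_inv)) {
      for (j in seq_along(cand_ix)) {
        a <- cand_ix[j]
        s <- H[a, a] - drop(H[a, free_ix] %*% Hff_inv %*% H[free_ix, a])
        if (is.finite(s) && s > 1e-12) {
          mi[j] <- (fit$N / 2) * r$g[a]^2 / s
          epc[j] <- -r$g[a] / s
        }
      }
    }
  }
  out <- data.frame(cand_tab, mi = mi, expected_change = epc,
                    stringsAsFactors = FALSE)
  out[order(-out$mi, na.last = TRUE), , drop = FALSE]
}

#' Standardised solution of a fitted path model
#'
#' Path coefficients are rescaled by the ratio of implied standard
#' deviations of source and target; covariances become correlations;
#' residual variances become proportions of implied variance.
#'
#' @param fit a fitted [websem].
#' @return Data frame with `parameter` and `standardized` columns, in
#'   `coef()` order.
#' @export
standardize_solution <- function(fit) {
  stopifnot(inherits(fit, "websem"))
  model <- fit$model
  sdv <- sqrt(diag(fit$Sigma))
  if (any(sdv <= 0)) stopf("zero implied variance; cannot standardise")
  names(sdv) <- model$variables
  std <- numeric(0)
  if (nrow(model$paths)) {
    b <- fit$theta[seq_len(nrow(model$paths))]
    std <- c(std, b * sdv[model$paths$source] / sdv[model$paths$target])
  }
  std <- c(std, fit$theta[nrow(model$paths) + seq_along(model$variables)] /
             sdv[model$variables]^2)
  if (nrow(model$covariances)) {
    ps <- fit$theta[nrow(model$paths) + length(model$variables) +
                      seq_len(nrow(model$covariances))]
    std <- c(std, ps / (sdv[model$covariances$a] * sdv[model$covariances$b]))
  }
  data.frame(parameter = names(fit$theta), standardized = unname(std),
             stringsAsFactors = FALSE)
}
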