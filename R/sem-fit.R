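## Maximum-likelihood covariance-structure engine.
##
## The model is held in reticular-action form: Sigma(theta) =
## (I - B)^-1 Psi (I - B)^-T with free entries of B (directed paths) and
## Psi (residual variances on the diagonal, covariances off it). The
## normal-theory discrepancy
##   F_ML(theta) = ln|Sigma| + tr(S Sigma^-1) - ln|S| - p
## is minimised by quasi-Newton with an analytic gradient; chi^2 = N * F_ML
## with the divisor-N sample covariance S (the convention that reproduces
## the study system's published fit indices).

## index pattern: integer arrays into B and Psi for one packing
## theta = c(beta[paths], psi_diag[1..p], psi_off[covs])
sem_pattern <- function(model) {
  v <- model$variables
  p <- length(v)
  ti <- match(model$paths$target, v); si <- match(model$paths$source, v)
  ai <- match(model$covariances$a, v); bi <- match(model$covariances$b, v)
  list(p = p, nb = length(ti), nc = length(ai),
       ti = ti, si = si, ai = ai, bi = bi)
}

sem_matrices <- function(pat, theta) {
  p <- pat$p
  B <- matrix(0, p, p); Psi <- matrix(0, p, p)
  if (pat$nb) B[cbind(pat$ti, pat$si)] <- theta[seq_len(pat$nb)]
  diag(Psi) <- theta[pat$nb + seq_len(p)]
  if (pat$nc) {
    vals <- theta[pat$nb + p + seq_len(pat$nc)]
    Psi[cbind(pat$ai, pat$bi)] <- vals
    Psi[cbind(pat$bi, pat$ai)] <- vals
  }
  A <- solve(diag(p) - B)
  list(B = B, Psi = Psi, A = A, Sigma = A %*% Psi %*% t(A))
}

## F_ML and its analytic gradient in the natural parameterisation.
## Returns NULL if Sigma is not positive definite.
sem_fml <- function(pat, theta, S, ldetS, grad = TRUE) {
  M <- sem_matrices(pat, theta)
  cS <- tryCatch(chol(M$Sigma), error = function(e) NULL)
  if (is.null(cS)) return(NULL)
  Sinv <- chol2inv(cS)
  F <- 2 * sum(log(diag(cS))) + sum(Sinv * S) - ldetS - pat$p
  out <- list(F = as.numeric(F), Sigma = M$Sigma, A = M$A)
  if (grad) {
    G <- Sinv - Sinv %*% S %*% Sinv
    gb <- if (pat$nb) {
      SGA <- M$Sigma %*% G %*% M$A
      2 * SGA[cbind(pat$si, pat$ti)]
    } else numeric(0)
    AGA <- crossprod(M$A, G %*% M$A)
    gc <- if (pat$nc) 2 * AGA[cbind(pat$ai, pat$bi)] else numeric(0)
    out$g <- c(gb, diag(AGA), gc)
  }
  out
}

## parameter-wise derivative matrices dSigma/dtheta_j in the RAM
## parameterisation: for a path (t <- s), A E_ts Sigma + its transpose;
## for a variance, A E_ii A^T; for a covariance, A (E_ab + E_ba) A^T
sem_dsigma <- function(pat, M) {
  out <- vector("list", pat$nb + pat$p + pat$nc)
  A <- M$A; Sigma <- M$Sigma
  for (j in seq_len(pat$nb)) {
    D <- outer(A[, pat$ti[j]], Sigma[pat$si[j], ])
    out[[j]] <- D + t(D)
  }
  for (i in seq_len(pat$p))
    out[[pat$nb + i]] <- outer(A[, i], A[, i])
  for (j in seq_len(pat$nc)) {
    D <- outer(A[, pat$ai[j]], A[, pat$bi[j]])
    out[[pat$nb + pat$p + j]] <- D + t(D)
  }
  out
}

## expected (Fisher) information on the F_ML scale:
## H_jk = tr(Sigma^-1 dSigma_j Sigma^-1 dSigma_k); the information of the
## log-likelihood is (N/2) times this
sem_expected_info <- function(pat, theta) {
  M <- sem_matrices(pat, theta)
  Sinv <- tryCatch(chol2inv(chol(M$Sigma)), error = function(e) NULL)
  if (is.null(Sinv)) return(NULL)
  D <- sem_dsigma(pat, M)
  W <- lapply(D, function(d) Sinv %*% d %*% Sinv)
  k <- length(D)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) for (l in j:k)
    H[j, l] <- H[l, j] <- sum(W[[j]] * D[[l]])
  H
}

## solve a (possibly ill-conditioned) symmetric system, retrying with a
## small ridge; NULL if hopeless
solve_ridged <- function(A) {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(out)) {
    r <- 1e-8 * mean(abs(diag(A)))
    out <- tryCatch(solve(A + diag(r, nrow(A))), error = function(e) NULL)
  }
  out
}

#' Divisor-N sample covariance
#'
#' Covariance of the column-centered data with divisor `N` (the
#' normal-theory maximum-likelihood convention used throughout the fitting
#' engine). A constant column is an error naming the variable; an exactly
#' singular result is flagged via the `singular` attribute.
#'
#' @param data numeric matrix or data frame, plots in rows.
#' @return `p x p` covariance matrix.
#' @export
sample_covariance <- function(data) {
  x <- as.matrix(data)
  if (nrow(x) < 2) stopf("need at least 2 rows")
  if (any(!is.finite(x))) stopf("data contain non-finite values")
  xc <- scale(x, center = TRUE, scale = FALSE)
  cst <- colSums(xc^2) <= .Machine$double.eps * 100 * nrow(x)
  if (any(cst))
    stopf("constant column(s): %s", paste(colnames(x)[cst], collapse = ", "))
  S <- crossprod(xc) / nrow(x)
  if (rcond(S) < .Machine$double.eps * 100) {
    warnf("sample covariance is singular or near-singular")
    attr(S, "singular") <- TRUE
  }
  S
}

## identification: rank of the Jacobian of vech(Sigma(theta)) over the free
## parameters, evaluated at the start values and at a fixed perturbation of
## them (proportional Jacobian columns at beta = 0 can be coincidental)
sem_identified <- function(pat, theta0) {
  jac_at <- function(theta) {
    base <- sem_matrices(pat, theta)$Sigma
    low <- lower.tri(base, diag = TRUE)
    vapply(seq_along(theta), function(j) {
      h <- 1e-5 * max(1, abs(theta[j]))
      tp <- theta; tp[j] <- tp[j] + h
      ((sem_matrices(pat, tp)$Sigma - base) / h)[low]
    }, numeric(sum(low)))
  }
  k <- length(theta0)
  pert <- theta0 + 0.1 * sin(seq_len(k) * 2.3) * pmax(1, abs(theta0))
  max(qr(jac_at(theta0))$rank, qr(jac_at(pert))$rank) >= k
}

#' Fit a path model by maximum likelihood
#'
#' Minimises the normal-theory discrepancy between the sample covariance of
#' the observed variables and the covariance implied by the model, giving
#' the likelihood-ratio chi-square against the saturated model, RMSEA and
#' its close-fit test, AIC on the full Gaussian log-likelihood, and Wald
#' standard errors from the inverse observed information.
#'
#' Residual variances are optimised on the log scale; start values are zero
#' paths and covariances with sample variances on the diagonal, with up to
#' `restarts` seeded random restarts if the gradient does not vanish.
#' Observed variables are standardised to unit variance before fitting by
#' default (AIC differences between models on the same variables are
#' invariant to this).
#'
#' @param model a [websem_model].
#' @param data matrix or data frame containing the model's variables
#'   (plots in rows).
#' @param standardize standardise each variable to unit (divisor-N)
#'   variance before fitting (default `TRUE`).
#' @param se compute standard errors and the parameter covariance matrix
#'   (default `TRUE`; skipped during model-search loops for speed).
#' @param start optional named vector of start values (names as in
#'   `coef()`), e.g. estimates from a previously fitted super-model.
#' @param restarts maximum number of random restarts on non-convergence.
#' @param grad_tol convergence criterion: maximum absolute working-scale
#'   gradient (default `1e-6`).
#' @return Object of class `websem`; see [summary.websem()],
#'   [modification_indices()], [standardize_solution()].
#' @export
websem <- function(model, data, standardize = TRUE, se = TRUE, start = NULL,
                   restarts = 20, grad_tol = 1e-6) {
  stopifnot(inherits(model, "websem_model"))
  x <- as.matrix(as.data.frame(data)[, model$variables, drop = FALSE])
  missing <- setdiff(model$variables, colnames(x))
  if (length(missing)) stopf("data lack variable(s): %s", paste(missing, collapse = ", "))
  N <- nrow(x)
  if (standardize) {
    sdN <- sqrt(colSums(scale(x, center = TRUE, scale = FALSE)^2) / N)
    if (any(sdN <= 0)) stopf("constant variable(s) cannot be standardised")
    x <- sweep(x, 2, sdN, "/")
  }
  S <- sample_covariance(x)
  ldetS <- determinant(S)$modulus[1]
  if (!is.finite(ldetS)) stopf("sample covariance is singular; cannot fit")
  pat <- sem_pattern(model)
  k <- websem_k(model)
  df <- websem_df(model)
  if (df < 0) stopf("model has more free parameters (%d) than moments", k)
  pn <- websem_param_names(model)

  theta0 <- c(rep(0, pat$nb), diag(S), rep(0, pat$nc))
  names(theta0) <- pn
  if (!is.null(start)) {
    hit <- intersect(names(start), pn)
    theta0[hit] <- start[hit]
    dg <- pat$nb + seq_len(pat$p)
    theta0[dg] <- pmax(theta0[dg], 1e-4)
  }
  if (!sem_identified(pat, theta0))
    stopf("model is not identified (rank-deficient moment Jacobian)")

  ## working scale: residual variances on the log scale
  to_work <- function(th) { th[pat$nb + seq_len(pat$p)] <- log(th[pat$nb + seq_len(pat$p)]); th }
  to_nat <- function(w) { w[pat$nb + seq_len(pat$p)] <- exp(w[pat$nb + seq_len(pat$p)]); w }
  fn <- function(w) {
    r <- sem_fml(pat, to_nat(w), S, ldetS, grad = FALSE)
    if (is.null(r) || !is.finite(r$F)) 1e10 else r$F
  }
  gr <- function(w) {
    th <- to_nat(w)
    r <- sem_fml(pat, th, S, ldetS)
    if (is.null(r)) return(rep(0, length(w)))
    g <- r$g
    dg <- pat$nb + seq_len(pat$p)
    g[dg] <- g[dg] * th[dg]   # chain rule for log variances
    g
  }
  run <- function(w0) {
    o <- stats::optim(w0, fn, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
    o$gmax <- max(abs(gr(o$par)))
    o
  }
  best <- run(to_work(theta0))
  r <- 0
  while (best$gmax > grad_tol && r < restarts) {
    r <- r + 1
    w0 <- with_seed(90210 + r, {
      th <- theta0
      if (pat$nb) th[seq_len(pat$nb)] <- stats::rnorm(pat$nb, 0, 0.3)
      if (pat$nc) th[pat$nb + pat$p + seq_len(pat$nc)] <- stats::rnorm(pat$nc, 0, 0.05)
      w <- to_work(th)
      w[pat$nb + seq_len(pat$p)] <- w[pat$nb + seq_len(pat$p)] + stats::rnorm(pat$p, 0, 0.2)
      w
    })
    cand <- run(w0)
    if (cand$gmax < best$gmax ||
        (cand$value < best$value - 1e-10 && cand$gmax <= grad_tol))
      best <- cand
  }
  converged <- best$gmax <= grad_tol
  if (!converged)
    stopf(paste("optimiser did not converge after %d restarts",
                "(F = %.6g, max |gradient| = %.3g)"), r, best$value, best$gmax)
  theta <- to_nat(best$par)
  names(theta) <- pn
  final <- sem_fml(pat, theta, S, ldetS)
  chisq <- max(0, N * final$F)
  p_chi <- if (df == 0) 1 else stats::pchisq(chisq, df, lower.tail = FALSE)
  ## Swain small-sample correction of the likelihood-ratio statistic: the
  ## raw N*F statistic is sharply inflated when the number of moments is
  ## large relative to N, which would make adequacy-driven model search
  ## chase sampling noise; the corrected p is used by the search loops
  swain <- if (df > 0) {
    q <- (sqrt(1 + 8 * k) - 1) / 2
    1 - (pat$p * (2 * pat$p^2 + 3 * pat$p - 1) -
           q * (2 * q^2 + 3 * q - 1)) / (12 * df * N)
  } else 1
  p_chi_corrected <- if (df == 0) 1 else
    stats::pchisq(swain * chisq, df, lower.tail = FALSE)
  Sig <- final$Sigma
  dimnames(Sig) <- list(model$variables, model$variables)
  logL <- -(N / 2) * (pat$p * log(2 * pi) + determinant(Sig)$modulus[1] +
                        sum(chol2inv(chol(Sig)) * S))
  fit <- structure(list(
    model = model, data = x, S = S, N = N, k = k, df = df,
    theta = theta, Sigma = Sig,
    chi_square = chisq, p_chi = p_chi,
    swain_factor = swain, p_chi_corrected = p_chi_corrected,
    rmsea = if (df > 0) rmsea(chisq, df, N) else NA_real_,
    p_rmsea_close = if (df > 0) rmsea_close_fit_p(chisq, df, N) else NA_real_,
    logL = as.numeric(logL), aic = as.numeric(-2 * logL + 2 * k),
    converged = converged, grad_norm = best$gmax, restarts_used = r,
    standardized_data = standardize,
    se = NULL, vcov = NULL), class = "websem")
  if (se) fit <- add_standard_errors(fit)
  fit
}

add_standard_errors <- function(fit) {
  pat <- sem_pattern(fit$model)
  H <- sem_expected_info(pat, fit$theta)
  k <- length(fit$theta)
  V <- NULL
  if (!is.null(H)) {
    info <- (fit$N / 2) * H
    V <- tryCatch(solve(info), error = function(e) NULL)
  }
  if (is.null(V) || any(diag(V) < 0)) {
    warnf("observed information is not positive definite; standard errors unavailable")
    fit$se <- stats::setNames(rep(NA_real_, k), names(fit$theta))
  } else {
    dimnames(V) <- list(names(fit$theta), names(fit$theta))
    fit$vcov <- V
    fit$se <- sqrt(diag(V))
  }
  fit$z <- fit$theta / fit$se
  fit$pvalue <- 2 * stats::pnorm(abs(fit$z), lower.tail = FALSE)
  ## residual variances tested one-sided against zero is not meaningful;
  ## keep the Wald z anyway for completeness
  fit
}

#' @export
print.websem <- function(x, ...) {
  cat(sprintf("websem fit: %d variables, k = %d free parameters, N = %d\n",
              length(x$model$variables), x$k, x$N))
  cat(sprintf("  chi^2 = %.3f, df = %d, P = %.3f | RMSEA = %.3f (close-fit P = %.3f) | AIC = %.1f\n",
              x$chi_square, x$df, x$p_chi,
              ifelse(is.na(x$rmsea), NaN, x$rmsea),
              ifelse(is.na(x$p_rmsea_close), NaN, x$p_rmsea_close), x$aic))
  invisible(x)
}

#' Summarise a fitted path model
#'
#' @param object a fitted [websem] object.
#' @param ... unused.
#' @return A `summary.websem` object: the fit indices plus a parameter
#'   table (estimate, standard error, z, P, significance stars,
#'   standardised estimate).
#' @export
summary.websem <- function(object, ...) {
  std <- standardize_solution(object)
  tab <- data.frame(parameter = names(object$theta),
                    estimate = unname(object$theta),
                    std_error = if (is.null(object$se)) NA_real_ else unname(object$se),
                    z = if (is.null(object$z)) NA_real_ else unname(object$z),
                    p_value = if (is.null(object$pvalue)) NA_real_ else unname(object$pvalue),
                    stars = p_stars(if (is.null(object$pvalue)) NA_real_ else unname(object$pvalue)),
                    standardized = std$standardized,
                    stringsAsFactors = FALSE)
  structure(list(fit = object, parameters = tab), class = "summary.websem")
}

#' @export
print.summary.websem <- function(x, ...) {
  print(x$fit)
  cat("\nParameters:\n")
  tab <- x$parameters
  tab$estimate <- round(tab$estimate, 4)
  tab$std_error <- round(tab$std_error, 4)
  tab$z <- round(tab$z, 2)
  tab$p_value <- signif(tab$p_value, 3)
  tab$standardized <- round(tab$standardized, 4)
  print(tab, row.names = FALSE)
  cat("signif. stars: ***P<=0.001, **P<=0.01, *P<=0.05, ns nonsignificant\n")
  invisible(x)
}

#' @export
coef.websem <- function(object, ...) object$theta

#' @export
vcov.websem <- function(object, ...) object$vcov

#' @export
logLik.websem <- function(object, ...)
  structure(object$logL, df = object$k, nobs = object$N, class = "logLik")

#' @export
fitted.websem <- function(object, ...) object$Sigma

#' Residual covariance of a fitted path model
#'
#' @param object a fitted [websem].
#' @param ... unused.
#' @return `S - Sigma(theta_hat)`, the sample-minus-implied covariance.
#' @export
residuals.websem <- function(object, ...) object$S - object$Sigma

#' Simulate data from a fitted path model
#'
#' Draws plots from the multivariate normal distribution with the implied
#' covariance (zero mean; the engine fits covariance structure only).
#'
#' @param object a fitted [websem].
#' @param nsim number of datasets.
#' @param seed integer seed (caller's RNG state is untouched).
#' @param n rows per dataset (defaults to the fitted sample size).
#' @param ... unused.
#' @return List of `nsim` data frames (a single data frame if `nsim = 1`).
#' @export
simulate.websem <- function(object, nsim = 1, seed = 1, n = object$N, ...) {
  out <- with_seed(seed, {
    R <- chol(object$Sigma)
    p <- ncol(R)
    lapply(seq_len(nsim), function(i) {
      z <- matrix(stats::rnorm(n * p), n, p) %*% R
      colnames(z) <- object$model$variables
      as.data.frame(z)
    })
  })
  if (nsim == 1) out[[1]] else out
}

#' Draw data from a specified (not fitted) path model
#'
#' Builds the implied covariance from explicit parameter values and draws
#' Gaussian data from it; the generating tool for parameter-recovery and
#' calibration experiments.
#'
#' @param model a [websem_model].
#' @param theta named parameter vector (names as in [websem_param_names]
#'   order: `"a->b"`, `"var(x)"`, `"a<~>b"`); omitted parameters default to
#'   zero paths/covariances and unit variances.
#' @param n number of rows.
#' @param seed integer seed.
#' @return Data frame of `n` draws.
#' @export
simulate_websem <- function(model, theta = NULL, n = 100, seed = 1) {
  Sig <- websem_sigma(model, theta)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * ncol(Sig)), n) %*% chol(Sig)
    colnames(z) <- model$variables
    as.data.frame(z)
  })
}

#' Implied covariance of a path model at given parameter values
#'
#' @inheritParams simulate_websem
#' @return The `p x p` implied covariance `(I-B)^-1 Psi (I-B)^-T`.
#' @export
websem_sigma <- function(model, theta = NULL) {
  pat <- sem_pattern(model)
  full <- stats::setNames(c(rep(0, pat$nb), rep(1, pat$p), rep(0, pat$nc)),
                          websem_param_names(model))
  if (!is.null(theta)) {
    unknown <- setdiff(names(theta), names(full))
    if (length(unknown)) stopf("unknown parameter(s): %s", paste(unknown, collapse = ", "))
    full[names(theta)] <- theta
  }
  Sig <- sem_matrices(pat, full)$Sigma
  dimnames(Sig) <- list(model$variables, model$variables)
  Sig
}

#' Plot a fitted web as a graph
#'
#' Directed paths are drawn as arrows (width proportional to the absolute
#' standardised coefficient), covariances as dashed undirected edges.
#'
#' @param x a fitted [websem].
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.websem <- function(x, ...) {
  g <- websem_graph(x)
  w <- igraph::E(g)$std_estimate
  igraph::plot.igraph(g, edge.width = 0.5 + 3 * abs(w),
                      edge.lty = ifelse(igraph::E(g)$relation == "covariance", 2, 1),
                      edge.label = igraph::E(g)$stars, ...)
  invisible(x)
}
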