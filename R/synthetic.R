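## Synthetic multitrophic communities with a known causal web: latent
## two-axis community states per trophic group evolve on a directed
## cross-level graph with shared environmental drivers; species counts are
## drawn from a log-linear abundance model around the latent axes.

#' Specify a generating causal web
#'
#' @param groups data frame with columns `group_id`, `trophic_level`
#'   (integer rank, 1 = producers), `compartment` (`"above"`/`"below"`),
#'   `producer` (logical).
#' @param edges list of directed cross-level links, each
#'   `list(source =, target =, block =)` with a 2x2 coefficient block
#'   mapping source axes to target axes.
#' @param within_level_covariances list of `list(a =, b =, block =)` noise
#'   covariance blocks between groups on the same trophic level.
#' @param env_loadings named list (by group) of 2x2 blocks mapping the two
#'   latent environmental axes onto the group's axes.
#' @param noise_sd length-2 positive vector: residual standard deviation of
#'   axis 1 and axis 2 of every group. Distinct values keep the two axes
#'   identifiable (axis 1 carries more variance, as leading PCA axes do).
#' @param direction_label `"bottom_up"` or `"top_down"`; bookkeeping only.
#' @return Object of class `web_spec`.
#' @export
web_spec <- function(groups, edges = list(), within_level_covariances = list(),
                     env_loadings = list(), noise_sd = c(1, 0.6),
                     direction_label = c("bottom_up", "top_down")) {
  direction_label <- match.arg(direction_label)
  stopifnot(is.data.frame(groups),
            all(c("group_id", "trophic_level") %in% names(groups)))
  ids <- as.character(groups$group_id)
  if (anyDuplicated(ids)) stopf("duplicate group ids")
  for (e in edges) {
    if (!all(c(e$source, e$target) %in% ids))
      stopf("edge %s->%s refers to undeclared group", e$source, e$target)
    if (!all(dim(as.matrix(e$block)) == c(2, 2)))
      stopf("edge coefficient blocks must be 2x2")
  }
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, 2)
  if (any(noise_sd <= 0)) stopf("noise_sd must be positive")
  if (length(edges)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = vapply(edges, `[[`, "", "source"),
                 to = vapply(edges, `[[`, "", "target")),
      directed = TRUE, vertices = ids)
    if (!igraph::is_acyclic(g)) stopf("cross-level edges contain a cycle")
  }
  structure(list(groups = groups, edges = edges,
                 within_level_covariances = within_level_covariances,
                 env_loadings = env_loadings, noise_sd = noise_sd,
                 direction_label = direction_label),
            class = "web_spec")
}

## assemble the full (2G x 2G) coefficient matrix B, noise covariance Psi
## and (2G x 2) environmental loading matrix of a web
web_matrices <- function(web) {
  ids <- as.character(web$groups$group_id)
  G <- length(ids)
  ax <- function(g) 2 * (match(g, ids) - 1) + 1:2
  B <- matrix(0, 2 * G, 2 * G)
  for (e in web$edges) B[ax(e$target), ax(e$source)] <- as.matrix(e$block)
  Psi <- diag(rep(web$noise_sd^2, G))
  for (wc in web$within_level_covariances) {
    Psi[ax(wc$a), ax(wc$b)] <- as.matrix(wc$block)
    Psi[ax(wc$b), ax(wc$a)] <- t(as.matrix(wc$block))
  }
  Lam <- matrix(0, 2 * G, 2)
  for (g in names(web$env_loadings)) Lam[ax(g), ] <- as.matrix(web$env_loadings[[g]])
  vn <- paste0(rep(ids, each = 2), ".ax", 1:2)
  dimnames(B) <- list(vn, vn); dimnames(Psi) <- list(vn, vn); rownames(Lam) <- vn
  list(B = B, Psi = Psi, Lam = Lam, ids = ids, varnames = vn)
}

#' Simulate latent community scores on a causal web
#'
#' The latent state of each group is a plot-level 2-vector following the
#' linear recursive system
#' `score(target) = sum of coefficient blocks * score(source) +
#' env loadings * env + noise`, with the two latent environmental axes
#' standard normal and Gaussian noise with the web's (co)variance
#' structure. The implied covariance of the stacked scores is
#' `(I-B)^-1 (Lambda Lambda^T + Psi) (I-B)^-T`.
#'
#' @param web a [web_spec].
#' @param n_plots number of plots (at least 5).
#' @param seed integer seed; output is deterministic given the seed.
#' @return List with `scores` (named list of `n_plots x 2` matrices, one
#'   per group, shared plot rownames) and `env` (`n_plots x 2` latent
#'   environmental axes).
#' @export
simulate_latent_scores <- function(web, n_plots, seed = 1) {
  stopifnot(inherits(web, "web_spec"))
  if (n_plots < 5) stopf("n_plots must be at least 5")
  M <- web_matrices(web)
  cP <- tryCatch(chol(M$Psi), error = function(e)
    stopf("within-level covariance blocks make the noise covariance indefinite"))
  plots <- sprintf("p%03d", seq_len(n_plots))
  with_seed(seed, {
    E <- matrix(stats::rnorm(n_plots * 2), n_plots, 2,
                dimnames = list(plots, c("env1", "env2")))
    U <- matrix(stats::rnorm(n_plots * nrow(M$B)), n_plots) %*% cP
    X <- (E %*% t(M$Lam) + U) %*% t(solve(diag(nrow(M$B)) - M$B))
    rownames(X) <- plots
    scores <- lapply(M$ids, function(g) {
      out <- X[, 2 * (match(g, M$ids) - 1) + 1:2, drop = FALSE]
      colnames(out) <- c("ax1", "ax2")
      out
    })
    names(scores) <- M$ids
    list(scores = scores, env = E)
  })
}

#' Specify a group's species abundance model
#'
#' @param n_species number of species (at least 3).
#' @param baseline_log_abundance length-`n_species` baseline log expected
#'   count per species.
#' @param loading_matrix `n_species x 2` species loadings on the group's
#'   latent axes; must have full column rank.
#' @param count_model `"poisson"` or `"lognormal_poisson"`.
#' @param overdispersion log-normal standard deviation added to the
#'   expected log count under `"lognormal_poisson"` (ignored otherwise).
#' @return Object of class `abundance_spec`.
#' @export
abundance_spec <- function(n_species, baseline_log_abundance, loading_matrix,
                           count_model = c("poisson", "lognormal_poisson"),
                           overdispersion = 0) {
  count_model <- match.arg(count_model)
  if (n_species < 3) stopf("n_species must be at least 3")
  loading_matrix <- as.matrix(loading_matrix)
  stopifnot(nrow(loading_matrix) == n_species, ncol(loading_matrix) == 2,
            length(baseline_log_abundance) == n_species, overdispersion >= 0)
  if (qr(loading_matrix)$rank < 2)
    stopf("loading_matrix must have full column rank")
  structure(list(n_species = n_species,
                 baseline_log_abundance = baseline_log_abundance,
                 loading_matrix = loading_matrix,
                 count_model = count_model,
                 overdispersion = overdispersion),
            class = "abundance_spec")
}

#' Draw a species count matrix around latent scores
#'
#' Expected log abundance of species `s` in plot `i` is
#' `baseline[s] + loading[s, ] . score[i, ]`; counts are Poisson around
#' `exp()` of that (with an extra log-normal layer under
#' `"lognormal_poisson"`).
#'
#' @param scores `n_plots x 2` latent score matrix with plot rownames.
#' @param spec an [abundance_spec].
#' @param seed integer seed.
#' @inheritParams community_matrix
#' @return A [community_matrix] of non-negative integer counts.
#' @export
scores_to_counts <- function(scores, spec, seed = 1, group_id = "group",
                             trophic_level = NA_integer_,
                             compartment = c("below", "above"),
                             producer = FALSE) {
  stopifnot(inherits(spec, "abundance_spec"))
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stopf("scores must be finite")
  logmu <- matrix(spec$baseline_log_abundance, nrow(scores), spec$n_species,
                  byrow = TRUE) + scores %*% t(spec$loading_matrix)
  counts <- with_seed(seed, {
    if (spec$count_model == "lognormal_poisson" && spec$overdispersion > 0)
      logmu <- logmu + matrix(stats::rnorm(length(logmu), 0, spec$overdispersion),
                              nrow(logmu))
    matrix(stats::rpois(length(logmu), exp(logmu)), nrow(logmu))
  })
  dimnames(counts) <- list(rownames(scores),
                           sprintf("sp%03d", seq_len(spec$n_species)))
  community_matrix(counts, group_id = group_id, trophic_level = trophic_level,
                   compartment = match.arg(compartment), producer = producer)
}

## canonical three-level, six-group web used for validation experiments
canonical_web <- function(scenario, strength) {
  groups <- data.frame(
    group_id = c("plants_a", "plants_b", "herbivores_a", "herbivores_b",
                 "predators_a", "predators_b"),
    trophic_level = c(1L, 1L, 2L, 2L, 3L, 3L),
    compartment = "above",
    producer = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  ## two parallel trophic chains; transmission acts on the dominant
  ## composition axis, axis 2 carries group-specific structure
  chain <- list(c("plants_a", "herbivores_a"), c("plants_b", "herbivores_b"),
                c("herbivores_a", "predators_a"), c("herbivores_b", "predators_b"))
  edges <- lapply(chain, function(pr) {
    if (scenario == "top_down") pr <- rev(pr)
    list(source = pr[1], target = pr[2], block = diag(c(strength, 0.4 * strength)))
  })
  if (strength == 0) edges <- list()
  noise_sd <- c(1, 0.6)
  wlc <- lapply(list(c("plants_a", "plants_b"),
                     c("herbivores_a", "herbivores_b"),
                     c("predators_a", "predators_b")),
                function(pr) list(a = pr[1], b = pr[2],
                                  block = diag(0.3 * noise_sd^2)))
  ## environment anchors the producers (strongly, as a successional
  ## gradient structures plant communities) in either causal regime
  env_load <- list(plants_a = rbind(c(1.6, 0), c(0, 1.1)),
                   plants_b = rbind(c(1.4, 0), c(0, 0.9)))
  web_spec(groups, edges = edges, within_level_covariances = wlc,
           env_loadings = env_load, noise_sd = noise_sd,
           direction_label = scenario)
}

#' Simulate a complete multitrophic dataset with known causality
#'
#' Builds a canonical six-group, three-level web (two producer, two
#' consumer and two top-consumer groups) wired in the requested causal
#' direction with cross-level coefficient blocks of magnitude `strength`,
#' simulates latent scores, species count matrices (around 40 species per
#' group) and a 13-column environment table of which 4 columns load on the
#' two latent environmental axes and 9 are pure noise.
#'
#' @param scenario `"bottom_up"` (plants drive consumers) or `"top_down"`
#'   (reversed paths).
#' @param n_plots number of plots (default 27, the study-design scale).
#' @param seed integer seed; identical arguments give identical datasets.
#' @param strength cross-level coefficient magnitude in `[0, 1)`; 0 removes
#'   all cross-level links (null web).
#' @param n_species species per group (default 40).
#' @return Object of class `synthetic_dataset`: `matrices` (named list of
#'   [community_matrix]), `env` (plot x 13 matrix), `latent` (true scores),
#'   `env_latent`, `web` (the generating [web_spec]), plus the call
#'   parameters.
#' @export
simulate_dataset <- function(scenario = c("bottom_up", "top_down"),
                             n_plots = 27, seed = 1, strength = 0.8,
                             n_species = 40) {
  scenario <- match.arg(scenario)
  if (strength < 0 || strength >= 1) stopf("strength must be in [0, 1)")
  web <- canonical_web(scenario, strength)
  lat <- simulate_latent_scores(web, n_plots, seed = seed_for_label(seed, "latent"))
  ids <- as.character(web$groups$group_id)
  matrices <- lapply(ids, function(g) {
    sp <- with_seed(seed_for_label(seed, paste0("abund:", g)), {
      abundance_spec(n_species,
                     baseline_log_abundance = stats::rnorm(n_species, log(20), 0.7),
                     loading_matrix = matrix(stats::rnorm(2 * n_species, 0, 0.6),
                                             n_species, 2))
    })
    i <- match(g, ids)
    scores_to_counts(lat$scores[[g]], sp,
                     seed = seed_for_label(seed, paste0("counts:", g)),
                     group_id = g,
                     trophic_level = web$groups$trophic_level[i],
                     compartment = web$groups$compartment[i],
                     producer = web$groups$producer[i])
  })
  names(matrices) <- ids
  env <- with_seed(seed_for_label(seed, "env"), {
    e <- lat$env
    sig <- cbind(e[, 1] + stats::rnorm(n_plots, 0, 0.3),
                 0.8 * e[, 1] + stats::rnorm(n_plots, 0, 0.3),
                 e[, 2] + stats::rnorm(n_plots, 0, 0.3),
                 0.8 * e[, 2] + stats::rnorm(n_plots, 0, 0.3))
    noise <- matrix(stats::rnorm(n_plots * 9), n_plots, 9)
    out <- cbind(sig, noise)
    dimnames(out) <- list(rownames(e), sprintf("env%02d", 1:13))
    out
  })
  structure(list(matrices = matrices, env = env, latent = lat$scores,
                 env_latent = lat$env, web = web, scenario = scenario,
                 n_plots = n_plots, seed = seed, strength = strength),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic %s dataset: %d plots, %d groups, strength %.2f, seed %d\n",
              x$scenario, x$n_plots, length(x$matrices), x$strength, x$seed))
  invisible(x)
}
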