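null_web <- function() {
  groups <- data.frame(group_id = c("g1", "g2", "g3"),
                       trophic_level = c(1L, 2L, 3L), compartment = "below",
                       producer = c(TRUE, FALSE, FALSE))
  web_spec(groups)
}

test_that("a null web yields independent group scores", {
  lat <- simulate_latent_scores(null_web(), n_plots = 4000, seed = 1)
  r12 <- cor(lat$scores$g1[, 1], lat$scores$g2[, 1])
  r23 <- cor(lat$scores$g2[, 2], lat$scores$g3[, 2])
  expect_lt(abs(r12), 0.05)
  expect_lt(abs(r23), 0.05)
})

test_that("an identity edge with vanishing noise copies scores", {
  groups <- data.frame(group_id = c("a", "b"), trophic_level = 1:2,
                       compartment = "below", producer = c(TRUE, FALSE))
  web <- web_spec(groups,
                  edges = list(list(source = "a", target = "b", block = diag(2))),
                  noise_sd = c(1e-6, 1e-6))
  # group a itself is then near-degenerate; give it env drive instead
  web2 <- web_spec(groups,
                   edges = list(list(source = "a", target = "b", block = diag(2))),
                   env_loadings = list(a = diag(2)), noise_sd = c(1e-6, 1e-6))
  lat <- simulate_latent_scores(web2, n_plots = 50, seed = 2)
  expect_equal(lat$scores$b, lat$scores$a, tolerance = 1e-4)
})

test_that("empirical covariance matches the implied-covariance oracle", {
  groups <- data.frame(group_id = c("a", "b", "c"), trophic_level = 1:3,
                       compartment = "below", producer = c(TRUE, FALSE, FALSE))
  web <- web_spec(groups,
                  edges = list(list(source = "a", target = "b", block = diag(0.8, 2)),
                               list(source = "b", target = "c", block = diag(0.8, 2))),
                  env_loadings = list(a = diag(c(0.5, 0.5))),
                  noise_sd = c(1, 0.6))
  lat <- simulate_latent_scores(web, n_plots = 10000, seed = 1)
  X <- cbind(lat$scores$a, lat$scores$b, lat$scores$c)
  emp <- crossprod(scale(X, center = TRUE, scale = FALSE)) / nrow(X)

  # oracle: direct matrix algebra, assembled independently of web_matrices()
  B <- matrix(0, 6, 6)
  B[3, 1] <- B[4, 2] <- 0.8   # a -> b per axis
  B[5, 3] <- B[6, 4] <- 0.8   # b -> c per axis
  Lam <- matrix(0, 6, 2); Lam[1, 1] <- Lam[2, 2] <- 0.5
  Psi <- diag(rep(c(1, 0.6)^2, 3))
  A <- solve(diag(6) - B)
  oracle <- A %*% (Lam %*% t(Lam) + Psi) %*% t(A)
  expect_equal(unname(emp), unname(oracle), tolerance = 0.06)
  # the headline chain covariance: cov(a1, c1) = 0.8 * 0.8 * var(a1)
  expect_equal(emp[1, 5], 0.64 * oracle[1, 1], tolerance = 0.05)
})

test_that("latent simulation is deterministic and validates inputs", {
  web <- null_web()
  l1 <- simulate_latent_scores(web, 20, seed = 5)
  l2 <- simulate_latent_scores(web, 20, seed = 5)
  expect_identical(l1, l2)
  expect_error(simulate_latent_scores(web, 4, seed = 1), "at least 5")
  groups <- data.frame(group_id = c("a", "b"), trophic_level = 1:2,
                       compartment = "below", producer = FALSE)
  expect_error(web_spec(groups,
                        edges = list(list(source = "a", target = "b", block = diag(2)),
                                     list(source = "b", target = "a", block = diag(2)))),
               "cycle")
})

test_that("count generation is reproducible and respects the abundance model", {
  set.seed(1)
  sc <- matrix(rnorm(10), 5, 2, dimnames = list(sprintf("p%d", 1:5), NULL))
  sp0 <- abundance_spec(3, baseline_log_abundance = rep(2, 3),
                        loading_matrix = matrix(c(1, 0, 0, 0, 1, 0), 3, 2))
  c1 <- scores_to_counts(sc, sp0, seed = 9)
  c2 <- scores_to_counts(sc, sp0, seed = 9)
  expect_identical(unclass(c1), unclass(c2))
  expect_true(all(c1 >= 0), all(c1 == floor(c1)))

  # (near-)zero loadings: identical expected abundance in every plot
  spz <- abundance_spec(4, baseline_log_abundance = log(c(5, 10, 20, 40)),
                        loading_matrix = rbind(c(1e-9, 0), c(0, 1e-9),
                                               c(0, 0), c(0, 0)))
  big <- scores_to_counts(matrix(rnorm(4000), 2000, 2,
                                 dimnames = list(sprintf("p%d", 1:2000), NULL)),
                          spz, seed = 4)
  expect_equal(unname(colMeans(big)), c(5, 10, 20, 40), tolerance = 0.1)

  expect_error(scores_to_counts(matrix(c(1, NA), 1, 2), sp0), "finite")
  expect_error(abundance_spec(2, rep(0, 2), matrix(0, 2, 2)), "n_species")
  expect_error(abundance_spec(3, rep(0, 3), matrix(rep(1, 6), 3, 2)), "rank")
})

test_that("PCA of deep count matrices recovers the latent axes", {
  # near-linear composition regime: gentle species loadings, deep counts
  set.seed(2)
  n <- 60
  sc <- cbind(rnorm(n, 0, 1.3), rnorm(n, 0, 0.7))
  rownames(sc) <- sprintf("p%02d", 1:n)
  sp <- abundance_spec(100, baseline_log_abundance = rnorm(100, log(20000), 0.5),
                       loading_matrix = matrix(rnorm(200, 0, 0.15), 100, 2))
  cm <- scores_to_counts(sc, sp, seed = 6)
  s <- pca_site_scores(to_relative_abundance(cm))
  pr <- procrustes_m2(s$scores, sc)
  expect_gt(pr$t_statistic, 0.99)
})

test_that("complete datasets are deterministic, aligned and well-formed", {
  d1 <- simulate_dataset("bottom_up", 27, seed = 3, strength = 0.8)
  d2 <- simulate_dataset("bottom_up", 27, seed = 3, strength = 0.8)
  expect_identical(lapply(d1$matrices, unclass), lapply(d2$matrices, unclass))
  expect_identical(d1$env, d2$env)
  expect_length(d1$matrices, 6)
  expect_equal(ncol(d1$env), 13)
  plots <- rownames(d1$env)
  for (m in d1$matrices) {
    expect_identical(rownames(m), plots)
    expect_true(all(m >= 0 & m == floor(m)))
  }
  expect_error(simulate_dataset("bottom_up", 27, strength = 1.2), "strength")
  expect_error(simulate_dataset("sideways"), "arg")
})

test_that("null-strength datasets show no cross-level congruence signal", {
  d <- simulate_dataset("bottom_up", 27, seed = 11, strength = 0)
  ss <- lapply(d$matrices, function(m) pca_site_scores(to_relative_abundance(m)))
  cg <- pairwise_congruence(ss, n_permutations = 199, seed = 11)
  lev <- setNames(d$web$groups$trophic_level, d$web$groups$group_id)
  cross <- cg[lev[cg$source_a] != lev[cg$source_b], ]
  # cross-level p-values look uniform: around 5% significant at alpha = .05
  expect_lt(mean(cross$p_perm < 0.05), 0.35)
  expect_gt(mean(cross$p_perm), 0.25)
})
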