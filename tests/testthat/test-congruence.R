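test_that("Procrustes fit is exact for identical and similar configurations", {
  x <- toy_scores(10, seed = 1)$scores
  expect_equal(procrustes_m2(x, x)$m_squared, 0, tolerance = 1e-12)
  expect_equal(procrustes_m2(x, x)$t_statistic, 1, tolerance = 1e-12)

  # rotation + uniform scale + translation leave congruence perfect
  y <- 3 * x %*% rot2(pi / 2) + matrix(c(5, -2), nrow(x), 2, byrow = TRUE)
  rownames(y) <- rownames(x)
  r <- procrustes_m2(x, y)
  expect_equal(r$m_squared, 0, tolerance = 1e-10)
  expect_equal(r$t_statistic, 1, tolerance = 1e-10)
})

test_that("Procrustes m2 is symmetric and similarity-invariant in general", {
  for (s in 1:5) {
    x <- toy_scores(8, seed = s)$scores
    y <- toy_scores(8, seed = s + 100)$scores
    a <- procrustes_m2(x, y); b <- procrustes_m2(y, x)
    expect_equal(a$m_squared, b$m_squared, tolerance = 1e-12)
    expect_gte(a$t_statistic, 0); expect_lte(a$t_statistic, 1)
    # reflection + scaling of one configuration
    y2 <- (y %*% diag(c(-1, 1)) %*% rot2(0.7)) * 0.2
    rownames(y2) <- rownames(y)
    expect_equal(procrustes_m2(x, y2)$t_statistic, a$t_statistic,
                 tolerance = 1e-10)
  }
})

test_that("Procrustes m2 matches the rotation-angle grid-search oracle", {
  for (s in 1:4) {
    x <- toy_scores(5, seed = s)$scores
    y <- toy_scores(5, seed = s + 50)$scores
    expect_equal(procrustes_m2(x, y)$m_squared, grid_m2(x, y, step = 1e-5),
                 tolerance = 1e-6)
  }
})

test_that("Procrustes agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  for (s in 1:3) {
    x <- toy_scores(12, seed = s)$scores
    y <- toy_scores(12, seed = s + 9)$scores
    vg <- vegan::protest(x, y, permutations = 99)
    expect_equal(procrustes_m2(x, y)$t_statistic, unname(vg$t0),
                 tolerance = 1e-8)
  }
})

test_that("protest p-value uses the add-one rule and is seed-deterministic", {
  x <- toy_scores(9, seed = 2)
  y <- toy_scores(9, seed = 3)
  r1 <- protest(x, y, n_permutations = 99, seed = 7)
  r2 <- protest(x, y, n_permutations = 99, seed = 7)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_gte(r1$p_perm, 1 / 100)

  # self-comparison: no permutation can beat t = 1 except ties
  rs <- protest(x, x, n_permutations = 99, seed = 1)
  expect_equal(rs$p_perm, 1 / 100)
  expect_error(protest(x, y, n_permutations = 0), "n_permutations")
})

test_that("protest p matches exhaustive enumeration at n = 5", {
  x <- toy_scores(5, seed = 4)$scores
  y <- toy_scores(5, seed = 14)$scores
  t_obs <- procrustes_m2(x, y)$t_statistic
  # oracle: all 120 row permutations of y
  permute_all <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in permute_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  ts <- vapply(permute_all(1:5), function(p) {
    yp <- y[p, , drop = FALSE]; rownames(yp) <- rownames(x)
    procrustes_m2(x, yp)$t_statistic
  }, numeric(1))
  p_exact <- mean(ts >= t_obs - 1e-12)
  p_mc <- protest(x, y, n_permutations = 999, seed = 3)$p_perm
  # Monte-Carlo p within the binomial 99% interval around the exact p
  se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(p_mc - p_exact), 2.58 * se + 1 / 1000 + 1e-12)
})

test_that("pairwise congruence enumerates all pairs, order-invariantly", {
  sets <- lapply(1:4, function(i) toy_scores(8, seed = i, id = paste0("g", i)))
  tab <- pairwise_congruence(sets, n_permutations = 49, seed = 5)
  expect_equal(nrow(tab), choose(4, 2))
  tab2 <- pairwise_congruence(rev(sets), n_permutations = 49, seed = 5)
  expect_equal(tab, tab2, ignore_attr = TRUE)
  one <- pairwise_congruence(sets[1:2], n_permutations = 49, seed = 5)
  expect_equal(nrow(one), 1L)
})

test_that("BH adjustment matches the hand computation and reports m*alpha", {
  rec <- data.frame(source_a = letters[1:4], source_b = LETTERS[1:4],
                    p_perm = c(0.01, 0.02, 0.03, 0.04))
  out <- adjust_pvalues(rec, alpha = 0.05)
  expect_equal(out$p_adjusted, rep(0.04, 4))
  expect_equal(attr(out, "expected_false_discoveries"), 0.2)

  allone <- data.frame(source_a = "a", source_b = "b", p_perm = 1)
  expect_equal(adjust_pvalues(allone)$p_adjusted, 1)

  m300 <- data.frame(source_a = paste0("a", 1:300), source_b = paste0("b", 1:300),
                     p_perm = runif(300))
  expect_equal(attr(adjust_pvalues(m300, alpha = 0.05),
                    "expected_false_discoveries"), 15)
})

test_that("group screening excludes unlinked candidates and merges redundant ones", {
  set.seed(8)
  n <- 20
  base <- matrix(rnorm(2 * n), n, 2, dimnames = list(sprintf("p%02d", 1:n), NULL))
  mk <- function(id, m, jitter = 0) {
    s <- m + matrix(rnorm(2 * n, 0, jitter), n, 2)
    dimnames(s) <- list(rownames(base), c("PC1", "PC2"))
    trophicweb:::new_score_set(s, c(0.6, 0.4), 2, id)
  }
  sets <- list(
    mk("plants", base),
    mk("fungi", base, 0.4),
    # redundant bacterial block: four near-copies of one configuration
    mk("bact1", base %*% rot2(1) + 0.2, 0.05),
    mk("bact2", base %*% rot2(1) + 0.2, 0.05),
    mk("bact3", base %*% rot2(1) + 0.2, 0.05),
    mk("bact4", base %*% rot2(1) + 0.2, 0.05),
    # candidate with no congruence to anything
    mk("bact5", matrix(rnorm(2 * n), n, 2))
  )
  tab <- pairwise_congruence(sets, n_permutations = 999, seed = 2)
  sc <- screen_groups(tab, candidates = paste0("bact", 1:5))
  expect_true(all(c("plants", "fungi") %in% sc$kept))
  expect_false("bact5" %in% sc$kept)
  kept_bact <- grep("^bact[1-4]$", sc$kept, value = TRUE)
  expect_length(kept_bact, 1L)
  rep_rows <- sc$report[sc$report$candidate %in% paste0("bact", 1:4), ]
  expect_true(all(rep_rows$representative == kept_bact))

  # two identical candidate score sets: one retained
  sets2 <- list(mk("ref", base), mk("c1", base, 0.3), mk("c2", base, 1e-9))
  sets2[[3]]$scores <- sets2[[2]]$scores
  tab2 <- pairwise_congruence(sets2, n_permutations = 999, seed = 3)
  sc2 <- screen_groups(tab2, candidates = c("c1", "c2"))
  expect_length(intersect(sc2$kept, c("c1", "c2")), 1L)
})

test_that("protest null p-values are uniform", {
  set.seed(31)
  B <- 199
  ps <- replicate(400, {
    x <- matrix(rnorm(20), 10, 2); y <- matrix(rnorm(20), 10, 2)
    rownames(x) <- rownames(y) <- sprintf("p%d", 1:10)
    protest(x, y, n_permutations = B, seed = sample.int(1e6, 1))$p_perm
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.07)
})
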