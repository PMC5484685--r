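canon_structure <- function(regime = "bottom_up") {
  trophic_structure(c(plants_a = 1, plants_b = 1, herbivores_a = 2,
                      herbivores_b = 2, predators_a = 3, predators_b = 3),
                    regime = regime)
}

test_that("axis-pair selection finds the most significant combination", {
  a <- toy_scores(20, seed = 1, id = "a")
  b <- a; b$source_id <- "b"
  sel <- axis_pair_selection(a, b)
  expect_equal(c(sel$axis_a, sel$axis_b), c(1, 1))
  expect_equal(sel$r, 1, tolerance = 1e-12)

  # construct: b's second axis tracks a's first
  set.seed(2)
  b2 <- toy_scores(20, seed = 3, id = "b")
  b2$scores[, 2] <- a$scores[, 1] + rnorm(20, 0, 0.05)
  sel2 <- axis_pair_selection(a, b2)
  expect_equal(c(sel2$axis_a, sel2$axis_b), c(1, 2))

  # brute-force oracle over random fixtures
  for (s in 1:6) {
    x <- toy_scores(15, seed = s)$scores
    y <- toy_scores(15, seed = s + 70)$scores
    sel3 <- axis_pair_selection(x, y)
    cors <- abs(outer(1:2, 1:2, Vectorize(function(i, j) cor(x[, i], y[, j]))))
    expect_equal(abs(sel3$r), max(cors), tolerance = 1e-12)
  }
})

test_that("initial models orient significant pairs by the regime", {
  set.seed(4)
  n <- 27
  base <- matrix(rnorm(2 * n), n, 2, dimnames = list(sprintf("p%02d", 1:n), NULL))
  mk <- function(id, m) {
    dimnames(m) <- list(rownames(base), c("PC1", "PC2"))
    trophicweb:::new_score_set(m, c(0.6, 0.4), 2, id)
  }
  ss <- list(mk("plants_a", base),
             mk("herbivores_a", 0.9 * base + matrix(rnorm(2 * n, 0, 0.4), n, 2)))
  es <- mk("env", matrix(rnorm(2 * n), n, 2)); es$source_id <- "env"
  cg <- pairwise_congruence(ss, n_permutations = 199, seed = 4)
  expect_lt(cg$p_perm[1], 0.05)
  m_bu <- initial_model(cg, ss, es, canon_structure("bottom_up"))
  m_td <- initial_model(cg, ss, es, canon_structure("top_down"))
  bu_cross <- m_bu$paths[!grepl("^env", m_bu$paths$source), ]
  td_cross <- m_td$paths[!grepl("^env", m_td$paths$source), ]
  expect_equal(nrow(bu_cross), 1L)
  expect_match(bu_cross$source, "^plants_a")
  expect_match(bu_cross$target, "^herbivores_a")
  # reversed under top-down, same axes
  expect_identical(td_cross$source, bu_cross$target)
  expect_identical(td_cross$target, bu_cross$source)

  # no significant pairs: only the environment block remains
  ss0 <- list(mk("plants_a", matrix(rnorm(2 * n), n, 2)),
              mk("herbivores_a", matrix(rnorm(2 * n), n, 2)))
  cg0 <- pairwise_congruence(ss0, n_permutations = 199, seed = 9)
  cg0$p_perm <- 1  # force the null screen
  m0 <- initial_model(cg0, ss0, es, canon_structure())
  expect_identical(m0$variables, c("env.PC1", "env.PC2"))
  expect_equal(nrow(m0$paths), 0L)
  expect_equal(nrow(m0$covariances), 1L)
})

test_that("admissible candidates respect the path/covariance rule", {
  st <- canon_structure("bottom_up")
  m <- websem_model(c("plants_a.PC1", "plants_a.PC2", "herbivores_a.PC1",
                      "predators_a.PC1", "env.PC1"),
                    paths = rbind(c("plants_a.PC1", "herbivores_a.PC1")))
  cand <- trophicweb:::admissible_candidates(m, st)
  key <- paste(cand$type, cand$source, cand$target)
  # no path against the bottom-up direction
  expect_false(any(cand$type == "path" &
                     cand$source == "herbivores_a.PC1" &
                     cand$target == "plants_a.PC1"))
  # upward paths and env paths are offered
  expect_true("path plants_a.PC2 herbivores_a.PC1" %in% key)
  expect_true("path herbivores_a.PC1 predators_a.PC1" %in% key)
  expect_true("path env.PC1 plants_a.PC1" %in% key)
  # within-level covariance offered, cross-level covariance not
  expect_true("covariance plants_a.PC1 plants_a.PC2" %in% key)
  expect_false(any(cand$type == "covariance" &
                     grepl("^plants", cand$source) & grepl("^herb", cand$target)))
  # nothing targets the environment
  expect_false(any(cand$target %in% c("env.PC1", "env.PC2")))
})

test_that("expansion is a no-op at an infinite threshold and finds omitted paths", {
  st <- trophic_structure(c(a = 1, b = 2), regime = "bottom_up")
  m_true <- websem_model(c("a.PC1", "a.PC2", "b.PC1", "b.PC2", "env.PC1", "env.PC2"),
                         paths = rbind(c("a.PC1", "b.PC1"), c("env.PC1", "a.PC1")),
                         covariances = rbind(c("env.PC1", "env.PC2")))
  d <- simulate_websem(m_true, c("a.PC1->b.PC1" = 0.6, "env.PC1->a.PC1" = 0.7),
                       n = 200, seed = 42)
  m_miss <- websem_model(m_true$variables,
                         paths = rbind(c("env.PC1", "a.PC1")),
                         covariances = rbind(c("env.PC1", "env.PC2")))
  ex_inf <- expand_via_mi(m_miss, d, st, mi_threshold = Inf)
  expect_equal(nrow(ex_inf$added), 0L)
  expect_equal(format_websem_model(ex_inf$model), format_websem_model(m_miss))

  hits <- vapply(1:40, function(s) {
    di <- simulate_websem(m_true, c("a.PC1->b.PC1" = 0.6, "env.PC1->a.PC1" = 0.7),
                          n = 200, seed = 500 + s)
    ex <- expand_via_mi(m_miss, di, st)
    nrow(ex$added) >= 1 &&
      ex$added$source[1] == "a.PC1" && ex$added$target[1] == "b.PC1"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("AIC pruning removes null paths, keeps true ones, and never raises AIC", {
  st <- trophic_structure(c(a = 1, b = 2), regime = "bottom_up")
  m_true <- websem_model(c("a.PC1", "a.PC2", "b.PC1"),
                         paths = rbind(c("a.PC1", "b.PC1")))
  m_extra <- websem_model(c("a.PC1", "a.PC2", "b.PC1"),
                          paths = rbind(c("a.PC1", "b.PC1"), c("a.PC2", "b.PC1")))
  res <- vapply(1:40, function(s) {
    d <- simulate_websem(m_true, c("a.PC1->b.PC1" = 0.6), n = 500, seed = 900 + s)
    pr <- prune_by_aic(m_extra, d)
    f0 <- websem(m_extra, d, se = FALSE)
    c(pruned = "a.PC2->b.PC1" %in% pr$removed,
      kept = nrow(pr$model$paths) >= 1 &&
        any(pr$model$paths$source == "a.PC1" & pr$model$paths$target == "b.PC1"),
      mono = pr$fit$aic <= f0$aic + 1e-9)
  }, logical(3))
  expect_gte(mean(res["pruned", ]), 0.85)
  expect_gte(mean(res["kept", ]), 0.95)
  expect_true(all(res["mono", ]))

  # an empty model passes through unchanged
  m_empty <- websem_model(c("a.PC1", "b.PC1"))
  d <- simulate_websem(m_empty, n = 50, seed = 1)
  pr0 <- prune_by_aic(m_empty, d)
  expect_length(pr0$removed, 0)
})

test_that("final searched models satisfy the regime's admissibility", {
  d <- simulate_dataset("bottom_up", 27, seed = 2, strength = 0.8)
  ss <- lapply(d$matrices, function(m) pca_site_scores(to_relative_abundance(m)))
  es <- environment_scores(d$env)
  cg <- pairwise_congruence(ss, n_permutations = 99, seed = 2)
  st <- canon_structure()
  dc <- compare_directions(ss, es, cg, st)
  expect_length(dc$failed, 0)
  lev <- c(st$levels, env = 0)
  for (regime in c("bottom_up", "top_down")) {
    mdl <- dc[[paste0("model_", regime)]]
    gsrc <- trophicweb:::var_group(mdl$paths$source, st)
    gtgt <- trophicweb:::var_group(mdl$paths$target, st)
    biotic <- gsrc != "env"
    if (regime == "bottom_up") expect_true(all(lev[gsrc[biotic]] < lev[gtgt[biotic]]))
    else expect_true(all(lev[gsrc[biotic]] > lev[gtgt[biotic]]))
    ga <- trophicweb:::var_group(mdl$covariances$a, st)
    gb <- trophicweb:::var_group(mdl$covariances$b, st)
    expect_true(all(lev[ga] == lev[gb]))
  }
  # determinism of the full comparison
  dc2 <- compare_directions(ss, es, cg, st)
  expect_identical(format_websem_model(dc$model_bottom_up),
                   format_websem_model(dc2$model_bottom_up))
  expect_equal(dc$delta_aic, dc2$delta_aic)
  expect_true(dc$preferred %in% c("bottom_up", "top_down", "equivocal"))
  expect_equal(dc$delta_aic, dc$fit_top_down$aic - dc$fit_bottom_up$aic)
})
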