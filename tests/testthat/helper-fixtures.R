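# small builders shared across test files

toy_counts <- function(n_plots = 6, n_species = 4, seed = 1, group_id = "g") {
  set.seed(seed)
  m <- matrix(rpois(n_plots * n_species, 8), n_plots, n_species,
              dimnames = list(sprintf("p%02d", seq_len(n_plots)),
                              sprintf("s%02d", seq_len(n_species))))
  community_matrix(m, group_id = group_id, trophic_level = 1L)
}

toy_scores <- function(n = 10, seed = 1, id = "x") {
  set.seed(seed)
  s <- matrix(rnorm(2 * n), n, 2,
              dimnames = list(sprintf("p%02d", seq_len(n)), c("PC1", "PC2")))
  trophicweb:::new_score_set(s, c(0.6, 0.4), 2, id)
}

rot2 <- function(theta) matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

# independent brute-force symmetric Procrustes m2: grid over rotation angle
# (with and without reflection), configurations pre-standardised the same way
grid_m2 <- function(x, y, step = 1e-5) {
  std <- function(m) { m <- scale(m, center = TRUE, scale = FALSE); m / sqrt(sum(m^2)) }
  x <- std(x); y <- std(y)
  best <- Inf
  for (refl in c(1, -1)) {
    yr <- y %*% diag(c(1, refl))
    # residual at angle t: 1 - 2*(a*cos t + b*sin t) + 1 with optimal scale;
    # scan angles directly on the residual with closed-form optimal scale
    ang <- seq(0, 2 * pi, by = step)
    C <- crossprod(x, yr)
    a <- C[1, 1] + C[2, 2]; b <- C[2, 1] - C[1, 2]
    tr <- a * cos(ang) + b * sin(ang)   # trace(X' Y R(t))
    # optimal uniform scale c minimises 1 - 2 c tr + c^2 -> c = tr, m2 = 1 - tr^2
    best <- min(best, min(1 - pmax(tr, 0)^2))
  }
  best
}
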