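test_that("min-max scaling maps extremes and is affine-invariant", {
  expect_equal(minmax_scale(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.3, 1)
  expect_equal(minmax_scale(x), x)                 # idempotent on [0,1]
  set.seed(91)
  y <- rnorm(20)
  expect_equal(minmax_scale(3 * y + 7), minmax_scale(y), tolerance = 1e-12)
  expect_error(minmax_scale(rep(2, 5)), "constant")
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(s <- minmax_scale_columns(m), "b")
  expect_identical(colnames(s), "a")
})

test_that("PCA axes are ordered, orthonormal, sign-fixed, and reconstructive", {
  set.seed(92)
  x <- cbind(a = rnorm(20))
  x <- cbind(x, b = 2 * x[, "a"])                  # perfectly correlated
  res <- pca_axes(x)
  expect_equal(res$variance_pct[1], 100, tolerance = 1e-9)
  y <- matrix(rnorm(30 * 5), 30, dimnames = list(NULL, paste0("v", 1:5)))
  r <- pca_axes(y)
  expect_equal(ncol(r$scores), 5)
  expect_equal(crossprod(r$loadings), diag(5), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(r$variance_pct) <= 1e-12))
  # sign rule: the largest-magnitude loading of each axis is negative
  for (j in seq_len(ncol(r$loadings)))
    expect_lt(r$loadings[which.max(abs(r$loadings[, j])), j], 0)
  # reconstruction of the centred data from all axes
  centred <- scale(y, scale = FALSE)
  expect_equal(r$scores %*% t(r$loadings), centred, tolerance = 1e-9,
               ignore_attr = TRUE)
  # axis count = min(samples - 1, variables)
  wide <- matrix(rnorm(6 * 10), 6, dimnames = list(NULL, paste0("w", 1:10)))
  expect_equal(ncol(pca_axes(wide)$scores), 5)
})

test_that("forward selection recovers a planted axis and respects its bounds", {
  set.seed(93)
  scores <- matrix(rnorm(24 * 6), 24,
                   dimnames = list(paste0("s", 1:24), paste0("PC", 1:6)))
  resp <- as.matrix(dist(scores[, 3]))
  sel <- dbrda_forward_select(resp, scores, permutations = 199, seed = 5)
  expect_equal(sel$retained$axis[1], "PC3")
  expect_gt(sel$retained$adj_r2_cum[1], 0.95)
  expect_equal(nrow(sel$retained), 1)              # nothing else enters
  # cumulative adjusted R2 is non-decreasing and within the slack of the
  # full model's adjusted R2
  expect_true(all(diff(c(0, sel$retained$adj_r2_cum)) >= -1e-12))
  expect_lte(max(sel$retained$adj_r2_cum), sel$full_adj_r2 + 0.01)
  expect_error(dbrda_forward_select(resp[, c(2:24, 1)], scores),
               "symmetric|aligned")
})

test_that("forward selection rarely retains anything from pure noise", {
  set.seed(94)
  scores <- matrix(rnorm(24 * 6), 24,
                   dimnames = list(paste0("s", 1:24), paste0("PC", 1:6)))
  kept <- vapply(1:8, function(i) {
    set.seed(200 + i)
    r <- as.matrix(dist(setNames(rnorm(24), rownames(scores))))
    nrow(dbrda_forward_select(r, scores, permutations = 199,
                              seed = i)$retained)
  }, numeric(1))
  expect_gte(sum(kept == 0), 7)
})

test_that("a shifted negative-valued response is handled like a distance", {
  set.seed(95)
  scores <- matrix(rnorm(20 * 4), 20,
                   dimnames = list(paste0("s", 1:20), paste0("PC", 1:4)))
  # betaNTI-like response: signal on axis 2, values straddling zero
  resp <- as.matrix(dist(scores[, 2])) - 1.5
  diag(resp) <- 0
  sel <- dbrda_forward_select(resp, scores, permutations = 199, seed = 3)
  expect_equal(sel$retained$axis[1], "PC2")
})

test_that("driver attribution picks the max-|loading| variable per axis", {
  fx <- loading_fixture()
  att <- attribute_drivers(c("PC2", "PC24", "PC8"), c("PC9", "PC5", "PC11"),
                           fx$loadings, env_vars = fx$env_vars)
  pa <- att$per_axis
  expect_equal(pa$top_env_variable[pa$axis == "PC2"], "pH")
  expect_equal(pa$top_env_loading[pa$axis == "PC2"], -0.7301)
  expect_equal(pa$top_env_variable[pa$axis == "PC5"], "Moisture")
  expect_equal(pa$top_env_loading[pa$axis == "PC5"], -0.7764)
  expect_equal(pa$process[pa$axis == "PC2"], "selection")
  expect_equal(pa$process[pa$axis == "PC5"], "dispersal")
  # invariance under sign flips of whole axes
  flipped <- fx$loadings
  flipped[, c("PC2", "PC5")] <- -flipped[, c("PC2", "PC5")]
  att2 <- attribute_drivers(c("PC2", "PC24", "PC8"), c("PC9", "PC5", "PC11"),
                            flipped, env_vars = fx$env_vars)
  expect_equal(att2$per_axis$top_env_variable, pa$top_env_variable)
  # single axis, single variable
  L1 <- matrix(0.4, 1, 1, dimnames = list("only", "PC1"))
  a1 <- attribute_drivers("PC1", character(0), L1)
  expect_equal(a1$per_axis$top_variable, "only")
  # empty retained sets are a valid, empty attribution
  a0 <- attribute_drivers(character(0), character(0), fx$loadings)
  expect_equal(nrow(a0$per_axis), 0)
})

test_that("RDA explained spans its closed-form extremes and null level", {
  set.seed(96)
  env <- matrix(rnorm(24 * 3), 24,
                dimnames = list(paste0("s", 1:24), c("a", "b", "c")))
  lin <- env %*% matrix(runif(3 * 15), 3, 15)
  lin <- lin - min(lin)
  colnames(lin) <- paste0("x", 1:15)
  rownames(lin) <- rownames(env)
  expect_equal(rda_explained(lin, env, transform = "identity"), 100,
               tolerance = 1e-6)
  # community orthogonal to the constraints (centred design, as RDA fits)
  comm <- matrix(rnorm(24 * 10), 24)
  X <- cbind(1, env)
  comm <- comm - X %*% solve(crossprod(X), crossprod(X, comm))
  comm <- comm - min(comm)
  dimnames(comm) <- list(rownames(env), paste0("y", 1:10))
  expect_lt(rda_explained(comm, env, transform = "identity"), 1e-6)
  # random community: expected explained fraction ~ q / (n - 1)
  set.seed(97)
  vals <- replicate(20, {
    rc <- matrix(rpois(24 * 40, 20), 24, 40,
                 dimnames = list(rownames(env), paste0("z", 1:40)))
    rda_explained(rc, env)
  })
  expect_lt(abs(mean(vals) / 100 - 3 / 23), 0.04)
  expect_error(rda_explained(lin[1:3, ], env[1:3, ]), "constraints")
})

test_that("the random-subcommunity control is calibrated for random sets", {
  set.seed(98)
  tab <- random_table(20, 40, seed = 99, lambda = 10)
  env <- matrix(rnorm(20 * 3), 20,
                dimnames = list(rownames(tab), c("a", "b", "c")))
  ps <- vapply(1:30, function(i) {
    set.seed(300 + i)
    ids <- sample(colnames(tab), 8)
    random_subcommunity_test(tab, env, ids, n_draws = 49,
                             seed = i)$p_two_sided
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.2)   # near-nominal type-I rate
  expect_gte(min(ps), 1 / 50)        # add-one convention: never zero
  expect_warning(random_subcommunity_test(tab, env, colnames(tab),
                                          n_draws = 9, seed = 1),
                 "degenerate")
})

test_that("the |betaNTI| response transform recovers the same planted axis", {
  set.seed(77)
  scores <- matrix(rnorm(20 * 4), 20,
                   dimnames = list(paste0("s", 1:20), paste0("PC", 1:4)))
  resp <- as.matrix(dist(scores[, 2])) - 1.5   # signed, betaNTI-like
  diag(resp) <- 0
  sel <- dbrda_forward_select(resp, scores, permutations = 199, seed = 2,
                              response_transform = "abs")
  expect_equal(sel$retained$axis[1], "PC2")
})
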