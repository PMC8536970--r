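test_that("taxon correlations behave on exact and null inputs", {
  set.seed(81)
  base <- rpois(8, 40) + 10L
  m <- cbind(t1 = base, t2 = 2L * base, t3 = rpois(8, 30) + 5L,
             t4 = rpois(8, 30) + 5L)
  rownames(m) <- paste0("s", 1:8)
  cm <- correlation_matrix(otu_table(m), transform = "none")
  expect_equal(cm["t1", "t2"], 1, tolerance = 1e-12)
  expect_equal(diag(cm), setNames(rep(1, 4), colnames(cm)))
  expect_true(isSymmetric(unclass(cm)))
  # independent noise: mean off-diagonal |r| near E|r| for n = 8
  set.seed(82)
  big <- matrix(rpois(8 * 50, 50), 8, 50,
                dimnames = list(paste0("s", 1:8), paste0("t", 1:50)))
  cb <- correlation_matrix(otu_table(big), transform = "none")
  offdiag <- abs(cb[upper.tri(cb)])
  expect_lt(abs(mean(offdiag) - sqrt(2 / pi) / sqrt(7)), 0.06)
  expect_error(correlation_matrix(otu_table(m[1:3, ])), "fewer than 4")
})

test_that("the RMT scan finds a threshold that splits planted blocks", {
  set.seed(42)
  n <- 30
  lat <- matrix(rnorm(n * 2), n)
  X <- cbind(lat[, 1] %o% rep(1, 20) + 0.35 * matrix(rnorm(n * 20), n),
             lat[, 2] %o% rep(1, 20) + 0.35 * matrix(rnorm(n * 20), n))
  colnames(X) <- paste0("t", 1:40)
  thr <- rmt_threshold(cor(X))
  expect_false(thr$fallback_used)
  expect_gt(thr$threshold, 0.30)
  expect_lt(thr$threshold, 0.90)
  net <- build_network(cor(X), thr$threshold)
  mod <- detect_modules(net)
  blk <- as.integer(sub("t", "", names(mod$membership))) <= 20
  expect_equal(mod$n_modules, 2)
  expect_true(all(table(mod$membership, blk) %in%
                    c(0, tabulate(mod$membership))))
})

test_that("degenerate or tiny correlation matrices fall back", {
  expect_warning(
    res <- rmt_threshold(diag(10), fallback = 0.8), "too small")
  expect_true(res$fallback_used)
  expect_equal(res$threshold, 0.8)
  expect_warning(res2 <- rmt_threshold(diag(30), fallback = 0.7))
  expect_true(res2$fallback_used)
})

test_that("network construction follows the |r| >= s_t edge rule", {
  A <- diag(4)
  rownames(A) <- colnames(A) <- paste0("n", 1:4)
  A[upper.tri(A)] <- A[lower.tri(A)] <- 0.05   # background correlations
  A["n1", "n2"] <- A["n2", "n1"] <- 0.9
  A["n1", "n3"] <- A["n3", "n1"] <- -0.8
  A["n3", "n4"] <- A["n4", "n3"] <- 0.75
  A["n2", "n4"] <- A["n4", "n2"] <- 0.1
  net <- build_network(A, 0.7)
  expect_equal(igraph::ecount(net), 3)  # both signs count as edges
  expect_error(build_network(A, 0.95), "no edge")
  full <- build_network(A, 1e-6)
  expect_equal(igraph::ecount(full), choose(4, 2))
  # threshold monotonicity: raising s_t never adds edges
  e1 <- igraph::ecount(build_network(A, 0.7))
  e2 <- igraph::ecount(build_network(A, 0.8))
  expect_lte(e2, e1)
})

test_that("greedy modularity resolves disjoint cliques exactly", {
  A <- matrix(0, 8, 8, dimnames = list(paste0("n", 1:8), paste0("n", 1:8)))
  A[1:4, 1:4] <- 0.9
  A[5:8, 5:8] <- 0.9
  diag(A) <- 1
  net <- build_network(A, 0.5)
  mod <- detect_modules(net)
  expect_equal(mod$modularity, 0.5, tolerance = 1e-12)
  expect_equal(mod$n_modules, 2)
  expect_equal(length(unique(mod$membership[paste0("n", 1:4)])), 1)
  expect_equal(length(unique(mod$membership[paste0("n", 5:8)])), 1)
  # complete graph: one module, Q = 0
  K <- matrix(0.9, 6, 6, dimnames = list(paste0("m", 1:6), paste0("m", 1:6)))
  diag(K) <- 1
  modK <- detect_modules(build_network(K, 0.5))
  expect_equal(modK$n_modules, 1)
  expect_equal(modK$modularity, 0)
  expect_gte(mod$modularity, -0.5)
  expect_lte(mod$modularity, 1)
})

test_that("planted multi-block graphs are recovered across seeds", {
  recovered <- 0
  for (s in 1:5) {
    set.seed(900 + s)
    n <- 60
    memb_true <- rep(1:3, each = 20)
    A <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      p <- if (memb_true[i] == memb_true[j]) 0.9 else 0.05
      A[i, j] <- A[j, i] <- rbinom(1, 1, p) * 0.9
    }
    diag(A) <- 1
    rownames(A) <- colnames(A) <- paste0("v", 1:n)
    mod <- detect_modules(build_network(A, 0.5), seed = s)
    tab <- table(mod$membership, memb_true[match(names(mod$membership),
                                                 paste0("v", 1:n))])
    acc <- sum(apply(tab, 2, max)) / sum(tab)
    if (acc >= 0.9) recovered <- recovered + 1
  }
  expect_gte(recovered, 4)
})

test_that("Zi and Pi match their defining formulas", {
  # star of 11 nodes, single module: center has max Zi; all Pi = 0
  n <- 11
  A <- matrix(0, n, n, dimnames = list(paste0("v", 1:n), paste0("v", 1:n)))
  A[1, 2:n] <- A[2:n, 1] <- 0.9
  A[2, 3] <- A[3, 2] <- 0.9  # breaks the degree tie so sd > 0
  diag(A) <- 1
  net <- build_network(A, 0.5)
  memb <- setNames(rep(1L, n), paste0("v", 1:n))
  roles <- zi_pi(net, memb)
  deg <- roles$degree
  zi_oracle <- (deg - mean(deg)) / sd(deg)
  expect_equal(roles$zi, zi_oracle, tolerance = 1e-12)
  expect_equal(which.max(roles$zi), 1L)
  expect_true(all(roles$pi == 0))
  expect_equal(sum(roles$zi), 0, tolerance = 1e-9)
})

test_that("Pi is 0.5 for an even two-module split and bounded by 1 - 1/M", {
  # v1 has one link into each of two 2-node modules
  A <- matrix(0, 5, 5, dimnames = list(paste0("v", 1:5), paste0("v", 1:5)))
  A[1, 2] <- A[2, 1] <- 0.9
  A[1, 4] <- A[4, 1] <- 0.9
  A[2, 3] <- A[3, 2] <- 0.9
  A[4, 5] <- A[5, 4] <- 0.9
  diag(A) <- 1
  net <- build_network(A, 0.5)
  memb <- setNames(c(1L, 1L, 1L, 2L, 2L), paste0("v", 1:5))
  roles <- zi_pi(net, memb)
  expect_equal(roles$pi[roles$taxon == "v1"], 0.5)
  expect_true(all(roles$pi <= 1 - 1 / 2 + 1e-12))
  expect_error(zi_pi(net, memb[-1]), "cover")
})

test_that("keystone roles partition the Zi-Pi plane at 2.5 and 0.62", {
  grid <- data.frame(taxon = paste0("x", 1:6), module = 1L, degree = 5L,
                     zi = c(3.0, 1.0, 3.0, 2.5, 0.0, 2.6),
                     pi = c(0.10, 0.70, 0.70, 0.62, 0.50, 0.62),
                     zi_flagged = FALSE)
  roles <- classify_keystones(grid)
  expect_equal(roles$role,
               c("module_hub", "connector", "network_hub",
                 "peripheral",   # both exactly at threshold: not exceeded
                 "peripheral", "module_hub"))
  ks <- keystone_taxa(grid)
  expect_setequal(ks$taxon, c("x1", "x2", "x3", "x6"))
  # permutation of rows leaves roles untouched
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(classify_keystones(grid[perm, ])$role, roles$role[perm])
})
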