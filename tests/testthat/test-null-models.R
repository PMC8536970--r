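test_that("betaMNTD handles the degenerate hand cases", {
  tr <- hand_tree()
  m <- rbind(s1 = c(3L, 0L, 0L), s2 = c(0L, 5L, 0L), s3 = c(3L, 0L, 0L))
  colnames(m) <- c("A", "B", "C")
  b <- beta_mntd(otu_table(m), tr)
  expect_equal(b["s1", "s3"], 0)          # identical communities
  expect_equal(b["s1", "s2"], 2)          # single-taxon pair: d(A,B)
  expect_true(isSymmetric(b))
})

test_that("betaMNTD equals the brute-force double-loop oracle", {
  for (case in 1:20) {
    tr <- simulate_tree(5, seed = 300 + case)
    tab <- random_table(4, 5, seed = 600 + case, lambda = 3)
    for (aw in c(TRUE, FALSE)) {
      expect_equal(beta_mntd(tab, tr, abundance_weighted = aw),
                   bmntd_bruteforce(tab, tr, abundance_weighted = aw),
                   tolerance = 1e-12)
    }
  }
})

test_that("betaMNTD agrees with an independent library implementation", {
  skip_if_not_installed("picante")
  tr <- simulate_tree(12, seed = 21)
  tab <- random_table(5, 12, seed = 22, lambda = 2)
  ours <- beta_mntd(tab, tr, abundance_weighted = TRUE)
  theirs <- as.matrix(picante::comdistnt(unclass(tab),
                                         ape::cophenetic.phylo(tr),
                                         abundance.weighted = TRUE))
  theirs <- theirs[rownames(ours), colnames(ours)]
  diag(theirs) <- 0
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("betaNTI is zero and flagged on a star phylogeny", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  m <- rbind(s1 = c(2L, 3L, 0L, 0L), s2 = c(0L, 0L, 4L, 1L),
             s3 = c(1L, 0L, 2L, 0L))
  colnames(m) <- c("A", "B", "C", "D")
  bn <- beta_nti(otu_table(m), star, reps = 99, seed = 1)
  expect_true(all(bn$bnti == 0))
  expect_true(all(bn$flagged[upper.tri(bn$flagged)]))
})

test_that("fully shared communities have an invariant null and are flagged", {
  # under the tip-shuffle null a taxon shared by both communities is its
  # own nearest relative at distance zero whatever the shuffle, so
  # identical communities have betaMNTD 0 in the observed data and in
  # every null replicate: the pair is flagged, not scored
  tr <- simulate_tree(30, seed = 31)
  set.seed(401)
  base <- rpois(30, 3) + 1L
  m <- rbind(s1 = base, s2 = base, s3 = rpois(30, 3) + 1L)
  storage.mode(m) <- "integer"
  colnames(m) <- tr$tip.label
  bn <- beta_nti(otu_table(m), tr, reps = 199, seed = 1)
  expect_equal(bn$bnti["s1", "s2"], 0)
  expect_true(bn$flagged["s1", "s2"])
})

test_that("clade-confined disjoint communities give strongly negative betaNTI", {
  # two communities drawn from the same small clade, sharing no taxa:
  # observed nearest-taxon distances are tiny against a 30-taxon pool
  clade <- paste0("(", paste0("c", 1:8, ":0.05", collapse = ","), "):3")
  bg <- paste0("(", paste0("b", 1:22, ":1", collapse = ","), "):1")
  tr <- ape::read.tree(text = paste0("(", clade, ",", bg, ");"))
  hits <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    m <- matrix(0L, 3, 30,
                dimnames = list(c("s1", "s2", "s3"),
                                c(paste0("c", 1:8), paste0("b", 1:22))))
    m["s1", 1:4] <- rpois(4, 5) + 1L
    m["s2", 5:8] <- rpois(4, 5) + 1L
    m["s3", 9:30] <- rpois(22, 3) + 1L    # background keeps the pool wide
    bn <- beta_nti(otu_table(m), tr, reps = 199, seed = s)
    if (bn$bnti["s1", "s2"] <= -2) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("betaNTI is symmetric and invariant to sample order", {
  tr <- simulate_tree(15, seed = 41)
  tab <- random_table(5, 15, seed = 42, lambda = 2)
  bn <- beta_nti(tab, tr, reps = 99, seed = 7)
  expect_true(isSymmetric(bn$bnti))
  perm <- c(3, 1, 5, 2, 4)
  tab2 <- otu_table(unclass(tab)[perm, ])
  bn2 <- beta_nti(tab2, tr, reps = 99, seed = 7)
  expect_equal(bn2$bnti, bn$bnti[perm, perm], tolerance = 1e-12)
})

test_that("Raup-Crick flags identical samples as less dissimilar than null", {
  hits <- 0
  for (s in 1:10) {
    set.seed(500 + s)
    pool <- rpois(12, 4) + 1L
    other <- matrix(rpois(24, 4) + 1L, 2, 12)
    m <- rbind(s1 = pool, s2 = pool, s3 = other[1, ], s4 = other[2, ])
    storage.mode(m) <- "integer"
    colnames(m) <- paste0("t", 1:12)
    rc <- raup_crick_bray(otu_table(m), reps = 999, seed = s)
    if (rc$rc["s1", "s2"] <= -0.95) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("Raup-Crick is bounded, deterministic, and order-invariant", {
  tab <- random_table(5, 10, seed = 52, lambda = 3)
  rc1 <- raup_crick_bray(tab, reps = 199, seed = 9)
  rc2 <- raup_crick_bray(tab, reps = 199, seed = 9)
  expect_identical(rc1$rc, rc2$rc)
  expect_true(all(rc1$rc >= -1 & rc1$rc <= 1))
  expect_true(isSymmetric(rc1$rc))
  perm <- c(4, 2, 5, 1, 3)
  rc3 <- raup_crick_bray(otu_table(unclass(tab)[perm, ]), reps = 199,
                         seed = 9)
  expect_equal(rc3$rc, rc1$rc[perm, perm], tolerance = 1e-12)
})

test_that("process classification follows the two-index decision rule", {
  # betaNTI takes precedence; >= 2 marks variable (heterogeneous) selection
  expect_equal(as.character(classify_pair(2.5, 0.1)),
               "heterogeneous_selection")
  expect_equal(as.character(classify_pair(2.5, -0.99)),
               "heterogeneous_selection")
  expect_equal(as.character(classify_pair(-2.5, 0.99)),
               "homogeneous_selection")
  expect_equal(as.character(classify_pair(0.5, 0.97)),
               "dispersal_limitation")
  expect_equal(as.character(classify_pair(-1.9, -0.96)),
               "homogenizing_dispersal")
  expect_equal(as.character(classify_pair(0, 0)), "undominated")
  # boundaries are inclusive for the significance thresholds
  expect_equal(as.character(classify_pair(2, 0)), "heterogeneous_selection")
  expect_equal(as.character(classify_pair(-2, 0)), "homogeneous_selection")
  expect_equal(as.character(classify_pair(0, 0.95)), "dispersal_limitation")
  expect_equal(as.character(classify_pair(0, -0.95)),
               "homogenizing_dispersal")
  expect_error(classify_pair(NA, 0), "non-finite")
  expect_error(classify_pair(0, 1.5), "outside")
})

test_that("classification is exhaustive and counts close per scope", {
  g <- design_groups()
  ids <- names(g)
  set.seed(61)
  bn <- sym_from_pairs(rnorm(choose(32, 2), 0, 2), ids)
  rc <- sym_from_pairs(runif(choose(32, 2), -1, 1), ids)
  reg <- summarize_contributions(bn, rc, g, "regional")
  expect_equal(attr(reg, "n_pairs"), 496)
  expect_equal(sum(reg$count), 496)
  within <- summarize_contributions(bn, rc, g, "within:TO")
  expect_equal(attr(within, "n_pairs"), choose(8, 2))
  btw <- summarize_contributions(bn, rc, g, "between:TO:BN")
  expect_equal(attr(btw, "n_pairs"), 64)
  # within + between over all scopes partitions the 496 pairs
  total <- sum(vapply(levels(g), function(l)
    attr(summarize_contributions(bn, rc, g, paste0("within:", l)),
         "n_pairs"), numeric(1))) +
    sum(apply(utils::combn(levels(g), 2), 2, function(p)
      attr(summarize_contributions(bn, rc, g,
                                   paste0("between:", p[1], ":", p[2])),
           "n_pairs")))
  expect_equal(total, 496)
  expect_error(summarize_contributions(bn, rc, g, "within:XX"),
               "unknown group")
})

test_that("a single-label scope reports 100 percent", {
  g <- design_groups(c("a", "b"), 3)
  ids <- names(g)
  bn <- sym_from_pairs(rep(3, choose(6, 2)), ids)
  rc <- sym_from_pairs(rep(0, choose(6, 2)), ids)
  s <- summarize_contributions(bn, rc, g, "regional")
  expect_equal(s$percent[s$label == "heterogeneous_selection"], 100)
  expect_equal(sum(s$percent), 100)
})

test_that("keystone subsetting keeps counts and flags empty samples", {
  tab <- random_table(5, 8, seed = 71)
  expect_identical(unclass(keystone_subcommunity(tab, colnames(tab)))[, ],
                   unclass(tab)[, ])
  sub <- keystone_subcommunity(tab, c("t2", "t5"))
  expect_identical(dim(sub), c(5L, 2L))
  expect_true(all(rowSums(unclass(sub)) <= rowSums(unclass(tab))))
  expect_error(keystone_subcommunity(tab, "nope"), "unknown taxon")
  m <- unclass(tab)
  m[1, c(2, 5)] <- 0L
  m[1, 1] <- 5L
  expect_warning(keystone_subcommunity(otu_table(m), c("t2", "t5")),
                 "excluded")
})

test_that("the per-pair-pool null is a valid, order-invariant variant", {
  tr <- simulate_tree(12, seed = 81)
  tab <- random_table(4, 12, seed = 82, lambda = 2)
  bn <- beta_nti(tab, tr, reps = 99, seed = 3, null_pool = "pair")
  expect_true(isSymmetric(bn$bnti))
  expect_true(all(is.finite(bn$bnti)))
  perm <- c(3, 1, 4, 2)
  bn2 <- beta_nti(otu_table(unclass(tab)[perm, ]), tr, reps = 99,
                  seed = 3, null_pool = "pair")
  expect_equal(bn2$bnti, bn$bnti[perm, perm], tolerance = 1e-12)
})
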