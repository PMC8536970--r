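# ---------------------------------------------------------------------------
# Phylogenetic turnover: betaMNTD / betaNTI
# ---------------------------------------------------------------------------

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For each taxon in one community, the patristic distance to its closest
#' relative in the other community, averaged over taxa and symmetrised
#' between the two directions. The abundance-weighted form (default)
#' weights each taxon's nearest-relative distance by its relative
#' abundance; the unweighted form averages over present taxa.
#'
#' A taxon shared by both communities contributes zero distance, so
#' identical communities have betaMNTD 0.
#'
#' @param table an [otu_table]; every taxon with a positive count must be a
#'   tip of `tree`.
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param abundance_weighted logical, default `TRUE`.
#' @return symmetric samples x samples matrix with zero diagonal.
#' @export
beta_mntd <- function(table, tree, abundance_weighted = TRUE) {
  m <- unclass_counts(as_otu_table(table))
  pool <- colnames(m)[colSums(m) > 0]
  if (length(pool) < 2) stop("fewer than 2 taxa in the regional pool")
  D <- patristic_distances(tree, pool)
  bmntd_from_dist(m[, pool, drop = FALSE], D, abundance_weighted)
}

# core betaMNTD given a count matrix (samples x pool taxa) and the matching
# patristic matrix; D's row/col order must equal the column order of m
bmntd_from_dist <- function(m, D, abundance_weighted) {
  P <- t(m)                                # taxa x samples
  pres <- P > 0
  if (any(colSums(pres) == 0)) stop("sample with no taxa")
  W <- if (abundance_weighted) {
    sweep(P, 2, colSums(P), "/")
  } else {
    sweep(pres * 1, 2, colSums(pres), "/")
  }
  M <- nearest_taxon_dist(D, pres)         # taxa x samples, M[i,l] = d(i, comm l)
  X <- crossprod(W, M)                     # X[k,l] = mean_{i in k} d(i, comm l)
  B <- (X + t(X)) / 2
  dimnames(B) <- list(rownames(m), rownames(m))
  diag(B) <- 0
  B
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standard-effect size of observed betaMNTD against a null that shuffles
#' taxon labels across the tips of the regional pool (taxa present in at
#' least one sample), independently for each replicate:
#' betaNTI = (betaMNTD_obs - mean null) / sd null. One shuffle per
#' replicate is applied to all sample pairs, so results do not depend on
#' the order pairs are evaluated in.
#'
#' Pairs with zero null standard deviation (e.g. on a star phylogeny,
#' where shuffling cannot change any distance) are set to 0 and flagged.
#'
#' @inheritParams beta_mntd
#' @param reps null replicates (>= 99; default 999).
#' @param seed integer seed.
#' @param null_pool `"regional"` (default) shuffles over the taxa present
#'   in any sample; `"pair"` restricts each pair's null to the taxa
#'   present in that pair (per-pair RNG streams seeded from the master
#'   seed and the sample ids).
#' @return object of class `beta_nti`: list with `bnti` (symmetric matrix),
#'   `observed` betaMNTD, `flagged` (logical matrix, sd-zero pairs),
#'   `reps`, `seed`, `abundance_weighted`.
#' @export
beta_nti <- function(table, tree, reps = 999, abundance_weighted = TRUE,
                     seed = 1L, null_pool = c("regional", "pair")) {
  null_pool <- match.arg(null_pool)
  if (reps < 99) stop("reps must be at least 99")
  m <- unclass_counts(as_otu_table(table))
  pool <- colnames(m)[colSums(m) > 0]
  if (length(pool) < 2) stop("fewer than 2 taxa in the regional pool")
  D <- patristic_distances(tree, pool)
  mm <- m[, pool, drop = FALSE]
  obs <- bmntd_from_dist(mm, D, abundance_weighted)

  n <- nrow(mm)
  s1 <- matrix(0, n, n)
  s2 <- matrix(0, n, n)
  if (null_pool == "regional") {
    set.seed(seed)
    for (r in seq_len(reps)) {
      perm <- sample.int(length(pool))
      Dn <- D[perm, perm]
      dimnames(Dn) <- dimnames(D)
      b <- bmntd_from_dist(mm, Dn, abundance_weighted)
      s1 <- s1 + b
      s2 <- s2 + b * b
    }
  } else {
    ids <- rownames(mm)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        sub <- colSums(mm[c(i, j), , drop = FALSE]) > 0
        Dp <- D[sub, sub, drop = FALSE]
        mp <- mm[c(i, j), sub, drop = FALSE]
        set.seed(pair_stream_seed(seed, ids[i], ids[j]))
        for (r in seq_len(reps)) {
          perm <- sample.int(ncol(mp))
          Dn <- Dp[perm, perm]
          dimnames(Dn) <- dimnames(Dp)
          b <- bmntd_from_dist(mp, Dn, abundance_weighted)[1, 2]
          s1[i, j] <- s1[i, j] + b
          s2[i, j] <- s2[i, j] + b * b
        }
        s1[j, i] <- s1[i, j]
        s2[j, i] <- s2[i, j]
      }
    }
  }
  mu <- s1 / reps
  va <- pmax(s2 / reps - mu^2, 0) * reps / (reps - 1)
  sdn <- sqrt(va)
  # relative tolerance: a null that is invariant up to floating-point
  # round-off (star trees, fully shared communities) counts as sd = 0;
  # the running-sum variance loses ~half the mantissa to cancellation,
  # hence the comfortably loose 1e-6 (real null sds are >= 1e-3)
  flagged <- sdn <= 1e-6 * (abs(mu) + 1)
  bnti <- matrix(0, n, n, dimnames = dimnames(obs))
  ok <- !flagged
  bnti[ok] <- (obs[ok] - mu[ok]) / sdn[ok]
  diag(bnti) <- 0
  diag(flagged) <- FALSE
  structure(list(bnti = bnti, observed = obs, flagged = flagged,
                 reps = reps, seed = seed,
                 abundance_weighted = abundance_weighted),
            class = "beta_nti")
}

# ---------------------------------------------------------------------------
# Taxonomic turnover: Raup-Crick with Bray-Curtis
# ---------------------------------------------------------------------------

# deterministic per-pair seed from the master seed and the two sample ids
# (order-insensitive), kept below 2^31
pair_stream_seed <- function(seed, a, b) {
  key <- paste(sort(c(a, b)), collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483587
  as.integer((seed %% 2147483587 + 7919 * h) %% 2147483646 + 1)
}

#' Raup-Crick turnover metric with Bray-Curtis dissimilarity
#'
#' For each sample pair, null communities are assembled probabilistically:
#' each sample's observed richness and total abundance are preserved, taxon
#' identities are drawn without replacement with probability proportional
#' to regional occupancy, and individuals are then allocated proportional
#' to regional relative abundance. RC = 2[(#null < obs) + 0.5 (#null =
#' obs)]/reps - 1, clamped to [-1, 1]; values above 0.95 (below -0.95)
#' mark significantly higher (lower) turnover than the stochastic
#' expectation.
#'
#' Each pair consumes its own RNG stream whose seed is derived from the
#' master seed and the (sorted) pair of sample ids, so results are
#' independent of both the order pairs are evaluated in and the row order
#' of the table.
#'
#' @param table an [otu_table].
#' @param reps null replicates per pair (default 999).
#' @param seed master integer seed.
#' @return object of class `rc_bray`: list with `rc` (symmetric matrix in
#'   [-1, 1]), `reps`, `seed`.
#' @export
raup_crick_bray <- function(table, reps = 999, seed = 1L) {
  if (reps < 1) stop("reps must be positive")
  m <- unclass_counts(as_otu_table(table))
  if (any(rowSums(m) == 0)) stop("sample with zero total count")
  n <- nrow(m)
  occup <- colSums(m > 0)
  regab <- colSums(m) / sum(m)
  rc <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  ids <- rownames(m)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      set.seed(pair_stream_seed(seed, ids[i], ids[j]))
      # canonical orientation (sorted ids) so the null stream, and hence
      # the value, does not depend on the table's row order
      pr <- if (ids[i] <= ids[j]) c(i, j) else c(j, i)
      v <- rc_bray_pair(m[pr[1], ], m[pr[2], ], occup, regab,
                        as.integer(reps))
      rc[i, j] <- v
      rc[j, i] <- v
    }
  }
  structure(list(rc = rc, reps = reps, seed = seed), class = "rc_bray")
}

# ---------------------------------------------------------------------------
# Process classification
# ---------------------------------------------------------------------------

#' Assembly-process labels
#' @return character vector of the five process labels in canonical order.
#' @export
process_labels <- function() {
  c("heterogeneous_selection", "homogeneous_selection",
    "dispersal_limitation", "homogenizing_dispersal", "undominated")
}

#' Classify a sample pair into an assembly process
#'
#' The betaNTI test takes precedence: betaNTI >= 2 is heterogeneous
#' (variable) selection and betaNTI <= -2 homogeneous selection. For
#' |betaNTI| < 2, RC >= 0.95 is drift under dispersal limitation,
#' RC <= -0.95 homogenizing dispersal, and anything else undominated (no
#' single process significant).
#'
#' @param bnti numeric vector of betaNTI values.
#' @param rc numeric vector of RC values in [-1, 1], recycled against
#'   `bnti`.
#' @return factor with levels [process_labels()].
#' @export
classify_pair <- function(bnti, rc) {
  k <- max(length(bnti), length(rc))
  bnti <- rep_len(bnti, k); rc <- rep_len(rc, k)
  if (any(!is.finite(bnti)) || any(!is.finite(rc)))
    stop("non-finite betaNTI or RC value")
  if (any(rc < -1 - 1e-9 | rc > 1 + 1e-9)) stop("RC outside [-1, 1]")
  lab <- ifelse(bnti >= 2, "heterogeneous_selection",
         ifelse(bnti <= -2, "homogeneous_selection",
         ifelse(rc >= 0.95, "dispersal_limitation",
         ifelse(rc <= -0.95, "homogenizing_dispersal", "undominated"))))
  factor(lab, levels = process_labels())
}

#' Per-pair process classification in long format
#'
#' @param bnti a [beta_nti] result or symmetric betaNTI matrix.
#' @param rc an [raup_crick_bray] result or symmetric RC matrix.
#' @param groups optional group map; adds group columns per sample.
#' @return data.frame with one row per unordered sample pair: `sample_a`,
#'   `sample_b`, `bnti`, `rc`, `label` (and groups when given).
#' @export
classify_pairs <- function(bnti, rc, groups = NULL) {
  B <- if (inherits(bnti, "beta_nti")) bnti$bnti else as.matrix(bnti)
  R <- if (inherits(rc, "rc_bray")) rc$rc else as.matrix(rc)
  if (!identical(dim(B), dim(R))) stop("betaNTI and RC matrices not aligned")
  ids <- rownames(B)
  if (!is.null(rownames(R)) && !identical(ids, rownames(R)))
    stop("betaNTI and RC sample ids differ")
  n <- nrow(B)
  idx <- which(upper.tri(B), arr.ind = TRUE)
  df <- data.frame(sample_a = ids[idx[, 1]], sample_b = ids[idx[, 2]],
                   bnti = B[idx], rc = R[idx],
                   stringsAsFactors = FALSE)
  df$label <- classify_pair(df$bnti, df$rc)
  if (!is.null(groups)) {
    g <- align_groups(groups, ids)
    df$group_a <- as.character(g[df$sample_a])
    df$group_b <- as.character(g[df$sample_b])
  }
  df
}

# round half up to one decimal, matching how the contribution percentages
# are conventionally printed
round1_half_up <- function(x) floor(x * 10 + 0.5) / 10

#' Relative contributions of assembly processes
#'
#' Classifies every unordered sample pair in the requested scope and
#' reports counts and percentages (one decimal, round-half-up) per process.
#' Scopes: `regional` (all C(n,2) pairs), `within:<group>` (pairs inside
#' one group), `between:<g1>:<g2>` (cross-group pairs only).
#'
#' @inheritParams classify_pairs
#' @param groups group map covering the samples.
#' @param scope scope string as above (default `"regional"`).
#' @return data.frame with `label`, `count`, `percent`; attributes
#'   `n_pairs` and `scope`.
#' @export
summarize_contributions <- function(bnti, rc, groups, scope = "regional") {
  df <- classify_pairs(bnti, rc, groups)
  parts <- strsplit(scope, ":", fixed = TRUE)[[1]]
  g <- align_groups(groups, unique(c(df$sample_a, df$sample_b)))
  keep <- switch(parts[1],
    regional = rep(TRUE, nrow(df)),
    within = {
      if (length(parts) != 2 || !parts[2] %in% levels(g))
        stop("unknown group label in scope: ", scope)
      df$group_a == parts[2] & df$group_b == parts[2]
    },
    between = {
      if (length(parts) != 3 || !all(parts[2:3] %in% levels(g)))
        stop("unknown group label in scope: ", scope)
      (df$group_a == parts[2] & df$group_b == parts[3]) |
      (df$group_a == parts[3] & df$group_b == parts[2])
    },
    stop("unknown scope: ", scope))
  sub <- df[keep, , drop = FALSE]
  counts <- table(factor(sub$label, levels = process_labels()))
  out <- data.frame(label = names(counts), count = as.integer(counts),
                    percent = round1_half_up(100 * as.integer(counts) /
                                             max(sum(counts), 1)),
                    stringsAsFactors = FALSE)
  attr(out, "n_pairs") <- sum(counts)
  attr(out, "scope") <- scope
  out
}

#' Subset an OTU table to a keystone taxon set
#'
#' Columns are subset with counts unchanged; samples left with a zero
#' keystone total are excluded with a warning (they cannot enter
#' pairwise turnover statistics).
#'
#' @param table an [otu_table].
#' @param keystone_ids taxon ids, all present in the table.
#' @return an [otu_table] restricted to the keystone taxa.
#' @export
keystone_subcommunity <- function(table, keystone_ids) {
  m <- unclass_counts(as_otu_table(table))
  keystone_ids <- unique(as.character(keystone_ids))
  missing <- setdiff(keystone_ids, colnames(m))
  if (length(missing))
    stop("unknown taxon id: ", paste(head(missing, 5), collapse = ", "))
  sub <- m[, keystone_ids, drop = FALSE]
  empty <- rowSums(sub) == 0
  if (any(empty)) {
    warning("samples with zero keystone total excluded: ",
            paste(rownames(sub)[empty], collapse = ", "))
    sub <- sub[!empty, , drop = FALSE]
  }
  otu_table(sub)
}
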