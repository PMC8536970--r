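# ---------------------------------------------------------------------------
# Alpha diversity
# ---------------------------------------------------------------------------

#' Shannon-Wiener diversity of a count vector
#'
#' H = -sum p_i log p_i over taxa with positive counts. Natural log by
#' default, so H is in nats and bounded by log(S).
#'
#' @param counts non-negative numeric vector with at least one positive
#'   entry.
#' @param base logarithm base; `exp(1)` (nats, default) or 2.
#' @return Shannon index (scalar).
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0) || any(!is.finite(counts))) stop("invalid counts")
  tot <- sum(counts)
  if (tot == 0) stop("all-zero count vector")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Chao1 richness estimate
#'
#' S_obs + F1^2 / (2 F2) when doubletons exist; the bias-corrected
#' S_obs + F1 (F1 - 1) / 2 when F2 = 0 (F1 and F2 are the singleton and
#' doubleton counts).
#'
#' @param counts non-negative integer vector.
#' @return estimated richness (scalar).
#' @export
chao1 <- function(counts) {
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("chao1 requires non-negative integer counts")
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

# ---------------------------------------------------------------------------
# Beta diversity
# ---------------------------------------------------------------------------

#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), computed by
#' [vegan::vegdist()]. Identical samples give 0, disjoint supports 1.
#'
#' @param table an [otu_table], count matrix or relative-abundance matrix
#'   (samples x taxa).
#' @return a [stats::dist] object with attribute `metric = "bray-curtis"`.
#' @export
bray_curtis <- function(table) {
  m <- if (is_otu_table(table)) unclass_counts(table) else as.matrix(table)
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (any(rowSums(m) == 0)) stop("sample with zero total count")
  d <- vegan::vegdist(m, method = "bray")
  attr(d, "metric") <- "bray-curtis"
  d
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group ones; R = (mean between-group rank - mean
#' within-group rank) / (n(n-1)/4), with mid-ranks for ties. The p-value
#' uses the add-one permutation convention and so is never zero. Wraps
#' [vegan::anosim()].
#'
#' @param dist a [stats::dist] object or symmetric dissimilarity matrix.
#' @param groups named group map (see [as_group_map()]) covering the
#'   samples of `dist`.
#' @param permutations number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return list with elements `R`, `p`, `permutations`, `seed`.
#' @export
anosim_test <- function(dist, groups, permutations = 999, seed = 1L) {
  if (!inherits(dist, "dist")) {
    m <- as.matrix(dist)
    if (!isSymmetric(unname(m))) stop("dissimilarity matrix not symmetric")
    dist <- as.dist(m)
  }
  ids <- labels(dist)
  g <- align_groups(groups, ids)
  if (nlevels(g) < 2) stop("ANOSIM needs at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 samples")
  set.seed(seed)
  fit <- vegan::anosim(dist, g, permutations = permutations)
  list(R = unname(fit$statistic), p = unname(fit$signif),
       permutations = permutations, seed = seed)
}

#' Group-level presence/absence of taxa
#'
#' A taxon is "present" in a group when it has a positive count in at least
#' half of that group's samples (ceiling at odd sizes; e.g. 4 of 8 counts
#' as present, 3 of 8 does not).
#'
#' @param table an [otu_table].
#' @param groups named group map covering the table's samples.
#' @return logical matrix, groups x taxa.
#' @export
presence_filter <- function(table, groups) {
  m <- unclass_counts(as_otu_table(table))
  g <- align_groups(groups, rownames(m))
  res <- t(vapply(levels(g), function(lv) {
    sub <- m[g == lv, , drop = FALSE]
    colSums(sub > 0) >= ceiling(nrow(sub) / 2)
  }, logical(ncol(m))))
  dimnames(res) <- list(levels(g), colnames(m))
  res
}

#' Principal coordinate analysis (classical multidimensional scaling)
#'
#' Double-centers the squared dissimilarities and eigendecomposes; axes are
#' ordered by eigenvalue and coordinates restricted to positive-eigenvalue
#' axes. Negative eigenvalues (non-Euclidean input) are reported, not
#' silently dropped.
#'
#' @param dist a [stats::dist] or symmetric dissimilarity matrix.
#' @return list with `coordinates` (samples x positive axes), `eigenvalues`
#'   (all, decreasing) and `variance_pct` (percent of positive-eigenvalue
#'   mass per retained axis).
#' @export
pcoa_ordination <- function(dist) {
  if (!inherits(dist, "dist")) {
    m <- as.matrix(dist)
    if (!isSymmetric(unname(m))) stop("asymmetric dissimilarity matrix")
    dist <- as.dist(m)
  }
  n <- attr(dist, "Size")
  # cmdscale warns when fewer than k eigenvalues are positive; that case
  # is handled explicitly below
  fit <- suppressWarnings(cmdscale(dist, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > max(eig) * 1e-12 & eig > 0)
  coords <- fit$points[, pos, drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  list(coordinates = coords,
       eigenvalues = eig,
       variance_pct = 100 * eig[pos] / sum(eig[pos]))
}

# ---------------------------------------------------------------------------
# Taxa-environment correlation screen
# ---------------------------------------------------------------------------

#' Pearson correlation screen between taxa and environmental factors
#'
#' Per taxon-factor pair, the Pearson r and its two-sided t-test p-value.
#' Pairs involving a constant column are returned as NA (undefined, not
#' zero) and flagged.
#'
#' @param taxa abundance matrix, samples x taxa.
#' @param env numeric matrix, samples x factors, same samples as `taxa`.
#' @return list of matrices `r` and `p` (taxa x factors), plus
#'   `constant_taxa` / `constant_factors` flags.
#' @export
pearson_screen <- function(taxa, env) {
  taxa <- as.matrix(taxa); env <- as.matrix(env)
  if (nrow(taxa) != nrow(env)) stop("sample mismatch between taxa and env")
  if (!is.null(rownames(taxa)) && !is.null(rownames(env)) &&
      !identical(rownames(taxa), rownames(env)))
    env <- env[rownames(taxa), , drop = FALSE]
  n <- nrow(taxa)
  if (n < 3) stop("fewer than 3 samples")
  const_t <- apply(taxa, 2, function(x) sd(x) == 0)
  const_e <- apply(env, 2, function(x) sd(x) == 0)
  r <- suppressWarnings(cor(taxa, env))
  r[const_t, ] <- NA
  r[, const_e] <- NA
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  p[is.na(r)] <- NA
  list(r = r, p = p,
       constant_taxa = names(const_t)[const_t],
       constant_factors = names(const_e)[const_e])
}
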