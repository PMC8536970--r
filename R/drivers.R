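# ---------------------------------------------------------------------------
# Scaling and PCA
# ---------------------------------------------------------------------------

#' Min-max scale a vector to [0, 1]
#'
#' (x - min) / (max - min); the minimum maps to 0 and the maximum to 1.
#' Affine-invariant for positive slopes. Constant vectors are an error --
#' they carry no contrast and are excluded upstream.
#'
#' @param x numeric vector.
#' @return scaled vector in [0, 1].
#' @export
minmax_scale <- function(x) {
  if (any(!is.finite(x))) stop("non-finite values")
  r <- range(x)
  if (r[1] == r[2]) stop("constant vector cannot be min-max scaled")
  (x - r[1]) / (r[2] - r[1])
}

#' Min-max scale the columns of a matrix
#'
#' Constant columns are dropped with a warning rather than scaled.
#'
#' @param x numeric matrix (samples x variables).
#' @return matrix of column-wise [minmax_scale()] values; attribute
#'   `dropped` lists excluded constant columns.
#' @export
minmax_scale_columns <- function(x) {
  x <- as.matrix(x)
  const <- apply(x, 2, function(v) min(v) == max(v))
  if (any(const))
    warning("constant columns excluded from scaling: ",
            paste(colnames(x)[const], collapse = ", "))
  out <- apply(x[, !const, drop = FALSE], 2, minmax_scale)
  rownames(out) <- rownames(x)
  attr(out, "dropped") <- colnames(x)[const]
  out
}

#' Principal component analysis with a fixed sign convention
#'
#' Eigendecomposition of the covariance of the column-centred input
#' (no further variable scaling: inputs are expected to be min-max scaled
#' already). Axes are ordered by eigenvalue. Sign convention: each axis is
#' flipped, if needed, so that its largest-magnitude loading is negative;
#' this makes axes reproducible across platforms (attribution later uses
#' absolute loadings, so the convention is cosmetic).
#'
#' @param x numeric matrix, samples x variables (>= 3 samples, >= 2
#'   variables).
#' @return list with `scores` (samples x axes), `loadings` (variables x
#'   axes, orthonormal columns), `variance_pct` (non-increasing, sums to
#'   100 over returned axes).
#' @export
pca_axes <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3 || ncol(x) < 2) stop("need >= 3 samples and >= 2 variables")
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  keep <- pr$sdev > pr$sdev[1] * 1e-10
  if (!any(keep)) stop("rank-0 input")
  L <- pr$rotation[, keep, drop = FALSE]
  S <- pr$x[, keep, drop = FALSE]
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] > 0) { L[, j] <- -L[, j]; S[, j] <- -S[, j] }
  }
  v <- pr$sdev[keep]^2
  list(scores = S, loadings = L, variance_pct = 100 * v / sum(pr$sdev^2))
}

# ---------------------------------------------------------------------------
# dbRDA forward selection
# ---------------------------------------------------------------------------

# shift a (possibly negative-valued) symmetric association matrix to a
# non-negative dissimilarity: when negative entries exist, subtract the
# off-diagonal minimum and keep the zero diagonal; an already non-negative
# response is left untouched (shifting it would only distort its geometry)
shift_nonnegative <- function(m) {
  m <- as.matrix(m)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("response matrix not symmetric")
  off <- m[upper.tri(m) | lower.tri(m)]
  if (min(off) < 0) m <- m - min(off)
  diag(m) <- 0
  as.dist(m)
}

#' Forward model selection of predictor axes against a turnover matrix
#'
#' Fits a distance-based redundancy analysis of the response matrix
#' (betaNTI or RC, which are not metric distances: the matrix is first
#' shifted by its off-diagonal minimum to a non-negative dissimilarity,
#' then embedded with a Lingoes correction via [vegan::capscale()]) on the
#' supplied predictor axes, and forward-selects axes on adjusted R-squared
#' (Ezekiel correction). A global permutation test of the full model acts
#' as gatekeeper: when the full model is not significant at `alpha`,
#' nothing is selected (without this, picking the best of many candidate
#' axes inflates the type-I error of the entry tests far beyond `alpha`).
#' At each step the candidate with the largest adjusted-R-squared gain
#' enters if its permutation p-value is below `alpha`. Selection stops
#' when (a) the best candidate's permutation p exceeds `alpha`, (b) the
#' model's adjusted R-squared would exceed the full-model adjusted
#' R-squared by more than `r2_slack`, or (c) no candidate improves the
#' adjusted R-squared. When the full model is saturated (as many axes as
#' residual degrees of freedom) its adjusted R-squared is undefined and
#' rule (b) is inapplicable; `full_adj_r2` is then `NA` and only rules
#' (a) and (c) stop the selection.
#'
#' `r2_slack` exists because when a single predictor carries essentially
#' all of the explainable structure, its adjusted R-squared equals the
#' full model's in expectation and fluctuates around it, so a strict
#' global-R-squared guard would halt the selection by a coin flip; one
#' adjusted-R-squared percentage point of slack covers that sampling
#' fluctuation while still vetoing genuinely overshooting candidates. An
#' exact (zero-residual) fit has an undefined permutation F; it is treated
#' as maximally significant.
#'
#' @param response symmetric numeric matrix (samples x samples) aligned to
#'   the rows of `predictors`.
#' @param predictors samples x axes matrix of predictor scores (e.g.
#'   `pca_axes(...)$scores`).
#' @param permutations permutation count for the entry tests (default
#'   999).
#' @param alpha entry significance level (default 0.05).
#' @param seed integer seed for the permutations.
#' @param r2_slack tolerance on the full-model adjusted R-squared bound
#'   (default 0.01).
#' @param response_transform `"shift"` (default: subtract the off-diagonal
#'   minimum when negative entries exist) or `"abs"` (absolute values of
#'   the response, for betaNTI-style signed matrices).
#' @return list with `retained` (data.frame: `axis`, `adj_r2_cum`, `p` in
#'   retention order; zero rows when nothing enters), `full_adj_r2`,
#'   `global_p` (permutation p of the full model), and the fitted `model`.
#' @export
dbrda_forward_select <- function(response, predictors, permutations = 999,
                                 alpha = 0.05, seed = 1L, r2_slack = 0.01,
                                 response_transform = c("shift", "abs")) {
  response_transform <- match.arg(response_transform)
  if (response_transform == "abs") response <- abs(as.matrix(response))
  d <- shift_nonnegative(response)
  dat <- as.data.frame(predictors)
  if (attr(d, "Size") != nrow(dat))
    stop("response and predictors have different sample counts")
  rn <- rownames(as.matrix(response))
  if (!is.null(rn) && !is.null(rownames(dat)) &&
      !identical(rn, rownames(dat)))
    stop("response and predictor samples not aligned")
  axes <- colnames(dat)
  fit <- function(terms) {
    f <- if (length(terms) == 0) "d ~ 1" else
      paste("d ~", paste(terms, collapse = " + "))
    f <- stats::as.formula(f)
    environment(f) <- environment()
    suppressMessages(vegan::capscale(f, data = dat, add = "lingoes"))
  }
  adj_r2 <- function(m) {
    r <- vegan::RsquareAdj(m)$adj.r.squared
    if (is.null(r) || !is.finite(r)) 0 else r
  }
  m_full <- fit(axes)
  full_adj_raw <- vegan::RsquareAdj(m_full)$adj.r.squared
  # a saturated full model (as many axes as residual df) has no defined
  # adjusted R-squared; the global bound is then inapplicable
  bound_active <- !is.null(full_adj_raw) && is.finite(full_adj_raw)
  full_adj <- if (bound_active) full_adj_raw else NA_real_
  current <- character(0)
  m_cur <- fit(current)
  cur_adj <- 0
  retained <- data.frame(axis = character(0), adj_r2_cum = numeric(0),
                         p = numeric(0), stringsAsFactors = FALSE)
  set.seed(seed)
  gt <- stats::anova(m_full, permutations = permutations)
  global_p <- gt[["Pr(>F)"]][1]
  if (is.na(global_p)) global_p <- 0                  # exact fit
  if (global_p > alpha)
    return(list(retained = retained, full_adj_r2 = full_adj,
                global_p = global_p, model = m_cur))
  repeat {
    remaining <- setdiff(axes, current)
    if (length(remaining) == 0) break
    cand_adj <- vapply(remaining, function(ax)
      adj_r2(fit(c(current, ax))), numeric(1))
    best <- remaining[which.max(cand_adj)]
    best_adj <- max(cand_adj)
    if (best_adj <= cur_adj) break                    # (c) no improvement
    if (bound_active && best_adj > full_adj + r2_slack)
      break                                           # (b) global bound
    tst <- stats::add1(m_cur, scope = paste("+", best),
                       test = "permutation", permutations = permutations)
    p <- tst[["Pr(>F)"]][nrow(tst)]
    if (is.na(p)) p <- 0                              # exact fit
    if (p > alpha) break                              # (a) not significant
    current <- c(current, best)
    m_cur <- fit(current)
    cur_adj <- best_adj
    retained <- rbind(retained,
                      data.frame(axis = best, adj_r2_cum = best_adj, p = p,
                                 stringsAsFactors = FALSE))
  }
  list(retained = retained, full_adj_r2 = full_adj, global_p = global_p,
       model = m_cur)
}

# ---------------------------------------------------------------------------
# Driver attribution
# ---------------------------------------------------------------------------

#' Map retained PCA axes to their primary factors and processes
#'
#' For each retained axis, the variable with the maximum absolute loading
#' is its primary factor. Factors topping an axis retained in the betaNTI
#' selection are selection-related; factors topping an axis retained by RC
#' but not betaNTI are dispersal-related. When `env_vars` is given, the
#' top loader is additionally reported separately among environmental
#' variables and among the remaining (taxon) rows.
#'
#' @param bnti_axes character vector of axes retained against betaNTI.
#' @param rc_axes character vector of axes retained against RC.
#' @param loadings variables x axes loading matrix (or a [pca_axes()]
#'   result).
#' @param env_vars optional character vector naming the environmental
#'   variables among the loading rows.
#' @return list with `per_axis` (axis, response set, top variables and
#'   loadings) and `factor_process` (factor, process) data.frames. Empty
#'   retained sets give empty frames.
#' @export
attribute_drivers <- function(bnti_axes, rc_axes, loadings,
                              env_vars = NULL) {
  if (is.list(loadings) && !is.null(loadings$loadings))
    loadings <- loadings$loadings
  L <- as.matrix(loadings)
  axes <- unique(c(bnti_axes, rc_axes))
  missing <- setdiff(axes, colnames(L))
  if (length(missing))
    stop("retained axes absent from loadings: ",
         paste(missing, collapse = ", "))
  top_of <- function(v) names(v)[which.max(abs(v))]
  rows <- lapply(axes, function(ax) {
    v <- setNames(L[, ax], rownames(L))
    process <- if (ax %in% bnti_axes) "selection" else "dispersal"
    out <- data.frame(axis = ax, process = process,
                      top_variable = top_of(v),
                      top_loading = v[top_of(v)],
                      stringsAsFactors = FALSE, row.names = NULL)
    if (!is.null(env_vars)) {
      ve <- v[intersect(names(v), env_vars)]
      vt <- v[setdiff(names(v), env_vars)]
      out$top_env_variable <- if (length(ve)) top_of(ve) else NA_character_
      out$top_env_loading <- if (length(ve)) ve[top_of(ve)] else NA_real_
      out$top_taxon <- if (length(vt)) top_of(vt) else NA_character_
      out$top_taxon_loading <- if (length(vt)) vt[top_of(vt)] else NA_real_
    }
    out
  })
  per_axis <- if (length(rows)) do.call(rbind, rows) else
    data.frame(axis = character(0), process = character(0),
               top_variable = character(0), top_loading = numeric(0))
  fp <- unique(per_axis[, c("top_variable", "process")])
  names(fp) <- c("factor", "process")
  rownames(fp) <- NULL
  list(per_axis = per_axis, factor_process = fp)
}

# ---------------------------------------------------------------------------
# RDA explained variance and the random-subcommunity control
# ---------------------------------------------------------------------------

#' Variance of community composition explained by environmental constraints
#'
#' Redundancy analysis of the (Hellinger-transformed by default) abundance
#' matrix on the environmental table; returns constrained inertia as a
#' percentage of total inertia over all constraint axes.
#'
#' @param community abundance matrix or [otu_table] (samples x taxa).
#' @param env numeric matrix of constraints (samples x factors), typically
#'   min-max scaled.
#' @param transform `"hellinger"` (default) or `"identity"`.
#' @return explained percentage (scalar in [0, 100]).
#' @export
rda_explained <- function(community, env,
                          transform = c("hellinger", "identity")) {
  transform <- match.arg(transform)
  Y <- if (is_otu_table(community)) unclass_counts(community) else
    as.matrix(community)
  env <- as.matrix(env)
  if (nrow(Y) != nrow(env)) stop("sample mismatch")
  if (ncol(env) > nrow(Y) - 1) stop("more constraints than samples - 1")
  if (transform == "hellinger") Y <- vegan::decostand(Y, "hellinger")
  dat <- as.data.frame(env)
  fit <- vegan::rda(Y ~ ., data = dat)
  100 * fit$CCA$tot.chi / fit$tot.chi
}

#' Compare a taxon set's environmental fit with random subcommunities
#'
#' Draws `n_draws` random subsets with as many taxa as the observed set,
#' scores each by [rda_explained()], and locates the observed set within
#' that null distribution by add-one empirical ranks:
#' upper p = (1 + #\{null >= obs\}) / (1 + n_draws), mirrored for the lower
#' tail, two-sided p = 2 min(upper, lower) capped at 1.
#'
#' @param table an [otu_table] holding the full community.
#' @param env constraint matrix as in [rda_explained()].
#' @param taxon_ids the observed taxon set (e.g. keystone taxa).
#' @param n_draws number of random subcommunities (default 99).
#' @param seed integer seed.
#' @param transform passed to [rda_explained()].
#' @return list with `observed`, `null` (vector of explained percentages),
#'   `p_upper`, `p_lower`, `p_two_sided`, `k`, `degenerate` flag.
#' @export
random_subcommunity_test <- function(table, env, taxon_ids, n_draws = 99,
                                     seed = 1L,
                                     transform = c("hellinger", "identity")) {
  transform <- match.arg(transform)
  m <- unclass_counts(as_otu_table(table))
  taxon_ids <- unique(as.character(taxon_ids))
  k <- length(taxon_ids)
  if (k >= ncol(m)) {
    if (k > ncol(m)) stop("k exceeds the taxon count")
    warning("taxon set spans the whole community; null is degenerate")
  }
  obs <- rda_explained(m[, taxon_ids, drop = FALSE], env, transform)
  set.seed(seed)
  null <- vapply(seq_len(n_draws), function(i) {
    draw <- sample(colnames(m), k)
    rda_explained(m[, draw, drop = FALSE], env, transform)
  }, numeric(1))
  p_up <- (1 + sum(null >= obs)) / (1 + n_draws)
  p_lo <- (1 + sum(null <= obs)) / (1 + n_draws)
  list(observed = obs, null = null, p_upper = p_up, p_lower = p_lo,
       p_two_sided = min(1, 2 * min(p_up, p_lo)), k = k,
       degenerate = k == ncol(m))
}
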