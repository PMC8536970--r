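# ---------------------------------------------------------------------------
# Correlation matrix and RMT threshold
# ---------------------------------------------------------------------------

#' Taxon-taxon Pearson correlation matrix for one sample group
#'
#' Correlations between taxa across the samples of one group, after
#' converting counts to relative abundances (default transform). Taxa are
#' retained only if present in at least half the group's samples (the same
#' presence rule used group-wide, see [presence_filter()]); constant taxa
#' are dropped since their correlation is undefined.
#'
#' @param table an [otu_table].
#' @param groups group map; `NULL` to use all samples as one group.
#' @param group group label to subset to (required when `groups` given).
#' @param transform `"relative"` (default) or `"none"` (raw counts).
#' @return symmetric correlation matrix (class `correlation_matrix`) with
#'   unit diagonal and attributes `transform`, `n_samples`, `group`.
#' @export
correlation_matrix <- function(table, groups = NULL, group = NULL,
                               transform = c("relative", "none")) {
  transform <- match.arg(transform)
  m <- unclass_counts(as_otu_table(table))
  if (!is.null(groups)) {
    if (is.null(group)) stop("give a group label when groups are supplied")
    g <- align_groups(groups, rownames(m))
    if (!group %in% levels(g)) stop("unknown group label: ", group)
    m <- m[g == group, , drop = FALSE]
  }
  if (nrow(m) < 4) stop("group has fewer than 4 samples")
  keep <- colSums(m > 0) >= ceiling(nrow(m) / 2)
  m <- m[, keep, drop = FALSE]
  x <- if (transform == "relative") relative_abundance(otu_table(m)) else m
  keep2 <- apply(x, 2, sd) > 0
  x <- x[, keep2, drop = FALSE]
  if (ncol(x) < 3) stop("fewer than 3 retained taxa")
  r <- cor(x)
  diag(r) <- 1
  structure(r, class = c("correlation_matrix", class(r)),
            transform = transform, n_samples = nrow(x), group = group)
}

# spectrum unfolding + nearest-neighbour spacing distribution test:
# p-value of a chi-square goodness-of-fit of the NNSD against the Poisson
# law P(d) = exp(-d). Returns NA when the spectrum is too degenerate.
nnsd_poisson_p <- function(eigenvalues) {
  ev <- sort(eigenvalues)
  # drop degenerate mass (repeated eigenvalues carry no spacing information
  # and break the unfolding spline)
  ev <- ev[c(TRUE, diff(ev) > 1e-8)]
  n <- length(ev)
  if (n < 20) return(NA_real_)
  # unfold by fitting a smooth spline to the empirical cumulative spectral
  # density; the unfolded spectrum has unit mean spacing by construction
  cdf <- (seq_len(n) - 0.5) / n
  sp <- tryCatch(smooth.spline(ev, cdf, df = min(10, n - 2)),
                 error = function(e) NULL)
  if (is.null(sp)) return(NA_real_)
  unfolded <- n * predict(sp, ev)$y
  d <- diff(unfolded)
  d <- d[d > 0]
  if (length(d) < 15) return(NA_real_)
  d <- d / mean(d)
  k <- ceiling(sqrt(length(d)))
  edges <- qexp((0:k) / k)
  obs <- tabulate(cut(d, breaks = edges, include.lowest = TRUE), nbins = k)
  expd <- length(d) / k
  stat <- sum((obs - expd)^2 / expd)
  pchisq(stat, df = k - 1, lower.tail = FALSE)
}

#' Random-matrix-theory correlation threshold
#'
#' Scans candidate thresholds; at each, entries with |r| below the
#' candidate are zeroed (unit diagonal kept) and the eigenvalue spectrum's
#' nearest-neighbour spacing distribution (NNSD) is tested against the
#' Poisson law P(d) = exp(-d) by chi-square goodness-of-fit after spline
#' unfolding. The threshold is the lowest candidate whose NNSD is
#' consistent with Poisson (p > alpha) and stays so for the next two scan
#' steps -- the point where the retained correlations behave as
#' system-specific signal rather than Wigner-type noise.
#'
#' @param corr a [correlation_matrix] (or symmetric matrix in [-1, 1]).
#' @param scan candidate thresholds (default `seq(0.30, 0.99, 0.01)`).
#' @param alpha significance level of the Poisson fit (default 0.05).
#' @param fallback threshold returned (flagged) when the matrix is too
#'   small (< 20 nodes) or no candidate qualifies; default `NA`.
#' @return list with `threshold`, `report` (data.frame of per-candidate
#'   node counts and Poisson p-values) and `fallback_used` flag.
#' @export
rmt_threshold <- function(corr, scan = seq(0.30, 0.99, by = 0.01),
                          alpha = 0.05, fallback = NA_real_) {
  A0 <- as.matrix(corr)
  if (any(scan <= 0) || any(scan >= 1)) stop("scan must lie within (0, 1)")
  scan <- sort(scan)
  if (nrow(A0) < 20) {
    warning("matrix too small for spectral statistics; using fallback")
    return(list(threshold = fallback, report = NULL, fallback_used = TRUE))
  }
  pvals <- vapply(scan, function(s) {
    A <- A0
    A[abs(A) < s] <- 0
    diag(A) <- 1
    deg <- rowSums(A != 0) - 1
    A <- A[deg > 0, deg > 0, drop = FALSE]
    if (nrow(A) < 20) return(NA_real_)
    nnsd_poisson_p(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
  n_nodes <- vapply(scan, function(s) {
    A <- A0; A[abs(A) < s] <- 0; diag(A) <- 0
    sum(rowSums(A != 0) > 0)
  }, numeric(1))
  report <- data.frame(threshold = scan, n_nodes = n_nodes, poisson_p = pvals)
  ok <- !is.na(pvals) & pvals > alpha
  s_t <- NA_real_
  for (i in seq_along(scan)) {
    horizon <- i:min(i + 2, length(scan))
    if (all(ok[horizon])) { s_t <- scan[i]; break }
  }
  if (is.na(s_t)) {
    warning("no candidate threshold passed the Poisson NNSD test; ",
            "using fallback")
    return(list(threshold = fallback, report = report, fallback_used = TRUE))
  }
  list(threshold = s_t, report = report, fallback_used = FALSE)
}

# ---------------------------------------------------------------------------
# Network construction and modules
# ---------------------------------------------------------------------------

#' Build an undirected co-occurrence network from a correlation matrix
#'
#' Edge (i, j) exists iff |r_ij| >= s_t for i != j (both correlation signs
#' count as association). Isolated nodes are removed and recorded.
#'
#' @param corr correlation matrix.
#' @param s_t threshold in (0, 1).
#' @return [igraph] graph with edge attribute `r`, graph attributes
#'   `threshold` and `isolated` (dropped node names).
#' @export
build_network <- function(corr, s_t) {
  if (!is.numeric(s_t) || is.na(s_t) || s_t <= 0 || s_t >= 1)
    stop("threshold must lie in (0, 1)")
  A <- as.matrix(corr)
  keep <- abs(A) >= s_t
  diag(keep) <- FALSE
  if (!any(keep)) stop("no edge survives threshold ", s_t)
  W <- A * keep
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = "r", diag = FALSE)
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  g <- igraph::delete_vertices(g, iso)
  g <- igraph::set_graph_attr(g, "threshold", s_t)
  g <- igraph::set_graph_attr(g, "isolated", iso)
  g
}

#' Detect network modules by greedy modularity maximisation
#'
#' Agglomerative CNM-style greedy optimisation of Newman-Girvan modularity
#' Q = sum_m [e_m/E - (d_m/2E)^2] on the unweighted graph, via
#' [igraph::cluster_fast_greedy()]. The merge dendrogram is cut at the
#' level with the highest modularity, re-evaluated in R (the library's
#' own cut can miss the final merges on degenerate graphs such as
#' cliques); ties go to the coarser partition. Deterministic; the seed
#' argument is accepted for interface uniformity and recorded.
#'
#' @param net an [igraph] graph.
#' @param seed integer, recorded in the result.
#' @return list with `membership` (named integer vector), `modularity` (Q)
#'   and `n_modules`.
#' @export
detect_modules <- function(net, seed = 1L) {
  if (igraph::vcount(net) == 0) stop("empty graph")
  set.seed(seed)
  g <- igraph::simplify(net)
  fit <- igraph::cluster_fast_greedy(g, weights = NULL)
  n <- igraph::vcount(g)
  kmin <- n - nrow(fit$merges)
  ks <- seq(kmin, n)
  qs <- vapply(ks, function(k)
    igraph::modularity(g, igraph::cut_at(fit, no = k)), numeric(1))
  k_best <- ks[which.max(qs)]   # which.max: first (coarsest) on ties
  memb <- igraph::cut_at(fit, no = k_best)
  names(memb) <- igraph::V(g)$name
  list(membership = setNames(as.integer(memb), names(memb)),
       modularity = igraph::modularity(g, memb),
       n_modules = length(unique(memb)),
       seed = seed)
}

# ---------------------------------------------------------------------------
# Node roles: Zi / Pi and keystones
# ---------------------------------------------------------------------------

#' Within-module degree (Zi) and participation coefficient (Pi)
#'
#' Zi = (k_i,within - mean_module) / sd_module, the z-score of a node's
#' within-module degree against the other members of its module; Pi =
#' 1 - sum_t (k_it / k_i)^2 over modules t, zero when all of a node's links
#' are internal. Modules whose within-degree standard deviation is zero
#' give Zi = 0, flagged.
#'
#' @param net an [igraph] graph (no isolated nodes).
#' @param membership named module assignment covering every node.
#' @return data.frame per node: `taxon`, `module`, `degree`, `zi`, `pi`,
#'   `zi_flagged`.
#' @export
zi_pi <- function(net, membership) {
  nodes <- igraph::V(net)$name
  if (!all(nodes %in% names(membership)))
    stop("membership must cover every node")
  memb <- membership[nodes]
  A <- as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
  A <- (A != 0) * 1
  deg <- rowSums(A)
  if (any(deg == 0)) stop("node of degree 0: ",
                          paste(nodes[deg == 0], collapse = ", "))
  mods <- sort(unique(memb))
  # k_it: links from node i into module t
  K <- vapply(mods, function(t) rowSums(A[, memb == t, drop = FALSE]),
              numeric(length(nodes)))
  if (is.null(dim(K))) K <- matrix(K, nrow = length(nodes))
  k_within <- K[cbind(seq_along(nodes), match(memb, mods))]
  zi <- numeric(length(nodes))
  flagged <- logical(length(nodes))
  for (t in mods) {
    in_t <- memb == t
    kw <- k_within[in_t]
    s <- sd(kw)
    if (length(kw) < 2 || is.na(s) || s == 0) {
      zi[in_t] <- 0
      flagged[in_t] <- TRUE
    } else {
      zi[in_t] <- (kw - mean(kw)) / s
    }
  }
  pi <- 1 - rowSums((K / deg)^2)
  data.frame(taxon = nodes, module = as.integer(memb), degree = deg,
             zi = zi, pi = pi, zi_flagged = flagged,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify node roles and keystone taxa from Zi / Pi
#'
#' Module hubs ("module organizers") have Zi > 2.5 with Pi <= 0.62,
#' connectors Pi > 0.62 with Zi <= 2.5, network hubs exceed both, all
#' other nodes are peripheral. Module hubs, connectors and network hubs
#' together are the keystone taxa.
#'
#' @param roles data.frame from [zi_pi()].
#' @param zi_threshold default 2.5.
#' @param pi_threshold default 0.62.
#' @return `roles` with an added `role` column; keystone rows carry a
#'   non-peripheral role.
#' @export
classify_keystones <- function(roles, zi_threshold = 2.5,
                               pi_threshold = 0.62) {
  hub <- roles$zi > zi_threshold
  con <- roles$pi > pi_threshold
  roles$role <- ifelse(hub & con, "network_hub",
                ifelse(hub, "module_hub",
                ifelse(con, "connector", "peripheral")))
  roles
}

#' @rdname classify_keystones
#' @export
keystone_taxa <- function(roles, zi_threshold = 2.5, pi_threshold = 0.62) {
  r <- classify_keystones(roles, zi_threshold, pi_threshold)
  r[r$role != "peripheral", c("taxon", "role", "module", "zi", "pi")]
}
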