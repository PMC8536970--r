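# ---------------------------------------------------------------------------
# Yule tree and Brownian niche traits
# ---------------------------------------------------------------------------

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Constant-rate pure-birth process: starting from two lineages at the
#' root, each lineage splits at rate `rate`; after the n-th tip appears the
#' tree is extended by one further exponential waiting time so all tips are
#' contemporaneous. Expected root-to-tip depth is sum_{k=2..n} 1/(k rate).
#' Byte-identical newick under a fixed seed.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @param rate per-lineage birth rate (default 1).
#' @return an ultrametric [ape::phylo] with tips `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, seed = 1L, rate = 1) {
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 2) stop("need at least 2 taxa")
  set.seed(seed)
  root <- n_taxa + 1L
  next_internal <- n_taxa + 2L
  # active lineages: parent node id and the time the lineage started
  act_parent <- c(root, root)
  act_start <- c(0, 0)
  edge <- matrix(integer(0), ncol = 2)
  elen <- numeric(0)
  t_now <- 0
  k <- 2L
  while (k < n_taxa) {
    t_now <- t_now + rexp(1, rate * k)
    j <- sample.int(k, 1)
    node <- next_internal
    next_internal <- next_internal + 1L
    edge <- rbind(edge, c(act_parent[j], node))
    elen <- c(elen, t_now - act_start[j])
    act_parent <- c(act_parent[-j], node, node)
    act_start <- c(act_start[-j], t_now, t_now)
    k <- k + 1L
  }
  t_end <- t_now + rexp(1, rate * n_taxa)
  for (j in seq_len(n_taxa)) {
    edge <- rbind(edge, c(act_parent[j], j))
    elen <- c(elen, t_end - act_start[j])
  }
  tree <- list(edge = edge, edge.length = elen,
               tip.label = paste0("t", seq_len(n_taxa)),
               Nnode = n_taxa - 1L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  validate_tree(tree)
}

#' Simulate Brownian niche optima along a tree
#'
#' Brownian motion from a root value of 0 with rate `sigma_B`, so a tip's
#' variance is sigma_B^2 times its root-to-tip path length and two tips
#' covary by their shared path length. This phylogenetic conservatism of
#' the niche trait is what makes environmental filtering leave a signal in
#' nearest-taxon phylogenetic turnover.
#'
#' @param tree an [ape::phylo].
#' @param sigma_B Brownian rate (> 0), default 1.
#' @param seed integer seed.
#' @return named numeric vector of tip trait values.
#' @export
simulate_traits <- function(tree, sigma_B = 1, seed = 1L) {
  if (sigma_B <= 0) stop("sigma_B must be positive")
  set.seed(seed)
  phytools::fastBM(validate_tree(tree), sig2 = sigma_B^2, a = 0)
}

# ---------------------------------------------------------------------------
# Regime specification and presets
# ---------------------------------------------------------------------------

#' Specify a community-assembly simulation regime
#'
#' The generator emulates a 4-group x 8-replicate sediment study design:
#' a lognormal metacommunity over a Yule phylogeny with Brownian niche
#' traits, six named environmental factors with group-structured means,
#' and one of two assembly regimes. Under `selection`, sample-level
#' sampling weights are the metacommunity times a Gaussian niche filter
#' exp(-(trait - env)^2 / (2 sigma_w^2)) around the sample's latent
#' environment; under `neutral`, weights mix the metacommunity with a
#' group-local pool drifted from it, `m` * meta + (1 - `m`) * pool, so
#' m = 1 is homogenizing dispersal and m near 0 dispersal limitation.
#' Communities are multinomial draws of `depth` individuals.
#'
#' `sigma_w` and `env_noise_sd` are expressed in units of the realised tip
#' trait standard deviation, so filtering strength is comparable across
#' tree realisations; `optima_quantiles` places group optima at quantiles
#' of the tip trait distribution. The default alternates two environmental
#' levels (quantiles 0.1 and 0.9) across the groups, the two-level,
#' strong-filtering design under which selection dominates between-level
#' turnover. The selection regime can mix in an immigrant fraction drawn
#' from the unfiltered metacommunity (mass effect, off by default). Note
#' that nearest-taxon turnover is a minimum-distance statistic: even trace
#' immigrants seed every clade with close relatives and rapidly erase the
#' between-level phylogenetic signal, which is why the default is 0.
#'
#' @param regime `"selection"` or `"neutral"`.
#' @param n_groups groups (default 4), `replicates` per group (default 8).
#' @param replicates samples per group.
#' @param n_taxa metacommunity richness (default 200).
#' @param depth individuals per sample (default 5000).
#' @param optima_quantiles trait quantile per group for the group optima;
#'   `NULL` alternates the two levels 0.1 and 0.9 across groups.
#' @param sigma_w niche filter width, trait-sd units (selection; default
#'   0.15).
#' @param immigration fraction of each sample's individuals drawn from
#'   the unfiltered metacommunity, a trace mass effect (selection; default
#'   0).
#' @param m dispersal mixing in [0, 1] (neutral; default 0.02).
#' @param drift_sd lognormal sd of the local-pool drift (neutral; default
#'   2).
#' @param sigma_B Brownian trait rate (default 1).
#' @param meta_sdlog lognormal sd of metacommunity abundances (default 2,
#'   a strongly uneven abundance distribution as typical of sediment 16S
#'   surveys).
#' @param env_noise_sd replicate noise on the latent environment,
#'   trait-sd units (default 0.05).
#' @param seed master seed; all randomness fans out from it.
#' @return a `regime_spec` list.
#' @export
regime_spec <- function(regime = c("selection", "neutral"), n_groups = 4,
                        replicates = 8, n_taxa = 200, depth = 5000,
                        optima_quantiles = NULL, sigma_w = 0.15,
                        immigration = 0, m = 0.02,
                        drift_sd = 2, sigma_B = 1, meta_sdlog = 2,
                        env_noise_sd = 0.05, seed = 1L) {
  regime <- match.arg(regime)
  if (m < 0 || m > 1) stop("m must lie in [0, 1]")
  if (sigma_w <= 0) stop("sigma_w must be positive")
  if (immigration < 0 || immigration >= 1)
    stop("immigration must lie in [0, 1)")
  if (depth < 1) stop("depth must be positive")
  if (is.null(optima_quantiles))
    optima_quantiles <- rep_len(c(0.1, 0.9), n_groups)
  if (length(optima_quantiles) != n_groups)
    stop("need one optimum quantile per group")
  structure(list(regime = regime, n_groups = n_groups,
                 replicates = replicates, n_taxa = n_taxa, depth = depth,
                 optima_quantiles = optima_quantiles, sigma_w = sigma_w,
                 immigration = immigration, m = m, drift_sd = drift_sd,
                 sigma_B = sigma_B,
                 meta_sdlog = meta_sdlog, env_noise_sd = env_noise_sd,
                 seed = as.integer(seed)),
            class = "regime_spec")
}

#' The four preset assembly regimes
#'
#' One preset per process the classifier should recover between groups:
#' divergent-optima filtering (heterogeneous selection), shared-optimum
#' filtering (homogeneous selection), neutral sampling from drifted local
#' pools with minimal mixing (dispersal limitation), and neutral sampling
#' straight from the metacommunity (homogenizing dispersal).
#'
#' @param seed master seed applied to every preset.
#' @param ... overrides passed to [regime_spec()] (e.g. `n_taxa`).
#' @return named list of `regime_spec`s.
#' @export
preset_regimes <- function(seed = 1L, ...) {
  list(
    heterogeneous_selection = regime_spec("selection", seed = seed, ...),
    homogeneous_selection = regime_spec("selection",
                                        optima_quantiles = rep(0.5, 4),
                                        seed = seed, ...),
    dispersal_limitation = regime_spec("neutral", m = 0.02, seed = seed, ...),
    homogenizing_dispersal = regime_spec("neutral", m = 1, seed = seed, ...)
  )
}

# ---------------------------------------------------------------------------
# Community simulation
# ---------------------------------------------------------------------------

# fixed structure of the six environmental factors: each responds linearly
# to the latent niche axis (standardised), with its own baseline and noise
env_factor_defs <- function() {
  data.frame(
    factor = c("pH", "ORP", "Moisture", "NH4", "TN", "TOC"),
    base = c(7.2, -120, 55, 12, 0.20, 1.8),
    slope = c(0.25, -45, 8, 4, 0.06, 0.5),
    noise = c(0.08, 12, 2.5, 1.2, 0.02, 0.15),
    stringsAsFactors = FALSE)
}

#' Simulate an OTU table, environmental table and group map under a regime
#'
#' See [regime_spec()] for the generative model. All randomness derives
#' from the spec's master seed (tree, traits, metacommunity, environments
#' and community draws each consume a fixed offset of it), so the same
#' spec reproduces byte-identical outputs.
#'
#' @param spec a [regime_spec()].
#' @param tree optional pre-built tree (defaults to a fresh Yule tree).
#' @param traits optional named niche optima for the tips.
#' @return list with `otu` ([otu_table]), `env` (samples x 6 factors),
#'   `groups` (named factor; labels TO/BO/TN/BN for 4 groups), `tree`,
#'   `traits`, `latent` (per-sample niche environment) and `spec`.
#' @export
simulate_communities <- function(spec, tree = NULL, traits = NULL) {
  stopifnot(inherits(spec, "regime_spec"))
  if (is.null(tree)) tree <- simulate_tree(spec$n_taxa, seed = spec$seed + 1L)
  if (is.null(traits))
    traits <- simulate_traits(tree, spec$sigma_B, seed = spec$seed + 2L)
  taxa <- tree$tip.label
  traits <- traits[taxa]
  n_samp <- spec$n_groups * spec$replicates

  set.seed(spec$seed + 3L)
  meta <- rlnorm(spec$n_taxa, 0, spec$meta_sdlog)
  meta <- meta / sum(meta)

  glabs <- if (spec$n_groups == 4) c("TO", "BO", "TN", "BN") else
    paste0("G", seq_len(spec$n_groups))
  groups <- factor(rep(glabs, each = spec$replicates), levels = glabs)
  sample_ids <- paste0(rep(glabs, each = spec$replicates),
                       rep(seq_len(spec$replicates), spec$n_groups))
  names(groups) <- sample_ids

  trait_sd <- sd(traits)
  optima <- quantile(traits, spec$optima_quantiles, names = FALSE)

  set.seed(spec$seed + 4L)
  latent <- optima[as.integer(groups)] +
    rnorm(n_samp, 0, spec$env_noise_sd * trait_sd)
  names(latent) <- sample_ids

  set.seed(spec$seed + 5L)
  if (spec$regime == "neutral") {
    pools <- vapply(seq_len(spec$n_groups), function(g) {
      w <- meta * exp(rnorm(spec$n_taxa, 0, spec$drift_sd))
      w / sum(w)
    }, numeric(spec$n_taxa))
  }
  counts <- matrix(0L, n_samp, spec$n_taxa,
                   dimnames = list(sample_ids, taxa))
  for (s in seq_len(n_samp)) {
    w <- if (spec$regime == "selection") {
      wf <- meta * exp(-(traits - latent[s])^2 /
                         (2 * (spec$sigma_w * trait_sd)^2))
      if (sum(wf) <= 0) wf <- meta
      (1 - spec$immigration) * wf / sum(wf) + spec$immigration * meta
    } else {
      spec$m * meta + (1 - spec$m) * pools[, as.integer(groups[s])]
    }
    if (sum(w) <= 0) w <- meta
    counts[s, ] <- as.integer(rmultinom(1, spec$depth, w))
  }

  set.seed(spec$seed + 6L)
  defs <- env_factor_defs()
  z <- (latent - mean(latent)) / max(trait_sd, 1e-12)
  env <- vapply(seq_len(nrow(defs)), function(f) {
    defs$base[f] + defs$slope[f] * z + rnorm(n_samp, 0, defs$noise[f])
  }, numeric(n_samp))
  dimnames(env) <- list(sample_ids, defs$factor)

  list(otu = otu_table(counts), env = env, groups = groups, tree = tree,
       traits = traits, latent = latent, spec = spec)
}

#' Write a simulated data set to disk
#'
#' Writes `otu_table.tsv`, `tree.nwk`, `env.tsv`, `groups.tsv` and
#' `spec.json` into a directory, in the formats the readers of this
#' package consume.
#'
#' @param sim result of [simulate_communities()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(sim$otu, file.path(dir, "otu_table.tsv"))
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  env_df <- data.frame(sample_id = rownames(sim$env), sim$env,
                       check.names = FALSE)
  write.table(env_df, file.path(dir, "env.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  grp_df <- data.frame(sample_id = names(sim$groups),
                       group = as.character(sim$groups))
  write.table(grp_df, file.path(dir, "groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
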