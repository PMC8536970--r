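# ---------------------------------------------------------------------------
# End-to-end pipeline
# ---------------------------------------------------------------------------

#' Assemble a pipeline configuration
#'
#' Inputs may be in-memory objects or file paths (read with the package's
#' readers). Every effective parameter is echoed into the run manifest.
#'
#' @param otu [otu_table] or TSV path.
#' @param tree [ape::phylo] or newick path.
#' @param env samples x factors matrix or TSV path.
#' @param groups named group map or TSV path.
#' @param depth rarefaction depth; `NULL` uses the minimum sample total.
#' @param rarefy_seed,null_seed,network_seed,driver_seed stage seeds.
#' @param reps null-model replicates (default 999).
#' @param abundance_weighted betaMNTD weighting (default TRUE).
#' @param permutations permutation count for ANOSIM and model selection.
#' @param alpha significance level for forward selection.
#' @param scan RMT threshold scan grid.
#' @param rmt_fallback threshold used when the RMT scan cannot decide.
#' @param zi_threshold,pi_threshold keystone role cutoffs (defaults 2.5 and
#'   0.62).
#' @param out_dir optional directory; when given, stage outputs and the
#'   manifest are written there as TSV/JSON.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(otu, tree, env, groups, depth = NULL,
                            rarefy_seed = 1L, null_seed = 1L,
                            network_seed = 1L, driver_seed = 1L,
                            reps = 999, abundance_weighted = TRUE,
                            permutations = 999, alpha = 0.05,
                            scan = seq(0.30, 0.99, by = 0.01),
                            rmt_fallback = 0.80, zi_threshold = 2.5,
                            pi_threshold = 0.62, out_dir = NULL) {
  structure(list(otu = otu, tree = tree, env = env, groups = groups,
                 depth = depth, rarefy_seed = rarefy_seed,
                 null_seed = null_seed, network_seed = network_seed,
                 driver_seed = driver_seed, reps = reps,
                 abundance_weighted = abundance_weighted,
                 permutations = permutations, alpha = alpha, scan = scan,
                 rmt_fallback = rmt_fallback, zi_threshold = zi_threshold,
                 pi_threshold = pi_threshold, out_dir = out_dir),
            class = "pipeline_config")
}

resolve_inputs <- function(config) {
  otu <- if (is.character(config$otu)) read_otu_table(config$otu) else
    as_otu_table(config$otu)
  tree <- if (is.character(config$tree)) read_tree(config$tree) else
    validate_tree(config$tree)
  env <- if (is.character(config$env)) read_env_table(config$env) else
    as.matrix(config$env)
  groups <- if (is.character(config$groups)) read_group_map(config$groups)
    else as_group_map(config$groups)
  list(otu = otu, tree = tree, env = env, groups = groups)
}

#' Run the full assembly-process pipeline
#'
#' Stages, in order: rarefaction; diversity (Shannon, Bray-Curtis, ANOSIM,
#' group presence); null models (betaNTI, Raup-Crick, process
#' classification and contribution summaries at regional / within-group /
#' between-group scope); per-group RMT networks with Zi-Pi keystone
#' classification; keystone-only null models; driver attribution (PCA of
#' min-max-scaled environmental factors and keystone abundances, dbRDA
#' forward selection against betaNTI and RC, highest-|loading|
#' attribution). A failing stage aborts with the stage name. Re-running
#' the same configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_run` list with one element per stage plus `manifest`
#'   (effective parameters, seeds, stage status, collected warnings).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  notes <- character(0)
  note <- function(...) notes <<- c(notes, paste0(...))
  stages <- character(0)
  run_stage <- function(name, expr) {
    res <- tryCatch(withCallingHandlers(expr, warning = function(w) {
      note(name, ": ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }

  inp <- run_stage("ingest", resolve_inputs(config))
  groups <- align_groups(inp$groups, rownames(inp$otu))
  env <- inp$env[rownames(inp$otu), , drop = FALSE]

  rar <- run_stage("rarefy",
                   rarefy(inp$otu, depth = config$depth,
                          seed = config$rarefy_seed))
  depth_used <- attr(rar, "rarefaction")$depth

  diversity <- run_stage("diversity", {
    bc <- bray_curtis(rar)
    list(shannon = apply(unclass_counts(rar), 1, shannon),
         bray_curtis = bc,
         anosim = anosim_test(bc, groups,
                              permutations = config$permutations,
                              seed = config$null_seed),
         presence = presence_filter(rar, groups))
  })

  processes <- run_stage("null_models", {
    bn <- beta_nti(rar, inp$tree, reps = config$reps,
                   abundance_weighted = config$abundance_weighted,
                   seed = config$null_seed)
    rc <- raup_crick_bray(rar, reps = config$reps, seed = config$null_seed)
    scopes <- c("regional", paste0("within:", levels(groups)),
                apply(utils::combn(levels(groups), 2), 2,
                      function(p) paste0("between:", p[1], ":", p[2])))
    summaries <- lapply(scopes, function(sc)
      summarize_contributions(bn, rc, groups, sc))
    names(summaries) <- scopes
    list(bnti = bn, rc = rc,
         pairs = classify_pairs(bn, rc, groups), summaries = summaries)
  })

  network <- run_stage("network", {
    per_group <- lapply(levels(groups), function(gl) {
      res <- tryCatch({
        cm <- correlation_matrix(rar, groups, gl)
        thr <- rmt_threshold(cm, scan = config$scan,
                             fallback = config$rmt_fallback)
        net <- build_network(cm, thr$threshold)
        mod <- detect_modules(net, seed = config$network_seed)
        roles <- classify_keystones(zi_pi(net, mod$membership),
                                    config$zi_threshold,
                                    config$pi_threshold)
        list(group = gl, threshold = thr$threshold,
             rmt_fallback_used = thr$fallback_used,
             n_nodes = igraph::vcount(net), n_edges = igraph::ecount(net),
             modularity = mod$modularity, n_modules = mod$n_modules,
             roles = roles)
      }, error = function(e) {
        note("network[", gl, "]: ", conditionMessage(e))
        NULL
      })
      res
    })
    names(per_group) <- levels(groups)
    keystones <- unique(unlist(lapply(per_group, function(x)
      if (!is.null(x)) x$roles$taxon[x$roles$role != "peripheral"])))
    list(per_group = per_group, keystones = keystones)
  })

  keystone_processes <- run_stage("keystone_null_models", {
    ks <- network$keystones
    if (length(ks) < 2) {
      note("keystone_null_models: fewer than 2 keystone taxa; stage empty")
      NULL
    } else {
      sub <- keystone_subcommunity(rar, ks)
      bn <- beta_nti(sub, inp$tree, reps = config$reps,
                     abundance_weighted = config$abundance_weighted,
                     seed = config$null_seed)
      rc <- raup_crick_bray(sub, reps = config$reps,
                            seed = config$null_seed)
      gsub <- droplevels(groups[rownames(sub)])
      list(bnti = bn, rc = rc,
           summary = summarize_contributions(bn, rc, gsub, "regional"))
    }
  })

  drivers <- run_stage("driver_attribution", {
    ks <- network$keystones
    env_scaled <- minmax_scale_columns(env)
    pred <- env_scaled
    if (length(ks) >= 1) {
      ka <- relative_abundance(rar)[, ks, drop = FALSE]
      ka <- minmax_scale_columns(ka)
      pred <- cbind(env_scaled, ka)
    }
    pca <- pca_axes(pred)
    sel_b <- dbrda_forward_select(processes$bnti$bnti, pca$scores,
                                  permutations = config$permutations,
                                  alpha = config$alpha,
                                  seed = config$driver_seed)
    sel_r <- dbrda_forward_select(processes$rc$rc, pca$scores,
                                  permutations = config$permutations,
                                  alpha = config$alpha,
                                  seed = config$driver_seed)
    attribution <- attribute_drivers(sel_b$retained$axis, sel_r$retained$axis,
                                     pca, env_vars = colnames(env_scaled))
    list(pca = pca, bnti_selection = sel_b, rc_selection = sel_r,
         attribution = attribution)
  })

  manifest <- list(
    parameters = list(
      depth = depth_used, rarefy_seed = config$rarefy_seed,
      reps = config$reps, null_seed = config$null_seed,
      abundance_weighted = config$abundance_weighted,
      permutations = config$permutations, alpha = config$alpha,
      scan = range(config$scan), rmt_fallback = config$rmt_fallback,
      zi_threshold = config$zi_threshold,
      pi_threshold = config$pi_threshold,
      network_seed = config$network_seed,
      driver_seed = config$driver_seed),
    stages = stages, warnings = notes)

  run <- list(table = rar, groups = groups, env = env,
              diversity = diversity, processes = processes,
              network = network, keystone_processes = keystone_processes,
              drivers = drivers, manifest = manifest)
  class(run) <- "pipeline_run"
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

# serialise the main outputs of a run as TSV/JSON
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(run$table, file.path(dir, "working_table.tsv"))
  wmat <- function(m, f) {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wmat(run$processes$bnti$bnti, "bnti.tsv")
  wmat(run$processes$rc$rc, "rc_bray.tsv")
  write.table(run$processes$pairs, file.path(dir, "pair_processes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summaries <- lapply(run$processes$summaries, function(s)
    list(n_pairs = attr(s, "n_pairs"),
         counts = setNames(as.list(s$count), s$label),
         percent = setNames(as.list(s$percent), s$label)))
  jsonlite::write_json(list(anosim = run$diversity$anosim,
                            process_summaries = summaries,
                            keystones = run$network$keystones),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Human-readable report of a pipeline run
#'
#' Prints the contribution summaries as tables (percentages to one
#' decimal), the keystone roster grouped by role (and phylum when
#' taxonomy is attached to the table), and the driver attribution.
#'
#' @param run a `pipeline_run` from [run_pipeline()].
#' @return the report lines, invisibly; printed to the console.
#' @export
report_run <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  fmt_pct <- function(x) sprintf("%.1f", x)
  out <- c("== Assembly-process report ==", "")
  a <- run$diversity$anosim
  out <- c(out, sprintf("ANOSIM (Bray-Curtis): R = %.3f, p = %.3g (%d perms)",
                        a$R, a$p, a$permutations), "")
  for (sc in names(run$processes$summaries)) {
    s <- run$processes$summaries[[sc]]
    out <- c(out, sprintf("-- %s (%d pairs)", sc, attr(s, "n_pairs")),
             sprintf("   %-24s %5d  %s%%", s$label, s$count,
                     fmt_pct(s$percent)), "")
  }
  ks <- run$network$keystones
  out <- c(out, "-- Keystone roster")
  if (length(ks) == 0) {
    out <- c(out, "   none")
  } else {
    roles <- do.call(rbind, lapply(Filter(Negate(is.null),
                                          run$network$per_group),
                                   function(x) x$roles))
    roles <- roles[roles$role != "peripheral", , drop = FALSE]
    tax <- attr(run$table, "taxonomy")
    for (rl in unique(roles$role)) {
      members <- unique(roles$taxon[roles$role == rl])
      out <- c(out, sprintf("   %s (%d): %s", rl, length(members),
                            paste(members, collapse = ", ")))
    }
    if (!is.null(tax)) {
      phyla <- table(tax[ks])
      out <- c(out, sprintf("   by lineage: %s",
                            paste(names(phyla), phyla, sep = "=",
                                  collapse = ", ")))
    }
  }
  out <- c(out, "", "-- Driver attribution")
  pa <- run$drivers$attribution$per_axis
  if (nrow(pa) == 0) {
    out <- c(out, "   no axis retained")
  } else {
    out <- c(out, sprintf("   %s [%s]: top %s (loading %.4f)", pa$axis,
                          pa$process, pa$top_variable, pa$top_loading))
  }
  cat(out, sep = "\n")
  invisible(out)
}
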