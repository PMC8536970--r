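# fixtures are built in code; nothing is read from disk except the shipped
# loading-table example

# small hand tree: ((A:1,B:1):1,C:2); patristic d(A,B)=2, d(A,C)=d(B,C)=4
hand_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# a reproducible random count table (samples x taxa) with positive totals
random_table <- function(n_samples, n_taxa, seed, lambda = 8) {
  set.seed(seed)
  repeat {
    m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa,
                dimnames = list(paste0("s", seq_len(n_samples)),
                                paste0("t", seq_len(n_taxa))))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(otu_table(m))
  }
}

# independent brute-force betaMNTD: explicit double loop over taxa
bmntd_bruteforce <- function(table, tree, abundance_weighted = TRUE) {
  m <- unclass(table)
  D <- ape::cophenetic.phylo(tree)[colnames(m), colnames(m)]
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (k in seq_len(n - 1)) for (l in seq(k + 1, n)) {
    half <- function(a, b) {
      ta <- which(m[a, ] > 0); tb <- which(m[b, ] > 0)
      w <- if (abundance_weighted) m[a, ta] / sum(m[a, ta]) else
        rep(1 / length(ta), length(ta))
      s <- 0
      for (q in seq_along(ta)) {
        dmin <- Inf
        for (r in tb) dmin <- min(dmin, D[ta[q], r])
        s <- s + w[q] * dmin
      }
      s
    }
    v <- (half(k, l) + half(l, k)) / 2
    out[k, l] <- v; out[l, k] <- v
  }
  out
}

# group map for the 4 x 8 design
design_groups <- function(labels = c("TO", "BO", "TN", "BN"), reps = 8) {
  g <- factor(rep(labels, each = reps), levels = labels)
  names(g) <- paste0(rep(labels, each = reps), seq_len(reps))
  g
}

# symmetric matrix from a vector of upper-triangle values (row-major pair
# order matching classify_pairs)
sym_from_pairs <- function(values, ids) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- NA
  idx <- which(is.na(m), arr.ind = TRUE)
  stopifnot(nrow(idx) == length(values))
  m[idx] <- values
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# the shipped example loading table (variables x retained axes)
loading_fixture <- function() {
  path <- system.file("extdata", "retained_axis_loadings.tsv",
                      package = "microassembly")
  fx <- utils::read.delim(path, check.names = FALSE)
  L <- as.matrix(fx[, -(1:2)])
  rownames(L) <- fx$variable
  list(loadings = L, env_vars = fx$variable[fx$type == "env"])
}
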