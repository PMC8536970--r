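#' @useDynLib microassembly, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cor.test cmdscale cov dist ecdf p.adjust pchisq
#'   prcomp pt quantile rnorm rlnorm rexp runif rmultinom sd smooth.spline
#'   predict qexp as.dist setNames
#' @importFrom utils read.table write.table head
NULL

# ---------------------------------------------------------------------------
# OTU table
# ---------------------------------------------------------------------------

#' Construct a validated OTU count table
#'
#' An `otu_table` is an integer count matrix with samples as rows and taxa
#' as columns, the observation unit consumed by every downstream stage.
#' Sample and taxon identifiers must be unique and counts finite and
#' non-negative.
#'
#' @param counts numeric matrix, samples x taxa, with dimnames.
#' @param taxonomy optional named character vector mapping taxon ids to
#'   lineage strings.
#' @return an `otu_table` (an integer matrix with class attribute and,
#'   optionally, a `taxonomy` attribute).
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("empty OTU table")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("OTU table requires sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite numbers")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)) || !all(colnames(counts) %in% names(taxonomy)))
      stop("taxonomy must be named by taxon id and cover all taxa")
    attr(counts, "taxonomy") <- taxonomy[colnames(counts)]
  }
  class(counts) <- c("otu_table", class(counts))
  counts
}

#' Test and coerce OTU tables
#'
#' @param x object to test or coerce.
#' @return `is_otu_table` returns a logical; `as_otu_table` a validated
#'   `otu_table`.
#' @export
is_otu_table <- function(x) inherits(x, "otu_table")

#' @rdname is_otu_table
#' @export
as_otu_table <- function(x) {
  if (is_otu_table(x)) return(x)
  otu_table(x)
}

# strip the class for plain matrix algebra
unclass_counts <- function(x) {
  x <- unclass(x)
  attr(x, "taxonomy") <- NULL
  x
}

#' Read an OTU count table from tab-separated text
#'
#' The file must have one header row of ids and one id column. Orientation
#' is normalised so the returned table always has samples as rows.
#'
#' @param path file path.
#' @param orientation `"samples-as-rows"` (default) or `"taxa-as-rows"`.
#' @return an [otu_table].
#' @export
read_otu_table <- function(path,
                           orientation = c("samples-as-rows", "taxa-as-rows")) {
  orientation <- match.arg(orientation)
  raw <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                    check.names = FALSE, comment.char = "")
  m <- as.matrix(raw)
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  if (orientation == "taxa-as-rows") m <- t(m)
  otu_table(m)
}

#' Write an OTU table as tab-separated text
#'
#' @param table an [otu_table].
#' @param path output file path.
#' @param orientation row unit written to disk.
#' @return the path, invisibly.
#' @export
write_otu_table <- function(table, path,
                            orientation = c("samples-as-rows",
                                            "taxa-as-rows")) {
  orientation <- match.arg(orientation)
  m <- unclass_counts(as_otu_table(table))
  if (orientation == "taxa-as-rows") m <- t(m)
  id_col <- if (orientation == "samples-as-rows") "sample_id" else "taxon_id"
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' @param table an [otu_table] or count matrix (samples x taxa).
#' @return a numeric matrix whose rows sum to one.
#' @export
relative_abundance <- function(table) {
  m <- unclass_counts(as_otu_table(table))
  tot <- rowSums(m)
  if (any(tot == 0)) stop("sample with zero total count")
  sweep(m, 1, tot, "/")
}

#' Rarefy every sample to a common depth
#'
#' Each sample's individuals are subsampled without replacement so that all
#' sample totals equal `depth`. Reproducible under a fixed seed; taxa absent
#' before rarefaction cannot appear afterwards.
#'
#' @param table an [otu_table].
#' @param depth target count per sample; defaults to the minimum sample
#'   total.
#' @param seed integer seed for the subsampling.
#' @return a rarefied [otu_table] (taxa with zero total retained).
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  table <- as_otu_table(table)
  m <- unclass_counts(table)
  tot <- rowSums(m)
  if (is.null(depth)) depth <- min(tot)
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be positive")
  if (depth > min(tot))
    stop("depth ", depth, " exceeds the smallest sample total ", min(tot))
  set.seed(seed)
  out <- m
  for (i in seq_len(nrow(m))) {
    if (tot[i] == depth) next
    pool <- rep.int(seq_len(ncol(m)), m[i, ])
    keep <- sample(pool, depth, replace = FALSE)
    out[i, ] <- tabulate(keep, nbins = ncol(m))
  }
  res <- otu_table(out)
  attr(res, "taxonomy") <- attr(table, "taxonomy")
  attr(res, "rarefaction") <- list(depth = depth, seed = seed)
  res
}

#' Restrict a table to its most abundant taxa
#'
#' Keeps the `n` taxa with the largest total counts (ties broken by column
#' order). Composable with [rarefy()] in either order; which order a study
#' intends is a design choice the caller makes explicitly.
#'
#' @param table an [otu_table].
#' @param n number of taxa to keep.
#' @return an [otu_table] with `n` columns.
#' @export
top_taxa <- function(table, n) {
  m <- unclass_counts(as_otu_table(table))
  if (n < 1 || n > ncol(m)) stop("n must be between 1 and the taxon count")
  keep <- order(colSums(m), decreasing = TRUE)[seq_len(n)]
  res <- otu_table(m[, sort(keep), drop = FALSE])
  attr(res, "taxonomy") <- attr(table, "taxonomy")[colnames(res)]
  res
}

# ---------------------------------------------------------------------------
# Phylogenetic tree
# ---------------------------------------------------------------------------

#' Read and validate a rooted phylogenetic tree
#'
#' Parses newick via \pkg{ape} and enforces the contract every phylogenetic
#' stage relies on: unique tip labels and non-negative branch lengths on all
#' edges (missing lengths are rejected, not defaulted).
#'
#' @param path newick file path.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("unparseable newick in ", path)
  validate_tree(tree)
}

#' @rdname read_tree
#' @param tree an [ape::phylo] object to validate in memory.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has edges without branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tree
}

#' Patristic distances between tree tips
#'
#' @param tree an [ape::phylo] object.
#' @param taxa optional taxon ids to restrict (and order) the matrix by;
#'   ids missing from the tree are an error.
#' @return symmetric matrix of tip-to-tip path lengths with zero diagonal.
#' @export
patristic_distances <- function(tree, taxa = NULL) {
  tree <- validate_tree(tree)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, tree$tip.label)
    if (length(missing))
      stop("taxa absent from tree: ", paste(head(missing, 5), collapse = ", "))
  }
  D <- ape::cophenetic.phylo(tree)
  if (!is.null(taxa)) D <- D[taxa, taxa, drop = FALSE]
  D
}

# ---------------------------------------------------------------------------
# Environmental table and group map
# ---------------------------------------------------------------------------

#' Read an environmental-parameter table
#'
#' Tab-separated text, samples as rows, one factor per column. Missing
#' values are a hard error: the analyses assume complete data and no
#' imputation is attempted.
#'
#' @param path file path.
#' @return numeric matrix, samples x factors.
#' @export
read_env_table <- function(path) {
  raw <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                    check.names = FALSE, comment.char = "")
  m <- as.matrix(raw)
  if (!is.numeric(m)) stop("non-numeric environmental values in ", path)
  if (anyNA(m)) stop("missing environmental values in ", path)
  if (anyDuplicated(rownames(m))) stop("duplicate sample id in ", path)
  m
}

#' Read a sample-to-group map
#'
#' Two tab-separated columns: sample id and group label. Every sample must
#' belong to exactly one group.
#'
#' @param path file path.
#' @return named factor of group labels, names are sample ids.
#' @export
read_group_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "", colClasses = "character")
  if (ncol(df) < 2) stop("group map needs sample and group columns")
  if (anyDuplicated(df[[1]])) stop("sample assigned to more than one group")
  as_group_map(setNames(df[[2]], df[[1]]))
}

#' @rdname read_group_map
#' @param groups named character vector or factor (names = sample ids).
#' @export
as_group_map <- function(groups) {
  if (is.null(names(groups))) stop("group map must be named by sample id")
  g <- factor(as.character(groups))
  names(g) <- names(groups)
  if (anyNA(g)) stop("missing group label")
  g
}

# align a group map to the rows of a table, erroring on unknown samples
align_groups <- function(groups, sample_ids) {
  groups <- as_group_map(groups)
  missing <- setdiff(sample_ids, names(groups))
  if (length(missing))
    stop("samples without group assignment: ",
         paste(head(missing, 5), collapse = ", "))
  droplevels(groups[sample_ids])
}
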