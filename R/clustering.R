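## Canberra-distance Ward.D2 clustering and deterministic leaf ordering,
## used to arrange heatmap rows/columns.

#' Canberra distance
#'
#' `canberra_distance()` computes `sum_i |x_i - y_i| / (|x_i| + |y_i|)`
#' between two vectors, with coordinates where both values are exactly zero
#' contributing 0. Note this differs from [stats::dist()]'s Canberra, which
#' drops zero/zero terms and rescales the sum by the number of terms kept;
#' here a zero/zero coordinate simply adds nothing. `canberra_dist()`
#' applies it to every pair of matrix rows.
#'
#' @param x,y Numeric vectors of equal length.
#' @return `canberra_distance()`: a single non-negative number.
#' @examples
#' canberra_distance(c(1, 0), c(0, 1))  # 2
#' canberra_distance(c(0, 3), c(0, 1))  # 0.5
#' @export
canberra_distance <- function(x, y) {
  if (length(x) != length(y)) {
    abort(sprintf("Vectors differ in length (%d vs %d).",
                  length(x), length(y)),
          class = "dormantx_dimension_error")
  }
  num <- abs(x - y)
  den <- abs(x) + abs(y)
  sum(ifelse(den == 0, 0, num / den))
}

#' @rdname canberra_distance
#' @param m Numeric matrix; rows are the objects to compare.
#' @return `canberra_dist()`: a `dist` object over the rows of `m`.
#' @export
canberra_dist <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- canberra_distance(m[i, ], m[j, ])
    }
  }
  as.dist(d)
}

#' Ward minimum-variance (ward.D2) hierarchical clustering
#'
#' Agglomerative clustering with the Ward.D2 criterion: the Lance–Williams
#' update is applied to squared dissimilarities and merge heights are
#' reported back on the original scale, so two singletons at distance `d`
#' merge at height `d`. Input is validated (symmetric, non-negative, zero
#' diagonal).
#'
#' @param d A `dist` object or a symmetric non-negative matrix with zero
#'   diagonal.
#' @return An [stats::hclust] object (fields `merge`, `height`, `order`,
#'   `labels`).
#' @examples
#' pts <- rbind(a = c(0, 0), b = c(0, 1), c = c(5, 5))
#' ward_d2_linkage(dist(pts))$height
#' @export
ward_d2_linkage <- function(d) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-12)) {
      abort("Distance matrix must be symmetric.",
            class = "dormantx_matrix_error")
    }
    if (any(m < 0) || any(abs(diag(m)) > 1e-12)) {
      abort("Distance matrix must be non-negative with zero diagonal.",
            class = "dormantx_matrix_error")
    }
    d <- as.dist(m)
  }
  if (any(d < 0)) {
    abort("Distances must be non-negative.", class = "dormantx_matrix_error")
  }
  hclust(d, method = "ward.D2")
}

#' Deterministic leaf order of a dendrogram
#'
#' Left-to-right depth-first leaf order with a fixed convention: at each
#' merge the earlier-created cluster goes left (singletons count as created
#' before any merge; two singletons order by leaf index). The result is a
#' permutation of all leaves, reproducible regardless of how the linkage
#' implementation happened to orient its subtrees.
#'
#' @param hc An [stats::hclust] object (e.g. from [ward_d2_linkage()]).
#' @return Character vector of leaf labels (or indices as character when the
#'   tree is unlabeled).
#' @export
leaf_order <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  labels <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1L))
  expand <- function(node) {
    if (node < 0) return(-node)          # singleton: leaf index
    a <- hc$merge[node, 1]
    b <- hc$merge[node, 2]
    ## creation time: singletons at 0, cluster k at step k
    ta <- if (a < 0) 0L else a
    tb <- if (b < 0) 0L else b
    first_left <- if (ta != tb) ta < tb else -a < -b
    if (first_left) c(expand(a), expand(b)) else c(expand(b), expand(a))
  }
  labels[expand(nrow(hc$merge))]
}

#' Cluster genes and samples for a heatmap layout
#'
#' Clusters rows (genes) and columns (samples) of `log2(normalized + 1)`
#' values with Canberra distance and Ward.D2 linkage — the arrangement used
#' for the dormancy heatmaps — and returns both trees with deterministic
#' leaf orders. Rows are not z-scaled by default (the heatmaps are based on
#' normalized read counts); set `scale_rows = TRUE` to z-score each gene
#' first.
#'
#' @param experiment A [count_experiment()].
#' @param genes Genes to cluster (rows); default all.
#' @param scale_rows Z-score rows before clustering (default `FALSE`).
#' @param normalized Optional precomputed [normalize_counts()] tibble.
#' @return List with `gene_tree`, `sample_tree` (hclust objects; a
#'   single-row/column input yields `NULL` for that tree), `gene_order`,
#'   `sample_order` (character vectors).
#' @examples
#' sim <- simulate_counts(count_sim_config(n_genes = 60, seed = 4))
#' cl <- cluster_heatmap(sim$experiment)
#' cl$sample_order
#' @export
cluster_heatmap <- function(experiment, genes = NULL, scale_rows = FALSE,
                            normalized = NULL) {
  norm <- resolve_normalized(experiment, normalized)
  if (!is.null(genes)) norm <- norm[norm$gene %in% genes, ]
  m <- log2(as.matrix(norm[experiment$sample_meta$sample]) + 1)
  rownames(m) <- norm$gene
  if (scale_rows) {
    m <- t(scale(t(m)))
    m[is.na(m)] <- 0  # constant rows
  }
  gene_tree <- if (nrow(m) > 1) ward_d2_linkage(canberra_dist(m)) else NULL
  sample_tree <- if (ncol(m) > 1) ward_d2_linkage(canberra_dist(t(m))) else NULL
  list(gene_tree = gene_tree, sample_tree = sample_tree,
       gene_order = if (is.null(gene_tree)) rownames(m) else leaf_order(gene_tree),
       sample_order = if (is.null(sample_tree)) colnames(m) else leaf_order(sample_tree))
}

#' Export a dendrogram as Newick
#'
#' Writes an [stats::hclust] tree in Newick format with merge heights as
#' branch lengths (via [ape::as.phylo()]).
#'
#' @param hc An hclust object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
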