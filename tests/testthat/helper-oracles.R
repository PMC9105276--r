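# Independent brute-force oracles used to validate the filter rules and the
# Ward.D2 linkage, written as direct loops/formulas separate from the
# package's vectorized implementations.

# --- filter-rule oracles: plain per-gene / per-model loops -------------------

# expressed(g, m): TPM >= tpm_min AND count >= count_min in at least one of
# the model's two stage samples; retained: expressed in >= min_models models.
oracle_expression <- function(counts, tpms, meta, cfg) {
  genes <- rownames(counts)
  models <- unique(meta$model)
  retained <- character(0)
  n_expr <- setNames(integer(length(genes)), genes)
  for (g in genes) {
    n_models_expr <- 0L
    for (m in models) {
      expressed <- FALSE
      for (st in c("active", "dormant")) {
        s <- meta$sample[meta$model == m & meta$stage == st]
        if (tpms[g, s] >= cfg$tpm_min && counts[g, s] >= cfg$count_min) {
          expressed <- TRUE
        }
      }
      if (expressed) n_models_expr <- n_models_expr + 1L
    }
    n_expr[g] <- n_models_expr
    if (n_models_expr >= cfg$min_models_expressed) retained <- c(retained, g)
  }
  list(retained = retained, n_expr = n_expr)
}

# direction from per-model fold changes: >= threshold-fold in the same
# direction in >= min_models_de models; both directions qualifying -> none
oracle_de <- function(fc_by_gene, cfg) {
  out <- character(length(fc_by_gene))
  names(out) <- names(fc_by_gene)
  for (g in names(fc_by_gene)) {
    fc <- fc_by_gene[[g]]
    up <- 0L
    down <- 0L
    for (v in fc) {
      if (v >= cfg$fc_threshold) up <- up + 1L
      if (v <= 1 / cfg$fc_threshold) down <- down + 1L
    }
    up_ok <- up >= cfg$min_models_de
    down_ok <- down >= cfg$min_models_de
    out[g] <- if (up_ok && down_ok) "none" else if (up_ok) "up"
      else if (down_ok) "down" else "none"
  }
  out
}

# persistent: stage-mean normalized counts >= floor in BOTH stages (inclusive)
oracle_persistent <- function(norm, meta, cfg) {
  genes <- rownames(norm)
  out <- setNames(logical(length(genes)), genes)
  for (g in genes) {
    ma <- mean(norm[g, meta$sample[meta$stage == "active"]])
    md <- mean(norm[g, meta$sample[meta$stage == "dormant"]])
    out[g] <- ma >= cfg$persistence_floor && md >= cfg$persistence_floor
  }
  out
}

# --- Ward.D2 oracle: greedy merges scored by the direct (Gram-free) ESS
# formula on squared dissimilarities, no Lance-Williams recursion ------------

# squared Ward distance between clusters A, B (index vectors) from the
# squared pairwise matrix: 2|A||B|/(|A|+|B|) * ||mu_A - mu_B||^2, with the
# centroid gap recovered from pairwise sums.
ward_oracle_dist2 <- function(d2, A, B) {
  nA <- length(A)
  nB <- length(B)
  cross <- sum(d2[A, B, drop = FALSE]) / (nA * nB)
  wA <- sum(d2[A, A, drop = FALSE]) / (2 * nA^2)
  wB <- sum(d2[B, B, drop = FALSE]) / (2 * nB^2)
  2 * nA * nB / (nA + nB) * (cross - wA - wB)
}

# returns merges as list of (height, sorted member indices of the new
# cluster); ties broken by smallest (i, j)
ward_oracle <- function(d) {
  d <- as.matrix(d)
  d2 <- d^2
  members <- lapply(seq_len(nrow(d)), identity)
  merges <- list()
  while (length(members) > 1) {
    best <- NULL
    for (i in seq_len(length(members) - 1)) {
      for (j in (i + 1):length(members)) {
        h2 <- ward_oracle_dist2(d2, members[[i]], members[[j]])
        if (is.null(best) || h2 < best$h2 - 1e-12) {
          best <- list(i = i, j = j, h2 = h2)
        }
      }
    }
    merged <- sort(c(members[[best$i]], members[[best$j]]))
    merges[[length(merges) + 1]] <-
      list(height = sqrt(max(best$h2, 0)), members = merged)
    members[[best$i]] <- merged
    members[[best$j]] <- NULL
  }
  merges
}

# hclust result -> same (height, members) representation
hclust_merges <- function(hc) {
  sets <- list()
  out <- list()
  for (s in seq_len(nrow(hc$merge))) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[s]] <- sort(c(grab(hc$merge[s, 1]), grab(hc$merge[s, 2])))
    out[[s]] <- list(height = hc$height[s], members = sets[[s]])
  }
  out
}

# --- shared builders ---------------------------------------------------------

# small experiment from explicit stage-mean matrices (genes x models)
build_experiment <- function(active, dormant, eff_length = NULL) {
  n_models <- ncol(active)
  models <- paste0("M", seq_len(n_models))
  genes <- rownames(active) %||% sprintf("g%02d", seq_len(nrow(active)))
  counts <- tibble::tibble(gene = genes)
  for (i in seq_len(n_models)) {
    counts[[paste0(models[i], "_active")]] <- active[, i]
    counts[[paste0(models[i], "_dormant")]] <- dormant[, i]
  }
  meta <- tibble::tibble(
    sample = as.vector(rbind(paste0(models, "_active"),
                             paste0(models, "_dormant"))),
    model = rep(models, each = 2),
    stage = rep(c("active", "dormant"), n_models))
  len <- eff_length %||% rep(1000, length(genes))
  count_experiment(counts, meta,
                   tibble::tibble(gene = genes, eff_length = len))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
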