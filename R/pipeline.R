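## End-to-end orchestration: partition (optional) -> quantify -> filters ->
## gene sets -> discriminative selection -> clustering, with one master seed
## and a machine-readable summary.

#' Run the dormancy immune-landscape pipeline end to end
#'
#' Executes every stage on either a ready count experiment or per-sample
#' alignment summaries:
#'
#' 1. **partition** (alignment input only) — species partitioning per sample,
#'    strict mode, then unique-gene aggregation into a count matrix;
#' 2. **quantify** — TPM, median-of-ratios size factors, normalized counts,
#'    per-model dormant/active fold changes;
#' 3. **filters** — expression filter, consensus DE calls on retained genes,
#'    dormancy-persistence calls on retained genes;
#' 4. **gene sets** — immune-group annotation of retained/DE/persistent
#'    genes and per-model signature shifts for each supplied signature;
#' 5. **discriminative** — random-forest importance ranking of retained
#'    immune genes;
#' 6. **clustering** — Ward.D2/Canberra trees of DE genes and samples.
#'
#' All randomness derives from `seed`; with a fixed seed the result bundle
#' (and every file written to `output_dir`) is identical across runs.
#'
#' @param experiment A [count_experiment()] (counts-input mode), or `NULL`
#'   when `alignments` is given.
#' @param alignments Named list (one element per sample) of alignment
#'   tibbles; requires `sample_meta` and `eff_length` to assemble the
#'   experiment after partitioning.
#' @param sample_meta,eff_length Experiment assembly inputs for alignment
#'   mode (see [count_experiment()]).
#' @param config A [filter_config()].
#' @param collection [gene_set_collection()] of immune groups.
#' @param signature_sets Named list of signature gene sets to summarize
#'   (default: packaged placeholder proliferation / androgen sets); sets with
#'   fewer than 2 genes present are skipped.
#' @param top_k Number of discriminative genes to select.
#' @param n_trees Random-forest size.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param output_dir Optional directory to write the result tables
#'   (TSV/JSON/Newick) into.
#' @return A `dormancy_run` object: list with `partition`, `size_factors`,
#'   `retained`, `fold_changes`, `de_calls`, `persistent`, `annotation`,
#'   `signature_shifts`, `ranking`, `clustering`, and `summary` (named list
#'   of stage counts).
#' @examples
#' sim <- simulate_counts(count_sim_config(n_genes = 300, seed = 9))
#' run <- run_pipeline(sim$experiment, seed = 9)
#' glance(run)
#' @export
run_pipeline <- function(experiment = NULL, alignments = NULL,
                         sample_meta = NULL, eff_length = NULL,
                         config = filter_config(),
                         collection = immune_gene_groups(),
                         signature_sets = default_signature_sets(),
                         top_k = 54, n_trees = 1000, seed = 1L,
                         output_dir = NULL) {
  if (is.null(experiment) == is.null(alignments)) {
    abort("Provide exactly one of `experiment` or `alignments`.",
          class = "dormantx_config_error")
  }

  partition <- NULL
  if (!is.null(alignments)) {
    if (is.null(sample_meta) || is.null(eff_length)) {
      abort("Alignment mode needs `sample_meta` and `eff_length`.",
            class = "dormantx_config_error")
    }
    parts <- lapply(alignments, partition_reads, mode = "strict")
    genes <- eff_length$gene
    counts <- tibble(gene = genes)
    for (nm in names(alignments)) {
      counts[[nm]] <- aggregate_counts(parts[[nm]]$reads, genes = genes)$count
    }
    partition <- purrr::map_dfr(parts, "report", .id = "sample")
    experiment <- count_experiment(counts, sample_meta, eff_length)
  }

  tpm_table <- tpm(experiment)
  sf <- size_factors(experiment)
  normalized <- normalize_counts(experiment)

  ef <- expression_filter(experiment, config, tpm_table = tpm_table)
  fc <- model_fold_changes(experiment, normalized = normalized)
  fc_retained <- fc[fc$gene %in% ef$genes, ]
  de <- consensus_de(fc_retained, config)
  pers <- persistent_genes(experiment, config, normalized = normalized)
  pers <- pers[pers$gene %in% ef$genes, ]

  annotation <- annotate_genes(ef$genes, collection)
  immune_genes <- annotation$gene[annotation$group != "unannotated"]

  shifts <- purrr::imap_dfr(signature_sets %||% list(), function(gs, nm) {
    if (length(intersect(gs, normalized$gene)) < 2) return(NULL)
    dplyr::mutate(
      signature_summary(experiment, gs, normalized = normalized)$model_shift,
      signature = nm, .before = 1)
  })

  ranking <- NULL
  if (length(intersect(immune_genes, normalized$gene)) >= 2) {
    ranking <- select_discriminative_features(
      experiment, genes = immune_genes, n_trees = n_trees,
      seed = derive_seed(seed, "forest"), rule_value = top_k,
      normalized = normalized)
  }

  de_genes <- de$gene[de$direction != "none"]
  clustering <- if (length(de_genes) >= 2) {
    cluster_heatmap(experiment, genes = de_genes, normalized = normalized)
  } else NULL

  de_immune <- de[de$direction != "none" & de$gene %in% immune_genes, ]
  summary <- list(
    mode = if (is.null(partition)) "counts" else "alignments",
    partition = if (is.null(partition)) "skipped" else
      as.list(colSums(partition[-1])),
    n_models = length(unique(experiment$sample_meta$model)),
    n_genes = nrow(experiment$counts),
    n_retained = length(ef$genes),
    n_de = sum(de$direction != "none"),
    n_de_up = sum(de$direction == "up"),
    n_de_down = sum(de$direction == "down"),
    n_persistent = sum(pers$persistent),
    n_immune_retained = length(immune_genes),
    n_de_immune = nrow(de_immune),
    n_persistent_immune = sum(pers$persistent & pers$gene %in% immune_genes),
    n_selected = if (is.null(ranking)) 0L else sum(ranking$ranking$selected),
    seed = as.integer(seed))

  run <- structure(
    list(partition = partition, size_factors = sf, retained = ef,
         fold_changes = fc, de_calls = de, persistent = pers,
         annotation = annotation, signature_shifts = shifts,
         ranking = ranking, clustering = clustering, summary = summary,
         config = config),
    class = "dormancy_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

## write the result bundle as plain-text tables; deterministic byte-for-byte
## under a fixed seed
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(dir, f)
  readr::write_tsv(run$retained$summary, out("retained_genes.tsv"))
  fc_wide <- tidyr::pivot_wider(run$fold_changes, names_from = "model",
                                values_from = "fc", names_prefix = "fc_")
  readr::write_tsv(
    dplyr::left_join(run$de_calls, fc_wide, by = "gene"),
    out("de_calls.tsv"))
  readr::write_tsv(run$persistent, out("persistent_genes.tsv"))
  readr::write_tsv(run$size_factors, out("size_factors.tsv"))
  readr::write_tsv(run$annotation, out("gene_annotation.tsv"))
  if (!is.null(run$signature_shifts) && nrow(run$signature_shifts) > 0) {
    readr::write_tsv(run$signature_shifts, out("signature_shifts.tsv"))
  }
  if (!is.null(run$ranking)) {
    readr::write_tsv(tidy(run$ranking), out("feature_ranking.tsv"))
  }
  if (!is.null(run$clustering)) {
    writeLines(run$clustering$gene_order, out("gene_order.txt"))
    writeLines(run$clustering$sample_order, out("sample_order.txt"))
    write_newick(run$clustering$gene_tree, out("gene_tree.nwk"))
    write_newick(run$clustering$sample_tree, out("sample_tree.nwk"))
  }
  if (!is.null(run$partition)) {
    readr::write_tsv(run$partition, out("partition_report.tsv"))
  }
  jsonlite::write_json(run$summary, out("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.dormancy_run <- function(x, ...) {
  s <- x$summary
  cat("<dormancy_run>\n")
  cat(sprintf("  %d genes, %d retained; DE: %d (%d up / %d down); persistent: %d\n",
              s$n_genes, s$n_retained, s$n_de, s$n_de_up, s$n_de_down,
              s$n_persistent))
  cat(sprintf("  immune: %d retained, %d DE, %d persistent; %d selected by forest\n",
              s$n_immune_retained, s$n_de_immune, s$n_persistent_immune,
              s$n_selected))
  invisible(x)
}

#' @describeIn run_pipeline DE calls joined with immune annotation, one row
#'   per retained gene.
#' @param x A `dormancy_run`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dormancy_run <- function(x, ...) {
  dplyr::left_join(x$de_calls, x$annotation, by = "gene") |>
    dplyr::left_join(dplyr::select(x$persistent, "gene", "persistent"),
                     by = "gene")
}

#' @describeIn run_pipeline One-row tibble of the stage counts.
#' @exportS3Method generics::glance
glance.dormancy_run <- function(x, ...) {
  s <- x$summary
  as_tibble(s[setdiff(names(s), c("partition", "mode"))])
}

#' Replay printed DE directions through the consensus rule
#'
#' Classification replay: takes a table of printed gene/direction calls
#' (e.g. `load_fixture("table2")`), synthesizes per-model fold changes
#' consistent with each printed direction (`de_fold`-fold in every model,
#' inverted for Down), and runs [consensus_de()] on them. Checks that the
#' rule as implemented reproduces every printed Up/Down label.
#'
#' @param calls Data frame with columns `gene` and `direction`
#'   (case-insensitive `up`/`down`).
#' @param config A [filter_config()].
#' @param n_models Number of models to synthesize.
#' @param de_fold Fold change planted in each model (must clear
#'   `config$fc_threshold`).
#' @return Tibble `gene`, `printed`, `replayed`, `match`.
#' @examples
#' replay <- replay_de_calls(load_fixture("table2"))
#' all(replay$match)
#' @export
replay_de_calls <- function(calls, config = filter_config(), n_models = 5,
                            de_fold = 4) {
  printed <- tolower(calls$direction)
  stopifnot(all(printed %in% c("up", "down")))
  fc <- tibble(
    gene = rep(calls$gene, each = n_models),
    model = rep(model_ids(n_models), nrow(calls)),
    fc = rep(ifelse(printed == "up", de_fold, 1 / de_fold),
             each = n_models))
  replayed <- consensus_de(fc, config)
  tibble(gene = calls$gene, printed = printed) |>
    dplyr::left_join(dplyr::select(replayed, "gene", replayed = "direction"),
                     by = "gene") |>
    dplyr::mutate(match = .data$printed == .data$replayed)
}
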