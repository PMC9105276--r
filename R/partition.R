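## Species partitioning of reads aligned to a combined human+mouse
## reference. PDX tissue mixes human tumor cells with mouse stroma; only
## reads mapping exclusively to the human genome/transcriptome feed the
## downstream expression analysis.

SPECIES_LEVELS <- c("human", "mouse")

validate_alignments <- function(alignments) {
  alignments <- as_tibble(alignments)
  need <- c("read_id", "species", "target_id", "score")
  if (!all(need %in% names(alignments))) {
    abort(sprintf("Alignment table needs columns: %s.",
                  paste(need, collapse = ", ")),
          class = "dormantx_format_error")
  }
  bad <- !is.na(alignments$species) &
    !alignments$species %in% SPECIES_LEVELS
  if (any(bad)) {
    abort(sprintf(
      "Unknown species tag '%s' for read '%s' (expected human/mouse).",
      alignments$species[bad][1], alignments$read_id[bad][1]),
      class = "dormantx_format_error")
  }
  alignments
}

#' Classify reads by species of alignment
#'
#' Assigns each read one of four categories from its hits in the combined
#' reference: `human_only` (all hits human), `mouse_only` (all hits mouse),
#' `both` (hits in each species), `unmapped` (no hits).
#'
#' @param alignments Per-hit tibble with columns `read_id`, `species`
#'   (`"human"`/`"mouse"`, `NA` for an unmapped placeholder row),
#'   `target_id`, `score` — as produced by [simulate_reads()],
#'   [read_alignment_tsv()] or [read_alignment_sam()].
#' @return A tibble `read_id`, `category`, one row per read, in first-seen
#'   read order.
#' @examples
#' aln <- tibble::tribble(
#'   ~read_id, ~species, ~target_id, ~score,
#'   "r1", "human", "GENE1", 60,
#'   "r2", "human", "GENE1", 60,
#'   "r2", "mouse", "Gm123", 58,
#'   "r3", NA, NA, 0)
#' classify_reads(aln)
#' @export
classify_reads <- function(alignments) {
  alignments <- validate_alignments(alignments)
  alignments |>
    dplyr::group_by(read_id = factor(.data$read_id,
                                     levels = unique(.data$read_id))) |>
    dplyr::summarise(
      has_human = any(.data$species == "human", na.rm = TRUE),
      has_mouse = any(.data$species == "mouse", na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(
      read_id = as.character(.data$read_id),
      category = dplyr::case_when(
        .data$has_human & .data$has_mouse ~ "both",
        .data$has_human ~ "human_only",
        .data$has_mouse ~ "mouse_only",
        TRUE ~ "unmapped")) |>
    dplyr::select("read_id", "category")
}

#' Partition reads and retain the human subset
#'
#' Splits reads by species category and returns the human-retained subset.
#' In `"strict"` mode (the default) only `human_only` reads are kept —
#' reads with any mouse alignment are excluded. In `"score_margin"` mode,
#' `both` reads are additionally rescued when their best human alignment
#' score exceeds their best mouse score by at least `margin`; reads not
#' meeting the margin (including ties) stay excluded, keeping the retained
#' set conservative toward human specificity.
#'
#' @inheritParams classify_reads
#' @param mode `"strict"` or `"score_margin"`.
#' @param margin Non-negative score margin for rescue (score_margin mode).
#' @return A list: `reads` — the human alignment rows of retained reads —
#'   and `report`, a one-row tibble with `n_total`, `n_human_only`,
#'   `n_mouse_only`, `n_both`, `n_unmapped`, `n_retained` (the category
#'   counts always sum to `n_total`).
#' @examples
#' sim <- simulate_reads(read_sim_config(n_reads = 500, seed = 1))
#' partition_reads(sim$alignments)$report
#' @export
partition_reads <- function(alignments, mode = c("strict", "score_margin"),
                            margin = 0) {
  mode <- match.arg(mode)
  alignments <- validate_alignments(alignments)
  if (nrow(alignments) == 0) {
    abort("Empty alignment input.", class = "dormantx_empty_input_error")
  }
  if (margin < 0) {
    abort("`margin` must be >= 0.", class = "dormantx_config_error")
  }
  cls <- classify_reads(alignments)
  keep <- cls$read_id[cls$category == "human_only"]
  if (mode == "score_margin") {
    both_ids <- cls$read_id[cls$category == "both"]
    if (length(both_ids) > 0) {
      best <- alignments |>
        dplyr::filter(.data$read_id %in% both_ids) |>
        dplyr::group_by(.data$read_id, .data$species) |>
        dplyr::summarise(best = max(.data$score), .groups = "drop") |>
        tidyr::pivot_wider(names_from = "species", values_from = "best")
      rescued <- best$read_id[best$human - best$mouse >= margin &
                                best$human - best$mouse > 0]
      if (margin == 0) {
        ## a zero margin still requires a strictly better human score
        rescued <- best$read_id[best$human > best$mouse]
      }
      keep <- c(keep, rescued)
    }
  }
  report <- tibble(
    n_total = nrow(cls),
    n_human_only = sum(cls$category == "human_only"),
    n_mouse_only = sum(cls$category == "mouse_only"),
    n_both = sum(cls$category == "both"),
    n_unmapped = sum(cls$category == "unmapped"),
    n_retained = length(keep))
  reads <- alignments |>
    dplyr::filter(.data$read_id %in% keep, .data$species == "human")
  list(reads = reads, report = report)
}

#' Read alignment summaries from the TSV dialect
#'
#' One row per hit: `read_id<TAB>species<TAB>target_id<TAB>score`; unmapped
#' reads appear once with empty species/target and score 0.
#'
#' @param path TSV file path (with header).
#' @return Alignment tibble as accepted by [classify_reads()].
#' @export
read_alignment_tsv <- function(path) {
  aln <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           read_id = readr::col_character(),
                           species = readr::col_character(),
                           target_id = readr::col_character(),
                           score = readr::col_double()))
  validate_alignments(aln)
}

#' Read alignment summaries from a SAM/BAM file
#'
#' Maps reference-sequence-name prefixes to species (default `GRCh38_` /
#' `GRCm38_`) and takes the alignment score from the `AS` tag when present,
#' else the mapping quality. Requires the Rsamtools package.
#'
#' @param path SAM or BAM file path.
#' @param prefixes Named character vector `c(human = ..., mouse = ...)` of
#'   reference-name prefixes.
#' @return Alignment tibble as accepted by [classify_reads()].
#' @export
read_alignment_sam <- function(path,
                               prefixes = c(human = "GRCh38_",
                                            mouse = "GRCm38_")) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("Rsamtools is required to read SAM/BAM input.",
          class = "dormantx_format_error")
  }
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "mapq"), tag = "AS")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  rname <- as.character(x$rname)
  species <- rep(NA_character_, length(rname))
  target <- rep(NA_character_, length(rname))
  for (sp in names(prefixes)) {
    hit <- !is.na(rname) & startsWith(rname, prefixes[[sp]])
    species[hit] <- sp
    target[hit] <- sub(prefixes[[sp]], "", rname[hit], fixed = TRUE)
  }
  unknown <- !is.na(rname) & is.na(species)
  if (any(unknown)) {
    abort(sprintf(
      "Reference name '%s' (read '%s') matches no species prefix.",
      rname[unknown][1], x$qname[unknown][1]),
      class = "dormantx_format_error")
  }
  as_tag <- x$tag$AS %||% rep(NA_integer_, length(rname))
  score <- ifelse(is.na(as_tag), x$mapq, as_tag)
  score[is.na(rname)] <- 0
  validate_alignments(tibble(read_id = x$qname, species = species,
                             target_id = target, score = as.numeric(score)))
}
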