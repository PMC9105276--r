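## Packaged reference fixtures: the printed PDX model metadata and gene
## tables, the immune gene groups, and the synthetic signature sets.

FIXTURE_FILES <- c(
  table1 = "table1_pdx_models.tsv",
  table2 = "table2_de_immune_genes.tsv",
  table3 = "table3_persistent_immune_genes.tsv",
  immune_groups = "immune_groups.gmt",
  proliferation_set = "signatures_synthetic.gmt",
  androgen_set = "signatures_synthetic.gmt")

#' Load a packaged fixture table
#'
#' Packaged transcriptions of the published result tables plus the shipped
#' gene-set files:
#'
#' * `"table1"` — molecular characteristics of the five PDX models
#'   (AR/PSA/SYP/ERG status, TMPRSS2-ERG fusion, PTEN status).
#' * `"table2"` — the 34 differentially expressed immune-related genes in
#'   dormancy with family and direction (30 up, 4 down).
#' * `"table3"` — the 24 dormancy-persistent immune-related genes with
#'   family.
#' * `"immune_groups"` — the 20 immune gene groups, as a long tibble
#'   (`group`, `gene`).
#' * `"proliferation_set"` / `"androgen_set"` — the synthetic placeholder
#'   signatures, as a long tibble (`set`, `gene`).
#'
#' Gene symbols are transcribed as printed, with formatting artifacts
#' normalized (noted in the fixture file headers).
#'
#' @param name One of the fixture names above.
#' @return A tibble.
#' @examples
#' nrow(load_fixture("table2"))
#' dplyr::count(load_fixture("table2"), direction)
#' @export
load_fixture <- function(name) {
  if (length(name) != 1L || !name %in% names(FIXTURE_FILES)) {
    abort(sprintf("Unknown fixture '%s'; available: %s.",
                  paste(name, collapse = ", "),
                  paste(names(FIXTURE_FILES), collapse = ", ")),
          class = "dormantx_lookup_error")
  }
  path <- system.file("extdata", FIXTURE_FILES[[name]], package = "dormantx")
  if (grepl("\\.gmt$", path)) {
    sets <- read_gmt(path)
    if (name == "proliferation_set") sets <- sets["proliferation"]
    if (name == "androgen_set") sets <- sets["androgen_response"]
    out <- tibble(set = rep(names(sets), lengths(sets)),
                  gene = unlist(sets, use.names = FALSE))
    if (name == "immune_groups") names(out)[1] <- "group"
    return(out)
  }
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  na = character())
}
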