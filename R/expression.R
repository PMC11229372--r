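# Cross-tabulation of differential expression against binding categories,
# and qChIP percent-input normalization.

#' Read a differential-expression table
#'
#' Expects a TSV with columns `gene_id`, `log2FC` (or `log2fc`) and `FDR`
#' (or `fdr`).
#'
#' @param path TSV path.
#' @param fdr_threshold Significance threshold on the FDR column
#'   (default 0.05).
#' @return A tibble: `gene_id`, `log2fc`, `fdr`, `significant`.
#' @export
read_de_table <- function(path, fdr_threshold = 0.05) {
  if (!file.exists(path)) {
    pc_abort(sprintf("DE table not found: %s", path), "pc_io_error")
  }
  raw <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         show_col_types = FALSE)
  names(raw) <- tolower(names(raw))
  needed <- c("gene_id", "log2fc", "fdr")
  if (!all(needed %in% names(raw))) {
    pc_abort("DE table needs columns gene_id, log2FC, FDR", "pc_parse_error")
  }
  tibble::tibble(gene_id = as.character(raw$gene_id),
                 log2fc = as.double(raw$log2fc),
                 fdr = as.double(raw$fdr),
                 significant = raw$fdr < fdr_threshold)
}

#' Summarise differential expression per binding category
#'
#' For each category of genes (e.g. motif status crossed with chromatin
#' compartment), reports the number of genes, how many are differentially
#' expressed, the DE proportion, and the mean log2 fold change over
#' down-regulated (`log2fc < 0`), up-regulated (`log2fc > 0`) and all
#' significant genes. Empty strata yield `NA` means, not zero. A
#' significant gene with `log2fc` exactly 0 counts in "all DE" but in
#' neither direction.
#'
#' @param de DE tibble with columns `gene_id`, `log2fc` and either
#'   `significant` or `fdr` (thresholded at `fdr_threshold`).
#' @param categories Tibble mapping `gene_id` to `category`; genes absent
#'   from it are dropped.
#' @param fdr_threshold Used only when `de` lacks a `significant` column.
#' @return A tibble, one row per category: `category`, `n_genes`, `n_de`,
#'   `prop_de`, `mean_lfc_down`, `mean_lfc_up`, `mean_lfc_de`.
#' @export
de_overlap_summary <- function(de, categories, fdr_threshold = 0.05) {
  de <- tibble::as_tibble(de)
  if (anyDuplicated(de$gene_id)) {
    pc_abort("duplicate gene_id in the DE table", "pc_validation_error")
  }
  if (!"significant" %in% names(de)) {
    if (!"fdr" %in% names(de)) {
      pc_abort("`de` needs a `significant` or `fdr` column", "pc_type_error")
    }
    de$significant <- de$fdr < fdr_threshold
  }
  if (!all(c("gene_id", "category") %in% names(categories))) {
    pc_abort("`categories` needs columns gene_id and category", "pc_type_error")
  }
  joined <- dplyr::inner_join(de, tibble::as_tibble(categories), by = "gene_id")
  mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  joined |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_de = sum(.data$significant),
      prop_de = sum(.data$significant) / dplyr::n(),
      mean_lfc_down = mean_or_na(.data$log2fc[.data$significant & .data$log2fc < 0]),
      mean_lfc_up = mean_or_na(.data$log2fc[.data$significant & .data$log2fc > 0]),
      mean_lfc_de = mean_or_na(.data$log2fc[.data$significant]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$category)
}

#' Normalise qChIP percent-input against a positive control region
#'
#' ChIP enrichment measured as percent of input DNA is divided by the
#' percent-input of a positive genomic control site, giving a unitless
#' enrichment relative to the control. Vectorised over replicates.
#'
#' @param pct_input_target Percent-input at the region of interest (>= 0).
#' @param pct_input_reference Percent-input at the positive control
#'   (> 0).
#' @return `pct_input_target / pct_input_reference`.
#' @examples
#' normalize_qchip(2, 4)  # 0.5
#' @export
normalize_qchip <- function(pct_input_target, pct_input_reference) {
  if (any(pct_input_target < 0) || any(pct_input_reference < 0)) {
    pc_abort("percent-input values must be non-negative", "pc_validation_error")
  }
  if (any(pct_input_reference == 0)) {
    pc_abort("reference percent-input is zero: cannot normalise",
             "pc_division_error")
  }
  pct_input_target / pct_input_reference
}

#' Summarise replicate qChIP enrichment
#'
#' Normalises each replicate's percent-input against the matching
#' replicate of the reference region, then reports the mean and standard
#' deviation per region.
#'
#' @param qchip Tibble with columns `region`, `replicate`, `pct_input`.
#' @param reference Name of the positive-control region present in
#'   `qchip`.
#' @return A tibble: `region`, `n`, `mean_enrichment`, `sd_enrichment`.
#' @export
qchip_summary <- function(qchip, reference) {
  qchip <- tibble::as_tibble(qchip)
  if (!all(c("region", "replicate", "pct_input") %in% names(qchip))) {
    pc_abort("`qchip` needs columns region, replicate, pct_input", "pc_type_error")
  }
  ref <- qchip[qchip$region == reference, c("replicate", "pct_input")]
  if (nrow(ref) == 0) {
    pc_abort(sprintf("reference region '%s' not found", reference), "pc_validation_error")
  }
  names(ref)[2] <- "ref_pct"
  qchip |>
    dplyr::filter(.data$region != reference) |>
    dplyr::inner_join(ref, by = "replicate") |>
    dplyr::mutate(enrichment = normalize_qchip(.data$pct_input, .data$ref_pct)) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_enrichment = mean(.data$enrichment),
                     sd_enrichment = stats::sd(.data$enrichment),
                     .groups = "drop")
}
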