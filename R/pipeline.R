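# End-to-end orchestration: simulate (or load) -> annotate -> scan ->
# colocalize -> DE link, with persisted TSV artifacts and a run log.

#' Assemble a pipeline run configuration
#'
#' Exactly one input mode must be used: a synthetic study (`synth`, a
#' [synth_config()]) or real files (`peaks` as a named label = path vector,
#' plus `gtf` and `housekeeping`; `fasta` and `pwm` enable motif flagging
#' and `de_table` enables the expression link).
#'
#' @param synth Optional [synth_config()].
#' @param peaks Named character vector of peak file paths (labels become
#'   protein names).
#' @param peak_format `"bed"` or `"narrowPeak"`.
#' @param gtf,housekeeping,fasta,de_table Optional input file paths.
#' @param pwm Optional `pwm` object or path to a count TSV.
#' @param het_map Optional heterochromatin map tibble or BED path; real
#'   runs default to [dm6_heterochromatin()].
#' @param halfwidth Promoter half-width in bases (default 200).
#' @param anchor Peak anchor, `"summit"` or `"midpoint"`.
#' @param p_threshold Motif p-value threshold (default 1e-4).
#' @param n_samples Monte Carlo draws per protein pair (default 5000).
#' @param seed Master seed for the whole run.
#' @return A `run_config` list.
#' @export
run_config <- function(synth = NULL, peaks = NULL, peak_format = "bed",
                       gtf = NULL, housekeeping = NULL, fasta = NULL,
                       pwm = NULL, het_map = NULL, de_table = NULL,
                       halfwidth = 200L, anchor = "summit",
                       p_threshold = 1e-4, n_samples = 5000L, seed = 1L) {
  structure(
    list(synth = synth, peaks = peaks, peak_format = peak_format, gtf = gtf,
         housekeeping = housekeeping, fasta = fasta, pwm = pwm,
         het_map = het_map, de_table = de_table,
         halfwidth = as.integer(halfwidth), anchor = anchor,
         p_threshold = p_threshold, n_samples = as.integer(n_samples),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

validate_run_config <- function(cfg) {
  if (!inherits(cfg, "run_config")) {
    pc_abort("`cfg` must come from run_config()", "pc_type_error")
  }
  synthetic <- !is.null(cfg$synth)
  real <- !is.null(cfg$peaks)
  if (synthetic == real) {
    pc_abort("exactly one of `synth` or `peaks` must be supplied", "pc_config_error")
  }
  if (real) {
    for (field in c("gtf", "housekeeping")) {
      if (is.null(cfg[[field]])) {
        pc_abort(sprintf("real-input runs require `%s`", field), "pc_config_error")
      }
    }
    paths <- c(cfg$peaks, cfg$gtf, cfg$housekeeping, cfg$fasta, cfg$de_table)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      pc_abort(sprintf("input file not found: %s", missing[1]), "pc_config_error")
    }
    if (!is.null(cfg$pwm) && is.null(cfg$fasta)) {
      pc_abort("motif scanning requires a `fasta` genome", "pc_config_error")
    }
  }
  invisible(cfg)
}

#' Run the full colocalization pipeline
#'
#' Validates the configuration up front (failing before any stage runs),
#' then executes: input acquisition (synthetic simulation or file
#' loading), peak annotation with compartment labels, optional motif
#' flagging, the pairwise Monte Carlo colocalization test over the
#' housekeeping promoter universe, distribution and combination-count
#' summaries, and (when a DE table is available) the expression link.
#' All tabular outputs are written under `outdir` with a provenance
#' header (package version, config hash, seed); identical configuration
#' and seed give byte-identical outputs.
#'
#' @param cfg A [run_config()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a list with `annotated`, `coloc` (a `coloc_test`),
#'   `distribution`, `combinations`, and when applicable `de_summary` and
#'   `flags`, plus the `files` written.
#' @export
run_coloc_pipeline <- function(cfg, outdir) {
  validate_run_config(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(cfg)
  header <- output_header(cfg$seed, cfg_hash)
  log_lines <- c(header,
                 sprintf("# anchor: %s", cfg$anchor),
                 sprintf("# promoter halfwidth: %d", cfg$halfwidth),
                 sprintf("# motif p threshold: %g", cfg$p_threshold),
                 sprintf("# tie rule: strict_greater; smoothing: none; Fo denominator: union"),
                 sprintf("# n_samples per pair: %d", cfg$n_samples))

  # --- acquire inputs ---
  if (!is.null(cfg$synth)) {
    study <- simulate_study(cfg$synth)
    genes <- study$genes
    het_map <- study$het_map
    peak_tbl <- study$peaks
    genome <- study$genome
    pwm <- cfg$synth$motif
    log_lines <- c(log_lines, "# input mode: synthetic")
  } else {
    genes <- read_gtf_genes(cfg$gtf, housekeeping = cfg$housekeeping)
    het_map <- cfg$het_map
    if (is.null(het_map)) het_map <- dm6_heterochromatin()
    if (is.character(het_map)) het_map <- read_peaks(het_map, "bed")[, c("chrom", "start", "end")]
    peak_tbl <- purrr::imap(cfg$peaks, function(p, lab) {
      read_peaks(p, cfg$peak_format, label = lab)
    }) |> dplyr::bind_rows()
    genome <- if (!is.null(cfg$fasta)) {
      as.character(Biostrings::readDNAStringSet(cfg$fasta))
    } else NULL
    if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))
    pwm <- cfg$pwm
    if (is.character(pwm)) pwm <- read_pwm(pwm, "tsv")
    log_lines <- c(log_lines, "# input mode: files")
  }

  # --- annotate ---
  annotated <- annotate_peaks(peak_tbl, genes, het_map,
                              halfwidth = cfg$halfwidth, anchor = cfg$anchor)

  # --- motif flags ---
  flags <- NULL
  if (!is.null(pwm) && !is.null(genome)) {
    flags <- flag_motif_peaks(peak_tbl, genome, pwm, p = cfg$p_threshold)
  }
  annotated$has_motif <- if (is.null(flags)) NA else flags

  # --- bound sets and colocalization ---
  hk_universe <- genes$gene_id[genes$housekeeping]
  bound <- annotated |>
    dplyr::filter(.data$feature == "promoter",
                  .data$gene_id %in% hk_universe) |>
    dplyr::distinct(.data$label, .data$gene_id) |>
    dplyr::select(protein = "label", "gene_id")
  coloc <- NULL
  if (dplyr::n_distinct(bound$protein) >= 2) {
    coloc <- coloc_test(bound, hk_universe, n_samples = cfg$n_samples,
                        seed = cfg$seed)
  }

  # --- summaries ---
  distribution <- summarize_peak_distribution(
    peak_tbl, genes, het_map,
    motif_flags = if (is.null(flags)) NULL else flags,
    halfwidth = cfg$halfwidth, anchor = cfg$anchor)
  merged <- merge_union(peak_tbl)
  combos <- combination_counts(merged)

  # --- expression link ---
  de_summary <- NULL
  if (!is.null(cfg$de_table)) {
    de <- read_de_table(cfg$de_table)
    categories <- annotated |>
      dplyr::filter(.data$feature == "promoter", !is.na(.data$gene_id)) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(
        category = paste0(.data$compartment[1],
                          if (isTRUE(any(.data$has_motif))) "_with_motif" else "_no_motif"),
        .groups = "drop")
    de_summary <- de_overlap_summary(de, categories)
  }

  # --- persist ---
  files <- character()
  save_tbl <- function(tbl, fname) {
    path <- file.path(outdir, fname)
    write_tsv_with_header(tbl, path, header)
    files[[length(files) + 1]] <<- path
  }
  save_tbl(annotated, "annotated_peaks.tsv")
  save_tbl(distribution, "peak_distribution.tsv")
  save_tbl(dplyr::mutate(combos, combination = as.character(.data$combination)),
           "combination_counts.tsv")
  if (!is.null(coloc)) save_tbl(tidy(coloc), "coloc_results.tsv")
  if (!is.null(de_summary)) save_tbl(de_summary, "de_summary.tsv")
  writeLines(log_lines, file.path(outdir, "run_log.txt"))

  invisible(list(annotated = annotated, coloc = coloc,
                 distribution = distribution, combinations = combos,
                 de_summary = de_summary, flags = flags, files = files))
}
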