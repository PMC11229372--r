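# Peak annotation around transcription start sites, the euchromatin /
# pericentromeric-heterochromatin partition, and promoter gene-set mapping.
#
# Gene models are tibbles with columns gene_id, chrom, strand, start, end,
# tss (all 0-based half-open; tss is a single 0-based position) and a
# logical housekeeping flag.

#' Built-in dm6 pericentromeric heterochromatin map
#'
#' Fixed coordinate blocks around the dm6 centromeres, stored 0-based
#' half-open (the published 1-based inclusive spans converted on entry).
#' Everything outside these blocks is treated as euchromatin.
#'
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
dm6_heterochromatin <- function() {
  tibble::tibble(
    chrom = c("2L", "2R", "3L", "3R", "X"),
    start = c(22000974L, 0L, 22962475L, 0L, 22628489L),
    end   = c(23513712L, 5398184L, 28110227L, 4174178L, 23542271L)
  )
}

#' Read gene models from a GTF file
#'
#' Keeps rows whose feature is `gene` (falling back to `transcript` when no
#' gene rows exist), extracts the `gene_id` attribute, and converts GTF
#' 1-based inclusive coordinates to the package's 0-based half-open
#' convention. The TSS is the span start for `+` genes and the last base of
#' the span for `-` genes.
#'
#' @param path GTF file path.
#' @param housekeeping Optional character vector (or path to a one-id-per-line
#'   file, see [read_housekeeping()]) marking housekeeping genes.
#' @return A gene-model tibble: `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss`, `housekeeping`.
#' @export
read_gtf_genes <- function(path, housekeeping = NULL) {
  if (!file.exists(path)) {
    pc_abort(sprintf("GTF file not found: %s", path), "pc_io_error")
  }
  raw <- readr::read_tsv(
    path, comment = "#", col_names = c("seqname", "source", "feature", "start",
                                       "end", "score", "strand", "frame",
                                       "attribute"),
    col_types = "ccciicccc", progress = FALSE
  )
  rows <- raw[raw$feature == "gene", ]
  if (nrow(rows) == 0) rows <- raw[raw$feature == "transcript", ]
  if (nrow(rows) == 0) {
    pc_abort("GTF contains no gene or transcript rows", "pc_parse_error")
  }
  gene_id <- stringr::str_match(rows$attribute, 'gene_id[ =]+"?([^";]+)"?')[, 2]
  if (anyNA(gene_id)) {
    pc_abort("GTF attribute column lacks gene_id", "pc_parse_error")
  }
  genes <- tibble::tibble(
    gene_id = gene_id,
    chrom = rows$seqname,
    strand = rows$strand,
    start = rows$start - 1L,   # GTF is 1-based inclusive
    end = rows$end,
    tss = ifelse(rows$strand == "-", rows$end - 1L, rows$start - 1L)
  )
  genes <- dplyr::distinct(genes, .data$gene_id, .keep_all = TRUE)
  hk <- character()
  if (!is.null(housekeeping)) {
    hk <- if (length(housekeeping) == 1 && file.exists(housekeeping)) {
      read_housekeeping(housekeeping)
    } else {
      as.character(housekeeping)
    }
  }
  genes$housekeeping <- genes$gene_id %in% hk
  dplyr::arrange(genes, .data$chrom, .data$tss)
}

#' Read a housekeeping-gene list (one gene id per line)
#'
#' @param path File with one gene identifier per line; a header line named
#'   `gene_id` is tolerated.
#' @return Character vector of gene ids.
#' @export
read_housekeeping <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids) & ids != "gene_id"]
  unique(ids)
}

#' Promoter windows around gene TSSs
#'
#' The promoter is the symmetric, strand-independent window of
#' `halfwidth` bases either side of the TSS (inclusive on both sides, so
#' 2 * halfwidth + 1 positions), clipped at the chromosome origin.
#'
#' @param genes Gene-model tibble.
#' @param halfwidth Half-width in bases (default 200, i.e. a +/-200 bp
#'   window).
#' @return A tibble `gene_id`, `chrom`, `start`, `end`, `tss` with the
#'   promoter span in 0-based half-open coordinates.
#' @export
promoter_windows <- function(genes, halfwidth = 200L) {
  if (!is.numeric(halfwidth) || halfwidth <= 0) {
    pc_abort("`halfwidth` must be a positive number of bases", "pc_validation_error")
  }
  halfwidth <- as.integer(halfwidth)
  tibble::tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = pmax(genes$tss - halfwidth, 0L),
    end = genes$tss + halfwidth + 1L,
    tss = genes$tss
  )
}

# Resolve each anchor point to (feature, gene_id) against gene models.
# Returns a tibble aligned to `anchors` rows.
resolve_features <- function(chrom, pos, genes, halfwidth) {
  n <- length(pos)
  feature <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  unknown <- !(chrom %in% unique(genes$chrom))
  if (any(unknown)) {
    rlang::warn(sprintf("%d peak(s) on chromosome(s) absent from the gene models; labelled intergenic",
                        sum(unknown)))
  }
  prom <- promoter_windows(genes, halfwidth)
  anchors <- tibble::tibble(chrom = chrom, start = pos, end = pos + 1L)
  hits <- overlap_join(anchors, prom)
  if (nrow(hits) > 0) {
    cand <- tibble::tibble(
      peak = hits$query,
      gene_id = prom$gene_id[hits$subject],
      dist = abs(pos[hits$query] - prom$tss[hits$subject])
    )
    # nearest TSS wins; ties broken by lexicographically smaller gene id
    best <- cand |>
      dplyr::arrange(.data$peak, .data$dist, .data$gene_id) |>
      dplyr::distinct(.data$peak, .keep_all = TRUE)
    feature[best$peak] <- "promoter"
    gene_id[best$peak] <- best$gene_id
  }
  # gene bodies for anchors not in any promoter window
  open_idx <- which(feature == "intergenic" & !unknown)
  if (length(open_idx) > 0) {
    sub_anchors <- tibble::tibble(chrom = chrom[open_idx],
                                  start = pos[open_idx],
                                  end = pos[open_idx] + 1L)
    bodies <- tibble::tibble(chrom = genes$chrom, start = genes$start,
                             end = genes$end)
    hits2 <- overlap_join(sub_anchors, bodies)
    if (nrow(hits2) > 0) {
      cand2 <- tibble::tibble(
        peak = open_idx[hits2$query],
        gene_id = genes$gene_id[hits2$subject],
        dist = abs(pos[open_idx[hits2$query]] - genes$tss[hits2$subject])
      )
      best2 <- cand2 |>
        dplyr::arrange(.data$peak, .data$dist, .data$gene_id) |>
        dplyr::distinct(.data$peak, .keep_all = TRUE)
      feature[best2$peak] <- "gene_body"
      gene_id[best2$peak] <- best2$gene_id
    }
  }
  tibble::tibble(feature = feature, gene_id = gene_id)
}

#' Annotate peaks with genomic features and compartments
#'
#' Each peak's anchor point (summit when present, else midpoint) is tested
#' against promoter windows first, then gene bodies; anchors matching
#' neither are intergenic. The compartment column marks anchors inside the
#' heterochromatin map.
#'
#' @param peaks Peak tibble.
#' @param genes Gene-model tibble.
#' @param het_map Heterochromatin map tibble (`chrom`, `start`, `end`),
#'   e.g. [dm6_heterochromatin()]; `NULL` labels everything euchromatin.
#' @param halfwidth Promoter half-width in bases (default 200).
#' @param anchor `"summit"` (summit when available, midpoint otherwise) or
#'   `"midpoint"`.
#' @return The peak tibble with added columns `anchor_pos`, `feature`
#'   (`promoter`/`gene_body`/`intergenic`), `gene_id`, `compartment`
#'   (`euchromatin`/`heterochromatin`).
#' @export
annotate_peaks <- function(peaks, genes, het_map = NULL, halfwidth = 200L,
                           anchor = c("summit", "midpoint")) {
  anchor <- match.arg(anchor)
  peaks <- validate_peaks(peaks)
  pos <- peak_anchor(peaks, anchor)
  res <- resolve_features(peaks$chrom, pos, genes, halfwidth)
  het <- if (is.null(het_map)) rep(FALSE, nrow(peaks)) else {
    point_in_intervals(peaks$chrom, pos, het_map)
  }
  peaks |>
    dplyr::mutate(anchor_pos = pos,
                  feature = res$feature,
                  gene_id = res$gene_id,
                  compartment = ifelse(het, "heterochromatin", "euchromatin"))
}

# TRUE where point (chrom, pos) lies in some interval of `map`
# (0-based half-open; interval starts are inclusive).
point_in_intervals <- function(chrom, pos, map) {
  out <- rep(FALSE, length(pos))
  for (ch in unique(map$chrom)) {
    rows <- map[map$chrom == ch, ]
    sel <- which(chrom == ch)
    if (length(sel) == 0) next
    for (j in seq_len(nrow(rows))) {
      out[sel] <- out[sel] | (pos[sel] >= rows$start[j] & pos[sel] < rows$end[j])
    }
  }
  out
}

#' Is each peak anchored in heterochromatin?
#'
#' @inheritParams annotate_peaks
#' @return Logical vector, one entry per peak: `TRUE` when the anchor point
#'   lies inside a heterochromatin block (block starts inclusive).
#' @export
is_heterochromatic <- function(peaks, het_map, anchor = c("summit", "midpoint")) {
  anchor <- match.arg(anchor)
  peaks <- validate_peaks(peaks)
  point_in_intervals(peaks$chrom, peak_anchor(peaks, anchor), het_map)
}

#' Genes whose promoters contain at least one peak anchor
#'
#' Maps a peak set to the set of genes with a peak anchor inside their
#' promoter window. A gene appears once however many peaks hit it; anchors
#' inside two overlapping promoter windows go to the gene with the nearest
#' TSS (ties to the lexicographically smaller gene id).
#'
#' @inheritParams annotate_peaks
#' @param housekeeping_only Restrict the result to housekeeping genes.
#' @return A tibble with a single sorted `gene_id` column.
#' @export
peaks_to_promoter_genes <- function(peaks, genes, halfwidth = 200L,
                                    anchor = c("summit", "midpoint"),
                                    housekeeping_only = FALSE) {
  anchor <- match.arg(anchor)
  ann <- annotate_peaks(peaks, genes, het_map = NULL, halfwidth = halfwidth,
                        anchor = anchor)
  ids <- unique(ann$gene_id[ann$feature == "promoter"])
  if (housekeeping_only) {
    hk <- genes$gene_id[genes$housekeeping]
    ids <- intersect(ids, hk)
  }
  tibble::tibble(gene_id = sort(ids))
}

#' Cross-tabulate peaks by feature, compartment and motif status
#'
#' Produces the counts behind binding-site distribution summaries: peaks
#' split by genomic feature, euchromatin versus heterochromatin, and
#' whether the peak carries a motif.
#'
#' @param peaks Peak tibble.
#' @param genes Gene-model tibble.
#' @param het_map Heterochromatin map tibble.
#' @param motif_flags Logical vector aligned to `peaks` rows (e.g. from
#'   [flag_motif_peaks()]); `NULL` records all peaks as `FALSE`.
#' @inheritParams annotate_peaks
#' @return A tibble with one row per occupied
#'   feature x compartment x motif cell: columns `feature`, `compartment`,
#'   `has_motif`, `n`, `pct` (percentage of all peaks). Empty input yields
#'   an empty table.
#' @export
summarize_peak_distribution <- function(peaks, genes, het_map = NULL,
                                        motif_flags = NULL, halfwidth = 200L,
                                        anchor = c("summit", "midpoint")) {
  anchor <- match.arg(anchor)
  peaks <- validate_peaks(peaks)
  if (is.null(motif_flags)) motif_flags <- rep(FALSE, nrow(peaks))
  if (length(motif_flags) != nrow(peaks)) {
    pc_abort("`motif_flags` must align with `peaks` (one flag per peak)",
             "pc_validation_error")
  }
  if (nrow(peaks) == 0) {
    return(tibble::tibble(feature = character(), compartment = character(),
                          has_motif = logical(), n = integer(), pct = double()))
  }
  ann <- annotate_peaks(peaks, genes, het_map, halfwidth, anchor)
  ann$has_motif <- motif_flags
  ann |>
    dplyr::group_by(.data$feature, .data$compartment, .data$has_motif) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::arrange(.data$feature, .data$compartment, .data$has_motif)
}
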