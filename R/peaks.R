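# Genomic-interval data model: peak tibbles, overlap computation, multi-set
# union with per-set membership, and BED/narrowPeak I/O.
#
# All coordinates are 0-based half-open ([start, end)), the BED convention.
# A "peak set" is a tibble with columns chrom, start, end, name, strand,
# summit and a `label` attribute-free column added when sets are stacked.

#' Read a peak set from BED or ENCODE narrowPeak
#'
#' Parses BED3/BED6 or 10-column narrowPeak files into a peak tibble with
#' 0-based half-open coordinates. For narrowPeak input, column 10 (the
#' point-source offset relative to `start`) is converted to an absolute
#' `summit` coordinate; the sentinel value -1 yields a missing summit.
#'
#' @param path Path to the peak file.
#' @param format Either `"bed"` (>= 3 tab-separated columns) or
#'   `"narrowPeak"` (exactly 10 columns).
#' @param label Optional set label stored in a `label` column (defaults to
#'   the file name without extension).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `summit`, `label`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t100\tp1\t5\t+", bed)
#' read_peaks(bed, format = "bed")
#' @export
read_peaks <- function(path, format = c("bed", "narrowPeak"), label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    pc_abort(sprintf("peak file not found: %s", path), "pc_io_error")
  }
  label <- label %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = double(), strand = character(),
                          summit = integer(), label = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  min_fields <- if (format == "bed") 3L else 10L
  bad <- which(if (format == "bed") nf < 3L else nf != 10L)
  if (length(bad) > 0) {
    pc_abort(sprintf("malformed %s line %d: expected %s fields, found %d",
                     format, bad[1],
                     if (format == "bed") ">= 3" else "exactly 10", nf[bad[1]]),
             "pc_parse_error")
  }
  get_col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- get_col(1)
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  bad_num <- which(is.na(start) | is.na(end))
  if (length(bad_num) > 0) {
    pc_abort(sprintf("malformed %s line %d: non-numeric coordinates",
                     format, bad_num[1]), "pc_parse_error")
  }
  bad_coord <- which(start >= end)
  if (length(bad_coord) > 0) {
    pc_abort(sprintf("invalid interval at line %d: start (%d) >= end (%d)",
                     bad_coord[1], start[bad_coord[1]], end[bad_coord[1]]),
             "pc_validation_error")
  }
  name <- get_col(4)
  name[is.na(name) | name == "."] <- NA_character_
  if (anyNA(name)) {
    auto <- sprintf("%s_%d", label, seq_along(chrom))
    name[is.na(name)] <- auto[is.na(name)]
  }
  score <- suppressWarnings(as.double(get_col(5)))
  strand <- get_col(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  summit <- rep(NA_integer_, length(chrom))
  if (format == "narrowPeak") {
    offset <- suppressWarnings(as.integer(get_col(10)))
    has_summit <- !is.na(offset) & offset >= 0L
    summit[has_summit] <- start[has_summit] + offset[has_summit]
  }
  peaks <- tibble::tibble(chrom = chrom, start = start, end = end,
                          name = name, score = score, strand = strand,
                          summit = summit, label = label)
  if (anyDuplicated(peaks$name)) {
    pc_abort("peak names must be unique within a set", "pc_validation_error")
  }
  dplyr::arrange(peaks, .data$chrom, .data$start)
}

#' Write a peak set as BED6 or narrowPeak
#'
#' @param peaks A peak tibble (columns `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand`, `summit`).
#' @param path Output path.
#' @param format `"bed"` (6 columns) or `"narrowPeak"` (10 columns; the
#'   summit is written as an offset in column 10, -1 when absent).
#' @return The path, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  peaks <- validate_peaks(peaks)
  score <- if ("score" %in% names(peaks)) ifelse(is.na(peaks$score), 0, peaks$score) else 0
  base <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                     score, peaks$strand)
  if (format == "narrowPeak") {
    offset <- ifelse(is.na(peaks$summit), -1L, peaks$summit - peaks$start)
    base <- cbind(base, -1, -1, -1, offset)
  }
  utils::write.table(base, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Find overlapping peak pairs between two sets
#'
#' Reports every pair of peaks (one from each set) on the same chromosome
#' sharing at least `min_overlap` bases. Adjacent half-open intervals share
#' no base and are not reported.
#'
#' @param a,b Peak tibbles.
#' @param min_overlap Minimum number of shared bases (>= 1).
#' @return A tibble with columns `name_a`, `name_b`, `chrom`, `overlap`
#'   (shared base count), ordered by row of `a` then row of `b`.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100, name = "a1")
#' b <- tibble::tibble(chrom = "chr1", start = 99, end = 200, name = "b1")
#' find_overlaps(a, b)
#' @export
find_overlaps <- function(a, b, min_overlap = 1L) {
  if (!is.numeric(min_overlap) || length(min_overlap) != 1 || min_overlap < 1) {
    pc_abort("`min_overlap` must be a single integer >= 1", "pc_validation_error")
  }
  min_overlap <- as.integer(min_overlap)
  a <- validate_peaks(a, "a")
  b <- validate_peaks(b, "b")
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble::tibble(name_a = character(), name_b = character(),
                          chrom = character(), overlap = integer()))
  }
  hits <- overlap_join(a, b, min_overlap)
  hits <- hits[order(hits$query, hits$subject), ]
  tibble::tibble(name_a = a$name[hits$query], name_b = b$name[hits$subject],
                 chrom = a$chrom[hits$query],
                 overlap = as.integer(hits$overlap))
}

#' Merge several peak sets into a union region set with membership
#'
#' Regions are the connected components of the overlap graph over all peaks
#' from all sets: two peaks are linked when they share at least
#' `min_overlap` bases, and linkage is transitive, so peaks that never
#' directly overlap can end up in one region through a chain. Each region
#' spans the union of its member peaks and records which input sets
#' contributed to it.
#'
#' @param sets Either a named list of peak tibbles (names become set
#'   labels) or a single tibble with a `label` column.
#' @param min_overlap Minimum shared bases linking two peaks (>= 1).
#' @return A tibble of class `merged_regions` with columns `chrom`, `start`,
#'   `end`, `region`, `n_peaks`, plus list-columns `labels` (contributing
#'   set labels, sorted) and `peaks` (contributing peak names).
#' @examples
#' sets <- list(
#'   A = tibble::tibble(chrom = "chr1", start = 0, end = 100, name = "a1"),
#'   B = tibble::tibble(chrom = "chr1", start = 50, end = 150, name = "b1")
#' )
#' merge_union(sets)
#' @export
merge_union <- function(sets, min_overlap = 1L) {
  if (!is.numeric(min_overlap) || length(min_overlap) != 1 || min_overlap < 1) {
    pc_abort("`min_overlap` must be a single integer >= 1", "pc_validation_error")
  }
  all_peaks <- stack_peak_sets(sets)
  if (nrow(all_peaks) == 0) {
    pc_abort("`sets` must contain at least one peak", "pc_validation_error")
  }
  hits <- overlap_join(all_peaks, all_peaks, as.integer(min_overlap))
  comp <- union_find_components(nrow(all_peaks), hits$query, hits$subject)
  idx <- split(seq_len(nrow(all_peaks)), comp)
  regions <- tibble::tibble(
    chrom = unname(vapply(idx, function(i) all_peaks$chrom[i[1]], "")),
    start = unname(vapply(idx, function(i) min(all_peaks$start[i]), integer(1))),
    end = unname(vapply(idx, function(i) max(all_peaks$end[i]), integer(1))),
    n_peaks = unname(lengths(idx)),
    labels = unname(lapply(idx, function(i) sort(unique(all_peaks$label[i])))),
    peaks = unname(lapply(idx, function(i) all_peaks$name[i]))
  )
  ord <- order(regions$chrom, regions$start)
  regions <- regions[ord, ]
  regions$region <- sprintf("region_%d", seq_len(nrow(regions)))
  regions <- regions[, c("chrom", "start", "end", "region", "n_peaks",
                         "labels", "peaks")]
  class(regions) <- c("merged_regions", class(regions))
  regions
}

# Stack a list of peak sets (or pass through a labelled tibble), ensuring
# globally unique peak names by prefixing the set label on collision.
stack_peak_sets <- function(sets) {
  if (is.data.frame(sets)) {
    if (!"label" %in% names(sets)) {
      pc_abort("a single peak tibble must carry a `label` column", "pc_validation_error")
    }
    out <- validate_label_groups(sets)
    return(out)
  }
  if (!is.list(sets) || length(sets) == 0) {
    pc_abort("`sets` must be a non-empty list of peak tibbles", "pc_validation_error")
  }
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- sprintf("set%d", seq_along(sets))
    names(sets) <- labels
  }
  stacked <- purrr::imap(sets, function(p, lab) {
    p <- validate_peaks(p, lab)
    p$label <- lab
    p
  })
  out <- dplyr::bind_rows(stacked)
  if (anyDuplicated(out$name)) {
    out$name <- paste(out$label, out$name, sep = ":")
  }
  out
}

validate_label_groups <- function(peaks) {
  split_sets <- split(peaks, peaks$label)
  stacked <- purrr::imap(split_sets, function(p, lab) validate_peaks(p, lab))
  out <- dplyr::bind_rows(stacked)
  if (anyDuplicated(out$name)) {
    out$name <- paste(out$label, out$name, sep = ":")
  }
  out
}

# Iterative union-find over an edge list; returns a component id per node.
union_find_components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) {
      nxt <- parent[x]
      parent[x] <<- root
      x <- nxt
    }
    root
  }
  for (i in seq_along(from)) {
    ra <- find(from[i]); rb <- find(to[i])
    if (ra != rb) parent[rb] <- ra
  }
  vapply(seq_len(n), find, integer(1))
}

#' Count merged regions by label combination
#'
#' Tallies the membership subsets of a merged region set, the counts shown
#' in UpSet-style colocalization summaries. By default each merged region
#' counts once; `count = "peaks"` instead counts the original contributing
#' peaks per combination.
#'
#' @param merged A `merged_regions` tibble from [merge_union()].
#' @param count `"regions"` (default) or `"peaks"`.
#' @return A tibble with columns `combination` (labels joined by `+`),
#'   `n_labels` and `n`, sorted by decreasing `n`.
#' @export
combination_counts <- function(merged, count = c("regions", "peaks")) {
  count <- match.arg(count)
  if (!all(c("labels", "n_peaks") %in% names(merged))) {
    pc_abort("`merged` must come from merge_union()", "pc_type_error")
  }
  combo <- vapply(merged$labels, function(l) paste(l, collapse = "+"), "")
  weight <- if (count == "regions") rep(1L, nrow(merged)) else merged$n_peaks
  tibble::tibble(combination = combo, weight = weight,
                 n_labels = lengths(merged$labels)) |>
    dplyr::group_by(.data$combination, .data$n_labels) |>
    dplyr::summarise(n = sum(.data$weight), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$combination) |>
    dplyr::select("combination", "n_labels", "n")
}
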