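# Internal validators and small helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Stop with a classed condition so tests can assert on error class.
pc_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "peakcoloc_error"))
}

# Validate a peak tibble: chrom/start/end (0-based half-open), optional
# name/strand/summit columns are filled with defaults.
validate_peaks <- function(peaks, arg = "peaks") {
  if (!is.data.frame(peaks)) {
    pc_abort(sprintf("`%s` must be a data frame of peaks", arg), "pc_type_error")
  }
  required <- c("chrom", "start", "end")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols) > 0) {
    pc_abort(sprintf("`%s` lacks required column(s): %s", arg,
                     paste(missing_cols, collapse = ", ")), "pc_type_error")
  }
  peaks <- tibble::as_tibble(peaks)
  if (!"name" %in% names(peaks)) {
    peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  }
  if (!"strand" %in% names(peaks)) peaks$strand <- "."
  if (!"summit" %in% names(peaks)) peaks$summit <- NA_integer_
  bad <- which(!(peaks$start >= 0 & peaks$start < peaks$end))
  if (length(bad) > 0) {
    pc_abort(sprintf("invalid interval (need 0 <= start < end) at row %d", bad[1]),
             "pc_validation_error")
  }
  s <- peaks$summit
  bad_summit <- which(!is.na(s) & !(s >= peaks$start & s < peaks$end))
  if (length(bad_summit) > 0) {
    pc_abort(sprintf("summit outside its interval at row %d", bad_summit[1]),
             "pc_validation_error")
  }
  if (anyDuplicated(peaks$name)) {
    pc_abort("peak names must be unique within a set", "pc_validation_error")
  }
  peaks
}

# Anchor point of each peak: summit when present and requested, else midpoint.
peak_anchor <- function(peaks, anchor = c("summit", "midpoint")) {
  anchor <- match.arg(anchor)
  mid <- peaks$start + (peaks$end - peaks$start) %/% 2L
  if (anchor == "midpoint") return(mid)
  ifelse(is.na(peaks$summit), mid, peaks$summit)
}

# All-pairs overlap join between two interval tibbles (0-based half-open).
# Returns a tibble of row indices into `a` and `b` plus shared base counts.
overlap_join <- function(a, b, min_overlap = 1L) {
  chroms <- sort(unique(c(a$chrom, b$chrom)))
  code_a <- match(a$chrom, chroms)
  code_b <- match(b$chrom, chroms)
  oa <- order(code_a, a$start)
  ob <- order(code_b, b$start)
  res <- interval_overlap_pairs(
    code_a[oa], as.integer(a$start[oa]), as.integer(a$end[oa]), as.integer(oa),
    code_b[ob], as.integer(b$start[ob]), as.integer(b$end[ob]), as.integer(ob),
    as.integer(min_overlap))
  tibble::tibble(query = res$query, subject = res$subject,
                 overlap = res$overlap)
}

# Deterministic 31-bit integer hash of a character key, mixed with a master
# seed. Used to give each protein pair its own reproducible RNG substream
# that does not depend on how many other pairs are analysed.
substream_seed <- function(master_seed, key) {
  h <- 0
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((h + as.double(master_seed) %% 2147483647) %% 2147483647)
}

# Header lines stamped onto every TSV the pipeline writes.
output_header <- function(seed, cfg_hash) {
  c(sprintf("# peakcoloc %s", as.character(utils::packageVersion("peakcoloc"))),
    sprintf("# seed: %s", format(seed)),
    sprintf("# config: %s", cfg_hash))
}

write_tsv_with_header <- function(x, path, header = NULL) {
  if (!is.null(header)) {
    writeLines(header, path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(path)
}
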