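# Position weight matrices, exact background score distributions for
# p-value -> score-threshold conversion, and two-strand sequence scanning.
#
# Scores are log2 odds against the background. The threshold for a target
# p-value is found by dynamic programming over a discretized score lattice:
# per-position scores are rounded once to a fixed grid step, and the exact
# distribution of the lattice word score under the background model is
# built by convolution. The scanner makes its pass/fail decision with the
# same lattice scores, so the threshold, the scanner and exhaustive word
# enumeration agree exactly -- including for words whose raw scores tie,
# which a refine-until-stable scheme can never resolve consistently.

DNA_ALPHABET <- c("A", "C", "G", "T")
NEG_SENTINEL <- -1000  # stands in for log2(0) when pseudocount = 0

new_pwm <- function(probs, background) {
  colnames(probs) <- DNA_ALPHABET
  log_odds <- log2(sweep(probs, 2, background, "/"))
  log_odds[!is.finite(log_odds)] <- NEG_SENTINEL
  structure(
    list(length = nrow(probs), probs = probs, background = background,
         log_odds = log_odds),
    class = "pwm"
  )
}

#' Build a position weight matrix from a count matrix
#'
#' Converts per-position nucleotide counts to probabilities with an
#' additive pseudocount, `probs[i, a] = (counts[i, a] + pseudocount) /
#' (rowsum + 4 * pseudocount)`, and derives log2-odds scores against the
#' background. Zero probabilities (possible only with `pseudocount = 0`)
#' get a large negative sentinel score instead of `-Inf`.
#'
#' @param counts Integer matrix, one row per motif position, columns in
#'   A, C, G, T order.
#' @param pseudocount Additive pseudocount (default 1).
#' @param background Background nucleotide frequencies (default uniform).
#' @return A `pwm` object: list with `length`, `probs`, `background`,
#'   `log_odds`.
#' @examples
#' pwm_from_counts(matrix(c(8, 0, 0, 0), nrow = 1))
#' @export
pwm_from_counts <- function(counts, pseudocount = 1,
                            background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4) {
    pc_abort("`counts` must have 4 columns (A, C, G, T)", "pc_validation_error")
  }
  if (any(counts < 0)) {
    pc_abort("`counts` must be non-negative", "pc_validation_error")
  }
  if (pseudocount < 0) {
    pc_abort("`pseudocount` must be >= 0", "pc_validation_error")
  }
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-6 ||
      any(background <= 0)) {
    pc_abort("`background` must be 4 positive frequencies summing to 1",
             "pc_validation_error")
  }
  rs <- rowSums(counts)
  if (pseudocount == 0 && any(rs == 0)) {
    pc_abort("all-zero count row needs a positive pseudocount",
             "pc_validation_error")
  }
  probs <- (counts + pseudocount) / (rs + 4 * pseudocount)
  new_pwm(probs, background)
}

#' Read a PWM from a count TSV or MEME minimal motif file
#'
#' The TSV format is one row per motif position with four columns in
#' A, C, G, T order (a header naming the bases is tolerated); values are
#' treated as counts. The MEME minimal format supplies probabilities
#' directly via its letter-probability matrix; only the first motif in the
#' file is read.
#'
#' @param path Input file path.
#' @param format `"tsv"` or `"meme"`.
#' @inheritParams pwm_from_counts
#' @return A `pwm` object.
#' @export
read_pwm <- function(path, format = c("tsv", "meme"), pseudocount = 1,
                     background = rep(0.25, 4)) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    pc_abort(sprintf("PWM file not found: %s", path), "pc_io_error")
  }
  if (format == "tsv") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (grepl("[ACGTacgt]", strsplit(lines[1], "\t")[[1]][1])) {
      lines <- lines[-1]
    }
    counts <- do.call(rbind, lapply(lines, function(l) {
      as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
    }))
    return(pwm_from_counts(counts, pseudocount, background))
  }
  lines <- readLines(path)
  start <- grep("^letter-probability matrix", lines)
  if (length(start) == 0) {
    pc_abort("no letter-probability matrix found in MEME file", "pc_parse_error")
  }
  rows <- list()
  for (i in seq(start[1] + 1, length(lines))) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(vals) != 4 || anyNA(vals)) break
    rows[[length(rows) + 1]] <- vals
  }
  probs <- do.call(rbind, rows)
  new_pwm(probs, background)
}

# Distribution of the rounded word score under the background model.
# Returns list(pmf, min_int): pmf[i] = P(S_int = min_int + i - 1).
score_int_distribution <- function(int_scores, background) {
  pmf <- 1
  total_min <- 0L
  for (i in seq_len(nrow(int_scores))) {
    row <- int_scores[i, ]
    mi <- min(row)
    span <- max(row) - mi
    new <- numeric(length(pmf) + span)
    for (a in 1:4) {
      off <- row[a] - mi
      idx <- seq_along(pmf) + off
      new[idx] <- new[idx] + background[a] * pmf
    }
    pmf <- new
    total_min <- total_min + mi
  }
  list(pmf = pmf, min_int = total_min)
}

threshold_at_step <- function(pwm, p, step) {
  int_scores <- round(pwm$log_odds / step)
  # Collapse scores more than 16 log2-odds units below their column max
  # (sentinel letters from zero probabilities): a word containing one sits
  # far below any threshold of practical interest, and without the clip the
  # DP lattice would be millions of cells wide.
  clip <- round(16 / step)
  for (i in seq_len(nrow(int_scores))) {
    int_scores[i, ] <- pmax(int_scores[i, ], max(int_scores[i, ]) - clip)
  }
  dist <- score_int_distribution(int_scores, pwm$background)
  tail <- rev(cumsum(rev(dist$pmf)))
  pass <- which(tail <= p)
  if (length(pass) == 0) {
    int_threshold <- dist$min_int + length(dist$pmf)  # above max: nothing passes
    p_achieved <- 0
  } else {
    int_threshold <- dist$min_int + pass[1] - 1L
    p_achieved <- tail[pass[1]]
  }
  list(int_threshold = int_threshold, p_achieved = p_achieved, step = step,
       int_scores = int_scores)
}

#' Score threshold for a target motif p-value
#'
#' Finds the minimal score t such that the probability of a random
#' background word scoring at or above t is at most `p`. Per-position
#' scores are rounded once to a lattice of `step` log2-odds units and the
#' exact distribution of the lattice word score is built by dynamic
#' programming. The returned threshold carries the lattice, and
#' [scan_sequence()] decides pass/fail on the same lattice, so the
#' threshold, the scanner and exhaustive enumeration of all words agree
#' exactly; the only approximation is the initial rounding, bounded by
#' `length * step / 2` score units (3.75e-3 for a 15-mer at the default
#' step, far below typical gaps between distinct word scores).
#'
#' @param pwm A `pwm` object.
#' @param p Target p-value, 0 < p <= 1 (default 1e-4).
#' @param step Score lattice step in log2-odds units (default 1e-4).
#' @return A `pwm_threshold` object: list with `score` (threshold in
#'   log2-odds units), `p` (requested), `p_achieved` (exact tail
#'   probability at the threshold on the lattice), `step` and
#'   `int_threshold` (the integer-lattice cut used by the scanner).
#' @export
score_threshold <- function(pwm, p = 1e-4, step = 1e-4) {
  if (!inherits(pwm, "pwm")) pc_abort("`pwm` must be a pwm object", "pc_type_error")
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1) {
    pc_abort("`p` must satisfy 0 < p <= 1", "pc_validation_error")
  }
  if (!is.numeric(step) || step <= 0) {
    pc_abort("`step` must be a positive score increment", "pc_validation_error")
  }
  cur <- threshold_at_step(pwm, p, step)
  structure(
    list(score = cur$int_threshold * cur$step, p = p,
         p_achieved = cur$p_achieved, step = cur$step,
         int_threshold = cur$int_threshold),
    class = "pwm_threshold"
  )
}

# Chromosome sequences as a named character vector (as.character() on a
# character vector would drop names).
genome_as_character <- function(genome) {
  seqs <- if (is.character(genome)) genome else as.character(genome)
  if (is.null(names(seqs))) {
    pc_abort("`genome` sequences must be named by chromosome", "pc_validation_error")
  }
  seqs
}

# Encode a DNA string as integer codes 1..4 (N and anything else -> NA).
encode_dna <- function(seq) {
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  match(chars, DNA_ALPHABET)
}

# Reverse-complement a per-position score matrix: reverse positions and
# swap A<->T, C<->G columns.
revcomp_matrix <- function(m) {
  m[rev(seq_len(nrow(m))), c(4, 3, 2, 1), drop = FALSE]
}

# Rounded and raw window scores for every window of length L; NA where the
# window contains an ambiguous base.
window_scores <- function(codes, score_matrix) {
  L <- nrow(score_matrix)
  n_win <- length(codes) - L + 1L
  if (n_win < 1) return(numeric(0))
  sc <- numeric(n_win)
  for (i in seq_len(L)) {
    sc <- sc + score_matrix[i, ][codes[i:(i + n_win - 1L)]]
  }
  unname(sc)
}

#' Scan a sequence for PWM hits on both strands
#'
#' Scores every window of the motif length on the forward strand and (by
#' default) the reverse complement; windows containing `N` are skipped.
#' Minus-strand hits are reported at the plus-strand coordinate of the
#' window start. When `threshold` is a [score_threshold()] object the
#' pass/fail decision uses the same discretized scores as the threshold
#' computation; a bare number is compared against raw log2-odds scores.
#'
#' @param seq A DNA string (character or `Biostrings::DNAString`).
#' @param pwm A `pwm` object.
#' @param threshold A `pwm_threshold` object or a numeric score cutoff.
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return A tibble of hits: `pos` (0-based window start on the plus
#'   strand), `strand`, `score` (raw log2-odds).
#' @export
scan_sequence <- function(seq, pwm, threshold, both_strands = TRUE) {
  if (!inherits(pwm, "pwm")) pc_abort("`pwm` must be a pwm object", "pc_type_error")
  codes <- encode_dna(seq)
  L <- pwm$length
  empty <- tibble::tibble(pos = integer(), strand = character(), score = double())
  if (length(codes) < L) return(empty)

  use_int <- inherits(threshold, "pwm_threshold")
  raw_fwd <- window_scores(codes, pwm$log_odds)
  if (use_int) {
    int_m <- round(pwm$log_odds / threshold$step)
    dec_fwd <- window_scores(codes, int_m) >= threshold$int_threshold
  } else {
    dec_fwd <- raw_fwd >= threshold
  }
  hits <- list()
  keep <- which(!is.na(dec_fwd) & dec_fwd)
  if (length(keep) > 0) {
    hits[[1]] <- tibble::tibble(pos = keep - 1L, strand = "+",
                                score = raw_fwd[keep])
  }
  if (both_strands) {
    rc_lo <- revcomp_matrix(pwm$log_odds)
    raw_rev <- window_scores(codes, rc_lo)
    if (use_int) {
      dec_rev <- window_scores(codes, revcomp_matrix(round(pwm$log_odds / threshold$step))) >=
        threshold$int_threshold
    } else {
      dec_rev <- raw_rev >= threshold
    }
    keep_r <- which(!is.na(dec_rev) & dec_rev)
    if (length(keep_r) > 0) {
      hits[[length(hits) + 1]] <- tibble::tibble(pos = keep_r - 1L, strand = "-",
                                                 score = raw_rev[keep_r])
    }
  }
  if (length(hits) == 0) return(empty)
  dplyr::arrange(dplyr::bind_rows(hits), .data$pos, .data$strand)
}

#' Scan a whole genome for PWM hits
#'
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @inheritParams scan_sequence
#' @return A BED-style tibble: `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based half-open; `end = start + motif length`).
#' @export
scan_genome <- function(genome, pwm, threshold, both_strands = TRUE) {
  seqs <- genome_as_character(genome)
  out <- purrr::imap(seqs, function(s, ch) {
    h <- scan_sequence(s, pwm, threshold, both_strands)
    if (nrow(h) == 0) return(NULL)
    tibble::tibble(chrom = ch, start = h$pos, end = h$pos + pwm$length,
                   score = h$score, strand = h$strand)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = double(), strand = character()))
  }
  out |>
    dplyr::mutate(name = sprintf("hit_%d", dplyr::row_number())) |>
    dplyr::select("chrom", "start", "end", "name", "score", "strand")
}

#' Flag peaks containing a motif site
#'
#' A peak is flagged when at least one of the supplied PWMs has at least
#' one hit within the peak span at that PWM's own p-value threshold (a
#' logical OR across PWMs, matching the practice of accepting a site if
#' any of several discovered motifs matches).
#'
#' @param peaks Peak tibble.
#' @param genome Named character vector or `Biostrings::DNAStringSet`.
#' @param pwms A single `pwm` or a list of `pwm` objects.
#' @param p Motif p-value threshold applied per PWM (default 1e-4).
#' @param both_strands Scan both strands (default `TRUE`).
#' @return Logical vector aligned to `peaks` rows.
#' @export
flag_motif_peaks <- function(peaks, genome, pwms, p = 1e-4, both_strands = TRUE) {
  peaks <- validate_peaks(peaks)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  seqs <- genome_as_character(genome)
  missing_chrom <- setdiff(unique(peaks$chrom), names(seqs))
  if (length(missing_chrom) > 0) {
    first <- peaks$name[peaks$chrom %in% missing_chrom][1]
    pc_abort(sprintf("chromosome %s (peak %s) absent from the genome",
                     peaks$chrom[peaks$chrom %in% missing_chrom][1], first),
             "pc_validation_error")
  }
  thresholds <- lapply(pwms, score_threshold, p = p)
  flags <- rep(FALSE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    subseq <- substr(seqs[[peaks$chrom[i]]], peaks$start[i] + 1L, peaks$end[i])
    for (j in seq_along(pwms)) {
      if (nrow(scan_sequence(subseq, pwms[[j]], thresholds[[j]], both_strands)) > 0) {
        flags[i] <- TRUE
        break
      }
    }
  }
  flags
}
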