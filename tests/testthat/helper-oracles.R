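# Independent brute-force oracles and small fixture generators used across
# the suite. These deliberately use different algorithms from the package
# (all-vs-all scans, label propagation, word enumeration) so agreement is
# meaningful.

random_peak_set <- function(n, chrom_len = 10000L, n_chroms = 1L,
                            max_width = 400L, prefix = "p") {
  chrom <- sprintf("chr%d", sample.int(n_chroms, n, replace = TRUE))
  start <- sample.int(chrom_len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width - 1L, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = start, end = start + width,
                 name = sprintf("%s%d", prefix, seq_len(n)))
}

# All-vs-all overlap scan (the O(n^2) oracle for find_overlaps).
brute_overlaps <- function(a, b, min_overlap = 1L) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_overlap) {
        out[[length(out) + 1]] <- tibble::tibble(
          name_a = a$name[i], name_b = b$name[j], chrom = a$chrom[i],
          overlap = as.integer(ov))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(name_a = character(), name_b = character(),
                          chrom = character(), overlap = integer()))
  }
  dplyr::bind_rows(out)
}

# Connected components over pairwise overlaps by iterative label
# propagation (independent of the package's union-find).
brute_components <- function(peaks, min_overlap = 1L) {
  n <- nrow(peaks)
  lab <- seq_len(n)
  edge <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || peaks$chrom[i] != peaks$chrom[j]) next
      ov <- min(peaks$end[i], peaks$end[j]) - max(peaks$start[i], peaks$start[j])
      if (ov >= min_overlap) edge[i, j] <- TRUE
    }
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(edge[i, ])
      if (length(nb) > 0) {
        m <- min(lab[i], lab[nb])
        if (m < lab[i]) { lab[i] <- m; changed <- TRUE }
        if (any(lab[nb] > m)) { lab[nb] <- m; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  lab
}

# Exhaustive word enumeration oracle for PWM thresholds: scores all 4^L
# words on the same lattice the package uses (per-position log2-odds
# rounded to `step`), computes each word's exact background probability
# and tail p-value by sorting, and marks the words whose tail is <= p.
# Integer lattice sums make tie handling exact.
enumerate_words <- function(pwm, p, step = 1e-4) {
  L <- pwm$length
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  int_m <- round(pwm$log_odds / step)
  score <- numeric(nrow(grid))
  prob <- rep(1, nrow(grid))
  for (i in seq_len(L)) {
    score <- unname(score + int_m[i, grid[, i]])
    prob <- unname(prob * pwm$background[grid[, i]])
  }
  ord <- order(score, decreasing = TRUE)
  # exact tail: P(S >= s_word), grouping equal lattice scores together
  cum <- cumsum(prob[ord])
  s_sorted <- score[ord]
  grp <- cumsum(c(TRUE, diff(s_sorted) < 0))
  grp_last <- tapply(seq_along(s_sorted), grp, max)
  tail_at <- numeric(nrow(grid))
  tail_at[ord] <- cum[grp_last[grp]]
  list(score = score * step, prob = prob, tail = tail_at, pass = tail_at <= p)
}

# Passing-word set according to the package's threshold (same rounded
# scores the scanner uses).
dp_pass_words <- function(pwm, threshold) {
  L <- pwm$length
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  int_m <- round(pwm$log_odds / threshold$step)
  s_int <- numeric(nrow(grid))
  for (i in seq_len(L)) s_int <- s_int + int_m[i, grid[, i]]
  unname(s_int >= threshold$int_threshold)
}

# Sharp test PWM: one strongly preferred base per position.
sharp_pwm <- function(L = 15L, seed = 42L, weight = 50L) {
  withr::with_seed(seed, {
    counts <- matrix(1L, L, 4)
    counts[cbind(seq_len(L), sample.int(4, L, replace = TRUE))] <- weight
  })
  pwm_from_counts(counts, pseudocount = 1)
}

consensus_word <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$probs, 1, which.max)], collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
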