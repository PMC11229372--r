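test_that("PWM probabilities and log-odds follow the pseudocount formula", {
  pwm <- pwm_from_counts(matrix(c(8, 0, 0, 0), nrow = 1), pseudocount = 1)
  expect_equal(unname(pwm$probs[1, "A"]), 0.75)
  expect_equal(unname(pwm$log_odds[1, "A"]), log2(0.75 / 0.25))
  # uniform counts against a uniform background score zero everywhere
  flat <- pwm_from_counts(matrix(2, nrow = 3, ncol = 4))
  expect_equal(unname(flat$log_odds), matrix(0, 3, 4))
  # zero probability with pseudocount 0 becomes a large negative sentinel
  hard <- pwm_from_counts(matrix(c(4, 0, 0, 0), nrow = 1), pseudocount = 0)
  expect_equal(unname(hard$probs[1, "A"]), 1)
  expect_true(all(hard$log_odds[1, c("C", "G", "T")] <= -999))
  expect_error(pwm_from_counts(matrix(0, 1, 4), pseudocount = 0),
               class = "pc_validation_error")
})

test_that("threshold at p = 0.25 on one position passes exactly the best letter", {
  pwm <- pwm_from_counts(matrix(c(10, 5, 3, 1), nrow = 1), pseudocount = 1)
  th <- score_threshold(pwm, p = 0.25)
  expect_equal(th$p_achieved, 0.25)
  # exactly one of the four letters scores at or above the threshold
  lo <- sort(unname(pwm$log_odds[1, ]), decreasing = TRUE)
  expect_lte(th$score, lo[1] + th$step)
  expect_gt(th$score, lo[2])
  expect_equal(sum(dp_pass_words(pwm, th)), 1)
  # p = 1 admits every word
  th_all <- score_threshold(pwm, p = 1)
  expect_equal(th_all$p_achieved, 1)
  expect_equal(th_all$score, min(pwm$log_odds), tolerance = 1e-3)
  expect_error(score_threshold(pwm, p = 0), class = "pc_validation_error")
})

test_that("DP thresholds reproduce exhaustive enumeration for random PWMs", {
  withr::with_seed(404, {
    for (rep in 1:8) {
      L <- sample(3:6, 1)
      counts <- matrix(stats::rpois(L * 4, 4) + 1L, ncol = 4)
      pwm <- pwm_from_counts(counts, pseudocount = 0.5)
      p <- sample(c(0.05, 0.01, 0.002), 1)
      th <- score_threshold(pwm, p)
      oracle <- enumerate_words(pwm, p)
      expect_equal(dp_pass_words(pwm, th), oracle$pass)
      # threshold tightness: passing mass <= p, one grid step looser exceeds p
      expect_lte(sum(oracle$prob[oracle$pass]), p)
      looser <- th; looser$int_threshold <- th$int_threshold - 1L
      expect_gt(sum(oracle$prob[dp_pass_words(pwm, looser)]), p)
    }
  })
})

test_that("implanted consensus words are found on the correct strand and position", {
  pwm <- sharp_pwm(L = 10, seed = 7, weight = 60)
  th <- score_threshold(pwm, 1e-4)
  word <- consensus_word(pwm)
  withr::with_seed(8, bg <- random_dna(60))
  seq_fwd <- paste0(substr(bg, 1, 5), word, substr(bg, 16, 60))
  hits <- scan_sequence(seq_fwd, pwm, th)
  expect_true(any(hits$pos == 5 & hits$strand == "+"))

  seq_rev <- paste0(substr(bg, 1, 5), revcomp_chr(word), substr(bg, 16, 60))
  hits_rev <- scan_sequence(seq_rev, pwm, th)
  expect_true(any(hits_rev$pos == 5 & hits_rev$strand == "-"))

  # windows containing N are skipped; short sequences give empty results
  seq_n <- paste0(substr(seq_fwd, 1, 7), "N", substr(seq_fwd, 9, 60))
  expect_false(any(scan_sequence(seq_n, pwm, th)$pos == 5))
  expect_equal(nrow(scan_sequence("ACGT", pwm, th)), 0)
})

test_that("scanning matches a naive per-window rescoring oracle", {
  withr::with_seed(505, {
    for (rep in 1:5) {
      L <- sample(4:6, 1)
      pwm <- pwm_from_counts(matrix(stats::rpois(L * 4, 4) + 1L, ncol = 4))
      seqc <- random_dna(500)
      # nudge the cutoff off any achievable word score so float summation
      # order cannot flip borderline windows between the two scanners
      t_raw <- unname(stats::quantile(replicate(50, {
        sum(pwm$log_odds[cbind(seq_len(L), sample.int(4, L, TRUE))])
      }), 0.9)) - 1e-7
      got <- scan_sequence(seqc, pwm, t_raw)
      # naive oracle: loop every window on both strands, rescore directly
      want <- list()
      for (pos in seq_len(nchar(seqc) - L + 1)) {
        win <- substr(seqc, pos, pos + L - 1)
        codes <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T"))
        sc_f <- sum(pwm$log_odds[cbind(seq_len(L), codes)])
        codes_r <- match(strsplit(revcomp_chr(win), "")[[1]], c("A", "C", "G", "T"))
        sc_r <- sum(pwm$log_odds[cbind(seq_len(L), codes_r)])
        if (sc_f >= t_raw) want[[length(want) + 1]] <- c(pos - 1, 1, sc_f)
        if (sc_r >= t_raw) want[[length(want) + 1]] <- c(pos - 1, 2, sc_r)
      }
      want <- do.call(rbind, want)
      expect_equal(nrow(got), NROW(want))
      if (NROW(want) > 0) {
        ord <- order(want[, 1], want[, 2])
        expect_equal(got$pos, as.integer(want[ord, 1]))
        expect_equal(got$strand, c("+", "-")[want[ord, 2]])
        expect_equal(got$score, want[ord, 3], tolerance = 1e-12)
      }
    }
  })
})

test_that("hit sets mirror under reverse complementation", {
  pwm <- sharp_pwm(L = 8, seed = 21, weight = 30)
  th <- score_threshold(pwm, 1e-3)
  withr::with_seed(22, seqc <- random_dna(2000))
  fwd <- scan_sequence(seqc, pwm, th)
  rev <- scan_sequence(revcomp_chr(seqc), pwm, th)
  # a + hit at pos on the forward sequence is a - hit at n - L - pos on the RC
  n <- nchar(seqc); L <- pwm$length
  mirrored <- sort((n - L) - rev$pos)
  expect_equal(sort(fwd$pos), mirrored)
})

test_that("peak motif flags equal implant ground truth and OR across PWMs", {
  pwm <- sharp_pwm(L = 12, seed = 31, weight = 80)
  cfg <- synth_config(seed = 13, n_genes = 120, n_chroms = 1,
                      chrom_length = 250000L, motif = pwm, implant_prob = 0.5)
  st <- simulate_study(cfg)
  flags <- flag_motif_peaks(st$peaks, st$genome, pwm, p = 1e-4)
  implanted <- st$peaks$name %in% st$implants$name
  # every implant whose sampled word itself passes the threshold must be found
  th <- score_threshold(pwm, 1e-4)
  word_passes <- vapply(st$implants$word, function(w) {
    nrow(scan_sequence(w, pwm, th)) > 0
  }, TRUE)
  must_find <- st$peaks$name %in% st$implants$name[word_passes]
  expect_true(all(flags[must_find]))
  # at p = 1e-4 over ~100 bp spans the expected number of chance hits across
  # all background-only peaks is well under one in twenty peaks
  expect_lte(sum(flags[!implanted]), 5)

  # a second PWM that matches nothing does not change the OR
  other <- sharp_pwm(L = 12, seed = 99, weight = 80)
  flags_or <- flag_motif_peaks(st$peaks, st$genome, list(pwm, other), p = 1e-4)
  expect_true(all(flags_or >= flags))

  bad <- dplyr::mutate(st$peaks[1, ], chrom = "chrZ")
  expect_error(flag_motif_peaks(bad, st$genome, pwm), "chrZ",
               class = "pc_validation_error")
})

test_that("PWM files round-trip through the TSV and MEME readers", {
  counts <- matrix(c(8, 1, 1, 0,
                     0, 9, 1, 0,
                     2, 2, 3, 3), ncol = 4, byrow = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tC\tG\tT",
               apply(counts, 1, paste, collapse = "\t")), f)
  pwm <- read_pwm(f, "tsv")
  expect_equal(pwm$probs, pwm_from_counts(counts)$probs)

  m <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF test", "letter-probability matrix: alength= 4 w= 2",
               " 0.7 0.1 0.1 0.1", " 0.1 0.1 0.1 0.7"), m)
  pm <- read_pwm(m, "meme")
  expect_equal(pm$length, 2)
  expect_equal(unname(pm$probs[1, "A"]), 0.7)
})
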