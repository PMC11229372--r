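# Exhaustive-enumeration oracle: P(|A ∩ B| > k) over all pairs of subsets
# of sizes n1, n2 from a universe of size u.
enum_tail <- function(u, n1, n2, k) {
  sets1 <- utils::combn(u, n1, simplify = FALSE)
  sets2 <- utils::combn(u, n2, simplify = FALSE)
  total <- 0L; exceed <- 0L
  for (a in sets1) for (b in sets2) {
    total <- total + 1L
    if (length(intersect(a, b)) > k) exceed <- exceed + 1L
  }
  exceed / total
}

test_that("observed statistic implements the shared-promoter fraction", {
  obs <- observed_stat(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(obs$k, 2L)
  expect_equal(obs$fo, 0.5)
  expect_equal(observed_stat(letters[1:4], letters[1:4])$fo, 1)
  expect_equal(observed_stat(letters[1:3], letters[10:12])$fo, 0)
  # the alternative denominator counts shared ids twice
  expect_equal(observed_stat(c("a", "b", "c"), c("b", "c", "d"),
                             denominator = "sum")$fo, 2 / 6)
  expect_error(observed_stat(character(), character()),
               class = "pc_validation_error")
})

test_that("hypergeometric tail equals exhaustive set-pair enumeration", {
  expect_equal(hypergeom_tail(10, 3, 3, 2), 1 / 120)
  expect_equal(hypergeom_tail(4, 2, 2, 0), 5 / 6)
  expect_equal(hypergeom_tail(10, 3, 4, 3), 0)
  grid <- expand.grid(u = 6:7, n1 = 2:3, n2 = 2:3, k = 0:2)
  for (i in seq_len(nrow(grid))) {
    with(grid[i, ], expect_equal(hypergeom_tail(u, n1, n2, k),
                                 enum_tail(u, n1, n2, k)))
  }
  expect_error(hypergeom_tail(10, 11, 3, 1), class = "pc_validation_error")
})

test_that("null sampling is reproducible with forced and degenerate cases", {
  expect_equal(withr::with_seed(1, sample_null(10, 10, 10, 20)), rep(1, 20))
  expect_equal(withr::with_seed(1, sample_null(10, 0, 5, 20)), rep(0, 20))
  a <- withr::with_seed(9, sample_null(200, 40, 30, 500))
  b <- withr::with_seed(9, sample_null(200, 40, 30, 500))
  expect_identical(a, b)
  # intersection sizes have the hypergeometric mean n1 n2 / u
  ks <- withr::with_seed(2, sample_null(10, 3, 3, 40000, stat = "count"))
  expect_equal(mean(ks), 0.9, tolerance = 0.05)
  expect_error(sample_null(10, 11, 3), class = "pc_validation_error")
})

test_that("empirical p-values follow the strict-exceedance definition", {
  fs <- c(0.0, 0.1, 0.2, 0.3)
  expect_equal(empirical_p(0.2, fs), 0.25)
  expect_equal(empirical_p(0.2, fs, tie_rule = "greater_equal"), 0.5)
  expect_equal(empirical_p(0.9, fs), 0)
  expect_equal(empirical_p(0.9, fs, smoothing = "add_one"), 1 / 5)
  expect_error(empirical_p(0.5, numeric(0)), class = "pc_validation_error")
})

test_that("empirical p-values converge to the hypergeometric tail", {
  set.seed(31)
  fs <- sample_null(10, 3, 3, 50000)
  fo <- observed_stat(c("a", "b", "c"), c("b", "c", "d"))$fo  # k = 2 of 3
  p_hat <- empirical_p(fo, fs)
  p_exact <- hypergeom_tail(10, 3, 3, 2)
  expect_lt(abs(p_hat - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 50000))
})

test_that("BH adjustment matches the hand-computed step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)), c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), class = "pc_validation_error")
  # independent step-up oracle on random vectors
  withr::with_seed(606, {
    for (rep in 1:10) {
      p <- runif(sample(3:12, 1))
      m <- length(p)
      ord <- order(p)
      q <- p[ord] * m / seq_len(m)
      q <- rev(cummin(rev(q)))
      q <- pmin(q, 1)
      want <- numeric(m); want[ord] <- q
      expect_equal(bh_adjust(p), want)
    }
  })
})

test_that("p-values from the fraction and from the raw count are identical", {
  withr::with_seed(707, {
    for (rep in 1:25) {
      u <- sample(50:300, 1)
      n1 <- sample.int(u %/% 2, 1); n2 <- sample.int(u %/% 2, 1)
      k <- sample(0:min(n1, n2), 1)
      fo <- k / (n1 + n2 - k)
      s <- sample.int(1e6, 1)
      fs <- withr::with_seed(s, sample_null(u, n1, n2, 1000))
      ks <- withr::with_seed(s, sample_null(u, n1, n2, 1000, stat = "count"))
      expect_identical(empirical_p(fo, fs), empirical_p(k, ks))
    }
  })
})

test_that("the greater-or-equal tie rule keeps the null rejection rate conservative", {
  # on a discrete intersection count, p = P(Fs >= Fo) guarantees
  # P(reject at alpha) <= alpha up to Monte Carlo noise
  base <- synth_config(seed = 555, n_genes = 1000, n_chroms = 2,
                       chrom_length = 2000000L, housekeeping_fraction = 1)
  gm <- simulate_gene_models(base)
  universe <- gm$genes$gene_id[gm$genes$housekeeping]
  p_ge <- vapply(1:300, function(rep) {
    cfg <- synth_config(seed = 555 + rep, n_genes = 1000, n_chroms = 2,
                        chrom_length = 2000000L, housekeeping_fraction = 1)
    bs <- simulate_bound_sets(cfg, gm$genes)
    coloc_test(bs$bound_sets, universe, n_samples = 2000, seed = rep,
               tie_rule = "greater_equal")$p_emp
  }, numeric(1))
  rate <- mean(p_ge <= 0.05)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
  expect_gt(rate, 0)
})

test_that("coloc_test produces a BH-corrected table deterministically", {
  sets <- list(A = letters[1:10], B = letters[5:14], C = letters[15:24])
  u <- letters
  ct <- coloc_test(sets, u, n_samples = 500, seed = 42)
  expect_s3_class(ct, "coloc_test")
  expect_equal(nrow(ct), 3)
  expect_equal(ct$p_adj, bh_adjust(ct$p_emp))
  expect_true(all(ct$p_adj >= ct$p_emp))
  ct2 <- coloc_test(sets, u, n_samples = 500, seed = 42)
  expect_identical(tidy(ct), tidy(ct2))
  # identical sets in a larger universe: full overlap, minimal p
  ident <- coloc_test(list(X = letters[1:5], Y = letters[1:5]), letters,
                      n_samples = 500, seed = 1)
  expect_equal(ident$fo, 1)
  expect_equal(ident$p_emp, 0)
  expect_error(coloc_test(list(A = letters[1:3]), letters),
               class = "pc_validation_error")
  expect_error(coloc_test(list(A = "zz", B = letters[1:3]), letters),
               class = "pc_validation_error")
})

test_that("per-pair substreams are unchanged when a protein is added", {
  sets2 <- list(A = letters[1:10], B = letters[5:14])
  sets3 <- c(sets2, list(C = letters[15:24]))
  ct2 <- coloc_test(sets2, letters, n_samples = 1000, seed = 7)
  ct3 <- coloc_test(sets3, letters, n_samples = 1000, seed = 7)
  ab2 <- ct2[ct2$protein1 == "A" & ct2$protein2 == "B", ]
  ab3 <- ct3[ct3$protein1 == "A" & ct3$protein2 == "B", ]
  expect_identical(ab2$p_emp, ab3$p_emp)
})

test_that("tidy, glance and autoplot expose the result", {
  sets <- list(A = letters[1:10], B = letters[5:14], C = letters[15:24])
  ct <- coloc_test(sets, letters, n_samples = 200, seed = 2)
  td <- tidy(ct)
  expect_false(inherits(td, "coloc_test"))
  expect_named(td, c("protein1", "protein2", "n1", "n2", "k", "fo",
                     "p_emp", "p_adj"))
  gl <- glance(ct)
  expect_equal(gl$n_pairs, 3)
  expect_equal(gl$universe_size, 26)
  expect_s3_class(autoplot(ct), "ggplot")
})
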