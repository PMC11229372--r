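test_that("the generator is fully deterministic given its seed", {
  cfg <- synth_config(seed = 5, n_genes = 200, n_chroms = 2,
                      chrom_length = 400000L,
                      motif = sharp_pwm(L = 8, seed = 3), implant_prob = 0.5)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$genes, b$genes)
  expect_identical(a$bound_sets, b$bound_sets)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$genome, b$genome)
  expect_identical(a$implants, b$implants)
})

test_that("gene models respect counts, spacing and the housekeeping fraction", {
  cfg <- synth_config(seed = 2, n_genes = 100, n_chroms = 2,
                      chrom_length = 200000L, housekeeping_fraction = 0.5)
  gm <- simulate_gene_models(cfg)
  expect_equal(nrow(gm$genes), 100)
  expect_equal(sum(gm$genes$housekeeping), 50)
  expect_true(all(gm$genes$start <= gm$genes$tss &
                    gm$genes$tss < gm$genes$end))
  # spans never overlap within a chromosome
  by_chrom <- split(gm$genes, gm$genes$chrom)
  for (g in by_chrom) {
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  expect_error(simulate_gene_models(
    synth_config(n_genes = 10000, chrom_length = 100000L, n_chroms = 1)),
    class = "pc_config_error")
})

test_that("TSS compartment labels agree with is_heterochromatic", {
  cfg <- synth_config(seed = 4, n_genes = 150, n_chroms = 2,
                      chrom_length = 300000L, het_fraction = 0.3)
  gm <- simulate_gene_models(cfg)
  tss_peaks <- tibble::tibble(chrom = gm$genes$chrom, start = gm$genes$tss,
                              end = gm$genes$tss + 1L,
                              name = gm$genes$gene_id)
  het <- is_heterochromatic(tss_peaks, gm$het_map, anchor = "midpoint")
  expect_equal(het, gm$genes$tss < 0.3 * cfg$chrom_length)
})

test_that("the bivariate Bernoulli joint solves the odds-ratio equation", {
  # independence
  expect_equal(peakcoloc:::bernoulli_joint_p11(0.5, 0.5, 1), 0.25)
  # theta = 9 with symmetric marginals: p11^2 = 9 (0.5 - p11)^2
  expect_equal(peakcoloc:::bernoulli_joint_p11(0.5, 0.5, 9), 0.375)
  # the implied odds ratio round-trips for random parameter draws
  withr::with_seed(808, {
    for (rep in 1:20) {
      p1 <- runif(1, 0.05, 0.9); p2 <- runif(1, 0.05, 0.9)
      th <- exp(runif(1, log(0.2), log(20)))
      p11 <- peakcoloc:::bernoulli_joint_p11(p1, p2, th)
      p10 <- p1 - p11; p01 <- p2 - p11; p00 <- 1 - p1 - p2 + p11
      expect_gte(p11, max(0, p1 + p2 - 1) - 1e-12)
      expect_lte(p11, min(p1, p2) + 1e-12)
      expect_equal((p11 * p00) / (p10 * p01), th, tolerance = 1e-9)
    }
  })
})

test_that("marginal binding rates and the odds ratio are attained at scale", {
  cfg <- synth_config(seed = 10, n_genes = 6000, n_chroms = 2,
                      chrom_length = 6000000L, housekeeping_fraction = 1,
                      proteins = tibble::tibble(name = c("P1", "P2"),
                                                p = c(0.2, 0.3)),
                      theta = 4)
  gm <- simulate_gene_models(cfg)
  bs <- simulate_bound_sets(cfg, gm$genes)
  m <- bs$truth$bound_matrix
  n <- nrow(m)
  for (j in 1:2) {
    p_hat <- mean(m[, j])
    p_true <- cfg$proteins$p[j]
    ci <- 2.58 * sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(p_hat - p_true), ci)
  }
  tab <- table(factor(m[, 1], 0:1), factor(m[, 2], 0:1))
  or_hat <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_gt(or_hat, 2.5)
  expect_lt(or_hat, 6.5)
})

test_that("theta = 1 leaves binding independent at scale", {
  cfg <- synth_config(seed = 12, n_genes = 10000, n_chroms = 2,
                      chrom_length = 10000000L, housekeeping_fraction = 1)
  gm <- simulate_gene_models(cfg)
  m <- simulate_bound_sets(cfg, gm$genes)$truth$bound_matrix
  tab <- table(factor(m[, 1], 0:1), factor(m[, 2], 0:1))
  log_or <- log((tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2]))
  se <- sqrt(sum(1 / tab))
  expect_lt(abs(log_or), 2.58 * se)
})

test_that("bound sets round-trip through peaks and annotation", {
  cfg <- synth_config(seed = 3, n_genes = 300, n_chroms = 2,
                      chrom_length = 600000L)
  st <- simulate_study(cfg)
  expect_equal(nrow(st$peaks), nrow(st$bound_sets))
  for (prot in unique(st$bound_sets$protein)) {
    got <- peaks_to_promoter_genes(dplyr::filter(st$peaks, label == prot),
                                   st$genes, housekeeping_only = TRUE)
    expect_equal(got$gene_id,
                 sort(unique(st$bound_sets$gene_id[st$bound_sets$protein == prot])))
  }
  # empty bound set yields an empty peak set
  empty <- bound_sets_to_peaks(st$bound_sets[0, ], st$genes, cfg)
  expect_equal(nrow(empty), 0)
  # two proteins bound at one gene become one merged region with both labels
  shared <- dplyr::filter(st$bound_sets, gene_id %in%
                            st$bound_sets$gene_id[duplicated(st$bound_sets$gene_id)])
  if (nrow(shared) >= 2) {
    g1 <- shared$gene_id[1]
    both <- bound_sets_to_peaks(dplyr::filter(st$bound_sets, gene_id == g1),
                                st$genes, cfg)
    m <- merge_union(both)
    expect_equal(nrow(m), 1)
    expect_equal(m$labels[[1]], sort(unique(both$label)))
  }
  # excessive jitter warns that recovery is no longer guaranteed
  jcfg <- synth_config(seed = 3, n_genes = 50, n_chroms = 1,
                       chrom_length = 100000L, summit_jitter = 500L)
  gm <- simulate_gene_models(jcfg)
  bs <- simulate_bound_sets(jcfg, gm$genes)
  expect_warning(bound_sets_to_peaks(bs$bound_sets, gm$genes, jcfg),
                 "recovery")
})

test_that("motif implanting records exact ground truth", {
  pwm <- sharp_pwm(L = 9, seed = 17, weight = 70)
  cfg_all <- synth_config(seed = 6, n_genes = 80, n_chroms = 1,
                          chrom_length = 160000L, motif = pwm,
                          implant_prob = 1)
  st <- simulate_study(cfg_all)
  expect_equal(sort(st$implants$name), sort(st$peaks$name))
  # each implanted word is literally present at the recorded position/strand
  for (i in seq_len(nrow(st$implants))) {
    imp <- st$implants[i, ]
    written <- substr(st$genome[[imp$chrom]], imp$pos + 1, imp$pos + pwm$length)
    expected <- if (imp$strand == "+") imp$word else revcomp_chr(imp$word)
    expect_equal(written, expected)
  }
  cfg_none <- synth_config(seed = 6, n_genes = 80, n_chroms = 1,
                           chrom_length = 160000L, motif = pwm,
                           implant_prob = 0)
  expect_equal(nrow(simulate_study(cfg_none)$implants), 0)
})

test_that("configuration validation names the violated constraint", {
  expect_error(synth_config(theta = 0), class = "pc_validation_error")
  expect_error(synth_config(housekeeping_fraction = 0), class = "pc_validation_error")
  expect_error(synth_config(peak_width = 0), class = "pc_validation_error")
  cfg <- synth_config(proteins = tibble::tibble(name = c("A", "B", "C"),
                                                p = c(0.2, 0.2, 0.2)),
                      theta = c(B = 2))
  gm <- simulate_gene_models(cfg)
  expect_error(simulate_bound_sets(cfg, gm$genes), "theta",
               class = "pc_validation_error")
})
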