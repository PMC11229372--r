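# Synthetic-data generator: gene models on synthetic chromosomes,
# correlated protein-binding indicators over housekeeping promoters
# (bivariate Bernoulli with a controlled odds ratio), promoter-centred
# peaks, and motif-implanted genome sequences -- all with recorded ground
# truth so annotation recovery, test calibration and power are checkable.

#' Configuration for the synthetic-data generator
#'
#' Bundles every simulation parameter. Binding indicators are drawn per
#' housekeeping gene: the first protein is the reference and every other
#' protein's indicator is drawn from the bivariate Bernoulli with the
#' configured marginals and pairwise odds ratio against the reference
#' (theta = 1 gives independence). All downstream draws are reproducible
#' from `seed`.
#'
#' @param seed Master seed.
#' @param n_chroms Number of synthetic chromosomes.
#' @param chrom_length Length of each chromosome in bases.
#' @param n_genes Total number of genes (split evenly across chromosomes).
#' @param housekeeping_fraction Fraction of genes flagged housekeeping
#'   (exact count, deterministic rounding).
#' @param het_fraction Fraction of each chromosome, from the origin,
#'   marked heterochromatic (a pericentromeric-like block); ignored when
#'   `het_blocks` is supplied.
#' @param het_blocks Optional explicit heterochromatin map tibble
#'   (`chrom`, `start`, `end`).
#' @param proteins Tibble with columns `name` and `p` (marginal binding
#'   probability per housekeeping promoter).
#' @param theta Pairwise odds ratio(s) of each non-reference protein with
#'   the reference: a single value recycled, or a named vector keyed by
#'   protein name. Must be > 0.
#' @param peak_width Width of simulated peaks in bases.
#' @param summit_jitter Maximum absolute offset of the peak summit from
#'   the TSS (uniform on `-summit_jitter .. summit_jitter`).
#' @param motif Optional `pwm` object used by [implant_motifs()].
#' @param implant_prob Probability that a peak receives a motif implant.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 1000000L,
                         n_genes = 1000L, housekeeping_fraction = 0.5,
                         het_fraction = 0.2, het_blocks = NULL,
                         proteins = tibble::tibble(name = c("P1", "P2"),
                                                   p = c(0.1, 0.1)),
                         theta = 1, peak_width = 100L, summit_jitter = 0L,
                         motif = NULL, implant_prob = 0) {
  if (housekeeping_fraction <= 0 || housekeeping_fraction > 1) {
    pc_abort("`housekeeping_fraction` must be in (0, 1]", "pc_validation_error")
  }
  if (any(proteins$p < 0 | proteins$p > 1)) {
    pc_abort("protein marginal probabilities must lie in [0, 1]",
             "pc_validation_error")
  }
  if (any(theta <= 0)) pc_abort("`theta` must be > 0", "pc_validation_error")
  if (peak_width <= 0) pc_abort("`peak_width` must be > 0", "pc_validation_error")
  if (implant_prob < 0 || implant_prob > 1) {
    pc_abort("`implant_prob` must be in [0, 1]", "pc_validation_error")
  }
  structure(
    list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
         chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
         housekeeping_fraction = housekeeping_fraction,
         het_fraction = het_fraction, het_blocks = het_blocks,
         proteins = tibble::as_tibble(proteins), theta = theta,
         peak_width = as.integer(peak_width),
         summit_jitter = as.integer(summit_jitter),
         motif = motif, implant_prob = implant_prob),
    class = "synth_config"
  )
}

#' Simulate gene models and a heterochromatin map
#'
#' Genes are laid out in equal non-overlapping slots along each
#' chromosome (so TSSs are close to uniformly spread), with random strand;
#' the TSS sits at the strand-appropriate end of the span. Exactly
#' `round(housekeeping_fraction * n_genes)` genes are flagged
#' housekeeping. The heterochromatin map is the configured block at the
#' start of each chromosome (or the explicit `het_blocks`).
#'
#' @param cfg A [synth_config()].
#' @return A list with `genes` (gene-model tibble) and `het_map`.
#' @export
simulate_gene_models <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  slot <- cfg$chrom_length %/% per_chrom
  if (slot < 600) {
    pc_abort("chromosomes too short to fit the requested genes without overlap",
             "pc_config_error")
  }
  withr::with_seed(cfg$seed + 1L, {
    rows <- purrr::map(seq_len(cfg$n_chroms), function(ci) {
      n_here <- min(per_chrom, cfg$n_genes - (ci - 1L) * per_chrom)
      if (n_here <= 0) return(NULL)
      idx <- seq_len(n_here)
      slot_start <- (idx - 1L) * slot
      span_start <- slot_start + slot %/% 4L
      span_end <- slot_start + (3L * slot) %/% 4L
      strand <- sample(c("+", "-"), n_here, replace = TRUE)
      tibble::tibble(
        gene_id = sprintf("g%04d_chr%d", idx, ci),
        chrom = sprintf("chr%d", ci),
        strand = strand,
        start = as.integer(span_start),
        end = as.integer(span_end),
        tss = as.integer(ifelse(strand == "+", span_start, span_end - 1L))
      )
    })
    genes <- dplyr::bind_rows(rows)
    n_hk <- round(cfg$housekeeping_fraction * nrow(genes))
    hk_idx <- sample(nrow(genes), n_hk)
    genes$housekeeping <- seq_len(nrow(genes)) %in% hk_idx
  })
  het_map <- cfg$het_blocks
  if (is.null(het_map)) {
    het_map <- tibble::tibble(
      chrom = sprintf("chr%d", seq_len(cfg$n_chroms)),
      start = 0L,
      end = as.integer(round(cfg$het_fraction * cfg$chrom_length))
    )
    het_map <- het_map[het_map$end > het_map$start, ]
  }
  list(genes = dplyr::arrange(genes, .data$chrom, .data$tss), het_map = het_map)
}

# Joint success probability p11 of a bivariate Bernoulli with marginals
# p1, p2 and odds ratio theta (Plackett construction).
bernoulli_joint_p11 <- function(p1, p2, theta) {
  if (theta == 1) return(p1 * p2)
  s <- 1 + (p1 + p2) * (theta - 1)
  disc <- s^2 - 4 * theta * (theta - 1) * p1 * p2
  p11 <- (s - sqrt(disc)) / (2 * (theta - 1))
  lower <- max(0, p1 + p2 - 1)
  upper <- min(p1, p2)
  if (p11 < lower - 1e-12 || p11 > upper + 1e-12) {
    pc_abort(sprintf(
      "infeasible (p1 = %g, p2 = %g, theta = %g): joint probability %g violates the Frechet bounds [%g, %g]",
      p1, p2, theta, p11, lower, upper), "pc_validation_error")
  }
  min(max(p11, lower), upper)
}

#' Simulate correlated bound-promoter sets
#'
#' Draws one binding indicator per protein per housekeeping gene. The
#' first configured protein is the reference: its indicators are i.i.d.
#' Bernoulli at its marginal, and every other protein is drawn
#' conditionally on the reference so that the pair attains the configured
#' odds ratio while keeping its own marginal. Non-reference proteins are
#' conditionally independent given the reference.
#'
#' @param cfg A [synth_config()].
#' @param genes Gene-model tibble from [simulate_gene_models()].
#' @return A list with `bound_sets` (tibble `protein`, `gene_id`) and
#'   `truth` (list: `bound_matrix` of 0/1 indicators, `p11` per
#'   non-reference protein, `universe` of housekeeping gene ids).
#' @export
simulate_bound_sets <- function(cfg, genes) {
  stopifnot(inherits(cfg, "synth_config"))
  hk <- genes$gene_id[genes$housekeeping]
  n <- length(hk)
  if (n == 0) pc_abort("no housekeeping genes to bind", "pc_config_error")
  prot <- cfg$proteins
  theta <- cfg$theta
  if (nrow(prot) > 1) {
    others <- prot$name[-1]
    if (is.null(names(theta))) {
      theta <- setNames(rep_len(theta, length(others)), others)
    } else if (!all(others %in% names(theta))) {
      pc_abort("named `theta` must cover every non-reference protein",
               "pc_validation_error")
    }
  }
  withr::with_seed(cfg$seed + 2L, {
    m <- matrix(0L, nrow = n, ncol = nrow(prot),
                dimnames = list(hk, prot$name))
    p_ref <- prot$p[1]
    ref <- rbinom(n, 1L, p_ref)
    m[, 1] <- ref
    if (nrow(prot) > 1) {
      for (j in 2:nrow(prot)) {
        pj <- prot$p[j]
        th <- theta[[prot$name[j]]]
        p11 <- bernoulli_joint_p11(p_ref, pj, th)
        cond1 <- if (p_ref > 0) p11 / p_ref else 0
        cond0 <- if (p_ref < 1) (pj - p11) / (1 - p_ref) else 0
        pr <- ifelse(ref == 1L, cond1, cond0)
        m[, j] <- rbinom(n, 1L, pr)
      }
    }
  })
  bound <- purrr::map(colnames(m), function(p) {
    tibble::tibble(protein = p, gene_id = rownames(m)[m[, p] == 1L])
  }) |> dplyr::bind_rows()
  p11 <- if (nrow(prot) > 1) {
    vapply(2:nrow(prot), function(j)
      bernoulli_joint_p11(prot$p[1], prot$p[j], theta[[prot$name[j]]]),
      numeric(1))
  } else numeric(0)
  list(bound_sets = bound,
       truth = list(bound_matrix = m,
                    p11 = setNames(p11, if (nrow(prot) > 1) prot$name[-1] else character()),
                    universe = hk))
}

#' Turn bound-promoter sets into peak sets
#'
#' Creates one peak per bound gene, centred on the TSS: the summit is the
#' TSS plus a uniform jitter in `-summit_jitter .. summit_jitter` and the
#' peak spans `peak_width` bases around it. With the summit anchor,
#' annotation recovers the bound sets exactly whenever
#' `summit_jitter <= promoter halfwidth`; a larger jitter triggers a
#' warning because recovery is no longer guaranteed.
#'
#' @param bound_sets Tibble (`protein`, `gene_id`) from
#'   [simulate_bound_sets()].
#' @param genes Gene-model tibble.
#' @param cfg A [synth_config()].
#' @param halfwidth Promoter half-width the peaks are meant to be
#'   recovered with (default 200; used only for the jitter warning).
#' @return A peak tibble with a `label` column holding the protein name.
#' @export
bound_sets_to_peaks <- function(bound_sets, genes, cfg, halfwidth = 200L) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$summit_jitter > halfwidth) {
    rlang::warn("summit_jitter exceeds the promoter halfwidth: annotation recovery is not guaranteed")
  }
  if (nrow(bound_sets) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          strand = character(), summit = integer(),
                          label = character()))
  }
  gene_lookup <- genes[match(bound_sets$gene_id, genes$gene_id), ]
  withr::with_seed(cfg$seed + 3L, {
    jitter <- if (cfg$summit_jitter > 0) {
      sample(seq(-cfg$summit_jitter, cfg$summit_jitter),
             nrow(bound_sets), replace = TRUE)
    } else rep(0L, nrow(bound_sets))
  })
  summit <- pmax(gene_lookup$tss + jitter, 0L)
  half <- cfg$peak_width %/% 2L
  start <- pmax(summit - half, 0L)
  tibble::tibble(
    chrom = gene_lookup$chrom,
    start = as.integer(start),
    end = as.integer(start + cfg$peak_width),
    name = paste(bound_sets$protein, bound_sets$gene_id, sep = "_"),
    strand = ".",
    summit = as.integer(summit),
    label = bound_sets$protein
  )
}

# Sample a word (one letter per row) from a PWM's probability matrix.
sample_pwm_word <- function(pwm) {
  paste(vapply(seq_len(pwm$length), function(i) {
    sample(DNA_ALPHABET, 1, prob = pwm$probs[i, ])
  }, ""), collapse = "")
}

revcomp_string <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Generate genome sequences with motif implants inside peaks
#'
#' Background sequence is drawn i.i.d. from the PWM's background
#' frequencies for every configured chromosome. Each peak then receives,
#' with probability `implant_prob`, a single word sampled from the PWM's
#' probability matrix, placed uniformly within the peak span on a
#' uniformly chosen strand; the implant position, strand and word are
#' recorded as ground truth. Peaks shorter than the motif are skipped
#' with a warning.
#'
#' @param cfg A [synth_config()] with a non-`NULL` `motif`.
#' @param peaks Peak tibble (e.g. from [bound_sets_to_peaks()]).
#' @return A list with `genome` (named character vector of chromosome
#'   sequences) and `implants` (tibble `name`, `chrom`, `pos`, `strand`,
#'   `word`; `pos` is the 0-based implant window start).
#' @export
implant_motifs <- function(cfg, peaks) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(cfg$motif)) pc_abort("`cfg$motif` must be a pwm object", "pc_config_error")
  pwm <- cfg$motif
  L <- pwm$length
  peaks <- validate_peaks(peaks)
  withr::with_seed(cfg$seed + 4L, {
    genome <- setNames(vapply(seq_len(cfg$n_chroms), function(ci) {
      paste(sample(DNA_ALPHABET, cfg$chrom_length, replace = TRUE,
                   prob = pwm$background), collapse = "")
    }, ""), sprintf("chr%d", seq_len(cfg$n_chroms)))
    too_short <- peaks$end - peaks$start < L
    if (any(too_short)) {
      rlang::warn(sprintf("%d peak(s) shorter than the motif were skipped",
                          sum(too_short)))
    }
    eligible <- which(!too_short)
    chosen <- eligible[runif(length(eligible)) < cfg$implant_prob]
    implants <- purrr::map(chosen, function(i) {
      pos <- peaks$start[i] +
        sample.int(peaks$end[i] - peaks$start[i] - L + 1L, 1L) - 1L
      strand <- sample(c("+", "-"), 1)
      word <- sample_pwm_word(pwm)
      inserted <- if (strand == "+") word else revcomp_string(word)
      ch <- peaks$chrom[i]
      genome[[ch]] <<- paste0(substr(genome[[ch]], 1, pos),
                              inserted,
                              substr(genome[[ch]], pos + L + 1L,
                                     nchar(genome[[ch]])))
      tibble::tibble(name = peaks$name[i], chrom = ch, pos = as.integer(pos),
                     strand = strand, word = word)
    }) |> dplyr::bind_rows()
  })
  if (nrow(implants) == 0) {
    implants <- tibble::tibble(name = character(), chrom = character(),
                               pos = integer(), strand = character(),
                               word = character())
  }
  list(genome = genome, implants = implants)
}

#' Run the full synthetic-study generator
#'
#' Convenience wrapper chaining [simulate_gene_models()],
#' [simulate_bound_sets()], [bound_sets_to_peaks()] and, when a motif is
#' configured, [implant_motifs()].
#'
#' @param cfg A [synth_config()].
#' @return A list: `genes`, `het_map`, `bound_sets`, `truth`, `peaks`,
#'   and (with a motif) `genome`, `implants`.
#' @export
simulate_study <- function(cfg) {
  gm <- simulate_gene_models(cfg)
  bs <- simulate_bound_sets(cfg, gm$genes)
  peaks <- bound_sets_to_peaks(bs$bound_sets, gm$genes, cfg)
  out <- list(genes = gm$genes, het_map = gm$het_map,
              bound_sets = bs$bound_sets, truth = bs$truth, peaks = peaks)
  if (!is.null(cfg$motif)) {
    imp <- implant_motifs(cfg, peaks)
    out$genome <- imp$genome
    out$implants <- imp$implants
  }
  out
}
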