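# Monte Carlo colocalization test over a housekeeping-promoter universe.
#
# For two proteins with N1 and N2 bound promoters inside a universe U, the
# observed statistic is the fraction of shared promoter ids,
# Fo = |A intersect B| / |A union B|. The null resamples pairs of random
# promoter sets of the same sizes (each set drawn without replacement, the
# two sets independent) and records the same fraction Fs; the empirical
# p-value is the proportion of Fs draws exceeding Fo. Because Fo is
# strictly increasing in the intersection size k at fixed N1 and N2, the
# exact large-sample limit of this p-value is the upper tail of the
# hypergeometric intersection-size distribution, which serves as the
# closed-form oracle.

#' Observed shared-promoter statistic for two bound sets
#'
#' @param a,b Character vectors of promoter/gene ids (each treated as a
#'   set).
#' @param denominator `"union"` (default; `Fo = k / |A union B|`, the
#'   Jaccard index) or `"sum"` (`Fo = k / (N1 + N2)`, which counts shared
#'   ids twice). Both are strictly increasing in `k` at fixed set sizes,
#'   so p-values are identical either way.
#' @return A one-row tibble: `n1`, `n2`, `k`, `fo`.
#' @examples
#' observed_stat(c("a", "b", "c"), c("b", "c", "d"))
#' @export
observed_stat <- function(a, b, denominator = c("union", "sum")) {
  denominator <- match.arg(denominator)
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0 && length(b) == 0) {
    pc_abort("both sets are empty: the shared fraction is undefined",
             "pc_validation_error")
  }
  k <- length(intersect(a, b))
  denom <- if (denominator == "union") length(union(a, b)) else length(a) + length(b)
  tibble::tibble(n1 = length(a), n2 = length(b), k = k, fo = k / denom)
}

#' Sample the null distribution of the shared fraction
#'
#' Draws `n_samples` independent pairs of uniform random subsets of sizes
#' `n1` and `n2` from a universe of `u` promoters (each subset without
#' replacement) and returns the shared fraction of each pair.
#'
#' @param u Universe size (number of housekeeping promoters).
#' @param n1,n2 Sizes of the two bound sets; both must be <= `u`.
#' @param n_samples Number of Monte Carlo draws (default 5000).
#' @param stat `"fraction"` returns Fs values; `"count"` returns raw
#'   intersection sizes (the two are deterministic transforms of each
#'   other at fixed `n1`, `n2`).
#' @param denominator Passed through to the fraction, see
#'   [observed_stat()].
#' @return Numeric (or integer, for `stat = "count"`) vector of length
#'   `n_samples`. Reproducible under `set.seed()`.
#' @export
sample_null <- function(u, n1, n2, n_samples = 5000L,
                        stat = c("fraction", "count"),
                        denominator = c("union", "sum")) {
  stat <- match.arg(stat)
  denominator <- match.arg(denominator)
  u <- as.integer(u); n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 > u || n2 > u) {
    pc_abort(sprintf("set sizes (%d, %d) cannot exceed the universe size %d",
                     n1, n2, u), "pc_validation_error")
  }
  if (n_samples < 1) pc_abort("`n_samples` must be >= 1", "pc_validation_error")
  ks <- pair_intersection_sizes(u, n1, n2, as.integer(n_samples))
  if (stat == "count") return(ks)
  denom <- if (denominator == "union") (n1 + n2 - ks) else (n1 + n2)
  fs <- ks / denom
  fs[ks == 0 & denom == 0] <- 0  # only possible when n1 = n2 = 0
  fs
}

#' Empirical p-value from a null sample
#'
#' With the defaults (`tie_rule = "strict_greater"`, no smoothing) the
#' p-value is the proportion of null statistics strictly exceeding the
#' observed one. `greater_equal` counts ties as exceedances;
#' `smoothing = "add_one"` returns `(count + 1) / (n + 1)`, which avoids
#' reporting exactly zero.
#'
#' @param fo Observed statistic.
#' @param fs Numeric vector of null statistics.
#' @param tie_rule `"strict_greater"` (default) or `"greater_equal"`.
#' @param smoothing `"none"` (default) or `"add_one"`.
#' @return The empirical p-value.
#' @export
empirical_p <- function(fo, fs, tie_rule = c("strict_greater", "greater_equal"),
                        smoothing = c("none", "add_one")) {
  tie_rule <- match.arg(tie_rule)
  smoothing <- match.arg(smoothing)
  if (length(fs) == 0) pc_abort("`fs` must be non-empty", "pc_validation_error")
  count <- if (tie_rule == "strict_greater") sum(fs > fo) else sum(fs >= fo)
  if (smoothing == "none") count / length(fs) else (count + 1) / (length(fs) + 1)
}

#' Exact upper tail of the hypergeometric intersection-size distribution
#'
#' When two subsets of sizes `n1` and `n2` are drawn uniformly without
#' replacement from a universe of `u` elements, their intersection size is
#' hypergeometric. This returns `P(X > k)`, the exact large-sample limit
#' of [empirical_p()] under the default strict-greater tie rule (the
#' shared fraction is strictly increasing in the intersection size at
#' fixed set sizes).
#'
#' @param u Universe size.
#' @param n1,n2 Subset sizes.
#' @param k Observed intersection size, `0 <= k <= min(n1, n2)`.
#' @return `P(X > k)`.
#' @examples
#' hypergeom_tail(10, 3, 3, 2)  # 1/120
#' @export
hypergeom_tail <- function(u, n1, n2, k) {
  if (n1 > u || n2 > u || k < 0 || k > min(n1, n2)) {
    pc_abort("need 0 <= k <= min(n1, n2) <= u", "pc_validation_error")
  }
  stats::phyper(k, n1, u - n1, n2, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction: p-values are sorted ascending,
#' scaled by `m / rank`, made monotone from the largest down and capped at
#' 1, then returned in the original order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    pc_abort("p-values must lie in [0, 1]", "pc_validation_error")
  }
  stats::p.adjust(pvals, method = "BH")
}

# Normalise bound-set input to a named list of character vectors.
as_bound_sets <- function(bound_sets) {
  if (is.data.frame(bound_sets)) {
    if (!all(c("protein", "gene_id") %in% names(bound_sets))) {
      pc_abort("bound-set tibble needs `protein` and `gene_id` columns",
               "pc_type_error")
    }
    sets <- split(as.character(bound_sets$gene_id), bound_sets$protein)
  } else if (is.list(bound_sets)) {
    sets <- lapply(bound_sets, as.character)
    if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
      pc_abort("bound sets supplied as a list must be named by protein",
               "pc_type_error")
    }
  } else {
    pc_abort("`bound_sets` must be a tibble (protein, gene_id) or a named list",
             "pc_type_error")
  }
  lapply(sets, unique)
}

#' Pairwise Monte Carlo colocalization test
#'
#' Runs the colocalization test for every unordered pair of bound sets:
#' computes the observed shared fraction, resamples the null within the
#' supplied promoter universe, derives empirical p-values and applies
#' Benjamini-Hochberg correction across all pairs. Each pair receives its
#' own RNG substream derived from the master seed and the pair's protein
#' names, so adding or removing a protein does not perturb the other
#' pairs' draws.
#'
#' @param bound_sets A tibble with columns `protein`, `gene_id` (one row
#'   per bound promoter) or a named list of gene-id vectors.
#' @param universe Character vector of promoter ids (the housekeeping
#'   promoter universe); every bound set must be a subset.
#' @param n_samples Monte Carlo draws per pair (default 5000).
#' @param seed Master seed (default 1).
#' @inheritParams empirical_p
#' @inheritParams observed_stat
#' @return A tibble of class `coloc_test`, one row per pair: `protein1`,
#'   `protein2`, `n1`, `n2`, `k`, `fo`, `p_emp`, `p_adj`, with
#'   `n_samples`, `seed` and `universe_size` stored as attributes.
#' @export
coloc_test <- function(bound_sets, universe, n_samples = 5000L, seed = 1L,
                       tie_rule = c("strict_greater", "greater_equal"),
                       smoothing = c("none", "add_one"),
                       denominator = c("union", "sum")) {
  tie_rule <- match.arg(tie_rule)
  smoothing <- match.arg(smoothing)
  denominator <- match.arg(denominator)
  sets <- as_bound_sets(bound_sets)
  if (length(sets) < 2) {
    pc_abort("need at least two bound sets", "pc_validation_error")
  }
  universe <- unique(as.character(universe))
  if (length(universe) < 2) {
    pc_abort("the promoter universe must contain at least two ids",
             "pc_validation_error")
  }
  stray <- setdiff(unlist(sets, use.names = FALSE), universe)
  if (length(stray) > 0) {
    pc_abort(sprintf("%d bound promoter id(s) are not in the universe (e.g. %s)",
                     length(stray), stray[1]), "pc_validation_error")
  }
  proteins <- sort(names(sets))
  pairs <- utils::combn(proteins, 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(j) {
    p1 <- pairs[1, j]; p2 <- pairs[2, j]
    obs <- observed_stat(sets[[p1]], sets[[p2]], denominator = denominator)
    sub_seed <- substream_seed(seed, paste(p1, p2, sep = "||"))
    fs <- withr::with_seed(sub_seed,
      sample_null(length(universe), obs$n1, obs$n2, n_samples,
                  stat = "fraction", denominator = denominator))
    tibble::tibble(protein1 = p1, protein2 = p2, n1 = obs$n1, n2 = obs$n2,
                   k = obs$k, fo = obs$fo,
                   p_emp = empirical_p(obs$fo, fs, tie_rule, smoothing))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- bh_adjust(out$p_emp)
  attr(out, "n_samples") <- as.integer(n_samples)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "universe_size") <- length(universe)
  class(out) <- c("coloc_test", class(out))
  out
}

#' @export
print.coloc_test <- function(x, ...) {
  cat(sprintf("Monte Carlo colocalization test: %d pair(s), universe of %d promoters, %d draws/pair (seed %d)\n",
              nrow(x), attr(x, "universe_size"), attr(x, "n_samples"),
              attr(x, "seed")))
  NextMethod()
}

#' Tidy a colocalization test result
#'
#' @param x A `coloc_test` object.
#' @param ... Unused.
#' @return A plain tibble of the per-pair results.
#' @export
tidy.coloc_test <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "coloc_test")
  attr(out, "n_samples") <- NULL
  attr(out, "seed") <- NULL
  attr(out, "universe_size") <- NULL
  tibble::as_tibble(out)
}

#' One-row summary of a colocalization test
#'
#' @param x A `coloc_test` object.
#' @param alpha Significance level for counting significant pairs on the
#'   BH-adjusted scale (default 0.05).
#' @param ... Unused.
#' @return A one-row tibble: `n_pairs`, `n_significant`, `min_p_adj`,
#'   `universe_size`, `n_samples`, `seed`.
#' @export
glance.coloc_test <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_significant = sum(x$p_adj <= alpha),
    min_p_adj = if (nrow(x) > 0) min(x$p_adj) else NA_real_,
    universe_size = attr(x, "universe_size"),
    n_samples = attr(x, "n_samples"),
    seed = attr(x, "seed")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
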