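#' Bonferroni-corrected per-test level
#'
#' @param alpha Family-wise error level.
#' @param n_tests Number of tests in the family.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 20)  # 0.0025
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Configuration for the bootstrap enrichment test
#'
#' @param n_boot Number of bootstrap iterations (default 10000).
#' @param alpha Family-wise level for the Bonferroni correction.
#' @param n_tests Number of tests (one per residue; default 20).
#' @param seed Integer seed; required for reproducibility.
#' @param sampling_unit `"residue"` (pooled residues of each set resampled
#'   with replacement; default) or `"protein"` (whole proteins resampled,
#'   mean of per-protein fractions).
#' @return A list of class `TestConfig`.
#' @export
test_config <- function(n_boot = 10000L, alpha = 0.05, n_tests = 20L,
                        seed = 1L, sampling_unit = c("residue", "protein")) {
  stopifnot(n_boot >= 1L, alpha > 0, alpha < 1, n_tests >= 1L)
  structure(list(n_boot = as.integer(n_boot), alpha = alpha,
                 n_tests = as.integer(n_tests), seed = as.integer(seed),
                 sampling_unit = match.arg(sampling_unit)),
            class = "TestConfig")
}

# n_boot x 20 matrix of bootstrap mean-composition replicates for one set
.boot_freqs <- function(set, n_boot, unit) {
  if (unit == "residue") {
    counts <- .pooled_counts(set)
    total <- sum(counts)
    # iid residue resampling == multinomial draw over observed frequencies
    t(stats::rmultinom(n_boot, size = total, prob = counts / total)) / total
  } else {
    cm <- composition_matrix(set)
    n <- nrow(cm)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    t(apply(idx, 1L, function(i) colMeans(cm[i, , drop = FALSE])))
  }
}

.star_levels <- function(p) {
  ifelse(p < 1e-4, "***", ifelse(p < 1e-3, "**", ifelse(p < 0.0025, "*", "ns")))
}

#' Bootstrap enrichment test of a query set against a background set
#'
#' For each canonical residue, compares the query set's frequency with the
#' background set's by bootstrap resampling (composition-profiler style). Both
#' sets are resampled `n_boot` times at the configured sampling unit; the
#' empirical distribution of frequency differences yields a two-tailed
#' empirical p-value with add-one correction,
#' `p = min(1, 2 * (k + 1) / (n_boot + 1))` where `k` counts bootstrap
#' differences on the opposite side of 0 from the observed difference
#' (doubling the directed tail keeps the family-wise type-I error at the
#' nominal level). Significance stars are assigned against
#' Bonferroni-corrected thresholds (`*` p < 0.0025, `**` p < 0.0010,
#' `***` p < 0.0001 at the defaults alpha = 0.05, 20 tests). The reported
#' effect size is `(q - b) / b` on the original, unresampled means.
#'
#' @param query,background Non-empty [protein_set()]s.
#' @param cfg A [test_config()].
#' @return Data frame of class `EnrichmentResult`, one row per residue:
#'   `residue`, `query_mean`, `background_mean`, `relative_difference`
#'   (NA with `undefined_background = TRUE` if the background frequency is 0),
#'   `p_value`, `significance`.
#' @export
bootstrap_enrichment <- function(query, background, cfg = test_config()) {
  stopifnot(inherits(query, "ProteinSet"), inherits(background, "ProteinSet"),
            length(query) > 0L, length(background) > 0L,
            inherits(cfg, "TestConfig"))
  q_counts <- .pooled_counts(query)
  b_counts <- .pooled_counts(background)
  if (cfg$sampling_unit == "residue") {
    q_mean <- q_counts / sum(q_counts)
    b_mean <- b_counts / sum(b_counts)
  } else {
    q_mean <- colMeans(composition_matrix(query))
    b_mean <- colMeans(composition_matrix(background))
  }
  set.seed(cfg$seed)
  qb <- .boot_freqs(query, cfg$n_boot, cfg$sampling_unit)
  bb <- .boot_freqs(background, cfg$n_boot, cfg$sampling_unit)
  diffs <- qb - bb                      # n_boot x 20
  d_obs <- q_mean - b_mean
  k <- vapply(seq_along(AA_ALPHABET), function(j) {
    if (d_obs[j] >= 0) sum(diffs[, j] <= 0) else sum(diffs[, j] >= 0)
  }, integer(1))
  p <- pmin(1, 2 * (k + 1) / (cfg$n_boot + 1))
  p[d_obs == 0] <- 1                    # no evidence either way
  bonf1 <- bonferroni_threshold(cfg$alpha, cfg$n_tests)
  undefined <- b_mean == 0
  rel <- ifelse(undefined, NA_real_, (q_mean - b_mean) / b_mean)
  out <- data.frame(
    residue = AA_ALPHABET,
    query_mean = unname(q_mean),
    background_mean = unname(b_mean),
    relative_difference = unname(rel),
    undefined_background = unname(undefined),
    p_value = p,
    significance = .star_levels(p),
    stringsAsFactors = FALSE)
  attr(out, "config") <- cfg
  attr(out, "bonferroni_level") <- bonf1
  class(out) <- c("EnrichmentResult", class(out))
  out
}

#' Pairwise correlation of residue contents across proteins
#'
#' Correlates the 20 composition columns across the proteins of a set and
#' reports two-sided p-values from the standard correlation test with n - 2
#' degrees of freedom, plus a mask of non-significant pairs at 0.05 (the
#' pairs a correlation plot would cross out). Constant columns yield
#' undefined r, reported as NA and masked.
#'
#' @param matrix A `CompositionMatrix` with >= 3 proteins.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha Mask level (default 0.05).
#' @return List of class `CorrelationTable` with 20 x 20 components `r`, `p`
#'   and logical `mask` (`TRUE` = not significant at `alpha`).
#' @export
correlation_analysis <- function(matrix, method = c("pearson", "spearman"),
                                 alpha = 0.05) {
  stopifnot(inherits(matrix, "CompositionMatrix"), nrow(matrix) >= 3L)
  method <- match.arg(method)
  x <- unclass(matrix)
  constant <- apply(x, 2L, function(v) stats::var(v) == 0)
  r <- suppressWarnings(stats::cor(x, method = method))
  n <- nrow(x)
  # two-sided p from the t transform, as cor.test reports for df = n - 2
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  r[constant, ] <- NA; r[, constant] <- NA
  p[constant, ] <- NA; p[, constant] <- NA
  diag(r)[!constant] <- 1
  mask <- is.na(p) | p > alpha
  structure(list(r = r, p = p, mask = mask, method = method, n = n),
            class = "CorrelationTable")
}
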