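#' Hudson Fst, parameter form
#'
#' Treats the two allele frequencies as known population parameters:
#' `F = (p1 - p2)^2 / (p1 (1 - p2) + p2 (1 - p1))`.  When the denominator is
#' zero (both frequencies 0, or both 1) the value is 0 by convention — the
#' populations are identical at the locus.  Vectorized.
#'
#' @param p1,p2 allele frequencies in `[0, 1]`
#' @return Fst in `[0, 1]`
#' @examples
#' fst_param(1, 0)        # fixed difference: 1
#' fst_param(0.5, 0.5)    # identical: 0
#' @export
fst_param <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  num <- (p1 - p2)^2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ifelse(den == 0, 0, num / den)
}

#' Hudson Fst, sample-corrected (Bhatia) components
#'
#' Per-locus numerator and denominator of the Hudson estimator with
#' finite-sample correction:
#' `N = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' `D = p1(1-p2) + p2(1-p1)`, with `n1`, `n2` haploid sample counts.  The
#' per-locus ratio `N/D` may be negative and is never truncated.  Vectorized;
#' returns the components so that genome-wide estimates can aggregate as a
#' ratio of averages ([fst_genomewide()]).
#'
#' @param p1,p2 sample allele frequencies
#' @param n1,n2 haploid sample counts (>= 2)
#' @param locus optional locus ids
#' @return data.frame of class `fst_pairs` with columns `locus`, `num`,
#'   `den`, `fst` (= `num/den`, `NA` where `den == 0`)
#' @export
fst_sample <- function(p1, n1, p2, n2, locus = NULL) {
  if (any(n1 < 2 | n2 < 2)) stop("haploid counts must be >= 2")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (is.null(locus)) locus <- seq_along(num)
  structure(data.frame(locus = locus, num = num, den = den,
                       fst = ifelse(den == 0, NA_real_, num / den),
                       stringsAsFactors = FALSE),
            class = c("fst_pairs", "data.frame"))
}

#' Genome-wide Fst as a ratio of averages
#'
#' `sum(N) / sum(D)` over loci with positive denominator — not the mean of
#' per-locus ratios, which is biased for loci with small denominators.
#'
#' @param pairs an `fst_pairs` data.frame (or any data.frame with `num` and
#'   `den` columns)
#' @return the genome-wide Fst estimate
#' @export
fst_genomewide <- function(pairs) {
  keep <- pairs$den > 0 & !is.na(pairs$den) & !is.na(pairs$num)
  if (!any(keep)) stop("no locus with positive denominator")
  sum(pairs$num[keep]) / sum(pairs$den[keep])
}

#' Percentile-bootstrap CI for genome-wide Fst
#'
#' Resamples loci with replacement `B` times, recomputes the
#' ratio-of-averages estimate, and takes empirical `alpha/2` and
#' `1 - alpha/2` percentiles.
#'
#' @param pairs an `fst_pairs` data.frame (>= 2 loci)
#' @param B bootstrap replicates (default 10000)
#' @param alpha two-sided level (default 0.05 for a 95% CI)
#' @param seed integer seed
#' @return list of class `boot_ci`: `estimate`, `lower`, `upper`, `alpha`,
#'   `B`, `seed`
#' @export
fst_bootstrap_ci <- function(pairs, B = 10000, alpha = 0.05, seed = 1) {
  L <- nrow(pairs)
  if (L < 2) stop("need at least 2 loci")
  set.seed(seed)
  num <- pairs$num
  den <- pairs$den
  keep <- den > 0 & !is.na(den) & !is.na(num)
  num <- num[keep]; den <- den[keep]; L <- length(num)
  idx <- matrix(sample.int(L, L * B, replace = TRUE), L, B)
  stats <- colSums(matrix(num[idx], L, B)) / colSums(matrix(den[idx], L, B))
  qs <- quantile(stats, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  structure(list(estimate = sum(num) / sum(den), lower = qs[1], upper = qs[2],
                 alpha = alpha, B = B, seed = seed),
            class = "boot_ci")
}

#' @export
print.boot_ci <- function(x, ...) {
  cat(sprintf("Fst = %.4f, %g%% CI [%.4f, %.4f] (percentile bootstrap, B=%d)\n",
              x$estimate, 100 * (1 - x$alpha), x$lower, x$upper, x$B))
  invisible(x)
}

#' Locus-specific branch length
#'
#' Branch length of focal population 2 against populations 1 and 3:
#' `(F12 + F23 - F13) / 2`.  May be negative.  The three branch lengths at a
#' locus sum to `(F12 + F23 + F13) / 2`, and the branches of populations 1
#' and 2 sum to `F12` exactly.
#'
#' @param f12 pairwise Fst between populations 1 and 2 (1 vs focal)
#' @param f23 pairwise Fst between populations 2 and 3 (focal vs 3)
#' @param f13 pairwise Fst between populations 1 and 3
#' @return the focal branch length; vectorized
#' @export
lsbl <- function(f12, f23, f13) (f12 + f23 - f13) / 2

#' Population branch statistic
#'
#' The same branch construction as [lsbl()] applied after transforming each
#' pairwise Fst to a divergence-time scale `T = -log(1 - Fst)`.  Requires all
#' pairwise Fst values below 1.
#'
#' @inheritParams lsbl
#' @return the focal population branch statistic; vectorized
#' @export
pbs <- function(f12, f23, f13) {
  if (any(c(f12, f23, f13) >= 1, na.rm = TRUE))
    stop("pairwise Fst >= 1 implies infinite divergence time")
  t12 <- -log1p(-f12); t23 <- -log1p(-f23); t13 <- -log1p(-f13)
  (t12 + t23 - t13) / 2
}
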