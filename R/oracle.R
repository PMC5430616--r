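#' Brute-force grid-search optimum of the K=2 likelihood
#'
#' Exhaustively scans every combination of per-sample ancestry proportions
#' and per-SNP component frequency pairs on a regular grid and returns the
#' maximum binomial admixture log-likelihood.  Complexity is exponential in
#' the number of samples — it exists to validate the EM optimizer on tiny
#' instances (exactly 4 samples) and is independent of the EM code path.
#'
#' @param gm a `geno_matrix` with exactly 4 samples
#' @param step grid resolution (default 0.02)
#' @param eps frequency clamp used in the likelihood (default 1e-6)
#' @return the maximum log-likelihood over the grid
#' @export
grid_loglik_max <- function(gm, step = 0.02, eps = 1e-6) {
  G <- gm$dosage
  storage.mode(G) <- "integer"
  .grid_loglik_max(G, step, eps)
}
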