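#' Specification of a synthetic admixed cohort
#'
#' Defines a Balding-Nichols style generative model for an admixed cohort
#' with known truth: per-locus ancestral frequencies drawn uniformly, K
#' ancestral populations drifting from the shared ancestor with parameters
#' `F_k`, Dirichlet-distributed individual ancestry proportions, nearly-pure
#' per-ancestry proxy pools, and optionally injected differentiated outlier
#' loci.
#'
#' The default Dirichlet mean (0.57 / 0.20 / 0.23, concentration 8) emulates
#' a tri-continental cohort with predominant European, and substantial
#' Amerindian and African, ancestry and broad individual ranges; the default
#' drift (`F = 0.15` per ancestry) is of continental magnitude.
#'
#' @param K number of ancestral components (default 3)
#' @param n_snps number of loci (default 3000)
#' @param n_admixed number of admixed cohort samples (default 500)
#' @param drift_F per-ancestry drift from the shared ancestor, in (0,1);
#'   recycled to length K (default 0.15)
#' @param ancestral_freq_range uniform range for the ancestral frequency
#'   (default `c(0.05, 0.95)`)
#' @param dirichlet_alpha K positive reals; defaults to concentration 8
#'   times mean `c(0.57, 0.20, 0.23)` when K = 3, else `rep(1, K)`
#' @param n_proxy_pool per-ancestry pool of candidate proxy samples,
#'   recycled to length K (default 50)
#' @param proxy_contamination fraction of admixed ancestry mixed into each
#'   proxy individual, in `[0, 0.5]` (default 0)
#' @param outliers data.frame with columns `locus` (index), `ancestry`
#'   (index), `freq` (target frequency), or NULL
#' @param missing_rate genotype missingness rate (default 0)
#' @param ancestry_labels component names (default `"anc1"...`)
#' @param seed integer seed; all randomness in [make_study()] derives from it
#' @return a list of class `cohort_spec`
#' @export
cohort_spec <- function(K = 3, n_snps = 3000, n_admixed = 500,
                        drift_F = 0.15,
                        ancestral_freq_range = c(0.05, 0.95),
                        dirichlet_alpha = NULL,
                        n_proxy_pool = 50,
                        proxy_contamination = 0,
                        outliers = NULL,
                        missing_rate = 0,
                        ancestry_labels = NULL,
                        seed = 1) {
  if (is.null(dirichlet_alpha))
    dirichlet_alpha <- if (K == 3) 8 * c(0.57, 0.20, 0.23) else rep(1, K)
  drift_F <- rep_len(drift_F, K)
  n_proxy_pool <- rep_len(n_proxy_pool, K)
  ancestry_labels <- ancestry_labels %||% paste0("anc", seq_len(K))
  stopifnot(K >= 1, n_snps >= 1, n_admixed >= 0,
            all(drift_F > 0 & drift_F < 1),
            all(dirichlet_alpha > 0), length(dirichlet_alpha) == K,
            proxy_contamination >= 0, proxy_contamination <= 0.5,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(outliers)) {
    stopifnot(all(c("locus", "ancestry", "freq") %in% names(outliers)))
    if (anyDuplicated(outliers$locus)) stop("duplicate outlier locus")
    stopifnot(all(outliers$locus >= 1 & outliers$locus <= n_snps),
              all(outliers$ancestry >= 1 & outliers$ancestry <= K))
  }
  structure(list(K = K, n_snps = n_snps, n_admixed = n_admixed,
                 drift_F = drift_F,
                 ancestral_freq_range = ancestral_freq_range,
                 dirichlet_alpha = dirichlet_alpha,
                 n_proxy_pool = n_proxy_pool,
                 proxy_contamination = proxy_contamination,
                 outliers = outliers, missing_rate = missing_rate,
                 ancestry_labels = ancestry_labels, seed = seed),
            class = "cohort_spec")
}

#' Draw drifted ancestral allele frequencies
#'
#' Balding-Nichols model: per locus a common ancestral frequency `p_anc` is
#' drawn uniformly in the spec's range; each ancestry k then draws
#' independently from `Beta(p_anc (1-F_k)/F_k, (1-p_anc)(1-F_k)/F_k)`, whose
#' mean is `p_anc` and variance `F_k p_anc (1 - p_anc)`.
#'
#' @param spec a `cohort_spec`
#' @param p_anc optional vector of ancestral frequencies (drawn if NULL)
#' @return K x n_snps matrix of component frequencies, attribute `p_anc`
#' @export
sample_ancestral_freqs <- function(spec, p_anc = NULL) {
  if (is.null(p_anc))
    p_anc <- runif(spec$n_snps, spec$ancestral_freq_range[1],
                   spec$ancestral_freq_range[2])
  P <- matrix(NA_real_, spec$K, spec$n_snps)
  for (k in seq_len(spec$K)) {
    Fk <- spec$drift_F[k]
    P[k, ] <- rbeta(spec$n_snps, p_anc * (1 - Fk) / Fk,
                    (1 - p_anc) * (1 - Fk) / Fk)
  }
  rownames(P) <- spec$ancestry_labels
  attr(P, "p_anc") <- p_anc
  P
}

#' Inject differentiated outlier loci
#'
#' Overwrites the named ancestry's frequency at each outlier locus with the
#' target value, leaving all other entries untouched.  Overwriting (rather
#' than shifting) makes the truth unambiguous for recovery tests.
#'
#' @param P K x n_snps component frequency matrix
#' @param outliers data.frame with `locus`, `ancestry`, `freq` (or NULL)
#' @return the modified matrix
#' @export
inject_differentiation <- function(P, outliers) {
  if (is.null(outliers) || nrow(outliers) == 0) return(P)
  if (anyDuplicated(outliers$locus)) stop("duplicate outlier locus")
  P[cbind(outliers$ancestry, outliers$locus)] <- outliers$freq
  P
}

#' Sample admixed genotypes
#'
#' Generative form of the admixture model: `g_ij ~ Binomial(2, (Q P)_ij)`,
#' independent across samples and loci.
#'
#' @param P K x n_snps component frequencies
#' @param Q samples x K ancestry proportions with sample ids as row names
#' @param seed integer seed (NULL: use current RNG state)
#' @param missing_rate fraction of entries set missing at random (default 0)
#' @param snps optional SNP map; a default map (all on chromosome 1, 10 kb
#'   apart, alleles A/G) is built if absent
#' @return a `geno_matrix`
#' @export
sample_admixed_genotypes <- function(P, Q, seed = NULL, missing_rate = 0,
                                     snps = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(ncol(Q) == nrow(P))
  n <- nrow(Q); m <- ncol(P)
  Fq <- Q %*% P
  G <- matrix(rbinom(n * m, 2L, Fq), n, m)
  if (missing_rate > 0)
    G[runif(n * m) < missing_rate] <- NA
  rownames(G) <- rownames(Q) %||% paste0("s", seq_len(n))
  if (is.null(snps))
    snps <- data.frame(id = paste0("snp", seq_len(m)), chrom = "1",
                       pos = 10000L * seq_len(m), cM = NA_real_,
                       a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  geno_matrix(G, snps)
}

.rdirichlet <- function(n, alpha) {
  m <- matrix(rgamma(n * length(alpha), alpha), n, length(alpha),
              byrow = TRUE)
  m / rowSums(m)
}

#' Generate a full synthetic study
#'
#' Draws component frequencies (with outlier injection), Dirichlet ancestry
#' proportions for the admixed cohort, nearly-pure proxy-pool individuals
#' (`Q = (1 - c) * indicator + c * Dirichlet(alpha)` with
#' `c = proxy_contamination`), and binomial genotypes for everyone.  All
#' randomness flows from `spec$seed` through fixed offsets per stage
#' (frequencies, cohort Q, proxy Q, genotypes), so an identical spec yields
#' an identical study.
#'
#' @param spec a [cohort_spec()]
#' @return list of class `synthetic_study`: `cohort` (`geno_matrix` of
#'   admixed samples), `proxies` (`geno_matrix` of pool samples),
#'   `combined` (both), `truth` (list: `Q`, `P`, `p_anc`, `outliers`,
#'   `pool_ancestry` named vector, `spec`)
#' @export
make_study <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  P <- sample_ancestral_freqs(spec)
  P <- inject_differentiation(P, spec$outliers)

  set.seed(spec$seed + 1L)
  Qa <- if (spec$n_admixed > 0)
    .rdirichlet(spec$n_admixed, spec$dirichlet_alpha)
  else matrix(numeric(0), 0, spec$K)

  set.seed(spec$seed + 2L)
  npool <- spec$n_proxy_pool
  Qp <- do.call(rbind, lapply(seq_len(spec$K), function(k) {
    ind <- matrix(0, npool[k], spec$K)
    ind[, k] <- 1
    cc <- spec$proxy_contamination
    (1 - cc) * ind + cc * .rdirichlet(npool[k], spec$dirichlet_alpha)
  }))
  pool_ancestry <- rep(spec$ancestry_labels, npool)

  ids_a <- if (spec$n_admixed > 0) sprintf("adm%04d", seq_len(spec$n_admixed))
           else character(0)
  ids_p <- sprintf("%s_p%03d", pool_ancestry,
                   unlist(lapply(npool, seq_len)))
  Q <- rbind(Qa, Qp)
  rownames(Q) <- c(ids_a, ids_p)
  colnames(Q) <- spec$ancestry_labels

  gm <- sample_admixed_genotypes(P, Q, seed = spec$seed + 3L,
                                 missing_rate = spec$missing_rate)
  cohort <- subset_geno(gm, samples = ids_a)
  proxies <- subset_geno(gm, samples = ids_p)
  truth <- list(Q = Q, P = P, p_anc = attr(P, "p_anc"),
                outliers = spec$outliers,
                pool_ancestry = setNames(pool_ancestry, ids_p),
                spec = spec)
  structure(list(cohort = cohort, proxies = proxies, combined = gm,
                 truth = truth),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", n_samples(x$cohort), "admixed +",
      n_samples(x$proxies), "proxy-pool samples,",
      n_snps(x$combined), "SNPs\n")
  invisible(x)
}
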