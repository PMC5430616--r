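#' Standardize dosages against a defining sample set
#'
#' Per SNP, subtracts the mean dosage of the defining samples (`2 * p_hat`)
#' and, with `patterson_scaling = TRUE` (the EIGENSOFT convention), divides by
#' `sqrt(2 * p_hat * (1 - p_hat))`.  SNPs monomorphic (or all-missing) in the
#' defining set are excluded.  Missing dosages are imputed to the defining-set
#' mean, i.e. 0 after centering.
#'
#' @param gm a `geno_matrix`
#' @param defining_samples sample ids that define means and scales
#' @param patterson_scaling logical; divide by the binomial SD (default TRUE)
#' @return list: `X` (standardized matrix over all samples of `gm`, excluded
#'   SNPs removed), `snp_ids`, `means`, `scales`
#' @export
standardize_dosage <- function(gm, defining_samples,
                               patterson_scaling = TRUE) {
  if (length(defining_samples) < 2)
    stop("need at least 2 defining samples")
  af <- allele_freq(gm, defining_samples)
  p <- af$freq / 1  # A1 frequency in defining set
  keep <- !is.na(p) & p > 0 & p < 1
  d <- gm$dosage[, keep, drop = FALSE]
  p <- p[keep]
  means <- 2 * p
  scales <- if (patterson_scaling) sqrt(2 * p * (1 - p)) else rep(1, length(p))
  X <- sweep(d, 2, means, "-")
  X[is.na(X)] <- 0
  X <- sweep(X, 2, scales, "/")
  list(X = X, snp_ids = gm$snps$id[keep], means = means, scales = scales)
}

#' Reference-defined PCA
#'
#' Fits principal components on the standardized genotypes of the defining
#' samples only, so the axes are determined solely by variation within that
#' set; other samples can then be projected onto these axes with
#' [pca_project()].  This is the geometry used when study samples define the
#' ancestry axes and external reference panels are plotted into them (or vice
#' versa for a reference-supervised PCA).
#'
#' Loadings are obtained by SVD of the standardized defining-sample matrix.
#' Sign convention: the largest-magnitude element of each loading column is
#' made positive.  Out-of-sample projections are not corrected for shrinkage
#' toward zero.
#'
#' @param gm a `geno_matrix` containing (at least) the defining samples
#' @param defining_samples sample ids defining the axes
#' @param n_components number of components to return
#' @param patterson_scaling see [standardize_dosage()]
#' @return list of class `pca_model`: `snp_ids`, `means`, `scales`,
#'   `loadings` (SNPs x k, orthonormal columns), `eigenvalues` (per-component
#'   variance), and `scores` (defining samples x k)
#' @export
pca_fit <- function(gm, defining_samples, n_components = 10,
                    patterson_scaling = TRUE) {
  std <- standardize_dosage(gm, defining_samples, patterson_scaling)
  # standardization centers each SNP at the defining-set mean dosage and
  # imputes missing to 0, so Xd columns have exactly zero mean already
  Xd <- std$X[defining_samples, , drop = FALSE]
  kmax <- min(length(defining_samples) - 1L, ncol(Xd))
  if (n_components > kmax) {
    warning("rank supports only ", kmax, " components; truncating")
    n_components <- kmax
  }
  sv <- svd(Xd, nu = n_components, nv = n_components)
  eig <- (sv$d^2 / (length(defining_samples) - 1))[seq_len(n_components)]
  V <- sv$v
  flip <- vapply(seq_len(ncol(V)),
                 function(j) sign(V[which.max(abs(V[, j])), j]), numeric(1))
  V <- sweep(V, 2, flip, "*")
  U <- sweep(sv$u, 2, flip, "*")
  scores <- U %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- defining_samples
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(n_components))
  structure(list(snp_ids = std$snp_ids, means = std$means,
                 scales = std$scales, loadings = V, eigenvalues = eig,
                 scores = scores),
            class = "pca_model")
}

#' Project samples onto fitted principal axes
#'
#' Standardizes `gm_other` with the model's means/scales (missing dosages
#' impute to 0 after centering) and multiplies by the loadings.  Model SNPs
#' absent from `gm_other` are treated as missing; if fewer than
#' `min_overlap` of the model SNPs are present the projection is refused as
#' unreliable.
#'
#' @param model a `pca_model` from [pca_fit()]
#' @param gm_other a `geno_matrix` sharing the model's SNPs
#' @param min_overlap minimum fraction of model SNPs required (default 0.8)
#' @return scores matrix (samples x components)
#' @export
pca_project <- function(model, gm_other, min_overlap = 0.8) {
  idx <- match(model$snp_ids, gm_other$snps$id)
  frac <- mean(!is.na(idx))
  if (frac < min_overlap)
    stop(sprintf("only %.0f%% of model SNPs present (need >= %.0f%%)",
                 100 * frac, 100 * min_overlap))
  d <- matrix(NA_real_, n_samples(gm_other), length(model$snp_ids),
              dimnames = list(sample_ids(gm_other), model$snp_ids))
  d[, !is.na(idx)] <- gm_other$dosage[, idx[!is.na(idx)], drop = FALSE]
  X <- sweep(d, 2, model$means, "-")
  X[is.na(X)] <- 0
  X <- sweep(X, 2, model$scales, "/")
  scores <- X %*% model$loadings
  colnames(scores) <- colnames(model$loadings)
  scores
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model:", length(x$snp_ids), "SNPs,", ncol(x$loadings),
      "components\n  eigenvalues:",
      paste(signif(x$eigenvalues, 4), collapse = " "), "\n")
  invisible(x)
}

#' Write PCA scores as TSV
#'
#' @param scores matrix of scores (samples x components)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_scores <- function(scores, path) {
  tab <- data.frame(sample_id = rownames(scores), scores,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
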