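#' Binomial admixture log-likelihood
#'
#' Log-likelihood of diploid genotypes under the independent-loci admixture
#' model: each genotype `g_ij ~ Binomial(2, f_ij)` with mixture frequency
#' `f_ij = sum_k Q[i,k] P[k,j]`.  Missing genotypes contribute 0.  Mixture
#' frequencies are clamped to `[eps, 1 - eps]` so a discordant genotype never
#' yields `-Inf`.
#'
#' @param gm a `geno_matrix`
#' @param Q samples x K matrix of ancestry proportions (rows on the simplex)
#' @param P K x SNPs matrix of component A1 allele frequencies
#' @param eps frequency clamp (default 1e-6)
#' @return the log-likelihood (a scalar); the binomial coefficient term is
#'   omitted, as is conventional
#' @export
admix_loglik <- function(gm, Q, P, eps = 1e-6) {
  G <- gm$dosage
  .loglik_matrix(G, Q, P, eps)
}

.loglik_matrix <- function(G, Q, P, eps) {
  F <- Q %*% P
  F[F < eps] <- eps
  F[F > 1 - eps] <- 1 - eps
  G0 <- G; G0[is.na(G0)] <- 0
  G2 <- 2 - G; G2[is.na(G2)] <- 0
  sum(G0 * log(F)) + sum(G2 * log1p(-F))
}

# one EM pass; returns fit at local optimum.
# Plain EM on this model is monotone but slow, so each iteration optionally
# tries an over-relaxed step x0 + s (x1 - x0) along the EM direction
# (projected back onto the constraints) and keeps it only when it improves
# the likelihood; the accepted log-likelihood sequence stays non-decreasing.
.em_run <- function(G, K, Q, P, fixed_rows = integer(0), fixed_Q = NULL,
                    tol = 1e-7, max_iter = 2000, eps = 1e-6,
                    accelerate = TRUE) {
  W <- !is.na(G)
  G0 <- G; G0[!W] <- 0
  G2 <- 2 - G; G2[!W] <- 0
  m_i <- 2 * rowSums(W)
  if (any(m_i == 0)) stop("sample with all genotypes missing")

  em_step <- function(Q, P) {
    F <- Q %*% P
    F[F < eps] <- eps
    F[F > 1 - eps] <- 1 - eps
    U <- G0 / F
    V <- G2 / (1 - F)
    TQU <- crossprod(Q, U)           # K x M
    TQV <- crossprod(Q, V)
    Pn <- (P * TQU) / (P * TQU + (1 - P) * TQV)
    Pn[!is.finite(Pn)] <- 0.5        # all-missing SNP column
    Pn[Pn < eps] <- eps
    Pn[Pn > 1 - eps] <- 1 - eps
    Qn <- Q * (U %*% t(P) + V %*% t(1 - P)) / m_i
    Qn <- Qn / rowSums(Qn)
    if (length(fixed_rows)) Qn[fixed_rows, ] <- fixed_Q
    list(Q = Qn, P = Pn)
  }
  project <- function(Q, P) {
    P[P < eps] <- eps
    P[P > 1 - eps] <- 1 - eps
    Q[Q < 0] <- 0
    Q <- Q / rowSums(Q)
    if (length(fixed_rows)) Q[fixed_rows, ] <- fixed_Q
    list(Q = Q, P = P)
  }

  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  s <- 2                               # over-relaxation step length
  repeat {
    iter <- iter + 1L
    st <- em_step(Q, P)
    if (accelerate && s > 1) {
      cand <- project(Q + s * (st$Q - Q), P + s * (st$P - P))
      ll_c <- .loglik_matrix(G, cand$Q, cand$P, eps)
      ll_1 <- .loglik_matrix(G, st$Q, st$P, eps)
      if (ll_c > ll_1) {
        st <- cand; ll <- ll_c; s <- min(s * 1.5, 16)
      } else {
        ll <- ll_1; s <- max(2, s / 2)
      }
    } else {
      ll <- .loglik_matrix(G, st$Q, st$P, eps)
    }
    Q <- st$Q; P <- st$P
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) / (abs(ll_prev) + .Machine$double.eps) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
  }
  list(Q = Q, P = P, loglik = ll, trace = trace, n_iter = iter,
       converged = converged)
}

.random_simplex <- function(n, K) {
  m <- matrix(rgamma(n * K, 1), n, K)
  m / rowSums(m)
}

.new_admix_fit <- function(run, K, mode, seed) {
  structure(list(K = K, Q = run$Q, P = run$P, loglik = run$loglik,
                 n_iter = run$n_iter, converged = run$converged,
                 trace = run$trace, mode = mode, seed = seed),
            class = "admix_fit")
}

#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf("admix_fit: K=%d, %s, loglik=%.2f, %d iterations%s\n",
              x$K, x$mode, x$loglik, x$n_iter,
              if (x$converged) "" else " (NOT converged)"))
  cat("  mean ancestry:", paste(sprintf("%.3f", colMeans(x$Q)), collapse = " "),
      "\n")
  invisible(x)
}

#' Unsupervised admixture fit
#'
#' Maximum-likelihood decomposition of genotypes into Q (ancestry
#' proportions) and P (component allele frequencies) by EM under the binomial
#' independent-loci model.  Multiple random restarts are run and the best
#' log-likelihood kept.  Component labels are standardized by descending mean
#' ancestry proportion.
#'
#' @param gm a `geno_matrix` (no all-missing samples)
#' @param K number of ancestral components
#' @param seed integer seed; restarts use `seed, seed+1, ...`
#' @param n_restarts random restarts (default 3)
#' @param tol relative log-likelihood change for convergence (default 1e-7)
#' @param max_iter maximum EM iterations per restart (default 2000)
#' @param eps allele-frequency clamp (default 1e-6)
#' @return an `admix_fit`: list with `K`, `Q`, `P`, `loglik`, `n_iter`,
#'   `converged`, `trace` (per-iteration log-likelihood), `mode`, `seed`
#' @export
fit_unsupervised <- function(gm, K, seed = 1, n_restarts = 3, tol = 1e-7,
                             max_iter = 2000, eps = 1e-6) {
  stopifnot(K >= 1)
  G <- gm$dosage
  if (K == 1) {
    # analytic optimum: Q all ones, P = observed allele frequencies
    p <- allele_freq(gm)$freq
    p[is.na(p)] <- 0.5
    p <- pmin(pmax(p, eps), 1 - eps)
    P <- matrix(p, 1, ncol(G))
    Q <- matrix(1, nrow(G), 1)
    ll <- .loglik_matrix(G, Q, P, eps)
    run <- list(Q = Q, P = P, loglik = ll, trace = ll, n_iter = 0L,
                converged = TRUE)
    return(.finish_fit(run, gm, K, "unsupervised", seed))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    Q0 <- .random_simplex(nrow(G), K)
    P0 <- matrix(runif(K * ncol(G), 0.05, 0.95), K, ncol(G))
    run <- .em_run(G, K, Q0, P0, tol = tol, max_iter = max_iter, eps = eps)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (!best$converged)
    warning("EM did not converge in ", max_iter, " iterations")
  .finish_fit(best, gm, K, "unsupervised", seed)
}

.finish_fit <- function(run, gm, K, mode, seed, label_order = NULL) {
  ord <- if (is.null(label_order)) order(colMeans(run$Q), decreasing = TRUE)
         else label_order
  run$Q <- run$Q[, ord, drop = FALSE]
  run$P <- run$P[ord, , drop = FALSE]
  rownames(run$Q) <- sample_ids(gm)
  colnames(run$P) <- gm$snps$id
  .new_admix_fit(run, K, mode, seed)
}

#' Supervised admixture fit with fixed proxy rows
#'
#' As [fit_unsupervised()], but the Q rows of designated proxy samples are
#' held fixed at the indicator vector of their assigned ancestry throughout
#' the optimization; all other Q rows and all of P are free.  Component order
#' follows the order of ancestry labels (factor levels of
#' `proxy_assignment`, or order of first appearance).
#'
#' @inheritParams fit_unsupervised
#' @param proxy_assignment named character vector: names are proxy sample
#'   ids (must be present in `gm`), values their ancestry labels.  Every
#'   ancestry must have at least one proxy; unequal panel sizes raise a
#'   warning.
#' @return an `admix_fit`; `$ancestries` holds the component labels
#' @export
fit_supervised <- function(gm, K = NULL, proxy_assignment, seed = 1,
                           n_restarts = 3, tol = 1e-7, max_iter = 2000,
                           eps = 1e-6) {
  ids <- names(proxy_assignment)
  if (is.null(ids))
    stop("proxy_assignment must be a named vector (sample id -> ancestry)")
  labels <- if (is.factor(proxy_assignment)) levels(droplevels(proxy_assignment))
            else unique(as.character(proxy_assignment))
  proxy_assignment <- setNames(as.character(proxy_assignment), ids)
  if (is.null(K)) K <- length(labels)
  if (length(labels) != K)
    stop("proxy_assignment defines ", length(labels), " ancestries but K=", K)
  counts <- table(factor(proxy_assignment, levels = labels))
  if (any(counts == 0)) stop("ancestry with zero proxies")
  if (length(unique(counts)) > 1)
    warning("proxy panel sizes are unequal: ",
            paste(labels, counts, sep = "=", collapse = ", "))
  rows <- match(names(proxy_assignment), sample_ids(gm))
  if (anyNA(rows)) stop("proxy samples not in genotype matrix")
  fixed_Q <- matrix(0, length(rows), K)
  fixed_Q[cbind(seq_along(rows), match(proxy_assignment, labels))] <- 1
  G <- gm$dosage
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    Q0 <- .random_simplex(nrow(G), K)
    Q0[rows, ] <- fixed_Q
    P0 <- matrix(runif(K * ncol(G), 0.05, 0.95), K, ncol(G))
    run <- .em_run(G, K, Q0, P0, fixed_rows = rows, fixed_Q = fixed_Q,
                   tol = tol, max_iter = max_iter, eps = eps)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (!best$converged)
    warning("EM did not converge in ", max_iter, " iterations")
  fit <- .finish_fit(best, gm, K, "supervised", seed,
                     label_order = seq_len(K))
  colnames(fit$Q) <- labels
  rownames(fit$P) <- labels
  fit$ancestries <- labels
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Component allele frequencies for fixed Q
#'
#' Per-SNP maximum-likelihood estimation of the K component frequencies with
#' the ancestry proportions held fixed, by per-locus EM (loci are
#' independent, so all SNPs iterate in parallel).  This extends a fit made on
#' one SNP set (e.g. an LD-pruned set) to arbitrary SNPs.
#'
#' @param gm a `geno_matrix`
#' @param Q samples x K ancestry proportions (rows on the simplex), rows
#'   matching `gm` samples
#' @param tol convergence on maximum absolute change in P (default 1e-6)
#' @param max_iter maximum iterations (default 1000)
#' @param eps frequency clamp (default 1e-6)
#' @return K x SNPs matrix of component A1 frequencies; columns for SNPs with
#'   all genotypes missing are `NA`
#' @export
component_freqs_given_Q <- function(gm, Q, tol = 1e-6, max_iter = 1000,
                                    eps = 1e-6) {
  G <- gm$dosage
  stopifnot(nrow(Q) == nrow(G))
  K <- ncol(Q)
  W <- !is.na(G)
  allmiss <- colSums(W) == 0
  G0 <- G; G0[!W] <- 0
  G2 <- 2 - G; G2[!W] <- 0
  p0 <- colSums(G0) / pmax(2 * colSums(W), 1)
  P <- matrix(rep(pmin(pmax(p0, eps), 1 - eps), each = K), K, ncol(G))
  for (it in seq_len(max_iter)) {
    F <- Q %*% P
    F[F < eps] <- eps
    F[F > 1 - eps] <- 1 - eps
    TQU <- crossprod(Q, G0 / F)
    TQV <- crossprod(Q, G2 / (1 - F))
    Pn <- (P * TQU) / (P * TQU + (1 - P) * TQV)
    Pn[!is.finite(Pn)] <- eps
    Pn[Pn < eps] <- eps
    Pn[Pn > 1 - eps] <- 1 - eps
    delta <- max(abs(Pn - P))
    P <- Pn
    if (delta < tol) break
  }
  P[, allmiss] <- NA_real_
  colnames(P) <- gm$snps$id
  P
}

#' Cross-validation over K by masked genotype entries
#'
#' Non-missing genotype cells are partitioned at random into `folds` folds.
#' For each K and fold, the fold's cells are masked (set missing), the model
#' refit, and the masked genotypes predicted as `2 * (Q P)`; the error is the
#' mean squared difference between observed genotype and prediction over
#' masked cells.  The K minimizing the mean error is the supported number of
#' ancestral components.
#'
#' @param gm a `geno_matrix`
#' @param K_range integer vector of K values to evaluate
#' @param folds number of folds (default 10)
#' @param seed integer seed controlling both fold assignment and fits
#' @param n_restarts restarts per fit (default 1; CV refits are numerous)
#' @param ... passed to [fit_unsupervised()] (`tol`, `max_iter`, ...)
#' @return list of class `cv_result`: `K_values`, `cv_error` (per-K mean
#'   masked-cell MSE), `folds`, `seed`, `best_K`
#' @export
cross_validate_K <- function(gm, K_range = 1:5, folds = 10, seed = 1,
                             n_restarts = 1, ...) {
  stopifnot(folds >= 2)
  G <- gm$dosage
  cells <- which(!is.na(G))
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(cells)))
  err <- matrix(NA_real_, length(K_range), folds)
  for (ki in seq_along(K_range)) {
    K <- K_range[ki]
    for (f in seq_len(folds)) {
      masked <- cells[fold_of == f]
      Gm <- G
      Gm[masked] <- NA
      gm_m <- gm
      gm_m$dosage <- Gm
      fit <- fit_unsupervised(gm_m, K, seed = seed + 1000L * f + K,
                              n_restarts = n_restarts, ...)
      pred <- 2 * (fit$Q %*% fit$P)
      err[ki, f] <- mean((G[masked] - pred[masked])^2)
    }
  }
  cv <- rowMeans(err)
  structure(list(K_values = K_range, cv_error = cv, folds = folds,
                 seed = seed, best_K = K_range[which.min(cv)],
                 fold_errors = err),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result (", x$folds, "folds ):\n")
  print(data.frame(K = x$K_values, cv_error = x$cv_error))
  cat("best K:", x$best_K, "\n")
  invisible(x)
}

#' Match estimated components to reference components
#'
#' Finds the permutation of the columns of `Q_est` minimizing the mean
#' absolute difference to `Q_ref` (labels in mixture models are arbitrary).
#'
#' @param Q_est,Q_ref samples x K ancestry matrices over the same samples
#' @return list: `perm` (column order for `Q_est`), `mae` (mean absolute
#'   error after matching)
#' @export
match_components <- function(Q_est, Q_ref) {
  K <- ncol(Q_ref)
  perms <- .permutations(K)
  maes <- vapply(seq_len(nrow(perms)), function(i)
    mean(abs(Q_est[, perms[i, ], drop = FALSE] - Q_ref)), numeric(1))
  best <- which.min(maes)
  list(perm = perms[best, ], mae = maes[best])
}

.permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(i) {
    cbind(i, matrix(setdiff(seq_len(K), i)[sub], nrow(sub), K - 1L))
  }))
}

#' Write Q and P matrices in ADMIXTURE-style layout
#'
#' `.Q`/`.P` files are whitespace-separated with no header (samples x K and
#' SNPs x K respectively); richer TSVs with headers are written alongside.
#'
#' @param fit an `admix_fit`
#' @param stem output path stem
#' @return `stem`, invisibly
#' @export
write_admixture <- function(fit, stem) {
  write.table(format(fit$Q, digits = 6), paste0(stem, ".Q"), sep = " ",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(format(t(fit$P), digits = 6), paste0(stem, ".P"), sep = " ",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  qt <- data.frame(sample_id = rownames(fit$Q), fit$Q, check.names = FALSE)
  write.table(qt, paste0(stem, ".Q.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pt <- data.frame(snp_id = colnames(fit$P), t(fit$P), check.names = FALSE)
  write.table(pt, paste0(stem, ".P.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(stem)
}
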