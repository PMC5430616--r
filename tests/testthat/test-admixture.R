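test_that("log-likelihood matches closed forms and is label-invariant", {
  gm <- make_gm(cbind(c(0, 1, 2), c(2, 2, 0)))
  # K = 1 with P at the observed frequencies equals the binomial closed form
  af <- allele_freq(gm)$freq
  Q1 <- matrix(1, 3, 1)
  P1 <- matrix(af, 1, 2)
  ll <- admix_loglik(gm, Q1, P1)
  closed <- sum(gm$dosage * log(rep(af, each = 3)) +
                (2 - gm$dosage) * log(rep(1 - af, each = 3)))
  expect_equal(ll, closed, tolerance = 1e-10)

  # one sample, one locus: g = 2 at mixture frequency 0.5 -> 2 ln 0.5
  gm1 <- make_gm(matrix(2, 1, 1))
  expect_equal(admix_loglik(gm1, matrix(c(0.5, 0.5), 1, 2),
                            matrix(c(0.3, 0.7), 2, 1)),
               2 * log(0.5), tolerance = 1e-12)

  # permuting component labels leaves the likelihood unchanged
  set.seed(1)
  Q <- matrix(rgamma(6, 1), 3, 2); Q <- Q / rowSums(Q)
  P <- matrix(runif(4, 0.1, 0.9), 2, 2)
  expect_equal(admix_loglik(gm, Q, P),
               admix_loglik(gm, Q[, 2:1], P[2:1, ]), tolerance = 1e-12)

  # truth beats a random parameter guess on simulated data
  sim <- two_pop_gm(n_per_pop = 30, m = 500, drift = 0.15, seed = 11)
  set.seed(2)
  Qr <- matrix(rgamma(120, 1), 60, 2); Qr <- Qr / rowSums(Qr)
  Pr <- matrix(runif(1000, 0.05, 0.95), 2, 500)
  Pc <- pmin(pmax(sim$P, 1e-6), 1 - 1e-6)
  expect_gt(admix_loglik(sim$gm, sim$Q, Pc),
            admix_loglik(sim$gm, Qr, Pr))
})

test_that("K=1 fit is the analytic optimum", {
  gm <- make_gm(cbind(c(0, 1, 2, 1), c(2, 2, 1, 2)))
  fit <- fit_unsupervised(gm, K = 1)
  expect_equal(unname(fit$Q[, 1]), rep(1, 4))
  expect_equal(unname(fit$P[1, ]), allele_freq(gm)$freq, tolerance = 1e-9)
})

test_that("EM keeps the likelihood non-decreasing and Q on the simplex", {
  sim <- two_pop_gm(n_per_pop = 25, m = 150, drift = 0.15, seed = 5)
  fit <- fit_unsupervised(sim$gm, K = 2, seed = 1, n_restarts = 1)
  expect_true(all(diff(fit$trace) >= -1e-6))
  expect_lt(max(abs(rowSums(fit$Q) - 1)), 1e-6)
  expect_true(all(fit$Q >= 0))
  expect_true(all(fit$P >= 1e-6 & fit$P <= 1 - 1e-6))
})

test_that("duplicated samples receive identical ancestry estimates", {
  sim <- two_pop_gm(n_per_pop = 15, m = 120, drift = 0.15, seed = 9,
                    n_admixed = 4, admix_q = 0.4)
  d <- sim$gm$dosage
  dup <- rbind(d, "x1_copy" = d["x1", ])
  gm <- geno_matrix(dup, sim$gm$snps)
  fit <- fit_unsupervised(gm, K = 2, seed = 3, n_restarts = 1)
  expect_equal(unname(fit$Q["x1", ]), unname(fit$Q["x1_copy", ]),
               tolerance = 1e-3)
})

test_that("unsupervised fit recovers the generating ancestry on spread cohorts", {
  # a cohort containing near-pure individuals (flat-ish Dirichlet) makes the
  # components identifiable without supervision
  spec <- cohort_spec(n_admixed = 300, n_snps = 2000, n_proxy_pool = 1,
                      dirichlet_alpha = 1.5 * c(0.57, 0.20, 0.23), seed = 7)
  st <- make_study(spec)
  gmc <- subset_geno(st$combined, samples = sample_ids(st$cohort))
  fit <- fit_unsupervised(gmc, K = 3, seed = 1, n_restarts = 1)
  m <- match_components(fit$Q, st$truth$Q[rownames(fit$Q), ])
  expect_lt(m$mae, 0.05)
})

test_that("supervised constraints hold exactly and all-proxy fits give panel frequencies", {
  sim <- two_pop_gm(n_per_pop = 10, m = 80, drift = 0.2, seed = 13)
  assign <- setNames(rep(c("A", "B"), each = 10), c(sim$pop1, sim$pop2))
  fit <- fit_supervised(sim$gm, proxy_assignment = assign, seed = 1,
                        n_restarts = 1)
  # proxy rows are exactly their indicator vectors
  expect_equal(unname(fit$Q[sim$pop1, "A"]), rep(1, 10))
  expect_equal(unname(fit$Q[sim$pop2, "A"]), rep(0, 10))
  # with every sample a proxy, P is the per-panel observed frequency
  pa <- allele_freq(sim$gm, sim$pop1)$freq
  pb <- allele_freq(sim$gm, sim$pop2)$freq
  expect_equal(unname(fit$P["A", ]), pmin(pmax(pa, 1e-6), 1 - 1e-6),
               tolerance = 1e-4)
  expect_equal(unname(fit$P["B", ]), pmin(pmax(pb, 1e-6), 1 - 1e-6),
               tolerance = 1e-4)
  # zero proxies for an ancestry is an error
  expect_error(fit_supervised(sim$gm, K = 3, proxy_assignment = assign),
               "K=3|zero")
})

test_that("component frequencies with fixed Q reduce to group frequencies and recover truth", {
  sim <- two_pop_gm(n_per_pop = 40, m = 100, drift = 0.2, seed = 17)
  # indicator Q: per-group observed frequencies
  P <- component_freqs_given_Q(sim$gm, sim$Q)
  pa <- allele_freq(sim$gm, sim$pop1)$freq
  expect_equal(unname(P[1, ]), pmin(pmax(pa, 1e-6), 1 - 1e-6),
               tolerance = 1e-5)
  # monomorphic zero column pins to the clamp
  gm0 <- make_gm(matrix(0, 4, 2))
  P0 <- component_freqs_given_Q(gm0, matrix(c(0.5, 0.5, 0.3, 0.7,
                                              0.6, 0.4, 0.2, 0.8), 4, 2,
                                            byrow = TRUE))
  expect_true(all(P0 <= 1e-5))
  # known P at held-out loci is recovered from admixed samples
  set.seed(21)
  n <- 500; m <- 300
  Q <- cbind(runif(n, 0.1, 0.9)); Q <- cbind(Q, 1 - Q)
  rownames(Q) <- paste0("s", 1:n)
  Ptrue <- rbind(runif(m, 0.05, 0.95), runif(m, 0.05, 0.95))
  gm <- sample_admixed_genotypes(Ptrue, Q, seed = 22)
  Pest <- component_freqs_given_Q(gm, Q)
  expect_lt(mean(abs(Pest - Ptrue)), 0.05)
})

test_that("masked-entry cross-validation is deterministic and matches binomial error at K=1", {
  set.seed(31)
  # homogeneous population: cv error at K=1 is about the binomial variance
  p <- runif(150, 0.2, 0.8)
  Q <- matrix(1, 80, 1); rownames(Q) <- paste0("s", 1:80)
  gm <- sample_admixed_genotypes(matrix(p, 1), Q, seed = 32)
  cv <- cross_validate_K(gm, K_range = 1, folds = 5, seed = 1)
  expect_equal(cv$cv_error, mean(2 * p * (1 - p)), tolerance = 0.05)
  cv2 <- cross_validate_K(gm, K_range = 1, folds = 5, seed = 1)
  expect_identical(cv$cv_error, cv2$cv_error)
})
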