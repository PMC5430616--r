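test_that("the branch scan reproduces the printed top-10 branch Fst column", {
  t4 <- table4_fixture()
  P <- rbind(eur = t4$f_eur, amr = t4$f_amr, afr = t4$f_afr)
  colnames(P) <- t4$id
  tab <- scan_lsbl(P, focal = "amr", snps = t4[, c("id", "chrom", "pos")])
  got <- tab$stat[match(t4$id, tab$id)]
  expect_equal(round(got, 3), t4$fst)
  # identical component frequencies give an all-zero scan
  P0 <- matrix(rep(runif(10), each = 3), 3)
  expect_true(all(scan_lsbl(P0)$stat == 0))
})

test_that("the pairwise scan reproduces the designated printed values", {
  t5 <- table5_fixture()
  tab <- scan_pairwise(setNames(t5$f_amr, t5$id), t5$f_beb,
                       snps = t5[, c("id", "chrom", "pos")])
  expect_equal(round(tab$stat[tab$id == "rs117487308"], 3), 0.786)
  expect_equal(round(tab$stat[tab$id == "rs4666032"], 3), 0.788)
  # component vs a European reference population at the strongest
  # Asian-comparison locus outside the shared region
  expect_equal(round(fst_param(0.878, 0.042), 3), 0.826)
  # identical frequency vectors scan to zero
  z <- scan_pairwise(t5$f_amr, t5$f_amr)
  expect_true(all(z$stat == 0))
})

test_that("ranks are a permutation with deterministic positional tie-breaks", {
  p <- c(a = 0.9, b = 0.1, c = 0.9, d = 0.5)
  snps <- data.frame(id = names(p), chrom = c("2", "1", "1", "1"),
                     pos = c(500L, 100L, 300L, 200L))
  tab <- scan_pairwise(p, rep(0, 4), snps = snps)
  expect_setequal(tab$rank, 1:4)
  # equal statistics order by (chromosome, position)
  expect_equal(tab$id[tab$rank == 1], "c")
  expect_equal(tab$id[tab$rank == 2], "a")
})

test_that("top-SNP region grouping matches the published region counts", {
  t4 <- table4_fixture()
  P4 <- rbind(t4$f_eur, t4$f_amr, t4$f_afr)
  tab4 <- scan_lsbl(P4, focal = 2, snps = t4[, c("id", "chrom", "pos")])
  expect_equal(nrow(top_regions(tab4, k = 10, merge_bp = 1e6)), 5L)

  t5 <- table5_fixture()
  tab5 <- scan_pairwise(setNames(t5$f_amr, t5$id), t5$f_beb,
                        snps = t5[, c("id", "chrom", "pos")])
  expect_equal(nrow(top_regions(tab5, k = 10, merge_bp = 1e6)), 8L)

  # k = 1 is a single one-SNP region
  r1 <- top_regions(tab4, k = 1)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$n_snps, 1L)
})

test_that("injected outlier loci dominate the scan ranking", {
  set.seed(6)
  spec <- cohort_spec(n_snps = 5000, n_admixed = 1, drift_F = 0.05, seed = 61)
  P <- sample_ancestral_freqs(spec)
  loci <- sample(which(attr(P, "p_anc") < 0.3), 20)
  P2 <- inject_differentiation(
    P, data.frame(locus = loci, ancestry = 2, freq = 0.9))
  colnames(P2) <- paste0("snp", seq_len(ncol(P2)))
  tab <- scan_lsbl(P2, focal = 2)
  hits <- sum(paste0("snp", loci) %in% tab$id[tab$rank <= 30])
  expect_gte(hits, 18)
})

test_that("Hotelling test is exact under equality and detects shifted means", {
  set.seed(41)
  Q <- cbind(runif(30, 0.2, 0.4), runif(30, 0.3, 0.5))
  Q <- cbind(Q, 1 - rowSums(Q))
  h0 <- hotelling_two_sample(Q, Q)
  expect_equal(h0$T2, 0)
  expect_equal(h0$p_value, 1)

  # cross-check the F conversion against R's own Hotelling-Lawley MANOVA
  Qa <- Q[1:15, 1:2]; Qb <- Q[16:30, 1:2] + 0.05
  ours <- hotelling_two_sample(Qa, Qb)
  g <- factor(rep(c("a", "b"), each = 15))
  man <- summary(stats::manova(rbind(Qa, Qb) ~ g),
                 test = "Hotelling-Lawley")$stats
  expect_equal(ours$F, unname(man[1, "approx F"]), tolerance = 1e-8)
  expect_equal(ours$p_value, unname(man[1, "Pr(>F)"]), tolerance = 1e-8)

  # power at the design scale: mean shift 0.10, sd 0.1, n = 100 per group
  alpha <- 0.05 / 15
  rej <- vapply(1:40, function(r) {
    set.seed(100 + r)
    A <- cbind(rnorm(100, 0.55, 0.1), rnorm(100, 0.20, 0.1))
    B <- cbind(rnorm(100, 0.55, 0.1), rnorm(100, 0.30, 0.1))
    hotelling_two_sample(A, B)$p_value < alpha
  }, logical(1))
  expect_gte(mean(rej), 0.95)

  # permuting group labels gives roughly uniform p-values
  pooled <- rbind(Qa, Qb - 0.05)
  pv <- vapply(1:60, function(r) {
    set.seed(r)
    idx <- sample(30, 15)
    hotelling_two_sample(pooled[idx, ], pooled[-idx, ])$p_value
  }, numeric(1))
  expect_gt(mean(pv > 0.5), 0.3)
  expect_gt(mean(pv < 0.5), 0.3)
})

test_that("TREEMIX counts reconstruct effective haploid sizes", {
  cnt <- treemix_counts(0.2, 0.5, 1538)
  expect_equal(unname(cnt[1, "a1"] + cnt[1, "a2"]), round(2 * 1538 * 0.2))
  expect_equal(unname(cnt[1, ]), c(a1 = 308L, a2 = 307L), ignore_attr = TRUE)
  expect_equal(unname(treemix_counts(0.2, 0, 1538)[1, "a1"]), 0L)
  expect_equal(unname(treemix_counts(0.2, 1, 1538)[1, "a2"]), 0L)
  # literal form collapses to at most 2 haploids
  lit <- treemix_counts(0.2, 0.5, 1538, literal = TRUE)
  expect_lte(lit[1, "a1"] + lit[1, "a2"], 2L)

  # round-trip through the gzipped export format
  counts <- list(popA = treemix_counts(0.2, c(0.1, 0.9), 100),
                 popB = treemix_counts(1.0, c(0.5, 0.5), 50))
  path <- write_treemix(counts, withr::local_tempfile(fileext = ".gz"))
  back <- readLines(gzfile(path))
  expect_equal(back[1], "popA popB")
  expect_equal(back[2], "4,36 50,50")
})
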