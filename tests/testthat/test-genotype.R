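test_that("allele frequencies use complete-case haploid counts", {
  gm <- make_gm(cbind(c(0, 1, 2), c(0, 0, 0), c(2, 2, NA)))
  af <- allele_freq(gm)
  expect_equal(af$freq, c(0.5, 0, 1))
  expect_equal(af$n, c(6L, 6L, 4L))
  # frequency of counting the other allele is the complement
  flipped <- gm
  flipped$dosage <- 2 - gm$dosage
  expect_equal(allele_freq(flipped)$freq, 1 - af$freq)
  # all-missing subset is flagged missing
  gm2 <- make_gm(rbind(c(NA, 0), c(NA, 1)))
  af2 <- allele_freq(gm2)
  expect_true(is.na(af2$freq[1]))
  expect_equal(af2$n[1], 0L)
})

test_that("call-rate and MAF filters keep exactly the qualifying SNPs", {
  # 6 SNPs over 100 samples with constructed call rates and MAFs
  set.seed(1)
  n <- 100
  cols <- list(
    ok1   = rep(c(0, 1), 50),            # cr 1.00, maf 0.25
    lowcr = c(rep(NA, 2), rep(1, 98)),   # cr 0.98
    ok2   = rep(c(0, 0, 0, 1), 25),      # maf 0.125
    lowmaf= c(rep(1, 4), rep(0, 96)),    # maf 0.02
    mono  = rep(0, n),                   # maf 0
    ok3   = rep(c(2, 0), 50))            # maf 0.5
  gm <- make_gm(do.call(cbind, cols))
  out <- filter_snps(gm, qc_thresholds(0.99, 0.05))
  expect_equal(out$snps$id, paste0("rs", c(1, 3, 6)))
  expect_equal(attr(out, "n_dropped"), 3L)
  # idempotent
  again <- filter_snps(out, qc_thresholds(0.99, 0.05))
  expect_equal(again$dosage, out$dosage)
  # null thresholds are the identity on complete data
  ident <- filter_snps(gm, qc_thresholds(0, 0))
  expect_equal(n_snps(ident), 6L)
})

test_that("pairwise r2 is composite LD on dosages", {
  gm <- make_gm(cbind(c(0, 1, 2, 0), c(0, 1, 2, 0), c(2, 1, 0, 2),
                      c(0, 2, 0, 2), c(0, 0, 2, 2), c(1, 1, 1, 1)))
  expect_equal(ld_r2(gm, 1, 2), 1)          # identical
  expect_equal(ld_r2(gm, 1, 3), 1)          # perfect anticorrelation squared
  expect_equal(ld_r2(gm, 4, 5), 0)          # orthogonal
  expect_true(is.na(ld_r2(gm, 1, 6)))       # zero variance
})

test_that("LD pruning leaves no within-window pair above the threshold", {
  # duplicates: exactly one survives
  gm <- make_gm(cbind(c(0, 1, 2, 0, 1), c(0, 1, 2, 0, 1)))
  expect_equal(ld_prune(gm, r2_max = 0.3), "rs1")

  # chain of 5 SNPs each perfectly correlated: one survives
  x <- c(0, 1, 2, 0, 2, 1)
  gm_chain <- make_gm(matrix(rep(x, 5), ncol = 5))
  expect_length(ld_prune(gm_chain, r2_max = 0.3), 1L)

  # independent simulated SNPs are all retained, and the pruned set is
  # exhaustively below threshold within every window
  set.seed(42)
  d <- matrix(rbinom(200 * 40, 2, 0.5), 200, 40)
  gm_ind <- make_gm(d)
  kept_ind <- ld_prune(gm_ind, r2_max = 0.3, window_snps = 10, step_snps = 2)
  expect_equal(length(kept_ind), 40L)
  sub <- subset_geno(gm_ind, snps = kept_ind)
  r2 <- suppressWarnings(cor(sub$dosage))^2
  diag(r2) <- 0
  expect_lt(max(r2), 0.3)
})

test_that("SNP intersection matches alleles, flips swapped dosages, drops ambiguous", {
  map_a <- data.frame(id = c("rs1", "rs2", "rs3", "rs4"), chrom = "1",
                      pos = c(100L, 200L, 300L, 400L), cM = NA_real_,
                      a1 = c("A", "C", "A", "A"), a2 = c("G", "T", "T", "G"))
  map_b <- map_a
  map_b$a1 <- c("A", "T", "A", "C")   # rs2 swapped, rs3 ambiguous A/T, rs4 irreconcilable
  map_b$a2 <- c("G", "C", "T", "T")
  da <- matrix(c(0, 1, 2, 2, 1, 0, 1, 1), 2, 4,
               dimnames = list(c("x", "y"), NULL))
  db <- matrix(c(0, 2, 2, 0, 1, 1, 0, 2), 2, 4,
               dimnames = list(c("u", "v"), NULL))
  expect_warning(out <- intersect_snps(geno_matrix(da, map_a),
                                       geno_matrix(db, map_b)),
                 "irreconcilable")
  expect_equal(out$a$snps$id, c("rs1", "rs2"))
  expect_equal(out$a$snps, out$b$snps)
  expect_equal(unname(out$b$dosage[, 2]), 2 - c(2, 0))  # flipped
  # identical maps are the identity up to the ambiguity rule (A/T rs3 drops)
  same <- intersect_snps(geno_matrix(da, map_a), geno_matrix(db, map_a))
  expect_equal(same$b$snps$id, c("rs1", "rs2", "rs4"))
  expect_equal(unname(same$b$dosage), unname(db[, c(1, 2, 4)]))
})

test_that("genotype IO round-trips dosages exactly in all three formats", {
  set.seed(3)
  d <- matrix(sample(c(0, 1, 2, NA), 60, replace = TRUE), 6, 10)
  rownames(d) <- paste0("ind", 1:6)
  map <- simple_map(10)
  map$a1 <- rep(c("A", "C"), 5); map$a2 <- rep(c("G", "T"), 5)
  gm <- geno_matrix(d, map)
  for (fmt in c("tsv", "plink-bed", "vcf")) {
    path <- file.path(withr::local_tempdir(), paste0("g.", fmt))
    write_genotypes(gm, path, fmt)
    back <- read_genotypes(path, fmt)
    expect_equal(back$dosage, gm$dosage, ignore_attr = TRUE,
                 label = paste("dosage via", fmt))
    expect_equal(back$snps$id, gm$snps$id)
    expect_equal(back$snps$pos, gm$snps$pos)
  }
})

test_that("triallelic VCF records are skipped with a warning", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "s1", "s2"), collapse = "\t"),
             "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
             "1\t200\tv2\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t1/2",
             "1\t300\tv3\tC\tT\t.\tPASS\t.\tGT\t1/1\t./.",
             "1\t400\tv4\tG\tA\t.\tPASS\t.\tGT\t0/1\t0/0",
             "1\t500\tv5\tT\tC\t.\tPASS\t.\tGT\t1/1\t0/1")
  writeLines(lines, tmp)
  expect_warning(gm <- read_genotypes(tmp, "vcf"), "multi-allelic")
  expect_equal(n_snps(gm), 4L)
  expect_equal(gm$snps$id, c("v1", "v3", "v4", "v5"))
  # A1 is REF: genotype 0/0 counts 2 copies
  expect_equal(unname(gm$dosage["s1", ]), c(2, 0, 1, 0))
  expect_true(is.na(gm$dosage["s2", "v3"]))
})

test_that("TSV fixture reads to the stated dosages", {
  dir <- withr::local_tempdir()
  writeLines(c("sample_id\tsnpA\tsnpB", "s1\t0\t2", "s2\t1\tNA", "s3\t2\t0"),
             file.path(dir, "g.tsv"))
  writeLines(c("id\tchrom\tpos\tcM\ta1\ta2",
               "snpA\t1\t100\tNA\tA\tG", "snpB\t2\t200\tNA\tC\tT"),
             file.path(dir, "g.map.tsv"))
  gm <- read_genotypes(file.path(dir, "g.tsv"), "tsv")
  expect_equal(dim(gm$dosage), c(3L, 2L))
  expect_equal(unname(gm$dosage[, "snpA"]), c(0, 1, 2))
  expect_equal(unname(gm$dosage[, "snpB"]), c(2, NA, 0))
})
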