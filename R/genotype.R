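#' Genotype matrix container
#'
#' A `geno_matrix` holds diploid biallelic genotypes as counts of the A1
#' (first/reference) allele: `0`, `1`, `2` or `NA` for missing.  Rows are
#' samples, columns SNPs.  The SNP map carries 1-based physical positions and
#' the two alleles, following BIM/VCF conventions.
#'
#' @param dosage integer or numeric matrix, samples x SNPs, entries in
#'   `{0, 1, 2, NA}`, counting copies of the A1 allele. Row names are sample
#'   ids; column names, if present, must equal `snps$id`.
#' @param snps data.frame with columns `id`, `chrom`, `pos` (1-based integer),
#'   `a1`, `a2`, and optionally `cM` (genetic map position).
#' @return An object of class `geno_matrix`: a list with elements `dosage`
#'   (matrix) and `snps` (data.frame).
#' @examples
#' gm <- geno_matrix(
#'   matrix(c(0, 1, 2, 2, NA, 0), nrow = 3,
#'          dimnames = list(c("s1", "s2", "s3"), NULL)),
#'   data.frame(id = c("rs1", "rs2"), chrom = c("1", "1"),
#'              pos = c(100L, 200L), a1 = c("A", "C"), a2 = c("G", "T")))
#' n_samples(gm); n_snps(gm)
#' @export
geno_matrix <- function(dosage, snps) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage))) {
    if (nrow(dosage) > 0)
      stop("dosage must have sample ids as row names")
    rownames(dosage) <- character(0)
  }
  if (anyDuplicated(rownames(dosage)))
    stop("duplicate sample ids")
  required <- c("id", "chrom", "pos", "a1", "a2")
  if (!all(required %in% names(snps)))
    stop("snps must have columns: ", paste(required, collapse = ", "))
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  snps$id <- as.character(snps$id)
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  if (!"cM" %in% names(snps)) snps$cM <- NA_real_
  if (ncol(dosage) != nrow(snps))
    stop("dosage has ", ncol(dosage), " columns but snp map has ",
         nrow(snps), " rows")
  if (anyDuplicated(snps$id)) stop("duplicate SNP ids")
  if (any(snps$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  if (any(snps$a1 == snps$a2)) stop("a1 and a2 must differ")
  bad <- !is.na(dosage) & !(dosage %in% c(0, 1, 2))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  colnames(dosage) <- snps$id
  structure(list(dosage = dosage, snps = snps), class = "geno_matrix")
}

#' @rdname geno_matrix
#' @param x,gm a `geno_matrix`
#' @export
n_samples <- function(gm) nrow(gm$dosage)

#' @rdname geno_matrix
#' @export
n_snps <- function(gm) ncol(gm$dosage)

#' @rdname geno_matrix
#' @export
sample_ids <- function(gm) rownames(gm$dosage)

#' @rdname geno_matrix
#' @param ... ignored
#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", n_samples(x), "samples x", n_snps(x), "SNPs\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param gm a `geno_matrix`
#' @param samples sample ids or indices to keep (default all)
#' @param snps SNP ids or indices to keep (default all)
#' @return a `geno_matrix` restricted to the requested samples/SNPs, in the
#'   requested order.
#' @export
subset_geno <- function(gm, samples = NULL, snps = NULL) {
  d <- gm$dosage
  map <- gm$snps
  if (!is.null(samples)) {
    if (is.character(samples)) {
      missing <- setdiff(samples, rownames(d))
      if (length(missing))
        stop("unknown sample ids: ", paste(head(missing, 5), collapse = ", "))
    }
    d <- d[samples, , drop = FALSE]
  }
  if (!is.null(snps)) {
    idx <- if (is.character(snps)) match(snps, map$id) else snps
    if (anyNA(idx)) stop("unknown SNP ids")
    d <- d[, idx, drop = FALSE]
    map <- map[idx, , drop = FALSE]
    rownames(map) <- NULL
  }
  geno_matrix(d, map)
}

#' QC thresholds
#'
#' Defaults follow the usual array-QC convention for admixture work:
#' drop SNPs with call rate below 99% or minor allele frequency below 5%.
#'
#' @param call_rate_min minimum per-SNP call rate, in `[0, 1]`
#' @param maf_min minimum minor allele frequency, in `[0, 0.5]`
#' @return a list of class `qc_thresholds`
#' @export
qc_thresholds <- function(call_rate_min = 0.99, maf_min = 0.05) {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 0.5)
  structure(list(call_rate_min = call_rate_min, maf_min = maf_min),
            class = "qc_thresholds")
}

#' Per-SNP A1 allele frequency
#'
#' Computes, over a sample subset, the frequency of the A1 allele and the
#' haploid sample count, with complete-case handling of missing genotypes:
#' `freq = sum(dosage) / (2 * n_nonmissing)`, `n = 2 * n_nonmissing`.
#' SNPs with no non-missing genotype in the subset get `NA` frequency and
#' `n = 0`.
#'
#' @param gm a `geno_matrix`
#' @param samples sample ids (default: all samples)
#' @return data.frame with columns `id`, `freq`, `n`
#' @examples
#' gm <- geno_matrix(matrix(c(0, 1, 2), 3, 1,
#'                          dimnames = list(paste0("s", 1:3), NULL)),
#'                   data.frame(id = "rs1", chrom = "1", pos = 1L,
#'                              a1 = "A", a2 = "G"))
#' allele_freq(gm)  # freq 0.5, n 6
#' @export
allele_freq <- function(gm, samples = NULL) {
  d <- gm$dosage
  if (!is.null(samples)) {
    if (length(samples) == 0) stop("sample subset is empty")
    d <- d[samples, , drop = FALSE]
  }
  nonmiss <- colSums(!is.na(d))
  freq <- ifelse(nonmiss > 0, colSums(d, na.rm = TRUE) / (2 * nonmiss), NA_real_)
  data.frame(id = gm$snps$id, freq = freq, n = 2L * nonmiss,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter SNPs on call rate and MAF
#'
#' Retains SNPs whose call rate is at least `thr$call_rate_min` and whose
#' minor allele frequency is at least `thr$maf_min`.  Idempotent.
#'
#' @param gm a `geno_matrix`
#' @param thr a [qc_thresholds()] object
#' @return the filtered `geno_matrix`, with attributes `n_retained` and
#'   `n_dropped`
#' @export
filter_snps <- function(gm, thr = qc_thresholds()) {
  d <- gm$dosage
  call_rate <- colMeans(!is.na(d))
  af <- allele_freq(gm)$freq
  maf <- pmin(af, 1 - af)
  keep <- call_rate >= thr$call_rate_min & !is.na(maf) & maf >= thr$maf_min
  out <- subset_geno(gm, snps = which(keep))
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Composite LD between two SNPs
#'
#' Squared Pearson correlation of dosage vectors over pairwise-complete
#' samples (composite LD; phase is not used).  Undefined (returns `NA`) when
#' either SNP has zero dosage variance among the complete pairs.
#'
#' @param gm a `geno_matrix`
#' @param snp_i,snp_j SNP ids or column indices
#' @return r-squared in `[0, 1]`, or `NA`
#' @export
ld_r2 <- function(gm, snp_i, snp_j) {
  i <- if (is.character(snp_i)) match(snp_i, gm$snps$id) else snp_i
  j <- if (is.character(snp_j)) match(snp_j, gm$snps$id) else snp_j
  x <- gm$dosage[, i]
  y <- gm$dosage[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) stop("fewer than 2 pairwise-complete samples")
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

# r2 matrix for a block of SNP columns (pairwise-complete), NA on zero variance
.r2_block <- function(d) {
  r <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))
  r * r
}

#' Greedy sliding-window LD pruning
#'
#' Slides a window of `window_snps` SNPs along the map (sorted by chromosome,
#' then position) advancing by `step_snps`.  Within each window, while any
#' retained pair has r-squared above `r2_max`, the member of the worst
#' offending pair with the lower MAF is dropped (ties: the later SNP in map
#' order).  The result never contains a within-window pair exceeding
#' `r2_max`.
#'
#' @param gm a `geno_matrix` with SNPs sorted by (chromosome, position)
#' @param r2_max retain threshold on pairwise r-squared (default 0.3)
#' @param window_snps window width in SNPs (default 50)
#' @param step_snps window advance in SNPs (default 5)
#' @return character vector of retained SNP ids, in map order
#' @export
ld_prune <- function(gm, r2_max = 0.3, window_snps = 50, step_snps = 5) {
  map <- gm$snps
  ord <- order(map$chrom, map$pos)
  if (!identical(ord, seq_len(nrow(map))))
    stop("SNPs must be sorted by (chromosome, position); reorder with subset_geno")
  af <- allele_freq(gm)$freq
  maf <- pmin(af, 1 - af)
  keep <- rep(TRUE, n_snps(gm))
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    start <- 1L
    repeat {
      win <- idx[seq.int(start, min(start + window_snps - 1L, length(idx)))]
      act <- win[keep[win]]
      if (length(act) >= 2) {
        r2 <- .r2_block(gm$dosage[, act, drop = FALSE])
        diag(r2) <- 0
        repeat {
          w <- which(r2 > r2_max, arr.ind = TRUE)
          if (nrow(w) == 0) break
          # worst offending pair
          top <- w[which.max(r2[w]), ]
          a <- act[top[1]]; b <- act[top[2]]
          drop <- if (maf[a] < maf[b]) a
                  else if (maf[b] < maf[a]) b
                  else max(a, b)        # tie: later map order
          k <- match(drop, act)
          keep[drop] <- FALSE
          r2[k, ] <- 0; r2[, k] <- 0
        }
      }
      if (start + window_snps - 1L >= length(idx)) break
      start <- start + step_snps
    }
  }
  map$id[keep]
}

#' Intersect two genotype matrices on shared SNPs
#'
#' Matches SNPs on id plus allele pair (order-insensitive).  When A1/A2 are
#' swapped between the two matrices, the second matrix's dosages are flipped
#' (`d -> 2 - d`) and its alleles relabelled so both outputs share an
#' identical SNP map.  Strand-ambiguous A/T and C/G SNPs are dropped, as are
#' SNPs whose allele pairs cannot be reconciled (with a warning).
#'
#' @param gm_a,gm_b `geno_matrix` objects
#' @return list with elements `a` and `b`, both on the shared map (order of
#'   `gm_a`)
#' @export
intersect_snps <- function(gm_a, gm_b) {
  ma <- gm_a$snps; mb <- gm_b$snps
  shared <- intersect(ma$id, mb$id)
  ia <- match(shared, ma$id); ib <- match(shared, mb$id)
  a1a <- ma$a1[ia]; a2a <- ma$a2[ia]
  a1b <- mb$a1[ib]; a2b <- mb$a2[ib]
  ambiguous <- (pmin(a1a, a2a) == "A" & pmax(a1a, a2a) == "T") |
               (pmin(a1a, a2a) == "C" & pmax(a1a, a2a) == "G")
  same <- a1a == a1b & a2a == a2b
  flipped <- a1a == a2b & a2a == a1b
  irreconcilable <- !same & !flipped
  if (any(irreconcilable))
    warning(sum(irreconcilable), " SNP(s) dropped: allele pairs irreconcilable")
  keep <- !ambiguous & !irreconcilable
  ia <- ia[keep]; ib <- ib[keep]; flipped <- flipped[keep]
  da <- gm_a$dosage[, ia, drop = FALSE]
  db <- gm_b$dosage[, ib, drop = FALSE]
  db[, flipped] <- 2 - db[, flipped]
  map <- ma[ia, , drop = FALSE]
  rownames(map) <- NULL
  list(a = geno_matrix(da, map), b = geno_matrix(db, map))
}
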