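#' Locus-specific branch-length scan over component frequencies
#'
#' For each SNP, computes the three parameter-form pairwise Hudson Fst values
#' among the K=3 component allele frequencies, then the branch length of the
#' focal component ([lsbl()]), and ranks SNPs by descending statistic (ties
#' broken by chromosome, then position).  This scans for loci whose focal
#' ancestry has differentiated most from a hypothetical single ancestral
#' population of all components.
#'
#' @param P 3 x SNPs matrix of component A1 frequencies (rows in component
#'   order; row names are component labels)
#' @param focal index (or row name) of the focal component
#' @param snps optional SNP map data.frame (`id`, `chrom`, `pos`) matching
#'   the columns of `P`; required for region grouping and tie-breaking
#' @param statistic `"lsbl"` (default) or `"pbs"`
#' @return data.frame of class `diff_table`, one row per scored SNP:
#'   ids/map columns, the component frequencies, the three pairwise Fst
#'   values, `stat`, and `rank`.  Attribute `summary` holds the mean, median
#'   and 75th percentile of the statistic.
#' @export
scan_lsbl <- function(P, focal = 2, snps = NULL, statistic = c("lsbl", "pbs")) {
  statistic <- match.arg(statistic)
  stopifnot(nrow(P) == 3)
  if (is.character(focal)) focal <- match(focal, rownames(P))
  others <- setdiff(1:3, focal)
  labs <- rownames(P) %||% paste0("K", 1:3)
  f12 <- fst_param(P[others[1], ], P[focal, ])   # other1 vs focal
  f23 <- fst_param(P[focal, ], P[others[2], ])   # focal vs other2
  f13 <- fst_param(P[others[1], ], P[others[2], ])
  stat <- if (statistic == "lsbl") lsbl(f12, f23, f13) else pbs(f12, f23, f13)
  tab <- data.frame(id = colnames(P) %||% as.character(seq_len(ncol(P))),
                    stringsAsFactors = FALSE)
  if (!is.null(snps)) {
    stopifnot(nrow(snps) == ncol(P))
    tab$id <- snps$id
    tab$chrom <- as.character(snps$chrom)
    tab$pos <- snps$pos
  }
  freq <- t(P)
  colnames(freq) <- paste0("f_", labs)
  tab <- cbind(tab, freq)
  tab$fst_12 <- f12; tab$fst_23 <- f23; tab$fst_13 <- f13
  tab$stat <- stat
  tab <- .rank_table(tab)
  attr(tab, "summary") <- c(mean = mean(stat, na.rm = TRUE),
                            median = median(stat, na.rm = TRUE),
                            p75 = unname(quantile(stat, 0.75, na.rm = TRUE)))
  attr(tab, "statistic") <- statistic
  class(tab) <- c("diff_table", "data.frame")
  tab
}

.rank_table <- function(tab) {
  o <- if (!is.null(tab$chrom))
    order(-tab$stat, tab$chrom, tab$pos)
  else order(-tab$stat)
  tab$rank <- NA_integer_
  tab$rank[o] <- seq_len(nrow(tab))
  tab[o, , drop = FALSE]
}

#' Pairwise differentiation scan
#'
#' Per-SNP pairwise Hudson Fst between a focal set of frequencies (e.g. an
#' admixture component) and a comparison population, ranked descending.  In
#' `mode = "param"` the parameter form is used ([fst_param()]); in
#' `mode = "sample"` the sample-corrected form ([fst_sample()]), which
#' requires haploid counts and can go negative.
#'
#' @param p_focal numeric vector of focal A1 frequencies
#' @param p_comp comparison-population A1 frequencies (same SNP order)
#' @param mode `"param"` or `"sample"`
#' @param n_focal,n_comp haploid counts (scalars or vectors), required for
#'   `mode = "sample"`.  For an admixture component of a cohort of N samples
#'   with mean focal ancestry `q_bar`, the documented default effective count
#'   is `2 * N * q_bar` (supply it explicitly).
#' @param snps optional SNP map (`id`, `chrom`, `pos`)
#' @return a `diff_table` (see [scan_lsbl()]) with columns `f_focal`,
#'   `f_comp`, `stat`, `rank`
#' @export
scan_pairwise <- function(p_focal, p_comp, mode = c("param", "sample"),
                          n_focal = NULL, n_comp = NULL, snps = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(p_focal) == length(p_comp))
  stat <- if (mode == "param") {
    fst_param(p_focal, p_comp)
  } else {
    if (is.null(n_focal) || is.null(n_comp))
      stop("mode='sample' needs haploid counts n_focal and n_comp")
    fst_sample(p_focal, n_focal, p_comp, n_comp)$fst
  }
  tab <- data.frame(id = names(p_focal) %||% as.character(seq_along(p_focal)),
                    stringsAsFactors = FALSE)
  if (!is.null(snps)) {
    stopifnot(nrow(snps) == length(p_focal))
    tab$id <- snps$id
    tab$chrom <- as.character(snps$chrom)
    tab$pos <- snps$pos
  }
  tab$f_focal <- p_focal
  tab$f_comp <- p_comp
  tab$stat <- stat
  tab <- .rank_table(tab)
  attr(tab, "statistic") <- paste0("pairwise_", mode)
  class(tab) <- c("diff_table", "data.frame")
  tab
}

#' Group top-ranked SNPs into genome regions
#'
#' Takes the `k` top-ranked SNPs of a scan and groups, per chromosome, SNPs
#' whose position is within `merge_bp` of the nearest member of the growing
#' group (single linkage).
#'
#' @param table a ranked `diff_table` with `chrom` and `pos` columns
#' @param k number of top SNPs to group (default 10)
#' @param merge_bp single-linkage merge distance in bp (default 1e6)
#' @return data.frame with one row per region: `region`, `chrom`, `start`,
#'   `end`, `n_snps`, `max_stat`, `top_snp`, `snps` (comma-separated ids),
#'   ordered by the best rank within the region
#' @export
top_regions <- function(table, k = 10, merge_bp = 1e6) {
  stopifnot(!is.null(table$chrom), !is.null(table$pos))
  top <- table[order(table$rank), , drop = FALSE][seq_len(min(k, nrow(table))), ]
  regions <- list()
  for (chr in unique(top$chrom)) {
    sub <- top[top$chrom == chr, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    gap <- c(Inf, diff(sub$pos))
    grp <- cumsum(gap > merge_bp)
    for (g in unique(grp)) regions[[length(regions) + 1L]] <- sub[grp == g, ]
  }
  out <- do.call(rbind, lapply(regions, function(r) {
    data.frame(chrom = r$chrom[1], start = min(r$pos), end = max(r$pos),
               n_snps = nrow(r), max_stat = max(r$stat),
               top_snp = r$id[which.max(r$stat)],
               snps = paste(r$id, collapse = ","),
               best_rank = min(r$rank), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$best_rank), , drop = FALSE]
  out$region <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("region", "chrom", "start", "end", "n_snps", "max_stat",
          "top_snp", "snps")]
}

#' Write a region report as BED and TSV
#'
#' BED uses 0-based half-open intervals; the TSV mirrors the full region
#' table.
#'
#' @param regions output of [top_regions()]
#' @param stem output path stem (writes `<stem>.bed` and `<stem>.tsv`)
#' @return `stem`, invisibly
#' @export
write_regions <- function(regions, stem) {
  bed <- data.frame(regions$chrom, regions$start - 1L, regions$end,
                    paste0("region_", regions$region))
  write.table(bed, paste0(stem, ".bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(regions, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(stem)
}

#' Two-sample Hotelling T-squared test on two ancestry components
#'
#' Classical two-sample Hotelling test of equality of mean vectors on a
#' chosen pair of ancestry components (with K=3 the third is determined by
#' the simplex constraint, so a bivariate test uses all the information).
#' `F = T2 * (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p)` with `p = 2`.
#'
#' @param Q_a,Q_b ancestry-proportion matrices for the two groups (samples x
#'   K, same column order)
#' @param components pair of column indices to test (default `c(1, 2)`)
#' @return list: `T2`, `F`, `df` (numerator, denominator), `p_value`
#' @export
hotelling_two_sample <- function(Q_a, Q_b, components = c(1, 2)) {
  stopifnot(length(components) == 2)
  Xa <- as.matrix(Q_a[, components, drop = FALSE])
  Xb <- as.matrix(Q_b[, components, drop = FALSE])
  n1 <- nrow(Xa); n2 <- nrow(Xb); p <- 2L
  if (n1 < 3 || n2 < 3) stop("each group needs at least 3 samples")
  d <- colMeans(Xa) - colMeans(Xb)
  S <- ((n1 - 1) * var(Xa) + (n2 - 1) * var(Xb)) / (n1 + n2 - 2)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("pooled covariance is singular; choose other components"))
  T2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% Sinv %*% d)
  Fstat <- T2 * (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p)
  df <- c(p, n1 + n2 - p - 1)
  pv <- pf(Fstat, df[1], df[2], lower.tail = FALSE)
  list(T2 = T2, F = Fstat, df = df, p_value = pv)
}

#' TREEMIX-style allele counts for an admixture component
#'
#' Converts a component allele frequency into integer biallelic counts with
#' an effective haploid sample size reflecting how much of the cohort the
#' component represents: `H = round(2 * n_samples * q_bar)`, A1 count
#' `round(H * p)`, A2 count `H - A1`.  With `literal = TRUE` the effective
#' size omits the cohort size (`H = round(2 * q_bar)`), which collapses the
#' counts to at most 2 and is retained only for comparability.
#'
#' @param q_bar mean focal admixture proportion, in `(0, 1]`
#' @param p per-SNP component A1 frequency (vector)
#' @param n_samples number of cohort samples
#' @param literal use the cohort-free effective size (default FALSE)
#' @return integer matrix with columns `a1`, `a2`
#' @export
treemix_counts <- function(q_bar, p, n_samples, literal = FALSE) {
  stopifnot(q_bar > 0, q_bar <= 1, all(p >= 0 & p <= 1))
  H <- if (literal) round(2 * q_bar) else round(2 * n_samples * q_bar)
  a1 <- as.integer(round(H * p))
  cbind(a1 = a1, a2 = as.integer(H) - a1)
}

#' Export population allele counts in TREEMIX format
#'
#' Standard TREEMIX input: a gzipped, space-separated file with a header of
#' population names and one `a1,a2` count pair per population per SNP row.
#'
#' @param counts named list of integer matrices with columns `a1`, `a2` (one
#'   per population, equal row counts)
#' @param path output path (`.gz` appended if absent)
#' @return the path written, invisibly
#' @export
write_treemix <- function(counts, path) {
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  m <- nrow(counts[[1]])
  stopifnot(all(vapply(counts, nrow, integer(1)) == m))
  cols <- lapply(counts, function(x) paste0(x[, "a1"], ",", x[, "a2"]))
  lines <- c(paste(names(counts), collapse = " "),
             do.call(paste, c(cols, sep = " ")))
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a differentiation table as TSV
#'
#' @param table a `diff_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_diff_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
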