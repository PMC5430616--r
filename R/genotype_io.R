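#' Read genotypes from PLINK BED, VCF, or TSV
#'
#' All formats are returned as a [geno_matrix()] whose dosages count the A1
#' allele.  Conventions per format:
#' \describe{
#'   \item{`tsv`}{header row `sample_id<TAB>snp1<TAB>...`, dosages 0/1/2/NA;
#'     SNP map read from the sidecar `<path>.map.tsv` (columns
#'     `id chrom pos a1 a2`, optionally `cM`).}
#'   \item{`plink-bed`}{binary bed v1.00, SNP-major, with `.bim`/`.fam`
#'     companions; `path` may omit the `.bed` extension.  A1 is the first
#'     (bim column 5) allele, as in PLINK.}
#'   \item{`vcf`}{VCF v4.x, GT field only; A1 is the REF allele, so `0/0`
#'     reads as dosage 2.  Multi-allelic records are skipped with a warning.}
#' }
#'
#' @param path input file path
#' @param format one of `"tsv"`, `"plink-bed"`, `"vcf"`
#' @return a `geno_matrix`
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, format = c("tsv", "plink-bed", "vcf")) {
  format <- match.arg(format)
  switch(format,
         "tsv" = .read_tsv(path),
         "plink-bed" = .read_plink(path),
         "vcf" = .read_vcf(path))
}

#' Write genotypes to PLINK BED, VCF, or TSV
#'
#' Inverse of [read_genotypes()]; round-trips are dosage-exact for all three
#' formats.
#'
#' @param gm a `geno_matrix`
#' @param path output path (for `plink-bed`, the stem or `.bed` path)
#' @param format one of `"tsv"`, `"plink-bed"`, `"vcf"`
#' @return `path`, invisibly
#' @export
write_genotypes <- function(gm, path, format = c("tsv", "plink-bed", "vcf")) {
  format <- match.arg(format)
  switch(format,
         "tsv" = .write_tsv(gm, path),
         "plink-bed" = .write_plink(gm, path),
         "vcf" = .write_vcf(gm, path))
  invisible(path)
}

.map_sidecar <- function(path) paste0(sub("\\.tsv$", "", path), ".map.tsv")

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id")
    stop("malformed TSV (", path, "): first column must be 'sample_id'")
  d <- as.matrix(tab[, -1, drop = FALSE])
  rownames(d) <- tab$sample_id
  mp <- .map_sidecar(path)
  if (!file.exists(mp)) stop("SNP map sidecar not found: ", mp)
  map <- read.table(mp, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!identical(map$id, colnames(d)))
    stop("structural error: SNP ids in ", mp, " do not match genotype columns")
  geno_matrix(d, map)
}

.write_tsv <- function(gm, path) {
  tab <- data.frame(sample_id = sample_ids(gm), gm$dosage,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  map <- gm$snps[, c("id", "chrom", "pos", "cM", "a1", "a2")]
  write.table(map, .map_sidecar(path), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

# ---- PLINK bed v1.00, SNP-major ---------------------------------------------
# 2-bit codes per sample: 00 = A1/A1 (dosage 2), 10 = het (1),
# 11 = A2/A2 (0), 01 = missing.

.plink_paths <- function(path) {
  stem <- sub("\\.bed$", "", path)
  list(bed = paste0(stem, ".bed"), bim = paste0(stem, ".bim"),
       fam = paste0(stem, ".fam"))
}

.read_plink <- function(path) {
  p <- .plink_paths(path)
  for (f in unlist(p)) if (!file.exists(f)) stop("file not found: ", f)
  fam <- read.table(p$fam, stringsAsFactors = FALSE)
  bim <- read.table(p$bim, stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cM", "pos", "a1", "a2"))
  n <- nrow(fam); m <- nrow(bim)
  bpv <- ceiling(n / 4)
  raw <- readBin(p$bed, "raw", n = 3 + m * bpv)
  if (length(raw) < 3 + m * bpv)
    stop("structural error: ", p$bed, " shorter than implied by .bim/.fam")
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("malformed file: ", p$bed, " lacks the bed v1.00 SNP-major magic")
  body <- as.integer(raw[-(1:3)])
  # decode all 4 two-bit fields of every byte at once
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)
  lookup <- c(2, NA, 1, 0)  # code 0,1,2,3 -> dosage
  d <- matrix(lookup[codes + 1L], nrow = 4L * bpv)[seq_len(n), , drop = FALSE]
  rownames(d) <- make.unique(as.character(fam$V2))
  map <- data.frame(id = bim$id, chrom = as.character(bim$chrom),
                    pos = bim$pos, cM = bim$cM, a1 = bim$a1, a2 = bim$a2,
                    stringsAsFactors = FALSE)
  geno_matrix(d, map)
}

.write_plink <- function(gm, path) {
  p <- .plink_paths(path)
  n <- n_samples(gm); m <- n_snps(gm)
  fam <- data.frame(sample_ids(gm), sample_ids(gm), 0L, 0L, 0L, -9L)
  write.table(fam, p$fam, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(gm$snps$chrom, gm$snps$id,
                    ifelse(is.na(gm$snps$cM), 0, gm$snps$cM),
                    gm$snps$pos, gm$snps$a1, gm$snps$a2)
  write.table(bim, p$bim, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bpv <- ceiling(n / 4)
  code <- matrix(1L, nrow = 4L * bpv, ncol = m)  # pad + missing = 01
  enc <- c(3L, 2L, 0L)  # dosage 0,1,2 -> code
  dc <- gm$dosage
  code[seq_len(n), ] <- ifelse(is.na(dc), 1L, enc[dc + 1L])
  c1 <- code[seq(1, 4L * bpv, by = 4), , drop = FALSE]
  c2 <- code[seq(2, 4L * bpv, by = 4), , drop = FALSE]
  c3 <- code[seq(3, 4L * bpv, by = 4), , drop = FALSE]
  c4 <- code[seq(4, 4L * bpv, by = 4), , drop = FALSE]
  byte <- c1 + 4L * c2 + 16L * c3 + 64L * c4
  con <- file(p$bed, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(byte)), con)
}

# ---- VCF (GT only) ----------------------------------------------------------

.read_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  if (any(multi))
    warning(sum(multi), " multi-allelic record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  # count REF (A1) alleles in the GT string
  gt[is.na(gt)] <- "./."
  ref_count <- function(s) {
    a <- strsplit(gsub("|", "/", s, fixed = TRUE), "/", fixed = TRUE)
    vapply(a, function(x) {
      if (any(x == ".")) NA_real_ else sum(x == "0")
    }, numeric(1))
  }
  d <- matrix(ref_count(as.vector(gt)), nrow = nrow(fix))
  d <- t(d)
  rownames(d) <- colnames(gt)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  map <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                    cM = NA_real_, a1 = fix$REF, a2 = fix$ALT,
                    stringsAsFactors = FALSE)
  geno_matrix(d, map)
}

.write_vcf <- function(gm, path) {
  gt_code <- c("1/1", "0/1", "0/0")  # dosage 0,1,2 of the REF (A1) allele
  d <- gm$dosage
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_code[d[ok] + 1]
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_ids(gm)), collapse = "\t"))
  body <- vapply(seq_len(n_snps(gm)), function(j) {
    paste(c(gm$snps$chrom[j], gm$snps$pos[j], gm$snps$id[j], gm$snps$a1[j],
            gm$snps$a2[j], ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
}
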