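# shared fixture builders; everything is generated in code

simple_map <- function(m, chrom = "1", a1 = "A", a2 = "G") {
  data.frame(id = paste0("rs", seq_len(m)), chrom = chrom,
             pos = 1000L * seq_len(m), cM = NA_real_,
             a1 = a1, a2 = a2, stringsAsFactors = FALSE)
}

make_gm <- function(dosage, map = NULL, ...) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("s", seq_len(nrow(dosage)))
  geno_matrix(dosage, map %||% simple_map(ncol(dosage), ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two drifted populations, n diploid samples each, plus optional admixed
two_pop_gm <- function(n_per_pop = 50, m = 200, drift = 0.1, seed = 1,
                       n_admixed = 0, admix_q = 0.5) {
  set.seed(seed)
  p_anc <- runif(m, 0.1, 0.9)
  p1 <- rbeta(m, p_anc * (1 - drift) / drift, (1 - p_anc) * (1 - drift) / drift)
  p2 <- rbeta(m, p_anc * (1 - drift) / drift, (1 - p_anc) * (1 - drift) / drift)
  Q <- rbind(cbind(rep(1, n_per_pop), 0), cbind(0, rep(1, n_per_pop)))
  if (n_admixed > 0)
    Q <- rbind(Q, cbind(rep(admix_q, n_admixed), 1 - admix_q))
  rownames(Q) <- c(paste0("a", seq_len(n_per_pop)),
                   paste0("b", seq_len(n_per_pop)),
                   if (n_admixed > 0) paste0("x", seq_len(n_admixed)))
  P <- rbind(p1, p2)
  gm <- sample_admixed_genotypes(P, Q, seed = seed + 1)
  list(gm = gm, Q = Q, P = P, p_anc = p_anc,
       pop1 = paste0("a", seq_len(n_per_pop)),
       pop2 = paste0("b", seq_len(n_per_pop)))
}

# printed frequency triplets and branch Fst of the top-10 Amerindian-branch
# scan (f_eur, f_amr, f_afr, fst), with map positions
table4_fixture <- function() {
  tab <- read.table(header = TRUE, text = "
id chrom pos f_eur f_amr f_afr fst
rs6498115  16 10965511 0.000 0.908 0.000 0.908
rs1834619   2 17901485 0.041 0.942 0.000 0.899
rs77979769 16 11343560 0.073 0.949 0.035 0.883
rs2288697   2 23860168 0.029 0.906 0.018 0.877
rs35346036 16 10951098 0.065 0.957 0.088 0.872
rs2021760  16 11343992 0.076 0.947 0.065 0.869
rs45601437 16 10989754 0.006 0.912 0.050 0.862
rs2866065  16 75822042 0.075 0.929 0.000 0.849
rs8054781  16 11384776 0.026 0.932 0.092 0.846
rs16964480 15 37284909 0.000 0.837 0.000 0.837")
  tab$chrom <- as.character(tab$chrom)
  tab
}

# printed focal/comparison frequency pairs of the top-10 Asian-comparison
# scan (f_amr vs f_beb), with map positions
table5_fixture <- function() {
  tab <- read.table(header = TRUE, text = "
id chrom pos f_amr f_beb fst
rs7631391    3  64514393 0.950 0.058 0.885
rs77594147   5 169155975 0.878 0.017 0.857
rs73318286   5 169162708 0.879 0.029 0.843
rs28649017  15  85438991 0.150 0.983 0.827
rs7151991   14  32635572 0.950 0.116 0.821
rs45601437  16  10989754 0.912 0.081 0.816
rs6498115   16  10965511 0.908 0.081 0.811
rs6088519   20  33132191 0.966 0.163 0.791
rs4666032    2  28254769 0.827 0.029 0.788
rs117487308 22  41195082 0.786 0.000 0.786")
  tab$chrom <- as.character(tab$chrom)
  tab
}
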