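# Small in-code fixtures shared across test files.

# genotype_matrix from a bare dosage matrix with autogenerated metadata
tiny_gm <- function(dos, a1 = NULL, a2 = NULL) {
  dos <- as.matrix(dos)
  d <- ncol(dos)
  if (is.null(a1)) a1 <- rep("A", d)
  if (is.null(a2)) a2 <- rep("G", d)
  genotype_matrix(dos,
                  data.frame(id = paste0("v", seq_len(d)), chrom = "1",
                             pos = 100L * seq_len(d), a1 = a1, a2 = a2,
                             stringsAsFactors = FALSE),
                  paste0("s", seq_len(nrow(dos))))
}

# hand-written PLINK fileset; `bytes` are the payload bytes after the header
write_raw_bed <- function(dir, bytes, n, d, mode_byte = 0x01,
                          magic = c(0x6c, 0x1b)) {
  prefix <- file.path(dir, "raw")
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(magic, mode_byte, bytes)), con)
  close(con)
  writeLines(sprintf("1\tv%d\t0\t%d\tA\tG", seq_len(d), 100L * seq_len(d)),
             paste0(prefix, ".bim"))
  writeLines(sprintf("s%d s%d 0 0 0 -9", seq_len(n), seq_len(n)),
             paste0(prefix, ".fam"))
  prefix
}

# covariate-free matrix of the right row count
no_covars <- function(n) matrix(numeric(0), nrow = n, ncol = 0)

# the standard parameter-recovery configuration: 10 causal variants
# (3 recessive, 2 dominant, 5 additive), h2 = 0.5, 30% prevalence
recovery_cfg <- function(seed, n_samples = 2000L, n_variants = 500L) {
  sim_config(n_samples = n_samples, n_variants = n_variants, n_causal = 10L,
             h2_liability = 0.5, dominance_fraction = 0.5,
             mode_weights = c(dominant = 0.4, recessive = 0.6,
                              overdominant = 0, overrecessive = 0),
             prevalence = 0.3, seed = seed)
}

# validation pseudo-R2 of a fresh fit on an 80/20 split of a cohort
holdout_r2 <- function(sim, kind, gamma = 0.1, iterations = 100L,
                       seed = 1L) {
  sp <- make_split(sim$G$samples, k = 5, test_fraction = 0.2, seed = seed)
  tr <- unlist(sp$folds)
  va <- sp$test_ids
  G_tr <- subset_samples(sim$G, tr)
  G_va <- subset_samples(sim$G, va)
  ph_tr <- sim$pheno[match(tr, sim$pheno$sample_id), , drop = FALSE]
  ph_va <- sim$pheno[match(va, sim$pheno$sample_id), , drop = FALSE]
  fit <- boost_fit(G_tr, ph_tr,
                   boost_params(gamma = gamma, iterations = iterations), kind)
  pgs <- predict_genetic_score(fit, G_va)
  Xe <- no_covars(nrow(ph_va))
  pseudo_r2(ph_va$y, pgs, Xe, y_fit = ph_va$y, pgs_fit = pgs, X_fit = Xe)
}
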