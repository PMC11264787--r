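# miR-eQTL scan: residualization with genotype PCs, per-SNP regression,
# cis/trans labelling, LD clumping.

make_geno <- function(n, snps, mafs, chr = NULL, pos = NULL) {
  D <- sapply(mafs, function(m) rbinom(n, 2, m))
  colnames(D) <- snps
  rownames(D) <- paste0("s", seq_len(n))
  list(dosages = D,
       variants = data.frame(snp = snps, chr = chr %||% 1L,
                             pos = pos %||% (1e5 * seq_along(snps))),
       mirna_loci = data.frame(mirna = "miR-1", chr = 1L, pos = 1.5e5))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("genotype PCs: residuals vanish for PC-aligned expression, determinism", {
  set.seed(50)
  n <- 200
  geno <- make_geno(n, paste0("rs", 1:50), runif(50, 0.1, 0.5))
  pcs <- genotype_pcs(geno$dosages)
  expect_equal(ncol(pcs), 10)
  expr <- matrix(pcs[, 1], 1, n, dimnames = list("miR-1", rownames(geno$dosages)))
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  r <- residualize_for_eqtl(expr, covs, geno$dosages)
  expect_lt(max(abs(r)), 1e-10)
  # identical across runs (fixed sign convention)
  expect_identical(genotype_pcs(geno$dosages), genotype_pcs(geno$dosages))

  # no structure: residuals close to centered input
  e2 <- matrix(rnorm(n), 1, n, dimnames = list("miR-1", rownames(geno$dosages)))
  r2 <- residualize_for_eqtl(e2, covs, geno$dosages)
  expect_gt(cor(r2[1, ], e2[1, ] - mean(e2[1, ])), 0.9)
  expect_warning(genotype_pcs(geno$dosages[1:8, ]), "PCs")
})

test_that("scan: beta identity, cis boundary, monomorphic skip", {
  set.seed(51)
  n <- 300
  geno <- make_geno(n, c("rs1", "rs2", "rs3"), c(0.3, 0.4, 0.2),
                    chr = c(1L, 1L, 2L),
                    pos = c(1150000L, 3000000L, 150000L))
  geno$dosages[, "rs3"] <- 1L                      # monomorphic
  y <- 0.8 * geno$dosages[, "rs1"] + rnorm(n)
  resid <- matrix(y - mean(y), 1, n,
                  dimnames = list("miR-1", rownames(geno$dosages)))
  hits <- eqtl_scan(geno, resid, alpha = 1e-4)
  expect_true("rs1" %in% hits$snp)
  expect_false("rs3" %in% hits$snp)
  # rs1 at distance exactly 1 Mb from the miRNA locus: cis (inclusive)
  expect_equal(hits$type[hits$snp == "rs1"], "cis")

  # beta/se/p equal a simple lm fit
  fit <- summary(lm(resid[1, ] ~ geno$dosages[, "rs1"]))$coefficients
  expect_equal(hits$beta[hits$snp == "rs1"], fit[2, 1], tolerance = 1e-10)
  expect_equal(hits$se[hits$snp == "rs1"], fit[2, 2], tolerance = 1e-10)
  expect_equal(hits$p[hits$snp == "rs1"], fit[2, 4], tolerance = 1e-10)

  # trans label beyond the window
  y2 <- 0.8 * geno$dosages[, "rs2"] + rnorm(n)
  resid2 <- matrix(y2 - mean(y2), 1, n, dimnames = dimnames(resid))
  hits2 <- eqtl_scan(geno, resid2, alpha = 1e-4)
  expect_equal(hits2$type[hits2$snp == "rs2"], "trans")

  bad <- geno; rownames(bad$dosages) <- paste0("x", seq_len(n))
  expect_error(eqtl_scan(bad, resid), "shared")
})

test_that("cis/trans labels are invariant to variant ordering", {
  set.seed(52)
  n <- 200
  geno <- make_geno(n, paste0("rs", 1:6), rep(0.3, 6),
                    chr = c(1L, 1L, 1L, 2L, 2L, 1L),
                    pos = c(1e5, 2e5, 5e6, 1e5, 9e6, 1.4e5))
  y <- rowSums(geno$dosages[, 1:2]) + rnorm(n, sd = 0.5)
  resid <- matrix(y - mean(y), 1, n,
                  dimnames = list("miR-1", rownames(geno$dosages)))
  h1 <- eqtl_scan(geno, resid, alpha = 0.01)
  perm <- c(4, 2, 6, 1, 5, 3)
  geno2 <- list(dosages = geno$dosages[, perm],
                variants = geno$variants[perm, ],
                mirna_loci = geno$mirna_loci)
  h2 <- eqtl_scan(geno2, resid, alpha = 0.01)
  m <- merge(h1, h2, by = "snp")
  expect_true(all(m$type.x == m$type.y))
})

test_that("planted cis-eQTL is recovered genome-wide at n = 2000", {
  recovered <- vapply(1:10, function(s) {
    co <- quiet(simulate_cohort(sim_spec(
      n_samples = 2000, n_mirna = 30, module_sizes = c(8, 6),
      gene_spec = list(n_genes = 10, n_targeted = 5, coupling = -0.3,
                       cell_beta = c(ery = 0.1, leu = 0.15, plt = 0.05)),
      genotype_spec = list(n_snps = 400, maf_range = c(0.1, 0.5),
                           block_size = 5, copy_prob = 0.9,
                           eqtl = list(snp = 3, mirna = 1, beta = 0.5,
                                       maf = 0.3)),
      seed = s)))
    ex <- residualize(normalize_counts(quiet(filter_features(co$mirna_counts))),
                      data.frame(batch = factor(co$samples$batch)))
    covs <- data.frame(age = co$samples$age, sex = co$samples$sex,
                       batch = factor(co$samples$batch))
    resid <- residualize_for_eqtl(ex["miR-001", , drop = FALSE], covs,
                                  co$genotypes$dosages)
    hits <- eqtl_scan(co$genotypes, resid, alpha = 5e-8)
    any(hits$snp == "rs00003" & hits$mirna == "miR-001")
  }, logical(1))
  expect_gte(mean(recovered), 0.9)
})

test_that("clumping: trivial cases and exhaustive-closure oracle", {
  set.seed(53)
  n <- 400
  # single hit
  geno1 <- make_geno(n, "rs1", 0.3)
  h1 <- data.frame(snp = "rs1", mirna = "miR-1", beta = 1, se = 0.1, p = 1e-10,
                   type = "cis")
  l1 <- clump_loci(h1, geno1)
  expect_equal(nrow(l1), 1)
  expect_equal(l1$top_lead, "rs1")
  expect_equal(l1$lead_snps, "rs1")

  # perfect LD pair: one locus, one lead
  D <- rbinom(n, 2, 0.3)
  geno2 <- list(dosages = cbind(rs1 = D, rs2 = D),
                variants = data.frame(snp = c("rs1", "rs2"), chr = 1L,
                                      pos = c(1e5, 2e5)),
                mirna_loci = data.frame(mirna = "miR-1", chr = 1L, pos = 1e5))
  rownames(geno2$dosages) <- paste0("s", 1:n)
  h2 <- data.frame(snp = c("rs1", "rs2"), mirna = "miR-1", beta = 1,
                   se = 0.1, p = c(1e-12, 1e-10), type = "cis")
  l2 <- clump_loci(h2, geno2)
  expect_equal(nrow(l2), 1)
  expect_equal(l2$n_snps, 2)
  expect_equal(l2$lead_snps, "rs1")

  # 8-SNP constructed LD vs exhaustive transitive closure
  base <- rbinom(n, 2, 0.4)
  mk <- function(r) ifelse(runif(n) < r, base, rbinom(n, 2, 0.4))
  D8 <- cbind(s1 = base, s2 = mk(0.95), s3 = mk(0.9), s4 = rbinom(n, 2, 0.3),
              s5 = mk(0.92), s6 = rbinom(n, 2, 0.2), s7 = mk(0.05),
              s8 = rbinom(n, 2, 0.45))
  rownames(D8) <- paste0("s", 1:n)
  geno8 <- list(dosages = D8,
                variants = data.frame(snp = colnames(D8), chr = 1L,
                                      pos = 1e5 * (1:8)),
                mirna_loci = data.frame(mirna = "miR-1", chr = 1L, pos = 1e5))
  h8 <- data.frame(snp = colnames(D8), mirna = "miR-1", beta = 1, se = 0.1,
                   p = c(1e-20, 1e-12, 1e-11, 1e-15, 1e-9, 1e-8, 1e-13, 1e-10),
                   type = "cis")
  l8 <- clump_loci(h8, geno8)
  r2 <- cor(D8)^2
  oracle <- clump_oracle(h8$p, r2, geno8$variants$pos, geno8$variants$chr)
  got <- integer(8); names(got) <- colnames(D8)
  for (i in seq_len(nrow(l8)))
    got[strsplit(l8$members[i], ";")[[1]]] <- l8$locus[i]
  # same partition up to label permutation
  expect_equal(length(unique(got)), length(unique(oracle)))
  expect_true(all(tapply(oracle, got, function(v) length(unique(v))) == 1))

  # partition property: every hit in exactly one locus
  expect_setequal(unlist(strsplit(l8$members, ";")), colnames(D8))
  # leads pairwise r2 < 0.1
  for (i in seq_len(nrow(l8))) {
    leads <- strsplit(l8$lead_snps[i], ";")[[1]]
    if (length(leads) > 1) {
      rl <- r2[leads, leads]
      expect_true(all(rl[upper.tri(rl)] < 0.1))
    }
  }
})

test_that("null genome yields no genome-wide hits", {
  set.seed(54)
  clean <- vapply(1:5, function(i) {
    n <- 500
    geno <- make_geno(n, paste0("rs", 1:200), runif(200, 0.1, 0.5))
    resid <- matrix(rnorm(3 * n), 3, n,
                    dimnames = list(paste0("m", 1:3), rownames(geno$dosages)))
    geno$mirna_loci <- data.frame(mirna = paste0("m", 1:3), chr = 2L,
                                  pos = 1e5 * (1:3))
    nrow(eqtl_scan(geno, resid, alpha = 5e-8)) == 0
  }, logical(1))
  expect_gte(mean(clean), 0.95)
})
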