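# Synthetic cohort generator: negative-binomial miRNA/gene counts with
# planted co-expression modules, vascular traits coupled to module factors
# with age/sex confounding, genes negatively coupled to targeting miRNAs
# with blood-cell confounding, and genotypes with LD blocks and planted
# cis-eQTLs. Every planted quantity is returned as ground truth so each
# downstream stage has a recoverable target; the ground truth is never
# consumed by analysis code.

#' Simulation specification
#'
#' Defaults describe a compact population cohort: 500 participants aged
#' 30-95, 200 miRNAs of which 140 fall into six planted modules (sizes
#' 40..10) and 60 are unassigned noise features, factor loadings 0.8 with
#' feature noise sd 0.6, negative-binomial counts (dispersion 0.1) with
#' per-sample library-size factors in \[0.7, 1.4\] and three sequencing
#' batches (shift sd 0.3). Module-trait couplings use standardized betas in
#' the 0.03-0.08 range; targeted genes couple to their miRNA at -0.3; one
#' cis-eQTL (beta 0.5, MAF 0.3) is planted on the first miRNA.
#'
#' @param n_samples,n_mirna cohort and miRNA panel size.
#' @param module_sizes integer vector of planted module sizes (each >= 2,
#'   sum <= n_mirna; the remainder is unassigned).
#' @param loading_range factor-loading range (uniform per feature).
#' @param factor_cor correlation between module factors, default 0.
#' @param noise_sd per-feature latent noise sd.
#' @param nb_dispersion negative-binomial dispersion (1/size), constant
#'   across features.
#' @param base_logmean_range natural-log range of per-feature baseline mean
#'   counts (default log 30 to log 800).
#' @param lib_range per-sample library-size factor range.
#' @param n_batch,batch_sd sequencing batches and per-feature batch shift sd.
#' @param trait_spec named list of module-trait couplings; each element
#'   `list(module =, beta =)` for traits `taci`, `si`, `pwv`, `rsh`; plus
#'   `wmh = list(module =, c_prime =, b_taci =)` for the mediation triple.
#' @param gene_spec `list(n_genes =, n_targeted =, coupling =, cell_beta =)`.
#' @param genotype_spec `list(n_snps =, maf_range =, block_size =,
#'   copy_prob =, eqtl = list(snp =, mirna =, beta =, maf =))`; `eqtl` may be
#'   NULL for a null genome.
#' @param seed global seed; every component draws from a named sub-stream.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_samples = 500, n_mirna = 200,
                     module_sizes = c(40, 30, 25, 20, 15, 10),
                     loading_range = c(0.8, 0.8), factor_cor = 0,
                     noise_sd = 0.6, nb_dispersion = 0.1,
                     base_logmean_range = log(c(30, 800)),
                     lib_range = c(0.7, 1.4),
                     n_batch = 3, batch_sd = 0.3,
                     trait_spec = list(
                       taci = list(module = 1, beta = -0.05),
                       si = list(module = 4, beta = 0.04),
                       pwv = list(module = 2, beta = 0.05),
                       rsh = list(module = 3, beta = 0.05),
                       wmh = list(module = 1, c_prime = 0.05, b_taci = -0.25)
                     ),
                     gene_spec = list(n_genes = 300, n_targeted = 150,
                                      coupling = -0.3,
                                      cell_beta = c(ery = 0.1, leu = 0.15,
                                                    plt = 0.05)),
                     genotype_spec = list(n_snps = 400,
                                          maf_range = c(0.05, 0.5),
                                          block_size = 10, copy_prob = 0.9,
                                          eqtl = list(snp = 5, mirna = 1,
                                                      beta = 0.5, maf = 0.3)),
                     seed = 1) {
  if (any(module_sizes < 2)) stop_mv("module sizes must be >= 2")
  if (sum(module_sizes) > n_mirna)
    stop_mv("sum of module sizes exceeds n_mirna")
  gs <- genotype_spec
  if (!is.null(gs)) {
    if (any(gs$maf_range <= 0 | gs$maf_range > 0.5))
      stop_mv("MAFs must lie in (0, 0.5]")
    if (!is.null(gs$eqtl)) {
      if (gs$eqtl$mirna > n_mirna)
        stop_mv("planted eQTL targets nonexistent miRNA %d", gs$eqtl$mirna)
      if (gs$eqtl$snp > gs$n_snps)
        stop_mv("planted eQTL on nonexistent SNP %d", gs$eqtl$snp)
    }
  }
  if (!is.null(gene_spec) && gene_spec$coupling >= 0)
    stop_mv("target coupling must be strictly negative")
  # couplings to modules beyond the planted count become uncoupled (NA)
  for (nm in names(trait_spec)) {
    if (!is.null(trait_spec[[nm]]$module) &&
        !is.na(trait_spec[[nm]]$module) &&
        trait_spec[[nm]]$module > length(module_sizes))
      trait_spec[[nm]]$module <- NA_integer_
  }
  if (!is.null(trait_spec$wmh) && is.na(trait_spec$wmh$module))
    trait_spec$wmh <- NULL
  spec <- as.list(environment())
  spec$gs <- NULL
  class(spec) <- "sim_spec"
  spec
}

mirna_ids <- function(n) sprintf("miR-%03d", seq_len(n))
gene_ids <- function(n) sprintf("GENE%04d", seq_len(n))
sample_ids <- function(n) sprintf("S%04d", seq_len(n))

#' Simulate genotype dosages with LD blocks and a planted cis-eQTL
#'
#' Two haplotypes per individual; within an LD block each successive SNP
#' copies the previous SNP's allele with probability `copy_prob` and is
#' otherwise redrawn at its own allele frequency (copy-with-mutation), so
#' adjacent-SNP LD rises with `copy_prob` (r2 = 1 at copy probability 1).
#' Variant positions tile chromosome 1; miRNA loci place the eQTL target
#' within the cis window of its SNP and all other miRNAs on chromosome 2.
#'
#' @param spec a [sim_spec()].
#' @return list: `dosages` (samples x SNPs, 0/1/2), `variants`
#'   (snp, chr, pos, maf), `mirna_loci` (mirna, chr, pos).
#' @export
simulate_genotypes <- function(spec) {
  gs <- spec$genotype_spec
  if (is.null(gs)) stop_mv("spec has no genotype_spec")
  n <- spec$n_samples
  m <- gs$n_snps
  with_seed(substream_seed(spec$seed, "genotypes"), {
    maf <- stats::runif(m, gs$maf_range[1], gs$maf_range[2])
    if (!is.null(gs$eqtl)) maf[gs$eqtl$snp] <- gs$eqtl$maf
    block <- (seq_len(m) - 1) %/% gs$block_size
    hap <- function() {
      h <- matrix(0L, n, m)
      for (j in seq_len(m)) {
        fresh <- stats::rbinom(n, 1, maf[j])
        if (j > 1 && block[j] == block[j - 1]) {
          cp <- stats::rbinom(n, 1, gs$copy_prob)
          h[, j] <- ifelse(cp == 1, h[, j - 1], fresh)
        } else h[, j] <- fresh
      }
      h
    }
    D <- hap() + hap()
    dimnames(D) <- list(sample_ids(n), sprintf("rs%05d", seq_len(m)))
    variants <- data.frame(snp = colnames(D), chr = 1L,
                           pos = 50000L * seq_len(m), maf = maf,
                           stringsAsFactors = FALSE)
    loci <- data.frame(mirna = mirna_ids(spec$n_mirna), chr = 2L,
                       pos = 100000L * seq_len(spec$n_mirna),
                       stringsAsFactors = FALSE)
    if (!is.null(gs$eqtl)) {
      loci$chr[gs$eqtl$mirna] <- 1L
      loci$pos[gs$eqtl$mirna] <- variants$pos[gs$eqtl$snp] + 10000L
    }
    list(dosages = D, variants = variants, mirna_loci = loci)
  })
}

#' Simulate the full synthetic cohort
#'
#' Generates genotypes, module factors (with age/sex confounding), latent
#' miRNA expression (factor loadings + planted eQTL + noise), negative
#' binomial miRNA and gene counts with batch shifts and library-size
#' offsets, raw vascular measurements whose derived traits carry the planted
#' module couplings, blood-cell counts confounding gene expression, and the
#' ground-truth record.
#'
#' @param spec a [sim_spec()].
#' @return list with `mirna_counts`, `gene_counts` (features x samples
#'   integer matrices), `samples` (per-sample phenotype/covariate table),
#'   `genotypes`, `predictions` (predicted miRNA-target table including the
#'   true pairs plus decoys), and `truth` (module labels, trait betas,
#'   mediation paths, eQTL, target pairs, latent matrices, library factors).
#' @export
simulate_cohort <- function(spec = sim_spec()) {
  n <- spec$n_samples
  p <- spec$n_mirna
  ids <- mirna_ids(p)
  sid <- sample_ids(n)
  geno <- if (!is.null(spec$genotype_spec)) simulate_genotypes(spec) else NULL

  # --- demographics and batches -------------------------------------------
  demo <- with_seed(substream_seed(spec$seed, "samples"), {
    age <- 30 + 65 * stats::rbeta(n, 1.5, 2.5)
    sex <- stats::rbinom(n, 1, 0.458)
    height <- ifelse(sex == 1, stats::rnorm(n, 178, 7), stats::rnorm(n, 165, 6.5))
    bmi <- pmax(16, stats::rnorm(n, 26, 4))
    list(age = age, sex = sex, height = height,
         weight = bmi * (height / 100)^2,
         batch = sample(rep_len(seq_len(spec$n_batch), n)),
         ery = stats::rnorm(n, 4.69, 0.43),
         leu = pmax(1.5, stats::rnorm(n, 5.68, 1.54)),
         plt = pmax(80, stats::rnorm(n, 238, 54)),
         lib_mirna = stats::runif(n, spec$lib_range[1], spec$lib_range[2]),
         lib_gene = stats::runif(n, spec$lib_range[1], spec$lib_range[2]))
  })
  z_age <- (demo$age - mean(demo$age)) / stats::sd(demo$age)

  # --- module factors and latent miRNA expression -------------------------
  M <- length(spec$module_sizes)
  labels <- rep(0L, p)
  idx <- 1
  for (m in seq_len(M)) {
    labels[idx:(idx + spec$module_sizes[m] - 1)] <- m
    idx <- idx + spec$module_sizes[m]
  }
  names(labels) <- ids
  lat <- with_seed(substream_seed(spec$seed, "latent"), {
    Fm <- matrix(stats::rnorm(n * M), n, M)
    if (spec$factor_cor != 0 && M > 1) {
      common <- stats::rnorm(n)
      Fm <- sqrt(spec$factor_cor) * common +
        sqrt(1 - spec$factor_cor) * Fm
    }
    # age/sex confounding into expression (small, so "adjust for age and
    # sex" is exercised downstream)
    Fm <- Fm + 0.1 * z_age + 0.05 * demo$sex
    load <- stats::runif(p, spec$loading_range[1], spec$loading_range[2])
    Z <- matrix(stats::rnorm(n * p, sd = max(spec$noise_sd, 0)), n, p)
    for (f in seq_len(p)) {
      if (labels[f] > 0) {
        Z[, f] <- load[f] * Fm[, labels[f]] + Z[, f]
      } else {
        Z[, f] <- stats::rnorm(n)           # unassigned: unit noise
      }
    }
    if (!is.null(geno) && !is.null(spec$genotype_spec$eqtl)) {
      e <- spec$genotype_spec$eqtl
      d <- geno$dosages[, e$snp]
      Z[, e$mirna] <- Z[, e$mirna] + e$beta * (d - mean(d))
    }
    dimnames(Z) <- list(sid, ids)
    list(Z = Z, Fm = Fm, load = load)
  })

  # --- counts --------------------------------------------------------------
  mirna_counts <- with_seed(substream_seed(spec$seed, "counts_mirna"), {
    nb_counts(t(lat$Z), demo$lib_mirna, demo$batch, spec)
  })

  # --- traits (raw measurements carrying the planted couplings) ------------
  ts <- spec$trait_spec
  tr <- with_seed(substream_seed(spec$seed, "traits"), {
    fac <- function(sp) if (is.null(sp) || is.na(sp$module)) 0 else
      sp$beta * lat$Fm[, sp$module]
    t_taci <- fac(ts$taci) - 0.30 * z_age - 0.05 * demo$sex +
      stats::rnorm(n, sd = 0.95)
    t_si <- fac(ts$si) - 0.25 * z_age + 0.10 * demo$sex +
      stats::rnorm(n, sd = 0.95)
    t_pwv <- fac(ts$pwv) + 0.55 * z_age + 0.05 * demo$sex +
      stats::rnorm(n, sd = 0.80)
    t_rsh <- fac(ts$rsh) - 0.25 * z_age + stats::rnorm(n, sd = 0.95)
    bsa <- bsa_du_bois(demo$height, demo$weight)
    si <- 51.83 + 8.51 * t_si
    sv <- si * bsa
    taci <- pmax(0.35, 1.04 + 0.25 * t_taci)
    pp <- sv / (taci * bsa)
    dbp <- pmax(50, stats::rnorm(n, 76.2, 8))
    sbp <- dbp + pmax(20, pp)
    hr <- pmax(40, stats::rnorm(n, 68, 10))
    pwv <- exp(log(6.2) + 0.35 * t_pwv)
    distance <- stats::rnorm(n, 0.6, 0.04)
    rsh <- exp(log(5.7) + 0.15 * t_rsh)
    flux_base <- exp(stats::rnorm(n, log(10), 0.3))
    lb <- -5.7 + 0.8 * z_age + 0.3 * demo$sex +
      (if (is.null(ts$wmh)) 0 else
        ts$wmh$c_prime * lat$Fm[, ts$wmh$module] + ts$wmh$b_taci * t_taci) +
      stats::rnorm(n, sd = 0.7)
    burden <- stats::plogis(lb)
    wm_vol <- pmax(300, stats::rnorm(n, 480, 40))
    list(sv = sv, sbp = sbp, dbp = dbp, hr = hr,
         distance = distance, transit_time = distance / pwv,
         flux_base = flux_base, flux_plateau = flux_base * (1 + rsh / 100),
         wmh_vol = burden * wm_vol, wm_vol = wm_vol, t_taci = t_taci)
  })

  samples <- data.frame(
    sample_id = sid, age = demo$age, sex = demo$sex, batch = demo$batch,
    height = demo$height, weight = demo$weight,
    sbp = tr$sbp, dbp = tr$dbp, sv = tr$sv, hr = tr$hr,
    distance = tr$distance, transit_time = tr$transit_time,
    flux_base = tr$flux_base, flux_plateau = tr$flux_plateau,
    wmh_vol = tr$wmh_vol, wm_vol = tr$wm_vol,
    ery = demo$ery, leu = demo$leu, plt = demo$plt,
    stringsAsFactors = FALSE
  )

  # --- genes with negative couplings to targeting miRNAs ------------------
  gsp <- spec$gene_spec
  gene <- with_seed(substream_seed(spec$seed, "genes"), {
    ng <- gsp$n_genes
    gid <- gene_ids(ng)
    target <- rep(NA_integer_, ng)
    assigned <- sample(which(labels > 0), gsp$n_targeted, replace = TRUE)
    target[seq_len(gsp$n_targeted)] <- assigned
    cb <- gsp$cell_beta
    conf <- cb["ery"] * zscore(demo$ery) + cb["leu"] * zscore(demo$leu) +
      cb["plt"] * zscore(demo$plt)
    G <- matrix(stats::rnorm(n * ng), n, ng)
    for (g in seq_len(ng)) {
      if (!is.na(target[g]))
        G[, g] <- gsp$coupling * zscore(lat$Z[, target[g]]) + conf + G[, g]
    }
    dimnames(G) <- list(sid, gid)
    counts <- with_seed(substream_seed(spec$seed, "counts_gene"),
                        nb_counts(t(G), demo$lib_gene, demo$batch, spec))
    list(counts = counts, target = target, gid = gid, latent = G)
  })

  # predicted-target table: the true pairs plus an equal number of decoys
  predictions <- with_seed(substream_seed(spec$seed, "predictions"), {
    true_idx <- which(!is.na(gene$target))
    true_pairs <- data.frame(mirna = ids[gene$target[true_idx]],
                             gene = gene$gid[true_idx],
                             source = "planted", stringsAsFactors = FALSE)
    null_gene <- gene$gid[is.na(gene$target)]
    decoys <- data.frame(
      mirna = sample(ids[labels > 0], length(null_gene), replace = TRUE),
      gene = null_gene, source = "decoy", stringsAsFactors = FALSE)
    rbind(true_pairs, decoys)
  })

  # term annotation: three designated terms enriched in true target genes
  # plus random background terms
  term_sets <- with_seed(substream_seed(spec$seed, "terms"), {
    gid <- gene$gid
    tgt <- gid[!is.na(gene$target)]
    nontgt <- setdiff(gid, tgt)
    sets <- list()
    for (k in 1:3) {
      sets[[sprintf("TERM_TARGET_%d", k)]] <-
        unique(c(sample(tgt, ceiling(0.4 * length(tgt))),
                 sample(nontgt, 5)))
    }
    for (k in 1:17) {
      sets[[sprintf("TERM_RANDOM_%02d", k)]] <-
        sample(gid, min(30, length(gid)))
    }
    sets
  })

  truth <- list(
    labels = labels,
    loadings = stats::setNames(lat$load, ids),
    trait_betas = data.frame(
      trait = c("taci", "si", "pwv", "rsh"),
      module = vapply(ts[c("taci", "si", "pwv", "rsh")],
                      function(s) as.integer(s$module), integer(1)),
      beta = vapply(ts[c("taci", "si", "pwv", "rsh")],
                    function(s) s$beta, numeric(1)),
      stringsAsFactors = FALSE),
    mediation = if (is.null(ts$wmh)) NULL else list(
      exposure = paste0("module", ts$wmh$module), mediator = "taci",
      outcome = "wmh_burden", a = ts$taci$beta, b = ts$wmh$b_taci,
      c_prime = ts$wmh$c_prime),
    eqtl = spec$genotype_spec$eqtl,
    target_pairs = data.frame(
      mirna = ids[gene$target[!is.na(gene$target)]],
      gene = gene$gid[!is.na(gene$target)], stringsAsFactors = FALSE),
    lib_factors = list(mirna = demo$lib_mirna, gene = demo$lib_gene)
  )

  list(mirna_counts = mirna_counts, gene_counts = gene$counts,
       samples = samples, genotypes = geno, predictions = predictions,
       term_sets = term_sets,
       truth = c(truth, list(latent_mirna = t(lat$Z), factors = lat$Fm,
                             latent_gene = t(gene$latent))))
}

# Negative-binomial counts from a latent (features x samples) log-expression
# matrix: mu = exp(base + latent + batch shift) * library factor.
nb_counts <- function(latent, lib, batch, spec) {
  pf <- nrow(latent)
  n <- ncol(latent)
  base <- stats::runif(pf, spec$base_logmean_range[1],
                       spec$base_logmean_range[2])
  shift <- matrix(stats::rnorm(pf * spec$n_batch, sd = spec$batch_sd),
                  pf, spec$n_batch)
  mu <- exp(base + latent + shift[, batch, drop = FALSE]) *
    rep(lib, each = pf)
  cnt <- matrix(stats::rnbinom(pf * n, mu = mu, size = 1 / spec$nb_dispersion),
                pf, n)
  dimnames(cnt) <- dimnames(latent)
  cnt
}

#' Write / read the ground-truth record as JSON
#'
#' @param truth ground-truth list from [simulate_cohort()] (the large latent
#'   matrices are dropped before serialization).
#' @param path file path.
#' @return `read_ground_truth` returns the list.
#' @export
write_ground_truth <- function(truth, path) {
  truth$latent_mirna <- NULL
  truth$latent_gene <- NULL
  truth$factors <- NULL
  truth$labels <- list(mirna = names(truth$labels),
                       module = unname(truth$labels))
  truth$loadings <- list(mirna = names(truth$loadings),
                         loading = unname(truth$loadings))
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$labels <- stats::setNames(as.integer(tr$labels$module), tr$labels$mirna)
  tr$loadings <- stats::setNames(tr$loadings$loading, tr$loadings$mirna)
  tr
}
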