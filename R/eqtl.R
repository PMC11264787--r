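# Genome-wide miR-eQTL scan: covariate residualization with genotype PCs,
# per-SNP regression, cis/trans labelling, and LD clumping into loci.

#' Genotype principal components
#'
#' Plain PCA of the centered, allele-frequency-scaled dosage matrix
#' (each SNP divided by sqrt(2 p (1 - p))). The sign of each component is
#' fixed so its largest-magnitude loading is positive, making the PCs
#' reproducible across runs.
#'
#' @param dosages samples x SNPs numeric matrix, entries in \[0, 2\].
#' @param n_pc number of components requested, default 10; when fewer are
#'   computable the available number is returned with a warning.
#' @return samples x PCs score matrix.
#' @export
genotype_pcs <- function(dosages, n_pc = 10) {
  p <- colMeans(dosages) / 2
  keep <- p > 0 & p < 1
  X <- dosages[, keep, drop = FALSE]
  p <- p[keep]
  X <- sweep(sweep(X, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  k <- min(n_pc, nrow(X) - 1, ncol(X))
  if (k < n_pc)
    warning(sprintf("only %d genotype PCs computable (requested %d)", k, n_pc))
  sv <- svd(X, nu = k, nv = 0)
  pcs <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) if (pcs[which.max(abs(pcs[, j])), j] < 0)
    pcs[, j] <- -pcs[, j]
  colnames(pcs) <- paste0("PC", seq_len(k))
  rownames(pcs) <- rownames(dosages)
  pcs
}

#' Residualize miRNA expression for the eQTL scan
#'
#' Regresses each miRNA's expression on age, sex, the first `n_pc` genotype
#' principal components and batch, and returns the residuals (mean 0 per
#' miRNA).
#'
#' @param mirna_expr features x samples expression matrix.
#' @param covariates data.frame with age, sex, batch columns (rows align
#'   with samples).
#' @param dosages samples x SNPs dosage matrix for the PCA.
#' @param n_pc genotype PCs to adjust for, default 10.
#' @return residual expression matrix, same shape as `mirna_expr`.
#' @export
residualize_for_eqtl <- function(mirna_expr, covariates, dosages, n_pc = 10) {
  pcs <- genotype_pcs(dosages, n_pc)
  residualize(mirna_expr, cbind(as.data.frame(covariates), as.data.frame(pcs)))
}

#' Genome-wide per-SNP association scan
#'
#' Simple linear regression (with intercept) of each miRNA residual on each
#' SNP dosage. Hits with p below `alpha` are labelled `cis` when the SNP lies
#' on the same chromosome within 1 Mb (inclusive) of the mature miRNA
#' position, `trans` otherwise. Monomorphic SNPs are skipped.
#'
#' @param geno list with `dosages` (samples x SNPs), `variants` (data.frame
#'   snp, chr, pos) and `mirna_loci` (data.frame mirna, chr, pos).
#' @param resid features x samples residual expression from
#'   [residualize_for_eqtl()].
#' @param alpha genome-wide significance level, default 5e-8.
#' @param cis_window cis distance in bp, default 1e6 (inclusive).
#' @param return_all also return sub-threshold associations, default FALSE.
#' @return data.frame of hits: snp, mirna, beta, se, p, type (cis/trans).
#' @export
eqtl_scan <- function(geno, resid, alpha = 5e-8, cis_window = 1e6,
                      return_all = FALSE) {
  D <- geno$dosages
  shared <- intersect(rownames(D), colnames(resid))
  if (!length(shared)) stop_mv("no shared samples between genotypes and expression")
  D <- D[shared, , drop = FALSE]
  resid <- resid[, shared, drop = FALSE]
  n <- length(shared)
  poly <- apply(D, 2, stats::sd) > 0
  D <- D[, poly, drop = FALSE]
  Dc <- sweep(D, 2, colMeans(D))
  sxx <- colSums(Dc^2)
  hits <- list()
  for (mir in rownames(resid)) {
    y <- resid[mir, ]
    yc <- y - mean(y)
    syy <- sum(yc^2)
    sxy <- as.numeric(crossprod(Dc, yc))
    beta <- sxy / sxx
    rss <- syy - beta * sxy
    se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
    tval <- beta / se
    p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
    sel <- if (return_all) seq_along(p) else which(p < alpha)
    if (!length(sel)) next
    hits[[mir]] <- data.frame(
      snp = colnames(D)[sel], mirna = mir,
      beta = beta[sel], se = se[sel], p = p[sel],
      stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    return(data.frame(snp = character(), mirna = character(), beta = numeric(),
                      se = numeric(), p = numeric(), type = character()))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  vmap <- geno$variants[match(out$snp, geno$variants$snp), ]
  mmap <- geno$mirna_loci[match(out$mirna, geno$mirna_loci$mirna), ]
  out$type <- ifelse(!is.na(mmap$chr) & vmap$chr == mmap$chr &
                       abs(vmap$pos - mmap$pos) <= cis_window, "cis", "trans")
  out
}

#' Clump significant SNPs into genomic risk loci
#'
#' Greedy, per miRNA: hits are sorted by ascending p; the best unassigned
#' hit seeds a locus, which absorbs (transitively) every unassigned hit with
#' dosage r-squared above `r2_locus` to any current member lying within
#' `pad_bp` of a member position. Lead SNPs within a locus are the greedy
#' most-significant-first subset with pairwise r-squared below `r2_lead`;
#' the top lead is the minimum-p member.
#'
#' @param hits data.frame from [eqtl_scan()].
#' @param geno genotype list as in [eqtl_scan()].
#' @param r2_locus clumping r-squared threshold, default 0.6 (exclusive,
#'   "greater than").
#' @param r2_lead lead-SNP independence threshold, default 0.1 (r2 must be
#'   strictly below).
#' @param pad_bp positional window for transitive absorption, default 1e6.
#' @return data.frame of loci: mirna, locus, top_lead, lead_snps
#'   (';'-separated), members (';'-separated), n_snps, chr, pos_min, pos_max,
#'   p_top.
#' @export
clump_loci <- function(hits, geno, r2_locus = 0.6, r2_lead = 0.1,
                       pad_bp = 1e6) {
  if (!nrow(hits)) stop_mv("no hits to clump")
  D <- geno$dosages
  vmap <- geno$variants
  out <- list()
  for (mir in unique(hits$mirna)) {
    h <- hits[hits$mirna == mir, , drop = FALSE]
    h <- h[order(h$p, h$snp), , drop = FALSE]
    pos <- vmap$pos[match(h$snp, vmap$snp)]
    chr <- vmap$chr[match(h$snp, vmap$snp)]
    r2 <- stats::cor(D[, h$snp, drop = FALSE])^2
    assigned <- rep(NA_integer_, nrow(h))
    locus_id <- 0L
    while (anyNA(assigned)) {
      locus_id <- locus_id + 1L
      seed <- which(is.na(assigned))[1]
      members <- seed
      repeat {
        cand <- which(is.na(assigned))
        cand <- setdiff(cand, members)
        grow <- cand[vapply(cand, function(i) {
          any(r2[i, members] > r2_locus &
                chr[i] == chr[members] &
                abs(pos[i] - pos[members]) <= pad_bp)
        }, logical(1))]
        if (!length(grow)) break
        members <- c(members, grow)
      }
      assigned[members] <- locus_id
      members <- sort(members)
      # leads: most significant first, pairwise r2 < r2_lead
      ord <- members[order(h$p[members])]
      leads <- integer(0)
      for (i in ord) {
        if (!length(leads) || all(r2[i, leads] < r2_lead)) leads <- c(leads, i)
      }
      out[[length(out) + 1]] <- data.frame(
        mirna = mir, locus = locus_id,
        top_lead = h$snp[ord[1]],
        lead_snps = paste(h$snp[leads], collapse = ";"),
        members = paste(h$snp[members], collapse = ";"),
        n_snps = length(members),
        chr = chr[ord[1]], pos_min = min(pos[members]),
        pos_max = max(pos[members]), p_top = h$p[ord[1]],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
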