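# Signed weighted co-expression network, built from scratch:
# biweight midcorrelation -> signed adjacency -> topological overlap ->
# average-linkage clustering with a hybrid tree cut -> module merging ->
# eigenvectors and module membership.

#' Biweight midcorrelation
#'
#' Robust correlation based on Tukey biweights around the median. With
#' u_i = (x_i - med(x)) / (9 MAD(x)) (MAD unscaled) and weights
#' w_i = (1 - u_i^2)^2 for |u_i| < 1 (0 otherwise), bicor is the weighted
#' centered cross-product normalized by the weighted norms. Outlying points
#' get weight ~0, so single gross outliers barely move the estimate.
#' Vectors with zero MAD fall back to Pearson correlation for that pair
#' (standard fallback), unless `fallback = FALSE`.
#'
#' @param x,y numeric vectors, length >= 3.
#' @param fallback use Pearson when MAD is zero? Default TRUE.
#' @return correlation in \[-1, 1\].
#' @export
bicor <- function(x, y, fallback = TRUE) {
  if (length(x) != length(y) || length(x) < 3)
    stop_mv("bicor needs two vectors of equal length >= 3")
  tx <- bicor_transform(x)
  ty <- bicor_transform(y)
  if (is.null(tx) || is.null(ty)) {
    if (!fallback) stop_mv("zero MAD and Pearson fallback disabled")
    return(stats::cor(x, y))
  }
  r <- sum(tx * ty)
  max(-1, min(1, r))
}

# Returns the normalized biweight-transformed vector, or NULL when MAD = 0.
bicor_transform <- function(x) {
  m <- stats::median(x)
  mad_x <- stats::median(abs(x - m))
  if (mad_x == 0) return(NULL)
  u <- (x - m) / (9 * mad_x)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xc <- (x - m) * w
  nrm <- sqrt(sum(xc^2))
  if (nrm == 0) return(NULL)
  xc / nrm
}

#' All-pairs biweight midcorrelation of a feature matrix
#'
#' @param expr features x samples numeric matrix.
#' @param fallback Pearson fallback for zero-MAD features (per feature).
#' @return symmetric features x features correlation matrix, unit diagonal.
#' @export
bicor_matrix <- function(expr, fallback = TRUE) {
  n <- nrow(expr)
  tmat <- matrix(0, ncol(expr), n)
  use_pearson <- logical(n)
  for (i in seq_len(n)) {
    ti <- bicor_transform(expr[i, ])
    if (is.null(ti)) {
      if (!fallback) stop_mv("feature %d has zero MAD", i)
      use_pearson[i] <- TRUE
      xc <- expr[i, ] - mean(expr[i, ])
      nrm <- sqrt(sum(xc^2))
      if (nrm == 0) stop_mv("feature %d is constant", i)
      ti <- xc / nrm
    }
    tmat[, i] <- ti
  }
  # mixed pairs: when either member used the Pearson fallback, the pair is
  # Pearson; normalized cross-products of the transformed columns give both
  if (any(use_pearson)) {
    pear <- apply(expr, 1, function(r) (r - mean(r)) / sqrt(sum((r - mean(r))^2)))
    tmat[, use_pearson] <- pear[, use_pearson]
    rmix <- crossprod(tmat)
    # pairs where exactly one side is robust: use Pearson on both sides
    mixed <- outer(use_pearson, !use_pearson) | outer(!use_pearson, use_pearson)
    rp <- crossprod(pear)
    rmix[mixed] <- rp[mixed]
    r <- rmix
  } else {
    r <- crossprod(tmat)
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(rownames(expr), rownames(expr))
  r
}

#' Signed soft-threshold adjacency
#'
#' a_ij = ((1 + rho_ij) / 2)^beta: negative correlations map toward 0 so
#' modules contain positively co-expressed features.
#'
#' @param corr symmetric correlation matrix, entries in \[-1, 1\].
#' @param beta soft-threshold power, >= 1.
#' @param signed use the signed transform (default TRUE); unsigned uses
#'   |rho|^beta.
#' @return adjacency matrix in \[0, 1\], unit diagonal.
#' @export
adjacency <- function(corr, beta, signed = TRUE) {
  if (beta < 1) stop_mv("soft-threshold power must be >= 1")
  if (max(abs(corr - t(corr))) > 1e-10) stop_mv("correlation matrix not symmetric")
  a <- if (signed) ((1 + corr) / 2)^beta else abs(corr)^beta
  diag(a) <- 1
  a
}

#' Scale-free-topology soft power selection
#'
#' For each candidate power the signed adjacency and connectivity
#' k_i = sum_j a_ij (j != i) are computed; connectivity is binned into
#' `n_bins` equal-width bins and log10 bin frequency regressed on log10
#' mean connectivity. The signed fit index is R^2 negated by the slope sign,
#' so decreasing (scale-free-like) degree laws score positively. The selected
#' power is the first on the grid whose fit reaches `target`; if none does,
#' the argmax power is returned with `reached_target = FALSE` and a warning.
#'
#' @param expr features x samples matrix (>= 30 features).
#' @param powers candidate integer powers (default 1:20).
#' @param target scale-free fit target R^2, default 0.90.
#' @param n_bins connectivity histogram bins, default 10.
#' @param corr optional precomputed correlation matrix.
#' @return list with `power`, `reached_target`, and `fit_table`
#'   (power, fit, mean_k).
#' @export
pick_soft_power <- function(expr, powers = 1:20, target = 0.90, n_bins = 10,
                            corr = NULL) {
  if (!is.null(expr) && nrow(expr) < 30)
    stop_mv("soft power selection needs >= 30 features")
  if (is.null(corr)) corr <- bicor_matrix(expr)
  fits <- vapply(powers, function(b) {
    a <- adjacency(corr, b)
    k <- colSums(a) - 1
    c(scale_free_fit(k, n_bins), mean(k))
  }, numeric(2))
  tab <- data.frame(power = powers, fit = fits[1, ], mean_k = fits[2, ])
  hit <- which(tab$fit >= target)
  if (length(hit)) {
    list(power = powers[hit[1]], reached_target = TRUE, fit_table = tab)
  } else {
    warning(sprintf("no power reached scale-free fit %.2f; using argmax", target))
    list(power = powers[which.max(tab$fit)], reached_target = FALSE,
         fit_table = tab)
  }
}

# Signed scale-free fit index from a connectivity vector: equal-width
# connectivity bins, log10 frequency regressed on log10 mean connectivity;
# R^2 signed so decreasing degree laws score positively.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(0)
  bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
  freq <- as.numeric(tapply(k, bin, length)) / length(k)
  mk <- as.numeric(tapply(k, bin, mean))
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(0)
  lf <- log10(freq[ok]); lk <- log10(mk[ok])
  fit <- stats::lm(lf ~ lk)
  r2 <- summary(fit)$r.squared
  unname(-sign(stats::coef(fit)[2]) * r2)
}

#' Topological overlap matrix
#'
#' Omega_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_u a_iu a_uj over u != i, j and k_i = sum_u a_iu over u != i;
#' unit diagonal. The corresponding dissimilarity is 1 - Omega.
#'
#' @param adj symmetric adjacency in \[0, 1\] with unit diagonal.
#' @return TOM similarity matrix in \[0, 1\].
#' @export
tom <- function(adj) {
  if (max(abs(adj - t(adj))) > 1e-10) stop_mv("adjacency not symmetric")
  a <- adj
  diag(a) <- 0
  l <- a %*% a               # sum_u a_iu a_uj, u != i and u != j after diag 0
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  om <- (l + a) / denom
  diag(om) <- 1
  om[om > 1] <- 1
  om[om < 0] <- 0
  dimnames(om) <- dimnames(adj)
  om
}

#' Hybrid tree-cut module detection
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity followed
#' by a two-phase hybrid cut: (1) a static cut of the dendrogram at an
#' adaptive height (`cut_frac` of the maximum merge height) yields candidate
#' branches, branches smaller than `min_size` are dissolved to label 0;
#' (2) a PAM-like assignment attaches each unlabelled feature to its nearest
#' retained module when its average dissimilarity to that module is below the
#' feature's median dissimilarity to all features. Labels are relabelled by
#' decreasing module size (1 = largest, 0 = unassigned).
#'
#' @param diss_tom square TOM dissimilarity, zero diagonal.
#' @param min_size minimum module size, default 5.
#' @param cut_frac static cut height as a fraction of the maximum merge
#'   height, default 0.97.
#' @return integer label vector (0 = unassigned), named by feature.
#' @export
cluster_modules <- function(diss_tom, min_size = 5, cut_frac = 0.97) {
  n <- nrow(diss_tom)
  if (n < min_size) {
    warning("fewer features than min_size; all unassigned")
    return(stats::setNames(integer(n), rownames(diss_tom)))
  }
  off <- diss_tom[upper.tri(diss_tom)]
  if (max(off) - min(off) < 1e-12) {
    # degenerate flat dissimilarity: a single module (if big enough)
    return(stats::setNames(rep(if (n >= min_size) 1L else 0L, n),
                           rownames(diss_tom)))
  }
  hc <- stats::hclust(stats::as.dist(diss_tom), method = "average")
  h <- cut_frac * max(hc$height)
  lab <- stats::cutree(hc, h = h)
  sizes <- table(lab)
  small <- as.integer(names(sizes)[sizes < min_size])
  lab[lab %in% small] <- 0L
  # PAM-like attachment of unlabelled features: a feature joins its nearest
  # module only when its average dissimilarity to that module is below both
  # (a) the feature's median dissimilarity to all features and (b) the
  # module's own radius (mean + 2 sd of within-module dissimilarities), so
  # unrelated noise features are not absorbed.
  mods <- setdiff(unique(lab), 0L)
  if (length(mods) && any(lab == 0L)) {
    radius <- vapply(mods, function(m) {
      w <- diss_tom[lab == m, lab == m]
      wv <- w[upper.tri(w)]
      mean(wv) + 2 * stats::sd(wv)
    }, numeric(1))
    for (i in which(lab == 0L)) {
      d_mod <- vapply(mods, function(m) mean(diss_tom[i, lab == m]), numeric(1))
      j <- which.min(d_mod)
      if (d_mod[j] < stats::median(diss_tom[i, -i]) &&
          is.finite(radius[j]) && d_mod[j] < radius[j]) lab[i] <- mods[j]
    }
  }
  relabel_by_size(lab, rownames(diss_tom))
}

relabel_by_size <- function(lab, feat_names = names(lab)) {
  mods <- setdiff(unique(lab), 0L)
  ord <- mods[order(-tabulate(match(lab, mods), length(mods)), mods)]
  new <- integer(length(lab))
  for (i in seq_along(ord)) new[lab == ord[i]] <- i
  stats::setNames(new, feat_names)
}

# Module colour aliases in the conventional size-rank order.
module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet"
)

color_alias <- function(labels) {
  k <- max(labels)
  cols <- c("grey", rep_len(module_colors, max(k, 1)))
  cols[labels + 1L]
}

#' Module eigenvector (eigen-miRNA)
#'
#' First principal component over samples of the per-feature standardized
#' module expression; the sign is aligned so the eigenvector correlates
#' non-negatively with the module-average expression profile.
#'
#' @param expr_module features x samples matrix for one module.
#' @return list with `eigen` (length-n sample vector, unit variance) and
#'   `explained_var` (fraction of module variance captured).
#' @export
eigenvector <- function(expr_module) {
  if (is.null(dim(expr_module))) expr_module <- matrix(expr_module, nrow = 1)
  v <- apply(expr_module, 1, stats::sd)
  if (any(v == 0)) {
    warning("dropping zero-variance feature(s) from module")
    expr_module <- expr_module[v > 0, , drop = FALSE]
    if (!nrow(expr_module)) stop_mv("module has no non-constant feature")
  }
  xs <- t(scale(t(expr_module)))            # standardize each feature
  if (nrow(xs) == 1) {
    return(list(eigen = zscore(as.numeric(xs)), explained_var = 1))
  }
  sv <- svd(t(xs), nu = 1, nv = 0)
  e <- sv$u[, 1]
  avg <- colMeans(xs)
  if (stats::cor(e, avg) < 0) e <- -e
  list(eigen = zscore(e), explained_var = sv$d[1]^2 / sum(sv$d^2))
}

#' Merge highly correlated modules and assemble the module partition
#'
#' Iteratively computes module eigenvectors, measures eigenvector correlation
#' dissimilarity (1 - cor), and merges the closest pair whenever it falls
#' below `cut_height` (0.2 corresponds to eigenvector correlation 0.8);
#' repeats until no pair qualifies. Ties break at the lowest label pair.
#' Returns the final partition with eigen matrix, module membership and
#' colour aliases by size rank.
#'
#' @param expr features x samples expression matrix (network input).
#' @param labels integer module labels from [cluster_modules()].
#' @param cut_height eigenvector dissimilarity below which modules merge;
#'   default 0.2.
#' @return a `module_partition`: list with `labels`, `colors`, `eigen`
#'   (samples x modules, columns standardized), `mm` (features x modules
#'   correlation), `sizes`, `merges` (number of merges performed).
#' @export
merge_modules <- function(expr, labels, cut_height = 0.2) {
  lab <- as.integer(labels)
  names(lab) <- names(labels) %||% rownames(expr)
  merges <- 0L
  repeat {
    mods <- sort(setdiff(unique(lab), 0L))
    if (length(mods) < 2) break
    E <- vapply(mods, function(m) {
      eigenvector(expr[lab == m, , drop = FALSE])$eigen
    }, numeric(ncol(expr)))
    d <- 1 - stats::cor(E)
    diag(d) <- Inf
    idx <- which(d == min(d), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    if (min(d) >= cut_height) break
    keep <- mods[min(idx)]
    drop <- mods[max(idx)]
    lab[lab == drop] <- keep
    merges <- merges + 1L
  }
  lab <- relabel_by_size(lab, names(lab))
  new_module_partition(expr, lab, merges)
}

new_module_partition <- function(expr, lab, merges = 0L) {
  mods <- sort(setdiff(unique(lab), 0L))
  if (length(mods)) {
    E <- vapply(mods, function(m) {
      eigenvector(expr[lab == m, , drop = FALSE])$eigen
    }, numeric(ncol(expr)))
    colnames(E) <- color_alias(mods)
    rownames(E) <- colnames(expr)
    mm <- stats::cor(t(expr), E)
    rownames(mm) <- rownames(expr)
  } else {
    E <- matrix(numeric(0), nrow = ncol(expr), ncol = 0)
    mm <- matrix(numeric(0), nrow = nrow(expr), ncol = 0)
  }
  structure(list(
    labels = lab,
    colors = stats::setNames(color_alias(lab), names(lab)),
    eigen = E,
    mm = mm,
    sizes = stats::setNames(tabulate(lab, length(mods)), color_alias(mods)),
    merges = merges
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module partition: %d features, %d modules (%d unassigned)\n",
              length(x$labels), length(x$sizes), sum(x$labels == 0)))
  if (length(x$sizes)) print(x$sizes)
  invisible(x)
}

#' Full network stage: expression matrix to module partition
#'
#' Runs correlation, soft-power selection, adjacency, TOM, hybrid tree cut
#' and module merging with the default parameters of the analysis
#' (scale-free target 0.90, minimum module size 5, merge cut height 0.2).
#'
#' @param expr batch-residualized features x samples expression matrix.
#' @param params list overriding `powers`, `target`, `min_size`,
#'   `cut_height`, `power` (fixing the power skips the search), or
#'   `fallback_power` (used when no candidate reaches the scale-free target;
#'   default 7, the customary power for signed networks, since the flagged
#'   argmax can grossly over-threshold when the degree distribution is far
#'   from scale-free).
#' @return list with `partition` (module_partition), `power`, `power_fit`
#'   (fit table), `diss_tom`.
#' @export
build_network <- function(expr, params = list()) {
  p <- utils::modifyList(list(powers = 1:20, target = 0.90, min_size = 5,
                              cut_height = 0.2, power = NULL,
                              fallback_power = 7), params)
  corr <- bicor_matrix(expr)
  if (is.null(p$power)) {
    sel <- suppressWarnings(pick_soft_power(NULL, powers = p$powers,
                                            target = p$target, corr = corr))
    p$power <- sel$power
    if (!sel$reached_target) {
      warning(sprintf(
        "no power reached the scale-free target; using default power %d",
        p$fallback_power))
      p$power <- p$fallback_power
    }
    fit_tab <- sel$fit_table
  } else fit_tab <- NULL
  a <- adjacency(corr, p$power)
  d <- 1 - tom(a)
  diag(d) <- 0
  lab <- cluster_modules(d, min_size = p$min_size)
  part <- merge_modules(expr, lab, cut_height = p$cut_height)
  list(partition = part, power = p$power, power_fit = fit_tab, diss_tom = d)
}
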