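# miRNA -> target-gene confirmation against expression data, overlap
# analysis, and term over-representation with semantic aggregation.

#' Confirm predicted miRNA targets against expression
#'
#' For every predicted (miRNA, gene) pair fits gene expression ~ miRNA
#' expression + covariates (age, sex, erythrocyte/leukocyte/platelet counts)
#' by OLS; the pair is confirmed when the miRNA coefficient is negative with
#' p < `p_thresh` (repression shows as negative association). Pairs whose
#' gene or miRNA is absent from the (filtered) expression matrices are
#' dropped and counted.
#'
#' @param predictions data.frame with columns `mirna`, `gene` and optionally
#'   `source`; duplicate pairs are collapsed (sources concatenated).
#' @param mirna_expr,gene_expr features x samples batch-residualized
#'   expression matrices with shared sample columns.
#' @param covariates data.frame of per-sample covariates.
#' @param p_thresh confirmation p threshold, default 0.05.
#' @return list with `pairs` (per-pair beta, p, confirmed) and `summary`
#'   (per miRNA: n_predicted, n_confirmed, percent_confirmed, n_dropped).
#' @export
confirm_targets <- function(predictions, mirna_expr, gene_expr,
                            covariates = NULL, p_thresh = 0.05) {
  stopifnot(all(c("mirna", "gene") %in% names(predictions)))
  if (!"source" %in% names(predictions)) predictions$source <- "user"
  key <- paste(predictions$mirna, predictions$gene, sep = "\r")
  src <- tapply(predictions$source, key, function(s)
    paste(sort(unique(s)), collapse = ";"))
  predictions <- predictions[!duplicated(key), c("mirna", "gene")]
  predictions$source <- as.character(src[paste(predictions$mirna,
                                               predictions$gene, sep = "\r")])
  present <- predictions$mirna %in% rownames(mirna_expr) &
    predictions$gene %in% rownames(gene_expr)
  n_drop <- sum(!present)
  if (n_drop) message(sprintf("confirm_targets: dropped %d pairs absent from expression", n_drop))
  pred <- predictions[present, , drop = FALSE]
  if (!nrow(pred)) stop_mv("no predicted pair present in the expression data")

  # Frisch-Waugh: residualize genes and miRNAs on covariates once, then each
  # pair reduces to a simple regression with covariate-adjusted df.
  n <- ncol(mirna_expr)
  if (!is.null(covariates)) {
    mirna_r <- residualize(mirna_expr, covariates)
    gene_r <- residualize(gene_expr[unique(pred$gene), , drop = FALSE], covariates)
    k <- qr(stats::model.matrix(~., data = as.data.frame(covariates)))$rank
  } else {
    mirna_r <- sweep(mirna_expr, 1, rowMeans(mirna_expr))
    gene_r <- sweep(gene_expr[unique(pred$gene), , drop = FALSE], 1,
                    rowMeans(gene_expr[unique(pred$gene), , drop = FALSE]))
    k <- 1
  }
  df <- n - k - 1
  if (df <= 2) stop_mv("too few residual degrees of freedom")
  beta <- p <- numeric(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    x <- mirna_r[pred$mirna[i], ]
    y <- gene_r[pred$gene[i], ]
    sxx <- sum(x^2)
    b <- sum(x * y) / sxx
    rss <- sum((y - b * x)^2)
    se <- sqrt(rss / df / sxx)
    beta[i] <- b
    p[i] <- 2 * stats::pt(abs(b / se), df = df, lower.tail = FALSE)
  }
  pred$beta <- beta
  pred$p <- p
  pred$confirmed <- beta < 0 & p < p_thresh
  summ <- do.call(rbind, lapply(split(pred, pred$mirna), function(d) {
    data.frame(mirna = d$mirna[1], n_predicted = nrow(d),
               n_confirmed = sum(d$confirmed),
               percent_confirmed = round(100 * mean(d$confirmed), 1),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(pairs = pred, summary = summ, n_dropped = n_drop)
}

#' Pairwise overlap of confirmed target-gene sets
#'
#' @param gene_sets named list (per miRNA) of confirmed gene id vectors.
#' @return data.frame: mirna_a, mirna_b, n_overlap for every unordered pair.
#' @export
target_overlap <- function(gene_sets) {
  if (length(gene_sets) < 2) stop_mv("need at least two gene sets")
  nms <- names(gene_sets)
  cmb <- utils::combn(nms, 2)
  data.frame(
    mirna_a = cmb[1, ], mirna_b = cmb[2, ],
    n_overlap = apply(cmb, 2, function(pr)
      length(intersect(gene_sets[[pr[1]]], gene_sets[[pr[2]]]))),
    stringsAsFactors = FALSE
  )
}

#' Hypergeometric over-representation p-values
#'
#' Upper-tail hypergeometric test per term: with N background genes, K hits,
#' a term of size m (after intersection with the background) and overlap x,
#' p = P(X >= x) for X ~ Hypergeom(N, K, m). Terms with zero overlap get
#' p = 1.
#'
#' @param hits character vector of hit genes (subset of background).
#' @param term_sets named list of term gene sets.
#' @param background character vector, the testable gene universe.
#' @return data.frame: term, n_term, n_overlap, p.
#' @export
hypergeom_enrich <- function(hits, term_sets, background) {
  if (!length(background)) stop_mv("empty background set")
  background <- unique(background)
  hits <- unique(intersect(hits, background))
  res <- lapply(names(term_sets), function(tm) {
    ts <- intersect(term_sets[[tm]], background)
    x <- length(intersect(hits, ts))
    p <- if (x == 0) 1 else
      stats::phyper(x - 1, length(hits), length(background) - length(hits),
                    length(ts), lower.tail = FALSE)
    data.frame(term = tm, n_term = length(ts), n_overlap = x, p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Aggregate semantically similar terms and combine p-values
#'
#' Complete-linkage clustering of the terms on 1 - similarity, cut so that
#' every within-group pairwise similarity is at least `threshold` (a property
#' complete linkage guarantees when cut at height 1 - threshold). When no
#' similarity matrix is supplied, the Jaccard index of the terms' gene sets
#' is used. Each group is represented by its lowest-p member; the member
#' p-values are combined by Fisher's method, X = -2 sum ln p against
#' chi-square with 2m df, and BH correction is applied across groups.
#'
#' @param enrich data.frame from [hypergeom_enrich()] (columns term, p).
#' @param similarity optional symmetric term x term similarity in \[0, 1\]
#'   with unit diagonal (e.g. an ontology-graph semantic similarity).
#' @param term_sets named list of term gene sets (used for the Jaccard
#'   default; required when `similarity` is NULL).
#' @param threshold minimum within-group similarity, default 0.5.
#' @param fdr significance level for the `significant` view, default 0.05.
#' @return list with `groups` (group, representative, members, p_combined,
#'   q, n_terms) and `significant` (rows with q < `fdr`).
#' @export
semantic_aggregate <- function(enrich, similarity = NULL, term_sets = NULL,
                               threshold = 0.5, fdr = 0.05) {
  terms <- enrich$term
  p <- enrich$p
  if (any(p == 0)) {
    warning("zero p-values clipped to smallest positive normal")
    p[p == 0] <- .Machine$double.xmin
  }
  if (is.null(similarity)) {
    if (is.null(term_sets)) stop_mv("supply a similarity matrix or term_sets")
    similarity <- jaccard_matrix(term_sets[terms])
  } else {
    similarity <- similarity[terms, terms, drop = FALSE]
  }
  if (length(terms) == 1) {
    grp <- stats::setNames(1L, terms)
  } else {
    hc <- stats::hclust(stats::as.dist(1 - similarity), method = "complete")
    grp <- stats::cutree(hc, h = 1 - threshold)
  }
  rows <- lapply(sort(unique(grp)), function(g) {
    idx <- which(grp == g)
    pg <- p[idx]
    X <- -2 * sum(log(pg))
    data.frame(
      group = g,
      representative = terms[idx][which.min(pg)],
      members = paste(terms[idx], collapse = ";"),
      n_terms = length(idx),
      p_combined = stats::pchisq(X, df = 2 * length(idx), lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  groups <- do.call(rbind, rows)
  groups$q <- bh_fdr(groups$p_combined)
  list(groups = groups, significant = groups[groups$q < fdr, , drop = FALSE])
}

jaccard_matrix <- function(sets) {
  n <- length(sets)
  m <- diag(1, n)
  dimnames(m) <- list(names(sets), names(sets))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      u <- length(union(sets[[i]], sets[[j]]))
      m[i, j] <- m[j, i] <- if (u == 0) 0 else
        length(intersect(sets[[i]], sets[[j]])) / u
    }
  }
  m
}
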