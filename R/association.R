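# Module-trait and miRNA-trait linear models, FDR control, hub selection,
# effect-modification and sensitivity analyses.

#' Covariate-adjusted linear association
#'
#' Ordinary least squares of `trait` on `predictor` plus covariates (with
#' intercept), on complete cases. Predictor and trait are z-standardized over
#' the analysis sample (so the coefficient is sd outcome per sd predictor)
#' unless `standardize = FALSE`. SE, two-sided p and 95 percent CI come from
#' the usual OLS t theory.
#'
#' @param predictor numeric sample vector (e.g. a module eigenvector or one
#'   miRNA's expression).
#' @param trait numeric sample vector (transformed trait).
#' @param covariates data.frame of adjustment covariates (may be NULL).
#' @param predictor_id,trait_id identifiers carried into the result row.
#' @param standardize z-score predictor and trait on the analysis sample.
#' @param model_tag free-text tag (primary, non-indexed, ...).
#' @return one-row data.frame: predictor, trait, beta, se, ci_lo, ci_hi, p,
#'   n, model.
#' @export
associate <- function(predictor, trait, covariates = NULL,
                      predictor_id = "predictor", trait_id = "trait",
                      standardize = TRUE, model_tag = "primary") {
  dat <- data.frame(.y = trait, .x = predictor)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (stats::sd(dat$.x) == 0) stop_mv("zero-variance predictor '%s'", predictor_id)
  if (standardize) {
    dat$.x <- zscore(dat$.x)
    dat$.y <- zscore(dat$.y)
  }
  fit <- stats::lm(.y ~ ., data = dat)
  if (n - fit$rank <= 2) stop_mv("too few residual degrees of freedom (n = %d)", n)
  sm <- summary(fit)$coefficients
  b <- sm[".x", 1]; se <- sm[".x", 2]; p <- sm[".x", 4]
  tcrit <- stats::qt(0.975, df = fit$df.residual)
  data.frame(predictor = predictor_id, trait = trait_id,
             beta = b, se = se, ci_lo = b - tcrit * se, ci_hi = b + tcrit * se,
             p = p, n = n, model = model_tag, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity; input order preserved.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same order and names.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop_mv("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Associate every module eigenvector with every trait
#'
#' Runs [associate()] for each (module, trait) pair with the given covariates
#' and applies BH correction jointly across all pairs (one step-up family per
#' analysis).
#'
#' @param eigen samples x modules eigen matrix.
#' @param traits data.frame of transformed trait columns (rows = samples).
#' @param covariates data.frame of adjustment covariates (age, sex).
#' @param model_tag tag copied into each row.
#' @return data.frame of association rows with a `q` column.
#' @export
associate_modules <- function(eigen, traits, covariates, model_tag = "primary") {
  rows <- list()
  for (m in colnames(eigen)) {
    for (tr in colnames(traits)) {
      rows[[length(rows) + 1]] <-
        associate(eigen[, m], traits[[tr]], covariates,
                  predictor_id = m, trait_id = tr, model_tag = model_tag)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Identify key modules
#'
#' A key module is one whose eigenvector is associated with at least one
#' trait at BH FDR below `fdr`.
#'
#' @param module_assoc output of [associate_modules()].
#' @param fdr FDR threshold, default 0.05 (0.1 used as the lenient view).
#' @return data.frame (module, trait, beta, q) of the qualifying pairs.
#' @export
key_modules <- function(module_assoc, fdr = 0.05) {
  module_assoc[module_assoc$q < fdr,
               c("predictor", "trait", "beta", "p", "q"), drop = FALSE]
}

#' Select hub miRNAs for key modules
#'
#' A hub miRNA (a) has module membership greater than `mm_thresh` in its
#' module and (b) is individually associated with the module's selected trait
#' at p below `p_thresh`. When a key module yields no hub and
#' `borderline = TRUE`, the member with maximal module membership is emitted
#' flagged `borderline` (so the module can still be followed up).
#'
#' @param partition a `module_partition`.
#' @param mirna_assoc data.frame of per-miRNA association rows (from
#'   [associate()]) with columns predictor (miRNA id), trait, beta, p.
#' @param keys data.frame (module colour, trait) pairs from [key_modules()].
#' @param mm_thresh module-membership threshold, default 0.8.
#' @param p_thresh association p threshold, default 0.05.
#' @param borderline emit a flagged fallback hub for hubless key modules.
#' @return data.frame: module, trait, mirna, mm, beta, p, borderline.
#' @export
select_hubs <- function(partition, mirna_assoc, keys,
                        mm_thresh = 0.8, p_thresh = 0.05, borderline = TRUE) {
  out <- list()
  for (i in seq_len(nrow(keys))) {
    mod <- keys$predictor[i]
    tr <- keys$trait[i]
    members <- names(partition$labels)[partition$colors == mod]
    if (!length(members) || !(mod %in% colnames(partition$mm))) next
    mm <- partition$mm[members, mod]
    asc <- mirna_assoc[mirna_assoc$trait == tr &
                         mirna_assoc$predictor %in% members, , drop = FALSE]
    asc$mm <- mm[asc$predictor]
    hubs <- asc[asc$mm > mm_thresh & asc$p < p_thresh, , drop = FALSE]
    if (nrow(hubs)) {
      hubs$borderline <- FALSE
    } else if (borderline && nrow(asc)) {
      hubs <- asc[which.max(asc$mm), , drop = FALSE]
      hubs$borderline <- TRUE
    }
    if (nrow(hubs)) {
      out[[length(out) + 1]] <- data.frame(
        module = mod, trait = tr, mirna = hubs$predictor, mm = hubs$mm,
        beta = hubs$beta, p = hubs$p, borderline = hubs$borderline,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(module = character(), trait = character(),
                      mirna = character(), mm = numeric(), beta = numeric(),
                      p = numeric(), borderline = logical()))
  }
  do.call(rbind, out)
}

#' Effect modification by age or sex, with stratified follow-up
#'
#' Fits trait ~ miRNA * modifier + covariates; when the product term is
#' significant (p < `p_thresh`) re-fits within strata: the four age quartiles
#' (sample quantiles, linear interpolation) for a continuous modifier, or the
#' modifier's levels for a binary one. Strata with fewer than 30 samples are
#' flagged `low_n`.
#'
#' @param mirna,trait numeric sample vectors.
#' @param modifier numeric sample vector (age) or binary vector (sex).
#' @param covariates data.frame of adjustment covariates (should include the
#'   main effect of the modifier when not already among them).
#' @param p_thresh interaction significance threshold, default 0.05.
#' @param ids named list with `mirna` and `trait` identifiers.
#' @return list with `interaction` (one-row data.frame: beta, se, p of the
#'   product term) and `strata` (data.frame of stratified [associate()] rows
#'   with `stratum` and `low_n`; NULL if the interaction is not significant).
#' @export
interaction_and_strata <- function(mirna, trait, modifier, covariates = NULL,
                                   p_thresh = 0.05,
                                   ids = list(mirna = "mirna", trait = "trait")) {
  if (length(unique(modifier[!is.na(modifier)])) < 2)
    stop_mv("modifier is constant")
  dat <- data.frame(.y = trait, .x = mirna, .mod = modifier)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat$.y <- zscore(dat$.y); dat$.x <- zscore(dat$.x)
  fit <- stats::lm(.y ~ .x * .mod + ., data = dat)
  sm <- summary(fit)$coefficients
  term <- grep("^\\.x:", rownames(sm), value = TRUE)[1]
  inter <- data.frame(mirna = ids$mirna, trait = ids$trait,
                      beta = sm[term, 1], se = sm[term, 2], p = sm[term, 4],
                      n = nrow(dat), stringsAsFactors = FALSE)
  strata <- NULL
  if (inter$p < p_thresh) {
    binary <- length(unique(dat$.mod)) == 2
    if (binary) {
      grp <- factor(dat$.mod)
    } else {
      qs <- stats::quantile(dat$.mod, probs = c(0.25, 0.5, 0.75), type = 7)
      grp <- cut(dat$.mod, breaks = c(-Inf, qs, Inf),
                 labels = c("Q1", "Q2", "Q3", "Q4"))
    }
    rows <- lapply(levels(grp), function(g) {
      idx <- grp == g
      cv <- dat[idx, setdiff(names(dat), c(".y", ".x", ".mod")), drop = FALSE]
      if (!ncol(cv)) cv <- NULL
      r <- associate(dat$.x[idx], dat$.y[idx], cv,
                     predictor_id = ids$mirna, trait_id = ids$trait,
                     model_tag = "stratified")
      r$stratum <- g
      r$low_n <- sum(idx) < 30
      r
    })
    strata <- do.call(rbind, rows)
  }
  list(interaction = inter, strata = strata)
}

#' Sensitivity analysis on non-indexed traits
#'
#' Re-runs the module-trait associations using the non-indexed cardiac
#' output, stroke volume, total arterial compliance and systemic vascular
#' resistance as outcomes, adjusted for age and sex, and again additionally
#' adjusting for BMI; returns a side-by-side table.
#'
#' @param eigen samples x modules eigen matrix.
#' @param traits data.frame containing `co_z`, `sv_z`, `tac_z`, `svr_z`.
#' @param covariates data.frame with age and sex columns.
#' @param bmi numeric BMI vector.
#' @return data.frame of association rows, model tags `non-indexed` and
#'   `non-indexed+BMI`.
#' @export
sensitivity_non_indexed <- function(eigen, traits, covariates, bmi) {
  non_idx <- intersect(c("co_z", "sv_z", "tac_z", "svr_z"), names(traits))
  if (!length(non_idx)) stop_mv("no non-indexed trait columns found")
  if (is.null(bmi) || all(is.na(bmi))) stop_mv("BMI column is empty")
  a1 <- associate_modules(eigen, traits[non_idx], covariates,
                          model_tag = "non-indexed")
  a2 <- associate_modules(eigen, traits[non_idx],
                          cbind(covariates, bmi = bmi),
                          model_tag = "non-indexed+BMI")
  rbind(a1, a2)
}
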