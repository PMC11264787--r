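# Linear mediation: exposure -> mediator -> outcome with covariates,
# product-of-coefficients indirect effect, proportion mediated, and
# nonparametric bootstrap inference.

#' Mediation analysis for one exposure/mediator/outcome triple
#'
#' Two covariate-adjusted OLS fits: mediator ~ exposure (+ covariates) gives
#' the a path; outcome ~ exposure + mediator (+ covariates) gives the direct
#' path c' and the b path. Indirect effect = a*b, total = c' + a*b,
#' proportion mediated = a*b / (c' + a*b). For linear Gaussian paths this
#' equals the structural-equation point estimates. Inference is by
#' nonparametric bootstrap (samples resampled with replacement): percentile
#' 95 percent CIs for the indirect effect and the proportion, and a two-sided
#' sign-proportion p for the indirect effect. The proportion is suppressed
#' (NA, `suppressed = TRUE`) when |total| falls below `total_floor` to avoid
#' ratio blow-up.
#'
#' @param exposure,mediator,outcome numeric sample vectors (standardized
#'   internally over complete cases).
#' @param covariates data.frame of adjustment covariates (age, sex), or NULL.
#' @param n_boot bootstrap replicates, >= 200; default 1000.
#' @param seed integer seed for the bootstrap resampling.
#' @param total_floor |total effect| below which the proportion is not
#'   reported; default 0.01 sd units.
#' @return a `mediation_result` (list/data.frame hybrid) with elements a, b,
#'   c_prime, indirect, total, proportion, ci_indirect, ci_proportion,
#'   p_indirect, n, suppressed.
#' @export
mediate <- function(exposure, mediator, outcome, covariates = NULL,
                    n_boot = 1000, seed = 1, total_floor = 0.01) {
  if (n_boot < 200) stop_mv("n_boot must be >= 200")
  dat <- data.frame(.x = exposure, .m = mediator, .y = outcome)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (isTRUE(all.equal(zscore(dat$.x), zscore(dat$.m))))
    stop_mv("mediator is collinear with exposure")
  dat$.x <- zscore(dat$.x); dat$.m <- zscore(dat$.m); dat$.y <- zscore(dat$.y)

  paths <- function(d) {
    fa <- stats::lm(.m ~ . - .y, data = d)
    fy <- stats::lm(.y ~ ., data = d)
    a <- stats::coef(fa)[".x"]
    b <- stats::coef(fy)[".m"]
    cp <- stats::coef(fy)[".x"]
    c(a = unname(a), b = unname(b), c_prime = unname(cp))
  }
  pt <- paths(dat)
  indirect <- pt["a"] * pt["b"]
  total <- pt["c_prime"] + indirect

  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      d <- dat[sample.int(n, n, replace = TRUE), , drop = FALSE]
      p <- paths(d)
      ind <- p["a"] * p["b"]
      c(ind, p["c_prime"] + ind)
    }, numeric(2))
  })
  ci_ind <- unname(stats::quantile(boot[1, ], c(0.025, 0.975)))
  prop_boot <- boot[1, ] / boot[2, ]
  p_ind <- 2 * min(mean(boot[1, ] <= 0), mean(boot[1, ] >= 0))
  p_ind <- min(1, max(p_ind, 1 / n_boot))

  suppressed <- abs(total) < total_floor
  res <- list(
    a = unname(pt["a"]), b = unname(pt["b"]), c_prime = unname(pt["c_prime"]),
    indirect = unname(indirect), total = unname(total),
    proportion = if (suppressed) NA_real_ else unname(indirect / total),
    ci_indirect = ci_ind,
    ci_proportion = if (suppressed) c(NA_real_, NA_real_) else
      unname(stats::quantile(prop_boot, c(0.025, 0.975))),
    p_indirect = p_ind, n = n, n_boot = n_boot, suppressed = suppressed
  )
  class(res) <- "mediation_result"
  res
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation (n = %d): a = %.4f, b = %.4f, c' = %.4f\n",
              x$n, x$a, x$b, x$c_prime))
  cat(sprintf("  indirect = %.4f [%.4f; %.4f], p = %.4g\n",
              x$indirect, x$ci_indirect[1], x$ci_indirect[2], x$p_indirect))
  if (x$suppressed) {
    cat("  proportion mediated suppressed (|total| below floor)\n")
  } else {
    cat(sprintf("  total = %.4f, proportion mediated = %.3f [%.3f; %.3f]\n",
                x$total, x$proportion, x$ci_proportion[1], x$ci_proportion[2]))
  }
  invisible(x)
}

#' Mediation across a hub set
#'
#' Runs [mediate()] with the module eigenvector and then each hub miRNA as
#' the exposure, for a fixed mediator trait and outcome trait.
#'
#' @param exposures named list of numeric sample vectors (first entry
#'   conventionally the module eigenvector, then hub miRNA expressions).
#' @param mediator,outcome numeric sample vectors (e.g. total arterial
#'   compliance index and WMH burden, transformed).
#' @param covariates data.frame (age, sex).
#' @param n_boot,seed bootstrap settings passed to [mediate()].
#' @return data.frame, one row per exposure: paths, indirect, total,
#'   proportion (and percent), CIs, p, suppressed flag.
#' @export
mediation_suite <- function(exposures, mediator, outcome, covariates = NULL,
                            n_boot = 1000, seed = 1) {
  rows <- lapply(names(exposures), function(nm) {
    r <- mediate(exposures[[nm]], mediator, outcome, covariates,
                 n_boot = n_boot, seed = substream_seed(seed, nm))
    data.frame(exposure = nm, a = r$a, b = r$b, c_prime = r$c_prime,
               indirect = r$indirect, total = r$total,
               proportion = r$proportion,
               percent_mediated = 100 * r$proportion,
               ci_ind_lo = r$ci_indirect[1], ci_ind_hi = r$ci_indirect[2],
               ci_prop_lo = r$ci_proportion[1], ci_prop_hi = r$ci_proportion[2],
               p_indirect = r$p_indirect, n = r$n, suppressed = r$suppressed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
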