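# Linear association models, FDR control, hub selection, effect modification.

test_that("associate: exact fit, partial-correlation identity, errors", {
  set.seed(20)
  n <- 200
  x <- rnorm(n)
  r <- suppressWarnings(associate(x, x, predictor_id = "m", trait_id = "t"))
  expect_equal(r$beta, 1, tolerance = 1e-10)
  expect_lt(r$p, 1e-100)
  expect_true(r$ci_lo <= r$beta && r$beta <= r$ci_hi)

  # beta on standardized data equals cor * sd ratio identity (no covariates)
  y <- 0.4 * x + rnorm(n)
  r2 <- associate(x, y)
  expect_equal(r2$beta, cor(x, y), tolerance = 1e-10)

  # with covariates: matches a direct lm fit on standardized data
  cov <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  r3 <- associate(x, y, cov)
  fit <- lm(scale(y) ~ scale(x) + age + sex, data = cov)
  expect_equal(r3$beta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(r3$p, summary(fit)$coefficients[2, 4], tolerance = 1e-10)

  expect_error(associate(rep(1, n), x), "zero-variance")
  expect_error(associate(rnorm(4), rnorm(4), data.frame(a = rnorm(4))), "degrees")
})

test_that("associate handles missing values by complete-case analysis", {
  set.seed(21)
  x <- rnorm(100); y <- 0.5 * x + rnorm(100)
  y[1:10] <- NA
  r <- associate(x, y)
  expect_equal(r$n, 90)
  r_cc <- associate(x[-(1:10)], y[-(1:10)])
  expect_equal(r$beta, r_cc$beta, tolerance = 1e-12)
})

test_that("BH adjustment: hand cases and brute-force oracle agreement", {
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(22)
  ok <- vapply(1:1000, function(i) {
    p <- runif(sample(1:20, 1))
    identical(bh_fdr(p), bh_oracle(p))
  }, logical(1))
  expect_true(all(ok))
})

test_that("hub selection applies both criteria with borderline fallback", {
  # minimal partition stub: one module "turquoise" with 3 members
  expr <- matrix(rnorm(3 * 50), 3, 50,
                 dimnames = list(c("a", "b", "c"), paste0("s", 1:50)))
  lab <- setNames(c(1L, 1L, 1L), c("a", "b", "c"))
  part <- mirvasc:::new_module_partition(expr, lab)
  part$mm <- matrix(c(0.913, 0.816, 0.79), 3, 1,
                    dimnames = list(c("a", "b", "c"), "turquoise"))
  keys <- data.frame(predictor = "turquoise", trait = "taci_z")
  mk_assoc <- function(p) data.frame(
    predictor = c("a", "b", "c"), trait = "taci_z",
    beta = c(-0.052, 0.03, 0.01), p = p, stringsAsFactors = FALSE)

  # a qualifies (MM .913, p .001); b fails p; c fails MM
  hubs <- select_hubs(part, mk_assoc(c(0.001, 0.056, 0.001)), keys)
  expect_equal(hubs$mirna, "a")
  expect_false(hubs$borderline)

  # nobody qualifies -> borderline fallback picks max MM
  hubs2 <- select_hubs(part, mk_assoc(c(0.2, 0.056, 0.3)), keys)
  expect_equal(hubs2$mirna, "a")
  expect_true(hubs2$borderline)
  expect_equal(nrow(select_hubs(part, mk_assoc(c(0.2, 0.056, 0.3)), keys,
                                borderline = FALSE)), 0)

  # MM exactly at the threshold does not qualify (strict >)
  part$mm[1, 1] <- 0.8
  hubs3 <- select_hubs(part, mk_assoc(c(0.001, 0.2, 0.2)), keys)
  expect_true(hubs3$borderline)
})

test_that("null p-values are uniform and type-I error is calibrated", {
  set.seed(23)
  nsim <- 2000
  pv <- vapply(seq_len(nsim), function(i) {
    associate(rnorm(1000), rnorm(1000))$p
  }, numeric(1))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
  t1 <- mean(pv < 0.05)
  expect_gte(t1, 0.035)
  expect_lte(t1, 0.065)
})

test_that("planted effects are recovered with nominal CI coverage", {
  set.seed(24)
  nsim <- 200
  n <- 2600
  covered <- vapply(seq_len(nsim), function(i) {
    x <- rnorm(n)
    y <- 0.06 * x + rnorm(n)
    r <- associate(x, y)
    truth <- 0.06 / sd(y)          # beta on the standardized outcome scale
    r$ci_lo <= truth && truth <= r$ci_hi
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("FDR family control across module x trait tests", {
  set.seed(25)
  n <- 200
  n_mod <- 14; n_tr <- 7
  any_disc <- vapply(1:500, function(i) {
    E <- matrix(rnorm(n * n_mod), n, n_mod,
                dimnames = list(NULL, paste0("m", 1:n_mod)))
    tt <- as.data.frame(matrix(rnorm(n * n_tr), n, n_tr))
    ma <- associate_modules(E, tt, NULL)
    any(ma$q < 0.05)
  }, logical(1))
  expect_lte(mean(any_disc), 0.10)
})

test_that("interaction models detect planted effect modification", {
  # slope difference 0.15 between strata at n = 2000: SE of the product
  # term is 2/sqrt(n) ~ 0.045, so analytic power ~ 0.92
  set.seed(26)
  hits <- vapply(1:25, function(i) {
    n <- 2000
    young <- rbinom(n, 1, 0.5)
    x <- rnorm(n)
    y <- 0.15 * x * young + rnorm(n)
    r <- interaction_and_strata(x, y, young)
    r$interaction$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # stratified estimates ordered correctly in one large run
  set.seed(27)
  n <- 4000
  age <- runif(n, 30, 95)
  young <- age < median(age)
  x <- rnorm(n)
  y <- 0.15 * x * young + rnorm(n)
  r <- interaction_and_strata(x, y, age)
  expect_lt(r$interaction$p, 0.05)
  expect_false(is.null(r$strata))
  b <- r$strata$beta[match(c("Q1", "Q4"), r$strata$stratum)]
  expect_gt(b[1], b[2])

  expect_error(interaction_and_strata(x, y, rep(1, n)), "constant")
})

test_that("interaction p-values are uniform under the null", {
  set.seed(28)
  pv <- vapply(1:400, function(i) {
    n <- 300
    interaction_and_strata(rnorm(n), rnorm(n), rnorm(n))$interaction$p
  }, numeric(1))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("non-indexed sensitivity analysis: BSA-constant equivalence and BMI attenuation", {
  set.seed(29)
  n <- 400
  E <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("m1", "m2")))
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  tac <- 0.3 * E[, 1] + rnorm(n)
  bsa <- rep(1.9, n)                      # constant BSA
  traits <- data.frame(tac_z = scale(tac)[, 1],
                       taci_z = scale(tac / bsa)[, 1],
                       sv_z = scale(rnorm(n))[, 1],
                       co_z = scale(rnorm(n))[, 1],
                       svr_z = scale(rnorm(n))[, 1])
  r_idx <- associate(E[, 1], traits$taci_z, covs)
  r_non <- associate(E[, 1], traits$tac_z, covs)
  expect_equal(r_idx$beta, r_non$beta, tolerance = 1e-10)

  out <- sensitivity_non_indexed(E, traits, covs, bmi = rnorm(n, 26, 4))
  expect_setequal(unique(out$model), c("non-indexed", "non-indexed+BMI"))
  expect_equal(nrow(out), 2 * 2 * 4)
  expect_error(sensitivity_non_indexed(E, traits, covs, bmi = rep(NA, n)),
               "BMI")

  # planted BMI confounding attenuates after adjustment, sign preserved
  # (the predictor also has a direct effect, so the adjusted beta stays
  # positive but smaller)
  bmi <- rnorm(n, 26, 4)
  x <- 0.4 * scale(bmi)[, 1] + rnorm(n)
  yc <- 0.25 * x + 0.5 * scale(bmi)[, 1] + rnorm(n)
  r_unadj <- associate(x, yc)
  r_adj <- associate(x, yc, data.frame(bmi = bmi))
  expect_lt(abs(r_adj$beta), abs(r_unadj$beta))
  expect_equal(sign(r_adj$beta), sign(r_unadj$beta))
})
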