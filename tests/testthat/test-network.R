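# Network construction: bicor, adjacency, TOM, power selection, tree cut,
# merging, eigenvectors.

test_that("bicor: exact limits, outlier robustness, oracle agreement", {
  x <- rnorm(20)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, -x), -1)

  x <- as.numeric(1:10)
  y <- x; y[10] <- 100
  b <- bicor(x, y)
  expect_gt(b, cor(x, y))            # outlier down-weighted vs Pearson
  expect_equal(b, bicor_oracle(x, y), tolerance = 1e-12)

  set.seed(5)
  for (i in 1:20) {
    u <- rnorm(15); v <- 0.5 * u + rnorm(15)
    expect_equal(bicor(u, v), bicor_oracle(u, v), tolerance = 1e-12)
  }
  expect_error(bicor(rep(1, 10), rnorm(10), fallback = FALSE), "MAD")
})

test_that("bicor_matrix matches pairwise bicor and handles zero-MAD fallback", {
  set.seed(6)
  expr <- matrix(rnorm(8 * 30), 8, 30, dimnames = list(paste0("f", 1:8), NULL))
  bm <- bicor_matrix(expr)
  expect_equal(bm, t(bm))
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(bm[i, j], bicor(expr[i, ], expr[j, ]), tolerance = 1e-12)
  # zero-MAD feature -> Pearson for its pairs
  expr[1, ] <- c(rep(0, 28), 1, 2)   # MAD 0 but not constant
  bm2 <- bicor_matrix(expr)
  expect_equal(bm2[1, 2], cor(expr[1, ], expr[2, ]), tolerance = 1e-12)
})

test_that("signed adjacency endpoints and power law", {
  corr <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(adjacency(corr, 7)[1, 2], 0.5^7)
  corr[1, 2] <- corr[2, 1] <- 1
  expect_equal(adjacency(corr, 7)[1, 2], 1)
  corr[1, 2] <- corr[2, 1] <- -1
  expect_equal(adjacency(corr, 7)[1, 2], 0)
  expect_error(adjacency(corr, 0.5), ">= 1")
})

test_that("TOM: hand example, identical-row maximum, and brute-force oracle", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  expect_equal(tom(a)[1, 2], 0.5)

  # identical rows with a_ij = 1 and full shared neighbourhood: maximal overlap
  a2 <- matrix(1, 3, 3)
  expect_equal(tom(a2)[1, 2], 1)

  set.seed(7)
  for (i in 1:3) {
    r <- matrix(runif(400), 20)
    adj <- (r + t(r)) / 2
    diag(adj) <- 1
    expect_lt(max(abs(tom(adj) - tom_oracle(adj))), 1e-12)
  }
  expect_error(tom(matrix(runif(9), 3)), "symmetric")
})

test_that("TOM output is a valid similarity on random adjacencies", {
  set.seed(8)
  r <- matrix(runif(900), 30)
  adj <- (r + t(r)) / 2; diag(adj) <- 1
  om <- tom(adj)
  expect_equal(om, t(om))
  expect_true(all(om >= 0 & om <= 1))
  expect_equal(unname(diag(om)), rep(1, 30))
})

test_that("soft power selection: determinism, degenerate grid, fit-table oracle", {
  set.seed(9)
  f <- matrix(rnorm(50 * 100), 50, 100)
  expr <- f
  expr[1:25, ] <- 0.9 * matrix(rep(rnorm(100), 25), 25, byrow = TRUE) +
    0.4 * f[1:25, ]
  rownames(expr) <- paste0("f", 1:50)
  s1 <- suppressWarnings(pick_soft_power(expr))
  s2 <- suppressWarnings(pick_soft_power(expr))
  expect_identical(s1$power, s2$power)
  expect_equal(s1$fit_table, s2$fit_table)

  g <- suppressWarnings(pick_soft_power(expr, powers = 1))
  expect_equal(g$power, 1)

  # fit table equals an independent re-computation binning by hand
  corr <- bicor_matrix(expr)
  for (b in c(2, 6)) {
    a <- adjacency(corr, b)
    k <- colSums(a) - 1
    bins <- cut(k, breaks = 10, include.lowest = TRUE)
    fr <- as.numeric(table(bins)) / length(k)
    mk <- as.numeric(tapply(k, bins, mean))
    ok <- fr > 0 & !is.na(mk)
    fit <- lm(log10(fr[ok]) ~ log10(mk[ok]))
    expected <- unname(-sign(coef(fit)[2]) * summary(fit)$r.squared)
    expect_equal(s1$fit_table$fit[s1$fit_table$power == b], expected,
                 tolerance = 1e-12)
  }
})

test_that("hybrid tree cut recovers planted blocks and dissolves small ones", {
  blocks <- c(rep(1, 20), rep(2, 20))
  d <- matrix(0.9, 40, 40)
  d[blocks == 1, blocks == 1] <- 0.1
  d[blocks == 2, blocks == 2] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(paste0("f", 1:40), paste0("f", 1:40))
  lab <- cluster_modules(d)
  expect_equal(length(unique(lab)), 2)
  expect_true(all(table(lab, blocks) %in% c(0, 20)))

  # block of size 4 dissolves below min_size
  blocks2 <- c(rep(1, 20), rep(2, 4))
  d2 <- matrix(0.9, 24, 24)
  d2[blocks2 == 1, blocks2 == 1] <- 0.1
  d2[blocks2 == 2, blocks2 == 2] <- 0.1
  diag(d2) <- 0
  dimnames(d2) <- list(paste0("f", 1:24), paste0("f", 1:24))
  lab2 <- cluster_modules(d2, min_size = 5)
  expect_true(all(lab2[blocks2 == 2] == 0))
  expect_true(all(lab2[blocks2 == 1] == 1))

  # flat dissimilarity -> single module
  d3 <- matrix(0.5, 10, 10); diag(d3) <- 0
  dimnames(d3) <- list(paste0("f", 1:10), paste0("f", 1:10))
  expect_true(all(cluster_modules(d3) == 1))
  # fewer features than min_size -> unassigned with warning
  expect_warning(l4 <- cluster_modules(d3[1:3, 1:3], min_size = 5), "fewer")
  expect_true(all(l4 == 0))
})

test_that("eigenvector: identical features, singleton, and dense-eigen oracle", {
  set.seed(10)
  prof <- rnorm(25)
  mod <- matrix(rep(prof, 4), 4, byrow = TRUE) * c(1, 2, 3, 4) + 1:4
  ev <- eigenvector(mod)
  expect_equal(ev$explained_var, 1, tolerance = 1e-12)
  expect_equal(abs(cor(ev$eigen, prof)), 1, tolerance = 1e-12)
  expect_gte(cor(ev$eigen, rowMeans(scale(t(mod)))), 0)

  single <- matrix(rnorm(25), 1)
  es <- eigenvector(single)
  expect_equal(abs(cor(es$eigen, single[1, ])), 1, tolerance = 1e-12)

  m5 <- matrix(rnorm(5 * 30), 5, 30)
  e5 <- eigenvector(m5)
  cv <- cov(scale(t(m5)))
  ed <- eigen(cv)
  expect_equal(e5$explained_var, ed$values[1] / sum(ed$values),
               tolerance = 1e-8)
  scores <- scale(t(m5)) %*% ed$vectors[, 1]
  expect_equal(abs(cor(e5$eigen, scores[, 1])), 1, tolerance = 1e-10)
})

test_that("module merging: duplicates merge, orthogonal modules do not, chains converge", {
  set.seed(11)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  mk <- function(f, k) t(sapply(seq_len(k), function(i) f + rnorm(n, sd = 0.2)))
  expr <- rbind(mk(f1, 6), mk(f1, 6), mk(f2, 6))
  rownames(expr) <- paste0("f", 1:18)
  colnames(expr) <- paste0("s", 1:n)
  labels <- rep(1:3, each = 6)
  names(labels) <- rownames(expr)
  part <- merge_modules(expr, labels)
  expect_equal(length(part$sizes), 2)        # duplicated module merged
  expect_equal(sort(unname(part$sizes)), c(6, 12))

  # orthogonal eigenvectors: no merge
  part2 <- merge_modules(expr[7:18, ], labels[7:18] - 1L)
  expect_equal(length(part2$sizes), 2)
  expect_equal(part2$merges, 0L)

  # chained similarity collapses to one module regardless of merge order
  g <- rnorm(n)
  exprc <- rbind(mk(g, 6), mk(g, 6), mk(g, 6))
  rownames(exprc) <- paste0("c", 1:18)
  colnames(exprc) <- paste0("s", 1:n)
  partc <- merge_modules(exprc, setNames(rep(1:3, each = 6), rownames(exprc)))
  expect_equal(length(partc$sizes), 1)
})

test_that("module partition invariants: labels, MM bounds, eigen scaling", {
  co <- quiet(simulate_cohort(small_spec(seed = 2)))
  ex <- residualize(normalize_counts(quiet(filter_features(co$mirna_counts))),
                    data.frame(batch = factor(co$samples$batch)))
  net <- quiet(build_network(ex))
  part <- net$partition
  expect_true(all(sort(unique(part$labels[part$labels > 0])) ==
                    seq_along(part$sizes)))
  expect_true(all(abs(part$mm) <= 1 + 1e-12))
  expect_equal(unname(apply(part$eigen, 2, sd)), rep(1, ncol(part$eigen)),
               tolerance = 1e-12)
  expect_true(all(part$sizes >= 5))
  # own-module membership dominates for nearly all assigned features
  assigned <- names(part$labels)[part$labels > 0]
  own_best <- vapply(assigned, function(f) {
    own <- part$colors[f]
    part$mm[f, own] >= max(part$mm[f, ]) - 1e-12
  }, logical(1))
  expect_gte(mean(own_best), 0.95)
})

test_that("planted modules are recovered on synthetic cohorts (ARI)", {
  aris <- vapply(1:3, function(s) {
    co <- quiet(simulate_cohort(sim_spec(seed = s)))
    ex <- residualize(normalize_counts(quiet(filter_features(co$mirna_counts))),
                      data.frame(batch = factor(co$samples$batch)))
    net <- quiet(build_network(ex))
    mclust::adjustedRandIndex(net$partition$labels,
                              co$truth$labels[rownames(ex)])
  }, numeric(1))
  expect_true(all(aris >= 0.8))
})
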