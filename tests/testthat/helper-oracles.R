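# Independent oracle implementations used to cross-check the package: each
# is a literal, brute-force rendering of the definition, kept separate from
# the implementation paths it validates.

# biweight midcorrelation by literal formula evaluation
bicor_oracle <- function(x, y) {
  bw <- function(v) {
    m <- median(v)
    u <- (v - m) / (9 * median(abs(v - m)))
    (1 - u^2)^2 * (abs(u) < 1)
  }
  wx <- bw(x); wy <- bw(y)
  xc <- (x - median(x)) * wx
  yc <- (y - median(y)) * wy
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# topological overlap by naive O(n^3) triple loop
tom_oracle <- function(adj) {
  n <- nrow(adj)
  om <- diag(1, n)
  k <- sapply(seq_len(n), function(i) sum(adj[i, -i]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
    om[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  om
}

# Benjamini-Hochberg step-up by direct definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- (n / seq_len(n)) * p[o]
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# upper-tail hypergeometric p by combinatorial summation
hyper_oracle <- function(x, n_hits, n_bg, n_term) {
  ks <- x:min(n_hits, n_term)
  sum(choose(n_hits, ks) * choose(n_bg - n_hits, n_term - ks)) /
    choose(n_bg, n_term)
}

# LD clump membership by exhaustive transitive closure (per seed order)
clump_oracle <- function(p, r2, pos, chr, r2_locus = 0.6, pad = 1e6) {
  n <- length(p)
  assigned <- rep(NA_integer_, n)
  lid <- 0
  while (anyNA(assigned)) {
    lid <- lid + 1
    seed <- order(p)[which(is.na(assigned[order(p)]))[1]]
    members <- seed
    repeat {
      added <- FALSE
      for (i in which(is.na(assigned))) {
        if (i %in% members) next
        for (m in members) {
          if (r2[i, m] > r2_locus && chr[i] == chr[m] &&
              abs(pos[i] - pos[m]) <= pad) {
            members <- c(members, i); added <- TRUE; break
          }
        }
      }
      if (!added) break
    }
    assigned[members] <- lid
  }
  assigned
}

# compact simulation spec used across tests (small but structured)
small_spec <- function(seed = 1, ...) {
  sim_spec(n_samples = 150, n_mirna = 60,
           module_sizes = c(15, 12, 10),
           gene_spec = list(n_genes = 40, n_targeted = 20, coupling = -0.3,
                            cell_beta = c(ery = 0.1, leu = 0.15, plt = 0.05)),
           genotype_spec = list(n_snps = 40, maf_range = c(0.1, 0.5),
                                block_size = 5, copy_prob = 0.9,
                                eqtl = list(snp = 3, mirna = 1, beta = 0.5,
                                            maf = 0.3)),
           seed = seed, ...)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
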