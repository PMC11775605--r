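# Independent oracles used across test files. Each is a brute-force or
# closed-form computation sharing no code with the implementation paths
# it checks.

# Distribution of the group-A total conditional on the grand total t,
# for nA + nB iid NB(mu, phi) samples, by enumerating every per-sample
# count vector summing to t and multiplying per-sample NB densities.
oracle_cond_dist <- function(t, nA = 2, nB = 2, phi = 0, mu = 7.3) {
  stopifnot(nA == 2, nB == 2)
  g <- expand.grid(y1 = 0:t, y2 = 0:t, y3 = 0:t)
  g <- g[g$y1 + g$y2 + g$y3 <= t, ]
  g$y4 <- t - g$y1 - g$y2 - g$y3
  dens <- function(y) {
    if (phi <= 0) stats::dpois(y, mu, log = TRUE)
    else stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE)
  }
  logw <- dens(g$y1) + dens(g$y2) + dens(g$y3) + dens(g$y4)
  w <- exp(logw - max(logw))
  a <- g$y1 + g$y2
  mass <- vapply(0:t, function(k) sum(w[a == k]), numeric(1))
  mass / sum(mass)
}

oracle_cond_p <- function(a, dist) {
  ks <- seq_along(dist) - 1L
  min(1, 2 * min(sum(dist[ks <= a]), sum(dist[ks >= a])))
}

# Two-sided exact signed-rank p by enumerating all 2^n sign assignments.
oracle_signrank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# Two-sided exact Mann-Whitney p by enumerating all choose(n+m, n)
# assignments of the pooled ranks to the first sample.
oracle_mw_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  sets <- utils::combn(n + m, n)
  w_all <- apply(sets, 2, function(idx) sum(sort(r)[idx])) - n * (n + 1) / 2
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Nei (1972) distance, locus by locus with explicit running sums.
oracle_nei <- function(px, py) {
  sx <- 0; sy <- 0; sxy <- 0
  for (l in seq_along(px)) {
    sx <- sx + px[l]^2 + (1 - px[l])^2
    sy <- sy + py[l]^2 + (1 - py[l])^2
    sxy <- sxy + px[l] * py[l] + (1 - px[l]) * (1 - py[l])
  }
  L <- length(px)
  -log((sxy / L) / sqrt((sx / L) * (sy / L)))
}

# Small simulation config for fast tests.
quick_cfg <- function(seed, n_genes = 600, ...) {
  sim_config(n_genes = n_genes, seed = seed, ...)
}
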