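# Independent brute-force oracles: literal step-by-step walks and exhaustive
# enumerations, kept separate from the package's vectorized implementations.

oracle_walk_es <- function(weights, member, tau = 1, es_mode = "diff") {
  n <- length(weights); m <- sum(member)
  w <- weights^tau
  denom <- sum(w[member])
  run <- 0; dev <- numeric(n)
  for (i in seq_len(n)) {
    run <- if (member[i]) {
      run + (if (denom > 0) w[i] / denom else 1 / m)
    } else {
      run - 1 / (n - m)
    }
    dev[i] <- run
  }
  if (es_mode == "diff") {
    max(c(0, dev)) + min(c(0, dev))
  } else {
    dev[which.max(abs(dev))]
  }
}

oracle_preranked_es <- function(scores, hit, weight_exponent = 1) {
  n <- length(scores); nh <- sum(hit)
  w <- abs(scores)^weight_exponent
  denom <- sum(w[hit])
  run <- 0; dev <- numeric(n)
  for (i in seq_len(n)) {
    run <- if (hit[i]) {
      run + (if (denom > 0) w[i] / denom else 1 / nh)
    } else {
      run - 1 / (n - nh)
    }
    dev[i] <- run
  }
  dev[which.max(abs(dev))]
}

# Exact Mann-Whitney two-sided p by enumerating every group assignment.
oracle_wilcox_p <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  u_obs <- sum(rank(c(x, y))[seq_len(nx)]) - nx * (nx + 1) / 2
  u_null <- apply(utils::combn(n, nx), 2L,
                  function(ix) sum(ix) - nx * (nx + 1) / 2)
  p <- if (u_obs > nx * (n - nx) / 2) 2 * mean(u_null >= u_obs) else
    2 * mean(u_null <= u_obs)
  min(1, p)
}

# Exact two-sided Fisher p by enumerating every table with the margins.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); n1 <- sum(tab[, 1])
  lo <- max(0, n1 - m2); hi <- min(n1, m1)
  dens <- vapply(lo:hi, function(x)
    choose(m1, x) * choose(m2, n1 - x) / choose(m1 + m2, n1), numeric(1))
  d_obs <- dens[a - lo + 1]
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

oracle_binom_p <- function(k, n, p0) {
  dens <- vapply(0:n, function(i)
    choose(n, i) * p0^i * (1 - p0)^(n - i), numeric(1))
  min(1, sum(dens[dens <= dens[k + 1] * (1 + 1e-7)]))
}

oracle_hyper_p <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Two-module simulation used by scoring/classification tests: programs with
# mirrored +/-1 latent activation in two balanced subtypes.
two_program_sim <- function(n_genes = 1000, n_samples = 300, n_members = 50,
                            rho = 0.8, shift = 1, seed = 1) {
  cfg <- sim_config(n_genes, n_samples,
                    modules = list(
                      planted_module("CD133-M", "PROM1", n_members, rho,
                                     c(A = shift, B = -shift)),
                      planted_module("CD44-M", "CD44", n_members, rho,
                                     c(A = -shift, B = shift))),
                    subtype_proportions = c(A = 0.5, B = 0.5),
                    rng_seed = seed)
  sim <- simulate_expression(cfg)
  sim$modules <- list(
    "CD133-M" = names(which(sim$truth$module_membership == "CD133-M")),
    "CD44-M" = names(which(sim$truth$module_membership == "CD44-M")))
  sim$truth_label <- ifelse(sim$truth$sample_subtype == "A",
                            "CD133-M", "CD44-M")
  sim
}
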