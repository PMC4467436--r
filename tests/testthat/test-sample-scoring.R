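test_that("ecdf transform matches direct enumeration", {
  m <- matrix(c(1, 2, 3, 9, 8, 7, 5, 5, 5), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  z <- ecdf_transform(m)
  expect_equal(unname(z["a", ]), c(1 / 3, 2 / 3, 1))
  expect_equal(unname(z["b", ]), c(1, 2 / 3, 1 / 3))
  expect_equal(unname(z["c", ]), c(1, 1, 1))
  expect_equal(attr(z, "constant_genes"), "c")

  m2 <- matrix(c(1, 3, 7, 9), 1, 4, dimnames = list("g", paste0("s", 1:4)))
  m2 <- rbind(m2, other = c(4, 4, 4, 4))
  expect_equal(unname(ecdf_transform(m2)["g", ]), c(0.25, 0.5, 0.75, 1))

  # duplicate sample columns transform identically
  m3 <- matrix(rnorm(40), 10, 4)
  dimnames(m3) <- list(paste0("g", 1:10), paste0("s", 1:4))
  m3[, 2] <- m3[, 1]
  z3 <- ecdf_transform(m3)
  expect_equal(z3[, 1], z3[, 2], ignore_attr = TRUE)
})

test_that("symmetric rank weights |N/2 - rank|", {
  z <- matrix(c(0.9, 0.3, 0.6, 0.1), 4, 1,
              dimnames = list(paste0("g", 1:4), "s1"))
  rk <- sample_rank_statistic(z, "s1")
  expect_equal(rk$weights, c(1, 0, 1, 2))
  expect_equal(rk$genes, c("g1", "g3", "g2", "g4"))
  # middle rank has minimal weight; reversing expression reverses the order
  expect_equal(which.min(rk$weights), 2L)
  rk_rev <- sample_rank_statistic(1 - z, "s1")
  expect_equal(rk_rev$order, rev(rk$order))
})

test_that("random walk ES: hand-computed toy and mirror cases", {
  # uniform weights, 6 genes, set at positions {1,4}
  es <- random_walk_es(rep(1, 6), c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(es, 0.5)
  # set at the top is the maximum over placements; bottom mirror is negative
  w <- c(5, 4, 3, 2, 1, 1)
  placements <- utils::combn(6, 2)
  es_all <- apply(placements, 2L, function(ix) {
    member <- rep(FALSE, 6); member[ix] <- TRUE
    random_walk_es(w, member)
  })
  expect_equal(max(es_all), es_all[1])   # {1,2} placement
  expect_gt(es_all[1], 0)
  expect_lt(es_all[ncol(placements)], 0) # {5,6} placement
  expect_error(random_walk_es(w, c(TRUE, rep(FALSE, 5))), "matched set size")
})

test_that("vectorized walk equals the brute-force oracle on small fixtures", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    w <- runif(n, 0, 3)
    ms <- 2:(n - 2)
    m <- ms[sample.int(length(ms), 1)]
    member <- rep(FALSE, n); member[sample(n, m)] <- TRUE
    tau <- sample(c(0.5, 1, 2), 1)
    for (mode in c("diff", "max")) {
      expect_equal(random_walk_es(w, member, tau, mode),
                   oracle_walk_es(w, member, tau, mode), tolerance = 1e-12)
    }
  }
})

test_that("score_samples composes the stages and matches the oracle end to end", {
  set.seed(11)
  x <- matrix(rnorm(10 * 4), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  sets <- list(S1 = c("g1", "g2", "g3"), S2 = c("g7", "g9"))
  es <- score_samples(x, sets)
  z <- ecdf_transform(x)
  for (j in 1:4) {
    rk <- sample_rank_statistic(z, j)
    for (s in names(sets)) {
      member <- rk$genes %in% sets[[s]]
      expect_equal(es[s, j], oracle_walk_es(rk$weights, member),
                   tolerance = 1e-12)
    }
  }
  # duplicate sample columns give duplicate ES columns
  x2 <- x; x2[, 2] <- x2[, 1]
  es2 <- score_samples(x2, sets)
  expect_equal(es2[, 1], es2[, 2], ignore_attr = TRUE)

  # ES invariant under monotone per-gene transforms
  x3 <- x
  x3[3, ] <- exp(x3[3, ]); x3[8, ] <- x3[8, ]^3
  expect_equal(unclass(score_samples(x3, sets)), unclass(es),
               ignore_attr = TRUE)

  # permuting samples permutes ES columns identically
  perm <- c(3, 1, 4, 2)
  expect_equal(score_samples(x[, perm], sets), es[, perm],
               ignore_attr = TRUE)

  # unmatched sets are skipped with warning; none matching is an error
  expect_warning(score_samples(x, c(sets, list(S3 = "g1"))), "skipping")
  expect_error(score_samples(x, list(S3 = c("zz", "yy"))), "no gene set")
})

test_that("module genes at the top score higher than at the bottom", {
  set.seed(3)
  x <- matrix(rnorm(200), 50, 4,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  x[1:10, 1] <- x[1:10, 1] + 10   # force set genes to the top of sample 1
  x[1:10, 2] <- x[1:10, 2] - 10   # and the bottom of sample 2
  es <- score_samples(x, list(S = paste0("g", 1:10)))
  expect_gt(es["S", "s1"], es["S", "s2"])
  expect_gt(es["S", "s1"], 0)
  expect_lt(es["S", "s2"], 0)
})

test_that("planted-set ES exceeds random same-size sets in the activated subtype", {
  sim <- two_program_sim(n_genes = 400, n_samples = 100, n_members = 20,
                         seed = 6)
  x <- sim$expression
  es <- score_samples(x, sim$modules["CD133-M"])
  a_samples <- names(which(sim$truth$sample_subtype == "A"))
  set.seed(1)
  rand_sets <- lapply(1:1000, function(i)
    sample(rownames(x), 20))
  names(rand_sets) <- paste0("R", 1:1000)
  es_rand <- score_samples(x, rand_sets)
  mean_planted <- mean(es["CD133-M", a_samples])
  q95 <- quantile(rowMeans(es_rand[, a_samples]), 0.95)
  expect_gt(mean_planted, q95)
})

test_that("classification is argmax with first-listed tie break", {
  sc <- matrix(c(0.5, -0.2, 0.3, 0.3), 2, 2,
               dimnames = list(c("CD133-M", "CD44-M"), c("s1", "s2")))
  expect_warning(cl <- classify(sc, c("CD133-M", "CD44-M")), "tie")
  expect_equal(cl$label, c("CD133-M", "CD133-M"))
  expect_equal(cl$margin, c(0.7, 0))
  expect_error(classify(sc, c("CD133-M", "NOPE")), "missing score")
})

test_that("two-program recovery approaches the latent-model accuracy ceiling", {
  sim <- two_program_sim(seed = 21)
  es <- score_samples(sim$expression, sim$modules)
  cl <- classify(es, c("CD133-M", "CD44-M"))
  acc <- mean(cl$label == sim$truth_label[cl$sample])
  # Bayes accuracy for +/-1 latent activation is pnorm(sqrt(2)) ~ 0.921
  expect_gt(acc, 0.85)
  expect_lt(acc, pnorm(sqrt(2)) + 3 * sqrt(0.08 * 0.92 / 300))
})
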