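test_that("flip neighborhoods match direct enumeration", {
  # additions allowed below the boundary, removals only at it
  expect_equal(neighborhood_size(regulatory_config(c(1, 0, 0, 0, 0)), k = 3), 5)
  expect_equal(neighborhood_size(regulatory_config(c(1, 1, 0, 0, 0)), k = 3), 2)
  expect_equal(neighborhood_size(regulatory_config(c(0, 0, 0, 0, 0)), k = 3), 5)
  expect_error(neighborhood(regulatory_config(c(1, 1, 1)), k = 3), "restricted")

  # cross-check the closed form against exhaustive flip enumeration
  for (n_r in 3:6) {
    for (k in 2:min(n_r, 4)) {
      for (size in 0:(k - 1)) {
        bits <- integer(n_r); if (size > 0) bits[seq_len(size)] <- 1L
        legal <- sum(vapply(seq_len(n_r), function(j) {
          b <- bits; b[j] <- 1L - b[j]
          sum(b) < k
        }, logical(1)))
        expect_equal(neighborhood_size(regulatory_config(bits), k), legal)
      }
    }
  }
})

test_that("proposals are uniform over the neighborhood", {
  set.seed(11)
  cfg <- regulatory_config(c(1, 0, 0, 0, 0))  # |eta| = 5 at k = 3
  draws <- replicate(10000, {
    p <- propose(cfg, k = 3)
    which(as.integer(p$config) != as.integer(cfg))
  })
  freq <- tabulate(draws, nbins = 5) / 10000
  expect_true(all(abs(freq - 0.2) < 0.02))
})

test_that("boundary proposals are removals with the right Hastings sizes", {
  set.seed(12)
  cfg <- regulatory_config(c(1, 1, 0, 0, 0))  # size = k - 1 for k = 3
  for (i in 1:50) {
    p <- propose(cfg, k = 3)
    expect_equal(config_size(p$config), 1)    # never an addition
    expect_equal(p$fwd, 2)                    # |eta| = n_i at the boundary
    expect_equal(p$rev, 5)                    # |eta| = n_r below it
  }
})

test_that("acceptance probability implements the Hastings ratio", {
  expect_equal(acceptance_probability(-3.5, -3.5, 4, 4), 1)
  expect_equal(acceptance_probability(-1, -Inf, 4, 4), 0)
  expect_equal(acceptance_probability(-2, -2 + log(2), 5, 5), 1)  # capped
  expect_equal(acceptance_probability(-2, -2, 2, 5), 2 / 5)
  expect_error(acceptance_probability(-Inf, -1, 2, 2), "finite")
})

test_that("chains are deterministic given a seed and respect the restriction", {
  sim <- toy_simulation(n = 6, seed = 3)
  pr <- build_problem(sim$data, "g1", paste0("g", 2:6))
  st <- chain_settings(iterations = 4000, seed = 99, k = 3)
  t1 <- run_chain(pr, flat_prior(), st)
  t2 <- run_chain(pr, flat_prior(), st)
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$score_trace, t2$score_trace)
  expect_true(all(rowSums(t1$samples) < 3))
  expect_equal(t1$n_s, nrow(t1$samples))
})

test_that("edge probabilities are inclusion frequencies", {
  tr <- manual_trace(rbind(c(1, 0), c(1, 1), c(0, 1), c(1, 0)))
  expect_equal(unname(edge_probabilities(tr)), c(0.75, 0.5))
  expect_equal(unname(edge_probabilities(manual_trace(rbind(c(0, 0, 0))))),
               c(0, 0, 0))
  expect_equal(unname(edge_probabilities(manual_trace(rbind(c(1, 0, 1))))),
               c(1, 0, 1))
})

test_that("exhaustive enumeration normalizes and matches the two-model case", {
  m <- rbind(g1 = c(1, 2, 4, 3, 6), g2 = c(1, 2, 3, 5, 5))
  d <- expression_dataset(m, perturbation_ids = paste0("p", 1:5))
  pr <- build_problem(d, "g1", "g2")
  marg <- exact_posterior(pr, flat_prior(), k = 2)
  s0 <- log_posterior_score(pr, regulatory_config(0L), flat_prior(), 2)$log_score
  s1 <- log_posterior_score(pr, regulatory_config(1L), flat_prior(), 2)$log_score
  expect_equal(unname(marg), exp(s1) / (exp(s0) + exp(s1)), tolerance = 1e-12)
})

test_that("MCMC edge probabilities converge to the exact marginals", {
  errs <- vapply(1:2, function(s) {
    sim <- toy_simulation(n = 6, n_p = NULL, seed = 20 + s, noise_sd = 0.1)
    tg <- sim$data$gene_ids[1]
    cand <- setdiff(sim$data$gene_ids, tg)
    pr <- build_problem(sim$data, tg, cand)
    ex <- exact_posterior(pr, flat_prior(), k = 3)
    tr <- run_chain(pr, flat_prior(),
                    chain_settings(iterations = 50000, seed = s, k = 3))
    max(abs(ex - edge_probabilities(tr)))
  }, numeric(1))
  expect_true(all(errs < 0.02))
})

test_that("empirical transitions between neighboring states are balanced", {
  sim <- toy_simulation(n = 5, seed = 31, noise_sd = 0.5)
  pr <- build_problem(sim$data, "g1", paste0("g", 2:5))
  tr <- run_chain(pr, flat_prior(),
                  chain_settings(iterations = 120000, seed = 5, k = 3))
  keys <- apply(tr$samples, 1, paste, collapse = "")
  a <- "0000"; b <- "1000"
  ab <- sum(keys[-length(keys)] == a & keys[-1] == b)
  ba <- sum(keys[-length(keys)] == b & keys[-1] == a)
  expect_gt(min(ab, ba), 100)           # both directions well sampled
  expect_lt(abs(log(ab / ba)), 0.2)     # detailed balance within MC error
})

test_that("sampled model sizes track the enumerated size distribution", {
  sim <- toy_simulation(n = 7, seed = 41, noise_sd = 1)
  cand <- paste0("g", 2:7)
  pr <- build_problem(sim$data, "g1", cand)
  k <- 4
  tr <- run_chain(pr, sparse_prior(),
                  chain_settings(iterations = 120000, seed = 8, k = k))
  emp <- tabulate(rowSums(tr$samples) + 1L, nbins = k) / tr$n_s
  # exact size distribution from full enumeration under the same posterior
  sizes <- 0:(k - 1)
  logw <- c(); szs <- c()
  for (m in sizes) {
    sets <- if (m == 0) list(integer(0)) else utils::combn(6, m, simplify = FALSE)
    for (sel in sets) {
      bits <- integer(6); bits[sel] <- 1L
      logw <- c(logw, log_posterior_score(pr, regulatory_config(bits),
                                          sparse_prior(), k)$log_score)
      szs <- c(szs, m)
    }
  }
  w <- exp(logw - max(logw)); w <- w / sum(w)
  exact_sz <- vapply(sizes, function(m) sum(w[szs == m]), numeric(1))
  expect_lt(max(abs(emp - exact_sz)), 0.02)
  # and the sparse prior shifts mass to smaller models than the flat prior
  tr_flat <- run_chain(pr, flat_prior(),
                       chain_settings(iterations = 120000, seed = 8, k = k))
  expect_lt(mean(rowSums(tr$samples)), mean(rowSums(tr_flat$samples)))
})

test_that("network inference fills only defined candidate pairs", {
  sim <- toy_simulation(n = 6, seed = 51)
  st <- chain_settings(iterations = 3000, seed = 1, k = 3)
  post <- infer_network(sim$data, settings = st)
  expect_true(all(is.na(diag(post$probabilities))))
  off <- post$probabilities[row(post$probabilities) != col(post$probabilities)]
  expect_true(all(off >= 0 & off <= 1))

  tf <- paste0("g", 1:3)
  post_tf <- infer_network(sim$data, candidates = tf, settings = st)
  expect_true(all(is.na(post_tf$probabilities[, c("g4", "g5", "g6")])))
  expect_true(all(!is.na(post_tf$probabilities["g4", tf])))

  expect_error(infer_network(sim$data, candidates = "gX", settings = st),
               "not in dataset")
})

test_that("per-gene seeds make inference order-independent and reproducible", {
  sim <- toy_simulation(n = 5, seed = 61)
  st <- chain_settings(iterations = 3000, seed = 4, k = 3)
  full <- infer_network(sim$data, settings = st)
  partial <- infer_network(sim$data, settings = st, targets = c("g4", "g2"))
  expect_equal(partial$probabilities["g2", ], full$probabilities["g2", ])
  expect_equal(partial$probabilities["g4", ], full$probabilities["g4", ])
  expect_identical(derive_seed(7, 3), derive_seed(7, 3))
  expect_false(derive_seed(7, 3) == derive_seed(7, 4))
})

test_that("self-perturbation columns are excluded from a gene's regression", {
  net <- generate_network(6, mean_degree = 2, seed = 71)
  d <- simulate_perturbations(net, noise_sd = 0.05, seed = 72)
  expect_equal(d$perturbed_genes, d$gene_ids)
  st <- chain_settings(iterations = 3000, seed = 2, k = 3)
  post_excl <- infer_network(d, settings = st)
  # manual exclusion must reproduce the default path exactly
  keep <- d$perturbed_genes != "g1"
  pr <- build_problem(subset_perturbations(d, keep), "g1", paste0("g", 2:6))
  gs <- st; gs$seed <- derive_seed(st$seed, 1)
  tr <- run_chain(pr, flat_prior(), gs)
  expect_equal(unname(post_excl$probabilities["g1", paste0("g", 2:6)]),
               unname(edge_probabilities(tr)))
})
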