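test_that("confusion rates follow the TPR/FPR/precision definitions", {
  genes <- c("t1", "t2", "t3", "r1", "r2")
  pairs <- data.frame(
    target = c("t1", "t1", "t2", "t2", "t3", "t3"),
    regulator = c("r1", "r2", "r1", "r2", "r1", "r2"),
    probability = c(0.9, 0.8, 0.7, 0.1, 0.1, 0.1))
  post <- manual_posterior(genes, pairs)
  gold <- gold_standard(data.frame(target = c("t1", "t1"),
                                   regulator = c("r1", "r2")),
                        regulator_mask = c("r1", "r2"))
  cm <- confusion_at_threshold(post, gold, tau = 0.5)
  expect_equal(unname(cm["tpr"]), 1)          # both true edges called
  expect_equal(unname(cm["fpr"]), 0.25)       # 1 of 4 non-edges called
  expect_equal(unname(cm["precision"]), 2 / 3)

  high <- confusion_at_threshold(post, gold, tau = 0.95)
  expect_equal(unname(high), c(0, 0, 1))      # empty call set convention
  low <- confusion_at_threshold(post, gold, tau = -1e-9)
  expect_equal(unname(low[c("tpr", "fpr")]), c(1, 1))
})

test_that("rates are within [0,1] and monotone in the threshold", {
  set.seed(5)
  genes <- c(paste0("t", 1:10), paste0("r", 1:4))
  pairs <- expand.grid(target = paste0("t", 1:10), regulator = paste0("r", 1:4),
                       stringsAsFactors = FALSE)
  pairs$probability <- runif(nrow(pairs))
  post <- manual_posterior(genes, pairs)
  gold <- gold_standard(pairs[sample(nrow(pairs), 8), c("target", "regulator")],
                        regulator_mask = paste0("r", 1:4))
  taus <- seq(-0.01, 1, by = 0.05)
  cm <- t(vapply(taus, function(tau) confusion_at_threshold(post, gold, tau),
                 numeric(3)))
  expect_true(all(cm >= 0 & cm <= 1))
  expect_true(all(diff(cm[, "tpr"]) <= 0))
  expect_true(all(diff(cm[, "fpr"]) <= 0))
})

test_that("perfect and inverted rankings give AUROC 1 and 0", {
  genes <- c("t1", "t2", "r1", "r2")
  pairs <- expand.grid(target = c("t1", "t2"), regulator = c("r1", "r2"),
                       stringsAsFactors = FALSE)
  gold <- gold_standard(data.frame(target = "t1", regulator = c("r1", "r2")),
                        regulator_mask = c("r1", "r2"))
  pairs$probability <- ifelse(pairs$target == "t1", 0.9, 0.2)
  expect_equal(roc_pr_curves(manual_posterior(genes, pairs), gold)$auroc, 1)
  pairs$probability <- ifelse(pairs$target == "t1", 0.2, 0.9)
  expect_equal(roc_pr_curves(manual_posterior(genes, pairs), gold)$auroc, 0)
})

test_that("random probabilities score near chance level", {
  genes <- c(paste0("t", 1:50), paste0("r", 1:4))
  pairs <- expand.grid(target = paste0("t", 1:50), regulator = paste0("r", 1:4),
                       stringsAsFactors = FALSE)
  aurocs <- vapply(1:5, function(s) {
    set.seed(s)
    pairs$probability <- runif(nrow(pairs))
    gold <- gold_standard(pairs[sample(nrow(pairs), 50), c("target", "regulator")],
                          regulator_mask = paste0("r", 1:4))
    roc_pr_curves(manual_posterior(genes, pairs), gold)$auroc
  }, numeric(1))
  expect_true(all(abs(aurocs - 0.5) < 0.1))
})

test_that("curve integration matches an independent ROC implementation", {
  set.seed(17)
  genes <- c(paste0("t", 1:30), paste0("r", 1:5))
  pairs <- expand.grid(target = paste0("t", 1:30), regulator = paste0("r", 1:5),
                       stringsAsFactors = FALSE)
  pairs$probability <- round(runif(nrow(pairs)), 2)  # force ties
  gold <- gold_standard(pairs[sample(nrow(pairs), 30), c("target", "regulator")],
                        regulator_mask = paste0("r", 1:5))
  ev <- roc_pr_curves(manual_posterior(genes, pairs), gold)
  keys <- paste(pairs$target, pairs$regulator)
  gkeys <- paste(gold$edges$target, gold$edges$regulator)
  oracle <- pROC::auc(pROC::roc(response = as.integer(keys %in% gkeys),
                                predictor = pairs$probability,
                                direction = "<", quiet = TRUE))
  expect_equal(ev$auroc, as.numeric(oracle), tolerance = 1e-10)
})

test_that("hand-enumerated two-edge curves are reproduced exactly", {
  genes <- c("t1", "t2", "r1")
  pairs <- data.frame(target = c("t1", "t2"), regulator = "r1",
                      probability = c(0.8, 0.3))
  gold <- gold_standard(data.frame(target = "t1", regulator = "r1"),
                        regulator_mask = "r1")
  ev <- roc_pr_curves(manual_posterior(genes, pairs), gold)
  # thresholds 0.8, 0.3, -eps: (fpr, tpr) = (0,0), (0,1), (1,1)
  expect_equal(ev$roc$fpr, c(0, 0, 1))
  expect_equal(ev$roc$tpr, c(0, 1, 1))
  expect_equal(ev$auroc, 1)
  # PR anchored at recall 0 with the first defined precision (tau = 0.3)
  expect_equal(ev$pr$recall, c(0, 1, 1))
  expect_equal(ev$pr$precision, c(1, 1, 0.5))
  expect_equal(ev$aupr, 1)
})

test_that("AUROC is invariant under monotone transforms of the probabilities", {
  set.seed(23)
  genes <- c(paste0("t", 1:20), "r1", "r2")
  pairs <- expand.grid(target = paste0("t", 1:20), regulator = c("r1", "r2"),
                       stringsAsFactors = FALSE)
  pairs$probability <- runif(nrow(pairs))
  gold <- gold_standard(pairs[sample(nrow(pairs), 10), c("target", "regulator")],
                        regulator_mask = c("r1", "r2"))
  a1 <- roc_pr_curves(manual_posterior(genes, pairs), gold)$auroc
  pairs$probability <- pairs$probability^3
  a2 <- roc_pr_curves(manual_posterior(genes, pairs), gold)$auroc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("a new true edge at top rank never hurts AUROC or AUPR", {
  set.seed(29)
  genes <- c(paste0("t", 1:12), "r1", "rx")
  pairs <- expand.grid(target = paste0("t", 1:12), regulator = "r1",
                       stringsAsFactors = FALSE)
  pairs$probability <- runif(nrow(pairs))
  gold_edges <- pairs[sample(nrow(pairs), 4), c("target", "regulator")]
  base <- roc_pr_curves(manual_posterior(genes, pairs),
                        gold_standard(gold_edges, c("r1", "rx")))
  extra <- rbind(pairs, data.frame(target = "t1", regulator = "rx",
                                   probability = 0.999))
  gold2 <- gold_standard(rbind(gold_edges,
                               data.frame(target = "t1", regulator = "rx")),
                         c("r1", "rx"))
  grown <- roc_pr_curves(manual_posterior(genes, extra), gold2)
  expect_gte(grown$auroc, base$auroc)
  expect_gte(grown$aupr, base$aupr)
})

test_that("gold edges outside the evaluation universe are dropped with notice", {
  genes <- c("t1", "t2", "r1")
  pairs <- data.frame(target = c("t1", "t2"), regulator = "r1",
                      probability = c(0.8, 0.3))
  gold <- gold_standard(data.frame(target = c("t1", "zz"),
                                   regulator = c("r1", "r1")),
                        regulator_mask = "r1")
  expect_message(ev <- roc_pr_curves(manual_posterior(genes, pairs), gold),
                 "outside the evaluation universe")
  expect_equal(ev$auroc, 1)
  # no overlap between mask and posterior regulators is an error
  bad <- gold_standard(data.frame(target = "t1", regulator = "q"),
                       regulator_mask = "q")
  expect_error(suppressMessages(
    roc_pr_curves(manual_posterior(genes, pairs), bad)), "no overlap")
})

test_that("network correlation behaves as a Pearson similarity", {
  sim <- toy_simulation(n = 5, seed = 81)
  st <- chain_settings(iterations = 3000, seed = 3, k = 3)
  post <- infer_network(sim$data, settings = st)
  expect_equal(network_correlation(post, post), 1)

  # complementary binary prior networks anticorrelate perfectly
  g <- c("a", "b", "c")
  w1 <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3, byrow = TRUE,
               dimnames = list(g, g))
  w2 <- (1 - w1); diag(w2) <- 0
  mk <- function(w) structure(list(weights = w,
                                   provenance = ifelse(w != 0, "direct", "none"),
                                   alpha_c = 1, gene_ids = g),
                              class = "prior_network")
  expect_equal(network_correlation(mk(w1), mk(w2)), -1)

  # constant vectors have no defined correlation
  const <- manual_posterior(g, data.frame(target = c("a", "a"),
                                          regulator = c("b", "c"),
                                          probability = c(0.4, 0.4)))
  expect_error(network_correlation(const, post), "zero variance|shared")
})

test_that("rank-sum comparison matches hand-ranked cases", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$U, 0)          # complete separation
  expect_lt(rs$p, 0.05)
  same <- rank_sum_test(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(same$U, 8)        # n1 n2 / 2 under exchangeability
  expect_equal(same$p, 1, tolerance = 1e-12)
  expect_error(rank_sum_test(c(1, 1), c(1, 1)), "degenerate")
  expect_error(rank_sum_test(1, c(1, 2)), "at least two")
})

test_that("replicated benchmarking reports per-prior tables and curves", {
  sim <- toy_simulation(n = 6, seed = 91, noise_sd = 0.1)
  gold <- gold_standard(network_edges(sim$network),
                        regulator_mask = sim$data$gene_ids)
  bench <- replicate_runner(
    sim$data,
    priors = list(flat = flat_prior(), sparse = sparse_prior()),
    gold = gold,
    settings = chain_settings(iterations = 2000, seed = 13, k = 3),
    n_replicates = 2)
  expect_equal(nrow(bench$summary), 4)
  expect_setequal(bench$table$prior, c("flat", "sparse"))
  expect_equal(dim(bench$p_values), c(2, 2))
  expect_equal(nrow(bench$avg_curves$flat$roc), 101)
  expect_true(all(bench$summary$auroc >= 0 & bench$summary$auroc <= 1))
})
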