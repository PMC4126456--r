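# Programmatic fixtures shared across test files. Everything is generated,
# nothing is stored on disk.

# small dataset with explicit values (no self-perturbation annotation)
toy_dataset <- function() {
  m <- rbind(g1 = c(1, 2, 4, 3),
             g2 = c(1, 2, 3, 5),
             g3 = c(2, 0, 1, 4))
  expression_dataset(m, perturbation_ids = paste0("p", 1:4))
}

# synthetic network + knockdown dataset
toy_simulation <- function(n = 6, n_p = NULL, seed = 1, noise_sd = 0.1,
                           mean_degree = 2) {
  net <- generate_network(n, mean_degree = mean_degree, seed = seed)
  data <- simulate_perturbations(net, noise_sd = noise_sd,
                                 seed = derive_seed(seed, 2), n_p = n_p)
  list(network = net, data = data)
}

# a random regression problem with gaussian rows (no network structure)
random_problem <- function(n_r, n_p, seed) {
  set.seed(seed)
  m <- matrix(rnorm((n_r + 1) * n_p), n_r + 1, n_p)
  d <- expression_dataset(m, gene_ids = paste0("g", seq_len(n_r + 1)),
                          perturbation_ids = paste0("p", seq_len(n_p)))
  build_problem(d, "g1", paste0("g", 2:(n_r + 1)))
}

# hand-made posterior network over arbitrary defined pairs
manual_posterior <- function(gene_ids, pairs) {
  n <- length(gene_ids)
  probs <- matrix(NA_real_, n, n, dimnames = list(gene_ids, gene_ids))
  for (r in seq_len(nrow(pairs))) {
    probs[pairs$target[r], pairs$regulator[r]] <- pairs$probability[r]
  }
  structure(
    list(probabilities = probs, gene_ids = gene_ids,
         candidates = unique(pairs$regulator), targets = unique(pairs$target),
         acceptance_rates = NULL, k = NA_integer_, settings = NULL),
    class = "posterior_network")
}

# manual sample trace for estimator tests
manual_trace <- function(samples, candidate_ids = NULL) {
  samples <- as.matrix(samples)
  if (is.null(candidate_ids)) candidate_ids <- paste0("g", seq_len(ncol(samples)))
  structure(
    list(samples = samples, n_s = nrow(samples),
         score_trace = numeric(nrow(samples)), accept_count = 0,
         acceptance_rate = NA_real_, k = ncol(samples) + 1L,
         candidate_ids = candidate_ids),
    class = "sample_trace")
}
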