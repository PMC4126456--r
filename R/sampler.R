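#' Chain settings for the configuration sampler
#'
#' @param iterations total Metropolis-Hastings iterations (default 50000).
#' @param burn_in iterations discarded before recording; default 10% of
#'   `iterations`.
#' @param thinning keep every `thinning`-th post-burn-in state (default 1).
#' @param seed master seed; per-gene and per-replicate seeds are derived
#'   deterministically from it (see [derive_seed()]).
#' @param k restriction parameter: only configurations with fewer than `k`
#'   regulators are explored. Must satisfy `2 <= k <= n_p`. `NULL` defers the
#'   choice to [infer_network()] (which uses [restriction_parameter()] when a
#'   prior network is supplied, and `n_p` otherwise).
#' @return object of class `chain_settings`.
#' @export
chain_settings <- function(iterations = 50000, burn_in = NULL, thinning = 1,
                           seed = 1, k = NULL) {
  iterations <- as.integer(iterations)
  if (is.null(burn_in)) burn_in <- floor(iterations / 10)
  burn_in <- as.integer(burn_in)
  thinning <- as.integer(thinning)
  if (iterations < 1) stop("iterations must be positive", call. = FALSE)
  if (burn_in < 0 || burn_in >= iterations) {
    stop("burn_in must lie in [0, iterations)", call. = FALSE)
  }
  if (thinning < 1) stop("thinning must be at least 1", call. = FALSE)
  structure(
    list(iterations = iterations, burn_in = burn_in, thinning = thinning,
         seed = as.integer(seed), k = if (is.null(k)) NULL else as.integer(k)),
    class = "chain_settings"
  )
}

#' Single-bit-flip neighborhood within the restricted space
#'
#' The neighborhood of a configuration consists of all single-bit flips that
#' stay inside the restricted space (size < k): removals are always legal;
#' additions only when the result still has fewer than k ones. Hence the
#' neighborhood size is `n_r` when the current size is at most `k - 2`, and
#' `n_i` (removals only) at the boundary `n_i = k - 1`.
#'
#' @param config a `regulatory_config` with size < k.
#' @param k restriction parameter.
#' @return list with `flips` (positions whose flip is legal) and `size`.
#' @export
neighborhood <- function(config, k) {
  bits <- as.integer(config)
  n_i <- config_size(config)
  if (n_i >= k) stop("configuration outside the restricted space", call. = FALSE)
  if (n_i <= k - 2) {
    flips <- seq_along(bits)
  } else {
    flips <- which(bits == 1L)
  }
  list(flips = flips, size = length(flips))
}

#' @rdname neighborhood
#' @export
neighborhood_size <- function(config, k) neighborhood(config, k)$size

#' Propose a neighboring configuration
#'
#' Draws uniformly from the single-bit-flip neighborhood and returns both
#' endpoint neighborhood sizes, which the Hastings correction needs because
#' neighborhoods are asymmetric at the size boundary. Uses R's RNG.
#'
#' @param config a `regulatory_config` with size < k.
#' @param k restriction parameter.
#' @return list with `config` (proposed `regulatory_config`), `fwd`
#'   (neighborhood size of the current state) and `rev` (of the proposal).
#' @export
propose <- function(config, k) {
  nb <- neighborhood(config, k)
  if (nb$size < 1) stop("empty proposal neighborhood", call. = FALSE)
  flip <- nb$flips[sample.int(nb$size, 1)]
  bits <- as.integer(config)
  bits[flip] <- 1L - bits[flip]
  prop <- regulatory_config(bits)
  list(config = prop, fwd = nb$size, rev = neighborhood_size(prop, k))
}

#' Metropolis-Hastings acceptance probability
#'
#' `min(1, exp(s' - s + log(fwd) - log(rev)))` where s and s' are the current
#' and proposed log scores; the `fwd/rev` factor is the Hastings correction
#' for the asymmetric flip neighborhoods. A proposal with `-Inf` score is
#' never accepted.
#'
#' @param current,proposed `model_score` objects or plain log-score numbers.
#' @param fwd,rev neighborhood sizes of the current and proposed states.
#' @return acceptance probability in \[0, 1\].
#' @export
acceptance_probability <- function(current, proposed, fwd, rev) {
  s_cur <- if (inherits(current, "model_score")) current$log_score else current
  s_prop <- if (inherits(proposed, "model_score")) proposed$log_score else proposed
  if (!is.finite(s_cur)) stop("current log score must be finite", call. = FALSE)
  if (s_prop == -Inf) return(0)
  min(1, exp(s_prop - s_cur + log(fwd) - log(rev)))
}

#' Run one Metropolis-Hastings chain for a gene
#'
#' Samples regulator configurations for the target gene of `problem` from
#' the g-prior posterior restricted to sizes below `settings$k`. The chain
#' starts from a sparse random configuration (each candidate included with
#' probability `min(0.5, (k-1)/(2 n_r))`, resampled until admissible),
#' proposes uniform single-bit flips, and re-records the current state on
#' rejection. The hot loop runs in compiled code with per-configuration
#' score memoization; R's RNG (seeded from `settings$seed`) drives every
#' random draw, so equal seeds give identical traces.
#'
#' @param problem a `regression_problem`.
#' @param prior a `bvs_prior` evaluator.
#' @param settings a `chain_settings` with non-`NULL` `k` (`2 <= k <= n_p`).
#' @param cond_cap condition-number cap for identifiability.
#' @return object of class `sample_trace`: list with `samples` (n_s x n_r
#'   0/1 matrix, post burn-in and thinning), `n_s`, `score_trace`,
#'   `accept_count`, `acceptance_rate`, `k`.
#' @export
run_chain <- function(problem, prior, settings, cond_cap = 1e10) {
  stopifnot(inherits(problem, "regression_problem"),
            inherits(prior, "bvs_prior"),
            inherits(settings, "chain_settings"))
  k <- settings$k
  if (is.null(k)) stop("settings$k must be set for run_chain", call. = FALSE)
  if (k > problem$n_p) {
    stop("k must not exceed the number of perturbations", call. = FALSE)
  }
  if (k < 2) stop("k must be at least 2 for sampling", call. = FALSE)

  enc <- encode_prior(prior, problem)
  set.seed(settings$seed)
  res <- .run_chain_cpp(problem$design, problem$response, k,
                        settings$iterations, settings$burn_in,
                        settings$thinning, enc$type, enc$alpha, enc$beta,
                        enc$gamma_row, cond_cap)
  if (res$unidentifiable_count > 0) {
    warning(res$unidentifiable_count,
            " unidentifiable configuration(s) scored -Inf", call. = FALSE)
  }
  structure(
    list(samples = res$samples,
         n_s = res$n_s,
         score_trace = as.numeric(res$score_trace),
         accept_count = res$accept_count,
         acceptance_rate = res$accept_count / settings$iterations,
         k = k,
         candidate_ids = problem$candidate_ids),
    class = "sample_trace"
  )
}

encode_prior <- function(prior, problem) {
  if (inherits(prior, "flat_prior")) {
    list(type = 0L, alpha = 1, beta = 1, gamma_row = numeric(problem$n_r))
  } else if (inherits(prior, "sparse_prior")) {
    list(type = 1L, alpha = prior$alpha, beta = prior$beta,
         gamma_row = numeric(problem$n_r))
  } else if (inherits(prior, "network_prior")) {
    list(type = 2L, alpha = 1, beta = 1,
         gamma_row = prior_gamma_row(prior$network, problem$target_id,
                                     problem$candidate_ids))
  } else {
    stop("unsupported prior evaluator", call. = FALSE)
  }
}

#' Posterior edge probabilities from a trace
#'
#' Element j is the fraction of recorded samples whose j-th bit is 1
#' (`n_ij / n_s`).
#'
#' @param trace a `sample_trace` with at least one sample.
#' @return numeric probability vector over the problem's candidates.
#' @export
edge_probabilities <- function(trace) {
  stopifnot(inherits(trace, "sample_trace"))
  if (trace$n_s < 1) stop("empty trace", call. = FALSE)
  p <- colMeans(trace$samples)
  names(p) <- trace$candidate_ids
  p
}

#' Exact posterior edge marginals by exhaustive enumeration
#'
#' Enumerates every configuration with fewer than k regulators, normalizes
#' the posterior scores by log-sum-exp, and returns the exact marginal
#' inclusion probability of each candidate. Only feasible for small spaces;
#' serves as the reference the Monte-Carlo estimates are validated against.
#'
#' @param problem a `regression_problem`.
#' @param prior a `bvs_prior` evaluator.
#' @param k restriction parameter.
#' @param max_configs enumeration guard (default 1e6).
#' @return named numeric vector of marginal probabilities.
#' @export
exact_posterior <- function(problem, prior, k, max_configs = 1e6) {
  stopifnot(inherits(problem, "regression_problem"))
  n_r <- problem$n_r
  sizes <- 0:(k - 1)
  total <- sum(choose(n_r, sizes))
  if (total > max_configs) {
    stop("configuration space too large to enumerate (", total, ")",
         call. = FALSE)
  }
  logw <- numeric(total)
  members <- vector("list", total)
  idx <- 0L
  for (m in sizes) {
    sets <- if (m == 0) list(integer(0)) else
      utils::combn(n_r, m, simplify = FALSE)
    for (sel in sets) {
      bits <- integer(n_r)
      bits[sel] <- 1L
      idx <- idx + 1L
      sc <- log_posterior_score(problem, regulatory_config(bits), prior, k)
      logw[idx] <- sc$log_score
      members[[idx]] <- sel
    }
  }
  mx <- max(logw)
  w <- exp(logw - mx)
  w <- w / sum(w)
  marg <- numeric(n_r)
  for (i in seq_len(total)) {
    marg[members[[i]]] <- marg[members[[i]]] + w[i]
  }
  names(marg) <- problem$candidate_ids
  marg
}

#' Derive a reproducible sub-seed
#'
#' Deterministically mixes a master seed with one or more stream indices
#' (gene index, replicate number, ...) using a multiplicative congruential
#' fold modulo a prime below 2^31, so per-gene chains and per-replicate runs
#' are independent yet reproducible.
#'
#' @param seed master integer seed.
#' @param ... integer stream indices.
#' @return integer seed in \[1, 2147483586\].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483587
  s <- as.numeric(seed) %% m
  for (x in c(...)) {
    s <- (s * 48271 + as.numeric(x)) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

#' Infer a posterior network over all target genes
#'
#' Runs one restricted Metropolis-Hastings chain per target gene (candidates
#' are the supplied regulator set minus the target itself) and assembles the
#' posterior edge-probability matrix: entry (i, j) estimates
#' `P(A_ij = 1 | data)`, the probability that gene j regulates gene i.
#' Entries outside the candidate set and the diagonal are `NA` (undefined,
#' not zero). Per-gene seeds are derived from `settings$seed` and the target
#' index, so results do not depend on execution order.
#'
#' @param dataset an `expression_dataset`.
#' @param candidates character vector of candidate regulator gene ids, or
#'   `"all"` (default) for every gene in the dataset.
#' @param prior a `bvs_prior`; defaults to the flat prior.
#' @param settings a `chain_settings`. If `settings$k` is `NULL`, k is taken
#'   from [restriction_parameter()] when `prior` is a network prior, and
#'   from the number of perturbations otherwise.
#' @param targets optional character vector of target genes to infer rows
#'   for (default: all genes in the dataset).
#' @param exclude_self_perturbations when `TRUE` (default) and the dataset
#'   annotates which gene each perturbation directly targets, the columns
#'   that perturb the current target gene are dropped from its regression:
#'   a gene's response to its own knockdown reflects the intervention, not
#'   regulation, and would otherwise act as a large unmodeled residual.
#' @return object of class `posterior_network`: list with `probabilities`
#'   (n x n matrix with `NA` for undefined pairs), `gene_ids`, `candidates`,
#'   `acceptance_rates`, `k`, `settings`.
#' @export
infer_network <- function(dataset, candidates = "all", prior = flat_prior(),
                          settings = chain_settings(), targets = NULL,
                          exclude_self_perturbations = TRUE) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(prior, "bvs_prior"))
  genes <- dataset$gene_ids
  if (identical(candidates, "all")) candidates <- genes
  candidates <- as.character(candidates)
  unknown <- setdiff(candidates, genes)
  if (length(unknown) > 0) {
    stop("candidate(s) not in dataset: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(targets)) targets <- genes
  n_p <- n_perturbations(dataset)
  k <- settings$k
  if (is.null(k)) {
    k <- if (inherits(prior, "network_prior")) {
      restriction_parameter(prior$network, n_targets = length(targets),
                            n_p = n_p)
    } else {
      n_p
    }
  }
  k <- min(as.integer(k), n_p)

  n <- length(genes)
  probs <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  acc <- stats::setNames(numeric(length(targets)), targets)
  for (tg in targets) {
    cand <- setdiff(candidates, tg)
    if (length(cand) == 0) {
      stop("no candidates left for target '", tg, "'", call. = FALSE)
    }
    ds <- dataset
    if (exclude_self_perturbations && !is.null(dataset$perturbed_genes)) {
      keep <- is.na(dataset$perturbed_genes) | dataset$perturbed_genes != tg
      if (sum(keep) < 2) {
        stop("fewer than two perturbations left for target '", tg,
             "' after excluding its own", call. = FALSE)
      }
      if (!all(keep)) ds <- subset_perturbations(dataset, keep)
    }
    problem <- build_problem(ds, tg, cand)
    gs <- settings
    gs$k <- min(k, problem$n_p)
    gs$seed <- derive_seed(settings$seed, match(tg, genes))
    trace <- run_chain(problem, prior, gs)
    probs[tg, cand] <- edge_probabilities(trace)
    acc[tg] <- trace$acceptance_rate
  }
  structure(
    list(probabilities = probs, gene_ids = genes, candidates = candidates,
         targets = targets, acceptance_rates = acc, k = k,
         settings = list(iterations = settings$iterations,
                         burn_in = settings$burn_in,
                         thinning = settings$thinning,
                         seed = settings$seed)),
    class = "posterior_network"
  )
}

#' @export
print.posterior_network <- function(x, ...) {
  cat(sprintf("posterior_network: %d genes, %d candidate regulators, k = %d\n",
              length(x$gene_ids), length(x$candidates), x$k))
  cat(sprintf("mean acceptance rate %.2f over %d chains\n",
              mean(x$acceptance_rates), length(x$acceptance_rates)))
  invisible(x)
}
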