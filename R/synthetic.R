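#' Generate a random stable linear regulatory network
#'
#' Draws a directed network on `n` genes in which each off-diagonal edge is
#' present independently with probability `mean_degree / (n - 1)`.
#' Interaction strengths have magnitudes uniform in `strength_range` and are
#' repressive (negative) with probability `p_negative`. The strength matrix
#' is rescaled, if necessary, so its spectral radius is at most 0.8: the
#' steady-state response map `(I - B)^{-1}` then exists and is well
#' conditioned, so simulated data reflect the regulatory structure rather
#' than numerical instability of the fixture.
#'
#' @param n number of genes (>= 2).
#' @param mean_degree expected number of regulators per gene (< n).
#' @param strength_range positive magnitude range (lo, hi), default (0.5, 1.5).
#' @param p_negative probability an edge is repressive (default 0.25).
#' @param seed integer seed; equal seeds give identical networks.
#' @return object of class `synthetic_network`: list with `strengths`
#'   (n x n matrix B, entry (i, k) = effect of regulator k on target i),
#'   `adjacency` (logical mask), `spectral_radius`, `gene_ids`.
#' @export
generate_network <- function(n, mean_degree = 2,
                             strength_range = c(0.5, 1.5),
                             p_negative = 0.25, seed = 1) {
  if (n < 2) stop("need at least two genes", call. = FALSE)
  if (mean_degree < 0 || mean_degree >= n) {
    stop("mean_degree must lie in [0, n)", call. = FALSE)
  }
  if (strength_range[1] <= 0 || diff(strength_range) < 0) {
    stop("strength_range must be positive and ordered", call. = FALSE)
  }
  set.seed(seed)
  p_edge <- mean_degree / (n - 1)
  B <- matrix(0, n, n)
  off <- which(row(B) != col(B))
  present <- off[stats::runif(length(off)) < p_edge]
  mag <- stats::runif(length(present), strength_range[1], strength_range[2])
  sign <- ifelse(stats::runif(length(present)) < p_negative, -1, 1)
  B[present] <- mag * sign
  sr <- spectral_radius(B)
  if (sr > 0.8) {
    B <- B * (0.8 / sr)
    sr <- spectral_radius(B)
  }
  gene_ids <- paste0("g", seq_len(n))
  dimnames(B) <- list(gene_ids, gene_ids)
  structure(
    list(strengths = B, adjacency = B != 0, spectral_radius = sr,
         gene_ids = gene_ids),
    class = "synthetic_network"
  )
}

spectral_radius <- function(B) {
  if (all(B == 0)) return(0)
  max(Mod(eigen(B, only.values = TRUE)$values))
}

#' @export
print.synthetic_network <- function(x, ...) {
  cat(sprintf("synthetic_network: %d genes, %d edges, spectral radius %.3f\n",
              length(x$gene_ids), sum(x$adjacency), x$spectral_radius))
  invisible(x)
}

#' True edge list of a synthetic network
#'
#' @param network a `synthetic_network`.
#' @return data frame with columns `target`, `regulator`.
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "synthetic_network"))
  idx <- which(network$adjacency, arr.ind = TRUE)
  data.frame(target = network$gene_ids[idx[, 1]],
             regulator = network$gene_ids[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Simulate steady-state perturbation responses
#'
#' For each perturbation column p, the network's steady-state response is
#' `x = (I - B)^{-1} p` (the self-consistent solution of the linear
#' regulation model, where each gene's response is the strength-weighted sum
#' of its regulators' responses plus its own direct perturbation), with
#' independent Gaussian measurement noise of standard deviation `noise_sd`
#' added to every entry. The default design is single-gene knockdowns, one
#' per column, encoded as a perturbation of -1 on the targeted gene; `n_p`
#' selects the first `n_p` knockdowns, giving an under-determined dataset
#' when `n_p < n`.
#'
#' @param network a `synthetic_network`.
#' @param design optional n x n_p perturbation matrix; default `-diag(n)`.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed for the noise draws.
#' @param n_p optional number of perturbations: keeps the first `n_p`
#'   columns of the default design.
#' @return an `expression_dataset`.
#' @export
simulate_perturbations <- function(network, design = NULL, noise_sd = 0.05,
                                   seed = 1, n_p = NULL) {
  stopifnot(inherits(network, "synthetic_network"))
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  n <- length(network$gene_ids)
  if (is.null(design)) {
    design <- -diag(n)
    colnames(design) <- paste0("kd_", network$gene_ids)
    if (!is.null(n_p)) {
      if (n_p < 2 || n_p > n) stop("n_p must lie in [2, n]", call. = FALSE)
      design <- design[, seq_len(n_p), drop = FALSE]
    }
  } else {
    design <- as.matrix(design)
    if (nrow(design) != n) stop("design must have one row per gene", call. = FALSE)
    if (any(colSums(abs(design)) == 0)) {
      stop("design columns must be nonzero", call. = FALSE)
    }
    if (is.null(colnames(design))) {
      colnames(design) <- paste0("p", seq_len(ncol(design)))
    }
  }
  responses <- solve(diag(n) - network$strengths, design)
  set.seed(seed)
  if (noise_sd > 0) {
    responses <- responses +
      matrix(stats::rnorm(length(responses), sd = noise_sd),
             nrow(responses), ncol(responses))
  }
  # columns hitting exactly one gene are annotated as perturbing it
  hits <- colSums(design != 0)
  perturbed <- ifelse(hits == 1,
                      network$gene_ids[apply(design != 0, 2, which.max)],
                      NA_character_)
  expression_dataset(responses, gene_ids = network$gene_ids,
                     perturbation_ids = colnames(design),
                     perturbed_genes = perturbed)
}

#' Degrade a true network into a synthetic prior network
#'
#' Emulates incomplete and imprecise external evidence (such as binding-site
#' and protein-interaction predictions): each true edge is retained with
#' probability `recall` and each absent off-diagonal pair is added as a
#' false edge with probability `false_rate`. All resulting edges carry the
#' uniform confidence `alpha_c`. The output is a synthetic stand-in for a
#' knowledge-derived prior network, not a reconstruction of one.
#'
#' @param network a `synthetic_network` (the ground truth).
#' @param recall probability of keeping each true edge.
#' @param false_rate probability of adding each absent pair.
#' @param alpha_c confidence weight of prior edges (default 2).
#' @param seed integer seed.
#' @return a `prior_network` over the network's genes.
#' @export
corrupt_prior <- function(network, recall, false_rate, alpha_c = 2, seed = 1) {
  stopifnot(inherits(network, "synthetic_network"))
  if (recall < 0 || recall > 1 || false_rate < 0 || false_rate > 1) {
    stop("recall and false_rate must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  n <- length(network$gene_ids)
  adj <- network$adjacency
  keep <- adj & matrix(stats::runif(n * n) < recall, n, n)
  add <- !adj & (row(adj) != col(adj)) &
    matrix(stats::runif(n * n) < false_rate, n, n)
  weights <- matrix(0, n, n,
                    dimnames = list(network$gene_ids, network$gene_ids))
  provenance <- matrix("none", n, n,
                       dimnames = list(network$gene_ids, network$gene_ids))
  weights[keep | add] <- alpha_c
  provenance[keep | add] <- "direct"
  structure(
    list(weights = weights, provenance = provenance, alpha_c = alpha_c,
         gene_ids = network$gene_ids),
    class = "prior_network"
  )
}
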