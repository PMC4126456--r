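#' Prior families over regulator configurations
#'
#' Three priors are supported for a gene's configuration vector:
#' \describe{
#'   \item{flat}{every admissible configuration is equally likely a priori.}
#'   \item{sparse}{a beta-binomial prior on the model size that favors
#'     regulatory programs with few regulators.}
#'   \item{network}{an exponential prior `P(A^i) ∝ exp(Γ^i · A^i)` driven by
#'     a weighted prior-knowledge network: configurations gain weight for
#'     every included edge that is supported by external evidence, while
#'     unsupported ("novel") edges are neither rewarded nor penalized.}
#' }
#' These constructors return lightweight evaluator objects consumed by
#' [log_posterior_score()], [run_chain()] and [infer_network()].
#'
#' @param alpha,beta positive shape parameters of the beta-binomial size
#'   prior; the defaults (1, 2) put monotonically decreasing mass on larger
#'   models.
#' @param network a `prior_network` object (see [build_prior_network()]).
#' @return an object of class `bvs_prior`.
#' @name bvs_priors
NULL

#' @rdname bvs_priors
#' @export
flat_prior <- function() {
  structure(list(type = "flat"), class = c("flat_prior", "bvs_prior"))
}

#' @rdname bvs_priors
#' @export
sparse_prior <- function(alpha = 1, beta = 2) {
  if (alpha <= 0 || beta <= 0) stop("shape parameters must be positive", call. = FALSE)
  structure(list(type = "sparse", alpha = alpha, beta = beta),
            class = c("sparse_prior", "bvs_prior"))
}

#' @rdname bvs_priors
#' @export
network_prior <- function(network) {
  stopifnot(inherits(network, "prior_network"))
  structure(list(type = "network", network = network),
            class = c("network_prior", "bvs_prior"))
}

#' Evaluate the log prior of a configuration
#'
#' Generic dispatched on the prior evaluator. For the network prior the
#' relevant row of the prior weight matrix is extracted using the problem's
#' target gene and candidate ordering.
#'
#' @param prior a `bvs_prior`.
#' @param config a `regulatory_config`.
#' @param problem the `regression_problem` the configuration refers to.
#' @param k restriction parameter (admissible sizes are < k).
#' @return log prior value (possibly `-Inf`).
#' @export
log_prior <- function(prior, config, problem, k) UseMethod("log_prior")

#' @export
log_prior.flat_prior <- function(prior, config, problem, k) {
  flat_log_prior(config)
}

#' @export
log_prior.sparse_prior <- function(prior, config, problem, k) {
  sparse_log_prior(config, alpha = prior$alpha, beta = prior$beta)
}

#' @export
log_prior.network_prior <- function(prior, config, problem, k) {
  gamma_row <- prior_gamma_row(prior$network, problem$target_id,
                               problem$candidate_ids)
  network_log_prior(config, gamma_row, k)
}

#' Flat (uniform) log prior
#'
#' Constant over configurations; returns 0 (normalization is irrelevant for
#' Metropolis-Hastings ratios).
#' @param config a `regulatory_config`.
#' @return 0.
#' @export
flat_log_prior <- function(config) 0

#' Beta-binomial sparse log prior
#'
#' Log of `choose(n_r, n_i) * B(n_i + alpha, n_r - n_i + beta) / B(alpha, beta)`
#' computed via log-gamma, where `n_i` is the configuration size and `n_r`
#' the number of candidates. Used as an unnormalized configuration score.
#'
#' @param config a `regulatory_config` of length n_r.
#' @param alpha,beta positive shapes (defaults 1 and 2).
#' @return log prior value.
#' @export
sparse_log_prior <- function(config, alpha = 1, beta = 2) {
  n_r <- length(config)
  n_i <- config_size(config)
  lchoose(n_r, n_i) + lbeta(n_i + alpha, n_r - n_i + beta) - lbeta(alpha, beta)
}

#' Network log prior for one configuration
#'
#' `Γ^i · A^i` for configurations with fewer than `k` regulators, `-Inf`
#' otherwise. Including an edge with zero prior weight leaves the value
#' unchanged, so previously unknown interactions are not penalized.
#'
#' @param config a `regulatory_config` of length n_r.
#' @param gamma_row numeric weight vector aligned with the candidate ordering.
#' @param k restriction parameter.
#' @return log prior value.
#' @export
network_log_prior <- function(config, gamma_row, k) {
  bits <- as.integer(config)
  if (length(gamma_row) != length(bits)) {
    stop("gamma_row length does not match configuration length", call. = FALSE)
  }
  if (config_size(config) >= k) return(-Inf)
  sum(gamma_row[bits == 1L])
}

#' Build a prior-knowledge network from TFBS and PPI evidence
#'
#' Constructs the weighted prior adjacency matrix Γ (rows = targets,
#' columns = regulators). Each TFBS edge regulator -> target contributes a
#' direct entry `Γ[target, regulator] = alpha_c`. Each undirected
#' protein-protein interaction (a, b) between transcription factors extends
#' the network with indirect entries: whenever b has a direct edge b -> g,
#' the binding partner a is credited with g as well (and symmetrically), on
#' the rationale that a TF in complex with a promoter-binding TF can regulate
#' the same target. The expansion is depth-1 only: partners of partners gain
#' nothing. All supported edges carry the same confidence `alpha_c`;
#' autoregulations are dropped.
#'
#' @param tfbs_edges two-column data frame or matrix (regulator_id,
#'   target_id) of directed binding-site evidence.
#' @param ppi_edges two-column data frame or matrix (tf_a, tf_b) of
#'   undirected physical interactions; may be `NULL` or empty.
#' @param gene_ids character vector: the gene universe the matrix is indexed
#'   by. All edge-list ids must resolve against it.
#' @param alpha_c positive confidence weight for supported edges (default 2).
#' @return object of class `prior_network`: list with `weights` (n x n
#'   matrix), `provenance` (character matrix, "none"/"direct"/"indirect"),
#'   `alpha_c`, `gene_ids`.
#' @export
build_prior_network <- function(tfbs_edges, ppi_edges = NULL, gene_ids,
                                alpha_c = 2) {
  if (alpha_c <= 0) stop("alpha_c must be positive", call. = FALSE)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("duplicated gene ids", call. = FALSE)
  n <- length(gene_ids)
  tfbs <- normalize_edges(tfbs_edges, "tfbs")
  ppi <- normalize_edges(ppi_edges, "ppi")
  all_ids <- unique(c(tfbs$from, tfbs$to, ppi$from, ppi$to))
  unknown <- setdiff(all_ids, gene_ids)
  if (length(unknown) > 0) {
    stop("unknown gene id(s) in edge lists: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  self_ppi <- ppi$from == ppi$to
  if (any(self_ppi)) {
    warning(sum(self_ppi), " self-interaction PPI pair(s) ignored", call. = FALSE)
    ppi <- ppi[!self_ppi, , drop = FALSE]
  }

  weights <- matrix(0, n, n, dimnames = list(gene_ids, gene_ids))
  provenance <- matrix("none", n, n, dimnames = list(gene_ids, gene_ids))

  # direct edges: regulator -> target stored as [target, regulator]
  direct <- unique(data.frame(target = tfbs$to, regulator = tfbs$from,
                              stringsAsFactors = FALSE))
  # indirect: for PPI pair (a,b), every direct target of b is credited to a
  # and vice versa; depth-1 only (built from direct edges exclusively).
  indirect <- NULL
  if (nrow(ppi) > 0 && nrow(direct) > 0) {
    expand <- function(binder, partner) {
      hit <- direct$regulator == binder
      if (!any(hit)) return(NULL)
      data.frame(target = direct$target[hit], regulator = partner,
                 stringsAsFactors = FALSE)
    }
    pieces <- vector("list", 2 * nrow(ppi))
    for (r in seq_len(nrow(ppi))) {
      pieces[[2 * r - 1]] <- expand(ppi$from[r], ppi$to[r])
      pieces[[2 * r]] <- expand(ppi$to[r], ppi$from[r])
    }
    indirect <- unique(do.call(rbind, pieces))
  }

  dropped_auto <- 0L
  place <- function(edges, label) {
    for (r in seq_len(NROW(edges))) {
      ti <- match(edges$target[r], gene_ids)
      ri <- match(edges$regulator[r], gene_ids)
      if (ti == ri) {
        dropped_auto <<- dropped_auto + 1L
        next
      }
      if (provenance[ti, ri] == "direct") next  # direct wins over indirect
      weights[ti, ri] <<- alpha_c
      provenance[ti, ri] <<- label
    }
  }
  place(direct, "direct")
  if (!is.null(indirect)) place(indirect, "indirect")
  if (dropped_auto > 0) {
    message(dropped_auto, " autoregulatory prior edge(s) dropped")
  }

  structure(
    list(weights = weights, provenance = provenance, alpha_c = alpha_c,
         gene_ids = gene_ids),
    class = "prior_network"
  )
}

normalize_edges <- function(edges, what) {
  if (is.null(edges) || NROW(edges) == 0) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop(what, " edge list needs two columns", call. = FALSE)
  data.frame(from = as.character(edges[[1]]), to = as.character(edges[[2]]),
             stringsAsFactors = FALSE)
}

#' @export
print.prior_network <- function(x, ...) {
  cat(sprintf("prior_network: %d genes, %d supported edges (alpha_c = %g)\n",
              length(x$gene_ids), sum(x$weights != 0), x$alpha_c))
  invisible(x)
}

#' Number of supported edges in a prior network
#' @param network a `prior_network`.
#' @return integer edge count (nonzero weight entries).
#' @export
prior_edge_count <- function(network) {
  stopifnot(inherits(network, "prior_network"))
  sum(network$weights != 0)
}

prior_gamma_row <- function(network, target_id, candidate_ids) {
  stopifnot(inherits(network, "prior_network"))
  if (!target_id %in% network$gene_ids) {
    stop("target '", target_id, "' not in prior network", call. = FALSE)
  }
  missing_c <- setdiff(candidate_ids, network$gene_ids)
  if (length(missing_c) > 0) {
    stop("candidate(s) not in prior network: ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  as.numeric(network$weights[target_id, candidate_ids])
}

#' Restriction parameter from average prior in-degree
#'
#' The restriction parameter k bounds the explored model sizes (only
#' configurations with fewer than k regulators are sampled). It is chosen as
#' the average number of prior-supported regulators per target gene, rounded
#' to the nearest integer (half away from zero), optionally capped at the
#' number of perturbations so that the restricted space stays identifiable.
#'
#' @param prior a `prior_network`, or directly a numeric edge count.
#' @param n_targets number of target genes.
#' @param n_p optional number of perturbations used as a cap.
#' @return integer k.
#' @examples
#' restriction_parameter(217, 21)      # 10
#' restriction_parameter(16372, 1317)  # 12
#' @export
restriction_parameter <- function(prior, n_targets, n_p = NULL) {
  if (inherits(prior, "prior_network")) {
    n_edges <- prior_edge_count(prior)
  } else {
    n_edges <- as.numeric(prior)
  }
  if (n_targets < 1) stop("n_targets must be at least 1", call. = FALSE)
  if (n_edges < 1) {
    stop("prior network has no edges; supply k explicitly", call. = FALSE)
  }
  k <- floor(n_edges / n_targets + 0.5)  # half away from zero (counts >= 0)
  if (!is.null(n_p)) k <- min(k, n_p)
  as.integer(k)
}
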