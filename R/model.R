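#' Binary regulator configuration
#'
#' A configuration is a 0/1 vector over a gene's candidate regulators: bit j
#' is 1 when candidate j is included in the regulatory program. The number of
#' ones (the model size) is cached because every score evaluation needs it.
#'
#' @param bits integer/logical vector of 0s and 1s.
#' @return object of class `regulatory_config` (integer vector with a `size`
#'   attribute).
#' @examples
#' cfg <- regulatory_config(c(1, 0, 1))
#' config_size(cfg)
#' @export
regulatory_config <- function(bits) {
  bits <- as.integer(bits)
  if (any(is.na(bits)) || any(bits != 0L & bits != 1L)) {
    stop("bits must be a vector of 0s and 1s", call. = FALSE)
  }
  structure(bits, size = sum(bits), class = "regulatory_config")
}

#' @rdname regulatory_config
#' @param config a `regulatory_config`.
#' @export
config_size <- function(config) {
  s <- attr(config, "size")
  if (is.null(s)) sum(as.integer(config)) else s
}

#' Build a per-gene regression problem
#'
#' Sets up the linear response model for one target gene: its perturbation
#' responses form the response vector and the responses of the candidate
#' regulators form the design rows. Both are mean-centered once here, which
#' plays the role of an unpenalized intercept and makes the coefficient of
#' determination (taken about the response mean) well defined.
#'
#' @param dataset an `expression_dataset`.
#' @param target gene id of the regulated gene.
#' @param candidates character vector of candidate regulator gene ids; must
#'   not contain the target (autoregulation is excluded from the model class).
#' @return object of class `regression_problem` with centered `response`
#'   (length n_p), centered `design` (n_r x n_p, one row per candidate),
#'   `target_index`, `candidate_indices`, `candidate_ids`, `n_r`, `n_p`.
#' @export
build_problem <- function(dataset, target, candidates) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (length(candidates) == 0) {
    stop("empty candidate set", call. = FALSE)
  }
  candidates <- as.character(candidates)
  target <- as.character(target)
  unknown <- setdiff(c(target, candidates), dataset$gene_ids)
  if (length(unknown) > 0) {
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(candidates)) {
    stop("duplicate candidate ids", call. = FALSE)
  }
  if (target %in% candidates) {
    stop("autoregulation excluded: target cannot be its own candidate",
         call. = FALSE)
  }
  ti <- match(target, dataset$gene_ids)
  ci <- match(candidates, dataset$gene_ids)
  y <- dataset$responses[ti, ]
  ybar <- mean(y)
  X <- dataset$responses[ci, , drop = FALSE]
  X <- X - rowMeans(X)
  structure(
    list(target_index = ti,
         target_id = target,
         candidate_indices = ci,
         candidate_ids = candidates,
         response = as.numeric(y - ybar),
         response_mean = ybar,
         design = unname(X),
         n_r = length(ci),
         n_p = length(y)),
    class = "regression_problem"
  )
}

#' Least-squares coefficient estimate for a regulator subset
#'
#' Solves the normal equations for the selected regulators. The Gram matrix
#' must be well conditioned: near-collinear candidate rows (reciprocal
#' condition number below `1/cond_cap`) raise a classed
#' `bvsnet_unidentifiable` error, which score evaluation maps to an excluded
#' configuration (log score -Inf) rather than a numerically meaningless fit.
#'
#' @param subdesign n_i x n_p matrix: the selected (centered) design rows.
#' @param response length-n_p (centered) response vector.
#' @param cond_cap condition-number cap for the Gram matrix (default 1e10).
#' @return numeric coefficient vector of length n_i.
#' @export
least_squares_estimate <- function(subdesign, response, cond_cap = 1e10) {
  subdesign <- as.matrix(subdesign)
  if (nrow(subdesign) < 1) stop("at least one regressor required", call. = FALSE)
  gram <- subdesign %*% t(subdesign)
  rc <- tryCatch(rcond(gram), error = function(e) 0)
  if (!is.finite(rc) || rc < 1 / cond_cap) {
    stop(unidentifiable_condition())
  }
  as.numeric(solve(gram, subdesign %*% response))
}

unidentifiable_condition <- function() {
  structure(
    class = c("bvsnet_unidentifiable", "error", "condition"),
    list(message = "unidentifiable configuration: ill-conditioned Gram matrix",
         call = NULL)
  )
}

#' Coefficient of determination of a configuration
#'
#' R-squared of the least-squares fit of the target's centered responses on
#' the selected regulator rows, clamped to \[0, 1\] against floating-point
#' drift. This is the only data summary that enters the marginal likelihood.
#'
#' @param problem a `regression_problem`.
#' @param config a `regulatory_config` over the problem's candidates with at
#'   least one selected regulator.
#' @param cond_cap condition-number cap passed to [least_squares_estimate()].
#' @return R-squared in \[0, 1\].
#' @export
coefficient_of_determination <- function(problem, config, cond_cap = 1e10) {
  stopifnot(inherits(problem, "regression_problem"))
  bits <- as.integer(config)
  if (length(bits) != problem$n_r) {
    stop("configuration length does not match candidate count", call. = FALSE)
  }
  sel <- which(bits == 1L)
  if (length(sel) == 0) stop("configuration selects no regulators", call. = FALSE)
  sub <- problem$design[sel, , drop = FALSE]
  beta <- least_squares_estimate(sub, problem$response, cond_cap)
  resid <- problem$response - as.numeric(t(sub) %*% beta)
  tss <- sum(problem$response^2)
  r2 <- 1 - sum(resid^2) / tss
  min(1, max(0, r2))
}

#' Zellner's constant for a configuration
#'
#' Scale of the g-prior covariance on the interaction strengths,
#' `c = max(n_p, n_i^2)`: the larger of the number of perturbations and the
#' squared model size. Recomputed for every scored configuration.
#'
#' @param n_p number of perturbations (>= 2).
#' @param n_i number of selected regulators (>= 0).
#' @return positive scalar.
#' @examples
#' zellner_c(19, 3)  # 19
#' zellner_c(19, 5)  # 25
#' @export
zellner_c <- function(n_p, n_i) {
  if (n_p < 2) stop("n_p must be at least 2", call. = FALSE)
  if (n_i < 0) stop("n_i must be nonnegative", call. = FALSE)
  max(n_p, n_i^2)
}

#' Unnormalized log posterior score of a regulator configuration
#'
#' Computes, in log space, the g-prior model score
#' \deqn{P(A^i | x^i, X^i) \propto (1+c)^{-(n_i+1)/2}
#'       \left(1 - \frac{c}{1+c} R^2\right)^{-(n_p-1)/2} P(A^i)}
#' with `c = max(n_p, n_i^2)` and the residual variance integrated out under
#' a Jeffreys prior. Configurations outside the restricted space (size >= k)
#' and unidentifiable configurations score `-Inf`. The empty configuration is
#' scored with `R^2 = 0` (intercept-only model).
#'
#' @param problem a `regression_problem`.
#' @param config a `regulatory_config`.
#' @param prior a prior evaluator created by [flat_prior()], [sparse_prior()]
#'   or [network_prior()].
#' @param k restriction parameter: only configurations with fewer than `k`
#'   regulators are admissible (`k <= n_p`).
#' @param cond_cap condition-number cap for identifiability.
#' @return object of class `model_score`: list with `log_score`,
#'   `log_marginal`, `log_prior`, `r_squared`, `c`.
#' @export
log_posterior_score <- function(problem, config, prior, k, cond_cap = 1e10) {
  stopifnot(inherits(problem, "regression_problem"))
  if (k > problem$n_p) {
    stop("restriction parameter k must not exceed the number of perturbations",
         call. = FALSE)
  }
  n_i <- config_size(config)
  n_p <- problem$n_p
  if (n_i >= k) {
    return(model_score(-Inf, NA_real_, NA_real_, NA_real_, NA_real_))
  }
  cc <- zellner_c(n_p, n_i)
  if (n_i == 0) {
    r2 <- 0
  } else {
    r2 <- tryCatch(
      coefficient_of_determination(problem, config, cond_cap),
      bvsnet_unidentifiable = function(e) {
        warning("unidentifiable configuration scored -Inf", call. = FALSE)
        NA_real_
      }
    )
    if (is.na(r2)) {
      return(model_score(-Inf, NA_real_, NA_real_, NA_real_, cc))
    }
  }
  log_marginal <- -((n_i + 1) / 2) * log1p(cc) -
    ((n_p - 1) / 2) * log(1 - (cc / (1 + cc)) * r2)
  log_pr <- log_prior(prior, config, problem, k)
  model_score(log_marginal + log_pr, log_marginal, log_pr, r2, cc)
}

model_score <- function(log_score, log_marginal, log_prior, r_squared, c) {
  structure(
    list(log_score = log_score, log_marginal = log_marginal,
         log_prior = log_prior, r_squared = r_squared, c = c),
    class = "model_score"
  )
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf("model_score: log_score = %.4f (marginal %.4f, prior %.4f, R2 %.4f, c %.0f)\n",
              x$log_score, x$log_marginal, x$log_prior, x$r_squared, x$c))
  invisible(x)
}
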