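#' Gold-standard edge set for network evaluation
#'
#' Holds the directed reference edges and the set of regulators whose
#' activities were actually assayed. Evaluation is restricted to pairs whose
#' regulator is in this mask, mirroring benchmarks where the reference
#' network covers only a subset of the transcription factors.
#'
#' @param edges two-column data frame or matrix (target_id, regulator_id).
#' @param regulator_mask character vector of regulator ids that are
#'   comparable; defaults to the regulators appearing in `edges`.
#' @return object of class `gold_standard`.
#' @export
gold_standard <- function(edges, regulator_mask = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("gold edges need two columns", call. = FALSE)
  edges <- data.frame(target = as.character(edges[[1]]),
                      regulator = as.character(edges[[2]]),
                      stringsAsFactors = FALSE)
  if (any(edges$target == edges$regulator)) {
    stop("gold standard contains self-edges", call. = FALSE)
  }
  edges <- unique(edges)
  if (is.null(regulator_mask)) regulator_mask <- unique(edges$regulator)
  regulator_mask <- as.character(regulator_mask)
  if (length(regulator_mask) == 0) {
    stop("regulator mask must be non-empty", call. = FALSE)
  }
  structure(list(edges = edges, regulator_mask = regulator_mask),
            class = "gold_standard")
}

pair_key <- function(target, regulator) paste(target, regulator, sep = "\r")

# Evaluation universe: every defined (target, regulator) posterior entry with
# the regulator in the gold mask, excluding self-pairs. Gold edges outside
# the universe are dropped with a message.
evaluation_pairs <- function(posterior, gold) {
  stopifnot(inherits(posterior, "posterior_network"),
            inherits(gold, "gold_standard"))
  probs <- posterior$probabilities
  regs <- intersect(colnames(probs), gold$regulator_mask)
  if (length(regs) == 0) {
    stop("no overlap between posterior regulators and gold mask", call. = FALSE)
  }
  sub <- probs[, regs, drop = FALSE]
  def <- which(!is.na(sub), arr.ind = TRUE)
  if (nrow(def) == 0) stop("no defined pairs to evaluate", call. = FALSE)
  target <- rownames(sub)[def[, 1]]
  regulator <- regs[def[, 2]]
  p <- sub[def]
  keys <- pair_key(target, regulator)
  gold_keys <- pair_key(gold$edges$target, gold$edges$regulator)
  outside <- setdiff(gold_keys, keys)
  if (length(outside) > 0) {
    message(length(outside), " gold edge(s) outside the evaluation universe dropped")
  }
  data.frame(target = target, regulator = regulator, probability = p,
             truth = keys %in% gold_keys, stringsAsFactors = FALSE)
}

#' Confusion rates of the called network at one threshold
#'
#' An edge is called present when its posterior probability is strictly
#' greater than `tau`. TPR is called-true over all true; FPR is called-false
#' over all non-edges of the universe; precision is called-true over all
#' called, defined as 1 when nothing is called (empty-prediction convention).
#'
#' @param posterior a `posterior_network`.
#' @param gold a `gold_standard`.
#' @param tau probability threshold.
#' @return named numeric vector `c(tpr, fpr, precision)`.
#' @export
confusion_at_threshold <- function(posterior, gold, tau) {
  pairs <- evaluation_pairs(posterior, gold)
  confusion_from_pairs(pairs, tau)
}

confusion_from_pairs <- function(pairs, tau) {
  calls <- pairs$probability > tau
  pos <- sum(pairs$truth)
  neg <- sum(!pairs$truth)
  tp <- sum(calls & pairs$truth)
  fp <- sum(calls & !pairs$truth)
  tpr <- if (pos > 0) tp / pos else NA_real_
  fpr <- if (neg > 0) fp / neg else 0
  pre <- if (sum(calls) > 0) tp / sum(calls) else 1
  c(tpr = tpr, fpr = fpr, precision = pre)
}

#' ROC and precision-recall curves of a posterior network
#'
#' Sweeps the call threshold over every observed posterior probability (plus
#' one value below the minimum so that everything is called) and integrates
#' the resulting curves by the trapezoidal rule. The PR curve is anchored at
#' recall 0 with the precision of the most stringent non-empty call set.
#'
#' @param posterior a `posterior_network`.
#' @param gold a `gold_standard` with at least one true edge inside the
#'   evaluation universe.
#' @return object of class `evaluation_result`: list with `roc` and `pr`
#'   data frames, `auroc`, `aupr`, `thresholds`.
#' @export
roc_pr_curves <- function(posterior, gold) {
  pairs <- evaluation_pairs(posterior, gold)
  if (sum(pairs$truth) == 0) {
    stop("no true edges in the evaluation universe; AUROC undefined",
         call. = FALSE)
  }
  taus <- c(sort(unique(pairs$probability), decreasing = TRUE), -1e-9)
  pts <- t(vapply(taus, function(tau) confusion_from_pairs(pairs, tau),
                  numeric(3)))
  roc <- data.frame(threshold = taus, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  ord <- order(roc$fpr, roc$tpr)
  auroc <- trapezoid(roc$fpr[ord], roc$tpr[ord])

  called <- vapply(taus, function(tau) any(pairs$probability > tau), logical(1))
  pr <- data.frame(threshold = taus[called],
                   recall = pts[called, "tpr"],
                   precision = pts[called, "precision"])
  pr <- pr[order(pr$recall, -pr$precision), ]
  anchor <- data.frame(threshold = NA_real_, recall = 0,
                       precision = pr$precision[1])
  pr_full <- rbind(anchor, pr)
  aupr <- trapezoid(pr_full$recall, pr_full$precision)

  structure(
    list(roc = roc, pr = pr_full, auroc = auroc, aupr = aupr,
         thresholds = taus),
    class = "evaluation_result"
  )
}

trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation_result: AUROC = %.3f, AUPR = %.3f (%d thresholds)\n",
              x$auroc, x$aupr, length(x$thresholds)))
  invisible(x)
}

#' Pearson correlation between two networks
#'
#' Renders both networks as vectors over a shared set of ordered
#' off-diagonal (target, regulator) pairs and returns their Pearson
#' correlation. Posterior networks contribute their defined probabilities,
#' prior networks their weights, and gold standards 0/1 indicators on the
#' partner's pair set (restricted to the gold regulator mask).
#'
#' @param a,b `posterior_network`, `prior_network` or `gold_standard`
#'   objects (at most one gold standard).
#' @return Pearson correlation in \[-1, 1\].
#' @export
network_correlation <- function(a, b) {
  if (inherits(a, "gold_standard") && inherits(b, "gold_standard")) {
    stop("at most one gold standard can be compared", call. = FALSE)
  }
  if (inherits(a, "gold_standard")) return(network_correlation(b, a))
  va <- network_pair_values(a)
  if (inherits(b, "gold_standard")) {
    keep <- va$regulator %in% b$regulator_mask
    va <- va[keep, , drop = FALSE]
    gold_keys <- pair_key(b$edges$target, b$edges$regulator)
    vb_values <- as.numeric(pair_key(va$target, va$regulator) %in% gold_keys)
    x <- va$value
    y <- vb_values
  } else {
    vb <- network_pair_values(b)
    ka <- pair_key(va$target, va$regulator)
    kb <- pair_key(vb$target, vb$regulator)
    shared <- intersect(ka, kb)
    if (length(shared) < 2) stop("fewer than two shared pairs", call. = FALSE)
    x <- va$value[match(shared, ka)]
    y <- vb$value[match(shared, kb)]
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a network vector; correlation undefined",
         call. = FALSE)
  }
  stats::cor(x, y)
}

network_pair_values <- function(x) {
  if (inherits(x, "posterior_network")) {
    m <- x$probabilities
  } else if (inherits(x, "prior_network")) {
    m <- x$weights
    diag(m) <- NA_real_
  } else {
    stop("unsupported network object", call. = FALSE)
  }
  def <- which(!is.na(m), arr.ind = TRUE)
  def <- def[def[, 1] != def[, 2], , drop = FALSE]
  data.frame(target = rownames(m)[def[, 1]],
             regulator = colnames(m)[def[, 2]],
             value = m[def], stringsAsFactors = FALSE)
}

#' Mann-Whitney rank-sum comparison of two AUROC samples
#'
#' Two-sided Mann-Whitney U test using the normal approximation with tie
#' correction (appropriate at the replicate counts used in benchmarking).
#'
#' @param a,b numeric vectors (length >= 2) of per-replicate summaries.
#' @return list with `U` (statistic for the `a`-over-`b` orientation) and
#'   `p` (two-sided p-value).
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("both samples need at least two values", call. = FALSE)
  }
  if (stats::sd(c(a, b)) == 0) {
    stop("degenerate constant samples", call. = FALSE)
  }
  w <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  )
  list(U = unname(w$statistic), p = w$p.value)
}

#' Replicated benchmark over several prior settings
#'
#' Runs [infer_network()] `n_replicates` times per prior setting, scoring
#' each posterior network against the gold standard. Replicate r uses the
#' same derived seed under every prior, so performance differences are
#' attributable to the priors alone. Reports per-replicate AUROC/AUPR, their
#' means and standard deviations, vertically averaged ROC and PR curves
#' (linear interpolation on a 101-point grid), and pairwise rank-sum
#' p-values between prior settings.
#'
#' @param dataset an `expression_dataset`.
#' @param priors named list of `bvs_prior` objects.
#' @param gold a `gold_standard`.
#' @param settings a `chain_settings`; its seed is the master seed.
#' @param n_replicates number of replicate runs per prior (>= 2).
#' @param candidates candidate regulator set passed to [infer_network()].
#' @return object of class `benchmark_result`: list with `summary`
#'   (data frame prior/replicate/auroc/aupr), `table` (mean and SD per
#'   prior), `avg_curves` (per-prior averaged ROC and PR data frames) and
#'   `p_values` (pairwise rank-sum matrix on AUROC).
#' @export
replicate_runner <- function(dataset, priors, gold, settings,
                             n_replicates = 2, candidates = "all") {
  stopifnot(is.list(priors), length(priors) >= 1,
            !is.null(names(priors)), all(nzchar(names(priors))))
  if (n_replicates < 2) stop("need at least two replicates", call. = FALSE)

  grid <- seq(0, 1, length.out = 101)
  rows <- list()
  curves <- list()
  for (pn in names(priors)) {
    roc_mat <- matrix(NA_real_, n_replicates, length(grid))
    pr_mat <- matrix(NA_real_, n_replicates, length(grid))
    for (r in seq_len(n_replicates)) {
      rs <- settings
      rs$seed <- derive_seed(settings$seed, 104729, r)
      post <- infer_network(dataset, candidates = candidates,
                            prior = priors[[pn]], settings = rs)
      ev <- roc_pr_curves(post, gold)
      rows[[length(rows) + 1]] <- data.frame(
        prior = pn, replicate = r, auroc = ev$auroc, aupr = ev$aupr,
        stringsAsFactors = FALSE)
      roc_mat[r, ] <- interp_curve(ev$roc$fpr, ev$roc$tpr, grid)
      pr_mat[r, ] <- interp_curve(ev$pr$recall, ev$pr$precision, grid)
    }
    curves[[pn]] <- list(
      roc = data.frame(fpr = grid, tpr = colMeans(roc_mat)),
      pr = data.frame(recall = grid, precision = colMeans(pr_mat)))
  }
  summary_df <- do.call(rbind, rows)
  tab <- do.call(rbind, lapply(split(summary_df, summary_df$prior), function(d) {
    data.frame(prior = d$prior[1],
               mean_auroc = mean(d$auroc), sd_auroc = stats::sd(d$auroc),
               mean_aupr = mean(d$aupr), sd_aupr = stats::sd(d$aupr),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL

  pnames <- names(priors)
  pv <- matrix(NA_real_, length(pnames), length(pnames),
               dimnames = list(pnames, pnames))
  if (length(pnames) > 1) {
    for (i in seq_along(pnames)) {
      for (j in seq_along(pnames)) {
        if (i == j) next
        ai <- summary_df$auroc[summary_df$prior == pnames[i]]
        aj <- summary_df$auroc[summary_df$prior == pnames[j]]
        pv[i, j] <- tryCatch(rank_sum_test(ai, aj)$p, error = function(e) NA_real_)
      }
    }
  }
  structure(
    list(summary = summary_df, table = tab, avg_curves = curves,
         p_values = pv, n_replicates = n_replicates),
    class = "benchmark_result"
  )
}

interp_curve <- function(x, y, grid) {
  ok <- is.finite(x) & is.finite(y)
  stats::approx(x[ok], y[ok], xout = grid, ties = max, rule = 2)$y
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("benchmark_result over", x$n_replicates, "replicates\n")
  print(x$table)
  invisible(x)
}
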