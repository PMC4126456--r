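#' Read a perturbation-response expression matrix from TSV
#'
#' Expected layout: tab-delimited UTF-8 text, header row of perturbation
#' ids, first column gene ids. Every cell must parse as a finite number;
#' the first offending cell is named in the error. Duplicate gene ids and
#' zero-variance rows are rejected.
#'
#' @param path file path.
#' @return an `expression_dataset`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           blank.lines.skip = TRUE, comment.char = "#")
  if (ncol(raw) < 3) {
    stop("malformed expression table: need a gene-id column and at least two perturbations",
         call. = FALSE)
  }
  gene_ids <- raw[[1]]
  pert_ids <- colnames(raw)[-1]
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value at gene '%s', perturbation '%s'",
                 gene_ids[bad[1, 1]], pert_ids[bad[1, 2]]), call. = FALSE)
  }
  expression_dataset(vals, gene_ids = gene_ids, perturbation_ids = pert_ids)
}

#' Write an expression dataset to TSV
#'
#' @param dataset an `expression_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(gene_id = dataset$gene_ids,
                   dataset$responses, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column edge list from TSV
#'
#' Lines starting with `#` and blank lines are skipped. A header row is
#' expected. Undirected lists are deduplicated order-insensitively
#' (`(A,B)` and `(B,A)` collapse to one edge).
#'
#' @param path file path.
#' @param directed logical; `FALSE` for undirected (e.g. protein
#'   interaction) lists.
#' @return data frame with columns `from`, `to`.
#' @export
read_edge_list <- function(path, directed = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          blank.lines.skip = TRUE, comment.char = "#")
  if (ncol(df) != 2) {
    stop("edge list must have exactly two columns, found ", ncol(df),
         call. = FALSE)
  }
  out <- data.frame(from = df[[1]], to = df[[2]], stringsAsFactors = FALSE)
  if (!directed) {
    a <- pmin(out$from, out$to)
    b <- pmax(out$from, out$to)
    out <- unique(data.frame(from = a, to = b, stringsAsFactors = FALSE))
  } else {
    out <- unique(out)
  }
  out
}

#' Write an edge list to TSV
#'
#' @param edges data frame with two columns.
#' @param path output file path.
#' @param col_names header names to use (default the data frame's names).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path, col_names = colnames(edges)) {
  edges <- as.data.frame(edges)
  colnames(edges) <- col_names
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a prior network to TSV
#'
#' One row per supported edge: `target_id`, `regulator_id`, `weight`,
#' `provenance` (direct or indirect).
#'
#' @param network a `prior_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_prior_network <- function(network, path) {
  stopifnot(inherits(network, "prior_network"))
  idx <- which(network$weights != 0, arr.ind = TRUE)
  df <- data.frame(
    target_id = network$gene_ids[idx[, 1]],
    regulator_id = network$gene_ids[idx[, 2]],
    weight = network$weights[idx],
    provenance = network$provenance[idx],
    stringsAsFactors = FALSE)
  df <- df[order(df$target_id, df$regulator_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prior network from TSV
#'
#' Inverse of [write_prior_network()]. The gene universe must be supplied
#' (typically the dataset's gene ids) so the weight matrix can be shaped
#' and edge ids validated.
#'
#' @param path file path.
#' @param gene_ids character vector: the gene universe.
#' @return a `prior_network`.
#' @export
read_prior_network <- function(path, gene_ids) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("target_id", "regulator_id", "weight")
  if (!all(need %in% colnames(df))) {
    stop("prior network table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  unknown <- setdiff(unique(c(df$target_id, df$regulator_id)), gene_ids)
  if (length(unknown) > 0) {
    stop("unknown gene id(s) in prior network: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- length(gene_ids)
  weights <- matrix(0, n, n, dimnames = list(gene_ids, gene_ids))
  provenance <- matrix("none", n, n, dimnames = list(gene_ids, gene_ids))
  ti <- match(df$target_id, gene_ids)
  ri <- match(df$regulator_id, gene_ids)
  weights[cbind(ti, ri)] <- as.numeric(df$weight)
  provenance[cbind(ti, ri)] <-
    if ("provenance" %in% colnames(df)) df$provenance else "direct"
  w <- unique(weights[weights != 0])
  alpha_c <- if (length(w) == 1) w else max(weights)
  structure(
    list(weights = weights, provenance = provenance, alpha_c = alpha_c,
         gene_ids = gene_ids),
    class = "prior_network"
  )
}

#' Write posterior edge probabilities to TSV
#'
#' One row per defined (target, regulator) pair: `target_id`,
#' `regulator_id`, `probability` (6 decimals), sorted for byte-stable
#' output under a fixed seed.
#'
#' @param posterior a `posterior_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(posterior, path) {
  stopifnot(inherits(posterior, "posterior_network"))
  pv <- network_pair_values(posterior)
  pv <- pv[order(pv$target, pv$regulator), ]
  df <- data.frame(target_id = pv$target, regulator_id = pv$regulator,
                   probability = sprintf("%.6f", pv$value),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read posterior edge probabilities from TSV
#'
#' Reconstructs a `posterior_network` from the defined pairs in the file;
#' the gene universe is the union of target and regulator ids unless given.
#'
#' @param path file path.
#' @param gene_ids optional gene universe.
#' @return a `posterior_network`.
#' @export
read_posterior <- function(path, gene_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("target_id", "regulator_id", "probability")
  if (!all(need %in% colnames(df))) {
    stop("posterior table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(gene_ids)) {
    gene_ids <- sort(unique(c(df$target_id, df$regulator_id)))
  }
  n <- length(gene_ids)
  probs <- matrix(NA_real_, n, n, dimnames = list(gene_ids, gene_ids))
  probs[cbind(match(df$target_id, gene_ids),
              match(df$regulator_id, gene_ids))] <- as.numeric(df$probability)
  structure(
    list(probabilities = probs, gene_ids = gene_ids,
         candidates = sort(unique(df$regulator_id)),
         targets = sort(unique(df$target_id)),
         acceptance_rates = NULL, k = NA_integer_, settings = NULL),
    class = "posterior_network"
  )
}

#' Write ROC/PR curve points to CSV
#'
#' @param result an `evaluation_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(result, path) {
  stopifnot(inherits(result, "evaluation_result"))
  roc <- result$roc
  pr <- result$pr[match(result$roc$threshold, result$pr$threshold), ]
  df <- data.frame(threshold = roc$threshold, fpr = roc$fpr, tpr = roc$tpr,
                   precision = pr$precision)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run-metadata sidecar
#'
#' JSON record of the configuration, master seed and per-gene acceptance
#' rates of a run, plus a content hash of the configuration for provenance.
#'
#' @param posterior a `posterior_network` produced by [infer_network()].
#' @param path output file path (conventionally `<run>.meta.json`).
#' @param extra optional named list merged into the record.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(posterior, path, extra = NULL) {
  stopifnot(inherits(posterior, "posterior_network"))
  meta <- list(
    package = "bvsnet",
    version = as.character(utils::packageVersion("bvsnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    k = posterior$k,
    settings = posterior$settings,
    candidates = posterior$candidates,
    acceptance_rates = as.list(posterior$acceptance_rates),
    config_hash = fnv1a_hash(c(posterior$k,
                               unlist(posterior$settings, use.names = FALSE),
                               posterior$candidates))
  )
  if (!is.null(extra)) meta <- utils::modifyList(meta, extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# 32-bit FNV-1a over the character rendering of a configuration vector
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(as.character(x), collapse = "|"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
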