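#' Construct a perturbation-response expression dataset
#'
#' Wraps a genes x perturbations matrix of steady-state expression responses
#' (e.g. log-ratios relative to unperturbed control). Rows are genes, columns
#' are perturbation experiments. The container validates the shape contracts
#' that every downstream regression relies on: at least two perturbations,
#' unique gene identifiers, all values finite, and nonzero variance in every
#' row (a constant row would make the coefficient of determination undefined).
#'
#' Each perturbation column may optionally be annotated with the gene it
#' directly targets (e.g. the gene knocked down by an siRNA). The linear
#' regulation model describes a gene's response to perturbations acting
#' elsewhere in the network; a gene's response to its *own* direct
#' perturbation is dominated by the intervention rather than by regulation,
#' so [infer_network()] excludes those columns per target gene when the
#' annotation is available. Columns named `kd_<gene id>` are auto-annotated.
#'
#' @param responses numeric matrix, rows = genes, columns = perturbations.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   the matrix rownames.
#' @param perturbation_ids character vector of perturbation labels; defaults
#'   to the matrix colnames.
#' @param perturbed_genes optional character vector (length = perturbations):
#'   the gene each column directly perturbs, `NA` if unknown or global.
#'   Default: parsed from perturbation ids of the form `kd_<gene id>`.
#' @return An object of class `expression_dataset` with elements `responses`,
#'   `gene_ids`, `perturbation_ids`, `perturbed_genes`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("g", 1:3), paste0("p", 1:4)))
#' d <- expression_dataset(m)
#' d$gene_ids
#' @export
expression_dataset <- function(responses,
                               gene_ids = rownames(responses),
                               perturbation_ids = colnames(responses),
                               perturbed_genes = NULL) {
  responses <- as.matrix(responses)
  if (!is.numeric(responses)) {
    stop("responses must be a numeric matrix", call. = FALSE)
  }
  if (is.null(gene_ids)) {
    gene_ids <- paste0("g", seq_len(nrow(responses)))
  }
  if (is.null(perturbation_ids)) {
    perturbation_ids <- paste0("p", seq_len(ncol(responses)))
  }
  gene_ids <- as.character(gene_ids)
  perturbation_ids <- as.character(perturbation_ids)
  if (length(gene_ids) != nrow(responses)) {
    stop("gene_ids length does not match row count", call. = FALSE)
  }
  if (length(perturbation_ids) != ncol(responses)) {
    stop("perturbation_ids length does not match column count", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicated gene id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (ncol(responses) < 2) {
    stop("at least two perturbations are required", call. = FALSE)
  }
  bad <- which(!is.finite(responses), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-finite value at gene '%s', perturbation '%s'",
                 gene_ids[bad[1, 1]], perturbation_ids[bad[1, 2]]),
         call. = FALSE)
  }
  vr <- apply(responses, 1, stats::var)
  if (any(vr == 0)) {
    stop("zero-variance response row(s): ",
         paste(gene_ids[vr == 0], collapse = ", "), call. = FALSE)
  }
  dimnames(responses) <- list(gene_ids, perturbation_ids)
  if (is.null(perturbed_genes)) {
    perturbed_genes <- parse_perturbed_genes(perturbation_ids, gene_ids)
  } else {
    perturbed_genes <- as.character(perturbed_genes)
    if (length(perturbed_genes) != length(perturbation_ids)) {
      stop("perturbed_genes length does not match perturbation count",
           call. = FALSE)
    }
    bad <- setdiff(perturbed_genes[!is.na(perturbed_genes)], gene_ids)
    if (length(bad) > 0) {
      stop("perturbed_genes refer to unknown gene(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(responses = responses,
         gene_ids = gene_ids,
         perturbation_ids = perturbation_ids,
         perturbed_genes = perturbed_genes),
    class = "expression_dataset"
  )
}

# columns named kd_<gene id> are annotated with the gene they knock down
parse_perturbed_genes <- function(perturbation_ids, gene_ids) {
  cand <- sub("^kd_", "", perturbation_ids)
  ifelse(grepl("^kd_", perturbation_ids) & cand %in% gene_ids,
         cand, NA_character_)
}

#' Subset the perturbation columns of a dataset
#'
#' @param dataset an `expression_dataset`.
#' @param cols integer or logical index over perturbation columns.
#' @return an `expression_dataset` with the selected columns.
#' @export
subset_perturbations <- function(dataset, cols) {
  stopifnot(inherits(dataset, "expression_dataset"))
  expression_dataset(dataset$responses[, cols, drop = FALSE],
                     gene_ids = dataset$gene_ids,
                     perturbation_ids = dataset$perturbation_ids[cols],
                     perturbed_genes = dataset$perturbed_genes[cols])
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d perturbations\n",
              length(x$gene_ids), length(x$perturbation_ids)))
  invisible(x)
}

#' Number of perturbations in a dataset
#' @param dataset an `expression_dataset`.
#' @return integer count of perturbation columns.
#' @export
n_perturbations <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  length(dataset$perturbation_ids)
}
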