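#' Beta-value matrix container
#'
#' A `beta_matrix` holds a sites-by-samples grid of DNA methylation beta
#' values in \[0, 1\], with `NA` as the missing marker, plus an optional
#' study-dataset label. Rows are methylation sites (e.g. `cg00000029`),
#' columns are samples; this matches the GEO series-matrix orientation and
#' is never inferred from the data.
#'
#' @param values numeric matrix, sites in rows, samples in columns.
#' @param site_ids character vector of unique site identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @param dataset_id optional single string naming the study dataset the
#'   samples belong to (samples from the same tissue, cell type and
#'   condition are conventionally grouped under one dataset ID).
#' @param validate if `TRUE` (default), check invariants. Out-of-range
#'   values are permitted here (they are data-entry artefacts that
#'   [qc_filter_samples()] removes); only structural invariants are
#'   enforced.
#'
#' @return An object of class `beta_matrix`: a list with elements `values`
#'   (numeric matrix with dimnames), and `dataset_id`.
#' @export
#' @examples
#' m <- beta_matrix(matrix(c(0.1, 0.9, 0.5, 0.4), 2, 2,
#'                         dimnames = list(c("cg01", "cg02"), c("S1", "S2"))))
#' dim(m)
beta_matrix <- function(values, site_ids = rownames(values),
                        sample_ids = colnames(values),
                        dataset_id = NULL, validate = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(site_ids)) {
    site_ids <- if (nrow(values) > 0) paste0("site", seq_len(nrow(values))) else character(0)
  }
  if (is.null(sample_ids)) {
    sample_ids <- if (ncol(values) > 0) paste0("sample", seq_len(ncol(values))) else character(0)
  }
  site_ids <- as.character(site_ids)
  sample_ids <- as.character(sample_ids)
  if (validate) {
    if (length(site_ids) != nrow(values))
      stop("length(site_ids) must equal nrow(values)", call. = FALSE)
    if (length(sample_ids) != ncol(values))
      stop("length(sample_ids) must equal ncol(values)", call. = FALSE)
    if (anyDuplicated(site_ids))
      stop("duplicate site IDs: ",
           paste(unique(site_ids[duplicated(site_ids)])[1:min(3, sum(duplicated(site_ids)))],
                 collapse = ", "), call. = FALSE)
    if (anyDuplicated(sample_ids))
      stop("duplicate sample IDs: ",
           paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
           call. = FALSE)
    if (!is.null(dataset_id) && (length(dataset_id) != 1 || !is.character(dataset_id)))
      stop("dataset_id must be a single string or NULL", call. = FALSE)
  }
  dimnames(values) <- list(site_ids, sample_ids)
  structure(list(values = values, dataset_id = dataset_id),
            class = "beta_matrix")
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' Site and sample identifiers of a beta matrix
#' @param m a [beta_matrix()].
#' @return character vector of identifiers.
#' @export
site_ids <- function(m) rownames(m$values)

#' @rdname site_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix: ", nrow(x$values), " sites x ", ncol(x$values),
      " samples", sep = "")
  if (!is.null(x$dataset_id)) cat(" [dataset ", x$dataset_id, "]", sep = "")
  cat("\n")
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat("  missing values: ", n_na, "\n", sep = "")
  if (nrow(x$values) > 0 && ncol(x$values) > 0) {
    show <- x$values[seq_len(min(5, nrow(x$values))),
                     seq_len(min(5, ncol(x$values))), drop = FALSE]
    print(round(show, 4))
  }
  invisible(x)
}

#' Subset a beta matrix by sites and/or samples
#'
#' @param x a [beta_matrix()].
#' @param i site selector (IDs, indices or logical).
#' @param j sample selector.
#' @param ... ignored.
#' @return a `beta_matrix` restricted to the selection.
#' @export
`[.beta_matrix` <- function(x, i, j, ...) {
  v <- x$values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  beta_matrix(v[i, j, drop = FALSE], dataset_id = x$dataset_id)
}
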