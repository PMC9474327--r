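# Container for a cells x genes expression matrix with per-cell sample labels
# and per-sample group labels. Kept deliberately light: a validated list with
# the matrix (base or Matrix sparse) plus two label tables joined by explicit
# ID columns, never by position.

#' Multi-sample single-cell expression dataset
#'
#' @param matrix Cells x genes matrix of nonnegative values (base matrix or a
#'   `Matrix` sparse matrix). Row names are cell IDs, column names gene IDs;
#'   defaults are generated when absent.
#' @param cell_sample Character vector, one sample ID per cell (row).
#' @param sample_group Named character vector mapping sample ID to group
#'   label, or a data frame with columns `sample_id` and `group`.
#' @return An object of class `"single_cell_dataset"`: a list with elements
#'   `matrix`, `cells` (data frame `cell_id`, `sample_id`) and `samples`
#'   (data frame `sample_id`, `group`).
#' @export
single_cell_dataset <- function(matrix, cell_sample, sample_group) {
  if (length(dim(matrix)) != 2)
    stop("single_cell_dataset: 'matrix' must be a cells x genes matrix",
         call. = FALSE)
  if (nrow(matrix) != length(cell_sample))
    stop(sprintf(
      "single_cell_dataset: %d matrix rows but %d cell_sample labels",
      nrow(matrix), length(cell_sample)), call. = FALSE)
  if (is.null(rownames(matrix)))
    rownames(matrix) <- sprintf("cell_%06d", seq_len(nrow(matrix)))
  if (is.null(colnames(matrix)))
    colnames(matrix) <- sprintf("gene_%04d", seq_len(ncol(matrix)))
  if (anyDuplicated(rownames(matrix)))
    stop("single_cell_dataset: duplicate cell IDs", call. = FALSE)
  if (anyDuplicated(colnames(matrix)))
    stop("single_cell_dataset: duplicate gene IDs", call. = FALSE)
  if (is.data.frame(sample_group)) {
    if (!all(c("sample_id", "group") %in% names(sample_group)))
      stop("single_cell_dataset: sample_group needs columns sample_id, group",
           call. = FALSE)
    samples <- data.frame(sample_id = as.character(sample_group$sample_id),
                          group = as.character(sample_group$group),
                          stringsAsFactors = FALSE)
  } else {
    samples <- data.frame(sample_id = names(sample_group),
                          group = as.character(sample_group),
                          stringsAsFactors = FALSE)
  }
  if (anyDuplicated(samples$sample_id))
    stop("single_cell_dataset: a sample maps to more than one group",
         call. = FALSE)
  cell_sample <- as.character(cell_sample)
  missing <- setdiff(unique(cell_sample), samples$sample_id)
  if (length(missing))
    stop(sprintf("single_cell_dataset: cells reference unknown samples: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  structure(list(
    matrix = matrix,
    cells = data.frame(cell_id = rownames(matrix), sample_id = cell_sample,
                       stringsAsFactors = FALSE),
    samples = samples),
    class = "single_cell_dataset")
}

#' @export
print.single_cell_dataset <- function(x, ...) {
  cat(sprintf("single_cell_dataset: %d cells x %d genes, %d samples, groups: %s\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$samples),
              paste(sprintf("%s (n=%d)", names(table(x$samples$group)),
                            table(x$samples$group)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.single_cell_dataset <- function(x) dim(x$matrix)

# group factor aligned with a vector of sample ids
sample_groups <- function(sc, sample_ids) {
  sc$samples$group[match(sample_ids, sc$samples$sample_id)]
}
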