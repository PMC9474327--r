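# Shared I/O: Matrix Market + CSV/TSV single-cell dialect, JSON parameter
# configs, seeded run logs. The Matrix Market file stores cells in rows; that
# convention is declared in every run log to avoid silent transposition.

#' Write a single-cell dataset to Matrix Market + metadata files
#'
#' Writes `matrix.mtx` (cells in rows, genes in columns), `genes.tsv`
#' (column `gene_id`) and `cells.csv` (columns `cell_id`, `sample_id`,
#' `group`) into `dir`.
#'
#' @param sc A [single_cell_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_single_cell <- function(sc, dir) {
  stopifnot(inherits(sc, "single_cell_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.csv"))
  m <- sc$matrix
  if (!inherits(m, "sparseMatrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  Matrix::writeMM(m, paths[1])
  write.table(data.frame(gene_id = colnames(sc$matrix)), paths[2],
              sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(cell_id = sc$cells$cell_id,
                     sample_id = sc$cells$sample_id,
                     group = sample_groups(sc, sc$cells$sample_id),
                     stringsAsFactors = FALSE)
  write.csv(meta, paths[3], quote = FALSE, row.names = FALSE)
  invisible(stats::setNames(paths, c("matrix", "genes", "cells")))
}

#' Read a single-cell dataset from Matrix Market + metadata files
#'
#' Reads the dialect written by [write_single_cell()]: a Matrix Market
#' matrix with cells in rows, a `genes.tsv` with a `gene_id` column and a
#' cell metadata CSV with `cell_id`, `sample_id`, `group` rows aligned with
#' the matrix rows. Dimension mismatches, duplicate IDs and cells lacking
#' metadata are rejected with the offending IDs named.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param genes_path Path to the gene table (TSV with `gene_id` column).
#' @param cells_path Path to the cell metadata CSV.
#' @return A [single_cell_dataset()].
#' @export
read_single_cell <- function(matrix_path, genes_path, cells_path) {
  for (p in c(matrix_path, genes_path, cells_path))
    if (!file.exists(p))
      stop(sprintf("read_single_cell: file not found: %s", p), call. = FALSE)
  m <- as(Matrix::readMM(matrix_path), "CsparseMatrix")
  genes <- read.delim(genes_path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(genes))
    stop("read_single_cell: gene table must have a 'gene_id' column",
         call. = FALSE)
  cells <- read.csv(cells_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "sample_id", "group")
  if (!all(need %in% names(cells)))
    stop(sprintf("read_single_cell: cell metadata must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  if (nrow(genes) != ncol(m))
    stop(sprintf("read_single_cell: matrix has %d gene columns but %d gene IDs",
                 ncol(m), nrow(genes)), call. = FALSE)
  if (nrow(cells) != nrow(m))
    stop(sprintf("read_single_cell: matrix has %d cell rows but %d metadata rows",
                 nrow(m), nrow(cells)), call. = FALSE)
  incomplete <- cells$cell_id[is.na(cells$sample_id) | cells$sample_id == "" |
                                is.na(cells$group) | cells$group == ""]
  if (length(incomplete))
    stop(sprintf("read_single_cell: cells lacking sample/group metadata: %s",
                 paste(incomplete, collapse = ", ")), call. = FALSE)
  dimnames(m) <- list(cells$cell_id, genes$gene_id)
  sample_group <- unique(cells[c("sample_id", "group")])
  single_cell_dataset(m, cells$sample_id, sample_group)
}

#' Read model parameters from a JSON config
#'
#' Parses a config of the form
#' `{"group": {...}, "shift": {...}, "noise": {...}, "config": {...}}`
#' into the package's parameter objects. Every section is optional; absent
#' sections yield `NULL` (`shift` defaults to the null shift when a shift is
#' semantically required by the caller).
#'
#' @param path Path to a JSON file.
#' @return A list with elements `group` ([group_params()] or `NULL`),
#'   `shift` ([shift_params()] or `NULL`), `noise` ([measurement_noise()] or
#'   `NULL`), `config` ([sim_config()] or `NULL`), and `raw` (the parsed
#'   JSON, echoed into run logs verbatim).
#' @export
read_params_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(group = NULL, shift = NULL, noise = NULL, config = NULL,
              raw = cfg)
  if (!is.null(cfg$group)) out$group <- do.call(group_params, as.list(cfg$group))
  if (!is.null(cfg$shift)) out$shift <- do.call(shift_params, as.list(cfg$shift))
  if (!is.null(cfg$noise)) out$noise <- do.call(measurement_noise, as.list(cfg$noise))
  if (!is.null(cfg$config)) out$config <- do.call(sim_config, as.list(cfg$config))
  out
}

#' Write a JSON run log
#'
#' Every command-line run emits a JSON log containing the subcommand, the
#' seed, the verbatim input config and the matrix orientation convention, so
#' the run can be reproduced exactly.
#'
#' @param path Output path.
#' @param entries Named list of log fields.
#' @return Invisibly, `path`.
#' @export
write_run_log <- function(path, entries) {
  entries$matrix_orientation <- "cells_in_rows"
  entries$package_version <- as.character(utils::packageVersion("scbulkmix"))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
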