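# Pseudobulk DE/DV pipeline: per-cell normalization, per-sample averaging,
# expression filtering, Welch t-test (DE) and two-sided F-test (DV) with BH
# correction, and per-sample decomposition of a gene's cell distribution into
# estimated subset parameters (mu+hat, mu-hat, rhat) by exact 1-D 2-means.

#' Per-cell normalization: log-transform, then rescale each cell
#'
#' Applies `log(1 + count)` and rescales each cell (row) so its values sum to
#' `scale` (default 1e6). Cells whose transformed row sum is zero are left
#' all-zero and their indices attached as attribute `zero_cells`.
#'
#' @param counts Cells x genes matrix of nonnegative raw counts (base or
#'   `Matrix` sparse).
#' @param scale Target row sum after rescaling.
#' @return Normalized matrix of the same class and dimnames, with attribute
#'   `zero_cells` (integer row indices of all-zero cells).
#' @examples
#' normalize_cells(matrix(c(1, 1), nrow = 1))  # c(5e5, 5e5)
#' @export
normalize_cells <- function(counts, scale = 1e6) {
  if (length(dim(counts)) != 2)
    stop("normalize_cells: 'counts' must be a matrix", call. = FALSE)
  if (min(counts) < 0)
    stop("normalize_cells: negative entries are not valid counts",
         call. = FALSE)
  logged <- log1p(counts)
  rs <- Matrix::rowSums(logged)
  zero <- which(rs == 0)
  fac <- scale / ifelse(rs == 0, 1, rs)
  if (inherits(logged, "Matrix")) {
    out <- Matrix::Diagonal(x = fac) %*% logged
    dimnames(out) <- dimnames(counts)
  } else {
    out <- logged * fac                     # recycles down columns = per cell
  }
  attr(out, "zero_cells") <- zero
  out
}

#' Pseudobulk: per-sample mean of single-cell values
#'
#' The bulk expression of each gene in each sample is the arithmetic mean of
#' the sample's single-cell values — the empirical counterpart of the model's
#' bulk value (the population mean of the cell distribution).
#'
#' @param sc A [single_cell_dataset()].
#' @param matrix Optional replacement cells x genes matrix (same rows as
#'   `sc$matrix`), e.g. the output of [normalize_cells()].
#' @return A base samples x genes matrix; row names are sample IDs in the
#'   order of `sc$samples`.
#' @export
pseudobulk <- function(sc, matrix = NULL) {
  stopifnot(inherits(sc, "single_cell_dataset"))
  mat <- if (is.null(matrix)) sc$matrix else matrix
  if (nrow(mat) != nrow(sc$cells))
    stop("pseudobulk: matrix rows do not match the dataset's cells",
         call. = FALSE)
  f <- factor(sc$cells$sample_id, levels = sc$samples$sample_id)
  counts <- tabulate(f, nbins = nlevels(f))
  if (any(counts == 0))
    stop(sprintf("pseudobulk: samples with no cells: %s",
                 paste(levels(f)[counts == 0], collapse = ", ")),
         call. = FALSE)
  ind <- Matrix::fac2sparse(f)           # samples x cells indicator
  sums <- as.matrix(ind %*% mat)
  out <- sums / counts
  dimnames(out) <- list(levels(f), colnames(mat))
  out
}

#' Filter genes by grand-mean bulk expression
#'
#' Keeps genes whose mean bulk expression across all samples is strictly
#' greater than `threshold`. Filtering out low-expressed genes is a required
#' preprocessing step here: the proportionality between the bulk value and
#' the cell-distribution mean is technically unstable for weakly expressed
#' genes.
#'
#' @param bulk Samples x genes pseudobulk matrix.
#' @param threshold Strict lower bound on the grand mean (default 20).
#' @return Character vector of retained gene IDs, with the grand means of
#'   all genes attached as attribute `grand_means`.
#' @export
filter_genes <- function(bulk, threshold = 20) {
  gm <- colMeans(bulk)
  keep <- names(gm)[gm > threshold]
  attr(keep, "grand_means") <- gm
  keep
}

# Welch t and two-sided F for one gene; handles zero-variance degeneracies.
test_one_gene <- function(x1, x2) {
  v1 <- var(x1); v2 <- var(x2)
  m1 <- mean(x1); m2 <- mean(x2)
  degen <- FALSE
  if (v1 == 0 && v2 == 0) {
    degen <- TRUE
    t_p <- if (m1 == m2) 1 else 0
    t_stat <- if (m1 == m2) 0 else Inf * sign(m2 - m1)
    f_p <- 1
    f_stat <- NA_real_
  } else if (v1 == 0 || v2 == 0) {
    degen <- TRUE
    tt <- t.test(x2, x1, var.equal = FALSE)
    t_p <- tt$p.value; t_stat <- unname(tt$statistic)
    f_stat <- if (v1 == 0) Inf else 0
    f_p <- 0
  } else {
    tt <- t.test(x2, x1, var.equal = FALSE)
    ft <- var.test(x2, x1)
    t_p <- tt$p.value; t_stat <- unname(tt$statistic)
    f_p <- ft$p.value; f_stat <- unname(ft$statistic)
  }
  c(mean1 = m1, mean2 = m2, var1 = v1, var2 = v2,
    t_stat = t_stat, t_p = t_p, f_stat = f_stat, f_p = f_p, degen = degen)
}

#' Per-gene DE and DV tests on pseudobulk values
#'
#' For each gene, compares the two groups with a two-sided Welch t-test
#' (unequal variances; DE) and a two-sided variance-ratio F-test (DV).
#' Benjamini-Hochberg correction is applied separately to the t and F
#' p-value vectors across the tested genes, and genes are flagged at
#' adjusted p below `alpha`. Zero-variance degeneracies are resolved by
#' convention (equal constant groups: p = 1; a constant group against a
#' varying one: F p = 0) and marked in the `degenerate` column.
#'
#' @param bulk Samples x genes pseudobulk matrix (row names = sample IDs).
#' @param groups Group label per sample, aligned with `rownames(bulk)`;
#'   exactly two levels, each with at least two samples.
#' @param alpha Adjusted-p threshold for the DE/DV flags.
#' @return A data frame of class `"de_dv_result"`, one row per gene:
#'   group means and variances (columns named after the group levels),
#'   `t_stat`, `t_p`, `t_p_adj`, `f_stat`, `f_p`, `f_p_adj`, logical `de`
#'   and `dv` flags and `degenerate`. The F statistic is the variance of the
#'   second group level over the first.
#' @export
de_dv_test <- function(bulk, groups, alpha = 0.05) {
  if (nrow(bulk) != length(groups))
    stop("de_dv_test: one group label per sample row is required",
         call. = FALSE)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2)
    stop(sprintf("de_dv_test: exactly two groups required, got %d",
                 nlevels(groups)), call. = FALSE)
  if (any(table(groups) < 2))
    stop("de_dv_test: each group needs at least two samples; t and F tests are undefined otherwise",
         call. = FALSE)
  if (ncol(bulk) == 0)
    stop("de_dv_test: no genes to test", call. = FALSE)
  lv <- levels(groups)
  res <- t(apply(bulk, 2, function(v)
    test_one_gene(v[groups == lv[1]], v[groups == lv[2]])))
  out <- data.frame(gene = colnames(bulk), res, row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out)[2:5] <- c(paste0("mean_", lv), paste0("var_", lv))
  out$t_p_adj <- p.adjust(out$t_p, method = "BH")
  out$f_p_adj <- p.adjust(out$f_p, method = "BH")
  out$de <- out$t_p_adj < alpha
  out$dv <- out$f_p_adj < alpha
  out$degenerate <- out$degen == 1
  out$degen <- NULL
  structure(out, class = c("de_dv_result", "data.frame"),
            group_levels = lv, alpha = alpha)
}

#' Decompose one sample's cell distribution into subset parameters
#'
#' Splits a 1-D vector of one gene's single-cell values into two clusters by
#' exact 2-means: values are sorted and every threshold partition is scored
#' by within-cluster sum of squares via prefix sums, so the returned split is
#' the global optimum (for k = 2 in one dimension the optimal clusters are
#' intervals). The cluster with the larger mean is subset +; the estimates
#' are \eqn{\hat\mu_\pm} (cluster means) and \eqn{\hat r} (fraction of cells
#' in subset +). Deterministic; ties in the objective resolve to the larger
#' subset-+ cluster.
#'
#' Vectors with fewer than two distinct values cannot support two clusters:
#' both means are set to the common value, \eqn{\hat r = 0} (a degenerate
#' gene is read as an all-"subset -" population of low/constant expression)
#' and `degenerate` is set.
#'
#' @param values Numeric vector of one sample's cell values for one gene.
#' @return A list: `mu_plus_hat`, `mu_minus_hat`, `r_hat`, `degenerate`.
#' @examples
#' decompose_sample(c(0, 0, 0, 10, 10))  # mu+ = 10, mu- = 0, r = 0.4
#' @export
decompose_sample <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1 || anyNA(values))
    stop("decompose_sample: need at least one finite cell value",
         call. = FALSE)
  if (length(unique(values)) < 2)
    return(list(mu_plus_hat = values[1], mu_minus_hat = values[1],
                r_hat = 0, degenerate = TRUE))
  v <- sort(values)
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  j <- seq_len(n - 1)                       # lower cluster = v[1..j]
  low_ss <- cs2[j] - cs[j]^2 / j
  hi_n <- n - j
  hi_sum <- cs[n] - cs[j]
  hi_ss <- (cs2[n] - cs2[j]) - hi_sum^2 / hi_n
  wss <- low_ss + hi_ss
  best <- which.min(wss)                    # smallest j among ties: largest subset +
  list(mu_plus_hat = hi_sum[best] / hi_n[best],
       mu_minus_hat = cs[best] / best,
       r_hat = hi_n[best] / n,
       degenerate = FALSE)
}

#' Decompose one gene across all samples
#'
#' Runs [decompose_sample()] on each sample's cells for `gene` and returns
#' the per-sample subset-parameter estimates with group labels, the
#' empirical view of how \eqn{\mu_+}, \eqn{\mu_-} and \eqn{r} differ between
#' groups for that gene.
#'
#' @param sc A [single_cell_dataset()].
#' @param gene Gene ID (column of `sc$matrix`).
#' @param matrix Optional replacement cells x genes matrix (e.g. normalized).
#' @return Data frame: `gene`, `sample_id`, `group`, `mu_plus_hat`,
#'   `mu_minus_hat`, `r_hat`, `degenerate`.
#' @export
decompose_gene <- function(sc, gene, matrix = NULL) {
  stopifnot(inherits(sc, "single_cell_dataset"))
  mat <- if (is.null(matrix)) sc$matrix else matrix
  if (!gene %in% colnames(mat))
    stop(sprintf("decompose_gene: unknown gene '%s'", gene), call. = FALSE)
  col <- as.numeric(mat[, gene])
  rows <- lapply(sc$samples$sample_id, function(s) {
    est <- decompose_sample(col[sc$cells$sample_id == s])
    data.frame(gene = gene, sample_id = s,
               group = sample_groups(sc, s),
               mu_plus_hat = est$mu_plus_hat,
               mu_minus_hat = est$mu_minus_hat,
               r_hat = est$r_hat, degenerate = est$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' End-to-end pseudobulk DE/DV pipeline
#'
#' Chains the full analysis: optional per-cell normalization
#' ([normalize_cells()]) for raw counts, pseudobulk averaging
#' ([pseudobulk()]), the strict grand-mean expression filter
#' ([filter_genes()]), the Welch-t / F / BH tests ([de_dv_test()]) and
#' per-sample decomposition ([decompose_gene()]) of the top DE gene, the top
#' DV gene (smallest raw p-values) and any genes in `decompose_genes`.
#'
#' @param sc A [single_cell_dataset()].
#' @param normalize If `TRUE` (default) treat the matrix as raw counts and
#'   apply [normalize_cells()]; set `FALSE` for data already on a normalized
#'   continuous scale (e.g. simulator output).
#' @param scale Row-sum target passed to [normalize_cells()].
#' @param min_mean Strict grand-mean filter threshold.
#' @param alpha Adjusted-p threshold for the DE/DV flags.
#' @param decompose_genes Additional gene IDs to decompose (on top of the
#'   top DE and top DV genes).
#' @return A list of class `"scbulk_pipeline"`: `tests` (a
#'   [de_dv_test()] result), `decomposition` (long per-sample estimates for
#'   the selected genes), `decomposition_summary` (per gene x group means of
#'   the estimates), and `log` (gene counts at each stage, parameters used).
#'   If no gene passes the filter a warning is issued and `tests` /
#'   `decomposition` are empty.
#' @export
run_pipeline <- function(sc, normalize = TRUE, scale = 1e6, min_mean = 20,
                         alpha = 0.05, decompose_genes = character()) {
  stopifnot(inherits(sc, "single_cell_dataset"))
  grp_sizes <- table(sc$samples$group)
  if (length(grp_sizes) != 2 || any(grp_sizes < 2))
    stop("run_pipeline: need exactly two groups with >= 2 samples each; t and F tests are undefined otherwise",
         call. = FALSE)
  mat <- if (normalize) normalize_cells(sc$matrix, scale = scale) else sc$matrix
  bulk <- pseudobulk(sc, matrix = mat)
  kept <- filter_genes(bulk, threshold = min_mean)
  log <- list(normalize = normalize, scale = scale, min_mean = min_mean,
              alpha = alpha, n_cells = nrow(sc$matrix),
              n_samples = nrow(sc$samples),
              n_genes_input = ncol(sc$matrix), n_genes_tested = length(kept))
  if (length(kept) == 0) {
    warning("run_pipeline: no genes pass the expression filter; empty result")
    return(structure(list(tests = NULL, decomposition = NULL,
                          decomposition_summary = NULL, log = log),
                     class = "scbulk_pipeline"))
  }
  groups <- sample_groups(sc, rownames(bulk))
  tests <- de_dv_test(bulk[, kept, drop = FALSE], groups, alpha = alpha)
  top_de <- tests$gene[which.min(tests$t_p)]
  top_dv <- tests$gene[which.min(tests$f_p)]
  targets <- unique(c(top_de, top_dv, intersect(decompose_genes, kept),
                      intersect(decompose_genes, colnames(mat))))
  decomp <- do.call(rbind, lapply(targets, function(g)
    decompose_gene(sc, g, matrix = mat)))
  summ <- aggregate(decomp[c("mu_plus_hat", "mu_minus_hat", "r_hat")],
                    by = decomp[c("gene", "group")], FUN = mean)
  log$top_de_gene <- top_de
  log$top_dv_gene <- top_dv
  log$n_de <- sum(tests$de)
  log$n_dv <- sum(tests$dv)
  structure(list(tests = tests, decomposition = decomp,
                 decomposition_summary = summ, log = log),
            class = "scbulk_pipeline")
}

#' @export
print.scbulk_pipeline <- function(x, ...) {
  l <- x$log
  cat(sprintf("scbulk pipeline: %d/%d genes tested (grand mean > %g)\n",
              l$n_genes_tested, l$n_genes_input, l$min_mean))
  if (!is.null(x$tests))
    cat(sprintf("  DE genes: %d, DV genes: %d (BH-adjusted p < %g)\n  top DE: %s, top DV: %s\n",
                l$n_de, l$n_dv, l$alpha, l$top_de_gene, l$top_dv_gene))
  invisible(x)
}
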