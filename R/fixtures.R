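# Synthetic multi-gene, multi-sample single-cell fixtures with known ground
# truth. Each gene is generated independently from the two-component mixture
# scheme under its own donor-population and shift parameters, so the DE/DV
# pipeline can be validated end-to-end without external data.

ARCHETYPE_LABELS <- c("null", "de", "dv_proportion", "dv_shift", "cancel",
                      "filtered")

#' Define one gene's generative archetype
#'
#' Couples a [group_params()] / [shift_params()] pair with per-gene cell
#' variances and a label describing the intended behaviour. The label is
#' checked against the closed forms at construction: a `"de"` gene must have
#' a nonzero bulk mean difference, `"dv_proportion"` / `"dv_shift"` /
#' `"cancel"` genes must have a (near-)zero mean difference, the two `dv`
#' labels a nonzero variance difference, and `"cancel"` a positive `d_plus`
#' with `alpha_r < 1`.
#'
#' @param name Gene ID.
#' @param gp Reference-group [group_params()].
#' @param shift A [shift_params()] (use the default null shift for `"null"`).
#' @param v_y_plus,v_y_minus Within-subset cell variances for this gene.
#' @param label One of `"null"`, `"de"`, `"dv_proportion"`, `"dv_shift"`,
#'   `"cancel"`, `"filtered"`.
#' @return An object of class `"gene_archetype"`.
#' @export
gene_archetype <- function(name, gp, shift = shift_params(),
                           v_y_plus = 1, v_y_minus = 1, label = "null") {
  check_group_params(gp)
  check_shift_params(shift)
  if (!label %in% ARCHETYPE_LABELS)
    stop(sprintf("gene_archetype: unknown label '%s' (expected one of %s)",
                 label, paste(ARCHETYPE_LABELS, collapse = ", ")),
         call. = FALSE)
  if (v_y_plus < 0 || v_y_minus < 0)
    stop("gene_archetype: cell variances must be >= 0", call. = FALSE)
  dmean <- mean_difference(gp, shift)      # also validates alpha_r * e_r
  dvar <- variance_bulk(apply_shift(gp, shift)) - variance_bulk(gp)
  tol <- 1e-8
  ok <- switch(label,
    null = abs(dmean) < tol && abs(dvar) < tol,
    de = abs(dmean) > tol,
    dv_proportion = abs(dmean) < tol && abs(dvar) > tol,
    dv_shift = abs(dmean) < tol && abs(dvar) > tol,
    cancel = abs(dmean) < tol && shift$d_plus > 0 && shift$alpha_r < 1,
    filtered = TRUE)
  if (!ok)
    stop(sprintf(
      paste0("gene_archetype '%s': label '%s' is inconsistent with the closed ",
             "forms (mean difference %.3g, variance difference %.3g)"),
      name, label, dmean, dvar), call. = FALSE)
  structure(list(name = name, gp = gp, shift = shift,
                 v_y_plus = v_y_plus, v_y_minus = v_y_minus, label = label,
                 delta_mean = dmean, delta_var = dvar),
            class = "gene_archetype")
}

#' Standard archetype panel for pipeline validation
#'
#' A panel of two-component genes on an already-normalized expression scale
#' (grand means above the default filter threshold of 20):
#' * `n_null` null genes — no group difference;
#' * one `de` gene — equal shifts in both subsets, no proportion change:
#'   pure mean difference, variance untouched;
#' * one `dv_proportion` gene — the proportion route to differential
#'   variability (unequal subset variances, proportion drop at the exact
#'   cancellation point, so means stay equal while variance falls);
#' * one `dv_shift` gene — the mean-gap route (tiny equal subset variances,
#'   strongly unequal shifts widen the gap at the cancellation point, so
#'   means stay equal while variance rises);
#' * one `cancel` gene — well-separated subsets where a positive subset-+
#'   shift is exactly offset by a proportion decrease: invisible to a bulk
#'   DE test, visible to per-sample decomposition as a raised
#'   \eqn{\hat\mu_+} and lowered \eqn{\hat r}.
#'
#' @param n_null Number of null genes.
#' @return Named list of [gene_archetype()] objects.
#' @export
archetype_panel <- function(n_null = 16) {
  base <- group_params(e_plus = 25, e_minus = 20, e_r = 0.5,
                       v_plus = 0.5, v_minus = 0.5, v_r = 0.01)
  panel <- list()
  for (i in seq_len(n_null))
    panel[[sprintf("null_%02d", i)]] <-
      gene_archetype(sprintf("null_%02d", i), base, label = "null")
  panel$de <- gene_archetype("de", base,
                             shift_params(d_plus = 0.4, d_minus = 0.4),
                             label = "de")
  gp_prop <- group_params(22, 21, 0.9, v_plus = 1, v_minus = 0.1, v_r = 0.001)
  panel$dv_proportion <- gene_archetype(
    "dv_proportion", gp_prop,
    shift_params(0.5, 0.5, cancellation_alpha_bound(gp_prop, 0.5, 0.5)),
    label = "dv_proportion")
  gp_gap <- group_params(22, 21, 0.9, v_plus = 0.01, v_minus = 0.01,
                         v_r = 0.001)
  panel$dv_shift <- gene_archetype(
    "dv_shift", gp_gap,
    shift_params(10, 0.1, cancellation_alpha_bound(gp_gap, 10, 0.1)),
    label = "dv_shift")
  gp_cancel <- group_params(30, 20, 0.5, v_plus = 0.5, v_minus = 0.5,
                            v_r = 0.01)
  panel$cancel <- gene_archetype(
    "cancel", gp_cancel,
    shift_params(0.5, 0, cancellation_alpha_bound(gp_cancel, 0.5, 0)),
    label = "cancel")
  panel
}

#' Generate a synthetic single-cell dataset with ground truth
#'
#' Assembles a cells x genes matrix gene by gene: for each archetype, donor
#' parameters are drawn per sample (group C from `gp`, group D via `shift`)
#' and each donor contributes `cells_per_sample` mixture cells. Genes are
#' statistically independent; all genes share the same cell/sample/group
#' structure. Values are continuous mixture draws on the normalized scale;
#' `nonnegative = TRUE` truncates at zero (flagging affected genes) and
#' `counts = TRUE` additionally rounds to integers for I/O realism — both
#' perturb the moments and are off by default.
#'
#' @param archetypes List of [gene_archetype()] objects (see
#'   [archetype_panel()]).
#' @param samples_per_group Donors per group.
#' @param cells_per_sample Cells per donor.
#' @param seed Integer seed; output is fully reproducible from it.
#' @param nonnegative Truncate values at zero.
#' @param counts Round to integer counts (implies `nonnegative`).
#' @return A list: `dataset` (a [single_cell_dataset()]), `truth` (data
#'   frame of per-gene, per-sample `mu_plus`, `mu_minus`, `r`, `group`,
#'   `archetype`), and `archetype_table` (per-gene label and closed-form
#'   mean/variance differences). Attribute `truncated_genes` lists genes
#'   affected by truncation.
#' @export
generate_dataset <- function(archetypes, samples_per_group, cells_per_sample,
                             seed = 1L, nonnegative = FALSE, counts = FALSE) {
  if (!length(archetypes))
    stop("generate_dataset: empty archetype list", call. = FALSE)
  bad <- !vapply(archetypes, inherits, logical(1), "gene_archetype")
  if (any(bad))
    stop(sprintf("generate_dataset: not gene_archetype objects at positions: %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  nms <- unname(vapply(archetypes, `[[`, character(1), "name"))
  if (anyDuplicated(nms))
    stop("generate_dataset: duplicate archetype names", call. = FALSE)
  if (counts) nonnegative <- TRUE
  n_s <- as.integer(samples_per_group)
  n_c <- as.integer(cells_per_sample)
  if (n_s < 2 || n_c < 1)
    stop("generate_dataset: need >= 2 samples per group and >= 1 cell per sample",
         call. = FALSE)

  sample_ids <- c(sprintf("C%03d", seq_len(n_s)), sprintf("D%03d", seq_len(n_s)))
  groups <- rep(c("C", "D"), each = n_s)
  cell_sample <- rep(sample_ids, each = n_c)
  n_cells_total <- length(cell_sample)

  set.seed(as.integer(seed))
  mat <- matrix(0, nrow = n_cells_total, ncol = length(archetypes),
                dimnames = list(sprintf("cell_%06d", seq_len(n_cells_total)),
                                nms))
  truth <- vector("list", length(archetypes))
  truncated <- character()
  for (g in seq_along(archetypes)) {
    a <- archetypes[[g]]
    cfg <- sim_config(n_samples = n_s, n_cells = n_c,
                      v_y_plus = a$v_y_plus, v_y_minus = a$v_y_minus,
                      seed = seed)
    donors <- rbind(sample_donor_params(a$gp, NULL, n_s),
                    sample_donor_params(a$gp, a$shift, n_s))
    col <- unlist(lapply(seq_len(nrow(donors)), function(i)
      simulate_cells(donors[i, ], cfg)), use.names = FALSE)
    if (nonnegative) {
      if (any(col < 0)) truncated <- c(truncated, a$name)
      col <- pmax(col, 0)
    }
    if (counts) col <- round(col)
    mat[, g] <- col
    truth[[g]] <- data.frame(gene = a$name, archetype = a$label,
                             sample_id = sample_ids, group = groups,
                             mu_plus = donors$mu_plus,
                             mu_minus = donors$mu_minus, r = donors$r,
                             stringsAsFactors = FALSE)
  }
  arch_tab <- data.frame(
    gene = nms,
    archetype = vapply(archetypes, `[[`, character(1), "label"),
    delta_mean = vapply(archetypes, `[[`, numeric(1), "delta_mean"),
    delta_var = vapply(archetypes, `[[`, numeric(1), "delta_var"),
    stringsAsFactors = FALSE)
  structure(list(
    dataset = single_cell_dataset(mat, cell_sample,
                                  data.frame(sample_id = sample_ids,
                                             group = groups)),
    truth = do.call(rbind, truth),
    archetype_table = arch_tab),
    truncated_genes = truncated)
}
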