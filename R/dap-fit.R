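#' Differentially abundant protein selection
#'
#' The package's central fit: runs the full label-free comparison on a PSM
#' count matrix and a group design, and returns the selected differentially
#' abundant proteins (DAPs) with their provenance. The procedure is
#'
#' 1. total-signal normalization ([normalize_total_signal()]), unless the
#'    matrix is already normalized;
#' 2. identification-frequency selection: IF strictly above `if_high` in one
#'    group and strictly below `if_low` in at least one other
#'    ([select_daps_by_if()]);
#' 3. F-ratio selection: one-way F across groups with
#'    `F >= f_threshold` and `p <= p_threshold` ([anova_f_selection()]),
#'    retained only where some pairwise |DAve| reaches `dave_threshold`;
#' 4. union of both selections, each protein labelled `"IF"`, `"F"` or
#'    `"both"`, annotated with per-group means, per-group IF, the pairwise
#'    DAve index for every group pair, and the F statistics.
#'
#' @param x a [psm_matrix()] (raw counts are normalized internally).
#' @param design a [group_design()]; at least two groups of two subjects or
#'   more.
#' @param f_threshold,p_threshold F-selection cutoffs (defaults 3.5 and
#'   0.05, applied jointly).
#' @param if_high,if_low IF-rule percent cutoffs (defaults 50 and 50, strict).
#' @param dave_threshold minimum |DAve| for an F-derived pairwise call
#'   (default 0.4).
#' @return An object of class `dap_fit` with components `table` (the DAP
#'   table), `if_table`, `anova`, `profiles` (group means, all proteins),
#'   `spearman` (group-profile rank correlations), `matrix` (normalized),
#'   `design`, `thresholds`, `call`. Methods: [print.dap_fit()],
#'   [summary.dap_fit()], [plot.dap_fit()].
#' @examples
#' sim <- simulate_cohort(sim_config(n_proteins = 150, seed = 7))
#' fit <- dap_fit(sim$matrix, sim$design)
#' fit
#' @export
dap_fit <- function(x, design, f_threshold = 3.5, p_threshold = 0.05,
                    if_high = 50, if_low = 50, dave_threshold = 0.4) {
  check_design(x, design)
  norm <- if (is_normalized(x)) x else normalize_total_signal(x)

  if_table <- identification_frequency(x, design)
  if_set <- select_daps_by_if(if_table, high = if_high, low = if_low)

  anova <- anova_f_selection(norm, design,
                             f_threshold = f_threshold,
                             p_threshold = p_threshold)
  profiles <- group_mean_profiles(norm, design)
  labs <- colnames(profiles)
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  dave <- vapply(pairs, function(p)
    dave_index(profiles[, p[1]], profiles[, p[2]]), numeric(nrow(profiles)))
  if (nrow(profiles) == 1L) dave <- matrix(dave, nrow = 1)
  dimnames(dave) <- list(rownames(profiles),
                         vapply(pairs, function(p)
                           paste0("DAve_", p[1], "_vs_", p[2]), ""))

  f_set <- anova$protein_id[anova$selected]
  # an F-selected protein must also show a direction: some pair at |DAve|
  # at or above the cut
  max_abs_dave <- apply(abs(dave), 1, function(d)
    if (all(is.na(d))) NA_real_ else max(d, na.rm = TRUE))
  f_set <- f_set[dave_pass(max_abs_dave[f_set], dave_threshold)]

  daps <- union(if_set, f_set)
  daps <- rownames(x)[rownames(x) %in% daps]   # matrix order
  source <- ifelse(daps %in% if_set & daps %in% f_set, "both",
                   ifelse(daps %in% if_set, "IF", "F"))
  tab <- data.frame(protein_id = daps, source = source,
                    stringsAsFactors = FALSE, row.names = NULL)
  mean_cols <- profiles[daps, , drop = FALSE]
  colnames(mean_cols) <- paste0("mean_", labs)
  if_cols <- if_table[daps, , drop = FALSE]
  colnames(if_cols) <- paste0("IF_", labs)
  idx <- match(daps, anova$protein_id)
  tab <- cbind(tab, mean_cols, if_cols, dave[daps, , drop = FALSE],
               F_ratio = anova$F_ratio[idx], p_value = anova$p_value[idx])
  rownames(tab) <- NULL

  structure(list(table = tab, if_table = if_table, anova = anova,
                 profiles = profiles,
                 spearman = spearman_group_correlation(profiles),
                 dave = dave, matrix = norm, design = design,
                 thresholds = list(f = f_threshold, p = p_threshold,
                                   if_high = if_high, if_low = if_low,
                                   dave = dave_threshold),
                 call = match.call()),
            class = "dap_fit")
}

#' @export
print.dap_fit <- function(x, ...) {
  src <- table(factor(x$table$source, levels = c("IF", "F", "both")))
  cat("Differentially abundant protein selection\n")
  cat(sprintf("  %d proteins, %d subjects, groups: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s (n=%d)", group_labels(x$design),
                            table(x$design$group)), collapse = ", ")))
  cat(sprintf("  %d DAPs selected: %d by IF rule, %d by F ratio, %d by both\n",
              nrow(x$table), src[["IF"]], src[["F"]], src[["both"]]))
  cat(sprintf("  thresholds: F >= %g & p <= %g; IF > %g%% / < %g%%; |DAve| >= %g\n",
              x$thresholds$f, x$thresholds$p, x$thresholds$if_high,
              x$thresholds$if_low, x$thresholds$dave))
  invisible(x)
}

#' Summarize a DAP selection
#'
#' @param object a [dap_fit()] object.
#' @param n number of top proteins (by F ratio) to show.
#' @param ... unused.
#' @export
summary.dap_fit <- function(object, n = 10, ...) {
  print(object)
  cat("\nSpearman correlation of group mean profiles:\n")
  print(round(object$spearman, 2))
  tab <- object$table[order(-object$table$F_ratio), ]
  cat(sprintf("\nTop %d DAPs by F ratio:\n", min(n, nrow(tab))))
  print(utils::head(tab, n), digits = 3)
  invisible(object)
}

#' Quality-control plot for a DAP selection
#'
#' Side-by-side dendrogram (Euclidean distance, Ward linkage) and PCA score
#' plot of the subjects on the DAP submatrix, the standard check that
#' subjects cluster by clinical group.
#'
#' @param x a [dap_fit()] object with at least 2 DAPs.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the [cluster_qc()] result.
#' @export
plot.dap_fit <- function(x, ...) {
  if (nrow(x$table) < 2) stop("need at least 2 DAPs to plot")
  sub <- psm_matrix(psm_values(x$matrix)[x$table$protein_id, , drop = FALSE],
                    normalized = TRUE)
  qc <- cluster_qc(sub, x$design)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(qc$hclust, main = "Subjects (Ward / Euclidean)", xlab = "", sub = "")
  grp <- x$design$group[match(rownames(qc$pca$x), x$design$subject)]
  graphics::plot(qc$pca$x[, 1:2], col = as.integer(grp), pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * qc$variance_share[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * qc$variance_share[2]),
                 main = "PCA of subjects", ...)
  graphics::legend("topright", legend = levels(grp), col = seq_len(nlevels(grp)),
                   pch = 19, cex = 0.8)
  invisible(qc)
}

#' Selected DAP identifiers
#'
#' @param object a `dap_fit` object.
#' @param source optional filter: `"IF"`, `"F"` or `"both"`.
#' @param ... unused.
#' @return Character vector of protein IDs.
#' @export
daps <- function(object, source = NULL, ...) {
  tab <- object$table
  if (!is.null(source)) tab <- tab[tab$source %in% source, ]
  tab$protein_id
}
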