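# round half away from zero, matching printed integer percentages
# (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Total-signal normalization
#'
#' Scales every subject column so that all column totals equal the mean of
#' the original column totals. This removes per-run loading differences while
#' preserving the overall count magnitude; zero entries stay exactly zero.
#'
#' @param x a raw [psm_matrix()].
#' @return A normalized `psm_matrix`.
#' @examples
#' m <- psm_matrix(matrix(c(10, 90, 30, 270), 2, 2,
#'                 dimnames = list(c("P1", "P2"), c("s1", "s2"))))
#' colSums(normalize_total_signal(m))
#' @export
normalize_total_signal <- function(x) {
  if (!inherits(x, "psm_matrix")) stop("'x' must be a psm_matrix")
  v <- psm_values(x)
  totals <- colSums(v)
  if (any(totals == 0))
    stop("subject(s) with all-zero counts: ",
         paste(colnames(v)[totals == 0], collapse = ", "))
  target <- mean(totals)
  psm_matrix(sweep(v, 2, target / totals, `*`), normalized = TRUE)
}

#' Per-group mean abundance profiles
#'
#' Arithmetic mean of (normalized) PSM values over each group's subjects,
#' per protein.
#'
#' @param x a `psm_matrix` (normalized for downstream DAve use).
#' @param design a [group_design()] covering the matrix's subjects.
#' @return Numeric matrix, proteins x groups.
#' @export
group_mean_profiles <- function(x, design) {
  check_design(x, design)
  v <- psm_values(x)
  gs <- group_subjects(design)
  out <- vapply(gs, function(s) rowMeans(v[, s, drop = FALSE]),
                numeric(nrow(v)))
  if (nrow(v) == 1L) out <- matrix(out, nrow = 1,
                                   dimnames = list(rownames(v), names(gs)))
  out
}

#' Spearman correlation between group profiles
#'
#' Rank correlation of the per-group mean abundance vectors, with average
#' ranks for ties. A constant profile has no defined rank correlation and is
#' reported as `NA`, never coerced to 0; the diagonal is always 1.
#'
#' @param profiles proteins-x-groups matrix as from [group_mean_profiles()].
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_group_correlation <- function(profiles) {
  if (ncol(profiles) < 2) stop("need at least 2 group profiles")
  r <- suppressWarnings(stats::cor(profiles, method = "spearman"))
  diag(r) <- 1
  r
}

#' Venn partition of group presence sets
#'
#' Counts the exclusive regions of the Venn diagram over per-group protein
#' presence sets: for g groups, all 2^g - 1 nonempty membership signatures.
#' Region counts sum to the size of the union.
#'
#' @param presence_sets named list, group label -> character vector of
#'   protein IDs present in that group.
#' @return Named integer vector; names are signatures like `"A"`, `"A&B"`.
#' @examples
#' overlap_partition(list(A = c("a", "b", "c"), B = c("b", "c", "d"),
#'                        C = c("c", "e")))
#' @export
overlap_partition <- function(presence_sets) {
  g <- length(presence_sets)
  if (g < 1) stop("need at least one set")
  labs <- names(presence_sets)
  if (is.null(labs) || any(labs == "")) stop("sets must be named")
  universe <- unique(unlist(presence_sets, use.names = FALSE))
  member <- vapply(presence_sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  # all nonempty signatures, ordered by region size then label order
  sigs <- expand.grid(rep(list(c(TRUE, FALSE)), g))[-(2^g), , drop = FALSE]
  names(sigs) <- labs
  counts <- apply(sigs, 1, function(s) {
    if (length(universe) == 0) return(0L)
    sum(colSums(t(member) == s) == g)
  })
  names(counts) <- apply(sigs, 1, function(s) paste(labs[as.logical(s)],
                                                    collapse = "&"))
  ord <- order(rowSums(sigs), decreasing = FALSE)
  counts <- counts[ord]
  storage.mode(counts) <- "integer"
  counts
}

#' Identification frequency (IF)
#'
#' Per protein and group, the percentage of the group's subjects in which
#' the protein is detected (PSM value strictly positive), rounded half away
#' from zero to an integer percent -- the convention under which detection in
#' 4 of 7 subjects prints as 57%.
#'
#' @inheritParams group_mean_profiles
#' @return Integer matrix, proteins x groups, values in 0..100.
#' @export
identification_frequency <- function(x, design) {
  check_design(x, design)
  det <- psm_values(x) > 0
  gs <- group_subjects(design)
  out <- vapply(gs, function(s)
    round_half_away(100 * rowMeans(det[, s, drop = FALSE])),
    numeric(nrow(det)))
  if (nrow(det) == 1L) out <- matrix(out, nrow = 1,
                                     dimnames = list(rownames(det), names(gs)))
  storage.mode(out) <- "integer"
  out
}

#' IF-rule selection of differentially abundant proteins
#'
#' A protein is selected when its identification frequency is strictly above
#' 50% in some group and strictly below 50% in at least one other group.
#' This presence/absence rule recovers condition-exclusive proteins that a
#' variance-based criterion misses.
#'
#' @param if_table integer IF matrix from [identification_frequency()].
#' @param high,low thresholds in percent (defaults 50/50; strict
#'   inequalities on both sides).
#' @return Character vector of selected protein IDs.
#' @export
select_daps_by_if <- function(if_table, high = 50, low = 50) {
  hit <- apply(if_table, 1, function(f) any(f > high) && any(f < low))
  rownames(if_table)[hit]
}

# vectorized one-way F over matrix rows; shared by protein- and term-level
# selection. Zero total variance => F = 0.
row_f_stats <- function(v, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  n <- ncol(v)
  if (k < 2) stop("need at least 2 groups")
  sizes <- table(group)
  if (any(sizes < 2)) stop("every group needs at least 2 subjects")
  grand <- rowMeans(v)
  means <- vapply(levels(group), function(g)
    rowMeans(v[, group == g, drop = FALSE]), numeric(nrow(v)))
  if (nrow(v) == 1L) means <- matrix(means, nrow = 1)
  ssb <- as.vector(means^2 %*% as.numeric(sizes)) - n * grand^2
  sst <- rowSums(v^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[sst <= .Machine$double.eps * n * pmax(grand^2, 1)] <- 0
  f[ssw == 0 & ssb > 0] <- Inf
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  data.frame(protein_id = rownames(v), F_ratio = f, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' F-ratio selection of differentially abundant proteins
#'
#' Per-protein one-way between/within-group variance ratio across all
#' groups, the univariate F-to-enter criterion of stepwise discriminant
#' analysis. A protein is selected when `F >= f_threshold` and
#' `p <= p_threshold` jointly hold; the p-value comes from the F
#' distribution with `g - 1` and `N - g` degrees of freedom.
#'
#' @inheritParams group_mean_profiles
#' @param f_threshold minimum F ratio (default 3.5).
#' @param p_threshold maximum p-value (default 0.05).
#' @return Data frame with columns `protein_id`, `F_ratio`, `p_value`,
#'   `selected`.
#' @export
anova_f_selection <- function(x, design, f_threshold = 3.5,
                              p_threshold = 0.05) {
  check_design(x, design)
  v <- psm_values(x)
  group <- design$group[match(colnames(v), design$subject)]
  res <- row_f_stats(v, group)
  res$selected <- res$F_ratio >= f_threshold & res$p_value <= p_threshold
  res
}

#' DAve differential-abundance index
#'
#' For mean abundances `a` and `b` of two compared conditions,
#' `DAve = ((a - b) / (a + b)) / 0.5`, bounded in `[-2, 2]`. A protein seen
#' exclusively in one condition takes the boundary value by convention:
#' `+2` when only `a` is positive, `-2` when only `b` is. Positive values
#' mean up in the first condition. Both means zero is undefined and returns
#' `NA`. The index is antisymmetric and invariant to common rescaling of
#' both means.
#'
#' @param a,b non-negative mean abundances (vectorized).
#' @return Numeric vector in `[-2, 2]`, `NA` where both means are zero.
#' @examples
#' dave_index(5, 0)   # +2: exclusive to condition A
#' dave_index(3, 1)   # 1
#' @export
dave_index <- function(a, b) {
  if (any(c(a, b) < 0, na.rm = TRUE)) stop("means must be non-negative")
  out <- ((a - b) / (a + b)) / 0.5
  out[a == 0 & b == 0] <- NA_real_
  out[a > 0 & b == 0] <- 2
  out[a == 0 & b > 0] <- -2
  out
}

#' DAve magnitude filter
#'
#' Retains a pairwise comparison when `|DAve| >= threshold` (default 0.4),
#' the two-sided magnitude cut used to call a direction on F-selected
#' proteins. `NA` (undefined DAve) is never retained.
#'
#' @param dave DAve values in `[-2, 2]`.
#' @param threshold magnitude cutoff (default 0.4, inclusive).
#' @return Logical vector.
#' @export
dave_pass <- function(dave, threshold = 0.4) {
  !is.na(dave) & abs(dave) >= threshold
}

#' Exact presence/absence test between two groups
#'
#' Two-sided exact rank-sum test on binary detection indicators (1 when a
#' protein's PSM value is positive in a subject). Under the permutation null
#' over group assignments the number of detected subjects falling in the
#' first group is hypergeometric, and the two-sided p-value doubles the
#' smaller tail (clamped at 1). With a small cohort the null is evaluated
#' exactly, never by normal approximation.
#'
#' @inheritParams group_mean_profiles
#' @param group_a,group_b the two group labels to compare.
#' @return Data frame per protein: detected counts and integer percents per
#'   group, `p_value` (exact), and `p_adjusted` (Benjamini-Hochberg across
#'   proteins).
#' @export
presence_test <- function(x, design, group_a, group_b) {
  check_design(x, design)
  gs <- group_subjects(design)
  for (g in c(group_a, group_b))
    if (!g %in% names(gs)) stop("unknown group: ", g)
  sa <- gs[[group_a]]; sb <- gs[[group_b]]
  na <- length(sa); nb <- length(sb)
  if (na < 2 || nb < 2) stop("both groups need at least 2 subjects")
  det <- psm_values(x) > 0
  ca <- rowSums(det[, sa, drop = FALSE])
  cb <- rowSums(det[, sb, drop = FALSE])
  p <- mapply(presence_p_exact, ca, cb, MoreArgs = list(na = na, nb = nb))
  data.frame(protein_id = rownames(det),
             detected_a = ca, percent_a = as.integer(round_half_away(100 * ca / na)),
             detected_b = cb, percent_b = as.integer(round_half_away(100 * cb / nb)),
             p_value = p,
             p_adjusted = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# exact two-sided p for t = detected-in-A out of m = ca + cb detected total,
# assignments of m detected subjects to a group of size na among N = na + nb
presence_p_exact <- function(ca, cb, na, nb) {
  m <- ca + cb
  lo <- stats::phyper(ca, m, na + nb - m, na)                    # P(T <= t)
  hi <- stats::phyper(ca - 1, m, na + nb - m, na, lower.tail = FALSE) # P(T >= t)
  min(1, 2 * min(lo, hi))
}

#' Clustering and PCA quality control
#'
#' Agglomerative clustering of subjects (Euclidean distance, Ward linkage)
#' and PCA of subjects on the selected-protein submatrix, used to check that
#' subjects group by clinical label and to spot outliers.
#'
#' @param x normalized `psm_matrix` restricted to the proteins of interest
#'   (at least 2).
#' @inheritParams group_mean_profiles
#' @return List with `hclust` (the dendrogram), `pca` (`prcomp` of
#'   subjects), and `variance_share` (per-component fraction of variance,
#'   summing to 1).
#' @export
cluster_qc <- function(x, design) {
  check_design(x, design)
  if (nrow(x) < 2) stop("need at least 2 proteins")
  if (ncol(x) < 3) stop("need at least 3 subjects")
  v <- t(psm_values(x))                      # subjects x proteins
  hc <- stats::hclust(stats::dist(v, method = "euclidean"),
                      method = "ward.D2")
  pca <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  share <- pca$sdev^2 / sum(pca$sdev^2)
  list(hclust = hc, pca = pca, variance_share = share)
}
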