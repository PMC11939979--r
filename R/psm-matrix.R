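#' PSM count matrix
#'
#' Wraps a protein-by-subject matrix of peptide-spectrum-match (PSM) counts,
#' the semi-quantitative abundance measure of spectral-count label-free
#' proteomics. Rows are proteins, columns are subjects. Raw matrices hold
#' non-negative integers; after total-signal normalization entries are
#' non-negative reals and the `normalized` flag is set.
#'
#' @param x numeric matrix with unique rownames (protein IDs) and unique
#'   colnames (subject IDs); no negative entries.
#' @param normalized logical flag, `TRUE` once column totals have been equalized.
#' @return An object of class `psm_matrix` (a numeric matrix with a
#'   `normalized` attribute).
#' @examples
#' m <- matrix(c(3, 0, 5, 2), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' psm_matrix(m)
#' @export
psm_matrix <- function(x, normalized = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("'x' must have protein rownames and subject colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate protein IDs in rownames")
  if (anyDuplicated(colnames(x)))
    stop("duplicate subject IDs in colnames")
  if (any(is.na(x)) || any(x < 0))
    stop("PSM values must be non-negative and non-missing")
  structure(x, normalized = isTRUE(normalized),
            class = c("psm_matrix", class(matrix())))
}

#' @export
print.psm_matrix <- function(x, ...) {
  cat(sprintf("psm_matrix: %d proteins x %d subjects (%s)\n",
              nrow(x), ncol(x),
              if (is_normalized(x)) "normalized" else "raw counts"))
  n <- min(nrow(x), 5L); m <- min(ncol(x), 6L)
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n) cat(sprintf("... %d more proteins\n", nrow(x) - n))
  invisible(x)
}

#' @rdname psm_matrix
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

# strip class, keep dimnames
psm_values <- function(x) {
  y <- unclass(x)
  attr(y, "normalized") <- NULL
  y
}

#' Subject-to-group design
#'
#' Assigns each subject to exactly one clinical group (e.g. healthy donors
#' and low-/high-risk patient strata). Group label order is kept as given and
#' determines the order of all per-group outputs.
#'
#' @param subject character vector of unique subject IDs.
#' @param group character or factor of the same length; at least two distinct
#'   groups, each nonempty.
#' @return A `group_design` data frame with columns `subject` and `group`
#'   (factor with levels in first-appearance order).
#' @examples
#' group_design(c("s1", "s2", "s3", "s4"), c("A", "A", "B", "B"))
#' @export
group_design <- function(subject, group) {
  subject <- as.character(subject)
  if (anyDuplicated(subject)) stop("duplicate subject IDs")
  if (length(subject) != length(group))
    stop("'subject' and 'group' lengths differ")
  if (!is.factor(group)) group <- factor(group, levels = unique(as.character(group)))
  group <- droplevels(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  structure(data.frame(subject = subject, group = group,
                       stringsAsFactors = FALSE),
            class = c("group_design", "data.frame"))
}

group_labels <- function(design) levels(design$group)

# named list: group label -> subject IDs
group_subjects <- function(design) {
  split(design$subject, design$group)
}

# check design covers the matrix columns exactly once; returns design
# restricted/ordered is not needed -- we index columns by subject ID.
check_design <- function(x, design) {
  missing <- setdiff(colnames(x), design$subject)
  if (length(missing))
    stop("subjects missing from design: ", paste(missing, collapse = ", "))
  extra <- setdiff(design$subject, colnames(x))
  if (length(extra))
    stop("design subjects absent from matrix: ", paste(extra, collapse = ", "))
  invisible(design)
}

#' Read and write the package's tabular formats
#'
#' Plain TSV with headers: the PSM matrix has a leading `protein_id` column
#' followed by one column per subject; the design table has columns
#' `subject` and `group`; the interaction table has columns `protein1`,
#' `protein2`, `databases_score`, `experiments_score` (scores in `[0, 1]`).
#'
#' @param x object to write.
#' @param path file path.
#' @return Readers return the corresponding object (`psm_matrix`,
#'   `group_design`, or a data frame of interactions); writers return the
#'   path invisibly.
#' @name spectronet-io
NULL

#' @rdname spectronet-io
#' @export
write_psm_tsv <- function(x, path) {
  df <- data.frame(protein_id = rownames(x), psm_values(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname spectronet-io
#' @param normalized for `read_psm_tsv`, whether the stored matrix is
#'   already normalized.
#' @export
read_psm_tsv <- function(path, normalized = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  psm_matrix(m, normalized = normalized)
}

#' @rdname spectronet-io
#' @export
write_design_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname spectronet-io
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  group_design(df$subject, df$group)
}

#' @rdname spectronet-io
#' @export
write_interactions_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname spectronet-io
#' @export
read_interactions_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_interactions(df)
}

validate_interactions <- function(df) {
  need <- c("protein1", "protein2", "databases_score", "experiments_score")
  if (!all(need %in% names(df)))
    stop("interaction table needs columns: ", paste(need, collapse = ", "))
  sc <- c(df$databases_score, df$experiments_score)
  if (any(is.na(sc)) || any(sc < 0) || any(sc > 1))
    stop("interaction scores must lie in [0, 1]")
  df
}
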