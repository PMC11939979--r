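#' Annotation sets over a protein universe
#'
#' A named collection of functional terms (GO terms, pathways, ...), each a
#' set of protein IDs, together with the universe against which enrichment
#' is judged. Every term's members must lie in the universe.
#'
#' @param sets named list, term ID -> character vector of protein IDs.
#' @param universe nonempty character vector of protein IDs.
#' @param descriptions optional named character vector of term
#'   descriptions; defaults to the term IDs.
#' @return An object of class `annotation_sets`.
#' @export
annotation_sets <- function(sets, universe, descriptions = NULL) {
  if (!length(universe)) stop("universe must be nonempty")
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  bad <- vapply(sets, function(s) any(!s %in% universe), logical(1))
  if (any(bad))
    stop("terms with members outside the universe: ",
         paste(names(sets)[bad], collapse = ", "))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  } else {
    descriptions <- descriptions[names(sets)]
    descriptions[is.na(descriptions)] <- ""
    names(descriptions) <- names(sets)
  }
  structure(list(sets = sets, descriptions = descriptions,
                 universe = universe),
            class = "annotation_sets")
}

#' @export
print.annotation_sets <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("annotation_sets: %d terms over a universe of %d proteins\n",
              length(x$sets), length(x$universe)))
  if (length(sz))
    cat(sprintf("  term sizes: min %d, median %g, max %d\n",
                min(sz), stats::median(sz), max(sz)))
  invisible(x)
}

#' Read and write GMT annotation files
#'
#' GMT is the tab-separated gene-set format: one term per line as
#' `term <TAB> description <TAB> member1 <TAB> member2 ...`. Reading goes
#' through [fgsea::gmtPathways()] (which keeps the member sets; term
#' descriptions are not preserved by that reader and default to the term
#' ID).
#'
#' @param path GMT file path.
#' @param universe universe for the resulting [annotation_sets()]; defaults
#'   to the union of all members.
#' @return `read_gmt` returns an `annotation_sets`; `write_gmt` returns the
#'   path invisibly.
#' @export
read_gmt <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  annotation_sets(sets, universe)
}

#' @rdname read_gmt
#' @param x an `annotation_sets`.
#' @export
write_gmt <- function(x, path) {
  lines <- vapply(names(x$sets), function(id)
    paste(c(id, x$descriptions[[id]], x$sets[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric functional enrichment
#'
#' Tests each annotation term for over-representation in a protein
#' selection with the one-sided (upper-tail) hypergeometric test:
#' `p = P(X >= overlap)` for `X` hypergeometric with the universe as
#' population, the term's members as successes and the selection as draws.
#' P-values are Benjamini-Hochberg adjusted across all tested terms; a term
#' is called enriched when its adjusted p-value is at or below
#' `fdr_threshold`.
#'
#' @param selection character vector of protein IDs; must be a subset of
#'   the annotation universe.
#' @param annotations an [annotation_sets()].
#' @param fdr_threshold BH-adjusted significance cutoff (default 0.01).
#' @return Data frame ordered by raw p-value: `term`, `description`,
#'   `overlap`, `term_size`, `selection_size`, `universe_size`, `p_value`,
#'   `p_adjusted`, `enriched`.
#' @examples
#' ann <- annotation_sets(list(T1 = c("a", "b", "c")), letters[1:10])
#' hypergeometric_enrichment(c("a", "b", "c", "d"), ann, fdr_threshold = 0.05)
#' @export
hypergeometric_enrichment <- function(selection, annotations,
                                      fdr_threshold = 0.01) {
  stopifnot(inherits(annotations, "annotation_sets"))
  selection <- unique(as.character(selection))
  uni <- annotations$universe
  offenders <- setdiff(selection, uni)
  if (length(offenders))
    stop("selection proteins outside the universe: ",
         paste(offenders, collapse = ", "))
  nu <- length(uni); k <- length(selection)
  res <- data.frame(term = names(annotations$sets),
                    description = unname(annotations$descriptions),
                    overlap = NA_integer_, term_size = NA_integer_,
                    selection_size = k, universe_size = nu,
                    p_value = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_along(annotations$sets)) {
    members <- annotations$sets[[i]]
    m <- length(members)
    x <- length(intersect(members, selection))
    res$overlap[i] <- x
    res$term_size[i] <- m
    res$p_value[i] <- stats::phyper(x - 1, m, nu - m, k, lower.tail = FALSE)
  }
  res$p_adjusted <- stats::p.adjust(res$p_value, "BH")
  res$enriched <- res$p_adjusted <= fdr_threshold
  res[order(res$p_value), , drop = FALSE]
}

#' Per-subject enrichment score matrix
#'
#' Applies [hypergeometric_enrichment()] to each subject's detected-protein
#' set (PSM value positive) and assembles a term-by-subject matrix of
#' enrichment scores, `-log10(raw p)`, the input of
#' [differential_enrichment()].
#'
#' @inheritParams group_mean_profiles
#' @param annotations an [annotation_sets()] whose universe contains the
#'   matrix's proteins.
#' @return Numeric matrix, terms x subjects, with attribute
#'   `score = "-log10(p)"`.
#' @export
subject_enrichment_matrix <- function(x, design, annotations) {
  check_design(x, design)
  v <- psm_values(x)
  scores <- vapply(colnames(v), function(s) {
    detected <- rownames(v)[v[, s] > 0]
    res <- hypergeometric_enrichment(detected, annotations,
                                     fdr_threshold = 1)
    -log10(pmax(res$p_value[match(names(annotations$sets), res$term)],
                .Machine$double.xmin))
  }, numeric(length(annotations$sets)))
  if (length(annotations$sets) == 1L)
    scores <- matrix(scores, nrow = 1)
  dimnames(scores) <- list(names(annotations$sets), colnames(v))
  attr(scores, "score") <- "-log10(p)"
  scores
}

#' Differentially enriched terms across groups
#'
#' One-way F selection on a term-by-subject enrichment score matrix, the
#' same kernel as [anova_f_selection()]: a term is differentially enriched
#' when `F >= f_threshold` and `p <= p_threshold` jointly hold. The result
#' depends on the score scale, which is recorded in the output.
#'
#' @param term_matrix numeric matrix, terms x subjects (e.g. from
#'   [subject_enrichment_matrix()]).
#' @param design a [group_design()] covering the matrix columns; every
#'   group needs at least 2 subjects.
#' @inheritParams anova_f_selection
#' @return Data frame `term`, `F_ratio`, `p_value`, `selected`, with a
#'   `score` attribute naming the score scale.
#' @export
differential_enrichment <- function(term_matrix, design, f_threshold = 3.5,
                                    p_threshold = 0.05) {
  missing <- setdiff(colnames(term_matrix), design$subject)
  if (length(missing))
    stop("subjects missing from design: ", paste(missing, collapse = ", "))
  group <- design$group[match(colnames(term_matrix), design$subject)]
  res <- row_f_stats(term_matrix, group)
  names(res)[names(res) == "protein_id"] <- "term"
  res$selected <- res$F_ratio >= f_threshold & res$p_value <= p_threshold
  attr(res, "score") <- attr(term_matrix, "score") %||% "user-supplied"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
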