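#' Synthetic-cohort configuration
#'
#' Parameters of the spectral-count cohort generator. Defaults emulate a
#' small three-group urine-proteomics study: groups of 5, 4 and 7 subjects
#' (healthy donors, low- and high-risk patients), about 2500 proteins, PSM
#' counts that are overdispersed around log-normal per-protein baselines,
#' sporadic detection dropout, and two kinds of planted signal -- proteins
#' exclusive to one group and proteins with a fold-change in one group.
#'
#' @param group_sizes named integer vector of group sizes, each at least 2
#'   (default `c(HD = 5, LRPCa = 4, HRPCa = 7)`).
#' @param n_proteins number of proteins (default 2490).
#' @param baseline_log_mean,baseline_log_sd log-scale mean and sd of the
#'   per-protein baseline abundance (defaults 3 and 1: median ~20 PSMs with
#'   a realistic dynamic range of roughly three orders of magnitude).
#' @param dispersion negative-binomial overdispersion of counts around the
#'   baseline (default 0.3; variance `mu + dispersion * mu^2`).
#' @param detection_prob probability a truly present protein is detected in
#'   a given subject (default 0.85); dropout zeroes cells independently.
#' @param n_exclusive_per_group planted group-exclusive proteins per group
#'   (default 20): zero counts outside their group.
#' @param n_foldchange_daps planted fold-change proteins (default 40):
#'   baseline multiplied (or divided) by `fold_change` in one group.
#' @param fold_change planted fold change, > 1 (default 4).
#' @param seed integer root seed for all draws.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(group_sizes = c(HD = 5, LRPCa = 4, HRPCa = 7),
                       n_proteins = 2490,
                       baseline_log_mean = 3, baseline_log_sd = 1,
                       dispersion = 0.3, detection_prob = 0.85,
                       n_exclusive_per_group = 20, n_foldchange_daps = 40,
                       fold_change = 4, seed = 1) {
  if (is.null(names(group_sizes)))
    names(group_sizes) <- paste0("G", seq_along(group_sizes))
  if (length(group_sizes) < 2 || any(group_sizes < 2))
    stop("need at least 2 groups of at least 2 subjects")
  if (detection_prob < 0 || detection_prob > 1)
    stop("detection_prob must lie in [0, 1]")
  if (fold_change <= 1) stop("fold_change must exceed 1")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (baseline_log_sd < 0) stop("baseline_log_sd must be non-negative")
  n_planted <- n_exclusive_per_group * length(group_sizes) + n_foldchange_daps
  if (n_planted > n_proteins)
    stop(sprintf("planted proteins (%d) exceed n_proteins (%d)",
                 n_planted, n_proteins))
  structure(list(group_sizes = group_sizes, n_proteins = n_proteins,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 dispersion = dispersion, detection_prob = detection_prob,
                 n_exclusive_per_group = n_exclusive_per_group,
                 n_foldchange_daps = n_foldchange_daps,
                 fold_change = fold_change, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a spectral-count cohort with planted ground truth
#'
#' Draws a protein-by-subject PSM count matrix under the configured model:
#' per-protein baselines are log-normal; detected counts are zero-truncated
#' negative binomial around the baseline (a detected protein contributes at
#' least one spectrum, so zeros carry presence/absence information only);
#' detection dropout independently zeroes cells with probability
#' `1 - detection_prob`. Planted exclusive proteins have structurally zero
#' counts outside their group; planted fold-change proteins have their
#' baseline multiplied (direction "up") or divided (direction "down") by
#' `fold_change` in one randomly chosen group. All draws descend from the
#' single root seed, so identical configurations reproduce identical
#' cohorts.
#'
#' @param config a [sim_config()].
#' @return List with `matrix` (raw [psm_matrix()]), `design`
#'   ([group_design()]) and `truth`: `exclusive_proteins` (group ->
#'   protein IDs) and `foldchange_proteins` (data frame `protein_id`,
#'   `group`, `direction`).
#' @examples
#' sim <- simulate_cohort(sim_config(n_proteins = 100, seed = 3))
#' sim$matrix
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sizes <- config$group_sizes
  labs <- names(sizes)
  ng <- length(sizes)
  n <- config$n_proteins
  nsub <- sum(sizes)
  proteins <- sprintf("P%04d", seq_len(n))
  subjects <- unlist(lapply(labs, function(g)
    paste0(g, "_", seq_len(sizes[[g]]))))
  design <- group_design(subjects, rep(labs, times = sizes))

  ne <- config$n_exclusive_per_group
  nf <- config$n_foldchange_daps
  planted <- sample(proteins, ne * ng + nf)
  exclusive <- if (ne > 0) {
    split(planted[seq_len(ne * ng)], rep(labs, each = ne))[labs]
  } else stats::setNames(rep(list(character(0)), ng), labs)
  fc_ids <- if (nf > 0) planted[ne * ng + seq_len(nf)] else character(0)
  fc_group <- if (nf > 0) sample(labs, nf, replace = TRUE) else character(0)
  fc_dir <- if (nf > 0) sample(c("up", "down"), nf, replace = TRUE)
            else character(0)

  baseline <- stats::rlnorm(n, config$baseline_log_mean,
                            config$baseline_log_sd)
  mu <- matrix(baseline, n, nsub, dimnames = list(proteins, subjects))
  grp_of <- design$group[match(subjects, design$subject)]
  for (i in seq_along(fc_ids)) {
    cols <- grp_of == fc_group[i]
    mu[fc_ids[i], cols] <- mu[fc_ids[i], cols] *
      if (fc_dir[i] == "up") config$fold_change else 1 / config$fold_change
  }
  # zero-truncated counts: 1 + NB with mean mu - 1, so the cell mean is mu
  counts <- matrix(1 + stats::rnbinom(n * nsub, mu = pmax(mu - 1, 0),
                                      size = 1 / config$dispersion),
                   n, nsub, dimnames = dimnames(mu))
  for (g in labs) {
    ids <- exclusive[[g]]
    if (length(ids)) counts[ids, grp_of != g] <- 0
  }
  if (config$detection_prob < 1) {
    drop <- matrix(stats::runif(n * nsub) > config$detection_prob, n, nsub)
    counts[drop] <- 0
  }
  list(matrix = psm_matrix(counts),
       design = design,
       truth = list(
         exclusive_proteins = exclusive,
         foldchange_proteins = data.frame(protein_id = fc_ids,
                                          group = fc_group,
                                          direction = fc_dir,
                                          stringsAsFactors = FALSE)))
}

#' Simulate a scale-free scored interactome
#'
#' Grows an undirected simple scale-free graph by preferential attachment
#' over a subset of the cohort's protein IDs and scores each edge with
#' independent uniform "databases" and "experiments" confidences -- the
#' statistical shape of a STRING-style interaction table. The highest-degree
#' nodes are recorded as the planted hub-like truth.
#'
#' @param protein_ids character pool of available protein IDs.
#' @param n_nodes number of nodes (must not exceed the pool size).
#' @param attach_edges edges attached per new node (default 2; must be
#'   below `n_nodes`).
#' @param seed integer seed.
#' @param n_hub_truth how many top-degree nodes to record (default 10).
#' @return List with `interactions` (data frame `protein1`, `protein2`,
#'   `databases_score`, `experiments_score`), `graph` (the \pkg{igraph}
#'   graph with protein-ID names) and `truth$hub_like_nodes`.
#' @export
simulate_interactome <- function(protein_ids, n_nodes, attach_edges = 2,
                                 seed = 1, n_hub_truth = 10) {
  if (n_nodes > length(protein_ids))
    stop("n_nodes exceeds the available protein IDs")
  if (attach_edges < 1 || attach_edges >= n_nodes)
    stop("need n_nodes > attach_edges >= 1")
  set.seed(seed)
  g <- igraph::sample_pa(n_nodes, m = attach_edges, directed = FALSE,
                         algorithm = "psumtree")
  igraph::V(g)$name <- sample(protein_ids, n_nodes)
  e <- igraph::as_data_frame(g, what = "edges")
  inter <- data.frame(protein1 = e$from, protein2 = e$to,
                      databases_score = stats::runif(nrow(e)),
                      experiments_score = stats::runif(nrow(e)),
                      stringsAsFactors = FALSE)
  deg <- sort(igraph::degree(g), decreasing = TRUE)
  list(interactions = inter, graph = g,
       truth = list(hub_like_nodes = names(deg)[seq_len(min(n_hub_truth,
                                                            n_nodes))]))
}

#' Simulate annotation sets with planted enriched terms
#'
#' Builds a GMT-style collection of functional terms over a protein
#' universe. Background terms are uniform random subsets; planted terms
#' draw a fraction `planting_strength` of their members from a given
#' protein pool (e.g. the planted DAPs), so their enrichment in that pool
#' is recoverable by the hypergeometric test.
#'
#' @param universe character vector of protein IDs (nonempty).
#' @param n_terms number of terms (0 gives an empty collection).
#' @param term_size_range integer range of term sizes (default `c(5, 25)`),
#'   bounded by the universe size.
#' @param planted_terms how many terms to plant (default 0).
#' @param planted_pool protein IDs the planted terms are biased towards;
#'   required when `planted_terms > 0`.
#' @param planting_strength fraction of a planted term's members drawn from
#'   the pool (default 0.8).
#' @param seed integer seed.
#' @return List with `annotations` (an [annotation_sets()]) and
#'   `truth$enriched_terms` (planted term IDs).
#' @export
simulate_annotations <- function(universe, n_terms,
                                 term_size_range = c(5, 25),
                                 planted_terms = 0, planted_pool = NULL,
                                 planting_strength = 0.8, seed = 1) {
  if (!length(universe)) stop("empty protein universe")
  if (max(term_size_range) > length(universe))
    stop("term sizes exceed the universe size")
  if (planted_terms > n_terms) stop("planted_terms exceeds n_terms")
  if (planted_terms > 0 && is.null(planted_pool))
    stop("planted_terms > 0 needs a planted_pool")
  set.seed(seed)
  sets <- list(); desc <- character(0)
  if (n_terms > 0) {
    ids <- sprintf("T%03d", seq_len(n_terms))
    sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                    n_terms, replace = TRUE)
    sets <- lapply(seq_len(n_terms), function(i) {
      if (i <= planted_terms) {
        k_pool <- min(round(planting_strength * sizes[i]),
                      length(planted_pool))
        members <- sample(planted_pool, k_pool)
        rest <- setdiff(universe, members)
        c(members, sample(rest, sizes[i] - k_pool))
      } else sample(universe, sizes[i])
    })
    names(sets) <- ids
    desc <- stats::setNames(ifelse(seq_len(n_terms) <= planted_terms,
                                   "planted enriched term",
                                   "background term"), ids)
  }
  list(annotations = annotation_sets(sets, universe, descriptions = desc),
       truth = list(enriched_terms = if (planted_terms > 0)
         names(sets)[seq_len(planted_terms)] else character(0)))
}
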