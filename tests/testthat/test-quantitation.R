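test_that("total-signal normalization equalizes column totals and keeps zeros", {
  m <- make_psm(cbind(c(10, 90, 0), c(30, 200, 70)))
  norm <- normalize_total_signal(m)
  # totals 100 and 300, target = mean = 200: entry 10 scales to 20
  expect_equal(unclass(norm)[1, 1], 20)
  expect_equal(unname(colSums(norm)), c(200, 200))
  expect_true(is_normalized(norm))
  expect_identical(unclass(norm)[3, 1], 0)

  same <- make_psm(cbind(c(5, 5), c(4, 6)))     # equal totals: unchanged
  expect_equal(unclass(normalize_total_signal(same)), unclass(same),
               ignore_attr = TRUE)

  bad <- make_psm(cbind(c(1, 2), c(0, 0)), subjects = c("ok", "empty"))
  expect_error(normalize_total_signal(bad), "empty")
})

test_that("normalization conserves equal totals on random matrices", {
  set.seed(1)
  for (i in 1:5) {
    m <- make_psm(matrix(rpois(20 * 6, 8), 20, 6))
    tot <- colSums(normalize_total_signal(m))
    expect_lt(max(abs(tot / mean(tot) - 1)), 1e-9)
  }
})

test_that("group mean profiles match a per-protein loop on the 5/4/7 cohort", {
  sim <- simulate_cohort(sim_config(n_proteins = 60,
                                    n_exclusive_per_group = 5,
                                    n_foldchange_daps = 10, seed = 8))
  prof <- group_mean_profiles(sim$matrix, sim$design)
  gs <- split(sim$design$subject, sim$design$group)
  for (g in names(gs)) {
    for (p in rownames(sim$matrix)) {
      expect_equal(prof[p, g], mean(unclass(sim$matrix)[p, gs[[g]]]))
    }
  }
  d2 <- sim$design; levels(d2$group) <- c(levels(d2$group), "ghost")
  expect_error(group_network(sim$matrix, d2, "nope",
                             data.frame(protein1 = "a", protein2 = "b",
                                        databases_score = 1,
                                        experiments_score = 1)), "unknown")
})

test_that("Spearman correlation of profiles follows the rank formula", {
  x <- c(1, 2, 3, 4, 5); y <- c(1, 3, 2, 5, 4)
  prof <- cbind(A = x, B = y, C = rev(x))
  r <- spearman_group_correlation(prof)
  expect_equal(r["A", "A"], 1)
  expect_equal(r["A", "B"], 0.8)        # 1 - 6*4 / (5*24)
  expect_equal(r["A", "C"], -1)
  expect_identical(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 3))

  const <- cbind(A = x, B = rep(2, 5))
  rc <- spearman_group_correlation(const)
  expect_true(is.na(rc["A", "B"]))      # undefined, not forced to 0
  expect_equal(unname(diag(rc)), c(1, 1))
})

test_that("Venn partition counts match exhaustive membership enumeration", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = c("c", "e"))
  got <- overlap_partition(sets)
  expect_identical(sum(got), length(unique(unlist(sets))))
  # brute force over elements
  univ <- unique(unlist(sets))
  for (el in univ) {
    sig <- paste(names(sets)[vapply(sets, function(s) el %in% s, NA)],
                 collapse = "&")
    expect_true(got[sig] >= 1)
  }
  expect_identical(got[["A"]], 1L)          # only "a"
  expect_identical(got[["A&B"]], 1L)        # only "b"
  expect_identical(got[["A&B&C"]], 1L)      # only "c"
  expect_identical(got[["C"]], 1L)          # only "e"
  expect_identical(got[["A&C"]], 0L)

  same <- overlap_partition(list(A = letters[1:4], B = letters[1:4],
                                 C = letters[1:4]))
  expect_identical(same[["A&B&C"]], 4L)
  expect_identical(sum(same), 4L)

  disj <- overlap_partition(list(A = "a", B = "b", C = "c"))
  expect_identical(unname(disj[c("A", "B", "C")]), c(1L, 1L, 1L))
  expect_identical(sum(disj), 3L)
})

test_that("identification frequency rounds half away from zero to integer percent", {
  m <- make_psm(rbind(c(rep(1, 4), rep(0, 3)),   # 4 of 7 -> 57
                      c(rep(1, 6), 0),           # 6 of 7 -> 86
                      rep(1, 7),                 # 7 of 7 -> 100
                      rep(0, 7)))                # 0 of 7 -> 0
  m2 <- make_psm(cbind(unclass(m), unclass(m)[, 1:4]),
                 subjects = sprintf("s%02d", 1:11))
  d2 <- group_design(colnames(m2), c(rep("HRPCa", 7), rep("LRPCa", 4)))
  iftab <- identification_frequency(m2, d2)
  expect_identical(unname(iftab[, "HRPCa"]), c(57L, 86L, 100L, 0L))
  # 1 of 4 -> 25
  m3 <- make_psm(rbind(c(1, 0, 0, 0, 1, 1, 1, 1, 1)))
  d3 <- group_design(colnames(m3), c(rep("LRPCa", 4), rep("HD", 5)))
  if3 <- identification_frequency(m3, d3)
  expect_identical(if3[1, "LRPCa"], 25L)
  expect_identical(if3[1, "HD"], 100L)
})

test_that("the IF rule selects strictly >50% somewhere and strictly <50% elsewhere", {
  iftab <- rbind(P1 = c(60, 40, 0),     # selected
                 P2 = c(100, 100, 100), # no low group
                 P3 = c(50, 40, 0),     # 50 is not > 50
                 P4 = c(51, 49, 100),   # selected
                 P5 = c(60, 50, 55))    # 50 is not < 50
  colnames(iftab) <- c("A", "B", "C")
  expect_setequal(select_daps_by_if(iftab), c("P1", "P4"))
})

test_that("one-way F selection matches anova(lm) and applies the joint rule", {
  m <- make_psm(rbind(c(10, 10, 11, 2, 2, 3, 2, 3, 2)), normalized = TRUE)
  d <- group_design(colnames(m), rep(c("A", "B", "C"), each = 3))
  res <- anova_f_selection(m, d)
  fit <- anova(lm(unclass(m)[1, ] ~ d$group))
  expect_equal(res$F_ratio, fit$`F value`[1])
  expect_equal(res$p_value, fit$`Pr(>F)`[1])
  expect_true(res$selected)

  # random matrix: per-row agreement with the lm oracle
  set.seed(21)
  mm <- make_psm(matrix(rpois(15 * 9, 10), 15, 9), normalized = TRUE)
  dd <- group_design(colnames(mm), rep(c("A", "B", "C"), each = 3))
  rr <- anova_f_selection(mm, dd)
  for (i in 1:15) {
    fi <- anova(lm(unclass(mm)[i, ] ~ dd$group))
    expect_equal(rr$F_ratio[i], fi$`F value`[1], tolerance = 1e-10)
    expect_equal(rr$p_value[i], fi$`Pr(>F)`[1], tolerance = 1e-10)
  }
  # joint condition: selected is exactly F >= 3.5 AND p <= 0.05
  expect_identical(rr$selected, rr$F_ratio >= 3.5 & rr$p_value <= 0.05)

  flat <- make_psm(rbind(rep(4, 9)), normalized = TRUE)
  rf <- anova_f_selection(flat, dd)
  expect_identical(rf$F_ratio, 0)      # zero total variance
  expect_false(rf$selected)
})

test_that("DAve index follows its formula, boundary convention and symmetries", {
  expect_identical(dave_index(5, 0), 2)
  expect_identical(dave_index(0, 5), -2)
  expect_equal(dave_index(3, 1), 1)
  expect_equal(dave_index(7, 7), 0)
  expect_true(is.na(dave_index(0, 0)))
  expect_error(dave_index(-1, 2), "non-negative")

  set.seed(9)
  a <- runif(200, 0, 50); b <- runif(200, 0, 50)
  expect_equal(dave_index(a, b), -dave_index(b, a))
  expect_true(all(abs(dave_index(a, b)) <= 2))
  expect_equal(dave_index(a, b), dave_index(3.7 * a, 3.7 * b))
})

test_that("the DAve magnitude filter is two-sided and inclusive", {
  expect_true(dave_pass(0.5))
  expect_true(dave_pass(0.4))
  expect_false(dave_pass(0.39))
  expect_true(dave_pass(-2))
  expect_true(dave_pass(-0.4))
  expect_false(dave_pass(NA))
})

test_that("exact presence test reproduces closed-form tail probabilities", {
  # 5/5 present in A vs 0/11 in B within a 16-subject cohort
  m <- make_psm(rbind(c(rep(3, 5), rep(0, 11)), rep(1, 16)))
  d <- group_design(colnames(m), c(rep("HD", 5), rep("PCa", 11)))
  res <- presence_test(m, d, "HD", "PCa")
  expect_equal(res$p_value[1], 2 / choose(16, 5))
  expect_equal(res$p_value[2], 1)      # identical presence patterns
  expect_identical(res$detected_a[1], 5)
  expect_identical(res$percent_b[1], 0L)

  m2 <- make_psm(rbind(c(rep(2, 4), rep(0, 7))))
  d2 <- group_design(colnames(m2), c(rep("LRPCa", 4), rep("HRPCa", 7)))
  expect_equal(presence_test(m2, d2, "LRPCa", "HRPCa")$p_value,
               2 / choose(11, 4))

  expect_error(presence_test(m, d, "HD", "nope"), "unknown")
  d3 <- group_design(colnames(m), c("X", rep("Y", 15)))
  expect_error(presence_test(m, d3, "X", "Y"), "at least 2")
})

test_that("exact presence test equals the exhaustive permutation oracle for N <= 12", {
  for (na in 2:6) {
    nb_max <- 12 - na
    for (nb in 2:nb_max) {
      for (ca in 0:na) {
        for (cb in 0:nb) {
          got <- spectronet:::presence_p_exact(ca, cb, na, nb)
          expect_equal(got, oracle_presence_p(ca, cb, na, nb),
                       tolerance = 1e-12,
                       info = sprintf("na=%d nb=%d ca=%d cb=%d",
                                      na, nb, ca, cb))
        }
      }
    }
  }
})

test_that("clustering QC merges duplicate subjects first and shares sum to 1", {
  set.seed(3)
  v <- matrix(rnorm(10 * 5, 10), 10, 5)
  v <- cbind(v, v[, 5])                         # duplicate subject
  m <- make_psm(pmax(v, 0), normalized = TRUE)
  d <- group_design(colnames(m), rep(c("A", "B"), each = 3))
  qc <- cluster_qc(m, d)
  first <- sort(qc$hclust$merge[1, ])
  expect_identical(first, c(-6L, -5L))          # the duplicated pair
  expect_equal(qc$hclust$height[1], 0)
  expect_equal(sum(qc$variance_share), 1)

  # well-separated planted groups: the top split equals the group partition
  sep <- make_psm(cbind(matrix(rpois(40 * 4, 5), 40, 4),
                        matrix(rpois(40 * 4, 60), 40, 4)), normalized = TRUE)
  dsep <- group_design(colnames(sep), rep(c("lo", "hi"), each = 4))
  qs <- cluster_qc(sep, dsep)
  cut <- stats::cutree(qs$hclust, k = 2)
  expect_identical(length(unique(cut[1:4])), 1L)
  expect_identical(length(unique(cut[5:8])), 1L)
  expect_false(cut[1] == cut[5])

  one <- make_psm(rbind(rep(1, 5)))
  done <- group_design(colnames(one), c("A", "A", "A", "B", "B"))
  expect_error(cluster_qc(one, done), "2 proteins")
})

test_that("dap_fit unions the two selections with correct provenance", {
  sim <- simulate_cohort(sim_config(n_proteins = 250, detection_prob = 1,
                                    seed = 13))
  fit <- dap_fit(sim$matrix, sim$design)
  planted_excl <- unlist(sim$truth$exclusive_proteins)
  tab <- fit$table
  expect_true(all(planted_excl %in% tab$protein_id))
  expect_true(all(tab$source[tab$protein_id %in% planted_excl]
                  %in% c("IF", "both")))
  # table is the union of the two selections and sources are consistent
  if_set <- select_daps_by_if(fit$if_table)
  expect_true(all(tab$protein_id[tab$source %in% c("IF", "both")] %in% if_set))
  expect_length(setdiff(if_set, tab$protein_id), 0)
  expect_true(all(c("F_ratio", "p_value", "DAve_HD_vs_LRPCa",
                    "DAve_HD_vs_HRPCa", "DAve_LRPCa_vs_HRPCa",
                    "IF_HD", "mean_HD") %in% colnames(tab)))
  expect_true(all(abs(as.matrix(tab[, grep("^DAve_", colnames(tab))])) <= 2,
                  na.rm = TRUE))
  expect_s3_class(fit, "dap_fit")
  expect_output(print(fit), "DAPs selected")
})

test_that("QC and null-distribution plots render without error", {
  sim <- simulate_cohort(sim_config(n_proteins = 120, seed = 23))
  fit <- dap_fit(sim$matrix, sim$design)
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  qc <- plot(fit)
  expect_named(qc, c("hclust", "pca", "variance_share"))
  g <- igraph::sample_gnm(20, 30)
  igraph::V(g)$name <- paste0("n", 1:20)
  ens <- random_ensemble(g, n = 15, seed = 2)
  expect_invisible(plot(ens))
  expect_output(print(summary(fit)), "Spearman")
})
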