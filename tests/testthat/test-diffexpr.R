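test_that("Mann-Whitney U handles the symmetric tied case and tiny exact cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$U, 4.5)
  expect_equal(r$p, 1, tolerance = 1e-12)

  r2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$U, 0)
  expect_equal(r2$p, 0.1, tolerance = 1e-12)  # 2 of the 20 assignments as extreme
  expect_identical(r2$method, "exact")

  expect_error(mann_whitney_u(1, c(1, 2)), "at least 2")
})

test_that("exact Mann-Whitney p equals full permutation enumeration", {
  set.seed(101)
  for (n1 in 2:5) for (n2 in 2:5) {
    for (rep in 1:3) {
      a <- sample(100, n1); b <- sample(100, n1 + n2)[seq_len(n2)] + 0.5
      r <- mann_whitney_u(a, b)
      expect_identical(r$method, "exact")
      expect_equal(r$p, enum_mw_p(a, b), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("the tie-corrected normal approximation tracks the reference test", {
  set.seed(5)
  for (rep in 1:10) {
    a <- sample(5, 8, replace = TRUE)  # forced ties
    b <- sample(5, 9, replace = TRUE)
    r <- mann_whitney_u(a, b)
    expect_identical(r$method, "normal_approx_tie_corrected")
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = FALSE))
    expect_equal(r$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("two-way ANOVA matches the aov decomposition on balanced data", {
  set.seed(21)
  f1 <- factor(rep(c("L", "P"), each = 6))
  f2 <- factor(rep(rep(c("c", "t"), each = 3), 2))
  for (rep in 1:5) {
    y <- rnorm(12, mean = 2 * (f1 == "L") + 0.7 * (f2 == "t"))
    mine <- two_way_anova(y, f1, f2, replicated = TRUE)
    ref <- summary(stats::aov(y ~ f1 * f2))[[1]]
    expect_equal(mine$sumsq, ref[1:3, "Sum Sq"], tolerance = 1e-9)
    expect_equal(mine$F, ref[1:3, "F value"], tolerance = 1e-9)
    expect_equal(mine$p, ref[1:3, "Pr(>F)"], tolerance = 1e-9)
  }
  # vectorized path agrees with the per-gene path
  Y <- matrix(rnorm(5 * 12), 5, 12, dimnames = list(paste0("g", 1:5), NULL))
  vec <- two_way_anova(Y, f1, f2, replicated = TRUE)
  for (i in 1:5) {
    single <- two_way_anova(Y[i, ], f1, f2, replicated = TRUE)
    expect_equal(unname(vec$f1$p[i]), single$p[1], tolerance = 1e-10)
    expect_equal(unname(vec[["f1:f2"]]$F[i]), single$F[3], tolerance = 1e-10)
  }
})

test_that("noiseless planted effects give p ~ 0 for the effect, p = 1 for none", {
  f1 <- factor(rep(c("L", "P"), each = 4))
  f2 <- factor(rep(c("c", "t"), 4))
  y <- ifelse(f1 == "L", 1, 0)  # pure strain effect, zero noise
  r <- two_way_anova(y, f1, f2, replicated = TRUE)
  expect_equal(r$p[r$term == "f1"], 0)
  expect_equal(r$p[r$term == "f2"], 1)
})

test_that("unreplicated layouts require the additive model", {
  f1 <- factor(c("L", "L", "P", "P"))
  f2 <- factor(c("c", "t", "c", "t"))
  y <- c(1, 2, 3, 5)
  expect_error(two_way_anova(y, f1, f2, replicated = TRUE), "replication")
  r <- two_way_anova(y, f1, f2, replicated = FALSE)
  ref <- summary(stats::aov(y ~ f1 + f2))[[1]]
  expect_equal(r$F, ref[1:2, "F value"], tolerance = 1e-9)
})

test_that("ANOVA p-values are uniform under a permuted-label null", {
  set.seed(99)
  f1 <- factor(rep(c("L", "P"), each = 6))
  f2 <- factor(rep(rep(c("c", "t"), each = 3), 2))
  Y <- matrix(rnorm(2000 * 12), 2000, 12)
  p <- two_way_anova(Y, f1, f2, replicated = TRUE)$f1$p
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("fold change is the antilogged group-mean ratio", {
  design <- make_design(reps = 2L)
  vals <- matrix(3, 3, nrow(design),
                 dimnames = list(paste0("g", 1:3), design$sample_id))
  g1 <- design$sample_id[design$strain == "S1"]
  g2 <- design$sample_id[design$strain == "S2"]
  vals[2, g1] <- 4  # log2 means 4 vs 3 -> ratio 2
  vals[3, g2] <- 5  # down in group1: ratio 0.25, fc 4, direction -1
  m <- make_expr(vals, design)
  fc <- fold_change(m, g1, g2)
  expect_equal(fc$ratio, c(1, 2, 0.25))
  expect_equal(fc$fc, c(1, 2, 4))
  expect_equal(fc$direction, c(1, 1, -1))
  expect_false(fc$fc[1] >= 1.5)
  # random-matrix oracle
  set.seed(3)
  vals2 <- matrix(rnorm(5 * nrow(design)), 5, nrow(design),
                  dimnames = list(paste0("r", 1:5), design$sample_id))
  m2 <- make_expr(vals2, design)
  fc2 <- fold_change(m2, g1, g2)
  brute <- 2^rowMeans(vals2[, g1]) / 2^rowMeans(vals2[, g2])
  expect_equal(fc2$ratio, unname(brute), tolerance = 1e-12)
  expect_error(fold_change(m2, c(g1, "nope"), g2), "nope")
})

test_that("BH adjustment matches the direct step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(13)
  for (rep in 1:10) {
    p <- runif(sample(2:50, 1))
    expect_equal(bh_adjust(p), naive_bh(p), tolerance = 1e-12)
    # rejections at level q match the classic step-up rule
    q <- 0.2
    srt <- sort(p)
    k <- which(srt <= seq_along(p) / length(p) * q)
    n_rej_stepup <- if (length(k)) sum(p <= srt[max(k)]) else 0L
    expect_identical(sum(bh_adjust(p) <= q), as.integer(n_rej_stepup))
  }
  expect_error(bh_adjust(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("three-list combination computes all Venn regions under both rules", {
  r <- combine_lists(c("1", "2"), c("2", "3"), c("3", "4"),
                     rule = "shared_by_2_of_3")
  expect_setequal(r$combined_set, c("2", "3"))
  expect_equal(unname(r$region_counts),
               c(1, 0, 1, 1, 0, 1, 0))  # a,b,c only; ab, ac, bc; abc
  expect_equal(sum(r$region_counts), 4)
  u <- combine_lists(c("1", "2"), c("2", "3"), c("3", "4"), rule = "union_all")
  expect_setequal(u$combined_set, c("1", "2", "3", "4"))
  same <- combine_lists(c("a", "b"), c("a", "b"), c("a", "b"),
                        rule = "shared_by_2_of_3")
  expect_setequal(same$combined_set, c("a", "b"))
  disj <- combine_lists("a", "b", "c", rule = "shared_by_2_of_3")
  expect_length(disj$combined_set, 0)
})

test_that("DE selection recovers planted effects and respects thresholds", {
  cfg <- sim_config(n_genes = 400, seed = 303)
  ds <- simulate_dataset(cfg)
  norm <- percentile_shift(ds$expr)$matrix
  sel <- suppressMessages(select_de_genes(norm))
  truth <- ds$truth
  combined <- combine_lists(sel$lists$list1, sel$lists$list2,
                            sel$lists$list3)$combined_set
  strain_genes <- truth$strain_de$gene
  # ANOVA list carries the strain-planted genes at default replication
  expect_gt(mean(strain_genes %in% sel$lists$list3), 0.8)
  expect_gt(mean(strain_genes %in% combined), 0.8)
  # with an infinite fold-change threshold the fc-based lists are empty
  sel_inf <- suppressMessages(select_de_genes(
    norm,
    criteria1 = selection_criteria(fc_threshold = Inf, test = "mann_whitney"),
    criteria2 = selection_criteria(fc_threshold = Inf)))
  expect_length(sel_inf$lists$list1, 0)
  expect_length(sel_inf$lists$list2, 0)
  # relaxing thresholds never shrinks any list
  sel_strict <- suppressMessages(select_de_genes(
    norm,
    criteria1 = selection_criteria(fc_threshold = 2, p_threshold = 0.01,
                                   test = "mann_whitney"),
    criteria2 = selection_criteria(fc_threshold = 2),
    criteria3 = selection_criteria(p_threshold = 0.01, test = "anova")))
  sel_loose <- suppressMessages(select_de_genes(
    norm,
    criteria1 = selection_criteria(fc_threshold = 1.2, p_threshold = 0.5,
                                   test = "mann_whitney"),
    criteria2 = selection_criteria(fc_threshold = 1.2),
    criteria3 = selection_criteria(p_threshold = 0.5, test = "anova")))
  for (nm in names(sel_strict$lists))
    expect_true(all(sel_strict$lists[[nm]] %in% sel_loose$lists[[nm]]))
})

test_that("rank tests at 3v3 cannot clear p<0.05: list 1 needs lists 2/3", {
  # the exact two-sided Mann-Whitney floor at 3 vs 3 is 2/C(6,3) = 0.1, so a
  # BH-thresholded list at 0.05 is structurally empty at this replication
  expect_equal(mann_whitney_u(c(1, 2, 3), c(9, 10, 11))$p, 0.1)
  cfg <- sim_config(n_genes = 200, seed = 77)
  norm <- percentile_shift(simulate_dataset(cfg)$expr)$matrix
  sel <- suppressMessages(select_de_genes(norm))
  expect_length(sel$lists$list1, 0)
})
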