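test_that("the generator is deterministic under a seed and sensitive to it", {
  cfg7 <- sim_config(n_genes = 150, seed = 7)
  a <- simulate_dataset(cfg7)
  b <- simulate_dataset(cfg7)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$promoters, b$promoters)
  expect_identical(a$targets, b$targets)
  expect_identical(a$truth$mirna, b$truth$mirna)
  c_ <- simulate_dataset(sim_config(n_genes = 150, seed = 8))
  expect_false(identical(a$expr$values, c_$expr$values))
})

test_that("planted set sizes follow the configured fractions exactly", {
  ds <- simulate_dataset(sim_config(n_genes = 1000, frac_strain_de = 0.05,
                                    seed = 2))
  expect_equal(nrow(ds$truth$strain_de), 50L)
  expect_error(sim_config(frac_strain_de = 0.7, frac_lps_de = 0.5),
               "exceeds 1")
})

test_that("null effects with zero noise give constant per-gene profiles", {
  ds <- simulate_dataset(sim_config(n_genes = 60, frac_strain_de = 0,
                                    frac_lps_de = 0, noise_sd_log2 = 0,
                                    seed = 5))
  expect_equal(nrow(ds$truth$strain_de), 0L)
  rng <- apply(ds$expr$values, 1L, function(v) diff(range(v)))
  expect_true(all(rng < 1e-9))
})

test_that("planted strain effects are realized at the configured size", {
  # empirical log2 mean difference within 3*sd/sqrt(arrays per strain) for
  # >= 95% of planted genes across seeds
  n_ok <- 0L; n_tot <- 0L
  for (s in 1:20) {
    cfg <- sim_config(n_genes = 200, seed = s)
    ds <- simulate_dataset(cfg)
    lg <- log2(ds$expr$values)
    s1 <- ds$expr$design$strain == cfg$strains[1]
    diffs <- rowMeans(lg[, s1]) - rowMeans(lg[, !s1])
    tr <- ds$truth$strain_de
    tol <- 3 * cfg$noise_sd_log2 / sqrt(sum(s1) / 2)
    err <- abs(diffs[tr$gene] - tr$log2_effect)
    n_ok <- n_ok + sum(err <= tol); n_tot <- n_tot + nrow(tr)
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("detection flags mark the configured low-intensity band", {
  cfg <- sim_config(n_genes = 500, flag_absent_quantile = 0.1, seed = 9)
  ds <- simulate_dataset(cfg)
  fr_a <- colMeans(ds$expr$flags == "A")
  fr_m <- colMeans(ds$expr$flags == "M")
  expect_true(all(abs(fr_a - 0.08) < 0.01))   # below q - 2%
  expect_true(all(abs(fr_m - 0.04) < 0.01))   # the +/- 2% band
  ds0 <- simulate_dataset(sim_config(n_genes = 100,
                                     flag_absent_quantile = 0, seed = 9))
  expect_true(all(ds0$expr$flags == "P"))
})

test_that("motif planting modifies exactly ceiling(rate * n) promoters", {
  set.seed(1)
  genes <- sprintf("g%02d", 1:10)
  promoters <- stats::setNames(
    rep(paste(rep("T", 100), collapse = ""), 10), genes)
  cons <- consensus_pwm("AAACCC")
  same <- plant_motifs(promoters, cons, genes, rate = 0, seed = 3)
  expect_identical(same$promoters, promoters)
  expect_equal(nrow(same$insertions), 0L)

  half <- plant_motifs(promoters, cons, genes, rate = 0.5, seed = 3)
  changed <- names(promoters)[half$promoters != promoters]
  expect_length(changed, 5L)
  expect_setequal(changed, half$insertions$gene)
  # scan at threshold 1.0 recovers every insertion at its recorded position
  for (i in seq_len(nrow(half$insertions))) {
    g <- half$insertions$gene[i]
    h <- scan_promoter(half$promoters[[g]], cons, threshold_frac = 1)
    expect_true(half$insertions$position[i] %in% h$position)
    expect_true(half$insertions$strand[i] %in%
                  h$strand[h$position == half$insertions$position[i]])
  }
  all_in <- plant_motifs(promoters, cons, genes, rate = 1, seed = 4)
  expect_length(unique(all_in$insertions$gene), 10L)
  for (i in seq_len(10)) {
    ins <- all_in$insertions[i, ]
    written <- substr(all_in$promoters[[ins$gene]], ins$position + 1,
                      ins$position + 6)
    expect_identical(written,
                     if (ins$strand == "+") ins$motif_seq
                     else revcomp_str(ins$motif_seq))
  }
  expect_error(plant_motifs(stats::setNames("TTT", "g1"), cons, "g1",
                            rate = 1, seed = 1), "longer than promoter")
})

test_that("target tables realize coverage and decoy structure", {
  tfs <- paste0("tf", 1:5)
  genes <- c(tfs, sprintf("g%03d", 1:95))
  mirnas <- paste0("m", 1:10)
  # coverage 0.8 over 5 TFs -> 4 truth-set targets per table, sum 8
  tabs <- make_target_tables(tfs, "m1", mirnas, genes,
                             coverage = 0.8, decoy_rate = 0.05, seed = 11)
  res <- aggregate_targets(tfs, tabs)
  row1 <- res[res$mirna == "m1", ]
  expect_equal(unname(unlist(row1[, c("TargetScan", "miRanda")])), c(4L, 4L))
  expect_equal(row1$sum, 8L)
  # coverage 1, no decoys: the planted miRNA is the only one with targets
  pure <- make_target_tables(tfs, "m1", mirnas, genes,
                             coverage = 1, decoy_rate = 0, seed = 12)
  expect_setequal(unique(pure$mirna), "m1")
  expect_setequal(pure$gene[pure$algorithm == "TargetScan"], tfs)
  expect_error(make_target_tables(tfs, "m1", character(0), genes,
                                  coverage = 1, decoy_rate = 0, seed = 1),
               "nonempty")
  expect_error(make_target_tables(tfs, "zz", mirnas, genes,
                                  coverage = 1, decoy_rate = 0, seed = 1),
               "one of mirnas")
})

test_that("every planted entity is cross-referenced in the outputs", {
  ds <- simulate_dataset(sim_config(n_genes = 300, seed = 15))
  genes <- rownames(ds$expr$values)
  expect_true(all(ds$truth$strain_de$gene %in% genes))
  expect_true(all(ds$truth$lps_de$gene %in% genes))
  expect_true(all(names(ds$truth$planted_pwms) %in% names(ds$pwms)))
  expect_true(all(ds$truth$mirna_tf_targets %in% ds$pwm_tf_map$tf_gene))
  for (alg in unique(ds$targets$algorithm))
    expect_true(ds$truth$mirna %in% ds$targets$mirna[ds$targets$algorithm == alg])
  expect_true(all(unlist(ds$go) %in% genes))
  expect_setequal(names(ds$promoters), genes)
})

test_that("dataset writer emits readable files that round-trip", {
  ds <- simulate_dataset(sim_config(n_genes = 80, promoter_length = 200,
                                    seed = 21))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  m <- read_expression(paths["matrix"], paths["samples"], paths["flags"])
  expect_equal(m$values, ds$expr$values, tolerance = 1e-8)
  expect_identical(m$flags, ds$expr$flags)
  prom <- read_promoters(paths["promoters"])
  expect_identical(prom, ds$promoters)
  lib <- read_jaspar(paths["pwms"])
  expect_identical(names(lib), names(ds$pwms))
  expect_equal(lib[[1]]$mat, ds$pwms[[1]]$mat, tolerance = 1e-6)
  tt <- read_target_tables(paths["targets"])
  expect_equal(nrow(tt), nrow(ds$targets))
  ann <- read_gene_sets(paths["go_gmt"], rownames(ds$expr$values))
  expect_setequal(names(ann$term_genes), names(ds$go))
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_identical(truth$mirna, ds$truth$mirna)
})

test_that("planted-signal round trip: zero noise, degenerate scan thresholds", {
  # a single planted PWM so that insertions never overwrite each other
  cfg <- sim_config(n_genes = 120, noise_sd_log2 = 0, promoter_length = 300,
                    motif_plant_rate = 1, planted_pwm_ids = "M0001", seed = 33)
  ds <- simulate_dataset(cfg)
  # expression: planted strain difference is exactly the configured effect
  lg <- log2(ds$expr$values)
  s1 <- ds$expr$design$strain == cfg$strains[1]
  diffs <- rowMeans(lg[, s1]) - rowMeans(lg[, !s1])
  tr <- ds$truth$strain_de
  expect_equal(unname(diffs[tr$gene]), tr$log2_effect, tolerance = 1e-9)
  # motifs: every consensus-spelling insertion is recovered even at the
  # degenerate threshold of 1.0 (sampled sites with mismatches score lower
  # by construction)
  ins <- ds$truth$motif_insertions
  cons <- ins$motif_seq == vapply(ds$pwms[ins$pwm], pwm_consensus, "")
  expect_gt(sum(cons), 0L)
  for (i in which(cons)) {
    h <- scan_promoter(ds$promoters[[ins$gene[i]]], ds$pwms[[ins$pwm[i]]],
                       threshold_frac = 1)
    expect_true(ins$position[i] %in% h$position)
  }
})
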