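test_that("PWM construction regularizes counts and probabilities alike", {
  counts <- matrix(c(8, 0, 0, 0,
                     0, 8, 0, 0,
                     0, 0, 8, 0,
                     0, 0, 0, 8), 4, 4)
  p <- pwm(counts, id = "M1")
  expect_true(all(abs(colSums(p$mat) - 1) < 1e-9))
  expect_identical(pwm_consensus(p), "ACGT")
  expect_error(pwm(counts[, 1:3], id = "bad"), "length must be >= 4")
  expect_error(pwm(matrix(-1, 4, 6), id = "neg"), "nonnegative")
})

test_that("window scoring equals a position-by-position hand sum", {
  set.seed(4)
  for (rep in 1:5) {
    L <- sample(4:8, 1)
    mat <- matrix(runif(4 * L), 4, L)
    p <- pwm(mat, id = "R")
    bg <- c(0.3, 0.2, 0.2, 0.3)
    win <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    idx <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T"))
    hand <- sum(log2(p$mat[cbind(idx, 1:L)] / (bg / sum(bg))[idx]))
    expect_equal(pwm_score(win, p, bg), hand, tolerance = 1e-12)
  }
})

test_that("uniform PWMs score zero and consensus windows score near L*log2(q)", {
  p_unif <- pwm(matrix(0.25, 4, 6), id = "U")
  expect_equal(pwm_score("ACGTAC", p_unif), 0, tolerance = 1e-9)
  cons <- consensus_pwm("ACGTAA")  # near-1 columns after pseudocount
  sc <- pwm_score("ACGTAA", cons)
  expect_equal(sc, 6 * log2((1 + 0.01) / (1 + 0.04) / 0.25), tolerance = 0.1)
  expect_equal(sc, pwm_max_score(cons), tolerance = 1e-12)
  # any single mismatch scores strictly lower
  expect_lt(pwm_score("CCGTAA", cons), sc)
  expect_error(pwm_score("ACNTAA", cons), "non-ACGT")
})

test_that("promoter scanning equals exhaustive window enumeration", {
  set.seed(9)
  for (rep in 1:5) {
    L <- sample(5:8, 1)
    p <- pwm(matrix(runif(4 * L), 4, L), id = "S")
    seqs <- paste(sample(c("A", "C", "G", "T", "N"), 400, replace = TRUE,
                         prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    frac <- 0.7
    hits <- scan_promoter(seqs, p, threshold_frac = frac)
    thr <- frac * pwm_max_score(p)
    expected <- list()
    S <- nchar(seqs)
    rc_all <- revcomp_str(seqs)
    for (i in 1:(S - L + 1)) {
      w <- substr(seqs, i, i + L - 1)
      if (!grepl("N", w) && pwm_score(w, p) >= thr)
        expected[[length(expected) + 1]] <- c(i - 1, "+")
      wrc <- substr(rc_all, S - (i + L - 1) + 1, S - i + 1)
      if (!grepl("N", wrc) && pwm_score(wrc, p) >= thr)
        expected[[length(expected) + 1]] <- c(i - 1, "-")
    }
    exp_df <- if (length(expected)) {
      d <- data.frame(position = as.integer(vapply(expected, `[`, "", 1)),
                      strand = vapply(expected, `[`, "", 2))
      d[order(d$position, d$strand), ]
    } else data.frame(position = integer(), strand = character())
    expect_equal(hits$position, exp_df$position)
    expect_equal(hits$strand, exp_df$strand)
  }
})

test_that("planted consensus sites are found on the stated strand and position", {
  cons <- consensus_pwm("AAACCC")
  base <- paste(rep("T", 300), collapse = "")
  fwd <- base; substr(fwd, 101, 106) <- "AAACCC"
  h <- scan_promoter(fwd, cons, threshold_frac = 1)
  expect_equal(nrow(h), 1L)
  expect_equal(h$position, 100L)  # 0-based
  expect_identical(h$strand, "+")
  rev_ <- base; substr(rev_, 101, 106) <- revcomp_str("AAACCC")
  h2 <- scan_promoter(rev_, cons, threshold_frac = 1)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$position, 100L)
  expect_identical(h2$strand, "-")
  # promoter shorter than the motif: zero hits, no error
  expect_equal(nrow(scan_promoter("TT", cons)), 0L)
})

test_that("raising the threshold never adds hits", {
  set.seed(23)
  p <- pwm(matrix(runif(24), 4, 6), id = "T")
  s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  fracs <- c(0.5, 0.7, 0.85, 1)
  counts <- vapply(fracs, function(f)
    nrow(scan_promoter(s, p, threshold_frac = f)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the enrichment factor follows its frequency-ratio definition", {
  cons <- consensus_pwm("AACCGG")
  bg_genes <- sprintf("g%03d", 1:100)
  promoters <- stats::setNames(rep(paste(rep("T", 200), collapse = ""), 100),
                               bg_genes)
  hit_genes <- bg_genes[1:10]
  for (g in hit_genes) substr(promoters[[g]], 51, 56) <- "AACCGG"
  set_genes <- bg_genes[c(1:5, 51:55)]  # 5 of 10 set genes carry the site
  res <- motif_enrichment(set_genes, bg_genes, promoters,
                          list(MTEST = cons), background = rep(0.25, 4),
                          threshold_frac = 1)
  expect_equal(res$hits_set, 5L)
  expect_equal(res$hits_bg, 10L)
  expect_equal(res$EF, (5 / 10) / (10 / 100))  # = 5
  expect_equal(res$p, hypergeometric_p(5, 10, 10, 100), tolerance = 1e-12)
})

test_that("the background scored against itself has EF identically 1", {
  set.seed(12)
  genes <- sprintf("g%02d", 1:30)
  promoters <- stats::setNames(vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""),
    character(1)), genes)
  pwms <- stats::setNames(
    lapply(1:3, function(i) pwm(matrix(runif(4 * 6), 4, 6),
                                id = paste0("M", i))),
    paste0("M", 1:3))
  res <- motif_enrichment(genes, genes, promoters, pwms, threshold_frac = 0.6)
  with_hits <- res$hits_bg > 0
  expect_true(all(res$EF[with_hits] == 1))
  expect_true(all(is.na(res$EF[!with_hits])))
  expect_true(all(res$p[with_hits] == 1))
})

test_that("JASPAR and TRANSFAC parsers round-trip / agree", {
  set.seed(6)
  pwms <- stats::setNames(lapply(1:2, function(i)
    pwm(matrix(sample(0:20, 4 * 7, replace = TRUE) + 1, 4, 7),
        id = sprintf("M%04d", i), tf_name = paste0("TF", i))),
    sprintf("M%04d", 1:2))
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "lib.jaspar")
  write_jaspar(pwms, jp)
  back <- read_jaspar(jp)
  expect_identical(names(back), names(pwms))
  expect_equal(back$M0001$mat, pwms$M0001$mat, tolerance = 1e-6)
  expect_identical(back$M0002$tf_name, "TF2")

  tf_txt <- c("ID M00001", "NA FOXTEST", "P0 A C G T",
              "01 8 0 0 0", "02 0 8 0 0", "03 0 0 8 0", "04 0 0 0 8",
              "05 8 0 0 0", "//")
  tp <- file.path(dir, "lib.transfac")
  writeLines(tf_txt, tp)
  tr <- read_transfac(tp)
  expect_identical(names(tr), "M00001")
  expect_identical(tr$M00001$tf_name, "FOXTEST")
  expect_identical(pwm_consensus(tr$M00001), "ACGTA")
})

test_that("promoter FASTA I/O preserves sequences keyed by gene id", {
  set.seed(3)
  promoters <- stats::setNames(vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = ""),
    character(1)), sprintf("gene%02d", 1:5))
  dir <- withr::local_tempdir()
  fp <- file.path(dir, "prom.fasta")
  write_promoters(promoters, fp)
  back <- read_promoters(fp)
  expect_identical(back, promoters)
})
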