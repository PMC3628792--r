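# Fixture builders and independent oracles used across the suite.

# small expression object: genes x samples log2 matrix with a 2x2(x durations)
# replicated design
make_design <- function(strains = c("S1", "S2"), treatments = c("control", "LPS"),
                        durations = "24h", reps = 3L) {
  d <- expand.grid(rep = seq_len(reps), duration = durations,
                   treatment = treatments, strain = strains,
                   stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_%s_%s_r%d", d$strain, d$treatment, d$duration, d$rep)
  d[, c("sample_id", "strain", "treatment", "duration")]
}

make_expr <- function(values, design, flags = NULL, scale = "log2_normalized") {
  colnames(values) <- design$sample_id
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(flags))
    flags <- matrix("P", nrow(values), ncol(values))
  expr_matrix(values, flags, design, scale = scale)
}

# exact two-sided Mann-Whitney p by full enumeration of label assignments
enum_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  x <- c(a, b)
  u_of <- function(idx) sum(rank(x)[idx]) - n1 * (n1 + 1) / 2
  obs <- abs(u_of(seq_len(n1)) - n1 * n2 / 2)
  sets <- utils::combn(n1 + n2, n1)
  dev <- apply(sets, 2L, function(idx) abs(u_of(idx) - n1 * n2 / 2))
  mean(dev >= obs - 1e-12)
}

# direct BH step-up formula: min over j >= i of m p_(j) / j
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m))
    adj[o[i]] <- min(1, min(m * sorted[i:m] / (i:m)))
  adj
}

# exact hypergeometric upper tail by enumeration of all draws
enum_hyper_p <- function(k, n, K, N) {
  marked <- seq_len(K)
  sets <- utils::combn(N, n)
  mean(apply(sets, 2L, function(s) sum(s %in% marked)) >= k)
}

# O(n^3) agglomeration from a distance matrix; ties broken by the smallest
# lexicographic cluster pair (on current cluster indices)
naive_agglomerate <- function(dm, method = c("average", "complete"), k = 1L) {
  method <- match.arg(method)
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        cross <- dm[clusters[[i]], clusters[[j]], drop = FALSE]
        dij <- if (method == "complete") max(cross) else mean(cross)
        if (dij < best_d - 1e-12) { best_d <- dij; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, clusters = clusters)
}

rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}

# degenerate near-certain PWM spelling a consensus
consensus_pwm <- function(consensus, id = "MTEST", pseudocount = 0.01) {
  bases <- strsplit(consensus, "")[[1]]
  mat <- matrix(0, 4L, length(bases), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) mat[bases[j], j] <- 1
  pwm(mat, id = id, pseudocount = pseudocount)
}

revcomp_str <- function(s) {
  paste(rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[strsplit(s, "")[[1]]]),
        collapse = "")
}

# expand a per-algorithm target-count table over a TF set into prediction
# tables whose intersection counts reproduce the printed counts
expand_count_table <- function(counts, tfs) {
  algos <- setdiff(names(counts), "mirna")
  do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    do.call(rbind, lapply(algos, function(alg) {
      n <- counts[[alg]][i]
      if (n == 0) return(NULL)
      data.frame(algorithm = alg, mirna = counts$mirna[i],
                 gene = tfs[seq_len(n)])
    }))
  }))
}

# planted motif-recovery simulation: one planted PWM + decoys, cluster vs
# background promoters; returns the p-rank of the planted PWM
motif_recovery_rank <- function(seed, n_bg = 200L, n_cluster = 20L,
                                n_pwms = 10L, plant_rate = 0.6,
                                promoter_length = 3000L) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_bg))
  promoters <- stats::setNames(vapply(seq_len(n_bg), function(i)
    paste(sample(c("A", "C", "G", "T"), promoter_length, replace = TRUE),
          collapse = ""), character(1)), genes)
  pwms <- stats::setNames(lapply(seq_len(n_pwms), function(i)
    mircascade:::random_pwm(sprintf("M%02d", i), sprintf("TF%02d", i),
                            len = sample(8:12, 1L))),
    sprintf("M%02d", seq_len(n_pwms)))
  cluster <- genes[seq_len(n_cluster)]
  pl <- plant_motifs(promoters, pwms[[1L]], cluster, rate = plant_rate,
                     seed = seed + 5000L)
  res <- motif_enrichment(cluster, genes, pl$promoters, pwms)
  match("M01", res$pwm)
}
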