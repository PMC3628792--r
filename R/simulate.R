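#' Configuration for the synthetic two-strain LPS experiment
#'
#' Defines the study conditions the generator emulates: two rat-like strains,
#' control vs LPS treatment at two durations with replicate arrays, log-normal
#' intensity noise, planted strain-differential and LPS-responsive genes at
#' fixed log2 effect sizes, detection flags, GO terms enriched in the planted
#' clusters, PWM motif occurrences planted in the promoters of one cluster,
#' and a bipartite miRNA -> TF target structure with one planted true
#' regulator.
#'
#' @param n_genes number of genes.
#' @param n_replicates_per_condition replicate arrays per condition (>= 2;
#'   rank tests and ANOVA are degenerate without replication).
#' @param strains pair of strain labels.
#' @param treatments treatment labels (control first).
#' @param durations duration labels.
#' @param frac_strain_de fraction of genes with a planted strain effect.
#' @param frac_lps_de fraction of genes with a planted LPS response.
#' @param log2_effect_strain,log2_effect_lps planted log2 effect sizes.
#' @param noise_sd_log2 array noise SD on the log2 scale.
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-gene
#'   baseline log2 intensities.
#' @param flag_absent_quantile per-sample intensity quantile below which a
#'   probe is flagged A (absent); a band of +/- 2 percent around it is
#'   flagged M (marginal). 0 disables absent flags.
#' @param n_go_terms number of GO terms (the last one is a TF-regulon term
#'   containing all TF genes).
#' @param go_term_size_range length-2 integer range of term sizes.
#' @param planted_go_enrichment_frac fraction of a planted term's members
#'   drawn from its target cluster.
#' @param promoter_length promoter length in bases (upstream region).
#' @param n_pwms number of PWMs (and TF genes) in the library.
#' @param planted_pwm_ids ids of the PWMs planted into cluster 1 promoters.
#' @param motif_plant_rate fraction of cluster-1 promoters receiving each
#'   planted motif.
#' @param n_mirnas number of miRNAs in the target tables.
#' @param true_mirna_target_coverage fraction of the planted-TF set targeted
#'   by the true regulator miRNA, per algorithm.
#' @param decoy_target_rate per-gene probability that a decoy miRNA targets a
#'   gene.
#' @param seed integer seed; identical (config, seed) gives byte-identical
#'   outputs.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(n_genes = 1000L,
                       n_replicates_per_condition = 3L,
                       strains = c("LEW", "PVG"),
                       treatments = c("control", "LPS"),
                       durations = c("24h", "48h"),
                       frac_strain_de = 0.05,
                       frac_lps_de = 0.05,
                       log2_effect_strain = 1.5,
                       log2_effect_lps = 1.5,
                       noise_sd_log2 = 0.4,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       flag_absent_quantile = 0.05,
                       n_go_terms = 50L,
                       go_term_size_range = c(10L, 60L),
                       planted_go_enrichment_frac = 0.6,
                       promoter_length = 3000L,
                       n_pwms = 10L,
                       planted_pwm_ids = c("M0001", "M0002", "M0003"),
                       motif_plant_rate = 0.6,
                       n_mirnas = 20L,
                       true_mirna_target_coverage = 0.8,
                       decoy_target_rate = 0.05,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_replicates_per_condition = as.integer(n_replicates_per_condition),
              strains = as.character(strains),
              treatments = as.character(treatments),
              durations = as.character(durations),
              frac_strain_de = frac_strain_de, frac_lps_de = frac_lps_de,
              log2_effect_strain = log2_effect_strain,
              log2_effect_lps = log2_effect_lps,
              noise_sd_log2 = noise_sd_log2,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              flag_absent_quantile = flag_absent_quantile,
              n_go_terms = as.integer(n_go_terms),
              go_term_size_range = as.integer(go_term_size_range),
              planted_go_enrichment_frac = planted_go_enrichment_frac,
              promoter_length = as.integer(promoter_length),
              n_pwms = as.integer(n_pwms),
              planted_pwm_ids = as.character(planted_pwm_ids),
              motif_plant_rate = motif_plant_rate,
              n_mirnas = as.integer(n_mirnas),
              true_mirna_target_coverage = true_mirna_target_coverage,
              decoy_target_rate = decoy_target_rate,
              seed = as.integer(seed))
  chk(is_count(cfg$n_genes), "n_genes must be a positive integer")
  chk(is_count(cfg$n_replicates_per_condition) &&
        cfg$n_replicates_per_condition >= 2,
      "n_replicates_per_condition must be an integer >= 2")
  chk(length(cfg$strains) == 2L && !anyDuplicated(cfg$strains),
      "strains must be two distinct labels")
  chk(length(cfg$treatments) >= 2L && "control" %in% cfg$treatments,
      "treatments must include 'control' and at least one stimulus")
  chk(length(cfg$durations) >= 1L, "durations must be nonempty")
  for (f in c("frac_strain_de", "frac_lps_de", "flag_absent_quantile",
              "planted_go_enrichment_frac", "motif_plant_rate",
              "true_mirna_target_coverage", "decoy_target_rate"))
    chk(is_frac(cfg[[f]]), f, " must be a fraction in [0, 1]")
  chk(cfg$frac_strain_de + cfg$frac_lps_de <= 1,
      "frac_strain_de + frac_lps_de exceeds 1: the planted sets are disjoint ",
      "by construction and cannot cover more than the whole gene set")
  for (f in c("log2_effect_strain", "log2_effect_lps", "noise_sd_log2",
              "baseline_log2_mean", "baseline_log2_sd"))
    chk(is.numeric(cfg[[f]]) && is.finite(cfg[[f]]), f, " must be finite")
  chk(cfg$noise_sd_log2 >= 0, "noise_sd_log2 must be nonnegative")
  chk(length(cfg$go_term_size_range) == 2L &&
        cfg$go_term_size_range[1] >= 2L &&
        diff(cfg$go_term_size_range) >= 0,
      "go_term_size_range must be an increasing pair >= 2")
  chk(is_count(cfg$promoter_length) && cfg$promoter_length >= 20L,
      "promoter_length must be an integer >= 20")
  chk(is_count(cfg$n_pwms), "n_pwms must be a positive integer")
  chk(length(cfg$planted_pwm_ids) >= 1L &&
        length(cfg$planted_pwm_ids) <= cfg$n_pwms,
      "planted_pwm_ids must name between 1 and n_pwms motifs")
  chk(is_count(cfg$n_mirnas) && cfg$n_mirnas >= 2L,
      "n_mirnas must be an integer >= 2")
  chk(is_count(abs(cfg$seed)) || cfg$seed == 0L, "seed must be an integer")
  structure(cfg, class = "sim_config")
}

random_dna <- function(n_seqs, len, freq = rep(0.25, 4)) {
  vapply(seq_len(n_seqs), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE, prob = freq), collapse = "")
  }, character(1))
}

random_pwm <- function(id, tf_name, len, pseudocount = 0.01) {
  mat <- matrix(0, 4L, len, dimnames = list(DNA_BASES, NULL))
  # highly informative columns, as for strong curated TF site matrices;
  # sites sampled from the PWM then score near the maximum achievable
  cons <- sample.int(4L, len, replace = TRUE)
  conc <- stats::runif(len, 0.93, 0.98)
  for (j in seq_len(len)) {
    mat[, j] <- (1 - conc[j]) / 3
    mat[cons[j], j] <- conc[j]
  }
  pwm(mat, id = id, tf_name = tf_name, pseudocount = pseudocount)
}

#' Plant PWM-sampled motif occurrences into promoters
#'
#' For \code{ceiling(rate * length(genes))} genes (sampled without
#' replacement), one sequence drawn from the PWM's per-position base
#' distributions is written at a uniformly chosen position on a uniformly
#' chosen strand; all other promoters are untouched. Insertion positions are
#' 0-based offsets from the distal end, matching \code{\link{scan_promoter}}.
#'
#' @param promoters named character vector of promoter sequences.
#' @param pwm a \code{\link{pwm}}.
#' @param genes gene ids eligible for planting (must all have promoters).
#' @param rate fraction of \code{genes} to modify.
#' @param seed integer seed.
#' @return A list: \code{promoters} (modified vector) and \code{insertions}
#'   (data.frame gene, position, strand, motif_seq).
#' @export
plant_motifs <- function(promoters, pwm, genes, rate, seed) {
  chk(inherits(pwm, "pwm"), "pwm must be a pwm object")
  chk(is_frac(rate), "rate must be in [0, 1]")
  miss <- setdiff(genes, names(promoters))
  chk(length(miss) == 0L, "genes without promoters: ",
      paste(utils::head(miss, 5L), collapse = ", "))
  L <- pwm$length
  short <- genes[nchar(promoters[genes]) < L]
  chk(length(short) == 0L, "motif longer than promoter for: ",
      paste(utils::head(short, 5L), collapse = ", "))
  n_mod <- ceiling(rate * length(genes))
  ins <- data.frame(gene = character(), position = integer(),
                    strand = character(), motif_seq = character())
  if (n_mod > 0L) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    chosen <- sample(genes, n_mod)
    for (g in chosen) {
      site <- paste(DNA_BASES[apply(pwm$mat, 2L, function(col)
        sample.int(4L, 1L, prob = col))], collapse = "")
      strand <- sample(c("+", "-"), 1L)
      written <- if (strand == "+") site else
        paste(rev(c("A" = "T", "C" = "G", "G" = "C", "T" = "A")[
          strsplit(site, "")[[1]]]), collapse = "")
      slen <- nchar(promoters[[g]])
      pos0 <- sample.int(slen - L + 1L, 1L) - 1L
      substr(promoters[[g]], pos0 + 1L, pos0 + L) <- written
      ins <- rbind(ins, data.frame(gene = g, position = pos0, strand = strand,
                                   motif_seq = site))
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  list(promoters = promoters, insertions = ins)
}

#' Generate the two-algorithm miRNA target tables
#'
#' The planted regulator miRNA targets \code{ceiling(coverage * |TF set|)}
#' genes of the truth TF set in each algorithm's table (sampled
#' independently); every decoy miRNA targets each gene independently with
#' probability \code{decoy_rate}.
#'
#' @param tf_targets character vector; the truth TF gene set of the planted
#'   regulator.
#' @param true_mirna id of the planted regulator.
#' @param mirnas character vector of all miRNA ids (nonempty, containing
#'   \code{true_mirna}).
#' @param genes gene universe decoy targets are drawn from.
#' @param coverage,decoy_rate fractions in [0, 1].
#' @param seed integer seed.
#' @param algorithms labels of the two prediction sources.
#' @return data.frame with columns algorithm, mirna, gene.
#' @export
make_target_tables <- function(tf_targets, true_mirna, mirnas, genes,
                               coverage, decoy_rate, seed,
                               algorithms = c("TargetScan", "miRanda")) {
  chk(length(mirnas) > 0L, "mirnas must be nonempty")
  chk(true_mirna %in% mirnas, "true_mirna must be one of mirnas")
  chk(is_frac(coverage) && is_frac(decoy_rate),
      "coverage and decoy_rate must be fractions")
  chk(!anyDuplicated(algorithms) && length(algorithms) >= 1L,
      "algorithm labels must be distinct")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  n_true <- ceiling(coverage * length(tf_targets))
  rows <- list()
  for (alg in algorithms) {
    if (n_true > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = alg, mirna = true_mirna,
        gene = sample(tf_targets, n_true))
    for (m in setdiff(mirnas, true_mirna)) {
      hit <- genes[stats::runif(length(genes)) < decoy_rate]
      if (length(hit) > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = alg, mirna = m, gene = hit)
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(algorithm = character(), mirna = character(), gene = character())
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic dataset with planted ground truth
#'
#' Produces every input the cascade consumes -- expression matrix with flags
#' and design, GO annotation, promoter set with planted motifs, PWM library,
#' miRNA target tables, PWM -> TF gene map -- plus the \code{truth} record of
#' what was planted. Identical (config, seed) gives identical output.
#'
#' Structure: strain-differential genes split evenly into cluster 1 (up in the
#' second strain) and cluster 2 (up in the first strain); LPS-responsive genes
#' respond within one strain each. The planted PWMs' motifs are written into
#' cluster-1 promoters; each PWM maps to a TF gene; the planted regulator
#' miRNA targets the TF genes of the planted PWMs. One GO term per cluster is
#' enriched for that cluster's genes and a TF-regulon term contains all TF
#' genes.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A \code{sim_dataset} list: \code{expr} (raw-scale
#'   \code{\link{expr_matrix}}), \code{go} (term -> genes list),
#'   \code{go_names}, \code{promoters}, \code{pwms}, \code{pwm_tf_map},
#'   \code{targets}, \code{truth}, \code{config}.
#' @export
simulate_dataset <- function(config) {
  chk(inherits(config, "sim_config"), "config must come from sim_config()")
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%04d", seq_len(n))

  ## planted DE structure (disjoint strain/LPS sets)
  n_sde <- round(config$frac_strain_de * n)
  n_lde <- round(config$frac_lps_de * n)
  de_pool <- sample(genes, n_sde + n_lde)
  strain_de <- de_pool[seq_len(n_sde)]
  lps_de <- de_pool[n_sde + seq_len(n_lde)]
  half <- ceiling(n_sde / 2)
  cluster2 <- strain_de[seq_len(half)]          # up in strains[1]
  cluster1 <- setdiff(strain_de, cluster2)      # up in strains[2]
  cluster_assignment <- c(
    stats::setNames(rep("cluster1", length(cluster1)), cluster1),
    stats::setNames(rep("cluster2", length(cluster2)), cluster2),
    stats::setNames(rep("lps", length(lps_de)), lps_de)
  )
  lps_strain <- if (n_lde > 0)
    config$strains[1L + (seq_len(n_lde) %% 2L)] else character(0)
  lps_sign <- if (n_lde > 0)
    sample(c(1, -1), n_lde, replace = TRUE) else numeric(0)

  ## design
  d <- expand.grid(rep = seq_len(config$n_replicates_per_condition),
                   duration = config$durations,
                   treatment = config$treatments,
                   strain = config$strains,
                   stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_%s_%s_r%d", d$strain, d$treatment, d$duration, d$rep)
  design <- d[, c("sample_id", "strain", "treatment", "duration")]

  ## log2 intensities
  baseline <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  mu <- matrix(baseline, n, nrow(design))
  eff_s <- config$log2_effect_strain
  is_s1 <- design$strain == config$strains[1L]
  mu[match(cluster2, genes), is_s1] <- mu[match(cluster2, genes), is_s1] + eff_s / 2
  mu[match(cluster2, genes), !is_s1] <- mu[match(cluster2, genes), !is_s1] - eff_s / 2
  mu[match(cluster1, genes), !is_s1] <- mu[match(cluster1, genes), !is_s1] + eff_s / 2
  mu[match(cluster1, genes), is_s1] <- mu[match(cluster1, genes), is_s1] - eff_s / 2
  for (i in seq_along(lps_de)) {
    gi <- match(lps_de[i], genes)
    cols <- design$strain == lps_strain[i] & design$treatment != "control"
    mu[gi, cols] <- mu[gi, cols] + lps_sign[i] * config$log2_effect_lps
  }
  lg <- mu + stats::rnorm(length(mu), 0, config$noise_sd_log2)
  raw <- 2^lg
  dimnames(raw) <- list(genes, design$sample_id)

  ## detection flags: per-sample quantile rank with a +/-2% marginal band
  q <- config$flag_absent_quantile
  flags <- matrix("P", n, nrow(design), dimnames = dimnames(raw))
  if (q > 0) {
    for (j in seq_len(ncol(raw))) {
      r <- rank(raw[, j], ties.method = "average") / n
      flags[r < q - 0.02, j] <- "A"
      flags[r >= q - 0.02 & r <= q + 0.02, j] <- "M"
    }
  }
  expr <- expr_matrix(raw, flags, design, scale = "raw")

  ## PWM library and TF genes
  non_de <- setdiff(genes, c(strain_de, lps_de))
  tf_genes <- sample(non_de, config$n_pwms)
  pwm_ids <- sprintf("M%04d", seq_len(config$n_pwms))
  bad_ids <- setdiff(config$planted_pwm_ids, pwm_ids)
  chk(length(bad_ids) == 0L, "planted_pwm_ids not in the generated library (",
      "ids are M0001..M", sprintf("%04d", config$n_pwms), "): ",
      paste(bad_ids, collapse = ", "))
  pwms <- stats::setNames(vector("list", config$n_pwms), pwm_ids)
  for (i in seq_len(config$n_pwms)) {
    pwms[[i]] <- random_pwm(pwm_ids[i], paste0("TF_", tf_genes[i]),
                            len = sample(8:12, 1L))
  }
  pwm_tf_map <- data.frame(pwm = pwm_ids, tf_gene = tf_genes)

  ## promoters with planted motifs in cluster 1
  promoters <- stats::setNames(
    random_dna(n, config$promoter_length), genes)
  insertions <- list()
  for (k in seq_along(config$planted_pwm_ids)) {
    pid <- config$planted_pwm_ids[k]
    pl <- plant_motifs(promoters, pwms[[pid]], cluster1,
                       rate = config$motif_plant_rate,
                       seed = derive_seed(config$seed, 100L + k))
    promoters <- pl$promoters
    if (nrow(pl$insertions) > 0L) pl$insertions$pwm <- pid
    insertions[[pid]] <- pl$insertions
  }
  insertions <- do.call(rbind, c(insertions, list(make.row.names = FALSE)))

  ## GO annotation: generic terms + 2 cluster-planted terms + TF regulon
  n_terms <- max(config$n_go_terms, 4L)
  term_ids <- sprintf("GO:%07d", seq_len(n_terms))
  term_names <- stats::setNames(sprintf("term_%03d", seq_len(n_terms)), term_ids)
  term_genes <- stats::setNames(vector("list", n_terms), term_ids)
  sz <- function() sample(seq(config$go_term_size_range[1L],
                              config$go_term_size_range[2L]), 1L)
  planted_terms <- c(cluster1 = term_ids[1L], cluster2 = term_ids[2L],
                     tf_regulon = term_ids[n_terms])
  for (i in seq_len(n_terms)) {
    size <- sz()
    tid <- term_ids[i]
    if (tid == planted_terms[["cluster1"]] && length(cluster1) > 0) {
      k_in <- min(ceiling(config$planted_go_enrichment_frac * size),
                  length(cluster1))
      members <- c(sample(cluster1, k_in),
                   sample(setdiff(genes, cluster1), size - k_in))
    } else if (tid == planted_terms[["cluster2"]] && length(cluster2) > 0) {
      k_in <- min(ceiling(config$planted_go_enrichment_frac * size),
                  length(cluster2))
      members <- c(sample(cluster2, k_in),
                   sample(setdiff(genes, cluster2), size - k_in))
    } else if (tid == planted_terms[["tf_regulon"]]) {
      size <- max(size, length(tf_genes))
      members <- c(tf_genes, sample(setdiff(genes, tf_genes),
                                    size - length(tf_genes)))
    } else {
      members <- sample(genes, size)
    }
    term_genes[[tid]] <- sort(unique(members))
  }

  ## miRNA target tables
  mirnas <- sprintf("miR-%03d", seq_len(config$n_mirnas))
  true_mirna <- sample(mirnas, 1L)
  tf_truth <- pwm_tf_map$tf_gene[pwm_tf_map$pwm %in% config$planted_pwm_ids]
  targets <- make_target_tables(
    tf_truth, true_mirna, mirnas, genes,
    coverage = config$true_mirna_target_coverage,
    decoy_rate = config$decoy_target_rate,
    seed = derive_seed(config$seed, 7L))
  chk(all(c("TargetScan", "miRanda") %in% unique(targets$algorithm)) ||
        config$true_mirna_target_coverage == 0,
      "internal: target tables incomplete")

  truth <- structure(list(
    strain_de = data.frame(
      gene = c(cluster2, cluster1),
      log2_effect = c(rep(eff_s, length(cluster2)),
                      rep(-eff_s, length(cluster1))),
      cluster = c(rep("cluster2", length(cluster2)),
                  rep("cluster1", length(cluster1)))),
    lps_de = data.frame(gene = lps_de, strain = lps_strain,
                        log2_effect = lps_sign * config$log2_effect_lps),
    cluster_assignment = cluster_assignment,
    planted_terms = planted_terms,
    planted_pwms = stats::setNames(
      rep("cluster1", length(config$planted_pwm_ids)), config$planted_pwm_ids),
    motif_insertions = insertions,
    mirna = true_mirna,
    mirna_tf_targets = tf_truth,
    seed = config$seed), class = "sim_truth")

  structure(list(expr = expr, go = term_genes, go_names = term_names,
                 promoters = promoters, pwms = pwms,
                 pwm_tf_map = pwm_tf_map, targets = targets,
                 truth = truth, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(paste0("sim_dataset: %d genes x %d samples; %d GO terms; ",
                     "%d PWMs (%d planted); %d miRNAs (regulator %s)\n"),
              nrow(x$expr$values), ncol(x$expr$values), length(x$go),
              length(x$pwms), length(x$truth$planted_pwms),
              x$config$n_mirnas, x$truth$mirna))
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits the expression TSVs (matrix, flags, sample sheet), the GO map as TSV
#' and GMT, promoters as FASTA (header = gene id), the PWM library in
#' JASPAR-style matrix text, the target tables TSV, the PWM -> TF map TSV and
#' the truth JSON.
#'
#' @param ds a \code{sim_dataset}.
#' @param dir output directory.
#' @return Invisibly, the named vector of paths.
#' @export
write_dataset <- function(ds, dir) {
  chk(inherits(ds, "sim_dataset"), "ds must be a sim_dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_expression(ds$expr, dir)
  ann <- go_annotation(ds$go, rownames(ds$expr$values), ds$go_names)
  write_gene_sets(ann, tsv_path = file.path(dir, "go_map.tsv"),
                  gmt_path = file.path(dir, "go_sets.gmt"))
  write_promoters(ds$promoters, file.path(dir, "promoters.fasta"))
  write_jaspar(ds$pwms, file.path(dir, "pwms.jaspar"))
  write_tsv(ds$targets, file.path(dir, "targets.tsv"))
  write_tsv(ds$pwm_tf_map, file.path(dir, "pwm_tf_map.tsv"))
  truth <- ds$truth
  class(truth) <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths,
              go_tsv = file.path(dir, "go_map.tsv"),
              go_gmt = file.path(dir, "go_sets.gmt"),
              promoters = file.path(dir, "promoters.fasta"),
              pwms = file.path(dir, "pwms.jaspar"),
              targets = file.path(dir, "targets.tsv"),
              pwm_tf_map = file.path(dir, "pwm_tf_map.tsv"),
              truth = file.path(dir, "truth.json")))
}
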