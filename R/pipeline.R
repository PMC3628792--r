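#' Configuration for a full cascade run
#'
#' Exactly one of \code{sim} (a \code{\link{sim_config}}) or \code{input}
#' (named list of file paths) must be supplied. In real-input mode the paths
#' are: \code{matrix}, \code{samplesheet}, \code{flags} (optional),
#' \code{go} (gene-term TSV or GMT), \code{promoters} (FASTA), \code{pwms}
#' (JASPAR matrix text), \code{targets} (algorithm/mirna/gene TSV),
#' \code{pwm_tf_map} (two-column TSV pwm, tf_gene).
#'
#' @param sim a \code{\link{sim_config}} or NULL.
#' @param input named list of input paths or NULL.
#' @param criteria1,criteria2,criteria3 \code{\link{selection_criteria}} for
#'   the three DE lists.
#' @param combine_rule \code{"union_all"} or \code{"shared_by_2_of_3"}.
#' @param anova_factors factor pair for List 3 (see
#'   \code{\link{select_de_genes}}).
#' @param k,linkage,distance clustering options.
#' @param min_term_size,max_term_size,go_alpha GO enrichment options.
#' @param threshold_frac,motif_alpha,background_model promoter-motif options;
#'   background model is \code{"bg_composition"} (promoter base composition)
#'   or \code{"uniform"}.
#' @param fame_B,fame_alpha,fame_top empirical-enrichment options: resamples
#'   per pair, significance threshold on the BH-adjusted p, and the number of
#'   top-ranked miRNAs tested.
#' @param family_map optional miRNA family map (data.frame mirna, family).
#' @param min_informative flag-filter threshold.
#' @param universe_mode \code{"filtered"} (detection-filtered universe,
#'   default) or \code{"all"} (whole annotation universe).
#' @param seed integer seed for every stochastic stage.
#' @return A \code{cascade_config} list.
#' @export
cascade_config <- function(sim = NULL, input = NULL,
                           criteria1 = selection_criteria(test = "mann_whitney"),
                           criteria2 = selection_criteria(),
                           criteria3 = selection_criteria(test = "anova"),
                           combine_rule = c("union_all", "shared_by_2_of_3"),
                           anova_factors = "strain_treatment",
                           k = 2L, linkage = "average",
                           distance = "one_minus_pearson",
                           min_term_size = 2L, max_term_size = 500L,
                           go_alpha = 0.05,
                           threshold_frac = 0.85, motif_alpha = 0.05,
                           background_model = c("bg_composition", "uniform"),
                           fame_B = 1000L, fame_alpha = 0.05, fame_top = 20L,
                           family_map = NULL,
                           min_informative = 1L,
                           universe_mode = c("filtered", "all"),
                           seed = 1L) {
  combine_rule <- match.arg(combine_rule)
  background_model <- match.arg(background_model)
  universe_mode <- match.arg(universe_mode)
  chk(xor(is.null(sim), is.null(input)),
      "exactly one of sim or input must be supplied")
  if (!is.null(sim)) chk(inherits(sim, "sim_config"),
                         "sim must come from sim_config()")
  if (!is.null(input)) {
    need <- c("matrix", "samplesheet", "go", "promoters", "pwms",
              "targets", "pwm_tf_map")
    miss <- setdiff(need, names(input))
    chk(length(miss) == 0L, "input is missing paths: ",
        paste(miss, collapse = ", "))
  }
  for (a in c("go_alpha", "motif_alpha", "fame_alpha"))
    chk(is_frac(get(a)) && get(a) > 0, a, " must be in (0, 1]")
  chk(is_frac(threshold_frac) && threshold_frac > 0,
      "threshold_frac must be in (0, 1]")
  chk(is_count(fame_B) && fame_B >= 100, "fame_B must be an integer >= 100")
  structure(list(sim = sim, input = input,
                 criteria1 = criteria1, criteria2 = criteria2,
                 criteria3 = criteria3,
                 combine_rule = combine_rule, anova_factors = anova_factors,
                 k = as.integer(k), linkage = linkage, distance = distance,
                 min_term_size = min_term_size, max_term_size = max_term_size,
                 go_alpha = go_alpha, threshold_frac = threshold_frac,
                 motif_alpha = motif_alpha, background_model = background_model,
                 fame_B = as.integer(fame_B), fame_alpha = fame_alpha,
                 fame_top = as.integer(fame_top), family_map = family_map,
                 min_informative = as.integer(min_informative),
                 universe_mode = universe_mode, seed = as.integer(seed)),
            class = "cascade_config")
}

load_cascade_inputs <- function(config) {
  if (!is.null(config$sim)) {
    ds <- simulate_dataset(config$sim)
    list(expr = ds$expr, go = ds$go, go_names = ds$go_names,
         promoters = ds$promoters, pwms = ds$pwms,
         pwm_tf_map = ds$pwm_tf_map, targets = ds$targets, truth = ds$truth)
  } else {
    inp <- config$input
    expr <- read_expression(inp$matrix, inp$samplesheet,
                            flags_path = inp$flags %||% NULL)
    # raw term -> gene sets; the universe is applied at the enrichment stage
    raw_sets <- if (grepl("\\.gmt$", inp$go, ignore.case = TRUE)) {
      lines <- readLines(inp$go)
      parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
      stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                      vapply(parts, `[`, character(1), 1L))
    } else {
      tab <- read_tsv(inp$go)
      chk(all(c("gene", "term") %in% names(tab)),
          "gene-term TSV needs columns 'gene' and 'term'")
      split(as.character(tab$gene), as.character(tab$term))
    }
    list(expr = expr, go = raw_sets, go_names = NULL,
         promoters = read_promoters(inp$promoters),
         pwms = read_jaspar(inp$pwms),
         pwm_tf_map = read_tsv(inp$pwm_tf_map),
         targets = read_target_tables(inp$targets),
         truth = NULL)
  }
}

subset_genes <- function(m, genes) {
  m$values <- m$values[genes, , drop = FALSE]
  m$flags <- m$flags[genes, , drop = FALSE]
  m
}

#' Run the knowledge-based enrichment cascade
#'
#' Executes normalize -> flag filter -> dual-criteria DE selection -> list
#' combination -> hierarchical clustering -> per-cluster GO enrichment ->
#' per-cluster promoter motif enrichment -> PWM-to-TF mapping -> miRNA target
#' aggregation -> empirical functional enrichment -> candidate annotation.
#' Empty intermediate sets terminate the cascade with a structured status
#' rather than an error; stage errors abort naming the stage. Identical
#' config + seed reproduces identical results.
#'
#' @param config a \code{\link{cascade_config}}.
#' @param out_dir optional directory; if given, all stage tables are written
#'   there via \code{\link{write_cascade}}.
#' @param dry_run if TRUE, only validates the configuration and input schemas
#'   and returns the provenance stub without computing.
#' @return A \code{cascade_run} object; see \code{summary.cascade_run}.
#' @export
run_cascade <- function(config, out_dir = NULL, dry_run = FALSE) {
  chk(inherits(config, "cascade_config"), "config must come from cascade_config()")
  prov <- list()
  note_stage <- function(stage, n_in, n_out, note = "") {
    prov[[length(prov) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, note = note)
    if (n_in > n_out && nzchar(note) == 0L)
      prov[[length(prov)]]$note <<- sprintf("dropped %d", n_in - n_out)
  }
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE))
  }
  finish <- function(status, terminated_at = NULL, ...) {
    out <- structure(
      c(list(status = status, terminated_at = terminated_at,
             provenance = do.call(rbind, prov), config = config),
        list(...)),
      class = "cascade_run")
    if (!is.null(out_dir)) write_cascade(out, out_dir)
    out
  }

  if (!is.null(config$input)) {
    miss <- Filter(function(p) !is.null(p) && !file.exists(p), config$input)
    chk(length(miss) == 0L, "missing input files: ",
        paste(unlist(miss), collapse = ", "))
  }
  if (dry_run) {
    note_stage("dry_run", 0L, 0L, "config and input schema validated")
    return(finish("dry_run"))
  }

  set.seed(config$seed)
  dat <- run("load_inputs", load_cascade_inputs(config))
  n0 <- nrow(dat$expr$values)
  note_stage("load_inputs", n0, n0)

  norm <- run("normalize", percentile_shift(dat$expr))
  note_stage("normalize", n0, n0)

  universe <- run("flag_filter",
                  flag_filter(dat$expr, config$min_informative))
  note_stage("flag_filter", n0, length(universe))
  if (length(universe) == 0L)
    return(finish("terminated", "flag_filter", norm_report = norm$report))

  m_f <- subset_genes(norm$matrix, universe)
  de <- run("differential_expression",
            select_de_genes(m_f, config$criteria1, config$criteria2,
                            config$criteria3,
                            anova_factors = config$anova_factors))
  venn <- combine_lists(de$lists$list1, de$lists$list2, de$lists$list3,
                        rule = config$combine_rule)
  combined <- venn$combined_set
  note_stage("differential_expression", length(universe), length(combined),
             sprintf("lists %d/%d/%d, rule %s",
                     length(de$lists$list1), length(de$lists$list2),
                     length(de$lists$list3), venn$rule))
  if (length(combined) < max(config$k, 2L))
    return(finish("terminated", "differential_expression",
                  norm_report = norm$report, universe = universe,
                  de = de, venn = venn))

  clusters <- run("clustering",
                  hierarchical_cluster(m_f, combined, linkage = config$linkage,
                                       distance = config$distance,
                                       k = config$k))
  note_stage("clustering", length(combined), length(combined),
             paste("sizes", paste(table(clusters$assignment), collapse = "/")))

  go_universe <- if (config$universe_mode == "filtered")
    universe else unique(unlist(list(names(dat$promoters), universe,
                                     rownames(dat$expr$values))))
  ann <- run("go_annotation",
             suppressWarnings(go_annotation(dat$go, go_universe,
                                            dat$go_names)))
  cluster_sets <- split(names(clusters$assignment), clusters$assignment)
  go_res <- run("go_enrichment", lapply(cluster_sets, function(g) {
    g <- intersect(g, ann$universe)
    if (length(g) == 0L) return(NULL)
    suppressWarnings(go_enrich(g, ann, config$min_term_size,
                               config$max_term_size))
  }))
  n_sig_go <- sum(vapply(go_res, function(r)
    if (is.null(r)) 0L else sum(r$p_adj < config$go_alpha), integer(1)))
  note_stage("go_enrichment", length(cluster_sets), n_sig_go,
             sprintf("%d terms below alpha across clusters", n_sig_go))

  bg_genes <- intersect(universe, names(dat$promoters))
  bg_freq <- if (config$background_model == "uniform")
    rep(0.25, 4) else NULL
  hits <- run("motif_scan",
              motif_hits(dat$promoters[bg_genes], dat$pwms,
                         background = bg_freq,
                         threshold_frac = config$threshold_frac))
  motif_res <- run("motif_enrichment", lapply(cluster_sets, function(g) {
    g <- intersect(g, bg_genes)
    if (length(g) == 0L) return(NULL)
    motif_enrichment(g, bg_genes, dat$promoters, dat$pwms,
                     threshold_frac = config$threshold_frac, hits = hits)
  }))
  enriched_pwms <- sort(unique(unlist(lapply(motif_res, function(r) {
    if (is.null(r)) character(0) else r$pwm[r$p_adj < config$motif_alpha]
  }))))
  note_stage("motif_enrichment", length(dat$pwms), length(enriched_pwms))
  common <- list(norm_report = norm$report, universe = universe, de = de,
                 venn = venn, clusters = clusters, go = go_res,
                 motif = motif_res, truth = dat$truth)
  if (length(enriched_pwms) == 0L)
    return(do.call(finish, c(list("terminated", "motif_enrichment"), common)))

  map <- dat$pwm_tf_map
  chk(all(c("pwm", "tf_gene") %in% names(map)),
      "[stage tf_mapping] pwm_tf_map needs columns pwm, tf_gene")
  enriched_tfs <- sort(unique(map$tf_gene[map$pwm %in% enriched_pwms]))
  note_stage("tf_mapping", length(enriched_pwms), length(enriched_tfs))
  if (length(enriched_tfs) == 0L)
    return(do.call(finish, c(list("terminated", "tf_mapping"), common)))

  ranking <- run("target_aggregation",
                 aggregate_targets(enriched_tfs, dat$targets,
                                   family_map = config$family_map))
  note_stage("target_aggregation", attr(ranking, "n_candidates"),
             nrow(ranking),
             sprintf("%d zero-count candidates excluded", attr(ranking, "n_zero")))
  if (nrow(ranking) == 0L)
    return(do.call(finish, c(list("terminated", "target_aggregation"),
                             common, list(enriched_pwms = enriched_pwms,
                                          enriched_tfs = enriched_tfs))))

  tf_in_univ <- intersect(enriched_tfs, ann$universe)
  tf_go <- if (length(tf_in_univ) > 0L)
    suppressWarnings(go_enrich(tf_in_univ, ann, config$min_term_size,
                               config$max_term_size)) else NULL
  fame_terms <- if (is.null(tf_go)) character(0) else
    utils::head(tf_go$term[tf_go$p_adj < config$go_alpha], 10L)
  fame <- NULL
  if (length(fame_terms) > 0L) {
    top_mirnas <- utils::head(ranking$mirna, config$fame_top)
    pairs <- expand.grid(mirna = top_mirnas, term = fame_terms,
                         stringsAsFactors = FALSE)
    fame <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      m <- pairs$mirna[i]; tid <- pairs$term[i]
      tgt <- intersect(unique(dat$targets$gene[dat$targets$mirna == m]),
                       ann$universe)
      r <- fame_empirical_p(tgt, ann$term_genes[[tid]], ann$universe,
                            B = config$fame_B,
                            seed = derive_seed(config$seed, 1000L + i))
      data.frame(mirna = m, term = tid,
                 name = if (!is.null(ann$term_names))
                   unname(ann$term_names[tid]) else tid,
                 observed = r$observed, p = r$p)
    }))
  }
  note_stage("fame", nrow(ranking) * max(length(fame_terms), 0L),
             if (is.null(fame)) 0L else nrow(fame),
             if (length(fame_terms) == 0L)
               "no enriched TF terms; empirical enrichment skipped" else "")

  report <- run("annotate",
                annotate_candidates(ranking, fame,
                                    p_threshold = config$fame_alpha))
  note_stage("annotate", nrow(ranking), nrow(report))
  do.call(finish, c(list("complete", NULL), common,
                    list(enriched_pwms = enriched_pwms,
                         enriched_tfs = enriched_tfs, tf_go = tf_go,
                         ranking = ranking, fame = fame, report = report)))
}

#' @export
print.cascade_run <- function(x, ...) {
  cat("cascade_run:", x$status,
      if (!is.null(x$terminated_at)) paste0("(at stage ", x$terminated_at, ")"),
      "\n")
  print(x$provenance, row.names = FALSE)
  if (!is.null(x$report) && nrow(x$report) > 0L) {
    cat("\ntop candidate miRNAs:\n")
    print(utils::head(x$report[, c("mirna", "sum", "rank", "significant_term")],
                      5L), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.cascade_run <- function(object, ...) {
  out <- list(status = object$status,
              terminated_at = object$terminated_at,
              provenance = object$provenance,
              n_universe = length(object$universe),
              n_combined = length(object$venn$combined_set %||% character(0)),
              enriched_pwms = object$enriched_pwms,
              enriched_tfs = object$enriched_tfs,
              top_mirna = if (!is.null(object$report) && nrow(object$report))
                object$report$mirna[1L] else NA_character_)
  class(out) <- "summary.cascade_run"
  out
}

#' @export
print.summary.cascade_run <- function(x, ...) {
  cat("cascade status:", x$status, "\n")
  if (!is.null(x$terminated_at)) cat("terminated at:", x$terminated_at, "\n")
  cat("analysis universe:", x$n_universe, "genes; combined DE set:",
      x$n_combined, "genes\n")
  cat("enriched PWMs:", paste(x$enriched_pwms, collapse = ", "), "\n")
  cat("enriched TF genes:", paste(x$enriched_tfs, collapse = ", "), "\n")
  cat("top-ranked candidate miRNA:", x$top_mirna, "\n")
  invisible(x)
}

#' Barplot of candidate miRNA target sums
#' @param x a \code{cascade_run} with a ranking.
#' @param top number of top candidates shown.
#' @param ... passed to \code{barplot}.
#' @export
plot.cascade_run <- function(x, top = 10L, ...) {
  chk(!is.null(x$report) && nrow(x$report) > 0L,
      "no candidate ranking to plot")
  r <- utils::head(x$report, top)
  graphics::barplot(stats::setNames(r$sum, r$mirna), las = 2,
                    ylab = "summed target count over enriched TFs", ...)
  invisible(x)
}

#' Write all cascade stage outputs to a directory
#'
#' Emits per-stage TSVs, the Venn JSON and a summary JSON. Output is
#' deterministic: identical config + seed gives byte-identical files.
#'
#' @param run a \code{cascade_run}.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_cascade <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(run$provenance, file.path(dir, "provenance.tsv"))
  if (!is.null(run$universe))
    writeLines(run$universe, file.path(dir, "universe.txt"))
  if (!is.null(run$de)) {
    for (nm in names(run$de$tables))
      write_tsv(run$de$tables[[nm]], file.path(dir, paste0("de_", nm, ".tsv")))
    jsonlite::write_json(
      list(region_counts = as.list(run$venn$region_counts),
           rule = run$venn$rule, combined_set = run$venn$combined_set),
      file.path(dir, "venn.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(run$clusters))
    write_tsv(data.frame(gene = names(run$clusters$assignment),
                         cluster = unname(run$clusters$assignment)),
              file.path(dir, "clusters.tsv"))
  for (part in c("go", "motif")) {
    res <- run[[part]]
    if (is.null(res)) next
    for (nm in names(res)) {
      if (is.null(res[[nm]])) next
      write_tsv(res[[nm]], file.path(dir, sprintf("%s_cluster%s.tsv", part, nm)))
    }
  }
  if (!is.null(run$enriched_tfs))
    writeLines(run$enriched_tfs, file.path(dir, "enriched_tfs.txt"))
  if (!is.null(run$report))
    write_tsv(run$report, file.path(dir, "mirna_report.tsv"))
  if (!is.null(run$fame))
    write_tsv(run$fame, file.path(dir, "fame_pairs.tsv"))
  jsonlite::write_json(
    list(status = run$status, terminated_at = run$terminated_at,
         seed = run$config$seed,
         top_mirna = if (!is.null(run$report) && nrow(run$report))
           run$report$mirna[1L] else NULL),
    file.path(dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
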