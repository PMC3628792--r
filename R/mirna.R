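#' Read miRNA target-prediction tables
#'
#' A single TSV with columns \code{algorithm}, \code{mirna}, \code{gene},
#' holding the predictions of one or more algorithms.
#'
#' @param path input TSV.
#' @return data.frame with those three character columns.
#' @export
read_target_tables <- function(path) {
  chk(file.exists(path), "no such file: ", path)
  tab <- read_tsv(path, colClasses = "character")
  chk(all(c("algorithm", "mirna", "gene") %in% names(tab)),
      "target table needs columns algorithm, mirna, gene")
  tab[, c("algorithm", "mirna", "gene")]
}

#' Aggregate target predictions over an enriched TF set and rank miRNAs
#'
#' For every miRNA and prediction algorithm, counts the predicted targets
#' falling inside the enriched TF gene set, sums the counts across algorithms,
#' and ranks by descending sum. Ties are broken by (1) more algorithms with a
#' nonzero count, (2) larger minimum per-algorithm count, (3) miRNA id
#' lexicographically. miRNAs with sum 0 are excluded from the report but
#' counted in the provenance attributes.
#'
#' @param enriched_tfs character vector of TF gene ids (nonempty).
#' @param tables data.frame with columns \code{algorithm}, \code{mirna},
#'   \code{gene} (one or more algorithms).
#' @param family_map optional data.frame (\code{mirna}, \code{family});
#'   when given, predictions are collapsed to the family level (union of the
#'   member miRNAs' target sets per algorithm).
#' @return data.frame with one row per reported miRNA: per-algorithm counts,
#'   \code{sum}, \code{rank} and \code{associated_tfs} (comma-joined union of
#'   per-algorithm hits). Attributes \code{n_candidates} and
#'   \code{n_zero} record the provenance counts.
#' @export
aggregate_targets <- function(enriched_tfs, tables, family_map = NULL) {
  enriched_tfs <- unique(as.character(enriched_tfs))
  chk(length(enriched_tfs) > 0L, "enriched_tfs must be nonempty")
  chk(is.data.frame(tables) &&
        all(c("algorithm", "mirna", "gene") %in% names(tables)),
      "tables needs columns algorithm, mirna, gene")
  chk(nrow(tables) > 0L, "no target predictions supplied")
  tables <- unique(tables[, c("algorithm", "mirna", "gene")])
  if (!is.null(family_map)) {
    chk(all(c("mirna", "family") %in% names(family_map)),
        "family_map needs columns mirna, family")
    idx <- match(tables$mirna, family_map$mirna)
    tables$mirna <- ifelse(is.na(idx), tables$mirna, family_map$family[idx])
    tables <- unique(tables)
  }
  algos <- sort(unique(tables$algorithm))
  mirnas <- sort(unique(tables$mirna))
  hit <- tables[tables$gene %in% enriched_tfs, , drop = FALSE]
  counts <- matrix(0L, length(mirnas), length(algos),
                   dimnames = list(mirnas, algos))
  if (nrow(hit) > 0L) {
    tab <- table(factor(hit$mirna, levels = mirnas),
                 factor(hit$algorithm, levels = algos))
    counts[] <- as.integer(tab)
  }
  assoc <- vapply(mirnas, function(m) {
    paste(sort(unique(hit$gene[hit$mirna == m])), collapse = ",")
  }, character(1))
  sums <- rowSums(counts)
  nz <- rowSums(counts > 0L)
  mins <- apply(counts, 1L, min)
  ord <- order(-sums, -nz, -mins, mirnas)
  keep <- ord[sums[ord] > 0L]
  out <- data.frame(mirna = mirnas[keep], counts[keep, , drop = FALSE],
                    sum = as.integer(sums[keep]),
                    rank = seq_along(keep),
                    associated_tfs = assoc[keep],
                    row.names = NULL, check.names = FALSE)
  attr(out, "n_candidates") <- length(mirnas)
  attr(out, "n_zero") <- sum(sums == 0L)
  attr(out, "algorithms") <- algos
  out
}

#' Empirical functional-enrichment p-value for a miRNA target set
#'
#' Tests whether a miRNA's predicted target set overlaps a functional (GO)
#' gene group more than expected for a random gene set of the same size drawn
#' uniformly without replacement from the universe. The add-one empirical
#' p-value is \code{(1 + #(resample overlap >= observed)) / (1 + B)}.
#'
#' @param targets character vector of predicted target gene ids (subset of
#'   the universe).
#' @param term_genes character vector; the functional gene group.
#' @param universe character vector of gene ids.
#' @param B number of resamples (>= 100).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A list: \code{observed}, \code{p}, \code{B}, \code{seed}.
#' @export
fame_empirical_p <- function(targets, term_genes, universe, B = 1000L, seed) {
  universe <- unique(as.character(universe))
  targets <- unique(as.character(targets))
  term_genes <- unique(as.character(term_genes))
  chk(all(targets %in% universe), "targets must lie in the universe")
  chk(all(term_genes %in% universe), "term_genes must lie in the universe")
  chk(length(targets) <= length(universe), "more targets than universe genes")
  chk(is_count(B) && B >= 100, "B must be an integer >= 100")
  observed <- length(intersect(targets, term_genes))
  n_t <- length(targets)
  in_term <- universe %in% term_genes
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n_univ <- length(universe)
  ge <- 0L
  for (b in seq_len(B)) {
    ov <- sum(in_term[sample.int(n_univ, n_t)])
    if (ov >= observed) ge <- ge + 1L
  }
  list(observed = observed, p = (1 + ge) / (1 + B), B = as.integer(B),
       seed = as.integer(seed))
}

#' Annotate top-ranked candidate miRNAs with significant functional terms
#'
#' Joins the target-aggregation ranking with empirical functional-enrichment
#' results: per (miRNA, term) pair the empirical p-values are BH-adjusted
#' across all tested pairs and the best significant term (if any) is attached
#' to the miRNA's row; miRNAs without a significant term show "-".
#'
#' @param records ranking from \code{\link{aggregate_targets}}.
#' @param fame data.frame with columns \code{mirna}, \code{term},
#'   \code{name} (optional), \code{observed}, \code{p} -- one row per tested
#'   pair; may have zero rows.
#' @param p_threshold significance threshold on the BH-adjusted empirical p.
#' @return \code{records} with added columns \code{significant_term},
#'   \code{term_p} and the full adjusted pair table as attribute
#'   \code{"fame_pairs"}.
#' @export
annotate_candidates <- function(records, fame, p_threshold = 0.05) {
  chk(is.data.frame(records) && "mirna" %in% names(records),
      "records must come from aggregate_targets")
  records$significant_term <- "-"
  records$term_p <- NA_real_
  if (!is.null(fame) && nrow(fame) > 0L) {
    chk(all(c("mirna", "term", "p") %in% names(fame)),
        "fame needs columns mirna, term, p")
    fame$p_adj <- bh_adjust(fame$p)
    sig <- fame[fame$p_adj < p_threshold, , drop = FALSE]
    sig <- sig[order(sig$p_adj, sig$p), , drop = FALSE]
    first <- sig[!duplicated(sig$mirna), , drop = FALSE]
    idx <- match(records$mirna, first$mirna)
    hit <- !is.na(idx)
    lab <- if ("name" %in% names(first)) first$name else first$term
    records$significant_term[hit] <- lab[idx[hit]]
    records$term_p[hit] <- first$p[idx[hit]]
  } else {
    fame <- data.frame(mirna = character(), term = character(),
                       p = numeric(), p_adj = numeric())
  }
  attr(records, "fame_pairs") <- fame
  records
}
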