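#' Hypergeometric upper-tail over-representation p-value
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n): the probability
#' of drawing at least k annotated genes when n genes are drawn without
#' replacement from a universe of N genes of which K carry the annotation.
#'
#' @param k overlap count.
#' @param n query-set size.
#' @param K annotated-set size in the universe.
#' @param N universe size.
#' @return Upper-tail probability; \code{P(X >= 0) = 1}.
#' @export
hypergeometric_p <- function(k, n, K, N) {
  chk(all(k >= 0), "k must be nonnegative")
  chk(all(n <= N) && all(K <= N), "n and K cannot exceed N")
  chk(all(k <= pmin(n, K)), "k cannot exceed min(n, K)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Construct a GO annotation object
#'
#' Flat term -> gene-set annotation with a declared universe. Annotated genes
#' outside the universe are dropped with a warning (the invariant is that
#' annotations are a subset of the universe). No ontology-graph propagation is
#' performed: annotations are taken as given flat sets.
#'
#' @param term_genes named list of character vectors (term id -> gene ids).
#' @param universe character vector of gene ids.
#' @param term_names optional named character vector of human-readable names.
#' @return A \code{go_annotation} object.
#' @export
go_annotation <- function(term_genes, universe, term_names = NULL) {
  chk(is.list(term_genes) && !is.null(names(term_genes)),
      "term_genes must be a named list")
  dup <- names(term_genes)[duplicated(names(term_genes))]
  chk(length(dup) == 0L, "duplicate term ids: ", paste(unique(dup), collapse = ", "))
  universe <- unique(as.character(universe))
  n_out <- sum(vapply(term_genes, function(g) sum(!(g %in% universe)), numeric(1)))
  if (n_out > 0)
    warning(n_out, " annotated gene entries outside the universe were dropped")
  term_genes <- lapply(term_genes, function(g) unique(intersect(g, universe)))
  structure(list(term_genes = term_genes, universe = universe,
                 term_names = term_names),
            class = "go_annotation")
}

#' Read a gene -> term map (two-column TSV) or a GMT file
#'
#' @param path input file. TSV must have columns \code{gene} and \code{term};
#'   GMT is the usual tab-separated one-set-per-line format (set id,
#'   description, members).
#' @param universe declared gene universe.
#' @param format \code{"tsv"} or \code{"gmt"} (guessed from the extension by
#'   default).
#' @return A \code{\link{go_annotation}}.
#' @export
read_gene_sets <- function(path, universe, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  chk(file.exists(path), "no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  if (format == "tsv") {
    tab <- read_tsv(path)
    chk(all(c("gene", "term") %in% names(tab)),
        "gene-term TSV needs columns 'gene' and 'term'")
    term_genes <- split(as.character(tab$gene), as.character(tab$term))
    term_names <- NULL
  } else {
    lines <- readLines(path)
    parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
    term_genes <- lapply(parts, function(p) p[-(1:2)])
    names(term_genes) <- vapply(parts, `[`, character(1), 1L)
    term_names <- stats::setNames(vapply(parts, `[`, character(1), 2L),
                                  names(term_genes))
  }
  go_annotation(term_genes, universe, term_names)
}

#' Write a GO annotation as a gene-term TSV and a GMT file
#'
#' @param ann a \code{\link{go_annotation}}.
#' @param tsv_path,gmt_path output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
write_gene_sets <- function(ann, tsv_path = NULL, gmt_path = NULL) {
  if (!is.null(tsv_path)) {
    df <- data.frame(
      gene = unlist(ann$term_genes, use.names = FALSE),
      term = rep(names(ann$term_genes), lengths(ann$term_genes))
    )
    write_tsv(df, tsv_path)
  }
  if (!is.null(gmt_path)) {
    nm <- ann$term_names %||% stats::setNames(names(ann$term_genes),
                                              names(ann$term_genes))
    lines <- vapply(names(ann$term_genes), function(tid) {
      paste(c(tid, unname(nm[tid]), ann$term_genes[[tid]]), collapse = "\t")
    }, character(1))
    writeLines(lines, gmt_path)
  }
  invisible(c(tsv = tsv_path, gmt = gmt_path))
}

#' GO term over-representation in a gene set
#'
#' Model-free categorical over-representation: for every term within the size
#' bounds, the overlap with the query is scored by the hypergeometric upper
#' tail against the annotation's universe, with BH correction across exactly
#' the tested terms.
#'
#' @param query character vector of gene ids; members outside the universe are
#'   dropped with a warning.
#' @param ann a \code{\link{go_annotation}}.
#' @param min_term_size,max_term_size size bounds on tested terms (defaults
#'   2 and 500; degenerate and uninformative terms inflate the BH family).
#' @return data.frame with one row per tested term (\code{term}, \code{name},
#'   \code{k}, \code{n}, \code{K}, \code{N}, \code{p}, \code{p_adj},
#'   \code{genes}), sorted by \code{p_adj} then \code{p}.
#' @export
go_enrich <- function(query, ann, min_term_size = 2L, max_term_size = 500L) {
  chk(inherits(ann, "go_annotation"), "ann must be a go_annotation")
  query <- unique(as.character(query))
  n_drop <- sum(!(query %in% ann$universe))
  if (n_drop > 0)
    warning(n_drop, " query genes outside the universe were dropped")
  query <- intersect(query, ann$universe)
  chk(length(query) > 0L, "query is empty after intersecting with the universe")
  sizes <- lengths(ann$term_genes)
  keep <- sizes >= min_term_size & sizes <= max_term_size
  terms <- names(ann$term_genes)[keep]
  if (length(terms) == 0L)
    return(data.frame(term = character(), name = character(), k = integer(),
                      n = integer(), K = integer(), N = integer(),
                      p = numeric(), p_adj = numeric(), genes = character()))
  N <- length(ann$universe)
  n <- length(query)
  K <- sizes[keep]
  ov <- lapply(ann$term_genes[keep], intersect, query)
  k <- lengths(ov)
  p <- hypergeometric_p(k, n, K, N)
  p_adj <- bh_adjust(p)
  nm <- if (!is.null(ann$term_names)) unname(ann$term_names[terms]) else terms
  out <- data.frame(term = terms, name = nm, k = as.integer(k),
                    n = n, K = as.integer(K), N = N, p = p, p_adj = p_adj,
                    genes = vapply(ov, paste, character(1), collapse = ","),
                    row.names = NULL)
  out[order(out$p_adj, out$p, out$term), , drop = FALSE]
}
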