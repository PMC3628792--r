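#' Construct an expression matrix object
#'
#' Container for a genes x samples intensity matrix together with per-probe
#' detection flags (P/M/A) and the sample design sheet (strain, treatment,
#' duration). All downstream stages of the cascade consume this object.
#'
#' @param values numeric genes x samples matrix with gene ids as rownames and
#'   sample ids as colnames.
#' @param flags character matrix of the same shape with entries in
#'   \code{c("P","M","A")}; if \code{NULL}, all probes are treated as present
#'   (with a warning).
#' @param design data.frame with one row per sample and columns
#'   \code{sample_id}, \code{strain}, \code{treatment} (control/LPS) and
#'   \code{duration}.
#' @param scale either \code{"raw"} (positive intensities) or
#'   \code{"log2_normalized"}.
#' @return An object of class \code{expr_matrix}.
#' @export
expr_matrix <- function(values, flags = NULL, design, scale = c("raw", "log2_normalized")) {
  scale <- match.arg(scale)
  chk(is.matrix(values) && is.numeric(values), "values must be a numeric matrix")
  chk(!is.null(rownames(values)), "values must carry gene ids as rownames")
  chk(!is.null(colnames(values)), "values must carry sample ids as colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  chk(length(dup) == 0L, "duplicate gene ids: ", paste(unique(dup), collapse = ", "))
  chk(all(is.finite(values)), "values must be finite")
  if (is.null(flags)) {
    warning("no detection flags supplied; defaulting all flags to P")
    flags <- matrix("P", nrow(values), ncol(values), dimnames = dimnames(values))
  }
  chk(identical(dim(flags), dim(values)), "flags must have the same shape as values")
  chk(all(flags %in% c("P", "M", "A")), "flags must be P, M or A")
  dimnames(flags) <- dimnames(values)
  chk(is.data.frame(design), "design must be a data.frame")
  need <- c("sample_id", "strain", "treatment", "duration")
  miss <- setdiff(need, names(design))
  chk(length(miss) == 0L, "design is missing columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(colnames(values), design$sample_id)
  chk(length(extra) == 0L,
      "samples missing from the design sheet: ", paste(extra, collapse = ", "))
  unknown <- setdiff(design$sample_id, colnames(values))
  chk(length(unknown) == 0L,
      "design rows with no matching sample column: ", paste(unknown, collapse = ", "))
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(
    list(values = values, flags = flags, design = design, scale = scale),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("design factors: strain {", paste(unique(x$design$strain), collapse = ", "),
      "}, treatment {", paste(unique(x$design$treatment), collapse = ", "),
      "}, duration {", paste(unique(x$design$duration), collapse = ", "), "}\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix, flags and sample sheet from TSV files
#'
#' The matrix file has the gene id in the first column and one column per
#' sample; the optional flags file has the same layout with P/M/A entries; the
#' sample sheet has columns \code{sample_id}, \code{strain}, \code{treatment},
#' \code{duration}.
#'
#' @param matrix_path path to the intensity TSV.
#' @param samplesheet_path path to the sample sheet TSV.
#' @param flags_path optional path to the flags TSV; if missing, flags default
#'   to P with a warning.
#' @param scale scale of the stored values ("raw" by default).
#' @return An \code{\link{expr_matrix}} object.
#' @export
read_expression <- function(matrix_path, samplesheet_path, flags_path = NULL,
                            scale = "raw") {
  chk(file.exists(matrix_path), "no such file: ", matrix_path)
  chk(file.exists(samplesheet_path), "no such file: ", samplesheet_path)
  tab <- read_tsv(matrix_path)
  gene <- as.character(tab[[1L]])
  vals <- tab[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  chk(!any(bad), "non-numeric matrix columns: ",
      paste(names(vals)[bad], collapse = ", "))
  values <- as.matrix(vals)
  rownames(values) <- gene
  design <- read_tsv(samplesheet_path)
  flags <- NULL
  if (!is.null(flags_path)) {
    chk(file.exists(flags_path), "no such file: ", flags_path)
    ftab <- read_tsv(flags_path, colClasses = "character")
    flags <- as.matrix(ftab[, -1L, drop = FALSE])
    rownames(flags) <- as.character(ftab[[1L]])
    chk(identical(rownames(flags), gene), "flags file gene order differs from matrix")
    flags <- flags[, colnames(values), drop = FALSE]
  }
  expr_matrix(values, flags, design, scale = scale)
}

#' Write an expression matrix, flags and sample sheet to a directory
#'
#' @param m an \code{\link{expr_matrix}}.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return Invisibly, the paths written.
#' @export
write_expression <- function(m, dir, prefix = "expression") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mp <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  fp <- file.path(dir, paste0(prefix, "_flags.tsv"))
  sp <- file.path(dir, paste0(prefix, "_samples.tsv"))
  write_tsv(data.frame(gene_id = rownames(m$values), m$values, check.names = FALSE), mp)
  write_tsv(data.frame(gene_id = rownames(m$flags), m$flags, check.names = FALSE), fp)
  write_tsv(m$design, sp)
  invisible(c(matrix = mp, flags = fp, samples = sp))
}

#' Percentile-shift normalization
#'
#' Log2-transforms raw intensities, centres each sample at its 75th
#' percentile, then centres each gene at its median across all samples. The
#' "divide by" convention of array percentile-shift processing is applied on
#' the raw scale, i.e. as subtraction after the log2 transform. The percentile
#' uses linear interpolation between order statistics (type 7), recorded in
#' the report.
#'
#' @param m a raw-scale \code{\link{expr_matrix}} with strictly positive values.
#' @return A list with the normalized \code{expr_matrix} (log2 scale) and a
#'   \code{report} carrying the per-sample 75th percentiles, per-gene medians
#'   and the quantile convention used.
#' @export
percentile_shift <- function(m) {
  chk(inherits(m, "expr_matrix"), "m must be an expr_matrix")
  chk(identical(m$scale, "raw"), "percentile_shift expects a raw-scale matrix")
  chk(all(m$values > 0), "raw intensities must be strictly positive (log2 undefined)")
  lg <- log2(m$values)
  p75 <- apply(lg, 2L, stats::quantile, probs = 0.75, names = FALSE, type = 7)
  lg <- sweep(lg, 2L, p75, "-")
  med <- apply(lg, 1L, stats::median)
  lg <- sweep(lg, 1L, med, "-")
  out <- m
  out$values <- lg
  out$scale <- "log2_normalized"
  report <- list(per_sample_p75 = stats::setNames(p75, colnames(m$values)),
                 per_gene_median = stats::setNames(med, rownames(m$values)),
                 quantile_type = 7L,
                 scale_before = "raw", scale_after = "log2_normalized")
  list(matrix = out, report = report)
}

#' Detection-flag filter
#'
#' Returns the genes carrying at least \code{min_informative} present (P) or
#' marginal (M) flags across all samples. This set is the default analysis
#' universe of the cascade.
#'
#' @param m an \code{\link{expr_matrix}} with populated flags.
#' @param min_informative minimum number of P/M flags required (default 1).
#' @return Character vector of gene ids.
#' @export
flag_filter <- function(m, min_informative = 1L) {
  chk(inherits(m, "expr_matrix"), "m must be an expr_matrix")
  chk(is_count(min_informative), "min_informative must be a positive integer")
  chk(min_informative <= ncol(m$values),
      "min_informative (", min_informative, ") exceeds the sample count (",
      ncol(m$values), ")")
  n_inf <- rowSums(m$flags == "P" | m$flags == "M")
  rownames(m$values)[n_inf >= min_informative]
}
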