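DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' A 4 x L matrix of per-position base probabilities over A, C, G, T. Count
#' matrices (column sums > 1) are converted to probabilities after adding the
#' pseudocount to every cell; probability matrices are re-regularized with the
#' pseudocount so no cell is exactly zero.
#'
#' @param mat 4 x L numeric matrix (rows A, C, G, T) of counts or
#'   probabilities.
#' @param id motif accession (e.g. a TRANSFAC-style id such as M00515).
#' @param tf_name transcription-factor name.
#' @param pseudocount regularization constant (default 0.01).
#' @return A \code{pwm} object.
#' @export
pwm <- function(mat, id, tf_name = id, pseudocount = 0.01) {
  chk(is.matrix(mat) && nrow(mat) == 4L, "mat must be a 4 x L matrix")
  chk(ncol(mat) >= 4L, "motif length must be >= 4")
  chk(all(mat >= 0), "matrix entries must be nonnegative")
  chk(pseudocount > 0, "pseudocount must be positive")
  rownames(mat) <- DNA_BASES
  cs <- colSums(mat)
  chk(all(cs > 0), "every column needs positive mass")
  # counts, or probability columns containing zeros, are regularized with the
  # pseudocount; fully positive probability matrices are kept as supplied so
  # that writing and re-reading a library is exact
  if (any(mat == 0) || any(abs(cs - 1) > 1e-6))
    mat <- mat + pseudocount
  mat <- sweep(mat, 2L, colSums(mat), "/")
  stopifnot(all(abs(colSums(mat) - 1) < 1e-9))
  structure(list(id = id, tf_name = tf_name, mat = mat,
                 pseudocount = pseudocount, length = ncol(mat)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s), length %d, consensus %s\n",
              x$id, x$tf_name, x$length, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per column)
#' @param x a \code{\link{pwm}}.
#' @return Character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$mat, 2L, which.max)], collapse = "")
}

#' Read a JASPAR-style matrix file into a PWM library
#'
#' Format: records starting with \code{>id name}, followed by four lines
#' \code{A  [ 1 2 3 ]} etc. (brackets optional).
#'
#' @param path input file.
#' @param pseudocount passed to \code{\link{pwm}}.
#' @return Named list of \code{pwm} objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.01) {
  chk(file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  starts <- grep("^>", lines)
  chk(length(starts) > 0L, "no JASPAR records ('>' headers) in ", path)
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    id <- toks[1]
    tf <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else id
    block <- lines[(starts[i] + 1L):(starts[i] + 4L)]
    rows <- lapply(block, function(l) {
      l <- gsub("[][]", " ", l)
      v <- strsplit(trimws(l), "\\s+")[[1]]
      list(base = v[1], vals = as.numeric(v[-1]))
    })
    bases <- vapply(rows, function(r) r$base, character(1))
    chk(setequal(bases, DNA_BASES), "malformed JASPAR record ", id)
    mat <- do.call(rbind, lapply(DNA_BASES, function(b) {
      rows[[which(bases == b)]]$vals
    }))
    out[[id]] <- pwm(mat, id = id, tf_name = tf, pseudocount = pseudocount)
  }
  out
}

#' Write a PWM library as a JASPAR-style matrix file
#'
#' Writes the probability matrices (after pseudocount regularization).
#'
#' @param pwms named list of \code{pwm} objects.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_jaspar <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    c(sprintf(">%s %s", p$id, p$tf_name),
      vapply(DNA_BASES, function(b) {
        sprintf("%s [ %s ]", b, paste(formatC(p$mat[b, ], format = "g",
                                              digits = 8), collapse = " "))
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read TRANSFAC-style count matrices into a PWM library
#'
#' Minimal parser for the classic flat format: \code{ID}/\code{NA} lines name
#' the motif and factor, \code{P0 A C G T} heads the matrix, numbered rows give
#' per-position counts, \code{//} terminates a record.
#'
#' @param path input file.
#' @param pseudocount passed to \code{\link{pwm}} (counts -> probabilities).
#' @return Named list of \code{pwm} objects.
#' @export
read_transfac <- function(path, pseudocount = 0.01) {
  chk(file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  out <- list()
  id <- NULL; tf <- NULL; rows <- list(); col_order <- NULL
  flush <- function() {
    if (is.null(id) || length(rows) == 0L) return()
    mat <- t(do.call(rbind, rows))  # rows were positions x bases
    rownames(mat) <- col_order
    mat <- mat[DNA_BASES, , drop = FALSE]
    out[[id]] <<- pwm(mat, id = id, tf_name = tf %||% id,
                      pseudocount = pseudocount)
  }
  for (l in lines) {
    if (grepl("^ID\\s", l)) {
      id <- strsplit(trimws(sub("^ID", "", l)), "\\s+")[[1]][1]
    } else if (grepl("^NA\\s", l)) {
      tf <- trimws(sub("^NA", "", l))
    } else if (grepl("^P0", l)) {
      col_order <- strsplit(trimws(sub("^P0", "", l)), "\\s+")[[1]]
      chk(setequal(col_order, DNA_BASES), "malformed P0 line in ", path)
    } else if (grepl("^[0-9]+\\s", l)) {
      v <- strsplit(trimws(l), "\\s+")[[1]]
      rows[[length(rows) + 1L]] <- as.numeric(v[2:5])
    } else if (grepl("^//", l)) {
      flush()
      id <- NULL; tf <- NULL; rows <- list(); col_order <- NULL
    }
  }
  flush()
  out
}

encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
}

log_ratio_matrix <- function(p, background) {
  chk(length(background) == 4L && all(background > 0),
      "background must be 4 positive base frequencies (zero frequency ",
      "would make the log-ratio unbounded)")
  background <- background / sum(background)
  log2(p$mat / background)
}

#' Log-likelihood-ratio score of one window against a PWM
#'
#' Sum over positions of \code{log2(p[base, pos] / q[base])} for background
#' base frequencies q. The consensus sequence attains the maximal achievable
#' score.
#'
#' @param window DNA string of exactly the motif length, free of N.
#' @param pwm a \code{\link{pwm}}.
#' @param background numeric length-4 base frequencies (A, C, G, T); default
#'   uniform.
#' @return Numeric score (log2 units).
#' @export
pwm_score <- function(window, pwm, background = rep(0.25, 4)) {
  lr <- log_ratio_matrix(pwm, background)
  code <- encode_dna(window)
  chk(length(code) == pwm$length, "window length must equal the motif length")
  chk(!anyNA(code), "window contains non-ACGT characters")
  sum(lr[cbind(code, seq_along(code))])
}

#' Maximal achievable PWM score under a background model
#' @inheritParams pwm_score
#' @return Numeric scalar.
#' @export
pwm_max_score <- function(pwm, background = rep(0.25, 4)) {
  lr <- log_ratio_matrix(pwm, background)
  sum(apply(lr, 2L, max))
}

scan_codes <- function(code, lr, thr) {
  L <- ncol(lr); S <- length(code)
  W <- S - L + 1L
  if (W < 1L) return(integer(0))
  sc <- numeric(W)
  for (j in seq_len(L)) {
    sc <- sc + lr[cbind(code[j:(j + W - 1L)], j)]
  }
  list(pos = which(!is.na(sc) & sc >= thr), scores = sc)
}

#' Scan a promoter sequence for PWM hits on both strands
#'
#' A hit is any window whose log-likelihood-ratio score reaches
#' \code{threshold_frac} times the maximal achievable score of the PWM.
#' Windows containing non-ACGT characters are skipped. Minus-strand hits are
#' found by scanning the reverse complement and reported in forward
#' coordinates. Positions are 0-based offsets from the distal (5') end of the
#' stored promoter sequence.
#'
#' @param seq promoter DNA string.
#' @param pwm a \code{\link{pwm}}.
#' @param background length-4 base frequencies; default uniform.
#' @param threshold_frac fraction of the maximal achievable score in (0, 1].
#' @return data.frame with columns \code{position}, \code{strand},
#'   \code{score}; zero rows when the promoter is shorter than the motif.
#' @export
scan_promoter <- function(seq, pwm, background = rep(0.25, 4),
                          threshold_frac = 0.85) {
  chk(is_frac(threshold_frac) && threshold_frac > 0,
      "threshold_frac must be in (0, 1]")
  lr <- log_ratio_matrix(pwm, background)
  thr <- threshold_frac * pwm_max_score(pwm, background)
  code <- encode_dna(seq)
  S <- length(code); L <- pwm$length
  if (S < L)
    return(data.frame(position = integer(), strand = character(),
                      score = numeric()))
  fwd <- scan_codes(code, lr, thr)
  rc <- rev(5L - code)  # complement (A<->T, C<->G), NA preserved
  rev_ <- scan_codes(rc, lr, thr)
  pos_f <- fwd$pos - 1L
  pos_r <- S - (rev_$pos + L - 1L)  # forward-strand start of the rc window
  out <- data.frame(
    position = c(pos_f, pos_r),
    strand = c(rep("+", length(pos_f)), rep("-", length(pos_r))),
    score = c(fwd$scores[fwd$pos], rev_$scores[rev_$pos])
  )
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Base composition of a promoter set
#' @param promoters named character vector of sequences.
#' @return Length-4 frequency vector over A, C, G, T (N ignored).
#' @export
promoter_base_freq <- function(promoters) {
  counts <- integer(4)
  for (s in promoters) {
    code <- encode_dna(s)
    tab <- tabulate(code[!is.na(code)], nbins = 4L)
    counts <- counts + tab
  }
  chk(sum(counts) > 0, "no ACGT content in the promoter set")
  stats::setNames(counts / sum(counts), DNA_BASES)
}

#' Gene-level PWM hit indicators over a promoter set
#'
#' @param promoters named character vector (gene id -> sequence).
#' @param pwms named list of \code{\link{pwm}} objects.
#' @param background length-4 base frequencies or \code{NULL} to use the
#'   composition of \code{promoters}.
#' @param threshold_frac hit threshold as a fraction of the maximal score.
#' @return Logical genes x PWMs matrix: TRUE if the promoter has >= 1 hit.
#' @export
motif_hits <- function(promoters, pwms, background = NULL,
                       threshold_frac = 0.85) {
  chk(length(promoters) > 0L && !is.null(names(promoters)),
      "promoters must be a named character vector")
  background <- background %||% promoter_base_freq(promoters)
  codes <- lapply(promoters, encode_dna)
  hits <- matrix(FALSE, length(promoters), length(pwms),
                 dimnames = list(names(promoters), names(pwms)))
  for (pi in seq_along(pwms)) {
    p <- pwms[[pi]]
    lr <- log_ratio_matrix(p, background)
    thr <- threshold_frac * pwm_max_score(p, background)
    L <- p$length
    for (gi in seq_along(codes)) {
      code <- codes[[gi]]
      if (length(code) < L) next
      f <- scan_codes(code, lr, thr)
      if (length(f$pos) > 0L) { hits[gi, pi] <- TRUE; next }
      r <- scan_codes(rev(5L - code), lr, thr)
      if (length(r$pos) > 0L) hits[gi, pi] <- TRUE
    }
  }
  hits
}

#' TFBS motif enrichment of a promoter set against a background
#'
#' For each PWM, genes are scored as hit / no-hit (>= 1 match anywhere on
#' either strand); the enrichment factor is the hit frequency in the gene set
#' divided by the hit frequency in the background, and the p-value is the
#' hypergeometric upper tail of drawing \code{hits_set} hit genes in a sample
#' of \code{|set|} from a background with \code{hits_bg} hit genes, BH-
#' corrected across the PWM library. The background must contain the set.
#'
#' @param set_genes character vector of cluster gene ids.
#' @param bg_genes character vector of background gene ids (superset of
#'   \code{set_genes}).
#' @param promoters named character vector covering the background genes.
#' @param pwms named list of \code{\link{pwm}} objects.
#' @param background length-4 base frequencies or NULL for the background
#'   promoter composition.
#' @param threshold_frac hit threshold as a fraction of the maximal score.
#' @param hits optional precomputed indicator matrix from
#'   \code{\link{motif_hits}} over the background promoters.
#' @return data.frame per PWM: \code{pwm}, \code{tf_name}, \code{hits_set},
#'   \code{hits_bg}, \code{set_size}, \code{bg_size}, \code{EF}, \code{p},
#'   \code{p_adj}, sorted by ascending p. \code{EF} is \code{NA} when the
#'   background has no hits.
#' @export
motif_enrichment <- function(set_genes, bg_genes, promoters, pwms,
                             background = NULL, threshold_frac = 0.85,
                             hits = NULL) {
  set_genes <- unique(as.character(set_genes))
  bg_genes <- unique(as.character(bg_genes))
  chk(length(set_genes) > 0L, "the gene set is empty")
  chk(length(bg_genes) > 0L, "the background is empty")
  out_set <- setdiff(set_genes, bg_genes)
  chk(length(out_set) == 0L, "set genes missing from the background: ",
      paste(utils::head(out_set, 5L), collapse = ", "))
  miss <- setdiff(bg_genes, names(promoters))
  chk(length(miss) == 0L, "background genes without promoters: ",
      paste(utils::head(miss, 5L), collapse = ", "))
  if (is.null(hits)) {
    hits <- motif_hits(promoters[bg_genes], pwms, background = background,
                       threshold_frac = threshold_frac)
  } else {
    chk(all(bg_genes %in% rownames(hits)),
        "precomputed hits do not cover the background")
    hits <- hits[bg_genes, names(pwms), drop = FALSE]
  }
  n_set <- length(set_genes); n_bg <- length(bg_genes)
  hits_set <- colSums(hits[set_genes, , drop = FALSE])
  hits_bg <- colSums(hits)
  ef <- ifelse(hits_bg > 0, (hits_set / n_set) / (hits_bg / n_bg), NA_real_)
  p <- hypergeometric_p(hits_set, n_set, hits_bg, n_bg)
  p_adj <- bh_adjust(p)
  out <- data.frame(
    pwm = names(pwms),
    tf_name = vapply(pwms, function(x) x$tf_name, character(1)),
    hits_set = as.integer(hits_set), hits_bg = as.integer(hits_bg),
    set_size = n_set, bg_size = n_bg,
    EF = ef, p = p, p_adj = p_adj, row.names = NULL
  )
  out[order(out$p, out$pwm), , drop = FALSE]
}

#' Read promoter sequences from a FASTA file (header = gene id)
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_promoters <- function(path) {
  chk(file.exists(path), "no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  out
}

#' Write promoter sequences to a FASTA file
#' @param promoters named character vector.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_promoters <- function(promoters, path) {
  ss <- Biostrings::DNAStringSet(promoters)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}
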