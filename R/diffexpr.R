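#' Mann-Whitney U test (exact for small tie-free samples)
#'
#' Computes the rank-sum U statistic for the first group with midrank tie
#' handling. The p-value is exact (full enumeration of label assignments, via
#' the null U distribution) when the pooled size is at most 12 and there are
#' no ties; otherwise a normal approximation with tie-corrected variance is
#' used. The method actually used is recorded as an attribute.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param alternative only \code{"two_sided"} is supported.
#' @param contrast optional label used in error messages.
#' @return A list with \code{U}, \code{p} and \code{method}.
#' @export
mann_whitney_u <- function(group_a, group_b, alternative = "two_sided",
                           contrast = NULL) {
  lab <- if (is.null(contrast)) "" else paste0(" in contrast ", contrast)
  chk(length(group_a) >= 2 && length(group_b) >= 2,
      "each group needs at least 2 observations", lab)
  chk(identical(alternative, "two_sided"), "only the two-sided test is supported")
  n1 <- length(group_a); n2 <- length(group_b)
  x <- c(group_a, group_b)
  r <- rank(x)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(x) > 0L
  if (!ties && n1 + n2 <= 12L) {
    # exact null distribution of U over all C(n1+n2, n1) assignments
    p_lo <- stats::pwilcox(u, n1, n2)
    p_hi <- stats::pwilcox(n1 * n2 - u, n1, n2)  # P(U >= u) by symmetry
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    nn <- n1 + n2
    tie_tab <- table(x)
    sig2 <- n1 * n2 / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u - n1 * n2 / 2) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx_tie_corrected"
  }
  list(U = u, p = p, method = method)
}

#' Two-way ANOVA per-factor F tests
#'
#' Standard sums-of-squares decomposition for a (balanced) two-factor layout.
#' With replication the model includes the interaction; without replication an
#' additive model is fitted. Implemented by nested least-squares fits, which
#' for balanced designs reproduces the classical sequential decomposition.
#'
#' @param values numeric response vector (one gene) or a genes x samples
#'   matrix for a vectorized fit across genes.
#' @param f1,f2 factors of the same length as the samples (e.g. strain and
#'   treatment).
#' @param replicated logical; if \code{FALSE} the additive model is used.
#' @return For a vector response, a data.frame with one row per term
#'   (\code{term}, \code{df}, \code{sumsq}, \code{F}, \code{p}); for a matrix
#'   response, a list of per-term data.frames with one row per gene
#'   (\code{F}, \code{p}).
#' @export
two_way_anova <- function(values, f1, f2, replicated = TRUE) {
  f1 <- factor(f1); f2 <- factor(f2)
  single <- is.null(dim(values))
  Y <- if (single) matrix(values, ncol = 1L) else t(values)
  chk(nrow(Y) == length(f1) && nrow(Y) == length(f2),
      "factor length must match the number of samples")
  chk(nlevels(f1) >= 2 && nlevels(f2) >= 2, "each factor needs >= 2 levels")
  cells <- table(f1, f2)
  chk(all(cells > 0), "empty design cells: ",
      paste(which(cells == 0), collapse = ", "))
  n <- nrow(Y)
  rss <- function(form) {
    fit <- stats::lm(form, data = list(Y = Y, f1 = f1, f2 = f2))
    colSums(as.matrix(stats::residuals(fit))^2)
  }
  r_f2 <- rss(Y ~ f2)
  r_f1 <- rss(Y ~ f1)
  r_add <- rss(Y ~ f1 + f2)
  if (replicated) {
    chk(all(cells >= 2), "interaction model requires replication in every cell")
    r_full <- rss(Y ~ f1 * f2)
    df_terms <- c(nlevels(f1) - 1L, nlevels(f2) - 1L,
                  (nlevels(f1) - 1L) * (nlevels(f2) - 1L))
    df_res <- n - nlevels(f1) * nlevels(f2)
    ss <- rbind(r_f2 - r_add, r_f1 - r_add, r_add - r_full)
    terms <- c("f1", "f2", "f1:f2")
  } else {
    r_full <- r_add
    df_terms <- c(nlevels(f1) - 1L, nlevels(f2) - 1L)
    df_res <- n - (nlevels(f1) + nlevels(f2) - 1L)
    ss <- rbind(r_f2 - r_add, r_f1 - r_add)
    terms <- c("f1", "f2")
  }
  chk(df_res > 0, "zero residual degrees of freedom; supply replicates or drop terms")
  ss[ss < 0] <- 0  # numerical guard, exact zero effects
  ms_res <- r_full / df_res
  tol <- 1e-12
  out <- vector("list", length(terms))
  names(out) <- terms
  for (i in seq_along(terms)) {
    ms <- ss[i, ] / df_terms[i]
    Fv <- ifelse(ms_res > tol, ms / ms_res, ifelse(ms > tol, Inf, NaN))
    p <- ifelse(is.nan(Fv), 1,
                ifelse(is.infinite(Fv), 0,
                       stats::pf(Fv, df_terms[i], df_res, lower.tail = FALSE)))
    out[[i]] <- data.frame(F = Fv, p = p, row.names = colnames(Y) %||% NULL)
  }
  if (single) {
    data.frame(term = terms, df = df_terms,
               sumsq = as.numeric(ss[, 1L]),
               F = vapply(out, function(d) d$F[1L], numeric(1)),
               p = vapply(out, function(d) d$p[1L], numeric(1)),
               row.names = NULL)
  } else {
    attr(out, "df_residual") <- df_res
    out
  }
}

#' Raw-scale fold change between two sample groups
#'
#' Fold change is the ratio of anti-logged group means of log2-normalized
#' values (a geometric-mean ratio on the raw scale). The direction-free value
#' \code{max(r, 1/r)} is used for thresholding; the sign gives the direction.
#'
#' @param m a log2-scale \code{\link{expr_matrix}}.
#' @param group1,group2 character vectors of sample ids.
#' @return data.frame with per-gene \code{ratio} (group1/group2),
#'   \code{fc} (direction-free) and \code{direction} (+1/-1).
#' @export
fold_change <- function(m, group1, group2) {
  chk(inherits(m, "expr_matrix"), "m must be an expr_matrix")
  chk(identical(m$scale, "log2_normalized"),
      "fold_change expects log2-normalized values")
  miss <- setdiff(c(group1, group2), colnames(m$values))
  chk(length(miss) == 0L, "samples not in the matrix: ", paste(miss, collapse = ", "))
  chk(length(group1) > 0 && length(group2) > 0, "contrast groups must be nonempty")
  m1 <- rowMeans(m$values[, group1, drop = FALSE])
  m2 <- rowMeans(m$values[, group2, drop = FALSE])
  ratio <- 2^(m1 - m2)
  data.frame(gene = rownames(m$values),
             ratio = ratio,
             fc = pmax(ratio, 1 / ratio),
             direction = ifelse(ratio >= 1, 1, -1),
             row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, capped at 1, with validation of the input range.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  chk(is.numeric(p), "p must be numeric")
  chk(all(is.finite(p) & p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Selection criteria for a differential-expression list
#'
#' @param fc_threshold minimum direction-free fold change (>= 1).
#' @param p_threshold p-value threshold in (0, 1]; the cascade's stringent
#'   mode uses 0.05, the less-stringent mode the unusually permissive 0.5.
#' @param test \code{"mann_whitney"} or \code{"anova"}.
#' @param correction multiple-testing correction; only \code{"BH"}.
#' @return A \code{selection_criteria} list.
#' @export
selection_criteria <- function(fc_threshold = 1.5, p_threshold = 0.05,
                               test = c("mann_whitney", "anova"),
                               correction = "BH") {
  test <- match.arg(test)
  chk(is.numeric(fc_threshold) && fc_threshold >= 1, "fc_threshold must be >= 1")
  chk(is.numeric(p_threshold) && p_threshold > 0 && p_threshold <= 1,
      "p_threshold must be in (0, 1]")
  chk(identical(correction, "BH"), "only BH correction is supported")
  if (p_threshold > 0.25)
    message("note: permissive p threshold (", p_threshold,
            ") - less-stringent screening mode")
  structure(list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                 test = test, correction = correction),
            class = "selection_criteria")
}

sample_ids <- function(design, strain = NULL, treatment = NULL, duration = NULL) {
  keep <- rep(TRUE, nrow(design))
  if (!is.null(strain)) keep <- keep & design$strain == strain
  if (!is.null(treatment)) keep <- keep & design$treatment == treatment
  if (!is.null(duration)) keep <- keep & design$duration == duration
  design$sample_id[keep]
}

#' Dual-criteria differential-expression selection (three lists)
#'
#' Builds the cascade's three candidate gene lists from a log2-normalized
#' matrix restricted to the analysis universe:
#' \itemize{
#'   \item List 1: strain contrast under LPS at the first duration -- genes
#'     passing the Mann-Whitney rank test (BH-adjusted p below the threshold)
#'     AND the fold-change threshold.
#'   \item List 2: treatment-vs-control fold change within either strain at
#'     the first duration -- fold-change criterion only.
#'   \item List 3: two-way ANOVA (BH-adjusted p below the threshold on the
#'     selected factor).
#' }
#'
#' @param m log2-normalized \code{\link{expr_matrix}} (already restricted to
#'   the analysis universe).
#' @param criteria1,criteria2,criteria3 \code{\link{selection_criteria}} for
#'   the three lists.
#' @param anova_factors which factor pair List 3 tests: \code{"strain_treatment"}
#'   (default) or \code{"treatment_duration"}.
#' @param anova_select which factor's adjusted p is thresholded (default the
#'   first of the pair, i.e. the strain main effect).
#' @param duration duration level used for Lists 1 and 2 (default the first).
#' @return A list with \code{lists} (character vectors of gene ids),
#'   \code{tables} (per-list DE tables) and \code{settings}.
#' @export
select_de_genes <- function(m,
                            criteria1 = selection_criteria(test = "mann_whitney"),
                            criteria2 = selection_criteria(),
                            criteria3 = selection_criteria(test = "anova"),
                            anova_factors = c("strain_treatment", "treatment_duration"),
                            anova_select = NULL,
                            duration = NULL) {
  chk(inherits(m, "expr_matrix"), "m must be an expr_matrix")
  chk(identical(m$scale, "log2_normalized"), "m must be log2-normalized")
  anova_factors <- match.arg(anova_factors)
  d <- m$design
  strains <- unique(d$strain)
  chk(length(strains) == 2L, "the design must contain exactly 2 strains")
  chk(all(c("control", "LPS") %in% d$treatment),
      "the design must contain control and LPS treatments")
  dur <- duration %||% sort(unique(d$duration))[1L]
  chk(dur %in% d$duration, "duration level not in design: ", dur)
  g1 <- sample_ids(d, strain = strains[1L], treatment = "LPS", duration = dur)
  g2 <- sample_ids(d, strain = strains[2L], treatment = "LPS", duration = dur)
  chk(length(g1) >= 2 && length(g2) >= 2,
      "List 1 requires >= 2 replicates per strain in the LPS/", dur, " cell")

  genes <- rownames(m$values)

  ## List 1: rank test + fold change, strain contrast under LPS
  mw <- apply(m$values, 1L, function(v) {
    r <- mann_whitney_u(v[g1], v[g2], contrast = "strain_under_LPS")
    c(r$U, r$p)
  })
  fc1 <- fold_change(m, g1, g2)
  p1_adj <- bh_adjust(mw[2L, ])
  tab1 <- data.frame(gene = genes, statistic = mw[1L, ], p = mw[2L, ],
                     p_adj = p1_adj, log2_fc = log2(fc1$ratio), fc = fc1$fc,
                     contrast = paste0(strains[1L], "-LPS-", dur, "_vs_",
                                       strains[2L], "-LPS-", dur),
                     row.names = NULL)
  list1 <- genes[is.finite(p1_adj) & p1_adj < criteria1$p_threshold &
                   fc1$fc >= criteria1$fc_threshold]

  ## List 2: treatment fold change within either strain (fold change only)
  fc_by_strain <- lapply(strains, function(s) {
    lps <- sample_ids(d, strain = s, treatment = "LPS", duration = dur)
    ctl <- sample_ids(d, strain = s, treatment = "control", duration = dur)
    chk(length(lps) > 0 && length(ctl) > 0,
        "List 2 contrast missing samples for strain ", s)
    fold_change(m, lps, ctl)
  })
  fc2 <- pmax(fc_by_strain[[1L]]$fc, fc_by_strain[[2L]]$fc)
  tab2 <- data.frame(gene = genes,
                     fc_strain1 = fc_by_strain[[1L]]$fc,
                     fc_strain2 = fc_by_strain[[2L]]$fc,
                     log2_fc_strain1 = log2(fc_by_strain[[1L]]$ratio),
                     log2_fc_strain2 = log2(fc_by_strain[[2L]]$ratio),
                     contrast = paste0("LPS_vs_control@", dur),
                     row.names = NULL)
  list2 <- genes[fc2 >= criteria2$fc_threshold]

  ## List 3: two-way ANOVA on all samples
  if (anova_factors == "strain_treatment") {
    f1 <- d$strain; f2 <- d$treatment
    fac_names <- c("strain", "treatment")
  } else {
    f1 <- d$treatment; f2 <- d$duration
    fac_names <- c("treatment", "duration")
  }
  sel_fac <- anova_select %||% fac_names[1L]
  chk(sel_fac %in% fac_names, "anova_select must be one of: ",
      paste(fac_names, collapse = ", "))
  an <- two_way_anova(m$values, f1, f2, replicated = TRUE)
  idx <- if (sel_fac == fac_names[1L]) "f1" else "f2"
  p3 <- an[[idx]]$p
  p3_adj <- bh_adjust(p3)
  tab3 <- data.frame(gene = genes, statistic = an[[idx]]$F, p = p3,
                     p_adj = p3_adj,
                     contrast = paste0("anova_", sel_fac, "_[",
                                       paste(fac_names, collapse = "x"), "]"),
                     row.names = NULL)
  list3 <- genes[is.finite(p3_adj) & p3_adj < criteria3$p_threshold]

  list(lists = list(list1 = list1, list2 = list2, list3 = list3),
       tables = list(list1 = tab1, list2 = tab2, list3 = tab3),
       settings = list(strains = strains, duration = dur,
                       anova_factors = fac_names, anova_select = sel_fac,
                       criteria = list(criteria1, criteria2, criteria3)))
}

#' Combine three gene lists into a Venn partition
#'
#' Computes the 7 region counts of the three-set Venn diagram and a combined
#' set under the declared rule: \code{"union_all"} (default) or
#' \code{"shared_by_2_of_3"}.
#'
#' @param a,b,c character vectors of gene ids.
#' @param rule combination rule.
#' @return A list with \code{region_counts}, \code{combined_set}, \code{rule}.
#' @export
combine_lists <- function(a, b, c, rule = c("union_all", "shared_by_2_of_3")) {
  rule <- match.arg(rule)
  a <- unique(as.character(a)); b <- unique(as.character(b))
  c <- unique(as.character(c))
  all_g <- union(union(a, b), c)
  in_a <- all_g %in% a; in_b <- all_g %in% b; in_c <- all_g %in% c
  region_counts <- c(
    a_only = sum(in_a & !in_b & !in_c),
    b_only = sum(!in_a & in_b & !in_c),
    c_only = sum(!in_a & !in_b & in_c),
    ab_only = sum(in_a & in_b & !in_c),
    ac_only = sum(in_a & !in_b & in_c),
    bc_only = sum(!in_a & in_b & in_c),
    abc = sum(in_a & in_b & in_c)
  )
  combined <- if (rule == "union_all") all_g else
    all_g[(in_a + in_b + in_c) >= 2L]
  list(region_counts = region_counts, combined_set = combined, rule = rule)
}
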