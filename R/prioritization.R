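# Stage 2: build the six criterion gene lists from the up-regulated DEGs,
# intersect them, and confirm marker co-expression.

.check_genes_present <- function(genes, m, what) {
  missing <- setdiff(genes, rownames(m))
  if (length(missing))
    stop(what, ": gene(s) missing: ", paste(missing, collapse = ", "))
}

.candidate_symbols <- function(candidates) {
  if (inherits(candidates, "gene_list")) candidates$symbols
  else as.character(candidates)
}

#' Genomic alteration profile of candidate genes
#'
#' For each gene: the percentage of samples with a +2 copy-number call, the
#' percentage with expression z-score > +1, and the alteration rate defined
#' literally as the sum of the two percentages. A patient altered in both
#' ways is counted twice, so the rate may exceed 100; `mode = "union"`
#' instead counts the percentage of samples with either alteration (requires
#' the two tables to share their sample set).
#'
#' @param genes Gene symbols (or a [gene_list]).
#' @param cna Copy-number call matrix (see [read_cna]).
#' @param z Z-score matrix (see [zscore_matrix]).
#' @param mode `"sum"` (default) or `"union"`.
#' @return Data.frame with gene, pct_amplified, pct_mrna_up, alteration_rate.
#' @export
alteration_profile <- function(genes, cna, z, mode = c("sum", "union")) {
  mode <- match.arg(mode)
  genes <- .candidate_symbols(genes)
  .check_genes_present(genes, cna, "alteration_profile (copy-number table)")
  .check_genes_present(genes, z, "alteration_profile (z-score matrix)")
  amp <- cna[genes, , drop = FALSE] == 2
  up <- z[genes, , drop = FALSE] > 1
  pct_amp <- 100 * rowMeans(amp)
  pct_up <- 100 * rowMeans(up)
  rate <- if (mode == "sum") pct_amp + pct_up else {
    common <- intersect(colnames(cna), colnames(z))
    if (length(common) < ncol(cna) || length(common) < ncol(z))
      stop("alteration_profile: union mode needs matching sample sets")
    100 * rowMeans(amp[, common, drop = FALSE] | up[, common, drop = FALSE])
  }
  data.frame(gene = genes, pct_amplified = unname(pct_amp),
             pct_mrna_up = unname(pct_up), alteration_rate = unname(rate),
             stringsAsFactors = FALSE)
}

#' GL1: genes with high genomic alteration rate
#'
#' Selects candidates whose alteration rate (see [alteration_profile])
#' strictly exceeds `threshold` percent, ranked by rate descending.
#'
#' @inheritParams alteration_profile
#' @param candidates Candidate genes (vector or [gene_list]).
#' @param threshold Alteration-rate threshold in percentage points.
#' @return A [gene_list] named "GL1".
#' @export
build_gl1 <- function(candidates, cna, z, threshold = 10, mode = "sum") {
  prof <- alteration_profile(candidates, cna, z, mode = mode)
  sel <- prof[prof$alteration_rate > threshold, ]
  sel <- sel[order(-sel$alteration_rate, sel$gene), ]
  gene_list("GL1", sel$gene,
            sprintf("alteration rate (amp + mRNA up) > %g%%", threshold))
}

#' GL2: genes amplified in a metastatic cohort
#'
#' Selects candidates whose +2 call frequency in the metastatic cohort
#' strictly exceeds `threshold` percent, ranked descending.
#'
#' @param candidates Candidate genes (vector or [gene_list]).
#' @param cna_metastatic Copy-number call matrix of the metastatic cohort.
#' @param threshold Amplification threshold in percentage points.
#' @return A [gene_list] named "GL2".
#' @export
build_gl2 <- function(candidates, cna_metastatic, threshold = 1) {
  genes <- .candidate_symbols(candidates)
  .check_genes_present(genes, cna_metastatic, "build_gl2")
  pct <- 100 * rowMeans(cna_metastatic[genes, , drop = FALSE] == 2)
  sel <- genes[pct > threshold]
  sel <- sel[order(-pct[match(sel, genes)], sel)]
  gene_list("GL2", sel,
            sprintf("copy-number amplification > %g%% of metastatic cohort",
                    threshold))
}

#' GL3: genes maximally expressed in the basal subtype
#'
#' A candidate is included iff its mean log2(FPKM + 1) among Basal samples
#' strictly exceeds its mean in every other PAM50 subtype; ties exclude.
#' Samples with unknown subtype are ignored; every subtype must have at
#' least one sample.
#'
#' @param candidates Candidate genes (vector or [gene_list]).
#' @param expr FPKM expression matrix.
#' @param clinical Clinical table supplying PAM50 labels.
#' @return A [gene_list] named "GL3" in candidate order.
#' @export
build_gl3 <- function(candidates, expr, clinical) {
  genes <- .candidate_symbols(candidates)
  .check_genes_present(genes, expr, "build_gl3")
  pam <- stats::setNames(clinical$PAM50, clinical$sample)
  ids <- intersect(colnames(expr), names(pam)[pam != "unknown"])
  subtypes <- c("LumA", "LumB", "HER2E", "Basal", "Normal-like")
  counts <- table(factor(pam[ids], levels = subtypes))
  if (any(counts == 0))
    stop("build_gl3: subtype(s) with zero samples: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  X <- log2(expr[genes, ids, drop = FALSE] + 1)
  means <- vapply(subtypes, function(s)
    rowMeans(X[, pam[ids] == s, drop = FALSE]), numeric(length(genes)))
  means <- matrix(means, nrow = length(genes),
                  dimnames = list(genes, subtypes))
  others <- setdiff(subtypes, "Basal")
  keep <- means[, "Basal"] > apply(means[, others, drop = FALSE], 1, max)
  gene_list("GL3", genes[keep],
            "strictly highest mean log2 expression in PAM50 Basal")
}

#' GL4: genes significantly enriched in TNBC samples
#'
#' One-sided Welch test (TNBC > non-TNBC) on log2(FPKM + 1), p < `p_max`.
#'
#' @param candidates Candidate genes (vector or [gene_list]).
#' @param expr FPKM expression matrix over TNBC and non-TNBC samples.
#' @param tnbc_ids Sample ids of the TNBC class.
#' @param p_max One-sided p-value threshold.
#' @return A [gene_list] named "GL4" in candidate order.
#' @export
build_gl4 <- function(candidates, expr, tnbc_ids, p_max = 0.05) {
  genes <- .candidate_symbols(candidates)
  .check_genes_present(genes, expr, "build_gl4")
  flags <- colnames(expr) %in% tnbc_ids
  if (sum(flags) < 2 || sum(!flags) < 2)
    stop("build_gl4: both TNBC and non-TNBC classes need >= 2 samples")
  X <- log2(expr[genes, , drop = FALSE] + 1)
  w <- .row_welch(X, which(flags), which(!flags))
  p <- mapply(.t_pvalue, w$t, w$df, MoreArgs = list(alternative = "greater"))
  gene_list("GL4", genes[p < p_max],
            sprintf("one-sided Welch TNBC > non-TNBC, p < %g", p_max))
}

#' GL5: genes whose high expression predicts poor survival on both endpoints
#'
#' Each gene's samples are split at the median of log2(FPKM + 1); the gene is
#' included iff the log-rank p-value is below `p_max` AND the high-expression
#' arm has worse survival (more observed than expected events), for both
#' overall survival and distant metastasis-free survival.
#'
#' @param candidates Candidate genes (vector or [gene_list]).
#' @param expr FPKM expression matrix.
#' @param clinical Clinical table with OS and DMFS columns.
#' @param p_max Log-rank p-value threshold per endpoint.
#' @return A [gene_list] named "GL5" in candidate order.
#' @export
build_gl5 <- function(candidates, expr, clinical, p_max = 0.05) {
  genes <- .candidate_symbols(candidates)
  .check_genes_present(genes, expr, "build_gl5")
  ids <- intersect(colnames(expr), clinical$sample)
  cl <- clinical[match(ids, clinical$sample), ]
  if (sum(cl$OS_event, na.rm = TRUE) == 0 &&
      sum(cl$DMFS_event, na.rm = TRUE) == 0)
    stop("build_gl5: cohort is fully censored on both endpoints")
  endpoint_pass <- function(xg, time, event) {
    ok <- !is.na(time) & !is.na(event)
    xg <- xg[ok]; time <- time[ok]; event <- event[ok]
    high <- xg > stats::median(xg)
    if (sum(high) == 0 || sum(!high) == 0) return(FALSE)
    lr <- logrank_test(time[high], event[high], time[!high], event[!high])
    lr$p < p_max && lr$direction > 0
  }
  X <- log2(expr[genes, ids, drop = FALSE] + 1)
  keep <- vapply(seq_along(genes), function(i) {
    endpoint_pass(X[i, ], cl$OS_time, cl$OS_event) &&
      endpoint_pass(X[i, ], cl$DMFS_time, cl$DMFS_event)
  }, logical(1))
  gene_list("GL5", genes[keep],
            sprintf("median split, log-rank p < %g and high arm worse, OS and DMFS",
                    p_max))
}

#' Split a cell-line panel into more- and less-sensitive halves
#'
#' Lines are ranked by ascending EC50 (ties broken by line id); the first
#' floor(n/2) lines are the more-sensitive (MS) class and the remaining
#' ceiling(n/2) the less-sensitive (LS) class, so a 37-line panel splits
#' 18 MS / 19 LS.
#'
#' @param panel A [cell_line_panel].
#' @return A list with `ms` and `ls` character vectors of line ids.
#' @export
classify_panel <- function(panel) {
  n <- length(panel$line)
  if (n < 2) stop("classify_panel: need at least 2 cell lines")
  ord <- panel$line[order(panel$ec50[panel$line], panel$line)]
  ms <- ord[seq_len(floor(n / 2))]
  list(ms = ms, ls = setdiff(ord, ms))
}

#' GL6: genes over-expressed in less-sensitive cell lines
#'
#' One-sided Welch test (LS > MS) on the panel's log2 expression, p < `p_max`.
#'
#' @param candidates Candidate genes (vector or [gene_list]).
#' @param panel A [cell_line_panel].
#' @param p_max One-sided p-value threshold.
#' @return A [gene_list] named "GL6" in candidate order.
#' @export
build_gl6 <- function(candidates, panel, p_max = 0.05) {
  genes <- .candidate_symbols(candidates)
  .check_genes_present(genes, panel$expr, "build_gl6")
  split <- classify_panel(panel)
  if (length(split$ms) < 2 || length(split$ls) < 2)
    stop("build_gl6: each sensitivity class needs >= 2 lines")
  X <- panel$expr[genes, , drop = FALSE]
  w <- .row_welch(X, match(split$ls, colnames(X)),
                  match(split$ms, colnames(X)))
  p <- mapply(.t_pvalue, w$t, w$df, MoreArgs = list(alternative = "greater"))
  gene_list("GL6", genes[p < p_max],
            sprintf("one-sided Welch LS > MS on EC50-ranked panel, p < %g",
                    p_max))
}

#' Confirm marker co-expression of candidate genes
#'
#' Keeps the genes whose Pearson correlation with the marker on
#' log2(FPKM + 1) satisfies r > `r_min` and p < `p_max`. Zero-variance genes
#' are recorded as failing, with a warning.
#'
#' @param genes Genes to test (vector or [gene_list]).
#' @param expr FPKM expression matrix containing the marker.
#' @param marker Marker gene symbol.
#' @param r_min Correlation threshold (strict).
#' @param p_max P-value threshold (strict).
#' @return A [gene_list] named "coexpressed" in input order.
#' @export
coexpression_confirm <- function(genes, expr, marker, r_min = 0.2,
                                 p_max = 0.05) {
  syms <- .candidate_symbols(genes)
  if (!marker %in% rownames(expr))
    stop("coexpression_confirm: marker '", marker, "' not in expression")
  .check_genes_present(syms, expr, "coexpression_confirm")
  X <- log2(expr + 1)
  mk <- X[marker, ]
  keep <- vapply(syms, function(g) {
    xg <- X[g, ]
    if (stats::sd(xg) == 0) {
      warning("coexpression_confirm: zero-variance gene '", g,
              "' recorded as failing")
      return(FALSE)
    }
    ct <- pearson_cor(xg, mk)
    ct$r > r_min && ct$p < p_max
  }, logical(1))
  gene_list("coexpressed", syms[keep],
            sprintf("Pearson r > %g and p < %g vs %s", r_min, p_max, marker))
}

#' Assemble the six criterion lists and their intersection
#'
#' Convenience wrapper running [build_gl1] through [build_gl6],
#' [intersect_gene_lists] and [coexpression_confirm] on prepared inputs.
#'
#' @param candidates Up-regulated DEG candidates (vector or [gene_list]).
#' @param cna TNBC-cohort copy-number calls.
#' @param z TNBC-cohort z-score matrix.
#' @param expr Full-cohort FPKM expression matrix.
#' @param clinical Full-cohort clinical table.
#' @param tnbc_ids TNBC sample ids.
#' @param cna_metastatic Metastatic-cohort copy-number calls.
#' @param panel A [cell_line_panel].
#' @param expr_coexpr Expression matrix used for the co-expression check
#'   (defaults to the TNBC columns of `expr`).
#' @param marker Marker gene symbol.
#' @param thresholds Named list overriding gl1_threshold, gl2_threshold,
#'   p_max (GL4/GL5/GL6), r_min, coexpr_p_max.
#' @return Object of class `prioritization_result`: the six lists, their
#'   intersection, the co-expression-confirmed subset, and parameters.
#' @export
prioritize <- function(candidates, cna, z, expr, clinical, tnbc_ids,
                       cna_metastatic, panel,
                       expr_coexpr = expr[, intersect(colnames(expr), tnbc_ids),
                                          drop = FALSE],
                       marker = "PTGS2", thresholds = list()) {
  th <- utils::modifyList(list(gl1_threshold = 10, gl2_threshold = 1,
                               p_max = 0.05, r_min = 0.2,
                               coexpr_p_max = 0.05), thresholds)
  gls <- list(
    GL1 = build_gl1(candidates, cna, z, threshold = th$gl1_threshold),
    GL2 = build_gl2(candidates, cna_metastatic,
                    threshold = th$gl2_threshold),
    GL3 = build_gl3(candidates, expr, clinical),
    GL4 = build_gl4(candidates, expr, tnbc_ids, p_max = th$p_max),
    GL5 = build_gl5(candidates, expr, clinical, p_max = th$p_max),
    GL6 = build_gl6(candidates, panel, p_max = th$p_max))
  inter <- intersect_gene_lists(gls)
  coex <- coexpression_confirm(inter, expr_coexpr, marker,
                               r_min = th$r_min, p_max = th$coexpr_p_max)
  structure(list(gene_lists = gls, intersection = inter, coexpressed = coex,
                 parameters = th, marker = marker),
            class = "prioritization_result")
}

#' @export
print.prioritization_result <- function(x, ...) {
  cat("<prioritization_result>\n")
  for (nm in names(x$gene_lists))
    cat(sprintf("  %s: %d genes\n", nm, length(x$gene_lists[[nm]])))
  cat(sprintf("  intersection: %d genes: %s\n", length(x$intersection),
              paste(x$intersection$symbols, collapse = " ")))
  cat(sprintf("  co-expressed with %s: %d genes\n", x$marker,
              length(x$coexpressed)))
  invisible(x)
}
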