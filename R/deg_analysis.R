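# Stage 1: stratify the cohort by marker z-score, run genome-wide
# differential expression with permutation p-values, apply the compound
# filter, and validate the signature by unsupervised clustering.

#' Stratify samples by marker-gene z-score
#'
#' High samples are those with marker z above `z_high`, trimmed to the top
#' `ceiling(fraction * n)` by z; low samples are those below `z_low`, trimmed
#' to the bottom `ceiling(fraction * n)`. The gate is applied first, then the
#' quantile cap.
#'
#' @param z Z-score matrix (see [zscore_matrix]).
#' @param marker Marker gene symbol; must be a row of `z`.
#' @param z_high,z_low Z-score gates (defaults +1 and -0.25).
#' @param fraction Quantile cap as a fraction of all samples (default 0.15).
#' @return Object of class `stratification`: list with `high_ids`, `low_ids`
#'   and the thresholds used.
#' @export
stratify <- function(z, marker, z_high = 1, z_low = -0.25, fraction = 0.15) {
  if (!marker %in% rownames(z))
    stop("stratify: marker '", marker, "' not found in the z-score matrix")
  zv <- z[marker, ]
  n <- length(zv)
  cap <- ceiling(fraction * n)
  hi <- names(zv)[zv > z_high]
  if (length(hi) == 0)
    stop("stratify: no sample has marker z > ", z_high,
         "; consider lowering z_high")
  hi <- hi[order(zv[hi], decreasing = TRUE)]
  hi <- hi[seq_len(min(cap, length(hi)))]
  lo <- names(zv)[zv < z_low]
  if (length(lo) == 0)
    stop("stratify: no sample has marker z < ", z_low,
         "; consider raising z_low")
  lo <- lo[order(zv[lo])]
  lo <- lo[seq_len(min(cap, length(lo)))]
  if (length(intersect(hi, lo)))
    stop("stratify: overlapping high/low groups; check thresholds")
  structure(list(high_ids = hi, low_ids = lo, z_high = z_high, z_low = z_low,
                 fraction = fraction),
            class = "stratification")
}

#' Genome-wide differential expression between marker-high and marker-low
#'
#' Per gene: Welch t on log2(FPKM + 1) (high vs low), a two-sided permutation
#' p-value (exhaustive when the number of label arrangements is at most
#' 20000, otherwise `n_perm` seeded draws with the add-one estimate),
#' Benjamini-Hochberg FDR, and linear-scale fold change
#' (mean_high + 1) / (mean_low + 1) on FPKM. The table is ranked by t
#' descending, ties broken by gene symbol.
#'
#' @param expr FPKM expression matrix covering all stratified samples.
#' @param strat A [stratify] result.
#' @param n_perm Number of permutations in sampled mode.
#' @param seed Integer seed for the permutation draws.
#' @return A `deg_table` data.frame with columns gene, t, fold_change, p,
#'   fdr, direction.
#' @export
run_deg <- function(expr, strat, n_perm = 1000, seed = 1) {
  hi <- strat$high_ids; lo <- strat$low_ids
  missing <- setdiff(c(hi, lo), colnames(expr))
  if (length(missing))
    stop("run_deg: stratified sample(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  if (length(hi) < 2 || length(lo) < 2)
    stop("run_deg: both groups need at least 2 samples")
  X <- log2(expr[, c(hi, lo), drop = FALSE] + 1)
  na <- length(hi); n <- na + length(lo)
  t_obs <- .welch_t_assignments(X, matrix(seq_len(na), ncol = 1), na)[, 1]
  perms <- .permutation_assignments(n, na, n_perm, seed)
  t_perm <- .welch_t_assignments(X, perms$assign, na)
  hits <- rowSums(abs(t_perm) >= abs(t_obs) - 1e-12)
  p <- if (perms$exhaustive) hits / perms$n_perm else
    (1 + hits) / (perms$n_perm + 1)
  fc <- (rowMeans(expr[, hi, drop = FALSE]) + 1) /
    (rowMeans(expr[, lo, drop = FALSE]) + 1)
  tab <- data.frame(gene = rownames(expr), t = t_obs, fold_change = fc,
                    p = p, fdr = bh_fdr(p),
                    direction = ifelse(t_obs >= 0, "up_in_high", "up_in_low"),
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(-tab$t, tab$gene), ]
  rownames(tab) <- NULL
  attr(tab, "n_perm") <- perms$n_perm
  attr(tab, "exhaustive") <- perms$exhaustive
  class(tab) <- c("deg_table", "data.frame")
  tab
}

#' Apply the compound DEG filter
#'
#' Strict inequalities throughout: up-regulated genes satisfy
#' fold_change > `fc`, p < `p`, t > `t_abs`, fdr < `fdr`; down-regulated
#' genes mirror these with fold_change < 1/`fc` and t < -`t_abs`.
#'
#' @param table A `deg_table` from [run_deg].
#' @param fc Linear fold-change threshold (default 1.5).
#' @param p P-value threshold (default 0.05).
#' @param t_abs Absolute t threshold (default 2).
#' @param fdr FDR threshold (default 0.35).
#' @return A list with `up` and `down` [gene_list]s, each ordered by the
#'   table's t-ranking.
#' @export
filter_deg <- function(table, fc = 1.5, p = 0.05, t_abs = 2, fdr = 0.35) {
  up <- table$fold_change > fc & table$p < p & table$t > t_abs &
    table$fdr < fdr
  down <- table$fold_change < 1 / fc & table$p < p & table$t < -t_abs &
    table$fdr < fdr
  crit <- sprintf("FC>%g, p<%g, |t|>%g, FDR<%g", fc, p, t_abs, fdr)
  list(up = gene_list("up_in_high", table$gene[up], crit),
       down = gene_list("up_in_low", table$gene[down], crit))
}

#' Validate a DEG signature by unsupervised clustering
#'
#' Z-scores the signature genes over the stratified samples, clusters the
#' samples with average linkage on Pearson correlation distance, cuts at
#' k = 2, and compares the partition against the high/low labels.
#'
#' @param expr FPKM expression matrix.
#' @param strat A [stratify] result.
#' @param signature A [gene_list] (non-empty) of signature genes.
#' @return A list with `confusion` (2 x 2 table), `exact_match` (logical),
#'   `ari` (Adjusted Rand Index) and `clusters` (named labels).
#' @export
validate_signature <- function(expr, strat, signature) {
  syms <- as.character(signature)
  if (length(syms) == 0) stop("validate_signature: empty signature")
  missing <- setdiff(syms, rownames(expr))
  if (length(missing))
    stop("validate_signature: signature gene(s) missing from expression: ",
         paste(missing, collapse = ", "))
  ids <- c(strat$high_ids, strat$low_ids)
  z <- zscore_matrix(expr[syms, ids, drop = FALSE])
  dend <- hclust_avg_pearson(t(z))
  cl <- cut_k(dend, 2)
  truth <- factor(ifelse(ids %in% strat$high_ids, "high", "low"),
                  levels = c("high", "low"))
  confusion <- table(cluster = cl, group = truth)
  ari <- mclust::adjustedRandIndex(cl, as.integer(truth))
  list(confusion = confusion, exact_match = isTRUE(all.equal(ari, 1)),
       ari = ari, clusters = cl)
}
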