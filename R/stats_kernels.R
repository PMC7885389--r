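# Statistical primitives shared by every pipeline stage.

#' Welch two-sample t-test
#'
#' Computes the Welch (unequal-variance) t statistic with the sign convention
#' `mean(a) - mean(b)`, and an analytic p-value from the Welch-Satterthwaite
#' degrees of freedom. When both groups are constant and equal, the statistic
#' is defined as 0 with p = 1; when constant but unequal, the statistic is
#' signed infinite with p = 0.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param alternative One of `"two.sided"`, `"greater"` (mean(a) > mean(b)),
#'   or `"less"`.
#' @return A list with elements `statistic`, `p`, `df`.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) < 2 || length(b) < 2)
    stop("welch_t: both groups must contain at least 2 observations")
  if (anyNA(a) || anyNA(b)) stop("welch_t: missing values are not supported")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  md <- mean(a) - mean(b)
  if (se2 == 0) {
    stat <- if (md == 0) 0 else sign(md) * Inf
    df <- NA_real_
  } else {
    stat <- md / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  p <- .t_pvalue(stat, df, alternative)
  list(statistic = stat, p = p, df = df)
}

.t_pvalue <- function(stat, df, alternative) {
  if (is.na(df)) { # degenerate zero-variance case
    return(switch(alternative,
      two.sided = if (stat == 0) 1 else 0,
      greater   = if (stat > 0) 0 else 1,
      less      = if (stat < 0) 0 else 1))
  }
  switch(alternative,
    two.sided = 2 * stats::pt(-abs(stat), df),
    greater   = stats::pt(stat, df, lower.tail = FALSE),
    less      = stats::pt(stat, df))
}

# Row-wise Welch t for a genes x samples matrix split into two column sets.
# Returns per-row statistic, Welch-Satterthwaite df, and group means.
# Zero-pooled-variance rows get t = 0 (equal means) or signed Inf.
.row_welch <- function(X, ia, ib) {
  na <- length(ia); nb <- length(ib)
  A <- X[, ia, drop = FALSE]; B <- X[, ib, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- (rowSums(A^2) - na * ma^2) / (na - 1)
  vb <- (rowSums(B^2) - nb * mb^2) / (nb - 1)
  va <- pmax(va, 0); vb <- pmax(vb, 0)
  se2 <- va / na + vb / nb
  md <- ma - mb
  t <- ifelse(se2 > 0, md / sqrt(se2), ifelse(md == 0, 0, sign(md) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               NA_real_)
  list(t = t, df = df, mean_a = ma, mean_b = mb)
}

# Welch t statistics for many label assignments at once.
# X: genes x n matrix; assign: na x B matrix of group-A column indices.
# Returns a genes x B matrix of statistics.
.welch_t_assignments <- function(X, assign, na) {
  n <- ncol(X); nb <- n - na
  B <- ncol(assign)
  P <- matrix(0, n, B)
  P[cbind(as.vector(assign), rep(seq_len(B), each = na))] <- 1
  ST <- rowSums(X); SST <- rowSums(X^2)
  SA <- X %*% P; SSA <- X^2 %*% P
  ma <- SA / na
  mb <- (ST - SA) / nb
  va <- pmax((SSA - na * ma^2) / (na - 1), 0)
  vb <- pmax(((SST - SSA) - nb * mb^2) / (nb - 1), 0)
  se2 <- va / na + vb / nb
  md <- ma - mb
  t <- ifelse(se2 > 0, md / sqrt(se2), ifelse(md == 0, 0, sign(md) * Inf))
  t
}

# Permutation label assignments for an n-sample, na-vs-(n-na) comparison.
# Exhaustive (all C(n, na) arrangements) when that count is at most
# `exhaustive_limit`, otherwise `n_perm` seeded random draws.
.permutation_assignments <- function(n, na, n_perm, seed,
                                     exhaustive_limit = 20000) {
  total <- choose(n, na)
  if (total <= exhaustive_limit) {
    list(assign = utils::combn(n, na), exhaustive = TRUE, n_perm = total)
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    assign <- replicate(n_perm, sample.int(n, na))
    list(assign = assign, exhaustive = FALSE, n_perm = n_perm)
  }
}

#' Two-sided permutation p-value for a two-group comparison
#'
#' Permutes group labels and compares the absolute Welch t statistic of each
#' relabelling against the observed one. When the number of distinct label
#' arrangements is at most `exhaustive_limit` the full enumeration is used
#' and the p-value is the exact tail proportion; otherwise `n_perm` seeded
#' random relabellings are drawn and the add-one estimate
#' p = (1 + #\{|t*| >= |t_obs|\}) / (n_perm + 1) is returned, which is never 0.
#'
#' @param values Numeric vector, one entry per sample.
#' @param labels Logical vector (TRUE = group A) or a two-level factor or
#'   character vector; the first level is group A.
#' @param n_perm Number of random permutations when sampling.
#' @param seed Integer seed for the sampled mode.
#' @param exhaustive_limit Enumeration threshold on `choose(n, nA)`.
#' @return A list with `p`, `statistic` (observed Welch t), `n_perm`, and
#'   `exhaustive`.
#' @export
permutation_p <- function(values, labels, n_perm = 1000, seed = 1,
                          exhaustive_limit = 20000) {
  grp <- .as_two_groups(labels)
  if (length(values) != length(grp))
    stop("permutation_p: values and labels must have equal length")
  ia <- which(grp); ib <- which(!grp)
  if (length(ia) == 0 || length(ib) == 0)
    stop("permutation_p: both groups must be present in labels")
  if (length(ia) < 2 || length(ib) < 2)
    stop("permutation_p: both groups must contain at least 2 samples")
  X <- matrix(values, nrow = 1)
  t_obs <- .welch_t_assignments(X, matrix(ia, ncol = 1), length(ia))[1, 1]
  perms <- .permutation_assignments(length(values), length(ia), n_perm, seed,
                                    exhaustive_limit)
  t_perm <- .welch_t_assignments(X, perms$assign, length(ia))[1, ]
  hits <- abs(t_perm) >= abs(t_obs) - 1e-12
  p <- if (perms$exhaustive) mean(hits) else (1 + sum(hits)) / (perms$n_perm + 1)
  list(p = p, statistic = t_obs, n_perm = perms$n_perm,
       exhaustive = perms$exhaustive)
}

.as_two_groups <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- as.factor(labels)
  if (nlevels(f) != 2)
    stop("labels must contain exactly two groups, got ", nlevels(f))
  f == levels(f)[1]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement
#' (wraps [stats::p.adjust] with `method = "BH"`).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("bh_fdr: p-values must lie in [0, 1] and contain no NA")
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A list with `r`, `p` (t-transform, n - 2 df), and `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_cor: unequal lengths")
  if (length(x) < 3) stop("pearson_cor: need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_cor: zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit] for a single group. Samples censored at an event
#' time are counted as at risk for that time.
#'
#' @param times Positive event/censoring times.
#' @param events 0/1 event indicators (1 = event).
#' @return An object of class `km_curve`: a list with `time`, `surv`,
#'   `n_risk`, `n_event`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("km_estimate: empty input")
  if (length(times) != length(events)) stop("km_estimate: length mismatch")
  if (any(times <= 0)) stop("km_estimate: times must be positive")
  if (!all(events %in% c(0, 1))) stop("km_estimate: events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event),
            class = "km_curve")
}

#' Two-group log-rank test
#'
#' Wraps [survival::survdiff]. Ties are handled with the standard
#' hypergeometric variance. The `direction` element is the sign of
#' (observed - expected) events in group A: +1 means group A fared worse.
#' If neither group has any event the statistic is 0 and p = 1.
#'
#' @param times_a,events_a Group A follow-up times and 0/1 event flags.
#' @param times_b,events_b Group B follow-up times and 0/1 event flags.
#' @return A list with `statistic` (chi-square, 1 df), `p`, `direction`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0)
    stop("logrank_test: both groups must be non-empty")
  if (sum(events_a) + sum(events_b) == 0)
    return(list(statistic = 0, p = 1, direction = 0))
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- factor(rep(c("A", "B"), c(length(times_a), length(times_b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stat <- unname(sd$chisq)
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       direction = sign(unname(sd$obs[1] - sd$exp[1])))
}

#' Average-linkage hierarchical clustering on Pearson correlation distance
#'
#' Clusters the rows of `x` (samples) using dissimilarity `1 - r` between
#' sample profiles and UPGMA (average) linkage.
#'
#' @param x Numeric matrix, samples in rows, features in columns. Every row
#'   must have nonzero variance.
#' @return An object of class [stats::hclust].
#' @export
hclust_avg_pearson <- function(x) {
  if (nrow(x) < 2) stop("hclust_avg_pearson: need at least 2 samples")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("hclust_avg_pearson: zero-variance sample profile(s): ",
         paste(bad, collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(t(x)))
  stats::hclust(d, method = "average")
}

#' Cut a dendrogram into k groups
#'
#' @param dend An [stats::hclust] object.
#' @param k Number of groups.
#' @return Integer vector of cluster labels named by sample.
#' @export
cut_k <- function(dend, k) stats::cutree(dend, k = k)
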