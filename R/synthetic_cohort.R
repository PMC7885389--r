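# Synthetic cohorts and cell-line panels with the statistical structure the
# prioritization pipeline assumes: log-normal FPKM with a planted
# marker-correlated gene block, discrete copy-number calls with per-gene
# amplification frequencies, exponential survival with expression-dependent
# hazard and uniform censoring, and a panel where resistance genes are
# over-expressed in high-EC50 lines.

.check_prob <- function(x, field) {
  if (anyNA(x) || any(x < 0 | x > 1))
    stop("cohort_spec: field '", field, "' must lie in [0, 1]")
}

#' Specify a synthetic patient cohort
#'
#' Defines the generative model for [simulate_cohort]. Expression is
#' log-normal: log2(FPKM + 1) ~ Normal(mu_g + effects, sigma) with per-gene
#' baselines drawn once from `mu_range`. The marker gene is drawn first and
#' elevated by `delta_basal` in PAM50-basal samples; marker-high patients are
#' the TNBC samples whose within-TNBC marker z-score exceeds 1. Planted genes
#' are then elevated by `delta` in marker-high patients (making co-expression
#' causal) and by `delta_basal` in basal samples (so they carry the
#' aggressive-subtype signature). Copy-number +2 calls are i.i.d. per gene at
#' `amp_freq` for planted genes and `background_amp` otherwise. Survival for
#' both endpoints is exponential with hazard
#' h0 * exp(surv_beta * s), where s is the standardized planted-block mean
#' expression and h0 fixes the baseline median at `median_os`; censoring is
#' uniform on (0, tau) with tau tuned so the expected censoring fraction is
#' `censor_frac`.
#'
#' @param n_patients Number of patients (>= 4).
#' @param n_genes Total genes in the universe (marker + planted + background).
#' @param marker_gene Marker symbol (default "PTGS2").
#' @param planted_genes Symbols co-regulated with the marker (up in
#'   marker-high patients; these also carry the amplification, subtype,
#'   survival and resistance structure).
#' @param planted_down_genes Symbols anti-regulated with the marker (down by
#'   `delta` in marker-high patients, no other planted structure); together
#'   with `planted_genes` they make the DEG signature two-sided, which is
#'   what correlation-distance clustering of samples requires.
#' @param delta Effect size (log2 units) added to planted genes in
#'   marker-high patients; must be >= 0.
#' @param sigma Within-group SD in log2 space.
#' @param mu_range Range of per-gene baseline means in log2 space.
#' @param amp_freq Per-gene probability of a +2 call for planted genes.
#' @param background_amp Probability of a +2 call for background genes.
#' @param surv_beta Log hazard ratio per SD of the planted-block score.
#' @param censor_frac Target censoring proportion.
#' @param tnbc_frac Fraction of ER-/PR-/HER2- samples.
#' @param basal_given_tnbc Probability a TNBC sample is PAM50 Basal.
#' @param subtype_probs Subtype probabilities for non-TNBC samples.
#' @param delta_basal Expression shift (log2 units) of marker and planted
#'   genes in basal samples; defaults to `2 * delta` (the target class of
#'   candidate genes is strongly basal-restricted).
#' @param median_os Baseline median survival (months) at s = 0.
#' @param seed Integer seed driving one root generator.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 120, n_genes = 1000,
                        marker_gene = "PTGS2",
                        planted_genes = sprintf("CAND%02d", 1:20),
                        planted_down_genes = sprintf("DOWN%02d", 1:20),
                        delta = 1, sigma = 0.5, mu_range = c(3, 8),
                        amp_freq = 0.15, background_amp = 0.01,
                        surv_beta = 1, censor_frac = 0.25,
                        tnbc_frac = 0.7, basal_given_tnbc = 1,
                        subtype_probs = c(LumA = 0.35, LumB = 0.25,
                                          HER2E = 0.2, `Normal-like` = 0.2),
                        delta_basal = 2 * delta, median_os = 60,
                        seed = 1L) {
  if (n_patients < 4) stop("cohort_spec: field 'n_patients' must be >= 4")
  if (delta < 0) stop("cohort_spec: field 'delta' must be >= 0")
  if (sigma <= 0) stop("cohort_spec: field 'sigma' must be > 0")
  if (delta_basal < 0) stop("cohort_spec: field 'delta_basal' must be >= 0")
  .check_prob(amp_freq, "amp_freq")
  .check_prob(background_amp, "background_amp")
  .check_prob(censor_frac, "censor_frac")
  .check_prob(tnbc_frac, "tnbc_frac")
  .check_prob(basal_given_tnbc, "basal_given_tnbc")
  .check_prob(subtype_probs, "subtype_probs")
  if (abs(sum(subtype_probs) - 1) > 1e-8)
    stop("cohort_spec: field 'subtype_probs' must sum to 1")
  if (marker_gene %in% c(planted_genes, planted_down_genes))
    stop("cohort_spec: planted gene fields must not contain the marker")
  if (length(intersect(planted_genes, planted_down_genes)))
    stop("cohort_spec: planted_genes and planted_down_genes must be disjoint")
  n_background <- n_genes - 1L - length(planted_genes) -
    length(planted_down_genes)
  if (n_background < 0)
    stop("cohort_spec: field 'n_genes' too small for marker + planted genes")
  genes <- c(marker_gene, planted_genes, planted_down_genes,
             if (n_background > 0) sprintf("G%04d", seq_len(n_background)))
  structure(list(n_patients = as.integer(n_patients),
                 n_genes = as.integer(n_genes), marker_gene = marker_gene,
                 planted_genes = planted_genes,
                 planted_down_genes = planted_down_genes, genes = genes,
                 delta = delta, sigma = sigma, mu_range = mu_range,
                 amp_freq = amp_freq, background_amp = background_amp,
                 surv_beta = surv_beta, censor_frac = censor_frac,
                 tnbc_frac = tnbc_frac, basal_given_tnbc = basal_given_tnbc,
                 subtype_probs = subtype_probs, delta_basal = delta_basal,
                 median_os = median_os, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Uniform-censoring window tau such that the expected censoring proportion
# over the cohort's hazard rates equals the target.
.censor_window <- function(rates, target) {
  f <- function(tau) mean((1 - exp(-rates * tau)) / (rates * tau)) - target
  stats::uniroot(f, lower = 1e-6, upper = 1e8, tol = 1e-10)$root
}

#' Simulate a patient cohort
#'
#' Draws expression, clinical and copy-number tables from a [cohort_spec].
#' Identical spec and seed give identical output.
#'
#' @param spec A `cohort_spec`.
#' @return Object of class `simulated_cohort`: list with `expression`
#'   (FPKM, genes x samples), `clinical` (see [read_clinical]), `cna`
#'   (calls in -2..+2), and `truth` (planted genes, marker-high ids, risk
#'   score, and the spec).
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  set.seed(spec$seed)
  n <- spec$n_patients
  genes <- spec$genes
  G <- length(genes)
  samples <- sprintf("S%03d", seq_len(n))

  # receptor status and subtype
  n_tnbc <- round(spec$tnbc_frac * n)
  tnbc <- logical(n)
  tnbc[sample.int(n, n_tnbc)] <- TRUE
  pam50 <- character(n)
  pam50[tnbc] <- ifelse(stats::runif(n_tnbc) < spec$basal_given_tnbc,
                        "Basal", "Normal-like")
  if (any(!tnbc))
    pam50[!tnbc] <- sample(names(spec$subtype_probs), sum(!tnbc),
                           replace = TRUE, prob = spec$subtype_probs)
  recept <- function() ifelse(stats::runif(n) < 0.35, "negative", "positive")
  er <- recept(); pr <- recept(); her2 <- recept()
  er[tnbc] <- pr[tnbc] <- her2[tnbc] <- "negative"
  # non-TNBC samples must keep at least one positive receptor
  allneg <- !tnbc & er == "negative" & pr == "negative" & her2 == "negative"
  er[allneg] <- "positive"
  basal <- pam50 == "Basal"

  # expression: marker first, then marker-high labelling, then planted block
  mu <- stats::runif(G, spec$mu_range[1], spec$mu_range[2])
  logx <- mu + spec$sigma * matrix(stats::rnorm(G * n), G, n,
                                   dimnames = list(genes, samples))
  logx[1, ] <- logx[1, ] + spec$delta_basal * basal
  marker_high <- rep(FALSE, n)
  if (n_tnbc >= 2) {
    mk <- logx[1, tnbc]
    zm <- (mk - mean(mk)) / sqrt(mean((mk - mean(mk))^2))
    marker_high[tnbc] <- zm > 1
  }
  planted_idx <- match(spec$planted_genes, genes)
  if (length(planted_idx)) {
    shift <- spec$delta * marker_high + spec$delta_basal * basal
    logx[planted_idx, ] <- logx[planted_idx, ] +
      matrix(shift, length(planted_idx), n, byrow = TRUE)
  }
  down_idx <- match(spec$planted_down_genes, genes)
  if (length(down_idx))
    logx[down_idx, ] <- logx[down_idx, ] -
      matrix(spec$delta * marker_high, length(down_idx), n, byrow = TRUE)
  fpkm <- pmax(2^logx - 1, 0)

  # copy-number calls: per-gene amplification frequency, i.i.d. across samples
  p_amp <- ifelse(genes %in% spec$planted_genes, spec$amp_freq,
                  spec$background_amp)
  u <- matrix(stats::runif(G * n), G, n)
  cna <- matrix(0L, G, n, dimnames = list(genes, samples))
  cna[u < p_amp] <- 2L
  cna[u >= p_amp & u < p_amp + 0.05] <- 1L
  cna[u >= p_amp + 0.05 & u < p_amp + 0.10] <- -1L
  cna[u >= p_amp + 0.10 & u < p_amp + 0.105] <- -2L

  # survival: exponential hazard scaled by the planted-block score
  if (length(planted_idx)) {
    s <- colMeans(logx[planted_idx, , drop = FALSE])
    s_sd <- stats::sd(s)
    s <- if (s_sd > 0) (s - mean(s)) / s_sd else rep(0, n)
  } else s <- rep(0, n)
  rate <- log(2) / spec$median_os * exp(spec$surv_beta * s)
  draw_endpoint <- function() {
    t_ev <- stats::rexp(n, rate)
    if (spec$censor_frac > 0) {
      tau <- .censor_window(rate, spec$censor_frac)
      cens <- stats::runif(n, 0, tau)
      list(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens))
    } else list(time = t_ev, event = rep(1L, n))
  }
  os <- draw_endpoint()
  dmfs <- draw_endpoint()

  clinical <- data.frame(sample = samples, ER = er, PR = pr, HER2 = her2,
                         PAM50 = pam50,
                         OS_time = os$time, OS_event = os$event,
                         DMFS_time = dmfs$time, DMFS_event = dmfs$event,
                         stringsAsFactors = FALSE)
  structure(list(expression = fpkm, clinical = clinical, cna = cna,
                 truth = list(planted_genes = spec$planted_genes,
                              planted_down_genes = spec$planted_down_genes,
                              marker_high = samples[marker_high],
                              tnbc = samples[tnbc],
                              risk_score = stats::setNames(s, samples),
                              spec = spec)),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> %d genes x %d samples (%d TNBC, %d marker-high, %d planted genes)\n",
              nrow(x$expression), ncol(x$expression), length(x$truth$tnbc),
              length(x$truth$marker_high), length(x$truth$planted_genes)))
  invisible(x)
}

#' Specify a synthetic cell-line panel
#'
#' @param genes Gene universe of the panel expression matrix.
#' @param resistance_genes Symbols over-expressed in high-EC50 (less
#'   sensitive) lines; must be a subset of `genes`.
#' @param n_lines Number of cell lines (>= 2; default 37).
#' @param ec50_range Low/high EC50 bounds in micromolar (log-uniform draw).
#' @param delta_panel Log2 expression shift of resistance genes in the
#'   upper-EC50 half.
#' @param sigma Within-line SD in log2 space.
#' @param mu_range Per-gene baseline range in log2 space.
#' @param seed Integer seed.
#' @return A validated `panel_spec` list.
#' @export
panel_spec <- function(genes, resistance_genes = character(), n_lines = 37,
                       ec50_range = c(0.5, 50), delta_panel = 3,
                       sigma = 0.5, mu_range = c(3, 8), seed = 1L) {
  if (n_lines < 2) stop("panel_spec: field 'n_lines' must be >= 2")
  if (ec50_range[1] <= 0 || ec50_range[1] >= ec50_range[2])
    stop("panel_spec: field 'ec50_range' must satisfy 0 < low < high")
  if (!all(resistance_genes %in% genes))
    stop("panel_spec: field 'resistance_genes' must be a subset of genes")
  structure(list(genes = genes, resistance_genes = resistance_genes,
                 n_lines = as.integer(n_lines), ec50_range = ec50_range,
                 delta_panel = delta_panel, sigma = sigma,
                 mu_range = mu_range, seed = as.integer(seed)),
            class = "panel_spec")
}

#' Simulate a cell-line panel
#'
#' EC50 values are drawn log-uniformly (distinct with probability one; exact
#' ties are re-jittered). Resistance genes receive a `delta_panel` shift in
#' the lines of the upper EC50 half, matching the panel-split rule of
#' [classify_panel].
#'
#' @param spec A `panel_spec`.
#' @return A [cell_line_panel].
#' @export
simulate_panel <- function(spec) {
  if (!inherits(spec, "panel_spec")) spec <- do.call(panel_spec, spec)
  set.seed(spec$seed)
  n <- spec$n_lines
  lines <- sprintf("CL%02d", seq_len(n))
  ec50 <- exp(stats::runif(n, log(spec$ec50_range[1]),
                           log(spec$ec50_range[2])))
  while (anyDuplicated(ec50))
    ec50[duplicated(ec50)] <- ec50[duplicated(ec50)] * (1 + 1e-9)
  names(ec50) <- lines
  G <- length(spec$genes)
  mu <- stats::runif(G, spec$mu_range[1], spec$mu_range[2])
  expr <- mu + spec$sigma * matrix(stats::rnorm(G * n), G, n,
                                   dimnames = list(spec$genes, lines))
  ls_lines <- lines[order(ec50, lines)][-seq_len(floor(n / 2))]
  ridx <- match(spec$resistance_genes, spec$genes)
  if (length(ridx))
    expr[ridx, ls_lines] <- expr[ridx, ls_lines] + spec$delta_panel
  cell_line_panel(lines, ec50, expr)
}

#' Write a simulated cohort to a directory
#'
#' Writes `expression.tsv`, `clinical.tsv`, `cna.tsv` and `truth.json`.
#'
#' @param cohort A `simulated_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_cna(cohort$cna, file.path(dir, "cna.tsv"))
  truth <- cohort$truth
  truth$spec <- truth$spec[setdiff(names(truth$spec), "genes")]
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
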