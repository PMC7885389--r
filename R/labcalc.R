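# Wet-lab arithmetic: Surveyor cleavage efficiency, caliper tumor volume,
# viability inhibition, and four-parameter logistic IC50 estimation.

#' Fraction of cleaved product from band densitometry
#'
#' fraction cleaved = sum(cleaved intensities) /
#' (sum(cleaved) + sum(parental)).
#'
#' @param cleaved Non-negative cleaved band intensities.
#' @param parental Non-negative parental band intensities.
#' @return Fraction in \[0, 1\].
#' @export
fraction_cleaved <- function(cleaved, parental) {
  if (any(cleaved < 0) || any(parental < 0))
    stop("fraction_cleaved: intensities must be non-negative")
  total <- sum(cleaved) + sum(parental)
  if (total <= 0)
    stop("fraction_cleaved: all intensities are zero")
  sum(cleaved) / total
}

#' Cleavage efficiency from the cleaved fraction
#'
#' efficiency = 1 - sqrt(1 - fraction cleaved), the standard indel-fraction
#' estimate for a mismatch-cleavage (Surveyor) assay, where re-annealing of
#' edited and unedited strands makes the cleaved fraction quadratic in the
#' editing efficiency.
#'
#' @param fraction_cleaved Value(s) in \[0, 1\].
#' @return Efficiency in \[0, 1\], monotone increasing in the input.
#' @export
cleavage_efficiency <- function(fraction_cleaved) {
  if (any(fraction_cleaved < 0 | fraction_cleaved > 1))
    stop("cleavage_efficiency: fraction cleaved must lie in [0, 1]")
  1 - sqrt(1 - fraction_cleaved)
}

#' Caliper tumor volume
#'
#' volume = (4/3) * pi * (L/2) * (W/2)^2 with the caliper convention that
#' the larger measurement is the length; inputs are auto-ordered.
#'
#' @param length,width Caliper measurements in mm (non-negative); vectorized.
#' @return Volume in cubic millimetres.
#' @export
tumor_volume <- function(length, width) {
  if (any(length < 0) || any(width < 0))
    stop("tumor_volume: measurements must be non-negative")
  l <- pmax(length, width)
  w <- pmin(length, width)
  (4 / 3) * pi * (l / 2) * (w / 2)^2
}

#' Percentage inhibition of cell viability
#'
#' (1 - treated/control) * 100; negative when the treated signal exceeds the
#' control.
#'
#' @param control_signal Vehicle-control signal (> 0).
#' @param treated_signal Treated-well signal.
#' @return Percentage inhibition.
#' @export
viability_inhibition <- function(control_signal, treated_signal) {
  if (any(control_signal <= 0))
    stop("viability_inhibition: control signal must be positive")
  (1 - treated_signal / control_signal) * 100
}

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Fits response = bottom + (top - bottom) / (1 + (dose/ic50)^hill) by
#' Levenberg-Marquardt least squares on log-dose ([minpack.lm::nls.lm]),
#' with the hill slope
#' bounded in (0.1, 10) and initial values taken from the data (top/bottom
#' from the response extremes, IC50 from the dose closest to the half-way
#' response). The IC50 is the dose at the midpoint between the fitted top
#' and bottom.
#'
#' @param doses Positive dose levels in micromolar (>= 4 levels).
#' @param responses Response as a fraction of the vehicle-control signal.
#' @param min_span Minimum required dynamic range of the responses.
#' @return List with `ic50`, `top`, `bottom`, `hill`, `resid_norm`,
#'   `converged`.
#' @export
fit_ic50 <- function(doses, responses, min_span = 0.3) {
  if (length(doses) != length(responses))
    stop("fit_ic50: doses and responses must have equal length")
  if (length(unique(doses)) < 4)
    stop("fit_ic50: at least 4 distinct dose levels are required")
  if (any(doses <= 0)) stop("fit_ic50: doses must be positive")
  span <- max(responses) - min(responses)
  if (span < min_span)
    stop("fit_ic50: degenerate response span (", signif(span, 3),
         " < ", min_span, "); curve is too flat to fit")
  ld <- log(doses)
  model <- function(p) p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
    (1 + exp(p[["hill"]] * (ld - p[["lic"]])))
  mid <- (max(responses) + min(responses)) / 2
  start <- c(top = max(responses), bottom = min(responses),
             lic = ld[which.min(abs(responses - mid))], hill = 1)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = function(p) responses - model(p),
                       lower = c(-Inf, -Inf, -Inf, 0.1),
                       upper = c(Inf, Inf, Inf, 10),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("fit_ic50: fit did not converge: ", conditionMessage(e)))
  if (!fit$info %in% 1:4)
    stop("fit_ic50: fit did not converge: ", fit$message)
  par <- as.list(fit$par)
  list(ic50 = exp(par$lic), top = par$top, bottom = par$bottom,
       hill = par$hill, resid_norm = sqrt(fit$deviance),
       converged = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
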