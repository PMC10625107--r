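# AP scoring. AP = SASA_initial / SASA_final over a simulation; values above 1
# mean solvent-accessible surface was buried, i.e. the peptides aggregated.
# The hydrophilicity-corrected scores combine the normalized AP' with the
# normalized hydrophilicity logP':
#   AP_H  = AP'^2 * logP'^0.5          (bias toward soluble aggregators)
#   AP_HC = AP_H * exp(-(logP' - mu)^2 / (2 sigma^2))
# where mu and sigma^2 describe the logP' distribution of experimentally
# validated aggregating pentapeptides.

#' Aggregation propensity from SASA pairs
#'
#' @param sasa_initial,sasa_final strictly positive solvent-accessible surface
#'   areas at the start and end of a simulation (any consistent area unit).
#' @return AP = `sasa_initial / sasa_final` (unitless); > 1 indicates surface
#'   burial, i.e. aggregation.
#' @examples
#' ap_from_sasa(300, 150)  # 2
#' @export
ap_from_sasa <- function(sasa_initial, sasa_final) {
  if (any(!is.finite(sasa_initial)) || any(!is.finite(sasa_final)) ||
      any(sasa_initial <= 0) || any(sasa_final <= 0))
    stop("SASA values must be strictly positive", call. = FALSE)
  sasa_initial / sasa_final
}

#' Min-max normalization of a score population
#'
#' Maps scores onto \[0, 1\] as `(x - min) / (max - min)`. Constants default to
#' the population's own range; externally supplied constants (for instance the
#' range of the full predicted space) are recorded and out-of-range values are
#' clipped to \[0, 1\].
#'
#' @param values numeric scores (e.g. predicted or simulated AP).
#' @param constants optional `c(min, max)` normalization constants.
#' @return numeric vector in \[0, 1\] with attribute `"constants"`.
#' @examples
#' normalize_scores(c(1, 1.5, 2))
#' @export
normalize_scores <- function(values, constants = NULL) {
  values <- as.numeric(values)
  external <- !is.null(constants)
  if (!external) {
    if (length(unique(values)) < 2L)
      stop("need at least 2 distinct values to self-normalize", call. = FALSE)
    constants <- range(values)
  }
  if (length(constants) != 2L || !all(is.finite(constants)) ||
      constants[2] <= constants[1])
    stop("degenerate normalization constants", call. = FALSE)
  out <- (values - constants[1]) / (constants[2] - constants[1])
  if (external) out <- pmin(pmax(out, 0), 1)
  attr(out, "constants") <- constants
  out
}

#' Hydrophilicity-correction parameters
#'
#' Mean and variance of the normalized hydrophilicity logP' among
#' experimentally validated aggregating pentapeptides; defaults are the
#' published constants mu = 0.4113, sigma^2 = 0.0657.
#'
#' @param mu mean logP' of validated aggregators, in \[0, 1\].
#' @param sigma2 variance of that logP', > 0.
#' @return list with elements `mu` and `sigma2`.
#' @export
hc_params <- function(mu = 0.4113, sigma2 = 0.0657) {
  if (!is.finite(mu) || mu < 0 || mu > 1) stop("mu must lie in [0, 1]",
                                               call. = FALSE)
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0",
                                              call. = FALSE)
  list(mu = mu, sigma2 = sigma2)
}

#' Hydrophilicity-corrected aggregation scores
#'
#' `ap_h()` is the soluble-aggregator score `AP'^2 * sqrt(logP')`; `ap_hc()`
#' multiplies it by the Gaussian penalty `hc_penalty()` centered on the
#' hydrophilicity of known aggregators, suppressing both the insoluble
#' (logP' near 0) and the fully soluble (logP' near 1) extremes.
#'
#' @param ap_prime normalized aggregation propensity in \[0, 1\].
#' @param logp_prime normalized hydrophilicity in \[0, 1\].
#' @param params [hc_params()].
#' @return unitless score(s).
#' @examples
#' ap_h(0.8, 0.25)          # 0.32
#' ap_hc(0.8, 0.4113)       # penalty 1 at mu: equals ap_h
#' @export
ap_h <- function(ap_prime, logp_prime) {
  check_unit_interval(ap_prime, "ap_prime")
  check_unit_interval(logp_prime, "logp_prime")
  ap_prime ^ 2 * sqrt(logp_prime)
}

#' @rdname ap_h
#' @export
hc_penalty <- function(logp_prime, params = hc_params()) {
  check_unit_interval(logp_prime, "logp_prime")
  exp(-(logp_prime - params$mu) ^ 2 / (2 * params$sigma2))
}

#' @rdname ap_h
#' @export
ap_hc <- function(ap_prime, logp_prime, params = hc_params()) {
  ap_h(ap_prime, logp_prime) * hc_penalty(logp_prime, params)
}

#' Report rounding
#'
#' Rounds half away from zero (the convention of printed score tables, where
#' e.g. an average of 1.1045 is reported as 1.105), unlike base `round()`
#' which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 3, the table convention).
#' @return rounded numeric vector.
#' @examples
#' round_report(1.1045)  # 1.105
#' @export
round_report <- function(x, digits = 3L) {
  m <- 10 ^ digits
  # pre-round at finer precision so decimal halves survive binary storage
  sign(x) * floor(round(abs(x) * m, 6) + 0.5) / m
}

check_unit_interval <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(name, " must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

#' Score table for a set of peptides
#'
#' Convenience assembly of the per-peptide score columns used in reports:
#' AP, AP', logP', AP_H and AP_HC.
#'
#' @param peptides character vector of single peptides.
#' @param ap numeric AP values aligned with `peptides`.
#' @param constants optional AP normalization constants `c(min, max)`.
#' @param params [hc_params()].
#' @return data.frame with columns `sequence, ap, ap_prime, logp_prime, ap_h,
#'   ap_hc`; normalization constants kept in attribute `"constants"`.
#' @export
score_table <- function(peptides, ap, constants = NULL, params = hc_params()) {
  peptides <- peptide(peptides)
  stopifnot(length(peptides) == length(ap))
  ap_prime <- normalize_scores(ap, constants)
  lp <- logp_normalized(peptides)
  out <- data.frame(sequence = peptides, ap = as.numeric(ap),
                    ap_prime = as.numeric(ap_prime), logp_prime = lp,
                    ap_h = ap_h(as.numeric(ap_prime), lp),
                    ap_hc = ap_hc(as.numeric(ap_prime), lp, params),
                    stringsAsFactors = FALSE)
  attr(out, "constants") <- attr(ap_prime, "constants")
  attr(out, "hc_params") <- params
  out
}
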