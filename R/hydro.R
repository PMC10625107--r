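# Wimley-White whole-residue hydrophilicity. logP of a peptide is the sum of
# per-residue water -> n-octanol transfer free energies; logP' is the min-max
# normalization of that sum against the theoretical length-n extremes
# (homopolymers of the most hydrophobic / most hydrophilic residue), which is
# the convention that reproduces published per-peptide logP' tables.

.ww_cache <- new.env(parent = emptyenv())

#' Wimley-White whole-residue octanol scale
#'
#' Per-residue free energy of transfer from water to n-octanol (kcal/mol),
#' charged side-chain forms for D, E, K and R and neutral histidine, as
#' appropriate at neutral pH. Higher values are more hydrophilic. The
#' constants ship as a versioned CSV under `inst/extdata/`.
#'
#' @param path optional path to an alternative scale CSV with columns
#'   `residue, delta_g_woct_kcal_per_mol`.
#' @return named numeric vector over the 20 standard residues.
#' @examples
#' ww_octanol_scale()[["W"]]  # most hydrophobic whole residue
#' @export
ww_octanol_scale <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ww_cache$scale)) return(.ww_cache$scale)
    path <- system.file("extdata", "wimley_white_octanol.csv",
                        package = "apscreen")
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  scale <- stats::setNames(tab$delta_g_woct_kcal_per_mol, tab$residue)
  missing <- setdiff(AA_ALPHABET, names(scale))
  if (length(missing))
    stop("scale is missing residue(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  .ww_cache$scale <- scale
  scale
}

#' Peptide hydrophilicity logP
#'
#' logP is the sum over residues of the Wimley-White whole-residue
#' water-to-octanol transfer free energy (kcal/mol); larger values mean a more
#' hydrophilic peptide. `logp_normalized()` rescales to \[0, 1\] using the
#' theoretical extremes for the peptide's length, `length * min` and
#' `length * max` over the scale, so a homopolymer of the most hydrophobic
#' residue maps to 0 and of the most hydrophilic to 1.
#'
#' @param peptides character vector of peptide sequences (no mixtures).
#' @param scale named numeric scale, by default [ww_octanol_scale()].
#' @return numeric vector, kcal/mol for `logp()`, unitless in \[0, 1\] for
#'   `logp_normalized()`.
#' @examples
#' logp("NRMMR")             # 3.13 kcal/mol
#' logp_normalized("NRMMR")  # 0.474
#' @export
logp <- function(peptides, scale = ww_octanol_scale()) {
  peptides <- peptide(peptides)
  if (any(is_mixed(peptides)))
    stop("logp is defined for single peptides", call. = FALSE)
  missing <- setdiff(AA_ALPHABET, names(scale))
  if (length(missing))
    stop("scale is missing residue(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  vapply(strsplit(peptides, ""), function(res) sum(scale[res]), numeric(1))
}

#' @rdname logp
#' @export
logp_normalized <- function(peptides, scale = ww_octanol_scale()) {
  peptides <- peptide(peptides)
  raw <- logp(peptides, scale)
  n <- nchar(peptides)
  b <- logp_bounds(1L, scale)
  (raw - n * b[1]) / (n * (b[2] - b[1]))
}

#' @rdname logp
#' @param length peptide length for which to compute the theoretical extremes.
#' @return `logp_bounds()` returns `c(min, max)` in kcal/mol: the logP of
#'   length-`length` homopolymers of the extreme-valued residues.
#' @export
logp_bounds <- function(length, scale = ww_octanol_scale()) {
  length <- as.integer(length)
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  c(length * min(scale), length * max(scale))
}
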