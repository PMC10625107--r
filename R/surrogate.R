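# Synthetic stand-in for coarse-grained MD label generation. The surrogate is
# a deterministic residue/position model plus seeded Gaussian noise, with
# structure planted to mimic what CGMD screens report qualitatively: aromatic
# residues drive aggregation most (pi-stacking), aliphatic hydrophobics next,
# polar residues weakly, charged residues and G/A suppress it, and mixing two
# oppositely charged peptides boosts aggregation beyond the component average
# (salt-bridge / Coulombic complementarity). Outputs live in the empirical AP
# range of CGMD screens (clipped to [0.8, 2.6]).

#' Surrogate model parameters
#'
#' @param position_weights 20 x 10 residue-by-position contribution table
#'   (rows ordered by the fixed alphabet); default
#'   [default_position_weights()].
#' @param pair_bonus AP bonus per adjacent aromatic-aromatic pair.
#' @param charge_penalty AP penalty per unit of absolute net side-chain
#'   charge.
#' @param mix_boost coefficient of the opposite-charge mixing boost
#'   `mix_boost * |q1| * |q2|` applied when the two components of a mixture
#'   carry opposite net side-chain charge.
#' @param noise_sd standard deviation of the Gaussian label noise.
#' @param base offset anchoring outputs near the empirical AP range.
#' @param clip output range `c(lo, hi)`.
#' @return list of validated parameters.
#' @export
surrogate_params <- function(position_weights = default_position_weights(),
                             pair_bonus = 0.06, charge_penalty = 0.03,
                             mix_boost = 0.12, noise_sd = 0.05,
                             base = 1.4, clip = c(0.8, 2.6)) {
  stopifnot(is.matrix(position_weights),
            nrow(position_weights) == 20L, ncol(position_weights) == 10L,
            noise_sd >= 0, length(clip) == 2L, clip[1] < clip[2])
  rownames(position_weights) <- AA_ALPHABET
  list(position_weights = position_weights, pair_bonus = pair_bonus,
       charge_penalty = charge_penalty, mix_boost = mix_boost,
       noise_sd = noise_sd, base = base, clip = clip)
}

#' @rdname surrogate_params
#' @export
default_position_weights <- function() {
  base_w <- c(A = -0.03, C = 0.10, D = -0.08, E = -0.08, F = 0.16, G = -0.03,
              H = 0.04, I = 0.10, K = -0.08, L = 0.10, M = 0.02, N = -0.03,
              P = 0.02, Q = -0.03, R = -0.08, S = 0.04, T = 0.04, V = 0.10,
              W = 0.16, Y = 0.16)
  # positional preferences within each pentapeptide frame (positions 6-10
  # repeat the 1-5 pattern so concatenated decapeptides behave like their
  # two halves): aromatics favor mid/C-terminal positions, aliphatics the
  # termini, S/T the N-terminus, P the first two positions.
  adj <- matrix(0, 20L, 5L, dimnames = list(AA_ALPHABET, NULL))
  adj[AA_AROMATIC, ] <- rep(c(-0.02, -0.01, 0.02, 0.01, 0.01), each = 3)
  adj[c("C", "I", "L", "V"), ] <- rep(c(0.02, 0, -0.01, 0, 0.01), each = 4)
  adj[c("S", "T"), ] <- rep(c(0.01, 0, -0.01, 0, 0), each = 2)
  adj["P", ] <- c(0.015, 0.01, -0.01, -0.01, 0)
  w <- matrix(base_w, 20L, 10L, dimnames = list(AA_ALPHABET, NULL))
  w + cbind(adj, adj)
}

# deterministic surrogate component for one single peptide
surrogate_single <- function(pep, params) {
  res <- strsplit(pep, "")[[1]]
  n <- length(res)
  w <- sum(params$position_weights[cbind(match(res, AA_ALPHABET), seq_len(n))])
  arom <- res %in% AA_AROMATIC
  n_pairs <- sum(arom[-1] & arom[-n])
  q <- sum(AA_SIDE_CHAIN_CHARGE[res])
  params$base + w + params$pair_bonus * n_pairs -
    params$charge_penalty * abs(q)
}

# deterministic surrogate component for any system (single or mixed)
surrogate_deterministic <- function(system, params) {
  parts <- strsplit(system, "+", fixed = TRUE)[[1]]
  if (length(parts) == 1L) return(surrogate_single(parts, params))
  q <- vapply(parts, function(p)
    sum(AA_SIDE_CHAIN_CHARGE[strsplit(p, "")[[1]]]), numeric(1))
  ap <- mean(vapply(parts, surrogate_single, numeric(1), params = params))
  if (prod(q) < 0) ap <- ap + params$mix_boost * abs(q[1]) * abs(q[2])
  ap
}

# counter-based noise: label i depends only on (seed, i), never on call order
surrogate_noise <- function(seed, indices, sd) {
  if (sd == 0) return(rep(0, length(indices)))
  vapply(indices, function(i) {
    sub <- (as.numeric(seed) * 1000003 + i * 7919) %% 2147483629
    set.seed(as.integer(sub))
    stats::rnorm(1, 0, sd)
  }, numeric(1))
}

#' Surrogate aggregation propensity
#'
#' Deterministic residue/position score plus seeded Gaussian noise, clipped to
#' the empirical AP range. Single systems score
#' `base + sum(position_weights) + pair_bonus * (aromatic adjacencies) -
#' charge_penalty * |net charge|`; mixtures score the mean of their components
#' plus `mix_boost * |q1| * |q2|` when the components carry opposite net
#' side-chain charge. Noise for system `i` is derived from `(seed, i)` so
#' labels are independent of evaluation order.
#'
#' @param systems character vector of peptide systems.
#' @param params [surrogate_params()].
#' @param seed integer seed for the noise stream.
#' @param indices per-system noise counters (default the position in
#'   `systems`).
#' @return numeric AP labels.
#' @export
surrogate_ap <- function(systems, params = surrogate_params(), seed = 0L,
                         indices = seq_along(systems)) {
  systems <- peptide_system(systems, canonical = FALSE)
  det <- vapply(systems, surrogate_deterministic, numeric(1), params = params,
                USE.NAMES = FALSE)
  ap <- det + surrogate_noise(seed, indices, params$noise_sd)
  pmin(pmax(ap, params$clip[1]), params$clip[2])
}

#' Labelled surrogate dataset
#'
#' @inheritParams surrogate_ap
#' @return data.frame with columns `system, ap`; surrogate provenance (seed
#'   and parameters) in attribute `"provenance"`.
#' @export
label_dataset <- function(systems, params = surrogate_params(), seed = 0L) {
  if (!length(systems)) stop("no systems to label", call. = FALSE)
  out <- data.frame(system = peptide_system(systems, canonical = FALSE),
                    ap = surrogate_ap(systems, params, seed),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- list(source = "surrogate", seed = seed,
                                  params = params)
  out
}

# sample one pentapeptide with a prescribed net side-chain charge
sample_charged_pentapeptide <- function(q) {
  neutral <- setdiff(AA_ALPHABET, c("D", "E", "K", "R"))
  res <- sample(neutral, 5L, replace = TRUE)
  if (q != 0) {
    pos <- sample.int(5L, abs(q))
    res[pos] <- sample(if (q > 0) c("K", "R") else c("D", "E"), abs(q),
                       replace = TRUE)
  }
  paste(res, collapse = "")
}

#' Transferability fixture: pentapeptide pairs with planted mixing boost
#'
#' Samples `n_pairs` pentapeptide pairs, a fraction of them carrying opposite
#' net side-chain charges (the planted charge-complementarity regime), and
#' scores each pentapeptide, the concatenated decapeptide and the equimolar
#' mixture with the surrogate.
#'
#' @param n_pairs number of pairs.
#' @param params [surrogate_params()].
#' @param seed integer seed governing both pair sampling and label noise.
#' @param opposite_frac fraction of pairs forced to opposite net charges
#'   (charges of magnitude 1 or 2); the rest are neutral-neutral.
#' @return data.frame of transfer records, see [transfer_records()].
#' @export
make_transfer_fixture <- function(n_pairs, params = surrogate_params(),
                                  seed = 0L, opposite_frac = 0.9) {
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 1L) stop("n_pairs must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  opposite <- runif(n_pairs) < opposite_frac
  pen1 <- character(n_pairs); pen2 <- character(n_pairs)
  for (i in seq_len(n_pairs)) {
    if (opposite[i]) {
      q1 <- sample(1:2, 1L); q2 <- -sample(1:2, 1L)
    } else q1 <- q2 <- 0L
    pen1[i] <- sample_charged_pentapeptide(q1)
    pen2[i] <- sample_charged_pentapeptide(q2)
  }
  base_idx <- 4L * (seq_len(n_pairs) - 1L)
  ap1 <- surrogate_ap(pen1, params, seed, indices = base_idx + 1L)
  ap2 <- surrogate_ap(pen2, params, seed, indices = base_idx + 2L)
  deca <- surrogate_ap(paste0(pen1, pen2), params, seed, indices = base_idx + 3L)
  mix <- surrogate_ap(paste(pen1, pen2, sep = "+"), params, seed,
                      indices = base_idx + 4L)
  transfer_records(pen1, pen2, ap1, ap2, deca, mix)
}

#' Per-position residue effect estimator
#'
#' Estimates the surrogate's residue-by-position contribution table from
#' labels of equal-length peptides: the mean label of peptides carrying
#' residue `r` at position `p`, centered by the per-position mean. On a
#' complete factorial space with noiseless additive labels (pair bonus and
#' charge penalty off) this recovers `position_weights` exactly up to the
#' additive base.
#'
#' @param peptides character vector of equal-length peptides.
#' @param labels numeric labels.
#' @return 20 x length matrix of centered per-position residue effects.
#' @export
fit_position_weights <- function(peptides, labels) {
  peptides <- peptide(peptides)
  stopifnot(length(peptides) == length(labels))
  n <- unique(nchar(peptides))
  if (length(n) != 1L) stop("peptides must share one length", call. = FALSE)
  res <- do.call(rbind, strsplit(peptides, ""))
  out <- matrix(NA_real_, 20L, n, dimnames = list(AA_ALPHABET, NULL))
  for (p in seq_len(n)) {
    m <- tapply(labels, factor(res[, p], levels = AA_ALPHABET), mean)
    out[, p] <- m - mean(m)
  }
  out
}
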