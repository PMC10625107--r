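# Aggregation-law statistics: quartile partition of normalized AP', residue
# composition by range and position, residue contribution groups, and the
# transferability analysis of concatenated / mixed two-pentapeptide systems.

#' Quartile partition of normalized scores
#'
#' Ranges A = \[0, 0.25), B = \[0.25, 0.5), C = \[0.5, 0.75), D = \[0.75, 1\]
#' over a normalized score population; ties at the interior boundaries go
#' upward and D is closed at 1.
#'
#' @param scores numeric scores in \[0, 1\].
#' @return factor with levels `A, B, C, D` and attribute `"counts"`.
#' @examples
#' partition_ranges(c(0.1, 0.3, 0.6, 0.9))
#' @export
partition_ranges <- function(scores) {
  scores <- as.numeric(scores)
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1))
    stop("scores must be normalized to [0, 1]", call. = FALSE)
  f <- cut(scores, breaks = c(0, 0.25, 0.5, 0.75, 1), labels = c("A", "B", "C", "D"),
           right = FALSE, include.lowest = FALSE)
  f[scores == 1] <- "D"
  attr(f, "counts") <- table(f)
  f
}

#' Residue contribution groups
#'
#' Grouping of the 20 residues by their statistical contribution to
#' aggregation: 1 aromatics (F, Y, W), 2 aliphatic hydrophobics plus cysteine
#' (C, I, L, V), 3 polarizable (H, S, T), 4 (M, P), 5 residues unfavorable to
#' aggregation (charged D/E/K/R, polar N/Q, and A/G).
#'
#' @return named integer vector, residue -> group id 1--5.
#' @export
residue_groups <- function() {
  g <- c(F = 1L, Y = 1L, W = 1L,
         C = 2L, I = 2L, L = 2L, V = 2L,
         H = 3L, S = 3L, T = 3L,
         M = 4L, P = 4L,
         D = 5L, E = 5L, K = 5L, R = 5L, N = 5L, Q = 5L, A = 5L, G = 5L)
  g[AA_ALPHABET]
}

#' Residue composition by score range
#'
#' For each range of the partition, the percentage of each residue either
#' summed over all positions (denominator: residue occurrences in the range)
#' or per position (denominator: sequences in the range).
#'
#' @param peptides character vector of equal-length single peptides.
#' @param ranges factor from [partition_ranges()] aligned with `peptides`.
#' @param per_position if TRUE return a 3-d array residue x position x range.
#' @return overall: 20 x 4 matrix of percentages (columns A--D); per position:
#'   20 x length x 4 array. Each distribution sums to 100.
#' @export
composition_by_range <- function(peptides, ranges, per_position = FALSE) {
  peptides <- peptide(peptides)
  if (any(is_mixed(peptides)))
    stop("composition is defined for single peptides", call. = FALSE)
  stopifnot(length(peptides) == length(ranges))
  n <- unique(nchar(peptides))
  if (length(n) != 1L) stop("peptides must share one length", call. = FALSE)
  res <- do.call(rbind, strsplit(peptides, ""))
  lev <- levels(ranges)
  if (per_position) {
    out <- array(NA_real_, c(20L, n, length(lev)),
                 dimnames = list(AA_ALPHABET, NULL, lev))
    for (r in lev) {
      sel <- res[ranges == r, , drop = FALSE]
      for (p in seq_len(n)) {
        cnt <- table(factor(sel[, p], levels = AA_ALPHABET))
        out[, p, r] <- 100 * as.numeric(cnt) / max(nrow(sel), 1L)
      }
    }
    return(out)
  }
  out <- matrix(NA_real_, 20L, length(lev), dimnames = list(AA_ALPHABET, lev))
  for (r in lev) {
    sel <- res[ranges == r, , drop = FALSE]
    cnt <- table(factor(as.vector(sel), levels = AA_ALPHABET))
    out[, r] <- 100 * as.numeric(cnt) / max(length(sel), 1L)
  }
  out
}

#' Net side-chain charge of a peptide
#'
#' `(#K + #R) - (#D + #E)`; histidine and the termini contribute zero. The
#' terminal amine/carboxylate pair can optionally be included (it cancels for
#' a free peptide, so the default excludes it).
#'
#' @param peptides character vector of single peptides.
#' @param include_termini include the zwitterionic terminal charges (net 0 for
#'   an unmodified peptide; exposed for completeness).
#' @return integer vector of signed net charges.
#' @examples
#' net_side_chain_charge(c("NRMMR", "DMGID"))  # +2, -2
#' @export
net_side_chain_charge <- function(peptides, include_termini = FALSE) {
  peptides <- peptide(peptides)
  q <- vapply(strsplit(peptides, ""),
              function(res) sum(AA_SIDE_CHAIN_CHARGE[res]), numeric(1))
  as.integer(q)  # termini contribute +1 - 1 = 0 when included
}

#' Transferability records for pentapeptide pairs
#'
#' Assembles the per-pair quantities of the transferability analysis:
#' component APs, their average `ap_avepen = (ap_pen1 + ap_pen2) / 2`, the AP
#' of the concatenated decapeptide and of the equimolar mixture, the deltas
#' against the average, and the components' net side-chain charges.
#'
#' @param pen1,pen2 pentapeptide sequences.
#' @param ap_pen1,ap_pen2,ap_deca,ap_mixpen AP values of the components, the
#'   concatenation and the mixture.
#' @return data.frame with one row per pair.
#' @examples
#' transfer_records("NRMMR", "DMGID", 1.150, 1.144, 1.659, 1.612)
#' @export
transfer_records <- function(pen1, pen2, ap_pen1, ap_pen2, ap_deca,
                             ap_mixpen) {
  pen1 <- peptide(pen1); pen2 <- peptide(pen2)
  ap_avepen <- (ap_pen1 + ap_pen2) / 2
  data.frame(pen1 = pen1, pen2 = pen2,
             ap_pen1 = ap_pen1, ap_pen2 = ap_pen2, ap_avepen = ap_avepen,
             ap_deca = ap_deca, ap_mixpen = ap_mixpen,
             delta_deca = ap_deca - ap_avepen,
             delta_mix = ap_mixpen - ap_avepen,
             charge1 = net_side_chain_charge(pen1),
             charge2 = net_side_chain_charge(pen2),
             stringsAsFactors = FALSE)
}

#' Transferability summary
#'
#' Summarizes a set of transfer records: the fraction and median of positive
#' mixing deltas, maximum deltas, the correlation between concatenation and
#' mixing deltas, mean absolute deviations of the component average from the
#' concatenated and mixed APs, and the top pairs passing the selection filter
#' (by default `ap_deca > 1.5` and `delta_deca > 0.4`). Top-table ties break
#' by delta descending, then lexicographic sequence.
#'
#' @param records data.frame from [transfer_records()].
#' @param min_deca,min_delta selection thresholds on `ap_deca` and
#'   `delta_deca`.
#' @param top_k rows retained in the top tables.
#' @return list with elements `frac_mix_positive`, `median_delta_mix`,
#'   `max_delta_deca`, `max_delta_mix`, `cor_deltas`, `mae_deca`, `mae_mix`,
#'   `selected` (filter table) and `top_mix` (top pairs by `delta_mix`).
#' @export
transfer_analysis <- function(records, min_deca = 1.5, min_delta = 0.4,
                              top_k = 200L) {
  stopifnot(nrow(records) >= 1L)
  ord <- function(d, key) {
    d[order(-d[[key]], d$pen1, d$pen2), , drop = FALSE]
  }
  sel <- records[records$ap_deca > min_deca & records$delta_deca > min_delta, ,
                 drop = FALSE]
  list(frac_mix_positive = mean(records$delta_mix > 0),
       median_delta_mix = stats::median(records$delta_mix),
       max_delta_deca = max(records$delta_deca),
       max_delta_mix = max(records$delta_mix),
       cor_deltas = if (nrow(records) > 2L)
         stats::cor(records$delta_deca, records$delta_mix) else NA_real_,
       mae_deca = mean(abs(records$ap_deca - records$ap_avepen)),
       mae_mix = mean(abs(records$ap_mixpen - records$ap_avepen)),
       selected = ord(sel, "delta_deca"),
       top_mix = utils::head(ord(records, "delta_mix"), top_k))
}
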