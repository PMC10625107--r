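#' Validate peptide sequences
#'
#' A peptide is a string of 1--10 one-letter codes over the 20 standard amino
#' acids. Lowercase input is accepted and normalized to uppercase.
#'
#' @param x character vector of candidate sequences.
#' @return The validated, uppercased character vector.
#' @examples
#' peptide("NRMMR")
#' @export
peptide <- function(x) {
  x <- toupper(as.character(x))
  n <- nchar(x)
  if (any(is.na(x)) || any(n < 1L | n > 10L))
    stop("peptide length must be between 1 and 10 residues", call. = FALSE)
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), x)
  if (any(bad)) {
    offending <- gsub(sprintf("[%s]", paste(AA_ALPHABET, collapse = "")), "",
                      x[bad])
    stop("invalid residue(s) ", paste(unique(strsplit(paste(offending,
         collapse = ""), "")[[1]]), collapse = ", "),
         " in sequence(s) ", paste(x[bad], collapse = ", "), call. = FALSE)
  }
  x
}

#' Peptide systems: single peptides or two-component mixtures
#'
#' A system is either a single peptide (`"NRMMR"`) or an equimolar mixture of
#' two peptides written `"PEN1+PEN2"`. Mixture identity is order-insensitive:
#' the canonical form sorts the two components lexicographically, so
#' `"B+A"` and `"A+B"` name the same system.
#'
#' @param x character vector of system strings.
#' @param canonical sort mixture components into canonical order (default TRUE).
#' @return character vector of validated system strings.
#' @examples
#' peptide_system(c("NRMMR", "DMGID+NRMMR"))
#' @export
peptide_system <- function(x, canonical = TRUE) {
  x <- toupper(as.character(x))
  parts <- strsplit(x, "+", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc > 2L))
    stop("mixed systems have exactly two components", call. = FALSE)
  vapply(parts, function(p) {
    p <- peptide(p)
    if (length(p) == 2L && canonical) p <- sort(p)
    paste(p, collapse = TOK_PLUS)
  }, character(1))
}

#' @rdname peptide_system
#' @export
is_mixed <- function(x) {
  grepl("+", as.character(x), fixed = TRUE)
}

#' Cardinality of the oligopeptide sequence space
#'
#' For single peptides of a given length the space holds `20^length`
#' sequences (3.2 million pentapeptides). For two-component mixtures the
#' count is the number of unordered pairs including self-pairs,
#' `N (N + 1) / 2` with `N = 20^length`.
#'
#' @param length peptide length, 1--10.
#' @param mixed count unordered two-component mixtures instead of single
#'   sequences.
#' @return a double (counts exceed the integer range).
#' @examples
#' space_size(5)            # 3.2e6 pentapeptides
#' space_size(5, mixed = TRUE)
#' @export
space_size <- function(length, mixed = FALSE) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L || length > 10L)
    stop("length must be between 1 and 10", call. = FALSE)
  n <- 20 ^ length
  if (mixed) n * (n + 1) / 2 else n
}

#' Latin-hypercube sample of peptide sequences
#'
#' Each sequence position is one Latin-hypercube dimension: the unit interval
#' is divided into `n_samples` strata per position, one point is drawn per
#' stratum, strata are independently permuted across positions, and each
#' point `u` is mapped to residue `floor(20 u)` of the alphabetically ordered
#' amino-acid alphabet. When `n_samples` is a multiple of 20 every residue
#' therefore appears exactly `n_samples / 20` times at every position.
#' Duplicate sequences are kept (a uniform stratification of positions does
#' not imply distinct strings) and flagged in the `"duplicates"` attribute.
#'
#' @param length peptide length.
#' @param n_samples number of sequences to draw.
#' @param seed integer seed; the draw is fully reproducible.
#' @return character vector of `n_samples` peptides with attribute
#'   `"duplicates"` (logical vector marking repeated occurrences).
#' @examples
#' lhs_sample(5, 20, seed = 1)
#' @export
lhs_sample <- function(length, n_samples, seed = 0L) {
  length <- as.integer(length)
  if (length < 1L || length > 10L) stop("length must be between 1 and 10",
                                        call. = FALSE)
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(n_samples, length)
  idx <- floor(20 * u) + 1L
  idx[idx > 20L] <- 20L  # guard u == 1 edge of the last stratum
  seqs <- apply(idx, 1L, function(i) paste(AA_ALPHABET[i], collapse = ""))
  dup <- duplicated(seqs)
  if (any(dup))
    message(sum(dup), " duplicate sequence(s) in LHS draw (kept)")
  attr(seqs, "duplicates") <- dup
  seqs
}

#' Enumerate the complete sequence space in lexicographic order
#'
#' Returns sequences in lexicographic order of the fixed alphabet, optionally
#' truncated. For streaming over large spaces without materializing them use
#' [space_iterator()].
#'
#' @param length peptide length.
#' @param limit optional maximum number of sequences to return.
#' @return character vector of sequences.
#' @examples
#' enumerate_space(2, limit = 3)  # "AA" "AC" "AD"
#' @export
enumerate_space <- function(length, limit = NULL) {
  total <- space_size(length)
  n <- if (is.null(limit)) total else min(total, limit)
  if (n > 5e7) stop("refusing to materialize > 5e7 sequences; use space_iterator()",
                    call. = FALSE)
  seqs_from_ranks(seq_len(n) - 1, length)
}

# rank (0-based, lexicographic) -> sequence string, vectorized
seqs_from_ranks <- function(ranks, length) {
  m <- matrix("", nrow = base::length(ranks), ncol = length)
  r <- ranks
  for (p in length:1) {
    m[, p] <- AA_ALPHABET[(r %% 20) + 1]
    r <- r %/% 20
  }
  do.call(paste0, split(m, col(m)))
}

#' Chunked iterator over the complete sequence space
#'
#' @param length peptide length.
#' @param chunk_size number of sequences yielded per call.
#' @return a function; each call returns the next chunk (character vector) or
#'   `NULL` when exhausted.
#' @examples
#' it <- space_iterator(2, chunk_size = 150)
#' length(it())  # 150
#' @export
space_iterator <- function(length, chunk_size = 100000L) {
  total <- space_size(length)
  pos <- 0
  function() {
    if (pos >= total) return(NULL)
    n <- min(chunk_size, total - pos)
    out <- seqs_from_ranks(pos + seq_len(n) - 1, length)
    pos <<- pos + n
    out
  }
}

#' Tokenize peptide systems for the regression network
#'
#' Single systems emit their residue tokens followed by blank placeholders up
#' to `model_length`; mixed systems emit the first component, the `'+'`
#' connector, then the second component. The placeholder occupies a dedicated
#' vocabulary id and never encodes a residue.
#'
#' @param systems character vector of peptide systems.
#' @param model_length fixed encoded length (5 or 10 for single models, 11 for
#'   mixed pentapeptides).
#' @param canonical canonicalize mixture order before encoding (default FALSE:
#'   training-time augmentation relies on keeping both orders).
#' @return integer matrix, one row per system, `model_length` columns, values
#'   indexing `apscreen_vocabulary()`.
#' @examples
#' tokenize_systems("NRMMR", 10)
#' @export
tokenize_systems <- function(systems, model_length, canonical = FALSE) {
  systems <- peptide_system(systems, canonical = canonical)
  vocab <- AA_VOCAB
  pad_id <- match(TOK_PAD, vocab)
  enc <- strsplit(systems, "")
  n_tok <- lengths(enc)
  if (any(n_tok > model_length))
    stop("encoded length ", max(n_tok), " exceeds model_length ",
         model_length, call. = FALSE)
  out <- matrix(pad_id, nrow = length(systems), ncol = model_length)
  for (i in seq_along(enc))
    out[i, seq_len(n_tok[i])] <- match(enc[[i]], vocab)
  storage.mode(out) <- "integer"
  out
}

#' @rdname tokenize_systems
#' @param tokens integer matrix as produced by `tokenize_systems()`.
#' @export
detokenize_systems <- function(tokens) {
  apply(tokens, 1L, function(row) {
    chars <- AA_VOCAB[row]
    paste(chars[chars != TOK_PAD], collapse = "")
  })
}

#' The model token vocabulary
#'
#' @return character vector: 20 residues, the `'+'` connector, the blank
#'   placeholder.
#' @export
apscreen_vocabulary <- function() AA_VOCAB

#' Swap augmentation for mixed systems
#'
#' Training data for two-component mixtures is augmented by swapping the
#' component order (B+A for every A+B) so the network cannot latch onto an
#' arbitrary position effect; labels are duplicated along with the systems.
#' Self-pairs (A+A) are not duplicated.
#'
#' @param systems character vector of mixed systems.
#' @param labels optional numeric labels aligned with `systems`.
#' @return data.frame with columns `system` and (if given) `label`.
#' @examples
#' augment_mixed(c("AAAAA+CCCCC"))
#' @export
augment_mixed <- function(systems, labels = NULL) {
  systems <- peptide_system(systems, canonical = FALSE)
  if (!all(is_mixed(systems)))
    stop("augment_mixed applies to mixed systems only", call. = FALSE)
  parts <- strsplit(systems, "+", fixed = TRUE)
  swapped <- vapply(parts, function(p) paste(rev(p), collapse = TOK_PLUS),
                    character(1))
  keep <- swapped != systems
  out <- data.frame(system = c(systems, swapped[keep]),
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(systems))
    out$label <- c(labels, labels[keep])
  }
  out
}
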