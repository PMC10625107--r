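# Readers and writers. CSV files are comma-separated UTF-8 with '#'-prefixed
# metadata lines so every artifact carries its own provenance (seed,
# normalization constants, score parameters). FASTA I/O covers one record per
# system; mixed systems may carry the '+' connector in the sequence line or,
# equivalently, a "pen1+pen2" system string in the header.

#' Read peptide systems from FASTA or CSV
#'
#' CSV files need a `sequence` column (optionally `ap`/`label`); FASTA files
#' hold one record per system. A `'+'` inside a sequence denotes a
#' two-component mixed system. Invalid residues are reported with the
#' offending record numbers.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"csv"`.
#' @return data.frame with column `system` and, when present in the input,
#'   `ap`.
#' @export
read_peptides <- function(path, format = c("auto", "fasta", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) %in% c("fa", "fasta", "faa"))
      "fasta" else "csv"
  if (format == "fasta") {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    if (!length(hdr)) stop("no FASTA records in ", path, call. = FALSE)
    ends <- c(hdr[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
    }, character(1))
    # a mixed system may be declared in the header instead of the sequence
    headers <- sub("^>\\s*", "", lines[hdr])
    from_header <- grepl("+", headers, fixed = TRUE) &
      !grepl("+", seqs, fixed = TRUE)
    seqs[from_header] <- vapply(strsplit(headers[from_header], "\\s+"),
                                `[[`, character(1), 1L)
    df <- data.frame(system = seqs, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    seq_col <- intersect(c("system", "sequence"), names(df))
    if (!length(seq_col))
      stop("CSV needs a 'sequence' (or 'system') column", call. = FALSE)
    names(df)[names(df) == seq_col[1]] <- "system"
    lab_col <- intersect(c("ap", "label"), names(df))
    df <- df[, c("system", lab_col), drop = FALSE]
    if (length(lab_col)) names(df)[2] <- "ap"
  }
  ok <- vapply(df$system, function(s)
    !inherits(try(peptide_system(s, canonical = FALSE), silent = TRUE),
              "try-error"), logical(1))
  if (!all(ok))
    stop("invalid sequence(s) at record(s) ",
         paste(which(!ok), collapse = ", "), ": ",
         paste(utils::head(df$system[!ok], 5L), collapse = ", "),
         call. = FALSE)
  df$system <- peptide_system(df$system, canonical = FALSE)
  rownames(df) <- NULL
  df
}

#' Write peptide systems as FASTA
#'
#' @param systems character vector of systems.
#' @param path output file.
#' @param names optional record names (default `seq1, seq2, ...`).
#' @export
write_peptides_fasta <- function(systems, path, names = NULL) {
  systems <- peptide_system(systems, canonical = FALSE)
  if (is.null(names)) names <- paste0("seq", seq_along(systems))
  writeLines(as.vector(rbind(paste0(">", names), systems)), path)
  invisible(path)
}

#' Write and read annotated score tables
#'
#' Scores are written as CSV preceded by `#`-prefixed metadata lines carrying
#' the normalization constants, score parameters and seed, so the file is
#' reproducible from its own header. `read_scores()` restores the data and
#' the metadata (attribute `"metadata"`).
#'
#' @param scores data.frame (e.g. from [score_table()]).
#' @param path output file.
#' @param annotations named list of metadata to embed.
#' @export
write_scores <- function(scores, path, annotations = list()) {
  constants <- attr(scores, "constants")
  if (!is.null(constants) && is.null(annotations$norm_constants))
    annotations$norm_constants <- constants
  hc <- attr(scores, "hc_params")
  if (!is.null(hc) && is.null(annotations$hc_params))
    annotations$hc_params <- unlist(hc)
  meta <- vapply(names(annotations), function(k)
    paste0("# ", k, ": ",
           paste(format(annotations[[k]], digits = 15), collapse = ",")),
    character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(unname(meta), con)
  utils::write.csv(scores, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- sub("^#\\s*", "", m)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*:\\s*", "", kv)
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    meta[[key]] <- if (any(is.na(num))) val else num
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                        stringsAsFactors = FALSE)
  attr(df, "metadata") <- meta
  df
}
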