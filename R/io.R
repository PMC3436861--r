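#' Read a FASTA sequence set
#'
#' Sequences are case-folded to upper case and validated against the
#' alphabet; the first non-alphabet character is reported with its record
#' name and offset.  Headers are preserved as dataset names.
#'
#' @param path FASTA file path.
#' @param alphabet an `mb_alphabet`; defaults to DNA.
#' @return An `mb_dataset`.
#' @export
read_fasta <- function(path, alphabet = dna_alphabet()) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("no sequences in '%s'", path))
  sequence_dataset(as.character(set), alphabet, names = names(set))
}

#' Write a dataset as FASTA
#'
#' @param dataset an `mb_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(dataset, path) {
  set <- Biostrings::BStringSet(dataset$sequences)
  names(set) <- dataset$names
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Parse a JASPAR-style position frequency matrix
#'
#' Plain-text PFM dialect: an optional `>` header line carrying the
#' matrix identifier and name, then one row per base in A, C, G, T order,
#' e.g. `A [ 4 19 0 ]` (brackets optional).  Counts are normalised per
#' position with the given pseudocount into a PWM; the number of columns
#' defines the motif width.
#'
#' @param path PFM file path.
#' @param pseudocount nonnegative count added to every cell before
#'   normalisation.
#' @return An `mb_pwm` (DNA alphabet) with attributes `identifier` and
#'   `name` from the header, if present.
#' @export
parse_jaspar_pfm <- function(path, pseudocount = 0) {
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty PFM file '%s'", path))
  id <- NA_character_; nm <- NA_character_
  if (startsWith(lines[1L], ">")) {
    hdr <- strsplit(trimws(sub("^>", "", lines[1L])), "[ \t]+")[[1L]]
    id <- hdr[1L]
    if (length(hdr) > 1L) nm <- paste(hdr[-1L], collapse = " ")
    lines <- lines[-1L]
  }
  alphabet <- dna_alphabet()
  if (length(lines) != 4L)
    stop("expected one row per base (A, C, G, T)")
  rows <- lapply(seq_along(lines), function(i) {
    ln <- trimws(lines[i])
    base <- toupper(substr(ln, 1L, 1L))
    if (base != alphabet$symbols[i])
      stop(sprintf("row %d: expected base %s, found '%s'",
                   i, alphabet$symbols[i], base))
    body <- gsub("[][]", " ", substr(ln, 2L, nchar(ln)))
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "[ \t]+")[[1L]]))
    if (anyNA(vals) || length(vals) == 0L)
      stop(sprintf("row %d: could not parse counts", i))
    if (any(vals < 0)) stop(sprintf("row %d: negative counts", i))
    vals
  })
  if (length(unique(lengths(rows))) != 1L)
    stop("ragged PFM: base rows have different numbers of columns")
  counts <- do.call(rbind, rows)          # 4 x W, bases in rows
  m <- t(counts) + pseudocount            # W x 4, positions in rows
  if (any(rowSums(m) <= 0))
    stop("a PFM column has zero total count and zero pseudocount")
  pwm <- make_pwm(m / rowSums(m), alphabet)
  attr(pwm, "identifier") <- id
  attr(pwm, "name") <- nm
  pwm
}
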