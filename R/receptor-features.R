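# Receptor sequence features: amino-acid composition, dipeptide composition,
# and exact overlapping motif occurrence counts, plus the corpus-level motif
# filter.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DIPEPTIDES <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))

check_sequence <- function(seq, strict = TRUE, min_len = 1L) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    gpcr_stop("sequence must be a single string", "gpcr_sequence_error")
  seq <- toupper(seq)
  if (nchar(seq) < min_len)
    gpcr_stop(sprintf("sequence shorter than %d residues", min_len),
              "gpcr_sequence_error")
  bad <- setdiff(strsplit(seq, "")[[1]], AA_ALPHABET)
  if (length(bad)) {
    if (strict)
      gpcr_stop(sprintf("invalid residue(s) %s in sequence",
                        paste(unique(bad), collapse = ", ")),
                "gpcr_sequence_error")
    # lenient: non-standard residues (B, J, O, U, X, Z, ...) are kept in
    # place so they break dipeptide windows and motif matches, but are not
    # themselves counted
  }
  seq
}

#' Amino-acid composition (20 counts)
#'
#' Raw counts of each standard amino acid, in fixed alphabetical order
#' A, C, D, ..., Y. With `normalize = TRUE` counts are divided by the
#' sequence length.
#'
#' @param seq Amino-acid sequence string.
#' @param strict Reject non-standard residues (default); lenient mode skips
#'   them.
#' @param normalize Return proportions instead of counts.
#' @return Named numeric vector of length 20.
#' @export
aa_frequencies <- function(seq, strict = TRUE, normalize = FALSE) {
  seq <- check_sequence(seq, strict)
  chars <- strsplit(seq, "")[[1]]
  out <- vapply(AA_ALPHABET, function(a) sum(chars == a), 0)
  if (normalize) out <- out / nchar(seq)
  out
}

#' Dipeptide composition (400 counts)
#'
#' Counts of all overlapping length-2 windows, in lexicographic order
#' AA, AC, ..., YY; the counts sum to `length - 1` for a standard-alphabet
#' sequence.
#'
#' @inheritParams aa_frequencies
#' @return Named numeric vector of length 400.
#' @export
dipeptide_frequencies <- function(seq, strict = TRUE, normalize = FALSE) {
  seq <- check_sequence(seq, strict, min_len = 2L)
  n <- nchar(seq)
  wins <- substring(seq, 1:(n - 1L), 2:n)
  tab <- table(factor(wins, levels = DIPEPTIDES))
  out <- setNames(as.numeric(tab), DIPEPTIDES)
  if (normalize) out <- out / (n - 1L)
  out
}

#' Count overlapping motif occurrences
#'
#' Number of exact, possibly overlapping occurrences of `motif` in `seq`
#' (`count_motif("AAAA", "AA")` is 3).
#'
#' @param seq Amino-acid sequence string.
#' @param motif Non-empty motif string over the amino-acid alphabet.
#' @return Non-negative integer count.
#' @export
count_motif <- function(seq, motif) {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif))
    gpcr_stop("motif must be a single non-empty string", "gpcr_sequence_error")
  if (!all(strsplit(toupper(motif), "")[[1]] %in% AA_ALPHABET))
    gpcr_stop(sprintf("motif '%s' contains non-amino-acid characters", motif),
              "gpcr_sequence_error")
  hits <- gregexpr(paste0("(?=", toupper(motif), ")"), toupper(seq),
                   perl = TRUE)[[1]]
  if (hits[1L] == -1L) 0L else length(hits)
}

#' Filter motifs by corpus-wide occurrence
#'
#' Motifs whose total occurrence count summed over all receptors is at most
#' 1 carry no discriminative information and are excluded; motifs with a
#' total of 2 or more are retained in their input order.
#'
#' @param motif_counts Numeric matrix, rows = receptors, columns = motifs
#'   (column names = motif strings).
#' @return Character vector of retained motifs, input order preserved.
#' @export
filter_motifs <- function(motif_counts) {
  if (is.null(colnames(motif_counts)))
    gpcr_stop("motif_counts needs motif strings as column names",
              "gpcr_argument_error")
  colnames(motif_counts)[colSums(motif_counts) >= 2]
}

#' Assemble the per-receptor feature vector
#'
#' Concatenation of amino-acid composition (20), dipeptide composition (400)
#' and per-motif occurrence counts, names prefixed with the feature-set tags
#' `1AAF:`, `2AAF:`, `MF:`.
#'
#' @param seq Amino-acid sequence string.
#' @param motifs Ordered, duplicate-free motif list (may be empty).
#' @param strict,normalize Passed to the composition features.
#' @return Named numeric vector of length `420 + length(motifs)`.
#' @export
receptor_vector <- function(seq, motifs = character(0), strict = TRUE,
                            normalize = FALSE) {
  if (anyDuplicated(motifs))
    gpcr_stop("motif list must be duplicate-free", "gpcr_argument_error")
  aa1 <- aa_frequencies(seq, strict, normalize)
  aa2 <- dipeptide_frequencies(seq, strict, normalize)
  mf <- vapply(motifs, function(m) as.numeric(count_motif(seq, m)), 0)
  c(setNames(aa1, paste0("1AAF:", names(aa1))),
    setNames(aa2, paste0("2AAF:", names(aa2))),
    if (length(motifs)) setNames(mf, paste0("MF:", motifs)) else NULL)
}

#' Read receptor sequences from FASTA
#'
#' The receptor identifier is the first whitespace-delimited token of the
#' header line.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of sequences (names = receptor IDs).
#' @export
read_receptor_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(ss), "[ \t]"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    gpcr_stop(sprintf("duplicate receptor id '%s' in %s",
                      ids[duplicated(ids)][1L], path), "gpcr_io_error")
  setNames(as.character(ss), ids)
}

#' Read a motif list (one motif per line)
#'
#' Empty lines and `#` comments are ignored.
#'
#' @param path Path to the motif file.
#' @return Character vector of motifs.
#' @export
read_motifs <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
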