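#' Reverse complement of a nucleotide sequence
#'
#' Standard Watson-Crick reverse complement over `{A, C, G, T, N}`;
#' `N` maps to `N`.
#'
#' @param nt_sequence Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' reverse_complement("ATGC")
reverse_complement <- function(nt_sequence) {
  stopifnot(is.character(nt_sequence))
  bad <- grepl("[^ACGTN]", nt_sequence)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(nt_sequence)))
}

frame_offsets <- c(`1` = 0L, `2` = 1L, `3` = 2L,
                   `-1` = 0L, `-2` = 1L, `-3` = 2L)

#' Six-frame translation of a nucleotide sequence
#'
#' Translates the forward strand at offsets 0, 1, 2 (frames +1, +2, +3) and
#' the reverse complement at offsets 0, 1, 2 (frames -1, -2, -3). Stop codons
#' are emitted as `*`; 1-2 trailing nucleotides that do not fill a codon are
#' dropped. Sequences shorter than 3 nt yield empty translations.
#'
#' @param nt_sequence A single nucleotide sequence (character).
#' @param genetic_code_id NCBI genetic code identifier (default "11",
#'   bacterial/archaeal).
#' @return A tibble with columns `frame` (+1..+3, -1..-3), `offset`, and
#'   `protein`.
#' @export
#' @examples
#' six_frame_translate("ATGAAA")
six_frame_translate <- function(nt_sequence, genetic_code_id = "11") {
  stopifnot(is.character(nt_sequence), length(nt_sequence) == 1L)
  code <- Biostrings::getGeneticCode(as.character(genetic_code_id))
  strands <- c(nt_sequence, reverse_complement(nt_sequence))
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  protein <- vapply(frames, function(f) {
    s <- strands[[if (f > 0) 1L else 2L]]
    off <- frame_offsets[[as.character(f)]]
    n_codon <- (nchar(s) - off) %/% 3L
    if (n_codon < 1L) return("")
    dna <- Biostrings::DNAString(substr(s, off + 1L, off + 3L * n_codon))
    as.character(Biostrings::translate(dna, genetic.code = code,
                                       no.init.codon = TRUE))
  }, character(1))
  tibble(frame = frames,
         offset = unname(frame_offsets[as.character(frames)]),
         protein = protein)
}

# Map an amino-acid interval [aa_start, aa_end] within a translation frame
# back to 1-based inclusive forward-strand nucleotide coordinates.
frame_to_nt <- function(frame, aa_start, aa_end, replicon_length) {
  off <- frame_offsets[[as.character(frame)]]
  if (frame > 0) {
    c(off + 3L * (aa_start - 1L) + 1L, off + 3L * aa_end)
  } else {
    # positions on the reverse complement, flipped to forward coordinates
    c(replicon_length - (off + 3L * aa_end) + 1L,
      replicon_length - (off + 3L * (aa_start - 1L) + 1L) + 1L)
  }
}
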