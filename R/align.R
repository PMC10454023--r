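#' Optimal local protein alignment
#'
#' Smith-Waterman local alignment under affine gap penalties (a gap of length
#' L costs `gap_open + L * gap_extend`), delegated to
#' [Biostrings::pairwiseAlignment()]. Returns the single maximum-scoring local
#' alignment; when no residue pair scores positively the raw score is 0 and
#' the alignment is empty.
#'
#' @param query,subject Protein sequences (single character strings) over the
#'   matrix alphabet.
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param params [alignment_params()] supplying gap penalties and the
#'   bit-score normalisation.
#' @return A one-row tibble (an HSP): `query_start`, `query_end`,
#'   `subject_start`, `subject_end` (1-based inclusive, amino acids),
#'   `align_length`, `n_identities`, `raw_score`, `bit_score`. Empty
#'   alignments carry `NA` coordinates and raw score 0.
#' @export
#' @examples
#' local_align("MKLV", "MKLV")
local_align <- function(query, subject, matrix = blosum62(),
                        params = alignment_params()) {
  stopifnot(is.character(query), length(query) == 1L, nzchar(query),
            is.character(subject), length(subject) == 1L, nzchar(subject))
  check_alphabet(c(query, subject), matrix)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(subject),
    type = "local", substitutionMatrix = matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  raw <- Biostrings::score(al)
  if (raw <= 0) return(empty_hsp(params))
  tibble(
    query_start = Biostrings::start(Biostrings::pattern(al)),
    query_end = Biostrings::end(Biostrings::pattern(al)),
    subject_start = Biostrings::start(Biostrings::subject(al)),
    subject_end = Biostrings::end(Biostrings::subject(al)),
    align_length = Biostrings::nchar(al),
    n_identities = Biostrings::nmatch(al),
    raw_score = raw,
    bit_score = bit_score(raw, params)
  )
}

empty_hsp <- function(params = alignment_params()) {
  tibble(query_start = NA_integer_, query_end = NA_integer_,
         subject_start = NA_integer_, subject_end = NA_integer_,
         align_length = 0L, n_identities = 0L,
         raw_score = 0, bit_score = bit_score(0, params))
}

check_alphabet <- function(sequences, matrix) {
  letters_ok <- rownames(matrix)
  residues <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  bad <- setdiff(residues, letters_ok)
  if (length(bad) > 0) {
    stop("residue(s) outside the matrix alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
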