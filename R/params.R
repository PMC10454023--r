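#' Alignment scoring parameters
#'
#' Bundles the affine gap penalties, the Karlin-Altschul normalisation
#' constants used to express raw Smith-Waterman scores in bits, and the
#' genetic code used for six-frame translation. The defaults are the classic
#' gapped BLOSUM62 11/1 parameterisation (lambda = 0.267, K = 0.041) with the
#' bacterial/archaeal genetic code (transl_table 11), i.e. the scoring system
#' a protein-vs-translated-genome search runs under by default.
#'
#' @param gap_open Positive integer, penalty for opening a gap.
#' @param gap_extend Positive integer, penalty per gapped residue
#'   (a gap of length L costs `gap_open + L * gap_extend`).
#' @param lambda Karlin-Altschul scale (per raw-score unit), > 0.
#' @param K Karlin-Altschul constant, in (0, 1).
#' @param genetic_code_id NCBI genetic code identifier (character or integer).
#'
#' @return A list of class `alignment_params`.
#' @export
#' @examples
#' alignment_params()
alignment_params <- function(gap_open = 11L, gap_extend = 1L,
                             lambda = 0.267, K = 0.041,
                             genetic_code_id = "11") {
  stopifnot(gap_open >= 1, gap_extend >= 1, gap_extend <= gap_open,
            lambda > 0, K > 0, K < 1)
  structure(
    list(gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         lambda = lambda, K = K, genetic_code_id = as.character(genetic_code_id)),
    class = "alignment_params"
  )
}

#' BLOSUM62 substitution matrix
#'
#' Returns the BLOSUM62 matrix shipped with Biostrings, which covers the 20
#' amino acids plus the ambiguity codes B, Z, X and the stop symbol `*`
#' (scored -4 against every residue and +1 against itself, so alignments may
#' cross translated stop codons at a penalty).
#'
#' @return An integer matrix with identical row and column alphabets.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Read or write a substitution matrix in NCBI text format
#'
#' The NCBI matrix text format is a whitespace-separated square table with a
#' header row of residue letters and one leading residue letter per row;
#' lines starting with `#` are comments.
#'
#' @param path File path.
#' @param matrix Integer substitution matrix with residue dimnames.
#' @return `read_substitution_matrix()` returns the matrix;
#'   `write_substitution_matrix()` returns `path` invisibly.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  alphabet <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  letters <- vapply(rows, `[[`, character(1), 1L)
  m <- do.call(rbind, lapply(rows, function(r) as.integer(r[-1])))
  dimnames(m) <- list(letters, alphabet)
  validate_substitution_matrix(m)
  m
}

#' @rdname read_substitution_matrix
#' @export
write_substitution_matrix <- function(matrix, path) {
  validate_substitution_matrix(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(" ", colnames(matrix)), collapse = " "), con)
  for (i in seq_len(nrow(matrix))) {
    writeLines(paste(c(rownames(matrix)[i], matrix[i, ]), collapse = " "), con)
  }
  invisible(path)
}

validate_substitution_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      !identical(rownames(m), colnames(m))) {
    stop("substitution matrix must be square with matching row/column alphabets",
         call. = FALSE)
  }
  if (!isTRUE(all(m == t(m)))) {
    stop("substitution matrix must be symmetric", call. = FALSE)
  }
  invisible(m)
}

#' Convert a raw local-alignment score to bits
#'
#' Applies the Karlin-Altschul normalisation
#' `bits = (lambda * raw - ln K) / ln 2`, a strictly increasing function of
#' the raw score. Hit filtering in this package is applied on this scale.
#'
#' @param raw_score Non-negative numeric vector of raw alignment scores.
#' @param params An [alignment_params()] object supplying `lambda` and `K`.
#' @return Numeric vector of bit scores.
#' @export
#' @examples
#' bit_score(0, alignment_params())  # -ln(K)/ln(2)
bit_score <- function(raw_score, params = alignment_params()) {
  stopifnot(all(raw_score >= 0))
  (params$lambda * raw_score - log(params$K)) / log(2)
}

#' Hit filter on bit score and query coverage
#'
#' A probe-vs-genome comparison is recorded as a genomic hit when the best
#' alignment bit score exceeds 150 and the query coverage exceeds 70%. Both
#' thresholds are strict.
#'
#' @param best_bit_score Numeric vector of best bit scores.
#' @param query_coverage Numeric vector of query coverages in `[0, 1]`.
#' @param score_threshold Score cutoff (default 150, strict).
#' @param coverage_threshold Coverage cutoff (default 0.70, strict).
#' @return Logical vector.
#' @export
#' @examples
#' passes_filter(151, 0.71)  # TRUE
#' passes_filter(150, 0.95)  # FALSE: the bound is strict
passes_filter <- function(best_bit_score, query_coverage,
                          score_threshold = 150, coverage_threshold = 0.70) {
  stopifnot(all(query_coverage >= 0 & query_coverage <= 1))
  best_bit_score > score_threshold & query_coverage > coverage_threshold
}
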