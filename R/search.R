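#' Search one genome with one protein probe
#'
#' Desk-scale stand-in for a translated protein-vs-genome (TBlastN-style)
#' search: every non-excluded replicon is translated in all six frames and the
#' probe is locally aligned against each translation. One HSP (the optimal
#' local alignment) is reported per frame when it reaches the HSP reporting
#' floor. Replicon-level results are merged into a single hit per
#' (probe, genome): the best bit score is the maximum across replicons and
#' the query coverage is the fraction of probe residues covered by the union
#' of HSP query ranges on the best-scoring replicon.
#'
#' @param probe A one-row data frame with columns `accession` and `sequence`
#'   (protein).
#' @param genome A data frame of replicons for one genome, with columns
#'   `genome_accession`, `replicon_accession`, `is_plasmid`, `sequence`.
#' @param matrix,params Scoring system, see [local_align()].
#' @param exclude_plasmids When `TRUE` (default), plasmid-flagged replicons
#'   contribute nothing, mirroring a "NOT plasmid" title filter.
#' @param score_threshold,coverage_threshold Hit filter, see [passes_filter()].
#' @param hsp_floor_bits HSPs below this bit score are not reported (affects
#'   coverage aggregation only, never the best score).
#' @return A one-row tibble: `probe_accession`, `genome_accession`,
#'   `best_bit_score`, `query_coverage`, `n_hsps`, `passes_filter`, and a
#'   list-column `hsps` of per-frame HSP tables.
#' @export
search_genome <- function(probe, genome, matrix = blosum62(),
                          params = alignment_params(),
                          exclude_plasmids = TRUE,
                          score_threshold = 150, coverage_threshold = 0.70,
                          hsp_floor_bits = 50) {
  stopifnot(nrow(genome) >= 1)
  genome_accession <- genome$genome_accession[[1]]
  reps <- if (exclude_plasmids) genome[!genome$is_plasmid, , drop = FALSE] else genome
  probe_seq <- probe$sequence[[1]]
  probe_len <- nchar(probe_seq)
  probe_aa <- Biostrings::AAString(probe_seq)

  hsps <- purrr::map_dfr(seq_len(nrow(reps)), function(i) {
    align_frames(probe_aa,
                 replicon_accession = reps$replicon_accession[[i]],
                 nt_sequence = reps$sequence[[i]],
                 matrix = matrix, params = params,
                 hsp_floor_bits = hsp_floor_bits)
  })

  summarise_hit(probe$accession[[1]], genome_accession, probe_len, hsps,
                params, score_threshold, coverage_threshold)
}

# Align a probe against all six frames of one replicon; returns the HSPs
# (one optimal local alignment per frame) at or above the reporting floor.
align_frames <- function(probe_aa, replicon_accession, nt_sequence,
                         matrix, params, hsp_floor_bits,
                         frames_aa = NULL) {
  if (is.null(frames_aa)) {
    tr <- six_frame_translate(nt_sequence, params$genetic_code_id)
    frames_aa <- setNames(tr$protein, tr$frame)
  }
  frames_aa <- frames_aa[nzchar(frames_aa)]
  if (length(frames_aa) == 0) return(hsp_prototype())
  subject_set <- Biostrings::AAStringSet(unname(frames_aa))
  raw <- Biostrings::pairwiseAlignment(
    pattern = subject_set, subject = probe_aa, type = "local",
    substitutionMatrix = matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE
  )
  bits <- bit_score(pmax(raw, 0), params)
  keep <- which(raw > 0 & bits >= hsp_floor_bits)
  if (length(keep) == 0) return(hsp_prototype())
  L <- nchar(nt_sequence)
  purrr::map_dfr(keep, function(i) {
    frame <- as.integer(names(frames_aa)[[i]])
    al <- Biostrings::pairwiseAlignment(
      pattern = subject_set[[i]], subject = probe_aa, type = "local",
      substitutionMatrix = matrix,
      gapOpening = params$gap_open, gapExtension = params$gap_extend
    )
    nt <- frame_to_nt(frame,
                      Biostrings::start(Biostrings::pattern(al)),
                      Biostrings::end(Biostrings::pattern(al)), L)
    tibble(
      replicon_accession = replicon_accession,
      frame = frame,
      query_start = Biostrings::start(Biostrings::subject(al)),
      query_end = Biostrings::end(Biostrings::subject(al)),
      subject_start = nt[[1]], subject_end = nt[[2]],
      align_length = Biostrings::nchar(al),
      n_identities = Biostrings::nmatch(al),
      raw_score = Biostrings::score(al),
      bit_score = bit_score(Biostrings::score(al), params)
    )
  })
}

hsp_prototype <- function() {
  tibble(replicon_accession = character(), frame = integer(),
         query_start = integer(), query_end = integer(),
         subject_start = integer(), subject_end = integer(),
         align_length = integer(), n_identities = integer(),
         raw_score = numeric(), bit_score = numeric())
}

summarise_hit <- function(probe_accession, genome_accession, probe_len, hsps,
                          params, score_threshold, coverage_threshold) {
  if (nrow(hsps) == 0) {
    return(tibble(probe_accession = probe_accession,
                  genome_accession = genome_accession,
                  best_bit_score = 0, query_coverage = 0, n_hsps = 0L,
                  passes_filter = FALSE, hsps = list(hsp_prototype())))
  }
  best_bit <- max(hsps$bit_score)
  best_replicon <- hsps$replicon_accession[[which.max(hsps$bit_score)]]
  on_best <- hsps[hsps$replicon_accession == best_replicon, , drop = FALSE]
  coverage <- interval_union_size(on_best$query_start, on_best$query_end) / probe_len
  tibble(probe_accession = probe_accession, genome_accession = genome_accession,
         best_bit_score = best_bit, query_coverage = coverage,
         n_hsps = nrow(hsps),
         passes_filter = passes_filter(best_bit, coverage,
                                       score_threshold, coverage_threshold),
         hsps = list(hsps))
}

# Total number of integers covered by the union of closed intervals.
interval_union_size <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  total <- 0L; cur_s <- starts[[1]]; cur_e <- ends[[1]]
  for (i in seq_along(starts)[-1]) {
    if (starts[[i]] <= cur_e + 1L) {
      cur_e <- max(cur_e, ends[[i]])
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- starts[[i]]; cur_e <- ends[[i]]
    }
  }
  total + (cur_e - cur_s + 1L)
}

#' Search many genomes with a probe set
#'
#' Runs [search_genome()] for every (probe, genome) combination and binds the
#' per-hit rows. Six-frame translations are computed once per replicon and
#' shared across probes.
#'
#' @param probes Data frame of probes (`accession`, `kind`, `sequence`).
#' @param genomes Replicon-level data frame, see [search_genome()].
#' @inheritParams search_genome
#' @return A tibble with one row per (probe, genome), as in [search_genome()].
#' @export
search_genomes <- function(probes, genomes, matrix = blosum62(),
                           params = alignment_params(),
                           exclude_plasmids = TRUE,
                           score_threshold = 150, coverage_threshold = 0.70,
                           hsp_floor_bits = 50) {
  store <- hit_store(probes, genomes, matrix, params, exclude_plasmids,
                     score_threshold, coverage_threshold, hsp_floor_bits)
  store_hits(store, unique(genomes$genome_accession))
}

# A lazy per-(probe, genome) hit cache so the hierarchical survey never
# aligns the same pair twice. Translations are cached per replicon.
hit_store <- function(probes, genomes, matrix = blosum62(),
                      params = alignment_params(), exclude_plasmids = TRUE,
                      score_threshold = 150, coverage_threshold = 0.70,
                      hsp_floor_bits = 50) {
  store <- new.env(parent = emptyenv())
  store$probes <- probes
  store$genomes <- split(genomes, genomes$genome_accession)
  store$matrix <- matrix
  store$params <- params
  store$exclude_plasmids <- exclude_plasmids
  store$score_threshold <- score_threshold
  store$coverage_threshold <- coverage_threshold
  store$hsp_floor_bits <- hsp_floor_bits
  store$translations <- new.env(parent = emptyenv())
  store$hits <- new.env(parent = emptyenv())
  store
}

store_translations <- function(store, replicon_accession, nt_sequence) {
  key <- replicon_accession
  if (is.null(store$translations[[key]])) {
    tr <- six_frame_translate(nt_sequence, store$params$genetic_code_id)
    store$translations[[key]] <- setNames(tr$protein, tr$frame)
  }
  store$translations[[key]]
}

store_hits <- function(store, genome_accessions) {
  purrr::map_dfr(genome_accessions, function(g) {
    purrr::map_dfr(seq_len(nrow(store$probes)), function(pi) {
      probe <- store$probes[pi, , drop = FALSE]
      key <- paste0(probe$accession, "\r", g)
      if (is.null(store$hits[[key]])) {
        genome <- store$genomes[[g]]
        if (is.null(genome)) {
          stop("genome not in store: ", g, call. = FALSE)
        }
        reps <- if (store$exclude_plasmids) {
          genome[!genome$is_plasmid, , drop = FALSE]
        } else genome
        probe_aa <- Biostrings::AAString(probe$sequence[[1]])
        hsps <- purrr::map_dfr(seq_len(nrow(reps)), function(i) {
          align_frames(probe_aa, reps$replicon_accession[[i]],
                       reps$sequence[[i]], store$matrix, store$params,
                       store$hsp_floor_bits,
                       frames_aa = store_translations(
                         store, reps$replicon_accession[[i]],
                         reps$sequence[[i]]))
        })
        store$hits[[key]] <- summarise_hit(
          probe$accession[[1]], g, nchar(probe$sequence[[1]]), hsps,
          store$params, store$score_threshold, store$coverage_threshold)
      }
      store$hits[[key]]
    })
  })
}
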