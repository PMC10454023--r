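# Independent oracles used to freeze expected values. These deliberately do
# not share code paths with the package implementation.

# Per-character reverse-complement lookup.
rc_oracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Codon-by-codon translation walk over an explicit codon table.
translate_oracle <- function(nt, offset = 0) {
  code <- Biostrings::getGeneticCode("11")
  n_codon <- (nchar(nt) - offset) %/% 3
  if (n_codon < 1) return("")
  aas <- vapply(seq_len(n_codon), function(k) {
    codon <- substr(nt, offset + 3 * (k - 1) + 1, offset + 3 * k)
    unname(code[[codon]])
  }, character(1))
  paste(aas, collapse = "")
}

# Exhaustive enumeration of all gapped local alignments in canonical form:
# an alignment is an increasing sequence of matched residue pairs; the
# unmatched residues between consecutive matched pairs cost one affine gap
# run per sequence. The optimum over all such sequences is the affine
# Smith-Waterman local score.
enumerate_local_score <- function(q, s, mat, gap_open = 11, gap_extend = 1) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc)
  m <- length(sc)
  gapcost <- function(d) if (d == 0) 0 else gap_open + gap_extend * d
  best <- 0
  rec <- function(i, j, score) {
    best <<- max(best, score)
    if (i > n || j > m) return(invisible())
    for (i2 in i:n) {
      for (j2 in j:m) {
        rec(i2 + 1L, j2 + 1L,
            score + mat[qc[[i2]], sc[[j2]]] - gapcost(i2 - i) - gapcost(j2 - j))
      }
    }
  }
  for (i0 in seq_len(n)) {
    for (j0 in seq_len(m)) {
      rec(i0 + 1L, j0 + 1L, mat[qc[[i0]], sc[[j0]]])
    }
  }
  best
}

# Exhaustive minimal set cover over an adjacency matrix (self included).
brute_min_cover_size <- function(adj) {
  diag(adj) <- TRUE
  n <- nrow(adj)
  for (k in seq_len(n)) {
    combos <- utils::combn(n, k, simplify = FALSE)
    for (cs in combos) {
      if (all(colSums(adj[cs, , drop = FALSE]) > 0)) return(k)
    }
  }
  n
}

# Independent recursive reference walk of the hierarchical survey, driven by
# a per-genome truth status table instead of alignments. Returns one row per
# taxon that the survey should probe.
reference_survey <- function(tree, manifest, statuses,
                             config = survey_config()) {
  ladder <- c("phylum", "class", "order", "family", "genus", "species")
  nodes <- tree$nodes
  rows <- list()

  kids_of <- function(t) sort(nodes$taxid[nodes$parent_taxid == t &
                                          nodes$taxid != t])
  rank_descendants <- function(t, rank) {
    found <- integer(0)
    for (k in kids_of(t)) {
      if (nodes$rank[nodes$taxid == k] == rank) found <- c(found, k)
      found <- c(found, rank_descendants(k, rank))
    }
    found
  }
  subtree_genomes <- function(t) {
    own <- manifest[manifest$taxid == t, , drop = FALSE]
    below <- lapply(kids_of(t), subtree_genomes)
    do.call(rbind, c(list(own), below))
  }
  level_of <- function(k, n) {
    if (k == 0) "absent"
    else if (k / n <= 0.5) "low"
    else if (k / n < 1) "partial"
    else "full"
  }
  probe_taxon <- function(t, rank) {
    entries <- subtree_genomes(t)
    if (is.null(entries) || nrow(entries) == 0) {
      rows[[length(rows) + 1L]] <<- data.frame(
        taxid = t, rank = rank, analyzed = FALSE, level_U = NA,
        level_C = NA, complete = NA)
      return(FALSE)  # do not descend
    }
    if (!(rank %in% c("genus", "species")) &&
        sum(entries$is_type_material) >= config$min_type_material) {
      entries <- entries[entries$is_type_material, , drop = FALSE]
    }
    st <- statuses[match(entries$genome_accession,
                         statuses$genome_accession), , drop = FALSE]
    n <- nrow(entries)
    lU <- level_of(sum(st$has_U), n)
    lC <- level_of(sum(st$has_C), n)
    comp <- lU %in% c("absent", "full") && lC %in% c("absent", "full")
    rows[[length(rows) + 1L]] <<- data.frame(
      taxid = t, rank = rank, analyzed = TRUE, level_U = lU, level_C = lC,
      complete = comp)
    !comp
  }
  descend <- function(t, depth) {
    if (depth > length(ladder)) return(invisible())
    for (child in rank_descendants(t, ladder[[depth]])) {
      if (probe_taxon(child, ladder[[depth]]) &&
          ladder[[depth]] != "species") {
        descend(child, depth + 1L)
      }
    }
  }
  descend(tree$root, 1L)
  tibble::as_tibble(do.call(rbind, rows))
}

# Random protein over the standard 20-letter alphabet.
random_probe <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
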