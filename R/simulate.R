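AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Evaluate code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_protein <- function(length, seed = NULL) {
  draw <- function() paste(sample(AA_ALPHABET, length, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

random_dna <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Mutate a protein to a target identity
#'
#' Substitutes residues at uniformly chosen positions (each with a uniformly
#' chosen different residue) so that the realized identity to the input is
#' `round((1 - target_identity) * length)` substitutions away, i.e. within
#' one residue of the target. Length is preserved and the draw is
#' deterministic per seed.
#'
#' @param sequence Protein sequence (single string over the 20-letter
#'   alphabet).
#' @param target_identity Fraction in `(0, 1]`.
#' @param seed Integer seed.
#' @return The mutated sequence.
#' @export
mutate_protein <- function(sequence, target_identity, seed) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  stopifnot(target_identity > 0, target_identity <= 1)
  n <- nchar(sequence)
  n_sub <- round((1 - target_identity) * n)
  if (n_sub == 0) return(sequence)
  with_seed(seed, {
    pos <- sample.int(n, n_sub)
    chars <- strsplit(sequence, "")[[1]]
    for (i in pos) {
      chars[[i]] <- sample(setdiff(AA_ALPHABET, chars[[i]]), 1L)
    }
    paste(chars, collapse = "")
  })
}

#' Back-translate a protein to a coding sequence
#'
#' Maps each residue to a uniformly chosen synonymous codon of the requested
#' genetic code and appends a uniformly chosen stop codon. Re-translating the
#' result recovers the protein.
#'
#' @param protein Protein sequence over the 20-letter alphabet.
#' @param seed Integer seed.
#' @param genetic_code_id NCBI genetic code id (default "11").
#' @return A nucleotide CDS of length `3 * (nchar(protein) + 1)`.
#' @export
back_translate <- function(protein, seed, genetic_code_id = "11") {
  stopifnot(is.character(protein), length(protein) == 1L, nzchar(protein))
  code <- Biostrings::getGeneticCode(as.character(genetic_code_id))
  codons_of <- split(names(code), unname(code))
  residues <- strsplit(protein, "")[[1]]
  bad <- setdiff(unique(residues), AA_ALPHABET)
  if (length(bad) > 0) {
    stop("non-standard residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    codons <- vapply(residues, function(a) {
      opts <- codons_of[[a]]
      opts[[sample.int(length(opts), 1L)]]
    }, character(1))
    stop_codon <- codons_of[["*"]][[sample.int(length(codons_of[["*"]]), 1L)]]
    paste(c(codons, stop_codon), collapse = "")
  })
}

#' Create a replicon for ORF planting
#'
#' @param sequence Background nucleotide sequence.
#' @return A `replicon` object tracking planted features.
#' @export
new_replicon <- function(sequence) {
  structure(list(sequence = sequence,
                 features = tibble(start = integer(), end = integer(),
                                   strand = character(), label = character())),
            class = "replicon")
}

#' Plant an ORF into a replicon
#'
#' Overwrites the region starting at `position` with the CDS
#' (reverse-complemented when `strand` is `"-"`) and records the feature.
#' Overlaps with previously planted ORFs are rejected.
#'
#' @param replicon A [new_replicon()] object.
#' @param cds Nucleotide coding sequence.
#' @param strand `"+"` or `"-"`.
#' @param position 1-based start on the forward strand.
#' @param label Feature label.
#' @return The updated replicon.
#' @export
plant_orf <- function(replicon, cds, strand = "+", position, label = "orf") {
  stopifnot(inherits(replicon, "replicon"), strand %in% c("+", "-"))
  len <- nchar(cds)
  end <- position + len - 1L
  if (position < 1L || end > nchar(replicon$sequence)) {
    stop("planted ORF does not fit the replicon", call. = FALSE)
  }
  f <- replicon$features
  if (any(position <= f$end & end >= f$start)) {
    stop("planted ORF overlaps a previous plant", call. = FALSE)
  }
  insert <- if (strand == "-") reverse_complement(cds) else cds
  s <- replicon$sequence
  replicon$sequence <- paste0(substr(s, 1L, position - 1L), insert,
                              substr(s, end + 1L, nchar(s)))
  replicon$features <- dplyr::bind_rows(
    f, tibble(start = as.integer(position), end = as.integer(end),
              strand = strand, label = label))
  replicon
}

#' Synthetic dataset configuration
#'
#' Describes a fully synthetic survey dataset: a rank-complete toy taxonomy,
#' genomes of uniform-background chromosomes (optionally with a plasmid
#' replicon), synthetic probe proteins, and a per-species presence plan that
#' places taxa in each of the four joint categories and every presence
#' level. The default scale is 2 phyla x 2 classes x 2 orders x 2 families x
#' 2 genera x 3 species x 4 genomes (384 genomes of 20 kb).
#'
#' @param seed Integer; fixes every downstream draw.
#' @param n_phyla,n_classes,n_orders,n_families,n_genera,n_species Counts
#'   per rank (children per node of the rank above).
#' @param n_genomes Genomes per species.
#' @param n_usha_probes,n_cpdb_probes Number of synthetic probes of each
#'   kind.
#' @param probe_length Probe length in amino acids (at least 200, so a
#'   perfect planted match clears the 150-bit filter with margin).
#' @param planted_identity Protein identity of planted homologs to their
#'   probe, in `(0, 1]`.
#' @param background_length Chromosome background length (nt).
#' @param plasmid_fraction Fraction of genomes receiving a plasmid replicon.
#' @param plasmid_length Plasmid background length (nt).
#' @param plant_on_plasmid Plant homologs on the plasmid instead of the
#'   chromosome (every genome then receives a plasmid).
#' @param reverse_strand_fraction Fraction of plants on the reverse strand.
#' @param type_material_fraction Fraction of each species' genomes flagged
#'   as type material.
#' @param n_decoys Decoy ORFs (random proteins) planted per chromosome.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_phyla = 2L, n_classes = 2L, n_orders = 2L,
                             n_families = 2L, n_genera = 2L, n_species = 3L,
                             n_genomes = 4L,
                             n_usha_probes = 2L, n_cpdb_probes = 1L,
                             probe_length = 220L,
                             planted_identity = 1.0,
                             background_length = 20000L,
                             plasmid_fraction = 0.25,
                             plasmid_length = 5000L,
                             plant_on_plasmid = FALSE,
                             reverse_strand_fraction = 0.5,
                             type_material_fraction = 0.5,
                             n_decoys = 2L) {
  fracs <- c(planted_identity, plasmid_fraction, reverse_strand_fraction,
             type_material_fraction)
  stopifnot(all(fracs >= 0 & fracs <= 1), planted_identity > 0,
            probe_length >= 200L, background_length >= 3L * probe_length + 10L)
  structure(as.list(environment()), class = "synthetic_config")
}

# Per-species presence plan: which archetype each species follows, chosen
# deterministically from its position in the taxonomy so that complete taxa
# of all four categories arise at several ranks and every presence level
# occurs at species rank.
plan_for_species <- function(path, ordinal) {
  cycle <- list(
    c("full", "low"), c("partial", "absent"), c("full", "full"),
    c("low", "partial"), c("absent", "absent"), c("full", "absent"),
    c("absent", "full"), c("partial", "partial"), c("low", "absent"),
    c("full", "partial"), c("absent", "low"), c("partial", "full"))
  if (path[["phylum"]] == 1L) c("full", "full")
  else if (path[["class"]] == 1L) c("absent", "absent")
  else if (path[["order"]] == 1L) c("full", "absent")
  else if (path[["family"]] == 1L) c("absent", "full")
  else cycle[[(ordinal - 1L) %% length(cycle) + 1L]]
}

plan_count <- function(level, n) {
  switch(level,
         absent = 0L,
         low = max(1L, n %/% 2L),
         partial = max(1L, n - 1L),
         full = n)
}

#' Generate a synthetic survey dataset
#'
#' Builds, deterministically from the seed, a rank-complete toy taxonomy, a
#' genome manifest with type-material flags, synthetic probe proteins, and
#' genome sequences with planted, divergence-controlled homologs of the
#' probes (forward or reverse strand, chromosome or plasmid) plus decoy
#' ORFs, together with a ground-truth manifest.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_dataset`: `tree` (taxonomy),
#'   `manifest`, `genomes` (replicon-level table), `probes`, and `truth`
#'   (list with `genomes` -- planted per-genome U/C status -- `plants`, and
#'   `species_plan`).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  # --- taxonomy -------------------------------------------------------------
  counter <- new.env(parent = emptyenv()); counter$next_id <- 1L
  new_taxid <- function() {
    id <- counter$next_id; counter$next_id <- id + 1L; id
  }
  nodes <- list()
  add_node <- function(taxid, parent, rank, name) {
    nodes[[length(nodes) + 1L]] <<- tibble(taxid = taxid,
                                           parent_taxid = parent,
                                           rank = rank, name = name)
  }
  root <- new_taxid()
  add_node(root, root, "superkingdom", "Synthetica")
  species <- list()
  counts <- c(phylum = cfg$n_phyla, class = cfg$n_classes,
              order = cfg$n_orders, family = cfg$n_families,
              genus = cfg$n_genera, species = cfg$n_species)
  build <- function(parent, depth, path, prefix) {
    rank <- names(counts)[[depth]]
    for (i in seq_len(counts[[depth]])) {
      t <- new_taxid()
      name <- paste0(toupper(substr(rank, 1, 1)), substr(rank, 2, 99), "_",
                     paste(c(prefix, i), collapse = "."))
      add_node(t, parent, rank, name)
      new_path <- c(path, setNames(i, rank))
      if (depth == length(counts)) {
        species[[length(species) + 1L]] <<- list(taxid = t, path = new_path)
      } else {
        build(t, depth + 1L, new_path, c(prefix, i))
      }
    }
  }
  build(root, 1L, integer(0), integer(0))
  tree <- new_taxonomy(dplyr::bind_rows(nodes))

  # --- probes ---------------------------------------------------------------
  probes <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(cfg$n_usha_probes), function(i) {
      tibble(accession = paste0("SYNU", i), kind = "UshA-like",
             sequence = random_protein(cfg$probe_length))
    }),
    purrr::map_dfr(seq_len(cfg$n_cpdb_probes), function(i) {
      tibble(accession = paste0("SYNC", i), kind = "CpdB-like",
             sequence = random_protein(cfg$probe_length))
    })
  )
  u_probes <- probes[probes$kind == "UshA-like", , drop = FALSE]
  c_probes <- probes[probes$kind == "CpdB-like", , drop = FALSE]

  # --- genomes and plants ---------------------------------------------------
  manifest_rows <- list(); replicon_rows <- list()
  plant_rows <- list(); truth_rows <- list(); plan_rows <- list()
  genome_no <- 0L
  for (si in seq_along(species)) {
    sp <- species[[si]]
    plan <- plan_for_species(sp$path, si)
    n <- cfg$n_genomes
    k_U <- plan_count(plan[[1]], n)
    k_C <- plan_count(plan[[2]], n)
    u_set <- sort(sample.int(n, k_U))
    c_set <- sort(sample.int(n, k_C))
    type_set <- sort(sample.int(n, round(cfg$type_material_fraction * n)))
    plan_rows[[si]] <- tibble(taxid = sp$taxid, plan_U = plan[[1]],
                              plan_C = plan[[2]], n_U = k_U, n_C = k_C)
    for (gi in seq_len(n)) {
      genome_no <- genome_no + 1L
      acc <- sprintf("G%04d", genome_no)
      has_plasmid <- cfg$plant_on_plasmid ||
        stats::runif(1) < cfg$plasmid_fraction
      chr <- new_replicon(random_dna(cfg$background_length))
      pls <- if (has_plasmid) new_replicon(random_dna(cfg$plasmid_length))
             else NULL
      plant_one <- function(probe_row, slot) {
        protein <- mutate_protein(probe_row$sequence,
                                  cfg$planted_identity,
                                  seed = sample.int(.Machine$integer.max, 1L))
        cds <- back_translate(protein,
                              seed = sample.int(.Machine$integer.max, 1L))
        strand <- if (stats::runif(1) < cfg$reverse_strand_fraction) "-"
                  else "+"
        on_plasmid <- cfg$plant_on_plasmid
        L <- if (on_plasmid) cfg$plasmid_length else cfg$background_length
        pos <- as.integer(floor(L * c(0.05, 0.40)[[slot]])) + 1L
        target <- if (on_plasmid) pls else chr
        target <- plant_orf(target, cds, strand, pos,
                            label = probe_row$accession)
        if (on_plasmid) pls <<- target else chr <<- target
        plant_rows[[length(plant_rows) + 1L]] <<- tibble(
          genome_accession = acc,
          replicon_accession = paste0(acc, if (on_plasmid) "_p1" else "_chr"),
          probe_accession = probe_row$accession, kind = probe_row$kind,
          identity = cfg$planted_identity, strand = strand,
          start = pos, end = pos + nchar(cds) - 1L)
      }
      if (gi %in% u_set) {
        pick <- (match(gi, u_set) - 1L) %% nrow(u_probes) + 1L
        plant_one(u_probes[pick, , drop = FALSE], 1L)
      }
      if (gi %in% c_set) {
        pick <- (match(gi, c_set) - 1L) %% nrow(c_probes) + 1L
        plant_one(c_probes[pick, , drop = FALSE], 2L)
      }
      for (d in seq_len(cfg$n_decoys)) {
        decoy <- random_protein(120L)
        chr <- plant_orf(chr, back_translate(
          decoy, seed = sample.int(.Machine$integer.max, 1L)),
          strand = if (d %% 2L == 0L) "-" else "+",
          position = as.integer(floor(cfg$background_length *
                                        (0.70 + 0.08 * (d - 1L)))) + 1L,
          label = paste0("decoy", d))
      }
      manifest_rows[[genome_no]] <- tibble(
        genome_accession = acc, taxid = sp$taxid,
        is_type_material = gi %in% type_set)
      reps <- tibble(genome_accession = acc,
                     replicon_accession = paste0(acc, "_chr"),
                     is_plasmid = FALSE, sequence = chr$sequence)
      if (has_plasmid) {
        reps <- dplyr::bind_rows(reps, tibble(
          genome_accession = acc, replicon_accession = paste0(acc, "_p1"),
          is_plasmid = TRUE, sequence = pls$sequence))
      }
      replicon_rows[[genome_no]] <- reps
      truth_rows[[genome_no]] <- tibble(
        genome_accession = acc, taxid = sp$taxid,
        is_type_material = gi %in% type_set,
        has_U_planted = gi %in% u_set,
        has_C_planted = gi %in% c_set)
    }
  }
  structure(list(
    tree = tree,
    manifest = dplyr::bind_rows(manifest_rows),
    genomes = dplyr::bind_rows(replicon_rows),
    probes = probes,
    truth = list(genomes = dplyr::bind_rows(truth_rows),
                 plants = dplyr::bind_rows(plant_rows),
                 species_plan = dplyr::bind_rows(plan_rows)),
    config = cfg
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$manifest), " genomes, ",
      nrow(x$tree$nodes), " taxa, ", nrow(x$probes), " probes (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}
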