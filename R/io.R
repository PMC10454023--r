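#' Read and write genome FASTA files
#'
#' Genomes are multi-record FASTA files, one record per replicon. The
#' description line carries the owning genome accession as a `genome=` field
#' and the word `plasmid` for plasmid-flagged replicons (mirroring a title
#' keyword convention), e.g. `>G0001_p1 genome=G0001 plasmid`.
#'
#' @param path FASTA path.
#' @param genomes Replicon-level genome table (`genome_accession`,
#'   `replicon_accession`, `is_plasmid`, `sequence`).
#' @return `read_genome_fasta()` returns the replicon-level tibble;
#'   `write_genome_fasta()` returns `path` invisibly.
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  headers <- names(set)
  first <- sub("\\s.*$", "", headers)
  genome <- stringr::str_match(headers, "genome=(\\S+)")[, 2]
  genome[is.na(genome)] <- first[is.na(genome)]
  tibble(
    genome_accession = genome,
    replicon_accession = first,
    is_plasmid = grepl("\\bplasmid\\b", headers),
    sequence = unname(as.character(set))
  )
}

#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(genomes, path) {
  set <- Biostrings::DNAStringSet(genomes$sequence)
  names(set) <- paste0(genomes$replicon_accession,
                       " genome=", genomes$genome_accession,
                       ifelse(genomes$is_plasmid, " plasmid", " chromosome"))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read and write protein probe FASTA files
#'
#' The description line carries the probe kind as a `kind=` field
#' (`UshA-like` or `CpdB-like`).
#'
#' @param path FASTA path.
#' @param probes Probe table (`accession`, `kind`, `sequence`).
#' @return `read_probe_fasta()` returns the probe tibble;
#'   `write_probe_fasta()` returns `path` invisibly.
#' @export
read_probe_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  kind <- stringr::str_match(headers, "kind=(\\S+)")[, 2]
  tibble(
    accession = sub("\\s.*$", "", headers),
    kind = ifelse(is.na(kind), "unknown", kind),
    sequence = unname(as.character(set))
  )
}

#' @rdname read_probe_fasta
#' @export
write_probe_fasta <- function(probes, path) {
  set <- Biostrings::AAStringSet(probes$sequence)
  names(set) <- paste0(probes$accession, " kind=", probes$kind)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a hit table as TSV
#'
#' Writes one row per (probe, genome) with the best bit score (2 decimals),
#' query coverage in percent (1 decimal), HSP count and filter outcome;
#' optionally an accompanying per-HSP table in a tabular-output style
#' (query, subject, percent identity, alignment length, query and subject
#' ranges, frame, bit score).
#'
#' @param hits Hit table from [search_genomes()].
#' @param path Output TSV path.
#' @param hsp_path Optional path for the per-HSP table.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path, hsp_path = NULL) {
  out <- tibble(
    probe_accession = hits$probe_accession,
    genome_accession = hits$genome_accession,
    best_bit_score = sprintf("%.2f", hits$best_bit_score),
    query_coverage_pct = sprintf("%.1f", 100 * hits$query_coverage),
    n_hsps = hits$n_hsps,
    passes_filter = hits$passes_filter
  )
  readr::write_tsv(out, path)
  if (!is.null(hsp_path)) {
    hsps <- tidyr::unnest(
      tibble(qseqid = hits$probe_accession, hsps = hits$hsps), "hsps")
    hsp_out <- tibble(
      qseqid = hsps$qseqid, sseqid = hsps$replicon_accession,
      pident = sprintf("%.1f", 100 * hsps$n_identities / hsps$align_length),
      length = hsps$align_length,
      qstart = hsps$query_start, qend = hsps$query_end,
      sstart = hsps$subject_start, send = hsps$subject_end,
      frame = hsps$frame, bitscore = sprintf("%.1f", hsps$bit_score)
    )
    readr::write_tsv(hsp_out, hsp_path)
  }
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Emits exactly the formats the pipeline consumes: a genome FASTA, a
#' nodes/names taxonomy dump, a manifest TSV, a probe FASTA, and the truth
#' manifest as JSON.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(dataset$genomes, file.path(dir, "genomes.fasta"))
  write_taxonomy(dataset$tree, file.path(dir, "nodes.dmp"),
                 file.path(dir, "names.dmp"))
  write_genome_manifest(dataset$manifest, file.path(dir, "manifest.tsv"))
  write_probe_fasta(dataset$probes, file.path(dir, "probes.fasta"))
  jsonlite::write_json(
    list(seed = dataset$config$seed,
         genomes = dataset$truth$genomes,
         plants = dataset$truth$plants,
         species_plan = dataset$truth$species_plan),
    file.path(dir, "truth.json"), dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}

#' Read a synthetic dataset from disk
#'
#' @param dir Directory written by [write_dataset()].
#' @return A list with `tree`, `manifest`, `genomes`, `probes`, `truth`.
#' @export
read_dataset <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(
    tree = load_taxonomy(file.path(dir, "nodes.dmp"),
                         file.path(dir, "names.dmp")),
    manifest = read_genome_manifest(file.path(dir, "manifest.tsv")),
    genomes = read_genome_fasta(file.path(dir, "genomes.fasta")),
    probes = read_probe_fasta(file.path(dir, "probes.fasta")),
    truth = list(genomes = tibble::as_tibble(truth$genomes),
                 plants = tibble::as_tibble(truth$plants),
                 species_plan = tibble::as_tibble(truth$species_plan))
  )
}

#' Read packaged per-genome score tables
#'
#' Transcriptions of published per-genome best-score tables (accession,
#' description, per-kind best bit scores), for example the set of E. coli
#' genomes lacking one of the two gene kinds or the avian pathogenic E. coli
#' (APEC) genome set.
#'
#' @param name One of `"ecoli_exception_genomes"`, `"apec_genomes"`,
#'   `"pmultocida_exception_genomes"`.
#' @return A tibble: `accession`, `description`, `usha_score`, `cpdb_score`.
#' @export
read_score_table <- function(name = c("ecoli_exception_genomes",
                                      "apec_genomes",
                                      "pmultocida_exception_genomes")) {
  name <- match.arg(name)
  readr::read_tsv(nucleosurvey_extdata(paste0(name, ".tsv")),
                  col_types = readr::cols(
                    accession = readr::col_character(),
                    description = readr::col_character(),
                    usha_score = readr::col_double(),
                    cpdb_score = readr::col_double()))
}

#' Read the packaged complete-taxon category lists
#'
#' The packaged transcription of the published four-way partition of the 590
#' complete taxa (rank, taxon name, taxid, category `both` / `u_only` /
#' `c_only` / `neither`).
#'
#' @return A tibble with one row per complete taxon.
#' @export
read_complete_taxa_categories <- function() {
  readr::read_tsv(nucleosurvey_extdata("complete_taxa_categories.tsv"),
                  col_types = readr::cols(
                    rank = readr::col_character(),
                    taxon = readr::col_character(),
                    taxid = readr::col_integer(),
                    category = readr::col_character()))
}

#' Read the packaged species joint-count vignettes
#'
#' Marginal per-species counts (total genomes, genomes hit by each kind,
#' genomes hit by both) for species whose joint breakdown is inferred with
#' [infer_categories_from_counts()].
#'
#' @return A tibble: `species`, `n_total`, `n_usha`, `n_cpdb`, `n_both`.
#' @export
read_species_joint_counts <- function() {
  readr::read_tsv(nucleosurvey_extdata("species_joint_counts.tsv"),
                  col_types = readr::cols(
                    species = readr::col_character(),
                    .default = readr::col_integer()))
}

#' Write a survey configuration as JSON
#'
#' @param config A [survey_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a survey configuration from JSON
#'
#' @param path JSON path.
#' @return A [survey_config()].
#' @export
read_survey_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(survey_config, vals)
}
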