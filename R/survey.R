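PRESENCE_LEVELS <- c("absent", "low", "partial", "full")

#' Survey configuration
#'
#' Bundles the eligibility and hit-filter settings of a survey run. By
#' default searches above the genus level are restricted to genomes of type
#' material; the restriction is dropped when fewer than `min_type_material`
#' type-material genomes are available and, as a rule, for searches within
#' genera and species. Plasmid-flagged replicons are excluded, and hits
#' require a bit score above 150 with query coverage above 70%.
#'
#' @param min_type_material Minimum number of type-material genomes for the
#'   type-material restriction to apply (default 5).
#' @param restrict_to_type_material_above_genus Apply the restriction at
#'   ranks above genus (default `TRUE`).
#' @param exclude_plasmids Exclude plasmid-flagged replicons (default `TRUE`).
#' @param score_threshold,coverage_threshold Hit filter, see
#'   [passes_filter()].
#' @param hsp_floor_bits HSP reporting floor in bits, see [search_genome()].
#' @return A list of class `survey_config`.
#' @export
survey_config <- function(min_type_material = 5L,
                          restrict_to_type_material_above_genus = TRUE,
                          exclude_plasmids = TRUE,
                          score_threshold = 150,
                          coverage_threshold = 0.70,
                          hsp_floor_bits = 50) {
  structure(list(
    min_type_material = as.integer(min_type_material),
    restrict_to_type_material_above_genus = restrict_to_type_material_above_genus,
    exclude_plasmids = exclude_plasmids,
    score_threshold = score_threshold,
    coverage_threshold = coverage_threshold,
    hsp_floor_bits = hsp_floor_bits
  ), class = "survey_config")
}

#' Genomes eligible for the survey of a taxon
#'
#' At ranks above genus, when at least `min_type_material` type-material
#' genomes are available, only those are analyzed; otherwise, and always at
#' genus and species rank, all genomes are analyzed.
#'
#' @param entries Manifest rows for the taxon (see [genomes_of()]).
#' @param rank Rank of the taxon being surveyed.
#' @param config A [survey_config()].
#' @return The eligible manifest rows.
#' @export
#' @examples
#' m <- tibble::tibble(genome_accession = paste0("G", 1:8),
#'                     taxid = 10L, is_type_material = rep(c(TRUE, FALSE), 4))
#' nrow(eligible_genomes(m, "phylum", survey_config()))   # 8: only 4 type
#' nrow(eligible_genomes(m[1:2, ], "species", survey_config()))
eligible_genomes <- function(entries, rank, config = survey_config()) {
  if (!config$restrict_to_type_material_above_genus ||
      rank %in% c("genus", "species")) {
    return(entries)
  }
  n_type <- sum(entries$is_type_material)
  if (n_type < config$min_type_material) return(entries)
  entries[entries$is_type_material, , drop = FALSE]
}

#' Classify a presence level
#'
#' Three presence tiers are distinguished among analyzed genomes with a hit:
#' at most 50%, more than 50% but less than 100%, and 100%; zero hits is
#' absence.
#'
#' @param k_hit_genomes Number of genomes with a hit, `0 <= k <= n`.
#' @param n_genomes Number of genomes analyzed, `>= 1`.
#' @return One of `"absent"`, `"low"`, `"partial"`, `"full"` (vectorised).
#' @export
#' @examples
#' classify_presence(4, 17)    # "low"
#' classify_presence(135, 138) # "partial"
classify_presence <- function(k_hit_genomes, n_genomes) {
  stopifnot(all(n_genomes >= 1), all(k_hit_genomes >= 0),
            all(k_hit_genomes <= n_genomes))
  frac <- k_hit_genomes / n_genomes
  dplyr::case_when(
    k_hit_genomes == 0 ~ "absent",
    frac <= 0.5 ~ "low",
    frac < 1 ~ "partial",
    TRUE ~ "full"
  )
}

#' Is the analysis of a taxon complete?
#'
#' A taxon is deemed complete when each gene kind is either absent or present
#' in 100% of the analyzed genomes; complete taxa are not pursued at lower
#' taxonomical levels.
#'
#' @param level_U,level_C Presence levels (see [classify_presence()]).
#' @return Logical (vectorised).
#' @export
#' @examples
#' is_complete("full", "absent")  # TRUE
#' is_complete("full", "low")     # FALSE
is_complete <- function(level_U, level_C) {
  stopifnot(all(level_U %in% PRESENCE_LEVELS), all(level_C %in% PRESENCE_LEVELS))
  level_U %in% c("absent", "full") & level_C %in% c("absent", "full")
}

#' Survey one taxon with a probe set
#'
#' Searches every eligible genome of the taxon with every probe, records the
#' per-probe hit counts and the per-kind union counts (a genome counts as
#' UshA-positive when any UshA-like probe yields a passing hit, and likewise
#' for CpdB-like probes), classifies the per-kind presence levels and decides
#' completeness.
#'
#' @param tree A `taxonomy_tree`.
#' @param manifest Genome manifest (see [read_genome_manifest()]).
#' @param genomes Replicon-level genome table (see [search_genome()]).
#' @param probes Probe table with columns `accession`, `kind`
#'   (`"UshA-like"` / `"CpdB-like"`), `sequence`.
#' @param taxid Taxon to survey.
#' @param config A [survey_config()].
#' @param matrix,params Scoring system.
#' @return A one-row survey tibble; see [hierarchical_survey()] for the
#'   column semantics. Taxa with no genomes are flagged `analyzed = FALSE`.
#' @export
survey_taxon <- function(tree, manifest, genomes, probes, taxid,
                         config = survey_config(), matrix = blosum62(),
                         params = alignment_params()) {
  store <- hit_store(probes, genomes, matrix, params,
                     config$exclude_plasmids, config$score_threshold,
                     config$coverage_threshold, config$hsp_floor_bits)
  survey_taxon_impl(store, tree, manifest, taxid, config)
}

survey_taxon_impl <- function(store, tree, manifest, taxid, config) {
  stop_unknown_taxid(tree, taxid)
  rank <- node_rank(tree, taxid)
  entries <- genomes_of(tree, manifest, taxid)
  base <- tibble(
    taxid = as.integer(taxid), taxon = node_name(tree, taxid), rank = rank,
    n_genomes_total = nrow(entries),
    n_type_material = sum(entries$is_type_material)
  )
  if (nrow(entries) == 0) {
    return(dplyr::bind_cols(base, tibble(
      analyzed = FALSE, n_genomes_analyzed = 0L,
      n_genomes_U = NA_integer_, n_genomes_C = NA_integer_,
      level_U = NA_character_, level_C = NA_character_, complete = NA,
      per_probe_hits = list(integer(0)), statuses = list(genome_status_prototype())
    )))
  }
  eligible <- eligible_genomes(entries, rank, config)
  hits <- store_hits(store, eligible$genome_accession)
  statuses <- genome_status(hits, store$probes)
  per_probe <- vapply(store$probes$accession, function(a) {
    sum(hits$passes_filter[hits$probe_accession == a])
  }, integer(1))
  n <- nrow(eligible)
  n_U <- sum(statuses$has_U)
  n_C <- sum(statuses$has_C)
  level_U <- classify_presence(n_U, n)
  level_C <- classify_presence(n_C, n)
  dplyr::bind_cols(base, tibble(
    analyzed = TRUE, n_genomes_analyzed = n,
    n_genomes_U = n_U, n_genomes_C = n_C,
    level_U = level_U, level_C = level_C,
    complete = is_complete(level_U, level_C),
    per_probe_hits = list(per_probe), statuses = list(statuses)
  ))
}

#' Hierarchical presence/absence survey with completeness pruning
#'
#' Drives the level-by-level survey down the taxonomic ladder (phylum, class,
#' order, family, genus, species). All taxa of the first rank below the root
#' are surveyed; thereafter the descendants of a taxon are surveyed only when
#' that taxon was analyzed and not complete. The descent never goes below
#' species. Traversal order is deterministic (ascending taxid within each
#' rank), and each (probe, genome) pair is aligned at most once across the
#' whole run.
#'
#' @inheritParams survey_taxon
#' @param root Taxid to start from (default: the tree root).
#' @param taxids Optional explicit set of taxa to survey instead of the
#'   systematic descent (no pruning logic; every listed taxon is surveyed).
#' @return An object of class `nuc_survey`: a list with `results` (one row
#'   per probed taxon: identification, genome counts, per-kind union counts
#'   `n_genomes_U` / `n_genomes_C`, presence levels, `complete`, plus
#'   list-columns with per-probe hit counts and per-genome statuses),
#'   `probes`, and `config`.
#' @export
hierarchical_survey <- function(tree, manifest, genomes, probes,
                                root = tree$root, taxids = NULL,
                                config = survey_config(),
                                matrix = blosum62(),
                                params = alignment_params()) {
  store <- hit_store(probes, genomes, matrix, params,
                     config$exclude_plasmids, config$score_threshold,
                     config$coverage_threshold, config$hsp_floor_bits)
  if (!is.null(taxids)) {
    results <- purrr::map_dfr(sort(unique(as.integer(taxids))),
                              function(t) survey_taxon_impl(store, tree,
                                                            manifest, t, config))
    return(new_nuc_survey(results, probes, config))
  }
  stop_unknown_taxid(tree, root)
  ladder <- RANK_LADDER[-1]  # phylum .. species
  frontier <- root
  results <- list()
  for (rank in ladder) {
    taxa <- sort(unique(unlist(lapply(frontier, descendant_taxa,
                                      tree = tree, rank = rank))))
    if (length(taxa) == 0) break
    level <- purrr::map_dfr(taxa, function(t) {
      survey_taxon_impl(store, tree, manifest, t, config)
    })
    results[[rank]] <- level
    frontier <- level$taxid[level$analyzed & !level$complete]
    if (rank == "species" || length(frontier) == 0) break
  }
  new_nuc_survey(dplyr::bind_rows(results), probes, config)
}

new_nuc_survey <- function(results, probes, config) {
  structure(list(results = results, probes = probes, config = config),
            class = "nuc_survey")
}

#' @export
print.nuc_survey <- function(x, ...) {
  cat("<nuc_survey> ", nrow(x$results), " taxa probed (",
      sum(x$results$analyzed), " analyzed, ",
      sum(x$results$complete, na.rm = TRUE), " complete)\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Tidy a survey into one row per probed taxon
#'
#' @param x A `nuc_survey`.
#' @param ... Unused.
#' @return The per-taxon results without list-columns.
#' @method tidy nuc_survey
#' @export
tidy.nuc_survey <- function(x, ...) {
  dplyr::select(x$results, -dplyr::any_of(c("per_probe_hits", "statuses")))
}

#' One-row-per-rank summary of a survey
#'
#' @param x A `nuc_survey`.
#' @param ... Unused.
#' @return The per-rank breakdown of [aggregate_levels()].
#' @method glance nuc_survey
#' @export
glance.nuc_survey <- function(x, ...) {
  aggregate_levels(x$results)
}

#' Presence-level map of a survey
#'
#' @param object A `nuc_survey`.
#' @param ... Unused.
#' @return A ggplot object: taxa by gene kind, tiles coloured by presence
#'   level.
#' @method autoplot nuc_survey
#' @export
autoplot.nuc_survey <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$analyzed, , drop = FALSE]
  long <- tidyr::pivot_longer(df, c("level_U", "level_C"),
                              names_to = "kind", values_to = "level")
  long$kind <- ifelse(long$kind == "level_U", "ushA-like", "cpdB-like")
  long$level <- factor(long$level, PRESENCE_LEVELS)
  ggplot2::ggplot(long, ggplot2::aes(.data$kind,
                                     paste0(.data$taxon, " [", .data$rank, "]"),
                                     fill = .data$level)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(absent = "grey85", low = "#66c2a5",
                                          partial = "#fc8d62", full = "#d53e4f"),
                               drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "presence") +
    ggplot2::theme_minimal()
}

presence_symbol <- function(level) {
  unname(c(absent = "-", low = "+<=50", partial = "+<100",
           full = "+100")[level])
}

#' Write per-taxon presence results as TSV
#'
#' Encodes the presence levels textually: `-` (absent), `+<=50`, `+<100`,
#' `+100`.
#'
#' @param survey A `nuc_survey`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_tsv <- function(survey, path) {
  df <- tidy(survey)
  out <- tibble(
    taxon = df$taxon, taxid = df$taxid, rank = df$rank,
    n_genomes_analyzed = df$n_genomes_analyzed,
    U = ifelse(df$analyzed, presence_symbol(df$level_U), "no genomes"),
    C = ifelse(df$analyzed, presence_symbol(df$level_C), "no genomes"),
    complete = df$complete
  )
  readr::write_tsv(out, path)
  invisible(path)
}
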