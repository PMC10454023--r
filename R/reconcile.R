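#' Per-genome joint gene status
#'
#' Reduces a hit table to one row per genome: a genome has an ushA-like gene
#' when at least one UshA-like probe yields a passing hit, and likewise for
#' cpdB-like genes with the CpdB-like probes.
#'
#' @param hits Hit table (rows as from [search_genome()]), covering all
#'   probes for each genome.
#' @param probes Probe table with `accession` and `kind`.
#' @return A tibble: `genome_accession`, `has_U`, `has_C`.
#' @export
genome_status <- function(hits, probes) {
  kinds <- setNames(probes$kind, probes$accession)
  df <- tibble(
    genome_accession = hits$genome_accession,
    kind = unname(kinds[hits$probe_accession]),
    passes = hits$passes_filter
  )
  out <- df |>
    dplyr::group_by(.data$genome_accession) |>
    dplyr::summarise(
      has_U = any(.data$passes & .data$kind == "UshA-like"),
      has_C = any(.data$passes & .data$kind == "CpdB-like"),
      .groups = "drop"
    )
  out
}

genome_status_prototype <- function() {
  tibble(genome_accession = character(), has_U = logical(), has_C = logical())
}

#' Genome statuses from per-kind best scores
#'
#' Classifies genomes from a table of per-kind best bit scores (such as a
#' transcription of a published per-genome score table), applying the strict
#' score filter with coverage assumed passing.
#'
#' @param scores Data frame with columns `genome_accession` (or `accession`),
#'   `usha_score`, `cpdb_score`.
#' @param score_threshold Strict score cutoff (default 150).
#' @return A status tibble as in [genome_status()].
#' @export
status_from_scores <- function(scores, score_threshold = 150) {
  acc <- scores[["genome_accession"]] %||% scores[["accession"]]
  tibble(genome_accession = acc,
         has_U = scores$usha_score > score_threshold,
         has_C = scores$cpdb_score > score_threshold)
}

#' Count genomes in the four joint-status categories
#'
#' @param statuses A status tibble (see [genome_status()]).
#' @return A one-row tibble: `n_both`, `n_u_only`, `n_c_only`, `n_neither`,
#'   `n_total`. The four categories always sum to `n_total`.
#' @export
categorize_genomes <- function(statuses) {
  tibble(
    n_both = sum(statuses$has_U & statuses$has_C),
    n_u_only = sum(statuses$has_U & !statuses$has_C),
    n_c_only = sum(!statuses$has_U & statuses$has_C),
    n_neither = sum(!statuses$has_U & !statuses$has_C),
    n_total = nrow(statuses)
  )
}

#' Infer the joint categories from marginal counts
#'
#' When per-genome results are not itemised but the totals are known -- the
#' number of genomes, the number hit by each gene kind, and the number hit by
#' both -- the full breakdown follows by inclusion-exclusion:
#' `u_only = n_U - n_both`, `c_only = n_C - n_both`,
#' `neither = n_total - n_U - n_C + n_both`.
#'
#' @param n_total Number of genomes.
#' @param n_U,n_C Number of genomes hit by each gene kind.
#' @param n_both Number of genomes hit by both kinds.
#' @return A one-row tibble as in [categorize_genomes()].
#' @export
#' @examples
#' infer_categories_from_counts(17, 17, 4, 4)      # 13 genomes ushA-only
#' infer_categories_from_counts(350, 219, 219, 219) # 131 double-negative
infer_categories_from_counts <- function(n_total, n_U, n_C, n_both) {
  if (n_both > min(n_U, n_C) || n_U > n_total || n_C > n_total ||
      any(c(n_total, n_U, n_C, n_both) < 0)) {
    stop("inconsistent counts: need n_both <= min(n_U, n_C) and ",
         "n_U, n_C <= n_total", call. = FALSE)
  }
  neither <- n_total - n_U - n_C + n_both
  if (neither < 0) {
    stop("inconsistent counts: n_U + n_C - n_both exceeds n_total",
         call. = FALSE)
  }
  tibble(n_both = n_both, n_u_only = n_U - n_both, n_c_only = n_C - n_both,
         n_neither = neither, n_total = n_total)
}

#' Partition complete taxa by joint gene-kind category
#'
#' Every complete taxon falls in exactly one of four categories, keyed by
#' whether each gene kind is present (level other than absent) or absent:
#' `both`, `u_only`, `c_only`, `neither`. Non-complete taxa are excluded.
#'
#' @param results Per-taxon results: a data frame with `level_U`, `level_C`
#'   and `complete` columns (e.g. `tidy()` of a `nuc_survey`).
#' @return The complete-taxon rows with an added `category` column.
#' @export
categorize_complete_taxa <- function(results) {
  cc <- results[!is.na(results$complete) & results$complete, , drop = FALSE]
  cc$category <- dplyr::case_when(
    cc$level_U != "absent" & cc$level_C != "absent" ~ "both",
    cc$level_U != "absent" ~ "u_only",
    cc$level_C != "absent" ~ "c_only",
    TRUE ~ "neither"
  )
  tibble::as_tibble(cc)
}

#' Aggregate survey results by taxonomic rank
#'
#' Produces the per-rank bookkeeping of a hierarchical survey: taxa probed,
#' taxa without sequenced genomes, taxa analyzed, taxa deemed complete, and
#' the breakdown of complete taxa by joint category, plus a `total` row.
#'
#' @param results Per-taxon results with columns `rank`, `analyzed`,
#'   `complete`, `level_U`, `level_C`.
#' @return A tibble with one row per rank present plus a `total` row:
#'   `rank`, `n_probed`, `n_without_genomes`, `n_analyzed`, `n_complete`,
#'   `n_both`, `n_u_only`, `n_c_only`, `n_neither`.
#' @export
aggregate_levels <- function(results) {
  cc <- categorize_complete_taxa(results)
  per_rank <- function(rows, cat_rows, label) {
    tibble(
      rank = label,
      n_probed = nrow(rows),
      n_without_genomes = sum(!rows$analyzed),
      n_analyzed = sum(rows$analyzed),
      n_complete = sum(cat_rows$complete),
      n_both = sum(cat_rows$category == "both"),
      n_u_only = sum(cat_rows$category == "u_only"),
      n_c_only = sum(cat_rows$category == "c_only"),
      n_neither = sum(cat_rows$category == "neither")
    )
  }
  ranks <- RANK_LADDER[RANK_LADDER %in% unique(results$rank)]
  rows <- purrr::map_dfr(ranks, function(r) {
    per_rank(results[results$rank == r, , drop = FALSE],
             cc[cc$rank == r, , drop = FALSE], r)
  })
  dplyr::bind_rows(rows, per_rank(results, cc, "total"))
}

# Largest-remainder (Hamilton) apportionment of percentages to one decimal:
# each count gets the floor of its share in tenths of a percent, and the
# tenths still missing from 100.0 go to the largest fractional remainders.
# The resulting percentages always sum to exactly 100.0.
apportion_percent <- function(counts, total, digits = 1) {
  p <- 10^digits
  shares <- 100 * p * counts / total
  base <- floor(shares)
  short <- round(100 * p - sum(base))
  if (short > 0) {
    extra <- order(shares - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  base / p
}

#' Correlation percentages between the two gene kinds
#'
#' Expresses a joint-category summary as one-decimal percentages of the
#' total, together with the combined concordant (both-or-neither) and
#' discordant percentages. Percentages are apportioned by largest remainder
#' so that the four categories sum to exactly 100.0 (and likewise the
#' concordant/discordant split).
#'
#' @param summary A one-row category summary (see [categorize_genomes()]).
#' @return A one-row tibble: `pct_both`, `pct_u_only`, `pct_c_only`,
#'   `pct_neither`, `pct_concordant`, `pct_discordant`.
#' @export
#' @examples
#' correlation_percentages(
#'   tibble::tibble(n_both = 185, n_u_only = 128, n_c_only = 46,
#'                  n_neither = 231, n_total = 590))
correlation_percentages <- function(summary) {
  if (summary$n_total <= 0) {
    stop("undefined: n_total must be positive", call. = FALSE)
  }
  cats <- apportion_percent(
    c(summary$n_both, summary$n_u_only, summary$n_c_only, summary$n_neither),
    summary$n_total)
  split2 <- apportion_percent(
    c(summary$n_both + summary$n_neither,
      summary$n_u_only + summary$n_c_only), summary$n_total)
  tibble(
    pct_both = cats[[1]], pct_u_only = cats[[2]], pct_c_only = cats[[3]],
    pct_neither = cats[[4]],
    pct_concordant = split2[[1]], pct_discordant = split2[[2]]
  )
}
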