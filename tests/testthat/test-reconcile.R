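test_that("per-genome status is the per-kind OR over passing hits", {
  probes <- tibble::tibble(
    accession = c("P07024", "P44569", "WP_000726911", "WP_011837008",
                  "O32133", "P08331", "AYV64543"),
    kind = c(rep("UshA-like", 5), rep("CpdB-like", 2)))
  hits <- tidyr::crossing(probe_accession = probes$accession,
                          genome_accession = c("G1", "G2", "G3"))
  hits$passes_filter <- FALSE
  # G1: nothing passes; G2: only the UshA-like probe O32133; G3: both kinds
  hits$passes_filter[hits$genome_accession == "G2" &
                     hits$probe_accession == "O32133"] <- TRUE
  hits$passes_filter[hits$genome_accession == "G3" &
                     hits$probe_accession %in% c("P07024", "P08331")] <- TRUE
  st <- genome_status(hits, probes)
  expect_equal(st$has_U[st$genome_accession == "G1"], FALSE)
  expect_equal(st$has_C[st$genome_accession == "G1"], FALSE)
  expect_equal(st$has_U[st$genome_accession == "G2"], TRUE)
  expect_equal(st$has_C[st$genome_accession == "G2"], FALSE)
  expect_equal(st$has_U[st$genome_accession == "G3"], TRUE)
  expect_equal(st$has_C[st$genome_accession == "G3"], TRUE)
})

test_that("the E. coli exception table yields 4 U-only and 14 C-only", {
  tab <- read_score_table("ecoli_exception_genomes")
  expect_equal(nrow(tab), 18L)
  summary <- categorize_genomes(status_from_scores(tab))
  expect_equal(summary$n_u_only, 4L)
  expect_equal(summary$n_c_only, 14L)
  expect_equal(summary$n_both, 0L)
  expect_equal(summary$n_neither, 0L)
  expect_equal(summary$n_total, 18L)
})

test_that("the five APEC genomes are all double positive", {
  tab <- read_score_table("apec_genomes")
  st <- status_from_scores(tab)
  expect_true(st$has_U[st$genome_accession == "NC_020163.1"])
  expect_true(st$has_C[st$genome_accession == "NC_020163.1"])
  summary <- categorize_genomes(st)
  expect_equal(summary$n_both, 5L)
  expect_equal(summary$n_total, 5L)
})

test_that("the borderline P. multocida score of 151 counts as a strict pass", {
  tab <- read_score_table("pmultocida_exception_genomes")
  summary <- categorize_genomes(status_from_scores(tab))
  # the genome scoring exactly 151 for the ushA-like probe is U-positive
  expect_equal(summary$n_both, 1L)
  expect_equal(summary$n_u_only, 1L)
  expect_equal(summary$n_c_only, 3L)
})

test_that("category counts are inferred correctly from marginal totals", {
  sapro <- infer_categories_from_counts(17, 17, 4, 4)
  expect_equal(sapro$n_u_only, 13L)
  expect_equal(sapro$n_neither, 0L)
  typhimurium <- infer_categories_from_counts(350, 219, 219, 219)
  expect_equal(typhimurium$n_neither, 131L)
  kpneu <- infer_categories_from_counts(1967, 1962, 1962, 1962)
  expect_equal(kpneu$n_neither, 5L)
  expect_error(infer_categories_from_counts(10, 8, 8, 9), "inconsistent")
  expect_error(infer_categories_from_counts(10, 8, 8, 2), "inconsistent")
})

test_that("inference from margins equals direct categorisation", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    st <- tibble::tibble(genome_accession = paste0("G", 1:n),
                         has_U = sample(c(TRUE, FALSE), n, replace = TRUE),
                         has_C = sample(c(TRUE, FALSE), n, replace = TRUE))
    direct <- categorize_genomes(st)
    inferred <- infer_categories_from_counts(
      n, sum(st$has_U), sum(st$has_C), sum(st$has_U & st$has_C))
    expect_equal(direct, inferred)
    expect_equal(direct$n_both + direct$n_u_only + direct$n_c_only +
                   direct$n_neither, direct$n_total)
  }
  expect_equal(categorize_genomes(
    tibble::tibble(genome_accession = character(), has_U = logical(),
                   has_C = logical()))$n_total, 0L)
})

test_that("complete taxa are partitioned into exactly one category each", {
  results <- tibble::tibble(
    taxid = 1:6,
    rank = "species",
    analyzed = TRUE,
    level_U = c("full", "absent", "full", "absent", "partial", "full"),
    level_C = c("full", "absent", "absent", "full", "full", "low"))
  results$complete <- is_complete(results$level_U, results$level_C)
  cc <- categorize_complete_taxa(results)
  expect_equal(nrow(cc), 4L)  # the two non-complete rows are excluded
  expect_equal(cc$category[cc$taxid == 1], "both")
  expect_equal(cc$category[cc$taxid == 2], "neither")
  expect_equal(cc$category[cc$taxid == 3], "u_only")
  expect_equal(cc$category[cc$taxid == 4], "c_only")
  expect_equal(anyDuplicated(cc$taxid), 0L)
})

test_that("the packaged category lists partition the 590 complete taxa", {
  fix <- read_complete_taxa_categories()
  expect_equal(nrow(fix), 590L)
  expect_equal(anyDuplicated(fix[, c("taxon", "taxid")]), 0L)
  # reconstruct levels from the categories and re-partition
  results <- tibble::tibble(
    taxid = fix$taxid, taxon = fix$taxon, rank = fix$rank, analyzed = TRUE,
    level_U = ifelse(fix$category %in% c("both", "u_only"), "full", "absent"),
    level_C = ifelse(fix$category %in% c("both", "c_only"), "full", "absent"),
    complete = TRUE)
  cc <- categorize_complete_taxa(results)
  expect_equal(cc$category, fix$category)
})

test_that("rank aggregation satisfies the conservation identities", {
  ds <- generate_dataset(synthetic_config(
    seed = 211, n_phyla = 2, n_classes = 2, n_orders = 1, n_families = 1,
    n_genera = 1, n_species = 2, n_genomes = 4, background_length = 6000,
    probe_length = 200))
  sv <- hierarchical_survey(ds$tree, ds$manifest, ds$genomes, ds$probes)
  agg <- glance(sv)
  total <- agg[agg$rank == "total", ]
  per_rank <- agg[agg$rank != "total", ]
  expect_equal(sum(per_rank$n_probed), total$n_probed)
  expect_equal(agg$n_analyzed, agg$n_probed - agg$n_without_genomes)
  expect_equal(agg$n_both + agg$n_u_only + agg$n_c_only + agg$n_neither,
               agg$n_complete)
  # independent recount from the tidy results
  got <- tidy(sv)
  expect_equal(total$n_probed, nrow(got))
  expect_equal(total$n_complete, sum(got$complete, na.rm = TRUE))
})

test_that("correlation percentages are one-decimal and sum to 100", {
  pct <- correlation_percentages(tibble::tibble(
    n_both = 185, n_u_only = 128, n_c_only = 46, n_neither = 231,
    n_total = 590))
  expect_equal(pct$pct_both, 31.4)
  expect_equal(pct$pct_u_only, 21.7)
  expect_equal(pct$pct_c_only, 7.8)
  expect_equal(pct$pct_neither, 39.1)
  expect_equal(pct$pct_concordant, 70.5)
  expect_equal(pct$pct_discordant, 29.5)
  expect_equal(correlation_percentages(tibble::tibble(
    n_both = 1, n_u_only = 0, n_c_only = 0, n_neither = 0,
    n_total = 1))$pct_both, 100.0)
  expect_error(correlation_percentages(tibble::tibble(
    n_both = 0, n_u_only = 0, n_c_only = 0, n_neither = 0, n_total = 0)),
    "undefined")
  # apportionment keeps the four categories summing to exactly 100.0,
  # each within one tenth of the unrounded share
  set.seed(77)
  for (i in 1:25) {
    counts <- as.integer(rmultinom(1, sample(50:2000, 1), runif(4)))
    p <- correlation_percentages(tibble::tibble(
      n_both = counts[1], n_u_only = counts[2], n_c_only = counts[3],
      n_neither = counts[4], n_total = sum(counts)))
    expect_equal(p$pct_both + p$pct_u_only + p$pct_c_only + p$pct_neither,
                 100)
    raw <- 100 * counts / sum(counts)
    expect_true(all(abs(c(p$pct_both, p$pct_u_only, p$pct_c_only,
                          p$pct_neither) - raw) < 0.1 + 1e-9))
  }
})
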