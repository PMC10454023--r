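# Small synthetic dataset shared across survey tests.
mini_config <- function(seed = 101, ...) {
  synthetic_config(seed = seed, n_phyla = 2, n_classes = 2, n_orders = 1,
                   n_families = 1, n_genera = 1, n_species = 2,
                   n_genomes = 4, background_length = 6000,
                   probe_length = 200, plasmid_fraction = 0.25, ...)
}

test_that("presence levels follow the three-tier rule with strict bounds", {
  expect_equal(classify_presence(4, 17), "low")
  expect_equal(classify_presence(135, 138), "partial")
  expect_equal(classify_presence(0, 10), "absent")
  expect_equal(classify_presence(5, 10), "low")      # 50% is still low
  expect_equal(classify_presence(6, 10), "partial")
  expect_equal(classify_presence(10, 10), "full")
  # exhaustive and monotone over k for fixed n
  for (n in c(1, 7, 20)) {
    lv <- classify_presence(0:n, rep(n, n + 1))
    ord <- match(lv, c("absent", "low", "partial", "full"))
    expect_true(all(diff(ord) >= 0))
    expect_equal(lv[1], "absent")
    expect_equal(lv[n + 1], "full")
  }
})

test_that("completeness requires each kind to be absent or fully present", {
  expect_true(is_complete("absent", "absent"))
  expect_true(is_complete("full", "absent"))
  expect_true(is_complete("full", "full"))
  expect_false(is_complete("full", "low"))
  expect_false(is_complete("partial", "absent"))
  expect_false(is_complete("low", "partial"))
})

test_that("type-material eligibility follows the rank and count rules", {
  mk <- function(n, n_type) {
    tibble::tibble(genome_accession = paste0("G", seq_len(n)), taxid = 1L,
                   is_type_material = seq_len(n) <= n_type)
  }
  cfg <- survey_config()
  expect_equal(nrow(eligible_genomes(mk(40, 10), "phylum", cfg)), 10L)
  expect_equal(nrow(eligible_genomes(mk(40, 4), "phylum", cfg)), 40L)
  expect_equal(nrow(eligible_genomes(mk(17, 3), "species", cfg)), 17L)
  expect_equal(nrow(eligible_genomes(mk(17, 12), "genus", cfg)), 17L)
})

test_that("surveying a species reflects the planted ground truth", {
  ds <- generate_dataset(mini_config())
  tree <- ds$tree
  # a species fully planted with both kinds
  plan <- ds$truth$species_plan
  sp_full <- plan$taxid[plan$plan_U == "full" & plan$plan_C == "full"][1]
  res <- survey_taxon(tree, ds$manifest, ds$genomes, ds$probes, sp_full)
  expect_true(res$analyzed)
  expect_equal(res$level_U, "full")
  expect_equal(res$level_C, "full")
  expect_true(res$complete)
  # a species planted U everywhere and C nowhere
  sp_uonly <- plan$taxid[plan$plan_U == "full" & plan$plan_C == "absent"][1]
  res2 <- survey_taxon(tree, ds$manifest, ds$genomes, ds$probes, sp_uonly)
  expect_equal(res2$level_U, "full")
  expect_equal(res2$level_C, "absent")
  expect_true(res2$complete)
  # union consistency: the per-kind count dominates every per-probe count
  pp <- res$per_probe_hits[[1]]
  u_accs <- ds$probes$accession[ds$probes$kind == "UshA-like"]
  expect_gte(res$n_genomes_U, max(pp[u_accs]))
})

test_that("a taxon with zero genomes is probed but not analyzed", {
  ds <- generate_dataset(mini_config(seed = 103))
  # graft an empty extra phylum onto the tree
  nodes <- ds$tree$nodes
  empty_phylum <- max(nodes$taxid) + 1L
  nodes <- rbind(nodes, tibble::tibble(
    taxid = empty_phylum, parent_taxid = ds$tree$root, rank = "phylum",
    name = "Phylum_empty"))
  tree <- nucleosurvey:::new_taxonomy(nodes)
  res <- survey_taxon(tree, ds$manifest, ds$genomes, ds$probes, empty_phylum)
  expect_false(res$analyzed)
  expect_true(is.na(res$complete))
  agg <- aggregate_levels(res)
  expect_equal(agg$n_without_genomes[agg$rank == "phylum"], 1L)
  expect_equal(agg$n_analyzed[agg$rank == "phylum"], 0L)
})

test_that("hierarchical survey equals an independent recursive walk", {
  ds <- generate_dataset(mini_config(seed = 107))
  sv <- hierarchical_survey(ds$tree, ds$manifest, ds$genomes, ds$probes)
  got <- tidy(sv)
  statuses <- tibble::tibble(
    genome_accession = ds$truth$genomes$genome_accession,
    has_U = ds$truth$genomes$has_U_planted,
    has_C = ds$truth$genomes$has_C_planted)
  want <- reference_survey(ds$tree, ds$manifest, statuses)
  expect_setequal(got$taxid, want$taxid)
  merged <- merge(got, want, by = "taxid", suffixes = c("_got", "_want"))
  expect_equal(merged$level_U_got, merged$level_U_want)
  expect_equal(merged$level_C_got, merged$level_C_want)
  expect_equal(merged$complete_got, merged$complete_want)
  # pruning soundness: no surveyed taxon has an analyzed complete ancestor
  surveyed <- got$taxid
  complete_analyzed <- got$taxid[!is.na(got$complete) & got$complete]
  for (t in surveyed) {
    anc <- ds$tree$nodes$parent_taxid[ds$tree$nodes$taxid == t]
    while (anc != ds$tree$root) {
      expect_false(anc %in% complete_analyzed)
      anc <- ds$tree$nodes$parent_taxid[ds$tree$nodes$taxid == anc]
    }
  }
})

test_that("an explicit taxon list is surveyed without descent", {
  ds <- generate_dataset(mini_config(seed = 109))
  sps <- descendant_taxa(ds$tree, ds$tree$root, "species")[1:3]
  sv <- hierarchical_survey(ds$tree, ds$manifest, ds$genomes, ds$probes,
                            taxids = sps)
  expect_setequal(tidy(sv)$taxid, sps)
})

test_that("presence TSV output encodes the levels textually", {
  ds <- generate_dataset(mini_config(seed = 113))
  sps <- descendant_taxa(ds$tree, ds$tree$root, "species")[1]
  sv <- hierarchical_survey(ds$tree, ds$manifest, ds$genomes, ds$probes,
                            taxids = sps)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_presence_tsv(sv, path)
  out <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  expect_true(all(out$U %in% c("-", "+<=50", "+<100", "+100", "no genomes")))
})
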