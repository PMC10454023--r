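# A synthetic panel built from `n_seeds` unrelated seed proteins, each with
# `n_copies - 1` mildly mutated copies; the generator's cluster assignment is
# the ground truth for relatedness grouping.
synthetic_panel <- function(n_seeds = 3, n_copies = 3, len = 120,
                            seed = 1) {
  rows <- list()
  for (i in seq_len(n_seeds)) {
    base <- random_probe(len, seed = seed + 100 * i)
    for (j in seq_len(n_copies)) {
      seqj <- if (j == 1) base else
        mutate_protein(base, 0.85, seed = seed + 100 * i + j)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        accession = sprintf("S%d_%d", i, j), cluster = i, sequence = seqj)
    }
  }
  dplyr::bind_rows(rows)
}

test_that("the pairwise matrix is symmetric with self-scores maximal", {
  panel <- synthetic_panel(n_seeds = 2, n_copies = 2)
  pm <- pairwise_matrix(panel)
  expect_identical(pm$scores, t(pm$scores))
  expect_true(all(diag(pm$scores) >= apply(pm$scores, 1, max) - 1e-9))
  # a single-protein panel is its self-score
  pm1 <- pairwise_matrix(panel[1, ])
  expect_equal(dim(pm1$scores), c(1L, 1L))
  expect_equal(pm1$scores[1, 1],
               local_align(panel$sequence[1], panel$sequence[1])$bit_score)
})

test_that("unrelated random proteins fall below the Nss threshold", {
  panel <- tibble::tibble(
    accession = c("A", "B"),
    sequence = c(random_probe(150, seed = 21), random_probe(150, seed = 22)))
  pm <- pairwise_matrix(panel)
  expect_lt(pm$scores["A", "B"], pm$nss_threshold)
  groups <- relatedness_groups(pm)
  expect_equal(length(unique(groups$group)), 2L)  # all singletons
})

test_that("a missing sequence is reported by panel member", {
  panel <- tibble::tibble(accession = c("A", "B"),
                          sequence = c(random_probe(100, 1), NA))
  expect_error(pairwise_matrix(panel), "B")
})

test_that("relatedness groups recover the generator's clusters", {
  panel <- synthetic_panel(n_seeds = 3, n_copies = 3, seed = 31)
  pm <- pairwise_matrix(panel)
  groups <- relatedness_groups(pm)
  expect_equal(length(unique(groups$group)), 3L)
  joined <- merge(groups, panel[, c("accession", "cluster")],
                  by.x = "member", by.y = "accession")
  # group labels are a relabelling of the planted clusters
  expect_equal(length(unique(paste(joined$group, joined$cluster))), 3L)
  # grouping is invariant to permutation of the panel
  set.seed(41)
  perm <- sample(nrow(panel))
  pm_perm <- pairwise_matrix(panel[perm, ])
  g2 <- relatedness_groups(pm_perm)
  joined2 <- merge(g2, panel[, c("accession", "cluster")],
                   by.x = "member", by.y = "accession")
  tab <- table(joined2$group, joined2$cluster)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("greedy probe selection covers the panel and matches the
           exhaustive minimal cover on small panels", {
  panel <- synthetic_panel(n_seeds = 3, n_copies = 3, seed = 51)
  pm <- pairwise_matrix(panel)
  sel <- select_probe_set(pm)
  expect_length(sel, 3L)  # one representative per cluster
  adj <- pm$scores >= pm$nss_threshold
  diag(adj) <- TRUE
  expect_true(all(colSums(adj[rownames(adj) %in% sel, , drop = FALSE]) > 0))
  expect_equal(length(sel), brute_min_cover_size(pm$scores >= pm$nss_threshold))

  # all-singleton matrix: every member selected
  lonely <- tibble::tibble(
    accession = c("A", "B", "C"),
    sequence = vapply(61:63, function(s) random_probe(130, s), character(1)))
  pm_l <- pairwise_matrix(lonely)
  expect_setequal(select_probe_set(pm_l), lonely$accession)

  # a hub related to everything: exactly one probe
  hub <- random_probe(150, seed = 71)
  spokes <- vapply(1:3, function(i) mutate_protein(hub, 0.9, seed = 70 + i),
                   character(1))
  pm_h <- pairwise_matrix(tibble::tibble(
    accession = c("HUB", paste0("S", 1:3)), sequence = c(hub, spokes)))
  expect_length(select_probe_set(pm_h), 1L)
})

test_that("the packaged panel fixture validates and tampering is caught", {
  panel <- read_probe_panel()
  report <- validate_panel_fixture(panel)
  expect_true(attr(report, "valid"))
  expect_equal(nrow(panel), 21L)
  expect_equal(sum(panel$selected), 7L)

  tampered <- panel
  tampered$length_aa[tampered$accession == "P07024"] <- 551L
  bad <- validate_panel_fixture(tampered)
  expect_false(attr(bad, "valid"))
  expect_match(bad$detail[bad$check == "selected_lengths"], "P07024")

  fewer <- panel
  fewer$selected[fewer$accession == "AYV64543"] <- FALSE
  bad2 <- validate_panel_fixture(fewer)
  expect_false(bad2$passed[bad2$check == "seven_selected"])
})
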