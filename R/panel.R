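#' Read the packaged nucleotidase probe panel
#'
#' The panel is a 21-protein set of experimentally studied periplasmic or
#' cell wall-bound bacterial nucleotidases (UshA-like 5'-nucleotidases and
#' CpdB-like 3'-nucleotidases) from which seven survey probes were selected:
#' five UshA-like (P07024, P44569, WP_000726911, WP_011837008, O32133) and
#' two CpdB-like (P08331, AYV64543). Only the metadata (accessions,
#' descriptions, lengths, kinds, selection flags) is packaged; sequences are
#' not.
#'
#' @param path Path to a panel TSV; defaults to the packaged fixture.
#' @return A tibble with columns `panel_no`, `accession`, `description`,
#'   `organism`, `length_aa`, `kind`, `selected`.
#' @export
read_probe_panel <- function(path = nucleosurvey_extdata("probe_panel.tsv")) {
  p <- readr::read_tsv(path, col_types = readr::cols(
    panel_no = readr::col_integer(),
    accession = readr::col_character(),
    description = readr::col_character(),
    organism = readr::col_character(),
    length_aa = readr::col_integer(),
    kind = readr::col_character(),
    selected = readr::col_integer()
  ))
  p$selected <- p$selected == 1L
  p
}

#' Path to a packaged data file
#'
#' @param file File name under the package's `extdata` directory; when empty,
#'   the directory itself.
#' @return A file path.
#' @export
nucleosurvey_extdata <- function(file = "") {
  system.file("extdata", file, package = "nucleosurvey", mustWork = TRUE)
}

#' All-vs-all relatedness matrix of a probe panel
#'
#' Aligns every pair of panel members with [local_align()] and records the
#' bit scores in a symmetric grid. The diagonal holds each protein's
#' self-alignment score (its row maximum). Off-diagonal scores below
#' `nss_threshold` are regarded as "not significant similitude".
#'
#' @param panel Data frame with columns `panel_no` (or `accession`) and
#'   `sequence`; all sequences must be present.
#' @param matrix,params Scoring system, see [local_align()].
#' @param nss_threshold Bit-score threshold below which two panel members are
#'   considered unrelated (default 50 bits).
#' @return A `panel_matrix` object: list with `scores` (symmetric numeric
#'   matrix, labelled by panel member) and `nss_threshold`.
#' @export
pairwise_matrix <- function(panel, matrix = blosum62(),
                            params = alignment_params(), nss_threshold = 50) {
  labels <- panel_labels(panel)
  if (!"sequence" %in% names(panel)) {
    stop("panel members without sequence: ", paste(labels, collapse = ", "),
         call. = FALSE)
  }
  missing <- which(is.na(panel$sequence) | !nzchar(panel$sequence))
  if (length(missing) > 0) {
    stop("panel members without sequence: ",
         paste(labels[missing], collapse = ", "), call. = FALSE)
  }
  n <- nrow(panel)
  scores <- base::matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- local_align(panel$sequence[[i]], panel$sequence[[j]],
                       matrix = matrix, params = params)$bit_score
      scores[i, j] <- s
      scores[j, i] <- s
    }
  }
  structure(list(scores = scores, nss_threshold = nss_threshold),
            class = "panel_matrix")
}

panel_labels <- function(panel) {
  if ("accession" %in% names(panel)) as.character(panel$accession)
  else if ("panel_no" %in% names(panel)) as.character(panel$panel_no)
  else as.character(seq_len(nrow(panel)))
}

#' @export
print.panel_matrix <- function(x, ...) {
  cat("<panel_matrix> ", nrow(x$scores), " members, Nss threshold ",
      x$nss_threshold, " bits\n", sep = "")
  print(round(x$scores, 1))
  invisible(x)
}

#' @method tidy panel_matrix
#' @export
tidy.panel_matrix <- function(x, ...) {
  df <- as.data.frame(as.table(x$scores), stringsAsFactors = FALSE)
  names(df) <- c("member_a", "member_b", "bit_score")
  out <- tibble::as_tibble(df)
  out$significant <- out$bit_score >= x$nss_threshold
  out
}

#' Heatmap of a panel relatedness matrix
#'
#' @param object A `panel_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot panel_matrix
#' @export
autoplot.panel_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$member_a, .data$member_b,
                                   fill = .data$bit_score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$bit_score)),
                       size = 2.5) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "bits") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Relatedness groups of a probe panel
#'
#' Connected components of the graph whose vertices are the panel members and
#' whose edges join pairs with an alignment score at or above the Nss
#' threshold (self-edges ignored). Members unrelated to everything else form
#' singleton groups.
#'
#' @param matrix A `panel_matrix` from [pairwise_matrix()].
#' @return A tibble with columns `member` and `group` (integer group id,
#'   numbered by first appearance).
#' @export
relatedness_groups <- function(matrix) {
  stopifnot(inherits(matrix, "panel_matrix"))
  adj <- matrix$scores >= matrix$nss_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  tibble(member = names(comp), group = as.integer(comp))
}

#' Greedy covering probe selection
#'
#' Selects a probe set that covers the whole panel: repeatedly picks the
#' member related (score at or above the Nss threshold, self included) to the
#' largest number of still-uncovered members, breaking ties by panel order.
#'
#' @param matrix A `panel_matrix` from [pairwise_matrix()].
#' @return Character vector of selected member labels, in selection order.
#' @export
select_probe_set <- function(matrix) {
  stopifnot(inherits(matrix, "panel_matrix"))
  adj <- matrix$scores >= matrix$nss_threshold
  diag(adj) <- TRUE
  labels <- rownames(adj)
  uncovered <- rep(TRUE, length(labels))
  selected <- character(0)
  while (any(uncovered)) {
    gain <- rowSums(adj[, uncovered, drop = FALSE])
    pick <- which.max(gain)  # ties: first (lowest panel order) wins
    selected <- c(selected, labels[[pick]])
    uncovered <- uncovered & !adj[pick, ]
  }
  selected
}

#' Validate the packaged probe panel fixture
#'
#' Checks the structural facts the survey relies on: 21 panel records; the
#' seven selected probes present (P07024, P44569, WP_000726911, WP_011837008,
#' O32133, P08331, AYV64543) with five UshA-like and two CpdB-like members;
#' and the printed lengths of the selected probes (550, 603, 690, 719, 462,
#' 647, 813 amino acids).
#'
#' @param panel A panel data frame as from [read_probe_panel()].
#' @return A tibble of checks with columns `check`, `passed`, `detail`.
#'   Attribute `valid` is `TRUE` when every check passed.
#' @export
validate_panel_fixture <- function(panel = read_probe_panel()) {
  expected <- tibble(
    accession = c("P07024", "P44569", "WP_000726911", "WP_011837008",
                  "O32133", "P08331", "AYV64543"),
    kind = c(rep("UshA-like", 5), rep("CpdB-like", 2)),
    length_aa = c(550L, 603L, 690L, 719L, 462L, 647L, 813L)
  )
  checks <- list()
  add <- function(check, passed, detail = "") {
    checks[[length(checks) + 1L]] <<- tibble(check = check, passed = passed,
                                             detail = detail)
  }
  add("panel_size_21", nrow(panel) == 21L, paste0("n=", nrow(panel)))
  sel <- panel[panel$selected, , drop = FALSE]
  add("seven_selected", nrow(sel) == 7L, paste0("n=", nrow(sel)))
  missing <- setdiff(expected$accession, sel$accession)
  add("selected_accessions", length(missing) == 0,
      paste(missing, collapse = ", "))
  kind_counts <- table(factor(sel$kind, c("UshA-like", "CpdB-like")))
  add("selected_kinds_5U_2C",
      kind_counts[["UshA-like"]] == 5L && kind_counts[["CpdB-like"]] == 2L,
      paste0("U=", kind_counts[["UshA-like"]], " C=", kind_counts[["CpdB-like"]]))
  joined <- dplyr::inner_join(expected, panel, by = "accession",
                              suffix = c("_expected", ""))
  bad_len <- joined$accession[joined$length_aa_expected != joined$length_aa]
  add("selected_lengths", nrow(joined) == 7L && length(bad_len) == 0,
      paste(bad_len, collapse = ", "))
  report <- dplyr::bind_rows(checks)
  attr(report, "valid") <- all(report$passed)
  report
}
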