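RANK_LADDER <- c("superkingdom", "phylum", "class", "order", "family",
                 "genus", "species")

#' Load a taxonomy from nodes/names dump files
#'
#' Reads the pipe-and-tab delimited dialect of the NCBI taxdump `nodes.dmp` /
#' `names.dmp` files (fields separated by `\t|\t`, records terminated by
#' `\t|`). Only scientific names are kept; ranks outside the
#' superkingdom-to-species ladder are mapped to `"no rank"` and such nodes are
#' traversed transparently. The root is the node that is its own parent.
#'
#' @param nodes_path Path to a nodes dump (taxid | parent taxid | rank).
#' @param names_path Path to a names dump (taxid | name | unique name | name
#'   class); rows whose name class is not `scientific name` are ignored.
#' @return A `taxonomy_tree` object: a list with `nodes` (a tibble `taxid`,
#'   `parent_taxid`, `rank`, `name`), `root` (taxid) and a children index.
#' @export
load_taxonomy <- function(nodes_path, names_path) {
  parse_dmp <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    rows <- strsplit(sub("\t\\|$", "", lines), "\t\\|\t")
    rows
  }
  nodes_rows <- parse_dmp(nodes_path)
  nodes <- tibble(
    taxid = as.integer(vapply(nodes_rows, `[[`, character(1), 1L)),
    parent_taxid = as.integer(vapply(nodes_rows, `[[`, character(1), 2L)),
    rank = vapply(nodes_rows, `[[`, character(1), 3L)
  )
  names_rows <- parse_dmp(names_path)
  name_class <- vapply(names_rows, function(r) {
    if (length(r) >= 4) r[[4]] else "scientific name"
  }, character(1))
  name_tbl <- tibble(
    taxid = as.integer(vapply(names_rows, `[[`, character(1), 1L)),
    name = vapply(names_rows, `[[`, character(1), 2L)
  )[name_class == "scientific name", ]
  nodes <- dplyr::left_join(nodes, name_tbl, by = "taxid")
  nodes$name[is.na(nodes$name)] <- paste0("taxid:", nodes$taxid[is.na(nodes$name)])
  new_taxonomy(nodes)
}

new_taxonomy <- function(nodes) {
  stopifnot(all(c("taxid", "parent_taxid", "rank", "name") %in% names(nodes)))
  if (anyDuplicated(nodes$taxid)) {
    stop("duplicated taxid(s): ",
         paste(unique(nodes$taxid[duplicated(nodes$taxid)]), collapse = ", "),
         call. = FALSE)
  }
  nodes$rank[!nodes$rank %in% RANK_LADDER] <- "no rank"
  is_root <- nodes$taxid == nodes$parent_taxid
  if (sum(is_root) != 1) {
    stop("taxonomy must have exactly one root (its own parent); found ",
         sum(is_root), call. = FALSE)
  }
  orphans <- setdiff(nodes$parent_taxid, nodes$taxid)
  if (length(orphans) > 0) {
    stop("parent taxid(s) missing from the taxonomy: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  root <- nodes$taxid[is_root]
  # reachability check doubles as a cycle check
  children <- split(nodes$taxid[!is_root], nodes$parent_taxid[!is_root])
  seen <- integer(0)
  frontier <- root
  while (length(frontier) > 0) {
    seen <- c(seen, frontier)
    frontier <- unlist(children[as.character(frontier)], use.names = FALSE)
  }
  unreachable <- setdiff(nodes$taxid, seen)
  if (length(unreachable) > 0) {
    stop("taxid(s) unreachable from the root (cycle?): ",
         paste(unreachable, collapse = ", "), call. = FALSE)
  }
  nodes <- nodes[order(nodes$taxid), ]
  structure(list(nodes = tibble::as_tibble(nodes), root = root,
                 children = children),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("<taxonomy_tree> ", nrow(x$nodes), " nodes, root taxid ", x$root,
      "\n", sep = "")
  print(dplyr::count(x$nodes, .data$rank))
  invisible(x)
}

#' Write a taxonomy as nodes/names dump files
#'
#' Inverse of [load_taxonomy()]; emits the pipe-and-tab taxdump dialect.
#'
#' @param tree A `taxonomy_tree`.
#' @param nodes_path,names_path Output paths.
#' @return The tree, invisibly.
#' @export
write_taxonomy <- function(tree, nodes_path, names_path) {
  n <- tree$nodes
  writeLines(paste0(n$taxid, "\t|\t", n$parent_taxid, "\t|\t", n$rank, "\t|"),
             nodes_path)
  writeLines(paste0(n$taxid, "\t|\t", n$name, "\t|\t\t|\tscientific name\t|"),
             names_path)
  invisible(tree)
}

taxon_children <- function(tree, taxid) {
  kids <- tree$children[[as.character(taxid)]]
  if (is.null(kids)) integer(0) else sort(kids)
}

stop_unknown_taxid <- function(tree, taxid) {
  if (!taxid %in% tree$nodes$taxid) {
    stop("unknown taxid: ", taxid, call. = FALSE)
  }
}

#' Descendants of a taxon at a given rank
#'
#' Walks the subtree below `taxid` (depth-first, ascending taxid among
#' siblings, so the order is deterministic) and returns every descendant
#' whose rank equals `rank`. Nodes with intermediate or missing ranks are
#' traversed transparently.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxid Taxon to start from (excluded from the result).
#' @param rank One of superkingdom, phylum, class, order, family, genus,
#'   species.
#' @return Integer vector of taxids.
#' @export
descendant_taxa <- function(tree, taxid, rank) {
  stop_unknown_taxid(tree, taxid)
  rank <- match.arg(rank, RANK_LADDER)
  out <- integer(0)
  walk <- function(t) {
    for (kid in taxon_children(tree, t)) {
      if (node_rank(tree, kid) == rank) out <<- c(out, kid)
      walk(kid)
    }
  }
  walk(taxid)
  out
}

node_rank <- function(tree, taxid) {
  tree$nodes$rank[match(taxid, tree$nodes$taxid)]
}

node_name <- function(tree, taxid) {
  tree$nodes$name[match(taxid, tree$nodes$taxid)]
}

#' Genomes assigned to a taxon or any of its descendants
#'
#' @param tree A `taxonomy_tree`.
#' @param manifest Genome manifest: a data frame with columns
#'   `genome_accession`, `taxid`, `is_type_material`.
#' @param taxid Taxon of interest.
#' @return The manifest rows whose taxid is `taxid` or a descendant of it.
#'   May be empty: taxa without sequenced genomes are a normal outcome.
#' @export
genomes_of <- function(tree, manifest, taxid) {
  stop_unknown_taxid(tree, taxid)
  wanted <- c(taxid, subtree_taxids(tree, taxid))
  tibble::as_tibble(manifest[manifest$taxid %in% wanted, , drop = FALSE])
}

subtree_taxids <- function(tree, taxid) {
  out <- integer(0)
  frontier <- taxon_children(tree, taxid)
  while (length(frontier) > 0) {
    out <- c(out, frontier)
    frontier <- unlist(lapply(frontier, taxon_children, tree = tree),
                       use.names = FALSE)
  }
  out
}

#' Read or write a genome manifest
#'
#' The manifest is a TSV with columns `genome_accession`, `taxid`,
#' `is_type_material` (0/1).
#'
#' @param path File path.
#' @param manifest Manifest data frame.
#' @return `read_genome_manifest()` returns a tibble; the writer returns
#'   `path` invisibly.
#' @export
read_genome_manifest <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(
    genome_accession = readr::col_character(),
    taxid = readr::col_integer(),
    is_type_material = readr::col_integer()
  ))
  m$is_type_material <- m$is_type_material == 1L
  m
}

#' @rdname read_genome_manifest
#' @export
write_genome_manifest <- function(manifest, path) {
  out <- manifest
  out$is_type_material <- as.integer(out$is_type_material)
  readr::write_tsv(out, path)
  invisible(path)
}
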