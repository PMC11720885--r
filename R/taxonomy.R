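#' Taxonomy trees: construction, lineage and lowest-common-ancestor queries
#'
#' A `taxonomy` object is a rooted, rank-labelled tree (root, phylum, class,
#' order, family, genus, species) over which peptide assignments are resolved.
#' Ranks between phylum and genus are optional: LCA operates on node identity
#' and callers project to a rank with [ancestor_at_rank()].
#'
#' @name taxonomy
NULL

TAXONOMY_RANKS <- c("root", "phylum", "class", "order", "family",
                    "genus", "species")

#' Build a taxonomy tree from a node table
#'
#' @param nodes data.frame with columns `taxon_id`, `parent_id`, `rank`,
#'   `name`. The single root row carries the sentinel parent `"ROOT"`.
#' @return an object of class `taxonomy`.
#' @export
taxonomy_tree <- function(nodes) {
  req <- c("taxon_id", "parent_id", "rank", "name")
  miss <- setdiff(req, names(nodes))
  if (length(miss)) stop("node table lacks column(s): ", paste(miss, collapse = ", "))
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)[, req]
  if (anyDuplicated(nodes$taxon_id)) stop("duplicate taxon_id values")
  bad_rank <- setdiff(unique(nodes$rank), TAXONOMY_RANKS)
  if (length(bad_rank)) stop("unknown rank(s): ", paste(bad_rank, collapse = ", "))
  roots <- nodes$taxon_id[nodes$parent_id == "ROOT"]
  if (length(roots) != 1L) stop("taxonomy must have exactly one root, found ", length(roots))
  unresolved <- setdiff(nodes$parent_id, c("ROOT", nodes$taxon_id))
  if (length(unresolved)) stop("parent_id values not in tree: ", paste(unresolved, collapse = ", "))

  parent <- stats::setNames(nodes$parent_id, nodes$taxon_id)
  rank <- stats::setNames(nodes$rank, nodes$taxon_id)
  # depth by walking up; also detects cycles
  depth <- stats::setNames(rep(NA_integer_, nrow(nodes)), nodes$taxon_id)
  for (id in nodes$taxon_id) {
    d <- 0L; cur <- id; seen <- character()
    while (parent[[cur]] != "ROOT") {
      if (cur %in% seen) stop("cycle detected at taxon ", id)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
      d <- d + 1L
      if (d > nrow(nodes)) stop("cycle detected at taxon ", id)
    }
    depth[[id]] <- d
  }
  # ranks must be non-decreasing along root->leaf paths
  ri <- match(rank, TAXONOMY_RANKS)
  for (id in nodes$taxon_id) {
    p <- parent[[id]]
    if (p != "ROOT" && ri[[match(p, nodes$taxon_id)]] > ri[[match(id, nodes$taxon_id)]]) {
      stop("rank of ", id, " (", rank[[id]], ") above its parent's rank")
    }
  }
  structure(list(nodes = nodes, parent = parent, rank = rank,
                 depth = depth, root = roots),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("taxonomy tree:", nrow(x$nodes), "nodes;",
      sum(x$rank == "genus"), "genera;",
      sum(x$rank == "phylum"), "phyla\n")
  invisible(x)
}

assert_taxa <- function(tree, taxa) {
  unknown <- setdiff(taxa, names(tree$parent))
  if (length(unknown)) stop("unknown taxon/taxa: ", paste(unknown, collapse = ", "))
}

#' Lineage of a taxon, root first
#'
#' @param tree a `taxonomy`.
#' @param taxon_id a taxon identifier.
#' @return character vector of taxon ids from the root down to `taxon_id`.
#' @export
lineage <- function(tree, taxon_id) {
  assert_taxa(tree, taxon_id)
  out <- taxon_id
  cur <- taxon_id
  while (tree$parent[[cur]] != "ROOT") {
    cur <- tree$parent[[cur]]
    out <- c(cur, out)
  }
  out
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node lying on the lineage of every taxon in the set; the
#' taxonomic resolution assigned to a peptide whose matched proteins span
#' those taxa. Commutative and associative over the set.
#'
#' @param tree a `taxonomy`.
#' @param taxa non-empty character vector of taxon ids.
#' @return a single taxon id.
#' @export
lca <- function(tree, taxa) {
  taxa <- unique(taxa)
  if (!length(taxa)) stop("lca of an empty taxon set is undefined")
  assert_taxa(tree, taxa)
  cur <- taxa[[1]]
  for (other in taxa[-1]) {
    a <- cur; b <- other
    while (tree$depth[[a]] > tree$depth[[b]]) a <- tree$parent[[a]]
    while (tree$depth[[b]] > tree$depth[[a]]) b <- tree$parent[[b]]
    while (a != b) {
      a <- tree$parent[[a]]
      b <- tree$parent[[b]]
    }
    cur <- a
  }
  cur
}

#' Ancestor of a taxon at a requested rank
#'
#' Walks the lineage of `taxon_id` and returns the unique node carrying
#' `rank`, or `NA` when the lineage terminates above that rank (e.g. the root
#' has no genus). A node at the requested rank returns itself, so taxa
#' resolved below genus project onto their genus.
#'
#' @param tree a `taxonomy`.
#' @param taxon_id a taxon id.
#' @param rank one of `r toString(TAXONOMY_RANKS)`.
#' @return a taxon id or `NA_character_`.
#' @export
ancestor_at_rank <- function(tree, taxon_id, rank) {
  if (!rank %in% TAXONOMY_RANKS) stop("unknown rank: ", rank)
  lin <- lineage(tree, taxon_id)
  hit <- lin[tree$rank[lin] == rank]
  if (length(hit)) hit[[1]] else NA_character_
}

#' Read / write the 4-column taxonomy TSV dialect
#'
#' Columns `taxon_id`, `parent_id`, `rank`, `name`; the root row has parent
#' `"ROOT"`.
#'
#' @param path file path.
#' @return `read_taxonomy()` returns a `taxonomy`; `write_taxonomy()` the path.
#' @export
read_taxonomy <- function(path) {
  taxonomy_tree(read_tsv_strict(path, c("taxon_id", "parent_id", "rank", "name")))
}

#' @rdname read_taxonomy
#' @param tree a `taxonomy`.
#' @export
write_taxonomy <- function(tree, path) {
  write_tsv(tree$nodes, path)
}

#' Read a protein-to-taxon map TSV (`protein_id`, `taxon_id`)
#'
#' @param path file path.
#' @return data.frame with columns `protein_id`, `taxon_id`.
#' @export
read_protein_map <- function(path) {
  read_tsv_strict(path, c("protein_id", "taxon_id"))
}
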