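#' Construct a taxonomy object from a node table
#'
#' A taxonomy is a rooted tree whose nodes carry a rank from the fixed ladder
#' domain > phylum > class > order > family > genus. Ranks strictly increase
#' in depth along any root-to-leaf path, every non-root node has exactly one
#' parent, and names are unique within a rank.
#'
#' @param nodes A data frame with columns `id` (integer), `name`, `rank`
#'   (one of [tax_ranks()]) and `parent` (integer id, `NA` for the root).
#' @return An object of class `taxonomy`: the node table plus a precomputed
#'   per-node lineage matrix (node id at each rank along the path to the
#'   root) stored as attribute `lineage`.
#' @export
taxonomy <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "name", "rank", "parent") %in% names(nodes)))
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$rank <- as.character(nodes$rank)
  nodes$name <- as.character(nodes$name)
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  if (!all(nodes$rank %in% TAX_RANKS)) stop("unknown rank in node table")
  root <- nodes$id[is.na(nodes$parent)]
  if (length(root) != 1L) stop("taxonomy must have exactly one root")
  for (r in unique(nodes$rank)) {
    nm <- nodes$name[nodes$rank == r]
    if (anyDuplicated(nm)) stop("names must be unique within rank ", r)
  }
  ri <- match(nodes$rank, TAX_RANKS)
  pi <- match(nodes$parent, nodes$id)
  bad <- !is.na(nodes$parent) & (is.na(pi) | ri <= ri[pi])
  if (any(bad)) stop("every child must have a known parent of shallower rank")
  lin <- matrix(NA_integer_, nrow(nodes), length(TAX_RANKS),
                dimnames = list(NULL, TAX_RANKS))
  for (i in seq_len(nrow(nodes))) {
    j <- i
    while (!is.na(j)) {
      lin[i, ri[j]] <- nodes$id[j]
      j <- pi[j]
    }
  }
  structure(nodes, lineage = lin, class = c("taxonomy", "data.frame"))
}

#' Build a synthetic taxonomy
#'
#' Creates a complete rank ladder under a single bacterial domain:
#' `n_phyla` phyla, one class per phylum, up to two orders per class, and
#' `families_per_phylum` families per phylum (distributed round-robin over
#' the orders), each family holding exactly one genus. The construction is
#' deterministic; `seed` is accepted for interface symmetry with the other
#' generators.
#'
#' @param n_phyla,families_per_phylum Positive counts.
#' @param seed Integer; unused by the deterministic construction.
#' @return A [taxonomy()] object.
#' @examples
#' tr <- build_taxonomy(2, 3, seed = 7)
#' sum(tr$rank == "family")
#' @export
build_taxonomy <- function(n_phyla, families_per_phylum, seed = 0L) {
  if (length(n_phyla) != 1L || length(families_per_phylum) != 1L ||
      is.na(n_phyla) || is.na(families_per_phylum) ||
      n_phyla < 1 || families_per_phylum < 1)
    stop("n_phyla and families_per_phylum must be positive counts")
  n_phyla <- as.integer(n_phyla)
  families_per_phylum <- as.integer(families_per_phylum)
  rows <- list(data.frame(id = 1L, name = "Bacteria", rank = "domain",
                          parent = NA_integer_, stringsAsFactors = FALSE))
  nid <- 1L
  fam_counter <- 0L
  for (p in seq_len(n_phyla)) {
    pid <- nid <- nid + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      id = pid, name = sprintf("Phylum_%02d", p), rank = "phylum",
      parent = 1L, stringsAsFactors = FALSE)
    cid <- nid <- nid + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      id = cid, name = sprintf("Class_%02d", p), rank = "class",
      parent = pid, stringsAsFactors = FALSE)
    n_orders <- min(2L, families_per_phylum)
    oids <- integer(n_orders)
    for (o in seq_len(n_orders)) {
      oid <- nid <- nid + 1L
      oids[o] <- oid
      rows[[length(rows) + 1L]] <- data.frame(
        id = oid, name = sprintf("Order_%02d_%d", p, o), rank = "order",
        parent = cid, stringsAsFactors = FALSE)
    }
    for (f in seq_len(families_per_phylum)) {
      fam_counter <- fam_counter + 1L
      fid <- nid <- nid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        id = fid, name = sprintf("Family_%02d", fam_counter), rank = "family",
        parent = oids[((f - 1L) %% n_orders) + 1L], stringsAsFactors = FALSE)
      gid <- nid <- nid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        id = gid, name = sprintf("Genus_%02d", fam_counter), rank = "genus",
        parent = fid, stringsAsFactors = FALSE)
    }
  }
  taxonomy(do.call(rbind, rows))
}

#' Per-rank lineage of a node
#'
#' @param tree A [taxonomy()] object.
#' @param id Node id(s).
#' @param what `"id"` for node ids, `"name"` for node names.
#' @return For one id, a named vector over ranks (NA above/below the node's
#'   span); for several, a matrix with one row per id.
#' @export
tax_lineage <- function(tree, id, what = c("name", "id")) {
  what <- match.arg(what)
  lin <- attr(tree, "lineage")
  rows <- match(id, tree$id)
  if (anyNA(rows)) stop("unknown node id")
  out <- lin[rows, , drop = FALSE]
  if (what == "name") {
    out <- matrix(tree$name[match(out, tree$id)], nrow(out), ncol(out),
                  dimnames = dimnames(out))
  }
  if (length(id) == 1L) out[1L, ] else out
}

#' Lineage string "domain;phylum;...;genus" for a node
#' @inheritParams tax_lineage
#' @return Character vector of semicolon-joined lineage names.
#' @export
tax_lineage_string <- function(tree, id) {
  lin <- tax_lineage(tree, id, "name")
  if (is.null(dim(lin))) lin <- matrix(lin, nrow = 1L)
  apply(lin, 1L, function(x) paste(x[!is.na(x)], collapse = ";"))
}

#' Lowest common ancestor of a set of nodes
#'
#' @param tree A [taxonomy()] object.
#' @param ids Node ids.
#' @return The id of the deepest node whose subtree contains all of `ids`.
#' @export
lca_node <- function(tree, ids) {
  lin <- attr(tree, "lineage")
  rows <- match(ids, tree$id)
  if (anyNA(rows)) stop("unknown node id")
  sub <- lin[rows, , drop = FALSE]
  out <- NA_integer_
  for (r in seq_along(TAX_RANKS)) {
    v <- unique(sub[, r])
    if (length(v) == 1L && !is.na(v)) out <- v else break
  }
  out
}

#' Nodes at a given rank
#' @inheritParams tax_lineage
#' @param rank One of [tax_ranks()].
#' @return The node-table rows at that rank, ordered by name.
#' @export
tax_nodes_at_rank <- function(tree, rank) {
  rank <- match.arg(rank, TAX_RANKS)
  out <- tree[tree$rank == rank, , drop = FALSE]
  out[order(out$name), , drop = FALSE]
}

#' Newick string for a taxonomy
#'
#' Leaves are genus names; internal node labels are kept.
#' @inheritParams tax_lineage
#' @return A single Newick string, semicolon-terminated.
#' @export
taxonomy_to_newick <- function(tree) {
  kids <- split(tree$id, factor(tree$parent, levels = tree$id))
  rec <- function(id) {
    ch <- kids[[as.character(id)]]
    nm <- tree$name[match(id, tree$id)]
    if (is.null(ch) || length(ch) == 0L) return(nm)
    paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")", nm)
  }
  root <- tree$id[is.na(tree$parent)]
  paste0(rec(root), ";")
}

#' Write a taxonomy as parent-child TSV and Newick
#'
#' @inheritParams tax_lineage
#' @param tsv,newick Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_taxonomy <- function(tree, tsv = NULL, newick = NULL) {
  if (!is.null(tsv))
    write.table(as.data.frame(tree), tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(newick))
    writeLines(taxonomy_to_newick(tree), newick)
  invisible(c(tsv, newick))
}
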