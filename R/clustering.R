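# Complete-linkage clustering of enzymes on symmetric E-value distances,
# cut at the similarity threshold. The result is a forest: one binary
# merge tree per cluster, plus one-node trees for unclustered sequences.
#
# Trees are lists of node records; every node carries the member record
# ids below it, the E-value of the merge that created it, and the union
# of its members' EC sets.

new_node <- function(node_id, left = NA_integer_, right = NA_integer_,
                     members, merge_evalue = NA_real_, ec_set = character(0),
                     record_id = NA_character_) {
  list(node_id = node_id, left = left, right = right, parent = NA_integer_,
       members = members, merge_evalue = merge_evalue,
       ec_set = ec_set, record_id = record_id,
       pattern_id = NA_character_, tried = FALSE)
}

#' Complete-linkage clustering into a forest of merge trees
#'
#' Standard agglomerative complete linkage: repeatedly merge the pair of
#' clusters with the smallest inter-cluster distance, where the distance
#' between clusters is the maximum over all cross pairs and an absent
#' pairwise distance counts as `+Inf`. Merging stops when the smallest
#' distance exceeds `cutoff`, so the single-tree dendrogram falls apart
#' into many trees; records that never merge become singleton trees.
#'
#' Ties between equal inter-cluster distances are broken by the
#' lexicographically smallest sorted pair of the two clusters' smallest
#' member ids, which makes the forest deterministic.
#'
#' @param distances data.frame (`id_a`, `id_b`, `evalue`) from
#'   [symmetrify()]; one entry per unordered pair (duplicates error).
#' @param ids character vector of all enzyme record ids to cluster.
#' @param ec_sets optional named list (id -> character vector of ECs)
#'   used to annotate nodes; leaves of unknown ids get empty EC sets.
#' @param cutoff E-value threshold ending the agglomeration.
#' @return an `enz_forest`: list with `trees`, each tree a list with
#'   `tree_id`, `root` (node id), `nodes` (list of node records),
#'   `members`, and `singleton` flag.
#' @export
complete_linkage <- function(distances, ids, ec_sets = NULL, cutoff = 1e-3) {
  ids <- as.character(ids)
  stopifnot(!anyDuplicated(ids))
  n <- length(ids)
  if (is.null(ec_sets)) ec_sets <- list()
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  if (nrow(distances) > 0L) {
    k <- key(distances$id_a, distances$id_b)
    if (anyDuplicated(k)) stop("duplicate distance entry for a pair")
    if (any(distances$id_a == distances$id_b)) stop("self-distance entry")
    unknown <- setdiff(c(distances$id_a, distances$id_b), ids)
    if (length(unknown)) stop("distance refers to unknown id: ", unknown[1])
  }
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  if (nrow(distances) > 0L) {
    D[cbind(distances$id_a, distances$id_b)] <- distances$evalue
    D[cbind(distances$id_b, distances$id_a)] <- distances$evalue
  }
  diag(D) <- Inf

  nodes <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    nodes[[i]] <- new_node(i, members = ids[i],
                           ec_set = ec_sets[[ids[i]]] %||% character(0),
                           record_id = ids[i])
  }
  n_nodes <- n
  active <- seq_len(n)           # node id of each active cluster
  act_min <- ids                 # smallest member id per active cluster
  # D rows/cols track active clusters, in the same order as `active`
  while (length(active) > 1L) {
    dmin <- min(D)
    if (!is.finite(dmin) || dmin > cutoff) break
    cand <- which(D == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pairs_a <- pmin(act_min[cand[, 1]], act_min[cand[, 2]])
    pairs_b <- pmax(act_min[cand[, 1]], act_min[cand[, 2]])
    pick <- order(pairs_a, pairs_b)[1L]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    ni <- active[i]; nj <- active[j]
    n_nodes <- n_nodes + 1L
    nodes[[n_nodes]] <- new_node(
      n_nodes, left = ni, right = nj,
      members = c(nodes[[ni]]$members, nodes[[nj]]$members),
      merge_evalue = dmin,
      ec_set = sort(unique(c(nodes[[ni]]$ec_set, nodes[[nj]]$ec_set))))
    nodes[[ni]]$parent <- n_nodes
    nodes[[nj]]$parent <- n_nodes
    newrow <- pmax(D[i, ], D[j, ])
    D[i, ] <- newrow; D[, i] <- newrow; D[i, i] <- Inf
    D <- D[-j, -j, drop = FALSE]
    active[i] <- n_nodes
    act_min[i] <- min(act_min[i], act_min[j])
    active <- active[-j]
    act_min <- act_min[-j]
  }
  nodes <- nodes[seq_len(n_nodes)]

  trees <- list()
  for (root_id in active) {
    tree_nodes <- collect_subtree(nodes, root_id)
    members <- nodes[[root_id]]$members
    trees[[length(trees) + 1L]] <- list(
      tree_id = length(trees) + 1L,
      root = root_id,
      nodes = tree_nodes,
      members = members,
      singleton = length(members) == 1L)
  }
  structure(list(trees = trees, cutoff = cutoff), class = "enz_forest")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add singleton trees for unclustered records
#'
#' Every enzyme id absent from the forest's trees gets an artificial
#' one-node tree, so unclustered sequences are still represented (later
#' by an exact-sequence pattern). [complete_linkage()] already does this
#' for the ids it is given; this covers records that never entered the
#' distance table.
#'
#' @param forest an `enz_forest`.
#' @param ids character vector of all enzyme record ids.
#' @param ec_sets optional named list (id -> ECs).
#' @return the augmented forest.
#' @export
add_singletons <- function(forest, ids, ec_sets = NULL) {
  have <- forest_members(forest)
  missing <- setdiff(as.character(ids), have)
  if (is.null(ec_sets)) ec_sets <- list()
  for (id in missing) {
    nd <- new_node(1L, members = id,
                   ec_set = ec_sets[[id]] %||% character(0), record_id = id)
    forest$trees[[length(forest$trees) + 1L]] <- list(
      tree_id = length(forest$trees) + 1L, root = 1L,
      nodes = stats::setNames(list(nd), "1"),
      members = id, singleton = TRUE)
  }
  forest
}

collect_subtree <- function(nodes, root_id) {
  out <- list()
  stack <- root_id
  while (length(stack)) {
    id <- stack[[1]]; stack <- stack[-1]
    nd <- nodes[[id]]
    out[[as.character(id)]] <- nd
    if (!is.na(nd$left)) stack <- c(stack, nd$left, nd$right)
  }
  out
}

#' @export
print.enz_forest <- function(x, ...) {
  nt <- length(x$trees)
  ns <- sum(vapply(x$trees, `[[`, logical(1), "singleton"))
  nm <- sum(vapply(x$trees, function(t) length(t$members), integer(1)))
  cat(sprintf("complete-linkage forest: %d trees (%d singletons), %d records, cutoff %g\n",
              nt, ns, nm, x$cutoff))
  invisible(x)
}

#' All record ids covered by a forest
#' @param forest an `enz_forest`.
#' @return character vector of record ids.
#' @export
forest_members <- function(forest) {
  unlist(lapply(forest$trees, `[[`, "members"), use.names = FALSE)
}

#' Clustering variability per EC group
#'
#' For each EC key at the requested resolution, counts the enzymes
#' annotated with it and the trees holding at least one of them. The
#' ratio sequences/trees is the average number of such enzymes per tree:
#' a large ratio means many near-identical sequences collapsed into few
#' trees (low variability), a ratio near 1 means high variability.
#'
#' @param forest an `enz_forest`.
#' @param records enzyme records (with `id` and `ec` columns).
#' @param level one of `"ec"` (full EC string, default), `"sub_subclass"`,
#'   `"subclass"`, `"class"`.
#' @return data.frame with `ec_group`, `n_trees`, `n_sequences`, `ratio`.
#' @export
tree_variability <- function(forest, records, level = "ec") {
  keyf <- switch(level,
    ec = identity,
    sub_subclass = function(e) sub("^((?:[^.]+\\.){2}[^.]+)\\..*$", "\\1", e),
    subclass = function(e) sub("^([^.]+\\.[^.]+)\\..*$", "\\1", e),
    class = function(e) sub("\\..*$", "", e),
    stop("unknown level: ", level))
  rec_keys <- lapply(records$ec, function(ecs) unique(keyf(ecs)))
  names(rec_keys) <- records$id
  all_keys <- sort(unique(unlist(rec_keys)))
  n_seq <- vapply(all_keys, function(k)
    sum(vapply(rec_keys, function(v) k %in% v, logical(1))), integer(1))
  n_trees <- vapply(all_keys, function(k) {
    sum(vapply(forest$trees, function(tr) {
      any(vapply(rec_keys[intersect(tr$members, names(rec_keys))],
                 function(v) k %in% v, logical(1)))
    }, logical(1)))
  }, integer(1))
  data.frame(ec_group = all_keys, n_trees = n_trees, n_sequences = n_seq,
             ratio = round(n_seq / n_trees, 2), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Export a forest as JSON (nested) and flat TSV
#'
#' @param forest an `enz_forest`.
#' @param json_path,tsv_path output paths (`NULL` to skip either).
#' @return invisibly, the flat node table (`tree_id`, `node_id`,
#'   `parent_id`, `merge_evalue`, `member_count`, `ec_list`).
#' @export
write_forest <- function(forest, json_path = NULL, tsv_path = NULL) {
  nest <- function(tree, id) {
    nd <- tree$nodes[[as.character(id)]]
    out <- list(node_id = nd$node_id, merge_evalue = nd$merge_evalue,
                members = as.list(nd$members), ec_set = as.list(nd$ec_set))
    if (!is.na(nd$left))
      out$children <- list(nest(tree, nd$left), nest(tree, nd$right))
    out
  }
  if (!is.null(json_path)) {
    obj <- lapply(forest$trees, function(tr)
      list(tree_id = tr$tree_id, singleton = tr$singleton,
           root = nest(tr, tr$root)))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  flat <- do.call(rbind, lapply(forest$trees, function(tr) {
    do.call(rbind, lapply(tr$nodes, function(nd) data.frame(
      tree_id = tr$tree_id, node_id = nd$node_id, parent_id = nd$parent,
      merge_evalue = nd$merge_evalue, member_count = length(nd$members),
      ec_list = paste(nd$ec_set, collapse = ";"), stringsAsFactors = FALSE)))
  }))
  rownames(flat) <- NULL
  if (!is.null(tsv_path))
    utils::write.table(flat, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(flat)
}

#' Newick export of a forest (for visual inspection)
#'
#' Branch "lengths" carry `-log10(merge E-value)` differences and are for
#' eyeballing topologies only.
#'
#' @param forest an `enz_forest`.
#' @return character vector, one Newick string per tree.
#' @export
forest_newick <- function(forest) {
  h <- function(e) if (is.na(e)) 0 else -log10(e)
  vapply(forest$trees, function(tr) {
    rec <- function(id, parent_h) {
      nd <- tr$nodes[[as.character(id)]]
      my_h <- if (is.na(nd$left)) 0 else h(nd$merge_evalue)
      bl <- max(parent_h - my_h, 0)
      if (is.na(nd$left))
        sprintf("%s:%.4g", nd$record_id, bl)
      else
        sprintf("(%s,%s):%.4g", rec(nd$left, my_h), rec(nd$right, my_h), bl)
    }
    root_h <- h(tr$nodes[[as.character(tr$root)]]$merge_evalue)
    paste0(rec(tr$root, root_h), ";")
  }, character(1))
}
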