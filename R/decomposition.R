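# Network decomposition: pull target fragments back through reaction atom
# maps, close the MFP set recursively, group it into strongly connected
# components and order the components topologically into solvable clusters.

# Pull one fragment pair back through one mapping entry.  Returns one link
# per product occurrence of fragment$metabolite in the entry (a reaction may
# produce the same metabolite more than once).
links_for_entry <- function(fragment, entry) {
  links <- list()
  # letter -> (substrate slot, substrate atom index)
  letter_slot <- integer(0); letter_pos <- integer(0); letter_key <- character(0)
  for (si in seq_along(entry$substrates)) {
    at <- entry$substrates[[si]]$atoms
    if (length(at)) {
      letter_key <- c(letter_key, at)
      letter_slot <- c(letter_slot, rep.int(si, length(at)))
      letter_pos <- c(letter_pos, seq_along(at))
    }
  }
  names(letter_slot) <- letter_key; names(letter_pos) <- letter_key
  for (po in seq_along(entry$products)) {
    prod <- entry$products[[po]]
    if (prod$met != fragment$metabolite) next
    L <- prod$atoms
    if (length(fragment$parent) && max(fragment$parent) > length(L))
      abort_validation("fragment %s exceeds atom count of %s in reaction %s",
                       mfp_id(fragment), prod$met, entry$id)
    pl <- L[fragment$parent]
    if (anyNA(letter_slot[pl]))
      abort_validation(
        "reaction %s: atom %d of %s has no substrate source (untracked influx must come from a media metabolite)",
        entry$id, fragment$parent[which(is.na(letter_slot[pl]))[1L]],
        fragment$metabolite)
    slots <- sort(unique(unname(letter_slot[pl])))
    sources <- list()
    for (si in slots) {
      par_atoms <- sort(letter_pos[pl[letter_slot[pl] == si]])
      kl <- L[fragment$product]
      prod_atoms <- if (length(kl))
        sort(letter_pos[kl[letter_slot[kl] == si]]) else integer(0)
      sources[[length(sources) + 1L]] <-
        mfp(entry$substrates[[si]]$met, par_atoms, prod_atoms)
    }
    links[[length(links) + 1L]] <- list(
      reaction = entry$id, flux_id = entry$flux_id %||% entry$id,
      weight = entry$weight, occurrence = po,
      type = if (length(sources) >= 2L) "bi" else "uni",
      sources = sources)
  }
  links
}

#' Substrate MFPs of a fragment pair through a reaction
#'
#' Pulls each atom of the parent (and product) fragment back through the
#' reaction's atom map to substrate atoms and partitions the preimage by
#' substrate.  One source MFP is emitted per substrate with a non-empty
#' preimage: two non-empty preimages give a bi-substrate (condensation) link
#' whose tandemer matrix enters balance equations as a Cauchy product; a
#' bi-substrate reaction in which one substrate receives no parent atoms is
#' demoted to a uni-substrate link.
#'
#' @param fragment An [mfp()] whose metabolite the reaction produces.
#' @param entry A mapping entry of a `"tandemer_network"` (an element of
#'   `network$reactions`).
#' @return List of links, one per product occurrence: each a list with
#'   `reaction`, `weight`, `type` (`"uni"`/`"bi"`) and `sources` (list of
#'   source [mfp()]s in substrate-slot order).
#' @export
substrate_mfps <- function(fragment, entry) {
  links <- links_for_entry(fragment, entry)
  if (!length(links))
    abort_validation("reaction %s does not produce %s", entry$id,
                     fragment$metabolite)
  links
}

#' Identify the minimal MFP set needed for a set of targets
#'
#' Starting from the target fragment pairs, traverses the network backwards,
#' iteratively adding the substrate MFPs of every producing reaction, until
#' closure.  Fragment pairs of media metabolites become boundary nodes (their
#' tandemer distributions are fixed by the tracer specification and their
#' producers are not traversed).
#'
#' @param network A `"tandemer_network"`.
#' @param targets List of [mfp()] targets.
#' @return An `"mfp_graph"`: list with `nodes` (internal MFPs, named by
#'   canonical id), `boundary` (media-metabolite MFPs), `edges` (one record
#'   per producing reaction occurrence), `targets`, `network`.
#' @export
identify_mfps <- function(network, targets) {
  nodes <- list(); boundary <- list(); edges <- list()
  target_ids <- character(0)
  queue <- list()
  push <- function(f) {
    id <- mfp_id(f)
    if (length(f$parent) == 0L) return(invisible(NULL))  # degenerate, dropped
    if (is_media_met(network, f$metabolite)) {
      if (is.null(boundary[[id]])) boundary[[id]] <<- f
    } else if (is.null(nodes[[id]])) {
      nodes[[id]] <<- f
      queue[[length(queue) + 1L]] <<- f
    }
    invisible(NULL)
  }
  for (f in targets) {
    n <- n_atoms_of(network, f$metabolite)
    if (length(f$parent) && max(f$parent) > n)
      abort_validation("target %s exceeds the %d atoms of %s",
                       mfp_id(f), n, f$metabolite)
    if (length(f$parent) == 0L) {
      warning(sprintf("dropping degenerate target %s (empty parent fragment)", mfp_id(f)))
      next
    }
    target_ids <- c(target_ids, mfp_id(f))
    push(f)
  }

  # producing entries per metabolite
  producers <- list()
  for (ei in seq_along(network$reactions)) {
    e <- network$reactions[[ei]]
    for (t in e$products) if (length(t$atoms))
      producers[[t$met]] <- c(producers[[t$met]], ei)
  }

  while (length(queue)) {
    f <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    eis <- unique(producers[[f$metabolite]])
    if (is.null(eis))
      abort_validation(
        "metabolite '%s' (needed for %s) has no producing reaction and is not a media metabolite",
        f$metabolite, mfp_id(f))
    for (ei in eis) {
      for (link in links_for_entry(f, network$reactions[[ei]])) {
        edges[[length(edges) + 1L]] <- list(
          target = mfp_id(f), reaction = link$reaction,
          flux_id = link$flux_id, weight = link$weight,
          occurrence = link$occurrence, type = link$type,
          sources = vapply(link$sources, mfp_id, ""),
          source_mfps = link$sources)
        for (s in link$sources) push(s)
      }
    }
  }

  nodes <- nodes[sort_radix(names(nodes))]
  boundary <- boundary[sort_radix(names(boundary))]
  structure(list(nodes = nodes, boundary = boundary, edges = edges,
                 targets = unique(target_ids), network = network,
                 clusters = NULL),
            class = "mfp_graph")
}

#' @export
print.mfp_graph <- function(x, ...) {
  cat(sprintf("<mfp_graph> %d internal MFPs, %d boundary (media) MFPs, %d edges",
              length(x$nodes), length(x$boundary), length(x$edges)))
  if (!is.null(x$clusters))
    cat(sprintf("; %d clusters (max size %d)", length(x$clusters),
                max(lengths(x$clusters))))
  cat("\n")
  invisible(x)
}

#' Cluster and order an MFP graph
#'
#' Decomposes the internal-node dependency graph into strongly connected
#' components and orders the components topologically, so that every edge
#' points from an earlier (or the same) cluster to a later one.  Components
#' are emitted in non-decreasing parent-fragment size; ties are broken by the
#' smallest canonical MFP id in the component, making the order deterministic.
#' Within a component all members share the same parent and product fragment
#' sizes (only same-size uni-substrate links can close a cycle; condensation
#' links always come from strictly smaller fragments).
#'
#' @param graph An `"mfp_graph"` from [identify_mfps()].
#' @return The graph with `clusters` (ordered list of member-id vectors),
#'   `cluster_parent_sizes` and `cluster_product_sizes` filled in.
#' @export
cluster_and_sort <- function(graph) {
  ids <- names(graph$nodes)
  if (length(ids) == 0L) {
    graph$clusters <- list()
    graph$cluster_parent_sizes <- integer(0)
    graph$cluster_product_sizes <- integer(0)
    return(graph)
  }
  from <- character(0); to <- character(0)
  for (e in graph$edges) {
    int_src <- e$sources[e$sources %in% ids]
    if (length(int_src)) {
      from <- c(from, int_src)
      to <- c(to, rep.int(e$target, length(int_src)))
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership[ids]
  members <- split(ids, memb)
  members <- lapply(members, sort_radix)

  psize <- vapply(members, function(m) length(graph$nodes[[m[1L]]]$parent), 0L)
  ksize <- vapply(members, function(m) length(graph$nodes[[m[1L]]]$product), 0L)
  for (ci in seq_along(members)) {
    sz <- vapply(members[[ci]], function(id) length(graph$nodes[[id]]$parent), 0L)
    if (length(unique(sz)) != 1L)
      abort_numerical("internal error: mixed parent sizes within one strongly connected component")
  }
  minid <- vapply(members, function(m) m[1L], "")

  # cluster-level DAG
  cl_of <- stats::setNames(rep(seq_along(members), lengths(members)),
                           unlist(members))
  nc <- length(members)
  preds <- vector("list", nc)
  indeg <- integer(nc)
  seen_edge <- character(0)
  for (i in seq_along(from)) {
    a <- unname(cl_of[from[i]]); b <- unname(cl_of[to[i]])
    if (a == b) next
    key <- paste(a, b)
    if (key %in% seen_edge) next
    seen_edge <- c(seen_edge, key)
    preds[[b]] <- c(preds[[b]], a)
    indeg[b] <- indeg[b] + 1L
  }
  succs <- vector("list", nc)
  for (key in seen_edge) {
    ab <- as.integer(strsplit(key, " ", fixed = TRUE)[[1L]])
    succs[[ab[1L]]] <- c(succs[[ab[1L]]], ab[2L])
  }

  # Kahn's algorithm with (parent size, smallest member id) priority
  order_out <- integer(0)
  remaining <- rep(TRUE, nc)
  while (any(remaining)) {
    ready <- which(remaining & indeg == 0L)
    if (!length(ready))
      abort_numerical("internal error: cluster graph is cyclic")
    pick <- ready[order(psize[ready], minid[ready], method = "radix")][1L]
    order_out <- c(order_out, pick)
    remaining[pick] <- FALSE
    for (s in succs[[pick]]) indeg[s] <- indeg[s] - 1L
  }

  graph$clusters <- members[order_out]
  names(graph$clusters) <- NULL
  graph$cluster_parent_sizes <- unname(psize[order_out])
  graph$cluster_product_sizes <- unname(ksize[order_out])
  graph
}

#' Decomposition statistics
#'
#' Summarizes an MFP graph: internal / boundary / total fragment-pair counts,
#' ordered cluster sizes, per-metabolite MFP counts and the theoretical
#' `< 3^n` bound on the number of fragment pairs a metabolite with `n` atoms
#' can contribute.
#'
#' @param graph An `"mfp_graph"`; clustered with [cluster_and_sort()] first if
#'   necessary.
#' @return List with `n_internal`, `n_boundary`, `n_total`, `n_clusters`,
#'   `cluster_sizes`, `max_cluster_size`, `cluster_parent_sizes`,
#'   `per_metabolite` (data.frame with the `3^n` bound check).
#' @export
decomposition_stats <- function(graph) {
  if (is.null(graph$clusters)) graph <- cluster_and_sort(graph)
  all_mfps <- c(graph$nodes, graph$boundary)
  mets <- vapply(all_mfps, `[[`, "", "metabolite")
  tab <- table(mets)
  per <- data.frame(metabolite = names(tab), n_mfps = as.integer(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  per$n_atoms <- vapply(per$metabolite,
                        function(m) n_atoms_of(graph$network, m), 0L)
  per$bound_3n <- 3^per$n_atoms
  per$within_bound <- per$n_mfps < per$bound_3n
  per <- per[order_radix(per$metabolite), , drop = FALSE]
  row.names(per) <- NULL
  list(n_internal = length(graph$nodes),
       n_boundary = length(graph$boundary),
       n_total = length(graph$nodes) + length(graph$boundary),
       n_clusters = length(graph$clusters),
       cluster_sizes = lengths(graph$clusters),
       max_cluster_size = if (length(graph$clusters))
         max(lengths(graph$clusters)) else 0L,
       cluster_parent_sizes = graph$cluster_parent_sizes,
       per_metabolite = per)
}
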