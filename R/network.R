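#' Tag and merge seed-node sets from the two omics layers
#'
#' @param proteomics_seeds,mrna_seeds character vectors of seed symbols.
#' @return tibble: `node`, `origin` (`"seed_proteomics"`, `"seed_mrna"`, or
#'   `"seed_both"` on overlap).
#' @export
merge_seed_sets <- function(proteomics_seeds, mrna_seeds) {
  p <- unique(trimws(proteomics_seeds))
  m <- unique(trimws(mrna_seeds))
  nodes <- sort(union(p, m), method = "radix")
  origin <- ifelse(nodes %in% p & nodes %in% m, "seed_both",
                   ifelse(nodes %in% p, "seed_proteomics", "seed_mrna"))
  tibble(node = nodes, origin = origin)
}

new_subnetwork <- function(members, edges) {
  deg <- setNames(integer(nrow(members)), members$node)
  if (nrow(edges) > 0) {
    tab <- table(c(edges$from, edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  members$degree <- as.integer(deg[members$node])
  comp <- rep(NA_integer_, nrow(members))
  if (nrow(members) > 0) {
    g <- igraph::graph_from_data_frame(
      as.data.frame(edges[, c("from", "to")]),
      directed = FALSE, vertices = members$node
    )
    cl <- igraph::components(g)
    # components numbered largest first, ties by smallest member symbol
    sizes <- cl$csize
    first_member <- vapply(seq_along(sizes), function(i) {
      sort(members$node[cl$membership[members$node] == i], method = "radix")[1]
    }, "")
    rank <- order_c(-sizes, first_member)
    comp <- match(cl$membership[members$node], rank)
  }
  members$component <- comp
  members <- members[order_c(members$node), ]
  structure(list(members = members, edges = edges),
            class = "subnetwork")
}

#' Extract the direct-interaction subnetwork of a seed set
#'
#' Induces the subgraph of the interaction network on the seed nodes: only
#' seeds and the known edges among them, with no intermediate connector
#' nodes. Members with no edge to any other seed are dropped when
#' `drop_isolated = TRUE` (the default). Connected components are numbered
#' largest first.
#'
#' @param seeds character vector of seed symbols, or a tibble with `node`
#'   (and optionally `origin`) columns as from [merge_seed_sets()].
#' @param net an [interaction_tbl()].
#' @param drop_isolated drop degree-0 members (default `TRUE`).
#' @return object of class `subnetwork`: list with `members` (tibble: `node`,
#'   `origin`, `degree`, `component`, `flag`) and `edges` (tibble: `from`,
#'   `to`, `relation`).
#' @export
direct_subnetwork <- function(seeds, net, drop_isolated = TRUE) {
  if (nrow(net) == 0) abort("interaction network is empty")
  if (!is.data.frame(seeds)) seeds <- tibble(node = unique(trimws(seeds)),
                                             origin = "seed")
  present <- seeds[seeds$node %in% net_nodes(net), , drop = FALSE]
  if (nrow(present) == 0) {
    warn("no seed node is present in the interaction network")
  }
  edges <- net[net$from %in% present$node & net$to %in% present$node, ,
               drop = FALSE]
  if (drop_isolated) {
    connected <- unique(c(edges$from, edges$to))
    present <- present[present$node %in% connected, , drop = FALSE]
  }
  present$flag <- ""
  new_subnetwork(as_tibble(present), as_tibble(edges))
}

#' Drop subnetwork members below a connection count
#'
#' Single-pass filter: members whose degree within the subnetwork is below
#' `k` are removed and the edges restricted to the survivors. Degrees are NOT
#' re-evaluated after removal (no iterative core decomposition); this is
#' documented behavior, and it makes the filter monotone in `k`.
#'
#' @param sub a `subnetwork` from [direct_subnetwork()].
#' @param k minimum within-subnetwork degree (default 3).
#' @return a filtered `subnetwork`.
#' @export
filter_min_connections <- function(sub, k = 3) {
  keep <- sub$members$node[sub$members$degree >= k]
  members <- sub$members[sub$members$node %in% keep,
                         setdiff(names(sub$members), c("degree", "component")),
                         drop = FALSE]
  edges <- sub$edges[sub$edges$from %in% keep & sub$edges$to %in% keep, ,
                     drop = FALSE]
  new_subnetwork(members, edges)
}

#' Add extra nodes to a subnetwork with their known interactions
#'
#' Adds each extra symbol with origin `"added"`, together with every network
#' edge joining it to a current member or to another extra. Extras with no
#' such edge — including symbols absent from the network altogether — are
#' retained but flagged.
#'
#' @param sub a `subnetwork`.
#' @param extras nonempty character vector of symbols to add.
#' @param net the full [interaction_tbl()] supplying the edges.
#' @return an augmented `subnetwork`.
#' @export
augment_with_nodes <- function(sub, extras, net) {
  extras <- unique(trimws(extras))
  if (length(extras) == 0) return(sub)
  extras <- setdiff(extras, sub$members$node)
  all_nodes <- c(sub$members$node, extras)
  new_edges <- net[(net$from %in% extras & net$to %in% all_nodes) |
                     (net$to %in% extras & net$from %in% all_nodes), ,
                   drop = FALSE]
  edges <- dplyr::bind_rows(sub$edges, as_tibble(new_edges))
  edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
  known <- net_nodes(net)
  unknown <- setdiff(extras, known)
  if (length(unknown) > 0) {
    warn(sprintf("added node(s) with no interactions known: %s",
                 paste(unknown, collapse = ", ")))
  }
  touched <- unique(c(edges$from, edges$to))
  add <- tibble(
    node = extras,
    origin = "added",
    flag = ifelse(extras %in% unknown, "no interactions known",
                  ifelse(extras %in% touched, "", "no edges to members"))
  )
  members <- dplyr::bind_rows(
    sub$members[, c("node", "origin", "flag")],
    add
  )
  new_subnetwork(members, edges)
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("subnetwork: %d members, %d edges, %d component(s)\n",
              nrow(x$members), nrow(x$edges),
              length(unique(stats::na.omit(x$members$component)))))
  print(x$members, ...)
  invisible(x)
}
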