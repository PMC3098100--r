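new_unified_network <- function(nodes, edges, seeds, partition_hash) {
  structure(list(nodes = nodes, edges = edges,
                 seeds = sort(unique(as.integer(seeds))),
                 partition_hash = partition_hash),
            class = "unified_network")
}

empty_edges <- function() {
  tibble(ue_a = integer(), ue_b = integer(), relation_type = character(),
         inferred = logical(), provenance = list(), evidence = list(),
         tags = list())
}

partition_fingerprint <- function(ue) {
  m <- arrange(ue$membership, .data$ue_id, .data$entity_id, .data$promiscuous)
  hash(list(m$ue_id, m$entity_id, m$promiscuous))
}

#' Restrict which relations enter a network
#'
#' Restrictions are pure predicates over a relation's type and attributes:
#' `relation_types` whitelists types; `require` demands, for each named
#' attribute, at least one value among those allowed; `forbid` rejects
#' relations holding any listed value.  Values are compared after the
#' catalog's normalization.
#'
#' @param relation_types Allowed relation types (`NULL` = all).
#' @param require Named list: attribute name -> allowed values.
#' @param forbid Named list: attribute name -> rejected values.
#' @return An object of class `edge_restriction`.
#' @export
edge_restriction <- function(relation_types = NULL, require = list(),
                             forbid = list()) {
  structure(list(relation_types = relation_types, require = require,
                 forbid = forbid),
            class = "edge_restriction")
}

relation_passes <- function(reg, rel, restriction) {
  if (is.null(restriction)) return(TRUE)
  if (!is.null(restriction$relation_types) &&
      !rel$relation_type %in% restriction$relation_types) {
    return(FALSE)
  }
  norm_of <- function(name, values) {
    kind <- attribute_kind(reg, name)
    if (is.na(kind)) return(character())
    normalize_values(values, kind)
  }
  for (nm in names(restriction$require)) {
    have <- rel$attr_norm$norm[rel$attr_norm$name == nm]
    want <- norm_of(nm, restriction$require[[nm]])
    if (length(intersect(have, want)) == 0L) return(FALSE)
  }
  for (nm in names(restriction$forbid)) {
    have <- rel$attr_norm$norm[rel$attr_norm$name == nm]
    bad <- norm_of(nm, restriction$forbid[[nm]])
    if (length(intersect(have, bad)) > 0L) return(FALSE)
  }
  TRUE
}

#' Select seed user entities by attribute queries
#'
#' Returns every user entity owning at least one member (promiscuous
#' attachments included) that matches at least one of the queries.
#'
#' @param ue A [unify()] result.
#' @param queries A tibble/data frame with columns `name` and `value`, or a
#'   named list mapping attribute names to value vectors.
#' @return Sorted integer vector of `ue_id`s.
#' @export
select_seeds <- function(ue, queries) {
  stopifnot(inherits(ue, "user_entities"))
  if (!is.data.frame(queries)) {
    queries <- tibble(name = rep(names(queries), lengths(queries)),
                      value = unlist(queries, use.names = FALSE))
  }
  reg <- ue$registry
  hits <- unlist(map(seq_len(nrow(queries)), function(i) {
    query_by_attribute(reg, queries$name[i], queries$value[i])
  }))
  m <- ue$membership
  sort(unique(m$ue_id[m$entity_id %in% hits]))
}

# All user-entity-level edges induced by the registry's relations that pass
# the restriction.  n-ary relations lift to the clique of their
# participants' user entities; promiscuous sharing can make one participant
# stand for several user entities.  Returns tibble(ue_a <= ue_b,
# relation_type, relation_id).
lifted_edges <- function(ue, restriction = NULL) {
  reg <- ue$registry
  e2ue <- entity_ue_map(ue)
  ent <- entities(reg)
  rel_ids <- ent$entity_id[ent$entity_type == "relation"]
  rows <- map(rel_ids, function(rid) {
    rel <- get_entity(reg, rid)
    if (!relation_passes(reg, rel, restriction)) return(NULL)
    ues <- unlist(e2ue[as.character(rel$participants)], use.names = FALSE)
    if (is.null(ues)) return(NULL)
    # self-loop only when the same ue occurs through >1 participant slot
    per_slot <- map(as.character(rel$participants), function(p) e2ue[[p]] %||% integer())
    pairs <- list()
    for (i in seq_along(per_slot)) {
      for (j in i:length(per_slot)) {
        if (i == j) next
        for (u in per_slot[[i]]) for (v in per_slot[[j]]) {
          pairs[[length(pairs) + 1L]] <- c(min(u, v), max(u, v))
        }
      }
    }
    if (length(pairs) == 0L) return(NULL)
    mat <- unique(do.call(rbind, pairs))
    tibble(ue_a = mat[, 1], ue_b = mat[, 2],
           relation_type = rel$relation_type, relation_id = rid)
  })
  out <- bind_rows(compact(rows))
  if (nrow(out) == 0L) {
    out <- tibble(ue_a = integer(), ue_b = integer(),
                  relation_type = character(), relation_id = integer())
  }
  out
}

bfs_levels <- function(node_ids, edge_a, edge_b, seeds) {
  level <- rep(NA_integer_, length(node_ids))
  names(level) <- as.character(node_ids)
  frontier <- intersect(seeds, node_ids)
  level[as.character(frontier)] <- 0L
  d <- 0L
  while (length(frontier) > 0L) {
    nxt <- unique(c(edge_b[edge_a %in% frontier], edge_a[edge_b %in% frontier]))
    nxt <- nxt[is.na(level[as.character(nxt)])]
    if (length(nxt) == 0L) break
    d <- d + 1L
    level[as.character(nxt)] <- d
    frontier <- nxt
  }
  level
}

#' Build a network around seed user entities
#'
#' Breadth-first expansion over the registry's relations (those passing the
#' restriction), lifted to user entities: seeds sit at level 0, their
#' partners at level 1, and level i+1 holds the partners of level-i nodes.
#' Nodes up to `depth` are included; all surviving edges among included
#' nodes are retained (so edges between two depth-level nodes appear, but no
#' node beyond `depth` does).  Every edge lists the source relation records
#' that contribute to it as provenance.
#'
#' @param ue A [unify()] result.
#' @param seeds Integer vector of seed `ue_id`s (see [select_seeds()]).
#' @param depth Number of expansion levels (>= 0).
#' @param restriction Optional [edge_restriction()].
#' @return An object of class `unified_network` with tibbles `nodes`
#'   (`ue_id`, `level`, `tags`) and `edges` (`ue_a`, `ue_b`,
#'   `relation_type`, `inferred`, `provenance`, `evidence`, `tags`).
#' @export
expand_network <- function(ue, seeds, depth = 1L, restriction = NULL) {
  stopifnot(inherits(ue, "user_entities"))
  if (depth < 0L) abort("depth must be >= 0")
  seeds <- sort(unique(as.integer(seeds)))
  all_ues <- sort(unique(ue$membership$ue_id))
  if (!all(seeds %in% all_ues)) {
    abort("some seeds are not user entities of this partition")
  }
  le <- lifted_edges(ue, restriction)
  simple <- le[le$ue_a != le$ue_b, , drop = FALSE]
  level <- bfs_levels(all_ues, simple$ue_a, simple$ue_b, seeds)
  keep <- all_ues[!is.na(level[as.character(all_ues)]) &
                  level[as.character(all_ues)] <= depth]
  nodes <- tibble(ue_id = keep,
                  level = unname(level[as.character(keep)]),
                  tags = rep(list(character()), length(keep)))
  le_in <- le[le$ue_a %in% keep & le$ue_b %in% keep, , drop = FALSE]
  edges <- if (nrow(le_in) == 0L) empty_edges() else {
    grp <- dplyr::group_by(le_in, .data$ue_a, .data$ue_b, .data$relation_type)
    ed <- dplyr::summarise(grp, provenance = list(sort(unique(.data$relation_id))),
                           .groups = "drop")
    ed$inferred <- FALSE
    ed$evidence <- rep(list(NULL), nrow(ed))
    ed$tags <- rep(list(character()), nrow(ed))
    ed[c("ue_a", "ue_b", "relation_type", "inferred",
         "provenance", "evidence", "tags")]
  }
  new_unified_network(nodes, edges, seeds, partition_fingerprint(ue))
}

#' @export
print.unified_network <- function(x, ...) {
  cat(sprintf(
    "<unified_network> %d node(s), %d edge(s) (%d inferred), %d seed(s)\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$inferred), length(x$seeds)
  ))
  invisible(x)
}

#' @export
tidy.unified_network <- function(x, ...) {
  e <- x$edges
  mutate(e,
         n_sources = map_int(.data$provenance, length),
         tags = map_chr(.data$tags, paste, collapse = ","))
}

#' @export
glance.unified_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_inferred = sum(x$edges$inferred),
    n_seeds = length(x$seeds),
    max_level = if (nrow(x$nodes)) max(x$nodes$level, na.rm = TRUE) else NA_integer_
  )
}

edge_key <- function(e) {
  if (nrow(e) == 0L) return(character())
  paste0(e$ue_a, "|", e$ue_b, "|", e$relation_type)
}

#' Tag nodes or edges of a network
#'
#' Tags are free-text labels attached to nodes or edges; retagging is
#' idempotent.  Unknown targets raise an error.
#'
#' @param net A `unified_network`.
#' @param tag Tag string.
#' @param nodes Integer vector of `ue_id`s to tag.
#' @param edges Two-column data frame/matrix of (`ue_a`, `ue_b`) pairs to
#'   tag (order-insensitive; all relation types between the pair are
#'   tagged).
#' @return The updated network.
#' @export
net_tag <- function(net, tag, nodes = NULL, edges = NULL) {
  stopifnot(inherits(net, "unified_network"))
  if (!is.null(nodes)) {
    miss <- setdiff(nodes, net$nodes$ue_id)
    if (length(miss) > 0L) {
      abort(sprintf("unknown node(s): %s", paste(miss, collapse = ", ")))
    }
    hit <- net$nodes$ue_id %in% nodes
    net$nodes$tags[hit] <- map(net$nodes$tags[hit],
                               function(t) sort(unique(c(t, tag))))
  }
  if (!is.null(edges)) {
    edges <- as.data.frame(edges)
    for (r in seq_len(nrow(edges))) {
      a <- min(edges[r, 1], edges[r, 2]); b <- max(edges[r, 1], edges[r, 2])
      hit <- net$edges$ue_a == a & net$edges$ue_b == b
      if (!any(hit)) abort(sprintf("unknown edge: %d-%d", a, b))
      net$edges$tags[hit] <- map(net$edges$tags[hit],
                                 function(t) sort(unique(c(t, tag))))
    }
  }
  net
}

#' Linker degree of a node
#'
#' The number of distinct neighbors of `ue_id` carrying `tag` — the count
#' used to rank candidate linkers between tagged (e.g. disease-associated)
#' node sets.
#'
#' @param net A `unified_network`.
#' @param ue_id Node id.
#' @param tag Tag to count among neighbors.
#' @return Integer.
#' @export
linker_degree <- function(net, ue_id, tag) {
  stopifnot(inherits(net, "unified_network"))
  if (!ue_id %in% net$nodes$ue_id) {
    abort(sprintf("unknown node: %s", ue_id))
  }
  e <- net$edges
  nbr <- unique(c(e$ue_b[e$ue_a == ue_id], e$ue_a[e$ue_b == ue_id]))
  nbr <- setdiff(nbr, ue_id)
  tagged <- net$nodes$ue_id[map_lgl(net$nodes$tags, function(t) tag %in% t)]
  length(intersect(nbr, tagged))
}

#' Degree-preserving randomization of a network
#'
#' Rewires the simple undirected view of the network by repeated double edge
#' swaps, preserving the degree sequence exactly and never introducing
#' multi-edges or self-loops.  The same `rng_seed` reproduces the identical
#' network.  Random edges carry no provenance; node levels are recomputed
#' from the original seeds on the rewired graph.
#'
#' @param net A `unified_network`.
#' @param rng_seed Integer seed.
#' @param n_swaps Number of attempted swaps (default 100 per edge).
#' @return A `unified_network`.
#' @export
randomize_network <- function(net, rng_seed, n_swaps = NULL) {
  stopifnot(inherits(net, "unified_network"))
  simple <- distinct(net$edges[net$edges$ue_a != net$edges$ue_b,
                               c("ue_a", "ue_b")])
  n_swaps <- n_swaps %||% (100L * max(1L, nrow(simple)))
  ids <- net$nodes$ue_id
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(simple$ue_a), to = as.character(simple$ue_b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(ids))
  )
  g2 <- withr::with_seed(rng_seed,
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = n_swaps)))
  el <- igraph::as_edgelist(g2)
  a <- as.integer(el[, 1]); b <- as.integer(el[, 2])
  edges <- tibble(ue_a = pmin(a, b), ue_b = pmax(a, b),
                  relation_type = "association", inferred = FALSE,
                  provenance = rep(list(integer()), length(a)),
                  evidence = rep(list(NULL), length(a)),
                  tags = rep(list(character()), length(a)))
  edges <- arrange(edges, .data$ue_a, .data$ue_b)
  level <- bfs_levels(ids, edges$ue_a, edges$ue_b, net$seeds)
  nodes <- tibble(ue_id = ids, level = unname(level[as.character(ids)]),
                  tags = rep(list(character()), length(ids)))
  new_unified_network(nodes, edges, net$seeds, net$partition_hash)
}

#' Combine two networks over the same partition
#'
#' Set algebra on node and edge sets (edges keyed by endpoints and relation
#' type).  Provenance, evidence and tags are unioned on shared elements; an
#' edge observed in either input stays observed.  Seeds are combined with
#' the same mode and node levels recomputed on the result.  Combining
#' networks built over different partitions is an error.
#'
#' @param a,b `unified_network`s over the same partition.
#' @param mode `"union"` or `"intersection"`.
#' @return A `unified_network`.
#' @export
combine_networks <- function(a, b, mode = c("union", "intersection")) {
  stopifnot(inherits(a, "unified_network"), inherits(b, "unified_network"))
  mode <- match.arg(mode)
  if (!identical(a$partition_hash, b$partition_hash)) {
    abort("networks were built over different partitions")
  }
  ka <- edge_key(a$edges); kb <- edge_key(b$edges)
  union_tags <- function(x, y) sort(unique(c(x, y)))
  merge_edges <- function(keys) {
    rows <- map(keys, function(k) {
      ia <- match(k, ka); ib <- match(k, kb)
      if (!is.na(ia) && !is.na(ib)) {
        ea <- a$edges[ia, ]; eb <- b$edges[ib, ]
        ea$provenance <- list(sort(unique(c(ea$provenance[[1]], eb$provenance[[1]]))))
        ev <- c(ea$evidence[[1]] %||% list(), eb$evidence[[1]] %||% list())
        ea$evidence <- list(if (length(ev) == 0L) NULL else ev)
        ea$tags <- list(union_tags(ea$tags[[1]], eb$tags[[1]]))
        ea$inferred <- ea$inferred && eb$inferred
        ea
      } else if (!is.na(ia)) a$edges[ia, ] else b$edges[match(k, kb), ]
    })
    bind_rows(rows)
  }
  if (mode == "union") {
    keys <- unique(c(ka, kb))
    node_ids <- sort(union(a$nodes$ue_id, b$nodes$ue_id))
    seeds <- union(a$seeds, b$seeds)
  } else {
    keys <- intersect(ka, kb)
    node_ids <- sort(intersect(a$nodes$ue_id, b$nodes$ue_id))
    seeds <- intersect(a$seeds, b$seeds)
  }
  edges <- if (length(keys) == 0L) empty_edges() else merge_edges(keys)
  edges <- edges[edges$ue_a %in% node_ids & edges$ue_b %in% node_ids, ]
  edges <- arrange(edges, .data$ue_a, .data$ue_b, .data$relation_type)
  tag_of <- function(net, id) {
    i <- match(id, net$nodes$ue_id)
    if (is.na(i)) character() else net$nodes$tags[[i]]
  }
  seeds <- intersect(seeds, node_ids)
  simple <- edges[edges$ue_a != edges$ue_b, ]
  level <- bfs_levels(node_ids, simple$ue_a, simple$ue_b, seeds)
  nodes <- tibble(
    ue_id = node_ids,
    level = unname(level[as.character(node_ids)]),
    tags = map(node_ids, function(i) union_tags(tag_of(a, i), tag_of(b, i)))
  )
  new_unified_network(nodes, edges, seeds, a$partition_hash)
}

#' Export a network to an igraph object
#'
#' Hands the network to the ambient graph library so shortest paths,
#' components, centralities and the rest of its toolbox apply directly;
#' levels, tags and inferred flags travel as vertex/edge attributes.
#'
#' @param net A `unified_network`.
#' @return An `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "unified_network"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(net$edges$ue_a),
               to = as.character(net$edges$ue_b),
               relation_type = net$edges$relation_type,
               inferred = net$edges$inferred),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes$ue_id),
                          level = net$nodes$level)
  )
  g
}
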