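`%||%` <- rlang::`%||%`

# Independent oracles used across the suite.  These deliberately avoid the
# package's index/union-find code paths: pairs by O(n^2) scan, components
# via igraph, BFS via igraph::distances, alignment scores via Biostrings.

# Brute-force equivalent-pair enumeration: for every unordered pair of
# non-relation entities and every atom, check db coverage and per-attribute
# shared normalized values by direct set intersection.
oracle_pairs <- function(reg, prot) {
  ent <- entities(reg, include_relations = FALSE)
  norm_values <- function(eid, nm) {
    e <- get_entity(reg, eid)
    e$attr_norm$norm[e$attr_norm$name == nm]
  }
  res <- list()
  ids <- ent$entity_id
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        a <- ids[i]; b <- ids[j]
        da <- ent$db_id[i]; db <- ent$db_id[j]
        for (at in prot$atoms) {
          dbs <- vapply(at$dbs, function(d) {
            if (is.character(d)) db_id_by_name(reg, d) else as.integer(d)
          }, integer(1))
          covered <- (da == dbs[1] && db == dbs[2]) ||
            (da == dbs[2] && db == dbs[1])
          if (!covered) next
          all_shared <- all(vapply(at$attributes, function(nm) {
            length(intersect(norm_values(a, nm), norm_values(b, nm))) > 0L
          }, logical(1)))
          if (all_shared) {
            res[[length(res) + 1L]] <- c(a, b)
            break
          }
        }
      }
    }
  }
  if (length(res) == 0L) {
    return(tibble::tibble(entity_a = integer(), entity_b = integer()))
  }
  m <- do.call(rbind, res)
  tibble::tibble(entity_a = m[, 1], entity_b = m[, 2])
}

# Transitive-closure partition oracle: connected components (igraph) of the
# pairs whose endpoints are both non-promiscuous, then promiscuous
# attachment through mixed pairs.  Returns the same membership shape as
# unify()$membership, with ue ids relabeled by smallest member.
oracle_partition <- function(reg, prot, pairs = NULL) {
  if (is.null(pairs)) pairs <- equivalence_pairs(reg, prot)$pairs
  ent <- entities(reg, include_relations = FALSE)
  dbs <- databases(reg)
  prom_db <- dbs$promiscuous | dbs$name %in% prot$promiscuous
  prom <- prom_db[ent$db_id]
  names(prom) <- as.character(ent$entity_id)
  core <- ent$entity_id[!prom]
  pa <- prom[as.character(pairs$entity_a)]
  pb <- prom[as.character(pairs$entity_b)]
  np <- pairs[!pa & !pb, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(np$entity_a), to = as.character(np$entity_b)),
    directed = FALSE, vertices = data.frame(name = as.character(core))
  )
  comp <- igraph::components(g)$membership
  groups <- split(as.integer(names(comp)), comp)
  groups <- groups[order(vapply(groups, min, integer(1)))]
  member_rows <- purrr::imap(groups, function(ids, k) {
    tibble::tibble(ue_id = as.integer(k), entity_id = sort(ids))
  })
  membership <- dplyr::bind_rows(member_rows)
  membership$ue_id <- as.integer(factor(membership$ue_id,
                                        levels = unique(membership$ue_id)))
  mixed <- pairs[xor(pa, pb), , drop = FALSE]
  if (nrow(mixed) > 0L) {
    pe <- ifelse(prom[as.character(mixed$entity_a)], mixed$entity_a, mixed$entity_b)
    ce <- ifelse(prom[as.character(mixed$entity_a)], mixed$entity_b, mixed$entity_a)
    att <- dplyr::distinct(tibble::tibble(
      ue_id = membership$ue_id[match(ce, membership$entity_id)],
      entity_id = as.integer(pe)
    ))
    att$promiscuous <- TRUE
    membership$promiscuous <- FALSE
    membership <- dplyr::bind_rows(membership, att)
  } else {
    membership$promiscuous <- FALSE
  }
  membership
}

# Canonical form of a partition for equality up to ue_id relabeling:
# a sorted list of sorted non-promiscuous member vectors, plus the set of
# (promiscuous entity, member-set signature) attachments.
canonical_partition <- function(membership) {
  core <- membership[!membership$promiscuous, ]
  groups <- split(core$entity_id, core$ue_id)
  groups <- lapply(groups, sort)
  sig <- vapply(groups, paste, character(1), collapse = ",")
  ord <- order(sig)
  prom <- membership[membership$promiscuous, ]
  prom_sig <- sort(paste0(prom$entity_id, "@",
                          sig[match(prom$ue_id, names(groups))]))
  list(classes = unname(sig[ord]), attachments = prom_sig)
}

# BFS distances from a seed set via igraph (independent of bfs_levels()).
oracle_bfs_levels <- function(node_ids, edges, seeds) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$ue_a), to = as.character(edges$ue_b)),
    directed = FALSE, vertices = data.frame(name = as.character(node_ids))
  )
  if (length(seeds) == 0L) {
    return(stats::setNames(rep(NA_integer_, length(node_ids)),
                           as.character(node_ids)))
  }
  d <- igraph::distances(g, v = as.character(seeds))
  lv <- apply(d, 2, min)
  lv[!is.finite(lv)] <- NA
  stats::setNames(as.integer(lv), colnames(d))
}

# Brute-force (x, z, y) triple enumeration for edge transfer.
oracle_transfer <- function(net, ue, criterion) {
  obs <- net$edges[!net$edges$inferred, , drop = FALSE]
  partner_sets <- function(u) {
    suppressWarnings(find_partners(ue, u, criterion, quiet = TRUE)$ue_id)
  }
  cache <- list()
  partners_of <- function(u) {
    k <- as.character(u)
    if (is.null(cache[[k]])) cache[[k]] <<- partner_sets(u)
    cache[[k]]
  }
  out <- character()
  obs_keys <- paste0(obs$ue_a, "|", obs$ue_b, "|", obs$relation_type)
  for (r in seq_len(nrow(obs))) {
    x <- obs$ue_a[r]; z <- obs$ue_b[r]; ty <- obs$relation_type[r]
    for (pair in list(c(x, z), c(z, x))) {
      for (y in partners_of(pair[2])) {
        a <- min(pair[1], y); b <- max(pair[1], y)
        k <- paste0(a, "|", b, "|", ty)
        if (!k %in% obs_keys) out <- c(out, k)
      }
    }
  }
  sort(unique(out))
}

# Edge set of a network as sorted keys (for set comparisons).
edge_keys <- function(net, inferred_only = FALSE) {
  e <- net$edges
  if (inferred_only) e <- e[e$inferred, , drop = FALSE]
  if (nrow(e) == 0L) return(character())
  sort(paste0(e$ue_a, "|", e$ue_b, "|", e$relation_type))
}

simple_edge_set <- function(net) {
  e <- dplyr::distinct(net$edges[c("ue_a", "ue_b")])
  if (nrow(e) == 0L) return(character())
  sort(paste0(e$ue_a, "|", e$ue_b))
}

# Biostrings local alignment score under the same gap convention
# (total gap penalty = gapOpening + gapExtension * length).
oracle_alignment_score <- function(a, b, scheme = "blosum62",
                                   gap_open = 10, gap_extend = 1) {
  mat <- switch(tolower(scheme),
    blosum62 = {
      e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
      e$BLOSUM62
    },
    pam250 = {
      e <- new.env(); utils::data("PAM250", package = "Biostrings", envir = e)
      e$PAM250
    }
  )
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend
  )
  s <- Biostrings::score(pa)
  max(0, s)
}

# Recompute alignment statistics from the reported aligned strings, using
# the substitution matrix directly (checks the stats are self-consistent).
recompute_stats <- function(st, len_a, len_b, scheme = "blosum62") {
  if (!nzchar(st$alignment_a)) {
    return(list(identity_pct = 0, similarity_pct = 0,
                coverage_pct_query = 0, coverage_pct_target = 0, score = 0))
  }
  e <- new.env()
  nm <- switch(tolower(scheme), blosum62 = "BLOSUM62", pam250 = "PAM250")
  utils::data(list = nm, package = "Biostrings", envir = e)
  S <- e[[nm]]
  xa <- strsplit(st$alignment_a, "")[[1]]
  xb <- strsplit(st$alignment_b, "")[[1]]
  L <- length(xa)
  aligned <- xa != "-" & xb != "-"
  sc <- 0; in_gap_a <- FALSE; in_gap_b <- FALSE
  for (k in seq_len(L)) {
    if (aligned[k]) {
      sc <- sc + S[xa[k], xb[k]]; in_gap_a <- FALSE; in_gap_b <- FALSE
    } else if (xa[k] == "-") {
      sc <- sc - (if (in_gap_a) 1 else 11); in_gap_a <- TRUE; in_gap_b <- FALSE
    } else {
      sc <- sc - (if (in_gap_b) 1 else 11); in_gap_b <- TRUE; in_gap_a <- FALSE
    }
  }
  list(
    identity_pct = 100 * sum(aligned & xa == xb) / L,
    similarity_pct = 100 * sum(vapply(which(aligned),
                                      function(k) S[xa[k], xb[k]] > 0,
                                      logical(1))) / L,
    coverage_pct_query = 100 * sum(xa != "-") / len_a,
    coverage_pct_target = 100 * sum(xb != "-") / len_b,
    score = sc
  )
}

random_aa_string <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
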