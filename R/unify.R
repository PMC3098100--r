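#' Enumerate equivalent record pairs under a protocol
#'
#' A pair of (non-relation) records is equivalent iff some atom of the
#' protocol covers their two databases (in either order) and the records
#' share at least one normalized value for every attribute named by that
#' atom.  Atoms are OR-ed: the result is the union of pairs over atoms.
#'
#' @param reg A [registry()].
#' @param prot A [protocol()].
#' @return A list with `pairs` (tibble `entity_a` < `entity_b`, distinct) and
#'   `evidence` (tibble `entity_a`, `entity_b`, `atom`, `attribute`, `value`
#'   recording, per firing atom, one shared value per attribute).
#' @export
equivalence_pairs <- function(reg, prot) {
  stopifnot(inherits(reg, "unify_registry"), inherits(prot, "unify_protocol"))
  ent <- entities(reg, include_relations = FALSE)
  attr_all <- attribute_table(reg)
  attr_all <- attr_all[attr_all$entity_id %in% ent$entity_id, ]
  ev_rows <- list()
  for (ai in seq_along(prot$atoms)) {
    a <- prot$atoms[[ai]]
    dbs <- resolve_dbs(reg, a$dbs)
    in_scope <- ent$entity_id[ent$db_id %in% dbs]
    db_of <- ent$db_id[match(in_scope, ent$entity_id)]
    names(db_of) <- as.character(in_scope)
    per_attr <- vector("list", length(a$attributes))
    names(per_attr) <- a$attributes
    ok <- TRUE
    for (nm in a$attributes) {
      tab <- attr_all[attr_all$name == nm & attr_all$entity_id %in% in_scope, ]
      if (nrow(tab) == 0L) { ok <- FALSE; break }
      shared <- character()
      groups <- split(tab$entity_id, tab$norm)
      pair_keys <- character()
      for (gv in names(groups)) {
        ids <- unique(groups[[gv]])
        if (length(ids) < 2L) next
        d <- db_of[as.character(ids)]
        ea <- ids[d == dbs[[1]]]
        eb <- ids[d == dbs[[2]]]
        if (length(ea) == 0L || length(eb) == 0L) next
        grid <- expand.grid(x = ea, y = eb, KEEP.OUT.ATTRS = FALSE)
        grid <- grid[grid$x != grid$y, , drop = FALSE]
        if (nrow(grid) == 0L) next
        lo <- pmin(grid$x, grid$y); hi <- pmax(grid$x, grid$y)
        keys <- paste0(lo, ":", hi)
        new <- !(keys %in% pair_keys) & !duplicated(keys)
        pair_keys <- c(pair_keys, keys[new])
        add <- rep(gv, sum(new)); names(add) <- keys[new]
        shared <- c(shared, add)
      }
      if (length(pair_keys) == 0L) { ok <- FALSE; break }
      per_attr[[nm]] <- shared
    }
    if (!ok) next
    keys <- Reduce(intersect, map(per_attr, names))
    if (length(keys) == 0L) next
    parts <- str_split(keys, ":", simplify = TRUE)
    for (nm in a$attributes) {
      ev_rows[[length(ev_rows) + 1L]] <- tibble(
        entity_a = as.integer(parts[, 1]),
        entity_b = as.integer(parts[, 2]),
        atom = ai, attribute = nm,
        value = unname(per_attr[[nm]][keys])
      )
    }
  }
  evidence <- bind_rows(ev_rows)
  if (nrow(evidence) == 0L) {
    evidence <- tibble(entity_a = integer(), entity_b = integer(),
                       atom = integer(), attribute = character(),
                       value = character())
  }
  pairs <- distinct(evidence[c("entity_a", "entity_b")])
  list(pairs = pairs, evidence = evidence)
}

# Union-find; ids are positions 1..n.  Roots are found by chasing parents
# (no in-place compression: unions always link root to root, so chains stay
# shallow at the sizes this package targets).
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Partition records into user entities
#'
#' Computes the equivalence classes ("user entities") of all non-relation
#' records under a protocol.  Records from promiscuous databases never drive
#' merging: classes are the connected components of the equivalence pairs
#' whose two endpoints are both non-promiscuous; each promiscuous record is
#' then attached to every class containing a non-promiscuous record it is
#' paired with (and so may belong to several classes, or to none).
#' Promiscuous-promiscuous pairs are ignored.  Every non-promiscuous record
#' lands in exactly one class; singletons are classes of size one.
#'
#' Class ids `ue_id` are dense integers ordered by each class's smallest
#' member `entity_id`, so the partition is reproducible.
#'
#' @param reg A [registry()].
#' @param prot A [protocol()].
#' @return An object of class `user_entities`: list with `membership`
#'   (tibble `ue_id`, `entity_id`, `db_id`, `promiscuous`), `evidence`
#'   (pair justifications, see [equivalence_pairs()]), `protocol`,
#'   `registry`.
#' @export
unify <- function(reg, prot) {
  stopifnot(inherits(reg, "unify_registry"), inherits(prot, "unify_protocol"))
  ent <- entities(reg, include_relations = FALSE)
  prom_db <- effective_promiscuous(reg, prot)
  ent$promiscuous <- prom_db[ent$db_id]
  eq <- equivalence_pairs(reg, prot)
  pairs <- eq$pairs
  prom_of <- ent$promiscuous
  names(prom_of) <- as.character(ent$entity_id)
  pa <- prom_of[as.character(pairs$entity_a)]
  pb <- prom_of[as.character(pairs$entity_b)]

  core <- ent[!ent$promiscuous, ]
  pos <- seq_len(nrow(core))
  names(pos) <- as.character(core$entity_id)
  parent <- uf_new(nrow(core))
  both_np <- pairs[!pa & !pb, , drop = FALSE]
  if (nrow(both_np) > 0L) {
    for (r in seq_len(nrow(both_np))) {
      i <- uf_find(parent, pos[[as.character(both_np$entity_a[r])]])
      j <- uf_find(parent, pos[[as.character(both_np$entity_b[r])]])
      if (i != j) parent[max(i, j)] <- min(i, j)
    }
  }
  root <- map_int(pos, function(i) uf_find(parent, i))
  # dense ue ids ordered by smallest member entity_id
  comp <- split(core$entity_id, root)
  mins <- map_int(comp, min)
  ord <- order(mins)
  ue_of_root <- integer(length(comp))
  ue_of_root[ord] <- seq_along(comp)
  names(ue_of_root) <- names(comp)
  members <- tibble(
    ue_id = unname(ue_of_root[as.character(root)]),
    entity_id = core$entity_id,
    db_id = core$db_id,
    promiscuous = FALSE
  )

  # attach promiscuous records through mixed pairs
  mixed <- pairs[xor(pa, pb), , drop = FALSE]
  attach <- NULL
  if (nrow(mixed) > 0L) {
    prom_ent <- ifelse(prom_of[as.character(mixed$entity_a)],
                       mixed$entity_a, mixed$entity_b)
    core_ent <- ifelse(prom_of[as.character(mixed$entity_a)],
                       mixed$entity_b, mixed$entity_a)
    ue_of_core <- members$ue_id[match(core_ent, members$entity_id)]
    attach <- distinct(tibble(
      ue_id = ue_of_core,
      entity_id = as.integer(prom_ent),
      db_id = ent$db_id[match(prom_ent, ent$entity_id)],
      promiscuous = TRUE
    ))
  }
  membership <- arrange(bind_rows(members, attach),
                        .data$ue_id, .data$promiscuous, .data$entity_id)
  structure(
    list(membership = membership, evidence = eq$evidence,
         protocol = prot, registry = reg),
    class = "user_entities"
  )
}

#' @export
print.user_entities <- function(x, ...) {
  m <- x$membership
  cat(sprintf(
    "<user_entities> %d user entit%s over %d record(s) (protocol '%s')\n",
    length(unique(m$ue_id)), if (length(unique(m$ue_id)) == 1L) "y" else "ies",
    length(unique(m$entity_id)), x$protocol$id
  ))
  invisible(x)
}

#' @export
tidy.user_entities <- function(x, ...) {
  reg <- x$registry
  dbs <- databases(reg)
  m <- x$membership
  m$database <- dbs$name[m$db_id]
  m$version <- dbs$version[m$db_id]
  m
}

#' @export
glance.user_entities <- function(x, ...) {
  m <- x$membership
  sizes <- table(m$ue_id[!m$promiscuous])
  tibble(
    n_user_entities = length(unique(m$ue_id)),
    n_records = length(unique(m$entity_id)),
    n_promiscuous_attachments = sum(m$promiscuous),
    n_singletons = sum(sizes == 1L),
    largest_class = if (length(sizes)) max(sizes) else 0L
  )
}

#' Backtrack a user entity to its source records
#'
#' Reports, for every member of the class (including attached promiscuous
#' records), the source database name and version, all original attributes,
#' and the rule firings (atom, attribute, shared value) that justify each
#' merge step inside the class.
#'
#' @param ue A [unify()] result.
#' @param ue_id Class id to report.
#' @return An object of class `ue_report`: list with `ue_id`, `members`
#'   (tibble `entity_id`, `database`, `version`, `promiscuous`,
#'   `attributes` list-column) and `justifications` (tibble `entity_a`,
#'   `entity_b`, `atom`, `attribute`, `value`).
#' @export
backtrack <- function(ue, ue_id) {
  stopifnot(inherits(ue, "user_entities"))
  m <- ue$membership[ue$membership$ue_id == ue_id, ]
  if (nrow(m) == 0L) abort(sprintf("unknown user entity id: %s", ue_id))
  reg <- ue$registry
  dbs <- databases(reg)
  members <- tibble(
    entity_id = m$entity_id,
    database = dbs$name[m$db_id],
    version = dbs$version[m$db_id],
    promiscuous = m$promiscuous,
    attributes = map(m$entity_id, function(i) get_entity(reg, i)$attributes)
  )
  ev <- ue$evidence
  just <- ev[ev$entity_a %in% m$entity_id & ev$entity_b %in% m$entity_id, ]
  structure(list(ue_id = ue_id, members = members, justifications = just),
            class = "ue_report")
}

#' @export
print.ue_report <- function(x, ...) {
  cat(sprintf("<ue_report> user entity %d: %d source record(s)\n",
              x$ue_id, nrow(x$members)))
  for (i in seq_len(nrow(x$members))) {
    r <- x$members[i, ]
    flag <- if (r$promiscuous) " [promiscuous]" else ""
    ats <- r$attributes[[1]]
    cat(sprintf("  #%d %s %s%s: %s\n", r$entity_id, r$database, r$version,
                flag,
                paste(map_chr(seq_along(ats), function(j) {
                  paste0(names(ats)[j], "=", paste(ats[[j]], collapse = "|"))
                }), collapse = "; ")))
  }
  if (nrow(x$justifications) > 0L) {
    cat("  merge justifications:\n")
    j <- x$justifications
    for (i in seq_len(nrow(j))) {
      cat(sprintf("    %d ~ %d via atom %d (%s = %s)\n", j$entity_a[i],
                  j$entity_b[i], j$atom[i], j$attribute[i], j$value[i]))
    }
  }
  invisible(x)
}

# entity_id -> integer vector of ue ids (promiscuous records map to several)
entity_ue_map <- function(ue) {
  m <- ue$membership
  split(m$ue_id, m$entity_id)
}
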