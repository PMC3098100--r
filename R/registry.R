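#' Create an empty record registry
#'
#' The registry is the in-memory store underneath everything else: it holds
#' external databases (sources), external entities (their records), external
#' entity relations (records linking two or more participant entities) and an
#' inverted index over normalized attribute values.  It has reference
#' semantics: registration functions modify it in place and return
#' identifiers, while all query functions return plain values or tibbles.
#'
#' Identifiers (`db_id`, `entity_id`) are dense integers assigned in
#' registration order, so runs over the same inputs are fully reproducible.
#'
#' @param catalog Optional attribute catalog as a tibble with columns `name`
#'   and `kind`; defaults to [default_attribute_catalog()].
#' @return An object of class `unify_registry`.
#' @seealso [register_database()], [register_entity()], [register_relation()],
#'   [query_by_attribute()], [write_registry()]
#' @export
#' @examples
#' reg <- registry()
#' db <- register_database(reg, "uniprot", "14.1")
#' register_entity(reg, db, "protein", list(UniprotAccession = "P12385"))
#' query_by_attribute(reg, "UniprotAccession", "p12385")
registry <- function(catalog = default_attribute_catalog()) {
  env <- new.env(parent = emptyenv())
  env$databases <- list()      # db_id -> list(db_id, name, version, promiscuous, sealed)
  env$db_keys   <- character() # "name\r version" -> position = db_id
  env$entities  <- list()      # entity_id -> record list
  env$index     <- new.env(parent = emptyenv()) # "name\x1fkey" -> integer ids
  env$adjacency <- new.env(parent = emptyenv()) # entity_id -> integer relation ids
  env$catalog   <- catalog
  structure(env, class = "unify_registry")
}

#' Seed attribute catalog
#'
#' Attribute names must be registered before use; this catalog seeds the
#' common ones.  `kind` drives value normalization: `identifier` values are
#' compared case-insensitively, `sequence` values are upper-cased with
#' whitespace stripped and indexed by digest, `integer` values must parse as
#' integers, `free` values are compared verbatim after trimming.
#'
#' @return A tibble with columns `name` and `kind`.
#' @export
default_attribute_catalog <- function() {
  tibble::tribble(
    ~name,               ~kind,
    "UniprotAccession",  "identifier",
    "UniprotEntry",      "identifier",
    "geneSymbol",        "identifier",
    "GeneID",            "integer",
    "taxID",             "integer",
    "ProteinSequence",   "sequence",
    "PDB",               "identifier",
    "Pfam",              "identifier",
    "GO",                "identifier",
    "name",              "identifier",
    "description",       "free",
    "function",          "free",
    "method",            "free",
    "interaction_type",  "free",
    "confidence",        "free",
    "role",              "free",
    "cardinality",       "free",
    "pubmed",            "identifier"
  )
}

#' Register a new attribute name
#'
#' The catalog is user-extensible at runtime: new identifier types or
#' descriptive types can be added before entities using them are registered.
#'
#' @param reg A [registry()].
#' @param name Attribute name.
#' @param kind One of `"identifier"`, `"integer"`, `"sequence"`, `"free"`.
#' @return `name`, invisibly.
#' @export
register_attribute <- function(reg, name, kind = "free") {
  stopifnot(inherits(reg, "unify_registry"))
  kind <- match.arg(kind, c("identifier", "integer", "sequence", "free"))
  if (name %in% reg$catalog$name) {
    abort(sprintf("attribute '%s' is already registered", name))
  }
  reg$catalog <- bind_rows(reg$catalog, tibble(name = name, kind = kind))
  invisible(name)
}

attribute_kind <- function(reg, name) {
  k <- reg$catalog$kind[match(name, reg$catalog$name)]
  k
}

# Normalize one character vector of raw values for a given attribute kind.
# Unparseable integer values come back as NA (callers decide to error/skip).
normalize_values <- function(values, kind) {
  v <- str_trim(as.character(values))
  switch(kind,
    identifier = tolower(v),
    sequence   = toupper(gsub("[[:space:]]", "", v)),
    integer    = {
      n <- suppressWarnings(as.integer(v))
      ifelse(is.na(n), NA_character_, as.character(n))
    },
    free       = v
  )
}

# Index key: sequences are keyed by digest + length so the inverted index
# stays small even for long polypeptides; everything else by normalized value.
index_key <- function(name, norm, kind) {
  if (kind == "sequence") {
    norm <- paste0(map_chr(norm, hash), ":", nchar(norm))
  }
  paste0(name, "\x1f", norm)
}

db_key <- function(name, version) paste0(name, "\r", version)

#' Register an external database
#'
#' A database is one data source (name + version).  Sources flagged
#' *promiscuous* (for example structural-domain classifications such as SCOP)
#' may share their records between several user entities during unification
#' but can never form a user entity alone.
#'
#' @param reg A [registry()].
#' @param name Source name; must be non-empty.
#' @param version Source version string.
#' @param promiscuous Logical flag; immutable once the database has entities.
#' @return The integer `db_id`.
#' @export
register_database <- function(reg, name, version = "", promiscuous = FALSE) {
  stopifnot(inherits(reg, "unify_registry"))
  if (!is.character(name) || length(name) != 1L || !nzchar(str_trim(name))) {
    abort("database name must be a non-empty string")
  }
  key <- db_key(name, version)
  if (key %in% reg$db_keys) {
    abort(sprintf("database ('%s', '%s') is already registered", name, version))
  }
  db_id <- length(reg$databases) + 1L
  reg$databases[[db_id]] <- list(
    db_id = db_id, name = name, version = version,
    promiscuous = isTRUE(promiscuous), sealed = FALSE
  )
  reg$db_keys <- c(reg$db_keys, key)
  db_id
}

check_db <- function(reg, db_id) {
  if (!is.numeric(db_id) || length(db_id) != 1L || is.na(db_id) ||
      db_id < 1L || db_id > length(reg$databases)) {
    abort(sprintf("unknown database id: %s", paste(db_id, collapse = ",")))
  }
  as.integer(db_id)
}

#' Look up a database id by name (and optionally version)
#' @param reg A [registry()].
#' @param name Database name.
#' @param version Optional version; if omitted the name must be unambiguous.
#' @return Integer `db_id`.
#' @export
db_id_by_name <- function(reg, name, version = NULL) {
  tbl <- databases(reg)
  hit <- tbl[tbl$name == name & (is.null(version) | tbl$version == (version %||% "")), ]
  if (nrow(hit) == 0L) abort(sprintf("no database named '%s'", name))
  if (nrow(hit) > 1L) abort(sprintf("database name '%s' is ambiguous; give a version", name))
  hit$db_id
}

# Validate + normalize an attribute multimap (named list of value vectors).
# Returns list(raw = named list of deduped trimmed raw values,
#              norm = tibble(name, value, norm, key)).
prepare_attributes <- function(reg, attributes, on_bad_integer = c("error", "drop")) {
  on_bad_integer <- match.arg(on_bad_integer)
  if (length(attributes) == 0L) {
    return(list(raw = list(),
                norm = tibble(name = character(), value = character(),
                              norm = character(), key = character())))
  }
  if (is.null(names(attributes)) || any(!nzchar(names(attributes)))) {
    abort("attributes must be a named list")
  }
  unknown <- setdiff(names(attributes), reg$catalog$name)
  if (length(unknown) > 0L) {
    abort(sprintf(
      "unregistered attribute name(s): %s (use register_attribute() first)",
      paste(unknown, collapse = ", ")
    ))
  }
  raw <- list()
  rows <- vector("list", length(attributes))
  for (i in seq_along(attributes)) {
    nm <- names(attributes)[[i]]
    kind <- attribute_kind(reg, nm)
    vals <- unique(str_trim(as.character(attributes[[i]])))
    vals <- vals[nzchar(vals)]
    if (length(vals) == 0L) next
    norm <- normalize_values(vals, kind)
    bad <- is.na(norm)
    if (any(bad)) {
      if (on_bad_integer == "error") {
        abort(sprintf("attribute '%s': value '%s' does not parse as %s",
                      nm, vals[bad][1], kind))
      }
      vals <- vals[!bad]; norm <- norm[!bad]
      if (length(vals) == 0L) next
    }
    # one (name, value) pair stored at most once, by normalized value
    keepers <- !duplicated(norm)
    vals <- vals[keepers]; norm <- norm[keepers]
    raw[[nm]] <- vals
    rows[[i]] <- tibble(name = nm, value = vals, norm = norm,
                        key = index_key(nm, norm, kind))
  }
  list(raw = raw, norm = bind_rows(rows))
}

index_add <- function(reg, keys, entity_id) {
  for (k in keys) {
    reg$index[[k]] <- c(reg$index[[k]], entity_id)
  }
}

#' Register an external entity
#'
#' One record from an external database: a protein, gene, compound or other
#' entry, with a multimap of attributes (each attribute may carry several
#' values; each name/value pair is stored once).
#'
#' @param reg A [registry()].
#' @param db_id Owning database id.
#' @param entity_type One of `"protein"`, `"gene"`, `"compound"`, `"other"`.
#' @param attributes Named list mapping attribute names to character vectors
#'   of values.  All names must be in the catalog.
#' @return The integer `entity_id`.
#' @export
register_entity <- function(reg, db_id, entity_type = "protein",
                            attributes = list()) {
  stopifnot(inherits(reg, "unify_registry"))
  db_id <- check_db(reg, db_id)
  entity_type <- match.arg(entity_type,
                           c("protein", "gene", "compound", "relation", "other"))
  if (entity_type == "relation") {
    abort("use register_relation() to register relations")
  }
  att <- prepare_attributes(reg, attributes)
  entity_id <- length(reg$entities) + 1L
  reg$entities[[entity_id]] <- list(
    entity_id = entity_id, db_id = db_id, entity_type = entity_type,
    attributes = att$raw, attr_norm = att$norm,
    relation_type = NA_character_, participants = NULL
  )
  reg$databases[[db_id]]$sealed <- TRUE
  index_add(reg, att$norm$key, entity_id)
  entity_id
}

#' Register an external entity relation
#'
#' Relations are themselves entities (subtype `"relation"`) linking two or
#' more participant entities, with relation-level attributes (detection
#' method, reliability, ...) and optional per-participant attributes (role,
#' cardinality, ...).  Self-relations are expressed by repeating an id.
#'
#' @param reg A [registry()].
#' @param db_id Owning database id.
#' @param relation_type One of `"interaction"`, `"reaction"`, `"complex"`,
#'   `"pathway"`, `"regulation"`, `"other"`.
#' @param participants Integer vector of participant entity ids (length >= 2);
#'   all must already exist.
#' @param attributes Relation-level attribute multimap.
#' @param participant_attributes Optional list (same length as
#'   `participants`) of per-participant attribute multimaps.
#' @return The integer `entity_id` of the relation.
#' @export
register_relation <- function(reg, db_id, relation_type, participants,
                              attributes = list(),
                              participant_attributes = NULL) {
  stopifnot(inherits(reg, "unify_registry"))
  db_id <- check_db(reg, db_id)
  relation_type <- match.arg(
    relation_type,
    c("interaction", "reaction", "complex", "pathway", "regulation", "other")
  )
  participants <- as.integer(participants)
  if (length(participants) < 2L) {
    abort("a relation needs at least 2 participants")
  }
  missing <- setdiff(participants, seq_along(reg$entities))
  if (length(missing) > 0L) {
    abort(sprintf("participant id(s) not in registry: %s",
                  paste(missing, collapse = ", ")))
  }
  if (!is.null(participant_attributes) &&
      length(participant_attributes) != length(participants)) {
    abort("participant_attributes must match participants in length")
  }
  pa <- map(seq_along(participants), function(i) {
    prepare_attributes(reg, participant_attributes[[i]] %||% list())$raw
  })
  att <- prepare_attributes(reg, attributes)
  entity_id <- length(reg$entities) + 1L
  reg$entities[[entity_id]] <- list(
    entity_id = entity_id, db_id = db_id, entity_type = "relation",
    attributes = att$raw, attr_norm = att$norm,
    relation_type = relation_type,
    participants = participants, participant_attributes = pa
  )
  reg$databases[[db_id]]$sealed <- TRUE
  index_add(reg, att$norm$key, entity_id)
  for (p in unique(participants)) {
    k <- as.character(p)
    reg$adjacency[[k]] <- c(reg$adjacency[[k]], entity_id)
  }
  entity_id
}

#' Attach further attribute values to an existing entity
#'
#' Used by importers that enrich records after creation (e.g. attaching a
#' sequence from a FASTA file).  Duplicate (name, value) pairs are ignored.
#'
#' @param reg A [registry()].
#' @param entity_id Target entity id.
#' @param attributes Named list of character vectors.
#' @return `entity_id`, invisibly.
#' @export
add_entity_attributes <- function(reg, entity_id, attributes) {
  stopifnot(inherits(reg, "unify_registry"))
  e <- get_entity(reg, entity_id)
  att <- prepare_attributes(reg, attributes)
  if (nrow(att$norm) > 0L) {
    new <- !(att$norm$key %in% e$attr_norm$key)
    att$norm <- att$norm[new, , drop = FALSE]
    for (nm in names(att$raw)) {
      keep <- att$norm$value[att$norm$name == nm]
      e$attributes[[nm]] <- c(e$attributes[[nm]] %||% character(), keep)
    }
    e$attr_norm <- bind_rows(e$attr_norm, att$norm)
    reg$entities[[entity_id]] <- e
    index_add(reg, att$norm$key, entity_id)
  }
  invisible(entity_id)
}

#' Query entities by attribute value
#'
#' Returns exactly the set of entity ids holding the given (name, value)
#' pair, compared after normalization (so identifier lookups are
#' case-insensitive).  Unknown attribute names yield an empty result with a
#' warning.
#'
#' @param reg A [registry()].
#' @param name Attribute name.
#' @param value Attribute value.
#' @param db Optional database id or name to restrict the result.
#' @return Sorted integer vector of entity ids.
#' @export
query_by_attribute <- function(reg, name, value, db = NULL) {
  stopifnot(inherits(reg, "unify_registry"))
  if (!name %in% reg$catalog$name) {
    warn(sprintf("attribute '%s' is not registered; returning no matches", name))
    return(integer())
  }
  kind <- attribute_kind(reg, name)
  norm <- normalize_values(value, kind)
  if (is.na(norm)) return(integer())
  ids <- reg$index[[index_key(name, norm, kind)]] %||% integer()
  ids <- sort(unique(ids))
  if (!is.null(db)) {
    if (is.character(db)) db <- db_id_by_name(reg, db)
    ids <- ids[map_int(ids, function(i) reg$entities[[i]]$db_id) == db]
  }
  ids
}

#' Relations a given entity participates in
#' @param reg A [registry()].
#' @param entity_id Entity id.
#' @return Sorted integer vector of relation entity ids.
#' @export
entity_relations <- function(reg, entity_id) {
  stopifnot(inherits(reg, "unify_registry"))
  entity_id <- as.integer(entity_id)
  if (entity_id < 1L || entity_id > length(reg$entities)) {
    abort(sprintf("unknown entity id: %s", entity_id))
  }
  sort(unique(reg$adjacency[[as.character(entity_id)]] %||% integer()))
}

#' Registered databases as a tibble
#' @param reg A [registry()].
#' @return Tibble with columns `db_id`, `name`, `version`, `promiscuous`.
#' @export
databases <- function(reg) {
  stopifnot(inherits(reg, "unify_registry"))
  if (length(reg$databases) == 0L) {
    return(tibble(db_id = integer(), name = character(),
                  version = character(), promiscuous = logical()))
  }
  tibble(
    db_id = map_int(reg$databases, "db_id"),
    name = map_chr(reg$databases, "name"),
    version = map_chr(reg$databases, "version"),
    promiscuous = map_lgl(reg$databases, "promiscuous")
  )
}

#' Registered entities as a tibble
#' @param reg A [registry()].
#' @param include_relations Keep relation-subtype entities? Default `TRUE`.
#' @return Tibble with `entity_id`, `db_id`, `entity_type`, `relation_type`.
#' @export
entities <- function(reg, include_relations = TRUE) {
  stopifnot(inherits(reg, "unify_registry"))
  if (length(reg$entities) == 0L) {
    return(tibble(entity_id = integer(), db_id = integer(),
                  entity_type = character(), relation_type = character()))
  }
  out <- tibble(
    entity_id = map_int(reg$entities, "entity_id"),
    db_id = map_int(reg$entities, "db_id"),
    entity_type = map_chr(reg$entities, "entity_type"),
    relation_type = map_chr(reg$entities, "relation_type")
  )
  if (!include_relations) out <- out[out$entity_type != "relation", ]
  out
}

#' All attribute values in long form
#' @param reg A [registry()].
#' @param names Optional attribute names to keep.
#' @return Tibble `entity_id`, `name`, `value`, `norm` (normalized value).
#' @export
attribute_table <- function(reg, names = NULL) {
  stopifnot(inherits(reg, "unify_registry"))
  rows <- map(reg$entities, function(e) {
    if (nrow(e$attr_norm) == 0L) return(NULL)
    tibble(entity_id = e$entity_id, name = e$attr_norm$name,
           value = e$attr_norm$value, norm = e$attr_norm$norm)
  })
  out <- bind_rows(compact(rows))
  if (nrow(out) == 0L) {
    out <- tibble(entity_id = integer(), name = character(),
                  value = character(), norm = character())
  }
  if (!is.null(names)) out <- out[out$name %in% names, ]
  out
}

#' Fetch one entity record
#' @param reg A [registry()].
#' @param entity_id Entity id.
#' @return The stored record as a list (`attributes` is a named list of
#'   character vectors; relations carry `participants`).
#' @export
get_entity <- function(reg, entity_id) {
  stopifnot(inherits(reg, "unify_registry"))
  entity_id <- as.integer(entity_id)
  if (entity_id < 1L || entity_id > length(reg$entities)) {
    abort(sprintf("unknown entity id: %s", entity_id))
  }
  reg$entities[[entity_id]]
}

#' @export
print.unify_registry <- function(x, ...) {
  ent <- entities(x)
  cat(sprintf(
    "<unify_registry> %d database(s), %d entit%s (%d relation%s)\n",
    length(x$databases), length(x$entities),
    if (length(x$entities) == 1L) "y" else "ies",
    sum(ent$entity_type == "relation"),
    if (sum(ent$entity_type == "relation") == 1L) "" else "s"
  ))
  invisible(x)
}

# ---- persistence -----------------------------------------------------------

REGISTRY_SCHEMA <- 1L

#' Save a registry to a single JSON file
#'
#' The on-disk form is schema-versioned JSON carrying raw (un-normalized)
#' values only; the inverted index and adjacency are rebuilt on load, so a
#' save/load round trip answers every query identically.
#'
#' @param reg A [registry()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(reg, path) {
  stopifnot(inherits(reg, "unify_registry"))
  payload <- list(
    schema = REGISTRY_SCHEMA,
    catalog = reg$catalog,
    databases = map(reg$databases, function(d) {
      d[c("name", "version", "promiscuous")]
    }),
    entities = map(reg$entities, function(e) {
      rec <- list(db_id = e$db_id, entity_type = e$entity_type,
                  attributes = map(e$attributes, as.list))
      if (e$entity_type == "relation") {
        rec$relation_type <- e$relation_type
        rec$participants <- e$participants
        rec$participant_attributes <- map(e$participant_attributes,
                                          function(a) map(a, as.list))
      }
      rec
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a registry written by [write_registry()]
#' @param path Path to the JSON file.
#' @return A [registry()].
#' @export
read_registry <- function(path) {
  payload <- jsonlite::read_json(path)
  if (!identical(as.integer(payload$schema), REGISTRY_SCHEMA)) {
    abort(sprintf("unsupported registry schema: %s", payload$schema))
  }
  cat_tbl <- bind_rows(map(payload$catalog, as_tibble))
  reg <- registry(catalog = cat_tbl)
  for (d in payload$databases) {
    register_database(reg, d$name, d$version, isTRUE(d$promiscuous))
  }
  for (e in payload$entities) {
    attrs <- map(e$attributes, function(v) unlist(v, use.names = FALSE))
    if (identical(e$entity_type, "relation")) {
      pa <- map(e$participant_attributes,
                function(a) map(a, function(v) unlist(v, use.names = FALSE)))
      if (length(pa) == 0L) pa <- NULL
      register_relation(reg, e$db_id, e$relation_type,
                        unlist(e$participants), attrs, pa)
    } else {
      register_entity(reg, e$db_id, e$entity_type, attrs)
    }
  }
  reg
}
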