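#' Dialect of the generic tabular record format
#'
#' Entity tables are UTF-8 TSV files with a header row, `#` comments and a
#' multi-value separator (default `|`).  One column carries the record's
#' native id (stored under `id_attribute`), an optional column carries the
#' entity type, and every other column is an attribute name from the
#' catalog.  Relation tables reuse the same dialect plus `relation_id`,
#' `relation_type` and `participants` columns (participants are
#' comma-separated native ids resolved against the same database's
#' entities).
#'
#' @param id_column Name of the native-id column.
#' @param id_attribute Attribute under which the native id is stored.
#' @param type_column Name of the entity-type column (optional in files).
#' @param sep Multi-value separator inside cells.
#' @param default_type Entity type used when the type column is absent.
#' @return A list of class `entity_dialect`.
#' @export
entity_dialect <- function(id_column = "external_id", id_attribute = "name",
                           type_column = "type", sep = "|",
                           default_type = "protein") {
  structure(list(id_column = id_column, id_attribute = id_attribute,
                 type_column = type_column, sep = sep,
                 default_type = default_type),
            class = "entity_dialect")
}

read_table_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Import an entity table
#'
#' Registers one external entity per non-comment row.  Cells may hold
#' several values joined by the dialect separator.  Rows whose integer-typed
#' attributes (taxID, GeneID, ...) fail to parse are skipped with a log
#' message; a missing id column is a hard error.
#'
#' @param path Path to the TSV file.
#' @param reg A [registry()].
#' @param db_id Target database id.
#' @param dialect An [entity_dialect()].
#' @return Integer count of entities registered (invisible attribute
#'   `skipped` carries the number of rows dropped).
#' @export
read_entity_table <- function(path, reg, db_id, dialect = entity_dialect()) {
  tab <- read_table_file(path)
  if (!dialect$id_column %in% names(tab)) {
    abort(sprintf("entity table %s lacks the id column '%s'",
                  path, dialect$id_column))
  }
  attr_cols <- setdiff(names(tab), c(dialect$id_column, dialect$type_column))
  n <- 0L; skipped <- 0L
  for (r in seq_len(nrow(tab))) {
    attrs <- list()
    attrs[[dialect$id_attribute]] <- tab[[dialect$id_column]][r]
    for (col in attr_cols) {
      cell <- tab[[col]][r]
      if (is.na(cell) || !nzchar(cell)) next
      vals <- str_split(cell, stringr::fixed(dialect$sep))[[1]]
      attrs[[col]] <- unique(c(attrs[[col]], vals))
    }
    typ <- if (dialect$type_column %in% names(tab) &&
               !is.na(tab[[dialect$type_column]][r])) {
      tab[[dialect$type_column]][r]
    } else {
      dialect$default_type
    }
    ok <- tryCatch({
      register_entity(reg, db_id, typ, attrs)
      TRUE
    }, rlang_error = function(e) {
      if (grepl("does not parse", conditionMessage(e))) {
        inform(sprintf("skipping row %d of %s: %s", r, basename(path),
                       conditionMessage(e)))
        FALSE
      } else {
        stop(e)
      }
    })
    if (ok) n <- n + 1L else skipped <- skipped + 1L
  }
  structure(n, skipped = skipped)
}

#' Import a relation table
#'
#' Each row registers one relation; participants are comma-separated native
#' ids looked up (via the dialect's `id_attribute`) among entities of the
#' same database.
#'
#' @inheritParams read_entity_table
#' @return Integer count of relations registered.
#' @export
read_relation_table <- function(path, reg, db_id, dialect = entity_dialect()) {
  tab <- read_table_file(path)
  need <- c("relation_id", "relation_type", "participants")
  if (!all(need %in% names(tab))) {
    abort(sprintf("relation table %s needs columns: %s",
                  path, paste(need, collapse = ", ")))
  }
  attr_cols <- setdiff(names(tab), need)
  n <- 0L
  for (r in seq_len(nrow(tab))) {
    part_ids <- str_trim(str_split(tab$participants[r], ",")[[1]])
    resolved <- map(part_ids, function(p) {
      query_by_attribute(reg, dialect$id_attribute, p, db = db_id)
    })
    if (any(map_int(resolved, length) == 0L)) {
      inform(sprintf("skipping relation row %d of %s: unresolved participant",
                     r, basename(path)))
      next
    }
    attrs <- list()
    attrs[[dialect$id_attribute]] <- tab$relation_id[r]
    for (col in attr_cols) {
      cell <- tab[[col]][r]
      if (is.na(cell) || !nzchar(cell)) next
      attrs[[col]] <- str_split(cell, stringr::fixed(dialect$sep))[[1]]
    }
    register_relation(reg, db_id, tab$relation_type[r],
                      map_int(resolved, 1L), attrs)
    n <- n + 1L
  }
  n
}

#' Export one database's entities to the tabular format
#'
#' Inverse of [read_entity_table()]: writes every non-relation entity of a
#' database, one row per entity, multi-values joined by the dialect
#' separator.
#'
#' @param reg A [registry()].
#' @param db_id Database id to export.
#' @param path Output path.
#' @param dialect An [entity_dialect()].
#' @return `path`, invisibly.
#' @export
write_entity_table <- function(reg, db_id, path, dialect = entity_dialect()) {
  ent <- entities(reg, include_relations = FALSE)
  ent <- ent[ent$db_id == db_id, ]
  recs <- map(ent$entity_id, function(i) get_entity(reg, i))
  attr_names <- sort(unique(unlist(map(recs, function(e) names(e$attributes)))))
  attr_names <- setdiff(attr_names, dialect$id_attribute)
  rows <- map(recs, function(e) {
    id_vals <- e$attributes[[dialect$id_attribute]] %||% as.character(e$entity_id)
    row <- c(paste(id_vals, collapse = dialect$sep), e$entity_type,
             map_chr(attr_names, function(a) {
               paste(e$attributes[[a]] %||% character(), collapse = dialect$sep)
             }))
    row
  })
  header <- c(dialect$id_column, dialect$type_column, attr_names)
  lines <- c(paste(header, collapse = "\t"),
             map_chr(rows, paste, collapse = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

# ---- PSI-MI TAB 2.5 --------------------------------------------------------

mitab_default_namespaces <- c(
  "uniprotkb" = "UniprotAccession",
  "entrez gene/locuslink" = "GeneID"
)

parse_mitab_field <- function(field) {
  # "ns:value|ns:value" -> tibble(ns, value); "-" -> empty
  field <- str_trim(field %||% "-")
  if (!nzchar(field) || field == "-") {
    return(tibble(ns = character(), value = character()))
  }
  toks <- str_split(field, stringr::fixed("|"))[[1]]
  ns <- sub(":.*$", "", toks)
  value <- sub("^[^:]*:", "", toks)
  value <- sub("\\(.*\\)$", "", value)  # strip trailing "(description)"
  value <- gsub('^"|"$', "", value)
  tibble(ns = tolower(ns), value = value)
}

#' Import a PSI-MI TAB 2.5 interaction file
#'
#' Parses the 15-column MITAB 2.5 core (extra columns are ignored).
#' Interactor ids and alt-ids (columns 1-4) become attributes through a
#' namespace map (`uniprotkb:` to UniprotAccession, `entrez
#' gene/locuslink:` to GeneID); unknown namespaces are preserved verbatim as
#' runtime-registered identifier attributes so nothing is lost before
#' unification.  Taxids (columns 10-11) become `taxID`, column 7 the
#' detection `method`, column 12 the `interaction_type` and column 15 the
#' raw `confidence`.  One binary relation is registered per data row;
#' interactor records are merged within the file by primary id.  Rows with
#' fewer than 15 columns are skipped and logged.
#'
#' @param path Path to the MITAB file.
#' @param reg A [registry()].
#' @param db_id Target database id.
#' @param namespaces Named character vector mapping (lower-case) namespaces
#'   to attribute names; extends the defaults.
#' @return Named integer vector `c(entities = ..., relations = ...)` with an
#'   attribute `skipped`.
#' @export
read_mitab <- function(path, reg, db_id, namespaces = character()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ns_map <- c(namespaces, mitab_default_namespaces)
  ns_map <- ns_map[!duplicated(names(ns_map))]
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(str_trim(lines))]
  lines <- lines[!str_starts(lines, "#")]
  seen <- new.env(parent = emptyenv())  # primary id -> entity_id
  n_ent <- 0L; n_rel <- 0L; skipped <- 0L

  field_attrs <- function(fields) {
    # id + alt-id columns for one interactor -> attribute multimap
    parsed <- bind_rows(map(fields, parse_mitab_field))
    attrs <- list()
    for (r in seq_len(nrow(parsed))) {
      at <- unname(ns_map[parsed$ns[r]])
      if (is.na(at)) at <- parsed$ns[r]
      if (!at %in% reg$catalog$name) {
        register_attribute(reg, at, "identifier")
      }
      attrs[[at]] <- unique(c(attrs[[at]], parsed$value[r]))
    }
    attrs
  }

  interactor <- function(id_field, alt_field, tax_field) {
    primary <- parse_mitab_field(id_field)
    if (nrow(primary) == 0L) return(NA_integer_)
    key <- paste0(primary$ns[1], ":", primary$value[1])
    if (!is.null(seen[[key]])) return(seen[[key]])
    attrs <- field_attrs(c(id_field, alt_field))
    tax <- parse_mitab_field(tax_field)
    tax <- tax$value[tax$ns == "taxid"]
    tax <- tax[!is.na(suppressWarnings(as.integer(tax)))]
    if (length(tax) > 0L) attrs$taxID <- tax
    id <- register_entity(reg, db_id, "protein", attrs)
    seen[[key]] <- id
    n_ent <<- n_ent + 1L
    id
  }

  for (ln in lines) {
    cols <- str_split(ln, stringr::fixed("\t"))[[1]]
    if (length(cols) < 15L) {
      inform(sprintf("skipping short MITAB row (%d columns)", length(cols)))
      skipped <- skipped + 1L
      next
    }
    a <- interactor(cols[1], cols[3], cols[10])
    b <- interactor(cols[2], cols[4], cols[11])
    if (is.na(a) || is.na(b)) {
      inform("skipping MITAB row without parseable interactor ids")
      skipped <- skipped + 1L
      next
    }
    rel_attrs <- list()
    if (cols[7] != "-") rel_attrs$method <- cols[7]
    if (cols[12] != "-") rel_attrs$interaction_type <- cols[12]
    if (cols[15] != "-") rel_attrs$confidence <- cols[15]
    register_relation(reg, db_id, "interaction", c(a, b), rel_attrs)
    n_rel <- n_rel + 1L
  }
  structure(c(entities = n_ent, relations = n_rel), skipped = skipped)
}

# ---- FASTA -----------------------------------------------------------------

#' Attach protein sequences from a FASTA file
#'
#' The header token up to the first whitespace is the record id.  If some
#' entity of the database already holds that id under `id_attribute`, the
#' sequence is attached to it as a `ProteinSequence` value; otherwise a new
#' protein entity is created carrying the id and the sequence.  Records with
#' empty sequences are skipped and logged.
#'
#' @param path Path to the FASTA file.
#' @param reg A [registry()].
#' @param db_id Target database id.
#' @param id_attribute Attribute the header id is matched against.
#' @return Integer count of records imported, with attributes `attached` and
#'   `created`.
#' @export
read_fasta_attributes <- function(path, reg, db_id, id_attribute = "name") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) return(structure(0L, attached = 0L, created = 0L))
  seqs <- Biostrings::readAAStringSet(path)
  attached <- 0L; created <- 0L
  for (i in seq_along(seqs)) {
    id <- str_split(names(seqs)[i], "\\s+")[[1]][1]
    s <- as.character(seqs[[i]])
    if (!nzchar(s)) {
      inform(sprintf("skipping FASTA record '%s': empty sequence", id))
      next
    }
    hits <- query_by_attribute(reg, id_attribute, id, db = db_id)
    if (length(hits) > 0L) {
      for (h in hits) add_entity_attributes(reg, h, list(ProteinSequence = s))
      attached <- attached + 1L
    } else {
      attrs <- list(ProteinSequence = s)
      attrs[[id_attribute]] <- id
      register_entity(reg, db_id, "protein", attrs)
      created <- created + 1L
    }
  }
  structure(attached + created, attached = attached, created = created)
}

# ---- network export --------------------------------------------------------

#' Write a network to SIF or provenance TSV
#'
#' SIF writes one `node relation_type node` line per edge (isolated nodes as
#' single-token lines); an empty network yields an empty file.  The TSV
#' format is a self-contained dump (node rows and edge rows, with levels,
#' seed flags, tags, inferred flags, provenance relation ids and transfer
#' evidence) that [read_network_tsv()] restores exactly.
#'
#' @param net A `unified_network`.
#' @param path Output path.
#' @param format `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif")) {
  stopifnot(inherits(net, "unified_network"))
  format <- match.arg(format)
  if (format == "sif") {
    e <- net$edges
    lines <- sprintf("%d %s %d", e$ue_a, e$relation_type, e$ue_b)
    isolated <- setdiff(net$nodes$ue_id, c(e$ue_a, e$ue_b))
    lines <- c(lines, as.character(isolated))
    readr::write_lines(lines, path)
    return(invisible(path))
  }
  pack_chr <- function(x) map_chr(x, function(v) paste(v, collapse = ","))
  pack_ev <- function(x) map_chr(x, function(v) {
    if (is.null(v) || length(v) == 0L) return("")
    as.character(jsonlite::toJSON(v, auto_unbox = TRUE, digits = NA))
  })
  n <- net$nodes
  node_rows <- tibble(
    record = "node", ue_a = n$ue_id, ue_b = NA_integer_,
    relation_type = "", level = n$level, seed = n$ue_id %in% net$seeds,
    inferred = NA, provenance = "", evidence = "", tags = pack_chr(n$tags)
  )
  e <- net$edges
  edge_rows <- tibble(
    record = "edge", ue_a = e$ue_a, ue_b = e$ue_b,
    relation_type = e$relation_type, level = NA_integer_, seed = NA,
    inferred = e$inferred, provenance = pack_chr(e$provenance),
    evidence = pack_ev(e$evidence), tags = pack_chr(e$tags)
  )
  out <- bind_rows(node_rows, edge_rows)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#unified_network\tpartition=%s", net$partition_hash), con)
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0L) {
    body <- do.call(paste, c(map(out, function(col) {
      x <- as.character(col); x[is.na(x)] <- ""; x
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a network written by [write_network()] in TSV format
#' @param path Path to the TSV file.
#' @return A `unified_network`.
#' @export
read_network_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readr::read_lines(path, n_max = 1L)
  phash <- if (str_starts(first, "#unified_network")) {
    sub("^.*partition=", "", first)
  } else {
    NA_character_
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  unpack_int <- function(x) map(x, function(v) {
    if (is.na(v) || !nzchar(v)) integer() else as.integer(str_split(v, ",")[[1]])
  })
  unpack_chr <- function(x) map(x, function(v) {
    if (is.na(v) || !nzchar(v)) character() else str_split(v, ",")[[1]]
  })
  unpack_ev <- function(x) map(x, function(v) {
    if (is.na(v) || !nzchar(v)) NULL else jsonlite::fromJSON(v, simplifyVector = FALSE)
  })
  nd <- tab[tab$record == "node", , drop = FALSE]
  ed <- tab[tab$record == "edge", , drop = FALSE]
  nodes <- tibble(
    ue_id = as.integer(nd$ue_a),
    level = suppressWarnings(as.integer(nd$level)),
    tags = unpack_chr(nd$tags)
  )
  edges <- tibble(
    ue_a = as.integer(ed$ue_a), ue_b = as.integer(ed$ue_b),
    relation_type = ed$relation_type,
    inferred = as.logical(ed$inferred),
    provenance = unpack_int(ed$provenance),
    evidence = unpack_ev(ed$evidence),
    tags = unpack_chr(ed$tags)
  )
  seeds <- as.integer(nd$ue_a[as.logical(nd$seed)])
  new_unified_network(nodes, edges, seeds, phash)
}
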