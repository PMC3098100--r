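#' Build one unification rule (atom)
#'
#' An atom names a pair of databases and a set of attribute names: two
#' records, one from each database, are equivalent under the atom iff they
#' share at least one value for EVERY named attribute (attributes are AND-ed
#' within an atom).  The database pair is unordered, and a pair `(A, A)`
#' compares records within one database.
#'
#' @param dbs Length-2 vector of database ids (integer) or names (character);
#'   the two may be equal.
#' @param attributes Non-empty character vector of attribute names.
#' @return An object of class `unify_atom`.
#' @export
atom <- function(dbs, attributes) {
  if (length(dbs) == 1L) dbs <- c(dbs, dbs)
  if (length(dbs) != 2L) abort("an atom crosses exactly two databases")
  if (length(attributes) == 0L) abort("an atom needs at least one attribute")
  structure(list(dbs = dbs, attributes = unique(as.character(attributes))),
            class = "unify_atom")
}

#' Build a unification protocol
#'
#' A protocol is a set of [atom()]s OR-ed together: two records are
#' equivalent if any atom makes them so.  The result of unification does not
#' depend on atom order.  `promiscuous` optionally names databases to treat
#' as promiscuous during unification, overlaying (never mutating) the flag
#' stored in the registry.
#'
#' @param atoms List of [atom()]s (possibly empty).
#' @param id Protocol identifier string.
#' @param promiscuous Character vector of database names.
#' @return An object of class `unify_protocol`.
#' @export
protocol <- function(atoms = list(), id = "protocol", promiscuous = character()) {
  if (inherits(atoms, "unify_atom")) atoms <- list(atoms)
  ok <- map_lgl(atoms, inherits, "unify_atom")
  if (!all(ok)) abort("atoms must be built with atom()")
  structure(list(id = id, atoms = atoms,
                 promiscuous = as.character(promiscuous)),
            class = "unify_protocol")
}

#' Cross every pair of databases with the same attribute set
#'
#' Convenience for rules of the form "these databases, crossed on these
#' attributes" (the shape of the recommended protocol): emits one atom per
#' unordered database pair, including each database with itself.
#'
#' @param dbs Vector of database ids or names (length >= 1).
#' @param attributes Attribute names, AND-ed within every atom.
#' @return List of [atom()]s.
#' @export
atoms_crossing <- function(dbs, attributes) {
  dbs <- unique(dbs)
  out <- list()
  for (i in seq_along(dbs)) {
    for (j in i:length(dbs)) {
      out[[length(out) + 1L]] <- atom(c(dbs[[i]], dbs[[j]]), attributes)
    }
  }
  out
}

#' @export
print.unify_protocol <- function(x, ...) {
  cat(sprintf("<unify_protocol> '%s': %d atom(s)", x$id, length(x$atoms)))
  if (length(x$promiscuous) > 0L) {
    cat(sprintf(", promiscuous: %s", paste(x$promiscuous, collapse = ", ")))
  }
  cat("\n")
  for (a in x$atoms) {
    cat(sprintf("  [%s x %s] %s\n", a$dbs[[1]], a$dbs[[2]],
                paste(a$attributes, collapse = " AND ")))
  }
  invisible(x)
}

#' Write a protocol to JSON
#'
#' Format: `{"id": ..., "promiscuous": [names], "atoms": [{"dbs": [a, b],
#' "attributes": [...]}, ...]}`.  Databases are stored as given (names
#' recommended for portability across registries).
#'
#' @param prot A [protocol()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(prot, path) {
  stopifnot(inherits(prot, "unify_protocol"))
  payload <- list(
    id = prot$id,
    promiscuous = as.list(prot$promiscuous),
    atoms = map(prot$atoms, function(a) {
      list(dbs = as.list(a$dbs), attributes = as.list(a$attributes))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a protocol written by [write_protocol()]
#' @param path Path to the JSON file.
#' @return A [protocol()].
#' @export
read_protocol <- function(path) {
  payload <- jsonlite::read_json(path)
  atoms <- map(payload$atoms, function(a) {
    atom(unlist(a$dbs), unlist(a$attributes))
  })
  protocol(atoms, id = payload$id %||% "protocol",
           promiscuous = unlist(payload$promiscuous) %||% character())
}

# Resolve an atom's databases against a registry -> integer ids.
resolve_dbs <- function(reg, dbs) {
  map_int(dbs, function(d) {
    if (is.character(d)) db_id_by_name(reg, d) else check_db(reg, d)
  })
}

# Effective promiscuity per db_id: registry flag OR protocol overlay.
effective_promiscuous <- function(reg, prot) {
  tbl <- databases(reg)
  tbl$promiscuous | tbl$name %in% prot$promiscuous
}
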