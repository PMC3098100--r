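# Substitution matrices are taken from the Biostrings data sets and cached
# per session; "identity" is a simple +1/-1 scheme over the residue alphabet.
scoring_cache <- new.env(parent = emptyenv())

scoring_matrix <- function(scheme) {
  scheme <- tolower(scheme)
  if (!is.null(scoring_cache[[scheme]])) return(scoring_cache[[scheme]])
  m <- switch(scheme,
    blosum62 = {
      e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
      e$BLOSUM62
    },
    pam250 = {
      e <- new.env(); utils::data("PAM250", package = "Biostrings", envir = e)
      e$PAM250
    },
    identity = {
      ab <- c(LETTERS, "*")
      m <- matrix(-1L, length(ab), length(ab), dimnames = list(ab, ab))
      diag(m) <- 1L
      m
    },
    abort(sprintf("unknown scoring scheme: '%s'", scheme))
  )
  scoring_cache[[scheme]] <- m
  m
}

#' Local pairwise alignment with affine gaps
#'
#' Smith-Waterman-Gotoh alignment of two amino-acid sequences under a named
#' substitution scheme (`"blosum62"`, `"pam250"` or `"identity"`) with
#' affine gap costs (a gap of length L costs `gap_open + gap_extend * L`).
#' The traceback is deterministic (diagonal preferred over gaps on ties, and
#' the first best-scoring cell in row-major order is used), so identical
#' inputs always give the identical alignment.
#'
#' Reported statistics are defined over the alignment columns:
#' `identity_pct` is the percentage of columns with identical residues,
#' `similarity_pct` the percentage of columns whose substitution score is
#' positive (gap columns count in the denominator of both), and
#' `coverage_pct_query` / `coverage_pct_target` the percentage of each
#' sequence's residues inside the aligned region.
#'
#' @param seq_a,seq_b Non-empty amino-acid sequence strings (query, target).
#' @param scheme Substitution scheme name.
#' @param gap_open,gap_extend Affine gap parameters (positive costs).
#' @return A one-row tibble: `score`, `identity_pct`, `similarity_pct`,
#'   `coverage_pct_query`, `coverage_pct_target`, `aligned_length`,
#'   `alignment_a`, `alignment_b`.
#' @export
align_pair <- function(seq_a, seq_b, scheme = "blosum62",
                       gap_open = 10, gap_extend = 1) {
  a <- toupper(gsub("[[:space:]]", "", seq_a))
  b <- toupper(gsub("[[:space:]]", "", seq_b))
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  S <- scoring_matrix(scheme)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  bad <- setdiff(c(ca, cb), rownames(S))
  if (length(bad) > 0L) {
    abort(sprintf("residue(s) not in the '%s' alphabet: %s",
                  scheme, paste(bad, collapse = ", ")))
  }
  n <- length(ca); m <- length(cb)
  go <- gap_open; ge <- gap_extend
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consumes b)
  F <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consumes a)
  sub <- S[ca, cb, drop = FALSE]
  # row-wise fill: F and the diagonal term vectorize over j, only the
  # E recurrence carries a dependency along the row
  for (i in seq_len(n)) {
    hprev <- H[i, ]; eprev <- E[i, ]; fprev <- F[i, ]
    frow <- pmax(hprev - go - ge, fprev - ge)
    dmax <- pmax(hprev, eprev, fprev)[seq_len(m)] + sub[i, ]
    hrow <- numeric(m + 1L)
    erow <- rep(NEG, m + 1L)
    e <- NEG
    for (j in seq_len(m)) {
      e <- max(hrow[j] - go - ge, e - ge)
      erow[j + 1L] <- e
      hrow[j + 1L] <- max(0, dmax[j], e, frow[j + 1L])
    }
    H[i + 1L, ] <- hrow; E[i + 1L, ] <- erow; F[i + 1L, ] <- frow
  }
  score <- max(H)
  if (score <= 0) {
    return(alignment_stats(0, "", "", nchar(a), nchar(b), S))
  }
  hit <- which(t(H) == score)[1]  # row-major first maximum
  i <- (hit - 1L) %/% (m + 1L)    # H row index - 1 (a position)
  j <- (hit - 1L) %% (m + 1L)
  al_a <- character(); al_b <- character()
  state <- "M"
  while (i > 0L || j > 0L) {
    if (state == "M") {
      if (H[i + 1L, j + 1L] <= 0) break
      diag_score <- if (i > 0L && j > 0L) {
        max(H[i, j], E[i, j], F[i, j]) + sub[i, j]
      } else {
        NEG
      }
      if (H[i + 1L, j + 1L] == diag_score) {
        al_a <- c(ca[i], al_a); al_b <- c(cb[j], al_b)
        prev <- H[i + 1L, j + 1L] - sub[i, j]
        i <- i - 1L; j <- j - 1L
        if (prev == H[i + 1L, j + 1L]) {
          state <- "M"
          if (H[i + 1L, j + 1L] <= 0) break
        } else if (prev == E[i + 1L, j + 1L]) {
          state <- "E"
        } else {
          state <- "F"
        }
      } else if (H[i + 1L, j + 1L] == E[i + 1L, j + 1L]) {
        state <- "E"
      } else {
        state <- "F"
      }
    } else if (state == "E") {
      al_a <- c("-", al_a); al_b <- c(cb[j], al_b)
      opened <- H[i + 1L, j] - go - ge
      cur <- E[i + 1L, j + 1L]
      j <- j - 1L
      state <- if (cur == opened) "M" else "E"
    } else {
      al_a <- c(ca[i], al_a); al_b <- c("-", al_b)
      opened <- H[i, j + 1L] - go - ge
      cur <- F[i + 1L, j + 1L]
      i <- i - 1L
      state <- if (cur == opened) "M" else "F"
    }
  }
  alignment_stats(score, paste(al_a, collapse = ""),
                  paste(al_b, collapse = ""), nchar(a), nchar(b), S)
}

alignment_stats <- function(score, al_a, al_b, len_a, len_b, S) {
  if (!nzchar(al_a)) {
    return(tibble(score = score, identity_pct = 0, similarity_pct = 0,
                  coverage_pct_query = 0, coverage_pct_target = 0,
                  aligned_length = 0L, alignment_a = "", alignment_b = ""))
  }
  xa <- strsplit(al_a, "")[[1]]; xb <- strsplit(al_b, "")[[1]]
  L <- length(xa)
  aligned <- xa != "-" & xb != "-"
  ident <- sum(aligned & xa == xb)
  pos <- sum(map_lgl(which(aligned), function(k) S[xa[k], xb[k]] > 0))
  tibble(
    score = score,
    identity_pct = 100 * ident / L,
    similarity_pct = 100 * pos / L,
    coverage_pct_query = 100 * sum(xa != "-") / len_a,
    coverage_pct_target = 100 * sum(xb != "-") / len_b,
    aligned_length = L,
    alignment_a = al_a,
    alignment_b = al_b
  )
}

#' Define how observed edges transfer to new partners
#'
#' In `"shared_attribute"` mode a user entity y is a partner of z when they
#' share at least one value for EVERY listed attribute (e.g. Pfam domains).
#' In `"sequence_similarity"` mode y is a partner when some member sequence
#' of y aligns to some member sequence of z with `measure` (similarity or
#' identity percentage) at or above `min_similarity` and with at least
#' `min_coverage` percent of z's sequence covered by the alignment
#' (`coverage_both = TRUE` additionally requires the same coverage of y's
#' sequence).
#'
#' @param mode `"shared_attribute"` or `"sequence_similarity"`.
#' @param attributes Attribute names (shared_attribute mode).
#' @param min_similarity,min_coverage Percent cutoffs in \[0, 100\].
#' @param scheme Substitution scheme for [align_pair()].
#' @param measure `"similarity"` or `"identity"`.
#' @param coverage_both Require coverage on both sequences?
#' @return An object of class `transfer_criterion`.
#' @export
transfer_criterion <- function(mode = c("shared_attribute", "sequence_similarity"),
                               attributes = NULL,
                               min_similarity = 90, min_coverage = 90,
                               scheme = "blosum62",
                               measure = c("similarity", "identity"),
                               coverage_both = FALSE) {
  mode <- match.arg(mode)
  measure <- match.arg(measure)
  if (mode == "shared_attribute" &&
      (is.null(attributes) || length(attributes) == 0L)) {
    abort("shared_attribute mode needs at least one attribute name")
  }
  if (min_similarity < 0 || min_similarity > 100 ||
      min_coverage < 0 || min_coverage > 100) {
    abort("cutoffs must lie in [0, 100]")
  }
  structure(list(mode = mode, attributes = attributes,
                 min_similarity = min_similarity, min_coverage = min_coverage,
                 scheme = scheme, measure = measure,
                 coverage_both = coverage_both),
            class = "transfer_criterion")
}

# Normalized values of the listed attributes per user entity (members plus
# promiscuous attachments: a user entity inherits all member attributes).
ue_attribute_values <- function(ue, names) {
  at <- attribute_table(ue$registry, names = names)
  m <- ue$membership
  joined <- dplyr::inner_join(at, m[c("entity_id", "ue_id")],
                              by = "entity_id", relationship = "many-to-many")
  split(joined[c("name", "norm")], joined$ue_id)
}

# All member sequences per user entity, computed in one pass: list keyed by
# ue_id (as character) of unique normalized sequences.
ue_sequence_sets <- function(ue) {
  at <- attribute_table(ue$registry, names = "ProteinSequence")
  m <- ue$membership
  joined <- dplyr::inner_join(at, m[c("entity_id", "ue_id")],
                              by = "entity_id", relationship = "many-to-many")
  lapply(split(joined$norm, joined$ue_id), unique)
}

ue_sequences <- function(ue, ue_id) {
  ue_sequence_sets(ue)[[as.character(ue_id)]] %||% character()
}

#' Find partner user entities under a transfer criterion
#'
#' Returns the user entities equivalent-for-transfer to `ue_id`: those
#' sharing every listed attribute, or those with a member sequence passing
#' the similarity and coverage cutoffs against a member sequence of
#' `ue_id` (the query plays the template role for coverage).  `ue_id`
#' itself is never returned.  Evidence records the shared values or the
#' alignment statistics.
#'
#' @param ue A [unify()] result.
#' @param ue_id Query user entity.
#' @param criterion A [transfer_criterion()].
#' @param candidates Optional integer vector restricting the search.
#' @param quiet Suppress the no-sequence warning (used internally).
#' @return Tibble with columns `ue_id` and `evidence` (list).
#' @export
find_partners <- function(ue, ue_id, criterion, candidates = NULL,
                          quiet = FALSE) {
  stopifnot(inherits(ue, "user_entities"),
            inherits(criterion, "transfer_criterion"))
  all_ues <- sort(unique(ue$membership$ue_id))
  if (!ue_id %in% all_ues) abort(sprintf("unknown user entity: %s", ue_id))
  pool <- setdiff(candidates %||% all_ues, ue_id)
  empty <- tibble(ue_id = integer(), evidence = list())
  if (criterion$mode == "shared_attribute") {
    vals <- ue_attribute_values(ue, criterion$attributes)
    mine <- vals[[as.character(ue_id)]]
    if (is.null(mine)) return(empty)
    rows <- map(pool, function(other) {
      theirs <- vals[[as.character(other)]]
      if (is.null(theirs)) return(NULL)
      shared <- map(criterion$attributes, function(nm) {
        intersect(mine$norm[mine$name == nm], theirs$norm[theirs$name == nm])
      })
      names(shared) <- criterion$attributes
      if (any(map_int(shared, length) == 0L)) return(NULL)
      tibble(ue_id = other, evidence = list(list(shared_values = shared)))
    })
    out <- bind_rows(compact(rows))
    return(if (nrow(out) == 0L) empty else out)
  }
  # sequence_similarity
  seq_sets <- ue_sequence_sets(ue)
  mine <- seq_sets[[as.character(ue_id)]] %||% character()
  if (length(mine) == 0L) {
    if (!quiet) {
      warn(sprintf("user entity %d has no sequences; no partners found", ue_id))
    }
    return(empty)
  }
  rows <- map(pool, function(other) {
    theirs <- seq_sets[[as.character(other)]] %||% character()
    for (sa in mine) {
      for (sb in theirs) {
        st <- align_pair(sa, sb, scheme = criterion$scheme)
        meas <- if (criterion$measure == "identity") st$identity_pct else st$similarity_pct
        pass <- meas >= criterion$min_similarity &&
          st$coverage_pct_query >= criterion$min_coverage &&
          (!criterion$coverage_both ||
             st$coverage_pct_target >= criterion$min_coverage)
        if (pass) {
          return(tibble(ue_id = other,
                        evidence = list(list(alignment = as.list(st)))))
        }
      }
    }
    NULL
  })
  out <- bind_rows(compact(rows))
  if (nrow(out) == 0L) empty else out
}

#' Predict new edges by relation transfer (generalized interologs)
#'
#' For every observed (non-inferred) edge x-z and every partner y of z under
#' the criterion, an edge x-y is added flagged `inferred`, citing the source
#' relation(s) of x-z plus the partner evidence; both endpoints serve as
#' templates (the rule is symmetric in x and z).  Observed edges are never
#' overwritten, and transfer templates are observed edges only (iterate the
#' call to chain predictions).  Partner user entities absent from the
#' network enter it as new nodes; node levels are recomputed from the seeds
#' over the augmented graph.
#'
#' @param net A `unified_network` built over `ue`.
#' @param ue The [unify()] partition the network was built over.
#' @param criterion A [transfer_criterion()].
#' @return A `unified_network` containing the observed edges unchanged plus
#'   the inferred edges.
#' @export
transfer_edges <- function(net, ue, criterion) {
  stopifnot(inherits(net, "unified_network"), inherits(ue, "user_entities"))
  if (!identical(net$partition_hash, partition_fingerprint(ue))) {
    abort("network was built over a different partition")
  }
  obs <- net$edges[!net$edges$inferred, , drop = FALSE]
  endpoints <- sort(unique(c(obs$ue_a, obs$ue_b)))
  partners <- map(endpoints, function(u) {
    find_partners(ue, u, criterion, quiet = TRUE)
  })
  names(partners) <- as.character(endpoints)

  acc <- new.env(parent = emptyenv())
  obs_keys <- edge_key(obs)
  add_candidate <- function(x, y, type, prov, tmpl, evid) {
    a <- min(x, y); b <- max(x, y)
    k <- paste0(a, "|", b, "|", type)
    if (k %in% obs_keys) return(invisible())
    rec <- acc[[k]] %||% list(ue_a = a, ue_b = b, relation_type = type,
                              provenance = integer(), evidence = list())
    rec$provenance <- sort(unique(c(rec$provenance, prov)))
    rec$evidence <- c(rec$evidence,
                      list(c(list(template = tmpl, partner = if (a == x) b else a),
                             evid)))
    acc[[k]] <- rec
    invisible()
  }
  for (r in seq_len(nrow(obs))) {
    x <- obs$ue_a[r]; z <- obs$ue_b[r]
    type <- obs$relation_type[r]; prov <- obs$provenance[[r]]
    for (tmpl in unique(c(z, x))) {
      other <- if (tmpl == z) x else z
      p <- partners[[as.character(tmpl)]]
      for (q in seq_len(nrow(p))) {
        add_candidate(other, p$ue_id[q], type, prov, tmpl, p$evidence[[q]])
      }
    }
  }
  keys <- sort(ls(acc))
  if (length(keys) == 0L) return(net)
  inferred <- bind_rows(map(keys, function(k) {
    rec <- acc[[k]]
    tibble(ue_a = rec$ue_a, ue_b = rec$ue_b,
           relation_type = rec$relation_type, inferred = TRUE,
           provenance = list(rec$provenance),
           evidence = list(rec$evidence), tags = list(character()))
  }))
  edges <- bind_rows(net$edges, inferred)
  edges <- arrange(edges, .data$ue_a, .data$ue_b, .data$relation_type,
                   .data$inferred)
  new_ids <- setdiff(unique(c(edges$ue_a, edges$ue_b)), net$nodes$ue_id)
  nodes <- bind_rows(net$nodes,
                     tibble(ue_id = new_ids, level = NA_integer_,
                            tags = rep(list(character()), length(new_ids))))
  nodes <- arrange(nodes, .data$ue_id)
  simple <- edges[edges$ue_a != edges$ue_b, ]
  level <- bfs_levels(nodes$ue_id, simple$ue_a, simple$ue_b, net$seeds)
  nodes$level <- unname(level[as.character(nodes$ue_id)])
  new_unified_network(nodes, edges, net$seeds, net$partition_hash)
}
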