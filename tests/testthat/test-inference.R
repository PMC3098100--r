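test_that("identical sequences align at 100/100/100", {
  s <- "MKTAYIAKQRQISFVKSHFSRQ"
  st <- align_pair(s, s)
  expect_equal(st$identity_pct, 100)
  expect_equal(st$similarity_pct, 100)
  expect_equal(st$coverage_pct_query, 100)
  expect_equal(st$coverage_pct_target, 100)
  expect_identical(st$aligned_length, nchar(s))
})

test_that("dissimilar toy sequences stay below any useful coverage cutoff", {
  st <- align_pair("PPPPPPPPPP", "GGGGGGGGGG")
  expect_lt(st$coverage_pct_query, 50)
  expect_lt(st$similarity_pct * st$coverage_pct_query, 100)
  expect_error(align_pair("", "MK"), "non-empty")
  expect_error(align_pair("MK", "MK", scheme = "nope"), "unknown scoring")
})

test_that("alignment scores match the reference aligner on toy pairs", {
  set.seed(101)
  alph <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mismatch <- 0L
  for (k in 1:120) {
    a <- random_aa_string(sample(1:12, 1), alph)
    b <- random_aa_string(sample(1:12, 1), alph)
    st <- align_pair(a, b)
    want <- oracle_alignment_score(a, b)
    if (!isTRUE(all.equal(st$score, want))) mismatch <- mismatch + 1L
    # reported stats must be self-consistent with the reported alignment
    rc <- recompute_stats(st, nchar(a), nchar(b))
    expect_equal(st$identity_pct, rc$identity_pct)
    expect_equal(st$similarity_pct, rc$similarity_pct)
    expect_equal(st$coverage_pct_query, rc$coverage_pct_query)
    expect_equal(st$coverage_pct_target, rc$coverage_pct_target)
    if (st$score > 0) expect_equal(st$score, rc$score)
  }
  expect_identical(mismatch, 0L)
})

test_that("alignment is deterministic and respects scheme choice", {
  a <- "HEAGAWGHEE"; b <- "PAWHEAE"
  expect_identical(align_pair(a, b), align_pair(a, b))
  st_id <- align_pair("MKTA", "MKTA", scheme = "identity")
  expect_equal(st_id$score, 4)
  st_pam <- align_pair(a, b, scheme = "pam250")
  expect_equal(st_pam$score, oracle_alignment_score(a, b, "pam250"))
})

test_that("attribute partners require every listed attribute to overlap", {
  reg <- registry()
  db <- register_database(reg, "db", "1")
  mk <- function(acc, pfam, tax) {
    register_entity(reg, db, "protein",
                    list(UniprotAccession = acc, Pfam = pfam, taxID = tax))
  }
  mk("A1", "PF1", 9606); mk("A2", "PF1", 9606)
  mk("A3", "PF1", 10090); mk("A4", "PF2", 9606)
  ue <- unify(reg, protocol(atoms_crossing("db", "UniprotAccession"), id = "p"))
  one <- transfer_criterion("shared_attribute", attributes = "Pfam")
  both <- transfer_criterion("shared_attribute",
                             attributes = c("Pfam", "taxID"))
  p1 <- find_partners(ue, 1L, one)
  expect_setequal(p1$ue_id, c(2L, 3L))
  expect_identical(p1$evidence[[1]]$shared_values$Pfam, "pf1")
  p2 <- find_partners(ue, 1L, both)
  expect_identical(p2$ue_id, 2L)
  # A4 shares PF2 with nobody: Pfam fails even though taxID matches
  expect_identical(nrow(find_partners(ue, 4L, both)), 0L)
  expect_identical(find_partners(ue, 4L, one)$ue_id, integer())
  # brute-force all-pairs check
  ues <- sort(unique(ue$membership$ue_id))
  for (u in ues) {
    got <- sort(find_partners(ue, u, both)$ue_id)
    want <- sort(Filter(function(v) {
      sv <- function(id, nm) {
        m <- ue$membership
        ids <- m$entity_id[m$ue_id == id]
        at <- attribute_table(ue$registry, names = nm)
        at$norm[at$entity_id %in% ids]
      }
      v != u && length(intersect(sv(u, "Pfam"), sv(v, "Pfam"))) > 0 &&
        length(intersect(sv(u, "taxID"), sv(v, "taxID"))) > 0
    }, ues))
    expect_identical(got, as.integer(want))
  }
})

test_that("sequence partners obey similarity and coverage cutoffs", {
  hs <- random_homolog_set(n_proteins = 6, n_twin_pairs = 2,
                           n_mutations = 1, rng_seed = 31)
  ue <- unify(hs$registry, hs$protocol)
  crit <- transfer_criterion("sequence_similarity",
                             min_similarity = 90, min_coverage = 90)
  # twins are verbatim-but-one-residue copies: found in both directions
  for (r in seq_len(nrow(hs$twins))) {
    ua <- ue$membership$ue_id[ue$membership$entity_id == hs$twins$entity_a[r]]
    ub <- ue$membership$ue_id[ue$membership$entity_id == hs$twins$entity_b[r]]
    expect_true(ub %in% find_partners(ue, ua, crit)$ue_id)
    expect_true(ua %in% find_partners(ue, ub, crit)$ue_id)
    ev <- find_partners(ue, ua, crit)
    st <- ev$evidence[[match(ub, ev$ue_id)]]$alignment
    expect_gte(st$similarity_pct, 90)
    expect_gte(st$coverage_pct_query, 90)
  }
  # a user entity without sequences warns and returns nothing
  reg2 <- hs$registry
  extra <- register_entity(reg2, 1L, "protein",
                           list(UniprotAccession = "HOMOLOG_999"))
  ue2 <- unify(reg2, hs$protocol)
  u_extra <- ue2$membership$ue_id[ue2$membership$entity_id == extra]
  expect_warning(out <- find_partners(ue2, u_extra, crit), "no sequences")
  expect_identical(nrow(out), 0L)
})

make_transfer_world <- function(seed, n_proteins = 8, n_twin_pairs = 2,
                                density = 0.35) {
  hs <- random_homolog_set(n_proteins = n_proteins,
                           n_twin_pairs = n_twin_pairs, rng_seed = seed)
  ue <- unify(hs$registry, hs$protocol)
  random_interactome(ue, density, rng_seed = seed)
  net <- expand_network(ue, sort(unique(ue$membership$ue_id)), depth = 0)
  list(ue = ue, net = net)
}

test_that("edge transfer equals brute-force triple enumeration", {
  for (seed in c(41, 42)) {
    w <- make_transfer_world(seed)
    crit <- transfer_criterion("sequence_similarity",
                               min_similarity = 90, min_coverage = 90)
    out <- transfer_edges(w$net, w$ue, crit)
    expect_identical(edge_keys(out, inferred_only = TRUE),
                     oracle_transfer(w$net, w$ue, crit))
    # observed subgraph identical before and after
    obs <- out$edges[!out$edges$inferred, ]
    expect_identical(obs[names(w$net$edges)], w$net$edges)
    # inferred edges carry provenance and evidence
    inf <- out$edges[out$edges$inferred, ]
    if (nrow(inf) > 0) {
      expect_true(all(lengths(inf$provenance) > 0))
      expect_true(all(lengths(inf$evidence) > 0))
    }
  }
})

test_that("a criterion matching nothing leaves the network unchanged", {
  w <- make_transfer_world(43, n_twin_pairs = 0)
  crit <- transfer_criterion("shared_attribute", attributes = "Pfam")
  expect_identical(transfer_edges(w$net, w$ue, crit)$edges, w$net$edges)
  # every sequence only matches itself at 100/100 -> identity transfer
  strict <- transfer_criterion("sequence_similarity",
                               min_similarity = 100, min_coverage = 100,
                               measure = "identity")
  expect_identical(transfer_edges(w$net, w$ue, strict)$edges, w$net$edges)
})

test_that("a twin of an interactor gains the transferred edge", {
  # x-z observed; y is z's near-copy: x-y must appear flagged inferred
  reg <- registry()
  db <- register_database(reg, "db", "1")
  sq <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVG"
  sq_mut <- sub("Q$", "E", sq)
  x <- register_entity(reg, db, "protein",
                       list(UniprotAccession = "X1",
                            ProteinSequence = "GGGGGGGGGGGGGGGGGGGG"))
  z <- register_entity(reg, db, "protein",
                       list(UniprotAccession = "Z1", ProteinSequence = sq))
  y <- register_entity(reg, db, "protein",
                       list(UniprotAccession = "Y1", ProteinSequence = sq_mut))
  register_relation(reg, db, "interaction", c(x, z))
  ue <- unify(reg, protocol(atoms_crossing("db", "UniprotAccession"), id = "p"))
  net <- expand_network(ue, sort(unique(ue$membership$ue_id)), depth = 0)
  crit <- transfer_criterion("sequence_similarity",
                             min_similarity = 90, min_coverage = 90)
  out <- transfer_edges(net, ue, crit)
  inf <- out$edges[out$edges$inferred, ]
  ue_x <- ue$membership$ue_id[ue$membership$entity_id == x]
  ue_y <- ue$membership$ue_id[ue$membership$entity_id == y]
  expect_identical(nrow(inf), 1L)
  expect_setequal(c(inf$ue_a, inf$ue_b), c(ue_x, ue_y))
  # evidence cites the template relation
  expect_identical(inf$provenance[[1]], net$edges$provenance[[1]])
})

test_that("raising cutoffs never adds predicted edges", {
  w <- make_transfer_world(44, n_proteins = 8, n_twin_pairs = 3)
  grid <- c(50, 70, 90, 100)
  n_inferred <- matrix(NA_integer_, length(grid), length(grid))
  sets <- list()
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      crit <- transfer_criterion("sequence_similarity",
                                 min_similarity = grid[i],
                                 min_coverage = grid[j])
      ks <- edge_keys(transfer_edges(w$net, w$ue, crit), inferred_only = TRUE)
      sets[[paste(i, j)]] <- ks
      n_inferred[i, j] <- length(ks)
    }
  }
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      if (i < length(grid)) {
        expect_true(all(sets[[paste(i + 1, j)]] %in% sets[[paste(i, j)]]))
      }
      if (j < length(grid)) {
        expect_true(all(sets[[paste(i, j + 1)]] %in% sets[[paste(i, j)]]))
      }
    }
  }
})

test_that("transfer is symmetric in the edge's endpoints", {
  # swap participant order in the observed relation: same predictions
  build <- function(swap) {
    reg <- registry()
    db <- register_database(reg, "db", "1")
    sq <- "MDNSDRNVEIWKIKKLIKSLEAARGNGTSMISLIIPPKDQ"
    x <- register_entity(reg, db, "protein",
                         list(UniprotAccession = "X", ProteinSequence = "WWWWWWWWWWWWWWW"))
    z <- register_entity(reg, db, "protein",
                         list(UniprotAccession = "Z", ProteinSequence = sq))
    register_entity(reg, db, "protein",
                    list(UniprotAccession = "Y",
                         ProteinSequence = sub("Q$", "N", sq)))
    ps <- if (swap) c(z, x) else c(x, z)
    register_relation(reg, db, "interaction", ps)
    ue <- unify(reg, protocol(atoms_crossing("db", "UniprotAccession"), id = "p"))
    net <- expand_network(ue, sort(unique(ue$membership$ue_id)), depth = 0)
    crit <- transfer_criterion("sequence_similarity",
                               min_similarity = 90, min_coverage = 90)
    edge_keys(transfer_edges(net, ue, crit), inferred_only = TRUE)
  }
  expect_identical(build(FALSE), build(TRUE))
})
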