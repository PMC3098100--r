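# Shared small world: a planted partition plus a random interactome.
make_world <- function(seed, density = 0.25, ...) {
  rr <- random_registry(n_databases = 2, entities_per_db = 10,
                        n_classes = 4, rng_seed = seed, ...)
  ue <- unify(rr$registry, rr$protocol)
  ia <- random_interactome(ue, density, rng_seed = seed)
  list(ue = ue, ia = ia, ues = sort(unique(ue$membership$ue_id)))
}

test_that("seed selection matches a per-member linear scan", {
  fx <- make_worked_example_fixture()
  ue <- unify(fx$registry, fx$protocol)
  expect_identical(select_seeds(ue, tibble::tibble(name = "UniprotEntry",
                                                  value = "ERF1_YEAST")), 1L)
  expect_identical(select_seeds(ue, list(UniprotEntry = "ZZZZ_YEAST")),
                   integer())
  w <- make_world(3)
  at <- attribute_table(w$ue$registry)
  at <- at[at$name == "UniprotAccession", ]
  picks <- at[sample(nrow(at), 5), ]
  got <- select_seeds(w$ue, tibble::tibble(name = picks$name,
                                           value = picks$value))
  m <- w$ue$membership
  want <- sort(unique(unlist(lapply(seq_len(nrow(picks)), function(r) {
    holders <- vapply(m$entity_id, function(e) {
      rec <- get_entity(w$ue$registry, e)
      picks$norm[r] %in% rec$attr_norm$norm[rec$attr_norm$name == picks$name[r]]
    }, logical(1))
    m$ue_id[holders]
  }))))
  expect_identical(got, want)
})

test_that("expansion levels follow seed-rooted breadth-first search", {
  # hand-built path a-b-c
  reg <- registry()
  db <- register_database(reg, "db", "1")
  a <- register_entity(reg, db, "protein", list(UniprotAccession = "A"))
  b <- register_entity(reg, db, "protein", list(UniprotAccession = "B"))
  cc <- register_entity(reg, db, "protein", list(UniprotAccession = "C"))
  register_relation(reg, db, "interaction", c(a, b))
  register_relation(reg, db, "interaction", c(b, cc))
  register_relation(reg, db, "interaction", c(a, a))
  ue <- unify(reg, protocol(atoms_crossing("db", "UniprotAccession"), id = "p"))
  n0 <- expand_network(ue, 1L, depth = 0)
  expect_identical(n0$nodes$ue_id, 1L)
  expect_identical(nrow(n0$edges), 1L)           # the a-a self-relation
  expect_identical(n0$edges$ue_a, n0$edges$ue_b)
  n1 <- expand_network(ue, 1L, depth = 1)
  expect_identical(n1$nodes$ue_id, c(1L, 2L))
  expect_identical(n1$nodes$level, c(0L, 1L))
  expect_false(3L %in% n1$nodes$ue_id)           # c is level 2
  expect_error(expand_network(ue, 1L, depth = -1), "depth")
  # random worlds vs the igraph distance oracle
  for (seed in c(5, 8)) {
    w <- make_world(seed)
    seeds <- w$ues[1:2]
    for (depth in 0:3) {
      net <- expand_network(w$ue, seeds, depth = depth)
      lv <- oracle_bfs_levels(w$ues, w$ia$truth_edges, seeds)
      keep <- names(lv)[!is.na(lv) & lv <= depth]
      expect_setequal(as.character(net$nodes$ue_id), keep)
      expect_identical(unname(lv[as.character(net$nodes$ue_id)]),
                       net$nodes$level)
    }
  }
})

test_that("depth-d networks are subgraphs of depth-(d+1) networks", {
  w <- make_world(7)
  seeds <- w$ues[1]
  for (d in 0:2) {
    small <- expand_network(w$ue, seeds, depth = d)
    big <- expand_network(w$ue, seeds, depth = d + 1)
    expect_true(all(small$nodes$ue_id %in% big$nodes$ue_id))
    expect_true(all(edge_keys(small) %in% edge_keys(big)))
  }
})

test_that("tightening an edge restriction never adds nodes or edges", {
  w <- make_world(9, density = 0.35)
  seeds <- w$ues[1:2]
  loose <- expand_network(w$ue, seeds, depth = 2)
  tight <- expand_network(w$ue, seeds, depth = 2,
                          restriction = edge_restriction(
                            require = list(method = "synthetic")))
  tighter <- expand_network(w$ue, seeds, depth = 2,
                            restriction = edge_restriction(
                              require = list(method = "no-such-method")))
  expect_true(all(tight$nodes$ue_id %in% loose$nodes$ue_id))
  expect_true(all(edge_keys(tight) %in% edge_keys(loose)))
  expect_identical(nrow(tighter$edges), 0L)
  expect_setequal(tighter$nodes$ue_id, seeds)
  forbidden <- expand_network(w$ue, seeds, depth = 2,
                              restriction = edge_restriction(
                                forbid = list(method = "synthetic")))
  expect_identical(nrow(forbidden$edges), 0L)
  wrong_type <- expand_network(w$ue, seeds, depth = 2,
                               restriction = edge_restriction(
                                 relation_types = "regulation"))
  expect_identical(nrow(wrong_type$edges), 0L)
})

test_that("tagging is idempotent, validated, and round-trip stable", {
  w <- make_world(11)
  net <- expand_network(w$ue, w$ues, depth = 0)
  v <- net$nodes$ue_id[1]
  net <- net_tag(net, "disease", nodes = v)
  net <- net_tag(net, "disease", nodes = v)
  expect_identical(net$nodes$tags[[1]], "disease")
  expect_error(net_tag(net, "x", nodes = max(w$ues) + 100L), "unknown node")
  if (nrow(net$edges) > 0) {
    e1 <- net$edges[1, c("ue_a", "ue_b")]
    net <- net_tag(net, "seen", edges = e1)
    net <- net_tag(net, "seen", edges = e1)
    expect_identical(net$edges$tags[[1]], "seen")
    expect_error(net_tag(net, "x", edges = data.frame(ue_a = -1, ue_b = -2)),
                 "unknown edge")
  }
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f, "tsv")
  expect_identical(read_network_tsv(f)$nodes$tags, net$nodes$tags)
})

test_that("linker degree counts distinct tagged neighbors", {
  # star with 4 leaves, 3 tagged
  reg <- registry()
  db <- register_database(reg, "db", "1")
  hub <- register_entity(reg, db, "protein", list(UniprotAccession = "HUB"))
  leaves <- vapply(1:4, function(i) {
    register_entity(reg, db, "protein",
                    list(UniprotAccession = paste0("L", i)))
  }, integer(1))
  for (l in leaves) register_relation(reg, db, "interaction", c(hub, l))
  ue <- unify(reg, protocol(atoms_crossing("db", "UniprotAccession"), id = "p"))
  net <- expand_network(ue, 1L, depth = 1)
  expect_identical(linker_degree(net, 1L, "disease"), 0L)
  net <- net_tag(net, "disease", nodes = 2:4)
  expect_identical(linker_degree(net, 1L, "disease"), 3L)
  expect_error(linker_degree(net, 99L, "disease"), "unknown node")
  # random world: equals a brute-force neighbor scan
  w <- make_world(13, density = 0.4)
  net2 <- expand_network(w$ue, w$ues, depth = 0)
  tagged <- sample(net2$nodes$ue_id, min(4, nrow(net2$nodes)))
  net2 <- net_tag(net2, "t", nodes = tagged)
  for (v in net2$nodes$ue_id) {
    e <- net2$edges
    nbr <- setdiff(unique(c(e$ue_b[e$ue_a == v], e$ue_a[e$ue_b == v])), v)
    expect_identical(linker_degree(net2, v, "t"),
                     length(intersect(nbr, tagged)))
  }
})

test_that("randomization preserves the degree multiset deterministically", {
  # a single-edge graph cannot be rewired
  reg <- registry()
  db <- register_database(reg, "db", "1")
  a <- register_entity(reg, db, "protein", list(UniprotAccession = "A"))
  b <- register_entity(reg, db, "protein", list(UniprotAccession = "B"))
  register_relation(reg, db, "interaction", c(a, b))
  ue <- unify(reg, protocol(atoms_crossing("db", "UniprotAccession"), id = "p"))
  net1 <- expand_network(ue, 1L, depth = 1)
  r1 <- randomize_network(net1, 99)
  expect_identical(simple_edge_set(r1), simple_edge_set(net1))
  degrees <- function(net) {
    e <- dplyr::distinct(net$edges[net$edges$ue_a != net$edges$ue_b,
                                   c("ue_a", "ue_b")])
    sort(tabulate(match(c(e$ue_a, e$ue_b), net$nodes$ue_id),
                  nbins = nrow(net$nodes)))
  }
  for (seed in c(2, 6, 15)) {
    w <- make_world(seed, density = 0.35)
    net <- expand_network(w$ue, w$ues[1], depth = 3)
    ra <- randomize_network(net, 1234)
    rb <- randomize_network(net, 1234)
    expect_identical(ra$edges, rb$edges)
    expect_identical(degrees(ra), degrees(net))
    expect_false(any(ra$edges$ue_a == ra$edges$ue_b))
    expect_identical(anyDuplicated(ra$edges[c("ue_a", "ue_b")]), 0L)
    expect_true(all(lengths(ra$edges$provenance) == 0L))
  }
})

test_that("network combination is set algebra with provenance union", {
  w <- make_world(21, density = 0.4)
  na <- expand_network(w$ue, w$ues[1], depth = 2)
  nb <- expand_network(w$ue, w$ues[2], depth = 2)
  inter <- combine_networks(na, nb, "intersection")
  uni <- combine_networks(na, nb, "union")
  expect_setequal(inter$nodes$ue_id, intersect(na$nodes$ue_id, nb$nodes$ue_id))
  expect_setequal(uni$nodes$ue_id, union(na$nodes$ue_id, nb$nodes$ue_id))
  expect_setequal(edge_keys(uni), union(edge_keys(na), edge_keys(nb)))
  common <- intersect(edge_keys(na), edge_keys(nb))
  expect_true(all(edge_keys(inter) %in% common))
  # commutativity and idempotence
  expect_identical(edge_keys(combine_networks(nb, na, "union")),
                   edge_keys(uni))
  expect_identical(edge_keys(combine_networks(na, na, "intersection")),
                   edge_keys(na))
  self <- combine_networks(na, na, "intersection")
  expect_identical(self$nodes$ue_id, na$nodes$ue_id)
  expect_identical(self$nodes$level, na$nodes$level)
  empty <- expand_network(w$ue, integer(), depth = 1)
  expect_identical(nrow(combine_networks(na, empty, "intersection")$nodes), 0L)
  # different partitions refuse to combine
  other <- make_world(22)
  net_other <- expand_network(other$ue, other$ues[1], depth = 1)
  expect_error(combine_networks(na, net_other, "union"),
               "different partitions")
})

test_that("autoplot methods return ggplot objects", {
  w <- make_world(25, density = 0.4)
  expect_s3_class(ggplot2::autoplot(w$ue), "ggplot")
  net <- expand_network(w$ue, w$ues[1], depth = 2)
  expect_s3_class(ggplot2::autoplot(net), "ggplot")
})
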