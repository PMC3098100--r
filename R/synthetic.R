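# Deterministic fixture and random-instance generators.  Everything other
# modules need for testing is generated in code: multi-source registries
# with planted equivalence classes, promiscuous annotator records, MITAB
# files and random interactomes, all reproducible under a fixed seed.

# sample() that never falls into the 1:n trap for length-1 inputs
resample <- function(x, ...) x[sample.int(length(x), ...)]

random_aa <- function(n, len = 40L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  map_chr(seq_len(n), function(i) {
    paste(sample(aa, len, replace = TRUE), collapse = "")
  })
}

#' Three-database fixture with protocol-dependent merging
#'
#' Builds the canonical didactic scenario: two sources each contribute two
#' protein records (`Prot1A`, `Prot2A` from source A; `Prot1B`, `Prot2B`
#' from source B) plus a promiscuous domain-annotation source.  Attribute
#' overlaps are arranged so that three protocols give three different
#' partitions:
#'
#' * `P1` (accession only) merges `Prot1A` with `Prot1B` and nothing else;
#' * `P2` (sequence AND taxon) merges nothing — the records carry different
#'   sequences even where accessions agree;
#' * `P3` (accession OR gene symbol) chains all four proteins into one
#'   user entity.
#'
#' The domain record shares a Pfam value with `Prot1A` and `Prot2B`; the
#' `Pfam`-crossing protocol `P_domains` shows promiscuous attachment.
#'
#' @return List with `registry`, `protocols` (named list `P1`, `P2`, `P3`,
#'   `P_domains`) and `entities` (named entity ids).
#' @export
make_figure_fixture <- function() {
  reg <- registry()
  dba <- register_database(reg, "sourceA", "1.0")
  dbb <- register_database(reg, "sourceB", "1.0")
  dbc <- register_database(reg, "domainsC", "1.0", promiscuous = TRUE)
  seqs <- c(
    p1a = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
    p1b = "MSDNWQPQTEWSGEYLLKRAAGHFDDLTAMKKV",
    p2a = "MALWMRLLPLLALLALWGPDPAAAFVNQHLCGS",
    p2b = "MGSSHHHHHHSSGLVPRGSHMASMTGGQQMGRG"
  )
  e <- list()
  e$Prot1A <- register_entity(reg, dba, "protein", list(
    name = "Prot1A", UniprotAccession = "U100", geneSymbol = "GSA",
    ProteinSequence = seqs[["p1a"]], taxID = 9606, Pfam = "PF00042"
  ))
  e$Prot2A <- register_entity(reg, dba, "protein", list(
    name = "Prot2A", UniprotAccession = "U200", geneSymbol = "GSB",
    ProteinSequence = seqs[["p2a"]], taxID = 9606
  ))
  e$Prot1B <- register_entity(reg, dbb, "protein", list(
    name = "Prot1B", UniprotAccession = "U100", geneSymbol = "GSB",
    ProteinSequence = seqs[["p1b"]], taxID = 9606
  ))
  e$Prot2B <- register_entity(reg, dbb, "protein", list(
    name = "Prot2B", UniprotAccession = "U300", geneSymbol = "GSB",
    ProteinSequence = seqs[["p2b"]], taxID = 9606, Pfam = "PF00042"
  ))
  e$DomainC <- register_entity(reg, dbc, "other", list(
    name = "DomainC", Pfam = "PF00042"
  ))
  dbs <- c("sourceA", "sourceB")
  protocols <- list(
    P1 = protocol(atoms_crossing(dbs, "UniprotAccession"), id = "P1"),
    P2 = protocol(atoms_crossing(dbs, c("ProteinSequence", "taxID")), id = "P2"),
    P3 = protocol(c(atoms_crossing(dbs, "UniprotAccession"),
                    atoms_crossing(dbs, "geneSymbol")), id = "P3"),
    P_domains = protocol(c(atoms_crossing(dbs, "UniprotAccession"),
                           atoms_crossing(c(dbs, "domainsC"), "Pfam")),
                         id = "P_domains")
  )
  list(registry = reg, protocols = protocols, entities = e)
}

#' Four-source worked example of accession-based unification
#'
#' Emulates one protein reported by four repositories under four native
#' identifiers (`P12385`, `EBI-6533`, `MINT-560710`, `REACT_1034`), each
#' record annotated with the same UniProt accession, the curated entry also
#' carrying the entry name `ERF1_YEAST`, a sequence, taxon and GeneID.  The
#' returned protocol is the recommended rule set (accession OR sequence AND
#' taxon OR GeneID, over all source pairs), under which the four records
#' collapse into a single user entity.
#'
#' @param drop_accession Optional name of one source (`"swisslike"`,
#'   `"intactlike"`, `"mintlike"`, `"reactomelike"`) whose record loses its
#'   UniprotAccession annotation — with no other rule firing for it, that
#'   record stays a singleton.
#' @return List with `registry`, `protocol` and `entities` (named ids).
#' @export
make_worked_example_fixture <- function(drop_accession = NULL) {
  reg <- registry()
  dbs <- c("swisslike", "intactlike", "mintlike", "reactomelike")
  ids <- map_int(dbs, function(d) register_database(reg, d, "1.0"))
  native <- c("P12385", "EBI-6533", "MINT-560710", "REACT_1034")
  seq45 <- "MDNSDRNVEIWKIKKLIKSLEAARGNGTSMISLIIPPKDQISRVA"
  e <- list()
  for (k in seq_along(dbs)) {
    attrs <- list(name = native[[k]])
    if (!identical(drop_accession, dbs[[k]])) {
      attrs$UniprotAccession <- "P12385"
    }
    if (k == 1L) {
      attrs$UniprotEntry <- "ERF1_YEAST"
      attrs$ProteinSequence <- seq45
      attrs$taxID <- 4932
      attrs$GeneID <- 852721
    }
    e[[dbs[[k]]]] <- register_entity(reg, ids[[k]], "protein", attrs)
  }
  prot <- protocol(
    c(atoms_crossing(dbs, "UniprotAccession"),
      atoms_crossing(dbs, c("ProteinSequence", "taxID")),
      atoms_crossing(dbs, "GeneID")),
    id = "recommended"
  )
  list(registry = reg, protocol = prot, entities = e)
}

#' Random multi-source registry with a planted partition
#'
#' Generates `n_databases` sources and distributes records among planted
#' equivalence classes.  Each class is realized as a chain: consecutive
#' members share a fresh accession value, so the class is exactly the
#' transitive closure of the pairwise links under the returned protocol;
#' classes never share values, records outside classes get unique
#' accessions.  Optionally a promiscuous annotator source contributes
#' records sharing a Pfam value with members of one or two classes.
#'
#' @param n_databases Number of (non-promiscuous) sources.
#' @param entities_per_db Records per source.
#' @param n_classes Number of planted multi-record classes.
#' @param class_size_range Range of class sizes (sampled uniformly).
#' @param promiscuous Add a promiscuous annotator source?
#' @param n_promiscuous Number of annotator records (each attaches to 1-2
#'   classes).
#' @param rng_seed Integer seed; same seed, same registry.
#' @return List with `registry`, `protocol`, `truth` (tibble `entity_id`,
#'   `class_id`; singleton records carry their own class) and
#'   `promiscuous_truth` (tibble `entity_id`, `class_id` of intended
#'   attachments).
#' @export
random_registry <- function(n_databases = 3L, entities_per_db = 12L,
                            n_classes = 5L, class_size_range = c(2L, 4L),
                            promiscuous = FALSE, n_promiscuous = 3L,
                            rng_seed = 1L) {
  n_databases <- as.integer(n_databases)
  entities_per_db <- as.integer(entities_per_db)
  n_classes <- as.integer(n_classes)
  withr::with_seed(rng_seed, {
    reg <- registry()
    db_names <- sprintf("db%02d", seq_len(n_databases))
    db_ids <- map_int(db_names, function(d) register_database(reg, d, "1"))
    slots <- tibble(
      db_id = rep(db_ids, each = entities_per_db),
      slot = seq_len(n_databases * entities_per_db)
    )
    n_total <- nrow(slots)
    sizes <- if (n_classes > 0L) {
      resample(seq(class_size_range[1], class_size_range[2]),
               n_classes, replace = TRUE)
    } else {
      integer()
    }
    while (sum(sizes) > n_total) sizes <- sizes[-length(sizes)]
    assignment <- rep(NA_integer_, n_total)
    picked <- if (sum(sizes) > 0L) sample(n_total, sum(sizes)) else integer()
    assignment[picked] <- rep(seq_along(sizes), sizes)

    ids <- integer(n_total)
    acc_counter <- 0L
    chain_values <- map(seq_along(sizes), function(cl) {
      sprintf("CHAIN_%03d_%03d", cl, seq_len(max(1L, sizes[cl] - 1L)))
    })
    member_rank <- integer(length(sizes))
    for (s in seq_len(n_total)) {
      cl <- assignment[s]
      attrs <- list(name = sprintf("rec%04d", s))
      if (is.na(cl)) {
        acc_counter <- acc_counter + 1L
        attrs$UniprotAccession <- sprintf("SOLO_%04d", acc_counter)
      } else {
        member_rank[cl] <- member_rank[cl] + 1L
        r <- member_rank[cl]
        vals <- character()
        if (r > 1L) vals <- c(vals, chain_values[[cl]][r - 1L])
        if (r < sizes[cl]) vals <- c(vals, chain_values[[cl]][r])
        if (length(vals) == 0L) vals <- sprintf("CHAIN_%03d_000", cl)
        attrs$UniprotAccession <- vals
      }
      attrs$taxID <- sample(c(9606L, 10090L, 4932L), 1L)
      ids[s] <- register_entity(reg, slots$db_id[s], "protein", attrs)
    }
    truth <- tibble(entity_id = ids, class_id = assignment)
    solo <- is.na(truth$class_id)
    truth$class_id[solo] <- max(0L, n_classes) + seq_len(sum(solo))

    prom_truth <- tibble(entity_id = integer(), class_id = integer())
    prom_db_name <- character()
    realized <- which(tabulate(truth$class_id[truth$class_id <= n_classes],
                               nbins = n_classes) > 0L)
    if (promiscuous && length(realized) > 0L && n_promiscuous > 0L) {
      pdb <- register_database(reg, "annotator", "1", promiscuous = TRUE)
      prom_db_name <- "annotator"
      for (k in seq_len(n_promiscuous)) {
        n_att <- sample(1:2, 1L)
        classes <- resample(realized, min(n_att, length(realized)))
        pf <- sprintf("PF%05d", k)
        for (cl in classes) {
          member <- resample(truth$entity_id[truth$class_id == cl], 1L)
          add_entity_attributes(reg, member, stats::setNames(list(pf), "Pfam"))
        }
        pid <- register_entity(reg, pdb, "other",
                               list(name = sprintf("dom%03d", k), Pfam = pf))
        prom_truth <- bind_rows(prom_truth,
                                tibble(entity_id = pid, class_id = classes))
      }
    }
    atoms <- atoms_crossing(db_names, "UniprotAccession")
    if (length(prom_db_name) > 0L) {
      # Pfam is crossed only against the annotator source, so domain values
      # attach promiscuous records without ever merging planted classes
      atoms <- c(atoms, map(db_names, function(d) {
        atom(c(d, prom_db_name), "Pfam")
      }))
    }
    list(registry = reg,
         protocol = protocol(atoms, id = sprintf("planted_seed%d", rng_seed)),
         truth = truth, promiscuous_truth = prom_truth)
  })
}

#' Random interactome over a partition
#'
#' Samples binary interactions between user entities: each unordered pair of
#' distinct user entities becomes a relation with probability `density`
#' (`density = 1` yields all k(k-1)/2 pairs, `0` none).  Participants are
#' random non-promiscuous members of the two classes, so the generator knows
#' the exact user-entity-level edge set it planted.
#'
#' @param ue A [unify()] result; relations are registered into its registry
#'   under a fresh `"interactions"` source.
#' @param density Edge probability in \[0, 1\].
#' @param rng_seed Integer seed.
#' @return List with `relation_ids` (integer) and `truth_edges` (tibble
#'   `ue_a` < `ue_b`).
#' @export
random_interactome <- function(ue, density, rng_seed = 1L) {
  stopifnot(inherits(ue, "user_entities"))
  if (density < 0 || density > 1) abort("density must lie in [0, 1]")
  reg <- ue$registry
  m <- ue$membership[!ue$membership$promiscuous, ]
  ues <- sort(unique(m$ue_id))
  withr::with_seed(rng_seed, {
    db <- register_database(reg, "interactions",
                            sprintf("run%d", rng_seed))
    rel_ids <- integer(); ea <- integer(); eb <- integer()
    if (length(ues) >= 2L) {
      for (i in seq_len(length(ues) - 1L)) {
        for (j in seq(i + 1L, length(ues))) {
          if (stats::runif(1) >= density) next
          pa <- m$entity_id[m$ue_id == ues[i]]
          pb <- m$entity_id[m$ue_id == ues[j]]
          rid <- register_relation(
            reg, db, "interaction",
            c(if (length(pa) == 1L) pa else sample(pa, 1L),
              if (length(pb) == 1L) pb else sample(pb, 1L)),
            list(method = "synthetic")
          )
          rel_ids <- c(rel_ids, rid)
          ea <- c(ea, ues[i]); eb <- c(eb, ues[j])
        }
      }
    }
    list(relation_ids = rel_ids, truth_edges = tibble(ue_a = ea, ue_b = eb))
  })
}

#' Generate a synthetic PSI-MI TAB 2.5 file
#'
#' Writes `n_rows` binary interactions over a pool of invented UniProt-style
#' accessions, with detection-method, interaction-type and confidence
#' columns filled, and returns the ground truth the file encodes.
#'
#' @param path Output path.
#' @param n_rows Number of interaction rows.
#' @param n_proteins Size of the interactor pool.
#' @param rng_seed Integer seed.
#' @return Tibble with columns `acc_a`, `acc_b` (one row per data row).
#' @export
random_mitab <- function(path, n_rows = 50L, n_proteins = 20L, rng_seed = 1L) {
  withr::with_seed(rng_seed, {
    accs <- sprintf("Q%05d", sample(10000:99999, n_proteins))
    genes <- sprintf("GENE%03d", seq_len(n_proteins))
    meth <- c('psi-mi:"MI:0018"(two hybrid)', 'psi-mi:"MI:0006"(anti bait coip)')
    itype <- 'psi-mi:"MI:0915"(physical association)'
    rows <- character(n_rows)
    ia <- sample(n_proteins, n_rows, replace = TRUE)
    ib <- sample(n_proteins, n_rows, replace = TRUE)
    for (r in seq_len(n_rows)) {
      a <- ia[r]; b <- ib[r]
      rows[r] <- paste(
        paste0("uniprotkb:", accs[a]), paste0("uniprotkb:", accs[b]),
        paste0("entrez gene/locuslink:", 1000L + a),
        paste0("entrez gene/locuslink:", 1000L + b),
        paste0("uniprotkb:", genes[a], "(gene name)"),
        paste0("uniprotkb:", genes[b], "(gene name)"),
        sample(meth, 1L), "-", "pubmed:12345678",
        "taxid:9606(Homo sapiens)", "taxid:9606(Homo sapiens)",
        itype, "psi-mi:MI:0469(IntAct)",
        sprintf("intact:EBI-%06d", r),
        sprintf("intact-miscore:%.2f", stats::runif(1)),
        sep = "\t"
      )
    }
    header <- paste0("#", paste(
      c("ID(s) interactor A", "ID(s) interactor B",
        "Alt. ID(s) interactor A", "Alt. ID(s) interactor B",
        "Alias(es) interactor A", "Alias(es) interactor B",
        "Interaction detection method(s)", "Publication 1st author(s)",
        "Publication Identifier(s)", "Taxid interactor A",
        "Taxid interactor B", "Interaction type(s)",
        "Source database(s)", "Interaction identifier(s)",
        "Confidence value(s)"), collapse = "\t"))
    readr::write_lines(c(header, rows), path)
    tibble(acc_a = accs[ia], acc_b = accs[ib])
  })
}

#' Random protein set with sequence homology structure
#'
#' Builds a registry of single-member user entities carrying short synthetic
#' sequences, where some pairs are near-duplicates (a few point mutations of
#' a common template) and the rest are unrelated — the substrate for
#' exercising similarity-based edge transfer.
#'
#' @param n_proteins Number of proteins.
#' @param n_twin_pairs Number of near-duplicate pairs planted among them.
#' @param sequence_length Sequence length (short, keeps alignment exact and
#'   fast).
#' @param n_mutations Point mutations separating the twins.
#' @param rng_seed Integer seed.
#' @return List with `registry`, `protocol` (accession-based, yielding all
#'   singletons), `twins` (tibble `entity_a`, `entity_b`).
#' @export
random_homolog_set <- function(n_proteins = 8L, n_twin_pairs = 2L,
                               sequence_length = 40L, n_mutations = 1L,
                               rng_seed = 1L) {
  withr::with_seed(rng_seed, {
    reg <- registry()
    db <- register_database(reg, "proteins", "1")
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    seqs <- random_aa(n_proteins, len = sequence_length)
    twin_a <- integer(); twin_b <- integer()
    if (n_twin_pairs > 0L) {
      stopifnot(2L * n_twin_pairs <= n_proteins)
      for (k in seq_len(n_twin_pairs)) {
        i <- 2L * k - 1L; j <- 2L * k
        s <- strsplit(seqs[i], "")[[1]]
        at <- sample(sequence_length, n_mutations)
        s[at] <- map_chr(s[at], function(ch) sample(setdiff(aa, ch), 1L))
        seqs[j] <- paste(s, collapse = "")
        twin_a <- c(twin_a, i); twin_b <- c(twin_b, j)
      }
    }
    ids <- map_int(seq_len(n_proteins), function(i) {
      register_entity(reg, db, "protein", list(
        name = sprintf("prot%03d", i),
        UniprotAccession = sprintf("HOMOLOG_%03d", i),
        ProteinSequence = seqs[i]
      ))
    })
    list(registry = reg,
         protocol = protocol(atoms_crossing("proteins", "UniprotAccession"),
                             id = "singletons"),
         twins = tibble(entity_a = ids[twin_a], entity_b = ids[twin_b]))
  })
}

#' Export a fixture as CLI-ready files
#'
#' Writes the named fixture as one entity table per source plus the
#' protocol(s) as JSON, so the shell pipeline (`import`, `unify`, ...) can
#' be exercised on files alone.
#'
#' @param name `"figure"` or `"worked_example"`.
#' @param dir Output directory (created if needed).
#' @return Invisible list of written paths.
#' @export
export_fixture <- function(name = c("figure", "worked_example"), dir) {
  name <- match.arg(name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- switch(name,
               figure = make_figure_fixture(),
               worked_example = make_worked_example_fixture())
  reg <- fx$registry
  dbs <- databases(reg)
  paths <- list()
  for (i in seq_len(nrow(dbs))) {
    p <- file.path(dir, paste0(dbs$name[i], ".tsv"))
    write_entity_table(reg, dbs$db_id[i], p)
    paths[[dbs$name[i]]] <- p
  }
  prots <- if (name == "figure") fx$protocols else list(recommended = fx$protocol)
  prom_names <- dbs$name[dbs$promiscuous]
  for (nm in names(prots)) {
    pr <- prots[[nm]]
    pr$promiscuous <- unique(c(pr$promiscuous, prom_names))
    p <- file.path(dir, paste0("protocol_", nm, ".json"))
    write_protocol(pr, p)
    paths[[paste0("protocol_", nm)]] <- p
  }
  dbfile <- file.path(dir, "databases.tsv")
  readr::write_tsv(dbs[c("name", "version", "promiscuous")], dbfile)
  paths$databases <- dbfile
  invisible(paths)
}
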