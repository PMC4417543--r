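test_that("normalization splits equivalences into both directions", {
  ont <- ontology()
  ont <- termforge:::ont_add_property(ont, property_record("r"))
  for (id in c("T:G", "T:B")) {
    ont <- termforge:::ont_add_term(ont, term_record(id))
  }
  ont <- termforge:::ont_add_term(ont, term_record(
    "T:A", logical_def = ce_and(ce_named("T:G"),
                                ce_some("r", ce_named("T:B")))))
  ax <- normalize(ont)
  atomic <- vapply(ax$atomic_subs, paste, "", collapse = "<")
  expect_true("T:A<T:G" %in% atomic)                       # A ⊑ G
  expect_length(ax$exist_rhs, 1L)                          # A ⊑ ∃r.B
  expect_identical(ax$exist_rhs[[1L]], c("T:A", "r", "T:B"))
  expect_length(ax$exist_lhs, 1L)                          # ∃r.B ⊑ fresh
  fresh <- ax$exist_lhs[[1L]][3L]
  expect_true(fresh %in% ax$fresh_names)
  conj <- vapply(ax$conj_subs, paste, "", collapse = "|")
  expect_true(any(grepl("T:A$", conj)))                    # G ⊓ F ⊑ A
  # fresh names are a pure function of the source axiom
  expect_identical(fresh, normalize(ont)$exist_lhs[[1L]][3L])
})

test_that("told-only ontologies normalize to their is_a edge set", {
  ont <- random_ontology(10, p_def = 0, p_rel = 0, seed = 2)
  ax <- normalize(ont)
  edges <- sort(unlist(lapply(ont$terms, function(t) {
    if (!length(t$told_parents)) return(character(0))
    paste(t$id, "<", t$told_parents)
  })))
  expect_identical(sort(vapply(ax$atomic_subs, function(a) {
    paste(a[1], "<", a[2])
  }, "")), unname(edges))
  expect_length(ax$exist_rhs, 0L)
  expect_length(ax$conj_subs, 0L)
})

test_that("saturation derives chains, conjunction firing and bottom", {
  doc <- paste("format-version: 1.4",
               "", "[Term]", "id: T:C", "name: c",
               "", "[Term]", "id: T:B", "name: b", "is_a: T:C",
               "", "[Term]", "id: T:A", "name: a", "is_a: T:B",
               sep = "\n")
  cl <- saturate(normalize(parse_obo(doc)))
  expect_true(cl$S["T:A", "T:C"])                          # CR1 twice
  expect_length(cl$unsatisfiable, 0L)

  ont <- ontology()
  for (id in c("T:A", "T:B")) {
    ont <- termforge:::ont_add_term(ont, term_record(id))
  }
  ont <- termforge:::ont_add_term(ont, term_record(
    "T:X", told_parents = c("T:A", "T:B")))
  ont <- termforge:::ont_add_disjoint(ont, "T:A", "T:B")
  cl <- saturate(normalize(ont))
  expect_identical(cl$unsatisfiable, "T:X")
})

test_that("role hierarchy and transitivity propagate role links", {
  # has_input ⊑ has_participant: defining 'metabolism of X' via participant
  # must subsume 'catabolism of X' defined via input
  ont <- ontology()
  ont <- termforge:::ont_add_property(
    ont, property_record("has_participant"))
  ont <- termforge:::ont_add_property(
    ont, property_record("has_input", parents = "has_participant"))
  ont <- termforge:::ont_add_property(
    ont, property_record("part_of", transitive = TRUE))
  for (id in c("T:M", "T:K", "T:X", "T:W1", "T:W2", "T:W3")) {
    ont <- termforge:::ont_add_term(ont, term_record(id))
  }
  ont <- termforge:::ont_add_term(ont, term_record(
    "T:METX", logical_def = ce_and(
      ce_named("T:M"), ce_some("has_participant", ce_named("T:X")))))
  ont <- termforge:::ont_add_term(ont, term_record(
    "T:CATX", told_parents = "T:M",
    logical_def = ce_and(ce_named("T:K"),
                         ce_some("has_input", ce_named("T:X")))))
  cl <- saturate(normalize(ont))
  expect_true(cl$S["T:CATX", "T:METX"])

  # part_of chains compose: P3 part_of W3 part_of W2 part_of W1 entails
  # membership in 'M part_of W1' — but only while part_of is transitive
  ont2 <- ont
  ont2$terms[["T:W2"]]$relationships <- list(
    list(property = "part_of", target = "T:W1"))
  ont2$terms[["T:W3"]]$relationships <- list(
    list(property = "part_of", target = "T:W2"))
  ont2 <- termforge:::ont_add_term(ont2, term_record(
    "T:PW1", logical_def = ce_and(ce_named("T:M"),
                                  ce_some("part_of", ce_named("T:W1")))))
  ont2 <- termforge:::ont_add_term(ont2, term_record(
    "T:P3", told_parents = "T:M",
    relationships = list(list(property = "part_of", target = "T:W3"))))
  expect_true(saturate(normalize(ont2))$S["T:P3", "T:PW1"])
  ont2$properties[["part_of"]]$transitive <- FALSE
  expect_false(saturate(normalize(ont2))$S["T:P3", "T:PW1"])
})

test_that("classification produces a transitively reduced taxonomy", {
  tax <- classify(mini_go_chebi()$ontology)
  expect_identical(tax$direct_supers[["GO:0009056"]], "GO:0008152")
  expect_identical(tax$direct_supers[["GO:0008150"]], character(0))
  # no direct edge is implied by two others
  edges <- taxonomy_edges(tax)
  cl <- saturate(normalize(mini_go_chebi()$ontology))
  for (k in seq_len(nrow(edges))) {
    a <- edges$child[k]; b <- edges$parent[k]
    others <- edges$parent[edges$child == a & edges$parent != b]
    expect_false(any(cl$S[others, b]))
  }
})

test_that("mutually defined classes merge into one equivalence group", {
  ont <- ontology()
  ont <- termforge:::ont_add_property(ont, property_record("r"))
  for (id in c("T:G", "T:F")) {
    ont <- termforge:::ont_add_term(ont, term_record(id))
  }
  defn <- ce_and(ce_named("T:G"), ce_some("r", ce_named("T:F")))
  ont <- termforge:::ont_add_term(ont, term_record("T:A", label = "a",
                                                   logical_def = defn))
  ont <- termforge:::ont_add_term(ont, term_record("T:B", label = "b",
                                                   logical_def = defn))
  tax <- classify(ont)
  grp <- Filter(function(g) "T:A" %in% g, tax$equiv_groups)[[1L]]
  expect_setequal(grp, c("T:A", "T:B"))
  expect_identical(tax$direct_supers[["T:A"]], tax$direct_supers[["T:B"]])
})

test_that("classification refuses incoherent ontologies", {
  ont <- ontology()
  for (id in c("T:A", "T:B")) {
    ont <- termforge:::ont_add_term(ont, term_record(id))
  }
  ont <- termforge:::ont_add_term(ont, term_record(
    "T:X", told_parents = c("T:A", "T:B")))
  ont <- termforge:::ont_add_disjoint(ont, "T:A", "T:B")
  err <- tryCatch(classify(ont), termforge_incoherent = function(e) e)
  expect_s3_class(err, "termforge_incoherent")
  expect_identical(err$unsatisfiable, "T:X")
})

test_that("placement finds equivalents, supers, subs and reverts cleanly", {
  ont <- figure4_fixture()
  before <- write_obo(ont)
  pl <- place(ont, ce_and(ce_named("GO:0009056"),
                          ce_some("has_input", ce_named("CHEBI:27656"))))
  expect_identical(write_obo(ont), before)       # revert semantics
  expect_identical(pl$direct_supers, "GO:0009822")
  expect_identical(pl$equivalents, character(0))
  expect_true(pl$satisfiable)
  expect_true(pl$ontology_coherent)

  # a bare named class is equivalent to itself
  pl2 <- place(ont, ce_named("GO:0009056"))
  expect_identical(pl2$equivalents, "GO:0009056")
  expect_identical(pl2$direct_supers,
                   classify(ont)$direct_supers[["GO:0009056"]])

  # conjoining disjoint classes is unsatisfiable
  m <- mini_go_chebi()$ontology
  pl3 <- place(m, ce_and(ce_named("GO:0008150"), ce_named("GO:0003674")))
  expect_false(pl3$satisfiable)
  expect_true(pl3$ontology_coherent)

  expect_error(place(ont, ce_named("NO:1")),
               class = "termforge_unknown_id")
})

test_that("inserting an intermediate class yields the expected rewrites", {
  # S ≡ K ⊓ ∃r.camptothecin with told parent K; inserting
  # M ≡ K ⊓ ∃r.alkaloid lands between K and S, so S's told link moves to M
  ont <- figure4_fixture()
  ont <- apply_new_term(ont, term_record(
    "TEST:0000900", label = "camptothecin catabolic process",
    told_parents = "GO:0009056",
    logical_def = ce_and(ce_named("GO:0009056"),
                         ce_some("has_input", ce_named("CHEBI:27656")))))
  ont <- obsolete_term(ont, "GO:0009822", "drop the alkaloid class") |>
    suppressWarnings()
  ont$terms[["GO:0009822"]] <- NULL
  expr <- ce_and(ce_named("GO:0009056"),
                 ce_some("has_input", ce_named("TEST:0000101")))
  pl <- place(ont, expr)
  expect_identical(pl$direct_subs, "TEST:0000900")
  rw <- relation_rewrites_for(ont, pl, "GO:2000001")
  expect_length(rw, 1L)
  expect_identical(rw[[1L]],
                   list(child = "TEST:0000900", drop_parent = "GO:0009056",
                        add_parent = "GO:2000001"))
  # committing with the rewrites makes asserted match entailed
  ont2 <- apply_new_term(ont, term_record(
    "GO:2000001", label = "alkaloid catabolic process",
    told_parents = pl$direct_supers, logical_def = expr), rw)
  tax <- classify(ont2)
  expect_identical(tax$direct_supers[["TEST:0000900"]], "GO:2000001")
  expect_identical(get_term(ont2, "TEST:0000900")$told_parents,
                   "GO:2000001")

  # a leaf placement yields no rewrites
  leaf <- place(ont, ce_and(ce_named("GO:0009056"),
                            ce_some("has_input", ce_named("CHEBI:27656"))))
  expect_identical(leaf$equivalents, "TEST:0000900")
})

test_that("subclass closures are reflexive, subset-true and exclude obsolete", {
  m <- mini_go_chebi()
  mf <- subclass_closure(m$ontology, "GO:0003674")
  bp <- subclass_closure(m$ontology, "GO:0008150")
  expect_length(intersect(mf, bp), 0L)
  expect_true(all(c("GO:0005215", "GO:0022857") %in% mf))
  expect_identical(subclass_closure(m$ontology, "CHEBI:27656"),
                   "CHEBI:27656")
  expect_setequal(subclass_closure(m$ontology,
                                   c("GO:0003674", "CHEBI:24431")),
                  union(mf, subclass_closure(m$ontology, "CHEBI:24431")))
  obs <- obsolete_term(m$ontology, "GO:0005488", "gone")
  expect_false("GO:0005488" %in% subclass_closure(obs, "GO:0003674"))
  expect_error(subclass_closure(m$ontology, "NO:1"),
               class = "termforge_unknown_id")
})

test_that("completion-rule reasoning matches the structural oracle", {
  for (seed in 1:25) {
    ont <- random_ontology(n_classes = sample(5:30, 1L), n_properties = 3,
                           p_isa = 0.12, p_def = 0.3, p_rel = 0.15,
                           seed = seed)
    expect_identical(reasoner_subsumption_set(ont),
                     oracle_subsumption_set(ont),
                     info = paste("seed", seed))
  }
})

test_that("adding an axiom never removes an entailment (monotonicity)", {
  set.seed(42)
  for (rep in 1:10) {
    ont <- random_ontology(12, p_def = 0.3, seed = 100 + rep)
    base <- reasoner_subsumption_set(ont)
    ids <- names(ont$terms)
    child <- sample(ids[-1], 1L)
    parent <- sample(setdiff(ids, child), 1L)
    # only add axioms that keep the told graph acyclic: earlier id as parent
    if (parent > child) { tmp <- child; child <- parent; parent <- tmp }
    ont$terms[[child]]$told_parents <-
      sort(unique(c(ont$terms[[child]]$told_parents, parent)))
    grown <- reasoner_subsumption_set(ont)
    expect_true(all(base %in% grown))
  }
})
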