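rel_map <- list("exports" = "exports", "part_of" = "part_of",
                "transports or maintains localization of" =
                  "transports_or_maintains_localization_of",
                "has target start location" = "has_target_start_location")

test_that("pattern strings parse into genus-differentia expressions", {
  p <- parse_pattern("GO:0006810 and 'exports' some ?X", rel_map)
  expect_identical(p$type, "and")
  expect_identical(p$parts[[1L]]$id, "GO:0006810")
  expect_identical(p$parts[[2L]]$property, "exports")
  expect_identical(p$parts[[2L]]$filler$name, "X")

  p2 <- parse_pattern("?P and 'part_of' some ?W", rel_map)
  expect_identical(p2$parts[[1L]]$name, "P")
  expect_identical(p2$parts[[2L]]$property, "part_of")

  p3 <- parse_pattern(paste0(
    "GO:0006810 and 'transports or maintains localization of' some ?X ",
    "[and 'has target start location' some ?F]"), rel_map)
  expect_length(p3$parts, 3L)
  expect_false(isTRUE(p3$parts[[2L]]$optional))
  expect_true(p3$parts[[3L]]$optional)
  expect_identical(termforge:::ce_var_names(p3$parts[[3L]]), "F")

  expect_error(parse_pattern("GO:1 and 'unknown rel' some ?X", rel_map),
               "unknown relation label")
  expect_error(parse_pattern("GO:1 and nonsense here", rel_map),
               "cannot parse")
})

test_that("the shipped catalogue loads and every pattern is well-formed", {
  ts <- shipped_templates()
  expect_gt(length(ts$templates), 40L)
  expect_true("chemical_export" %in% names(ts$templates))
  ce <- ts$templates$chemical_export
  cls <- Filter(function(f) f$kind == "class", ce$fields)
  expect_length(cls, 1L)
  expect_identical(cls[[1L]]$subsets, "chebi")
  for (tp in ts$templates) {
    n_class <- sum(vapply(tp$fields, function(f) f$kind == "class",
                          logical(1)))
    expect_gte(n_class, 1L)
    expect_lte(n_class, 3L)
    expect_s3_class(tp$pattern, "class_expression")
    # grounding with every class field bound leaves no variables
    expect_true(all(termforge:::ce_var_names(tp$pattern) %in%
                      names(tp$fields)))
  }
})

test_that("config errors are caught at load time", {
  expect_error(load_templates(list(templates = list(
    list(name = "t1", pattern = "GO:1 and 'exports' some ?Y",
         fields = list(list(name = "X", kind = "class",
                            subsets = list("chebi")))),
    relations = list(exports = "exports")))),
    "undeclared|unknown relation")
  expect_identical(length(load_templates(list())$templates), 0L)
  expect_error(load_templates(list(
    relations = list(exports = "exports"),
    templates = list(
      list(name = "dup", pattern = "GO:1 and 'exports' some ?X",
           fields = list(list(name = "X", kind = "class",
                              subsets = list("chebi")))),
      list(name = "dup", pattern = "GO:1 and 'exports' some ?X",
           fields = list(list(name = "X", kind = "class",
                              subsets = list("chebi"))))))),
    "duplicate template name")
})

test_that("binding validation checks presence, resolution and subsets", {
  ts <- shipped_templates()
  m <- mini_go_chebi()
  reasoner <- el_reasoner(m$ontology)
  tpl <- ts$templates$chemical_export

  expect_identical(
    validate_binding(tpl, list(X = "CHEBI:27656", ref = "PMID:12345"),
                     reasoner, ts),
    character(0))
  f1 <- validate_binding(tpl, list(X = "CHEBI:27656"), reasoner, ts)
  expect_match(f1, "ref")                      # missing literature reference
  f2 <- validate_binding(tpl, list(X = "GO:0009056", ref = "PMID:1"),
                         reasoner, ts)
  expect_match(f2, "outside the allowed subset")
  f3 <- validate_binding(tpl, list(X = "CHEBI:27656", ref = "not a curie"),
                         reasoner, ts)
  expect_match(f3, "malformed reference")
  f4 <- validate_binding(tpl, list(X = "NO:999", ref = "PMID:1"),
                         reasoner, ts)
  expect_match(f4, "unknown class")
})

test_that("instantiation grounds logic, text, synonyms and references", {
  ts <- shipped_templates()
  m <- mini_go_chebi()
  reasoner <- el_reasoner(m$ontology)

  reg <- instantiate(ts$templates$regulation,
                     list(X = "TEST:0000201", ref = "PMID:77"),
                     reasoner, ts)
  expect_identical(reg$label, "regulation of cell migration")
  expect_true(ce_equal(reg$logical_def, ce_and(
    ce_named("GO:0065007"),
    ce_some("regulates", ce_named("TEST:0000201")))))
  expect_identical(reg$def_xrefs, "PMID:77")

  exp_ <- instantiate(ts$templates$chemical_export,
                      list(X = "CHEBI:27656", ref = "PMID:1"),
                      reasoner, ts)
  expect_true(ce_equal(exp_$logical_def, ce_and(
    ce_named("GO:0006810"),
    ce_some("exports", ce_named("CHEBI:27656")))))

  # synonym rules apply to each synonym of the bound class
  cat_ <- instantiate(ts$templates$catabolism,
                      list(X = "CHEBI:27656", ref = "PMID:1"),
                      reasoner, ts)
  syn_texts <- vapply(cat_$synonyms, function(s) s$text, "")
  expect_true("(S)-camptothecin catabolic process" %in% syn_texts)
  expect_true(all(vapply(cat_$synonyms, function(s) s$scope, "") ==
                    "EXACT"))

  # quoted class labels in patterns resolve against the ontology
  pd <- instantiate(ts$templates$plant_development,
                    list(P = "TEST:0000401", ref = "PMID:2"),
                    reasoner, ts)
  expect_true("TEST:0000202" %in% termforge:::ce_class_ids(pd$logical_def))
  expect_identical(pd$label, "leaf development")
})

test_that("optional fields drop their conjuncts and text segments", {
  ts <- shipped_templates()
  m <- mini_go_chebi()
  reasoner <- el_reasoner(m$ontology)
  tpl <- ts$templates$chemical_transport_from_to

  bare <- instantiate(tpl, list(X = "TEST:0000102", ref = "PMID:1"),
                      reasoner, ts)
  expect_identical(bare$label, "glucose transport")
  expect_length(bare$logical_def$parts, 2L)

  with_t <- instantiate(tpl, list(X = "TEST:0000102", T = "TEST:0000302",
                                  ref = "PMID:1"), reasoner, ts)
  expect_identical(with_t$label, "glucose transport to vesicle")
  expect_length(with_t$logical_def$parts, 3L)
  expect_true("TEST:0000302" %in%
                termforge:::ce_class_ids(with_t$logical_def))

  # instantiation is deterministic
  expect_identical(write_obo(ontology()), write_obo(ontology()))
  expect_identical(ce_key(with_t$logical_def),
                   ce_key(instantiate(tpl, list(X = "TEST:0000102",
                                                T = "TEST:0000302",
                                                ref = "PMID:1"),
                                      reasoner, ts)$logical_def))
})
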