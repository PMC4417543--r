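#' Built-in toy ontologies
#'
#' Deterministic fixture ontologies used throughout the documentation and
#' test suite. Identifiers of well-known GO/ChEBI/PO/CL/Uberon/PATO classes
#' keep their familiar CURIEs; purely synthetic filler classes use the
#' `TEST:` prefix.
#'
#' `figure4_fixture()` builds the camptothecin-catabolism worked example: a
#' small metabolic-process branch, an alkaloid branch with camptothecin
#' (CHEBI:27656), and 'alkaloid catabolic process' (GO:0009822) defined as
#' catabolic process that has_input some alkaloid. Placing the candidate
#' `catabolic process and has_input some camptothecin` on this fixture lets
#' the reasoner infer the more specific superclass GO:0009822 rather than
#' the told genus alone.
#'
#' @return an `obo_ontology`.
#' @export
figure4_fixture <- function() {
  ont <- ontology(ontology_tag = "termforge-figure4-fixture")
  ont <- ont_add_property(ont, property_record("has_input", "has input"))
  add <- function(ont, ...) ont_add_term(ont, term_record(...))
  ont <- add(ont, "GO:0008152", "metabolic process",
             namespace = "biological_process")
  ont <- add(ont, "GO:0009056", "catabolic process",
             namespace = "biological_process",
             told_parents = "GO:0008152")
  ont <- add(ont, "TEST:0000101", "alkaloid", namespace = "chebi_ontology")
  ont <- add(ont, "CHEBI:27656", "camptothecin",
             namespace = "chebi_ontology",
             synonyms = list(list(text = "(S)-camptothecin",
                                  scope = "EXACT")),
             told_parents = "TEST:0000101")
  ont <- add(ont, "GO:0009822", "alkaloid catabolic process",
             namespace = "biological_process",
             told_parents = "GO:0009056",
             logical_def = ce_and(
               ce_named("GO:0009056"),
               ce_some("has_input", ce_named("TEST:0000101"))))
  validate_ontology(ont, character(0))
}

#' @description
#' `mini_go_chebi()` builds a ~45-class fixture spanning the three GO
#' branches (biological_process under GO:0008150, molecular_function under
#' GO:0003674, cellular_component under GO:0005575), a ChEBI chemical-entity
#' branch, and single-class stand-ins for the plant-anatomy, cell-type,
#' gross-anatomy and quality ontologies, together with the relation set the
#' shipped template catalogue needs. It returns the ontology and the named
#' subset roots (BP, MF, CC, chebi, plant, cell, Uberon) used for field
#' validation and autocompletion.
#'
#' @return `mini_go_chebi()`: a list with elements `ontology` and `subsets`
#'   (named list of root-id character vectors).
#' @rdname figure4_fixture
#' @export
mini_go_chebi <- function() {
  ont <- ontology(ontology_tag = "termforge-mini-go-chebi")
  prop <- function(ont, id, label, parents = character(0),
                   transitive = FALSE) {
    ont_add_property(ont, property_record(id, label, parents, transitive))
  }
  ont <- prop(ont, "part_of", "part of", transitive = TRUE)
  ont <- prop(ont, "occurs_in", "occurs in")
  ont <- prop(ont, "regulates", "regulates")
  ont <- prop(ont, "negatively_regulates", "negatively regulates",
              parents = "regulates")
  ont <- prop(ont, "positively_regulates", "positively regulates",
              parents = "regulates")
  ont <- prop(ont, "has_participant", "has participant")
  ont <- prop(ont, "has_input", "has input", parents = "has_participant")
  ont <- prop(ont, "has_output", "has output", parents = "has_participant")
  ont <- prop(ont, "has_intermediate", "has intermediate")
  ont <- prop(ont, "transports_or_maintains_localization_of",
              "transports or maintains localization of")
  ont <- prop(ont, "imports", "imports")
  ont <- prop(ont, "exports", "exports")
  ont <- prop(ont, "has_target_start_location", "has target start location")
  ont <- prop(ont, "has_target_end_location", "has target end location")
  ont <- prop(ont, "results_in", "results_in")
  ont <- prop(ont, "regulates_level_of", "regulates level of")
  ont <- prop(ont, "results_in_assembly_of", "results_in_assembly_of")
  ont <- prop(ont, "results_in_disassembly_of", "results_in_disassembly_of")
  ont <- prop(ont, "results_in_development_of", "results in development of")
  ont <- prop(ont, "results_in_formation_of", "results in formation of")
  ont <- prop(ont, "results_in_developmental_progression_of",
              "results in developmental progression of")
  ont <- prop(ont, "results_in_morphogenesis_of",
              "results in morphogenesis of")
  ont <- prop(ont, "results_in_structural_organization_of",
              "results in structural organization of")
  ont <- prop(ont, "results_in_acquisition_of_features_of",
              "results in acquisition of features of")
  ont <- prop(ont, "alters_location_of", "alters location of")
  ont <- prop(ont, "capable_of", "capable_of")
  ont <- prop(ont, "bearer_of", "bearer of")

  add <- function(ont, id, label, parents = character(0), def = NULL,
                  ns = "biological_process", syn = list()) {
    ont_add_term(ont, term_record(id, label, namespace = ns,
                                  told_parents = parents, logical_def = def,
                                  synonyms = syn))
  }
  # biological_process branch
  ont <- add(ont, "GO:0008150", "biological_process")
  ont <- add(ont, "GO:0008152", "metabolic process", "GO:0008150")
  ont <- add(ont, "GO:0009056", "catabolic process", "GO:0008152")
  ont <- add(ont, "GO:0009058", "biosynthetic process", "GO:0008152")
  ont <- add(ont, "GO:0009822", "alkaloid catabolic process", "GO:0009056",
             def = ce_and(ce_named("GO:0009056"),
                          ce_some("has_input", ce_named("TEST:0000101"))))
  ont <- add(ont, "GO:0006810", "transport", "GO:0008150")
  ont <- add(ont, "GO:0055085", "transmembrane transport", "GO:0006810")
  ont <- add(ont, "GO:0016192", "vesicle-mediated transport", "GO:0006810")
  ont <- add(ont, "GO:0065007", "biological regulation", "GO:0008150")
  ont <- add(ont, "GO:0050789", "regulation of biological process",
             "GO:0065007",
             def = ce_and(ce_named("GO:0065007"),
                          ce_some("regulates", ce_named("GO:0008150"))))
  ont <- add(ont, "GO:0050896", "response to stimulus", "GO:0008150")
  ont <- add(ont, "GO:0070887", "cellular response to chemical stimulus",
             "GO:0050896")
  ont <- add(ont, "GO:0048878", "chemical homeostasis", "GO:0065007")
  ont <- add(ont, "GO:0055082", "cellular chemical homeostasis",
             "GO:0048878")
  ont <- add(ont, "GO:0030154", "cell differentiation", "GO:0008150")
  ont <- add(ont, "GO:0022607", "cellular component assembly", "GO:0008150")
  ont <- add(ont, "GO:0022411", "cellular component disassembly",
             "GO:0008150")
  ont <- add(ont, "GO:0008104", "protein localization", "GO:0008150")
  ont <- add(ont, "GO:0045184", "establishment of protein localization",
             "GO:0008104")
  ont <- add(ont, "TEST:0000201", "cell migration", "GO:0008150")
  ont <- add(ont, "TEST:0000202", "anatomical structure development",
             "GO:0008150")
  ont <- add(ont, "TEST:0000203",
             "anatomical structure formation involved in morphogenesis",
             "TEST:0000202")
  ont <- add(ont, "TEST:0000204", "developmental maturation", "GO:0008150")
  ont <- add(ont, "TEST:0000205", "anatomical structure morphogenesis",
             "GO:0008150")
  ont <- add(ont, "TEST:0000206", "anatomical structure arrangement",
             "GO:0008150")
  ont <- add(ont, "TEST:0000207", "cell-type specific apoptotic process",
             "GO:0008150")
  # molecular_function branch
  ont <- add(ont, "GO:0003674", "molecular_function",
             ns = "molecular_function")
  ont <- add(ont, "GO:0005215", "transporter activity", "GO:0003674",
             ns = "molecular_function")
  ont <- add(ont, "GO:0022857", "transmembrane transporter activity",
             "GO:0005215", ns = "molecular_function")
  ont <- add(ont, "GO:0015291",
             "secondary active transmembrane transporter activity",
             "GO:0022857", ns = "molecular_function")
  ont <- add(ont, "GO:0015563", "uptake transmembrane transporter activity",
             "GO:0022857", ns = "molecular_function")
  ont <- add(ont, "GO:0042626",
             "ATPase-coupled transmembrane transporter activity",
             "GO:0022857", ns = "molecular_function")
  ont <- add(ont, "GO:0005488", "binding", "GO:0003674",
             ns = "molecular_function")
  # cellular_component branch
  ont <- add(ont, "GO:0005575", "cellular_component",
             ns = "cellular_component")
  ont <- add(ont, "TEST:0000301", "membrane", "GO:0005575",
             ns = "cellular_component")
  ont <- add(ont, "TEST:0000302", "vesicle", "GO:0005575",
             ns = "cellular_component")
  ont <- add(ont, "TEST:0000303", "megasome", "GO:0005575",
             ns = "cellular_component")
  ont <- add(ont, "GO:0043234", "protein complex", "GO:0005575",
             ns = "cellular_component")
  # chemical entities
  ont <- add(ont, "CHEBI:24431", "chemical entity", ns = "chebi_ontology")
  ont <- add(ont, "TEST:0000101", "alkaloid", "CHEBI:24431",
             ns = "chebi_ontology")
  ont <- add(ont, "CHEBI:27656", "camptothecin", "TEST:0000101",
             ns = "chebi_ontology",
             syn = list(list(text = "(S)-camptothecin", scope = "EXACT")))
  ont <- add(ont, "TEST:0000102", "glucose", "CHEBI:24431",
             ns = "chebi_ontology")
  ont <- add(ont, "TEST:0000103", "lactose", "CHEBI:24431",
             ns = "chebi_ontology")
  # external-ontology stand-ins for the remaining template subset roots
  ont <- add(ont, "PO:0025131", "plant anatomical entity", ns = "plant")
  ont <- add(ont, "TEST:0000401", "leaf", "PO:0025131", ns = "plant")
  ont <- add(ont, "CL:0000003", "native cell", ns = "cell")
  ont <- add(ont, "TEST:0000402", "neuron", "CL:0000003", ns = "cell")
  ont <- add(ont, "UBERON:0001062", "anatomical entity", ns = "uberon")
  ont <- add(ont, "TEST:0000403", "heart", "UBERON:0001062", ns = "uberon")
  ont <- add(ont, "PATO:0002487", "single-organism process quality",
             ns = "quality")
  ont <- add(ont, "PATO:0002486", "multi-organism process quality",
             ns = "quality")

  ont <- ont_add_disjoint(ont, "GO:0008150", "GO:0003674")
  ont <- ont_add_disjoint(ont, "GO:0008150", "GO:0005575")
  ont <- validate_ontology(ont, character(0))

  subsets <- list(
    BP = "GO:0008150", MF = "GO:0003674", CC = "GO:0005575",
    chebi = "CHEBI:24431", plant = "PO:0025131", cell = "CL:0000003",
    Uberon = "UBERON:0001062", "GO:0050789" = "GO:0050789")
  list(ontology = ont, subsets = subsets)
}

#' Seeded random ontology generator
#'
#' Generates an acyclic ontology for oracle-based testing of the reasoner:
#' classes are created in order and may only reference earlier classes, so
#' both the asserted hierarchy and the definition graph are acyclic by
#' construction. Each ordered pair of classes gets an asserted `is_a` edge
#' with probability `p_isa`; each class (from the third onward) receives a
#' genus-differentia logical definition with probability `p_def` (genus and
#' filler drawn from earlier classes, relation drawn from the property
#' pool); each class gets one relationship line with probability `p_rel`.
#' Properties are plain (no hierarchy, not transitive) so an independent
#' structural-subsumption oracle stays straightforward. Output is a pure
#' function of the arguments: the global RNG state is saved and restored.
#'
#' @param n_classes number of classes.
#' @param n_properties number of properties in the pool.
#' @param p_isa probability of an asserted `is_a` edge per ordered class
#'   pair.
#' @param p_def probability that a class receives a logical definition.
#' @param p_rel probability that a class receives one relationship line.
#' @param seed integer seed.
#' @return an `obo_ontology`.
#' @export
random_ontology <- function(n_classes, n_properties = 2, p_isa = 0.1,
                            p_def = 0.25, p_rel = 0.1, seed = 1) {
  stopifnot(n_classes >= 1, n_properties >= 1,
            p_isa >= 0, p_isa <= 1, p_def >= 0, p_def <= 1,
            p_rel >= 0, p_rel <= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  ids <- sprintf("TEST:%07d", seq_len(n_classes))
  props <- sprintf("test_rel_%d", seq_len(n_properties))
  ont <- ontology(ontology_tag = "termforge-random")
  for (p in props) ont <- ont_add_property(ont, property_record(p))

  for (i in seq_len(n_classes)) {
    parents <- character(0)
    logical_def <- NULL
    rels <- list()
    if (i >= 2) {
      earlier <- ids[seq_len(i - 1L)]
      parents <- earlier[stats::runif(i - 1L) < p_isa]
      if (i >= 3 && stats::runif(1) < p_def) {
        genus <- sample(earlier, 1L)
        filler <- sample(earlier, 1L)
        rel <- sample(props, 1L)
        logical_def <- ce_and(ce_named(genus),
                              ce_some(rel, ce_named(filler)))
      }
      if (stats::runif(1) < p_rel) {
        rels <- list(list(property = sample(props, 1L),
                          target = sample(earlier, 1L)))
      }
    }
    ont <- ont_add_term(ont, term_record(
      ids[i], label = paste("random class", i),
      told_parents = sort(unique(parents)), relationships = rels,
      logical_def = logical_def))
  }
  validate_ontology(ont, character(0))
}
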