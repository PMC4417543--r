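# Shared test scaffolding: a workspace with an on-disk ontology, queue,
# id-policy state and the shipped template catalogue.

shipped_template_path <- function() {
  p <- system.file("extdata", "go_templates.yaml", package = "termforge")
  if (nzchar(p)) p else file.path("..", "..", "inst", "extdata",
                                  "go_templates.yaml")
}

make_workspace <- function(ont = mini_go_chebi()$ontology,
                           range = c(2000001L, 2001000L)) {
  dir <- tempfile("termforge-ws-")
  dir.create(dir)
  write_obo_file(ont, file.path(dir, "ontology.obo"))
  list(
    dir = dir,
    ontology_path = file.path(dir, "ontology.obo"),
    queue = request_queue(file.path(dir, "queue.jsonl")),
    policy = id_policy("GO", 7, range[1], range[2],
                       file.path(dir, "ids.txt")),
    changelog = file.path(dir, "changelog.tsv"))
}

shipped_templates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_templates(shipped_template_path())
    cache
  }
})

# A deterministic definable candidate over an existing ontology. Odd seeds
# draw genus/property/filler at random; even seeds generalize an existing
# defined class (same genus and property, filler lifted to a told parent),
# which lands the candidate *above* that class and can force relation
# rewrites of its children. Returns NULL when the even-seed strategy finds
# no suitable class.
acceptance_candidate <- function(ont, seed) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(90000L + seed)
  ids <- names(ont$terms)
  props <- names(ont$properties)
  if (seed %% 2L == 1L) {
    return(ce_and(ce_named(sample(ids, 1L)),
                  ce_some(sample(props, 1L), ce_named(sample(ids, 1L)))))
  }
  defined <- Filter(function(t) !is.null(t$logical_def), ont$terms)
  defined <- Filter(function(t) {
    filler <- t$logical_def$parts[[2L]]$filler$id
    length(ont$terms[[filler]]$told_parents) > 0L
  }, defined)
  if (!length(defined)) return(NULL)
  d <- defined[[sample(length(defined), 1L)]]$logical_def
  filler <- d$parts[[2L]]$filler$id
  lifted <- sample(ont$terms[[filler]]$told_parents, 1L)
  ce_and(ce_named(d$parts[[1L]]$id),
         ce_some(d$parts[[2L]]$property, ce_named(lifted)))
}

# One-off template set binding a genus/filler pair through the real
# template machinery (each bound class is its own subset root).
pair_template_set <- function(cand) {
  rel <- cand$parts[[2L]]$property
  relations <- list()
  relations[[rel]] <- rel
  load_templates(list(
    relations = relations,
    subsets = list(),
    templates = list(list(
      name = "candidate", namespace = "test",
      fields = list(
        list(name = "G", kind = "class",
             subsets = list(cand$parts[[1L]]$id)),
        list(name = "F", kind = "class",
             subsets = list(cand$parts[[2L]]$filler$id))),
      pattern = sprintf("?G and '%s' some ?F", rel),
      name_pattern = "generated class [G.id] by [F.id]",
      def_pattern = "Any [G] related through the pattern to [F]."))))
}
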