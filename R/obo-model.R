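#' Ontology container and term/property records
#'
#' An `obo_ontology` holds terms (classes) and properties (relations) keyed by
#' identifier, plus declared disjoint class pairs. Identifiers are CURIEs
#' (`"PREFIX:LOCAL"`) for classes; property identifiers may be label-like
#' tokens (e.g. `has_input`), as is customary in OBO cross-product
#' definitions.
#'
#' @param format_tag value for the `format-version` header line.
#' @param ontology_tag value for the `ontology` header line (may be `""`).
#' @return `ontology()` returns an empty `obo_ontology`.
#' @export
ontology <- function(format_tag = "1.4", ontology_tag = "") {
  structure(
    list(
      terms = list(),
      properties = list(),
      disjoint_pairs = list(),
      format_tag = format_tag,
      ontology_tag = ontology_tag,
      header_extra = character(0)
    ),
    class = "obo_ontology"
  )
}

#' @param id class identifier (CURIE).
#' @param label class label; must be unique among non-obsolete terms.
#' @param namespace OBO namespace string.
#' @param definition textual definition.
#' @param def_xrefs character vector of definition cross-references.
#' @param comment free-text comment.
#' @param synonyms list of `list(text =, scope =)` entries; scope is one of
#'   EXACT, BROAD, NARROW, RELATED.
#' @param told_parents character vector of asserted `is_a` parents.
#' @param relationships list of `list(property =, target =)` entries.
#' @param logical_def optional [class_expression] equivalence axiom
#'   (genus-differentia conjunction), or `NULL`.
#' @param obsolete logical obsoletion flag.
#' @param created_by requester/curator identifier for provenance.
#' @param creation_date ISO-8601 timestamp string.
#' @param stub whether the term is an auto-created stub for an external
#'   reference.
#' @param extra verbatim unparsed tag lines preserved for round-trip.
#' @rdname ontology
#' @export
term_record <- function(id, label = id, namespace = "", definition = "",
                        def_xrefs = character(0), comment = "",
                        synonyms = list(), told_parents = character(0),
                        relationships = list(), logical_def = NULL,
                        obsolete = FALSE, created_by = "",
                        creation_date = "", stub = FALSE,
                        extra = character(0)) {
  check_curie(id)
  if (obsolete && (length(told_parents) || length(relationships) ||
                   !is.null(logical_def))) {
    stop("obsolete term ", id,
         " must not carry is_a links, relationships or a logical definition")
  }
  structure(
    list(id = id, label = label, namespace = namespace,
         definition = definition, def_xrefs = def_xrefs, comment = comment,
         synonyms = synonyms, told_parents = told_parents,
         relationships = relationships, logical_def = logical_def,
         obsolete = obsolete, created_by = created_by,
         creation_date = creation_date, stub = stub, extra = extra),
    class = "term_record"
  )
}

#' @param transitive whether the property is transitive.
#' @param parents character vector of super-properties.
#' @rdname ontology
#' @export
property_record <- function(id, label = id, parents = character(0),
                            transitive = FALSE) {
  structure(
    list(id = id, label = label, parents = parents, transitive = transitive),
    class = "property_record"
  )
}

check_curie <- function(id) {
  if (!is.character(id) || length(id) != 1L ||
      !grepl("^[^:[:space:]]+:[^:[:space:]]+$", id)) {
    stop("not a valid CURIE class id: ", deparse(id))
  }
  invisible(id)
}

curie_prefix <- function(id) sub(":.*$", "", id)

#' @param x,ont an `obo_ontology`.
#' @rdname ontology
#' @export
term_ids <- function(ont) names(ont$terms)

#' @rdname ontology
#' @export
get_term <- function(ont, id) {
  t <- ont$terms[[id]]
  if (is.null(t)) stop("unknown term id: ", id)
  t
}

#' @rdname ontology
#' @export
print.obo_ontology <- function(x, ...) {
  n_obs <- sum(vapply(x$terms, function(t) t$obsolete, logical(1)))
  n_def <- sum(vapply(x$terms, function(t) !is.null(t$logical_def),
                      logical(1)))
  cat(sprintf(
    "<obo_ontology> %d terms (%d obsolete, %d with logical definitions), %d properties, %d disjoint pairs\n",
    length(x$terms), n_obs, n_def, length(x$properties),
    length(x$disjoint_pairs)))
  invisible(x)
}

# Insert helpers used by fixtures and commit; validation happens at parse /
# apply time, so these stay cheap.
ont_add_term <- function(ont, term) {
  stopifnot(inherits(term, "term_record"))
  ont$terms[[term$id]] <- term
  ont
}

ont_add_property <- function(ont, prop) {
  stopifnot(inherits(prop, "property_record"))
  ont$properties[[prop$id]] <- prop
  ont
}

ont_add_disjoint <- function(ont, a, b) {
  pair <- sort(c(a, b))
  key <- paste(pair, collapse = "|")
  keys <- vapply(ont$disjoint_pairs, paste, "", collapse = "|")
  if (!key %in% keys) ont$disjoint_pairs <- c(ont$disjoint_pairs, list(pair))
  ont
}

# Non-obsolete labels (and synonym texts) keyed by term id.
ont_labels <- function(ont, include_obsolete = FALSE) {
  keep <- vapply(ont$terms, function(t) include_obsolete || !t$obsolete,
                 logical(1))
  vapply(ont$terms[keep], function(t) t$label, "")
}

# Resolve a class label to an id among non-obsolete terms; error when absent
# or ambiguous (labels are unique by load-time invariant).
resolve_label <- function(ont, label) {
  labs <- ont_labels(ont)
  hit <- names(labs)[labs == label]
  if (length(hit) != 1L) stop("cannot resolve class label: '", label, "'")
  hit
}

#' Add a new term to an ontology, rewriting child relations
#'
#' Returns a new ontology value with `term` inserted and, for each rewrite
#' `(child, drop_parent, add_parent)`, the child's asserted `is_a` link to
#' `drop_parent` replaced by a link to `add_parent`. The input ontology is
#' never mutated. Rewrites are how an intermediate class inserted between an
#' existing child and its former parent keeps the asserted hierarchy equal to
#' the entailed one.
#'
#' @param ont an `obo_ontology`.
#' @param term a [term_record()] whose id is not yet present.
#' @param rewrites list of `list(child =, drop_parent =, add_parent =)`.
#' @return the updated `obo_ontology`.
#' @export
apply_new_term <- function(ont, term, rewrites = list()) {
  stopifnot(inherits(ont, "obo_ontology"), inherits(term, "term_record"))
  if (!is.null(ont$terms[[term$id]])) {
    stop(errorCondition(paste0("id collision: ", term$id,
                               " already present in the ontology"),
                        class = c("termforge_id_collision", "termforge_error")))
  }
  for (rw in rewrites) {
    for (ref in c(rw$child, rw$drop_parent, rw$add_parent)) {
      if (ref != term$id && is.null(ont$terms[[ref]])) {
        stop(errorCondition(paste0("unknown rewrite target: ", ref),
                            class = c("termforge_unknown_id",
                                      "termforge_error")))
      }
    }
  }
  ont <- ont_add_term(ont, term)
  for (rw in rewrites) {
    child <- ont$terms[[rw$child]]
    parents <- setdiff(child$told_parents, rw$drop_parent)
    child$told_parents <- sort(unique(c(parents, rw$add_parent)))
    ont$terms[[rw$child]] <- child
  }
  ont
}

#' Obsolete a term
#'
#' Marks the term obsolete, clears its `is_a` links, relationships and
#' logical definition, and records the reason in the term comment. The label
#' is kept unchanged so the term remains findable. No other term is touched;
#' children keep their (now dangling-to-obsolete) `is_a` lines, which raise a
#' warning on the next parse.
#'
#' @param ont an `obo_ontology`.
#' @param id class id to obsolete.
#' @param reason free-text reason, stored in the `comment:` field.
#' @return the updated `obo_ontology`.
#' @export
obsolete_term <- function(ont, id, reason = "") {
  t <- ont$terms[[id]]
  if (is.null(t)) {
    stop(errorCondition(paste0("unknown term id: ", id),
                        class = c("termforge_unknown_id", "termforge_error")))
  }
  if (t$obsolete) {
    stop(errorCondition(paste0("term already obsolete: ", id),
                        class = c("termforge_illegal_state",
                                  "termforge_error")))
  }
  t$obsolete <- TRUE
  t$told_parents <- character(0)
  t$relationships <- list()
  t$logical_def <- NULL
  if (nzchar(reason)) {
    t$comment <- if (nzchar(t$comment)) paste0(t$comment, " ", reason) else reason
  }
  ont$terms[[id]] <- t
  ont
}
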