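#' Class expressions
#'
#' The EL fragment used throughout the package: a class expression is a named
#' class, an existential restriction over a property, or a conjunction of at
#' least two expressions. Equivalence axioms attached to ontology terms
#' (genus-differentia logical definitions) are built from these constructors.
#'
#' Conjunctions are flattened on construction (no nested conjunctions) and
#' structural equality is order-insensitive for conjunction parts; see
#' [ce_equal()].
#'
#' @param id a class identifier (CURIE string, e.g. `"GO:0009056"`).
#' @param property a property identifier (CURIE or label-like token such as
#'   `"has_input"`).
#' @param filler a `class_expression` for the existential filler.
#' @param ... two or more `class_expression` objects (or a single list of
#'   them) to conjoin.
#' @return an object of class `class_expression`.
#' @examples
#' ce_and(ce_named("GO:0009056"), ce_some("has_input", ce_named("CHEBI:27656")))
#' @name class_expression
NULL

new_ce <- function(type, fields) {
  structure(c(list(type = type), fields), class = "class_expression")
}

#' @rdname class_expression
#' @export
ce_named <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  new_ce("named", list(id = id))
}

#' @rdname class_expression
#' @export
ce_some <- function(property, filler) {
  stopifnot(is.character(property), length(property) == 1L, nzchar(property))
  if (is.character(filler)) filler <- ce_named(filler)
  stopifnot(inherits(filler, "class_expression"))
  new_ce("some", list(property = property, filler = filler))
}

#' @rdname class_expression
#' @export
ce_and <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1L]], "class_expression")) {
    parts <- parts[[1L]]
  }
  flat <- list()
  for (p in parts) {
    stopifnot(inherits(p, "class_expression"))
    if (p$type == "and") flat <- c(flat, p$parts) else flat <- c(flat, list(p))
  }
  if (length(flat) == 1L) return(flat[[1L]])
  if (length(flat) < 2L) stop("a conjunction needs at least two parts")
  new_ce("and", list(parts = flat))
}

# Variable leaf used only inside template patterns (never in a grounded
# definition); `optional` marks a bracketed conjunct tied to an optional field.
ce_var <- function(name, optional = FALSE) {
  new_ce("var", list(name = name, optional = optional))
}

# Label leaf: a quoted class label in a template pattern, resolved to a named
# class against the loaded ontologies at instantiation time.
ce_label <- function(text) {
  new_ce("label", list(text = text))
}

#' Canonical key of a class expression
#'
#' Deterministic string form used for structural comparison and for deriving
#' fresh class names during normalization. Conjunction parts are sorted, so
#' the key is order-insensitive.
#'
#' @param x a `class_expression`.
#' @return a single string.
#' @export
ce_key <- function(x) {
  stopifnot(inherits(x, "class_expression"))
  switch(x$type,
    named = x$id,
    var   = paste0("?", x$name, if (isTRUE(x$optional)) "[opt]" else ""),
    label = paste0("'", x$text, "'"),
    some  = paste0("some(", x$property, ",", ce_key(x$filler), ")"),
    and   = paste0("and(", paste(sort(vapply(x$parts, ce_key, "")),
                                 collapse = ","), ")"),
    stop("unknown expression type: ", x$type)
  )
}

#' Structural equality of class expressions
#'
#' @param a,b `class_expression` objects.
#' @return `TRUE` if the expressions are structurally equal (conjunction part
#'   order is ignored).
#' @export
ce_equal <- function(a, b) identical(ce_key(a), ce_key(b))

# All named class ids mentioned in an expression.
ce_class_ids <- function(x) {
  switch(x$type,
    named = x$id,
    some  = ce_class_ids(x$filler),
    and   = unique(unlist(lapply(x$parts, ce_class_ids))),
    character(0)
  )
}

# All property ids mentioned in an expression.
ce_property_ids <- function(x) {
  switch(x$type,
    some = unique(c(x$property, ce_property_ids(x$filler))),
    and  = unique(unlist(lapply(x$parts, ce_property_ids))),
    character(0)
  )
}

# Variable names mentioned in an expression (template patterns only).
ce_var_names <- function(x) {
  switch(x$type,
    var  = x$name,
    some = ce_var_names(x$filler),
    and  = unique(unlist(lapply(x$parts, ce_var_names))),
    character(0)
  )
}

#' @export
print.class_expression <- function(x, ...) {
  cat("<class_expression> ", ce_key(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.class_expression <- function(x, ...) ce_key(x)

# Conversion to/from plain lists for JSON persistence of queued requests.
ce_to_list <- function(x) {
  switch(x$type,
    named = list(type = "named", id = x$id),
    some  = list(type = "some", property = x$property,
                 filler = ce_to_list(x$filler)),
    and   = list(type = "and", parts = lapply(x$parts, ce_to_list)),
    stop("cannot serialize expression type: ", x$type)
  )
}

ce_from_list <- function(x) {
  switch(x$type,
    named = ce_named(x$id),
    some  = ce_some(x$property, ce_from_list(x$filler)),
    and   = ce_and(lapply(x$parts, ce_from_list)),
    stop("cannot deserialize expression type: ", x$type)
  )
}
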