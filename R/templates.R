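#' Parse a template logical pattern
#'
#' Patterns follow the compact genus-differentia syntax used in
#' cross-product template catalogues:
#'
#' ```
#' expr     := conjunct (" and " conjunct)*
#' conjunct := CURIE | 'class label' | relation-term | "[" conjunct "]"
#' relation-term := 'relation label' " some " (CURIE | ?VAR | 'class label')
#' ```
#'
#' e.g. `"GO:0006810 and 'exports' some ?X"`. Bracketed conjuncts are
#' optional: they are dropped at instantiation when their variable is left
#' unbound. Quoted relation labels are resolved against `relation_map`
#' (label to property id); quoted class labels are resolved against the
#' loaded ontologies at instantiation time.
#'
#' @param text the pattern string.
#' @param relation_map named character vector or list mapping quoted
#'   relation labels to property ids.
#' @return a [class_expression] whose leaves may be variables; optional
#'   conjuncts carry an `optional` flag.
#' @export
parse_pattern <- function(text, relation_map) {
  conj_texts <- split_top_level(text)
  if (!length(conj_texts)) stop("empty pattern")
  parts <- lapply(conj_texts, function(ct) {
    ct <- trimws(ct)
    optional <- FALSE
    if (startsWith(ct, "[") && endsWith(ct, "]")) {
      optional <- TRUE
      ct <- trimws(substr(ct, 2L, nchar(ct) - 1L))
      ct <- trimws(sub("^and\\s+", "", ct))
    }
    part <- parse_conjunct(ct, relation_map)
    part$optional <- optional
    part
  })
  if (length(parts) == 1L) parts[[1L]] else new_ce("and", list(parts = parts))
}

# Split a pattern into top-level conjuncts. Conjuncts are separated by
# " and " outside quotes; a bracketed optional group "[and ... ]" is a
# conjunct of its own (its leading "and" lives inside the brackets).
split_top_level <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  out <- character(0); buf <- character(0)
  flush <- function() {
    piece <- trimws(paste(buf, collapse = ""))
    if (nzchar(piece)) out <<- c(out, piece)
    buf <<- character(0)
  }
  in_quote <- FALSE; depth <- 0L
  k <- 1L
  while (k <= length(chars)) {
    ch <- chars[k]
    if (ch == "'") in_quote <- !in_quote
    if (!in_quote && depth == 0L && ch == "[") {
      flush(); depth <- 1L; buf <- c(buf, ch); k <- k + 1L; next
    }
    if (!in_quote && depth > 0L) {
      if (ch == "[") depth <- depth + 1L
      if (ch == "]") {
        depth <- depth - 1L
        if (depth == 0L) {
          buf <- c(buf, ch); flush(); k <- k + 1L; next
        }
      }
      buf <- c(buf, ch); k <- k + 1L; next
    }
    if (!in_quote && depth == 0L && ch == " " &&
        k + 4L <= length(chars) &&
        identical(paste(chars[k:(k + 4L)], collapse = ""), " and ")) {
      flush(); k <- k + 5L; next
    }
    buf <- c(buf, ch); k <- k + 1L
  }
  flush()
  out
}

parse_conjunct <- function(ct, relation_map) {
  if (startsWith(ct, "'")) {
    close <- regexpr("'", substr(ct, 2L, nchar(ct)), fixed = TRUE)
    if (close < 0) stop("unterminated quoted label in pattern: ", ct)
    label <- substr(ct, 2L, close)
    rest <- trimws(substr(ct, close + 2L, nchar(ct)))
    if (!nzchar(rest)) return(ce_label(label))
    if (!startsWith(rest, "some ")) {
      stop("expected 'some' after relation label in pattern: ", ct)
    }
    pid <- relation_map[[label]]
    if (is.null(pid)) stop("unknown relation label in pattern: '", label, "'")
    return(ce_some(pid, parse_filler(trimws(substr(rest, 6L, nchar(rest))))))
  }
  if (startsWith(ct, "?")) return(ce_var(substr(ct, 2L, nchar(ct))))
  if (grepl("^[^:[:space:]]+:[^:[:space:]]+$", ct)) return(ce_named(ct))
  stop("cannot parse pattern conjunct: ", ct)
}

parse_filler <- function(tok) {
  if (startsWith(tok, "?")) return(ce_var(substr(tok, 2L, nchar(tok))))
  if (startsWith(tok, "'") && endsWith(tok, "'")) {
    return(ce_label(substr(tok, 2L, nchar(tok) - 1L)))
  }
  if (grepl("^[^:[:space:]]+:[^:[:space:]]+$", tok)) return(ce_named(tok))
  stop("cannot parse existential filler: ", tok)
}

#' Load a template catalogue
#'
#' Reads a YAML template configuration: a `relations` map (quoted relation
#' label to property id), named `subsets` (subset name to root class ids),
#' and a `templates` list. Each template declares its input fields (`class`,
#' `text` or `xref_list` kind; class fields name the subsets whose closure
#' restricts them), a logical `pattern`, a `name_pattern` and `def_pattern`
#' with `[V]` / `[V.id]` placeholders and `{...}` optional segments, and
#' optional `synonym_rules`. A required `ref` literature-reference field is
#' added implicitly when a template declares no `xref_list` field.
#'
#' @param config path to the YAML file, or an already-parsed list.
#' @return a `template_set`: list with `templates` (named list of
#'   `template_spec`), `relations`, and `subsets`.
#' @export
load_templates <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  relations <- cfg$relations
  if (is.null(relations)) relations <- list()
  subsets <- lapply(cfg$subsets %||% list(), unlist)

  templates <- list()
  for (tc in cfg$templates %||% list()) {
    if (is.null(tc$name) || !nzchar(tc$name)) stop("template without a name")
    if (!is.null(templates[[tc$name]])) {
      stop("duplicate template name: ", tc$name)
    }
    fields <- lapply(tc$fields %||% list(), function(f) {
      list(name = f$name,
           kind = f$kind %||% "class",
           required = !isFALSE(f$required),
           subsets = unlist(f$subsets) %||% character(0))
    })
    names(fields) <- vapply(fields, function(f) f$name, "")
    if (anyDuplicated(names(fields))) {
      stop("template ", tc$name, ": duplicate field names")
    }
    if (!any(vapply(fields, function(f) f$kind == "xref_list", logical(1)))) {
      fields$ref <- list(name = "ref", kind = "xref_list", required = TRUE,
                         subsets = character(0))
    }
    class_fields <- Filter(function(f) f$kind == "class", fields)
    if (length(class_fields) < 1L || length(class_fields) > 3L) {
      stop("template ", tc$name, ": needs between 1 and 3 class fields, has ",
           length(class_fields))
    }
    for (f in class_fields) {
      if (!length(f$subsets)) {
        stop("template ", tc$name, ": class field ", f$name,
             " needs at least one subset root")
      }
    }
    pattern <- parse_pattern(tc$pattern, relations)
    declared <- names(fields)
    used <- unique(c(ce_var_names(pattern),
                     placeholder_fields(tc$name_pattern),
                     placeholder_fields(tc$def_pattern)))
    missing <- setdiff(used, declared)
    if (length(missing)) {
      stop("template ", tc$name, ": undeclared variable(s): ",
           paste(missing, collapse = ", "))
    }
    syn_rules <- lapply(tc$synonym_rules %||% list(), function(r) {
      list(field = r$field, scope = r$scope %||% "EXACT",
           pattern = r$pattern)
    })
    templates[[tc$name]] <- structure(
      list(name = tc$name, namespace = tc$namespace %||% "",
           fields = fields, pattern = pattern, pattern_text = tc$pattern,
           name_pattern = tc$name_pattern %||% "",
           def_pattern = tc$def_pattern %||% "",
           synonym_rules = syn_rules),
      class = "template_spec")
  }
  structure(list(templates = templates, relations = relations,
                 subsets = subsets),
            class = "template_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

placeholder_fields <- function(pattern) {
  if (is.null(pattern) || !nzchar(pattern)) return(character(0))
  m <- gregexpr("\\[([A-Za-z][A-Za-z0-9_]*)(\\.id)?\\]", pattern)[[1L]]
  if (m[1L] < 0) return(character(0))
  hits <- regmatches(pattern, gregexpr(
    "\\[([A-Za-z][A-Za-z0-9_]*)(\\.id)?\\]", pattern))[[1L]]
  unique(sub("\\.id$", "", sub("^\\[", "", sub("\\]$", "", hits))))
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d templates, %d relation labels, %d subsets\n",
              length(x$templates), length(x$relations), length(x$subsets)))
  invisible(x)
}

#' @export
print.template_spec <- function(x, ...) {
  cls <- Filter(function(f) f$kind == "class", x$fields)
  cat("<template_spec> ", x$name, "\n", sep = "")
  cat("  pattern: ", x$pattern_text, "\n", sep = "")
  cat("  class fields: ",
      paste(vapply(cls, function(f) {
        paste0(f$name, ":", paste(f$subsets, collapse = "+"))
      }, ""), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Resolve a field's subset names to root class ids.
field_roots <- function(field, template_set) {
  roots <- character(0)
  for (s in field$subsets) {
    r <- template_set$subsets[[s]]
    roots <- c(roots, if (is.null(r)) s else r)   # a CURIE is its own root
  }
  unique(roots)
}

#' Validate a binding against a template
#'
#' Checks that every required field is bound, that class-valued fields
#' resolve in the loaded ontologies and fall inside the reasoner-derived
#' subclass closure of their subset roots, and that literature references
#' have CURIE shape (`PREFIX:value`). Failures are returned as data, not
#' thrown.
#'
#' @param template a `template_spec`.
#' @param binding named list mapping field names to values (class id
#'   strings, free text, or character vectors for `xref_list` fields).
#' @param ontologies an `obo_ontology` or `el_reasoner_handle`.
#' @param template_set the `template_set` the template came from (for subset
#'   root resolution).
#' @return character vector of human-readable failures; empty when valid.
#' @export
validate_binding <- function(template, binding, ontologies, template_set) {
  stopifnot(inherits(template, "template_spec"))
  ont <- as_ontology(ontologies)
  failures <- character(0)
  fail <- function(...) failures <<- c(failures, paste0(...))

  for (f in template$fields) {
    v <- binding[[f$name]]
    if (is.null(v) || !length(v) || all(!nzchar(v))) {
      if (f$required) fail("missing required field: ", f$name)
      next
    }
    if (f$kind == "class") {
      if (is.null(ont$terms[[v]])) {
        fail("field ", f$name, ": unknown class id ", v)
        next
      }
      roots <- field_roots(f, template_set)
      known <- roots[vapply(roots, function(r) !is.null(ont$terms[[r]]),
                            logical(1))]
      if (!length(known)) {
        fail("field ", f$name, ": no subset root resolves (",
             paste(roots, collapse = ", "), ")")
        next
      }
      if (!v %in% subclass_closure(ontologies, known)) {
        fail("field ", f$name, ": class ", v,
             " is outside the allowed subset (roots ",
             paste(known, collapse = ", "), ")")
      }
    } else if (f$kind == "xref_list") {
      bad <- v[!grepl("^[A-Za-z][A-Za-z0-9_.-]*:\\S+$", v)]
      for (b in bad) fail("field ", f$name, ": malformed reference '", b, "'")
    }
  }
  failures
}

#' Instantiate a candidate term from a template and binding
#'
#' Grounds the logical pattern (substituting bound classes for variables,
#' resolving quoted class labels, and dropping optional conjuncts whose
#' variable is unbound), fills the label and definition text patterns, and
#' generates synonyms by applying each synonym rule to every synonym of the
#' rule's bound class. [validate_binding()] must have returned no failures.
#'
#' @inheritParams validate_binding
#' @return a `candidate_term`: label, definition, def_xrefs, synonyms,
#'   grounded logical_def, namespace.
#' @export
instantiate <- function(template, binding, ontologies, template_set) {
  failures <- validate_binding(template, binding, ontologies, template_set)
  if (length(failures)) {
    stop(errorCondition(
      paste0("binding fails validation: ", paste(failures, collapse = "; ")),
      failures = failures,
      class = c("termforge_invalid_binding", "termforge_error")))
  }
  ont <- as_ontology(ontologies)
  logical_def <- ground_pattern(template$pattern, binding, ont)

  label <- subst_text(template$name_pattern, template, binding, ont)
  definition <- subst_text(template$def_pattern, template, binding, ont)

  synonyms <- list()
  for (rule in template$synonym_rules) {
    v <- binding[[rule$field]]
    if (is.null(v)) next
    src <- get_term(ont, v)
    for (s in src$synonyms) {
      text <- gsub(paste0("[", rule$field, "]"), s$text, rule$pattern,
                   fixed = TRUE)
      synonyms[[length(synonyms) + 1L]] <- list(text = text,
                                                scope = rule$scope)
    }
  }
  xref_field <- Filter(function(f) f$kind == "xref_list", template$fields)
  def_xrefs <- unlist(lapply(names(xref_field),
                             function(nm) binding[[nm]])) %||% character(0)

  structure(
    list(label = label, definition = definition,
         def_xrefs = as.character(def_xrefs), synonyms = synonyms,
         logical_def = logical_def, namespace = template$namespace,
         told_parents = character(0), relationships = list(),
         created_by = "", creation_date = ""),
    class = "candidate_term")
}

#' @export
print.candidate_term <- function(x, ...) {
  cat("<candidate_term> ", x$label, "\n", sep = "")
  if (!is.null(x$logical_def)) {
    cat("  logical_def: ", ce_key(x$logical_def), "\n", sep = "")
  }
  cat("  definition: ", x$definition, "\n", sep = "")
  invisible(x)
}

ground_pattern <- function(pattern, binding, ont) {
  ground1 <- function(x) {
    switch(x$type,
      named = ce_named(x$id),
      label = ce_named(resolve_label(ont, x$text)),
      var = {
        v <- binding[[x$name]]
        if (is.null(v)) NULL else ce_named(v)
      },
      some = {
        f <- ground1(x$filler)
        if (is.null(f)) NULL else ce_some(x$property, f)
      },
      and = stop("nested conjunction in pattern"),
      stop("unexpected pattern node: ", x$type)
    )
  }
  parts <- if (pattern$type == "and") pattern$parts else list(pattern)
  grounded <- list()
  for (p in parts) {
    g <- ground1(p)
    if (is.null(g)) {
      if (!isTRUE(p$optional)) {
        stop("unbound non-optional variable in pattern: ",
             paste(ce_var_names(p), collapse = ", "))
      }
      next
    }
    grounded[[length(grounded) + 1L]] <- g
  }
  if (length(grounded) == 1L) grounded[[1L]] else ce_and(grounded)
}

# Fill [V] / [V.id] placeholders; `{...}` optional segments are dropped when
# any referenced field inside is unbound.
subst_text <- function(pattern, template, binding, ont) {
  if (is.null(pattern) || !nzchar(pattern)) return("")
  out <- pattern
  # optional segments
  repeat {
    m <- regexpr("\\{[^{}]*\\}", out)
    if (m < 0) break
    seg <- substr(out, m + 1L, m + attr(m, "match.length") - 2L)
    flds <- placeholder_fields(seg)
    keep <- all(vapply(flds, function(f) !is.null(binding[[f]]), logical(1)))
    replacement <- if (keep) seg else ""
    out <- paste0(substr(out, 1L, m - 1L), replacement,
                  substr(out, m + attr(m, "match.length"), nchar(out)))
  }
  for (f in placeholder_fields(out)) {
    v <- binding[[f]]
    if (is.null(v)) stop("text pattern references unbound field: ", f)
    kind <- template$fields[[f]]$kind
    text <- if (identical(kind, "class")) get_term(ont, v)$label else
      paste(v, collapse = ", ")
    out <- gsub(paste0("[", f, ".id]"), v[1L], out, fixed = TRUE)
    out <- gsub(paste0("[", f, "]"), text, out, fixed = TRUE)
  }
  out
}
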