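#' Parse an OBO 1.4 document
#'
#' Reads the OBO flat-file subset used by GO-style ontologies: a header
#' (`format-version`, `ontology`), `[Term]` stanzas with tags `id, name,
#' namespace, def, comment, synonym, is_a, relationship, intersection_of,
#' disjoint_from, is_obsolete, created_by, creation_date`, and `[Typedef]`
#' stanzas with `id, name, is_a, is_transitive`. Unknown tags inside a stanza
#' are preserved verbatim and re-emitted on write, so round-trips are
#' lossless without supporting all of OBO 1.4.
#'
#' A stanza with exactly one plain `intersection_of: <genus>` line and one or
#' more `intersection_of: <relation> <filler>` lines yields a
#' genus-differentia logical definition
#' `Conjunction(Named(genus), Existential(relation, Named(filler)), ...)`.
#'
#' References to unknown class ids are load-time errors, unless the
#' reference's CURIE prefix appears in `external_prefixes`, in which case a
#' stub term is auto-created (mirroring multi-ontology loading without
#' implementing imports). `is_a` links pointing at obsolete terms raise a
#' warning.
#'
#' @param text the document as a single string or a character vector of
#'   lines.
#' @param external_prefixes CURIE prefixes for which dangling references
#'   auto-create stub terms instead of erroring.
#' @return an `obo_ontology`.
#' @seealso [write_obo()], [read_obo()]
#' @export
parse_obo <- function(text, external_prefixes = character(0)) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(text)
  }
  # strip trailing "!" comments (OBO line comments) outside quoted strings
  lines <- vapply(lines, strip_obo_comment, "", USE.NAMES = FALSE)

  ont <- ontology(format_tag = "", ontology_tag = "")
  n <- length(lines)
  i <- 1L

  # ---- header ----
  while (i <= n && !grepl("^\\[", lines[i])) {
    ln <- trimws(lines[i])
    if (nzchar(ln)) {
      tv <- split_tag(ln, i)
      if (tv$tag == "format-version") {
        ont$format_tag <- tv$value
      } else if (tv$tag == "ontology") {
        ont$ontology_tag <- tv$value
      } else {
        ont$header_extra <- c(ont$header_extra, ln)
      }
    }
    i <- i + 1L
  }

  # ---- stanzas ----
  pending_disjoint <- list()
  while (i <= n) {
    header <- trimws(lines[i])
    if (!header %in% c("[Term]", "[Typedef]")) {
      obo_syntax_error(i, paste0("unsupported stanza: ", header))
    }
    start <- i
    i <- i + 1L
    tags <- list()   # list of list(tag=, value=, line=)
    while (i <= n && !grepl("^\\[", lines[i])) {
      ln <- trimws(lines[i])
      if (nzchar(ln)) {
        tv <- split_tag(ln, i)
        tags[[length(tags) + 1L]] <- c(tv, list(line = i))
      }
      i <- i + 1L
    }
    if (identical(header, "[Term]")) {
      parsed <- parse_term_stanza(tags, start)
      if (!is.null(ont$terms[[parsed$term$id]])) {
        obo_syntax_error(start, paste0("duplicate term id: ", parsed$term$id))
      }
      ont$terms[[parsed$term$id]] <- parsed$term
      pending_disjoint <- c(pending_disjoint, parsed$disjoint)
    } else {
      prop <- parse_typedef_stanza(tags, start)
      if (!is.null(ont$properties[[prop$id]])) {
        obo_syntax_error(start, paste0("duplicate typedef id: ", prop$id))
      }
      ont$properties[[prop$id]] <- prop
    }
  }

  for (dp in pending_disjoint) ont <- ont_add_disjoint(ont, dp[1L], dp[2L])

  validate_ontology(ont, external_prefixes)
}

#' @param path path to an OBO file.
#' @rdname parse_obo
#' @export
read_obo <- function(path, external_prefixes = character(0)) {
  parse_obo(readLines(path, warn = FALSE), external_prefixes)
}

strip_obo_comment <- function(ln) {
  # a "!" starts a comment unless inside a double-quoted string
  chars <- strsplit(ln, "", fixed = TRUE)[[1L]]
  in_quote <- FALSE
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch == "\"" && (k == 1L || chars[k - 1L] != "\\")) in_quote <- !in_quote
    if (ch == "!" && !in_quote) return(trimws(substr(ln, 1L, k - 1L)))
  }
  ln
}

split_tag <- function(ln, lineno) {
  m <- regexpr(":", ln, fixed = TRUE)
  if (m < 0) obo_syntax_error(lineno, paste0("expected 'tag: value' line: ", ln))
  list(tag = substr(ln, 1L, m - 1L),
       value = trimws(substr(ln, m + 1L, nchar(ln))))
}

obo_syntax_error <- function(lineno, msg) {
  stop(errorCondition(sprintf("OBO syntax error at line %d: %s", lineno, msg),
                      class = c("termforge_obo_syntax", "termforge_error")))
}

term_tags <- c("id", "name", "namespace", "def", "comment", "synonym",
               "is_a", "relationship", "intersection_of", "disjoint_from",
               "is_obsolete", "created_by", "creation_date")

parse_term_stanza <- function(tags, start) {
  id <- NULL; label <- ""; namespace <- ""; definition <- ""
  def_xrefs <- character(0); comment <- ""; synonyms <- list()
  parents <- character(0); rels <- list(); inter <- list()
  obsolete <- FALSE; created_by <- ""; creation_date <- ""
  extra <- character(0); disjoint <- list()

  for (tv in tags) {
    tag <- tv$tag; value <- tv$value; ln <- tv$line
    if (!tag %in% term_tags) {
      extra <- c(extra, paste0(tag, ": ", value))
      next
    }
    switch(tag,
      id = { id <- value },
      name = { label <- value },
      namespace = { namespace <- value },
      comment = { comment <- value },
      created_by = { created_by <- value },
      creation_date = { creation_date <- value },
      is_obsolete = { obsolete <- identical(value, "true") },
      def = {
        parsed <- parse_quoted(value, ln)
        definition <- parsed$text
        def_xrefs <- parse_xref_list(parsed$rest, ln)
      },
      synonym = {
        parsed <- parse_quoted(value, ln)
        rest <- trimws(parsed$rest)
        scope <- sub("\\s.*$", "", rest)
        if (!scope %in% c("EXACT", "BROAD", "NARROW", "RELATED")) {
          obo_syntax_error(ln, paste0("bad synonym scope: ", rest))
        }
        synonyms[[length(synonyms) + 1L]] <- list(text = parsed$text,
                                                  scope = scope)
      },
      is_a = { parents <- c(parents, first_token(value)) },
      disjoint_from = {
        disjoint[[length(disjoint) + 1L]] <- c(NA_character_,
                                               first_token(value))
      },
      relationship = {
        toks <- strsplit(value, "\\s+")[[1L]]
        if (length(toks) < 2L) {
          obo_syntax_error(ln, "relationship needs '<property> <target>'")
        }
        rels[[length(rels) + 1L]] <- list(property = toks[1L],
                                          target = toks[2L])
      },
      intersection_of = {
        toks <- strsplit(value, "\\s+")[[1L]]
        inter[[length(inter) + 1L]] <-
          if (length(toks) == 1L) list(genus = toks[1L], line = ln)
          else list(property = toks[1L], filler = toks[2L], line = ln)
      }
    )
  }
  if (is.null(id)) obo_syntax_error(start, "[Term] stanza without id")

  logical_def <- NULL
  if (length(inter)) {
    genus <- Filter(function(x) !is.null(x$genus), inter)
    diffs <- Filter(function(x) is.null(x$genus), inter)
    if (length(genus) != 1L || length(diffs) < 1L) {
      obo_syntax_error(start, paste0(
        "term ", id, ": intersection_of needs exactly one genus and at ",
        "least one '<relation> <filler>' differentia"))
    }
    logical_def <- ce_and(c(
      list(ce_named(genus[[1L]]$genus)),
      lapply(diffs, function(d) ce_some(d$property, ce_named(d$filler)))))
  }

  if (obsolete) {
    # spec invariant: obsolete terms carry no axioms
    parents <- character(0); rels <- list(); logical_def <- NULL
  }

  term <- term_record(
    id = id, label = label, namespace = namespace, definition = definition,
    def_xrefs = def_xrefs, comment = comment, synonyms = synonyms,
    told_parents = sort(unique(parents)), relationships = rels,
    logical_def = logical_def, obsolete = obsolete, created_by = created_by,
    creation_date = creation_date, extra = extra)
  disjoint <- lapply(disjoint, function(d) c(id, d[2L]))
  list(term = term, disjoint = disjoint)
}

parse_typedef_stanza <- function(tags, start) {
  id <- NULL; label <- ""; parents <- character(0); transitive <- FALSE
  for (tv in tags) {
    switch(tv$tag,
      id = { id <- tv$value },
      name = { label <- tv$value },
      is_a = { parents <- c(parents, first_token(tv$value)) },
      is_transitive = { transitive <- identical(tv$value, "true") },
      obo_syntax_error(tv$line, paste0("unsupported [Typedef] tag: ", tv$tag))
    )
  }
  if (is.null(id)) obo_syntax_error(start, "[Typedef] stanza without id")
  property_record(id = id, label = label, parents = sort(unique(parents)),
                  transitive = transitive)
}

first_token <- function(value) strsplit(trimws(value), "\\s+")[[1L]][1L]

parse_quoted <- function(value, lineno) {
  if (!startsWith(value, "\"")) {
    obo_syntax_error(lineno, paste0("expected quoted string: ", value))
  }
  chars <- strsplit(value, "", fixed = TRUE)[[1L]]
  out <- character(0)
  k <- 2L
  while (k <= length(chars)) {
    ch <- chars[k]
    if (ch == "\\" && k < length(chars)) {
      out <- c(out, chars[k + 1L]); k <- k + 2L; next
    }
    if (ch == "\"") {
      return(list(text = paste(out, collapse = ""),
                  rest = substr(value, k + 1L, nchar(value))))
    }
    out <- c(out, ch); k <- k + 1L
  }
  obo_syntax_error(lineno, "unterminated quoted string")
}

parse_xref_list <- function(rest, lineno) {
  rest <- trimws(rest)
  if (!nzchar(rest)) return(character(0))
  if (!startsWith(rest, "[") || !endsWith(rest, "]")) {
    obo_syntax_error(lineno, paste0("expected [xref, ...] list: ", rest))
  }
  inner <- trimws(substr(rest, 2L, nchar(rest) - 1L))
  if (!nzchar(inner)) return(character(0))
  trimws(strsplit(inner, ",", fixed = TRUE)[[1L]])
}

validate_ontology <- function(ont, external_prefixes) {
  # label uniqueness among non-obsolete terms
  labs <- ont_labels(ont)
  labs <- labs[nzchar(labs)]
  dup <- labs[duplicated(labs)]
  if (length(dup)) {
    stop(errorCondition(
      paste0("duplicate labels among non-obsolete terms: ",
             paste(unique(dup), collapse = ", ")),
      class = c("termforge_duplicate_label", "termforge_error")))
  }

  # collect class references, auto-stub external prefixes, error otherwise
  refs <- list()
  for (t in ont$terms) {
    for (p in t$told_parents) refs[[length(refs) + 1L]] <- c(t$id, p, "is_a")
    for (r in t$relationships) {
      refs[[length(refs) + 1L]] <- c(t$id, r$target, "relationship")
      check_property_known(ont, r$property, t$id)
    }
    if (!is.null(t$logical_def)) {
      for (cid in ce_class_ids(t$logical_def)) {
        refs[[length(refs) + 1L]] <- c(t$id, cid, "intersection_of")
      }
      for (pid in ce_property_ids(t$logical_def)) {
        check_property_known(ont, pid, t$id)
      }
    }
  }
  for (dp in ont$disjoint_pairs) {
    for (cid in dp) refs[[length(refs) + 1L]] <- c(dp[1L], cid, "disjoint_from")
  }

  for (ref in refs) {
    target <- ref[2L]
    if (is.null(ont$terms[[target]])) {
      if (curie_prefix(target) %in% external_prefixes) {
        ont$terms[[target]] <- term_record(target, label = target, stub = TRUE)
      } else {
        stop(errorCondition(
          paste0("dangling reference: term ", ref[1L], " ", ref[3L], " -> ",
                 target),
          class = c("termforge_dangling_ref", "termforge_error")))
      }
    }
  }
  for (ref in refs) {
    if (ref[3L] == "is_a" && isTRUE(ont$terms[[ref[2L]]]$obsolete)) {
      warning("term ", ref[1L], " has an is_a link to obsolete term ",
              ref[2L], call. = FALSE)
    }
  }
  # order terms by id for deterministic downstream iteration
  if (length(ont$terms)) ont$terms <- ont$terms[order(names(ont$terms))]
  if (length(ont$properties)) {
    ont$properties <- ont$properties[order(names(ont$properties))]
  }
  ont
}

check_property_known <- function(ont, pid, owner) {
  if (is.null(ont$properties[[pid]])) {
    stop(errorCondition(
      paste0("term ", owner, " references undeclared property: ", pid),
      class = c("termforge_dangling_ref", "termforge_error")))
  }
}

#' Serialize an ontology to OBO format
#'
#' Serialization is deterministic: stanzas are sorted by id ([Term] first,
#' then [Typedef]) and tags are written in a fixed canonical order, so two
#' serializations of the same ontology value are byte-identical and
#' `parse_obo(write_obo(o))` is structurally equal to `o`.
#'
#' @param ont an `obo_ontology`.
#' @return the document as a single string.
#' @export
write_obo <- function(ont) {
  stopifnot(inherits(ont, "obo_ontology"))
  out <- character(0)
  emit <- function(...) out[[length(out) + 1L]] <<- paste0(...)

  emit("format-version: ",
       if (nzchar(ont$format_tag)) ont$format_tag else "1.4")
  if (nzchar(ont$ontology_tag)) emit("ontology: ", ont$ontology_tag)
  for (h in ont$header_extra) emit(h)

  # disjoint_from lines live in the stanza of the pair's first id
  disjoint_by_term <- list()
  for (dp in ont$disjoint_pairs) {
    disjoint_by_term[[dp[1L]]] <- sort(c(disjoint_by_term[[dp[1L]]], dp[2L]))
  }

  for (id in sort(names(ont$terms))) {
    t <- ont$terms[[id]]
    emit("")
    emit("[Term]")
    emit("id: ", t$id)
    if (nzchar(t$label)) emit("name: ", t$label)
    if (nzchar(t$namespace)) emit("namespace: ", t$namespace)
    if (nzchar(t$definition)) {
      emit("def: \"", escape_quoted(t$definition), "\" [",
           paste(t$def_xrefs, collapse = ", "), "]")
    }
    if (nzchar(t$comment)) emit("comment: ", t$comment)
    if (length(t$synonyms)) {
      syn_lines <- vapply(t$synonyms, function(s) {
        paste0("synonym: \"", escape_quoted(s$text), "\" ", s$scope, " []")
      }, "")
      for (s in sort(syn_lines)) emit(s)
    }
    if (!t$obsolete) {
      for (p in sort(unique(t$told_parents))) emit("is_a: ", p)
      if (!is.null(t$logical_def)) {
        parts <- t$logical_def$parts
        genus <- Filter(function(p) p$type == "named", parts)
        diffs <- Filter(function(p) p$type == "some", parts)
        emit("intersection_of: ", genus[[1L]]$id)
        diff_lines <- vapply(diffs, function(d) {
          paste0("intersection_of: ", d$property, " ", d$filler$id)
        }, "")
        for (d in sort(diff_lines)) emit(d)
      }
      if (length(t$relationships)) {
        rel_lines <- vapply(t$relationships, function(r) {
          paste0("relationship: ", r$property, " ", r$target)
        }, "")
        for (r in sort(unique(rel_lines))) emit(r)
      }
      for (d in disjoint_by_term[[t$id]]) emit("disjoint_from: ", d)
    }
    if (t$obsolete) emit("is_obsolete: true")
    if (nzchar(t$created_by)) emit("created_by: ", t$created_by)
    if (nzchar(t$creation_date)) emit("creation_date: ", t$creation_date)
    for (x in t$extra) emit(x)
  }

  for (id in sort(names(ont$properties))) {
    p <- ont$properties[[id]]
    emit("")
    emit("[Typedef]")
    emit("id: ", p$id)
    if (nzchar(p$label)) emit("name: ", p$label)
    for (sp in sort(unique(p$parents))) emit("is_a: ", sp)
    if (p$transitive) emit("is_transitive: true")
  }

  paste0(paste(out, collapse = "\n"), "\n")
}

escape_quoted <- function(x) gsub("\"", "\\\\\"", x)

#' @param path destination file path; written atomically
#'   (temp-file-then-rename).
#' @rdname write_obo
#' @export
write_obo_file <- function(ont, path) {
  txt <- write_obo(ont)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writeLines(sub("\n$", "", txt), tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Structural equality of two ontologies
#'
#' Two ontologies are structurally equal when their canonical OBO
#' serializations are identical (stub flags do not affect serialization).
#'
#' @param a,b `obo_ontology` objects.
#' @return logical.
#' @export
ont_equal <- function(a, b) identical(write_obo(a), write_obo(b))
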