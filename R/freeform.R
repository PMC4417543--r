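#' Similar-label collision warnings
#'
#' Before a free-form class request is queued, its label is compared
#' (case-folded) against every label and synonym of every non-obsolete
#' class. A warning is raised when the edit distance is at most 2, or when
#' one string is a substring of the other and their lengths differ by at
#' most 3. An identical string is an `exact` warning (distance 0); anything
#' else is `near`. The classic example: requesting 'omegasome' against an
#' ontology containing 'megasome' yields one near warning at distance 1.
#'
#' @param label the proposed class label.
#' @param ontologies an `obo_ontology` or `el_reasoner_handle`.
#' @return a data.frame sorted by distance then class id, with columns
#'   `existing_id`, `existing_text`, `matched_field` (label/synonym),
#'   `distance`, `kind` (exact/near).
#' @export
similar_label_warnings <- function(label, ontologies) {
  ont <- as_ontology(ontologies)
  q <- tolower(trimws(label))
  ids <- character(0); texts <- character(0); fields <- character(0)
  for (t in ont$terms) {
    if (t$obsolete) next
    if (nzchar(t$label)) {
      ids <- c(ids, t$id); texts <- c(texts, t$label)
      fields <- c(fields, "label")
    }
    for (s in t$synonyms) {
      ids <- c(ids, t$id); texts <- c(texts, s$text)
      fields <- c(fields, "synonym")
    }
  }
  empty <- data.frame(existing_id = character(0),
                      existing_text = character(0),
                      matched_field = character(0),
                      distance = integer(0), kind = character(0),
                      stringsAsFactors = FALSE)
  if (!length(ids)) return(empty)
  low <- tolower(texts)
  dist <- as.integer(utils::adist(q, low))
  substr_hit <- (grepl(q, low, fixed = TRUE) |
                   vapply(low, function(x) grepl(x, q, fixed = TRUE),
                          logical(1))) &
    abs(nchar(low) - nchar(q)) <= 3L
  warn <- dist <= 2L | substr_hit
  if (!any(warn)) return(empty)
  out <- data.frame(
    existing_id = ids[warn], existing_text = texts[warn],
    matched_field = fields[warn], distance = dist[warn],
    kind = ifelse(dist[warn] == 0L, "exact", "near"),
    stringsAsFactors = FALSE)
  out <- out[order(out$distance, out$existing_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Submit a free-form class request
#'
#' Non-templated requests let experienced curators specify a class directly:
#' label, textual definition, told parents, plain relationships and
#' synonyms, but no equivalence axiom — classification will place the class
#' by its told parents only. Validation extends the templated path with
#' similar-label checking: an exact label/synonym collision always blocks;
#' near collisions block unless `force = TRUE` (the curator dismisses the
#' warning). Free-form requests share the queue, id policy and review/commit
#' path with templated requests, but are guarded by their own allow-list.
#'
#' @param queue a [request_queue()].
#' @param request named list with `label`, `definition`, optional
#'   `def_xrefs`, `told_parents` (at least one), optional `relationships`
#'   (list of `list(property =, target =)`), optional `synonyms`,
#'   `namespace`.
#' @param requester requester identifier (e-mail).
#' @param ontologies an `obo_ontology` or `el_reasoner_handle`.
#' @param policy an [id_policy()].
#' @param force dismiss near-similarity warnings.
#' @param allowed optional allow-list for the free-form path.
#' @param now timestamp override.
#' @return the pending `term_request`.
#' @export
submit_freeform <- function(queue, request, requester, ontologies, policy,
                            force = FALSE, allowed = NULL, now = NULL) {
  check_requester(requester, allowed)
  ont <- as_ontology(ontologies)
  label <- trimws(request$label %||% "")
  if (!nzchar(label)) {
    stop(errorCondition("free-form request needs a non-empty label",
                        class = c("termforge_invalid_binding",
                                  "termforge_error")))
  }
  parents <- as.character(request$told_parents %||% character(0))
  if (!length(parents)) {
    stop(errorCondition("free-form request needs at least one parent",
                        class = c("termforge_invalid_binding",
                                  "termforge_error")))
  }
  for (p in parents) {
    if (is.null(ont$terms[[p]])) {
      stop(errorCondition(paste0("unknown parent class: ", p),
                          class = c("termforge_unknown_id",
                                    "termforge_error")))
    }
  }
  rels <- request$relationships %||% list()
  for (r in rels) {
    if (is.null(ont$properties[[r$property]])) {
      stop(errorCondition(paste0("unknown property: ", r$property),
                          class = c("termforge_unknown_id",
                                    "termforge_error")))
    }
    if (is.null(ont$terms[[r$target]])) {
      stop(errorCondition(paste0("unknown relationship target: ", r$target),
                          class = c("termforge_unknown_id",
                                    "termforge_error")))
    }
  }

  warnings <- similar_label_warnings(label, ont)
  blocking <- warnings[warnings$kind == "exact" | !force, , drop = FALSE]
  if (nrow(blocking)) {
    stop(errorCondition(
      paste0("similar classes already exist: ",
             paste(sprintf("%s ('%s', %s, distance %d)",
                           blocking$existing_id, blocking$existing_text,
                           blocking$kind, blocking$distance),
                   collapse = "; ")),
      warnings = blocking,
      class = c("termforge_similar_label", "termforge_error")))
  }

  assigned <- next_id(policy, ont)
  ts <- now %||% iso_now()
  candidate <- structure(
    list(label = label, definition = request$definition %||% "",
         def_xrefs = as.character(request$def_xrefs %||% character(0)),
         synonyms = request$synonyms %||% list(),
         logical_def = NULL,
         namespace = request$namespace %||% "",
         told_parents = sort(unique(parents)), relationships = rels,
         created_by = requester, creation_date = ts),
    class = "candidate_term")
  # no equivalence axiom, so the reasoner can only place it by told parents
  placement <- structure(
    list(equivalents = character(0), direct_supers = sort(unique(parents)),
         direct_subs = character(0), satisfiable = TRUE,
         ontology_coherent = TRUE),
    class = "placement_result")
  finish_submit(queue, candidate, placement, list(), assigned, requester, ts)
}
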