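#' Build a subset-restricted suggestion index
#'
#' Collects one entry per label and per synonym of every non-obsolete class
#' and tags each entry with every configured subset whose reasoner-derived
#' subclass closure contains the class. The index is an in-memory structure
#' rebuilt on load; autocompletion backends for ontology input fields are
#' desk-scale, so no persistence is needed.
#'
#' @param ontologies an `obo_ontology` or `el_reasoner_handle` (possibly
#'   merging several source ontologies).
#' @param subsets named list mapping subset names to character vectors of
#'   root class ids; roots may live in different source ontologies.
#' @return a `suggestion_index`.
#' @export
build_index <- function(ontologies, subsets = list()) {
  ont <- as_ontology(ontologies)
  closures <- lapply(subsets, function(roots) {
    subclass_closure(ontologies, unlist(roots))
  })
  ids <- character(0); texts <- character(0); sources <- character(0)
  labels <- character(0)
  for (t in ont$terms) {
    if (t$obsolete || !nzchar(t$label)) next
    ids <- c(ids, t$id); texts <- c(texts, t$label)
    sources <- c(sources, "label"); labels <- c(labels, t$label)
    for (s in t$synonyms) {
      ids <- c(ids, t$id); texts <- c(texts, s$text)
      sources <- c(sources, "synonym"); labels <- c(labels, t$label)
    }
  }
  tags <- lapply(ids, function(id) {
    names(closures)[vapply(closures, function(cl) id %in% cl, logical(1))]
  })
  structure(
    list(entries = data.frame(id = ids, text = texts, source = sources,
                              label = labels, stringsAsFactors = FALSE),
         tags = tags, subset_names = names(subsets)),
    class = "suggestion_index")
}

#' @export
print.suggestion_index <- function(x, ...) {
  cat(sprintf("<suggestion_index> %d entries over %d classes; subsets: %s\n",
              nrow(x$entries), length(unique(x$entries$id)),
              paste(x$subset_names, collapse = ", ")))
  invisible(x)
}

#' Ranked term suggestions for a query
#'
#' Case-insensitive lookup over labels and synonyms, ranked by match tier:
#' 1 = whole-label prefix, 2 = prefix of any word in the label,
#' 3 = synonym prefix, 4 = substring anywhere. Ties break by shorter label,
#' then class id, so the ranking is a total deterministic order. When a
#' subset name is given, results are restricted to its closure.
#'
#' @param index a `suggestion_index`.
#' @param query query string; an empty query returns no results.
#' @param subset optional subset name to filter by.
#' @param limit maximum number of results (>= 1).
#' @return data.frame with columns `id`, `label`, `score` (the tier; lower
#'   is better), at most `limit` rows.
#' @export
suggest <- function(index, query, subset = NULL, limit = 10L) {
  stopifnot(inherits(index, "suggestion_index"), limit >= 1L)
  empty <- data.frame(id = character(0), label = character(0),
                      score = integer(0), stringsAsFactors = FALSE)
  if (!nzchar(trimws(query))) return(empty)
  if (!is.null(subset) && !subset %in% index$subset_names) {
    stop(errorCondition(paste0("unknown subset name: ", subset),
                        class = c("termforge_unknown_subset",
                                  "termforge_error")))
  }
  q <- tolower(trimws(query))
  e <- index$entries
  keep <- rep(TRUE, nrow(e))
  if (!is.null(subset)) {
    keep <- vapply(index$tags, function(tg) subset %in% tg, logical(1))
  }
  text <- tolower(e$text)
  tier <- rep(NA_integer_, nrow(e))
  is_sub <- grepl(q, text, fixed = TRUE)
  word_prefix <- vapply(strsplit(text, "[^[:alnum:]]+"), function(w) {
    any(startsWith(w, q))
  }, logical(1))
  lab <- e$source == "label"
  tier[is_sub] <- 4L
  tier[word_prefix & !lab] <- 3L                 # synonym prefix tier
  tier[startsWith(text, q) & !lab] <- 3L
  tier[word_prefix & lab] <- 2L
  tier[startsWith(text, q) & lab] <- 1L
  hit <- keep & !is.na(tier)
  if (!any(hit)) return(empty)
  res <- data.frame(id = e$id[hit], label = e$label[hit],
                    score = tier[hit], stringsAsFactors = FALSE)
  # best tier per class, then deterministic tie-breaking
  res <- res[order(res$score, nchar(res$label), res$id), , drop = FALSE]
  res <- res[!duplicated(res$id), , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, limit)
}
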