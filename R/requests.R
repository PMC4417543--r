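#' Permanent identifier policy
#'
#' New classes receive permanent identifiers immediately at request time,
#' drawn from a customizable pattern and numeric range: `prefix`, zero-padded
#' `width`, and an inclusive integer range reserved for generated classes.
#' Allocations are persisted to a state file (one integer per line, appended
#' before an id is handed out), so no identifier is ever issued twice even
#' across process restarts; ids already present in the loaded ontology count
#' as allocated.
#'
#' @param prefix CURIE prefix, e.g. `"GO"`.
#' @param width digit count for zero-padding.
#' @param range_start,range_end inclusive integer allocation range.
#' @param state_path path of the persisted allocation file.
#' @return an `id_policy`.
#' @export
id_policy <- function(prefix, width, range_start, range_end, state_path) {
  stopifnot(range_start <= range_end, width >= 1)
  structure(list(prefix = prefix, width = width,
                 range_start = as.integer(range_start),
                 range_end = as.integer(range_end),
                 state_path = state_path),
            class = "id_policy")
}

policy_allocated <- function(policy) {
  if (!file.exists(policy$state_path)) return(integer(0))
  as.integer(readLines(policy$state_path, warn = FALSE))
}

#' Allocate the next permanent identifier
#'
#' Returns the smallest unallocated integer in the policy range (skipping
#' ids already present in `ont`), zero-padded and prefixed. The allocation
#' is persisted before the id is returned.
#'
#' @param policy an [id_policy()].
#' @param ont optional `obo_ontology` whose existing ids are treated as
#'   allocated.
#' @return a class id string.
#' @export
next_id <- function(policy, ont = NULL) {
  stopifnot(inherits(policy, "id_policy"))
  taken <- policy_allocated(policy)
  if (!is.null(ont)) {
    fmt <- function(n) sprintf("%s:%0*d", policy$prefix, policy$width, n)
    in_ont <- vapply(policy$range_start:policy$range_end,
                     function(n) !is.null(ont$terms[[fmt(n)]]), logical(1))
    taken <- c(taken, (policy$range_start:policy$range_end)[in_ont])
  }
  free <- setdiff(policy$range_start:policy$range_end, taken)
  if (!length(free)) {
    stop(errorCondition(
      sprintf("identifier range exhausted: %s %d..%d", policy$prefix,
              policy$range_start, policy$range_end),
      class = c("termforge_range_exhausted", "termforge_error")))
  }
  n <- min(free)
  cat(n, "\n", sep = "", file = policy$state_path, append = TRUE)
  sprintf("%s:%0*d", policy$prefix, policy$width, n)
}

#' Persistent request queue
#'
#' The review queue is an append-only event log: one JSON record per line,
#' either a submission (the full request: candidate term, assigned id,
#' placement, rewrites, provenance) or a status-change event. Replaying the
#' log reconstructs the current queue state, which makes the queue
#' crash-tolerant by construction.
#'
#' @param path path of the queue file (created on first append).
#' @return a `request_queue` handle.
#' @export
request_queue <- function(path) {
  structure(list(path = path), class = "request_queue")
}

queue_append <- function(queue, record) {
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, null = "null")
  cat(line, "\n", sep = "", file = queue$path, append = TRUE)
  invisible(queue)
}

#' Load the current queue state
#'
#' @param queue a [request_queue()].
#' @return named list of `term_request` objects keyed by request id.
#' @export
load_queue <- function(queue) {
  stopifnot(inherits(queue, "request_queue"))
  state <- list()
  if (!file.exists(queue$path)) return(state)
  lines <- readLines(queue$path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(state)
  # one batched parse of the whole event log
  records <- jsonlite::fromJSON(
    paste0("[", paste(lines, collapse = ","), "]"),
    simplifyVector = FALSE)
  for (rec in records) {
    key <- as.character(rec$request_id)
    if (identical(rec$type, "submit")) {
      state[[key]] <- request_from_record(rec)
    } else if (identical(rec$type, "status")) {
      req <- state[[key]]
      if (is.null(req)) next
      if (identical(rec$status, "committed")) {
        req$committed <- TRUE
        # an obsoleted request stays obsoleted after its stub is written
        if (!identical(req$status, "obsoleted")) req$status <- "committed"
      } else {
        req$status <- rec$status
      }
      if (!is.null(rec$note) && nzchar(rec$note)) req$review_note <- rec$note
      for (fld in intersect(names(rec$edits %||% list()),
                            c("label", "definition"))) {
        req$candidate[[fld]] <- rec$edits[[fld]]
      }
      if (!is.null(rec$edits$synonyms)) {
        req$candidate$synonyms <- lapply(rec$edits$synonyms, function(s) {
          list(text = s$text, scope = s$scope)
        })
      }
      state[[key]] <- req
    }
  }
  state
}

request_from_record <- function(rec) {
  cand <- rec$candidate
  candidate <- list(
    label = cand$label, definition = cand$definition,
    def_xrefs = as.character(unlist(cand$def_xrefs)),
    synonyms = lapply(cand$synonyms %||% list(), function(s) {
      list(text = s$text, scope = s$scope)
    }),
    logical_def = if (is.null(cand$logical_def)) NULL else
      ce_from_list(cand$logical_def),
    namespace = cand$namespace %||% "",
    told_parents = as.character(unlist(cand$told_parents)),
    relationships = lapply(cand$relationships %||% list(), function(r) {
      list(property = r$property, target = r$target)
    }),
    created_by = cand$created_by %||% "",
    creation_date = cand$creation_date %||% "")
  class(candidate) <- "candidate_term"
  pl <- rec$placement
  placement <- structure(
    list(equivalents = as.character(unlist(pl$equivalents)),
         direct_supers = as.character(unlist(pl$direct_supers)),
         direct_subs = as.character(unlist(pl$direct_subs)),
         satisfiable = isTRUE(pl$satisfiable),
         ontology_coherent = isTRUE(pl$ontology_coherent)),
    class = "placement_result")
  structure(
    list(request_id = rec$request_id, candidate = candidate,
         assigned_id = rec$assigned_id, placement = placement,
         rewrites = lapply(rec$rewrites %||% list(), function(r) {
           list(child = r$child, drop_parent = r$drop_parent,
                add_parent = r$add_parent)
         }),
         requester = rec$requester, submitted_at = rec$submitted_at,
         status = rec$status, review_note = rec$review_note %||% "",
         committed = FALSE),
    class = "term_request")
}

#' @export
print.term_request <- function(x, ...) {
  cat(sprintf("<term_request> #%d %s '%s' [%s] by %s\n", x$request_id,
              x$assigned_id, x$candidate$label, x$status, x$requester))
  invisible(x)
}

request_to_record <- function(req) {
  cand <- req$candidate
  list(
    type = "submit", request_id = req$request_id,
    assigned_id = req$assigned_id, requester = req$requester,
    submitted_at = req$submitted_at, status = req$status,
    candidate = list(
      label = cand$label, definition = cand$definition,
      def_xrefs = as.list(cand$def_xrefs),
      synonyms = cand$synonyms,
      logical_def = if (is.null(cand$logical_def)) NULL else
        ce_to_list(cand$logical_def),
      namespace = cand$namespace,
      told_parents = as.list(cand$told_parents),
      relationships = cand$relationships,
      created_by = cand$created_by, creation_date = cand$creation_date),
    placement = list(
      equivalents = as.list(req$placement$equivalents),
      direct_supers = as.list(req$placement$direct_supers),
      direct_subs = as.list(req$placement$direct_subs),
      satisfiable = req$placement$satisfiable,
      ontology_coherent = req$placement$ontology_coherent),
    rewrites = req$rewrites)
}

next_request_id <- function(state) {
  if (!length(state)) return(1L)
  max(vapply(state, function(r) as.integer(r$request_id), integer(1))) + 1L
}

iso_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Submit a templated class request
#'
#' Runs the full request pipeline: permission check, binding validation,
#' candidate instantiation, and reasoner placement. Submission fails when
#' the hypothetical class is equivalent to an existing named class (the
#' error names the existing id), unsatisfiable, or would make the ontology
#' incoherent. On success a permanent id is allocated, relation rewrites for
#' existing children are computed, provenance is recorded, and a pending
#' request is appended to the queue.
#'
#' @param queue a [request_queue()].
#' @param template a `template_spec`.
#' @param binding named list of field values (see [validate_binding()]).
#' @param requester requester identifier (e-mail).
#' @param ontologies an `obo_ontology` or `el_reasoner_handle`.
#' @param policy an [id_policy()].
#' @param template_set the `template_set` the template belongs to.
#' @param allowed optional character vector of permitted requesters; `NULL`
#'   disables the check.
#' @param now timestamp override (ISO-8601 string), for reproducible logs.
#' @return the pending `term_request`.
#' @export
submit_request <- function(queue, template, binding, requester, ontologies,
                           policy, template_set, allowed = NULL,
                           now = NULL) {
  check_requester(requester, allowed)
  ont <- as_ontology(ontologies)
  failures <- validate_binding(template, binding, ontologies, template_set)
  if (length(failures)) {
    stop(errorCondition(
      paste0("invalid request: ", paste(failures, collapse = "; ")),
      failures = failures,
      class = c("termforge_invalid_binding", "termforge_error")))
  }
  candidate <- instantiate(template, binding, ontologies, template_set)
  placement <- place(ont, candidate$logical_def)
  check_placement(placement)
  assigned <- next_id(policy, ont)
  rewrites <- relation_rewrites_for(ontologies, placement, assigned)
  candidate$created_by <- requester
  candidate$creation_date <- now %||% iso_now()

  finish_submit(queue, candidate, placement, rewrites, assigned, requester,
                candidate$creation_date)
}

check_requester <- function(requester, allowed) {
  if (is.null(requester) || !nzchar(requester)) {
    stop(errorCondition("missing requester identifier",
                        class = c("termforge_unauthorized",
                                  "termforge_error")))
  }
  if (!is.null(allowed) && !requester %in% allowed) {
    stop(errorCondition(
      paste0("requester not authorized: ", requester),
      class = c("termforge_unauthorized", "termforge_error")))
  }
}

check_placement <- function(placement) {
  if (!placement$ontology_coherent) {
    stop(errorCondition(
      "adding the candidate would make the ontology incoherent",
      class = c("termforge_incoherent", "termforge_error")))
  }
  if (!placement$satisfiable) {
    stop(errorCondition(
      "candidate class is unsatisfiable",
      class = c("termforge_unsatisfiable", "termforge_error")))
  }
  if (length(placement$equivalents)) {
    stop(errorCondition(
      paste0("duplicate class: equivalent to existing ",
             paste(placement$equivalents, collapse = ", ")),
      existing_id = placement$equivalents,
      class = c("termforge_duplicate", "termforge_error")))
  }
}

finish_submit <- function(queue, candidate, placement, rewrites, assigned,
                          requester, now) {
  state <- load_queue(queue)
  req <- structure(
    list(request_id = next_request_id(state), candidate = candidate,
         assigned_id = assigned, placement = placement, rewrites = rewrites,
         requester = requester, submitted_at = now, status = "pending",
         review_note = ""),
    class = "term_request")
  queue_append(queue, request_to_record(req))
  req
}

#' Query the lifecycle status of a class id
#'
#' Answers the biocurator-facing question "is this generated id usable
#' yet?": ids of committed or approved requests report `approved`, pending
#' requests `pending`, anything else (including obsoleted requests and ids
#' never seen) `unknown`.
#'
#' @param queue a [request_queue()].
#' @param id a character vector of class ids (the queue is replayed once
#'   for the whole vector).
#' @return for each id one of `"approved"`, `"pending"`, `"unknown"`.
#' @export
request_status <- function(queue, id) {
  state <- load_queue(queue)
  by_id <- character(0)
  for (req in state) {
    by_id[[req$assigned_id]] <- switch(req$status,
                                       committed = , approved = "approved",
                                       pending = "pending",
                                       "unknown")
  }
  out <- unname(by_id[id])
  out[is.na(out)] <- "unknown"
  out
}

#' Review a pending request
#'
#' Reviewers may approve (optionally with textual edits restricted to label,
#' definition and synonyms — the logical definition is immutable at review)
#' or obsolete a request. There is no reject: because the permanent id was
#' issued at submission, obsoletion is the only way to retire a request, and
#' a later commit writes the id as an obsolete stub term so it remains
#' resolvable.
#'
#' @param queue a [request_queue()].
#' @param request_id integer request id.
#' @param action `"approve"` or `"obsolete"`.
#' @param edits optional named list with any of `label`, `definition`,
#'   `synonyms`.
#' @param note review note stored with the request.
#' @return the updated `term_request`.
#' @export
review_request <- function(queue, request_id, action = c("approve",
                                                         "obsolete"),
                           edits = NULL, note = "") {
  action <- match.arg(action)
  state <- load_queue(queue)
  req <- state[[as.character(request_id)]]
  if (is.null(req)) {
    stop(errorCondition(paste0("unknown request id: ", request_id),
                        class = c("termforge_unknown_request",
                                  "termforge_error")))
  }
  ok <- switch(action,
               approve = identical(req$status, "pending"),
               obsolete = req$status %in% c("pending", "approved"))
  if (!ok) {
    stop(errorCondition(
      sprintf("illegal transition: request %d is %s, cannot %s",
              request_id, req$status, action),
      class = c("termforge_illegal_transition", "termforge_error")))
  }
  if (!is.null(edits)) {
    illegal <- setdiff(names(edits), c("label", "definition", "synonyms"))
    if (length(illegal)) {
      stop(errorCondition(
        paste0("review edits may only touch label/definition/synonyms, not: ",
               paste(illegal, collapse = ", ")),
        class = c("termforge_illegal_edit", "termforge_error")))
    }
  }
  new_status <- if (action == "approve") "approved" else "obsoleted"
  queue_append(queue, list(type = "status", request_id = req$request_id,
                           status = new_status, note = note,
                           edits = edits))
  load_queue(queue)[[as.character(request_id)]]
}

#' Commit reviewed requests to the ontology file
#'
#' Processes each selected request separately, in request-id order, the way
#' a per-request version-control commit would: reload the ontology from the
#' file (clean-checkout analogue), re-run the quick checks (assigned id
#' still unused, label still free, still no equivalent named class, still
#' satisfiable), apply the new term with freshly recomputed relation
#' rewrites (or an obsolete stub for obsoleted requests), write the file
#' atomically, and append one changelog entry. A failing request aborts only
#' itself; later requests still proceed.
#'
#' @param queue a [request_queue()].
#' @param ontology_path path of the OBO file to update.
#' @param request_ids requests to commit; `NULL` commits every approved or
#'   obsoleted request.
#' @param changelog_path optional path of the changelog file (one line per
#'   request: timestamp, request id, assigned id, action).
#' @param external_prefixes passed through to [parse_obo()].
#' @param now timestamp override for the changelog.
#' @return a data.frame report: `request_id`, `assigned_id`, `action`,
#'   `ok`, `message`.
#' @export
commit_requests <- function(queue, ontology_path, request_ids = NULL,
                            changelog_path = NULL,
                            external_prefixes = character(0), now = NULL) {
  state <- load_queue(queue)
  eligible <- Filter(function(r) {
    r$status %in% c("approved", "obsoleted") && !isTRUE(r$committed)
  }, state)
  ids <- if (is.null(request_ids)) {
    vapply(eligible, function(r) as.integer(r$request_id), integer(1))
  } else {
    as.integer(request_ids)
  }
  ids <- sort(unique(ids))
  rows <- list()
  for (rid in ids) {
    req <- state[[as.character(rid)]]
    res <- tryCatch({
      if (is.null(req)) stop("unknown request id: ", rid)
      if (!req$status %in% c("approved", "obsoleted") ||
          isTRUE(req$committed)) {
        stop("request ", rid, " is ",
             if (isTRUE(req$committed)) "already committed" else req$status,
             "; only approved or obsoleted requests can be committed")
      }
      ont <- read_obo(ontology_path, external_prefixes)
      if (!is.null(ont$terms[[req$assigned_id]])) {
        stop("id collision: ", req$assigned_id, " already in the ontology")
      }
      action <- if (identical(req$status, "obsoleted")) "obsolete" else "add"
      if (action == "add") {
        term <- candidate_to_term(req$candidate, req$assigned_id)
        rewrites <- list()
        if (!is.null(req$candidate$logical_def)) {
          placement <- place(ont, req$candidate$logical_def)
          if (length(placement$equivalents)) {
            stop("stale duplicate: now equivalent to existing ",
                 paste(placement$equivalents, collapse = ", "))
          }
          if (!placement$satisfiable) stop("candidate no longer satisfiable")
          term$told_parents <- placement$direct_supers
          rewrites <- relation_rewrites_for(ont, placement, req$assigned_id)
        }
        if (req$candidate$label %in% ont_labels(ont)) {
          stop("label collision: '", req$candidate$label,
               "' already in the ontology")
        }
        ont <- apply_new_term(ont, term, rewrites)
      } else {
        stub <- term_record(req$assigned_id, label = req$candidate$label,
                            namespace = req$candidate$namespace,
                            comment = req$review_note,
                            created_by = req$candidate$created_by,
                            creation_date = req$candidate$creation_date,
                            obsolete = TRUE)
        ont <- ont_add_term(ont, stub)
      }
      write_obo_file(ont, ontology_path)
      queue_append(queue, list(type = "status", request_id = rid,
                               status = "committed", note = "",
                               edits = NULL))
      if (!is.null(changelog_path)) {
        cat(paste(now %||% iso_now(), rid, req$assigned_id, action,
                  sep = "\t"),
            "\n", sep = "", file = changelog_path, append = TRUE)
      }
      list(ok = TRUE, action = action, message = "committed")
    }, error = function(e) {
      list(ok = FALSE,
           action = if (!is.null(req) && identical(req$status, "obsoleted"))
             "obsolete" else "add",
           message = conditionMessage(e))
    })
    rows[[length(rows) + 1L]] <- data.frame(
      request_id = rid,
      assigned_id = if (is.null(req)) NA_character_ else req$assigned_id,
      action = res$action, ok = res$ok, message = res$message,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(request_id = integer(0), assigned_id = character(0),
                      action = character(0), ok = logical(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

candidate_to_term <- function(candidate, id) {
  term_record(
    id, label = candidate$label, namespace = candidate$namespace,
    definition = candidate$definition, def_xrefs = candidate$def_xrefs,
    synonyms = candidate$synonyms,
    told_parents = candidate$told_parents,
    relationships = candidate$relationships,
    logical_def = candidate$logical_def,
    created_by = candidate$created_by,
    creation_date = candidate$creation_date)
}

# note: for committed templated requests told_parents are overwritten with
# the commit-time direct superclasses before apply_new_term.
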