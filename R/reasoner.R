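#' EL-profile structural reasoner
#'
#' Subsumption reasoning for the description-logic fragment that
#' genus-differentia definitions live in: conjunction and existential
#' restriction (OWL 2 EL), plus a role hierarchy, role transitivity and
#' class disjointness encoded as bottom. The pipeline is the classic one:
#' [normalize()] rewrites all axioms into a small set of normal forms over
#' named and fresh classes, [saturate()] computes the least fixpoint of the
#' EL completion rules, and [classify()] condenses the resulting subsumption
#' closure into a direct (transitively reduced) taxonomy.
#'
#' @name el_reasoner
NULL

TF_TOP <- "owl:Thing"
TF_BOT <- "owl:Nothing"
TF_TEMP <- "TFTMP:0000001"

#' Normalize an ontology into EL normal forms
#'
#' Asserted `is_a` links become atomic subsumptions `A ⊑ B`;
#' relationship lines become `A ⊑ ∃r.B`; an equivalence axiom
#' `A ≡ C1 ⊓ ... ⊓ Cn` is split into both directions, using
#' deterministic fresh class names (derived from the canonical serialization
#' of the source expression) for existential conjuncts and for the binary
#' folding of the conjunction; disjoint pairs become
#' `A ⊓ B ⊑ ⊥`. Obsolete terms contribute nothing.
#'
#' @param ont an `obo_ontology`.
#' @param extra_axioms optional list of `list(id =, expr =)` equivalence
#'   axioms added on top of the ontology (used for hypothetical-class
#'   placement).
#' @return an `el_axioms` normalized axiom set.
#' @export
normalize <- function(ont, extra_axioms = list()) {
  stopifnot(inherits(ont, "obo_ontology"))
  atomic <- list(); conj <- list(); erhs <- list(); elhs <- list()
  fresh <- character(0)

  filler_name <- function(expr) {
    if (expr$type != "named") {
      stop(errorCondition(
        paste0("unsupported expression form (filler must be a named class): ",
               ce_key(expr)),
        class = c("termforge_unsupported_expr", "termforge_error")))
    }
    expr$id
  }

  # A ⊑ expr, expr in genus-differentia shape
  enc_sub <- function(a, expr) {
    switch(expr$type,
      named = { atomic[[length(atomic) + 1L]] <<- c(a, expr$id) },
      some  = { erhs[[length(erhs) + 1L]] <<-
                  c(a, expr$property, filler_name(expr$filler)) },
      and   = { for (p in expr$parts) enc_sub(a, p) },
      stop(errorCondition(
        paste0("unsupported expression form: ", ce_key(expr)),
        class = c("termforge_unsupported_expr", "termforge_error")))
    )
  }

  # returns a named-class handle for expr, creating fresh names as needed
  enc_name <- function(expr) {
    switch(expr$type,
      named = expr$id,
      some = {
        f <- paste0("TF_FRESH:", ce_key(expr))
        fresh <<- unique(c(fresh, f))
        elhs[[length(elhs) + 1L]] <<-
          c(expr$property, filler_name(expr$filler), f)
        f
      },
      stop(errorCondition(
        paste0("unsupported expression form: ", ce_key(expr)),
        class = c("termforge_unsupported_expr", "termforge_error")))
    )
  }

  # expr ⊑ a
  enc_sup <- function(expr, a) {
    if (expr$type != "and") {
      h <- enc_name(expr)
      atomic[[length(atomic) + 1L]] <<- c(h, a)
      return(invisible(NULL))
    }
    handles <- vapply(expr$parts, enc_name, "")
    acc <- handles[1L]
    for (k in 2L:length(handles)) {
      target <- if (k == length(handles)) a else {
        f <- paste0("TF_FRESH:fold(",
                    paste(sort(handles[1:k]), collapse = ","), "->", a, ")")
        fresh <<- unique(c(fresh, f))
        f
      }
      conj[[length(conj) + 1L]] <<- c(acc, handles[k], target)
      acc <- target
    }
  }

  add_equiv <- function(id, expr) {
    enc_sub(id, expr)
    enc_sup(expr, id)
  }

  for (t in ont$terms) {
    if (t$obsolete) next
    for (p in t$told_parents) atomic[[length(atomic) + 1L]] <- c(t$id, p)
    for (r in t$relationships) {
      erhs[[length(erhs) + 1L]] <- c(t$id, r$property, r$target)
    }
    if (!is.null(t$logical_def)) add_equiv(t$id, t$logical_def)
  }
  for (ax in extra_axioms) add_equiv(ax$id, ax$expr)

  bottom <- lapply(ont$disjoint_pairs, function(dp) c(dp[1L], dp[2L], TF_BOT))

  role_subs <- list()
  for (p in ont$properties) {
    for (sp in p$parents) role_subs[[length(role_subs) + 1L]] <- c(p$id, sp)
  }
  role_trans <- names(ont$properties)[
    vapply(ont$properties, function(p) p$transitive, logical(1))]

  named <- names(ont$terms)[
    !vapply(ont$terms, function(t) t$obsolete, logical(1))]
  extra_ids <- vapply(extra_axioms, function(a) a$id, "")

  structure(
    list(atomic_subs = atomic, conj_subs = c(conj, bottom),
         exist_rhs = erhs, exist_lhs = elhs,
         role_subs = role_subs, role_trans = role_trans,
         fresh_names = fresh,
         named_classes = sort(unique(c(named, extra_ids))),
         roles = sort(unique(names(ont$properties)))),
    class = "el_axioms"
  )
}

#' Saturate a normalized axiom set under the EL completion rules
#'
#' Computes the least fixpoint of the completion rules: propagation through
#' atomic subsumptions, conjunction axioms, existential introduction and
#' elimination, role hierarchy, role transitivity, and bottom propagation
#' along role edges. Always terminates (finite vocabulary).
#'
#' @param ax an `el_axioms` set from [normalize()].
#' @return an `el_closure` with components `entities`, the reflexive
#'   transitive subsumption matrix `S` (`S[a, b]` means `b` is an entailed
#'   superclass of `a`), role-edge matrices `R`, and the `unsatisfiable`
#'   entity set.
#' @export
saturate <- function(ax) {
  stopifnot(inherits(ax, "el_axioms"))
  ents <- unique(c(ax$named_classes, ax$fresh_names,
                   unlist(lapply(ax$atomic_subs, identity)),
                   vapply(ax$conj_subs, `[`, character(3), 1:3),
                   vapply(ax$exist_rhs, `[`, "", 1L),
                   vapply(ax$exist_rhs, `[`, "", 3L),
                   vapply(ax$exist_lhs, `[`, "", 2L),
                   vapply(ax$exist_lhs, `[`, "", 3L),
                   TF_TOP, TF_BOT))
  ents <- sort(unique(ents))
  n <- length(ents)
  idx <- seq_len(n); names(idx) <- ents
  bot <- idx[[TF_BOT]]; top <- idx[[TF_TOP]]

  roles <- sort(unique(c(ax$roles,
                         vapply(ax$exist_rhs, `[`, "", 2L),
                         vapply(ax$exist_lhs, `[`, "", 1L),
                         unlist(ax$role_subs))))
  nr <- length(roles)
  ridx <- seq_len(max(nr, 1L)); names(ridx) <- if (nr) roles else "none"

  # reflexive-transitive role closure for CR5
  rsup <- lapply(seq_len(nr), function(r) r)
  if (length(ax$role_subs)) {
    radj <- lapply(seq_len(nr), function(r) integer(0))
    for (rs in ax$role_subs) {
      radj[[ridx[[rs[1L]]]]] <- c(radj[[ridx[[rs[1L]]]]], ridx[[rs[2L]]])
    }
    for (r in seq_len(nr)) {
      seen <- r; stack <- r
      while (length(stack)) {
        cur <- stack[length(stack)]; stack <- stack[-length(stack)]
        for (s in radj[[cur]]) if (!s %in% seen) {
          seen <- c(seen, s); stack <- c(stack, s)
        }
      }
      rsup[[r]] <- seen
    }
  }
  trans <- if (nr) which(roles %in% ax$role_trans) else integer(0)

  # axiom indexes
  subs_by <- vector("list", n)            # b -> supers B (A'=b ⊑ B)
  for (a in ax$atomic_subs) {
    i <- idx[[a[1L]]]; subs_by[[i]] <- c(subs_by[[i]], idx[[a[2L]]])
  }
  conj_by <- vector("list", n)            # a1 -> list of c(a2, b); symmetric
  for (a in ax$conj_subs) {
    i1 <- idx[[a[1L]]]; i2 <- idx[[a[2L]]]; ib <- idx[[a[3L]]]
    conj_by[[i1]] <- c(conj_by[[i1]], list(c(i2, ib)))
    conj_by[[i2]] <- c(conj_by[[i2]], list(c(i1, ib)))
  }
  erhs_by <- vector("list", n)            # a -> list of c(role, b)
  for (a in ax$exist_rhs) {
    i <- idx[[a[1L]]]
    erhs_by[[i]] <- c(erhs_by[[i]], list(c(ridx[[a[2L]]], idx[[a[3L]]])))
  }
  # elhs_by[[r]][[b]] -> targets A' for axiom exists r.b ⊑ A'
  elhs_by <- lapply(seq_len(max(nr, 1L)), function(r) vector("list", n))
  for (a in ax$exist_lhs) {
    r <- ridx[[a[1L]]]; ib <- idx[[a[2L]]]
    elhs_by[[r]][[ib]] <- c(elhs_by[[r]][[ib]], idx[[a[3L]]])
  }

  S <- matrix(FALSE, n, n, dimnames = list(ents, ents))
  R <- lapply(seq_len(max(nr, 1L)), function(r) matrix(FALSE, n, n))

  queue <- vector("list", 256L); qh <- 0L; qt <- 0L
  push <- function(item) {
    qt <<- qt + 1L
    if (qt > length(queue)) length(queue) <<- 2L * qt
    queue[[qt]] <<- item
  }
  add_sub <- function(a, b) {
    if (!S[a, b]) { S[a, b] <<- TRUE; push(c(0L, a, b)) }
  }
  add_edge <- function(r, a, b) {
    if (!R[[r]][a, b]) {
      R[[r]][a, b] <<- TRUE
      push(c(r, a, b))
      for (s in rsup[[r]]) if (s != r) add_edge(s, a, b)
    }
  }

  for (a in seq_len(n)) { add_sub(a, a); add_sub(a, top) }

  while (qh < qt) {
    qh <- qh + 1L
    it <- queue[[qh]]
    if (it[1L] == 0L) {
      a <- it[2L]; b <- it[3L]                      # b entered S(a)
      for (B in subs_by[[b]]) add_sub(a, B)          # CR1
      for (cx in conj_by[[b]]) {                     # CR2 (and bottom conj)
        if (S[a, cx[1L]]) add_sub(a, cx[2L])
      }
      for (eb in erhs_by[[b]]) add_edge(eb[1L], a, eb[2L])   # CR3
      # CR4 with a as edge target: edges (r, x, a), axiom exists r.b ⊑ A'
      if (nr) {
        for (r in seq_len(nr)) {
          tg <- elhs_by[[r]][[b]]
          if (is.null(tg) && b != bot) next
          xs <- which(R[[r]][, a])
          if (!length(xs)) next
          for (x in xs) {
            for (A2 in tg) add_sub(x, A2)
            if (b == bot) add_sub(x, bot)            # CR-bottom
          }
        }
      }
    } else {
      r <- it[1L]; a <- it[2L]; b <- it[3L]          # edge (a, b) in R(r)
      sups_b <- which(S[b, ])
      for (bp in sups_b) {                           # CR4
        for (A2 in elhs_by[[r]][[bp]]) add_sub(a, A2)
      }
      if (S[b, bot]) add_sub(a, bot)                 # CR-bottom
      if (r %in% trans) {                            # CR6
        for (cc in which(R[[r]][b, ])) add_edge(r, a, cc)
        for (x in which(R[[r]][, a])) add_edge(r, x, b)
      }
    }
  }

  unsat <- setdiff(ents[S[, bot]], TF_BOT)   # ⊥ itself is trivially there
  structure(
    list(entities = ents, S = S,
         R = stats::setNames(R[seq_len(nr)], roles),
         unsatisfiable = unsat,
         named_classes = ax$named_classes),
    class = "el_closure"
  )
}

# Entailed named superclasses of a named class (reflexive), from a closure.
closure_supers <- function(cl, id) {
  if (!id %in% rownames(cl$S)) stop("unknown class in closure: ", id)
  s <- colnames(cl$S)[cl$S[id, ]]
  intersect(s, cl$named_classes)
}

#' Cached reasoner handle
#'
#' Bundles an ontology with its saturated closure so repeated subset and
#' classification queries (binding validation, suggestion-index builds) do
#' not re-run saturation.
#'
#' @param ont an `obo_ontology`.
#' @return an `el_reasoner_handle`.
#' @export
el_reasoner <- function(ont) {
  structure(list(ontology = ont, closure = saturate(normalize(ont))),
            class = "el_reasoner_handle")
}

as_closure <- function(x) {
  if (inherits(x, "el_closure")) return(x)
  if (inherits(x, "el_reasoner_handle")) return(x$closure)
  if (inherits(x, "obo_ontology")) return(saturate(normalize(x)))
  stop("cannot obtain a subsumption closure from ", class(x)[1L])
}

as_ontology <- function(x) {
  if (inherits(x, "obo_ontology")) return(x)
  if (inherits(x, "el_reasoner_handle")) return(x$ontology)
  stop("cannot obtain an ontology from ", class(x)[1L])
}

#' Classify an ontology into a direct taxonomy
#'
#' Computes the full entailed subsumption closure and condenses it to the
#' transitive reduction over equivalence-group representatives: each class
#' maps to its direct (most specific entailed) superclasses. Obsolete terms
#' are excluded. Errors when the ontology is incoherent; the condition
#' carries the unsatisfiable class set in its `unsatisfiable` field.
#'
#' @param ont an `obo_ontology` or `el_reasoner_handle`.
#' @return an `el_taxonomy` with `direct_supers`, `direct_subs` (named lists
#'   of sorted character vectors) and `equiv_groups`.
#' @export
classify <- function(ont) {
  cl <- as_closure(ont)
  named <- cl$named_classes
  unsat <- intersect(cl$unsatisfiable, named)
  if (length(unsat)) {
    stop(errorCondition(
      paste0("ontology is incoherent; unsatisfiable classes: ",
             paste(sort(unsat), collapse = ", ")),
      unsatisfiable = sort(unsat),
      class = c("termforge_incoherent", "termforge_error")))
  }
  taxonomy_from_closure(cl, named)
}

taxonomy_from_closure <- function(cl, named) {
  named <- sort(named)
  Sn <- cl$S[named, named, drop = FALSE]

  # equivalence groups: mutual subsumption; representative = smallest id
  rep_of <- stats::setNames(named, named)
  equiv_groups <- list()
  seen <- character(0)
  for (a in named) {
    if (a %in% seen) next
    grp <- named[Sn[a, ] & Sn[, a]]
    seen <- c(seen, grp)
    for (g in grp) rep_of[[g]] <- grp[1L]
    equiv_groups[[length(equiv_groups) + 1L]] <- grp
  }
  reps <- sort(unique(unname(rep_of)))
  Sr <- Sn[reps, reps, drop = FALSE]

  direct_supers <- stats::setNames(vector("list", length(named)), named)
  direct_subs <- stats::setNames(
    lapply(named, function(x) character(0)), named)
  for (a in reps) {
    strict <- reps[Sr[a, ] & reps != a]
    strict <- strict[!vapply(strict, function(b) {
      any(vapply(setdiff(strict, b), function(cc) Sr[cc, b], logical(1)))
    }, logical(1))]
    direct_supers[[a]] <- sort(strict)
  }
  # expand to all members of each equivalence group
  for (a in named) direct_supers[[a]] <- direct_supers[[rep_of[[a]]]]
  for (a in reps) {
    for (b in direct_supers[[a]]) {
      grp_a <- named[rep_of == rep_of[[a]]]
      for (bb in named[rep_of == rep_of[[b]]]) {
        direct_subs[[bb]] <- sort(unique(c(direct_subs[[bb]], grp_a)))
      }
    }
  }
  structure(
    list(classes = named, direct_supers = direct_supers,
         direct_subs = direct_subs, equiv_groups = equiv_groups),
    class = "el_taxonomy"
  )
}

#' @export
print.el_taxonomy <- function(x, ...) {
  cat(sprintf("<el_taxonomy> %d classes, %d direct is_a edges\n",
              length(x$classes),
              sum(lengths(x$direct_supers))))
  invisible(x)
}

#' Direct is_a edges of a taxonomy as a data frame
#'
#' @param tax an `el_taxonomy`.
#' @return a data.frame with columns `child`, `parent`, sorted.
#' @export
taxonomy_edges <- function(tax) {
  stopifnot(inherits(tax, "el_taxonomy"))
  child <- rep(names(tax$direct_supers), lengths(tax$direct_supers))
  parent <- unlist(tax$direct_supers, use.names = FALSE)
  if (is.null(parent)) parent <- character(0)
  df <- data.frame(child = child, parent = parent,
                   stringsAsFactors = FALSE)
  df[order(df$child, df$parent), , drop = FALSE]
}

taxonomy_equal <- function(a, b) {
  identical(taxonomy_edges(a), taxonomy_edges(b)) &&
    identical(lapply(a$equiv_groups, sort), lapply(b$equiv_groups, sort))
}

#' Place a hypothetical class
#'
#' Adds a temporary class defined to be equivalent to `expr`, saturates the
#' extended axiom set from scratch, and reports the reasoner verdict:
#' equivalent named classes (duplicate detection), the most specific entailed
#' named superclasses, the most general entailed named subclasses, whether
#' the candidate is satisfiable, and whether the rest of the ontology is
#' coherent. The input ontology value is left untouched — the temporary
#' axioms exist only inside this call.
#'
#' @param ont an `obo_ontology`.
#' @param expr a grounded [class_expression].
#' @return a `placement_result`.
#' @export
place <- function(ont, expr) {
  stopifnot(inherits(ont, "obo_ontology"), inherits(expr, "class_expression"))
  for (cid in ce_class_ids(expr)) {
    if (is.null(ont$terms[[cid]])) {
      stop(errorCondition(paste0("unknown class in expression: ", cid),
                          class = c("termforge_unknown_id",
                                    "termforge_error")))
    }
  }
  for (pid in ce_property_ids(expr)) {
    if (is.null(ont$properties[[pid]])) {
      stop(errorCondition(paste0("unknown property in expression: ", pid),
                          class = c("termforge_unknown_id",
                                    "termforge_error")))
    }
  }
  ax <- normalize(ont, extra_axioms = list(list(id = TF_TEMP, expr = expr)))
  cl <- saturate(ax)

  named <- setdiff(cl$named_classes, TF_TEMP)
  ontology_coherent <- !any(named %in% cl$unsatisfiable)
  satisfiable <- !TF_TEMP %in% cl$unsatisfiable

  S <- cl$S
  equivalents <- named[S[TF_TEMP, named] & S[named, TF_TEMP]]
  above <- setdiff(named[S[TF_TEMP, named]], c(equivalents))
  below <- setdiff(named[S[named, TF_TEMP]], c(equivalents))
  # most specific supers: drop any with a *strictly* smaller class also in
  # `above` (mutually equivalent supers must not eliminate each other),
  # then collapse each equivalence cluster to its smallest id, as the
  # taxonomy does
  minimal <- above[!vapply(above, function(b) {
    others <- setdiff(above, b)
    any(S[others, b] & !S[b, others])
  }, logical(1))]
  direct_supers <- unique(vapply(minimal, function(b) {
    min(minimal[S[minimal, b] & S[b, minimal]])
  }, ""))
  # most general subs: drop any with a strictly larger class also in
  # `below`; equivalence-cluster members are all kept, as in the taxonomy
  direct_subs <- below[!vapply(below, function(b) {
    others <- setdiff(below, b)
    any(S[b, others] & !S[others, b])
  }, logical(1))]

  structure(
    list(equivalents = sort(equivalents),
         direct_supers = sort(direct_supers),
         direct_subs = sort(direct_subs),
         satisfiable = satisfiable,
         ontology_coherent = ontology_coherent),
    class = "placement_result"
  )
}

#' @export
print.placement_result <- function(x, ...) {
  cat("<placement_result>\n")
  cat("  satisfiable:      ", x$satisfiable, "\n")
  cat("  ontology coherent:", x$ontology_coherent, "\n")
  cat("  equivalents:      ", paste(x$equivalents, collapse = ", "), "\n")
  cat("  direct supers:    ", paste(x$direct_supers, collapse = ", "), "\n")
  cat("  direct subs:      ", paste(x$direct_subs, collapse = ", "), "\n")
  invisible(x)
}

#' Relation rewrites implied by inserting a new class
#'
#' When a new class lands between existing children and their former
#' parents, the children's asserted `is_a` links must move down to the new
#' class so the asserted hierarchy stays equal to the entailed taxonomy. For
#' each direct subclass of the placed class, every told parent that is an
#' entailed superclass of the new class is replaced by the new id.
#'
#' @param ont the `obo_ontology` the placement was computed on.
#' @param placement a `placement_result` with empty `equivalents`.
#' @param new_id the permanent id the new class will receive.
#' @return list of `list(child =, drop_parent =, add_parent =)`.
#' @export
relation_rewrites_for <- function(ont, placement, new_id) {
  stopifnot(inherits(placement, "placement_result"))
  if (length(placement$equivalents)) {
    stop("no rewrites for a duplicate class (equivalents non-empty)")
  }
  if (!length(placement$direct_subs)) return(list())
  cl <- as_closure(ont)
  supers_new <- unique(unlist(lapply(placement$direct_supers, function(d) {
    closure_supers(cl, d)
  })))
  out <- list()
  for (s in placement$direct_subs) {
    for (p in intersect(get_term(ont, s)$told_parents, supers_new)) {
      out[[length(out) + 1L]] <- list(child = s, drop_parent = p,
                                      add_parent = new_id)
    }
  }
  ord <- order(vapply(out, function(r) paste(r$child, r$drop_parent), ""))
  out[ord]
}

#' Entailed subclass closure of a set of roots
#'
#' Returns the roots plus every non-obsolete named class entailed to be a
#' subclass of any root (direct and indirect, through both asserted links
#' and logical definitions).
#'
#' @param x an `obo_ontology` or `el_reasoner_handle`.
#' @param roots character vector of class ids.
#' @return sorted character vector of class ids.
#' @export
subclass_closure <- function(x, roots) {
  cl <- as_closure(x)
  named <- cl$named_classes
  for (r in roots) {
    if (!r %in% named) {
      stop(errorCondition(paste0("unknown root class: ", r),
                          class = c("termforge_unknown_id",
                                    "termforge_error")))
    }
  }
  hit <- named[rowSums(cl$S[named, roots, drop = FALSE]) > 0]
  sort(unique(c(roots, hit)))
}
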