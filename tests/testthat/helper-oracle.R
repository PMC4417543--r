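# Independent structural-subsumption oracle.
#
# Brute-force fixpoint over named-class pairs, working directly on the
# original axioms (told is_a links, relationship lines, genus-differentia
# definitions with plain properties — the fragment random_ontology
# generates). Deliberately a different algorithm from the package's
# normalization + completion-rule saturation: no normal forms, no fresh
# classes, no role-edge sets; just chaotic iteration of the closure
#
#   Known(A, A)                                   reflexivity
#   A is_a P                    => Known(A, P)    told edges
#   E defined as G ⊓ ∃r.F       => Known(E, G)    definition, left to right
#   Known(A, B), Known(B, C)    => Known(A, C)    transitivity
#   Known(A, genus) and, for every differentia ∃r.F, some P with
#   Known(A, P) carrying a relationship or definition part ∃r.t
#   with Known(t, F)            => Known(A, E)    definition, right to left
#
# until nothing changes.

oracle_subsumption_matrix <- function(ont) {
  ids <- names(ont$terms)
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  K <- diag(n) > 0
  defs <- lapply(ont$terms, function(t) {
    d <- t$logical_def
    if (is.null(d)) return(NULL)
    if (d$type == "and") d$parts else list(d)
  })
  rels <- lapply(ont$terms, function(t) t$relationships)
  told <- lapply(ont$terms, function(t) t$told_parents)

  # does A entail ∃r.f', with f' any class already known below f?
  entails_some <- function(a, r, filler) {
    ok_filler <- K[, idx[[filler]]]
    for (p in which(K[a, ])) {
      for (rl in rels[[p]]) {
        if (identical(rl$property, r) && ok_filler[idx[[rl$target]]]) {
          return(TRUE)
        }
      }
      for (part in defs[[p]]) {
        if (part$type == "some" && identical(part$property, r) &&
            ok_filler[idx[[part$filler$id]]]) {
          return(TRUE)
        }
      }
    }
    FALSE
  }

  repeat {
    before <- sum(K)
    for (a in seq_len(n)) {
      for (p in told[[a]]) K[a, idx[[p]]] <- TRUE
    }
    for (e in seq_len(n)) {
      for (part in defs[[e]]) {
        if (part$type == "named") K[e, idx[[part$id]]] <- TRUE
      }
    }
    K <- K | ((K %*% K) > 0)
    for (e in seq_len(n)) {
      if (is.null(defs[[e]])) next
      for (a in seq_len(n)) {
        if (K[a, e]) next
        ok <- TRUE
        for (part in defs[[e]]) {
          hit <- if (part$type == "named") K[a, idx[[part$id]]] else
            entails_some(a, part$property, part$filler$id)
          if (!hit) { ok <- FALSE; break }
        }
        if (ok) K[a, e] <- TRUE
      }
    }
    if (sum(K) == before) break
  }
  dimnames(K) <- list(ids, ids)
  K
}

oracle_subsumes <- function(ont, a_id, b_id) {
  oracle_subsumption_matrix(ont)[a_id, b_id]
}

# Entailed named-class pairs (reflexive) as a sorted "A < B" key vector.
oracle_subsumption_set <- function(ont) {
  K <- oracle_subsumption_matrix(ont)
  ids <- rownames(K)
  out <- character(0)
  for (a in seq_along(ids)) {
    for (b in which(K[a, ])) out <- c(out, paste(ids[a], "<", ids[b]))
  }
  sort(out)
}

# Same pair set from the package's completion-rule reasoner.
reasoner_subsumption_set <- function(ont) {
  cl <- saturate(normalize(ont))
  named <- cl$named_classes
  S <- cl$S[named, named, drop = FALSE]
  out <- character(0)
  for (a in named) {
    for (b in named[S[a, ]]) out <- c(out, paste(a, "<", b))
  }
  sort(out)
}
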