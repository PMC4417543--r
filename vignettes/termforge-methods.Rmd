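---
title: "How termforge generates, places and commits ontology classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How termforge generates, places and commits ontology classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termforge)
```

## The model

termforge treats a new ontology class request as a triple: a **logical
definition** in genus-differentia form, **textual building blocks**
(label, definition, synonyms) generated from the same bound inputs, and
**provenance** (requester, timestamp, literature reference). The logical
definition is an OWL equivalence axiom in the EL fragment:

$$
C \;\equiv\; G \;\sqcap\; \exists r_1.F_1 \;\sqcap\; \dots \;\sqcap\; \exists r_k.F_k
$$

with a named genus $G$ and named fillers $F_i$. Everything the workflow
does — duplicate defense, satisfiability checking, hierarchy placement,
autocompletion subsets — is a subsumption query against this axiom set.

### Supported logic

The reasoner covers EL with a role hierarchy, role transitivity, and class
disjointness encoded as $A \sqcap B \sqsubseteq \bot$: conjunction and
existential restriction only, no inverse roles, no cardinality, no
nominals. Every pattern in the shipped template catalogue fits this
fragment, and subsumption in it is polynomial, which is what makes
per-request reasoning affordable.

### Normalization and saturation

`normalize()` rewrites all axioms into the usual EL normal forms
($A \sqsubseteq B$; $A_1 \sqcap A_2 \sqsubseteq B$;
$A \sqsubseteq \exists r.B$; $\exists r.B \sqsubseteq A$; role axioms).
An equivalence is split into both directions; the right-to-left direction
introduces fresh class names for existential conjuncts and for the binary
folding of $n$-ary conjunctions. Fresh names are derived from the
canonical serialization of their source expression
(`TF_FRESH:some(has_input,CHEBI:27656)` and the like), so two
axioms over the same subexpression share one fresh name and saturation
traces are reproducible run to run. This sharing is also what makes
duplicate detection work: a hypothetical class defined by the same
expression as an existing class reaches the existing class's conjunction
axiom through the shared fresh names, and mutual subsumption falls out.

`saturate()` computes the least fixpoint of the standard EL completion
rules with a worklist: atomic propagation, conjunction firing, existential
introduction ($A' \in S(A),\, A' \sqsubseteq \exists r.B \Rightarrow (A,B)
\in R(r)$) and elimination, role-hierarchy copying of edges, transitive
composition, and bottom propagation backwards along role edges. The
vocabulary is finite, every rule only adds facts, so termination is
structural. Unsatisfiable classes are those whose subsumer set contains
$\bot$; $\bot$ itself is excluded from that report.

### Classification and placement

`classify()` restricts the closure to named, non-obsolete classes, merges
mutually subsuming classes into equivalence groups (represented by their
lexicographically smallest id), and takes the transitive reduction of the
remaining partial order: a direct superclass is an entailed strict
superclass not implied by another. All result sets everywhere are sorted
by class id — ordering is never load-order-dependent.

`place()` answers the per-request question. It rebuilds the normalized
axiom set with one extra equivalence `TMP ≡ expr` for a reserved temporary
id, saturates from scratch, and reports equivalent named classes, the most
specific entailed superclasses, the most general entailed subclasses,
candidate satisfiability, and whether the rest of the ontology is
coherent. Saturating from scratch (rather than maintaining an incremental
index) is a deliberate choice: the ontologies in scope are desk-scale,
correctness is easier to argue, and the temporary axioms never touch the
caller's ontology value — R's copy semantics give the revert guarantee for
free.

The placement's direct *subclasses* drive **relation rewrites**: when the
new class lands between an existing child and one of the child's told
parents (the told parent is an entailed superclass of the new class), the
child's asserted `is_a` link moves down to the new class. Combined with
asserting the placement's direct superclasses as the new class's told
parents, the asserted hierarchy stays equal to the entailed taxonomy after
commit. The alternative reading — deriving the new class's asserted
parents from its subclasses — does not type-check against what a placement
returns, so the package asserts supers for the new class and rewrites
subs, and tests the combination with the incremental-equals-batch
property.

## Templates

Templates are data, not code: a YAML catalogue declares for each template
its typed input fields, a logical pattern, a label pattern, a definition
pattern and optional synonym rules. The pattern grammar is the compact
form used in cross-product catalogues:

```
GO:0006810 and 'exports' some ?X
?P and 'part_of' some ?W
GO:0006810 and 'transports or maintains localization of' some ?X
    [and 'has target start location' some ?F]
```

Quoted relation labels resolve through an explicit label-to-property map
in the same file; quoted class labels resolve against the loaded
ontologies at instantiation time; `[...]` marks an optional conjunct that
is dropped when its field is unbound. A production deployment of this
workflow would let each template run arbitrary script code; re-encoding
the catalogue declaratively removes code execution from the request path
and keeps every shipped pattern expressible — templates needing bespoke
logic are out of scope by design.

Text patterns use `[X]` for the bound class's label and `[X.id]` for its
CURIE. Optional *text* segments are delimited with `{...}` rather than
reusing square brackets (label patterns like `[X] transport{ from [F]}`),
because `[...]` already means *placeholder* in text position; a segment is
dropped when any field referenced inside is unbound. The shipped label and
definition wordings follow GO editorial conventions; they are conventions
of this package (flagged as such in the catalogue comments), since the
production wordings live in code that is not part of any published
catalogue. Synonym rules default to EXACT scope and apply the rule pattern
to *each synonym* of the bound class, which is how `(S)-camptothecin`
yields `(S)-camptothecin catabolic process`.

Binding validation returns failures as data (missing required fields,
classes outside their field's reasoner-derived subset closure, malformed
literature references) rather than exceptions, so a user interface can
show all of them at once. Every template implicitly requires a literature
reference field unless it declares its own `xref_list` field.

## Identifiers, queue, review, commit

Permanent identifiers come from a configurable pattern and range
(`prefix`, zero-padded width, inclusive integer range). `next_id()`
persists the allocation (append, fsync-on-close semantics of the
filesystem) *before* returning the id, and ids already present in the
loaded ontology count as allocated; this is what makes the
1,000-submission crash/reload property hold.

The queue is an append-only event log, one JSON record per line: a
submission record carries the full request (candidate, assigned id,
placement, rewrites, provenance), and status-change records carry review
outcomes and textual edits. Replaying the log *is* the queue state, so a
half-written trailing line after a crash costs at most the event being
written. Review can approve (with edits restricted to label, definition
and synonyms — the logical definition is immutable once reasoned about) or
obsolete; there is no reject, because the permanent id was issued at
submission. An obsoleted request is committed as an obsolete stub term so
its identifier remains resolvable — the no-delete rule implies the id must
live somewhere, and an obsolete term is the established convention.

`commit_requests()` processes each request separately, in request-id
order, mimicking one version-control commit per request: reload the
ontology file, re-run the quick checks (id unused, still no equivalent
named class, still satisfiable, label still free), apply the term with
freshly recomputed rewrites, write the file atomically
(write-temp-then-rename), and append one changelog line. A failing request
aborts only itself — the stale-duplicate case, where an earlier request in
the same batch committed the same pattern, is detected by the re-check and
reported per-request.

## Free-form requests and the similarity warning

Free-form requests carry told parents and plain relationships but no
equivalence axiom, so classification can place them only by their told
parents; the pipeline synthesizes the corresponding placement rather than
invoking the reasoner. The extra validation is the similar-label check:
case-folded comparison against all labels and synonyms, warning when the
edit distance is at most 2 **or** one string contains the other with a
length difference of at most 3. No published metric exists for this check;
this rule family is the smallest one that is symmetric, has a testable
threshold, and fires on the canonical omegasome/megasome example (distance
1 *and* substring) while staying quiet on unrelated -some words like
ribosome/megasome (distance 4, not a bounded substring). Exact collisions
always block; near collisions block unless the requester dismisses them
(`force`), exactly because near matches are sometimes legitimately
different things.

## Fixtures and the random-ontology generator

`figure4_fixture()` is the five-class worked example
(metabolic/catabolic processes, alkaloid, camptothecin, and *alkaloid
catabolic process* defined as catabolic process with alkaloid input).
`mini_go_chebi()` is a ~50-class fixture spanning the three GO branches, a
ChEBI branch, and single-class stand-ins for the plant-anatomy, cell-type,
gross-anatomy and quality ontologies, plus the full relation set of the
shipped catalogue — every template's subset roots resolve against it.
Well-known classes keep their familiar CURIEs so examples read naturally;
synthetic filler uses a `TEST:` prefix. One fixture id is worth noting:
the catabolism pattern's genus is GO:0009056 throughout, which is the id
the catalogue uses, even though one published rendering of the worked
example prints a different id for 'catabolic process'; the fixtures follow
the catalogue.

`random_ontology()` generates the test distribution for the reasoner:
classes are created in order and reference only earlier classes, so told
and definition graphs are acyclic by construction. Defaults — three
properties, `p_isa = 0.1` per ordered pair, `p_def = 0.25`, `p_rel = 0.1`
— produce sparse, GO-shaped DAGs: a few roots, multiple inheritance,
roughly a quarter of classes cross-product-defined, which mirrors the
axiomatization density that makes pattern-based generation useful in the
first place. Properties in generated ontologies are plain (no hierarchy,
no transitivity) so the independent test oracle — a brute-force fixpoint
over named-class pairs on the raw axioms, a genuinely different algorithm
from the worklist saturation — stays simple enough to trust by
inspection; role hierarchy and transitivity are covered by hand-built
cases with hand-computed expectations instead. What passing these tests
shows is correctness of the calculus on acyclic, moderately axiomatized
ontologies; it does not exercise definition cycles (unsupported),
million-class scale, or the annotation richness of a real GO release.

## Problem sizes and numerical choices

The shipped test suite and acceptance script use 200 random ontologies of
5–30 classes for the oracle-equivalence check, 100 submit→commit→classify
cycles (including candidates that insert intermediate classes and force
rewrites), 50 randomized duplicate-defense bindings, and 1,000 identifier
allocations with a queue reopening every 100 — sizes chosen so the whole
suite re-runs in minutes on one core while every code path is crossed many
times. There are no floating-point tolerances anywhere: every comparison
in the system (subsumption sets, taxonomy edges, serialized documents,
identifiers) is exact, and determinism is engineered by sorting every
result set by id, fixing tag order in the writer, and deriving fresh names
and fixture content from canonical serializations and explicit seeds.

## Known limitations

- OBO support is a deliberate subset: one genus plus existential
  differentiae; no `union_of`, no `equivalent_to` between named classes,
  no annotations beyond the supported tags (unknown tags are preserved
  verbatim but not interpreted).
- The reasoner is EL-only; patterns needing inverse roles or cardinality
  cannot be expressed or validated.
- The queue is single-writer; concurrent submissions from multiple
  processes would interleave ids safely (allocation is persisted first)
  but could interleave log lines unsafely.
- Label uniqueness is enforced ontology-wide at load and commit time, not
  per namespace.
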