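# termforge

Template-driven generation of new ontology classes for OBO-format
ontologies, with reasoning-based validation and placement, permanent
identifier allocation, a reviewable request queue, and commit-back to the
ontology file.

## The problem

Biomedical ontologies such as the Gene Ontology grow by thousands of classes
a year, and most new classes instantiate a small number of recurring design
patterns: *regulation of X*, *X catabolic process*, *X transport from F to
T*, and so on. Each pattern pairs an OWL equivalence axiom in
genus-differentia form,

```
'X catabolic process'  ≡  'catabolic process' ⊓ ∃ has_input . X
```

with textual building blocks (label, definition, synonyms). Given such a
pattern and a bound input class (say camptothecin, CHEBI:27656), everything
about the new class is mechanical: its axioms, its text, and — crucially —
its *placement*. An EL reasoner can check whether an equivalent class
already exists (duplicate defense), whether the candidate is satisfiable,
and which existing classes are its most specific superclasses and most
general subclasses, even when those are not the told genus. In the worked
example shipped with the package, `catabolic process ⊓ ∃has_input.camptothecin`
is placed under *alkaloid catabolic process* (GO:0009822), not merely under
*catabolic process*, because camptothecin is an alkaloid.

termforge implements that whole request workflow at desk scale, for
biocurators and ontology engineers:

- **obo model** — reader/writer for an OBO 1.4 subset with
  `intersection_of` logical definitions; deterministic serialization and
  lossless round-trips.
- **EL reasoner** — normalization to EL normal forms, completion-rule
  saturation (conjunction, existentials, role hierarchy, transitivity,
  disjointness-as-bottom), classification into a transitively reduced
  taxonomy, and incremental placement of a hypothetical class with revert
  semantics.
- **template engine** — a declarative YAML catalogue of class-generation
  patterns (the full GO catalogue ships in
  `inst/extdata/go_templates.yaml`), binding validation against
  reasoner-derived subset closures, and candidate instantiation.
- **suggestion index** — subset-restricted autocompletion over labels and
  synonyms.
- **request pipeline** — permanent id allocation from a configurable
  range, an append-only persisted queue, approve/modify/obsolete review
  (there is no reject: ids are permanent), and per-request commits.
- **freeform requests** — non-templated classes with similar-label
  collision warnings (edit distance and bounded substring).
- **fixtures** — deterministic toy ontologies and a seeded random-ontology
  generator used for oracle-based testing.
- **cli** — a `termforge` entry point (`inst/bin/termforge`) wiring a YAML
  config to all of the above.

## Worked example

```r
library(termforge)

ont <- figure4_fixture()            # camptothecin-catabolism toy ontology
pl  <- place(ont, ce_and(ce_named("GO:0009056"),
                         ce_some("has_input", ce_named("CHEBI:27656"))))
pl
#> <placement_result>
#>   satisfiable:       TRUE
#>   ontology coherent: TRUE
#>   equivalents:
#>   direct supers:     GO:0009822
#>   direct subs:
```

The reasoner infers the more specific superclass *alkaloid catabolic
process* — the candidate is satisfiable, duplicates nothing, and will be
committed with `is_a: GO:0009822`.

The same inference through the full pipeline:

```r
ts     <- load_templates(system.file("extdata", "go_templates.yaml",
                                     package = "termforge"))
mini   <- mini_go_chebi()
dir    <- tempfile(); dir.create(dir)
write_obo_file(mini$ontology, file.path(dir, "go.obo"))
queue  <- request_queue(file.path(dir, "queue.jsonl"))
policy <- id_policy("GO", 7, 2000001, 2001000, file.path(dir, "ids.txt"))

req <- submit_request(queue, ts$templates$catabolism,
                      list(X = "CHEBI:27656", ref = "PMID:12345"),
                      "curator@example.org", mini$ontology, policy, ts)
req
#> <term_request> #1 GO:2000001 'camptothecin catabolic process' [pending] by curator@example.org

review_request(queue, 1, "approve")
commit_requests(queue, file.path(dir, "go.obo"))
#>   request_id assigned_id action   ok   message
#> 1          1  GO:2000001    add TRUE committed

request_status(queue, "GO:2000001")
#> [1] "approved"
```

The committed stanza carries the permanent id GO:2000001, the generated
label, definition, synonyms, the literature reference, provenance
(`created_by`, `creation_date`), the equivalence axiom, and an `is_a` link
to the inferred superclass GO:0009822.

From a shell, the same flow is
`termforge request catabolism --bind X=CHEBI:27656 --ref PMID:12345 --user ...`,
then `termforge review approve 1` and `termforge commit --all`
(see `inst/bin/termforge`; every subcommand takes `--config config.yaml`).

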