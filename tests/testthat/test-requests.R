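test_that("id allocation starts at the range floor and skips existing ids", {
  ws <- make_workspace()
  expect_identical(next_id(ws$policy), "GO:2000001")
  expect_identical(next_id(ws$policy), "GO:2000002")

  # an id already present in the ontology counts as allocated
  ws2 <- make_workspace()
  ont <- read_obo(ws2$ontology_path)
  ont <- apply_new_term(ont, term_record("GO:2000001", label = "taken",
                                         told_parents = "GO:0008150"))
  expect_identical(next_id(ws2$policy, ont), "GO:2000002")

  tiny <- id_policy("GO", 7, 1, 2, file.path(ws$dir, "tiny.txt"))
  next_id(tiny); next_id(tiny)
  expect_error(next_id(tiny), class = "termforge_range_exhausted")
})

test_that("a submitted request goes pending with its reasoner placement", {
  ws <- make_workspace()
  ts <- shipped_templates()
  ont <- read_obo(ws$ontology_path)
  req <- submit_request(ws$queue, ts$templates$catabolism,
                        list(X = "CHEBI:27656", ref = "PMID:12345"),
                        "curator@example.org", ont, ws$policy, ts,
                        allowed = "curator@example.org")
  expect_identical(req$status, "pending")
  expect_identical(req$assigned_id, "GO:2000001")
  expect_identical(req$placement$direct_supers, "GO:0009822")
  expect_identical(req$candidate$created_by, "curator@example.org")
  expect_identical(request_status(ws$queue, "GO:2000001"), "pending")
  expect_identical(request_status(ws$queue, "GO:9999999"), "unknown")

  expect_error(
    submit_request(ws$queue, ts$templates$catabolism,
                   list(X = "CHEBI:27656", ref = "PMID:1"),
                   "stranger@example.org", ont, ws$policy, ts,
                   allowed = "curator@example.org"),
    class = "termforge_unauthorized")
  expect_error(
    submit_request(ws$queue, ts$templates$catabolism,
                   list(ref = "PMID:1"), "curator@example.org", ont,
                   ws$policy, ts),
    class = "termforge_invalid_binding")
})

test_that("queue state survives close and reopen", {
  ws <- make_workspace()
  ts <- shipped_templates()
  ont <- read_obo(ws$ontology_path)
  r1 <- submit_request(ws$queue, ts$templates$catabolism,
                       list(X = "CHEBI:27656", ref = "PMID:1"),
                       "a@b.org", ont, ws$policy, ts)
  review_request(ws$queue, r1$request_id, "approve", note = "fine")
  reopened <- request_queue(ws$queue$path)
  state <- load_queue(reopened)
  expect_length(state, 1L)
  expect_identical(state[[1L]]$status, "approved")
  expect_identical(state[[1L]]$review_note, "fine")
  expect_true(ce_equal(state[[1L]]$candidate$logical_def,
                       r1$candidate$logical_def))
})

test_that("review edits text, never logic, and enforces transitions", {
  ws <- make_workspace()
  ts <- shipped_templates()
  ont <- read_obo(ws$ontology_path)
  r1 <- submit_request(ws$queue, ts$templates$biosynthesis,
                       list(X = "TEST:0000102", ref = "PMID:1"),
                       "a@b.org", ont, ws$policy, ts)
  r1b <- review_request(ws$queue, r1$request_id, "approve",
                        edits = list(definition = "Better wording."))
  expect_identical(r1b$status, "approved")
  expect_identical(r1b$candidate$definition, "Better wording.")
  expect_error(review_request(ws$queue, r1$request_id, "approve"),
               class = "termforge_illegal_transition")
  expect_error(
    review_request(ws$queue, r1$request_id, "obsolete",
                   edits = list(logical_def = "x")),
    class = "termforge_illegal_edit")
  expect_error(review_request(ws$queue, 999L, "approve"),
               class = "termforge_unknown_request")
})

test_that("commit adds the class, updates children and logs one entry each", {
  ws <- make_workspace()
  ts <- shipped_templates()
  ont <- read_obo(ws$ontology_path)
  r1 <- submit_request(ws$queue, ts$templates$catabolism,
                       list(X = "CHEBI:27656", ref = "PMID:1"),
                       "a@b.org", ont, ws$policy, ts)
  r2 <- submit_request(ws$queue, ts$templates$biosynthesis,
                       list(X = "TEST:0000103", ref = "PMID:2"),
                       "a@b.org", ont, ws$policy, ts)
  review_request(ws$queue, r1$request_id, "approve")
  review_request(ws$queue, r2$request_id, "approve")
  report <- commit_requests(ws$queue, ws$ontology_path,
                            changelog_path = ws$changelog)
  expect_identical(nrow(report), 2L)
  expect_true(all(report$ok))
  expect_length(readLines(ws$changelog), 2L)   # one entry per request

  ont2 <- read_obo(ws$ontology_path)
  tax <- classify(ont2)
  expect_identical(tax$direct_supers[[r1$assigned_id]],
                   r1$placement$direct_supers)
  expect_identical(request_status(ws$queue, r1$assigned_id), "approved")

  # resubmitting the committed pattern is rejected, naming the committed id
  err <- tryCatch(
    submit_request(ws$queue, ts$templates$catabolism,
                   list(X = "CHEBI:27656", ref = "PMID:1"),
                   "a@b.org", ont2, ws$policy, ts),
    termforge_duplicate = function(e) e)
  expect_s3_class(err, "termforge_duplicate")
  expect_identical(err$existing_id, r1$assigned_id)
})

test_that("a stale duplicate inside one commit batch fails only itself", {
  ws <- make_workspace()
  ts <- shipped_templates()
  ont <- read_obo(ws$ontology_path)
  # same logical content submitted twice before any commit
  r1 <- submit_request(ws$queue, ts$templates$metabolism,
                       list(X = "TEST:0000102", ref = "PMID:1"),
                       "a@b.org", ont, ws$policy, ts)
  r2 <- submit_request(ws$queue, ts$templates$metabolism,
                       list(X = "TEST:0000102", ref = "PMID:2"),
                       "a@b.org", ont, ws$policy, ts)
  review_request(ws$queue, r1$request_id, "approve")
  review_request(ws$queue, r2$request_id, "approve")
  report <- commit_requests(ws$queue, ws$ontology_path)
  expect_identical(report$ok, c(TRUE, FALSE))
  expect_match(report$message[2L], "stale duplicate")
  expect_match(report$message[2L], r1$assigned_id, fixed = TRUE)
  # the failed request is still approved (not committed)
  expect_false(isTRUE(load_queue(ws$queue)[[
    as.character(r2$request_id)]]$committed))
})

test_that("obsoleted requests commit as obsolete stubs with no axioms", {
  ws <- make_workspace()
  ts <- shipped_templates()
  ont <- read_obo(ws$ontology_path)
  r1 <- submit_request(ws$queue, ts$templates$chemical_import,
                       list(X = "TEST:0000102", ref = "PMID:1"),
                       "a@b.org", ont, ws$policy, ts)
  review_request(ws$queue, r1$request_id, "obsolete", note = "redundant")
  report <- commit_requests(ws$queue, ws$ontology_path)
  expect_true(all(report$ok))
  ont2 <- read_obo(ws$ontology_path)
  stub <- get_term(ont2, r1$assigned_id)
  expect_true(stub$obsolete)
  expect_length(stub$told_parents, 0L)
  expect_null(stub$logical_def)
  expect_match(stub$comment, "redundant")
  # the permanent id resolves but is not usable
  expect_identical(request_status(ws$queue, r1$assigned_id), "unknown")
})

test_that("identifier allocation never reuses ids across crash/reload", {
  ws <- make_workspace()
  ont <- read_obo(ws$ontology_path)
  issued <- character(0)
  for (batch in 1:5) {
    policy <- id_policy("GO", 7, 2000001, 2001000,
                        ws$policy$state_path)     # fresh handle = reload
    for (k in 1:40) issued <- c(issued, next_id(policy, ont))
  }
  expect_length(issued, 200L)
  expect_false(anyDuplicated(issued) > 0)
  nums <- as.integer(sub("^GO:", "", issued))
  expect_true(all(nums >= 2000001 & nums <= 2001000))
})
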