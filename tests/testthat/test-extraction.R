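doc_of <- function(id = "doc1", text = "Some article text.") {
  paper_document(id, "Synthetic kinase 1", text)
}

test_that("relevance assessment parses the constrained response format", {
  backend <- mock_backend(list(
    "relevance::pos" = '```json\n{"relevant": true, "reasons": "sites listed"}\n```',
    "relevance::neg" = '```json\n{"relevant": false, "reasons": "no residues"}\n```'))
  expect_true(assess_relevance(doc_of("pos"), backend)$relevant)
  expect_false(assess_relevance(doc_of("neg"), backend)$relevant)
})

test_that("free-prose responses exhaust retries and raise a format error", {
  calls <- new.env(); calls$n <- 0
  backend <- llm_backend(function(prompt, document, stage, doc_id) {
    calls$n <- calls$n + 1
    "I think this paper is probably about the right protein."
  })
  expect_error(assess_relevance(doc_of(), backend, retries = 2),
               class = "pocketlit_format_error")
  expect_equal(calls$n, 3)  # initial call + 2 retries
  # oversized documents fail loudly instead of being truncated
  expect_error(
    assess_relevance(doc_of(text = strrep("x", 100)), backend,
                     char_budget = 50),
    class = "pocketlit_validation_error")
})

test_that("extraction validates residue tokens and keeps pockets with >= 1 valid residue", {
  resp <- paste0(
    '```json\n{"pockets": [{"name": "ATP site", "description": "d", ',
    '"residues": ["A:LYS:271", "A:ASP:381", "A:XYZ:12"]}]}\n```')
  backend <- mock_backend(list("extract::doc1" = resp))
  expect_warning(p <- extract_pockets(doc_of(), backend), "A:XYZ:12")
  expect_equal(nrow(p), 1)
  expect_equal(nrow(p$residues[[1]]), 2)
  expect_equal(p$stage, "extracted")

  # a pocket whose tokens all fail is dropped entirely
  resp2 <- paste0(
    '```json\n{"pockets": [{"name": "bad", "description": "d", ',
    '"residues": ["A:XYZ:12"]},{"name": "good", "description": "d", ',
    '"residues": ["A:TYR:1"]}]}\n```')
  backend2 <- mock_backend(list("extract::doc1" = resp2))
  suppressWarnings(p2 <- extract_pockets(doc_of(), backend2))
  expect_equal(p2$name, "good")

  # empty-list sentinel
  backend3 <- mock_backend(list("extract::doc1" = '```json\n{"pockets": []}\n```'))
  expect_equal(nrow(extract_pockets(doc_of(), backend3)), 0)
})

test_that("refinement can unify split pockets, drop irrelevant sites, or pass through", {
  extracted <- pocket_table(
    name = c("site (part 1)", "site (part 2)", "DNA-binding groove"),
    description = c("d", "d", "nucleic acid contacts"),
    residues = list(c("A:LYS:10", "A:VAL:11"), c("A:LEU:12", "A:ASN:13"),
                    c("A:ARG:50", "A:ARG:51")))
  extracted$doc_id <- "doc1"; extracted$stage <- "extracted"
  unified <- paste0(
    '```json\n{"pockets": [{"name": "site", "description": "d", ',
    '"residues": ["A:LYS:10", "A:VAL:11", "A:LEU:12", "A:ASN:13"]}]}\n```')
  backend <- mock_backend(list("refine::doc1" = unified))
  ref <- refine_pockets(doc_of(), extracted, backend)
  expect_equal(nrow(ref), 1)
  expect_equal(ref$stage, "refined")
  expect_setequal(format_residue_token(ref$residues[[1]]),
                  c("A:LYS:10", "A:VAL:11", "A:LEU:12", "A:ASN:13"))

  # identity refinement just updates the stage tags
  same <- paste0(
    '```json\n{"pockets": [{"name": "site (part 1)", "description": "d", ',
    '"residues": ["A:LYS:10", "A:VAL:11"]}]}\n```')
  backend2 <- mock_backend(list("refine::doc1" = same))
  ref2 <- refine_pockets(doc_of(), extracted[1, ], backend2)
  expect_equal(ref2$residues[[1]], extracted$residues[[1]])
  expect_equal(ref2$stage, "refined")

  # backend failure falls back to the unrefined input with a warning
  failing <- llm_backend(function(...) stop("boom"))
  expect_warning(ref3 <- refine_pockets(doc_of(), extracted, failing),
                 "keeping unrefined")
  expect_equal(nrow(ref3), 3)
  expect_equal(unique(ref3$stage), "refined")
})

test_that("the pipeline short-circuits irrelevant papers and never calls later stages", {
  # only the relevance key exists: any extract/refine call would error
  backend <- mock_backend(list(
    "relevance::neg" = '```json\n{"relevant": false, "reasons": "n/a"}\n```'))
  out <- run_extraction_pipeline(doc_of("neg"), backend)
  expect_false(out$decision$relevant)
  expect_equal(nrow(out$pockets), 0)
})

test_that("the mock-driven workflow is bit-reproducible and recovers planted truth", {
  fx <- make_structure(default_fixture(seed = 11))
  corpus <- make_corpus(fx, n_negative = 1)
  backend <- mock_backend(corpus$responses)
  runs <- lapply(1:2, function(i) {
    lapply(corpus$documents, run_extraction_pipeline, backend = backend)
  })
  expect_identical(runs[[1]], runs[[2]])
  # noiseless corpus: refined output equals the planted truth exactly
  for (k in seq_along(corpus$documents)) {
    doc <- corpus$documents[[k]]
    truth <- corpus$truth_by_doc[[doc$doc_id]]
    got <- runs[[1]][[k]]$pockets
    expect_equal(nrow(got), nrow(truth))
    for (i in seq_len(nrow(truth))) {
      expect_equal(jaccard(got$residues[[i]], truth$residues[[i]]), 1)
    }
  }
})

test_that("two planted sites extract as two pockets with disjoint residue sets", {
  spec <- fixture_spec(
    seed = 5, n_chains = 1, chain_len = 40,
    pockets = list(list(name = "orthosteric site", ids = 5:10, type = "single"),
                   list(name = "allosteric site", ids = 25:30, type = "single")),
    decoys = 0)
  fx <- make_structure(spec)
  corpus <- make_corpus(fx, n_negative = 0)
  backend <- mock_backend(corpus$responses)
  multi <- corpus$documents[[which(vapply(corpus$documents, `[[`, "", "doc_id") == "multi01")]]
  out <- run_extraction_pipeline(multi, backend)
  expect_equal(nrow(out$pockets), 2)
  k1 <- format_residue_token(out$pockets$residues[[1]])
  k2 <- format_residue_token(out$pockets$residues[[2]])
  expect_length(intersect(k1, k2), 0)
})
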