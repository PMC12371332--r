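# Three-stage prompted extraction workflow: (i) relevance assessment,
# (ii) pocket extraction, (iii) pocket refinement, all against the same
# backend. Stages demand a fenced JSON block; malformed responses are
# retried up to `retries` times before failing. Residue tokens in stage
# output are validated with parse_residue_token(); invalid tokens are
# dropped with a warning and a pocket survives only if at least one valid
# residue remains.

#' Load a stage prompt template
#'
#' Templates ship as editable text assets under `inst/prompts/` and use
#' `{{target}}` (and, for refinement, `{{pockets}}`) placeholders.
#'
#' @param stage One of `"relevance"`, `"extract"`, `"refine"`.
#' @param prompt_dir Directory of templates; defaults to the installed ones.
#' @return Template string.
#' @export
load_prompt <- function(stage = c("relevance", "extract", "refine"),
                        prompt_dir = NULL) {
  stage <- match.arg(stage)
  if (is.null(prompt_dir)) {
    prompt_dir <- system.file("prompts", package = "pocketlit")
  }
  path <- file.path(prompt_dir, paste0(stage, ".txt"))
  if (!file.exists(path)) {
    stopf("no prompt template for stage '%s' in '%s'", stage, prompt_dir,
          class = "pocketlit_io_error")
  }
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

render_prompt <- function(template, values) {
  for (key in names(values)) {
    template <- gsub(paste0("{{", key, "}}"), values[[key]], template,
                     fixed = TRUE)
  }
  template
}

# extract the first fenced ```json block (or any fenced block / bare JSON
# object as fallbacks) and parse it; NULL if nothing parses
parse_json_response <- function(response) {
  candidates <- character()
  m <- regmatches(response,
                  regexec("```json\\s*\\n(.*?)```", response))[[1]]
  if (length(m) == 2) candidates <- c(candidates, m[[2]])
  m <- regmatches(response, regexec("```\\s*\\n(.*?)```", response))[[1]]
  if (length(m) == 2) candidates <- c(candidates, m[[2]])
  if (grepl("^\\s*\\{", response)) candidates <- c(candidates, response)
  for (cand in candidates) {
    parsed <- tryCatch(jsonlite::fromJSON(cand, simplifyVector = FALSE),
                       error = function(e) NULL)
    if (!is.null(parsed)) return(parsed)
  }
  NULL
}

# run one stage with retries; `accept` maps parsed JSON -> result or NULL
stage_call <- function(doc, backend, stage, prompt, accept, retries = 2) {
  last_problem <- NULL
  for (attempt in seq_len(retries + 1)) {
    response <- tryCatch(
      backend_complete(backend, prompt, doc$text, stage, doc$doc_id),
      error = function(e) e)
    if (inherits(response, "error")) {
      last_problem <- conditionMessage(response)
      next
    }
    parsed <- parse_json_response(response)
    if (!is.null(parsed)) {
      result <- accept(parsed)
      if (!is.null(result)) return(result)
    }
    last_problem <- sprintf("unparseable %s response", stage)
  }
  stopf("stage '%s' failed for document '%s' after %d attempt(s): %s",
        stage, doc$doc_id, retries + 1, last_problem %||% "unknown",
        class = if (grepl("^unparseable", last_problem %||% ""))
          "pocketlit_format_error" else "pocketlit_backend_error")
}

#' Assess whether a paper is relevant
#'
#' Stage one of the workflow: asks the backend whether the article
#' describes the target protein and contains a residue-level description of
#' a small-molecule binding site.
#'
#' @param doc A `paper_document`.
#' @param backend An `llm_backend`.
#' @param retries Retries on backend failure or malformed output.
#' @param char_budget Maximum document size passed to the backend; larger
#'   documents fail loudly rather than being truncated silently.
#' @param prompt_dir Optional prompt template directory override.
#' @return A `relevance_decision`: list with `relevant` (logical),
#'   `reasons` (string) and `doc_id`.
#' @export
assess_relevance <- function(doc, backend, retries = 2, char_budget = 400000,
                             prompt_dir = NULL) {
  if (nchar(doc$text) > char_budget) {
    stopf("document '%s' exceeds the %d-character budget", doc$doc_id,
          char_budget, class = "pocketlit_validation_error")
  }
  prompt <- render_prompt(load_prompt("relevance", prompt_dir),
                          list(target = doc$target_name))
  accept <- function(parsed) {
    if (!is.list(parsed) ||
        !(isTRUE(parsed$relevant) || isFALSE(parsed$relevant))) {
      return(NULL)
    }
    list(relevant = isTRUE(parsed$relevant),
         reasons = as.character(parsed$reasons %||% ""),
         doc_id = doc$doc_id)
  }
  out <- stage_call(doc, backend, "relevance", prompt, accept, retries)
  structure(out, class = "relevance_decision")
}

# parse one pocket entry from stage JSON, validating residue tokens;
# returns NULL if no valid residue survives
parse_pocket_entry <- function(entry, doc_id, stage_tag) {
  if (!is.list(entry) || is.null(entry$name) || is.null(entry$residues)) {
    return(NULL)
  }
  tokens <- unlist(entry$residues)
  refs <- lapply(tokens, function(tok) {
    tryCatch(parse_residue_token(tok), error = function(e) {
      warn(sprintf("dropping invalid residue token '%s' in pocket '%s' (%s)",
                   tok, entry$name, doc_id))
      NULL
    })
  })
  refs <- bind_rows(refs)
  if (nrow(refs) == 0) {
    warn(sprintf("dropping pocket '%s' (%s): no valid residues", entry$name,
                 doc_id))
    return(NULL)
  }
  tibble(
    name = as.character(entry$name),
    description = as.character(entry$description %||% ""),
    residues = list(distinct_residues(refs)),
    doc_id = doc_id,
    stage = stage_tag
  )
}

parse_pocket_response <- function(parsed, doc_id, stage_tag) {
  if (!is.list(parsed) || is.null(parsed$pockets)) return(NULL)
  if (length(parsed$pockets) == 0) {
    return(tibble(name = character(), description = character(),
                  residues = list(), doc_id = character(), stage = character()))
  }
  rows <- lapply(parsed$pockets, parse_pocket_entry, doc_id = doc_id,
                 stage_tag = stage_tag)
  bind_rows(rows)
}

#' Extract binding pockets from a paper
#'
#' Stage two: asks the backend for every distinct small-molecule binding
#' site with explicit residues. Invalid residue tokens are dropped with a
#' warning; a pocket is kept only if at least one valid residue remains.
#'
#' @inheritParams assess_relevance
#' @return An extracted-pocket tibble with columns `name`, `description`,
#'   `residues` (list of residue-ref tibbles), `doc_id`, `stage`.
#' @export
extract_pockets <- function(doc, backend, retries = 2, prompt_dir = NULL) {
  prompt <- render_prompt(load_prompt("extract", prompt_dir),
                          list(target = doc$target_name))
  accept <- function(parsed) parse_pocket_response(parsed, doc$doc_id, "extracted")
  stage_call(doc, backend, "extract", prompt, accept, retries)
}

#' Refine extracted pockets
#'
#' Stage three: presents the current extraction back to the backend for
#' correction — adding missed residues, re-unifying improperly split sites,
#' and dropping sites irrelevant for small-molecule binding. Residue
#' validation is re-applied to the refined output. If the backend fails and
#' `fallback_to_input` is `TRUE`, the unrefined input is returned with a
#' warning (stage tags updated).
#'
#' @param pockets Extracted-pocket tibble from [extract_pockets()].
#' @param fallback_to_input Return the input (tagged `refined`) on backend
#'   failure instead of erroring.
#' @inheritParams assess_relevance
#' @return Refined extracted-pocket tibble (`stage = "refined"`).
#' @export
refine_pockets <- function(doc, pockets, backend, retries = 2,
                           fallback_to_input = TRUE, prompt_dir = NULL) {
  current <- lapply(seq_len(nrow(pockets)), function(i) {
    list(name = pockets$name[[i]], description = pockets$description[[i]],
         residues = as.list(format_residue_token(pockets$residues[[i]])))
  })
  prompt <- render_prompt(
    load_prompt("refine", prompt_dir),
    list(target = doc$target_name,
         pockets = jsonlite::toJSON(current, auto_unbox = TRUE, pretty = TRUE)))
  accept <- function(parsed) parse_pocket_response(parsed, doc$doc_id, "refined")
  out <- tryCatch(
    stage_call(doc, backend, "refine", prompt, accept, retries),
    error = function(e) {
      if (!fallback_to_input) stop(e)
      warn(sprintf("refinement failed for '%s'; keeping unrefined pockets (%s)",
                   doc$doc_id, conditionMessage(e)))
      mutate(pockets, stage = "refined")
    })
  out
}

#' Run the full three-stage extraction workflow on one paper
#'
#' Relevance assessment short-circuits: documents judged irrelevant are
#' never sent to the extraction or refinement stages. All stages use the
#' same backend.
#'
#' @inheritParams assess_relevance
#' @param config A [pipeline_config()] list (retries, character budget,
#'   prompt directory, refinement fallback).
#' @return List with `decision` (a `relevance_decision`) and `pockets`
#'   (refined extracted-pocket tibble; empty when irrelevant).
#' @export
run_extraction_pipeline <- function(doc, backend, config = pipeline_config()) {
  decision <- assess_relevance(
    doc, backend, retries = config$retries,
    char_budget = config$char_budget, prompt_dir = config$prompt_dir)
  empty <- tibble(name = character(), description = character(),
                  residues = list(), doc_id = character(), stage = character())
  if (!decision$relevant) {
    return(list(decision = decision, pockets = empty))
  }
  extracted <- extract_pockets(doc, backend, retries = config$retries,
                               prompt_dir = config$prompt_dir)
  refined <- refine_pockets(doc, extracted, backend, retries = config$retries,
                            fallback_to_input = config$refine_fallback,
                            prompt_dir = config$prompt_dir)
  list(decision = decision, pockets = refined)
}
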