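# Text-completion backends. The extraction stages only ever talk to a
# backend through complete(backend, prompt, document, stage, doc_id), so a
# real chat-completion HTTP service and the deterministic mock used for
# offline runs are interchangeable. The mock is keyed by (stage, doc_id)
# and always returns the same response for the same key, which makes the
# whole pipeline bit-reproducible.

#' Create a text-completion backend
#'
#' @param complete_fn Function `(prompt, document, stage, doc_id) -> string`.
#' @param name Model/backend name recorded in provenance.
#' @param temperature Sampling temperature metadata (0 for deterministic).
#' @return An `llm_backend` object.
#' @export
llm_backend <- function(complete_fn, name = "custom", temperature = 0) {
  structure(list(complete_fn = complete_fn, name = name,
                 temperature = temperature),
            class = "llm_backend")
}

#' Send one completion request
#'
#' @param backend An `llm_backend`.
#' @param prompt Instruction prompt for the stage.
#' @param document Full article text.
#' @param stage Stage tag (`"relevance"`, `"extract"`, `"refine"`).
#' @param doc_id Document identifier (used by the mock backend for keying).
#' @return The raw response string.
#' @export
backend_complete <- function(backend, prompt, document, stage, doc_id) {
  stopifnot(inherits(backend, "llm_backend"))
  backend$complete_fn(prompt, document, stage, doc_id)
}

#' Deterministic mock backend
#'
#' Serves canned responses keyed by `"<stage>::<doc_id>"`, either from a
#' named list or from a directory of text files named
#' `<stage>__<doc_id>.txt`. Identical keys always yield identical
#' responses, so pipelines driven by the mock are reproducible byte for
#' byte. Missing keys raise a backend error, mimicking a failed request.
#'
#' @param responses Named list of response strings keyed
#'   `"<stage>::<doc_id>"`, or `NULL` when `dir` is given.
#' @param dir Directory of canned response files.
#' @return An `llm_backend`.
#' @export
mock_backend <- function(responses = NULL, dir = NULL) {
  if (is.null(responses) && is.null(dir)) {
    abort("mock_backend needs `responses` or `dir`")
  }
  if (!is.null(dir)) {
    files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
    keys <- sub("\\.txt$", "", basename(files))
    keys <- sub("__", "::", keys, fixed = TRUE)
    responses <- setNames(
      lapply(files, function(f) {
        paste(readLines(f, warn = FALSE), collapse = "\n")
      }),
      keys)
  }
  llm_backend(
    complete_fn = function(prompt, document, stage, doc_id) {
      key <- paste0(stage, "::", doc_id)
      if (!key %in% names(responses)) {
        stopf("mock backend has no canned response for '%s'", key,
              class = "pocketlit_backend_error")
      }
      responses[[key]]
    },
    name = "mock", temperature = 0)
}

#' Write mock responses to a directory
#'
#' Serializes a named response list (as accepted by [mock_backend()]) into
#' the one-file-per-key layout that `mock_backend(dir = ...)` reads back.
#'
#' @param responses Named list keyed `"<stage>::<doc_id>"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mock_responses <- function(responses, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(responses)) {
    fname <- paste0(sub("::", "__", key, fixed = TRUE), ".txt")
    writeLines(responses[[key]], file.path(dir, fname))
  }
  invisible(dir)
}
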