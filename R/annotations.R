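# Benchmark corpus I/O: per-paper annotation JSONs and paper markdown
# documents. One JSON per paper records whether the paper describes any
# small-molecule binding site for the target and, if so, the annotated
# pockets (name, description, constituent residues). Papers with no sites
# are negative controls. The JSON schema shipped in
# inst/extdata/annotation-schema.json documents the on-disk dialect.

#' Construct a pocket annotation table
#'
#' @param name,description Character vectors, one entry per pocket.
#' @param residues List of residue-ref tibbles (one per pocket), or a list
#'   of character vectors of residue tokens.
#' @return A tibble with columns `name`, `description` and a `residues`
#'   list-column of residue-ref tibbles.
#' @export
pocket_table <- function(name = character(), description = character(),
                         residues = list()) {
  residues <- lapply(residues, function(r) {
    if (is.character(r)) r <- parse_residue_token(r)
    as_tibble(r)
  })
  tibble(name = as.character(name),
         description = as.character(description),
         residues = residues)
}

#' Construct a paper annotation
#'
#' @param doc_id Document identifier (typically the markdown file stem).
#' @param target_name Protein target the paper was annotated against.
#' @param relevant Does the paper describe any binding site for the target?
#' @param pockets A pocket table from [pocket_table()]; must be empty when
#'   `relevant` is `FALSE`.
#' @return A `paper_annotation` object.
#' @export
paper_annotation <- function(doc_id, target_name, relevant,
                             pockets = pocket_table()) {
  ann <- structure(
    list(doc_id = doc_id, target_name = target_name,
         relevant = isTRUE(relevant), pockets = pockets),
    class = "paper_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  problems <- character()
  if (!is.character(ann$doc_id) || length(ann$doc_id) != 1 || ann$doc_id == "") {
    problems <- c(problems, "doc_id must be a non-empty string")
  }
  if (!is.logical(ann$relevant) || length(ann$relevant) != 1 || is.na(ann$relevant)) {
    problems <- c(problems, "relevant must be TRUE or FALSE")
  }
  p <- ann$pockets
  if (!is.data.frame(p) || !all(c("name", "description", "residues") %in% names(p))) {
    problems <- c(problems, "pockets must have name/description/residues")
  } else {
    if (any(is.na(p$name) | p$name == "")) {
      problems <- c(problems, "every pocket needs a non-empty name")
    }
    for (i in seq_len(nrow(p))) {
      r <- p$residues[[i]]
      if (!is.data.frame(r) || nrow(r) == 0) {
        problems <- c(problems, sprintf("pocket %d has no residues", i))
      } else if (anyDuplicated(res_key(r$chain_id, r$res_id, r$icode))) {
        problems <- c(problems, sprintf("pocket %d has duplicate residues", i))
      }
    }
    if (isFALSE(ann$relevant) && nrow(p) > 0) {
      problems <- c(problems, "irrelevant paper must have zero pockets")
    }
  }
  if (length(problems) > 0) {
    abort(paste0("invalid paper annotation:\n",
                 paste0("- ", problems, collapse = "\n")),
          class = "pocketlit_validation_error")
  }
  invisible(ann)
}

#' @export
print.paper_annotation <- function(x, ...) {
  cat(sprintf("<paper_annotation> %s (target: %s, relevant: %s, %d pocket%s)\n",
              x$doc_id, x$target_name, x$relevant, nrow(x$pockets),
              if (nrow(x$pockets) == 1) "" else "s"))
  invisible(x)
}

#' Read a paper annotation JSON
#'
#' Validates the file against the documented schema: top-level `doc_id`,
#' `target_name`, `relevant` and a `pockets` array whose entries each carry
#' `name`, `description` and a non-empty unique `residues` token array.
#'
#' @param path Path to the annotation JSON.
#' @return A `paper_annotation`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) {
    stopf("annotation file not found: '%s'", path, class = "pocketlit_io_error")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  required <- c("doc_id", "target_name", "relevant", "pockets")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stopf("annotation '%s' missing field(s): %s", path,
          paste(missing, collapse = ", "), class = "pocketlit_validation_error")
  }
  pockets <- lapply(raw$pockets, function(p) {
    missing <- setdiff(c("name", "description", "residues"), names(p))
    if (length(missing) > 0) {
      stopf("pocket in '%s' missing field(s): %s", path,
            paste(missing, collapse = ", "), class = "pocketlit_validation_error")
    }
    list(name = p$name, description = p$description,
         residues = parse_residue_token(unlist(p$residues)))
  })
  paper_annotation(
    doc_id = raw$doc_id,
    target_name = raw$target_name,
    relevant = isTRUE(raw$relevant),
    pockets = pocket_table(
      name = vapply(pockets, `[[`, "", "name"),
      description = vapply(pockets, `[[`, "", "description"),
      residues = lapply(pockets, `[[`, "residues")
    )
  )
}

#' Write a paper annotation JSON
#'
#' Inverse of [read_annotation()]: residues serialize to
#' `"CHAIN:RESNAME:RESID[ICODE]"` tokens and the round-trip reproduces the
#' annotation exactly at the data level.
#'
#' @param annotation A `paper_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  validate_annotation(annotation)
  payload <- list(
    doc_id = annotation$doc_id,
    target_name = annotation$target_name,
    relevant = annotation$relevant,
    pockets = lapply(seq_len(nrow(annotation$pockets)), function(i) {
      list(
        name = annotation$pockets$name[[i]],
        description = annotation$pockets$description[[i]],
        residues = as.list(format_residue_token(annotation$pockets$residues[[i]]))
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a paper markdown document
#'
#' Reads a GROBID-style markdown article verbatim (line endings normalized
#' to `"\n"`).
#'
#' @param path Path to the markdown file.
#' @param target_name Protein target this document is being screened for.
#' @param doc_id Document identifier; defaults to the file stem.
#' @return A `paper_document`: list with `doc_id`, `target_name`, `text`.
#' @export
read_paper_markdown <- function(path, target_name,
                                doc_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) {
    stopf("paper markdown not found: '%s'", path, class = "pocketlit_io_error")
  }
  txt <- readChar(path, file.size(path), useBytes = TRUE)
  Encoding(txt) <- "UTF-8"
  txt <- gsub("\r\n", "\n", txt, fixed = TRUE)
  txt <- gsub("\r", "\n", txt, fixed = TRUE)
  paper_document(doc_id = doc_id, target_name = target_name, text = txt)
}

#' Construct a paper document
#' @param doc_id Document identifier.
#' @param target_name Protein target name.
#' @param text Markdown text (non-empty).
#' @return A `paper_document` object.
#' @export
paper_document <- function(doc_id, target_name, text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text))) {
    stopf("paper document '%s' has empty text", doc_id,
          class = "pocketlit_validation_error")
  }
  structure(list(doc_id = doc_id, target_name = target_name, text = text),
            class = "paper_document")
}

#' @export
print.paper_document <- function(x, ...) {
  cat(sprintf("<paper_document> %s (target: %s, %d chars)\n",
              x$doc_id, x$target_name, nchar(x$text)))
  invisible(x)
}
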