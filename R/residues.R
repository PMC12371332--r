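# Residue references and token parsing.
#
# A residue reference ("residue ref") is a row of a tibble with columns
# chain_id, res_name, res_id, icode. Identity is (chain_id, res_id, icode);
# res_name is carried for verification. Literature tokens use the dialect
# "CHAIN:RESNAME:RESID[ICODE]" (e.g. "A:TYR:123", "A:TYR:123A"), with the
# chain-less forms "TYR123" and one-letter "Y123" accepted and expanded
# against a default chain.

.aa3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.aa1 <- setNames(names(.aa3), unname(.aa3))

# residue names accepted in literature tokens: the 20 standard amino acids
# plus common variants seen in structures
.known_res_names <- c(names(.aa3), "MSE", "SEC", "PYL", "UNK")

#' Construct a residue reference tibble
#'
#' @param chain_id,res_name,res_id,icode Vectors (recycled) giving the chain
#'   identifier, three-letter residue name, residue number and optional
#'   insertion code (`NA` or `""` for none).
#' @return A tibble with columns `chain_id`, `res_name`, `res_id`, `icode`.
#' @export
residue_ref <- function(chain_id, res_name, res_id, icode = NA_character_) {
  out <- tibble(
    chain_id = as.character(chain_id),
    res_name = toupper(as.character(res_name)),
    res_id = as.integer(res_id),
    icode = as.character(icode)
  )
  out$icode[is.na(out$icode) | out$icode == ""] <- NA_character_
  out
}

#' Parse a literature residue token
#'
#' Accepts the canonical `"A:TYR:123"` form (optionally with a trailing
#' insertion-code letter, `"A:TYR:123A"`), the chain-less `"TYR123"` form,
#' and the one-letter `"Y123"` form which is expanded via the standard
#' amino-acid code table. Chain-less forms are assigned `default_chain`.
#'
#' @param token Character vector of residue tokens.
#' @param default_chain Chain assigned to tokens that carry no chain field.
#' @return A residue-ref tibble, one row per token.
#' @examples
#' parse_residue_token(c("A:TYR:123", "Y124"), default_chain = "A")
#' @export
parse_residue_token <- function(token, default_chain = "A") {
  if (length(token) == 0) return(residue_ref(character(), character(), integer()))
  rows <- lapply(token, function(tok) {
    tok0 <- trimws(tok)
    parts <- strsplit(tok0, ":", fixed = TRUE)[[1]]
    if (length(parts) == 3) {
      chain <- parts[[1]]
      name <- toupper(parts[[2]])
      m <- regmatches(parts[[3]], regexec("^([0-9]+)([A-Za-z]?)$", parts[[3]]))[[1]]
      if (length(m) == 0 || chain == "") {
        stopf("cannot parse residue token '%s'", tok0, class = "pocketlit_parse_error")
      }
      if (!name %in% .known_res_names) {
        stopf("unrecognized residue name in token '%s'", tok0,
              class = "pocketlit_parse_error")
      }
      icode <- if (m[[3]] == "") NA_character_ else toupper(m[[3]])
      return(residue_ref(chain, name, as.integer(m[[2]]), icode))
    }
    if (length(parts) == 1) {
      m <- regmatches(tok0, regexec("^([A-Za-z]{1,3})([0-9]+)([A-Za-z]?)$", tok0))[[1]]
      if (length(m) == 0) {
        stopf("cannot parse residue token '%s'", tok0, class = "pocketlit_parse_error")
      }
      name <- toupper(m[[2]])
      if (nchar(name) == 1) {
        if (!name %in% names(.aa1)) {
          stopf("unknown one-letter residue code in token '%s'", tok0,
                class = "pocketlit_parse_error")
        }
        name <- .aa1[[name]]
      } else if (nchar(name) == 2 || !name %in% .known_res_names) {
        stopf("cannot parse residue token '%s'", tok0, class = "pocketlit_parse_error")
      }
      icode <- if (m[[4]] == "") NA_character_ else toupper(m[[4]])
      return(residue_ref(default_chain, name, as.integer(m[[3]]), icode))
    }
    stopf("cannot parse residue token '%s'", tok0, class = "pocketlit_parse_error")
  })
  bind_rows(rows)
}

#' Format residue refs as tokens
#'
#' Inverse of [parse_residue_token()]: renders `"CHAIN:RESNAME:RESID[ICODE]"`.
#'
#' @param residues A residue-ref tibble.
#' @return Character vector of tokens.
#' @export
format_residue_token <- function(residues) {
  ic <- ifelse(is.na(residues$icode), "", residues$icode)
  paste0(residues$chain_id, ":", residues$res_name, ":", residues$res_id, ic)
}

#' One-letter code for three-letter residue names
#'
#' Nonstandard residues map to `"X"`; selenomethionine (`MSE`) maps to `"M"`
#' when `alias_mse` is `TRUE` (the default).
#'
#' @param res_name Character vector of three-letter residue names.
#' @param alias_mse Treat MSE as methionine.
#' @return Character vector of one-letter codes.
#' @export
residue_one_letter <- function(res_name, alias_mse = TRUE) {
  code <- unname(.aa3[toupper(res_name)])
  if (alias_mse) code[toupper(res_name) == "MSE"] <- "M"
  code[is.na(code)] <- "X"
  code
}

# deduplicate a residue-ref tibble on the identity key
distinct_residues <- function(residues) {
  residues[!duplicated(res_key(residues$chain_id, residues$res_id, residues$icode)), ]
}
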