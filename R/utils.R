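# internal helpers shared across modules

# canonical residue identity key: equality is on (chain, number, insertion
# code); the residue name is carried for verification but not identity
res_key <- function(chain_id, res_id, icode) {
  paste0(chain_id, "|", res_id, "|", ifelse(is.na(icode), "", icode))
}

# chain-agnostic key, used when a pocket's chain assignment is ambiguous
res_key_nochain <- function(res_id, icode) {
  paste0(res_id, "|", ifelse(is.na(icode), "", icode))
}

# pairwise squared distances between rows of two n x 3 matrices
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
}

as_xyz_matrix <- function(df) {
  m <- cbind(df$x, df$y, df$z)
  storage.mode(m) <- "double"
  m
}

stopf <- function(fmt, ..., class = NULL) {
  abort(sprintf(fmt, ...), class = class)
}
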