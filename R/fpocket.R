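# Fpocket-style geometric pockets. The standard Fpocket output layout is
# consumed as-is: <dir>/pockets/pocket<N>_atm.pdb lists the contacting
# protein atoms of pocket N and pocket<N>_vert.pqr its alpha-sphere
# centers, with the sphere radius as the last numeric field of each
# ATOM/HETATM record. Alpha-sphere detection itself is out of scope; only
# its outputs are read.

new_geometric_pocket <- function(id, spheres, atoms) {
  structure(list(id = id, spheres = as_tibble(spheres), atoms = atoms),
            class = "geometric_pocket")
}

#' @export
print.geometric_pocket <- function(x, ...) {
  cat(sprintf("<geometric_pocket> #%s: %d alpha sphere(s), %d atom(s)\n",
              paste(x$id, collapse = "+"), nrow(x$spheres), nrow(x$atoms)))
  invisible(x)
}

# parse an Fpocket vertex PQR: whitespace-separated ATOM/HETATM records
# whose last five numeric fields are x, y, z, charge, radius
read_vert_pqr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (length(lines) == 0) {
    return(tibble(x = double(), y = double(), z = double(), radius = double()))
  }
  rows <- lapply(lines, function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    nums <- suppressWarnings(as.numeric(tok))
    nums <- nums[!is.na(nums)]
    if (length(nums) < 5) {
      stopf("cannot parse PQR record in '%s': %s", path, ln,
            class = "pocketlit_io_error")
    }
    v <- tail(nums, 5)
    tibble(x = v[[1]], y = v[[2]], z = v[[3]], radius = v[[5]])
  })
  out <- bind_rows(rows)
  if (any(out$radius <= 0)) {
    stopf("non-positive alpha-sphere radius in '%s'", path,
          class = "pocketlit_io_error")
  }
  out
}

#' Read an Fpocket output directory
#'
#' Expects the standard layout `pockets/pocket<N>_atm.pdb` +
#' `pockets/pocket<N>_vert.pqr` under `path` (or those files directly in
#' `path`). A pocket missing either half of the pair is skipped with a
#' warning; an empty directory yields an empty list.
#'
#' @param path Fpocket output directory.
#' @return List of `geometric_pocket` objects ordered by pocket index, each
#'   with `id`, `spheres` (tibble `x`, `y`, `z`, `radius`) and `atoms`
#'   (atom tibble as from [read_pdb()]).
#' @export
read_fpocket_dir <- function(path) {
  pdir <- file.path(path, "pockets")
  if (!dir.exists(pdir)) pdir <- path
  if (!dir.exists(pdir)) {
    stopf("no such Fpocket directory: '%s'", path, class = "pocketlit_io_error")
  }
  atm <- list.files(pdir, pattern = "^pocket[0-9]+_atm\\.pdb$")
  vert <- list.files(pdir, pattern = "^pocket[0-9]+_vert\\.pqr$")
  idx_of <- function(f) as.integer(sub("^pocket([0-9]+)_.*$", "\\1", f))
  ids <- sort(union(idx_of(atm), idx_of(vert)))
  pockets <- list()
  for (id in ids) {
    a <- file.path(pdir, sprintf("pocket%d_atm.pdb", id))
    v <- file.path(pdir, sprintf("pocket%d_vert.pqr", id))
    if (!file.exists(a) || !file.exists(v)) {
      warn(sprintf("pocket %d: missing %s file, skipped", id,
                   if (file.exists(a)) "vert.pqr" else "atm.pdb"))
      next
    }
    pocket <- tryCatch({
      spheres <- read_vert_pqr(v)
      atoms <- read_pdb(a, keep_hetero = TRUE)
      if (nrow(spheres) == 0) stopf("pocket %d has no alpha spheres", id)
      new_geometric_pocket(id, spheres, atoms)
    }, error = function(e) {
      warn(sprintf("pocket %d unreadable (%s), skipped", id,
                   conditionMessage(e)))
      NULL
    })
    if (!is.null(pocket)) pockets[[length(pockets) + 1]] <- pocket
  }
  pockets
}

#' Fraction of a residue's atoms in contact with alpha spheres
#'
#' An atom is "in contact" when its center lies within sphere radius +
#' `contact_tol` of some sphere center of the pocket.
#'
#' @param atoms Atom tibble (heavy atoms of one residue).
#' @param spheres Alpha-sphere tibble (`x`, `y`, `z`, `radius`).
#' @param contact_tol Contact tolerance added to each radius (Angstrom).
#' @return Fraction in `[0, 1]` (0 for an empty sphere list).
#' @export
residue_contact_fraction <- function(atoms, spheres, contact_tol = 1.0) {
  stopifnot(nrow(atoms) >= 1)
  if (nrow(spheres) == 0) return(0)
  d2 <- cross_dist2(as_xyz_matrix(atoms), as_xyz_matrix(spheres))
  lim2 <- matrix((spheres$radius + contact_tol)^2, nrow(atoms),
                 nrow(spheres), byrow = TRUE)
  mean(apply(d2 <= lim2, 1, any))
}

#' Residues of a geometric pocket
#'
#' Resolves the pocket's contacting atoms to structure residues and keeps
#' those whose full heavy-atom contact fraction (computed on the
#' structure's atoms) reaches `residue_match_threshold`.
#'
#' @param pocket A `geometric_pocket`.
#' @param structure A `protein_structure`.
#' @param residue_match_threshold Minimum contact fraction (inclusive).
#' @param contact_tol Contact tolerance in Angstrom.
#' @return Residue-ref tibble with a `contact_fraction` column.
#' @export
geometric_pocket_residues <- function(pocket, structure,
                                      residue_match_threshold = 0.5,
                                      contact_tol = 1.0) {
  cand <- distinct_residues(
    pocket$atoms[, c("chain_id", "res_name", "res_id", "icode")])
  if (nrow(cand) == 0) return(mutate(cand, contact_fraction = double()))
  cand$contact_fraction <- vapply(seq_len(nrow(cand)), function(i) {
    atoms <- residue_heavy_atoms(structure, cand[i, ])
    if (nrow(atoms) == 0) atoms <- pocket$atoms[
      res_key(pocket$atoms$chain_id, pocket$atoms$res_id, pocket$atoms$icode) ==
        res_key(cand$chain_id[[i]], cand$res_id[[i]], cand$icode[[i]]), ]
    residue_contact_fraction(atoms, pocket$spheres, contact_tol = contact_tol)
  }, 0)
  filter(cand, .data$contact_fraction >= residue_match_threshold)
}

#' Select geometric pockets supported by literature pockets
#'
#' A geometric pocket is retained iff the Jaccard index between its residue
#' set and some mapped literature pocket's residue set reaches
#' `pocket_match_jaccard` (inclusive); all supporting mapped pockets are
#' recorded.
#'
#' @param geom List of `geometric_pocket` objects.
#' @param mapped A `mapped_pockets` tibble from [resolve_pockets()].
#' @param structure A `protein_structure`.
#' @param config A [pipeline_config()] list.
#' @return A `selected_pockets` tibble: `geom_id`, `pocket` (list of
#'   `geometric_pocket`), `residues` (list), `support` (list of indices
#'   into `mapped`), `best_jaccard`.
#' @export
select_pockets <- function(geom, mapped, structure,
                           config = pipeline_config()) {
  rows <- list()
  for (g in geom) {
    res <- geometric_pocket_residues(
      g, structure,
      residue_match_threshold = config$residue_match_threshold,
      contact_tol = config$contact_tol)
    keys <- residue_keyset(res)
    jac <- vapply(seq_len(nrow(mapped)), function(i) {
      jaccard(keys, residue_keyset(mapped$residues[[i]]))
    }, 0)
    support <- which(jac >= config$pocket_match_jaccard & jac > 0)
    if (length(support) > 0) {
      rows[[length(rows) + 1]] <- tibble(
        geom_id = g$id, pocket = list(g),
        residues = list(select(res, -"contact_fraction")),
        support = list(support), best_jaccard = max(jac))
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(geom_id = integer(), pocket = list(), residues = list(),
           support = list(), best_jaccard = double())
  class(out) <- c("selected_pockets", class(tibble()))
  out
}

#' Merge overlapping selected pockets
#'
#' Builds the transitive closure (union-find) of pairwise merges: two
#' selected pockets merge when their residue-set Jaccard strictly exceeds
#' `merge_overlap_threshold`, or when they share a supporting literature
#' pocket (the route by which information from different publications about
#' the same site is consolidated). A merged pocket is the union of sphere
#' sets, atoms and residues of its components.
#'
#' @param selected A `selected_pockets` tibble from [select_pockets()].
#' @param mapped The `mapped_pockets` tibble used for selection (for
#'   consolidated names/descriptions); optional.
#' @param merge_overlap_threshold Jaccard above which two pockets merge
#'   (strict).
#' @return List of merged `geometric_pocket` objects, each with a
#'   `residues` tibble, a `support` index vector, and a consolidated
#'   `label` attached.
#' @export
merge_pockets <- function(selected, mapped = NULL,
                          merge_overlap_threshold = 0.5) {
  n <- nrow(selected)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[[max(ri, rj)]] <<- min(ri, rj)
  }
  keysets <- lapply(selected$residues, residue_keyset)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      shared_support <- length(intersect(selected$support[[i]],
                                         selected$support[[j]])) > 0
      jac <- jaccard(keysets[[i]], keysets[[j]])
      if (jac > merge_overlap_threshold || shared_support) union_(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  lapply(sort(unique(roots)), function(r) {
    members <- which(roots == r)
    spheres <- distinct(bind_rows(lapply(selected$pocket[members],
                                         `[[`, "spheres")))
    atoms <- distinct(bind_rows(lapply(selected$pocket[members],
                                       `[[`, "atoms")))
    residues <- distinct_residues(bind_rows(selected$residues[members]))
    support <- sort(unique(unlist(selected$support[members])))
    merged <- new_geometric_pocket(
      id = selected$geom_id[members], spheres = spheres, atoms = atoms)
    merged$residues <- residues
    merged$support <- support
    if (!is.null(mapped) && length(support) > 0) {
      merged$label <- paste(unique(mapped$name[support]), collapse = " + ")
      merged$description <- paste(unique(mapped$description[support]),
                                  collapse = " | ")
    }
    merged
  })
}
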