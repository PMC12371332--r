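# Deterministic synthetic fixtures. Every input the pipeline consumes can
# be generated offline with known ground truth: small multi-chain
# structures with planted cavity-forming residue shells, alpha-sphere sets
# covering those cavities (written in the Fpocket output layout), a paper
# corpus (markdown documents + annotation JSONs) and canned mock-backend
# responses consistent with the planted truth. Geometry is idealized, not
# physically realistic: chains are bead strings with 5 heavy atoms per
# residue, pocket residues sit on a two-ring shell around a cavity center,
# and distinct sites are placed ~70 A apart so that every distance-based
# predicate in the pipeline has an unambiguous answer.

# fixed heavy-atom offsets (A) applied around each residue center
.atom_offsets <- matrix(c(
   0.6,  0.4,  0.0,   # N
   0.0,  0.0,  0.0,   # CA
  -0.6,  0.4,  0.0,   # C
  -0.6, -0.5,  0.4,   # O
   0.0, -0.6, -0.5    # CB
), ncol = 3, byrow = TRUE)
.atom_names <- c("N", "CA", "C", "O", "CB")
.atom_elements <- c("N", "C", "C", "O", "C")

# shell geometry around a cavity center
.shell_radius_xz <- 4.0
.shell_dy <- 2.5
.cavity_sphere_radius <- 4.6
.site_spacing <- 70
.backbone_step <- 3
.chain_y_gap <- 100

#' Specify a synthetic fixture
#'
#' @param seed Integer seed; fully determines every generated artifact.
#' @param n_chains Number of (identical-sequence) chains.
#' @param chain_len Residues per chain.
#' @param pockets List of planted pockets; each element is a list with
#'   `name`, `ids` (residue numbers within `1:chain_len`) and `type`
#'   (`"single"` — replicated in every chain around its own cavity — or
#'   `"interface"` — residues split between chains 1 and 2 around one
#'   shared cavity).
#' @param decoys Number of decoy alpha-sphere pockets placed on ordinary
#'   backbone residues.
#' @param target_name Target protein name used in documents/annotations.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, n_chains = 2, chain_len = 30,
                         pockets = list(list(name = "inhibitor site",
                                             ids = 10:15, type = "single")),
                         decoys = 1, target_name = "Synthetic kinase 1") {
  stopifnot(n_chains >= 1, chain_len >= 5)
  for (p in pockets) {
    stopifnot(all(p$ids >= 1), all(p$ids <= chain_len))
    if (identical(p$type, "interface") && n_chains < 2) {
      abort("interface pockets need at least two chains")
    }
  }
  structure(list(seed = seed, n_chains = n_chains, chain_len = chain_len,
                 pockets = pockets, decoys = decoys,
                 target_name = target_name),
            class = "fixture_spec")
}

# positions of the m shell residues around a cavity center
shell_positions <- function(center, m) {
  t <- seq_len(m) - 1
  theta <- 2 * pi * t / m
  cbind(center[[1]] + .shell_radius_xz * cos(theta),
        center[[2]] + ifelse(t %% 2 == 0, .shell_dy, -.shell_dy),
        center[[3]] + .shell_radius_xz * sin(theta))
}

#' Generate a synthetic structure with planted pockets
#'
#' Chains are identical-sequence bead strings laid along parallel lines
#' ~100 A apart; each planted pocket relocates its residues onto a concave
#' two-ring shell around a dedicated cavity center (one center per chain
#' for `"single"` pockets, one shared center straddling chains 1 and 2 for
#' `"interface"` pockets). Cavity centers are ~70 A apart, far from the
#' backbone lines.
#'
#' @param spec A [fixture_spec()].
#' @return List with `structure` (a `protein_structure`), `truth` (tibble
#'   of planted sites: `pocket`, `site`, `type`, `center`, `residues`),
#'   `lit_pockets` (pocket table of the literature-level ground truth) and
#'   `spec`.
#' @export
make_structure <- function(spec) {
  set.seed(spec$seed)
  chains <- LETTERS[seq_len(spec$n_chains)]
  seq_names <- sample(names(.aa3), spec$chain_len, replace = TRUE)
  # residue centers: backbone default, overridden for planted residues
  centers <- list()
  for (ci in seq_along(chains)) {
    centers[[chains[[ci]]]] <- cbind(
      .backbone_step * seq_len(spec$chain_len),
      rep(.chain_y_gap * ci, spec$chain_len),
      rep(0, spec$chain_len))
  }
  truth <- list()
  site_idx <- 0
  for (pi in seq_along(spec$pockets)) {
    p <- spec$pockets[[pi]]
    if (identical(p$type, "interface")) {
      site_idx <- site_idx + 1
      center <- c(.site_spacing * site_idx, -60, 0)
      m <- length(p$ids)
      half <- ceiling(m / 2)
      owner <- c(rep(chains[[1]], half), rep(chains[[2]], m - half))
      pos <- shell_positions(center, m)
      for (k in seq_len(m)) {
        centers[[owner[[k]]]][p$ids[[k]], ] <- pos[k, ]
      }
      truth[[length(truth) + 1]] <- tibble(
        pocket = p$name, site = site_idx, type = "interface",
        center = list(center),
        residues = list(residue_ref(owner, seq_names[p$ids], p$ids)))
    } else {
      for (ci in seq_along(chains)) {
        site_idx <- site_idx + 1
        center <- c(.site_spacing * site_idx, -60, 0)
        pos <- shell_positions(center, length(p$ids))
        for (k in seq_along(p$ids)) {
          centers[[chains[[ci]]]][p$ids[[k]], ] <- pos[k, ]
        }
        truth[[length(truth) + 1]] <- tibble(
          pocket = p$name, site = site_idx, type = "single",
          center = list(center),
          residues = list(residue_ref(chains[[ci]], seq_names[p$ids], p$ids)))
      }
    }
  }
  atoms <- list()
  serial <- 0
  for (ci in seq_along(chains)) {
    for (ri in seq_len(spec$chain_len)) {
      ctr <- centers[[chains[[ci]]]][ri, ]
      for (ai in seq_len(nrow(.atom_offsets))) {
        serial <- serial + 1
        atoms[[serial]] <- tibble(
          chain_id = chains[[ci]], res_name = seq_names[[ri]],
          res_id = ri, icode = NA_character_, serial = serial,
          atom_name = .atom_names[[ai]], element = .atom_elements[[ai]],
          x = ctr[[1]] + .atom_offsets[ai, 1],
          y = ctr[[2]] + .atom_offsets[ai, 2],
          z = ctr[[3]] + .atom_offsets[ai, 3],
          occupancy = 1, is_heavy = TRUE)
      }
    }
  }
  atoms <- bind_rows(atoms)
  atoms$vdw_radius <- suppressWarnings(vdw_radius(atoms$element))
  # literature-level pockets: chain hints as planted (interface pockets
  # carry both chains; single pockets are hinted on chain A only, the way
  # a paper would describe one subunit of a homomer)
  lit <- lapply(spec$pockets, function(p) {
    if (identical(p$type, "interface")) {
      m <- length(p$ids); half <- ceiling(m / 2)
      owner <- c(rep(chains[[1]], half), rep(chains[[2]], m - half))
      residue_ref(owner, seq_names[p$ids], p$ids)
    } else {
      residue_ref(chains[[1]], seq_names[p$ids], p$ids)
    }
  })
  list(
    structure = new_protein_structure(atoms),
    truth = bind_rows(truth),
    lit_pockets = pocket_table(
      name = vapply(spec$pockets, `[[`, "", "name"),
      description = sprintf("Planted %s pocket of %s",
                            vapply(spec$pockets, `[[`, "", "type"),
                            spec$target_name),
      residues = lit),
    spec = spec)
}

#' Generate alpha-sphere pockets for a synthetic structure
#'
#' Writes one Fpocket-layout pocket per planted cavity (two concentric
#' spheres at the cavity center that put every planted residue in contact)
#' plus `decoys` decoy pockets on unplanted backbone stretches of chain A,
#' and serializes everything under `dir/pockets/` so that
#' [read_fpocket_dir()] round-trips it.
#'
#' @param fixture Output of [make_structure()].
#' @param dir Output directory (created if needed).
#' @return List of `geometric_pocket` objects (planted sites first, then
#'   decoys), invisibly; files are the primary output.
#' @export
make_alpha_spheres <- function(fixture, dir) {
  spec <- fixture$spec
  structure_ <- fixture$structure
  dir.create(file.path(dir, "pockets"), recursive = TRUE, showWarnings = FALSE)
  pockets <- list()
  pid <- 0
  write_pocket <- function(spheres, atoms) {
    pid <<- pid + 1
    g <- new_geometric_pocket(pid, spheres, atoms)
    write_pdb(atoms, file.path(dir, "pockets", sprintf("pocket%d_atm.pdb", pid)))
    pqr <- sprintf(
      "ATOM  %5d APOL STP C%4d    %8.3f%8.3f%8.3f %7.2f %6.3f",
      seq_len(nrow(spheres)), pid, spheres$x, spheres$y, spheres$z,
      0, spheres$radius)
    writeLines(c("HEADER synthetic alpha-sphere vertices", pqr),
               file.path(dir, "pockets", sprintf("pocket%d_vert.pqr", pid)))
    pockets[[length(pockets) + 1]] <<- g
  }
  for (si in seq_len(nrow(fixture$truth))) {
    center <- fixture$truth$center[[si]]
    res <- fixture$truth$residues[[si]]
    atoms <- residue_heavy_atoms(structure_, res)
    spheres <- tibble(
      x = center[[1]], y = center[[2]], z = center[[3]],
      radius = c(.cavity_sphere_radius, 2.0))
    write_pocket(spheres, atoms)
  }
  planted_ids <- sort(unique(unlist(lapply(spec$pockets, `[[`, "ids"))))
  free <- setdiff(seq_len(spec$chain_len), planted_ids)
  for (d in seq_len(spec$decoys %||% 0)) {
    if (length(free) < 4) break
    ids <- free[seq_len(min(4, length(free)))]
    free <- setdiff(free, ids)
    res <- structure_residues(structure_, chain_id = "A")
    res <- res[res$res_id %in% ids, ]
    atoms <- residue_heavy_atoms(structure_, res)
    mid <- colMeans(as_xyz_matrix(atoms))
    spheres <- tibble(x = mid[[1]], y = mid[[2]] - 2, z = mid[[3]] + 2,
                      radius = 3.5)
    write_pocket(spheres, atoms)
  }
  invisible(pockets)
}

# templated paper text mentioning a set of pockets at residue level
render_paper_text <- function(target_name, pockets, relevant = TRUE) {
  if (!relevant) {
    return(paste0(
      "# Expression and purification of ", target_name, "\n\n",
      "We report an optimized protocol for the recombinant expression of ",
      target_name, " and characterize its thermal stability. ",
      "No structural analysis of ligand binding was performed; binding-site ",
      "residues are not discussed in this work.\n"))
  }
  body <- vapply(seq_len(nrow(pockets)), function(i) {
    toks <- format_residue_token(pockets$residues[[i]])
    paste0(
      "## ", pockets$name[[i]], "\n\n",
      "Mutagenesis and structural analysis of ", target_name,
      " show that the ", pockets$name[[i]],
      " accommodates the ligand through direct contacts with residues ",
      paste(toks, collapse = ", "), ". ",
      "Substitution of any of these residues strongly reduced ligand binding.\n")
  }, "")
  paste0("# Ligand recognition by ", target_name, "\n\n",
         paste(body, collapse = "\n"))
}

pockets_to_json <- function(pockets, malformed_tokens = FALSE) {
  entries <- lapply(seq_len(nrow(pockets)), function(i) {
    toks <- as.list(format_residue_token(pockets$residues[[i]]))
    if (malformed_tokens && i == 1) {
      toks <- c(toks, list("A:XYZ:12", "A:TYR:abc"))
    }
    list(name = pockets$name[[i]],
         description = pockets$description[[i]],
         residues = toks)
  })
  jsonlite::toJSON(list(pockets = entries), auto_unbox = TRUE, pretty = TRUE)
}

fenced <- function(json) paste0("```json\n", json, "\n```")

#' Generate a paper corpus with canned mock responses
#'
#' Emits the three benchmark tiers for the fixture's target: negative
#' controls (no binding sites), one single-site document per planted
#' pocket, and one multi-site document when two or more pockets are
#' planted. Annotations match the planted truth; mock responses are
#' consistent with it, optionally corrupted to exercise the refinement and
#' validation paths (the refinement response always restores the truth).
#'
#' @param fixture Output of [make_structure()].
#' @param n_negative Number of negative-control documents.
#' @param noise List of corruption knobs applied to the *extraction*
#'   responses: `split_pockets` (split each pocket into two fragments),
#'   `hallucinate` (append residues absent from the truth),
#'   `malformed_tokens` (append syntactically invalid residue tokens).
#' @return List with `documents`, `annotations`, `responses` (named list
#'   for [mock_backend()]), and `truth_by_doc`.
#' @export
make_corpus <- function(fixture, n_negative = 1,
                        noise = list(split_pockets = FALSE,
                                     hallucinate = FALSE,
                                     malformed_tokens = FALSE)) {
  target <- fixture$spec$target_name
  lit <- fixture$lit_pockets
  documents <- list(); annotations <- list(); responses <- list()
  truth_by_doc <- list()
  add_doc <- function(doc_id, pockets, relevant) {
    documents[[length(documents) + 1]] <<- paper_document(
      doc_id, target, render_paper_text(target, pockets, relevant))
    annotations[[length(annotations) + 1]] <<- paper_annotation(
      doc_id, target, relevant,
      if (relevant) pockets else pocket_table())
    truth_by_doc[[doc_id]] <<- pockets
    responses[[paste0("relevance::", doc_id)]] <<- fenced(jsonlite::toJSON(
      list(relevant = relevant,
           reasons = if (relevant) "residue-level site description"
                     else "no binding-site residues reported"),
      auto_unbox = TRUE))
    if (relevant) {
      corrupted <- corrupt_pockets(pockets, noise)
      responses[[paste0("extract::", doc_id)]] <<- fenced(
        pockets_to_json(corrupted,
                        malformed_tokens = isTRUE(noise$malformed_tokens)))
      responses[[paste0("refine::", doc_id)]] <<- fenced(pockets_to_json(pockets))
    }
  }
  for (k in seq_len(n_negative)) {
    add_doc(sprintf("neg%02d", k), pocket_table(), FALSE)
  }
  for (i in seq_len(nrow(lit))) {
    add_doc(sprintf("single%02d", i), lit[i, ], TRUE)
  }
  if (nrow(lit) >= 2) add_doc("multi01", lit, TRUE)
  list(documents = documents, annotations = annotations,
       responses = responses, truth_by_doc = truth_by_doc)
}

# apply scripted corruptions to an extraction response
corrupt_pockets <- function(pockets, noise) {
  out <- pockets
  if (isTRUE(noise$split_pockets) && nrow(out) > 0) {
    rows <- list()
    for (i in seq_len(nrow(out))) {
      res <- out$residues[[i]]
      if (nrow(res) >= 4) {
        half <- floor(nrow(res) / 2)
        rows[[length(rows) + 1]] <- tibble(
          name = paste0(out$name[[i]], " (part 1)"),
          description = out$description[[i]],
          residues = list(res[seq_len(half), ]))
        rows[[length(rows) + 1]] <- tibble(
          name = paste0(out$name[[i]], " (part 2)"),
          description = out$description[[i]],
          residues = list(res[(half + 1):nrow(res), ]))
      } else {
        rows[[length(rows) + 1]] <- out[i, ]
      }
    }
    out <- bind_rows(rows)
  }
  if (isTRUE(noise$hallucinate) && nrow(out) > 0) {
    out$residues[[1]] <- bind_rows(
      out$residues[[1]], residue_ref("A", "GLY", 999L))
  }
  out
}

#' Write a complete fixture bundle to disk
#'
#' Emits the structure PDB, the Fpocket-layout alpha-sphere directory, the
#' markdown corpus, annotation JSONs and mock-backend response files.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @param n_negative Negative-control documents in the corpus.
#' @return The fixture list from [make_structure()], augmented with
#'   `corpus` and `paths`, invisibly.
#' @export
write_fixture_bundle <- function(spec, dir, n_negative = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fixture <- make_structure(spec)
  write_pdb(fixture$structure, file.path(dir, "structure.pdb"))
  make_alpha_spheres(fixture, file.path(dir, "fpocket"))
  corpus <- make_corpus(fixture, n_negative = n_negative)
  dir.create(file.path(dir, "papers"), showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), showWarnings = FALSE)
  for (doc in corpus$documents) {
    writeLines(doc$text, file.path(dir, "papers", paste0(doc$doc_id, ".md")))
  }
  for (ann in corpus$annotations) {
    write_annotation(ann, file.path(dir, "annotations",
                                    paste0(ann$doc_id, ".json")))
  }
  write_mock_responses(corpus$responses, file.path(dir, "responses"))
  fixture$corpus <- corpus
  fixture$paths <- list(
    pdb = file.path(dir, "structure.pdb"),
    fpocket = file.path(dir, "fpocket"),
    papers = file.path(dir, "papers"),
    annotations = file.path(dir, "annotations"),
    responses = file.path(dir, "responses"))
  invisible(fixture)
}
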