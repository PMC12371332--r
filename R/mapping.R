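# Residue-to-structure mapping. Literature residue lists rarely map
# cleanly onto a specific PDB structure (engineered constructs, numbering
# errors, wrong or missing chain ids), so mapping proceeds in stages:
# (i) candidate chains are found by positional sequence similarity,
# (ii) residues are mapped onto every candidate chain and spatially
# clustered with MeanShift, (iii) clusters are matched back to the
# literature pocket by residue overlap, (iv) a matched cluster spanning
# several chains becomes one interface pocket, (v) otherwise the pocket is
# replicated onto each candidate chain (homomer case).

#' Positional similarity between a pocket and a chain
#'
#' The fraction of pocket residues whose (residue number, insertion code)
#' exists in the chain with an agreeing residue name. This deliberately
#' ignores the literature chain id, which is frequently wrong or absent.
#' An optional constant-offset scan (disabled by default) handles uniformly
#' renumbered constructs.
#'
#' @param pocket_residues Residue-ref tibble of the literature pocket.
#' @param structure A `protein_structure`.
#' @param chain_id Chain to score against.
#' @param offset Constant added to pocket residue numbers before lookup.
#' @return Fraction in `[0, 1]`.
#' @export
chain_similarity <- function(pocket_residues, structure, chain_id, offset = 0L) {
  if (is.null(pocket_residues) || nrow(pocket_residues) == 0) {
    abort("pocket has no residues", class = "pocketlit_validation_error")
  }
  res <- structure_residues(structure, chain_id = chain_id)
  if (nrow(res) == 0) {
    stopf("no chain '%s' in structure", chain_id, class = "pocketlit_lookup_error")
  }
  chain_key <- res_key_nochain(res$res_id, res$icode)
  chain_name <- setNames(res$res_name, chain_key)
  pocket <- distinct_residues(pocket_residues)
  pkey <- res_key_nochain(pocket$res_id + as.integer(offset), pocket$icode)
  hit <- pkey %in% chain_key & pocket$res_name == chain_name[pkey]
  mean(ifelse(is.na(hit), FALSE, hit))
}

#' Assign candidate chains to a pocket
#'
#' Scores every chain with [chain_similarity()] and keeps those at or above
#' `chain_threshold` (inclusive). The literature chain id is used only as a
#' tie-breaking hint in the ordering, never as a hard constraint. An
#' optional `offset_scan` tries constant residue-numbering offsets and uses
#' the best-scoring one per chain.
#'
#' @param pocket_residues Residue-ref tibble.
#' @param structure A `protein_structure`.
#' @param chain_threshold Minimum similarity (default 0.6, inclusive).
#' @param offset_scan Integer offsets to try (e.g. `-5:5`); `NULL` disables.
#' @return A `chain_assignment` tibble: `chain_id`, `similarity`, `offset`,
#'   ordered by decreasing similarity with literature-hinted chains first
#'   among ties.
#' @export
assign_chains <- function(pocket_residues, structure, chain_threshold = 0.6,
                          offset_scan = NULL) {
  chains <- structure_chains(structure)
  offsets <- c(0L, setdiff(as.integer(offset_scan %||% integer()), 0L))
  score <- lapply(chains, function(ch) {
    sims <- vapply(offsets, function(off) {
      chain_similarity(pocket_residues, structure, ch, offset = off)
    }, 0)
    best <- which.max(sims)
    tibble(chain_id = ch, similarity = sims[[best]], offset = offsets[[best]])
  })
  score <- bind_rows(score)
  hinted <- unique(pocket_residues$chain_id)
  score$hinted <- score$chain_id %in% hinted
  score <- arrange(score, desc(.data$similarity), desc(.data$hinted),
                   .data$chain_id)
  kept <- filter(score, .data$similarity >= chain_threshold)
  if (nrow(kept) == 0) {
    abort(
      sprintf("pocket is unmappable: best chain similarity %.2f (< %.2f)",
              max(score$similarity), chain_threshold),
      class = "pocketlit_unmappable_pocket",
      best_score = max(score$similarity))
  }
  select(kept, "chain_id", "similarity", "offset")
}

# map pocket residues onto one candidate chain: the structure residues at
# matching (number, icode) with agreeing name
map_pocket_to_chain <- function(pocket_residues, structure, chain_id,
                                offset = 0L) {
  res <- structure_residues(structure, chain_id = chain_id)
  pocket <- distinct_residues(pocket_residues)
  key <- res_key_nochain(res$res_id, res$icode)
  pkey <- res_key_nochain(pocket$res_id + as.integer(offset), pocket$icode)
  idx <- match(pkey, key)
  ok <- !is.na(idx) & pocket$res_name == res$res_name[idx]
  ok[is.na(ok)] <- FALSE
  res[idx[ok], c("chain_id", "res_name", "res_id", "icode")]
}

#' Cluster structure residues spatially
#'
#' Each residue is represented by its heavy-atom centroid and clustered
#' with [mean_shift()]. Input order (hence clustering) is deterministic.
#'
#' @param structure A `protein_structure`.
#' @param residues Residue-ref tibble of structure-resolved residues.
#' @param bandwidth MeanShift bandwidth in Angstrom.
#' @return A `residue_cluster` tibble: one row per cluster with `cluster`
#'   id, `members` (residue-ref tibble), `centroid` (length-3 vector) and
#'   `chains` (character vector of chains spanned).
#' @export
cluster_residues <- function(structure, residues, bandwidth = 8) {
  if (nrow(residues) == 0) {
    abort("no residues to cluster", class = "pocketlit_validation_error")
  }
  cent <- residue_centroids(structure, residues)
  # preserve the caller's residue order for determinism
  ord <- match(res_key(residues$chain_id, residues$res_id, residues$icode),
               res_key(cent$chain_id, cent$res_id, cent$icode))
  ord <- ord[!is.na(ord)]
  cent <- cent[ord, ]
  ms <- mean_shift(as_xyz_matrix(cent), bandwidth = bandwidth)
  ids <- sort(unique(ms$cluster))
  rows <- lapply(ids, function(k) {
    mem <- cent[ms$cluster == k, ]
    tibble(
      cluster = k,
      members = list(select(mem, "chain_id", "res_name", "res_id", "icode")),
      centroid = list(c(mean(mem$x), mean(mem$y), mean(mem$z))),
      chains = list(unique(mem$chain_id)))
  })
  bind_rows(rows)
}

#' Overlap between a residue cluster and a literature pocket
#'
#' The fraction of the pocket's residues represented in the cluster,
#' compared chain-agnostically (on residue number + insertion code + name)
#' because the pocket's chain assignment is in general ambiguous across
#' candidate chains. Matched iff the overlap reaches `cluster_threshold`
#' (inclusive).
#'
#' @param cluster_members Residue-ref tibble of cluster members.
#' @param pocket_residues Residue-ref tibble of the literature pocket.
#' @param cluster_threshold Match threshold (default 0.7).
#' @return List with `overlap` and `matched`.
#' @export
match_cluster_to_pocket <- function(cluster_members, pocket_residues,
                                    cluster_threshold = 0.7) {
  stopifnot(nrow(cluster_members) > 0)
  pocket <- distinct_residues(pocket_residues)
  pkey <- paste0(res_key_nochain(pocket$res_id, pocket$icode), "|",
                 pocket$res_name)
  ckey <- unique(paste0(
    res_key_nochain(cluster_members$res_id, cluster_members$icode), "|",
    cluster_members$res_name))
  overlap <- length(intersect(pkey, ckey)) / length(pkey)
  list(overlap = overlap, matched = overlap >= cluster_threshold)
}

#' Map literature pockets onto a structure
#'
#' Runs the full mapping workflow for each extracted pocket: candidate
#' chains by sequence similarity, residue mapping onto every candidate
#' chain, joint MeanShift clustering of the mapped residues, and
#' cluster-to-pocket matching. A matched cluster spanning two or more
#' chains yields a single interface pocket carrying the cluster's
#' residues; otherwise the originally mapped residues are replicated once
#' per candidate chain. Unmappable pockets are reported and skipped.
#'
#' @param pockets Extracted-pocket tibble (`name`, `description`,
#'   `residues`, optionally `doc_id`).
#' @param structure A `protein_structure`.
#' @param config A [pipeline_config()] list (chain/cluster thresholds,
#'   bandwidth, offset scan).
#' @return A `mapped_pockets` tibble: one row per emitted pocket with
#'   columns `name`, `description`, `source`, `interface`, `chains` (list),
#'   `residues` (list of structure-resolved residue-ref tibbles) and
#'   `n_residues`; skipped pockets are recorded in the `skipped` attribute.
#' @export
resolve_pockets <- function(pockets, structure, config = pipeline_config()) {
  out <- list()
  skipped <- tibble(name = character(), reason = character())
  for (i in seq_len(nrow(pockets))) {
    name <- pockets$name[[i]]
    desc <- pockets$description[[i]]
    src <- if ("doc_id" %in% names(pockets)) pockets$doc_id[[i]] else NA_character_
    residues <- pockets$residues[[i]]
    assignment <- tryCatch(
      assign_chains(residues, structure,
                    chain_threshold = config$chain_match_threshold,
                    offset_scan = config$offset_scan),
      error = function(e) e)
    if (inherits(assignment, "error")) {
      warn(sprintf("skipping pocket '%s': %s", name, conditionMessage(assignment)))
      skipped <- bind_rows(skipped,
                           tibble(name = name,
                                  reason = conditionMessage(assignment)))
      next
    }
    mapped_per_chain <- lapply(seq_len(nrow(assignment)), function(k) {
      map_pocket_to_chain(residues, structure, assignment$chain_id[[k]],
                          offset = assignment$offset[[k]])
    })
    all_mapped <- distinct_residues(bind_rows(mapped_per_chain))
    if (nrow(all_mapped) == 0) {
      skipped <- bind_rows(skipped,
                           tibble(name = name, reason = "no residues mapped"))
      next
    }
    clusters <- cluster_residues(structure, all_mapped,
                                 bandwidth = config$bandwidth)
    interface_row <- NULL
    for (k in seq_len(nrow(clusters))) {
      m <- match_cluster_to_pocket(clusters$members[[k]], residues,
                                   cluster_threshold = config$cluster_match_threshold)
      if (m$matched && length(clusters$chains[[k]]) >= 2) {
        interface_row <- tibble(
          name = name, description = desc, source = src, interface = TRUE,
          chains = list(sort(clusters$chains[[k]])),
          residues = list(clusters$members[[k]]),
          n_residues = nrow(clusters$members[[k]]))
        break  # first matched multi-chain cluster wins
      }
    }
    if (!is.null(interface_row)) {
      out[[length(out) + 1]] <- interface_row
    } else {
      for (k in seq_len(nrow(assignment))) {
        mem <- mapped_per_chain[[k]]
        if (nrow(mem) == 0) next
        out[[length(out) + 1]] <- tibble(
          name = name, description = desc, source = src, interface = FALSE,
          chains = list(assignment$chain_id[[k]]),
          residues = list(mem), n_residues = nrow(mem))
      }
    }
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(name = character(), description = character(), source = character(),
           interface = logical(), chains = list(), residues = list(),
           n_residues = integer())
  attr(res, "skipped") <- skipped
  class(res) <- c("mapped_pockets", class(tibble()))
  res
}

#' Export mapped pockets with atom coordinates
#'
#' Serializes mapped pockets to JSON, including per-residue heavy-atom
#' coordinates resolved against the structure, the pocket name and its
#' literature description.
#'
#' @param mapped A `mapped_pockets` tibble from [resolve_pockets()].
#' @param structure The `protein_structure` the pockets were mapped onto.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_mapped_pockets <- function(mapped, structure, path) {
  payload <- lapply(seq_len(nrow(mapped)), function(i) {
    res <- mapped$residues[[i]]
    atoms <- residue_heavy_atoms(structure, res)
    list(
      name = mapped$name[[i]],
      description = mapped$description[[i]],
      interface = mapped$interface[[i]],
      chains = as.list(mapped$chains[[i]]),
      residues = lapply(seq_len(nrow(res)), function(j) {
        sel <- atoms$chain_id == res$chain_id[[j]] &
          atoms$res_id == res$res_id[[j]] &
          (is.na(res$icode[[j]]) & is.na(atoms$icode) |
             !is.na(atoms$icode) & atoms$icode %in% res$icode[[j]])
        a <- atoms[sel, ]
        list(token = format_residue_token(res[j, ]),
             atoms = lapply(seq_len(nrow(a)), function(t) {
               list(name = a$atom_name[[t]], element = a$element[[t]],
                    xyz = c(a$x[[t]], a$y[[t]], a$z[[t]]))
             }))
      }))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
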