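test_that("chain similarity counts positional id+name agreement", {
  fx <- make_structure(default_fixture(seed = 21, n_chains = 1))
  s <- fx$structure
  res <- structure_residues(s, "A")
  # 5 residues: 3 exact, 1 with a wrong name, 1 with an absent id -> 0.6
  pocket <- residue_ref(
    "A",
    c(res$res_name[1:3], "TRP", "GLY"),
    c(res$res_id[1:3], res$res_id[4], 999L))
  if (res$res_name[4] == "TRP") pocket$res_name[4] <- "PHE"
  expect_equal(chain_similarity(pocket, s, "A"), 0.6)
  # all present and agreeing -> 1.0
  full <- residue_ref("A", res$res_name[1:5], res$res_id[1:5])
  expect_equal(chain_similarity(full, s, "A"), 1.0)
  # numbering entirely out of range -> 0.0
  off <- residue_ref("A", res$res_name[1:5], res$res_id[1:5] + 500L)
  expect_equal(chain_similarity(off, s, "A"), 0)
  # the offset scan recovers a constant renumbering
  expect_equal(chain_similarity(full, s, "A", offset = 0), 1)
  shifted <- residue_ref("A", res$res_name[1:5], res$res_id[1:5] + 3L)
  expect_equal(chain_similarity(shifted, s, "A", offset = -3L), 1)
  expect_error(chain_similarity(residue_ref(character(), character(), integer()),
                                s, "A"),
               class = "pocketlit_validation_error")
})

test_that("chain assignment is inclusive at 0.6 and lists all equivalent chains", {
  fx <- make_structure(default_fixture(seed = 22, n_chains = 2))
  s <- fx$structure
  res <- structure_residues(s, "A")
  # homodimer: both identical chains qualify at similarity 1.0
  full <- residue_ref("A", res$res_name[1:5], res$res_id[1:5])
  asg <- assign_chains(full, s, chain_threshold = 0.6)
  expect_setequal(asg$chain_id, c("A", "B"))
  expect_equal(asg$similarity, c(1, 1))

  # a pocket scoring exactly at the threshold is kept (inclusive)
  pocket5 <- residue_ref(
    "A", c(res$res_name[1:3], "ZZZ1", "ZZZ2"),
    c(res$res_id[1:3], 998L, 999L))
  pocket5$res_name[4:5] <- c("GLY", "GLY")
  expect_equal(chain_similarity(pocket5, s, "A"), 0.6)
  asg5 <- assign_chains(pocket5, s, chain_threshold = 0.6)
  expect_true("A" %in% asg5$chain_id)

  # nothing passes -> unmappable error carrying the best score
  bad <- residue_ref("A", rep("GLY", 5), 900:904)
  err <- tryCatch(assign_chains(bad, s), error = function(e) e)
  expect_s3_class(err, "pocketlit_unmappable_pocket")
  expect_equal(err$best_score, 0)

  # raising the threshold never adds candidate chains (monotonicity)
  for (thr in c(0.2, 0.4, 0.6, 0.8)) {
    lo <- nrow(assign_chains(full, s, chain_threshold = thr))
    hi <- tryCatch(nrow(assign_chains(full, s, chain_threshold = thr + 0.2)),
                   error = function(e) 0L)
    expect_true(hi <= lo)
  }
})

test_that("mean shift finds the planted number of spatial groups deterministically", {
  # two groups ~50 A apart with bandwidth 8 -> 2 clusters
  g1 <- matrix(rnorm(30, 0, 1), ncol = 3)
  g2 <- matrix(rnorm(30, 0, 1), ncol = 3) + 50
  ms <- mean_shift(rbind(g1, g2), bandwidth = 8)
  expect_equal(length(unique(ms$cluster)), 2)
  expect_equal(length(unique(ms$cluster[1:10])), 1)
  # single point -> its own cluster
  expect_equal(mean_shift(matrix(1:3, 1), bandwidth = 8)$cluster, 1L)
  # everything within 2 A at bandwidth 8 -> 1 cluster
  tight <- matrix(runif(30, 0, 2), ncol = 3)
  expect_equal(length(unique(mean_shift(tight, bandwidth = 8)$cluster)), 1)
  # determinism: identical input -> identical output
  expect_identical(mean_shift(rbind(g1, g2), bandwidth = 8),
                   mean_shift(rbind(g1, g2), bandwidth = 8))
})

test_that("cluster-to-pocket overlap is normalized by pocket size and inclusive at 0.7", {
  pocket <- residue_ref("A", rep("GLY", 10), 1:10)
  all_in <- residue_ref("B", rep("GLY", 10), 1:10)  # chain-agnostic compare
  m <- match_cluster_to_pocket(all_in, pocket)
  expect_equal(m$overlap, 1.0)
  expect_true(m$matched)
  seven <- residue_ref("B", rep("GLY", 7), 1:7)
  m7 <- match_cluster_to_pocket(seven, pocket)
  expect_equal(m7$overlap, 0.7)
  expect_true(m7$matched)  # inclusive threshold
  one <- residue_ref("B", "GLY", 1)
  m1 <- match_cluster_to_pocket(one, pocket)
  expect_equal(m1$overlap, 0.1)
  expect_false(m1$matched)
})

test_that("homotetramer pockets replicate once per chain", {
  spec <- fixture_spec(seed = 31, n_chains = 4, chain_len = 25,
                       pockets = list(list(name = "VSD4 site", ids = 8:13,
                                           type = "single")),
                       decoys = 0)
  fx <- make_structure(spec)
  mapped <- resolve_pockets(fx$lit_pockets, fx$structure)
  expect_equal(nrow(mapped), 4)
  expect_false(any(mapped$interface))
  expect_setequal(unlist(mapped$chains), c("A", "B", "C", "D"))
  # each replica carries the full planted residue set on its own chain
  for (i in seq_len(nrow(mapped))) {
    expect_equal(sort(mapped$residues[[i]]$res_id), 8:13)
    expect_equal(unique(mapped$residues[[i]]$chain_id), mapped$chains[[i]])
  }
  # residue conservation: each mapped residue appears in exactly one replica
  keys <- unlist(lapply(mapped$residues, function(r)
    pocketlit:::res_key(r$chain_id, r$res_id, r$icode)))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("interface pockets are detected as one multi-chain pocket", {
  spec <- fixture_spec(seed = 32, n_chains = 2, chain_len = 30,
                       pockets = list(list(name = "etomidate site",
                                           ids = c(5, 6, 7, 20, 21, 22),
                                           type = "interface")),
                       decoys = 0)
  fx <- make_structure(spec)
  mapped <- resolve_pockets(fx$lit_pockets, fx$structure)
  expect_equal(nrow(mapped), 1)
  expect_true(mapped$interface[[1]])
  expect_setequal(mapped$chains[[1]], c("A", "B"))
  # recovers the planted residue set exactly
  planted <- fx$truth$residues[[1]]
  expect_equal(jaccard(mapped$residues[[1]], planted), 1)
  # the interface residues really straddle the chains in space
  atoms <- pocketlit:::residue_heavy_atoms(fx$structure, mapped$residues[[1]])
  a <- atoms[atoms$chain_id == "A", ]; b <- atoms[atoms$chain_id == "B", ]
  d2 <- pocketlit:::cross_dist2(cbind(a$x, a$y, a$z), cbind(b$x, b$y, b$z))
  expect_true(min(sqrt(d2)) < 8)
})

test_that("a monomer pocket maps to a single replica equal to its input", {
  fx <- make_structure(default_fixture(seed = 33, n_chains = 1, decoys = 0))
  mapped <- resolve_pockets(fx$lit_pockets, fx$structure)
  expect_equal(nrow(mapped), 1)
  expect_false(mapped$interface[[1]])
  expect_equal(jaccard(mapped$residues[[1]], fx$lit_pockets$residues[[1]]), 1)
  # unmappable pockets are skipped with a report, not fatal
  junk <- pocket_table("ghost", "not in structure", list("A:GLY:500"))
  junk$doc_id <- "x"; junk$stage <- "refined"
  both <- dplyr::bind_rows(fx$lit_pockets[, c("name", "description", "residues")],
                           junk[, c("name", "description", "residues")])
  expect_warning(m2 <- resolve_pockets(both, fx$structure), "unmappable")
  expect_equal(nrow(m2), 1)
  expect_equal(attr(m2, "skipped")$name, "ghost")
})

test_that("mapped-pocket JSON export includes per-residue atom coordinates", {
  fx <- make_structure(default_fixture(seed = 34, n_chains = 1, decoys = 0))
  mapped <- resolve_pockets(fx$lit_pockets, fx$structure)
  path <- tempfile(fileext = ".json")
  write_mapped_pockets(mapped, fx$structure, path)
  out <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_length(out, 1)
  expect_equal(out[[1]]$name, "inhibitor site")
  expect_length(out[[1]]$residues, 6)
  expect_length(out[[1]]$residues[[1]]$atoms[[1]]$xyz, 3)
})
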