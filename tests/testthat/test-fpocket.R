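write_min_fpocket <- function(dir) {
  dir.create(file.path(dir, "pockets"), recursive = TRUE)
  atm <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       2.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   2       2.000   1.500   0.000  1.00  0.00           C",
    "END")
  vert <- c(
    "HEADER fpocket vertices",
    "ATOM      1 APOL STP C   1       1.000   0.500   0.000    0.00  1.800",
    "ATOM      2 APOL STP C   1       1.500   0.000   0.500    0.00  2.100")
  writeLines(atm, file.path(dir, "pockets", "pocket1_atm.pdb"))
  writeLines(vert, file.path(dir, "pockets", "pocket1_vert.pqr"))
  dir
}

test_that("a minimal Fpocket layout reads into spheres and atoms", {
  dir <- write_min_fpocket(tempfile())
  pockets <- read_fpocket_dir(dir)
  expect_length(pockets, 1)
  expect_equal(nrow(pockets[[1]]$spheres), 2)
  expect_equal(pockets[[1]]$spheres$radius, c(1.8, 2.1))
  expect_equal(pockets[[1]]$spheres$x, c(1.0, 1.5))
  expect_equal(nrow(pockets[[1]]$atoms), 3)
})

test_that("an empty directory yields an empty list; unpaired pockets are skipped", {
  empty <- tempfile(); dir.create(file.path(empty, "pockets"), recursive = TRUE)
  expect_length(read_fpocket_dir(empty), 0)
  # atm present, vert missing -> skipped with warning, others still load
  dir <- write_min_fpocket(tempfile())
  writeLines("ATOM      1  CA  GLY A   9       0.0   0.0   0.0  1.00  0.00           C",
             file.path(dir, "pockets", "pocket2_atm.pdb"))
  expect_warning(pockets <- read_fpocket_dir(dir), "pocket 2")
  expect_length(pockets, 1)
  expect_error(read_fpocket_dir(tempfile()), class = "pocketlit_io_error")
})

test_that("residue contact fractions follow the radius + tolerance rule", {
  spheres <- tibble::tibble(x = 0, y = 0, z = 0, radius = 2)
  at <- function(...) {
    xyz <- rbind(...)
    tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], is_heavy = TRUE)
  }
  # all four atoms inside the sphere
  expect_equal(residue_contact_fraction(
    at(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), spheres), 1.0)
  # two of four atoms within radius + tol (tol 1 -> limit 3)
  expect_equal(residue_contact_fraction(
    at(c(0, 0, 0), c(2.5, 0, 0), c(5, 0, 0), c(0, 6, 0)), spheres,
    contact_tol = 1), 0.5)
  # no spheres at all
  expect_equal(residue_contact_fraction(
    at(c(0, 0, 0)), spheres[0, ]), 0)
})

test_that("geometric pocket residues honor the residue-match threshold limits", {
  fx <- make_structure(default_fixture(seed = 41, n_chains = 1, decoys = 0))
  geom <- make_alpha_spheres(fx, tempfile())
  g <- geom[[1]]
  all_contact <- geometric_pocket_residues(g, fx$structure,
                                           residue_match_threshold = 0)
  expect_equal(sort(all_contact$res_id), 10:15)
  full <- geometric_pocket_residues(g, fx$structure,
                                    residue_match_threshold = 1)
  # planted shell atoms are all in contact, so threshold 1 keeps them too
  expect_equal(sort(full$res_id), 10:15)
  expect_true(all(full$contact_fraction == 1))
})

test_that("selection keeps supported pockets only and is monotone in the threshold", {
  fx <- make_structure(default_fixture(seed = 42, n_chains = 1, decoys = 2))
  dir <- tempfile()
  make_alpha_spheres(fx, dir)
  geom <- read_fpocket_dir(dir)
  expect_length(geom, 3)  # 1 planted site + 2 decoys
  mapped <- resolve_pockets(fx$lit_pockets, fx$structure)
  sel <- select_pockets(geom, mapped, fx$structure)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$geom_id, 1L)
  expect_equal(sel$best_jaccard, 1)
  # no mapped pockets -> empty selection
  none <- resolve_pockets(fx$lit_pockets[0, ], fx$structure)
  expect_equal(nrow(select_pockets(geom, none, fx$structure)), 0)
  # monotonicity: raising the Jaccard threshold never adds pockets
  counts <- vapply(c(0, 0.3, 0.6, 0.9, 1), function(thr) {
    cfg <- pipeline_config(pocket_match_jaccard = thr)
    nrow(select_pockets(geom, mapped, fx$structure, cfg))
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("merging is transitive, conserves spheres, and honors strict overlap", {
  mk <- function(id, ids, sphere_x) {
    g <- pocketlit:::new_geometric_pocket(
      id, tibble::tibble(x = sphere_x, y = 0, z = 0, radius = 2),
      tibble::tibble(chain_id = "A", res_name = "GLY", res_id = ids,
                     icode = NA_character_, serial = ids, atom_name = "CA",
                     element = "C", x = ids, y = 0, z = 0, occupancy = 1,
                     is_heavy = TRUE, vdw_radius = 1.7))
    tibble::tibble(geom_id = id, pocket = list(g),
                   residues = list(residue_ref("A", "GLY", ids)),
                   support = list(integer()), best_jaccard = 1)
  }
  # A-B Jaccard 0.8 > 0.5 -> merge, union of spheres
  sel <- dplyr::bind_rows(mk(1, 1:9, 0), mk(2, 1:10, 5))
  sel$support <- list(1L, 1L)
  merged <- merge_pockets(sel, merge_overlap_threshold = 0.5)
  expect_length(merged, 1)
  expect_equal(nrow(merged[[1]]$spheres), 2)
  # disjoint pockets with distinct support stay apart
  sel2 <- dplyr::bind_rows(mk(1, 1:5, 0), mk(2, 20:24, 50))
  sel2$support <- list(1L, 2L)
  expect_length(merge_pockets(sel2, merge_overlap_threshold = 0.5), 2)
  # transitivity: A~B and B~C merge all three even when A,C are disjoint
  selT <- dplyr::bind_rows(mk(1, 1:6, 0), mk(2, 4:9, 5), mk(3, 7:12, 10))
  selT$support <- list(1L, 2L, 3L)
  # Jaccard(1,2) = 3/9 = 1/3, Jaccard(2,3) = 1/3, Jaccard(1,3) = 0
  merged_t <- merge_pockets(selT, merge_overlap_threshold = 0.3)
  expect_length(merged_t, 1)
  expect_equal(nrow(merged_t[[1]]$spheres), 3)
  # strict comparator: at exactly the threshold no merge happens
  expect_length(merge_pockets(selT, merge_overlap_threshold = 1 / 3), 3)
  # shared supporting literature pocket forces a merge regardless of overlap
  sel3 <- dplyr::bind_rows(mk(1, 1:5, 0), mk(2, 20:24, 50))
  sel3$support <- list(1L, 1L)
  expect_length(merge_pockets(sel3, merge_overlap_threshold = 0.5), 1)
})
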