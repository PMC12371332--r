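# Volumetric grid construction. A selected alpha-sphere pocket becomes a
# rectangular lattice with 1.5 A default spacing bounded by the pocket
# heavy-atom coordinates; nodes are kept if they fall inside an alpha
# sphere, then truncated to the convex hull of the pocket atoms (spheres
# protruding into bulk solvent would otherwise inflate the volume), and
# finally pruned where they sit closer than the Van der Waals radius to
# any protein atom.

new_pocket_grid <- function(origin, spacing, points, pocket_id = NA,
                            dims = NULL) {
  structure(
    list(origin = origin, spacing = spacing,
         points = as.matrix(points), pocket_id = pocket_id, dims = dims),
    class = "pocket_grid")
}

#' @export
print.pocket_grid <- function(x, ...) {
  cat(sprintf(
    "<pocket_grid> pocket %s: %d point(s), %.2f A spacing, origin (%.2f, %.2f, %.2f)\n",
    paste(x$pocket_id, collapse = "+"), nrow(x$points), x$spacing,
    x$origin[[1]], x$origin[[2]], x$origin[[3]]))
  invisible(x)
}

#' Build the alpha-sphere grid of a pocket
#'
#' Lays a rectangular lattice (default 1.5 A steps) over the bounding box
#' of the pocket's heavy atoms, anchored at the per-axis minimum, and
#' retains the nodes whose distance to some alpha-sphere center is at most
#' that sphere's radius. A zero-extent axis degenerates to a single layer
#' with a warning.
#'
#' @param pocket A `geometric_pocket` (with `spheres` and `atoms`).
#' @param spacing Lattice step in Angstrom.
#' @return A `pocket_grid` with `origin`, `spacing`, retained `points`
#'   (m x 3 matrix) and the full lattice dimensions in `dims`.
#' @export
build_grid <- function(pocket, spacing = 1.5) {
  stopifnot(spacing > 0)
  heavy <- filter(pocket$atoms, .data$is_heavy)
  if (nrow(heavy) == 0 || nrow(pocket$spheres) == 0) {
    abort("pocket needs at least one heavy atom and one alpha sphere",
          class = "pocketlit_validation_error")
  }
  xyz <- as_xyz_matrix(heavy)
  lo <- apply(xyz, 2, min)
  hi <- apply(xyz, 2, max)
  if (any(hi - lo < spacing)) {
    warn("pocket bounding box is degenerate on some axis; single-layer grid there")
  }
  axes <- lapply(1:3, function(a) seq(lo[[a]], hi[[a]], by = spacing))
  nodes <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]],
                                 KEEP.OUT.ATTRS = FALSE))
  colnames(nodes) <- NULL
  centers <- as_xyz_matrix(pocket$spheres)
  d2 <- cross_dist2(nodes, centers)
  r2 <- matrix(pocket$spheres$radius^2, nrow(nodes), nrow(centers),
               byrow = TRUE)
  keep <- rowSums(d2 <= r2 + 1e-9) > 0
  new_pocket_grid(origin = lo, spacing = spacing,
                  points = nodes[keep, , drop = FALSE],
                  pocket_id = pocket$id,
                  dims = vapply(axes, length, 0L))
}

#' Truncate a grid to the convex hull of the pocket atoms
#'
#' Removes grid points strictly outside the convex hull of the pocket's
#' heavy atoms; boundary points are retained. With a degenerate hull
#' (fewer than four unique atoms, or all coplanar) the grid is returned
#' unchanged with a warning.
#'
#' @param grid A `pocket_grid`.
#' @param pocket_heavy_atoms Atom tibble of pocket heavy atoms.
#' @return The filtered `pocket_grid`.
#' @export
hull_filter <- function(grid, pocket_heavy_atoms) {
  heavy <- filter(pocket_heavy_atoms, .data$is_heavy)
  hs <- convex_hull_halfspaces(as_xyz_matrix(heavy))
  if (is.null(hs)) {
    warn("degenerate convex hull (<4 unique non-coplanar atoms); grid unchanged")
    return(grid)
  }
  keep <- points_in_hull(grid$points, hs)
  grid$points <- grid$points[keep, , drop = FALSE]
  grid
}

#' Prune grid points clashing with protein atoms
#'
#' Removes every grid point lying strictly closer than the Van der Waals
#' radius to any heavy atom of the structure. Not strictly required for
#' docking (engines handle steric clashes), so it can be disabled in the
#' pipeline configuration; it mainly improves the visual pocket
#' representation.
#'
#' @param grid A `pocket_grid`.
#' @param structure A `protein_structure` (may be empty).
#' @return The pruned `pocket_grid`.
#' @export
vdw_prune <- function(grid, structure) {
  if (is.null(structure) || nrow(structure) == 0 || nrow(grid$points) == 0) {
    return(grid)
  }
  heavy <- filter(structure, .data$is_heavy)
  if (nrow(heavy) == 0) return(grid)
  d2 <- cross_dist2(grid$points, as_xyz_matrix(heavy))
  r2 <- matrix(heavy$vdw_radius^2, nrow(grid$points), nrow(heavy),
               byrow = TRUE)
  clash <- rowSums(d2 < r2 - 1e-9) > 0
  grid$points <- grid$points[!clash, , drop = FALSE]
  grid
}

#' Write a pocket grid to disk
#'
#' Formats: `"pdb"` writes one HETATM pseudo-atom per retained point;
#' `"xyz"` writes plain whitespace-separated coordinates; `"dx"` writes an
#' OpenDX scalar field over the full lattice with a 0/1 occupancy mask.
#'
#' @param grid A `pocket_grid`.
#' @param path Output file path.
#' @param format One of `"pdb"`, `"dx"`, `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, format = c("pdb", "dx", "xyz")) {
  format <- match.arg(format)
  pts <- grid$points
  if (nrow(pts) == 0) warn("writing an empty pocket grid")
  if (format == "pdb") {
    lines <- vapply(seq_len(nrow(pts)), function(i) {
      sprintf("HETATM%5d  C   GRD P%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
              i %% 100000, (i - 1) %/% 100 + 1, pts[i, 1], pts[i, 2], pts[i, 3])
    }, "")
    writeLines(c(lines, "END"), path)
  } else if (format == "xyz") {
    writeLines(sprintf("%.4f %.4f %.4f", pts[, 1], pts[, 2], pts[, 3]),
               path)
  } else {
    dims <- grid$dims
    if (is.null(dims)) {
      abort("DX output needs lattice dimensions (grid built by build_grid)")
    }
    axes <- lapply(1:3, function(a) {
      grid$origin[[a]] + grid$spacing * (seq_len(dims[[a]]) - 1)
    })
    full <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]],
                                  KEEP.OUT.ATTRS = FALSE))
    key <- function(m) sprintf("%.4f|%.4f|%.4f", m[, 1], m[, 2], m[, 3])
    mask <- as.integer(key(full) %in% key(pts))
    # OpenDX order: x slowest, z fastest; expand.grid varied x fastest
    arr <- array(mask, dim = dims)
    vals <- mask_dx_order(arr)
    header <- c(
      sprintf("object 1 class gridpositions counts %d %d %d",
              dims[[1]], dims[[2]], dims[[3]]),
      sprintf("origin %.4f %.4f %.4f", grid$origin[[1]], grid$origin[[2]],
              grid$origin[[3]]),
      sprintf("delta %.4f 0 0", grid$spacing),
      sprintf("delta 0 %.4f 0", grid$spacing),
      sprintf("delta 0 0 %.4f", grid$spacing),
      sprintf("object 2 class gridconnections counts %d %d %d",
              dims[[1]], dims[[2]], dims[[3]]),
      sprintf("object 3 class array type double rank 0 items %d data follows",
              length(vals)))
    body <- vapply(split(vals, ceiling(seq_along(vals) / 3)),
                   function(v) paste(sprintf("%d", v), collapse = " "), "")
    writeLines(c(header, body,
                 "attribute \"dep\" string \"positions\"",
                 "object \"pocket mask\" class field"), path)
  }
  invisible(path)
}

# flatten a 3d mask in DX order (x slowest, z fastest)
mask_dx_order <- function(arr) {
  as.vector(aperm(arr, c(3, 2, 1)))
}

#' Read back a DX grid mask
#'
#' Counterpart of `write_grid(format = "dx")`, used to round-trip the
#' retained-node mask.
#'
#' @param path Path to an OpenDX file written by [write_grid()].
#' @return A `pocket_grid` whose points are the mask's on-nodes.
#' @export
read_grid_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  counts <- as.integer(strsplit(
    sub(".*counts ", "", lines[grepl("gridpositions", lines)]), " ")[[1]])
  origin <- as.numeric(strsplit(sub("^origin ", "", lines[grepl("^origin", lines)]),
                                " ")[[1]])
  deltas <- lines[grepl("^delta", lines)]
  spacing <- max(as.numeric(strsplit(sub("^delta ", "", deltas[[1]]), " ")[[1]]))
  start <- which(grepl("data follows", lines)) + 1
  end <- which(grepl("^attribute", lines)) - 1
  vals <- as.integer(unlist(strsplit(trimws(lines[start:end]), "\\s+")))
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  idx <- which(arr == 1, arr.ind = TRUE)
  pts <- cbind(origin[[1]] + (idx[, 1] - 1) * spacing,
               origin[[2]] + (idx[, 2] - 1) * spacing,
               origin[[3]] + (idx[, 3] - 1) * spacing)
  pts <- pts[order(pts[, 3], pts[, 2], pts[, 1]), , drop = FALSE]
  new_pocket_grid(origin = origin, spacing = spacing, points = pts,
                  dims = counts)
}

#' Full grid pipeline for one pocket
#'
#' Convenience wrapper chaining [build_grid()], [hull_filter()] and
#' [vdw_prune()].
#'
#' @param pocket A `geometric_pocket`.
#' @param structure A `protein_structure` used for Van der Waals pruning
#'   (`NULL` to skip).
#' @param spacing Lattice step in Angstrom.
#' @param prune_vdw Apply the Van der Waals pruning stage.
#' @return A `pocket_grid`.
#' @export
pocket_grid_pipeline <- function(pocket, structure = NULL, spacing = 1.5,
                                 prune_vdw = TRUE) {
  grid <- build_grid(pocket, spacing = spacing)
  grid <- hull_filter(grid, pocket$atoms)
  if (prune_vdw && !is.null(structure)) grid <- vdw_prune(grid, structure)
  grid
}
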