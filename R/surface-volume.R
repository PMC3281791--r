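#' Van der Waals radius set
#'
#' Element-based Bondi radii used by the surface and volume calculations:
#' C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, Se 1.90; unknown elements fall
#' back to `default`.
#'
#' @param overrides Named numeric vector of element -> radius (Angstrom)
#'   replacements or additions.
#' @param default Radius for elements not in the table.
#' @return A list of class `radius_set` with `radii` and `default`.
#' @export
vdw_radii <- function(overrides = NULL, default = 1.70) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      abort("overrides must be a named numeric vector")
    radii[toupper(names(overrides))] <- as.numeric(overrides)
  }
  if (any(radii <= 0) || default <= 0) abort("radii must be positive")
  structure(list(radii = radii, default = default), class = "radius_set")
}

atom_radii <- function(atoms, radii = vdw_radii()) {
  el <- toupper(if (is.data.frame(atoms)) atoms$element else atoms)
  r <- unname(radii$radii[el])
  r[is.na(r)] <- radii$default
  r
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Computes per-atom accessible areas by sampling `n_points` directions on
#' each atom's probe-expanded sphere (deterministic golden-section spiral)
#' and counting the sample points not buried inside any neighbouring
#' expanded sphere. Per-atom area is the exposed fraction times
#' `4*pi*(r + probe)^2`.
#'
#' @param atoms Atom tibble (needs `element`, `x`, `y`, `z`; residue
#'   columns are used for the per-residue aggregation when present).
#' @param radii A [vdw_radii()] radius set.
#' @param probe Probe radius in Angstrom (1.4 approximates a water
#'   molecule; 0 gives the bare van der Waals surface).
#' @param n_points Sphere sample count per atom (>= 1; 960 keeps the
#'   discretisation error below ~1% for protein-sized atoms).
#' @return A list of class `sasa_result`: `per_atom` (input rows plus
#'   `area`), `per_residue` (chain/resno/resname/area), `total_area`,
#'   `probe`, `n_points`.
#' @examples
#' a <- tibble::tibble(chain = "A", resno = 1, resname = "GLY",
#'                     elety = "C", element = "C", x = 0, y = 0, z = 0)
#' shrake_rupley_sasa(a)$total_area   # 4*pi*(1.7 + 1.4)^2
#' @export
shrake_rupley_sasa <- function(atoms, radii = vdw_radii(), probe = 1.4,
                               n_points = 960) {
  if (is.null(atoms) || nrow(atoms) == 0) abort("atoms must be non-empty")
  if (probe < 0) abort("probe must be >= 0")
  if (n_points <= 0) abort("n_points must be positive")
  area <- cpp_sasa(model_xyz(atoms), atom_radii(atoms, radii), probe,
                   as.integer(n_points))
  per_atom <- mutate(as_tibble(atoms), area = area)
  per_residue <- NULL
  if (all(c("chain", "resno", "resname") %in% names(per_atom))) {
    per_residue <- per_atom |>
      group_by(.data$chain, .data$resno,
               insert = if ("insert" %in% names(per_atom)) .data$insert
                        else "",
               .data$resname) |>
      summarise(area = sum(.data$area), .groups = "drop")
  }
  structure(list(per_atom = per_atom, per_residue = per_residue,
                 total_area = sum(area), probe = probe,
                 n_points = as.integer(n_points)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total %.1f A^2 (%d atoms, probe %.2f A, %d points)\n",
              x$total_area, nrow(x$per_atom), x$probe, x$n_points))
  invisible(x)
}

#' Buried surface area of a two-group complex
#'
#' `BSA = ASA(A) + ASA(B) - ASA(A union B)`; the interface area is
#' reported as `BSA / 2` (the per-side convention, so one complexation
#' event has a single interface area).
#'
#' @param group_a,group_b Disjoint atom tibbles.
#' @inheritParams shrake_rupley_sasa
#' @return A list of class `bsa_result`: `bsa`, `interface_area`, and the
#'   three underlying `sasa_result` objects (`sasa_a`, `sasa_b`,
#'   `sasa_ab`).
#' @export
buried_surface_area <- function(group_a, group_b, radii = vdw_radii(),
                                probe = 1.4, n_points = 960) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0)
    abort("both groups must be non-empty")
  xa <- model_xyz(group_a); xb <- model_xyz(group_b)
  shared <- nrow(neighbor_pairs(xa, xb, 1e-6))
  if (shared > 0)
    abort("groups overlap: the same atom position appears in both")
  sa <- shrake_rupley_sasa(group_a, radii, probe, n_points)
  sb <- shrake_rupley_sasa(group_b, radii, probe, n_points)
  sab <- shrake_rupley_sasa(bind_rows(as_tibble(group_a), as_tibble(group_b)),
                            radii, probe, n_points)
  bsa <- max(0, sa$total_area + sb$total_area - sab$total_area)
  structure(list(bsa = bsa, interface_area = bsa / 2, sasa_a = sa,
                 sasa_b = sb, sasa_ab = sab),
            class = "bsa_result")
}

#' Grid-based molecular volume
#'
#' Counts grid cells whose centers lie within `r_i + probe` of any atom.
#' Cell centers sit at integer multiples of `spacing` in the global frame,
#' so translation by a lattice vector leaves the count exactly invariant.
#' The deposited-structure convention is 1 Angstrom spacing with a 0
#' Angstrom probe (the protein volume per se).
#'
#' @inheritParams shrake_rupley_sasa
#' @param spacing Grid spacing in Angstrom (> 0).
#' @return A list of class `volume_result`: `volume` (Angstrom^3,
#'   `occupied_cells * spacing^3`), `grid_spacing`, `probe`,
#'   `occupied_cells`.
#' @export
grid_volume <- function(atoms, radii = vdw_radii(), spacing = 1.0,
                        probe = 0.0) {
  if (is.null(atoms) || nrow(atoms) == 0) abort("atoms must be non-empty")
  if (spacing <= 0) abort("spacing must be positive")
  res <- cpp_grid_volume(model_xyz(atoms),
                         atom_radii(atoms, radii) + probe, spacing)
  structure(list(volume = res$volume, grid_spacing = spacing, probe = probe,
                 occupied_cells = res$occupied_cells),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("<volume_result> %.0f A^3 (%.2f A grid, probe %.2f A)\n",
              x$volume, x$grid_spacing, x$probe))
  invisible(x)
}

#' Detect interior cavities on a grid
#'
#' Marks cells whose centers lie within `r_i + probe` of any atom as solid,
#' flood-fills the empty cells reachable from the bounding-box boundary
#' (6-connectivity), and reports the remaining empty connected components
#' as cavities. Components smaller than `min_cells` cells are discarded as
#' grid noise. The probe radius (default 1.4 Angstrom) determines which
#' voids a water-sized probe cannot reach from outside.
#'
#' @inheritParams grid_volume
#' @param min_cells Minimum component size kept (cells).
#' @return A tibble (class `cavity_set`) sorted by volume descending:
#'   `cavity`, `volume` (cell_count * spacing^3), `cell_count`, centroid
#'   `cx`, `cy`, `cz`.
#' @export
detect_cavities <- function(atoms, radii = vdw_radii(), spacing = 1.0,
                            probe = 1.4, min_cells = 3) {
  if (is.null(atoms) || nrow(atoms) == 0) abort("atoms must be non-empty")
  if (spacing <= 0) abort("spacing must be positive")
  res <- cpp_cavities(model_xyz(atoms), atom_radii(atoms, radii) + probe,
                      spacing)
  out <- tibble(cell_count = res$cell_count, cx = res$cx, cy = res$cy,
                cz = res$cz) |>
    filter(.data$cell_count >= min_cells) |>
    mutate(volume = .data$cell_count * spacing^3) |>
    arrange(dplyr::desc(.data$volume)) |>
    mutate(cavity = row_number()) |>
    select("cavity", "volume", "cell_count", "cx", "cy", "cz")
  class(out) <- c("cavity_set", class(out))
  out
}
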