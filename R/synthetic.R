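#' @title Synthetic ground-truth structures
#' @description Seeded generators of toy coordinate sets with known
#'   geometry, so surface, volume, cavity, contact and superposition code
#'   can be tested without any downloaded structure: sphere bodies with
#'   known volumes and cavities, ideal helical chains with a known
#'   hydrogen-bond pattern, two-chain complexes with planted interactions
#'   at mid-cutoff distances, and rigid or noisy chain copies. Every
#'   generator is a pure function of its arguments and seed.
#' @name synthetic
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

lattice_ball <- function(radius, spacing, inner = 0) {
  k <- ceiling(radius / spacing)
  g <- expand.grid(x = (-k:k) * spacing, y = (-k:k) * spacing,
                   z = (-k:k) * spacing)
  r <- sqrt(g$x^2 + g$y^2 + g$z^2)
  g[r <= radius & r > inner, , drop = FALSE]
}

#' Generate a pseudo-atom sphere body
#'
#' `solid_cluster` packs carbon pseudo-atoms on a cubic lattice filling a
#' ball (no interior probe-sized void can exist: every interior point lies
#' within a lattice half-diagonal, far below the expanded atom radius, of
#' some atom). `hollow_shell` fills only the shell between `inner_radius`
#' and `inner_radius + thickness`, enclosing a single interior region; a
#' shell thinner than two probe diameters could leak and is rejected.
#' Coordinates get a tiny seeded jitter (+-0.05 Angstrom) so grids are not
#' perfectly aligned with atom positions.
#'
#' @param kind `"solid_cluster"` or `"hollow_shell"`.
#' @param inner_radius Ball radius (solid) or interior radius (shell), in
#'   Angstrom (> 0).
#' @param thickness Shell thickness (Angstrom), hollow shell only.
#' @param seed Integer seed.
#' @param probe Probe radius the body must be tight against (used only to
#'   validate `thickness`).
#' @param spacing Lattice spacing of the pseudo-atoms.
#' @return A single-chain [struct_model()] of carbon pseudo-atoms.
#' @export
make_sphere_body <- function(kind = c("solid_cluster", "hollow_shell"),
                             inner_radius = 6, thickness = 3, seed = 1,
                             probe = 1.4, spacing = 1.4) {
  kind <- match.arg(kind)
  if (inner_radius <= 0 || thickness <= 0) abort("radii must be positive")
  if (kind == "hollow_shell" && thickness < 2 * probe)
    abort("shell thickness below two probe radii would leak")
  pts <- if (kind == "solid_cluster")
    lattice_ball(inner_radius, spacing)
  else
    lattice_ball(inner_radius + thickness, spacing, inner = inner_radius)
  jit <- with_seed(seed,
                   matrix(runif(3 * nrow(pts), -0.05, 0.05), ncol = 3))
  atoms <- tibble(
    chain = "A", resno = seq_len(nrow(pts)), resname = "UNK",
    elety = "C", element = "C",
    x = pts$x + jit[, 1], y = pts$y + jit[, 2], z = pts$z + jit[, 3])
  struct_model(atoms, entry_id = toupper(substr(kind, 1, 4)))
}

# place atom D from A-B-C frame with bond |CD|, angle BCD (deg), torsion
# ABCD (deg)
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Generate an ideal alpha-helical chain
#'
#' Backbone N, CA, C, O atoms built by internal coordinates with phi =
#' -57, psi = -47, omega = 180 degrees and standard bond geometry (rise
#' about 1.5 Angstrom per residue), giving the canonical i -> i+4
#' O...N hydrogen-bond pattern.
#'
#' @param n_res Number of residues (>= 5).
#' @param sequence One-letter sequence of length `n_res`, or `NULL` for
#'   poly-alanine.
#' @return A single-chain [struct_model()] with backbone atoms only.
#' @export
make_helix_chain <- function(n_res, sequence = NULL) {
  if (n_res < 5) abort("n_res must be >= 5")
  if (is.null(sequence)) sequence <- strrep("A", n_res)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters1) != n_res)
    abort("sequence length must equal n_res")
  rev3 <- setNames(names(AA_3TO1)[1:20], unname(AA_3TO1)[1:20])
  res3 <- unname(rev3[letters1])
  if (any(is.na(res3))) abort("sequence contains unknown letters")

  phi <- -57; psi <- -47; omega <- 180
  n_xyz <- matrix(NA_real_, n_res, 3)
  ca_xyz <- matrix(NA_real_, n_res, 3)
  c_xyz <- matrix(NA_real_, n_res, 3)
  n_xyz[1, ] <- c(0, 0, 0)
  ca_xyz[1, ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  c_xyz[1, ] <- ca_xyz[1, ] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res - 1)) {
    n_xyz[i + 1, ] <- nerf_place(n_xyz[i, ], ca_xyz[i, ], c_xyz[i, ],
                                 1.329, 116.2, psi)
    ca_xyz[i + 1, ] <- nerf_place(ca_xyz[i, ], c_xyz[i, ], n_xyz[i + 1, ],
                                  1.458, 121.7, omega)
    c_xyz[i + 1, ] <- nerf_place(c_xyz[i, ], n_xyz[i + 1, ],
                                 ca_xyz[i + 1, ], 1.525, 111.2, phi)
  }
  # carbonyl O in the peptide plane, anti to the bisector of CA and next N
  o_xyz <- matrix(NA_real_, n_res, 3)
  for (i in seq_len(n_res)) {
    vnext <- if (i < n_res) n_xyz[i + 1, ]
             else nerf_place(n_xyz[i, ], ca_xyz[i, ], c_xyz[i, ],
                             1.329, 116.2, psi)
    u <- ca_xyz[i, ] - c_xyz[i, ]; u <- u / sqrt(sum(u^2))
    v <- vnext - c_xyz[i, ]; v <- v / sqrt(sum(v^2))
    w <- -(u + v); w <- w / sqrt(sum(w^2))
    o_xyz[i, ] <- c_xyz[i, ] + 1.231 * w
  }

  per_res <- function(i) {
    tibble(chain = "A", resno = i, resname = res3[i],
           elety = c("N", "CA", "C", "O"),
           element = c("N", "C", "C", "O"),
           x = c(n_xyz[i, 1], ca_xyz[i, 1], c_xyz[i, 1], o_xyz[i, 1]),
           y = c(n_xyz[i, 2], ca_xyz[i, 2], c_xyz[i, 2], o_xyz[i, 2]),
           z = c(n_xyz[i, 3], ca_xyz[i, 3], c_xyz[i, 3], o_xyz[i, 3]))
  }
  struct_model(bind_rows(lapply(seq_len(n_res), per_res)),
               entry_id = "HELX")
}

#' Specification of a planted two-chain complex
#'
#' @param n_salt_bridges,n_hbonds,n_disulfides,n_apolar_contacts Requested
#'   cross-chain interaction counts (>= 0).
#' @param interface_apolar_fraction Fraction of the `n_pad` passive
#'   interface pad residues that are apolar; apolar pad residues sit in
#'   van der Waals range (3.8 Angstrom) and add to the detected vdW count,
#'   polar pads sit at 4.5 Angstrom and are inert.
#' @param clearance Minimum distance (Angstrom) between cross-chain atoms
#'   of different interface sites and between the chain bodies; must
#'   exceed the largest detection cutoff (4.0). Within one planted site
#'   the backbone pseudo-atoms still stay beyond every detection cutoff
#'   of the partner chain.
#' @param n_pad Number of passive pad residues at the interface.
#' @param body_radius Radius (Angstrom) of each chain's mixed-composition
#'   body blob (surface material for patch statistics).
#' @param seed Integer seed (site jitter, body composition).
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(n_salt_bridges = 0, n_hbonds = 0, n_disulfides = 0,
                       n_apolar_contacts = 0,
                       interface_apolar_fraction = 0, clearance = 8,
                       n_pad = 12, body_radius = 6, seed = 1) {
  counts <- c(n_salt_bridges, n_hbonds, n_disulfides, n_apolar_contacts)
  if (any(counts < 0)) abort("requested counts must be >= 0")
  if (interface_apolar_fraction < 0 || interface_apolar_fraction > 1)
    abort("interface_apolar_fraction must be in [0, 1]")
  if (clearance <= 4.0)
    abort("clearance must exceed the largest detection cutoff (4.0)")
  if (n_pad < 0 || body_radius <= 0)
    abort("n_pad must be >= 0 and body_radius positive")
  structure(list(n_salt_bridges = n_salt_bridges, n_hbonds = n_hbonds,
                 n_disulfides = n_disulfides,
                 n_apolar_contacts = n_apolar_contacts,
                 interface_apolar_fraction = interface_apolar_fraction,
                 clearance = clearance, n_pad = n_pad,
                 body_radius = body_radius, seed = seed),
            class = "plant_spec")
}

#' Generate a two-chain complex with planted interactions
#'
#' Chains A and B straddle the z = 0 interface plane. Each requested
#' interaction occupies its own site along x (sites spaced by `clearance`
#' + 6 Angstrom) with the interacting atom pair placed symmetrically at a
#' mid-cutoff distance: salt bridges Asp OD2 - Lys NZ at 3.0, hydrogen
#' bonds Ser OG - Ser OG at 2.9, disulfides Cys SG - SG at 2.05, apolar
#' contacts Leu CD1 - CD1 at 3.8. Backbone pseudo-atoms sit 2.6 Angstrom
#' behind each functional atom along z, keeping every non-planted
#' cross-chain pair beyond its detection cutoff; a mixed-composition body
#' blob per chain (for surface-patch statistics) sits beyond `clearance`
#' from the partner chain. The construction is deterministic per seed.
#'
#' @param spec A [plant_spec()].
#' @return A two-chain [struct_model()].
#' @export
make_planted_complex <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  site_spacing <- spec$clearance + 6
  n_pad <- spec$n_pad
  kinds <- c(rep("salt", spec$n_salt_bridges),
             rep("hbond", spec$n_hbonds),
             rep("ss", spec$n_disulfides),
             rep("apolar", spec$n_apolar_contacts),
             rep("pad", n_pad))
  gaps <- c(salt = 3.0, hbond = 2.9, ss = 2.05, apolar = 3.8,
            pad_apolar = 3.8, pad_polar = 4.5)
  site_info <- list(
    salt  = list(res_a = "ASP", atom_a = "OD2", el_a = "O",
                 res_b = "LYS", atom_b = "NZ",  el_b = "N"),
    hbond = list(res_a = "SER", atom_a = "OG", el_a = "O",
                 res_b = "SER", atom_b = "OG", el_b = "O"),
    ss    = list(res_a = "CYS", atom_a = "SG", el_a = "S",
                 res_b = "CYS", atom_b = "SG", el_b = "S"),
    apolar = list(res_a = "LEU", atom_a = "CD1", el_a = "C",
                  res_b = "LEU", atom_b = "CD1", el_b = "C"),
    pad_apolar = list(res_a = "LEU", atom_a = "CD1", el_a = "C",
                      res_b = "LEU", atom_b = "CD1", el_b = "C"),
    pad_polar = list(res_a = "SER", atom_a = "OG", el_a = "O",
                     res_b = "SER", atom_b = "OG", el_b = "O"))

  built <- with_seed(spec$seed, {
    n_apolar_pad <- round(spec$interface_apolar_fraction * n_pad)
    pad_kinds <- sample(c(rep("pad_apolar", n_apolar_pad),
                          rep("pad_polar", n_pad - n_apolar_pad)))
    kinds[kinds == "pad"] <- pad_kinds
    jitter_xy <- matrix(runif(2 * length(kinds), -0.3, 0.3), ncol = 2)
    comp_seeds <- runif(2)
    list(kinds = kinds, jitter_xy = jitter_xy, comp_seeds = comp_seeds)
  })
  kinds <- built$kinds

  rows_a <- list(); rows_b <- list()
  resno_a <- 0; resno_b <- 0
  for (k in seq_along(kinds)) {
    kind <- kinds[k]
    info <- site_info[[kind]]
    g <- gaps[[kind]]
    x0 <- k * site_spacing + built$jitter_xy[k, 1]
    y0 <- built$jitter_xy[k, 2]
    resno_a <- resno_a + 1
    rows_a[[length(rows_a) + 1]] <- tibble(
      chain = "A", resno = resno_a, resname = info$res_a,
      elety = c("CA", info$atom_a), element = c("C", info$el_a),
      x = x0, y = y0, z = c(-(g / 2 + 2.6), -g / 2))
    resno_b <- resno_b + 1
    rows_b[[length(rows_b) + 1]] <- tibble(
      chain = "B", resno = resno_b, resname = info$res_b,
      elety = c("CA", info$atom_b), element = c("C", info$el_b),
      x = x0, y = y0, z = c(g / 2 + 2.6, g / 2))
  }

  # mixed-composition surface bodies, far from the partner chain
  body <- lattice_ball(spec$body_radius, 2.4)
  body_res <- function(chain, sign, start_resno, comp_seed) {
    n <- nrow(body)
    apolar <- with_seed(round(comp_seed * 1e6),
                        runif(n) < 0.5)
    tibble(
      chain = chain,
      resno = start_resno + seq_len(n),
      resname = ifelse(apolar, "LEU", "SER"),
      elety = ifelse(apolar, "CD1", "OG"),
      element = ifelse(apolar, "C", "O"),
      x = body$x - site_spacing,
      y = body$y,
      z = sign * (body$z + spec$clearance + 6 + spec$body_radius))
  }
  rows_a[[length(rows_a) + 1]] <-
    body_res("A", -1, resno_a, built$comp_seeds[1])
  rows_b[[length(rows_b) + 1]] <-
    body_res("B", +1, resno_b, built$comp_seeds[2])

  struct_model(bind_rows(c(rows_a, rows_b)), entry_id = "PLNT")
}

#' Apply a rigid motion and optional coordinate noise to a model
#'
#' Rotation angles are extrinsic x, y, z Euler angles in radians applied
#' about the origin, followed by the translation, then zero-mean Gaussian
#' noise of standard deviation `noise_sigma` per coordinate (seeded).
#'
#' @param model A [struct_model()].
#' @param rotation_angles Length-3 numeric (radians).
#' @param translation Length-3 numeric (Angstrom).
#' @param noise_sigma Per-coordinate noise standard deviation (Angstrom).
#' @param seed Integer seed for the noise.
#' @return A [struct_model()] with transformed coordinates.
#' @export
rigid_perturb <- function(model, rotation_angles = c(0, 0, 0),
                          translation = c(0, 0, 0), noise_sigma = 0,
                          seed = 1) {
  stopifnot(inherits(model, "struct_model"))
  if (nrow(model$atoms) == 0) abort("model has no atoms")
  r <- euler_rotation(rotation_angles)
  xyz <- model_xyz(model$atoms) %*% t(r)
  xyz <- sweep(xyz, 2, translation, "+")
  if (noise_sigma > 0)
    xyz <- xyz + with_seed(seed,
                           matrix(rnorm(length(xyz), 0, noise_sigma),
                                  ncol = 3))
  out <- model
  out$atoms$x <- xyz[, 1]; out$atoms$y <- xyz[, 2]; out$atoms$z <- xyz[, 3]
  out
}

euler_rotation <- function(angles) {
  a <- angles[1]; b <- angles[2]; c <- angles[3]
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}
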