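#' Characterise one chain-chain interface
#'
#' Computes the buried surface area of a chain pair (`BSA = ASA(A) +
#' ASA(B) - ASA(A union B)`; interface area = BSA/2), the interfacing
#' residues (per-residue accessible area drops by more than
#' `dasa_threshold` upon complexation; the 0.1 Angstrom^2 default filters
#' sampling noise at 960 sphere points), and the inter-chain contact
#' counts of the pair (hydrogen bonds by atom pair; salt bridges — with
#' the bidentate sub-count —, van der Waals contacts and disulfides by
#' residue pair).
#'
#' @param model A [struct_model()].
#' @param pair Character vector of two chain ids.
#' @param radii A [vdw_radii()] set.
#' @param probe Probe radius (Angstrom).
#' @param n_points Sphere sample count per atom.
#' @param dasa_threshold Minimum per-residue accessible-area drop
#'   (Angstrom^2) for a residue to count as interfacing.
#' @param cutoffs Per-kind contact cutoffs (see [find_contacts()]).
#' @return A list of class `interface_summary`.
#' @export
pairwise_interface_summary <- function(model, pair, radii = vdw_radii(),
                                       probe = 1.4, n_points = 960,
                                       dasa_threshold = 0.1,
                                       cutoffs = list()) {
  stopifnot(inherits(model, "struct_model"), length(pair) == 2)
  ids <- chain_ids(model)
  if (!all(pair %in% ids))
    abort(paste0("unknown chain(s): ",
                 paste(setdiff(pair, ids), collapse = ", ")))
  a <- model_chain(model, pair[1])
  b <- model_chain(model, pair[2])
  bsa <- buried_surface_area(a, b, radii, probe, n_points)

  res_free <- bind_rows(bsa$sasa_a$per_residue, bsa$sasa_b$per_residue)
  res_cplx <- bsa$sasa_ab$per_residue
  dres <- left_join(res_free,
                    rename(res_cplx, area_complex = "area"),
                    by = c("chain", "resno", "insert", "resname")) |>
    mutate(dasa = .data$area - .data$area_complex) |>
    filter(.data$dasa > dasa_threshold)
  residues1 <- filter(dres, .data$chain == pair[1]) |>
    select("chain", "resno", "insert", "resname", "dasa")
  residues2 <- filter(dres, .data$chain == pair[2]) |>
    select("chain", "resno", "insert", "resname", "dasa")

  sub <- struct_model(bind_rows(a, b), entry_id = model$entry_id)
  contacts <- find_contacts(sub, cutoffs = cutoffs) |>
    filter(.data$span == "inter")
  cnt <- count_interactions(contacts)
  pick <- function(kind) {
    r <- filter(cnt, .data$kind == !!kind)
    if (nrow(r) == 0) 0L else as.integer(r$count)
  }
  n_bid <- {
    r <- filter(cnt, .data$kind == "salt_bridge")
    if (nrow(r) == 0) 0L else as.integer(r$n_bidentate)
  }
  structure(
    list(chain_pair = pair, bsa = bsa$bsa,
         interface_area = bsa$interface_area,
         residues1 = residues1, residues2 = residues2,
         n_hbonds = pick("hbond"), n_salt_bridges = pick("salt_bridge"),
         n_bidentate = n_bid, n_vdw = pick("vdw"),
         n_disulfides = pick("disulfide"), contacts = contacts,
         probe = probe, n_points = n_points),
    class = "interface_summary")
}

#' @export
print.interface_summary <- function(x, ...) {
  cat(sprintf(
    "<interface_summary> %s/%s  area %.1f A^2 (BSA %.1f), %d+%d residues\n",
    x$chain_pair[1], x$chain_pair[2], x$interface_area, x$bsa,
    nrow(x$residues1), nrow(x$residues2)))
  cat(sprintf("  HB %d  SB %d (%d bidentate)  vdW %d  SS %d\n",
              x$n_hbonds, x$n_salt_bridges, x$n_bidentate, x$n_vdw,
              x$n_disulfides))
  invisible(x)
}

#' @rdname quatstab-tidiers
#' @export
tidy.interface_summary <- function(x, ...) {
  tibble(chain1 = x$chain_pair[1], chain2 = x$chain_pair[2],
         interface_area = x$interface_area, bsa = x$bsa,
         n_residues1 = nrow(x$residues1), n_residues2 = nrow(x$residues2),
         n_hbonds = x$n_hbonds, n_salt_bridges = x$n_salt_bridges,
         n_bidentate = x$n_bidentate, n_vdw = x$n_vdw,
         n_disulfides = x$n_disulfides)
}

#' Classify every chain-chain interface of an assembly
#'
#' Computes all pairwise interface summaries, ranks them by interface
#' area, and labels them. In a four-chain assembly the two largest
#' area-disjoint pairs become `tight_dimer` (the back-to-back dimers of a
#' dimer-of-dimers tetramer) and the remaining non-negligible pairs
#' `tetramer_interface`; with two chains the single pair is a
#' `tight_dimer`. Pairs with interface area below `negligible_area` are
#' `negligible`. Also reports the assembly-level buried area
#' `sum(chain ASA) - ASA(assembly)`.
#'
#' @inheritParams pairwise_interface_summary
#' @param negligible_area Interface areas (Angstrom^2) at or below this are
#'   labelled negligible (grid/sampling noise scale).
#' @return A list of class `assembly_interface_map`: `summaries` (named
#'   list of [pairwise_interface_summary()] results), `labels` (tibble
#'   `chain1`, `chain2`, `interface_area`, `label`),
#'   `tetramer_buried_area`.
#' @export
classify_assembly_interfaces <- function(model, radii = vdw_radii(),
                                         probe = 1.4, n_points = 960,
                                         dasa_threshold = 0.1,
                                         cutoffs = list(),
                                         negligible_area = 10) {
  ids <- chain_ids(model)
  if (length(ids) < 2) abort("need at least 2 polymer chains")
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  summaries <- lapply(pairs, function(p)
    pairwise_interface_summary(model, p, radii, probe, n_points,
                               dasa_threshold, cutoffs))
  names(summaries) <- vapply(pairs, paste, character(1), collapse = "/")
  lab <- bind_rows(lapply(summaries, tidy)) |>
    arrange(dplyr::desc(.data$interface_area)) |>
    mutate(label = "negligible")

  big <- which(lab$interface_area > negligible_area)
  if (length(ids) == 2) {
    if (length(big) > 0) lab$label[big[1]] <- "tight_dimer"
  } else {
    taken <- character()
    n_tight <- 0
    for (k in seq_len(nrow(lab))) {
      if (lab$interface_area[k] <= negligible_area) next
      chs <- c(lab$chain1[k], lab$chain2[k])
      if (n_tight < floor(length(ids) / 2) &&
          !any(chs %in% taken)) {
        lab$label[k] <- "tight_dimer"
        taken <- c(taken, chs)
        n_tight <- n_tight + 1
      } else {
        lab$label[k] <- "tetramer_interface"
      }
    }
  }

  chain_asa <- vapply(ids, function(ch)
    shrake_rupley_sasa(model_chain(model, ch), radii, probe,
                       n_points)$total_area, numeric(1))
  asm_asa <- shrake_rupley_sasa(polymer_atoms(model), radii, probe,
                                n_points)$total_area
  structure(list(summaries = summaries, labels = lab,
                 tetramer_buried_area = sum(chain_asa) - asm_asa),
            class = "assembly_interface_map")
}

#' @export
print.assembly_interface_map <- function(x, ...) {
  cat("<assembly_interface_map>\n")
  print(as.data.frame(x$labels))
  cat(sprintf("  assembly buried area: %.1f A^2\n",
              x$tetramer_buried_area))
  invisible(x)
}

#' @rdname quatstab-tidiers
#' @export
tidy.assembly_interface_map <- function(x, ...) {
  details <- bind_rows(lapply(x$summaries, tidy))
  left_join(x$labels |> select("chain1", "chain2", "label"),
            details, by = c("chain1", "chain2")) |>
    arrange(dplyr::desc(.data$interface_area))
}

#' @rdname quatstab-tidiers
#' @export
glance.assembly_interface_map <- function(x, ...) {
  tibble(n_pairs = nrow(x$labels),
         n_tight_dimer = sum(x$labels$label == "tight_dimer"),
         n_tetramer_interface =
           sum(x$labels$label == "tetramer_interface"),
         tetramer_buried_area = x$tetramer_buried_area)
}

#' Hydrophobic enrichment P-value of an interface
#'
#' Observed statistic: the fraction of the pair's buried surface area
#' contributed by apolar (C, S) atoms. Null distribution: `n_samples`
#' random surface patches, each grown from a uniformly chosen exposed atom
#' by nearest-neighbour accretion on its own chain until the patch's
#' isolated-chain accessible area reaches the interface area (one side's
#' share of the BSA). `P = Pr(patch apolar fraction >= observed)`, ties
#' counting as exceedances, so a low P flags an interface more apolar than
#' almost any random surface patch of equal area. Seeded and reproducible.
#'
#' @inheritParams pairwise_interface_summary
#' @param n_samples Number of null patches (>= 100).
#' @param seed Integer seed for the patch sampler.
#' @param apolar Elements counted as apolar.
#' @return A single probability in `[0, 1]` with attributes
#'   `observed_apolar_fraction` and `n_samples`.
#' @export
hydrophobic_pvalue <- function(model, pair, n_samples = 2000, seed = 1,
                               radii = vdw_radii(), probe = 1.4,
                               n_points = 960, apolar = c("C", "S")) {
  if (n_samples < 100) abort("n_samples must be >= 100")
  a <- model_chain(model, pair[1])
  b <- model_chain(model, pair[2])
  bsa <- buried_surface_area(a, b, radii, probe, n_points)
  if (bsa$bsa <= 0) abort("zero-area interface")

  # per-atom area lost upon complexation, on both sides
  free_area <- c(bsa$sasa_a$per_atom$area, bsa$sasa_b$per_atom$area)
  cplx_area <- bsa$sasa_ab$per_atom$area
  datom <- pmax(0, free_area - cplx_area)
  els <- toupper(c(a$element, b$element))
  obs <- sum(datom[els %in% apolar]) / sum(datom)

  null <- null_patch_fractions(list(bsa$sasa_a, bsa$sasa_b),
                               target = bsa$interface_area,
                               n_samples = n_samples, seed = seed,
                               apolar = apolar)
  p <- mean(null >= obs - 1e-12)
  structure(p, observed_apolar_fraction = obs, n_samples = n_samples)
}

# Grow n_samples surface patches by nearest-neighbour accretion and return
# their apolar area fractions. `sasas` is a list of per-chain sasa_result
# objects (isolated chains).
null_patch_fractions <- function(sasas, target, n_samples, seed,
                                 apolar = c("C", "S")) {
  chains <- lapply(sasas, function(s) {
    pa <- s$per_atom
    exposed <- which(pa$area > 0)
    list(xyz = model_xyz(pa), area = pa$area,
         apolar = toupper(pa$element) %in% apolar, exposed = exposed)
  })
  # chain picked proportionally to its number of exposed atoms (uniform
  # over exposed seed atoms overall)
  n_exp <- vapply(chains, function(c) length(c$exposed), numeric(1))
  if (sum(n_exp) == 0) abort("no exposed atoms to sample patches from")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vapply(seq_len(n_samples), function(k) {
    ci <- sample.int(length(chains), 1, prob = n_exp)
    ch <- chains[[ci]]
    seed_atom <- ch$exposed[sample.int(length(ch$exposed), 1)]
    grow_patch_fraction(ch, seed_atom, target)
  }, numeric(1))
}

grow_patch_fraction <- function(ch, seed_atom, target) {
  exposed <- ch$exposed
  d2 <- rowSums(sweep(ch$xyz[exposed, , drop = FALSE], 2,
                      ch$xyz[seed_atom, ], "-")^2)
  ord <- exposed[order(d2)]
  cum <- cumsum(ch$area[ord])
  k <- which(cum >= target)[1]
  if (is.na(k)) k <- length(ord)   # whole surface smaller than target
  patch <- ord[seq_len(k)]
  sum(ch$area[patch][ch$apolar[patch]]) / sum(ch$area[patch])
}
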