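#' @title Contact inventories: salt bridges, H-bonds, disulfides, van der
#'   Waals
#' @description
#' Distance-based interaction detectors over the polymer atoms of a
#' structure model, each returning a tibble of class `interaction_set`
#' with one row per interacting residue pair (columns `kind`, residue
#' identities, `n_atom_pairs`, `min_dist`, `span` = intra/inter by chain,
#' `bidentate`, and an `atom_pairs` list-column with the contributing atom
#' pairs and distances). All cutoffs are strict (`<`): a pair exactly at
#' the cutoff does not count, and atoms pairs claimed by a
#' higher-precedence kind (disulfide > salt bridge > H-bond > van der
#' Waals) never re-count in a lower one.
#'
#' Definitions:
#' * **salt bridge** (`cutoff` 3.5): an acidic carboxylate oxygen (Asp
#'   OD1/OD2, Glu OE1/OE2, C-terminal OXT) within cutoff of a basic
#'   side-chain nitrogen (Lys NZ, Arg NE/NH1/NH2, His ND1/NE2, N-terminal
#'   backbone N). Counted once per residue pair; `bidentate` flags >= 2
#'   simultaneous atom pairs. His counts as basic regardless of
#'   protonation (the crystal structures carry no hydrogens).
#' * **hydrogen bond** (`cutoff` 3.5): any N/O/S heavy-atom pair between
#'   distinct, non-covalently-bonded residues (the sequential backbone
#'   C(i)-N(i+1) peptide pair is excluded); purely distance-based since
#'   donor hydrogens are absent. Counted per atom pair.
#' * **disulfide** (`cutoff` 2.5): Cys SG-SG pairs.
#' * **van der Waals contact** (`cutoff` 4.0): residue pairs with >= 1
#'   apolar (C or S) heavy-atom pair within cutoff, excluding atoms pairs
#'   already assigned above. Counted once per residue pair.
#'
#' @param model A [struct_model()] (or atom tibble) with polymer chains.
#' @param cutoff Distance cutoff in Angstrom for the detector's own kind.
#' @param sb_cutoff,ss_cutoff,hb_cutoff Cutoffs used internally for the
#'   higher-precedence kinds that mask atom pairs.
#' @return An `interaction_set` tibble (possibly empty).
#' @name contacts
NULL

prep_polymer <- function(model) {
  at <- if (inherits(model, "struct_model")) {
    polymer_atoms(model)
  } else {
    m <- as_tibble(model)
    if ("het" %in% names(m)) m <- filter(m, !.data$het)
    m
  }
  if (nrow(at) == 0) abort("model has no polymer atoms")
  if (!"insert" %in% names(at)) at$insert <- ""
  at$.idx <- seq_len(nrow(at))
  # residue order index per chain (handles insertion codes)
  res <- at |>
    distinct(.data$chain, .data$resno, .data$insert) |>
    arrange(.data$chain, .data$resno, .data$insert) |>
    group_by(.data$chain) |>
    mutate(.res_ord = row_number()) |>
    ungroup()
  left_join(at, res, by = c("chain", "resno", "insert"))
}

# cross (or self) neighbour pairs annotated with both atoms' identities
atom_pair_table <- function(a, b, cutoff, self = FALSE) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(chain1 = character(), resno1 = integer(),
                  insert1 = character(), resname1 = character(),
                  elety1 = character(), ord1 = integer(),
                  chain2 = character(), resno2 = integer(),
                  insert2 = character(), resname2 = character(),
                  elety2 = character(), ord2 = integer(),
                  dist = numeric(), idx1 = integer(), idx2 = integer()))
  }
  np <- neighbor_pairs(model_xyz(a), model_xyz(b), cutoff)
  out <- tibble(
    chain1 = a$chain[np$i], resno1 = a$resno[np$i],
    insert1 = a$insert[np$i], resname1 = a$resname[np$i],
    elety1 = a$elety[np$i], ord1 = a$.res_ord[np$i],
    chain2 = b$chain[np$j], resno2 = b$resno[np$j],
    insert2 = b$insert[np$j], resname2 = b$resname[np$j],
    elety2 = b$elety[np$j], ord2 = b$.res_ord[np$j],
    dist = np$dist, idx1 = a$.idx[np$i], idx2 = b$.idx[np$j])
  if (self) out <- filter(out, .data$idx1 < .data$idx2)
  # distinct residues only
  filter(out, !(.data$chain1 == .data$chain2 &
                  .data$resno1 == .data$resno2 &
                  .data$insert1 == .data$insert2))
}

# canonical residue-pair orientation, so each unordered pair appears once
canonicalise_pairs <- function(p) {
  swap <- (p$chain2 < p$chain1) |
    (p$chain2 == p$chain1 & p$resno2 < p$resno1) |
    (p$chain2 == p$chain1 & p$resno2 == p$resno1 & p$insert2 < p$insert1)
  flip <- function(x1, x2) {
    tmp <- x1[swap]; x1[swap] <- x2[swap]; x2[swap] <- tmp
    list(x1, x2)
  }
  for (f in c("chain", "resno", "insert", "resname", "elety", "ord",
              "idx")) {
    v <- flip(p[[paste0(f, "1")]], p[[paste0(f, "2")]])
    p[[paste0(f, "1")]] <- v[[1]]
    p[[paste0(f, "2")]] <- v[[2]]
  }
  p
}

pair_key <- function(p) {
  k1 <- paste(p$chain1, p$resno1, p$insert1, p$elety1)
  k2 <- paste(p$chain2, p$resno2, p$insert2, p$elety2)
  paste(pmin(k1, k2), pmax(k1, k2), sep = " | ")
}

# roll atom pairs up to residue-pair rows
summarise_interactions <- function(p, kind) {
  if (nrow(p) == 0) return(empty_interactions())
  p <- canonicalise_pairs(p)
  out <- p |>
    group_by(.data$chain1, .data$resno1, .data$insert1, .data$resname1,
             .data$chain2, .data$resno2, .data$insert2, .data$resname2) |>
    summarise(
      n_atom_pairs = n(), min_dist = min(.data$dist),
      atom_pairs = list(dplyr::pick("elety1", "elety2", "dist")),
      .groups = "drop") |>
    mutate(kind = .env$kind,
           span = ifelse(.data$chain1 == .data$chain2, "intra", "inter"),
           bidentate = if (.env$kind == "salt_bridge")
             .data$n_atom_pairs >= 2 else NA) |>
    select("kind", "chain1", "resno1", "insert1", "resname1", "chain2",
           "resno2", "insert2", "resname2", "n_atom_pairs", "min_dist",
           "span", "bidentate", "atom_pairs") |>
    arrange(.data$chain1, .data$resno1, .data$chain2, .data$resno2)
  class(out) <- c("interaction_set", class(out))
  out
}

empty_interactions <- function() {
  out <- tibble(kind = character(), chain1 = character(),
                resno1 = integer(), insert1 = character(),
                resname1 = character(), chain2 = character(),
                resno2 = integer(), insert2 = character(),
                resname2 = character(), n_atom_pairs = integer(),
                min_dist = numeric(), span = character(),
                bidentate = logical(), atom_pairs = list())
  class(out) <- c("interaction_set", class(out))
  out
}

acidic_atoms <- function(at) {
  filter(at, (.data$resname == "ASP" & .data$elety %in% c("OD1", "OD2")) |
           (.data$resname == "GLU" & .data$elety %in% c("OE1", "OE2")) |
           .data$elety == "OXT")
}

basic_atoms <- function(at) {
  nterm <- at |>
    group_by(.data$chain) |>
    filter(.data$.res_ord == min(.data$.res_ord), .data$elety == "N") |>
    ungroup()
  side <- filter(at, (.data$resname == "LYS" & .data$elety == "NZ") |
                   (.data$resname == "ARG" &
                      .data$elety %in% c("NE", "NH1", "NH2")) |
                   (.data$resname == "HIS" &
                      .data$elety %in% c("ND1", "NE2")))
  bind_rows(side, nterm) |> distinct(.data$.idx, .keep_all = TRUE)
}

#' @rdname contacts
#' @export
find_salt_bridges <- function(model, cutoff = 3.5) {
  at <- prep_polymer(model)
  p <- atom_pair_table(acidic_atoms(at), basic_atoms(at), cutoff)
  summarise_interactions(p, "salt_bridge")
}

#' @rdname contacts
#' @export
find_disulfides <- function(model, cutoff = 2.5) {
  at <- prep_polymer(model)
  sg <- filter(at, .data$resname == "CYS", .data$elety == "SG")
  p <- atom_pair_table(sg, sg, cutoff, self = TRUE)
  summarise_interactions(p, "disulfide")
}

#' @rdname contacts
#' @export
find_hbonds <- function(model, cutoff = 3.5, sb_cutoff = 3.5,
                        ss_cutoff = 2.5) {
  at <- prep_polymer(model)
  da <- filter(at, .data$element %in% c("N", "O", "S"))
  p <- atom_pair_table(da, da, cutoff, self = TRUE)
  if (nrow(p) > 0) {
    # peptide-bond C(i)-N(i+1) pairs are covalent, not hydrogen bonds
    covalent <- p$chain1 == p$chain2 &
      ((p$elety1 == "C" & p$elety2 == "N" & p$ord2 == p$ord1 + 1) |
         (p$elety2 == "C" & p$elety1 == "N" & p$ord1 == p$ord2 + 1))
    p <- p[!covalent, ]
    masked <- higher_kind_keys(at, sb_cutoff = sb_cutoff,
                               ss_cutoff = ss_cutoff)
    p <- p[!(pair_key(p) %in% masked), ]
  }
  summarise_interactions(p, "hbond")
}

#' @rdname contacts
#' @export
find_vdw_contacts <- function(model, cutoff = 4.0, sb_cutoff = 3.5,
                              ss_cutoff = 2.5, hb_cutoff = 3.5) {
  at <- prep_polymer(model)
  apolar <- filter(at, .data$element %in% c("C", "S"))
  p <- atom_pair_table(apolar, apolar, cutoff, self = TRUE)
  if (nrow(p) > 0) {
    masked <- higher_kind_keys(at, sb_cutoff = sb_cutoff,
                               ss_cutoff = ss_cutoff,
                               hb_cutoff = hb_cutoff, with_hbonds = TRUE)
    p <- p[!(pair_key(p) %in% masked), ]
  }
  summarise_interactions(p, "vdw")
}

# atom-pair keys already claimed by higher-precedence interaction kinds
higher_kind_keys <- function(at, sb_cutoff = 3.5, ss_cutoff = 2.5,
                             hb_cutoff = 3.5, with_hbonds = FALSE) {
  sg <- filter(at, .data$resname == "CYS", .data$elety == "SG")
  keys <- character()
  pss <- atom_pair_table(sg, sg, ss_cutoff, self = TRUE)
  keys <- c(keys, pair_key(pss))
  psb <- atom_pair_table(acidic_atoms(at), basic_atoms(at), sb_cutoff)
  keys <- c(keys, pair_key(psb))
  if (with_hbonds) {
    da <- filter(at, .data$element %in% c("N", "O", "S"))
    phb <- atom_pair_table(da, da, hb_cutoff, self = TRUE)
    keys <- c(keys, pair_key(phb))
  }
  unique(keys)
}

#' Run all four contact detectors with the precedence chain
#'
#' @inheritParams contacts
#' @param cutoffs Named list overriding per-kind cutoffs (`salt_bridge`,
#'   `hbond`, `disulfide`, `vdw`).
#' @return A combined `interaction_set` tibble.
#' @export
find_contacts <- function(model, cutoffs = list()) {
  cut <- utils::modifyList(
    list(salt_bridge = 3.5, hbond = 3.5, disulfide = 2.5, vdw = 4.0),
    cutoffs)
  out <- bind_rows(
    find_disulfides(model, cut$disulfide),
    find_salt_bridges(model, cut$salt_bridge),
    find_hbonds(model, cut$hbond, sb_cutoff = cut$salt_bridge,
                ss_cutoff = cut$disulfide),
    find_vdw_contacts(model, cut$vdw, sb_cutoff = cut$salt_bridge,
                      ss_cutoff = cut$disulfide, hb_cutoff = cut$hbond))
  class(out) <- c("interaction_set", class(out))
  out
}

#' Count interactions by kind and span
#'
#' Counting units follow the deposited-structure conventions: salt bridges,
#' van der Waals contacts and disulfides count residue pairs; hydrogen
#' bonds count atom pairs; `n_bidentate` counts salt-bridge residue pairs
#' with two or more simultaneous atom pairs.
#'
#' @param interactions An `interaction_set` tibble.
#' @return Tibble with columns `kind`, `span`, `count`, `n_bidentate`.
#' @export
count_interactions <- function(interactions) {
  if (nrow(interactions) == 0)
    return(tibble(kind = character(), span = character(),
                  count = integer(), n_bidentate = integer()))
  interactions |>
    group_by(.data$kind, .data$span) |>
    summarise(
      count = ifelse(first(.data$kind) == "hbond",
                     sum(.data$n_atom_pairs), n()),
      n_bidentate = sum(.data$bidentate %in% TRUE),
      .groups = "drop")
}

#' Export an interaction set as TSV
#'
#' @param interactions An `interaction_set` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_interactions_tsv <- function(interactions, path) {
  flat <- interactions |>
    select(-"atom_pairs") |>
    rename(min_distance = "min_dist")
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
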