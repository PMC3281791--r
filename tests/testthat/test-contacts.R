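# two-residue fixture: an Asp carboxylate oxygen near a Lys terminal amine
salt_pair_model <- function(d, chain2 = "A") {
  toy_model(
    atom_row(chain = "A", resno = 1, resname = "ASP", elety = "OD2",
             element = "O"),
    atom_row(chain = "A", resno = 1, resname = "ASP", elety = "CA",
             element = "C", z = -2.5),
    atom_row(chain = chain2, resno = 10, resname = "LYS", elety = "NZ",
             element = "N", x = d),
    atom_row(chain = chain2, resno = 10, resname = "LYS", elety = "CA",
             element = "C", x = d, z = 2.5))
}

test_that("salt bridges follow the strict distance rule and bidentate flag", {
  sb <- find_salt_bridges(salt_pair_model(3.0))
  expect_equal(nrow(sb), 1)
  expect_equal(sb$span, "intra")
  expect_false(sb$bidentate)
  expect_equal(sb$min_dist, 3.0, tolerance = 1e-9)

  expect_equal(nrow(find_salt_bridges(salt_pair_model(3.5))), 0)

  # second carboxylate oxygen within range -> bidentate, still one pair
  m <- salt_pair_model(3.0)
  m$atoms <- dplyr::bind_rows(
    m$atoms,
    atom_row(chain = "A", resno = 1, resname = "ASP", elety = "OD1",
             element = "O", y = 0.8))
  sb2 <- find_salt_bridges(struct_model(m$atoms))
  expect_equal(nrow(sb2), 1)
  expect_true(sb2$bidentate)
  expect_equal(sb2$n_atom_pairs, 2)
})

test_that("N-terminal amine counts as basic, C-terminal OXT as acidic", {
  m <- toy_model(
    atom_row(chain = "A", resno = 1, resname = "GLY", elety = "N",
             element = "N"),
    atom_row(chain = "A", resno = 2, resname = "GLY", elety = "CA",
             element = "C", x = 20),
    atom_row(chain = "B", resno = 5, resname = "GLY", elety = "OXT",
             element = "O", x = 2.8))
  sb <- find_salt_bridges(m)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$span, "inter")
})

test_that("hydrogen bonds use N/O/S pairs, strict cutoff, no covalent peptide pair", {
  m <- toy_model(
    atom_row(resno = 1, resname = "ALA", elety = "O", element = "O"),
    atom_row(resno = 5, resname = "ALA", elety = "N", element = "N",
             x = 2.9))
  expect_equal(nrow(find_hbonds(m)), 1)

  m2 <- toy_model(
    atom_row(resno = 1, resname = "ALA", elety = "O", element = "O"),
    atom_row(resno = 5, resname = "ALA", elety = "N", element = "N",
             x = 3.6))
  expect_equal(nrow(find_hbonds(m2)), 0)

  # consecutive backbone C-N at peptide-bond distance is not an H-bond
  m3 <- toy_model(
    atom_row(resno = 1, resname = "ALA", elety = "C", element = "C"),
    atom_row(resno = 2, resname = "ALA", elety = "N", element = "N",
             x = 1.33))
  expect_equal(nrow(find_hbonds(m3)), 0)
})

test_that("the ideal helix shows the canonical i to i+4 backbone bond pattern", {
  h <- make_helix_chain(15)
  hb <- find_hbonds(h)
  i4 <- dplyr::filter(hb, resno2 - resno1 == 4,
                      purrr::map_lgl(atom_pairs, function(p)
                        any(p$elety1 == "O" & p$elety2 == "N" |
                              p$elety1 == "N" & p$elety2 == "O")))
  expect_equal(nrow(i4), 11)
})

test_that("disulfides are Cys SG pairs under 2.5 A with chain span labels", {
  m <- toy_model(
    atom_row(chain = "A", resno = 1, resname = "CYS", elety = "SG",
             element = "S"),
    atom_row(chain = "B", resno = 1, resname = "CYS", elety = "SG",
             element = "S", x = 2.05))
  ss <- find_disulfides(m)
  expect_equal(nrow(ss), 1)
  expect_equal(ss$span, "inter")

  m2 <- toy_model(
    atom_row(chain = "A", resno = 1, resname = "CYS", elety = "SG",
             element = "S"),
    atom_row(chain = "A", resno = 9, resname = "CYS", elety = "SG",
             element = "S", x = 4.0))
  expect_equal(nrow(find_disulfides(m2)), 0)
})

test_that("van der Waals contacts count apolar residue pairs once", {
  m <- toy_model(
    atom_row(resno = 1, resname = "LEU", elety = "CD1", element = "C"),
    atom_row(resno = 7, resname = "LEU", elety = "CD1", element = "C",
             x = 3.8),
    atom_row(resno = 7, resname = "LEU", elety = "CD2", element = "C",
             x = 3.9, y = 0.4))
  vdw <- find_vdw_contacts(m)
  expect_equal(nrow(vdw), 1)          # one residue pair, two atom pairs
  expect_equal(vdw$n_atom_pairs, 2)

  m2 <- toy_model(
    atom_row(resno = 1, resname = "LEU", elety = "CD1", element = "C"),
    atom_row(resno = 7, resname = "LEU", elety = "CD1", element = "C",
             x = 4.6))
  expect_equal(nrow(find_vdw_contacts(m2)), 0)
})

test_that("an atom pair contributes to at most one interaction kind", {
  # SG-SG at disulfide range: claimed by the disulfide, invisible to
  # H-bond (S is a donor/acceptor) and vdW (S is apolar) detectors
  m <- toy_model(
    atom_row(chain = "A", resno = 1, resname = "CYS", elety = "SG",
             element = "S"),
    atom_row(chain = "B", resno = 1, resname = "CYS", elety = "SG",
             element = "S", x = 2.05))
  expect_equal(nrow(find_disulfides(m)), 1)
  expect_equal(nrow(find_hbonds(m)), 0)
  expect_equal(nrow(find_vdw_contacts(m)), 0)

  # acid-base pair at 3.0: salt bridge, not an H-bond
  msb <- salt_pair_model(3.0)
  expect_equal(nrow(find_salt_bridges(msb)), 1)
  expect_equal(nrow(find_hbonds(msb)), 0)

  # free SG-SG at 3.0: past disulfide range, claimed by the H-bond kind
  m3 <- toy_model(
    atom_row(chain = "A", resno = 1, resname = "CYS", elety = "SG",
             element = "S"),
    atom_row(chain = "B", resno = 1, resname = "CYS", elety = "SG",
             element = "S", x = 3.0))
  expect_equal(nrow(find_disulfides(m3)), 0)
  expect_equal(nrow(find_hbonds(m3)), 1)
  expect_equal(nrow(find_vdw_contacts(m3)), 0)
})

test_that("contact detection is invariant under chain swap and rigid motion", {
  m <- make_planted_complex(plant_spec(2, 1, 1, 2, seed = 3))
  base <- count_interactions(dplyr::filter(find_contacts(m),
                                           span == "inter"))

  swapped <- m
  swapped$atoms$chain <- ifelse(swapped$atoms$chain == "A", "B", "A")
  cs <- count_interactions(dplyr::filter(find_contacts(swapped),
                                         span == "inter"))
  expect_equal(dplyr::arrange(base, kind), dplyr::arrange(cs, kind))

  moved <- rigid_perturb(m, c(0.5, -1.1, 0.7), c(20, -5, 12))
  cm <- count_interactions(dplyr::filter(find_contacts(moved),
                                         span == "inter"))
  expect_equal(dplyr::arrange(base, kind), dplyr::arrange(cm, kind))
})

test_that("planted complexes are recovered exactly across 50 seeds", {
  for (seed in 1:50) {
    spec <- plant_spec(n_salt_bridges = seed %% 4, n_hbonds = (seed + 1) %% 3,
                       n_disulfides = seed %% 2,
                       n_apolar_contacts = (seed + 2) %% 5,
                       seed = seed)
    cc <- dplyr::filter(find_contacts(make_planted_complex(spec)),
                        span == "inter")
    got <- function(k) sum(cc$kind == k)
    expect_equal(got("salt_bridge"), spec$n_salt_bridges, info = seed)
    expect_equal(got("hbond"), spec$n_hbonds, info = seed)
    expect_equal(got("disulfide"), spec$n_disulfides, info = seed)
    expect_equal(got("vdw"), spec$n_apolar_contacts, info = seed)
  }
})

test_that("intra plus inter counts partition the totals per kind", {
  m <- make_planted_complex(plant_spec(2, 2, 1, 3, seed = 8))
  all <- find_contacts(m)
  cnt <- count_interactions(all)
  by_kind <- dplyr::summarise(dplyr::group_by(cnt, kind),
                              total = sum(count))
  for (k in by_kind$kind) {
    tot <- dplyr::filter(by_kind, kind == k)$total
    parts <- dplyr::filter(cnt, kind == k)
    expect_equal(sum(parts$count), tot)
  }
  # and the TSV export round-trips the flat columns
  f <- withr::local_tempfile(fileext = ".tsv")
  export_interactions_tsv(all, f)
  flat <- utils::read.delim(f)
  expect_equal(nrow(flat), nrow(all))
  expect_true(all(c("kind", "chain1", "resno1", "min_distance", "span")
                  %in% names(flat)))
})
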