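test_that("distant chains give a zero interface with no residues", {
  h <- make_helix_chain(8)
  b <- dplyr::mutate(model_chain(h, "A"), chain = "B", x = x + 50)
  m <- struct_model(dplyr::bind_rows(model_chain(h, "A"), b))
  s <- pairwise_interface_summary(m, c("A", "B"), n_points = 240)
  expect_equal(s$interface_area, 0)
  expect_equal(nrow(s$residues1), 0)
  expect_equal(nrow(s$residues2), 0)
  expect_error(pairwise_interface_summary(m, c("A", "Z")), "unknown")
})

test_that("interfacing residues match an independent per-residue ASA difference", {
  h <- make_helix_chain(10)
  a <- model_chain(h, "A")
  b <- dplyr::mutate(a, chain = "B", x = x + 6.5)
  m <- struct_model(dplyr::bind_rows(a, b))
  s <- pairwise_interface_summary(m, c("A", "B"), n_points = 240)

  # oracle: recompute the per-residue drop from three direct SASA calls
  free <- dplyr::bind_rows(
    shrake_rupley_sasa(a, n_points = 240)$per_residue,
    shrake_rupley_sasa(b, n_points = 240)$per_residue)
  cplx <- shrake_rupley_sasa(dplyr::bind_rows(a, b),
                             n_points = 240)$per_residue
  j <- dplyr::left_join(free, dplyr::rename(cplx, a2 = area),
                        by = c("chain", "resno", "insert", "resname"))
  want <- dplyr::filter(j, area - a2 > 0.1)
  got <- dplyr::bind_rows(s$residues1, s$residues2)
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$chain, got$resno),
                  paste(want$chain, want$resno))
})

test_that("interface area is symmetric and vanishes under separation", {
  h <- make_helix_chain(8)
  a <- model_chain(h, "A")
  b <- dplyr::mutate(a, chain = "B", x = x + 6.5)
  m <- struct_model(dplyr::bind_rows(a, b))
  s1 <- pairwise_interface_summary(m, c("A", "B"), n_points = 240)
  s2 <- pairwise_interface_summary(m, c("B", "A"), n_points = 240)
  expect_equal(s1$interface_area, s2$interface_area, tolerance = 1e-9)

  areas <- vapply(c(8, 14, 50), function(d) {
    bb <- dplyr::mutate(a, chain = "B", x = x + d)
    mm <- struct_model(dplyr::bind_rows(a, bb))
    pairwise_interface_summary(mm, c("A", "B"),
                               n_points = 240)$interface_area
  }, numeric(1))
  expect_true(all(diff(c(s1$interface_area, areas)) <= 1e-9))
  expect_equal(areas[3], 0)
})

test_that("a D2-like toy tetramer is classified as a dimer of dimers", {
  tet <- toy_tetramer(seed = 2)
  cm <- classify_assembly_interfaces(tet, n_points = 240)
  lab <- cm$labels
  tight <- dplyr::filter(lab, label == "tight_dimer")
  expect_equal(nrow(tight), 2)
  # the two tight pairs are disjoint and are the large-contact x pairs
  expect_setequal(unlist(tight[, c("chain1", "chain2")]),
                  c("A", "B", "C", "D"))
  expect_setequal(paste(tight$chain1, tight$chain2),
                  c("A B", "C D"))
  expect_gt(min(tight$interface_area),
            max(dplyr::filter(lab, label == "tetramer_interface")$interface_area))
  expect_gt(cm$tetramer_buried_area, 0)
  expect_equal(sum(lab$label == "tetramer_interface"), 2)
})

test_that("classification follows geometry, not chain labels", {
  tet <- toy_tetramer(seed = 6)
  relab <- tet
  map <- c(A = "D", B = "C", C = "B", D = "A")
  relab$atoms$chain <- unname(map[relab$atoms$chain])
  cm1 <- classify_assembly_interfaces(tet, n_points = 240)
  cm2 <- classify_assembly_interfaces(relab, n_points = 240)
  key <- function(cm, what) {
    t <- dplyr::filter(cm$labels, label == what)
    sort(paste(pmin(t$chain1, t$chain2), pmax(t$chain1, t$chain2)))
  }
  # A/B <-> D/C and C/D <-> B/A: same geometric pairs under the relabeling
  expect_equal(key(cm2, "tight_dimer"), c("A B", "C D"))
  expect_equal(key(cm1, "tight_dimer"), c("A B", "C D"))
  expect_equal(cm1$tetramer_buried_area, cm2$tetramer_buried_area,
               tolerance = 1e-9)
})

test_that("a two-chain model yields a single tight dimer", {
  h <- make_helix_chain(8)
  a <- model_chain(h, "A")
  b <- dplyr::mutate(a, chain = "B", x = x + 6.5)
  m <- struct_model(dplyr::bind_rows(a, b))
  cm <- classify_assembly_interfaces(m, n_points = 240)
  expect_equal(cm$labels$label, "tight_dimer")
  expect_error(classify_assembly_interfaces(h), "at least 2")
})

test_that("a uniformly apolar surface gives hydrophobic P = 1", {
  m <- make_planted_complex(plant_spec(n_apolar_contacts = 4,
                                       interface_apolar_fraction = 1,
                                       n_pad = 4, seed = 5))
  # make both bodies all-carbon: every patch ties the observed fraction
  m$atoms$elety <- "CD1"
  m$atoms$element <- "C"
  m$atoms$resname <- "LEU"
  p <- hydrophobic_pvalue(m, c("A", "B"), n_samples = 200, seed = 3,
                          n_points = 240)
  expect_equal(as.numeric(p), 1)
})

test_that("the hydrophobic P-value is deterministic given a seed", {
  m <- make_planted_complex(plant_spec(n_apolar_contacts = 3,
                                       interface_apolar_fraction = 0.5,
                                       seed = 4))
  p1 <- hydrophobic_pvalue(m, c("A", "B"), n_samples = 300, seed = 17,
                           n_points = 240)
  p2 <- hydrophobic_pvalue(m, c("A", "B"), n_samples = 300, seed = 17,
                           n_points = 240)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_error(hydrophobic_pvalue(m, c("A", "B"), n_samples = 50),
               "n_samples")
})

test_that("an all-apolar planted interface on mixed chains is detected as enriched", {
  m <- make_planted_complex(plant_spec(n_apolar_contacts = 6,
                                       interface_apolar_fraction = 1,
                                       n_pad = 0, body_radius = 14,
                                       seed = 2))
  p <- hydrophobic_pvalue(m, c("A", "B"), n_samples = 2000, seed = 11,
                          n_points = 240)
  expect_equal(attr(p, "observed_apolar_fraction"), 1)
  expect_lt(as.numeric(p), 0.05)
})

test_that("P is approximately uniform when the observation is its own null draw", {
  m <- make_planted_complex(plant_spec(n_apolar_contacts = 2, seed = 6))
  s <- shrake_rupley_sasa(model_chain(m, "A"), n_points = 240)
  nulls <- quatstab:::null_patch_fractions(list(s), target = 120,
                                           n_samples = 400, seed = 21)
  draws <- quatstab:::null_patch_fractions(list(s), target = 120,
                                           n_samples = 50, seed = 99)
  ps <- vapply(draws, function(o) mean(nulls >= o - 1e-12), numeric(1))
  expect_gte(mean(ps), 0.4)
  expect_lte(mean(ps), 0.6)
})
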