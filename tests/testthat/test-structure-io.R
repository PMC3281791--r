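test_that("a minimal hand-written PDB parses into one chain, one residue, two atoms", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb_lines, f)
  m <- read_structure(f)
  expect_s3_class(m, "struct_model")
  expect_equal(chain_ids(m), "A")
  at <- polymer_atoms(m)
  expect_equal(nrow(at), 2)
  expect_equal(unique(at$resno), 1)
  expect_equal(at$elety, c("N", "CA"))
  expect_equal(at$x[1], 11.104, tolerance = 1e-6)
  expect_equal(m$space_group, "P 21 21 21")
})

test_that("alternate locations resolve to highest occupancy, ties alphabetically", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CB AALA A   2       5.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   2       7.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  m <- read_structure(f)
  at <- polymer_atoms(m)
  expect_equal(nrow(at), 2)
  expect_equal(at$x[at$resno == 1], 0)    # occupancy 0.6 wins
  expect_equal(at$x[at$resno == 2], 5)    # tie -> alt-loc A
})

test_that("waters and cofactors are flagged hetero and hydrogens dropped", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  HA  ALA A   1       0.500   0.500   0.000  1.00  0.00           H",
    "HETATM    3  O   HOH A 101       3.000   0.000   0.000  1.00  0.00           O",
    "HETATM    4  SD  SAM A 201       6.000   0.000   0.000  1.00  0.00           S",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(polymer_atoms(m)), 1)       # hydrogens gone, het out
  expect_equal(sum(m$atoms$het), 2)
  expect_false("H" %in% m$atoms$element)
})

test_that("sequence extraction maps residues and honours the source", {
  m <- toy_model(atom_row(resno = 1, resname = "ALA", elety = "CA"),
                 atom_row(resno = 2, resname = "GLY", elety = "CA", x = 4))
  expect_equal(extract_sequence(m, "A"), "AG")
  m2 <- toy_model(atom_row(resno = 1, resname = "XYZ", elety = "CA"))
  expect_equal(extract_sequence(m2, "A"), "X")
  m3 <- m
  m3$seqres <- list(A = c("ALA", "GLY", "PRO", "PRO"))
  expect_equal(extract_sequence(m3, "A", source = "seqres"), "AGPP")
  expect_error(extract_sequence(m, "Z"), "no polymer atoms")
})

test_that("write/read round trip preserves counts and coordinates to PDB precision", {
  h <- make_helix_chain(12, "ACDEFGHIKLMN")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(h, f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), nrow(h$atoms))
  expect_equal(length(chain_ids(m)), length(chain_ids(h)))
  expect_lt(max(abs(model_xyz(polymer_atoms(m)) -
                      model_xyz(polymer_atoms(h)))), 1e-3)
  expect_equal(extract_sequence(m, "A"), "ACDEFGHIKLMN")
})

test_that("REMARK 350 transforms are captured and drive assembly building", {
  h <- make_helix_chain(8)
  f <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(h, f)
  writeLines(c(remark350_222_lines, readLines(f)), f2)
  m <- read_structure(f2)
  expect_length(m$transforms, 4)
  asm <- build_assembly(m)
  expect_equal(length(chain_ids(asm)), 4)
  expect_equal(nrow(asm$atoms), 4 * nrow(h$atoms))
  # 222 point symmetry: chain centroids pairwise equidistant from center
  cents <- sapply(chain_ids(asm), function(ch) {
    colMeans(model_xyz(model_chain(asm, ch)))
  })
  g <- rowMeans(cents)
  d <- apply(cents, 2, function(c) sqrt(sum((c - g)^2)))
  expect_lt(max(d) - min(d), 1e-6)
})

test_that("assembly building validates rotations and scales chain counts", {
  h <- make_helix_chain(8)
  id <- build_assembly(h, list(assembly_transform(diag(3))))
  expect_equal(length(chain_ids(id)), 1)
  expect_false(chain_ids(id) == "ZZZ")
  expect_equal(model_xyz(polymer_atoms(id)), model_xyz(polymer_atoms(h)))

  # k transforms -> k times the polymer chains
  tfs <- lapply(1:3, function(k)
    assembly_transform(diag(3), c(30 * k, 0, 0), op_id = k))
  expect_equal(length(chain_ids(build_assembly(h, tfs))), 3)

  bad <- diag(3); bad[1, 1] <- -1   # reflection
  expect_error(assembly_transform(bad), "orthonormal")
  expect_error(build_assembly(h, list()), "transforms")
})

test_that("rigid assembly copies preserve intra-chain distances", {
  h <- make_helix_chain(10)
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  asm <- build_assembly(h, list(assembly_transform(rot, c(5, -3, 2))))
  d0 <- dist(model_xyz(polymer_atoms(h)))
  d1 <- dist(model_xyz(model_chain(asm, chain_ids(asm)[1])))
  expect_lt(max(abs(d0 - d1)), 1e-6)
})

test_that("mmCIF files parse atoms and assembly operators", {
  cif <- c(
    "data_TOY",
    "_symmetry.space_group_name_H-M 'I 2 2 2'",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 10.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 10.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 2.009 1.422 0.000 1.00 10.00 ? 1 ALA A C 1",
    "#",
    "loop_",
    "_pdbx_struct_assembly_gen.assembly_id",
    "_pdbx_struct_assembly_gen.oper_expression",
    "_pdbx_struct_assembly_gen.asym_id_list",
    "1 '(1-4)' A",
    "#",
    "loop_",
    "_pdbx_struct_oper_list.id",
    "_pdbx_struct_oper_list.type",
    "_pdbx_struct_oper_list.matrix[1][1]",
    "_pdbx_struct_oper_list.matrix[1][2]",
    "_pdbx_struct_oper_list.matrix[1][3]",
    "_pdbx_struct_oper_list.vector[1]",
    "_pdbx_struct_oper_list.matrix[2][1]",
    "_pdbx_struct_oper_list.matrix[2][2]",
    "_pdbx_struct_oper_list.matrix[2][3]",
    "_pdbx_struct_oper_list.vector[2]",
    "_pdbx_struct_oper_list.matrix[3][1]",
    "_pdbx_struct_oper_list.matrix[3][2]",
    "_pdbx_struct_oper_list.matrix[3][3]",
    "_pdbx_struct_oper_list.vector[3]",
    "1 'identity operation' 1 0 0 0 0 1 0 0 0 0 1 0",
    "2 'crystal symmetry operation' -1 0 0 30 0 -1 0 30 0 0 1 0",
    "3 'crystal symmetry operation' -1 0 0 30 0 1 0 0 0 0 -1 30",
    "4 'crystal symmetry operation' 1 0 0 0 0 -1 0 30 0 0 -1 30",
    "#")
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, f)
  m <- read_structure(f)
  expect_equal(nrow(polymer_atoms(m)), 3)
  expect_equal(m$space_group, "I 2 2 2")
  expect_length(m$transforms, 4)
  asm <- build_assembly(m)
  expect_equal(length(chain_ids(asm)), 4)
})

test_that("unreadable files raise a parse error naming the file", {
  expect_error(read_structure("/nonexistent/file.pdb"), "not found")
})
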