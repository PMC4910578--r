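test_that("a minimal single-atom PDB record parses into one chain/residue/atom", {
  txt <- c(pdb_line(serial = 1, x = 1.5, y = -2.25, z = 3.125), "END")
  s <- parse_structure(txt)
  expect_s3_class(s, "plgic_structure")
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(unique(s$atoms$chain), "A")
  expect_equal(s$atoms$resno, 1L)
  expect_equal(unname(unlist(s$atoms[1, c("x", "y", "z")])), c(1.5, -2.25, 3.125))
  expect_length(s$ligands, 0)
})

test_that("malformed coordinate records and unknown formats raise clear errors", {
  bad <- c(pdb_line(), "ATOM      2  CA  ALA A")
  expect_error(parse_structure(bad), "line 2")
  expect_error(parse_structure(pdb_line(), format = "xyz"), "arg")
})

test_that("altloc groups collapse to the highest-occupancy conformer, ties by label", {
  txt <- c(
    pdb_line(serial = 1, alt = "A", x = 1, occ = 0.4),
    pdb_line(serial = 2, alt = "B", x = 2, occ = 0.6),
    pdb_line(serial = 3, name = "CB", alt = "A", x = 5, occ = 0.5),
    pdb_line(serial = 4, name = "CB", alt = "B", x = 6, occ = 0.5),
    "END"
  )
  s <- parse_structure(txt)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$x[s$atoms$elety == "CA"], 2)  # higher occupancy wins
  expect_equal(s$atoms$x[s$atoms$elety == "CB"], 5)  # tie: label order
})

test_that("ligand extraction excludes solvent but keeps site-occupying cations", {
  txt <- c(
    pdb_line(serial = 1),
    pdb_line("HETATM", 2, name = "O", resn = "HOH", chain = "A", resno = 100,
             x = 9, elem = "O"),
    pdb_line("HETATM", 3, name = "ZN", resn = "ZN", chain = "A", resno = 101,
             x = 12, elem = "ZN"),
    pdb_line("HETATM", 4, name = "BA", resn = "BA", chain = "A", resno = 102,
             x = 15, elem = "BA"),
    "END"
  )
  s <- parse_structure(txt)
  hets <- vapply(s$ligands, `[[`, "", "het_name")
  expect_setequal(hets, c("ZN", "BA"))
  expect_length(extract_ligands(s, include = "ZN"), 1L)

  water_only <- parse_structure(c(
    pdb_line(serial = 1),
    pdb_line("HETATM", 2, name = "O", resn = "HOH", chain = "A", resno = 50,
             x = 8, elem = "O"), "END"))
  expect_length(water_only$ligands, 0)
})

test_that("a planted pseudo-ligand is recovered as exactly one instance", {
  pl <- plant_ligand(fixture_pentamer(), 1)
  ligs <- pl$structure$ligands
  expect_length(ligs, 1L)
  expect_equal(ligs[[1]]$key, pl$expected$ligand_key)
  expect_equal(nrow(ligs[[1]]$atoms), 4L)
})

test_that("select_calpha returns residues in chain then residue order", {
  pent <- fixture_pentamer()
  sel <- select_calpha(pent$structure, "A:5-14")
  expect_equal(nrow(sel), 10L)
  expect_equal(sel$resno, 5:14)
  expect_error(select_calpha(pent$structure, "Z"), "missing chain")

  ## het residues without alpha carbons are skipped
  pl <- plant_ligand(pent, 9, chains = "A")
  all_a <- select_calpha(pl$structure, "A")
  expect_equal(nrow(all_a), pent$truth$n_residues)

  ## the whole-structure selection is deterministic across calls
  expect_identical(select_calpha(pent$structure), select_calpha(pent$structure))
})

test_that("an ECD selection matches the generator's residue count", {
  pent <- fixture_pentamer()
  ecd_res <- as.integer(names(pent$truth$domain)[pent$truth$domain == "ECD"])
  sel <- select_calpha(pent$structure,
                       sprintf("A:%d-%d", min(ecd_res), max(ecd_res)))
  expect_equal(nrow(sel), length(ecd_res))
})

test_that("parse/write round trip preserves keys exactly and coordinates to field precision", {
  s <- fixture_pentamer()$structure
  rt <- parse_structure(write_structure(s), label = s$label)
  key0 <- plgicmap:::res_key(s$atoms$chain, s$atoms$resno, s$atoms$ins)
  key1 <- plgicmap:::res_key(rt$atoms$chain, rt$atoms$resno, rt$atoms$ins)
  expect_identical(key1, key0)
  for (col in c("x", "y", "z")) {
    expect_lt(max(abs(rt$atoms[[col]] - s$atoms[[col]])), 1e-3)
  }
  ## identity re-emission is byte-stable
  expect_identical(write_structure(rt), write_structure(rt))
})

test_that("write_structure applies rigid transforms and flags overflow", {
  txt <- c(pdb_line(x = 1, y = 0, z = 0), "END")
  s <- parse_structure(txt)
  rot90 <- rigid_transform(rotation_about_axis(c(0, 0, 1), pi / 2))
  out <- parse_structure(write_structure(s, transform = rot90))
  expect_equal(unname(unlist(out$atoms[1, c("x", "y", "z")])), c(0, 1, 0),
               tolerance = 1e-3)
  expect_error(
    write_structure(s, transform = rigid_transform(t = c(1e5, 0, 0))),
    "overflow")
})

test_that("a random rigid transform superposes back onto the original below 1e-3 A", {
  s <- fixture_pentamer()$structure
  moved <- parse_structure(write_structure(
    s, transform = rigid_transform(rotation_about_axis(c(1, 1, 0), 1.1),
                                   c(4, -7, 2))))
  p <- as.matrix(moved$atoms[, c("x", "y", "z")])
  q <- as.matrix(s$atoms[, c("x", "y", "z")])
  expect_lt(kabsch_fit(p, q)$rmsd, 1e-3)
})

test_that("mmCIF input is read with author numbering preserved", {
  cif <- c(
    "data_test", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol", "label_atom_id",
                            "label_alt_id", "label_comp_id", "label_asym_id",
                            "label_entity_id", "label_seq_id",
                            "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                            "Cartn_z", "occupancy", "B_iso_or_equiv",
                            "pdbx_formal_charge", "auth_seq_id",
                            "auth_comp_id", "auth_asym_id", "auth_atom_id",
                            "pdbx_PDB_model_num")),
    "ATOM 1 C CA . ALA A 1 1 ? 1.000 2.000 3.000 1.00 0.00 ? 10 ALA A CA 1",
    "ATOM 2 C CA . GLY A 1 2 ? 4.000 5.000 6.000 1.00 0.00 ? 11 GLY A CA 1"
  )
  s <- parse_structure(cif, format = "mmcif")
  expect_equal(s$atoms$resno, c(10L, 11L))
  expect_equal(s$atoms$resid, c("ALA", "GLY"))
  expect_equal(s$atoms$x, c(1, 4))
})
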