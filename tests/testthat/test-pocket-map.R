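test_that("ligand contacts match the planted brute-force set and respect the cutoff", {
  pent <- fixture_pentamer()
  for (cls in c(1, 7, 9)) {
    pl <- plant_ligand(pent, cls)
    cs <- ligand_contacts(pl$structure, pl$expected$ligand_key,
                          cutoff = plgicmap:::FIXTURE_CONTACT_CUTOFF)
    expect_identical(lapply(cs$contacts, sort), lapply(pl$expected$contacts, sort),
                     info = paste("site class", cls))
  }
  expect_error(ligand_contacts(plant_ligand(pent, 1)$structure, "A:901:",
                               cutoff = -1), "positive")
})

test_that("a ligand farther than the cutoff from every atom yields an empty contact set", {
  pent <- fixture_pentamer()
  pl <- plant_ligand(pent, 9, chains = "A")
  at <- pl$structure$atoms
  sel <- at$het
  ## push the ligand 20 A radially outward
  xy <- as.matrix(at[sel, c("x", "y")])
  ctr <- colMeans(xy)
  u <- ctr / sqrt(sum(ctr^2))
  at[sel, c("x", "y")] <- sweep(xy, 2, 20 * u, `+`)
  s2 <- plgicmap:::new_structure("FAR", at)
  cs <- ligand_contacts(s2, s2$ligands[[1]],
                        cutoff = plgicmap:::FIXTURE_CONTACT_CUTOFF)
  expect_length(cs$contacts, 0)
})

test_that("contact sets grow monotonically with the cutoff and are rigid-invariant", {
  pent <- fixture_pentamer()
  pl <- plant_ligand(pent, 8, chains = "A")
  cs_small <- ligand_contacts(pl$structure, pl$expected$ligand_key, cutoff = 5.5)
  cs_big <- ligand_contacts(pl$structure, pl$expected$ligand_key, cutoff = 7.5)
  expect_true(all(unlist(cs_small$contacts) %in% unlist(cs_big$contacts)))

  moved <- apply_random_rigid(pl$structure, seed = 17)
  cs_moved <- ligand_contacts(moved, pl$expected$ligand_key,
                              cutoff = plgicmap:::FIXTURE_CONTACT_CUTOFF)
  cs_orig <- ligand_contacts(pl$structure, pl$expected$ligand_key,
                             cutoff = plgicmap:::FIXTURE_CONTACT_CUTOFF)
  expect_identical(cs_moved$contacts, cs_orig$contacts)
})

test_that("every plantable site class is recovered by the classification cascade", {
  pent <- fixture_pentamer()
  aln <- fixture_alignment()
  for (cls in 1:10) {
    pl <- plant_ligand(pent, cls)
    cs <- ligand_contacts(pl$structure, pl$expected$ligand_key,
                          cutoff = plgicmap:::FIXTURE_CONTACT_CUTOFF)
    sc <- classify_site(cs, pl$structure, aln)
    expect_equal(sc$site_class, cls, info = paste("site class", cls))
    expect_equal(sc$interface, cls %in% c(1, 2, 3, 7),
                 info = paste("interface flag for class", cls))
    if (sc$interface) {
      expect_equal(sc$principal_chain, "A")
      expect_equal(sc$complementary_chain, "B")
    }
  }
})

test_that("single-chain contact sets are never classified as interface sites", {
  pent <- fixture_pentamer()
  aln <- fixture_alignment()
  for (cls in c(4, 5, 6, 8, 9, 10)) {
    pl <- plant_ligand(pent, cls, chains = "C")
    cs <- ligand_contacts(pl$structure, pl$expected$ligand_key,
                          cutoff = plgicmap:::FIXTURE_CONTACT_CUTOFF)
    expect_length(cs$contacts, 1L)
    sc <- classify_site(cs, pl$structure, aln)
    expect_false(sc$site_class %in% c(1, 2, 3, 7))
  }
})

test_that("occlusion scoring reproduces constructed overlap fractions", {
  pent <- fixture_pentamer()
  s <- pent$structure
  far <- matrix(c(500, 500, 500), 1, 3)
  expect_equal(occlusion_score(far, s), 0)

  ca <- select_calpha(s)
  on_atoms <- as.matrix(ca[1:4, c("x", "y", "z")])
  expect_equal(occlusion_score(on_atoms, s), 1)

  ## k of n atoms clashing -> k/n
  mixed <- rbind(on_atoms[1:2, ], far, far)
  expect_equal(occlusion_score(mixed, s), 0.5)
})

test_that("identity transfer maps the full pocket and is judged plausible", {
  pent <- fixture_pentamer()
  aln <- fixture_alignment()
  pl <- plant_ligand(pent, 4, chains = "A")
  cs <- ligand_contacts(pl$structure, pl$expected$ligand_key,
                        cutoff = plgicmap:::FIXTURE_CONTACT_CUTOFF)
  corr <- alignment_correspondence(aln, "A", "A", pl$structure, "A",
                                   pent$structure, "A")
  tr <- transfer_site(cs, corr, pl$structure, pent$structure)
  expect_setequal(unname(unlist(tr$mapped)), unname(unlist(cs$contacts)))
  expect_equal(tr$unmapped_count, 0L)
  expect_lte(tr$occlusion, 0.25)
  expect_equal(tr$verdict, "plausible")
})

test_that("transfer onto the insertion-occluded variant is rejected", {
  pent <- fixture_pentamer()
  occ <- fixture_occluded()
  pl <- plant_ligand(pent, 4, chains = "A")
  cs <- ligand_contacts(pl$structure, pl$expected$ligand_key,
                        cutoff = plgicmap:::FIXTURE_CONTACT_CUTOFF)
  corr <- structural_correspondence(pl$structure, "A", occ$structure, "A")
  tr <- transfer_site(cs, corr, pl$structure, occ$structure)
  expect_gt(tr$occlusion, 0.25)
  expect_equal(tr$verdict, "occluded")
})

test_that("transfer fails loudly with too few mappable pocket residues", {
  pent <- fixture_pentamer()
  pl <- plant_ligand(pent, 9, chains = "A")
  cs <- ligand_contacts(pl$structure, pl$expected$ligand_key,
                        cutoff = plgicmap:::FIXTURE_CONTACT_CUTOFF)
  empty_corr <- plgicmap:::new_correspondence(
    c("X", "A"), c("Y", "A"),
    data.frame(source_key = "A:1:", target_key = "A:1:", flagged = FALSE),
    "alignment")
  expect_error(transfer_site(cs, list(empty_corr), pl$structure,
                             pent$structure), "fewer than 3")
})

test_that("the atlas reports planted classes once each and merges shared pockets", {
  pent <- fixture_pentamer()
  aln <- fixture_alignment()
  s <- pent$structure
  for (cls in c(1, 7, 9)) {
    s <- plant_ligand(list(structure = s, truth = pent$truth), cls)$structure
  }
  atlas <- build_site_atlas(list(SYNTH = s), aln,
                            cutoff = plgicmap:::FIXTURE_CONTACT_CUTOFF)
  expect_equal(nrow(atlas), 3L)
  expect_setequal(atlas$site_class, c(1, 7, 9))
  expect_equal(attr(atlas, "n_classes"), 3L)

  ## two copies in one pocket merge into a single occurrence
  s2 <- plant_ligand(pent, 8, chains = "A")$structure
  s2 <- plant_ligand(list(structure = s2, truth = pent$truth), 8,
                     chains = "A")$structure
  atlas2 <- build_site_atlas(list(SYNTH = s2), aln,
                             cutoff = plgicmap:::FIXTURE_CONTACT_CUTOFF)
  expect_equal(nrow(atlas2), 1L)
  expect_equal(atlas2$n_copies, 2L)
})

test_that("an empty structure list yields an empty atlas", {
  atlas <- build_site_atlas(list(), fixture_alignment())
  expect_equal(nrow(atlas), 0L)
  expect_equal(attr(atlas, "n_classes"), 0L)
})
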