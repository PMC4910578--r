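test_that("ideal helix and strand traces are labelled from Ca geometry alone", {
  hx <- plgicmap:::helix_points(12, start = c(0, 0, 0))
  s <- ca_trace_structure(hx)
  expect_gte(sum(assign_sse(s, "A") == "H"), 10)

  st <- plgicmap:::strand_points(8, start = c(0, 0, 0),
                                 dir = c(1, 0, 0), perp = c(0, 1, 0))
  s2 <- ca_trace_structure(st)
  expect_gte(sum(assign_sse(s2, "A") == "E"), 6)

  expect_error(assign_sse(ca_trace_structure(hx[1:4, ]), "A"), "fewer than 5")
})

test_that("SSE assignment agrees with the generator's planted labels (>= 90%)", {
  pent <- fixture_pentamer()
  lab <- assign_sse(pent$structure, "A")
  truth <- pent$truth$sse[names(lab)]
  expect_gte(mean(lab == truth), 0.9)
})

test_that("structural correspondence of a rigid copy is the identity pairing", {
  pent <- fixture_pentamer()
  moved <- apply_random_rigid(pent$structure, seed = 3)
  corr <- structural_correspondence(pent$structure, "A", moved, "A")
  expect_equal(nrow(corr$pairs), pent$truth$n_residues)
  expect_true(all(corr$pairs$source_key == corr$pairs$target_key))
  expect_lt(attr(corr, "rmsd"), 1e-6)
})

test_that("structural correspondence survives 0.3 A coordinate noise (>= 95% identity)", {
  pent <- fixture_pentamer()
  noisy <- perturb_state(pent, noise_sd = 0.3, seed = 11)$structure
  corr <- structural_correspondence(pent$structure, "A", noisy, "A")
  frac <- mean(corr$pairs$source_key == corr$pairs$target_key) *
    nrow(corr$pairs) / pent$truth$n_residues
  expect_gte(frac, 0.95)
})

test_that("structural correspondence is symmetric and transform-invariant on rigid copies", {
  pent <- fixture_pentamer()
  moved <- apply_random_rigid(pent$structure, seed = 5)
  fwd <- structural_correspondence(pent$structure, "A", moved, "A")
  rev <- structural_correspondence(moved, "A", pent$structure, "A")
  expect_identical(fwd$pairs$source_key, rev$pairs$target_key)
  expect_identical(fwd$pairs$target_key, rev$pairs$source_key)

  moved2 <- apply_random_rigid(pent$structure, seed = 8)
  corr2 <- structural_correspondence(moved2, "A", moved, "A")
  expect_identical(corr2$pairs, fwd$pairs)
})

test_that("alignment correspondence pairs column-sharing residues and honours gaps", {
  aln <- master_alignment(
    c(a = "VTGLSAKEND", b = "VTGLSAKEND"),
    anchors = rep("none", 10)
  )
  sa <- sequence_structure("VTGLSAKEND", label = "SA")
  sb <- sequence_structure("VTGLSAKEND", label = "SB")
  corr <- alignment_correspondence(aln, "a", "b", sa, "A", sb, "A")
  expect_equal(nrow(corr$pairs), 10L)
  expect_identical(corr$pairs$source_key, corr$pairs$target_key)

  aln2 <- master_alignment(
    c(a = "VTGLSAKEND", b = "VTG-----ND"),
    anchors = rep("none", 10)
  )
  sb2 <- sequence_structure("VTGND", label = "SB2")
  corr2 <- alignment_correspondence(aln2, "a", "b", sa, "A", sb2, "A")
  expect_equal(nrow(corr2$pairs), 10L - 5L)
})

test_that("alignment correspondence matches a brute-force column scan on gapped rows", {
  set.seed(7)
  for (rep in 1:3) {
    n <- 30L
    aa <- sample(names(plgicmap:::AA1TO3), n, replace = TRUE)
    gaps_a <- sort(sample(n, 4)); gaps_b <- sort(sample(n, 6))
    row_a <- aa; row_a[gaps_a] <- "-"
    row_b <- aa; row_b[gaps_b] <- "-"
    aln <- master_alignment(c(a = paste(row_a, collapse = ""),
                              b = paste(row_b, collapse = "")),
                            anchors = rep("none", n))
    sa <- sequence_structure(paste(row_a[row_a != "-"], collapse = ""))
    sb <- sequence_structure(paste(row_b[row_b != "-"], collapse = ""))
    corr <- alignment_correspondence(aln, "a", "b", sa, "A", sb, "A")
    ## brute force: walk the columns, counting ungapped positions
    expected <- NULL
    pa <- 0L; pb <- 0L
    for (j in seq_len(n)) {
      ga <- row_a[j] == "-"; gb <- row_b[j] == "-"
      if (!ga) pa <- pa + 1L
      if (!gb) pb <- pb + 1L
      if (!ga && !gb) expected <- rbind(expected, c(pa, pb))
    }
    expect_equal(nrow(corr$pairs), nrow(expected))
    expect_equal(plgicmap:::split_key(corr$pairs$source_key)$resno, expected[, 1])
    expect_equal(plgicmap:::split_key(corr$pairs$target_key)$resno, expected[, 2])
  }
})

test_that("sequence/structure mismatches beyond 2% abort with positions listed", {
  aln <- master_alignment(c(a = "VTGLSAKEND", b = "VTGLSAKEND"),
                          anchors = rep("none", 10))
  sa <- sequence_structure("VTGLSAKEND")
  sbad <- sequence_structure("VTGASAKEEE")  # 3/10 mismatched
  expect_error(
    alignment_correspondence(aln, "a", "b", sa, "A", sbad, "A"),
    "mismatch")
})

test_that("alignment and structural correspondences agree on >= 90% of pairs", {
  pent <- fixture_pentamer()
  aln <- fixture_alignment()
  ## two homolog chains built from the same template, different ring positions
  cs <- structural_correspondence(pent$structure, "A", pent$structure, "B")
  ca <- alignment_correspondence(aln, "A", "B",
                                 pent$structure, "A", pent$structure, "B")
  key_s <- paste(cs$pairs$source_key, cs$pairs$target_key)
  key_a <- paste(ca$pairs$source_key, ca$pairs$target_key)
  expect_gte(length(intersect(key_s, key_a)) / length(key_a), 0.9)
})

test_that("the strand-8' validator enforces hydrophobic/any/hydrophobic-or-small", {
  mk <- function(...) {
    rows <- c(...)
    n <- nchar(rows[1])
    anchors <- rep("none", n)
    anchors[4:6] <- "strand8p"
    master_alignment(rows, anchors)
  }
  rep1 <- validate_strand8(mk(b3 = "KNDVTGSEQ"))
  expect_true(all(rep1$pass))
  expect_equal(rep1$windows[["b3"]], "VTG")

  rep2 <- validate_strand8(mk(bad = "KNDDTGSEQ"))
  expect_false(rep2$pass[["bad"]])
  expect_equal(rep2$violations$position, 1L)

  expect_error(validate_strand8(master_alignment(c(x = "AAAA"),
                                                 rep("none", 4))),
               "strand8p")
})

test_that("validator violation counts equal a brute-force per-row scan", {
  hydro <- plgicmap:::HYDROPHOBIC_AA
  small <- plgicmap:::SMALL_AA
  set.seed(13)
  aas <- setdiff(names(plgicmap:::AA1TO3), character())
  rows <- vapply(1:20, function(i)
    paste(sample(aas, 9, replace = TRUE), collapse = ""), "")
  names(rows) <- paste0("r", 1:20)
  anchors <- rep("none", 9); anchors[4:6] <- "strand8p"
  rep <- validate_strand8(master_alignment(rows, anchors))
  brute <- 0L
  for (r in rows) {
    w <- strsplit(substr(r, 4, 6), "")[[1]]
    if (!(w[1] %in% hydro)) brute <- brute + 1L
    if (!(w[3] %in% c(hydro, small))) brute <- brute + 1L
  }
  expect_equal(nrow(rep$violations), brute)
})

test_that("master alignment invariants are enforced", {
  expect_error(master_alignment(c(a = "AAA", b = "AAAA"), rep("none", 4)),
               "length")
  expect_error(master_alignment(c(a = "AAAA"), c("loopA", "none", "loopA", "none")),
               "contiguous")
  expect_error(master_alignment(c(a = "AAAA"), rep("loopZ", 4)), "unknown anchor")
})

test_that("alignment files round-trip through FASTA plus sidecar", {
  aln <- fixture_alignment()
  fa <- tempfile(fileext = ".fasta"); sc <- tempfile(fileext = ".tsv")
  write_alignment(aln, fa, sc)
  back <- read_alignment(fa, sc)
  expect_identical(unname(back$rows), unname(aln$rows))
  expect_identical(back$anchors, aln$anchors)
  unlink(c(fa, sc))
})
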