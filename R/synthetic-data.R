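## Synthetic pentamer fixtures with planted ground truth.
##
## The generator emits C5-symmetric pentamers of two-domain subunits:
## an ECD block (an N-terminal helix plus inner/outer strand bundles and
## the binding-site loops A-G) stacked on a four-helix TMD (M1-M4).
## Domains are internally rigid; perturb_state() applies controlled
## twist/tilt of the ECD relative to the TMD, the motion the analysis
## pipeline is meant to recover.  Fixtures are alpha-carbon plus
## pseudo-ligand heavy atoms only (no side chains), so contact detection
## on synthetic data uses Ca atoms as the heavy-atom set; tests use a
## 6.5 A contact cutoff on fixtures versus 4.0 A on real structures.

FIXTURE_CONTACT_CUTOFF <- 6.5

#' Specification for a synthetic pentamer
#'
#' @param seed Integer seed controlling sequence sampling and noise.
#' @param n_chains Number of subunits (5).
#' @param ecd_residues,tmd_residues Approximate residue counts per
#'   domain (minimum 30 each); strand and helix lengths are scaled to
#'   meet them.
#' @param ring_radius Radius of the subunit-centre ring, Angstrom.
#' @param noise_sd Gaussian coordinate noise, Angstrom.
#' @param occluding_insertion Lengthen the strand5-strand5' loop so that
#'   it fills the vestibule pocket (the insertion that blocks the
#'   vestibule site in anion-selective receptors).
#' @return A `plgic_synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L, n_chains = 5L, ecd_residues = 90L,
                           tmd_residues = 90L, ring_radius = 17,
                           noise_sd = 0, occluding_insertion = FALSE) {
  if (ecd_residues < 30L || tmd_residues < 30L) {
    stop("ecd_residues and tmd_residues must each be at least 30")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (n_chains != 5L) stop("the generator emits pentamers (n_chains = 5)")
  structure(
    list(seed = as.integer(seed), n_chains = 5L,
         ecd_residues = as.integer(ecd_residues),
         tmd_residues = as.integer(tmd_residues),
         ring_radius = ring_radius, noise_sd = noise_sd,
         occluding_insertion = isTRUE(occluding_insertion)),
    class = "plgic_synthetic_spec"
  )
}

## ---- geometry primitives ------------------------------------------------

## Ideal alpha helix: rise 1.5 A, 100 deg/residue, radius 2.3 A, axis
## along `dir` (unit), starting at `start`.
helix_points <- function(n, start, dir = c(0, 0, 1), phase = 0) {
  dir <- dir / sqrt(sum(dir^2))
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * dir) * dir; u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  i <- seq_len(n) - 1L
  ang <- phase + i * 100 * pi / 180
  t(vapply(seq_len(n), function(k) {
    start + i[k] * 1.5 * dir + 2.3 * (cos(ang[k]) * u + sin(ang[k]) * v)
  }, numeric(3)))
}

## Extended strand: 3.4 A/residue along `dir` with a +/-0.5 A zigzag
## perpendicular to it (keeps the Ca(i),Ca(i+1),Ca(i+2) angle > 115 deg).
strand_points <- function(n, start, dir, perp) {
  dir <- dir / sqrt(sum(dir^2)); perp <- perp / sqrt(sum(perp^2))
  i <- seq_len(n) - 1L
  t(vapply(seq_len(n), function(k) {
    start + i[k] * 3.4 * dir + ((-1)^i[k]) * 0.5 * perp
  }, numeric(3)))
}

## Loop: points on a tight circle (radius 2.6 A, 72 deg angular step),
## which fails both the helix and strand distance masks.
loop_points <- function(n, center, normal = c(0, 0, 1), phase = 0) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * normal) * normal; u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  ang <- phase + (seq_len(n) - 1L) * 72 * pi / 180
  t(vapply(seq_len(n), function(k) {
    center + 2.6 * (cos(ang[k]) * u + sin(ang[k]) * v)
  }, numeric(3)))
}

## Straight connector with step >= 3.8 A (outside the strand distance
## window), interpolating between the previous and next segment.
connector_points <- function(n, from, to) {
  f <- seq_len(n) / (n + 1L)
  t(vapply(f, function(t0) from + t0 * (to - from), numeric(3)))
}

## ---- subunit layout -----------------------------------------------------

## Segment table for one subunit in its local frame.  Local coordinates
## are (r, t, z): radial offset from the subunit centre ring, tangential
## offset toward the plus-side neighbour, and height along the pore axis.
subunit_layout <- function(spec) {
  sl <- max(4L, (spec$ecd_residues - 54L) %/% 4L)     # ECD strand length
  hl <- max(8L, (spec$tmd_residues - 10L) %/% 4L)     # TMD helix length
  s_span <- (sl - 1L) * 3.4
  h_span <- (hl - 1L) * 1.5
  z_tmd0 <- 4; z_tmd1 <- z_tmd0 + h_span              # TMD bottom/top
  z_s0 <- 50; z_s1 <- z_s0 + s_span                   # ECD strand bottom/top
  ins_len <- if (spec$occluding_insertion) 6L else 0L
  ## type: H/E/C/X (X = connector, coil); anchor "none" where unlabeled
  list(
    sl = sl, hl = hl, z_tmd0 = z_tmd0, z_tmd1 = z_tmd1,
    z_s0 = z_s0, z_s1 = z_s1, ins_len = ins_len,
    segments = list(
      list(id = "helix1",  type = "H", n = 12L, anchor = "helix1",
           kind = "helix", at = c(5, -2, z_s1 + 2), dir = c(0, 0, 1)),
      list(id = "c1",      type = "C", n = 2L, anchor = "none", kind = "conn"),
      list(id = "strand5", type = "E", n = sl, anchor = "strand5",
           kind = "strand", at = c(-5, -2, z_s1), dir = c(0, 0, -1), perp = c(1, 0, 0)),
      list(id = "loop55p", type = "C", n = 4L + ins_len, anchor = "none",
           kind = "loop55p", at = c(-5.5, 0, z_s0 - 3)),
      list(id = "strand5p", type = "E", n = sl, anchor = "strand5p",
           kind = "strand", at = c(-5, 2, z_s0), dir = c(0, 0, 1), perp = c(1, 0, 0)),
      list(id = "c2",      type = "C", n = 2L, anchor = "none", kind = "conn"),
      list(id = "loopA",   type = "C", n = 4L, anchor = "loopA",
           kind = "loop", at = c(2, 6, z_s0 + 12)),
      list(id = "strand7", type = "E", n = sl, anchor = "strand7",
           kind = "strand", at = c(1, 4, z_s1 - 8), dir = c(0, 0, -1), perp = c(0, 1, 0)),
      list(id = "loopG",   type = "C", n = 4L, anchor = "loopG",
           kind = "loop", at = c(0, -7, z_s0 - 5)),
      list(id = "loopD",   type = "C", n = 4L, anchor = "loopD",
           kind = "loop", at = c(-1, -7, z_s0 + 16)),
      list(id = "loopE",   type = "C", n = 4L, anchor = "loopE",
           kind = "loop", at = c(-1, -7, z_s0 + 8)),
      list(id = "loopB",   type = "C", n = 4L, anchor = "loopB",
           kind = "loop", at = c(2, 7, z_s0 + 14)),
      list(id = "strand9", type = "E", n = sl, anchor = "strand9",
           kind = "strand", at = c(6, 3, z_s0), dir = c(0, 0, 1), perp = c(0, 1, 0)),
      list(id = "loopC",   type = "C", n = 5L, anchor = "loopC",
           kind = "loop", at = c(4, 9, z_s0 + 8)),
      list(id = "strand8p", type = "E", n = 3L, anchor = "strand8p",
           kind = "strand", at = c(-2, -6, z_s0 - 1), dir = c(1, 0, 0), perp = c(0, 0, 1)),
      list(id = "loopF",   type = "C", n = 4L, anchor = "loopF",
           kind = "loop", at = c(2, -8, z_s0 - 4)),
      list(id = "preM1",   type = "C", n = 4L, anchor = "preM1", kind = "conn"),
      list(id = "M1", type = "H", n = hl, anchor = "M1",
           kind = "helix", at = c(3, -6, z_tmd1), dir = c(0, 0, -1)),
      list(id = "c3", type = "C", n = 2L, anchor = "none", kind = "conn"),
      list(id = "M2", type = "H", n = hl, anchor = "M2",
           kind = "helix", at = c(-7, 0, z_tmd0), dir = c(0, 0, 1)),
      list(id = "c4", type = "C", n = 2L, anchor = "none", kind = "conn"),
      list(id = "M3", type = "H", n = hl, anchor = "M3",
           kind = "helix", at = c(3, 6, z_tmd1), dir = c(0, 0, -1)),
      list(id = "c5", type = "C", n = 2L, anchor = "none", kind = "conn"),
      list(id = "M4", type = "H", n = hl, anchor = "M4",
           kind = "helix", at = c(9, 0, z_tmd0), dir = c(0, 0, 1))
    )
  )
}

## Build one subunit in local (r, t, z) coordinates.  Returns a matrix of
## Ca positions plus per-residue segment id / anchor / type vectors.
build_subunit <- function(layout) {
  xyz <- NULL; seg_id <- character(); anchor <- character(); type <- character()
  pending_conn <- NULL
  segs <- layout$segments
  for (k in seq_along(segs)) {
    sg <- segs[[k]]
    if (sg$kind == "conn") { pending_conn <- sg; next }
    pts <- switch(sg$kind,
      helix  = helix_points(sg$n, start = sg$at, dir = sg$dir),
      strand = strand_points(sg$n, start = sg$at, dir = sg$dir, perp = sg$perp),
      loop   = loop_points(sg$n, center = sg$at),
      loop55p = {
        base <- loop_points(4L, center = sg$at)
        if (sg$n > 4L) {
          ## vestibule-occluding insertion: extra residues bulging
          ## radially inward, in front of the strand5/5' wall
          nin <- sg$n - 4L
          zmid <- (layout$z_s0 + layout$z_s1) / 2
          ins <- t(vapply(seq_len(nin), function(i) {
            ang <- (i - 1L) * 72 * pi / 180
            c(-10.5 + 2.0 * cos(ang), 2.0 * sin(ang),
              zmid + 1.2 * ((i - 1L) %% 3L - 1L))
          }, numeric(3)))
          rbind(base[1:2, , drop = FALSE], ins, base[3:4, , drop = FALSE])
        } else base
      }
    )
    if (!is.null(pending_conn)) {
      if (is.null(xyz)) {
        cp <- NULL
      } else {
        cp <- connector_points(pending_conn$n, xyz[nrow(xyz), ], pts[1L, ])
      }
      if (!is.null(cp)) {
        xyz <- rbind(xyz, cp)
        seg_id <- c(seg_id, rep(pending_conn$id, nrow(cp)))
        anchor <- c(anchor, rep(pending_conn$anchor, nrow(cp)))
        type <- c(type, rep("C", nrow(cp)))
      }
      pending_conn <- NULL
    }
    xyz <- rbind(xyz, pts)
    seg_id <- c(seg_id, rep(sg$id, nrow(pts)))
    anchor <- c(anchor, rep(sg$anchor, nrow(pts)))
    type <- c(type, rep(sg$type, nrow(pts)))
  }
  list(xyz = xyz, seg_id = seg_id, anchor = anchor, type = type)
}

## Deterministic residue sequence for one subunit (shared by all chains).
sample_sequence <- function(sub, seed) {
  pools <- list(H = c("A", "L", "E", "K", "R", "Q", "I"),
                E = c("V", "I", "T", "Y", "F", "L"),
                C = c("G", "S", "N", "D", "T", "P"))
  n <- length(sub$type)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  aa <- vapply(seq_len(n), function(i) sample(pools[[sub$type[i]]], 1L), "")
  ## the strand-8' packing motif: hydrophobic / any / hydrophobic-or-small
  s8 <- which(sub$seg_id == "strand8p")
  if (length(s8) == 3L) aa[s8] <- c("V", "T", "G")
  aa
}

## Chain frame: rotate local (r, t, z) into the global frame of chain k
## (angle 72*(k-1) degrees, counter-clockwise viewed from extracellular).
chain_angle <- function(k) (k - 1L) * 72 * pi / 180

local_to_global <- function(xyz, theta, ring_radius) {
  ur <- c(cos(theta), sin(theta), 0)
  ut <- c(-sin(theta), cos(theta), 0)
  t(apply(xyz, 1L, function(p) (ring_radius + p[1]) * ur + p[2] * ut + c(0, 0, p[3])))
}

#' Generate a synthetic C5-symmetric pentamer with ground truth
#'
#' @param spec A `plgic_synthetic_spec` from [synthetic_spec()].
#' @return List with `structure` (a `plgic_structure`) and `truth`, a
#'   ground-truth record holding per-residue SSE labels, the anchor map,
#'   per-residue domain assignment, the ungapped master alignment over
#'   the five chains, and the seeds used.
#' @export
make_pentamer <- function(spec = synthetic_spec()) {
  layout <- subunit_layout(spec)
  sub <- build_subunit(layout)
  aa <- sample_sequence(sub, spec$seed)
  n <- length(aa)
  chains <- LETTERS[seq_len(spec$n_chains)]

  rows <- list()
  atoms <- NULL
  for (k in seq_along(chains)) {
    g <- local_to_global(sub$xyz, chain_angle(k), spec$ring_radius)
    atoms <- rbind(atoms, data.frame(
      chain = chains[k], resno = seq_len(n), ins = "",
      resid = AA1TO3[aa], elety = "CA", elesy = "C",
      x = g[, 1], y = g[, 2], z = g[, 3],
      o = 1, alt = "", het = FALSE, stringsAsFactors = FALSE
    ))
    rows[[chains[k]]] <- paste(aa, collapse = "")
  }
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(spec$seed + 1000L)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, spec$noise_sd)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, spec$noise_sd)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, spec$noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }

  domain <- ifelse(sub$anchor %in% TMD_ANCHORS |
                     sub$seg_id %in% c("c3", "c4", "c5"), "TMD",
                   ifelse(sub$anchor == "preM1", "junction", "ECD"))
  label <- if (spec$occluding_insertion) "SYNTH-OCC" else "SYNTH"
  s <- new_structure(label, atoms,
                     metadata = list(synthetic = list(spec = spec, layout = layout)))
  aln <- master_alignment(unlist(rows), anchors = sub$anchor)
  sse <- setNames(rep(sub$type, length(chains)),
                  res_key(rep(chains, each = n), rep(seq_len(n), length(chains))))
  truth <- list(
    spec = spec,
    sse = sse,
    anchor = setNames(sub$anchor, seq_len(n)),
    seg_id = setNames(sub$seg_id, seq_len(n)),
    domain = setNames(domain, seq_len(n)),
    alignment = aln,
    chains = chains,
    n_residues = n
  )
  list(structure = s, truth = truth)
}

## Residue keys of a segment/anchor on a given chain.
truth_keys <- function(truth, chain, seg = NULL, anchor = NULL) {
  idx <- seq_len(truth$n_residues)
  if (!is.null(seg)) idx <- idx[truth$seg_id %in% seg]
  if (!is.null(anchor)) idx <- idx[truth$anchor[idx] %in% anchor]
  res_key(rep(chain, length(idx)), idx)
}

## Mean CA position over residue keys.
mean_ca <- function(s, keys) {
  ca <- select_calpha(s)
  colMeans(as.matrix(ca[ca$key %in% keys, c("x", "y", "z")]))
}

#' Apply a controlled conformational change to a synthetic pentamer
#'
#' Rotates every ECD alpha carbon rigidly about the pore axis by
#' `twist` degrees, then tilts each subunit's ECD by `tilt` degrees
#' about its own radial axis through the domain junction.  The TMD is
#' untouched.  Optionally displaces the loop C residues toward the
#' complementary subunit's loop D (the apparent capping/uncapping
#' motion) and adds Gaussian coordinate noise.
#'
#' @param pent A list from [make_pentamer()] (structure + truth).
#' @param twist,tilt Degrees.
#' @param noise_sd Gaussian noise, Angstrom.
#' @param seed Seed for the noise stream.
#' @param loopc_shift Displacement of loop C along the line from its tip
#'   to the neighbouring subunit's loop D centroid, Angstrom (positive =
#'   toward loop D).
#' @return A new list with the perturbed `structure` and the original
#'   `truth` augmented with the planted motion.
#' @export
perturb_state <- function(pent, twist = 0, tilt = 0, noise_sd = 0, seed = 1L,
                          loopc_shift = 0) {
  s <- pent$structure; truth <- pent$truth
  at <- s$atoms
  layout <- s$metadata$synthetic$layout
  z_junction <- (layout$z_tmd1 + 50) / 2   # between TMD top and ECD bottom
  ecd_res <- names(truth$domain)[truth$domain == "ECD"]
  for (k in seq_along(truth$chains)) {
    ch <- truth$chains[k]
    sel <- which(at$chain == ch & !at$het & as.character(at$resno) %in% ecd_res)
    if (!length(sel)) next
    xyz <- as.matrix(at[sel, c("x", "y", "z")])
    if (twist != 0) {
      R <- rotation_about_axis(c(0, 0, 1), twist * pi / 180)
      xyz <- xyz %*% t(R)
    }
    if (tilt != 0) {
      theta <- chain_angle(k) + twist * pi / 180
      ur <- c(cos(theta), sin(theta), 0)
      R <- rotation_about_axis(ur, tilt * pi / 180)
      ctr <- c(0, 0, z_junction)
      xyz <- sweep(sweep(xyz, 2L, ctr) %*% t(R), 2L, ctr, `+`)
    }
    at[sel, c("x", "y", "z")] <- xyz
  }
  if (loopc_shift != 0) {
    for (k in seq_along(truth$chains)) {
      ch <- truth$chains[k]
      nb <- truth$chains[(k %% length(truth$chains)) + 1L]
      tmp <- new_structure(s$label, at)
      lc <- truth_keys(truth, ch, seg = "loopC")
      tip <- as.numeric(mean_ca(tmp, lc[ceiling(length(lc) / 2)]))
      ld <- as.numeric(mean_ca(tmp, truth_keys(truth, nb, seg = "loopD")))
      dirv <- (ld - tip) / sqrt(sum((ld - tip)^2))
      sel <- which(at$chain == ch & !at$het &
                     res_key(at$chain, at$resno) %in% lc)
      at[sel, c("x", "y", "z")] <-
        sweep(as.matrix(at[sel, c("x", "y", "z")]), 2L, loopc_shift * dirv, `+`)
    }
  }
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    m <- nrow(at)
    at$x <- at$x + stats::rnorm(m, 0, noise_sd)
    at$y <- at$y + stats::rnorm(m, 0, noise_sd)
    at$z <- at$z + stats::rnorm(m, 0, noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  truth$planted_motion <- list(twist = twist, tilt = tilt,
                               noise_sd = noise_sd, seed = seed,
                               loopc_shift = loopc_shift)
  st <- new_structure(paste0(s$label, "-STATE"), at, metadata = s$metadata)
  list(structure = st, truth = truth)
}

## Anchor signature of each plantable site class: which segments, on
## which chain roles, surround the planted ligand.
plant_position <- function(s, truth, site_class, chain_p, chain_c) {
  mid <- function(a, b) (a + b) / 2
  switch(as.character(site_class),
    "1" = mid(mean_ca(s, truth_keys(truth, chain_p, seg = c("loopB", "loopC"))),
              mean_ca(s, truth_keys(truth, chain_c, seg = c("loopD", "loopE")))),
    "2" = {
      s7 <- truth_keys(truth, chain_p, seg = "strand7")
      s7low <- s7[(length(s7) - 2L):length(s7)]   # membrane-proximal end
      mid(mean_ca(s, s7low),
          mean_ca(s, truth_keys(truth, chain_c, seg = c("loopF", "loopG"))))
    },
    "3" = {
      ## a point ion must reach both faces: sit closer to strand 7
      s7 <- truth_keys(truth, chain_p, seg = "strand7")
      s7low <- s7[(length(s7) - 2L):length(s7)]
      a <- mean_ca(s, s7low)
      b <- mean_ca(s, truth_keys(truth, chain_c, seg = c("loopF", "loopG")))
      a + 0.38 * (b - a)
    },
    "4" = {
      w <- mean_ca(s, truth_keys(truth, chain_p, seg = c("strand5", "strand5p")))
      u <- w[1:2] / sqrt(sum(w[1:2]^2))
      c(6.5 * u, w[3])
    },
    "5" = mid(mean_ca(s, truth_keys(truth, chain_p, seg = c("strand5", "strand5p"))),
              mean_ca(s, truth_keys(truth, chain_p, seg = "strand9"))),
    "6" = {
      h <- mean_ca(s, truth_keys(truth, chain_p, seg = "helix1"))
      k <- match(chain_p, truth$chains)
      theta <- chain_angle(k)
      h - 3.2 * c(-sin(theta), cos(theta), 0)
    },
    "7" = mid(mean_ca(s, truth_keys(truth, chain_p, seg = "M3")),
              mean_ca(s, truth_keys(truth, chain_c, seg = "M1"))),
    "8" = {
      p <- rbind(mean_ca(s, truth_keys(truth, chain_p, seg = "M1")),
                 mean_ca(s, truth_keys(truth, chain_p, seg = "M2")),
                 mean_ca(s, truth_keys(truth, chain_p, seg = "M3")))
      colMeans(p)
    },
    "9" = mid(mean_ca(s, truth_keys(truth, chain_p, seg = "M1")),
              mean_ca(s, truth_keys(truth, chain_p, seg = "M4"))),
    "10" = {
      m3 <- truth_keys(truth, chain_p, seg = "M3")
      m4 <- truth_keys(truth, chain_p, seg = "M4")
      mid(mean_ca(s, m3[(length(m3) - 4L):length(m3)]),  # M3 runs downward
          mean_ca(s, m4[1:5]))                           # M4 starts at the bottom
    },
    stop("site class ", site_class, " cannot be planted on the synthetic geometry")
  )
}

#' Plant a pseudo-ligand of a given site class
#'
#' Places a rigid multi-atom pseudo-ligand (a single cation for class 3)
#' so that its fixture-cutoff contact set carries the anchor signature
#' of the requested class, and returns the expected contact set computed
#' by an independent brute-force scan.
#'
#' @param pent A list from [make_pentamer()] / [perturb_state()].
#' @param site_class Integer 1-10 (all classes except the pore are
#'   placeable; interface classes use `chains`, intra-subunit classes the
#'   first element of `chains`).
#' @param chains Chain ids: `c(principal, complementary)` for interface
#'   classes, a single chain otherwise.  Defaults to `c("A", "B")`.
#' @param cutoff Contact cutoff used for the expected set (fixture
#'   default 6.5 A, Ca-as-heavy-atom convention).
#' @return List with `structure` (ligand added) and `expected`, a
#'   `plgic_contact_set` of the planted ground truth.
#' @export
plant_ligand <- function(pent, site_class, chains = c("A", "B"),
                         cutoff = FIXTURE_CONTACT_CUTOFF) {
  s <- pent$structure; truth <- pent$truth
  chain_p <- chains[1]
  chain_c <- if (length(chains) > 1L) chains[2] else
    truth$chains[(match(chain_p, truth$chains) %% length(truth$chains)) + 1L]
  ctr <- plant_position(s, truth, site_class, chain_p, chain_c)
  cation <- site_class == 3
  if (cation) {
    lig_xyz <- matrix(ctr, 1L, 3L)
    resid <- "ZN"; elety <- "ZN"; elesy <- "ZN"
  } else {
    offs <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(-0.7, 1.2, 0),
                  c(-0.7, -1.2, 0.8))
    lig_xyz <- sweep(offs, 2L, ctr, `+`)
    resid <- "LIG"; elety <- paste0("C", seq_len(nrow(lig_xyz))); elesy <- "C"
  }
  existing <- s$atoms$resno[s$atoms$het & s$atoms$chain == chain_p]
  resno <- if (length(existing)) max(existing) + 1L else 901L
  lig <- data.frame(
    chain = chain_p, resno = resno, ins = "", resid = resid,
    elety = elety, elesy = elesy,
    x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
    o = 1, alt = "", het = TRUE, stringsAsFactors = FALSE
  )
  s2 <- new_structure(s$label, rbind(s$atoms, lig), metadata = s$metadata)

  ## expected contacts: independent plain double loop over residues
  prot <- s2$atoms[!s2$atoms$het, , drop = FALSE]
  keys <- res_key(prot$chain, prot$resno, prot$ins)
  contacts <- list()
  for (key in unique(keys)) {
    ra <- prot[keys == key, c("x", "y", "z"), drop = FALSE]
    hit <- FALSE
    for (i in seq_len(nrow(ra))) {
      for (j in seq_len(nrow(lig_xyz))) {
        if (sqrt(sum((as.numeric(ra[i, ]) - lig_xyz[j, ])^2)) <= cutoff) {
          hit <- TRUE; break
        }
      }
      if (hit) break
    }
    if (hit) {
      ch <- strsplit(key, ":", fixed = TRUE)[[1]][1]
      contacts[[ch]] <- c(contacts[[ch]], key)
    }
  }
  expected <- new_contact_set(
    ligand_key = res_key(chain_p, resno),
    het_name = resid, contacts = contacts, cutoff = cutoff
  )
  list(structure = s2, expected = expected,
       truth = c(truth, list(planted_site = list(class = site_class,
                                                 chains = c(chain_p, chain_c),
                                                 ligand_resno = resno))))
}
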