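# Shared fixtures, built once per test run.  All fixtures are generated
# in code; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture_pentamer <- function() {
  if (is.null(.fixture_env$pent)) {
    .fixture_env$pent <- make_pentamer(synthetic_spec(seed = 42))
  }
  .fixture_env$pent
}

fixture_alignment <- function() fixture_pentamer()$truth$alignment

fixture_occluded <- function() {
  if (is.null(.fixture_env$occ)) {
    .fixture_env$occ <- make_pentamer(synthetic_spec(seed = 42,
                                                     occluding_insertion = TRUE))
  }
  .fixture_env$occ
}

# Structure from a bare Ca trace (one chain), used for SSE unit tests.
ca_trace_structure <- function(xyz, chain = "A", resid = "ALA",
                               label = "TRACE") {
  n <- nrow(xyz)
  atoms <- data.frame(
    chain = chain, resno = seq_len(n), ins = "", resid = resid,
    elety = "CA", elesy = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, alt = "", het = FALSE, stringsAsFactors = FALSE
  )
  plgicmap:::new_structure(label, atoms)
}

# Minimal chain whose sequence matches a one-letter string; coordinates
# on a loose spiral so every residue has a distinct CA.
sequence_structure <- function(seq1, chain = "A", label = "SEQ") {
  aa <- strsplit(seq1, "")[[1]]
  n <- length(aa)
  t <- seq_len(n)
  xyz <- cbind(10 * cos(t / 3), 10 * sin(t / 3), 3.4 * t)
  s <- ca_trace_structure(xyz, chain = chain, label = label)
  s$atoms$resid <- plgicmap:::AA1TO3[aa]
  plgicmap:::new_structure(label, s$atoms)
}

# A fixed-width PDB ATOM/HETATM line.
pdb_line <- function(type = "ATOM", serial = 1, name = "CA", alt = " ",
                     resn = "ALA", chain = "A", resno = 1, ins = " ",
                     x = 0, y = 0, z = 0, occ = 1, b = 0, elem = "C") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resn, chain, resno, ins, x, y, z, occ, b, elem)
}

apply_random_rigid <- function(s, seed = 1) {
  set.seed(seed)
  tr <- rigid_transform(plgicmap:::random_rotation(), stats::runif(3, -20, 20))
  at <- s$atoms
  at[, c("x", "y", "z")] <- apply_transform(as.matrix(at[, c("x", "y", "z")]), tr)
  plgicmap:::new_structure(s$label, at, metadata = s$metadata)
}

# Independent rotational optimizer: minimize RMSD over rotations
# parameterized by Euler angles (translation solved at the centroids).
bruteforce_min_rmsd <- function(p, q, n_starts = 8) {
  pc <- sweep(p, 2, colMeans(p)); qc <- sweep(q, 2, colMeans(q))
  obj <- function(ang) {
    Rz1 <- rotation_about_axis(c(0, 0, 1), ang[1])
    Ry <- rotation_about_axis(c(0, 1, 0), ang[2])
    Rz2 <- rotation_about_axis(c(0, 0, 1), ang[3])
    R <- Rz1 %*% Ry %*% Rz2
    sqrt(mean(rowSums((pc %*% t(R) - qc)^2)))
  }
  best <- Inf
  set.seed(99)
  for (k in seq_len(n_starts)) {
    start <- stats::runif(3, -pi, pi)
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-14))
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}
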