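## Least-squares rigid superposition and RMSD bookkeeping.
##
## All superpositions are alpha-carbon based and correspondence-driven:
## no outlier trimming is performed, so every matched residue pair
## contributes to the reported RMSD.

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) RMSD of point set `p` onto point set `q`.  Reflections are
#' excluded by construction.
#'
#' @param p,q Numeric matrices of matched points (n x 3), n >= 3.
#' @param weights Optional non-negative weights, length n.
#' @param subset_label Free-form label stored on the result.
#' @return A `plgic_superposition`: list with `rotation` (3x3, det +1),
#'   `translation`, `rmsd` (Angstrom), `n_pairs` and `subset_label`.
#'   The fitted map is `x %*% t(rotation) + translation`.
#' @export
kabsch_fit <- function(p, q, weights = NULL, subset_label = "custom") {
  p <- as.matrix(p); q <- as.matrix(q)
  if (!all(dim(p) == dim(q)) || ncol(p) != 3L) {
    stop("p and q must be matched n x 3 matrices")
  }
  n <- nrow(p)
  if (n < 3L) stop("at least 3 point pairs are required for a rigid fit")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0) stop("invalid weights")
  w <- w / sum(w)
  cp <- colSums(p * w); cq <- colSums(q * w)
  pc <- sweep(p, 2L, cp); qc <- sweep(q, 2L, cq)
  sv <- svd(crossprod(pc * w, qc))
  if (sv$d[2] < 1e-10) {
    stop("degenerate geometry: points are collinear, rotation is not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  fitted <- sweep(p %*% t(R), 2L, t, `+`)
  rmsd <- sqrt(sum(w * rowSums((fitted - q)^2)))
  structure(
    list(rotation = R, translation = t, rmsd = rmsd, n_pairs = n,
         subset_label = subset_label),
    class = "plgic_superposition"
  )
}

#' @export
print.plgic_superposition <- function(x, ...) {
  cat(sprintf("<superposition [%s]: %d pairs, RMSD %.4f A>\n",
              x$subset_label, x$n_pairs, x$rmsd))
  invisible(x)
}

## Gather matched CA coordinate pairs from a correspondence (or a list
## of correspondences), optionally restricted to a set of source keys.
corr_ca_pairs <- function(a, b, corrs, source_keys = NULL) {
  if (inherits(corrs, "plgic_correspondence")) corrs <- list(corrs)
  ca_a <- select_calpha(a); ca_b <- select_calpha(b)
  P <- NULL; Q <- NULL; keys <- character()
  for (corr in corrs) {
    pr <- corr$pairs
    if (!is.null(source_keys)) {
      pr <- pr[pr$source_key %in% source_keys, , drop = FALSE]
    }
    ia <- match(pr$source_key, ca_a$key)
    ib <- match(pr$target_key, ca_b$key)
    ok <- !is.na(ia) & !is.na(ib)
    P <- rbind(P, as.matrix(ca_a[ia[ok], c("x", "y", "z")]))
    Q <- rbind(Q, as.matrix(ca_b[ib[ok], c("x", "y", "z")]))
    keys <- c(keys, pr$source_key[ok])
  }
  list(P = P, Q = Q, keys = keys)
}

#' Superpose two structures on a residue subset
#'
#' Restricts a correspondence set to a domain subset (a set of source
#' residue keys, e.g. from [anchor_keys()]) and performs a Kabsch fit
#' over the matched alpha carbons.
#'
#' @param a,b `plgic_structure`s (source, target).
#' @param corrs A correspondence or list of correspondences from
#'   [structural_correspondence()] / [alignment_correspondence()].
#' @param subset Optional character vector of source residue keys; `NULL`
#'   uses every matched pair.
#' @param subset_label Label recorded on the result (e.g. "ECD", "TMD",
#'   "subunit", "pentamer").
#' @return A `plgic_superposition`.
#' @export
superpose_subset <- function(a, b, corrs, subset = NULL,
                             subset_label = if (is.null(subset)) "subunit" else "custom") {
  pq <- corr_ca_pairs(a, b, corrs, source_keys = subset)
  if (is.null(pq$P) || nrow(pq$P) < 3L) {
    stop("subset restriction leaves fewer than 3 matched residues")
  }
  kabsch_fit(pq$P, pq$Q, subset_label = subset_label)
}

## Correspondences for one ordered chain pairing between two structures,
## built either from the master alignment or structurally, memoized in
## `cache` (an environment) across calls.
chain_pair_corrs <- function(a, b, chains_a, chains_b, mode, aln, row_for,
                             cache = NULL) {
  lapply(seq_along(chains_a), function(i) {
    ca <- chains_a[i]; cb <- chains_b[i]
    id <- paste(a$label, ca, b$label, cb, mode, sep = "|")
    if (!is.null(cache) && !is.null(cache[[id]])) return(cache[[id]])
    corr <- if (mode == "alignment") {
      alignment_correspondence(aln, row_for(a, ca), row_for(b, cb), a, ca, b, cb)
    } else {
      structural_correspondence(a, ca, b, cb)
    }
    if (!is.null(cache)) cache[[id]] <- corr
    corr
  })
}

#' Pairwise RMSD matrix over an ensemble
#'
#' Computes the symmetric matrix of pairwise alpha-carbon RMSDs over a
#' list of structures.  In pentamer mode each entry is minimized over the
#' five cyclic chain-order assignments (mirror assignments are never
#' considered, preserving the counter-clockwise subunit convention).
#'
#' @param structures Named list of `plgic_structure`s (>= 2).
#' @param mode `"alignment"` (requires `aln`) or `"structural"`.
#' @param aln Master alignment used when `mode = "alignment"`.
#' @param subset Optional source residue-key subset (applied per
#'   structure through `subset_for`, see below) restricting the fit.
#' @param subset_for Optional `function(structure)` returning the source
#'   key subset for that structure; overrides `subset`.
#' @param pentamer_mode Minimize over cyclic chain assignments.
#' @param chains Optional character vector of chain ids defining the ring
#'   order; defaults to each structure's chain order.
#' @param row_for `function(structure, chain)` mapping a chain to its
#'   alignment row id (default: the chain id itself).
#' @param subset_label Label stored on the result.
#' @return A `plgic_rmsd_matrix`: list with `labels`, `matrix`,
#'   `subset_label`, `mode`.
#' @export
pairwise_rmsd <- function(structures, mode = c("alignment", "structural"),
                          aln = NULL, subset = NULL, subset_for = NULL,
                          pentamer_mode = FALSE, chains = NULL,
                          row_for = function(s, chain) chain,
                          subset_label = if (pentamer_mode) "pentamer" else "subunit") {
  mode <- match.arg(mode)
  if (length(structures) < 2L) stop("need at least two structures")
  labels <- names(structures) %||% vapply(structures, `[[`, "", "label")
  if (is.null(names(structures))) names(structures) <- labels
  n <- length(structures)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- structures[[i]]; b <- structures[[j]]
      sub_a <- if (!is.null(subset_for)) subset_for(a) else subset
      val <- tryCatch({
        ch_a <- chains %||% protein_chains(a)
        ch_b <- chains %||% protein_chains(b)
        if (pentamer_mode) {
          k <- length(ch_a)
          rmsds <- vapply(seq_len(k) - 1L, function(shift) {
            cb <- ch_b[((seq_len(k) - 1L + shift) %% k) + 1L]
            corrs <- chain_pair_corrs(a, b, ch_a, cb, mode, aln, row_for, cache)
            superpose_subset(a, b, corrs, subset = sub_a,
                             subset_label = subset_label)$rmsd
          }, 0)
          min(rmsds)
        } else {
          corrs <- chain_pair_corrs(a, b, ch_a, ch_b, mode, aln, row_for, cache)
          superpose_subset(a, b, corrs, subset = sub_a,
                           subset_label = subset_label)$rmsd
        }
      }, error = function(e) NA_real_)
      m[i, j] <- m[j, i] <- val
    }
  }
  structure(
    list(labels = labels, matrix = m, subset_label = subset_label, mode = mode),
    class = "plgic_rmsd_matrix"
  )
}

#' @export
print.plgic_rmsd_matrix <- function(x, ...) {
  cat(sprintf("<RMSD matrix [%s, %s]: %d structures>\n",
              x$subset_label, x$mode, length(x$labels)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Longitudinal pore axis of a pentamer
#'
#' The reference axis is the principal axis of the pooled alpha-carbon
#' cloud of the supplied residues (by convention the M2 helices),
#' oriented so that `positive_toward` (e.g. the ECD centroid) lies on
#' the positive side.
#'
#' @param s A `plgic_structure`.
#' @param keys Residue keys defining the axis cloud; `NULL` uses every
#'   alpha carbon.
#' @param positive_toward Optional 3-vector the axis should point toward.
#' @return List with unit `axis` and `center`.
#' @export
pore_axis <- function(s, keys = NULL, positive_toward = NULL) {
  ca <- select_calpha(s)
  if (!is.null(keys)) ca <- ca[ca$key %in% keys, , drop = FALSE]
  if (nrow(ca) < 3L) stop("too few residues to define a pore axis")
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  center <- colMeans(xyz)
  ax <- prcomp(xyz, center = TRUE)$rotation[, 1]
  if (!is.null(positive_toward) &&
      sum((positive_toward - center) * ax) < 0) ax <- -ax
  list(axis = as.numeric(ax), center = as.numeric(center))
}

#' Rigid-body domain-motion decomposition
#'
#' Quantifies how the extracellular domain moves relative to the
#' transmembrane domain between two conformations of the same subunit.
#' The TMDs are superposed first; the residual ECD-onto-ECD rotation,
#' expressed in the TMD frame, is decomposed into a twist about the pore
#' axis and a tilt (swing) of that axis.
#'
#' @param a,b Source and target `plgic_structure`s.
#' @param corr Correspondence for the subunit being analysed.
#' @param ecd_keys,tmd_keys Source residue keys of the two domains.
#' @param axis Pore axis of the target structure (list from
#'   [pore_axis()]); computed from all target alpha carbons when `NULL`.
#' @return A `plgic_domain_motion`: list with `twist` and `tilt`
#'   (degrees, in `[0, 180]`), `residual_rmsd_ecd`, `residual_rmsd_tmd`
#'   (Angstrom) and `degenerate` (TRUE when the rotation angle is below
#'   0.1 degrees, in which case twist and tilt are reported as 0).
#' @export
domain_motion <- function(a, b, corr, ecd_keys, tmd_keys, axis = NULL) {
  fit_tmd <- superpose_subset(a, b, corr, subset = tmd_keys, subset_label = "TMD")
  fit_ecd <- superpose_subset(a, b, corr, subset = ecd_keys, subset_label = "ECD")
  if (is.null(axis)) axis <- pore_axis(b)
  ## residual ECD rotation after the TMD alignment, in the target frame
  R_res <- fit_ecd$rotation %*% t(fit_tmd$rotation)
  dec <- swing_twist(R_res, axis$axis)
  degenerate <- dec$total < 0.1
  structure(
    list(
      twist = if (degenerate) 0 else dec$twist,
      tilt = if (degenerate) 0 else dec$swing,
      residual_rmsd_ecd = fit_ecd$rmsd,
      residual_rmsd_tmd = fit_tmd$rmsd,
      degenerate = degenerate
    ),
    class = "plgic_domain_motion"
  )
}

#' @export
print.plgic_domain_motion <- function(x, ...) {
  cat(sprintf(
    "<domain motion: twist %.2f deg, tilt %.2f deg, ECD rmsd %.3f A, TMD rmsd %.3f A%s>\n",
    x$twist, x$tilt, x$residual_rmsd_ecd, x$residual_rmsd_tmd,
    if (x$degenerate) ", degenerate" else ""
  ))
  invisible(x)
}

#' Export an RMSD matrix as TSV
#'
#' @param m A `plgic_rmsd_matrix`.
#' @param file Output path.
#' @export
write_rmsd_tsv <- function(m, file) {
  df <- as.data.frame(m$matrix)
  df <- cbind(structure_label = rownames(df), df)
  df[is.na(df)] <- "."
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
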