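## Residue-level correspondences between chains.
##
## Two routes produce the same Correspondence contract: the curated
## master alignment (anchor-annotated, sequence-based) and a
## sequence-independent structural matcher that seeds a Kabsch fit from
## compatible secondary-structure segments and refines by iterative
## nearest-neighbour pairing.  Correspondences are always one-to-one and
## monotone in both chains' residue order: pLGIC subunits are
## topologically sequential, and enforcing monotonicity keeps results
## deterministic.

ANCHOR_LABELS <- c(paste0("loop", LETTERS[1:7]),
                   "strand5", "strand5p", "strand7", "strand8p", "strand9",
                   "helix1", "preM1", "M1", "M2", "M3", "M4", "MX", "MA",
                   "none")

ECD_ANCHORS <- c(paste0("loop", LETTERS[1:7]),
                 "strand5", "strand5p", "strand7", "strand8p", "strand9",
                 "helix1")
TMD_ANCHORS <- c("M1", "M2", "M3", "M4")
ICD_ANCHORS <- c("MX", "MA")

#' Construct a master alignment
#'
#' @param rows Named character vector of equal-length gapped sequences
#'   (gap character `-`).
#' @param anchors Character vector, one label per column, drawn from the
#'   anchor vocabulary (loopA..loopG, strand5/5p/7/8p/9, helix1, preM1,
#'   M1..M4, MX, MA, none).  Each label must occupy a contiguous block.
#' @return A `plgic_alignment`.
#' @export
master_alignment <- function(rows, anchors) {
  rows <- vapply(rows, toupper, "")
  L <- unique(nchar(rows))
  if (length(L) != 1L) stop("alignment rows differ in length")
  if (length(anchors) != L) stop("anchor track length does not match rows")
  bad <- setdiff(unique(anchors), ANCHOR_LABELS)
  if (length(bad)) stop("unknown anchor label(s): ", paste(bad, collapse = ", "))
  r <- rle(anchors)
  dup <- r$values[r$values != "none"]
  if (anyDuplicated(dup)) {
    stop("anchor label(s) occupy non-contiguous blocks: ",
         paste(unique(dup[duplicated(dup)]), collapse = ", "))
  }
  structure(list(rows = rows, anchors = anchors), class = "plgic_alignment")
}

#' @export
print.plgic_alignment <- function(x, ...) {
  cat(sprintf("<master alignment: %d rows x %d columns, %d anchor blocks>\n",
              length(x$rows), nchar(x$rows[1]),
              sum(rle(x$anchors)$values != "none")))
  invisible(x)
}

#' Anchor blocks of an alignment
#'
#' @param aln A `plgic_alignment`.
#' @return Data frame with `label`, `start`, `end` (column indices).
#' @export
anchor_blocks <- function(aln) {
  r <- rle(aln$anchors)
  end <- cumsum(r$lengths)
  out <- data.frame(label = r$values, start = end - r$lengths + 1L, end = end,
                    stringsAsFactors = FALSE)
  out[out$label != "none", , drop = FALSE]
}

#' Read a master alignment from aligned FASTA plus an anchor sidecar
#'
#' The sidecar is tab-separated with columns `label`, `start`, `end`
#' (1-based alignment columns).
#'
#' @param fasta Path to an aligned FASTA file.
#' @param sidecar Path to the anchor annotation file.
#' @return A `plgic_alignment`.
#' @export
read_alignment <- function(fasta, sidecar) {
  ali <- bio3d::read.fasta(fasta)$ali
  rows <- apply(ali, 1L, paste, collapse = "")
  ann <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  anchors <- rep("none", nchar(rows[1]))
  for (i in seq_len(nrow(ann))) {
    anchors[ann$start[i]:ann$end[i]] <- ann$label[i]
  }
  master_alignment(rows, anchors)
}

#' Write a master alignment as aligned FASTA plus an anchor sidecar
#'
#' @param aln A `plgic_alignment`.
#' @param fasta,sidecar Output paths.
#' @export
write_alignment <- function(aln, fasta, sidecar) {
  con <- file(fasta, "w"); on.exit(close(con), add = TRUE)
  for (id in names(aln$rows)) {
    writeLines(c(paste0(">", id), aln$rows[[id]]), con)
  }
  utils::write.table(anchor_blocks(aln), sidecar, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fasta)
}

## Map alignment columns of one row to ungapped sequence positions
## (NA at gaps).
column_positions <- function(aln, row) {
  chars <- strsplit(aln$rows[[row]], "")[[1]]
  pos <- cumsum(chars != "-")
  pos[chars == "-"] <- NA_integer_
  pos
}

## Residue table of a chain in alignment-row coordinates, with the
## sequence agreement check (engineered constructs may mismatch in a few
## positions; those pairs are kept but flagged).  Tolerance: 2%.
row_residue_map <- function(aln, row, s, chain, tol = 0.02) {
  if (!row %in% names(aln$rows)) {
    stop("alignment has no row '", row, "'")
  }
  res <- chain_residues(s, chain)
  rowseq <- gsub("-", "", aln$rows[[row]], fixed = TRUE)
  n <- min(nchar(rowseq), nrow(res))
  if (nchar(rowseq) != nrow(res)) {
    ## length mismatch counts toward the mismatch budget
    extra <- abs(nchar(rowseq) - nrow(res))
  } else {
    extra <- 0L
  }
  chainseq <- aa321(res$resid)
  rowchars <- strsplit(rowseq, "")[[1]]
  mismatch <- which(rowchars[seq_len(n)] != chainseq[seq_len(n)])
  frac <- (length(mismatch) + extra) / max(nchar(rowseq), nrow(res))
  if (frac > tol) {
    stop(sprintf(
      "row '%s' does not match chain %s of '%s' (%.1f%% mismatch; positions %s)",
      row, chain, s$label, 100 * frac,
      paste(utils::head(mismatch, 10), collapse = ",")
    ))
  }
  res$pos <- seq_len(nrow(res))
  res$flagged <- res$pos %in% mismatch
  res
}

new_correspondence <- function(source, target, pairs, mode) {
  if (anyDuplicated(pairs$source_key) || anyDuplicated(pairs$target_key)) {
    stop("correspondence is not one-to-one")
  }
  structure(
    list(source = source, target = target, pairs = pairs, mode = mode),
    class = "plgic_correspondence"
  )
}

#' @export
print.plgic_correspondence <- function(x, ...) {
  cat(sprintf("<correspondence [%s] %s/%s -> %s/%s: %d pairs>\n",
              x$mode, x$source[1], x$source[2], x$target[1], x$target[2],
              nrow(x$pairs)))
  invisible(x)
}

#' Correspondence from the master alignment
#'
#' Residues of the two chains that share an alignment column are paired;
#' gap columns produce no pair.  Both chains' sequences must agree with
#' their alignment rows (at most 2% mismatched positions, which are
#' paired but flagged).
#'
#' @param aln A `plgic_alignment`.
#' @param row_a,row_b Row identifiers.
#' @param a,b `plgic_structure`s.
#' @param chain_a,chain_b Chain ids within `a` and `b`.
#' @return A `plgic_correspondence` with `mode = "alignment"`.
#' @export
alignment_correspondence <- function(aln, row_a, row_b, a, chain_a, b, chain_b) {
  pos_a <- column_positions(aln, row_a)
  pos_b <- column_positions(aln, row_b)
  map_a <- row_residue_map(aln, row_a, a, chain_a)
  map_b <- row_residue_map(aln, row_b, b, chain_b)
  shared <- which(!is.na(pos_a) & !is.na(pos_b) &
                    pos_a <= nrow(map_a) & pos_b <= nrow(map_b))
  ia <- pos_a[shared]; ib <- pos_b[shared]
  ok <- !is.na(map_a$x[ia]) & !is.na(map_b$x[ib])  # paired residues need a CA
  pairs <- data.frame(
    source_key = map_a$key[ia[ok]],
    target_key = map_b$key[ib[ok]],
    flagged = map_a$flagged[ia[ok]] | map_b$flagged[ib[ok]],
    stringsAsFactors = FALSE
  )
  new_correspondence(c(a$label, chain_a), c(b$label, chain_b), pairs,
                     mode = "alignment")
}

#' Residue keys aligned to a set of anchors
#'
#' @param aln A `plgic_alignment`.
#' @param row Alignment row for the chain.
#' @param s A `plgic_structure`.
#' @param chain Chain id.
#' @param anchors Character vector of anchor labels.
#' @return Character vector of residue keys.
#' @export
anchor_keys <- function(aln, row, s, chain, anchors) {
  pos <- column_positions(aln, row)
  map <- row_residue_map(aln, row, s, chain)
  cols <- which(aln$anchors %in% anchors & !is.na(pos) & pos <= nrow(map))
  map$key[pos[cols]]
}

#' Anchor label of each residue of a chain
#'
#' @inheritParams anchor_keys
#' @return Named character vector (names = residue keys, values = anchor
#'   labels, `"none"` outside anchor blocks).
#' @export
residue_anchors <- function(aln, row, s, chain) {
  pos <- column_positions(aln, row)
  map <- row_residue_map(aln, row, s, chain)
  out <- setNames(rep("none", nrow(map)), map$key)
  cols <- which(!is.na(pos) & pos <= nrow(map))
  out[map$key[pos[cols]]] <- aln$anchors[cols]
  out
}

## ---- Calpha-only secondary structure assignment -------------------------

#' Assign secondary structure from alpha-carbon geometry
#'
#' A distance-mask assignment in the spirit of P-SEA: a residue is a
#' helix candidate when d(i,i+3) is in [4.4, 6.4] A and d(i,i+4) in
#' [5.7, 7.7] A; a strand candidate when d(i,i+2) is in [6.0, 7.4] A and
#' the Ca(i), Ca(i+1), Ca(i+2) angle exceeds 115 degrees.  Candidate
#' segments shorter than 5 (helix) or 3 (strand) residues are relabelled
#' coil.  Residues with missing alpha carbons are labelled coil.
#'
#' @param s A `plgic_structure`.
#' @param chain Chain id.
#' @return Character vector of labels in `{H, E, C}`, named by residue
#'   key, one per protein residue of the chain.
#' @export
assign_sse <- function(s, chain) {
  res <- chain_residues(s, chain)
  n <- nrow(res)
  if (sum(!is.na(res$x)) < 5L) stop("chain has fewer than 5 alpha carbons")
  xyz <- as.matrix(res[, c("x", "y", "z")])
  d <- function(i, j) sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  lab <- rep("C", n)

  helix_hit <- rep(FALSE, n)
  if (n >= 5L) {
    i <- seq_len(n - 4L)
    d3 <- d(i, i + 3L); d4 <- d(i, i + 4L)
    helix_hit[i] <- !is.na(d3) & !is.na(d4) &
      d3 >= 4.4 & d3 <= 6.4 & d4 >= 5.7 & d4 <= 7.7
  }
  helix_cand <- rep(FALSE, n)
  for (i in which(helix_hit)) helix_cand[i:(i + 4L)] <- TRUE

  strand_hit <- rep(FALSE, n)
  if (n >= 3L) {
    i <- seq_len(n - 2L)
    d2 <- d(i, i + 2L)
    v1 <- xyz[i, , drop = FALSE] - xyz[i + 1L, , drop = FALSE]
    v2 <- xyz[i + 2L, , drop = FALSE] - xyz[i + 1L, , drop = FALSE]
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    strand_hit[i] <- !is.na(d2) & d2 >= 6.0 & d2 <= 7.4 & !is.na(ang) & ang > 115
  }
  strand_cand <- rep(FALSE, n)
  for (i in which(strand_hit)) strand_cand[i:(i + 2L)] <- TRUE

  ## helix takes precedence where the masks overlap
  keep_runs <- function(cand, minlen) {
    r <- rle(cand)
    r$values[r$values & r$lengths < minlen] <- FALSE
    inverse.rle(r)
  }
  h <- keep_runs(helix_cand, 5L)
  e <- keep_runs(strand_cand & !h, 3L)
  lab[h] <- "H"; lab[e] <- "E"
  lab[is.na(res$x)] <- "C"
  setNames(lab, res$key)
}

## Contiguous H/E segments of an SSE string.
sse_segments <- function(labels) {
  r <- rle(unname(labels))
  end <- cumsum(r$lengths)
  df <- data.frame(type = r$values, start = end - r$lengths + 1L, end = end,
                   len = r$lengths, stringsAsFactors = FALSE)
  df[df$type %in% c("H", "E"), , drop = FALSE]
}

## Monotone segment pairing by dynamic programming; segments match when
## of equal type with length ratio >= 0.5, scored by that ratio.
match_segments <- function(sa, sb) {
  na <- nrow(sa); nb <- nrow(sb)
  if (!na || !nb) return(NULL)
  score <- matrix(0, na + 1L, nb + 1L)
  from <- matrix(0L, na + 1L, nb + 1L)  # 1 = diag, 2 = up, 3 = left
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      m <- if (sa$type[i] == sb$type[j]) {
        r <- min(sa$len[i], sb$len[j]) / max(sa$len[i], sb$len[j])
        if (r >= 0.5) r else -Inf
      } else -Inf
      cand <- c(score[i, j] + m, score[i, j + 1L], score[i + 1L, j])
      k <- which.max(cand)
      score[i + 1L, j + 1L] <- cand[k]
      from[i + 1L, j + 1L] <- k
    }
  }
  pairs <- NULL
  i <- na + 1L; j <- nb + 1L
  while (i > 1L && j > 1L) {
    k <- from[i, j]
    if (k == 1L) { pairs <- rbind(c(i - 1L, j - 1L), pairs); i <- i - 1L; j <- j - 1L }
    else if (k == 2L) i <- i - 1L
    else j <- j - 1L
  }
  pairs
}

## Longest monotone subset: indices kept so that b-order is strictly
## increasing (a-order already is).  O(n^2) DP, ties resolved toward the
## earliest (lowest residue number) pairing.
longest_monotone <- function(border) {
  n <- length(border)
  if (n <= 1L) return(seq_len(n))
  best <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (border[j] < border[i] && best[j] + 1L > best[i]) {
        best[i] <- best[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  out <- integer(0)
  while (i > 0L) { out <- c(i, out); i <- prev[i] }
  out
}

#' Sequence-independent structural correspondence between two chains
#'
#' Matches secondary-structure segments by type and length
#' compatibility, seeds a Kabsch fit from the matched segment cores, and
#' refines by iterative nearest-neighbour pairing of alpha carbons
#' within a cutoff, enforcing a one-to-one monotone pairing at each
#' step.  Iteration stops when the pair set is stable or after
#' `max_iter` rounds.
#'
#' @param a,b `plgic_structure`s.
#' @param chain_a,chain_b Chain ids.
#' @param cutoff Pairing cutoff in Angstrom (default 3.5).
#' @param max_iter Iteration cap (default 50).
#' @return A `plgic_correspondence` with `mode = "structural"` and
#'   attributes `rmsd` (final post-fit RMSD) and `iterations`.
#' @export
structural_correspondence <- function(a, chain_a, b, chain_b,
                                      cutoff = 3.5, max_iter = 50L) {
  ra <- chain_residues(a, chain_a); rb <- chain_residues(b, chain_b)
  ka <- which(!is.na(ra$x)); kb <- which(!is.na(rb$x))
  xa <- as.matrix(ra[ka, c("x", "y", "z")])
  xb <- as.matrix(rb[kb, c("x", "y", "z")])

  la <- assign_sse(a, chain_a)[ka]
  lb <- assign_sse(b, chain_b)[kb]
  sa <- sse_segments(la); sb <- sse_segments(lb)
  seg <- match_segments(sa, sb)
  seeds_a <- integer(0); seeds_b <- integer(0)
  if (!is.null(seg)) {
    for (r in seq_len(nrow(seg))) {
      i <- seg[r, 1L]; j <- seg[r, 2L]
      m <- min(sa$len[i], sb$len[j])
      ca <- sa$start[i] + (sa$len[i] - m) %/% 2L
      cb <- sb$start[j] + (sb$len[j] - m) %/% 2L
      seeds_a <- c(seeds_a, ca:(ca + m - 1L))
      seeds_b <- c(seeds_b, cb:(cb + m - 1L))
    }
  }
  if (length(seeds_a) < 3L) {
    stop(sprintf(
      "structural matching failed for %s/%s vs %s/%s: only %d seed pairs from %d/%d segments",
      a$label, chain_a, b$label, chain_b, length(seeds_a), nrow(sa), nrow(sb)
    ))
  }

  fit <- kabsch_fit(xa[seeds_a, , drop = FALSE], xb[seeds_b, , drop = FALSE])
  pa <- seeds_a; pb <- seeds_b
  iter <- 0L
  repeat {
    iter <- iter + 1L
    xa_t <- apply_transform(xa, rigid_transform(fit$rotation, fit$translation))
    ## nearest target within cutoff for every source residue
    d2 <- outer(rowSums(xa_t^2), rowSums(xb^2), `+`) - 2 * xa_t %*% t(xb)
    d2[d2 < 0] <- 0
    nn <- max.col(-d2, ties.method = "first")
    nd <- sqrt(d2[cbind(seq_along(nn), nn)])
    cand <- which(nd <= cutoff)
    ## greedy one-to-one by increasing distance, then lower residue number
    ord <- cand[order(nd[cand], cand)]
    used_b <- logical(nrow(xb))
    na_idx <- integer(0); nb_idx <- integer(0)
    for (i in ord) {
      j <- nn[i]
      if (!used_b[j]) {
        used_b[j] <- TRUE
        na_idx <- c(na_idx, i); nb_idx <- c(nb_idx, j)
      }
    }
    o <- order(na_idx)
    na_idx <- na_idx[o]; nb_idx <- nb_idx[o]
    keep <- longest_monotone(nb_idx)
    na_idx <- na_idx[keep]; nb_idx <- nb_idx[keep]
    if (length(na_idx) < 3L) {
      stop("structural matching collapsed below 3 pairs during refinement")
    }
    stable <- identical(na_idx, pa) && identical(nb_idx, pb)
    pa <- na_idx; pb <- nb_idx
    fit <- kabsch_fit(xa[pa, , drop = FALSE], xb[pb, , drop = FALSE])
    if (stable || iter >= max_iter) break
  }

  pairs <- data.frame(
    source_key = ra$key[ka[pa]],
    target_key = rb$key[kb[pb]],
    flagged = FALSE,
    stringsAsFactors = FALSE
  )
  corr <- new_correspondence(c(a$label, chain_a), c(b$label, chain_b), pairs,
                             mode = "structural")
  attr(corr, "rmsd") <- fit$rmsd
  attr(corr, "iterations") <- iter
  corr
}

#' Export correspondences as TSV
#'
#' @param corr A `plgic_correspondence` or list of them.
#' @param file Output path.
#' @export
write_correspondence_tsv <- function(corr, file) {
  if (inherits(corr, "plgic_correspondence")) corr <- list(corr)
  df <- do.call(rbind, lapply(corr, function(cc) {
    cbind(
      data.frame(source = paste(cc$source, collapse = "/"),
                 target = paste(cc$target, collapse = "/"),
                 mode = cc$mode, stringsAsFactors = FALSE),
      cc$pairs
    )
  }))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

## ---- strand 8' motif ----------------------------------------------------

#' Validate the strand-8' packing motif across alignment rows
#'
#' The three columns anchored as strand 8' must follow the pattern
#' hydrophobic / any / hydrophobic-or-small (e.g. VTG in the
#' GABA-A beta3 subunit).  Hydrophobic = {A,V,L,I,M,F,W,C}; small =
#' {G,A,S}.  Gapped window positions are not checked.
#'
#' @param aln A `plgic_alignment` with a width-3 `strand8p` block.
#' @return A `plgic_motif_report`: list with `windows` (per-row 3-mers),
#'   `pass` (per-row logical) and `violations` (data frame with `row`,
#'   `position`, `aa`).
#' @export
validate_strand8 <- function(aln) {
  blocks <- anchor_blocks(aln)
  b <- blocks[blocks$label == "strand8p", , drop = FALSE]
  if (!nrow(b)) stop("alignment has no strand8p anchor block")
  if (b$end - b$start + 1L != 3L) {
    stop("strand8p anchor block must span exactly 3 columns")
  }
  cols <- b$start:b$end
  windows <- vapply(aln$rows, function(r) {
    paste(strsplit(r, "")[[1]][cols], collapse = "")
  }, "")
  viol <- NULL
  for (id in names(windows)) {
    w <- strsplit(windows[[id]], "")[[1]]
    if (w[1] != "-" && !(w[1] %in% HYDROPHOBIC_AA)) {
      viol <- rbind(viol, data.frame(row = id, position = 1L, aa = w[1],
                                     stringsAsFactors = FALSE))
    }
    if (w[3] != "-" && !(w[3] %in% c(HYDROPHOBIC_AA, SMALL_AA))) {
      viol <- rbind(viol, data.frame(row = id, position = 3L, aa = w[3],
                                     stringsAsFactors = FALSE))
    }
  }
  viol <- viol %||% data.frame(row = character(), position = integer(),
                               aa = character(), stringsAsFactors = FALSE)
  structure(
    list(windows = windows,
         pass = setNames(!(names(windows) %in% viol$row), names(windows)),
         violations = viol),
    class = "plgic_motif_report"
  )
}

#' @export
print.plgic_motif_report <- function(x, ...) {
  cat(sprintf("<strand-8' motif report: %d/%d rows pass>\n",
              sum(x$pass), length(x$pass)))
  if (nrow(x$violations)) print(x$violations)
  invisible(x)
}
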