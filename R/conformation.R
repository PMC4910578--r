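## Pocket-geometry tables and conformational grouping.
##
## Distances between alpha carbons of pocket-forming residues are
## internal to each structure, so no superposition is involved; they
## quantify how conformational states reshape each pocket.

#' Define a named inter-anchor alpha-carbon distance
#'
#' @param label Column label.
#' @param role_a,role_b Chain role of each endpoint: `"plus"`
#'   (principal), `"minus"` (complementary) or `"same"` (the plus
#'   chain).
#' @param anchor_a,anchor_b Anchor labels.
#' @param offset_a,offset_b 1-based position within the anchor's residue
#'   stretch; `NA` selects the middle residue (the "tip" for loop C).
#' @return A `plgic_distance_def`.
#' @export
distance_definition <- function(label, role_a, anchor_a, offset_a = NA,
                                role_b, anchor_b, offset_b = NA) {
  stopifnot(role_a %in% c("plus", "minus", "same"),
            role_b %in% c("plus", "minus", "same"))
  structure(
    list(label = label,
         a = list(role = role_a, anchor = anchor_a, offset = offset_a),
         b = list(role = role_b, anchor = anchor_b, offset = offset_b)),
    class = "plgic_distance_def"
  )
}

#' The default ECD-interface distance set
#'
#' Ten distances between the plus and minus subunits probing the two
#' interface subsites: loop B to loop E (2), loop C tip to loop D (2),
#' loop C tip to loop E (1), loop A to loop G (2), loop A to loop F (1),
#' strand 7 to loop F (1) and loop C to loop F (1).  Endpoints sit at
#' block midpoints or the first/last residue of the stretch.
#'
#' @return List of `plgic_distance_def`s.
#' @export
default_distance_set <- function() {
  dd <- distance_definition
  list(
    dd("loopB1_loopE1", "plus", "loopB", 1, "minus", "loopE", 1),
    dd("loopB2_loopE2", "plus", "loopB", NA, "minus", "loopE", NA),
    dd("loopCtip_loopD1", "plus", "loopC", NA, "minus", "loopD", 1),
    dd("loopCtip_loopD2", "plus", "loopC", NA, "minus", "loopD", NA),
    dd("loopCtip_loopE", "plus", "loopC", NA, "minus", "loopE", NA),
    dd("loopA1_loopG1", "plus", "loopA", 1, "minus", "loopG", 1),
    dd("loopA2_loopG2", "plus", "loopA", NA, "minus", "loopG", NA),
    dd("loopA_loopF", "plus", "loopA", NA, "minus", "loopF", NA),
    dd("strand7_loopF", "plus", "strand7", NA, "minus", "loopF", NA),
    dd("loopC_loopF", "plus", "loopC", 1, "minus", "loopF", NA)
  )
}

resolve_endpoint <- function(ep, s, aln, plus_chain, minus_chain, row_for) {
  chain <- if (ep$role == "minus") minus_chain else plus_chain
  keys <- tryCatch(anchor_keys(aln, row_for(chain), s, chain, ep$anchor),
                   error = function(e) character())
  if (!length(keys)) return(NULL)
  off <- ep$offset
  if (is.na(off)) off <- ceiling(length(keys) / 2)
  if (off < 1L || off > length(keys)) return(NULL)
  ca <- select_calpha(s)
  row <- ca[ca$key == keys[off], , drop = FALSE]
  if (!nrow(row)) return(NULL)
  as.numeric(row[1, c("x", "y", "z")])
}

#' Pocket-geometry distance table across conformational states
#'
#' One internal alpha-carbon distance per (state, definition), measured
#' in each state's own frame.
#'
#' @param states Named list of `plgic_structure`s.
#' @param defs List of `plgic_distance_def`s.
#' @param aln Master alignment.
#' @param interface Chain roles: either `c(plus = , minus = )` applied to
#'   every state, or a named list per state label.
#' @param row_for `function(chain) row id` (default identity).
#' @return A `plgic_geometry_table`: matrix (states x definitions) with
#'   `NA` in flagged cells (listed in attribute `missing`).
#' @export
distance_table <- function(states, defs, aln,
                           interface = c(plus = "A", minus = "B"),
                           row_for = function(chain) chain) {
  labels <- names(states)
  m <- matrix(NA_real_, length(states), length(defs),
              dimnames = list(labels, vapply(defs, `[[`, "", "label")))
  missing <- list()
  for (lab in labels) {
    s <- states[[lab]]
    ifc <- if (is.list(interface)) interface[[lab]] else interface
    for (j in seq_along(defs)) {
      d <- defs[[j]]
      pa <- resolve_endpoint(d$a, s, aln, ifc[["plus"]], ifc[["minus"]], row_for)
      pb <- resolve_endpoint(d$b, s, aln, ifc[["plus"]], ifc[["minus"]], row_for)
      if (is.null(pa) || is.null(pb)) {
        missing[[length(missing) + 1L]] <- c(lab, d$label)
      } else {
        m[lab, j] <- sqrt(sum((pa - pb)^2))
      }
    }
  }
  structure(m, class = c("plgic_geometry_table", class(m)),
            missing = missing)
}

#' Per-pocket variability across states
#'
#' For each named pocket (a group of distance definitions), the maximum
#' absolute pairwise difference over its columns and all state pairs.
#'
#' @param table A `plgic_geometry_table` with at least two states.
#' @param pockets Named list mapping pocket names to definition labels.
#' @return Named numeric vector of maximal distance changes, Angstrom.
#' @export
pocket_variability <- function(table, pockets) {
  if (nrow(table) < 2L) {
    stop("pocket variability needs at least two states")
  }
  vapply(pockets, function(cols) {
    sub <- table[, intersect(cols, colnames(table)), drop = FALSE]
    if (!ncol(sub)) return(NA_real_)
    rng <- apply(sub, 2L, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2L) return(NA_real_)
      max(x) - min(x)
    })
    max(rng, na.rm = TRUE)
  }, 0)
}

#' Group structures by conformational similarity
#'
#' Single-linkage agglomeration of a pairwise RMSD matrix, cut at a
#' distance threshold.  Groups are reported in a deterministic order
#' (by the label order of their first member).
#'
#' @param m A `plgic_rmsd_matrix` or plain symmetric matrix.
#' @param threshold Linkage cut height, Angstrom (default 2.5, between
#'   the within-group and between-group separations typical of the
#'   pentamer ensemble).
#' @return A `plgic_grouping`: list with `partition` (list of label
#'   vectors), `threshold`, `method`.
#' @export
group_conformations <- function(m, threshold = 2.5) {
  mat <- if (inherits(m, "plgic_rmsd_matrix")) m$matrix else as.matrix(m)
  if (nrow(mat) == 1L) {
    return(structure(list(partition = list(rownames(mat) %||% "1"),
                          threshold = threshold, method = "single"),
                     class = "plgic_grouping"))
  }
  off <- mat[upper.tri(mat)]
  if (any(is.na(off))) {
    idx <- which(is.na(mat) & upper.tri(mat), arr.ind = TRUE)
    stop("RMSD matrix has missing entries: ",
         paste(apply(idx, 1L, function(i)
           paste(rownames(mat)[i[1]], colnames(mat)[i[2]], sep = "-")),
           collapse = ", "))
  }
  hc <- stats::hclust(stats::as.dist(mat), method = "single")
  h <- if (is.finite(threshold)) threshold else max(hc$height) + 1
  members <- stats::cutree(hc, h = h)
  labs <- names(members)
  groups <- split(labs, members)
  ord <- order(vapply(groups, function(g) min(match(g, labs)), 0L))
  structure(
    list(partition = unname(groups[ord]), threshold = threshold,
         method = "single"),
    class = "plgic_grouping"
  )
}

#' @export
print.plgic_grouping <- function(x, ...) {
  cat(sprintf("<conformational grouping: %d group(s) at %.2f A (%s linkage)>\n",
              length(x$partition), x$threshold, x$method))
  for (i in seq_along(x$partition)) {
    cat(sprintf("  group %d: %s\n", i, paste(x$partition[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Export a geometry table as TSV
#'
#' @param table A `plgic_geometry_table`.
#' @param file Output path.  Missing cells are written as `.`.
#' @export
write_geometry_tsv <- function(table, file) {
  df <- as.data.frame(unclass(table))
  df <- cbind(state = rownames(df), df)
  df[is.na(df)] <- "."
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
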