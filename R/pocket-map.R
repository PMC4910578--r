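## Ligand-contact detection, ten-class binding-site classification,
## cross-structure site transfer and steric-occlusion scoring.
##
## The site taxonomy: ECD-interface subsites 1 and 2, the interface
## cation site 3, the ECD vestibule site 4, the ECD packing-core site 5,
## the helix-1 site 6, the TMD-interface site 7, the TMD intra-subunit
## site 8, the M1/M4 groove site 9 and the M3/M4 near-ICD site 10.
## Channel blockers in the ion pore are detected only to be excluded.

SUBSITE1_ANCHORS <- c("loopB", "loopC", "loopD", "loopE")
SUBSITE2_ANCHORS <- c("loopG", "loopF", "strand7")
INNER_SHEET_ANCHORS <- c("strand5", "strand5p", "strand7")
OUTER_SHEET_ANCHORS <- c("strand8p", "strand9")
CATION_ELEMENTS <- c("ZN", "BA", "CA", "MG", "SR", "CD", "NA", "K", "CS")

new_contact_set <- function(ligand_key, het_name, contacts, cutoff) {
  contacts <- contacts[vapply(contacts, length, 0L) > 0L]
  structure(
    list(ligand_key = ligand_key, het_name = het_name,
         contacts = contacts, cutoff = cutoff),
    class = "plgic_contact_set"
  )
}

#' @export
print.plgic_contact_set <- function(x, ...) {
  cat(sprintf("<contact set: %s (%s), cutoff %.1f A, %d residues on %d chain(s)>\n",
              x$ligand_key, x$het_name, x$cutoff,
              sum(vapply(x$contacts, length, 0L)), length(x$contacts)))
  invisible(x)
}

## Heavy atoms of a structure's protein chains (bio3d convention,
## hydrogens/deuteriums dropped).
protein_heavy <- function(s) {
  at <- s$atoms
  at[!at$het & !(at$elesy %in% c("H", "D")), , drop = FALSE]
}

find_ligand <- function(s, lig) {
  if (is.character(lig)) {
    hit <- Filter(function(l) l$key == lig, s$ligands)
    if (!length(hit)) stop("structure '", s$label, "' has no ligand '", lig, "'")
    lig <- hit[[1]]
  }
  lig
}

#' Contact residues of a bound ligand
#'
#' Exhaustive heavy-atom distance scan: a residue is a contact when any
#' of its heavy atoms lies within `cutoff` of any ligand heavy atom.
#' Contacts are reported per chain, in residue order.
#'
#' @param s A `plgic_structure`.
#' @param lig A ligand instance (from [extract_ligands()]) or its key.
#' @param cutoff Heavy-atom distance cutoff, Angstrom.  Default 4.0 (the
#'   ligand-interaction-diagram convention); synthetic Ca-only fixtures
#'   use 6.5.
#' @return A `plgic_contact_set`.
#' @export
ligand_contacts <- function(s, lig, cutoff = 4.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  lig <- find_ligand(s, lig)
  lx <- as.matrix(lig$atoms[, c("x", "y", "z")])
  if (!nrow(lx)) stop("ligand ", lig$key, " has no heavy atoms")
  prot <- protein_heavy(s)
  px <- as.matrix(prot[, c("x", "y", "z")])
  d2 <- outer(rowSums(px^2), rowSums(lx^2), `+`) - 2 * px %*% t(lx)
  near <- rowSums(d2 <= cutoff^2 + 1e-9) > 0L
  keys <- res_key(prot$chain, prot$resno, prot$ins)
  hit_keys <- unique(keys[near])
  chain_order <- unique(prot$chain)
  contacts <- list()
  for (ch in chain_order) {
    k <- hit_keys[split_key(hit_keys)$chain == ch]
    if (length(k)) {
      ord <- order(split_key(k)$resno, split_key(k)$ins)
      contacts[[ch]] <- k[ord]
    }
  }
  new_contact_set(lig$key, lig$het_name, contacts, cutoff)
}

## Perpendicular distance of points from the axis line and their height
## along it.
axis_coords <- function(xyz, axis) {
  rel <- sweep(matrix(xyz, ncol = 3L), 2L, axis$center)
  h <- as.numeric(rel %*% axis$axis)
  perp <- rel - outer(h, axis$axis)
  list(radius = sqrt(rowSums(perp^2)), height = h)
}

ligand_centroid <- function(s, ligand_key) {
  lig <- find_ligand(s, ligand_key)
  colMeans(as.matrix(lig$atoms[, c("x", "y", "z")]))
}

#' Classify a bound ligand into the ten-site taxonomy
#'
#' Decision cascade: (1) the domain is taken from the anchor membership
#' of the contact majority; (2) ligands in the transmembrane pore region
#' are flagged pore-facing and left unclassified; (3) interface sites
#' (two chains with at least two contact residues each) split into ECD
#' subsites 1/2, the cation site 3, and the TMD interface site 7;
#' (4) ECD intra-subunit ligands become the vestibule site 4 (centroid
#' inside the pore-axis cylinder), the packing-core site 5 (contacts
#' split between inner and outer sheet anchors) or the helix-1 site 6;
#' (5) TMD intra-subunit ligands become site 8 (M1/M2/M3), site 9
#' (M1/M4 groove) or site 10 (M3/M4, lower third of the TMD).
#'
#' @param cs A `plgic_contact_set`.
#' @param s The structure the ligand belongs to.
#' @param aln Master alignment resolving anchors.
#' @param row_for `function(chain) row id` mapping chains to alignment
#'   rows (default: identity).
#' @param vestibule_radius Radius of the pore-axis cylinder separating
#'   vestibule from packing-core ligands, Angstrom.
#' @param axis Optional pre-computed pore axis ([pore_axis()]).
#' @return A `plgic_site_class`: list with `site_class` (integer or
#'   `NA` for unclassified), `domain`, `interface`, `principal_chain`,
#'   `complementary_chain`, `anchor_overlap` (named fractions),
#'   `pore_facing` and `diagnostic`.
#' @export
classify_site <- function(cs, s, aln, row_for = function(chain) chain,
                          vestibule_radius = 8, axis = NULL) {
  result <- function(site_class, domain, interface = FALSE, principal = "",
                     complementary = "", overlap = numeric(), pore = FALSE,
                     diagnostic = "") {
    structure(list(site_class = site_class, domain = domain,
                   interface = interface, principal_chain = principal,
                   complementary_chain = complementary,
                   anchor_overlap = overlap, pore_facing = pore,
                   diagnostic = diagnostic),
              class = "plgic_site_class")
  }
  if (!length(cs$contacts)) {
    return(result(NA_integer_, "unresolved", diagnostic = "empty contact set"))
  }

  anchors <- character(); anchor_chain <- character()
  for (ch in names(cs$contacts)) {
    res_anch <- tryCatch(residue_anchors(aln, row_for(ch), s, ch),
                         error = function(e) NULL)
    if (is.null(res_anch)) {
      return(result(NA_integer_, "unresolved",
                    diagnostic = paste0("anchors unresolvable for chain ", ch)))
    }
    a <- res_anch[cs$contacts[[ch]]]
    a[is.na(a)] <- "none"
    anchors <- c(anchors, unname(a))
    anchor_chain <- c(anchor_chain, rep(ch, length(a)))
  }
  n_total <- length(anchors)
  overlap <- table(anchors[anchors != "none"]) / n_total
  overlap <- setNames(as.numeric(overlap), names(overlap))

  frac_in <- function(set, chains = NULL) {
    sel <- anchors %in% set
    if (!is.null(chains)) sel <- sel & anchor_chain %in% chains
    sum(sel) / n_total
  }
  dom_counts <- c(
    ECD = sum(anchors %in% ECD_ANCHORS),
    TMD = sum(anchors %in% TMD_ANCHORS),
    ICD = sum(anchors %in% ICD_ANCHORS),
    junction = sum(anchors == "preM1")
  )
  if (all(dom_counts == 0L)) {
    return(result(NA_integer_, "unresolved", overlap = overlap,
                  diagnostic = "no contact lies in an anchored region"))
  }
  domain <- names(dom_counts)[which.max(dom_counts)]
  eff_domain <- if (domain == "junction") "TMD" else domain

  if (is.null(axis)) {
    m2 <- unlist(lapply(names(cs$contacts), function(ch) {
      tryCatch(anchor_keys(aln, row_for(ch), s, ch, "M2"),
               error = function(e) character())
    }))
    all_m2 <- tryCatch(unlist(lapply(protein_chains(s), function(ch) {
      anchor_keys(aln, row_for(ch), s, ch, "M2")
    })), error = function(e) character())
    ecd_keys_all <- tryCatch(unlist(lapply(protein_chains(s), function(ch) {
      anchor_keys(aln, row_for(ch), s, ch, ECD_ANCHORS)
    })), error = function(e) character())
    ecd_ctr <- if (length(ecd_keys_all)) mean_ca(s, ecd_keys_all) else NULL
    axis <- if (length(all_m2) >= 3L) {
      pore_axis(s, all_m2, positive_toward = ecd_ctr)
    } else {
      pore_axis(s, positive_toward = ecd_ctr)
    }
  }
  ctr <- ligand_centroid(s, cs$ligand_key)
  ax <- axis_coords(ctr, axis)

  ## pore region of the TMD: channel blockers are out of scope
  if (eff_domain == "TMD" && ax$radius < vestibule_radius) {
    return(result(NA_integer_, domain, overlap = overlap, pore = TRUE,
                  diagnostic = "ligand lies in the ion pore"))
  }

  chain_counts <- vapply(cs$contacts, length, 0L)
  interface <- sum(chain_counts >= 2L) >= 2L
  ifc_chains <- names(chain_counts)[order(-chain_counts)][1:2]

  if (interface && eff_domain == "ECD") {
    lig <- find_ligand(s, cs$ligand_key)
    monatomic_cation <- nrow(lig$atoms) == 1L &&
      lig$atoms$elesy[1] %in% CATION_ELEMENTS
    ## principal (+) face carries loops A-C plus strands 7 and 9;
    ## the complementary (-) face carries loops D-G
    per_chain_plus <- vapply(ifc_chains, function(ch)
      frac_in(c("loopA", "loopB", "loopC", "strand7", "strand9"), ch) -
        frac_in(c("loopD", "loopE", "loopF", "loopG"), ch), 0)
    principal <- ifc_chains[which.max(per_chain_plus)]
    complementary <- setdiff(ifc_chains, principal)[1]
    if (monatomic_cation && frac_in(c("loopF", "strand7")) > 0) {
      return(result(3L, "ECD", TRUE, principal, complementary, overlap))
    }
    f1 <- frac_in(SUBSITE1_ANCHORS)
    f2 <- frac_in(SUBSITE2_ANCHORS)
    cls <- if (f1 >= f2) 1L else 2L
    return(result(cls, "ECD", TRUE, principal, complementary, overlap))
  }
  if (interface && eff_domain == "TMD") {
    per_chain_plus <- vapply(ifc_chains, function(ch)
      frac_in(c("M2", "M3"), ch), 0)
    principal <- ifc_chains[which.max(per_chain_plus)]
    complementary <- setdiff(ifc_chains, principal)[1]
    return(result(7L, domain, TRUE, principal, complementary, overlap))
  }

  if (eff_domain == "ECD") {
    if (ax$radius < vestibule_radius) {
      return(result(4L, "ECD", overlap = overlap))
    }
    n_inner <- sum(anchors %in% INNER_SHEET_ANCHORS)
    n_outer <- sum(anchors %in% OUTER_SHEET_ANCHORS)
    if (n_inner >= 1L && n_outer >= 1L &&
        (n_inner + n_outer) >= 0.5 * n_total) {
      return(result(5L, "ECD", overlap = overlap))
    }
    anch_tab <- table(anchors[anchors != "none"])
    if (length(anch_tab) && names(which.max(anch_tab)) == "helix1") {
      return(result(6L, "ECD", overlap = overlap))
    }
    return(result(NA_integer_, "ECD", overlap = overlap,
                  diagnostic = "ECD intra-subunit ligand without a site signature"))
  }
  if (eff_domain == "TMD") {
    cnt <- vapply(c("M1", "M2", "M3", "M4"), function(a) sum(anchors == a), 0L)
    s8 <- cnt[["M1"]] + cnt[["M2"]] + cnt[["M3"]]
    s9 <- cnt[["M1"]] + cnt[["M4"]]
    s10 <- cnt[["M3"]] + cnt[["M4"]]
    ## TMD extent along the axis, from the contact chains' helices
    tmd_keys <- unlist(lapply(names(cs$contacts), function(ch) {
      tryCatch(anchor_keys(aln, row_for(ch), s, ch, TMD_ANCHORS),
               error = function(e) character())
    }))
    ca <- select_calpha(s)
    tz <- axis_coords(as.matrix(ca[ca$key %in% tmd_keys, c("x", "y", "z")]),
                      axis)$height
    lower_third <- ax$height <= min(tz) + (max(tz) - min(tz)) / 3
    if (lower_third && s10 >= max(s8, s9)) {
      return(result(10L, domain, overlap = overlap))
    }
    if (s9 > s8) return(result(9L, domain, overlap = overlap))
    if (s8 > 0L) return(result(8L, domain, overlap = overlap))
    return(result(NA_integer_, domain, overlap = overlap,
                  diagnostic = "TMD ligand without a helix signature"))
  }
  result(NA_integer_, domain, overlap = overlap,
         diagnostic = "ICD ligands are outside the site taxonomy")
}

#' @export
print.plgic_site_class <- function(x, ...) {
  cls <- if (is.na(x$site_class)) "unclassified" else x$site_class
  cat(sprintf("<site classification: class %s, %s%s%s>\n", cls, x$domain,
              if (x$interface) sprintf(", interface %s+/%s-",
                                       x$principal_chain, x$complementary_chain)
              else "",
              if (x$pore_facing) ", pore-facing" else ""))
  invisible(x)
}

#' Steric-occlusion score of a placed ligand
#'
#' Fraction of ligand heavy atoms lying within the clash distance of any
#' target heavy atom outside the excluded (pocket) residues.  Solvent
#' molecules are ignored.
#'
#' @param ligand_xyz n x 3 matrix of placed ligand heavy atoms.
#' @param target A `plgic_structure` in whose frame the ligand sits.
#' @param exclude Residue keys to ignore (the mapped pocket).
#' @param clash Clash distance, Angstrom (default 2.8).
#' @return A fraction in `[0, 1]`.
#' @export
occlusion_score <- function(ligand_xyz, target, exclude = character(),
                            clash = 2.8) {
  ligand_xyz <- matrix(as.numeric(ligand_xyz), ncol = 3L)
  at <- target$atoms
  at <- at[!(at$elesy %in% c("H", "D")) &
             !(at$resid %in% SOLVENT_EXCLUDE), , drop = FALSE]
  keys <- res_key(at$chain, at$resno, at$ins)
  at <- at[!(keys %in% exclude), , drop = FALSE]
  if (!nrow(at)) return(0)
  tx <- as.matrix(at[, c("x", "y", "z")])
  d2 <- outer(rowSums(ligand_xyz^2), rowSums(tx^2), `+`) - 2 * ligand_xyz %*% t(tx)
  mean(apply(d2, 1L, min) <= clash^2 + 1e-9)
}

#' Transfer a binding site onto another structure
#'
#' Maps each contact residue through its chain's correspondence, places
#' the source ligand in the target frame by a pocket-local superposition
#' of the mapped residues, and scores steric occlusion of the placed
#' footprint.  Sites whose footprint is blocked beyond the rejection
#' threshold are given the verdict `"occluded"`.
#'
#' @param cs A `plgic_contact_set` on the source structure.
#' @param corrs List of correspondences (source chain -> target chain),
#'   one per contact chain.
#' @param source,target `plgic_structure`s.
#' @param clash Clash distance for the occlusion scan, Angstrom.
#' @param threshold Occlusion fraction above which the verdict is
#'   `"occluded"` (default 0.25).
#' @return A `plgic_transferred_site`: list with `mapped` (named list of
#'   target residue keys per target chain), `unmapped_count`,
#'   `occlusion`, `verdict` and `placed_ligand` (matrix).
#' @export
transfer_site <- function(cs, corrs, source, target, clash = 2.8,
                          threshold = 0.25) {
  if (inherits(corrs, "plgic_correspondence")) corrs <- list(corrs)
  by_chain <- list()
  for (corr in corrs) by_chain[[corr$source[2]]] <- corr
  mapped <- list(); unmapped <- 0L
  src_keys <- character(); tgt_keys <- character()
  for (ch in names(cs$contacts)) {
    corr <- by_chain[[ch]]
    if (is.null(corr)) {
      stop("no correspondence supplied for contact chain '", ch, "'")
    }
    idx <- match(cs$contacts[[ch]], corr$pairs$source_key)
    hit <- !is.na(idx)
    unmapped <- unmapped + sum(!hit)
    tk <- corr$pairs$target_key[idx[hit]]
    tch <- corr$target[2]
    mapped[[tch]] <- c(mapped[[tch]], tk)
    src_keys <- c(src_keys, cs$contacts[[ch]][hit])
    tgt_keys <- c(tgt_keys, tk)
  }
  if (length(src_keys) < 3L) {
    stop("fewer than 3 pocket residues are mappable; cannot place the ligand")
  }
  ca_s <- select_calpha(source); ca_t <- select_calpha(target)
  is_ <- match(src_keys, ca_s$key); it_ <- match(tgt_keys, ca_t$key)
  ok <- !is.na(is_) & !is.na(it_)
  if (sum(ok) < 3L) stop("fewer than 3 mapped pocket residues have alpha carbons")
  fit <- kabsch_fit(as.matrix(ca_s[is_[ok], c("x", "y", "z")]),
                    as.matrix(ca_t[it_[ok], c("x", "y", "z")]),
                    subset_label = "pocket")
  lig <- find_ligand(source, cs$ligand_key)
  placed <- apply_transform(as.matrix(lig$atoms[, c("x", "y", "z")]),
                            rigid_transform(fit$rotation, fit$translation))
  occ <- occlusion_score(placed, target, exclude = unlist(mapped), clash = clash)
  structure(
    list(source_site = cs, target_label = target$label, mapped = mapped,
         unmapped_count = unmapped, occlusion = occ,
         verdict = if (occ > threshold) "occluded" else "plausible",
         pocket_rmsd = fit$rmsd, placed_ligand = placed),
    class = "plgic_transferred_site"
  )
}

#' @export
print.plgic_transferred_site <- function(x, ...) {
  cat(sprintf("<transferred site -> %s: %d mapped, %d unmapped, occlusion %.2f (%s)>\n",
              x$target_label, length(unlist(x$mapped)), x$unmapped_count,
              x$occlusion, x$verdict))
  invisible(x)
}

#' Build a binding-site atlas over a curated structure set
#'
#' One row per (structure, ligand occurrence): contacts are detected,
#' classified, and multiple copies of a ligand sharing at least half of
#' their contact residues are merged into a single site occurrence.
#'
#' @param structures Named list of `plgic_structure`s.
#' @param aln Master alignment.
#' @param row_for `function(structure_label, chain) row id`; default uses
#'   the chain id.
#' @param cutoff Contact cutoff, Angstrom.
#' @param include Optional het-name filter passed to [extract_ligands()].
#' @param vestibule_radius Passed to [classify_site()].
#' @return A `plgic_site_atlas`: data frame with one row per site
#'   occurrence (`structure`, `ligand`, `ligand_key`, `site_class`,
#'   `domain`, `interface`, `principal_chain`, `complementary_chain`,
#'   `chains`, `n_contacts`, `residues`) plus attribute `n_classes`.
#' @export
build_site_atlas <- function(structures, aln,
                             row_for = function(label, chain) chain,
                             cutoff = 4.0, include = NULL,
                             vestibule_radius = 8) {
  rows <- list()
  for (lab in names(structures)) {
    s <- structures[[lab]]
    ligs <- extract_ligands(s, include = include)
    occ <- list()
    for (lig in ligs) {
      cs <- ligand_contacts(s, lig, cutoff = cutoff)
      if (!length(cs$contacts)) next
      cls <- classify_site(cs, s, aln,
                           row_for = function(ch) row_for(lab, ch),
                           vestibule_radius = vestibule_radius)
      res_all <- unlist(cs$contacts)
      merged <- FALSE
      for (i in seq_along(occ)) {
        prev <- occ[[i]]
        ov <- length(intersect(prev$residues, res_all)) /
          min(length(prev$residues), length(res_all))
        same <- identical(prev$site_class, cls$site_class)
        if (same && ov >= 0.5) {
          occ[[i]]$residues <- union(prev$residues, res_all)
          occ[[i]]$n_copies <- prev$n_copies + 1L
          merged <- TRUE
          break
        }
      }
      if (!merged) {
        occ[[length(occ) + 1L]] <- list(
          structure = lab, ligand = lig$het_name, ligand_key = lig$key,
          site_class = cls$site_class, domain = cls$domain,
          interface = cls$interface, principal_chain = cls$principal_chain,
          complementary_chain = cls$complementary_chain,
          chains = paste(names(cs$contacts), collapse = ","),
          residues = res_all, n_copies = 1L, pore_facing = cls$pore_facing
        )
      }
    }
    rows <- c(rows, occ)
  }
  df <- do.call(rbind, lapply(rows, function(r) data.frame(
    structure = r$structure, ligand = r$ligand, ligand_key = r$ligand_key,
    site_class = r$site_class, domain = r$domain, interface = r$interface,
    principal_chain = r$principal_chain,
    complementary_chain = r$complementary_chain,
    chains = r$chains, n_contacts = length(r$residues),
    n_copies = r$n_copies, pore_facing = r$pore_facing,
    residues = paste(r$residues, collapse = ";"),
    stringsAsFactors = FALSE
  )))
  df <- df %||% data.frame()
  attr(df, "n_classes") <- length(unique(stats::na.omit(df$site_class)))
  class(df) <- c("plgic_site_atlas", "data.frame")
  df
}

#' Export a site atlas as TSV and/or JSON
#'
#' @param atlas A `plgic_site_atlas`.
#' @param tsv,json Optional output paths.
#' @export
write_atlas <- function(atlas, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    out <- as.data.frame(atlas)
    out[is.na(out)] <- "."
    utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(as.data.frame(atlas), json, auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(atlas)
}
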