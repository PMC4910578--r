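## Coordinate containers and PDB/mmCIF input-output.
##
## A `plgic_structure` is a light S3 wrapper around an atom table in the
## bio3d column convention (chain, resno, insert, resid, elety, elesy,
## x, y, z, o, alt, het).  Author residue numbering with insertion codes
## is canonical throughout; residues are addressed by "chain:resno:ins"
## keys (see res_key()).

#' Default solvent and buffer heteroatom exclusion list
#'
#' Het groups on this list are never reported as ligand instances.
#' Divalent cations such as BA and ZN are deliberately absent because
#' they occupy genuine binding sites (the interface cation site and the
#' transmembrane zinc site) and must survive ligand extraction.
#'
#' @export
SOLVENT_EXCLUDE <- c("HOH", "DOD", "NA", "CL", "K", "SO4", "PO4",
                     "GOL", "EDO", "PEG", "ACT")

new_structure <- function(label, atoms, metadata = list()) {
  required <- c("chain", "resno", "ins", "resid", "elety", "elesy",
                "x", "y", "z", "o", "alt", "het")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) {
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  }
  atoms$ins[is.na(atoms$ins)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  rownames(atoms) <- NULL
  s <- structure(
    list(label = label, atoms = atoms, metadata = metadata),
    class = "plgic_structure"
  )
  s$ligands <- extract_ligands(s)
  s
}

#' @export
print.plgic_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain[!x$atoms$het])
  cat(sprintf(
    "<plgic_structure '%s': %d atoms, %d protein chains (%s), %d ligand instance(s)>\n",
    x$label, nrow(x$atoms), length(ch), paste(ch, collapse = ","),
    length(x$ligands)
  ))
  invisible(x)
}

is_structure <- function(x) inherits(x, "plgic_structure")

## Guess an element symbol from an atom name when the element column is
## blank (common in minimal hand-written PDB records).
guess_element <- function(elety) {
  e <- toupper(sub("^[0-9']+", "", trimws(elety)))
  two <- substr(e, 1, 2)
  one <- substr(e, 1, 1)
  ifelse(two %in% c("FE", "ZN", "MG", "BR", "CL", "NA", "CA", "BA", "MN"),
         two, one)
}

## Highest-occupancy altloc policy: within each (chain, resno, ins, elety)
## group keep the alternate with the largest occupancy; ties break by
## altloc label order ("" < "A" < "B" ...).
collapse_altloc <- function(at) {
  if (!any(nzchar(at$alt))) return(at)
  grp <- paste(at$chain, at$resno, at$ins, at$elety, sep = "\r")
  ord <- order(grp, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(grp[ord]), , drop = FALSE]
  at[order(as.integer(rownames(at))), , drop = FALSE]
}

#' Parse a macromolecular coordinate file
#'
#' Reads PDB or mmCIF coordinates into a `plgic_structure`.  All ATOM and
#' HETATM records are represented; alternate locations are collapsed to
#' the highest-occupancy conformer; author residue numbering and
#' insertion codes are preserved.  Waters and buffer components (see
#' [SOLVENT_EXCLUDE]) are never reported as ligands.
#'
#' @param x Path to a coordinate file, or the file content itself as a
#'   character vector (one string with embedded newlines, or one element
#'   per line).
#' @param format `"pdb"` (default) or `"mmcif"`.  mmCIF is read-only.
#' @param label Structure label; defaults to the file base name or
#'   `"structure"` for in-memory text.
#' @return A `plgic_structure` with fields `label`, `atoms` (data frame),
#'   `ligands` (list of ligand instances) and `metadata`.
#' @export
parse_structure <- function(x, format = c("pdb", "mmcif"), label = NULL) {
  format <- match.arg(format)
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    path <- x
    if (is.null(label)) {
      label <- toupper(sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path),
                           ignore.case = TRUE))
    }
  } else {
    lines <- if (length(x) == 1L) strsplit(x, "\n", fixed = TRUE)[[1]] else x
    path <- tempfile(fileext = if (format == "pdb") ".pdb" else ".cif")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
    if (is.null(label)) label <- "structure"
  }

  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    rec <- grep("^(ATOM  |HETATM)", lines)
    if (!length(rec)) stop("no ATOM/HETATM records found in '", label, "'")
    bad <- rec[nchar(lines[rec]) < 54 |
                 is.na(suppressWarnings(as.numeric(substr(lines[rec], 31, 38))))]
    if (length(bad)) {
      stop(sprintf("malformed coordinate record at line %d: '%s'",
                   bad[1], lines[bad[1]]))
    }
    pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  } else {
    pdb <- suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
  }

  a <- pdb$atom
  at <- data.frame(
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = as.integer(a$resno),
    ins   = ifelse(is.na(a$insert), "", a$insert),
    resid = toupper(a$resid),
    elety = a$elety,
    elesy = ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)),
                   guess_element(a$elety), toupper(trimws(a$elesy))),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o),
    alt = ifelse(is.na(a$alt), "", a$alt),
    het = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    stop("non-finite coordinates in '", label, "'")
  }
  at <- collapse_altloc(at)
  new_structure(label, at, metadata = list(source = format))
}

#' Extract ligand instances from a structure
#'
#' Returns every het group that is not on the solvent/buffer exclusion
#' list, optionally restricted to a set of het names.  Monatomic ions
#' that occupy real sites (e.g. BA, ZN) are retained.
#'
#' @param s A `plgic_structure`.
#' @param include Optional character vector of het names to keep.
#' @param exclude Het names to drop; defaults to [SOLVENT_EXCLUDE].
#' @return A list of ligand instances, each a list with `het_name`,
#'   `chain_id`, `number`, `ins`, `key` and an `atoms` data frame of
#'   heavy atoms.
#' @export
extract_ligands <- function(s, include = NULL, exclude = SOLVENT_EXCLUDE) {
  at <- s$atoms
  het <- at[at$het & !(at$resid %in% toupper(exclude)) &
              !(at$elesy %in% c("H", "D")), , drop = FALSE]
  if (!is.null(include)) {
    het <- het[het$resid %in% toupper(include), , drop = FALSE]
  }
  if (!nrow(het)) return(list())
  key <- res_key(het$chain, het$resno, het$ins)
  out <- lapply(split(seq_len(nrow(het)), factor(key, levels = unique(key))),
                function(i) {
    g <- het[i, , drop = FALSE]
    list(
      het_name = g$resid[1], chain_id = g$chain[1],
      number = g$resno[1], ins = g$ins[1],
      key = res_key(g$chain[1], g$resno[1], g$ins[1]),
      atoms = g
    )
  })
  unname(out)
}

## Parse a selection expression: NULL (all protein chains), a character
## vector of chain ids, or "A:10-20,B" style range expressions.
parse_selection <- function(selection) {
  if (is.null(selection)) return(NULL)
  parts <- unlist(strsplit(selection, ",", fixed = TRUE))
  lapply(trimws(parts), function(p) {
    if (grepl(":", p, fixed = TRUE)) {
      bits <- strsplit(p, "[:-]")[[1]]
      list(chain = bits[1], from = as.integer(bits[2]), to = as.integer(bits[3]))
    } else {
      list(chain = p, from = NA_integer_, to = NA_integer_)
    }
  })
}

#' Select alpha-carbon positions
#'
#' Returns one entry per selected residue that possesses a CA atom, in
#' chain order then residue order.  Het residues without alpha carbons
#' are silently skipped.
#'
#' @param s A `plgic_structure`.
#' @param selection `NULL` for all chains, or a selection expression such
#'   as `"A"`, `"A:10-20"` or `"A:10-20,B"`.
#' @return Data frame with columns `key`, `chain`, `resno`, `ins`,
#'   `resid`, `x`, `y`, `z`.
#' @export
select_calpha <- function(s, selection = NULL) {
  at <- s$atoms
  ca <- at[at$elety == "CA" & at$elesy == "C", , drop = FALSE]
  sel <- parse_selection(selection)
  if (!is.null(sel)) {
    chains <- vapply(sel, `[[`, "", "chain")
    missing <- setdiff(chains, unique(at$chain))
    if (length(missing)) {
      stop("selection names missing chain(s): ", paste(missing, collapse = ", "))
    }
    keep <- rep(FALSE, nrow(ca))
    for (cl in sel) {
      m <- ca$chain == cl$chain
      if (!is.na(cl$from)) m <- m & ca$resno >= cl$from & ca$resno <= cl$to
      keep <- keep | m
    }
    ca <- ca[keep, , drop = FALSE]
  }
  ## chain order follows first appearance in the file, residues keep
  ## author order within each chain
  chain_order <- unique(at$chain)
  ca <- ca[order(match(ca$chain, chain_order), ca$resno, ca$ins), , drop = FALSE]
  data.frame(
    key = res_key(ca$chain, ca$resno, ca$ins),
    chain = ca$chain, resno = ca$resno, ins = ca$ins, resid = ca$resid,
    x = ca$x, y = ca$y, z = ca$z,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a structure as PDB text
#'
#' Emits valid PDB-format coordinate records, optionally after applying a
#' rigid transform.  Chain identifiers and author numbering (including
#' insertion codes) are preserved.
#'
#' @param s A `plgic_structure`.
#' @param file Optional path; when given the text is also written there.
#' @param transform Optional rigid transform from [rigid_transform()].
#' @return The PDB text, invisibly when `file` is given.
#' @export
write_structure <- function(s, file = NULL, transform = NULL) {
  at <- s$atoms
  if (!nrow(at)) stop("refusing to write an empty structure")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (!is.null(transform)) xyz <- apply_transform(xyz, transform)
  if (any(abs(xyz) > 9999.999)) {
    stop("coordinate overflow: values exceed the fixed-width PDB field")
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(
    file = tmp,
    xyz = as.numeric(t(xyz)),
    type = ifelse(at$het, "HETATM", "ATOM"),
    resno = at$resno, resid = at$resid,
    eleno = seq_len(nrow(at)), elety = at$elety,
    chain = ifelse(nzchar(at$chain), at$chain, " "),
    insert = ifelse(nzchar(at$ins), at$ins, ""),
    o = at$o, b = rep(0, nrow(at)), elesy = at$elesy
  )
  txt <- readLines(tmp, warn = FALSE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(paste(txt, collapse = "\n")))
  }
  paste(txt, collapse = "\n")
}

## Protein residues of one chain in author order: data frame with key,
## resno, ins, resid, plus CA coordinates where present.
chain_residues <- function(s, chain) {
  at <- s$atoms
  at <- at[at$chain == chain & !at$het, , drop = FALSE]
  if (!nrow(at)) stop("structure '", s$label, "' has no chain '", chain, "'")
  key <- res_key(at$chain, at$resno, at$ins)
  first <- !duplicated(key)
  res <- data.frame(
    key = key[first], resno = at$resno[first], ins = at$ins[first],
    resid = at$resid[first], stringsAsFactors = FALSE
  )
  ca <- at[at$elety == "CA", , drop = FALSE]
  cakey <- res_key(ca$chain, ca$resno, ca$ins)
  idx <- match(res$key, cakey)
  res$x <- ca$x[idx]; res$y <- ca$y[idx]; res$z <- ca$z[idx]
  res
}

## One-letter sequence of a chain's protein residues.
chain_sequence <- function(s, chain) {
  paste(aa321(chain_residues(s, chain)$resid), collapse = "")
}

protein_chains <- function(s) unique(s$atoms$chain[!s$atoms$het])
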