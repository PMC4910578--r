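## End-to-end orchestration from a single YAML configuration.
##
## A run configuration names the structures (files or synthetic
## generator recipes), the master alignment, and the analysis blocks to
## execute (atlas, rmsd, grouping, geometry, transfer).  Every output is
## TSV or JSON; a run manifest records the tool version, a config hash,
## per-file checksums and every threshold in force, so an unchanged
## config reproduces all numeric outputs.

#' Load and validate a run configuration
#'
#' @param config Path to a YAML file or an already-parsed list.
#' @return The validated configuration list.
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$structures) || !length(cfg$structures)) {
    stop("configuration must list at least one structure")
  }
  labels <- vapply(cfg$structures, function(s) s$label %||% "", "")
  if (any(!nzchar(labels)) || anyDuplicated(labels)) {
    stop("every structure entry needs a unique label")
  }
  for (st in cfg$structures) {
    if (is.null(st$path) && is.null(st$synthetic)) {
      stop("structure '", st$label, "' needs a 'path' or a 'synthetic' recipe")
    }
    if (!is.null(st$path) && !file.exists(st$path)) {
      stop("structure file not found: ", st$path)
    }
  }
  for (f in c("fasta", "sidecar")) {
    p <- cfg$alignment[[f]]
    if (!is.null(p) && !file.exists(p)) stop("alignment file not found: ", p)
  }
  blocks <- names(cfg$analyses %||% list())
  unknown <- setdiff(blocks, c("atlas", "rmsd", "grouping", "geometry", "transfer"))
  if (length(unknown)) stop("unknown analysis block(s): ",
                            paste(unknown, collapse = ", "))
  for (bl in cfg$analyses %||% list()) {
    bad <- setdiff(bl$structures %||% character(), labels)
    if (length(bad)) {
      stop("analysis block references unknown structure label(s): ",
           paste(bad, collapse = ", "))
    }
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg
}

load_config_structures <- function(cfg) {
  out <- list()
  for (st in cfg$structures) {
    if (!is.null(st$path)) {
      out[[st$label]] <- parse_structure(st$path,
                                         format = st$format %||% "pdb",
                                         label = st$label)
    } else {
      rc <- st$synthetic
      spec <- synthetic_spec(
        seed = rc$seed %||% cfg$seed,
        ecd_residues = rc$ecd_residues %||% 90L,
        tmd_residues = rc$tmd_residues %||% 90L,
        ring_radius = rc$ring_radius %||% 17,
        noise_sd = rc$base_noise_sd %||% 0,
        occluding_insertion = isTRUE(rc$occluding_insertion)
      )
      pent <- make_pentamer(spec)
      if (!is.null(rc$twist) || !is.null(rc$tilt) || !is.null(rc$noise_sd) ||
          !is.null(rc$loopc_shift)) {
        pent <- perturb_state(pent, twist = rc$twist %||% 0,
                              tilt = rc$tilt %||% 0,
                              noise_sd = rc$noise_sd %||% 0,
                              seed = rc$seed %||% cfg$seed,
                              loopc_shift = rc$loopc_shift %||% 0)
      }
      if (!is.null(rc$plant)) {
        pent <- plant_ligand(pent, rc$plant$site_class,
                             chains = unlist(rc$plant$chains) %||% c("A", "B"))
      }
      s <- pent$structure
      s$label <- st$label
      s$metadata$truth <- pent$truth
      out[[st$label]] <- s
    }
  }
  out
}

config_alignment <- function(cfg, structures) {
  if (!is.null(cfg$alignment$fasta)) {
    read_alignment(cfg$alignment$fasta, cfg$alignment$sidecar)
  } else {
    ## synthetic-only runs can fall back on the generator's own alignment
    tr <- Filter(Negate(is.null),
                 lapply(structures, function(s) s$metadata$truth$alignment))
    if (!length(tr)) stop("no alignment configured and no synthetic fallback")
    tr[[1]]
  }
}

#' Execute a configured pipeline run
#'
#' Blocks run in dependency order (parse, correspond, superpose and
#' contacts, classify and transfer, tables and grouping).  A failing
#' block is isolated: the run continues, the failure is logged, and the
#' bundle's `status` becomes non-zero at the end.
#'
#' @param config Path to a YAML configuration or a configuration list.
#' @param out Output directory (overrides the config's `output`).
#' @param verbose Log progress to standard error.
#' @return A `plgic_report_bundle`: list with `outputs` (named file
#'   paths), `manifest`, `errors` and `status` (0 on full success).
#' @export
run_pipeline <- function(config, out = NULL, verbose = FALSE) {
  cfg <- read_run_config(config)
  outdir <- out %||% cfg$output %||% "plgicmap-run"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (verbose) message(sprintf(...))

  outputs <- list(); errors <- list()
  thresholds <- list()
  run_block <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      log("block '%s' failed: %s", name, conditionMessage(e))
      NULL
    })
  }

  log("loading %d structure(s)", length(cfg$structures))
  structures <- load_config_structures(cfg)
  aln <- config_alignment(cfg, structures)
  an <- cfg$analyses %||% list()
  pick <- function(bl) {
    labs <- bl$structures %||% names(structures)
    structures[labs]
  }

  rmsd_matrix <- NULL
  if (!is.null(an$atlas)) {
    run_block("atlas", function() {
      cutoff <- an$atlas$cutoff %||% 4.0
      thresholds$contact_cutoff <<- cutoff
      atlas <- build_site_atlas(pick(an$atlas), aln, cutoff = cutoff,
                                vestibule_radius = an$atlas$vestibule_radius %||% 8)
      thresholds$vestibule_radius <<- an$atlas$vestibule_radius %||% 8
      p1 <- file.path(outdir, "atlas.tsv"); p2 <- file.path(outdir, "atlas.json")
      write_atlas(atlas, tsv = p1, json = p2)
      outputs$atlas_tsv <<- p1; outputs$atlas_json <<- p2
      log("atlas: %d occurrence(s), %d class(es)", nrow(atlas),
          attr(atlas, "n_classes"))
    })
  }
  if (!is.null(an$rmsd)) {
    run_block("rmsd", function() {
      bl <- an$rmsd
      m <- pairwise_rmsd(pick(bl), mode = bl$mode %||% "alignment", aln = aln,
                         pentamer_mode = isTRUE(bl$pentamer %||% TRUE))
      rmsd_matrix <<- m
      p <- file.path(outdir, "rmsd.tsv")
      write_rmsd_tsv(m, p)
      outputs$rmsd_tsv <<- p
      log("rmsd: %d x %d matrix", length(m$labels), length(m$labels))
    })
  }
  if (!is.null(an$grouping)) {
    run_block("grouping", function() {
      thr <- an$grouping$threshold %||% 2.5
      thresholds$grouping_threshold <<- thr
      m <- rmsd_matrix
      if (is.null(m)) stop("grouping requires the rmsd block")
      grp <- group_conformations(m, threshold = thr)
      p <- file.path(outdir, "grouping.json")
      jsonlite::write_json(
        list(threshold = thr, method = grp$method, partition = grp$partition),
        p, auto_unbox = TRUE, digits = NA)
      outputs$grouping_json <<- p
      log("grouping: %d group(s)", length(grp$partition))
    })
  }
  if (!is.null(an$geometry)) {
    run_block("geometry", function() {
      bl <- an$geometry
      ifc <- unlist(bl$interface) %||% c(plus = "A", minus = "B")
      tab <- distance_table(pick(bl), default_distance_set(), aln,
                            interface = ifc)
      p <- file.path(outdir, "geometry.tsv")
      write_geometry_tsv(tab, p)
      outputs$geometry_tsv <<- p
      log("geometry: %d state(s) x %d distance(s)", nrow(tab), ncol(tab))
    })
  }
  if (!is.null(an$transfer)) {
    run_block("transfer", function() {
      bl <- an$transfer
      src <- structures[[bl$source]]; tgt <- structures[[bl$target]]
      if (is.null(src) || is.null(tgt)) stop("transfer needs source and target labels")
      cutoff <- bl$cutoff %||% 4.0
      clash <- bl$clash %||% 2.8
      thr <- bl$threshold %||% 0.25
      thresholds$clash_distance <<- clash
      thresholds$occlusion_threshold <<- thr
      ligs <- extract_ligands(src)
      rows <- lapply(ligs, function(lig) {
        cs <- ligand_contacts(src, lig, cutoff = cutoff)
        corrs <- lapply(names(cs$contacts), function(ch) {
          structural_correspondence(src, ch, tgt, ch)
        })
        tr <- transfer_site(cs, corrs, src, tgt, clash = clash, threshold = thr)
        data.frame(ligand = lig$het_name, ligand_key = lig$key,
                   mapped = length(unlist(tr$mapped)),
                   unmapped = tr$unmapped_count,
                   occlusion = tr$occlusion, verdict = tr$verdict,
                   stringsAsFactors = FALSE)
      })
      p <- file.path(outdir, "transfer.tsv")
      utils::write.table(do.call(rbind, rows), p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs$transfer_tsv <<- p
    })
  }

  files <- unlist(lapply(cfg$structures, `[[`, "path"))
  manifest <- list(
    tool = "plgicmap",
    version = as.character(utils::packageVersion("plgicmap")),
    seed = cfg$seed,
    config_hash = digest_config(cfg),
    structure_checksums = if (length(files))
      as.list(tools::md5sum(files)) else list(),
    thresholds = thresholds,
    blocks_run = names(an),
    errors = errors
  )
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  outputs$manifest <- mp
  structure(
    list(outputs = outputs, manifest = manifest, errors = errors,
         status = if (length(errors)) 1L else 0L),
    class = "plgic_report_bundle"
  )
}

digest_config <- function(cfg) {
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.plgic_report_bundle <- function(x, ...) {
  cat(sprintf("<report bundle: %d output(s), status %d>\n",
              length(x$outputs), x$status))
  for (nm in names(x$outputs)) cat(sprintf("  %s: %s\n", nm, x$outputs[[nm]]))
  invisible(x)
}

#' Materialize the standard synthetic fixture set
#'
#' Writes a base pentamer, a twisted/tilted conformational state, a
#' vestibule-occluded variant, planted-ligand structures for each
#' placeable site class, the generator's master alignment (aligned FASTA
#' plus anchor sidecar) and a ground-truth JSON sidecar.
#'
#' @param dir Output directory.
#' @param seed Generator seed.
#' @return Invisibly, the list of written paths.
#' @export
write_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  base <- make_pentamer(synthetic_spec(seed = seed))
  paths$base <- file.path(dir, "synth_base.pdb")
  write_structure(base$structure, file = paths$base)
  state <- perturb_state(base, twist = 5, tilt = 2, noise_sd = 0.1,
                         seed = seed + 1L)
  paths$state <- file.path(dir, "synth_state_twist5.pdb")
  write_structure(state$structure, file = paths$state)
  occ <- make_pentamer(synthetic_spec(seed = seed, occluding_insertion = TRUE))
  paths$occluded <- file.path(dir, "synth_occluded.pdb")
  write_structure(occ$structure, file = paths$occluded)
  planted <- list()
  for (cls in c(1:10)[-c(3)]) {
    pl <- plant_ligand(base, cls)
    p <- file.path(dir, sprintf("synth_site%02d.pdb", cls))
    write_structure(pl$structure, file = p)
    paths[[sprintf("site%02d", cls)]] <- p
    planted[[as.character(cls)]] <- list(
      site_class = cls, ligand_key = pl$expected$ligand_key,
      contacts = pl$expected$contacts, cutoff = pl$expected$cutoff
    )
  }
  paths$fasta <- file.path(dir, "synth_alignment.fasta")
  paths$sidecar <- file.path(dir, "synth_anchors.tsv")
  write_alignment(base$truth$alignment, paths$fasta, paths$sidecar)
  truth <- list(
    seed = seed,
    sse = as.list(base$truth$sse),
    anchor = as.list(base$truth$anchor),
    domain = as.list(base$truth$domain),
    planted_motion = list(twist = 5, tilt = 2, noise_sd = 0.1),
    planted_ligands = planted
  )
  paths$truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
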