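# Pipeline orchestration: run the requested analysis stages from a config
# (YAML file or list) and emit machine-readable reports plus a manifest that
# suffices to re-run the pipeline bit-identically.

#' Read a pipeline configuration file
#'
#' YAML with keys: `stages` (subset of `motifs`, `contacts`, `fingerprint`,
#' `metrics`, `simulate`), `output_dir`, `seed`, `fasta`, `structure`,
#' `trajectory`, `regions` (name -> `[start, end]`), `parameters` (overrides
#' for [analysis_parameters()]), `synthetic` (overrides for the demo spec:
#' `which` = `apo`/`holo`, `n_frames`), `motif_pair`, `hbond`
#' (`donor_residue`, `donor_atom`, `acceptor_atom`), `windows`.
#'
#' @param path YAML file path.
#' @return Config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' @noRd
config_params <- function(config) {
  ov <- config$parameters %||% list()
  do.call(analysis_parameters, ov)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order and writes the report
#' bundle: a motif TSV, the Table-1-style occupancy CSV, the paired-motif
#' class CSV, the fingerprint CSV, metrics CSVs (RMSD, RMSF, bend, PCA) and
#' a JSON manifest (parameters, frame count, stride, seed, package version).
#' With the `simulate` stage, the system is generated from the bundled demo
#' spec (selected and sized via `config$synthetic`); otherwise `structure`/
#' `trajectory` paths are loaded. Identical config and seed give a
#' byte-identical report bundle.
#'
#' @param config A `run_config`, a YAML path, or a plain list.
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- config$stages %||% c("simulate", "contacts")
  known <- c("motifs", "contacts", "fingerprint", "metrics", "simulate")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  needs_sys <- any(c("contacts", "fingerprint", "metrics") %in% stages)
  if (needs_sys && !("simulate" %in% stages) && is.null(config$structure))
    stopf("stages %s need a structure/trajectory or the simulate stage",
          paste(intersect(stages, c("contacts", "fingerprint", "metrics")),
                collapse = ","))
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_params(config)
  seed <- as.integer(config$seed %||% 1L)
  label <- config$label %||% "system"
  results <- list()
  paths <- character(0)
  emit <- function(name) file.path(out_dir, name)

  # -- simulate / load ------------------------------------------------------
  sys <- NULL
  truth <- NULL
  if ("simulate" %in% stages) {
    sy <- config$synthetic %||% list()
    which_demo <- sy$which %||% "apo"
    nfr <- as.integer(sy$n_frames %||% 1000L)
    spec <- if (identical(which_demo, "holo")) demo_holo_spec(nfr, seed = seed)
            else demo_apo_spec(nfr, seed = seed)
    traj <- synthesize_trajectory(spec)
    sys <- traj$system
    truth <- traj$truth
    results$truth <- truth
    regions <- spec_regions(spec)
  } else if (needs_sys) {
    sys <- load_system(config$structure, config$trajectory,
                       stride_ns = config$stride_ns %||% 1)
    regions <- if (!is.null(config$regions)) region_definition(config$regions)
               else default_htspo_regions()
  }
  if (!is.null(config$regions)) regions <- region_definition(config$regions)

  # -- motifs ---------------------------------------------------------------
  if ("motifs" %in% stages) {
    fasta <- config$fasta %||%
      system.file("extdata", "P30536_hTSPO.fasta", package = "choltraj")
    seqs <- read_fasta(fasta)
    rg <- if (exists("regions", inherits = FALSE) && !is.null(regions)) regions
          else default_htspo_regions()
    hits <- lapply(seqs, function(s) find_named_motifs(s, rg))
    results$motifs <- hits
    mt <- emit("motifs.tsv")
    rows <- do.call(rbind, lapply(seq_along(seqs), function(i)
      write_motif_tsv(hits[[i]], tempfile(), sequence_id = seqs[[i]]$id)))
    utils::write.table(rows, mt, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, mt)
  }

  # -- contacts -------------------------------------------------------------
  if ("contacts" %in% stages) {
    series <- region_contact_series(sys, regions, params)
    results$series <- series
    rep1 <- occupancy_report(series, label)
    results$occupancy <- rep1
    p1 <- emit("occupancy.csv")
    write_occupancy_table(rep1, p1)
    paths <- c(paths, p1)
    pair <- config$motif_pair %||%
      (if (all(c("CRAC", "CARC") %in% series$regions)) c("CRAC", "CARC"))
    if (!is.null(pair)) {
      cl <- motif_occupancy_classes(series, pair[1], pair[2])
      results$motif_classes <- cl
      p2 <- emit("motif_classes.csv")
      cls <- list(cl); names(cls) <- label
      write_motif_class_table(cls, p2, trace_path = emit("motif_class_trace.tsv"))
      paths <- c(paths, p2, emit("motif_class_trace.tsv"))
    }
    lf <- assign_leaflets(sys, frame = 1L)
    results$leaflets <- lf
    p3 <- emit("leaflets.csv")
    utils::write.csv(lf, p3, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p3)
  }

  # -- fingerprint ----------------------------------------------------------
  if ("fingerprint" %in% stages) {
    if (length(molecules_of_class(sys, "ligand")) == 0L)
      stopf("fingerprint stage: system contains no molecule of class 'ligand'")
    windows <- config$windows
    hbonds <- NULL
    hb <- config$hbond %||% list(donor_residue = 53, donor_atom = "CB",
                                 acceptor_atom = "O1")
    lig_mol <- molecules_of_class(sys, "ligand")[1]
    acc_res <- unique(sys$atoms$residue_index[sys$atoms$molecule_id == lig_mol])[1]
    hbonds <- list(W_carbonyl = list(
      donor = list(residue = hb$donor_residue, atom = hb$donor_atom),
      acceptor = list(residue = acc_res, atom = hb$acceptor_atom)))
    fp <- fingerprint_report(sys, params, windows = windows, hbonds = hbonds)
    results$fingerprint <- fp
    p <- emit("fingerprint.csv")
    write_fingerprint_csv(fp, p)
    paths <- c(paths, p)
  }

  # -- metrics --------------------------------------------------------------
  if ("metrics" %in% stages) {
    rsel <- select_atoms(sys, residue_range = params$rmsd_selection,
                         molecule_class = "protein", backbone = TRUE,
                         heavy_only = TRUE)
    rmsd <- rmsd_series(sys, rsel)
    results$rmsd <- rmsd
    p1 <- emit("rmsd.csv")
    utils::write.csv(rmsd, p1, row.names = FALSE, quote = FALSE)
    csel <- select_atoms(sys, residue_range = params$rmsd_selection,
                         molecule_class = "protein", calpha = TRUE)
    tmax <- max(frame_times(sys))
    w0 <- min(params$equilibration_start_ns, tmax / 2)
    rmsf <- rmsf_profile(sys, csel, window = c(w0, tmax))
    results$rmsf <- rmsf
    p2 <- emit("rmsf.csv")
    utils::write.csv(rmsf, p2, row.names = FALSE, quote = FALSE)
    helix_rg <- Filter(function(nm) startsWith(nm, "TM"), names(regions))
    bends <- list()
    brow <- list()
    for (nm in helix_rg) {
      r <- as_region_list(regions)[[nm]]
      nres <- sum(sys$atoms$name == "CA" & sys$atoms$residue_index >= r[1] &
                    sys$atoms$residue_index <= r[2])
      if (nres < 8) next
      bp <- bend_profile(sys, r, params = params)
      bends[[nm]] <- bp
      brow[[nm]] <- data.frame(helix = nm, residue = bp$residues,
                               max_angle = apply(bp$angles, 2, max),
                               mean_angle = colMeans(bp$angles))
    }
    results$bend <- bends
    p3 <- emit("bend.csv")
    utils::write.csv(do.call(rbind, brow), p3, row.names = FALSE, quote = FALSE)
    pca <- pca_modes(sys, csel, ncomp = 5)
    results$pca <- pca
    p4 <- emit("pca.csv")
    utils::write.csv(data.frame(component = seq_along(pca$eigenvalues[1:10]),
                                eigenvalue_A2 = pca$eigenvalues[1:10]),
                     p4, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p1, p2, p3, p4)
  }

  manifest <- list(
    package = "choltraj",
    version = as.character(utils::packageVersion("choltraj")),
    stages = stages, seed = seed, label = label,
    parameters = unclass(params),
    frame_count = if (!is.null(sys)) n_frames(sys) else NA,
    stride_ns = if (!is.null(sys) && n_frames(sys) > 1)
      frame_times(sys)[2] - frame_times(sys)[1] else NA,
    outputs = basename(paths))
  mp <- emit("manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, mp)
  invisible(c(results, list(paths = paths)))
}
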