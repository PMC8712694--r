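# Configuration-driven orchestration: run the whole analysis battery on one
# trajectory and write tidy CSV/JSON outputs plus a manifest of every
# convention and parameter used.

default_pipeline_params <- function() {
  list(
    padding = 1.0,
    z_spacing = 0.5,
    radial_cutoff = 10,
    temperature = 300,
    bulk_density = 0.0334,
    dewetting_count_threshold = 1L,
    dewetting_persistence_ns = 1.0,
    contact_cutoff = 5.0,
    contact_min_atom_pairs = 2L,
    contact_persistence = 5L,
    consensus_min_subunits = 3L,
    gate_contact_cutoff = 7.5,
    sasa_probe = 1.4,
    sasa_n_points = 960L,
    water_probe_radius = 1.15)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order - regions, radius profile,
#' hydration/PMF, helix kinematics, contacts, RMSD - on one structure +
#' trajectory, writing each result as CSV and a JSON manifest that records
#' every parameter, threshold and seed in effect. Deterministic given `seed`.
#'
#' @param config a list, or path to a YAML/JSON file, with entries:
#'   `structure` (PDB path), `trajectory` (DCD path), `topology` (annotation
#'   path, optional - defaults to [channel_topology()]), `output_dir`,
#'   `frame_interval` (ns), optional `stages` (character subset of
#'   `c("regions", "radius", "hydration", "kinematics", "contacts",
#'   "metrics")`), optional `params` overriding any default in the manifest,
#'   optional `seed`.
#' @return the manifest list, invisibly; all outputs are files under
#'   `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(config)
      else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (fld in c("structure", "trajectory", "output_dir")) {
    if (is.null(config[[fld]]))
      stop("pipeline config is missing required field '", fld, "'")
  }
  for (fld in c("structure", "trajectory")) {
    if (!file.exists(config[[fld]]))
      stop("pipeline config field '", fld, "' points to a missing file: ",
           config[[fld]])
  }
  stages <- config$stages %||% c("regions", "radius", "hydration",
                                 "kinematics", "contacts", "metrics")
  params <- utils::modifyList(default_pipeline_params(), config$params %||% list())
  seed <- config$seed %||% 1L
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  topology <- if (!is.null(config$topology)) read_topology(config$topology)
    else channel_topology()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  st <- run_stage("load", read_channel_pdb(config$structure))
  traj <- run_stage("load", load_trajectory(
    config$trajectory, st$atoms,
    frame_interval = config$frame_interval %||% 0.1))
  outputs <- list()
  emit <- function(tbl, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(tbl, path, row.names = FALSE)
    outputs[[file]] <<- path
    path
  }
  regions <- run_stage("regions",
                       define_regions(st, topology, padding = params$padding))
  if ("regions" %in% stages) emit(regions, "regions.csv")
  if ("radius" %in% stages) run_stage("radius", {
    zr <- range(st$xyz[!is_water_atom(st$atoms), 3])
    z_grid <- seq(floor(zr[1]), ceiling(zr[2]), by = params$z_spacing)
    prof <- average_radius_profile(traj, z_grid = z_grid,
                                   include_side_chains = TRUE, seed = seed)
    emit(prof, "radius_profile.csv")
    prof_nosc <- average_radius_profile(traj, z_grid = z_grid,
                                        include_side_chains = FALSE,
                                        seed = seed)
    emit(prof_nosc, "radius_profile_no_side_chains.csv")
  })
  if ("hydration" %in% stages) run_stage("hydration", {
    ws <- water_series(traj, regions, radial_cutoff = params$radial_cutoff)
    emit(ws, "water_counts.csv")
    hydro <- ws[ws$region == "hydrophobic", ]
    emit(detect_dewetting(hydro, params$dewetting_count_threshold,
                          params$dewetting_persistence_ns),
         "dewetting_intervals.csv")
    pmf <- pmf_axial(traj, temperature = params$temperature,
                     bulk_density = params$bulk_density,
                     radial_cutoff = params$radial_cutoff)
    emit(tidy(pmf), "pmf_axial.csv")
    pmf2 <- pmf_radial_axial(traj, temperature = params$temperature,
                             bulk_density = params$bulk_density,
                             radial_cutoff = params$radial_cutoff)
    emit(tidy(pmf2), "pmf_radial_axial.csv")
    emit(hydrophobicity_profile(st, topology), "hydrophobicity_profile.csv")
  })
  if ("kinematics" %in% stages) run_stage("kinematics", {
    rot <- rotation_series(traj, topology)
    emit(rot, "rotation_angles.csv")
    emit(rotation_summary(rot), "rotation_mean.csv")
    emit(chi1_series(traj, topology$gate_residue, topology$subunits[1]),
         "gate_chi1.csv")
    emit(atom_contact_series(traj, topology$gate_residue,
                             topology$subunits[1],
                             cutoff = params$gate_contact_cutoff),
         "gate_atom_contacts.csv")
  })
  if ("contacts" %in% stages) run_stage("contacts", {
    ev <- contact_events(traj, topology, cutoff = params$contact_cutoff,
                         min_atom_pairs = params$contact_min_atom_pairs,
                         persistence = params$contact_persistence)
    emit(ev, "contact_events.csv")
    emit(consensus_events(ev, topology,
                          min_subunits = params$consensus_min_subunits),
         "consensus_events.csv")
  })
  if ("metrics" %in% stages) run_stage("metrics", {
    for (preset in c("all_backbone", "tm4_backbone", "pore_helix_backbone")) {
      sel <- rmsd_selection(traj$atoms, topology, preset)
      align <- rmsd_selection(traj$atoms, topology, "all_backbone")
      emit(rmsd_series(traj, st, align, sel), paste0("rmsd_", preset, ".csv"))
    }
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("poregate")),
    r_version = R.version.string,
    inputs = config[c("structure", "trajectory", "topology")],
    frame_interval_ns = traj$frame_interval,
    n_frames = n_frames(traj),
    n_atoms = nrow(traj$atoms),
    stages = stages,
    seed = seed,
    params = params,
    region_bounds = as.data.frame(regions),
    outputs = names(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
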