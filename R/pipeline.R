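# Config-driven analysis pipeline: one entry point chaining the stages, with
# deterministic, seeded outputs. Each JSON artifact carries a provenance
# header (tool version, config hash, seed).

.vibmd_version <- function()
  as.character(utils::packageVersion("vibmd"))

.config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # small deterministic polynomial hash; avoids external digest dependencies
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.provenance <- function(config)
  list(tool = "vibmd", version = .vibmd_version(),
       config_hash = .config_hash(config),
       seed = if (!is.null(config$seed)) config$seed else NA)

.write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

.cfg_selection <- function(sel) {
  if (is.null(sel)) NULL
  else atom_selection(sel$indices, if (is.null(sel$label)) "" else sel$label)
}

.load_traj <- function(config) {
  if (is.null(config$input) || !file.exists(config$input))
    stop("input trajectory not found: ",
         if (is.null(config$input)) "<missing>" else config$input)
  tr <- read_trajectory(config$input,
                        timestep = if (is.null(config$timestep)) 1
                                   else config$timestep)
  if (!is.null(config$equilibration_fs) && config$equilibration_fs > 0)
    tr <- trim_equilibration(tr, config$equilibration_fs)
  if (!is.null(tr$cell) && isTRUE(config$unwrap)) tr <- unwrap(tr)
  if (is.null(tr$velocities)) tr <- derive_velocities(tr)
  tr
}

#' Run one analysis stage from a configuration
#'
#' The single entry point chaining the package's stages. `command` selects
#' the stage; `config` is a named list (or path to a YAML file) with the
#' fields that stage needs: `input` (extended-XYZ trajectory), `timestep`
#' (fs), `equilibration_fs`, `unwrap`, `selection` (list with `indices`,
#' `label`), `glide` (list: `mirror_axis`, `plane_offset`, `glide_vector`,
#' `cutoff`), spectra options (`window`, `segments`, `bands`, `temperature`,
#' `n_adsorbates`), local-mode options (`molecules`: list of index vectors),
#' peak options (`min_prominence`, `min_separation`, `window_halfwidth`),
#' `reference` (CSV path with `reference`,`calculated`,`label` columns),
#' `exclude` labels, synthetic options (`layout`, `temperature`, `n_steps`,
#' `dt`, `friction`, `scheme`), and `seed`. Outputs are written under
#' `out_dir` and are byte-reproducible given the same config and seed.
#'
#' @param command one of "synth", "dos", "ellipsoids", "symmetry",
#'   "localmodes", "assign", "compare"
#' @param config named list or path to a YAML config file
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list of the paths written
#' @export
vibmd_run <- function(command = c("synth", "dos", "ellipsoids", "symmetry",
                                  "localmodes", "assign", "compare"),
                      config = list(), out_dir = ".") {
  command <- match.arg(command)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- .provenance(config)
  paths <- character(0)
  pjoin <- function(...) file.path(out_dir, paste0(...))

  if (command == "synth") {
    seed <- if (is.null(config$seed)) 1L else config$seed
    layout <- if (is.null(config$layout)) "single" else config$layout
    toy <- glycinate_toy(layout = layout)
    ispec <- integrator_spec(
      scheme = if (is.null(config$scheme)) "langevin" else config$scheme,
      T = if (is.null(config$temperature)) 500 else config$temperature,
      dt = if (is.null(config$dt)) 0.25 else config$dt,
      n_steps = if (is.null(config$n_steps)) 40000 else config$n_steps,
      friction = if (is.null(config$friction)) 0.01 else config$friction,
      seed = seed)
    tr <- integrate_dynamics(toy$model, ispec)
    p <- pjoin("trajectory.xyz")
    write_trajectory(tr, p, header_comment = sprintf("seed=%d", seed))
    meta <- c(prov, list(layout = layout,
                         targets = as.list(toy$target_frequencies)))
    pm <- pjoin("synth_meta.json"); .write_json(meta, pm)
    paths <- c(p, pm)
  } else if (command == "dos") {
    tr <- .load_traj(config)
    sel <- .cfg_selection(config$selection)
    S <- mass_weighted_psd(tr, sel,
                           window = if (is.null(config$window)) "hann"
                                    else config$window,
                           segments = if (is.null(config$segments)) 1
                                      else config$segments)
    if (!is.null(config$n_adsorbates) && config$n_adsorbates > 1)
      S <- normalize_per_adsorbate(S, config$n_adsorbates)
    p <- pjoin("dos.csv")
    utils::write.csv(data.frame(wavenumber_cm1 = S$wavenumbers,
                                intensity = S$intensity), p,
                     row.names = FALSE)
    T_ <- if (is.null(config$temperature)) 500 else config$temperature
    bands <- if (is.null(config$bands)) default_bands() else config$bands
    counts <- lapply(bands, function(b)
      band_mode_count(S, c(max(b[[1]], min(S$wavenumbers)),
                           min(b[[2]], max(S$wavenumbers))), T_))
    pm <- pjoin("dos_meta.json")
    .write_json(c(prov, list(normalization = S$normalization,
                             resolution_cm1 = S$resolution,
                             band_mode_counts = counts)), pm)
    paths <- c(p, pm)
  } else if (command %in% c("ellipsoids", "symmetry")) {
    tr <- .load_traj(config)
    ms <- mean_structure(tr, .cfg_selection(config$selection))
    g <- config$glide
    glide <- if (!is.null(g))
      match_under_symmetry(ms,
        mirror_axis = if (is.null(g$mirror_axis)) "y" else g$mirror_axis,
        plane_offset = if (is.null(g$plane_offset)) 0 else g$plane_offset,
        glide_vector = if (is.null(g$glide_vector)) c(0, 0, 0)
                       else unlist(g$glide_vector),
        cutoff = if (is.null(g$cutoff)) 1.0 else g$cutoff)
    if (command == "symmetry") {
      if (is.null(glide)) stop("symmetry stage requires a glide config")
      sels <- if (is.null(config$report_selections))
        list(atom_selection(seq_len(nrow(ms$mean_positions)), "all"))
      else lapply(config$report_selections, .cfg_selection)
      dev <- rms_symmetry_deviation(ms, glide, sels)
      p <- pjoin("symmetry.json")
      .write_json(c(prov, list(rms_deviation_angstrom = as.list(dev))), p)
      paths <- p
    } else {
      U <- displacement_matrices(tr, ms)
      if (!is.null(glide)) U <- symmetrize_displacement_matrices(U, glide)
      rep_ <- ellipsoid_report(U)
      p <- pjoin("ellipsoids.csv")
      utils::write.csv(rep_, p, row.names = FALSE)
      paths <- p
      if (!is.null(ms$cell)) {
        pc <- pjoin("adp.cif")
        write_adp_cif(ms, U, pc)
        paths <- c(paths, pc)
      }
      pm <- pjoin("ellipsoids_meta.json")
      .write_json(c(prov, list(symmetrized = !is.null(glide),
                               n_frames = ms$n_frames_averaged)), pm)
      paths <- c(paths, pm)
    }
  } else if (command == "localmodes") {
    tr <- .load_traj(config)
    mols <- if (is.null(config$molecules)) list(1:9) else config$molecules
    basis <- build_local_mode_basis(glycinate_topology())
    series <- lapply(mols, function(idx)
      project_velocities(tr, basis, atom_selection(unlist(idx))))
    ls <- local_mode_spectra(series,
                             window = if (is.null(config$window)) "hann"
                                      else config$window)
    wide <- data.frame(wavenumber_cm1 = ls[[1]]$wavenumbers)
    for (nm in names(ls)) wide[[nm]] <- ls[[nm]]$intensity
    p <- pjoin("local_mode_spectra.csv")
    utils::write.csv(wide, p, row.names = FALSE)
    pm <- pjoin("localmodes_meta.json")
    .write_json(c(prov, list(modes = names(ls),
                             n_molecules = length(series))), pm)
    paths <- c(p, pm)
  } else if (command == "assign") {
    spec_file <- if (is.null(config$dos_csv)) stop("assign needs dos_csv")
                 else config$dos_csv
    lm_file <- if (is.null(config$localmodes_csv))
      stop("assign needs localmodes_csv") else config$localmodes_csv
    dos <- utils::read.csv(spec_file)
    S <- vib_spectrum(dos[[1]], dos[[2]], "raw")
    wide <- utils::read.csv(lm_file, check.names = FALSE)
    ls <- lapply(wide[-1], function(col)
      normalize_unit_area(vib_spectrum(wide[[1]], pmax(col, 0), "raw")))
    pk <- detect_peaks(S,
      min_prominence = if (is.null(config$min_prominence)) 0.05
                       else config$min_prominence,
      min_separation = if (is.null(config$min_separation)) 10
                       else config$min_separation,
      round5 = TRUE)
    at <- assign_peaks(pk, ls,
      window_halfwidth = if (is.null(config$window_halfwidth)) 25
                         else config$window_halfwidth)
    p <- pjoin("assignments.csv")
    utils::write.csv(data.frame(frequency = at$frequency,
                                assignment = at$assignment), p,
                     row.names = FALSE)
    pm <- pjoin("assignments.json")
    .write_json(c(prov, list(peaks = lapply(seq_len(nrow(at)), function(i)
      list(frequency = at$frequency[i],
           contributions = as.list(at$contributions[[i]]))))), pm)
    paths <- c(p, pm)
  } else {                                   # compare
    ref_file <- if (is.null(config$reference)) stop("compare needs reference")
                else config$reference
    if (!file.exists(ref_file)) stop("reference file not found: ", ref_file)
    pairs <- utils::read.csv(ref_file, stringsAsFactors = FALSE)
    stats_all <- rms_discrepancy(pairs)
    out <- list(n_pairs = nrow(stats_all$pairs),
                rms_abs_cm1 = stats_all$rms_abs,
                rms_rel_pct = stats_all$rms_rel)
    if (!is.null(config$exclude)) {
      st2 <- rms_discrepancy(pairs, exclude = unlist(config$exclude))
      out$excluding <- list(labels = as.list(unlist(config$exclude)),
                            rms_abs_cm1 = st2$rms_abs,
                            rms_rel_pct = st2$rms_rel)
    }
    p <- pjoin("discrepancy.json")
    .write_json(c(prov, out), p)
    paths <- p
  }
  invisible(paths)
}
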