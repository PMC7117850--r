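#' Default pipeline configuration
#'
#' A desk-scale demo configuration: a scaled tibia phantom coarse enough for
#' the micro-FE solve to finish in minutes, one synthetic bending curve per
#' specimen, and a small longitudinal study. Every calibration default
#' mirrors the scanner calibration chain in
#' \code{\link{calibration_constants}}. Override any entry via the
#' \code{config} argument of \code{\link{run_pipeline}} or a YAML file.
#'
#' @param seed master seed; stage seeds derive from it.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    phantom = list(voxel_size = 0.036, noise_sd = 4),
    calibration = list(),
    voi = list(offset_mm = 0.35, trab_fraction = 0.12, cort_fraction = 0.05,
               r_close_mm = 0.09),
    fe = list(force_N = 35, bc = "fixed", occupancy = 4, tol = 1e-8),
    bending = list(yield_threshold = 0.9, stiffness_window = c(0.2, 0.8)),
    stats = list(alpha = 0.05, sham = "sham"),
    study = list(n_per_group = 3, timepoints = c(11, 14, 22, 34, 52))
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Entries present in the file override \code{\link{default_config}}.
#'
#' @param path YAML or JSON file.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config(if (!is.null(user$seed)) user$seed else 1L)
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    else cfg[[nm]] <- user[[nm]]
  }
  cfg
}

.config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

.stage_done <- function(outdir, stage, hash) {
  mf <- file.path(outdir, paste0(stage, ".manifest.json"))
  if (!file.exists(mf)) return(FALSE)
  m <- jsonlite::read_json(mf)
  identical(m$config_hash, hash)
}

.write_manifest <- function(outdir, stage, hash, artifacts, t0) {
  jsonlite::write_json(
    list(stage = stage, config_hash = hash,
         artifacts = artifacts,
         elapsed_s = round(as.numeric(Sys.time()) - t0, 2),
         version = as.character(utils::packageVersion("tibiamech")),
         written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(outdir, paste0(stage, ".manifest.json")),
    auto_unbox = TRUE, digits = NA)
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order - generate (phantom volume,
#' bending curve, study table), morphometry (threshold, VOIs, shell
#' exclusion, trabecular and cortical parameter sets, phantom density
#' calibration), fe (35-N axial compression, principal-strain summaries per
#' VOI), bend (full bending property set using the measured mid-diaphysis
#' geometry), stats (repeated-measures comparison of the study table).
#' Each stage writes its artifacts plus a manifest carrying the config
#' hash; rerunning with an unchanged config skips completed stages.
#'
#' @param config a config list (see \code{\link{default_config}}) or a
#'   YAML/JSON path.
#' @param outdir output directory (created if needed).
#' @param verbose print per-stage progress and timing.
#' @return invisibly, the result bundle (named list of stage outputs).
#' @export
run_pipeline <- function(config = default_config(), outdir = "tibiamech_out",
                         verbose = TRUE) {
  if (is.character(config)) config <- load_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  say <- function(...) if (verbose) message(sprintf(...))
  bundle <- list(config = config)
  consts <- do.call(calibration_constants, config$calibration)

  # -- generate ----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  gen_rds <- file.path(outdir, "generate.rds")
  done <- .stage_done(outdir, "generate", hash)
  if (done && !file.exists(gen_rds))
    stop("generate stage: manifest present but its artifact is missing or ",
         "corrupt; delete ", file.path(outdir, "generate.manifest.json"),
         " and rerun the pipeline")
  if (done) {
    say("generate: up to date, skipping")
    gen <- readRDS(gen_rds)
  } else {
    say("generate: phantom volume, curve, study table")
    tspec <- do.call(tibia_spec, c(config$phantom, list(seed = config$seed)))
    tib <- generate_full_tibia(tspec)
    curve <- generate_curve(curve_spec(noise_sd = 0.5, seed = config$seed + 1L))
    design <- study_design(
      groups = data.frame(name = c("control", "sham", "low", "medium", "high"),
                          n_animals = rep(config$study$n_per_group, 5)),
      timepoints = config$study$timepoints, seed = config$seed + 2L)
    study <- generate_study(design)
    write_volume(tib$volume, file.path(outdir, "phantom.tiff"))
    write_curve(curve, file.path(outdir, "curve.csv"))
    write_study(study, file.path(outdir, "study.csv"))
    gen <- list(tibia = tib, curve = curve, study = study)
    saveRDS(gen, gen_rds)
    .write_manifest(outdir, "generate", hash,
                    c("phantom.tiff", "curve.csv", "study.csv"), t0)
  }
  bundle$generate <- gen

  # -- morphometry -------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  mor_rds <- file.path(outdir, "morphometry.rds")
  done <- .stage_done(outdir, "morphometry", hash)
  if (done && !file.exists(mor_rds))
    stop("morphometry stage: manifest present but its artifact is missing or ",
         "corrupt; delete ", file.path(outdir, "morphometry.manifest.json"),
         " and rerun the pipeline")
  if (done) {
    say("morphometry: up to date, skipping")
    mor <- readRDS(mor_rds)
  } else {
    say("morphometry: segmenting and measuring")
    vol <- gen$tibia$volume
    mask <- segment_threshold(vol, consts$threshold_grayscale)
    pmap <- fit_phantom_map(mean(vol$data[gen$tibia$labels$insert_low]),
                            mean(vol$data[gen$tibia$labels$insert_high]))
    tvoi <- locate_trabecular_voi(vol, config$voi$offset_mm, config$voi$trab_fraction)
    cvoi <- locate_cortical_voi(vol, config$voi$cort_fraction)
    split <- exclude_cortical_shell(mask, tvoi, vol$voxel_size,
                                    config$voi$r_close_mm)
    trab <- trabecular_metrics(vol, split$trab_mask, tvoi, pmap)
    cort <- cortical_metrics(vol, mask, cvoi, pmap)
    tab <- rbind(metrics_to_table(trab, "phantom"),
                 metrics_to_table(cort, "phantom"))
    write.csv(tab, file.path(outdir, "morphometry.csv"), row.names = FALSE)
    mor <- list(trabecular = trab, cortical = cort, phantom_map = pmap,
                trab_voi = tvoi, cort_voi = cvoi, mask = mask,
                trab_mask = split$trab_mask)
    saveRDS(mor, mor_rds)
    .write_manifest(outdir, "morphometry", hash, "morphometry.csv", t0)
  }
  bundle$morphometry <- mor

  # -- fe ----------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  fe_rds <- file.path(outdir, "fe.rds")
  done <- .stage_done(outdir, "fe", hash)
  if (done && !file.exists(fe_rds))
    stop("fe stage: manifest present but its artifact is missing or ",
         "corrupt; delete ", file.path(outdir, "fe.manifest.json"),
         " and rerun the pipeline")
  if (done) {
    say("fe: up to date, skipping")
    fe <- readRDS(fe_rds)
  } else {
    say("fe: meshing and solving the %g-N compression", config$fe$force_N)
    model <- build_mesh(gen$tibia$volume, consts, config$fe$occupancy)
    model <- apply_compression(model, config$fe$force_N, config$fe$bc)
    sol <- solve_fe(model, tol = config$fe$tol)
    strains <- element_strains(model, sol$u)
    fe <- list(
      trabecular = strain_summary(strains, fe_voi_elements(model, mor$trab_voi)),
      cortical = strain_summary(strains, fe_voi_elements(model, mor$cort_voi)),
      iterations = sol$iterations, n_elements = nrow(model$e2n))
    write_mesh_vtk(model, file.path(outdir, "mesh.vtk"))
    jsonlite::write_json(fe, file.path(outdir, "fe_strains.json"),
                         auto_unbox = TRUE, digits = NA)
    saveRDS(fe, fe_rds)
    .write_manifest(outdir, "fe", hash, c("mesh.vtk", "fe_strains.json"), t0)
  }
  bundle$fe <- fe

  # -- bend --------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  say("bend: deriving the bending property set")
  L <- gen$tibia$landmarks$total_length_L
  bend <- analyze_bending_curve(
    gen$curve, span_from_length(L),
    I = mor$cortical$I_min, c_max = mor$cortical$c_max,
    b_ap = mor$cortical$b_ap,
    yield_threshold = config$bending$yield_threshold,
    stiffness_window = config$bending$stiffness_window)
  write.csv(as.data.frame(unclass(bend)), file.path(outdir, "bending.csv"),
            row.names = FALSE)
  .write_manifest(outdir, "bend", hash, "bending.csv", t0)
  bundle$bend <- bend

  # -- stats -------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  say("stats: repeated-measures comparison")
  bundle$stats <- compare_groups(gen$study, sham = config$stats$sham,
                                 alpha = config$stats$alpha)
  .write_manifest(outdir, "stats", hash, character(), t0)

  say("pipeline complete")
  invisible(bundle)
}

#' Summary tables from a pipeline bundle
#'
#' Deterministically ordered tables: the morphometric parameter sets, the
#' per-VOI strain summary, the bending property set (with its standard
#' column names), and the group mean/SD table with vs-sham flags.
#'
#' @param bundle result of \code{\link{run_pipeline}}.
#' @return named list of data.frames.
#' @export
pipeline_report <- function(bundle) {
  if (is.null(bundle) || is.null(bundle$morphometry))
    stop("pipeline_report: empty or incomplete bundle")
  bend <- bundle$bend
  bend_tab <- data.frame(
    `Yield force, F_y (N)` = bend$F_y,
    `Ultimate force, F_ult (N)` = bend$F_ult,
    `Stiffness, k (N/mm)` = bend$k,
    `Postyield displacement (mm)` = bend$PYD,
    `Work to yield (mJ)` = bend$W_y,
    `Postyield energy (mJ)` = bend$PYE,
    `Work to failure (mJ)` = bend$W_fail,
    `Yield stress (MPa)` = bend$sigma_y,
    `Ultimate stress (MPa)` = bend$sigma_ult,
    `Young's modulus, E (GPa)` = bend$E,
    `Strain to yield (ue)` = bend$strain_to_yield,
    `Strain to failure (ue)` = bend$strain_to_failure,
    `Resilience (MPa)` = bend$resilience,
    `Toughness (MPa)` = bend$toughness,
    check.names = FALSE)
  strain_tab <- data.frame(
    voi = c("trabecular", "cortical"),
    mean_tensile_ue = c(bundle$fe$trabecular$mean_tensile,
                        bundle$fe$cortical$mean_tensile),
    mean_compressive_ue = c(bundle$fe$trabecular$mean_compressive,
                            bundle$fe$cortical$mean_compressive))
  morpho <- rbind(metrics_to_table(bundle$morphometry$trabecular, "phantom"),
                  metrics_to_table(bundle$morphometry$cortical, "phantom"))
  morpho <- morpho[order(morpho$parameter), ]
  study_sum <- summarize_groups(bundle$generate$study)
  vs_sham <- do.call(rbind, lapply(names(bundle$stats), function(p) {
    v <- bundle$stats[[p]]$vs_sham
    v$parameter <- p
    v[order(v$group, v$week), ]
  }))
  list(morphometry = morpho, fe_strains = strain_tab,
       bending = bend_tab, group_summary = study_sum, vs_sham = vs_sham)
}
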