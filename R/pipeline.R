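#' Run the full synthetic-cohort conductivity pipeline
#'
#' Chains every stage: phantom atlas construction, high-frequency
#' conductivity assignment, synthetic cohort generation per model,
#' microstructure-to-CTI conversion, low-frequency conductivity, per-ROI
#' cohort tables with normality screening, and the TOST equivalence roster.
#' All outputs land under \code{out_dir}:
#' \itemize{
#'   \item \code{atlas/} — tissue and ROI label volumes + ROI dictionary
#'   \item \code{sigma_h.nii.gz}, \code{sigma_h.json} — the high-frequency
#'     conductivity volume and its per-class provenance
#'   \item \code{<model>/cohort_table.csv}, \code{normality.csv},
#'     \code{boxplot_summary.json} and (optionally) per-subject volumes
#'   \item \code{equivalence.csv}, \code{verdicts.json} — roster results and
#'     the pair x model verdict matrix
#'   \item \code{manifest.json} — configuration echo, all numeric constants,
#'     interpretation notices and the config hash
#' }
#' Outputs are deterministic given the configuration (including its seed).
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created; must not exist or be empty).
#' @return invisibly, a list with the in-memory results (\code{atlas},
#'   \code{sigma_h}, \code{tables}, \code{equivalence}, \code{out_dir}).
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0) {
    stop("run_pipeline: output directory exists and is not empty: ", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("run_pipeline: stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  for (msg in cti_interpretation_notices()) message("note: ", msg)

  atlas <- stage("atlas", build_default_atlas(cfg$grid_shape, cfg$voxel_mm))
  write_atlas(atlas, file.path(out_dir, "atlas"))

  sigma_h <- stage("sigma_h",
                   build_sigma_h(atlas, cfg$frequency, cfg$sigma_h_overrides))
  write_volume(sigma_h$sigma_h, file.path(out_dir, "sigma_h.nii.gz"),
               pixdim = atlas$grid$voxel_mm, origin = atlas$grid$origin)
  jsonlite::write_json(
    list(frequency_hz = sigma_h$frequency,
         per_class_S_per_m = as.list(sigma_h$per_class)),
    file.path(out_dir, "sigma_h.json"), auto_unbox = TRUE, digits = NA)

  config <- cti_config(beta = cfg$beta)
  tables <- list()
  for (model in cfg$models) {
    mdir <- file.path(out_dir, model)
    dir.create(mdir, showWarnings = FALSE)
    asym <- cfg$asymmetry
    if (!is.null(asym) && !is.null(names(asym))) {
      asym <- asym[[model]]
    }
    spec <- stage(paste0(model, ":spec"),
                  cohort_spec(model, cfg$n_subjects, cfg$seed,
                              asymmetry = asym,
                              grid_shape = cfg$grid_shape))
    cohort <- stage(paste0(model, ":cohort"), generate_cohort(spec, atlas))
    if (isTRUE(cfg$write_volumes)) {
      stage(paste0(model, ":volumes"),
            write_cohort_volumes(cohort, atlas, sigma_h, config, mdir,
                                 scaling = cfg$noddi_scaling))
    }
    tab <- stage(paste0(model, ":table"), {
      if (model == "noddi") {
        cohort_table(cohort, atlas, sigma_h, config,
                     scaling = cfg$noddi_scaling)
      } else {
        cohort_table(cohort, atlas, sigma_h, config)
      }
    })
    write.csv(tab, file.path(mdir, "cohort_table.csv"), row.names = FALSE)
    write.csv(screen_normality(tab, cfg$alpha),
              file.path(mdir, "normality.csv"), row.names = FALSE)
    jsonlite::write_json(boxplot_summary(tab),
                         file.path(mdir, "boxplot_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    tables[[model]] <- tab
  }

  all_tab <- do.call(rbind, tables)
  equiv <- stage("equivalence",
                 run_comparison_roster(all_tab, default_roster(),
                                       bounds = cfg$bounds,
                                       alpha = cfg$alpha))
  write.csv(equiv, file.path(out_dir, "equivalence.csv"), row.names = FALSE)
  verdicts <- lapply(split(equiv, paste(equiv$roi_a, "vs", equiv$roi_b)),
                     function(g) {
                       stats::setNames(lapply(seq_len(nrow(g)), function(i) {
                         list(equivalent = g$equivalent[i],
                              different = g$different[i])
                       }), g$model)
                     })
  jsonlite::write_json(verdicts, file.path(out_dir, "verdicts.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    package = "ctimaps",
    version = as.character(packageVersion("ctimaps")),
    config_hash = unname(tools::md5sum(cfg_path)),
    constants = list(
      d_par_mm2_s = 1.7e-3, d_iso_mm2_s = 3.0e-3, Dis_mm2_s = 3.0e-3,
      decw_mm2_s = 3.0e-3, beta = cfg$beta,
      frequency_hz = cfg$frequency,
      sigma_h_per_class = as.list(sigma_h$per_class)
    ),
    interpretation_notices = cti_interpretation_notices()
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(atlas = atlas, sigma_h = sigma_h, tables = tables,
                 equivalence = equiv, out_dir = out_dir))
}

# per-subject NIfTI outputs: parameter maps, CTI maps and sigma_L
write_cohort_volumes <- function(cohort, atlas, sigma_h, config, dir,
                                 scaling = "paper") {
  geom <- list(pixdim = atlas$grid$voxel_mm, origin = atlas$grid$origin)
  for (subj in names(cohort$subjects)) {
    sdir <- file.path(dir, subj)
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    params <- cohort$subjects[[subj]]
    for (p in names(params)) {
      write_volume(params[[p]], file.path(sdir, paste0(p, ".nii.gz")),
                   pixdim = geom$pixdim, origin = geom$origin)
    }
    cti <- if (cohort$model == "noddi") {
      cti_from_params(params, cohort$model, scaling = scaling)
    } else {
      cti_from_params(params, cohort$model)
    }
    sig <- sigma_low(cti, sigma_h, config)
    for (p in c("alpha", "di", "de")) {
      write_volume(cti[[p]], file.path(sdir, paste0("cti_", p, ".nii.gz")),
                   pixdim = geom$pixdim, origin = geom$origin)
    }
    write_volume(sig$sigma_L, file.path(sdir, "sigma_L.nii.gz"),
                 pixdim = geom$pixdim, origin = geom$origin)
    write_volume(array(as.integer(sig$valid_mask), dim(sig$sigma_L)),
                 file.path(sdir, "valid_mask.nii.gz"),
                 pixdim = geom$pixdim, origin = geom$origin,
                 datatype = "int16")
  }
  invisible(dir)
}
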