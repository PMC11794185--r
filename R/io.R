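#' Read a 3-D parameter volume from NIfTI
#'
#' Reads a single 3-D NIfTI image into a plain numeric array, keeping the
#' grid geometry (voxel size and origin) as attributes.
#'
#' @param path path to a .nii or .nii.gz file.
#' @return numeric 3-D array with attributes \code{pixdim} and \code{origin}.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3) {
    stop("read_volume: expected a 3-D volume, got shape ",
         paste(dm, collapse = "x"), " in ", path)
  }
  xf <- RNifti::xform(img)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dm)
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  attr(arr, "origin") <- unname(xf[1:3, 4])
  arr
}

#' Write a 3-D volume to NIfTI
#'
#' @param vol numeric or integer 3-D array; \code{pixdim}/\code{origin}
#'   attributes (as set by [read_volume()]) are honored if present.
#' @param path output path (.nii or .nii.gz).
#' @param pixdim voxel dimensions in mm.
#' @param origin world coordinate of the first voxel.
#' @param datatype NIfTI storage type; "double" preserves values exactly.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path, pixdim = attr(vol, "pixdim"),
                         origin = attr(vol, "origin"),
                         datatype = "double") {
  if (length(dim(vol)) != 3) {
    stop("write_volume: expected a 3-D volume, got shape ",
         paste(dim(vol), collapse = "x"))
  }
  if (is.null(pixdim)) pixdim <- c(1, 1, 1)
  if (is.null(origin)) origin <- c(0, 0, 0)
  arr <- vol
  attributes(arr) <- list(dim = dim(vol))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pixdim
  xf <- rbind(cbind(diag(pixdim), origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Check that two volumes share a grid
#'
#' Raises an alignment error when dimensions, voxel sizes or origins differ;
#' used before any voxelwise combination of volumes read from disk.
#'
#' @param a,b arrays as returned by [read_volume()].
#' @param what label used in the error message.
#' @return TRUE, invisibly.
#' @export
assert_aligned <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    stop("alignment error: ", what, " have different shapes (",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), ")")
  }
  pa <- attr(a, "pixdim"); pb <- attr(b, "pixdim")
  oa <- attr(a, "origin"); ob <- attr(b, "origin")
  if (!is.null(pa) && !is.null(pb) && !isTRUE(all.equal(pa, pb))) {
    stop("alignment error: ", what, " have different voxel sizes")
  }
  if (!is.null(oa) && !is.null(ob) && !isTRUE(all.equal(oa, ob))) {
    stop("alignment error: ", what, " have different origins")
  }
  invisible(TRUE)
}

#' Write a tissue atlas to disk
#'
#' Tissue labels and ROI labels as integer NIfTI volumes plus the ROI
#' dictionary as CSV (columns code, name, tissue, pair_code).
#'
#' @param atlas a \code{tissue_atlas}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geom <- list(pixdim = atlas$grid$voxel_mm, origin = atlas$grid$origin)
  write_volume(atlas$labels, file.path(dir, "tissue_labels.nii.gz"),
               pixdim = geom$pixdim, origin = geom$origin, datatype = "int16")
  write_volume(atlas$roi_labels, file.path(dir, "roi_labels.nii.gz"),
               pixdim = geom$pixdim, origin = geom$origin, datatype = "int16")
  write.csv(atlas$roi_table, file.path(dir, "roi_table.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a tissue atlas written by [write_atlas()]
#'
#' @param dir directory containing tissue_labels.nii.gz, roi_labels.nii.gz
#'   and roi_table.csv.
#' @return a \code{tissue_atlas}.
#' @export
read_atlas <- function(dir) {
  labels <- read_volume(file.path(dir, "tissue_labels.nii.gz"))
  roi_labels <- read_volume(file.path(dir, "roi_labels.nii.gz"))
  assert_aligned(labels, roi_labels, "atlas label volumes")
  roi_table <- read.csv(file.path(dir, "roi_table.csv"),
                        stringsAsFactors = FALSE)
  grid <- list(shape = dim(labels), voxel_mm = attr(labels, "pixdim"),
               origin = attr(labels, "origin"))
  lab <- array(as.integer(labels), dim = dim(labels))
  rlab <- array(as.integer(roi_labels), dim = dim(roi_labels))
  structure(list(labels = lab, roi_labels = rlab, roi_table = roi_table,
                 grid = grid),
            class = "tissue_atlas")
}

#' Assemble and validate a pipeline configuration
#'
#' @param models character vector of microstructure models to run.
#' @param n_subjects cohort size per model.
#' @param seed master seed for the synthetic cohorts.
#' @param beta intracellular/extracellular ionic concentration ratio.
#' @param frequency high-frequency conductivity evaluation frequency, Hz.
#' @param bounds TOST equivalence bounds, S/m.
#' @param alpha level of the equivalence and difference tests.
#' @param grid_shape phantom grid (voxel counts).
#' @param voxel_mm voxel size, mm.
#' @param noddi_scaling "paper" or "canonical" NODDI tortuosity convention.
#' @param sigma_h_overrides optional named per-class conductivity overrides.
#' @param asymmetry optional asymmetry injection list (see [cohort_spec()]),
#'   or a single-model list applied to every model via [example_asymmetry()]
#'   semantics; pass a named list (names = models) for per-model injections.
#' @param write_volumes write per-subject NIfTI volumes (parameter maps,
#'   CTI maps, sigma_L) under the run directory; off by default because the
#'   tables and verdicts are the analysis products.
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(models = c("noddi", "sandi", "smt"),
                       n_subjects = 30, seed = 1, beta = 0.41,
                       frequency = 128e6, bounds = c(-0.05, 0.05),
                       alpha = 0.05, grid_shape = c(64L, 64L, 64L),
                       voxel_mm = 2, noddi_scaling = c("paper", "canonical"),
                       sigma_h_overrides = NULL, asymmetry = NULL,
                       write_volumes = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  noddi_scaling <- match.arg(noddi_scaling)
  stopifnot(is.numeric(beta), length(beta) == 1, beta > 0,
            is.numeric(frequency), frequency > 0,
            length(bounds) == 2, bounds[1] < bounds[2],
            alpha > 0, alpha < 0.5, n_subjects >= 1)
  if (!is.null(asymmetry) && !is.null(names(asymmetry))) {
    unknown <- setdiff(names(asymmetry), models)
    if (length(unknown) > 0) {
      stop("run_config: asymmetry given for model(s) not being run: ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(models = models, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), beta = beta, frequency = frequency,
                 bounds = bounds, alpha = alpha,
                 grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
                 noddi_scaling = noddi_scaling,
                 sigma_h_overrides = sigma_h_overrides,
                 asymmetry = asymmetry, write_volumes = write_volumes),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file must provide at least \code{models}, \code{n_subjects},
#' \code{seed} and \code{beta}; all other fields take the [run_config()]
#' defaults. Unknown fields are a schema error.
#'
#' @param path YAML file.
#' @return a \code{run_config}.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("models", "n_subjects", "seed", "beta")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop("read_config: schema error, missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  unknown <- setdiff(names(cfg), names(formals(run_config)))
  if (length(unknown) > 0) {
    stop("read_config: schema error, unknown field(s): ",
         paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$bounds)) cfg$bounds <- as.numeric(cfg$bounds)
  if (!is.null(cfg$grid_shape)) cfg$grid_shape <- as.integer(cfg$grid_shape)
  do.call(run_config, cfg)
}
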