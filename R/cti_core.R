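#' CTI conversion configuration
#'
#' @param beta ratio of intracellular to extracellular ionic concentrations
#'   (dimensionless, > 0). The value is not identifiable from diffusion data
#'   alone; 0.41 follows the CTI literature this conversion builds on and is
#'   recorded in every run's provenance.
#' @param denominator_floor smallest admissible value of
#'   \eqn{\alpha d_e + \beta(1-\alpha)d_i} (mm^2/s) before a voxel is masked
#'   rather than allowed to produce an arbitrarily large conductivity.
#' @return list of class \code{cti_config}.
#' @export
cti_config <- function(beta = 0.41, denominator_floor = 1e-12) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta > 0,
            is.numeric(denominator_floor), denominator_floor >= 0)
  structure(list(beta = beta, denominator_floor = denominator_floor),
            class = "cti_config")
}

#' Effective low-frequency conductivity
#'
#' Computes the position-wise scale factor
#' \deqn{\eta = \frac{\alpha\,\sigma_H}{\alpha d_e + \beta(1-\alpha)d_i}}
#' and the effective isotropic low-frequency conductivity
#' \eqn{\sigma_L = \eta\,d_e}. Voxels whose denominator falls below the
#' configured floor, whose CTI inputs are masked, or whose \eqn{\sigma_H} is
#' zero (background) get \eqn{\sigma_L = 0} and are excluded from downstream
#' statistics via the validity mask. On valid voxels
#' \eqn{0 \le \sigma_L \le \sigma_H} always holds, with equality when
#' \eqn{\alpha = 1} or \eqn{d_i = 0}.
#'
#' @param cti a [cti_maps()] object.
#' @param sigma_h a \code{sigma_h_atlas} (see [build_sigma_h()]) or a numeric
#'   array of high-frequency conductivities aligned with \code{cti}.
#' @param config a [cti_config()].
#' @return object of class \code{conductivity_volume} with fields
#'   \code{sigma_L}, \code{eta}, \code{valid_mask} and \code{model}.
#' @export
#' @examples
#' m <- noddi_to_cti(0.7, 0.5, 0.1)
#' sigma_low(m, 0.5864)$sigma_L # 0.4874
sigma_low <- function(cti, sigma_h, config = cti_config()) {
  stopifnot(inherits(cti, "cti_maps"), inherits(config, "cti_config"))
  sh <- if (inherits(sigma_h, "sigma_h_atlas")) sigma_h$sigma_h else sigma_h
  if (length(sh) == 1) sh <- rep(sh, length(cti$alpha))
  if (!is.null(dim(cti$alpha)) && !is.null(dim(sh)) &&
      !identical(dim(cti$alpha), dim(sh))) {
    stop("sigma_low: grid mismatch between CTI maps (",
         paste(dim(cti$alpha), collapse = "x"), ") and sigma_h (",
         paste(dim(sh), collapse = "x"), ")")
  }
  if (length(sh) != length(cti$alpha)) {
    stop("sigma_low: grid mismatch (", length(cti$alpha), " vs ",
         length(sh), " voxels)")
  }
  den <- cti$alpha * cti$de + config$beta * (1 - cti$alpha) * cti$di
  valid <- cti$valid_mask & !is.na(den) & den >= config$denominator_floor &
    !is.na(sh) & sh > 0
  eta <- ifelse(valid, cti$alpha * sh / den, 0)
  sigma_L <- ifelse(valid, eta * cti$de, 0)
  dm <- dim(cti$alpha)
  if (!is.null(dm)) {
    dim(eta) <- dm; dim(sigma_L) <- dm; dim(valid) <- dm
  }
  structure(list(sigma_L = sigma_L, eta = eta, valid_mask = valid,
                 model = cti$model, beta = config$beta),
            class = "conductivity_volume")
}

#' @export
print.conductivity_volume <- function(x, ...) {
  v <- x$sigma_L[x$valid_mask]
  cat(sprintf(
    "<conductivity_volume> model=%s, beta=%.3g, %d valid voxels, median sigma_L %.4f S/m\n",
    x$model, x$beta, length(v), if (length(v)) median(v) else NA_real_))
  invisible(x)
}
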