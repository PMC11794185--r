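#' Dawson integral
#'
#' Evaluates \eqn{D(x) = e^{-x^2} \int_0^x e^{t^2} dt =
#' (\sqrt{\pi}/2) e^{-x^2} \mathrm{erfi}(x)}, the kernel of the Watson
#' orientation-coherence integral. Fully vectorized: the Maclaurin series
#' \eqn{D(x) = \sum_n (-2x^2)^n x/(2n+1)!!} is used for |x| < 4.5 and the
#' asymptotic expansion
#' \eqn{D(x) \sim \frac{1}{2x}\sum_k (2k-1)!!/(2x^2)^k}, truncated at its
#' smallest term, beyond. Worst-case absolute error is ~2e-9 at the branch
#' point (cancellation in the alternating series on one side, the optimal
#' asymptotic truncation error \eqn{\sim e^{-x^2}} on the other) and below
#' 1e-12 elsewhere; accuracy is verified against a quadrature oracle in the
#' test suite.
#'
#' @param x numeric vector.
#' @return numeric vector, \code{D(x)}.
#' @export
#' @examples
#' dawson_fn(1) # 0.5380795...
dawson_fn <- function(x) {
  out <- numeric(length(x))
  out[is.na(x)] <- NA_real_
  ax <- abs(x)
  small <- !is.na(x) & ax < 4.5
  if (any(small)) {
    xs <- ax[small]
    u <- -2 * xs^2
    term <- xs
    s <- xs
    for (n in 1:70) {
      term <- term * u / (2 * n + 1)
      s <- s + term
    }
    out[small] <- s
  }
  large <- !is.na(x) & !small
  if (any(large)) {
    xl <- ax[large]
    u <- 1 / (2 * xl^2)
    term <- rep(1, length(xl))
    s <- term
    for (k in 1:30) {
      new_term <- term * (2 * k - 1) * u
      # asymptotic series: stop each element at its smallest term
      grown <- abs(new_term) >= abs(term)
      new_term[grown] <- 0
      term <- new_term
      s <- s + term
    }
    out[large] <- s / (2 * xl)
  }
  out * sign(x)
}

#' Watson concentration parameter from the orientation dispersion index
#'
#' The orientation dispersion index (ODI) of the NODDI model maps to the
#' Watson-distribution concentration parameter through
#' \eqn{\kappa = 1/\tan(\pi\,\mathrm{ODI}/2)}. ODI = 1 corresponds to fully
#' dispersed sticks (\eqn{\kappa = 0}); ODI \eqn{\to 0} corresponds to
#' perfectly coherent sticks (\eqn{\kappa \to \infty}); the returned value is
#' capped at \code{kappa_cap} so that ODI = 0 maps to a large finite
#' concentration (the coherence \eqn{\tau} there equals 1 to well below
#' display precision).
#'
#' @param odi numeric vector in \[0, 1\].
#' @param kappa_cap upper cap applied to the returned concentration.
#' @return numeric vector of concentrations \eqn{\kappa \ge 0}.
#' @export
#' @examples
#' kappa_from_odi(0.5) # 1
kappa_from_odi <- function(odi, kappa_cap = 1e6) {
  bad <- !is.na(odi) & (odi < 0 | odi > 1)
  if (any(bad)) {
    stop("kappa_from_odi: ODI outside [0, 1] (first offending value ",
         format(odi[bad][1]), ")")
  }
  kap <- ifelse(odi == 0, kappa_cap, 1 / tan(pi * odi / 2))
  pmin(pmax(kap, 0), kappa_cap)
}

#' Orientation dispersion index from the Watson concentration parameter
#'
#' Inverse of [kappa_from_odi()]: \eqn{\mathrm{ODI} = (2/\pi)\arctan(1/\kappa)}.
#'
#' @param kappa numeric vector of concentrations, \eqn{\kappa \ge 0}.
#' @return numeric vector of ODI values in \[0, 1\].
#' @export
odi_from_kappa <- function(kappa) {
  if (any(!is.na(kappa) & kappa < 0)) stop("odi_from_kappa: negative concentration")
  (2 / pi) * atan2(1, kappa)
}

#' Watson orientation coherence
#'
#' Computes \eqn{\tau(\kappa) = E[\cos^2\theta]} under the Watson axial
#' density \eqn{\propto e^{\kappa\cos^2\theta}\sin\theta}, the coherence
#' factor entering the NODDI extracellular tortuosity model. In closed form
#' \deqn{\tau(\kappa) = -\frac{1}{2\kappa} +
#'   \frac{1}{2\sqrt{\kappa}\,D(\sqrt{\kappa})}}
#' with \eqn{D} the Dawson integral ([dawson_fn()]). \eqn{\tau} increases
#' monotonically from 1/3 (isotropic dispersion, \eqn{\kappa = 0}) to 1
#' (perfectly aligned sticks, \eqn{\kappa \to \infty}).
#'
#' @param kappa numeric vector, \eqn{\kappa \ge 0}.
#' @return numeric vector of coherences in \[1/3, 1\].
#' @export
#' @examples
#' tau_from_kappa(1) # 0.4292307...
tau_from_kappa <- function(kappa) {
  if (any(!is.na(kappa) & kappa < 0)) stop("tau_from_kappa: negative concentration")
  out <- rep(NA_real_, length(kappa))
  tiny <- !is.na(kappa) & kappa < 1e-7
  # series about kappa = 0: tau = 1/3 + 4 kappa/45 + O(kappa^2); avoids the
  # 1/(2 kappa) cancellation at extreme arguments
  out[tiny] <- 1 / 3 + 4 * kappa[tiny] / 45
  ok <- !is.na(kappa) & !tiny
  if (any(ok)) {
    k <- kappa[ok]
    x <- sqrt(k)
    out[ok] <- -1 / (2 * k) + 1 / (2 * x * dawson_fn(x))
  }
  pmin(pmax(out, 1 / 3), 1)
}

clip_param <- function(x, lower, upper, name) {
  bad <- !is.na(x) & (x < lower | x > upper)
  n_bad <- sum(bad)
  if (n_bad > 0) {
    warning(sprintf("%s: %d value(s) outside [%g, %g] clipped", name, n_bad,
                    lower, upper), call. = FALSE)
    x <- pmin(pmax(x, lower), upper)
  }
  x
}

#' Construct a CTI map set
#'
#' Container for the common currency of all microstructure-to-conductivity
#' conversions: the extracellular volume fraction \code{alpha}, the
#' orientation-averaged intracellular diffusivity \code{di} and extracellular
#' diffusivity \code{de} (both mm^2/s), plus a validity mask. Masked voxels
#' are excluded from all downstream statistics.
#'
#' @param alpha,di,de numeric arrays (or vectors) of matching shape.
#' @param valid_mask logical array of the same shape.
#' @param model character tag recording the source model.
#' @return an object of class \code{cti_maps}.
#' @export
cti_maps <- function(alpha, di, de, valid_mask, model = "unknown") {
  stopifnot(length(alpha) == length(di), length(di) == length(de),
            length(de) == length(valid_mask))
  structure(list(alpha = alpha, di = di, de = de,
                 valid_mask = valid_mask, model = model),
            class = "cti_maps")
}

#' @export
print.cti_maps <- function(x, ...) {
  n <- length(x$alpha)
  cat(sprintf("<cti_maps> model=%s, %d voxels (%d valid)\n",
              x$model, n, sum(x$valid_mask)))
  invisible(x)
}

#' Convert NODDI parameter maps to CTI quantities
#'
#' Maps the NODDI parameters (neurite fraction \code{fi}, orientation
#' dispersion index \code{odi}, isotropic fraction \code{fiso}) to the CTI
#' triplet (alpha, di, de). The intracellular stick population carries
#' parallel diffusivity \eqn{d_{i\parallel} = f_i(1-f_{iso})\,d_\parallel}
#' and zero perpendicular diffusivity, so \eqn{d_i = d_{i\parallel}/3}. The
#' extracellular matrix is tortuosity-scaled by the Watson coherence
#' \eqn{\tau}:
#' \deqn{d_{e\parallel} = d_{i\parallel}(1 - f_i(1-\tau)), \quad
#'       d_{e\perp} = d_{i\parallel}(1 - f_i(1+\tau)/2)}
#' and the matrix mean is \eqn{d_{ecm} = (d_{e\parallel}+2d_{e\perp})/3}.
#' The extracellular fraction is \eqn{\alpha = f_{iso}+(1-f_{iso})(1-f_i)}
#' and the total extracellular diffusivity mixes the matrix with free water:
#' \deqn{d_e = \frac{(1-f_{iso})(1-f_i)\,d_{ecm} + f_{iso}\,d_{iso}}
#'   {f_{iso} + (1-f_i)(1-f_{iso})}.}
#' Voxels where that denominator vanishes (pure intracellular voxels,
#' \code{fi = 1, fiso = 0}) are masked.
#'
#' \code{scaling = "paper"} scales the parallel diffusivity by
#' \code{fi*(1-fiso)} before the tortuosity step as above;
#' \code{"canonical"} uses the unscaled intrinsic \code{d_par} inside the
#' extracellular tortuosity expressions (the original NODDI convention) while
#' keeping \code{di} as the stick average \code{fi*(1-fiso)*d_par/3}.
#'
#' Out-of-range inputs are clipped to their physical range with a warning;
#' \code{NA} inputs propagate to the validity mask.
#'
#' @param fi,odi,fiso numeric arrays in \[0, 1\].
#' @param d_par intrinsic stick diffusivity, mm^2/s (default 1.7e-3).
#' @param d_iso free-water diffusivity, mm^2/s (default 3.0e-3).
#' @param scaling "paper" or "canonical" tortuosity convention.
#' @param kappa_cap concentration cap passed to [kappa_from_odi()].
#' @return a [cti_maps()] object.
#' @export
#' @examples
#' m <- noddi_to_cti(0.7, 0.5, 0.1)
#' c(m$alpha, m$di, m$de) # 0.37, 3.57e-4, 1.2277e-3
noddi_to_cti <- function(fi, odi, fiso, d_par = 1.7e-3, d_iso = 3.0e-3,
                         scaling = c("paper", "canonical"), kappa_cap = 1e6) {
  scaling <- match.arg(scaling)
  dm <- dim(fi)
  fi <- clip_param(fi, 0, 1, "fi")
  odi <- clip_param(odi, 0, 1, "odi")
  fiso <- clip_param(fiso, 0, 1, "fiso")

  kap <- kappa_from_odi(odi, kappa_cap = kappa_cap)
  tau <- tau_from_kappa(kap)

  di_par <- fi * (1 - fiso) * d_par
  di <- di_par / 3
  d_tort <- if (scaling == "paper") di_par else rep(d_par, length.out = length(fi))
  de_par <- d_tort - d_tort * fi * (1 - tau)
  de_perp <- d_tort - d_tort * fi * (1 + tau) / 2
  decm <- (de_par + 2 * de_perp) / 3

  alpha <- fiso + (1 - fiso) * (1 - fi)
  den <- fiso + (1 - fi) * (1 - fiso)
  valid <- !is.na(fi) & !is.na(odi) & !is.na(fiso) & den > 0
  de <- ifelse(valid, ((1 - fiso) * (1 - fi) * decm + fiso * d_iso) / den, 0)
  alpha[is.na(alpha)] <- 0
  di[is.na(di)] <- 0
  if (!is.null(dm)) {
    dim(alpha) <- dm; dim(di) <- dm; dim(de) <- dm; dim(valid) <- dm
  }
  cti_maps(alpha, di, de, valid, model = "noddi")
}

#' Convert SANDI parameter maps to CTI quantities
#'
#' The SANDI extracellular signal fraction maps directly to the
#' extracellular fraction, \eqn{\alpha = f_e}; the intracellular diffusivity
#' mixes the neurite and soma compartments,
#' \eqn{d_i = (1-f_e)(f_{in} D_{in} + (1-f_{in}) D_{is})} with the soma
#' diffusivity fixed at \eqn{D_{is} = 3\times10^{-3}} mm^2/s; and the
#' extracellular diffusivity is the fraction-weighted \eqn{d_e = f_e D_{ec}}.
#'
#' @param fe extracellular signal fraction in \[0, 1\].
#' @param fin intraneurite fraction of the intracellular space, \[0, 1\].
#' @param Din intraneurite diffusivity, mm^2/s.
#' @param Dec extracellular diffusivity, mm^2/s.
#' @param Dis soma diffusivity, mm^2/s (default 3e-3).
#' @return a [cti_maps()] object.
#' @export
#' @examples
#' m <- sandi_to_cti(0.5, 0.6, 2e-3, 1.5e-3)
#' c(m$alpha, m$di, m$de) # 0.5, 1.2e-3, 0.75e-3
sandi_to_cti <- function(fe, fin, Din, Dec, Dis = 3.0e-3) {
  dm <- dim(fe)
  fe <- clip_param(fe, 0, 1, "fe")
  fin <- clip_param(fin, 0, 1, "fin")
  Din <- clip_param(Din, 0, Inf, "Din")
  Dec <- clip_param(Dec, 0, Inf, "Dec")

  alpha <- fe
  di <- (1 - fe) * (fin * Din + (1 - fin) * Dis)
  de <- fe * Dec
  valid <- !is.na(alpha) & !is.na(di) & !is.na(de)
  alpha[!valid] <- 0; di[!valid] <- 0; de[!valid] <- 0
  if (!is.null(dm)) {
    dim(alpha) <- dm; dim(di) <- dm; dim(de) <- dm; dim(valid) <- dm
  }
  cti_maps(alpha, di, de, valid, model = "sandi")
}

#' Convert SMT parameter maps to CTI quantities
#'
#' The spherical mean technique resolves an intra-neurite fraction
#' \code{fin}, intrinsic diffusivity \code{Din} and extra-neurite microscopic
#' mean diffusivity \code{De}. The CTI associations are
#' \eqn{\alpha = 1 - f_{in}}, \eqn{d_i = f_{in} D_{in}} and
#' \eqn{d_e = D_e} (the extra-neurite mean diffusivity carried through
#' unchanged).
#'
#' @param fin intra-neurite volume fraction in \[0, 1\].
#' @param Din intrinsic diffusivity, mm^2/s.
#' @param De extra-neurite microscopic mean diffusivity, mm^2/s.
#' @return a [cti_maps()] object.
#' @export
#' @examples
#' m <- smt_to_cti(0.65, 2.0e-3, 1.1e-3)
#' c(m$alpha, m$di, m$de) # 0.35, 1.3e-3, 1.1e-3
smt_to_cti <- function(fin, Din, De) {
  dm <- dim(fin)
  fin <- clip_param(fin, 0, 1, "fin")
  Din <- clip_param(Din, 0, Inf, "Din")
  De <- clip_param(De, 0, Inf, "De")

  alpha <- 1 - fin
  di <- fin * Din
  de <- De
  valid <- !is.na(alpha) & !is.na(di) & !is.na(de)
  alpha[!valid] <- 0; di[!valid] <- 0; de[!valid] <- 0
  if (!is.null(dm)) {
    dim(alpha) <- dm; dim(di) <- dm; dim(de) <- dm; dim(valid) <- dm
  }
  cti_maps(alpha, di, de, valid, model = "smt")
}

#' Extracellular fraction and diffusivity from explicit compartments
#'
#' General two-compartment extracellular reduction used by the full CTI
#' signal model: given matrix and free-water extracellular fractions
#' (\code{fecm}, \code{fecw}), the intracellular fraction \code{fi} and the
#' matrix diffusivity \code{decm},
#' \deqn{\alpha = \frac{f_{ecm}+f_{ecw}}{f_{ecm}+f_{ecw}+f_i}, \quad
#'       d_e = \frac{f_{ecm}}{f_{ecm}+f_{ecw}} d_{ecm} +
#'             \frac{f_{ecw}}{f_{ecm}+f_{ecw}} d_{ecw}.}
#' The free-water diffusivity defaults to \eqn{3\times10^{-3}} mm^2/s.
#' Voxels with no extracellular content (\code{fecm + fecw = 0}) have an
#' undefined \code{de} and are masked (\code{de = NA}).
#'
#' @param fecm,fecw extracellular matrix / water fractions, >= 0.
#' @param fi intracellular fraction, >= 0.
#' @param decm extracellular matrix diffusivity, mm^2/s.
#' @param decw free-water diffusivity, mm^2/s (default 3e-3).
#' @return list with elements \code{alpha}, \code{de} and \code{valid_mask}.
#' @export
#' @examples
#' cti_alpha_de(0.3, 0.1, 0.6, 1.0e-3) # alpha 0.4, de 1.5e-3
cti_alpha_de <- function(fecm, fecw, fi, decm, decw = 3.0e-3) {
  if (any(!is.na(fecm) & fecm < 0) || any(!is.na(fecw) & fecw < 0) ||
      any(!is.na(fi) & fi < 0)) {
    stop("cti_alpha_de: compartment fractions must be nonnegative")
  }
  fec <- fecm + fecw
  tot <- fec + fi
  if (any(!is.na(tot) & tot == 0)) {
    stop("cti_alpha_de: all compartment fractions are zero")
  }
  alpha <- fec / tot
  valid <- !is.na(fec) & fec > 0
  de <- ifelse(valid, (fecm * decm + fecw * decw) / fec, NA_real_)
  list(alpha = alpha, de = de, valid_mask = valid)
}

#' Convert one subject's fitted parameter maps
#'
#' Dispatches a named list of parameter volumes to the adapter for
#' \code{model}. Expected names: NODDI \code{fi, odi, fiso}; SANDI
#' \code{fe, fin, Din, Dec}; SMT \code{fin, Din, De}.
#'
#' @param params named list of numeric arrays.
#' @param model one of "noddi", "sandi", "smt".
#' @param ... passed to the model adapter (e.g. \code{scaling}).
#' @return a [cti_maps()] object.
#' @export
cti_from_params <- function(params, model = c("noddi", "sandi", "smt"), ...) {
  model <- match.arg(model)
  need <- model_parameters(model)
  missing <- setdiff(need, names(params))
  if (length(missing) > 0) {
    stop("cti_from_params: missing parameter map(s): ",
         paste(missing, collapse = ", "))
  }
  switch(model,
    noddi = noddi_to_cti(params$fi, params$odi, params$fiso, ...),
    sandi = sandi_to_cti(params$fe, params$fin, params$Din, params$Dec, ...),
    smt   = smt_to_cti(params$fin, params$Din, params$De, ...)
  )
}

#' Parameter names required by each microstructure model
#'
#' @param model one of "noddi", "sandi", "smt".
#' @return character vector of parameter map names.
#' @export
model_parameters <- function(model = c("noddi", "sandi", "smt")) {
  model <- match.arg(model)
  switch(model,
    noddi = c("fi", "odi", "fiso"),
    sandi = c("fe", "fin", "Din", "Dec"),
    smt   = c("fin", "Din", "De")
  )
}

# physical range of each parameter (fractions vs diffusivities)
parameter_range <- function(param) {
  if (param %in% c("fi", "odi", "fiso", "fe", "fin")) c(0, 1) else c(0, Inf)
}
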