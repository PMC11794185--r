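# Independent oracles used across the suite.

# E[cos^2 theta] under the Watson axial density ~ exp(kappa cos^2 theta),
# by adaptive quadrature (exponent shifted by -kappa for stability).
watson_tau_quad <- function(kappa) {
  num <- integrate(function(th) cos(th)^2 * exp(kappa * (cos(th)^2 - 1)) *
                     sin(th), 0, pi, rel.tol = 1e-12)$value
  den <- integrate(function(th) exp(kappa * (cos(th)^2 - 1)) * sin(th),
                   0, pi, rel.tol = 1e-12)$value
  num / den
}

# Exact signed-rank p-values by exhaustive enumeration of all 2^n sign
# assignments (feasible for n <= ~15).
enum_signed_rank <- function(diffs, shift = 0) {
  d <- diffs - shift
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)
  p_greater <- mean(W >= V)
  p_less <- mean(W <= V)
  list(statistic = V, p_greater = p_greater, p_less = p_less,
       p_two_sided = min(1, 2 * min(p_greater, p_less)))
}

# Shared small atlas for cohort-level tests (built once per test run).
small_atlas <- local({
  atlas <- NULL
  function() {
    if (is.null(atlas)) atlas <<- build_default_atlas(c(48L, 48L, 48L))
    atlas
  }
})

# Fake single-ROI atlas + conductivity volume for ROI-statistics tests.
toy_atlas <- function(values_len = 5) {
  labels <- array(0L, c(4, 4, 4))
  roi_labels <- array(0L, c(4, 4, 4))
  labels[seq_len(values_len)] <- 2L
  roi_labels[seq_len(values_len)] <- 1L
  structure(list(labels = labels, roi_labels = roi_labels,
                 roi_table = data.frame(code = 1L, name = "toy_roi",
                                        tissue = "GM",
                                        pair_code = NA_integer_),
                 grid = list(shape = c(4L, 4L, 4L), voxel_mm = rep(1, 3),
                             origin = c(0, 0, 0))),
            class = "tissue_atlas")
}

toy_sigma <- function(values, mask = rep(TRUE, length(values))) {
  sigma_L <- array(0, c(4, 4, 4))
  valid <- array(FALSE, c(4, 4, 4))
  sigma_L[seq_along(values)] <- values
  valid[seq_along(values)] <- mask
  structure(list(sigma_L = sigma_L, eta = sigma_L, valid_mask = valid,
                 model = "toy", beta = 0.41),
            class = "conductivity_volume")
}
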