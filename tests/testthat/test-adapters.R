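test_that("Dawson integral matches quadrature across both branches", {
  dawson_quad <- function(x) {
    integrate(function(t) exp(t^2 - x^2), 0, x, rel.tol = 1e-13)$value
  }
  for (x in c(0.1, 0.5, 1, 2, 3.7, 4.4, 4.6, 4.9, 5.1, 8, 20)) {
    expect_lt(abs(dawson_fn(x) - dawson_quad(x)), 5e-9)
  }
  # frozen spot values (quadrature oracle, rel.tol 1e-13)
  expect_equal(dawson_fn(1), 0.5380795069127684, tolerance = 1e-12)
  expect_equal(dawson_fn(2), 0.3013403889237919, tolerance = 1e-12)
  expect_equal(dawson_fn(-1), -dawson_fn(1))
  expect_equal(dawson_fn(0), 0)
})

test_that("kappa_from_odi evaluates and caps the concentration", {
  expect_equal(kappa_from_odi(0.5), 1, tolerance = 1e-12)
  expect_equal(kappa_from_odi(1), 0, tolerance = 1e-10)
  expect_equal(kappa_from_odi(0.1), 6.313751514675044, tolerance = 1e-10)
  expect_equal(kappa_from_odi(0), 1e6)              # capped, no error
  expect_equal(kappa_from_odi(0, kappa_cap = 50), 50)
  expect_error(kappa_from_odi(-0.1), "ODI")
  expect_error(kappa_from_odi(1.5), "ODI")
})

test_that("kappa <-> odi round-trips and is strictly monotone", {
  odi <- seq(0.005, 0.995, by = 0.005)
  kap <- kappa_from_odi(odi)
  expect_true(all(diff(kap) < 0)) # strictly decreasing in odi
  expect_lt(max(abs(odi_from_kappa(kap) - odi)), 1e-10)
})

test_that("Watson coherence matches the quadrature oracle and its limits", {
  for (k in c(0.01, 0.1, 1, 3, 10, 50)) {
    expect_lt(abs(tau_from_kappa(k) - watson_tau_quad(k)), 1e-6)
  }
  expect_equal(tau_from_kappa(1), 0.429230705827751, tolerance = 1e-9)
  expect_equal(tau_from_kappa(0), 1 / 3)
  expect_lt(abs(tau_from_kappa(1e-4) - 1 / 3), 1e-3)
  expect_lt(abs(tau_from_kappa(1e4) - 1), 1e-3)
  kap <- 10^seq(-4, 4, length.out = 300)
  tau <- tau_from_kappa(kap)
  expect_true(all(diff(tau) >= 0))
  expect_true(all(tau >= 1 / 3 & tau <= 1))
  expect_error(tau_from_kappa(-1), "negative")
})

test_that("NODDI conversion reproduces the worked example and edge cases", {
  m <- noddi_to_cti(0.7, 0.5, 0.1)
  expect_equal(m$alpha, 0.37, tolerance = 1e-12)
  expect_equal(m$di, 0.357e-3, tolerance = 1e-12)
  expect_equal(m$de, 1.2276e-3, tolerance = 1e-4) # hand arithmetic, 4 s.f.
  expect_true(m$valid_mask)

  # isotropic-only voxel: all weight on free water
  iso <- noddi_to_cti(0.4, 0.3, 1)
  expect_equal(iso$alpha, 1)
  expect_equal(iso$di, 0)
  expect_equal(iso$de, 3.0e-3)

  # degenerate all-intracellular voxel is masked
  deg <- noddi_to_cti(1, 0.3, 0)
  expect_false(deg$valid_mask)
  expect_equal(deg$alpha, 0)

  # NA propagates to the mask
  na <- noddi_to_cti(c(0.5, NA), c(0.3, 0.3), c(0.1, 0.1))
  expect_equal(na$valid_mask, c(TRUE, FALSE))
})

test_that("NODDI canonical scaling uses the unscaled intrinsic diffusivity", {
  paper <- noddi_to_cti(0.6, 0.4, 0.1, scaling = "paper")
  canon <- noddi_to_cti(0.6, 0.4, 0.1, scaling = "canonical")
  expect_equal(canon$alpha, paper$alpha)
  expect_equal(canon$di, paper$di)
  # canonical extracellular matrix diffusivity is larger by 1/(fi(1-fiso))
  tau <- tau_from_kappa(kappa_from_odi(0.4))
  d_par <- 1.7e-3
  decm_canon <- (d_par * (1 - 0.6 * (1 - tau)) +
                   2 * d_par * (1 - 0.6 * (1 + tau) / 2)) / 3
  de_expect <- (0.9 * 0.4 * decm_canon + 0.1 * 3e-3) / (0.1 + 0.4 * 0.9)
  expect_equal(canon$de, de_expect, tolerance = 1e-12)
  expect_gt(canon$de, paper$de)
})

test_that("SANDI conversion reproduces the worked example and edge cases", {
  m <- sandi_to_cti(0.5, 0.6, 2e-3, 1.5e-3)
  expect_equal(m$alpha, 0.5)
  expect_equal(m$di, 1.2e-3, tolerance = 1e-12)
  expect_equal(m$de, 0.75e-3, tolerance = 1e-12)

  full <- sandi_to_cti(1, 0.5, 2e-3, 1.4e-3)
  expect_equal(full$alpha, 1)
  expect_equal(full$di, 0)
  expect_equal(full$de, 1.4e-3)

  none <- sandi_to_cti(0, 0.5, 2e-3, 1.4e-3)
  expect_equal(none$alpha, 0)
})

test_that("SMT conversion reproduces the worked example and edge cases", {
  m <- smt_to_cti(0.65, 2.0e-3, 1.1e-3)
  expect_equal(m$alpha, 0.35)
  expect_equal(m$di, 1.3e-3, tolerance = 1e-12)
  expect_equal(m$de, 1.1e-3)

  free <- smt_to_cti(0, 2e-3, 1.1e-3)
  expect_equal(free$alpha, 1)
  expect_equal(free$di, 0)
  expect_equal(free$de, 1.1e-3)

  stick <- smt_to_cti(1, 2e-3, 1.1e-3)
  expect_equal(stick$alpha, 0)
})

test_that("explicit-compartment reduction computes alpha and de", {
  r <- cti_alpha_de(0.3, 0.1, 0.6, 1.0e-3)
  expect_equal(r$alpha, 0.4)
  expect_equal(r$de, 1.5e-3, tolerance = 1e-12)

  expect_equal(cti_alpha_de(0.2, 0, 0.5, 1.3e-3)$de, 1.3e-3)
  expect_equal(cti_alpha_de(0.2, 0.2, 0.5, 1e-3, decw = 2e-3)$de, 1.5e-3)

  deg <- cti_alpha_de(0, 0, 0.5, 1e-3)
  expect_false(deg$valid_mask)
  expect_true(is.na(deg$de))

  expect_error(cti_alpha_de(0, 0, 0, 1e-3), "zero")
  expect_error(cti_alpha_de(-0.1, 0.2, 0.5, 1e-3), "nonnegative")
})

test_that("adapters preserve physical invariants on random voxels", {
  set.seed(42)
  n <- 5000
  fi <- runif(n); odi <- runif(n, 0.01, 1); fiso <- runif(n)
  fe <- runif(n); fin <- runif(n)
  Din <- runif(n, 0, 3e-3); Dec <- runif(n, 0, 3e-3); De <- runif(n, 0, 3e-3)
  for (m in list(noddi_to_cti(fi, odi, fiso),
                 sandi_to_cti(fe, fin, Din, Dec),
                 smt_to_cti(fin, Din, De))) {
    expect_true(all(m$alpha >= 0 & m$alpha <= 1))
    expect_true(all(m$di >= 0))
    expect_true(all(m$de >= 0))
  }
  # the two free-water mixing weights always sum to one when defined
  den <- fiso + (1 - fi) * (1 - fiso)
  ok <- den > 0
  w_sum <- ((1 - fiso[ok]) * (1 - fi[ok]) + fiso[ok]) / den[ok]
  expect_lt(max(abs(w_sum - 1)), 1e-12)
})

test_that("out-of-range inputs are clipped with a warning, not an error", {
  expect_warning(m <- smt_to_cti(c(1.2, 0.5), c(2e-3, 2e-3), c(1e-3, 1e-3)),
                 "clipped")
  expect_equal(m$alpha[1], 0) # fin clipped to 1
  expect_warning(noddi_to_cti(0.5, 0.3, -0.1), "fiso")
})

test_that("cti_from_params dispatches and validates parameter names", {
  p <- list(fin = 0.5, Din = 2e-3, De = 1.1e-3)
  m <- cti_from_params(p, "smt")
  expect_s3_class(m, "cti_maps")
  expect_equal(m$model, "smt")
  expect_error(cti_from_params(list(fin = 0.5), "smt"), "missing parameter")
  expect_equal(model_parameters("noddi"), c("fi", "odi", "fiso"))
})
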