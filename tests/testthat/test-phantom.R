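test_that("default atlas satisfies its structural invariants", {
  atlas <- build_default_atlas(c(64, 64, 64))
  tab <- atlas$roi_table
  expect_equal(anyDuplicated(tab$code), 0)
  expect_equal(anyDuplicated(tab$name), 0)
  # every ROI voxel has a tissue label, and the ROI's declared class
  for (i in seq_len(nrow(tab))) {
    lab <- atlas$labels[atlas$roi_labels == tab$code[i]]
    expect_true(all(lab == c(CSF = 1L, GM = 2L, WM = 3L)[[tab$tissue[i]]]),
                label = paste("tissue of", tab$name[i]))
  }
  # hippocampal subfields are gray matter
  hc <- tab[grepl("hippocampus", tab$name), ]
  expect_equal(nrow(hc), 6)
  expect_true(all(hc$tissue == "GM"))
  # paired ROIs have identical voxel counts and consistent back-references
  counts <- vapply(tab$code, function(c) sum(atlas$roi_labels == c),
                   numeric(1))
  paired <- which(!is.na(tab$pair_code))
  expect_gt(length(paired), 0)
  for (i in paired) {
    j <- match(tab$pair_code[i], tab$code)
    expect_equal(counts[i], counts[j], label = tab$name[i])
    expect_equal(tab$pair_code[j], tab$code[i])
  }
  # the phantom is exactly mirror symmetric about the x mid-plane
  expect_identical(atlas$labels, atlas$labels[64:1, , ])
  for (side in c("putamen", "amygdala", "thalamus")) {
    l <- tab$code[tab$name == paste0(side, "_left")]
    r <- tab$code[tab$name == paste0(side, "_right")]
    mirrored <- atlas$roi_labels[64:1, , ]
    expect_identical(which(mirrored == l), which(atlas$roi_labels == r))
  }
})

test_that("grids too small for the ROI layout fail with a sizing error", {
  expect_error(build_default_atlas(c(16, 16, 16)), "grid too small.*ROI")
  expect_error(build_default_atlas(c(8, 8, 8)), "at least 16")
})

test_that("cohorts are bit-reproducible and seed-sensitive", {
  atlas <- small_atlas()
  spec1 <- cohort_spec("smt", n_subjects = 2, seed = 1,
                       grid_shape = c(48L, 48L, 48L))
  c1 <- generate_cohort(spec1, atlas)
  c2 <- generate_cohort(spec1, atlas)
  expect_identical(c1$subjects, c2$subjects)
  spec2 <- cohort_spec("smt", n_subjects = 2, seed = 2,
                       grid_shape = c(48L, 48L, 48L))
  c3 <- generate_cohort(spec2, atlas)
  expect_false(identical(c1$subjects[[1]]$fin, c3$subjects[[1]]$fin))
})

test_that("a subject's volumes do not depend on cohort size", {
  atlas <- small_atlas()
  gs <- c(48L, 48L, 48L)
  s1 <- generate_cohort(cohort_spec("noddi", 1, seed = 5, grid_shape = gs),
                        atlas)$subjects[[1]]
  s3 <- generate_cohort(cohort_spec("noddi", 3, seed = 5, grid_shape = gs),
                        atlas)$subjects[[1]]
  expect_identical(s1, s3)
})

test_that("parameter maps respect physical ranges and zero background", {
  atlas <- small_atlas()
  for (model in c("noddi", "sandi", "smt")) {
    spec <- cohort_spec(model, 1, seed = 3, grid_shape = c(48L, 48L, 48L))
    subj <- generate_cohort(spec, atlas)$subjects[[1]]
    expect_named(subj, model_parameters(model))
    for (p in names(subj)) {
      rng <- if (p %in% c("Din", "Dec", "De")) c(0, Inf) else c(0, 1)
      brain <- subj[[p]][atlas$labels > 0]
      expect_true(all(brain >= rng[1] & brain <= min(rng[2], 1e9)),
                  label = paste(model, p, "range"))
      expect_true(all(subj[[p]][atlas$labels == 0] == 0),
                  label = paste(model, p, "background"))
    }
  }
})

test_that("asymmetry injection shifts the ROI mean by the offset", {
  atlas <- small_atlas()
  # fi ~ N(0.40, 0.05) in GM; +0.1 keeps the mass far from the bounds, so
  # the sample-mean difference estimates the offset directly
  spec <- cohort_spec("noddi", 170, seed = 9,
                      asymmetry = list(list(roi = "putamen_left",
                                            param = "fi", offset = 0.1)),
                      grid_shape = c(48L, 48L, 48L))
  cohort <- generate_cohort(spec, atlas)
  lcode <- atlas$roi_table$code[atlas$roi_table$name == "putamen_left"]
  rcode <- atlas$roi_table$code[atlas$roi_table$name == "putamen_right"]
  lv <- unlist(lapply(cohort$subjects,
                      function(s) s$fi[atlas$roi_labels == lcode]))
  rv <- unlist(lapply(cohort$subjects,
                      function(s) s$fi[atlas$roi_labels == rcode]))
  expect_gte(length(lv), 1e4)
  expect_equal(mean(lv) - mean(rv), 0.1, tolerance = 0.01)
  # offsets are re-clipped to the physical range
  spec2 <- cohort_spec("noddi", 1, seed = 9,
                       asymmetry = list(list(roi = "putamen_left",
                                             param = "fi", offset = 0.9)),
                       grid_shape = c(48L, 48L, 48L))
  s <- generate_cohort(spec2, atlas)$subjects[[1]]
  expect_true(all(s$fi[atlas$roi_labels == lcode] <= 1))
})

test_that("paired ROI draws are exchangeable without injected asymmetry", {
  atlas <- small_atlas()
  lcode <- atlas$roi_table$code[atlas$roi_table$name == "putamen_left"]
  rcode <- atlas$roi_table$code[atlas$roi_table$name == "putamen_right"]
  # aggregate over master seeds: any systematic left-right asymmetry would
  # reject nearly always, while exchangeable draws reject at ~the 0.01 level
  stats <- vapply(1:20, function(seed) {
    spec <- cohort_spec("smt", 5, seed, grid_shape = c(48L, 48L, 48L))
    cohort <- generate_cohort(spec, atlas)
    lv <- unlist(lapply(cohort$subjects,
                        function(s) s$fin[atlas$roi_labels == lcode]))
    rv <- unlist(lapply(cohort$subjects,
                        function(s) s$fin[atlas$roi_labels == rcode]))
    c(p = wilcox.test(lv, rv)$p.value, diff = mean(lv) - mean(rv))
  }, numeric(2))
  expect_lt(mean(stats["p", ] < 0.01), 0.25)
  expect_lt(abs(mean(stats["diff", ])), 0.005)
})

test_that("cohort specifications are validated", {
  tp <- default_tissue_params("smt")
  expect_error(cohort_spec("smt", 2, 1, tissue_params = tp[tp$param != "De", ]),
               "no truncated-normal specification")
  tp_bad <- tp; tp_bad$upper[tp_bad$param == "fin"] <- 1.5
  expect_error(cohort_spec("smt", 2, 1, tissue_params = tp_bad),
               "invalid bounds")
  expect_error(cohort_spec("smt", 2, 1,
                           asymmetry = list(list(roi = "putamen_left",
                                                 param = "odi",
                                                 offset = 0.1))),
               "not a smt parameter")
  expect_error(generate_subject(cohort_spec("smt", 1, 1,
                                            grid_shape = c(64L, 64L, 64L)),
                                small_atlas(), 1),
               "does not match")
})
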