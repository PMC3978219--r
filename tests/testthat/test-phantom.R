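test_that("phantom generation is byte-identical under a fixed seed", {
  spec <- phantom_spec(scale = 0.5, seed = 9L)
  a <- make_subject(spec)
  b <- make_subject(spec)
  expect_identical(a$pet$data, b$pet$data)
  expect_identical(a$t1$data, b$t1$data)
  expect_identical(a$ct$data, b$ct$data)
  c <- make_subject(phantom_spec(scale = 0.5, seed = 10L))
  expect_false(identical(a$pet$data, c$pet$data))
})

test_that("without blur and noise the PET reproduces the ratios exactly", {
  spec <- canonical_spec(psf_fwhm_mm = 0)
  s <- make_subject(spec)
  sch <- phantom_region_scheme()
  # quantify on the native PET grid: no resampling, no degradation
  for (rg in c("precuneus", "posterior_cingulate", "occipital")) {
    m <- region_mask(s$truth_atlas_pet, sch, rg)
    expect_equal(regional_mean(s$pet, m) / 100,
                 unname(s$spec$cortical_ratios[rg]), tolerance = 1e-9)
  }
  # multi-sector regions: expected value is the PET-grid voxel-weighted mean
  counts <- tabulate(s$truth_atlas_pet$volume$data[s$truth_atlas_pet$volume$data %in% 1:9], 9)
  glob_expected <- sum(counts * s$spec$cortical_ratios) / sum(counts)
  mglob <- region_mask(s$truth_atlas_pet, sch, "global")
  expect_equal(regional_mean(s$pet, mglob) / 100, glob_expected, tolerance = 1e-9)
  cb <- region_mask(s$truth_atlas_pet, sch, "cerebellum")
  expect_equal(regional_mean(s$pet, cb), 100, tolerance = 1e-9)
})

test_that("the PSF blur conserves total signal away from the grid boundary", {
  spec <- canonical_spec(psf_fwhm_mm = 0)
  s0 <- make_subject(spec)
  blurred <- smooth_volume(s0$pet, 5)
  expect_lt(abs(sum(blurred$data) - sum(s0$pet$data)) / sum(s0$pet$data), 0.005)
})

test_that("phantom truth atlas covers every tissue voxel exactly once", {
  fc <- fx_canonical()
  s <- fc$subject
  tissue <- s$truth_tissues$gm$data + s$truth_tissues$wm$data > 0
  atlas <- s$truth_atlas$volume$data
  expect_true(all(atlas[tissue] >= 1 & atlas[tissue] <= 12))
  expect_true(all(atlas[!tissue & s$truth_tissues$csf$data == 0] == 0))
  expect_equal(s$truth_suvr[["cerebellum"]], 1)
})

test_that("degenerate geometry raises a spec error naming a region", {
  spec <- phantom_spec()
  spec$head_radii[3] <- 18  # too flat a head: no cortex above z = 16 (precuneus)
  expect_error(make_subject(spec), class = "petsuvr_error_spec")
})

test_that("cohort draws converge to the generating profiles", {
  ch <- make_cohort(1000, 1, seed = 11L, build_volumes = FALSE)
  pa <- ch$cohort[ch$cohort$group == "patient", ]
  expect_lt(abs(mean(pa$global) - 1.50), 0.03)
  expect_lt(abs(sd(pa$global) - 0.32), 0.04)

  flat <- table2_profiles("route2", "control")
  flat$sd <- 0
  ch0 <- make_cohort(1, 3, control_profile = flat, seed = 5L, build_volumes = FALSE)
  co <- ch0$cohort[ch0$cohort$group == "control", ]
  expect_equal(sd(co$global), 0)

  ch1 <- make_cohort(30, 30, seed = 1L, build_volumes = FALSE)
  ch2 <- make_cohort(30, 30, seed = 2L, build_volumes = FALSE)
  expect_false(identical(ch1$cohort$global, ch2$cohort$global))
  expect_lt(abs(mean(ch1$cohort$global) - mean(ch2$cohort$global)), 0.2)
})

test_that("cohort subjects inherit their drawn uptake ratios", {
  ch <- make_cohort(1, 1, spec_base = phantom_spec(scale = 0.5), seed = 3L)
  expect_length(ch$subjects, 2)
  s1 <- ch$subjects[[1]]
  drawn <- ch$cohort[1, ]
  expect_equal(s1$spec$cortical_ratios[["precuneus"]], drawn$precuneus)
  expect_equal(s1$truth_suvr[["precuneus"]], drawn$precuneus)
})

test_that("white-matter binding inflates population-masked quantification most", {
  fc <- fx_canonical()
  tpl <- fc$template
  sch <- tpl$scheme
  pop_gm <- binarize_probability(tpl$gm_prob_population, 0.3)
  a_pop <- mask_atlas(tpl$atlas, pop_gm, sch)
  subj_gm <- binarize_probability(fc$subject$truth_tissues$gm, 0.3)
  a_subj <- mask_atlas(tpl$atlas, subj_gm, sch)
  errs <- vapply(c(1.3, 1.6, 1.9), function(wm) {
    spec <- canonical_spec(wm_ratio = wm)
    s <- make_subject(spec)
    pet_t1 <- resample(s$pet, identity_transform(), grid_of(s$t1))
    truth <- s$truth_suvr[["global"]]
    c(pop = suvr_by_region(pet_t1, a_pop, tpl$atlas, sch)[["global"]] - truth,
      subj = suvr_by_region(pet_t1, a_subj, tpl$atlas, sch)[["global"]] - truth)
  }, numeric(2))
  # population-masked error strictly increases with WM binding
  expect_true(all(diff(errs["pop", ]) > 0))
  # and changes more than the subject-masked error does
  expect_gt(diff(range(errs["pop", ])), diff(range(errs["subj", ])))
  # subject-specific masking stays closer to truth at the published WM level
  expect_lt(abs(errs["subj", 2]), abs(errs["pop", 2]))
})

test_that("fixtures export and reload faithfully", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec(scale = 0.5, seed = 4L)
  s <- make_subject(spec)
  export_fixture(s, dir)
  pet <- read_volume(file.path(dir, "pet.nii.gz"))
  expect_equal(pet$data, s$pet$data, tolerance = 1e-5)
  truth <- read.csv(file.path(dir, "truth_suvr.csv"))
  expect_equal(nrow(truth), length(s$truth_suvr))
  tr <- read_transform(file.path(dir, "ct_to_t1.mat"))
  expect_equal(tr$matrix, s$applied_transforms$ct_t1$matrix, tolerance = 1e-12)
  export_template(make_template(spec), dir)
  expect_true(file.exists(file.path(dir, "scheme.json")))
  expect_true(file.exists(file.path(dir, "gm_prob_population.nii.gz")))
})
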