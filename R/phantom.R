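#' Digital brain phantom specification
#'
#' Describes one synthetic subject: a nested-ellipsoid head (skull shell,
#' CSF shell, cortical grey-matter ribbon, white-matter core, and a
#' posterior-inferior cerebellar compartment with a midline vermis slab),
#' parcellated into the nine cortical sector regions plus cerebellum, vermis
#' and white matter. PET uptake per structure is expressed relative to the
#' cerebellar level, with elevated nonspecific white-matter binding; the PET
#' is blurred by the scanner point-spread function and degraded by Gaussian
#' noise. The T1 grid is 1 mm isotropic and the PET/CT grid 1 x 1 x 1.5 mm,
#' and the PET/CT pair is displaced from the T1 by a known rigid/affine
#' misalignment, as is the subject's anatomy from the template.
#'
#' @param cortical_ratios Named vector of uptake ratios (relative to
#'   cerebellum) for the nine sector regions; defaults emulate a
#'   cognitively-normal amyloid profile.
#' @param wm_ratio,csf_ratio White-matter and CSF uptake ratios (defaults
#'   1.6 and 0.3).
#' @param psf_fwhm_mm Scanner PSF full-width-at-half-maximum (default 5 mm).
#' @param noise_sd_fraction PET noise SD as a fraction of the cerebellar
#'   level, in \[0, 0.2\] (default 0.05).
#' @param mri_noise_sd T1/CT noise as a fraction of their intensity scale
#'   (default 0.02).
#' @param misalignment_ct_t1 `affine_transform` mapping CT/PET world space
#'   onto T1 world space (the truth the CT-to-T1 registration must recover).
#' @param misalignment_t1_template `affine_transform` mapping subject T1
#'   world space onto template world space.
#' @param pop_gm_fwhm_mm Smoothing applied to the canonical grey-matter map
#'   to emulate a population-average probability map (default 8 mm).
#' @param scale Global geometry scale factor; 0.5 gives a half-size head on
#'   a correspondingly smaller grid (voxel sizes unchanged) for fast tests.
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(cortical_ratios = NULL,
                         wm_ratio = 1.6, csf_ratio = 0.3,
                         psf_fwhm_mm = 5, noise_sd_fraction = 0.05,
                         mri_noise_sd = 0.02,
                         misalignment_ct_t1 = default_ct_misalignment(),
                         misalignment_t1_template = default_template_misalignment(),
                         pop_gm_fwhm_mm = 8, scale = 1, seed = 1L) {
  if (is.null(cortical_ratios)) cortical_ratios <- default_cn_ratios()
  need <- sector_region_names()
  if (!setequal(names(cortical_ratios), need))
    stop_petsuvr(sprintf("cortical_ratios must name exactly: %s", paste(need, collapse = ", ")),
                 "usage")
  cortical_ratios <- cortical_ratios[need]
  if (any(c(cortical_ratios, wm_ratio, csf_ratio) <= 0))
    stop_petsuvr("uptake ratios must be strictly positive", "usage")
  if (psf_fwhm_mm < 0) stop_petsuvr("psf_fwhm_mm must be >= 0", "usage")
  if (noise_sd_fraction < 0 || noise_sd_fraction > 0.2)
    stop_petsuvr("noise_sd_fraction must lie in [0, 0.2]", "usage")
  shape_t1 <- as.integer(round(c(80, 96, 80) * scale))
  shape_pet <- as.integer(c(round(80 * scale), round(96 * scale), round(80 * scale / 1.5)))
  structure(list(
    cortical_ratios = cortical_ratios, wm_ratio = wm_ratio, csf_ratio = csf_ratio,
    psf_fwhm_mm = psf_fwhm_mm, noise_sd_fraction = noise_sd_fraction,
    mri_noise_sd = mri_noise_sd,
    misalignment_ct_t1 = misalignment_ct_t1,
    misalignment_t1_template = misalignment_t1_template,
    pop_gm_fwhm_mm = pop_gm_fwhm_mm, scale = scale, seed = as.integer(seed),
    head_radii = c(33, 41, 29) * scale,
    skull_frac = 0.91, csf_frac = 0.82, ribbon_mm = 9 * scale,
    atlas_margin_mm = 3 * scale,
    cerebellum_level = 100,
    vox_t1 = c(1, 1, 1), vox_pet = c(1, 1, 1.5),
    shape_t1 = shape_t1, shape_pet = shape_pet),
    class = "phantom_spec")
}

sector_region_names <- function() {
  c("frontal", "temporal", "insular", "parietal", "occipital",
    "orbitofrontal", "anterior_cingulate", "posterior_cingulate", "precuneus")
}

#' @rdname phantom_spec
#' @export
default_cn_ratios <- function() {
  c(frontal = 1.19, temporal = 1.16, insular = 1.19, parietal = 1.15,
    occipital = 1.22, orbitofrontal = 1.23, anterior_cingulate = 1.30,
    posterior_cingulate = 1.36, precuneus = 1.14)
}

#' @rdname phantom_spec
#' @export
default_ct_misalignment <- function() {
  affine_transform(c(3, -2, 1.5, 0, 0, 2 * pi / 180, 1, 1, 1, 0, 0, 0))
}

#' @rdname phantom_spec
#' @export
default_template_misalignment <- function() {
  affine_transform(c(-2, 3, -1.5, 1.5 * pi / 180, 0, 0, 1.03, 0.98, 1.02, 0, 0, 0))
}

#' @rdname phantom_spec
#' @export
phantom_region_scheme <- function() {
  # the four ROIs are anatomically parts of their lobes, so the five lobes
  # cover the whole cortex: orbitofrontal and anterior cingulate sit in the
  # frontal lobe, posterior cingulate and precuneus in the parietal lobe
  memb <- list(frontal = c(1L, 6L, 7L), temporal = 2L, insular = 3L,
               parietal = c(4L, 8L, 9L), occipital = 5L,
               orbitofrontal = 6L, anterior_cingulate = 7L,
               posterior_cingulate = 8L, precuneus = 9L)
  region_scheme(memb, cerebellum = 10L, vermis = 11L)
}

# deterministic RNG scope that restores the caller's stream
with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

phantom_grid_t1 <- function(spec) {
  aff <- diag(c(spec$vox_t1, 1))
  aff[1:3, 4] <- -spec$vox_t1 * (spec$shape_t1 - 1) / 2
  grid_spec(spec$shape_t1, aff)
}

phantom_grid_pet <- function(spec) {
  aff <- diag(c(spec$vox_pet, 1))
  aff[1:3, 4] <- -spec$vox_pet * (spec$shape_pet - 1) / 2
  grid_spec(spec$shape_pet, aff)
}

# Structural label of each world point (template-space anatomy).
# 1-9 cortical sectors, 10 cerebellum, 11 vermis, 12 white matter,
# 13 CSF shell, 14 skull, 0 background.
phantom_classify <- function(w, spec) {
  s <- spec$scale
  r <- spec$head_radii
  x <- w[, 1]; y <- w[, 2]; z <- w[, 3]
  rho <- sqrt((x / r[1])^2 + (y / r[2])^2 + (z / r[3])^2)
  r_in <- spec$csf_frac * r - spec$ribbon_mm
  rho_in <- sqrt((x / r_in[1])^2 + (y / r_in[2])^2 + (z / r_in[3])^2)

  lab <- integer(length(x))
  inside <- rho <= 1
  lab[inside & rho > spec$skull_frac] <- 14L
  csf <- inside & rho <= spec$skull_frac & rho > spec$csf_frac
  lab[csf] <- 13L
  brain <- inside & rho <= spec$csf_frac

  cereb <- brain & z < -10 * s & y < -8 * s
  lab[cereb] <- ifelse(abs(x[cereb]) <= 5 * s, 11L, 10L)

  cerebrum <- brain & !cereb
  core <- cerebrum & rho_in <= 1
  lab[core] <- 12L
  # lateral ventricles: paired CSF cavities inside the white-matter core;
  # anatomically expected, and they anchor the rotational degrees of freedom
  # of intensity-based registration
  vent <- core &
    (((abs(x) - 8 * s) / (4 * s))^2 + ((y - 6 * s) / (11 * s))^2 +
       ((z - 6 * s) / (5 * s))^2) <= 1
  lab[vent] <- 13L
  ribbon <- cerebrum & rho_in > 1

  xm <- x[ribbon]; ym <- y[ribbon]; zm <- z[ribbon]
  medial <- abs(xm) < 7 * s
  sec <- integer(sum(ribbon))
  sec[medial & ym > 12 * s & zm < 2 * s] <- 6L   # orbitofrontal
  sec[medial & ym > 12 * s & zm >= 2 * s] <- 7L  # anterior cingulate
  sec[medial & ym <= 2 * s & zm >= 2 * s & zm < 16 * s] <- 8L  # posterior cingulate
  sec[medial & ym <= 2 * s & zm >= 16 * s] <- 9L # precuneus
  todo <- sec == 0L
  sec[todo & ym > 12 * s] <- 1L                  # frontal
  todo <- sec == 0L
  sec[todo & zm < -2 * s] <- 2L                  # temporal (inferior band)
  todo <- sec == 0L
  sec[todo & zm > 14 * s] <- 4L                  # parietal (vertex)
  todo <- sec == 0L
  sec[todo & ym < -18 * s] <- 5L                 # occipital
  todo <- sec == 0L
  sec[todo & zm > 12 * s] <- 4L                  # parietal (posterior shoulder)
  sec[sec == 0L] <- 3L                           # insular
  lab[ribbon] <- sec
  lab
}

phantom_label_names <- function() {
  setNames(c(sector_region_names(), "cerebellum", "vermis", "white_matter"),
           as.character(1:12))
}

intensity_lut <- function(lab, values) {
  # values: named by class code as character
  out <- numeric(length(lab))
  for (code in names(values)) out[lab == as.integer(code)] <- values[[code]]
  out
}

t1_intensities <- function(lab) {
  v <- numeric(length(lab))
  v[lab == 14L] <- 15
  v[lab == 13L] <- 30
  v[lab >= 1L & lab <= 11L] <- 70   # cortical + cerebellar grey matter
  v[lab == 12L] <- 110
  v
}

ct_intensities <- function(lab) {
  v <- numeric(length(lab))
  v[lab == 14L] <- 500
  v[lab == 13L] <- 5
  v[lab >= 1L & lab <= 11L] <- 35
  v[lab == 12L] <- 30
  v
}

pet_ratios <- function(lab, spec) {
  v <- numeric(length(lab))
  v[lab == 14L] <- 0.05
  v[lab == 13L] <- spec$csf_ratio
  for (i in 1:9) v[lab == i] <- spec$cortical_ratios[[i]]
  v[lab == 10L | lab == 11L] <- 1
  v[lab == 12L] <- spec$wm_ratio
  v
}

#' Build one phantom subject
#'
#' Synthesises the paired T1 / CT / PET volumes of one subject together with
#' the ground truth every pipeline test compares against: crisp tissue
#' probability maps, the 12-label truth atlas, the true regional uptake
#' ratios, and the misalignment transforms that were actually applied. The
#' subject's anatomy is the canonical (template) anatomy seen through the
#' inverse of the subject-to-template transform; CT and PET additionally sit
#' on their own grid displaced by the CT-to-T1 misalignment. All randomness
#' is governed by `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_subject`: list with `t1`, `ct`, `pet` (`pet_volume`s),
#'   `truth_tissues` (list `csf`/`gm`/`wm` of `probability_map`s),
#'   `truth_atlas` (`label_atlas` on the T1 grid), `truth_atlas_pet` (same
#'   truth sampled on the native PET/CT grid), `truth_suvr` (named vector of
#'   voxel-weighted report-region ratios), `applied_transforms`, and the
#'   `spec`.
#' @export
make_subject <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g_t1 <- phantom_grid_t1(spec)
  g_pet <- phantom_grid_pet(spec)
  M_tpl <- spec$misalignment_t1_template
  M_ct <- spec$misalignment_ct_t1

  # subject T1 grid: anatomy = canonical scene at the template-space point
  w_t1 <- apply_transform(M_tpl, voxel_world_coords(g_t1))
  lab_t1 <- phantom_classify(w_t1, spec)

  empty <- setdiff(1:11, unique(lab_t1))
  if (length(empty))
    stop_petsuvr(sprintf("phantom geometry left region(s) empty: %s",
                         paste(phantom_label_names()[as.character(empty)], collapse = ", ")),
                 "spec")

  # CT/PET grid: through CT->T1 misalignment first, then subject->template
  w_pet <- apply_transform(M_tpl, apply_transform(M_ct, voxel_world_coords(g_pet)))
  lab_pet <- phantom_classify(w_pet, spec)

  out <- with_seed_local(spec$seed, {
    t1d <- t1_intensities(lab_t1) + rnorm(length(lab_t1), 0, spec$mri_noise_sd * 110)
    ctd <- ct_intensities(lab_pet) + rnorm(length(lab_pet), 0, spec$mri_noise_sd * 50)
    petd <- pet_ratios(lab_pet, spec) * spec$cerebellum_level
    pet_vol <- volume(array(petd, g_pet$shape), g_pet$affine)
    pet_vol <- smooth_volume(pet_vol, spec$psf_fwhm_mm)
    if (spec$noise_sd_fraction > 0)
      pet_vol$data <- pet_vol$data +
        rnorm(length(pet_vol$data), 0, spec$noise_sd_fraction * spec$cerebellum_level)
    list(t1d = t1d, ctd = ctd, pet = pet_vol)
  })

  t1 <- volume(array(out$t1d, g_t1$shape), g_t1$affine)
  ct <- volume(array(out$ctd, g_pet$shape), g_pet$affine)

  atlas_arr <- array(ifelse(lab_t1 <= 12L, lab_t1, 0L) * 1.0, g_t1$shape)
  truth_atlas <- label_atlas(volume(atlas_arr, g_t1$affine), phantom_label_names())
  # same truth sampled on the native PET/CT grid (exact, no resampling)
  atlas_pet_arr <- array(ifelse(lab_pet <= 12L, lab_pet, 0L) * 1.0, g_pet$shape)
  truth_atlas_pet <- label_atlas(volume(atlas_pet_arr, g_pet$affine), phantom_label_names())
  tiss <- function(codes) {
    probability_map(volume(array((lab_t1 %in% codes) * 1.0, g_t1$shape), g_t1$affine))
  }
  truth_tissues <- list(csf = tiss(13L), gm = tiss(1:11), wm = tiss(12L))

  # report-region truth = voxel-weighted mean of the member sectors' ratios
  counts <- tabulate(lab_t1[lab_t1 >= 1 & lab_t1 <= 9], 9)
  scheme <- phantom_region_scheme()
  ratios <- unname(spec$cortical_ratios)
  truth_suvr <- vapply(scheme$region_names, function(rg) {
    memb <- scheme$membership[[rg]]
    sum(counts[memb] * ratios[memb]) / sum(counts[memb])
  }, numeric(1))
  truth_suvr <- c(truth_suvr, cerebellum = 1, vermis = 1)

  structure(list(t1 = t1, ct = ct, pet = out$pet,
                 truth_tissues = truth_tissues, truth_atlas = truth_atlas,
                 truth_atlas_pet = truth_atlas_pet,
                 truth_suvr = truth_suvr,
                 applied_transforms = list(ct_t1 = M_ct, t1_template = M_tpl),
                 spec = spec),
            class = "phantom_subject")
}

#' Template-space reference data for the phantom world
#'
#' Builds the "population" side of route 1 and the registration targets of
#' both routes from the canonical (unmisaligned, noiseless) anatomy: the
#' tracer PET template (canonical uptake blurred by the PSF), the T1
#' template, the template-space truth atlas, and a population-average
#' grey-matter probability map (the canonical grey-matter map smoothed by
#' `pop_gm_fwhm_mm`, deliberately not matched to any individual subject).
#'
#' Two grey-matter maps are returned: `gm_prob` is the canonical (crisp)
#' template-space tissue probability, appropriate when validating parameter
#' recovery; `gm_prob_population` is its smoothed population-average
#' counterpart, which reproduces the white-matter spill-over bias of
#' template-based quantification when used as the route-1 mask.
#'
#' @param spec A [phantom_spec()].
#' @return List with `pet`, `t1`, `atlas`, `gm_prob`, `gm_prob_population`,
#'   `scheme`.
#' @export
make_template <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g_t1 <- phantom_grid_t1(spec)
  g_pet <- phantom_grid_pet(spec)
  lab_t1 <- phantom_classify(voxel_world_coords(g_t1), spec)
  lab_pet <- phantom_classify(voxel_world_coords(g_pet), spec)

  pet_tpl <- volume(array(pet_ratios(lab_pet, spec) * spec$cerebellum_level, g_pet$shape),
                    g_pet$affine)
  pet_tpl <- smooth_volume(pet_tpl, spec$psf_fwhm_mm)
  t1_tpl <- volume(array(t1_intensities(lab_t1), g_t1$shape), g_t1$affine)
  # The template-space parcellation follows anatomical conventions: each
  # cortical label covers its gyral sector down into the subjacent white
  # matter (atlas_margin_mm), so the grey-matter mask decides what is kept.
  spec_wide <- spec
  spec_wide$ribbon_mm <- spec$ribbon_mm + spec$atlas_margin_mm
  lab_wide <- phantom_classify(voxel_world_coords(g_t1), spec_wide)
  atlas_lab <- ifelse(lab_t1 <= 12L, lab_t1, 0L)
  take <- lab_t1 == 12L & lab_wide >= 1L & lab_wide <= 9L
  atlas_lab[take] <- lab_wide[take]
  atlas <- label_atlas(volume(array(atlas_lab * 1.0, g_t1$shape), g_t1$affine),
                       phantom_label_names())
  gm_crisp <- volume(array((lab_t1 %in% 1:11) * 1.0, g_t1$shape), g_t1$affine)
  gm_pop <- smooth_volume(gm_crisp, spec$pop_gm_fwhm_mm)
  gm_pop$data[gm_pop$data < 0] <- 0
  gm_pop$data[gm_pop$data > 1] <- 1
  list(pet = pet_tpl, t1 = t1_tpl, atlas = atlas,
       gm_prob = probability_map(gm_crisp),
       gm_prob_population = probability_map(gm_pop),
       scheme = phantom_region_scheme())
}

#' Simulate a cohort of phantom subjects
#'
#' Draws per-subject regional uptake ratios from group profiles (mean and SD
#' per region; the defaults in [table2_profiles()] reproduce the published
#' cohort summaries), truncating draws below 0.5, and optionally builds a
#' full `phantom_subject` per draw. The generating draws are returned as a
#' cohort truth table ready for the statistics layer.
#'
#' @param n_patients,n_controls Group sizes.
#' @param patient_profile,control_profile Tibbles with columns `region`,
#'   `mean`, `sd` covering the ten report regions.
#' @param spec_base `phantom_spec` supplying geometry, noise and
#'   misalignments for built subjects.
#' @param seed Integer seed for the draws (and, offset per subject, for the
#'   built volumes).
#' @param route Route label written into the truth table.
#' @param build_volumes If `TRUE` (default) a `phantom_subject` is built per
#'   draw; `FALSE` returns only the truth table, which is all the
#'   group-statistics properties need.
#' @return List with `cohort` (tibble: `subject_id`, `group`, `route`, one
#'   column per region) and `subjects` (list of `phantom_subject` or
#'   `NULL`).
#' @export
make_cohort <- function(n_patients, n_controls,
                        patient_profile = table2_profiles("route2", "patient"),
                        control_profile = table2_profiles("route2", "control"),
                        spec_base = phantom_spec(), seed = 1L,
                        route = "route2", build_volumes = TRUE) {
  stopifnot(n_patients >= 1, n_controls >= 1)
  check_profile <- function(p) {
    if (!all(c("region", "mean", "sd") %in% names(p)) || any(p$mean <= 0) || any(p$sd < 0))
      stop_petsuvr("profiles need columns region/mean/sd with positive means", "usage")
    p
  }
  check_profile(patient_profile); check_profile(control_profile)
  regions <- c("global", sector_region_names())
  draw_subject <- function(profile) {
    vals <- vapply(regions, function(rg) {
      row <- profile[profile$region == rg, ]
      if (nrow(row) != 1)
        stop_petsuvr(sprintf("profile missing region '%s'", rg), "usage")
      for (try in 1:20) {
        v <- rnorm(1, row$mean, row$sd)
        if (v >= 0.5) return(v)
      }
      stop_petsuvr(sprintf("could not draw a ratio >= 0.5 for region '%s'", rg), "spec")
    }, numeric(1))
    vals
  }
  draws <- with_seed_local(seed, {
    lapply(seq_len(n_patients + n_controls), function(i) {
      draw_subject(if (i <= n_patients) patient_profile else control_profile)
    })
  })
  ids <- sprintf("S%03d", seq_len(n_patients + n_controls))
  cohort <- dplyr::bind_rows(lapply(seq_along(draws), function(i) {
    tibble(subject_id = ids[i],
           group = if (i <= n_patients) "patient" else "control",
           route = route, !!!as.list(draws[[i]]))
  }))
  subjects <- NULL
  if (build_volumes) {
    subjects <- lapply(seq_along(draws), function(i) {
      sp <- spec_base
      sp$cortical_ratios <- draws[[i]][sector_region_names()]
      sp$seed <- spec_base$seed + i
      make_subject(sp)
    })
    names(subjects) <- ids
  }
  list(cohort = cohort, subjects = subjects)
}

#' Published cohort SUVr summary profiles
#'
#' Mean and SD of the regional SUVr for each clinical group and
#' quantification route, as printed in the source cohort's summary table;
#' used as generating profiles for simulated cohorts.
#'
#' @param route `"route1"` or `"route2"`.
#' @param group `"patient"` or `"control"`.
#' @return Tibble with columns `region`, `mean`, `sd`.
#' @export
table2_profiles <- function(route = c("route1", "route2"),
                            group = c("patient", "control")) {
  route <- match.arg(route); group <- match.arg(group)
  regions <- c("global", sector_region_names())
  vals <- switch(paste(route, group),
    "route1 patient" = list(m = c(1.47, 1.49, 1.42, 1.37, 1.54, 1.43, 1.47, 1.59, 1.82, 1.56),
                            s = c(.24, .28, .22, .27, .25, .22, .31, .31, .31, .30)),
    "route2 patient" = list(m = c(1.50, 1.54, 1.45, 1.46, 1.51, 1.49, 1.60, 1.67, 1.74, 1.56),
                            s = c(.32, .38, .30, .32, .35, .31, .41, .41, .36, .36)),
    "route1 control" = list(m = c(1.25, 1.29, 1.19, 1.14, 1.26, 1.24, 1.22, 1.36, 1.55, 1.20),
                            s = c(.13, .17, .13, .13, .14, .13, .17, .20, .27, .14)),
    "route2 control" = list(m = c(1.18, 1.19, 1.16, 1.19, 1.15, 1.22, 1.23, 1.30, 1.36, 1.14),
                            s = c(.09, .13, .07, .11, .09, .08, .16, .16, .14, .09)))
  tibble(region = regions, mean = vals$m, sd = vals$s)
}

#' Write a phantom subject (and optional template) to disk
#'
#' Stable fixture layout: `t1.nii.gz`, `ct.nii.gz`, `pet.nii.gz`,
#' `truth_atlas.nii.gz`, `tissue_{csf,gm,wm}.nii.gz`, `truth_suvr.csv`,
#' `ct_to_t1.mat`, `t1_to_template.mat`. The directory can be fed directly
#' to the quantification drivers / the command line.
#'
#' @param subject A `phantom_subject`.
#' @param directory Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_fixture <- function(subject, directory) {
  stopifnot(inherits(subject, "phantom_subject"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write_volume(subject$t1, file.path(directory, "t1.nii.gz"))
  write_volume(subject$ct, file.path(directory, "ct.nii.gz"))
  write_volume(subject$pet, file.path(directory, "pet.nii.gz"))
  write_volume(subject$truth_atlas$volume, file.path(directory, "truth_atlas.nii.gz"))
  for (nm in names(subject$truth_tissues))
    write_volume(subject$truth_tissues[[nm]],
                 file.path(directory, sprintf("tissue_%s.nii.gz", nm)))
  write.csv(data.frame(region = names(subject$truth_suvr),
                       truth_suvr = unname(subject$truth_suvr)),
            file.path(directory, "truth_suvr.csv"), row.names = FALSE)
  write_transform(subject$applied_transforms$ct_t1, file.path(directory, "ct_to_t1.mat"))
  write_transform(subject$applied_transforms$t1_template,
                  file.path(directory, "t1_to_template.mat"))
  invisible(directory)
}

#' @rdname export_fixture
#' @param template Output of [make_template()].
#' @export
export_template <- function(template, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write_volume(template$pet, file.path(directory, "template_pet.nii.gz"))
  write_volume(template$t1, file.path(directory, "template_t1.nii.gz"))
  write_volume(template$atlas$volume, file.path(directory, "atlas.nii.gz"))
  write_volume(template$gm_prob, file.path(directory, "gm_prob.nii.gz"))
  write_volume(template$gm_prob_population,
               file.path(directory, "gm_prob_population.nii.gz"))
  write_region_scheme(template$scheme, file.path(directory, "scheme.json"))
  invisible(directory)
}
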