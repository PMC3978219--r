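#' Mean uptake over a mask
#'
#' Arithmetic mean of the PET intensities over the mask's 1-voxels; the
#' elementary measurement behind every regional SUV.
#'
#' @param pet `pet_volume`.
#' @param mask `binary_mask` on the same grid.
#' @return Scalar mean intensity.
#' @export
regional_mean <- function(pet, mask) {
  stopifnot(inherits(pet, "pet_volume"), inherits(mask, "binary_mask"))
  if (!same_grid(pet, mask))
    stop_petsuvr("PET and mask are not on the same grid", "geometry")
  n <- sum(mask$data)
  if (n == 0)
    stop_petsuvr("mask is empty", "emptiness")
  sum(pet$data[mask$data > 0]) / n
}

#' Cerebellum-normalised SUVr table
#'
#' Divides each region's mean SUV by the cerebellar reference mean, producing
#' the dimensionless SUVr that all group statistics operate on. Injected
#' dose and body weight cancel in the ratio, so raw image intensities are
#' valid SUV inputs.
#'
#' @param means Tibble with columns `region`, `voxels`, `mean_suv` (one row
#'   per report region, cerebellum and vermis rows included).
#' @param cerebellum_mean Reference mean (> 0), whole cerebellum with the
#'   vermis excluded.
#' @param subject_id,route Identifiers carried into the table.
#' @return A `suvr_table`: tibble with columns `subject_id`, `route`,
#'   `region`, `voxels`, `mean_suv`, `suvr`, plus attribute
#'   `cerebellum_mean`.
#' @export
normalize_suvr <- function(means, cerebellum_mean, subject_id = "subject", route = "route1") {
  if (!is.finite(cerebellum_mean) || cerebellum_mean <= 0)
    stop_petsuvr("cerebellar reference mean must be strictly positive", "reference")
  if (any(means$voxels <= 0))
    stop_petsuvr("every region must contain at least one voxel", "emptiness")
  out <- tibble(subject_id = subject_id, route = route,
                region = means$region, voxels = as.integer(means$voxels),
                mean_suv = means$mean_suv,
                suvr = means$mean_suv / cerebellum_mean)
  attr(out, "cerebellum_mean") <- cerebellum_mean
  class(out) <- c("suvr_table", class(out))
  out
}

suvr_from_atlas <- function(pet, atlas_masked, atlas_full, scheme, subject_id, route) {
  regions <- scheme$region_names
  rows <- purrr::map(regions, function(rg) {
    m <- region_mask(atlas_masked, scheme, rg)
    tibble(region = rg, voxels = voxel_count(m), mean_suv = regional_mean(pet, m))
  })
  # reference: whole cerebellum (vermis excluded), NOT grey-matter masked
  cb_mask <- region_mask(atlas_full, scheme, "cerebellum")
  cb_mean <- regional_mean(pet, cb_mask)
  rows <- c(rows, list(tibble(region = "cerebellum", voxels = voxel_count(cb_mask),
                              mean_suv = cb_mean)))
  normalize_suvr(dplyr::bind_rows(rows), cb_mean, subject_id, route)
}

#' Template-space quantification (route 1)
#'
#' Registers the subject PET onto the tracer template (12 DOF, trilinear
#' interpolation), quantifies regional uptake in template space with the
#' template-space atlas restricted to a population grey-matter mask
#' (probability strictly greater than `gm_threshold`), and normalises to the
#' whole-cerebellum (vermis-excluded) mean.
#'
#' @param pet Subject PET `pet_volume`.
#' @param template Template `pet_volume` (tracer contrast) the PET is
#'   registered to.
#' @param atlas Template-space `label_atlas`.
#' @param gm_prob Template-space grey-matter `probability_map` (population
#'   map; shares the atlas grid).
#' @param scheme `region_scheme`.
#' @param gm_threshold Grey-matter probability threshold (default 0.3,
#'   strict inequality).
#' @param subject_id Identifier written into the output table.
#' @param registration List of [register_affine()] control settings.
#' @param cost Registration cost; the default `correlation_ratio` suits the
#'   PET-to-template pairing.
#' @param audit_dir Optional directory: the recovered transform, resampled
#'   PET and masks are written there for audit.
#' @return A `suvr_table` (route = `"route1"`) with attribute `registration`
#'   holding the `registration_result`.
#' @export
run_route1 <- function(pet, template, atlas, gm_prob, scheme,
                       gm_threshold = 0.3, subject_id = "subject",
                       registration = list(), cost = "correlation_ratio",
                       audit_dir = NULL) {
  if (!same_grid(atlas$volume, gm_prob))
    stop_petsuvr("route 1: atlas and grey-matter map must share the template grid", "geometry")
  reg <- register_affine(pet, template, dof = 12, cost = cost, control = registration)
  pet_tpl <- resample(pet, reg$transform, grid_of(atlas$volume), "trilinear")
  gm_mask <- binarize_probability(gm_prob, gm_threshold)
  atlas_gm <- mask_atlas(atlas, gm_mask, scheme)
  out <- suvr_from_atlas(pet_tpl, atlas_gm, atlas, scheme, subject_id, "route1")
  attr(out, "registration") <- reg
  if (!is.null(audit_dir)) {
    dir.create(audit_dir, recursive = TRUE, showWarnings = FALSE)
    write_transform(reg$transform, file.path(audit_dir, "pet_to_template.mat"))
    write_volume(pet_tpl, file.path(audit_dir, "pet_template_space.nii.gz"))
    write_volume(gm_mask, file.path(audit_dir, "gm_mask.nii.gz"))
  }
  out
}

#' Subject-space MRI-based quantification (route 2)
#'
#' Quantifies on the individual T1 grid: the CT (acquired together with the
#' PET on a hybrid scanner, so PET and CT share a grid) is registered onto
#' the subject T1 and the recovered transform moves the PET into T1 space;
#' grey matter is segmented from the T1 and binarised; the template-space
#' atlas is brought into subject space through the *inverse* of the
#' T1-to-template transform; regional means are taken under the
#' subject-specific grey-matter mask and normalised to the whole-cerebellum
#' (vermis-excluded) mean. PET data never leave the subject's own space.
#'
#' @param pet,ct,t1 Subject volumes; `ct` and `t1` are required.
#' @param atlas Template-space `label_atlas`.
#' @param template Template T1-contrast `pet_volume` (target of the
#'   T1-to-template registration).
#' @param scheme `region_scheme`.
#' @param gm_threshold Grey-matter probability threshold (default 0.3).
#' @param subject_id Identifier written into the output table.
#' @param registration List of [register_affine()] control settings.
#' @param audit_dir Optional directory for transforms and masks.
#' @return A `suvr_table` (route = `"route2"`) with attributes
#'   `registration_ct` and `registration_t1`.
#' @export
run_route2 <- function(pet, ct, t1, atlas, template, scheme,
                       gm_threshold = 0.3, subject_id = "subject",
                       registration = list(), audit_dir = NULL) {
  if (missing(ct) || missing(t1) || is.null(ct) || is.null(t1))
    stop_petsuvr("route 2 requires both a CT and a T1 volume", "usage")
  reg_ct <- register_affine(ct, t1, dof = 12, cost = "correlation_ratio",
                            control = registration)
  pet_t1 <- resample(pet, reg_ct$transform, grid_of(t1), "trilinear")
  tissues <- segment_tissues(t1)
  gm_mask <- binarize_probability(tissues$gm, gm_threshold)
  reg_t1 <- register_affine(t1, template, dof = 12, cost = "normalized_correlation",
                            control = registration)
  atlas_subj <- transform_labels(atlas, invert(reg_t1$transform), grid_of(t1))
  atlas_gm <- mask_atlas(atlas_subj, gm_mask, scheme)
  out <- suvr_from_atlas(pet_t1, atlas_gm, atlas_subj, scheme, subject_id, "route2")
  attr(out, "registration_ct") <- reg_ct
  attr(out, "registration_t1") <- reg_t1
  if (!is.null(audit_dir)) {
    dir.create(audit_dir, recursive = TRUE, showWarnings = FALSE)
    write_transform(reg_ct$transform, file.path(audit_dir, "ct_to_t1.mat"))
    write_transform(reg_t1$transform, file.path(audit_dir, "t1_to_template.mat"))
    write_volume(pet_t1, file.path(audit_dir, "pet_t1_space.nii.gz"))
    write_volume(gm_mask, file.path(audit_dir, "gm_mask.nii.gz"))
  }
  out
}

#' Write / read an SUVr table as CSV
#'
#' One row per region with columns `subject_id`, `route`, `region`,
#' `voxels`, `mean_suv`, `suvr`.
#'
#' @param table A `suvr_table`.
#' @param path CSV path.
#' @export
write_suvr_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_suvr_table
#' @export
read_suvr_table <- function(path) {
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
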