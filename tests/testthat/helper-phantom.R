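# Shared phantom fixtures, built once per test run and memoised.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# canonical world: no noise, no misalignment (unit-test workhorse)
canonical_spec <- function(...) {
  args <- utils::modifyList(
    list(noise_sd_fraction = 0, mri_noise_sd = 0,
         misalignment_ct_t1 = identity_transform(),
         misalignment_t1_template = identity_transform()),
    list(...))
  do.call(phantom_spec, args)
}

fx_canonical <- function() fixture("canonical", function() {
  spec <- canonical_spec()
  list(spec = spec, subject = make_subject(spec), template = make_template(spec))
})

# study conditions: defaults (5% noise, 5 mm PSF, misalignments on)
fx_study <- function() fixture("study", function() {
  spec <- phantom_spec(seed = 7L)
  list(spec = spec, subject = make_subject(spec), template = make_template(spec))
})

fx_route1 <- function() fixture("route1", function() {
  st <- fx_study()
  run_route1(st$subject$pet, st$template$pet, st$template$atlas,
             st$template$gm_prob, st$template$scheme, subject_id = "p1")
})

fx_route2 <- function() fixture("route2", function() {
  st <- fx_study()
  run_route2(st$subject$pet, st$subject$ct, st$subject$t1,
             st$template$atlas, st$template$t1, st$template$scheme,
             subject_id = "p1")
})

# PET resampled onto the T1 grid (identity: canonical world is aligned)
canonical_pet_t1 <- function() fixture("canonical_pet_t1", function() {
  fc <- fx_canonical()
  resample(fc$subject$pet, identity_transform(), grid_of(fc$subject$t1))
})

# regional SUVr of a PET against a (possibly masked) atlas, truth-style
suvr_by_region <- function(pet, atlas_masked, atlas_full, scheme) {
  cb <- regional_mean(pet, region_mask(atlas_full, scheme, "cerebellum"))
  vapply(scheme$region_names, function(rg)
    regional_mean(pet, region_mask(atlas_masked, scheme, rg)) / cb, numeric(1))
}

expect_suvr_close <- function(tab, truth, tol) {
  tab <- as.data.frame(tab)
  for (rg in setdiff(tab$region, c("cerebellum", "vermis"))) {
    expect_lt(abs(tab$suvr[tab$region == rg] - truth[[rg]]), tol,
              label = sprintf("|suvr - truth| for %s", rg))
  }
}
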