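test_that("probability binarisation uses a strict threshold", {
  m <- probability_map(volume(array(c(0.2, 0.3, 0.4, 1), c(1, 2, 2)), diag(4)))
  out <- binarize_probability(m, 0.3)
  expect_equal(as.numeric(out$data), c(0, 0, 1, 1))  # 0.3 itself excluded
  allone <- probability_map(volume(array(1, c(2, 2, 2)), diag(4)))
  expect_equal(sum(binarize_probability(allone)$data), 8)
  low <- probability_map(volume(array(0.1, c(2, 2, 2)), diag(4)))
  expect_error(binarize_probability(low, 0.3), class = "petsuvr_error_emptiness")
  expect_error(binarize_probability(m, 1.2), class = "petsuvr_error_usage")
})

test_that("binarisation is monotone in the threshold and matches a voxel scan", {
  fc <- fx_canonical()
  gm <- fc$template$gm_prob_population
  counts <- vapply(c(0.2, 0.3, 0.5, 0.7), function(th)
    voxel_count(binarize_probability(gm, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(voxel_count(binarize_probability(gm, 0.3)), sum(gm$data > 0.3))
})

test_that("tissue segmentation recovers the phantom classes", {
  fc <- fx_canonical()  # noiseless T1 with exact class intensities
  seg <- segment_tissues(fc$subject$t1)
  hard <- (seg$gm$data > 0.5) * 2 + (seg$wm$data > 0.5) * 3 + (seg$csf$data > 0.5) * 1
  truth <- fc$subject$truth_tissues
  truth_hard <- truth$csf$data * 1 + truth$gm$data * 2 + truth$wm$data * 3
  brain <- truth_hard > 0
  expect_gte(mean(hard[brain] == truth_hard[brain]), 0.99)
  # class identity is fixed by intensity rank: GM map must hit the ribbon
  expect_gte(sum(seg$gm$data * truth$gm$data) / sum(truth$gm$data), 0.9)
})

test_that("segmentation tolerates noise (Dice of thresholded GM >= 0.90)", {
  spec <- canonical_spec(mri_noise_sd = 0.02, seed = 3L)
  s <- make_subject(spec)
  seg <- segment_tissues(s$t1)
  gm <- binarize_probability(seg$gm, 0.3)
  truth <- s$truth_tissues$gm$data
  dice <- 2 * sum(gm$data * truth) / (sum(gm$data) + sum(truth))
  expect_gte(dice, 0.90)
})

test_that("segmentation fails loudly on degenerate input", {
  flat <- volume(array(50, c(20, 20, 20)), diag(4))
  expect_error(segment_tissues(flat), class = "petsuvr_error_segmentation")
})

test_that("grey-matter masking of the atlas only removes voxels", {
  fc <- fx_canonical()
  atlas <- fc$subject$truth_atlas
  ones <- binary_mask(volume(array(1, dim(atlas$volume$data)), atlas$volume$affine))
  expect_identical(mask_atlas(atlas, ones)$volume$data, atlas$volume$data)
  zeros <- binary_mask(volume(array(0, dim(atlas$volume$data)), atlas$volume$affine))
  expect_error(mask_atlas(atlas, zeros), class = "petsuvr_error_emptiness")

  gm <- binarize_probability(fc$subject$truth_tissues$gm, 0.3)
  masked <- mask_atlas(atlas, gm, fc$template$scheme)
  for (lb in c(1L, 5L, 10L, 12L)) {
    expect_equal(sum(masked$volume$data == lb),
                 sum(atlas$volume$data == lb & gm$data == 1))
    expect_lte(sum(masked$volume$data == lb), sum(atlas$volume$data == lb))
  }
  # grid mismatch is a geometry error
  off <- binary_mask(volume(array(1, dim(atlas$volume$data)), diag(c(2, 2, 2, 1))))
  expect_error(mask_atlas(atlas, off), class = "petsuvr_error_geometry")
})

test_that("region masks follow the scheme definitions", {
  fc <- fx_canonical()
  atlas <- fc$subject$truth_atlas
  sch <- fc$template$scheme
  glob <- region_mask(atlas, sch, "global")
  expect_equal(voxel_count(glob), sum(atlas$volume$data %in% 1:9))
  # cerebellar reference excludes the vermis
  cb <- region_mask(atlas, sch, "cerebellum")
  vm <- region_mask(atlas, sch, "vermis")
  expect_equal(sum(cb$data * vm$data), 0)
  expect_gt(voxel_count(vm), 0)
  # lobes are mutually disjoint
  fr <- region_mask(atlas, sch, "frontal")
  oc <- region_mask(atlas, sch, "occipital")
  expect_equal(sum(fr$data * oc$data), 0)
  expect_error(region_mask(atlas, sch, "hippocampus"), class = "petsuvr_error_usage")
})

test_that("the five lobes exactly tile the global cortex", {
  fc <- fx_canonical()
  atlas <- fc$subject$truth_atlas
  sch <- fc$template$scheme
  lobes <- c("frontal", "temporal", "insular", "parietal", "occipital")
  union <- Reduce(`|`, lapply(lobes, function(l) region_mask(atlas, sch, l)$data > 0))
  glob <- region_mask(atlas, sch, "global")$data > 0
  expect_identical(union, glob)
})

test_that("region schemes validate membership and survive JSON round-trips", {
  memb <- list(frontal = c(1L, 6L, 7L), temporal = 2L, insular = 3L,
               parietal = c(4L, 8L, 9L), occipital = 5L, orbitofrontal = 6L,
               anterior_cingulate = 7L, posterior_cingulate = 8L, precuneus = 9L)
  bad <- memb; bad$frontal <- c(bad$frontal, 10L)  # cerebellum label leaking in
  expect_error(region_scheme(bad, 10L, 11L), class = "petsuvr_error_usage")
  sch <- region_scheme(memb, 10L, 11L)
  expect_setequal(sch$membership$global, 1:9)
  path <- withr::local_tempfile(fileext = ".json")
  write_region_scheme(sch, path)
  sch2 <- read_region_scheme(path)
  expect_equal(sch2$membership, sch$membership)
  expect_equal(sch2$cerebellum, sch$cerebellum)
})
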