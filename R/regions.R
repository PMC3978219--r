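#' Labelled parcellation atlas
#'
#' A `label_atlas` couples an integer-valued volume with a label-to-name
#' table. Label 0 is background; every other label occurring in the volume
#' must be named.
#'
#' @param vol `pet_volume` with non-negative integer values.
#' @param label_names Named integer vector or a `label -> name` character
#'   vector indexed by label, e.g. `c(`1` = "frontal", ...)`.
#' @return A `label_atlas`.
#' @export
label_atlas <- function(vol, label_names) {
  stopifnot(inherits(vol, "pet_volume"))
  d <- vol$data
  if (any(d < 0) || max(abs(d - round(d))) > 1e-9)
    stop_petsuvr("atlas labels must be non-negative integers", "format")
  present <- sort(unique(as.integer(d)))
  present <- present[present > 0]
  known <- as.integer(names(label_names))
  missing <- setdiff(present, known)
  if (length(missing))
    stop_petsuvr(sprintf("atlas labels without a name: %s", paste(missing, collapse = ", ")),
                 "format")
  structure(list(volume = vol, label_names = label_names), class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  present <- sort(unique(as.integer(x$volume$data)))
  present <- present[present > 0]
  cat(sprintf("<label_atlas> %d labels on a %s grid\n", length(present),
              paste(dim(x$volume$data), collapse = " x ")))
  invisible(x)
}

atlas_labels <- function(atlas) {
  present <- sort(unique(as.integer(atlas$volume$data)))
  present[present > 0]
}

#' Region scheme: grouping atlas labels into report regions
#'
#' Defines the ten cortical report regions (a global cortex plus five lobes
#' and four regions of interest) and the cerebellar reference (whole
#' cerebellum with the vermis excluded) as sets of atlas labels. The
#' `global` region is the union of all cortical member labels. Reference
#' labels may not appear in any target region.
#'
#' @param membership Named list mapping each target region (other than
#'   `global`) to an integer vector of atlas labels.
#' @param cerebellum,vermis Integer atlas labels of the reference structures.
#' @return A `region_scheme` with elements `region_names`, `reference_names`,
#'   `membership` (including the derived `global` entry), `cerebellum`,
#'   `vermis`.
#' @export
region_scheme <- function(membership, cerebellum, vermis) {
  target_names <- c("frontal", "temporal", "insular", "parietal", "occipital",
                    "orbitofrontal", "anterior_cingulate", "posterior_cingulate",
                    "precuneus")
  if (!setequal(names(membership), target_names))
    stop_petsuvr(sprintf("membership must name exactly the regions: %s",
                         paste(target_names, collapse = ", ")), "usage")
  membership <- membership[target_names]
  if (any(lengths(membership) == 0))
    stop_petsuvr("every target region must contain at least one label", "usage")
  refs <- c(cerebellum, vermis)
  hit <- vapply(membership, function(l) any(l %in% refs), logical(1))
  if (any(hit))
    stop_petsuvr(sprintf("reference labels appear in target region(s): %s",
                         paste(names(membership)[hit], collapse = ", ")), "usage")
  membership <- c(list(global = sort(unique(unlist(membership)))), membership)
  structure(list(region_names = c("global", target_names),
                 reference_names = c("cerebellum", "vermis"),
                 membership = membership,
                 cerebellum = as.integer(cerebellum),
                 vermis = as.integer(vermis)),
            class = "region_scheme")
}

#' @rdname region_scheme
#' @param path JSON file with fields `membership` (region -> label array),
#'   `cerebellum`, `vermis`.
#' @export
read_region_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  region_scheme(lapply(x$membership, as.integer),
                as.integer(x$cerebellum), as.integer(x$vermis))
}

#' @rdname region_scheme
#' @param scheme A `region_scheme`.
#' @export
write_region_scheme <- function(scheme, path) {
  jsonlite::write_json(list(membership = scheme$membership[setdiff(names(scheme$membership), "global")],
                            cerebellum = scheme$cerebellum, vermis = scheme$vermis),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Binary mask of one report region
#'
#' Union of the region's member labels. `region` may also be `"cerebellum"`
#' (the whole-cerebellum reference, vermis excluded) or `"vermis"`.
#'
#' @param atlas A `label_atlas`.
#' @param scheme A `region_scheme`.
#' @param region Region name.
#' @return A `binary_mask`.
#' @export
region_mask <- function(atlas, scheme, region) {
  stopifnot(inherits(atlas, "label_atlas"), inherits(scheme, "region_scheme"))
  labs <- if (region %in% names(scheme$membership)) {
    scheme$membership[[region]]
  } else if (region == "cerebellum") {
    scheme$cerebellum
  } else if (region == "vermis") {
    scheme$vermis
  } else {
    stop_petsuvr(sprintf("unknown region '%s'", region), "usage")
  }
  m <- (array(as.integer(atlas$volume$data), dim(atlas$volume$data)) %in% labs)
  binary_mask(volume(array(m * 1.0, dim(atlas$volume$data)), atlas$volume$affine))
}

#' Restrict an atlas to a grey-matter mask
#'
#' Keeps labels only where the mask is 1; voxels outside become background.
#' All labels, including the cerebellar reference if present, are masked
#' identically — callers that want an unmasked reference take it from the
#' unmasked atlas.
#'
#' @param atlas A `label_atlas`.
#' @param gm A `binary_mask` on the same grid.
#' @param scheme Optional `region_scheme`; if given, an error names any
#'   target region that masking empties.
#' @return The masked `label_atlas`.
#' @export
mask_atlas <- function(atlas, gm, scheme = NULL) {
  stopifnot(inherits(atlas, "label_atlas"), inherits(gm, "binary_mask"))
  if (!same_grid(atlas$volume, gm))
    stop_petsuvr("atlas and mask are not on the same grid", "geometry")
  out <- atlas$volume$data * gm$data
  if (sum(out) == 0)
    stop_petsuvr("grey-matter masking removed every labelled voxel", "emptiness")
  masked <- label_atlas(volume(out, atlas$volume$affine), atlas$label_names)
  if (!is.null(scheme)) {
    for (rg in setdiff(scheme$region_names, "global")) {
      if (voxel_count(region_mask(masked, scheme, rg)) == 0)
        stop_petsuvr(sprintf("grey-matter masking emptied region '%s'", rg), "emptiness")
    }
  }
  masked
}
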