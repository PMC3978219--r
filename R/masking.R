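#' Probability maps and binary masks
#'
#' `probability_map()` validates a volume as a per-voxel probability (values
#' in \[0, 1\]); `binary_mask()` validates a strictly 0/1 volume;
#' `binarize_probability()` thresholds a probability map with a *strict*
#' inequality — a voxel is kept only if its probability exceeds the
#' threshold, so at the default 0.3 exactly-0.3 voxels are excluded.
#'
#' @param vol A `pet_volume`.
#' @return `probability_map()` / `binary_mask()` return classed volumes;
#'   `binarize_probability()` returns a `binary_mask`.
#' @export
probability_map <- function(vol) {
  stopifnot(inherits(vol, "pet_volume"))
  if (min(vol$data) < -1e-6 || max(vol$data) > 1 + 1e-6)
    stop_petsuvr("probability map values must lie in [0, 1]", "format")
  structure(vol, class = c("probability_map", "pet_volume"))
}

#' @rdname probability_map
#' @export
binary_mask <- function(vol) {
  stopifnot(inherits(vol, "pet_volume"))
  if (!all(vol$data %in% c(0, 1)))
    stop_petsuvr("mask values must be strictly 0 or 1", "format")
  structure(vol, class = c("binary_mask", "pet_volume"))
}

#' @rdname probability_map
#' @param map A `probability_map` (a plain `pet_volume` is validated first).
#' @param threshold Probability threshold in (0, 1); default 0.3.
#' @export
binarize_probability <- function(map, threshold = 0.3) {
  if (!inherits(map, "probability_map")) map <- probability_map(map)
  if (threshold <= 0 || threshold >= 1)
    stop_petsuvr("threshold must lie strictly inside (0, 1)", "usage")
  m <- (map$data > threshold) * 1.0
  if (sum(m) == 0)
    stop_petsuvr(sprintf("binarisation at %.3g produced an empty mask", threshold), "emptiness")
  binary_mask(volume(m, map$affine))
}

#' @rdname probability_map
#' @param x A `binary_mask`.
#' @export
voxel_count <- function(x) {
  stopifnot(inherits(x, "binary_mask"))
  sum(x$data)
}

#' Tissue segmentation of a T1 image
#'
#' Three-class (CSF / grey matter / white matter) soft segmentation by a
#' Gaussian mixture fitted to the intensities inside an automatic brain
#' mask. This is an intensity-only stand-in for full anatomical segmentation
#' pipelines: no spatial priors or MRF regularisation are applied, which is
#' adequate for phantom data and clean T1 contrast. Classes are identified
#' by their mean-intensity rank (CSF < GM < WM for T1-like contrast), so the
#' labelling is deterministic.
#'
#' @param t1 `pet_volume` with T1-weighted contrast.
#' @param brain_mask Optional `binary_mask` restricting the fit; by default
#'   voxels above 18% of the 99.5th intensity percentile are used.
#' @param max_fit_voxels Number of voxels (deterministic stride subsample)
#'   used to fit the mixture; posteriors are then evaluated at every brain
#'   voxel.
#' @return A list of three `probability_map`s: `csf`, `gm`, `wm`. Inside the
#'   brain they sum to 1; outside they are 0.
#' @export
segment_tissues <- function(t1, brain_mask = NULL, max_fit_voxels = 20000L) {
  stopifnot(inherits(t1, "pet_volume"))
  if (is.null(brain_mask)) {
    thr <- 0.18 * quantile(t1$data, 0.995, names = FALSE)
    inside <- t1$data > thr
  } else {
    stopifnot(inherits(brain_mask, "binary_mask"))
    inside <- brain_mask$data > 0
  }
  vals <- t1$data[inside]
  if (length(vals) < 100 || diff(quantile(vals, c(0.02, 0.98), names = FALSE)) <
      0.05 * max(abs(vals)))
    stop_petsuvr("T1 intensities show fewer than three distinguishable modes; cannot segment",
                 "segmentation")
  stride <- max(1L, length(vals) %/% max_fit_voxels)
  fit_vals <- vals[seq(1L, length(vals), by = stride)]
  fit <- tryCatch({
    bic <- mclust::mclustBIC(fit_vals, G = 3, modelNames = "V", verbose = FALSE)
    mclust::Mclust(fit_vals, G = 3, modelNames = "V", x = bic, verbose = FALSE)
  }, error = function(e) NULL)
  if (!is.null(fit) && !is.null(fit$parameters) &&
      length(unique(round(fit$parameters$mean, 8))) == 3) {
    mu <- fit$parameters$mean
    sig <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sig) == 1) sig <- rep(sig, 3)
    pro <- fit$parameters$pro
  } else {
    # (near-)noiseless intensities defeat the mixture EM (zero within-class
    # variance); fall back to 3-means on the same values
    uniq <- sort(unique(fit_vals))
    ctrs <- if (length(uniq) <= 10) {
      freq <- table(fit_vals)
      sort(as.numeric(names(sort(freq, decreasing = TRUE)[1:3])))
    } else {
      quantile(fit_vals, c(0.1, 0.5, 0.9), names = FALSE)
    }
    if (length(unique(ctrs)) < 3)
      stop_petsuvr("could not separate three tissue intensity modes", "segmentation")
    km <- tryCatch(stats::kmeans(fit_vals, centers = ctrs, iter.max = 50),
                   error = function(e) NULL)
    if (is.null(km) || length(unique(round(km$centers, 8))) < 3)
      stop_petsuvr("could not separate three tissue intensity modes", "segmentation")
    mu <- as.numeric(km$centers)
    sig <- vapply(1:3, function(k) {
      s <- sd(fit_vals[km$cluster == k])
      if (!is.finite(s) || s == 0) diff(range(fit_vals)) * 1e-4 else s
    }, numeric(1))
    pro <- tabulate(km$cluster, 3) / length(fit_vals)
  }
  ord <- order(mu)  # CSF < GM < WM
  dens <- vapply(1:3, function(k) pro[k] * dnorm(vals, mu[k], max(sig[k], 1e-8)),
                 numeric(length(vals)))
  tot <- rowSums(dens)
  tot[tot == 0] <- 1
  maps <- lapply(ord, function(k) {
    arr <- array(0, dim(t1$data))
    arr[inside] <- dens[, k] / tot
    probability_map(volume(arr, t1$affine))
  })
  names(maps) <- c("csf", "gm", "wm")
  maps
}
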