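#' Intensity-based affine registration
#'
#' Estimates the 6/9/12-degree-of-freedom affine transform mapping the moving
#' volume's world space onto the fixed volume's world space by minimising an
#' intensity cost over a multi-resolution pyramid (smoothed and downsampled
#' by 4x, 2x, then full resolution). The search is a derivative-free
#' Nelder-Mead descent over the active parameters, initialised at the
#' centre-of-mass alignment of the two images; it is fully deterministic for
#' fixed inputs and settings.
#'
#' Cost functions: `correlation_ratio` (variance of the moving intensities
#' conditioned on binned fixed intensities; the default for cross-modal
#' pairs such as CT to T1 or PET to a tracer template),
#' `normalized_correlation` (1 - |Pearson r|, for same-modality pairs), and
#' `mean_squares`.
#'
#' @param moving,fixed `pet_volume` objects with overlapping fields of view
#'   and at least 16 voxels per axis.
#' @param dof Degrees of freedom: 6 (rigid), 9 (+scales) or 12 (+shears).
#' @param cost Cost function (see Details).
#' @param control List of settings: `levels` (downsampling factors, default
#'   `c(4, 2, 1)`), `maxit` per level (default 200), `reltol` for the simplex
#'   (default 1e-6), `nbins` for the correlation ratio (default 32).
#' @param init Optional `affine_transform` starting estimate; default is
#'   centre-of-mass alignment.
#' @return A `registration_result`: list with `transform`
#'   (`affine_transform`), `final_cost`, `n_iterations`, `converged`, plus
#'   the `cost` and `dof` used.
#' @export
register_affine <- function(moving, fixed, dof = 12,
                            cost = c("correlation_ratio", "normalized_correlation", "mean_squares"),
                            control = list(), init = NULL) {
  cost <- match.arg(cost)
  stopifnot(inherits(moving, "pet_volume"), inherits(fixed, "pet_volume"))
  if (any(dim(moving$data) < 16L) || any(dim(fixed$data) < 16L))
    stop_petsuvr("registration needs at least 16 voxels per axis in both volumes", "geometry")
  if (!fov_overlap(moving, fixed))
    stop_petsuvr("moving and fixed fields of view do not overlap in world space", "geometry")
  ctrl <- modifyList(list(levels = c(4, 2, 1), maxit = 200, reltol = 1e-6,
                          nbins = 32L, restarts = 1L),
                     control)
  dof <- match.arg(as.character(dof), c("6", "9", "12"))
  n_active <- as.integer(dof)

  p0 <- if (is.null(init)) com_init_params(moving, fixed) else init$params
  active <- seq_len(n_active)
  parscale <- c(1, 1, 1, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02)

  p_init <- p0
  total_it <- 0L
  converged <- TRUE
  fcost <- NA_real_
  level_fn <- NULL
  nlev <- length(ctrl$levels)
  for (li in seq_len(nlev)) {
    f <- ctrl$levels[li]
    mv <- pyramid_level(moving, f)
    fx <- pyramid_level(fixed, f)
    # progressive degrees of freedom: rigid at the coarsest level, scales at
    # the middle, shears only at full resolution — keeps the coarse search
    # out of the affine self-map family of near-ellipsoidal objects
    dof_here <- if (li == nlev) n_active else if (li == nlev - 1) min(n_active, 9L) else min(n_active, 6L)
    active <- seq_len(dof_here)
    fn <- function(pa) {
      p <- p0; p[active] <- pa
      registration_cost(p, mv, fx, cost, ctrl$nbins)
    }
    opt <- optim(p0[active], fn, method = "Nelder-Mead",
                 control = list(maxit = ctrl$maxit, reltol = ctrl$reltol,
                                parscale = parscale[active]))
    p0[active] <- opt$par
    total_it <- total_it + opt$counts[["function"]]
    fcost <- opt$value
    if (opt$convergence != 0) converged <- FALSE
    level_fn <- fn
    if (li == nlev) {
      for (r in seq_len(ctrl$restarts)) {
        # fresh simplex around the current optimum sharpens the final fit
        opt <- optim(p0[active], fn, method = "Nelder-Mead",
                     control = list(maxit = ctrl$maxit, reltol = ctrl$reltol,
                                    parscale = parscale[active]))
        p0[active] <- opt$par
        total_it <- total_it + opt$counts[["function"]]
        fcost <- opt$value
      }
    }
  }
  active <- seq_len(n_active)
  # guard against a coarse level having wandered into a basin that the full
  # resolution cannot repair: never return worse than the initialisation
  c_init <- level_fn(p_init[active])
  if (c_init < fcost) {
    p0 <- p_init
    opt <- optim(p_init[active], level_fn, method = "Nelder-Mead",
                 control = list(maxit = ctrl$maxit, reltol = ctrl$reltol,
                                parscale = parscale[active]))
    p0[active] <- opt$par
    total_it <- total_it + opt$counts[["function"]]
    fcost <- opt$value
    if (opt$convergence != 0) converged <- FALSE
  }
  if (!converged)
    warn("registration stopped at the iteration cap before the simplex converged")
  structure(list(transform = affine_transform(p0), final_cost = fcost,
                 n_iterations = total_it, converged = converged,
                 cost = cost, dof = n_active),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %d-DOF, cost %s = %.6g, %d evaluations, %s\n",
              x$dof, x$cost, x$final_cost, x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(x$transform)
  invisible(x)
}

fov_overlap <- function(a, b) {
  corners <- function(v) {
    d <- dim(v$data) - 1
    ijk <- as.matrix(expand.grid(c(0, d[1]), c(0, d[2]), c(0, d[3])))
    sweep(ijk %*% t(v$affine[1:3, 1:3]), 2, v$affine[1:3, 4], `+`)
  }
  ca <- corners(a); cb <- corners(b)
  all(apply(ca, 2, max) >= apply(cb, 2, min) & apply(cb, 2, max) >= apply(ca, 2, min))
}

# centre-of-mass initial translation (intensity-weighted, world space)
com_init_params <- function(moving, fixed) {
  com_world <- function(v) {
    d <- dim(v$data)
    w <- pmax(v$data, 0)
    tot <- sum(w)
    if (tot <= 0) {
      ctr <- (d - 1) / 2
    } else {
      wi <- apply(w, 1, sum); wj <- apply(w, 2, sum); wk <- apply(w, 3, sum)
      ctr <- c(sum((seq_len(d[1]) - 1) * wi), sum((seq_len(d[2]) - 1) * wj),
               sum((seq_len(d[3]) - 1) * wk)) / tot
    }
    as.numeric(v$affine[1:3, 1:3] %*% ctr + v$affine[1:3, 4])
  }
  tr <- com_world(fixed) - com_world(moving)
  c(tr, 0, 0, 0, 1, 1, 1, 0, 0, 0)
}

# smooth + stride-subsample a volume by integer factor
pyramid_level <- function(vol, factor) {
  if (factor <= 1) return(vol)
  sm <- smooth_volume(vol, fwhm_mm = mean(voxel_sizes(vol)) * factor)
  d <- dim(sm$data)
  idx <- lapply(d, function(n) seq(1L, n, by = as.integer(factor)))
  data <- sm$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  aff <- sm$affine %*% diag(c(factor, factor, factor, 1))
  structure(list(data = data, affine = aff), class = "pet_volume")
}

registration_cost <- function(params, moving, fixed, cost, nbins) {
  tr <- tryCatch(affine_transform(params), error = function(e) NULL)
  if (is.null(tr)) return(1e10)
  m <- resample(moving, tr, grid_of(fixed), "trilinear", fill = NA_real_)$data
  ok <- !is.na(m)
  frac <- mean(ok)
  if (frac < 0.05) return(1e10)
  mv <- m[ok]; fv <- fixed$data[ok]
  penalty <- 1 + 4 * max(0, 0.5 - frac)  # discourage shrinking the overlap
  val <- switch(cost,
    mean_squares = mean((mv - fv)^2),
    normalized_correlation = {
      if (sd(mv) == 0 || sd(fv) == 0) 1 else 1 - abs(stats::cor(mv, fv))
    },
    correlation_ratio = {
      rng <- range(fv)
      if (diff(rng) == 0 || var(mv) == 0) return(1 * penalty)
      bin <- pmin(nbins, 1L + as.integer((fv - rng[1]) / diff(rng) * nbins))
      n_k <- tabulate(bin, nbins)
      s1 <- rowsum_vec(mv, bin, nbins)
      s2 <- rowsum_vec(mv * mv, bin, nbins)
      within <- sum(pmax(0, s2 - s1^2 / pmax(n_k, 1)))
      tot <- sum(mv * mv) - sum(mv)^2 / length(mv)
      within / tot
    })
  val * penalty
}

rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

#' Resample a label atlas through an affine transform
#'
#' Each label's indicator image is resampled with trilinear interpolation
#' onto the target grid; a voxel is assigned the label whose interpolated
#' weight is highest, provided that weight exceeds 0.5 (the binarisation
#' threshold). No label absent from the input can appear in the output.
#'
#' @param atlas A `label_atlas` (see [label_atlas()]).
#' @param transform `affine_transform` from atlas world space to target world
#'   space.
#' @param target `grid_spec` for the output.
#' @return A `label_atlas` on the target grid.
#' @export
transform_labels <- function(atlas, transform, target) {
  stopifnot(inherits(atlas, "label_atlas"))
  if (inherits(target, "pet_volume")) target <- grid_of(target)
  labs <- sort(unique(as.integer(atlas$volume$data)))
  labs <- labs[labs > 0]
  best_w <- array(0, target$shape)
  best_l <- array(0L, target$shape)
  for (lb in labs) {
    ind <- structure(list(data = (atlas$volume$data == lb) * 1.0,
                          affine = atlas$volume$affine), class = "pet_volume")
    w <- resample(ind, transform, target, "trilinear", fill = 0)$data
    take <- w > 0.5 & w > best_w
    best_l[take] <- lb
    best_w[take] <- w[take]
  }
  label_atlas(volume(best_l * 1.0, target$affine), atlas$label_names)
}
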