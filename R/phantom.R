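#' Specify a synthetic shell phantom
#'
#' Describes an ellipsoidal pericardial "sac" containing a fat shell of known
#' angular thickness, voxelised onto an anisotropic CT-like lattice. Defaults
#' emulate a non-contrast calcium-score acquisition: 0.5 x 0.5 mm in-plane
#' spacing with 2.5 mm slices, fat attenuation in \[-190, -30\] HU,
#' myocardium/blood interior around 40 HU and air background at -1000 HU.
#'
#' @param shape grid dimensions (voxels).
#' @param spacing voxel spacing (mm).
#' @param semi_axes ellipsoid semi-axes `c(a, b, c)` in mm, aligned with the
#'   grid axes unless `rotation` is given; must fit in the grid with a
#'   2-voxel margin.
#' @param thickness fat-shell thickness: a single non-negative number (mm) or
#'   a function `f(theta, phi)` of azimuth/polar angle (radians) returning mm.
#'   Must not exceed `min(semi_axes)/2`.
#' @param fat_hu fat HU distribution: `list(family = "normal", mean, sd)`
#'   (truncated to the fat window) or `list(family = "uniform", min, max)`.
#' @param fat_window HU support of the fat distribution.
#' @param interior_hu HU of non-fat sac interior.
#' @param background_hu HU outside the sac.
#' @param noise_sd additive Gaussian noise sd (HU), applied everywhere.
#' @param rotation optional 3x3 rotation matrix applied to the ellipsoid.
#' @param seed integer seed driving all randomness of the phantom.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(160, 160, 40),
                         spacing = c(0.5, 0.5, 2.5),
                         semi_axes = c(38, 34, 30),
                         thickness = 6,
                         fat_hu = list(family = "normal", mean = -100, sd = 25),
                         fat_window = c(-190, -30),
                         interior_hu = 40,
                         background_hu = -1000,
                         noise_sd = 0,
                         rotation = NULL,
                         seed = 1L) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  semi_axes <- as.numeric(semi_axes)
  stopifnot(length(shape) == 3, length(spacing) == 3, all(spacing > 0),
            length(semi_axes) == 3, all(semi_axes > 0))
  t_fun <- if (is.function(thickness)) thickness
           else { tc <- as.numeric(thickness); function(theta, phi) rep(tc, length(theta)) }
  ang <- expand.grid(theta = seq(0, 2 * pi, length.out = 73),
                     phi = seq(0, pi, length.out = 37))
  tv <- t_fun(ang$theta, ang$phi)
  if (any(tv < 0)) stop("thickness function must be non-negative")
  if (max(tv) > min(semi_axes) / 2)
    stop(sprintf("shell thicker than the ellipsoid allows: max t = %.1f mm > min(semi-axes)/2 = %.1f mm",
                 max(tv), min(semi_axes) / 2))
  R <- if (is.null(rotation)) diag(3) else {
    rotation <- as.matrix(rotation)
    stopifnot(all(dim(rotation) == c(3, 3)))
    if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
      stop("`rotation` must be orthonormal")
    rotation
  }
  # bounding half-extent of the rotated ellipsoid along each grid axis
  half_ext <- sqrt(colSums((R * semi_axes)^2))
  if (any(half_ext + 2 * spacing > (shape * spacing) / 2))
    stop("semi-axes do not fit inside the grid with a 2-voxel margin")
  structure(list(shape = shape, spacing = spacing, semi_axes = semi_axes,
                 thickness = t_fun, fat_hu = fat_hu, fat_window = fat_window,
                 interior_hu = interior_hu, background_hu = background_hu,
                 noise_sd = noise_sd, rotation = R, seed = as.integer(seed)),
            class = "phantom_spec")
}

draw_fat_hu <- function(n, dist, window) {
  if (n == 0) return(numeric(0))
  fam <- match.arg(dist$family, c("normal", "uniform"))
  if (fam == "uniform") {
    lo <- max(dist$min, window[1]); hi <- min(dist$max, window[2])
    return(stats::runif(n, lo, hi))
  }
  # truncated normal by rejection; the default (-100, 25) accepts ~97%
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, dist$mean, dist$sd)
    out <- c(out, x[x >= window[1] & x <= window[2]])
  }
  out[seq_len(n)]
}

#' Voxelise a shell phantom
#'
#' Builds the CT volume, sac mask and fat (EAT) mask described by a
#' [phantom_spec()], together with a ground-truth record. A voxel belongs to
#' a region iff its centre lies inside the region: the sac is the ellipsoid
#' interior; fat is the sac subset whose radial coordinate (ellipsoid frame)
#' exceeds the local surface radius minus the angular thickness.
#'
#' @param spec a `phantom_spec`.
#' @return list with `ct` ([image_volume()]), `sac`, `eat` ([mask_volume()])
#'   and `truth`: exact voxel counts and volumes (mm^3), the analytic shell
#'   volume for spherical constant-thickness phantoms, per-angle thickness on
#'   the 1-degree sweep grid, semi-axes, and fat-HU sample moments.
#' @export
make_shell_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set_seed_if(spec$seed)
  d <- spec$shape; sp <- spec$spacing
  centre <- (d - 1) / 2 * sp
  xs <- (seq_len(d[1]) - 1) * sp[1] - centre[1]
  ys <- (seq_len(d[2]) - 1) * sp[2] - centre[2]
  zs <- (seq_len(d[3]) - 1) * sp[3] - centre[3]
  px <- array(xs, d)
  py <- array(rep(ys, each = d[1]), d)
  pz <- array(rep(zs, each = d[1] * d[2]), d)
  # coordinates in the ellipsoid frame
  Rt <- t(spec$rotation)
  ex <- Rt[1, 1] * px + Rt[1, 2] * py + Rt[1, 3] * pz
  ey <- Rt[2, 1] * px + Rt[2, 2] * py + Rt[2, 3] * pz
  ez <- Rt[3, 1] * px + Rt[3, 2] * py + Rt[3, 3] * pz
  a <- spec$semi_axes
  q <- (ex / a[1])^2 + (ey / a[2])^2 + (ez / a[3])^2
  sac <- q <= 1
  r <- sqrt(ex^2 + ey^2 + ez^2)
  rr <- pmax(r, .Machine$double.eps)
  # surface radius along each voxel's direction, and local shell thickness
  r_surf <- 1 / sqrt((ex / rr / a[1])^2 + (ey / rr / a[2])^2 + (ez / rr / a[3])^2)
  theta <- atan2(ey, ex); theta[theta < 0] <- theta[theta < 0] + 2 * pi
  phi <- acos(pmin(pmax(ez / rr, -1), 1))
  tloc <- array(spec$thickness(as.vector(theta), as.vector(phi)), d)
  fat <- sac & (r >= r_surf - tloc) & (tloc > 0)

  ct <- array(spec$background_hu, d)
  ct[sac] <- spec$interior_hu
  nfat <- sum(fat)
  hu <- draw_fat_hu(nfat, spec$fat_hu, spec$fat_window)
  ct[fat] <- hu
  if (spec$noise_sd > 0) ct <- ct + stats::rnorm(length(ct), 0, spec$noise_sd)

  vv <- prod(sp)
  th_grid <- outer(seq(0, 359) * pi / 180, seq(0, 179) * pi / 180,
                   function(th, ph) spec$thickness(th, ph))
  spherical <- diff(range(a)) < 1e-9
  const_t <- diff(range(th_grid)) < 1e-9
  analytic <- if (spherical && const_t) {
    t0 <- th_grid[1]
    4 / 3 * pi * (a[1]^3 - (a[1] - t0)^3)
  } else NA_real_
  truth <- list(
    semi_axes = a,
    centre = centre,
    n_sac_voxels = sum(sac), n_fat_voxels = nfat,
    sac_volume_mm3 = sum(sac) * vv,
    fat_volume_mm3 = nfat * vv,
    fat_volume_analytic_mm3 = analytic,
    thickness_field = th_grid,
    hu_mean = if (nfat) mean(hu) else NA_real_,
    hu_sd = if (nfat) stats::sd(hu) else NA_real_,
    # surface voxel count bounds the voxelisation error of the shell volume
    n_surface_voxels = local({
      db <- .edt_anisotropic(array(as.integer(sac), d), d, sp)
      sum(sac & db <= sqrt(sum(sp^2)))
    })
  )
  list(ct = image_volume(ct, sp),
       sac = mask_volume(array(as.integer(sac), d), sp),
       eat = mask_volume(array(as.integer(fat), d), sp),
       truth = truth)
}

#' Specify a survival simulation
#'
#' Event times follow an exponential proportional-hazards model:
#' `T = -log(U) / (lambda0 * exp(x' beta))` with independent uniform
#' censoring on `[0, t_max]`. Features come from a multivariate normal or are
#' supplied directly (e.g., a phantom-batch feature table).
#'
#' @param n number of subjects (ignored if `features` given).
#' @param p number of features when simulating from a standard normal.
#' @param mean,cov optional MVN parameters (defaults: zero mean, identity).
#' @param features optional data.frame/matrix of features to use as-is
#'   (numeric columns; an `id` column is honoured).
#' @param beta named numeric vector of true log-hazard coefficients; names
#'   must exist among the feature columns.
#' @param lambda0 baseline hazard (per day); default gives a median event
#'   time of about 600 days at `x' beta = 0`.
#' @param t_max censoring horizon in days (`Inf` = no censoring); default 6
#'   years of follow-up.
#' @param seed integer seed.
#' @return A `simsurv_spec` list.
#' @export
simsurv_spec <- function(n = 400, p = 50, mean = NULL, cov = NULL,
                         features = NULL, beta,
                         lambda0 = log(2) / 600, t_max = 2190,
                         seed = 1L) {
  stopifnot(is.numeric(beta), !is.null(names(beta)), lambda0 > 0)
  structure(list(n = as.integer(n), p = as.integer(p), mean = mean, cov = cov,
                 features = features, beta = beta, lambda0 = lambda0,
                 t_max = t_max, seed = as.integer(seed)),
            class = "simsurv_spec")
}

#' Simulate survival data with a known linear predictor
#'
#' @param spec a [simsurv_spec()].
#' @return list with `features` (data.frame incl. `id`), `surv` (a
#'   `survival_table`) and `truth` (`beta`, per-subject linear predictor and
#'   uncensored event times).
#' @export
simulate_survival <- function(spec) {
  stopifnot(inherits(spec, "simsurv_spec"))
  set_seed_if(spec$seed)
  if (is.null(spec$features)) {
    p <- spec$p; n <- spec$n
    mu <- if (is.null(spec$mean)) rep(0, p) else spec$mean
    sg <- if (is.null(spec$cov)) diag(p) else spec$cov
    X <- MASS::mvrnorm(n, mu = mu, Sigma = sg)
    colnames(X) <- if (!is.null(names(mu)) && !is.null(spec$mean)) names(mu)
                   else paste0("f", seq_len(p))
    ids <- paste0("S", seq_len(n))
  } else {
    fdf <- as.data.frame(spec$features)
    ids <- if ("id" %in% names(fdf)) as.character(fdf$id)
           else paste0("S", seq_len(nrow(fdf)))
    fdf$id <- NULL
    X <- as.matrix(fdf)
    n <- nrow(X)
  }
  missing_beta <- setdiff(names(spec$beta), colnames(X))
  if (length(missing_beta))
    stop("beta names not among the features: ",
         paste(missing_beta, collapse = ", "))
  lp <- as.vector(X[, names(spec$beta), drop = FALSE] %*% spec$beta)
  u <- stats::runif(n)
  t_event <- -log(u) / (spec$lambda0 * exp(lp))
  c_time <- if (is.finite(spec$t_max)) stats::runif(n, 0, spec$t_max)
            else rep(Inf, n)
  time <- pmin(t_event, c_time)
  event <- as.integer(t_event <= c_time)
  time <- pmax(time, 1e-6)  # survival_table requires strictly positive times
  surv <- validate_survival_table(
    data.frame(id = ids, time = time, event = event,
               stringsAsFactors = FALSE))
  list(features = data.frame(id = ids, X, check.names = FALSE),
       surv = surv,
       truth = list(beta = spec$beta, linear_predictor = lp,
                    event_time = t_event))
}
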