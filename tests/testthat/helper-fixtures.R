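# Shared fixtures, built once per session and cached (phantom voxelisation
# and ray sweeps are the expensive parts of the suite).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 40 mm spherical sac with a constant 6 mm fat shell on the CT calcium-score
# lattice (0.5 x 0.5 mm in-plane, 2.5 mm slices)
sphere_fine <- function() fixture("sphere_fine", function()
  make_shell_phantom(phantom_spec(
    shape = c(176, 176, 40), spacing = c(0.5, 0.5, 2.5),
    semi_axes = c(40, 40, 40), thickness = 6, seed = 7)))

# axis-aligned ellipsoid, diameters 120 x 90 x 60 mm
ellipsoid_coarse <- function(rotation = NULL) {
  key <- if (is.null(rotation)) "ellipsoid" else
    paste0("ellipsoid_rot", signif(sum(rotation), 6))
  fixture(key, function()
    make_shell_phantom(phantom_spec(
      shape = c(134, 134, 56), spacing = c(1, 1, 2.5),
      semi_axes = c(60, 45, 30), thickness = 5, seed = 3,
      rotation = rotation)))
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
}

# axis-aligned box mask (1-based inclusive index ranges)
box_mask <- function(dims, spacing, i, j, k) {
  a <- array(0L, dims)
  a[i[1]:i[2], j[1]:j[2], k[1]:k[2]] <- 1L
  mask_volume(a, spacing)
}

# solid isotropic sphere mask of radius R (mm) at spacing h
solid_sphere_mask <- function(R, h) {
  n <- ceiling(2 * R / h) + 7
  ctr <- (n - 1) / 2 * h
  xs <- (0:(n - 1)) * h - ctr
  px <- array(xs, c(n, n, n))
  py <- aperm(px, c(2, 1, 3))
  pz <- aperm(px, c(3, 2, 1))
  a <- array(0L, c(n, n, n))
  a[px^2 + py^2 + pz^2 <= R^2] <- 1L
  mask_volume(a, rep(h, 3))
}

# independent all-pairs concordance oracle: explicit double loop
brute_force_cindex <- function(risk, time, event) {
  usable <- 0; conc <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- (time[i] < time[j] && event[i] == 1) ||
          (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!ok) next
    usable <- usable + 1
    if (risk[i] > risk[j]) conc <- conc + 1
    else if (risk[i] == risk[j]) conc <- conc + 0.5
  }
  conc / usable
}

# hand product-limit estimator at each distinct event time
hand_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  vapply(tt, function(u) {
    d <- sum(time == u & event == 1)
    r <- sum(time >= u)
    s <<- s * (1 - d / r)
    s
  }, numeric(1)) -> surv
  data.frame(time = tt, surv = surv)
}
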