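# ---- voxel grid helpers -----------------------------------------------------

# linear index of voxel coordinates (1-based) on a grid
voxel_index <- function(coords, grid_dim) {
  coords <- matrix(coords, ncol = 3)
  (coords[, 3] - 1) * grid_dim[1] * grid_dim[2] +
    (coords[, 2] - 1) * grid_dim[1] + coords[, 1]
}

voxel_coords <- function(idx, grid_dim) {
  idx0 <- idx - 1L
  x <- idx0 %% grid_dim[1]
  y <- (idx0 %/% grid_dim[1]) %% grid_dim[2]
  z <- idx0 %/% (grid_dim[1] * grid_dim[2])
  cbind(x = x + 1L, y = y + 1L, z = z + 1L)
}

#' Spherical voxel mask
#'
#' All voxels whose Euclidean distance (in voxel units) from `center` is at
#' most `radius`, clipped at the grid boundary. The sphere-ROI unit follows
#' the source convention of a radius expressed in voxels; with large voxels
#' a millimetre radius may be intended instead — set `radius` accordingly.
#'
#' @param center Integer voxel coordinates (x, y, z), inside the grid.
#' @param radius Radius in voxel units (0 gives exactly the centre voxel).
#' @param grid_dim Grid dimensions.
#' @return Integer vector of linear voxel indices.
#' @export
sphere_mask <- function(center, radius, grid_dim) {
  if (length(center) != 3L || length(grid_dim) != 3L)
    stopf("center and grid_dim must have length 3")
  if (any(center < 1 | center > grid_dim)) stopf("center lies outside the grid")
  if (radius < 0) stopf("radius must be non-negative")
  r <- floor(radius)
  rng <- lapply(1:3, function(d)
    max(1, center[d] - r):min(grid_dim[d], center[d] + r))
  box <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  d2 <- (box[, 1] - center[1])^2 + (box[, 2] - center[2])^2 + (box[, 3] - center[3])^2
  sort(voxel_index(box[d2 <= radius^2, , drop = FALSE], grid_dim))
}

# separable Gaussian smoothing of a voxels-by-time matrix (grid in rows)
# via banded kernel matrices along each axis
smooth_matrix_gaussian <- function(M, grid_dim, sigma) {
  if (sigma <= 0) return(M)
  kern1d <- function(n) {
    d <- outer(seq_len(n), seq_len(n), function(i, j) i - j)
    K <- exp(-d^2 / (2 * sigma^2))
    K[abs(d) > ceiling(3 * sigma)] <- 0
    K / rowSums(K)
  }
  nx <- grid_dim[1]; ny <- grid_dim[2]; nz <- grid_dim[3]
  nt <- ncol(M)
  A <- array(M, dim = c(nx, ny, nz * nt))
  Kx <- kern1d(nx); Ky <- kern1d(ny); Kz <- kern1d(nz)
  # along x
  A <- array(Kx %*% matrix(A, nrow = nx), dim = c(nx, ny, nz * nt))
  # along y
  A <- aperm(A, c(2, 1, 3))
  A <- array(Ky %*% matrix(A, nrow = ny), dim = c(ny, nx, nz * nt))
  A <- aperm(A, c(2, 1, 3))
  # along z (fold time out first)
  A <- array(A, dim = c(nx, ny, nz, nt))
  A <- aperm(A, c(3, 1, 2, 4))
  A <- array(Kz %*% matrix(A, nrow = nz), dim = c(nz, nx, ny, nt))
  A <- aperm(A, c(2, 3, 1, 4))
  matrix(A, nrow = nx * ny * nz)
}

#' Noise specification for the BOLD simulator
#'
#' @param ar1 Temporal lag-1 autocorrelation of the voxel noise.
#' @param sd Innovation standard deviation in percent-signal-change units
#'   (before spatial smoothing).
#' @param smooth_sigma Spatial Gaussian kernel width (voxels) applied to the
#'   noise field.
#' @return List of class `ambicon_noise_spec`.
#' @export
noise_spec <- function(ar1 = 0.3, sd = 0.5, smooth_sigma = 1) {
  if (abs(ar1) >= 1) stopf("ar1 must lie in (-1, 1)")
  if (sd <= 0) stopf("innovation sd must be positive")
  structure(list(ar1 = ar1, sd = sd, smooth_sigma = smooth_sigma),
            class = "ambicon_noise_spec")
}

#' Default planted-effect pattern
#'
#' Four spherical regions mirroring the reported effect pattern: a
#' ventromedial-prefrontal-like region with a negative ambiguity-level slope
#' (-0.015 PSC per card), a ventral-striatum-like region with a positive
#' conflict-level slope (+0.002 PSC per card), a medial-prefrontal-like
#' region whose ambiguity main effect couples to ambiguity aversion
#' (`ln gamma_A`, target correlation +0.61), and a second striatal region
#' whose conflict main effect couples to conflict aversion (`gamma_C`,
#' target correlation -0.67).
#'
#' @param grid_dim Grid dimensions; centres scale with the grid.
#' @param radius Region radius in voxels.
#' @return Data frame with one row per region: `name`, `x`, `y`, `z`,
#'   `radius`, `regressor`, `amplitude`, `amplitude_sd`, `couple_to`,
#'   `couple_r`.
#' @export
default_planted_effects <- function(grid_dim = c(24, 24, 24), radius = 3) {
  frac <- rbind(vmPFC = c(0.28, 0.30, 0.25),
                left_VS = c(0.72, 0.30, 0.72),
                mPFC = c(0.28, 0.72, 0.72),
                right_VS = c(0.72, 0.72, 0.28))
  centers <- t(apply(frac, 1, function(f) pmax(1, round(f * grid_dim))))
  data.frame(
    name = rownames(frac),
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    radius = radius,
    regressor = c("ambiguity_level", "conflict_level", "ambiguity", "conflict"),
    amplitude = c(-0.015, 0.002, 0.3, 0.3),
    amplitude_sd = c(0.003, 0.0005, 0.15, 0.15),
    couple_to = c(NA, NA, "ln_gamma_a", "gamma_c"),
    couple_r = c(NA, NA, 0.61, -0.67),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# per-subject amplitudes for one region: coupled regions realise the target
# correlation exactly in the sampled cohort (residualisation construction)
planted_amplitudes <- function(region, cohort, seed) {
  n <- nrow(cohort)
  with_seed(seed, {
    if (is.na(region$couple_to)) {
      rnorm(n, region$amplitude, region$amplitude_sd)
    } else {
      z <- as.vector(scale(cohort[[region$couple_to]]))
      e <- rnorm(n)
      e <- e - z * sum(e * z) / sum(z * z)   # empirically orthogonal to z
      e <- e / sd(e)
      r <- region$couple_r
      a <- r * z + sqrt(1 - r^2) * e
      a <- a / sd(a)
      region$amplitude + region$amplitude_sd * a
    }
  })
}

#' Simulate a cohort's voxelwise BOLD data with planted effects
#'
#' Per subject and run, the signal is the subject's first-level design
#' matrix (main model, including that subject's response times) multiplied
#' by region amplitudes: every voxel of a planted region responds to the
#' region's designated regressor with the subject's amplitude (drawn around
#' the region mean; attitude-coupled regions realise their target
#' between-subject correlation exactly in the sampled cohort). AR(1) noise
#' with the requested innovation SD is added after spatial Gaussian
#' smoothing of the noise field; the planted signal itself is not smoothed,
#' so planted per-unit amplitudes are exactly recoverable. Output is raw
#' intensity around a baseline of 100, so percent-signal-change conversion
#' is part of the analysis path.
#'
#' @param cohort [sample_population()] output.
#' @param sessions Per-subject session list ([simulate_cohort_choices()]).
#' @param choices_list Per-subject choice records.
#' @param planted Planted-effect table ([default_planted_effects()]); may
#'   have zero rows for pure-noise data.
#' @param grid_dim Voxel grid dimensions.
#' @param noise A [noise_spec()].
#' @param seed Integer master seed.
#' @return Object of class `ambicon_voxel_dataset`: list with `subjects`
#'   (per subject: `runs` — voxels-by-volumes raw matrices —, `session`,
#'   `choices`, `design`), `grid_dim`, `tr`, `planted`, `amplitudes`
#'   (subjects-by-regions ground truth), `cohort`, `noise`, `seed`.
#' @export
simulate_bold <- function(cohort, sessions, choices_list,
                          planted = default_planted_effects(grid_dim),
                          grid_dim = c(24, 24, 24),
                          noise = noise_spec(),
                          seed = 1L) {
  n_sub <- nrow(cohort)
  if (length(sessions) != n_sub || length(choices_list) != n_sub)
    stopf("sessions and choices_list must have one element per subject")
  nvox <- prod(grid_dim)
  if (nrow(planted) > 0) {
    for (i in seq_len(nrow(planted))) {
      ctr <- c(planted$x[i], planted$y[i], planted$z[i])
      if (any(ctr < 1 | ctr > grid_dim)) stopf("planted region outside the grid")
    }
  }
  masks <- lapply(seq_len(nrow(planted)), function(i)
    sphere_mask(c(planted$x[i], planted$y[i], planted$z[i]),
                planted$radius[i], grid_dim))
  amp <- if (nrow(planted) > 0) {
    sapply(seq_len(nrow(planted)), function(i)
      planted_amplitudes(planted[i, , drop = FALSE], cohort,
                         child_seed(seed, 900 + i)))
  } else {
    matrix(numeric(0), n_sub, 0)
  }
  if (nrow(planted) > 0) colnames(amp) <- planted$name

  subjects <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    session <- sessions[[s]]
    design <- build_design_matrix(session, choices_list[[s]])
    n_vols <- session$volumes_per_run
    runs <- vector("list", session$n_runs)
    for (r in seq_len(session$n_runs)) {
      rows <- design$run == r
      Xr <- design$X[rows, design$task_cols, drop = FALSE]
      sig <- matrix(0, nvox, n_vols)
      for (i in seq_len(nrow(planted))) {
        reg <- planted$regressor[i]
        if (!reg %in% colnames(Xr)) stopf("planted regressor %s not in design", reg)
        sig[masks[[i]], ] <- sig[masks[[i]], , drop = FALSE] +
          rep(amp[s, i] * Xr[, reg], each = length(masks[[i]]))
      }
      eps <- with_seed(child_seed(seed, s * 1000 + r), {
        innov <- matrix(rnorm(nvox * n_vols, 0, noise$sd), nvox, n_vols)
        e <- innov
        e[, 1] <- innov[, 1] / sqrt(1 - noise$ar1^2)
        for (t in 2:n_vols) e[, t] <- noise$ar1 * e[, t - 1] + innov[, t]
        smooth_matrix_gaussian(e, grid_dim, noise$smooth_sigma)
      })
      runs[[r]] <- 100 * (1 + (sig + eps) / 100)
    }
    subjects[[s]] <- list(runs = runs, session = session,
                          choices = choices_list[[s]], design = design)
  }
  names(subjects) <- cohort$subject_id
  structure(list(subjects = subjects, grid_dim = grid_dim,
                 tr = sessions[[1]]$tr, planted = planted,
                 amplitudes = amp, cohort = cohort, noise = noise,
                 seed = seed),
            class = "ambicon_voxel_dataset")
}

#' @export
print.ambicon_voxel_dataset <- function(x, ...) {
  cat(sprintf("ambicon voxel dataset: %d subjects, grid %s, %d run(s) x %d volumes, %d planted region(s)\n",
              length(x$subjects), paste(x$grid_dim, collapse = "x"),
              x$subjects[[1]]$session$n_runs,
              x$subjects[[1]]$session$volumes_per_run, nrow(x$planted)))
  invisible(x)
}

#' Generate a complete synthetic study
#'
#' Cohort, per-subject sessions and choices, and voxelwise BOLD data with
#' the default planted-effect pattern, all from one master seed.
#'
#' @param spec [population_spec()].
#' @param gambles Gamble table; default [generate_gamble_set()].
#' @param n_runs,volumes_per_run Session geometry (defaults are the
#'   desk-scale 2 runs of 120 volumes; the acquisition-scale study used 4
#'   runs of 200).
#' @param grid_dim Voxel grid.
#' @param planted Planted-effect table; `NULL` for pure noise.
#' @param noise [noise_spec()].
#' @param seed Master seed.
#' @param ... Further [build_session()] arguments (e.g. `trials_per_type`).
#' @return An `ambicon_voxel_dataset`.
#' @export
simulate_study <- function(spec = population_spec(),
                           gambles = generate_gamble_set(),
                           n_runs = 2L, volumes_per_run = 120L,
                           grid_dim = c(24, 24, 24),
                           planted = default_planted_effects(grid_dim),
                           noise = noise_spec(),
                           seed = 1L, ...) {
  cohort <- sample_population(spec, seed = child_seed(seed, 1))
  sim <- simulate_cohort_choices(cohort, gambles, seed = child_seed(seed, 2),
                                 n_runs = n_runs,
                                 volumes_per_run = volumes_per_run, ...)
  if (is.null(planted)) planted <- default_planted_effects(grid_dim)[0, ]
  simulate_bold(cohort, sim$sessions, sim$choices, planted = planted,
                grid_dim = grid_dim, noise = noise,
                seed = child_seed(seed, 3))
}
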