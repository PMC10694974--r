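# Synthetic voxel phantoms: a porous hemp-shive slab perforated by two
# classes of straight xylem-like channels, plus a stochastically branching
# tubular hyphal network grown from the slab surface, with exact ground
# truth (labels, centerline skeleton, branch points, tips, total length).

#' Phantom configuration
#'
#' Collects every knob of the synthetic phantom in one validated list.
#' Defaults are the stated world the pipeline is tested against: 1.41 um
#' voxels, a slab occupying half of the z extent with a target solid
#' fraction of 0.25 carved by straight channels of radii 6 um (small xylem)
#' and 20 um (large xylem), a hyphal network of 2.88 um diameter whose
#' per-micrometre branching rate decays exponentially with distance to the
#' slab surface, and three grey-level classes 60/140/220 with Gaussian
#' noise of sd 10 on an 8-bit range. The slab cross-section is a honeycomb
#' of thin-walled lumens (nominal radius `small`, the realised size is
#' tuned to the target solid fraction) plus a few larger circular vessels
#' (radius `large`).
#'
#' @param shape integer voxel triple (nx, ny, nz); the slab is a z-central
#'   band spanning all of x and y, channels run along x.
#' @param voxel_size_um voxel edge length in micrometres.
#' @param shive_slab_fraction fraction of the z extent occupied by the slab.
#' @param vessel_radii_um named numeric `c(small =, large =)` channel radii:
#'   `small` is the nominal lumen radius of the honeycomb lattice (the
#'   realised radius is tuned to hit the target solid fraction), `large`
#'   the radius of the sparse large xylem vessels.
#' @param vessel_max_counts named maxima per radius class (`small` caps the
#'   lattice sites, `large` is the number of large vessels placed).
#' @param target_solid_fraction solid / (solid + pores) aimed for, in (0, 1].
#' @param hypha_radius_um tube radius of rendered hyphae.
#' @param branch_rate_at_surface branch points per micrometre of hypha at
#'   distance 0 from the slab surface.
#' @param branch_rate_decay_um e-folding distance of the branching rate
#'   (`Inf` for a constant rate).
#' @param hypha_length_budget_um total centerline length to grow.
#' @param n_seed_hyphae number of hyphae started on the slab surface.
#' @param class_means grey levels `c(background, hyphae, shive)`, strictly
#'   increasing.
#' @param noise_sd grey-level standard deviation of the rendering noise.
#' @param seed default RNG seed used when an operation is not given one.
#' @return a validated list of class `phantom_config`.
#' @examples
#' cfg <- phantom_config(shape = c(64, 64, 64))
#' cfg$target_solid_fraction
#' @export
phantom_config <- function(shape = c(144L, 144L, 144L),
                           voxel_size_um = 1.41,
                           shive_slab_fraction = 0.5,
                           vessel_radii_um = c(small = 15, large = 30),
                           vessel_max_counts = c(small = Inf, large = 3),
                           target_solid_fraction = 0.25,
                           hypha_radius_um = 1.44,
                           branch_rate_at_surface = 0.02,
                           branch_rate_decay_um = 100,
                           hypha_length_budget_um = 2e4,
                           n_seed_hyphae = 100L,
                           class_means = c(60, 140, 220),
                           noise_sd = 10,
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    mycomat_error("config", "shape must be three positive integers")
  if (voxel_size_um <= 0) mycomat_error("config", "voxel_size_um must be > 0")
  if (!(target_solid_fraction > 0 && target_solid_fraction <= 1))
    mycomat_error("config", "target_solid_fraction must be in (0, 1]")
  if (any(vessel_radii_um < 0) || hypha_radius_um < 0)
    mycomat_error("config", "radii must be >= 0")
  if (is.unsorted(class_means, strictly = TRUE))
    mycomat_error("config", "class_means must be strictly increasing (background < hyphae < shive)")
  if (noise_sd < 0) mycomat_error("config", "noise_sd must be >= 0")
  if (shive_slab_fraction <= 0 || shive_slab_fraction > 1)
    mycomat_error("config", "shive_slab_fraction must be in (0, 1]")
  if (branch_rate_at_surface < 0 || branch_rate_decay_um <= 0)
    mycomat_error("config", "branching parameters must be positive")
  if (hypha_length_budget_um < 0)
    mycomat_error("config", "hypha_length_budget_um must be >= 0")
  structure(list(
    shape = shape, voxel_size_um = voxel_size_um,
    shive_slab_fraction = shive_slab_fraction,
    vessel_radii_um = vessel_radii_um, vessel_max_counts = vessel_max_counts,
    target_solid_fraction = target_solid_fraction,
    hypha_radius_um = hypha_radius_um,
    branch_rate_at_surface = branch_rate_at_surface,
    branch_rate_decay_um = branch_rate_decay_um,
    hypha_length_budget_um = hypha_length_budget_um,
    n_seed_hyphae = as.integer(n_seed_hyphae),
    class_means = class_means, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "phantom_config")
}

new_phantom_truth <- function(labels, apparent, config) {
  structure(list(
    labels = labels,
    apparent_shive_mask = apparent,
    skeleton_voxels = matrix(integer(0), 0, 3),
    branch_points = matrix(integer(0), 0, 3),
    tips = matrix(integer(0), 0, 3),
    true_total_length_um = 0,
    true_diameter_um = 2 * config$hypha_radius_um,
    true_solid_fraction = sum(labels == 2L) / max(sum(apparent), 1L),
    voxel_size_um = config$voxel_size_um,
    config = config
  ), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<phantom_truth> %d x %d x %d voxels @ %.3g um\n", d[1], d[2], d[3],
              x$voxel_size_um))
  cat(sprintf("  solid fraction %.4f | hypha length %.1f um | %d branch points, %d tips\n",
              x$true_solid_fraction, x$true_total_length_um,
              nrow(x$branch_points), nrow(x$tips)))
  invisible(x)
}

#' Generate a porous shive-slab phantom
#'
#' Builds a solid slab (label 2) spanning the full x-y extent and the
#' central `shive_slab_fraction` of the z extent, then carves straight
#' x-aligned cylindrical channels: a few large xylem vessels at random
#' non-overlapping positions, plus a jittered square lattice of small
#' xylem lumens separated by thin cell walls, emulating the honeycomb
#' cross-section of woody tissue. The small-lumen radius is adjusted by
#' bisection (the jittered lattice is fixed first, so the construction is
#' deterministic per seed) until the achieved solid fraction is within
#' 0.02 of `target_solid_fraction`. All channels keep a margin to the
#' slice borders and slab faces, so every pore is an enclosed hole on
#' x-slices and vessel filling can recover the apparent volume. The
#' apparent mask is the full slab box (solid plus channels).
#'
#' @param config a [phantom_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return a `phantom_truth` with `labels`, `apparent_shive_mask` and
#'   `true_solid_fraction` populated.
#' @export
generate_shive_phantom <- function(config, seed = config$seed) {
  d <- config$shape
  if (prod(d) == 0) mycomat_error("config", "zero-size volume")
  vox <- config$voxel_size_um
  z0 <- max(1L, as.integer(round(d[3] / 2 - config$shive_slab_fraction * d[3] / 2)) + 1L)
  z1 <- min(d[3], z0 + as.integer(round(config$shive_slab_fraction * d[3])) - 1L)
  slab <- array(0L, dim = d)
  slab[, , z0:z1] <- 2L
  apparent <- array(FALSE, dim = d)
  apparent[, , z0:z1] <- TRUE
  slab_n <- sum(apparent)
  target <- config$target_solid_fraction
  radii_vox <- config$vessel_radii_um / vox
  if (target >= 1 || all(radii_vox <= 0)) {
    return(new_phantom_truth(slab, apparent, config))
  }
  slab_thick <- z1 - z0 + 1L
  pick <- function(v, nm, default) if (nm %in% names(v)) v[[nm]] else default
  r_large <- pick(radii_vox, "large", max(radii_vox))
  r_small <- pick(radii_vox, "small", min(radii_vox))
  if (2 * ceiling(max(radii_vox)) + 4 > slab_thick)
    mycomat_error("infeasible_geometry",
                  "slab too thin to host a channel of the largest requested radius")
  set.seed(seed)
  nxy <- d[1] * d[2]
  carve_disk <- function(yc, zc, r) {
    ri <- ceiling(r)
    g <- expand.grid(dy = -ri:ri, dz = -ri:ri)
    g <- g[g$dy^2 + g$dz^2 <= r^2, , drop = FALSE]
    yy <- yc + g$dy; zz <- zc + g$dz
    keep <- yy >= 1L & yy <= d[2] & zz >= z0 & zz <= z1
    yy <- yy[keep]; zz <- zz[keep]
    if (!length(yy)) return(integer(0))
    rep((yy - 1L) * d[1] + (zz - 1L) * nxy, each = d[1]) +
      rep(seq_len(d[1]), times = length(yy))
  }
  # large vessels: random non-overlapping centres with wall margins
  large_idx <- integer(0)
  n_large <- pick(config$vessel_max_counts, "large", 0L)
  if (is.finite(n_large) && n_large > 0L && r_large > 0) {
    rl <- ceiling(r_large)
    centres <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centres) < n_large && tries < 400L * n_large) {
      tries <- tries + 1L
      ylo <- rl + 3L; yhi <- d[2] - rl - 2L
      zlo <- z0 + rl + 2L; zhi <- z1 - rl - 2L
      if (ylo > yhi || zlo > zhi) break
      yc <- if (ylo == yhi) ylo else sample(seq(ylo, yhi), 1L)
      zc <- if (zlo == zhi) zlo else sample(seq(zlo, zhi), 1L)
      # enforce separation for the first attempts, then accept touching
      min_sep2 <- if (tries < 150L * n_large) (2 * r_large + 2)^2 else 4
      if (nrow(centres) == 0L ||
          all((centres[, 1] - yc)^2 + (centres[, 2] - zc)^2 > min_sep2)) {
        centres <- rbind(centres, c(yc, zc))
        large_idx <- c(large_idx, carve_disk(yc, zc, r_large))
      }
    }
  }
  # honeycomb lattice of rounded-rectangular lumens (radial files of
  # thin-walled xylem/fibre lumens); the wall grid stays connected at any
  # lumen size, which keeps the shive a single object for the size filter
  wall_vox <- 3
  p_pref <- max(5, 2 * r_small + wall_vox)
  face_wall <- 2L # solid voxels kept at the slab faces / slice borders
  grid_centres <- function(lo, hi, p_pref) {
    span <- hi - lo + 1
    n <- max(1L, as.integer(floor(span / p_pref)))
    p_eff <- span / n
    list(centres = lo + p_eff * (seq_len(n) - 0.5), pitch = p_eff)
  }
  gy <- grid_centres(1L + face_wall, d[2] - face_wall, p_pref)
  gz <- grid_centres(z0 + face_wall, z1 - face_wall, p_pref)
  sites <- expand.grid(y = gy$centres, z = gz$centres)
  if (nrow(sites)) {
    sites$y <- sites$y + sample(-1:1, nrow(sites), replace = TRUE)
    sites$z <- sites$z + sample(-1:1, nrow(sites), replace = TRUE)
    n_small_max <- pick(config$vessel_max_counts, "small", Inf)
    if (is.finite(n_small_max) && n_small_max < nrow(sites))
      sites <- sites[sample.int(nrow(sites), n_small_max), , drop = FALSE]
  }
  ay_max <- gy$pitch / 2 - 1
  az_max <- gz$pitch / 2 - 1
  carve_rect <- function(yc, zc, ay, az) {
    # enumerate integer voxel coordinates covered by the (possibly
    # fractional-centre) lumen directly, to avoid rounding artefacts
    yy0 <- seq(ceiling(yc - ay), floor(yc + ay))
    zz0 <- seq(ceiling(zc - az), floor(zc + az))
    if (!length(yy0) || !length(zz0)) return(integer(0))
    g <- expand.grid(yy = yy0, zz = zz0)
    # rounded corners of radius 2
    ey <- pmax(abs(g$yy - yc) - (ay - 2), 0)
    ez <- pmax(abs(g$zz - zc) - (az - 2), 0)
    g <- g[ey^2 + ez^2 <= 4, , drop = FALSE]
    yy <- as.integer(g$yy); zz <- as.integer(g$zz)
    # never carve through the retained face walls: pores stay enclosed
    keep <- yy >= 1L + face_wall & yy <= d[2] - face_wall &
      zz >= z0 + face_wall & zz <= z1 - face_wall
    yy <- yy[keep]; zz <- zz[keep]
    if (!length(yy)) return(integer(0))
    rep((yy - 1L) * d[1] + (zz - 1L) * nxy, each = d[1]) +
      rep(seq_len(d[1]), times = length(yy))
  }
  carve_at <- function(s) {
    labels <- slab
    if (length(large_idx)) labels[large_idx] <- 0L
    if (s > 0 && nrow(sites)) {
      idx <- unlist(lapply(seq_len(nrow(sites)), function(i)
        carve_rect(sites$y[i], sites$z[i], s * ay_max, s * az_max)),
        use.names = FALSE)
      labels[idx] <- 0L
    }
    labels
  }
  eps_of <- function(labels) sum(labels == 2L) / slab_n
  s_top <- 1
  eps_hi <- eps_of(carve_at(s_top))
  if (eps_hi > target + 0.02) {
    # let neighbouring lumens merge (walls dissolve locally) before giving up
    s_top <- 1.3
    eps_hi <- eps_of(carve_at(s_top))
  }
  eps_lo <- eps_of(carve_at(0))
  if (eps_hi > target + 0.02)
    mycomat_error("infeasible_geometry", sprintf(
      "smallest reachable solid fraction %.3f is above target %.3f", eps_hi, target))
  if (eps_lo < target - 0.02)
    mycomat_error("infeasible_geometry", sprintf(
      "large vessels alone already undershoot the target (%.3f < %.3f)",
      eps_lo, target))
  lo <- 0; hi <- s_top
  labels <- NULL
  for (iter in 1:20) {
    mid <- (lo + hi) / 2
    labels <- carve_at(mid)
    eps <- eps_of(labels)
    if (abs(eps - target) <= 0.02) break
    if (eps > target) lo <- mid else hi <- mid
  }
  if (abs(eps_of(labels) - target) > 0.02) {
    # discrete geometry can step across the tolerance band; fall back to
    # the bracketing endpoints, then carve just enough voxels of the next
    # lumen ring to land on the target
    lab_lo <- carve_at(lo)
    lab_hi <- carve_at(hi)
    e_lo <- eps_of(lab_lo); e_hi <- eps_of(lab_hi)
    if (abs(e_hi - target) <= 0.02) {
      labels <- lab_hi
    } else if (abs(e_lo - target) <= 0.02) {
      labels <- lab_lo
    } else {
      ring <- which(lab_lo == 2L & lab_hi == 0L)
      need <- round((e_lo - target) * slab_n)
      if (need > 0 && need <= length(ring)) {
        labels <- lab_lo
        labels[ring[seq_len(need)]] <- 0L
      }
    }
  }
  if (abs(eps_of(labels) - target) > 0.02)
    mycomat_error("infeasible_geometry", sprintf(
      "could not reach target solid fraction %.3f (achieved %.3f)",
      target, eps_of(labels)))
  new_phantom_truth(labels, apparent, config)
}

# rows of `dir` are unit vectors; returns unit vectors drawn uniformly
# within a cone of half-angle `max_angle` around each row (draw in the +z
# frame, then rotate +z onto the row direction by Rodrigues' formula)
perturb_directions <- function(dir, max_angle) {
  n <- nrow(dir)
  u <- runif(n)
  cosa <- 1 - u * (1 - cos(max_angle))
  sina <- sqrt(pmax(0, 1 - cosa^2))
  phi <- runif(n, 0, 2 * pi)
  v <- cbind(sina * cos(phi), sina * sin(phi), cosa)
  ax <- cbind(-dir[, 2], dir[, 1], 0)  # z x dir
  axn <- sqrt(rowSums(ax^2))
  out <- matrix(0, n, 3)
  para <- axn < 1e-12
  if (any(para)) { # dir is +z or -z: mirror the cone for -z
    sgn <- sign(dir[para, 3])
    out[para, 1] <- v[para, 1]
    out[para, 2] <- v[para, 2]
    out[para, 3] <- v[para, 3] * sgn
  }
  np <- which(!para)
  if (length(np)) {
    a <- ax[np, , drop = FALSE] / axn[np]
    vv <- v[np, , drop = FALSE]
    ct <- dir[np, 3]
    st <- axn[np]
    cross_av <- cbind(a[, 2] * vv[, 3] - a[, 3] * vv[, 2],
                      a[, 3] * vv[, 1] - a[, 1] * vv[, 3],
                      a[, 1] * vv[, 2] - a[, 2] * vv[, 1])
    adotv <- rowSums(a * vv)
    out[np, ] <- vv * ct + cross_av * st + a * (adotv * (1 - ct))
  }
  out / sqrt(rowSums(out^2))
}

#' Grow a branching hyphal network on a shive phantom
#'
#' Fixed-step persistent random walk seeded on the slab surface: each
#' active tip advances one voxel length per step with a bounded turning
#' angle, branches as a Bernoulli event with per-step probability
#' `branch_rate_at_surface * exp(-dist / branch_rate_decay_um) * step`,
#' where `dist` is the Euclidean distance to the apparent shive surface,
#' and stops when the total centerline length reaches the budget or the
#' walker leaves the volume. Centerlines are dilated to `hypha_radius_um`;
#' hypha voxels never overwrite shive solid voxels. Skeleton, branch
#' points, tips and the exact summed centerline length are recorded as
#' ground truth.
#'
#' @param truth a `phantom_truth` from [generate_shive_phantom()].
#' @param config a [phantom_config()].
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @param max_turn_angle bound on the per-step turning angle (radians);
#'   the 8-degree default gives a persistence length of roughly 300 um,
#'   matching the nearly straight growth of vegetative hyphae.
#' @return the updated `phantom_truth`.
#' @export
grow_hyphae_phantom <- function(truth, config, seed = config$seed + 1L,
                                max_turn_angle = 8 * pi / 180) {
  d <- config$shape
  vox <- config$voxel_size_um
  if (config$hypha_radius_um / vox > min(d) / 2)
    mycomat_error("infeasible_geometry", "hypha radius larger than the volume")
  if (config$hypha_length_budget_um <= 0) return(truth)
  set.seed(seed)
  dist_surface <- distance_to_mask(truth$apparent_shive_mask) * vox
  slab_z <- range(which(apply(truth$apparent_shive_mask, 3, any)))
  step <- vox
  budget <- config$hypha_length_budget_um
  n_seeds <- max(1L, config$n_seed_hyphae)
  side <- ifelse(seq_len(n_seeds) %% 2 == 0, 1, -1)
  zface <- pmin(pmax(ifelse(side > 0, slab_z[2] + 1L, slab_z[1] - 1L), 1L), d[3])
  pos <- cbind(runif(n_seeds, 1, d[1]), runif(n_seeds, 1, d[2]), zface)
  dir <- perturb_directions(cbind(0, 0, side), 60 * pi / 180)
  lin_of <- function(v) as.integer(v[, 1] + d[1] * (v[, 2] - 1) +
                                     d[1] * d[2] * (v[, 3] - 1))
  clamp_vox <- function(p) cbind(pmin(pmax(round(p[, 1]), 1), d[1]),
                                 pmin(pmax(round(p[, 2]), 1), d[2]),
                                 pmin(pmax(round(p[, 3]), 1), d[3]))
  visited <- logical(prod(d))
  cl_idx <- list()
  branch_idx <- list()
  tip_idx <- list()
  step_dist <- list()
  branch_dist <- list()
  total_len <- 0
  start_li <- lin_of(clamp_vox(pos))
  visited[start_li] <- TRUE
  cl_idx[[1L]] <- start_li
  max_steps <- ceiling(budget / step)
  steps_done <- 0L
  # grow in waves: the current generation runs to its natural end (volume
  # border, shive solid) while spawned branches wait for the next wave, so
  # the reachable depth is set by the walk itself, not the budget split
  child_pos <- list(); child_dir <- list()
  while ((nrow(pos) || length(child_pos)) && steps_done < max_steps) {
    if (!nrow(pos)) {
      pos <- do.call(rbind, child_pos); dir <- do.call(rbind, child_dir)
      child_pos <- list(); child_dir <- list()
    }
    n <- nrow(pos)
    m <- min(n, max_steps - steps_done)   # budget cap within the round
    if (m < n) { pos <- pos[seq_len(m), , drop = FALSE]; dir <- dir[seq_len(m), , drop = FALSE] }
    dir <- perturb_directions(dir, max_turn_angle)
    newp <- pos + dir
    v <- round(newp)
    inb <- v[, 1] >= 1 & v[, 1] <= d[1] & v[, 2] >= 1 & v[, 2] <= d[2] &
      v[, 3] >= 1 & v[, 3] <= d[3]
    li <- integer(nrow(v)); li[inb] <- lin_of(v[inb, , drop = FALSE])
    blocked <- inb & truth$labels[pmax(li, 1L)] == 2L
    dead <- !inb | blocked
    if (any(dead)) tip_idx[[length(tip_idx) + 1L]] <- lin_of(clamp_vox(pos[dead, , drop = FALSE]))
    alive <- which(!dead)
    if (!length(alive)) { pos <- pos[0, , drop = FALSE]; dir <- dir[0, , drop = FALSE]; next }
    li <- li[alive]
    pos <- newp[alive, , drop = FALSE]
    dir <- dir[alive, , drop = FALSE]
    fresh <- !visited[li]
    visited[li[fresh]] <- TRUE
    cl_idx[[length(cl_idx) + 1L]] <- li[fresh]
    steps_done <- steps_done + length(alive)
    total_len <- total_len + length(alive) * step
    dist_li <- dist_surface[li]
    step_dist[[length(step_dist) + 1L]] <- dist_li
    rate <- config$branch_rate_at_surface *
      (if (is.finite(config$branch_rate_decay_um))
        exp(-dist_li / config$branch_rate_decay_um) else 1)
    br <- which(runif(length(alive)) < rate * step)
    if (length(br)) {
      branch_idx[[length(branch_idx) + 1L]] <- li[br]
      branch_dist[[length(branch_dist) + 1L]] <- dist_li[br]
      child_pos[[length(child_pos) + 1L]] <- pos[br, , drop = FALSE]
      child_dir[[length(child_dir) + 1L]] <- perturb_directions(dir[br, , drop = FALSE], 60 * pi / 180)
    }
  }
  if (nrow(pos)) tip_idx[[length(tip_idx) + 1L]] <- lin_of(clamp_vox(pos))
  cl_idx <- unlist(cl_idx)
  branch_idx <- unlist(branch_idx) %||% integer(0)
  tip_idx <- unlist(tip_idx) %||% integer(0)
  step_dist <- unlist(step_dist) %||% numeric(0)
  branch_dist <- unlist(branch_dist) %||% numeric(0)
  labels <- truth$labels
  if (length(cl_idx)) {
    r_vox <- config$hypha_radius_um / vox
    if (r_vox >= 1) {
      ri <- ceiling(r_vox)
      g <- expand.grid(dx = -ri:ri, dy = -ri:ri, dz = -ri:ri)
      g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= r_vox^2, , drop = FALSE]
      coords <- arrayInd(cl_idx, d)
      xx <- outer(coords[, 1], g$dx, "+")
      yy <- outer(coords[, 2], g$dy, "+")
      zz <- outer(coords[, 3], g$dz, "+")
      keep <- xx >= 1 & xx <= d[1] & yy >= 1 & yy <= d[2] & zz >= 1 & zz <= d[3]
      idx <- (xx[keep] - 1L) + d[1] * (yy[keep] - 1L) + d[1] * d[2] * (zz[keep] - 1L) + 1L
      idx <- unique(idx)
      idx <- idx[labels[idx] != 2L]
      labels[idx] <- 1L
    } else {
      labels[cl_idx[labels[cl_idx] != 2L]] <- 1L
    }
  }
  truth$labels <- labels
  truth$skeleton_voxels <- arrayInd(unique(cl_idx), d)
  truth$branch_points <- arrayInd(unique(branch_idx), d)
  truth$tips <- arrayInd(unique(tip_idx), d)
  truth$step_distances_um <- step_dist
  truth$step_length_um <- step
  truth$branch_distances_um <- branch_dist
  truth$true_total_length_um <- total_len
  truth$true_solid_fraction <- sum(truth$labels == 2L) / max(sum(truth$apparent_shive_mask), 1L)
  truth
}

#' Exact distance-shell profile from generator truth
#'
#' Builds the branching-frequency shell profile from the exact per-step
#' and per-branch-event distance records of [grow_hyphae_phantom()]
#' (every step contributes its true length to the shell it landed in, and
#' every branch event is counted, without voxel discretisation), the
#' generative counterpart of [branching_frequency_profile()].
#'
#' @param truth a `phantom_truth` with a grown network.
#' @param shell_width_um shell width (default 50).
#' @return a `shell_profile` data.frame.
#' @export
truth_shell_profile <- function(truth, shell_width_um = 50) {
  sd_um <- truth$step_distances_um
  bd_um <- truth$branch_distances_um
  if (is.null(sd_um))
    mycomat_error("config", "truth has no step records; grow the network first")
  interior <- sum(bd_um == 0)
  sk_shell <- ceiling(sd_um[sd_um > 0] / shell_width_um) - 1L
  br_shell <- ceiling(bd_um[bd_um > 0] / shell_width_um) - 1L
  n_shell <- max(c(sk_shell, br_shell, -1L)) + 1L
  shells <- seq_len(n_shell) - 1L
  branch_count <- tabulate(br_shell + 1L, nbins = n_shell)
  length_um <- tabulate(sk_shell + 1L, nbins = n_shell) * truth$step_length_um
  freq <- ifelse(length_um > 0, branch_count / length_um, NA_real_)
  out <- data.frame(shell_index = shells,
                    r_inner_um = shells * shell_width_um,
                    r_outer_um = (shells + 1) * shell_width_um,
                    branch_count = branch_count,
                    length_um = length_um,
                    frequency_per_um = freq,
                    relative_frequency = freq / freq[1])
  class(out) <- c("shell_profile", "data.frame")
  attr(out, "interior_branch_count") <- interior
  attr(out, "shell_width_um") <- shell_width_um
  out
}

#' Ground-truth skeleton graph of a phantom
#'
#' Packages the exact centerline, branch points and tips recorded by
#' [grow_hyphae_phantom()] as a `skeleton_graph`, so that the shell
#' statistics can be evaluated directly on generator truth.
#'
#' @param truth a `phantom_truth` with a grown network.
#' @return a `skeleton_graph`.
#' @export
truth_skeleton_graph <- function(truth) {
  d <- dim(truth$labels)
  skm <- array(FALSE, d)
  skm[truth$skeleton_voxels] <- TRUE
  structure(list(skeleton_mask = skm,
                 skeleton_voxels = truth$skeleton_voxels,
                 branch_points = truth$branch_points,
                 tips = truth$tips,
                 degree = NULL,
                 voxel_size_um = truth$voxel_size_um, dim = d),
            class = "skeleton_graph")
}

#' Render a phantom to a noisy grayscale volume
#'
#' Grey value = class mean of the voxel's label plus i.i.d. Gaussian noise,
#' clipped to the 8-bit dynamic range.
#'
#' @param truth a `phantom_truth`.
#' @param config a [phantom_config()]; class means must be strictly ordered
#'   background < hyphae < shive.
#' @param seed RNG seed (defaults to `config$seed + 2`).
#' @return a [voxel_volume()] with slice axis 1 (perpendicular to the
#'   channel axis, so that xylem channels are enclosed holes on slices).
#' @export
render_grayscale <- function(truth, config, seed = config$seed + 2L) {
  if (is.unsorted(config$class_means, strictly = TRUE))
    mycomat_error("config", "class_means must be strictly increasing")
  set.seed(seed)
  d <- dim(truth$labels)
  v <- config$class_means[truth$labels + 1L]
  if (config$noise_sd > 0) v <- v + rnorm(length(v), 0, config$noise_sd)
  v <- pmin(pmax(v, 0), 255)
  voxel_volume(array(v, dim = d), voxel_size_um = config$voxel_size_um,
               slice_axis = 1L, provenance = "synthetic phantom")
}
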