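# Morphometry of the segmented hyphal network: curve skeleton, branch/tip
# classification, EDT-based mean diameter, volumetric total length, and the
# distance-shell branching-frequency profile around the substrate.

#' Skeletonize a hyphal mask
#'
#' Distance-ordered homotopic thinning of the binary mask down to a
#' one-voxel-wide curve skeleton (topology preserving in the (26, 6)
#' adjacency pair), followed by pruning of terminal spurs shorter than
#' `prune_min_vox` and clustering of 26-adjacent branch voxels into single
#' branch points.
#'
#' @param hyphae a `hyphae_segmentation` (or a bare logical 3D array).
#' @param voxel_size_um voxel size; taken from `hyphae` when available.
#' @param prune_min_vox terminal branches with fewer voxels than this are
#'   removed (suppresses digitization spurs at tube end caps).
#' @return an object of class `skeleton_graph`: coordinates of skeleton
#'   voxels, branch points (cluster representatives), tips, voxel degrees
#'   and the skeleton mask.
#' @export
skeletonize_hyphae <- function(hyphae, voxel_size_um = NULL, prune_min_vox = 5L) {
  mask <- if (inherits(hyphae, "hyphae_segmentation")) hyphae$mask else hyphae
  vox <- voxel_size_um %||%
    (if (inherits(hyphae, "hyphae_segmentation")) hyphae$voxel_size_um else 1)
  d <- dim(mask)
  if (!any(mask)) {
    return(structure(list(skeleton_mask = array(FALSE, d),
                          skeleton_voxels = matrix(integer(0), 0, 3),
                          branch_points = matrix(integer(0), 0, 3),
                          tips = matrix(integer(0), 0, 3),
                          degree = integer(0), voxel_size_um = vox, dim = d),
                     class = "skeleton_graph"))
  }
  pr <- cpp_edt_sq(as.logical(mask), as.integer(d))
  skel <- array(cpp_thin3d(as.logical(mask), as.integer(d), pr), dim = d)
  skel <- prune_spurs(skel, prune_min_vox)
  classify_skeleton(skel, vox)
}

# neighbours helper: 26-neighbourhood offsets as an integer matrix
neighbor_offsets26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

# remove terminal paths shorter than min_len voxels (walk from each tip to
# the first junction); repeated until stable
prune_spurs <- function(skel, min_len) {
  if (min_len <= 0) return(skel)
  d <- dim(skel)
  off <- neighbor_offsets26()
  repeat {
    deg <- array(cpp_neighbor_count26(as.logical(skel), as.integer(d)), dim = d)
    tips <- which(skel & deg == 1L)
    if (!length(tips)) return(skel)
    removed_any <- FALSE
    for (t in tips) {
      path <- integer(0)
      cur <- arrayInd(t, d)[1, ]
      prev <- NULL
      hit_junction <- FALSE
      for (step in seq_len(min_len)) {
        path <- c(path, cur[1] + d[1] * (cur[2] - 1) + d[1] * d[2] * (cur[3] - 1))
        nb <- sweep(off, 2, cur, "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
        nb <- nb[ok, , drop = FALSE]
        li <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
        li <- li[skel[li]]
        if (!is.null(prev)) li <- li[li != prev]
        li <- setdiff(li, path)
        if (length(li) == 0L) break          # isolated short path: keep
        if (length(li) > 1L || deg[li[1]] >= 3L) { hit_junction <- TRUE; break }
        prev <- path[length(path)]
        cur <- arrayInd(li[1], d)[1, ]
      }
      if (hit_junction && length(path) < min_len) {
        skel[path] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) return(skel)
  }
}

classify_skeleton <- function(skel, vox) {
  d <- dim(skel)
  deg_arr <- array(cpp_neighbor_count26(as.logical(skel), as.integer(d)), dim = d)
  coords <- mask_coords(skel)
  idx <- coords_to_index(coords, d)
  deg <- deg_arr[idx]
  tips <- coords[deg == 1L, , drop = FALSE]
  branch_voxels <- skel & (deg_arr >= 3L)
  # merge 26-adjacent branch voxels into one branch point per cluster
  if (any(branch_voxels)) {
    bl <- label_components(branch_voxels, 26L)
    bc <- mask_coords(branch_voxels)
    bid <- bl[coords_to_index(bc, d)]
    reps <- do.call(rbind, lapply(split(seq_len(nrow(bc)), bid), function(ii) {
      ctr <- colMeans(bc[ii, , drop = FALSE])
      bc[ii[which.min(rowSums(sweep(bc[ii, , drop = FALSE], 2, ctr, "-")^2))], ]
    }))
    rownames(reps) <- NULL
  } else {
    reps <- matrix(integer(0), 0, 3)
  }
  structure(list(skeleton_mask = skel, skeleton_voxels = coords,
                 branch_points = reps, tips = tips, degree = deg,
                 voxel_size_um = vox, dim = d),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d voxels, %d branch points, %d tips\n",
              nrow(x$skeleton_voxels), nrow(x$branch_points), nrow(x$tips)))
  invisible(x)
}

#' Mean hyphal diameter from skeleton x EDT
#'
#' Samples the Euclidean distance transform of the hypha mask (distance to
#' the nearest background voxel) at the skeleton voxels, averages the local
#' radii, and reports twice the mean as a diameter in micrometres. A
#' digitization correction (voxels) is subtracted from each local radius
#' before averaging; the default 0.1 voxel balances the centre-to-centre
#' overestimate of the discrete distance transform on axis-aligned tubes
#' against the off-axis zigzag of thinned skeletons on oblique tubes,
#' calibrated once on digital cylinders and phantom networks (see the
#' methods vignette; 0 and 0.5 are the uncorrected and full half-voxel
#' variants).
#'
#' @param skel a `skeleton_graph`.
#' @param hyphae a `hyphae_segmentation` (or logical array).
#' @param voxel_size_um voxel size in micrometres.
#' @param boundary_correction_vox radius correction in voxels.
#' @param exclude_mask optional logical array of obstacle voxels (e.g. the
#'   shive solid mask): where a hypha touches an obstacle the distance
#'   transform measures the contact, not the fibre radius, so skeleton
#'   voxels whose local EDT is truncated by the obstacle are excluded from
#'   the average.
#' @return mean diameter in micrometres.
#' @export
mean_hyphal_diameter <- function(skel, hyphae, voxel_size_um = skel$voxel_size_um,
                                 boundary_correction_vox = 0.1,
                                 exclude_mask = NULL) {
  if (nrow(skel$skeleton_voxels) == 0L)
    mycomat_error("no_hyphae", "empty skeleton: no hyphae to measure")
  mask <- if (inherits(hyphae, "hyphae_segmentation")) hyphae$mask else hyphae
  d <- dim(mask)
  idx <- coords_to_index(skel$skeleton_voxels, d)
  edt <- sqrt(cpp_edt_sq(as.logical(mask), as.integer(d)))[idx]
  if (!is.null(exclude_mask)) {
    free <- sqrt(cpp_edt_sq(as.logical(mask | exclude_mask), as.integer(d)))[idx]
    keep <- free - edt <= 0.5  # nearest background is free space, not obstacle
    if (any(keep)) edt <- edt[keep] # degenerate all-contact case: keep all
  }
  r <- edt - boundary_correction_vox
  2 * mean(pmax(r, 0.5)) * voxel_size_um
}

#' Total hyphal length from volume and diameter
#'
#' `l = 4 V / (pi d^2)`: the length of a cylinder of volume `V` and
#' diameter `d`.
#'
#' @param V_hyphae_um3 total hyphal volume in cubic micrometres.
#' @param d_hyphae_um mean hyphal diameter in micrometres (> 0).
#' @return total length in micrometres.
#' @examples
#' total_hyphal_length(pi * 2.82^2 * 141, 5.64) # a single cylinder: 141 um
#' @export
total_hyphal_length <- function(V_hyphae_um3, d_hyphae_um) {
  if (V_hyphae_um3 == 0) return(0)
  if (d_hyphae_um <= 0)
    mycomat_error("config", "d_hyphae_um must be > 0 for the length conversion")
  4 * V_hyphae_um3 / (pi * d_hyphae_um^2)
}

#' Branch point and tip counts
#'
#' @param skel a `skeleton_graph`.
#' @return named integer vector `c(n_branch, n_tips)`.
#' @export
count_branch_points_tips <- function(skel) {
  c(n_branch = nrow(skel$branch_points), n_tips = nrow(skel$tips))
}

#' Hyphal summary statistics
#'
#' Convenience wrapper assembling diameter, total length, volume and
#' branch/tip counts.
#'
#' @param skel a `skeleton_graph`.
#' @param hyphae a `hyphae_segmentation`.
#' @param voxel_size_um voxel size.
#' @param ... passed to [mean_hyphal_diameter()].
#' @return list of class `hyphal_summary`.
#' @export
hyphal_summary <- function(skel, hyphae, voxel_size_um = skel$voxel_size_um, ...) {
  d_um <- mean_hyphal_diameter(skel, hyphae, voxel_size_um, ...)
  V <- if (inherits(hyphae, "hyphae_segmentation")) hyphae$V_hyphae_um3 else
    sum(hyphae) * voxel_size_um^3
  cnt <- count_branch_points_tips(skel)
  structure(list(d_hyphae_um = d_um,
                 l_hyphae_um = total_hyphal_length(V, d_um),
                 V_hyphae_um3 = V,
                 n_branch = unname(cnt["n_branch"]),
                 n_tips = unname(cnt["n_tips"])),
            class = "hyphal_summary")
}

#' Distance-shell branching-frequency profile
#'
#' Treats the substrate (apparent shive mask) as the central piece and
#' divides the surrounding volume into concentric shells of width
#' `shell_width_um` by Euclidean distance to the substrate surface. Branch
#' points and skeleton voxels are binned into shells; per-shell hyphal
#' length is either the skeleton voxel count times the voxel size times a
#' mean-chord correction (default 1.2 for 26-connected digital paths) or
#' the volumetric estimate `4 V_shell / (pi d^2)`. The branching frequency
#' of a shell is its branch count divided by its hyphal length. Branch
#' points inside the substrate are tallied separately and excluded from
#' the exterior profile.
#'
#' @param skel a `skeleton_graph`.
#' @param shive a `shive_segmentation` with a non-empty apparent mask (or a
#'   bare logical array used as the substrate mask).
#' @param hyphae a `hyphae_segmentation`; required for the volumetric
#'   length method.
#' @param shell_width_um shell width in micrometres (default 50).
#' @param length_method `"skeleton"` (chord-corrected voxel count) or
#'   `"volumetric"`.
#' @param chord_correction multiplier converting skeleton voxel count times
#'   voxel size into path length.
#' @param normalize reference for the relative-frequency column: first
#'   shell (`"first_shell"`) or the all-shell total (`"total"`).
#' @return a data.frame of class `shell_profile` with one row per shell:
#'   `shell_index`, `r_inner_um`, `r_outer_um`, `branch_count`,
#'   `length_um`, `frequency_per_um`, `relative_frequency`; the number of
#'   substrate-interior branch points is attached as attribute
#'   `interior_branch_count`.
#' @export
branching_frequency_profile <- function(skel, shive, hyphae = NULL,
                                        shell_width_um = 50,
                                        length_method = c("skeleton", "volumetric"),
                                        chord_correction = 1.2,
                                        normalize = c("first_shell", "total")) {
  length_method <- match.arg(length_method)
  normalize <- match.arg(normalize)
  apparent <- if (inherits(shive, "shive_segmentation")) shive$apparent_mask else shive
  if (is.null(apparent) || !any(apparent))
    mycomat_error("no_substrate", "apparent shive mask is empty: no reference surface")
  vox <- skel$voxel_size_um
  d <- skel$dim
  dist_um <- distance_to_mask(apparent) * vox
  sk_idx <- coords_to_index(skel$skeleton_voxels, d)
  br_idx <- if (nrow(skel$branch_points)) coords_to_index(skel$branch_points, d) else integer(0)
  sk_d <- dist_um[sk_idx]
  br_d <- dist_um[br_idx]
  interior_branches <- sum(br_d == 0)
  sk_shell <- ceiling(sk_d[sk_d > 0] / shell_width_um) - 1L
  br_shell <- ceiling(br_d[br_d > 0] / shell_width_um) - 1L
  n_shell <- max(c(sk_shell, br_shell, -1L)) + 1L
  if (n_shell == 0L) {
    out <- data.frame(shell_index = integer(0), r_inner_um = numeric(0),
                      r_outer_um = numeric(0), branch_count = integer(0),
                      length_um = numeric(0), frequency_per_um = numeric(0),
                      relative_frequency = numeric(0))
    class(out) <- c("shell_profile", "data.frame")
    attr(out, "interior_branch_count") <- interior_branches
    return(out)
  }
  shells <- 0:(n_shell - 1L)
  branch_count <- tabulate(br_shell + 1L, nbins = n_shell)
  sk_count <- tabulate(sk_shell + 1L, nbins = n_shell)
  if (length_method == "skeleton") {
    length_um <- sk_count * vox * chord_correction
  } else {
    if (is.null(hyphae))
      mycomat_error("config", "volumetric length method needs the hyphae segmentation")
    mask <- if (inherits(hyphae, "hyphae_segmentation")) hyphae$mask else hyphae
    hy_d <- dist_um[which(mask)]
    hy_shell <- ceiling(hy_d[hy_d > 0] / shell_width_um) - 1L
    V_shell <- tabulate(hy_shell + 1L, nbins = n_shell) * vox^3
    d_mean <- mean_hyphal_diameter(skel, mask, vox)
    length_um <- 4 * V_shell / (pi * d_mean^2)
  }
  freq <- ifelse(length_um > 0, branch_count / length_um, NA_real_)
  ref <- if (normalize == "first_shell") freq[1] else
    sum(branch_count) / sum(length_um)
  out <- data.frame(shell_index = shells,
                    r_inner_um = shells * shell_width_um,
                    r_outer_um = (shells + 1) * shell_width_um,
                    branch_count = branch_count,
                    length_um = length_um,
                    frequency_per_um = freq,
                    relative_frequency = freq / ref)
  class(out) <- c("shell_profile", "data.frame")
  attr(out, "interior_branch_count") <- interior_branches
  attr(out, "shell_width_um") <- shell_width_um
  attr(out, "length_method") <- length_method
  out
}
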