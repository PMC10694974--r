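# Micro-CT segmentation pipeline: per-slice non-local-means denoising,
# hybrid global/local binarization, grey-value masking, multilevel Otsu
# classing, size-filtered shive extraction, per-slice closing + vessel
# filling for the apparent substrate volume, solid fraction, and hyphae
# segmentation with a small-object filter.

#' Segmentation parameters
#'
#' @param nlm_strength filtering strength of the non-local-means denoiser
#'   (same scale as the grey values; set to the expected noise sd).
#' @param nlm_patch_um patch diameter scale of the denoiser.
#' @param adaptive_window_um side length of the local-mean window of the
#'   binarization.
#' @param adaptive_sensitivity dimensionless margin of the local threshold:
#'   a voxel is foreground when its denoised value exceeds
#'   `min(t_global, (1 + sensitivity) * local_mean)`.
#' @param n_otsu_classes number of multilevel Otsu classes (default 3:
#'   background remnants, hyphae, shive).
#' @param shive_min_volume_um3 minimum object volume classified as a shive.
#' @param hyphae_min_volume_um3 minimum object volume kept as hyphae.
#' @param closing_radius_um per-slice closing disk radius for the apparent
#'   volume (the scale of the large vessel pores).
#' @param connectivity 6, 18 or 26 neighbourhood for 3D components.
#' @return a validated list of class `segmentation_params`.
#' @export
segmentation_params <- function(nlm_strength = 10,
                                nlm_patch_um = 4.2,
                                adaptive_window_um = 40,
                                adaptive_sensitivity = 0.15,
                                n_otsu_classes = 3L,
                                shive_min_volume_um3 = 140000,
                                hyphae_min_volume_um3 = 280,
                                closing_radius_um = 30,
                                connectivity = 26L) {
  if (shive_min_volume_um3 <= 0 || hyphae_min_volume_um3 <= 0)
    mycomat_error("config", "minimum volumes must be > 0")
  if (n_otsu_classes < 2L) mycomat_error("config", "n_otsu_classes must be >= 2")
  if (closing_radius_um <= 0) mycomat_error("config", "closing_radius_um must be > 0")
  if (!connectivity %in% c(6L, 18L, 26L))
    mycomat_error("config", "connectivity must be 6, 18 or 26")
  structure(list(nlm_strength = nlm_strength, nlm_patch_um = nlm_patch_um,
                 adaptive_window_um = adaptive_window_um,
                 adaptive_sensitivity = adaptive_sensitivity,
                 n_otsu_classes = as.integer(n_otsu_classes),
                 shive_min_volume_um3 = shive_min_volume_um3,
                 hyphae_min_volume_um3 = hyphae_min_volume_um3,
                 closing_radius_um = closing_radius_um,
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

# Global background/foreground cut of the denoised volume: lowest 3-class
# Otsu threshold, unless the 3-class solution merely split the darkest
# mode (middle class mean close to the bottom class mean), in which case
# the upper threshold is the true background cut. Volumes with fewer than
# 3 distinct values fall back to a single Otsu threshold; constant volumes
# are entirely background.
global_background_threshold <- function(den) {
  u <- length(unique(round(den, 6)))
  if (u < 2) return(Inf)
  if (u < 3) return(otsu_threshold(den))
  thr <- multi_otsu(den, k = 3L)
  m1 <- mean(den[den <= thr[1]])
  m2 <- mean(den[den > thr[1] & den <= thr[2]])
  m3 <- mean(den[den > thr[2]])
  if (is.finite(m2) && is.finite(m3) && (m2 - m1) < 0.25 * (m3 - m2))
    thr[2] else thr[1]
}

#' Denoise and background-mask a volume
#'
#' Applies a non-local-means filter slice by slice along the volume's slice
#' axis, then zeroes the background: a voxel is kept when its denoised
#' value exceeds `min(t_global, (1 + s) * local_mean)`, where `t_global`
#' is the lowest threshold of a multilevel Otsu over the denoised volume
#' and `local_mean` is a per-slice box mean over the configured window.
#' The global term keeps object interiors (where the local mean equals the
#' object level); the local term adapts to background drift and leaves a
#' small population of bright background remnants that the later
#' multilevel classing absorbs as its darkest class. Foreground voxels
#' retain their denoised grey value; background voxels are exactly 0.
#'
#' @param vol a [voxel_volume()].
#' @param params a [segmentation_params()].
#' @return a [voxel_volume()] of masked denoised grey values, with the
#'   thresholds used attached as attribute `thresholds`.
#' @export
preprocess_volume <- function(vol, params = segmentation_params()) {
  stopifnot(is_voxel_volume(vol))
  d <- dim(vol$values)
  p <- with_slice_axis_last(vol$values, vol$slice_axis)
  dd <- dim(p$arr)
  win_vox <- max(1L, as.integer(round(params$adaptive_window_um / vol$voxel_size_um / 2)))
  if (2 * win_vox + 1 > min(dd[1], dd[2]))
    mycomat_error("config", "adaptive window larger than the slice extent")
  patch_r <- max(1L, as.integer(round(params$nlm_patch_um / vol$voxel_size_um / 2)))
  den <- cpp_nlm_slices(as.numeric(p$arr), as.integer(dd),
                        params$nlm_strength, patch_r, 2L * patch_r)
  t_global <- global_background_threshold(den)
  lm <- cpp_boxmean_slices(den, as.integer(dd), win_vox)
  thr <- pmin(t_global, (1 + params$adaptive_sensitivity) * lm)
  out <- ifelse(den > thr, den, 0)
  out <- undo_slice_axis(array(out, dim = dd), p$perm)
  res <- voxel_volume(out, vol$voxel_size_um, vol$slice_axis,
                      provenance = paste0(vol$provenance, " [preprocessed]"))
  attr(res, "thresholds") <- list(global = t_global,
                                  sensitivity = params$adaptive_sensitivity,
                                  window_vox = 2L * win_vox + 1L)
  res
}

#' Multilevel Otsu classing of a masked volume
#'
#' Assigns every nonzero voxel one of `n_otsu_classes` ordered classes
#' (1 = darkest foreground, highest = brightest); thresholds are computed
#' over nonzero voxels only, zero voxels keep class 0.
#'
#' @param masked a foreground-masked [voxel_volume()] from
#'   [preprocess_volume()].
#' @param params a [segmentation_params()].
#' @return integer array of class indices (0..n classes), with thresholds
#'   attached as attribute `thresholds`.
#' @export
multilevel_classes <- function(masked, params = segmentation_params()) {
  stopifnot(is_voxel_volume(masked))
  v <- masked$values
  nz <- v[v > 0]
  k <- params$n_otsu_classes
  if (length(unique(nz)) < k)
    mycomat_error("degenerate_histogram", sprintf(
      "masked volume has %d distinct nonzero grey values; %d classes requested",
      length(unique(nz)), k))
  thr <- multi_otsu(nz, k = k)
  cls <- array(0L, dim = dim(v))
  sel <- v > 0
  cls[sel] <- findInterval(v[sel], thr) + 1L
  attr(cls, "thresholds") <- thr
  cls
}

new_shive_segmentation <- function(solid_mask, labels, voxel_size_um) {
  structure(list(solid_mask = solid_mask, labels = labels,
                 apparent_mask = NULL,
                 V_solid_um3 = sum(solid_mask) * voxel_size_um^3,
                 V_solid_plus_pores_um3 = NA_real_,
                 epsilon_substrate = NA_real_,
                 apparent_density_kg_m3 = NA_real_,
                 voxel_size_um = voxel_size_um),
            class = "shive_segmentation")
}

#' Build a shive segmentation from existing masks
#'
#' Useful for computing solid fractions of masks obtained elsewhere (or
#' constructed analytically) without rerunning the pipeline.
#'
#' @param solid_mask logical 3D array of solid substrate voxels.
#' @param voxel_size_um voxel size.
#' @param apparent_mask optional logical array of the pore-filled substrate
#'   (defaults to unset; use [compute_apparent_mask()] to derive it).
#' @return a `shive_segmentation`.
#' @export
shive_segmentation_from_masks <- function(solid_mask, voxel_size_um,
                                          apparent_mask = NULL) {
  sh <- new_shive_segmentation(solid_mask, array(0L, dim(solid_mask)),
                               voxel_size_um)
  if (!is.null(apparent_mask)) {
    if (!all(dim(apparent_mask) == dim(solid_mask)) ||
        any(solid_mask & !apparent_mask))
      mycomat_error("config", "solid_mask must be contained in apparent_mask")
    sh$apparent_mask <- apparent_mask
    sh$V_solid_plus_pores_um3 <- sum(apparent_mask) * voxel_size_um^3
  }
  sh
}

#' Extract the shive solid mask
#'
#' Takes the brightest multilevel class, labels its connected components
#' under the configured connectivity, and keeps only components whose
#' volume reaches `shive_min_volume_um3` (threshold converted to a voxel
#' count with `ceiling`, so an object must strictly reach the physical
#' volume).
#'
#' @param classes class-index volume from [multilevel_classes()].
#' @param vol the source [voxel_volume()] (for the voxel size).
#' @param params a [segmentation_params()].
#' @return a `shive_segmentation` with `solid_mask`, per-object `labels`
#'   and `V_solid_um3` populated.
#' @export
extract_shive_mask <- function(classes, vol, params = segmentation_params()) {
  kmax <- max(classes)
  vox3 <- vol$voxel_size_um^3
  if (kmax == 0L) {
    return(new_shive_segmentation(array(FALSE, dim(classes)),
                                  array(0L, dim(classes)), vol$voxel_size_um))
  }
  bright <- classes == kmax
  lab <- label_components(bright, params$connectivity)
  min_vox <- ceiling(params$shive_min_volume_um3 / vox3)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_vox)
  solid <- array(lab %in% keep & lab > 0L, dim = dim(classes))
  lab[!solid] <- 0L
  # relabel kept objects 1..n
  if (length(keep)) {
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  new_shive_segmentation(solid, lab, vol$voxel_size_um)
}

#' Compute the apparent (pore-filled) shive mask
#'
#' Per cross-sectional slice along `slice_axis`: morphological closing with
#' a Euclidean disk of radius `closing_radius_um` followed by hole filling,
#' which fills the xylem vessel channels. The solid mask is guaranteed to
#' be contained in the result.
#'
#' @param shive a `shive_segmentation` from [extract_shive_mask()].
#' @param params a [segmentation_params()].
#' @param slice_axis axis perpendicular to the cross-sections (default 1,
#'   the channel cross-section axis of the phantoms).
#' @return the `shive_segmentation` with `apparent_mask` and
#'   `V_solid_plus_pores_um3` set.
#' @export
compute_apparent_mask <- function(shive, params = segmentation_params(),
                                  slice_axis = 1L) {
  solid <- shive$solid_mask
  p <- with_slice_axis_last(solid, slice_axis)
  dd <- dim(p$arr)
  r_vox <- params$closing_radius_um / shive$voxel_size_um
  if (2 * r_vox >= min(dd[1], dd[2]))
    mycomat_error("config", "closing radius exceeds the slice extent")
  if (!any(solid)) {
    shive$apparent_mask <- array(FALSE, dim(solid))
    shive$V_solid_plus_pores_um3 <- 0
    return(shive)
  }
  a <- p$arr
  # closing by a Euclidean disk via two distance transforms per slice
  closed <- array(FALSE, dim = dd)
  for (s in seq_len(dd[3])) {
    sl <- a[, , s, drop = FALSE]
    d2 <- array(cpp_edt_sq(!as.logical(sl), as.integer(c(dd[1], dd[2], 1L))),
                dim = dim(sl))
    dil_s <- d2 <= r_vox^2
    d3 <- array(cpp_edt_sq(as.logical(dil_s), as.integer(c(dd[1], dd[2], 1L))),
                dim = dim(sl))
    # erosion of the dilated set: keep where the ball stays inside
    clo_s <- dil_s & (d3 > r_vox^2)
    closed[, , s] <- clo_s[, , 1]
  }
  filled <- array(cpp_fill_holes_slices(as.logical(closed), as.integer(dd)),
                  dim = dd)
  apparent <- undo_slice_axis(filled, p$perm) | solid
  shive$apparent_mask <- apparent
  shive$V_solid_plus_pores_um3 <- sum(apparent) * shive$voxel_size_um^3
  shive
}

#' Solid fraction and apparent density of the substrate
#'
#' `epsilon = V_solid / V_solid_plus_pores` from voxel counts; the apparent
#' density is `epsilon` times the cell-wall solid density.
#'
#' @param shive a `shive_segmentation` with the apparent mask computed.
#' @param solid_density_kg_m3 solid (cell-wall) density of the substrate.
#' @return the `shive_segmentation` with `epsilon_substrate` and
#'   `apparent_density_kg_m3` set.
#' @export
shive_solid_fraction <- function(shive, solid_density_kg_m3 = 1450) {
  if (is.null(shive$apparent_mask) || !any(shive$apparent_mask))
    mycomat_error("no_substrate", "apparent shive mask is empty")
  eps <- sum(shive$solid_mask) / sum(shive$apparent_mask)
  shive$epsilon_substrate <- eps
  shive$apparent_density_kg_m3 <- eps * solid_density_kg_m3
  shive
}

#' Segment the hyphal network
#'
#' Removes the segmented shive voxels from the original grey volume,
#' separates the remaining hyphae from the background with a single Otsu
#' threshold, and removes connected components smaller than
#' `hyphae_min_volume_um3`.
#'
#' @param vol the original (raw) [voxel_volume()].
#' @param shive a `shive_segmentation`.
#' @param params a [segmentation_params()].
#' @return an object of class `hyphae_segmentation` with the binary `mask`,
#'   `V_hyphae_um3` and `n_objects`.
#' @export
extract_hyphae_mask <- function(vol, shive, params = segmentation_params()) {
  stopifnot(is_voxel_volume(vol))
  v <- vol$values
  remain <- v[!shive$solid_mask]
  empty <- function() structure(list(mask = array(FALSE, dim(v)),
                                     V_hyphae_um3 = 0, n_objects = 0L,
                                     threshold = NA_real_,
                                     voxel_size_um = vol$voxel_size_um),
                                class = "hyphae_segmentation")
  if (length(unique(remain)) < 2L) {
    warning("no grey-value structure outside the shives; returning an empty hyphae mask")
    return(empty())
  }
  thr <- otsu_threshold(remain)
  mask <- (v > thr) & !shive$solid_mask
  if (!any(mask)) {
    warning("no hyphae voxels above the Otsu threshold")
    return(empty())
  }
  lab <- label_components(mask, params$connectivity)
  vox3 <- vol$voxel_size_um^3
  min_vox <- ceiling(params$hyphae_min_volume_um3 / vox3)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_vox)
  mask <- array(lab %in% keep & lab > 0L, dim = dim(v))
  structure(list(mask = mask, V_hyphae_um3 = sum(mask) * vox3,
                 n_objects = length(keep), threshold = thr,
                 voxel_size_um = vol$voxel_size_um),
            class = "hyphae_segmentation")
}

#' Run the full segmentation pipeline
#'
#' Composes [preprocess_volume()], [multilevel_classes()],
#' [extract_shive_mask()], [compute_apparent_mask()],
#' [shive_solid_fraction()] and [extract_hyphae_mask()] in order and
#' returns both segmentations plus a structured log of every threshold
#' actually used. An all-background volume yields empty masks rather than
#' an error.
#'
#' @param vol a [voxel_volume()].
#' @param params a [segmentation_params()].
#' @param solid_density_kg_m3 solid density used for the apparent density.
#' @return list with elements `shive`, `hyphae`, `log`.
#' @export
run_segmentation_pipeline <- function(vol, params = segmentation_params(),
                                      solid_density_kg_m3 = 1450) {
  masked <- preprocess_volume(vol, params)
  log <- list(preprocess = attr(masked, "thresholds"))
  if (!any(masked$values > 0)) {
    shive <- new_shive_segmentation(array(FALSE, dim(vol$values)),
                                    array(0L, dim(vol$values)), vol$voxel_size_um)
    shive$apparent_mask <- array(FALSE, dim(vol$values))
    shive$V_solid_plus_pores_um3 <- 0
    hyphae <- structure(list(mask = array(FALSE, dim(vol$values)),
                             V_hyphae_um3 = 0, n_objects = 0L,
                             threshold = NA_real_,
                             voxel_size_um = vol$voxel_size_um),
                        class = "hyphae_segmentation")
    return(list(shive = shive, hyphae = hyphae,
                log = c(log, list(note = "volume is entirely background"))))
  }
  classes <- multilevel_classes(masked, params)
  log$otsu_thresholds <- attr(classes, "thresholds")
  shive <- extract_shive_mask(classes, vol, params)
  shive <- compute_apparent_mask(shive, params, slice_axis = vol$slice_axis)
  if (any(shive$apparent_mask)) {
    shive <- shive_solid_fraction(shive, solid_density_kg_m3)
  }
  hyphae <- extract_hyphae_mask(vol, shive, params)
  log$hyphae_threshold <- hyphae$threshold
  log$n_shive_objects <- max(shive$labels)
  log$n_hyphae_objects <- hyphae$n_objects
  log$epsilon_substrate <- shive$epsilon_substrate
  list(shive = shive, hyphae = hyphae, log = log)
}
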