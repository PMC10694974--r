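# Internal numerical utilities shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multilevel Otsu thresholds
#'
#' Computes `k - 1` thresholds maximising the between-class variance of a
#' grey-value sample over a 256-bin histogram (dynamic programming over
#' segment scores, exact for the binned histogram).
#'
#' @param v numeric vector of grey values.
#' @param k number of classes (>= 2).
#' @param n_bins histogram resolution.
#' @return numeric vector of `k - 1` increasing thresholds (bin edges);
#'   assign classes with `findInterval(v, thresholds)`.
#' @examples
#' v <- c(rnorm(300, 60, 5), rnorm(300, 140, 5), rnorm(300, 220, 5))
#' multi_otsu(v, 3)
#' @export
multi_otsu <- function(v, k = 3L, n_bins = 256L) {
  k <- as.integer(k)
  if (k < 2L) mycomat_error("config", "multi_otsu needs k >= 2")
  v <- as.numeric(v)
  if (length(unique(v)) < k)
    mycomat_error("degenerate_histogram", sprintf(
      "histogram has %d distinct values but %d classes were requested",
      length(unique(v)), k))
  rng <- range(v)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, all.inside = TRUE), nbins = n_bins)
  centers <- (br[-1] + br[-(n_bins + 1L)]) / 2
  p <- h / sum(h)
  cumP <- c(0, cumsum(p))
  cumM <- c(0, cumsum(p * centers))
  # S[i, j]: contribution of the segment of bins (i .. j-1) in 0-based edges;
  # with 1-based edge indices e in 1..(n_bins+1), segment (e1, e2], e1 < e2.
  dP <- outer(cumP, cumP, function(a, b) a - b) # dP[e2, e1] = P(e1..e2]
  dM <- outer(cumM, cumM, function(a, b) a - b)
  S <- ifelse(dP > 0, dM^2 / pmax(dP, 1e-300), -Inf)
  ne <- n_bins + 1L
  # D[c][e]: best score of first c classes covering edges 1..e
  D <- S[, 1L] # one class ending at edge e: S[e, 1]
  parent <- vector("list", k)
  for (cl in 2:k) {
    Dn <- rep(-Inf, ne)
    arg <- integer(ne)
    for (e in seq(cl + 1L, ne)) {
      cand <- D[cl:(e - 1L)] + S[e, cl:(e - 1L)]
      j <- which.max(cand)
      Dn[e] <- cand[j]
      arg[e] <- (cl:(e - 1L))[j]
    }
    parent[[cl]] <- arg
    D <- Dn
  }
  thr <- numeric(k - 1L)
  e <- ne
  for (cl in k:2) {
    e <- parent[[cl]][e]
    thr[cl - 1L] <- br[e]
  }
  thr
}

#' Single Otsu threshold
#'
#' @param v numeric vector of grey values.
#' @param n_bins histogram resolution.
#' @return scalar threshold; foreground is `v > threshold`.
#' @export
otsu_threshold <- function(v, n_bins = 256L) {
  multi_otsu(v, k = 2L, n_bins = n_bins)
}

# squared EDT of a mask (distance in voxels from TRUE voxels to nearest
# FALSE voxel); thin wrapper keeping dim bookkeeping in one place
edt_sq <- function(mask) {
  d <- dim(mask)
  if (is.null(d) || length(d) != 3L) mycomat_error("config", "mask must be a 3D array")
  out <- cpp_edt_sq(as.logical(mask), as.integer(d))
  array(out, dim = d)
}

# Euclidean distance (voxels) from every voxel to the nearest TRUE voxel
# of `mask` (0 inside the mask).
distance_to_mask <- function(mask) {
  sqrt(edt_sq(!mask))
}

label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  if (!connectivity %in% c(6L, 18L, 26L))
    mycomat_error("config", "connectivity must be 6, 18 or 26")
  array(cpp_label(as.logical(mask), as.integer(d), as.integer(connectivity)), dim = d)
}

# coordinates (n x 3 integer matrix, 1-based) of TRUE voxels
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

coords_to_index <- function(coords, d) {
  as.vector(coords[, 1] + d[1] * (coords[, 2] - 1) + d[1] * d[2] * (coords[, 3] - 1))
}

dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
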