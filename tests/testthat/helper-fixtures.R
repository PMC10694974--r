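# Shared fixtures and independent oracles (deliberately implemented with
# plain base R, not the package's C++ primitives).

# stamp a solid tube of radius r between two points into a logical array
stamp_tube <- function(arr, p0, p1, r) {
  d <- dim(arr)
  n <- ceiling(sqrt(sum((p1 - p0)^2))) * 2
  for (t in seq(0, 1, length.out = n + 1)) {
    c0 <- p0 + t * (p1 - p0)
    ri <- ceiling(r)
    xs <- max(1, floor(c0[1] - ri)):min(d[1], ceiling(c0[1] + ri))
    ys <- max(1, floor(c0[2] - ri)):min(d[2], ceiling(c0[2] + ri))
    zs <- max(1, floor(c0[3] - ri)):min(d[3], ceiling(c0[3] + ri))
    g <- expand.grid(x = xs, y = ys, z = zs)
    keep <- (g$x - c0[1])^2 + (g$y - c0[2])^2 + (g$z - c0[3])^2 <= r^2
    arr[cbind(g$x, g$y, g$z)[keep, , drop = FALSE]] <- TRUE
  }
  arr
}

# axis-aligned digital cylinder along x
make_cylinder <- function(r, len = 100L) {
  pad <- 2L * ceiling(r) + 4L
  d <- c(len, 2L * pad + 1L, 2L * pad + 1L)
  tube <- array(FALSE, d)
  c0 <- pad + 1L
  for (y in seq_len(d[2])) for (z in seq_len(d[3]))
    if ((y - c0)^2 + (z - c0)^2 <= r^2) tube[, y, z] <- TRUE
  tube
}

# Y-shaped union of three tubes meeting at one junction
make_y_mask <- function(r = 2.5) {
  a <- array(FALSE, c(64, 64, 64))
  j <- c(32, 32, 20)
  a <- stamp_tube(a, c(32, 32, 4), j, r)
  a <- stamp_tube(a, j, c(16, 32, 48), r)
  stamp_tube(a, j, c(48, 32, 48), r)
}

# rooted binary tree of tubes with two branching levels:
# 3 junctions, 4 leaves + 1 root end = 5 endpoints
make_tree_mask <- function(r = 2.5) {
  b <- array(FALSE, c(96, 64, 96))
  b <- stamp_tube(b, c(48, 32, 4), c(48, 32, 28), r)
  b <- stamp_tube(b, c(48, 32, 28), c(28, 32, 52), r)
  b <- stamp_tube(b, c(48, 32, 28), c(68, 32, 52), r)
  b <- stamp_tube(b, c(28, 32, 52), c(16, 32, 80), r)
  b <- stamp_tube(b, c(28, 32, 52), c(40, 32, 80), r)
  b <- stamp_tube(b, c(68, 32, 52), c(56, 32, 80), r)
  stamp_tube(b, c(68, 32, 52), c(80, 32, 80), r)
}

# brute-force 26-neighbour count at given coordinates
brute_neighbor_count <- function(mask, coords) {
  d <- dim(mask)
  apply(coords, 1, function(p) {
    cnt <- 0L
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- p + c(dx, dy, dz)
      if (all(q >= 1) && all(q <= d) && mask[q[1], q[2], q[3]]) cnt <- cnt + 1L
    }
    cnt
  })
}

# brute-force 26-connected components via BFS on coordinates
brute_component_sizes <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  coords <- which(mask, arr.ind = TRUE)
  nxt <- 0L
  sizes <- integer(0)
  for (i in seq_len(nrow(coords))) {
    p <- coords[i, ]
    if (lab[p[1], p[2], p[3]] != 0L) next
    nxt <- nxt + 1L
    queue <- list(p)
    lab[p[1], p[2], p[3]] <- nxt
    size <- 0L
    while (length(queue)) {
      q <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      size <- size + 1L
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        w <- q + c(dx, dy, dz)
        if (all(w >= 1) && all(w <= d) && mask[w[1], w[2], w[3]] &&
            lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- nxt
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

dice_of <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# compact phantom world reused across tests (the stated conditions:
# eps 0.25, 1.41 um voxels, class means 60/140/220, noise sd 10)
small_phantom <- function(seed, shape = c(96L, 96L, 96L), ...) {
  dots <- list(...)
  if (!"vessel_radii_um" %in% names(dots) && min(shape) < 96) {
    # scale the vessel classes down so they fit thin test slabs
    dots$vessel_radii_um <- c(small = 8, large = 12)
    dots$vessel_max_counts <- c(small = Inf, large = 2)
  }
  cfg <- do.call(phantom_config, c(list(shape = shape, seed = seed), dots))
  truth <- generate_shive_phantom(cfg, seed)
  truth <- grow_hyphae_phantom(truth, cfg)
  list(cfg = cfg, truth = truth)
}
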