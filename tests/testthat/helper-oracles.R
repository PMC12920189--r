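# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (no EDT, no Hungarian, no labeling).

# all-pairs surface-distance HD95 (6-connectivity surface, like the package)
brute_hd95 <- function(a, b, q = 0.95) {
  surf <- function(m) {
    v <- m$values
    d <- dim(v)
    keep <- array(FALSE, d)
    idx <- which(v, arr.ind = TRUE)
    offs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
    for (r in seq_len(nrow(idx))) {
      x <- idx[r, ]
      for (off in offs) {
        y <- x + off
        if (any(y < 1) || any(y > d) || !v[y[1], y[2], y[3]]) {
          keep[x[1], x[2], x[3]] <- TRUE
          break
        }
      }
    }
    which(keep, arr.ind = TRUE)
  }
  sp <- a$spacing
  pa <- t(t(surf(a)) * sp)
  pb <- t(t(surf(b)) * sp)
  dm2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  dm2[dm2 < 0] <- 0
  dm <- sqrt(dm2)
  max(stats::quantile(apply(dm, 1, min), q, names = FALSE, type = 7),
      stats::quantile(apply(dm, 2, min), q, names = FALSE, type = 7))
}

brute_voxelwise <- function(gt, pred) {
  g <- gt$values
  p <- pred$values
  ov <- sum(g & p)
  list(dice = 100 * 2 * ov / (sum(g) + sum(p)),
       recall = 100 * ov / sum(g),
       precision = 100 * ov / sum(p))
}

# recursive flood fill with an explicit stack, 26-connectivity
brute_components <- function(values) {
  d <- dim(values)
  lab <- array(0L, d)
  cur <- 0L
  for (s in which(values)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      z <- (v - 1) %/% (d[1] * d[2]) + 1
      rem <- (v - 1) %% (d[1] * d[2])
      y <- rem %/% d[1] + 1
      x <- rem %% d[1] + 1
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        xx <- x + dx; yy <- y + dy; zz <- z + dz
        if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3])
          next
        if (values[xx, yy, zz] && lab[xx, yy, zz] == 0L) {
          lab[xx, yy, zz] <- cur
          stack <- c(stack, (zz - 1) * d[1] * d[2] + (yy - 1) * d[1] + xx)
        }
      }
    }
  }
  lab
}

# exhaustive optimal assignment: maximise total pairwise Dice
brute_best_assignment <- function(dice) {
  n <- nrow(dice); m <- ncol(dice)
  if (n <= m) {
    perms <- utils::combn(m, n, simplify = FALSE)
    best <- 0
    for (cols in perms) {
      for (p in all_perms(cols)) {
        tot <- sum(dice[cbind(seq_len(n), p)])
        if (tot > best) best <- tot
      }
    }
    best
  } else {
    brute_best_assignment(t(dice))
  }
}

all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in all_perms(x[-i]))
      out[[length(out) + 1]] <- c(x[i], rest)
  out
}

# a mask holding a solid axis-aligned cuboid
cube_mask <- function(dim3, lo, size, spacing = c(1, 1, 1)) {
  v <- array(FALSE, dim = dim3)
  v[lo[1]:(lo[1] + size[1] - 1), lo[2]:(lo[2] + size[2] - 1),
    lo[3]:(lo[3] + size[3] - 1)] <- TRUE
  binary_mask(v, spacing)
}

# randomly overlapping structure sets for refinement invariants
random_structure_set <- function(seed, dim3 = c(32, 32, 32), postop = FALSE) {
  set.seed(seed)
  brain <- binary_mask(array(TRUE, dim3))
  rnd_sphere <- function(vol)
    synth_component_mask(vol, dim3, c(1, 1, 1), runif(3, 10, 22))
  if (!postop) {
    structure_set(list(
      TC = rnd_sphere(runif(1, 1, 4)),
      NETC = rnd_sphere(runif(1, 0.3, 2)),
      SNFH = rnd_sphere(runif(1, 1, 5)),
      BRAIN = brain))
  } else {
    structure_set(list(
      ET = rnd_sphere(runif(1, 0.2, 1.5)),
      CAVITY = rnd_sphere(runif(1, 1, 4)),
      SNFH = rnd_sphere(runif(1, 1, 5)),
      BRAIN = brain))
  }
}

# small phantom parameters used when full-size geometry is not the point
small_params <- function() {
  phantom_params(grid_shape = c(64, 64, 64),
                 brain_axes_mm = c(27, 29, 25),
                 tc_volume_ml = c(8, 16),
                 cavity_volume_ml = c(5, 10))
}
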