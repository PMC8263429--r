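# Independent brute-force oracles, deliberately written against different
# primitives than the package (vectorised label propagation instead of BFS,
# array shifts instead of C++ neighbour loops, explicit order-statistic
# interpolation instead of stats::quantile).

oracle_offsets <- function(connectivity) {
  offs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    o <- abs(dx) + abs(dy) + abs(dz)
    if (o == 0) next
    if (connectivity == 6 && o > 1) next
    if (connectivity == 18 && o > 2) next
    offs[[length(offs) + 1]] <- c(dx, dy, dz)
  }
  offs
}

# shifted(v) = arr(v - offset); cells shifted in from outside get `fill`
oracle_shift <- function(arr, offset, fill) {
  d <- dim(arr)
  out <- array(fill, dim = d)
  idx_src <- idx_dst <- vector("list", 3)
  for (a in 1:3) {
    o <- offset[a]
    if (abs(o) >= d[a]) return(out)
    if (o >= 0) {
      idx_src[[a]] <- seq_len(d[a] - o)
      idx_dst[[a]] <- seq_len(d[a] - o) + o
    } else {
      idx_src[[a]] <- seq_len(d[a] + o) - o
      idx_dst[[a]] <- seq_len(d[a] + o)
    }
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Connected components by iterated min-id propagation to a fixed point,
# then relabelled 1..k in ascending order of each component's smallest
# column-major linear index.
oracle_label <- function(arr, connectivity = 26) {
  d <- dim(arr)
  cur <- array(Inf, dim = d)
  cur[arr] <- which(arr)
  offs <- oracle_offsets(connectivity)
  repeat {
    nxt <- cur
    for (o in offs) {
      sh <- oracle_shift(cur, o, Inf)
      nxt <- array(pmin(nxt, sh), dim = d)
    }
    nxt[!arr] <- Inf
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  ids <- sort(unique(cur[is.finite(cur)]))
  lab <- array(0L, dim = d)
  if (length(ids)) lab[arr] <- match(cur[arr], ids)
  lab
}

# face-neighbour inner boundary via logical shifts (grid edge counts out)
oracle_boundary <- function(arr) {
  d <- dim(arr)
  faces <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  any_out <- array(FALSE, dim = d)
  for (o in faces) {
    neigh <- oracle_shift(arr, -o, FALSE)  # neigh(v) = arr(v + o)
    any_out <- any_out | !neigh
  }
  arr & any_out
}

# all-pairs directed minimum distances in physical mm, one per src row
oracle_min_dists <- function(src_coords, ref_coords, spacing) {
  ref_mm <- sweep(ref_coords - 1, 2, spacing, `*`)
  apply(src_coords, 1, function(v) {
    p <- (v - 1) * spacing
    sqrt(min(rowSums(sweep(ref_mm, 2, p, `-`)^2)))
  })
}

# linear interpolation between closest order statistics
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  if (n == 1) return(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_dice <- function(a, b) {
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(NA_real_)
  sum(a & b) / (0.5 * na + 0.5 * nb)
}

# full structure-level detection recount from raw arrays
oracle_detection <- function(truth_arr, pred_arr, connectivity = 26,
                             threshold = 0.5) {
  lt <- oracle_label(truth_arr, connectivity)
  lp <- oracle_label(pred_arr, connectivity)
  cfrac_of <- function(lab, k, ref) sum(ref[lab == k]) / sum(lab == k)
  kp <- max(lp); kt <- max(lt)
  cf_pred <- if (kp) vapply(1:kp, cfrac_of, numeric(1), lab = lp,
                            ref = truth_arr) else numeric(0)
  cf_truth <- if (kt) vapply(1:kt, cfrac_of, numeric(1), lab = lt,
                             ref = pred_arr) else numeric(0)
  list(cf_pred = cf_pred, cf_truth = cf_truth,
       tp_cnn = sum(cf_pred > threshold), fp = sum(cf_pred <= threshold),
       tp_gt = sum(cf_truth > threshold), fn = sum(cf_truth <= threshold))
}

# reproducible random blob-ish test mask: thresholded smoothed noise
random_mask_array <- function(d, p = 0.2, seed = 1) {
  set.seed(seed)
  arr <- array(stats::runif(prod(d)) < p, dim = d)
  arr
}

solid_cube_mask <- function(grid, lo, edge, spacing = c(1, 1, 1)) {
  arr <- array(FALSE, dim = grid)
  arr[lo[1]:(lo[1] + edge - 1), lo[2]:(lo[2] + edge - 1),
      lo[3]:(lo[3] + edge - 1)] <- TRUE
  binary_mask(arr, spacing)
}
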