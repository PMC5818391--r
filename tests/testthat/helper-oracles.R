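# Independent oracles used to check package operations.

# 26-connected component by iterative minimum-label propagation (an
# algorithm independent of the package's frontier BFS): every qualifying
# voxel starts with its own label; labels relax to the neighbourhood
# minimum until a fixed point; the component is the seed's label class.
oracle_component_26 <- function(qual, seed_idx) {
  d <- dim(qual)
  lab <- array(as.numeric(seq_along(qual)), d)
  lab[!qual] <- NA_real_
  shift_arr <- function(a, o) {
    out <- array(NA_real_, d)
    src <- lapply(1:3, function(ax) {
      i <- seq_len(d[ax]) - o[ax]
      i[i < 1 | i > d[ax]] <- NA
      i
    })
    ok <- lapply(src, function(i) which(!is.na(i)))
    out[ok[[1]], ok[[2]], ok[[3]]] <-
      a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
    out
  }
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  repeat {
    new <- lab
    for (k in seq_len(nrow(offs))) {
      sh <- shift_arr(lab, offs[k, ])
      new <- pmin(new, sh, na.rm = TRUE)
    }
    new[!qual] <- NA_real_
    if (identical(new, lab)) break
    lab <- new
  }
  !is.na(lab) & lab == lab[seed_idx[1], seed_idx[2], seed_idx[3]]
}

# Closed-form center value of a uniform unit ball of radius R convolved
# with an isotropic Gaussian (sigma), written from the 1-D radial integral.
oracle_ball_center <- function(R, sigma) {
  erf1 <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  erf1(R / (sigma * sqrt(2))) - sqrt(2 / pi) * (R / sigma) * exp(-R^2 / (2 * sigma^2))
}

# Brute-force single-slice CT disk: voxel centers in slice iz within the
# in-plane radius.
oracle_ct_disk <- function(grid, center, radius) {
  xs <- grid$origin[1] + (seq_len(grid$dims[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$dims[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(grid$dims[3]) - 1) * grid$spacing[3]
  iz <- which.min(abs(zs - center[3]))
  # tie: lower index (which.min already returns the first minimum)
  sel <- outer((xs - center[1])^2, (ys - center[2])^2, `+`) <= radius^2
  list(iz = iz, sel = sel)
}
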