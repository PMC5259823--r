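# Independent brute-force oracles. These deliberately avoid the
# package's code paths: random (seeded) sphere sampling instead of the
# Fibonacci lattice, Monte-Carlo volume integration instead of the
# cubic grid, and plain-loop recounting for the propensity formulas.

# Brute-force ASA of a set of spheres: per sphere, n random surface
# points; a point is accessible when outside every other sphere.
# xyz: n x 3 centres; radii: already expanded (vdw + probe).
brute_asa <- function(xyz, radii, n = 1e5, seed = 42) {
  set.seed(seed)
  m <- nrow(xyz)
  vapply(seq_len(m), function(i) {
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * radii[i], 2, xyz[i, ], "+")
    ok <- rep(TRUE, n)
    for (j in seq_len(m)[-i]) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      ok <- ok & d2 >= radii[j]^2
    }
    mean(ok) * 4 * pi * radii[i]^2
  }, numeric(1))
}

# Monte-Carlo estimate of the fraction of a probe sphere lying outside
# all occluding spheres.
mc_outside_fraction <- function(center, centers, radii, sphere_radius,
                                n = 1e6, seed = 7) {
  set.seed(seed)
  pts <- matrix(stats::runif(3 * n, -sphere_radius, sphere_radius), ncol = 3)
  pts <- pts[rowSums(pts^2) <= sphere_radius^2, , drop = FALSE]
  pts <- sweep(pts, 2, center, "+")
  if (is.null(centers) || !nrow(centers)) return(1)
  out <- rep(TRUE, nrow(pts))
  for (j in seq_len(nrow(centers))) {
    d2 <- (pts[, 1] - centers[j, 1])^2 + (pts[, 2] - centers[j, 2])^2 +
      (pts[, 3] - centers[j, 3])^2
    out <- out & d2 >= radii[j]^2
  }
  mean(out)
}

# Plain-loop recount of interface/non-interface frequencies and RIR
# from raw residue-type lists.
recount_rir <- function(iface_types, noniface_types) {
  keys <- sort(unique(c(iface_types, noniface_types)))
  f <- w <- Fc <- W <- numeric(length(keys))
  names(f) <- names(w) <- names(Fc) <- names(W) <- keys
  for (t in iface_types) f[t] <- f[t] + 1
  for (t in noniface_types) Fc[t] <- Fc[t] + 1
  for (k in keys) {
    w[k] <- f[k] / sum(f)
    W[k] <- Fc[k] / sum(Fc)
  }
  list(f = f, F = Fc, w = w, W = W,
       rir = ifelse(W > 0, w / W, NA_real_))
}
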