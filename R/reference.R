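# Internal reference-chain builder. One idealized backbone is constructed in
# chemical bonding order (NeRF placement plus in-plane trilateration for the
# hydrogens); every discretization distance of the DMDGP order is then
# measured from it, which guarantees a mutually consistent, feasible distance
# set whose solution set is exactly the torsion-sign (orientation-bit)
# mirror family of the reference chain.

.deg <- function(x) x * pi / 180

# standard NeRF placement: point d with |d - c| = bond, angle(b, c, d) = angle,
# torsion(a, b, c, d) = torsion (degrees)
nerf_place <- function(a, b, c, bond, angle, torsion) {
  th <- .deg(angle)
  ph <- .deg(torsion)
  bc <- c - b
  bc <- bc / .norm3(bc)
  n <- .cross3(b - a, bc)
  nn <- .norm3(n)
  if (nn <= 1e-12) stop("degenerate-reference: collinear NeRF frame")
  n <- n / nn
  m <- .cross3(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# measured torsion (degrees) of four points, used by tests as an oracle
measure_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / .norm3(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# law of cosines for a 1-3 distance
.d13 <- function(r1, r2, angle) sqrt(r1^2 + r2^2 - 2 * r1 * r2 * cos(.deg(angle)))

# Build an idealized backbone chain in chemical order. Returns a list of
# coordinates keyed "KIND.res". Torsions: psi_i about CA-C (magnitude
# params$psi), phi_i about N-CA (magnitude params$phi), omega about C-N
# (params$omega plus optional jitter drawn from the current RNG stream).
build_reference_chain <- function(n_residues, params) {
  p <- params
  at <- new.env(parent = emptyenv())
  put <- function(kind, res, xyz) assign(paste0(kind, ".", res), xyz, envir = at)
  get1 <- function(kind, res) get(paste0(kind, ".", res), envir = at)

  put("N", 1L, c(0, 0, 0))
  put("CA", 1L, c(p$b_n_ca, 0, 0))
  thr <- .deg(p$a_n_ca_c)
  put("C", 1L, c(p$b_n_ca - p$b_ca_c * cos(thr), p$b_ca_c * sin(thr), 0))
  place_ha <- function(res) {
    ca <- get1("CA", res); n <- get1("N", res); cc <- get1("C", res)
    pts <- trilaterate(ca, n, cc,
                       p$b_ca_ha,
                       .d13(p$b_ca_ha, p$b_n_ca, p$a_n_ca_ha),
                       .d13(p$b_ca_ha, p$b_ca_c, p$a_c_ca_ha),
                       tol = 1e-6)
    if (length(pts) == 0L)
      stop("infeasible-geometry: HA placement impossible for these angles")
    pts[[1L]] # consistent handedness for every residue
  }
  put("HA", 1L, place_ha(1L))

  omegas <- rep(p$omega, max(0L, n_residues - 1L))
  if (p$omega_jitter > 0 && n_residues > 1L)
    omegas <- omegas + stats::rnorm(n_residues - 1L, 0, p$omega_jitter)

  for (i in seq_len(n_residues)[-1L]) {
    n_prev <- get1("N", i - 1L); ca_prev <- get1("CA", i - 1L)
    c_prev <- get1("C", i - 1L)
    ni <- nerf_place(n_prev, ca_prev, c_prev, p$b_c_n, p$a_ca_c_n, p$psi)
    put("N", i, ni)
    cai <- nerf_place(ca_prev, c_prev, ni, p$b_n_ca, p$a_c_n_ca, omegas[i - 1L])
    put("CA", i, cai)
    # amide hydrogen: fixed by its angles to C(i-1) and CA(i); exactly in the
    # C-N-CA plane because the three angles around N sum to 360 degrees
    hpts <- trilaterate(ni, c_prev, cai,
                        p$b_n_h,
                        .d13(p$b_n_h, p$b_c_n, p$a_c_n_h),
                        .d13(p$b_n_h, p$b_n_ca, p$a_h_n_ca),
                        tol = 1e-4)
    if (length(hpts) == 0L)
      stop("infeasible-geometry: H placement impossible for these angles")
    put("H", i, hpts[[1L]])
    ci <- nerf_place(c_prev, ni, cai, p$b_ca_c, p$a_n_ca_c, p$phi)
    put("C", i, ci)
    put("HA", i, place_ha(i))
  }
  at
}

# Discretization distance set for the order, measured from a reference chain:
# the pairwise distances of the first three vertices plus, for every t >= 4,
# the distances from t to t-1, t-2, t-3. Returns a data frame (i, j, value).
reference_distances <- function(order, chain) {
  key <- paste0(order$kind, ".", order$residue)
  coords <- t(vapply(key, function(k) get(k, envir = chain), numeric(3L)))
  np <- nrow(order)
  ii <- c(1L, 1L, 2L)
  jj <- c(2L, 3L, 3L)
  for (t in 4:np) {
    ii <- c(ii, t - 1L, t - 2L, t - 3L)
    jj <- c(jj, t, t, t)
  }
  val <- sqrt(rowSums((coords[ii, , drop = FALSE] - coords[jj, , drop = FALSE])^2))
  data.frame(i = ii, j = jj, value = val)
}
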