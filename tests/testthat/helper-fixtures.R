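# Shared fixtures: all built in code, nothing on disk.

# Rectangular bar volume + mask (label T5) for closed-form FE oracles.
# Optionally two HU layers stacked in z (hu2 for the upper half).
bar_fixture <- function(width = 10, depth = 10, height = 20, hu = 500,
                        hu2 = NULL, spacing = 1) {
  pad <- 2
  nx <- width + 2 * pad
  ny <- depth + 2 * pad
  nz <- height + 2 * pad
  vox <- array(0, c(nx, ny, nz))
  lab <- array(0L, c(nx, ny, nz))
  xs <- seq_len(nx) - 1
  in_x <- xs >= pad & xs < pad + width
  in_y <- (seq_len(ny) - 1) >= pad & (seq_len(ny) - 1) < pad + depth
  in_z <- (seq_len(nz) - 1) >= pad & (seq_len(nz) - 1) < pad + height
  bar <- outer(outer(in_x, in_y, "&"), in_z, "&")
  vox[bar] <- hu
  if (!is.null(hu2)) {
    upper <- (seq_len(nz) - 1) >= pad + height / 2
    bar_up <- outer(outer(in_x, in_y, "&"), in_z & upper, "&")
    vox[bar_up] <- hu2
  }
  lab[bar] <- 5L  # T5
  list(volume = ct_volume(vox, spacing = rep(spacing, 3)),
       mask = label_mask(lab, spacing = rep(spacing, 3)))
}

# Elastic-only material cards (no yielding within the test range)
elastic_cards <- function(n, E = 1000) {
  tibble::tibble(E_z = rep(E, n), sigma = 1e9, sigma_min = 1e9, eps_ab = 1)
}

# Independent dense-assembly oracle for an isotropic 8-node hexahedron:
# Lame-form constitutive matrix and 3x3x3 Gauss quadrature, coded separately
# from the implementation under test.
oracle_iso_hex_stiffness <- function(E, nu, hx, hy, hz) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  # Gauss points and weights (3-point rule)
  gp <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5, 8, 5) / 9
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  signs <- signs[c(1, 2, 4, 3, 5, 6, 8, 7), ]  # standard corner order
  K <- matrix(0, 24, 24)
  for (a in 1:3) for (b in 1:3) for (c3 in 1:3) {
    xi <- gp[a]; eta <- gp[b]; zeta <- gp[c3]
    w <- gw[a] * gw[b] * gw[c3] * hx * hy * hz / 8
    B <- matrix(0, 6, 24)
    for (i in 1:8) {
      sx <- signs[i, 1]; sy <- signs[i, 2]; sz <- signs[i, 3]
      dx <- sx * (1 + eta * sy) * (1 + zeta * sz) / 8 * 2 / hx
      dy <- sy * (1 + xi * sx) * (1 + zeta * sz) / 8 * 2 / hy
      dz <- sz * (1 + xi * sx) * (1 + eta * sy) / 8 * 2 / hz
      j <- 3 * (i - 1)
      B[1, j + 1] <- dx; B[2, j + 2] <- dy; B[3, j + 3] <- dz
      B[4, j + 2] <- dz; B[4, j + 3] <- dy
      B[5, j + 1] <- dz; B[5, j + 3] <- dx
      B[6, j + 1] <- dy; B[6, j + 2] <- dx
    }
    K <- K + t(B) %*% D %*% B * w
  }
  K
}

# Brute-force AUC oracle: fraction of (positive, negative) pairs with the
# positive scored higher, ties counted one half.
oracle_pair_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
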