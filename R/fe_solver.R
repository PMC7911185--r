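#' Nonlinear displacement-controlled compression of a meshed vertebra
#'
#' The solver performs an incremental displacement-controlled compression:
#' the inferior endplate nodes are constrained, the superior endplate nodes
#' are driven downward in uniform z-steps, and after every step the element
#' principal stresses (centroid values) are checked against the material
#' strength limits. Elements follow a three-state pseudo-plastic law:
#' ELASTIC until the maximum principal stress exceeds the tensile limit or
#' the magnitude of the minimum principal stress exceeds the compressive
#' limit, then YIELDED with the tangent stiffness scaled to a plastic
#' plateau (5% by default), then FAILED (softening, 0.1%) once the
#' accumulated post-yield strain exceeds the plastic strain capacity. The
#' run ends at the prescribed total displacement or as soon as the reaction
#' falls below a fraction of its running maximum. The failure point is the
#' peak of the recorded load-displacement curve.
#'
#' All element elasticity matrices are proportional to one unit transversely
#' isotropic matrix (the anisotropy ratios are fixed by the material
#' mapping), so assembly scales a single reference hexahedron stiffness by
#' the per-element axial modulus times its state factor.
#'
#' @name fe_solver
NULL

# 6x24 strain-displacement matrix of the 8-node hex at natural point (xi,
# eta, zeta), for a box element with edges (hx, hy, hz). Voigt order
# (xx, yy, zz, yz, xz, xy), engineering shears.
hex_b_matrix <- function(xi, eta, zeta, hx, hy, hz) {
  s <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
             c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  B <- matrix(0, 6, 24)
  for (i in 1:8) {
    dNdx <- 0.125 * s[i, 1] * (1 + eta * s[i, 2]) * (1 + zeta * s[i, 3]) * 2 / hx
    dNdy <- 0.125 * s[i, 2] * (1 + xi * s[i, 1]) * (1 + zeta * s[i, 3]) * 2 / hy
    dNdz <- 0.125 * s[i, 3] * (1 + xi * s[i, 1]) * (1 + eta * s[i, 2]) * 2 / hz
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- dNdx
    B[2, c0 + 2] <- dNdy
    B[3, c0 + 3] <- dNdz
    B[4, c0 + 2] <- dNdz; B[4, c0 + 3] <- dNdy
    B[5, c0 + 1] <- dNdz; B[5, c0 + 3] <- dNdx
    B[6, c0 + 1] <- dNdy; B[6, c0 + 2] <- dNdx
  }
  B
}

#' Stiffness matrix of a single box hexahedral element
#'
#' Full 2x2x2 Gauss integration of an 8-node hexahedron with edge lengths
#' `hx`, `hy`, `hz` (mm) and elasticity matrix `D` (MPa, Voigt order
#' xx, yy, zz, yz, xz, xy).
#'
#' @param D 6x6 elasticity matrix.
#' @param hx,hy,hz Element edge lengths in mm.
#' @return The 24x24 element stiffness (N/mm), dof order
#'   (u1, v1, w1, ..., u8, v8, w8).
#' @export
hex_stiffness <- function(D, hx, hy, hz = hx) {
  g <- 1 / sqrt(3)
  detJ <- hx * hy * hz / 8
  K <- matrix(0, 24, 24)
  for (xi in c(-g, g)) for (eta in c(-g, g)) for (zeta in c(-g, g)) {
    B <- hex_b_matrix(xi, eta, zeta, hx, hy, hz)
    K <- K + crossprod(B, D %*% B) * detJ
  }
  (K + t(K)) / 2
}

# per-element dof index matrix (m x 24)
element_dofs <- function(elements) {
  m <- nrow(elements)
  out <- matrix(0L, m, 24)
  for (i in 1:8) {
    base <- 3L * (elements[, i] - 1L)
    out[, 3 * (i - 1) + 1] <- base + 1L
    out[, 3 * (i - 1) + 2] <- base + 2L
    out[, 3 * (i - 1) + 3] <- base + 3L
  }
  out
}

#' Assemble the global stiffness matrix of a mesh
#'
#' Sparse symmetric assembly; each element contributes its axial modulus
#' (times an optional per-element state factor) multiplied into the
#' reference unit-modulus hexahedron stiffness.
#'
#' @param mesh A [build_mesh()] result.
#' @param cards [material_cards()] for the mesh.
#' @param state_factor Optional per-element stiffness multiplier (default 1;
#'   the solver passes its plastic/softening factors here).
#' @return A symmetric sparse matrix (`Matrix::dsCMatrix`), 3 dofs per node.
#' @export
assemble_stiffness <- function(mesh, cards, state_factor = NULL) {
  stopifnot(inherits(mesh, "vertefail_mesh"), nrow(cards) == nrow(mesh$elements))
  scale <- cards$E_z * (state_factor %||% 1)
  e <- mesh$edge_length
  K_ref <- hex_stiffness(unit_elasticity_matrix(), e, e, e)
  edofs <- element_dofs(mesh$elements)
  asm <- assembly_index(edofs)
  assemble_from_scale(asm, as.vector(K_ref), scale, 3L * nrow(mesh$nodes))
}

assembly_index <- function(edofs) {
  list(
    i = as.vector(edofs[, rep(1:24, times = 24)]),
    j = as.vector(edofs[, rep(1:24, each = 24)])
  )
}

assemble_from_scale <- function(asm, kref_vec, scale, ndof) {
  x <- as.vector(outer(scale, kref_vec))
  K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = x, dims = c(ndof, ndof))
  Matrix::forceSymmetric(K)
}

# Precompute the triplet aggregation map for one block of the partitioned
# stiffness (rows/cols renumbered by rank vectors; rank 0 = outside block).
# Assemblies then reduce to a scale lookup, one rowsum() and an @x refill
# of a fixed-pattern template.
block_map <- function(i_rank, j_rank, elem_of, kref_of, kref_vec,
                      nrow, ncol, symmetric = FALSE) {
  sel <- which(i_rank > 0L & j_rank > 0L & (!symmetric | i_rank <= j_rank))
  io <- i_rank[sel]; jo <- j_rank[sel]
  ord <- order(jo, io)
  ios <- io[ord]; jos <- jo[ord]
  nsel <- length(sel)
  newgrp <- c(TRUE, ios[-1] != ios[-nsel] | jos[-1] != jos[-nsel])
  pos <- integer(nsel); pos[ord] <- cumsum(newgrp)
  template <- Matrix::sparseMatrix(i = ios[newgrp], j = jos[newgrp],
                                   x = rep(0, sum(newgrp)), dims = c(nrow, ncol),
                                   symmetric = symmetric)
  ends <- c(which(newgrp[-1]), nsel)  # last triplet index of each group
  list(elem = elem_of[sel][ord], kv = kref_vec[kref_of[sel]][ord], ends = ends,
       template = template)
}

# aggregate sorted triplet values into the template's slot vector by
# cumulative-sum differencing (grouped sums without hashing)
block_fill <- function(blk, scale) {
  cs <- cumsum(scale[blk$elem] * blk$kv)
  M <- blk$template
  M@x <- cs[blk$ends] - c(0, cs[blk$ends[-length(blk$ends)]])
  M
}

# vectorized eigenvalues of symmetric 3x3 tensors in Voigt rows
# (xx, yy, zz, yz, xz, xy); returns m x 3, descending
principal_sym3 <- function(V, engineering_shear = FALSE) {
  V <- matrix(V, ncol = 6)
  a <- V[, 1]; b <- V[, 2]; c <- V[, 3]
  sh <- if (engineering_shear) 0.5 else 1
  d <- sh * V[, 4]; e <- sh * V[, 5]; f <- sh * V[, 6]
  q <- (a + b + c) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * (d^2 + e^2 + f^2)
  p <- sqrt(pmax(p2, 0) / 6)
  aq <- a - q; bq <- b - q; cq <- c - q
  detB <- aq * (bq * cq - d^2) - f * (f * cq - d * e) + e * (f * d - bq * e)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  cbind(e1, 3 * q - e1 - e3, e3)
}

#' @describeIn fe_solver Run the incremental compression analysis.
#' @param mesh A [build_mesh()] result.
#' @param cards [material_cards()] for the mesh.
#' @param total_displacement Prescribed displacement magnitude in mm
#'   (default 2% of the specimen height).
#' @param n_steps Number of equal displacement increments (default 40).
#' @param post_yield,post_failure Tangent stiffness factors of yielded and
#'   failed elements.
#' @param stop_fraction Stop once the reaction falls below this fraction of
#'   its running maximum.
#' @param residual_stress On failure an element's accumulated stress is
#'   released down to this fraction (crushed trabecular bone retains a small
#'   residual strength); the release is what makes the global reaction curve
#'   soften and peak.
#' @param constraint `"fixed"` fully fixes the inferior nodes (the default
#'   compression boundary condition); `"uniaxial"` constrains only their z
#'   dof (plus minimal lateral pins against rigid modes), which reproduces
#'   uniaxial closed-form solutions exactly and is used by validation
#'   oracles.
#' @return A `load_displacement_curve` tibble: `step`, `displacement` (mm),
#'   `reaction` (N, compression positive), `n_yielded`, `n_failed`; with
#'   attributes `flags` (e.g. divergence) and `height` (mm).
#' @export
solve_compression <- function(mesh, cards, total_displacement = NULL,
                              n_steps = 40, post_yield = 0.05,
                              post_failure = 0.001, stop_fraction = 0.7,
                              residual_stress = 0.05,
                              constraint = c("fixed", "uniaxial")) {
  constraint <- match.arg(constraint)
  stopifnot(inherits(mesh, "vertefail_mesh"), nrow(cards) == nrow(mesh$elements))
  m <- nrow(mesh$elements)
  nn <- nrow(mesh$nodes)
  ndof <- 3L * nn
  height <- diff(range(mesh$nodes[, 3]))
  if (is.null(total_displacement)) total_displacement <- 0.02 * height
  if (total_displacement <= 0) {
    abort("total_displacement must be > 0", class = "vertefail_solver_error")
  }
  inf_n <- mesh$inferior_nodes
  sup_n <- mesh$superior_nodes
  if (length(inf_n) == 0 || length(sup_n) == 0) {
    abort("boundary node sets must be nonempty", class = "vertefail_solver_error")
  }
  sup_z <- 3L * (sup_n - 1L) + 3L
  cdofs <- if (constraint == "fixed") {
    c(as.vector(t(cbind(3L * (inf_n - 1L) + 1L, 3L * (inf_n - 1L) + 2L,
                        3L * (inf_n - 1L) + 3L))), sup_z)
  } else {
    ord <- inf_n[order(mesh$nodes[inf_n, 1], mesh$nodes[inf_n, 2])]
    pin_a <- ord[1]                 # pin x and y
    pin_b <- ord[length(ord)]       # pin y (blocks rotation about z)
    c(3L * (inf_n - 1L) + 3L,
      3L * (pin_a - 1L) + 1L, 3L * (pin_a - 1L) + 2L,
      3L * (pin_b - 1L) + 2L, sup_z)
  }
  cdofs <- unique(cdofs)
  uc_pat <- numeric(length(cdofs))
  uc_pat[match(sup_z, cdofs)] <- -1   # unit downward displacement
  fdofs <- setdiff(seq_len(ndof), cdofs)

  e <- mesh$edge_length
  D_unit <- unit_elasticity_matrix()
  K_ref_vec <- as.vector(hex_stiffness(D_unit, e, e, e))
  Bc <- hex_b_matrix(0, 0, 0, e, e, e)         # 6 x 24, centroid
  tBc <- t(Bc)
  tD <- t(D_unit)
  elem_vol <- e^3
  edofs <- element_dofs(mesh$elements)
  sup_sel <- which(as.vector(edofs) %in% sup_z)  # entries feeding loaded dofs
  asm <- assembly_index(edofs)
  # precomputed triplet -> (element, K_ref entry) decomposition and the
  # aggregation maps for the free-free and free-constrained blocks
  L <- length(asm$i)
  elem_of <- rep.int(seq_len(m), 576)
  kref_of <- rep(seq_len(576), each = m)
  free_rank <- integer(ndof); free_rank[fdofs] <- seq_along(fdofs)
  cons_rank <- integer(ndof); cons_rank[cdofs] <- seq_along(cdofs)
  blk_ff <- block_map(free_rank[asm$i], free_rank[asm$j], elem_of, kref_of,
                      K_ref_vec, length(fdofs), length(fdofs), symmetric = TRUE)
  blk_fc <- block_map(free_rank[asm$i], cons_rank[asm$j], elem_of, kref_of,
                      K_ref_vec, length(fdofs), length(cdofs), symmetric = FALSE)

  state <- integer(m)                 # 0 elastic, 1 yielded, 2 failed
  factors <- c(1, post_yield, post_failure)
  eq_at_yield <- rep(NA_real_, m)
  sig <- matrix(0, m, 6)
  eps <- matrix(0, m, 6)

  dd <- total_displacement / n_steps
  du <- numeric(ndof)
  need_assemble <- TRUE
  chol_fac <- NULL
  K <- NULL
  du_f_unit <- NULL
  reaction <- 0
  max_reaction <- 0
  flags <- character(0)
  rows <- vector("list", n_steps)
  n_rec <- 0L

  for (step in seq_len(n_steps)) {
    if (need_assemble) {
      scale_eff <- cards$E_z * factors[state + 1L]
      Kff <- block_fill(blk_ff, scale_eff)
      Kfc <- block_fill(blk_fc, scale_eff)
      ok <- tryCatch({
        chol_fac <- if (is.null(chol_fac)) {
          Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE)
        } else {
          Matrix::update(chol_fac, Kff)
        }
        TRUE
      }, error = function(err) FALSE)
      if (!ok) {
        flags <- c(flags, "diverged")
        break
      }
      du_f_unit <- as.numeric(Matrix::solve(chol_fac, -(Kfc %*% uc_pat)))
      need_assemble <- FALSE
    }
    du[fdofs] <- du_f_unit * dd
    du[cdofs] <- uc_pat * dd

    Ue <- matrix(du[edofs], m, 24)
    d_eps <- Ue %*% tBc
    eps <- eps + d_eps
    sig <- sig + (d_eps %*% tD) * (cards$E_z * factors[state + 1L])

    p_sig <- principal_sym3(sig)
    p_eps <- principal_sym3(eps, engineering_shear = TRUE)
    eq <- pmax(abs(p_eps[, 1]), abs(p_eps[, 3]))

    yield_now <- state == 0L &
      (p_sig[, 1] > cards$sigma | -p_sig[, 3] > cards$sigma_min)
    fail_now <- state == 1L & (eq - eq_at_yield > cards$eps_ab)
    if (any(yield_now)) {
      state[yield_now] <- 1L
      eq_at_yield[yield_now] <- eq[yield_now]
    }
    if (any(fail_now)) {
      state[fail_now] <- 2L
      sig[fail_now, ] <- residual_stress * sig[fail_now, ]
    }
    if (any(yield_now) || any(fail_now)) need_assemble <- TRUE

    # reaction transmitted through the loaded surface, from element
    # internal forces (this is what softens when failed stress is released)
    reaction <- -sum(as.vector(sig %*% Bc)[sup_sel]) * elem_vol

    n_rec <- n_rec + 1L
    rows[[n_rec]] <- c(step, step * dd, reaction, sum(state >= 1L), sum(state == 2L))
    max_reaction <- max(max_reaction, reaction)
    if (n_rec >= 2 && reaction < stop_fraction * max_reaction) {
      flags <- c(flags, "stopped_at_softening")
      break
    }
  }

  if (n_rec == 0L) {
    abort("solver diverged before completing a single step",
          class = "vertefail_solver_error")
  }
  rec <- do.call(rbind, rows[seq_len(n_rec)])
  curve <- tibble(
    step = as.integer(rec[, 1]), displacement = rec[, 2], reaction = rec[, 3],
    n_yielded = as.integer(rec[, 4]), n_failed = as.integer(rec[, 5])
  )
  structure(curve, class = c("load_displacement_curve", class(curve)),
            flags = flags, height = height,
            total_displacement = total_displacement)
}

#' Extract the failure point from a load-displacement curve
#'
#' The failure load is the global maximum of the recorded reaction; the
#' failure displacement is the prescribed displacement at that maximum.
#' Ties break toward the smallest displacement. A curve that rises
#' monotonically to its last step never softened, so the last point is
#' returned flagged `"no_peak_observed"`.
#'
#' @param curve A [solve_compression()] result (>= 2 recorded steps).
#' @return A `failure_point` list: `failure_load` (N), `failure_displacement`
#'   (mm), `flag` (`"ok"` or `"no_peak_observed"`).
#' @export
extract_failure <- function(curve) {
  if (nrow(curve) < 2) {
    abort("need at least 2 recorded steps", class = "vertefail_solver_error")
  }
  imax <- which.max(curve$reaction)   # first maximum: smallest displacement
  flag <- if (imax == nrow(curve) && all(diff(curve$reaction) >= 0)) {
    "no_peak_observed"
  } else {
    "ok"
  }
  structure(list(failure_load = curve$reaction[imax],
                 failure_displacement = curve$displacement[imax],
                 flag = flag),
            class = "failure_point")
}

#' @export
print.failure_point <- function(x, ...) {
  cat(sprintf("<failure_point> load = %.1f N at %.3f mm%s\n",
              x$failure_load, x$failure_displacement,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}
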