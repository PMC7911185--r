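test_that("the hex stiffness matches an independent isotropic dense oracle", {
  E <- 1500; nu <- 0.3
  card <- tibble::tibble(E_x = E, E_y = E, E_z = E,
                         G_xy = E / (2 * (1 + nu)), G_xz = E / (2 * (1 + nu)),
                         G_yz = E / (2 * (1 + nu)),
                         nu_xy = nu, nu_xz = nu, nu_yz = nu)
  for (dims in list(c(2, 2, 2), c(1.5, 2, 3))) {
    K <- hex_stiffness(elasticity_matrix(card), dims[1], dims[2], dims[3])
    K_oracle <- oracle_iso_hex_stiffness(E, nu, dims[1], dims[2], dims[3])
    expect_lt(max(abs(K - K_oracle)) / max(abs(K_oracle)), 1e-8)
  }
})

test_that("assembled stiffness has rigid-body null space and is linear in moduli", {
  bar <- bar_fixture(width = 4, depth = 4, height = 6, hu = 300)
  mesh <- build_mesh(bar$mask, bar$volume, "T5", edge_length = 2)
  cards <- material_cards(mesh)
  K <- assemble_stiffness(mesh, cards)
  expect_s4_class(K, "dsCMatrix")
  # rigid translation along each axis gives zero force (before BCs)
  for (ax in 1:3) {
    u <- numeric(3 * nrow(mesh$nodes))
    u[seq(ax, length(u), by = 3)] <- 1
    expect_lt(max(abs(K %*% u)), 1e-8 * max(abs(K)))
  }
  cards2 <- cards; cards2$E_z <- 2 * cards$E_z
  K2 <- assemble_stiffness(mesh, cards2)
  expect_equal(as.matrix(K2), 2 * as.matrix(K), tolerance = 1e-12)
})

test_that("a homogeneous elastic bar reproduces E*A*d/L within 2%", {
  bar <- bar_fixture(width = 10, depth = 10, height = 20, hu = 500)
  mesh <- build_mesh(bar$mask, bar$volume, "T5", edge_length = 2)
  E <- 1000
  cards <- elastic_cards(nrow(mesh$elements), E = E)
  d <- 0.05
  curve <- solve_compression(mesh, cards, total_displacement = d, n_steps = 5,
                             constraint = "uniaxial")
  A <- 10 * 10; L <- 20
  expect_lt(abs(curve$reaction[5] - E * A * d / L) / (E * A * d / L), 0.02)
})

test_that("two layers in series add their compliances within 2%", {
  bar <- bar_fixture(width = 10, depth = 10, height = 20, hu = 500)
  mesh <- build_mesh(bar$mask, bar$volume, "T5", edge_length = 2)
  E1 <- 800; E2 <- 1600
  z_mid <- mean(range(mesh$nodes[, 3]))
  elem_zc <- rowMeans(matrix(mesh$nodes[mesh$elements, 3], nrow(mesh$elements), 8))
  cards <- elastic_cards(nrow(mesh$elements), E = E1)
  cards$E_z[elem_zc > z_mid] <- E2
  d <- 0.05
  curve <- solve_compression(mesh, cards, total_displacement = d, n_steps = 5,
                             constraint = "uniaxial")
  A <- 100
  k_series <- A / (10 / E1 + 10 / E2)
  expect_lt(abs(curve$reaction[5] - k_series * d) / (k_series * d), 0.02)
})

test_that("a compression-limited bar plateaus near sigma_min * A", {
  bar <- bar_fixture(width = 10, depth = 10, height = 20, hu = 500)
  mesh <- build_mesh(bar$mask, bar$volume, "T5", edge_length = 2)
  E <- 1000; smin <- 2.0
  cards <- tibble::tibble(E_z = rep(E, nrow(mesh$elements)), sigma = 1e9,
                          sigma_min = smin, eps_ab = 0.01)
  curve <- solve_compression(mesh, cards, total_displacement = 0.1, n_steps = 100,
                             constraint = "uniaxial")
  A <- 100
  # reaction at the step where the whole bar has just yielded
  at_yield <- which(curve$n_yielded == nrow(mesh$elements))[1]
  expect_false(is.na(at_yield))
  expect_lt(abs(curve$reaction[at_yield] - smin * A) / (smin * A), 0.05)
})

test_that("the elastic regime is linear in displacement to 1e-6 relative", {
  bar <- bar_fixture(width = 6, depth = 6, height = 10, hu = 400)
  mesh <- build_mesh(bar$mask, bar$volume, "T5", edge_length = 2)
  cards <- elastic_cards(nrow(mesh$elements))
  curve <- solve_compression(mesh, cards, total_displacement = 0.02, n_steps = 8)
  slopes <- curve$reaction / curve$displacement
  expect_lt(max(abs(slopes - slopes[1])) / slopes[1], 1e-6)
})

test_that("scaling all moduli and strengths by c scales the failure load by c", {
  v <- make_vertebra_volume("T9", 120, noise_sd = 5, seed = 4)
  mesh <- build_mesh(v$mask, v$volume, "T9", edge_length = 2.5)
  cards <- material_cards(mesh)
  curve1 <- solve_compression(mesh, cards, n_steps = 20)
  cards_c <- cards
  cc <- 1.7
  cards_c$E_z <- cc * cards$E_z
  cards_c$sigma <- cc * cards$sigma
  cards_c$sigma_min <- cc * cards$sigma_min
  curve2 <- solve_compression(mesh, cards_c, n_steps = 20)
  expect_equal(nrow(curve1), nrow(curve2))
  expect_equal(curve2$n_yielded, curve1$n_yielded)
  expect_equal(curve2$reaction, cc * curve1$reaction, tolerance = 1e-10)
  fp1 <- extract_failure(curve1); fp2 <- extract_failure(curve2)
  expect_equal(fp2$failure_load, cc * fp1$failure_load, tolerance = 1e-10)
  expect_equal(fp2$failure_displacement, fp1$failure_displacement)
})

test_that("failure extraction takes the peak with first-occurrence ties", {
  mk <- function(d, r) {
    structure(tibble::tibble(step = seq_along(d), displacement = d, reaction = r,
                             n_yielded = 0L, n_failed = 0L),
              class = c("load_displacement_curve", "tbl_df", "tbl", "data.frame"))
  }
  fp <- extract_failure(mk(c(0.1, 0.2, 0.3), c(100, 180, 150)))
  expect_equal(fp$failure_load, 180)
  expect_equal(fp$failure_displacement, 0.2)
  expect_equal(fp$flag, "ok")

  rising <- extract_failure(mk(c(0.1, 0.2, 0.3), c(100, 150, 180)))
  expect_equal(rising$failure_displacement, 0.3)
  expect_equal(rising$flag, "no_peak_observed")

  tie <- extract_failure(mk(c(0.1, 0.2, 0.3, 0.4), c(100, 180, 150, 180)))
  expect_equal(tie$failure_displacement, 0.2)

  expect_error(extract_failure(mk(0.1, 100)), class = "vertefail_solver_error")
})

test_that("larger lumbar bodies fail at higher load and displacement than thoracic", {
  fp_for <- function(level) {
    v <- make_vertebra_volume(level, 130, noise_sd = 0)
    mesh <- build_mesh(v$mask, v$volume, level, edge_length = 2.5)
    extract_failure(solve_compression(mesh, material_cards(mesh), n_steps = 25))
  }
  t6 <- fp_for("T6"); l4 <- fp_for("L4")
  expect_gt(l4$failure_load, t6$failure_load)
  expect_gt(l4$failure_displacement, t6$failure_displacement)
})
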