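test_that("a solid cube meshes to the exact expected element count", {
  cube <- bar_fixture(width = 20, depth = 20, height = 20, hu = 300)
  m2 <- build_mesh(cube$mask, cube$volume, "T5", edge_length = 2)
  expect_equal(nrow(m2$elements), (20 / 2)^3)  # 1000
  m25 <- build_mesh(cube$mask, cube$volume, "T5", edge_length = 2.5)
  expect_equal(nrow(m25$elements), (20 / 2.5)^3)  # 512
})

test_that("element count on a sphere tracks its volume within 10%", {
  r <- 10
  n <- 2 * r + 5
  cc <- (n + 1) / 2
  coords <- seq_len(n) - cc
  inside <- outer(outer(coords^2, coords^2, "+"), coords^2, "+") <= r^2
  lab <- array(0L, c(n, n, n)); lab[inside] <- 5L
  vol <- ct_volume(array(200, c(n, n, n)))
  mask <- label_mask(lab)
  for (e in c(2, 2.5)) {
    m <- build_mesh(mask, vol, "T5", edge_length = e)
    expect_lt(abs(nrow(m$elements) - (4 / 3) * pi * r^3 / e^3) /
                ((4 / 3) * pi * r^3 / e^3), 0.1)
  }
})

test_that("mesh volume matches the mask volume within 10% at fine edges", {
  v <- make_vertebra_volume("T10", 130, noise_sd = 0)
  mask_vol <- sum(v$mask$labels == 10L) * prod(v$mask$spacing)
  for (e in c(1.5, 2)) {
    m <- build_mesh(v$mask, v$volume, "T10", edge_length = e)
    expect_lt(abs(mesh_volume(m) - mask_vol) / mask_vol, 0.1)
  }
})

test_that("meshing is deterministic and validates its inputs", {
  v <- make_vertebra_volume("T6", 110, noise_sd = 5, seed = 9)
  a <- build_mesh(v$mask, v$volume, "T6")
  b <- build_mesh(v$mask, v$volume, "T6")
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$elements, b$elements)
  expect_identical(a$element_hu, b$element_hu)

  expect_error(build_mesh(v$mask, v$volume, "T6", edge_length = 0.5),
               class = "vertefail_mesh_error")
  expect_error(build_mesh(v$mask, v$volume, "L5"),  # empty label
               class = "vertefail_mesh_error")
})

test_that("boundary sets are the disjoint endplate node layers of the body", {
  v <- make_vertebra_volume("L1", 130, noise_sd = 0)
  m <- build_mesh(v$mask, v$volume, "L1")
  expect_gt(length(m$inferior_nodes), 0)
  expect_gt(length(m$superior_nodes), 0)
  expect_length(intersect(m$inferior_nodes, m$superior_nodes), 0)
  # mesh z extent ~ body height (posterior block is shorter and inset)
  geo <- vertebra_geometry("L1")
  expect_lt(abs(diff(range(m$nodes[, 3])) - geo$h), 2 * m$edge_length)
  # no orphan nodes; all elements reference valid nodes
  expect_setequal(sort(unique(as.vector(m$elements))), seq_len(nrow(m$nodes)))
})

test_that("a disconnected mask keeps its largest component with a warning", {
  lab <- array(0L, c(24, 10, 10))
  lab[2:9, 3:8, 3:8] <- 5L       # big block (8x6x6)
  lab[18:20, 3:5, 3:5] <- 5L     # small far block
  vol <- ct_volume(array(100, dim(lab)))
  expect_warning(m <- build_mesh(label_mask(lab), vol, "T5", edge_length = 2),
                 "largest component")
  expect_lte(mesh_volume(m), 8 * 6 * 6 * 1.5)
})

test_that("the convergence sweep is mesh-independent on a homogeneous bar", {
  bar <- bar_fixture(width = 15, depth = 15, height = 15, hu = 400)
  edges <- c(1.5, 2.5, 3)  # all divide the bar dimensions exactly
  sweep <- convergence_sweep(bar$mask, bar$volume, "T5", edges = edges,
                             constraint = "uniaxial")
  expect_equal(nrow(sweep), length(edges))
  ref <- sweep$failure_load[1]
  expect_true(all(abs(sweep$failure_load - ref) / ref < 0.01))
  expect_equal(attr(sweep, "selected_edge"), 3)
})

test_that("the mesh text dump is written and parseable", {
  bar <- bar_fixture(width = 6, depth = 6, height = 8, hu = 300)
  m <- build_mesh(bar$mask, bar$volume, "T5", edge_length = 2)
  path <- file.path(withr::local_tempdir(), "mesh.txt")
  write_mesh(m, path)
  lines <- readLines(path)
  expect_true(any(lines == "nodes"))
  expect_true(any(lines == "elements"))
  expect_true(any(startsWith(lines, "inferior")))
})
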