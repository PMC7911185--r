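#' Build a voxel-coarsened hexahedral FE mesh of a labelled vertebra
#'
#' Overlays a regular grid of cubic 8-node hexahedra (edge `edge_length`)
#' on the labelled region and keeps every element at least half of whose
#' volume lies inside the mask (estimated from the voxel centers it
#' contains). Element HU is the mean HU of its member voxels. Boundary node
#' sets are the mesh faces at the lowest/highest z extent of the vertebral
#' body (the endplates); the posterior-element block does not span the full
#' body height and therefore never contributes boundary nodes. Meshing is
#' deterministic.
#'
#' @param mask A [label_mask()].
#' @param volume Congruent [ct_volume()] supplying HU.
#' @param level Vertebral level name.
#' @param edge_length Element edge length in mm (1 to 4; 2 mm default, the
#'   mesh-converged value).
#' @param min_fill Minimum inside-volume fraction for keeping an element.
#' @return A `vertefail_mesh`: `nodes` (n x 3 mm), `elements` (m x 8 node
#'   indices, standard isoparametric corner order), `element_hu`,
#'   `element_fill`, `edge_length`, `inferior_nodes`, `superior_nodes`.
#' @export
build_mesh <- function(mask, volume, level, edge_length = 2, min_fill = 0.5) {
  check_congruent(volume, mask)
  if (edge_length < 1 || edge_length > 4) {
    abort("edge_length must be within [1, 4] mm", class = "vertefail_mesh_error")
  }
  lab <- level_label(level)
  idx <- which(mask$labels == lab, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    abort(sprintf("empty mask for level %s", level), class = "vertefail_mesh_error")
  }
  sp <- mask$spacing
  # world coordinates of member voxel centers
  cx <- mask$origin[1] + (idx[, 1] - 1) * sp[1]
  cy <- mask$origin[2] + (idx[, 2] - 1) * sp[2]
  cz <- mask$origin[3] + (idx[, 3] - 1) * sp[3]
  hu <- volume$voxels[idx]

  # element grid tiles the mask's physical bounding box (voxel boundaries,
  # not centers), so masks whose extent is a multiple of the edge length
  # coarsen without spurious half-filled boundary layers
  g0 <- c(min(cx), min(cy), min(cz)) - sp / 2
  ex <- floor((cx - g0[1]) / edge_length)
  ey <- floor((cy - g0[2]) / edge_length)
  ez <- floor((cz - g0[3]) / edge_length)
  ndx <- max(ex) + 1; ndy <- max(ey) + 1; ndz <- max(ez) + 1
  cell <- ex + ndx * (ey + ndy * ez)  # 0-based linear cell id

  agg <- tibble(cell = cell, hu = hu) %>%
    group_by(.data$cell) %>%
    summarise(n = dplyr::n(), hu = mean(.data$hu), .groups = "drop")
  # denominator: how many voxel centers of the full grid fall in each cell
  # (counting actual centers, not edge^3/voxel volume, avoids parity
  # artifacts when the edge is not an integer multiple of the spacing)
  axis_cell_counts <- function(n_axis, orig, spc, g0_a, n_cells) {
    centers <- orig + (seq_len(n_axis) - 1) * spc
    k <- floor((centers - g0_a) / edge_length)
    tabulate(k[k >= 0 & k < n_cells] + 1L, nbins = n_cells)
  }
  dims <- dim(mask$labels)
  cnt_x <- axis_cell_counts(dims[1], mask$origin[1], sp[1], g0[1], ndx)
  cnt_y <- axis_cell_counts(dims[2], mask$origin[2], sp[2], g0[2], ndy)
  cnt_z <- axis_cell_counts(dims[3], mask$origin[3], sp[3], g0[3], ndz)
  cell_x <- agg$cell %% ndx
  cell_y <- (agg$cell %/% ndx) %% ndy
  cell_z <- agg$cell %/% (ndx * ndy)
  agg$fill <- agg$n / (cnt_x[cell_x + 1] * cnt_y[cell_y + 1] * cnt_z[cell_z + 1])
  agg <- filter(agg, .data$fill >= min_fill)
  if (nrow(agg) == 0) {
    abort("no element passes the volume-fill rule", class = "vertefail_mesh_error")
  }

  kx <- agg$cell %% ndx
  ky <- (agg$cell %/% ndx) %% ndy
  kz <- agg$cell %/% (ndx * ndy)

  comp <- largest_component(kx, ky, kz)
  if (!all(comp)) {
    warn(sprintf("mesh is disconnected; keeping largest component (%d of %d elements)",
                 sum(comp), length(comp)))
    agg <- agg[comp, , drop = FALSE]
    kx <- kx[comp]; ky <- ky[comp]; kz <- kz[comp]
  }

  # lattice nodes: corner (i,j,k) of cell (kx,ky,kz) has lattice index
  # (kx+i, ky+j, kz+k), i,j,k in {0,1}
  nnx <- ndx + 1; nny <- ndy + 1
  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  m <- nrow(agg)
  conn_lat <- matrix(0L, m, 8)
  for (c8 in 1:8) {
    conn_lat[, c8] <- (kx + corner[c8, 1]) +
      nnx * ((ky + corner[c8, 2]) + nny * (kz + corner[c8, 3]))
  }
  used <- sort(unique(as.vector(conn_lat)))
  elements <- matrix(match(conn_lat, used), m, 8)
  li <- used %% nnx
  lj <- (used %/% nnx) %% nny
  lk <- used %/% (nnx * nny)
  nodes <- cbind(g0[1] + li * edge_length,
                 g0[2] + lj * edge_length,
                 g0[3] + lk * edge_length)

  zmin <- min(nodes[, 3]); zmax <- max(nodes[, 3])
  tol <- edge_length / 10
  inferior <- which(nodes[, 3] < zmin + tol)
  superior <- which(nodes[, 3] > zmax - tol)
  if (length(inferior) == 0 || length(superior) == 0 ||
      length(intersect(inferior, superior)) > 0) {
    abort("boundary node sets must be disjoint and nonempty (mesh too thin?)",
          class = "vertefail_mesh_error")
  }

  structure(list(
    nodes = nodes, elements = elements,
    element_hu = agg$hu, element_fill = agg$fill,
    edge_length = edge_length, level = level,
    inferior_nodes = inferior, superior_nodes = superior
  ), class = "vertefail_mesh")
}

#' @export
print.vertefail_mesh <- function(x, ...) {
  cat(sprintf("<vertefail_mesh> %s: %d hex elements (%.1f mm edge), %d nodes, %d/%d boundary nodes\n",
              x$level %||% "?", nrow(x$elements), x$edge_length, nrow(x$nodes),
              length(x$inferior_nodes), length(x$superior_nodes)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# face-adjacency connected components on lattice cells; returns logical
# membership of the largest component (frontier-expansion flood fill)
largest_component <- function(kx, ky, kz) {
  m <- length(kx)
  key <- function(x, y, z) paste(x, y, z)
  id <- setNames(seq_len(m), key(kx, ky, kz))
  offs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  comp <- integer(m)
  cur <- 0L
  for (s in seq_len(m)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      nb <- integer(0)
      for (d in 1:6) {
        cand <- id[key(kx[frontier] + offs[d, 1], ky[frontier] + offs[d, 2],
                       kz[frontier] + offs[d, 3])]
        nb <- c(nb, cand[!is.na(cand)])
      }
      nb <- unique(nb[comp[nb] == 0L])
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp == which.max(tabulate(comp))
}

#' Mesh total volume (mm^3)
#' @param mesh A `vertefail_mesh`.
#' @return Total element volume in mm^3.
#' @export
mesh_volume <- function(mesh) nrow(mesh$elements) * mesh$edge_length^3

#' Mesh convergence sweep over element edge lengths
#'
#' Runs the full mesh + material + nonlinear compression pipeline for a
#' ladder of element edge lengths and reports the failure load per edge,
#' plus the coarsest edge whose failure load is within `tol` (default 5%)
#' of the finest edge's value.
#'
#' @param mask,volume,level As in [build_mesh()].
#' @param edges Edge lengths in mm (default 1.5 to 3.0 by 0.25).
#' @param tol Relative agreement threshold against the finest edge.
#' @param ... Passed to [solve_compression()].
#' @return A tibble `(edge_length, n_elements, failure_load,
#'   failure_displacement, rel_dev)` with attribute `selected_edge`.
#' @export
convergence_sweep <- function(mask, volume, level,
                              edges = seq(1.5, 3, by = 0.25), tol = 0.05, ...) {
  rows <- purrr::map_dfr(edges, function(e) {
    mesh <- build_mesh(mask, volume, level, edge_length = e)
    cards <- material_cards(mesh)
    curve <- solve_compression(mesh, cards, ...)
    fp <- extract_failure(curve)
    tibble(edge_length = e, n_elements = nrow(mesh$elements),
           failure_load = fp$failure_load,
           failure_displacement = fp$failure_displacement)
  })
  ref <- rows$failure_load[which.min(rows$edge_length)]
  rows$rel_dev <- abs(rows$failure_load - ref) / ref
  ok <- rows$edge_length[rows$rel_dev <= tol]
  attr(rows, "selected_edge") <- if (length(ok) > 0) max(ok) else min(rows$edge_length)
  rows
}

#' Write a mesh to a simple portable text format
#'
#' Three sections (`nodes`, `elements`, `sets`) in plain text; readable by
#' eye and by any downstream tool.
#'
#' @param mesh A `vertefail_mesh`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# vertefail mesh: %d nodes, %d hex elements, edge %.3f mm",
                     nrow(mesh$nodes), nrow(mesh$elements), mesh$edge_length), con)
  writeLines("nodes", con)
  utils::write.table(format(mesh$nodes, digits = 10), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines("elements", con)
  utils::write.table(mesh$elements, con, row.names = FALSE, col.names = FALSE)
  writeLines("sets", con)
  writeLines(paste("inferior", paste(mesh$inferior_nodes, collapse = " ")), con)
  writeLines(paste("superior", paste(mesh$superior_nodes, collapse = " ")), con)
  invisible(path)
}
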