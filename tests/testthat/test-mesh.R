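# Mesh generation: region tags, conformity, refinement, quality, export.

geom <- build_anatomy(anatomy_params())

test_that("refinement strictly increases node count; quality above threshold", {
  mc <- mesh_geometry(geom, "coarse", 2)
  mm <- mesh_geometry(geom, "medium", 2)
  expect_gt(nrow(mm$nodes), nrow(mc$nodes))
  expect_gt(mc$quality, 1)
  expect_gt(mm$quality, 1)
})

test_that("element region areas match the analytic region areas", {
  m <- mesh_geometry(geom, "coarse", 2)
  elems <- do.call(cbind, lapply(m$blocks, function(b) b$elems[c(1, 3, 6), ]))
  region <- unlist(lapply(m$blocks, `[[`, "region"))
  ar <- vapply(seq_len(ncol(elems)), function(e) {
    P <- m$nodes[elems[, e], , drop = FALSE]
    abs((P[2, 1] - P[1, 1]) * (P[3, 2] - P[1, 2]) -
          (P[3, 1] - P[1, 1]) * (P[2, 2] - P[1, 2])) / 2
  }, numeric(1))
  for (rg in seq_along(m$region_names)) {
    got <- sum(ar[region == rg])
    ref <- geom$areas[[m$region_names[rg]]]
    if (rg == 3L) {
      # the fat cedes the apex wedge and the sheath-corner chord by design:
      # meshed area sits a few percent below the ideal region, never above
      expect_gt(got / ref, 0.90)
      expect_lt(got / ref, 1.001)
    } else {
      expect_equal(got, ref, tolerance = 0.005,
                   label = paste("area of", m$region_names[rg]))
    }
  }
})

test_that("every element carries exactly one region tag and all are used", {
  m <- mesh_geometry(geom, "coarse", 2)
  region <- unlist(lapply(m$blocks, `[[`, "region"))
  nel <- sum(vapply(m$blocks, function(b) ncol(b$elems), 1))
  expect_equal(length(region), nel)
  expect_setequal(unique(region), 1:5)
})

test_that("tied interfaces are conforming, the contact interface is not", {
  eye <- mesh_eye(geom, "coarse", 2)
  # vitreous boundary nodes coincide with shell inner nodes (shared ids):
  # the inner sclera chain nodes must belong to both a shell and a
  # vitreous element
  ids <- eye$chains$inner_sclera[c(2, 5, 10)]
  for (n in ids) {
    regs <- unique(eye$region[apply(eye$elems == n, 2, any)])
    expect_true(all(c(1L, 2L) %in% regs))
  }
  # fat nodes are disjoint from eye nodes in the combined mesh
  comb <- mesh_geometry(geom, "coarse", 2)
  expect_gt(length(comb$contact$slave), 10)
  expect_true(all(comb$contact$slave > comb$n_eye))
})

test_that("contact surfaces coincide at rest (no penetration, tight gaps)", {
  m <- mesh_geometry(geom, "coarse", 2)
  ci <- contact_interface(m)
  expect_gt(min(ci$gap, na.rm = TRUE), -1e-3)
  # slaves sit on the master surface except along the excised corner chords
  # and the apex truncation (about a fifth of the chain)
  expect_gt(mean(abs(ci$gap) < 1e-3), 0.75)
  expect_true(all(ci$tangential == 0))
})

test_that("boundary chains lie on their geometric curves", {
  m <- mesh_eye(geom, "coarse", 2)
  out <- m$nodes[m$chains$outer_sclera, ]
  mis <- abs((out[, 1] / geom$a_o)^2 + ((out[, 2] - geom$zc) / geom$b_o)^2 - 1)
  # all but the canal-cut end lie on the outer ellipse
  expect_lt(max(mis[seq_len(length(mis) - 2)]), 1e-8)
  inn <- m$nodes[m$chains$inner_sclera, ]
  mis <- abs((inn[, 1] / geom$a_i)^2 + ((inn[, 2] - geom$zc) / geom$b_i)^2 - 1)
  expect_lt(max(mis), 1e-8)
})

test_that("mesh export writes readable VTK and MSH", {
  m <- mesh_eye(geom, "coarse", 2)
  f1 <- tempfile(fileext = ".vtk")
  write_vtk(m, f1, point_data = list(uz = m$nodes[, 2]))
  txt <- readLines(f1)
  expect_true(any(grepl("UNSTRUCTURED_GRID", txt)))
  expect_true(any(grepl("POINT_DATA", txt)))
  f2 <- tempfile(fileext = ".msh")
  write_msh(m, f2)
  txt <- readLines(f2)
  expect_true(any(grepl("\\$Nodes", txt)))
  expect_true(any(grepl("ocular_coats", txt)))
  expect_equal(as.integer(txt[which(txt == "$Nodes") + 1]), nrow(m$nodes))
  unlink(c(f1, f2))
})

test_that("quartic elevation produces valid meshes with more nodes", {
  m2 <- mesh_eye(geom, "coarse", 2)
  m4 <- mesh_eye(geom, "coarse", 4)
  expect_gt(nrow(m4$nodes), 2 * nrow(m2$nodes))
  expect_equal(nrow(m4$elems), 15) # 15-node quartic triangles
  # isoparametric maps are invertible at the quadrature points
  tab <- orbitfem:::basis_tables(4)
  ef <- element_fields(m4, tissue_registry(),
                       numeric(2 * nrow(m4$nodes)))
  expect_true(all(is.finite(ef[, "J"])))
  expect_equal(unname(ef[, "J"]), rep(1, ncol(m4$elems)), tolerance = 1e-9)
})
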