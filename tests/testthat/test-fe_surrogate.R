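test_that("geometry invariants are enforced with informative errors", {
  expect_error(geometry_params(cortical_thickness = 25),
               "cortical_thickness")
  expect_error(geometry_params(implant_length = 30), "implant_length")
  expect_error(geometry_params(implant_diameter = 20), "implant_diameter")
  expect_error(geometry_params(mesh_density = 0), "mesh_density")
  expect_error(geometry_params(notch_depth = 2), "notch_depth")
})

test_that("default mesh has three populated regions and boundary tags", {
  mesh <- build_mesh(geometry_params())
  expect_setequal(unique(mesh$region),
                  c("titanium", "cortical", "trabecular"))
  for (tag in c("inferior_border", "mesial_border", "distal_border")) {
    expect_gt(length(mesh$boundary[[tag]]), 0)
  }
  expect_gt(nrow(mesh$boundary$load_surface), 0)
  # no degenerate triangles
  areas <- vapply(seq_len(nrow(mesh$elements)), function(e) {
    n <- mesh$elements[e, ]
    ((mesh$nodes[n[2], 1] - mesh$nodes[n[1], 1]) *
       (mesh$nodes[n[3], 2] - mesh$nodes[n[1], 2]) -
       (mesh$nodes[n[3], 1] - mesh$nodes[n[1], 1]) *
       (mesh$nodes[n[2], 2] - mesh$nodes[n[1], 2])) / 2
  }, numeric(1))
  expect_true(all(areas > 0))
})

test_that("meshing is deterministic and refinement preserves region areas", {
  p <- geometry_params(mesh_density = 0.8)
  m1 <- build_mesh(p, seed = 3L)
  m2 <- build_mesh(p, seed = 3L)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elements, m2$elements)

  fine <- build_mesh(geometry_params(mesh_density = 0.4))
  expect_gt(nrow(fine$elements), nrow(m1$elements))
  for (reg in c("titanium", "cortical", "trabecular")) {
    expect_equal(region_area(fine, reg), region_area(m1, reg),
                 tolerance = 0.01)
  }
})

test_that("homogeneous patch under uniform traction carries uniform stress", {
  fx <- make_analytic_fixture("patch")
  field <- assemble_and_solve(fx$mesh, fx$materials, fx$load)
  expect_lt(max(abs(field$syy - fx$expected$sigma_yy)), 1e-8)
  expect_lt(max(abs(field$sxx)), 1e-8)
  expect_lt(max(abs(field$von_mises - fx$expected$von_mises)), 1e-8)
})

test_that("stress scales linearly with load and is E-invariant when homogeneous", {
  fx <- make_analytic_fixture("patch")
  f1 <- assemble_and_solve(fx$mesh, fx$materials, fx$load)
  double_load <- load_case(axial = 2 * fx$load$axial, lingual = 0,
                           mesial = 0, angle_to_occlusal_plane = 90)
  f2 <- assemble_and_solve(fx$mesh, fx$materials, double_load)
  expect_lt(max(abs(f2$syy - 2 * f1$syy)), 1e-10 * max(abs(f1$syy)))

  # scaling the modulus of a homogeneous body leaves the stress unchanged
  stiffer <- list(titanium = elastic_material(
    2 * fx$materials$titanium$youngs_modulus, 0))
  f3 <- assemble_and_solve(fx$mesh, stiffer, fx$load)
  expect_lt(max(abs(f3$von_mises - f1$von_mises)),
            1e-10 * max(f1$von_mises))

  # ... but a bi-material mesh is statically indeterminate in E
  cfg <- default_study_config(mesh_density = 1.2)
  mesh <- build_mesh(cfg$geometry)
  fa <- assemble_and_solve(mesh, cfg$materials, cfg$load)
  mats2 <- cfg$materials
  mats2$titanium <- elastic_material(2e5, 0.3)
  fb <- assemble_and_solve(mesh, mats2, cfg$load)
  expect_gt(max(abs(fb$von_mises - fa$von_mises)) / max(fa$von_mises),
            0.01)
})

test_that("bi-material series strip matches the compound-bar closed form", {
  fx <- make_analytic_fixture("compound_bar")
  field <- assemble_and_solve(fx$mesh, fx$materials, fx$load)
  expect_equal(max(abs(field$syy - fx$expected$sigma_yy)) /
                 abs(fx$expected$sigma_yy), 0, tolerance = 0.02)
  u <- attr(field, "displacements")
  top_nodes <- which(abs(fx$mesh$nodes[, 2] -
                           max(fx$mesh$nodes[, 2])) < 1e-9)
  expect_equal(mean(u[2 * top_nodes]), fx$expected$end_displacement,
               tolerance = 0.02)
})

test_that("stress invariants follow the closed-form tensor algebra", {
  expect_equal(von_mises(100, 0, 0, 0), 100)
  expect_equal(max_principal(100, 0, 0, 0), 100)
  expect_equal(von_mises(50, 50, 0, 50), 0)
  expect_equal(von_mises(100, -100, 0, 0), sqrt(3) * 100)
  expect_equal(von_mises(100, -100, 0, 0), 173.205, tolerance = 1e-5)
  expect_equal(max_principal(100, -100, 0, 0), 100)
  # out-of-plane component can govern the principal value
  expect_equal(max_principal(10, 20, 0, 80), 80)
  # pure shear
  expect_equal(von_mises(0, 0, 10, 0), sqrt(3) * 10)
  expect_equal(max_principal(0, 0, 10, 0), 10)
})

test_that("critical point search arg-maxes with deterministic tie-breaking", {
  cfg <- default_study_config(mesh_density = 1.2)
  mesh <- build_mesh(cfg$geometry)
  field <- assemble_and_solve(mesh, cfg$materials, cfg$load)
  # uniform synthetic field: lowest element index wins
  fu <- field
  fu$von_mises <- rep(1, nrow(fu))
  expect_equal(find_critical_point(fu, mesh, "titanium")$element,
               which(mesh$region == "titanium")[1])
  # a single perturbed element is found
  target <- which(mesh$region == "cortical")[5]
  fu$von_mises[target] <- 2
  expect_equal(find_critical_point(fu, mesh, "cortical")$element, target)
  expect_error(find_critical_point(field, mesh, "enamel"), "empty")
})

test_that("the critical von Mises element sits in the implant neck band", {
  cfg <- default_study_config("external_hexagon")
  mesh <- build_mesh(cfg$geometry)
  field <- assemble_and_solve(mesh, cfg$materials, cfg$load)
  cp <- find_critical_point(field, mesh, "titanium", "von_mises")
  cy <- element_centroids(mesh)[cp$element, 2]
  H <- cfg$geometry$bone_height
  # neck band: within the upper quarter of the embedded implant depth
  # (junction region at/above the crest included)
  expect_gte(cy, H - cfg$geometry$implant_length / 4)
})

test_that("the critical von Mises value is mesh-converged within 5%", {
  vals <- vapply(c(0.5, 0.25), function(h) {
    cfg <- default_study_config(mesh_density = h)
    mesh <- build_mesh(cfg$geometry)
    field <- assemble_and_solve(mesh, cfg$materials, cfg$load)
    find_critical_point(field, mesh, "titanium")$value
  }, numeric(1))
  expect_lt(abs(vals[2] - vals[1]) / vals[1], 0.05)
})

test_that("notched strip concentrates stress and converges under refinement", {
  fx <- make_analytic_fixture("notched_strip")
  field <- assemble_and_solve(fx$mesh, fx$materials, fx$load)
  cp <- find_critical_point(field, fx$mesh, "titanium")
  # concentration: waist maximum well above the gross-section nominal
  expect_gt(cp$value, 1.2 * fx$load$axial / 6)
  # the titanium net section carries nearly the whole force, never more
  avg <- fx$expected$net_section_avg(fx$mesh, field)
  expect_lt(abs(avg), abs(fx$expected$nominal_net_stress))
  expect_equal(avg, fx$expected$nominal_net_stress, tolerance = 0.05)
  # the net-section functional is mesh-convergent and Richardson-stable
  ref <- fx$expected$reference_fn()
  expect_true(is.finite(ref$extrapolated))
  expect_lt(abs(ref$levels[3] - ref$levels[2]),
            abs(ref$levels[2] - ref$levels[1]))
  expect_equal(avg, ref$extrapolated, tolerance = 0.02)
})

test_that("mesh and stress fields round-trip through CSV export", {
  mesh <- build_mesh(geometry_params(mesh_density = 1.5))
  cfg <- default_study_config()
  field <- assemble_and_solve(mesh, cfg$materials, cfg$load)
  td <- withr::local_tempdir()
  export_mesh_csv(mesh, file.path(td, "nodes.csv"),
                  file.path(td, "elems.csv"))
  export_stress_csv(field, file.path(td, "stress.csv"))
  export_vtk(mesh, file.path(td, "mesh.vtk"),
             cell_scalars = list(von_mises = field$von_mises))
  nodes <- utils::read.csv(file.path(td, "nodes.csv"))
  elems <- utils::read.csv(file.path(td, "elems.csv"))
  stress <- utils::read.csv(file.path(td, "stress.csv"))
  expect_equal(nrow(nodes), nrow(mesh$nodes))
  expect_equal(nrow(elems), nrow(mesh$elements))
  expect_equal(stress$von_mises, field$von_mises)
  expect_true(file.exists(file.path(td, "mesh.vtk")))
})
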