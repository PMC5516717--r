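#' Geometry parameters for the 2D implant-in-bone surrogate
#'
#' Describes a buccolingual cross-section: a rectangular bone block with a
#' cortical band of given thickness over a trabecular core, and a titanium
#' implant bonded into the crest. The implant-abutment connection type is
#' encoded as a chamfered neck notch (a trapezoidal narrowing of the implant
#' just below the crest, with 45-degree chamfers); the external-hexagon
#' connection maps to a deeper notch than the internal one, reflecting its
#' weaker resistance to oblique loads.
#'
#' @param bone_height Bone section height, mm.
#' @param bone_width Bone section width, mm.
#' @param cortical_thickness Cortical band thickness, mm (< bone_height).
#' @param implant_length Implant length below the crest, mm (< bone_height).
#' @param implant_diameter Implant diameter, mm (< bone_width).
#' @param connection `"external_hexagon"` or `"internal_hexagon"`.
#' @param abutment_height Height of the abutment/crown column above the bone
#'   crest at which the occlusal load acts, mm. This is the moment arm that
#'   turns the transverse load component into neck bending.
#' @param mesh_density Target element edge length, mm.
#' @param notch_depth Neck-notch depth per side, mm; defaults to 0.6
#'   (external) or 0.3 (internal).
#' @param notch_band Depth interval of the notch below the crest, mm,
#'   default `c(0.5, 1.5)` (inside the cortical band).
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(bone_height = 22, bone_width = 15,
                            cortical_thickness = 2,
                            implant_length = 8, implant_diameter = 3.5,
                            connection = c("external_hexagon",
                                           "internal_hexagon"),
                            abutment_height = 7,
                            mesh_density = 0.5,
                            notch_depth = NULL,
                            notch_band = c(0.5, 1.5)) {
  connection <- match.arg(connection)
  if (is.null(notch_depth)) {
    notch_depth <- if (connection == "external_hexagon") 0.6 else 0.3
  }
  p <- list(bone_height = bone_height, bone_width = bone_width,
            cortical_thickness = cortical_thickness,
            implant_length = implant_length,
            implant_diameter = implant_diameter,
            connection = connection, abutment_height = abutment_height,
            mesh_density = mesh_density,
            notch_depth = notch_depth, notch_band = notch_band)
  for (f in c("bone_height", "bone_width", "cortical_thickness",
              "implant_length", "implant_diameter", "abutment_height",
              "mesh_density")) {
    if (!is.numeric(p[[f]]) || p[[f]] <= 0) {
      stop(sprintf("`%s` must be > 0", f), call. = FALSE)
    }
  }
  if (cortical_thickness >= bone_height) {
    stop("`cortical_thickness` must be smaller than `bone_height`",
         call. = FALSE)
  }
  if (implant_length >= bone_height) {
    stop("`implant_length` must be smaller than `bone_height`", call. = FALSE)
  }
  if (implant_diameter >= bone_width) {
    stop("`implant_diameter` must be smaller than `bone_width`",
         call. = FALSE)
  }
  if (notch_depth < 0 || notch_depth >= implant_diameter / 2) {
    stop("`notch_depth` must lie in [0, implant_diameter/2)", call. = FALSE)
  }
  structure(p, class = "geometry_params")
}

#' Linear elastic material
#'
#' @param youngs_modulus Young's modulus, MPa (> 0).
#' @param poisson_ratio Poisson's ratio in `[0, 0.5)`.
#' @return An object of class `elastic_material`.
#' @export
elastic_material <- function(youngs_modulus, poisson_ratio = 0.3) {
  stopifnot(youngs_modulus > 0, poisson_ratio >= 0, poisson_ratio < 0.5)
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio),
            class = "elastic_material")
}

#' Masticatory load case
#'
#' Occlusal force by component. The 2D surrogate collapses the lingual and
#' mesial components into a single in-plane transverse component equal to
#' their vector resultant; the axial component acts downward along the
#' implant axis.
#'
#' @param axial Axial (intrusive) component, N.
#' @param lingual Lingual component, N.
#' @param mesial Mesial component, N.
#' @param angle_to_occlusal_plane Resultant angle to the occlusal plane,
#'   degrees (metadata; the components define the direction).
#' @return An object of class `load_case` with fields `resultant` (N) and
#'   `transverse` (N, in-plane).
#' @export
load_case <- function(axial = 114.6, lingual = 17.1, mesial = 23.4,
                      angle_to_occlusal_plane = 75) {
  resultant <- sqrt(axial^2 + lingual^2 + mesial^2)
  if (resultant <= 0) stop("resultant load magnitude must be > 0",
                           call. = FALSE)
  structure(list(axial = axial, lingual = lingual, mesial = mesial,
                 angle_to_occlusal_plane = angle_to_occlusal_plane,
                 transverse = sqrt(lingual^2 + mesial^2),
                 resultant = resultant),
            class = "load_case")
}

# subdivide each breakpoint interval to the target edge length
refine_breaks <- function(breaks, h) {
  breaks <- sort(unique(breaks))
  out <- unlist(lapply(seq_len(length(breaks) - 1L), function(i) {
    n <- max(1L, ceiling((breaks[i + 1L] - breaks[i]) / h))
    seq(breaks[i], breaks[i + 1L], length.out = n + 1L)[-(n + 1L)]
  }))
  c(out, breaks[length(breaks)])
}

# structured triangulation of a tensor grid; region assigned by centroid
structured_mesh <- function(xs, ys, region_fun) {
  nx <- length(xs)
  ny <- length(ys)
  nodes <- cbind(x = rep(xs, times = ny), y = rep(ys, each = nx))
  cell_i <- rep(seq_len(nx - 1L), times = ny - 1L)
  cell_j <- rep(seq_len(ny - 1L), each = nx - 1L)
  bl <- (cell_j - 1L) * nx + cell_i
  br <- bl + 1L
  tl <- bl + nx
  tr <- tl + 1L
  # two CCW triangles per cell, diagonal bl-tr
  elements <- rbind(cbind(bl, br, tr), cbind(bl, tr, tl))
  ord <- order(rep(seq_along(bl), 2L), rep(c(1L, 2L), each = length(bl)))
  elements <- elements[ord, , drop = FALSE]
  dimnames(elements) <- NULL
  cx <- (nodes[elements[, 1], 1] + nodes[elements[, 2], 1] +
           nodes[elements[, 3], 1]) / 3
  cy <- (nodes[elements[, 1], 2] + nodes[elements[, 2], 2] +
           nodes[elements[, 3], 2]) / 3
  list(nodes = nodes, elements = elements, region = region_fun(cx, cy))
}

# horizontal boundary edges of a structured mesh at y = y0 with both nodes
# satisfying the x-predicate; returned as a 2-column node-index matrix
top_edges <- function(nodes, y0, x_pred, tol = 1e-9) {
  on_line <- which(abs(nodes[, 2] - y0) < tol & x_pred(nodes[, 1]))
  if (length(on_line) < 2L) return(matrix(integer(0), ncol = 2L))
  on_line <- on_line[order(nodes[on_line, 1])]
  cbind(on_line[-length(on_line)], on_line[-1L])
}

#' Build the surrogate mesh
#'
#' Generates a conforming structured triangulation of the implant/bone
#' cross-section: linear triangles, with the material interfaces (cortical
#' band, implant flanks, notch band) aligned to grid lines so each element
#' lies in exactly one region. A titanium abutment column rises
#' `abutment_height` above the bone crest and carries the load surface on
#' its occlusal (top) face; grid cells above the crest outside the column
#' are discarded and the nodes renumbered. The chamfered notch profile is
#' resolved by centroid classification (a staircase approximation of the
#' 45-degree chamfer at the mesh scale). The mesh is a deterministic
#' function of the parameters; `seed` is accepted for interface stability
#' and reserved for future unstructured meshing.
#'
#' @param params A [geometry_params()] object.
#' @param seed Integer, stored with the mesh.
#' @return An object of class `implant_mesh`: node coordinates (mm), element
#'   connectivity, per-element region (`titanium`, `cortical`, `trabecular`),
#'   and boundary tags (`inferior_border`, `mesial_border`, `distal_border`
#'   node sets; `load_surface` edge matrix).
#' @export
build_mesh <- function(params, seed = 1L) {
  stopifnot(inherits(params, "geometry_params"))
  W <- params$bone_width
  H <- params$bone_height
  xc <- W / 2
  hw <- params$implant_diameter / 2
  nd <- params$notch_depth
  nb <- params$notch_band
  ch <- nd # 45-degree chamfer height equals notch depth
  ab <- params$abutment_height
  top <- H + ab
  x_breaks <- c(0, xc - hw, xc - hw + nd, xc, xc + hw - nd, xc + hw, W)
  y_breaks <- c(0, H - params$implant_length, H - params$cortical_thickness,
                H - nb[2] - ch, H - nb[2], H - nb[1], H - nb[1] + ch, H, top)
  y_breaks <- y_breaks[y_breaks >= 0 & y_breaks <= top]
  xs <- refine_breaks(x_breaks, params$mesh_density)
  ys <- refine_breaks(y_breaks, params$mesh_density)

  # implant half-width profile with chamfered notch
  half_width <- function(y) {
    d <- H - y # depth below crest
    w <- rep(hw, length(y))
    if (nd > 0) {
      core <- d >= nb[1] & d <= nb[2]
      upper <- d < nb[1] & d > nb[1] - ch
      lower <- d > nb[2] & d < nb[2] + ch
      w[core] <- hw - nd
      w[upper] <- hw - nd + (nb[1] - d[upper])
      w[lower] <- hw - nd + (d[lower] - nb[2])
    }
    w
  }
  region_fun <- function(cx, cy) {
    above_crest <- cy > H
    in_implant <- cy >= H - params$implant_length &
      abs(cx - xc) <= half_width(pmin(cy, H))
    ifelse(above_crest,
           ifelse(abs(cx - xc) <= hw, "titanium", "void"),
           ifelse(in_implant, "titanium",
                  ifelse(cy >= H - params$cortical_thickness, "cortical",
                         "trabecular")))
  }
  m <- structured_mesh(xs, ys, region_fun)
  # discard void cells above the crest and renumber the surviving nodes
  keep <- m$region != "void"
  elements <- m$elements[keep, , drop = FALSE]
  region <- m$region[keep]
  used <- sort(unique(as.vector(elements)))
  remap <- integer(nrow(m$nodes))
  remap[used] <- seq_along(used)
  elements[] <- remap[elements]
  nodes <- m$nodes[used, , drop = FALSE]
  tol <- 1e-9
  boundary <- list(
    inferior_border = which(abs(nodes[, 2]) < tol),
    mesial_border = which(abs(nodes[, 1]) < tol),
    distal_border = which(abs(nodes[, 1] - W) < tol),
    load_surface = top_edges(nodes, top,
                             function(x) abs(x - xc) <= hw + tol)
  )
  structure(list(nodes = nodes, elements = elements, region = region,
                 boundary = boundary, params = params, seed = seed),
            class = "implant_mesh")
}

#' @export
print.implant_mesh <- function(x, ...) {
  cat("Implant-in-bone surrogate mesh (plane strain)\n")
  cat("  nodes:", nrow(x$nodes), " elements:", nrow(x$elements), "\n")
  cat("  regions:", paste(sprintf("%s=%d", names(table(x$region)),
                                  table(x$region)), collapse = ", "), "\n")
  invisible(x)
}

# plane-strain constitutive matrix
plane_strain_D <- function(E, nu) {
  f <- E / ((1 + nu) * (1 - 2 * nu))
  f * matrix(c(1 - nu, nu, 0,
               nu, 1 - nu, 0,
               0, 0, (1 - 2 * nu) / 2), 3, 3)
}

# per-element CST geometry: shape-derivative coefficients and signed area
element_geometry <- function(nodes, elements) {
  x1 <- nodes[elements[, 1], 1]; y1 <- nodes[elements[, 1], 2]
  x2 <- nodes[elements[, 2], 1]; y2 <- nodes[elements[, 2], 2]
  x3 <- nodes[elements[, 3], 1]; y3 <- nodes[elements[, 3], 2]
  area <- ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
  list(b = cbind(y2 - y3, y3 - y1, y1 - y2),
       c = cbind(x3 - x2, x1 - x3, x2 - x1),
       area = area)
}

# 3x6 strain-displacement matrix for one element
b_matrix <- function(b, c, area) {
  matrix(c(b[1], 0, c[1],
           0, c[1], b[1],
           b[2], 0, c[2],
           0, c[2], b[2],
           b[3], 0, c[3],
           0, c[3], b[3]), nrow = 3) / (2 * area)
}

# sparse global stiffness for a subset of elements (unit thickness)
assemble_stiffness <- function(mesh, materials, which_elements = NULL) {
  if (is.null(which_elements)) which_elements <- seq_len(nrow(mesh$elements))
  geo <- element_geometry(mesh$nodes, mesh$elements)
  if (any(geo$area[which_elements] <= 0)) {
    stop("assembly error: non-positive element area", call. = FALSE)
  }
  ndof <- 2L * nrow(mesh$nodes)
  ntrip <- 36L * length(which_elements)
  ii <- integer(ntrip); jj <- integer(ntrip); vv <- numeric(ntrip)
  pos <- 0L
  for (e in which_elements) {
    mat <- materials[[mesh$region[e]]]
    D <- plane_strain_D(mat$youngs_modulus, mat$poisson_ratio)
    B <- b_matrix(geo$b[e, ], geo$c[e, ], geo$area[e])
    Ke <- geo$area[e] * crossprod(B, D %*% B)
    nd <- mesh$elements[e, ]
    dofs <- c(2L * nd[1] - 1L, 2L * nd[1], 2L * nd[2] - 1L, 2L * nd[2],
              2L * nd[3] - 1L, 2L * nd[3])
    idx <- pos + seq_len(36L)
    ii[idx] <- rep(dofs, times = 6L)
    jj[idx] <- rep(dofs, each = 6L)
    vv[idx] <- as.vector(Ke)
    pos <- pos + 36L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(ndof, ndof))
}

# consistent nodal forces for a uniform traction with total resultant
# (fx, fy) distributed over the tagged load-surface edges
traction_forces <- function(mesh, fx, fy) {
  edges <- mesh$boundary$load_surface
  if (nrow(edges) == 0L) stop("load surface is not tagged", call. = FALSE)
  len <- sqrt((mesh$nodes[edges[, 2], 1] - mesh$nodes[edges[, 1], 1])^2 +
                (mesh$nodes[edges[, 2], 2] - mesh$nodes[edges[, 1], 2])^2)
  total <- sum(len)
  f <- numeric(2L * nrow(mesh$nodes))
  for (k in seq_len(nrow(edges))) {
    share <- len[k] / total / 2
    for (nd in edges[k, ]) {
      f[2L * nd - 1L] <- f[2L * nd - 1L] + fx * share
      f[2L * nd] <- f[2L * nd] + fy * share
    }
  }
  f
}

# fixed DOFs for the implant-model boundary conditions: inferior border
# fully restrained, mesial/distal borders restrained normal to the surface
model_fixed_dofs <- function(mesh) {
  inf <- mesh$boundary$inferior_border
  sides <- c(mesh$boundary$mesial_border, mesh$boundary$distal_border)
  sort(unique(c(2L * inf - 1L, 2L * inf, 2L * sides - 1L)))
}

solve_constrained <- function(K, f, fixed_dofs) {
  free <- setdiff(seq_along(f), fixed_dofs)
  u <- numeric(length(f))
  sol <- tryCatch(
    Matrix::solve(K[free, free, drop = FALSE], f[free]),
    error = function(e) stop("singular stiffness matrix (insufficient ",
                             "constraints?): ", conditionMessage(e),
                             call. = FALSE)
  )
  u[free] <- as.vector(sol)
  u
}

# element stresses/strains from a displacement vector
element_stresses <- function(mesh, materials, u) {
  geo <- element_geometry(mesh$nodes, mesh$elements)
  m <- nrow(mesh$elements)
  out <- matrix(0, m, 8)
  colnames(out) <- c("sxx", "syy", "sxy", "szz", "von_mises",
                     "max_principal", "eps_vm", "exx")
  for (e in seq_len(m)) {
    mat <- materials[[mesh$region[e]]]
    B <- b_matrix(geo$b[e, ], geo$c[e, ], geo$area[e])
    nd <- mesh$elements[e, ]
    dofs <- c(2L * nd[1] - 1L, 2L * nd[1], 2L * nd[2] - 1L, 2L * nd[2],
              2L * nd[3] - 1L, 2L * nd[3])
    eps <- as.vector(B %*% u[dofs])
    D <- plane_strain_D(mat$youngs_modulus, mat$poisson_ratio)
    s <- as.vector(D %*% eps)
    szz <- mat$poisson_ratio * (s[1] + s[2])
    vm <- von_mises(s[1], s[2], s[3], szz)
    out[e, ] <- c(s[1], s[2], s[3], szz, vm,
                  max_principal(s[1], s[2], s[3], szz),
                  vm / mat$youngs_modulus, eps[1])
  }
  out
}

#' Solve the surrogate elasticity problem
#'
#' Assembles and solves the linear plane-strain problem on an implant mesh:
#' the inferior border is fully fixed, the mesial and distal borders are
#' fixed in the direction normal to the surface, and the load is applied as
#' a uniform traction over the tagged load surface with resultant equal to
#' the load case resultant (axial component downward, transverse component
#' in-plane).
#'
#' @param mesh An [build_mesh()] mesh (or a fixture mesh with the same tags).
#' @param materials Named list mapping each region present in the mesh to an
#'   [elastic_material()].
#' @param load A [load_case()].
#' @return A `stress_field`: data frame with one row per element (stress
#'   tensor components in MPa, `von_mises`, `max_principal`, equivalent
#'   elastic strain `eps_vm = von_mises / E`), with the nodal displacement
#'   vector attached as attribute `displacements`.
#' @export
assemble_and_solve <- function(mesh, materials, load) {
  stopifnot(inherits(mesh, "implant_mesh"), inherits(load, "load_case"))
  regions <- unique(mesh$region)
  missing <- setdiff(regions, names(materials))
  if (length(missing) > 0L) {
    stop("no material supplied for region(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  K <- assemble_stiffness(mesh, materials)
  f <- traction_forces(mesh, fx = load$transverse, fy = -load$axial)
  u <- solve_constrained(K, f, model_fixed_dofs(mesh))
  s <- element_stresses(mesh, materials, u)
  field <- data.frame(element = seq_len(nrow(mesh$elements)),
                      region = mesh$region, s[, 1:7])
  class(field) <- c("stress_field", "data.frame")
  attr(field, "displacements") <- u
  field
}

#' Von Mises equivalent stress (plane strain, with the out-of-plane stress)
#'
#' @param sxx,syy,sxy,szz Stress tensor components, MPa (vectorised).
#' @return Von Mises stress, MPa (>= 0).
#' @export
von_mises <- function(sxx, syy, sxy, szz = 0) {
  sqrt(pmax(0, 0.5 * ((sxx - syy)^2 + (syy - szz)^2 + (szz - sxx)^2) +
              3 * sxy^2))
}

#' Maximum principal stress (plane strain, including the out-of-plane axis)
#'
#' @param sxx,syy,sxy,szz Stress tensor components, MPa (vectorised).
#' @return Largest principal stress, MPa.
#' @export
max_principal <- function(sxx, syy, sxy, szz = 0) {
  centre <- (sxx + syy) / 2
  radius <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  pmax(centre + radius, szz)
}

#' Locate the critical element of a stress field
#'
#' Arg-max of the chosen scalar metric over the elements of one region;
#' ties are broken toward the lowest element index.
#'
#' @param field A `stress_field` from [assemble_and_solve()].
#' @param mesh The mesh the field was computed on.
#' @param region Region name (`"titanium"`, `"cortical"`, `"trabecular"`).
#' @param metric `"von_mises"` or `"max_principal"`.
#' @return List with `element` (index into the mesh) and `value` (MPa).
#' @export
find_critical_point <- function(field, mesh, region = "titanium",
                                metric = c("von_mises", "max_principal")) {
  metric <- match.arg(metric)
  in_region <- which(mesh$region == region)
  if (length(in_region) == 0L) {
    stop(sprintf("region '%s' is empty", region), call. = FALSE)
  }
  vals <- field[[metric]][in_region]
  best <- in_region[which.max(vals)] # which.max takes the first maximum
  list(element = best, value = field[[metric]][best])
}

#' Export a mesh as CSV node and element tables
#'
#' @param mesh An `implant_mesh`.
#' @param node_path,element_path Output CSV paths.
#' @export
export_mesh_csv <- function(mesh, node_path, element_path) {
  utils::write.csv(data.frame(id = seq_len(nrow(mesh$nodes)),
                              x = mesh$nodes[, 1], y = mesh$nodes[, 2]),
                   node_path, row.names = FALSE)
  utils::write.csv(data.frame(id = seq_len(nrow(mesh$elements)),
                              n1 = mesh$elements[, 1],
                              n2 = mesh$elements[, 2],
                              n3 = mesh$elements[, 3],
                              region = mesh$region),
                   element_path, row.names = FALSE)
  invisible(NULL)
}

#' Export a stress field as CSV
#'
#' @param field A `stress_field`.
#' @param path Output CSV path.
#' @export
export_stress_csv <- function(field, path) {
  utils::write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(NULL)
}

#' Export mesh and a scalar field in legacy VTK format (visualisation aid)
#'
#' @param mesh An `implant_mesh`.
#' @param path Output `.vtk` path.
#' @param cell_scalars Optional named list of per-element scalar vectors.
#' @export
export_vtk <- function(mesh, path, cell_scalars = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 2.0",
               "implantfatigue surrogate mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", n)), con)
  writeLines(sprintf("%g %g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$elements[, 1] - 1L,
                     mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(
    mesh$region, levels = c("titanium", "cortical", "trabecular")))), con)
  if (!is.null(cell_scalars)) {
    for (nm in names(cell_scalars)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%g", cell_scalars[[nm]]), con)
    }
  }
  invisible(NULL)
}
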