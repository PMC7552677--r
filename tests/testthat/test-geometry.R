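test_that("leaflet angles interpolate between open and closed", {
  p <- geometry_params(open_angle_deg = 85, closed_angle_deg = 25)
  expect_equal(unname(leaflet_angles(0, p)), c(85, 85))
  expect_equal(leaflet_angles(100, p)[["affected"]], 25)
  expect_equal(leaflet_angles(100, p)[["functional"]], 85)
  expect_equal(leaflet_angles(50, p)[["affected"]], 55)
  expect_error(leaflet_angles(120, p), "0, 100")
})

test_that("segment rasterization is deterministic and area-consistent", {
  expect_equal(sum(rasterize_segments(list(), 10, 8, 1)), 0)
  # axis-aligned rectangle: segment of length 5 with thickness 3 at h = 1
  # covers exactly the cells whose centers fall in the envelope
  seg <- list(list(x0 = 2.5, y0 = 3.5, x1 = 6.5, y1 = 3.5, thickness = 3))
  r <- rasterize_segments(seg, 10, 8, 1)
  expect_equal(sum(r), 5 * 3)
  # inclined leaflet: solid cell count approximates the analytic capsule area
  th <- 30 * pi / 180
  len <- 40; thick <- 6; h <- 0.5
  seg2 <- list(list(x0 = 10, y0 = 10, x1 = 10 + len * cos(th),
                    y1 = 10 + len * sin(th), thickness = thick))
  r2 <- rasterize_segments(seg2, 120, 100, h)
  area <- len * thick  # rotated rectangle
  expect_lt(abs(sum(r2) * h^2 - area) / area, 0.1)
})

test_that("healthy geometry has three valve orifices and mirror symmetry", {
  m <- coarse_mask(27, 0, 5)
  gaps <- orifice_widths(m)
  expect_length(gaps, 3)
  # central orifice flanked by two equal laterals; leaflets occupy width
  expect_equal(gaps[1], gaps[3])
  expect_lt(sum(gaps), 27)
  # cell-wise mirror symmetry about the centerline
  expect_equal(m$solid, m$solid[, rev(seq_len(m$ny))])
  # inlet and outlet openings match the nominal widths to one cell
  expect_lt(abs(sum(!m$solid[1, ]) * m$spacing - 27), m$spacing + 1e-9)
  expect_lt(abs(sum(!m$solid[m$nx, ]) * m$spacing - 27), m$spacing + 1e-9)
})

test_that("full one-leaflet closure removes the affected lateral orifice", {
  m <- coarse_mask(27, 100, 5)
  expect_length(orifice_widths(m), 2)
  m19 <- build_geometry(case_spec(19, 0, 5), coarse_geo())
  expect_lt(abs(sum(!m19$solid[1, ]) * m19$spacing - 19),
            m19$spacing + 1e-9)
  expect_length(orifice_widths(m19), 3)
})

test_that("valve-plane open area is non-increasing in dysfunction", {
  open_area <- vapply(c(0, 50, 100), function(f)
    sum(orifice_widths(coarse_mask(27, f, 5))), numeric(1))
  expect_true(all(diff(open_area) <= 1e-9))
})

test_that("grid refinement changes the solid fraction by < 5%", {
  co <- solid_fraction(coarse_mask(27, 50, 5))
  fi <- solid_fraction(build_geometry(case_spec(27, 50, 5),
                                      geometry_params(grid_spacing_mm = 0.45)))
  expect_lt(abs(fi - co) / co, 0.05)
})

test_that("degenerate geometries are rejected", {
  expect_error(geometry_params(open_angle_deg = 20, closed_angle_deg = 25),
               "closed_angle_deg")
  expect_error(geometry_params(leaflet_length_mm = -1), "positive")
  expect_error(build_geometry(case_spec(19, 0, 5),
                              geometry_params(grid_spacing_mm = 8)),
               "too coarse")
})

test_that("region labels partition the domain", {
  m <- coarse_mask(23, 50, 5)
  expect_true(all(m$region[m$solid] == 0))
  expect_true(all(m$region %in% 0:4))
  for (lab in c("LVOT", "VALVE_PLANE", "SINUS", "AORTA"))
    expect_gt(sum(region_cells(m, lab)), 0)
  # LVOT strictly upstream of the valve plane
  lv <- which(region_cells(m, "LVOT"), arr.ind = TRUE)
  expect_true(all(m$xc[lv[, 1]] < m$valve_x_mm))
})
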