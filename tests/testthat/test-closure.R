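test_that("closure saturates to a competent valve when leaflets are long", {
  q <- fixture_params(AL = 30, PL = 60, CL = 50)
  cl <- emulate_closure(build_valve_curves(q, 100))
  expect_true(all(cl$edges$gap == 0))
  expect_equal(cl$oa_closed_form, 0)
})

test_that("with no leaflet tissue the orifice recovers the annular ellipse", {
  q <- fixture_params(AL = 1e-9, PL = 0, CL = 0, D_shape = 0, SF_shape = 0)
  target <- pi * q$AP * q$IC / 4
  a100 <- emulate_closure(build_valve_curves(q, 100))$oa_closed_form
  a400 <- emulate_closure(build_valve_curves(q, 400))$oa_closed_form
  expect_lt(abs(a400 - target) / target, 0.005)
  expect_lt(abs(a400 - target), abs(a100 - target))
})

test_that("edges are symmetric about the coaptation line and match the gap", {
  cl <- emulate_closure(build_valve_curves(fixture_params(), 80))
  expect_equal(cl$edges$y_anterior - cl$edges$y_posterior, cl$edges$gap)
  expect_equal(cl$edges$y_anterior + cl$edges$y_posterior, rep(0, 80))
  expect_equal(cl$oa_closed_form, sum(cl$edges$gap) * cl$delta_x)
})

test_that("joint length scaling scales gaps by c and area by c^2", {
  q <- fixture_params()
  cc <- coaptation_constants()
  for (c_fac in c(0.5, 2)) {
    qs <- q
    for (nm in c("AP", "IC", "AL", "PL", "CL", "AH", "PH", "SF_shape")) {
      qs[[nm]] <- q[[nm]] * c_fac
    }
    # reference lengths are lengths too: scale them with the geometry
    ccs <- coaptation_constants(
      h_ref = cc$h_ref * c_fac, ap_ref = cc$ap_ref * c_fac
    )
    cl <- emulate_closure(build_valve_curves(q, 100), constants = cc)
    cls <- emulate_closure(build_valve_curves(qs, 100), constants = ccs)
    expect_equal(cls$edges$gap, c_fac * cl$edges$gap, tolerance = 1e-12)
    expect_equal(cls$oa_closed_form, c_fac^2 * cl$oa_closed_form, tolerance = 1e-12)
  }
})

test_that("vectorized orifice area is deterministic and matches emulate_closure", {
  q <- sample_physical(25, seed = 5, quiet = TRUE)
  y1 <- emulate_orifice_area(q, 150)
  expect_identical(y1, emulate_orifice_area(q, 150))
  y2 <- vapply(seq_len(25), function(i) {
    emulate_closure(build_valve_curves(q[i, ], 150))$oa_closed_form
  }, numeric(1))
  expect_equal(y1, y2, tolerance = 1e-12)
})

test_that("orifice area is monotone in IC (up) and PL (down)", {
  base <- fixture_params()
  ics <- seq(25, 55, length.out = 12)
  a_ic <- vapply(ics, function(v) emulate_orifice_area(fixture_params(IC = v), 200), numeric(1))
  expect_true(all(diff(a_ic) >= 0))
  pls <- seq(8, 30, length.out = 12)
  a_pl <- vapply(pls, function(v) emulate_orifice_area(fixture_params(PL = v), 200), numeric(1))
  expect_true(all(diff(a_pl) <= 0))
})

test_that("gap-length algorithm agrees with the closed-form area within 2%", {
  q <- sample_physical(8, seed = 9, quiet = TRUE)
  for (i in seq_len(8)) {
    cl <- emulate_closure(build_valve_curves(q[i, ], 400))
    if (cl$oa_closed_form == 0) next
    ga <- gap_length_area(edge_curve(cl, "anterior"), edge_curve(cl, "posterior"),
      n_planes = 40
    )
    expect_lt(abs(ga$area_mm2 - cl$oa_closed_form) / cl$oa_closed_form, 0.02)
  }
})

test_that("generated datasets are reproducible, finite and non-degenerate", {
  d1 <- generate_dataset(120, seed = 21)
  d2 <- generate_dataset(120, seed = 21)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(d1, f1)
  write_dataset_csv(d2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_true(all(is.finite(d1$orifice_area_mm2)))
  expect_true(all(d1$orifice_area_mm2 >= 0))
  expect_gt(var(d1$orifice_area_mm2), 0)
  # optional noise stays non-negative
  dn <- generate_dataset(50, seed = 21, noise_sd = 5)
  expect_true(all(dn$orifice_area_mm2 >= 0))
})

test_that("closed configurations export as OBJ polylines", {
  cl <- emulate_closure(build_valve_curves(fixture_params(), 10))
  f <- withr::local_tempfile(fileext = ".obj")
  write_closure_obj(cl, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "v ")), 20)
  expect_equal(sum(startsWith(lines, "l ")), 2)
})
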