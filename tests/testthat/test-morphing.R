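# Stamp extrusion, the morphing solve and contour-only identification.

test_that("stamps interpolate the contour samples exactly", {
  rec <- small_record()
  cp <- rec$contours[[3]]
  st <- extrude_stamps(cp)
  a <- cp$contour[cp$contour$surface == "anterior", ]
  b <- cp$contour[cp$contour$surface == "posterior", ]
  expect_equal(st$anterior(a$r), a$z, tolerance = 1e-12)
  expect_equal(st$posterior(b$r), b$z, tolerance = 1e-12)
  # anterior apex height differs from the undeformed apex by DefA
  cp0 <- extract_contours(rec, 0)
  st0 <- extrude_stamps(cp0)
  expect_equal(st0$anterior(0) - st$anterior(0), rec$states[[3]]$DefA,
               tolerance = 1e-9)
  # undeformed stamp reproduces the in-vivo cap between samples too
  a0 <- cp0$contour[cp0$contour$surface == "anterior", ]
  rr <- seq(0, max(a0$r), length.out = 40)
  expect_lt(max(abs(st0$anterior(rr) -
                      stats::spline(a0$r, a0$z, xout = rr)$y)), 5e-3)
})

test_that("malformed contours are rejected", {
  rec <- small_record()
  cp <- rec$contours[[1]]
  shuffled <- cp
  shuffled$contour$r[2:1] <- shuffled$contour$r[1:2]
  expect_error(extrude_stamps(shuffled), "ordered")
  crossing <- cp
  crossing$contour$z[crossing$contour$surface == "posterior"] <-
    crossing$contour$z[crossing$contour$surface == "anterior"] + 0.1
  expect_error(extrude_stamps(crossing), "above")
})

test_that("identity morph leaves the model in place", {
  # default planform density: the stamp spline must reproduce the surface
  # between contour samples to sub-micron accuracy, which a very coarse
  # contour cannot provide
  p0 <- eye_geometry_params(iop_mmHg = 0)
  m0 <- build_eye_mesh(p0, cornea_material = morph_material())
  pre0 <- prestress_eye(m0)
  rec0 <- structure(list(model = pre0$model, U_pre = pre0$U_pre,
                         states = list(), z_apex_invivo = NA_real_),
                    class = "nct_record")
  cp0 <- extract_contours(rec0, 0)
  st0 <- extrude_stamps(cp0)
  mr <- morph_full_field(pre0, st0)
  expect_lte(max(abs(mr$U_morph)), 1e-3)   # <= 1 um
  expect_lte(mr$vertical_residual, 1e-3)
})

test_that("morphing imprints a deformed state and conserves corneal volume", {
  rec <- small_record()
  prem <- fix_get("morph_pre_small", function()
    prestress_eye(build_eye_mesh(small_params(),
                                 cornea_material = morph_material())))
  st3 <- extrude_stamps(rec$contours[[3]])
  mr <- morph_full_field(prem, st3)
  expect_lte(mr$vertical_residual, 1e-3)
  expect_lte(mr$max_J_dev, 0.02)
  # imprinted apex deflection equals the record's DefA (within the
  # imprint tolerance plus the prestress mismatch of the morph model)
  X0 <- prem$model$nodes
  apex <- prem$model$node_sets$apex_anterior
  z_apex_invivo <- (X0 + prem$U_pre)[apex, 3]
  defa_morph <- z_apex_invivo - (X0 + mr$U_morph)[apex, 3]
  expect_lt(abs(defa_morph - rec$states[[3]]$DefA), 0.02)
  # the cavity pressure rises with the imprint
  expect_gt(mr$iop_MPa, prem$model$cavity$p0)
})

test_that("zero-deformation contours abort the enriched identification", {
  rec <- small_record()
  cps <- rec$contours[1:3]
  cps[[1]]$DefA <- 0
  expect_error(enriched_identification(cps, params = small_params()),
               "zero-deformation")
})

test_that("degradation ordering from contours is stable under the morph modulus", {
  # The identified absolute values depend on the surrogate modulus E
  # through the morph model's own prestress (the stress-free geometry of
  # the surrogate scales with its stiffness), but the feasibility claim
  # -- reduced fiber stiffness is detectable and ordered -- must not.
  rec_H <- small_record()
  rec_K2 <- fix_get("small_record_KKII", function()
    generate_reference_record("KK-II", params = small_params()))
  k1_for <- function(rec, prem) {
    ei <- enriched_identification(rec$contours[1:3],
                                  params = small_params(),
                                  pulse = pulse_load(),
                                  k2_grid = 200, morph_pre = prem)
    ei$search$params_mean[["k1"]]
  }
  for (E in c(1, 2)) {
    prem <- prestress_eye(build_eye_mesh(
      small_params(), cornea_material = morph_material(E = E)))
    k1_H <- k1_for(rec_H, prem)
    k1_K2 <- k1_for(rec_K2, prem)
    expect_gt(k1_H, k1_K2)
  }
})
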