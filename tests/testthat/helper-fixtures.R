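# Shared fixtures, built lazily and cached for the whole test session.
# Tiny/small fixtures serve the unit tests; the default-scale fixtures are
# the study conditions used by the acceptance tests.

.fixtures <- new.env(parent = emptyenv())

fix_get <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# geometry small enough for solver unit tests, large enough to be a shell
tiny_params <- function(...) {
  eye_geometry_params(n_planform = 3, n_layers = 1, n_limbus = 1, ...)
}

small_params <- function(...) {
  eye_geometry_params(n_planform = 4, n_layers = 2, n_limbus = 1, ...)
}

tiny_model <- function() {
  fix_get("tiny_model", function() build_eye_mesh(tiny_params()))
}

# small-scale healthy record for module tests (fast; not the study fixture)
small_record <- function() {
  fix_get("small_record", function()
    generate_reference_record("H", params = small_params()))
}

# default-scale records: the study conditions for the acceptance tests
# (generation wall time is kept alongside for the runtime contracts)
default_record <- function(set) {
  fix_get(paste0("rec_", set), function() {
    t0 <- Sys.time()
    rec <- generate_reference_record(set, seed = 1L)
    attr(rec, "generation_seconds") <-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    rec
  })
}

# stress-free result of the default healthy fixture (shared with t7-style
# reload checks)
default_prestress <- function() {
  fix_get("prestress_H", function()
    prestress_eye(build_eye_mesh(eye_geometry_params(),
                                 cornea_material = reference_material("H"))))
}

# prestressed morph model (material-set independent)
morph_prestress <- function() {
  fix_get("morph_pre", function()
    prestress_eye(build_eye_mesh(eye_geometry_params(),
                                 cornea_material = morph_material())))
}

# a random deformation gradient with J in [0.9, 1.2]
random_defgrad <- function() {
  repeat {
    F <- diag(3) + matrix(stats::runif(9, -0.15, 0.15), 3, 3)
    J <- det(F)
    if (J > 0.9 && J < 1.2) return(F)
  }
}

# single unit-cube model built from raw element machinery (internal API)
unit_cube_coords <- function(L = 1) {
  X <- egmeye:::hex_corners()
  (X + 1) / 2 * L
}

expect_rel_equal <- function(actual, expected, tol) {
  scale <- max(abs(expected), .Machine$double.eps)
  expect_lt(max(abs(actual - expected)) / scale, tol)
}
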