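# Equilibrium-gap identification: sensitivity vectors, least squares,
# per-state identification and the nested k2 objective.

# small deformation state shared by the algebraic tests
egm_state <- function() {
  fix_get("egm_state", function() {
    m <- tiny_model()
    set.seed(21)
    u <- stats::rnorm(egmeye:::model_ndof(m), 0, 5e-3)
    u[m$bc$fixed_dofs] <- 0
    list(model = m, U = egmeye:::unflatten_disp(u))
  })
}

test_that("sensitivity vectors vanish at zero displacement and rebuild f_int", {
  st <- egm_state()
  m <- st$model
  S0 <- compute_sensitivity_vectors(m, matrix(0, nrow(m$nodes), 3), 200)
  expect_equal(max(abs(S0$c_K)), 0)
  expect_equal(max(abs(S0$c_mu)), 0)
  expect_equal(max(abs(S0$c_k1)), 0)
  S <- compute_sensitivity_vectors(m, st$U, 200)
  mat <- m$groups$cornea$material
  rebuilt <- mat$K * S$c_K + mat$mu * S$c_mu + mat$k1 * S$c_k1 + S$f_known
  direct <- assemble_internal_forces(m, st$U)
  expect_rel_equal(rebuilt, direct, 1e-13)
  # the mask drops exactly the constrained DOFs
  expect_equal(S$mask, setdiff(seq_len(egmeye:::model_ndof(m)),
                               m$bc$fixed_dofs))
})

test_that("exactly consistent data returns the generating triple", {
  st <- egm_state()
  S <- compute_sensitivity_vectors(st$model, st$U, 200)
  f_ext <- 10 * S$c_K + 0.275 * S$c_mu + 0.04 * S$c_k1 + S$f_known
  fit <- solve_linear_parameters(S, f_ext)
  expect_rel_equal(c(fit$K, fit$mu, fit$k1), c(10, 0.275, 0.04), 1e-10)
  expect_false(any(fit$constrained))
  td <- generics::tidy(fit)
  expect_equal(td$estimate, c(10, 0.275, 0.04), tolerance = 1e-9)
})

test_that("perturbed data gives the pseudo-inverse least-squares solution", {
  st <- egm_state()
  S <- compute_sensitivity_vectors(st$model, st$U, 200)
  set.seed(30)
  f_ext <- 10 * S$c_K + 0.275 * S$c_mu + 0.04 * S$c_k1 + S$f_known +
    stats::rnorm(length(S$c_K), 0, 1e-5)
  fit <- solve_linear_parameters(S, f_ext)
  # independent oracle: SVD pseudo-inverse on the masked system
  A <- cbind(S$c_K[S$mask], S$c_mu[S$mask], S$c_k1[S$mask])
  b <- (f_ext - S$f_known)[S$mask]
  sv <- svd(A)
  x_ref <- sv$v %*% (crossprod(sv$u, b) / sv$d)
  expect_rel_equal(c(fit$K, fit$mu, fit$k1), as.numeric(x_ref), 1e-8)
  # the quadratic objective is convex along any line through the optimum
  obj <- function(p) sum((A %*% p - b)^2)
  p0 <- c(fit$K, fit$mu, fit$k1)
  set.seed(31)
  for (trial in 1:5) {
    d <- stats::rnorm(3)
    expect_gt(obj(p0 + 0.1 * d) + obj(p0 - 0.1 * d) - 2 * obj(p0), 0)
  }
})

test_that("non-negativity constraints activate on infeasible data", {
  st <- egm_state()
  S <- compute_sensitivity_vectors(st$model, st$U, 200)
  fit <- solve_linear_parameters(S, -S$c_K + S$f_known)
  expect_equal(fit$K, 0)
  expect_true(fit$constrained[["K"]])
})

test_that("rank deficiency is reported for an unstretched fiber column", {
  st <- egm_state()
  S <- compute_sensitivity_vectors(st$model, st$U, 200)
  S$c_k1 <- S$c_k1 * 0   # fiber direction carries no information
  fit <- solve_linear_parameters(S, 10 * S$c_K + 0.275 * S$c_mu + S$f_known)
  expect_true(any(grepl("k1", fit$warnings)))
})

test_that("known-material folding is equivalent to pre-subtracted forces", {
  st <- egm_state()
  S <- compute_sensitivity_vectors(st$model, st$U, 200)
  f_ext <- 10 * S$c_K + 0.275 * S$c_mu + 0.04 * S$c_k1 + S$f_known
  fit1 <- solve_linear_parameters(S, f_ext)
  S2 <- S; S2$f_known <- numeric(length(S$f_known))
  fit2 <- solve_linear_parameters(S2, f_ext - S$f_known)
  expect_rel_equal(c(fit1$K, fit1$mu, fit1$k1),
                   c(fit2$K, fit2$mu, fit2$k1), 1e-12)
})

test_that("identify_states is deterministic and per-state independent", {
  st <- egm_state()
  S <- compute_sensitivity_vectors(st$model, st$U, 200)
  f_ext <- 10 * S$c_K + 0.275 * S$c_mu + 0.04 * S$c_k1 + S$f_known
  states <- list(list(U = st$U, f_ext = f_ext),
                 list(U = st$U, f_ext = f_ext))
  tab <- identify_states(st$model, states, 200)
  expect_equal(tab$K[1], tab$K[2])
  expect_equal(tab$k1[1], tab$k1[2])
})

test_that("f_rel follows the population-standard-deviation convention", {
  # two-state toy: triples (1,1,1) and (3,3,3) -> each parameter has mean
  # 2 and population sd 1, so f_rel = 3 * (1/2)
  toy <- tibble::tibble(K = c(1, 3), mu = c(1, 3), k1 = c(1, 3))
  expect_equal(egmeye:::f_rel_from_params(toy)$f_rel, 1.5)
  # identical triples give zero
  same <- tibble::tibble(K = c(2, 2), mu = c(5, 5), k1 = c(1, 1))
  expect_equal(egmeye:::f_rel_from_params(same)$f_rel, 0)
  # scaling all parameters leaves the relative scatter unchanged
  expect_equal(egmeye:::f_rel_from_params(toy * 10)$f_rel, 1.5)
})

test_that("grid search handles degenerate grids and fiber-free data", {
  st <- egm_state()
  S <- compute_sensitivity_vectors(st$model, st$U, 200)
  mk_state <- function(noise_seed) {
    set.seed(noise_seed)
    list(U = st$U, f_ext = 10 * S$c_K + 0.275 * S$c_mu + S$f_known +
           stats::rnorm(length(S$c_K), 0, 1e-8))
  }
  states <- lapply(1:3, mk_state)
  expect_error(grid_search_k2(st$model, states[1:2]), "3 deformation")
  # single-point grid returns that point
  ks1 <- grid_search_k2(st$model, states, k2_grid = 150)
  expect_equal(ks1$k2_hat, 150)
  # generating k1 = 0: flag trips and the curve is flat within noise
  ks <- grid_search_k2(st$model, states, k2_grid = c(50, 150, 300))
  expect_false(ks$identifiable)
  expect_lt(diff(range(ks$curve$f_rel)), 1e-3)
})
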