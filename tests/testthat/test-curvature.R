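test_that("curvature of a sampled circle is 1/r and converges under refinement", {
  for (r in c(10, 26.5, 100)) {
    err <- sapply(c(361L, 3601L, 20001L), function(n) {
      crv <- circle_curve(r, n)
      abs(curvature_at(crv, (n - 1L) %/% 2L) - 1 / r)
    })
    expect_true(all(diff(err) < 0))      # refinement shrinks the error
    expect_lt(err[3], 1e-6)
  }
})

test_that("curvature vanishes on a line and is 2 at a parabola vertex", {
  tt <- seq(-1, 1, length.out = 2001)
  line <- parametric_curve(tt, tt, 2 * tt)
  expect_equal(curvature_at(line, 1001L), 0)
  parab <- parametric_curve(tt, tt, tt^2)
  # closed form: y'' / (1 + y'^2)^(3/2) = 2 at the vertex
  expect_equal(curvature_at(parab, 1001L), 2, tolerance = 1e-8)
})

test_that("curvature is invariant under rigid rotation and translation", {
  set.seed(42)
  for (i in 1:10) {
    phi <- runif(1, 0, 2 * pi)
    shift <- runif(2, -50, 50)
    r <- runif(1, 5, 60)
    base <- circle_curve(r, 2001L)
    moved <- circle_curve(r, 2001L, phi = phi, cx = shift[1], cy = shift[2])
    expect_equal(curvature_at(moved, 1000L), curvature_at(base, 1000L),
                 tolerance = 1e-9)
  }
})

test_that("curvature errors at endpoints and degenerate tangents", {
  crv <- circle_curve(10, 100L)
  expect_error(curvature_at(crv, 1L), "endpoints")
  expect_error(curvature_at(crv, 99L), "endpoints")
  cusp <- parametric_curve(seq(-1, 1, length.out = 101),
                           rep(0, 101), rep(0, 101))
  expect_error(curvature_at(cusp, 51L), "degenerate")
})

test_that("osculating circle recovers the generating circle and the paper-scale radius", {
  crv <- circle_curve(10, 20001L, cx = 3, cy = -4)
  oc <- osculating_circle(crv, 10000L)
  expect_equal(oc$radius, 10, tolerance = 1e-6)
  expect_lt(sqrt(sum((oc$center - c(3, -4))^2)), 1e-4)

  tt <- seq(-1, 1, length.out = 2001)
  parab <- parametric_curve(tt, tt, tt^2)
  oc2 <- osculating_circle(parab, 1001L)
  expect_equal(oc2$radius, 0.5, tolerance = 1e-7)
  expect_equal(oc2$center, c(0, 0.5), tolerance = 1e-6)

  # a neck-nodule-scale curvature corresponds to a ~26 mm radius
  expect_equal(1 / 0.0385, 25.97, tolerance = 1e-3)
  line <- parametric_curve(tt, tt, 2 * tt)
  expect_error(osculating_circle(line, 1001L), "flat")
})

test_that("pinned-pinned buckling: closed form matches the FD eigen-solve", {
  m <- buckling_model(EI = 1, GA = 1, kappa_shear = 1, k_p = 0.1, k_w = 1,
                      L = pi)
  sol <- buckling_solution(m, 1)
  expect_true(sol$buckles)
  expect_equal(sol$critical_load, 2.1, tolerance = 1e-12)
  for (n in 1:3) {
    closed <- buckling_solution(m, n)$critical_load
    fd <- buckling_critical_load_fd(m, n)
    expect_lt(abs(fd - closed) / closed, 1e-6)
  }
})

test_that("doubling the beam length shifts the critical load by the (n*pi/L)^2 factor", {
  m1 <- buckling_model(EI = 2, GA = 1.5, kappa_shear = 5 / 6, k_p = 0.2,
                       k_w = 0.8, L = 1)
  m2 <- buckling_model(EI = 2, GA = 1.5, kappa_shear = 5 / 6, k_p = 0.2,
                       k_w = 0.8, L = 2)
  b <- 0.8 * (5 / 6) * 1.5
  a <- 0.2 * 2
  p1 <- buckling_solution(m1, 1)$critical_load
  p2 <- buckling_solution(m2, 1)$critical_load
  # the foundation term b/mu^2 quadruples when L doubles
  expect_equal(p2 - a - b, 4 * (p1 - a - b), tolerance = 1e-12)
})

test_that("the buckling profile satisfies the equation on the grid", {
  m <- buckling_model(EI = 1, GA = 1, kappa_shear = 1, k_p = 0.1, k_w = 1,
                      L = pi)
  sol <- buckling_solution(m, 1, n_grid = 2001L)
  expect_lt(buckling_residual(m, sol$critical_load, sol$x, sol$deflection),
            1e-8)
  # the trivial solution v = 0 has zero residual for any load
  expect_equal(buckling_residual(m, 5, sol$x, rep(0, 2001L)), 0)
})

test_that("zero foundation stiffness yields an explicit no-buckling result", {
  m <- buckling_model(EI = 1, GA = 1, kappa_shear = 1, k_p = 0.3, k_w = 0,
                      L = 1)
  sol <- buckling_solution(m, 1)
  expect_false(sol$buckles)
  expect_true(is.na(sol$critical_load))
})
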