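# Solver building blocks: stencils, free surface, sources, stability and
# linearity.  The heavier physics checks (wave speeds, travel times,
# radiation pattern) live in the acceptance suite.

test_that("the default stencil satisfies its exactness invariants", {
  a <- default_stencil()
  n <- -1:3
  expect_lt(abs(sum(a)), 1e-12)
  expect_equal(sum(n * a), 1)
  for (p in 2:4) expect_lt(abs(sum(n^p * a)), 1e-12)  # degree-4 exactness
  expect_silent(validate_stencil(a))
  expect_error(validate_stencil(c(-1, 0, 1, 0, 0)), "linear")
  expect_error(validate_stencil(rep(0.2, 5)), "constants")
})

test_that("biased derivatives annihilate constants and resolve ramps", {
  f <- array(3.7, c(12, 8, 8))
  for (ax in 1:3) for (dir in c("forward", "backward"))
    expect_equal(spatial_derivative(f, ax, dir, h = 50),
                 array(0, dim(f)))
  x <- (1:12) * 2.5
  ramp <- array(rep(x, 64), c(12, 8, 8))
  d <- spatial_derivative(ramp, 1, "forward", h = 1)
  expect_equal(d[3:8, 4, 4], rep(2.5, 6))
  d <- spatial_derivative(ramp, 1, "backward", h = 1)
  expect_equal(d[4:10, 4, 4], rep(2.5, 7))
  # cubic exactness at interior nodes
  cub <- array(rep(x^3, 64), c(12, 8, 8))
  d <- spatial_derivative(cub, 1, "forward", h = 2.5)
  expect_equal(d[3:8, 4, 4], 3 * x[3:8]^2, tolerance = 1e-12)
  expect_error(spatial_derivative(ramp, 4, "forward"), "axis")
})

test_that("build validates the CFL condition and source placement", {
  mat <- material_model(vp = 6000, vs = 3464, rho = 2700)
  g <- sim_grid(30, 30, 20, dx = 200, nt = 10, dt = 0.05)
  expect_error(build_simulation(mat, g), "maximum stable dt")
  g2 <- sim_grid(30, 30, 20, dx = 200, duration = 1, cfl = 0.4)
  h <- build_simulation(mat, g2)
  expect_equal(h$dt, 0.4 * 200 / 6000)
  expect_equal(h$nt, ceiling(1 / h$dt))
  src <- point_source(x = 1e6, y = 100, depth = 100, mt = rep(1, 6))
  expect_error(build_simulation(mat, g2, src), "outside the grid")
})

test_that("zero state with no source is a fixed point of the update", {
  h <- tiny_sim(nx = 12, ny = 12, nz = 10, duration = 0.1)
  st <- rk4_step(h, zero_state(h))
  for (f in names(st)) expect_equal(max(abs(st[[f]])), 0)
})

test_that("free surface zeroes tractions and mirrors them antisymmetrically", {
  set.seed(5)
  h <- tiny_sim(nx = 10, ny = 10, nz = 8)
  st <- zero_state(h)
  for (f in names(st)) st[[f]][] <- rnorm(length(st[[f]]))
  out <- apply_free_surface(st, n_ghost = 3)
  for (f in c("szz", "sxz", "syz")) {
    expect_equal(max(abs(out$state[[f]][, , 8])), 0)
    for (q in 1:3)
      expect_equal(out$ghost[[f]][, , q], -out$state[[f]][, , 8 - q])
  }
  # after a solver step with a source, surface tractions stay exactly zero
  src <- point_source(x = 900, y = 900, depth = 600, mt = rep(1e13, 6), fc = 4)
  h2 <- tiny_sim(nx = 10, ny = 10, nz = 8, duration = 0.2, source = src)
  rec <- run_simulation(h2, surface_every = 0)
  for (f in c("szz", "sxz", "syz"))
    expect_equal(max(abs(rec$final[[f]][, , 8])), 0)
  expect_gt(max(abs(rec$final$vx)), 0)  # the run did something
})

test_that("the solver is linear in the source", {
  mk <- function(amp, x = 3000, y = 3000)
    point_source(x = x, y = y, depth = 2000, mt = c(0, 0, 0, amp, 0, 0),
                 fc = 3)
  run1 <- function(src) {
    h <- tiny_sim(nx = 30, ny = 30, nz = 20, dx = 200, duration = 0.45,
                  source = src)
    run_simulation(h, receivers = rbind(c(22, 16, 20)), surface_every = 0)
  }
  rA <- run1(mk(1e13))
  rA2 <- run1(mk(2e13))
  expect_equal(rA2$receivers$v, 2 * rA$receivers$v, tolerance = 1e-12)
  # superposition of two distinct sources
  rB <- run1(mk(1e13, x = 2200, y = 3600))
  both <- point_source(x = 3000, y = 3000, depth = 2000,
                       mt = c(0, 0, 0, 1e13, 0, 0), fc = 3)
  both[[2]] <- mk(1e13, x = 2200, y = 3600)[[1]]
  rAB <- run1(both)
  # superposition, relative to the signal scale
  expect_lt(max(abs(rAB$receivers$v - (rA$receivers$v + rB$receivers$v))),
            1e-10 * max(abs(rAB$receivers$v)))
})

test_that("a one-subfault finite fault equals the corresponding point source", {
  mat <- material_model(vp = 6000, vs = 3464, rho = 2700)
  g <- sim_grid(30, 30, 20, dx = 200, duration = 0.45, cfl = 0.4)
  sf <- data.frame(x = 3000, y = 3000, depth = 2000, strike = 30, dip = 70,
                   rake = -160, slip = 0.5, area = 4e6, onset = 0.02,
                   rise = 0.4)
  mu <- 2700 * 3464^2
  ps <- point_source(x = 3000, y = 3000, depth = 2000,
                     mt = mt_from_sdr(30, 70, -160, mu * sf$area * sf$slip),
                     fc = 1 / sf$rise, t0 = sf$onset + 1.2 * sf$rise)
  hf <- build_simulation(mat, g, finite_fault_source(sf))
  hp <- build_simulation(mat, g, ps)
  rcv <- rbind(c(20, 18, 20))
  rf <- run_simulation(hf, receivers = rcv, surface_every = 0)
  rp <- run_simulation(hp, receivers = rcv, surface_every = 0)
  expect_equal(rf$receivers$v, rp$receivers$v, tolerance = 1e-12)
})

test_that("double-couple tensors from strike/dip/rake are trace-free and scale", {
  for (sdr in list(c(0, 90, 0), c(138, 73, -163), c(45, 30, 110))) {
    mt <- mt_from_sdr(sdr[1], sdr[2], sdr[3], 1e15)
    expect_lt(abs(mt["Mxx"] + mt["Myy"] + mt["Mzz"]), 1e-6 * 1e15)
    expect_equal(unname(mt_from_sdr(sdr[1], sdr[2], sdr[3], 2e15)),
                 unname(2 * mt))
  }
  # vertical strike-slip along north: pure Mxy couple
  mt <- mt_from_sdr(0, 90, 0, 1)
  expect_equal(unname(mt[c("Mxx", "Myy", "Mzz", "Mxz", "Myz")]),
               rep(0, 5), tolerance = 1e-12)
  expect_equal(abs(unname(mt["Mxy"])), 1)
})

test_that("elastic energy does not grow after the source switches off", {
  mat <- material_model(vp = 4000, vs = 2300, rho = 2500)
  g <- sim_grid(50, 50, 50, dx = 100, duration = 0.5, cfl = 0.4)
  src <- point_source(x = 2500, y = 2500, depth = 2500,
                      mt = rep(1e13, 6), fc = 8, t0 = 0.15)
  h <- build_simulation(mat, g, src, free_surface = FALSE,
                        sponge = list(width = 0, alpha = 0))
  s1 <- round(0.32 / h$dt); s2 <- round(0.48 / h$dt)
  rec <- run_simulation(h, surface_every = 0, snapshot_steps = c(s1, s2))
  E1 <- state_energy(rec$snapshots[[1]], mat, 100^3)
  E2 <- state_energy(rec$snapshots[[2]], mat, 100^3)
  expect_gt(E1, 0)
  expect_lte(E2, E1 * 1.01)
})

test_that("surface motion from a shallow source decays with depth", {
  mat <- material_model(vp = 4000, vs = 2300, rho = 2500)
  g <- sim_grid(80, 40, 50, dx = 100, duration = 2.2, cfl = 0.4)
  src <- point_source(x = 2000, y = 2000, depth = 200,
                      mt = c(1, 1, 1, 0, 0, 0) * 1e13, fc = 4)
  h <- build_simulation(mat, g, src, free_surface = TRUE)
  rcvs <- cbind(60, 20, c(50, 40, 30))
  rec <- run_simulation(h, receivers = rcvs, surface_every = 0)
  rms <- apply(rec$receivers$v, 3, function(m) sqrt(mean(m^2)))
  expect_gt(rms[1], rms[2])
  expect_gt(rms[2], rms[3])
})

test_that("point-force reciprocity holds on a homogeneous model", {
  mat <- material_model(vp = 6000, vs = 6000 / sqrt(3), rho = 2700)
  g <- sim_grid(50, 50, 50, dx = 200, duration = 1.4, cfl = 0.4)
  A <- c(18, 25, 25); B <- c(34, 27, 23)
  mk <- function(p) point_source(x = (p[1] - 1) * 200, y = (p[2] - 1) * 200,
                                 depth = (50 - p[3]) * 200,
                                 force = c(0, 0, 1e10), fc = 2)
  hA <- build_simulation(mat, g, mk(A), free_surface = FALSE,
                         sponge = list(width = 10, alpha = 0.02))
  hB <- build_simulation(mat, g, mk(B), free_surface = FALSE,
                         sponge = list(width = 10, alpha = 0.02))
  a <- run_simulation(hA, receivers = rbind(B), surface_every = 0)$receivers$v[, 3, 1]
  b <- run_simulation(hB, receivers = rbind(A), surface_every = 0)$receivers$v[, 3, 1]
  expect_lt(sqrt(mean((a - b)^2)) / sqrt(mean(a^2)), 0.02)
})

test_that("waveform misfit against the analytic plane wave shrinks with dx", {
  mat <- material_model(vp = 6000, vs = 6000 / sqrt(3), rho = 2700)
  misfit <- sapply(c(400, 200, 100), function(dx) {
    nx <- round(24000 / dx)
    g <- sim_grid(nx, 6, 6, dx, duration = 1.8, cfl = 0.2)
    st <- plane_wave_state(g, mat, wavelength = 3200, type = "P", x0 = 6000,
                           width = 2400)
    h <- build_simulation(mat, g, NULL, free_surface = FALSE,
                          sponge = list(width = 0, alpha = 0))
    i_r <- round(12000 / dx) + 1
    rec <- run_simulation(h, receivers = rbind(c(i_r, 3, 3)),
                          surface_every = 0, init_state = st)
    tt <- rec$receivers$t
    # analytic: the packet translates at vp
    xr <- 12000 - 6000 - 6000 * tt
    ref <- 1e-3 * sin(-2 * pi * xr / 3200) * exp(-(xr / 2400)^2)
    v <- rec$receivers$v[, 1, 1]
    sqrt(mean((v - (-ref))^2)) / sqrt(mean(ref^2))
  })
  expect_true(all(diff(misfit) < 0))
})

test_that("PGV extraction reduces records correctly", {
  h <- tiny_sim(nx = 12, ny = 12, nz = 10, duration = 0.15)
  rec <- run_simulation(h, surface_every = 1)
  expect_equal(max(rec$pgv_h), 0)          # no source: all quiet
  # synthetic record: sinusoid on vx only
  rec$vx <- array(0, c(3, 3, 5)); rec$vy <- rec$vz <- rec$vx
  for (k in 1:5) rec$vx[, , k] <- 0.25 * sin(k)
  expect_equal(extract_pgv(rec, "vx"), matrix(0.25 * max(abs(sin(1:5))), 3, 3),
               ignore_attr = TRUE)
  # georeferencing attaches a grid centered on the configured point
  h2 <- tiny_sim(nx = 12, ny = 12, nz = 10, duration = 0.1,
                 geo = list(lon = 100, lat = 25))
  rec2 <- run_simulation(h2, surface_every = 0)
  g <- extract_pgv(rec2, "horizontal")
  expect_s3_class(g, "geo_grid")
  expect_equal(g$spec$nrows, 12)
  lon_span <- (g$spec$ncols - 1) * g$spec$cell_size
  expect_equal(lon_span * 111320 * cos(25 * pi / 180), 11 * 200,
               tolerance = 1e-6)
})

test_that("subfault tables round-trip through the plain-text format", {
  sf <- data.frame(x = c(1000, 2000), y = c(1500, 1500),
                   depth = c(3000, 3500), strike = c(138, 138),
                   dip = c(73, 73), rake = c(-163, -163),
                   slip = c(0.4, 0.8), area = c(4e6, 4e6),
                   onset = c(0, 0.3), rise = c(0.5, 0.5))
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# synthetic two-subfault rupture",
               paste(names(sf), collapse = " "),
               apply(sf, 1, paste, collapse = " ")), path)
  back <- read_subfault_table(path)
  expect_equal(back$slip, sf$slip)
  src <- finite_fault_source(back)
  expect_length(src, 2)
  expect_equal(src[[2]]$t0, 0.3 + 1.2 * 0.5)
})
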