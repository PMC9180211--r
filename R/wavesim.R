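# Desk-scale 3-D velocity-stress elastic finite-difference simulator:
# R-side configuration, source handling and wrappers around the C++ core.

#' Default biased stencil coefficients
#'
#' Coefficients `a_n`, `n = -1..3`, of the one-sided forward difference
#' operator `L^F(U)_i = (1/dx) sum a_n U_{i+n}`; the backward operator is
#' the mirrored-negated counterpart.  The default set is the exact
#' degree-4 finite-difference weight vector on the biased node set
#' \{-1, 0, 1, 2, 3\}: `(-1/4, -5/6, 3/2, -1/2, 1/12)`.  It satisfies
#' `sum a_n = 0` (annihilates constants), `sum n a_n = 1` (exact on linear
#' fields) and is exact for polynomials up to degree 4.  Alternative
#' coefficient sets (e.g. dispersion-optimised ones from the literature)
#' can be passed anywhere a stencil is accepted, subject to
#' [validate_stencil()].
#'
#' @return numeric vector of length 5, names `a-1`..`a3`.
#' @export
default_stencil <- function() {
  setNames(c(-1 / 4, -5 / 6, 3 / 2, -1 / 2, 1 / 12),
           paste0("a", -1:3))
}

#' Validate stencil coefficients
#'
#' Checks the two exactness invariants every admissible coefficient set must
#' satisfy: `sum a_n = 0` and `sum n a_n = 1`.
#'
#' @param a numeric vector of length 5 (offsets -1..3).
#' @param tol tolerance on the invariants.
#' @return `a`, invisibly; error otherwise.
#' @export
validate_stencil <- function(a, tol = 1e-10) {
  if (length(a) != 5 || any(!is.finite(a)))
    stop("stencil must be 5 finite coefficients for offsets -1..3",
         call. = FALSE)
  n <- -1:3
  if (abs(sum(a)) > tol) stop("stencil does not annihilate constants",
                              call. = FALSE)
  if (abs(sum(n * a) - 1) > tol)
    stop("stencil is not exact on linear fields", call. = FALSE)
  invisible(a)
}

#' One-sided biased spatial derivative
#'
#' Applies the forward operator `L^F` or backward operator `L^B` (its
#' mirrored-negated form) along one axis of a 3-D array.  Near boundaries
#' where the biased stencil would leave the array, a low-order fallback
#' (central / one-sided two-point) is used; the stated polynomial exactness
#' holds at interior nodes.
#'
#' @param field 3-D numeric array.
#' @param axis 1, 2 or 3.
#' @param direction `"forward"` or `"backward"`.
#' @param coeffs stencil coefficients (see [default_stencil()]).
#' @param h grid spacing.
#' @return array of the same shape.
#' @export
spatial_derivative <- function(field, axis, direction = c("forward", "backward"),
                               coeffs = default_stencil(), h = 1) {
  direction <- match.arg(direction)
  d <- dim(field)
  if (is.null(d) || length(d) != 3) stop("field must be a 3-D array",
                                         call. = FALSE)
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3", call. = FALSE)
  validate_stencil(coeffs)
  out <- cpp_deriv(as.numeric(field), as.integer(d), as.integer(axis),
                   direction == "forward", as.numeric(coeffs), h)
  array(out, d)
}

#' Elastic material model
#'
#' Either a homogeneous half-space (scalar `vp`, `vs`, `rho`) or a stack of
#' flat layers given as a data frame with columns `depth_top` (m below the
#' free surface, first row 0), `vp`, `vs`, `rho`.  Lame constants are
#' derived as `mu = rho vs^2`, `lambda = rho (vp^2 - 2 vs^2)`.
#'
#' @param vp,vs,rho P velocity (m/s), S velocity (m/s), density (kg/m^3).
#' @param layers optional layered model data frame (overrides the scalars).
#' @return object of class `material_model`.
#' @export
material_model <- function(vp = 6000, vs = vp / sqrt(3), rho = 2700,
                           layers = NULL) {
  if (!is.null(layers)) {
    stopifnot(all(c("depth_top", "vp", "vs", "rho") %in% names(layers)),
              layers$depth_top[1] == 0,
              !is.unsorted(layers$depth_top, strictly = TRUE))
    vp <- layers$vp; vs <- layers$vs; rho <- layers$rho
  }
  stopifnot(all(rho > 0), all(vs >= 0), all(vp > 0), all(vp^2 > 2 * vs^2 * 0))
  if (any(vp^2 - 2 * vs^2 <= 0))
    stop("lambda must be positive: need vp^2 > 2 vs^2", call. = FALSE)
  structure(list(vp = vp, vs = vs, rho = rho, layers = layers),
            class = "material_model")
}

#' Simulation grid
#'
#' Uniform computational grid, optionally terrain-following in the
#' vertical: with an elevation grid each column is stretched so the top
#' node follows the surface (a restricted vertical case of curvilinear
#' gridding; horizontal metric terms are neglected, valid for gentle
#' topography).
#'
#' @param nx,ny,nz cells per axis (`k = nz` is the top / free surface).
#' @param dx spacing in meters (cubic cells on flat terrain).
#' @param nt number of time steps (alternative to `duration`).
#' @param duration simulated time in seconds.
#' @param dt time step; default `cfl * h_min / vp_max`, validated in
#'   [build_simulation()].
#' @param cfl Courant number used when `dt` is derived (default 0.4).
#' @return object of class `sim_grid`.
#' @export
sim_grid <- function(nx, ny, nz, dx, nt = NULL, duration = NULL, dt = NULL,
                     cfl = 0.4) {
  stopifnot(nx >= 5, ny >= 5, nz >= 5, dx > 0)
  if (is.null(nt) && is.null(duration))
    stop("give either nt or duration", call. = FALSE)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz), dx = dx, nt = nt,
                 duration = duration, dt = dt, cfl = cfl),
            class = "sim_grid")
}

#' Ricker wavelet
#'
#' `(1 - 2 pi^2 fc^2 tau^2) exp(-pi^2 fc^2 tau^2)`, `tau = t - t0`; unit
#' peak amplitude.  The default source-time function (applied to the moment
#' rate).
#'
#' @param t time(s), s.
#' @param fc corner frequency, Hz.
#' @param t0 center time (default `1.2 / fc` for causal onset).
#' @return numeric vector.
#' @export
ricker <- function(t, fc, t0 = 1.2 / fc) {
  u <- (pi * fc * (t - t0))^2
  (1 - 2 * u) * exp(-u)
}

# unit-integral Gaussian pulse (alternative moment-rate shape)
gauss_pulse <- function(t, fc, t0 = 1.2 / fc) {
  s <- 1 / (2 * pi * fc / 4)   # width tied to corner frequency
  exp(-((t - t0) / s)^2 / 2) / (s * sqrt(2 * pi))
}

#' Moment tensor from strike, dip and rake
#'
#' Standard double-couple moment tensor of a shear dislocation, returned in
#' the solver's east-north-up frame as
#' `(Mxx, Myy, Mzz, Mxy, Mxz, Myz)`.
#'
#' @param strike,dip,rake fault angles in degrees.
#' @param m0 scalar seismic moment, N m.
#' @return numeric vector of length 6.
#' @export
mt_from_sdr <- function(strike, dip, rake, m0 = 1) {
  f <- strike * pi / 180; d <- dip * pi / 180; l <- rake * pi / 180
  # north-east-down components of the double couple
  Mnn <- -m0 * (sin(d) * cos(l) * sin(2 * f) + sin(2 * d) * sin(l) * sin(f)^2)
  Mne <- m0 * (sin(d) * cos(l) * cos(2 * f) + 0.5 * sin(2 * d) * sin(l) * sin(2 * f))
  Mnd <- -m0 * (cos(d) * cos(l) * cos(f) + cos(2 * d) * sin(l) * sin(f))
  Mee <- m0 * (sin(d) * cos(l) * sin(2 * f) - sin(2 * d) * sin(l) * cos(f)^2)
  Med <- -m0 * (cos(d) * cos(l) * sin(f) - cos(2 * d) * sin(l) * cos(f))
  Mdd <- m0 * sin(2 * d) * sin(l)
  # map (n, e, d) -> (x = e, y = n, z = u)
  c(Mxx = Mee, Myy = Mnn, Mzz = Mdd, Mxy = Mne, Mxz = -Med, Myz = -Mnd)
}

#' Point moment-tensor or force source
#'
#' Position is in grid meters (`x`, `y` from the south-west corner, `depth`
#' below the free surface).  The mechanism is a moment tensor — given
#' directly as `(Mxx, Myy, Mzz, Mxy, Mxz, Myz)` in N m or via
#' strike/dip/rake and `m0` — or a body force vector in N.  The source-time
#' function scales the moment rate (or force); `"ricker"` has unit peak so
#' the peak moment rate equals the tensor magnitude.
#'
#' @param x,y,depth position, m.
#' @param mt moment tensor, length 6, N m.
#' @param strike,dip,rake,m0 alternative mechanism specification.
#' @param force body force vector `(fx, fy, fz)`, N (mutually exclusive
#'   with a moment tensor).
#' @param stf `"ricker"` or `"gauss"` (unit integral).
#' @param fc corner frequency, Hz.
#' @param t0 source center time, s (default `1.2 / fc`).
#' @return object of class `quake_source` (a one-element source list).
#' @export
point_source <- function(x, y, depth, mt = NULL, strike = NULL, dip = NULL,
                         rake = NULL, m0 = 1e15, force = NULL,
                         stf = c("ricker", "gauss"), fc = 1, t0 = 1.2 / fc) {
  stf <- match.arg(stf)
  if (!is.null(force)) {
    stopifnot(length(force) == 3)
    mech <- c(as.numeric(force), 0, 0, 0)
    type <- 1L
  } else {
    if (is.null(mt)) {
      if (is.null(strike)) stop("give mt, strike/dip/rake, or force",
                                call. = FALSE)
      mt <- mt_from_sdr(strike, dip, rake, m0)
    }
    stopifnot(length(mt) == 6)
    mech <- as.numeric(mt)
    type <- 0L
  }
  src <- list(x = x, y = y, depth = depth, mech = mech, type = type,
              stf = stf, fc = fc, t0 = t0)
  structure(list(src), class = "quake_source")
}

#' Finite-fault source from a subfault table
#'
#' Each subfault becomes a point moment-tensor source: moment
#' `m0 = mu * area * slip` with `mu` taken from the material model at the
#' subfault location, mechanism from strike/dip/rake, corner frequency
#' `1 / rise`, and center time `onset + 1.2 * rise`.  A single-subfault
#' fault is exactly equivalent to the corresponding point source.
#'
#' @param subfaults data frame with columns `x`, `y`, `depth` (m),
#'   `strike`, `dip`, `rake` (deg), `slip` (m), `area` (m^2), `onset` (s),
#'   `rise` (s).
#' @param stf source-time-function shape shared by all subfaults.
#' @return object of class `quake_source`.
#' @export
finite_fault_source <- function(subfaults, stf = c("ricker", "gauss")) {
  stf <- match.arg(stf)
  need <- c("x", "y", "depth", "strike", "dip", "rake", "slip", "area",
            "onset", "rise")
  miss <- setdiff(need, names(subfaults))
  if (length(miss)) stop("subfault table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  srcs <- lapply(seq_len(nrow(subfaults)), function(i) {
    sf <- subfaults[i, ]
    list(x = sf$x, y = sf$y, depth = sf$depth,
         mech = as.numeric(mt_from_sdr(sf$strike, sf$dip, sf$rake, 1)),
         type = 0L, stf = stf, fc = 1 / sf$rise, t0 = sf$onset + 1.2 * sf$rise,
         slip = sf$slip, area = sf$area, needs_mu = TRUE)
  })
  structure(srcs, class = "quake_source")
}

#' Read a plain-text subfault table
#'
#' Whitespace-separated columns `x y depth strike dip rake slip area onset
#' rise` (units as in [finite_fault_source()]); lines starting with `#` are
#' comments.
#'
#' @param path file path.
#' @return subfault data frame.
#' @export
read_subfault_table <- function(path) {
  df <- read.table(path, header = TRUE, comment.char = "#")
  need <- c("x", "y", "depth", "strike", "dip", "rake", "slip", "area",
            "onset", "rise")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("subfault table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df
}

# expand material to per-node arrays given per-column spacing dzcol (nx x ny)
.expand_material <- function(material, nx, ny, nz, dzcol) {
  n <- nx * ny * nz
  if (is.null(material$layers)) {
    rho <- rep(material$rho, n)
    mu <- rep(material$rho * material$vs^2, n)
    lam <- rep(material$rho * (material$vp^2 - 2 * material$vs^2), n)
  } else {
    ly <- material$layers
    rho <- mu <- lam <- numeric(n)
    # depth below surface of node (i,j,k): (nz - k) * dz(i,j)
    kdep <- rep(nz:1 - 1, each = nx * ny)           # nz - k for k = 1..nz
    dz_all <- rep(as.numeric(dzcol), times = nz)
    depth <- kdep * dz_all
    li <- findInterval(depth, ly$depth_top)
    li[li < 1] <- 1
    rho <- ly$rho[li]
    mu <- ly$rho[li] * ly$vs[li]^2
    lam <- ly$rho[li] * (ly$vp[li]^2 - 2 * ly$vs[li]^2)
  }
  list(rho = rho, lam = lam, mu = mu)
}

#' Assemble a simulation
#'
#' Expands the material over the grid (terrain-following in the vertical
#' when an elevation grid is supplied), validates the CFL condition,
#' discretizes sources to their nearest nodes, and samples source-time
#' functions at half-step resolution for the Runge-Kutta stages.
#'
#' @param material a [material_model()].
#' @param grid a [sim_grid()].
#' @param source a [point_source()] / [finite_fault_source()], or `NULL`
#'   for a source-free run (e.g. marching an initial state).
#' @param elevation optional `nx x ny` matrix of surface elevation (m above
#'   the model bottom `z_bottom`); columns are vertically stretched so the
#'   top node tracks the surface.
#' @param z_bottom model bottom elevation used with `elevation` (default
#'   `-(nz-1) * dx` below zero elevation).
#' @param free_surface apply the traction-image free surface at the top.
#' @param sponge list with `width` (cells) and `alpha` (damping factor) of
#'   the exponential absorbing layer; `width` may be a single number or a
#'   vector `(x, y, bottom, top)`.  The top width is forced to 0 when
#'   `free_surface` is `TRUE`.
#' @param geo optional list `(lon, lat)` of the grid-center geographic
#'   position, used to georeference surface outputs via a local flat-earth
#'   approximation.
#' @return a `quake_sim` handle for [run_simulation()].
#' @export
build_simulation <- function(material, grid, source = NULL, elevation = NULL,
                             z_bottom = NULL, free_surface = TRUE,
                             sponge = list(width = 15, alpha = 0.02),
                             geo = NULL) {
  stopifnot(inherits(material, "material_model"), inherits(grid, "sim_grid"))
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz; dx <- grid$dx

  if (!is.null(elevation)) {
    if (!all(dim(elevation) == c(nx, ny)))
      stop("elevation must be an nx x ny matrix", call. = FALSE)
    zb <- z_bottom %||% (-(nz - 1) * dx)
    thick <- elevation - zb
    if (any(thick <= 0)) stop("elevation must lie above z_bottom", call. = FALSE)
    dzcol <- thick / (nz - 1)
  } else {
    dzcol <- matrix(dx, nx, ny)
  }

  vpmax <- max(material$vp)
  hmin <- min(dx, min(dzcol))
  dt_max <- grid$cfl * hmin / vpmax
  dt <- grid$dt %||% dt_max
  if (dt > dt_max * (1 + 1e-12))
    stop(sprintf("dt = %.6g violates the CFL condition; maximum stable dt is %.6g s",
                 dt, dt_max), call. = FALSE)
  nt <- grid$nt %||% ceiling(grid$duration / dt)

  mat <- .expand_material(material, nx, ny, nz, dzcol)

  # discretize sources
  srcs <- if (is.null(source)) list() else unclass(source)
  nsrc <- length(srcs)
  src_idx <- integer(nsrc); src_type <- integer(nsrc)
  src_mech <- matrix(0, max(nsrc, 1), 6)
  src_volinv <- numeric(max(nsrc, 1))
  src_scale <- numeric(nsrc)
  for (s in seq_len(nsrc)) {
    sr <- srcs[[s]]
    i <- round(sr$x / dx); j <- round(sr$y / dx)
    dzc <- dzcol[pmin(pmax(i + 1, 1), nx), pmin(pmax(j + 1, 1), ny)]
    k <- (nz - 1) - round(sr$depth / dzc)
    if (i < 2 || i > nx - 3 || j < 2 || j > ny - 3 || k < 2 || k > nz - 1)
      stop(sprintf("source %d at (%.0f, %.0f, depth %.0f) outside the grid interior",
                   s, sr$x, sr$y, sr$depth), call. = FALSE)
    src_idx[s] <- i + nx * (j + ny * k)   # 0-based linear index
    src_type[s] <- sr$type
    mech <- sr$mech
    scale <- 1
    if (isTRUE(sr$needs_mu)) {            # subfault: m0 = mu * area * slip
      mu_here <- mat$mu[src_idx[s] + 1]
      scale <- mu_here * sr$area * sr$slip
    }
    src_mech[s, ] <- mech
    src_scale[s] <- scale
    src_volinv[s] <- 1 / (dx * dx * dzc)
  }
  # sample source-time functions at half-step resolution
  t_half <- seq(0, by = dt / 2, length.out = 2 * nt + 1)
  stf_half <- matrix(0, length(t_half), max(nsrc, 1))
  for (s in seq_len(nsrc)) {
    sr <- srcs[[s]]
    w <- switch(sr$stf,
                ricker = ricker(t_half, sr$fc, sr$t0),
                gauss = gauss_pulse(t_half, sr$fc, sr$t0))
    stf_half[, s] <- w * src_scale[s]
  }

  sw <- sponge$width %||% 15
  if (length(sw) == 1) sw <- c(sw, sw, sw, if (free_surface) 0 else sw)
  if (free_surface) sw[4] <- 0

  structure(list(
    nx = nx, ny = ny, nz = nz, dx = dx, dzcol = dzcol, dt = dt, nt = nt,
    material = material, rho = mat$rho, lam = mat$lam, mu = mat$mu,
    free_surface = free_surface,
    sponge_width = as.integer(sw), sponge_alpha = sponge$alpha %||% 0.02,
    coeffs = default_stencil(),
    src_idx = src_idx, src_type = src_type,
    src_mech = src_mech, src_volinv = src_volinv, stf_half = stf_half,
    nsrc = nsrc, geo = geo
  ), class = "quake_sim")
}

#' @export
print.quake_sim <- function(x, ...) {
  cat(sprintf("quake_sim: %d x %d x %d grid, dx = %g m, dt = %g s, nt = %d (%.2f s)\n",
              x$nx, x$ny, x$nz, x$dx, x$dt, x$nt, x$nt * x$dt))
  cat(sprintf("  %d source(s), free surface: %s, sponge width %s\n",
              x$nsrc, x$free_surface,
              paste(x$sponge_width, collapse = "/")))
  invisible(x)
}

#' Run a simulation
#'
#' Marches the 9-component velocity-stress state with classic four-stage
#' Runge-Kutta; the forward/backward one-sided operators alternate per
#' stage and per axis on the fixed cycle
#' `forward if (step + stage + axis) mod 2 == 0`.  Fully deterministic.
#'
#' @param handle a `quake_sim` from [build_simulation()].
#' @param receivers optional matrix/data frame of receiver node indices
#'   (1-based columns `i`, `j`, `k`); full velocity time histories are
#'   returned at these nodes.
#' @param surface_every record the full surface velocity field every this
#'   many steps (`0` disables surface recording; PGV is always tracked at
#'   every step).
#' @param snapshot_steps integer steps at which to return full 3-D state
#'   snapshots (0 = initial state).
#' @param init_state optional named list of nine `nx x ny x nz` arrays
#'   (`vx`..`syz`) used as the initial condition.
#' @param step0 alternation-cycle offset (used when resuming).
#' @return object of class `surface_record`: `times`, surface `vx`/`vy`/
#'   `vz` arrays, `pgv_h`/`pgv_3d` matrices, receiver series, snapshots,
#'   `final` state and grid metadata.
#' @export
run_simulation <- function(handle, receivers = NULL, surface_every = 1,
                           snapshot_steps = integer(0), init_state = NULL,
                           step0 = 0) {
  stopifnot(inherits(handle, "quake_sim"))
  rcv <- if (is.null(receivers)) matrix(integer(0), 0, 3) else {
    m <- as.matrix(as.data.frame(receivers)[, 1:3])
    storage.mode(m) <- "integer"
    if (any(m < 1) || any(m[, 1] > handle$nx) || any(m[, 2] > handle$ny) ||
        any(m[, 3] > handle$nz))
      stop("receiver indices outside the grid", call. = FALSE)
    m - 1L
  }
  is_list <- NULL
  if (!is.null(init_state)) {
    nm <- c("vx", "vy", "vz", "sxx", "syy", "szz", "sxy", "sxz", "syz")
    if (!all(nm %in% names(init_state)))
      stop("init_state must contain fields ", paste(nm, collapse = ", "),
           call. = FALSE)
    is_list <- lapply(init_state[nm], as.numeric)
  }
  record_surface <- surface_every > 0
  res <- cpp_run_sim(
    dims = c(handle$nx, handle$ny, handle$nz), dx = handle$dx,
    invdz = as.numeric(1 / handle$dzcol),
    rho = handle$rho, lam = handle$lam, mu = handle$mu,
    coeff = as.numeric(handle$coeffs), dt = handle$dt, nt = handle$nt,
    step0 = as.integer(step0), free_surface = handle$free_surface,
    sponge_width = handle$sponge_width, sponge_alpha = handle$sponge_alpha,
    src_idx = handle$src_idx, src_type = handle$src_type,
    src_mech = handle$src_mech, src_volinv = handle$src_volinv,
    stf_half = handle$stf_half, init_state = is_list,
    surface_every = max(1L, as.integer(surface_every)), receivers = rcv,
    snapshot_steps = as.integer(snapshot_steps),
    record_surface = record_surface, return_final = TRUE)

  nx <- handle$nx; ny <- handle$ny
  out <- list(
    times = if (record_surface) res$surf_t else numeric(0),
    vx = if (record_surface) array(res$surf_vx, c(nx, ny, res$nrec)),
    vy = if (record_surface) array(res$surf_vy, c(nx, ny, res$nrec)),
    vz = if (record_surface) array(res$surf_vz, c(nx, ny, res$nrec)),
    pgv_h = matrix(res$pgv_h, nx, ny),
    pgv_3d = matrix(res$pgv_3d, nx, ny),
    receivers = if (nrow(rcv)) list(
      t = seq(0, by = handle$dt, length.out = handle$nt + 1),
      v = array(res$rcv, c(handle$nt + 1, 3, nrow(rcv)),
                dimnames = list(NULL, c("vx", "vy", "vz"), NULL))
    ),
    snapshots = lapply(res$snapshots, function(st) {
      out <- lapply(st, function(v) array(v, c(nx, ny, handle$nz)))
      attr(out, "step") <- attr(st, "step")
      out
    }),
    final = lapply(res$final, function(v) array(v, c(nx, ny, handle$nz))),
    dt = handle$dt, dx = handle$dx, nt = handle$nt, geo = handle$geo
  )
  structure(out, class = "surface_record")
}

#' @export
print.surface_record <- function(x, ...) {
  cat(sprintf("surface_record: %d x %d surface, %d steps of %g s, max PGV %.4g m/s\n",
              nrow(x$pgv_h), ncol(x$pgv_h), x$nt, x$dt, max(x$pgv_h)))
  invisible(x)
}

#' Advance a state by one Runge-Kutta step
#'
#' Single-step wrapper around the solver core, mainly for verification:
#' applies the four-stage update with the documented operator alternation
#' to an explicit state.
#'
#' @param handle a `quake_sim` from [build_simulation()].
#' @param state named list of nine arrays (see [run_simulation()]);
#'   defaults to the all-zero state.
#' @param step_index position in the alternation cycle.
#' @return the advanced state (list of nine arrays).
#' @export
rk4_step <- function(handle, state = NULL, step_index = 0) {
  h1 <- handle
  h1$nt <- 1L
  h1$stf_half <- handle$stf_half[seq_len(min(3, nrow(handle$stf_half))), ,
                                 drop = FALSE]
  if (nrow(h1$stf_half) < 3)
    h1$stf_half <- rbind(h1$stf_half,
                         matrix(0, 3 - nrow(h1$stf_half), ncol(h1$stf_half)))
  rec <- run_simulation(h1, surface_every = 0, init_state = state,
                        step0 = step_index)
  rec$final
}

#' Apply the traction-image free surface to a state
#'
#' Zeroes the traction components (`szz`, `sxz`, `syz`) on the top layer
#' and returns the antisymmetrically mirrored ghost planes that the
#' one-sided stencils read above the surface:
#' `sigma(ghost g) = -sigma(surface - g)`.
#'
#' @param state named list of nine `nx x ny x nz` arrays.
#' @param n_ghost number of ghost planes to materialise (default 3, the
#'   stencil's upward reach).
#' @return list with `state` (tractions zeroed at the surface) and `ghost`
#'   (list of `szz`, `sxz`, `syz` arrays of dim `nx x ny x n_ghost`).
#' @export
apply_free_surface <- function(state, n_ghost = 3) {
  nz <- dim(state$szz)[3]
  for (f in c("szz", "sxz", "syz")) state[[f]][, , nz] <- 0
  ghost <- lapply(state[c("szz", "sxz", "syz")], function(a) {
    g <- array(0, c(dim(a)[1], dim(a)[2], n_ghost))
    for (q in seq_len(n_ghost)) g[, , q] <- -a[, , nz - q]
    g
  })
  list(state = state, ghost = ghost)
}

#' Peak ground velocity from a surface record
#'
#' Per-cell maximum over time of the configured component norm.  The
#' horizontal norm `sqrt(vx^2 + vy^2)` (the default, matching the
#' PGV-intensity law's convention here) and the 3-component norm are
#' tracked at every time step during the run; per-component maxima use the
#' decimated surface record.
#'
#' @param record a [run_simulation()] result.
#' @param component `"horizontal"`, `"three"`, `"vx"`, `"vy"` or `"vz"`.
#' @return if the record carries georeferencing, a [geo_grid()] of PGV in
#'   m/s; otherwise a plain `nx x ny` matrix (with attribute `dx`).
#' @export
extract_pgv <- function(record, component = c("horizontal", "three",
                                              "vx", "vy", "vz")) {
  component <- match.arg(component)
  m <- switch(component,
              horizontal = record$pgv_h,
              three = record$pgv_3d,
              vx = apply(abs(record$vx), c(1, 2), max),
              vy = apply(abs(record$vy), c(1, 2), max),
              vz = apply(abs(record$vz), c(1, 2), max))
  if (is.null(record$geo)) {
    attr(m, "dx") <- record$dx
    return(m)
  }
  # local flat-earth georeferencing about the grid center
  lat0 <- record$geo$lat
  cs <- record$dx / (111320 * cos(lat0 * pi / 180))
  nx <- nrow(m); ny <- ncol(m)
  spec <- grid_spec(record$geo$lon - (nx - 1) / 2 * cs,
                    record$geo$lat - (ny - 1) / 2 * cs, cs,
                    nrows = ny, ncols = nx)
  geo_grid(spec, t(m))
}

#' First-arrival pick by threshold crossing
#'
#' Returns the first time at which `|v|` exceeds `frac` of its maximum.
#' Comparing picks between two receivers cancels the source onset delay,
#' which is how arrival times are checked against ray-theoretical times.
#'
#' @param t time vector.
#' @param v velocity series.
#' @param frac threshold as a fraction of the series maximum.
#' @return pick time, s.
#' @export
pick_first_arrival <- function(t, v, frac = 0.1) {
  a <- abs(v)
  thr <- frac * max(a)
  if (thr == 0) return(NA_real_)
  t[which(a >= thr)[1]]
}

#' Envelope peak time of a narrowband waveform
#'
#' Smooths `|v|` with a running mean of width `period` (removing the
#' carrier oscillation) and returns the sub-sample time of the envelope
#' maximum by parabolic refinement.  Differencing the peak times of two
#' receivers gives a cycle-skip-free propagation-speed measurement for
#' wave-packet verification runs.
#'
#' @param t time vector.
#' @param v velocity series.
#' @param period carrier period, s.
#' @return envelope peak time, s.
#' @export
envelope_peak_time <- function(t, v, period) {
  dt <- t[2] - t[1]
  w <- max(3L, round(period / dt))
  if (w %% 2 == 0) w <- w + 1L
  env <- stats::filter(abs(v), rep(1 / w, w), sides = 2)
  k <- which.max(env)
  tp <- t[k]
  if (k > 1 && k < length(env) && all(is.finite(env[(k - 1):(k + 1)]))) {
    y1 <- env[k - 1]; y2 <- env[k]; y3 <- env[k + 1]
    den <- y1 - 2 * y2 + y3
    if (den != 0) tp <- tp + 0.5 * (y1 - y3) / den * dt
  }
  tp
}

#' Discrete elastic energy of a state
#'
#' Kinetic plus strain energy, `sum 1/2 rho v^2 + 1/2 sigma : epsilon`,
#' with strain recovered from stress through the isotropic compliance.
#' Used to verify that the scheme does not spuriously create energy after
#' the source switches off.
#'
#' @param state named list of nine arrays.
#' @param material a [material_model()] (homogeneous only).
#' @param cell_volume cell volume, m^3.
#' @return total energy, J.
#' @export
state_energy <- function(state, material, cell_volume) {
  rho <- material$rho[1]
  mu <- rho * material$vs[1]^2
  lam <- rho * (material$vp[1]^2 - 2 * material$vs[1]^2)
  kin <- 0.5 * rho * (state$vx^2 + state$vy^2 + state$vz^2)
  trs <- state$sxx + state$syy + state$szz
  dev <- function(s, d) s - d * lam * trs / (3 * lam + 2 * mu)
  eps_xx <- dev(state$sxx, 1) / (2 * mu)
  eps_yy <- dev(state$syy, 1) / (2 * mu)
  eps_zz <- dev(state$szz, 1) / (2 * mu)
  eps_xy <- state$sxy / (2 * mu)
  eps_xz <- state$sxz / (2 * mu)
  eps_yz <- state$syz / (2 * mu)
  strain <- 0.5 * (state$sxx * eps_xx + state$syy * eps_yy +
                   state$szz * eps_zz +
                   2 * (state$sxy * eps_xy + state$sxz * eps_xz +
                        state$syz * eps_yz))
  sum(kin + strain) * cell_volume
}

#' Plane-wave initial state
#'
#' Gaussian-modulated sinusoidal P or S plane wave travelling in +x through
#' a homogeneous medium, with the consistent velocity-stress relation
#' (`sxx = -rho vp vx` for P; `sxy = -rho vs vy` for S), uniform in y and
#' z.  Used for phase-speed and convergence verification.
#'
#' @param grid a [sim_grid()].
#' @param material homogeneous [material_model()].
#' @param wavelength carrier wavelength, m.
#' @param type `"P"` or `"S"`.
#' @param x0 packet center, m.
#' @param width Gaussian envelope width, m (default 1.5 wavelengths).
#' @param amplitude peak particle velocity, m/s.
#' @return named list of nine arrays (an initial state).
#' @export
plane_wave_state <- function(grid, material, wavelength, type = c("P", "S"),
                             x0, width = 1.5 * wavelength, amplitude = 1e-3) {
  type <- match.arg(type)
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  x <- (seq_len(nx) - 1) * grid$dx
  carrier <- amplitude * sin(2 * pi * (x - x0) / wavelength) *
    exp(-((x - x0) / width)^2)
  rho <- material$rho[1]
  vp <- material$vp[1]; vs <- material$vs[1]
  lam <- rho * (vp^2 - 2 * vs^2); mu <- rho * vs^2
  zero <- array(0, c(nx, ny, nz))
  line <- function(v) array(rep(v, times = ny * nz), c(nx, ny, nz))
  st <- list(vx = zero, vy = zero, vz = zero, sxx = zero, syy = zero,
             szz = zero, sxy = zero, sxz = zero, syz = zero)
  if (type == "P") {
    st$vx <- line(carrier)
    st$sxx <- line(-rho * vp * carrier)
    st$syy <- st$szz <- line(-rho * vp * carrier * lam / (lam + 2 * mu))
  } else {
    st$vy <- line(carrier)
    st$sxy <- line(-rho * vs * carrier)
  }
  st
}
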