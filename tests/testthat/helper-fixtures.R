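# shared fixture builders (everything generated in code; no stored data)

tiny_hdi <- function() hdi_table(data.frame(year = c(1976, 2000, 2021),
                                            hdi = c(0.38, 0.59, 0.76)))

flat_hdi <- function(value = 0.7) hdi_table(data.frame(year = 1950:2021,
                                                       hdi = value))

# hand-built catalog from a known law (single region, no noise)
toy_catalog <- function(region = "e", beta = -7, theta = 0.5,
                        n = 5, seed = 1) {
  set.seed(seed)
  hdi <- flat_hdi()
  rows <- lapply(seq_len(n), function(i) {
    pe <- setNames(numeric(7), paste0("pe", 5:11))
    pe[sample(7, 3)] <- 10^runif(3, 3, 5)
    r <- 10^(beta + theta * (5:11))
    E <- sum(pmin(r, 1) * pe)
    data.frame(id = sprintf("t%02d", i), region_code = region, year = 2000,
               magnitude = 6, O = max(1, floor(E + 0.5)),
               as.list(pe))
  })
  do.call(rbind, rows)
}

# small homogeneous simulation handle for solver unit tests
tiny_sim <- function(nx = 30, ny = 30, nz = 20, dx = 200, duration = 0.5,
                     source = NULL, free_surface = TRUE,
                     sponge = list(width = 6, alpha = 0.02), ...) {
  mat <- material_model(vp = 6000, vs = 6000 / sqrt(3), rho = 2700)
  g <- sim_grid(nx, ny, nz, dx, duration = duration, cfl = 0.4)
  build_simulation(mat, g, source, free_surface = free_surface,
                   sponge = sponge, ...)
}

zero_state <- function(handle) {
  z <- array(0, c(handle$nx, handle$ny, handle$nz))
  setNames(rep(list(z), 9),
           c("vx", "vy", "vz", "sxx", "syy", "szz", "sxy", "sxz", "syz"))
}
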