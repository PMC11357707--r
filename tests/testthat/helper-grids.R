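# Small constructed grids and independent reference solvers used across
# the verification tests.

# homogeneous block grid of one tissue class (no phantom geometry)
homogeneous_grid <- function(dm, class = "muscle", spacing = 1e-3,
                             origin = -dm * spacing / 2) {
  classes <- c("air", "cortical bone", "cancellous bone", "cartilage",
               "muscle", "spinal cord", "applicator")
  structure(list(origin = origin, spacing = spacing, dim = as.integer(dm),
                 labels = array(match(class, classes), dim = dm),
                 classes = classes,
                 applicator_mask = array(FALSE, dim = dm)),
            class = "label_grid")
}

# mark a set of voxels (logical array) as fixed-temperature applicator
set_dirichlet <- function(grid, mask) {
  grid$labels[mask] <- match("applicator", grid$classes)
  grid$applicator_mask <- mask
  grid
}

# brute-force explicit (forward Euler) reference for the same spatial
# discretization: harmonic-mean face conductances, Robin at tissue-air
# faces and the outer boundary, Dirichlet on applicator voxels. Written
# independently of the package solver (dense loops over neighbor shifts).
explicit_reference <- function(grid, library, sar_values, bc, t_init,
                               duration, dt) {
  dm <- grid$dim
  lab <- grid$labels
  kcl <- vapply(grid$classes, function(cl)
    lookup(library, cl)$thermal_conductivity, numeric(1))
  rcl <- vapply(grid$classes, function(cl)
    lookup(library, cl)$density, numeric(1))
  ccl <- vapply(grid$classes, function(cl)
    lookup(library, cl)$specific_heat, numeric(1))
  kv <- array(kcl[lab], dim = dm)
  h <- grid$spacing; Af <- h^2; V <- h^3
  air <- lab == match("air", grid$classes)
  app <- lab == match("applicator", grid$classes)
  tissue <- !air & !app
  cap <- array(rcl[lab] * ccl[lab] * V, dim = dm)
  q <- array(rcl[lab], dim = dm) * sar_values * V

  Tm <- array(t_init, dim = dm)
  Tm[app] <- bc$applicator_temperature
  nstep <- round(duration / dt)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  idx <- arrayInd(seq_len(prod(dm)), dm)
  for (n in seq_len(nstep)) {
    flux <- array(0, dim = dm)   # W into each voxel
    for (s in seq_len(nrow(shifts))) {
      nb <- idx + matrix(shifts[s, ], nrow(idx), 3, byrow = TRUE)
      in_dom <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
        nb[, 2] >= 1 & nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
      me <- which(tissue)
      sel <- me[in_dom[me]]
      nbl <- nb[sel, , drop = FALSE]
      nbi <- nbl[, 1] + (nbl[, 2] - 1) * dm[1] + (nbl[, 3] - 1) * dm[1] * dm[2]
      is_air_nb <- air[nbi]
      is_t_or_app <- !is_air_nb
      ka <- kv[sel]; kb <- kv[nbi]
      G <- ifelse(ka + kb > 0, Af / h * 2 * ka * kb / (ka + kb), 0)
      dT <- Tm[nbi] - Tm[sel]
      add <- numeric(length(sel))
      add[is_t_or_app] <- (G * dT)[is_t_or_app]
      add[is_air_nb] <- bc$convective_h * Af *
        (bc$external_temperature - Tm[sel])[is_air_nb]
      flux[sel] <- flux[sel] + add
      # outer boundary face
      outs <- me[!in_dom[me]]
      flux[outs] <- flux[outs] + bc$convective_h * Af *
        (bc$external_temperature - Tm[outs])
    }
    Tm[tissue] <- Tm[tissue] + dt * (flux[tissue] + q[tissue]) / cap[tissue]
    Tm[app] <- bc$applicator_temperature
  }
  Tm
}

# closed-form attenuation oracle: alpha from the complex wavenumber
# k = omega*sqrt(mu0 eps0 (eps_r - j sigma/(omega eps0))), alpha = -Im(k)
alpha_complex_oracle <- function(eps_r, sigma, frequency) {
  mu0 <- 4e-7 * pi; eps0 <- 8.8541878128e-12
  w <- 2 * pi * frequency
  k <- w * sqrt(mu0 * eps0 * complex(real = eps_r,
                                     imaginary = -sigma / (w * eps0)))
  if (Im(k) > 0) k <- -k
  -Im(k)
}
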