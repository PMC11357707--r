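# Transient bioheat solver: 7-point finite-volume discretization on the
# voxel grid, backward-Euler time stepping via a single sparse Cholesky
# factorization (static properties => constant system matrix).
#
# rho c dT/dt = div(k grad T) + rho * SAR        (ex vivo: no perfusion)
#
# Boundary conditions: Robin (convective) on every face between tissue and
# air — both the vertebra/disk surface and the outer domain boundary — and
# a Dirichlet fixed temperature on the water-cooled applicator surface.
# Air is not a conducting medium in this model; it acts only through the
# convective condition and is reported at the external temperature.

#' Thermal boundary conditions
#'
#' @param convective_h Convective heat-transfer coefficient at tissue-air
#'   interfaces (W/m^2/degC), default 10.
#' @param external_temperature Ambient temperature (degC), default 20.
#' @param applicator_temperature Fixed temperature of the cooled
#'   applicator surface (degC), default 30 (isothermal approximation of
#'   the water-cooled shaft).
#' @return An object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(convective_h = 10, external_temperature = 20,
                                applicator_temperature = 30) {
  stopifnot(convective_h >= 0)
  structure(list(convective_h = convective_h,
                 external_temperature = external_temperature,
                 applicator_temperature = applicator_temperature),
            class = "boundary_conditions")
}

#' Ablation protocol
#'
#' @param generator_setpoint Generator console power (W), > 0.
#' @param nominal_applied_power Power at the antenna used by the
#'   simulation (W), > 0. The nominal values (40 W for the 80 W setpoint,
#'   60 W for 120 W) are used rather than the exact -2.84 dB chain values
#'   (41.6 / 62.4 W); see [applied_power()] for the chain arithmetic.
#' @param duration Ablation duration (s), > 0.
#' @param initial_temperature Initial tissue temperature (degC).
#' @return An object of class `ablation_protocol`.
#' @export
ablation_protocol <- function(generator_setpoint, nominal_applied_power,
                              duration, initial_temperature) {
  stopifnot(generator_setpoint > 0, nominal_applied_power > 0, duration > 0)
  structure(list(generator_setpoint = generator_setpoint,
                 nominal_applied_power = nominal_applied_power,
                 duration = duration,
                 initial_temperature = initial_temperature),
            class = "ablation_protocol")
}

#' Wrap a user-built SAR array as a `sar_field`
#'
#' For constructed or analytic sources (verification studies); values are
#' specific absorption rate in W/kg on the grid's voxels.
#'
#' @param grid A `label_grid`.
#' @param values 3D numeric array matching `grid$dim`.
#' @param applied_power Nominal applied power (W), or `NA`.
#' @return A `sar_field`.
#' @export
as_sar_field <- function(grid, values, applied_power = NA_real_) {
  stopifnot(identical(dim(values), as.integer(grid$dim)) ||
              all(dim(values) == grid$dim))
  structure(list(grid = grid, values = values,
                 applied_power = applied_power, params = NULL),
            class = "sar_field")
}

.tri_corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))

# trilinear interpolation stencil for a world position: 8 linear indices
# and weights in the voxel-center frame
.trilinear_stencil <- function(grid, position) {
  u <- (position - grid$origin) / grid$spacing - 0.5
  i0 <- floor(u)
  f <- u - i0
  i0 <- i0 + 1  # 1-based lower corner
  for (d in 1:3) {
    if (i0[d] < 1) { i0[d] <- 1; f[d] <- 0 }
    if (i0[d] > grid$dim[d] - 1) { i0[d] <- grid$dim[d] - 1; f[d] <- 1 }
  }
  corners <- .tri_corners
  idx <- (i0[1] + corners[, 1]) +
    (i0[2] + corners[, 2] - 1) * grid$dim[1] +
    (i0[3] + corners[, 3] - 1) * grid$dim[1] * grid$dim[2]
  w <- (ifelse(corners[, 1] == 1, f[1], 1 - f[1])) *
    (ifelse(corners[, 2] == 1, f[2], 1 - f[2])) *
    (ifelse(corners[, 3] == 1, f[3], 1 - f[3]))
  list(idx = as.integer(idx), w = w)
}

#' Solve the transient bioheat problem
#'
#' Backward-Euler (implicit, unconditionally stable) integration with
#' uniform steps `duration/ceiling(duration/max_dt) <= max_dt`. Face
#' conductivities across tissue interfaces use the harmonic mean; faces
#' between tissue and air (internal surfaces and the outer domain
#' boundary) carry the convective condition; applicator voxels are held at
#' the applicator temperature. The system matrix is factored once
#' (CHOLMOD) and reused for every step.
#'
#' @param grid A `label_grid`.
#' @param library A [material_library()] resolving every grid label.
#' @param sar A `sar_field` on the same grid.
#' @param bc [boundary_conditions()].
#' @param protocol [ablation_protocol()] (duration and initial
#'   temperature are used here).
#' @param max_dt Maximum time step (s), default 10.
#' @param probes Optional list of [probe_spec()]s sampled at every
#'   internal step into sensor logs.
#' @param store `"steps"` (snapshot at every step; steps are `<= max_dt`
#'   apart) or `"final"` (initial and final only, to bound memory on fine
#'   grids).
#' @param perfusion_coefficient Volumetric perfusion heat-sink coefficient
#'   rho_b c_b omega (W/m^3/degC). Fixed at 0 for all ex vivo work; the
#'   argument exists as a documented extension hook.
#' @param blood_temperature Perfusion reference temperature (degC).
#' @return An object of class `temperature_field`: `grid`, `times` (s),
#'   `values` (list of 3D arrays, degC), `probe_logs` (list of
#'   `sensor_log`, if probes given), `protocol`, `bc`.
#' @export
solve_bioheat <- function(grid, library, sar, bc, protocol, max_dt = 10,
                          probes = NULL, store = c("steps", "final"),
                          perfusion_coefficient = 0, blood_temperature = 37) {
  store <- match.arg(store)
  stopifnot(inherits(grid, "label_grid"), inherits(sar, "sar_field"),
            inherits(bc, "boundary_conditions"),
            inherits(protocol, "ablation_protocol"), max_dt > 0)
  if (!all(is.finite(sar$values))) stop("non-finite SAR values")
  dm <- grid$dim; N <- prod(dm)
  lab <- as.integer(grid$labels)
  kcl <- vapply(grid$classes, function(cl)
    lookup(library, cl)$thermal_conductivity, numeric(1))
  rcl <- vapply(grid$classes, function(cl)
    lookup(library, cl)$density, numeric(1))
  ccl <- vapply(grid$classes, function(cl)
    lookup(library, cl)$specific_heat, numeric(1))
  if (!all(is.finite(c(kcl, rcl, ccl)))) stop("non-finite material properties")
  air_code <- match("air", grid$classes)
  app_code <- match("applicator", grid$classes)

  unknown <- which(lab != air_code & lab != app_code)
  Nu <- length(unknown)
  if (Nu == 0L) stop("no tissue voxels to solve for")
  red <- integer(N); red[unknown] <- seq_len(Nu)

  h <- grid$spacing; Af <- h^2; V <- h^3
  kv <- kcl[lab]
  T_app <- bc$applicator_temperature
  T_ext <- bc$external_temperature
  hconv <- bc$convective_h

  diag_add <- numeric(Nu)
  rhs_const <- numeric(Nu)
  tri_i <- vector("list", 3); tri_j <- vector("list", 3); tri_x <- vector("list", 3)

  strides <- c(1L, dm[1], dm[1] * dm[2])
  for (d in 1:3) {
    ii <- arrayInd(seq_len(N), dm)
    keep <- ii[, d] < dm[d]
    a <- which(keep); b <- a + strides[d]
    la <- lab[a]; lb <- lab[b]
    ra <- red[a]; rb <- red[b]
    ua <- ra > 0; ub <- rb > 0

    # tissue-tissue conduction, harmonic-mean face conductivity
    tt <- ua & ub
    if (any(tt)) {
      ka <- kv[a[tt]]; kb <- kv[b[tt]]
      G <- Af / h * ifelse(ka + kb > 0, 2 * ka * kb / (ka + kb), 0)
      ia <- ra[tt]; ib <- rb[tt]
      tri_i[[d]] <- c(ia, ib); tri_j[[d]] <- c(ib, ia); tri_x[[d]] <- c(-G, -G)
      # ia (ib) values are unique within a direction: each voxel has at
      # most one +d (-d) face, so plain indexed addition accumulates safely
      dd <- numeric(Nu)
      dd[ia] <- G
      dd[ib] <- dd[ib] + G
      diag_add <- diag_add + dd
    }

    # tissue-applicator: Dirichlet coupling through the face
    for (side in 1:2) {
      if (side == 1) { tu <- ua & lb == app_code; iu <- ra[tu]; ku <- kv[a[tu]]; kn <- kv[b[tu]] }
      else           { tu <- ub & la == app_code; iu <- rb[tu]; ku <- kv[b[tu]]; kn <- kv[a[tu]] }
      if (any(tu)) {
        G <- Af / h * 2 * ku * kn / (ku + kn)
        diag_add[iu] <- diag_add[iu] + G
        rhs_const[iu] <- rhs_const[iu] + G * T_app
      }
    }

    # tissue-air: Robin condition on the shared face
    for (side in 1:2) {
      if (side == 1) { tu <- ua & lb == air_code; iu <- ra[tu] }
      else           { tu <- ub & la == air_code; iu <- rb[tu] }
      if (any(tu)) {
        diag_add[iu] <- diag_add[iu] + hconv * Af
        rhs_const[iu] <- rhs_const[iu] + hconv * Af * T_ext
      }
    }
  }

  # outer domain boundary: Robin on every exposed face of a tissue voxel
  iu_all <- arrayInd(unknown, dm)
  n_exposed <- rowSums(iu_all == 1L) +
    (iu_all[, 1] == dm[1]) + (iu_all[, 2] == dm[2]) + (iu_all[, 3] == dm[3])
  diag_add <- diag_add + hconv * Af * n_exposed
  rhs_const <- rhs_const + hconv * Af * T_ext * n_exposed

  # perfusion hook (zero ex vivo)
  if (perfusion_coefficient > 0) {
    diag_add <- diag_add + perfusion_coefficient * V
    rhs_const <- rhs_const + perfusion_coefficient * V * blood_temperature
  }

  # volumetric source (W per voxel)
  q <- rcl[lab[unknown]] * sar$values[unknown] * V
  cap <- rcl[lab[unknown]] * ccl[lab[unknown]] * V

  nstep <- ceiling(protocol$duration / max_dt)
  dt <- protocol$duration / nstep

  A <- Matrix::sparseMatrix(
    i = c(unlist(tri_i), seq_len(Nu)),
    j = c(unlist(tri_j), seq_len(Nu)),
    x = c(unlist(tri_x), diag_add + cap / dt),
    dims = c(Nu, Nu))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A, uplo = "L"))

  # snapshot builder
  full_at <- function(Tu) {
    full <- array(T_ext, dim = dm)
    full[lab == app_code] <- T_app
    full[unknown] <- Tu
    full
  }
  snap0 <- array(protocol$initial_temperature, dim = dm)
  snap0[grid$applicator_mask] <- T_app

  stencils <- NULL
  if (!is.null(probes)) {
    stencils <- lapply(probes, function(p) {
      u <- (p$position - grid$origin) / grid$spacing
      if (any(u < 0) || any(u > grid$dim))
        stop(sprintf("probe '%s' outside grid domain", p$name))
      .trilinear_stencil(grid, p$position)
    })
    plog <- matrix(NA_real_, nrow = nstep + 1L, ncol = length(probes))
    plog[1, ] <- vapply(stencils, function(s) sum(snap0[s$idx] * s$w),
                        numeric(1))
  }

  Tu <- rep(protocol$initial_temperature, Nu)
  times <- c(0, dt * seq_len(nstep))
  values <- vector("list", if (store == "steps") nstep + 1L else 2L)
  values[[1]] <- snap0
  rhs_src <- q + rhs_const
  for (n in seq_len(nstep)) {
    bvec <- cap / dt * Tu + rhs_src
    Tu <- as.numeric(Matrix::solve(ch, bvec, system = "A"))
    if (!all(is.finite(Tu))) stop("solver produced non-finite temperatures")
    full <- full_at(Tu)
    if (store == "steps") values[[n + 1L]] <- full
    else if (n == nstep) values[[2L]] <- full
    if (!is.null(probes))
      plog[n + 1L, ] <- vapply(stencils, function(s) sum(full[s$idx] * s$w),
                               numeric(1))
  }

  logs <- NULL
  if (!is.null(probes)) {
    logs <- lapply(seq_along(probes), function(k) {
      sensor_log(channel = probes[[k]]$name,
                 nominal_position = probes[[k]]$position,
                 times = times, temperatures = plog[, k],
                 provenance = "simulated",
                 nominal_distance = probes[[k]]$nominal_distance)
    })
    names(logs) <- vapply(probes, function(p) p$name, character(1))
  }

  structure(list(grid = grid,
                 times = if (store == "steps") times
                         else c(0, protocol$duration),
                 values = values, probe_logs = logs,
                 protocol = protocol, bc = bc),
            class = "temperature_field")
}

#' End-to-end protocol simulation
#'
#' Convenience pipeline: build phantom, place applicator, synthesize the
#' directional SAR field at the protocol's nominal applied power, solve
#' the bioheat problem, and sample the default probes. Deterministic for a
#' fixed configuration.
#'
#' @param spec [phantom_spec()].
#' @param pose [applicator_pose()]; default [default_applicator_pose()].
#' @param params [directional_source_params()].
#' @param protocol [ablation_protocol()].
#' @param bc [boundary_conditions()].
#' @param library [material_library()].
#' @param spacing Voxel edge (m), default 1e-3.
#' @param max_dt Maximum time step (s), default 10.
#' @param probes Probe list; default T1/T2 from [default_probes()].
#' @param store Snapshot storage policy, see [solve_bioheat()].
#' @return List with `field` (a `temperature_field`) and `logs` (named
#'   list of `sensor_log`).
#' @export
simulate_protocol <- function(spec = phantom_spec(), pose = NULL,
                              params = directional_source_params(),
                              protocol, bc = boundary_conditions(),
                              library = load_default_library(),
                              spacing = 1e-3, max_dt = 10, probes = NULL,
                              store = "steps") {
  if (is.null(pose)) pose <- default_applicator_pose(spec)
  grid <- build_phantom(spec, spacing)
  grid <- place_applicator(grid, pose)
  if (is.null(probes)) probes <- default_probes(pose)[c("T1", "T2")]
  sar <- synthesize_sar(grid, pose, params, library,
                        protocol$nominal_applied_power)
  field <- solve_bioheat(grid, library, sar, bc, protocol, max_dt = max_dt,
                         probes = probes, store = store)
  list(field = field, logs = field$probe_logs)
}

#' Build an anchor simulator for source calibration
#'
#' Returns a closure `(params) -> final anchor-probe temperature` that
#' reuses one phantom build across calibration evaluations.
#'
#' @inheritParams simulate_protocol
#' @param probe The anchor [probe_spec()].
#' @return Function of `params`.
#' @export
make_anchor_simulator <- function(spec = phantom_spec(), pose = NULL,
                                  protocol, probe,
                                  bc = boundary_conditions(),
                                  library = load_default_library(),
                                  spacing = 1e-3, max_dt = 10) {
  if (is.null(pose)) pose <- default_applicator_pose(spec)
  grid <- place_applicator(build_phantom(spec, spacing), pose)
  function(params) {
    sar <- synthesize_sar(grid, pose, params, library,
                          protocol$nominal_applied_power)
    field <- solve_bioheat(grid, library, sar, bc, protocol,
                           probes = list(probe), store = "final")
    lg <- field$probe_logs[[1]]
    lg$temperatures[length(lg$temperatures)]
  }
}
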