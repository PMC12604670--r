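## R-side interface to the Langevin engine.
##
## Reduced Lennard-Jones units throughout: lengths in sigma, energies in
## epsilon, kB = 1, bead mass 1, time in tau_LJ = sigma sqrt(m/eps).

#' Simulation parameters for the bead-spring Langevin engine
#'
#' Defaults are the Kremer-Grest bead-spring model: FENE bonds `K = 30
#' eps/sigma^2`, `R0 = 1.5 sigma`, WCA repulsion with cutoff
#' `2^(1/6) sigma`, cosine bending with `kappa_bend = 4 eps` (persistence
#' length ~4 sigma at T = 1), damping `gamma = 0.1 / tau_LJ` and timestep
#' `dt = 0.01 tau_LJ`.
#'
#' @param K,R0 FENE spring constant (eps/sigma^2) and maximum extension
#'   (sigma).
#' @param eps,sigma WCA energy and length scales.
#' @param kappa_bend Bending constant (eps); 0 disables bending.
#' @param gamma Langevin damping rate (1/tau_LJ).
#' @param dt Timestep (tau_LJ).
#' @param temperature Reduced temperature (kB = 1).
#' @param wall_gap Slit gap (sigma) between two harmonic walls at
#'   `z = +/- gap/2`; `NULL` disables walls.
#' @param wall_gap_start,wall_ramp_steps Optional linear ramp of the gap
#'   from `wall_gap_start` down to `wall_gap` over `wall_ramp_steps` steps
#'   (used for disk compression).
#' @param wall_k Wall spring constant (eps/sigma^2).
#' @param fmax Cap on the pair-force magnitude (soft push for resolving
#'   build-time overlaps); 0 disables the cap.
#' @param fmax_end When `> fmax`, the cap ramps linearly from `fmax` to
#'   `fmax_end` over the run (gradual push-off).
#' @param sigma_start When `> 0`, the WCA diameter grows linearly from
#'   `sigma_start` to `sigma` over the run: the repulsive core stays
#'   impenetrable at every stage, so build-time overlaps are resolved
#'   without any possibility of strand crossing.
#' @return A `sim_params` list.
#' @export
sim_params <- function(K = 30, R0 = 1.5, eps = 1, sigma = 1, kappa_bend = 4,
                       gamma = 0.1, dt = 0.01, temperature = 1,
                       wall_gap = NULL, wall_gap_start = NULL,
                       wall_ramp_steps = 0, wall_k = 50, fmax = 0,
                       fmax_end = 0, sigma_start = 0) {
  stopifnot(dt > 0, gamma > 0, R0 > sigma)
  structure(list(K = K, R0 = R0, eps = eps, sigma = sigma,
                 kappa_bend = kappa_bend, gamma = gamma, dt = dt,
                 temperature = temperature,
                 wall = !is.null(wall_gap),
                 gap_end = wall_gap %||% -1,
                 gap_start = wall_gap_start %||% (wall_gap %||% -1),
                 ramp_steps = wall_ramp_steps,
                 wall_k = wall_k, fmax = fmax, fmax_end = fmax_end,
                 sigma_start = sigma_start),
            class = "sim_params")
}

.par_list <- function(p)
  list(K = p$K, R0 = p$R0, eps = p$eps, sigma = p$sigma,
       kappa_bend = p$kappa_bend, gamma = p$gamma, dt = p$dt,
       temperature = p$temperature, wall = p$wall,
       gap_start = p$gap_start, gap_end = p$gap_end,
       ramp_steps = p$ramp_steps, wall_k = p$wall_k, fmax = p$fmax,
       fmax_end = p$fmax_end %||% 0, sigma_start = p$sigma_start %||% 0)

#' Initial simulation state from a network
#'
#' Bead positions from the network; velocities drawn from the
#' Maxwell-Boltzmann distribution at the target temperature.
#'
#' @param network An `olympic_network`.
#' @param params A [sim_params()].
#' @param seed Integer seed for the initial velocities.
#' @return A `sim_state` (positions, velocities, ring lengths, network).
#' @export
sim_state <- function(network, params = sim_params(), seed = 1) {
  pos <- net_positions(network)
  vel <- with_seed(seed, matrix(stats::rnorm(length(pos),
                                             sd = sqrt(params$temperature)),
                                nrow(pos), 3))
  structure(list(pos = pos, vel = vel,
                 ring_len = ring_lengths(network),
                 network = network, time = 0),
            class = "sim_state")
}

#' Advance a simulation state by n steps
#'
#' BAOAB Langevin integration with the forces described in [sim_params()].
#' Aborts with a diagnostic if a FENE bond overstretches or coordinates
#' become non-finite. Identical (state, params, n_steps, seed) give a
#' bitwise-identical trajectory.
#'
#' @param state A [sim_state()].
#' @param params A [sim_params()].
#' @param n_steps Number of timesteps.
#' @param dump_every Store a configuration every this many steps (0: none).
#' @param seed Integer seed for the thermostat noise.
#' @return Updated `sim_state` with elements `trajectory` (list of n x 3
#'   matrices), `dump_time`, `dump_temp` (instantaneous kinetic
#'   temperature at each dump) and `mean_temp` over the run.
#' @export
run_langevin <- function(state, params, n_steps, dump_every = 0, seed = 1) {
  stopifnot(inherits(state, "sim_state"), inherits(params, "sim_params"))
  res <- cpp_langevin_run(state$pos, state$vel,
                          as.integer(state$ring_len), .par_list(params),
                          as.numeric(n_steps), as.numeric(dump_every),
                          as.numeric(seed))
  n <- nrow(state$pos)
  frames <- NULL
  if (res$n_dumps > 0) {
    frames <- lapply(seq_len(res$n_dumps), function(f) {
      matrix(res$frames[((f - 1) * n * 3 + 1):(f * n * 3)],
             n, 3, byrow = TRUE)
    })
  }
  state$pos <- res$pos
  state$vel <- res$vel
  state$time <- state$time + n_steps * params$dt
  state$trajectory <- frames
  state$dump_time <- res$dump_time
  state$dump_temp <- res$dump_temp
  state$mean_temp <- res$mean_temp
  state$network <- set_positions(state$network, res$pos)
  state
}

#' Per-term potential energy of a configuration
#'
#' @param state A [sim_state()] (or a list with `pos` and `ring_len`).
#' @param params A [sim_params()].
#' @return List with `fene`, `wca`, `bend`, `wall` and `total` energies.
#' @export
potential_energy <- function(state, params = sim_params()) {
  cpp_energy(state$pos, as.integer(state$ring_len), .par_list(params))
}

#' Equilibration diagnostic on a radius-of-gyration series
#'
#' Passes when at least 95% of the Rg values lie within two standard
#' deviations of the mean and the series shows no trend
#' (|linear slope| x duration <= `trend_tol` standard deviations).
#'
#' @param rg Numeric vector of per-frame radius of gyration values.
#' @param trend_tol Trend guard in units of the series SD (default 0.5).
#' @return An `equilibration_report` list: `mean`, `sd`,
#'   `frac_within_2sd`, `trend_sd`, `pass`.
#' @export
equilibration_report <- function(rg, trend_tol = 0.5) {
  stopifnot(length(rg) >= 10)
  m <- mean(rg); s <- stats::sd(rg)
  frac <- mean(abs(rg - m) <= 2 * s)
  tt <- seq_along(rg)
  slope <- stats::coef(stats::lm(rg ~ tt))[2]
  trend_sd <- if (s > 0) abs(slope) * length(rg) / s else 0
  structure(list(mean = m, sd = s, frac_within_2sd = frac,
                 trend_sd = unname(trend_sd),
                 pass = frac >= 0.95 && trend_sd <= trend_tol),
            class = "equilibration_report")
}

#' @export
print.equilibration_report <- function(x, ...) {
  cat(sprintf("Rg %.3f +/- %.3f sigma; %.1f%% within 2 SD; trend %.2f SD; %s\n",
              x$mean, x$sd, 100 * x$frac_within_2sd, x$trend_sd,
              if (x$pass) "equilibrated" else "NOT equilibrated"))
  invisible(x)
}

#' Radius of gyration of a configuration
#' @param pos n x 3 coordinate matrix.
#' @return Scalar Rg.
#' @export
radius_of_gyration <- function(pos) {
  ctr <- colMeans(pos)
  sqrt(mean(rowSums(sweep(pos, 2, ctr)^2)))
}

#' Equilibration + production protocol with topology conservation check
#'
#' Runs equilibration (no dumps), then production with configuration dumps,
#' computes the per-frame radius of gyration, applies the 95%-within-2SD
#' equilibration criterion with a trend guard, and verifies that the full
#' linking matrix is identical before and after the run (aborting
#' otherwise: the topology of an Olympic network must be conserved).
#'
#' @param network An `olympic_network`.
#' @param params A [sim_params()].
#' @param equil_steps,prod_steps Step counts. Paper-scale runs use 1e8 and
#'   1.5e9; desk-scale analyses here default to much smaller counts set by
#'   the caller.
#' @param dump_every Production dump stride.
#' @param seed Integer seed.
#' @param check_topology Verify the link matrix before/after (default TRUE).
#' @param soft_steps Length of an initial bead-growth phase (the WCA
#'   diameter ramps from 0.3 sigma up to sigma) that resolves build-time
#'   ring-ring overlaps; the repulsive core is impenetrable throughout, so
#'   no strand crossing can occur. 0 disables it. Counted as part of
#'   equilibration.
#' @return List: `state`, `trajectory`, `rg`, `report`
#'   (an [equilibration_report()]), `link_ok`, `link_before`.
#' @export
run_protocol <- function(network, params = sim_params(), equil_steps = 1e5,
                         prod_steps = 4e5, dump_every = 2000, seed = 1,
                         check_topology = TRUE, soft_steps = 2e4) {
  link_before <- if (check_topology) link_matrix(network) else NULL
  st <- sim_state(network, params, seed = seed)
  if (soft_steps > 0) {
    ## two-stage push-off. Stage 1: very small timestep and a low force
    ## cap, so even deep build-time near-contacts (e.g. a maxicircle pass
    ## grazing a minicircle bead) separate without kicking any bond near
    ## its FENE limit. Stage 2: normal timestep with the cap at
    ## 200 eps/sigma -- far above any bonded/bending drive force, so
    ## strands cannot be pulled through each other, yet bounded.
    ## Both stages run at reduced temperature.
    gentle <- params
    gentle$dt <- params$dt / 5
    gentle$fmax <- 50
    gentle$temperature <- 0.05 * params$temperature
    st <- run_langevin(st, gentle, min(5e3, soft_steps), dump_every = 0,
                       seed = seed + 4L)
    soft <- params
    soft$fmax <- 200
    soft$temperature <- 0.1 * params$temperature
    st <- run_langevin(st, soft, soft_steps, dump_every = 0, seed = seed + 2L)
    equil_steps <- max(0, equil_steps - soft_steps)
  }
  st <- run_langevin(st, params, equil_steps, dump_every = 0, seed = seed)
  st <- run_langevin(st, params, prod_steps, dump_every = dump_every,
                     seed = seed + 1L)
  rg <- vapply(st$trajectory, radius_of_gyration, 1.0)
  report <- equilibration_report(rg)
  link_ok <- NA
  if (check_topology) {
    link_after <- link_matrix(st$network)
    link_ok <- identical(link_before, link_after)
    if (!link_ok)
      stop("topology violation: linking matrix changed during the run")
  }
  list(state = st, trajectory = st$trajectory, rg = rg, report = report,
       link_ok = link_ok, link_before = link_before)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Optimal translation + proper rotation (no reflection) mapping `X` onto
#' `ref`. Degenerate (rank-deficient) configurations fall back to
#' translation-only alignment with a warning.
#'
#' @param X,ref n x 3 coordinate matrices.
#' @return Aligned copy of `X`.
#' @export
kabsch_align <- function(X, ref) {
  stopifnot(nrow(X) == nrow(ref))
  cx <- colMeans(X); cr <- colMeans(ref)
  X0 <- sweep(X, 2, cx); R0 <- sweep(ref, 2, cr)
  H <- t(X0) %*% R0
  sv <- svd(H)
  if (min(sv$d) < 1e-10 * max(sv$d)) {
    warning("degenerate configuration: translation-only alignment")
    return(sweep(X0, 2, cr, "+"))
  }
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  rot <- sv$v %*% D %*% t(sv$u)
  sweep(X0 %*% t(rot), 2, cr, "+")
}

#' Per-frame observables of a trajectory
#'
#' Radius of gyration, per-ring centres of mass, and (optionally) the
#' rigid-body aligned ring COMs: each frame is superposed onto the first
#' by removing translation and rotation (proper rotations only), so that
#' residual ring motion reflects internal network dynamics.
#'
#' @param trajectory List of n x 3 frames (from [run_langevin()] or
#'   [run_protocol()]).
#' @param network The `olympic_network` the frames belong to.
#' @param align Superpose all frames onto frame 1 (default TRUE).
#' @param align_on Ring indices whose beads define the superposition
#'   (default: all minicircles).
#' @param keep_frames Also return the aligned frames themselves (memory
#'   permitting), e.g. for marker analyses on bead subsets.
#' @return List: `rg` (vector), `ring_com` (array frame x ring x 3, raw),
#'   `aligned_com` (same, aligned; NULL if `align = FALSE`),
#'   `aligned_frames` (list or NULL), `ring_class` (character vector).
#' @export
observables <- function(trajectory, network, align = TRUE, align_on = NULL,
                        keep_frames = FALSE) {
  stopifnot(length(trajectory) >= 2)
  len <- ring_lengths(network)
  off <- c(0L, cumsum(len))
  nr <- length(len)
  ring_class <- vapply(network$rings, `[[`, "", "class")
  align_on <- align_on %||% which(ring_class == "mini")
  bead_sel <- unlist(lapply(align_on, function(r) (off[r] + 1):off[r + 1]))
  nf <- length(trajectory)
  ring_com <- array(NA_real_, c(nf, nr, 3))
  aligned_com <- if (align) array(NA_real_, c(nf, nr, 3)) else NULL
  ref <- trajectory[[1]][bead_sel, , drop = FALSE]
  aligned_frames <- if (align && keep_frames) vector("list", nf) else NULL
  rg <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- trajectory[[f]]
    rg[f] <- radius_of_gyration(fr)
    if (align) {
      fr_al <- fr
      cx <- colMeans(fr[bead_sel, , drop = FALSE])
      cr <- colMeans(ref)
      X0 <- sweep(fr[bead_sel, , drop = FALSE], 2, cx)
      H <- t(X0) %*% sweep(ref, 2, cr)
      sv <- svd(H)
      if (min(sv$d) < 1e-10 * max(sv$d)) {
        warning("degenerate frame: translation-only alignment")
        fr_al <- sweep(sweep(fr, 2, cx), 2, cr, "+")
      } else {
        D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
        rot <- sv$v %*% D %*% t(sv$u)
        fr_al <- sweep(sweep(fr, 2, cx) %*% t(rot), 2, cr, "+")
      }
      for (r in seq_len(nr))
        aligned_com[f, r, ] <- colMeans(fr_al[(off[r] + 1):off[r + 1], ,
                                              drop = FALSE])
      if (keep_frames) aligned_frames[[f]] <- fr_al
    }
    for (r in seq_len(nr))
      ring_com[f, r, ] <- colMeans(fr[(off[r] + 1):off[r + 1], , drop = FALSE])
  }
  list(rg = rg, ring_com = ring_com, aligned_com = aligned_com,
       aligned_frames = aligned_frames, ring_class = ring_class)
}

#' 3D ensemble MSD of marker positions over frames
#'
#' Plain MSD (average over all initial times and markers) of a
#' frame x marker x 3 position array, e.g. aligned ring centres of mass.
#'
#' @param coms Array `[frame, marker, 3]`.
#' @param ids Marker indices to include.
#' @param dt Time per frame (any unit).
#' @param max_lag Largest lag in frames.
#' @return An `msd_curve` (lag in the same unit as `dt`).
#' @export
marker_msd <- function(coms, ids, dt = 1, max_lag = NULL) {
  nf <- dim(coms)[1]
  max_lag <- as.integer(max_lag %||% (nf %/% 2))
  ss <- numeric(max_lag); cnt <- numeric(max_lag)
  for (id in ids) {
    xyz <- coms[, id, ]
    for (L in seq_len(max_lag)) {
      d <- xyz[(1 + L):nf, , drop = FALSE] - xyz[1:(nf - L), , drop = FALSE]
      ss[L] <- ss[L] + sum(d^2)
      cnt[L] <- cnt[L] + (nf - L)
    }
  }
  .msd_curve((1:max_lag) * dt, ss / cnt, as.integer(cnt), "marker_msd")
}
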