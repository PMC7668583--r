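#' Desk-scale C-alpha bead force field
#'
#' A minimal coarse-grained model — one bead per residue — whose purpose
#' is to exercise the contact-guided REMD machinery end to end, not to
#' reproduce all-atom thermodynamics. Terms: harmonic virtual bonds
#' (default 0.38 nm), harmonic pseudo-angles, purely repulsive excluded
#' volume (r^-12) for non-contact pairs, an optional structure-based
#' 12-10 well at the reference-contact distances (a weak Go-like term
#' giving the landscape a native funnel), and the sigmoid contact
#' restraints evaluated by their closed form.
#'
#' @param ref Optional reference [structure_model()]; when given, its
#'   native contacts define the Go-like wells at their reference
#'   distances.
#' @param restraints Optional restraint tibble (columns `i`, `j`) to bias
#'   with the sigmoid potential.
#' @param sigmoid A [sigmoid_params()] for the restraints.
#' @param bond_k,bond_r0 Bond stiffness (kJ/mol/nm^2) and length (nm).
#' @param angle_k,angle_theta0 Angle stiffness (kJ/mol/rad^2) and rest
#'   angle (rad).
#' @param ev_sigma,ev_eps Excluded-volume radius (nm) and strength
#'   (kJ/mol).
#' @param native_eps Depth of the Go-like contact well, kJ/mol.
#' @param cutoff,min_sep Native-contact definition used for the Go term.
#' @return A `bead_forcefield` list ready for the integrator.
#' @export
bead_forcefield <- function(ref = NULL, restraints = NULL,
                            sigmoid = sigmoid_params(),
                            bond_k = 8000, bond_r0 = 0.38,
                            angle_k = 20, angle_theta0 = 1.85,
                            ev_sigma = 0.40, ev_eps = 1,
                            native_eps = 3,
                            cutoff = remd_defaults()$contact_cutoff_nm,
                            min_sep = remd_defaults()$min_seq_sep) {
  if (any(c(bond_k, angle_k, ev_eps, native_eps) < 0)) {
    abort("force-field stiffnesses must be non-negative.")
  }
  nat <- if (is.null(ref)) {
    tibble(i = integer(), j = integer(), r_ref = numeric())
  } else {
    native_contacts(ref, cutoff, min_sep)
  }
  res <- if (is.null(restraints)) tibble(i = integer(), j = integer())
         else restraints
  structure(list(
    bond_k = bond_k, bond_r0 = bond_r0,
    angle_k = angle_k, angle_theta0 = angle_theta0,
    ev_sigma = ev_sigma, ev_eps = ev_eps,
    native_eps = native_eps,
    native_pairs = unname(cbind(as.integer(nat$i), as.integer(nat$j))),
    native_r = as.numeric(nat$r_ref),
    restraint_pairs = unname(cbind(as.integer(res$i), as.integer(res$j))),
    sigmoid_A = sigmoid$A, sigmoid_alpha = sigmoid$alpha,
    sigmoid_r0 = sigmoid$r0, sigmoid_k = sigmoid$k
  ), class = "bead_forcefield")
}

ff_as_list <- function(ff) {
  stopifnot(inherits(ff, "bead_forcefield"))
  unclass(ff)
}

#' Potential energy and forces of a bead model
#'
#' @param model A [structure_model()].
#' @param ff A [bead_forcefield()].
#' @return The potential energy (kJ/mol) with the analytic forces
#'   (kJ/mol/nm, one row per bead) attached as attribute `"forces"`.
#' @examples
#' m <- make_folded_fixture(10, "helix", seed = 1)
#' toy_energy(m, bead_forcefield(ref = m))
#' @export
toy_energy <- function(model, ff) {
  model <- as_structure_model(model)
  check_ff_indices(ff, model)
  out <- cpp_energy_forces(coords_matrix(model), ff_as_list(ff))
  structure(out$energy, forces = out$forces)
}

check_ff_indices <- function(ff, model) {
  mx <- suppressWarnings(max(ff$native_pairs, ff$restraint_pairs, 1L))
  if (mx > nrow(model)) {
    abort("force field references residues beyond the model.")
  }
  invisible(ff)
}

#' Langevin dynamics of the bead model
#'
#' BAOAB-split Langevin integration at a fixed temperature. Defaults
#' (dt = 0.01 ps, friction 1/ps, bead mass 110 g/mol) resolve the bond
#' vibration comfortably. Draws come from R's RNG stream, so runs are
#' reproducible under `set.seed()` / the `seed` argument.
#'
#' @param model Starting [structure_model()].
#' @param ff A [bead_forcefield()].
#' @param temperature Bath temperature, K.
#' @param n_steps Number of integration steps.
#' @param dt Time step, ps.
#' @param friction Langevin friction, 1/ps (0 gives plain velocity
#'   Verlet: no thermostat, no noise).
#' @param mass Bead mass, g/mol.
#' @param velocities Optional starting velocity matrix (nm/ps); default
#'   Maxwell-Boltzmann at `temperature`.
#' @param sample_interval Steps between stored frames (0 = store none).
#' @param seed Optional integer seed applied just for this run.
#' @return A `langevin_state` list: final `model`, `velocities`,
#'   `energy`, and (if sampled) a `trajectory` tibble plus per-sample
#'   potential/kinetic energies.
#' @export
langevin_run <- function(model, ff, temperature, n_steps,
                         dt = 0.01, friction = 1, mass = 110,
                         velocities = NULL, sample_interval = 0,
                         seed = NULL) {
  model <- as_structure_model(model)
  check_ff_indices(ff, model)
  n <- nrow(model)
  run1 <- function() {
    v0 <- velocities
    if (is.null(v0)) {
      v0 <- matrix(stats::rnorm(3 * n, sd = sqrt(.kB * temperature / mass)),
                   n, 3)
    }
    cpp_langevin_run(coords_matrix(model), v0, ff_as_list(ff), temperature,
                     dt, friction, mass, as.integer(n_steps),
                     as.integer(sample_interval))
  }
  out <- if (is.null(seed)) run1() else with_seed(seed, run1())
  final <- structure_model(out$coords, res_id = model$res_id,
                           res_name = model$res_name,
                           label = attr(model, "label"))
  traj <- NULL
  if (out$n_samples > 0) {
    steps <- sample_interval * seq_len(out$n_samples)
    frames <- purrr::map(seq_len(out$n_samples), function(s) {
      co <- matrix(out$frames[((s - 1) * n * 3 + 1):(s * n * 3)],
                   ncol = 3, byrow = TRUE)
      structure_model(co, res_id = model$res_id, res_name = model$res_name)
    })
    traj <- trajectory_from_frames(frames, times = steps * dt / 1000,
                                   temperature = temperature)
  }
  structure(list(model = final, velocities = out$velocities,
                 energy = out$energy, trajectory = traj,
                 sampled_energy = out$sampled_energy[seq_len(out$n_samples)],
                 sampled_kinetic = out$sampled_kinetic[seq_len(out$n_samples)],
                 temperature = temperature),
            class = "langevin_state")
}

#' @rdname langevin_run
#' @param state A `langevin_state` (or a [structure_model()] for the
#'   first step).
#' @export
langevin_step <- function(state, ff, temperature, dt = 0.01, friction = 1,
                          mass = 110) {
  if (is_structure_model(state)) {
    return(langevin_run(state, ff, temperature, n_steps = 1, dt = dt,
                        friction = friction, mass = mass))
  }
  langevin_run(state$model, ff, temperature, n_steps = 1, dt = dt,
               friction = friction, mass = mass,
               velocities = state$velocities)
}

#' Run toy replica-exchange molecular dynamics
#'
#' Interleaves blocks of Langevin dynamics with parity-alternating
#' Metropolis exchange sweeps between adjacent temperature slots. All
#' replicas start from the same configuration (typically an unfolded
#' fixture). On an accepted swap the two configurations migrate between
#' temperature slots and velocities are rescaled by sqrt(T_new / T_old),
#' so each temperature slot yields a demultiplexed constant-temperature
#' trajectory — the object ensemble statistics are computed on.
#'
#' @param start Starting [structure_model()] shared by all replicas.
#' @param ff A [bead_forcefield()].
#' @param ladder A `temperature_ladder` from [build_ladder()].
#' @param n_steps Total Langevin steps per replica.
#' @param exchange_interval Steps between exchange sweeps (default 1000).
#' @param sample_interval Steps between stored frames (default
#'   `exchange_interval`).
#' @param dt,friction,mass Integrator settings, as [langevin_run()].
#' @param seed Integer master seed; the whole run (velocities, noise,
#'   exchange draws) is reproducible given it.
#' @return A `remd_run` list: `frames` (long tibble: `slot`,
#'   `temperature`, `frame`, `time_ns`, `res_id`, `x`, `y`, `z`),
#'   `exchanges` (one row per attempted swap with energies, Delta,
#'   probability, draw, outcome), `ladder`, `final` states, and the run
#'   settings.
#' @export
run_remd <- function(start, ff, ladder, n_steps,
                     exchange_interval = remd_defaults()$exchange_interval,
                     sample_interval = exchange_interval,
                     dt = 0.01, friction = 1, mass = 110, seed = 1) {
  start <- as_structure_model(start)
  check_ff_indices(ff, start)
  temps <- ladder$temperature
  n_slots <- length(temps)
  n_rounds <- max(1L, as.integer(ceiling(n_steps / exchange_interval)))
  n <- nrow(start)

  with_seed(seed, {
    coords <- purrr::map(seq_len(n_slots), ~coords_matrix(start))
    vels <- purrr::map(temps, function(tt) {
      matrix(stats::rnorm(3 * n, sd = sqrt(.kB * tt / mass)), n, 3)
    })
    energies <- rep(NA_real_, n_slots)
    frame_rows <- vector("list", n_rounds)
    exch_rows <- vector("list", n_rounds)
    fl <- ff_as_list(ff)

    for (round in seq_len(n_rounds)) {
      block <- min(exchange_interval, n_steps - (round - 1) * exchange_interval)
      slot_frames <- vector("list", n_slots)
      for (s in seq_len(n_slots)) {
        out <- cpp_langevin_run(coords[[s]], vels[[s]], fl, temps[s], dt,
                                friction, mass, as.integer(block),
                                as.integer(sample_interval))
        coords[[s]] <- out$coords
        vels[[s]] <- out$velocities
        energies[s] <- out$energy
        if (out$n_samples > 0) {
          ns <- out$n_samples
          step0 <- (round - 1) * exchange_interval
          slot_frames[[s]] <- tibble(
            slot = s - 1L, temperature = temps[s],
            step = step0 + sample_interval * rep(seq_len(ns), each = n),
            res_id = rep(start$res_id, ns),
            x = out$frames[3 * (seq_len(ns * n) - 1) + 1],
            y = out$frames[3 * (seq_len(ns * n) - 1) + 2],
            z = out$frames[3 * (seq_len(ns * n) - 1) + 3]
          )
        }
      }
      parity <- if (round %% 2 == 1) "even" else "odd"
      # a sweep happens only after a complete exchange block
      dec <- if (block == exchange_interval) {
        attempt_exchanges(energies, temps, parity)
      } else {
        attempt_exchanges(numeric(0), numeric(0), parity)
      }
      if (nrow(dec) > 0) {
        dec$round <- round
        dec$e_lo <- energies[dec$slot_lo + 1]
        dec$e_hi <- energies[dec$slot_hi + 1]
        for (rw in which(dec$accepted)) {
          a <- dec$slot_lo[rw] + 1L
          b <- dec$slot_hi[rw] + 1L
          tmp <- coords[[a]]; coords[[a]] <- coords[[b]]; coords[[b]] <- tmp
          # configurations migrate; velocities rescale to the new bath
          va <- vels[[a]]; vb <- vels[[b]]
          vels[[a]] <- vb * sqrt(temps[a] / temps[b])
          vels[[b]] <- va * sqrt(temps[b] / temps[a])
          ea <- energies[a]; energies[a] <- energies[b]; energies[b] <- ea
        }
      }
      exch_rows[[round]] <- dec
      frame_rows[[round]] <- dplyr::bind_rows(slot_frames)
    }

    frames <- dplyr::bind_rows(frame_rows)
    if (nrow(frames) > 0) {
      frames <- dplyr::mutate(frames,
        frame = match(.data$step, sort(unique(.data$step))),
        time_ns = .data$step * dt / 1000, .after = "temperature")
    }
    structure(list(
      frames = frames,
      exchanges = dplyr::bind_rows(exch_rows),
      ladder = ladder,
      final = list(coords = coords, velocities = vels, energies = energies),
      settings = list(n_steps = n_steps, exchange_interval = exchange_interval,
                      sample_interval = sample_interval, dt = dt,
                      friction = friction, mass = mass, seed = seed),
      start = start
    ), class = "remd_run")
  })
}

#' Extract one temperature slot of an REMD run as a trajectory
#'
#' @param run A `remd_run`.
#' @param slot 0-based temperature slot (0 = lowest temperature).
#' @return A `trajectory_ensemble` tibble.
#' @export
slot_trajectory <- function(run, slot = 0) {
  fr <- run$frames[run$frames$slot == slot, , drop = FALSE]
  if (nrow(fr) == 0) abort(sprintf("no frames stored for slot %d.", slot))
  out <- tibble(frame = fr$frame, time_ns = fr$time_ns, res_id = fr$res_id,
                res_name = "ALA", x = fr$x, y = fr$y, z = fr$z)
  new_trajectory(out, temperature = fr$temperature[1])
}

#' @export
print.remd_run <- function(x, ...) {
  cat(sprintf("<remd_run> %d replicas, %d steps, exchange every %d steps\n",
              nrow(x$ladder), x$settings$n_steps,
              x$settings$exchange_interval))
  if (nrow(x$exchanges) > 0) {
    cat(sprintf("  exchange acceptance: %.1f%% over %d attempts\n",
                100 * mean(x$exchanges$accepted), nrow(x$exchanges)))
  }
  invisible(x)
}
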