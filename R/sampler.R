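# Composite likelihood/contact energy over sequence space and
# replica-exchange Metropolis MCMC.

#' Composite sequence energy model
#'
#' Energy of a sequence is
#' `-likelihood_weight * Lbar(seq) - contact_weight * C(seq)`, where `Lbar`
#' is the mean per-residue log-likelihood from the likelihood adapter and
#' `C` the contact density (contacts per residue) from the contact
#' adapter. Lower energy means a more plausible, more contact-rich
#' sequence. Both adapters are expected to return O(1)-per-residue values
#' so the default unit weights put the terms on comparable scales.
#'
#' @param likelihood_scorer Function `sequence -> numeric`.
#' @param contact_scorer Function `sequence -> numeric`.
#' @param likelihood_weight,contact_weight Non-negative weights.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(likelihood_scorer, contact_scorer,
                         likelihood_weight = 1, contact_weight = 1) {
  stopifnot(is.function(likelihood_scorer), is.function(contact_scorer),
            likelihood_weight >= 0, contact_weight >= 0)
  structure(list(likelihood_scorer = likelihood_scorer,
                 contact_scorer = contact_scorer,
                 likelihood_weight = likelihood_weight,
                 contact_weight = contact_weight),
            class = "energy_model")
}

#' Evaluate the composite energy of a sequence
#'
#' @param seq A [protein_sequence] or character scalar.
#' @param model An [energy_model].
#' @return Finite numeric scalar; lower is better.
#' @export
composite_energy <- function(seq, model) {
  stopifnot(inherits(model, "energy_model"))
  id <- if (inherits(seq, "protein_sequence")) seq$id else "<sequence>"
  res <- if (inherits(seq, "protein_sequence")) seq$residues else seq
  lik <- 0
  con <- 0
  if (model$likelihood_weight > 0) {
    lik <- tryCatch(model$likelihood_scorer(res), error = function(e) {
      stop(sprintf("likelihood scorer failed for %s: %s", id, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (model$contact_weight > 0) {
    con <- tryCatch(model$contact_scorer(res), error = function(e) {
      stop(sprintf("contact scorer failed for %s: %s", id, conditionMessage(e)),
           call. = FALSE)
    })
  }
  e <- -model$likelihood_weight * lik - model$contact_weight * con
  if (!is.finite(e)) stop(sprintf("non-finite energy for %s", id))
  e
}

#' Replica-exchange sampler configuration
#'
#' @param n_replicas Number of replicas (>= 1).
#' @param temperatures Strictly ascending positive temperatures, one per
#'   replica; default is a geometric ladder spanning \[0.2, 2\], matched
#'   to the O(0.1) per-mutation energy scale of the composite energy so
#'   the cold end genuinely descends.
#' @param steps_per_replica Metropolis steps per replica.
#' @param swap_interval Steps between neighbour-swap attempts.
#' @param seed Integer seed.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_replicas = 4, temperatures = NULL,
                           steps_per_replica = 500, swap_interval = 10,
                           seed = 1) {
  if (is.null(temperatures)) {
    temperatures <- if (n_replicas == 1) 0.2 else
      exp(seq(log(0.2), log(2), length.out = n_replicas))
  }
  stopifnot(n_replicas >= 1, length(temperatures) == n_replicas,
            all(temperatures > 0), steps_per_replica >= 0, swap_interval >= 1)
  if (n_replicas > 1 && any(diff(temperatures) <= 0)) {
    stop("temperatures must be strictly ascending")
  }
  structure(list(n_replicas = as.integer(n_replicas),
                 temperatures = as.numeric(temperatures),
                 steps_per_replica = as.integer(steps_per_replica),
                 swap_interval = as.integer(swap_interval),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' One Metropolis step in sequence space
#'
#' Proposes a single-site mutation (uniform position, uniform over the
#' other letters of the alphabet) and accepts with probability
#' `min(1, exp(-dE / T))`. Uses the current R random number stream; seed
#' management belongs to the caller.
#'
#' @param state List with `sequence` (character) and `energy`.
#' @param temperature Positive temperature.
#' @param model An [energy_model].
#' @param alphabet Residue alphabet (default the 20 canonical letters).
#' @return List with `sequence`, `energy` and `accepted`.
#' @export
metropolis_step <- function(state, temperature, model,
                            alphabet = AA_ALPHABET) {
  stopifnot(temperature > 0)
  letters <- strsplit(state$sequence, "")[[1]]
  pos <- sample.int(length(letters), 1)
  alt <- alphabet[alphabet != letters[pos]]
  letters[pos] <- alt[sample.int(length(alt), 1)]
  cand <- paste(letters, collapse = "")
  e_new <- composite_energy(cand, model)
  d_e <- e_new - state$energy
  accepted <- d_e < 0 || runif(1) < exp(-d_e / temperature)
  if (accepted) list(sequence = cand, energy = e_new, accepted = TRUE)
  else list(sequence = state$sequence, energy = state$energy, accepted = FALSE)
}

#' Replica swap acceptance probability
#'
#' `min(1, exp((1/Ti - 1/Tj) * (Ei - Ej)))` for a colder replica `i`
#' (`Ti < Tj`) exchanging states with a hotter replica `j`.
#'
#' @param e_i,e_j Replica energies.
#' @param t_i,t_j Replica temperatures with `t_i < t_j`, both positive.
#' @return Probability in \[0, 1\].
#' @export
replica_swap_probability <- function(e_i, e_j, t_i, t_j) {
  if (t_i <= 0 || t_j <= 0) stop("temperatures must be positive")
  if (t_i >= t_j) stop("expected t_i < t_j")
  min(1, exp((1 / t_i - 1 / t_j) * (e_i - e_j)))
}

#' Run replica-exchange MCMC over sequence space
#'
#' Parallel Metropolis chains at the configured temperature ladder, with
#' deterministic alternating even/odd neighbour-pair swap attempts every
#' `swap_interval` steps. Fully reproducible for a fixed seed and fixed
#' scorers; with a single replica it reduces exactly to plain Metropolis.
#'
#' @param cfg A [sampler_config].
#' @param model An [energy_model].
#' @param start Starting sequence (character or [protein_sequence]);
#'   `NULL` draws a uniform random sequence of length `length`.
#' @param length Length of the random start when `start` is `NULL`.
#' @param alphabet Residue alphabet.
#' @param record `"full"` keeps per-step sequences; `"energies"` keeps only
#'   the energy traces (cheaper for long runs).
#' @return An object of class `remc_trajectory`: `replicas` (list of
#'   data.frames `step`, `sequence`, `energy`), `swaps` (data.frame `step`,
#'   `replica_i`, `replica_j`, `accepted`), `best` (list `sequence`,
#'   `energy`) and `config`.
#' @export
run_remc <- function(cfg, model, start = NULL, length = 40,
                     alphabet = AA_ALPHABET, record = c("full", "energies")) {
  stopifnot(inherits(cfg, "sampler_config"), inherits(model, "energy_model"))
  record <- match.arg(record)
  with_local_seed(cfg$seed, {
    if (is.null(start)) {
      start <- paste(sample(alphabet, length, replace = TRUE), collapse = "")
    } else if (inherits(start, "protein_sequence")) start <- start$residues
    n_rep <- cfg$n_replicas
    e0 <- composite_energy(start, model)
    states <- replicate(n_rep, list(sequence = start, energy = e0),
                        simplify = FALSE)
    n_steps <- cfg$steps_per_replica
    energies <- matrix(NA_real_, nrow = n_steps, ncol = n_rep)
    seqs <- if (record == "full") {
      matrix(NA_character_, nrow = n_steps, ncol = n_rep)
    } else NULL
    swaps <- list()
    best <- list(sequence = start, energy = e0)
    swap_event <- 0L
    for (step in seq_len(n_steps)) {
      for (r in seq_len(n_rep)) {
        states[[r]] <- metropolis_step(states[[r]], cfg$temperatures[r],
                                       model, alphabet)
        energies[step, r] <- states[[r]]$energy
        if (!is.null(seqs)) seqs[step, r] <- states[[r]]$sequence
        if (states[[r]]$energy < best$energy) {
          best <- list(sequence = states[[r]]$sequence,
                       energy = states[[r]]$energy)
        }
      }
      if (n_rep > 1 && step %% cfg$swap_interval == 0) {
        swap_event <- swap_event + 1L
        first <- if (swap_event %% 2L == 1L) 1L else 2L
        i <- first
        while (i + 1L <= n_rep) {
          p <- replica_swap_probability(states[[i]]$energy,
                                        states[[i + 1L]]$energy,
                                        cfg$temperatures[i],
                                        cfg$temperatures[i + 1L])
          acc <- runif(1) < p
          if (acc) {
            tmp <- states[[i]]
            states[[i]] <- states[[i + 1L]]
            states[[i + 1L]] <- tmp
          }
          swaps[[length(swaps) + 1L]] <-
            data.frame(step = step, replica_i = i, replica_j = i + 1L,
                       accepted = acc)
          i <- i + 2L
        }
      }
    }
    replicas <- lapply(seq_len(n_rep), function(r) {
      df <- data.frame(step = seq_len(n_steps), energy = energies[, r])
      if (!is.null(seqs)) df$sequence <- seqs[, r]
      df
    })
    structure(list(replicas = replicas,
                   swaps = if (length(swaps)) do.call(rbind, swaps) else
                     data.frame(step = integer(), replica_i = integer(),
                                replica_j = integer(), accepted = logical()),
                   best = best, config = cfg),
              class = "remc_trajectory")
  })
}

#' Export a trajectory as JSON lines
#'
#' One JSON object per recorded state plus one per swap attempt.
#'
#' @param traj An `remc_trajectory`.
#' @param path Output file.
#' @export
write_trajectory_jsonl <- function(traj, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in seq_along(traj$replicas)) {
    df <- traj$replicas[[r]]
    for (k in seq_len(nrow(df))) {
      rec <- list(type = "state", replica = r, step = df$step[k],
                  energy = df$energy[k])
      if (!is.null(df$sequence)) rec$sequence <- df$sequence[k]
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  if (nrow(traj$swaps)) {
    for (k in seq_len(nrow(traj$swaps))) {
      writeLines(jsonlite::toJSON(list(type = "swap",
                                       step = traj$swaps$step[k],
                                       replica_i = traj$swaps$replica_i[k],
                                       replica_j = traj$swaps$replica_j[k],
                                       accepted = traj$swaps$accepted[k]),
                                  auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}
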