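# Fragment library generation and the fold-recombining genetic algorithm
# with burial-proportional stochastic selection.

#' Genetic algorithm configuration
#'
#' Full-scale defaults: population 100, 20 offspring per epoch, 200
#' epochs, compactness threshold 0.5, 40-residue founder fragments from
#' an 800-member library. Recombination is a mixture of
#' interior splice and end-to-end fusion; offspring are capped at
#' `max_child_length` residues.
#'
#' @param population_size Constant population target.
#' @param offspring_per_epoch Offspring generated per epoch.
#' @param epochs Number of epochs.
#' @param mutation_rate Per-position substitution probability.
#' @param refine_steps Metropolis refinement steps per offspring.
#' @param p_splice Probability of the splice operator (else fusion).
#' @param max_child_length Maximum offspring length.
#' @param min_child_length Minimum offspring length.
#' @param compactness_threshold Burial fraction above which a candidate
#'   counts as compact.
#' @param tm_threshold TM-score threshold for CATH assignment/clustering.
#' @param fragment_length Founder fragment length.
#' @param library_size Founder library size.
#' @param refine_temperature Temperature for offspring refinement (the
#'   coldest rung of the default ladder).
#' @param sasa_points Sphere points for pipeline burial calls.
#' @param seed Integer seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100, offspring_per_epoch = 20,
                      epochs = 200, mutation_rate = 0.02, refine_steps = 100,
                      p_splice = 0.5, max_child_length = 250,
                      compactness_threshold = 0.5, tm_threshold = 0.5,
                      fragment_length = 40, library_size = 800,
                      refine_temperature = 0.2, sasa_points = 240,
                      min_child_length = 10, seed = 1) {
  stopifnot(population_size >= 2, offspring_per_epoch >= 1, epochs >= 0,
            mutation_rate >= 0, mutation_rate <= 1, refine_steps >= 0,
            p_splice >= 0, p_splice <= 1, max_child_length >= 2)
  structure(list(population_size = as.integer(population_size),
                 offspring_per_epoch = as.integer(offspring_per_epoch),
                 epochs = as.integer(epochs),
                 mutation_rate = mutation_rate,
                 refine_steps = as.integer(refine_steps),
                 p_splice = p_splice,
                 max_child_length = as.integer(max_child_length),
                 compactness_threshold = compactness_threshold,
                 tm_threshold = tm_threshold,
                 fragment_length = as.integer(fragment_length),
                 library_size = as.integer(library_size),
                 min_child_length = as.integer(min_child_length),
                 refine_temperature = refine_temperature,
                 sasa_points = as.integer(sasa_points),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Construct a population individual
#'
#' @param id Identifier.
#' @param sequence A [protein_sequence].
#' @param structure A [protein_structure].
#' @param burial Burial fraction value (numeric) or [burial_fraction()]
#'   result.
#' @param parents Character vector of parent ids (empty for founders).
#' @param operator Operator that created the individual (`"founder"`,
#'   `"splice"`, `"fusion"`).
#' @param epoch Epoch of creation (0 for founders).
#' @return An object of class `individual`.
#' @export
new_individual <- function(id, sequence, structure, burial,
                           parents = character(), operator = "founder",
                           epoch = 0L) {
  if (inherits(burial, "burial_fraction")) burial <- burial$value
  structure(list(id = id, sequence = sequence, structure = structure,
                 burial = burial,
                 lineage = list(parents = parents, operator = operator,
                                epoch = as.integer(epoch)),
                 epoch = as.integer(epoch)),
            class = "individual")
}

#' Generate the founder fragment library
#'
#' Runs `n` independently seeded replica-exchange MCMC searches from
#' random starts; the best state of each run becomes a fragment. Duplicate
#' sequences are regenerated (up to 5 extra attempts each); structure
#' predictor failures skip the fragment with a warning and another run is
#' attempted until `n` fragments are collected or the retry budget is
#' exhausted.
#'
#' @param n Library size.
#' @param length Fragment length.
#' @param sampler_cfg A [sampler_config] (its seed anchors the per-run
#'   seeds).
#' @param model An [energy_model].
#' @param backends A backend suite providing `structure_predictor`.
#' @param sasa_points Sphere points for burial.
#' @return List of `individual` founders (operator `"founder"`).
#' @export
generate_fragment_library <- function(n = 800, length = 40, sampler_cfg,
                                      model, backends, sasa_points = 240) {
  stopifnot(n >= 1)
  frags <- list()
  seen <- character()
  attempt <- 0L
  budget <- 5L * n + 25L
  while (length(frags) < n) {
    attempt <- attempt + 1L
    if (attempt > budget) {
      stop("fragment library retry budget exhausted at ", length(frags),
           " unique fragments")
    }
    cfg_i <- sampler_cfg
    cfg_i$seed <- sampler_cfg$seed + attempt
    traj <- run_remc(cfg_i, model, length = length, record = "energies")
    seqchr <- traj$best$sequence
    if (seqchr %in% seen) next
    id <- sprintf("frag%04d", length(frags) + 1L)
    ps <- protein_sequence(id, seqchr)
    st <- tryCatch(backends$structure_predictor(ps), error = function(e) {
      warning(sprintf("structure prediction failed for %s: %s", id,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(st)) next
    b <- burial_fraction(st, n_sphere_points = sasa_points)
    seen <- c(seen, seqchr)
    frags[[length(frags) + 1L]] <- new_individual(id, ps, st, b,
                                                  operator = "founder")
    frags[[length(frags)]]$origin <- cfg_i$seed
  }
  frags
}

#' Recombine two parent sequences
#'
#' With probability `p_splice`, an interior splice
#' `a[1..x] + b[y..Lb]` with `x in [1, La-1]`, `y in [2, Lb]`; otherwise an
#' end-to-end fusion `a + b`. Children outside `[min_length, max_length]`
#' are resampled (after 100 attempts a constrained splice is forced).
#' Uses the current R random number stream.
#'
#' @param a,b Parent sequences ([protein_sequence] or character).
#' @param p_splice Probability of the splice operator (else fusion).
#' @param max_length Maximum child length.
#' @param min_length Minimum child length (scorers need at least 3
#'   residues; the GA default keeps children at miniprotein scale).
#' @return List with `sequence` (character) and `operator`.
#' @export
recombine <- function(a, b, p_splice = 0.5, max_length = 250,
                      min_length = 3) {
  sa <- if (inherits(a, "protein_sequence")) a$residues else a
  sb <- if (inherits(b, "protein_sequence")) b$residues else b
  la <- nchar(sa)
  lb <- nchar(sb)
  stopifnot(la >= 2, lb >= 2)
  for (try in seq_len(100)) {
    if (runif(1) < p_splice) {
      x <- sample.int(la - 1L, 1)
      y <- sample(2:lb, 1)
      child <- paste0(substr(sa, 1, x), substr(sb, y, lb))
      op <- "splice"
    } else {
      child <- paste0(sa, sb)
      op <- "fusion"
    }
    if (nchar(child) <= max_length && nchar(child) >= min_length) {
      return(list(sequence = child, operator = op))
    }
  }
  # force a splice that fits
  x <- sample.int(min(la - 1L, max_length - 1L), 1)
  y <- min(max(2L, lb - (max_length - x) + 1L),
           max(2L, lb - (min_length - x) + 1L))
  list(sequence = paste0(substr(sa, 1, x), substr(sb, y, lb)),
       operator = "splice")
}

#' Mutate a sequence
#'
#' Each position is independently substituted with probability `rate`; a
#' substituted position always receives a different letter.
#'
#' @param residues Character sequence.
#' @param rate Per-position substitution probability in \[0, 1\].
#' @param alphabet Residue alphabet.
#' @return Mutated character sequence.
#' @export
mutate_sequence <- function(residues, rate, alphabet = AA_ALPHABET) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(residues)
  letters <- strsplit(residues, "")[[1]]
  hit <- runif(length(letters)) < rate
  for (i in which(hit)) {
    alt <- alphabet[alphabet != letters[i]]
    letters[i] <- alt[sample.int(length(alt), 1)]
  }
  paste(letters, collapse = "")
}

#' Refine a sequence by single-temperature Metropolis
#'
#' Runs `steps` Metropolis steps over the same energy landscape as the
#' fragment sampler at the coldest ladder temperature and returns the
#' final state (not the best-visited one).
#'
#' @param residues Character sequence.
#' @param steps Number of steps (>= 0).
#' @param model An [energy_model].
#' @param temperature Refinement temperature.
#' @return Refined character sequence.
#' @export
refine <- function(residues, steps, model, temperature = 0.2) {
  stopifnot(steps >= 0)
  if (steps == 0) return(residues)
  state <- list(sequence = residues, energy = composite_energy(residues, model))
  for (k in seq_len(steps)) {
    state <- metropolis_step(state, temperature, model)
  }
  state$sequence
}

#' Burial-proportional stochastic selection
#'
#' Weighted sampling without replacement of `target` survivors with
#' weight `burial + eps`; the small floor keeps zero-burial individuals
#' selectable. Pools at or below the target are returned unchanged.
#'
#' @param pool List of `individual` objects.
#' @param target Number of survivors.
#' @param eps Weight floor.
#' @return List of surviving individuals (in pool order).
#' @export
stochastic_select <- function(pool, target = 100, eps = 1e-6) {
  if (length(pool) <= target) return(pool)
  w <- vapply(pool, function(x) x$burial, numeric(1)) + eps
  stopifnot(all(w > 0))
  idx <- sample.int(length(pool), target, replace = FALSE, prob = w)
  pool[sort(idx)]
}

make_offspring_id <- function(epoch, existing) {
  repeat {
    id <- sprintf("%06X_R%d", sample.int(16^6, 1) - 1L, epoch)
    if (!(id %in% existing)) return(id)
  }
}

#' Run the fold-recombining genetic algorithm
#'
#' Each epoch produces `offspring_per_epoch` children (two parents chosen
#' uniformly without replacement; recombine, mutate, Metropolis-refine,
#' predict structure, score burial), extends the pool, and applies
#' burial-proportional stochastic selection back to the constant
#' population size. Every individual is annotated against the reference
#' library through the search-engine adapter; putative novel folds are
#' compact (burial above threshold) and CATH-unassignable candidates,
#' deduplicated by greedy TM-threshold cluster representatives.
#'
#' @param cfg A [ga_config].
#' @param backends A backend suite (see [surrogate_backends()]).
#' @param library Optional founder library from
#'   [generate_fragment_library()]; generated at `cfg$library_size` when
#'   `NULL`.
#' @param model Optional [energy_model]; default combines the suite's
#'   likelihood and contact scorers at unit weights.
#' @param logger Optional [run_logger()]; epoch records are logged as
#'   `"epoch"` events.
#' @param annotate When `FALSE`, skip structure search, novelty calls and
#'   the cumulative census (the records then carry only `epoch` and
#'   `mean_burial`); useful for compactness-trend studies where the
#'   reference library plays no role.
#' @return An object of class `ga_run`: `records` (one row per epoch:
#'   `epoch`, `mean_burial`, `cumulative_unique_cath`, `cumulative_novel`,
#'   `n_new_novel`), `population`, `archive`, `calls` (per-individual
#'   novelty calls) and `config`.
#' @export
run_ga <- function(cfg, backends, library = NULL, model = NULL, logger = NULL,
                   annotate = TRUE) {
  stopifnot(inherits(cfg, "ga_config"))
  if (is.null(model)) {
    model <- energy_model(backends$likelihood_scorer, backends$contact_scorer)
  }
  if (is.null(library)) {
    library <- generate_fragment_library(cfg$library_size, cfg$fragment_length,
                                         sampler_config(seed = cfg$seed),
                                         model, backends,
                                         sasa_points = cfg$sasa_points)
  }
  stopifnot(length(library) >= cfg$population_size)
  with_local_seed(cfg$seed, {
    population <- library[sort(sample.int(length(library), cfg$population_size))]
    archive <- population
    names(archive) <- vapply(population, `[[`, character(1), "id")
    calls <- list()
    if (annotate) {
      calls <- lapply(population, function(ind) {
        novelty_call(ind$burial, backends$search_engine(ind$structure),
                     compactness_threshold = cfg$compactness_threshold,
                     tm_threshold = cfg$tm_threshold,
                     candidate_id = ind$id)
      })
      names(calls) <- names(archive)
    }
    records <- vector("list", cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      offspring <- list()
      for (k in seq_len(cfg$offspring_per_epoch)) {
        parents <- population[sample.int(length(population), 2)]
        rec <- recombine(parents[[1]]$sequence, parents[[2]]$sequence,
                         p_splice = cfg$p_splice,
                         max_length = cfg$max_child_length,
                         min_length = cfg$min_child_length)
        seqchr <- mutate_sequence(rec$sequence, cfg$mutation_rate)
        seqchr <- refine(seqchr, cfg$refine_steps, model,
                         temperature = cfg$refine_temperature)
        id <- make_offspring_id(epoch, names(archive))
        ps <- protein_sequence(id, seqchr)
        st <- tryCatch(backends$structure_predictor(ps), error = function(e) {
          warning(sprintf("dropping offspring %s: %s", id, conditionMessage(e)))
          NULL
        })
        if (is.null(st)) next
        b <- burial_fraction(st, n_sphere_points = cfg$sasa_points)
        ind <- new_individual(id, ps, st, b,
                              parents = c(parents[[1]]$id, parents[[2]]$id),
                              operator = rec$operator, epoch = epoch)
        offspring[[length(offspring) + 1L]] <- ind
        archive[[id]] <- ind
        if (annotate) {
          calls[[id]] <- novelty_call(ind$burial,
                                      backends$search_engine(ind$structure),
                                      compactness_threshold = cfg$compactness_threshold,
                                      tm_threshold = cfg$tm_threshold,
                                      candidate_id = id)
        }
      }
      population <- stochastic_select(c(population, offspring),
                                      target = cfg$population_size)
      records[[epoch]] <- data.frame(
        epoch = epoch,
        mean_burial = mean(vapply(population, `[[`, numeric(1), "burial")))
    }
    records <- if (cfg$epochs > 0) do.call(rbind, records) else
      data.frame(epoch = integer(), mean_burial = numeric())
    census <- NULL
    if (annotate) {
      census <- cumulative_census(archive, calls,
                                  pairwise_tm = archive_pairwise_tm(archive),
                                  tm_threshold = cfg$tm_threshold,
                                  epochs = cfg$epochs)
      if (cfg$epochs > 0) {
        records <- merge(records, census$per_epoch, by = "epoch")
      } else {
        records$cumulative_unique_cath <- integer(0)
        records$cumulative_novel <- integer(0)
        records$n_new_novel <- integer(0)
      }
    }
    if (!is.null(logger)) {
      for (i in seq_len(nrow(records))) {
        log_event(logger, "epoch", as.list(records[i, ]))
      }
    }
    structure(list(records = records, population = population,
                   archive = archive, calls = calls,
                   novel_representatives = if (is.null(census)) character() else
                     census$novel_representatives,
                   config = cfg),
              class = "ga_run")
  })
}

# pairwise TM between archive members via the sliding-window convention
# (d0 from the longer chain), memoised per unordered pair; the window
# stride is chosen so at most ~5 windows are scored per pair, which is
# plenty for the >= 0.5 absorb-or-found decision
archive_pairwise_tm <- function(archive) {
  cache <- new.env(parent = emptyenv())
  function(id1, id2) {
    key <- paste(sort(c(id1, id2)), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    a <- ca_coords(archive[[id1]]$structure)
    b <- ca_coords(archive[[id2]]$structure)
    stride <- max(1L, ceiling((abs(nrow(a) - nrow(b)) + 1L) / 5L))
    tm <- sliding_window_tm(a, b, stride = stride, stop_at = 0.5)
    cache[[key]] <- tm
    tm
  }
}

#' Cumulative fold census over an archive
#'
#' Per-epoch cumulative counts of unique assigned CATH labels and of
#' putative novel folds. Novelty requires compactness and
#' non-assignability (the `novel` flag of the call); novel candidates are
#' deduplicated incrementally: within each epoch candidates are taken in
#' order of descending burial (ties lexicographic id) and absorbed into an
#' existing representative when their pairwise TM reaches the threshold,
#' otherwise founding a new representative. Counters are non-decreasing
#' by construction.
#'
#' @param archive Named list of `individual` objects (names = ids).
#' @param calls Named list of novelty calls aligned to `archive`.
#' @param pairwise_tm Function `(id1, id2) -> numeric` TM-score.
#' @param tm_threshold Clustering threshold.
#' @param epochs Number of epochs covered (defaults to the archive
#'   maximum).
#' @return List with `per_epoch` (data.frame `epoch`,
#'   `cumulative_unique_cath`, `cumulative_novel`, `n_new_novel`) and
#'   `novel_representatives` (character ids).
#' @export
cumulative_census <- function(archive, calls, pairwise_tm,
                              tm_threshold = 0.5, epochs = NULL) {
  ids <- names(archive)
  ep <- vapply(archive, `[[`, integer(1), "epoch")
  if (is.null(epochs)) epochs <- if (length(ep)) max(ep) else 0L
  seen_labels <- character()
  reps <- character()
  rows <- vector("list", epochs)
  # epoch 0 founders contribute to the baseline before epoch 1
  for (e in 0:epochs) {
    members <- ids[ep == e]
    lab <- vapply(members, function(id) {
      x <- calls[[id]]$assigned_label
      if (is.null(x)) NA_character_ else x
    }, character(1))
    seen_labels <- union(seen_labels, lab[!is.na(lab)])
    novel_ids <- members[vapply(members, function(id) isTRUE(calls[[id]]$novel),
                                logical(1))]
    if (length(novel_ids)) {
      bur <- vapply(novel_ids, function(id) archive[[id]]$burial, numeric(1))
      novel_ids <- novel_ids[order(-bur, novel_ids)]
      for (id in novel_ids) {
        absorbed <- FALSE
        for (r in reps) {
          if (pairwise_tm(id, r) >= tm_threshold) { absorbed <- TRUE; break }
        }
        if (!absorbed) reps <- c(reps, id)
      }
    }
    if (e >= 1) {
      rows[[e]] <- data.frame(epoch = e,
                              cumulative_unique_cath = length(seen_labels),
                              cumulative_novel = length(reps),
                              n_new_novel = length(novel_ids))
    }
  }
  per_epoch <- if (epochs > 0) do.call(rbind, rows) else
    data.frame(epoch = integer(), cumulative_unique_cath = integer(),
               cumulative_novel = integer(), n_new_novel = integer())
  list(per_epoch = per_epoch, novel_representatives = reps)
}
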