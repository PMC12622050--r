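# Fragment library, recombination operators, selection, and the GA loop.

small_ga_world <- local({
  env <- new.env(parent = emptyenv())
  function() {
    if (is.null(env$lib)) {
      f <- nf_fixtures()
      env$lib <- generate_fragment_library(
        14, 40, sampler_config(n_replicas = 2, steps_per_replica = 30, seed = 3),
        f$model, f$backends)
    }
    env$lib
  }
})

test_that("fragment library has the requested size with unique sequences", {
  f <- nf_fixtures()
  one <- generate_fragment_library(1, 40,
                                   sampler_config(n_replicas = 1,
                                                  steps_per_replica = 10,
                                                  seed = 8),
                                   f$model, f$backends)
  expect_length(one, 1)
  lib <- small_ga_world()
  expect_length(lib, 14)
  seqs <- vapply(lib, function(x) x$sequence$residues, character(1))
  expect_equal(anyDuplicated(seqs), 0)
  expect_true(all(nchar(seqs) == 40))
  expect_true(all(vapply(lib, function(x) x$burial >= 0 && x$burial <= 1,
                         logical(1))))
})

test_that("recombination respects operator contracts and provenance", {
  a <- paste(rep("A", 40), collapse = "")
  v <- paste(rep("V", 40), collapse = "")
  set.seed(17)
  fus <- recombine(a, v, p_splice = 0, max_length = 250)
  expect_equal(fus$operator, "fusion")
  expect_equal(nchar(fus$sequence), 80)
  expect_equal(fus$sequence, paste0(a, v))
  for (i in 1:500) {
    sp <- recombine(a, v, p_splice = 1, max_length = 250)
    expect_equal(sp$operator, "splice")
    letters <- strsplit(sp$sequence, "")[[1]]
    x <- sum(letters == "A")
    tail_len <- sum(letters == "V")
    # interior cuts only: x in [1, La-1], suffix length in [1, Lb-1]
    expect_true(x >= 1 && x <= 39)
    expect_true(tail_len >= 1 && tail_len <= 39)
    expect_equal(paste(letters, collapse = ""),
                 paste0(substr(a, 1, x), substr(v, 41 - tail_len, 40)))
  }
})

test_that("recombination enforces the length cap", {
  a <- paste(rep("A", 200), collapse = "")
  v <- paste(rep("V", 200), collapse = "")
  set.seed(19)
  for (i in 1:100) {
    child <- recombine(a, v, p_splice = 0.5, max_length = 250)
    expect_lte(nchar(child$sequence), 250)
    expect_gte(nchar(child$sequence), 3)
  }
})

test_that("mutation respects the rate contract", {
  s <- paste(rep("ACDEFGHIKL", 4), collapse = "")
  set.seed(23)
  expect_equal(mutate_sequence(s, 0), s)
  m1 <- mutate_sequence(s, 1)
  expect_true(all(strsplit(m1, "")[[1]] != strsplit(s, "")[[1]]))
  # empirical per-position substitution frequency
  rate <- 0.05
  n_pos <- 40 * 2500
  hits <- 0
  for (i in 1:2500) {
    m <- mutate_sequence(s, rate)
    hits <- hits + sum(strsplit(m, "")[[1]] != strsplit(s, "")[[1]])
  }
  p_hat <- hits / n_pos
  expect_lt(abs(p_hat - rate), 4 * sqrt(rate * (1 - rate) / n_pos))
})

test_that("refinement descends in expectation and is deterministic per seed", {
  model <- nf_toy_letter_model()
  s <- paste(rep("ACDEFGHIKL", 3), collapse = "")
  expect_equal(refine(s, 0, model), s)
  e0 <- composite_energy(s, model)
  deltas <- vapply(1:50, function(sd) {
    set.seed(sd)
    composite_energy(refine(s, 30, model, temperature = 0.2), model) - e0
  }, numeric(1))
  expect_lt(mean(deltas), 0)
  set.seed(101)
  r1 <- refine(s, 25, model, temperature = 0.2)
  set.seed(101)
  r2 <- refine(s, 25, model, temperature = 0.2)
  expect_identical(r1, r2)
})

fake_individual <- function(id, burial) {
  structure(list(id = id, burial = burial, epoch = 0L), class = "individual")
}

test_that("selection keeps small pools and matches the hypergeometric oracle", {
  pool <- lapply(1:10, function(i) fake_individual(paste0("i", i), 0.5))
  expect_identical(stochastic_select(pool, 10), pool)
  expect_identical(stochastic_select(pool, 15), pool)
  # equal burials: inclusion probability target/pool for every member
  pool120 <- lapply(1:120, function(i) fake_individual(sprintf("i%03d", i), 0.42))
  set.seed(29)
  counts <- integer(120)
  n_trials <- 4000
  for (t in 1:n_trials) {
    surv <- stochastic_select(pool120, 100)
    idx <- as.integer(sub("i", "", vapply(surv, `[[`, character(1), "id")))
    counts[idx] <- counts[idx] + 1
  }
  freq <- counts / n_trials
  expect_true(all(abs(freq - 100 / 120) < 0.035))
})

test_that("selection frequencies are proportional to burial weights", {
  pool <- list(fake_individual("high", 0.8), fake_individual("low", 0.2))
  set.seed(31)
  wins <- 0
  for (t in 1:10000) {
    surv <- stochastic_select(pool, 1)
    wins <- wins + (surv[[1]]$id == "high")
  }
  p <- 0.8 / 1.0
  expect_lt(abs(wins / 10000 - p), 3 * sqrt(p * (1 - p) / 10000))
})

test_that("zero-burial individuals stay selectable", {
  pool <- c(lapply(1:5, function(i) fake_individual(paste0("z", i), 0)),
            list(fake_individual("pos", 0.9)))
  set.seed(33)
  surv <- stochastic_select(pool, 3)
  expect_length(surv, 3)
})

test_that("repeated selection raises mean burial in expectation", {
  set.seed(37)
  burials <- runif(120, 0, 1)
  pool <- lapply(seq_along(burials), function(i) {
    fake_individual(sprintf("p%03d", i), burials[i])
  })
  gains <- vapply(1:1000, function(t) {
    surv <- stochastic_select(pool, 60)
    mean(vapply(surv, `[[`, numeric(1), "burial")) - mean(burials)
  }, numeric(1))
  expect_gt(mean(gains), 0)
})

test_that("the GA keeps a constant population and complete acyclic lineage", {
  f <- nf_fixtures()
  lib <- small_ga_world()
  cfg <- ga_config(population_size = 10, offspring_per_epoch = 4, epochs = 3,
                   refine_steps = 5, library_size = 14, seed = 7,
                   max_child_length = 80)
  run <- run_ga(cfg, f$backends, library = lib, model = f$model)
  expect_length(run$population, 10)
  expect_equal(nrow(run$records), 3)
  # lineage: every non-founder's parents exist and were created earlier
  for (ind in run$archive) {
    if (ind$lineage$operator == "founder") next
    for (p in ind$lineage$parents) {
      expect_true(p %in% names(run$archive))
      expect_lt(run$archive[[p]]$epoch, ind$epoch)
    }
  }
  # census counters are non-decreasing
  expect_true(all(diff(run$records$cumulative_unique_cath) >= 0))
  expect_true(all(diff(run$records$cumulative_novel) >= 0))
})

test_that("a zero-epoch GA returns the initial population untouched", {
  f <- nf_fixtures()
  lib <- small_ga_world()
  cfg <- ga_config(population_size = 10, offspring_per_epoch = 4, epochs = 0,
                   refine_steps = 0, library_size = 14, seed = 7)
  run <- run_ga(cfg, f$backends, library = lib, model = f$model)
  expect_equal(nrow(run$records), 0)
  expect_length(run$population, 10)
  expect_true(all(vapply(run$population, function(x) x$lineage$operator,
                         character(1)) == "founder"))
})

test_that("GA runs are reproducible per seed", {
  f <- nf_fixtures()
  lib <- small_ga_world()
  cfg <- ga_config(population_size = 8, offspring_per_epoch = 3, epochs = 2,
                   refine_steps = 4, library_size = 14, seed = 11,
                   max_child_length = 80)
  r1 <- run_ga(cfg, f$backends, library = lib, model = f$model)
  r2 <- run_ga(cfg, f$backends, library = lib, model = f$model)
  expect_identical(r1$records, r2$records)
  expect_identical(names(r1$archive), names(r2$archive))
})

test_that("cumulative census matches a hand tally on a rigged archive", {
  mk <- function(id, epoch, burial) {
    structure(list(id = id, burial = burial, epoch = as.integer(epoch)),
              class = "individual")
  }
  archive <- list(
    f1 = mk("f1", 0, 0.3), f2 = mk("f2", 0, 0.6),
    a1 = mk("a1", 1, 0.7), a2 = mk("a2", 1, 0.65), b1 = mk("b1", 2, 0.8))
  call <- function(id, label, novel) {
    structure(list(candidate_id = id,
                   assigned_label = label, novel = novel,
                   compact = novel || !is.null(label), best_hit = NULL),
              class = "novelty_call")
  }
  calls <- list(
    f1 = call("f1", "1.10.8.10", FALSE),   # assigned founder
    f2 = call("f2", NULL, TRUE),           # novel founder
    a1 = call("a1", NULL, TRUE),           # novel, clusters with f2
    a2 = call("a2", "2.40.50.100", FALSE), # assigned
    b1 = call("b1", NULL, TRUE))           # novel, distinct fold
  tm <- function(i, j) {
    if (all(c(i, j) %in% c("f2", "a1"))) 0.8 else 0.2
  }
  cen <- cumulative_census(archive, calls, tm, tm_threshold = 0.5, epochs = 2)
  # epoch 1: labels {1.10.8.10, 2.40.50.100}; novel reps {f2} (a1 absorbed)
  expect_equal(cen$per_epoch$cumulative_unique_cath, c(2, 2))
  expect_equal(cen$per_epoch$cumulative_novel, c(1, 2))
  expect_equal(sort(cen$novel_representatives), c("b1", "f2"))
  # empty annotations give zero counts
  cen0 <- cumulative_census(list(), list(), tm, epochs = 0)
  expect_equal(nrow(cen0$per_epoch), 0)
})
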