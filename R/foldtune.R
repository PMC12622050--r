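# Structure-first foldtuning: iterative enrichment of a generative
# sequence model toward compact, CATH-unassignable structures, plus the
# sampling-hyperparameter scan harness.

#' Foldtuning round configuration
#'
#' Full-scale defaults: 10,000 sequences per round, the 100 most-compact
#' novel survivors as the finetuning set, sampling at top_k 950 and
#' temperature 1.5, five rounds.
#'
#' @param n_samples Sequences generated per round.
#' @param top_n Size of the finetuning set.
#' @param top_k Sampling vocabulary truncation.
#' @param temperature Sampling temperature.
#' @param rounds Number of rounds in a campaign.
#' @param compactness_threshold,tm_threshold Novelty-filter thresholds.
#' @param sasa_points Sphere points for burial.
#' @param seed Integer seed; per-round seeds are derived from it.
#' @return An object of class `round_config`.
#' @export
round_config <- function(n_samples = 10000, top_n = 100, top_k = 950,
                         temperature = 1.5, rounds = 5,
                         compactness_threshold = 0.5, tm_threshold = 0.5,
                         sasa_points = 240, seed = 1) {
  stopifnot(n_samples >= 1, top_n >= 1, top_n <= n_samples, rounds >= 0)
  structure(list(n_samples = as.integer(n_samples), top_n = as.integer(top_n),
                 top_k = as.integer(top_k), temperature = temperature,
                 rounds = as.integer(rounds),
                 compactness_threshold = compactness_threshold,
                 tm_threshold = tm_threshold,
                 sasa_points = as.integer(sasa_points),
                 seed = as.integer(seed)),
            class = "round_config")
}

#' Run one foldtuning round
#'
#' Generates `n_samples` sequences from the current generator state,
#' predicts structures, scores burial, annotates against the reference
#' library, keeps the novel survivors (compact and unassignable), ranks
#' them by descending burial fraction (ties lexicographic id) and
#' finetunes the generator on the `top_n` most compact. If fewer than
#' `top_n` survive, all survivors are used and a warning is raised.
#'
#' @param state Generator state (adapter-owned).
#' @param cfg A [round_config].
#' @param backends Backend suite with `sequence_generator`,
#'   `structure_predictor` and `search_engine`.
#' @param round Round index (used for seed derivation and ids).
#' @return List with `report` (class `round_report`: `round`,
#'   `mean_burial`, `n_novel`, `n_cath`, `structural_hit_rate`,
#'   `selected_ids`), `state` (the finetuned generator state), `samples`
#'   (annotation data.frame) and `selected` (named character vector of
#'   finetuning sequences).
#' @export
run_round <- function(state, cfg, backends, round = 1L) {
  stopifnot(inherits(cfg, "round_config"))
  gen <- backends$sequence_generator
  seqs <- gen$sample(state, cfg$n_samples, cfg$top_k, cfg$temperature,
                     seed = stage_seed(cfg$seed, paste0("round", round)))
  names(seqs) <- sprintf("r%d_%05d", round, seq_along(seqs))
  structures <- lapply(names(seqs), function(id) {
    backends$structure_predictor(protein_sequence(id, seqs[[id]]))
  })
  ann <- annotate_structures(structures, backends,
                             compactness_threshold = cfg$compactness_threshold,
                             tm_threshold = cfg$tm_threshold,
                             sasa_points = cfg$sasa_points)
  tab <- ann$table
  survivors <- tab[tab$novel, , drop = FALSE]
  survivors <- survivors[order(-survivors$burial, survivors$id), , drop = FALSE]
  if (nrow(survivors) < cfg$top_n) {
    warning(sprintf("round %d: only %d novel survivors (< top_n = %d); finetuning on all",
                    round, nrow(survivors), cfg$top_n))
    selected <- survivors
  } else {
    selected <- survivors[seq_len(cfg$top_n), , drop = FALSE]
  }
  new_state <- gen$finetune(state, unname(seqs[selected$id]))
  assigned <- tab$assigned_label[!is.na(tab$assigned_label)]
  report <- structure(list(round = as.integer(round),
                           mean_burial = mean(tab$burial),
                           n_novel = sum(tab$novel),
                           n_cath = length(unique(assigned)),
                           structural_hit_rate = mean(!is.na(tab$assigned_label)),
                           selected_ids = selected$id),
                      class = "round_report")
  list(report = report, state = new_state, samples = tab,
       selected = seqs[selected$id])
}

#' Run a foldtuning campaign
#'
#' Threads the generator state through `cfg$rounds` rounds and aggregates
#' per-round reports plus a campaign summary (pooled novel count and
#' discovery rate over all generated sequences).
#'
#' @param cfg A [round_config].
#' @param backends Backend suite.
#' @param state Optional initial generator state; default
#'   `backends$sequence_generator$init()`.
#' @return An object of class `foldtune_campaign`: `reports` (data.frame,
#'   one row per round with the Table-style columns), `round_reports`
#'   (list of `round_report`), `summary` (list `pooled_novel`,
#'   `total_samples`, `discovery`), `selected` (per-round finetuning
#'   sets) and `state` (final generator state).
#' @export
run_campaign <- function(cfg, backends, state = NULL) {
  stopifnot(inherits(cfg, "round_config"))
  if (is.null(state)) state <- backends$sequence_generator$init()
  reports <- list()
  selected <- list()
  for (r in seq_len(cfg$rounds)) {
    res <- run_round(state, cfg, backends, round = r)
    state <- res$state
    reports[[r]] <- res$report
    selected[[r]] <- res$selected
  }
  df <- if (length(reports)) {
    do.call(rbind, lapply(reports, function(x) {
      data.frame(round = x$round, mean_burial = x$mean_burial,
                 n_novel = x$n_novel, n_cath = x$n_cath,
                 structural_hit_rate = x$structural_hit_rate)
    }))
  } else {
    data.frame(round = integer(), mean_burial = numeric(),
               n_novel = integer(), n_cath = integer(),
               structural_hit_rate = numeric())
  }
  pooled <- sum(df$n_novel)
  total <- cfg$rounds * cfg$n_samples
  structure(list(reports = df, round_reports = reports,
                 summary = list(pooled_novel = pooled, total_samples = total,
                                discovery = if (total > 0) discovery_rate(pooled, total) else NULL),
                 selected = selected, state = state, config = cfg),
            class = "foldtune_campaign")
}

#' Sampling-hyperparameter scan
#'
#' For each (top_k, temperature) cell, samples `n_per_cell` sequences from
#' the base generator and reports the five scan statistics: unique CATH
#' (4-level) and CAT (3-level) label counts among assigned samples, the
#' fraction with no CATH assignment, the fraction compact (burial above
#' threshold), and the fraction satisfying both novelty conditions.
#'
#' @param grid data.frame with columns `top_k` and `temperature`.
#' @param n_per_cell Samples per cell (> 0).
#' @param backends Backend suite.
#' @param compactness_threshold,tm_threshold Filter thresholds.
#' @param sasa_points Sphere points for burial.
#' @param seed Integer seed; cell seeds are derived from it.
#' @return data.frame with one row per cell: `top_k`, `temperature`,
#'   `n_cath_unique`, `n_cat_unique`, `frac_no_cath`, `frac_compact`,
#'   `frac_both`.
#' @export
hyperparam_scan <- function(grid, n_per_cell, backends,
                            compactness_threshold = 0.5, tm_threshold = 0.5,
                            sasa_points = 240, seed = 1) {
  stopifnot(is.data.frame(grid), all(c("top_k", "temperature") %in% names(grid)))
  if (n_per_cell <= 0) stop("n_per_cell must be positive")
  gen <- backends$sequence_generator
  base_state <- gen$init()
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tk <- grid$top_k[i]
    tp <- grid$temperature[i]
    seqs <- gen$sample(base_state, n_per_cell, tk, tp,
                       seed = stage_seed(seed, sprintf("scan_%s_%s", tk, tp)))
    names(seqs) <- sprintf("scan%02d_%04d", i, seq_along(seqs))
    structures <- lapply(names(seqs), function(id) {
      backends$structure_predictor(protein_sequence(id, seqs[[id]]))
    })
    tab <- annotate_structures(structures, backends,
                               compactness_threshold = compactness_threshold,
                               tm_threshold = tm_threshold,
                               sasa_points = sasa_points)$table
    assigned <- tab$assigned_label[!is.na(tab$assigned_label)]
    data.frame(top_k = tk, temperature = tp,
               n_cath_unique = length(unique(assigned)),
               n_cat_unique = length(unique(cath_prefix(assigned, 3))),
               frac_no_cath = mean(is.na(tab$assigned_label)),
               frac_compact = mean(tab$compact),
               frac_both = mean(tab$novel))
  })
  do.call(rbind, rows)
}
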