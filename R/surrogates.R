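# Deterministic desk-scale surrogate backends for the external models the
# pipelines would otherwise call (sequence likelihood, contact density,
# structure prediction, inverse folding, energy scoring, structure search,
# generative sampling with a finetune hook). Every surrogate is
# deterministic given its inputs and seed, so full pipelines are exactly
# reproducible without any download.

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

.nf_cache <- new.env(parent = emptyenv())

#' Surrogate structure predictor (lattice chain growth)
#'
#' Deterministic greedy self-avoiding chain growth on a cubic lattice with
#' 3.8 A spacing: each residue is placed on the free neighbour that creates
#' the most new hydrophobic-hydrophobic contacts (Kyte-Doolittle > 0
#' defines hydrophobic), with ties broken by a hash of (sequence,
#' position) and dead ends resolved by backtracking. Returns a
#' C-alpha-only structure using the surrogate pseudo-radius convention.
#'
#' @param seq A [protein_sequence] or character scalar.
#' @param id Identifier when `seq` is a bare string.
#' @return A [protein_structure] (CA only).
#' @export
toy_structure_predictor <- function(seq, id = NULL) {
  if (is.character(seq)) seq <- protein_sequence(if (is.null(id)) "toy" else id, seq)
  if (seq$length < 2) stop("need at least 2 residues")
  if (seq$length > 512) stop("surrogate predictor supports lengths up to 512")
  hyd <- unname(is_hydrophobic(seq$residues))
  lat <- cpp_lattice_fold(seq$residues, hyd, 500000L)
  coords <- lat * CA_BOND
  atoms <- data.frame(res_index = seq_len(seq$length), atom_name = "CA",
                      element = "C",
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      radius = CA_PSEUDO_RADIUS, stringsAsFactors = FALSE)
  protein_structure(seq$id, seq, atoms)
}

#' Ideal extended-chain builder
#'
#' Straight C-alpha chain at the virtual bond spacing; the maximally
#' solvent-exposed reference conformation for the surrogate representation.
#'
#' @inheritParams toy_structure_predictor
#' @return A [protein_structure] (CA only).
#' @export
extended_chain_structure <- function(seq, id = NULL) {
  if (is.character(seq)) seq <- protein_sequence(if (is.null(id)) "ext" else id, seq)
  if (seq$length < 2) stop("need at least 2 residues")
  atoms <- data.frame(res_index = seq_len(seq$length), atom_name = "CA",
                      element = "C",
                      x = (seq_len(seq$length) - 1) * CA_BOND, y = 0, z = 0,
                      radius = CA_PSEUDO_RADIUS, stringsAsFactors = FALSE)
  protein_structure(seq$id, seq, atoms)
}

#' Generate the bundled fixture sequence corpus
#'
#' Sequences drawn from a planted second-order process (the next residue
#' follows a preferred deterministic successor of the previous two with
#' probability 0.6, otherwise uniform), so that a fitted Markov model can
#' separate corpus members from their shuffles. The copy shipped in
#' `inst/extdata/toy_corpus.fasta` was written with `seed = 101`.
#'
#' @param n Number of sequences.
#' @param length Sequence length.
#' @param seed Integer seed.
#' @return Named character vector of sequences.
#' @export
make_fixture_corpus <- function(n = 200, length = 40, seed = 101) {
  succ <- outer(seq_len(20), seq_len(20),
                function(i, j) ((i * 3 + j * 7) %% 20) + 1)
  with_local_seed(seed, {
    seqs <- vapply(seq_len(n), function(k) {
      idx <- integer(length)
      idx[1:2] <- sample.int(20, 2, replace = TRUE)
      for (p in 3:length) {
        idx[p] <- if (runif(1) < 0.6) succ[idx[p - 2], idx[p - 1]] else sample.int(20, 1)
      }
      paste(AA_ALPHABET[idx], collapse = "")
    }, character(1))
    names(seqs) <- sprintf("corpus_%03d", seq_len(n))
    seqs
  })
}

#' Fit the surrogate likelihood model
#'
#' Order-2 Markov model with Laplace smoothing over the 20-letter alphabet,
#' fit to a sequence corpus (the bundled fixture corpus by default).
#'
#' @param corpus Character vector of training sequences; `NULL` loads the
#'   bundled corpus.
#' @return An object of class `toy_likelihood_model`.
#' @export
toy_likelihood_model <- function(corpus = NULL) {
  if (is.null(corpus)) {
    path <- system.file("extdata", "toy_corpus.fasta", package = "novelforge")
    if (nzchar(path)) {
      recs <- read_fasta_sequences(path)
      corpus <- vapply(recs, function(s) s$residues, character(1))
    } else {
      corpus <- make_fixture_corpus()
    }
  }
  counts <- array(1, dim = c(20, 20, 20))  # Laplace
  for (s in corpus) {
    idx <- match(strsplit(s, "")[[1]], AA_ALPHABET)
    if (length(idx) < 3) next
    for (p in 3:length(idx)) {
      counts[idx[p - 2], idx[p - 1], idx[p]] <- counts[idx[p - 2], idx[p - 1], idx[p]] + 1
    }
  }
  tot <- apply(counts, c(1, 2), sum)
  logp <- log(sweep(counts, c(1, 2), tot, "/"))
  structure(list(logp = logp, order = 2L), class = "toy_likelihood_model")
}

default_likelihood_model <- function() {
  if (is.null(.nf_cache$likelihood_model)) {
    .nf_cache$likelihood_model <- toy_likelihood_model()
  }
  .nf_cache$likelihood_model
}

#' Surrogate sequence likelihood
#'
#' Mean per-residue log-probability of a sequence under the fitted
#' order-2 Markov model. Always negative; magnitude O(1) per residue.
#'
#' @param seq A [protein_sequence] or character scalar (length >= 3).
#' @param model A `toy_likelihood_model`; default is the bundled one.
#' @return Numeric scalar in (-Inf, 0).
#' @export
toy_likelihood <- function(seq, model = NULL) {
  if (inherits(seq, "protein_sequence")) seq <- seq$residues
  check_residues(seq)
  idx <- match(strsplit(seq, "")[[1]], AA_ALPHABET)
  if (length(idx) < 3) stop("need at least 3 residues")
  if (is.null(model)) model <- default_likelihood_model()
  n <- length(idx)
  mean(model$logp[cbind(idx[1:(n - 2)], idx[2:(n - 1)], idx[3:n])])
}

#' Surrogate contact density
#'
#' Contacts per residue of the surrogate-predicted structure: CA pairs
#' closer than 8 A with sequence separation >= 3.
#'
#' @inheritParams toy_structure_predictor
#' @return Non-negative numeric scalar.
#' @export
toy_contact_scorer <- function(seq, id = NULL) {
  if (inherits(seq, "protein_structure")) {
    return(cpp_contact_count(ca_coords(seq), 8.0, 3L) / n_residues(seq))
  }
  res <- if (inherits(seq, "protein_sequence")) seq$residues else seq
  cpp_lattice_contact_density(res, unname(is_hydrophobic(res)), 8.0, 3L,
                              500000L)
}

#' Surrogate inverse folder
#'
#' Re-noises the template sequence: each position is substituted with
#' probability `noise_rate` (new residue always differs from the old).
#' Deterministic per seed.
#'
#' @param template A [protein_structure] or [protein_sequence].
#' @param n Number of designs.
#' @param noise_rate Per-position substitution probability.
#' @param seed Integer seed.
#' @return List of [protein_sequence] designs named `<template>_ifd<i>`.
#' @export
toy_inverse_folder <- function(template, n, noise_rate = 0.15, seed = 1) {
  seq <- if (inherits(template, "protein_structure")) template$sequence else template
  stopifnot(noise_rate >= 0, noise_rate <= 1, n >= 0)
  with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      protein_sequence(sprintf("%s_ifd%03d", seq$id, i),
                       mutate_sequence(seq$residues, noise_rate))
    })
  })
}

#' Surrogate energy scorer
#'
#' Pseudo Rosetta-like total energy of a structure:
#' `-1.0 * (hydrophobic-hydrophobic contacts) - 0.2 * (all contacts)`,
#' with contacts defined as CA pairs < 8 A at sequence separation >= 3.
#'
#' @param s A [protein_structure].
#' @return Numeric total pseudo-energy (<= 0).
#' @export
toy_energy_scorer <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  co <- ca_coords(s)
  hyd <- unname(is_hydrophobic(s$sequence$residues))
  -1.0 * cpp_hh_contact_count(co, hyd, 8.0, 3L) -
    0.2 * cpp_contact_count(co, 8.0, 3L)
}

#' Surrogate structure-search engine
#'
#' Scores a query against every member of a reference library by the
#' maximum sliding-window fixed-alignment TM-score of the shorter chain
#' against the longer, with `d0` taken from the longer length (a
#' deterministic, conservative stand-in for an alignment-free search
#' tool). Hits are returned sorted by decreasing TM-score.
#'
#' @param query A [protein_structure].
#' @param refdb A reference library from [make_fixture_refdb()] or
#'   [read_refdb()].
#' @param stride Window stride (1 = exhaustive enumeration).
#' @return data.frame with columns `query_id`, `target_id`, `tm_score`,
#'   `cath_label`.
#' @export
toy_search_engine <- function(query, refdb, stride = 1L) {
  stopifnot(inherits(query, "protein_structure"))
  qc <- ca_coords(query)
  rows <- lapply(names(refdb$structures), function(tid) {
    tc <- ca_coords(refdb$structures[[tid]])
    tm <- sliding_window_tm(qc, tc, stride = stride)
    data.frame(query_id = query$id, target_id = tid, tm_score = tm,
               cath_label = refdb$labels$cath_label[refdb$labels$id == tid],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  if (is.null(hits)) {
    return(data.frame(query_id = character(), target_id = character(),
                      tm_score = numeric(), cath_label = character(),
                      stringsAsFactors = FALSE))
  }
  hits[order(-hits$tm_score, hits$target_id), , drop = FALSE]
}

# Max fixed-alignment TM of the shorter coordinate set slid along the
# longer; d0 from the longer length. step_div controls the seed-fragment
# density of the underlying TM search (the engine is a stand-in for an
# approximate production search tool, so it uses a coarser seeding than
# the precision TM-score entry point).
sliding_window_tm <- function(a, b, stride = 1L, step_div = 2L,
                              stop_at = Inf) {
  if (nrow(a) > nrow(b)) { tmp <- a; a <- b; b <- tmp }
  l <- nrow(a); L <- nrow(b)
  d0 <- tm_d0(L)
  best <- 0
  for (start in seq(1, L - l + 1, by = max(1L, as.integer(stride)))) {
    win <- b[start:(start + l - 1), , drop = FALSE]
    best <- max(best, cpp_tm_fixed(a, win, d0, step_div))
    if (best >= stop_at) break
  }
  best
}

#' Build a synthetic reference fold library
#'
#' Generates `n_folds` distinct lattice folds (independent random
#' sequences folded by the surrogate predictor) plus coordinate-jittered
#' copies as additional members, labelled with 4-level CATH-style strings.
#' Fold distinctness is verified (cross-fold TM < 0.5 for at least 95% of
#' pairs), regenerating offending folds as needed.
#'
#' @param n_folds Number of distinct folds.
#' @param members_per_fold Members per fold (>= 1; the first is unjittered).
#' @param seed Integer seed.
#' @param length Member chain length.
#' @return A `reference_library`: list with `structures` (named list of
#'   [protein_structure]) and `labels` (data.frame `id`, `cath_label`).
#' @export
make_fixture_refdb <- function(n_folds = 6, members_per_fold = 2, seed = 1,
                               length = 40) {
  stopifnot(n_folds >= 1, members_per_fold >= 1)
  folds <- list()
  attempt <- 0
  f <- 1
  while (f <= n_folds) {
    attempt <- attempt + 1
    if (attempt > 20 * n_folds) stop("could not generate distinct folds")
    seq <- with_local_seed(seed * 1000 + attempt, random_sequence(length))
    cand <- toy_structure_predictor(protein_sequence(sprintf("fold%02d", f), seq))
    ok <- TRUE
    if (length(folds) > 0) {
      tms <- vapply(folds, function(x) {
        sliding_window_tm(ca_coords(cand), ca_coords(x))
      }, numeric(1))
      ok <- mean(tms < 0.5) >= 0.95
    }
    if (ok) { folds[[f]] <- cand; f <- f + 1 }
  }
  structures <- list()
  labels <- NULL
  for (f in seq_len(n_folds)) {
    base <- folds[[f]]
    for (m in seq_len(members_per_fold)) {
      id <- sprintf("ref_f%02d_m%02d", f, m)
      s <- base
      s$id <- id
      s$sequence$id <- id
      if (m > 1) {
        jit <- with_local_seed(seed * 7919 + f * 100 + m, {
          matrix(runif(3 * n_residues(base), -0.4, 0.4), ncol = 3)
        })
        s$atoms[, c("x", "y", "z")] <- s$atoms[, c("x", "y", "z")] + jit
      }
      structures[[id]] <- s
      labels <- rbind(labels, data.frame(
        id = id,
        cath_label = sprintf("%d.%d.%d.%d", (f - 1) %% 3 + 1, 10 + f, f, m),
        stringsAsFactors = FALSE))
    }
  }
  structure(list(structures = structures, labels = labels),
            class = "reference_library")
}

#' Write / read a reference library as a directory of PDBs plus a label TSV
#'
#' @param refdb A `reference_library`.
#' @param dir Directory path (created if needed); the label table is
#'   written as `labels.tsv` with columns `id`, `cath_label`.
#' @return `dir` (invisibly) for `write_refdb`; a `reference_library` for
#'   `read_refdb`.
#' @export
write_refdb <- function(refdb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(refdb$structures)) {
    write_structure(refdb$structures[[id]], file.path(dir, paste0(id, ".pdb")))
  }
  write.table(refdb$labels, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_refdb
#' @export
read_refdb <- function(dir) {
  labels <- read.table(file.path(dir, "labels.tsv"), sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
  structures <- list()
  for (id in labels$id) {
    txt <- paste(readLines(file.path(dir, paste0(id, ".pdb"))), collapse = "\n")
    structures[[id]] <- parse_structure(txt, id = id)
  }
  structure(list(structures = structures, labels = labels),
            class = "reference_library")
}

random_sequence <- function(length, hydrophobic_bias = 0) {
  w <- rep(1, 20)
  if (hydrophobic_bias != 0) {
    w <- ifelse(KYTE_DOOLITTLE[AA_ALPHABET] > 0, 1 + hydrophobic_bias, 1)
  }
  paste(sample(AA_ALPHABET, length, replace = TRUE, prob = w), collapse = "")
}

# ---- surrogate generative sequence model (3-mer interpolated) ----------

#' Initialise the surrogate sequence generator
#'
#' A 3-mer interpolated categorical model (orders 0/1/2 mixed at
#' 0.1/0.2/0.7) with top-k truncation and temperature scaling at sampling
#' time, plus a finetune hook that re-estimates counts with weight 0.5
#' toward a provided sequence set. Stands in for a causal protein language
#' model with a finetuning interface.
#'
#' @param corpus Training sequences; `NULL` uses the bundled fixture corpus.
#' @param length Length of sequences the generator emits.
#' @return An object of class `toy_generator_state`.
#' @export
init_toy_generator <- function(corpus = NULL, length = 40) {
  if (is.null(corpus)) {
    path <- system.file("extdata", "toy_corpus.fasta", package = "novelforge")
    corpus <- if (nzchar(path)) {
      vapply(read_fasta_sequences(path), function(s) s$residues, character(1))
    } else make_fixture_corpus()
  }
  structure(list(counts = count_kmers(corpus), length = length),
            class = "toy_generator_state")
}

count_kmers <- function(seqs, pseudocount = 0.02) {
  # small smoothing mass so that a ~100-sequence finetuning set dominates
  # its own re-estimated tables
  c3 <- array(pseudocount, dim = c(20, 20, 20))
  c2 <- matrix(pseudocount, 20, 20)
  c1 <- rep(pseudocount, 20)
  for (s in seqs) {
    idx <- match(strsplit(s, "")[[1]], AA_ALPHABET)
    n <- length(idx)
    for (p in seq_len(n)) {
      c1[idx[p]] <- c1[idx[p]] + 1
      if (p >= 2) c2[idx[p - 1], idx[p]] <- c2[idx[p - 1], idx[p]] + 1
      if (p >= 3) c3[idx[p - 2], idx[p - 1], idx[p]] <- c3[idx[p - 2], idx[p - 1], idx[p]] + 1
    }
  }
  list(c3 = c3, c2 = c2, c1 = c1)
}

generator_next_prob <- function(state, i1, i2) {
  cs <- state$counts
  p1 <- cs$c1 / sum(cs$c1)
  p2 <- cs$c2[i2, ] / sum(cs$c2[i2, ])
  p3 <- cs$c3[i1, i2, ] / sum(cs$c3[i1, i2, ])
  0.7 * p3 + 0.2 * p2 + 0.1 * p1
}

# top_k is on the production model's token vocabulary scale (hundreds to
# thousands); map it to the 20-letter alphabet as ceiling(top_k / 50),
# clamped to [1, 20].
effective_top_k <- function(top_k) max(1L, min(20L, as.integer(ceiling(top_k / 50))))

#' Sample sequences from the surrogate generator
#'
#' @param state A `toy_generator_state`.
#' @param n Number of sequences.
#' @param top_k Vocabulary truncation on the production token scale
#'   (mapped internally to the 20-letter alphabet).
#' @param temperature Softmax temperature; `temperature -> 0` recovers
#'   deterministic argmax sampling.
#' @param seed Integer seed.
#' @return Named character vector of `n` sequences.
#' @export
toy_generator_sample <- function(state, n, top_k = 950, temperature = 1.5,
                                 seed = 1) {
  stopifnot(inherits(state, "toy_generator_state"), temperature >= 0)
  k_eff <- effective_top_k(top_k)
  L <- state$length
  with_local_seed(seed, {
    out <- vapply(seq_len(n), function(j) {
      idx <- integer(L)
      p0 <- state$counts$c1 / sum(state$counts$c1)
      idx[1] <- sample_categorical(p0, k_eff, temperature)
      p1 <- state$counts$c2[idx[1], ] / sum(state$counts$c2[idx[1], ])
      idx[2] <- sample_categorical(p1, k_eff, temperature)
      for (p in 3:L) {
        pr <- generator_next_prob(state, idx[p - 2], idx[p - 1])
        idx[p] <- sample_categorical(pr, k_eff, temperature)
      }
      paste(AA_ALPHABET[idx], collapse = "")
    }, character(1))
    names(out) <- sprintf("gen_%05d", seq_len(n))
    out
  })
}

sample_categorical <- function(p, k_eff, temperature) {
  ord <- order(-p, seq_along(p))
  keep <- ord[seq_len(k_eff)]
  if (temperature < 1e-8) return(keep[1])
  w <- p[keep]^(1 / temperature)
  keep[sample.int(length(keep), 1, prob = w / sum(w))]
}

#' Log-likelihood of a sequence under the generator state
#'
#' Mean per-residue interpolated log-probability (no truncation or
#' temperature), used to verify that finetuning shifts the model toward a
#' sequence set.
#'
#' @param state A `toy_generator_state`.
#' @param seq Character sequence or [protein_sequence].
#' @return Numeric scalar (< 0).
#' @export
toy_generator_loglik <- function(state, seq) {
  if (inherits(seq, "protein_sequence")) seq <- seq$residues
  idx <- match(strsplit(seq, "")[[1]], AA_ALPHABET)
  stopifnot(length(idx) >= 3)
  lp <- vapply(3:length(idx), function(p) {
    log(generator_next_prob(state, idx[p - 2], idx[p - 1])[idx[p]])
  }, numeric(1))
  mean(lp)
}

#' Finetune the surrogate generator on a sequence set
#'
#' Re-estimates the k-mer tables as an equal-mass 0.5/0.5 mixture of the
#' current tables and tables fit to `seqs`.
#'
#' @param state A `toy_generator_state`.
#' @param seqs Character vector (or list of [protein_sequence]).
#' @return The updated `toy_generator_state`.
#' @export
toy_generator_finetune <- function(state, seqs) {
  if (is.list(seqs)) seqs <- vapply(seqs, function(s) {
    if (inherits(s, "protein_sequence")) s$residues else s
  }, character(1))
  if (length(seqs) == 0) return(state)
  new <- count_kmers(seqs)
  mix <- function(a, b) {
    a <- a / sum(a); b <- b / sum(b)
    0.5 * a + 0.5 * b
  }
  state$counts <- list(c3 = array(mix(state$counts$c3, new$c3), dim = c(20, 20, 20)),
                       c2 = matrix(mix(state$counts$c2, new$c2), 20, 20),
                       c1 = mix(state$counts$c1, new$c1))
  state
}

#' Assemble the surrogate backend suite
#'
#' Binds every adapter interface used by the pipelines (likelihood scorer,
#' contact scorer, structure predictor, inverse folder, energy scorer,
#' structure-search engine, generative sequence model with finetune hook)
#' to its deterministic surrogate.
#'
#' @param refdb Reference library for the search engine; `NULL` builds a
#'   small fixture library with [make_fixture_refdb()].
#' @param likelihood_model Optional `toy_likelihood_model`.
#' @param generator_length Length of generator-emitted sequences.
#' @param inverse_noise Noise ladder cycled across inverse-folded designs.
#' @param search_stride Window stride for the surrogate search engine.
#' @return An object of class `backend_suite`.
#' @export
surrogate_backends <- function(refdb = NULL, likelihood_model = NULL,
                               generator_length = 40,
                               inverse_noise = seq(0.05, 0.5, length.out = 10),
                               search_stride = 1L) {
  if (is.null(refdb)) refdb <- make_fixture_refdb(seed = 1)
  model <- if (is.null(likelihood_model)) default_likelihood_model() else likelihood_model
  structure(list(
    likelihood_scorer = function(seq) toy_likelihood(seq, model),
    contact_scorer = function(seq) toy_contact_scorer(seq),
    structure_predictor = function(seq, id = NULL) toy_structure_predictor(seq, id),
    inverse_folder = function(template, n, seed = 1) {
      rates <- rep_len(inverse_noise, n)
      designs <- vector("list", n)
      for (i in seq_len(n)) {
        designs[[i]] <- toy_inverse_folder(template, 1, noise_rate = rates[i],
                                           seed = seed * 10000 + i)[[1]]
        designs[[i]]$id <- sprintf("%s_ifd%03d", template$id, i)
      }
      designs
    },
    energy_scorer = function(s) toy_energy_scorer(s),
    search_engine = function(query) toy_search_engine(query, refdb,
                                                      stride = search_stride),
    sequence_generator = list(
      init = function() init_toy_generator(length = generator_length),
      sample = function(state, n, top_k, temperature, seed) {
        toy_generator_sample(state, n, top_k, temperature, seed)
      },
      finetune = function(state, seqs) toy_generator_finetune(state, seqs)
    ),
    refdb = refdb
  ), class = "backend_suite")
}
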