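# Inverse-folding funnel landscapes: per-template scatter of
# energy-per-residue against TM-score to the template, and a rule-based
# classification of landscape shape.

#' Greedy sequence-identity clustering
#'
#' For equal-length designs off one template, identity is the exact-match
#' fraction. Greedy by input order: the first ungrouped sequence founds a
#' cluster and absorbs every later ungrouped sequence with identity at or
#' above the threshold; cluster founders are the representatives.
#'
#' @param seqs Character vector (or list of [protein_sequence]) of
#'   equal-length sequences.
#' @param threshold Identity threshold in \[0, 1\].
#' @return List with `representatives` (integer indices into `seqs`) and
#'   `assignment` (integer cluster index per sequence).
#' @export
cluster_by_identity <- function(seqs, threshold = 0.60) {
  if (is.list(seqs)) seqs <- vapply(seqs, function(s) {
    if (inherits(s, "protein_sequence")) s$residues else s
  }, character(1))
  n <- length(seqs)
  if (n == 0) return(list(representatives = integer(), assignment = integer()))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) stop("sequences must all have equal length")
  mat <- do.call(rbind, strsplit(seqs, ""))
  assignment <- rep(NA_integer_, n)
  reps <- integer()
  for (i in seq_len(n)) {
    if (!is.na(assignment[i])) next
    reps <- c(reps, i)
    cl <- length(reps)
    assignment[i] <- cl
    if (i < n) {
      for (j in (i + 1):n) {
        if (!is.na(assignment[j])) next
        if (mean(mat[i, ] == mat[j, ]) >= threshold) assignment[j] <- cl
      }
    }
  }
  list(representatives = reps, assignment = assignment)
}

#' Stability-filter pass for a landscape point
#'
#' Both thresholds are strict: energy per residue below -2.2 REU/aa and
#' TM-score to the template above 0.5.
#'
#' @param energy_per_residue Numeric (REU/aa).
#' @param tm_to_template Numeric TM-score.
#' @param energy_threshold,tm_threshold Strict thresholds.
#' @return Logical.
#' @export
pass_filter <- function(energy_per_residue, tm_to_template,
                        energy_threshold = -2.2, tm_threshold = 0.5) {
  energy_per_residue < energy_threshold & tm_to_template > tm_threshold
}

#' Build an inverse-folding landscape for a template
#'
#' Samples `n` inverse-folded designs, preclusters them by sequence
#' identity to minimise redundancy, and for each cluster representative
#' predicts a structure, scores its total energy per residue and its
#' fixed-alignment TM-score to the template. Per-design backend failures
#' drop the design with a warning.
#'
#' @param template A [protein_structure].
#' @param n Number of initial designs.
#' @param backends Backend suite with `inverse_folder`,
#'   `structure_predictor` and `energy_scorer`.
#' @param seed Integer seed.
#' @param identity_threshold Preclustering identity threshold.
#' @param energy_threshold,tm_threshold Pass-filter thresholds.
#' @return An object of class `funnel_landscape`: `template_id`, `points`
#'   (data.frame `design_id`, `energy_per_residue`, `tm_to_template`,
#'   `passes`), `n_initial`, `identity_threshold`.
#' @export
build_landscape <- function(template, n = 200, backends, seed = 1,
                            identity_threshold = 0.60,
                            energy_threshold = -2.2, tm_threshold = 0.5) {
  stopifnot(inherits(template, "protein_structure"))
  designs <- backends$inverse_folder(template, n, seed = seed)
  cl <- cluster_by_identity(designs, threshold = identity_threshold)
  reps <- designs[cl$representatives]
  tcoords <- ca_coords(template)
  rows <- list()
  for (d in reps) {
    row <- tryCatch({
      st <- backends$structure_predictor(d)
      e <- backends$energy_scorer(st) / n_residues(st)
      tm <- tm_score_fixed_alignment(ca_coords(st), tcoords)$value
      data.frame(design_id = d$id, energy_per_residue = e, tm_to_template = tm,
                 passes = pass_filter(e, tm, energy_threshold, tm_threshold),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("dropping design %s: %s", d$id, conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  points <- if (length(rows)) do.call(rbind, rows) else
    data.frame(design_id = character(), energy_per_residue = numeric(),
               tm_to_template = numeric(), passes = logical())
  structure(list(template_id = template$id, points = points,
                 n_initial = n, identity_threshold = identity_threshold),
            class = "funnel_landscape")
}

#' Funnel classification parameters
#'
#' Funnel-versus-pathology judgements on energy landscapes are
#' traditionally made by eye; this fixed rule table makes them
#' reproducible. All constants are exposed here.
#'
#' @param rho_funnel Spearman correlation at or below which (with low
#'   trapped fraction) a landscape is a funnel.
#' @param rho_flat Absolute correlation below which a landscape is flat.
#' @param trapped_max Maximum trapped fraction for a funnel verdict.
#' @param low_energy_quantile Energy quantile defining the low-energy
#'   subset.
#' @param tm_threshold TM threshold separating on-target from trapped
#'   states.
#' @param bin_width TM histogram bin width for mode counting.
#' @param min_mode_points Minimum points for a histogram bin to count as
#'   a mode.
#' @param min_points Minimum landscape size for a classification.
#' @return List of parameters.
#' @export
funnel_params <- function(rho_funnel = -0.3, rho_flat = 0.15,
                          trapped_max = 0.1, low_energy_quantile = 0.25,
                          tm_threshold = 0.5, bin_width = 0.1,
                          min_mode_points = 3, min_points = 10) {
  as.list(environment())
}

count_tm_modes <- function(tm, bin_width, min_points) {
  breaks <- seq(0, 1 + bin_width, by = bin_width)
  counts <- tabulate(pmin(findInterval(tm, breaks, rightmost.closed = TRUE),
                          length(breaks) - 1), nbins = length(breaks) - 1)
  padded <- c(0, counts, 0)
  modes <- 0L
  for (i in seq_along(counts)) {
    if (counts[i] >= min_points && counts[i] > padded[i] && counts[i] > padded[i + 2]) {
      modes <- modes + 1L
    }
  }
  modes
}

#' Classify an inverse-folding landscape
#'
#' Computes the Spearman correlation between energy per residue and
#' TM-score, the trapped fraction (low-energy points below the TM
#' threshold) and the number of TM modes in the low-energy subset, then
#' applies the rule table in order: `off_target_minimum` when the median
#' TM of the low-energy subset is below the TM threshold;
#' `multi_minimum` when the low-energy subset has two or more TM modes;
#' `flat` when |rho| is below `rho_flat` (degenerate all-equal energies
#' are flat by convention); `funnel` when rho is at or below `rho_funnel`
#' and the trapped fraction is below `trapped_max`; otherwise
#' `ambiguous`. Landscapes with fewer than `min_points` points are
#' reported as `insufficient`.
#'
#' @param land A `funnel_landscape` (or data.frame of points).
#' @param params See [funnel_params()].
#' @return An object of class `funnel_verdict`: `classification`,
#'   `spearman_rho`, `trapped_fraction`, `low_energy_tm_modes`,
#'   `pass_fraction`, `n_points`.
#' @export
classify_funnel <- function(land, params = funnel_params()) {
  pts <- if (inherits(land, "funnel_landscape")) land$points else land
  e <- pts$energy_per_residue
  tm <- pts$tm_to_template
  n <- length(e)
  pass_fraction <- if ("passes" %in% names(pts) && n > 0) mean(pts$passes) else NA_real_
  verdict <- function(class, rho = NA_real_, trapped = NA_real_, modes = NA_integer_) {
    structure(list(classification = class, spearman_rho = rho,
                   trapped_fraction = trapped, low_energy_tm_modes = modes,
                   pass_fraction = pass_fraction, n_points = n),
              class = "funnel_verdict")
  }
  if (n < params$min_points) return(verdict("insufficient"))
  degenerate <- length(unique(e)) == 1
  rho <- if (degenerate) 0 else suppressWarnings(cor(e, tm, method = "spearman"))
  if (is.na(rho)) rho <- 0
  low <- e <= quantile(e, params$low_energy_quantile, type = 7)
  tm_low <- tm[low]
  trapped <- mean(tm_low < params$tm_threshold)
  modes <- count_tm_modes(tm_low, params$bin_width, params$min_mode_points)
  if (degenerate) return(verdict("flat", rho, trapped, modes))
  if (median(tm_low) < params$tm_threshold) {
    return(verdict("off_target_minimum", rho, trapped, modes))
  }
  if (modes >= 2) return(verdict("multi_minimum", rho, trapped, modes))
  if (abs(rho) < params$rho_flat) return(verdict("flat", rho, trapped, modes))
  if (rho <= params$rho_funnel && trapped < params$trapped_max) {
    return(verdict("funnel", rho, trapped, modes))
  }
  verdict("ambiguous", rho, trapped, modes)
}

#' Export a landscape as a TSV table
#'
#' @param land A `funnel_landscape`.
#' @param path Output file.
#' @export
write_landscape_tsv <- function(land, path) {
  write.table(land$points, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
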