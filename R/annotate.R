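# CATH assignment from structure-search hits, novelty calls, greedy
# TM-threshold clustering and fold-census statistics.

parse_cath_label <- function(label) {
  parts <- strsplit(label, ".", fixed = TRUE)[[1]]
  if (length(parts) < 1 || length(parts) > 4 ||
      any(!grepl("^[0-9]+$", parts))) {
    stop("malformed CATH label: ", label)
  }
  as.integer(parts)
}

# Exact half-even rounding of (100 * num / den) to one decimal, in integer
# arithmetic; census inputs are integer counts, so the reported percentage
# is computed without floating-point ties.
round_pct_tenths <- function(num, den) {
  sign <- ifelse(num < 0, -1, 1)
  n <- abs(as.numeric(num)) * 1000
  d <- as.numeric(den)
  q <- n %/% d
  r <- n - q * d
  up <- (2 * r > d) | (2 * r == d & q %% 2 == 1)
  sign * (q + as.numeric(up)) / 10
}

cath_prefix <- function(labels, depth) {
  vapply(strsplit(labels, ".", fixed = TRUE), function(p) {
    paste(p[seq_len(min(depth, length(p)))], collapse = ".")
  }, character(1))
}

#' Assign a CATH label from structure-search hits
#'
#' A query is assigned if and only if its best hit exceeds the TM
#' threshold (strictly); the assigned label is the label of the maximal
#' hit, with exact ties broken by lexicographic target id.
#'
#' @param hits data.frame with columns `query_id`, `target_id`,
#'   `tm_score`, `cath_label` (all hits for one query; may be empty).
#' @param tm_threshold Assignment threshold (strict `>`).
#' @return List with `assigned` (logical), `assigned_label` (character or
#'   `NULL`) and `best_hit` (single-row data.frame or `NULL`).
#' @export
assign_cath <- function(hits, tm_threshold = 0.5) {
  if (is.null(hits) || nrow(hits) == 0) {
    return(list(assigned = FALSE, assigned_label = NULL, best_hit = NULL))
  }
  if (length(unique(hits$query_id)) > 1) {
    stop("assign_cath expects hits for a single query")
  }
  invisible(lapply(hits$cath_label, parse_cath_label))
  ord <- order(-hits$tm_score, hits$target_id)
  best <- hits[ord[1], , drop = FALSE]
  if (best$tm_score > tm_threshold) {
    list(assigned = TRUE, assigned_label = best$cath_label, best_hit = best)
  } else {
    list(assigned = FALSE, assigned_label = NULL, best_hit = best)
  }
}

#' Call novelty for a candidate
#'
#' A candidate is compact when its burial fraction strictly exceeds the
#' compactness threshold, and novel when it is compact and has no CATH
#' assignment.
#'
#' @param burial Numeric burial value or [burial_fraction()] result.
#' @param hits Structure-search hits for the candidate (see
#'   [assign_cath()]).
#' @param compactness_threshold Strict burial threshold.
#' @param tm_threshold Strict assignment threshold.
#' @param candidate_id Optional id recorded in the call.
#' @return An object of class `novelty_call` with fields `candidate_id`,
#'   `compact`, `assigned_label`, `best_hit`, `novel`.
#' @export
novelty_call <- function(burial, hits, compactness_threshold = 0.5,
                         tm_threshold = 0.5, candidate_id = NULL) {
  if (inherits(burial, "burial_fraction")) burial <- burial$value
  if (is.null(candidate_id)) {
    candidate_id <- if (!is.null(hits) && nrow(hits) > 0) hits$query_id[1] else NA_character_
  }
  a <- assign_cath(hits, tm_threshold)
  compact <- burial > compactness_threshold
  structure(list(candidate_id = candidate_id,
                 compact = compact,
                 assigned_label = a$assigned_label,
                 best_hit = a$best_hit,
                 novel = compact && !a$assigned),
            class = "novelty_call")
}

#' Greedy TM-threshold clustering
#'
#' Orders candidates by descending burial (ties broken by lexicographic
#' id; plain id order when burial is not supplied). The first unclustered
#' id founds a cluster and absorbs every unclustered id whose TM-score to
#' the founder reaches the threshold; the process repeats until all ids
#' are clustered.
#'
#' @param ids Character vector of candidate ids.
#' @param pairwise_tm Function `(id1, id2) -> numeric`.
#' @param threshold Absorption threshold (`tm >= threshold`).
#' @param burial Optional named numeric vector of burial values.
#' @return An object of class `cluster_set`: list of clusters, each with
#'   `representative_id` and `member_ids` (the representative included).
#' @export
greedy_tm_cluster <- function(ids, pairwise_tm, threshold = 0.5,
                              burial = NULL) {
  ord <- if (is.null(burial)) order(ids) else order(-burial[ids], ids)
  queue <- ids[ord]
  clusters <- list()
  while (length(queue) > 0) {
    founder <- queue[1]
    queue <- queue[-1]
    if (length(queue) > 0) {
      tm <- vapply(queue, function(x) pairwise_tm(founder, x), numeric(1))
      members <- queue[tm >= threshold]
      queue <- queue[tm < threshold]
    } else members <- character()
    clusters[[length(clusters) + 1L]] <-
      list(representative_id = founder, member_ids = c(founder, members))
  }
  structure(clusters, class = "cluster_set")
}

#' Fold census at each CATH level
#'
#' @param labels Character vector of assigned CATH labels (4-level dotted
#'   strings).
#' @param novel_clusters Number of novel cluster representatives.
#' @return An object of class `fold_census`: unique counts at levels C,
#'   CA, CAT and CATH, plus `novel_clusters` and `total_labels`.
#' @export
fold_census <- function(labels, novel_clusters = 0L) {
  labels <- labels[!is.na(labels)]
  invisible(lapply(labels, parse_cath_label))
  structure(list(C = length(unique(cath_prefix(labels, 1))),
                 CA = length(unique(cath_prefix(labels, 2))),
                 CAT = length(unique(cath_prefix(labels, 3))),
                 CATH = length(unique(cath_prefix(labels, 4))),
                 novel_clusters = as.integer(novel_clusters),
                 total_labels = length(labels)),
            class = "fold_census")
}

#' Census growth report
#'
#' Absolute deltas and percentage increases per CATH level between two
#' censuses, with percentages rounded half-even to one decimal.
#'
#' @param before,after `fold_census` objects (or lists with counts at the
#'   compared levels).
#' @param levels Levels to compare.
#' @return data.frame with columns `level`, `before`, `after`, `delta`,
#'   `pct_increase`.
#' @export
census_stats <- function(before, after, levels = c("C", "CA", "CAT", "CATH")) {
  rows <- lapply(levels, function(lv) {
    b <- before[[lv]]
    a <- after[[lv]]
    if (is.null(b) || is.null(a)) stop("missing level: ", lv)
    if (b <= 0) stop("zero baseline at level ", lv)
    data.frame(level = lv, before = b, after = a, delta = a - b,
               pct_increase = round_pct_tenths(a - b, b),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Novel fold discovery rate
#'
#' @param novel Number of novel candidates (0 <= novel <= total).
#' @param total Total candidates (> 0).
#' @return List with `fraction`, `per_million` and `percent` (the
#'   percentage rounded half-even to one decimal).
#' @export
discovery_rate <- function(novel, total) {
  stopifnot(total > 0, novel >= 0, novel <= total)
  fraction <- novel / total
  list(fraction = fraction,
       per_million = 1e6 * fraction,
       percent = round_pct_tenths(novel, total))
}

#' Annotate candidate structures against a reference library
#'
#' Convenience wrapper running burial, structure search and
#' [novelty_call()] for each candidate.
#'
#' @param structures List of [protein_structure] objects.
#' @param backends Backend suite providing `search_engine`.
#' @param compactness_threshold,tm_threshold Call thresholds.
#' @param sasa_points Sphere points for burial.
#' @return List with `calls` (named list of `novelty_call`) and `table`
#'   (data.frame `id`, `burial`, `compact`, `assigned_label`, `best_tm`,
#'   `novel`).
#' @export
annotate_structures <- function(structures, backends,
                                compactness_threshold = 0.5,
                                tm_threshold = 0.5, sasa_points = 240) {
  bur <- vapply(structures, function(s) {
    burial_fraction(s, n_sphere_points = sasa_points)$value
  }, numeric(1))
  calls <- lapply(seq_along(structures), function(i) {
    s <- structures[[i]]
    novelty_call(bur[i], backends$search_engine(s), compactness_threshold,
                 tm_threshold, candidate_id = s$id)
  })
  names(calls) <- vapply(structures, `[[`, character(1), "id")
  tab <- do.call(rbind, lapply(seq_along(calls), function(i) {
    cl <- calls[[i]]
    data.frame(id = cl$candidate_id,
               burial = bur[i],
               compact = cl$compact,
               assigned_label = if (is.null(cl$assigned_label)) NA_character_ else cl$assigned_label,
               best_tm = if (is.null(cl$best_hit)) NA_real_ else cl$best_hit$tm_score,
               novel = cl$novel,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(calls = calls, table = tab)
}
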