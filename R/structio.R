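# Structure and sequence I/O, SASA, burial fraction, superposition and
# fixed-alignment TM-score.

#' Construct a protein sequence
#'
#' A lightweight container for a single amino-acid sequence. Only the
#' twenty canonical one-letter codes are accepted; `X` and other ambiguity
#' codes are rejected.
#'
#' @param id Character identifier.
#' @param residues Character scalar of one-letter residue codes.
#' @return An object of class `protein_sequence` with fields `id`,
#'   `residues` and `length`.
#' @examples
#' protein_sequence("frag1", "ACDEFGHIKL")
#' @export
protein_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1,
            is.character(residues), length(residues) == 1, nzchar(residues))
  check_residues(residues, id)
  structure(list(id = id, residues = residues, length = nchar(residues)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d aa)\n", x$id, x$length))
  invisible(x)
}

#' Construct a protein structure
#'
#' Single-chain atomic model with 1-based contiguous residue numbering.
#' Atom radii drive SASA; structures whose only atoms are C-alpha pseudo
#' atoms use the surrogate pseudo-radius convention (3.0 A).
#'
#' @param id Character identifier.
#' @param sequence A [protein_sequence] (or character scalar).
#' @param atoms data.frame with columns `res_index`, `atom_name`, `element`,
#'   `x`, `y`, `z`, `radius`.
#' @param per_residue_confidence Optional numeric vector in \[0, 100\]
#'   (pLDDT-like), one value per residue.
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(id, sequence, atoms, per_residue_confidence = NULL) {
  if (is.character(sequence)) sequence <- protein_sequence(id, sequence)
  stopifnot(inherits(sequence, "protein_sequence"), is.data.frame(atoms))
  need <- c("res_index", "atom_name", "element", "x", "y", "z", "radius")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  }
  L <- sequence$length
  idx <- sort(unique(atoms$res_index))
  if (!identical(as.integer(idx), seq_len(L))) {
    stop("residue indices must be contiguous 1..L and match the sequence length")
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  if (any(atoms$radius <= 0)) stop("atom radii must be positive")
  if (!is.null(per_residue_confidence)) {
    stopifnot(length(per_residue_confidence) == L,
              all(per_residue_confidence >= 0 & per_residue_confidence <= 100))
  }
  structure(list(id = id, sequence = sequence, atoms = atoms,
                 per_residue_confidence = per_residue_confidence),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %s: %d residues, %d atoms\n",
              x$id, x$sequence$length, nrow(x$atoms)))
  invisible(x)
}

#' Number of residues in a structure
#' @param s A `protein_structure`.
#' @return Integer residue count.
#' @export
n_residues <- function(s) s$sequence$length

#' Extract C-alpha coordinates
#'
#' @param s A `protein_structure`.
#' @return L x 3 numeric matrix of CA coordinates in residue order.
#' @export
ca_coords <- function(s) {
  ca <- s$atoms[s$atoms$atom_name == "CA", , drop = FALSE]
  ca <- ca[order(ca$res_index), , drop = FALSE]
  if (nrow(ca) != n_residues(s)) {
    stop(sprintf("structure %s is missing CA atoms", s$id))
  }
  as.matrix(ca[, c("x", "y", "z")])
}

is_ca_only <- function(s) all(s$atoms$atom_name == "CA")

#' Parse a PDB-format structure
#'
#' Reads a single-chain PDB text into a [protein_structure]. Record parsing
#' is delegated to \pkg{bio3d}; this wrapper enforces the package's model:
#' exactly one chain (multi-chain input is an error naming the chains),
#' insertion codes rejected, alternate locations resolved to the
#' highest-occupancy conformer (ties broken in favour of altloc `A`),
#' hydrogens dropped, and residues renumbered 1..L in file order.
#'
#' @param text PDB-format character scalar, or a vector of lines.
#' @param id Identifier for the resulting structure (default `"structure"`).
#' @return A [protein_structure]. B-factors in \[0, 100\] are retained as
#'   `per_residue_confidence` (residue means).
#' @export
parse_structure <- function(text, id = "structure") {
  if (length(text) > 1) text <- paste(text, collapse = "\n")
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(text, tf)
  pdb <- bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records found")
  chains <- unique(at$chain)
  chains[is.na(chains)] <- " "
  if (length(unique(chains)) > 1) {
    stop("multi-chain input not supported; found chains: ",
         paste(sort(unique(chains)), collapse = ", "))
  }
  if (any(!is.na(at$insert) & nzchar(at$insert))) {
    stop("insertion codes are not supported")
  }
  # altloc policy: per (residue, atom name) keep highest occupancy, ties 'A'
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(nzchar(alt))) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$resno, at$elety, sep = "|")
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[nzchar(alt)])) {
      rows <- which(key == k)
      if (length(rows) <= 1) next
      ord <- order(-occ[rows], alt[rows] != "A", alt[rows])
      keep[rows] <- FALSE
      keep[rows[ord[1]]] <- TRUE
    }
    at <- at[keep, , drop = FALSE]
  }
  # drop hydrogens
  elem <- toupper(sub("^\\s+|\\s+$", "", at$elesy))
  guess <- substr(gsub("[0-9 ]", "", at$elety), 1, 1)
  elem[is.na(elem) | !nzchar(elem)] <- guess[is.na(elem) | !nzchar(elem)]
  hyd <- elem %in% c("H", "D")
  at <- at[!hyd, , drop = FALSE]
  elem <- elem[!hyd]
  if (nrow(at) == 0) stop("no heavy atoms found")

  res_keys <- paste(at$resno, at$resid)
  res_order <- unique(res_keys)
  res_index <- match(res_keys, res_order)
  res3 <- toupper(at$resid[match(res_order, res_keys)])
  unknown <- setdiff(unique(res3), names(AA3))
  if (length(unknown) > 0) {
    stop("non-canonical residue(s): ", paste(unknown, collapse = ", "))
  }
  seq1 <- paste(AA3[res3], collapse = "")

  bad_elem <- setdiff(unique(elem), names(VDW_RADII))
  if (length(bad_elem) > 0) {
    stop("no van der Waals radius for element(s): ",
         paste(bad_elem, collapse = ", "))
  }
  atoms <- data.frame(res_index = as.integer(res_index),
                      atom_name = at$elety,
                      element = elem,
                      x = at$x, y = at$y, z = at$z,
                      radius = unname(VDW_RADII[elem]),
                      stringsAsFactors = FALSE)
  # C-alpha-only surrogate convention
  if (all(atoms$atom_name == "CA")) atoms$radius <- CA_PSEUDO_RADIUS

  conf <- NULL
  b <- at$b
  if (!all(is.na(b)) && all(b[!is.na(b)] >= 0) && all(b[!is.na(b)] <= 100)) {
    conf <- as.numeric(tapply(b, res_index, mean, na.rm = TRUE))
    if (any(is.na(conf))) conf <- NULL
  }
  protein_structure(id, protein_sequence(id, seq1), atoms, conf)
}

#' Write a structure as PDB text
#'
#' @param s A [protein_structure].
#' @param file Optional path; when `NULL` the PDB text is returned as a
#'   character scalar.
#' @return PDB text (invisibly when written to a file).
#' @export
write_structure <- function(s, file = NULL) {
  stopifnot(inherits(s, "protein_structure"))
  tf <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  at <- s$atoms
  res3 <- AA1TO3[strsplit(s$sequence$residues, "")[[1]]]
  b <- if (is.null(s$per_residue_confidence)) rep(0, n_residues(s)) else
    s$per_residue_confidence
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = tf, xyz = xyz,
                   resno = at$res_index,
                   resid = unname(res3[at$res_index]),
                   eleno = seq_len(nrow(at)),
                   elety = at$atom_name,
                   chain = "A",
                   o = rep(1, nrow(at)),
                   b = unname(b[at$res_index]),
                   elesy = at$element,
                   verbose = FALSE)
  if (is.null(file)) {
    txt <- paste(readLines(tf), collapse = "\n")
    unlink(tf)
    return(txt)
  }
  invisible(s)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return List of [protein_sequence] objects.
#' @export
read_fasta_sequences <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  lapply(names(recs), function(nm) protein_sequence(nm, toupper(recs[[nm]])))
}

#' Write sequences to a FASTA file
#'
#' @param seqs List of [protein_sequence] objects (or named character vector).
#' @param path Output path. Lines wrap at 60 residues.
#' @export
write_fasta_sequences <- function(seqs, path) {
  if (is.character(seqs)) {
    ids <- names(seqs)
    vals <- unname(seqs)
  } else {
    ids <- vapply(seqs, function(s) s$id, character(1))
    vals <- vapply(seqs, function(s) s$residues, character(1))
  }
  seqinr::write.fasta(as.list(vals), names = ids, file.out = path,
                      nbchar = 60, as.string = TRUE)
  invisible(path)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the atomic spheres using a deterministic
#' golden-spiral point set, so results are exactly reproducible for a fixed
#' `n_sphere_points`.
#'
#' @param s A [protein_structure].
#' @param probe_radius Probe radius in Angstrom (water, 1.4 A).
#' @param n_sphere_points Number of test points per atom (>= 92).
#' @return An object of class `sasa_result` with `per_atom_area`,
#'   `per_residue_area` and `total` (all in A^2).
#' @export
shrake_rupley_sasa <- function(s, probe_radius = PROBE_RADIUS,
                               n_sphere_points = 960) {
  stopifnot(inherits(s, "protein_structure"), n_sphere_points >= 92,
            probe_radius >= 0)
  coords <- as.matrix(s$atoms[, c("x", "y", "z")])
  if (any(!is.finite(coords))) stop("NaN or infinite coordinates")
  per_atom <- cpp_shrake_rupley(coords, s$atoms$radius, probe_radius,
                                as.integer(n_sphere_points))
  per_res <- as.numeric(tapply(per_atom, s$atoms$res_index, sum))
  structure(list(per_atom_area = as.numeric(per_atom),
                 per_residue_area = per_res,
                 total = sum(per_atom)),
            class = "sasa_result")
}

ca_reference_per_residue <- function() {
  # accessible area of an interior residue of an ideal extended C-alpha
  # chain: two neighbouring spheres at the virtual bond distance each
  # remove a spherical cap, leaving a band of area 2*pi*R*b
  2 * pi * (CA_PSEUDO_RADIUS + PROBE_RADIUS) * CA_BOND
}

#' Burial fraction (compactness proxy)
#'
#' Fraction of the linear-chain reference surface area that is buried in
#' the folded structure: `1 - folded_sasa / reference_sasa`, clamped to
#' \[0, 1\]. The reference is conformation independent: for all-atom
#' structures it is the sum of per-residue theoretical maximum accessible
#' areas (Tien-style Gly-X-Gly scale); for C-alpha-only surrogate
#' structures it is the per-residue accessible area of an ideal extended
#' C-alpha chain.
#'
#' @param s A [protein_structure] with at least 2 residues.
#' @param n_sphere_points Passed to [shrake_rupley_sasa()].
#' @return An object of class `burial_fraction` with `value`,
#'   `folded_sasa` and `reference_sasa`.
#' @export
burial_fraction <- function(s, n_sphere_points = 960) {
  stopifnot(inherits(s, "protein_structure"))
  if (n_residues(s) < 2) stop("burial fraction requires at least 2 residues")
  sasa <- shrake_rupley_sasa(s, n_sphere_points = n_sphere_points)
  if (is_ca_only(s)) {
    ref <- n_residues(s) * ca_reference_per_residue()
  } else {
    letters <- strsplit(s$sequence$residues, "")[[1]]
    missing <- setdiff(unique(letters), names(MAX_ASA_TIEN))
    if (length(missing) > 0) {
      stop("no reference area for residue(s): ", paste(missing, collapse = ", "))
    }
    ref <- sum(MAX_ASA_TIEN[letters])
  }
  value <- min(max(1 - sasa$total / ref, 0), 1)
  structure(list(value = value, folded_sasa = sasa$total, reference_sasa = ref),
            class = "burial_fraction")
}

#' @export
print.burial_fraction <- function(x, ...) {
  cat(sprintf("<burial_fraction> %.3f (folded %.1f / reference %.1f A^2)\n",
              x$value, x$folded_sasa, x$reference_sasa))
  invisible(x)
}

#' Tabulate burial fractions for a set of structures
#'
#' @param structures List of [protein_structure] objects.
#' @param ... Passed to [burial_fraction()].
#' @return data.frame with columns `id`, `length`, `burial`, `folded_sasa`,
#'   `reference_sasa` suitable for `write.table(..., sep = "\t")`.
#' @export
burial_table <- function(structures, ...) {
  rows <- lapply(structures, function(s) {
    b <- burial_fraction(s, ...)
    data.frame(id = s$id, length = n_residues(s), burial = b$value,
               folded_sasa = b$folded_sasa, reference_sasa = b$reference_sasa,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kabsch rigid-body superposition
#'
#' Least-squares optimal proper rotation (reflection corrected) and
#' translation mapping `mobile` onto `target`.
#'
#' @param mobile,target N x 3 coordinate matrices, N >= 3.
#' @return An object of class `superposition` with `rotation` (3 x 3,
#'   det +1), `translation` and `rmsd`.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) stop("coordinate sets differ in length")
  if (nrow(mobile) < 3) stop("need at least 3 points")
  if (any(!is.finite(mobile)) || any(!is.finite(target))) {
    stop("non-finite coordinates")
  }
  res <- cpp_kabsch(mobile, target)
  structure(list(rotation = res$rotation,
                 translation = as.numeric(res$translation),
                 rmsd = res$rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param sp A `superposition`.
#' @param coords N x 3 matrix.
#' @return Transformed N x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  t(sp$rotation %*% t(as.matrix(coords)) + sp$translation)
}

tm_d0 <- function(L) max(1.24 * (L - 15)^(1 / 3) - 1.8, 0.5)

#' TM-score under a fixed residue correspondence
#'
#' Length-normalised structural similarity for two equal-length structures
#' with the residue-i to residue-i correspondence, maximised over
#' fragment-seeded superpositions (seed windows of length L, L/2, ... 4,
#' each refined by iterative distance-cutoff subset selection). The
#' normalisation constant is `d0 = max(1.24 (L - 15)^(1/3) - 1.8, 0.5)`.
#'
#' @param query,template Equal-length [protein_structure] objects with CA
#'   atoms, or L x 3 CA coordinate matrices.
#' @return An object of class `tm_score` with `value`, `d0` and
#'   `aligned_length`.
#' @export
tm_score_fixed_alignment <- function(query, template) {
  qc <- if (inherits(query, "protein_structure")) ca_coords(query) else as.matrix(query)
  tc <- if (inherits(template, "protein_structure")) ca_coords(template) else as.matrix(template)
  if (nrow(qc) != nrow(tc)) stop("query and template differ in length")
  L <- nrow(qc)
  if (L < 3) stop("need at least 3 residues")
  d0 <- tm_d0(L)
  value <- cpp_tm_fixed(qc, tc, d0, 4L)
  structure(list(value = value, d0 = d0, aligned_length = L),
            class = "tm_score")
}

#' @export
print.tm_score <- function(x, ...) {
  cat(sprintf("<tm_score> %.4f (L = %d, d0 = %.2f A)\n",
              x$value, x$aligned_length, x$d0))
  invisible(x)
}
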