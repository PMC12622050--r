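# Shared fixtures, built once per test session. Everything is generated
# in code from fixed seeds; nothing is downloaded.

nf_fixtures <- local({
  env <- new.env(parent = emptyenv())
  function() {
    if (is.null(env$backends)) {
      env$refdb <- make_fixture_refdb(n_folds = 4, members_per_fold = 2,
                                      seed = 2)
      env$backends <- surrogate_backends(refdb = env$refdb)
      env$model <- energy_model(env$backends$likelihood_scorer,
                                env$backends$contact_scorer)
    }
    env
  }
})

# a deterministic set of surrogate structures for geometry tests
nf_random_structures <- function(n, length = 20, seed = 5) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    s <- paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = "")
    toy_structure_predictor(protein_sequence(sprintf("rand%02d", i), s))
  })
}

# fast letter-count energy model for sampler statistics (no lattice calls):
# energy = 0.8 * (# of V) - 0.3 * (# of A), an enumerable toy landscape
nf_toy_letter_model <- function() {
  energy_model(
    likelihood_scorer = function(s) {
      letters <- strsplit(s, "")[[1]]
      -0.8 * sum(letters == "V") + 0.3 * sum(letters == "A")
    },
    contact_scorer = function(s) 0,
    likelihood_weight = 1, contact_weight = 0)
}

# independent quaternion (Horn) superposition oracle for Kabsch tests
horn_rmsd <- function(P, Q) {
  Pc <- scale(P, scale = FALSE)
  Qc <- scale(Q, scale = FALSE)
  M <- t(Pc) %*% Qc
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    nrow = 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- (sum(Pc^2) + sum(Qc^2) - 2 * lambda) / nrow(P)
  sqrt(max(e2, 0))
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         nrow = 3, byrow = TRUE)
}
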