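# Deterministic surrogate backends.

test_that("the lattice predictor is deterministic and self-avoiding", {
  s <- paste(sample(AA_ALPHABET, 40, replace = TRUE), collapse = "")
  a <- toy_structure_predictor(s)
  b <- toy_structure_predictor(s)
  expect_identical(a$atoms, b$atoms)
  d <- as.matrix(dist(ca_coords(a)))
  diag(d) <- Inf
  expect_gte(min(d), 3.8 - 1e-9)
})

test_that("hydrophobic chains fold more compactly than polar ones", {
  polyH <- toy_structure_predictor(paste(rep("L", 40), collapse = ""))
  polyP <- toy_structure_predictor(paste(rep("S", 40), collapse = ""))
  expect_gt(burial_fraction(polyH)$value, burial_fraction(polyP)$value)
})

test_that("corpus sequences out-score their shuffles under the toy likelihood", {
  corpus <- make_fixture_corpus(n = 100, seed = 101)
  model <- toy_likelihood_model(corpus)
  set.seed(3)
  better <- vapply(corpus, function(s) {
    shuffled <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    toy_likelihood(s, model) > toy_likelihood(shuffled, model)
  }, logical(1))
  expect_gte(mean(better), 0.95)
})

test_that("toy likelihood matches a hand calculation from the fitted table", {
  model <- toy_likelihood_model(c("ACDACD", "ACDA"))
  # by hand: transitions of "ACD" is the single step A,C -> D
  expect_equal(toy_likelihood("ACD", model),
               model$logp[match("A", AA_ALPHABET), match("C", AA_ALPHABET),
                          match("D", AA_ALPHABET)])
  # mean over the two transitions of "ACDA"
  lp2 <- model$logp[match("C", AA_ALPHABET), match("D", AA_ALPHABET),
                    match("A", AA_ALPHABET)]
  expect_equal(toy_likelihood("ACDA", model),
               mean(c(toy_likelihood("ACD", model), lp2)))
  expect_error(toy_likelihood("AC", model), "at least 3")
})

test_that("contact density equals a brute-force pair count", {
  s <- paste(sample(AA_ALPHABET, 30, replace = TRUE), collapse = "")
  st <- toy_structure_predictor(s)
  co <- ca_coords(st)
  brute <- 0
  for (i in 1:(nrow(co) - 3)) {
    for (j in (i + 3):nrow(co)) {
      if (sqrt(sum((co[i, ] - co[j, ])^2)) < 8) brute <- brute + 1
    }
  }
  expect_equal(toy_contact_scorer(st), brute / nrow(co))
  expect_gte(toy_contact_scorer(s), 0)
  ext <- extended_chain_structure(paste(rep("A", 20), collapse = ""))
  expect_equal(cpp_contact_count(ca_coords(ext), 8.0, 3L), 0)
})

test_that("the inverse folder respects its noise contract", {
  tmpl <- protein_sequence("t", paste(rep("ACDEFGHIKL", 4), collapse = ""))
  same <- toy_inverse_folder(tmpl, 3, noise_rate = 0, seed = 1)
  expect_true(all(vapply(same, function(d) d$residues == tmpl$residues,
                         logical(1))))
  full <- toy_inverse_folder(tmpl, 3, noise_rate = 1, seed = 1)
  for (d in full) {
    expect_true(all(strsplit(d$residues, "")[[1]] !=
                      strsplit(tmpl$residues, "")[[1]]))
  }
  designs <- toy_inverse_folder(tmpl, 250, noise_rate = 0.2, seed = 5)
  subs <- vapply(designs, function(d) {
    sum(strsplit(d$residues, "")[[1]] != strsplit(tmpl$residues, "")[[1]])
  }, numeric(1))
  n_pos <- 250 * 40
  expect_lt(abs(sum(subs) / n_pos - 0.2), 4 * sqrt(0.2 * 0.8 / n_pos))
  # deterministic per seed
  again <- toy_inverse_folder(tmpl, 250, noise_rate = 0.2, seed = 5)
  expect_identical(vapply(again, `[[`, character(1), "residues"),
                   vapply(designs, `[[`, character(1), "residues"))
})

test_that("the energy scorer is a hand-checkable contact sum", {
  ext <- extended_chain_structure(paste(rep("L", 10), collapse = ""))
  expect_equal(toy_energy_scorer(ext), 0)
  # 5-residue toy: an L-shaped chain with one i,i+3 and one i,i+4 contact
  atoms <- data.frame(res_index = 1:5, atom_name = "CA", element = "C",
                      x = c(0, 3.8, 7.6, 7.6, 3.8),
                      y = c(0, 0, 0, 3.8, 3.8), z = 0, radius = 3.0)
  s <- protein_structure("toy5", protein_sequence("toy5", "LLSLL"), atoms)
  # pairs with |i-j| >= 3 and d < 8: (1,4) d=sqrt(7.6^2+3.8^2)>8? no ->
  # 8.497 excluded; (1,5) d=sqrt(3.8^2+3.8^2)=5.37 in; (2,5) d=3.8 in.
  # hydrophobic pairs among those (L at 1,2,4,5): (1,5) and (2,5)
  expect_equal(cpp_contact_count(ca_coords(s), 8.0, 3L), 2)
  expect_equal(toy_energy_scorer(s), -1.0 * 2 - 0.2 * 2)
  # more contacts can only lower the pseudo-energy
  compact <- toy_structure_predictor(paste(rep("L", 30), collapse = ""))
  loose <- extended_chain_structure(paste(rep("L", 30), collapse = ""))
  expect_lt(toy_energy_scorer(compact), toy_energy_scorer(loose))
})

test_that("the search engine finds library members exactly", {
  f <- nf_fixtures()
  member <- f$refdb$structures[["ref_f02_m01"]]
  hits <- toy_search_engine(member, f$refdb)
  expect_equal(hits$target_id[1], "ref_f02_m01")
  expect_equal(hits$tm_score[1], 1.0, tolerance = 1e-9)
  expect_true(all(diff(hits$tm_score) <= 1e-12))
  empty <- f$refdb
  empty$structures <- list()
  empty$labels <- empty$labels[0, ]
  expect_equal(nrow(toy_search_engine(member, empty)), 0)
})

test_that("denser window enumeration can only raise the windowed TM", {
  f <- nf_fixtures()
  set.seed(9)
  q <- toy_structure_predictor(paste(sample(AA_ALPHABET, 25, replace = TRUE),
                                     collapse = ""))
  h1 <- toy_search_engine(q, f$refdb, stride = 1)
  h5 <- toy_search_engine(q, f$refdb, stride = 5)
  for (tid in h1$target_id) {
    expect_gte(h1$tm_score[h1$target_id == tid] + 1e-12,
               h5$tm_score[h5$target_id == tid])
  }
})

test_that("fixture reference libraries are labelled and structurally distinct", {
  db1 <- make_fixture_refdb(n_folds = 1, members_per_fold = 2, seed = 4)
  expect_length(db1$structures, 2)
  expect_true(all(grepl("^1\\.11\\.1\\.[0-9]+$", db1$labels$cath_label)))
  f <- nf_fixtures()
  for (lab in f$refdb$labels$cath_label) {
    expect_length(strsplit(lab, ".", fixed = TRUE)[[1]], 4)
  }
  # within-fold similarity exceeds cross-fold similarity on average
  s11 <- ca_coords(f$refdb$structures[["ref_f01_m01"]])
  s12 <- ca_coords(f$refdb$structures[["ref_f01_m02"]])
  within <- tm_score_fixed_alignment(s11, s12)$value
  cross <- vapply(sprintf("ref_f%02d_m01", 2:4), function(id) {
    tm_score_fixed_alignment(s11, ca_coords(f$refdb$structures[[id]]))$value
  }, numeric(1))
  expect_gt(within, mean(cross))
  expect_gt(within, 0.5)
  expect_true(all(cross < 0.5))
})

test_that("reference libraries round-trip through the directory layout", {
  db <- make_fixture_refdb(n_folds = 2, members_per_fold = 1, seed = 6)
  dir <- file.path(tempdir(), "refdb_rt")
  write_refdb(db, dir)
  back <- read_refdb(dir)
  expect_setequal(names(back$structures), names(db$structures))
  expect_equal(back$labels, db$labels)
  co1 <- ca_coords(db$structures[[1]])
  co2 <- ca_coords(back$structures[[names(db$structures)[1]]])
  expect_equal(co1, co2, tolerance = 1e-3, ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})

test_that("the generator honours temperature, top-k and per-seed determinism", {
  state <- init_toy_generator(length = 30)
  cold1 <- toy_generator_sample(state, 3, top_k = 950, temperature = 0,
                                seed = 1)
  cold2 <- toy_generator_sample(state, 3, top_k = 950, temperature = 0,
                                seed = 99)
  # argmax sampling is deterministic regardless of seed
  expect_identical(unname(cold1), unname(cold2))
  expect_equal(length(unique(cold1)), 1)
  a <- toy_generator_sample(state, 10, 950, 1.5, seed = 7)
  b <- toy_generator_sample(state, 10, 950, 1.5, seed = 7)
  expect_identical(a, b)
  c <- toy_generator_sample(state, 10, 950, 1.5, seed = 8)
  expect_false(identical(unname(a), unname(c)))
  # a top-k of 50 maps to a single allowed letter per step
  k1 <- toy_generator_sample(state, 2, top_k = 50, temperature = 2, seed = 3)
  expect_identical(unname(k1)[1], unname(k1)[2])
})

test_that("every adapter in the suite honours its signature", {
  f <- nf_fixtures()
  b <- f$backends
  expect_true(is.function(b$likelihood_scorer))
  expect_true(is.numeric(b$likelihood_scorer("ACDEFGHIKL")))
  expect_lt(b$likelihood_scorer("ACDEFGHIKL"), 0)
  expect_gte(b$contact_scorer("ACDEFGHIKL"), 0)
  st <- b$structure_predictor(protein_sequence("x", "ACDEFGHIKLMNPQRSTVWY"))
  expect_s3_class(st, "protein_structure")
  designs <- b$inverse_folder(st, 4, seed = 2)
  expect_length(designs, 4)
  expect_true(all(vapply(designs, inherits, logical(1), "protein_sequence")))
  expect_true(is.numeric(b$energy_scorer(st)))
  hits <- b$search_engine(st)
  expect_true(all(c("query_id", "target_id", "tm_score", "cath_label") %in%
                    names(hits)))
  gen <- b$sequence_generator
  s0 <- gen$init()
  seqs <- gen$sample(s0, 3, 950, 1.5, 5)
  expect_length(seqs, 3)
  s1 <- gen$finetune(s0, seqs)
  expect_s3_class(s1, "toy_generator_state")
})
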