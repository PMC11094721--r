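test_that("nussinov recovers the enumeration maximum pairing", {
  expect_equal(nrow(nussinov_fold(rna_sequence("GGGAAAACCC"))$pairs), 3L)
  expect_equal(nrow(nussinov_fold(rna_sequence("AAAA"))$pairs), 0L)
  expect_equal(nrow(nussinov_fold(rna_sequence("GC"))$pairs), 0L)
  set.seed(11)
  for (k in 1:20) {
    seq <- random_rna(sample(6:12, 1))
    chars <- seq_chars(seq)
    best <- max(vapply(enum_structures(chars), NROW, 1L))
    expect_equal(nrow(nussinov_fold(seq)$pairs), best)
  }
})

test_that("constrained MFE fold matches hand-derived example", {
  model <- energy_model(pair_energies = c(GC = -3), stack_bonus = -1)
  res <- zuker_fold(hairpin_seq(), model)
  expect_equal(res$total_score, -11)         # 3 pairs * -3 + 2 stacks * -1
  expect_equal(nrow(res$structure$pairs), 3L)
  # zero pseudoenergy is a no-op
  sh0 <- shape_constraint(numeric(9), slope = 0, intercept = 0)
  expect_equal(zuker_fold(hairpin_seq(), model, sh0)$total_score, -11)
  # +10 per paired nucleotide dominates every pair: empty optimum
  sh10 <- shape_constraint(numeric(9), slope = 0, intercept = 10)
  res10 <- zuker_fold(hairpin_seq(), model, sh10)
  expect_equal(nrow(res10$structure$pairs), 0L)
  expect_equal(res10$total_score, 0)
  expect_error(zuker_fold(hairpin_seq(), model,
                          shape_constraint(numeric(4))),
               class = "fb_consistency_error")
})

test_that("MFE dynamic program equals exhaustive enumeration", {
  set.seed(7)
  model <- energy_model()
  for (k in 1:30) {
    seq <- random_rna(sample(5:12, 1))
    chars <- seq_chars(seq)
    shape <- if (k %% 2 == 0) {
      shape_constraint(runif(seq$length, 0, 1.5),
                       slope = runif(1, 0, 3),
                       intercept = runif(1, -1, 1))
    } else NULL
    pe <- if (is.null(shape)) numeric(seq$length) else
      deigan_pseudoenergy(shape$scores, shape$slope, shape$intercept)
    res <- zuker_fold(seq, model, shape)
    scores <- vapply(enum_structures(chars), oracle_score, 1.0,
                     chars = chars, pair_e = model$pair_energies,
                     stack = model$stack_bonus, pe = pe)
    expect_equal(res$total_score, min(scores), tolerance = 1e-9)
    # the returned structure really achieves that score (recomputed)
    expect_equal(score_structure(res$structure, seq, model, shape),
                 res$total_score, tolerance = 1e-9)
  }
})

test_that("raising one position's pseudoenergy never lowers the optimum", {
  set.seed(21)
  model <- energy_model()
  for (k in 1:10) {
    seq <- random_rna(15)
    s <- runif(15)
    base <- zuker_fold(seq, model, shape_constraint(s))$total_score
    s2 <- s
    i <- sample(15, 1)
    s2[i] <- s2[i] + 1          # deigan is nondecreasing in s for m >= 0
    expect_gte(zuker_fold(seq, model, shape_constraint(s2))$total_score,
               base - 1e-12)
  }
})

test_that("pair probabilities are a distribution matching enumeration", {
  m0 <- energy_model(stack_bonus = 0)
  seq <- hairpin_seq()
  P <- pair_probabilities(seq, m0)
  expect_true(all(P >= 0 & P <= 1))
  expect_true(all(rowSums(P) + colSums(P) <= 1 + 1e-12))
  chars <- seq_chars(seq)
  structs <- enum_structures(chars)
  w <- vapply(structs, function(p)
    exp(-oracle_score(p, chars, m0$pair_energies, 0, numeric(9)) / 0.6163),
    1.0)
  p08 <- sum(w[vapply(structs, function(p)
    any(p[, 1] == 0 & p[, 2] == 8), TRUE)]) / sum(w)
  expect_equal(P[1, 9], p08, tolerance = 1e-9)
  # every marginal, not just the outermost pair
  for (i in 1:8) for (j in (i + 1):9) {
    pij <- sum(w[vapply(structs, function(p)
      any(p[, 1] == i - 1 & p[, 2] == j - 1), TRUE)]) / sum(w)
    expect_equal(P[i, j], pij, tolerance = 1e-9)
  }
})

test_that("MEA folding handles short sequences and favorable pairs", {
  expect_equal(nrow(mea_fold(rna_sequence("GC"))$pairs), 0L)
  ss <- mea_fold(hairpin_seq(), gamma = 6)
  expect_gte(nrow(ss$pairs), 1L)
  # structure respects the usual invariants (constructor re-validates)
  expect_s3_class(secondary_structure(ss$pairs, ss$length), 
                  "secondary_structure")
})

test_that("energy model validation rejects non-physical settings", {
  expect_error(energy_model(stack_bonus = 0.5), class = "fb_config_error")
  expect_error(energy_model(pair_energies = c(AA = -1)),
               class = "fb_config_error")
  expect_error(energy_model(min_loop = 0), class = "fb_config_error")
})

test_that("the ensemble panel contract holds", {
  seq <- rna_sequence("AAAA")
  panel <- lapply(1:6, function(k) panel_member(paste0("nuss", k),
                                                "nussinov"))
  tracks <- ensemble_predict(seq, panel)
  expect_length(tracks, 6L)
  expect_true(all(vapply(tracks, function(t) all(t == 0L), TRUE)))
  # member order in output == member order in config
  panel2 <- default_panel()[c(3, 1, 2, 6, 5, 4)]
  tr2 <- ensemble_predict(hairpin_seq(), panel2)
  expect_equal(names(tr2), vapply(panel2, `[[`, "", "name"))
  expect_error(ensemble_predict(seq, panel[1:5]), class = "fb_config_error")
})

test_that("the default panel yields diverse tracks on a structured RNA", {
  fam <- generate_family(321, length_range = c(40L, 40L), n_members = 1L)
  tracks <- ensemble_predict(fam$members[[1]]$seq)
  expect_gte(length(unique(lapply(tracks, paste, collapse = ""))), 2L)
})

test_that("adapter members read external structure files", {
  seq <- hairpin_seq(); ss <- hairpin_ss()
  f <- withr::local_tempfile()
  writeLines(c(seq$residues, format_dotbracket(ss)), f)
  panel <- default_panel()
  panel[[1]] <- panel_member("external", "adapter", file = f)
  tracks <- ensemble_predict(seq, panel)
  expect_equal(tracks$external, pairedness(ss))
  panel[[1]] <- panel_member("missing", "adapter", file = "no/such.db")
  expect_error(ensemble_predict(seq, panel), class = "fb_input_error")
  expect_error(ensemble_predict(rna_sequence("ACGUACGU"), {
    p <- default_panel(); p[[2]] <- panel_member("external", "adapter",
                                                 file = f); p
  }), class = "fb_input_error")   # length mismatch names the member
})
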