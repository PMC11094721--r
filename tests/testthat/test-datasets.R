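test_that("random structures honor the grammar constraints", {
  set.seed(71)
  for (k in 1:10) {
    ss <- random_structure(sample(20:60, 1))
    expect_s3_class(ss, "secondary_structure")
    expect_gte(nrow(ss$pairs), 1L)
    expect_true(all(ss$pairs[, 2] - ss$pairs[, 1] - 1 >= 3))
  }
  expect_error(random_structure(5), class = "fb_config_error")
})

test_that("family members stay compatible with the family structure", {
  canonical <- c("AU", "UA", "GC", "CG", "GU", "UG")
  for (seed in c(81, 82)) {
    fam <- generate_family(seed, n_members = 4L, mutation_rate = 0.2)
    ss <- fam$members[[1]]$structure
    for (m in fam$members) {
      expect_identical(m$structure$pairs, ss$pairs)
      chars <- strsplit(m$seq$residues, "")[[1]]
      types <- paste0(chars[ss$pairs[, 1] + 1], chars[ss$pairs[, 2] + 1])
      expect_true(all(types %in% canonical))
    }
  }
})

test_that("zero mutation rate duplicates the seed sequence", {
  fam <- generate_family(83, n_members = 3L, mutation_rate = 0)
  seqs <- vapply(fam$members, function(m) m$seq$residues, "")
  expect_length(unique(seqs), 1L)
})

test_that("different family seeds give distinct sequences", {
  f1 <- generate_family(91)
  f2 <- generate_family(92)
  s1 <- vapply(f1$members, function(m) m$seq$residues, "")
  s2 <- vapply(f2$members, function(m) m$seq$residues, "")
  expect_length(intersect(s1, s2), 0L)
  # and regeneration from the same seed is identical
  expect_identical(generate_family(91)$members[[1]]$seq$residues, s1[1])
})

dummy_family <- function(name, len) {
  seq <- rna_sequence(strrep("ACGU", ceiling(len / 4)) |> substr(1, len),
                      id = name)
  structure_family(name, list(list(seq = seq,
                                   structure = secondary_structure(NULL,
                                                                   len))))
}

test_that("stratified splits preserve the length distribution", {
  fams <- lapply(1:100, function(k) dummy_family(sprintf("f%03d", k), 40L))
  sp <- stratified_family_split(fams, split_spec(test_fraction = 0.02,
                                                 seed = 2))
  expect_length(sp$test, 2L)
  expect_length(sp$train, 98L)
  # disjoint and complete
  nm <- function(fl) sort(vapply(fl, `[[`, "", "name"))
  expect_length(intersect(nm(sp$test), nm(sp$train)), 0L)
  expect_equal(sort(c(nm(sp$test), nm(sp$train))), nm(fams))
  # 200 families over several bins: per-bin test histogram within +/-1
  # of proportionality
  lens <- rep(c(30L, 80L, 130L, 180L), each = 50L)
  fams2 <- lapply(seq_along(lens), function(k)
    dummy_family(sprintf("g%03d", k), lens[k]))
  sp2 <- stratified_family_split(fams2, split_spec(test_fraction = 0.1,
                                                   seed = 3))
  got <- table(vapply(sp2$test, `[[`, 1L, "representative_length"))
  expect_true(all(abs(as.numeric(got) - 5) <= 1))
})

test_that("member capping is bounded, uniform and seeded", {
  fam_small <- generate_family(95, n_members = 3L)
  fam_big <- generate_family(96, n_members = 8L)
  capped <- cap_family_members(list(fam_small, fam_big), cap = 5L,
                               seed = 1)
  expect_length(capped[[1]]$members, 3L)
  expect_length(capped[[2]]$members, 5L)
  again <- cap_family_members(list(fam_small, fam_big), cap = 5L, seed = 1)
  expect_identical(vapply(capped[[2]]$members, function(m) m$seq$id, ""),
                   vapply(again[[2]]$members, function(m) m$seq$id, ""))
})

test_that("length-bin sampling balances bins", {
  lens <- c(seq(10L, 480L, by = 10L), 489L)
  fams <- lapply(seq_along(lens), function(k)
    dummy_family(sprintf("b%03d", k), lens[k]))
  bins <- unique(vapply(fams, `[[`, 1L, "representative_length") %/% 50L)
  expect_length(bins, 10L)
  out <- length_bin_sample(fams, bin_width = 50L, per_bin = 4L, seed = 4)
  expect_length(out, 40L)
  # a bin smaller than per_bin yields all its families
  small <- lapply(1:2, function(k) dummy_family(paste0("s", k), 20L))
  expect_length(length_bin_sample(small, per_bin = 3L, seed = 1), 2L)
})

test_that("global identity screening drops near-duplicates only", {
  a <- rna_sequence("GGGAAACCCUUUGGGAAACCC")
  expect_equal(sequence_identity(a, a), 1)
  b <- rna_sequence("GGGAAACCCUUUGGGAAACCG")   # one mismatch
  expect_gt(sequence_identity(a, b), 0.9)
  d <- rna_sequence(strrep("AU", 11) |> substr(1, 21))
  expect_lt(sequence_identity(a, d), 0.6)
  kept <- similarity_filter(list(a, d), list(b), threshold = 0.85)
  expect_equal(vapply(kept, `[[`, "", "residues"), d$residues)
  expect_length(similarity_filter(list(a, d), list(), 0.85), 2L)
})

test_that("benchmark corpora reconcile with their manifest and reproduce", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- build_benchmark(5, 30L, d1)
  man <- yaml::read_yaml(file.path(d1, "manifest.yaml"))
  fam_dirs <- list.dirs(file.path(d1, "families"), recursive = FALSE)
  expect_length(fam_dirs, man$counts$train_families +
                  man$counts$test_families)
  n_dbn <- length(list.files(d1, pattern = "\\.dbn$", recursive = TRUE))
  expect_equal(n_dbn, man$counts$train_sequences + man$counts$test_sequences)
  # no retained test sequence is >0.85 identical to any train sequence
  train_seqs <- unlist(lapply(r1$train, function(f)
    lapply(f$members, `[[`, "seq")), recursive = FALSE)
  for (fam in r1$test) for (m in fam$members) {
    ids <- vapply(train_seqs, function(t) sequence_identity(m$seq, t), 1.0)
    expect_lte(max(ids), 0.85)
  }
  # byte-identical regeneration
  build_benchmark(5, 30L, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     label = f)
  }
  # corpus reloads into equivalent families
  back <- read_benchmark(d1)
  expect_length(back$train, man$counts$train_families)
  expect_s3_class(back$train[[1]], "structure_family")
})
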