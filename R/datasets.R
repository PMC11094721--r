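#' Create a structure family
#'
#' A named group of sequences sharing one reference nested structure —
#' the atomic unit of every split, fold assignment and sampling step.
#'
#' @param name family name.
#' @param members list of `list(seq = rna_sequence, structure =
#'   secondary_structure)` entries.
#' @return object of class `structure_family` with fields `name`,
#'   `members` and `representative_length` (the longest member, which
#'   represents the family in all length binning).
#' @export
structure_family <- function(name, members) {
  if (length(members) < 1L) {
    fb_stop("a family needs at least one member", "fb_config_error")
  }
  lens <- vapply(members, function(m) m$seq$length, 1L)
  structure(list(name = name, members = members,
                 representative_length = max(lens)),
            class = "structure_family")
}

#' @export
print.structure_family <- function(x, ...) {
  cat(sprintf("<structure_family> %s: %d members, representative length %d\n",
              x$name, length(x$members), x$representative_length))
  invisible(x)
}

# ---- random nested structure grammar -------------------------------------

# Recursive helix/loop grammar over an interval. Helix lengths are
# geometric (min helix_min), hairpin/internal loop sizes uniform, and
# interiors branch into multiloops with probability branch_p. Consumes the
# current RNG stream.
sample_structure_interval <- function(i, j, opts) {
  span <- j - i + 1L
  if (span < 2L * opts$helix_min + opts$loop_min) return(NULL)
  # random offsets create bulges/dangling ends
  a <- i + sample(0:min(2L, span - 1L), 1L)
  b <- j - sample(0:min(2L, j - a), 1L)
  maxh <- (b - a + 1L - opts$loop_min) %/% 2L
  if (maxh < opts$helix_min) return(NULL)
  # helix length: min + geometric tail (continuation prob helix_p)
  h <- min(opts$helix_min + rgeom(1L, 1 - opts$helix_p), maxh)
  pairs <- cbind(a + seq_len(h) - 1L, b - seq_len(h) + 1L)
  lo <- a + h
  hi <- b - h
  inner <- NULL
  if (hi - lo + 1L >= 2L * opts$helix_min + opts$loop_min) {
    if (runif(1L) < opts$branch_p && hi - lo + 1L >=
          2L * (2L * opts$helix_min + opts$loop_min) + 1L) {
      mid <- sample(seq(lo + 2L * opts$helix_min + opts$loop_min - 1L,
                        hi - (2L * opts$helix_min + opts$loop_min)), 1L)
      inner <- rbind(sample_structure_interval(lo, mid, opts),
                     sample_structure_interval(mid + 1L, hi, opts))
    } else {
      # leave a small internal loop before the next helix
      gap <- sample(0:2, 1L)
      inner <- sample_structure_interval(lo + gap, hi - gap, opts)
    }
  }
  rbind(pairs, inner)
}

#' Sample a random nested secondary structure
#'
#' Draws from a recursive helix/loop grammar honoring the minimum hairpin
#' loop; retries (up to `max_tries`) until at least one pair forms, then
#' errors.
#'
#' @param length sequence length (>= 10).
#' @param min_loop minimum hairpin loop size.
#' @param helix_min,helix_p minimum helix length and geometric growth
#'   parameter.
#' @param loop_min smallest hairpin loop the grammar leaves open.
#' @param branch_p probability of branching into a multiloop.
#' @param max_tries resampling bound.
#' @return a `secondary_structure`.
#' @export
random_structure <- function(length, min_loop = 3L, helix_min = 2L,
                             helix_p = 0.3, loop_min = 3L,
                             branch_p = 0.25, max_tries = 100L) {
  if (length < 10L) fb_stop("length must be >= 10", "fb_config_error")
  opts <- list(helix_min = as.integer(helix_min), helix_p = helix_p,
               loop_min = max(as.integer(loop_min), as.integer(min_loop)),
               branch_p = branch_p)
  for (k in seq_len(max_tries)) {
    pairs <- sample_structure_interval(0L, length - 1L, opts)
    if (!is.null(pairs) && NROW(pairs) > 0L) {
      return(secondary_structure(pairs, length, min_loop = min_loop))
    }
  }
  fb_stop("could not sample a paired structure at this length",
          "fb_config_error")
}

pair_pool <- function(allow_gu) {
  pool <- c("GC", "CG", "AU", "UA", if (allow_gu) c("GU", "UG"))
  w <- c(0.3, 0.3, 0.15, 0.15, if (allow_gu) c(0.05, 0.05))
  list(pool = pool, w = w / sum(w))
}

#' Generate a synthetic RNA structural family
#'
#' Samples one reference nested structure, emits a seed sequence
#' compatible with it (complementary bases at paired positions, random
#' loop residues), then derives members by seeded point mutations:
#' unpaired positions mutate freely while paired positions mutate
#' compensatorily — both partners are replaced by a fresh complementary
#' pair — so every member still folds on the family structure. This
#' emulates how sequences within an Rfam-style family diverge in primary
#' sequence while conserving the secondary structure.
#'
#' @param seed integer seed (the family is a pure function of its
#'   arguments).
#' @param length_range inclusive sequence length range.
#' @param n_members member count.
#' @param mutation_rate per-position (per-pair) mutation probability.
#' @param name family name.
#' @param allow_gu include GU/UG wobble pairs in the pool.
#' @param min_loop minimum hairpin loop size.
#' @return a `structure_family`.
#' @export
generate_family <- function(seed, length_range = c(24L, 64L),
                            n_members = 4L, mutation_rate = 0.1,
                            name = sprintf("fam%05d", seed),
                            allow_gu = TRUE, min_loop = 3L) {
  if (n_members < 1L) fb_stop("n_members must be >= 1", "fb_config_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lens <- seq.int(length_range[1L], length_range[2L])
  len <- lens[sample.int(length(lens), 1L)]
  ss <- random_structure(len, min_loop = min_loop)
  pp <- pair_pool(allow_gu)
  chars <- sample(c("A", "C", "G", "U"), len, replace = TRUE)
  ptypes <- sample(pp$pool, NROW(ss$pairs), replace = TRUE, prob = pp$w)
  chars[ss$pairs[, 1L] + 1L] <- substr(ptypes, 1L, 1L)
  chars[ss$pairs[, 2L] + 1L] <- substr(ptypes, 2L, 2L)
  unpaired <- setdiff(seq_len(len), as.vector(ss$pairs) + 1L)

  members <- lapply(seq_len(n_members), function(m) {
    mchars <- chars
    if (m > 1L && mutation_rate > 0) {
      for (u in unpaired) {
        if (runif(1L) < mutation_rate) {
          mchars[u] <- sample(setdiff(c("A", "C", "G", "U"), mchars[u]), 1L)
        }
      }
      for (p in seq_len(NROW(ss$pairs))) {
        if (runif(1L) < mutation_rate) {
          nt <- sample(pp$pool, 1L, prob = pp$w)
          mchars[ss$pairs[p, 1L] + 1L] <- substr(nt, 1L, 1L)
          mchars[ss$pairs[p, 2L] + 1L] <- substr(nt, 2L, 2L)
        }
      }
    }
    list(seq = rna_sequence(paste(mchars, collapse = ""),
                            id = sprintf("%s_m%02d", name, m)),
         structure = ss)
  })
  structure_family(name, members)
}

# ---- family-wise splits and sampling -------------------------------------

#' Split specification
#'
#' @param test_fraction fraction of families reserved for the test set.
#' @param n_train_per_family_cap at most this many sequences kept per
#'   training family.
#' @param bin_width representative-length bin width (nt).
#' @param similarity_threshold global-identity threshold above which a
#'   test sequence is considered contaminated by the training set.
#' @param seed integer seed.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.02, n_train_per_family_cap = 5L,
                       bin_width = 50L, similarity_threshold = 0.85,
                       seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    fb_stop("test_fraction must be in (0, 1)", "fb_config_error")
  }
  if (bin_width < 1L) fb_stop("bin_width must be >= 1", "fb_config_error")
  structure(list(test_fraction = test_fraction,
                 n_train_per_family_cap = as.integer(n_train_per_family_cap),
                 bin_width = as.integer(bin_width),
                 similarity_threshold = similarity_threshold,
                 seed = as.integer(seed)),
            class = "split_spec")
}

rep_length_bins <- function(families, bin_width) {
  lens <- vapply(families, `[[`, 1L, "representative_length")
  lens %/% bin_width        # bin edges [0,w), [w,2w), ...
}

#' Stratified family-wise train/test split
#'
#' Families are binned by representative length and the test picks are
#' allocated proportionally across bins (largest-remainder rounding, floor
#' 0), preserving the length distribution. Sampling within bins is
#' uniform without replacement and seeded.
#'
#' @param families list of `structure_family`s (>= 2).
#' @param spec a `split_spec`.
#' @return list with `train` and `test` family lists (disjoint, complete).
#' @export
stratified_family_split <- function(families, spec = split_spec()) {
  if (length(families) < 2L) {
    fb_stop("need at least two families to split", "fb_config_error")
  }
  bins <- rep_length_bins(families, spec$bin_width)
  total <- max(1L, round(length(families) * spec$test_fraction))
  counts <- table(bins)
  exact <- as.numeric(counts) / length(families) * total
  take <- floor(exact)
  rem <- total - sum(take)
  if (rem > 0L) {
    ord <- order(exact - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  }
  take <- pmin(take, as.numeric(counts))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  test_idx <- integer(0)
  for (k in seq_along(counts)) {
    members <- which(bins == as.integer(names(counts)[k]))
    if (take[k] > 0L) {
      test_idx <- c(test_idx, sample(members, take[k]))
    }
  }
  if (length(test_idx) == 0L) {
    fb_stop("test fraction rounds to an empty test set", "fb_config_error")
  }
  list(train = families[-test_idx], test = families[test_idx])
}

#' Cap the member count of every family
#'
#' Uniform, seeded subsampling without replacement down to `cap` members.
#'
#' @param families list of `structure_family`s.
#' @param cap maximum members retained per family.
#' @param seed integer seed.
#' @return list of capped families.
#' @export
cap_family_members <- function(families, cap = 5L, seed = 1L) {
  if (cap < 1L) fb_stop("cap must be >= 1", "fb_config_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(families, function(fam) {
    if (length(fam$members) <= cap) return(fam)
    structure_family(fam$name, fam$members[sort(sample(length(fam$members),
                                                       cap))])
  })
}

#' Balanced per-bin family sampling
#'
#' Bins families by representative length and samples up to `per_bin`
#' families from each bin (all of them when a bin is smaller), mirroring
#' the length-balanced construction of independent test sets.
#'
#' @param families list of `structure_family`s.
#' @param bin_width bin width in nt.
#' @param per_bin families sampled per bin.
#' @param seed integer seed.
#' @return list of sampled families.
#' @export
length_bin_sample <- function(families, bin_width = 50L, per_bin = 4L,
                              seed = 1L) {
  if (per_bin < 1L) fb_stop("per_bin must be >= 1", "fb_config_error")
  bins <- rep_length_bins(families, bin_width)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  keep <- integer(0)
  for (b in sort(unique(bins))) {
    members <- which(bins == b)
    keep <- c(keep, if (length(members) <= per_bin) members
              else sort(sample(members, per_bin)))
  }
  families[keep]
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment (match 1, mismatch 0, gap -1);
#' identity is matches divided by alignment length. A lightweight
#' stand-in for CD-HIT's similarity screen.
#'
#' @param a,b `rna_sequence`s or plain strings.
#' @return identity in `[0, 1]`.
#' @export
sequence_identity <- function(a, b) {
  sa <- if (inherits(a, "rna_sequence")) a$residues else a
  sb <- if (inherits(b, "rna_sequence")) b$residues else b
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    chartr("U", "T", sa), chartr("U", "T", sb), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 1)
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::pattern(aln)))
}

#' Drop candidates too similar to a reference set
#'
#' Removes every candidate whose global identity to any reference
#' sequence exceeds the threshold. Set the option
#' `foldboost.cdhit_identity` to a function `(candidate_string,
#' reference_strings) -> max identity` to delegate the screen to an
#' external tool such as CD-HIT.
#'
#' @param candidates list of `rna_sequence`s (or strings).
#' @param reference list of `rna_sequence`s (or strings); empty retains
#'   everything.
#' @param threshold identity above which a candidate is dropped.
#' @return the retained subset of `candidates`.
#' @export
similarity_filter <- function(candidates, reference, threshold = 0.85) {
  if (length(reference) == 0L) return(candidates)
  hook <- getOption("foldboost.cdhit_identity", NULL)
  refs <- vapply(reference, function(r)
    if (inherits(r, "rna_sequence")) r$residues else r, "")
  keep <- vapply(candidates, function(cand) {
    cs <- if (inherits(cand, "rna_sequence")) cand$residues else cand
    maxid <- if (!is.null(hook)) hook(cs, refs)
      else max(vapply(refs, function(r) sequence_identity(cs, r), 1.0))
    maxid <= threshold
  }, TRUE)
  candidates[keep]
}

#' Generate a full synthetic benchmark corpus on disk
#'
#' Generates families, caps the training-side member counts, performs the
#' stratified family-wise split, screens every test sequence against the
#' training sequences with the identity filter, and writes
#' `families/<name>/<member>.fasta` + `.dbn` plus a `manifest.yaml`
#' recording seeds and counts. Regeneration from the manifest seed is
#' byte-identical.
#'
#' @param seed master seed.
#' @param n_families number of families to generate (>= 30).
#' @param out_dir output directory.
#' @param spec a `split_spec`.
#' @param length_range,n_members,mutation_rate forwarded to
#'   [generate_family()].
#' @return invisibly, a list with `train`, `test` family lists and the
#'   manifest.
#' @export
build_benchmark <- function(seed, n_families, out_dir,
                            spec = split_spec(seed = seed),
                            length_range = c(24L, 64L), n_members = 4L,
                            mutation_rate = 0.1) {
  if (n_families < 30L) {
    fb_stop("n_families must be >= 30", "fb_config_error")
  }
  families <- lapply(seq_len(n_families), function(k)
    generate_family(seed * 1000L + k, length_range = length_range,
                    n_members = n_members, mutation_rate = mutation_rate,
                    name = sprintf("fam%03d", k)))
  parts <- stratified_family_split(families, spec)
  train <- cap_family_members(parts$train, spec$n_train_per_family_cap,
                              seed = spec$seed)
  train_seqs <- unlist(lapply(train, function(f)
    lapply(f$members, `[[`, "seq")), recursive = FALSE)
  test <- list()
  for (fam in parts$test) {
    kept_seqs <- similarity_filter(lapply(fam$members, `[[`, "seq"),
                                   train_seqs,
                                   spec$similarity_threshold)
    kept_ids <- vapply(kept_seqs, `[[`, "", "id")
    members <- Filter(function(m) m$seq$id %in% kept_ids, fam$members)
    if (length(members) > 0L) {
      test[[length(test) + 1L]] <- structure_family(fam$name, members)
    }
  }
  if (length(test) == 0L) {
    fb_stop("the similarity filter removed the whole test set",
            "fb_config_error")
  }

  dir.create(file.path(out_dir, "families"), recursive = TRUE,
             showWarnings = FALSE)
  write_split <- function(fams, role) {
    for (fam in fams) {
      fdir <- file.path(out_dir, "families", fam$name)
      dir.create(fdir, showWarnings = FALSE)
      for (m in fam$members) {
        write_fasta(list(m$seq), file.path(fdir, paste0(m$seq$id, ".fasta")))
        writeLines(c(m$seq$residues, format_dotbracket(m$structure)),
                   file.path(fdir, paste0(m$seq$id, ".dbn")))
      }
    }
    data.frame(family = vapply(fams, `[[`, "", "name"),
               members = vapply(fams, function(f) length(f$members), 1L),
               representative_length =
                 vapply(fams, `[[`, 1L, "representative_length"),
               role = role)
  }
  manifest <- list(
    generator = "foldboost::build_benchmark",
    seed = seed, n_families = n_families,
    length_range = as.integer(length_range), n_members = n_members,
    mutation_rate = mutation_rate,
    spec = unclass(spec),
    counts = list(train_families = length(train),
                  test_families = length(test),
                  train_sequences = sum(vapply(train, function(f)
                    length(f$members), 1L)),
                  test_sequences = sum(vapply(test, function(f)
                    length(f$members), 1L))),
    families = rbind(write_split(train, "train"), write_split(test, "test")))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(train = train, test = test, manifest = manifest))
}

#' Load a benchmark corpus written by [build_benchmark()]
#'
#' @param dir corpus directory containing `manifest.yaml`.
#' @return list with `train` and `test` family lists.
#' @export
read_benchmark <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  fam_tab <- as.data.frame(manifest$families)
  load_family <- function(name) {
    fdir <- file.path(dir, "families", name)
    dbns <- sort(list.files(fdir, pattern = "\\.dbn$", full.names = TRUE))
    members <- lapply(dbns, function(f) {
      lines <- readLines(f, warn = FALSE)
      list(seq = rna_sequence(lines[1L],
                              id = sub("\\.dbn$", "", basename(f))),
           structure = parse_dotbracket(lines[2L]))
    })
    structure_family(name, members)
  }
  list(train = lapply(fam_tab$family[fam_tab$role == "train"], load_family),
       test = lapply(fam_tab$family[fam_tab$role == "test"], load_family))
}
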