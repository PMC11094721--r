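#' Lightweight nearest-pair energy model
#'
#' A deliberately small thermodynamic stand-in used by the self-contained
#' folding engines: one energy per canonical pair type, one bonus per
#' stacked pair, and a hairpin-loop constraint. Energies are kcal/mol-like
#' floats, negative = favorable.
#'
#' @param pair_energies named numeric vector over the canonical pair types
#'   `AU, UA, GC, CG, GU, UG`.
#' @param stack_bonus energy added whenever pairs `(i,j)` and `(i+1,j-1)`
#'   are both present; must be `<= 0` (stacking is a bonus, which is also
#'   what keeps the dynamic program exact).
#' @param min_loop minimum number of unpaired nucleotides in a hairpin loop.
#' @param allow_pairs subset of pair types allowed to form (defaults to all
#'   types present in `pair_energies`).
#' @return object of class `energy_model`.
#' @export
energy_model <- function(pair_energies = c(AU = -2, UA = -2, GC = -3,
                                           CG = -3, GU = -1, UG = -1),
                         stack_bonus = -1, min_loop = 3L,
                         allow_pairs = names(pair_energies)) {
  canonical <- c("AU", "UA", "GC", "CG", "GU", "UG")
  if (!all(names(pair_energies) %in% canonical)) {
    fb_stop("only canonical pair types may carry energies",
            "fb_config_error")
  }
  if (!all(allow_pairs %in% names(pair_energies))) {
    fb_stop("allow_pairs must be a subset of pair_energies",
            "fb_config_error")
  }
  if (stack_bonus > 0) {
    fb_stop("stack_bonus must be <= 0", "fb_config_error")
  }
  if (min_loop < 1L) fb_stop("min_loop must be >= 1", "fb_config_error")
  structure(list(pair_energies = pair_energies,
                 stack_bonus = stack_bonus,
                 min_loop = as.integer(min_loop),
                 allow_pairs = allow_pairs),
            class = "energy_model")
}

# l x l matrix of pair energies; +Inf where pairing is disallowed
pair_energy_matrix <- function(seq, model) {
  n <- seq$length
  chars <- seq_chars(seq)
  emat <- matrix(Inf, n, n)
  if (n < model$min_loop + 2L) return(emat)
  e <- model$pair_energies[model$allow_pairs]
  for (i in seq_len(n - model$min_loop - 1L)) {
    j <- (i + model$min_loop + 1L):n
    type <- paste0(chars[i], chars[j])
    hit <- match(type, names(e))
    ok <- !is.na(hit)
    emat[i, j[ok]] <- e[hit[ok]]
  }
  emat
}

shape_pe <- function(shape, n) {
  if (is.null(shape)) return(numeric(n))
  if (length(shape$scores) != n) {
    fb_stop("SHAPE constraint length does not match the sequence",
            "fb_consistency_error")
  }
  deigan_pseudoenergy(shape$scores, shape$slope, shape$intercept)
}

#' Maximum-pairing (Nussinov) folding
#'
#' Maximizes the number of canonical pairs subject to the hairpin-loop
#' constraint, by the standard O(l^3) recurrence with deterministic
#' tie-breaking (pairing beats bifurcation; smallest 5' index wins).
#'
#' @param seq an `rna_sequence`.
#' @param min_loop minimum hairpin loop size.
#' @param allow_pairs canonical pair types allowed to form.
#' @return a `secondary_structure`.
#' @export
nussinov_fold <- function(seq, min_loop = 3L,
                          allow_pairs = c("AU", "UA", "GC", "CG",
                                          "GU", "UG")) {
  model <- energy_model(
    pair_energies = setNames(rep(-1, length(allow_pairs)), allow_pairs),
    stack_bonus = 0, min_loop = min_loop, allow_pairs = allow_pairs)
  emat <- pair_energy_matrix(seq, model)
  res <- cpp_mfe_fold(emat, 0, as.integer(min_loop), numeric(seq$length))
  secondary_structure(res$pairs, seq$length, min_loop = min_loop)
}

#' Zuker-style soft-constrained minimum-free-energy folding
#'
#' Minimizes the sum of pair energies, stacking bonuses for adjacent pairs,
#' and — when a SHAPE-like constraint is supplied — Deigan pseudoenergies
#' added once per paired nucleotide (twice per pair). The optimal score is
#' unique even when the minimizing structure is not; the traceback is
#' deterministic under the documented tie-break.
#'
#' @param seq an `rna_sequence`.
#' @param model an `energy_model`.
#' @param shape optional `shape_constraint` of the same length as `seq`.
#' @return object of class `constrained_fold_result` with `structure`,
#'   `total_score` and `pseudoenergy_contribution`.
#' @export
zuker_fold <- function(seq, model = energy_model(), shape = NULL) {
  pe <- shape_pe(shape, seq$length)
  emat <- pair_energy_matrix(seq, model)
  res <- cpp_mfe_fold(emat, model$stack_bonus, model$min_loop, pe)
  ss <- secondary_structure(res$pairs, seq$length, min_loop = model$min_loop)
  structure(list(structure = ss,
                 total_score = res$score,
                 pseudoenergy_contribution =
                   if (NROW(ss$pairs) > 0L) sum(pe[as.vector(ss$pairs) + 1L])
                   else 0),
            class = "constrained_fold_result")
}

#' Recompute the score of a structure under a model and constraint
#'
#' Independent of the dynamic program: sums pair energies, stacking bonuses
#' for adjacent pairs, and pseudoenergies over paired positions. Used to
#' check `constrained_fold_result$total_score`.
#'
#' @inheritParams zuker_fold
#' @param ss the `secondary_structure` to score.
#' @return numeric score.
#' @export
score_structure <- function(ss, seq, model = energy_model(), shape = NULL) {
  pe <- shape_pe(shape, seq$length)
  if (NROW(ss$pairs) == 0L) return(0)
  chars <- seq_chars(seq)
  type <- paste0(chars[ss$pairs[, 1L] + 1L], chars[ss$pairs[, 2L] + 1L])
  if (!all(type %in% model$allow_pairs)) {
    fb_stop("structure contains pairs the model disallows",
            "fb_consistency_error")
  }
  pair_e <- sum(model$pair_energies[type])
  key <- paste(ss$pairs[, 1L], ss$pairs[, 2L])
  stacked <- sum(paste(ss$pairs[, 1L] + 1L, ss$pairs[, 2L] - 1L) %in% key)
  pair_e + stacked * model$stack_bonus + sum(pe[as.vector(ss$pairs) + 1L])
}

#' Base-pair probabilities from a McCaskill-style partition function
#'
#' Boltzmann ensemble over all nested structures under the model's pair
#' energies (stacking is not part of this ensemble; see the methods
#' vignette). Internal per-nucleotide rescaling guards against overflow.
#'
#' @inheritParams zuker_fold
#' @param rt thermal energy RT in the model's units (0.6163 kcal/mol at
#'   37 degrees C).
#' @return l x l upper-triangular matrix of pair probabilities.
#' @export
pair_probabilities <- function(seq, model = energy_model(), rt = 0.6163) {
  emat <- pair_energy_matrix(seq, model)
  wmat <- ifelse(is.finite(emat), exp(-emat / rt), 0)
  cpp_pair_probs(wmat, model$min_loop)
}

#' Maximum-expected-accuracy folding
#'
#' Computes pair probabilities with [pair_probabilities()] and then
#' maximizes `sum over pairs of 2*gamma*p(i,j) + sum over unpaired k of
#' q(k)` (with `q(k) = 1 - sum_j p(k,j)`) by a Nussinov-style dynamic
#' program.
#'
#' @inheritParams pair_probabilities
#' @param gamma pair-accuracy weight, > 0.
#' @return a `secondary_structure`.
#' @export
mea_fold <- function(seq, model = energy_model(), gamma = 1, rt = 0.6163) {
  if (gamma <= 0) fb_stop("gamma must be > 0", "fb_config_error")
  n <- seq$length
  if (n < model$min_loop + 2L) {
    return(secondary_structure(NULL, n, min_loop = model$min_loop))
  }
  P <- pair_probabilities(seq, model, rt)
  q <- 1 - rowSums(P) - colSums(P)
  # maximizing the gain equals minimizing its negation over the same
  # nested-structure space; pairs that do not pay for themselves are
  # never chosen because the empty alternative scores 0
  allowed <- is.finite(pair_energy_matrix(seq, model))
  emat <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    j <- which(allowed[i, ])
    if (length(j)) emat[i, j] <- -(2 * gamma * P[i, j] - q[i] - q[j])
  }
  res <- cpp_mfe_fold(emat, 0, model$min_loop, numeric(n))
  secondary_structure(res$pairs, n, min_loop = model$min_loop)
}
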