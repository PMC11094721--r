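#' SHAPE-like constraint object
#'
#' Per-position SHAPE-like scores together with the Deigan linear
#' pseudoenergy parameters (slope `m`, intercept `b`). Pipeline-produced
#' constraints satisfy `S = 1 - Y` elementwise.
#'
#' @param scores numeric vector in `[0, 1]` (high = likely unpaired).
#' @param slope,intercept Deigan parameters in energy units; the defaults
#'   (1.8, -0.6) are the widely used values of the RNAstructure family.
#' @return object of class `shape_constraint`.
#' @export
shape_constraint <- function(scores, slope = 1.8, intercept = -0.6) {
  if (!all(is.finite(scores)) || !is.finite(slope) ||
      !is.finite(intercept)) {
    fb_stop("scores and Deigan parameters must be finite",
            "fb_config_error")
  }
  if (any(scores < 0)) {
    fb_stop("SHAPE-like scores must be >= 0", "fb_domain_error")
  }
  structure(list(scores = as.numeric(scores), slope = slope,
                 intercept = intercept),
            class = "shape_constraint")
}

#' Convert pairing probabilities to SHAPE-like scores
#'
#' `S = 1 - Y`: a high pairing probability maps to a low SHAPE-like
#' reactivity, mirroring how probing reagents preferentially modify
#' flexible (unpaired) backbones.
#'
#' @param y pairing probabilities in `[0, 1]`.
#' @param slope,intercept Deigan parameters attached to the result.
#' @return a `shape_constraint` with `scores = 1 - y`.
#' @export
to_shape_scores <- function(y, slope = 1.8, intercept = -0.6) {
  if (any(y < 0 | y > 1)) {
    fb_stop("probabilities must lie in [0, 1]", "fb_domain_error")
  }
  shape_constraint(1 - y, slope, intercept)
}

#' Deigan linear pseudoenergy
#'
#' `dG(s) = m * ln(s + 1) + b`, added once per paired nucleotide in the
#' constrained dynamic program (so twice per pair).
#'
#' @param s SHAPE-like score(s), `>= 0`.
#' @param slope,intercept the linear parameters `m` and `b`.
#' @return pseudoenergy value(s).
#' @export
deigan_pseudoenergy <- function(s, slope = 1.8, intercept = -0.6) {
  if (any(s < 0)) {
    fb_stop("SHAPE-like scores must be >= 0", "fb_domain_error")
  }
  slope * log(s + 1) + intercept
}

#' Write a SHAPE score file
#'
#' Two-column dialect consumed by the RNAstructure family of tools:
#' `position(1-based) score`, one line per position — so externally
#' installed constrained folders can optionally be driven by Stage-1
#' scores.
#'
#' @param shape a `shape_constraint` (or numeric score vector).
#' @param path output path.
#' @export
write_shape_file <- function(shape, path) {
  s <- if (inherits(shape, "shape_constraint")) shape$scores else shape
  writeLines(sprintf("%d %.6f", seq_along(s), s), path)
  invisible(path)
}

#' Read a SHAPE score file
#' @param path path of a two-column `position score` file.
#' @param slope,intercept Deigan parameters for the resulting constraint.
#' @return a `shape_constraint`.
#' @export
read_shape_file <- function(path, slope = 1.8, intercept = -0.6) {
  fields <- strsplit(trimws(readLines(path, warn = FALSE)), "[ \t]+")
  fields <- fields[lengths(fields) >= 2L]
  pos <- as.integer(vapply(fields, `[`, "", 1L))
  val <- as.numeric(vapply(fields, `[`, "", 2L))
  shape_constraint(val[order(pos)], slope, intercept)
}

#' End-to-end two-stage structure prediction
#'
#' Runs the ensemble panel, encodes the `l x 10` input tensor, applies the
#' Stage-1 network in eval mode, converts the pairing probabilities to
#' SHAPE-like scores (`S = 1 - Y`) and Deigan pseudoenergies, and folds
#' with the chosen registered constrained optimizer. Deterministic given a
#' fixed checkpoint.
#'
#' @param seq an `rna_sequence` (`l >= 4`; lengths at or beyond the
#'   training padding target draw a warning, not an error — prediction is
#'   unpadded).
#' @param checkpoint a checkpoint list from [load_checkpoint()] /
#'   [train_fold()] output (needs `params`, `state`, `net_config` or
#'   `config`).
#' @param panel ensemble panel (member order must match the checkpoint).
#' @param optimizer name of a registered constrained folder (see
#'   [registered_folders()]).
#' @param slope,intercept Deigan parameters.
#' @return list with `structure` (the final `secondary_structure`),
#'   `fold` (the `constrained_fold_result`) and `diagnostics` (`y`, `s`,
#'   the per-member `tracks` and member structures).
#' @export
predict_structure <- function(seq, checkpoint, panel = default_panel(),
                              optimizer = "zuker", slope = 1.8,
                              intercept = -0.6) {
  cfg <- checkpoint$net_config %||% checkpoint$config
  if (!is.null(checkpoint$member_order)) {
    got <- vapply(panel, `[[`, "", "name")
    if (!identical(got, checkpoint$member_order)) {
      fb_stop("panel member order does not match the checkpoint",
              "fb_config_error")
    }
  }
  if (seq$length >= 512L) {
    warning("sequence length >= 512 nt; the model was trained on shorter sequences")
  }
  ens <- ensemble_predict(seq, panel, structures = TRUE)
  tensor <- build_input(seq, ens$tracks)
  y <- stage1_forward(tensor, checkpoint$params, cfg, checkpoint$state,
                      mode = "eval")
  shape <- to_shape_scores(y, slope, intercept)
  folder <- get_folder(optimizer)
  fold <- folder(seq, shape)
  list(structure = fold$structure, fold = fold,
       diagnostics = list(y = y, s = shape$scores, tracks = ens$tracks,
                          member_structures = ens$structures))
}
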