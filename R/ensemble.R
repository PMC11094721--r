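#' Define one ensemble member
#'
#' A member is either one of the in-repo engines (`nussinov`, `zuker`,
#' `mea`) with its parameters, or an `adapter` that reads an externally
#' produced structure file (dot-bracket or CT, sniffed per file) instead of
#' computing.
#'
#' @param name member label (frozen into trained checkpoints).
#' @param engine one of "nussinov", "zuker", "mea", "adapter".
#' @param model `energy_model` for the computing engines.
#' @param gamma MEA weight (mea engine only).
#' @param file structure file path (adapter engine only).
#' @param format structure file dialect for adapters ("auto", "dotbracket",
#'   "ct", "bpseq").
#' @return a `panel_member` object.
#' @export
panel_member <- function(name,
                         engine = c("nussinov", "zuker", "mea", "adapter"),
                         model = energy_model(), gamma = 1,
                         file = NULL, format = "auto") {
  engine <- match.arg(engine)
  if (engine == "adapter" && is.null(file)) {
    fb_stop(sprintf("adapter member '%s' needs a file", name),
            "fb_config_error")
  }
  structure(list(name = name, engine = engine, model = model,
                 gamma = gamma, file = file, format = format),
            class = "panel_member")
}

#' The default six-member prediction panel
#'
#' Six cheap, genuinely different single-sequence decision rules that stand
#' in for a panel of external thermodynamic predictors: maximum pairing,
#' pair-only MFE, stacking MFE, two MEA variants, and MFE with the GU
#' wobble disabled. Any member can be replaced by an adapter that reads a
#' real tool's output.
#'
#' @param model base `energy_model` shared by the members.
#' @return list of six `panel_member` objects.
#' @export
default_panel <- function(model = energy_model()) {
  nogu <- energy_model(pair_energies = model$pair_energies,
                       stack_bonus = model$stack_bonus,
                       min_loop = model$min_loop,
                       allow_pairs = c("AU", "UA", "GC", "CG"))
  nostack <- energy_model(pair_energies = model$pair_energies,
                          stack_bonus = 0, min_loop = model$min_loop,
                          allow_pairs = model$allow_pairs)
  list(panel_member("nussinov",     "nussinov", model = model),
       panel_member("mfe_nostack",  "zuker",    model = nostack),
       panel_member("mfe_stack",    "zuker",    model = model),
       panel_member("mea_g1",       "mea",      model = nostack, gamma = 1),
       panel_member("mea_g6",       "mea",      model = nostack, gamma = 6),
       panel_member("mfe_nogu",     "zuker",    model = nogu))
}

#' Run a single panel member on a sequence
#'
#' @param seq an `rna_sequence`.
#' @param member a `panel_member`.
#' @return the member's `secondary_structure`.
#' @export
run_member <- function(seq, member) {
  ss <- switch(member$engine,
    nussinov = nussinov_fold(seq, min_loop = member$model$min_loop,
                             allow_pairs = member$model$allow_pairs),
    zuker = zuker_fold(seq, member$model)$structure,
    mea = mea_fold(seq, member$model, gamma = member$gamma),
    adapter = {
      if (!file.exists(member$file)) {
        fb_stop(sprintf("adapter member '%s': file '%s' not found",
                        member$name, member$file), "fb_input_error")
      }
      read_structure_file(member$file, format = member$format,
                          min_loop = member$model$min_loop)
    })
  if (ss$length != seq$length) {
    fb_stop(sprintf("member '%s' returned a structure of length %d for a %d-nt sequence",
                    member$name, ss$length, seq$length), "fb_input_error")
  }
  ss
}

#' Run the full ensemble panel
#'
#' @param seq an `rna_sequence`.
#' @param members list of exactly six `panel_member`s (the network input
#'   encoding is six tracks wide).
#' @param structures if TRUE also return each member's structure.
#' @return named list of six pairedness tracks (integer vectors of length
#'   `seq$length`), in member order; with `structures = TRUE`, a list with
#'   elements `tracks` and `structures`.
#' @export
ensemble_predict <- function(seq, members = default_panel(),
                             structures = FALSE) {
  if (length(members) != 6L) {
    fb_stop("the panel must contain exactly 6 members", "fb_config_error")
  }
  ss <- lapply(members, function(m) run_member(seq, m))
  names(ss) <- vapply(members, `[[`, "", "name")
  tracks <- lapply(ss, pairedness)
  if (structures) list(tracks = tracks, structures = ss) else tracks
}

# ---- registry of constrained folding optimizers (Stage 2) ----------------

.folders <- new.env(parent = emptyenv())

#' Register a constrained folding optimizer
#'
#' Optimizers take `(seq, shape, ...)` and return a
#' `constrained_fold_result`; Stage 2 can be pointed at any registered
#' optimizer to probe robustness of the pipeline against the folder choice.
#'
#' @param name optimizer name.
#' @param fn function `(seq, shape)` returning a `constrained_fold_result`.
#' @export
register_folder <- function(name, fn) {
  assign(name, fn, envir = .folders)
  invisible(name)
}

#' Names of the registered constrained folding optimizers
#' @return character vector.
#' @export
registered_folders <- function() sort(ls(.folders))

get_folder <- function(name) {
  if (!exists(name, envir = .folders, inherits = FALSE)) {
    fb_stop(sprintf("unknown optimizer '%s'; registered: %s", name,
                    paste(registered_folders(), collapse = ", ")),
            "fb_config_error")
  }
  get(name, envir = .folders, inherits = FALSE)
}

register_default_folders <- function() {
  model <- energy_model()
  register_folder("zuker", function(seq, shape = NULL)
    zuker_fold(seq, model, shape))
  register_folder("zuker_nostack", function(seq, shape = NULL)
    zuker_fold(seq, energy_model(pair_energies = model$pair_energies,
                                 stack_bonus = 0,
                                 min_loop = model$min_loop), shape))
  register_folder("zuker_nogu", function(seq, shape = NULL)
    zuker_fold(seq, energy_model(pair_energies = model$pair_energies,
                                 stack_bonus = model$stack_bonus,
                                 min_loop = model$min_loop,
                                 allow_pairs = c("AU", "UA", "GC", "CG")),
               shape))
}

.onLoad <- function(libname, pkgname) {
  register_default_folders()
}
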