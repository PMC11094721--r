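#' Run the scaled-down synthetic benchmark experiment
#'
#' The package's end-to-end experiment at desk scale: generate a corpus of
#' synthetic structural families, hold out a stratified test split, train
#' the Stage-1 labeling network on the remaining families, and evaluate
#' (i) Stage-1 structure-location labeling against the unanimity consensus
#' baseline, (ii) pair-level F1 of every ensemble member, and (iii)
#' pair-level F1 of the full two-stage pipeline under each requested
#' constrained optimizer. All randomness derives from `seed`.
#'
#' @param seed master seed for corpus generation and training.
#' @param n_families number of synthetic families.
#' @param test_fraction fraction of families held out.
#' @param net_config Stage-1 architecture (desk scale by default).
#' @param train_config training preset (desk scale by default).
#' @param panel ensemble panel.
#' @param optimizers registered constrained folders to evaluate in Stage 2.
#' @param slope,intercept Deigan parameters for Stage 2.
#' @return list with `model` (the [train_fold()] result), `label`
#'   (data.frame of per-RNA labeling F1 for the network and the consensus),
#'   `pair` (data.frame of per-RNA pair F1 per member and per optimizer)
#'   and `summary` (named medians).
#' @export
run_synthetic_benchmark <- function(seed = 1L, n_families = 60L,
                                    test_fraction = 0.2,
                                    net_config = desk_network_config(),
                                    train_config =
                                      training_config("desk", seed = seed),
                                    panel = default_panel(),
                                    optimizers = c("zuker",
                                                   "zuker_nostack"),
                                    slope = 1.8, intercept = -0.6) {
  families <- lapply(seq_len(n_families), function(k)
    generate_family(seed * 1000L + k, name = sprintf("fam%03d", k)))
  parts <- stratified_family_split(
    families, split_spec(test_fraction = test_fraction, seed = seed))
  model <- train_fold(parts$train, parts$test, net_config, train_config,
                      panel)

  truths <- unlist(lapply(parts$test, `[[`, "members"), recursive = FALSE)
  test_ex <- prepare_examples(parts$test, panel)
  label_rows <- list()
  pair_rows <- list()
  for (k in seq_along(test_ex)) {
    ex <- test_ex[[k]]
    truth <- truths[[k]]$structure
    y <- stage1_forward(ex$tensor, model$params, net_config, model$state,
                        mode = "eval")
    label_rows[[k]] <- data.frame(
      rna = ex$seq$id,
      network = label_metrics(as.integer(y >= 0.5), ex$target)[["f1"]],
      consensus = label_metrics(consensus_labels(ex$tracks),
                                ex$target)[["f1"]])
    member_f1 <- vapply(panel, function(m)
      pair_metrics(run_member(ex$seq, m), truth)[["f1"]], 1.0)
    names(member_f1) <- vapply(panel, `[[`, "", "name")
    shape <- to_shape_scores(y, slope, intercept)
    boosted <- vapply(optimizers, function(o)
      pair_metrics(get_folder(o)(ex$seq, shape)$structure, truth)[["f1"]],
      1.0)
    names(boosted) <- paste0("boosted_", optimizers)
    pair_rows[[k]] <- data.frame(rna = ex$seq$id, t(c(member_f1, boosted)))
  }
  label <- do.call(rbind, label_rows)
  pair <- do.call(rbind, pair_rows)
  med <- vapply(pair[, -1, drop = FALSE], median, 1.0)
  summary <- c(stage1_label_f1 = median(label$network),
               consensus_label_f1 = median(label$consensus),
               med)
  list(model = model, label = label, pair = pair, summary = summary,
       n_test_rnas = nrow(label),
       n_train_families = length(parts$train),
       n_test_families = length(parts$test))
}
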