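#' One-hot encode a sequence
#'
#' Fixed column order A, C, G, U; row k is the unit vector of residue k.
#'
#' @param seq an `rna_sequence`.
#' @return l x 4 binary matrix.
#' @export
one_hot <- function(seq) {
  chars <- seq_chars(seq)
  idx <- match(chars, c("A", "C", "G", "U"))
  if (anyNA(idx)) fb_stop("non-ACGU residue", "fb_alphabet_error")
  m <- matrix(0, seq$length, 4L, dimnames = list(NULL, c("A", "C", "G", "U")))
  m[cbind(seq_len(seq$length), idx)] <- 1
  m
}

#' Build the l x 10 network input tensor
#'
#' Column-stacks the one-hot sequence encoding (columns 1-4) and the six
#' ensemble pairedness tracks (columns 5-10) in fixed member order.
#'
#' @param seq an `rna_sequence`.
#' @param tracks list of six binary tracks of length `seq$length`.
#' @return object of class `input_tensor`: list with `values` (l x 10
#'   matrix), `true_length` and `mask`.
#' @export
build_input <- function(seq, tracks) {
  if (length(tracks) != 6L) {
    fb_stop("exactly 6 ensemble tracks are required", "fb_consistency_error")
  }
  if (any(lengths(tracks) != seq$length)) {
    fb_stop("track length does not match the sequence",
            "fb_consistency_error")
  }
  if (any(unlist(tracks) != 0 & unlist(tracks) != 1)) {
    fb_stop("tracks must be binary", "fb_consistency_error")
  }
  values <- cbind(one_hot(seq), do.call(cbind, lapply(tracks, as.numeric)))
  colnames(values) <- c("A", "C", "G", "U",
                        if (!is.null(names(tracks))) names(tracks)
                        else paste0("member", 1:6))
  structure(list(values = values, true_length = seq$length,
                 mask = rep(1L, seq$length)),
            class = "input_tensor")
}

#' Zero-pad a batch of input tensors to a common length
#'
#' Training batches are padded along the position axis so they can be
#' stacked; prediction never pads — the network is applied per sequence at
#' its native length.
#'
#' @param tensors list of `input_tensor`s.
#' @param target padded length (the training default is 512).
#' @return list with `values` (list of target x 10 matrices, original
#'   order) and `masks` (list of binary vectors with `true_length` leading
#'   ones).
#' @export
pad_batch <- function(tensors, target = 512L) {
  lens <- vapply(tensors, `[[`, 1L, "true_length")
  if (any(lens > target)) {
    fb_stop(sprintf("sequence of length %d exceeds the padding target %d",
                    max(lens), target), "fb_length_error")
  }
  values <- lapply(tensors, function(t) {
    rbind(t$values,
          matrix(0, target - t$true_length, ncol(t$values)))
  })
  masks <- lapply(lens, function(l) c(rep(1L, l), rep(0L, target - l)))
  list(values = values, masks = masks)
}

#' Recover the sequence and tracks from an input tensor
#'
#' Inverse of [build_input()] on real (non-padded) positions; used to check
#' that the encoding is lossless.
#'
#' @param tensor an `input_tensor`.
#' @return list with `residues` (string) and `tracks` (list of 6 vectors).
#' @export
decode_input <- function(tensor) {
  v <- tensor$values[seq_len(tensor$true_length), , drop = FALSE]
  residues <- paste(c("A", "C", "G", "U")[max.col(v[, 1:4, drop = FALSE])],
                    collapse = "")
  list(residues = residues,
       tracks = lapply(5:10, function(k) as.integer(v[, k])))
}

#' Dump an input tensor as TSV (debug aid)
#' @param tensor an `input_tensor`.
#' @param path output path.
#' @export
write_input_tsv <- function(tensor, path) {
  utils::write.table(tensor$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
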