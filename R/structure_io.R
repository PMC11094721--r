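#' @useDynLib foldboost, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rbinom runif rnorm setNames aggregate rgeom
#' @importFrom utils head write.csv
NULL

# condition helper: every package error carries a distinct class so callers
# (and tests) can discriminate format vs consistency vs unsupported-feature
fb_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fb_error")))
}

#' Create an RNA sequence object
#'
#' Canonicalizes the residues (case-folded, `T` silently converted to `U`)
#' and validates that only the four standard nucleotides remain. Sequences
#' over any other alphabet are rejected rather than coerced.
#'
#' @param residues single string of residues (A/C/G/U, `T` accepted).
#' @param id sequence identifier.
#' @return an object of class `rna_sequence` with fields `id`, `residues`
#'   and `length`.
#' @examples
#' rna_sequence("gggaaaccc", id = "hairpin")
#' @export
rna_sequence <- function(residues, id = "seq") {
  if (length(residues) != 1L || !is.character(residues)) {
    fb_stop("residues must be a single string", "fb_format_error")
  }
  res <- chartr("tT", "uU", residues)
  res <- toupper(res)
  if (nchar(res) < 1L) fb_stop("empty sequence", "fb_format_error")
  if (grepl("[^ACGU]", res)) {
    fb_stop(sprintf("sequence '%s' contains non-ACGU residues", id),
            "fb_alphabet_error")
  }
  structure(list(id = id, residues = res, length = nchar(res)),
            class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (%d nt)\n", x$id, x$length))
  invisible(x)
}

seq_chars <- function(seq) strsplit(seq$residues, "", fixed = TRUE)[[1]]

#' Create a secondary structure object
#'
#' A nested set of base pairs over a sequence of length `length`. Pairs are
#' 0-based `(i, j)` tuples with `i < j`. Construction enforces the three
#' structural invariants: each position pairs at most once, no two pairs
#' cross, and every hairpin loop spans at least `min_loop` unpaired
#' nucleotides.
#'
#' @param pairs integer matrix with two columns (0-based indices), or NULL /
#'   0-row matrix for the open chain.
#' @param length sequence length (nt).
#' @param min_loop minimum hairpin loop size (default 3).
#' @return object of class `secondary_structure` with fields `pairs`
#'   (ordered two-column matrix) and `length`.
#' @export
secondary_structure <- function(pairs, length, min_loop = 3L) {
  length <- as.integer(length)
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
  }
  colnames(pairs) <- c("i", "j")
  if (NROW(pairs) > 0L) {
    if (any(pairs < 0L) || any(pairs >= length)) {
      fb_stop("pair index out of range", "fb_consistency_error")
    }
    flip <- pairs[, 1L] > pairs[, 2L]
    pairs[flip, ] <- pairs[flip, c(2L, 1L)]
    if (any(pairs[, 1L] == pairs[, 2L])) {
      fb_stop("a position cannot pair with itself", "fb_consistency_error")
    }
    if (anyDuplicated(as.vector(pairs))) {
      fb_stop("a position participates in more than one pair",
              "fb_consistency_error")
    }
    if (any(pairs[, 2L] - pairs[, 1L] - 1L < min_loop)) {
      fb_stop(sprintf("hairpin loop shorter than min_loop = %d", min_loop),
              "fb_consistency_error")
    }
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    if (has_crossing(pairs)) {
      fb_stop("crossing base pairs (pseudoknot) are not supported",
              "fb_pseudoknot_error")
    }
  }
  structure(list(pairs = pairs, length = length),
            class = "secondary_structure")
}

# pairs sorted by i; crossing iff i < k <= j < m for some pair (k, m)
has_crossing <- function(pairs) {
  np <- NROW(pairs)
  if (np < 2L) return(FALSE)
  for (a in seq_len(np - 1L)) {
    i <- pairs[a, 1L]; j <- pairs[a, 2L]
    k <- pairs[(a + 1L):np, 1L]; m <- pairs[(a + 1L):np, 2L]
    if (any(k <= j & m > j)) return(TRUE)
  }
  FALSE
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d pairs\n", x$length,
              NROW(x$pairs)))
  invisible(x)
}

#' Per-position pairedness track of a structure
#'
#' @param ss a `secondary_structure`.
#' @return integer vector of length `ss$length`; 1 where the position
#'   participates in a pair, 0 elsewhere.
#' @export
pairedness <- function(ss) {
  v <- integer(ss$length)
  if (NROW(ss$pairs) > 0L) v[as.vector(ss$pairs) + 1L] <- 1L
  v
}

#' Parse a dot-bracket string
#'
#' Matches `(` with `)` via a stack; `.` marks unpaired positions. Extended
#' pseudoknot alphabets (`[`, `{`, letters) are rejected with a distinct
#' error rather than silently dropped.
#'
#' @param text dot-bracket string.
#' @param min_loop minimum hairpin loop size enforced on the result.
#' @return a `secondary_structure`.
#' @examples
#' parse_dotbracket("((((...))))")
#' @export
parse_dotbracket <- function(text, min_loop = 3L) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("(", ")", "."))) {
    bad <- setdiff(unique(chars), c("(", ")", "."))
    if (any(bad %in% c("[", "]", "{", "}", "<", ">")) ||
        any(grepl("[A-Za-z]", bad))) {
      fb_stop("multi-layer bracket alphabets (pseudoknots) are not supported",
              "fb_pseudoknot_error")
    }
    fb_stop(sprintf("invalid dot-bracket characters: %s",
                    paste(bad, collapse = " ")), "fb_format_error")
  }
  stack <- integer(0)
  pairs <- list()
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k - 1L)
    } else if (chars[k] == ")") {
      if (length(stack) == 0L) {
        fb_stop("unbalanced brackets: unmatched ')'", "fb_format_error")
      }
      pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], k - 1L)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) {
    fb_stop("unbalanced brackets: unmatched '('", "fb_format_error")
  }
  secondary_structure(do.call(rbind, pairs), length(chars),
                      min_loop = min_loop)
}

#' Format a structure as a dot-bracket string
#'
#' @param ss a `secondary_structure`.
#' @return dot-bracket string of length `ss$length`.
#' @export
format_dotbracket <- function(ss) {
  chars <- rep(".", ss$length)
  if (NROW(ss$pairs) > 0L) {
    chars[ss$pairs[, 1L] + 1L] <- "("
    chars[ss$pairs[, 2L] + 1L] <- ")"
  }
  paste(chars, collapse = "")
}

partner_vector <- function(ss) {
  # 1-based partner per position, 0 if unpaired (CT/BPSEQ convention)
  p <- integer(ss$length)
  if (NROW(ss$pairs) > 0L) {
    p[ss$pairs[, 1L] + 1L] <- ss$pairs[, 2L] + 1L
    p[ss$pairs[, 2L] + 1L] <- ss$pairs[, 1L] + 1L
  }
  p
}

pairs_from_partner <- function(partner) {
  idx <- which(partner > 0L & partner > seq_along(partner))
  if (length(idx) == 0L) return(NULL)
  cbind(idx - 1L, partner[idx] - 1L)
}

check_partner_symmetry <- function(partner) {
  for (k in which(partner > 0L)) {
    if (partner[k] > length(partner) || partner[partner[k]] != k) {
      fb_stop("inconsistent partner annotations", "fb_format_error")
    }
  }
}

#' Write a sequence + structure as CT text
#'
#' Standard 6-column CT (RNAstructure dialect): index, base, previous index,
#' next index, 1-based pairing partner (0 when unpaired), index.
#'
#' @param seq an `rna_sequence`.
#' @param ss a matching `secondary_structure`.
#' @return a single CT string (lines separated by newline).
#' @export
format_ct <- function(seq, ss) {
  if (seq$length != ss$length) {
    fb_stop("sequence and structure lengths differ", "fb_consistency_error")
  }
  n <- seq$length
  bases <- seq_chars(seq)
  partner <- partner_vector(ss)
  lines <- c(sprintf("%d %s", n, seq$id),
             sprintf("%d %s %d %d %d %d", seq_len(n), bases,
                     seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L),
                     partner, seq_len(n)))
  paste(lines, collapse = "\n")
}

#' Parse CT text
#'
#' @param text CT-format text (single string or character vector of lines).
#' @param min_loop minimum hairpin loop size enforced on the result.
#' @return list with `seq` (`rna_sequence`) and `structure`
#'   (`secondary_structure`).
#' @export
parse_ct <- function(text, min_loop = 3L) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) fb_stop("truncated CT input", "fb_format_error")
  header <- strsplit(lines[1L], "[ \t]+")[[1]]
  n <- suppressWarnings(as.integer(header[1L]))
  if (is.na(n) || length(lines) - 1L < n) {
    fb_stop("CT header count does not match data lines", "fb_format_error")
  }
  id <- if (length(header) > 1L) paste(header[-1L], collapse = " ") else "ct"
  fields <- strsplit(lines[1L + seq_len(n)], "[ \t]+")
  bases <- vapply(fields, `[`, "", 2L)
  partner <- vapply(fields, function(f) {
    v <- suppressWarnings(as.integer(f[5L]))
    if (is.na(v)) fb_stop("malformed CT data line", "fb_format_error")
    v
  }, 1L)
  check_partner_symmetry(partner)
  seq <- rna_sequence(paste(bases, collapse = ""), id = id)
  ss <- tryCatch(
    secondary_structure(pairs_from_partner(partner), n, min_loop = min_loop),
    fb_pseudoknot_error = function(e) stop(e))
  list(seq = seq, structure = ss)
}

#' Write a sequence + structure as BPSEQ text
#'
#' bpRNA dialect: one `index base partner` line per position, 1-based,
#' partner 0 when unpaired.
#' @param seq an `rna_sequence`.
#' @param ss a matching `secondary_structure`.
#' @return a single BPSEQ string.
#' @export
format_bpseq <- function(seq, ss) {
  if (seq$length != ss$length) {
    fb_stop("sequence and structure lengths differ", "fb_consistency_error")
  }
  paste(sprintf("%d %s %d", seq_len(seq$length), seq_chars(seq),
                partner_vector(ss)), collapse = "\n")
}

#' Parse BPSEQ text
#'
#' @inheritParams parse_ct
#' @return list with `seq` and `structure`.
#' @export
parse_bpseq <- function(text, min_loop = 3L) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) fb_stop("empty BPSEQ input", "fb_format_error")
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 3L)) {
    fb_stop("malformed BPSEQ line", "fb_format_error")
  }
  idx <- as.integer(vapply(fields, `[`, "", 1L))
  if (!identical(idx, seq_along(idx))) {
    fb_stop("BPSEQ indices must be 1..n in order", "fb_format_error")
  }
  bases <- vapply(fields, `[`, "", 2L)
  partner <- as.integer(vapply(fields, `[`, "", 3L))
  check_partner_symmetry(partner)
  seq <- rna_sequence(paste(bases, collapse = ""), id = "bpseq")
  list(seq = seq,
       structure = secondary_structure(pairs_from_partner(partner),
                                       length(idx), min_loop = min_loop))
}

#' Read a multi-record FASTA file
#'
#' @param path FASTA file path.
#' @return list of `rna_sequence` objects (T canonicalized to U).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("[ \t].*$", "", names(set))
  lapply(seq_along(set),
         function(k) rna_sequence(as.character(set[[k]]), id = ids[k]))
}

#' Write sequences to a FASTA file
#'
#' @param seqs list of `rna_sequence` objects.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  lines <- unlist(lapply(seqs, function(s) c(paste0(">", s$id), s$residues)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a structure file for an external-predictor adapter
#'
#' Accepts dot-bracket (a structure line, optionally preceded by a FASTA-ish
#' header and sequence line), CT, or BPSEQ; the dialect is sniffed per file
#' unless forced.
#'
#' @param path file path.
#' @param format one of "auto", "dotbracket", "ct", "bpseq".
#' @param min_loop minimum hairpin loop size.
#' @return a `secondary_structure`.
#' @export
read_structure_file <- function(path,
                                format = c("auto", "dotbracket", "ct",
                                           "bpseq"),
                                min_loop = 3L) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) fb_stop("empty structure file", "fb_format_error")
  if (format == "auto") {
    db_line <- grepl("^[().]+$", trimws(lines))
    format <- if (any(db_line)) "dotbracket"
      else if (length(strsplit(trimws(lines[1L]), "[ \t]+")[[1]]) >= 3L &&
               length(strsplit(trimws(lines[length(lines)]), "[ \t]+")[[1]]) == 3L)
        "bpseq" else "ct"
  }
  switch(format,
    dotbracket = {
      db <- trimws(lines[grepl("^[().]+$", trimws(lines))])
      if (length(db) == 0L) fb_stop("no dot-bracket line", "fb_format_error")
      parse_dotbracket(db[[1L]], min_loop = min_loop)
    },
    ct = parse_ct(paste(lines, collapse = "\n"), min_loop)$structure,
    bpseq = parse_bpseq(paste(lines, collapse = "\n"), min_loop)$structure)
}
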