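# Independent brute-force oracles used to check the dynamic programs and
# network layers. Everything here is a naive loop implementation, written
# without reference to the package internals it checks.

# all nested structures over a sequence (0-based pair matrices)
enum_structures <- function(chars, min_loop = 3,
                            allow = c("AU", "UA", "GC", "CG", "GU", "UG")) {
  rec <- function(i, j) {
    if (j - i + 1 < min_loop + 2) return(list(matrix(integer(0), ncol = 2)))
    out <- rec(i, j - 1)
    for (k in i:(j - min_loop - 1)) {
      if (!(paste0(chars[k + 1], chars[j + 1]) %in% allow)) next
      left <- if (k - 1 >= i) rec(i, k - 1)
              else list(matrix(integer(0), ncol = 2))
      inner <- rec(k + 1, j - 1)
      for (L in left) for (I in inner) {
        out[[length(out) + 1]] <- rbind(L, I, c(k, j))
      }
    }
    out
  }
  rec(0, length(chars) - 1)
}

# true energy of a structure: pair energies + stacks + per-nucleotide
# pseudoenergies (summed plainly, no optimality shortcuts)
oracle_score <- function(pairs, chars, pair_e, stack, pe) {
  if (NROW(pairs) == 0) return(0)
  type <- paste0(chars[pairs[, 1] + 1], chars[pairs[, 2] + 1])
  key <- paste(pairs[, 1], pairs[, 2])
  n_stack <- sum(paste(pairs[, 1] + 1, pairs[, 2] - 1) %in% key)
  sum(pair_e[type]) + n_stack * stack + sum(pe[as.vector(pairs) + 1])
}

random_rna <- function(n) {
  rna_sequence(paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                     collapse = ""))
}

# naive loop stride-2 convolution: out[i] reads 2i-1, 2i, 2i+1 (0-based)
oracle_conv <- function(X, K) {
  L <- nrow(X); n <- dim(K)[3]
  Lout <- ceiling(L / 2)
  out <- matrix(0, Lout, n)
  for (i in seq_len(Lout) - 1) {
    for (j in seq_len(n)) {
      acc <- 0
      for (t in -1:1) {
        p <- 2 * i + t
        if (p >= 0 && p <= L - 1) {
          acc <- acc + sum(K[t + 2, , j] * X[p + 1, ])
        }
      }
      out[i + 1, j] <- acc
    }
  }
  out
}

# naive loop transpose convolution via the explicit extension tensor
oracle_tconv <- function(F_, K) {
  M <- nrow(F_); cc <- ncol(F_); n <- dim(K)[3]
  E <- matrix(0, 2 * M, cc)
  E[seq(1, 2 * M, by = 2), ] <- F_
  out <- matrix(0, 2 * M, n)
  for (i in seq_len(2 * M) - 1) {
    for (j in seq_len(n)) {
      acc <- 0
      for (t in -1:1) {
        p <- i + t
        if (p >= 0 && p <= 2 * M - 1) {
          acc <- acc + sum(K[t + 2, , j] * E[p + 1, ])
        }
      }
      out[i + 1, j] <- acc
    }
  }
  out
}

# naive multi-head attention with explicit per-row softmax loops
oracle_attention <- function(Q, K, V, proj, heads) {
  hd <- dim(proj$Wq)[2]
  out <- matrix(0, nrow(Q), hd * heads)
  for (h in seq_len(heads)) {
    Qh <- Q %*% proj$Wq[, , h]
    Kh <- K %*% proj$Wk[, , h]
    Vh <- V %*% proj$Wv[, , h]
    for (r in seq_len(nrow(Q))) Qh[r, ] <- Qh[r, ] + proj$bq[, h]
    for (r in seq_len(nrow(K))) Kh[r, ] <- Kh[r, ] + proj$bk[, h]
    for (r in seq_len(nrow(V))) Vh[r, ] <- Vh[r, ] + proj$bv[, h]
    for (r in seq_len(nrow(Q))) {
      s <- as.numeric(Kh %*% Qh[r, ]) / sqrt(hd)
      a <- exp(s - max(s)); a <- a / sum(a)
      out[r, (h - 1) * hd + seq_len(hd)] <- as.numeric(t(Vh) %*% a)
    }
  }
  out
}

# a tiny deterministic hairpin fixture shared across files
hairpin_seq <- function() rna_sequence("GGGAAACCC", id = "hairpin")
hairpin_ss <- function() secondary_structure(
  cbind(c(0, 1, 2), c(8, 7, 6)), 9)

# small synthetic families without the full generator (cheap fixtures)
toy_family <- function(name, len, seed) {
  generate_family(seed, length_range = c(len, len), n_members = 2L,
                  mutation_rate = 0.05, name = name)
}
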