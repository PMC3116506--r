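# Independent oracles. These deliberately avoid the package's own code
# paths: the alignment oracle is a memoized recursion over explicit edit
# sequences, the binomial oracles use choose() arithmetic or outcome
# enumeration, and the chi-square / BH oracles are written out by hand.

# Best affine-gap score over all alignments: read consumed fully, reference
# tail free; each maximal gap run costs open + extend * length.
oracle_align_score <- function(read, ref, match = 2, mismatch = 1,
                               open = 1, ext = 10) {
  n <- nchar(read); m <- nchar(ref)
  rc <- strsplit(read, "")[[1]]
  fc <- strsplit(ref, "")[[1]]
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(i, j, prev) {
    if (i > n) return(0) # free reference tail
    key <- paste(i, j, prev)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- -Inf
    if (j <= m) {
      s <- if (rc[i] == fc[j]) match else -mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "M"))
      best <- max(best, -(ext + if (prev == "X") 0 else open) +
                    rec(i, j + 1L, "X"))
    }
    best <- max(best, -(ext + if (prev == "Y") 0 else open) +
                  rec(i + 1L, j, "Y"))
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, "M")
}

# P(X >= (N+1)/2), X ~ Bin(N, p), from explicit choose() arithmetic
oracle_majority <- function(N, p) {
  k <- ((N + 1) / 2):N
  sum(choose(N, k) * p^k * (1 - p)^(N - k))
}

# P(X <= k) by enumeration of all 2^N outcomes (tiny N only)
oracle_binom_cdf_enum <- function(N, p, k) {
  grid <- expand.grid(rep(list(c(0L, 1L)), N))
  cnt <- rowSums(grid)
  w <- p^cnt * (1 - p)^(N - cnt)
  sum(w[cnt <= k])
}

# Pearson chi-square written out by hand
oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Benjamini-Hochberg step-up, hand implementation
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# wrap a pair of gapped strings as an alignment object for classify_errors
mk_aln <- function(ref_aln, read_aln, read_id = "r", ref_id = "ref") {
  structure(list(read_id = read_id, ref_id = ref_id,
                 aligned_read = read_aln, aligned_ref = ref_aln,
                 score = NA_real_,
                 ref_end = nchar(gsub("-", "", ref_aln))),
            class = "pyro_alignment")
}

# reconstruct the read from its reference and calls (round-trip check)
apply_calls <- function(ref_seq, calls) {
  chars <- strsplit(ref_seq, "")[[1]]
  covered <- max(calls$ref_pos)
  out <- character(0)
  for (p in seq_len(covered)) {
    rows <- calls[calls$ref_pos == p, , drop = FALSE]
    rows <- rows[order(rows$read_pos), , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      ty <- rows$error_type[i]
      if (ty == "none") out <- c(out, chars[p])
      else if (ty == "deletion") NULL
      else if (ty == "ambiguous") out <- c(out, "N")
      else if (ty == "mismatch") out <- c(out, "?") # base unknown from calls
      else if (ty == "insertion") out <- c(out, "+") # inserted base unknown
    }
  }
  paste(out, collapse = "")
}
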