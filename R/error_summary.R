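#' Normal-approximation binomial confidence interval
#'
#' `p +/- 1.96 * sqrt(p * (1 - p) / n)`, the interval form used for all
#' rate and fraction summaries.
#'
#' @param p point estimate (proportion in `[0, 1]`).
#' @param n number of trials.
#' @return `c(lower, upper)` on the proportion scale.
#' @export
binom_ci <- function(p, n) {
  half <- 1.96 * sqrt(p * (1 - p) / n)
  c(lower = p - half, upper = p + half)
}

# Per-read bookkeeping shared by summaries and spatial maps. Evaluated
# positions are the aligned columns attributed to a read: its bases
# (insertions included, since an inserted base is a read base) plus its
# deletion columns. For a numeric window w (read coordinates from the 5'
# end) the denominator is min(w, read length) + deletions with read_pos <= w.
per_read_stats <- function(calls, reads, window = "full") {
  if (is.numeric(window)) {
    if (window < 1) stop("window must be >= 1 or \"full\"")
    if (window > max(reads$length))
      stop("empty evaluation: window (", window,
           ") exceeds every read length")
    calls <- calls[calls$read_pos <= window, , drop = FALSE]
  }
  f <- factor(calls$read_id, levels = reads$id)
  ty <- factor(calls$error_type, levels = .pyro_call_states)
  tab <- table(f, ty)
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  base_len <- if (is.numeric(window)) pmin(window, reads$length) else reads$length
  evaluated <- as.integer(base_len) + counts[, "deletion"]
  ref_map <- calls$ref_id[!duplicated(calls$read_id)]
  names(ref_map) <- calls$read_id[!duplicated(calls$read_id)]
  n_err <- rowSums(counts[, .pyro_error_types, drop = FALSE])
  data.frame(read_id = reads$id,
             ref_id = unname(ref_map[reads$id]),
             plate = if ("plate" %in% names(reads)) reads$plate else NA,
             evaluated = evaluated,
             insertion = counts[, "insertion"],
             deletion = counts[, "deletion"],
             mismatch = counts[, "mismatch"],
             ambiguous = counts[, "ambiguous"],
             n_errors = n_err,
             stringsAsFactors = FALSE)
}

#' Accuracy and quality summary per reference and overall
#'
#' For each reference (plus a `Total` row): the number of sequences, the
#' number of evaluated positions, the per-type and total error rates as
#' percentages with 95% normal-approximation binomial confidence
#' intervals, the per-sequence median rate `q_1/2` for each type, and the
#' percentage of error-free sequences (no call of any error type in the
#' window) with its interval. The window is measured in read coordinates
#' from the 5' end (the first sequenced bases), mapped through the
#' alignment; `window = "full"` evaluates entire reads.
#'
#' @param calls a call table including `none` rows (see [call_errors()]).
#' @param reads the `pyro_reads` table the calls were made from.
#' @param window integer number of read bases, or `"full"`.
#' @return A `data.frame` with one row per reference plus `Total`.
#' @export
summarize_errors <- function(calls, reads, window = "full") {
  prs <- per_read_stats(calls, reads, window)
  prs <- prs[!is.na(prs$ref_id), , drop = FALSE]
  groups <- c(split(prs, prs$ref_id), list(Total = prs))
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    npos <- sum(d$evaluated)
    one <- function(k) {
      p <- sum(d[[k]]) / npos
      ci <- binom_ci(p, npos)
      c(rate = 100 * p, lo = 100 * ci[["lower"]], hi = 100 * ci[["upper"]],
        q50 = 100 * median(d[[k]] / d$evaluated))
    }
    per_type <- lapply(.pyro_error_types, one)
    names(per_type) <- .pyro_error_types
    tot <- one("n_errors")
    ef <- mean(d$n_errors == 0L)
    efci <- binom_ci(ef, nrow(d))
    out <- data.frame(ref_id = g, n_sequences = nrow(d), n_positions = npos,
                      stringsAsFactors = FALSE)
    for (t in .pyro_error_types) {
      v <- per_type[[t]]
      out[[paste0(t, "_pct")]] <- v[["rate"]]
      out[[paste0(t, "_lo")]] <- v[["lo"]]
      out[[paste0(t, "_hi")]] <- v[["hi"]]
      out[[paste0(t, "_q50")]] <- v[["q50"]]
    }
    out$total_pct <- tot[["rate"]]
    out$total_lo <- tot[["lo"]]
    out$total_hi <- tot[["hi"]]
    out$total_q50 <- tot[["q50"]]
    out$error_free_pct <- 100 * ef
    out$error_free_lo <- 100 * efci[["lower"]]
    out$error_free_hi <- 100 * efci[["upper"]]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-position error and coverage profile for one reference
#'
#' For every reference position: the fraction of assigned reads whose
#' aligned span still extends to that position, and the per-type error
#' rate among the covering reads.
#'
#' @param calls a call table including `none` rows.
#' @param reads the `pyro_reads` table.
#' @param ref a reference id or 1-row `pyro_refs` table.
#' @return A `data.frame` with columns `ref_pos`, `coverage`, and one rate
#'   column per error type.
#' @export
position_profile <- function(calls, reads, ref) {
  rid <- if (is.character(ref)) ref else ref_id(ref)
  cc <- calls[calls$ref_id == rid, , drop = FALSE]
  if (nrow(cc) == 0L) stop("no calls for reference ", rid)
  span <- tapply(cc$ref_pos, cc$read_id, max)
  n_assigned <- length(span)
  L <- max(cc$ref_pos)
  covering <- rev(cumsum(rev(tabulate(span, nbins = L))))
  err <- cc[cc$error_type != "none", , drop = FALSE]
  rates <- sapply(.pyro_error_types, function(t) {
    cnt <- tabulate(err$ref_pos[err$error_type == t], nbins = L)
    ifelse(covering > 0, cnt / covering, 0)
  })
  out <- data.frame(ref_pos = seq_len(L),
                    coverage = covering / n_assigned)
  out <- cbind(out, as.data.frame(rates))
  out
}

#' Write a summary or profile table as TSV
#'
#' @param x a data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
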