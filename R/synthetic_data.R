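#' Generate a reference sequence with controlled homopolymer structure
#'
#' Builds a random template containing exactly `n_homopolymers` maximal runs
#' of three or more identical bases, no two closer than 3 bp, with a GC
#' fraction within 0.02 of `gc_target`. This emulates the spiked-in control
#' fragments, which are a few hundred bp long with a large number of
#' homopolymers, without shipping the proprietary sequences themselves; the
#' output is synthetic.
#'
#' @param length target length in bp.
#' @param gc_target target GC fraction in (0, 1).
#' @param n_homopolymers exact number of maximal runs of length >= 3.
#' @param homopolymer_lengths optional vector of run lengths (3-6, recycled
#'   or sampled when `NULL`).
#' @param seed integer seed; the same seed reproduces the same sequence.
#' @param id sequence identifier.
#' @return A one-row `pyro_refs` table.
#' @export
generate_reference <- function(length, gc_target, n_homopolymers,
                               homopolymer_lengths = NULL, seed = 1L,
                               id = "synthetic_ref") {
  stopifnot(length >= 1, gc_target > 0, gc_target < 1, n_homopolymers >= 0)
  set.seed(as.integer(seed))
  n <- as.integer(n_homopolymers)
  hp_len <- if (n == 0L) integer(0)
  else if (is.null(homopolymer_lengths))
    sample(3:6, n, replace = TRUE, prob = c(0.5, 0.25, 0.15, 0.10))
  else rep_len(as.integer(homopolymer_lengths), n)
  if (any(hp_len < 3L)) stop("homopolymer lengths must be >= 3")

  spacer_min <- if (n > 1L) 3L * (n - 1L) else 0L
  free <- length - sum(hp_len) - spacer_min
  if (free < 0L)
    stop("infeasible: ", n, " homopolymers of total length ", sum(hp_len),
         " (+ spacers) exceed sequence length ", length)

  # gap sizes: internal gaps >= 3, ends >= 0, remainder spread at random
  gaps <- c(0L, rep(3L, max(0L, n - 1L)), 0L)[seq_len(n + 1L)]
  if (n == 0L) gaps <- length
  extra <- free
  if (n >= 1L && extra > 0L) {
    add <- tabulate(sample.int(n + 1L, extra, replace = TRUE), n + 1L)
    gaps <- gaps + add
  }

  bases <- c("A", "C", "G", "T")
  is_gc <- c(FALSE, TRUE, TRUE, FALSE)
  pick <- function(allowed) {
    w <- ifelse(is_gc[match(allowed, bases)], gc_target, 1 - gc_target)
    sample(allowed, 1L, prob = w)
  }
  run_base <- character(n)
  for (k in seq_len(n)) run_base[k] <- pick(bases)

  seq_out <- character(0)
  for (k in seq_len(n + 1L)) {
    prev_run <- if (k > 1L) run_base[k - 1L] else NA_character_
    next_run <- if (k <= n) run_base[k] else NA_character_
    g <- gaps[k]
    if (g > 0L) {
      gap <- character(g)
      for (i in seq_len(g)) {
        last1 <- if (i > 1L) gap[i - 1L]
        else if (length(seq_out)) seq_out[length(seq_out)] else NA_character_
        last2 <- if (i > 2L) gap[i - 2L]
        else if (i == 2L && length(seq_out)) seq_out[length(seq_out)]
        else if (i == 1L && length(seq_out) > 1L) seq_out[length(seq_out) - 1L]
        else NA_character_
        allowed <- bases
        if (i == 1L && !is.na(prev_run)) allowed <- setdiff(allowed, prev_run)
        if (i == g && !is.na(next_run)) allowed <- setdiff(allowed, next_run)
        if (!is.na(last1) && !is.na(last2) && last1 == last2)
          allowed <- setdiff(allowed, last1)
        gap[i] <- pick(allowed)
      }
      seq_out <- c(seq_out, gap)
    }
    if (k <= n) seq_out <- c(seq_out, rep(run_base[k], hp_len[k]))
  }

  seq_out <- adjust_gc(seq_out, gc_target, tol = 0.02)
  out <- data.frame(id = id, bases = paste(seq_out, collapse = ""),
                    length = length(seq_out), stringsAsFactors = FALSE)
  class(out) <- c("pyro_refs", "data.frame")
  if (count_homopolymers(out) != n)
    stop("internal error: homopolymer count drifted during generation")
  out
}

# Flip A/T <-> C/G at positions where the swap creates no run of 3 and does
# not touch a run boundary, until GC is within tol of the target.
adjust_gc <- function(chars, gc_target, tol) {
  is_gc <- function(b) b %in% c("C", "G")
  n <- length(chars)
  safe_swap <- function(i, new) {
    old <- chars[i]
    chars[i] <- new
    lo <- max(1L, i - 2L); hi <- min(n, i + 2L)
    win <- chars[lo:hi]
    ok <- !any(rle(win)$lengths >= 3L)
    chars[i] <- old
    ok
  }
  for (iter in seq_len(4L * n)) {
    gc <- mean(is_gc(chars))
    if (abs(gc - gc_target) <= tol) break
    want_gc <- gc < gc_target
    cand <- which(is_gc(chars) != want_gc)
    cand <- cand[sample.int(length(cand))]
    done <- FALSE
    for (i in cand) {
      repl <- if (want_gc) sample(c("C", "G"), 1L) else sample(c("A", "T"), 1L)
      # only flip positions not inside a run of >= 2 to keep runs intact
      left <- if (i > 1L) chars[i - 1L] else ""
      right <- if (i < n) chars[i + 1L] else ""
      if (chars[i] == left || chars[i] == right) next
      if (safe_swap(i, repl)) { chars[i] <- repl; done <- TRUE; break }
    }
    if (!done) stop("infeasible: cannot reach GC target ", gc_target,
                    " within 0.02 under homopolymer constraints")
  }
  if (abs(mean(is_gc(chars)) - gc_target) > tol)
    stop("infeasible: cannot reach GC target ", gc_target)
  chars
}

#' Synthetic stand-ins for the six control DNA fragments
#'
#' Six synthetic references with the published lengths (572, 552, 500, 532,
#' 592, 516 bp), GC contents spanning 0.53-0.66 and homopolymer counts
#' between 20 and 34. These stand in for the proprietary Roche control
#' fragment Type I sequences, which cannot be redistributed; only their
#' printed summary characteristics are reproduced.
#'
#' @param seed integer seed.
#' @return A six-row `pyro_refs` table.
#' @export
synthetic_control_refs <- function(seed = 20110519L) {
  spec <- data.frame(
    id = paste0("ref", 1:6),
    length = c(572L, 552L, 500L, 532L, 592L, 516L),
    gc = c(0.53, 0.66, 0.55, 0.58, 0.62, 0.60),
    nhp = c(24L, 28L, 20L, 22L, 34L, 26L)
  )
  out <- do.call(rbind, lapply(seq_len(6L), function(i) {
    generate_reference(spec$length[i], spec$gc[i], spec$nhp[i],
                       seed = seed + i, id = spec$id[i])
  }))
  class(out) <- c("pyro_refs", "data.frame")
  out
}

#' Simulator configuration
#'
#' The generative model injects at most one event per covered reference
#' position, drawn from a single categorical draw whose per-type
#' probabilities follow a logistic link:
#' `logit p_t = qlogis(baseline_t) + beta_position_t * (pos/len) +`
#' `beta_homopolymer[code, t] + beta_y_t * y_norm + region_offset`,
#' where `y_norm` is the within-region normalized y coordinate (regions are
#' congruent vertical strips, so this equals the plate-normalized y). Read
#' length is then truncated: with probability `full_length_prob` a read is
#' full length, otherwise the covered length is drawn uniformly between
#' `min_length` and the reference length, emulating the decline in read
#' numbers beyond ~300 bases caused by 3' quality trimming.
#'
#' Default baselines are back-calculated so that, combined with the default
#' slopes, realized full-length type rates land near the published
#' Titanium control-read profile (insertions ~0.5%, deletions ~0.35%,
#' mismatch/ambiguous ~0.1% each); defaults for the slopes encode the
#' reported structure (indels enriched in homopolymers, all types rising
#' toward the 3' end, opposite y gradients for insertions and deletions).
#'
#' @param n_reads reads per reference per plate.
#' @param plates character vector of plate identifiers.
#' @param baseline named per-type baseline probabilities (at position 0,
#'   homopolymer code 0, y_norm 0, no region offset).
#' @param beta_position per-type slope on position as a fraction of
#'   reference length.
#' @param beta_homopolymer 6 x 4 matrix of effects, rows = codes
#'   (0,1,3,4,5,6), columns = (insertion, deletion, mismatch, ambiguous).
#' @param beta_y per-type slope on the normalized y coordinate.
#' @param region_offsets `n_regions` x 4 matrix of per-region logit offsets
#'   (default all zero).
#' @param full_length_prob probability that a read is untrimmed.
#' @param min_length minimum covered reference length after trimming, bp.
#' @param n_regions number of congruent vertical strip regions per plate.
#' @param seed integer seed driving all randomness.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_reads = 2000L,
                       plates = paste0("plate", 1:3),
                       baseline = c(insertion = 0.0021, deletion = 0.0030,
                                    mismatch = 4e-04, ambiguous = 3e-04),
                       beta_position = c(insertion = 1.0, deletion = 0.5,
                                         mismatch = 1.5, ambiguous = 2.0),
                       beta_homopolymer = default_hp_effects(),
                       beta_y = c(insertion = 0.5, deletion = -0.5,
                                  mismatch = 0, ambiguous = 0),
                       region_offsets = NULL,
                       full_length_prob = 0.25, min_length = 300L,
                       n_regions = 15L, seed = 1L) {
  baseline <- unlist(baseline)[.pyro_error_types]
  if (anyNA(baseline) || any(baseline < 0) || any(baseline > 1))
    stop("baseline must give probabilities in [0,1] for all four error types")
  beta_position <- rep_len(unlist(beta_position), 4L)
  beta_y <- rep_len(unlist(beta_y), 4L)
  if (is.null(region_offsets)) region_offsets <- matrix(0, n_regions, 4L)
  region_offsets <- as.matrix(region_offsets)
  if (nrow(region_offsets) != n_regions || ncol(region_offsets) != 4L)
    stop("region_offsets must be n_regions x 4")
  bh <- as.matrix(beta_homopolymer)
  if (nrow(bh) != 6L || ncol(bh) != 4L)
    stop("beta_homopolymer must be 6 x 4 (codes 0,1,3,4,5,6 by error type)")
  rownames(bh) <- as.character(.pyro_hp_codes)
  if (min_length < 1L) stop("min_length must be >= 1")
  if (n_regions < 1L) stop("need at least one region")
  cfg <- list(n_reads = as.integer(n_reads), plates = as.character(plates),
              baseline = baseline, beta_position = beta_position,
              beta_homopolymer = bh, beta_y = beta_y,
              region_offsets = region_offsets,
              full_length_prob = full_length_prob,
              min_length = as.integer(min_length),
              n_regions = as.integer(n_regions), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_hp_effects <- function() {
  m <- rbind(`0` = c(0, 0, 0, 0),
             `1` = c(0.2, 0.2, 0, 0),
             `3` = c(0.5, 0.8, 0, 0),
             `4` = c(0.7, 1.0, 0, 0),
             `5` = c(0.9, 1.2, 0, 0),
             `6` = c(1.1, 1.4, 0, 0))
  colnames(m) <- .pyro_error_types
  m
}

#' Simulate 454-like reads with a truth log
#'
#' For each plate and reference, beads are placed uniformly within a region
#' chosen uniformly among `n_regions` congruent vertical strips of the unit
#' plate, the covered reference length is drawn from the read-length model,
#' and each covered position receives at most one error event under the
#' logistic link described in [sim_config()]. Insertions add a random base
#' after the position, deletions remove the base, mismatches substitute a
#' different base, ambiguous events write `N`. Every injected event is
#' recorded in the truth log. The same configuration (including seed)
#' reproduces the output bit for bit.
#'
#' @param refs a `pyro_refs` table.
#' @param cfg a [sim_config()] object.
#' @param codes optional precomputed [homopolymer_codes()] list.
#' @return A list with elements `reads` (a `pyro_reads` table), `truth`
#'   (list with `events`: read_id/ref_id/ref_pos/error_type, and
#'   `read_info`: read_id/ref_id/plate/covered_length), and `config`.
#' @export
simulate_reads <- function(refs, cfg = sim_config(), codes = NULL) {
  stopifnot(inherits(cfg, "sim_config"), nrow(refs) >= 1L)
  if (is.null(codes)) codes <- homopolymer_codes(refs)
  set.seed(cfg$seed)
  R <- cfg$n_regions
  type_names <- .pyro_error_types

  reads_acc <- list()
  ev_acc <- list()
  info_acc <- list()
  k <- 0L
  for (plate in cfg$plates) {
    for (i in seq_len(nrow(refs))) {
      k <- k + 1L
      rid <- refs$id[i]
      L <- refs$length[i]
      code <- as.character(codes[[rid]])
      A <- matrix(0, L, 4L)
      for (t in 1:4) {
        A[, t] <- qlogis(cfg$baseline[t]) +
          cfg$beta_position[t] * (seq_len(L) / L) +
          cfg$beta_homopolymer[code, t]
      }
      n <- cfg$n_reads
      region <- sample.int(R, n, replace = TRUE)
      x <- round((region - 1L) / R + runif(n) / R, 6)
      y <- round(runif(n), 6)
      y_norm <- y # vertical strips span the full plate height
      B <- outer(y_norm, cfg$beta_y) + cfg$region_offsets[region, , drop = FALSE]
      full <- runif(n) < cfg$full_length_prob
      mn <- min(cfg$min_length, L)
      tlen <- ifelse(full, L, floor(runif(n, mn, L + 1e-9)))
      tlen <- pmin(pmax(as.integer(tlen), 1L), L)
      sim <- cpp_inject_errors(refs$bases[i], A, B, tlen)
      ids <- sprintf("%s_%s_%04d", plate, rid, seq_len(n))
      reads_acc[[k]] <- data.frame(
        id = ids, bases = as.character(sim$sequences), plate = plate,
        region = region, x = x, y = y,
        length = nchar(as.character(sim$sequences)),
        stringsAsFactors = FALSE)
      ev_acc[[k]] <- data.frame(
        read_id = ids[sim$ev_read], ref_id = rep(rid, length(sim$ev_read)),
        ref_pos = sim$ev_pos, error_type = type_names[sim$ev_type],
        stringsAsFactors = FALSE)
      info_acc[[k]] <- data.frame(
        read_id = ids, ref_id = rid, plate = plate,
        covered_length = tlen, stringsAsFactors = FALSE)
    }
  }
  reads <- do.call(rbind, reads_acc)
  class(reads) <- c("pyro_reads", "data.frame")
  list(reads = reads,
       truth = list(events = do.call(rbind, ev_acc),
                    read_info = do.call(rbind, info_acc)),
       config = cfg)
}

#' Write a simulation truth log as TSV
#'
#' @param truth the `truth` element of a [simulate_reads()] result.
#' @param path output path prefix; writes `<path>` (events) and the per-read
#'   info next to it with suffix `.info.tsv`.
#' @export
write_truth <- function(truth, path) {
  write.table(truth$events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$read_info, paste0(path, ".info.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
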