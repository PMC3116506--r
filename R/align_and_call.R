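#' Alignment scoring parameters
#'
#' Score = sum of match/mismatch terms minus, for each maximal gap run,
#' `gap_open + gap_extend * length`. The gap penalties default to the pair
#' retained after the original penalty screen (open 1, extend 10), which
#' strongly favors short gaps; the substitution scores were never part of
#' that screen and are exposed as free parameters.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (>= 0, subtracted).
#' @param gap_open gap opening penalty (>= 0).
#' @param gap_extend per-base gap extension penalty (>= 0).
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = 1, gap_open = 1, gap_extend = 10) {
  if (mismatch < 0 || gap_open < 0 || gap_extend < 0)
    stop("penalties must be >= 0")
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

#' Assign a read to its best-matching reference
#'
#' Replaces the original BLASTn sorting step with a shared k-mer count:
#' the read is assigned to the reference sharing the largest number of
#' distinct k-mers (default k = 11). Ties are broken by full alignment
#' score, then by reference order (with a warning).
#'
#' @param read a read: character string or 1-row `pyro_reads` table.
#' @param refs a `pyro_refs` table.
#' @param k k-mer size; the read must be at least k bases long.
#' @param params [align_params()] used only for tie-breaking.
#' @param kmer_index optional precomputed [build_kmer_index()].
#' @return A list with `ref_id` and `score` (the shared k-mer count).
#' @export
assign_reference <- function(read, refs, k = 11L, params = align_params(),
                             kmer_index = NULL) {
  b <- ref_bases(read)
  if (nchar(b) < k) stop("read shorter than k-mer size (", k, ")")
  if (is.null(kmer_index)) kmer_index <- build_kmer_index(refs, k)
  km <- unique(substring(b, seq_len(nchar(b) - k + 1L),
                         k:nchar(b)))
  shared <- vapply(kmer_index, function(set) sum(km %in% set), 0L)
  best <- max(shared)
  cand <- which(shared == best)
  if (length(cand) > 1L) {
    scores <- vapply(cand, function(i) {
      cpp_align_affine(b, refs$bases[i], params$match, params$mismatch,
                       params$gap_open, params$gap_extend)$score
    }, 0)
    top <- cand[scores == max(scores)]
    if (length(top) > 1L)
      warning("ambiguous reference assignment for read ",
              ref_id(read) %||% "?", "; keeping first by input order")
    cand <- top[1L]
  }
  list(ref_id = refs$id[cand[1L]], score = best)
}

#' @rdname assign_reference
#' @export
build_kmer_index <- function(refs, k = 11L) {
  out <- lapply(refs$bases, function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, seq_len(nchar(s) - k + 1L), k:nchar(s)))
  })
  names(out) <- refs$id
  out
}

#' Optimal affine-gap alignment of a read against its reference
#'
#' Global on the read; the reference overhang beyond the read's 3' end is
#' free (reads are quality-trimmed prefixes of the template, so penalizing
#' the uncovered tail would miscount deletions). Deterministic
#' tie-breaking: at equal score, match/mismatch is preferred over a
#' read-side gap (deletion), which is preferred over a reference-side gap
#' (insertion).
#'
#' @param read read sequence (string or 1-row `pyro_reads` table).
#' @param ref reference sequence (string or 1-row `pyro_refs` table).
#' @param params an [align_params()] object.
#' @return A list of class `pyro_alignment`: `read_id`, `ref_id`,
#'   `aligned_read`, `aligned_ref` (equal-length gapped strings), `score`,
#'   and `ref_end`, the last covered reference position.
#' @export
align_affine <- function(read, ref, params = align_params()) {
  rb <- ref_bases(read)
  fb <- ref_bases(ref)
  if (nchar(rb) < 1L || nchar(fb) < 1L) stop("sequences must be non-empty")
  aln <- cpp_align_affine(rb, fb, params$match, params$mismatch,
                          params$gap_open, params$gap_extend)
  structure(list(read_id = ref_id(read), ref_id = ref_id(ref),
                 aligned_read = aln$aligned_read,
                 aligned_ref = aln$aligned_ref,
                 score = aln$score, ref_end = aln$ref_end),
            class = "pyro_alignment")
}

#' Classify every aligned position of a read
#'
#' Emits one call per reference position covered by the read plus one call
#' per inserted base. A reference-gap column is an insertion, reported at
#' the 1-based reference position of the base preceding the gap run (an
#' insertion before position 1 is anchored to position 1 with a warning); a
#' read-gap column is a deletion at that reference position; differing
#' bases are a mismatch, a read `N` is an ambiguous call, identical bases
#' are `none`. Reference positions beyond the covered span produce no call.
#'
#' @param aln a `pyro_alignment`.
#' @return A `data.frame` with columns `read_id`, `ref_id`, `ref_pos`,
#'   `error_type`, `read_pos`.
#' @export
classify_errors <- function(aln) {
  stopifnot(inherits(aln, "pyro_alignment"))
  rc <- strsplit(aln$aligned_ref, "", fixed = TRUE)[[1]]
  qc <- strsplit(aln$aligned_read, "", fixed = TRUE)[[1]]
  if (length(rc) != length(qc)) stop("aligned strings differ in length")
  if (any(rc == "-" & qc == "-")) stop("alignment column with two gaps")
  ref_gap <- rc == "-"
  read_gap <- qc == "-"
  ref_pos <- cumsum(!ref_gap)
  read_pos <- cumsum(!read_gap)
  if (any(ref_gap & ref_pos == 0L)) {
    warning("insertion before reference position 1; anchored to position 1")
  }
  type <- ifelse(ref_gap, "insertion",
          ifelse(read_gap, "deletion",
          ifelse(qc == "N", "ambiguous",
          ifelse(qc == rc, "none", "mismatch"))))
  data.frame(read_id = aln$read_id %||% NA_character_,
             ref_id = aln$ref_id %||% NA_character_,
             ref_pos = pmax(ref_pos, 1L),
             error_type = type,
             read_pos = as.integer(read_pos),
             stringsAsFactors = FALSE)
}

#' Assign, align and classify a whole read set
#'
#' Convenience driver for the per-read pipeline stage: each read is
#' assigned to its reference by shared k-mers, aligned with affine gaps,
#' and classified position by position.
#'
#' @param reads a `pyro_reads` table.
#' @param refs a `pyro_refs` table.
#' @param params an [align_params()] object.
#' @param k k-mer size for reference assignment.
#' @return A call table (columns `read_id`, `ref_id`, `ref_pos`,
#'   `error_type`, `read_pos`) covering every evaluated position of every
#'   read, `none` rows included.
#' @export
call_errors <- function(reads, refs, params = align_params(), k = 11L) {
  idx <- build_kmer_index(refs, k)
  ref_lookup <- setNames(seq_len(nrow(refs)), refs$id)
  acc <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rd <- reads[i, ]
    asg <- assign_reference(rd, refs, k = k, params = params,
                            kmer_index = idx)
    aln <- align_affine(rd, refs[ref_lookup[[asg$ref_id]], ], params)
    acc[[i]] <- classify_errors(aln)
  }
  out <- do.call(rbind, acc)
  rownames(out) <- NULL
  out
}
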