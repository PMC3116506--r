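#' Per-position homopolymer coding of a reference sequence
#'
#' A homopolymer is a maximal run of three or more identical bases. The
#' coding scheme marks the first and last base of each run, plus up to two
#' flanking positions on either side (clipped at the sequence ends), with
#' code 1; strictly interior run positions carry the run length, capped at
#' 6; everything else is 0. Code 2 never occurs. Interior codes take
#' precedence where the flank zone of one run overlaps the interior of an
#' adjacent run.
#'
#' @param ref a reference: a character string, or a 1-row `pyro_refs` table.
#' @return An integer vector of codes over \{0,1,3,4,5,6\}, one per
#'   reference position, with the reference id in attribute `ref_id`.
#' @export
annotate_homopolymers <- function(ref) {
  b <- ref_bases(ref)
  chars <- strsplit(b, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("A", "C", "G", "T")))
    stop("reference contains characters outside A/C/G/T")
  n <- length(chars)
  codes <- integer(n)
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$lengths >= 3L)
  for (k in runs) { # flank + boundary zone first
    lo <- max(1L, starts[k] - 2L)
    hi <- min(n, ends[k] + 2L)
    codes[lo:hi] <- 1L
  }
  for (k in runs) { # interior codes win over any overlapping flank zone
    s <- starts[k]; e <- ends[k]
    if (e - s >= 2L) codes[(s + 1L):(e - 1L)] <- min(r$lengths[k], 6L)
  }
  attr(codes, "ref_id") <- ref_id(ref)
  codes
}

#' Count homopolymers in a reference sequence
#'
#' @inheritParams annotate_homopolymers
#' @return The number of maximal runs of length >= 3.
#' @export
count_homopolymers <- function(ref) {
  chars <- strsplit(ref_bases(ref), "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("A", "C", "G", "T")))
    stop("reference contains characters outside A/C/G/T")
  sum(rle(chars)$lengths >= 3L)
}

#' Homopolymer codes for a reference set
#'
#' @param refs a `pyro_refs` table.
#' @return A named list of code vectors, one per reference.
#' @export
homopolymer_codes <- function(refs) {
  out <- lapply(seq_len(nrow(refs)), function(i) annotate_homopolymers(refs[i, ]))
  names(out) <- refs$id
  out
}

#' Write per-position homopolymer codes as TSV
#'
#' Columns `ref_id`, `pos`, `code`.
#' @param codes a list from [homopolymer_codes()].
#' @param path output path.
#' @export
write_homopolymer_codes <- function(codes, path) {
  df <- do.call(rbind, lapply(names(codes), function(id) {
    data.frame(ref_id = id, pos = seq_along(codes[[id]]),
               code = as.integer(codes[[id]]), stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ref_bases <- function(ref) {
  if (is.character(ref) && length(ref) == 1L) return(toupper(ref))
  if (is.data.frame(ref) && nrow(ref) == 1L) return(ref$bases)
  if (is.list(ref) && !is.null(ref$bases)) return(ref$bases)
  stop("expected a single sequence (string or one-row table)")
}

ref_id <- function(ref) {
  if (is.character(ref) && length(ref) == 1L) return(NA_character_)
  if ((is.data.frame(ref) || is.list(ref)) && !is.null(ref$id)) return(ref$id)
  NA_character_
}
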