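#' Read reference or read sequences from FASTA
#'
#' References are plain FASTA records over A/C/G/T. Reads additionally carry
#' bead location metadata in a whitespace-separated `key=value` dialect on
#' the header line: `>read1 plate=P1 region=3 x=100.0 y=200.0`. Real 454
#' read identifiers encode the well location opaquely; this explicit dialect
#' replaces it so that plate/region/coordinate information survives a round
#' trip through FASTA.
#'
#' @param path path to a FASTA file.
#' @param expect_metadata if `TRUE`, parse `plate`, `region`, `x`, `y` from
#'   each header and return a read table; otherwise return a reference table.
#' @return A `data.frame` with one row per record, in file order. References:
#'   columns `id`, `bases`, `length` (class `pyro_refs`). Reads: columns
#'   `id`, `bases`, `plate`, `region`, `x`, `y`, `length`
#'   (class `pyro_reads`).
#' @export
read_fasta <- function(path, expect_metadata = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) {
    return(if (expect_metadata) empty_reads() else empty_refs())
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA in ", path, ": line ", nonblank[1],
         " does not start a record ('>' expected)")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  headers <- trimws(names(set))
  bases <- gsub("[ \t\r]", "", toupper(as.character(set)))
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, "", 1L)
  if (any(nchar(bases) == 0L)) {
    stop("malformed FASTA in ", path, ": empty sequence for record ",
         ids[which(nchar(bases) == 0L)[1]])
  }

  if (!expect_metadata) {
    bad <- grepl("[^ACGT]", bases)
    if (any(bad)) {
      stop("reference ", ids[which(bad)[1]],
           " contains characters outside A/C/G/T")
    }
    out <- data.frame(id = ids, bases = bases, length = nchar(bases),
                      stringsAsFactors = FALSE, row.names = NULL)
    rownames(out) <- NULL
    class(out) <- c("pyro_refs", "data.frame")
    return(out)
  }

  bad <- grepl("[^ACGTN]", bases)
  if (any(bad)) {
    stop("read ", ids[which(bad)[1]], " contains characters outside A/C/G/T/N")
  }
  meta <- lapply(seq_along(headers), function(i) {
    toks <- strsplit(headers[i], "[ \t]+")[[1]][-1]
    kv <- toks[grepl("=", toks, fixed = TRUE)]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    need <- c("plate", "region", "x", "y")
    miss <- setdiff(need, keys)
    if (length(miss)) {
      stop("read ", ids[i], ": missing metadata key(s) ",
           paste(miss, collapse = ", "))
    }
    setNames(as.list(vals), keys)[need]
  })
  out <- data.frame(
    id = ids,
    bases = bases,
    plate = vapply(meta, function(m) m$plate, ""),
    region = as.integer(vapply(meta, function(m) m$region, "")),
    x = as.numeric(vapply(meta, function(m) m$x, "")),
    y = as.numeric(vapply(meta, function(m) m$y, "")),
    length = nchar(bases),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (anyNA(out$region) || anyNA(out$x) || anyNA(out$y)) {
    bad <- which(is.na(out$region) | is.na(out$x) | is.na(out$y))[1]
    stop("read ", out$id[bad], ": non-numeric region/x/y metadata")
  }
  class(out) <- c("pyro_reads", "data.frame")
  out
}

empty_refs <- function() {
  out <- data.frame(id = character(), bases = character(), length = integer(),
                    stringsAsFactors = FALSE)
  class(out) <- c("pyro_refs", "data.frame")
  out
}

empty_reads <- function() {
  out <- data.frame(id = character(), bases = character(), plate = character(),
                    region = integer(), x = numeric(), y = numeric(),
                    length = integer(), stringsAsFactors = FALSE)
  class(out) <- c("pyro_reads", "data.frame")
  out
}

#' Write references or reads to FASTA
#'
#' Reads are written with the `plate=... region=... x=... y=...` header
#' dialect understood by [read_fasta()]; coordinates are printed with
#' `%.15g` so that a write/read round trip is lossless.
#'
#' @param x a `pyro_refs` or `pyro_reads` table.
#' @param path output path.
#' @param width line-wrapping width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  headers <- if (inherits(x, "pyro_reads")) {
    sprintf(">%s plate=%s region=%d x=%.15g y=%.15g",
            x$id, x$plate, x$region, x$x, x$y)
  } else {
    paste0(">", x$id)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(headers[i], con)
    s <- x$bases[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write and read per-position error-call tables
#'
#' Tab-separated, one row per evaluated position (including `none` rows) or
#' per insertion event, with a header row. `ref_pos` is the 1-based,
#' fully-closed reference coordinate; insertions are anchored to the base
#' preceding the gap. The extra `read_pos` column records the 1-based read
#' coordinate of the call (for deletions, the last read base consumed before
#' the gap), which windowed summaries need.
#'
#' @param calls a call table from [classify_errors()] or [call_errors()].
#' @param path file path.
#' @return `write_calls`: `path`, invisibly. `read_calls`: the call table.
#' @export
write_calls <- function(calls, path) {
  stopifnot(is.data.frame(calls))
  cols <- c("read_id", "ref_id", "ref_pos", "error_type", "read_pos")
  write.table(calls[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(read_id = "character", ref_id = "character",
                                   ref_pos = "integer", error_type = "character",
                                   read_pos = "integer"))
  bad <- setdiff(unique(out$error_type), .pyro_call_states)
  if (length(bad)) stop("unknown error_type value(s): ", paste(bad, collapse = ", "))
  out
}

#' Run configuration
#'
#' Plumbing for the end-to-end pipeline: alignment parameters, the analysis
#' window, spatial-map parameters, permutation count and the master seed
#' (echoed into every output).
#'
#' @param match,mismatch,gap_open,gap_extend alignment scores/penalties;
#'   penalties must be non-negative. Defaults reproduce the gap settings
#'   retained after the original penalty screen (open 1, extend 10).
#' @param window analysis window in read bases, or `"full"`.
#' @param seed integer master seed.
#' @param spatial_window,spatial_stride sliding-window size/stride in plate
#'   coordinate units (`NULL` = derived from the coordinate span).
#' @param n_perm permutation count for correlation tests.
#' @param simulate if `TRUE`, [run_pipeline()] starts from simulated data.
#' @param n_reads,n_plates simulator dimensions used when `simulate = TRUE`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(match = 2, mismatch = 1, gap_open = 1, gap_extend = 10,
                       window = 101, seed = 1L, spatial_window = NULL,
                       spatial_stride = NULL, n_perm = 999L, simulate = TRUE,
                       n_reads = 200L, n_plates = 2L) {
  if (gap_open < 0 || gap_extend < 0 || mismatch < 0)
    stop("gap and mismatch penalties must be >= 0")
  if (!(identical(window, "full") || (is.numeric(window) && window >= 1)))
    stop("window must be >= 1 or \"full\"")
  cfg <- list(match = match, mismatch = mismatch, gap_open = gap_open,
              gap_extend = gap_extend, window = window,
              seed = as.integer(seed), spatial_window = spatial_window,
              spatial_stride = spatial_stride, n_perm = as.integer(n_perm),
              simulate = isTRUE(simulate) || identical(simulate, "TRUE"),
              n_reads = as.integer(n_reads), n_plates = as.integer(n_plates))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path path of a plain-text `key=value` configuration file.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  keys <- sub("=.*$", "", lines)
  vals <- sub("^[^=]*=", "", lines)
  kv <- setNames(as.list(trimws(vals)), trimws(keys))
  num <- c("match", "mismatch", "gap_open", "gap_extend", "seed",
           "spatial_window", "spatial_stride", "n_perm", "n_reads", "n_plates")
  for (k in intersect(names(kv), num)) kv[[k]] <- as.numeric(kv[[k]])
  if (!is.null(kv$window) && kv$window != "full")
    kv$window <- as.numeric(kv$window)
  do.call(run_config, kv)
}

#' @rdname run_config
#' @param cfg a `run_config` object.
#' @export
write_run_config <- function(cfg, path) {
  flat <- cfg[!vapply(cfg, is.null, TRUE)]
  writeLines(sprintf("%s=%s", names(flat),
                     vapply(flat, function(v) format(v, digits = 15), "")),
             path)
  invisible(path)
}
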