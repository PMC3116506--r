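#' Empirical plate layout from bead coordinates
#'
#' The plate geometry is never published, so region and plate centers are
#' taken as data-driven centroids of the observed bead coordinates: the
#' region center is the centroid of the reads in that region, the plate
#' center the centroid of all reads on the plate.
#'
#' @param reads a `pyro_reads` table.
#' @return A list of class `plate_layout` with `regions` (plate, region,
#'   cx, cy, n) and `plates` (plate, cx, cy, n).
#' @export
compute_layout <- function(reads) {
  if (nrow(reads) == 0L) stop("no reads")
  key <- interaction(reads$plate, reads$region, drop = TRUE)
  regions <- data.frame(
    plate = tapply(reads$plate, key, `[`, 1L),
    region = as.integer(tapply(reads$region, key, `[`, 1L)),
    cx = as.numeric(tapply(reads$x, key, mean)),
    cy = as.numeric(tapply(reads$y, key, mean)),
    n = as.integer(tapply(reads$x, key, length)),
    stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  plates <- data.frame(
    plate = tapply(reads$plate, reads$plate, `[`, 1L),
    cx = as.numeric(tapply(reads$x, reads$plate, mean)),
    cy = as.numeric(tapply(reads$y, reads$plate, mean)),
    n = as.integer(tapply(reads$x, reads$plate, length)),
    stringsAsFactors = FALSE)
  rownames(plates) <- NULL
  structure(list(regions = regions, plates = plates), class = "plate_layout")
}

#' Balanced error/non-error covariate table
#'
#' One row per error call (`error = 1`) plus, per plate, an equal number of
#' error-free positions sampled uniformly without replacement
#' (`error = 0`), each annotated with the seven explanatory variables:
#' `Position` (reference position as a fraction of reference length),
#' `Seq.type` (reference id), `Homopolymer` (code 0/1/3-6), `Dist.region`
#' and `Dist.plate` (Euclidean distances to the empirical centroids),
#' `Seq.length` (read length in bp) and `Region`. Insertion rows take the
#' covariates of the anchoring reference position. Bead `x`/`y`
#' coordinates are carried along for gradient analyses. The balanced
#' sample is drawn per plate because the downstream models are per-plate.
#'
#' Error-free positions are drawn either from the `none` rows of `calls`,
#' or — when `spans` is supplied (read_id, ref_id, covered_length) — from
#' the implied covered positions directly, which avoids materializing one
#' row per correct base on large simulations. Every position at which an
#' error was detected is excluded from the error-free pool, insertion
#' anchors included: an anchor is a position at which an error is
#' reported, and letting it double as a control measurably attenuates the
#' fitted slopes.
#'
#' @param calls a call table (with or without `none` rows, see `spans`).
#' @param reads a `pyro_reads` table.
#' @param refs a `pyro_refs` table.
#' @param codes a [homopolymer_codes()] list.
#' @param layout a [compute_layout()] result.
#' @param seed integer seed for the error-free sample.
#' @param spans optional data.frame (`read_id`, `ref_id`,
#'   `covered_length`), e.g. a simulation truth log's `read_info`.
#' @return A `data.frame`, one row per sampled position.
#' @export
build_covariate_table <- function(calls, reads, refs, codes, layout,
                                  seed = 1L, spans = NULL) {
  set.seed(as.integer(seed))
  err <- calls[calls$error_type != "none", , drop = FALSE]
  plate_of <- setNames(reads$plate, reads$id)
  err_plate <- plate_of[err$read_id]

  err_key <- paste(err$read_id, err$ref_pos)

  pick_none <- function(pl, need) {
    if (is.null(spans)) {
      pool <- calls[calls$error_type == "none" &
                      plate_of[calls$read_id] == pl, , drop = FALSE]
      pool <- pool[!paste(pool$read_id, pool$ref_pos) %in% err_key, ,
                   drop = FALSE]
      if (nrow(pool) < need) {
        warning("plate ", pl, ": only ", nrow(pool),
                " error-free positions for ", need, " errors; using all")
        need <- nrow(pool)
      }
      take <- pool[sample.int(nrow(pool), need), , drop = FALSE]
      data.frame(read_id = take$read_id, ref_id = take$ref_id,
                 ref_pos = take$ref_pos, stringsAsFactors = FALSE)
    } else {
      sp <- spans[plate_of[spans$read_id] == pl, , drop = FALSE]
      total <- sum(sp$covered_length)
      ex <- err[err_plate == pl, , drop = FALSE]
      bad <- paste(ex$read_id, ex$ref_pos)
      if (total - nrow(ex) < need) {
        warning("plate ", pl, ": fewer error-free positions than errors; using all")
      }
      cum <- cumsum(sp$covered_length)
      got <- NULL
      tries <- 0L
      while ((is.null(got) || nrow(got) < need) && tries < 50L) {
        tries <- tries + 1L
        m <- min(total, ceiling((need - if (is.null(got)) 0L else nrow(got)) * 1.2) + 10L)
        idx <- sample.int(total, m)
        ri <- findInterval(idx - 1L, c(0L, cum), rightmost.closed = FALSE)
        pos <- idx - c(0L, cum)[ri]
        cand <- data.frame(read_id = sp$read_id[ri], ref_id = sp$ref_id[ri],
                           ref_pos = pos, stringsAsFactors = FALSE)
        cand <- cand[!paste(cand$read_id, cand$ref_pos) %in% bad, , drop = FALSE]
        got <- unique(rbind(got, cand))
      }
      if (nrow(got) < need) need <- nrow(got)
      got[seq_len(need), , drop = FALSE]
    }
  }

  rows <- list()
  for (pl in unique(reads$plate)) {
    e <- err[err_plate == pl, , drop = FALSE]
    ne <- pick_none(pl, nrow(e))
    rows[[pl]] <- rbind(
      data.frame(read_id = e$read_id, ref_id = e$ref_id, ref_pos = e$ref_pos,
                 error = 1L, error_type = e$error_type,
                 stringsAsFactors = FALSE),
      data.frame(read_id = ne$read_id, ref_id = ne$ref_id, ref_pos = ne$ref_pos,
                 error = 0L, error_type = "none", stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  annotate_covariates(tab, reads, refs, codes, layout)
}

# attach the seven explanatory variables (plus plate, x, y) to sampled rows
annotate_covariates <- function(tab, reads, refs, codes, layout) {
  ridx <- match(tab$read_id, reads$id)
  fidx <- match(tab$ref_id, refs$id)
  if (anyNA(ridx) || anyNA(fidx)) stop("rows reference unknown reads or references")
  tab$plate <- reads$plate[ridx]
  tab$Position <- tab$ref_pos / refs$length[fidx]
  tab$Seq.type <- factor(tab$ref_id, levels = refs$id)
  code_val <- integer(nrow(tab))
  for (rid in unique(tab$ref_id)) {
    sel <- tab$ref_id == rid
    code_val[sel] <- codes[[rid]][tab$ref_pos[sel]]
  }
  tab$Homopolymer <- factor(code_val, levels = .pyro_hp_codes)
  rkey <- paste(reads$plate[ridx], reads$region[ridx])
  lkey <- paste(layout$regions$plate, layout$regions$region)
  li <- match(rkey, lkey)
  if (anyNA(li)) stop("reads in regions absent from the layout")
  tab$Dist.region <- sqrt((reads$x[ridx] - layout$regions$cx[li])^2 +
                            (reads$y[ridx] - layout$regions$cy[li])^2)
  pi_ <- match(tab$plate, layout$plates$plate)
  tab$Dist.plate <- sqrt((reads$x[ridx] - layout$plates$cx[pi_])^2 +
                           (reads$y[ridx] - layout$plates$cy[pi_])^2)
  tab$Seq.length <- reads$length[ridx]
  tab$Region <- factor(reads$region[ridx])
  tab$x <- reads$x[ridx]
  tab$y <- reads$y[ridx]
  tab
}
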