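#' Sliding-window spatial map of error rate or read length
#'
#' Slides a square window across the bead coordinates of one plate. For
#' each grid anchor the cell value is the error rate of the given type
#' (erroneous evaluated positions / evaluated positions) over the reads
#' whose bead falls in the window, or the mean read length for
#' `metric = "length"`. Cells with fewer than `min_support` reads are
#' flagged unsupported (`NA` value), not zero. Window and stride default
#' to 1/20 of the coordinate span and half the window; the original
#' sliding-window parameters were never published, so these are declared
#' defaults, echoed in the result's attributes.
#'
#' @param calls a call table including `none` rows.
#' @param reads a `pyro_reads` table (one plate, or use `plate`).
#' @param metric one of the four error types, `"total"`, or `"length"`.
#' @param window window side length in coordinate units.
#' @param stride anchor step in coordinate units.
#' @param min_support minimum reads per supported cell.
#' @param plate optional plate id to filter on.
#' @param region optional region id to filter on (for region-wise maps).
#' @return A `data.frame` of class `pyro_grid` (`x`, `y`, `value`,
#'   `n_reads`, `supported`), with the parameters as attributes. `x`/`y`
#'   are window centers.
#' @export
spatial_map <- function(calls, reads,
                        metric = c("insertion", "deletion", "mismatch",
                                   "ambiguous", "total", "length"),
                        window = NULL, stride = NULL, min_support = 20L,
                        plate = NULL, region = NULL) {
  metric <- match.arg(metric)
  if (!is.null(plate)) reads <- reads[reads$plate == plate, , drop = FALSE]
  if (!is.null(region)) reads <- reads[reads$region == region, , drop = FALSE]
  if (nrow(reads) == 0L) stop("no reads on this plate/region")
  if (length(unique(reads$plate)) > 1L)
    stop("reads span several plates; pass `plate`")
  prs <- per_read_stats(calls, reads, window = "full")
  val_num <- switch(metric,
                    total = prs$n_errors,
                    length = reads$length,
                    prs[[metric]])
  val_den <- if (metric == "length") rep(1L, nrow(reads)) else prs$evaluated

  xr <- range(reads$x); yr <- range(reads$y)
  span <- max(xr[2] - xr[1], yr[2] - yr[1])
  if (is.null(window)) window <- span / 20
  if (is.null(stride)) stride <- window / 2
  if (window <= 0 || stride <= 0) stop("window and stride must be > 0")

  # anchors run to the coordinate maximum with half-open [a, a + window)
  # cells, so stride == window tiles the plate into disjoint cells
  anchors <- function(r) seq(r[1], r[2], by = stride)
  xs <- anchors(xr); ys <- anchors(yr)
  grid <- expand.grid(x0 = xs, y0 = ys)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x0 <- grid$x0[i]; y0 <- grid$y0[i]
    sel <- reads$x >= x0 & reads$x < x0 + window &
      reads$y >= y0 & reads$y < y0 + window
    n <- sum(sel)
    v <- if (n >= min_support) sum(val_num[sel]) / sum(val_den[sel]) else NA_real_
    data.frame(x = x0 + window / 2, y = y0 + window / 2, value = v,
               n_reads = n, supported = n >= min_support)
  })
  out <- do.call(rbind, res)
  attr(out, "metric") <- metric
  attr(out, "window") <- window
  attr(out, "stride") <- stride
  attr(out, "min_support") <- min_support
  class(out) <- c("pyro_grid", "data.frame")
  out
}

#' Monotonic spatial trend of a grid
#'
#' Spearman rank correlation of the supported cell values against each
#' coordinate axis. A constant grid has trend 0 by convention. Region-wise
#' trends are obtained by building the map with `spatial_map(region = r)`.
#'
#' @param grid a `pyro_grid`.
#' @return A `data.frame` with one row per axis: `axis`, `rho`,
#'   `n_cells`.
#' @export
gradient_summary <- function(grid) {
  g <- grid[grid$supported & !is.na(grid$value), , drop = FALSE]
  one <- function(axis) {
    if (nrow(g) < 3L || length(unique(g[[axis]])) < 3L)
      return(data.frame(axis = axis, rho = NA_real_, n_cells = nrow(g)))
    rho <- if (sd(g$value) == 0) 0
    else suppressWarnings(cor(g[[axis]], g$value, method = "spearman"))
    data.frame(axis = axis, rho = rho, n_cells = nrow(g))
  }
  rbind(one("x"), one("y"))
}
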