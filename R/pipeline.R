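#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> call -> annotate -> summarize ->
#' covariate table -> model/decompose -> spatial -> coverage, writing each
#' stage's TSV outputs plus a JSON manifest into `workdir`. One master
#' seed fans out into per-stage seeds (stage-name hashed) so stages are
#' individually reproducible; re-running with the same configuration
#' yields byte-identical TSV outputs.
#'
#' @param config a [run_config()] object or path to a `key=value` file.
#' @param workdir output directory (created if needed).
#' @param refs optional `pyro_refs`; defaults to the synthetic control
#'   fragments when simulating.
#' @param reads optional `pyro_reads`; required when `config$simulate` is
#'   `FALSE`.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, workdir, refs = NULL, reads = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  stopifnot(inherits(cfg, "run_config"))
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stages <- character(0)
  t0 <- Sys.time()
  note <- function(stage, ...) {
    message(sprintf("[pyroerr %s] %s", stage, paste0(...)))
  }
  run_stage <- function(stage, fun) {
    note(stage, "start (seed ", stage_seed(cfg$seed, stage), ")")
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (cfg$simulate) {
    run_stage("simulate", function() {
      if (is.null(refs))
        refs <<- synthetic_control_refs(stage_seed(cfg$seed, "refs"))
      sim <- simulate_reads(refs, sim_config(
        n_reads = cfg$n_reads, plates = paste0("plate", seq_len(cfg$n_plates)),
        seed = stage_seed(cfg$seed, "simulate")))
      reads <<- sim$reads
      paths$refs <<- file.path(workdir, "refs.fa")
      paths$reads <<- file.path(workdir, "reads.fa")
      paths$truth <<- file.path(workdir, "truth_events.tsv")
      write_fasta(refs, paths$refs)
      write_fasta(reads, paths$reads)
      write_truth(sim$truth, paths$truth)
    })
    stages <- c(stages, "simulate")
  }
  if (is.null(refs) || is.null(reads))
    stop("refs and reads are required when simulate = FALSE")

  params <- align_params(cfg$match, cfg$mismatch, cfg$gap_open, cfg$gap_extend)
  calls <- run_stage("call", function() {
    cl <- call_errors(reads, refs, params)
    paths$calls <<- file.path(workdir, "calls.tsv")
    write_calls(cl, paths$calls)
    cl
  })
  stages <- c(stages, "call")

  codes <- run_stage("annotate", function() {
    cd <- homopolymer_codes(refs)
    paths$codes <<- file.path(workdir, "homopolymer_codes.tsv")
    write_homopolymer_codes(cd, paths$codes)
    cd
  })
  stages <- c(stages, "annotate")

  run_stage("summarize", function() {
    paths$summary_window <<- file.path(workdir, "summary_window.tsv")
    paths$summary_full <<- file.path(workdir, "summary_full.tsv")
    write_tsv(summarize_errors(calls, reads, cfg$window), paths$summary_window)
    write_tsv(summarize_errors(calls, reads, "full"), paths$summary_full)
    paths$profile <<- file.path(workdir, paste0("profile_", refs$id[1], ".tsv"))
    write_tsv(position_profile(calls, reads, refs$id[1]), paths$profile)
  })
  stages <- c(stages, "summarize")

  tab <- run_stage("table", function() {
    layout <- compute_layout(reads)
    tb <- build_covariate_table(calls, reads, refs, codes, layout,
                                seed = stage_seed(cfg$seed, "table"))
    paths$table <<- file.path(workdir, "covariate_table.tsv")
    write_tsv(tb, paths$table)
    tb
  })
  stages <- c(stages, "table")

  run_stage("model", function() {
    fit_rows <- list(); dec_rows <- list()
    for (pl in unique(tab$plate)) {
      for (ty in .pyro_error_types) {
        n1 <- sum(tab$plate == pl & tab$error == 1L & tab$error_type == ty)
        if (n1 < 30L) next # too few events for a stable per-type fit
        fit <- suppressWarnings(fit_logistic(tab, pl, ty))
        cf <- fit$coefficients
        cf$plate <- pl; cf$error_type <- ty
        cf$deviance_explained <- deviance_explained(fit)
        fit_rows[[paste(pl, ty)]] <- cf
        dec <- suppressWarnings(decompose_all(tab, pl, ty))
        dec$plate <- pl; dec$error_type <- ty
        dec_rows[[paste(pl, ty)]] <- dec
      }
    }
    paths$fits <<- file.path(workdir, "logistic_fits.tsv")
    paths$decomposition <<- file.path(workdir, "decomposition.tsv")
    write_tsv(do.call(rbind, fit_rows), paths$fits)
    write_tsv(do.call(rbind, dec_rows), paths$decomposition)
    if (length(unique(tab$plate)) >= 2L) {
      err_by_plate <- do.call(rbind, lapply(split(tab, tab$plate), function(d) {
        data.frame(plate = d$plate[1], errors = sum(d$error == 1L),
                   non_errors = sum(d$error == 0L))
      }))
      hom <- plate_homogeneity(err_by_plate)
      paths$homogeneity <<- file.path(workdir, "plate_homogeneity.tsv")
      write_tsv(data.frame(chi2 = hom$chi2, df = hom$df, p = hom$p),
                paths$homogeneity)
    }
  })
  stages <- c(stages, "model")

  run_stage("spatial", function() {
    pl <- unique(reads$plate)[1]
    for (m in c("insertion", "deletion", "length")) {
      g <- spatial_map(calls, reads, metric = m, window = cfg$spatial_window,
                       stride = cfg$spatial_stride, plate = pl)
      p <- file.path(workdir, sprintf("spatial_%s_%s.tsv", pl, m))
      paths[[paste0("spatial_", m)]] <<- p
      write_tsv(as.data.frame(g), p)
    }
  })
  stages <- c(stages, "spatial")

  run_stage("coverage", function() {
    paths$coverage <<- file.path(workdir, "coverage.tsv")
    write_tsv(coverage_grid(), paths$coverage)
  })
  stages <- c(stages, "coverage")

  manifest <- list(
    package = "pyroerr",
    version = as.character(packageVersion("pyroerr")),
    seed = cfg$seed,
    parameters = cfg[c("match", "mismatch", "gap_open", "gap_extend",
                       "window", "n_perm")],
    stages = stages,
    outputs = paths,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(workdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# derive a reproducible per-stage seed from the master seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 131 + h) %% .Machine$integer.max)
}
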