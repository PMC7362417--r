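#' Histogram summary with peak detection
#'
#' Fixed-bin-width histogram of a value series, normalized to a density,
#' optionally smoothed with a centered moving average, with peaks reported
#' as local maxima of the (smoothed) density above a prominence floor.
#'
#' @param values numeric series (>= 10 values).
#' @param bin_width bin width in the values' units (default 2).
#' @param smoothing_window moving-average window in bins (odd; default 3;
#'   1 disables smoothing).
#' @param prominence minimum peak height as a fraction of the maximum
#'   smoothed density (default 0.05).
#' @return object of class `DistributionSummary`: list with `breaks`,
#'   `mids`, `counts`, `density`, `smoothed`, `peaks` (bin-midpoint
#'   locations, ascending), and `params`.
#' @export
summarize_distribution <- function(values, bin_width = 2,
                                   smoothing_window = 3,
                                   prominence = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 10L)
    stop("need at least 10 values to summarize a distribution")
  stopifnot(bin_width > 0, smoothing_window >= 1)
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width  # constant series: one bin
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE,
                      right = FALSE, include.lowest = TRUE)
  density <- h$counts / (length(values) * bin_width)
  # centered moving average with partial windows at the edges
  half <- (smoothing_window - 1) %/% 2
  nb <- length(density)
  smoothed <- vapply(seq_len(nb), function(i) {
    w <- max(1L, i - half):min(nb, i + half)
    mean(density[w])
  }, numeric(1))
  floor_h <- prominence * max(smoothed)
  is_peak <- if (nb == 1L) TRUE else vapply(seq_len(nb), function(i) {
    left <- if (i == 1L) -Inf else smoothed[i - 1L]
    right <- if (i == nb) -Inf else smoothed[i + 1L]
    smoothed[i] >= left && smoothed[i] > right && smoothed[i] >= floor_h
  }, logical(1))
  structure(list(breaks = h$breaks, mids = h$mids, counts = h$counts,
                 density = density, smoothed = smoothed,
                 peaks = sort(h$mids[is_peak]),
                 params = list(bin_width = bin_width,
                               smoothing_window = smoothing_window,
                               prominence = prominence,
                               n = length(values))),
            class = "DistributionSummary")
}

#' @export
print.DistributionSummary <- function(x, ...) {
  cat(sprintf("DistributionSummary: %d values in %d bins of width %g; peaks at %s\n",
              x$params$n, length(x$mids), x$params$bin_width,
              paste(signif(x$peaks, 4), collapse = ", ")))
  invisible(x)
}

default_config <- function() {
  list(kind = "breathing",
       superhelix = list(),       # overrides for superhelix_spec()
       breathing = list(),        # overrides for breathing_spec()
       chromatosome = list(),     # overrides for chromatosome_spec()
       peel = NULL,               # list(n_entry, n_exit, lift) for kind "peeled"
       replicas = 1L,
       seed = 1L,
       cutoff = 6.0,
       stages = c("unwrap", "endtoend", "rg"),
       bin_width = 2,
       smoothing_window = 3,
       output_dir = ".")
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  stopifnot(cfg$kind %in% c("breathing", "wrapped", "peeled",
                            "chromatosome"),
            cfg$replicas >= 1L, cfg$cutoff > 0)
  cfg
}

# hash of the scientific configuration (output location excluded)
config_hash <- function(cfg) {
  cfg$output_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), f)
  unname(tools::md5sum(f))
}

build_replica <- function(cfg, r) {
  seed_r <- as.integer(cfg$seed) + r - 1L
  spec <- do.call(superhelix_spec, cfg$superhelix)
  switch(cfg$kind,
    breathing = {
      br <- do.call(breathing_spec,
                    utils::modifyList(cfg$breathing, list(seed = seed_r)))
      make_breathing_trajectory(spec, br)
    },
    wrapped = {
      a <- make_wrapped_ncp(spec)
      new_trajectory(a, list(a$xyz), labels = a$labels)
    },
    peeled = {
      p <- cfg$peel
      if (is.null(p)) stop("kind 'peeled' needs a peel: {n_entry, n_exit}")
      a <- peel_ends(make_wrapped_ncp(spec), p$n_entry, p$n_exit,
                     lift = if (is.null(p$lift)) 4 else p$lift,
                     cutoff = cfg$cutoff)
      new_trajectory(a, list(a$xyz), labels = a$labels)
    },
    chromatosome = {
      cs <- do.call(chromatosome_spec,
                    utils::modifyList(cfg$chromatosome,
                                      list(core = spec, seed = seed_r)))
      a <- make_chromatosome(cs)
      new_trajectory(a, list(a$xyz), labels = a$labels)
    })
}

#' Run an end-to-end analysis pipeline
#'
#' Generates (or loads) the configured replicas, runs the requested
#' analysis stages, and writes per-replica tables, cross-replica
#' aggregates, distribution summaries, and a machine-readable manifest
#' (config, config hash, seeds, package version, and the conventions in
#' effect).  Re-running with the same config and seed reproduces every
#' output byte for byte.
#'
#' @param config a config list or path to a YAML config file.  Fields:
#'   `kind` (`"breathing"`, `"wrapped"`, `"peeled"`, `"chromatosome"`),
#'   `superhelix` / `breathing` / `chromatosome` (spec overrides), `peel`,
#'   `replicas`, `seed`, `cutoff`, `stages` (subset of `"unwrap"`,
#'   `"endtoend"`, `"rg"`, `"rmsd"`, `"angles"`), `bin_width`,
#'   `smoothing_window`, `output_dir`.
#' @return list with the aggregate `SeriesStat`s per stage, distribution
#'   summaries, and the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  t0 <- Sys.time()
  message("[generate] building ", cfg$replicas, " replica(s) of kind '",
          cfg$kind, "'")
  out <- list(stages = list(), distributions = list())
  meta_common <- list(config_hash = hash, seed = cfg$seed,
                      package_version = as.character(
                        utils::packageVersion("nucleowrap")))
  stage_series <- setNames(vector("list", length(cfg$stages)), cfg$stages)
  angle_tables <- list()
  for (r in seq_len(cfg$replicas)) {
    traj <- build_replica(cfg, r)
    for (st in cfg$stages) {
      s <- switch(st,
        unwrap = {
          us <- unwrap_series(traj, cutoff = cfg$cutoff)
          write_table(us$records,
                      file.path(cfg$output_dir,
                                sprintf("unwrap_rep%d.tsv", r)),
                      meta = c(meta_common, replica = r),
                      units = c(n_entry = "bp", n_exit = "bp",
                                n_total = "bp"))
          us$stat
        },
        endtoend = end_to_end_series(traj),
        rg = rg_series(traj),
        rmsd = rmsd_series(traj, sel = list(name = "P")),
        angles = {
          at <- linker_angle_series(traj)
          angle_tables[[r]] <- at
          series_stat(at$angle_P1_P2_P4)
        },
        stop("unknown stage: ", st))
      stage_series[[st]] <- c(stage_series[[st]], list(s))
    }
    rm(traj)
    gc(verbose = FALSE)
  }
  for (st in cfg$stages) {
    agg <- aggregate_replicas(stage_series[[st]])
    out$stages[[st]] <- agg
    write_table(data.frame(frame = seq_len(agg$n), mean = agg$values,
                           sd = agg$sd_values),
                file.path(cfg$output_dir, sprintf("%s_aggregate.tsv", st)),
                meta = c(meta_common, stage = st,
                         sd_convention = "population"),
                units = c(mean = if (st == "unwrap") "bp"
                          else if (st == "angles") "degrees"
                          else "Angstrom"))
    pooled <- as.numeric(sapply(stage_series[[st]],
                                function(s) s$values))
    if (length(pooled) >= 10L) {
      ds <- summarize_distribution(pooled, bin_width = cfg$bin_width,
                                   smoothing_window = cfg$smoothing_window)
      out$distributions[[st]] <- ds
      write_table(data.frame(mid = ds$mids, count = ds$counts,
                             density = ds$density,
                             smoothed = ds$smoothed),
                  file.path(cfg$output_dir,
                            sprintf("%s_distribution.tsv", st)),
                  meta = c(meta_common, stage = st,
                           peaks = paste(ds$peaks, collapse = ",")))
    }
  }
  manifest <- list(
    config = cfg, config_hash = hash,
    package_version = meta_common$package_version,
    conventions = list(
      cutoff_tie_rule = "a base pair at exactly the cutoff is wrapped",
      core_definition = "all heavy atoms of histone chains",
      sd_convention = "population SD across replicas",
      contact_rule = "strict inequality, heavy atoms only",
      rmsd_fit = "least-squares superposition, reflections disallowed"),
    stages_run = cfg$stages,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest,
                       file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  out$manifest <- manifest
  message("[done] ", length(cfg$stages), " stage(s) in ",
          sprintf("%.1f s", manifest$elapsed_s))
  invisible(out)
}
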