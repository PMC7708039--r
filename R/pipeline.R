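#' Pipeline configuration
#'
#' Collects and validates the settings for a full run: acquisition and
#' ground-truth components for the simulation stage, lifetime grid and
#' discrepancy target for the inversion, Gaussian decomposition settings,
#' the donor-only reference lifetime, optional structure/geometry settings,
#' and the global seed that drives all randomness.
#'
#' @param components Data frame of ground-truth lifetime components for
#'   the simulation stage (see [lifetime_components()]), or a path to a
#'   decay trace file to analyze instead of simulating.
#' @param acq An [acquisition()] object.
#' @param grid A [lifetime_grid()].
#' @param chi2_target Reduced chi-square target for [mem_fit()].
#' @param max_components Maximum Gaussians for [fit_gaussians()].
#' @param threshold_fraction Peak threshold for [count_peaks()].
#' @param tau_D Donor-only reference lifetime in ns.
#' @param structure Optional `structure_model` (or path to a PDB file) for
#'   the geometry stage.
#' @param geometry List of geometry settings: `span = c(from, to)` base
#'   pairs for the twist series, `twist_initial`, `hinge`, `arm_length`,
#'   `extrusion_site`, `n_blocks`.
#' @param seed Global integer seed; every random stage derives from it.
#' @param outdir Optional output directory; when set, [run_pipeline()]
#'   writes the trace, distribution, landscape and geometry reports there.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(components = NULL, acq = acquisition(),
                            grid = lifetime_grid(), chi2_target = 1,
                            max_components = 4, threshold_fraction = 0.02,
                            tau_D = 4.9, structure = NULL, geometry = NULL,
                            seed = 1L, outdir = NULL) {
  stopifnot(inherits(acq, "acquisition"), inherits(grid, "lifetime_grid"))
  stopifnot(chi2_target > 0, max_components >= 1, tau_D > 0)
  stopifnot(threshold_fraction >= 0, threshold_fraction < 1)
  if (!is.null(components) && is.data.frame(components)) {
    total <- sum(components$amplitude)
    if (abs(total - 1) > 1e-9) {
      stop(sprintf("component amplitudes must sum to 1 (got %.12g)", total),
        call. = FALSE
      )
    }
  }
  if (!is.null(geometry)) {
    stopifnot(is.list(geometry))
  }
  structure(
    list(
      components = components, acq = acq, grid = grid,
      chi2_target = chi2_target, max_components = max_components,
      threshold_fraction = threshold_fraction, tau_D = tau_D,
      structure = structure, geometry = geometry,
      seed = as.integer(seed), outdir = outdir
    ),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "outdir")])
}

pipeline_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full lifetime-FRET / geometry pipeline
#'
#' Executes simulate (or read) -> maximum-entropy inversion -> peak
#' counting and Gaussian decomposition -> FRET landscape, plus the
#' geometry stage when a structure is configured. Each stage logs its
#' parameters to stderr; outputs are deterministic given the config seed,
#' and every written file embeds the config hash and package version.
#'
#' @param config A [pipeline_config()].
#' @return A list with elements `trace`, `distribution`, `n_peaks`,
#'   `landscape`, `mean_E_grid`, `geometry` (or `NULL`), `config_hash`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(
#'   components = lifetime_components(4.9, 1),
#'   acq = acquisition(n_channels = 1024),
#'   grid = lifetime_grid(n = 80), seed = 3
#' )
#' rep <- run_pipeline(cfg)
#' nrow(rep$landscape) # 1 donor-only peak
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  version <- as.character(utils::packageVersion("fretscape"))
  stamp <- c(config_hash = hash, fretscape_version = version)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
        call. = FALSE
      )
    })
  }

  acq <- config$acq
  acq$seed <- config$seed
  trace <- run_stage("simulate", {
    if (is.character(config$components)) {
      pipeline_log("simulate", paste("reading trace from", config$components))
      read_decay(config$components)
    } else if (is.data.frame(config$components)) {
      pipeline_log("simulate", sprintf(
        "simulating %d-component decay, seed %d",
        nrow(config$components), config$seed
      ))
      simulate_decay(config$components, acq)
    } else {
      stop("no components or trace path configured", call. = FALSE)
    }
  })

  dist <- run_stage("mem", {
    pipeline_log("mem", sprintf(
      "inverting on %d-point grid, chi2 target %g",
      length(config$grid), config$chi2_target
    ))
    mem_fit(trace, config$grid, chi2_target = config$chi2_target)
  })

  n_peaks <- run_stage("peaks", count_peaks(dist, config$threshold_fraction))
  peaks <- run_stage("peaks", {
    pipeline_log("peaks", sprintf("%d peak(s) above threshold", n_peaks))
    fit_gaussians(dist,
      max_components = config$max_components,
      threshold_fraction = config$threshold_fraction
    )
  })
  landscape <- run_stage("fret", {
    pipeline_log("fret", sprintf("tau_D = %g ns", config$tau_D))
    conformational_landscape(peaks, config$tau_D)
  })
  mean_e_grid <- run_stage("fret", as.numeric(average_fret(dist, config$tau_D)))

  geometry <- NULL
  if (!is.null(config$structure)) {
    geometry <- run_stage("geometry", {
      model <- if (is.character(config$structure)) {
        read_structure(config$structure)
      } else {
        config$structure
      }
      g <- config$geometry %||% list()
      out <- list()
      if (!is.null(g$span)) {
        tw <- twist_series(model, g$span[1], g$span[2])
        ref <- g$twist_initial %||% tw[seq_len(max(1, length(tw) %/% 4))]
        out$untwist <- untwist_angle(tw, ref, n_blocks = g$n_blocks %||% 5)
      }
      if (!is.null(g$hinge)) {
        arm <- g$arm_length %||% 5
        out$bend <- descriptor_series("bend", vapply(
          seq_along(model$coords),
          function(m) bend_angle(model, g$hinge, arm, m), numeric(1)
        ), n_blocks = g$n_blocks %||% 5)
        out$bend_direction <- descriptor_series("bend_direction", vapply(
          seq_along(model$coords),
          function(m) bend_direction_dihedral(model, g$hinge, arm, m), numeric(1)
        ), n_blocks = g$n_blocks %||% 5)
      }
      if (!is.null(g$extrusion_site)) {
        out$extrusion <- purrr::map(g$extrusion_site, function(site) {
          descriptor_series(
            sprintf("base_extrusion_W%d", site),
            vapply(
              seq_along(model$coords),
              function(m) base_extrusion_dihedral(model, site, m), numeric(1)
            ),
            n_blocks = g$n_blocks %||% 5
          )
        })
      }
      pipeline_log("geometry", sprintf("%d descriptor group(s)", length(out)))
      out
    })
  }

  report <- list(
    trace = trace, distribution = dist, n_peaks = n_peaks,
    landscape = landscape, mean_E_grid = mean_e_grid,
    geometry = geometry, config_hash = hash
  )

  if (!is.null(config$outdir)) {
    run_stage("write", write_pipeline_report(report, config, stamp))
  }
  report
}

write_pipeline_report <- function(report, config, stamp) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$outdir, f)
  write_decay(report$trace, p("trace.tsv"), extra_header = stamp)
  write_distribution(report$distribution, p("distribution.tsv"),
    extra = as.list(stamp)
  )
  ls_tab <- tibble::as_tibble(report$landscape)
  writeLines(
    c(
      sprintf("# %s: %s", names(stamp), stamp),
      paste(names(ls_tab), collapse = "\t"),
      apply(ls_tab, 1, function(r) paste(format(r, digits = 10, trim = TRUE), collapse = "\t"))
    ),
    p("landscape.tsv")
  )
  jsonlite::write_json(
    c(
      as.list(stamp),
      list(
        n_peaks = report$n_peaks,
        tau_D = attr(report$landscape, "tau_D"),
        mean_E_peaks = attr(report$landscape, "mean_E"),
        mean_E_grid = report$mean_E_grid
      )
    ),
    p("summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(report$geometry)) {
    geo <- purrr::imap(
      purrr::list_flatten(report$geometry),
      function(d, nm) {
        blk <- attr(d, "block")
        list(
          descriptor = attr(d, "name"), units = attr(d, "units"),
          mean = blk$mean, block_sd = blk$block_sd,
          values = d$value
        )
      }
    )
    jsonlite::write_json(c(as.list(stamp), list(descriptors = geo)),
      p("geometry.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
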