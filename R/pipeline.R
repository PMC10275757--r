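run_config_defaults <- function() {
  list(
    stages = c("retina", "licks"),
    preset = "15MHz",
    seed = 1L,
    out_dir = "sonosim-run",
    log_level = "info",
    overrides = list()
  )
}

known_stages <- c("field", "retina", "ecog", "licks")

#' Load and validate a pipeline run configuration
#'
#' Reads a YAML configuration with keys `stages` (subset of "field",
#' "retina", "ecog", "licks"), `preset` (a [us_preset()] name), `seed`,
#' `out_dir`, `log_level` and `overrides` (named numeric generator
#' overrides, passed to [generator_config()]). Missing keys take defaults;
#' an empty file yields the full default configuration. All schema
#' violations (unknown keys, unknown stages, bad types) are reported
#' together. Configurations round-trip losslessly through
#' [save_run_config()].
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- run_config_defaults()
  problems <- character(0)
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown)) {
    problems <- c(problems, sprintf("unknown key(s): %s",
                                    paste(unknown, collapse = ", ")))
  }
  for (nm in intersect(names(raw), names(cfg))) cfg[[nm]] <- raw[[nm]]
  bad_stages <- setdiff(cfg$stages, known_stages)
  if (length(bad_stages)) {
    problems <- c(problems, sprintf("unknown stage(s): %s",
                                    paste(bad_stages, collapse = ", ")))
  }
  if (!cfg$preset %in% c("0.5MHz", "2.25MHz", "15MHz")) {
    problems <- c(problems, sprintf("unknown preset: %s", cfg$preset))
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    problems <- c(problems, "`seed` must be a single integer")
  }
  if (length(cfg$overrides) &&
      (!is.list(cfg$overrides) || is.null(names(cfg$overrides)) ||
         any(names(cfg$overrides) == ""))) {
    problems <- c(problems, "`overrides` must be a named list")
  }
  if (length(problems)) {
    abort(paste0("invalid run config:\n  - ",
                 paste(problems, collapse = "\n  - ")))
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Write a run configuration back to YAML
#'
#' @param config A `run_config` (or plain list with the same keys).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the generate-and-analyze pipeline
#'
#' Executes the configured stages in dependency order, writes each stage's
#' tables as CSV under `out_dir`, and returns (and writes) a JSON manifest
#' listing inputs, outputs, MD5 hashes, seed and package version. The same
#' configuration and seed reproduce the same manifest hashes.
#'
#' Stages: `"field"` characterizes the preset transducer beam;
#' `"retina"` generates a synthetic MEA recording and computes per-cell
#' response metrics plus dispersion/centre statistics; `"ecog"` generates
#' a surface recording and computes the N1 activation map; `"licks"`
#' generates behavioural sessions and computes session metrics.
#'
#' @param config A `run_config` from [load_run_config()], or `NULL` for
#'   defaults.
#' @param out_dir Output directory; overrides the config entry.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  cfg <- config %||% structure(run_config_defaults(), class = "run_config")
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- do.call(generator_config, c(list(seed = cfg$seed), cfg$overrides))
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }
  for (stage in cfg$stages) {
    if (stage == "field") {
      pre <- us_preset(cfg$preset)
      put(characterize_beam(pre$transducer, pre$medium), "beam_metrics.csv")
    } else if (stage == "retina") {
      mea <- gen_retina_mea(gen)
      put(mea$cells, "retina_cells_truth.csv")
      cr <- cell_responses(mea$spikes, mea$events)
      resp <- dplyr::inner_join(
        cr[cr$responsive, ],
        mea$cells[, c("cell", "x", "y")], by = "cell"
      )
      put(cr, "retina_cell_responses.csv")
      if (nrow(resp) >= 2) {
        put(tibble(
          dispersion = spatial_dispersion(resp),
          centre_x = response_centre(resp)$x,
          centre_y = response_centre(resp)$y,
          n_responding = nrow(resp)
        ), "retina_spatial.csv")
      }
    } else if (stage == "ecog") {
      rec <- gen_ecog(gen)
      ev <- evoked_potential(rec$traces)
      amps <- dplyr::inner_join(ev$n1, rec$layout, by = "channel")
      map <- ecog_activation_map(amps, noise_sd = mean(ev$n1$noise_sd))
      put(amps, "ecog_n1.csv")
      put(glance(map), "ecog_activation.csv")
    } else if (stage == "licks") {
      lk <- gen_licks(gen)
      put(session_metrics(lk$sessions), "lick_session_metrics.csv")
      put(lk$truth, "lick_truth.csv")
    }
  }
  manifest <- list(
    package = "sonosim",
    version = as.character(utils::packageVersion("sonosim")),
    seed = cfg$seed,
    preset = cfg$preset,
    stages = cfg$stages,
    outputs = lapply(files, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
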