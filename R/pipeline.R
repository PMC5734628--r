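CONFIG_DEFAULTS <- function() list(
  phantom = "iq",
  sphere_concentration = 20,
  background_concentration = 2,
  solution_concentration = 20,     # brain fill solution
  gray_white_ratio = 4,
  replicates = NULL,               # 12 for iq, 10 for brain
  conditions = c("stationary", "repositioned"),
  max_rotation_deg = 5,
  max_displacement_mm = 20,
  first_durations = c(2, 4, 5),
  half_life = 109.77,
  profiles = NULL,                 # default set chosen per phantom
  counts_per_mL_per_min = 600,
  post_filter_fwhm = 0,
  supersampling = 4L,
  master_seed = 1L,
  alpha = 0.05,
  output_dir = NULL,
  write_images = FALSE)

#' Validate and complete an experiment configuration
#'
#' Accepts a named list, or a path to a YAML or JSON file, checks every
#' field, fills documented defaults and rejects unknown keys. All
#' problems are collected and reported together.
#'
#' @param raw named list, or path to a `.yaml`/`.yml`/`.json` file.
#' @return An object of class `experiment_config`.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1) {
    raw <- if (grepl("\\.json$", raw)) jsonlite::fromJSON(raw, simplifyVector = TRUE)
    else yaml::read_yaml(raw)
  }
  if (!is.list(raw)) stop("config must be a named list or a config file path")
  defaults <- CONFIG_DEFAULTS()
  errors <- character(0)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    errors <- c(errors, paste0("unknown config keys: ", paste(unknown, collapse = ", "),
                               " (valid: ", paste(names(defaults), collapse = ", "), ")"))
  cfg <- utils::modifyList(defaults, raw[intersect(names(raw), names(defaults))])
  if (!cfg$phantom %in% c("iq", "brain"))
    errors <- c(errors, "phantom must be 'iq' or 'brain'")
  if (is.null(cfg$replicates))
    cfg$replicates <- if (identical(cfg$phantom, "brain")) 10L else 12L
  cfg$replicates <- as.integer(cfg$replicates)
  if (is.na(cfg$replicates) || cfg$replicates < 2)
    errors <- c(errors, "replicates must be an integer >= 2")
  for (f in c("sphere_concentration", "background_concentration",
              "solution_concentration", "counts_per_mL_per_min"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      errors <- c(errors, paste0(f, " must be > 0"))
  if (!is.numeric(cfg$gray_white_ratio) || cfg$gray_white_ratio <= 1)
    errors <- c(errors, "gray_white_ratio must be > 1")
  if (!all(cfg$conditions %in% c("stationary", "repositioned")) ||
      !length(cfg$conditions))
    errors <- c(errors, "conditions must be a subset of {stationary, repositioned}")
  if (!is.numeric(cfg$max_rotation_deg) || cfg$max_rotation_deg < 0)
    errors <- c(errors, "max_rotation_deg must be >= 0")
  if (!is.numeric(cfg$max_displacement_mm) || cfg$max_displacement_mm < 0)
    errors <- c(errors, "max_displacement_mm must be >= 0")
  if (!is.numeric(cfg$first_durations) || any(cfg$first_durations <= 0))
    errors <- c(errors, "first_durations must all be > 0 (minutes)")
  if (!is.numeric(cfg$half_life) || cfg$half_life <= 0)
    errors <- c(errors, "half_life must be > 0 minutes (may be Inf)")
  if (is.null(cfg$profiles)) {
    cfg$profiles <- if (identical(cfg$phantom, "brain")) brain_recon_profiles()
    else iq_recon_profiles()[c("TOF-4mm", "TOF+PSF-4mm")]
  } else if (is.character(cfg$profiles)) {
    registry <- if (identical(cfg$phantom, "brain")) brain_recon_profiles()
    else iq_recon_profiles()
    bad <- setdiff(cfg$profiles, names(registry))
    if (length(bad))
      errors <- c(errors, paste0("unknown recon label(s): ", paste(bad, collapse = ", "),
                                 " (valid: ", paste(names(registry), collapse = ", "), ")"))
    else cfg$profiles <- registry[cfg$profiles]
  }
  if (is.list(cfg$profiles) && !all(vapply(cfg$profiles, inherits, TRUE, "recon_profile")))
    errors <- c(errors, "profiles must be recon_profile objects or known labels")
  if (length(errors))
    stop("invalid experiment config:\n  - ", paste(errors, collapse = "\n  - "))
  cfg$master_seed <- as.integer(cfg$master_seed)
  structure(cfg, class = "experiment_config")
}

measurements_to_records <- function(measurements, phantom) {
  if (identical(phantom, "brain")) {
    data.frame(target = measurements$region, metric = "mean",
               recon = measurements$recon, condition = measurements$condition,
               frame_duration = measurements$frame_duration,
               replicate = measurements$replicate,
               value = measurements$rc_mean)
  } else {
    long <- lapply(c(max = "rc_max", peak = "rc_peak", mean = "rc_mean"),
                   function(col) data.frame(
                     target = measurements$sphere_mm, metric = NA_character_,
                     recon = measurements$recon, condition = measurements$condition,
                     frame_duration = measurements$frame_duration,
                     replicate = measurements$replicate,
                     value = measurements[[col]]))
    for (m in names(long)) long[[m]]$metric <- m
    do.call(rbind, long)
  }
}

#' Run a full replicate experiment
#'
#' Simulates and quantifies every (profile x frame plan x condition x
#' replicate) cell of the configured design and aggregates the precision
#' comparison. The stationary series is one phantom position measured
#' over successive equal-count frames; the repositioned series draws a
#' fresh rigid transform per replicate and uses the first frame's count
#' statistics. Everything is deterministic for a fixed master seed.
#'
#' @param config an [validate_config()] result, or the raw list/file it
#'   accepts.
#' @return list with `measurements` (per-replicate metric rows),
#'   `records` (long RC table: target, metric, recon, condition, value),
#'   `tables` (one [precision_table()] per frame duration), `summaries`
#'   and `manifest`. Written as CSV/JSON under `config$output_dir` when
#'   set.
#' @export
run_experiment <- function(config = list()) {
  cfg <- if (inherits(config, "experiment_config")) config else validate_config(config)
  is_brain <- identical(cfg$phantom, "brain")
  if (is_brain) {
    built <- build_brain_scene(cfg$solution_concentration, cfg$gray_white_ratio)
    sc <- built$scene
    template <- built$template
  } else {
    sc <- build_iq_scene(cfg$sphere_concentration, cfg$background_concentration)
  }
  measurements <- NULL
  stream <- 0L
  for (pname in names(cfg$profiles)) {
    profile <- cfg$profiles[[pname]]
    kernel <- if (!is_brain) make_peak_kernel(profile$grid) else NULL
    for (fd in cfg$first_durations) {
      schedule <- equal_counts_schedule(fd, cfg$replicates, cfg$half_life)
      for (condition in cfg$conditions) {
        stream <- stream + 1L
        for (r in seq_len(cfg$replicates)) {
          repositioned <- identical(condition, "repositioned")
          transform <- if (repositioned)
            sample_transform(cfg$max_rotation_deg, cfg$max_displacement_mm,
                             seed = derive_seed(cfg$master_seed, r, 0L, stream))
          else rigid_transform()
          frame <- if (repositioned) 1L else r
          noise <- noise_model(cfg$counts_per_mL_per_min, cfg$post_filter_fwhm,
                               seed = derive_seed(cfg$master_seed, r, frame, stream + 1000L))
          # repositioning can push the phantom rim past the grid edge,
          # as it would leave a scanner's field of view; analysis regions
          # stay interior, so coverage is deliberately not enforced
          img <- simulate_replicate(sc, profile, schedule, frame, transform,
                                    noise, supersampling = cfg$supersampling,
                                    check_coverage = FALSE)
          if (isTRUE(cfg$write_images) && !is.null(cfg$output_dir)) {
            dir.create(file.path(cfg$output_dir, "images"), recursive = TRUE,
                       showWarnings = FALSE)
            write_replicate(img, file.path(cfg$output_dir, "images",
                                           sprintf("%s_%s_fd%g_rep%02d", pname, condition, fd, r)))
          }
          rows <- if (is_brain)
            region_means(img, template, realignment = transform, replicate = r,
                         condition = condition, recon_label = pname,
                         frame_duration = fd)
          else
            measure_iq_replicate(img, sc, transform = transform, kernel = kernel,
                                 replicate = r, condition = condition,
                                 recon_label = pname, frame_duration = fd)
          measurements <- rbind(measurements, rows)
        }
      }
    }
  }
  records <- measurements_to_records(measurements, cfg$phantom)
  tables <- list()
  if (all(c("stationary", "repositioned") %in% cfg$conditions)) {
    for (fd in cfg$first_durations)
      tables[[sprintf("fd%g", fd)]] <-
        precision_table(records[records$frame_duration == fd, ], alpha = cfg$alpha)
  }
  summaries <- boxplot_summaries(records)
  manifest <- list(package_version = as.character(utils::packageVersion("petprecision")),
                   config = unclass(cfg)[setdiff(names(cfg), "profiles")],
                   profiles = lapply(cfg$profiles, function(p)
                     list(label = p$label, voxel_size = p$grid$voxel_size,
                          fwhm = p$fwhm, psf_iterations = p$psf_iterations)),
                   timestamp = format(Sys.time(), tz = "UTC"))
  out <- list(measurements = measurements, records = records, tables = tables,
              summaries = summaries, manifest = manifest)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(measurements, file.path(cfg$output_dir, "measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(records, file.path(cfg$output_dir, "records.csv"),
                     row.names = FALSE)
    for (nm in names(tables)) {
      utils::write.csv(tables[[nm]]$tests,
                       file.path(cfg$output_dir, sprintf("ftests_%s.csv", nm)),
                       row.names = FALSE)
      writeLines(render_precision_markdown(tables[[nm]]),
                 file.path(cfg$output_dir, sprintf("ftests_%s.md", nm)))
    }
    writeLines(jsonlite::toJSON(summaries, auto_unbox = TRUE, digits = NA),
               file.path(cfg$output_dir, "boxplot_summaries.json"))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                null = "null", force = TRUE),
               file.path(cfg$output_dir, "manifest.json"))
  }
  out
}

#' Render a precision table as markdown
#'
#' Human-readable rendering of a [precision_table()]: significant
#' p-values printed, non-significant cells shown as "-".
#'
#' @param table a [precision_table()] result.
#' @export
render_precision_markdown <- function(table) {
  disp <- table$display
  header <- paste0("| target | ", paste(colnames(disp), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(disp) + 1), collapse = "|"), "|")
  rows <- vapply(seq_len(nrow(disp)), function(i)
    paste0("| ", rownames(disp)[i], " | ", paste(disp[i, ], collapse = " | "), " |"),
    character(1))
  c(header, sep, rows)
}
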