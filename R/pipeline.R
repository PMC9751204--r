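#' Run configuration
#'
#' Builds (and validates) the configuration consumed by [analyze_run()].
#' All analysis parameters live here so a run is reproducible from its
#' persisted configuration alone; the seed is recorded in the run log.
#'
#' @param input path(s) to TIFF stack(s); a length-2 character vector is
#'   read as a blue/red stack pair.
#' @param layout `"split_lr"`, `"split_tb"`, `"single"`, or `"two_files"`.
#' @param pre list of [preprocess_config()] overrides.
#' @param coloc_method `"position"`, `"intensity"`, or `"both"`.
#' @param coloc_radius matching radius (px) for position-detected
#'   colocalization.
#' @param coloc_sfr SFR for intensity-detected colocalization.
#' @param drift `"auto"`, `"none"`, or `"fixed:drow,dcol"` (also accepts
#'   `list(mode =, drow =, dcol =)`).
#' @param max_shift drift search bound, px.
#' @param min_auto_coloc percent; below this measured colocalization the
#'   automatic drift estimate is considered unreliable (there is nothing
#'   correlated between the channels) and the frame is re-analyzed without
#'   correction.
#' @param out_dir output directory (`NULL`: no files written).
#' @param label condition label.
#' @param seed RNG seed (background sampling).
#' @param overlay write an overlay PNG of the first frame.
#' @return a `vq_run_config` list.
#' @export
run_config <- function(input = NULL, layout = "split_lr", pre = list(),
                       coloc_method = c("both", "position", "intensity"),
                       coloc_radius = 2, coloc_sfr = 2,
                       drift = "auto", max_shift = 10L, min_auto_coloc = 10,
                       out_dir = NULL, label = "sample", seed = 1L,
                       overlay = !is.null(out_dir)) {
  coloc_method <- match.arg(coloc_method)
  if (is.character(drift)) {
    if (grepl("^fixed:", drift)) {
      v <- as.integer(strsplit(sub("^fixed:", "", drift), ",")[[1]])
      drift <- list(mode = "fixed", drow = v[1], dcol = v[2])
    } else drift <- list(mode = match.arg(drift, c("auto", "none")))
  }
  structure(list(input = input, layout = layout,
                 pre = do.call(preprocess_config, pre),
                 coloc_method = coloc_method, coloc_radius = coloc_radius,
                 coloc_sfr = coloc_sfr, drift = drift,
                 max_shift = as.integer(max_shift),
                 min_auto_coloc = min_auto_coloc,
                 out_dir = out_dir, label = label, seed = as.integer(seed),
                 overlay = overlay),
            class = "vq_run_config")
}

analyze_channel <- function(grid, cfg, channel, seed) {
  detect_vesicles(grid, cfg$pre, channel = channel, seed = seed)
}

analyze_frame <- function(frame, cfg) {
  seed <- cfg$seed + frame$frame_index
  blue <- analyze_channel(frame$blue, cfg, "blue", seed)
  single <- is.null(frame$red)
  if (single)
    return(list(blue = blue, red = NULL, coloc = NULL, drift = NULL,
                frame_index = frame$frame_index))
  red <- analyze_channel(frame$red, cfg, "red", seed + 1000L)
  drift <- switch(cfg$drift$mode,
                  none = drift_offset(0L, 0L, mode = "none"),
                  fixed = drift_offset(cfg$drift$drow, cfg$drift$dcol,
                                       mode = "fixed"),
                  auto = estimate_drift(blue$corrected, red$corrected,
                                        cfg$max_shift))
  run_coloc <- function(off) {
    res <- list()
    if (cfg$coloc_method %in% c("position", "both")) {
      red_aligned <- apply_drift(red$spots, off, align = TRUE)
      res$position <- colocalize_by_position(blue$spots, red_aligned,
                                             cfg$coloc_radius)
      res$position$drift <- off
    }
    if (cfg$coloc_method %in% c("intensity", "both"))
      res$intensity <- colocalize_by_intensity(blue$spots, red$spots,
                                               blue$corrected, red$corrected,
                                               blue$model, red$model,
                                               cfg$coloc_sfr, drift = off)
    res
  }
  coloc <- run_coloc(drift)
  if (cfg$drift$mode == "auto") {
    measured <- mean(vapply(coloc, function(x) x$frac_mean, numeric(1)))
    if (is.finite(measured) && measured < cfg$min_auto_coloc) {
      # the correlation peak of an uncolocalized sample is spurious;
      # fall back to no correction rather than invent an offset
      drift <- drift_offset(0L, 0L, mode = "none")
      coloc <- run_coloc(drift)
    }
  }
  mark_pairs <- function(spots, ids, partner) {
    hit <- match(ids, spots$table$id)
    spots$table$colocalized[hit] <- TRUE
    spots$table$partner_id[hit] <- partner
    spots
  }
  primary <- coloc[[if (cfg$coloc_method == "position") "position" else "intensity"]]
  if (is.null(primary)) primary <- coloc[[1]]
  if (nrow(primary$pairs)) {
    blue$spots <- mark_pairs(blue$spots, primary$pairs$blue_id,
                             primary$pairs$red_id)
    red$spots <- mark_pairs(red$spots, primary$pairs$red_id,
                            primary$pairs$blue_id)
  }
  list(blue = blue, red = red, coloc = coloc, drift = drift,
       frame_index = frame$frame_index)
}

#' Analyze an image stack (or in-memory frames) end to end
#'
#' For every frame: preprocess both channels, detect and normalize spots,
#' fit the per-channel background models, resolve the drift offset,
#' colocalize, and write per-frame tables; then summarize the condition
#' (population statistics per channel, mean colocalized fractions). A
#' frame that fails is logged and skipped; the run continues.
#'
#' @param config a [run_config()].
#' @param frames optional list of [channel_frame()]s, bypassing file input
#'   (used by tests and by [simulate_run()] round-trips).
#' @return a `vq_run_report` list: per-frame results, per-channel
#'   [summarize_population()] summaries, colocalization fractions, the
#'   configuration, and any frame errors.
#' @export
analyze_run <- function(config, frames = NULL) {
  stopifnot(inherits(config, "vq_run_config"))
  if (is.null(frames)) {
    if (is.null(config$input)) stop("config$input is required")
    frames <- if (length(config$input) == 2)
      read_stack_pair(config$input[1], config$input[2])
    else read_stack(config$input, config$layout)
  }
  t0 <- Sys.time()
  results <- list()
  errors <- list()
  log_lines <- character(0)
  for (fr in frames) {
    tf <- Sys.time()
    res <- tryCatch(analyze_frame(fr, config), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- list(frame = fr$frame_index,
                                            message = conditionMessage(res))
      log_lines <- c(log_lines, jsonlite::toJSON(
        list(stage = "frame", frame = fr$frame_index, status = "error",
             message = conditionMessage(res)), auto_unbox = TRUE))
      next
    }
    results[[length(results) + 1L]] <- res
    log_lines <- c(log_lines, jsonlite::toJSON(
      list(stage = "frame", frame = fr$frame_index, status = "ok",
           n_blue = n_spots(res$blue$spots),
           n_red = if (is.null(res$red)) NA else n_spots(res$red$spots),
           seconds = round(as.numeric(Sys.time() - tf, units = "secs"), 3)),
      auto_unbox = TRUE))
  }
  summarize_channel <- function(ch) {
    sets <- lapply(results, function(r) r[[ch]]$spots)
    sets <- Filter(Negate(is.null), sets)
    if (!length(sets)) return(NULL)
    summarize_population(sets, n_images = length(sets), channel = ch)
  }
  coloc_frac <- function(method) {
    v <- vapply(results, function(r)
      if (!is.null(r$coloc[[method]])) r$coloc[[method]]$frac_mean else NA_real_,
      numeric(1))
    if (all(is.na(v))) NULL else mean(v, na.rm = TRUE)
  }
  report <- structure(list(
    frames = results,
    summary = list(blue = summarize_channel("blue"),
                   red = summarize_channel("red")),
    coloc_pct = list(position = coloc_frac("position"),
                     intensity = coloc_frac("intensity")),
    errors = errors, config = config,
    seconds = as.numeric(Sys.time() - t0, units = "secs")),
    class = "vq_run_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (r in results) {
      base <- file.path(config$out_dir,
                        sprintf("%s_frame%03d", config$label, r$frame_index))
      sp <- Filter(Negate(is.null),
                   list(r$blue$spots, if (!is.null(r$red)) r$red$spots))
      write_spot_table(sp, paste0(base, "_spots.csv"))
      for (m in names(r$coloc))
        if (nrow(r$coloc[[m]]$pairs))
          write.csv(r$coloc[[m]]$pairs,
                    paste0(base, "_pairs_", m, ".csv"), row.names = FALSE)
    }
    if (config$overlay && length(results)) {
      r1 <- results[[1]]
      if (!is.null(r1$red))
        write_overlay_png(r1$blue$corrected, r1$red$corrected,
                          r1$blue$spots, r1$red$spots,
                          coloc = r1$coloc[[1]],
                          path = file.path(config$out_dir,
                                           paste0(config$label, "_overlay.png")))
    }
    writeLines(log_lines, file.path(config$out_dir,
                                    paste0(config$label, "_run_log.jsonl")))
    jsonlite::write_json(report_json(report),
                         file.path(config$out_dir,
                                   paste0(config$label, "_report.json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

report_json <- function(report) {
  sum_json <- function(s) {
    if (is.null(s)) return(NULL)
    list(N = s$N, n_spots = s$n_spots, n_images = s$n_images,
         I_int_mean = unname(s$I_int["mean"]), I_int_sd = unname(s$I_int["sd"]),
         I_tot_mean = unname(s$I_tot["mean"]), I_tot_sd = unname(s$I_tot["sd"]),
         weibull_I_tot = if (s$fitted && !is.null(s$weibull$I_tot))
           s$weibull$I_tot[c("shape", "scale", "mode")] else NULL)
  }
  list(label = report$config$label, seed = report$config$seed,
       sfr = report$config$pre$sfr,
       n_frames = length(report$frames), n_errors = length(report$errors),
       blue = sum_json(report$summary$blue), red = sum_json(report$summary$red),
       coloc_pct = report$coloc_pct, seconds = report$seconds)
}

#' @export
print.vq_run_report <- function(x, ...) {
  cat(sprintf("<vq_run_report> %s: %d frame(s), %d error(s)\n",
              x$config$label, length(x$frames), length(x$errors)))
  for (ch in c("blue", "red"))
    if (!is.null(x$summary[[ch]])) print(x$summary[[ch]])
  for (m in names(x$coloc_pct))
    if (!is.null(x$coloc_pct[[m]]))
      cat(sprintf("  %s colocalization: %.1f%%\n", m, x$coloc_pct[[m]]))
  invisible(x)
}

#' Simulate a scene from a configuration and write it to disk
#'
#' CLI backend: takes [scene_params()] overrides (or a JSON file of them),
#' renders the scene, and writes the dual-view TIFF, the truth CSV, and
#' the parameter JSON.
#'
#' @param scene list of [scene_params()] overrides, or a path to a JSON
#'   file of them.
#' @param out,truth,params output paths (`NULL` skips truth/params).
#' @param seed overrides the seed in `scene` when not `NULL`.
#' @return the [generate_scene()] result, invisibly.
#' @export
simulate_run <- function(scene = list(), out, truth = NULL, params = NULL,
                         seed = NULL) {
  if (is.character(scene))
    scene <- jsonlite::read_json(scene, simplifyVector = TRUE)
  if (!is.null(scene$illumination) && is.character(scene$illumination$width))
    scene$illumination$width <- Inf
  if (!is.null(seed)) scene$seed <- as.integer(seed)
  if (!is.null(scene$intensity_weibull))
    scene$intensity_weibull <- lapply(scene$intensity_weibull, unlist)
  sp <- do.call(scene_params, scene)
  sc <- generate_scene(sp)
  write_scene(sc, out, truth, params)
  invisible(sc)
}
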