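# Batch measurement driver mirroring the interactive workflow: every
# project in a directory is processed with identical settings so related
# images are strictly comparable.

#' Camera configuration file
#'
#' Describes a camera/filter combination: the order in which channels are
#' extracted, which channel pairs to align (the nearest channels in mean
#' spectral sensitivity), and the path of the sensitivity CSV.
#'
#' @param path JSON file with fields `name`, `channel_order`,
#'   `align_pairs` (list of `[fixed, moving]`), `sensitivity_csv`.
#' @return An object of class `camera_config`.
#' @export
read_camera_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("name", "channel_order")
  miss <- setdiff(req, names(obj))
  if (length(miss))
    stop("read_camera_config: missing field(s) ", paste(miss, collapse = ", "))
  if (!is.null(obj$align_pairs)) {
    ap <- obj$align_pairs
    ap <- if (is.matrix(ap)) ap
          else if (is.data.frame(ap)) as.matrix(ap)
          else if (is.list(ap)) do.call(rbind, ap)
          else matrix(ap, ncol = 2, byrow = TRUE)
    bad <- setdiff(as.character(ap), obj$channel_order)
    if (length(bad))
      stop("read_camera_config: alignment channel(s) ",
           paste(bad, collapse = ", "), " not in channel_order")
    obj$align_pairs <- ap
  }
  structure(obj, class = "camera_config")
}

log_jsonl <- function(con, ...) {
  rec <- list(...)
  rec$time <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
}

#' Batch measurement of every project in a directory
#'
#' Processes each `*.mspec.json` project (sorted by name, so output is
#' independent of file-listing order) with identical settings: builds and
#' normalises the stack, optionally maps to cone-catch quanta, measures
#' every region (the whole image when a project has none), and optionally
#' computes granularity spectra and pairwise JND / pattern-difference
#' matrices. When pattern analysis is requested and projects carry scale
#' bars, stacks are first rescaled to a common pixels-per-mm.
#'
#' @param directory directory containing project files and their sources.
#' @param out_dir output directory for CSVs and the run log (default
#'   `directory`).
#' @param cone_map optional [fit_cone_map()] model (or path to a model
#'   JSON) applied before measurement.
#' @param granularity compute per-region band-energy spectra on
#'   `pattern_channel`.
#' @param pattern_channel channel used for granularity (default the first
#'   channel of each stack).
#' @param band_sizes granularity band sizes (px), default octave series.
#' @param target_px_per_mm uniform scale for pattern analysis; required
#'   when comparing granularity across photographs of different scales.
#' @param jnd_noise optional [receptor_noise()]; when given (with
#'   `cone_map`), writes the pairwise chromatic JND matrix over all
#'   measured regions.
#' @return Invisibly, a list with `status` (0 success, 1 partial failure,
#'   2 fatal), `measurements` data frame, and output file paths.
#' @export
batch_measure <- function(directory, out_dir = directory, cone_map = NULL,
                          granularity = FALSE, pattern_channel = NULL,
                          band_sizes = NULL, target_px_per_mm = NULL,
                          jnd_noise = NULL) {
  files <- sort(list.files(directory, pattern = "\\.mspec\\.json$",
                           full.names = TRUE))
  if (!length(files))
    stop("batch_measure: no .mspec.json projects in ", directory)
  if (is.character(cone_map)) cone_map <- read_cone_map(cone_map)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "batch_run_log.jsonl")
  con <- file(logf, "w"); on.exit(close(con))
  log_jsonl(con, event = "start",
            package_version = as.character(utils::packageVersion("multispec")),
            n_projects = length(files),
            settings = list(granularity = granularity,
                            cone_map = !is.null(cone_map),
                            target_px_per_mm = target_px_per_mm))
  meas_all <- list(); gran_all <- list(); failed <- 0L
  for (f in files) {
    pname <- sub("\\.mspec\\.json$", "", basename(f))
    res <- tryCatch({
      proj <- read_project(f)
      stack <- build_stack(proj, base_dir = dirname(f))
      if (!is.null(cone_map)) stack <- apply_cone_map(stack, cone_map)
      if (!is.null(target_px_per_mm) && !is.null(stack$px_per_mm)) {
        fac <- target_px_per_mm / stack$px_per_mm
        stack <- rescale_to_uniform(stack, target_px_per_mm)
        proj$regions <- lapply(proj$regions, rescale_region, factor = fac)
      }
      m <- measure_regions(stack, proj$regions)
      m <- cbind(project = pname, m)
      g <- NULL
      if (granularity) {
        pc <- pattern_channel %||% stack$channel_names[1]
        regs <- if (length(proj$regions)) proj$regions else list(NULL)
        g <- do.call(rbind, lapply(regs, function(rg) {
          sp <- granularity_spectrum(stack$channels[[pc]], region = rg,
                                     band_sizes = band_sizes,
                                     px_per_mm = stack$px_per_mm)
          cbind(project = pname,
                region = if (is.null(rg)) "whole_image" else rg$label,
                channel = pc, as.data.frame(sp))
        }))
      }
      list(m = m, g = g)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      log_jsonl(con, event = "project_failed", project = pname,
                error = conditionMessage(res))
      message("batch_measure: skipping ", pname, ": ",
              conditionMessage(res))
    } else {
      meas_all[[pname]] <- res$m
      if (!is.null(res$g)) gran_all[[pname]] <- res$g
      log_jsonl(con, event = "project_done", project = pname,
                n_rows = nrow(res$m))
    }
  }
  if (!length(meas_all)) {
    log_jsonl(con, event = "end", status = 2L)
    stop("batch_measure: every project failed (see ", logf, ")")
  }
  meas <- do.call(rbind, meas_all)
  meas <- meas[order(meas$project, meas$region, meas$channel), ]
  rownames(meas) <- NULL
  out <- list(status = if (failed) 1L else 0L, measurements = meas,
              files = character(0))
  mf <- file.path(out_dir, "measurements.csv")
  utils::write.csv(meas, mf, row.names = FALSE)
  out$files <- mf
  if (length(gran_all)) {
    gran <- do.call(rbind, gran_all)
    gran <- gran[order(gran$project, gran$region, gran$size_px), ]
    rownames(gran) <- NULL
    gf <- file.path(out_dir, "granularity.csv")
    utils::write.csv(gran, gf, row.names = FALSE)
    out$granularity <- gran; out$files <- c(out$files, gf)
  }
  if (!is.null(jnd_noise) && !is.null(cone_map)) {
    jm <- jnd_matrix(data.frame(
      region = paste(meas$project, meas$region, sep = ":"),
      channel = meas$channel, mean = meas$mean,
      stringsAsFactors = FALSE), jnd_noise)
    jf <- file.path(out_dir, "jnd_matrix.csv")
    utils::write.csv(as.data.frame(jm), jf, row.names = TRUE)
    out$jnd <- jm; out$files <- c(out$files, jf)
  }
  log_jsonl(con, event = "end", status = out$status)
  invisible(out)
}
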