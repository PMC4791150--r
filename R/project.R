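#' Multispectral project
#'
#' A project records everything needed to rebuild a calibrated stack from
#' its source images: source paths (relative, one per channel), per-channel
#' alignment offsets and scale, grey-standard selections with their stated
#' reflectances, a scale-bar record, and named regions of interest. It
#' serialises to documented JSON ([write_project()]) so a reloaded project
#' rebuilds the identical stack.
#'
#' @param sources named list, channel name -> `list(path, plane)` where
#'   `path` is relative to the project directory and `plane` selects the
#'   plane of a multi-plane file (default 1).
#' @param standards list of `list(reflectance_percent, region)` selections.
#' @param alignment named list, channel -> `list(dx, dy, scale)` applied
#'   when building the stack (default identity).
#' @param scale_bar optional `list(p1, p2, length_mm)` (see
#'   [set_scale_bar()]).
#' @param regions list of [region()] objects to measure.
#' @param normalization `list(method = "auto" | "dark-point" | "none")`.
#' @return An object of class `mspec_project`.
#' @export
mspec_project <- function(sources, standards = list(), alignment = NULL,
                          scale_bar = NULL, regions = list(),
                          normalization = list(method = "auto")) {
  if (!length(sources) || is.null(names(sources)))
    stop("mspec_project: sources must be a named list (channel -> path)")
  sources <- lapply(sources, function(s) {
    if (is.character(s)) s <- list(path = s, plane = 1L)
    if (is.null(s$plane)) s$plane <- 1L
    s
  })
  structure(list(sources = sources, standards = standards,
                 alignment = alignment, scale_bar = scale_bar,
                 regions = regions, normalization = normalization),
            class = "mspec_project")
}

#' @export
print.mspec_project <- function(x, ...) {
  cat(sprintf("<mspec_project: channels %s; %d standard(s), %d region(s)%s>\n",
              paste(names(x$sources), collapse = ", "),
              length(x$standards), length(x$regions),
              if (!is.null(x$scale_bar)) "; scale bar set" else ""))
  invisible(x)
}

#' Record a scale bar on a project
#'
#' @param project an [mspec_project()].
#' @param p1,p2 endpoints `c(x, y)` of a line drawn along a feature of
#'   known physical length.
#' @param physical_length_mm the feature's length in mm (> 0).
#' @return The project with `scale_bar` set; pixels per mm is their
#'   Euclidean distance divided by the length.
#' @export
set_scale_bar <- function(project, p1, p2, physical_length_mm) {
  if (physical_length_mm <= 0) stop("set_scale_bar: length must be > 0")
  d <- sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
  if (d == 0) stop("set_scale_bar: zero-length scale bar line")
  project$scale_bar <- list(p1 = as.numeric(p1), p2 = as.numeric(p2),
                            length_mm = as.numeric(physical_length_mm))
  project
}

#' Pixels-per-mm implied by a project's scale bar
#' @param project an [mspec_project()].
#' @return Numeric, or `NULL` when no scale bar is recorded.
#' @export
project_px_per_mm <- function(project) {
  sb <- project$scale_bar
  if (is.null(sb)) return(NULL)
  sqrt(sum((sb$p1 - sb$p2)^2)) / sb$length_mm
}

region_to_list <- function(reg)
  list(label = reg$label, vertices = unname(apply(reg$vertices, 1, as.numeric,
                                                  simplify = FALSE)),
       pool = reg$pool)

region_from_list <- function(lst)
  region(lst$label, do.call(rbind, lapply(lst$vertices, as.numeric)),
         pool = lst$pool)

#' Write a project to JSON
#' @param project an [mspec_project()].
#' @param path output path (conventionally `<name>.mspec.json`).
#' @return `path`, invisibly.
#' @export
write_project <- function(project, path) {
  std <- lapply(project$standards, function(s)
    list(reflectance_percent = s$reflectance_percent,
         region = region_to_list(s$region)))
  obj <- list(format = "multispec-project", version = 1L,
              sources = project$sources,
              standards = std,
              alignment = project$alignment,
              scale_bar = project$scale_bar,
              regions = lapply(project$regions, region_to_list),
              normalization = project$normalization)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a project from JSON
#' @param path a file written by [write_project()].
#' @return An [mspec_project()].
#' @export
read_project <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$format) || obj$format != "multispec-project")
    stop("read_project: ", path, " is not a multispec project file")
  std <- lapply(obj$standards, function(s)
    list(reflectance_percent = as.numeric(s$reflectance_percent),
         region = region_from_list(s$region)))
  sb <- obj$scale_bar
  if (!is.null(sb))
    sb <- list(p1 = as.numeric(unlist(sb$p1)), p2 = as.numeric(unlist(sb$p2)),
               length_mm = as.numeric(sb$length_mm))
  al <- obj$alignment
  if (!is.null(al))
    al <- lapply(al, function(a) list(dx = as.numeric(a$dx),
                                      dy = as.numeric(a$dy),
                                      scale = as.numeric(a$scale)))
  mspec_project(sources = obj$sources, standards = std, alignment = al,
                scale_bar = sb,
                regions = lapply(obj$regions, region_from_list),
                normalization = lapply(obj$normalization, identity))
}

# Measure the project's standard selections on a raw (linear) stack and
# fit the normalisation model the project asks for.
fit_project_standards <- function(project, raw_stack) {
  if (!length(project$standards))
    stop("build_stack: project defines no grey standards")
  dims <- dim(raw_stack)
  stds <- lapply(project$standards, function(s) {
    mask <- rasterize_region(s$region, dims)
    if (!any(mask))
      stop("build_stack: standard region '", s$region$label,
           "' lies outside the image bounds")
    mp <- vapply(raw_stack$channels, function(ch) mean(ch[mask], na.rm = TRUE),
                 numeric(1))
    standard_measurement(s$reflectance_percent, mp, region = s$region$label)
  })
  method <- project$normalization$method %||% "auto"
  if (method == "dark-point") {
    if (length(stds) != 1L)
      stop("build_stack: dark-point estimation requires exactly one standard")
    models <- lapply(raw_stack$channel_names, function(nm)
      estimate_dark_point(raw_stack$channels[[nm]], stds[[1]], channel = nm))
    new_norm_model(raw_stack$channel_names,
                   vapply(models, function(m) unname(m$slope), numeric(1)),
                   vapply(models, function(m) unname(m$intercept), numeric(1)),
                   rep(NA_real_, length(models)), "histogram-dark-point")
  } else {
    fit_normalization(stds)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the calibrated 32-bit stack a project describes
#'
#' Loads each source channel as 16-bit linear pixels, converts to floating
#' point, applies the stored per-channel alignment (scale about centre,
#' then translation), and normalises to reflectance using the project's
#' standard selections. Deterministic: the same project and sources give
#' an identical stack.
#'
#' @param project an [mspec_project()].
#' @param base_dir directory against which relative source paths resolve.
#' @param normalize build an unnormalised (linear) stack when `FALSE` or
#'   when the project's normalisation method is `"none"`.
#' @param model optional externally fitted `norm_model` (e.g. from the
#'   sequential method) used instead of the project's own standards.
#' @return An [mspec_stack()].
#' @export
build_stack <- function(project, base_dir = ".", normalize = TRUE,
                        model = NULL) {
  chans <- list()
  for (nm in names(project$sources)) {
    src <- project$sources[[nm]]
    p <- file.path(base_dir, src$path)
    if (!file.exists(p)) stop("build_stack: missing source image ", p)
    img <- load_linear_image(p, channel = as.integer(src$plane),
                             channel_name = nm)
    m <- matrix(as.numeric(img), nrow(img), ncol(img))
    al <- project$alignment[[nm]]
    if (!is.null(al))
      m <- transform_channel(m, dx = al$dx %||% 0, dy = al$dy %||% 0,
                             scale = al$scale %||% 1)
    chans[[nm]] <- m
  }
  stack <- mspec_stack(chans, normalized = FALSE,
                       px_per_mm = project_px_per_mm(project),
                       alignment = project$alignment)
  method <- project$normalization$method %||% "auto"
  if (!normalize || method == "none") return(stack)
  if (is.null(model)) model <- fit_project_standards(project, stack)
  apply_normalization(stack, model)
}
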