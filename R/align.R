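# Exhaustive coarse-to-fine channel alignment.
#
# Channels of a multispectral stack come from separate exposures (filter
# changes knock the camera; refocusing between wavebands zooms slightly),
# so each moving channel is registered to a fixed channel by minimising
# the absolute pixel difference over a 3x3 offset grid whose spacing
# starts large (e.g. 128 px) and halves down to 1 px, optionally nested
# inside a hill-climbing search over a centre-anchored scale factor.
# Feature-based registration is deliberately avoided: it is unreliable
# between UV and visible channels.

#' Mean absolute difference between two channels at a candidate alignment
#'
#' The moving channel is scaled about its centre then shifted by
#' `(dx, dy)`; the cost is the mean absolute difference over pixels where
#' both channels are defined (and inside `roi` if given). The mean -- not
#' the raw sum -- is used so that candidates with small overlaps are not
#' artificially favoured.
#'
#' @param fixed,moving numeric matrices of identical dimensions.
#' @param dx,dy integer pixel shift applied to the moving channel.
#' @param scale magnification about the moving channel's centre.
#' @param roi optional logical mask (same dimensions) restricting the
#'   comparison, e.g. a detailed region when the scene is mostly plain.
#' @return Non-negative cost; error if the overlap is empty.
#' @export
sad_cost <- function(fixed, moving, dx = 0, dy = 0, scale = 1, roi = NULL) {
  if (!identical(dim(fixed), dim(moving)))
    stop("sad_cost: channels must share dimensions")
  mv <- transform_channel(moving, dx = dx, dy = dy, scale = scale)
  d <- abs(fixed - mv)
  if (!is.null(roi)) d[!roi] <- NA_real_
  ok <- !is.na(d)
  if (!any(ok)) stop("sad_cost: empty overlap at offset (", dx, ", ", dy, ")")
  mean(d[ok])
}

new_alignment_result <- function(dx, dy, scale, cost, trace) {
  structure(list(dx = as.integer(dx), dy = as.integer(dy), scale = scale,
                 cost = cost, trace = trace),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment: dx=%d dy=%d scale=%.5f cost=%.6g (%d evaluations)>\n",
              x$dx, x$dy, x$scale, x$cost, nrow(x$trace)))
  invisible(x)
}

#' Coarse-to-fine translation alignment
#'
#' Evaluates the cost on a 3x3 grid of candidate offsets spaced by the
#' current step around the incumbent, moves to the best, halves the step,
#' and stops after the 1-px level. Deterministic: ties prefer the smaller
#' offset magnitude, then lexicographic (dx, dy).
#'
#' @inheritParams sad_cost
#' @param start_offset initial grid spacing, a positive power of two;
#'   reduced with a warning when the image is smaller than twice this.
#' @param scale fixed scale applied during the search (used by
#'   [align_with_scale()]).
#' @return An `alignment_result` with fields `dx`, `dy`, `scale`, `cost`
#'   and a `trace` data frame of every candidate visited.
#' @export
align_translation <- function(fixed, moving, start_offset = 128, roi = NULL,
                              scale = 1) {
  if (start_offset < 1 || bitwAnd(as.integer(start_offset),
                                  as.integer(start_offset) - 1L) != 0)
    stop("align_translation: start_offset must be a positive power of two")
  lim <- min(dim(fixed))
  if (lim < 2 * start_offset) {
    while (start_offset > 1 && lim < 2 * start_offset)
      start_offset <- start_offset / 2
    ms_warn("multispec_offset_reduced",
            "start_offset reduced to ", start_offset,
            " for a ", paste(dim(fixed), collapse = "x"), " image")
  }
  best <- c(dx = 0L, dy = 0L)
  best_cost <- sad_cost(fixed, moving, 0, 0, scale = scale, roi = roi)
  trace <- list(data.frame(level = NA_integer_, dx = 0L, dy = 0L,
                           cost = best_cost))
  off <- as.integer(start_offset)
  seen <- new.env(parent = emptyenv())
  while (off >= 1L) {
    # recentre on the best of the 3x3 grid until the incumbent is best,
    # then halve the spacing
    repeat {
      cand <- expand.grid(ddx = c(-off, 0L, off), ddy = c(-off, 0L, off))
      cand <- cand[!(cand$ddx == 0L & cand$ddy == 0L), ]
      costs <- numeric(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        dx <- best[["dx"]] + cand$ddx[i]; dy <- best[["dy"]] + cand$ddy[i]
        key <- paste(dx, dy)
        if (is.null(seen[[key]])) {
          seen[[key]] <- tryCatch(
            sad_cost(fixed, moving, dx, dy, scale = scale, roi = roi),
            error = function(e) Inf)
          trace[[length(trace) + 1L]] <-
            data.frame(level = off, dx = dx, dy = dy, cost = seen[[key]])
        }
        costs[i] <- seen[[key]]
      }
      ord <- order(costs,
                   abs(best[["dx"]] + cand$ddx) + abs(best[["dy"]] + cand$ddy),
                   best[["dx"]] + cand$ddx, best[["dy"]] + cand$ddy)
      if (costs[ord[1]] < best_cost) {
        best_cost <- costs[ord[1]]
        best <- c(dx = best[["dx"]] + cand$ddx[ord[1]],
                  dy = best[["dy"]] + cand$ddy[ord[1]])
      } else break
    }
    off <- off %/% 2L
  }
  new_alignment_result(best[["dx"]], best[["dy"]], scale, best_cost,
                       do.call(rbind, trace))
}

#' Exhaustive full-window translation search
#'
#' Brute-force enumeration of every integer offset within `max_offset`;
#' guaranteed global optimum of the cost, feasible only for small images.
#' Useful when the coarse-to-fine search stalls on periodic textures.
#'
#' @inheritParams align_translation
#' @param max_offset enumeration half-width in pixels.
#' @return An `alignment_result`.
#' @export
align_exhaustive <- function(fixed, moving, max_offset = 16, roi = NULL,
                             scale = 1) {
  best <- NULL; best_cost <- Inf; trace <- list()
  for (dy in -max_offset:max_offset) for (dx in -max_offset:max_offset) {
    cost <- tryCatch(sad_cost(fixed, moving, dx, dy, scale = scale, roi = roi),
                     error = function(e) Inf)
    trace[[length(trace) + 1L]] <- data.frame(level = 0L, dx = dx, dy = dy,
                                              cost = cost)
    better <- cost < best_cost ||
      (cost == best_cost && !is.null(best) &&
       (abs(dx) + abs(dy) < abs(best[1]) + abs(best[2])))
    if (better) { best <- c(dx, dy); best_cost <- cost }
  }
  new_alignment_result(best[1], best[2], scale, best_cost,
                       do.call(rbind, trace))
}

#' Joint translation and scale alignment
#'
#' Hill-climbs on a centre-anchored scale factor: the current scale is
#' perturbed by +/- the scale step, each candidate is fully re-aligned in
#' translation; if a perturbation improves the cost the search continues
#' from it, otherwise the step is halved, until the step drops below
#' 0.001. Ties prefer the scale nearer 1.
#'
#' @inheritParams align_translation
#' @param initial_scale_step first scale perturbation, in (0, 0.1].
#' @return An `alignment_result` (its trace is the final alignment's).
#' @export
align_with_scale <- function(fixed, moving, initial_scale_step = 0.01,
                             roi = NULL, start_offset = 128) {
  if (initial_scale_step <= 0 || initial_scale_step > 0.1)
    stop("align_with_scale: scale step must be in (0, 0.1]")
  evalscale <- local({
    cache <- new.env(parent = emptyenv())
    function(s) {
      key <- sprintf("%.9f", s)
      if (!is.null(cache[[key]])) return(cache[[key]])
      r <- suppressWarnings(align_translation(fixed, moving,
                                              start_offset = start_offset,
                                              roi = roi, scale = s))
      cache[[key]] <- r
      r
    }
  })
  cur <- evalscale(1)
  step <- initial_scale_step
  while (step >= 0.001) {
    up <- evalscale(cur$scale + step)
    dn <- evalscale(cur$scale - step)
    cand <- list(cur, up, dn)
    costs <- vapply(cand, function(r) r$cost, numeric(1))
    devs <- vapply(cand, function(r) abs(r$scale - 1), numeric(1))
    pick <- order(costs, devs)[1]
    if (pick == 1L) step <- step / 2 else cur <- cand[[pick]]
  }
  cur
}
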