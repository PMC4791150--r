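# Polynomial mapping from camera channel space to receptor cone-catch
# space. Camera colours are device dependent, so a per-receptor polynomial
# in the normalised camera quanta (no intercept: zero camera response must
# map to zero catch) is fitted against quanta computed from a reflectance
# spectra library under a chosen illuminant. Natural spectra are smooth
# enough for such low-order mappings to fit almost perfectly.

#' Polynomial term set over camera channels
#'
#' Terms are all single channels, all distinct pairwise products when the
#' interaction level is at least 2, all distinct triple products at level
#' 3, and squared channels when requested. There is never an intercept.
#'
#' @param channels character vector of base channel names.
#' @param interaction_level 1, 2 or 3.
#' @param squares include squared-channel terms.
#' @return An object of class `polynomial_terms`: list of character
#'   multisets with printable labels.
#' @export
polynomial_terms <- function(channels, interaction_level = 2,
                             squares = FALSE) {
  if (!interaction_level %in% 1:3)
    stop("polynomial_terms: interaction level must be 1, 2 or 3")
  if (anyDuplicated(channels)) stop("polynomial_terms: duplicate channels")
  terms <- lapply(channels, function(ch) ch)
  if (interaction_level >= 2 && length(channels) >= 2) {
    cmb <- utils::combn(channels, 2, simplify = FALSE)
    terms <- c(terms, cmb)
  }
  if (interaction_level >= 3 && length(channels) >= 3) {
    cmb <- utils::combn(channels, 3, simplify = FALSE)
    terms <- c(terms, cmb)
  }
  if (squares) terms <- c(terms, lapply(channels, function(ch) c(ch, ch)))
  labels <- vapply(terms, term_label, character(1))
  structure(list(channels = channels, terms = terms, labels = labels,
                 interaction_level = interaction_level, squares = squares),
            class = "polynomial_terms")
}

term_label <- function(term) {
  u <- unique(term)
  cnt <- vapply(u, function(x) sum(term == x), integer(1))
  paste(ifelse(cnt > 1, paste0(u, "^", cnt), u), collapse = "*")
}

#' @export
print.polynomial_terms <- function(x, ...) {
  cat(sprintf("<polynomial_terms: level %d%s, %d terms: %s>\n",
              x$interaction_level, if (x$squares) " + squares" else "",
              length(x$terms), paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Expand channel values into polynomial term values
#'
#' Each term's value is the product of its channel values, in term-list
#' order.
#'
#' @param channel_values named numeric vector, or a matrix/data frame with
#'   one column per channel (rows are samples or pixels).
#' @param terms a [polynomial_terms()].
#' @return A numeric vector (single sample) or matrix (one column per
#'   term) with the term labels as names.
#' @export
expand_terms <- function(channel_values, terms) {
  if (is.null(dim(channel_values))) {
    miss <- setdiff(terms$channels, names(channel_values))
    if (length(miss))
      stop("expand_terms: missing channel ", paste(miss, collapse = ", "))
    out <- vapply(terms$terms, function(tm) prod(channel_values[tm]),
                  numeric(1))
    names(out) <- terms$labels
    return(out)
  }
  cv <- as.matrix(channel_values)
  miss <- setdiff(terms$channels, colnames(cv))
  if (length(miss))
    stop("expand_terms: missing channel ", paste(miss, collapse = ", "))
  out <- vapply(terms$terms, function(tm) {
    v <- cv[, tm[1]]
    for (ch in tm[-1]) v <- v * cv[, ch]
    v
  }, numeric(nrow(cv)))
  out <- matrix(out, nrow = nrow(cv))
  colnames(out) <- terms$labels
  out
}

#' Build the paired camera/receptor training table
#'
#' For every spectrum in the library, computes the von-Kries-normalised
#' quantum catches of the camera channels and of the receptor channels
#' under the same illuminant (white reference: flat 100% reflectance).
#'
#' @param camera,receptors [sensitivity_bank()] objects; the camera must
#'   have at least as many channels as there are receptors.
#' @param illuminant a `spectral_curve` on the banks' grid.
#' @param library a [reflectance_library()] on the same grid.
#' @return A data frame with one row per spectrum, camera channels first
#'   then receptor channels; attributes `camera_channels` and
#'   `receptor_channels`.
#' @export
build_training_table <- function(camera, receptors, illuminant, library) {
  if (length(camera) < length(receptors))
    stop("build_training_table: the number of camera channels (",
         length(camera), ") must be equal to or greater than the number ",
         "of receptors (", length(receptors), ")")
  if (!same_grid(camera$curves[[1]], library$spectra[[1]]))
    stop("build_training_table: camera and library wavelength ranges differ")
  if (!same_grid(receptors$curves[[1]], library$spectra[[1]]))
    stop("build_training_table: receptor and library wavelength ranges differ")
  cam_wr <- white_reference(camera, illuminant)
  rec_wr <- white_reference(receptors, illuminant)
  # vectorised: quanta are crossproducts of (sens * illum) with reflectance
  refl <- vapply(library$spectra, function(s) s$values,
                 numeric(length(library$spectra[[1]]$values)))
  cam_w <- vapply(camera$curves, function(s) s$values * illuminant$values,
                  numeric(nrow(refl)))
  rec_w <- vapply(receptors$curves, function(s) s$values * illuminant$values,
                  numeric(nrow(refl)))
  cam_q <- crossprod(refl, cam_w)   # spectra x channels
  rec_q <- crossprod(refl, rec_w)
  cam_q <- sweep(cam_q, 2, cam_wr$quanta, "/")
  rec_q <- sweep(rec_q, 2, rec_wr$quanta, "/")
  colnames(cam_q) <- camera$channel_names
  colnames(rec_q) <- receptors$channel_names
  out <- as.data.frame(cbind(cam_q, rec_q))
  attr(out, "camera_channels") <- camera$channel_names
  attr(out, "receptor_channels") <- receptors$channel_names
  out
}

# Gaussian information criteria for a no-intercept least-squares fit.
fit_criterion <- function(rss, n, k, which = c("AIC", "BIC")) {
  which <- match.arg(which)
  pen <- if (which == "AIC") 2 else log(n)
  n * log(rss / n) + pen * k
}

fit_ols_terms <- function(X, y) {
  qr_ <- qr(X)
  keep <- seq_len(ncol(X))
  dropped <- character(0)
  if (qr_$rank < ncol(X)) {
    keep <- sort(qr_$pivot[seq_len(qr_$rank)])
    dropped <- colnames(X)[-keep]
    X <- X[, keep, drop = FALSE]
    qr_ <- qr(X)
  }
  coef <- qr.coef(qr_, y)
  rss <- sum((y - X %*% coef)^2)
  list(coef = coef, rss = rss, keep = keep, dropped = dropped)
}

#' Fit polynomial cone-catch mapping models
#'
#' Per receptor: ordinary least squares with no intercept on the expanded
#' camera term matrix. Optional backward stepwise simplification greedily
#' removes, one at a time, the term whose removal most improves the AIC or
#' BIC, stopping when no removal improves it; BIC penalises terms more
#' heavily and so tends to remove more of them. The training R-squared is
#' computed against the uncentred total sum of squares, consistent with
#' the absent intercept.
#'
#' @param table a [build_training_table()] result.
#' @param terms a [polynomial_terms()] over the camera channels.
#' @param simplification `"none"`, `"AIC"` or `"BIC"`.
#' @return An object of class `cone_map`: per-receptor surviving term
#'   labels, coefficients and R-squared, plus provenance fields.
#' @export
fit_cone_map <- function(table, terms, simplification = c("none", "AIC", "BIC")) {
  simplification <- match.arg(simplification)
  cam <- attr(table, "camera_channels")
  rec <- attr(table, "receptor_channels")
  if (is.null(cam) || is.null(rec))
    stop("fit_cone_map: table lacks camera/receptor channel attributes")
  X_full <- expand_terms(as.matrix(table[cam]), terms)
  n <- nrow(X_full)
  if (n < 2 * length(terms$terms))
    stop("fit_cone_map: need at least twice as many spectra (", n,
         ") as terms (", length(terms$terms), ")")
  receptors <- list()
  for (r in rec) {
    y <- table[[r]]
    fit <- fit_ols_terms(X_full, y)
    if (length(fit$dropped))
      ms_warn("multispec_aliased_terms",
              "receptor ", r, ": dropped aliased term(s) ",
              paste(fit$dropped, collapse = ", "))
    labels <- colnames(X_full)[fit$keep]
    X <- X_full[, fit$keep, drop = FALSE]
    if (simplification != "none") {
      crit <- fit_criterion(fit$rss, n, ncol(X), simplification)
      repeat {
        if (ncol(X) <= 1L) break
        cand_crit <- rep(Inf, ncol(X))
        cand_fit <- vector("list", ncol(X))
        for (j in seq_len(ncol(X))) {
          f <- fit_ols_terms(X[, -j, drop = FALSE], y)
          cand_fit[[j]] <- f
          cand_crit[j] <- fit_criterion(f$rss, n, ncol(X) - 1L, simplification)
        }
        # deterministic tie-break: lexicographically first dropped label
        best_j <- order(cand_crit, labels)[1]
        if (cand_crit[best_j] < crit) {
          crit <- cand_crit[best_j]
          X <- X[, -best_j, drop = FALSE]
          labels <- labels[-best_j]
          fit <- cand_fit[[best_j]]
        } else break
      }
    }
    r2 <- 1 - fit$rss / sum(y^2)
    receptors[[r]] <- list(terms = labels,
                           coefficients = stats::setNames(
                             as.numeric(fit$coef), labels),
                           r2 = r2)
  }
  structure(list(receptors = receptors, camera_channels = cam,
                 receptor_channels = rec, terms = terms,
                 simplification = simplification),
            class = "cone_map")
}

#' @export
print.cone_map <- function(x, ...) {
  cat(sprintf("<cone_map: %s -> %s (%s simplification)>\n",
              paste(x$camera_channels, collapse = ","),
              paste(x$receptor_channels, collapse = ","),
              x$simplification))
  for (r in names(x$receptors))
    cat(sprintf("  %s: %d terms, R^2 = %.6f\n", r,
                length(x$receptors[[r]]$terms), x$receptors[[r]]$r2))
  invisible(x)
}

#' Training R-squared per receptor
#' @param model a `cone_map`.
#' @return Named numeric vector.
#' @export
cone_map_r2 <- function(model)
  vapply(model$receptors, function(r) r$r2, numeric(1))

#' Convert a normalised stack to cone-catch images
#'
#' Applies the fitted polynomial per pixel: camera channels are expanded
#' into term values and dotted with each receptor's coefficients. Negative
#' reflectances (possible under an intercept normalisation model) are
#' floored at zero first, with a `multispec_floored_pixels` warning, since
#' quantum catches cannot be negative; output values above 1 are preserved
#' (fluorescent or specular surfaces).
#'
#' @param stack a normalised [mspec_stack()] containing at least the
#'   model's camera channels.
#' @param model a `cone_map`.
#' @return An [mspec_stack()] whose channels are the receptors.
#' @export
apply_cone_map <- function(stack, model) {
  if (!stack$normalized)
    stop("apply_cone_map: stack must be normalised to reflectance first")
  miss <- setdiff(model$camera_channels, stack$channel_names)
  if (length(miss))
    stop("apply_cone_map: stack lacks channel(s) ",
         paste(miss, collapse = ", "))
  dims <- dim(stack)
  cv <- vapply(model$camera_channels, function(nm)
    as.numeric(stack$channels[[nm]]), numeric(prod(dims)))
  if (any(cv < 0, na.rm = TRUE)) {
    ms_warn("multispec_floored_pixels",
            sum(cv < 0, na.rm = TRUE),
            " negative pixel(s) floored at 0 before cone mapping")
    cv[cv < 0] <- 0
  }
  colnames(cv) <- model$camera_channels
  full_terms <- expand_terms(cv, model$terms)
  out <- lapply(model$receptors, function(r) {
    v <- as.numeric(full_terms[, r$terms, drop = FALSE] %*% r$coefficients)
    matrix(v, dims[1], dims[2])
  })
  names(out) <- model$receptor_channels
  mspec_stack(out, normalized = TRUE, px_per_mm = stack$px_per_mm)
}

#' Write / read a cone-map model as JSON
#' @param model a `cone_map`.
#' @param path JSON path.
#' @return `path` (write) or a `cone_map` (read).
#' @export
write_cone_map <- function(model, path) {
  obj <- list(format = "multispec-conemap", version = 1L,
              camera_channels = model$camera_channels,
              receptor_channels = model$receptor_channels,
              interaction_level = model$terms$interaction_level,
              squares = model$terms$squares,
              simplification = model$simplification,
              receptors = lapply(model$receptors, function(r)
                list(terms = r$terms,
                     coefficients = as.list(r$coefficients), r2 = r$r2)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cone_map
#' @export
read_cone_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$format) || obj$format != "multispec-conemap")
    stop("read_cone_map: not a cone-map model file")
  cam <- as.character(unlist(obj$camera_channels))
  terms <- polynomial_terms(cam, obj$interaction_level, isTRUE(obj$squares))
  receptors <- lapply(obj$receptors, function(r)
    list(terms = as.character(unlist(r$terms)),
         coefficients = unlist(r$coefficients), r2 = as.numeric(r$r2)))
  structure(list(receptors = receptors, camera_channels = cam,
                 receptor_channels = as.character(unlist(obj$receptor_channels)),
                 terms = terms, simplification = obj$simplification),
            class = "cone_map")
}
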