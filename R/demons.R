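#' Demons registration parameters
#'
#' `sigma` is the width (in voxels) of the Gaussian kernel that regularizes
#' the displacement field after each update; `k` is the normalization
#' factor weighting the intensity-difference term in the force
#' denominators. The defaults (sigma = 1, k = 0.4) are the fixed values the
#' method uses for all registrations, single resolution, no multiresolution
#' pyramid. Iteration runs to `max_iterations`; a positive
#' `convergence_tol` additionally stops early once the relative decrease
#' of the mean squared intensity difference (MSD) over a 5-iteration
#' window falls below it. The default (0) disables early stopping: when
#' the two images are already well aligned outside a small region, the
#' global MSD plateaus long before the region of interest has finished
#' evolving, so the full budget is the safer default.
#'
#' @param sigma Gaussian kernel width, voxels, default 1.
#' @param k force normalization factor, default 0.4.
#' @param max_iterations iteration budget, default 200.
#' @param convergence_tol relative MSD decrease threshold; 0 (default)
#'   disables early stopping.
#' @return An object of class `registration_params`.
#' @export
registration_params <- function(sigma = 1, k = 0.4, max_iterations = 200,
                                convergence_tol = 0) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (!is.numeric(k) || k <= 0) stop("k must be > 0", call. = FALSE)
  if (!is.numeric(max_iterations) || max_iterations < 1)
    stop("max_iterations must be >= 1", call. = FALSE)
  structure(list(sigma = sigma, k = k,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "registration_params")
}

# Denominator floor below which a force term contributes zero.
DEMONS_EPS <- 1e-9

#' Symmetric (active-force) Demons update
#'
#' Per-voxel update, in the backward-mapping convention of
#' [warp_image()]:
#' `u = (I - I') * [ gS / (|gS|^2 + k^2 (I - I')^2) + gM / (|gM|^2 + k^2 (I - I')^2) ]`
#' where `I` is the static intensity, `I'` the warped-moving intensity, and
#' `gS`, `gM` their spatial gradients (HU/mm). The moving-gradient term is
#' the "active force" that accelerates convergence over the classic
#' static-gradient-only form. Voxels where a denominator falls below a
#' small floor contribute zero for that term. Swapping the two images
#' negates the force.
#'
#' @param static,warped_moving grid-compatible [volume_image()]s (the
#'   moving image already warped by the current field).
#' @param k normalization factor, default 0.4.
#' @return A 4D array `dim x 3` of displacement updates (mm).
#' @export
demons_force <- function(static, warped_moving, k = 0.4) {
  stopifnot(inherits(static, "volume_image"), inherits(warped_moving, "volume_image"))
  stop_if_incompatible(static, warped_moving, "static and warped moving images")
  d <- dim(static$values)
  u <- cpp_demons_force(as.numeric(static$values), as.numeric(warped_moving$values),
                        d, static$spacing, k, DEMONS_EPS)
  array(u, c(d, 3L))
}

#' Gaussian regularization of a displacement field
#'
#' Componentwise Gaussian convolution with kernel width `sigma` (voxels),
#' truncated at 3 sigma, boundaries handled by nearest-edge replication.
#'
#' @param field a [displacement_field()].
#' @param sigma kernel width in voxels, default 1.
#' @return A [displacement_field()].
#' @export
regularize_field <- function(field, sigma = 1) {
  stopifnot(inherits(field, "displacement_field"), sigma > 0)
  d <- dim(field$vectors)[1:3]
  out <- field$vectors
  for (c in 1:3)
    out[, , , c] <- array(cpp_smooth3(as.numeric(field$vectors[, , , c]), d,
                                      rep(sigma, 3)), d)
  displacement_field(out, field$spacing, field$origin)
}

#' Single-resolution symmetric-force Demons registration
#'
#' Iterates `D_n = G_sigma * (D_{n-1} + u_n)` where `u_n` is the symmetric
#' Demons force ([demons_force()]) computed between the static image and
#' the moving image warped by `D_{n-1}`, and `G_sigma` is componentwise
#' Gaussian smoothing ([regularize_field()]). The moving gradient is
#' recomputed on the warped moving image at every iteration. Runs at a
#' single resolution. Identical inputs yield an identically zero field for
#' any iteration budget.
#'
#' @param static,moving grid-compatible [volume_image()]s (already
#'   preprocessed and rigidly aligned).
#' @param params a [registration_params()].
#' @return An object of class `demons_registration` with elements `field`
#'   (a [displacement_field()]), `msd` (mean squared intensity difference
#'   per iteration), `iterations`, `converged`, `params`.
#' @export
demons_register <- function(static, moving, params = registration_params()) {
  stopifnot(inherits(static, "volume_image"), inherits(moving, "volume_image"),
            inherits(params, "registration_params"))
  stop_if_incompatible(static, moving, "static and moving images")
  d <- dim(static$values)
  res <- cpp_demons_run(as.numeric(static$values), as.numeric(moving$values),
                        d, static$spacing, params$sigma, params$k,
                        params$max_iterations, params$convergence_tol,
                        -1000, DEMONS_EPS)
  field <- displacement_field(array(res$field, c(d, 3L)),
                              static$spacing, static$origin)
  structure(list(field = field, msd = as.numeric(res$msd),
                 iterations = res$iterations, converged = res$converged,
                 params = params),
            class = "demons_registration")
}

#' @export
print.demons_registration <- function(x, ...) {
  cat(sprintf("<demons_registration> %d iterations (%s), MSD %.4g -> %.4g\n",
              x$iterations, if (x$converged) "converged" else "budget reached",
              x$msd[1], x$msd[length(x$msd)]))
  print(x$field)
  invisible(x)
}

#' @export
summary.demons_registration <- function(object, ...) {
  mag <- sqrt(rowSums(matrix(object$field$vectors, ncol = 3L)^2))
  out <- list(iterations = object$iterations, converged = object$converged,
              msd_first = object$msd[1], msd_last = object$msd[length(object$msd)],
              mean_displacement_mm = mean(mag), max_displacement_mm = max(mag),
              params = object$params)
  class(out) <- "summary.demons_registration"
  out
}

#' @export
print.summary.demons_registration <- function(x, ...) {
  cat(sprintf(paste0("Demons registration (sigma = %g voxels, k = %g)\n",
                     "  iterations: %d (%s)\n",
                     "  MSD: %.4g -> %.4g\n",
                     "  displacement: mean %.3f mm, max %.3f mm\n"),
              x$params$sigma, x$params$k, x$iterations,
              if (x$converged) "converged" else "budget reached",
              x$msd_first, x$msd_last,
              x$mean_displacement_mm, x$max_displacement_mm))
  invisible(x)
}

#' Plot the Demons convergence curve
#'
#' Mean squared intensity difference against iteration, log-scaled.
#'
#' @param x a `demons_registration`.
#' @param ... passed to [plot()].
#' @importFrom graphics plot
#' @export
plot.demons_registration <- function(x, ...) {
  plot(seq_along(x$msd), x$msd, type = "l", log = "y",
       xlab = "iteration", ylab = "mean squared intensity difference", ...)
  invisible(x)
}
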