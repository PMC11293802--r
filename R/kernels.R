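#' Kernel specification for spatial weighting
#'
#' The kernel maps the distance from a focal region to each observation's
#' region into a weight in \[0, 1\]; `bandwidth` is the decay scale b. When
#' the bandwidth is to be estimated, supply `D`, the upper bound of its
#' Uniform(0, D) prior, instead of a fixed `bandwidth`.
#'
#' Kernels: exponential `exp(-d/b)`, gaussian `exp(-(d/b)^2)`, and
#' bi-square `(1-(d/b)^2)^2` for `d < b`, zero beyond.
#'
#' @param kernel One of `"exponential"`, `"gaussian"`, `"bisquare"`.
#' @param bandwidth Fixed positive bandwidth, or `NULL` to estimate.
#' @param D Positive upper bound of the uniform bandwidth prior (required
#'   when `bandwidth` is `NULL`).
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(kernel = c("exponential", "gaussian", "bisquare"),
                        bandwidth = NULL, D = NULL) {
  kernel <- match.arg(kernel)
  if (is.null(bandwidth) && is.null(D)) {
    stop("supply a fixed bandwidth or a prior upper bound D")
  }
  if (!is.null(bandwidth) && bandwidth <= 0) stop("bandwidth must be positive")
  if (!is.null(D) && D <= 0) stop("D must be positive")
  structure(list(kernel = kernel, bandwidth = bandwidth, D = D),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("kernel_spec: %s, %s\n", x$kernel,
              if (is.null(x$bandwidth)) sprintf("bandwidth ~ Uniform(0, %g)", x$D)
              else sprintf("bandwidth fixed at %g", x$bandwidth)))
  invisible(x)
}

kernel_id <- function(kernel) {
  match(kernel, c("exponential", "gaussian", "bisquare")) - 1L
}

#' Kernel weights for distances to a focal region
#'
#' @param d Nonnegative numeric vector of distances.
#' @param spec A [kernel_spec()] with a fixed bandwidth, or a kernel name
#'   (then `bandwidth` must be given).
#' @param bandwidth Bandwidth override (positive).
#' @return Numeric weights in \[0, 1\], equal to 1 at `d = 0` and
#'   nonincreasing in `d`.
#' @examples
#' kernel_weights(10, kernel_spec("exponential", bandwidth = 100)) # 0.904...
#' @export
kernel_weights <- function(d, spec, bandwidth = NULL) {
  if (is.character(spec)) spec <- kernel_spec(spec, bandwidth = bandwidth)
  b <- if (!is.null(bandwidth)) bandwidth else spec$bandwidth
  if (is.null(b)) stop("no bandwidth: spec has only a prior bound")
  if (b <= 0) stop("bandwidth must be positive")
  if (any(d < 0)) stop("distances must be nonnegative")
  switch(spec$kernel,
    exponential = exp(-d / b),
    gaussian    = exp(-(d / b)^2),
    bisquare    = ifelse(d < b, (1 - (d / b)^2)^2, 0))
}
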