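#' Logarithmic size grid for the fragmentation solver
#'
#' The solver works in the variable `w = log(x)` on a uniform grid
#' `w_1, ..., w_p, ..., w_I` with spacing `delta_w` and a pivot index `p`
#' such that `w_p = 0` (`x_p = 1`). The uniform spacing gives the index
#' arithmetic `w_i + w_j = w_(i+j-p)` that the redistribution sum relies on.
#'
#' @param xmin,xmax Size range covered by the grid; must bracket 1.
#' @param size Number of grid points `I`. Default 600.
#' @param snap_log2 If `TRUE`, `delta_w` is adjusted so that `log(2)` is an
#'   integer number of grid steps. Required for the Dirac-half kernel, whose
#'   redistribution is a single index shift by `log(2)/delta_w`.
#' @return An object of class `log_grid` with fields `w`, `x = exp(w)`,
#'   `delta_w`, `p` and `size`.
#' @examples
#' g <- log_grid(1e-4, 1e3, 600)
#' g$x[g$p] # exactly 1
#' @export
log_grid <- function(xmin = 1e-4, xmax = 1e3, size = 600L, snap_log2 = FALSE) {
  if (!(xmin > 0 && xmin < 1 && xmax > 1)) stop_frag("need 0 < xmin < 1 < xmax")
  if (size < 10L) stop_frag("grid size must be at least 10")
  delta_w <- log(xmax / xmin) / (size - 1L)
  if (snap_log2) delta_w <- log(2) / max(1L, round(log(2) / delta_w))
  p <- as.integer(round(1 + (0 - log(xmin)) / delta_w))
  p <- max(2L, min(size - 1L, p))
  w <- (seq_len(size) - p) * delta_w
  structure(list(w = w, x = exp(w), delta_w = delta_w, p = p, size = as.integer(size)),
            class = "log_grid")
}

#' @export
print.log_grid <- function(x, ...) {
  cat(sprintf("<log_grid> I = %d points, x in [%.3g, %.3g], delta_w = %.4g, pivot p = %d\n",
              x$size, min(x$x), max(x$x), x$delta_w, x$p))
  invisible(x)
}

default_grid <- function(kernel, xmin = 1e-4, xmax = 1e3, size = 600L) {
  log_grid(xmin, xmax, size, snap_log2 = !is.null(kernel$atom))
}
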