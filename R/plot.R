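# Quick-look plotting of fitted smooths (base graphics).

#' Plot the smooth terms of a fit
#'
#' Draws each univariate smooth's contribution over its covariate range with
#' the pointwise 95% band (dashed). Tensor terms are skipped; export them
#' with [predict_terms()] on a grid for contour plotting.
#'
#' @param x an `hg_fit` with a `data` element (as produced by the model
#'   constructors).
#' @param n_grid grid points per smooth.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hg_fit <- function(x, n_grid = 200, ...) {
  if (is.null(x$data)) stop("fit carries no data; plot via predict_terms()")
  sm <- Filter(function(tm) tm$type == "smooth" && length(tm$vars) == 1L,
               x$design$terms)
  if (!length(sm)) return(invisible(x))
  op <- graphics::par(mfrow = c(1, length(sm)))
  on.exit(graphics::par(op))
  for (tm in sm) {
    xv <- x$data[[tm$vars]]
    grid <- seq(min(xv), max(xv), length.out = n_grid)
    nd <- x$data[rep(1L, n_grid), , drop = FALSE]
    nd[[tm$vars]] <- grid
    for (v in setdiff(names(nd), tm$vars))
      if (is.numeric(nd[[v]])) nd[[v]] <- stats::median(x$data[[v]])
    pt <- predict_terms(x, nd)$terms[[tm$label]]
    graphics::plot(grid, pt$value, type = "l", xlab = tm$vars,
                   ylab = tm$label, ...)
    graphics::lines(grid, pt$lower, lty = 2)
    graphics::lines(grid, pt$upper, lty = 2)
  }
  invisible(x)
}
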