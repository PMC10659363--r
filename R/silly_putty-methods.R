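#' @export
print.silly_putty <- function(x, ...) {
  what <- if (identical(x$method, "silly_putty")) "Multi-start SillyPutty fit"
          else "SillyPutty refinement"
  cat(what, "\n", sep = "")
  cat(sprintf("  samples: %d   clusters: %d   ASW: %s\n",
              x$n, x$k_effective,
              if (is.na(x$asw)) "NA" else sprintf("%.4f", x$asw)))
  cat(sprintf("  termination: %s after %d reassignment%s\n",
              x$termination, x$iterations, if (x$iterations == 1L) "" else "s"))
  if (!is.null(x$restarts)) {
    cat(sprintf("  restarts: %d (best: #%d)\n", x$restarts, x$best_restart))
  }
  invisible(x)
}

#' @export
labels.silly_putty <- function(object, ...) object$labels

#' Summary of a SillyPutty fit
#'
#' Reports cluster sizes, per-cluster mean silhouette widths, and the
#' termination diagnostics of the refinement.
#'
#' @param object A `"silly_putty"` object.
#' @param ... Unused.
#' @return A list of class `"summary.silly_putty"`.
#' @export
summary.silly_putty <- function(object, ...) {
  cl <- NULL
  if (!is.null(object$profile)) {
    p <- object$profile
    cl <- data.frame(
      cluster = sort(unique(p$cluster)),
      size = as.integer(table(p$cluster)[as.character(sort(unique(p$cluster)))]),
      mean_s = as.numeric(tapply(p$s, p$cluster, mean)[as.character(sort(unique(p$cluster)))]),
      min_s = as.numeric(tapply(p$s, p$cluster, min)[as.character(sort(unique(p$cluster)))])
    )
  }
  structure(list(fit = object, clusters = cl), class = "summary.silly_putty")
}

#' @export
print.summary.silly_putty <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$clusters)) {
    cat("\nPer-cluster silhouette summary:\n")
    print(x$clusters, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$fit$restart_asw)) {
    cat(sprintf("\nRestart ASW: min %.4f / median %.4f / max %.4f\n",
                min(x$fit$restart_asw), stats::median(x$fit$restart_asw),
                max(x$fit$restart_asw)))
  }
  invisible(x)
}

#' Silhouette plot of a SillyPutty fit
#'
#' Draws the classic silhouette bar plot: widths sorted within cluster,
#' one shaded block per cluster, with the ASW marked.
#'
#' @param x A `"silly_putty"` object with a non-degenerate profile.
#' @param col Colours recycled over clusters.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the reordered silhouette widths.
#' @export
plot.silly_putty <- function(x, col = NULL, ...) {
  if (is.null(x$profile)) stop("degenerate fit has no silhouette profile")
  p <- x$profile
  ord <- order(p$cluster, -p$s)
  s <- p$s[ord]
  cl <- p$cluster[ord]
  ucl <- unique(cl)
  if (is.null(col)) col <- grDevices::gray.colors(length(ucl))
  graphics::barplot(rev(s), horiz = TRUE, border = NA, space = 0,
                    col = rev(col[match(cl, ucl)]),
                    xlab = "silhouette width", ...)
  graphics::abline(v = x$asw, lty = 2)
  graphics::mtext(sprintf("ASW = %.3f (%d clusters)", x$asw, x$k_effective),
                  side = 3, line = 0.5)
  invisible(s)
}
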