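# broom-style tidiers and ggplot2 autoplot methods for the report objects.
# Registered softly so the package works without broom/ggplot2 attached.

#' Tidy a CV report
#'
#' One row per fold with its held-out accuracy.
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A data frame with columns `fold`, `accuracy`, `model`.
#' @export
tidy.cv_report <- function(x, ...) {
  data.frame(fold = seq_along(x$fold_accuracies),
             accuracy = x$fold_accuracies,
             model = x$model)
}

#' Glance at a CV report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A one-row data frame (same shape as [report_row()]).
#' @export
glance.cv_report <- function(x, ...) report_row(x)

#' @export
tidy.training_history <- function(x, ...) {
  long <- utils::stack(as.data.frame(x)[setdiff(names(x), "epoch")])
  data.frame(epoch = rep(x$epoch, length.out = nrow(long)),
             metric = as.character(long$ind), value = long$values)
}

#' Plot a quanvolution feature map
#'
#' Four tiles, one per qubit channel, on the shared `[-1, 1]` expectation
#' scale.
#'
#' @param object A `feature_map` from [quanvolve_image()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_map <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for autoplot")
  }
  d <- dim(object)
  df <- expand.grid(row = seq_len(d[1L]), col = seq_len(d[2L]), channel = seq_len(d[3L]))
  df$value <- as.vector(unclass(object))
  df$channel <- paste0("<Z", df$channel - 1L, ">")
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel, nrow = 1L) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "navy",
                                  mid = "white", high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "<Z>")
}

#' Plot a training history
#'
#' Loss and accuracy (and their validation counterparts when present)
#' against the epoch.
#'
#' @param object A `training_history` from [train_hybrid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.training_history <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for autoplot")
  }
  df <- tidy.training_history(object)
  ggplot2::ggplot(df, ggplot2::aes(x = epoch, y = value, colour = metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}

utils::globalVariables(c("col", "row", "value", "metric", "epoch", "channel"))

# generics live in broom/ggplot2; register our methods only if available
register_s3_soft <- function(pkg, generic, class) {
  if (requireNamespace(pkg, quietly = TRUE)) {
    registerS3method(generic, class, get(paste0(generic, ".", class),
                                         envir = asNamespace("quanvolve")),
                     envir = asNamespace(pkg))
  }
}

.onLoad <- function(libname, pkgname) {
  register_s3_soft("broom", "tidy", "cv_report")
  register_s3_soft("broom", "glance", "cv_report")
  register_s3_soft("broom", "tidy", "training_history")
  register_s3_soft("ggplot2", "autoplot", "feature_map")
  register_s3_soft("ggplot2", "autoplot", "training_history")
}
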