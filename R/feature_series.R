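#' Feature series: a time-ordered matrix of collective variables
#'
#' The exchange container between featurisation, tICA and microstate
#' clustering: a frames-by-features numeric matrix plus the physical time per
#' frame and free-form provenance. One `feature_series` holds one contiguous
#' trajectory; stages that accept multiple disjoint trajectories take a list
#' of them and never let time-lagged pairs straddle a boundary.
#'
#' @param values Numeric matrix, frames x features.
#' @param frame_interval Physical time per frame (arbitrary but consistent
#'   units; the pipeline carries them through to timescales and MFPTs).
#' @param provenance Named list recording how the series was produced.
#' @return An object of class `feature_series`.
#' @export
feature_series <- function(values, frame_interval = 1, provenance = list()) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    abort("feature values must be finite numerics")
  if (frame_interval <= 0) abort("frame_interval must be > 0")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  structure(
    list(values = values, frame_interval = frame_interval,
         provenance = provenance),
    class = "feature_series"
  )
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %d frames x %d features, dt = %g\n",
              nrow(x$values), ncol(x$values), x$frame_interval))
  invisible(x)
}

#' @export
dim.feature_series <- function(x) dim(x$values)

#' @export
as.matrix.feature_series <- function(x, ...) x$values

#' @export
as_tibble.feature_series <- function(x, ...) {
  out <- as_tibble(x$values)
  out$frame <- seq_len(nrow(x$values))
  out$time <- (out$frame - 1) * x$frame_interval
  dplyr::relocate(out, "frame", "time")
}

#' Write / read a feature series as tab-delimited text
#'
#' Plain TSV with a header row; the frame interval is stored in a `#dt=`
#' comment on the first line so a round trip preserves the time base.
#'
#' @param x A [feature_series()].
#' @param path File path.
#' @return `read_feature_series()` returns a `feature_series`.
#' @export
write_feature_series <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#dt=%.17g", x$frame_interval), con)
  utils::write.table(x$values, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_series
#' @export
read_feature_series <- function(path) {
  first <- readLines(path, n = 1)
  dt <- if (startsWith(first, "#dt=")) {
    as.numeric(sub("^#dt=", "", first))
  } else 1
  skip <- if (startsWith(first, "#dt=")) 1L else 0L
  vals <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                      skip = skip, check.names = FALSE))
  feature_series(vals, frame_interval = dt,
                 provenance = list(source = path))
}

# coerce x into a list of feature_series (stages accepting disjoint trajs)
as_series_list <- function(x) {
  if (inherits(x, "feature_series")) return(list(x))
  if (is.matrix(x)) return(list(feature_series(x)))
  if (is.list(x) && all(vapply(x, inherits, TRUE, "feature_series"))) return(x)
  abort("expected a feature_series, a matrix, or a list of feature_series")
}
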