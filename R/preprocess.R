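#' Background-correct probe intensities
#'
#' \code{method = "none"} returns the input unchanged.  \code{method =
#' "shift"} subtracts a low-quantile per-sample baseline and floors the
#' result at a small positive constant, a deliberately simple stand-in for
#' convolution-based background models: downstream statistics here operate
#' on within-probeset log-ratios and depend only weakly on the background
#' model.
#'
#' @param m a linear-scale \code{ProbeMatrix}.
#' @param method \code{"none"} or \code{"shift"}.
#' @param baseline_quantile quantile defining the per-sample baseline
#'   (default 0.005, i.e. the 0.5th percentile).
#' @param floor lower bound applied after subtraction (default 1.0).
#' @return A \code{ProbeMatrix} on the linear scale.
#' @export
background_correct <- function(m, method = c("none", "shift"),
                               baseline_quantile = 0.005, floor = 1.0) {
  method <- match.arg(method)
  if (m$scale != "linear") {
    stop("background_correct_scale: input must be linear scale")
  }
  if (method == "none") return(m)
  x <- m$intensity
  base <- apply(x, 2L, stats::quantile, probs = baseline_quantile,
                names = FALSE, type = 7)
  x <- sweep(x, 2L, base, "-")
  x[x < floor] <- floor
  ProbeMatrix(x, m$probeset_id, m$probe_index, scale = "linear")
}

#' Quantile-normalize sample columns
#'
#' Every sample column is mapped onto the across-sample mean of order
#' statistics, preserving within-column rank order; tied values receive the
#' average of the values assigned to the tied ranks.
#'
#' @param m a linear-scale \code{ProbeMatrix} with >= 2 samples.
#' @return A \code{ProbeMatrix} whose columns share an identical multiset
#'   of values.
#' @export
quantile_normalize <- function(m) {
  if (m$scale != "linear") stop("quantile_normalize_scale: input must be linear scale")
  if (ncol(m$intensity) < 2L) stop("quantile_normalize_samples: need >= 2 samples")
  x <- limma::normalizeQuantiles(m$intensity, ties = TRUE)
  dimnames(x) <- dimnames(m$intensity)
  ProbeMatrix(x, m$probeset_id, m$probe_index, scale = "linear")
}

#' Log2-transform a linear-scale probe matrix
#'
#' @param m a linear-scale \code{ProbeMatrix} with all intensities > 0.
#' @return A \code{ProbeMatrix} with scale flag \code{log2}.
#' @export
log2_transform <- function(m) {
  if (m$scale != "linear") stop("log2_transform_scale: input already log2")
  bad <- which(m$intensity <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("log2_transform_nonpositive: non-positive value at probeset %s probe %d sample %s",
                 m$probeset_id[bad[1L, 1L]], m$probe_index[bad[1L, 1L]],
                 colnames(m$intensity)[bad[1L, 2L]]))
  }
  ProbeMatrix(log2(m$intensity), m$probeset_id, m$probe_index, scale = "log2")
}

#' Invert the log2 transform
#'
#' @param m a log2-scale \code{ProbeMatrix}.
#' @return The matrix back on the linear scale.
#' @export
linear_transform <- function(m) {
  if (m$scale != "log2") stop("linear_transform_scale: input already linear")
  ProbeMatrix(2^m$intensity, m$probeset_id, m$probe_index, scale = "linear")
}

#' Summarize probe-level values to one expression value per probeset
#'
#' \code{median_polish} runs Tukey median polish on each probeset's
#' probe x sample sub-matrix (row sweeps first, tolerance 1e-6, at most 10
#' iterations) and reports overall + column effects per sample, the usual
#' robust multi-probe summary for short-oligo arrays; \code{mean} reports
#' per-sample probe means.
#'
#' @param m a log2-scale \code{ProbeMatrix}.
#' @param method \code{"median_polish"} or \code{"mean"}.
#' @return A data.frame (class \code{ProbesetExpression}) with
#'   \code{probeset_id} and one summarized log2 column per sample.
#' @export
summarize_probesets <- function(m, method = c("median_polish", "mean")) {
  method <- match.arg(method)
  if (m$scale != "log2") stop("summarize_probesets_scale: input must be log2 scale")
  sets <- unique(m$probeset_id)
  idx <- split(seq_along(m$probeset_id), m$probeset_id)[sets]
  ns <- ncol(m$intensity)
  out <- matrix(NA_real_, length(sets), ns,
                dimnames = list(sets, colnames(m$intensity)))
  single_warned <- FALSE
  for (i in seq_along(sets)) {
    sub <- m$intensity[idx[[i]], , drop = FALSE]
    if (method == "mean" || nrow(sub) == 1L) {
      if (method == "median_polish" && nrow(sub) == 1L && !single_warned) {
        warning("summarize_probesets: single-probe probeset(s); median_polish falls back to mean")
        single_warned <- TRUE
      }
      out[i, ] <- colMeans(sub)
    } else {
      mp <- suppressWarnings(  # iteration cap is intentional, not a failure
        stats::medpolish(sub, eps = 1e-6, maxiter = 10L, trace.iter = FALSE,
                         na.rm = FALSE))
      out[i, ] <- mp$overall + mp$col
    }
  }
  res <- data.frame(probeset_id = sets, out, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("ProbesetExpression", "data.frame")
  res
}
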