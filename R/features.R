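#' Band features for a stream of epochs
#'
#' Applies one of the three time-frequency feature extractors to every
#' epoch of a [slice_epochs()] tibble, flattening the electrodes-by-bands
#' matrix into one row per epoch (electrode-major order, columns named
#' `<electrode>_<band>`; nine electrodes and three bands give the 27
#' features per epoch used for classification).
#'
#' @param epochs Tibble from [slice_epochs()] (list-column `data` of
#'   channels-by-samples matrices).
#' @param fs Sampling rate in Hz.
#' @param method "fft" (band power, expects a high-passed trial), "hht"
#'   (Hilbert-Huang marginal-spectrum peaks) or "st" (Stockwell
#'   marginal-spectrum peaks).
#' @param bands Band list from [band_set()].
#' @param ... Extra arguments for the per-epoch extractor
#'   ([fft_band_features()], [hht_band_features()], [st_band_features()]).
#' @return Tibble: `epoch_id`, `window_id`, `state`, `t_begin`, then one
#'   numeric column per feature.
#' @export
epoch_features <- function(epochs, fs, method = c("fft", "hht", "st"),
                           bands = band_set(), ...) {
  method <- match.arg(method)
  fn <- switch(method,
               fft = function(m) fft_band_features(m, fs, bands, ...),
               hht = function(m) hht_band_features(m, fs, bands, ...),
               st = function(m) st_band_features(m, fs, bands, ...))
  feats <- lapply(epochs$data, function(m) {
    fm <- fn(m)
    v <- as.vector(t(fm))  # electrode-major
    names(v) <- paste(rep(rownames(fm), each = ncol(fm)),
                      rep(colnames(fm), times = nrow(fm)), sep = "_")
    v
  })
  fmat <- do.call(rbind, feats)
  out <- dplyr::bind_cols(
    epochs[, c("epoch_id", "window_id", "state", "t_begin")],
    tibble::as_tibble(fmat))
  attr(out, "method") <- method
  out
}
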