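#' Simulate a 4-channel Sanger chromatogram around an editing site
#'
#' Produces a synthetic trace for an 11-mer sequence context centered on an
#' adenosine, where the center position carries a mixed A/G signal: the
#' G-channel peak height is proportional to `true_level` and the A-channel
#' peak to `1 - true_level`. Peaks are Gaussian with one basecall every 12
#' scan points; independent Gaussian noise of standard deviation
#' `noise_sd` is added to every channel and intensities are clipped at
#' zero.
#'
#' @param true_level True editing proportion in `[0, 1]`.
#' @param context 11-character DNA string centered on `A`.
#' @param peak_width Gaussian peak standard deviation in scan points
#'   (default 2.5; basecall spacing is 12 points).
#' @param noise_sd Additive noise standard deviation on the intensity
#'   scale (full peak height is 1000); must be non-negative.
#' @param seed Integer seed.
#' @return A list of class `chromatogram_trace` with `trace` (tibble
#'   `index, basecall, chanA, chanC, chanG, chanT`), `basecalls` (tibble
#'   `base, call_index, scan_index`) and `center_index` (the basecall index
#'   of the edited adenosine).
#' @export
#' @examples
#' tr <- simulate_chromatogram(0.3, "CTGACAGTTGA", seed = 1)
#' estimate_editing(tr, tr$center_index)
simulate_chromatogram <- function(true_level, context = "CTGACAGTTGA",
                                  peak_width = 2.5, noise_sd = 10,
                                  seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  if (true_level < 0 || true_level > 1) abort("`true_level` must lie in [0, 1]")
  bases <- strsplit(toupper(context), "", fixed = TRUE)[[1]]
  if (length(bases) %% 2 != 1) abort("`context` must have odd length")
  center <- (length(bases) + 1) %/% 2
  if (bases[center] != "A") abort("`context` must be centered on an A")
  if (!all(bases %in% BASES)) abort("`context` must contain only A/C/G/T")
  if (!is.null(seed)) local_seed(as.integer(seed))

  spacing <- 12L
  amp <- 1000
  n_scan <- spacing * (length(bases) + 1L)
  scan_at <- spacing * seq_along(bases)
  idx <- seq_len(n_scan)

  chan <- matrix(0, n_scan, 4, dimnames = list(NULL, BASES))
  for (i in seq_along(bases)) {
    shape <- exp(-((idx - scan_at[i])^2) / (2 * peak_width^2))
    if (i == center) {
      chan[, "A"] <- chan[, "A"] + amp * (1 - true_level) * shape
      chan[, "G"] <- chan[, "G"] + amp * true_level * shape
    } else {
      chan[, bases[i]] <- chan[, bases[i]] + amp * shape
    }
  }
  if (noise_sd > 0) chan <- chan + rnorm(length(chan), 0, noise_sd)
  chan <- pmax(chan, 0)

  basecall <- rep(NA_character_, n_scan)
  basecall[scan_at] <- bases
  trace <- tibble(
    index = idx, basecall = basecall,
    chanA = chan[, "A"], chanC = chan[, "C"],
    chanG = chan[, "G"], chanT = chan[, "T"]
  )
  structure(
    list(
      trace = trace,
      basecalls = tibble(
        base = bases, call_index = seq_along(bases), scan_index = scan_at
      ),
      center_index = center
    ),
    class = "chromatogram_trace"
  )
}

#' @export
print.chromatogram_trace <- function(x, ...) {
  cat(sprintf(
    "<chromatogram_trace> %d scan points, %d basecalls (%s)\n",
    nrow(x$trace), nrow(x$basecalls), paste(x$basecalls$base, collapse = "")
  ))
  invisible(x)
}
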