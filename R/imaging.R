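#' Quantize an 8-bit grayscale image to the encoder's voltage grid
#'
#' Pixel values 0-255 are mapped linearly onto the 0-5 V stimulus window and
#' rounded to the experimental 0.5 V step (ties to even), giving 11 distinct
#' stimulus levels: 0, 0.5, ..., 5 V.
#'
#' @param image Numeric matrix with values in `[0, 255]`.
#' @return An object of class `quantized_image` with elements `voltages`
#'   (matrix of grid voltages), `original` (the input) and `shape`.
#' @examples
#' q <- quantize_image(matrix(c(0, 128, 255), 1))
#' q$voltages
#' @export
quantize_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(image)) || any(image < 0) || any(image > 255)) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  v <- round(image * 5 / 255 / 0.5) * 0.5
  structure(
    list(voltages = v, original = image, shape = dim(image)),
    class = "quantized_image"
  )
}

#' @export
print.quantized_image <- function(x, ...) {
  cat(sprintf("<quantized_image: %d x %d, %d distinct levels>\n",
              x$shape[1], x$shape[2], length(unique(as.vector(x$voltages)))))
  invisible(x)
}

#' Encode a quantized image into a spike volume
#'
#' Every pixel is encoded independently through the device model with a
#' pixel-indexed substream of the program seed. In rate mode the
#' `n_trials` trials are concatenated in time, giving
#' `T = n_pulses * n_trials` frames; count and timing modes use a single
#' trial (`T = n_pulses`). With `shared_noise = TRUE` pixels holding the
#' same quantized level share one pulse-train realization per level.
#'
#' @param q A [quantize_image()] result.
#' @param program A [pulse_program()].
#' @param device A [device_params()] object.
#' @param i_st Thresholding current (A).
#' @param shared_noise Share pulse trains across pixels of equal level?
#' @param noise Logical; apply device readout noise?
#' @return An object of class `spike_volume`: logical `H x W x T` array of
#'   spikes plus encoding metadata.
#' @export
encode_image <- function(q, program, device, i_st,
                         shared_noise = FALSE, noise = TRUE) {
  stopifnot(inherits(q, "quantized_image"))
  program <- materialize_ramp(program, device, i_st)
  h <- q$shape[1]; w <- q$shape[2]
  n_tr <- if (program$mode == "rate") program$n_trials else 1L
  tt <- program$n_pulses * n_tr
  vflat <- as.vector(q$voltages)
  spk_flat <- matrix(FALSE, nrow = h * w, ncol = tt)

  encode_unit <- function(v, unit) {
    spk <- logical(tt)
    for (tr in seq_len(n_tr)) {
      train <- encode_trial(v, program, device, i_st, tr,
                            unit = unit, noise = noise)
      spk[((tr - 1L) * program$n_pulses + 1L):(tr * program$n_pulses)] <-
        train$spikes
    }
    spk
  }

  if (shared_noise) {
    lv <- sort(unique(vflat))
    per_level <- lapply(seq_along(lv), function(i) encode_unit(lv[i], i))
    for (px in seq_along(vflat)) {
      spk_flat[px, ] <- per_level[[match(vflat[px], lv)]]
    }
  } else {
    for (px in seq_along(vflat)) {
      spk_flat[px, ] <- encode_unit(vflat[px], px)
    }
  }

  p_max <- if (program$mode == "rate") {
    spike_probability(5, program, device, i_st)
  } else {
    NA_real_
  }
  structure(
    list(spikes = array(spk_flat, dim = c(h, w, tt)), t_p = program$t_p,
         mode = program$mode, n_pulses = program$n_pulses, n_trials = n_tr,
         p_max = p_max, program = program, device = device, i_st = i_st,
         shape = c(h, w)),
    class = "spike_volume"
  )
}

#' @export
print.spike_volume <- function(x, ...) {
  cat(sprintf("<spike_volume: %d x %d x %d (%s), t_p = %.3g s>\n",
              x$shape[1], x$shape[2], dim(x$spikes)[3], x$mode, x$t_p))
  invisible(x)
}

# Noise-free expected spike count of the count-mode ramp at the top of the
# stimulus window; count-mode reconstruction normalizer.
count_mode_max <- function(vol) {
  r <- resolve_ramp(vol$program, vol$device, vol$i_st)
  ramp <- seq(r[1], r[2], length.out = vol$n_pulses)
  v_star <- spiking_threshold(5, vol$i_st, vol$device, terminal = "top")
  max(1L, sum(ramp > v_star))
}

# Shared pixel-intensity mappings used by reconstruction and the CC trace.
gray_from_counts <- function(counts, t, vol) {
  norm <- if (vol$mode == "rate") {
    max(t * vol$p_max, 1e-12)
  } else {
    min(t, count_mode_max(vol))
  }
  pmin(pmax(round(255 * counts / norm), 0), 255)
}

gray_from_first_spike <- function(first, vol, reverse) {
  # earlier spike -> darker raw value; censored (no spike yet) -> brightest
  denom <- max(vol$n_pulses - 1L, 1L)
  g <- 255 * (pmin(first, vol$n_pulses) - 1L) / denom
  g[is.na(g)] <- 255
  g <- pmin(pmax(round(g), 0), 255)
  if (reverse) 255 - g else g
}

first_spike_index <- function(flat, t) {
  sub <- flat[, seq_len(t), drop = FALSE] + 0
  idx <- max.col(sub, ties.method = "first")
  idx[rowSums(sub) == 0] <- NA_integer_
  idx
}

#' Reconstruct an image from a spike volume at a given timestep
#'
#' Rate and count modes rebuild pixel intensity from the cumulative spike
#' count up to frame `t`, rescaled to 0-255 by the expected maximum count
#' (rate: `t * p(5 V)` with the closed-form spike probability; count: the
#' noise-free crossing count of the ramp at 5 V). Timing mode maps the
#' first-spike index so that earlier spikes give darker raw values; the raw
#' reconstruction is therefore contrast-reversed relative to the original,
#' and `reverse = TRUE` re-inverts it.
#'
#' @param vol A [encode_image()] result.
#' @param t Frame index, `1..T`.
#' @param reverse Timing mode only: re-invert the contrast-reversed image.
#' @return Numeric matrix of 8-bit gray values.
#' @export
reconstruct_image <- function(vol, t, reverse = FALSE) {
  stopifnot(inherits(vol, "spike_volume"))
  tt <- dim(vol$spikes)[3]
  if (!is.numeric(t) || length(t) != 1L || t < 1 || t > tt) {
    stop("`t` must lie in 1..", tt, call. = FALSE)
  }
  t <- as.integer(t)
  flat <- matrix(vol$spikes, nrow = prod(vol$shape), ncol = tt)
  g <- if (vol$mode %in% c("rate", "count")) {
    gray_from_counts(rowSums(flat[, seq_len(t), drop = FALSE]), t, vol)
  } else {
    gray_from_first_spike(first_spike_index(flat, t), vol, reverse)
  }
  matrix(g, vol$shape[1], vol$shape[2])
}

#' Correlation-coefficient trace of an encoded image
#'
#' Pearson correlation between the original gray values and the
#' reconstruction at every frame, tracking how encoding fidelity builds up
#' over time. Timing mode correlates against the re-inverted reconstruction.
#' Frames whose reconstruction is constant give `NA` (the correlation is
#' undefined there).
#'
#' @param q The [quantize_image()] result the volume was encoded from.
#' @param vol The [encode_image()] spike volume.
#' @param frames Frame indices at which to evaluate (default: all).
#' @return A tibble of class `cc_trace` with columns `t`, `time_s`, `cc`.
#' @export
cc_trace <- function(q, vol, frames = NULL) {
  stopifnot(inherits(q, "quantized_image"), inherits(vol, "spike_volume"))
  orig <- as.vector(q$original)
  if (stats::sd(orig) == 0) {
    stop("correlation is undefined for a constant original image",
         call. = FALSE)
  }
  tt <- dim(vol$spikes)[3]
  if (is.null(frames)) frames <- seq_len(tt)
  flat <- matrix(vol$spikes, nrow = prod(vol$shape), ncol = tt)
  counting <- vol$mode %in% c("rate", "count")
  cum <- if (counting) t(apply(flat, 1, cumsum)) else NULL
  cc <- vapply(frames, function(t) {
    rec <- if (counting) {
      gray_from_counts(cum[, t], t, vol)
    } else {
      gray_from_first_spike(first_spike_index(flat, t), vol, reverse = TRUE)
    }
    if (stats::sd(rec) == 0) NA_real_ else stats::cor(orig, rec)
  }, numeric(1))
  out <- tibble::tibble(t = as.integer(frames),
                        time_s = as.integer(frames) * vol$t_p,
                        cc = cc)
  class(out) <- c("cc_trace", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
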