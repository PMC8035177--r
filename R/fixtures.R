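#' Synthetic image fixtures
#'
#' Deterministic generators for the images used throughout the package's
#' examples and tests, standing in for photographs and digit sets that are
#' not redistributed:
#'
#' * `gradient`: left-to-right linear ramp from 0 to 255.
#' * `checkerboard`: alternating 0/255 tiles.
#' * `disk`: bright disk on a dark ground (a simple phantom).
#' * `blobs`: digit-like classes, each a fixed template of Gaussian bumps at
#'   class-specific positions, plus i.i.d. pixel noise. At high contrast the
#'   classes are linearly separable.
#'
#' Generation is deterministic given the arguments; `blobs` images and their
#' class templates derive from `seed` alone.
#'
#' @param kind Fixture type.
#' @param shape Integer vector `c(rows, cols)`.
#' @param n_classes Number of blob-digit classes.
#' @param n_per_class Images per class.
#' @param contrast Signal amplitude of the blob templates in units of the
#'   pixel-noise standard deviation; `Inf` (or huge values) give noise-free
#'   class templates.
#' @param noise_sd Pixel-noise standard deviation (gray levels).
#' @param tile Checkerboard tile size in pixels.
#' @param seed Integer seed.
#' @return For `gradient`, `checkerboard` and `disk`: a numeric matrix of
#'   gray values 0-255. For `blobs`: a list of class `blob_digits` with
#'   `images` (array `n x rows x cols`), `labels` (integer class ids,
#'   0-based) and the generating parameters.
#' @examples
#' g <- make_fixture("gradient", shape = c(1, 256))
#' range(g)
#' b <- make_fixture("blobs", shape = c(28, 28), n_classes = 2,
#'                   n_per_class = 5, seed = 3)
#' dim(b$images)
#' @export
make_fixture <- function(kind = c("gradient", "checkerboard", "disk", "blobs"),
                         shape = c(64L, 64L),
                         n_classes = 10L,
                         n_per_class = 100L,
                         contrast = 3,
                         noise_sd = 63,
                         tile = 8L,
                         seed = 1L) {
  kind <- match.arg(kind)
  if (length(shape) != 2L || any(shape < 1L) || any(shape != round(shape))) {
    stop("`shape` must be two positive integers", call. = FALSE)
  }
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  switch(kind,
    gradient = {
      col_vals <- if (w == 1L) 0 else (seq_len(w) - 1L) * 255 / (w - 1L)
      matrix(rep(round(col_vals), each = h), h, w)
    },
    checkerboard = {
      ri <- (seq_len(h) - 1L) %/% tile
      ci <- (seq_len(w) - 1L) %/% tile
      255 * outer(ri, ci, function(a, b) (a + b) %% 2L)
    },
    disk = {
      cx <- (w + 1) / 2; cy <- (h + 1) / 2
      r <- min(h, w) / 4
      d2 <- outer(seq_len(h), seq_len(w),
                  function(i, j) (i - cy)^2 + (j - cx)^2)
      255 * (d2 <= r^2)
    },
    blobs = make_blob_digits(h, w, n_classes, n_per_class, contrast,
                             noise_sd, seed)
  )
}

make_blob_digits <- function(h, w, n_classes, n_per_class, contrast,
                             noise_sd, seed) {
  if (n_classes < 2L) stop("blobs need at least 2 classes", call. = FALSE)
  amp <- if (is.finite(contrast)) contrast * noise_sd else 255
  sigma_blob <- min(h, w) / 8
  templates <- with_substream(seed, 1L, code = {
    lapply(seq_len(n_classes), function(k) {
      n_bumps <- 3L
      cx <- stats::runif(n_bumps, 0.15 * w, 0.85 * w)
      cy <- stats::runif(n_bumps, 0.15 * h, 0.85 * h)
      tpl <- matrix(0, h, w)
      for (b in seq_len(n_bumps)) {
        tpl <- tpl + outer(seq_len(h), seq_len(w), function(i, j) {
          exp(-((i - cy[b])^2 + (j - cx[b])^2) / (2 * sigma_blob^2))
        })
      }
      tpl / max(tpl)
    })
  })
  n <- n_classes * n_per_class
  labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
  images <- array(0, dim = c(n, h, w))
  for (i in seq_len(n)) {
    tpl <- templates[[labels[i] + 1L]] * min(amp, 255)
    noise <- if (is.finite(contrast)) {
      with_substream(seed, 2L, i, code = stats::rnorm(h * w, 0, noise_sd))
    } else {
      0
    }
    images[i, , ] <- pmin(pmax(round(tpl + noise), 0), 255)
  }
  structure(
    list(images = images, labels = labels, templates = templates,
         n_classes = n_classes, contrast = contrast, noise_sd = noise_sd,
         shape = c(h, w), seed = seed),
    class = "blob_digits"
  )
}

#' @export
print.blob_digits <- function(x, ...) {
  cat(sprintf(
    "<blob_digits: %d images (%d classes x %d), %d x %d, contrast %.3g>\n",
    dim(x$images)[1], x$n_classes, dim(x$images)[1] / x$n_classes,
    x$shape[1], x$shape[2], x$contrast
  ))
  invisible(x)
}

#' Split a blob-digit fixture into train and test sets
#'
#' Deterministic stratified split: within each class the first
#' `ceiling(train_frac * n)` images go to the training set.
#'
#' @param b A [make_fixture()] `blobs` result.
#' @param train_frac Fraction of each class assigned to training.
#' @return A list with `train` and `test`, each holding `images` and
#'   `labels`.
#' @export
split_blob_digits <- function(b, train_frac = 0.8) {
  stopifnot(inherits(b, "blob_digits"))
  take <- unlist(lapply(split(seq_along(b$labels), b$labels), function(idx) {
    idx[seq_len(ceiling(train_frac * length(idx)))]
  }), use.names = FALSE)
  sel <- function(idx) list(images = b$images[idx, , , drop = FALSE],
                            labels = b$labels[idx])
  list(train = sel(sort(take)),
       test = sel(sort(setdiff(seq_along(b$labels), take))))
}
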