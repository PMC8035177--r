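#' Train the rectifier network used for ANN-to-SNN conversion
#'
#' Trains a fully connected two-layer network (784 inputs, a rectified
#' hidden layer, a linear output layer read through softmax cross-entropy)
#' by mini-batch stochastic gradient descent. The constraints that make the
#' network convertible to a spiking network are built in: no bias terms
#' anywhere, no regularization, and a rectifier hidden activation (its
#' functional equivalence to the integrate-and-fire neuron is what the
#' conversion exploits).
#'
#' @param images Training images: array `n x rows x cols` or matrix
#'   `n x pixels`, gray values 0-255 (or already scaled to `[0, 1]`).
#' @param labels Integer class ids (0-based) or a factor; at least two
#'   distinct classes are required.
#' @param hidden Hidden-layer width (default 100).
#' @param lr Learning rate (default 0.0001).
#' @param epochs Training epochs (default 100).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer seed controlling weight initialization and epoch
#'   shuffling; training is deterministic given the seed.
#' @return An object of class `snn_model`: weight matrices `w1`
#'   (pixels x hidden) and `w2` (hidden x classes), `v_th` (per-layer firing
#'   thresholds, `NULL` until [threshold_balance()] is applied), the class
#'   labels, and a per-epoch loss/accuracy trace.
#' @examples
#' b <- make_fixture("blobs", shape = c(8, 8), n_classes = 2,
#'                   n_per_class = 10, seed = 1)
#' m <- train_ann(b$images, b$labels, hidden = 8, epochs = 3, seed = 1)
#' glance(m)
#' @export
train_ann <- function(images, labels, hidden = 100L, lr = 1e-4,
                      epochs = 100L, batch_size = 32L, seed = 1L) {
  x <- flatten_images(images)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("training requires at least two classes", call. = FALSE)
  }
  n <- nrow(x)
  if (length(labels) != n) stop("labels do not match images", call. = FALSE)
  k <- length(classes)
  yi <- match(labels, classes) # 1-based class index
  d <- ncol(x)

  w1 <- with_substream(seed, 1L, code = {
    matrix(stats::rnorm(d * hidden, 0, sqrt(2 / d)), d, hidden)
  })
  w2 <- with_substream(seed, 2L, code = {
    matrix(stats::rnorm(hidden * k, 0, sqrt(2 / hidden)), hidden, k)
  })

  trace <- tibble::tibble(epoch = integer(), loss = numeric(),
                          accuracy = numeric())
  for (ep in seq_len(epochs)) {
    ord <- with_substream(seed, 3L, ep, code = sample.int(n))
    ep_loss <- 0; ep_hits <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      z1 <- xb %*% w1
      a1 <- pmax(z1, 0)
      z2 <- a1 %*% w2
      p <- softmax_rows(z2)
      yb <- yi[idx]
      m <- length(idx)
      ep_loss <- ep_loss - sum(log(pmax(p[cbind(seq_len(m), yb)], 1e-300)))
      ep_hits <- ep_hits + sum(max.col(z2, ties.method = "first") == yb)
      # per-sample gradients are summed over the mini-batch (not averaged):
      # stepping then matches per-image updates at the same learning rate
      dz2 <- p
      dz2[cbind(seq_len(m), yb)] <- dz2[cbind(seq_len(m), yb)] - 1
      dw2 <- crossprod(a1, dz2)
      dz1 <- (dz2 %*% t(w2)) * (z1 > 0)
      dw1 <- crossprod(xb, dz1)
      w1 <- w1 - lr * dw1
      w2 <- w2 - lr * dw2
    }
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      epoch = ep, loss = ep_loss / n, accuracy = ep_hits / n
    ))
  }
  structure(
    list(w1 = w1, w2 = w2, v_th = NULL, classes = classes,
         input_shape = if (length(dim(images)) == 3L) dim(images)[2:3] else NULL,
         trace = trace, lr = lr, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed)),
    class = "snn_model"
  )
}

flatten_images <- function(images) {
  x <- if (length(dim(images)) == 3L) {
    n <- dim(images)[1]
    matrix(images, nrow = n) # column-major flatten, consistent everywhere
  } else if (is.matrix(images)) {
    images
  } else {
    stop("`images` must be an n x rows x cols array or an n x pixels matrix",
         call. = FALSE)
  }
  if (max(x) > 1) x <- x / 255
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' @export
print.snn_model <- function(x, ...) {
  cat(sprintf("<snn_model: %d-%d-%d, %s>\n",
              nrow(x$w1), ncol(x$w1), ncol(x$w2),
              if (is.null(x$v_th)) "unbalanced" else
                sprintf("v_th = (%.3g, %.3g)", x$v_th[1], x$v_th[2])))
  invisible(x)
}

#' @export
tidy.snn_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(layer = 1L,
                   from = rep(seq_len(nrow(x$w1)), times = ncol(x$w1)),
                   to = rep(seq_len(ncol(x$w1)), each = nrow(x$w1)),
                   weight = as.vector(x$w1)),
    tibble::tibble(layer = 2L,
                   from = rep(seq_len(nrow(x$w2)), times = ncol(x$w2)),
                   to = rep(seq_len(ncol(x$w2)), each = nrow(x$w2)),
                   weight = as.vector(x$w2))
  )
}

#' @export
glance.snn_model <- function(x, ...) {
  tibble::tibble(
    n_input = nrow(x$w1), n_hidden = ncol(x$w1), n_output = ncol(x$w2),
    epochs = x$epochs, lr = x$lr,
    final_loss = utils::tail(x$trace$loss, 1),
    train_accuracy = utils::tail(x$trace$accuracy, 1),
    balanced = !is.null(x$v_th)
  )
}

#' Class predictions of the trained rectifier network
#'
#' @param model An [train_ann()] model.
#' @param images Images as in [train_ann()].
#' @return Integer vector of predicted class ids (ties broken toward the
#'   lowest class index).
#' @export
ann_predict <- function(model, images) {
  x <- flatten_images(images)
  z2 <- pmax(x %*% model$w1, 0) %*% model$w2
  model$classes[max.col(z2, ties.method = "first")]
}

#' Balance the firing thresholds of the converted spiking network
#'
#' Sets each layer's integrate-and-fire threshold to the maximum
#' pre-activation (dot product of the layer weights with the incoming spike
#' vector) observed over a calibration set of encoder spike trains and all
#' timesteps. Layers are processed sequentially: the second layer is
#' calibrated on the spiking output that the first layer produces under its
#' own freshly balanced threshold.
#'
#' @param model An [train_ann()] model.
#' @param calib_spikes Calibration spike trains from the encoder front-end: a
#'   list of `pixels x timesteps` binary matrices (one per instance), or a
#'   single such matrix.
#' @return The model with `v_th` set to the two per-layer thresholds.
#' @export
threshold_balance <- function(model, calib_spikes) {
  stopifnot(inherits(model, "snn_model"))
  if (is.matrix(calib_spikes)) calib_spikes <- list(calib_spikes)
  if (length(calib_spikes) == 0L) {
    stop("calibration set must be nonempty", call. = FALSE)
  }
  v1 <- -Inf
  pre1 <- lapply(calib_spikes, function(x) {
    a <- crossprod(x, model$w1) # timesteps x hidden
    v1 <<- max(v1, max(a))
    a
  })
  if (v1 <= 0) {
    stop("layer-1 pre-activations are nonpositive; cannot balance",
         call. = FALSE)
  }
  v2 <- -Inf
  for (a in pre1) {
    s1 <- if_layer_run(a, v1)
    v2 <- max(v2, max(s1 %*% model$w2))
  }
  if (v2 <= 0) {
    stop("layer-2 pre-activations are nonpositive; cannot balance",
         call. = FALSE)
  }
  model$v_th <- c(v1, v2)
  model
}

# Run an integrate-and-fire layer over pre-activations (timesteps x neurons);
# returns the binary spike output matrix of the same shape.
if_layer_run <- function(pre, v_th) {
  tt <- nrow(pre); nn <- ncol(pre)
  v <- numeric(nn)
  out <- matrix(0, tt, nn)
  for (t in seq_len(tt)) {
    v <- v + pre[t, ]
    f <- v > v_th
    out[t, f] <- 1
    v[f] <- 0
  }
  out
}

#' One timestep of an integrate-and-fire layer
#'
#' Accumulates the weighted input spikes into the membrane potential; every
#' neuron whose potential strictly exceeds its threshold emits a spike and
#' resets to the resting potential (zero).
#'
#' @param state List with element `v_mem` (numeric vector of membrane
#'   potentials), as returned by a previous call; use
#'   `list(v_mem = numeric(n))` to start from rest.
#' @param x Binary input spike vector.
#' @param weights Weight matrix (`length(x)` rows).
#' @param v_th Scalar firing threshold (> 0).
#' @return A list with the updated `state` and the binary `spikes` output
#'   vector.
#' @examples
#' st <- list(v_mem = 0)
#' w <- matrix(1, 1, 1)
#' for (t in 1:3) {
#'   step <- if_step(st, 1, w, v_th = 2.5)
#'   st <- step$state
#' }
#' step$spikes # fires on the third step
#' @export
if_step <- function(state, x, weights, v_th) {
  if (!is.matrix(weights) || nrow(weights) != length(x)) {
    stop("`weights` must be a matrix with one row per input", call. = FALSE)
  }
  if (!all(x %in% c(0, 1, TRUE, FALSE))) {
    stop("`x` must be binary", call. = FALSE)
  }
  v <- state$v_mem
  if (length(v) != ncol(weights)) {
    stop("membrane-potential length must match the layer width", call. = FALSE)
  }
  v <- v + as.vector(crossprod(weights, as.numeric(x)))
  spikes <- as.numeric(v > v_th)
  v[spikes == 1] <- 0
  list(state = list(v_mem = v), spikes = spikes)
}

#' Spike-encode an image for the spiking network front-end
#'
#' Quantizes the image to the encoder's 11-level voltage grid and emits one
#' binary spike train per pixel. The default (`method = "bernoulli"`) draws
#' per-pixel, per-timestep Bernoulli spikes from the closed-form rate-mode
#' spike probability; `method = "device"` instead simulates every sampling
#' pulse through the device model (stochastic sampling-gate amplitude plus
#' optional readout noise). The two paths are statistically
#' indistinguishable (the closed form is the exact spike probability of the
#' noise-free device path).
#'
#' @param image Numeric matrix, gray values 0-255.
#' @param program A rate-mode [pulse_program()].
#' @param device A [device_params()] object.
#' @param i_st Thresholding current (A).
#' @param timesteps Number of timesteps to emit.
#' @param seed Integer seed (defaults to the program seed).
#' @param method Spike generation path.
#' @param noise Device path only: apply readout noise?
#' @return Binary matrix `pixels x timesteps` (column-major pixel order).
#' @export
encoder_frontend <- function(image, program, device, i_st, timesteps,
                             seed = program$seed,
                             method = c("bernoulli", "device"),
                             noise = TRUE) {
  method <- match.arg(method)
  if (program$mode != "rate") {
    stop("the SNN front-end uses rate-mode encoding", call. = FALSE)
  }
  q <- quantize_image(image)
  vflat <- as.vector(q$voltages)
  n <- length(vflat)
  lv <- sort(unique(vflat))
  if (method == "bernoulli") {
    p_lv <- spike_probability(lv, program, device, i_st)
    p <- p_lv[match(vflat, lv)]
    with_substream(seed, 4L, code = {
      matrix(stats::runif(n * timesteps) < p, n, timesteps) + 0
    })
  } else {
    with_substream(seed, 5L, code = {
      amps <- matrix(stats::rnorm(n * timesteps, program$mu_tg,
                                  program$sigma_tg), n, timesteps)
      cur <- matrix(
        psc_current(rep(vflat, timesteps), as.vector(amps), device,
                    noise = noise),
        n, timesteps
      )
      (cur > i_st) + 0
    })
  }
}

#' Spiking-network inference on encoder spike trains
#'
#' Runs the converted spiking network (integrate-and-fire neurons with
#' balanced thresholds) on a batch of images for `timesteps` steps, feeding
#' each image through the encoder front-end. The prediction is the class
#' with the largest cumulative output spike count (ties toward the lowest
#' class index); `readout = "membrane"` instead accumulates the output
#' membrane potential without firing and takes its argmax.
#'
#' @param images Array `n x rows x cols` or matrix `n x pixels`, gray 0-255.
#' @param model A threshold-balanced [train_ann()] model.
#' @param program A rate-mode [pulse_program()].
#' @param device A [device_params()] object.
#' @param i_st Thresholding current (A).
#' @param timesteps Number of inference timesteps.
#' @param labels Optional true class ids; enables the error trace.
#' @param seed Integer seed for the front-end sampling.
#' @param checkpoints Timesteps at which to record the running error
#'   (default: 10 roughly even checkpoints).
#' @param readout `"spikes"` (cumulative output-spike argmax) or
#'   `"membrane"`.
#' @param frontend_probs Optional precomputed `n x pixels` matrix of spike
#'   probabilities; bypasses quantization (used to feed closed-form rates
#'   directly).
#' @param sample_input If `FALSE`, the per-pixel spike probabilities are fed
#'   into the first layer as analog rates at every timestep instead of being
#'   sampled into binary spikes; isolates conversion loss from sampling
#'   noise.
#' @return An object of class `snn_inference` with `predictions`, the
#'   output-spike `counts`, and a `trace` tibble (`timestep`, `error` when
#'   labels are supplied).
#' @export
snn_infer <- function(images, model, program, device, i_st, timesteps,
                      labels = NULL, seed = program$seed,
                      checkpoints = NULL,
                      readout = c("spikes", "membrane"),
                      frontend_probs = NULL, sample_input = TRUE) {
  readout <- match.arg(readout)
  if (is.null(model$v_th)) {
    stop("balance the model with threshold_balance() before inference",
         call. = FALSE)
  }
  if (is.null(frontend_probs)) {
    x <- flatten_images(images) * 255
    lv_v <- round(x * 5 / 255 / 0.5) * 0.5
    lv <- sort(unique(as.vector(lv_v)))
    p_lv <- spike_probability(lv, program, device, i_st)
    pmat <- matrix(p_lv[match(as.vector(lv_v), lv)], nrow(lv_v), ncol(lv_v))
  } else {
    pmat <- frontend_probs
  }
  n <- nrow(pmat); d <- ncol(pmat)
  if (d != nrow(model$w1)) {
    stop("image pixel count does not match the model input layer",
         call. = FALSE)
  }
  if (is.null(checkpoints)) {
    checkpoints <- unique(pmax(1L, round(seq_len(10L) * timesteps / 10)))
  }
  h <- ncol(model$w1); k <- ncol(model$w2)
  vmem1 <- matrix(0, n, h)
  vmem2 <- matrix(0, n, k)
  counts <- matrix(0, n, k)
  trace <- NULL
  withr::with_seed(substream_seed(seed, 6L), {
    for (t in seq_len(timesteps)) {
      xt <- if (sample_input) {
        (matrix(stats::runif(n * d), n, d) < pmat) + 0
      } else {
        pmat
      }
      vmem1 <- vmem1 + xt %*% model$w1
      f1 <- vmem1 > model$v_th[1]
      vmem1[f1] <- 0
      vmem2 <- vmem2 + (f1 + 0) %*% model$w2
      if (readout == "spikes") {
        f2 <- vmem2 > model$v_th[2]
        vmem2[f2] <- 0
        counts <- counts + f2
      } else {
        counts <- vmem2
      }
      if (t %in% checkpoints && !is.null(labels)) {
        pred <- model$classes[max.col(counts, ties.method = "first")]
        trace <- dplyr::bind_rows(trace, tibble::tibble(
          timestep = t, error = mean(pred != labels)
        ))
      }
    }
  })
  predictions <- model$classes[max.col(counts, ties.method = "first")]
  structure(
    list(predictions = predictions, counts = counts, trace = trace,
         timesteps = as.integer(timesteps), readout = readout,
         labels = labels),
    class = "snn_inference"
  )
}

#' @export
print.snn_inference <- function(x, ...) {
  cat(sprintf("<snn_inference: %d images, %d timesteps, %s readout>\n",
              length(x$predictions), x$timesteps, x$readout))
  if (!is.null(x$labels)) {
    cat(sprintf("  final error: %.3f\n", mean(x$predictions != x$labels)))
  }
  invisible(x)
}

#' @export
tidy.snn_inference <- function(x, ...) {
  if (is.null(x$trace)) {
    tibble::tibble(timestep = x$timesteps,
                   error = if (is.null(x$labels)) NA_real_ else
                     mean(x$predictions != x$labels))
  } else {
    x$trace
  }
}
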