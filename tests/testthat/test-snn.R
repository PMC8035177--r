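snn_prog <- function(seed = 2L, sigma = 1.0) {
  pulse_program("rate", mu_tg = -5.5, sigma_tg = sigma, seed = seed)
}
IST_SNN <- 2e-10

test_that("training separates a linearly separable two-class set", {
  b <- make_fixture("blobs", shape = c(28, 28), n_classes = 2,
                    n_per_class = 100, contrast = 3, seed = 7)
  m <- train_ann(b$images, b$labels, epochs = 100, seed = 1)
  expect_gte(glance(m)$train_accuracy, 0.95)
  expect_equal(dim(m$w1), c(784L, 100L))
  expect_equal(dim(m$w2), c(100L, 2L))
  expect_null(m$v_th) # no bias terms, thresholds unset until balancing
})

test_that("per-epoch training loss decreases at the default learning rate", {
  b <- make_fixture("blobs", shape = c(12, 12), n_classes = 2,
                    n_per_class = 50, seed = 9)
  m <- train_ann(b$images, b$labels, hidden = 20, epochs = 15, seed = 2)
  loss <- m$trace$loss
  expect_lt(loss[length(loss)], loss[1])
  expect_true(all(diff(loss) < 1e-3)) # nonincreasing within float tolerance
})

test_that("training is deterministic given the seed and rejects bad labels", {
  b <- make_fixture("blobs", shape = c(8, 8), n_classes = 2,
                    n_per_class = 10, seed = 3)
  m1 <- train_ann(b$images, b$labels, hidden = 8, epochs = 2, seed = 5)
  m2 <- train_ann(b$images, b$labels, hidden = 8, epochs = 2, seed = 5)
  expect_identical(m1$w1, m2$w1)
  expect_identical(m1$w2, m2$w2)
  expect_error(train_ann(b$images, rep(0L, 40)), "two classes")
})

test_that("threshold balancing takes the running maximum pre-activation", {
  m <- list(w1 = matrix(0, 4, 3), w2 = matrix(0.5, 3, 2))
  m$w1[2, 1] <- 0.7 # single positive weight
  class(m) <- "snn_model"
  x <- matrix(0, 4, 2); x[2, ] <- 1 # one active input, two timesteps
  mb <- threshold_balance(m, x)
  expect_equal(mb$v_th[1], 0.7) # the single positive weight
  expect_equal(mb$v_th[2], 0.5) # layer 2 calibrated on layer-1 spikes
  expect_error(threshold_balance(m, list()), "nonempty")
})

test_that("layer-1 threshold is nondecreasing in the calibration-set size", {
  b <- make_fixture("blobs", shape = c(10, 10), n_classes = 2,
                    n_per_class = 20, seed = 11)
  m <- train_ann(b$images, b$labels, hidden = 12, epochs = 10, seed = 1)
  prog <- snn_prog()
  calib <- lapply(1:12, function(i)
    encoder_frontend(b$images[i, , ], prog, dev0, IST_SNN, 40,
                     seed = substream_seed(1L, i)))
  v1 <- vapply(c(3L, 6L, 12L), function(k) {
    threshold_balance(m, calib[seq_len(k)])$v_th[1]
  }, numeric(1))
  expect_true(all(diff(v1) >= 0))
  expect_true(all(v1 > 0))
})

test_that("integrate-and-fire neuron follows the hand-simulated trace", {
  # unit weight, threshold 2.5, constant input: fires at steps 3, 6, 9
  st <- list(v_mem = 0)
  w <- matrix(1, 1, 1)
  fired <- integer(0)
  for (t in 1:9) {
    step <- if_step(st, 1, w, v_th = 2.5)
    st <- step$state
    if (step$spikes == 1) fired <- c(fired, t)
  }
  expect_equal(fired, c(3L, 6L, 9L))
  expect_equal(st$v_mem, 0) # reset to resting potential after the spike
  # zero input forever: no spikes, no drift
  st <- list(v_mem = numeric(2))
  step <- if_step(st, c(0, 0), matrix(1, 2, 2), 1)
  expect_equal(step$spikes, c(0, 0))
  expect_equal(step$state$v_mem, c(0, 0))
  expect_error(if_step(st, c(1, 1), matrix(1, 3, 2), 1), "one row per input")
  expect_error(if_step(st, c(2, 0), matrix(1, 2, 2), 1), "binary")
})

test_that("front-end spike fractions hit the closed-form transfer function", {
  prog <- snn_prog(seed = 19)
  img <- matrix(seq(0, 255, length.out = 11), 1) # one pixel per grid level
  p <- spike_probability(quantize_image(img)$voltages[1, ], prog, dev0,
                         IST_SNN)
  tt <- 2000L
  for (method in c("bernoulli", "device")) {
    fr <- encoder_frontend(img, prog, dev0, IST_SNN, tt, method = method,
                           noise = FALSE)
    p_hat <- rowMeans(fr)
    expect_true(all(abs(p_hat - p) < 3 * sqrt(p * (1 - p) / tt) + 1e-9),
                label = paste(method, "front-end matches the closed form"))
  }
  # black and white extremes
  frb <- encoder_frontend(matrix(0, 4, 4), prog, dev0, IST_SNN, 400)
  frw <- encoder_frontend(matrix(255, 4, 4), prog, dev0, IST_SNN, 400)
  expect_lt(mean(frb), 0.06) # p(0 V) = 0.025 under the default calibration
  expect_gt(mean(frw), 0.5)  # p(5 V) = 0.62
})

test_that("device-level and Bernoulli front-ends match in mean and variance", {
  prog <- snn_prog(seed = 23)
  img <- matrix(c(64, 128, 192), 1)
  tt <- 1500L
  fb <- encoder_frontend(img, prog, dev0, IST_SNN, tt, method = "bernoulli")
  fd <- encoder_frontend(img, prog, dev0, IST_SNN, tt, method = "device",
                         noise = FALSE)
  p <- spike_probability(quantize_image(img)$voltages[1, ], prog, dev0,
                         IST_SNN)
  se <- sqrt(p * (1 - p) / tt)
  expect_true(all(abs(rowMeans(fb) - rowMeans(fd)) < 4 * se))
  v_b <- apply(fb, 1, stats::var)
  v_d <- apply(fd, 1, stats::var)
  expect_equal(v_b, p * (1 - p), tolerance = 0.15)
  expect_equal(v_d, p * (1 - p), tolerance = 0.15)
})

test_that("converted network agrees with the rectifier network when fed rates", {
  b <- make_fixture("blobs", shape = c(28, 28), n_classes = 10,
                    n_per_class = 60, seed = 5)
  sp <- split_blob_digits(b, train_frac = 0.75)
  m <- train_ann(sp$train$images, sp$train$labels, epochs = 40, seed = 1)
  prog <- snn_prog()
  calib <- lapply(1:50, function(i)
    encoder_frontend(sp$train$images[i, , ], prog, dev0, IST_SNN, 100,
                     seed = substream_seed(2L, i)))
  mb <- threshold_balance(m, calib)
  expect_length(mb$v_th, 2)
  pred_ann <- ann_predict(m, sp$test$images)
  res <- snn_infer(sp$test$images, mb, prog, dev0, IST_SNN, 400,
                   seed = 3, sample_input = FALSE)
  expect_gte(mean(res$predictions == pred_ann), 0.95)
})

test_that("inference requires balanced thresholds and reproduces from a seed", {
  b <- make_fixture("blobs", shape = c(28, 28), n_classes = 2,
                    n_per_class = 15, seed = 13)
  m <- train_ann(b$images, b$labels, epochs = 10, seed = 1)
  prog <- snn_prog()
  expect_error(
    snn_infer(b$images, m, prog, dev0, IST_SNN, 10),
    "threshold_balance"
  )
  calib <- lapply(1:10, function(i)
    encoder_frontend(b$images[i, , ], prog, dev0, IST_SNN, 50,
                     seed = substream_seed(4L, i)))
  mb <- threshold_balance(m, calib)
  r1 <- snn_infer(b$images, mb, prog, dev0, IST_SNN, 60, labels = b$labels,
                  seed = 9)
  r2 <- snn_infer(b$images, mb, prog, dev0, IST_SNN, 60, labels = b$labels,
                  seed = 9)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$counts, r2$counts)
  expect_s3_class(tidy(r1), "tbl_df")
  # output spike counts cannot exceed the number of timesteps
  expect_true(all(r1$counts <= 60))
})

test_that("model summaries expose architecture and training state", {
  b <- make_fixture("blobs", shape = c(8, 8), n_classes = 2,
                    n_per_class = 10, seed = 3)
  m <- train_ann(b$images, b$labels, hidden = 6, epochs = 2, seed = 5)
  g <- glance(m)
  expect_equal(g$n_hidden, 6)
  expect_false(g$balanced)
  td <- tidy(m)
  expect_equal(nrow(td), 64 * 6 + 6 * 2)
})
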