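#' Configuration of the surrogate 1-D residual network
#'
#' Desk-scale surrogate of the audited classifier family: a stem block
#' (convolution, rectifier, max-pooling), four feature blocks of exactly
#' three residual blocks each, and a fully connected head mapping the pooled
#' final features to a single logit; the score is `100 * sigmoid(logit)`,
#' so it lies in \[0, 100\] by construction.
#'
#' @param channels integer vector of 4 channel counts, one per feature block.
#' @param kernel_size residual convolution kernel width (odd).
#' @param input_samples expected samples per lead (default 2500, i.e. 10 s
#'   at 250 Hz).
#' @param input_rate expected sampling rate in Hz.
#' @param stem_kernel stem convolution width (odd).
#' @param stem_pool stem max-pool width.
#' @param threshold default operating threshold on the 0--100 score (9.7,
#'   the fixed-sensitivity operating point of the audited model family).
#' @param seed initialization seed.
#' @return a `surrogate_config` list.
#' @export
surrogate_config <- function(channels = c(16L, 32L, 64L, 128L),
                             kernel_size = 7L, input_samples = 2500L,
                             input_rate = 250, stem_kernel = 15L,
                             stem_pool = 4L, threshold = 9.7, seed = 1L) {
  assert_that(length(channels) == 4L && all(channels >= 1),
              "channels must list 4 positive counts (4 feature blocks)")
  assert_that(kernel_size %% 2 == 1 && stem_kernel %% 2 == 1,
              "kernel widths must be odd")
  list(channels = as.integer(channels), kernel_size = as.integer(kernel_size),
       input_samples = as.integer(input_samples), input_rate = input_rate,
       stem_kernel = as.integer(stem_kernel), stem_pool = as.integer(stem_pool),
       n_res_per_block = 3L, threshold = threshold, seed = as.integer(seed))
}

# He-normal conv weight: list of k matrices (out x in), one per tap.
init_conv <- function(out_ch, in_ch, k) {
  sd <- sqrt(2 / (in_ch * k))
  W <- lapply(seq_len(k), function(j) matrix(stats::rnorm(out_ch * in_ch, sd = sd),
                                             out_ch, in_ch))
  list(W = W, b = numeric(out_ch), k = k)
}

conv_out_len <- function(L, k, stride) {
  p <- k %/% 2
  (L + 2L * p - k) %/% stride + 1L
}

# 1-D convolution: Y[, t] = b + sum_j W[[j]] %*% Xp[, j + stride*(t-1)].
conv_fwd <- function(X, conv, stride = 1L) {
  k <- conv$k; p <- k %/% 2L; L <- ncol(X)
  Lout <- conv_out_len(L, k, stride)
  Xp <- cbind(matrix(0, nrow(X), p), X, matrix(0, nrow(X), p))
  Y <- matrix(conv$b, length(conv$b), Lout)
  base <- stride * (seq_len(Lout) - 1L)
  for (j in seq_len(k)) Y <- Y + conv$W[[j]] %*% Xp[, j + base, drop = FALSE]
  Y
}

conv_bwd <- function(dY, X, conv, stride = 1L) {
  k <- conv$k; p <- k %/% 2L; L <- ncol(X)
  Lout <- ncol(dY)
  Xp <- cbind(matrix(0, nrow(X), p), X, matrix(0, nrow(X), p))
  dXp <- matrix(0, nrow(X), L + 2L * p)
  dW <- vector("list", k)
  base <- stride * (seq_len(Lout) - 1L)
  for (j in seq_len(k)) {
    cols <- j + base
    dW[[j]] <- dY %*% t(Xp[, cols, drop = FALSE])
    dXp[, cols] <- dXp[, cols, drop = FALSE] + crossprod(conv$W[[j]], dY)
  }
  list(dX = dXp[, (p + 1L):(p + L), drop = FALSE],
       grad = list(W = dW, b = rowSums(dY), k = k))
}

maxpool_fwd <- function(X, width) {
  L <- ncol(X); Lout <- L %/% width
  Y <- X[, seq(1L, by = width, length.out = Lout), drop = FALSE]
  arg <- matrix(seq(1L, by = width, length.out = Lout), nrow(X), Lout, byrow = TRUE)
  if (width > 1L) for (j in 2:width) {
    cand <- X[, seq(j, by = width, length.out = Lout), drop = FALSE]
    better <- cand > Y
    Y[better] <- cand[better]
    argj <- matrix(seq(j, by = width, length.out = Lout), nrow(X), Lout, byrow = TRUE)
    arg[better] <- argj[better]
  }
  list(Y = Y, arg = arg, L = L)
}

maxpool_bwd <- function(dY, pool_cache) {
  dX <- matrix(0, nrow(dY), pool_cache$L)
  ridx <- cbind(as.vector(row(dY)), as.vector(pool_cache$arg))
  dX[ridx] <- dX[ridx] + as.vector(dY)
  dX
}

relu <- function(x) (x > 0) * x

# Pre-activation residual unit without normalization:
#   out = shortcut(x) + conv2(relu(conv1(relu(x)))).
# The shortcut is a 1x1 strided projection when the stride or channel count
# changes, otherwise the identity.
init_res_unit <- function(in_ch, out_ch, k, stride) {
  u <- list(conv1 = init_conv(out_ch, in_ch, k),
            conv2 = init_conv(out_ch, out_ch, k),
            stride = stride,
            proj = NULL)
  if (stride != 1L || in_ch != out_ch) u$proj <- init_conv(out_ch, in_ch, 1L)
  # residual branch starts near zero so deep stacks train stably
  u$conv2$W <- lapply(u$conv2$W, function(w) w * 0.2)
  u
}

res_fwd <- function(x, u) {
  a1 <- relu(x)
  y1 <- conv_fwd(a1, u$conv1, u$stride)
  a2 <- relu(y1)
  y2 <- conv_fwd(a2, u$conv2, 1L)
  sc <- if (is.null(u$proj)) x else conv_fwd(a1, u$proj, u$stride)
  list(out = y2 + sc, cache = list(x = x, a1 = a1, y1 = y1, a2 = a2))
}

res_bwd <- function(dout, u, cache) {
  b2 <- conv_bwd(dout, cache$a2, u$conv2, 1L)
  dy1 <- b2$dX * (cache$y1 > 0)
  b1 <- conv_bwd(dy1, cache$a1, u$conv1, u$stride)
  da1 <- b1$dX
  grad <- list(conv1 = b1$grad, conv2 = b2$grad, stride = u$stride, proj = NULL)
  if (is.null(u$proj)) {
    dx <- da1 * (cache$x > 0) + dout
  } else {
    bp <- conv_bwd(dout, cache$a1, u$proj, u$stride)
    grad$proj <- bp$grad
    dx <- (da1 + bp$dX) * (cache$x > 0)
  }
  list(dX = dx, grad = grad)
}

#' Build the surrogate network
#'
#' Deterministically initializes all weights from `config$seed`. The forward
#' pass accepts a 12 x `input_samples` matrix and produces a 0--100 score.
#'
#' @param config a [surrogate_config()].
#' @return an object of class `ecg_surrogate` (config + weights).
#' @export
build_surrogate <- function(config = surrogate_config()) {
  ch <- config$channels
  with_seed(config$seed, {
    w <- list(stem = init_conv(ch[1], 12L, config$stem_kernel), blocks = list())
    in_ch <- ch[1]
    for (b in 1:4) {
      units <- list()
      for (j in seq_len(config$n_res_per_block)) {
        units[[j]] <- init_res_unit(if (j == 1L) in_ch else ch[b], ch[b],
                                    config$kernel_size,
                                    stride = if (j == 1L) 2L else 1L)
      }
      w$blocks[[b]] <- units
      in_ch <- ch[b]
    }
    w$head <- list(W = matrix(stats::rnorm(ch[4], sd = 1 / sqrt(ch[4])), 1L),
                   b = 0)
    structure(list(config = config, weights = w, trained = FALSE),
              class = "ecg_surrogate")
  })
}

#' @export
print.ecg_surrogate <- function(x, ...) {
  cat(sprintf("<ecg_surrogate> channels %s, input 12 x %d @ %g Hz, %s\n",
              paste(x$config$channels, collapse = "/"), x$config$input_samples,
              x$config$input_rate,
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

check_input <- function(model, X) {
  assert_that(is.matrix(X) && nrow(X) == 12L,
              "expected a 12 x %d input matrix (12 leads), got %d x %d",
              model$config$input_samples, NROW(X), NCOL(X))
  assert_that(ncol(X) == model$config$input_samples,
              "expected 12 x %d input, got %d samples; use resample_record()/pad",
              model$config$input_samples, ncol(X))
}

# Full forward pass. Returns score, logit, per-block outputs (pre-pooling
# feature maps) and, when keep_cache, everything backward passes need.
surrogate_forward <- function(model, X, keep_cache = FALSE) {
  check_input(model, X)
  w <- model$weights
  s0 <- conv_fwd(X, w$stem, 2L)
  s1 <- relu(s0)
  pl <- maxpool_fwd(s1, model$config$stem_pool)
  h <- pl$Y
  block_out <- vector("list", 4L)
  caches <- vector("list", 4L)
  for (b in 1:4) {
    ucaches <- vector("list", length(w$blocks[[b]]))
    for (j in seq_along(w$blocks[[b]])) {
      r <- res_fwd(h, w$blocks[[b]][[j]])
      h <- r$out
      ucaches[[j]] <- r$cache
    }
    block_out[[b]] <- h
    caches[[b]] <- ucaches
  }
  hf <- relu(h)
  pooled <- rowMeans(hf)
  logit <- as.numeric(w$head$W %*% pooled + w$head$b)
  out <- list(score = 100 * stats::plogis(logit), logit = logit,
              block_out = block_out, pooled = pooled)
  if (keep_cache)
    out$cache <- list(X = X, s0 = s0, s1 = s1, pool = pl, caches = caches,
                      h4 = h, hf = hf)
  out
}

# Backprop d(logit) through the head and blocks (b_stop+1)..4, returning the
# gradient w.r.t. block b_stop's output feature map (b_stop >= 1), or the
# full weight-gradient list when b_stop = 0.
surrogate_backward <- function(model, fwd, dlogit = 1, b_stop = 0L,
                               collect_blocks = FALSE) {
  w <- model$weights
  cache <- fwd$cache
  L4 <- ncol(cache$hf)
  dpooled <- as.numeric(w$head$W) * dlogit
  dhf <- matrix(dpooled / L4, length(dpooled), L4)
  dh <- dhf * (cache$h4 > 0)
  grads <- list(blocks = vector("list", 4L))
  d_blocks <- vector("list", 4L)
  if (b_stop == 0L)
    grads$head <- list(W = matrix(fwd$pooled * dlogit, 1L), b = dlogit)
  for (b in 4:1) {
    if (collect_blocks) d_blocks[[b]] <- rowSums(dh)
    if (b == b_stop) return(list(d_block = dh))
    gunits <- vector("list", length(w$blocks[[b]]))
    for (j in rev(seq_along(w$blocks[[b]]))) {
      r <- res_bwd(dh, w$blocks[[b]][[j]], cache$caches[[b]][[j]])
      dh <- r$dX
      gunits[[j]] <- r$grad
    }
    grads$blocks[[b]] <- gunits
  }
  if (collect_blocks) return(list(d_blocks = d_blocks))
  ds1 <- maxpool_bwd(dh, cache$pool)
  ds0 <- ds1 * (cache$s0 > 0)
  bs <- conv_bwd(ds0, cache$X, w$stem, 2L)
  grads$stem <- bs$grad
  grads
}

records_to_matrices <- function(model, records) {
  if (is_ecg_record(records)) records <- list(records)
  lapply(records, function(r) {
    if (is_ecg_record(r)) {
      if (abs(r$sampling_rate - model$config$input_rate) > 1e-9)
        stopf("record %s sampled at %g Hz but model expects %g Hz; use resample_record()",
              r$record_id, r$sampling_rate, model$config$input_rate)
      r$signal
    } else as.matrix(r)
  })
}

record_ids <- function(records) {
  if (is_ecg_record(records)) records <- list(records)
  vapply(seq_along(records), function(i) {
    r <- records[[i]]
    if (is_ecg_record(r)) r$record_id else sprintf("x%04d", i)
  }, "")
}

#' Score records with the surrogate
#'
#' @param model an [build_surrogate()] model (trained or untrained).
#' @param records a list of [ecg_record()] (or a single record).
#' @param threshold operating threshold on the 0--100 score; a score
#'   greater than or equal to the threshold is called high risk
#'   (boundary inclusive).
#' @return data.frame with `record_id`, `score` (in \[0, 100\]),
#'   `risk_class` (`"high"`/`"low"`) and `threshold_used`, rows in input
#'   order.
#' @export
predict_scores <- function(model, records, threshold = model$config$threshold) {
  Xs <- records_to_matrices(model, records)
  scores <- vapply(Xs, function(X) surrogate_forward(model, X)$score, 1)
  data.frame(record_id = record_ids(records), score = scores,
             risk_class = classify_risk(scores, threshold),
             threshold_used = threshold, stringsAsFactors = FALSE)
}

#' Dichotomize a 0--100 score at an operating threshold
#'
#' High risk iff `score >= threshold` (the boundary itself is high risk).
#'
#' @param score numeric vector in \[0, 100\].
#' @param threshold operating threshold (default 9.7).
#' @return character vector, `"high"` or `"low"`.
#' @export
classify_risk <- function(score, threshold = 9.7) {
  assert_that(all(score >= 0 & score <= 100), "scores must lie in [0, 100]")
  ifelse(score >= threshold, "high", "low")
}

#' Pooled activations of one feature block
#'
#' Global time-average of the block's output feature map: one vector per
#' record whose length equals the block's channel count. This is the
#' activation space used for concept attribution and phenotype clustering.
#'
#' @param model surrogate model.
#' @param records list of [ecg_record()].
#' @param block_index feature block, 1--4.
#' @return numeric matrix, rows = records (rownames = record ids), columns =
#'   block channels.
#' @export
extract_activations <- function(model, records, block_index) {
  assert_that(block_index %in% 1:4, "block_index must be one of 1, 2, 3, 4")
  Xs <- records_to_matrices(model, records)
  acts <- t(vapply(Xs, function(X)
    rowMeans(surrogate_forward(model, X)$block_out[[block_index]]),
    numeric(model$config$channels[block_index])))
  rownames(acts) <- record_ids(records)
  acts
}

# One forward per record, pooled activations for all four blocks at once.
extract_activations_all <- function(model, records) {
  Xs <- records_to_matrices(model, records)
  per <- lapply(Xs, function(X)
    lapply(surrogate_forward(model, X)$block_out, rowMeans))
  out <- lapply(1:4, function(b) {
    m <- do.call(rbind, lapply(per, `[[`, b))
    rownames(m) <- record_ids(records)
    m
  })
  out
}

# One forward+backward per record, pooled logit gradients for all blocks.
pooled_logit_gradients_all <- function(model, records) {
  Xs <- records_to_matrices(model, records)
  per <- lapply(Xs, function(X) {
    fwd <- surrogate_forward(model, X, keep_cache = TRUE)
    surrogate_backward(model, fwd, collect_blocks = TRUE)$d_blocks
  })
  lapply(1:4, function(b) {
    m <- do.call(rbind, lapply(per, `[[`, b))
    rownames(m) <- record_ids(records)
    m
  })
}

#' Gradient of the LVSD logit w.r.t. a block's pooled activation
#'
#' For each record, backpropagates the positive-class logit to the chosen
#' block's output feature map and sums over time, yielding the directional
#' sensitivity of the logit to a uniform per-channel shift of the block
#' output -- the gradient in the pooled activation space that TCAV dots with
#' concept directions.
#'
#' @param model surrogate model.
#' @param records list of [ecg_record()].
#' @param block_index feature block, 1--4.
#' @return matrix, rows = records, columns = block channels.
#' @export
pooled_logit_gradients <- function(model, records, block_index) {
  assert_that(block_index %in% 1:4, "block_index must be one of 1, 2, 3, 4")
  Xs <- records_to_matrices(model, records)
  g <- t(vapply(Xs, function(X) {
    fwd <- surrogate_forward(model, X, keep_cache = TRUE)
    rowSums(surrogate_backward(model, fwd, b_stop = block_index)$d_block)
  }, numeric(model$config$channels[block_index])))
  rownames(g) <- record_ids(records)
  g
}

#' Save / load a surrogate checkpoint
#'
#' The checkpoint is an RDS archive holding weights, configuration, seed and
#' a format version.
#' @param model surrogate model.
#' @param path checkpoint path.
#' @return `path` (save) or the model (load).
#' @export
save_surrogate <- function(model, path) {
  saveRDS(list(format = "ecgaudit-surrogate-v1", config = model$config,
               weights = model$weights, trained = model$trained), path)
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) {
  x <- readRDS(path)
  assert_that(identical(x$format, "ecgaudit-surrogate-v1"),
              "not an ecgaudit surrogate checkpoint: %s", path)
  structure(list(config = x$config, weights = x$weights, trained = x$trained),
            class = "ecg_surrogate")
}
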