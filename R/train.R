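# Flatten / rebuild the nested weight list so the optimizer can treat the
# model as one parameter vector. Conv params are lists of k tap matrices.
flatten_params <- function(w) {
  out <- list()
  walk <- function(x, prefix) {
    if (is.list(x) && !is.null(x$W) && !is.null(x$b) && !is.null(x$k)) {
      for (j in seq_along(x$W)) out[[paste0(prefix, ".W", j)]] <<- x$W[[j]]
      out[[paste0(prefix, ".b")]] <<- x$b
    } else if (is.list(x) && !is.null(x$W)) {  # head
      out[[paste0(prefix, ".W")]] <<- x$W
      out[[paste0(prefix, ".b")]] <<- x$b
    } else if (is.list(x)) {
      for (nm in names(x) %||% seq_along(x))
        walk(x[[nm]], paste0(prefix, ".", nm))
    }
  }
  w$stride <- NULL
  walk(w$stem, "stem")
  for (b in seq_along(w$blocks))
    for (j in seq_along(w$blocks[[b]])) {
      u <- w$blocks[[b]][[j]]
      walk(u$conv1, sprintf("b%d.u%d.c1", b, j))
      walk(u$conv2, sprintf("b%d.u%d.c2", b, j))
      if (!is.null(u$proj)) walk(u$proj, sprintf("b%d.u%d.pr", b, j))
    }
  walk(w$head, "head")
  out
}

apply_flat_update <- function(w, upd) {
  get_upd <- function(key) upd[[key]]
  patch_conv <- function(conv, prefix) {
    for (j in seq_along(conv$W))
      conv$W[[j]] <- conv$W[[j]] + get_upd(paste0(prefix, ".W", j))
    conv$b <- conv$b + get_upd(paste0(prefix, ".b"))
    conv
  }
  w$stem <- patch_conv(w$stem, "stem")
  for (b in seq_along(w$blocks))
    for (j in seq_along(w$blocks[[b]])) {
      u <- w$blocks[[b]][[j]]
      u$conv1 <- patch_conv(u$conv1, sprintf("b%d.u%d.c1", b, j))
      u$conv2 <- patch_conv(u$conv2, sprintf("b%d.u%d.c2", b, j))
      if (!is.null(u$proj)) u$proj <- patch_conv(u$proj, sprintf("b%d.u%d.pr", b, j))
      w$blocks[[b]][[j]] <- u
    }
  w$head$W <- w$head$W + get_upd("head.W")
  w$head$b <- w$head$b + get_upd("head.b")
  w
}

#' Training configuration for the surrogate
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param weight_decay decoupled L2 weight decay.
#' @param val_fraction held-out fraction (stratified by label).
#' @param seed seed for the split, shuffling and nothing else (weights come
#'   from the model's own seed).
#' @param verbose print per-epoch progress.
#' @return a list of training settings.
#' @export
train_config <- function(epochs = 4L, batch_size = 16L, lr = 1e-3,
                         weight_decay = 1e-4, val_fraction = 0.25,
                         seed = 1L, verbose = FALSE) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr = lr, weight_decay = weight_decay, val_fraction = val_fraction,
       seed = as.integer(seed), verbose = isTRUE(verbose))
}

#' Train the surrogate on a synthetic cohort
#'
#' Binary cross-entropy on the LVSD logit, Adam optimizer, stratified
#' held-out split. Fully deterministic given (model seed, cohort, config
#' seed): the same call reproduces the same weights and held-out scores
#' bitwise.
#'
#' @param model an untrained [build_surrogate()] model.
#' @param cohort list with `records` and `metadata` (from
#'   [simulate_cohort()]); labels are `metadata$label == "LVSD"`.
#' @param config a [train_config()].
#' @return list with `model` (trained), `history` (data.frame: epoch, loss,
#'   val_auroc), `val_ids` and `val_scores`.
#' @export
train_surrogate <- function(model, cohort, config = train_config()) {
  meta <- cohort$metadata
  y_all <- as.integer(meta$label == "LVSD")
  assert_that(length(unique(y_all)) == 2L,
              "cohort has a single class; no decision boundary to learn")
  Xs <- records_to_matrices(model, cohort$records[meta$record_id])
  n <- length(Xs)
  idx <- with_seed(config$seed, {
    val <- unlist(lapply(split(seq_len(n), y_all), function(ix)
      sample(ix, max(1L, round(config$val_fraction * length(ix))))))
    list(val = sort(val), train = setdiff(seq_len(n), val))
  })
  tr <- idx$train; va <- idx$val
  params <- flatten_params(model$weights)
  m1 <- lapply(params, function(p) p * 0)
  m2 <- m1
  t_step <- 0L
  history <- data.frame()
  order_seeds <- with_seed(config$seed + 1L, sample.int(2^30, config$epochs))
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(order_seeds[ep], sample(tr))
    losses <- numeric(0)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (batch in batches) {
      gsum <- NULL
      bloss <- 0
      for (i in batch) {
        fwd <- surrogate_forward(model, Xs[[i]], keep_cache = TRUE)
        pr <- stats::plogis(fwd$logit)
        yi <- y_all[i]
        bloss <- bloss + (log1p(exp(-abs(fwd$logit))) +
                            max(fwd$logit, 0) - yi * fwd$logit)
        g <- surrogate_backward(model, fwd, dlogit = pr - yi)
        gf <- flatten_params(g)
        gsum <- if (is.null(gsum)) gf else
          Map(function(a, b) a + b, gsum, gf)
      }
      nb <- length(batch)
      t_step <- t_step + 1L
      upd <- vector("list", length(params))
      names(upd) <- names(params)
      for (k in names(params)) {
        gk <- gsum[[k]] / nb + config$weight_decay * params[[k]]
        m1[[k]] <- 0.9 * m1[[k]] + 0.1 * gk
        m2[[k]] <- 0.999 * m2[[k]] + 0.001 * gk^2
        mhat <- m1[[k]] / (1 - 0.9^t_step)
        vhat <- m2[[k]] / (1 - 0.999^t_step)
        upd[[k]] <- -config$lr * mhat / (sqrt(vhat) + 1e-8)
        params[[k]] <- params[[k]] + upd[[k]]
      }
      model$weights <- apply_flat_update(model$weights, upd)
      losses <- c(losses, bloss / nb)
    }
    val_scores <- vapply(va, function(i)
      surrogate_forward(model, Xs[[i]])$score, 1)
    val_auroc <- auroc(val_scores, y_all[va])
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                         val_auroc = val_auroc))
    if (config$verbose)
      message(sprintf("epoch %d: loss %.4f, val AUROC %.3f",
                      ep, mean(losses), val_auroc))
  }
  model$trained <- TRUE
  val_scores <- vapply(va, function(i) surrogate_forward(model, Xs[[i]])$score, 1)
  list(model = model, history = history,
       val_ids = meta$record_id[va], val_scores = val_scores,
       val_labels = y_all[va])
}
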