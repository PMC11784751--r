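# Losses and the joint training loop.
#
# Two losses per network and position:
#  * SPL, the subimage prediction loss: mean absolute error between the
#    predicted and true plane (all pixels for the plane network, odd columns
#    only for the refine network);
#  * PPL, the probability prediction loss: per-pixel cross-entropy of the
#    511-class head against the one-hot residual class, natural-log
#    convention (the coder always accounts in log2; only the optimizer sees
#    nats).
# Training is joint over both networks with teacher forcing: priors and the
# left (even-column) plane fed to the refine network are ground truth, which
# matches the information available at encode time.

#' Subimage prediction loss (mean absolute error)
#'
#' @param y True plane (matrix).
#' @param yhat Predicted plane (matrix, same shape).
#' @param scope `"all"` pixels or `"odd-columns"` only.
#' @return Scalar loss.
#' @export
spl_loss <- function(y, yhat, scope = c("all", "odd-columns")) {
  scope <- match.arg(scope)
  if (!identical(dim(y), dim(yhat))) stop("shape mismatch")
  w <- scope_weights(dim(y), scope)
  sum(abs(y - yhat) * w) / sum(w)
}

#' Probability prediction loss (cross-entropy over 511 residual classes)
#'
#' @param true_residual Integer matrix in `[0, 510]`.
#' @param prob Array `h x w x 511` of predicted class probabilities.
#' @param scope `"all"` or `"odd-columns"`.
#' @return Mean `-log p` at the true class over in-scope pixels (nats).
#' @export
ppl_loss <- function(true_residual, prob, scope = c("all", "odd-columns")) {
  scope <- match.arg(scope)
  d <- dim(prob)
  if (!identical(dim(true_residual), d[1:2])) stop("shape mismatch")
  w <- scope_weights(d[1:2], scope)
  pm <- matrix(prob, d[1L] * d[2L], d[3L])
  pt <- pm[cbind(seq_len(d[1L] * d[2L]), as.vector(true_residual) + 1L)]
  sum(-log(pmax(pt, 1e-300)) * as.vector(w)) / sum(w)
}

scope_weights <- function(dm, scope) {
  w <- matrix(1, dm[1L], dm[2L])
  if (scope == "odd-columns") w[, col_parity_kept(dm[2L], "even")] <- 0
  w
}

#' Training configuration
#'
#' Defaults follow the reference training recipe (128-pixel crops, batch 24,
#' Adam at 1e-3 halved every 500 epochs, 2000 epochs); `desk_profile()`
#' shrinks everything to CPU scale for tests and examples.
#'
#' @param crop_size Square crop side in pixels.
#' @param batch_size Crops per optimization step.
#' @param lr Initial Adam learning rate.
#' @param lr_halving_period Epochs between learning-rate halvings.
#' @param epochs Number of passes over the dataset.
#' @param loss_weight_lambda Weight of SPL relative to PPL in the total loss.
#' @param seed RNG seed for cropping order.
#' @return Object of class `train_config`.
#' @export
train_config <- function(crop_size = 128L, batch_size = 24L, lr = 1e-3,
                         lr_halving_period = 500L, epochs = 2000L,
                         loss_weight_lambda = 1, seed = 1L) {
  stopifnot(crop_size >= 8L, batch_size >= 1L, lr > 0, lr_halving_period >= 1L,
            epochs >= 1L, loss_weight_lambda >= 0)
  structure(list(crop_size = as.integer(crop_size),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_halving_period = as.integer(lr_halving_period),
                 epochs = as.integer(epochs),
                 loss_weight_lambda = loss_weight_lambda,
                 seed = as.integer(seed)), class = "train_config")
}

#' @rdname train_config
#' @export
desk_profile <- function(crop_size = 32L, batch_size = 2L, epochs = 5L, ...) {
  train_config(crop_size = crop_size, batch_size = batch_size, epochs = epochs, ...)
}

#' Learning rate at a given epoch under the halving schedule
#'
#' @param cfg A [train_config()].
#' @param epoch 1-based epoch index.
#' @return `lr * 2^-floor((epoch - 1) / period)`.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$lr * 2^(-((epoch - 1L) %/% cfg$lr_halving_period))
}

random_crop <- function(image, size) {
  h <- nrow(image); w <- ncol(image)
  size_h <- min(size, h); size_w <- min(size, w)
  y <- sample.int(h - size_h + 1L, 1L)
  x <- sample.int(w - size_w + 1L, 1L)
  image[y + seq_len(size_h) - 1L, x + seq_len(size_w) - 1L, drop = FALSE]
}

# Build the tape loss for one crop; returns list(loss node, ppl, spl scalars).
crop_loss <- function(tape, model, crop, lambda) {
  parts <- split_level1(pad_to_even(crop))
  priors <- list(parts$a)
  terms <- list(); coefs <- numeric(0)
  ppl_sum <- 0; spl_sum <- 0
  for (pos in c("d", "b", "c")) {
    true <- parts[[pos]]
    out <- forward_plane(model, priors, tape = tape)
    w_all <- scope_weights(dim(true), "all")
    pred_now <- ad_value(out$pred); dim(pred_now) <- dim(true)
    target <- compute_residual(true, pred_now)   # detached: Q is not differentiable
    l_spl <- ad_mae(tape, out$pred, true, w_all)
    l_ppl <- ad_softmax_ce(tape, out$logits, target, w_all)
    out2 <- forward_refine(model, priors, left_context(true), tape = tape)
    w_odd <- scope_weights(dim(true), "odd-columns")
    pred2_now <- ad_value(out2$pred); dim(pred2_now) <- dim(true)
    target2 <- compute_residual(true, pred2_now)
    l_spl2 <- ad_mae(tape, out2$pred, true, w_odd)
    l_ppl2 <- ad_softmax_ce(tape, out2$logits, target2, w_odd)
    terms <- c(terms, list(l_ppl, l_ppl2, l_spl, l_spl2))
    coefs <- c(coefs, 1, 1, lambda, lambda)
    ppl_sum <- ppl_sum + ad_value(l_ppl) + ad_value(l_ppl2)
    spl_sum <- spl_sum + ad_value(l_spl) + ad_value(l_spl2)
    priors <- c(priors, list(true))
  }
  total <- ad_weighted_sum(tape, terms, coefs)
  list(loss = total, ppl = ppl_sum, spl = spl_sum)
}

ad_weighted_sum <- function(tape, nodes, coefs) {
  out <- sum(vapply(nodes, ad_value, numeric(1L)) * coefs)
  ad_op(tape, out, function(g) {
    for (i in seq_along(nodes)) ad_accum(nodes[[i]], g * coefs[i])
  })
}

adam_state <- function() new.env(parent = emptyenv())

adam_update <- function(state, params, grads, lr, net = "net", beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  tk <- paste0("t.", net)
  state[[tk]] <- (if (is.null(state[[tk]])) 0L else state[[tk]]) + 1L
  t <- state[[tk]]
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    key_m <- paste0("m.", net, ".", nm); key_v <- paste0("v.", net, ".", nm)
    m <- if (is.null(state[[key_m]])) g * 0 else state[[key_m]]
    v <- if (is.null(state[[key_v]])) g * 0 else state[[key_v]]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state[[key_m]] <- m; state[[key_v]] <- v
    mhat <- m / (1 - beta1^t); vhat <- v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params
}

#' Train the codec model on a set of images
#'
#' Joint Adam training of the plane and refine networks with teacher-forced
#' priors. Each step draws `batch_size` random crops; one epoch is
#' `ceiling(n_images / batch_size)` steps. Aborts on a non-finite loss with a
#' seed and step report.
#'
#' @param model A [codec_model()] to start from.
#' @param images List of pixel matrices (e.g. from [generate_dataset()]).
#' @param cfg A [train_config()] (use [desk_profile()] for CPU-scale runs).
#' @param verbose Print per-epoch progress.
#' @return The trained `codec_model`, with a `history` data frame
#'   (step, epoch, loss, ppl, spl, lr).
#' @export
train_codec <- function(model, images, cfg = desk_profile(), verbose = FALSE) {
  stopifnot(inherits(model, "codec_model"), length(images) >= 1L,
            inherits(cfg, "train_config"))
  n_plane <- length(model$plane)
  state <- adam_state()
  steps_per_epoch <- max(1L, ceiling(length(images) / cfg$batch_size))
  hist <- list()
  step <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_at_epoch(cfg, epoch)
      for (s in seq_len(steps_per_epoch)) {
        step <- step + 1L
        tape <- ad_tape()
        crops <- lapply(seq_len(cfg$batch_size), function(i)
          random_crop(images[[sample.int(length(images), 1L)]], cfg$crop_size))
        losses <- lapply(crops, function(cr)
          crop_loss(tape, model, cr, cfg$loss_weight_lambda))
        total <- ad_weighted_sum(tape, lapply(losses, `[[`, "loss"),
                                 rep(1 / cfg$batch_size, cfg$batch_size))
        if (!is.finite(ad_value(total)))
          stop(sprintf("training diverged (non-finite loss) at step %d, seed %d",
                       step, cfg$seed))
        ad_backward(tape, total)
        grads <- collect_param_grads(tape, model)
        model$plane <- adam_update(state, model$plane, grads$plane, lr, net = "plane")
        model$refine <- adam_update(state, model$refine, grads$refine, lr, net = "refine")
        hist[[step]] <- data.frame(
          step = step, epoch = epoch, loss = ad_value(total),
          ppl = mean(vapply(losses, `[[`, numeric(1L), "ppl")),
          spl = mean(vapply(losses, `[[`, numeric(1L), "spl")), lr = lr)
      }
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.4f  lr %.2e", epoch, cfg$epochs,
                        hist[[step]]$loss, lr))
    }
  })
  new_hist <- do.call(rbind, hist)
  model$history <- if (is.null(model$history)) new_hist else rbind(model$history, new_hist)
  model
}

# Gradients accumulate on the per-tape cached parameter leaves created by
# wrap_params(); read them back by parameter name.
collect_param_grads <- function(tape, model) {
  get_g <- function(nodes) if (is.null(nodes)) list() else lapply(nodes, function(n) n$grad)
  list(plane = get_g(tape$param_cache$plane),
       refine = get_g(tape$param_cache$refine))
}
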