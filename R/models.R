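# Network definitions.
#
# Two networks share one architecture family:
#  * the plane network predicts a whole level-1 subimage from up to three
#    previously coded subimages (3 input channels, absent priors zero-filled);
#  * the refine network additionally sees the already-coded even columns of
#    the current plane (4 input channels) and is used for the odd columns.
#
# Each network is: a ResBlock feature extractor (3 basic residual blocks,
# stride 1, no normalization so outputs are batch-size independent and
# bit-reproducible), a prediction head (3x3 conv + sigmoid * 255), and a
# 4-stage UNet probability head with squeeze-and-excitation attention after
# every upsampling stage and a 511-way per-pixel softmax.

#' Network and codec configuration
#'
#' @param base_channels Width of the ResBlock feature extractor (default 64).
#' @param unet_channels Encoder channel schedule of the 4-stage UNet
#'   (default `c(64, 128, 256, 512)`); the decoder mirrors it.
#' @param se_reduction Squeeze-and-excitation bottleneck ratio (default 16);
#'   must divide every attended (decoder) channel count.
#' @param num_classes Residual alphabet size; fixed at 511 for 8-bit input.
#' @return Object of class `codec_config`.
#' @export
codec_config <- function(base_channels = 64L, unet_channels = c(64L, 128L, 256L, 512L),
                         se_reduction = 16L, num_classes = 511L) {
  stopifnot(num_classes == 511L, length(unet_channels) == 4L,
            base_channels >= 1L, all(unet_channels >= 1L))
  attended <- c(unet_channels[3:1], unet_channels[1L])  # decoder stage outputs
  if (any(attended %% se_reduction != 0L))
    stop("se_reduction must divide every decoder channel count")
  structure(list(
    base_channels = as.integer(base_channels),
    unet_channels = as.integer(unet_channels),
    se_reduction = as.integer(se_reduction),
    num_classes = 511L,
    n_priors_plane = 3L,
    n_priors_refine = 4L
  ), class = "codec_config")
}

# Desk-scale profile used throughout the package's own tests and examples:
# small enough for CPU work, same topology as the default.
#' @rdname codec_config
#' @export
codec_config_small <- function() {
  codec_config(base_channels = 8L, unet_channels = c(8L, 8L, 8L, 8L),
               se_reduction = 4L)
}

he_init <- function(rng_dim, fan_in) {
  array(stats::rnorm(prod(rng_dim), sd = sqrt(2 / fan_in)), rng_dim)
}

conv_param <- function(params, name, kh, kw, cin, cout) {
  params[[paste0(name, ".w")]] <- he_init(c(kh, kw, cin, cout), kh * kw * cin)
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

dense_param <- function(params, name, cin, cout) {
  params[[paste0(name, ".w")]] <- matrix(stats::rnorm(cout * cin, sd = sqrt(2 / cin)), cout, cin)
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

init_network_params <- function(cfg, in_channels) {
  B <- cfg$base_channels
  U <- cfg$unet_channels
  p <- list()
  p <- conv_param(p, "stem", 3L, 3L, in_channels, B)
  for (i in 1:3) {
    p <- conv_param(p, sprintf("res%d.c1", i), 3L, 3L, B, B)
    p <- conv_param(p, sprintf("res%d.c2", i), 3L, 3L, B, B)
  }
  p <- conv_param(p, "pred", 3L, 3L, B, 1L)
  # UNet encoder
  cin <- B
  for (i in 1:4) {
    p <- conv_param(p, sprintf("enc%d", i), 3L, 3L, cin, U[i])
    cin <- U[i]
  }
  p <- conv_param(p, "bott", 3L, 3L, U[4L], U[4L])
  # UNet decoder: stage i consumes up(x) concat enc_(5-i)
  dec_out <- c(U[3L], U[2L], U[1L], U[1L])
  dec_in <- c(U[4L] + U[4L], dec_out[1L] + U[3L], dec_out[2L] + U[2L], dec_out[3L] + U[1L])
  for (i in 1:4) {
    p <- conv_param(p, sprintf("dec%d", i), 3L, 3L, dec_in[i], dec_out[i])
    r <- cfg$se_reduction
    p <- dense_param(p, sprintf("se%d.fc1", i), dec_out[i], dec_out[i] %/% r)
    p <- dense_param(p, sprintf("se%d.fc2", i), dec_out[i] %/% r, dec_out[i])
  }
  p <- conv_param(p, "cls", 1L, 1L, dec_out[4L], cfg$num_classes)
  # Class-head bias starts at the log of a broad discretized Laplacian
  # centered on the zero-error class 255 (scale 15 gray levels): residuals
  # of any reasonable predictor are Laplacian-like, so training starts from
  # a sane marginal and spends its budget on conditioning. Standard
  # log-prior bias initialization for classifier heads.
  j <- 0:(cfg$num_classes - 1L)
  logprior <- -abs(j - 255) / 15
  p[["cls.b"]] <- logprior - log(sum(exp(logprior)))
  p
}

#' Create a codec model with freshly initialized weights
#'
#' The model bundles the plane network, the refine network, and the
#' configuration. Weights are He-initialized from `seed`.
#'
#' @param config A [codec_config()].
#' @param seed Integer seed that fully determines the initialization.
#' @return Object of class `codec_model`.
#' @export
codec_model <- function(config = codec_config(), seed = 1L) {
  stopifnot(inherits(config, "codec_config"))
  with_seed(seed, {
    plane <- init_network_params(config, config$n_priors_plane)
    refine <- init_network_params(config, config$n_priors_refine)
  })
  structure(list(
    config = config,
    plane = plane,
    refine = refine,
    seed = as.integer(seed),
    history = NULL
  ), class = "codec_model")
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- forward passes ---------------------------------------------------------

# Wrap a parameter list in tape leaves (training) or pass through (inference).
# Leaves are cached per tape and network so every forward pass in one
# optimization step accumulates gradients on the same nodes.
wrap_params <- function(tape, params, key = NULL) {
  if (is.null(tape)) return(params)
  if (!is.null(key)) {
    if (is.null(tape$param_cache)) tape$param_cache <- list()
    cached <- tape$param_cache[[key]]
    if (!is.null(cached)) return(cached)
  }
  nodes <- lapply(params, function(p) ad_leaf(tape, p))
  if (!is.null(key)) tape$param_cache[[key]] <- nodes
  nodes
}

#' Stack prior planes into a fixed-channel network input
#'
#' Planes (pixel matrices in `[0, 255]`) are scaled to `[0, 1]` and stacked
#' along the channel axis in coding order; missing channels up to `n_channels`
#' are zero-filled (the "blank matrix" convention that lets one network serve
#' every position).
#'
#' @param planes List of 1 or more equally sized matrices.
#' @param n_channels Fixed channel count of the network input.
#' @return Array `h x w x n_channels`.
#' @export
stack_priors <- function(planes, n_channels) {
  stopifnot(length(planes) >= 1L, length(planes) <= n_channels)
  dm <- dim(planes[[1L]])
  if (!all(vapply(planes, function(p) identical(dim(p), dm), logical(1L))))
    stop("prior planes must share one shape")
  x <- array(0, c(dm[1L], dm[2L], n_channels))
  for (i in seq_along(planes)) x[, , i] <- planes[[i]] / 255
  x
}

resblock_stack <- function(tape, x, P) {
  h <- ad_relu(tape, ad_conv2d(tape, x, P[["stem.w"]], P[["stem.b"]]))
  for (i in 1:3) {
    t1 <- ad_relu(tape, ad_conv2d(tape, h, P[[sprintf("res%d.c1.w", i)]], P[[sprintf("res%d.c1.b", i)]]))
    t2 <- ad_conv2d(tape, t1, P[[sprintf("res%d.c2.w", i)]], P[[sprintf("res%d.c2.b", i)]])
    h <- ad_relu(tape, ad_add(tape, h, t2))
  }
  h
}

predict_head <- function(tape, latent, P) {
  ad_scale(tape, ad_sigmoid(tape, ad_conv2d(tape, latent, P[["pred.w"]], P[["pred.b"]])), 255)
}

se_block <- function(tape, x, P, i) {
  z <- ad_gap(tape, x)
  s <- ad_sigmoid(tape, ad_dense(tape,
    ad_relu(tape, ad_dense(tape, z, P[[sprintf("se%d.fc1.w", i)]], P[[sprintf("se%d.fc1.b", i)]])),
    P[[sprintf("se%d.fc2.w", i)]], P[[sprintf("se%d.fc2.b", i)]]))
  ad_scale_channels(tape, x, s)
}

unet_logits <- function(tape, latent, P) {
  d <- dim(as_hwc(ad_value(latent)))
  H <- d[1L]; W <- d[2L]
  H2 <- 16L * ceiling(H / 16L); W2 <- 16L * ceiling(W / 16L)
  x <- if (H2 != H || W2 != W) ad_pad_reflect(tape, latent, H2, W2) else latent
  enc <- vector("list", 4L)
  for (i in 1:4) {
    x <- ad_relu(tape, ad_conv2d(tape, x, P[[sprintf("enc%d.w", i)]], P[[sprintf("enc%d.b", i)]]))
    enc[[i]] <- x
    x <- ad_avgpool2(tape, x)
  }
  x <- ad_relu(tape, ad_conv2d(tape, x, P[["bott.w"]], P[["bott.b"]]))
  for (i in 1:4) {
    x <- ad_concat(tape, ad_upsample2(tape, x), enc[[5L - i]])
    x <- ad_relu(tape, ad_conv2d(tape, x, P[[sprintf("dec%d.w", i)]], P[[sprintf("dec%d.b", i)]]))
    x <- se_block(tape, x, P, i)
  }
  x <- ad_conv2d(tape, x, P[["cls.w"]], P[["cls.b"]])
  if (H2 != H || W2 != W) x <- ad_crop(tape, x, H, W) else x
}

# Shared forward: latent -> (pred, logits). Returns nodes when tape given,
# else list(pred = matrix, prob = h x w x 511 array).
network_forward <- function(tape, xin, P) {
  latent <- resblock_stack(tape, xin, P)
  pred <- predict_head(tape, latent, P)
  logits <- unet_logits(tape, latent, P)
  if (is.null(tape)) {
    pv <- pred
    dim(pv) <- dim(pred)[1:2]
    list(pred = pv, prob = softmax_hwk(logits))
  } else {
    list(pred = pred, logits = logits)
  }
}

#' Run the plane network on previously coded subimages
#'
#' @param model A [codec_model()].
#' @param priors List of 1-3 already-coded level-1 planes (matrices).
#' @param tape Internal; an autodiff tape during training.
#' @return `list(pred = h x w matrix in [0,255], prob = h x w x 511 array)`
#'   in inference mode.
#' @export
forward_plane <- function(model, priors, tape = NULL) {
  cfg <- model$config
  stopifnot(length(priors) >= 1L, length(priors) <= 3L)
  xin <- stack_priors(priors, cfg$n_priors_plane)
  network_forward(tape, if (is.null(tape)) xin else ad_leaf(tape, xin),
                  wrap_params(tape, model$plane, key = "plane"))
}

#' Run the refine network on priors plus the coded left (even) columns
#'
#' @param model A [codec_model()].
#' @param priors List of 1-3 already-coded level-1 planes.
#' @param left_plane The already-coded even columns presented at level-1
#'   resolution, with each odd column filled by the average of its even
#'   neighbors (see the codec's `left_context()` convention); any
#'   deterministic function of the even columns keeps encoder and decoder
#'   in lockstep.
#' @param tape Internal; an autodiff tape during training.
#' @return As [forward_plane()].
#' @export
forward_refine <- function(model, priors, left_plane, tape = NULL) {
  cfg <- model$config
  stopifnot(length(priors) >= 1L, length(priors) <= 3L)
  xin <- stack_priors(c(priors, list(left_plane)), cfg$n_priors_refine)
  # the left plane always occupies the last channel
  n <- length(priors)
  if (n < 3L) {
    xin[, , 4L] <- xin[, , n + 1L]
    xin[, , n + 1L] <- 0
  }
  network_forward(tape, if (is.null(tape)) xin else ad_leaf(tape, xin),
                  wrap_params(tape, model$refine, key = "refine"))
}

# ---- checkpoint I/O ---------------------------------------------------------

#' Save / load a codec model
#'
#' The checkpoint is a single RDS archive holding both parameter sets, the
#' configuration, and the training history.
#'
#' @param model A `codec_model`.
#' @param path File path.
#' @return `load_model` returns the `codec_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "codec_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "codec_model")) stop("not a codec model checkpoint")
  model
}

# ---- S3 methods -------------------------------------------------------------

n_params <- function(params) sum(vapply(params, length, numeric(1L)))

#' @export
print.codec_model <- function(x, ...) {
  cfg <- x$config
  cat("Tunable multi-scale lossless codec model\n")
  cat(sprintf("  feature channels: %d; UNet schedule: %s; SE reduction: %d\n",
              cfg$base_channels, paste(cfg$unet_channels, collapse = "-"),
              cfg$se_reduction))
  cat(sprintf("  plane network: %s parameters; refine network: %s parameters\n",
              format(n_params(x$plane), big.mark = ","),
              format(n_params(x$refine), big.mark = ",")))
  if (is.null(x$history)) {
    cat("  weights: random initialization (seed ", x$seed, ")\n", sep = "")
  } else {
    h <- x$history
    cat(sprintf("  trained %d steps; final loss %.4f (ppl %.4f, spl %.4f)\n",
                nrow(h), h$loss[nrow(h)], h$ppl[nrow(h)], h$spl[nrow(h)]))
  }
  invisible(x)
}

#' @export
summary.codec_model <- function(object, ...) {
  print(object)
  cat("  residual alphabet: ", object$config$num_classes, " classes\n", sep = "")
  if (!is.null(object$history)) {
    cat("  loss trajectory (5-number summary):\n")
    print(stats::fivenum(object$history$loss))
  }
  invisible(object)
}

#' @export
plot.codec_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history to plot")
  h <- x$history
  graphics::plot(h$step, h$loss, type = "l", xlab = "step", ylab = "loss",
                 main = "Training loss", ...)
  graphics::lines(h$step, h$ppl, col = "steelblue")
  graphics::legend("topright", c("total", "probability (PPL)"),
                   col = c("black", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' Predict a subimage plane from its priors
#'
#' Convenience `predict` method: runs the plane network (or, with
#' `left_plane`, the refine network) and returns the predicted plane and the
#' per-pixel 511-class probability volume.
#'
#' @param object A `codec_model`.
#' @param priors List of already-coded planes.
#' @param left_plane Optional plane with odd columns zeroed; switches to the
#'   refine network.
#' @param ... Unused.
#' @export
predict.codec_model <- function(object, priors, left_plane = NULL, ...) {
  if (is.null(left_plane)) forward_plane(object, priors)
  else forward_refine(object, priors, left_plane)
}
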