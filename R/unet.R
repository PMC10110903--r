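# 3D segmentation U-Net: four encoder blocks (3x3x3 conv + ReLU + 2x2x2
# max-pool), symmetric decoder (2x2x2 stride-2 deconvolution + skip
# concatenation + 3x3x3 conv), final 1x1x1 conv + 2-channel softmax.
# Binary cross-entropy loss, Adam optimizer, seeded He initialization.
# Compiled kernels live in src/layers.cpp; everything is single-threaded
# and deterministic.

.he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

#' Build a segmentation U-Net
#'
#' Allocates seeded He-initialized weights for the architecture described
#' by `config`. The encoder halves each spatial axis four times, so the
#' central latent tensor has shape `input_shape / 16` by the last encoder
#' channel count; for the full-scale preset that is 6 x 6 x 3 x 512 = 55296
#' features.
#'
#' @param config a [UNetConfig-class].
#' @return a [SegNetModel-class] with untrained weights.
#' @examples
#' m <- buildModel(UNetConfig("desk", seed = 1))
#' latentLength(m)  # 256
#' @export
buildModel <- function(config) {
  validObject(config)
  enc_ch <- config@encoder_channels
  up_ch <- config@decoder_deconv_channels
  cv_ch <- config@decoder_conv_channels
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(config@seed)
  w <- list()
  cin <- 1L
  for (i in 1:4) {
    w[[paste0("enc", i, ".W")]] <- .he_init(c(3, 3, 3, cin, enc_ch[i]), 27 * cin)
    w[[paste0("enc", i, ".b")]] <- numeric(enc_ch[i])
    cin <- enc_ch[i]
  }
  din <- enc_ch[4]
  for (j in 1:4) {
    skip <- enc_ch[5 - j]
    w[[paste0("dec", j, ".Wup")]] <- .he_init(c(2, 2, 2, din, up_ch[j]), 8 * din)
    w[[paste0("dec", j, ".bup")]] <- numeric(up_ch[j])
    cat_ch <- up_ch[j] + skip
    w[[paste0("dec", j, ".W")]] <- .he_init(c(3, 3, 3, cat_ch, cv_ch[j]), 27 * cat_ch)
    w[[paste0("dec", j, ".b")]] <- numeric(cv_ch[j])
    din <- cv_ch[j]
  }
  w[["final.W"]] <- matrix(rnorm(cv_ch[4] * 2, 0, sqrt(2 / cv_ch[4])), cv_ch[4], 2)
  w[["final.b"]] <- numeric(2)
  new("SegNetModel", weights = w, config = config,
      training_history = numeric())
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

.check_volume <- function(config, volume) {
  if (!identical(dim(volume), as.integer(config@input_shape)))
    stop("volume shape ", paste(dim(volume), collapse = "x"),
         " does not match network input ",
         paste(config@input_shape, collapse = "x"))
}

.normalize_volume <- function(volume, config) {
  if (!config@normalize) return(volume)
  s <- sd(volume)
  if (s == 0) s <- 1
  (volume - mean(volume)) / s
}

# Forward pass. Returns the 2-channel softmax probabilities and (when
# cache = TRUE) every intermediate needed for backpropagation.
.unet_forward <- function(w, config, volume, cache = FALSE, encoder_only = FALSE) {
  x <- array(volume, c(config@input_shape, 1L))
  acts <- pools <- args <- vector("list", 4)
  for (i in 1:4) {
    pre <- conv3d_fwd(x, dim(x), w[[paste0("enc", i, ".W")]],
                      w[[paste0("enc", i, ".b")]])
    a <- pmax(pre, 0); dim(a) <- dim(pre)
    mp <- maxpool3d_fwd(a, dim(a))
    acts[[i]] <- a; pools[[i]] <- x <- mp$out; args[[i]] <- mp$arg
  }
  bottleneck <- x
  if (encoder_only)
    return(list(bottleneck = bottleneck))
  d <- bottleneck
  dins <- cats <- dec_acts <- vector("list", 4)
  for (j in 1:4) {
    dins[[j]] <- d
    u <- upconv3d_fwd(d, dim(d), w[[paste0("dec", j, ".Wup")]],
                      w[[paste0("dec", j, ".bup")]])
    skip <- acts[[5 - j]]
    cat_arr <- c(u, skip)
    dim(cat_arr) <- c(dim(u)[1:3], dim(u)[4] + dim(skip)[4])
    pre <- conv3d_fwd(cat_arr, dim(cat_arr), w[[paste0("dec", j, ".W")]],
                      w[[paste0("dec", j, ".b")]])
    d <- pmax(pre, 0); dim(d) <- dim(pre)
    cats[[j]] <- cat_arr; dec_acts[[j]] <- d
  }
  n_vox <- prod(config@input_shape)
  feat <- matrix(d, n_vox, dim(d)[4])
  logits <- sweep(feat %*% w[["final.W"]], 2, w[["final.b"]], "+")
  mx <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - mx); e2 <- exp(logits[, 2] - mx)
  prob_fg <- e2 / (e1 + e2)
  out <- list(prob_fg = prob_fg, bottleneck = bottleneck)
  if (cache)
    out <- c(out, list(x0 = array(volume, c(config@input_shape, 1L)),
                       acts = acts, pools = pools, args = args,
                       dins = dins, cats = cats, dec_acts = dec_acts,
                       feat = feat))
  out
}

# BCE loss and full gradient for one (normalized) volume/mask pair.
.unet_loss_grad <- function(w, config, volume, mask, grad = TRUE) {
  fw <- .unet_forward(w, config, volume, cache = grad)
  y <- as.numeric(mask)
  eps <- 1e-12
  p <- pmin(pmax(fw$prob_fg, eps), 1 - eps)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  if (!grad) return(list(loss = loss))
  n_vox <- length(y)
  G <- cbind((1 - p) - (1 - y), p - y) / n_vox  # d loss / d logits
  g <- list()
  g[["final.W"]] <- t(fw$feat) %*% G
  g[["final.b"]] <- colSums(G)
  gd <- G %*% t(w[["final.W"]])
  gd <- array(gd, dim(fw$dec_acts[[4]]))
  gskips <- vector("list", 4)
  for (j in 4:1) {
    gpre <- gd * (fw$dec_acts[[j]] > 0)
    cb <- conv3d_bwd(fw$cats[[j]], dim(fw$cats[[j]]),
                     w[[paste0("dec", j, ".W")]], gpre)
    g[[paste0("dec", j, ".W")]] <- cb$gw
    g[[paste0("dec", j, ".b")]] <- cb$gb
    cu <- dim(fw$dins[[j]])[4]
    cu_out <- dim(cb$gin)[4] - dim(fw$acts[[5 - j]])[4]
    gu <- cb$gin[, , , seq_len(cu_out), drop = FALSE]
    gskips[[5 - j]] <- cb$gin[, , , cu_out + seq_len(dim(fw$acts[[5 - j]])[4]),
                              drop = FALSE]
    ub <- upconv3d_bwd(fw$dins[[j]], dim(fw$dins[[j]]),
                       w[[paste0("dec", j, ".Wup")]], gu)
    g[[paste0("dec", j, ".Wup")]] <- ub$gw
    g[[paste0("dec", j, ".bup")]] <- ub$gb
    gd <- ub$gin
  }
  gp <- gd  # gradient at the bottleneck (= pooled output of encoder 4)
  for (i in 4:1) {
    ga <- maxpool3d_bwd(gp, fw$args[[i]], dim(fw$acts[[i]]))
    ga <- ga + gskips[[i]]
    gpre <- ga * (fw$acts[[i]] > 0)
    xin <- if (i == 1) fw$x0 else fw$pools[[i - 1]]
    cb <- conv3d_bwd(xin, dim(xin), w[[paste0("enc", i, ".W")]], gpre)
    g[[paste0("enc", i, ".W")]] <- cb$gw
    g[[paste0("enc", i, ".b")]] <- cb$gb
    gp <- cb$gin
  }
  list(loss = loss, grad = g)
}

#' Train a segmentation U-Net
#'
#' Minimizes the binary cross-entropy of the foreground softmax channel
#' with Adam (beta1 = 0.9, beta2 = 0.999) at the configured learning rate
#' and batch size, recording the mean training loss per epoch. On the first
#' training call the final-layer bias is set to the logit of the mean
#' foreground fraction of the training masks (class-prior initialization):
#' starting calibrated to the class imbalance removes the early
#' all-background collapse phase, whose sign-consistent gradients otherwise
#' silence the deep encoder channels that carry the latent features.
#' Training is deterministic given the configuration seed.
#'
#' @param model a [SegNetModel-class].
#' @param volumes list of 3D intensity arrays matching the input shape.
#' @param masks list of 3D binary arrays (same shapes).
#' @param epochs override of the configured epoch count.
#' @return the trained [SegNetModel-class] with `training_history` filled.
#' @export
trainModel <- function(model, volumes, masks, epochs = NULL) {
  config <- model@config
  if (length(volumes) == 0L) stop("empty training dataset")
  if (length(volumes) != length(masks))
    stop("volumes and masks must pair up")
  for (v in volumes) .check_volume(config, v)
  for (m in masks) {
    .check_volume(config, m)
    if (!all(m %in% c(0, 1))) stop("masks must be binary")
  }
  epochs <- as.integer(epochs %||% config@epochs)
  volumes <- lapply(volumes, .normalize_volume, config = config)
  w <- model@weights
  if (!length(model@training_history)) {
    fg <- mean(vapply(masks, mean, 0))
    fg <- min(max(fg, 1e-4), 1 - 1e-4)
    w[["final.b"]] <- c(0, qlogis(fg))  # class-prior head initialization
  }
  mstate <- lapply(w, function(p) array(0, dim(p) %||% length(p)))
  vstate <- lapply(w, function(p) array(0, dim(p) %||% length(p)))
  lr <- config@learning_rate
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  t_step <- 0L
  n <- length(volumes)
  history <- numeric(epochs)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(config@seed + 1L)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    batches <- split(ord, ceiling(seq_along(ord) / config@batch_size))
    for (bt in batches) {
      acc <- NULL
      bloss <- 0
      for (ix in bt) {
        lg <- .unet_loss_grad(w, config, volumes[[ix]], masks[[ix]])
        bloss <- bloss + lg$loss
        if (is.null(acc)) acc <- lg$grad
        else for (k in names(acc)) acc[[k]] <- acc[[k]] + lg$grad[[k]]
      }
      nb <- length(bt)
      t_step <- t_step + 1L
      for (k in names(w)) {
        gk <- acc[[k]] / nb
        mstate[[k]] <- b1 * mstate[[k]] + (1 - b1) * gk
        vstate[[k]] <- b2 * vstate[[k]] + (1 - b2) * gk^2
        mhat <- mstate[[k]] / (1 - b1^t_step)
        vhat <- vstate[[k]] / (1 - b2^t_step)
        w[[k]] <- w[[k]] - lr * mhat / (sqrt(vhat) + adam_eps)
      }
      ep_loss <- ep_loss + bloss
    }
    history[ep] <- ep_loss / n
  }
  model@weights <- w
  model@training_history <- c(model@training_history, history)
  model
}

#' Segment a volume
#'
#' Runs the network and thresholds the foreground softmax probability at
#' 0.5; a probability of exactly 0.5 is assigned to the foreground.
#'
#' @param model a [SegNetModel-class].
#' @param volume 3D intensity array matching the input shape.
#' @return 3D logical array (predicted mask).
#' @export
segmentVolume <- function(model, volume) {
  .check_volume(model@config, volume)
  v <- .normalize_volume(volume, model@config)
  fw <- .unet_forward(model@weights, model@config, v)
  array(fw$prob_fg >= 0.5, model@config@input_shape)
}

#' Extract the central latent vector
#'
#' Flattens the bottleneck activations in x-fastest order (x, then y, then
#' z, then channel); this ordering is stable across calls and is the
#' feature indexing used by [buildFeaturePanel()].
#'
#' @param model a [SegNetModel-class].
#' @param volume 3D intensity array matching the input shape.
#' @return numeric vector of length [latentLength()].
#' @export
extractLatent <- function(model, volume) {
  .check_volume(model@config, volume)
  v <- .normalize_volume(volume, model@config)
  fw <- .unet_forward(model@weights, model@config, v, encoder_only = TRUE)
  as.vector(fw$bottleneck)
}
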