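## Compact dense-network engine: fully-connected layers, backprop, Adam.
## Powers the simple DNN, the joint autoencoder-classifier, and the joint
## variational autoencoder-classifier. Everything runs on base-R matrix
## algebra and R's RNG, so trained models are exactly reproducible from
## (architecture, data, seed).

act_fun <- function(z, act) switch(act,
  linear = z,
  relu = pmax(z, 0),
  sigmoid = stats::plogis(z),
  tanh = tanh(z),
  stop("unknown activation: ", act))

act_grad <- function(z, a, act) switch(act,  # dA/dZ given pre/post activation
  linear = 1,
  relu = (z > 0) * 1,
  sigmoid = a * (1 - a),
  tanh = 1 - a^2,
  stop("unknown activation: ", act))

# He-initialized MLP; draws from the caller's RNG state.
mlp_new <- function(widths, acts) {
  stopifnot(length(acts) == length(widths) - 1)
  layers <- vector("list", length(acts))
  for (l in seq_along(acts)) {
    fan_in <- widths[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * widths[l + 1], 0, sqrt(2 / fan_in)),
                 fan_in, widths[l + 1]),
      b = numeric(widths[l + 1]),
      act = acts[l])
  }
  layers
}

net_forward <- function(net, X, dropout = 0, train = FALSE) {
  L <- length(net)
  A <- vector("list", L + 1)
  Z <- vector("list", L)
  masks <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net[[l]]$W, 2, net[[l]]$b, `+`)
    a <- act_fun(Z[[l]], net[[l]]$act)
    if (train && dropout > 0 && l < L) {
      m <- matrix(stats::rbinom(length(a), 1, 1 - dropout) / (1 - dropout),
                  nrow(a), ncol(a))
      a <- a * m
      masks[[l]] <- m
    }
    A[[l + 1]] <- a
  }
  list(A = A, Z = Z, masks = masks)
}

# dOut: gradient w.r.t. the network output (or w.r.t. the final
# pre-activation if out_is_dZ). Returns per-layer grads and dX.
net_backward <- function(net, cache, dOut, out_is_dZ = FALSE, l2 = 0) {
  L <- length(net)
  grads <- vector("list", L)
  dA <- dOut
  for (l in L:1) {
    dZ <- if (l == L && out_is_dZ) dA else {
      if (!is.null(cache$masks[[l]])) dA <- dA * cache$masks[[l]]
      dA * act_grad(cache$Z[[l]], cache$A[[l + 1]], net[[l]]$act)
    }
    grads[[l]] <- list(W = crossprod(cache$A[[l]], dZ) + l2 * net[[l]]$W,
                       b = colSums(dZ))
    dA <- dZ %*% t(net[[l]]$W)
  }
  list(grads = grads, dX = dA)
}

adam_init <- function(net) lapply(net, function(l)
  list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))

adam_step <- function(net, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (l in seq_along(net)) {
    s <- state[[l]]
    g <- grads[[l]]
    s$mW <- b1 * s$mW + (1 - b1) * g$W
    s$vW <- b2 * s$vW + (1 - b2) * g$W^2
    s$mb <- b1 * s$mb + (1 - b1) * g$b
    s$vb <- b2 * s$vb + (1 - b2) * g$b^2
    cor1 <- 1 - b1^t
    cor2 <- 1 - b2^t
    net[[l]]$W <- net[[l]]$W - lr * (s$mW / cor1) / (sqrt(s$vW / cor2) + eps)
    net[[l]]$b <- net[[l]]$b - lr * (s$mb / cor1) / (sqrt(s$vb / cor2) + eps)
    state[[l]] <- s
  }
  list(net = net, state = state)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Joint autoencoder-classifier total loss
#'
#' Weighted average of the reconstruction and classification losses:
#' `w * recon + (1 - w) * clf`.
#'
#' @param recon reconstruction loss (>= 0).
#' @param clf classification loss (>= 0).
#' @param w weight in \[0, 1\].
#' @return Scalar total loss.
#' @export
joint_ae_total_loss <- function(recon, clf, w) {
  if (!is.numeric(w) || w < 0 || w > 1) stop("w must lie in [0, 1]")
  w * recon + (1 - w) * clf
}

#' Variational joint model total loss
#'
#' `recon + kl + c * clf`, the sum of reconstruction loss, KL divergence of
#' the latent posterior from the standard normal prior, and the
#' classification loss scaled by `c`.
#'
#' @param recon reconstruction loss.
#' @param kl KL divergence (>= 0), e.g. from [kl_gaussian()].
#' @param clf classification loss.
#' @param c positive scalar weight on the classification loss.
#' @return Scalar total loss.
#' @export
vae_total_loss <- function(recon, kl, clf, c = 1) {
  if (kl < 0) stop("kl must be >= 0")
  if (c <= 0) stop("c must be positive")
  recon + kl + c * clf
}

#' Gaussian KL divergence of a diagonal posterior from N(0, I)
#'
#' `-0.5 * sum(1 + log sigma^2 - mu^2 - sigma^2)` over latent units, per
#' sample (rows of the inputs).
#'
#' @param mu matrix (samples x latent units) of posterior means.
#' @param logvar matching matrix of posterior log-variances.
#' @return Per-sample KL values.
#' @export
kl_gaussian <- function(mu, logvar) {
  mu <- rbind(mu)
  logvar <- rbind(logvar)
  -0.5 * rowSums(1 + logvar - mu^2 - exp(logvar))
}

recon_loss_grad <- function(xhat, x, scale, n_batch) {
  # mean over entries; BCE pairs with a sigmoid output (gradient given as dZ)
  if (scale == "beta") {
    ph <- pmin(pmax(xhat, 1e-12), 1 - 1e-12)
    list(loss = -mean(x * log(ph) + (1 - x) * log(1 - ph)),
         d = (xhat - x) / length(x), is_dZ = TRUE)
  } else {
    list(loss = mean((xhat - x)^2),
         d = 2 * (xhat - x) / length(x), is_dZ = FALSE)
  }
}

minibatches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

#' Train the standalone deep neural network classifier
#'
#' Fully-connected classifier on an N-wide input (N = 200 by default in the
#' evaluation protocol): hidden relu layers and a single sigmoid output node
#' trained on binary cross-entropy with Adam.
#'
#' @param x samples-by-features matrix.
#' @param y binary labels (0/1 or case/control).
#' @param hidden hidden-layer widths (default `c(128, 64)`).
#' @param epochs training epochs; the full-scale default is 1000, reduced-
#'   scale runs pass a smaller value.
#' @param batch_size minibatch size (default 128).
#' @param lr Adam learning rate (full-scale default 1e-4).
#' @param dropout hidden-layer dropout rate (default 0).
#' @param l2 weight penalty (default 0).
#' @param seed RNG seed (initialization, shuffling, dropout).
#' @return A `dl_model` with `kind = "simple_dnn"`.
#' @export
train_simple_dnn <- function(x, y, hidden = c(128, 64), epochs = 1000,
                             batch_size = 128, lr = 1e-4, dropout = 0,
                             l2 = 0, seed = 1L) {
  x <- as.matrix(x)
  y <- as01(y)
  if (anyNA(x)) stop("NaN/NA in features")
  set.seed(seed)
  net <- mlp_new(c(ncol(x), hidden, 1),
                 c(rep("relu", length(hidden)), "sigmoid"))
  st <- adam_init(net)
  t <- 0
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    for (bi in minibatches(nrow(x), batch_size)) {
      xb <- x[bi, , drop = FALSE]
      yb <- y[bi]
      fw <- net_forward(net, xb, dropout, train = TRUE)
      p <- fw$A[[length(fw$A)]]
      dZ <- (p - yb) / length(yb)
      bk <- net_backward(net, fw, dZ, out_is_dZ = TRUE, l2 = l2)
      t <- t + 1
      up <- adam_step(net, bk$grads, st, lr, t)
      net <- up$net
      st <- up$state
    }
    p_all <- net_forward(net, x)$A[[length(net) + 1]]
    hist[ep] <- bce_loss(p_all, y)
    if (!is.finite(hist[ep]))
      stop("training diverged (loss not finite) at epoch ", ep)
  }
  structure(list(kind = "simple_dnn", nets = list(clf = net),
                 hyper = list(epochs = epochs, batch_size = batch_size,
                              lr = lr, dropout = dropout, l2 = l2,
                              seed = seed),
                 loss_history = hist),
            class = "dl_model")
}

#' Train a joint autoencoder-classifier
#'
#' Encoder N-128-64 into a 32-unit bottleneck, decoder 64-128-N, and a small
#' classifier head on the bottleneck. The total loss is the weighted average
#' `w * recon + (1 - w) * BCE` ([joint_ae_total_loss()]); reconstruction is
#' mean squared error on the M scale and binary cross-entropy (sigmoid
#' output) on the beta scale.
#'
#' @param x samples-by-features matrix on `scale`.
#' @param y binary labels.
#' @param scale `"M"` or `"beta"`; decides the reconstruction loss wiring.
#' @param encoder,bottleneck,clf_hidden architecture widths.
#' @param w weight on the reconstruction loss, in \[0, 1\] (default 0.5).
#' @param epochs full-scale default 2000.
#' @param batch_size,lr,dropout,l2,seed as in [train_simple_dnn()].
#' @return A `dl_model` with `kind = "joint_ae"` and a decoder.
#' @export
train_joint_ae <- function(x, y, scale = c("M", "beta"),
                           encoder = c(128, 64), bottleneck = 32,
                           clf_hidden = 16, w = 0.5, epochs = 2000,
                           batch_size = 128, lr = 1e-4, dropout = 0,
                           l2 = 0, seed = 1L) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  y <- as01(y)
  if (anyNA(x)) stop("NaN/NA in features")
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  set.seed(seed)
  N <- ncol(x)
  enc <- mlp_new(c(N, encoder, bottleneck),
                 c(rep("relu", length(encoder)), "linear"))
  dec <- mlp_new(c(bottleneck, rev(encoder), N),
                 c(rep("relu", length(encoder)),
                   if (scale == "beta") "sigmoid" else "linear"))
  clf <- mlp_new(c(bottleneck, clf_hidden, 1),
                 c(rep("relu", length(clf_hidden)), "sigmoid"))
  st_e <- adam_init(enc); st_d <- adam_init(dec); st_c <- adam_init(clf)
  t <- 0
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    for (bi in minibatches(nrow(x), batch_size)) {
      xb <- x[bi, , drop = FALSE]
      yb <- y[bi]
      fe <- net_forward(enc, xb, train = TRUE)
      z <- fe$A[[length(enc) + 1]]
      fd <- net_forward(dec, z, train = TRUE)
      xhat <- fd$A[[length(dec) + 1]]
      fc <- net_forward(clf, z, dropout, train = TRUE)
      p <- fc$A[[length(clf) + 1]]

      rg <- recon_loss_grad(xhat, xb, scale, length(yb))
      bd <- net_backward(dec, fd, w * rg$d, out_is_dZ = rg$is_dZ, l2 = l2)
      dZc <- (1 - w) * (p - yb) / length(yb)
      bc <- net_backward(clf, fc, dZc, out_is_dZ = TRUE, l2 = l2)
      be <- net_backward(enc, fe, bd$dX + bc$dX, l2 = l2)
      t <- t + 1
      up <- adam_step(enc, be$grads, st_e, lr, t); enc <- up$net; st_e <- up$state
      up <- adam_step(dec, bd$grads, st_d, lr, t); dec <- up$net; st_d <- up$state
      up <- adam_step(clf, bc$grads, st_c, lr, t); clf <- up$net; st_c <- up$state
    }
    z <- net_forward(enc, x)$A[[length(enc) + 1]]
    xhat <- net_forward(dec, z)$A[[length(dec) + 1]]
    p <- net_forward(clf, z)$A[[length(clf) + 1]]
    hist[ep] <- joint_ae_total_loss(
      recon_loss_grad(xhat, x, scale, nrow(x))$loss, bce_loss(p, y), w)
    if (!is.finite(hist[ep]))
      stop("training diverged (loss not finite) at epoch ", ep)
  }
  structure(list(kind = "joint_ae",
                 nets = list(encoder = enc, decoder = dec, clf = clf),
                 scale = scale,
                 hyper = list(w = w, epochs = epochs, batch_size = batch_size,
                              lr = lr, dropout = dropout, l2 = l2,
                              seed = seed),
                 loss_history = hist),
            class = "dl_model")
}

#' Train a joint variational autoencoder-classifier
#'
#' As [train_joint_ae()] but with a 32-unit sampling bottleneck: the encoder
#' trunk feeds linear `mu` and `logvar` heads, latents are reparameterized as
#' `z = mu + exp(logvar / 2) * eps`, and the total loss is
#' `recon + KL + c * BCE` ([vae_total_loss()]). Reconstruction is summed
#' over features (averaged over the batch), the conventional VAE scaling.
#' At prediction time the deterministic `mu` is used.
#'
#' @inheritParams train_joint_ae
#' @param clf_weight the scalar `c` on the classification loss (default 1).
#' @param epochs full-scale default 2250.
#' @return A `dl_model` with `kind = "joint_vae"`.
#' @export
train_joint_vae <- function(x, y, scale = c("M", "beta"),
                            encoder = c(128, 64), bottleneck = 32,
                            clf_hidden = 16, clf_weight = 1, epochs = 2250,
                            batch_size = 128, lr = 1e-4, dropout = 0,
                            l2 = 0, seed = 1L) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  y <- as01(y)
  if (anyNA(x)) stop("NaN/NA in features")
  set.seed(seed)
  N <- ncol(x)
  trunk <- mlp_new(c(N, encoder), rep("relu", length(encoder)))
  head_mu <- mlp_new(c(encoder[length(encoder)], bottleneck), "linear")
  head_lv <- mlp_new(c(encoder[length(encoder)], bottleneck), "linear")
  dec <- mlp_new(c(bottleneck, rev(encoder), N),
                 c(rep("relu", length(encoder)),
                   if (scale == "beta") "sigmoid" else "linear"))
  clf <- mlp_new(c(bottleneck, clf_hidden, 1),
                 c(rep("relu", length(clf_hidden)), "sigmoid"))
  st <- lapply(list(trunk, head_mu, head_lv, dec, clf), adam_init)
  t <- 0
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    for (bi in minibatches(nrow(x), batch_size)) {
      xb <- x[bi, , drop = FALSE]
      yb <- y[bi]
      m <- length(yb)
      ft <- net_forward(trunk, xb, train = TRUE)
      h <- ft$A[[length(trunk) + 1]]
      fmu <- net_forward(head_mu, h, train = TRUE)
      flv <- net_forward(head_lv, h, train = TRUE)
      mu <- fmu$A[[2]]
      lv <- pmin(pmax(flv$A[[2]], -10), 10)   # clamp for stability
      eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
      z <- mu + exp(lv / 2) * eps
      fd <- net_forward(dec, z, train = TRUE)
      xhat <- fd$A[[length(dec) + 1]]
      fc <- net_forward(clf, z, dropout, train = TRUE)
      p <- fc$A[[length(clf) + 1]]

      # recon summed over features, averaged over batch
      if (scale == "beta") {
        drec <- ncol(xb) * (xhat - xb) / length(xb)
        rec_is_dZ <- TRUE
      } else {
        drec <- 2 * (xhat - xb) / m
        rec_is_dZ <- FALSE
      }
      bd <- net_backward(dec, fd, drec, out_is_dZ = rec_is_dZ, l2 = l2)
      dZc <- clf_weight * (p - yb) / m
      bc <- net_backward(clf, fc, dZc, out_is_dZ = TRUE, l2 = l2)
      dz <- bd$dX + bc$dX
      dmu <- dz + mu / m                      # + dKL/dmu
      dlv <- dz * eps * exp(lv / 2) / 2 + (exp(lv) - 1) / (2 * m)
      bmu <- net_backward(head_mu, fmu, dmu, l2 = l2)
      blv <- net_backward(head_lv, flv, dlv, l2 = l2)
      bt <- net_backward(trunk, ft, bmu$dX + blv$dX, l2 = l2)
      t <- t + 1
      up <- adam_step(trunk, bt$grads, st[[1]], lr, t)
      trunk <- up$net; st[[1]] <- up$state
      up <- adam_step(head_mu, bmu$grads, st[[2]], lr, t)
      head_mu <- up$net; st[[2]] <- up$state
      up <- adam_step(head_lv, blv$grads, st[[3]], lr, t)
      head_lv <- up$net; st[[3]] <- up$state
      up <- adam_step(dec, bd$grads, st[[4]], lr, t)
      dec <- up$net; st[[4]] <- up$state
      up <- adam_step(clf, bc$grads, st[[5]], lr, t)
      clf <- up$net; st[[5]] <- up$state
    }
    h <- net_forward(trunk, x)$A[[length(trunk) + 1]]
    mu <- net_forward(head_mu, h)$A[[2]]
    lv <- pmin(pmax(net_forward(head_lv, h)$A[[2]], -10), 10)
    xhat <- net_forward(dec, mu)$A[[length(dec) + 1]]
    p <- net_forward(clf, mu)$A[[length(clf) + 1]]
    rec <- if (scale == "beta") {
      ph <- pmin(pmax(xhat, 1e-12), 1 - 1e-12)
      -mean(rowSums(x * log(ph) + (1 - x) * log(1 - ph)))
    } else mean(rowSums((xhat - x)^2))
    hist[ep] <- vae_total_loss(rec, max(mean(kl_gaussian(mu, lv)), 0),
                               bce_loss(p, y), clf_weight)
    if (!is.finite(hist[ep]))
      stop("training diverged (loss not finite) at epoch ", ep)
  }
  structure(list(kind = "joint_vae",
                 nets = list(trunk = trunk, head_mu = head_mu,
                             head_lv = head_lv, decoder = dec, clf = clf),
                 scale = scale,
                 hyper = list(clf_weight = clf_weight, epochs = epochs,
                              batch_size = batch_size, lr = lr,
                              dropout = dropout, l2 = l2, seed = seed),
                 loss_history = hist),
            class = "dl_model")
}

dl_latent <- function(model, x) {
  x <- as.matrix(x)
  if (model$kind == "joint_ae")
    net_forward(model$nets$encoder, x)$A[[length(model$nets$encoder) + 1]]
  else if (model$kind == "joint_vae") {
    h <- net_forward(model$nets$trunk, x)$A[[length(model$nets$trunk) + 1]]
    net_forward(model$nets$head_mu, h)$A[[2]]
  } else stop("model has no latent space")
}

#' Score samples with a trained deep model
#'
#' @param model a `dl_model`.
#' @param x samples-by-features matrix.
#' @return Per-sample sigmoid class scores in (0, 1).
#' @export
dl_score <- function(model, x) {
  x <- as.matrix(x)
  p <- if (model$kind == "simple_dnn")
    net_forward(model$nets$clf, x)$A[[length(model$nets$clf) + 1]]
  else net_forward(model$nets$clf, dl_latent(model, x))[["A"]][[
    length(model$nets$clf) + 1]]
  as.numeric(p)
}

#' Reconstruct inputs through a trained autoencoder model
#'
#' @param model a `dl_model` with a decoder (`joint_ae` or `joint_vae`).
#' @param x samples-by-features matrix on the model's scale.
#' @return Reconstructed matrix of the same shape.
#' @export
dl_reconstruct <- function(model, x) {
  if (is.null(model$nets$decoder)) stop("model has no decoder")
  z <- dl_latent(model, x)
  net_forward(model$nets$decoder, z)$A[[length(model$nets$decoder) + 1]]
}

#' Reconstruction quality of an autoencoder model
#'
#' Pearson correlation between the flattened input and its reconstruction.
#'
#' @param model a `dl_model` with a decoder.
#' @param features samples-by-features matrix.
#' @return Correlation in \[-1, 1\].
#' @export
reconstruction_quality <- function(model, features) {
  xhat <- dl_reconstruct(model, as.matrix(features))
  stats::cor(as.vector(as.matrix(features)), as.vector(xhat))
}

#' @export
print.dl_model <- function(x, ...) {
  cat("dl_model [", x$kind, "], final loss ",
      signif(x$loss_history[length(x$loss_history)], 4), " after ",
      length(x$loss_history), " epochs\n", sep = "")
  invisible(x)
}
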