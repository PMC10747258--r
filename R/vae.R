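# 1-D fully convolutional variational autoencoder, implemented directly on
# BLAS matrix products (im2col convolutions, manual backpropagation, Adam).
#
# Activation layout: a batch of B series with C channels of length L is a
# (B, C*L) matrix whose column j holds channel ((j-1) %% C) + 1 at position
# ((j-1) %/% C) + 1 (channel fastest). Convolution weights are stored as
# (C_in * K, C_out) matrices with rows ordered channel-fastest.

conv_geom <- function(c_in, l_in, k, stride, pad) {
  l_out <- (l_in + 2L * pad - k) %/% stride + 1L
  stopifnot((l_in + 2L * pad - k) %% stride == 0L)
  # gather index into the *unpadded* input: idx[t, j] with j = c + (kk-1)*c_in,
  # t = output position; 0 marks a padding tap
  jj <- seq_len(c_in * k)
  cj <- (jj - 1L) %% c_in + 1L
  kj <- (jj - 1L) %/% c_in + 1L
  tt <- seq_len(l_out)
  q <- outer(tt - 1L, kj, function(t, kk) t * stride + kk) - pad  # position
  idx <- q * 0L
  idx[] <- ifelse(q >= 1L & q <= l_in, cj[col(q)] + (q - 1L) * c_in, 0L)
  storage.mode(idx) <- "integer"
  list(c_in = c_in, l_in = l_in, k = k, stride = stride, pad = pad,
       l_out = l_out, idx = idx)
}

im2col <- function(x, g) cpp_im2col(x, g$idx)

col2im <- function(m, g, b) cpp_col2im(m, g$idx, b, g$c_in * g$l_in)

# channel-major (B, C*L) <-> row-major (B*L, C) conversions
to_rows <- function(x, c_ch) cpp_to_rows(x, c_ch)

to_chan <- function(y, c_ch, b) cpp_to_chan(y, c_ch, b)

conv_fwd <- function(x, w, bias, g) {
  b <- nrow(x)
  xc <- im2col(x, g)
  y <- xc %*% w
  y <- y + rep(bias, each = nrow(y))
  list(out = to_chan(y, ncol(w), b), xc = xc)
}

conv_bwd <- function(dout, xc, w, g, b) {
  dyc <- to_rows(dout, ncol(w))
  dw <- crossprod(xc, dyc)
  db <- colSums(dyc)
  dxp <- col2im(dyc %*% t(w), g, b)
  list(dx = dxp, dw = dw, db = db)
}

elu <- function(x) cpp_elu(x)

bn_fwd <- function(x, gamma, beta, c_ch, run, training, momentum = 0.1,
                   eps = 1e-5) {
  if (training) {
    st <- cpp_bn_stats(x, c_ch)
    mu <- st$mu
    v <- st$var
    run$mu <- (1 - momentum) * run$mu + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * v
  } else {
    mu <- run$mu
    v <- run$var
  }
  invstd <- 1 / sqrt(v + eps)
  ap <- cpp_bn_apply(x, mu, invstd, gamma, beta, c_ch)
  list(out = ap$y, xhat = ap$xhat, invstd = invstd, run = run)
}

bn_bwd <- function(dy, cache, gamma, c_ch) {
  cpp_bn_bwd(dy, cache$xhat, cache$invstd, gamma, c_ch)
}

#' Configuration of the convolutional variational autoencoder
#'
#' The encoder applies `length(channels)` convolution blocks (convolution,
#' batch normalization, ELU), each with the given kernel and stride, halving
#' the sequence length per block at the default stride 2; the defaults
#' compress a 1024-sample segment to a 32-position, 40-channel feature map.
#' Two dense heads then produce the latent mean and log-variance of dimension
#' `latent_dim`. The decoder mirrors the encoder with transposed
#' convolutions; its final layer is linear.
#'
#' @param input_len Input segment length in samples (default 1024).
#' @param channels Integer vector of encoder channel counts per block
#'   (default `c(8, 12, 16, 24, 40)`, a lean progression into the 40-channel bottleneck).
#' @param latent_dim Latent dimension d (default 32).
#' @param kernel,stride Convolution kernel size and stride (defaults 16, 2;
#'   `kernel - stride` must be even so symmetric padding preserves exact
#'   length halving).
#' @param epochs,batch,lr Training epochs (default 100), mini-batch size
#'   (default 64), Adam learning rate (default 1e-3).
#' @param seed Integer seed controlling initialization, shuffling and latent
#'   sampling.
#' @return A list of class `vae_config`.
#' @export
vae_config <- function(input_len = 1024L, channels = c(8L, 12L, 16L, 24L, 40L),
                       latent_dim = 32L, kernel = 16L, stride = 2L,
                       epochs = 100L, batch = 64L, lr = 1e-3, seed = 1L) {
  if ((kernel - stride) %% 2L != 0L) {
    abort("`kernel - stride` must be even for symmetric padding.")
  }
  if (input_len %% stride^length(channels) != 0L) {
    abort("`input_len` must be divisible by stride^(number of blocks).")
  }
  structure(
    list(input_len = as.integer(input_len), channels = as.integer(channels),
         latent_dim = as.integer(latent_dim), kernel = as.integer(kernel),
         stride = as.integer(stride), epochs = as.integer(epochs),
         batch = as.integer(batch), lr = lr, seed = as.integer(seed)),
    class = "vae_config"
  )
}

vae_init <- function(cfg) {
  k <- cfg$kernel
  pad <- (k - cfg$stride) %/% 2L
  chans <- c(1L, cfg$channels)
  n_blk <- length(cfg$channels)
  lens <- cfg$input_len / cfg$stride^(0:n_blk)
  enc <- vector("list", n_blk)
  geoms <- vector("list", n_blk)
  rnorm_mat <- function(nr, nc, sd) matrix(rnorm(nr * nc, sd = sd), nr, nc)
  for (i in seq_len(n_blk)) {
    fan_in <- chans[i] * k
    geoms[[i]] <- conv_geom(chans[i], as.integer(lens[i]), k, cfg$stride, pad)
    enc[[i]] <- list(
      w = rnorm_mat(fan_in, chans[i + 1L], sqrt(2 / fan_in)),
      b = numeric(chans[i + 1L]),
      gamma = rep(1, chans[i + 1L]), beta = numeric(chans[i + 1L]),
      run = list(mu = numeric(chans[i + 1L]), var = rep(1, chans[i + 1L]))
    )
  }
  flat <- as.integer(lens[n_blk + 1L]) * chans[n_blk + 1L]
  d <- cfg$latent_dim
  glorot <- function(nr, nc) rnorm_mat(nr, nc, sqrt(2 / (nr + nc)))
  dec <- vector("list", n_blk)
  for (i in seq_len(n_blk)) {
    # decoder block i upsamples with transposed conv: channels rev
    c_in_t <- chans[n_blk + 2L - i]
    c_out_t <- chans[n_blk + 1L - i]
    fan_in <- c_in_t * k
    dec[[i]] <- list(
      w = rnorm_mat(c_out_t * k, c_in_t, sqrt(2 / fan_in)),
      b = numeric(c_out_t),
      gamma = rep(1, c_out_t), beta = numeric(c_out_t),
      run = list(mu = numeric(c_out_t), var = rep(1, c_out_t)),
      geom = conv_geom(c_out_t, as.integer(lens[n_blk + 1L - i]),
                       k, cfg$stride, pad)
    )
  }
  list(
    enc = enc, geoms = geoms,
    w_mu = glorot(flat, d), b_mu = numeric(d),
    w_lv = glorot(flat, d), b_lv = numeric(d),
    w_dec = glorot(d, flat), b_dec = numeric(flat),
    dec = dec, flat = flat
  )
}

tconv_forward <- function(x, layer) {
  # layer$geom is the conv geometry of the reverse direction:
  # geom$c_in = this layer's output channels, geom$l_out = its input length
  g <- layer$geom
  b <- nrow(x)
  xr <- to_rows(x, ncol(layer$w))      # (b * l_out, c_in_t)
  m <- xr %*% t(layer$w)               # (b * l_out, c_out_t * k)
  outp <- col2im(m, g, b)
  list(out = cpp_add_channel_bias(outp, layer$b, g$c_in), xr = xr)
}

tconv_backward <- function(dout, xr, layer) {
  g <- layer$geom
  b <- nrow(dout)
  db <- cpp_channel_sums(dout, g$c_in)
  dm <- im2col(dout, g)                     # (b * l_out, c_out_t * k)
  dx <- to_chan(dm %*% layer$w, ncol(layer$w), b)
  dw <- crossprod(dm, xr)
  list(dx = dx, dw = dw, db = db)
}

vae_forward_pass <- function(params, cfg, x, training, eps_z = NULL) {
  b <- nrow(x)
  n_blk <- length(cfg$channels)
  cache <- list(enc = vector("list", n_blk), dec = vector("list", n_blk))
  h <- x
  for (i in seq_len(n_blk)) {
    ly <- params$enc[[i]]
    cv <- conv_fwd(h, ly$w, ly$b, params$geoms[[i]])
    bn <- bn_fwd(cv$out, ly$gamma, ly$beta, ncol(ly$w), ly$run, training)
    if (training) params$enc[[i]]$run <- bn$run
    act <- elu(bn$out)
    cache$enc[[i]] <- list(xc = cv$xc, bn = bn, pre = bn$out, act = act)
    h <- act
  }
  flat_h <- h
  mu <- flat_h %*% params$w_mu + rep(params$b_mu, each = b)
  lv <- flat_h %*% params$w_lv + rep(params$b_lv, each = b)
  lv <- pmin(pmax(lv, -10), 10)
  if (is.null(eps_z)) eps_z <- matrix(rnorm(b * cfg$latent_dim), b)
  z <- mu + exp(0.5 * lv) * eps_z
  hd_pre <- z %*% params$w_dec + rep(params$b_dec, each = b)
  hd <- elu(hd_pre)
  g <- hd
  for (i in seq_len(n_blk)) {
    ly <- params$dec[[i]]
    tc <- tconv_forward(g, ly)
    if (i < n_blk) {
      bn <- bn_fwd(tc$out, ly$gamma, ly$beta, ly$geom$c_in, ly$run, training)
      if (training) params$dec[[i]]$run <- bn$run
      act <- elu(bn$out)
      cache$dec[[i]] <- list(xr = tc$xr, bn = bn, pre = bn$out, act = act)
      g <- act
    } else {
      cache$dec[[i]] <- list(xr = tc$xr)
      g <- tc$out
    }
  }
  list(x_hat = g, mu = mu, lv = lv, z = z, eps_z = eps_z,
       flat_h = flat_h, hd_pre = hd_pre, hd = hd, cache = cache,
       params = params)
}

vae_loss_terms <- function(x, fw) {
  recon <- mean(rowMeans((x - fw$x_hat)^2))
  s2 <- exp(fw$lv)
  kld <- mean(0.5 * rowSums(fw$mu^2 + s2 - fw$lv - 1))
  list(recon = recon, kld = kld, loss = recon + kld)
}

vae_backward_pass <- function(params, cfg, x, fw) {
  b <- nrow(x)
  l_in <- cfg$input_len
  n_blk <- length(cfg$channels)
  grads <- list(enc = vector("list", n_blk), dec = vector("list", n_blk))

  dg <- 2 * (fw$x_hat - x) / (b * l_in)        # d recon / d x_hat
  for (i in rev(seq_len(n_blk))) {
    ly <- params$dec[[i]]
    cc <- cache_i <- fw$cache$dec[[i]]
    if (i < n_blk) {
      dg <- cpp_elu_grad_mul(dg, cc$pre, cc$act)
      bnb <- bn_bwd(dg, cc$bn, ly$gamma, ly$geom$c_in)
      tcb <- tconv_backward(bnb$dx, cc$xr, ly)
      grads$dec[[i]] <- list(dw = tcb$dw, db = tcb$db,
                             dgamma = bnb$dgamma, dbeta = bnb$dbeta)
    } else {
      tcb <- tconv_backward(dg, cc$xr, ly)
      grads$dec[[i]] <- list(dw = tcb$dw, db = tcb$db,
                             dgamma = NULL, dbeta = NULL)
    }
    dg <- tcb$dx
  }
  dhd <- cpp_elu_grad_mul(dg, fw$hd_pre, fw$hd)
  grads$w_dec <- crossprod(fw$z, dhd)
  grads$b_dec <- colSums(dhd)
  dz <- dhd %*% t(params$w_dec)

  s2 <- exp(fw$lv)
  dmu <- dz + fw$mu / b
  dlv <- dz * fw$eps_z * 0.5 * exp(0.5 * fw$lv) + 0.5 * (s2 - 1) / b
  dlv[fw$lv <= -10 | fw$lv >= 10] <- 0  # clamp boundary

  grads$w_mu <- crossprod(fw$flat_h, dmu)
  grads$b_mu <- colSums(dmu)
  grads$w_lv <- crossprod(fw$flat_h, dlv)
  grads$b_lv <- colSums(dlv)
  dh <- dmu %*% t(params$w_mu) + dlv %*% t(params$w_lv)

  for (i in rev(seq_len(n_blk))) {
    ly <- params$enc[[i]]
    cc <- fw$cache$enc[[i]]
    dh <- cpp_elu_grad_mul(dh, cc$pre, cc$act)
    bnb <- bn_bwd(dh, cc$bn, ly$gamma, ncol(ly$w))
    cvb <- conv_bwd(bnb$dx, cc$xc, ly$w, params$geoms[[i]], b)
    grads$enc[[i]] <- list(dw = cvb$dw, db = cvb$db,
                           dgamma = bnb$dgamma, dbeta = bnb$dbeta)
    dh <- cvb$dx
  }
  grads
}

adam_make <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(adam_flatten(params)), v = zero_like(adam_flatten(params)),
       t = 0L)
}

adam_flatten <- function(params) {
  out <- list()
  n_blk <- length(params$enc)
  for (i in seq_len(n_blk)) {
    ly <- params$enc[[i]]
    out[[paste0("enc", i, ".w")]] <- ly$w
    out[[paste0("enc", i, ".b")]] <- ly$b
    out[[paste0("enc", i, ".gamma")]] <- ly$gamma
    out[[paste0("enc", i, ".beta")]] <- ly$beta
  }
  out$w_mu <- params$w_mu; out$b_mu <- params$b_mu
  out$w_lv <- params$w_lv; out$b_lv <- params$b_lv
  out$w_dec <- params$w_dec; out$b_dec <- params$b_dec
  for (i in seq_len(n_blk)) {
    ly <- params$dec[[i]]
    out[[paste0("dec", i, ".w")]] <- ly$w
    out[[paste0("dec", i, ".b")]] <- ly$b
    if (!is.null(ly$gamma)) {
      out[[paste0("dec", i, ".gamma")]] <- ly$gamma
      out[[paste0("dec", i, ".beta")]] <- ly$beta
    }
  }
  out
}

grads_flatten <- function(grads, n_blk, last_blk) {
  out <- list()
  for (i in seq_len(n_blk)) {
    gy <- grads$enc[[i]]
    out[[paste0("enc", i, ".w")]] <- gy$dw
    out[[paste0("enc", i, ".b")]] <- gy$db
    out[[paste0("enc", i, ".gamma")]] <- gy$dgamma
    out[[paste0("enc", i, ".beta")]] <- gy$dbeta
  }
  out$w_mu <- grads$w_mu; out$b_mu <- grads$b_mu
  out$w_lv <- grads$w_lv; out$b_lv <- grads$b_lv
  out$w_dec <- grads$w_dec; out$b_dec <- grads$b_dec
  for (i in seq_len(n_blk)) {
    gy <- grads$dec[[i]]
    out[[paste0("dec", i, ".w")]] <- gy$dw
    out[[paste0("dec", i, ".b")]] <- gy$db
    if (!is.null(gy$dgamma)) {
      out[[paste0("dec", i, ".gamma")]] <- gy$dgamma
      out[[paste0("dec", i, ".beta")]] <- gy$dbeta
    }
  }
  out
}

adam_step <- function(params, grads, state, lr,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  n_blk <- length(params$enc)
  flat_g <- grads_flatten(grads, n_blk, n_blk)
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  flat_p <- adam_flatten(params)
  for (nm in names(flat_g)) {
    g <- flat_g[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    flat_p[[nm]] <- flat_p[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  # write back
  for (i in seq_len(n_blk)) {
    params$enc[[i]]$w <- flat_p[[paste0("enc", i, ".w")]]
    params$enc[[i]]$b <- flat_p[[paste0("enc", i, ".b")]]
    params$enc[[i]]$gamma <- flat_p[[paste0("enc", i, ".gamma")]]
    params$enc[[i]]$beta <- flat_p[[paste0("enc", i, ".beta")]]
  }
  params$w_mu <- flat_p$w_mu; params$b_mu <- flat_p$b_mu
  params$w_lv <- flat_p$w_lv; params$b_lv <- flat_p$b_lv
  params$w_dec <- flat_p$w_dec; params$b_dec <- flat_p$b_dec
  for (i in seq_len(n_blk)) {
    params$dec[[i]]$w <- flat_p[[paste0("dec", i, ".w")]]
    params$dec[[i]]$b <- flat_p[[paste0("dec", i, ".b")]]
    if (!is.null(params$dec[[i]]$gamma)) {
      params$dec[[i]]$gamma <- flat_p[[paste0("dec", i, ".gamma")]]
      params$dec[[i]]$beta <- flat_p[[paste0("dec", i, ".beta")]]
    }
  }
  list(params = params, state = state)
}

segments_matrix <- function(segments) {
  if (is.matrix(segments)) return(segments)
  if (is.data.frame(segments) && "x" %in% names(segments)) {
    return(do.call(rbind, segments$x))
  }
  abort("`segments` must be a matrix or a tibble with list-column `x`.")
}

# per-segment min-max normalization to [0, 1]; constant segments map to 0
normalize_segments <- function(m) {
  rng <- apply(m, 1, function(r) diff(range(r)))
  lo <- apply(m, 1, min)
  rng[rng == 0] <- 1
  (m - lo) / rng
}

#' Train the convolutional variational autoencoder on spectrum segments
#'
#' Minimizes the sum of the per-sample mean squared reconstruction error and
#' the Kullback-Leibler divergence of the latent Gaussian from the standard
#' normal,
#' \deqn{Loss = \frac1L\sum_l (x_l-\hat x_l)^2 +
#'   \frac12\sum_i (\mu_i^2 + \sigma_i^2 - \log\sigma_i^2 - 1),}
#' with Adam on shuffled mini-batches. Segments are min-max normalized to
#' \[0, 1\] individually before entering the network, so the representation
#' reflects waveform shape rather than absolute amplitude.
#'
#' @param segments A [segment_for_sqa()] tibble (list-column `x`) or a
#'   numeric matrix with one 1024-sample segment per row.
#' @param cfg A [vae_config()].
#' @return An object of class `dus_vae`: trained parameters, the config and
#'   a per-epoch loss log.
#' @export
train_vae <- function(segments, cfg = vae_config()) {
  m <- segments_matrix(segments)
  if (nrow(m) == 0L) abort("no segments to train on.")
  if (ncol(m) != cfg$input_len) {
    abort(sprintf("segments have %d samples; config expects %d.",
                  ncol(m), cfg$input_len))
  }
  x_all <- normalize_segments(m)
  n <- nrow(x_all)
  log_rows <- vector("list", cfg$epochs)

  withr::with_seed(cfg$seed, {
    params <- vae_init(cfg)
    state <- adam_make(params)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      tot <- c(loss = 0, recon = 0, kld = 0)
      nb <- 0L
      for (b0 in seq(1L, n, by = cfg$batch)) {
        idx <- ord[b0:min(b0 + cfg$batch - 1L, n)]
        if (length(idx) < 2L) next  # batch-norm needs >= 2 samples
        xb <- x_all[idx, , drop = FALSE]
        fw <- vae_forward_pass(params, cfg, xb, training = TRUE)
        params <- fw$params  # running BN stats updated
        lt <- vae_loss_terms(xb, fw)
        gr <- vae_backward_pass(params, cfg, xb, fw)
        upd <- adam_step(params, gr, state, cfg$lr)
        params <- upd$params
        state <- upd$state
        tot <- tot + c(lt$loss, lt$recon, lt$kld)
        nb <- nb + 1L
      }
      log_rows[[ep]] <- tibble(epoch = ep, loss = tot[[1]] / nb,
                               recon = tot[[2]] / nb, kld = tot[[3]] / nb)
    }
  })

  structure(
    list(params = params, cfg = cfg, log = dplyr::bind_rows(log_rows)),
    class = "dus_vae"
  )
}

#' @export
print.dus_vae <- function(x, ...) {
  cat(sprintf(
    "<dus_vae> input %d, latent %d, blocks %s; trained %d epochs (final loss %.4g)\n",
    x$cfg$input_len, x$cfg$latent_dim,
    paste(x$cfg$channels, collapse = "-"),
    nrow(x$log), utils::tail(x$log$loss, 1)
  ))
  invisible(x)
}

#' Encode segments to latent means and variances
#'
#' Deterministic inference pass (batch normalization uses the running
#' statistics frozen at training time).
#'
#' @param model A trained [train_vae()] model.
#' @param segments Segments as in [train_vae()].
#' @return A list with matrices `mu` and `sigma2` (rows = segments, columns =
#'   latent dimensions).
#' @export
vae_encode <- function(model, segments) {
  m <- segments_matrix(segments)
  x <- normalize_segments(m)
  cfg <- model$cfg
  fw <- vae_forward_pass(model$params, cfg, x, training = FALSE,
                         eps_z = matrix(0, nrow(x), cfg$latent_dim))
  list(mu = fw$mu, sigma2 = exp(fw$lv))
}

#' Full forward pass for one or more segments
#'
#' @inheritParams vae_encode
#' @param sample If `TRUE`, the latent vector is drawn as
#'   `mu + sqrt(sigma2) * eps` with standard-normal `eps`; if `FALSE`, the
#'   mean is used (`z = mu`).
#' @param seed Optional seed for the latent draw.
#' @return A list with `mu_z`, `sigma2_z`, `z`, `x_hat`, and scalar `loss`,
#'   `recon`, `kld` evaluated on the (normalized) input.
#' @export
vae_forward <- function(model, segments, sample = FALSE, seed = NULL) {
  m <- segments_matrix(segments)
  if (ncol(m) != model$cfg$input_len) abort("wrong input length.")
  x <- normalize_segments(m)
  cfg <- model$cfg
  eps_z <- if (sample) {
    if (!is.null(seed)) {
      withr::with_seed(seed, matrix(rnorm(nrow(x) * cfg$latent_dim), nrow(x)))
    } else {
      matrix(rnorm(nrow(x) * cfg$latent_dim), nrow(x))
    }
  } else {
    matrix(0, nrow(x), cfg$latent_dim)
  }
  fw <- vae_forward_pass(model$params, cfg, x, training = FALSE, eps_z = eps_z)
  lt <- vae_loss_terms(x, fw)
  list(mu_z = fw$mu, sigma2_z = exp(fw$lv), z = fw$z, x_hat = fw$x_hat,
       loss = lt$loss, recon = lt$recon, kld = lt$kld)
}

#' Closed-form latent and reconstruction loss terms
#'
#' `vae_kld()` is the Kullback-Leibler divergence of `N(mu, diag(sigma2))`
#' from the standard normal, `0.5 * sum(mu^2 + sigma2 - log(sigma2) - 1)`;
#' it is zero iff `mu = 0` and `sigma2 = 1`, and nonnegative term by term.
#' `vae_recon_error()` is the length-averaged squared error between a segment
#' and its reconstruction.
#'
#' @param mu,sigma2 Latent mean and variance vectors.
#' @param x,x_hat Input and reconstructed segments.
#' @name vae_loss
#' @examples
#' vae_kld(rep(0, 32), rep(1, 32)) # 0
#' vae_kld(1, 1)                   # 0.5
#' @export
vae_kld <- function(mu, sigma2) {
  if (any(sigma2 <= 0)) abort("`sigma2` must be positive.")
  0.5 * sum(mu^2 + sigma2 - log(sigma2) - 1)
}

#' @rdname vae_loss
#' @export
vae_recon_error <- function(x, x_hat) {
  mean((x - x_hat)^2)
}
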