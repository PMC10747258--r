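#' Tidiers for fitted model objects
#'
#' `tidy()` on a trained VAE returns the per-epoch loss log (`epoch`, `loss`,
#' `recon`, `kld`); `glance()` a one-row training summary. `tidy()` on a
#' self-organizing map returns one row per neuron with grid coordinates and a
#' `weight` list-column; `glance()` its settings. `tidy()` on a fitted
#' quality model returns the training-corpus score table; `glance()` the
#' frozen calibration.
#'
#' @param x A `dus_vae`, `dus_som` or `sqa_model` object.
#' @param ... Unused.
#' @name fetalhr_tidiers
NULL

#' @rdname fetalhr_tidiers
#' @export
tidy.dus_vae <- function(x, ...) x$log

#' @rdname fetalhr_tidiers
#' @export
glance.dus_vae <- function(x, ...) {
  final <- x$log[nrow(x$log), ]
  tibble(
    epochs = nrow(x$log),
    final_loss = final$loss,
    final_recon = final$recon,
    final_kld = final$kld,
    latent_dim = x$cfg$latent_dim,
    input_len = x$cfg$input_len
  )
}

#' @rdname fetalhr_tidiers
#' @export
tidy.dus_som <- function(x, ...) {
  tibble(
    neuron = seq_len(nrow(x$weights)),
    row = x$gx,
    col = x$gy,
    weight = lapply(seq_len(nrow(x$weights)), function(i) x$weights[i, ])
  )
}

#' @rdname fetalhr_tidiers
#' @export
glance.dus_som <- function(x, ...) {
  tibble(rows = x$grid[1], cols = x$grid[2], d = x$d,
         iterations = x$iterations, lr = x$lr, sigma = x$sigma)
}

#' @rdname fetalhr_tidiers
#' @export
tidy.sqa_model <- function(x, ...) x$train_scores

#' @rdname fetalhr_tidiers
#' @export
glance.sqa_model <- function(x, ...) {
  tibble(
    qe_min = x$stats$qe_min,
    qe_max = x$stats$qe_max,
    th = x$stats$th,
    th_quantile = x$th_quantile,
    n_train = nrow(x$train_scores),
    vae_final_loss = utils::tail(x$vae$log$loss, 1)
  )
}
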