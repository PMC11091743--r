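# Minimal dense-network machinery for the ZINB autoencoder.
# Parameters live in a flat named list of matrices/vectors so the optimizer
# and gradient accumulation can treat them uniformly.

glorot <- function(fan_in, fan_out) {
  l <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -l, l), fan_in, fan_out)
}

relu <- function(x) (x > 0) * x

#' Create a ZINB autoencoder
#'
#' Symmetric fully connected architecture: input -> hidden encoder layers
#' (ReLU) -> linear bottleneck z -> hidden decoder layers (ReLU) -> three
#' parameter heads (dropout probability pi via logistic, mean mu via
#' size-factor-scaled exponential, dispersion theta via exponential).
#'
#' @param n_genes input width.
#' @param hidden encoder hidden widths (decoder mirrors them); default
#'   \code{c(256, 128)}.
#' @param bottleneck latent dimension d (default 32).
#' @param seed seed for Glorot-uniform weight initialization.
#' @return a list of class \code{zae} with \code{params}, \code{hidden},
#'   \code{bottleneck}, \code{n_genes}.
#' @export
zae_new <- function(n_genes, hidden = c(256, 128), bottleneck = 32, seed = 0) {
  set.seed(seed)
  widths_enc <- c(n_genes, hidden, bottleneck)
  widths_dec <- c(bottleneck, rev(hidden))
  params <- list()
  for (i in seq_len(length(widths_enc) - 1)) {
    params[[paste0("enc_W", i)]] <- glorot(widths_enc[i], widths_enc[i + 1])
    params[[paste0("enc_b", i)]] <- numeric(widths_enc[i + 1])
  }
  for (i in seq_len(length(widths_dec) - 1)) {
    params[[paste0("dec_W", i)]] <- glorot(widths_dec[i], widths_dec[i + 1])
    params[[paste0("dec_b", i)]] <- numeric(widths_dec[i + 1])
  }
  last <- widths_dec[length(widths_dec)]
  for (h in c("pi", "mu", "theta")) {
    params[[paste0("head_W_", h)]] <- glorot(last, n_genes)
    params[[paste0("head_b_", h)]] <- numeric(n_genes)
  }
  structure(list(params = params, hidden = hidden, bottleneck = bottleneck,
                 n_genes = n_genes),
            class = "zae")
}

affine <- function(x, W, b) {
  m <- x %*% W
  m + rep(b, each = nrow(m))
}

#' Encode cells into the latent space
#'
#' @param model a \code{\link{zae_new}} model.
#' @param x cells x genes standardized input.
#' @param corrupt_sd standard deviation of additive zero-mean Gaussian noise
#'   applied to the input before encoding (denoising corruption; use 0 for
#'   clean/eval encoding). Draws from the current RNG stream.
#' @return list with \code{z} (cells x d) and \code{cache} for backprop.
#' @export
zae_encode <- function(model, x, corrupt_sd = 0) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_genes)
    stop("input width ", ncol(x), " != trained width ", model$n_genes)
  if (corrupt_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), 0, corrupt_sd), nrow(x))
  p <- model$params
  n_enc <- length(model$hidden) + 1
  acts <- vector("list", n_enc + 1)
  acts[[1]] <- x
  h <- x
  for (i in seq_len(n_enc)) {
    pre <- affine(h, p[[paste0("enc_W", i)]], p[[paste0("enc_b", i)]])
    h <- if (i < n_enc) relu(pre) else pre  # linear bottleneck
    acts[[i + 1]] <- h
  }
  list(z = h, cache = list(acts = acts, n_enc = n_enc))
}

#' Decode latent points into ZINB parameters
#'
#' The mu head is multiplied by each cell's size factor so the likelihood is
#' evaluated on the raw count scale; pi and theta do not depend on the size
#' factor. Outputs are clipped to pi in (1e-6, 1-1e-6), mu and theta in
#' [1e-5, 1e6].
#'
#' @param model a \code{zae} model.
#' @param z cells x d latent matrix.
#' @param size_factors per-cell positive size factors.
#' @return list with \code{pi}, \code{mu}, \code{theta} (cells x genes) and
#'   \code{cache}.
#' @export
zae_decode <- function(model, z, size_factors) {
  if (any(size_factors <= 0)) stop("size factors must be positive")
  p <- model$params
  n_dec <- length(model$hidden)
  acts <- vector("list", n_dec + 1)
  acts[[1]] <- z
  h <- z
  for (i in seq_len(n_dec)) {
    h <- relu(affine(h, p[[paste0("dec_W", i)]], p[[paste0("dec_b", i)]]))
    acts[[i + 1]] <- h
  }
  pre_pi <- affine(h, p$head_W_pi, p$head_b_pi)
  pre_mu <- affine(h, p$head_W_mu, p$head_b_mu)
  pre_th <- affine(h, p$head_W_theta, p$head_b_theta)

  pi_ <- pmin(pmax(1 / (1 + exp(-pre_pi)), zinb_clip_pi[1]), zinb_clip_pi[2])
  mu_raw <- size_factors * exp(pmin(pre_mu, 30))
  mu_ <- pmin(pmax(mu_raw, zinb_clip_val[1]), zinb_clip_val[2])
  th_raw <- exp(pmin(pre_th, 30))
  th_ <- pmin(pmax(th_raw, zinb_clip_val[1]), zinb_clip_val[2])

  # derivative of output w.r.t. pre-activation (0 where clipped/saturated)
  dmu <- mu_ * (mu_raw == mu_ & pre_mu < 30)
  dth <- th_ * (th_raw == th_ & pre_th < 30)
  dpi <- pi_ * (1 - pi_)
  list(pi = pi_, mu = mu_, theta = th_,
       cache = list(acts = acts, n_dec = n_dec,
                    dpi_dpre = dpi, dmu_dpre = dmu, dth_dpre = dth))
}

# Backprop through the decoder given dL/d(pi, mu, theta).
# Returns gradients for decoder/head params and dL/dz.
zae_decoder_grad <- function(model, cache, dpi, dmu, dtheta) {
  p <- model$params
  g <- list()
  d_pre_pi <- dpi * cache$dpi_dpre
  d_pre_mu <- dmu * cache$dmu_dpre
  d_pre_th <- dtheta * cache$dth_dpre
  h <- cache$acts[[cache$n_dec + 1]]
  g$head_W_pi <- crossprod(h, d_pre_pi);  g$head_b_pi <- colSums(d_pre_pi)
  g$head_W_mu <- crossprod(h, d_pre_mu);  g$head_b_mu <- colSums(d_pre_mu)
  g$head_W_theta <- crossprod(h, d_pre_th)
  g$head_b_theta <- colSums(d_pre_th)
  dh <- tcrossprod(d_pre_pi, p$head_W_pi) +
    tcrossprod(d_pre_mu, p$head_W_mu) +
    tcrossprod(d_pre_th, p$head_W_theta)
  for (i in rev(seq_len(cache$n_dec))) {
    dpre <- dh * (cache$acts[[i + 1]] > 0)  # ReLU mask
    g[[paste0("dec_W", i)]] <- crossprod(cache$acts[[i]], dpre)
    g[[paste0("dec_b", i)]] <- colSums(dpre)
    dh <- tcrossprod(dpre, p[[paste0("dec_W", i)]])
  }
  list(grads = g, dz = dh)
}

# Backprop through the encoder given dL/dz. Returns encoder param gradients.
zae_encoder_grad <- function(model, cache, dz) {
  p <- model$params
  g <- list()
  dh <- dz
  for (i in rev(seq_len(cache$n_enc))) {
    dpre <- if (i < cache$n_enc) dh * (cache$acts[[i + 1]] > 0) else dh
    g[[paste0("enc_W", i)]] <- crossprod(cache$acts[[i]], dpre)
    g[[paste0("enc_b", i)]] <- colSums(dpre)
    dh <- tcrossprod(dpre, p[[paste0("enc_W", i)]])
  }
  g
}

# elementwise accumulation of two flat grad lists (b may be NULL / partial)
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

grad_scale <- function(g, s) {
  if (s == 1) return(g)
  lapply(g, function(x) x * s)
}

# rescale the whole gradient list so its global L2 norm is <= max_norm
clip_grads <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(grads)
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (nrm > max_norm) grads <- grad_scale(grads, max_norm / nrm)
  grads
}

# ---- AdaDelta -------------------------------------------------------------

#' AdaDelta optimizer state
#'
#' @param params flat named list of parameter arrays to optimize.
#' @param rho decay of the squared-gradient / squared-update accumulators.
#' @param eps numerical stabilizer.
#' @return optimizer state list.
#' @export
adadelta_new <- function(params, rho = 0.9, eps = 1e-6) {
  zeros <- lapply(params, function(x) x * 0)
  list(Eg = zeros, Ex = zeros, rho = rho, eps = eps)
}

#' One AdaDelta update
#'
#' @param opt state from \code{\link{adadelta_new}}.
#' @param params current parameters (flat named list).
#' @param grads gradients (same names; missing entries are skipped).
#' @param lr learning-rate multiplier (default 1.0).
#' @return list with updated \code{params} and \code{opt}.
#' @export
adadelta_step <- function(opt, params, grads, lr = 1.0) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$Eg[[nm]] <- opt$rho * opt$Eg[[nm]] + (1 - opt$rho) * g^2
    dx <- -sqrt(opt$Ex[[nm]] + opt$eps) / sqrt(opt$Eg[[nm]] + opt$eps) * g
    opt$Ex[[nm]] <- opt$rho * opt$Ex[[nm]] + (1 - opt$rho) * dx^2
    params[[nm]] <- params[[nm]] + lr * dx
  }
  list(params = params, opt = opt)
}

#' Save / load a model checkpoint
#'
#' @param state any model state list (e.g. the result of \code{zc_pretrain}
#'   or \code{zc_fit}).
#' @param path checkpoint file path.
#' @return \code{zae_save} the path invisibly; \code{zae_load} the state.
#' @export
zae_save <- function(state, path) { saveRDS(state, path); invisible(path) }

#' @rdname zae_save
#' @export
zae_load <- function(path) readRDS(path)
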