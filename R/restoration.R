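#' Gaussian point-spread function kernel
#'
#' Builds the isotropic 2-D Gaussian PSF
#' `psf(m, n) = exp(-(m^2 + n^2) / (2 sigma_b^2))` on the integer grid
#' `[-half_width, half_width]^2`, renormalised to unit sum after truncation.
#'
#' @param sigma_b Gaussian width in pixels (> 0).
#' @param half_width kernel half width; defaults to `ceiling(3 * sigma_b)`.
#' @return a `psf_kernel`: list with `sigma_b`, `kernel`, `half_width`.
#' @examples
#' k <- make_psf(2)
#' sum(k$kernel)  # 1
#' @export
make_psf <- function(sigma_b, half_width = ceiling(3 * sigma_b)) {
  if (!is.numeric(sigma_b) || sigma_b <= 0) stop("sigma_b must be > 0")
  m <- -half_width:half_width
  k <- exp(-outer(m^2, m^2, "+") / (2 * sigma_b^2))
  structure(list(sigma_b = sigma_b, kernel = k / sum(k),
                 half_width = as.integer(half_width)),
            class = "psf_kernel")
}

#' TV-l1 deblurring configuration
#'
#' @param lambda balancing parameter between the l1 fidelity and the
#'   anisotropic total-variation penalty (default 0.01).
#' @param outer_iters outer half-quadratic iterations.
#' @param beta_init,beta_growth,beta_max geometric schedule of the quadratic
#'   coupling weight.
#' @export
tv_deblur_config <- function(lambda = 0.01, outer_iters = 8,
                             beta_init = 1, beta_growth = 2, beta_max = 256) {
  stopifnot(lambda > 0, outer_iters >= 1, beta_init > 0, beta_growth > 1)
  structure(list(lambda = lambda, outer_iters = as.integer(outer_iters),
                 beta_init = beta_init, beta_growth = beta_growth,
                 beta_max = beta_max),
            class = "tv_deblur_config")
}

#' MMWF configuration
#'
#' @param window odd square-window side length (pixels), >= 3.
#' @param gamma_sq_rule how the noise variance gamma^2 is set:
#'   `"global_mean_of_local_variances"` (default, per slice) or `"fixed"`.
#' @param gamma_sq_fixed value used when `gamma_sq_rule = "fixed"`.
#' @export
mmwf_config <- function(window = 5,
                        gamma_sq_rule = c("global_mean_of_local_variances", "fixed"),
                        gamma_sq_fixed = 0) {
  window <- as.integer(window)
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  stopifnot(gamma_sq_fixed >= 0)
  structure(list(window = window, gamma_sq_rule = match.arg(gamma_sq_rule),
                 gamma_sq_fixed = gamma_sq_fixed),
            class = "mmwf_config")
}

#' Deblurring objective: l1 fidelity plus anisotropic TV penalty
#'
#' Evaluates `||psf (*) f - g||_1 + lambda * ||grad f||_1` with slice-wise
#' 2-D convolution under symmetric boundary padding and forward-difference
#' gradients (zero difference at the trailing boundary).
#'
#' @param f_slice,g_slice 2-D matrices of equal shape.
#' @param psf a [make_psf()] kernel.
#' @param lambda penalty weight.
#' @return non-negative scalar.
#' @export
tv_objective <- function(f_slice, g_slice, psf, lambda) {
  if (!all(dim(f_slice) == dim(g_slice))) stop("f and g must have the same shape")
  kf <- cpp_conv2d_sym(f_slice, psf$kernel)
  gx <- rbind(diff(f_slice), 0)
  gy <- cbind(t(diff(t(f_slice))), 0)
  sum(abs(kf - g_slice)) + lambda * (sum(abs(gx)) + sum(abs(gy)))
}

# Embed a centred convolution kernel into an nr x nc optical transfer
# function (kernel centre wrapped to element [1, 1]).
psf2otf <- function(kernel, nr, nc) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  pad <- matrix(0, nr, nc)
  pad[seq_len(kr), seq_len(kc)] <- kernel
  pad <- pad[((seq_len(nr) - 1 + (kr %/% 2)) %% nr) + 1,
             ((seq_len(nc) - 1 + (kc %/% 2)) %% nc) + 1]
  fft(pad)
}

# Blend the border of g towards its blurred version so that the periodic
# extension used by the frequency-domain solver has no wrap-around jumps.
edge_taper <- function(g, psf) {
  h <- max(psf$half_width, 1)
  nr <- nrow(g); nc <- ncol(g)
  ramp <- function(n) pmin(1, pmin(seq_len(n) - 1, n - seq_len(n)) / h)
  w <- outer(ramp(nr), ramp(nc), pmin)
  gb <- cpp_conv2d_sym(g, psf$kernel)
  w * g + (1 - w) * gb
}

soft_shrink <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fast TV-l1 deblurring of one slice by half-quadratic splitting
#'
#' Minimises the [tv_objective()] by introducing auxiliary variables for the
#' fidelity residual and the gradient, alternating closed-form shrinkage
#' steps with a frequency-domain quadratic solve (periodic extension with
#' edge tapering), while the quadratic coupling weight beta follows a
#' geometric schedule. The returned slice is the best iterate under the
#' objective (evaluated against the original `g_slice`), so the objective at
#' the output never exceeds the objective at the input; the per-iteration
#' trace is attached as attribute `"objective_trace"`.
#'
#' @param g_slice observed (blurred) non-negative 2-D slice.
#' @param psf a [make_psf()] kernel (unit sum).
#' @param cfg a [tv_deblur_config()].
#' @return restored non-negative slice of the same shape.
#' @export
tv_l1_deblur <- function(g_slice, psf, cfg = tv_deblur_config()) {
  if (!all(is.finite(g_slice))) stop("g contains non-finite values")
  nr <- nrow(g_slice); nc <- ncol(g_slice)
  g <- edge_taper(g_slice, psf)

  K <- psf2otf(psf$kernel, nr, nc)
  Dx <- psf2otf(matrix(c(1, -1), 2, 1), nr, nc)   # forward diff along rows
  Dy <- psf2otf(matrix(c(1, -1), 1, 2), nr, nc)
  denom <- Mod(K)^2 + Mod(Dx)^2 + Mod(Dy)^2
  denom[denom < 1e-12] <- 1e-12

  conv_per <- function(x, H) Re(fft(fft(x) * H, inverse = TRUE)) / (nr * nc)

  f <- g_slice
  best_f <- g_slice
  best_obj <- tv_objective(g_slice, g_slice, psf, cfg$lambda)
  trace <- best_obj
  beta <- cfg$beta_init
  for (it in seq_len(cfg$outer_iters)) {
    kf <- conv_per(f, K)
    u <- soft_shrink(kf - g, 1 / beta)
    dx <- soft_shrink(conv_per(f, Dx), cfg$lambda / beta)
    dy <- soft_shrink(conv_per(f, Dy), cfg$lambda / beta)
    rhs <- Conj(K) * fft(g + u) + Conj(Dx) * fft(dx) + Conj(Dy) * fft(dy)
    f <- Re(fft(rhs / denom, inverse = TRUE)) / (nr * nc)
    f[f < 0] <- 0
    obj <- tv_objective(f, g_slice, psf, cfg$lambda)
    if (obj < best_obj) { best_obj <- obj; best_f <- f }
    trace <- c(trace, best_obj)
    beta <- min(beta * cfg$beta_growth, cfg$beta_max)
  }
  structure(best_f, objective_trace = trace)
}

#' Local window statistics for the MMWF
#'
#' @param window_values numeric vector of pixel values in the neighbourhood.
#' @return list with `mu_bar` (median; even counts average the two central
#'   order statistics) and `sigma_n_sq` (population variance).
#' @examples
#' mmwf_window_stats(c(1, 2, 3, 4))$mu_bar  # 2.5
#' @export
mmwf_window_stats <- function(window_values) {
  if (!length(window_values)) stop("window must be nonempty")
  list(mu_bar = median(window_values),
       sigma_n_sq = mean(window_values^2) - mean(window_values)^2)
}

#' Median modified Wiener filtering of one slice
#'
#' For every pixel, `out = mu_bar + max(0, s2 - gamma2) / s2 * (x - mu_bar)`
#' where `mu_bar` and `s2` are the local median and population variance of
#' the square window (symmetric padding) and `gamma2` is the noise variance
#' - by default the mean of all local variances of the slice, computed in a
#' first pass. Pixels with zero local variance return the local median, and
#' a negative Wiener gain is clamped to zero.
#'
#' @param g_slice 2-D matrix.
#' @param cfg a [mmwf_config()].
#' @return filtered slice of the same shape.
#' @export
mmwf_denoise <- function(g_slice, cfg = mmwf_config()) {
  st <- cpp_local_median_var(g_slice, cfg$window)
  med <- st$median; v <- st$var
  gamma2 <- if (cfg$gamma_sq_rule == "fixed") cfg$gamma_sq_fixed else mean(v)
  gain <- ifelse(v > 0, pmax(v - gamma2, 0) / v, 0)
  out <- med + gain * (g_slice - med)
  matrix(out, nrow(g_slice), ncol(g_slice))
}

#' Restoration configuration for a pipeline condition
#'
#' @param method `"none"`, `"deblur"` or `"denoise"`.
#' @param sigma_b PSF width used when deblurring.
#' @param tv a [tv_deblur_config()].
#' @param mmwf a [mmwf_config()].
#' @param name condition label; defaults to a descriptive string.
#' @export
restoration_config <- function(method = c("none", "deblur", "denoise"),
                               sigma_b = 2, tv = tv_deblur_config(),
                               mmwf = mmwf_config(), name = NULL) {
  method <- match.arg(method)
  name <- name %||% switch(method,
    none = "raw",
    deblur = sprintf("deblur_sb%g", sigma_b),
    denoise = sprintf("denoise_w%d", mmwf$window))
  structure(list(method = method, sigma_b = sigma_b, tv = tv, mmwf = mmwf,
                 name = name),
            class = "restoration_config")
}

#' Restore a volume slice-by-slice
#'
#' Applies the configured restoration independently to every axial slice
#' with the same parameters; `method = "none"` returns the input unchanged.
#'
#' @param vol 3-D volume.
#' @param cfg a [restoration_config()].
#' @return restored volume of identical shape.
#' @export
restore_volume <- function(vol, cfg) {
  stop_if_not_volume(vol)
  if (!inherits(cfg, "restoration_config")) stop("cfg must be a restoration_config")
  if (cfg$method == "none") return(vol)
  out <- vol
  if (cfg$method == "deblur") {
    psf <- make_psf(cfg$sigma_b)
    for (z in seq_len(dim(vol)[3]))
      out[, , z] <- tv_l1_deblur(vol[, , z], psf, cfg$tv)
  } else if (cfg$method == "denoise") {
    for (z in seq_len(dim(vol)[3]))
      out[, , z] <- mmwf_denoise(vol[, , z], cfg$mmwf)
  } else stop(sprintf("unknown restoration method '%s'", cfg$method))
  attributes(out) <- attributes(vol)
  out
}
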