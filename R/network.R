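# Light-weight depth-2 U-Net family.
#
# Encoder levels carry n and 2n channels, the bottleneck 4n. Downsampling is
# 2x2 max pooling (stride 2), upsampling a 2x2 transposed convolution
# (stride 2). Each level applies size-preserving 3x3 convolutions, each
# followed by channel-wise (batch) normalization and a ReLU; a final 1x1
# projection maps back to one channel. The lower skip connection
# (concatenation) is always present; the top-level skip and the global
# residual addition of the input are switchable, giving the U-Net^{r,t},
# U-Net^{-r,t}, U-Net^{r,-t} and U-Net^{-r,-t} variants. The bottleneck uses
# a single convolution so that the theoretical influence footprint stays
# within the 41x41 padding budget (two bottleneck convolutions would reach
# 44 px; see measure_receptive_field).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Network architecture specification
#'
#' @param n filters in the uppermost level (channels double per level:
#'   n, 2n, 4n).
#' @param residual global residual addition of the input to the output
#'   (`r` vs `-r`).
#' @param top_skip top-level skip concatenation (`t` vs `-t`).
#' @param enc_convs,dec_convs 3x3 convolutions per encoder/decoder level.
#' @param bottleneck_convs 3x3 convolutions in the bottleneck.
#' @param seed weight-initialization seed (He fan-in normal).
#' @return object of class `"net_spec"`.
#' @export
net_spec <- function(n = 4, residual = FALSE, top_skip = FALSE,
                     enc_convs = 2, dec_convs = 2, bottleneck_convs = 1,
                     seed = 1) {
  if (!is_count(n) || n < 1) stopf("n must be a positive integer")
  structure(list(n = as.integer(n), residual = isTRUE(residual),
                 top_skip = isTRUE(top_skip), depth = 2L,
                 enc_convs = as.integer(enc_convs),
                 dec_convs = as.integer(dec_convs),
                 bottleneck_convs = as.integer(bottleneck_convs),
                 seed = seed),
            class = "net_spec")
}

#' @export
format.net_spec <- function(x, ...) {
  sprintf("U-Net^{%s,%s} (n=%d, depth=%d)",
          if (x$residual) "r" else "¬r",
          if (x$top_skip) "t" else "¬t", x$n, x$depth)
}

#' @export
print.net_spec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

init_conv <- function(kh, kw, cin, cout, bn = TRUE) {
  w <- array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
             dim = c(kh, kw, cin, cout))
  u <- list(w = w, b = numeric(cout))
  if (bn) {
    u$gamma <- rep(1, cout)
    u$beta <- numeric(cout)
  }
  u
}

init_buffers <- function(cout) list(rm = numeric(cout), rv = rep(1, cout))

#' Build a U-Net model from a specification
#'
#' @param spec a [net_spec()].
#' @param in_channels input (= output) channel count; 1 for normal use, >1
#'   only via [export_pseudobatch()].
#' @return object of class `"bsn_net"` holding `spec`, `params` (weights)
#'   and `buffers` (normalization running statistics).
#' @export
build_unet <- function(spec = net_spec(), in_channels = 1) {
  n <- spec$n
  stack_sizes <- function(cin, cout, k) {
    cins <- c(cin, rep(cout, k - 1))
    lapply(seq_len(k), function(i) c(cins[i], cout))
  }
  with_seed(derive_seed(spec$seed, 101L), {
    mk_stack <- function(sizes) lapply(sizes, function(s)
      init_conv(3, 3, s[1], s[2]))
    params <- list(
      enc1 = mk_stack(stack_sizes(in_channels, n, spec$enc_convs)),
      enc2 = mk_stack(stack_sizes(n, 2 * n, spec$enc_convs)),
      bott = mk_stack(stack_sizes(2 * n, 4 * n, spec$bottleneck_convs)),
      up1  = init_conv(2, 2, 4 * n, 2 * n, bn = FALSE),
      dec1 = mk_stack(stack_sizes(4 * n, 2 * n, spec$dec_convs)),
      up0  = init_conv(2, 2, 2 * n, n, bn = FALSE),
      dec0 = mk_stack(stack_sizes(if (spec$top_skip) 2 * n else n, n,
                                  spec$dec_convs)),
      proj = init_conv(1, 1, n, in_channels, bn = FALSE)
    )
    buffers <- list(
      enc1 = lapply(params$enc1, function(u) init_buffers(length(u$b))),
      enc2 = lapply(params$enc2, function(u) init_buffers(length(u$b))),
      bott = lapply(params$bott, function(u) init_buffers(length(u$b))),
      dec1 = lapply(params$dec1, function(u) init_buffers(length(u$b))),
      dec0 = lapply(params$dec0, function(u) init_buffers(length(u$b)))
    )
    structure(list(spec = spec, params = params, buffers = buffers,
                   in_channels = as.integer(in_channels)),
              class = "bsn_net")
  })
}

# ---- per-channel helpers on (H, W, C, N) arrays ----

ch_sum <- function(x) {
  d <- dim(x)
  cs <- colSums(matrix(x, d[1] * d[2]))       # columns ordered c fastest, n slowest
  rowSums(matrix(cs, d[3]))
}

ch_expand <- function(v, d) rep(v, each = d[1] * d[2])  # recycles over N

relu <- function(x) { x[x < 0] <- 0; x }

arr_cat <- function(a, b) {
  d <- dim(a)
  out <- array(0, dim = c(d[1], d[2], d[3] + dim(b)[3], d[4]))
  out[, , seq_len(d[3]), ] <- a
  out[, , d[3] + seq_len(dim(b)[3]), ] <- b
  out
}

maybe_half <- function(x, half) if (half) cpp_round_half(x) else x

# conv + BN + ReLU unit. Training convolutions run in single precision
# (fp = "float"); fp = "double" keeps the full double path for gradient
# verification. Inference always uses the exact double path.
unit_fwd <- function(u, buf, x, train, half, fp = "float") {
  colp <- NULL
  z <- if (train && fp == "float") {
    r <- cpp_conv2d_fwd_f(x, u$w, u$b, keep_col = TRUE)
    colp <- r$col
    r$y
  } else cpp_conv2d_fwd(x, u$w, u$b, exact = !train)
  if (train) {
    st <- cpp_bn_stats(z)
    mu <- st$mu
    var <- st$var
    buf$rm <- (1 - BN_MOMENTUM) * buf$rm + BN_MOMENTUM * mu
    unb <- if (st$m > 1) st$m / (st$m - 1) else 1
    buf$rv <- (1 - BN_MOMENTUM) * buf$rv + BN_MOMENTUM * var * unb
  } else {
    mu <- buf$rm
    var <- buf$rv
  }
  y <- cpp_bn_relu_fwd(z, u$gamma, u$beta, mu, var, BN_EPS)
  y <- maybe_half(y, half)
  cache <- if (train) list(x = x, z = z, mu = mu, var = var, col = colp)
           else NULL
  list(y = y, cache = cache, buf = buf)
}

unit_bwd <- function(u, cache, dy, fp = "float") {
  bn <- cpp_bn_relu_bwd(cache$z, dy, u$gamma, u$beta, cache$mu, cache$var,
                        BN_EPS)
  g <- if (fp == "float")
    cpp_conv2d_bwd_f(cache$x, u$w, bn$dz, cache$col %||% NULL)
  else cpp_conv2d_bwd(cache$x, u$w, bn$dz)
  list(dx = g$dx,
       grads = list(w = g$dw, b = g$db, gamma = bn$dgamma, beta = bn$dbeta))
}

stack_fwd <- function(units, bufs, x, train, half, fp = "float") {
  caches <- vector("list", length(units))
  for (i in seq_along(units)) {
    r <- unit_fwd(units[[i]], bufs[[i]], x, train, half, fp)
    x <- r$y
    caches[[i]] <- r$cache
    if (train) bufs[[i]] <- r$buf
  }
  list(y = x, caches = caches, bufs = bufs)
}

stack_bwd <- function(units, caches, dy, fp = "float") {
  grads <- vector("list", length(units))
  for (i in rev(seq_along(units))) {
    r <- unit_bwd(units[[i]], caches[[i]], dy, fp)
    dy <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dy, grads = grads)
}

#' Forward pass of the U-Net
#'
#' @param model a [build_unet()] model.
#' @param x input: a matrix (single image) or `(H, W, C, N)` array with
#'   `C == model$in_channels`; `H` and `W` must be divisible by 4.
#' @param train if `TRUE`, use batch normalization statistics and return a
#'   cache for [net_backward()]; updates running statistics in the returned
#'   `buffers` element.
#' @param precision `"single"` (double-precision reference path) or
#'   `"half"`: weights and every stored activation are rounded to IEEE
#'   binary16, with accumulation kept wide, emulating fp16 tensor-core
#'   inference.
#' @param fp training compute precision: `"float"` (single-precision
#'   convolutions, the usual training precision) or `"double"` (reference
#'   path used by the gradient checks). Ignored at inference.
#' @return in inference mode, the output with the shape of `x`; in training
#'   mode a list `y`, `cache`, `buffers`.
#' @export
net_forward <- function(model, x, train = FALSE,
                        precision = c("single", "half"),
                        fp = c("float", "double")) {
  precision <- match.arg(precision)
  fp <- match.arg(fp)
  half <- precision == "half"
  was_mat <- is.matrix(x) && length(dim(x)) == 2
  if (was_mat) x <- array(x, dim = c(dim(x), 1, 1))
  d <- dim(x)
  if (d[1] %% 4 || d[2] %% 4)
    stopf("input %dx%d not divisible by 4: pad to %dx%d",
          d[1], d[2], 4 * ceiling(d[1] / 4), 4 * ceiling(d[2] / 4))
  if (d[3] != model$in_channels)
    stopf("expected %d input channels, got %d", model$in_channels, d[3])
  if (train && half) stopf("half precision is inference-only")
  if (train && model$in_channels > 1)
    stopf("pseudo-batch models are inference-only")
  p <- model$params
  bufs <- model$buffers
  if (half) {
    p <- rapply(p, cpp_round_half, how = "replace")
    x <- cpp_round_half(x)
  }
  input <- x

  e1 <- stack_fwd(p$enc1, bufs$enc1, x, train, half, fp)
  pl1 <- cpp_maxpool2_fwd(e1$y)
  e2 <- stack_fwd(p$enc2, bufs$enc2, pl1$y, train, half, fp)
  pl2 <- cpp_maxpool2_fwd(e2$y)
  bt <- stack_fwd(p$bott, bufs$bott, pl2$y, train, half, fp)
  u1 <- maybe_half(cpp_upconv2_fwd(bt$y, p$up1$w, p$up1$b, exact = !train), half)
  d1in <- arr_cat(u1, e2$y)
  d1 <- stack_fwd(p$dec1, bufs$dec1, d1in, train, half, fp)
  u0 <- maybe_half(cpp_upconv2_fwd(d1$y, p$up0$w, p$up0$b, exact = !train), half)
  d0in <- if (model$spec$top_skip) arr_cat(u0, e1$y) else u0
  d0 <- stack_fwd(p$dec0, bufs$dec0, d0in, train, half, fp)
  y <- maybe_half(cpp_conv2d_fwd(d0$y, p$proj$w, p$proj$b, exact = !train), half)
  if (model$spec$residual) y <- maybe_half(y + input, half)

  if (!train) {
    if (was_mat) y <- matrix(y, d[1], d[2])
    return(y)
  }
  list(y = y,
       cache = list(input = input, e1 = e1, pl1 = pl1, e2 = e2, pl2 = pl2,
                    bt = bt, d1in = d1in, d1 = d1, d0in = d0in, d0 = d0, fp = fp,
                    xdims = list(e1 = dim(e1$y), e2 = dim(e2$y))),
       buffers = list(enc1 = e1$bufs, enc2 = e2$bufs, bott = bt$bufs,
                      dec1 = d1$bufs, dec0 = d0$bufs))
}

#' Backward pass (gradients of a scalar loss w.r.t. all parameters)
#'
#' @param model the model used in the forward pass.
#' @param cache the `cache` element returned by `net_forward(train = TRUE)`.
#' @param dy gradient of the loss w.r.t. the network output (same shape).
#' @return list with `grads` mirroring `model$params`.
#' @export
net_backward <- function(model, cache, dy) {
  p <- model$params
  fp <- cache$fp %||% "float"
  n <- model$spec$n * model$in_channels
  grads <- list()

  # residual: dy flows unchanged into proj and also adds to d(input), which
  # we do not need (input has no parameters upstream)
  gproj <- cpp_conv2d_bwd(cache$d0$y, p$proj$w, dy)
  grads$proj <- list(w = gproj$dw, b = gproj$db)
  r0 <- stack_bwd(p$dec0, cache$d0$caches, gproj$dx, fp)
  grads$dec0 <- r0$grads
  if (model$spec$top_skip) {
    du0 <- r0$dx[, , seq_len(n), , drop = FALSE]
    de1_skip <- r0$dx[, , n + seq_len(n), , drop = FALSE]
  } else {
    du0 <- r0$dx
    de1_skip <- NULL
  }
  gup0 <- cpp_upconv2_bwd(cache$d1$y, p$up0$w, du0)
  grads$up0 <- list(w = gup0$dw, b = gup0$db)
  r1 <- stack_bwd(p$dec1, cache$d1$caches, gup0$dx, fp)
  grads$dec1 <- r1$grads
  du1 <- r1$dx[, , seq_len(2 * n), , drop = FALSE]
  de2_skip <- r1$dx[, , 2 * n + seq_len(2 * n), , drop = FALSE]
  gup1 <- cpp_upconv2_bwd(cache$bt$y, p$up1$w, du1)
  grads$up1 <- list(w = gup1$dw, b = gup1$db)
  rb <- stack_bwd(p$bott, cache$bt$caches, gup1$dx, fp)
  grads$bott <- rb$grads
  dpl2 <- cpp_maxpool2_bwd(rb$dx, cache$pl2$idx, cache$xdims$e2)
  r2 <- stack_bwd(p$enc2, cache$e2$caches, dpl2 + de2_skip, fp)
  grads$enc2 <- r2$grads
  dpl1 <- cpp_maxpool2_bwd(r2$dx, cache$pl1$idx, cache$xdims$e1)
  de1 <- if (is.null(de1_skip)) dpl1 else dpl1 + de1_skip
  re1 <- stack_bwd(p$enc1, cache$e1$caches, de1, fp)
  grads$enc1 <- re1$grads
  grads[c("enc1", "enc2", "bott", "up1", "dec1", "up0", "dec0", "proj")]
}

# ---- parameter vector <-> tree ----

params_to_vec <- function(params) unlist(params, use.names = FALSE)

vec_to_params <- function(template, vec) {
  i <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    k <- length(x)
    out <- vec[(i + 1L):(i + k)]
    i <<- i + k
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  out <- walk(template)
  stopifnot(i == length(vec))
  out
}

#' Theoretical influence footprint of a network specification
#'
#' Backward window arithmetic over the conv / pool / transposed-conv chain;
#' returns the side length (px) of the square input region that can
#' influence one output pixel. Cheap, used for padding validation;
#' [measure_receptive_field()] verifies it empirically.
#'
#' @param spec a [net_spec()].
#' @return integer extent in pixels (same in both dimensions).
#' @export
rf_theoretical <- function(spec) {
  w <- 1L
  w <- w + 2L * spec$dec_convs            # dec0 (full res)
  w <- w %/% 2L + 1L                      # upconv 0
  w <- w + 2L * spec$dec_convs            # dec1
  w <- w %/% 2L + 1L                      # upconv 1
  w <- w + 2L * spec$bottleneck_convs     # bottleneck
  w <- 2L * w                             # pool 2
  w <- w + 2L * spec$enc_convs            # enc2
  w <- 2L * w                             # pool 1
  w <- w + 2L * spec$enc_convs            # enc1
  as.integer(w)
}

#' Measure the receptive field of a model empirically
#'
#' Perturbs one input pixel and records the bounding box of output pixels
#' that change; by shift symmetry this footprint has the same extents as the
#' set of input pixels influencing one central output pixel. To avoid
#' underestimation through inactive ReLUs or max-pool selections, the
#' measurement maximizes over random non-negative weight draws, both
#' perturbation signs, and pooling-grid alignments.
#'
#' @param model a `"bsn_net"` (its architecture is re-drawn with positive
#'   weights), or any function mapping a matrix to a matrix.
#' @param input_size probe image side (divisible by 4); increase if the
#'   footprint touches the border.
#' @param draws random weight draws for `"bsn_net"` models.
#' @param delta perturbation magnitude.
#' @return `c(axial, lateral)` extents in pixels.
#' @export
measure_receptive_field <- function(model, input_size = 128, draws = 3,
                                    delta = 5) {
  funs <- if (is.function(model)) {
    list(model)
  } else if (inherits(model, "bsn_net")) {
    lapply(seq_len(draws), function(k) {
      m <- build_unet(net_spec(
        n = model$spec$n, residual = model$spec$residual,
        top_skip = model$spec$top_skip, enc_convs = model$spec$enc_convs,
        dec_convs = model$spec$dec_convs,
        bottleneck_convs = model$spec$bottleneck_convs,
        seed = derive_seed(model$spec$seed, 7000L + k)))
      m$params <- rapply(m$params, abs, how = "replace")
      function(x) net_forward(m, x)
    })
  } else stopf("model must be a bsn_net or a function")

  S <- input_size
  ext <- c(0L, 0L)
  for (f in funs) {
    base <- with_seed(derive_seed(99L, S), matrix(runif(S * S, 0.4, 0.6), S, S))
    y0 <- f(base)
    for (sr in 0:3) for (sc in 0:3) {
      r0 <- S %/% 2 + sr; c0 <- S %/% 2 + sc
      for (dl in c(delta, -delta)) {
        x <- base
        x[r0, c0] <- x[r0, c0] + dl
        dyy <- abs(f(x) - y0)
        hit <- which(dyy > 1e-8, arr.ind = TRUE)
        if (nrow(hit) == 0) next
        if (min(hit) <= 1 || max(hit[, 1]) >= S || max(hit[, 2]) >= S)
          stopf("probe image too small (footprint reached the border); retry with larger input_size")
        ext <- pmax(ext, c(diff(range(hit[, 1])) + 1L,
                           diff(range(hit[, 2])) + 1L))
      }
    }
  }
  c(axial = ext[1], lateral = ext[2])
}

#' Export a pseudo-batched copy of a single-channel model
#'
#' Replicates the learned weights for each of `channels` channels while
#' setting every weight that would introduce channel interdependencies to
#' exactly zero (block-diagonal kernels). Normalization statistics are
#' frozen and replicated, so output channel i equals the single-channel
#' model applied to input channel i. The exported model is inference-only.
#'
#' @param model a trained single-channel `"bsn_net"`.
#' @param channels channel count (>= 1).
#' @return a `"bsn_net"` with `in_channels = channels`.
#' @export
export_pseudobatch <- function(model, channels = 4) {
  if (!inherits(model, "bsn_net")) stopf("model must be a bsn_net")
  if (model$in_channels != 1) stopf("model must have a single channel")
  if (!is_count(channels) || channels < 1) stopf("channels must be >= 1")
  R <- as.integer(channels)
  rep_w <- function(w) {
    d <- dim(w)
    out <- array(0, dim = c(d[1], d[2], d[3] * R, d[4] * R))
    for (k in seq_len(R))
      out[, , (k - 1) * d[3] + seq_len(d[3]), (k - 1) * d[4] + seq_len(d[4])] <- w
    out
  }
  # First conv after a concatenation: the replicated input is laid out as
  # [upsampled block 1..R | skip block 1..R], not block-contiguous, so the
  # two halves of each kernel go to different channel ranges.
  rep_w_concat <- function(w, cin_a) {
    d <- dim(w)
    cin_b <- d[3] - cin_a
    out <- array(0, dim = c(d[1], d[2], d[3] * R, d[4] * R))
    for (k in seq_len(R)) {
      co <- (k - 1) * d[4] + seq_len(d[4])
      out[, , (k - 1) * cin_a + seq_len(cin_a), co] <-
        w[, , seq_len(cin_a), , drop = FALSE]
      out[, , R * cin_a + (k - 1) * cin_b + seq_len(cin_b), co] <-
        w[, , cin_a + seq_len(cin_b), , drop = FALSE]
    }
    out
  }
  rep_unit <- function(u, concat_cin_a = NULL) {
    u$w <- if (is.null(concat_cin_a)) rep_w(u$w)
           else rep_w_concat(u$w, concat_cin_a)
    u$b <- rep(u$b, R)
    if (!is.null(u$gamma)) { u$gamma <- rep(u$gamma, R); u$beta <- rep(u$beta, R) }
    u
  }
  rep_stack_concat <- function(stack, cin_a) {
    stack[[1]] <- rep_unit(stack[[1]], concat_cin_a = cin_a)
    if (length(stack) > 1)
      stack[-1] <- lapply(stack[-1], rep_unit)
    stack
  }
  rep_buf <- function(bf) list(rm = rep(bf$rm, R), rv = rep(bf$rv, R))
  m4 <- model
  m4$params <- list(
    enc1 = lapply(model$params$enc1, rep_unit),
    enc2 = lapply(model$params$enc2, rep_unit),
    bott = lapply(model$params$bott, rep_unit),
    up1 = rep_unit(model$params$up1),
    dec1 = rep_stack_concat(model$params$dec1, 2L * model$spec$n),
    up0 = rep_unit(model$params$up0),
    dec0 = if (model$spec$top_skip)
      rep_stack_concat(model$params$dec0, model$spec$n)
    else lapply(model$params$dec0, rep_unit),
    proj = rep_unit(model$params$proj)
  )
  m4$buffers <- lapply(model$buffers, function(st) lapply(st, rep_buf))
  m4$in_channels <- R
  m4
}
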