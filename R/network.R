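#' Segmentation network configuration
#'
#' Describes the encoder-bridge-decoder (U-Net) backbone: double-convolution
#' blocks (3x3, "same" padding), 2x2 max-pool downsampling, 2x2 stride-2
#' transposed-convolution upsampling and skip connections. A normalization
#' layer follows every convolution; instance normalization is the default
#' because it keeps per-site intensity statistics local and avoids the
#' degradation that shared batch statistics suffer under non-IID data.
#'
#' @param in_channels Number of input image channels (1 for grayscale).
#' @param base_channels Feature width of the first encoder level.
#' @param depth Number of down-sampling levels (the bridge sits below the
#'   deepest encoder block). Input height/width must be divisible by
#'   `2^depth`.
#' @param norm_kind One of `"instance"`, `"batch"`, `"none"`.
#' @param out_channels Number of output channels (1 for binary masks; the
#'   final 1x1 convolution emits logits, sigmoid is applied in losses and
#'   metrics only).
#' @return A `network_config` object (a validated list).
#' @examples
#' network_config(depth = 2, base_channels = 8)
#' @export
network_config <- function(in_channels = 1L, base_channels = 8L, depth = 2L,
                           norm_kind = c("instance", "batch", "none"),
                           out_channels = 1L) {
  norm_kind <- match.arg(norm_kind)
  check_number(depth, "depth", min = 1)
  check_number(base_channels, "base_channels", min = 1)
  check_number(in_channels, "in_channels", min = 1)
  check_number(out_channels, "out_channels", min = 1)
  structure(
    list(
      in_channels = as.integer(in_channels),
      base_channels = as.integer(base_channels),
      depth = as.integer(depth),
      norm_kind = norm_kind,
      out_channels = as.integer(out_channels)
    ),
    class = "network_config"
  )
}

# channel plan: one row per learned layer, used by init and enumeration
unet_layer_plan <- function(config) {
  b <- config$base_channels
  d <- config$depth
  rows <- list()
  add <- function(prefix, kind, cin, cout, k) {
    rows[[length(rows) + 1]] <<- list(
      prefix = prefix, kind = kind,
      cin = as.integer(cin), cout = as.integer(cout), k = as.integer(k)
    )
  }
  for (i in seq_len(d) - 1L) {
    cin <- if (i == 0) config$in_channels else b * 2^(i - 1)
    cw <- b * 2^i
    add(sprintf("encoder.block%d.conv1", i), "conv", cin, cw, 3)
    add(sprintf("encoder.block%d.norm1", i), "norm", cw, cw, 0)
    add(sprintf("encoder.block%d.conv2", i), "conv", cw, cw, 3)
    add(sprintf("encoder.block%d.norm2", i), "norm", cw, cw, 0)
  }
  cb <- b * 2^d
  add("bridge.conv1", "conv", b * 2^(d - 1), cb, 3)
  add("bridge.norm1", "norm", cb, cb, 0)
  add("bridge.conv2", "conv", cb, cb, 3)
  add("bridge.norm2", "norm", cb, cb, 0)
  for (i in rev(seq_len(d) - 1L)) {
    cw <- b * 2^i
    add(sprintf("decoder.block%d.up", i), "convt", cw * 2, cw, 2)
    add(sprintf("decoder.block%d.conv1", i), "conv", cw * 2, cw, 3)
    add(sprintf("decoder.block%d.norm1", i), "norm", cw, cw, 0)
    add(sprintf("decoder.block%d.conv2", i), "conv", cw, cw, 3)
    add(sprintf("decoder.block%d.norm2", i), "norm", cw, cw, 0)
  }
  add("final", "conv", b, config$out_channels, 1)
  rows
}

#' Build a segmentation model with deterministic initialization
#'
#' Convolution weights use He-normal initialization (`sd = sqrt(2 / fan_in)`),
#' biases start at zero, normalization scales at one and shifts at zero. The
#' same `(config, seed)` pair always yields a bit-identical parameter set.
#'
#' @param config A [network_config()].
#' @param seed Integer seed controlling initialization.
#' @return A `unet_model` object: a list with elements `config` and `params`
#'   (the named parameter set).
#' @examples
#' m <- build_model(network_config(depth = 1, base_channels = 2), seed = 1)
#' length(get_parameters(m))
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  plan <- unet_layer_plan(config)
  params <- list()
  with_seed(derive_seed(seed, 104729L), {
    for (ly in plan) {
      if (ly$kind == "conv" || ly$kind == "convt") {
        k <- ly$k
        fan_in <- k * k * ly$cin
        w <- array(
          stats::rnorm(k * k * ly$cin * ly$cout, sd = sqrt(2 / fan_in)),
          dim = c(k, k, ly$cin, ly$cout)
        )
        params[[paste0(ly$prefix, ".weight")]] <- w
        params[[paste0(ly$prefix, ".bias")]] <- numeric(ly$cout)
      } else { # norm
        if (config$norm_kind == "none") next
        params[[paste0(ly$prefix, ".gamma")]] <- rep(1, ly$cout)
        params[[paste0(ly$prefix, ".beta")]] <- numeric(ly$cout)
        if (config$norm_kind == "batch") {
          params[[paste0(ly$prefix, ".running_mean")]] <- numeric(ly$cout)
          params[[paste0(ly$prefix, ".running_var")]] <- rep(1, ly$cout)
        }
      }
    }
  })
  structure(list(config = config, params = params), class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf(
    "<unet_model> depth %d, base %d, %s norm, %s parameters in %d arrays\n",
    x$config$depth, x$config$base_channels, x$config$norm_kind,
    format(n_parameters(x), big.mark = ","), length(x$params)
  ))
  invisible(x)
}

#' Total number of scalar parameters in a model or parameter set
#' @param x A `unet_model` or a named list of parameter arrays.
#' @return Integer count of scalars across all arrays.
#' @export
n_parameters <- function(x) {
  p <- if (inherits(x, "unet_model")) x$params else x
  sum(vapply(p, length, integer(1)))
}

#' Get or set model parameters
#'
#' `get_parameters()` returns the named list of parameter arrays (hierarchical
#' names such as `"encoder.block0.conv1.weight"`). `set_parameters()` replaces
#' them, requiring exactly matching names and shapes, so that
#' `set_parameters(model, get_parameters(model))` is the identity.
#'
#' @param model A `unet_model`.
#' @param params Named list of arrays matching the model's parameter set.
#' @return `get_parameters()`: the named list; `set_parameters()`: the
#'   updated model.
#' @export
get_parameters <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  model$params
}

#' @rdname get_parameters
#' @export
set_parameters <- function(model, params) {
  stopifnot(inherits(model, "unet_model"))
  cur <- model$params
  if (!setequal(names(params), names(cur))) {
    extra <- setdiff(names(params), names(cur))
    miss <- setdiff(names(cur), names(params))
    stop2(
      "parameter names do not match the model",
      if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")),
      if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", "))
    )
  }
  for (nm in names(cur)) {
    d0 <- dim(cur[[nm]]) %||% length(cur[[nm]])
    d1 <- dim(params[[nm]]) %||% length(params[[nm]])
    if (!identical(as.integer(d0), as.integer(d1))) {
      stop2("shape mismatch for parameter '", nm, "'")
    }
  }
  model$params <- params[names(cur)]
  model
}

#' Split parameter names into shared and personalized sets
#'
#' Names matching any of `personalized_patterns` form the personalized part
#' (kept local, never aggregated); all remaining names form the shared part
#' (broadcast and aggregated by the server). A pattern containing glob
#' metacharacters (`*?[`) is interpreted as a glob over the full name;
#' otherwise it matches as a fixed substring. The default pattern `"norm"`
#' personalizes every normalization-layer parameter.
#'
#' @param params A `unet_model`, a named parameter list, or a character
#'   vector of parameter names.
#' @param personalized_patterns Character vector of patterns; empty vector
#'   means everything is shared.
#' @return A `parameter_partition`: list with character vectors `shared` and
#'   `personalized` (disjoint, jointly covering all names).
#' @examples
#' m <- build_model(network_config(depth = 1, base_channels = 2), seed = 1)
#' part <- partition_parameters(m, "norm")
#' length(part$shared) + length(part$personalized) == length(get_parameters(m))
#' @export
partition_parameters <- function(params, personalized_patterns = "norm") {
  nms <- if (inherits(params, "unet_model")) {
    names(params$params)
  } else if (is.character(params)) {
    params
  } else {
    names(params)
  }
  hit <- rep(FALSE, length(nms))
  for (pat in personalized_patterns) {
    if (grepl("[*?[]", pat)) {
      hit <- hit | grepl(utils::glob2rx(pat), nms)
    } else {
      hit <- hit | grepl(pat, nms, fixed = TRUE)
    }
  }
  structure(
    list(
      shared = nms[!hit], personalized = nms[hit],
      patterns = as.character(personalized_patterns)
    ),
    class = "parameter_partition"
  )
}

# ---------------------------------------------------------------------------
# forward / backward machinery (arrays are (H, W, C, N), column-major)

NORM_EPS <- 1e-5

norm_fwd <- function(x, params, prefix, kind, train) {
  if (kind == "none") {
    return(list(y = x, cache = list(kind = "none"), params = params))
  }
  d <- dim(x)
  m <- d[1] * d[2]
  C <- d[3]
  N <- d[4]
  gamma <- params[[paste0(prefix, ".gamma")]]
  beta <- params[[paste0(prefix, ".beta")]]
  if (kind == "instance") {
    fw <- cpp_instnorm_fwd(x, gamma, beta, NORM_EPS)
    return(list(
      y = fw$y,
      cache = list(kind = kind, xhat = fw$xhat, invstd = fw$invstd,
                   gamma = gamma, d = d),
      params = params
    ))
  }
  xm <- matrix(x, nrow = m)
  # batch normalization: statistics per channel over (H, W, N)
  rm_ <- params[[paste0(prefix, ".running_mean")]]
  rv_ <- params[[paste0(prefix, ".running_var")]]
  if (train) {
    cm <- matrix(colMeans(xm), C, N)
    mu_c <- rowMeans(cm)
    cm2 <- matrix(colMeans(xm * xm), C, N)
    v_c <- rowMeans(cm2) - mu_c^2
    params[[paste0(prefix, ".running_mean")]] <- 0.9 * rm_ + 0.1 * mu_c
    params[[paste0(prefix, ".running_var")]] <- 0.9 * rv_ + 0.1 * v_c
  } else {
    mu_c <- rm_
    v_c <- rv_
  }
  invstd_c <- 1 / sqrt(v_c + NORM_EPS)
  mu_col <- rep(mu_c, times = N)
  is_col <- rep(invstd_c, times = N)
  xhat <- (xm - rep(mu_col, each = m)) * rep(is_col, each = m)
  y <- xhat * rep(rep(gamma, times = N), each = m) +
    rep(rep(beta, times = N), each = m)
  dim(y) <- d
  list(
    y = y,
    cache = list(kind = kind, xhat = xhat, invstd_c = invstd_c, gamma = gamma,
                 d = d, train = train),
    params = params
  )
}

norm_bwd <- function(dy, cache) {
  if (cache$kind == "none") {
    return(list(dx = dy, grads = list()))
  }
  d <- cache$d
  if (cache$kind == "instance") {
    bw <- cpp_instnorm_bwd(dy, cache$xhat, cache$invstd, cache$gamma,
      as.integer(d)
    )
    return(list(dx = bw$dx, grads = list(gamma = bw$dgamma, beta = bw$dbeta)))
  }
  m <- d[1] * d[2]
  C <- d[3]
  N <- d[4]
  dym <- matrix(dy, nrow = m)
  xhat <- cache$xhat
  gamma <- cache$gamma
  dgamma <- rowSums(matrix(colSums(dym * xhat), C, N))
  dbeta <- rowSums(matrix(colSums(dym), C, N))
  dyg <- dym * rep(rep(gamma, times = N), each = m)
  if (isTRUE(cache$train)) {
    M <- m * N
    s1 <- rowSums(matrix(colSums(dyg), C, N)) / M
    s2 <- rowSums(matrix(colSums(dyg * xhat), C, N)) / M
    dx <- rep(rep(cache$invstd_c, times = N), each = m) *
      (dyg - rep(rep(s1, times = N), each = m) -
        xhat * rep(rep(s2, times = N), each = m))
  } else {
    # eval-mode batch norm: fixed statistics, a plain affine map
    dx <- dyg * rep(rep(cache$invstd_c, times = N), each = m)
  }
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

block_fwd <- function(params, prefix, x, kind, train, want_cache = FALSE) {
  c1 <- cpp_conv2d_fwd(
    x, params[[paste0(prefix, ".conv1.weight")]],
    params[[paste0(prefix, ".conv1.bias")]]
  )
  n1 <- norm_fwd(c1, params, paste0(prefix, ".norm1"), kind, train)
  params <- n1$params
  r1 <- cpp_relu(n1$y)
  c2 <- cpp_conv2d_fwd(
    r1, params[[paste0(prefix, ".conv2.weight")]],
    params[[paste0(prefix, ".conv2.bias")]]
  )
  n2 <- norm_fwd(c2, params, paste0(prefix, ".norm2"), kind, train)
  params <- n2$params
  r2 <- cpp_relu(n2$y)
  cache <- if (want_cache) {
    list(x = x, n1 = n1$cache, r1 = r1, n2 = n2$cache, r2 = r2)
  }
  list(out = r2, cache = cache, params = params)
}

block_bwd <- function(params, prefix, cache, dout, grads) {
  dn2 <- cpp_relu_bwd(dout, cache$r2)
  nb2 <- norm_bwd(dn2, cache$n2)
  if (length(nb2$grads)) {
    grads[[paste0(prefix, ".norm2.gamma")]] <- nb2$grads$gamma
    grads[[paste0(prefix, ".norm2.beta")]] <- nb2$grads$beta
  }
  cb2 <- cpp_conv2d_bwd(
    cache$r1, params[[paste0(prefix, ".conv2.weight")]],
    nb2$dx
  )
  grads[[paste0(prefix, ".conv2.weight")]] <- cb2$dw
  grads[[paste0(prefix, ".conv2.bias")]] <- cb2$db
  dn1 <- cpp_relu_bwd(cb2$dx, cache$r1)
  nb1 <- norm_bwd(dn1, cache$n1)
  if (length(nb1$grads)) {
    grads[[paste0(prefix, ".norm1.gamma")]] <- nb1$grads$gamma
    grads[[paste0(prefix, ".norm1.beta")]] <- nb1$grads$beta
  }
  cb1 <- cpp_conv2d_bwd(
    cache$x, params[[paste0(prefix, ".conv1.weight")]],
    nb1$dx
  )
  grads[[paste0(prefix, ".conv1.weight")]] <- cb1$dw
  grads[[paste0(prefix, ".conv1.bias")]] <- cb1$db
  list(dx = cb1$dx, grads = grads)
}

concat_channels <- function(a, b) {
  da <- dim(a)
  db_ <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db_[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db_[3]), ] <- b
  out
}

# core forward pass; x is (H, W, C, N)
unet_forward <- function(params, config, x, train = FALSE, upto = "logits",
                         want_cache = FALSE) {
  d <- config$depth
  kind <- config$norm_kind
  dx_ <- dim(x)
  if (length(dx_) != 4) stop2("input must be a 4-d array (H, W, C, N)")
  if (dx_[3] != config$in_channels) {
    stop2(
      "input has ", dx_[3], " channels, model expects ",
      config$in_channels
    )
  }
  if (dx_[1] %% 2^d != 0 || dx_[2] %% 2^d != 0) {
    stop2("input height/width must be divisible by 2^depth = ", 2^d)
  }
  cache <- if (want_cache) list(enc = vector("list", d))
  skips <- vector("list", d)
  h <- x
  for (i in seq_len(d)) {
    bl <- block_fwd(params, sprintf("encoder.block%d", i - 1L), h, kind,
      train,
      want_cache = want_cache
    )
    params <- bl$params
    skips[[i]] <- bl$out
    pl <- cpp_maxpool_fwd(bl$out)
    if (want_cache) {
      cache$enc[[i]] <- list(
        block = bl$cache, idx = pl$idx,
        xdim = dim(bl$out)
      )
    }
    h <- pl$y
  }
  br <- block_fwd(params, "bridge", h, kind, train, want_cache = want_cache)
  params <- br$params
  representation <- br$out
  if (want_cache) cache$bridge <- br$cache
  if (upto == "bridge") {
    return(list(
      representation = representation, params = params,
      cache = cache
    ))
  }
  if (want_cache) cache$dec <- vector("list", d)
  h <- representation
  for (i in rev(seq_len(d))) {
    up_w <- params[[sprintf("decoder.block%d.up.weight", i - 1L)]]
    up_b <- params[[sprintf("decoder.block%d.up.bias", i - 1L)]]
    up <- cpp_convt2_fwd(h, up_w, up_b)
    hcat <- concat_channels(up, skips[[i]])
    bl <- block_fwd(params, sprintf("decoder.block%d", i - 1L), hcat, kind,
      train,
      want_cache = want_cache
    )
    if (want_cache) {
      cache$dec[[i]] <- list(
        up_in = h, c_up = dim(up)[3],
        block = bl$cache
      )
    }
    params <- bl$params
    h <- bl$out
  }
  logits <- cpp_conv2d_fwd(h, params[["final.weight"]], params[["final.bias"]])
  if (want_cache) cache$final_in <- h
  list(
    logits = logits, representation = representation, params = params,
    cache = cache
  )
}

# backward pass; dlogits matches logits, drep (optional) matches the bridge
# representation (the contrastive path enters there). Returns named gradients.
unet_backward <- function(params, config, cache, dlogits, drep = NULL) {
  d <- config$depth
  grads <- list()
  fb <- cpp_conv2d_bwd(cache$final_in, params[["final.weight"]], dlogits)
  grads[["final.weight"]] <- fb$dw
  grads[["final.bias"]] <- fb$db
  dh <- fb$dx
  dskips <- vector("list", d)
  for (i in seq_len(d)) {
    dc <- cache$dec[[i]]
    bb <- block_bwd(params, sprintf("decoder.block%d", i - 1L), dc$block,
      dh,
      grads = grads
    )
    grads <- bb$grads
    c_up <- dc$c_up
    c_tot <- dim(bb$dx)[3]
    dup <- bb$dx[, , seq_len(c_up), , drop = FALSE]
    dskips[[i]] <- bb$dx[, , (c_up + 1):c_tot, , drop = FALSE]
    ub <- cpp_convt2_bwd(
      dc$up_in,
      params[[sprintf("decoder.block%d.up.weight", i - 1L)]], dup
    )
    grads[[sprintf("decoder.block%d.up.weight", i - 1L)]] <- ub$dw
    grads[[sprintf("decoder.block%d.up.bias", i - 1L)]] <- ub$db
    dh <- ub$dx
  }
  if (!is.null(drep)) dh <- dh + drep
  bb <- block_bwd(params, "bridge", cache$bridge, dh, grads = grads)
  grads <- bb$grads
  dh <- bb$dx
  for (i in rev(seq_len(d))) {
    ec <- cache$enc[[i]]
    dblock <- cpp_maxpool_bwd(dh, ec$idx, ec$xdim) + dskips[[i]]
    bb <- block_bwd(params, sprintf("encoder.block%d", i - 1L), ec$block,
      dblock,
      grads = grads
    )
    grads <- bb$grads
    dh <- bb$dx
  }
  grads
}

# accept (H,W), (H,W,N) for single-channel models, or full (H,W,C,N)
coerce_batch <- function(x, in_channels) {
  if (is.matrix(x)) {
    dim(x) <- c(dim(x), 1L, 1L)
    return(x)
  }
  d <- dim(x)
  if (length(d) == 3) {
    if (in_channels != 1) {
      stop2("3-d input is ambiguous for multi-channel models; pass (H,W,C,N)")
    }
    dim(x) <- c(d[1], d[2], 1L, d[3])
    return(x)
  }
  if (length(d) == 4) {
    return(x)
  }
  stop2("input must have 2, 3 or 4 dimensions")
}

#' Run the network, returning logits and the bridge representation
#'
#' A single forward pass produces both the pre-sigmoid pixel logits and the
#' latent representation `R(x)`: the output of the bridge (deepest) block,
#' after its activation and before any decoder layer. The representation of
#' a `(H, W)` input has shape `(H/2^depth, W/2^depth, base_channels * 2^depth)`
#' per sample.
#'
#' @param model A `unet_model`.
#' @param x Input batch: `(H, W)` matrix, `(H, W, N)` array (single-channel),
#'   or `(H, W, C, N)` array, values expected in `[0, 1]`.
#' @param train Logical; `TRUE` uses training-mode normalization (batch
#'   statistics, running-stat updates for batch norm). Evaluation mode is the
#'   default.
#' @return List with `logits` (`(H, W, out_channels, N)`) and
#'   `representation` (`(H', W', C', N)`).
#' @examples
#' m <- build_model(network_config(depth = 1, base_channels = 2), seed = 1)
#' out <- forward_with_representation(m, matrix(0.5, 8, 8))
#' dim(out$representation)
#' @export
forward_with_representation <- function(model, x, train = FALSE) {
  stopifnot(inherits(model, "unet_model"))
  x <- coerce_batch(x, model$config$in_channels)
  fw <- unet_forward(model$params, model$config, x, train = train)
  list(logits = fw$logits, representation = fw$representation)
}
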