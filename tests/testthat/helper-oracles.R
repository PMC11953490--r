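# Shared fixtures and independent brute-force oracles. Oracles are written as
# explicit element loops so they share no code path with the package
# implementations they check.

tiny_net <- function(depth = 1L, base = 2L, norm = "instance") {
  network_config(
    in_channels = 1L, base_channels = base, depth = depth,
    norm_kind = norm
  )
}

# small multi-site datasets (8x8 images) for fast federation tests
tiny_sites <- function(n_k = c(9L, 7L), hw = 8L, seed = 7L) {
  lapply(seq_along(n_k), function(k) {
    prof <- site_profile(
      site_id = k, n_k = n_k[k],
      intensity_mean = 0.85 - 0.1 * k, intensity_shift = 0.1 * k,
      noise_sd = 0.04, shape_family = "ellipse", size_range = c(1, 2),
      image_size = c(hw, hw), seed = derive_seed(seed, k)
    )
    make_site_dataset(prof)
  })
}

tiny_fed <- function(rounds = 2L, local_epochs = 1L, batch_size = 4L,
                     learning_rate = 1e-3, augment = FALSE, ...) {
  federation_config(
    rounds = rounds, local_epochs = local_epochs, batch_size = batch_size,
    learning_rate = learning_rate, augment = augment, ...
  )
}

# ---- loop oracles -----------------------------------------------------------

dice_oracle <- function(p, y, eps = 1e-6) {
  n <- dim(p)[3]
  acc <- 0
  for (i in seq_len(n)) {
    s <- 0
    a <- 0
    b <- 0
    for (r in seq_len(dim(p)[1])) {
      for (cc in seq_len(dim(p)[2])) {
        s <- s + y[r, cc, i] * p[r, cc, i]
        a <- a + y[r, cc, i]
        b <- b + p[r, cc, i]
      }
    }
    acc <- acc + 1 - 2 * s / (a + b + eps)
  }
  acc / n
}

bce_oracle <- function(p, y, eps = 1e-6) {
  n <- dim(p)[3]
  acc <- 0
  for (i in seq_len(n)) {
    s <- 0
    m <- 0
    for (r in seq_len(dim(p)[1])) {
      for (cc in seq_len(dim(p)[2])) {
        pv <- min(max(p[r, cc, i], eps), 1 - eps)
        s <- s - (y[r, cc, i] * log(pv) + (1 - y[r, cc, i]) * log(1 - pv))
        m <- m + 1
      }
    }
    acc <- acc + s / m
  }
  acc / n
}

cosine_oracle <- function(a, b) {
  sab <- 0
  saa <- 0
  sbb <- 0
  for (i in seq_along(a)) {
    sab <- sab + a[i] * b[i]
    saa <- saa + a[i]^2
    sbb <- sbb + b[i]^2
  }
  sab / (sqrt(saa) * sqrt(sbb))
}

# naive unstabilized two-way softmax form
contrastive_oracle <- function(xi, xi_g, xi_b, tau, beta) {
  sg <- cosine_oracle(xi, xi_g)
  sb <- cosine_oracle(xi, xi_b)
  -beta * log(exp(sg / tau) / (exp(sg / tau) + exp(sb / tau)))
}

embedding_oracle <- function(r) {
  C <- dim(r)[3]
  avg <- numeric(C)
  mx <- numeric(C)
  for (c_ in seq_len(C)) {
    s <- -Inf
    tot <- 0
    m <- 0
    for (i in seq_len(dim(r)[1])) {
      for (j in seq_len(dim(r)[2])) {
        tot <- tot + r[i, j, c_]
        m <- m + 1
        if (r[i, j, c_] > s) s <- r[i, j, c_]
      }
    }
    avg[c_] <- tot / m
    mx[c_] <- s
  }
  c(avg, mx)
}

# independent Adam implementation for the federated-averaging oracle
adam_oracle_init <- function(params) {
  list(
    m = lapply(params, function(p) 0 * p),
    v = lapply(params, function(p) 0 * p), t = 0
  )
}

adam_oracle_step <- function(params, grads, st, lr, b1 = 0.9, b2 = 0.999,
                             eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(grads)) {
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * grads[[nm]]
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, st = st)
}

# add small noise to every parameter so ReLU pre-activations sit away from
# exact kinks (zero-initialized biases otherwise put whole channels at 0,
# where two-sided finite differences and the subgradient legitimately differ)
jitter_params <- function(params, sd = 0.02, seed = 11L) {
  with_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(s)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    expr
  }
  with_seed(seed, {
    for (nm in names(params)) {
      d <- dim(params[[nm]])
      params[[nm]] <- params[[nm]] + rnorm(length(params[[nm]]), sd = sd)
      dim(params[[nm]]) <- d
    }
    params
  })
}

expect_params_equal <- function(a, b, tol = 1e-6) {
  expect_setequal(names(a), names(b))
  for (nm in names(a)) {
    expect_lt(max(abs(a[[nm]] - b[[nm]])), tol)
  }
}
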