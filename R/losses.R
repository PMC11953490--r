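#' Loss configuration
#'
#' Bundles the scalar hyperparameters of the local training objective
#' `L = L_Dice + mu * L_BCE + alpha * L_con`.
#'
#' @param mu Weight of the binary cross-entropy term inside the supervised
#'   loss (default 1.0).
#' @param alpha Weight of the contrastive regularizer in the total loss
#'   (default 1.0; 0 disables it, giving plain supervised training).
#' @param tau Temperature of the contrastive softmax (default 0.5; smaller
#'   values sharpen the contrast between the global and previous-round
#'   similarities).
#' @param epsilon Numerical floor used to smooth the Dice denominator and to
#'   clamp probabilities before logarithms (default 1e-6).
#' @return A `loss_config` object.
#' @export
loss_config <- function(mu = 1.0, alpha = 1.0, tau = 0.5, epsilon = 1e-6) {
  check_number(mu, "mu", min = 0)
  check_number(alpha, "alpha", min = 0)
  check_number(tau, "tau", min = 0, strict = TRUE)
  check_number(epsilon, "epsilon", min = 0, strict = TRUE)
  structure(list(mu = mu, alpha = alpha, tau = tau, epsilon = epsilon),
    class = "loss_config"
  )
}

# split (H, W) / (H, W, n) into per-sample slices as a 3-d array
as_sample_array <- function(x, name) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) == 4 && dim(x)[3] == 1) {
    # (H, W, 1, N) logits-style input
    x <- array(x, dim(x)[c(1, 2, 4)])
  }
  if (length(dim(x)) != 3) stop2(name, " must be (H, W) or (H, W, n)")
  x
}

check_pair <- function(pred, target) {
  pred <- as_sample_array(pred, "pred")
  target <- as_sample_array(target, "target")
  if (!identical(dim(pred), dim(target))) {
    stop2("pred and target shapes differ")
  }
  list(pred = pred, target = target)
}

#' Soft Dice loss
#'
#' Mean over samples of `1 - 2 |y * p| / (|y| + |p| + epsilon)`, where `|.|`
#' sums over pixels and `*` is the element-wise product. `epsilon` is added to
#' the denominator only, so nonempty cases are essentially exact and the
#' all-empty case evaluates to 1.
#'
#' @param pred_prob Predicted foreground probabilities in `[0, 1]`,
#'   shape `(H, W)` or `(H, W, n)`.
#' @param target Binary ground-truth masks of the same shape.
#' @param epsilon Denominator smoothing (default 1e-6).
#' @return Scalar loss in `[0, 1]`.
#' @examples
#' y <- matrix(0, 4, 4); y[2:3, 2:3] <- 1
#' dice_loss(y, y) # ~0
#' @export
dice_loss <- function(pred_prob, target, epsilon = 1e-6) {
  pt <- check_pair(pred_prob, target)
  if (min(pt$pred) < 0 || max(pt$pred) > 1) {
    stop2("pred_prob values must lie in [0, 1]")
  }
  n <- dim(pt$pred)[3]
  m <- dim(pt$pred)[1] * dim(pt$pred)[2]
  pm <- matrix(pt$pred, m, n)
  ym <- matrix(pt$target, m, n)
  inter <- colSums(ym * pm)
  denom <- colSums(ym) + colSums(pm) + epsilon
  mean(1 - 2 * inter / denom)
}

#' Binary cross-entropy loss
#'
#' Mean over samples of the per-sample pixel-mean of
#' `-(y log p + (1 - y) log(1 - p))`; probabilities are clamped to
#' `[epsilon, 1 - epsilon]` before the logarithms.
#'
#' @inheritParams dice_loss
#' @return Nonnegative scalar.
#' @examples
#' bce_loss(matrix(0.5, 2, 2), matrix(1, 2, 2)) # log(2)
#' @export
bce_loss <- function(pred_prob, target, epsilon = 1e-6) {
  pt <- check_pair(pred_prob, target)
  p <- pmin(pmax(pt$pred, epsilon), 1 - epsilon)
  y <- pt$target
  n <- dim(p)[3]
  m <- dim(p)[1] * dim(p)[2]
  ll <- -(y * log(p) + (1 - y) * log(1 - p))
  mean(colMeans(matrix(ll, m, n)))
}

#' Supervised segmentation loss (Dice + mu * BCE)
#'
#' @inheritParams dice_loss
#' @param cfg A [loss_config()]; `cfg$mu` weights the BCE term and
#'   `cfg$epsilon` is passed to both component losses.
#' @return Nonnegative scalar `dice_loss + mu * bce_loss`.
#' @export
supervised_loss <- function(pred_prob, target, cfg = loss_config()) {
  dice_loss(pred_prob, target, cfg$epsilon) +
    cfg$mu * bce_loss(pred_prob, target, cfg$epsilon)
}

#' Cosine similarity
#'
#' `sim(a, b) = a'b / (||a|| ||b||)`. Zero-norm inputs are an error: a dead
#' (all-zero) embedding indicates an upstream bug and must not silently score
#' zero similarity.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1)) # 1/sqrt(2)
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop2("vectors must have equal length")
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop2("zero-norm vector in cosine_similarity")
  sum(a * b) / (na * nb)
}

#' Adaptive contrastive weight beta = exp(-n_k / N)
#'
#' Strengthens the contrastive pull towards the global model for data-poor
#' clients: the fewer samples a client holds relative to the federation total
#' `N`, the closer beta is to 1.
#'
#' @param n_k Client sample count, `0 <= n_k <= N`.
#' @param N Total training samples across all clients, `N > 0`.
#' @return Scalar in `(0, 1]`.
#' @examples
#' beta_weight(0, 100) # 1
#' beta_weight(100, 100) # exp(-1)
#' @export
beta_weight <- function(n_k, N) {
  check_number(N, "N", min = 0, strict = TRUE)
  check_number(n_k, "n_k", min = 0)
  if (n_k > N) stop2("n_k must not exceed N")
  exp(-n_k / N)
}

# rows of a matrix, or a single vector, as a list of vectors
as_embedding_rows <- function(x, name) {
  if (is.matrix(x)) {
    return(x)
  }
  if (is.numeric(x)) {
    return(matrix(x, nrow = 1))
  }
  stop2(name, " must be a numeric vector or a (n x d) matrix")
}

#' Weighted model-contrastive loss
#'
#' The two-way temperature-scaled softmax loss
#' `-beta * log( exp(s_g/tau) / (exp(s_g/tau) + exp(s_b/tau)) )` with
#' `s_g = sim(xi, xi_g)` (similarity of the live local embedding to the
#' global-model embedding) and `s_b = sim(xi, xi_b)` (to the previous-round
#' local embedding). Computed in log-sum-exp form, so large `1/tau` cannot
#' overflow. Matrix inputs (one embedding per row) return the unweighted mean
#' of per-sample losses.
#'
#' @param xi,xi_g,xi_b Embedding vectors of equal length, or matrices with one
#'   embedding per row.
#' @param tau Positive temperature.
#' @param beta Positive weight, typically [beta_weight()].
#' @return Nonnegative scalar.
#' @examples
#' weighted_contrastive_loss(c(1, 0), c(1, 0), c(0, 1), tau = 1, beta = 1)
#' # log(1 + exp(-1))
#' @export
weighted_contrastive_loss <- function(xi, xi_g, xi_b, tau = 0.5, beta = 1.0) {
  check_number(tau, "tau", min = 0, strict = TRUE)
  check_number(beta, "beta", min = 0, strict = TRUE)
  xi <- as_embedding_rows(xi, "xi")
  xi_g <- as_embedding_rows(xi_g, "xi_g")
  xi_b <- as_embedding_rows(xi_b, "xi_b")
  n <- nrow(xi)
  ls <- vapply(seq_len(n), function(i) {
    s_g <- cosine_similarity(xi[i, ], xi_g[i, ])
    s_b <- cosine_similarity(xi[i, ], xi_b[i, ])
    z <- (s_b - s_g) / tau
    # log(1 + exp(z)), stable for large |z|
    if (z > 35) z else log1p(exp(z))
  }, numeric(1))
  beta * mean(ls)
}

#' Total local training loss
#'
#' `total = supervised + alpha * contrastive`.
#'
#' @param sup Supervised loss value.
#' @param con Contrastive loss value.
#' @param alpha Nonnegative weight.
#' @return Scalar.
#' @export
total_loss <- function(sup, con, alpha = 1.0) {
  check_number(alpha, "alpha", min = 0)
  if (!is.finite(sup) || !is.finite(con)) stop2("loss components must be finite")
  sup + alpha * con
}

# ---------------------------------------------------------------------------
# training-internal gradients (logit-space where it matters for stability)

# dice + mu * bce gradient with respect to logits z, for p = sigmoid(z).
# pred p: (H, W, n); target y: (H, W, n). Returns (H, W, n) array, already
# scaled for the mean over the n samples.
supervised_grad_logits <- function(p, y, mu, epsilon) {
  d <- dim(p)
  m <- d[1] * d[2]
  n <- d[3]
  pm <- matrix(p, m, n)
  ym <- matrix(y, m, n)
  inter <- colSums(ym * pm)
  denom <- colSums(ym) + colSums(pm) + epsilon
  # d(dice_i)/dp_j = 2*inter/denom^2 - 2*y_j/denom
  ddice_dp <- rep(2 * inter / denom^2, each = m) -
    ym * rep(2 / denom, each = m)
  dz <- ddice_dp * pm * (1 - pm) / n + mu * (pm - ym) / (m * n)
  dim(dz) <- d
  dz
}

# contrastive loss value and gradient wrt the live embeddings.
# xi, xi_g, xi_b: (n x d) matrices. Returns list(loss, dxi) where loss is the
# batch mean and dxi is scaled for that mean.
contrastive_value_grad <- function(xi, xi_g, xi_b, tau, beta) {
  n <- nrow(xi)
  dxi <- matrix(0, n, ncol(xi))
  ls <- numeric(n)
  for (i in seq_len(n)) {
    v <- xi[i, ]
    g <- xi_g[i, ]
    b <- xi_b[i, ]
    nv <- sqrt(sum(v * v))
    ng <- sqrt(sum(g * g))
    nb <- sqrt(sum(b * b))
    if (nv == 0 || ng == 0 || nb == 0) {
      stop2("zero-norm embedding in contrastive loss")
    }
    s_g <- sum(v * g) / (nv * ng)
    s_b <- sum(v * b) / (nv * nb)
    z <- (s_b - s_g) / tau
    ls[i] <- beta * (if (z > 35) z else log1p(exp(z)))
    q <- beta * stats::plogis(z) / tau # dL/ds_b = q, dL/ds_g = -q
    dsg <- g / (nv * ng) - s_g * v / nv^2
    dsb <- b / (nv * nb) - s_b * v / nv^2
    dxi[i, ] <- q * (dsb - dsg)
  }
  list(loss = mean(ls), dxi = dxi / n)
}
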