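test_that("representation shape follows C = base * 2^depth, H' = H / 2^depth", {
  for (depth in 1:4) {
    net <- network_config(in_channels = 1, base_channels = 2, depth = depth)
    m <- build_model(net, seed = 1)
    x <- array(runif(32 * 32), c(32, 32, 1, 1))
    out <- forward_with_representation(m, x)
    expect_identical(
      dim(out$representation)[1:3],
      as.integer(c(32 / 2^depth, 32 / 2^depth, 2 * 2^depth))
    )
    expect_identical(dim(out$logits), as.integer(c(32, 32, 1, 1)))
  }
  # the spec-level example: depth 2, base 8, 64x64 input
  m <- build_model(network_config(base_channels = 8, depth = 2), seed = 1)
  out <- forward_with_representation(m, array(0.5, c(64, 64, 1, 3)))
  expect_identical(dim(out$representation), as.integer(c(16, 16, 32, 3)))
})

test_that("same seed gives bit-identical initialization and outputs", {
  net <- tiny_net(depth = 2)
  m1 <- build_model(net, seed = 42)
  m2 <- build_model(net, seed = 42)
  expect_identical(get_parameters(m1), get_parameters(m2))
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  expect_identical(
    forward_with_representation(m1, x),
    forward_with_representation(m2, x)
  )
  m3 <- build_model(net, seed = 43)
  expect_false(identical(get_parameters(m1), get_parameters(m3)))
})

test_that("total parameter count matches independent layer enumeration", {
  # depth 4, base 16, instance norm: enumerate layer shapes by hand
  b <- 16L
  d <- 4L
  count <- 0
  cin <- 1L
  for (i in 0:(d - 1)) {
    cw <- b * 2^i
    count <- count + (9 * cin * cw + cw) + 2 * cw # conv1 + norm1
    count <- count + (9 * cw * cw + cw) + 2 * cw # conv2 + norm2
    cin <- cw
  }
  cb <- b * 2^d
  count <- count + (9 * cin * cb + cb) + 2 * cb +
    (9 * cb * cb + cb) + 2 * cb
  for (i in (d - 1):0) {
    cw <- b * 2^i
    count <- count + (4 * (2 * cw) * cw + cw) # transposed conv
    count <- count + (9 * (2 * cw) * cw + cw) + 2 * cw
    count <- count + (9 * cw * cw + cw) + 2 * cw
  }
  count <- count + (1 * b * 1 + 1) # final 1x1 conv
  m <- build_model(network_config(base_channels = b, depth = d), seed = 1)
  expect_identical(n_parameters(m), as.integer(count))
})

test_that("get/set parameters round-trip is the identity and validates", {
  m <- build_model(tiny_net(depth = 2), seed = 3)
  p <- get_parameters(m)
  m2 <- set_parameters(m, p)
  expect_identical(get_parameters(m2), p)
  # changing a reachable parameter changes the output
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  base <- forward_with_representation(m, x)$logits
  p2 <- p
  p2[["final.bias"]] <- p2[["final.bias"]] + 1
  shifted <- forward_with_representation(set_parameters(m, p2), x)$logits
  expect_equal(max(abs(shifted - base - 1)), 0, tolerance = 1e-12)
  # shape mismatch and unknown names error
  bad <- p
  bad[["final.weight"]] <- array(0, c(2, 2, 2, 1))
  expect_error(set_parameters(m, bad), "shape mismatch")
  names(bad)[1] <- "nonexistent.layer"
  expect_error(set_parameters(m, bad), "names do not match")
})

test_that("zeroed final layer maps any input to the bias value", {
  m <- build_model(tiny_net(), seed = 1)
  p <- get_parameters(m)
  p[["final.weight"]] <- 0 * p[["final.weight"]]
  p[["final.bias"]] <- 0.37
  m <- set_parameters(m, p)
  out <- forward_with_representation(m, array(0, c(8, 8, 1, 2)))
  expect_true(all(abs(out$logits - 0.37) < 1e-12))
})

test_that("duplicated samples in a batch give identical rows (eval mode)", {
  m <- build_model(tiny_net(depth = 2), seed = 9)
  img <- matrix(runif(16 * 16), 16, 16)
  x <- array(0, c(16, 16, 1, 2))
  x[, , 1, 1] <- img
  x[, , 1, 2] <- img
  out <- forward_with_representation(m, x)
  expect_identical(out$logits[, , , 1], out$logits[, , , 2])
  expect_identical(out$representation[, , , 1], out$representation[, , , 2])
})

test_that("truncated (bridge-only) forward equals the full pass representation", {
  net <- tiny_net(depth = 2)
  m <- build_model(net, seed = 5)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  full <- pcrfed:::unet_forward(m$params, net, x, train = FALSE)
  trunc <- pcrfed:::unet_forward(m$params, net, x,
    train = FALSE,
    upto = "bridge"
  )
  expect_identical(full$representation, trunc$representation)
})

test_that("invalid input shapes are rejected at forward time", {
  m <- build_model(tiny_net(depth = 2), seed = 1)
  expect_error(
    forward_with_representation(m, array(0, c(10, 10, 1, 1))),
    "divisible"
  )
  expect_error(
    forward_with_representation(m, array(0, c(16, 16, 3, 1))),
    "channels"
  )
})

test_that("partition is a disjoint cover for any pattern list", {
  m <- build_model(network_config(base_channels = 4, depth = 2), seed = 1)
  nms <- names(get_parameters(m))
  for (pats in list(character(0), "*", "norm", c("conv1", "up"), "zzz")) {
    part <- partition_parameters(m, pats)
    expect_length(intersect(part$shared, part$personalized), 0)
    expect_setequal(c(part$shared, part$personalized), nms)
  }
  expect_length(partition_parameters(m, character(0))$personalized, 0)
  expect_setequal(partition_parameters(m, "*")$personalized, nms)
})

test_that("'norm' pattern selects exactly the normalization parameters", {
  m <- build_model(tiny_net(depth = 2), seed = 1)
  # independent enumeration of normalization-layer names for depth 2
  expected <- c(t(outer(
    c(
      "encoder.block0.norm1", "encoder.block0.norm2",
      "encoder.block1.norm1", "encoder.block1.norm2",
      "bridge.norm1", "bridge.norm2",
      "decoder.block1.norm1", "decoder.block1.norm2",
      "decoder.block0.norm1", "decoder.block0.norm2"
    ),
    c(".gamma", ".beta"), paste0
  )))
  part <- partition_parameters(m, "norm")
  expect_setequal(part$personalized, expected)
})

test_that("backpropagation matches central finite differences", {
  for (norm in c("instance", "batch", "none")) {
    net <- tiny_net(depth = 2, norm = norm)
    m <- build_model(net, seed = 3)
    params <- jitter_params(get_parameters(m), sd = 0.05)
    set.seed(21)
    x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
    y <- array(rbinom(8 * 8 * 2, 1, 0.35), c(8, 8, 2))
    pg <- get_parameters(m)
    pb <- jitter_params(pg, sd = 0.03, seed = 4)
    tau <- 0.5
    beta <- 0.7
    alpha <- 1.3
    loss_fn <- function(pp) {
      fw <- pcrfed:::unet_forward(pp, net, x, train = TRUE)
      p <- array(plogis(fw$logits), c(8, 8, 2))
      sup <- dice_loss(p, y) + bce_loss(p, y)
      xi <- site_embedding(fw$representation)
      xig <- site_embedding(
        pcrfed:::unet_forward(pg, net, x, upto = "bridge")$representation
      )
      xib <- site_embedding(
        pcrfed:::unet_forward(pb, net, x, upto = "bridge")$representation
      )
      sup + alpha * weighted_contrastive_loss(xi, xig, xib, tau, beta)
    }
    fw <- pcrfed:::unet_forward(params, net, x, train = TRUE, want_cache = TRUE)
    p <- array(plogis(fw$logits), c(8, 8, 2))
    dlog <- pcrfed:::supervised_grad_logits(p, y, 1, 1e-6)
    dim(dlog) <- c(8, 8, 1, 2)
    ef <- pcrfed:::embed_fwd(fw$representation)
    xig <- pcrfed:::embed_fwd(
      pcrfed:::unet_forward(pg, net, x, upto = "bridge")$representation
    )$xi
    xib <- pcrfed:::embed_fwd(
      pcrfed:::unet_forward(pb, net, x, upto = "bridge")$representation
    )$xi
    con <- pcrfed:::contrastive_value_grad(ef$xi, xig, xib, tau, beta)
    drep <- pcrfed:::embed_bwd(alpha * con$dxi, ef)
    grads <- pcrfed:::unet_backward(params, net, fw$cache, dlog, drep)
    h <- 1e-5
    set.seed(33)
    for (nm in sample(names(grads), 8)) {
      i <- sample(length(grads[[nm]]), 1)
      pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params
      pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (loss_fn(pp) - loss_fn(pm)) / (2 * h)
      expect_lt(
        abs(fd - grads[[nm]][i]) / max(1e-4, abs(fd)),
        1e-3
      )
    }
  }
})

test_that("checkpoints round-trip bit-exactly", {
  net <- tiny_net(depth = 1)
  m <- build_model(net, seed = 8)
  dir <- file.path(tempdir(), "ckpt_test")
  save_checkpoint(get_parameters(m), dir, net,
    round = 7, seed = 8,
    patterns = "norm"
  )
  ck <- load_checkpoint(dir)
  expect_identical(ck$params, get_parameters(m))
  expect_identical(ck$meta$round, 7L)
  expect_identical(ck$meta$network$depth, net$depth)
  expect_identical(ck$meta$partition_patterns, "norm")
  unlink(dir, recursive = TRUE)
})
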