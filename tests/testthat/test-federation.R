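test_that("broadcast overwrites exactly the shared names", {
  net <- tiny_net()
  m <- build_model(net, seed = 1)
  nms <- names(get_parameters(m))
  client <- list(id = 1, n_k = 5, params = get_parameters(m))
  global_full <- jitter_params(get_parameters(m), sd = 0.1, seed = 2)

  # empty personalized set: full overwrite
  part <- partition_parameters(nms, character(0))
  srv <- list(global_params = global_full[part$shared])
  cl2 <- broadcast_shared(srv, client, part)
  expect_identical(cl2$params, global_full[nms])

  # all personalized: no-op
  part <- partition_parameters(nms, "*")
  cl3 <- broadcast_shared(list(global_params = list()), client, part)
  expect_identical(cl3$params, client$params)

  # mixed: changed entries are the shared names exactly
  part <- partition_parameters(nms, "norm")
  srv <- list(global_params = global_full[part$shared])
  cl4 <- broadcast_shared(srv, client, part)
  changed <- nms[vapply(
    nms,
    function(nm) !identical(cl4$params[[nm]], client$params[[nm]]),
    logical(1)
  )]
  expect_setequal(changed, part$shared)
})

test_that("aggregation is the n_k/N weighted mean of shared entries", {
  net <- tiny_net()
  m <- build_model(net, seed = 1)
  nms <- names(get_parameters(m))
  part <- partition_parameters(nms, "norm")
  mk_client <- function(id, n_k, value) {
    p <- get_parameters(m)
    for (nm in nms) p[[nm]] <- array(value, dim(p[[nm]]) %||% length(p[[nm]]))
    list(id = id, n_k = n_k, params = p)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  # equal sizes, values 0 and 4: mean 2
  agg <- aggregate_shared(list(mk_client(1, 3, 0), mk_client(2, 3, 4)), part, 6)
  expect_true(all(vapply(agg, function(a) all(a == 2), logical(1))))

  # sizes 1 and 3, values 0 and 4: 0.25*0 + 0.75*4 = 3
  agg <- aggregate_shared(list(mk_client(1, 1, 0), mk_client(2, 3, 4)), part, 4)
  expect_true(all(vapply(agg, function(a) all(a == 3), logical(1))))

  # identical clients: fixed point
  c1 <- mk_client(1, 2, 0.7)
  agg <- aggregate_shared(list(c1, mk_client(2, 5, 0.7)), part, 7)
  expect_equal(agg, c1$params[part$shared], tolerance = 1e-12)

  # convex combination bound on random inputs, and weights summing to one
  set.seed(13)
  cls <- lapply(1:3, function(k) {
    list(
      id = k, n_k = k,
      params = jitter_params(get_parameters(m), sd = 0.5, seed = k)
    )
  })
  agg <- aggregate_shared(cls, part, 6)
  for (nm in part$shared) {
    lo <- pmin(
      cls[[1]]$params[[nm]], cls[[2]]$params[[nm]],
      cls[[3]]$params[[nm]]
    )
    hi <- pmax(
      cls[[1]]$params[[nm]], cls[[2]]$params[[nm]],
      cls[[3]]$params[[nm]]
    )
    expect_true(all(agg[[nm]] >= lo - 1e-12 & agg[[nm]] <= hi + 1e-12))
  }
  expect_error(aggregate_shared(cls, part, 0), "N")
})

test_that("personalized arrays are byte-identical across aggregation", {
  datasets <- tiny_sites()
  net <- tiny_net()
  fed <- tiny_fed(rounds = 1L, seed = 5)
  ini <- pcrfed:::init_federation(datasets, net, fed)
  before <- lapply(ini$clients, function(cl) cl$params[ini$partition$personalized])
  agg <- aggregate_shared(ini$clients, ini$partition, ini$server$N)
  expect_false(any(ini$partition$personalized %in% names(agg)))
  after <- lapply(ini$clients, function(cl) cl$params[ini$partition$personalized])
  expect_identical(before, after)
})

test_that("zero learning rate freezes parameters; alpha 0 collapses the loss", {
  datasets <- tiny_sites()
  net <- tiny_net()
  fed <- tiny_fed(rounds = 1L, learning_rate = 0, local_epochs = 2L, seed = 3)
  ini <- pcrfed:::init_federation(datasets, net, fed)
  up <- client_update(ini$clients[[1]], net, fed, round = 1, N = ini$server$N)
  expect_identical(up$client$params, ini$clients[[1]]$params)

  fed0 <- tiny_fed(rounds = 1L, loss = loss_config(alpha = 0), seed = 3)
  up0 <- client_update(ini$clients[[1]], net, fed0, round = 1, N = ini$server$N)
  expect_identical(up0$record$loss_total, up0$record$loss_sup)
  expect_true(all(up0$record$loss_con == 0))
})

test_that("previous-round cache equals the end-of-round parameters", {
  datasets <- tiny_sites()
  net <- tiny_net()
  fed <- tiny_fed(rounds = 2L, seed = 4)
  ini <- pcrfed:::init_federation(datasets, net, fed)
  expect_identical(ini$clients[[1]]$prev_params, ini$clients[[1]]$params)
  rr <- run_round(ini$server, ini$clients, ini$partition, net, fed)
  for (cl in rr$clients) expect_identical(cl$prev_params, cl$params)
})

test_that("first-round contrastive loss is the constant beta * log 2", {
  datasets <- tiny_sites(n_k = c(9L, 7L))
  net <- tiny_net()
  fed <- tiny_fed(rounds = 1L, seed = 6)
  ini <- pcrfed:::init_federation(datasets, net, fed)
  rr <- run_round(ini$server, ini$clients, ini$partition, net, fed)
  N <- ini$server$N
  for (k in seq_along(datasets)) {
    beta <- beta_weight(ini$clients[[k]]$n_k, N)
    expect_equal(rr$log$loss_con[k], beta * log(2), tolerance = 1e-9)
  }
})

test_that("single client with empty partition: global equals trained params", {
  datasets <- tiny_sites(n_k = 7L)
  net <- tiny_net()
  fed <- tiny_fed(rounds = 1L, partition_patterns = character(0), seed = 8)
  ini <- pcrfed:::init_federation(datasets, net, fed)
  rr <- run_round(ini$server, ini$clients, ini$partition, net, fed)
  expect_identical(
    rr$server$global_params,
    rr$clients[[1]]$params[ini$partition$shared]
  )
})

test_that("identical config and seed reproduce the identical run", {
  datasets <- tiny_sites()
  net <- tiny_net()
  fed <- tiny_fed(rounds = 2L, seed = 11, augment = TRUE)
  r1 <- run_federation(datasets, net, fed)
  r2 <- run_federation(datasets, net, fed)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$server$global_params, r2$server$global_params)
  for (k in seq_along(datasets)) {
    expect_identical(r1$clients[[k]]$params, r2$clients[[k]]$params)
  }
})

test_that("doubling local epochs halves the rounds needed for equal steps", {
  datasets <- tiny_sites(n_k = 9L)
  net <- tiny_net()
  ini <- pcrfed:::init_federation(datasets, net, tiny_fed(seed = 2))
  n <- ini$clients[[1]]$n_k # training-split size (9 raw samples -> 7 train)
  steps <- function(E, rounds, bs = 4L) {
    fed <- tiny_fed(local_epochs = E, batch_size = bs, seed = 2)
    total <- 0
    cl <- ini$clients[[1]]
    for (t in seq_len(rounds)) {
      up <- client_update(cl, net, fed, round = t, N = ini$server$N)
      cl <- up$client
      total <- total + nrow(up$record)
    }
    total
  }
  expect_identical(steps(E = 1, rounds = 4), steps(E = 2, rounds = 2))
  expect_equal(steps(E = 1, rounds = 2), 2 * ceiling(n / 4))
})

test_that("batch size larger than the split falls back to full batch", {
  datasets <- tiny_sites(n_k = 5L)
  net <- tiny_net()
  fed <- tiny_fed(rounds = 1L, batch_size = 64L, seed = 9)
  ini <- pcrfed:::init_federation(datasets, net, fed)
  up <- client_update(ini$clients[[1]], net, fed, round = 1, N = ini$server$N)
  expect_identical(nrow(up$record), 1L) # one full-batch step per epoch
})

test_that("run_federation with zero rounds returns the initial state", {
  datasets <- tiny_sites()
  net <- tiny_net()
  fed <- tiny_fed(rounds = 0L, seed = 10)
  run <- run_federation(datasets, net, fed)
  ini <- pcrfed:::init_federation(datasets, net, fed)
  expect_identical(run$server$global_params, ini$server$global_params)
  expect_identical(run$clients[[1]]$params, ini$clients[[1]]$params)
  expect_identical(nrow(run$log), 0L)
})

test_that("resuming from a checkpoint reproduces the uninterrupted trajectory", {
  datasets <- tiny_sites()
  net <- tiny_net()
  dir <- file.path(tempdir(), "resume_test")
  fed <- tiny_fed(rounds = 4L, seed = 12, checkpoint_every = 2L)
  full <- run_federation(datasets, net, fed, checkpoint_dir = dir)
  resumed <- run_federation(datasets, net, fed,
    resume_from = file.path(dir, "state_round_0002.rds")
  )
  expect_identical(full$server$global_params, resumed$server$global_params)
  for (k in seq_along(datasets)) {
    expect_identical(full$clients[[k]]$params, resumed$clients[[k]]$params)
  }
  expect_identical(
    full$log[full$log$round > 2, ],
    resumed$log[resumed$log$round > 2, ]
  )
  unlink(dir, recursive = TRUE)
})

test_that("tidy, glance and autoplot summarize a run", {
  datasets <- tiny_sites()
  net <- tiny_net()
  run <- run_federation(datasets, net, tiny_fed(rounds = 2L, seed = 13))
  td <- tidy(run)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 4L) # 2 rounds x 2 clients
  gl <- glance(run)
  expect_identical(gl$clients, 2L)
  expect_identical(gl$rounds, 2L)
  expect_true(gl$mean_val_dice >= 0 && gl$mean_val_dice <= 1)
  expect_s3_class(autoplot(run), "ggplot")
})
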