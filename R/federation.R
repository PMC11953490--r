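#' Federation configuration
#'
#' Hyperparameters of the federated optimization loop. Defaults mirror the
#' production setting (200 rounds, batch 32, Adam at 1e-4 with betas
#' (0.9, 0.999)); desk-scale runs typically lower `rounds` and raise
#' `learning_rate` (see the package vignette).
#'
#' @param rounds Number of communication rounds `T`.
#' @param local_epochs Local epochs `E` per client per round.
#' @param batch_size Minibatch size (a client with fewer training samples
#'   falls back to full-batch).
#' @param learning_rate Adam learning rate.
#' @param adam_betas Length-2 numeric, Adam `(beta1, beta2)`.
#' @param partition_patterns Patterns defining the personalized parameter set
#'   (see [partition_parameters()]); `character(0)` shares everything.
#' @param loss A [loss_config()].
#' @param seed Integer run seed; every RNG stream is derived from it.
#' @param augment Logical, apply random rotation/flip/crop to training batches.
#' @param threshold Probability threshold for validation Dice.
#' @param checkpoint_every Rounds between checkpoints (0 = never).
#' @return A `federation_config` object.
#' @export
federation_config <- function(rounds = 200L, local_epochs = 1L,
                              batch_size = 32L, learning_rate = 1e-4,
                              adam_betas = c(0.9, 0.999),
                              partition_patterns = "norm",
                              loss = loss_config(), seed = 1L,
                              augment = TRUE, threshold = 0.5,
                              checkpoint_every = 0L) {
  check_number(rounds, "rounds", min = 0)
  check_number(local_epochs, "local_epochs", min = 1)
  check_number(batch_size, "batch_size", min = 1)
  check_number(learning_rate, "learning_rate", min = 0)
  stopifnot(inherits(loss, "loss_config"), length(adam_betas) == 2)
  structure(
    list(
      rounds = as.integer(rounds), local_epochs = as.integer(local_epochs),
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      adam_betas = adam_betas,
      partition_patterns = as.character(partition_patterns),
      loss = loss, seed = as.integer(seed), augment = isTRUE(augment),
      threshold = threshold, checkpoint_every = as.integer(checkpoint_every)
    ),
    class = "federation_config"
  )
}

#' Copy the server's shared parameters into a client
#'
#' Overwrites the client's shared-partition entries with the global values;
#' personalized entries are untouched.
#'
#' @param server Server state (list with element `global_params`).
#' @param client Client state (list with element `params`).
#' @param partition A `parameter_partition`.
#' @return The updated client.
#' @export
broadcast_shared <- function(server, client, partition) {
  for (nm in partition$shared) {
    g <- server$global_params[[nm]]
    if (is.null(g)) stop2("server is missing shared parameter '", nm, "'")
    d0 <- dim(client$params[[nm]]) %||% length(client$params[[nm]])
    d1 <- dim(g) %||% length(g)
    if (!identical(as.integer(d0), as.integer(d1))) {
      stop2("shape mismatch broadcasting '", nm, "'")
    }
    client$params[[nm]] <- g
  }
  client
}

#' Aggregate shared parameters across clients (FedAvg)
#'
#' For every shared name, the new global value is the sample-size-weighted
#' mean `sum_k (n_k / N) * omega_k`. Personalized entries are never read.
#'
#' @param clients List of client states (elements `params`, `n_k`).
#' @param partition A `parameter_partition`.
#' @param N Total training-sample count `sum(n_k)`.
#' @return Named list: the new global shared parameters.
#' @export
aggregate_shared <- function(clients, partition, N) {
  check_number(N, "N", min = 0, strict = TRUE)
  w <- vapply(clients, function(cl) cl$n_k / N, numeric(1))
  out <- list()
  for (nm in partition$shared) {
    acc <- clients[[1]]$params[[nm]] * w[1]
    if (length(clients) > 1) {
      for (k in 2:length(clients)) {
        pk <- clients[[k]]$params[[nm]]
        d0 <- dim(acc) %||% length(acc)
        d1 <- dim(pk) %||% length(pk)
        if (!identical(as.integer(d0), as.integer(d1))) {
          stop2("inconsistent shapes for '", nm, "' across clients")
        }
        acc <- acc + pk * w[k]
      }
    }
    out[[nm]] <- acc
  }
  out
}

# assemble a list of samples into x (H, W, 1, n) and y (H, W, n)
stack_batch <- function(samples) {
  H <- nrow(samples[[1]]$image)
  W <- ncol(samples[[1]]$image)
  n <- length(samples)
  x <- array(0, c(H, W, 1L, n))
  y <- array(0, c(H, W, n))
  for (i in seq_len(n)) {
    x[, , 1L, i] <- samples[[i]]$image
    y[, , i] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

default_crop_size <- function(H, W) c(floor(H * 7 / 8), floor(W * 7 / 8))

#' One local client update (E epochs of Eq.-style total-loss minimization)
#'
#' Runs `local_epochs` of minibatch Adam on the client's training split.
#' The supervised term is Dice + mu * BCE on the live model's predictions.
#' When `alpha > 0`, each batch additionally passes through two frozen
#' evaluation-mode snapshots: the received global model (its shared part
#' merged over the client's own personalized part -- taken at entry, i.e.
#' immediately after broadcast) and the client's previous-round model. Their
#' pooled bridge embeddings anchor the weighted contrastive loss with
#' `beta = exp(-n_k / N)`; no gradient flows into either snapshot. After the
#' final epoch the previous-round cache is set to the newly updated
#' parameters. All parameters, shared and personalized, are updated locally.
#'
#' @param client Client state: list with `id`, `n_k`, `params`, `prev_params`,
#'   `opt`, `data` (a `list(train, val, test)` of samples).
#' @param net A [network_config()].
#' @param fed A [federation_config()].
#' @param round Communication-round index (seeds the data order).
#' @param N Federation-wide training-sample total.
#' @return List: updated `client` and `record`, a tibble with one row per
#'   optimizer step (`round`, `client`, `epoch`, `step`, `loss_sup`,
#'   `loss_con`, `loss_total`).
#' @export
client_update <- function(client, net, fed, round, N) {
  train <- client$data$train
  n <- length(train)
  if (n == 0) stop2("client ", client$id, " has an empty training split")
  alpha <- fed$loss$alpha
  mu <- fed$loss$mu
  tau <- fed$loss$tau
  epsl <- fed$loss$epsilon
  beta <- beta_weight(client$n_k, N)
  snap_global <- client$params # post-broadcast merged snapshot
  snap_prev <- client$prev_params
  bs <- min(fed$batch_size, n)
  H <- nrow(train[[1]]$image)
  W <- ncol(train[[1]]$image)
  crop <- default_crop_size(H, W)
  params <- client$params
  opt <- client$opt
  rec <- list()
  for (epoch in seq_len(fed$local_epochs)) {
    es <- derive_seed(fed$seed, round, client$id, epoch)
    with_seed(es, {
      perm <- sample.int(n)
      chunks <- split(perm, ceiling(seq_along(perm) / bs))
      for (si in seq_along(chunks)) {
        samples <- train[chunks[[si]]]
        if (fed$augment) {
          samples <- lapply(samples, augment_sample, crop_size = crop)
        }
        bt <- stack_batch(samples)
        nb <- length(samples)
        fw <- unet_forward(params, net, bt$x,
          train = TRUE,
          want_cache = TRUE
        )
        params <- fw$params # batch-norm running stats, if any
        p <- array(sigmoid(fw$logits), c(H, W, nb))
        loss_sup <- dice_loss(p, bt$y, epsl) + mu * bce_loss(p, bt$y, epsl)
        dlogits <- supervised_grad_logits(p, bt$y, mu, epsl)
        dim(dlogits) <- c(H, W, 1L, nb)
        drep <- NULL
        loss_con <- 0
        if (alpha > 0) {
          ef <- embed_fwd(fw$representation)
          rep_g <- unet_forward(snap_global, net, bt$x,
            train = FALSE,
            upto = "bridge"
          )$representation
          rep_b <- unet_forward(snap_prev, net, bt$x,
            train = FALSE,
            upto = "bridge"
          )$representation
          xi_g <- embed_fwd(rep_g)$xi
          xi_b <- embed_fwd(rep_b)$xi
          con <- contrastive_value_grad(ef$xi, xi_g, xi_b, tau, beta)
          loss_con <- con$loss
          drep <- embed_bwd(alpha * con$dxi, ef)
        }
        grads <- unet_backward(params, net, fw$cache, dlogits, drep)
        st <- adam_step(params, grads, opt, fed$learning_rate,
          fed$adam_betas
        )
        params <- st$params
        opt <- st$state
        rec[[length(rec) + 1]] <- list(
          round = round, client = client$id, epoch = epoch, step = si,
          loss_sup = loss_sup, loss_con = loss_con,
          loss_total = loss_sup + alpha * loss_con
        )
      }
    })
  }
  client$params <- params
  client$opt <- opt
  client$prev_params <- params
  list(client = client, record = dplyr::bind_rows(lapply(rec, tibble::as_tibble)))
}

# mean Dice of a parameter set over a list of samples (evaluation mode)
eval_dice <- function(params, net, samples, threshold = 0.5,
                      batch_size = 32L) {
  if (length(samples) == 0) stop2("empty evaluation split")
  n <- length(samples)
  scores <- numeric(n)
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  for (ch in idx) {
    bt <- stack_batch(samples[ch])
    fw <- unet_forward(params, net, bt$x, train = FALSE)
    p <- array(sigmoid(fw$logits), dim(bt$y))
    for (j in seq_along(ch)) {
      pred <- (p[, , j] >= threshold) * 1
      scores[ch[j]] <- dice_score(pred, bt$y[, , j])
    }
  }
  mean(scores)
}

#' Run one communication round
#'
#' Broadcast shared parameters to every client, run all local updates (full
#' participation, ascending client id), aggregate the shared partition, and
#' advance the round counter. The returned log holds each client's mean
#' training losses over the round and its validation Dice after the update.
#'
#' @param server Server state (`round`, `global_params`, `N`).
#' @param clients List of client states.
#' @param partition A `parameter_partition`.
#' @param net A [network_config()].
#' @param fed A [federation_config()].
#' @return List `server`, `clients`, `log` (tibble: `round`, `client`, `n_k`,
#'   `loss_sup`, `loss_con`, `loss_total`, `dice_val`).
#' @export
run_round <- function(server, clients, partition, net, fed) {
  t_now <- server$round + 1L
  clients <- lapply(clients, broadcast_shared,
    server = server,
    partition = partition
  )
  logs <- vector("list", length(clients))
  for (k in seq_along(clients)) {
    up <- client_update(clients[[k]], net, fed, round = t_now, N = server$N)
    clients[[k]] <- up$client
    dice_val <- eval_dice(
      clients[[k]]$params, net, clients[[k]]$data$val,
      fed$threshold, fed$batch_size
    )
    logs[[k]] <- tibble::tibble(
      round = t_now, client = clients[[k]]$id, n_k = clients[[k]]$n_k,
      loss_sup = mean(up$record$loss_sup),
      loss_con = mean(up$record$loss_con),
      loss_total = mean(up$record$loss_total),
      dice_val = dice_val
    )
  }
  server$global_params <- aggregate_shared(clients, partition, server$N)
  server$round <- t_now
  list(server = server, clients = clients, log = dplyr::bind_rows(logs))
}

init_federation <- function(datasets, net, fed) {
  model <- build_model(net, seed = fed$seed)
  partition <- partition_parameters(model, fed$partition_patterns)
  clients <- lapply(seq_along(datasets), function(k) {
    ds <- datasets[[k]]
    if (is.null(ds$train)) stop2("dataset ", k, " lacks a train split")
    list(
      id = k, n_k = length(ds$train), params = model$params,
      prev_params = model$params, opt = adam_init(model$params), data = ds
    )
  })
  N <- sum(vapply(clients, `[[`, integer(1), "n_k"))
  server <- list(
    round = 0L,
    global_params = model$params[partition$shared], N = N
  )
  list(
    server = server, clients = clients, partition = partition,
    model = model
  )
}

#' Run a full federated training session
#'
#' Initializes all clients from one seeded model, then runs `fed$rounds`
#' communication rounds of [run_round()]. The previous-round parameter cache
#' starts at the initial global model, which makes the contrastive term an
#' inert constant (`beta * log 2`) in the first round. Identical
#' `(datasets, net, fed)` inputs always reproduce the identical log and
#' parameter trajectory.
#'
#' @param datasets List with one `list(train, val, test)` of samples per
#'   client, e.g. from [fixture_datasets()].
#' @param net A [network_config()].
#' @param fed A [federation_config()].
#' @param log_path Optional path; per-round JSON-lines records are appended.
#' @param checkpoint_dir Optional directory for checkpoints every
#'   `fed$checkpoint_every` rounds (plus a resumable full-state snapshot).
#' @param resume_from Optional path to a full-state snapshot written by a
#'   previous run; training continues from its round counter with an
#'   identical trajectory to an uninterrupted run.
#' @param verbose Print one progress line per round.
#' @return A `pcr_fed` object: list with `server`, `clients`, `partition`,
#'   `net`, `fed` and `log` (tibble of per-round, per-client records).
#' @export
run_federation <- function(datasets, net = network_config(),
                           fed = federation_config(), log_path = NULL,
                           checkpoint_dir = NULL, resume_from = NULL,
                           verbose = FALSE) {
  if (!is.null(resume_from)) {
    state <- readRDS(resume_from)
    server <- state$server
    clients <- state$clients
    partition <- state$partition
    for (k in seq_along(datasets)) clients[[k]]$data <- datasets[[k]]
    log <- state$log
  } else {
    ini <- init_federation(datasets, net, fed)
    server <- ini$server
    clients <- ini$clients
    partition <- ini$partition
    log <- NULL
  }
  if (!is.null(log_path) && is.null(resume_from) && file.exists(log_path)) {
    unlink(log_path)
  }
  while (server$round < fed$rounds) {
    rr <- run_round(server, clients, partition, net, fed)
    server <- rr$server
    clients <- rr$clients
    log <- dplyr::bind_rows(log, rr$log)
    if (!is.null(log_path)) append_jsonl(rr$log, log_path)
    if (verbose) {
      message(sprintf(
        "round %3d  mean val Dice %.4f", server$round,
        mean(rr$log$dice_val)
      ))
    }
    if (!is.null(checkpoint_dir) && fed$checkpoint_every > 0 &&
      server$round %% fed$checkpoint_every == 0) {
      write_round_checkpoints(
        checkpoint_dir, server, clients, partition,
        net, fed, log
      )
    }
  }
  structure(
    list(
      server = server, clients = clients, partition = partition,
      net = net, fed = fed, log = log %||% tibble::tibble()
    ),
    class = "pcr_fed"
  )
}

#' @export
print.pcr_fed <- function(x, ...) {
  cat(sprintf(
    "<pcr_fed> %d clients, %d/%d rounds, alpha = %g, %d shared / %d personalized arrays\n",
    length(x$clients), x$server$round, x$fed$rounds, x$fed$loss$alpha,
    length(x$partition$shared), length(x$partition$personalized)
  ))
  if (nrow(x$log)) {
    last <- x$log[x$log$round == max(x$log$round), ]
    cat(sprintf("final mean validation Dice: %.4f\n", mean(last$dice_val)))
  }
  invisible(x)
}

#' Final personalized parameters of one client
#'
#' The deployed model for client `k`: the aggregated global shared part
#' merged over the client's own personalized part.
#'
#' @param run A `pcr_fed` object.
#' @param k Client index.
#' @return Named parameter list.
#' @export
final_client_params <- function(run, k) {
  params <- run$clients[[k]]$params
  for (nm in run$partition$shared) {
    params[[nm]] <- run$server$global_params[[nm]]
  }
  params
}
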