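#' Dice overlap score between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. When both masks are empty the score is
#' defined as 1 (evaluation convention: a correctly predicted absent
#' foreground is a perfect prediction).
#'
#' @param pred_mask,target_mask Binary (0/1) matrices or arrays of equal
#'   shape.
#' @return Scalar in `[0, 1]`, symmetric in its arguments.
#' @examples
#' a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
#' dice_score(a, a) # 1
#' @export
dice_score <- function(pred_mask, target_mask) {
  if (!identical(dim(pred_mask), dim(target_mask))) {
    stop2("mask shapes differ")
  }
  if (!all(pred_mask %in% c(0, 1)) || !all(target_mask %in% c(0, 1))) {
    stop2("masks must be binary (0/1)")
  }
  sp <- sum(pred_mask)
  st <- sum(target_mask)
  if (sp + st == 0) {
    return(1)
  }
  2 * sum(pred_mask * target_mask) / (sp + st)
}

#' Mean Dice of a model over a dataset split
#'
#' Runs the model in evaluation mode, thresholds `sigmoid(logits)` at
#' `threshold`, and averages the per-sample [dice_score()].
#'
#' @param model A `unet_model`, or a list with elements `params` and a
#'   [network_config()] under `config`/`net`.
#' @param samples List of samples (`list(image, mask)`).
#' @param threshold Probability threshold (default 0.5).
#' @return Mean Dice in `[0, 1]`.
#' @export
evaluate_client <- function(model, samples, threshold = 0.5) {
  net <- model$config %||% model$net
  eval_dice(model$params, net, samples, threshold)
}

#' Per-client evaluation of a finished federated run
#'
#' Evaluates each client's final personalized model (global shared part plus
#' the client's personalized part, see [final_client_params()]) on the chosen
#' split of that client's own data.
#'
#' @param run A `pcr_fed` object.
#' @param split `"test"` (default), `"val"` or `"train"`.
#' @param threshold Probability threshold.
#' @return Tibble: `client`, `n_k`, `dice`. The unweighted mean over clients
#'   is the conventional "average" summary.
#' @export
evaluate_run <- function(run, split = c("test", "val", "train"),
                         threshold = NULL) {
  split <- match.arg(split)
  threshold <- threshold %||% run$fed$threshold
  rows <- purrr::map(run$clients, function(cl) {
    params <- final_client_params(run, cl$id)
    tibble::tibble(
      client = cl$id, n_k = cl$n_k,
      dice = eval_dice(params, run$net, cl$data[[split]], threshold)
    )
  })
  dplyr::bind_rows(rows)
}

#' Train and evaluate a reference baseline
#'
#' `"fedavg"` is federated averaging: the contrastive weight is forced to 0
#' and the personalized partition emptied, so every round is plain broadcast /
#' supervised local training / weighted aggregation. `"local_only"` trains
#' each client alone with no communication, on a matched step budget
#' (`rounds * local_epochs` local epochs, i.e. the same number of gradient
#' steps per client as the federated runs).
#'
#' @param kind `"fedavg"` or `"local_only"`.
#' @param datasets Per-client datasets, as for [run_federation()].
#' @param net A [network_config()].
#' @param fed A [federation_config()]; the same config (and seed) used for the
#'   personalized run it is compared against.
#' @param split Evaluation split.
#' @return Tibble: `method`, `client`, `n_k`, `dice`.
#' @export
run_baseline <- function(kind = c("fedavg", "local_only"), datasets,
                         net = network_config(), fed = federation_config(),
                         split = "test") {
  kind <- match.arg(kind)
  if (kind == "fedavg") {
    fed$loss$alpha <- 0
    fed$partition_patterns <- character(0)
    run <- run_federation(datasets, net, fed)
    out <- evaluate_run(run, split)
  } else {
    fed_local <- fed
    fed_local$loss$alpha <- 0
    ini <- init_federation(datasets, net, fed_local)
    rows <- purrr::map(ini$clients, function(cl) {
      for (t in seq_len(fed_local$rounds)) {
        cl <- client_update(cl, net, fed_local, round = t, N = ini$server$N)$client
      }
      tibble::tibble(
        client = cl$id, n_k = cl$n_k,
        dice = eval_dice(
          cl$params, net, cl$data[[split]],
          fed_local$threshold
        )
      )
    })
    out <- dplyr::bind_rows(rows)
  }
  dplyr::mutate(out, method = kind, .before = 1)
}

#' Hyperparameter sweep
#'
#' Runs one full federated session per value of the swept parameter, holding
#' the seed and everything else fixed, and evaluates each run on the test
#' split. `alpha` and `tau` address the loss configuration; `local_epochs`
#' the federation configuration.
#'
#' @param parameter `"alpha"`, `"tau"` or `"local_epochs"`.
#' @param values Numeric vector of parameter values (nonempty).
#' @param datasets Per-client datasets.
#' @param net A [network_config()].
#' @param fed Base [federation_config()].
#' @return A `pcr_sweep` tibble: `parameter`, `value`, `client`, `n_k`,
#'   `dice`.
#' @export
sweep_hyperparameter <- function(parameter = c("alpha", "tau", "local_epochs"),
                                 values, datasets, net = network_config(),
                                 fed = federation_config()) {
  parameter <- match.arg(parameter)
  if (length(values) == 0) stop2("values must be nonempty")
  rows <- purrr::map(values, function(v) {
    fv <- fed
    if (parameter == "alpha") {
      fv$loss$alpha <- v
    } else if (parameter == "tau") {
      fv$loss$tau <- v
    } else {
      fv$local_epochs <- as.integer(v)
    }
    run <- run_federation(datasets, net, fv)
    dplyr::mutate(evaluate_run(run, "test"),
      parameter = parameter,
      value = v, .before = 1
    )
  })
  structure(dplyr::bind_rows(rows), class = c("pcr_sweep", "tbl_df", "tbl",
    "data.frame"
  ))
}
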