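# round-log serialization and checkpointing

# append one JSON record per row; fixed column order and 10 significant
# digits so identical runs give byte-identical files
append_jsonl <- function(log, path) {
  con <- file(path, open = "a")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    row <- as.list(log[i, c(
      "round", "client", "n_k", "loss_sup",
      "loss_con", "loss_total", "dice_val"
    )])
    writeLines(
      jsonlite::toJSON(row, auto_unbox = TRUE, digits = 10),
      con
    )
  }
  invisible(path)
}

#' Write the round-log CSV summary
#'
#' One row per round: the unweighted mean validation Dice plus one column per
#' client.
#'
#' @param log Round-log tibble (as in a `pcr_fed` object's `log`).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_log_csv <- function(log, path) {
  wide <- dplyr::summarise(
    dplyr::group_by(log, .data$round),
    mean_dice = mean(.data$dice_val),
    .groups = "drop"
  )
  for (k in sort(unique(log$client))) {
    wide[[paste0("dice_client_", k)]] <-
      log$dice_val[log$client == k][order(log$round[log$client == k])]
  }
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a parameter checkpoint
#'
#' A checkpoint is a directory holding `params.rds` (the named parameter
#' arrays, bit-exact) and `meta.json` (network configuration, partition
#' patterns, round index, seed). `load_checkpoint()` restores both;
#' the round-trip is exact.
#'
#' @param params Named list of parameter arrays.
#' @param path Checkpoint directory (created if needed).
#' @param net A [network_config()].
#' @param round Round index to record.
#' @param seed Run seed to record.
#' @param patterns Personalized-partition patterns to record.
#' @return `save_checkpoint()`: the path, invisibly. `load_checkpoint()`:
#'   list with `params` and `meta`.
#' @export
save_checkpoint <- function(params, path, net, round = 0L, seed = 1L,
                            patterns = character(0)) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  saveRDS(params, file.path(path, "params.rds"))
  meta <- list(
    network = unclass(net), partition_patterns = as.character(patterns),
    round = as.integer(round), seed = as.integer(seed)
  )
  writeLines(
    jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
    file.path(path, "meta.json")
  )
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  params <- readRDS(file.path(path, "params.rds"))
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
  nc <- meta$network
  meta$network <- network_config(
    in_channels = nc$in_channels, base_channels = nc$base_channels,
    depth = nc$depth, norm_kind = nc$norm_kind, out_channels = nc$out_channels
  )
  list(params = params, meta = meta)
}

# per-round checkpoint set: global + one per client + resumable full state
write_round_checkpoints <- function(dir, server, clients, partition, net,
                                    fed, log) {
  t <- server$round
  base <- file.path(dir, sprintf("round_%04d_global", t))
  save_checkpoint(server$global_params, base, net,
    round = t,
    seed = fed$seed, patterns = partition$patterns
  )
  for (cl in clients) {
    save_checkpoint(
      cl$params,
      file.path(dir, sprintf("round_%04d_client_%d", t, cl$id)), net,
      round = t, seed = fed$seed, patterns = partition$patterns
    )
  }
  state <- list(
    server = server,
    clients = lapply(clients, function(cl) {
      cl$data <- NULL # datasets are reattached on resume
      cl
    }),
    partition = partition, net = net, fed = fed, log = log
  )
  saveRDS(state, file.path(dir, sprintf("state_round_%04d.rds", t)))
  invisible(dir)
}
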