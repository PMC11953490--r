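# Adam optimizer over a named list of parameter arrays.

adam_init <- function(params) {
  # 0 * p keeps each array's dim attribute (and plain vectors plain)
  list(
    m = lapply(params, function(p) 0 * p),
    v = lapply(params, function(p) 0 * p),
    t = 0L
  )
}

# one Adam step; only names present in `grads` are updated (running
# normalization statistics carry no gradient and are left untouched).
adam_step <- function(params, grads, state, lr, betas = c(0.9, 0.999),
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]
  b2 <- betas[2]
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
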