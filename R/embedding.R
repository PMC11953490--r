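#' Parameter-free site embedding of a bridge representation
#'
#' Maps a latent representation `R(x)` to a fixed-length vector by spatial
#' pooling per channel: the first `C` entries are channel-wise spatial
#' averages, the last `C` entries channel-wise spatial maxima (fusion
#' `"concat"`, the default, length `2C`). Fusion `"sum"` adds the two
#' statistics element-wise (length `C`). The layer has no learned parameters;
#' it exists so the contrastive loss can compare models through a compact,
#' permutation-invariant summary of the bridge features.
#'
#' @param r Representation array: `(H', W', C)` for one sample or
#'   `(H', W', C, N)` for a batch.
#' @param fusion `"concat"` (default) or `"sum"`.
#' @return A numeric vector (single sample) or an `N x d` matrix with one
#'   embedding per row (`d = 2C` for concat, `C` for sum).
#' @examples
#' r <- array(2, c(3, 3, 4))
#' site_embedding(r) # eight entries, all 2
#' @export
site_embedding <- function(r, fusion = c("concat", "sum")) {
  fusion <- match.arg(fusion)
  single <- length(dim(r)) == 3
  if (single) dim(r) <- c(dim(r), 1L)
  if (length(dim(r)) != 4) stop2("r must be (H', W', C) or (H', W', C, N)")
  d <- dim(r)
  if (d[1] < 1 || d[2] < 1) stop2("empty spatial extent")
  emb <- embed_fwd(r)$xi
  if (fusion == "sum") {
    C <- d[3]
    emb <- emb[, seq_len(C), drop = FALSE] +
      emb[, C + seq_len(C), drop = FALSE]
  }
  if (single) emb[1, ] else emb
}

# internal: concat embedding with cache for the backward pass.
# r: (H', W', C, N) -> xi: (N x 2C); amax: linear argmax per (channel, sample)
embed_fwd <- function(r) {
  d <- dim(r)
  m <- d[1] * d[2]
  C <- d[3]
  N <- d[4]
  rm_ <- matrix(r, m, C * N)
  avg <- colMeans(rm_)
  amax <- max.col(t(rm_), ties.method = "first")
  mx <- rm_[cbind(amax, seq_len(C * N))]
  xi <- cbind(
    t(matrix(avg, C, N)),
    t(matrix(mx, C, N))
  )
  list(xi = xi, amax = amax, d = d)
}

# dxi: (N x 2C) -> gradient wrt r, (H', W', C, N)
embed_bwd <- function(dxi, cache) {
  d <- cache$d
  m <- d[1] * d[2]
  C <- d[3]
  N <- d[4]
  davg <- as.vector(t(dxi[, seq_len(C), drop = FALSE])) # per (c, n) column
  dmax <- as.vector(t(dxi[, C + seq_len(C), drop = FALSE]))
  dr <- matrix(rep(davg / m, each = m), m, C * N)
  dr[cbind(cache$amax, seq_len(C * N))] <-
    dr[cbind(cache$amax, seq_len(C * N))] + dmax
  dim(dr) <- d
  dr
}
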