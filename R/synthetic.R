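#' Synthetic-site profile
#'
#' Describes one simulated imaging site. Sites differ in background level,
#' foreground intensity, noise, organ-shape family and size range, emulating
#' the two non-IID axes of multi-site medical data: intensity-distribution
#' shift and quantity skew.
#'
#' @param site_id Integer site index.
#' @param n_k Number of image/mask pairs the site holds.
#' @param intensity_mean Foreground mean intensity before normalization,
#'   in (0, 1).
#' @param intensity_shift Site-specific background level.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param shape_family `"ellipse"` (random oriented ellipse) or `"blob"`
#'   (ellipse-free star-convex shape with smooth radial perturbation).
#' @param size_range Length-2 vector: min/max shape radius in pixels.
#' @param image_size Length-2 vector `(H, W)`; must stay divisible by
#'   `2^depth` of the paired network.
#' @param seed Integer seed; a profile fully determines its samples.
#' @return A `site_profile` object.
#' @export
site_profile <- function(site_id, n_k, intensity_mean = 0.8,
                         intensity_shift = 0.2, noise_sd = 0.05,
                         shape_family = c("ellipse", "blob"),
                         size_range = c(8, 16), image_size = c(64, 64),
                         seed = 1L) {
  shape_family <- match.arg(shape_family)
  check_number(n_k, "n_k", min = 1)
  check_number(noise_sd, "noise_sd", min = 0)
  if (length(size_range) != 2 || size_range[1] > size_range[2] ||
    size_range[1] <= 0) {
    stop2("size_range must be an increasing positive interval")
  }
  if (max(size_range) * 2 + 4 > min(image_size)) {
    stop2("size_range too large for image_size")
  }
  structure(
    list(
      site_id = as.integer(site_id), n_k = as.integer(n_k),
      intensity_mean = intensity_mean, intensity_shift = intensity_shift,
      noise_sd = noise_sd, shape_family = shape_family,
      size_range = size_range, image_size = as.integer(image_size),
      seed = as.integer(seed)
    ),
    class = "site_profile"
  )
}

# one random foreground mask (H x W, values 0/1), nonempty by construction
random_shape_mask <- function(H, W, shape_family, size_range) {
  rmax <- size_range[2]
  cy <- runif(1, rmax + 2, H - rmax - 1)
  cx <- runif(1, rmax + 2, W - rmax - 1)
  a <- runif(1, size_range[1], size_range[2])
  b <- runif(1, size_range[1], size_range[2])
  th <- runif(1, 0, pi)
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  if (shape_family == "ellipse") {
    u <- (xx * cos(th) + yy * sin(th)) / a
    v <- (-xx * sin(th) + yy * cos(th)) / b
    mask <- (u^2 + v^2) <= 1
  } else {
    # star-convex blob: base radius modulated by low-order harmonics
    r0 <- (a + b) / 2
    amp <- runif(3, 0, 0.25)
    ph <- runif(3, 0, 2 * pi)
    ang <- atan2(yy, xx)
    rad <- sqrt(xx^2 + yy^2)
    rfun <- r0 * (1 + amp[1] * cos(2 * ang + ph[1]) +
      amp[2] * cos(3 * ang + ph[2]) +
      amp[3] * cos(4 * ang + ph[3]))
    mask <- rad <= pmax(rfun, 1)
  }
  mask * 1
}

#' Generate one site's raw samples
#'
#' Produces `n_k` image/mask pairs: background pixels at
#' `intensity_shift + N(0, noise_sd)`, one random foreground shape filled at
#' `intensity_mean + N(0, noise_sd)`, mask equal to the shape support. Images
#' are *pre-normalization*; pass them through [normalize_sample()] (or use
#' [make_site_dataset()]) before feeding a model. Fully determined by the
#' profile's seed.
#'
#' @param profile A [site_profile()].
#' @return List of `n_k` samples, each `list(image = matrix, mask = matrix)`
#'   with a nonempty binary mask.
#' @export
generate_site <- function(profile) {
  stopifnot(inherits(profile, "site_profile"))
  H <- profile$image_size[1]
  W <- profile$image_size[2]
  lapply(seq_len(profile$n_k), function(i) {
    with_seed(derive_seed(profile$seed, profile$site_id, i), {
      mask <- random_shape_mask(
        H, W, profile$shape_family,
        profile$size_range
      )
      img <- matrix(profile$intensity_shift, H, W)
      img[mask == 1] <- profile$intensity_mean
      if (profile$noise_sd > 0) {
        img <- img + matrix(rnorm(H * W, sd = profile$noise_sd), H, W)
      }
      list(image = img, mask = mask)
    })
  })
}

#' Min-max normalize an image to `[0, 1]`
#'
#' Per-sample rescaling `(x - min) / (max - min)`; a constant image maps to
#' all zeros (the degenerate case has no information to preserve and zero
#' avoids division by zero).
#'
#' @param image Numeric matrix with finite values.
#' @return Matrix with values in `[0, 1]`.
#' @export
normalize_sample <- function(image) {
  if (!all(is.finite(image))) stop2("image must contain finite values")
  rng <- range(image)
  if (rng[1] == rng[2]) {
    return(matrix(0, nrow(image), ncol(image)))
  }
  (image - rng[1]) / (rng[2] - rng[1])
}

# ---------------------------------------------------------------------------
# geometric augmentation

# rotate about the image center ((H+1)/2, (W+1)/2) by `angle` degrees.
# bilinear for continuous images, nearest for masks; out-of-range fills 0.
rotate_image <- function(img, angle, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(img)
  W <- ncol(img)
  th <- angle * pi / 180
  cy <- (H + 1) / 2
  cx <- (W + 1) / 2
  di <- matrix(seq_len(H), H, W) - cy
  dj <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  si <- cy + cos(th) * di + sin(th) * dj
  sj <- cx - sin(th) * di + cos(th) * dj
  out <- matrix(0, H, W)
  if (method == "nearest") {
    ri <- round(si)
    rj <- round(sj)
    ok <- ri >= 1 & ri <= H & rj >= 1 & rj <= W
    out[ok] <- img[cbind(ri[ok], rj[ok])]
    return(out)
  }
  i0 <- floor(si)
  j0 <- floor(sj)
  fi <- si - i0
  fj <- sj - j0
  val <- function(ii, jj) {
    ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
    v <- matrix(0, H, W)
    v[ok] <- img[cbind(ii[ok], jj[ok])]
    v
  }
  out <- (1 - fi) * (1 - fj) * val(i0, j0) +
    fi * (1 - fj) * val(i0 + 1, j0) +
    (1 - fi) * fj * val(i0, j0 + 1) +
    fi * fj * val(i0 + 1, j0 + 1)
  out
}

#' Apply a fixed geometric transform to a sample
#'
#' Deterministic core of the augmentation pipeline: rotation (image bilinear,
#' mask nearest-neighbor, re-binarized), then horizontal flip, then crop to
#' `crop_size` at `crop_offset` padded back to the original size with zeros at
#' the same location. Image and mask receive identical geometry.
#'
#' @param sample `list(image, mask)`.
#' @param angle Rotation in degrees (0 = none).
#' @param flip Logical horizontal flip.
#' @param crop_size Length-2 `(h, w)` crop window, or `NULL` to skip cropping.
#' @param crop_offset Length-2 0-based `(top, left)` offset of the window.
#' @return Transformed sample.
#' @export
transform_sample <- function(sample, angle = 0, flip = FALSE,
                             crop_size = NULL, crop_offset = c(0, 0)) {
  img <- sample$image
  mask <- sample$mask
  H <- nrow(img)
  W <- ncol(img)
  if (angle != 0) {
    img <- rotate_image(img, angle, "bilinear")
    mask <- (rotate_image(mask, angle, "nearest") >= 0.5) * 1
  }
  if (flip) {
    img <- img[, W:1]
    mask <- mask[, W:1]
  }
  if (!is.null(crop_size)) {
    ch <- crop_size[1]
    cw <- crop_size[2]
    if (ch > H || cw > W) stop2("crop larger than image")
    t0 <- crop_offset[1]
    l0 <- crop_offset[2]
    if (t0 < 0 || l0 < 0 || t0 + ch > H || l0 + cw > W) {
      stop2("crop window out of bounds")
    }
    keep_i <- (t0 + 1):(t0 + ch)
    keep_j <- (l0 + 1):(l0 + cw)
    im2 <- matrix(0, H, W)
    mk2 <- matrix(0, H, W)
    im2[keep_i, keep_j] <- img[keep_i, keep_j]
    mk2[keep_i, keep_j] <- mask[keep_i, keep_j]
    img <- im2
    mask <- mk2
  }
  list(image = img, mask = mask)
}

#' Randomly augment a training sample
#'
#' Draws, from the current RNG stream: a rotation angle uniform in
#' `[-max_angle, max_angle]` degrees, a horizontal flip with probability
#' `flip_prob`, and a random crop window of size `crop_size` (padded back to
#' the original size), then applies them via [transform_sample()].
#'
#' @inheritParams transform_sample
#' @param max_angle Maximum absolute rotation in degrees (default 10).
#' @param flip_prob Probability of a horizontal flip (default 0.5).
#' @param crop_size `(h, w)` crop window, `NULL` (default) to skip cropping.
#' @return Augmented sample.
#' @export
augment_sample <- function(sample, max_angle = 10, flip_prob = 0.5,
                           crop_size = NULL) {
  angle <- runif(1, -max_angle, max_angle)
  flip <- runif(1) < flip_prob
  off <- c(0, 0)
  if (!is.null(crop_size)) {
    H <- nrow(sample$image)
    W <- ncol(sample$image)
    off <- c(
      sample.int(H - crop_size[1] + 1L, 1L) - 1L,
      sample.int(W - crop_size[2] + 1L, 1L) - 1L
    )
  }
  transform_sample(sample, angle = angle, flip = flip, crop_size = crop_size,
    crop_offset = off
  )
}

#' Split samples into train/validation/test sets
#'
#' Seeded random permutation, then `floor(ratio_val * n)` validation samples,
#' `floor(ratio_test * n)` test samples and the remainder for training (the
#' 7 : 1.5 : 1.5 convention by default).
#'
#' @param samples List of samples.
#' @param ratios Length-3 numeric `(train, val, test)` summing to 1.
#' @param seed Integer seed for the permutation.
#' @return `list(train =, val =, test =)`, pairwise disjoint, jointly equal to
#'   the input set.
#' @export
split_dataset <- function(samples, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  n <- length(samples)
  if (n < 3) stop2("need at least 3 samples to split")
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-8) {
    stop2("ratios must be three numbers summing to 1")
  }
  n_val <- floor(ratios[2] * n)
  n_test <- floor(ratios[3] * n)
  perm <- with_seed(derive_seed(seed, 7919L), sample.int(n))
  n_train <- n - n_val - n_test
  list(
    train = samples[perm[seq_len(n_train)]],
    val = samples[perm[n_train + seq_len(n_val)]],
    test = samples[perm[n_train + n_val + seq_len(n_test)]]
  )
}

#' Packaged multi-site fixtures
#'
#' Site-count fixtures for desk-scale experiments. `"prostate_counts"` mirrors
#' the per-site sample counts of a public six-site prostate MRI collection
#' (421, 384, 468, 175, 261, 158); `"cervical_counts"` mirrors an eight-center
#' cervical CT cohort (255, 219, 197, 129, 41, 43, 76, 73; total 1033);
#' `"toy4"` is a four-site benchmark (60, 50, 30, 20) small enough for CPU
#' test runs. Intensity parameters are spread across sites so the generated
#' marginal pixel distributions are measurably non-IID; the counts are the
#' quantity-skew axis.
#'
#' @param name One of `"prostate_counts"`, `"cervical_counts"`, `"toy4"`.
#' @param seed Base seed stored in the profiles.
#' @param image_size Image size passed to every profile.
#' @return List of [site_profile()]s.
#' @examples
#' sum(vapply(build_fixture("cervical_counts"), `[[`, integer(1), "n_k"))
#' @export
build_fixture <- function(name = c("toy4", "prostate_counts",
                            "cervical_counts"),
                          seed = 1L, image_size = c(64, 64)) {
  name <- match.arg(name)
  counts <- switch(name,
    prostate_counts = c(421L, 384L, 468L, 175L, 261L, 158L),
    cervical_counts = c(255L, 219L, 197L, 129L, 41L, 43L, 76L, 73L),
    toy4 = c(60L, 50L, 30L, 20L)
  )
  K <- length(counts)
  # deterministic spreads across sites: background level, foreground mean,
  # noise, shape family and size range all vary to force distinct marginals
  fg <- seq(0.70, 0.92, length.out = K)
  bg <- seq(0.08, 0.40, length.out = K)
  ns <- seq(0.03, 0.08, length.out = K)
  fam <- rep(c("ellipse", "blob"), length.out = K)
  # shape radii scale with the image so the foreground fraction (and hence
  # the intensity marginals) stay comparable across resolutions
  sc <- min(image_size) / 64
  smin <- pmax(1, round(seq(6, 10, length.out = K) * sc))
  smax <- pmax(2, round(seq(12, 20, length.out = K) * sc))
  purrr::map(seq_len(K), function(k) {
    site_profile(
      site_id = k, n_k = counts[k], intensity_mean = fg[k],
      intensity_shift = bg[k], noise_sd = ns[k], shape_family = fam[k],
      size_range = c(smin[k], smax[k]), image_size = image_size,
      seed = derive_seed(seed, 53L, k)
    )
  })
}

#' Generate, normalize and split one site's dataset
#'
#' Convenience wrapper: [generate_site()], per-sample [normalize_sample()],
#' then [split_dataset()] with the 7 : 1.5 : 1.5 rule.
#'
#' @param profile A [site_profile()].
#' @param ratios Split ratios, see [split_dataset()].
#' @return `list(train, val, test)` of normalized samples, plus attribute
#'   `"profile"`.
#' @export
make_site_dataset <- function(profile, ratios = c(0.70, 0.15, 0.15)) {
  samples <- generate_site(profile)
  samples <- lapply(samples, function(s) {
    list(image = normalize_sample(s$image), mask = s$mask)
  })
  ds <- split_dataset(samples, ratios, seed = profile$seed)
  attr(ds, "profile") <- profile
  ds
}

#' Build the full multi-site dataset for a fixture
#'
#' @inheritParams build_fixture
#' @param ratios Split ratios per site.
#' @return List with one `list(train, val, test)` per site.
#' @export
fixture_datasets <- function(name = "toy4", seed = 1L,
                             image_size = c(64, 64),
                             ratios = c(0.70, 0.15, 0.15)) {
  profiles <- build_fixture(name, seed = seed, image_size = image_size)
  lapply(profiles, make_site_dataset, ratios = ratios)
}

#' Pairwise intensity divergence between sites
#'
#' Kolmogorov-Smirnov distance between pooled pixel-intensity samples of each
#' site pair, as a measurable check that the generator's non-IID intensity
#' shift survives per-sample normalization.
#'
#' @param datasets List of per-site datasets (`list(train, val, test)` or a
#'   plain list of samples).
#' @param max_pixels Per-site cap on pooled pixels (subsampled
#'   deterministically).
#' @return Tibble with columns `site_a`, `site_b`, `ks`.
#' @export
site_intensity_divergence <- function(datasets, max_pixels = 20000L) {
  pool <- lapply(seq_along(datasets), function(k) {
    ds <- datasets[[k]]
    samples <- if (!is.null(ds$train)) c(ds$train, ds$val, ds$test) else ds
    px <- unlist(lapply(samples, function(s) as.vector(s$image)))
    if (length(px) > max_pixels) {
      px <- px[seq(1L, length(px), length.out = max_pixels)]
    }
    px
  })
  K <- length(pool)
  pairs <- utils::combn(K, 2)
  ks <- apply(pairs, 2, function(ab) {
    suppressWarnings(
      as.numeric(stats::ks.test(pool[[ab[1]]], pool[[ab[2]]])$statistic)
    )
  })
  tibble::tibble(site_a = pairs[1, ], site_b = pairs[2, ], ks = ks)
}
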