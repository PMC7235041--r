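#' Gabor filter bank for the HMAX S1 layer
#'
#' Standard HMAX parameterization: filter sizes 7x7 to 37x37 in steps of 2
#' (16 sizes, paired into 8 scale bands), four orientations, aspect ratio
#' 0.3, with `sigma = 0.0036 s^2 + 0.35 s + 0.18` and `lambda = sigma / 0.8`
#' for size `s`. Filters are restricted to a circular support, zero-mean and
#' unit-norm.
#'
#' @param orientations Orientation angles in radians (default 0, 45, 90,
#'   135 degrees).
#' @param sizes Odd filter sizes in pixels; consecutive pairs form the scale
#'   bands.
#' @param pool_sizes C1 spatial pool size (pixels) per band; pooling windows
#'   overlap by half a pool.
#' @param aspect Gabor aspect ratio (gamma).
#' @return `gabor_bank`: list with `filters` (size x orientation list of
#'   matrices), `masks` (circular supports), `orientations`, `sizes`,
#'   `pool_sizes`, `n_bands`.
#' @export
gabor_bank <- function(orientations = c(0, 45, 90, 135) * pi / 180,
                       sizes = seq(7, 37, by = 2),
                       pool_sizes = seq(8, 22, by = 2),
                       aspect = 0.3) {
  stopifnot(length(sizes) %% 2 == 0, length(pool_sizes) == length(sizes) / 2,
            all(sizes %% 2 == 1))
  filters <- vector("list", length(sizes))
  masks <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    sigma <- 0.0036 * s^2 + 0.35 * s + 0.18
    lambda <- sigma / 0.8
    half <- (s - 1) / 2
    g <- expand.grid(x = -half:half, y = -half:half)
    mask <- matrix(g$x^2 + g$y^2 <= half^2, s, s)
    filters[[si]] <- lapply(orientations, function(theta) {
      x0 <- g$x * cos(theta) + g$y * sin(theta)
      y0 <- -g$x * sin(theta) + g$y * cos(theta)
      f <- exp(-(x0^2 + aspect^2 * y0^2) / (2 * sigma^2)) *
        cos(2 * pi * x0 / lambda)
      f <- matrix(f, s, s)
      f[!mask] <- 0
      f[mask] <- f[mask] - mean(f[mask])       # zero-mean on support
      f / sqrt(sum(f^2))                        # unit norm
    })
    masks[[si]] <- mask * 1
  }
  structure(list(filters = filters, masks = masks,
                 orientations = orientations, sizes = sizes,
                 pool_sizes = pool_sizes, n_bands = length(pool_sizes)),
            class = "gabor_bank")
}

# FFT-based 2-D linear cross-correlation machinery. All kernels are embedded
# centered in a common (max size) frame so one padded image FFT serves every
# filter; "same"-size output is then a fixed-offset crop.
fft_frame <- function(img_dim, max_kernel) {
  c(img_dim[1] + max_kernel - 1L, img_dim[2] + max_kernel - 1L)
}

pad_replicate <- function(m, p) {
  ri <- pmin(pmax(seq_len(nrow(m) + 2 * p) - p, 1), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m) + 2 * p) - p, 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

pad_to <- function(m, dims) {
  out <- matrix(0, dims[1], dims[2])
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

embed_centered <- function(kernel, frame_kernel) {
  out <- matrix(0, frame_kernel, frame_kernel)
  off <- (frame_kernel - nrow(kernel)) / 2
  out[off + seq_len(nrow(kernel)), off + seq_len(ncol(kernel))] <- kernel
  out
}

# cross-correlation = convolution with the 180-degree rotated kernel
rot180 <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]

xcorr_same_fft <- function(fft_img, kernel, img_dim, frame_kernel, frame) {
  k <- pad_to(rot180(embed_centered(kernel, frame_kernel)), frame)
  full <- Re(stats::fft(fft_img * stats::fft(k), inverse = TRUE)) / prod(frame)
  off <- (frame_kernel - 1) / 2
  full[off + seq_len(img_dim[1]), off + seq_len(img_dim[2])]
}

#' HMAX S1 responses
#'
#' Per orientation and filter size, the absolute normalized cross-correlation
#' of the Gabor filter with the image: `|f * patch| / ||patch||`, with the
#' patch norm (mean-centered, over the filter's circular support). The image
#' is replicate-padded so every output pixel has full filter support.
#' Responses to a constant image are exactly zero (zero-mean filters), and
#' adding a constant offset to the image leaves responses unchanged (both
#' numerator and centered norm ignore the local mean).
#'
#' @param image Numeric matrix (grayscale, values in `[0, 1]`), minimum side
#'   64 pixels.
#' @param bank A [gabor_bank()].
#' @return `s1_stack`: list of size-indexed lists of orientation-indexed
#'   response matrices (same size as the image), plus dims/bank metadata.
#' @export
s1_responses <- function(image, bank) {
  image <- as.matrix(image)
  if (min(dim(image)) < 64) {
    stop("image too small: minimum side is 64 pixels", call. = FALSE)
  }
  if (!all(is.finite(image))) stop("image has non-finite pixels", call. = FALSE)
  img_dim <- dim(image)
  frame_kernel <- max(bank$sizes)
  # replicate-pad so every output pixel has full filter support (no border
  # artifacts: a constant image then yields exactly zero responses)
  pad <- (frame_kernel - 1L) / 2
  padded <- pad_replicate(image, pad)
  pad_dim <- dim(padded)
  frame <- fft_frame(pad_dim, frame_kernel)
  fft_img <- stats::fft(pad_to(padded, frame))
  fft_img2 <- stats::fft(pad_to(padded^2, frame))
  crop_r <- pad + seq_len(img_dim[1])
  crop_c <- pad + seq_len(img_dim[2])

  resp <- vector("list", length(bank$sizes))
  for (si in seq_along(bank$sizes)) {
    mask <- bank$masks[[si]]
    area <- sum(mask)
    sum1 <- xcorr_same_fft(fft_img, mask, pad_dim, frame_kernel, frame)
    sum2 <- xcorr_same_fft(fft_img2, mask, pad_dim, frame_kernel, frame)
    # centered patch norm over the filter support: DC-offset invariant
    denom <- sqrt(pmax(sum2 - sum1^2 / area, 0))[crop_r, crop_c]
    resp[[si]] <- lapply(bank$filters[[si]], function(f) {
      num <- xcorr_same_fft(fft_img, f, pad_dim, frame_kernel, frame)[crop_r, crop_c]
      out <- abs(num) / pmax(denom, 1e-12)
      out[denom < 1e-8] <- 0
      out
    })
  }
  structure(list(responses = resp, img_dim = img_dim,
                 sizes = bank$sizes, orientations = bank$orientations),
            class = "s1_stack")
}

#' HMAX C1 pooling
#'
#' Per orientation and scale band: element-wise max over the band's two
#' filter sizes, then local max over an overlapping spatial pool grid
#' (window = the band's pool size, stride = half the window). The pooled
#' grids are concatenated deterministically (band, then orientation, then
#' grid in column-major order) into one feature vector.
#'
#' @param s1 An [s1_responses()] stack from the same bank.
#' @param bank The [gabor_bank()].
#' @return `c1_features`: numeric vector (non-negative), with attribute
#'   `layout` describing the per-band grid sizes.
#' @export
c1_pool <- function(s1, bank) {
  if (!identical(s1$sizes, bank$sizes)) {
    stop("S1 stack does not match bank", call. = FALSE)
  }
  feats <- list()
  layout <- list()
  for (b in seq_len(bank$n_bands)) {
    p <- bank$pool_sizes[b]
    stride <- max(1L, floor(p / 2))
    rs <- seq(1L, s1$img_dim[1] - p + 1L, by = stride)
    cs <- seq(1L, s1$img_dim[2] - p + 1L, by = stride)
    for (oi in seq_along(bank$orientations)) {
      m <- pmax(s1$responses[[2 * b - 1]][[oi]], s1$responses[[2 * b]][[oi]])
      pooled <- matrix(0, length(rs), length(cs))
      for (ci in seq_along(cs)) {
        block <- m[, cs[ci]:(cs[ci] + p - 1L), drop = FALSE]
        for (ri in seq_along(rs)) {
          pooled[ri, ci] <- max(block[rs[ri]:(rs[ri] + p - 1L), ])
        }
      }
      feats[[length(feats) + 1L]] <- as.numeric(pooled)
      layout[[length(layout) + 1L]] <- c(band = b, orientation = oi,
                                         rows = length(rs), cols = length(cs))
    }
  }
  structure(unlist(feats), layout = layout, class = "c1_features")
}

#' C1 feature vector of one image
#'
#' Convenience composition of [s1_responses()] and [c1_pool()].
#'
#' @inheritParams s1_responses
#' @return `c1_features` vector.
#' @export
c1_features <- function(image, bank) c1_pool(s1_responses(image, bank), bank)

#' Visual-similarity model DM from stimulus images
#'
#' Encodes every image through the HMAX C1 layer and takes the correlation
#' distance (`1 - Pearson r`) between C1 feature vectors -- the low-level
#' visual control model for the RSA.
#'
#' @param images Named list of grayscale image matrices (common size;
#'   values in `[0, 1]`).
#' @param bank A [gabor_bank()] (default bank if omitted).
#' @return A model [item_dm()] with `model_kind = "visual_similarity"`.
#'   Items with degenerate (constant) C1 vectors raise an error naming them.
#' @export
visual_model_dm <- function(images, bank = gabor_bank()) {
  if (length(images) < 2L) stop("need >= 2 images", call. = FALSE)
  items <- names(images)
  if (is.null(items)) items <- paste0("item", seq_along(images))
  dims <- vapply(images, dim, integer(2))
  if (any(dims != dims[, 1])) stop("images must share a common size", call. = FALSE)
  first <- as.numeric(c1_features(images[[1]], bank))
  feats <- cbind(first,
                 vapply(images[-1], function(im) as.numeric(c1_features(im, bank)),
                        numeric(length(first))))
  colnames(feats) <- items
  sds <- apply(feats, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("degenerate C1 features for item(s): %s",
                 paste(items[sds == 0], collapse = ", ")), call. = FALSE)
  }
  r <- stats::cor(feats)
  dm <- item_dm(1 - r[lower.tri(r)], items)
  attr(dm, "model_kind") <- "visual_similarity"
  dm
}
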