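#' ZO-1-guided block projection of a z-stack
#'
#' Epithelial monolayers have uneven thickness, so a plain maximum projection
#' mixes out-of-plane signal into the tricellular channel. Instead, the
#' junctional (guide) stack determines, for every `block_size` x
#' `block_size` patch, the slice with the highest intensity energy (sum of
#' squared intensities — defocus spreads light and always lowers it,
#' whereas the plain sum is essentially blur-invariant); the output image
#' is composed of the corresponding patches taken from the target stack.
#' Ties (e.g. blocks without guide signal) go to the lower slice index.
#' Edge blocks may be smaller than `block_size`; the block grid is
#' anchored at the image origin.
#'
#' @param guide 3D numeric array (slice, row, col) of the junctional channel.
#' @param target 3D array with the same dimensions; defaults to `guide`.
#' @param block_size patch size in pixels (>= 1).
#' @return an object of class `tj_projection`: list with `pixels` (2D
#'   matrix), `provenance` (per-block chosen slice index matrix) and
#'   `block_size`.
#' @export
guided_block_projection <- function(guide, target = guide, block_size = 20) {
  if (length(dim(guide)) != 3) stopf("guide must be a 3D array (slice, row, col)")
  if (!all(dim(guide) == dim(target)))
    stopf("guide and target stacks must have identical dimensions")
  if (block_size < 1) stopf("block_size must be >= 1")
  ns <- dim(guide)[1]; H <- dim(guide)[2]; W <- dim(guide)[3]
  br <- ceiling(seq_len(H) / block_size)
  bc <- ceiling(seq_len(W) / block_size)
  nbr <- max(br); nbc <- max(bc)
  if (ns == 1) {
    return(structure(list(pixels = matrix(target[1, , ], H, W),
                          provenance = matrix(1L, nbr, nbc),
                          block_size = block_size),
                     class = "tj_projection"))
  }
  sums <- array(0, dim = c(ns, nbr, nbc))
  for (s in seq_len(ns)) {
    m <- matrix(guide[s, , ], H, W)^2
    sums[s, , ] <- t(rowsum(t(rowsum(m, br)), bc))
  }
  prov <- matrix(0L, nbr, nbc)
  for (i in seq_len(nbr))
    for (j in seq_len(nbc))
      prov[i, j] <- which.max(sums[, i, j])  # which.max: lowest index on ties
  out <- matrix(0, H, W)
  for (i in seq_len(nbr)) {
    rs <- which(br == i)
    for (j in seq_len(nbc)) {
      cs <- which(bc == j)
      out[rs, cs] <- target[prov[i, j], rs, cs]
    }
  }
  structure(list(pixels = out, provenance = prov, block_size = block_size),
            class = "tj_projection")
}

#' Blocks of an image with enough guide signal to define focus
#'
#' The per-block focus (and hence the projection provenance) is only
#' defined where the guide channel actually has signal in the block: an
#' empty block sees nothing but defocused light leaking in from its
#' neighbors, and its argmax slice is arbitrary. A block counts as a signal
#' block when its intensity energy is at least `min_equiv_px` times the
#' squared reference intensity (i.e., the equivalent of a few
#' full-brightness boundary pixels).
#'
#' @param img 2D in-focus guide image.
#' @param block_size block size in pixels.
#' @param min_equiv_px minimum signal, in full-intensity pixel equivalents.
#' @param ref_intensity reference (full) intensity; defaults to the image
#'   maximum.
#' @return logical matrix over the block grid.
#' @export
focus_signal_blocks <- function(img, block_size = 20, min_equiv_px = 5,
                                ref_intensity = max(img)) {
  img <- as_intensity_matrix(img, "img")
  br <- ceiling(seq_len(nrow(img)) / block_size)
  bc <- ceiling(seq_len(ncol(img)) / block_size)
  en <- t(rowsum(t(rowsum(img^2, br)), bc))
  en >= min_equiv_px * ref_intensity^2
}

#' Estimate image noise from the nuclear area
#'
#' Tricellulin is absent from the nucleus, so the mean tricellular-channel
#' intensity under the nuclear mask estimates the background (noise) level.
#' The signal-to-noise ratio is `SNR = MaxIntensity / (2 * Noise)`.
#'
#' @param tric projected tricellular-channel image (matrix or
#'   `tj_projection`).
#' @param nuclear_mask logical matrix marking nuclear pixels; must be
#'   nonempty.
#' @return object of class `tj_noise_model`: list with `noise`,
#'   `max_intensity`, `snr` (`NA` with a warning when `noise == 0`).
#' @export
estimate_noise <- function(tric, nuclear_mask) {
  img <- as_intensity_matrix(tric, "tric")
  if (!any(nuclear_mask))
    stopf("nuclear mask is empty: supply a nuclei image / mask")
  if (!all(dim(nuclear_mask) == dim(img)))
    stopf("nuclear_mask extent does not match the image")
  noise <- mean(img[nuclear_mask])
  maxI <- max(img)
  snr <- if (noise > 0) maxI / (2 * noise) else {
    warnf("noise level is 0; SNR undefined, contrast adjustment will be a pass-through")
    NA_real_
  }
  structure(list(noise = noise, max_intensity = maxI, snr = snr),
            class = "tj_noise_model")
}

#' Noise-subtract and SNR-divide contrast adjustment
#'
#' `out = clip(I - noise, 0, Inf) / snr`. The transform is monotone, so pixel
#' ordering above the noise level is preserved; the localization score built
#' on intensity ratios is unaffected by the global scale. With `noise == 0`
#' (degenerate mask) the division is skipped and the noise-subtracted image
#' returned unchanged.
#'
#' @param tric projected tricellular image.
#' @param model a `tj_noise_model` from [estimate_noise()] on the same image.
#' @return adjusted image matrix.
#' @export
adjust_contrast <- function(tric, model) {
  img <- as_intensity_matrix(tric, "tric")
  stopifnot(inherits(model, "tj_noise_model"))
  out <- pmax(img - model$noise, 0)
  if (is.na(model$snr)) return(out)
  if (model$snr <= 0) stopf("snr must be positive")
  out / model$snr
}

#' Segment nuclei by global thresholding
#'
#' Otsu global threshold, hole filling, and removal of objects below
#' `min_area` px^2.
#'
#' @param nuclei projected nuclear-channel image.
#' @param min_area minimum object area kept (px^2).
#' @return logical matrix (nuclear mask).
#' @export
nuclear_mask <- function(nuclei, min_area = 30) {
  img <- as_intensity_matrix(nuclei, "nuclei")
  rng <- max(img)
  if (rng <= 0) stopf("no nuclear foreground found (blank image)")
  norm <- img / rng
  thr <- EBImage::otsu(EBImage::Image(norm))
  mask <- norm > thr
  if (!any(mask)) stopf("no nuclear foreground found at the Otsu threshold")
  mask <- EBImage::imageData(EBImage::fillHull(mask * 1)) > 0
  lab <- label_components(mask, connectivity = 4)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area)
  mask <- matrix(lab %in% keep, nrow(img), ncol(img))
  if (!any(mask))
    stopf("all nuclear objects smaller than min_area = %d", min_area)
  mask
}
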