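## Per-plane intensity statistics and windowed thumbnail rendering. All
## arithmetic is deterministic and documented: rounding is half-up after
## scaling, downsampling is block-mean over integer-factor blocks followed
## by nearest-neighbour for the remainder.

.roundHalfUp <- function(x) floor(x + 0.5)

#' Per-plane intensity statistics
#'
#' Exact order statistics and arithmetic mean of one 2-D plane; the median
#' of even-sized data is the midpoint of the lower and upper middle
#' values.
#'
#' @param plane Non-empty numeric matrix (or vector).
#' @return Named numeric `c(min, max, mean, median)`.
#' @examples
#' planeStats(matrix(0:3, 2))   # 0, 3, 1.5, 1.5
#' @export
planeStats <- function(plane) {
    v <- as.numeric(plane)
    if (!length(v)) stop("domain error: empty plane")
    c(min = min(v), max = max(v), mean = mean(v), median = stats::median(v))
}

#' Read a single image plane from a baseline TIFF
#'
#' Uncompressed grayscale TIFF only; integer sample values are returned
#' as stored (not rescaled to 0..1).
#'
#' @param path TIFF file.
#' @return Numeric matrix.
#' @export
readPlaneTIFF <- function(path) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img
}

#' Construct rendering settings
#'
#' @param window_min,window_max Per-channel intensity windows
#'   (`window_min < window_max` for active channels).
#' @param color Per-channel RGB tints: a channels x 3 matrix in 0..255, or
#'   a vector of length 3 for a single channel.
#' @param active Logical per-channel flags.
#' @return A [RenderingSettings-class].
#' @export
renderingSettings <- function(window_min, window_max, color, active = NULL) {
    if (is.null(dim(color))) color <- matrix(color, nrow = 1L)
    n <- length(window_min)
    if (is.null(active)) active <- rep(TRUE, n)
    new("RenderingSettings", window_min = as.numeric(window_min),
        window_max = as.numeric(window_max), color = color, active = active)
}

## block-mean downsample by integer factor, then nearest-neighbour to the
## exact target size
.downsample <- function(m, out_h, out_w) {
    h <- nrow(m); w <- ncol(m)
    f <- max(1L, min(h %/% out_h, w %/% out_w))
    if (f > 1L) {
        h2 <- h %/% f; w2 <- w %/% f
        m <- m[seq_len(h2 * f), seq_len(w2 * f), drop = FALSE]
        ## mean over f x f blocks
        m <- array(m, c(f, h2, f * w2))
        m <- colMeans(m)
        m <- array(aperm(array(m, c(h2, f, w2)), c(2, 1, 3)), c(f, h2 * w2))
        m <- matrix(colMeans(m), h2, w2)
        h <- h2; w <- w2
    }
    ri <- pmin(h, pmax(1L, ceiling(seq_len(out_h) * h / out_h)))
    ci <- pmin(w, pmax(1L, ceiling(seq_len(out_w) * w / out_w)))
    m[ri, ci, drop = FALSE]
}

#' Render an RGB thumbnail from per-channel planes
#'
#' Each active channel is linearly windowed,
#' `v -> clamp((v - window_min) / (window_max - window_min), 0, 1)`,
#' scaled to 0..255, tinted by its RGB color and rounded half-up; the
#' integer channel contributions are then summed with saturation at 255
#' (so compositing is exactly channel-order invariant), and the composite
#' is downsampled so its longer edge equals `min(max_edge, original
#' edge)`, preserving aspect ratio.
#'
#' @param planes List of equally sized numeric matrices, one per channel.
#' @param settings A [RenderingSettings-class] covering all channels.
#' @param max_edge Maximum output edge length (>= 1).
#' @return Integer array `height x width x 3` with values in 0..255.
#' @examples
#' pl <- matrix(50, 8, 8)
#' s <- renderingSettings(0, 100, c(0, 255, 0))
#' renderThumbnail(list(pl), s, 8)[1, 1, ]   # 0 128 0
#' @export
renderThumbnail <- function(planes, settings, max_edge) {
    stopifnot(max_edge >= 1)
    n <- length(planes)
    if (length(settings@window_min) != n)
        stop("settings error: settings must cover all ", n, " channel(s)")
    validObject(settings)
    h <- nrow(planes[[1L]]); w <- ncol(planes[[1L]])
    acc <- array(0, c(h, w, 3L))
    for (ch in seq_len(n)) {
        if (!settings@active[ch]) next
        wmin <- settings@window_min[ch]; wmax <- settings@window_max[ch]
        v <- pmin(1, pmax(0, (planes[[ch]] - wmin) / (wmax - wmin)))
        for (rgb in 1:3)
            acc[, , rgb] <- acc[, , rgb] +
                .roundHalfUp(v * settings@color[ch, rgb])
    }
    acc <- pmin(acc, 255)
    long <- max(h, w)
    target <- min(max_edge, long)
    out_h <- max(1L, as.integer(.roundHalfUp(h * target / long)))
    out_w <- max(1L, as.integer(.roundHalfUp(w * target / long)))
    if (h >= w) out_h <- as.integer(target) else out_w <- as.integer(target)
    out <- array(0L, c(out_h, out_w, 3L))
    for (rgb in 1:3)
        out[, , rgb] <- as.integer(.roundHalfUp(.downsample(acc[, , rgb],
                                                            out_h, out_w)))
    out
}

#' Write a thumbnail as PNG
#'
#' @param thumb Integer array from [renderThumbnail()].
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
writeThumbnailPNG <- function(thumb, path) {
    png::writePNG(thumb / 255, path)
    invisible(path)
}
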