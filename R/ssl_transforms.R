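#' Signal transformations for the self-supervised pretext task
#'
#' Six elementary ECG transformations whose *recognition* is the pretext
#' objective of the representation-learning stage: Gaussian noise addition,
#' amplitude scaling, negation (vertical flip), temporal inversion
#' (horizontal flip), permutation of equal-length segments, and
#' time-warping (segment-wise stretch/squeeze). All transformations
#' preserve segment length. Randomized transformations draw from the
#' session RNG; wrap in `set.seed()` for reproducibility.
#'
#' @param x Numeric vector (one ECG window).
#' @param noise_sd Standard deviation of the added noise (>= 0).
#' @param factor Positive scale factor.
#' @param n_segments Number of equal pieces for permutation/warping (the
#'   last piece absorbs any remainder).
#' @param warp_ratio Stretch/squeeze ratio, > 1; each piece is randomly
#'   stretched to `length * warp_ratio` or squeezed to
#'   `length / warp_ratio`, then the concatenation is linearly resampled
#'   back to the original length.
#' @return The transformed vector, same length as `x`.
#' @name ssl_transforms
NULL

#' @rdname ssl_transforms
#' @export
t_noise <- function(x, noise_sd = 0.05) {
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  if (noise_sd == 0) return(x)
  x + stats::rnorm(length(x), 0, noise_sd)
}

#' @rdname ssl_transforms
#' @export
t_scale <- function(x, factor) {
  if (!is_scalar_number(factor) || factor <= 0) stop_invalid("`factor` must be > 0")
  factor * x
}

#' @rdname ssl_transforms
#' @export
t_negate <- function(x) -x

#' @rdname ssl_transforms
#' @export
t_time_invert <- function(x) rev(x)

split_points <- function(n, n_segments) {
  if (n_segments < 1L) stop_invalid("`n_segments` must be >= 1")
  if (n_segments > n) stop_invalid("`n_segments` (%d) exceeds segment length (%d)", n_segments, n)
  base <- n %/% n_segments
  sizes <- rep(base, n_segments)
  sizes[n_segments] <- sizes[n_segments] + n - base * n_segments  # last absorbs remainder
  ends <- cumsum(sizes)
  cbind(start = c(1L, head(ends, -1L) + 1L), end = ends)
}

#' @rdname ssl_transforms
#' @export
t_permute <- function(x, n_segments = 20) {
  pts <- split_points(length(x), n_segments)
  if (n_segments == 1L) return(x)
  ord <- sample.int(n_segments)
  unlist(lapply(ord, function(j) x[pts[j, 1L]:pts[j, 2L]]), use.names = FALSE)
}

#' @rdname ssl_transforms
#' @export
t_time_warp <- function(x, n_segments = 20, warp_ratio = 1.05) {
  if (!is_scalar_number(warp_ratio) || warp_ratio <= 1) {
    stop_invalid("`warp_ratio` must be > 1")
  }
  pts <- split_points(length(x), n_segments)
  # alternate stretched and squeezed pieces (random starting phase) so the
  # cumulative time drift stays bounded by one piece
  first <- sample(c(TRUE, FALSE), 1L)
  stretch <- rep_len(c(first, !first), n_segments)
  pieces <- lapply(seq_len(n_segments), function(j) {
    seg <- x[pts[j, 1L]:pts[j, 2L]]
    m <- length(seg)
    new_len <- max(2L, round(if (stretch[j]) m * warp_ratio else m / warp_ratio))
    if (m == 1L) return(rep(seg, new_len))
    stats::approx(seq_len(m), seg, n = new_len)$y
  })
  warped <- unlist(pieces, use.names = FALSE)
  stats::approx(seq_along(warped), warped, n = length(x))$y
}

#' Default parameters of the six pretext transformations
#'
#' The scale transformation draws its factor uniformly from the two-point
#' set `scale_factors` so that scaled windows are separated from originals
#' by a clear margin in either direction.
#'
#' @param noise_sd,n_segments,warp_ratio See [ssl_transforms].
#' @param scale_factors Candidate scale factors, one drawn per window.
#' @return A list of class `transform_specs`.
#' @export
transform_specs <- function(noise_sd = 0.05, scale_factors = c(0.7, 1.3),
                            n_segments = 20, warp_ratio = 1.05) {
  structure(list(noise_sd = noise_sd, scale_factors = scale_factors,
                 n_segments = n_segments, warp_ratio = warp_ratio),
            class = "transform_specs")
}

#' Transformation kinds, in head order
#' @return Character vector of the six transformation names.
#' @export
transform_kinds <- function() {
  c("noise", "scale", "negate", "time_invert", "permute", "time_warp")
}

apply_transform <- function(x, kind, specs) {
  switch(kind,
         noise = t_noise(x, specs$noise_sd),
         scale = t_scale(x, sample(specs$scale_factors, 1L)),
         negate = t_negate(x),
         time_invert = t_time_invert(x),
         permute = t_permute(x, specs$n_segments),
         time_warp = t_time_warp(x, specs$n_segments, specs$warp_ratio),
         stop_invalid("unknown transformation '%s'", kind))
}

#' Build the pretext dataset: stacked transformed windows + one-hot heads
#'
#' Every input window yields seven rows — the original plus one row per
#' transformation — stacked in shuffled order. The label matrix has one
#' column per transformation head; each row has exactly one positive entry,
#' or none for an untransformed original.
#'
#' @param segments Numeric matrix, one normalized window per row.
#' @param specs A [transform_specs()].
#' @param seed Optional RNG seed for the transformation draws and the
#'   shuffle.
#' @return A list of class `pretext_dataset` with `inputs`
#'   (`7 * nrow(segments)` rows), `labels` (0/1 matrix, 6 columns named by
#'   [transform_kinds()]) and `source` (index of the originating window).
#' @export
build_pretext_dataset <- function(segments, specs = transform_specs(), seed = NULL) {
  if (!is.matrix(segments)) segments <- matrix(segments, nrow = 1L)
  kinds <- transform_kinds()
  n <- nrow(segments)
  with_seed(seed, {
    n_var <- length(kinds) + 1L
    inputs <- matrix(0, n * n_var, ncol(segments))
    labels <- matrix(0, n * n_var, length(kinds),
                     dimnames = list(NULL, kinds))
    source <- integer(n * n_var)
    row <- 0L
    for (i in seq_len(n)) {
      x <- segments[i, ]
      row <- row + 1L
      inputs[row, ] <- x; source[row] <- i
      for (k in seq_along(kinds)) {
        row <- row + 1L
        inputs[row, ] <- apply_transform(x, kinds[k], specs)
        labels[row, k] <- 1
        source[row] <- i
      }
    }
    ord <- sample.int(nrow(inputs))
    structure(list(inputs = inputs[ord, , drop = FALSE],
                   labels = labels[ord, , drop = FALSE],
                   source = source[ord]),
              class = "pretext_dataset")
  })
}

#' @export
print.pretext_dataset <- function(x, ...) {
  cat(sprintf("<pretext_dataset> %d rows x %d samples | heads: %s\n",
              nrow(x$inputs), ncol(x$inputs), paste(colnames(x$labels), collapse = ", ")))
  invisible(x)
}
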