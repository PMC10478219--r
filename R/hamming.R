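#' Binary pattern utilities and rotation-minimised Hamming distance
#'
#' Tools to compare a binarized pattern (e.g. the `+1` state of a
#' colony snapshot) against a target pattern: nearest-neighbour
#' rescaling to a common pixel count, rotation in 15-degree steps, and
#' the normalized Hamming distance, reported as its minimum over all
#' rotated versions.
#'
#' @name hamming
NULL

check_binary <- function(a, arg = "pattern") {
  if (!is.matrix(a) || !all(a %in% c(0, 1)))
    abort(sprintf("`%s` must be a binary 0/1 matrix.", arg),
          class = "cpim_usage_error")
  invisible(a)
}

#' Convert a lattice state to a binary pattern
#'
#' Maps one differentiated state to 1 and everything else to 0.
#'
#' @param lattice Code lattice.
#' @param state Which state becomes foreground (default `+1`).
#' @return Binary 0/1 matrix.
#' @export
binarize_lattice <- function(lattice, state = 1L) {
  g <- unclass(lattice); attributes(g) <- list(dim = dim(g))
  (g == state) * 1L
}

#' Rescale a binary pattern by nearest-neighbour resampling
#'
#' @param pattern Binary 0/1 matrix.
#' @param target_shape Integer `c(rows, cols)` (a single number is
#'   recycled); both `>= 2`.
#' @return Binary matrix of the requested shape.
#' @export
rescale_binary <- function(pattern, target_shape) {
  check_binary(pattern)
  if (length(target_shape) == 1) target_shape <- rep(target_shape, 2)
  if (any(target_shape < 2))
    abort("target dimensions must be >= 2.", class = "cpim_usage_error")
  src_i <- pmin(nrow(pattern),
                floor((seq_len(target_shape[1]) - 0.5) *
                        nrow(pattern) / target_shape[1]) + 1)
  src_j <- pmin(ncol(pattern),
                floor((seq_len(target_shape[2]) - 0.5) *
                        ncol(pattern) / target_shape[2]) + 1)
  pattern[src_i, src_j, drop = FALSE]
}

#' Rotate a binary pattern about its centre
#'
#' Inverse-mapping rotation with nearest-neighbour interpolation;
#' pixels that fall outside the frame are filled with background 0.
#' The output has the same shape and is strictly binary.
#'
#' @param pattern Binary 0/1 matrix.
#' @param angle_degrees Rotation angle (counter-clockwise).
#' @return Binary matrix of the same shape.
#' @export
rotate_binary <- function(pattern, angle_degrees) {
  check_binary(pattern)
  ang <- angle_degrees %% 360
  if (ang == 0) return(pattern)
  n1 <- nrow(pattern); n2 <- ncol(pattern)
  th <- ang * pi / 180
  c1 <- (n1 + 1) / 2; c2 <- (n2 + 1) / 2
  i <- matrix(seq_len(n1) - c1, n1, n2)
  j <- matrix(rep(seq_len(n2) - c2, each = n1), n1, n2)
  # inverse rotation of the output grid into source coordinates
  si <- round(cos(th) * i + sin(th) * j + c1)
  sj <- round(-sin(th) * i + cos(th) * j + c2)
  ok <- si >= 1 & si <= n1 & sj >= 1 & sj <= n2
  out <- matrix(0, n1, n2)
  out[ok] <- pattern[cbind(si[ok], sj[ok])]
  storage.mode(out) <- storage.mode(pattern)
  out
}

#' Normalized Hamming distance between two binary patterns
#'
#' The fraction of pixel positions at which the two patterns differ.
#'
#' @param a,b Binary 0/1 matrices of equal shape (rescale first if
#'   they differ).
#' @return A number in `[0, 1]`.
#' @export
hamming_distance <- function(a, b) {
  check_binary(a, "a"); check_binary(b, "b")
  if (!all(dim(a) == dim(b)))
    abort("patterns must have equal shapes; use rescale_binary() first.",
          class = "cpim_usage_error")
  mean(a != b)
}

#' Minimum Hamming distance over rotations
#'
#' Rotates `b` in steps of `step` degrees (24 versions at the default
#' 15-degree step) and returns the smallest normalized Hamming
#' distance to `a` together with the minimizing angle.
#'
#' @inheritParams hamming_distance
#' @param step Rotation step in degrees.
#' @return A list with `distance`, `angle` and the per-angle tibble
#'   `by_angle`.
#' @export
min_hamming_over_rotations <- function(a, b, step = 15) {
  angles <- seq(0, 360 - step, by = step)
  d <- vapply(angles, function(ang)
    hamming_distance(a, rotate_binary(b, ang)), numeric(1))
  k <- which.min(d)
  list(distance = d[k], angle = angles[k],
       by_angle = tibble(angle = angles, distance = d))
}
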