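# DistanceDistribution: probability density over a distance grid (nm).
# Shared by the rotamer and DEER modules.

#' Construct a distance distribution P(r)
#'
#' @param r strictly increasing, (approximately) uniformly spaced distance grid
#'   in nanometres.
#' @param p non-negative densities on `r`; renormalized so that
#'   `sum(p) * dr == 1`.
#' @param metadata optional named list carried along (smoothing width, chosen
#'   regularization parameter, flags ...).
#' @return object of class `distance_distribution` with fields `r`, `p`,
#'   `metadata`.
#' @export
distance_distribution <- function(r, p, metadata = list()) {
  r <- as.numeric(r); p <- as.numeric(p)
  if (length(r) != length(p)) stop("r and p must have the same length")
  if (length(r) < 2L) stop("distance grid needs at least two points")
  dr <- diff(r)
  if (any(dr <= 0)) stop("r grid must be strictly increasing")
  if (max(dr) - min(dr) > 1e-6 * mean(dr))
    stop("r grid must be uniformly spaced")
  if (any(p < -1e-12 * max(abs(p)))) stop("negative probability density")
  p[p < 0] <- 0
  mass <- sum(p) * mean(dr)
  if (mass <= 0) stop("distribution has zero mass")
  structure(list(r = r, p = p / mass, metadata = metadata),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat("<distance_distribution> ", length(x$r), " points on [",
      format(min(x$r)), ", ", format(max(x$r)), "] nm\n", sep = "")
  cat("  mean r: ", format(round(distribution_mean(x), 3)), " nm; modes: ",
      paste(round(find_modes(x), 2), collapse = ", "), " nm\n", sep = "")
  invisible(x)
}

#' @export
plot.distance_distribution <- function(x, ...) {
  graphics::plot(x$r, x$p, type = "l", xlab = "r (nm)", ylab = "P(r)", ...)
}

#' Mean of a distance distribution
#' @param dist a [distance_distribution()].
#' @return mean distance in nm.
#' @export
distribution_mean <- function(dist) {
  dr <- mean(diff(dist$r))
  sum(dist$r * dist$p) * dr
}

#' Locate modes of a distance distribution
#'
#' Positions of local maxima whose density reaches at least
#' `min_rel_height * max(p)`. A flat distribution has no local maxima and
#' yields an empty vector.
#'
#' @param dist a [distance_distribution()].
#' @param min_rel_height fraction of the global maximum below which local
#'   maxima are ignored (default 0.05).
#' @return ascending numeric vector of mode positions (nm).
#' @export
find_modes <- function(dist, min_rel_height = 0.05) {
  p <- dist$p; r <- dist$r
  n <- length(p)
  if (n < 3L) return(numeric(0))
  is_max <- logical(n)
  # a point is a local maximum if strictly above the nearest differing
  # neighbours; plateaus report their first point
  for (i in 2:(n - 1)) {
    if (p[i] > p[i + 1] && p[i] > p[i - 1]) is_max[i] <- TRUE
    else if (p[i] > p[i - 1] && p[i] == p[i + 1]) {
      j <- i
      while (j < n && p[j + 1] == p[i]) j <- j + 1
      if (j < n && p[j + 1] < p[i]) is_max[i] <- TRUE
    }
  }
  keep <- is_max & p >= min_rel_height * max(p)
  sort(r[keep])
}

#' Write / read a distance distribution as CSV (columns r_nm, p)
#' @param dist a [distance_distribution()].
#' @param path file path.
#' @return `path` (write) or a [distance_distribution()] (read).
#' @export
write_distribution <- function(dist, path) {
  utils::write.csv(data.frame(r_nm = dist$r, p = dist$p), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  d <- utils::read.csv(path)
  distance_distribution(d$r_nm, d$p)
}
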