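#' Radius of gyration of a set of location records
#'
#' Root-mean-square distance of all records (with multiplicity) from their
#' barycenter: `sqrt(mean(||p_j - p_c||^2))` with `p_c` the mean of all
#' records. A global descriptor of how far an individual ranges.
#'
#' @param x,y record coordinates in meters (equal-length vectors, n >= 1).
#' @return Radius of gyration in meters.
#' @export
radius_of_gyration <- function(x, y) {
  if (length(x) == 0) stop_param("radius_of_gyration needs >= 1 record")
  cx <- mean(x); cy <- mean(y)
  sqrt(mean((x - cx)^2 + (y - cy)^2))
}

#' Shannon entropy of location visit frequencies
#'
#' `-sum_j p(j) log2 p(j)` over distinct locations `j`, where `p(j)` is the
#' share of records at location `j`. Zero for a user who never leaves one
#' location; `log2(o)` when all `o` locations are visited equally.
#'
#' @param x,y record coordinates (equal-length vectors, n >= 1).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(x, y) {
  if (length(x) == 0) stop_param("shannon_entropy needs >= 1 record")
  p <- table(paste(x, y)) / length(x)
  -sum(p * log2(p))
}

#' Per-user global movement descriptors
#'
#' @param trajs list of `mob_trajectory` objects.
#' @return data.frame with columns `user_id`, `rog_m`, `entropy_bits`,
#'   `n_locations`.
#' @export
mobility_features <- function(trajs) {
  rows <- lapply(trajs, function(tr) {
    data.frame(user_id = tr$user_id[1],
               rog_m = radius_of_gyration(tr$x, tr$y),
               entropy_bits = shannon_entropy(tr$x, tr$y),
               n_locations = length(unique(paste(tr$x, tr$y))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
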