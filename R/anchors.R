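#' Detect a user's anchor points
#'
#' An anchor point is an area the user visits with at least a threshold
#' share of their records. The greedy merge works on distinct recorded
#' locations: repeatedly take the unconsumed location with the highest
#' record count (ties: earliest first visit, then lexicographic location
#' key), merge it with all unconsumed locations within `alpha_m` of it into
#' one "examinee", and mark them consumed. Examinees whose aggregated count
#' reaches `beta` of the user's total records become anchors; an anchor's
#' centroid is the record-count-weighted mean of its member locations.
#'
#' Defaults follow common practice for cell-tower traces: `alpha_m = 500`
#' meters, `beta = 0.2` (roughly the share of records most users generate at
#' home or work).
#'
#' @param traj a `mob_trajectory` (nonempty).
#' @param alpha_m merge distance threshold, meters (> 0).
#' @param beta frequency threshold as a fraction of the user's records
#'   (0 < beta < 1).
#' @return A `mob_anchors` object: list with `user_id`, `anchors`
#'   (data.frame `x`, `y`, `record_count`, plus member locations as an
#'   attribute), `total_records`, and (after zone projection) `zone_ids`.
#' @export
detect_anchors <- function(traj, alpha_m = 500, beta = 0.2) {
  if (nrow(traj) == 0) stop_param("detect_anchors: empty trajectory")
  if (alpha_m <= 0 || beta <= 0 || beta >= 1)
    stop_param("detect_anchors: need alpha_m > 0 and 0 < beta < 1")
  key <- paste(traj$x, traj$y)
  tab <- tapply(seq_len(nrow(traj)), key, identity)
  locs <- data.frame(key = names(tab),
                     x = vapply(tab, function(i) traj$x[i[1]], numeric(1)),
                     y = vapply(tab, function(i) traj$y[i[1]], numeric(1)),
                     count = vapply(tab, length, integer(1)),
                     first_t = vapply(tab, function(i) min(traj$abs_t[i]),
                                      numeric(1)),
                     stringsAsFactors = FALSE)
  # deterministic greedy order: count desc, first visit asc, key asc
  locs <- locs[order(-locs$count, locs$first_t, locs$key), , drop = FALSE]
  consumed <- rep(FALSE, nrow(locs))
  examinees <- list()
  for (i in seq_len(nrow(locs))) {
    if (consumed[i]) next
    d <- euclid(locs$x[i], locs$y[i], locs$x, locs$y)
    memb <- which(!consumed & d <= alpha_m)
    consumed[memb] <- TRUE
    examinees[[length(examinees) + 1L]] <- memb
  }
  total <- nrow(traj)
  anchors <- list(); members <- list()
  for (memb in examinees) {
    cnt <- sum(locs$count[memb])
    if (cnt >= beta * total) {
      w <- locs$count[memb]
      anchors[[length(anchors) + 1L]] <-
        data.frame(x = sum(locs$x[memb] * w) / sum(w),
                   y = sum(locs$y[memb] * w) / sum(w),
                   record_count = cnt)
      members[[length(members) + 1L]] <- locs[memb, c("x", "y", "count")]
    }
  }
  a <- if (length(anchors)) do.call(rbind, anchors)
       else data.frame(x = numeric(0), y = numeric(0),
                       record_count = integer(0))
  rownames(a) <- NULL
  attr(a, "members") <- members
  structure(list(user_id = traj$user_id[1], anchors = a,
                 total_records = total, zone_ids = integer(0)),
            class = "mob_anchors")
}

#' @export
print.mob_anchors <- function(x, ...) {
  cat(sprintf("<mob_anchors> user %s: %d anchor(s) from %d records",
              x$user_id, nrow(x$anchors), x$total_records))
  if (length(x$zone_ids)) cat(", zones {", paste(x$zone_ids, collapse = ","),
                              "}")
  cat("\n")
  invisible(x)
}

#' Project anchors onto zones
#'
#' Fills `zone_ids` with the set of zones containing the anchor centroids.
#'
#' @param anchor_set a `mob_anchors` object.
#' @param zones a `mob_zones` object ([make_grid_zones()] or
#'   [read_zones_geojson()]).
#' @return The `mob_anchors` object with `zone_ids` set.
#' @export
project_anchors_to_zones <- function(anchor_set, zones) {
  if (missing(zones) || is.null(zones))
    stop_param("no zones supplied; use make_grid_zones() for grid-cell ",
               "fallback zoning")
  a <- anchor_set$anchors
  anchor_set$zone_ids <-
    if (nrow(a) == 0) integer(0)
    else sort(unique(zone_of(a$x, a$y, zones)))
  anchor_set
}

#' Jaccard similarity of two zone-id sets
#'
#' `|a intersect b| / |a union b|`; two empty sets score 0 by convention.
#'
#' @param a,b vectors of zone ids.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard similarity matrix over users' anchor zones
#'
#' @param anchor_sets list of zone-projected `mob_anchors` objects.
#' @return Symmetric matrix with unit diagonal, dimnames = user ids.
#' @export
anchor_similarity_matrix <- function(anchor_sets) {
  n <- length(anchor_sets)
  ids <- vapply(anchor_sets, function(a) a$user_id, character(1))
  S <- diag(1, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      S[i, j] <- S[j, i] <- jaccard_similarity(anchor_sets[[i]]$zone_ids,
                                               anchor_sets[[j]]$zone_ids)
    }
  }
  dimnames(S) <- list(ids, ids)
  S
}

#' Hierarchically cluster users by anchor-set similarity
#'
#' Agglomerative clustering on distance `1 - similarity`. Users with empty
#' anchor sets have similarity 0 to everyone and end up in their own
#' clusters rather than aborting the run.
#'
#' @param similarity symmetric matrix with unit diagonal (from
#'   [anchor_similarity_matrix()]).
#' @param k desired number of clusters, or `NULL` with `h` a distance cut.
#' @param h distance threshold cut (used when `k` is `NULL`).
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return A `mob_clustering` object: list with `labels` (named integer
#'   vector user -> cluster), `similarity`, and the `hclust` merge record.
#' @export
cluster_users <- function(similarity, k = NULL, h = NULL,
                          linkage = "average") {
  if (!isTRUE(all.equal(similarity, t(similarity), tolerance = 1e-8)))
    stop_param("similarity matrix must be symmetric")
  n <- nrow(similarity)
  ids <- rownames(similarity) %||% as.character(seq_len(n))
  if (n == 1) {
    labels <- stats::setNames(1L, ids)
    return(structure(list(labels = labels, similarity = similarity,
                          linkage_record = NULL), class = "mob_clustering"))
  }
  d <- stats::as.dist(1 - similarity)
  hc <- stats::hclust(d, method = linkage)
  labels <- if (!is.null(k)) stats::cutree(hc, k = min(k, n))
            else stats::cutree(hc, h = h %||% 0.5)
  names(labels) <- ids
  structure(list(labels = labels, similarity = similarity,
                 linkage_record = hc),
            class = "mob_clustering")
}

#' @export
print.mob_clustering <- function(x, ...) {
  cat(sprintf("<mob_clustering> %d users in %d cluster(s)\n",
              length(x$labels), length(unique(x$labels))))
  invisible(x)
}
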