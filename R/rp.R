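#' Convex hull of a 2-D point set
#'
#' Counter-clockwise convex polygon containing all points. Collinear point
#' sets (including two-point sets) degenerate to a two-vertex segment hull,
#' which is sufficient for the relative-position index since the extreme
#' points along any direction are retained.
#'
#' @param points n x 2 numeric matrix, n >= 2 distinct points.
#' @return Matrix of hull vertices in counter-clockwise order.
#' @export
convex_hull <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) fs_validation_error("points must be n x 2")
  if (nrow(unique(points)) < 2L)
    fs_validation_error("need >= 2 distinct points for a hull")
  idx <- grDevices::chull(points)
  hull <- points[idx, , drop = FALSE]
  if (nrow(hull) >= 3L) {
    # chull returns clockwise order; reverse to counter-clockwise
    v <- rbind(hull, hull[1, ])
    area2 <- sum(v[-nrow(v), 1] * v[-1, 2] - v[-1, 1] * v[-nrow(v), 2])
    if (area2 < 0) hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  }
  rownames(hull) <- NULL
  colnames(hull) <- c("x", "y")
  hull
}

#' Group geometry: center of mass and convex boundary
#'
#' The center is the arithmetic mean of all the group's points (not only the
#' hull vertices); the boundary is the convex hull.
#'
#' @param points n x 2 scores of one group's wells.
#' @param sample_id optional group label.
#' @return An object of class `group_geometry` with `points`, `center`,
#'   `hull`, `sample_id`.
#' @export
group_geometry <- function(points, sample_id = NA_character_) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) fs_validation_error("points must be n x 2")
  structure(
    list(points = points, center = colMeans(points),
         hull = convex_hull(points), sample_id = sample_id),
    class = "group_geometry"
  )
}

# Scalar projection of (p - from) onto the unit vector of direction `dir`.
scalar_proj <- function(p, from, dir) {
  u <- dir / sqrt(sum(dir^2))
  sum((p - from) * u)
}

# Boundary point of `g` with the smallest scalar projection of (A - ref)
# onto the direction `dir` (vertex of the hull; ties -> smallest index).
extreme_vertex <- function(g, ref, dir) {
  u <- dir / sqrt(sum(dir^2))
  proj <- as.numeric((g$hull - matrix(ref, nrow(g$hull), 2, byrow = TRUE)) %*% u)
  g$hull[which.min(proj), ]
}

#' Relative-position (RP) index of a group pair
#'
#' Quantifies the mutual position of two point groups in the score plane from
#' four key points: the centers of mass C1, C2 and the boundary points A1, A2
#' facing the other group. A1 is the hull vertex of group 1 with the smallest
#' scalar projection of C2->A1 onto C2->C1 (the vertex of group 1 reaching
#' furthest toward/past group 2), and A2 symmetrically. Then
#'
#'   RP_12 = proj(C1->A2 on C1->C2) / proj(C1->A1 on C1->C2)
#'
#' with signed scalar projections. RP_12 > 1 means the groups are separated
#' (the larger, the further apart), 0 < RP_12 < 1 means the boundaries
#' intersect, and RP_12 < 0 means the groups are merged (both centers inside
#' the overlap region). The pair value is min(RP_12, RP_21); boundary values
#' classify conservatively (exactly 1 -> intersecting, exactly 0 -> merged).
#'
#' @param g1,g2 `group_geometry` objects with distinct centers.
#' @return An object of class `rp_result` with `rp_12`, `rp_21`, `rp_pair`,
#'   `classification` (one of `"separated"`, `"intersecting"`, `"merged"`).
#' @export
rp_pairwise <- function(g1, g2) {
  stopifnot(inherits(g1, "group_geometry"), inherits(g2, "group_geometry"))
  d <- g2$center - g1$center
  scale <- max(sqrt(sum(d^2)), 1e-300)
  span <- max(abs(rbind(g1$points, g2$points))) + 1
  if (sqrt(sum(d^2)) < 1e-12 * span)
    fs_computation_error(sprintf(
      "merged: identical centers for groups '%s' and '%s'", g1$sample_id, g2$sample_id))
  one_direction <- function(ga, gb) {
    # RP_ab seen from ga: direction Ca -> Cb
    dir_ab <- gb$center - ga$center
    Aa <- extreme_vertex(ga, gb$center, ga$center - gb$center)  # min proj of Cb->Aa on Cb->Ca
    Ab <- extreme_vertex(gb, ga$center, dir_ab)                  # min proj of Ca->Ab on Ca->Cb
    num <- scalar_proj(Ab, ga$center, dir_ab)
    den <- scalar_proj(Aa, ga$center, dir_ab)
    if (abs(den) < 1e-12 * scale)
      fs_computation_error(sprintf(
        "zero denominator in RP for groups '%s'/'%s': boundary point projects onto the center",
        ga$sample_id, gb$sample_id))
    list(rp = num / den, A_own = Aa, A_other = Ab)
  }
  r12 <- one_direction(g1, g2)
  r21 <- one_direction(g2, g1)
  rp_pair <- min(r12$rp, r21$rp)
  classification <- if (rp_pair > 1) "separated" else if (rp_pair > 0) "intersecting" else "merged"
  structure(
    list(
      sample_a = g1$sample_id, sample_b = g2$sample_id,
      rp_12 = r12$rp, rp_21 = r21$rp, rp_pair = rp_pair,
      classification = classification
    ),
    class = "rp_result"
  )
}

#' @export
print.rp_result <- function(x, ...) {
  cat(sprintf("rp_result: RP_12 = %.4g, RP_21 = %.4g, pair = %.4g (%s)\n",
              x$rp_12, x$rp_21, x$rp_pair, x$classification))
  invisible(x)
}

#' Overall RP over N groups
#'
#' Aggregates the pairwise index over all unordered group pairs using
#' min(RP_ij, RP_ji) per pair. The default `"pair_mean"` normalization is the
#' arithmetic mean over unordered pairs; `"printed"` divides the double sum
#' over ordered pairs by 0.5 N (N - 1), which equals twice the pair mean.
#' Higher values mean better overall discrimination.
#'
#' @param groups list of `group_geometry` objects (>= 2).
#' @param normalization `"pair_mean"` (default) or `"printed"`.
#' @return Dimensionless scalar.
#' @export
rp_overall <- function(groups, normalization = c("pair_mean", "printed")) {
  normalization <- match.arg(normalization)
  if (length(groups) < 2L) fs_validation_error("need >= 2 groups for overall RP")
  vals <- c()
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j > i) {
        res <- tryCatch(rp_pairwise(groups[[i]], groups[[j]]),
          fluorsep_computation_error = function(e) {
            fs_computation_error(sprintf("pair (%s, %s): %s",
              groups[[i]]$sample_id, groups[[j]]$sample_id, conditionMessage(e)))
          })
        vals <- c(vals, res$rp_pair)
      }
    }
  }
  m <- mean(vals)
  if (normalization == "printed") 2 * m else m
}

#' Pairwise RP table for a score cloud's samples
#'
#' @param cloud a `score_cloud`; blanks are excluded.
#' @return data.frame: sample_a, sample_b, rp_ab, rp_ba, rp_pair,
#'   classification.
#' @export
rp_table <- function(cloud) {
  groups <- sample_groups(cloud)
  rows <- list()
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j > i) {
        r <- rp_pairwise(groups[[i]], groups[[j]])
        rows[[length(rows) + 1L]] <- data.frame(
          sample_a = r$sample_a, sample_b = r$sample_b,
          rp_ab = r$rp_12, rp_ba = r$rp_21, rp_pair = r$rp_pair,
          classification = r$classification, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Group geometries of a score cloud's samples (blanks excluded)
#' @param cloud a `score_cloud`.
#' @return Named list of `group_geometry` objects.
#' @export
sample_groups <- function(cloud) {
  stopifnot(inherits(cloud, "score_cloud"))
  meta <- cloud$meta
  keep <- !meta$is_blank
  ids <- unique(meta$sample_id[keep])
  out <- lapply(ids, function(s) {
    group_geometry(cloud$scores[keep & meta$sample_id == s, 1:2, drop = FALSE], sample_id = s)
  })
  names(out) <- ids
  out
}
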