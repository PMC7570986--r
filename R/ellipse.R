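#' Confidence ellipse of a replicate score cloud
#'
#' Builds the elliptical confidence region of one sample's replicate points in
#' the 2-D score plane. The boundary is the set of points x with
#' (x - c)' S^-1 (x - c) = scale2, where c is the replicate mean and S the
#' sample covariance. Two scaling conventions are offered:
#'
#' * `"student"` (default): scale2 = t(1 - (1 - level)/2, n - 1)^2, the squared
#'   two-sided Student quantile. This is a replicate-coverage style region that
#'   visibly covers the replicate points, the convention used when ellipses are
#'   drawn on score plots.
#' * `"hotelling"`: scale2 = 2 (n - 1) / (n (n - 2)) * F(level; 2, n - 2), the
#'   Hotelling T-squared confidence region for the class mean (much smaller).
#'
#' @param points n x 2 matrix of replicate scores, n >= 3, not collinear.
#' @param level confidence level in (0, 1); default 0.80.
#' @param method `"student"` or `"hotelling"` (see above).
#' @param sample_id optional label carried on the object.
#' @return An object of class `confidence_ellipse` with fields `center`,
#'   `cov`, `scale2`, `n`, `level`, `sample_id`.
#' @export
confidence_ellipse <- function(points, level = 0.80,
                               method = c("student", "hotelling"),
                               sample_id = NA_character_) {
  method <- match.arg(method)
  points <- as.matrix(points)
  if (ncol(points) != 2L) fs_validation_error("replicate points must be n x 2")
  n <- nrow(points)
  if (n < 3L) fs_validation_error("need >= 3 replicate points for a confidence ellipse")
  if (!is.finite(level) || level <= 0 || level >= 1)
    fs_validation_error("confidence level must be in (0, 1)")
  ctr <- colMeans(points)
  S <- stats::cov(points)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev, 0) * 1e-12 || min(ev) <= 0)
    fs_computation_error(paste0(
      "singular covariance (collinear or coincident replicates)",
      if (!is.na(sample_id)) paste0(" for sample '", sample_id, "'")
    ))
  scale2 <- switch(method,
    student   = stats::qt(1 - (1 - level) / 2, df = n - 1)^2,
    hotelling = {
      if (n < 4L) fs_validation_error("hotelling region needs n >= 4")
      2 * (n - 1) / (n * (n - 2)) * stats::qf(level, 2, n - 2)
    }
  )
  make_ellipse(ctr, S, scale2, sample_id = sample_id, n = n, level = level)
}

#' Construct an ellipse from explicit geometry
#'
#' Low-level constructor for an elliptical region with boundary
#' (x - center)' cov^-1 (x - center) = scale2. A circle of radius r is
#' `make_ellipse(center, diag(2), r^2)`.
#'
#' @param center length-2 numeric center.
#' @param cov 2 x 2 symmetric positive-definite shape matrix.
#' @param scale2 positive squared Mahalanobis radius of the boundary.
#' @param sample_id,n,level optional metadata.
#' @return A `confidence_ellipse`.
#' @export
make_ellipse <- function(center, cov, scale2, sample_id = NA_character_,
                         n = NA_integer_, level = NA_real_) {
  center <- as.numeric(center)
  cov <- as.matrix(cov)
  if (length(center) != 2L || !all(dim(cov) == 2L))
    fs_validation_error("ellipse geometry must be 2-D")
  if (max(abs(cov - t(cov))) > 1e-8 * max(abs(cov), 1))
    fs_validation_error("covariance must be symmetric")
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) fs_validation_error("covariance must be positive definite")
  if (!is.finite(scale2) || scale2 <= 0) fs_validation_error("scale2 must be positive")
  structure(
    list(center = center, cov = cov, scale2 = scale2,
         sample_id = sample_id, n = n, level = level),
    class = "confidence_ellipse"
  )
}

#' @export
print.confidence_ellipse <- function(x, ...) {
  cat(sprintf(
    "confidence_ellipse%s: center (%.4g, %.4g), scale2 %.4g\n",
    if (!is.na(x$sample_id)) paste0(" [", x$sample_id, "]") else "",
    x$center[1], x$center[2], x$scale2
  ))
  invisible(x)
}

#' Mahalanobis distance to an ellipse's class or an explicit class
#'
#' D_M = sqrt((x - c)' S^-1 (x - c)). With a `confidence_ellipse`, c and S are
#' its center and covariance; with a labelled point set, they are estimated
#' from the points.
#'
#' @param point length-2 numeric, or an n x 2 matrix of points.
#' @param class a `confidence_ellipse`, or an m x 2 matrix of class members
#'   (m >= 3, non-degenerate).
#' @return Non-negative distance(s).
#' @export
mahalanobis_distance <- function(point, class) {
  if (inherits(class, "confidence_ellipse")) {
    ctr <- class$center
    S <- class$cov
  } else {
    pts <- as.matrix(class)
    if (nrow(pts) < 3L) fs_validation_error("class point set needs >= 3 points")
    ctr <- colMeans(pts)
    S <- stats::cov(pts)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev, 0) * 1e-12 || min(ev) <= 0)
    fs_computation_error("singular covariance in Mahalanobis distance")
  x <- if (is.matrix(point)) point else matrix(point, nrow = 1)
  sqrt(stats::mahalanobis(x, center = ctr, cov = S))
}

# Is p strictly inside the elliptical region?
point_in_ellipse <- function(p, e) {
  stats::mahalanobis(matrix(p, nrow = 1), e$center, e$cov) < e$scale2
}

# Evaluate the normalized boundary form h(p) = (p-c)'S^-1(p-c)/scale2 - 1.
# Zero on the boundary, negative inside.
ellipse_form <- function(e, pts) {
  pts <- if (is.matrix(pts)) pts else matrix(pts, nrow = 1)
  stats::mahalanobis(pts, e$center, e$cov) / e$scale2 - 1
}

#' Boundary intersection points of two ellipses
#'
#' Computes all real intersection points of two ellipse boundaries by reducing
#' the pair of conics to a quartic: ellipse `a` is whitened to the unit circle
#' u'u = 1, ellipse `b` becomes a general conic Q(u) = 0, and substituting
#' y^2 = 1 - x^2 yields a degree-4 polynomial in x whose real roots are
#' polished by 2-D Newton iteration on the pair of boundary equations.
#'
#' Transversal crossings are returned once; a tangential contact (parallel
#' boundary normals) is returned twice, so the row count equals the crossing
#' multiplicity used by [pair_crossing_number()]. Coincident boundaries return
#' a zero-row matrix with attribute `coincident = TRUE`.
#'
#' @param a,b `confidence_ellipse` objects.
#' @param tol residual tolerance for accepting a root (normalized boundary
#'   equations), default 1e-7.
#' @return A matrix with 0-4 rows of (x, y) intersection coordinates.
#' @export
ellipse_intersection_points <- function(a, b, tol = 1e-7) {
  stopifnot(inherits(a, "confidence_ellipse"), inherits(b, "confidence_ellipse"))
  # whiten a: boundary of a is p = ca + T u with |u| = 1
  Ra <- chol(a$cov)                      # a$cov = t(Ra) %*% Ra
  Tm <- sqrt(a$scale2) * t(Ra)
  Sbi <- solve(b$cov)
  d <- a$center - b$center
  M <- t(Tm) %*% Sbi %*% Tm / b$scale2   # conic of b in u-space:
  l <- as.numeric(t(Tm) %*% Sbi %*% d) / b$scale2   # u'Mu + 2 l.u + c0 = 0
  c0 <- as.numeric(t(d) %*% Sbi %*% d) / b$scale2 - 1
  msc <- max(abs(M), abs(l), abs(c0), 1)

  # coincident boundaries: conic of b equals the unit circle (M = sI, l = 0,
  # c0 = -s)
  s <- (M[1, 1] + M[2, 2]) / 2
  if (abs(M[1, 1] - s) < 1e-9 * msc && abs(M[2, 2] - s) < 1e-9 * msc &&
      abs(M[1, 2]) < 1e-9 * msc && max(abs(l)) < 1e-9 * msc &&
      abs(c0 + s) < 1e-9 * msc) {
    out <- matrix(numeric(0), ncol = 2)
    attr(out, "coincident") <- TRUE
    return(out)
  }

  # On the unit circle: Q(x, y) = f(x) + y g(x) with y^2 = 1 - x^2,
  # f(x) = (q1-q3) x^2 + q4 x + (q3+q6), g(x) = q2 x + q5
  q1 <- M[1, 1]; q2 <- 2 * M[1, 2]; q3 <- M[2, 2]
  q4 <- 2 * l[1]; q5 <- 2 * l[2]; q6 <- c0
  A2 <- q1 - q3; A1 <- q4; A0 <- q3 + q6
  B1 <- q2; B0 <- q5
  fx <- function(x) (A2 * x + A1) * x + A0
  gx <- function(x) B1 * x + B0
  eps <- 1e-12 * msc

  cand <- list()
  add_candidate <- function(x, y) cand[[length(cand) + 1L]] <<- c(x, y)

  if (max(abs(B1), abs(B0)) < eps) {
    # no y term: solve f(x) = 0; each root with |x| < 1 gives a +/- y pair
    roots <- if (abs(A2) < eps) {
      if (abs(A1) < eps) numeric(0) else -A0 / A1
    } else {
      disc <- A1^2 - 4 * A2 * A0
      if (disc < 0) numeric(0) else (-A1 + c(-1, 1) * sqrt(disc)) / (2 * A2)
    }
    for (x in roots) {
      if (abs(x) <= 1 + 1e-9) {
        x <- max(-1, min(1, x))
        y <- sqrt(max(0, 1 - x^2))
        add_candidate(x, y)
        add_candidate(x, -y)
      }
    }
  } else {
    # quartic f(x)^2 - (1 - x^2) g(x)^2 = 0 (ascending coefficients)
    co <- c(
      A0^2 - B0^2,
      2 * A1 * A0 - 2 * B1 * B0,
      A1^2 + 2 * A2 * A0 + B0^2 - B1^2,
      2 * A2 * A1 + 2 * B1 * B0,
      A2^2 + B1^2
    )
    deg <- max(which(abs(co) > max(abs(co)) * 1e-14))
    if (deg >= 2L) {
      rts <- polyroot(co[seq_len(deg)])
      for (r in rts) {
        if (abs(Im(r)) > 1e-5 * (1 + abs(Re(r)))) next
        x <- Re(r)
        if (abs(x) > 1 + 1e-6) next
        x <- max(-1, min(1, x))
        g <- gx(x)
        if (abs(g) > 1e-8 * msc) {
          add_candidate(x, -fx(x) / g)
        } else {
          y <- sqrt(max(0, 1 - x^2))
          add_candidate(x, y)
          add_candidate(x, -y)
        }
      }
    }
  }
  if (length(cand) == 0L) return(matrix(numeric(0), ncol = 2))

  # Newton-polish each candidate on F(u) = (u.u - 1, Q(u)) and gate on the
  # residual of both boundary equations
  conicQ <- function(u) {
    as.numeric(t(u) %*% M %*% u) + 2 * sum(l * u) + c0
  }
  polished <- matrix(numeric(0), ncol = 2)
  for (u0 in cand) {
    u <- u0
    for (it in 1:4) {
      Fv <- c(sum(u^2) - 1, conicQ(u))
      J <- rbind(2 * u, 2 * as.numeric(M %*% u + l))
      dt <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
      if (abs(dt) < 1e-10 * msc) break   # tangency: Jacobian singular, keep root
      u <- u - solve(J, Fv)
    }
    if (abs(sum(u^2) - 1) <= tol && abs(conicQ(u)) <= tol * msc)
      polished <- rbind(polished, u)
  }
  if (nrow(polished) == 0L) return(matrix(numeric(0), ncol = 2))

  # cluster to unique contact points; multiplicity 2 when boundary normals
  # are parallel there (tangency counts as a double crossing)
  keep <- rep(TRUE, nrow(polished))
  for (i in seq_len(nrow(polished))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(polished))) {
      if (j > i && keep[j] &&
          sum((polished[i, ] - polished[j, ])^2) < (1e-6)^2) keep[j] <- FALSE
    }
  }
  uniq <- polished[keep, , drop = FALSE]
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(uniq))) {
    u <- uniq[i, ]
    n1 <- u                                  # normal of unit circle
    n2 <- as.numeric(M %*% u + l)            # normal of conic b
    crossp <- n1[1] * n2[2] - n1[2] * n2[1]
    tangent <- abs(crossp) < 1e-6 * sqrt(sum(n1^2)) * sqrt(sum(n2^2))
    p <- a$center + as.numeric(Tm %*% u)
    out <- rbind(out, p)
    if (tangent) out <- rbind(out, p)
  }
  if (nrow(out) > 4L) out <- out[seq_len(4L), , drop = FALSE]
  rownames(out) <- NULL
  colnames(out) <- c("x", "y")
  out
}

#' Crossing number of an ellipse pair
#'
#' Classifies the mutual position of two confidence ellipses:
#' * containment (no boundary intersections, one center strictly inside the
#'   other region, including coincident ellipses) is postulated to count as 4
#'   crossings, reflecting maximal overlap;
#' * disjoint ellipses count 0;
#' * otherwise the crossing number equals the number of boundary intersection
#'   points (a tangential contact counts 2).
#'
#' @param a,b `confidence_ellipse` objects.
#' @return An object of class `pair_crossing` with fields `sample_a`,
#'   `sample_b`, `n_boundary_points`, `containment`, `crossing_number`.
#' @export
pair_crossing_number <- function(a, b) {
  pts <- ellipse_intersection_points(a, b)
  coincident <- isTRUE(attr(pts, "coincident"))
  n_pts <- nrow(pts)
  if (n_pts == 0L) {
    containment <- coincident ||
      point_in_ellipse(a$center, b) || point_in_ellipse(b$center, a)
    crn <- if (containment) 4L else 0L
  } else {
    containment <- FALSE
    crn <- min(n_pts, 4L)
  }
  structure(
    list(
      sample_a = a$sample_id, sample_b = b$sample_id,
      n_boundary_points = if (containment) 0L else as.integer(n_pts),
      containment = containment,
      crossing_number = as.integer(crn),
      points = pts
    ),
    class = "pair_crossing"
  )
}

#' Total crossing number (CrN) over a score plot
#'
#' Sums the pairwise crossing numbers over all unordered pairs of sample
#' confidence ellipses. Lower CrN means better discrimination: a plot of
#' mutually disjoint ellipses scores 0.
#'
#' @param ellipses list of `confidence_ellipse` objects (>= 2).
#' @return Non-negative integer total.
#' @export
total_crossing_number <- function(ellipses) {
  if (length(ellipses) < 2L) fs_validation_error("need >= 2 ellipses for CrN")
  total <- 0L
  for (i in seq_along(ellipses)) {
    for (j in seq_along(ellipses)) {
      if (j > i)
        total <- total + pair_crossing_number(ellipses[[i]], ellipses[[j]])$crossing_number
    }
  }
  total
}

#' Pairwise crossing table for a set of ellipses
#'
#' @param ellipses list of `confidence_ellipse` objects.
#' @return data.frame with one row per unordered pair: `sample_a`, `sample_b`,
#'   `n_points`, `containment`, `crossing_number`.
#' @export
crossing_table <- function(ellipses) {
  rows <- list()
  for (i in seq_along(ellipses)) {
    for (j in seq_along(ellipses)) {
      if (j > i) {
        pc <- pair_crossing_number(ellipses[[i]], ellipses[[j]])
        rows[[length(rows) + 1L]] <- data.frame(
          sample_a = pc$sample_a, sample_b = pc$sample_b,
          n_points = pc$n_boundary_points, containment = pc$containment,
          crossing_number = pc$crossing_number, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Number of discriminated groups
#'
#' Samples are considered separated when their confidence ellipses do not
#' intersect; samples linked by intersecting ellipses merge transitively into
#' one group. The count of connected components is the "number of groups"
#' discrimination metric (higher is better, maximum = number of samples).
#'
#' An alternative predicate links two samples when the Mahalanobis distance
#' between their centers, under the pooled within-pair covariance, is below
#' `dm_threshold` (default 4, the distance that corresponds to visual
#' non-intersection of 80% ellipses for 5 replicates).
#'
#' @param ellipses list of `confidence_ellipse` objects (>= 1); the
#'   Mahalanobis predicate needs the `n` field set (true for ellipses from
#'   [confidence_ellipse()]).
#' @param predicate `"ellipse"` (default) or `"mahalanobis"`.
#' @param dm_threshold center-distance threshold for the Mahalanobis predicate.
#' @return Positive integer number of groups.
#' @export
count_groups <- function(ellipses, predicate = c("ellipse", "mahalanobis"),
                         dm_threshold = 4) {
  predicate <- match.arg(predicate)
  n <- length(ellipses)
  if (n < 1L) fs_validation_error("need >= 1 ellipse")
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        linked <- if (predicate == "ellipse") {
          pair_crossing_number(ellipses[[i]], ellipses[[j]])$crossing_number > 0L
        } else {
          a <- ellipses[[i]]; b <- ellipses[[j]]
          na <- if (is.na(a$n)) 2L else a$n
          nb <- if (is.na(b$n)) 2L else b$n
          Sp <- ((na - 1) * a$cov + (nb - 1) * b$cov) / (na + nb - 2)
          dm <- sqrt(stats::mahalanobis(matrix(a$center, 1), b$center, Sp))
          dm < dm_threshold
        }
        adj[i, j] <- adj[j, i] <- linked
      }
    }
  }
  n_components(adj)
}

#' Fit one confidence ellipse per sample of a score cloud
#'
#' Blank wells are excluded; each remaining sample's replicate scores (first
#' two components) get a [confidence_ellipse()].
#'
#' @param cloud a `score_cloud`.
#' @param level confidence level, default 0.80.
#' @param method scaling convention, see [confidence_ellipse()].
#' @return Named list of `confidence_ellipse` objects, one per sample.
#' @export
sample_ellipses <- function(cloud, level = 0.80, method = "student") {
  stopifnot(inherits(cloud, "score_cloud"))
  meta <- cloud$meta
  keep <- !meta$is_blank
  ids <- unique(meta$sample_id[keep])
  out <- lapply(ids, function(s) {
    pts <- cloud$scores[keep & meta$sample_id == s, 1:2, drop = FALSE]
    confidence_ellipse(pts, level = level, method = method, sample_id = s)
  })
  names(out) <- ids
  out
}

#' Ellipse table for export
#' @param ellipses named list of `confidence_ellipse` objects.
#' @return data.frame: sample_id, cx, cy, cov_xx, cov_xy, cov_yy, scale2.
#' @export
ellipse_table <- function(ellipses) {
  do.call(rbind, lapply(ellipses, function(e) data.frame(
    sample_id = e$sample_id, cx = e$center[1], cy = e$center[2],
    cov_xx = e$cov[1, 1], cov_xy = e$cov[1, 2], cov_yy = e$cov[2, 2],
    scale2 = e$scale2, stringsAsFactors = FALSE
  )))
}
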