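# Shared fixtures and independent oracles, all built in code.

circle <- function(cx, cy, r, id = NA_character_) {
  make_ellipse(c(cx, cy), diag(2), r^2, sample_id = id)
}

random_ellipse <- function() {
  ctr <- stats::runif(2, -3, 3)
  A <- matrix(stats::rnorm(4), 2)
  S <- A %*% t(A) + diag(2) * 0.05
  make_ellipse(ctr, S, stats::runif(1, 0.5, 4))
}

# Independent crossing-count oracle: densely sample the boundary of `a`
# parametrically and count sign changes of b's normalized boundary form.
oracle_crossings <- function(a, b, m = 4096) {
  th <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  Ra <- chol(a$cov)
  Tm <- sqrt(a$scale2) * t(Ra)
  pts <- t(a$center + Tm %*% rbind(cos(th), sin(th)))
  h <- stats::mahalanobis(pts, b$center, b$cov) / b$scale2 - 1
  s <- sign(h)
  sum(s != c(s[-1], s[1]))
}

# O(n^3) brute-force convex hull: a point is a hull vertex iff it is not
# strictly inside the triangle of any three other points.
brute_hull_vertices <- function(pts) {
  n <- nrow(pts)
  in_triangle <- function(p, a, b, c) {
    s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
    s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
    (s1 > 0 && s2 > 0 && s3 > 0) || (s1 < 0 && s2 < 0 && s3 < 0)
  }
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    for (a in others) for (b in others) for (c in others) {
      if (a < b && b < c &&
          in_triangle(pts[i, ], pts[a, ], pts[b, ], pts[c, ])) {
        keep[i] <- FALSE
      }
    }
  }
  pts[keep, , drop = FALSE]
}

# Small raw-spectra fixture: one condition, two samples x 2 replicates plus a
# blank, 3 wavelengths.
tiny_spectra <- function() {
  vals <- rbind(
    c(10, 20, 30), c(11, 21, 31),
    c(40, 50, 60), c(41, 51, 61),
    c(10, 10, 10)
  )
  meta <- data.frame(
    well_id = paste0("w", 1:5),
    sample_id = c("A", "A", "B", "B", "BLK"),
    replicate = c(1, 2, 1, 2, 1),
    is_blank = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    condition = "c1", stringsAsFactors = FALSE
  )
  spectra_matrix(vals, c(400, 401, 402), meta)
}

write_tiny_csvs <- function(dir) {
  sp <- tiny_spectra()
  spath <- file.path(dir, "spectra.csv")
  mpath <- file.path(dir, "meta.csv")
  write_spectra(sp, spath, mpath)
  list(spectra = spath, meta = mpath)
}

# Hand-verified Mahalanobis-membership fixture: class A's fifth well sits
# within D_M <= 4 of both classes; every other well matches only its own.
ambiguous_fixture <- function() {
  A <- rbind(c(0.1, 0), c(-0.1, 0), c(0, 0.1), c(0, -0.1), c(1, 0))
  B <- rbind(c(5.2, 0), c(2.8, 0), c(4, 1.2), c(4, -1.2), c(4, 0))
  list(scores = rbind(A, B), labels = rep(c("A", "B"), each = 5))
}
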