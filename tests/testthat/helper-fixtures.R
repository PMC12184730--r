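# Small hand-constructed segment tables used across the module tests.

# A valid two-whisker segment table with simple geometry.
make_segments <- function() {
  data.frame(
    whisker_id = rep(c("W1", "W2"), each = 3),
    animal_id = rep(c("A1", "A2"), each = 3),
    sex = rep(c("F", "M"), each = 3),
    sampling_year = rep(c(2018L, 2019L), each = 3),
    collection_date = rep(as.Date(c("2018-02-01", "2019-03-01")), each = 3),
    segment_index = rep(0:2, 2),
    start_mm = rep(c(0, 2, 4), 2),
    end_mm = rep(c(2, 4, 6), 2),
    d13C = c(-22.1, -22.3, -21.9, -21.5, -21.7, -21.6),
    d15N = c(11.2, 11.5, 11.1, 9.8, 9.9, 10.1),
    cn_ratio = c(3.2, 3.5, 3.8, 3.1, 3.4, 3.6),
    stringsAsFactors = FALSE
  )
}

# A niche_ellipse with prescribed geometry (unit circle by default), for
# geometric tests that need exact shapes rather than fitted ones.
make_ellipse <- function(mu = c(0, 0), sigma = diag(2), n = 1000) {
  sea <- pi * sqrt(det(sigma))
  structure(list(mu = mu, sigma = sigma, n = n, sea = sea,
                 seac = sea * (n - 1) / (n - 2)),
            class = "niche_ellipse")
}

# Test whether points (rows of `pts`) lie inside a counter-clockwise convex
# polygon, via signs of edge cross products. Independent of the package's
# clipping code.
points_in_convex_polygon <- function(pts, poly) {
  inside <- rep(TRUE, nrow(pts))
  np <- nrow(poly)
  for (i in seq_len(np)) {
    a <- poly[i, ]
    b <- poly[if (i == np) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (pts[, 2] - a[2]) -
      (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & cross >= -1e-12
  }
  inside
}
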