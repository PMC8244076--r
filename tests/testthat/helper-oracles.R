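# Independent oracles used across the test suite.  These deliberately do
# not share code with the package implementation.

# Exhaustive point-to-triangle minimization: for every triangle evaluate
# the in-plane projection (if its barycentric coordinates are inside), the
# three clamped edge projections, and the three vertices, and return the
# global minimum distance.
oracle_surface_distance <- function(q, s) {
  p <- s$points; tr <- s$triangles
  vapply(seq_len(nrow(q)), function(iq) {
    x <- q[iq, ]
    best <- Inf
    for (t1 in seq_len(nrow(tr))) {
      a <- p[tr[t1, 1], ]; b <- p[tr[t1, 2], ]; c <- p[tr[t1, 3], ]
      # vertices
      best <- min(best, sqrt(sum((x - a)^2)), sqrt(sum((x - b)^2)), sqrt(sum((x - c)^2)))
      # edges
      for (e in list(list(a, b), list(b, c), list(c, a))) {
        d <- e[[2]] - e[[1]]
        t2 <- sum((x - e[[1]]) * d) / sum(d * d)
        t2 <- min(1, max(0, t2))
        best <- min(best, sqrt(sum((x - e[[1]] - t2 * d)^2)))
      }
      # face interior
      n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
             (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
             (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
      nn <- sum(n * n)
      if (nn > 0) {
        proj <- x - n * sum((x - a) * n) / nn
        # barycentric test via areas
        area2 <- function(u, v, w) {
          cr <- c((v - u)[2] * (w - u)[3] - (v - u)[3] * (w - u)[2],
                  (v - u)[3] * (w - u)[1] - (v - u)[1] * (w - u)[3],
                  (v - u)[1] * (w - u)[2] - (v - u)[2] * (w - u)[1])
          sum(cr * n) / sqrt(nn)
        }
        A <- area2(a, b, c)
        l1 <- area2(proj, b, c) / A; l2 <- area2(a, proj, c) / A; l3 <- area2(a, b, proj) / A
        if (l1 >= -1e-12 && l2 >= -1e-12 && l3 >= -1e-12)
          best <- min(best, sqrt(sum((x - proj)^2)))
      }
    }
    best
  }, numeric(1))
}

# Step-by-step greedy-zipper simulator: a direct transcription of the
# published procedure, kept independent of the package implementation.
# Returns the triangle list in band-local indices (ring1 points first).
oracle_zipper <- function(q1, q2) {
  n1 <- nrow(q1); n2 <- nrow(q2)
  d2 <- function(a, b) sum((a - b)^2)
  # start: first point of ring1, closest point of ring2
  s1 <- 1L
  s2 <- which.min(apply(q2, 1, function(r) d2(r, q1[s1, ])))
  succ1 <- function(k) if (k == n1) 1L else k + 1L
  cand1 <- succ1(s1)
  fw <- if (s2 == n2) 1L else s2 + 1L
  bw <- if (s2 == 1L) n2 else s2 - 1L
  dir2 <- if (d2(q2[fw, ], q1[cand1, ]) <= d2(q2[bw, ], q1[cand1, ])) 1L else -1L
  succ2 <- function(k) { k2 <- k + dir2; if (k2 == 0L) n2 else if (k2 == n2 + 1L) 1L else k2 }
  cand2 <- succ2(s2)
  P1 <- s1; P2 <- s2
  ins1 <- 1L; ins2 <- 1L
  tris <- NULL
  i <- 2L
  repeat {
    if (i > n1 + n2) break
    dA <- d2(q1[cand1, ], q2[P2, ])
    dB <- d2(q2[cand2, ], q1[P1, ])
    take1 <- dA <= dB
    if (ins1 > n1) take1 <- FALSE
    if (ins2 > n2) take1 <- TRUE
    if (take1) {
      tris <- rbind(tris, c(P1, n1 + P2, cand1))
      P1 <- cand1
      ins1 <- ins1 + 1L
      cand1 <- if (ins1 < n1) succ1(P1) else s1
    } else {
      tris <- rbind(tris, c(P1, n1 + P2, n1 + cand2))
      P2 <- cand2
      ins2 <- ins2 + 1L
      cand2 <- if (ins2 < n2) succ2(P2) else s2
    }
    i <- i + 1L
  }
  if (ins1 > n1) tris <- rbind(tris, c(P1, n1 + P2, n1 + s2))
  else tris <- rbind(tris, c(P1, n1 + P2, s1))
  tris
}

# Random closed ring of n points: wobbly circle, optionally in a shifted
# parallel plane.
random_ring <- function(n, seed, z = 0, r0 = 1) {
  set.seed(seed)
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- r0 * (1 + stats::runif(1, -0.3, 0.3) * cos(sample(2:5, 1) * t) +
               stats::runif(n, -0.05, 0.05))
  cbind(r * cos(t), r * sin(t), z + stats::runif(n, -0.05, 0.05))
}

# Open fan disk whose single boundary ring is exactly `ring` (row order);
# flip controls which side the apex sits on / the winding.
ring_disk <- function(ring, apex_offset = c(0, 0, -0.5), flip = FALSE) {
  n <- nrow(ring)
  apex <- colMeans(ring) + apex_offset
  tr <- cbind(seq_len(n), c(2:n, 1L), n + 1L)
  if (flip) tr <- tr[, c(2, 1, 3)]
  tri_surface(rbind(ring, apex), tr)
}

# Union-find connected-components count over triangle edge adjacency.
oracle_component_count <- function(s, cells = seq_len(nrow(s$triangles))) {
  tr <- s$triangles[cells, , drop = FALSE]
  parent <- seq_len(nrow(tr))
  find <- function(x) { while (parent[x] != x) { x <- parent[x] }; x }
  ek <- list()
  for (k in 1:3) {
    a <- pmin(tr[, k], tr[, k %% 3 + 1]); b <- pmax(tr[, k], tr[, k %% 3 + 1])
    ek[[k]] <- paste(a, b)
  }
  edge_map <- split(rep(seq_len(nrow(tr)), 3), unlist(ek))
  for (grp in edge_map) if (length(grp) > 1) {
    r0 <- find(grp[1])
    for (g in grp[-1]) { r1 <- find(g); if (r0 != r1) parent[r1] <- r0 }
  }
  length(unique(vapply(seq_len(nrow(tr)), find, integer(1))))
}

# mesh fingerprint: sorted cell signatures on rounded coordinates --
# equality up to reindexing
cell_fingerprint <- function(s, cells = seq_len(nrow(s$triangles)), digits = 9) {
  sig <- vapply(cells, function(c1) {
    v <- s$triangles[c1, ]
    crd <- round(s$points[v, , drop = FALSE], digits)
    paste(sort(apply(crd, 1, paste, collapse = ",")), collapse = ";")
  }, character(1))
  sort(sig)
}

edge_lengths_of <- function(s) {
  tr <- s$triangles
  i <- c(tr[, 1], tr[, 2], tr[, 3]); j <- c(tr[, 2], tr[, 3], tr[, 1])
  key <- paste(pmin(i, j), pmax(i, j))
  keep <- !duplicated(key)
  sqrt(rowSums((s$points[i[keep], , drop = FALSE] - s$points[j[keep], , drop = FALSE])^2))
}

# points on the ring separating two cell-tag groups
inter_tag_points <- function(s, tag) {
  a <- unique(as.vector(s$triangles[s$cell_tags == tag, , drop = FALSE]))
  b <- unique(as.vector(s$triangles[s$cell_tags != tag, , drop = FALSE]))
  intersect(a, b)
}
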