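# Shared fixtures and independent oracles. Fixtures are built in code; no
# binary files are stored.

# UV sphere mesh (n_lat rings x n_lon meridians), radius r, centered at ctr.
make_uv_sphere <- function(r = 1, n_lat = 24, n_lon = 48, ctr = c(0, 0, 0)) {
  lat <- seq(0, pi, length.out = n_lat + 1)
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  # interior rings plus two pole vertices
  verts <- rbind(c(0, 0, r),
                 do.call(rbind, lapply(lat[-c(1, n_lat + 1)], function(th)
                   cbind(r * sin(th) * cos(lon), r * sin(th) * sin(lon),
                         r * cos(th)))),
                 c(0, 0, -r))
  verts <- sweep(verts, 2, ctr, "+")
  nr <- n_lat - 1  # interior rings
  idx <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 0L
  faces <- list()
  # top cap
  for (j in seq_len(n_lon))
    faces[[length(faces) + 1L]] <- c(1L, idx(1, j) + 1L, idx(1, j + 1) + 1L)
  # bands
  if (nr > 1) for (i in seq_len(nr - 1)) for (j in seq_len(n_lon)) {
    a <- idx(i, j) + 1L; b <- idx(i, j + 1) + 1L
    c3 <- idx(i + 1, j) + 1L; d <- idx(i + 1, j + 1) + 1L
    faces[[length(faces) + 1L]] <- c(a, c3, b)
    faces[[length(faces) + 1L]] <- c(b, c3, d)
  }
  # bottom cap
  last <- nrow(verts)
  for (j in seq_len(n_lon))
    faces[[length(faces) + 1L]] <- c(last, idx(nr, j + 1) + 1L, idx(nr, j) + 1L)
  f <- do.call(rbind, faces)
  # orient all faces outward
  m <- surface_mesh(verts, f, subject_id = "sphere")
  fc <- (verts[f[, 1], ] + verts[f[, 2], ] + verts[f[, 3], ]) / 3
  nrm <- aortashape:::face_normals(verts, f)
  out <- rowSums(nrm * sweep(fc, 2, ctr)) > 0
  f[!out, ] <- f[!out, c(1, 3, 2)]
  surface_mesh(verts, f, subject_id = "sphere")
}

# straight-axis cylinder tube mesh via the package generator
make_cylinder <- function(radius = 20, length = 100, n_axial = 40, n_circ = 48) {
  cl <- make_centerline(length, 0, n_axial, arc_angle_deg = 0)
  make_tube(cl, radius, n_circ, subject_id = "cylinder")
}

# unit tetrahedron mesh (smallest valid mesh)
make_tetrahedron <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  surface_mesh(v, f, subject_id = "tet")
}

# --- independent oracles ---

# Pearson correlation by the raw covariance/variance formula.
pearson_bruteforce <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy / sqrt(sxx * syy)
}

# AUC by pairwise enumeration: P(score_pos > score_neg) + 0.5 P(tie).
auc_pairs <- function(prob, labels) {
  labels <- as.logical(labels)
  pos <- prob[labels]
  neg <- prob[!labels]
  wins <- 0
  for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# PCA by explicit covariance eigendecomposition (feasible only at tiny 3N).
pca_bruteforce <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / (nrow(X) - 1)
  eigen(C, symmetric = TRUE)
}

# a small cohort CSV written to a temp file
write_cohort_fixture <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

base_cohort_df <- function(n = 2) {
  data.frame(subject_id = sprintf("P%02d", seq_len(n)),
             valve = rep(c("BAV", "TAV"), length.out = n),
             surgery = rep(c(TRUE, FALSE), length.out = n),
             diameter_sinus = seq(40, by = 1, length.out = n),
             diameter_stj = seq(35, by = 1, length.out = n),
             diameter_midaa = seq(44, by = 1, length.out = n),
             orifice_area = seq(300, by = 5, length.out = n),
             flow_jet = seq(1.5, by = 0.1, length.out = n))
}
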