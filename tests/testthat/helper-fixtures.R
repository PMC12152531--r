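# Shared fixtures: tiny annotation sets built in code, random instance
# generators, and independent oracles used by the property tests.

mk_meta <- function(id = "m-0001", ...) micrograph_meta(id, ...)

mk_set <- function(particles_xy, fibrils_xyxy, label = "s1",
                   meta = mk_meta()) {
  particles <- tibble::tibble(
    particle_id = sprintf("p%03d", seq_len(nrow(particles_xy))),
    x = particles_xy[, 1], y = particles_xy[, 2])
  fibrils <- tibble::tibble(
    fibril_id = sprintf("f%03d", seq_len(nrow(fibrils_xyxy))),
    x1 = fibrils_xyxy[, 1], y1 = fibrils_xyxy[, 2],
    x2 = fibrils_xyxy[, 3], y2 = fibrils_xyxy[, 4])
  annotation_set(meta, particles, fibrils, sample_label = label)
}

# random micrograph-like instance: particles and non-degenerate fibrils
# scattered over a square field
random_instance <- function(n_particles, n_fibrils, extent = 1000) {
  particles <- cbind(runif(n_particles, 0, extent),
                     runif(n_particles, 0, extent))
  fib <- matrix(NA_real_, n_fibrils, 4)
  for (i in seq_len(n_fibrils)) {
    repeat {
      f <- runif(4, 0, extent)
      if ((f[1] - f[3])^2 + (f[2] - f[4])^2 > 1) break
    }
    fib[i, ] <- f
  }
  mk_set(particles, fib)
}

# independent point-to-segment distance: cross-product formula for the
# interior case, explicit endpoint branches otherwise
oracle_psd <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  L <- sqrt(vx^2 + vy^2)
  t <- ((px - x1) * vx + (py - y1) * vy) / L^2
  if (t < 0) {
    sqrt((px - x1)^2 + (py - y1)^2)
  } else if (t > 1) {
    sqrt((px - x2)^2 + (py - y2)^2)
  } else {
    abs(vx * (py - y1) - vy * (px - x1)) / L
  }
}

# brute-force assignment oracle: explicit double loop over all
# particle-fibril pairs, first-minimum tie-break
oracle_assign <- function(ann, params) {
  P <- ann$particles; Fb <- ann$fibrils
  out <- data.frame(particle_id = P$particle_id,
                    status = "unbound",
                    fibril_id = NA_character_,
                    distance = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(Fb) == 0) return(out)
  for (i in seq_len(nrow(P))) {
    d <- numeric(nrow(Fb))
    for (j in seq_len(nrow(Fb))) {
      d[j] <- oracle_psd(P$x[i], P$y[i],
                         Fb$x1[j], Fb$y1[j], Fb$x2[j], Fb$y2[j])
    }
    j_best <- which.min(d)
    out$distance[i] <- d[j_best]
    if (d[j_best] <= params$threshold) {
      out$status[i] <- "bound"
      out$fibril_id[i] <- Fb$fibril_id[j_best]
    }
  }
  out
}

# write a tiny annotation CSV pair to a temp dir; returns the two paths
write_annotation_fixture <- function(dir, particles, fibrils) {
  pf <- file.path(dir, "particles.csv")
  ff <- file.path(dir, "fibrils.csv")
  utils::write.csv(particles, pf, row.names = FALSE)
  utils::write.csv(fibrils, ff, row.names = FALSE)
  list(particles = pf, fibrils = ff)
}
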