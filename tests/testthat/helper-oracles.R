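# Brute-force reference implementations used as independent oracles.
# These are deliberately written as plain voxel loops / textbook formulas,
# sharing no code with the package internals they check.

# per-voxel scalar-loop PE computation
oracle_pe_maps <- function(s0, s_early, s_late, floor) {
  d <- dim(s0)
  pe_e <- pe_l <- array(NA_real_, d)
  valid <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (s0[i, j, k] > floor) {
      valid[i, j, k] <- TRUE
      pe_e[i, j, k] <- (s_early[i, j, k] - s0[i, j, k]) / s0[i, j, k] * 100
      pe_l[i, j, k] <- (s_late[i, j, k] - s0[i, j, k]) / s0[i, j, k] * 100
    }
  }
  list(pe_early = pe_e, pe_late = pe_l, valid = valid)
}

# triple-loop maximum intensity projection
oracle_mip <- function(vol, axis) {
  d <- dim(vol)
  rest <- setdiff(1:3, axis)
  out <- array(-Inf, d[rest])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    ijk <- c(i, j, k)
    out[ijk[rest[1]], ijk[rest[2]]] <-
      max(out[ijk[rest[1]], ijk[rest[2]]], vol[i, j, k])
  }
  out
}

# neighbor offsets for a given 3D connectivity
oracle_offsets <- function(connectivity) {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  manh <- rowSums(abs(offs))
  keep <- switch(as.character(connectivity),
                 "6" = manh == 1, "18" = manh <= 2, "26" = rep(TRUE, nrow(offs)))
  as.matrix(offs[keep, ])
}

# flood-fill (BFS) connected-component labeling
oracle_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- oracle_offsets(connectivity)
  lab <- array(0L, d)
  cur <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k] || lab[i, j, k] > 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j, k), ncol = 3)
    lab[i, j, k] <- cur
    while (nrow(queue) > 0) {
      v <- queue[1, , drop = TRUE]
      queue <- queue[-1, , drop = FALSE]
      for (o in seq_len(nrow(offs))) {
        w <- v + offs[o, ]
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- cur
          queue <- rbind(queue, w)
        }
      }
    }
  }
  lab
}

# full brute-force FTV: threshold, flood-fill filter, SER gate, count
oracle_ftv <- function(pe_early, ser, valid, voi, voxel_cc, pe_t, ser_t,
                       min_cluster, connectivity = 26) {
  d <- dim(pe_early)
  mask <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    mask[i, j, k] <- isTRUE(valid[i, j, k]) && isTRUE(voi[i, j, k]) &&
      !is.na(pe_early[i, j, k]) && pe_early[i, j, k] >= pe_t
  }
  lab <- oracle_label(mask, connectivity)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0L])
    for (c_id in which(sizes < min_cluster)) mask[lab == c_id] <- FALSE
  }
  count <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] && !is.na(ser[i, j, k]) && ser[i, j, k] >= ser_t)
      count <- count + 1L
  }
  count * voxel_cc
}

# random study fixture with controllable shape and intensity range
random_study <- function(shape = c(8, 8, 4), smax = 500,
                         voxel_size_mm = c(0.7, 0.94, 2.0)) {
  n <- prod(shape)
  dce_study(array(stats::runif(n, 1, smax), shape),
            array(stats::runif(n, 0, 2 * smax), shape),
            array(stats::runif(n, 0, 2 * smax), shape),
            voxel_size_mm = voxel_size_mm)
}

# clustered random mask: a few seeded blobs plus salt noise, so that the
# connectivity filter has real work to do
random_blob_mask <- function(shape, n_blobs = 3, blob_r = 2, salt = 0.02) {
  m <- array(FALSE, shape)
  for (b in seq_len(n_blobs)) {
    c0 <- sapply(shape, function(s) sample(s, 1))
    for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
      for (k in seq_len(shape[3])) {
        if (sum((c(i, j, k) - c0)^2) <= blob_r^2) m[i, j, k] <- TRUE
      }
  }
  m | array(stats::runif(prod(shape)) < salt, shape)
}
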