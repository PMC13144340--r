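# shared fixtures and independent oracles for the test suite

# a small cohort configuration; overrides via ...
tiny_config <- function(...) {
  args <- list(n_participants = 4, grid_dims = c(6L, 6L, 6L), n_stimuli = 3,
               segment_duration_s = 60, gap_s = 3,
               kappa_by_frame = c(neutral = 1, threat = 1, blame = 1),
               gamma_proximity = 0, seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# memoised cohorts so several tests can share one simulation
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# rows of signal voxels within the masked matrices
signal_rows <- function(cohort, voxel_ids) {
  match(cohort$truth$signal_voxel_ids, voxel_ids)
}

# independent least-squares oracle via the normal equations
ols_oracle <- function(x, y) {
  xtx <- crossprod(x)
  beta <- solve(xtx, crossprod(x, y))
  res <- y - x %*% beta
  df <- nrow(x) - ncol(x)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(xtx)) * s2)
  list(beta = drop(beta), se = se, residuals = drop(res), df = df)
}

# brute-force TFCE oracle: explicit per-threshold connected-component
# summation with a plain flood fill (independent of the compiled path)
tfce_oracle <- function(stat3d, mask, E = 0.5, H = 2, dh, connectivity = 6) {
  dims <- dim(mask)
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  s <- abs(offsets$dx) + abs(offsets$dy) + abs(offsets$dz)
  keep <- if (connectivity == 6) s == 1 else if (connectivity == 18)
    s >= 1 & s <= 2 else s >= 1
  offsets <- offsets[keep, ]
  enhance <- function(w) {
    out <- array(0, dims)
    vmax <- max(w)
    if (vmax <= 0) return(out)
    for (h in seq(dh, vmax + 1e-12, by = dh)) {
      active <- w + 1e-12 >= h & mask != 0
      seen <- array(FALSE, dims)
      for (start in which(active & !seen)) {
        if (seen[start]) next
        queue <- start
        comp <- integer(0)
        seen[start] <- TRUE
        while (length(queue) > 0) {
          v <- queue[1]; queue <- queue[-1]
          comp <- c(comp, v)
          pos <- arrayInd(v, dims)
          for (o in seq_len(nrow(offsets))) {
            p <- pos + c(offsets$dx[o], offsets$dy[o], offsets$dz[o])
            if (any(p < 1) || any(p > dims)) next
            li <- p[1] + (p[2] - 1) * dims[1] + (p[3] - 1) * dims[1] * dims[2]
            if (active[li] && !seen[li]) {
              seen[li] <- TRUE
              queue <- c(queue, li)
            }
          }
        }
        out[comp] <- out[comp] + length(comp)^E * h^H * dh
      }
    }
    out
  }
  enhance(pmax(stat3d, 0)) - enhance(pmax(-stat3d, 0))
}
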