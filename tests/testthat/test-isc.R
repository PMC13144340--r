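test_that("pearson_map matches the definitional oracle and handles
          degenerate voxels", {
  set.seed(4)
  a <- matrix(rnorm(6 * 5), 6, 5)
  b <- matrix(rnorm(6 * 5), 6, 5)
  r <- pearson_map(a, b)
  oracle <- vapply(1:6, function(v) cor(a[v, ], b[v, ]), numeric(1))
  expect_lt(max(abs(r - oracle)), 1e-12)
  expect_equal(attr(r, "n_zero_variance"), 0)

  expect_equal(as.numeric(pearson_map(a, a)), rep(1, 6), tolerance = 1e-12)
  expect_equal(as.numeric(pearson_map(a, -a)), rep(-1, 6), tolerance = 1e-12)

  a0 <- a; a0[3, ] <- 7  # constant series
  r0 <- pearson_map(a0, b)
  expect_equal(r0[3], 0)
  expect_equal(attr(r0, "n_zero_variance"), 1)

  expect_error(pearson_map(a, b[, 1:4]), "dimensions differ")
  expect_error(pearson_map(a[, 1:2], b[, 1:2]), "at least 3")
})

test_that("fisher_z is atanh with a finite clamp at |r| = 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.9), 1.4722, tolerance = 1e-4)
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_lt(fisher_z(1), 8.5)
  expect_equal(fisher_z(-1), -fisher_z(1))
  expect_error(fisher_z(1.01), "outside")
})

test_that("all_pair_maps produces one symmetric map per pair and segment", {
  co <- cached("tiny_cohort", simulate_cohort(tiny_config()))
  pre <- cached("tiny_pre", preprocess_cohort(co))
  pm <- all_pair_maps(pre$series_by_participant, pre$segments, pre$voxel_ids)
  n <- length(pre$series_by_participant)
  expect_equal(dim(pm$z)[2], n * (n - 1) / 2)
  expect_equal(dim(pm$z)[3], nrow(pre$segments))
  expect_equal(nrow(participant_pairs(1:27)), 351)  # C(27, 2)
  # symmetry: reversing participant order leaves each pair's map unchanged
  rev_series <- rev(pre$series_by_participant)
  pm_rev <- all_pair_maps(rev_series, pre$segments, pre$voxel_ids)
  k <- which(pm$pairs$i == "sub01" & pm$pairs$j == "sub02")
  k_rev <- which((pm_rev$pairs$i == "sub01" & pm_rev$pairs$j == "sub02") |
                   (pm_rev$pairs$i == "sub02" & pm_rev$pairs$j == "sub01"))
  expect_equal(pm$z[, k, ], pm_rev$z[, k_rev, ], tolerance = 1e-12)
  # missing segment is a named error
  broken <- pre$series_by_participant
  broken[[2]] <- broken[[2]][-1]
  expect_error(all_pair_maps(broken, pre$segments, pre$voxel_ids),
               "missing segments")
})

test_that("pipeline z-maps equal brute-force atanh(cor) voxel by voxel", {
  # independent oracle on a small toy: per-voxel cor() + atanh
  set.seed(11)
  dims <- c(4L, 4L, 4L)
  series <- lapply(1:3, function(i)
    lapply(1:2, function(s) matrix(rnorm(prod(dims) * 30), prod(dims), 30)))
  names(series) <- paste0("p", 1:3)
  segments <- data.frame(stimulus_id = c("s1", "s2"),
                         frame = c("neutral", "blame"),
                         topic = c("t", "t"))
  pm <- all_pair_maps(series, segments, seq_len(prod(dims)))
  pairs <- participant_pairs(names(series))
  for (k in seq_len(nrow(pairs))) for (s in 1:2) {
    oracle <- atanh(vapply(seq_len(prod(dims)), function(v)
      cor(series[[pairs$i_idx[k]]][[s]][v, ],
          series[[pairs$j_idx[k]]][[s]][v, ]), numeric(1)))
    expect_lt(max(abs(pm$z[, k, s] - oracle)), 1e-10)
  }
})

test_that("condition averaging is the element-wise mean within groups", {
  set.seed(12)
  v <- 10
  series <- lapply(1:2, function(i)
    lapply(1:6, function(s) matrix(rnorm(v * 20), v, 20)))
  names(series) <- c("a", "b")
  segments <- data.frame(stimulus_id = rep(c("s1", "s2"), 3),
                         frame = rep(c("neutral", "threat", "blame"), each = 2),
                         topic = "t")
  pm <- all_pair_maps(series, segments, 1:v)
  avg <- average_by_condition(pm, "frame")
  for (f in c("neutral", "threat", "blame")) {
    idx <- which(segments$frame == f)
    oracle <- (pm$z[, 1, idx[1]] + pm$z[, 1, idx[2]]) / 2
    expect_lt(max(abs(avg$z[, 1, avg$scope$condition == f] - oracle)), 1e-12)
  }
  # identical maps average to any member; +c/-c average to zero
  pm2 <- pm
  pm2$z[, , segments$frame == "neutral"] <- 1.3
  ti <- which(segments$frame == "threat")
  pm2$z[, , ti[1]] <- 0.7
  pm2$z[, , ti[2]] <- -0.7
  avg2 <- average_by_condition(pm2, "frame")
  expect_equal(unname(avg2$z[, 1, avg2$scope$condition == "neutral"]),
               rep(1.3, v))
  expect_equal(max(abs(avg2$z[, , avg2$scope$condition == "threat"])), 0)
  # frame x topic grouping keeps both labels
  avg3 <- average_by_condition(pm, "frame_topic")
  expect_equal(sort(unique(avg3$scope$frame)),
               sort(unique(segments$frame)))
})

test_that("unmatched baseline has the stated combinatorics and captures
          shared drift", {
  set.seed(13)
  v <- 8; len <- 25
  # 2 segments -> exactly 2 unmatched ordered combinations
  si <- lapply(1:2, function(s) matrix(rnorm(v * len), v, len))
  sj <- lapply(1:2, function(s) matrix(rnorm(v * len), v, len))
  bl <- baseline_map(si, sj)
  expect_equal(attr(bl, "n_combinations"), 2L)
  oracle <- (fisher_z(pearson_map(si[[1]], sj[[2]])) +
               fisher_z(pearson_map(si[[2]], sj[[1]]))) / 2
  expect_lt(max(abs(bl - oracle)), 1e-12)
  expect_error(baseline_map(si[1], sj[1]), "at least 2 segments")

  # a shared global drift in all segments drives the baseline positive
  drift <- matrix(rep(seq_len(len), each = v), v, len)
  si_d <- lapply(si, function(m) 0.2 * m + drift)
  sj_d <- lapply(sj, function(m) 0.2 * m + drift)
  expect_gt(mean(baseline_map(si_d, sj_d)), 1)

  # truncation to the shorter segment
  sj_short <- list(sj[[1]][, 1:15], sj[[2]][, 1:15])
  expect_silent(baseline_map(si, sj_short))

  # subsampling cap with a recorded seed
  si_many <- lapply(1:20, function(s) matrix(rnorm(v * len), v, len))
  bl_many <- baseline_map(si_many, si_many, max_combinations = 50, seed = 2)
  expect_equal(attr(bl_many, "n_combinations"), 50L)
})

test_that("baseline subtraction is element-wise and refuses to run twice", {
  set.seed(14)
  v <- 6
  series <- lapply(1:2, function(i)
    lapply(1:3, function(s) matrix(rnorm(v * 20), v, 20)))
  names(series) <- c("a", "b")
  segments <- data.frame(stimulus_id = paste0("s", 1:3), frame = "neutral",
                         topic = "t")
  pm <- all_pair_maps(series, segments, 1:v)
  bl <- all_baseline_maps(series)
  out <- subtract_baseline(pm, bl)
  expect_true(out$baseline_subtracted)
  expect_lt(max(abs(out$z[, 1, 2] - (pm$z[, 1, 2] - bl[, 1]))), 1e-12)
  # zero baseline is the identity; subtracting the map itself zeroes it
  zero <- subtract_baseline(pm, matrix(0, v, 1))
  expect_equal(zero$z, pm$z)
  self <- subtract_baseline(pm, pm$z[, , 2, drop = TRUE] |> as.matrix())
  expect_equal(max(abs(self$z[, , 2])), 0)
  expect_error(subtract_baseline(out, bl), "already subtracted")
  expect_error(subtract_baseline(pm, bl[1:3, , drop = FALSE]), "baseline is")
})

test_that("mean signal-voxel z matches atanh of the closed form over many
          segments", {
  cfg <- tiny_config(n_participants = 3, n_stimuli = 17,
                     segment_duration_s = 100, seed = 31)
  co <- cached("recovery_cohort", simulate_cohort(cfg))
  pre <- cached("recovery_pre", preprocess_cohort(co))
  pm <- all_pair_maps(pre$series_by_participant, pre$segments, pre$voxel_ids)
  sig <- signal_rows(co, pre$voxel_ids)
  expect_gte(dim(pm$z)[3], 50)
  seg_means <- apply(pm$z[sig, , , drop = FALSE], 3, mean)
  se <- sd(seg_means) / sqrt(length(seg_means))
  expect_lt(abs(mean(seg_means) - atanh(expected_pair_isc(cfg, 0, 0,
                                                          "neutral"))),
            3 * se)
})
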