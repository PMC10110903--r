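# Shared fixtures: tiny phantom configurations and deterministic toy data
# built in code at test time.

desk_phantom_config <- function(n = 8, seed = 11, ...) {
  PhantomConfig(n_patients = n, grid_shape = c(32L, 32L, 16L),
                voxel_spacing = c(2, 2, 3), seed = seed, ...)
}

tiny_unet_config <- function(seed = 3) {
  UNetConfig("desk", input_shape = c(16, 16, 16),
             encoder_channels = c(2, 3, 4, 5),
             decoder_deconv_channels = c(5, 4, 3, 2),
             decoder_conv_channels = c(4, 3, 2, 2), seed = seed)
}

# censored toy records used across survival tests
toy_records <- function(seed = 42, n = 12) {
  set.seed(seed)
  list(time = round(rexp(n, 0.4) + 0.05, 3),
       event = rbinom(n, 1, 0.7),
       score = round(rnorm(n), 3))
}

# brute-force Harrell's c: explicit pair enumeration
bf_harrells_c <- function(time, event, score) {
  num <- den <- 0
  n <- length(time)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      num <- num + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
    }
  }
  num / den
}

# one small end-to-end pipeline run shared by several tests (built once)
cached_demo_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generateCohort(desk_phantom_config(n = 24, seed = 61))
      net <- UNetConfig("desk", epochs = 8L, seed = 61)
      # tiny demo cohort: stratification/sample-size warnings are expected
      cache <<- suppressWarnings(
        runDesep(cohort, net_config = net, seg_train_n = 10L,
                 n_folds = 4L, test_fraction = 0.25,
                 k_grid = c(2, 4, 8), seed = 61))
    }
    cache
  }
})

# brute-force ASSD via all-pairs distances over boundary voxels
bf_assd <- function(a, b, spacing) {
  ba <- desep:::.boundary_voxels(a != 0) %*% diag(spacing)
  bb <- desep:::.boundary_voxels(b != 0) %*% diag(spacing)
  dmin <- function(P, Q) {
    sapply(seq_len(nrow(P)), function(i)
      min(sqrt(colSums((t(Q) - P[i, ])^2))))
  }
  (mean(dmin(ba, bb)) + mean(dmin(bb, ba))) / 2
}
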