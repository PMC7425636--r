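test_that("pearson matches the closed form and handles degenerate input", {
  bins <- bin_table(c(chr1 = 4e6), 1e6)
  x <- genomic_track(bins, c(1, 2, 3, 4))
  y <- genomic_track(bins, c(2, 4, 5, 9))
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, genomic_track(bins, -c(1, 2, 3, 4))), -1)
  expect_equal_tol(pearson(x, y), oracle_pearson(x$value, y$value))
  expect_warning(r <- pearson(x, genomic_track(bins, rep(2, 4))), "constant")
  expect_true(is.na(r))
  expect_warning(
    r2 <- pearson(genomic_track(bins, c(1, 2, NA, NA)),
                  genomic_track(bins, c(3, 1, NA, NA))),
    "fewer than 3")
  expect_true(is.na(r2))
})

test_that("correlation reports are symmetric, scoped, and oracle-exact", {
  spec <- sim_spec(seed = 2)
  g <- generate_genome(spec)
  set.seed(91)
  n <- nrow(g$bins)
  tracks <- list(a = genomic_track(g$bins, rnorm(n)),
                 b = genomic_track(g$bins, rnorm(n)),
                 c = genomic_track(g$bins, rnorm(n)))
  rep1 <- correlation_report(tracks, "genome")
  expect_equal(rep1$r, t(rep1$r))
  expect_true(all(diag(rep1$r) == 1))
  for (i in 1:3) for (j in 1:3)
    expect_equal_tol(rep1$r[i, j],
                     oracle_pearson(tracks[[i]]$value, tracks[[j]]$value))
  # identical tracks: off-diagonal 1
  rep_dup <- correlation_report(list(a = tracks$a, b = tracks$a), "genome")
  expect_equal(rep_dup$r["a", "b"], 1)
  # invariance to rescaling and shifting
  tracks2 <- tracks
  tracks2$a <- genomic_track(g$bins, 5 - 3 * tracks$a$value)
  rep2 <- correlation_report(tracks2, "genome")
  expect_equal(abs(rep2$r), abs(rep1$r), tolerance = 1e-12)
  # chromosome scope selects only that chromosome's bins
  rep_chr <- correlation_report(tracks, "chromosome", chrom = "chr4")
  sel <- g$bins$chrom == "chr4"
  expect_equal_tol(rep_chr$r["a", "b"],
                   oracle_pearson(tracks$a$value[sel], tracks$b$value[sel]))
  expect_equal(rep_chr$n["a", "b"], sum(sel))
})

test_that("TAD-scoped reports use only bins with the matching label", {
  cm <- random_cm(c(chr1 = 30e6), seed = 92)
  seg <- call_tads(cm, 1.0)
  trk <- list(x = genomic_track(cm$bins, rnorm(30)),
              y = genomic_track(cm$bins, rnorm(30)))
  lab <- rep(NA_character_, 30)
  for (r in seq_len(nrow(seg))) lab[seg$start_bin[r]:seg$end_bin[r]] <- seg$label[r]
  for (scope in c("TAD", "interTAD")) {
    n_scope <- sum(lab == scope, na.rm = TRUE)
    if (n_scope >= 3) {
      rp <- correlation_report(trk, scope, seg = seg)
      sel <- !is.na(lab) & lab == scope
      expect_equal_tol(rp$r["x", "y"],
                       oracle_pearson(trk$x$value[sel], trk$y$value[sel]))
    }
  }
  expect_error(correlation_report(trk, "TAD"), "need a TADSegmentation")
})

test_that("windowed correlation attains its minimal p on identical tracks", {
  spec <- sim_spec(seed = 3)
  g <- generate_genome(spec)
  set.seed(93)
  x <- genomic_track(g$bins, rnorm(nrow(g$bins)))
  w <- windowed_correlation(x, x, 1e7, n_perm = 99, seed = 5)
  expect_equal(w$mean_r, 1)
  expect_equal(w$p_value, 1 / 100)
  expect_equal(length(w$null_mean_r), 99)
})

test_that("whole-chromosome windows reduce to per-chromosome correlation", {
  bins <- bin_table(c(chr1 = 20e6, chr2 = 20e6), 1e6)
  set.seed(94)
  x <- genomic_track(bins, rnorm(40))
  y <- genomic_track(bins, rnorm(40))
  w <- windowed_correlation(x, y, 20e6, n_perm = 100, seed = 6)
  expect_equal(length(w$window_r), 2)
  for (k in 1:2) {
    sel <- bins$chrom == paste0("chr", k)
    expect_equal_tol(w$window_r[k],
                     oracle_pearson(x$value[sel], y$value[sel]))
  }
  # p-values are conservative: never below 1/(1+n_perm)
  expect_gte(w$p_value, 1 / 101)
  bins1 <- bin_table(c(chr1 = 20e6), 1e6)
  expect_error(
    windowed_correlation(genomic_track(bins1, rnorm(20)),
                         genomic_track(bins1, rnorm(20)),
                         20e6, n_perm = 100, seed = 1),
    "fewer than 2 usable windows")
})

test_that("downsample control is deterministic and consistent at full size", {
  bins <- bin_table(c(chr1 = 50e6), 1e6)
  set.seed(95)
  x <- genomic_track(bins, rnorm(50))
  y <- genomic_track(bins, x$value * 0.5 + rnorm(50, 0, 0.5))
  src <- 1:40
  full_r <- cor(x$value[src], y$value[src])
  ctrl_full <- downsample_control(x, y, src, target_n = 40, n_reps = 20,
                                  seed = 7)
  expect_true(all(abs(ctrl_full$replicates - full_r) < 1e-12))
  ctrl_a <- downsample_control(x, y, src, target_n = 15, n_reps = 100,
                               seed = 8)
  ctrl_b <- downsample_control(x, y, src, target_n = 15, n_reps = 100,
                               seed = 8)
  expect_identical(ctrl_a$replicates, ctrl_b$replicates)
  # replicate mean approaches the full-set coefficient as target_n grows
  ctrl_big <- downsample_control(x, y, src, target_n = 38, n_reps = 200,
                                 seed = 9)
  expect_lt(abs(mean(ctrl_big$replicates) - full_r), 0.05)
  expect_error(downsample_control(x, y, src, target_n = 2), ">= 3")
  expect_error(downsample_control(x, y, src, target_n = 41), "exceeds")
  q <- control_quantile(ctrl_a, full_r)
  expect_true(q >= 0 && q <= 1)
})
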