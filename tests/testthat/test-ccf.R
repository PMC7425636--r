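test_that("the 5 Mb separation cutoff is inclusive", {
  # contacts only at exactly 5 Mb separation must all be excluded
  bins <- bin_table(c(chr1 = 8e6), 1e6)
  m <- matrix(0, 8, 8)
  for (i in 1:3) m[i, i + 5] <- 1
  m <- m + t(m)
  ccf <- expect_warning(compute_ccf(contact_matrix(bins, m)), "zero")
  expect_true(all(ccf$raw == 0))
})

test_that("with only inter-chromosomal contacts, total equals inter CCF", {
  bins <- bin_table(c(chr1 = 3e6, chr2 = 3e6), 1e6)
  m <- matrix(0, 6, 6)
  m[1:3, 4:6] <- matrix(1:9, 3)
  m <- m + t(m)
  cm <- contact_matrix(bins, m)
  expect_equal(compute_ccf(cm, "total")$raw,
               compute_ccf(cm, "inter_chromosomal")$raw)
})

test_that("CCF matches the double-loop oracle on random fixtures", {
  fixtures <- list(
    random_cm(c(chr1 = 10e6), seed = 11),
    random_cm(c(chr1 = 20e6, chr2 = 15e6, chr3 = 8e6), seed = 12),
    random_cm(c(chr1 = 12e6, chr2 = 9e6), seed = 13, masked = c(2, 7, 15)))
  for (cm in fixtures) {
    for (scope in c("total", "inter_chromosomal")) {
      for (ms in c(0, 2e6, 5e6)) {
        got <- suppressWarnings(compute_ccf(cm, scope, ms)$raw)
        expect_equal_tol(got, oracle_ccf(cm, scope, ms))
      }
    }
  }
  # ones matrix, separation of 2 bins: raw counts pairs with |i-j| > 2
  bins <- bin_table(c(chr1 = 10e6), 1e6)
  ones <- matrix(1, 10, 10); diag(ones) <- 0
  cm1 <- contact_matrix(bins, ones)
  got <- compute_ccf(cm1, "total", 2e6)$raw
  expect_equal(got, vapply(1:10, function(i)
    sum(abs(i - (1:10)) > 2), numeric(1)))
})

test_that("percent-of-max is scale-invariant with max 100 genome-wide", {
  cm <- random_cm(c(chr1 = 15e6, chr2 = 10e6), seed = 21)
  a <- compute_ccf(cm)
  cm2 <- contact_matrix(cm$bins, cm$counts * 7.3)
  b <- compute_ccf(cm2)
  expect_equal(a$percent, b$percent)
  expect_equal(max(a$percent, na.rm = TRUE), 100)
  expect_true(all(a$percent >= 0 & a$percent <= 100, na.rm = TRUE))
})

test_that("raising min_separation never increases CCF; inter is unaffected", {
  cm <- random_cm(c(chr1 = 25e6, chr2 = 12e6), seed = 22)
  seps <- c(0, 1e6, 3e6, 5e6, 10e6)
  raws <- sapply(seps, function(ms) compute_ccf(cm, "total", ms)$raw)
  for (k in 2:ncol(raws)) expect_true(all(raws[, k] <= raws[, k - 1]))
  inters <- sapply(seps, function(ms)
    compute_ccf(cm, "inter_chromosomal", ms)$raw)
  expect_true(all(inters == inters[, 1]))
})

test_that("chromosome-length normalization divides by chromosome bp", {
  bins <- bin_table(c(chr1 = 2e6, chr2 = 4e6), 1e6)
  m <- matrix(3, 6, 6); diag(m) <- 0
  ccf <- compute_ccf(contact_matrix(bins, m), min_separation = 0)
  norm <- normalize_by_chrom_length(ccf)
  expect_equal(norm$value, ccf$raw / c(2e6, 2e6, 4e6, 4e6, 4e6, 4e6))
})

test_that("GC division rescales per bin and flags zero GC", {
  cm <- random_cm(c(chr1 = 6e6), seed = 31)
  ccf <- compute_ccf(cm, min_separation = 0)
  gc <- genomic_track(cm$bins, rep(c(0.3, 0.6), 3))
  div <- normalize_by_gc_division(ccf, gc)
  expect_equal(div$value, ccf$raw / rep(c(0.3, 0.6), 3))
  gc0 <- genomic_track(cm$bins, c(0.5, 0, 0.5, 0.5, 0.5, 0.5))
  expect_warning(div0 <- normalize_by_gc_division(ccf, gc0), "zero GC")
  expect_true(is.na(div0$value[2]))
  # constant gc: correlations with any track unchanged
  gc_const <- genomic_track(cm$bins, rep(0.5, 6))
  other <- genomic_track(cm$bins, rnorm(6))
  expect_equal(pearson(normalize_by_gc_division(ccf, gc_const), other),
               pearson(ccf_track(ccf, "raw"), other))
})

test_that("GC regression leaves residuals orthogonal to GC", {
  cm <- random_cm(c(chr1 = 50e6), seed = 41)
  n <- nrow(cm$bins)
  set.seed(42)
  gcv <- runif(n, 0.3, 0.6)
  gc <- genomic_track(cm$bins, gcv)

  # exactly linear: residuals vanish
  lin <- cm
  lin_ccf <- compute_ccf(lin, min_separation = 0)
  lin_ccf$raw <- 2 + 3 * gcv
  expect_equal_tol(regress_out_gc(lin_ccf, gc)$value, rep(0, n), 1e-10)

  # noisy linear: slope recovered, residuals uncorrelated with gc
  noisy <- lin_ccf
  set.seed(43)
  noisy$raw <- 2 + 3 * gcv + rnorm(n, 0, 0.1)
  res <- regress_out_gc(noisy, gc)
  fit <- lm(noisy$raw ~ gcv)
  expect_equal(unname(coef(fit)[2]), 3, tolerance = 0.15)
  expect_lt(abs(cor(res$value, gcv)), 1e-10)
  expect_lt(abs(mean(res$value)), 1e-10)

  # gc orthogonal to raw in sample: residuals are centered raw
  ortho <- lin_ccf
  x <- rnorm(n)
  x <- residuals(lm(x ~ gcv))  # exactly uncorrelated with gc
  ortho$raw <- x + 5
  res2 <- regress_out_gc(ortho, gc)
  expect_equal_tol(res2$value, x - mean(x), 1e-9)

  expect_error(regress_out_gc(noisy, genomic_track(cm$bins, rep(0.4, n))),
               "constant")
})

test_that("combined removal equals sequential length then GC steps", {
  cm <- random_cm(c(chr1 = 20e6, chr2 = 10e6), seed = 51)
  set.seed(52)
  gc <- genomic_track(cm$bins, runif(30, 0.3, 0.6))
  ccf <- compute_ccf(cm, min_separation = 0)
  combo <- combined_confounder_removal(ccf, gc)
  seq2 <- regress_out_gc(normalize_by_chrom_length(ccf), gc)
  expect_equal(combo$value, seq2$value)
  expect_lt(abs(cor(combo$value, gc$value)), 1e-10)
})
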