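test_that("expected model averages contacts by separation", {
  bins <- bin_table(c(chr1 = 4e6, chr2 = 3e6), 1e6)
  cm <- contact_matrix(bins, matrix(2.5, 7, 7))
  em <- expected_matrix(cm)
  expect_true(all(em$distance_mean[1:3] == 2.5))
  expect_equal(em$inter_mean, 2.5)

  # counts equal to separation force mean(d) = d
  m <- abs(outer(1:4, 1:4, "-"))
  cm2 <- contact_matrix(bin_table(c(chr1 = 4e6), 1e6), m)
  em2 <- expected_matrix(cm2)
  expect_equal(unname(em2$distance_mean), c(1, 2, 3))
  expect_true(is.na(em2$inter_mean))

  # random fixture vs brute-force group-by-distance oracle
  cm3 <- random_cm(c(chr1 = 12e6, chr2 = 8e6), seed = 61, masked = c(3, 14))
  em3 <- expected_matrix(cm3)
  orc <- oracle_expected(cm3)
  for (d in names(orc$dist))
    expect_equal_tol(em3$distance_mean[as.integer(d)], orc$dist[[d]])
  expect_equal_tol(em3$inter_mean, orc$inter)
})

test_that("O/E normalization gives unit diagonal means", {
  bins <- bin_table(c(chr1 = 5e6), 1e6)
  cm <- contact_matrix(bins, matrix(4, 5, 5))
  oe <- observed_over_expected(cm, expected_matrix(cm))
  expect_true(all(oe$counts[!is.na(oe$counts)] == 1))
  expect_true(all(is.na(diag(oe$counts))))

  cm2 <- random_cm(c(chr1 = 15e6, chr2 = 10e6), seed = 62, masked = 4)
  em2 <- expected_matrix(cm2)
  oe2 <- observed_over_expected(cm2, em2)
  # every distance diagonal has mean 1 (definitional normalization)
  ci <- match(cm2$bins$chrom, unique(cm2$bins$chrom))
  off <- stats::ave(seq_len(25), ci, FUN = seq_along)
  for (d in 1:5) {
    vals <- oe2$counts[outer(ci, ci, "==") &
                       abs(outer(off, off, "-")) == d]
    expect_lt(abs(mean(vals, na.rm = TRUE) - 1), 1e-12)
  }
  # entrywise against the oracle means
  orc <- oracle_expected(cm2)
  for (i in 1:25) for (j in 1:25) {
    if (i == j || cm2$bins$masked[i] || cm2$bins$masked[j]) next
    e <- if (ci[i] == ci[j]) orc$dist[[as.character(abs(off[i] - off[j]))]]
         else orc$inter
    expect_equal_tol(oe2$counts[i, j], cm2$counts[i, j] / e)
  }
})

test_that("correlation matrix matches the pairwise oracle", {
  cm <- random_cm(c(chr1 = 10e6, chr2 = 6e6), seed = 63)
  oe <- observed_over_expected(cm, expected_matrix(cm))
  corr <- correlation_matrix(oe)
  orc <- oracle_corr(oe$counts)
  off_diag <- row(orc) != col(orc)
  expect_equal_tol(corr$counts[off_diag], orc[off_diag])
  expect_true(all(diag(corr$counts) == 1))

  # identical rows correlate at 1
  bins <- bin_table(c(chr1 = 4e6), 1e6)
  m <- rbind(c(4, 4, 2, 8), c(4, 4, 2, 8), c(2, 2, 5, 1), c(8, 8, 1, 3))
  cd <- correlation_matrix(contact_matrix(bins, m))
  expect_equal(cd$counts[1, 2], 1)

  # row 2 = 10 - row 1 elementwise (symmetric by construction): r = -1
  neg <- rbind(c(2, 8, 5, 1), c(8, 2, 5, 9), c(5, 5, 3, 4), c(1, 9, 4, 7))
  cn <- correlation_matrix(contact_matrix(bins, neg))
  expect_equal(cn$counts[1, 2], -1)

  # zero-variance rows go missing with a warning
  flat <- m
  flat[3, ] <- 2; flat[, 3] <- 2
  expect_warning(cf <- correlation_matrix(contact_matrix(bins, flat)),
                 "zero variance")
  expect_true(all(is.na(cf$counts[3, ])))
})

test_that("a two-block checkerboard yields a rank-1 PC1 separating blocks", {
  bins <- bin_table(c(chr1 = 10e6), 1e6)
  blk <- rep(c(1, -1), each = 5)
  C <- outer(blk, blk)
  corr <- contact_matrix(bins, C, nonneg = FALSE)
  ref <- genomic_track(bins, blk)
  comp <- call_compartments(corr, ref)
  expect_true(all(comp$label[1:5] == "A"))
  expect_true(all(comp$label[6:10] == "B"))
  expect_gt(comp$pve, 0.99)
})

test_that("compartment calls are equivariant under bin permutation", {
  cm <- random_cm(c(chr1 = 20e6), seed = 64)
  # plant weak structure so PC1 is well-defined
  blk <- rep(c(1.5, 0.8), each = 10)
  cm$counts <- cm$counts * outer(blk, blk)
  cm$counts <- (cm$counts + t(cm$counts)) / 2
  oe <- observed_over_expected(cm, expected_matrix(cm))
  corr <- correlation_matrix(oe)
  ref <- genomic_track(cm$bins, blk)
  comp <- call_compartments(corr, ref)
  set.seed(65)
  p <- sample(20)
  corr_p <- contact_matrix(cm$bins, corr$counts[p, p], nonneg = FALSE)
  comp_p <- call_compartments(corr_p, genomic_track(cm$bins, blk[p]))
  expect_equal(comp_p$pc1, comp$pc1[p], tolerance = 1e-9)
  expect_equal(comp_p$pve, comp$pve)
})

test_that("PC1 is invariant (up to sign) to global matrix rescaling", {
  cm <- random_cm(c(chr1 = 15e6), seed = 66)
  ref <- genomic_track(cm$bins, rnorm(15))
  a <- compartment_pipeline(cm, ref)
  cm2 <- contact_matrix(cm$bins, cm$counts * 11)
  b <- compartment_pipeline(cm2, ref)
  expect_equal(a$pc1, b$pc1, tolerance = 1e-9)
  expect_equal(a$pve, b$pve, tolerance = 1e-12)
  expect_true(a$pve > 0 && a$pve <= 1)
})

test_that("planted compartments are recovered from simulation", {
  spec <- sim_spec(seed = 1)
  g <- generate_genome(spec)
  hic <- generate_hic(g)
  comp <- compartment_pipeline(hic, genomic_track(g$bins, g$bins$gc, "gc"))
  agree <- mean(comp$label == g$truth$compartment, na.rm = TRUE)
  expect_gt(agree, 0.9)
  hic0 <- generate_hic(g, decay_only = TRUE)
  comp0 <- compartment_pipeline(hic0, genomic_track(g$bins, g$bins$gc, "gc"))
  expect_gt(comp$pve, comp0$pve)
})
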