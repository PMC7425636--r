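# Independent brute-force oracles and fixture builders. Every oracle is a
# direct transcription of the defining formula, kept free of the package's
# vectorized/prefix-sum implementation paths.

# random symmetric non-negative contact matrix over a given grid
random_cm <- function(chrom_lengths, bin_size = 1e6, seed = 1,
                      masked = integer(0)) {
  set.seed(seed)
  bins <- bin_table(chrom_lengths, bin_size)
  n <- nrow(bins)
  m <- matrix(rpois(n * n, 5) * runif(n * n, 0.5, 1.5), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (length(masked)) bins$masked[masked] <- TRUE
  contact_matrix(bins, m)
}

# double-loop CCF oracle
oracle_ccf <- function(cm, scope, min_separation) {
  bins <- cm$bins
  ci <- match(bins$chrom, unique(bins$chrom))
  off <- stats::ave(seq_len(nrow(bins)), ci, FUN = seq_along)
  band <- ceiling(min_separation / attr(bins, "bin_size"))
  n <- nrow(bins)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (bins$masked[i]) next
    s <- 0
    for (j in seq_len(n)) {
      if (j == i || bins$masked[j]) next
      if (ci[i] == ci[j]) {
        if (scope == "inter_chromosomal") next
        if (abs(off[i] - off[j]) <= band) next
      }
      v <- cm$counts[i, j]
      if (!is.na(v)) s <- s + v
    }
    raw[i] <- s
  }
  raw
}

# group-by-distance expected model oracle
oracle_expected <- function(cm) {
  bins <- cm$bins
  ci <- match(bins$chrom, unique(bins$chrom))
  off <- stats::ave(seq_len(nrow(bins)), ci, FUN = seq_along)
  n <- nrow(bins)
  by_d <- list()
  inter <- numeric(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || bins$masked[i] || bins$masked[j]) next
    v <- cm$counts[i, j]
    if (is.na(v)) next
    if (ci[i] == ci[j]) {
      d <- as.character(abs(off[i] - off[j]))
      by_d[[d]] <- c(by_d[[d]], v)
    } else inter <- c(inter, v)
  }
  list(dist = vapply(by_d, mean, numeric(1)),
       inter = if (length(inter)) mean(inter) else NA_real_)
}

# pairwise-complete row-correlation oracle
oracle_corr <- function(mat) {
  n <- nrow(mat)
  C <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(mat[i, ]) & !is.na(mat[j, ])
    if (sum(ok) < 2) next
    x <- mat[i, ok]; y <- mat[j, ok]
    sx <- sqrt(sum((x - mean(x))^2))
    sy <- sqrt(sum((y - mean(y))^2))
    if (sx == 0 || sy == 0) next
    C[i, j] <- sum((x - mean(x)) * (y - mean(y))) / (sx * sy)
  }
  C
}

# pair-enumeration modularity oracle for bins a..b (global) of one chromosome
oracle_modularity <- function(cm, a, b, gamma) {
  bins <- cm$bins
  idx <- which(bins$chrom == bins$chrom[a])
  A <- cm$counts[idx, idx]
  A[is.na(A)] <- 0
  diag(A) <- 0
  A[bins$masked[idx], ] <- 0
  A[, bins$masked[idx]] <- 0
  k <- rowSums(A)
  twom <- sum(k)
  la <- match(a, idx); lb <- match(b, idx)
  s <- 0
  for (i in la:lb) for (j in la:lb) {
    if (i < j) s <- s + A[i, j] - gamma * k[i] * k[j] / twom
  }
  s
}

# exhaustive-tiling segmentation oracle: max total clamped score over all
# 2^(n-1) tilings of positions 1..n, via plain recursion on a score matrix
oracle_best_tiling <- function(score_mat) {
  n <- nrow(score_mat)
  best_from <- function(s) {
    if (s > n) return(0)
    max(vapply(s:n, function(e)
      max(score_mat[s, e], 0) + best_from(e + 1), numeric(1)))
  }
  best_from(1)
}

# all segment scores of a single-run chromosome, by the pair-sum definition
oracle_score_matrix <- function(cm, gamma) {
  n <- nrow(cm$bins)
  sm <- matrix(NA_real_, n, n)
  for (a in seq_len(n)) for (b in a:n)
    sm[a, b] <- oracle_modularity(cm, a, b, gamma)
  sm
}

# two-pass Pearson oracle
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# inter-chromosomal contact preference of small chromosomes, with the known
# per-pair modifiers (bias, compartment) divided out so that only the
# small-pair boost remains: 1.0 when off, small_boost when on
norm_pair_pref <- function(hic, genome) {
  bins <- genome$bins
  ci <- match(bins$chrom, unique(bins$chrom))
  cls <- genome$classes[bins$chrom]
  b <- genome$truth$bias
  comp <- genome$truth$compartment
  modifier <- outer(b, b) *
    ifelse(outer(comp, comp, "=="), genome$spec$c_same, 1)
  ratio <- hic$counts / modifier
  inter <- outer(ci, ci, "!=")
  ss <- inter & outer(cls == "small", cls == "small", "&")
  ll <- inter & outer(cls == "large", cls == "large", "&")
  mean(ratio[ss]) / mean(ratio[ll])
}

expect_equal_tol <- function(a, b, tol = 1e-12) {
  expect_true(max(abs(a - b), na.rm = TRUE) <= tol)
}
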