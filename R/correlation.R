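#' Pearson correlation between two genomic tracks
#'
#' Computed over bins where both tracks are present and unmasked (pairwise
#' deletion). Needs at least 3 joint bins and a non-constant pair.
#'
#' @param x,y `GenomicTrack`s (or numeric vectors of equal length).
#' @return the sample Pearson coefficient, or `NA` (with a warning) when the
#'   joint support is too small or a track is constant on it.
#' @export
pearson <- function(x, y) {
  vx <- track_value(x)
  vy <- track_value(y)
  if (length(vx) != length(vy)) stopf("track lengths differ")
  ok <- !is.na(vx) & !is.na(vy)
  if (inherits(x, "GenomicTrack")) ok <- ok & !x$bins$masked
  if (sum(ok) < 3) {
    warnf("fewer than 3 joint bins; correlation undefined")
    return(NA_real_)
  }
  if (stats::sd(vx[ok]) == 0 || stats::sd(vy[ok]) == 0) {
    warnf("constant track on the joint support; correlation undefined")
    return(NA_real_)
  }
  stats::cor(vx[ok], vy[ok])
}

#' All-pairs correlation report for a set of tracks
#'
#' The report mirrors the conventional chromatin-state correlation heatmap: one row/column per
#' track (chromatin states first, then total and inter-chromosomal CCF by
#' convention of the caller), Pearson coefficients computed on the bins
#' selected by `scope` with pairwise deletion, and the per-cell bin count.
#'
#' @param tracks named list of `GenomicTrack`s on a common grid.
#' @param scope `"genome"`, `"chromosome"` (then give `chrom`), `"TAD"` or
#'   `"interTAD"` (then give `seg`).
#' @param seg a `TADSegmentation`, required for TAD scopes.
#' @param chrom chromosome name, required for chromosome scope.
#' @return a `CorrelationReport`: list with `r` and `n` matrices and `scope`.
#' @export
correlation_report <- function(tracks,
                               scope = c("genome", "chromosome", "TAD",
                                         "interTAD"),
                               seg = NULL, chrom = NULL) {
  scope <- match.arg(scope)
  if (length(names(tracks)) != length(tracks))
    stopf("tracks must be a named list")
  bins <- tracks[[1]]$bins
  sel <- !bins$masked
  if (scope == "chromosome") {
    if (is.null(chrom)) stopf("chromosome scope needs chrom")
    sel <- sel & bins$chrom == chrom
  } else if (scope %in% c("TAD", "interTAD")) {
    if (is.null(seg)) stopf("TAD scopes need a TADSegmentation")
    lab <- rep(NA_character_, n_bins(bins))
    for (r in seq_len(nrow(seg)))
      lab[seg$start_bin[r]:seg$end_bin[r]] <- seg$label[r]
    sel <- sel & !is.na(lab) & lab == scope
  }
  k <- length(tracks)
  nm <- names(tracks)
  r <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  n <- matrix(0L, k, k, dimnames = list(nm, nm))
  vals <- lapply(tracks, function(t) ifelse(sel, t$value, NA_real_))
  if (sum(sel) < 3)
    warnf("scope '%s' has fewer than 3 usable bins; report is all-missing",
          scope)
  for (i in seq_len(k)) for (j in i:k) {
    ok <- !is.na(vals[[i]]) & !is.na(vals[[j]])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) >= 3 && stats::sd(vals[[i]][ok]) > 0 &&
        stats::sd(vals[[j]][ok]) > 0)
      r[i, j] <- r[j, i] <- if (i == j) 1 else
        stats::cor(vals[[i]][ok], vals[[j]][ok])
  }
  structure(list(r = r, n = n, scope = scope,
                 chrom = chrom),
            class = "CorrelationReport")
}

#' Windowed correlation with a randomized (cyclic-shift) control
#'
#' Tiles the genome into consecutive fixed-length windows within each
#' chromosome, computes the Pearson coefficient of `x` and `y` per window
#' (where at least 3 joint bins exist), and compares the mean observed
#' coefficient against a null built by cyclically shifting the `y` track
#' along the concatenated genome by uniform random offsets, which preserves
#' each track's autocorrelation. The empirical p-value is
#' `(1 + #{|mean null r| >= |mean observed r|}) / (1 + n_perm)`.
#'
#' @param x,y `GenomicTrack`s.
#' @param window_bp window length in bp (default 10 Mb; must be a multiple of
#'   the bin size).
#' @param n_perm number of cyclic-shift permutations (>= 100 recommended).
#' @param seed integer seed for the random offsets.
#' @return a `WindowedCorrelation`: list with `window_bp`, `window_r`
#'   (per-window observed coefficients), `mean_r`, `null_mean_r` (length
#'   `n_perm`), `p_value`, `n_perm`, `seed`.
#' @export
windowed_correlation <- function(x, y, window_bp = 1e7, n_perm = 200,
                                 seed = 1) {
  bins <- x$bins
  bs <- bin_size_of(bins)
  if (window_bp %% bs != 0) stopf("window_bp must be a multiple of bin_size")
  wb <- window_bp %/% bs
  ci <- chrom_id(bins)
  off <- bin_offset(bins)
  win <- paste(ci, (off - 1L) %/% wb)
  win_ids <- unique(win)
  vx <- x$value
  mean_win_r <- function(vy) {
    rs <- vapply(win_ids, function(w) {
      i <- win == w
      ok <- i & !is.na(vx) & !is.na(vy) & !bins$masked
      if (sum(ok) < 3) return(NA_real_)
      if (stats::sd(vx[ok]) == 0 || stats::sd(vy[ok]) == 0) return(NA_real_)
      stats::cor(vx[ok], vy[ok])
    }, numeric(1))
    rs
  }
  obs <- mean_win_r(y$value)
  if (sum(!is.na(obs)) < 2) stopf("fewer than 2 usable windows")
  mean_obs <- mean(obs, na.rm = TRUE)
  n <- n_bins(bins)
  set.seed(seed)
  offsets <- sample.int(n - 1L, n_perm, replace = TRUE)
  null_mean <- vapply(offsets, function(k) {
    vy <- y$value[c((k + 1):n, 1:k)]
    mean(mean_win_r(vy), na.rm = TRUE)
  }, numeric(1))
  p <- (1 + sum(abs(null_mean) >= abs(mean_obs), na.rm = TRUE)) / (1 + n_perm)
  structure(list(window_bp = window_bp, window_r = obs, mean_r = mean_obs,
                 null_mean_r = null_mean, p_value = p, n_perm = n_perm,
                 seed = seed),
            class = "WindowedCorrelation")
}

#' Downsampling control for sample-size effects
#'
#' Draws `n_reps` subsamples of `target_n` bins without replacement from
#' `source_bins` (typically the large-chromosome bins) and records the
#' Pearson coefficient of `x` and `y` on each subsample. An observed
#' coefficient from a small-chromosome bin set can then be located within
#' this replicate distribution via [control_quantile()]: a small-chromosome
#' value outside the central mass is an outlier not explained by its smaller
#' sample size.
#'
#' @param x,y `GenomicTrack`s.
#' @param source_bins integer vector of bin indices to subsample from.
#' @param target_n subsample size (>= 3).
#' @param n_reps number of replicates (default 100).
#' @param seed integer seed.
#' @return a `DownsampleControl`: list with `replicates` (length `n_reps`),
#'   `target_n`, `n_reps`, `seed`.
#' @export
downsample_control <- function(x, y, source_bins, target_n, n_reps = 100,
                               seed = 1) {
  if (target_n < 3) stopf("target_n must be >= 3")
  if (target_n > length(source_bins))
    stopf("target_n exceeds the source bin set (%d > %d)", target_n,
          length(source_bins))
  vx <- x$value
  vy <- y$value
  set.seed(seed)
  reps <- vapply(seq_len(n_reps), function(i) {
    s <- sample(source_bins, target_n)
    ok <- !is.na(vx[s]) & !is.na(vy[s])
    if (sum(ok) < 3 || stats::sd(vx[s][ok]) == 0 || stats::sd(vy[s][ok]) == 0)
      return(NA_real_)
    stats::cor(vx[s][ok], vy[s][ok])
  }, numeric(1))
  structure(list(replicates = reps, target_n = target_n, n_reps = n_reps,
                 seed = seed),
            class = "DownsampleControl")
}

#' Empirical quantile of an observed coefficient in a downsampled null
#'
#' @param ctrl a [downsample_control()] result.
#' @param observed the observed coefficient to locate.
#' @return the empirical quantile `mean(replicates <= observed)`; values in
#'   `[0.025, 0.975]` lie inside the central 95% of the replicate
#'   distribution.
#' @export
control_quantile <- function(ctrl, observed) {
  mean(ctrl$replicates <= observed, na.rm = TRUE)
}
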