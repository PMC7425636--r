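# Modularity internals shared by modularity_score() and call_tads().
# For one chromosome: A is the intra-chromosomal submatrix with the main
# diagonal removed and masked bins zeroed; k_i its row sums; 2m their total.
chrom_modularity_env <- function(cm, chrom) {
  bins <- cm$bins
  idx <- which(bins$chrom == chrom)
  if (length(idx) == 0) stopf("chromosome '%s' not in bin table", chrom)
  A <- cm$counts[idx, idx, drop = FALSE]
  A[is.na(A)] <- 0
  diag(A) <- 0
  msk <- bins$masked[idx]
  A[msk, ] <- 0
  A[, msk] <- 0
  k <- rowSums(A)
  list(idx = idx, A = A, k = k, twom = sum(k), masked = msk)
}

#' Modularity score of a candidate TAD segment
#'
#' The score of bins `a..b` (global indices, one chromosome) is
#' `sum_{a <= i < j <= b} (A[i,j] - gamma * k_i * k_j / (2m))`, the network
#' modularity of the segment against the degree-product null with resolution
#' `gamma`, where `k_i` is bin i's intra-chromosomal contact total (diagonal
#' excluded) and `2m` the chromosome's total.
#'
#' @param cm a `ContactMatrix`.
#' @param a,b first and last bin of the segment (global indices, `a <= b`).
#' @param gamma resolution parameter (default 1.0).
#' @return the segment score (0 for single-bin segments).
#' @export
modularity_score <- function(cm, a, b, gamma = 1.0) {
  bins <- cm$bins
  if (a > b) stopf("a must be <= b")
  if (bins$chrom[a] != bins$chrom[b])
    stopf("segment spans chromosomes %s and %s", bins$chrom[a], bins$chrom[b])
  env <- chrom_modularity_env(cm, bins$chrom[a])
  loc <- match(c(a, b), env$idx)
  segment_mod_score(env, loc[1], loc[2], gamma)
}

segment_mod_score <- function(env, s, e, gamma) {
  if (env$twom == 0) {
    warnf("chromosome has no intra-chromosomal contacts; score is 0")
    return(0)
  }
  sel <- s:e
  S <- sum(env$A[sel, sel]) / 2
  K <- sum(env$k[sel])
  sumk2 <- sum(env$k[sel]^2)
  S - gamma * (K^2 - sumk2) / (2 * env$twom)
}

#' Segment a genome into TADs by modularity dynamic programming
#'
#' Each chromosome's contiguous unmasked runs are tiled into segments
#' maximizing the total clamped modularity `sum(max(score(segment), 0))`
#' via the dynamic program `best[e] = max_{s <= e} best[s-1] +
#' max(score(s, e), 0)`; ties prefer the later split point (shorter final
#' segment). Segments of at least 3 bins with positive score are labeled
#' `TAD`; all shorter or non-positive segments are `interTAD`.
#'
#' @param cm a `ContactMatrix` of raw counts.
#' @param gamma modularity resolution parameter (default 1.0).
#' @return a `TADSegmentation`: data.frame with columns `chrom`,
#'   `start_bin`, `end_bin` (global, inclusive), `start`, `end` (bp),
#'   `n_bins`, `score`, `label`; attribute `gamma`.
#' @export
call_tads <- function(cm, gamma = 1.0) {
  bins <- cm$bins
  out <- list()
  for (chrom in chrom_order_of(bins)) {
    env <- chrom_modularity_env(cm, chrom)
    unmasked <- which(!env$masked)
    if (length(unmasked) == 0) next
    runs <- split(unmasked, cumsum(c(1, diff(unmasked) != 1)))
    for (run in runs) {
      seg <- dp_segment_run(env, run, gamma)
      if (nrow(seg) == 0) next
      seg$chrom <- chrom
      seg$start_bin <- env$idx[seg$s_loc]
      seg$end_bin <- env$idx[seg$e_loc]
      out[[length(out) + 1L]] <- seg
    }
  }
  seg <- do.call(rbind, out)
  seg$start <- bins$start[seg$start_bin]
  seg$end <- bins$end[seg$end_bin]
  seg$n_bins <- seg$end_bin - seg$start_bin + 1L
  seg$label <- ifelse(seg$n_bins >= 3 & seg$score > 0, "TAD", "interTAD")
  seg <- seg[, c("chrom", "start_bin", "end_bin", "start", "end",
                 "n_bins", "score", "label")]
  rownames(seg) <- NULL
  structure(seg, gamma = gamma, bin_size = bin_size_of(bins),
            class = c("TADSegmentation", "data.frame"))
}

# DP over one contiguous unmasked run; run holds local (chromosome) indices.
dp_segment_run <- function(env, run, gamma) {
  L <- length(run)
  # segment scores via prefix sums on the run submatrix
  Asub <- env$A[run, run, drop = FALSE]
  P <- Asub
  for (j in seq_len(ncol(P))) P[, j] <- cumsum(P[, j])
  for (i in seq_len(nrow(P))) P[i, ] <- cumsum(P[i, ])
  ck <- cumsum(env$k[run])
  ck2 <- cumsum(env$k[run]^2)
  pre <- function(i, j) if (i == 0 || j == 0) 0 else P[i, j]
  score <- function(s, e) {
    S <- (pre(e, e) - pre(s - 1, e) - pre(e, s - 1) + pre(s - 1, s - 1)) / 2
    K <- ck[e] - if (s > 1) ck[s - 1] else 0
    k2 <- ck2[e] - if (s > 1) ck2[s - 1] else 0
    if (env$twom == 0) 0 else S - gamma * (K^2 - k2) / (2 * env$twom)
  }
  best <- c(0, rep(-Inf, L))
  choice <- integer(L)
  raw_sc <- rep(NA_real_, L)
  for (e in seq_len(L)) {
    for (s in seq_len(e)) {
      sc <- score(s, e)
      val <- best[s] + max(sc, 0)
      if (val >= best[e + 1]) {  # >= : ties go to the later split point
        best[e + 1] <- val
        choice[e] <- s
        raw_sc[e] <- sc
      }
    }
  }
  s_loc <- integer(0); e_loc <- integer(0); sc <- numeric(0)
  e <- L
  while (e >= 1) {
    s <- choice[e]
    s_loc <- c(run[s], s_loc)
    e_loc <- c(run[e], e_loc)
    sc <- c(raw_sc[e], sc)
    e <- s - 1
  }
  data.frame(s_loc = s_loc, e_loc = e_loc, score = sc)
}

#' Split a track into TAD and interTAD components
#'
#' @param track a `GenomicTrack`.
#' @param seg a `TADSegmentation` on the same grid.
#' @return list with `tad` and `intertad` `GenomicTrack`s: values retained
#'   only on bins with the matching label, missing elsewhere.
#' @export
split_by_tad <- function(track, seg) {
  lab <- rep(NA_character_, n_bins(track$bins))
  for (r in seq_len(nrow(seg)))
    lab[seg$start_bin[r]:seg$end_bin[r]] <- seg$label[r]
  v <- track$value
  tad <- ifelse(!is.na(lab) & lab == "TAD", v, NA_real_)
  itad <- ifelse(!is.na(lab) & lab == "interTAD", v, NA_real_)
  list(tad = genomic_track(track$bins, tad, "tad"),
       intertad = genomic_track(track$bins, itad, "intertad"))
}

#' Write a TAD segmentation as BED
#' @param seg a `TADSegmentation`.
#' @param path output path; the name field carries the label, score in col 5.
#' @export
write_tads_bed <- function(seg, path) {
  utils::write.table(
    data.frame(seg$chrom, seg$start, seg$end, seg$label,
               sprintf("%.6g", seg$score)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
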