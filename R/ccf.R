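#' Compute the cumulative contact frequency (CCF) per bin
#'
#' CCF of a bin is the sum of its raw contact frequencies over all other
#' bins, after removing the main diagonal and, for the `total` scope, all
#' intra-chromosomal pairs separated by up to `min_separation` (inclusive:
#' at 1 Mb bins and the 5 Mb default, pairs with `|i - j| <= 5` are
#' excluded). The `inter_chromosomal` scope keeps only pairs on different
#' chromosomes. CCF is also reported as the percentage of the maximum CCF
#' over unmasked bins of the map, making maps of different depth comparable.
#'
#' @param cm a `ContactMatrix` (raw, non-normalized counts).
#' @param scope `"total"` or `"inter_chromosomal"`.
#' @param min_separation intra-chromosomal separation cutoff in bp
#'   (default 5 Mb); converted to bins as `ceiling(min_separation/bin_size)`.
#' @return a `CCFProfile`: list with `bins`, `raw`, `percent`, `scope`,
#'   `min_separation`. Masked bins carry `NA`.
#' @export
compute_ccf <- function(cm, scope = c("total", "inter_chromosomal"),
                        min_separation = 5e6) {
  scope <- match.arg(scope)
  if (min_separation < 0) stopf("min_separation must be >= 0")
  bins <- cm$bins
  if (all(bins$masked)) stopf("all bins are masked")
  ci <- chrom_id(bins)
  off <- bin_offset(bins)
  same <- outer(ci, ci, "==")
  if (scope == "inter_chromosomal") {
    allowed <- !same
  } else {
    band <- ceiling(min_separation / bin_size_of(bins))
    sep <- abs(outer(off, off, "-"))
    allowed <- !same | (same & sep > band)
  }
  allowed[bins$masked, ] <- FALSE
  allowed[, bins$masked] <- FALSE
  cnt <- cm$counts
  cnt[is.na(cnt)] <- 0
  raw <- rowSums(cnt * allowed)
  raw[bins$masked] <- NA_real_
  mx <- max(raw, na.rm = TRUE)
  if (mx == 0) {
    warnf("all CCF values are zero; percent track set to zero")
    percent <- ifelse(is.na(raw), NA_real_, 0)
  } else {
    percent <- 100 * raw / mx
  }
  structure(list(bins = bins, raw = raw, percent = percent, scope = scope,
                 min_separation = min_separation),
            class = "CCFProfile")
}

#' @export
print.CCFProfile <- function(x, ...) {
  cat(sprintf("CCFProfile (%s, min separation %g bp): %d bins, max raw %g\n",
              x$scope, x$min_separation, length(x$raw),
              suppressWarnings(max(x$raw, na.rm = TRUE))))
  invisible(x)
}

#' Extract a CCF profile as a genomic track
#' @param ccf a `CCFProfile`.
#' @param what `"raw"` or `"percent"`.
#' @return a `GenomicTrack`.
#' @export
ccf_track <- function(ccf, what = c("raw", "percent")) {
  what <- match.arg(what)
  genomic_track(ccf$bins, ccf[[what]],
                name = paste0("ccf_", ccf$scope, "_", what))
}

#' Normalize CCF by chromosome length
#'
#' Divides each bin's raw CCF by the bp length of its chromosome, a control
#' for the tendency of small chromosomes to accumulate more contacts.
#'
#' @param ccf a `CCFProfile`.
#' @return a `GenomicTrack` of length-normalized CCF.
#' @export
normalize_by_chrom_length <- function(ccf) {
  lens <- chrom_lengths_of(ccf$bins)
  genomic_track(ccf$bins, ccf$raw / lens[ccf$bins$chrom],
                name = "ccf_per_bp")
}

#' Normalize CCF by GC content (simple division)
#'
#' @param ccf a `CCFProfile`.
#' @param gc a `GenomicTrack` of GC fractions (positive on unmasked bins).
#' @return a `GenomicTrack` of `raw / gc`; bins with missing GC are missing.
#' @export
normalize_by_gc_division <- function(ccf, gc) {
  g <- track_value(gc)
  v <- ccf$raw / g
  zero <- !ccf$bins$masked & !is.na(g) & g == 0
  if (any(zero)) {
    warnf("%d unmasked bin(s) have zero GC; set to missing", sum(zero))
    v[zero] <- NA_real_
  }
  genomic_track(ccf$bins, v, name = "ccf_gc_divided")
}

#' Remove the GC-content effect from CCF by linear regression
#'
#' Fits ordinary least squares `value ~ gc` over unmasked bins where both are
#' present and returns the residuals, which have zero mean and zero sample
#' correlation with GC.
#'
#' @param x a `CCFProfile` (raw CCF is used) or a `GenomicTrack`.
#' @param gc a `GenomicTrack` of GC fractions.
#' @return a `GenomicTrack` of residuals.
#' @export
regress_out_gc <- function(x, gc) {
  bins <- if (inherits(x, "CCFProfile")) x$bins else x$bins
  v <- track_value(x)
  g <- track_value(gc)
  ok <- !bins$masked & !is.na(v) & !is.na(g)
  if (sum(ok) < 3) stopf("need >= 3 unmasked bins with GC present")
  if (stats::sd(g[ok]) == 0) stopf("GC track is constant; slope undefined")
  fit <- stats::lm(v[ok] ~ g[ok])
  out <- rep(NA_real_, length(v))
  out[ok] <- stats::residuals(fit)
  genomic_track(bins, out, name = "ccf_gc_residual")
}

#' Remove chromosome-length and GC effects jointly
#'
#' Applies [normalize_by_chrom_length()] and then [regress_out_gc()] on the
#' result, in that order.
#'
#' @param ccf a `CCFProfile`.
#' @param gc a `GenomicTrack` of GC fractions.
#' @return a `GenomicTrack` of residuals.
#' @export
combined_confounder_removal <- function(ccf, gc) {
  regress_out_gc(normalize_by_chrom_length(ccf), gc)
}
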