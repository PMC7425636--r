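#' Built-in chromatin-state catalogs and activity groupings
#'
#' Three published-style catalogs are built in: the human 15-state HMM
#' segmentation (`"human15"`), the mouse 7-state histone-mark segmentation
#' (`"mouse7"`) and the fly 9-color segmentation (`"fly9"`). Each maps every
#' state to `active`, `inactive` or `other`.
#'
#' @param name one of `"human15"`, `"mouse7"`, `"fly9"`, or `"custom"` (then
#'   supply `mapping`).
#' @param mapping for `"custom"`: named character vector state -> group.
#' @return a `StateGrouping`: named character vector state -> group with
#'   values in `{"active", "inactive", "other"}`.
#' @export
state_grouping <- function(name = c("human15", "mouse7", "fly9", "custom"),
                           mapping = NULL) {
  name <- match.arg(name)
  g <- switch(name,
    human15 = c(
      "Active_Promoter" = "active", "Weak_Promoter" = "active",
      "Poised_Promoter" = "active", "Strong_Enhancer" = "active",
      "Strong_Enhancer_2" = "active", "Weak_Enhancer" = "active",
      "Weak_Enhancer_2" = "active", "Insulator" = "other",
      "Txn_Transition" = "active", "Txn_Elongation" = "active",
      "Weak_Txn" = "active", "Polycomb_Repressed" = "other",
      "Heterochromatin" = "inactive", "Repetitive_CNV" = "inactive",
      "Repetitive_CNV_2" = "inactive"),
    mouse7 = c(
      "H3K4me3" = "active", "H3K4me1/3" = "active", "H3K4me1" = "active",
      "H3K4me1+H3K36me3" = "active", "H3K36me3" = "active",
      "H3K27me3" = "inactive", "Unmarked" = "other"),
    fly9 = c(
      "RED" = "active", "MAGENTA" = "active", "BROWN" = "other",
      "YELLOW" = "other", "GREEN" = "other", "DARKGRAY" = "inactive",
      "DARKBLUE" = "inactive", "LIGHTBLUE" = "inactive",
      "LIGHTGRAY" = "inactive"),
    custom = {
      if (is.null(mapping) || is.null(names(mapping)))
        stopf("custom grouping needs a named mapping")
      bad <- setdiff(unique(mapping), c("active", "inactive", "other"))
      if (length(bad)) stopf("unknown group(s): %s", paste(bad, collapse = ","))
      mapping
    })
  structure(g, class = c("StateGrouping", class(g)))
}

#' Construct a chromatin-state segmentation
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `state`
#'   (0-based half-open, non-overlapping within a chromosome).
#' @param catalog optional character vector fixing the state set and display
#'   order; defaults to the states present.
#' @return a `StateSegmentation` (data.frame with a `catalog` attribute).
#' @export
state_segmentation <- function(intervals, catalog = NULL) {
  need <- c("chrom", "start", "end", "state")
  if (!all(need %in% names(intervals)))
    stopf("intervals need columns %s", paste(need, collapse = ", "))
  if (is.null(catalog)) catalog <- sort(unique(intervals$state))
  extra <- setdiff(intervals$state, catalog)
  if (length(extra)) stopf("state(s) not in catalog: %s",
                           paste(extra, collapse = ", "))
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  for (ch in unique(intervals$chrom)) {
    d <- intervals[intervals$chrom == ch, ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stopf("overlapping state intervals on %s", ch)
  }
  rownames(intervals) <- NULL
  structure(intervals, catalog = catalog,
            class = c("StateSegmentation", "data.frame"))
}

#' Read a chromatin-state segmentation from BED4
#' @param path BED file with columns chrom, start, end, state.
#' @param catalog optional state catalog (see [state_segmentation()]).
#' @return a `StateSegmentation`.
#' @export
read_state_bed <- function(path, catalog = NULL) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 4) stopf("state BED needs 4 columns")
  names(d)[1:4] <- c("chrom", "start", "end", "state")
  state_segmentation(d[, 1:4], catalog)
}

#' Per-bin chromatin-state coverage fractions
#'
#' For each bin and state, the fraction of the bin covered by intervals of
#' that state. Intervals spanning a bin boundary contribute to each
#' overlapped bin proportionally to the overlap length, so each state's total
#' annotated bp is conserved. Bins with no annotation are flagged
#' unannotated and are excluded from downstream correlation analyses.
#'
#' @param seg a `StateSegmentation`.
#' @param bins a `BinTable`.
#' @return a `StateCoverage`: list with `bins`, `fractions` (bins x states
#'   matrix) and `annotated` (logical per bin).
#' @export
bin_state_coverage <- function(seg, bins) {
  catalog <- attr(seg, "catalog")
  bs <- bin_size_of(bins)
  frac <- matrix(0, n_bins(bins), length(catalog),
                 dimnames = list(NULL, catalog))
  lens <- chrom_lengths_of(bins)
  first_row <- match(chrom_order_of(bins), bins$chrom)
  names(first_row) <- chrom_order_of(bins)
  truncated <- 0L
  for (r in seq_len(nrow(seg))) {
    ch <- seg$chrom[r]
    if (!ch %in% names(lens)) {
      warnf("state interval chromosome '%s' not in bin table; skipped", ch)
      next
    }
    s <- seg$start[r]
    e <- seg$end[r]
    if (e > lens[[ch]]) {
      truncated <- truncated + 1L
      e <- lens[[ch]]
    }
    if (e <= s) next
    b0 <- s %/% bs
    b1 <- (e - 1) %/% bs
    rows <- first_row[[ch]] + (b0:b1)
    ov <- pmin(e, bins$end[rows]) - pmax(s, bins$start[rows])
    frac[rows, seg$state[r]] <- frac[rows, seg$state[r]] +
      ov / (bins$end[rows] - bins$start[rows])
  }
  if (truncated > 0)
    warnf("%d interval(s) extended past the chromosome end; truncated",
          truncated)
  structure(list(bins = bins, fractions = frac,
                 annotated = rowSums(frac) > 0),
            class = "StateCoverage")
}

#' Aggregate state coverage into active and inactive fractions
#'
#' @param cov a `StateCoverage`.
#' @param grouping a [state_grouping()] covering the coverage catalog.
#' @return list of `GenomicTrack`s `active` and `inactive` (per-bin summed
#'   fractions; unannotated bins missing).
#' @export
group_fractions <- function(cov, grouping) {
  catalog <- colnames(cov$fractions)
  missing_states <- setdiff(catalog, names(grouping))
  if (length(missing_states))
    stopf("state(s) absent from grouping: %s",
          paste(missing_states, collapse = ", "))
  sum_group <- function(gr) {
    cols <- intersect(catalog, names(grouping)[grouping == gr])
    v <- rowSums(cov$fractions[, cols, drop = FALSE])
    v[!cov$annotated] <- NA_real_
    v
  }
  list(active = genomic_track(cov$bins, sum_group("active"), "active"),
       inactive = genomic_track(cov$bins, sum_group("inactive"), "inactive"))
}

#' Per-state coverage tracks
#' @param cov a `StateCoverage`.
#' @return named list of `GenomicTrack`s, one per catalog state (unannotated
#'   bins missing).
#' @export
state_tracks <- function(cov) {
  out <- lapply(colnames(cov$fractions), function(s) {
    v <- cov$fractions[, s]
    v[!cov$annotated] <- NA_real_
    genomic_track(cov$bins, v, s)
  })
  stats::setNames(out, colnames(cov$fractions))
}

#' Write per-state coverage as a wide TSV keyed by bin
#' @param cov a `StateCoverage`.
#' @param path output path.
#' @export
write_state_coverage <- function(cov, path) {
  d <- cbind(cov$bins[, c("chrom", "start", "end")],
             as.data.frame(cov$fractions), annotated = cov$annotated)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
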