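#' Build a genome bin table
#'
#' Tiles each chromosome with fixed-size, non-overlapping bins in coordinate
#' order. Coordinates are 0-based, half-open throughout the package. The last
#' bin of a chromosome may be shorter than `bin_size`.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp; the
#'   name order defines the global bin order.
#' @param bin_size bin width in bp.
#' @param gc optional per-bin GC fraction in `[0, 1]`, aligned to the grid.
#' @return a `BinTable`: a data.frame with columns `chrom`, `start`, `end`,
#'   `gc`, `masked`, plus attributes `bin_size`, `chrom_order` and
#'   `chrom_lengths`.
#' @export
bin_table <- function(chrom_lengths, bin_size, gc = NULL) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stopf("chrom_lengths must have unique names")
  if (!is_count(bin_size)) stopf("bin_size must be a positive integer")
  if (any(chrom_lengths <= 0)) stopf("chromosome lengths must be positive")
  rows <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    start <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = start,
               end = pmin(start + bin_size, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, rows)
  bins$gc <- if (is.null(gc)) NA_real_ else {
    if (length(gc) != nrow(bins)) stopf("gc length %d != bin count %d",
                                        length(gc), nrow(bins))
    as.numeric(gc)
  }
  bins$masked <- FALSE
  structure(bins,
            bin_size = as.integer(bin_size),
            chrom_order = names(chrom_lengths),
            chrom_lengths = chrom_lengths,
            class = c("BinTable", "data.frame"))
}

n_bins <- function(bins) nrow(bins)

bin_size_of <- function(bins) attr(bins, "bin_size")

chrom_order_of <- function(bins) attr(bins, "chrom_order")

chrom_lengths_of <- function(bins) attr(bins, "chrom_lengths")

# integer chromosome id per bin, in the stated chromosome order
chrom_id <- function(bins) match(bins$chrom, chrom_order_of(bins))

# 1-based position of each bin within its chromosome
bin_offset <- function(bins) {
  ci <- chrom_id(bins)
  stats::ave(seq_along(ci), ci, FUN = seq_along)
}

#' Read a bin table from a BED3(+gc) file
#'
#' Expects contiguous fixed-size bins per chromosome (the last bin of a
#' chromosome may be short). A numeric fourth column, when present, is taken
#' as the per-bin GC fraction.
#'
#' @param path BED file path (no header).
#' @return a [bin_table()] object.
#' @export
read_bin_table_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 3) stopf("bin table BED needs >= 3 columns")
  chroms <- unique(d[[1]])
  lens <- vapply(chroms, function(ch) max(d[[3]][d[[1]] == ch]), numeric(1))
  names(lens) <- chroms
  widths <- d[[3]] - d[[2]]
  bs <- max(widths)
  bins <- bin_table(lens, bs)
  key_in <- paste(d[[1]], d[[2]])
  key_grid <- paste(bins$chrom, bins$start)
  if (!identical(sort(key_in), sort(key_grid)))
    stopf("input bins do not tile the genome contiguously at %d bp", bs)
  if (ncol(d) >= 4 && is.numeric(d[[4]]))
    bins$gc <- d[[4]][match(key_grid, key_in)]
  bins
}

#' Write a bin table as BED3(+gc)
#' @param bins a `BinTable`.
#' @param path output path.
#' @export
write_bin_table_bed <- function(bins, path) {
  d <- data.frame(bins$chrom, bins$start, bins$end)
  if (!all(is.na(bins$gc))) d$gc <- bins$gc
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a genomic track aligned to a bin grid
#'
#' A track is a per-bin numeric value with `NA` for missing; masked bins
#' always carry `NA`.
#'
#' @param bins a `BinTable`.
#' @param value numeric vector of length `nrow(bins)`.
#' @param name optional track name.
#' @return a `GenomicTrack`.
#' @export
genomic_track <- function(bins, value, name = NULL) {
  if (length(value) != nrow(bins))
    stopf("track length %d != bin count %d", length(value), nrow(bins))
  value <- as.numeric(value)
  value[bins$masked] <- NA_real_
  structure(list(bins = bins, value = value, name = name),
            class = "GenomicTrack")
}

track_value <- function(x) {
  if (inherits(x, "GenomicTrack")) x$value
  else if (inherits(x, "CCFProfile")) x$raw
  else if (is.numeric(x)) x
  else stopf("cannot interpret object of class %s as a track",
             paste(class(x), collapse = "/"))
}

#' Write a track as bedGraph
#'
#' Bins with missing values are omitted, per bedGraph convention.
#'
#' @param track a `GenomicTrack`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  b <- track$bins
  keep <- !is.na(track$value)
  d <- data.frame(b$chrom[keep], b$start[keep], b$end[keep],
                  track$value[keep])
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Mask bins overlapping a set of regions
#'
#' Any bin overlapping a region by at least 1 bp is flagged masked. Masking
#' is monotone: bins already masked stay masked. Typical use is excluding
#' centromeres before correlation analyses.
#'
#' @param x a `BinTable` or `ContactMatrix`.
#' @param regions data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return object of the same class with updated masks.
#' @export
mask_regions <- function(x, regions) {
  if (inherits(x, "ContactMatrix")) {
    x$bins <- mask_regions(x$bins, regions)
    return(x)
  }
  bins <- x
  if (nrow(regions) == 0) return(bins)
  for (r in seq_len(nrow(regions))) {
    ch <- regions$chrom[r]
    if (!ch %in% chrom_order_of(bins)) {
      warnf("region chromosome '%s' not in bin table; skipped", ch)
      next
    }
    hit <- bins$chrom == ch & bins$start < regions$end[r] &
      bins$end > regions$start[r]
    bins$masked <- bins$masked | hit
  }
  bins
}
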