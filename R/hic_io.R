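#' Construct a contact matrix over a bin grid
#'
#' @param bins a `BinTable`.
#' @param counts square numeric matrix of contact frequencies indexed by the
#'   global bin index; must be symmetric and non-negative (`NA` allowed for
#'   missing entries).
#' @param nonneg require non-negative entries (disabled internally for
#'   correlation matrices, which share the container).
#' @return a `ContactMatrix`: `list(bins, counts)`.
#' @export
contact_matrix <- function(bins, counts, nonneg = TRUE) {
  if (!inherits(bins, "BinTable")) stopf("bins must be a BinTable")
  counts <- as.matrix(counts)
  n <- n_bins(bins)
  if (nrow(counts) != n || ncol(counts) != n)
    stopf("matrix is %d x %d but bin table has %d bins",
          nrow(counts), ncol(counts), n)
  if (nonneg && any(counts < 0, na.rm = TRUE))
    stopf("contact matrix has negative entries")
  asym <- max(abs(counts - t(counts)), na.rm = TRUE)
  scale <- max(1, max(abs(counts), na.rm = TRUE))
  if (!is.finite(asym)) asym <- 0
  if (asym > 1e-8 * scale)
    stopf("matrix is not symmetric (max |m - t(m)| = %g)", asym)
  dimnames(counts) <- NULL
  structure(list(bins = bins, counts = counts), class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %d bins (%d masked), bin size %d bp, total %g\n",
              n_bins(x$bins), sum(x$bins$masked), bin_size_of(x$bins),
              sum(x$counts, na.rm = TRUE)))
  invisible(x)
}

#' Read a dense whitespace-separated contact matrix
#'
#' Accepts a full square matrix or an upper-triangular one (ragged rows of
#' decreasing length, diagonal included). A full matrix whose lower triangle
#' is all zero/missing while the upper triangle has data is mirrored.
#'
#' @param path text file path.
#' @param bins the `BinTable` defining the expected dimension.
#' @return a `ContactMatrix`.
#' @export
read_dense_matrix <- function(path, bins) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  lens <- lengths(toks)
  n <- n_bins(bins)
  vals <- suppressWarnings(lapply(toks, as.numeric))
  if (anyNA(unlist(vals)) && any(!unlist(toks) %in% c("NA", "nan", "NaN")
                                 & is.na(unlist(vals))))
    stopf("non-numeric entries in %s", path)
  m <- matrix(NA_real_, n, n)
  if (length(lines) == n && all(lens == n)) {
    m <- do.call(rbind, vals)
  } else if (length(lines) == n && all(lens == seq(n, 1))) {
    for (i in seq_len(n)) m[i, i:n] <- vals[[i]]
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
  } else {
    stopf("matrix in %s is %d row(s) of width %s; expected %d x %d",
          path, length(lines), paste(unique(lens), collapse = ","), n, n)
  }
  if (any(m < 0, na.rm = TRUE)) stopf("negative contact count in %s", path)
  low <- m[lower.tri(m)]
  up <- t(m)[lower.tri(m)]
  if (all(is.na(low) | low == 0) && any(up != 0, na.rm = TRUE)) {
    m[lower.tri(m)] <- up  # upper-triangular input: mirror
  }
  m[is.na(m)] <- 0
  contact_matrix(bins, m)
}

#' Write a contact matrix as dense text at full precision
#' @param cm a `ContactMatrix`.
#' @param path output path.
#' @export
write_dense_matrix <- function(cm, path) {
  lines <- apply(cm$counts, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cooler-layout contact matrix from text tables
#'
#' Reads the single-resolution cooler group layout from its text dump: a
#' directory holding `chroms.tsv` (`name`, `length`), `bins.tsv` (`chrom`,
#' `start`, `end`, optional `gc`) and `pixels.tsv` (`bin1_id`, `bin2_id`,
#' `count`; 0-based bin ids, upper triangle). Pixels are densified and
#' mirrored.
#'
#' @param dir directory containing the three tables (headers required).
#' @return a `ContactMatrix`.
#' @export
read_cooler_tables <- function(dir) {
  f <- function(name) file.path(dir, name)
  for (nm in c("chroms.tsv", "bins.tsv", "pixels.tsv"))
    if (!file.exists(f(nm))) stopf("missing %s in %s", nm, dir)
  chroms <- utils::read.table(f("chroms.tsv"), header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  bt <- utils::read.table(f("bins.tsv"), header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  px <- utils::read.table(f("pixels.tsv"), header = TRUE, sep = "\t")
  lens <- stats::setNames(chroms$length, chroms$name)
  bs <- max(bt$end - bt$start)
  bins <- bin_table(lens, bs)
  if (nrow(bt) != n_bins(bins))
    stopf("bins.tsv has %d bins; grid expects %d", nrow(bt), n_bins(bins))
  if ("gc" %in% names(bt)) bins$gc <- bt$gc
  n <- n_bins(bins)
  if (any(px$bin1_id < 0 | px$bin1_id >= n | px$bin2_id < 0 | px$bin2_id >= n))
    stopf("pixel bin ids out of range [0, %d)", n)
  m <- matrix(0, n, n)
  i <- px$bin1_id + 1L
  j <- px$bin2_id + 1L
  m[cbind(i, j)] <- px$count
  m[cbind(j, i)] <- px$count
  contact_matrix(bins, m)
}

#' Mask bins with no observed contacts
#'
#' Bins whose entire matrix row (hence column) is zero or missing carry no
#' information and are removed from all downstream analyses by masking.
#'
#' @param cm a `ContactMatrix`.
#' @return the `ContactMatrix` with empty bins masked; counts unchanged.
#' @export
mask_empty_bins <- function(cm) {
  rs <- rowSums(abs(cm$counts), na.rm = TRUE)
  cm$bins$masked <- cm$bins$masked | rs == 0
  cm
}

#' Aggregate a contact matrix to a coarser resolution
#'
#' Groups of `factor` consecutive bins within each chromosome are summed
#' (trailing partial groups allowed), conserving total count mass exactly.
#' An aggregate bin is masked only if all its constituents are masked; GC is
#' averaged weighted by bin width.
#'
#' @param cm a `ContactMatrix`.
#' @param factor positive integer aggregation factor.
#' @return a `ContactMatrix` on the coarser grid.
#' @export
rebin <- function(cm, factor) {
  if (!is_count(factor)) stopf("factor must be a positive integer")
  if (factor == 1) return(cm)
  bins <- cm$bins
  lens <- chrom_lengths_of(bins)
  coarse <- bin_table(lens, bin_size_of(bins) * factor)
  grp <- rep(NA_integer_, n_bins(bins))
  off <- bin_offset(bins)
  ci <- chrom_id(bins)
  cci <- chrom_id(coarse)
  coff <- bin_offset(coarse)
  for (c in unique(ci)) {
    fine_idx <- which(ci == c)
    want <- (off[fine_idx] - 1L) %/% factor + 1L
    grp[fine_idx] <- which(cci == c)[want]
  }
  n2 <- n_bins(coarse)
  M <- matrix(0, n_bins(bins), n2)
  M[cbind(seq_len(n_bins(bins)), grp)] <- 1
  cnt <- cm$counts
  cnt[is.na(cnt)] <- 0
  coarse_counts <- t(M) %*% cnt %*% M
  w <- bins$end - bins$start
  for (g in seq_len(n2)) {
    members <- which(grp == g)
    coarse$masked[g] <- all(bins$masked[members])
    gcv <- bins$gc[members]
    if (!all(is.na(gcv)))
      coarse$gc[g] <- sum(gcv * w[members], na.rm = TRUE) /
        sum(w[members][!is.na(gcv)])
  }
  contact_matrix(coarse, coarse_counts)
}
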