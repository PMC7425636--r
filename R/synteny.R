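#' Construct a synteny block map between two genomes
#'
#' @param blocks data.frame with columns `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`, `strand` (`"+"` or `"-"`); coordinates
#'   0-based half-open; A-side blocks non-overlapping.
#' @param min_block_bp minimum A-side block length (default 2 Mb).
#' @return a `SyntenyMap` (data.frame with a `min_block_bp` attribute).
#' @export
synteny_map <- function(blocks, min_block_bp = 2e6) {
  need <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
            "strand")
  if (!all(need %in% names(blocks)))
    stopf("blocks need columns %s", paste(need, collapse = ", "))
  if (any(!blocks$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  len_a <- blocks$end_a - blocks$start_a
  if (any(len_a < min_block_bp))
    stopf("%d block(s) shorter than the %g bp minimum on the A side",
          sum(len_a < min_block_bp), min_block_bp)
  if (any(len_a != blocks$end_b - blocks$start_b))
    stopf("A-side and B-side block lengths differ")
  blocks <- blocks[order(blocks$chrom_a, blocks$start_a), , drop = FALSE]
  for (ch in unique(blocks$chrom_a)) {
    d <- blocks[blocks$chrom_a == ch, ]
    if (nrow(d) > 1 && any(d$start_a[-1] < d$end_a[-nrow(d)]))
      stopf("overlapping A-side blocks on %s", ch)
  }
  rownames(blocks) <- NULL
  structure(blocks, min_block_bp = min_block_bp,
            class = c("SyntenyMap", "data.frame"))
}

#' Read a synteny map from 7-column TSV
#' @param path tab-separated file: chrA, startA, endA, chrB, startB, endB,
#'   strand (no header).
#' @param min_block_bp minimum A-side block length.
#' @return a `SyntenyMap`.
#' @export
read_synteny_map <- function(path, min_block_bp = 2e6) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(d) <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
                "strand")
  synteny_map(d, min_block_bp)
}

#' Classify chromosomes as large or small
#'
#' The default follows the convention of calling human chromosomes 1-9
#' "large" and 14-22 "small"; anything else (or unparsable names) is
#' "other". An explicit mapping overrides the numeric rule.
#'
#' @param chroms character vector of chromosome names.
#' @param large,small integer ranks classed large/small under the numeric
#'   rule.
#' @param mapping optional named character vector chrom -> class, used as-is.
#' @return a `ChromSizeClass`: named character vector chrom -> class in
#'   `{"large", "small", "other"}`.
#' @export
chrom_size_class <- function(chroms, large = 1:9, small = 14:22,
                             mapping = NULL) {
  if (!is.null(mapping)) {
    cls <- mapping[chroms]
    names(cls) <- chroms
  } else {
    num <- suppressWarnings(as.integer(gsub("^chr", "", chroms)))
    cls <- ifelse(is.na(num), "other",
                  ifelse(num %in% large, "large",
                         ifelse(num %in% small, "small", "other")))
    names(cls) <- chroms
  }
  structure(cls, class = c("ChromSizeClass", class(cls)))
}

# map an A-side interval [s, e) inside one block to B coordinates
block_project_interval <- function(blk, s, e) {
  if (blk$strand == "+") {
    c(blk$start_b + (s - blk$start_a), blk$start_b + (e - blk$start_a))
  } else {
    c(blk$end_b - (e - blk$start_a), blk$end_b - (s - blk$start_a))
  }
}

#' Project a genomic track through a synteny map
#'
#' Each A-side bin's value is distributed over the B-side bins its mapped
#' fragments land in, proportionally to fragment overlap lengths (ambiguously
#' mapped bins are thus split proportionally). B-side bins accumulate
#' contributions; total projected mass equals the total value of A-side bins
#' overlapping any block. Minus-strand blocks reverse orientation.
#'
#' @param x_a `GenomicTrack` on the A genome.
#' @param map a `SyntenyMap`.
#' @param bins_b `BinTable` of the B genome.
#' @return a `GenomicTrack` on `bins_b` (bins receiving no projection are
#'   missing).
#' @export
project_track <- function(x_a, map, bins_b) {
  bins_a <- x_a$bins
  lens_b <- chrom_lengths_of(bins_b)
  bs_b <- bin_size_of(bins_b)
  first_row_b <- stats::setNames(match(chrom_order_of(bins_b), bins_b$chrom),
                                 chrom_order_of(bins_b))
  out <- rep(0, n_bins(bins_b))
  touched <- rep(FALSE, n_bins(bins_b))
  map <- as.data.frame(map)
  # truncate blocks exceeding chromosome bounds
  lens_a <- chrom_lengths_of(bins_a)
  for (r in seq_len(nrow(map))) {
    ea <- min(map$end_a[r], lens_a[[map$chrom_a[r]]])
    eb <- min(map$end_b[r], lens_b[[map$chrom_b[r]]])
    if (ea < map$end_a[r] || eb < map$end_b[r]) {
      warnf("block %d exceeds chromosome bounds; truncated", r)
      cut <- min(ea - map$start_a[r], eb - map$start_b[r])
      map$end_a[r] <- map$start_a[r] + cut
      map$end_b[r] <- map$start_b[r] + cut
    }
  }
  for (i in which(!is.na(x_a$value))) {
    b_s <- bins_a$start[i]
    b_e <- bins_a$end[i]
    hits <- which(map$chrom_a == bins_a$chrom[i] & map$start_a < b_e &
                  map$end_a > b_s)
    if (length(hits) == 0) next
    pieces <- list()
    total <- 0
    for (h in hits) {
      s <- max(b_s, map$start_a[h])
      e <- min(b_e, map$end_a[h])
      be <- block_project_interval(map[h, ], s, e)
      pieces[[length(pieces) + 1L]] <- list(chrom = map$chrom_b[h],
                                            s = be[1], e = be[2])
      total <- total + (e - s)
    }
    v <- x_a$value[i]
    for (p in pieces) {
      fr0 <- first_row_b[[p$chrom]]
      j0 <- p$s %/% bs_b
      j1 <- (p$e - 1) %/% bs_b
      rows <- fr0 + (j0:j1)
      ov <- pmin(p$e, bins_b$end[rows]) - pmax(p$s, bins_b$start[rows])
      out[rows] <- out[rows] + v * ov / total
      touched[rows] <- TRUE
    }
  }
  out[!touched] <- NA_real_
  genomic_track(bins_b, out, name = x_a$name)
}

#' Per-unit paired CCF table across a synteny map
#'
#' Splits every block into 1-bin homology units on the A-side grid, pairs
#' each unit's A-side CCF (percent) with the overlap-weighted mean CCF of its
#' mapped B-side location, and annotates both sides' chromosome size class.
#'
#' @param ccf_a,ccf_b `CCFProfile`s for the two genomes.
#' @param map a `SyntenyMap`.
#' @param classes_a,classes_b `ChromSizeClass` mappings for each genome.
#' @return data.frame with columns `chrom_a`, `start_a`, `chrom_b`, `a`,
#'   `b`, `class_a`, `class_b` (one row per usable homology unit).
#' @export
syntenic_ccf_table <- function(ccf_a, ccf_b, map, classes_a, classes_b) {
  bins_a <- ccf_a$bins
  bins_b <- ccf_b$bins
  bs_a <- bin_size_of(bins_a)
  bs_b <- bin_size_of(bins_b)
  first_row_a <- stats::setNames(match(chrom_order_of(bins_a), bins_a$chrom),
                                 chrom_order_of(bins_a))
  first_row_b <- stats::setNames(match(chrom_order_of(bins_b), bins_b$chrom),
                                 chrom_order_of(bins_b))
  rows <- list()
  for (r in seq_len(nrow(map))) {
    ch_a <- map$chrom_a[r]
    # unit boundaries: A-side grid cut to the block
    s0 <- map$start_a[r]
    e0 <- map$end_a[r]
    first_cut <- (s0 %/% bs_a + 1) * bs_a
    inner <- if (first_cut <= e0) seq(first_cut, e0, by = bs_a) else numeric(0)
    cuts <- unique(c(s0, inner, e0))
    for (u in seq_len(length(cuts) - 1)) {
      us <- cuts[u]
      ue <- cuts[u + 1]
      arow <- first_row_a[[ch_a]] + us %/% bs_a
      av <- ccf_a$percent[arow]
      if (is.na(av)) next
      be <- block_project_interval(map[r, ], us, ue)
      j0 <- be[1] %/% bs_b
      j1 <- (be[2] - 1) %/% bs_b
      brows <- first_row_b[[map$chrom_b[r]]] + (j0:j1)
      ov <- pmin(be[2], bins_b$end[brows]) - pmax(be[1], bins_b$start[brows])
      bv <- ccf_b$percent[brows]
      if (all(is.na(bv))) next
      w <- ov[!is.na(bv)]
      bv <- sum(bv[!is.na(bv)] * w) / sum(w)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom_a = ch_a, start_a = us, chrom_b = map$chrom_b[r],
        a = av, b = bv,
        class_a = unname(classes_a[ch_a]),
        class_b = unname(classes_b[map$chrom_b[r]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' CCF correlation across syntenic blocks for a chromosome size-class pair
#'
#' Pearson correlation of paired per-unit CCF values between two genomes,
#' restricted to homology units whose A-side and B-side chromosomes fall in
#' the requested size classes. High correlations for translocated
#' (large <-> small) pairs indicate that CCF is a block-intrinsic property
#' carried through rearrangements.
#'
#' @inheritParams syntenic_ccf_table
#' @param pair length-2 character vector: A-side class, B-side class (each
#'   `"large"` or `"small"`).
#' @return the Pearson coefficient (or `NA` with a warning if fewer than 3
#'   paired units).
#' @export
syntenic_ccf_correlation <- function(ccf_a, ccf_b, map, classes_a, classes_b,
                                     pair = c("large", "large")) {
  tab <- syntenic_ccf_table(ccf_a, ccf_b, map, classes_a, classes_b)
  sel <- tab[tab$class_a == pair[1] & tab$class_b == pair[2], , drop = FALSE]
  if (is.null(sel) || nrow(sel) < 3) {
    warnf("fewer than 3 paired regions for class pair %s-%s",
          pair[1], pair[2])
    return(NA_real_)
  }
  stats::cor(sel$a, sel$b)
}
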