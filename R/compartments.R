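#' Expected contact frequency model
#'
#' Averages contact frequencies over all unmasked intra-chromosomal bin pairs
#' at each genomic separation (in bins, pooled across chromosomes, diagonal
#' excluded), plus a single mean for inter-chromosomal pairs. This is the
#' distance-decay null used to normalize the observed map.
#'
#' @param cm a `ContactMatrix`.
#' @return an `ExpectedModel`: list with `distance_mean` (indexed by
#'   separation in bins, `NA` where no data), `inter_mean`, `bin_size`.
#' @export
expected_matrix <- function(cm) {
  bins <- cm$bins
  ci <- chrom_id(bins)
  off <- bin_offset(bins)
  same <- outer(ci, ci, "==")
  sep <- abs(outer(off, off, "-"))
  ok <- !bins$masked
  okp <- outer(ok, ok, "&") & !is.na(cm$counts)
  intra <- same & sep > 0 & okp
  maxd <- max(tapply(off, ci, max)) - 1L
  distance_mean <- rep(NA_real_, max(maxd, 1L))
  if (any(intra)) {
    m <- tapply(cm$counts[intra], sep[intra], mean)
    distance_mean[as.integer(names(m))] <- as.numeric(m)
  }
  inter <- !same & okp
  inter_mean <- if (any(inter)) mean(cm$counts[inter]) else NA_real_
  structure(list(distance_mean = distance_mean, inter_mean = inter_mean,
                 bin_size = bin_size_of(bins)),
            class = "ExpectedModel")
}

#' Observed-over-expected normalization
#'
#' Divides every contact by its expected value under the distance-decay
#' model: intra-chromosomal pairs by the mean at their separation,
#' inter-chromosomal pairs by the global inter mean. Entries with missing or
#' zero expected value, the main diagonal, and masked bins are missing.
#'
#' @param cm a `ContactMatrix`.
#' @param model an [expected_matrix()] model computed on the same grid.
#' @return a `ContactMatrix` of O/E ratios (with `NA` for missing).
#' @export
observed_over_expected <- function(cm, model) {
  bins <- cm$bins
  ci <- chrom_id(bins)
  off <- bin_offset(bins)
  same <- outer(ci, ci, "==")
  sep <- abs(outer(off, off, "-"))
  E <- matrix(model$inter_mean, n_bins(bins), n_bins(bins))
  dm <- model$distance_mean
  E[same] <- dm[pmax(sep[same], 1L)]
  E[same & sep == 0] <- NA_real_
  E[!is.na(E) & E == 0] <- NA_real_
  oe <- cm$counts / E
  oe[bins$masked, ] <- NA_real_
  oe[, bins$masked] <- NA_real_
  contact_matrix(bins, oe)
}

#' Correlation matrix of an O/E contact map
#'
#' Pearson correlation of every row pair of the observed-over-expected
#' matrix, computed over columns present in both rows. The checkerboard sign
#' pattern of this matrix carries the compartment signal.
#'
#' @param oe an O/E `ContactMatrix` from [observed_over_expected()].
#' @return a `ContactMatrix` holding the symmetric correlation matrix
#'   (diagonal 1 on usable bins; zero-variance rows missing, with a warning).
#' @export
correlation_matrix <- function(oe) {
  bins <- oe$bins
  if (sum(!bins$masked) < 3) stopf("need >= 3 unmasked bins")
  C <- suppressWarnings(stats::cor(oe$counts, use = "pairwise.complete.obs"))
  sds <- apply(oe$counts, 1, stats::sd, na.rm = TRUE)
  flat <- !bins$masked & (is.na(sds) | sds == 0)
  if (any(flat)) {
    warnf("%d row(s) with zero variance; correlations set missing", sum(flat))
    C[flat, ] <- NA_real_
    C[, flat] <- NA_real_
  }
  C[bins$masked, ] <- NA_real_
  C[, bins$masked] <- NA_real_
  usable <- !bins$masked & !flat
  diag(C)[usable] <- 1
  C <- (C + t(C)) / 2  # remove pairwise-deletion asymmetry at rounding level
  contact_matrix(bins, C, nonneg = FALSE)
}

#' Call A/B compartments from a Hi-C correlation matrix
#'
#' Runs PCA on the (mean-imputed, column-centered) correlation matrix
#' restricted to usable bins and takes the first principal component as the
#' compartment coordinate. Because the PC sign is arbitrary, it is oriented
#' so that PC1 correlates positively with a reference track of activity
#' (GC content or active-state fraction); bins with oriented PC1 > 0 are
#' labeled `A`, < 0 `B`. The proportion of variance explained (PVE) by PC1
#' is reported; a genome with real compartments shows a much higher PVE than
#' a decay-only map.
#'
#' @param corr a correlation `ContactMatrix` from [correlation_matrix()].
#' @param orientation_reference a `GenomicTrack` used to fix the PC1 sign.
#' @param mode `"genome"` (default; one PCA on the whole-genome matrix) or
#'   `"chromosome"` (independent PCA per chromosome, per-chromosome PVE).
#' @return a `CompartmentTrack`: list with `bins`, `pc1`, `label` (`"A"`,
#'   `"B"` or `NA`), `pve`, `orientation_reference`, `mode`.
#' @export
call_compartments <- function(corr, orientation_reference,
                              mode = c("genome", "chromosome")) {
  mode <- match.arg(mode)
  bins <- corr$bins
  ref <- track_value(orientation_reference)
  pc1 <- rep(NA_real_, n_bins(bins))
  one_pca <- function(idx) {
    M <- corr$counts[idx, idx, drop = FALSE]
    usable <- idx[colSums(!is.na(M)) > 0]
    if (length(usable) < 3) stopf("need >= 3 usable bins for PCA")
    M <- corr$counts[usable, usable, drop = FALSE]
    for (j in seq_len(ncol(M))) {
      mj <- is.na(M[, j])
      if (any(mj)) M[mj, j] <- mean(M[, j], na.rm = TRUE)
    }
    p <- stats::prcomp(M, center = TRUE, scale. = FALSE)
    scores <- p$x[, 1]
    r <- suppressWarnings(stats::cor(scores, ref[usable],
                                     use = "complete.obs"))
    if (is.na(r) || r == 0)
      warnf("PC1 uncorrelated with orientation reference; sign left as computed")
    else if (r < 0) scores <- -scores
    list(idx = usable, scores = scores,
         pve = p$sdev[1]^2 / sum(p$sdev^2))
  }
  if (mode == "genome") {
    res <- one_pca(which(!bins$masked))
    pc1[res$idx] <- res$scores
    pve <- res$pve
  } else {
    ci <- chrom_id(bins)
    pve <- stats::setNames(rep(NA_real_, length(chrom_order_of(bins))),
                           chrom_order_of(bins))
    for (c in unique(ci)) {
      idx <- which(ci == c & !bins$masked)
      if (length(idx) < 3) next
      res <- one_pca(idx)
      pc1[res$idx] <- res$scores
      pve[chrom_order_of(bins)[c]] <- res$pve
    }
  }
  label <- ifelse(is.na(pc1) | pc1 == 0, NA_character_,
                  ifelse(pc1 > 0, "A", "B"))
  ref_name <- if (inherits(orientation_reference, "GenomicTrack") &&
                  !is.null(orientation_reference$name))
    orientation_reference$name else "reference"
  structure(list(bins = bins, pc1 = pc1, label = label, pve = pve,
                 orientation_reference = ref_name, mode = mode),
            class = "CompartmentTrack")
}

#' Full compartment pipeline from a raw contact matrix
#'
#' Convenience wrapper chaining [expected_matrix()],
#' [observed_over_expected()], [correlation_matrix()] and
#' [call_compartments()].
#'
#' @inheritParams call_compartments
#' @param cm a raw `ContactMatrix`.
#' @return a `CompartmentTrack`.
#' @export
compartment_pipeline <- function(cm, orientation_reference,
                                 mode = c("genome", "chromosome")) {
  oe <- observed_over_expected(cm, expected_matrix(cm))
  call_compartments(correlation_matrix(oe), orientation_reference, mode)
}

#' Write a compartment call as bedGraph (PC1) and BED (A/B labels)
#' @param comp a `CompartmentTrack`.
#' @param bedgraph_path,bed_path output paths (either may be `NULL`).
#' @export
write_compartments <- function(comp, bedgraph_path = NULL, bed_path = NULL) {
  if (!is.null(bedgraph_path))
    write_bedgraph(genomic_track(comp$bins, comp$pc1, "pc1"), bedgraph_path)
  if (!is.null(bed_path)) {
    keep <- !is.na(comp$label)
    b <- comp$bins
    utils::write.table(
      data.frame(b$chrom[keep], b$start[keep], b$end[keep], comp$label[keep]),
      bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  invisible(comp)
}
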