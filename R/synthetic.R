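#' Specification of a synthetic Hi-C study
#'
#' Defines a small genome whose raw Hi-C maps carry, by construction, the
#' structures the analysis pipeline is meant to recover: power-law distance
#' decay, an alternating A/B compartment checkerboard, per-bin visibility
#' biases coupled to chromatin activity, a GC confound coupled to activity,
#' and an inter-chromosomal contact preference of the small chromosomes.
#'
#' @param chrom_lengths named chromosome lengths in bp; defaults to six
#'   chromosomes of 200/180/150/60/50/40 Mb, the first three classed large
#'   and the last three small.
#' @param bin_size bin width in bp (default 1 Mb).
#' @param alpha distance-decay exponent: intra contacts scale as
#'   `s^-alpha` (default 1.0).
#' @param comp_block_mean_bins mean compartment block length in bins
#'   (default 10, i.e. 10 Mb at the default resolution).
#' @param c_same contact multiplier for same-compartment pairs (default 2.0;
#'   cross-compartment pairs use 1.0).
#' @param beta coupling of log visibility bias to activity (default 0.8).
#' @param sigma sd of the lognormal noise on the visibility bias
#'   (default 0.2).
#' @param mu_inter baseline inter-chromosomal rate relative to depth
#'   (default 0.01).
#' @param small_boost multiplier on contacts between two small chromosomes
#'   (default 1.5; set 1 to switch the preference off).
#' @param depth sequencing-depth scale: expected counts at separation 1 for
#'   unit biases (default 30).
#' @param seed master seed; all stages draw from named substreams of it.
#' @return a `SimSpec` list.
#' @export
sim_spec <- function(chrom_lengths = NULL, bin_size = 1e6, alpha = 1.0,
                     comp_block_mean_bins = 10, c_same = 2.0, beta = 0.8,
                     sigma = 0.2, mu_inter = 0.01, small_boost = 1.5,
                     depth = 30, seed = 1) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- c(chr1 = 200e6, chr2 = 180e6, chr3 = 150e6,
                       chr4 = 60e6, chr5 = 50e6, chr6 = 40e6)
  }
  stopifnot(alpha >= 0, c_same > 0, mu_inter > 0, small_boost > 0, depth > 0)
  n <- length(chrom_lengths)
  classes <- stats::setNames(
    rep(c("large", "small"), c(ceiling(n / 2), floor(n / 2))),
    names(chrom_lengths))
  structure(list(chrom_lengths = chrom_lengths, bin_size = bin_size,
                 alpha = alpha, comp_block_mean_bins = comp_block_mean_bins,
                 c_same = c_same, beta = beta, sigma = sigma,
                 mu_inter = mu_inter, small_boost = small_boost,
                 depth = depth, seed = seed, classes = classes),
            class = "SimSpec")
}

#' Generate a synthetic genome with known ground truth
#'
#' Lays out alternating A/B compartment blocks (geometric block lengths with
#' the configured mean), draws per-bin activity from `Beta(8, 2)` in A and
#' `Beta(2, 8)` in B, derives the visibility bias
#' `b_i = exp(beta * activity_i + sigma * eps_i)` (normalized to mean 1), a
#' GC track `0.38 + 0.1 * activity + noise` (a planted GC confound), and a
#' chromatin-state segmentation (human 15-state catalog names) whose per-bin
#' active-group coverage reproduces the activity.
#'
#' @param spec a [sim_spec()].
#' @return list with `bins` (`BinTable`, GC filled), `truth` (data.frame with
#'   `compartment`, `activity`, `bias`), `states` (`StateSegmentation`),
#'   `classes` (`ChromSizeClass`), `spec`.
#' @export
generate_genome <- function(spec) {
  bins <- bin_table(spec$chrom_lengths, spec$bin_size)
  n <- n_bins(bins)
  ci <- chrom_id(bins)
  set.seed(substream_seed(spec$seed, "genome"))
  comp <- character(n)
  for (c in unique(ci)) {
    idx <- which(ci == c)
    cur <- sample(c("A", "B"), 1)
    pos <- 1L
    while (pos <= length(idx)) {
      len <- 1L + stats::rgeom(1, 1 / spec$comp_block_mean_bins)
      comp[idx[pos:min(pos + len - 1L, length(idx))]] <- cur
      cur <- if (cur == "A") "B" else "A"
      pos <- pos + len
    }
  }
  activity <- ifelse(comp == "A", stats::rbeta(n, 8, 2),
                     stats::rbeta(n, 2, 8))
  bias <- exp(spec$beta * activity + spec$sigma * stats::rnorm(n))
  bias <- bias / mean(bias)
  gc <- pmin(pmax(0.38 + 0.1 * activity + stats::rnorm(n, 0, 0.04), 0.2),
             0.8)
  bins$gc <- gc
  set.seed(substream_seed(spec$seed, "states"))
  states <- synth_state_intervals(bins, activity)
  truth <- data.frame(compartment = comp, activity = activity, bias = bias)
  list(bins = bins, truth = truth, states = states,
       classes = chrom_size_class(names(spec$chrom_lengths),
                                  mapping = spec$classes),
       spec = spec)
}

# One active and one inactive run per bin, with the split at the activity
# fraction; states rotate through the catalog groups for variety.
synth_state_intervals <- function(bins, activity) {
  grouping <- state_grouping("human15")
  act_states <- names(grouping)[grouping == "active"]
  inact_states <- names(grouping)[grouping == "inactive"]
  n <- n_bins(bins)
  a_choice <- sample(act_states, n, replace = TRUE)
  i_choice <- sample(inact_states, n, replace = TRUE)
  w <- bins$end - bins$start
  cut <- bins$start + round(activity * w)
  rows <- list(
    data.frame(chrom = bins$chrom, start = bins$start, end = cut,
               state = a_choice, stringsAsFactors = FALSE),
    data.frame(chrom = bins$chrom, start = cut, end = bins$end,
               state = i_choice, stringsAsFactors = FALSE))
  d <- do.call(rbind, rows)
  d <- d[d$end > d$start, ]
  state_segmentation(d, catalog = names(grouping))
}

#' Sample a synthetic raw Hi-C contact matrix
#'
#' Expected counts are `depth * b_i * b_j * s^-alpha * c(comp_i, comp_j)`
#' within chromosomes (separation `s` in bins) and
#' `depth * b_i * b_j * mu_inter * boost * c(comp_i, comp_j)` between
#' chromosomes, where `boost = small_boost` when both chromosomes are small.
#' Counts are Poisson-sampled on the upper triangle and mirrored; the main
#' diagonal is zero.
#'
#' @param genome a [generate_genome()] bundle (or a list with `bins`,
#'   `truth`, `classes`, `spec`).
#' @param decay_only logical; if `TRUE`, compartment structure, biases and
#'   the small-chromosome boost are all switched off, leaving pure distance
#'   decay (the negative control for compartment PVE).
#' @return a `ContactMatrix` of integer counts.
#' @export
generate_hic <- function(genome, decay_only = FALSE) {
  spec <- genome$spec
  bins <- genome$bins
  n <- n_bins(bins)
  ci <- chrom_id(bins)
  off <- bin_offset(bins)
  b <- if (decay_only) rep(1, n) else genome$truth$bias
  comp <- genome$truth$compartment
  cls <- genome$classes[bins$chrom]
  same <- outer(ci, ci, "==")
  sep <- abs(outer(off, off, "-"))
  cmat <- if (decay_only) matrix(1, n, n) else
    ifelse(outer(comp, comp, "=="), spec$c_same, 1)
  boost <- if (decay_only) matrix(1, n, n) else
    ifelse(outer(cls == "small", cls == "small", "&"), spec$small_boost, 1)
  lam <- spec$depth * outer(b, b)
  intra <- same & sep > 0
  lam[intra] <- lam[intra] * sep[intra]^(-spec$alpha) * cmat[intra]
  lam[!same] <- lam[!same] * spec$mu_inter * boost[!same] * cmat[!same]
  diag(lam) <- 0
  set.seed(substream_seed(spec$seed, "matrix"))
  up <- which(upper.tri(lam))
  m <- matrix(0, n, n)
  m[up] <- stats::rpois(length(up), lam[up])
  m <- m + t(m)
  contact_matrix(bins, m)
}

#' Generate a rearranged genome pair sharing block-intrinsic activity
#'
#' Genome A is generated as in [generate_genome()]; its chromosomes are then
#' partitioned into synteny blocks (>= 2 Mb, geometric lengths), which are
#' shuffled across the chromosomes of genome B (with random strand flips),
#' carrying each block's per-bin activity, compartment and visibility bias
#' along. At least 20% of blocks change chromosome size class, emulating
#' translocations between large and small chromosomes. Independent Hi-C maps
#' are sampled for both genomes, so any CCF agreement across the map reflects
#' the shared block-intrinsic structure, not shared noise.
#'
#' @param spec a [sim_spec()].
#' @param block_mean_bins mean synteny block length in bins (default 8,
#'   minimum 2).
#' @return list with `genome_a`, `genome_b` (each a genome bundle plus `hic`)
#'   and `map` (a `SyntenyMap`).
#' @export
generate_synteny_pair <- function(spec, block_mean_bins = 8) {
  ga <- generate_genome(spec)
  ga$hic <- generate_hic(ga)
  bins_a <- ga$bins
  bs <- spec$bin_size
  ci <- chrom_id(bins_a)
  set.seed(substream_seed(spec$seed, "synteny"))
  # partition each A chromosome into blocks of >= 2 bins
  blocks <- list()
  for (c in unique(ci)) {
    idx <- which(ci == c)
    L <- length(idx)
    pos <- 1L
    while (pos <= L) {
      len <- 2L + stats::rgeom(1, 1 / (block_mean_bins - 1))
      if (pos + len - 1L > L) len <- L - pos + 1L
      if (len < 2L) {  # absorb a trailing short remainder
        blocks[[length(blocks)]]$len <- blocks[[length(blocks)]]$len + len
      } else {
        blocks[[length(blocks) + 1L]] <- list(chrom = chrom_order_of(bins_a)[c],
                                              start_bin = idx[pos], len = len)
      }
      pos <- pos + len
    }
  }
  nb <- length(blocks)
  cls_a <- ga$classes
  # shuffle until enough blocks change size class (deterministic under seed)
  for (try in 1:100) {
    ord <- sample.int(nb)
    fill <- assign_blocks(blocks[ord], spec$chrom_lengths, bs)
    from_cls <- vapply(blocks[ord], function(b) unname(cls_a[b$chrom]), "")
    to_cls <- cls_a[fill$chrom_b]
    if (mean(from_cls != to_cls) >= 0.20) break
  }
  strand <- sample(c("+", "-"), nb, replace = TRUE, prob = c(0.7, 0.3))
  shuffled <- blocks[ord]
  map <- data.frame(
    chrom_a = vapply(shuffled, `[[`, "", "chrom"),
    start_a = (vapply(shuffled, `[[`, 1, "start_bin") -
                 vapply(shuffled, function(b)
                   match(b$chrom, bins_a$chrom), 1L)) * bs,
    end_a = NA_real_,
    chrom_b = fill$chrom_b, start_b = fill$start_b,
    end_b = NA_real_, strand = strand, stringsAsFactors = FALSE)
  lens <- vapply(shuffled, `[[`, 1, "len") * bs
  map$end_a <- map$start_a + lens
  map$end_b <- map$start_b + lens
  # build genome B: carry per-bin truth through the map
  lens_b <- tapply(map$end_b, map$chrom_b, max)
  lens_b <- stats::setNames(as.numeric(lens_b[names(spec$chrom_lengths)]),
                            names(spec$chrom_lengths))
  bins_b <- bin_table(lens_b, bs)
  nB <- n_bins(bins_b)
  truth_b <- data.frame(compartment = rep(NA_character_, nB),
                        activity = NA_real_, bias = NA_real_)
  gc_b <- rep(NA_real_, nB)
  first_a <- stats::setNames(match(chrom_order_of(bins_a), bins_a$chrom),
                             chrom_order_of(bins_a))
  first_b <- stats::setNames(match(chrom_order_of(bins_b), bins_b$chrom),
                             chrom_order_of(bins_b))
  for (r in seq_len(nrow(map))) {
    nbin <- (map$end_a[r] - map$start_a[r]) %/% bs
    arows <- first_a[[map$chrom_a[r]]] + map$start_a[r] %/% bs + 0:(nbin - 1)
    brows <- first_b[[map$chrom_b[r]]] + map$start_b[r] %/% bs + 0:(nbin - 1)
    if (map$strand[r] == "-") arows <- rev(arows)
    truth_b[brows, ] <- ga$truth[arows, ]
    gc_b[brows] <- bins_a$gc[arows]
  }
  bins_b$gc <- gc_b
  gb <- list(bins = bins_b, truth = truth_b,
             classes = chrom_size_class(names(lens_b),
                                        mapping = spec$classes),
             spec = `class<-`(utils::modifyList(
               unclass(spec),
               list(chrom_lengths = lens_b,
                    seed = substream_seed(spec$seed, "genome_b"))),
               "SimSpec"))
  gb$states <- NULL
  gb$hic <- generate_hic(gb)
  list(genome_a = ga, genome_b = gb,
       map = synteny_map(map, min_block_bp = 2 * bs))
}

# greedy fill of shuffled blocks into B chromosomes targeting the given
# lengths; returns per-block B chromosome and start (bp)
assign_blocks <- function(shuffled, target_lengths, bs) {
  chroms <- names(target_lengths)
  cur <- 1L
  used <- 0
  chrom_b <- character(length(shuffled))
  start_b <- numeric(length(shuffled))
  for (i in seq_along(shuffled)) {
    len <- shuffled[[i]]$len * bs
    if (cur < length(chroms) && used + len > target_lengths[[cur]] &&
        used > 0) {
      cur <- cur + 1L
      used <- 0
    }
    chrom_b[i] <- chroms[cur]
    start_b[i] <- used
    used <- used + len
  }
  list(chrom_b = chrom_b, start_b = start_b)
}
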