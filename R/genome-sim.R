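# Synthetic Hi-C / Repli-Seq data with planted compartments, histone-mark
# clusters, loops and a strengthening cluster.

# default per-cluster mean z-score archetypes over 9 histone marks.
# Clusters 1-3 are active (A-like), 4 is depleted of both activating and
# repressive marks apart from mild H3K79me2 (the B-type subcompartment whose
# within-cluster contacts strengthen after cohesin degradation), 5-6 carry
# facultative / constitutive repressive marks.
histone_marks <- c("H3K36me3", "H3K27ac", "H3K4me1", "H4K16ac", "H3K79me2",
                   "H2AZ", "H4K20me3", "H3K27me3", "H3K9me3")

default_archetypes <- function() {
  a <- rbind(
    c( 1.5,  1.4,  1.0,  1.0,  1.0,  1.0, -0.8, -0.8, -0.8),
    c( 0.8,  0.6,  1.2,  0.5,  0.3,  0.8, -0.5, -0.3, -0.5),
    c( 0.2,  0.8,  0.8,  0.6,  0.2,  0.4, -0.2, -0.6, -0.4),
    c(-0.8, -0.8, -0.7, -0.6,  0.3, -0.5, -0.4, -0.7, -0.6),
    c(-0.8, -0.6, -0.4, -0.4, -0.5, -0.2,  0.5,  1.5,  0.4),
    c(-1.0, -0.9, -0.8, -0.6, -0.7, -0.6,  1.2,  0.4,  1.5))
  colnames(a) <- histone_marks
  a
}

#' Specification of a synthetic genome (one chromosome)
#'
#' Plants, over `n_bins` contiguous bins: an A/B compartment sign per bin, a
#' per-bin histone-mark cluster assignment drawn blockwise (A bins from
#' clusters 1-3, B bins from 4-6), loops, and a cluster whose within-cluster
#' contacts are multiplied by `strengthen_factor` in the post-treatment
#' matrix.
#'
#' @param n_bins number of bins.
#' @param resolution bp per bin.
#' @param block_size bins per compartment/cluster block.
#' @param compartment_pattern `"alternating"` (strict A/B/A/B checkerboard of
#'   blocks) or `"random"` (block signs drawn at random).
#' @param archetypes k x 9 matrix of cluster mean z-scores (default built in).
#' @param strengthen_cluster cluster id whose within-cluster contacts are
#'   boosted post-treatment.
#' @param strengthen_factor multiplicative boost.
#' @param comp_strength,clust_strength block enrichment of expected contacts
#'   for same-compartment / same-cluster bin pairs.
#' @param n_loops planted loop count.
#' @param loop_strength focal boost at loop pixels.
#' @param base_count expected near-diagonal contact count.
#' @param decay_exponent distance-decay exponent of expected contacts.
#' @param track_noise sd of mark-track noise around the archetype.
#' @param count_noise `"poisson"` for sampled counts, `"none"` for exact
#'   expected values.
#' @param early_late expected Repli-Seq read counts `c(high, low)`: A bins get
#'   `high` early / `low` late reads, B bins the reverse.
#' @param seed integer seed.
#' @export
genome_spec <- function(n_bins = 240, resolution = 25000, block_size = 10,
                        compartment_pattern = c("alternating", "random"),
                        archetypes = default_archetypes(),
                        strengthen_cluster = 4L, strengthen_factor = 2,
                        comp_strength = 0.6, clust_strength = 0.4,
                        n_loops = 12, loop_strength = 4,
                        base_count = 60, decay_exponent = 1,
                        track_noise = 0.3, count_noise = c("poisson", "none"),
                        early_late = c(90, 30), seed = 1L) {
  compartment_pattern <- match.arg(compartment_pattern)
  count_noise <- match.arg(count_noise)
  if (n_bins %% block_size != 0) stop("n_bins must be a multiple of block_size")
  spec <- list(n_bins = as.integer(n_bins), resolution = resolution,
               block_size = as.integer(block_size),
               compartment_pattern = compartment_pattern,
               archetypes = archetypes, k = nrow(archetypes),
               strengthen_cluster = as.integer(strengthen_cluster),
               strengthen_factor = strengthen_factor,
               comp_strength = comp_strength, clust_strength = clust_strength,
               n_loops = n_loops, loop_strength = loop_strength,
               base_count = base_count, decay_exponent = decay_exponent,
               track_noise = track_noise, count_noise = count_noise,
               early_late = early_late, seed = seed)
  class(spec) <- "genome_spec"
  spec
}

#' Generate synthetic contact matrices, tracks and loops
#'
#' @param spec a [genome_spec()].
#' @return list with `pre` and `post` ([contact_matrix()], raw counts),
#'   `tracks` (data.frame: bin coordinates, 9 mark tracks, `early`, `late`),
#'   `loops` (1-based bin pairs), and `truth` (per-bin `compartment` sign,
#'   `clusters`, `strengthen_cluster`, `strengthen_factor`, `loops`).
#' @export
generate_contact_data <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_bins
    nb <- n / spec$block_size
    block_sign <- switch(spec$compartment_pattern,
      alternating = rep_len(c(1, -1), nb),
      random = sample(c(1, -1), nb, replace = TRUE))
    compartment <- rep(block_sign, each = spec$block_size)
    a_clusters <- seq_len(ceiling(spec$k / 2))
    b_clusters <- setdiff(seq_len(spec$k), a_clusters)
    # A blocks draw from active clusters, B blocks from repressive ones; the
    # assignment cycles through each cluster set in shuffled order so every
    # cluster covers a comparable share of the genome
    block_cluster <- integer(nb)
    ia <- which(block_sign > 0)
    ib <- which(block_sign <= 0)
    block_cluster[ia] <- rep_len(sample(a_clusters), length(ia))[sample(length(ia))]
    block_cluster[ib] <- rep_len(sample(b_clusters), length(ib))[sample(length(ib))]
    clusters <- rep(block_cluster, each = spec$block_size)

    dist <- abs(outer(seq_len(n), seq_len(n), "-"))
    lambda <- spec$base_count / (1 + dist)^spec$decay_exponent
    same_comp <- outer(compartment, compartment, "==")
    same_clust <- outer(clusters, clusters, "==")
    lambda <- lambda * (1 + spec$comp_strength * same_comp)
    lambda <- lambda * (1 + spec$clust_strength * (same_comp & same_clust))

    loops <- data.frame(bin_i = integer(), bin_j = integer())
    if (spec$n_loops > 0) {
      # keep loops well clear of the diagonal so aggregate-peak windows and
      # their distance-decay corner blocks stay inside the upper triangle
      span <- max(26, pmin(round(n / 3), 60))
      bi <- sample(15:(n - 15 - span), spec$n_loops, replace = TRUE)
      bj <- bi + sample(25:span, spec$n_loops, replace = TRUE)
      loops <- unique(data.frame(bin_i = pmin(bi, bj), bin_j = pmax(bi, bj)))
      lam_loops <- lambda
      lam_loops[cbind(loops$bin_i, loops$bin_j)] <-
        lambda[cbind(loops$bin_i, loops$bin_j)] * spec$loop_strength
      lam_loops[cbind(loops$bin_j, loops$bin_i)] <-
        lam_loops[cbind(loops$bin_i, loops$bin_j)]
      lambda <- lam_loops
    }

    in_strengthen <- clusters == spec$strengthen_cluster
    boost <- outer(in_strengthen, in_strengthen) * (spec$strengthen_factor - 1) + 1
    lambda_post <- lambda * boost

    draw <- function(lam) {
      if (spec$count_noise == "none") return(lam)
      m <- matrix(0, n, n)
      ut <- upper.tri(lam, diag = TRUE)
      m[ut] <- stats::rpois(sum(ut), lam[ut])
      m + t(m) - diag(diag(m))
    }
    pre <- contact_matrix(draw(lambda), spec$resolution)
    post <- contact_matrix(draw(lambda_post), spec$resolution)

    z <- spec$archetypes[clusters, , drop = FALSE] +
      matrix(stats::rnorm(n * ncol(spec$archetypes), sd = spec$track_noise),
             n, ncol(spec$archetypes))
    colnames(z) <- colnames(spec$archetypes)
    el <- spec$early_late
    early_lam <- ifelse(compartment > 0, el[1], el[2])
    late_lam <- ifelse(compartment > 0, el[2], el[1])
    if (spec$count_noise == "poisson") {
      early <- stats::rpois(n, early_lam)
      late <- stats::rpois(n, late_lam)
    } else {
      early <- early_lam
      late <- late_lam
    }
    bins <- data.frame(chrom = "chrS", start = (seq_len(n) - 1L) * spec$resolution,
                       end = seq_len(n) * spec$resolution)
    tracks <- cbind(bins, as.data.frame(z), early = early, late = late)

    list(pre = pre, post = post, tracks = tracks, loops = loops,
         truth = list(compartment = compartment, clusters = clusters,
                      strengthen_cluster = spec$strengthen_cluster,
                      strengthen_factor = spec$strengthen_factor,
                      loops = loops))
  })
}
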