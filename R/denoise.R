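#' Denoise a read pileup into clusters of unique lesions
#'
#' Greedy divisive abundance-p-value clustering of unique clustering
#' sequences, in the spirit of amplicon denoisers. All sequences start in one
#' cluster seeded by the most abundant sequence. For a member sequence at
#' Hamming distance d from its cluster center, the expected number of
#' error-derived reads is `lambda = reads(cluster) * (error_rate / 3)^d`
#' (errors are uniform across positions and substitutions). The abundance
#' p-value is the Poisson tail probability of seeing at least the observed
#' count, conditioned on the sequence being seen at all:
#' `P(X >= a | X >= 1), X ~ Poisson(lambda)`. While any sequence has
#' p-value < `omega_a`, the most significant one founds a new cluster and
#' every sequence is reassigned to the center most likely to have generated
#' it. Reads of error sequences are absorbed into their center's count.
#'
#' With `error_rate = 0` mismatches cannot be generated, so every distinct
#' sequence founds its own cluster.
#'
#' @param pileup Tibble `seq`, `count` from [tally_pileup()].
#' @param error_rate Per-base error rate, e.g. from [estimate_error_rate()].
#' @param omega_a Abundance p-value threshold for founding a new cluster
#'   (default 0.01).
#' @param max_iter Safety cap on cluster divisions.
#' @return Tibble `center` (sequence), `reads` (aggregated cluster count),
#'   `n_members`, sorted by decreasing reads.
#' @export
denoise_pileup <- function(pileup, error_rate, omega_a = 0.01,
                           max_iter = 10000L) {
  stopifnot(omega_a > 0, omega_a < 1, error_rate >= 0)
  if (nrow(pileup) == 0L) {
    return(tibble::tibble(center = character(), reads = numeric(),
                          n_members = integer()))
  }
  pileup <- dplyr::arrange(pileup, dplyr::desc(.data$count), .data$seq)
  seqs <- pileup$seq
  counts <- pileup$count
  n <- length(seqs)

  if (error_rate == 0) {
    return(tibble::tibble(center = seqs, reads = as.numeric(counts),
                          n_members = 1L))
  }

  mat <- seq_matrix(seqs)
  centers <- 1L                     # indices into seqs
  assign <- rep(1L, n)
  dist_assigned <- hamming_to(mat, seqs[1])
  log_err <- log(error_rate / 3)

  cluster_reads <- function() {
    as.numeric(tapply(counts, factor(assign, levels = centers), sum))
  }

  for (iter in seq_len(max_iter)) {
    creads <- cluster_reads()
    lam <- creads[match(assign, centers)] * exp(dist_assigned * log_err)
    # abundance p-value, conditioned on >= 1 read
    pval <- ifelse(
      dist_assigned == 0L, 1,
      stats::ppois(counts - 1L, lam, lower.tail = FALSE) /
        stats::ppois(0L, lam, lower.tail = FALSE)
    )
    pval[lam == 0 & dist_assigned > 0L] <- ifelse(
      counts[lam == 0 & dist_assigned > 0L] >= 1L, 0, 1)
    cand <- which(pval < omega_a)
    if (length(cand) == 0L) break
    new_center <- cand[which.min(pval[cand])]

    centers <- c(centers, new_center)
    d_new <- hamming_to(mat, seqs[new_center])
    # reassign to the center most likely to generate each sequence:
    # compare reads_c * (e/3)^d on the log scale, using current cluster reads
    creads <- c(creads, counts[new_center])
    lam_cur <- log(creads[match(assign, centers)]) + dist_assigned * log_err
    lam_new <- log(counts[new_center]) + d_new * log_err
    move <- lam_new > lam_cur
    move[new_center] <- TRUE
    assign[move] <- new_center
    dist_assigned[move] <- d_new[move]
  }

  out <- tibble::tibble(
    center = seqs[centers],
    reads = cluster_reads(),
    n_members = as.integer(table(factor(assign, levels = centers)))
  )
  dplyr::arrange(out, dplyr::desc(.data$reads), .data$center)
}

#' Remove shadow clusters next to vastly larger lesions
#'
#' A cluster whose center lies within Hamming distance `distance` of a
#' cluster at least `ratio_threshold` times larger is a shadow generated by
#' recurrent errors and is removed (its reads are discarded, not
#' reassigned).
#'
#' @param clusters Tibble `center`, `reads` from [denoise_pileup()].
#' @param ratio_threshold Size ratio above which the neighbor shadows the
#'   cluster (default 1e4).
#' @param distance Maximum Hamming distance defining a shadow (default 1).
#' @return The surviving clusters, with attribute `removed_fraction` (the
#'   fraction of cluster calls removed) and `removed` (the dropped rows).
#' @export
remove_shadows <- function(clusters, ratio_threshold = 1e4, distance = 1L) {
  n <- nrow(clusters)
  if (n <= 1L) {
    out <- clusters
    attr(out, "removed_fraction") <- 0
    attr(out, "removed") <- clusters[0, ]
    return(out)
  }
  mat <- seq_matrix(clusters$center)
  drop <- logical(n)
  ord <- order(-clusters$reads)
  for (big in ord) {
    d <- hamming_to(mat, clusters$center[big])
    shadowed <- d > 0L & d <= distance &
      clusters$reads[big] >= ratio_threshold * clusters$reads
    drop <- drop | shadowed
  }
  out <- clusters[!drop, ]
  attr(out, "removed_fraction") <- mean(drop)
  attr(out, "removed") <- clusters[drop, ]
  out
}
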