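#' Partition aligned homologs into subfamilies by encoding cost
#'
#' Agglomerative merging starts from singletons; at every step the pair of
#' clusters whose merge lowers the total encoding cost the most (smallest
#' cost delta) is merged, ties broken by the lexicographically smallest
#' pair of cluster labels. The returned partition is the state with the
#' global cost minimum over the whole merge trajectory.
#'
#' The encoding cost of a cluster is the column-wise negative log marginal
#' likelihood of its residues under a symmetric Dirichlet-multinomial
#' (concentration `alpha` per residue), summed over the alignment's match
#' columns. This closed-form cost penalizes model complexity through the
#' marginal likelihood itself, behaves correctly at small cluster sizes,
#' and is exhaustively checkable against enumeration of all partitions.
#'
#' @param alignment Character matrix or named vector of aligned sequences
#'   (at least 2 rows).
#' @param alpha Dirichlet concentration per residue (default 1/20, total
#'   prior mass 1 per column).
#' @return A `subfamily_partition`: `cluster_of` (named by sequence id;
#'   labels `C1`, `C2`, ... in decreasing size order), `cluster_sizes`,
#'   `total_cost` (nats) and the merge `trajectory` (step, merged pair,
#'   total cost).
#' @export
detect_subfamilies <- function(alignment, alpha = 1 / 20) {
  aln <- as_alignment(alignment)
  n <- nrow(aln)
  if (n < 2) stop("subfamily detection needs at least 2 sequences",
                  call. = FALSE)
  ids <- rownames(aln)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  aa <- amino_acids()
  gapfrac <- colMeans(aln == "-")
  use <- which(gapfrac <= 0.5)
  R <- matrix(match(aln[, use, drop = FALSE], aa), n, length(use))

  # per-sequence 20 x K count matrices, collapsed progressively
  counts <- lapply(seq_len(n), function(i) {
    C <- matrix(0L, 20, length(use))
    j <- which(!is.na(R[i, ]))
    C[cbind(R[i, j], j)] <- 1L
    C
  })
  cost_of <- function(C) dirmult_cost(C, alpha)

  members <- lapply(seq_len(n), identity)   # row indices per active cluster
  label <- seq_len(n)                        # min member index = label
  costs <- vapply(counts, cost_of, numeric(1))
  active <- rep(TRUE, n)

  # pair delta cache (upper triangle over original slots)
  delta <- matrix(NA_real_, n, n)
  pair_delta <- function(i, j)
    cost_of(counts[[i]] + counts[[j]]) - costs[i] - costs[j]
  act <- which(active)
  for (a in seq_along(act)) for (b in seq_len(a - 1L))
    delta[act[b], act[a]] <- pair_delta(act[b], act[a])

  total <- sum(costs)
  traj <- data.frame(step = 0L, merged = "", total_cost = total,
                     stringsAsFactors = FALSE)
  merges <- list()
  best_total <- total
  best_step <- 0L

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    idx <- which(!is.na(delta), arr.ind = TRUE)
    vals <- delta[idx]
    # min delta; ties -> lexicographically smallest (label_i, label_j)
    ord <- order(vals, pmin(label[idx[, 1]], label[idx[, 2]]),
                 pmax(label[idx[, 1]], label[idx[, 2]]))
    pick <- idx[ord[1], ]
    i <- pick[1]; j <- pick[2]
    counts[[i]] <- counts[[i]] + counts[[j]]
    members[[i]] <- c(members[[i]], members[[j]])
    label[i] <- min(label[i], label[j])
    costs[i] <- cost_of(counts[[i]])
    active[j] <- FALSE
    total <- sum(costs[active])
    delta[j, ] <- NA_real_; delta[, j] <- NA_real_
    for (k in which(active)) {
      if (k == i) next
      lo <- min(i, k); hi <- max(i, k)
      delta[lo, hi] <- pair_delta(lo, hi)
    }
    merges[[step]] <- c(i, j)
    traj <- rbind(traj, data.frame(
      step = step, merged = sprintf("%s+%s", ids[i], ids[j]),
      total_cost = total, stringsAsFactors = FALSE))
    if (total < best_total) { best_total <- total; best_step <- step }
  }

  # replay merges up to the global-minimum step
  assign <- seq_len(n)
  if (best_step > 0) for (s in seq_len(best_step)) {
    m <- merges[[s]]
    assign[assign == m[2]] <- m[1]
  }
  sizes <- table(assign)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(paste0("C", seq_along(ord)),
                             names(sizes)[ord])
  cluster_of <- stats::setNames(unname(relabel[as.character(assign)]), ids)
  structure(list(
    cluster_of = cluster_of,
    cluster_sizes = sort(table(cluster_of), decreasing = TRUE),
    total_cost = best_total,
    trajectory = traj,
    alpha = alpha), class = "subfamily_partition")
}

# column-wise Dirichlet-multinomial negative log marginal likelihood
dirmult_cost <- function(C, alpha = 1 / 20) {
  A0 <- 20 * alpha
  m <- colSums(C)
  -(sum(lgamma(C + alpha)) - length(C) * lgamma(alpha)
    + length(m) * lgamma(A0) - sum(lgamma(m + A0)))
}

# total cost of an arbitrary partition (shared by tests/oracles)
partition_cost <- function(alignment, assignment, alpha = 1 / 20) {
  aln <- as_alignment(alignment)
  aa <- amino_acids()
  gapfrac <- colMeans(aln == "-")
  use <- which(gapfrac <= 0.5)
  R <- matrix(match(aln[, use, drop = FALSE], aa), nrow(aln), length(use))
  sum(vapply(unique(assignment), function(g) {
    rows <- which(assignment == g)
    C <- matrix(0L, 20, length(use))
    for (i in rows) {
      j <- which(!is.na(R[i, ]))
      C[cbind(R[i, j], j)] <- C[cbind(R[i, j], j)] + 1L
    }
    dirmult_cost(C, alpha)
  }, numeric(1)))
}

#' @export
print.subfamily_partition <- function(x, ...) {
  cat(sprintf("subfamily_partition: %d sequences in %d clusters (cost %.1f nats)\n",
              length(x$cluster_of), length(x$cluster_sizes), x$total_cost))
  print(x$cluster_sizes)
  invisible(x)
}

#' Select the major subfamilies of a partition
#'
#' Returns the clusters holding at least `min_fraction` of all sequences,
#' largest first, together with their combined coverage fraction.
#'
#' @param partition A `subfamily_partition` (or a named cluster-size
#'   vector).
#' @param min_fraction Size threshold as a fraction of all sequences,
#'   in (0, 1]; default 0.05.
#' @return List with `labels` (largest first), `sizes` and `coverage`
#'   (fraction of sequences in the selected clusters).
#' @export
select_major_subfamilies <- function(partition, min_fraction = 0.05) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  sizes <- if (inherits(partition, "subfamily_partition"))
    partition$cluster_sizes else partition
  sizes <- sort(stats::setNames(as.integer(sizes), names(sizes)),
                decreasing = TRUE)
  total <- sum(sizes)
  keep <- sizes[sizes >= min_fraction * total]
  list(labels = names(keep), sizes = keep,
       coverage = sum(keep) / total)
}

#' Build one profile per selected subfamily plus a pooled unspecific model
#'
#' Each selected cluster's rows yield one profile; the unspecific model is
#' built from all rows of the alignment pooled (it matches members of
#' every subfamily, mirroring a generic ion-channel family model). All
#' models are calibrated before return.
#'
#' @param alignment Character matrix of aligned sequences.
#' @param partition A `subfamily_partition` over the alignment rows.
#' @param selected Cluster labels to model (e.g. from
#'   [select_major_subfamilies()]).
#' @param pseudocount_weight,n_samples,sample_length,rng_seed Passed to
#'   [build_profile()] / [calibrate_model()].
#' @return List with `models` (named by cluster label) and `unspecific`.
#' @export
build_subfamily_models <- function(alignment, partition, selected,
                                   pseudocount_weight = 2,
                                   n_samples = 200, sample_length = 300,
                                   rng_seed = 1) {
  aln <- as_alignment(alignment)
  cl <- partition$cluster_of
  stopifnot(all(selected %in% cl))
  models <- list()
  for (s in seq_along(selected)) {
    lab <- selected[s]
    rows <- names(cl)[cl == lab]
    if (length(rows) < 2)
      warning(sprintf("cluster '%s' has fewer than 2 sequences", lab))
    m <- build_profile(aln[rows, , drop = FALSE], pseudocount_weight,
                       name = lab)
    models[[lab]] <- calibrate_model(m, n_samples, sample_length,
                                     rng_seed = rng_seed + s)
  }
  un <- build_profile(aln, pseudocount_weight, name = "unspecific")
  un <- calibrate_model(un, n_samples, sample_length,
                        rng_seed = rng_seed + length(selected) + 1L)
  list(models = models, unspecific = un)
}

#' Write a subfamily partition and its merge trajectory as TSV
#'
#' @param partition A `subfamily_partition`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_partition <- function(partition, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_report(
    data.frame(sequence_id = names(partition$cluster_of),
               cluster_label = unname(partition$cluster_of),
               stringsAsFactors = FALSE),
    file.path(dir, "partition.tsv"))
  write_tsv_report(partition$trajectory, file.path(dir, "cost_trajectory.tsv"))
  invisible(dir)
}
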