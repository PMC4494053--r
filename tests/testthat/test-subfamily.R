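test_that("a tight single family stays one cluster", {
  cfg <- synthetic_config(n_subfamilies = 1, seqs_per_subfamily = 8,
                          n_decoys = 0, subfamily_divergence = 0.5,
                          within_subfamily_divergence = 0.02,
                          ankyrin_repeat_count = c(fam1 = 0), rng_seed = 4)
  sim <- generate_superfamily(cfg)
  part <- detect_subfamilies(channel_alignment(sim))
  expect_length(part$cluster_sizes, 1)
  expect_error(detect_subfamilies(tiny_alignment("ACDE", 1)), "at least 2")
})

test_that("two planted families match the exhaustive best partition", {
  for (sd in c(1, 5)) {
    cfg <- synthetic_config(n_subfamilies = 2, seqs_per_subfamily = 4,
                            n_decoys = 0,
                            ankyrin_repeat_count = c(fam1 = 0, fam2 = 0),
                            rng_seed = sd)
    sim <- generate_superfamily(cfg)
    aln <- channel_alignment(sim)
    part <- detect_subfamilies(aln)
    # recovered clusters equal the planted families
    fam <- sub("_m.*", "", names(part$cluster_of))
    expect_length(part$cluster_sizes, 2)
    expect_true(all(table(part$cluster_of, fam) %in% c(0, 4)))
    # cost achieves the optimum over all set partitions of the 8 rows
    costs <- vapply(all_partitions(8), function(p) {
      asg <- integer(8)
      for (k in seq_along(p)) asg[p[[k]]] <- k
      trpprof:::partition_cost(aln, asg)
    }, numeric(1))
    expect_lte(part$total_cost, min(costs) + 1e-8)
  }
})

test_that("every accepted merge is the minimum-delta merge available", {
  cfg <- synthetic_config(n_subfamilies = 2, seqs_per_subfamily = 3,
                          n_decoys = 0,
                          ankyrin_repeat_count = c(fam1 = 0, fam2 = 0),
                          rng_seed = 17)
  sim <- generate_superfamily(cfg)
  aln <- channel_alignment(sim)
  part <- detect_subfamilies(aln)
  traj <- part$trajectory
  # recompute the first merge's delta against all pairs independently
  n <- nrow(aln)
  singles <- vapply(seq_len(n), function(i)
    trpprof:::partition_cost(aln[i, , drop = FALSE], 1L), numeric(1))
  deltas <- c()
  for (i in seq_len(n)) for (j in seq_len(i - 1)) {
    paircost <- trpprof:::partition_cost(aln[c(i, j), , drop = FALSE],
                                         c(1L, 1L))
    deltas <- c(deltas, paircost - singles[i] - singles[j])
  }
  observed_first_delta <- traj$total_cost[2] - traj$total_cost[1]
  expect_equal(observed_first_delta, min(deltas), tolerance = 1e-8)
})

test_that("duplicating every sequence leaves the clustering unchanged", {
  cfg <- synthetic_config(n_subfamilies = 2, seqs_per_subfamily = 4,
                          n_decoys = 0,
                          ankyrin_repeat_count = c(fam1 = 0, fam2 = 0),
                          rng_seed = 23)
  sim <- generate_superfamily(cfg)
  aln <- channel_alignment(sim)
  dup <- rbind(aln, aln)
  rownames(dup) <- c(rownames(aln), paste0(rownames(aln), "_copy"))
  p1 <- detect_subfamilies(aln)
  p2 <- detect_subfamilies(dup)
  # same partition of the original rows, up to label names
  orig <- p2$cluster_of[rownames(aln)]
  expect_equal(length(unique(orig)), length(p1$cluster_sizes))
  expect_true(all(table(p1$cluster_of, orig) %in%
                    c(0, as.integer(p1$cluster_sizes))))
})

test_that("major-subfamily selection follows the size threshold", {
  sizes <- c(A = 90, B = 6, C = 4)
  sel <- select_major_subfamilies(sizes, 0.05)
  expect_identical(sel$labels, c("A", "B"))
  expect_equal(sel$coverage, 0.96)
  expect_length(select_major_subfamilies(sizes, 0.95)$labels, 0)
})

test_that("subfamily models discriminate held-out members; the pooled model hits all", {
  cfg <- synthetic_config(n_subfamilies = 3, seqs_per_subfamily = 10,
                          n_decoys = 0,
                          ankyrin_repeat_count = c(fam1 = 0, fam2 = 0,
                                                   fam3 = 0),
                          rng_seed = 29)
  sim <- generate_superfamily(cfg)
  members <- names(sim$truth$family_of)
  train <- members[grepl("_m0[1-5]$", members)]
  test <- setdiff(members, train)
  aln <- channel_alignment(sim, train)
  part <- detect_subfamilies(aln)
  sel <- select_major_subfamilies(part)
  built <- build_subfamily_models(aln, part, sel$labels, rng_seed = 2)
  expect_length(built$models, 3)
  expect_equal(built$unspecific$name, "unspecific")
  # label clusters by their training family
  famof <- stats::setNames(sub("_m.*", "", names(part$cluster_of)),
                           names(part$cluster_of))
  cluster_family <- tapply(famof, part$cluster_of[names(famof)],
                           function(x) unique(x)[1])
  for (id in test) {
    bits <- vapply(built$models, function(m)
      score_sequence(m, sim$records[[id]], id)$bit_score, numeric(1))
    bestcl <- names(which.max(bits))
    expect_equal(unname(cluster_family[bestcl]), sim$truth$family_of[[id]])
    # pooled model yields a significant hit for every subfamily member
    eun <- model_evalue(built$unspecific,
                        score_sequence(built$unspecific,
                                       sim$records[[id]])$bit_score,
                        length(test))
    expect_lt(eun, 1e-10)
  }
})
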