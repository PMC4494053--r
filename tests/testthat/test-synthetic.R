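test_that("generator produces the configured record counts and labels", {
  cfg <- synthetic_config(n_subfamilies = 6, seqs_per_subfamily = 30,
                          n_decoys = 12, rng_seed = 3)
  sim <- generate_superfamily(cfg)
  members <- names(sim$truth$family_of)[sim$truth$family_of != "decoy"]
  expect_length(members, 180)
  expect_length(sim$records, 192)
  expect_setequal(names(sim$records), names(sim$truth$family_of))
  # planted repeat arrays shift the channel core
  expect_equal(unname(sim$truth$channel_start[["fam1_m01"]]), 28 * 33 + 1)
  expect_equal(unname(sim$truth$repeat_count_of[["fam2_m05"]]), 11)

  cfg0 <- synthetic_config(n_decoys = 0, rng_seed = 3)
  sim0 <- generate_superfamily(cfg0)
  expect_false(any(sim0$truth$family_of == "decoy"))
})

test_that("identical config and seed give byte-identical FASTA", {
  cfg <- synthetic_config(n_subfamilies = 2, seqs_per_subfamily = 4,
                          n_decoys = 3, rng_seed = 11,
                          ankyrin_repeat_count = c(fam1 = 3, fam2 = 0))
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(generate_superfamily(cfg)$records, f1)
  write_fasta(generate_superfamily(cfg)$records, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(synthetic_config(within_subfamily_divergence = 0.6,
                                subfamily_divergence = 0.5),
               "within_subfamily_divergence")
  expect_error(synthetic_config(subfamily_divergence = 1.4),
               "subfamily_divergence")
  expect_error(synthetic_config(n_decoys = -1), "n_decoys")
  expect_error(synthetic_config(decoy_length_range = c(500, 100)),
               "decoy_length_range")
})

test_that("planted disjunct columns are verifiably disjunct in the alignment", {
  pp <- generate_pushpull_alignment(n_push = 8, n_pull = 8, n_query = 2,
                                    n_columns = 120, n_disjunct = 9,
                                    noise = 0.15, rng_seed = 7)
  push <- pp$alignment[names(pp$labels)[pp$labels == "push"], , drop = FALSE]
  pull <- pp$alignment[names(pp$labels)[pp$labels == "pull"], , drop = FALSE]
  for (j in pp$truth$disjunct_columns$column)
    expect_length(intersect(unique(push[, j]), unique(pull[, j])), 0)
  expect_error(generate_pushpull_alignment(n_columns = 10, n_disjunct = 11),
               "n_disjunct")
  # zero planted sites
  pp0 <- generate_pushpull_alignment(n_disjunct = 0, rng_seed = 2)
  expect_equal(nrow(pp0$truth$disjunct_columns), 0)
})

test_that("noise = 0 makes every non-planted column constant", {
  pp <- generate_pushpull_alignment(n_push = 5, n_pull = 5, n_query = 0,
                                    n_columns = 60, n_disjunct = 4,
                                    noise = 0, rng_seed = 13)
  other <- setdiff(seq_len(60), pp$truth$disjunct_columns$column)
  for (j in other) expect_length(unique(pp$alignment[, j]), 1)
})

test_that("fragmentation removes whole units and updates the truth", {
  cfg <- synthetic_config(n_subfamilies = 1, seqs_per_subfamily = 6,
                          n_decoys = 0, subfamily_divergence = 0.5,
                          ankyrin_repeat_count = c(fam1 = 28), rng_seed = 5)
  sim <- generate_superfamily(cfg)
  # fraction 0: unchanged
  out0 <- fragment_records(sim$records, sim$truth, fraction = 0, rng_seed = 1)
  expect_identical(out0$records, sim$records)
  out <- fragment_records(sim$records, sim$truth, fraction = 1, rng_seed = 1)
  expect_true(length(out$truth$fragmented) == 6)
  for (id in out$truth$fragmented) {
    removed <- sim$truth$repeat_count_of[[id]] - out$truth$repeat_count_of[[id]]
    expect_gte(removed, 2)
    expect_equal(nchar(sim$records[[id]]) - nchar(out$records[[id]]),
                 removed * 33)
    # channel core intact
    expect_identical(
      substr(out$records[[id]], out$truth$channel_start[[id]],
             out$truth$channel_end[[id]]),
      substr(sim$records[[id]], sim$truth$channel_start[[id]],
             sim$truth$channel_end[[id]]))
  }
})

test_that("a fragmented record still classifies into its family", {
  cfg <- synthetic_config(n_subfamilies = 2, seqs_per_subfamily = 8,
                          n_decoys = 0,
                          ankyrin_repeat_count = c(fam1 = 10, fam2 = 0),
                          rng_seed = 19)
  sim <- generate_superfamily(cfg)
  aln <- channel_alignment(sim)
  fams <- sub("_m.*", "", rownames(aln))
  models <- lapply(unique(fams), function(f) {
    m <- build_profile(aln[fams == f, , drop = FALSE], name = f)
    calibrate_model(m, 200, 240, rng_seed = match(f, unique(fams)))
  })
  names(models) <- unique(fams)
  frag <- fragment_records(sim$records, sim$truth, fraction = 1, rng_seed = 2)
  id <- "fam1_m01"
  un <- calibrate_model(build_profile(aln, name = "unspecific"), 200, 240,
                        rng_seed = 9)
  verdicts <- classify_records(models, un, frag$records[id],
                               profile = "census", database_size = 16)
  expect_equal(verdicts$verdict, "fam1")
})
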