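col_matrix <- function(residues) {
  m <- matrix(residues, length(residues), 1)
  rownames(m) <- paste0("s", seq_along(residues))
  m
}

test_that("conservation spans the 0-11 scale with the property table", {
  expect_equal(unname(conservation_scores(col_matrix(rep("K", 6)))), 11)
  # residues disagreeing on every property status
  expect_equal(unname(conservation_scores(
    col_matrix(c("G", "D", "P", "K", "I", "W")))), 0)
  # {I, L, V}: score from independent property enumeration (= 9)
  ilv <- c("I", "L", "V")
  expect_equal(unname(conservation_scores(col_matrix(ilv))),
               oracle_property_score(ilv))
  expect_equal(oracle_property_score(ilv), 9)
  # random columns always agree with the independent enumeration
  set.seed(30)
  for (rep in 1:20) {
    res <- sample(amino_acids(), sample(2:8, 1), replace = TRUE)
    expect_equal(unname(conservation_scores(col_matrix(res))),
                 oracle_property_score(res))
  }
  # gap handling
  expect_equal(unname(conservation_scores(col_matrix(c("K", "K", "-")))), 0)
  expect_true(is.na(conservation_scores(col_matrix(c("-", "-")))))
})

test_that("mR equals exhaustive pair enumeration", {
  labels <- stats::setNames(rep(c("push", "pull"), c(3, 3)),
                            paste0("s", 1:6))
  # hand example: push {A,A,S}, pull {G,G,G} -> 1 - 1/3
  aln <- col_matrix(c("A", "A", "S", "G", "G", "G"))
  expect_equal(unname(mr_scores(aln, labels)), 2 / 3)
  # degenerate columns
  expect_equal(unname(mr_scores(col_matrix(rep("A", 6)), labels)), 0)
  expect_equal(unname(mr_scores(col_matrix(c("A", "A", "A", "G", "G", "G")),
                                labels)), 1)
  expect_error(mr_scores(aln, labels[labels == "push"]), "non-empty")
  # random alignments up to 8 sequences vs brute force, gaps included
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    labs <- stats::setNames(sample(rep(c("push", "pull"),
                                       c(ceiling(n / 2), floor(n / 2)))),
                            paste0("s", seq_len(n)))
    m <- matrix(sample(c(amino_acids(), "-"), n * 5, TRUE), n, 5)
    rownames(m) <- paste0("s", seq_len(n))
    got <- mr_scores(m, labs)
    want <- vapply(seq_len(5), function(j)
      brute_mr_column(stats::setNames(m[, j], rownames(m)), labs),
      numeric(1))
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("label swap leaves scores unchanged and swaps query calls", {
  pp <- generate_pushpull_alignment(n_push = 6, n_pull = 6, n_query = 2,
                                    n_columns = 80, n_disjunct = 5,
                                    noise = 0.1, rng_seed = 44)
  swapped <- ifelse(pp$labels == "push", "pull", "push")
  names(swapped) <- names(pp$labels)
  r1 <- specificity_report(pp$alignment, pp$labels, pp$query_ids,
                           n_permutations = 300, rng_seed = 10)
  r2 <- specificity_report(pp$alignment, swapped, pp$query_ids,
                           n_permutations = 300, rng_seed = 10)
  expect_equal(r1$columns$mr, r2$columns$mr)
  expect_setequal(r1$disjunct_sites, r2$disjunct_sites)
  calls1 <- r1$query_calls$call
  calls2 <- r2$query_calls$call
  expect_identical(calls2, ifelse(calls1 == "pull", "push",
                                  ifelse(calls1 == "push", "pull", calls1)))
})

test_that("the z filter is strict and degenerate columns never qualify", {
  z <- c(2.9, 3.0, 3.1, NA, 10)
  expect_identical(trpprof:::significant_set(z, 3), c(3L, 5L))
  # constant column: sd 0 under permutation, z absent
  labels <- stats::setNames(rep(c("push", "pull"), each = 5),
                            paste0("s", 1:10))
  m <- matrix("A", 10, 2)
  m[, 2] <- c(rep("C", 5), rep("W", 5))
  rownames(m) <- names(labels)
  pz <- permutation_z(m, labels, n_permutations = 200, rng_seed = 1)
  expect_true(is.na(pz$z[1]))
  expect_false(1 %in% pz$significant)
  # a fully disjunct column is detected
  expect_true(2 %in% pz$significant)
  expect_gt(pz$z[2], 3)
})

test_that("disjunctness checks the observed residue sets", {
  labels <- stats::setNames(rep(c("push", "pull"), each = 3),
                            paste0("s", 1:6))
  m <- trpprof::as_alignment(stats::setNames(
    c("AA", "AS", "SA", "GT", "GA", "TG"), names(labels)))
  sites <- disjunct_sites(m, labels, significant = c(1L, 2L))
  expect_true(sites$disjunct[sites$column == 1])   # {A,S} vs {G,T}
  expect_false(sites$disjunct[sites$column == 2])  # A shared
})

test_that("query voting follows the push/pull/neither rule", {
  labels <- stats::setNames(rep(c("push", "pull"), each = 3),
                            paste0("s", 1:6))
  rows <- c(s1 = "AC", s2 = "AC", s3 = "SC", s4 = "GC", s5 = "GC", s6 = "TC",
            qpull = "GC", qodd = "WC", qgap = "-C")
  m <- trpprof::as_alignment(rows)
  sites <- disjunct_sites(m, labels, significant = 1L)
  qc <- classify_queries(sites, m, c("qpull", "qodd", "qgap"))
  expect_equal(qc$calls$call[qc$calls$query_id == "qpull"], "pull")
  expect_equal(qc$calls$call[qc$calls$query_id == "qodd"], "ambiguous")
  expect_equal(unname(qc$votes["qgap", 1]), "neither")
})

test_that("pure-noise alignments produce almost no disjunct calls", {
  false_sites <- 0
  for (sd in 1:10) {
    pp <- generate_pushpull_alignment(n_push = 10, n_pull = 10, n_query = 0,
                                      n_columns = 50, n_disjunct = 0,
                                      noise = 0.1, rng_seed = sd)
    pz <- permutation_z(pp$alignment, pp$labels, n_permutations = 300,
                        rng_seed = 100 + sd)
    sites <- disjunct_sites(pp$alignment, pp$labels, pz$significant)
    false_sites <- false_sites + sum(sites$disjunct)
  }
  expect_lte(false_sites, 2)
})

test_that("the default push/pull preset is recovered exactly", {
  pp <- preset_pushpull_default(rng_seed = 5)
  rep <- specificity_report(pp$alignment, pp$labels, pp$query_ids,
                            n_permutations = 1000, rng_seed = 9)
  expect_setequal(rep$disjunct_sites, pp$truth$disjunct_columns$column)
  expect_length(rep$disjunct_sites, 17)
  expect_true(all(rep$query_calls$call == "pull"))
})
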