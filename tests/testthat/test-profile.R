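test_that("match emissions follow the background-mixture pseudocount", {
  aln <- trpprof::as_alignment(c(s1 = "A", s2 = "A", s3 = "A"))
  m <- build_profile(aln, pseudocount_weight = 2)
  # (3 + 2*0.05) / (3 + 2)
  expect_equal(unname(m$match_emissions["A", 1]), 0.62)
  m0 <- build_profile(aln, pseudocount_weight = 0)
  expect_equal(unname(m0$match_emissions["A", 1]), 1.0)
  # 10 ungapped columns -> consensus length 10
  aln10 <- tiny_alignment("ACDEFGHIKL", 4)
  expect_equal(build_profile(aln10)$consensus_length, 10)
  expect_error(build_profile(matrix(character(0), 0, 0)), "empty")
  expect_error(build_profile(trpprof::as_alignment(c(a = "--", b = "--"))),
               "column")
})

test_that("emissions and transitions normalize after build and rebuild", {
  set.seed(21)
  aa <- amino_acids()
  aln <- matrix(sample(c(aa, "-"), 6 * 12, TRUE,
                       prob = c(rep(0.9 / 20, 20), 0.1)), 6, 12)
  rownames(aln) <- paste0("s", 1:6)
  m <- build_profile(aln)
  expect_true(all(abs(colSums(m$match_emissions) - 1) < 1e-9))
  expect_true(all(abs(colSums(m$transitions[c("MM", "MI", "MD"), ]) - 1) < 1e-9))
  expect_true(all(abs(colSums(m$transitions[c("IM", "II"), ]) - 1) < 1e-9))
  expect_true(all(abs(colSums(m$transitions[c("DM", "DD"), ]) - 1) < 1e-9))
  # rebuild from realigned rows keeps normalization
  recs <- stats::setNames(
    apply(aln, 1, function(r) paste0(r[r != "-"], collapse = "")),
    rownames(aln))
  recs <- recs[nchar(recs) > 0]
  m2 <- build_profile(trpprof:::realign_to_model(m, recs))
  expect_true(all(abs(colSums(m2$match_emissions) - 1) < 1e-9))
})

test_that("Viterbi equals exhaustive path enumeration on small models", {
  set.seed(42)
  aa <- amino_acids()
  checked <- 0
  for (rep in 1:40) {
    K <- sample(1:3, 1)
    nseq <- sample(2:4, 1)
    aln <- matrix(sample(c(aa, "-"), nseq * K, TRUE,
                         prob = c(rep(0.045, 20), 0.1)), nseq, K)
    if (all(colMeans(aln == "-") > 0.5)) next
    rownames(aln) <- paste0("s", seq_len(nseq))
    model <- build_profile(aln)
    s <- paste0(sample(aa, sample(1:4, 1), TRUE), collapse = "")
    expect_equal(score_sequence(model, s)$bit_score,
                 brute_viterbi(model, s), tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gte(checked, 25)
})

test_that("hand-computed log-odds of a two-column toy model is reproduced", {
  # two identical rows 'AC', no pseudocounts: P(A)=P(C)=1, tMM=(1+0)/(1+0)=1
  aln <- trpprof::as_alignment(c(s1 = "AC", s2 = "AC"))
  m <- build_profile(aln, pseudocount_weight = 0)
  # score("AC") = log2(1/0.05) + log2(tMM=1) + log2(1/0.05) = 2*log2(20)
  expect_equal(score_sequence(m, "AC")$bit_score, 2 * log2(20),
               tolerance = 1e-12)
  # a single matched residue scores log2(20)
  expect_equal(score_sequence(m, "A")$bit_score, log2(20), tolerance = 1e-12)
})

test_that("scoring favors the consensus and flags bad symbols", {
  set.seed(3)
  cons <- paste0(sample(amino_acids(), 30, TRUE), collapse = "")
  m <- build_profile(tiny_alignment(cons, 4))
  fwd <- score_sequence(m, cons)$bit_score
  rev <- score_sequence(m, paste0(rev(strsplit(cons, "")[[1]]), collapse = ""))
  expect_gt(fwd, rev$bit_score)
  expect_gt(fwd, 0)
  expect_error(score_sequence(m, "ACDB"), "B")
  # envelope covers the emitted region
  h <- score_sequence(m, paste0("DDDDD", cons, "DDDDD"))
  expect_equal(h$env_start, 6)
  expect_equal(h$env_end, 5 + nchar(cons))
  expect_equal(h$cols_matched, 30)
})

test_that("method-of-moments Gumbel fit recovers known parameters", {
  set.seed(77)
  # draw from Gumbel(mu = 5, lambda = 0.7) by inversion
  x <- 5 - log(-log(stats::runif(5000))) / 0.7
  fit <- trpprof:::fit_gumbel_moments(x)
  expect_lt(abs(fit$lambda - 0.7) / 0.7, 0.10)
  expect_lt(abs(fit$mu - 5) / 5, 0.10)
  # larger samples tighten the spread of recovered mu
  mus <- function(n) vapply(1:8, function(s) {
    set.seed(s)
    trpprof:::fit_gumbel_moments(5 - log(-log(stats::runif(n))) / 0.7)$mu
  }, numeric(1))
  expect_lt(stats::sd(mus(5000)), stats::sd(mus(500)))
  expect_error(trpprof:::fit_gumbel_moments(rep(1, 200)), "degenerate")
})

test_that("calibration is seed-deterministic and E-values behave", {
  m <- build_profile(tiny_alignment("ACDEFGHIKL", 3))
  c1 <- calibrate_model(m, 150, 80, rng_seed = 5)
  c2 <- calibrate_model(m, 150, 80, rng_seed = 5)
  expect_identical(c1$calibration, c2$calibration)
  expect_error(calibrate_model(m, 50, 80), "n_samples")
  expect_error(model_evalue(m, 10, 100), "not calibrated")
  # linear in database size, monotone decreasing in score, E(mu) = N
  expect_equal(model_evalue(c1, 12, 2000), 2 * model_evalue(c1, 12, 1000))
  expect_gt(model_evalue(c1, 10, 100), model_evalue(c1, 20, 100))
  expect_equal(model_evalue(c1, c1$calibration$mu, 500), 500)
  expect_equal(model_evalue(c1, Inf, 500), 0)
})

test_that("model serialization round-trips scores exactly", {
  set.seed(10)
  cons <- paste0(sample(amino_acids(), 25, TRUE), collapse = "")
  m <- calibrate_model(build_profile(tiny_alignment(cons, 3), name = "toy"),
                       150, 60, rng_seed = 2)
  f <- tempfile(fileext = ".jsonl")
  write_models(list(m), f)
  m2 <- read_models(f)[["toy"]]
  probe <- paste0(sample(amino_acids(), 40, TRUE), collapse = "")
  expect_equal(score_sequence(m2, probe)$bit_score,
               score_sequence(m, probe)$bit_score)
  expect_equal(m2$calibration$mu, m$calibration$mu)
})
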