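# Independent brute-force oracles used across the suite. Each one is a
# direct enumeration, deliberately sharing no code with the implementation
# it checks.

# exhaustive local-path enumeration over a profile model (models with few
# columns, short sequences only)
brute_viterbi <- function(model, seq) {
  enc <- trpprof:::encode_residues(seq)
  lod <- trpprof:::model_lod(model)
  ltr <- trpprof:::model_ltr(model)
  K <- ncol(lod)
  L <- length(enc)
  best <- -Inf
  extend <- function(type, i, j, sc) {
    if (type == "M") best <<- max(best, sc)
    if (j >= K) return(invisible())
    trs <- switch(type, M = c("MM", "MI", "MD"), I = c("IM", "II"),
                  D = c("DM", "DD"))
    for (t in trs) {
      nt <- substr(t, 2, 2)
      ni <- if (nt %in% c("M", "I")) i + 1 else i
      nj <- if (nt == "I") j else j + 1
      if (nt %in% c("M", "I") && ni > L) next
      add <- ltr[t, j] + if (nt == "M") lod[enc[ni], nj] else 0
      extend(nt, ni, nj, sc + add)
    }
  }
  for (i in seq_len(L)) for (j in seq_len(K))
    extend("M", i, j, lod[enc[i], j])
  best
}

# all set partitions of 1..n (Bell-number enumeration)
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

# mR by explicit enumeration of every sequence pair
brute_mr_column <- function(column, labels) {
  ids <- names(labels)
  within <- c()
  between <- c()
  for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
    differ <- column[ids[i]] != column[ids[j]]
    if (labels[ids[i]] == labels[ids[j]]) within <- c(within, differ)
    else between <- c(between, differ)
  }
  mean(between) - mean(within)
}

# maximum number of pairwise-compatible hits by exhaustive subset search
brute_max_tiling <- function(hits, max_overlap) {
  n <- nrow(hits)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    ok <- TRUE
    if (length(idx) > 1) {
      for (a in seq_along(idx)) for (b in seq_len(a - 1)) {
        ov <- min(hits$end[idx[a]], hits$end[idx[b]]) -
          max(hits$start[idx[a]], hits$start[idx[b]]) + 1
        if (ov > max_overlap) { ok <- FALSE; break }
      }
    }
    if (ok) best <- length(idx)
  }
  best
}

# Levenshtein distance on token vectors by recursion with memoisation
brute_edit_distance <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  d <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- min(d(i - 1, j) + 1, d(i, j - 1) + 1,
               d(i - 1, j - 1) + (a[i] != b[j]))
    memo[[key]] <- val
    val
  }
  d(length(a), length(b))
}

# the top candidate hits a repeat-unit profile scan produces on a sequence
# (same filters count_repeats applies), capped at `n_top`
scan_candidates <- function(seq, model, threshold, n_top = 5,
                            min_coverage = 0.80) {
  v <- trpprof:::score_all_ends(model, seq)
  K <- model$consensus_length
  cand <- data.frame(start = v$end_start, end = seq_along(v$end_score),
                     bits = v$end_score, nmatch = v$end_nmatch)
  cand <- cand[is.finite(cand$bits) & cand$bits >= threshold &
                 cand$nmatch >= min_coverage * K, , drop = FALSE]
  cand <- cand[order(-cand$bits), , drop = FALSE]
  cand[seq_len(min(n_top, nrow(cand))), , drop = FALSE]
}

# fixed small test alignment: three identical rows
tiny_alignment <- function(seq = "ACDE", n = 3) {
  trpprof::as_alignment(stats::setNames(rep(seq, n), paste0("s", seq_len(n))))
}

# independently coded residue-property sets for the conservation oracle
oracle_property_score <- function(residues) {
  sets <- list(
    hydrophobic = c("A","C","F","G","H","I","K","L","M","T","V","W","Y"),
    polar = c("C","D","E","H","K","N","Q","R","S","T","W","Y"),
    small = c("A","C","D","G","N","P","S","T","V"),
    tiny = c("A","G","S"),
    aliphatic = c("I","L","V"),
    aromatic = c("F","H","W","Y"),
    positive = c("H","K","R"),
    negative = c("D","E"),
    charged = c("D","E","H","K","R"),
    proline = "P")
  if (length(unique(residues)) == 1) return(11L)
  sum(vapply(sets, function(s) {
    inset <- residues %in% s
    all(inset) || !any(inset)
  }, logical(1)))
}
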