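#' Build a position-specific profile model from an alignment
#'
#' Match columns are the alignment columns with at most 50% gap occupancy.
#' Match emissions use a background-mixture pseudocount:
#' `(count + w * background) / (n_residues + w)` with a single weight `w`.
#' Transitions among match/insert/delete states are estimated from the
#' observed state paths with the same scheme (`w/3` per outgoing edge).
#' Scores reported by [score_sequence()] are local Viterbi log-odds in
#' bits; insert emissions equal the background.
#'
#' @param alignment Character matrix (rows = sequences) or named character
#'   vector of equal-length aligned strings; `-` is the gap.
#' @param pseudocount_weight Non-negative pseudocount weight (effective
#'   prior counts), default 2.
#' @param background Named probability vector over the 20 residues.
#' @param name Model name.
#' @return A `profile_model` object: match emissions (20 x K), transition
#'   probabilities (7 x K; rows MM, MI, MD, IM, II, DM, DD), consensus
#'   length K, background, original match-column indices, and (after
#'   [calibrate_model()]) Gumbel calibration parameters.
#' @export
build_profile <- function(alignment, pseudocount_weight = 2,
                          background = uniform_background(),
                          name = "profile") {
  aln <- as_alignment(alignment)
  if (nrow(aln) < 1 || ncol(aln) < 1)
    stop("empty alignment", call. = FALSE)
  stopifnot(pseudocount_weight >= 0)
  aa <- amino_acids()
  gapfrac <- colMeans(aln == "-")
  match_cols <- which(gapfrac <= 0.5)
  if (!length(match_cols))
    stop("alignment has no usable (<=50% gapped) columns", call. = FALSE)
  K <- length(match_cols)
  w <- pseudocount_weight

  em <- matrix(0, 20, K, dimnames = list(aa, NULL))
  for (k in seq_len(K)) {
    col <- aln[, match_cols[k]]
    col <- col[col != "-"]
    cnt <- table(factor(col, levels = aa))
    em[, k] <- (as.numeric(cnt) + w * background[aa]) / (length(col) + w)
  }

  # transition counts from per-row state paths over match/insert columns
  tc <- matrix(0, 7, K,
               dimnames = list(c("MM", "MI", "MD", "IM", "II", "DM", "DD"),
                               NULL))
  is_match <- logical(ncol(aln))
  is_match[match_cols] <- TRUE
  col_of <- cumsum(is_match)  # model column governing each alignment column
  for (r in seq_len(nrow(aln))) {
    row <- aln[r, ]
    states <- character(0)   # "M<k>", "I<k>", "D<k>"
    cols <- integer(0)
    for (j in seq_len(ncol(aln))) {
      if (is_match[j]) {
        states <- c(states, if (row[j] == "-") "D" else "M")
        cols <- c(cols, col_of[j])
      } else if (row[j] != "-") {
        states <- c(states, "I")
        cols <- c(cols, col_of[j])  # insert attached to preceding column
      }
    }
    if (length(states) < 2) next
    for (s in seq_len(length(states) - 1)) {
      k <- cols[s]  # source column; only columns 1..K-1 have outgoing edges
      if (k < 1 || k > K - 1) next
      key <- paste0(states[s], states[s + 1])
      if (key %in% rownames(tc)) tc[key, k] <- tc[key, k] + 1
    }
  }
  tr <- matrix(0, 7, K, dimnames = dimnames(tc))
  for (k in seq_len(K)) {
    for (grp in list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))) {
      tot <- sum(tc[grp, k])
      tr[grp, k] <- (tc[grp, k] + w / 3) / (tot + w * length(grp) / 3)
    }
  }

  model <- structure(list(
    name = name,
    match_emissions = em,
    insert_emissions = background,
    transitions = tr,
    consensus_length = K,
    background = background,
    match_cols = match_cols,
    pseudocount_weight = w,
    calibration = NULL), class = "profile_model")
  model
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("profile_model '%s': %d match columns%s\n", x$name,
              x$consensus_length,
              if (is.null(x$calibration)) " (uncalibrated)"
              else sprintf(" (Gumbel mu=%.2f, lambda=%.3f)",
                           x$calibration$mu, x$calibration$lambda)))
  invisible(x)
}

# cached log2-odds emission and log2 transition matrices
model_lod <- function(model) {
  log2(model$match_emissions / model$background[rownames(model$match_emissions)])
}
model_ltr <- function(model) log2(model$transitions)

#' Score a sequence against a profile model
#'
#' Computes the best local alignment score in bits (base-2 log-odds of the
#' Viterbi path likelihood against the background), the envelope (1-based
#' inclusive residue coordinates covered by the optimal path) and the
#' number of match states used.
#'
#' @param model A `profile_model`.
#' @param seq Protein sequence (character scalar, 20-residue alphabet;
#'   other symbols raise an error listing them).
#' @param id Protein identifier for the hit row.
#' @param database_size If given and the model is calibrated, the hit's
#'   E-value is filled in; otherwise `e_value` is `NA`.
#' @return One-row data.frame (`protein_id`, `model`, `bit_score`,
#'   `e_value`, `env_start`, `env_end`, `cols_matched`) with the match
#'   path in `attr(, "match_path")`.
#' @export
score_sequence <- function(model, seq, id = "query", database_size = NULL) {
  stopifnot(inherits(model, "profile_model"))
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  enc <- encode_residues(seq, sprintf("sequence '%s'", id))
  v <- viterbi_local_cpp(model_lod(model), model_ltr(model), enc, FALSE)
  ev <- if (!is.null(database_size) && !is.null(model$calibration))
    model_evalue(model, v$score, database_size) else NA_real_
  hit <- data.frame(protein_id = id, model = model$name,
                    bit_score = v$score, e_value = ev,
                    env_start = v$env_start, env_end = v$env_end,
                    cols_matched = v$cols_matched,
                    stringsAsFactors = FALSE)
  attr(hit, "match_path") <- v$match_path
  hit
}

# per-end-position best local hits (for repeat tiling)
score_all_ends <- function(model, seq, id = "query") {
  enc <- encode_residues(seq, sprintf("sequence '%s'", id))
  viterbi_local_cpp(model_lod(model), model_ltr(model), enc, TRUE)
}

# realign sequences to a model: residue at every match column, "-" for
# deletions and columns outside the optimal path envelope
realign_to_model <- function(model, records) {
  rows <- vapply(names(records), function(id) {
    hit <- score_sequence(model, records[[id]], id)
    mp <- attr(hit, "match_path")
    chars <- seq_chars(records[[id]])
    out <- rep("-", model$consensus_length)
    out[mp > 0] <- chars[mp[mp > 0]]
    paste0(out, collapse = "")
  }, character(1))
  as_alignment(rows)
}

# Gumbel (EVD) fit by method of moments
fit_gumbel_moments <- function(scores) {
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0)
    stop("calibration error: degenerate score sample (sd = 0)", call. = FALSE)
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.57721566490153286 / lambda
  list(mu = mu, lambda = lambda)
}

#' Calibrate a model's E-value parameters on random sequences
#'
#' Scores `n_samples` i.i.d. background sequences of length
#' `sample_length` and fits a Gumbel law to the bit-score sample by the
#' method of moments (`lambda = pi/(sd*sqrt(6))`,
#' `mu = mean - gamma/lambda`).
#'
#' @param model A `profile_model`.
#' @param n_samples At least 100 random sequences.
#' @param sample_length Length of each random sequence.
#' @param rng_seed Integer seed (calibration is seed-deterministic).
#' @return The model with `calibration` filled in (`mu`, `lambda`,
#'   `n_samples`, `sample_length`).
#' @export
calibrate_model <- function(model, n_samples = 200, sample_length = 300,
                            rng_seed = 1) {
  stopifnot(inherits(model, "profile_model"))
  if (n_samples < 100) stop("n_samples must be >= 100", call. = FALSE)
  withr_seed(rng_seed)
  aa <- amino_acids()
  p <- model$background[aa]
  lod <- model_lod(model); ltr <- model_ltr(model)
  scores <- vapply(seq_len(n_samples), function(i) {
    enc <- sample.int(20, sample_length, replace = TRUE, prob = p)
    viterbi_local_cpp(lod, ltr, enc, FALSE)$score
  }, numeric(1))
  fit <- fit_gumbel_moments(scores)
  model$calibration <- list(mu = fit$mu, lambda = fit$lambda,
                            n_samples = as.integer(n_samples),
                            sample_length = as.integer(sample_length))
  model
}

#' E-value of a bit score under a calibrated model
#'
#' `E = database_size * exp(-lambda * (bit_score - mu))`, clipped below at
#' zero; monotone decreasing in the score and linear in the database size.
#'
#' @param model Calibrated `profile_model`.
#' @param bit_score Score(s) in bits.
#' @param database_size Number of sequences searched.
#' @return Expected number of equal-or-better random hits.
#' @export
model_evalue <- function(model, bit_score, database_size) {
  if (is.null(model$calibration))
    stop(sprintf("model '%s' is not calibrated", model$name), call. = FALSE)
  cal <- model$calibration
  pmax(0, database_size * exp(-cal$lambda * (bit_score - cal$mu)))
}

# strict inclusion rule shared by iterative_search and scan filters
included_by_evalue <- function(evalues, threshold) {
  names(evalues)[evalues < threshold & is.finite(evalues)]
}

#' Iterative profile search with a strict inclusion threshold
#'
#' Iteration 1 builds a single-sequence profile from the query
#' (pseudocounts only); each iteration scans the database, includes hits
#' with `E < inclusion_evalue` (strict), realigns the included sequences
#' to the model and rebuilds it. The search stops when the included set
#' is unchanged or after `max_iterations` iterations.
#'
#' @param query Named character vector of length 1 (the seed sequence).
#' @param database Named character vector of protein sequences.
#' @param max_iterations Default 5.
#' @param inclusion_evalue Default 1e-20; hits at exactly the threshold
#'   are not included.
#' @param pseudocount_weight Passed to [build_profile()].
#' @param n_samples,sample_length Calibration settings per iteration.
#' @param rng_seed Integer seed (one calibration seed per iteration is
#'   derived from it).
#' @return List with `included` (protein ids, always containing the
#'   query), `final_model`, `alignment` of the included set, and
#'   `n_iterations`.
#' @export
iterative_search <- function(query, database, max_iterations = 5,
                             inclusion_evalue = 1e-20,
                             pseudocount_weight = 2,
                             n_samples = 200, sample_length = 300,
                             rng_seed = 1) {
  stopifnot(max_iterations >= 1)
  if (!length(database)) stop("empty database", call. = FALSE)
  stopifnot(length(query) == 1, !is.null(names(query)))
  qid <- names(query)
  aln <- as_alignment(query)
  included <- qid
  model <- NULL
  iterations <- 0L
  for (it in seq_len(max_iterations)) {
    iterations <- it
    model <- build_profile(aln, pseudocount_weight,
                           name = paste0("search_", qid))
    model <- calibrate_model(model, n_samples, sample_length,
                             rng_seed = rng_seed + it)
    ev <- vapply(names(database), function(id)
      model_evalue(model,
                   score_sequence(model, database[[id]], id)$bit_score,
                   length(database)), numeric(1))
    new_included <- sort(unique(c(qid, included_by_evalue(ev, inclusion_evalue))))
    pool <- database[setdiff(new_included, qid)]
    pool <- c(query, pool)
    aln <- realign_to_model(model, pool)
    if (setequal(new_included, included) && it > 1) {
      included <- new_included
      break
    }
    included <- new_included
  }
  list(included = included, final_model = model, alignment = aln,
       n_iterations = iterations)
}

#' Extract the transmembrane region of a sequence with flanks
#'
#' Predicts membrane-spanning helices by Kyte-Doolittle hydropathy
#' (window 19, threshold 1.6, runs of at least 6 consecutive qualifying
#' windows merged into one helix) and returns the span from the first
#' helix start minus `flank` to the last helix end plus `flank`, clipped
#' to the sequence.
#'
#' @param seq Protein sequence.
#' @param flank Residues added on both sides (default 20).
#' @param window Hydropathy window length (odd; default 19).
#' @param threshold Window-mean hydropathy cutoff (default 1.6).
#' @param min_run Minimum number of consecutive qualifying windows.
#' @return List with `start`, `end`, `sequence` (the extracted span) and
#'   `helices` (data.frame of helix coordinates), or `NULL` when no
#'   membrane helix is predicted (a signal, not an error).
#' @export
extract_tm_region <- function(seq, flank = 20, window = 19, threshold = 1.6,
                              min_run = 6) {
  stopifnot(flank >= 0)
  chars <- seq_chars(seq)
  hyd <- kyte_doolittle()[chars]
  if (anyNA(hyd)) stop("sequence contains non-amino-acid symbols",
                       call. = FALSE)
  L <- length(chars)
  if (L < window) return(NULL)
  means <- stats::filter(hyd, rep(1 / window, window), sides = 2)
  half <- (window - 1L) %/% 2L
  centers <- (half + 1L):(L - half)
  qual <- !is.na(means[centers]) & means[centers] > threshold
  helices <- runs_to_helices(centers, qual, min_run, half, L)
  if (!nrow(helices)) return(NULL)
  span <- tm_span_from_helices(helices, flank, L)
  list(start = span[1], end = span[2],
       sequence = substr(seq, span[1], span[2]), helices = helices)
}

# runs of qualifying window centers -> helix coordinate table
runs_to_helices <- function(centers, qual, min_run, half, L) {
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  if (!length(keep))
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = pmax(1L, centers[starts[keep]] - half),
             end = pmin(L, centers[ends[keep]] + half))
}

# flanking arithmetic, clipped to [1, L]
tm_span_from_helices <- function(helices, flank, L) {
  c(max(1L, min(helices$start) - as.integer(flank)),
    min(L, max(helices$end) + as.integer(flank)))
}

#' Serialize profile models to versioned JSON lines
#'
#' One model per line: name, emissions, transitions, background and
#' calibration, with a format version tag.
#'
#' @param models A `profile_model` or list of them.
#' @param path Output file.
#' @return `read_models()`: named list of `profile_model`s.
#' @export
write_models <- function(models, path) {
  if (inherits(models, "profile_model")) models <- list(models)
  lines <- vapply(models, function(m) {
    jsonlite::toJSON(list(
      format_version = 1L, name = m$name,
      match_emissions = m$match_emissions,
      transitions = m$transitions,
      background = as.list(m$background),
      match_cols = m$match_cols,
      pseudocount_weight = m$pseudocount_weight,
      calibration = m$calibration), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  lines <- readLines(path)
  models <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    em <- as.matrix(x$match_emissions)
    rownames(em) <- amino_acids()
    tr <- as.matrix(x$transitions)
    rownames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
    structure(list(
      name = x$name, match_emissions = em,
      insert_emissions = unlist(x$background),
      transitions = tr, consensus_length = ncol(em),
      background = unlist(x$background), match_cols = x$match_cols,
      pseudocount_weight = x$pseudocount_weight,
      calibration = x$calibration), class = "profile_model")
  })
  stats::setNames(models, vapply(models, `[[`, character(1), "name"))
}
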