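#' Named threshold profiles for model scans
#'
#' `"census"` applies `E < 1e-25` with at least 80% model coverage (for
#' database-wide censuses); `"genome"` applies `E < 1e-10` with no
#' coverage requirement (for per-genome scans). Both inequalities are
#' strict.
#'
#' @param name `"census"` or `"genome"`.
#' @return List with `evalue_threshold` and `coverage_threshold`.
#' @export
threshold_profile <- function(name = c("census", "genome")) {
  name <- match.arg(name)
  switch(name,
         census = list(evalue_threshold = 1e-25, coverage_threshold = 0.80),
         genome = list(evalue_threshold = 1e-10, coverage_threshold = 0))
}

#' Scan proteins against a set of calibrated profile models
#'
#' Emits every hit with `e_value < evalue_threshold` (strict) and model
#' coverage `cols_matched / consensus_length >= coverage_threshold`;
#' coverage is measured on the model, not the protein.
#'
#' @param models List of calibrated `profile_model`s (typically the
#'   subfamily models plus the unspecific model).
#' @param records Named character vector of protein sequences.
#' @param evalue_threshold,coverage_threshold Filter settings; see
#'   [threshold_profile()] for the named defaults.
#' @param database_size E-value scaling; defaults to `length(records)`.
#' @return data.frame of hits (`protein_id`, `model`, `bit_score`,
#'   `e_value`, `env_start`, `env_end`, `cols_matched`, `coverage`),
#'   possibly empty.
#' @export
scan_models <- function(models, records,
                        evalue_threshold = 1e-25, coverage_threshold = 0.80,
                        database_size = length(records)) {
  if (inherits(models, "profile_model")) models <- list(models)
  rows <- list()
  for (m in models) {
    if (is.null(m$calibration))
      stop(sprintf("model '%s' is not calibrated", m$name), call. = FALSE)
    for (id in names(records)) {
      hit <- score_sequence(m, records[[id]], id,
                            database_size = database_size)
      hit$coverage <- hit$cols_matched / m$consensus_length
      rows[[length(rows) + 1L]] <- hit
    }
  }
  hits <- do.call(rbind, rows)
  attr(hits, "match_path") <- NULL
  filter_hits(hits, evalue_threshold, coverage_threshold)
}

# strict E-value inequality; coverage measured on the model
filter_hits <- function(hits, evalue_threshold, coverage_threshold) {
  if (is.null(hits) || !nrow(hits)) return(empty_hits())
  keep <- hits$e_value < evalue_threshold &
    hits$coverage >= coverage_threshold
  hits[keep, , drop = FALSE]
}

empty_hits <- function() {
  data.frame(protein_id = character(0), model = character(0),
             bit_score = numeric(0), e_value = numeric(0),
             env_start = integer(0), env_end = integer(0),
             cols_matched = integer(0), coverage = numeric(0),
             stringsAsFactors = FALSE)
}

#' Competitive best-hit family assignment for one protein
#'
#' The best hit is the one with the smallest E-value (ties: larger bit
#' score, then lexicographic model name). A protein whose best hit is the
#' unspecific model is `"excluded"` from family assignment; a protein
#' with no significant hits is `"unclassified"`; otherwise the verdict is
#' the best hit's subfamily.
#'
#' @param hits Hit rows for a single protein (a multi-protein table is an
#'   error).
#' @param unspecific_name Name of the pooled unspecific model.
#' @return List (`classification_result`): `protein_id`, `verdict`,
#'   `best_hit` (one-row data.frame or `NULL`), `all_significant_hits`.
#' @export
assign_family <- function(hits, unspecific_name = "unspecific") {
  if (is.null(hits) || !nrow(hits)) {
    return(structure(list(protein_id = NA_character_,
                          verdict = "unclassified",
                          best_hit = NULL,
                          all_significant_hits = empty_hits()),
                     class = "classification_result"))
  }
  ids <- unique(hits$protein_id)
  if (length(ids) > 1)
    stop("assign_family() expects hits of a single protein", call. = FALSE)
  ord <- order(hits$e_value, -hits$bit_score, hits$model)
  hits <- hits[ord, , drop = FALSE]
  best <- hits[1, , drop = FALSE]
  verdict <- if (best$model == unspecific_name) "excluded" else best$model
  structure(list(protein_id = ids, verdict = verdict, best_hit = best,
                 all_significant_hits = hits),
            class = "classification_result")
}

#' Classify a set of proteins with the competitive best-hit rule
#'
#' Runs [scan_models()] over the subfamily models plus the unspecific
#' model and applies [assign_family()] per protein.
#'
#' @param models Named list of calibrated subfamily models.
#' @param unspecific The pooled unspecific model.
#' @param records Named character vector of proteins.
#' @param profile Named threshold profile (see [threshold_profile()]), or
#'   `NULL` to use the explicit thresholds.
#' @param evalue_threshold,coverage_threshold Explicit filter settings.
#' @param database_size E-value scaling.
#' @return data.frame of verdicts: `protein_id`, `verdict`, `best_model`,
#'   `best_evalue`, `best_bits`, `n_hits`.
#' @export
classify_records <- function(models, unspecific, records,
                             profile = "census",
                             evalue_threshold = NULL,
                             coverage_threshold = NULL,
                             database_size = length(records)) {
  if (!is.null(profile)) {
    p <- threshold_profile(profile)
    if (is.null(evalue_threshold)) evalue_threshold <- p$evalue_threshold
    if (is.null(coverage_threshold)) coverage_threshold <- p$coverage_threshold
  }
  all_models <- c(models, list(unspecific = unspecific))
  hits <- scan_models(all_models, records, evalue_threshold,
                      coverage_threshold, database_size)
  out <- lapply(names(records), function(id) {
    res <- assign_family(hits[hits$protein_id == id, , drop = FALSE],
                         unspecific_name = unspecific$name)
    data.frame(protein_id = id, verdict = res$verdict,
               best_model = if (is.null(res$best_hit)) NA_character_
                            else res$best_hit$model,
               best_evalue = if (is.null(res$best_hit)) NA_real_
                             else res$best_hit$e_value,
               best_bits = if (is.null(res$best_hit)) NA_real_
                           else res$best_hit$bit_score,
               n_hits = nrow(res$all_significant_hits),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Benchmark subfamily models on labeled records
#'
#' Sensitivity of family f is the fraction of family-f records whose
#' verdict is f; selectivity of f is the fraction of verdict-f records
#' truly in f. A family with no records (or no predictions) has the
#' corresponding metric reported as absent (`NA`), not 0; macro averages
#' skip absent values.
#'
#' @param models,unspecific,records,profile,database_size As in
#'   [classify_records()].
#' @param true_family Named character vector: true family per record id.
#' @return List with `per_family` (data.frame: family, n, sensitivity,
#'   selectivity), `macro_sensitivity`, `macro_selectivity` and the raw
#'   `verdicts`.
#' @export
benchmark_models <- function(models, unspecific, records, true_family,
                             profile = "census",
                             database_size = length(records)) {
  stopifnot(all(names(records) %in% names(true_family)))
  verdicts <- classify_records(models, unspecific, records,
                               profile = profile,
                               database_size = database_size)
  res <- benchmark_from_verdicts(verdicts, true_family)
  res$verdicts <- verdicts
  res
}

# metric arithmetic, kept free of scoring so it can be unit-tested
benchmark_from_verdicts <- function(verdicts, true_family) {
  truth <- true_family[verdicts$protein_id]
  fams <- sort(unique(truth))
  per <- lapply(fams, function(f) {
    in_f <- truth == f
    pred_f <- verdicts$verdict == f
    sens <- if (!any(in_f)) NA_real_ else mean(pred_f[in_f])
    sel <- if (!any(pred_f)) NA_real_ else mean(in_f[pred_f])
    data.frame(family = f, n = sum(in_f), sensitivity = sens,
               selectivity = sel, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_family = per,
       macro_sensitivity = mean(per$sensitivity, na.rm = TRUE),
       macro_selectivity = mean(per$selectivity, na.rm = TRUE))
}

#' Write classification verdicts and a benchmark report as TSV
#'
#' @param benchmark Output of [benchmark_models()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_report(benchmark$verdicts, file.path(dir, "verdicts.tsv"))
  write_tsv_report(
    benchmark$per_family, file.path(dir, "benchmark.tsv"),
    meta = sprintf("macro sensitivity %.4f, macro selectivity %.4f",
                   benchmark$macro_sensitivity, benchmark$macro_selectivity))
  invisible(dir)
}
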