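#' Pipeline configuration
#'
#' Bundles all stage parameters behind one object with a single top-level
#' seed; every stage derives its own seed from it, so a rerun with the
#' same configuration reproduces byte-identical artifacts.
#'
#' @param synthetic A [synthetic_config()] describing the simulated
#'   superfamily.
#' @param profile Threshold profile name, `"census"` or `"genome"`.
#' @param flank Seed-extraction flank in residues (default 20; 25 is the
#'   documented alternative).
#' @param inclusion_evalue,max_iterations Iterative-search settings.
#' @param min_fraction Major-subfamily size threshold.
#' @param clustering_threshold Percent identity for redundancy clustering.
#' @param min_repeats Fragmented-model boundary for the long-repeat
#'   family.
#' @param n_permutations Permutations for the specificity stage.
#' @param rng_seed Top-level seed.
#' @param stages Character vector of stages to run (any of `"simulate"`,
#'   `"build"`, `"benchmark"`, `"classify"`, `"cluster"`, `"repeats"`,
#'   `"specificity"`).
#' @return A `pipeline_config` list; an unknown profile name is an error
#'   raised before any stage runs.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            profile = "census",
                            flank = 20,
                            inclusion_evalue = 1e-20,
                            max_iterations = 5,
                            min_fraction = 0.05,
                            clustering_threshold = 80,
                            min_repeats = 27,
                            n_permutations = 1000,
                            rng_seed = 1,
                            stages = c("simulate", "build", "benchmark",
                                       "classify", "cluster", "repeats",
                                       "specificity")) {
  if (!profile %in% c("census", "genome"))
    stop(sprintf("unknown threshold profile '%s'", profile), call. = FALSE)
  known <- c("simulate", "build", "benchmark", "classify", "cluster",
             "repeats", "specificity")
  if (!all(stages %in% known))
    stop(sprintf("unknown stage(s): %s",
                 paste(setdiff(stages, known), collapse = ", ")),
         call. = FALSE)
  structure(list(synthetic = synthetic, profile = profile, flank = flank,
                 inclusion_evalue = inclusion_evalue,
                 max_iterations = max_iterations,
                 min_fraction = min_fraction,
                 clustering_threshold = clustering_threshold,
                 min_repeats = min_repeats,
                 n_permutations = n_permutations,
                 rng_seed = as.integer(rng_seed), stages = stages),
            class = "pipeline_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate, seed extraction, iterative search, subfamily
#' detection, model building, benchmark, classification, redundancy
#' clustering, repeat annotation and specificity analysis (honoring the
#' configured stage list), writing every artifact plus a JSON manifest
#' (resolved configuration, seed, stage timings, md5 of every file) to
#' `outdir`. A stage failure aborts with an error naming the stage and
#' leaves a `FAILED` marker in the run directory.
#'
#' @param config A [pipeline_config()].
#' @param outdir Run directory (created).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(outdir, "FAILED"))
  manifest <- list(config = unclass_config(config), stages = list())
  seed <- config$rng_seed
  state <- new.env(parent = emptyenv())

  stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 2))
    message(sprintf("stage %-12s done (%.1fs)", name,
                    manifest$stages[[name]]$seconds))
  }

  stage("simulate", function() {
    state$sim <- generate_superfamily(config$synthetic)
    write_superfamily(state$sim, file.path(outdir, "simulate"))
    state$pp <- preset_pushpull_default(rng_seed = seed + 17L)
    write_alignment(state$pp$alignment,
                    file.path(outdir, "simulate", "pushpull.afa"))
  })

  stage("build", function() {
    sim <- state$sim
    members <- names(sim$truth$family_of)[sim$truth$family_of != "decoy"]
    fams <- unique(sim$truth$family_of[members])
    # one seed exemplar per family, TM region with flanks as the query
    included <- character(0)
    envelopes <- character(0)
    for (i in seq_along(fams)) {
      f <- fams[i]
      exemplar <- members[sim$truth$family_of[members] == f][1]
      tm <- extract_tm_region(sim$records[[exemplar]], flank = config$flank)
      if (is.null(tm)) stop(sprintf("no TM region in exemplar '%s'", exemplar))
      q <- stats::setNames(tm$sequence, exemplar)
      res <- iterative_search(q, sim$records,
                              max_iterations = config$max_iterations,
                              inclusion_evalue = config$inclusion_evalue,
                              rng_seed = seed + 100L + i)
      ids <- setdiff(res$included, exemplar)
      for (id in union(exemplar, res$included)) {
        if (id %in% names(envelopes)) next
        hit <- score_sequence(res$final_model, sim$records[[id]], id)
        envelopes[[id]] <- substr(sim$records[[id]], hit$env_start,
                                  hit$env_end)
      }
      included <- union(included, res$included)
    }
    state$envelopes <- envelopes[included]
    write_fasta(state$envelopes, file.path(outdir, "hit_envelopes.fasta"))
    aln <- align_with_mafft(state$envelopes)
    write_alignment(aln, file.path(outdir, "hits_aligned.afa"))
    part <- detect_subfamilies(aln)
    write_partition(part, file.path(outdir, "subfamilies"))
    sel <- select_major_subfamilies(part, config$min_fraction)
    state$built <- build_subfamily_models(aln, part, sel$labels,
                                          rng_seed = seed + 200L)
    state$partition <- part
    state$selection <- sel
    write_models(c(state$built$models, list(state$built$unspecific)),
                 file.path(outdir, "models.jsonl"))
  })

  stage("benchmark", function() {
    sim <- state$sim
    members <- names(sim$truth$family_of)[sim$truth$family_of != "decoy"]
    bm <- benchmark_models(state$built$models, state$built$unspecific,
                           sim$records[members],
                           truth_by_cluster(state, sim),
                           profile = config$profile)
    state$benchmark <- bm
    write_benchmark(bm, file.path(outdir, "benchmark"))
  })

  stage("classify", function() {
    sim <- state$sim
    verdicts <- classify_records(state$built$models, state$built$unspecific,
                                 sim$records, profile = config$profile)
    state$verdicts <- verdicts
    write_tsv_report(verdicts, file.path(outdir, "verdicts.tsv"))
  })

  stage("cluster", function() {
    cl <- greedy_cluster(state$envelopes, config$clustering_threshold)
    write_clusters(cl, file.path(outdir, "identity_clusters.tsv"))
    write_fasta(extract_centroids(cl, state$envelopes),
                file.path(outdir, "centroids.fasta"))
  })

  stage("repeats", function() {
    sim <- state$sim
    unit <- build_profile(sim$truth$unit_alignment, name = "ankyrin_unit")
    unit <- calibrate_model(unit, sample_length = 200,
                            rng_seed = seed + 300L)
    members <- names(sim$truth$family_of)[sim$truth$family_of != "decoy"]
    anns <- lapply(members, function(id)
      count_repeats(sim$records[[id]], unit, id = id))
    write_annotations(anns, file.path(outdir, "repeat_annotations.tsv"))
    counts <- vapply(anns, `[[`, numeric(1), "ankyrin_count")
    frag <- mapply(function(id, ct)
      flag_fragmented(sim$truth$family_of[[id]], ct,
                      trpn_family = "fam1",
                      min_repeats = config$min_repeats),
      members, counts)
    write_tsv_report(
      data.frame(protein_id = members, ankyrin_count = counts,
                 fragmented = unname(frag), stringsAsFactors = FALSE),
      file.path(outdir, "repeat_counts.tsv"))
  })

  stage("specificity", function() {
    pp <- if (!is.null(state$pp)) state$pp
          else preset_pushpull_default(rng_seed = seed + 17L)
    rep <- specificity_report(pp$alignment, pp$labels, pp$query_ids,
                              n_permutations = config$n_permutations,
                              rng_seed = seed + 400L)
    write_specificity_report(rep, file.path(outdir, "specificity"))
  })

  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(outdir, "manifest.json"))
  manifest$files <- as.list(tools::md5sum(files))
  names(manifest$files) <- substring(names(manifest$files),
                                     nchar(outdir) + 2L)
  manifest$rng_seed <- seed
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$synthetic <- unclass(out$synthetic)
  out$synthetic$ankyrin_repeat_count <-
    as.list(out$synthetic$ankyrin_repeat_count)
  out
}

# map detected-cluster labels onto true families by majority vote so the
# benchmark can compare verdicts with ground truth
truth_by_cluster <- function(state, sim) {
  cl <- state$partition$cluster_of
  fams <- sim$truth$family_of[names(cl)]
  map <- tapply(fams, cl, function(x) names(sort(table(x),
                                                 decreasing = TRUE))[1])
  truth <- sim$truth$family_of
  inv <- stats::setNames(names(map), unname(map))
  stats::setNames(ifelse(truth %in% names(inv), inv[truth], truth),
                  names(truth))
}

# pooled MSA via the mafft command-line aligner (deterministic defaults)
align_with_mafft <- function(records) {
  mafft <- Sys.which("mafft")
  if (!nzchar(mafft))
    stop("mafft is required for the pipeline alignment stage", call. = FALSE)
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".afa")
  on.exit(unlink(c(fin, fout)))
  write_fasta(records, fin)
  status <- system2(mafft, c("--quiet", "--retree", "2", fin),
                    stdout = fout, stderr = FALSE)
  if (status != 0) stop("mafft failed", call. = FALSE)
  aln <- read_alignment(fout)
  toupper_alignment(aln[names(records), , drop = FALSE])
}

toupper_alignment <- function(aln) {
  m <- toupper(aln)
  dim(m) <- dim(aln)
  dimnames(m) <- dimnames(aln)
  m
}
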