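#' Configuration for the synthetic superfamily generator
#'
#' The generator emulates the statistical structure of a channel
#' superfamily: divergent subfamilies sharing a transmembrane core,
#' N-terminal tandem ankyrin arrays of family-specific length, unrelated
#' decoys, and (via [fragment_records()]) truncated gene models.
#'
#' @param n_subfamilies Number of subfamilies.
#' @param seqs_per_subfamily Members generated per subfamily.
#' @param channel_length Length of the shared transmembrane core, residues.
#' @param subfamily_divergence Per-site substitution probability applied to
#'   the ancestral core to derive each subfamily consensus, in `[0,1]`.
#' @param within_subfamily_divergence Per-site substitution probability
#'   applied to the subfamily consensus to derive each member; must be
#'   strictly smaller than `subfamily_divergence` or the subfamilies are
#'   not recoverable.
#' @param ankyrin_repeat_count Named integer vector mapping family label to
#'   the number of tandem ankyrin units planted at the N-terminus. Default:
#'   family 1 carries 28 units (a TRP-N-like gating-spring array), family 2
#'   carries 11 (TRP-A-like), families 3 and 4 carry 6 and 4, the rest none.
#' @param ankyrin_unit_length Length of one ankyrin unit (default 33, the
#'   canonical repeat length).
#' @param ankyrin_unit_divergence Per-site substitution probability applied
#'   to the unit consensus for every planted copy.
#' @param n_decoys Number of unrelated background-frequency decoys.
#' @param decoy_length_range Two integers, uniform length range for decoys.
#' @param rng_seed Integer seed; identical config + seed gives identical
#'   output.
#' @return A `synthetic_config` list; invalid settings raise an error
#'   naming the offending field.
#' @export
synthetic_config <- function(n_subfamilies = 6,
                             seqs_per_subfamily = 30,
                             channel_length = 240,
                             subfamily_divergence = 0.5,
                             within_subfamily_divergence = 0.10,
                             ankyrin_repeat_count = NULL,
                             ankyrin_unit_length = 33,
                             ankyrin_unit_divergence = 0.15,
                             n_decoys = 60,
                             decoy_length_range = c(100, 800),
                             rng_seed = 42) {
  fam <- paste0("fam", seq_len(n_subfamilies))
  if (is.null(ankyrin_repeat_count)) {
    counts <- c(28, 11, 6, 4)
    ankyrin_repeat_count <- stats::setNames(
      c(counts, rep(0, max(0, n_subfamilies - 4)))[seq_len(n_subfamilies)], fam)
  }
  cfg <- list(n_subfamilies = as.integer(n_subfamilies),
              seqs_per_subfamily = as.integer(seqs_per_subfamily),
              channel_length = as.integer(channel_length),
              subfamily_divergence = subfamily_divergence,
              within_subfamily_divergence = within_subfamily_divergence,
              ankyrin_repeat_count = ankyrin_repeat_count,
              ankyrin_unit_length = as.integer(ankyrin_unit_length),
              ankyrin_unit_divergence = ankyrin_unit_divergence,
              n_decoys = as.integer(n_decoys),
              decoy_length_range = as.integer(decoy_length_range),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "synthetic_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop(sprintf("invalid configuration field '%s': %s", field, why),
                  call. = FALSE)
  }
  chk(cfg$n_subfamilies >= 0, "n_subfamilies", "must be >= 0")
  chk(cfg$seqs_per_subfamily >= 0, "seqs_per_subfamily", "must be >= 0")
  chk(cfg$channel_length >= 1, "channel_length", "must be >= 1")
  chk(cfg$ankyrin_unit_length >= 1, "ankyrin_unit_length", "must be >= 1")
  chk(cfg$n_decoys >= 0, "n_decoys", "must be >= 0")
  for (f in c("subfamily_divergence", "within_subfamily_divergence",
              "ankyrin_unit_divergence"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be in [0,1]")
  chk(cfg$within_subfamily_divergence < cfg$subfamily_divergence,
      "within_subfamily_divergence",
      "must be < subfamily_divergence, otherwise subfamilies are not recoverable")
  chk(all(cfg$ankyrin_repeat_count >= 0), "ankyrin_repeat_count",
      "counts must be >= 0")
  chk(length(cfg$decoy_length_range) == 2 &&
        cfg$decoy_length_range[1] <= cfg$decoy_length_range[2] &&
        cfg$decoy_length_range[1] >= 1,
      "decoy_length_range", "must be two increasing positive lengths")
  invisible(cfg)
}

# mutate characters at `rate`; positions flagged in helix_mask resample from
# the hydrophobic alphabet (membrane spans conserve hydrophobicity), others
# uniformly from the 19 alternatives
hydrophobic_alphabet <- function() c("A", "C", "F", "I", "L", "M", "V")

mutate_chars <- function(chars, rate, helix_mask = NULL) {
  n <- length(chars)
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(chars)
  aa <- amino_acids()
  hyd <- hydrophobic_alphabet()
  for (i in hit) {
    pool <- if (!is.null(helix_mask) && helix_mask[i]) hyd else aa
    pool <- setdiff(pool, chars[i])
    chars[i] <- pool[sample.int(length(pool), 1)]
  }
  chars
}

# deterministic helix layout for a core of given length: up to six 21-residue
# membrane spans separated by even linkers
helix_layout <- function(len) {
  n_helix <- max(1L, min(6L, len %/% 40L))
  hlen <- 21L
  gap <- (len - n_helix * hlen) %/% (n_helix + 1L)
  starts <- gap + (seq_len(n_helix) - 1L) * (hlen + gap) + 1L
  data.frame(start = starts, end = starts + hlen - 1L)
}

random_chars <- function(n, pool = amino_acids()) {
  pool[sample.int(length(pool), n, replace = TRUE)]
}

#' Generate a synthetic channel superfamily with ground truth
#'
#' One random ancestral transmembrane core is drawn; each subfamily
#' derives its consensus by mutating the ancestor at
#' `subfamily_divergence`, and members mutate their consensus at
#' `within_subfamily_divergence`. Families with a positive
#' `ankyrin_repeat_count` get an N-terminal tandem array of mutated copies
#' of one ankyrin unit consensus. Decoys are i.i.d. background sequences.
#'
#' @param config A [synthetic_config()].
#' @return A list with `records` (named character vector) and `truth`, a
#'   list holding `family_of`, `repeat_count_of`, `channel_start`,
#'   `channel_end` (all named by protein id), the `unit_consensus`, a
#'   `unit_alignment` character matrix of the planted unit copies, and the
#'   helix layout of the core.
#' @export
generate_superfamily <- function(config) {
  validate_config(config)
  withr_seed(config$rng_seed)
  aa <- amino_acids()
  L <- config$channel_length
  hel <- helix_layout(L)
  hmask <- rep(FALSE, L)
  for (k in seq_len(nrow(hel))) hmask[hel$start[k]:hel$end[k]] <- TRUE
  ancestor <- random_chars(L)
  ancestor[hmask] <- random_chars(sum(hmask), hydrophobic_alphabet())
  unit_consensus <- random_chars(config$ankyrin_unit_length)

  fams <- names(config$ankyrin_repeat_count)
  records <- character(0)
  family_of <- character(0)
  repeat_count_of <- integer(0)
  channel_start <- integer(0)
  unit_rows <- list()

  for (f in fams) {
    consensus <- mutate_chars(ancestor, config$subfamily_divergence, hmask)
    n_units <- config$ankyrin_repeat_count[[f]]
    for (m in seq_len(config$seqs_per_subfamily)) {
      id <- sprintf("%s_m%02d", f, m)
      core <- mutate_chars(consensus, config$within_subfamily_divergence, hmask)
      units <- character(0)
      if (n_units > 0) {
        for (u in seq_len(n_units)) {
          uc <- mutate_chars(unit_consensus, config$ankyrin_unit_divergence)
          unit_rows[[paste0(id, "_u", u)]] <- uc
          units <- c(units, paste0(uc, collapse = ""))
        }
      }
      nterm <- paste0(units, collapse = "")
      records[[id]] <- paste0(nterm, paste0(core, collapse = ""))
      family_of[[id]] <- f
      repeat_count_of[[id]] <- n_units
      channel_start[[id]] <- nchar(nterm) + 1L
    }
  }
  for (d in seq_len(config$n_decoys)) {
    id <- sprintf("decoy%03d", d)
    len <- sample(config$decoy_length_range[1]:config$decoy_length_range[2], 1)
    records[[id]] <- paste0(random_chars(len), collapse = "")
    family_of[[id]] <- "decoy"
    repeat_count_of[[id]] <- 0L
    channel_start[[id]] <- NA_integer_
  }

  unit_alignment <- if (length(unit_rows)) do.call(rbind, unit_rows) else NULL
  truth <- list(
    family_of = family_of,
    repeat_count_of = repeat_count_of,
    channel_start = channel_start,
    channel_end = channel_start + L - 1L,
    unit_consensus = paste0(unit_consensus, collapse = ""),
    unit_alignment = unit_alignment,
    helices = hel)
  list(records = records, truth = truth, config = config)
}

# channel-core substrings of member records (the planted alignment; the
# generator uses no indels inside the core, so cores are column-addressable)
#' Extract the planted channel-core alignment of member records
#'
#' @param sim Output of [generate_superfamily()].
#' @param ids Optional subset of protein ids (members only).
#' @return Character matrix, one row per member, `channel_length` columns.
#' @export
channel_alignment <- function(sim, ids = NULL) {
  members <- names(sim$truth$family_of)[sim$truth$family_of != "decoy"]
  if (!is.null(ids)) members <- intersect(ids, members)
  rows <- vapply(members, function(id) {
    substr(sim$records[[id]], sim$truth$channel_start[[id]],
           sim$truth$channel_end[[id]])
  }, character(1))
  as_alignment(rows)
}

#' Generate a push/pull alignment with planted disjunct columns
#'
#' At each planted column the push group draws residues from a small
#' "push" set and the pull group from a disjoint "pull" set (group sets of
#' size 1 or 2: specificity-determining positions are near-invariant
#' within groups). All other columns carry a shared consensus with i.i.d.
#' substitution noise. Query rows copy a pull-set residue at every planted
#' column and behave like group rows elsewhere.
#'
#' @param n_push,n_pull,n_query Row counts for the two mechanism groups
#'   and the query sequences.
#' @param n_columns Alignment width.
#' @param n_disjunct Number of planted completely-disjunct columns; must
#'   not exceed `n_columns`.
#' @param noise Per-site substitution probability on non-planted columns.
#' @param rng_seed Integer seed.
#' @return List with `alignment` (character matrix; rows named
#'   `push*`/`pull*`/`query*`), `labels` (push/pull assignment of group
#'   rows), `query_ids`, and `truth` holding `disjunct_columns`
#'   (data.frame: `column` 1-based, `push_set`, `pull_set`).
#' @export
generate_pushpull_alignment <- function(n_push = 10, n_pull = 10, n_query = 4,
                                        n_columns = 300, n_disjunct = 17,
                                        noise = 0.1, rng_seed = 1) {
  if (n_disjunct > n_columns)
    stop("n_disjunct must not exceed n_columns", call. = FALSE)
  stopifnot(n_push >= 1, n_pull >= 1, noise >= 0, noise <= 1)
  withr_seed(rng_seed)
  aa <- amino_acids()
  cols <- sort(sample.int(n_columns, n_disjunct))
  consensus <- random_chars(n_columns)
  n <- n_push + n_pull + n_query
  m <- matrix("", n, n_columns)
  rownames(m) <- c(sprintf("push%02d", seq_len(n_push)),
                   sprintf("pull%02d", seq_len(n_pull)),
                   if (n_query > 0) sprintf("query%02d", seq_len(n_query)))
  for (i in seq_len(n)) m[i, ] <- mutate_chars(consensus, noise)
  push_sets <- pull_sets <- character(n_disjunct)
  for (k in seq_along(cols)) {
    picks <- sample(aa, 4)
    ps <- picks[seq_len(sample(1:2, 1))]
    ls <- picks[3:4][seq_len(sample(1:2, 1))]
    push_sets[k] <- paste0(sort(ps), collapse = "")
    pull_sets[k] <- paste0(sort(ls), collapse = "")
    j <- cols[k]
    m[seq_len(n_push), j] <- sample(ps, n_push, replace = TRUE)
    m[n_push + seq_len(n_pull), j] <- sample(ls, n_pull, replace = TRUE)
    if (n_query > 0)
      m[n_push + n_pull + seq_len(n_query), j] <-
        sample(ls, n_query, replace = TRUE)
  }
  labels <- stats::setNames(rep(c("push", "pull"), c(n_push, n_pull)),
                            rownames(m)[seq_len(n_push + n_pull)])
  truth <- list(disjunct_columns = data.frame(
    column = cols, push_set = push_sets, pull_set = pull_sets,
    stringsAsFactors = FALSE))
  list(alignment = m, labels = labels,
       query_ids = if (n_query > 0) rownames(m)[n_push + n_pull + seq_len(n_query)]
                   else character(0),
       truth = truth)
}

#' Preset: the default push/pull alignment
#'
#' The `pushpull-default` preset plants 17 completely disjunct columns in a
#' 300-column alignment of 10 push, 10 pull and 4 query rows at noise 0.1.
#'
#' @param rng_seed Integer seed.
#' @return See [generate_pushpull_alignment()].
#' @export
preset_pushpull_default <- function(rng_seed = 1) {
  generate_pushpull_alignment(n_push = 10, n_pull = 10, n_query = 4,
                              n_columns = 300, n_disjunct = 17,
                              noise = 0.1, rng_seed = rng_seed)
}

#' Preset: a TRP-N-like repeat protein
#'
#' One protein carrying a tandem N-terminal array of 28 ankyrin units (33
#' residues each, mutated copies of a unit consensus) followed by a
#' transmembrane channel core, plus a fresh training alignment of unit
#' copies drawn from the same consensus at the same divergence.
#'
#' @param rng_seed Integer seed.
#' @param n_units Planted full units (default 28).
#' @param half_unit Append the N-terminal half of one further unit copy
#'   between the array and the core (the repeat counter must still report
#'   `n_units`: the lower-number convention).
#' @param n_training_units Rows of the returned unit training alignment.
#' @return List with `record` (named character vector of length 1),
#'   `unit_alignment` (training alignment), `truth` (`repeat_count`,
#'   channel coordinates).
#' @export
preset_trpn_like <- function(rng_seed = 1, n_units = 28, half_unit = FALSE,
                             n_training_units = 24) {
  withr_seed(rng_seed)
  ulen <- 33L
  unit_consensus <- random_chars(ulen)
  div <- 0.15
  units <- vapply(seq_len(n_units), function(u)
    paste0(mutate_chars(unit_consensus, div), collapse = ""), character(1))
  half <- if (half_unit)
    paste0(mutate_chars(unit_consensus, div)[seq_len(ulen %/% 2)],
           collapse = "") else ""
  L <- 240L
  hel <- helix_layout(L)
  hmask <- rep(FALSE, L)
  for (k in seq_len(nrow(hel))) hmask[hel$start[k]:hel$end[k]] <- TRUE
  core <- random_chars(L)
  core[hmask] <- random_chars(sum(hmask), hydrophobic_alphabet())
  nterm <- paste0(paste0(units, collapse = ""), half)
  rec <- stats::setNames(paste0(nterm, paste0(core, collapse = "")), "trpn_like")
  training <- do.call(rbind, lapply(seq_len(n_training_units), function(u)
    mutate_chars(unit_consensus, div)))
  rownames(training) <- sprintf("unit%02d", seq_len(n_training_units))
  list(record = rec,
       unit_alignment = training,
       truth = list(repeat_count = n_units,
                    channel_start = nchar(nterm) + 1L,
                    channel_end = nchar(nterm) + L))
}

#' Truncate records from the N-terminus, emulating fragmented gene models
#'
#' A fraction of member records with at least two planted ankyrin units is
#' truncated by removing a random number (at least 2) of whole units from
#' the N-terminus; the channel core is left intact and the ground truth
#' repeat counts and channel coordinates are updated.
#'
#' @param records Named character vector (as from
#'   [generate_superfamily()]).
#' @param truth The matching ground-truth list.
#' @param fraction Probability that an eligible record is fragmented.
#' @param rng_seed Integer seed.
#' @param unit_length Ankyrin unit length used when the records were
#'   generated.
#' @return List with updated `records` and `truth`; `truth$fragmented`
#'   names the truncated records.
#' @export
fragment_records <- function(records, truth, fraction, rng_seed = 1,
                             unit_length = 33) {
  stopifnot(fraction >= 0, fraction <= 1)
  withr_seed(rng_seed)
  eligible <- names(records)[!is.na(truth$repeat_count_of[names(records)]) &
                               truth$repeat_count_of[names(records)] >= 2]
  hit <- eligible[stats::runif(length(eligible)) < fraction]
  for (id in hit) {
    k <- truth$repeat_count_of[[id]]
    drop <- if (k == 2) 2L else sample(2:k, 1)
    cut <- drop * unit_length
    records[[id]] <- substr(records[[id]], cut + 1L, nchar(records[[id]]))
    truth$repeat_count_of[[id]] <- k - drop
    truth$channel_start[[id]] <- truth$channel_start[[id]] - cut
    truth$channel_end[[id]] <- truth$channel_end[[id]] - cut
  }
  truth$fragmented <- hit
  list(records = records, truth = truth)
}

#' Write generator output to disk
#'
#' Records go to FASTA, the ground truth to a TSV sidecar
#' (`protein_id`, `family`, `repeat_count`) and, for push/pull data, the
#' site plan to JSON. Column indices in files are 0-based.
#'
#' @param sim Output of [generate_superfamily()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_superfamily <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$records, file.path(dir, "records.fasta"))
  truth <- data.frame(protein_id = names(sim$truth$family_of),
                      family = unname(sim$truth$family_of),
                      repeat_count = unname(
                        sim$truth$repeat_count_of[names(sim$truth$family_of)]),
                      stringsAsFactors = FALSE)
  write_tsv_report(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

# every stochastic entry point seeds the RNG explicitly
withr_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}
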