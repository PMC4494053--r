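#' Count tandem ankyrin repeats by profile scanning with greedy tiling
#'
#' All local hits of the unit model with bit score at or above
#' `per_unit_bit_threshold` are collected (best hit ending at every
#' sequence position); hits matching fewer than `min_coverage` of the
#' unit model's columns are never counted, which operationalizes the
#' lower-number reporting convention for ambiguous repeat ends. Greedy
#' tiling then accepts hits in decreasing bit-score order, discarding any
#' candidate that overlaps an accepted hit by more than
#' `overlap_fraction` of the unit length.
#'
#' @param seq Protein sequence.
#' @param repeat_model Calibrated `profile_model` built from an ankyrin
#'   unit alignment.
#' @param per_unit_bit_threshold Minimum per-unit bit score; default is
#'   the 99th percentile of the model's calibrated random-score Gumbel.
#' @param overlap_fraction Tolerated overlap between accepted units as a
#'   fraction of unit length (default 0.10; tandem units abut tightly).
#' @param min_coverage Minimum fraction of unit model columns a counted
#'   hit must match (default 0.80).
#' @param id Protein identifier.
#' @return A `domain_annotation`: `protein_id`, `segments` (data.frame of
#'   `domain_type`, `start`, `end`, `bit_score`, 1-based inclusive,
#'   sorted, non-overlapping beyond the tolerance) and `ankyrin_count`.
#' @export
count_repeats <- function(seq, repeat_model, per_unit_bit_threshold = NULL,
                          overlap_fraction = 0.10, min_coverage = 0.80,
                          id = "protein") {
  stopifnot(inherits(repeat_model, "profile_model"))
  if (is.null(per_unit_bit_threshold)) {
    if (is.null(repeat_model$calibration))
      stop("give per_unit_bit_threshold or calibrate the repeat model",
           call. = FALSE)
    cal <- repeat_model$calibration
    per_unit_bit_threshold <- cal$mu - log(-log(0.99)) / cal$lambda
  }
  K <- repeat_model$consensus_length
  tol <- overlap_fraction * K
  L <- nchar(seq)
  candidates_in <- function(from, to) {
    sub <- substr(seq, from, to)
    v <- score_all_ends(repeat_model, sub, id)
    cand <- data.frame(start = v$end_start + from - 1L,
                       end = seq_along(v$end_score) + from - 1L,
                       bits = v$end_score, nmatch = v$end_nmatch)
    cand[is.finite(cand$bits) &
           cand$bits >= per_unit_bit_threshold &
           cand$nmatch >= min_coverage * K, , drop = FALSE]
  }
  # a strong unit's extended alignment can mask a weaker neighbour's own
  # best path, so after each tiling round the still-uncovered intervals
  # (expanded by the overlap tolerance) are re-scanned until no further
  # hit clears the threshold
  accepted <- greedy_tile(candidates_in(1L, L), max_overlap = tol)
  repeat {
    iv <- uncovered_intervals(L, accepted, expand = floor(tol),
                              min_width = ceiling(min_coverage * K))
    if (!nrow(iv)) break
    cand <- do.call(rbind, lapply(seq_len(nrow(iv)), function(r)
      candidates_in(iv$from[r], iv$to[r])))
    fresh <- greedy_tile(cand, max_overlap = tol, accepted = accepted)
    if (!nrow(fresh)) break
    accepted <- rbind(accepted, fresh)
  }
  segments <- if (nrow(accepted)) {
    data.frame(domain_type = "ANK", start = accepted$start,
               end = accepted$end, bit_score = accepted$bits,
               stringsAsFactors = FALSE)
  } else {
    data.frame(domain_type = character(0), start = integer(0),
               end = integer(0), bit_score = numeric(0),
               stringsAsFactors = FALSE)
  }
  segments <- segments[order(segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  structure(list(protein_id = id, segments = segments,
                 ankyrin_count = nrow(segments),
                 threshold = per_unit_bit_threshold),
            class = "domain_annotation")
}

#' Greedy non-overlapping tiling of scored intervals
#'
#' Accepts hits in decreasing bit-score order (ties: smaller start, then
#' smaller end), discarding any hit that overlaps an already accepted hit
#' by more than `max_overlap` residues.
#'
#' @param hits data.frame with columns `start`, `end`, `bits`.
#' @param max_overlap Tolerated overlap in residues.
#' @param accepted Optional data.frame of already accepted intervals the
#'   new hits must also respect (those rows are not returned).
#' @return The accepted rows, in acceptance order.
#' @export
greedy_tile <- function(hits, max_overlap = 0, accepted = NULL) {
  if (is.null(hits) || !nrow(hits))
    return(if (is.null(hits)) hits else hits[0, , drop = FALSE])
  ord <- order(-hits$bits, hits$start, hits$end)
  hits <- hits[ord, , drop = FALSE]
  astart <- if (!is.null(accepted)) accepted$start else numeric(0)
  aend <- if (!is.null(accepted)) accepted$end else numeric(0)
  acc <- integer(0)
  for (i in seq_len(nrow(hits))) {
    ov <- pmax(0, pmin(c(aend, hits$end[acc]), hits$end[i]) -
                 pmax(c(astart, hits$start[acc]), hits$start[i]) + 1)
    if (!length(ov) || all(ov <= max_overlap)) acc <- c(acc, i)
  }
  out <- hits[acc, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# maximal intervals of [1, L] not covered by accepted hits, expanded by
# `expand` residues into the covered neighbourhood
uncovered_intervals <- function(L, accepted, expand = 0, min_width = 1) {
  covered <- rep(FALSE, L)
  for (r in seq_len(nrow(accepted)))
    covered[accepted$start[r]:accepted$end[r]] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(!r$values)
  iv <- data.frame(from = pmax(1L, starts[keep] - as.integer(expand)),
                   to = pmin(L, ends[keep] + as.integer(expand)))
  iv[iv$to - iv$from + 1L >= min_width, , drop = FALSE]
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat(sprintf("domain_annotation '%s': %d ankyrin unit(s)\n",
              x$protein_id, x$ankyrin_count))
  if (nrow(x$segments)) print(x$segments)
  invisible(x)
}

#' Domain arrangement strings and their edit distance
#'
#' `arrangement_string()` returns the ordered domain-type tokens of an
#' annotation (e.g. 28 `ANK` tokens followed by `CHANNEL`).
#' `arrangement_distance()` is the Levenshtein edit distance between two
#' token sequences.
#'
#' @param annotation A `domain_annotation`, or a character vector of
#'   tokens.
#' @param a,b Annotations or token vectors.
#' @return `arrangement_string()`: character vector of tokens.
#'   `arrangement_distance()`: non-negative integer.
#' @export
arrangement_string <- function(annotation) {
  if (inherits(annotation, "domain_annotation"))
    annotation$segments$domain_type
  else as.character(annotation)
}

#' @rdname arrangement_string
#' @export
arrangement_distance <- function(a, b) {
  ta <- arrangement_string(a)
  tb <- arrangement_string(b)
  toks <- unique(c(ta, tb))
  if (length(toks) > 52) stop("too many distinct domain types", call. = FALSE)
  code <- stats::setNames(c(letters, LETTERS)[seq_along(toks)], toks)
  as.integer(utils::adist(paste0(code[ta], collapse = ""),
                          paste0(code[tb], collapse = "")))
}

#' Flag a fragmented TRP-N-like gene model
#'
#' Homologs of the long-repeat (TRP-N-like) family with fewer than
#' `min_repeats` counted ankyrin units correspond to fragmented gene
#' models; the rule applies only to that family.
#'
#' @param family Family verdict of the protein.
#' @param annotation A `domain_annotation` or an integer repeat count.
#' @param trpn_family Label of the long-repeat family the rule applies to.
#' @param min_repeats Boundary (default 27): a count of 27 or more is not
#'   flagged.
#' @return Logical.
#' @export
flag_fragmented <- function(family, annotation, trpn_family = "fam1",
                            min_repeats = 27) {
  count <- if (inherits(annotation, "domain_annotation"))
    annotation$ankyrin_count else as.integer(annotation)
  identical(family, trpn_family) && count < min_repeats
}

#' Write domain annotations as a BED-like TSV
#'
#' Coordinates in the file are 0-based half-open (BED convention);
#' in-memory annotations are 1-based inclusive.
#'
#' @param annotations List of `domain_annotation`s.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  rows <- lapply(annotations, function(a) {
    if (!nrow(a$segments)) return(NULL)
    data.frame(protein_id = a$protein_id,
               start = a$segments$start - 1L, end = a$segments$end,
               domain_type = a$segments$domain_type,
               bit_score = a$segments$bit_score, stringsAsFactors = FALSE)
  })
  write_tsv_report(do.call(rbind, rows), path,
                   meta = "coordinates are 0-based half-open")
  invisible(path)
}
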