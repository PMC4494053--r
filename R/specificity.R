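#' Physico-chemical conservation score per alignment column (0-11)
#'
#' A column of one repeated residue with no gaps scores 11 (perfect
#' conservation). Otherwise the score is the number (0-10) of
#' physico-chemical properties from the fixed 10-property table
#' (see [residue_properties()]) whose status is uniform across the
#' column: possessed by every residue, or possessed by none. A gap makes
#' every property status non-uniform, so any gapped column scores 0; a
#' column of only gaps has no score (`NA`).
#'
#' @param alignment Character matrix or named aligned strings.
#' @return Integer vector, one score per column (`NA` for all-gap
#'   columns).
#' @export
conservation_scores <- function(alignment) {
  aln <- as_alignment(alignment)
  props <- residue_properties()
  apply(aln, 2, function(col) {
    if (all(col == "-")) return(NA_integer_)
    if (any(col == "-")) return(0L)
    res <- unique(col)
    if (length(res) == 1) return(11L)
    have <- props[, res, drop = FALSE]
    sum(rowSums(have) == length(res) | rowSums(have) == 0)
  })
}

# integer-encode an alignment with gap as the 21st symbol
encode_with_gap <- function(aln) {
  symbols <- c(amino_acids(), "-")
  m <- matrix(match(aln, symbols), nrow(aln), ncol(aln))
  if (anyNA(m)) stop("alignment contains symbols outside the amino-acid alphabet",
                     call. = FALSE)
  dimnames(m) <- dimnames(aln)
  m
}

#' Two-group multi-Relief score per alignment column
#'
#' For every column, `mr = D_between - D_within`, where `D_between` is
#' the mean residue-mismatch indicator over all cross-group sequence
#' pairs and `D_within` the mean over all within-group pairs (both groups
#' pooled). Gaps count as a 21st symbol. High scores mark columns that
#' are conserved within groups but differ between them; `mr` lies in
#' `[-1, 1]`.
#'
#' @param alignment Character matrix; rows not named in `labels` (e.g.
#'   query sequences) are ignored.
#' @param labels Named character vector mapping row names to `"push"` or
#'   `"pull"`; both groups must be non-empty.
#' @return Numeric vector of per-column mR scores.
#' @export
mr_scores <- function(alignment, labels) {
  aln <- as_alignment(alignment)
  m <- encode_with_gap(aln[names(labels), , drop = FALSE])
  g1 <- which(labels == "push")
  g2 <- which(labels == "pull")
  if (!length(g1) || !length(g2))
    stop("both groups must be non-empty", call. = FALSE)
  mr_from_encoded(m, g1, g2)
}

# count-based all-pairs mismatch computation shared with the permutation
# test; g1/g2 are row indices into the encoded matrix
mr_from_encoded <- function(m, g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  C <- ncol(m)
  s_cross <- numeric(C)   # sum over symbols of c1 * c2
  s_within <- numeric(C)  # sum over symbols of c1*(c1-1) + c2*(c2-1)
  for (a in seq_len(21)) {
    c1 <- .colSums(m[g1, , drop = FALSE] == a, n1, C)
    c2 <- .colSums(m[g2, , drop = FALSE] == a, n2, C)
    s_cross <- s_cross + c1 * c2
    s_within <- s_within + c1 * (c1 - 1) + c2 * (c2 - 1)
  }
  d_between <- 1 - s_cross / (n1 * n2)
  n_within_pairs <- n1 * (n1 - 1) / 2 + n2 * (n2 - 1) / 2
  d_within <- if (n_within_pairs > 0) 1 - (s_within / 2) / n_within_pairs
              else 0
  d_between - d_within
}

#' Permutation z-test for per-column mR scores
#'
#' Group labels are shuffled `n_permutations` times;
#' `z = (mr_obs - mean_perm) / sd_perm` per column. Columns with zero
#' permutation spread have no z score and are never significant. The
#' significant set keeps columns with `z > z_threshold` (strict,
#' one-sided).
#'
#' @param alignment Character matrix.
#' @param labels Push/pull labels of the group rows.
#' @param n_permutations At least 100 (default 1000).
#' @param z_threshold Default 3.
#' @param rng_seed Integer seed.
#' @return List: `mr` (observed), `z` (NA where undefined),
#'   `significant` (column indices, 1-based), `perm_mean`, `perm_sd`.
#' @export
permutation_z <- function(alignment, labels, n_permutations = 1000,
                          z_threshold = 3, rng_seed = 1) {
  stopifnot(n_permutations >= 100)
  aln <- as_alignment(alignment)
  m <- encode_with_gap(aln[names(labels), , drop = FALSE])
  g1 <- which(labels == "push")
  g2 <- which(labels == "pull")
  if (!length(g1) || !length(g2))
    stop("both groups must be non-empty", call. = FALSE)
  obs <- mr_from_encoded(m, g1, g2)
  withr_seed(rng_seed)
  n <- nrow(m)
  perm <- matrix(0, n_permutations, ncol(m))
  for (p in seq_len(n_permutations)) {
    sh <- sample.int(n)
    perm[p, ] <- mr_from_encoded(m, sh[seq_along(g1)],
                                 sh[length(g1) + seq_along(g2)])
  }
  mu <- colMeans(perm)
  sdev <- apply(perm, 2, stats::sd)
  z <- ifelse(sdev > 0, (obs - mu) / sdev, NA_real_)
  list(mr = obs, z = z,
       significant = significant_set(z, z_threshold),
       perm_mean = mu, perm_sd = sdev,
       n_permutations = as.integer(n_permutations))
}

# strict one-sided filter; NA z never significant
significant_set <- function(z, z_threshold) {
  which(!is.na(z) & z > z_threshold)
}

#' Completely disjunct columns among significant sites
#'
#' Keeps the significant columns whose observed push residue set and pull
#' residue set share no symbol; gaps count as a symbol for the
#' disjointness test.
#'
#' @param alignment Character matrix.
#' @param labels Push/pull labels of the group rows.
#' @param significant Column indices (1-based) to test.
#' @return data.frame: `column`, `push_set`, `pull_set` (sorted,
#'   collapsed), `disjunct`.
#' @export
disjunct_sites <- function(alignment, labels, significant) {
  aln <- as_alignment(alignment)
  push_rows <- names(labels)[labels == "push"]
  pull_rows <- names(labels)[labels == "pull"]
  out <- lapply(significant, function(j) {
    ps <- sort(unique(aln[push_rows, j]))
    ls <- sort(unique(aln[pull_rows, j]))
    data.frame(column = j,
               push_set = paste0(ps, collapse = ""),
               pull_set = paste0(ls, collapse = ""),
               disjunct = !length(intersect(ps, ls)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(out)) do.call(rbind, out)
         else data.frame(column = integer(0), push_set = character(0),
                         pull_set = character(0), disjunct = logical(0),
                         stringsAsFactors = FALSE)
  out
}

#' Classify query sequences against disjunct sites
#'
#' At each completely disjunct site a query's residue votes `"push"` if
#' it belongs to the push residue set, `"pull"` if it belongs to the pull
#' set, otherwise `"neither"` (a gap always votes `"neither"`). The
#' overall call is `"pull"` iff every site votes pull, `"push"` iff every
#' site votes push, otherwise `"ambiguous"`. Queries are never part of
#' the group statistics.
#'
#' @param sites data.frame from [disjunct_sites()] (only rows with
#'   `disjunct == TRUE` are used).
#' @param alignment Character matrix containing the query rows.
#' @param query_ids Row names of the queries.
#' @return List with `calls` (data.frame `query_id`, `call`) and `votes`
#'   (matrix queries x sites).
#' @export
classify_queries <- function(sites, alignment, query_ids) {
  aln <- as_alignment(alignment)
  sites <- sites[sites$disjunct, , drop = FALSE]
  votes <- matrix("neither", length(query_ids), nrow(sites),
                  dimnames = list(query_ids,
                                  if (nrow(sites)) sites$column else NULL))
  for (k in seq_len(nrow(sites))) {
    ps <- seq_chars(sites$push_set[k])
    ls <- seq_chars(sites$pull_set[k])
    for (q in query_ids) {
      r <- aln[q, sites$column[k]]
      votes[q, k] <- if (r == "-") "neither"
        else if (r %in% ps) "push"
        else if (r %in% ls) "pull"
        else "neither"
    }
  }
  call_of <- function(v) {
    if (length(v) && all(v == "pull")) "pull"
    else if (length(v) && all(v == "push")) "push"
    else "ambiguous"
  }
  calls <- data.frame(query_id = query_ids,
                      call = vapply(query_ids, function(q)
                        call_of(votes[q, ]), character(1)),
                      stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(calls = calls, votes = votes)
}

#' Full specificity report for a push/pull alignment
#'
#' Runs the conservation score, the mR score, the permutation z-test, the
#' complete-disjunctness filter and the query classification in one pass.
#'
#' @param alignment Character matrix (group rows plus optional query
#'   rows).
#' @param labels Push/pull labels of the group rows; query rows are
#'   excluded from all group statistics.
#' @param query_ids Optional query row names.
#' @param n_permutations,z_threshold,rng_seed See [permutation_z()].
#' @return A `specificity_report`: `columns` (per-column data.frame:
#'   `column`, `conservation`, `mr`, `z`, `significant`, `disjunct`,
#'   `push_set`, `pull_set`), `significant_sites`, `disjunct_sites`
#'   (column indices), `query_calls`, `votes`.
#' @export
specificity_report <- function(alignment, labels, query_ids = character(0),
                               n_permutations = 1000, z_threshold = 3,
                               rng_seed = 1) {
  aln <- as_alignment(alignment)
  cons <- conservation_scores(aln[names(labels), , drop = FALSE])
  pz <- permutation_z(aln, labels, n_permutations, z_threshold, rng_seed)
  sites <- disjunct_sites(aln, labels, pz$significant)
  disj <- sites$column[sites$disjunct]
  cols <- data.frame(column = seq_len(ncol(aln)),
                     conservation = cons, mr = pz$mr, z = pz$z,
                     significant = seq_len(ncol(aln)) %in% pz$significant,
                     disjunct = seq_len(ncol(aln)) %in% disj,
                     push_set = NA_character_, pull_set = NA_character_,
                     stringsAsFactors = FALSE)
  cols$push_set[sites$column] <- sites$push_set
  cols$pull_set[sites$column] <- sites$pull_set
  qc <- if (length(query_ids)) classify_queries(sites, aln, query_ids)
        else list(calls = data.frame(query_id = character(0),
                                     call = character(0)),
                  votes = NULL)
  structure(list(columns = cols,
                 significant_sites = pz$significant,
                 disjunct_sites = disj,
                 query_calls = qc$calls, votes = qc$votes,
                 n_permutations = pz$n_permutations,
                 z_threshold = z_threshold),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf(
    "specificity_report: %d columns, %d significant (z > %g), %d completely disjunct\n",
    nrow(x$columns), length(x$significant_sites), x$z_threshold,
    length(x$disjunct_sites)))
  if (nrow(x$query_calls)) {
    cat("query calls:\n")
    print(x$query_calls)
  }
  invisible(x)
}

#' Write a specificity report as TSV (column indices 0-based in files)
#'
#' @param report A `specificity_report`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_specificity_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- report$columns
  cols$column <- cols$column - 1L
  write_tsv_report(cols, file.path(dir, "columns.tsv"),
                   meta = "column indices are 0-based")
  write_tsv_report(report$query_calls, file.path(dir, "query_calls.tsv"))
  invisible(dir)
}
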