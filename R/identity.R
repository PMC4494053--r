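#' Percent identity of two sequences under global alignment
#'
#' Sequences are aligned globally with affine gaps (match +1, mismatch
#' -1, gap opening 10, gap extension 1, Needleman-Wunsch/Gotoh); identity
#' is 100 times the number of identical aligned residue pairs divided by
#' the number of alignment columns, excluding columns that fall inside a
#' terminal gap run of either sequence (length-difference tolerant).
#' Symmetric.
#'
#' @param a,b Protein sequences (non-empty).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  r <- nw_identity_cpp(encode_residues(a, "sequence a"),
                       encode_residues(b, "sequence b"))
  if (r$columns == 0) return(0)
  100 * r$matches / r$columns
}

# identity from an explicit pair of aligned strings (kept as the shared
# definition for cross-checks against an external aligner)
aligned_identity <- function(p, s) {
  pc <- seq_chars(p)
  sc <- seq_chars(s)
  keep <- !terminal_gap_mask(pc) & !terminal_gap_mask(sc)
  if (!any(keep)) return(0)
  100 * sum(pc[keep] == sc[keep] & pc[keep] != "-") / sum(keep)
}

terminal_gap_mask <- function(chars) {
  n <- length(chars)
  mask <- rep(FALSE, n)
  i <- 1L
  while (i <= n && chars[i] == "-") { mask[i] <- TRUE; i <- i + 1L }
  i <- n
  while (i >= 1L && chars[i] == "-") { mask[i] <- TRUE; i <- i - 1L }
  mask
}

#' Greedy centroid clustering at an identity threshold
#'
#' Sequences are processed in decreasing length order (ties by id); each
#' sequence joins the first existing centroid with identity strictly
#' above the threshold, otherwise it founds a new cluster. By
#' construction every member is more than `threshold` percent identical
#' to its centroid and all centroid pairs are at most `threshold` percent
#' identical; both properties are audited on the output before return.
#'
#' @param records Named character vector of sequences.
#' @param threshold Percent identity threshold (default 80).
#' @return List of `identity_cluster`s (each: `centroid_id`,
#'   `member_ids`, `identities_to_centroid`), with the audit summary in
#'   `attr(, "audit")`.
#' @export
greedy_cluster <- function(records, threshold = 80) {
  stopifnot(length(records) >= 1, !is.null(names(records)))
  ord <- order(-nchar(records), names(records))
  records <- records[ord]
  centroid_ids <- character(0)
  clusters <- list()
  enc <- lapply(records, encode_residues)
  for (id in names(records)) {
    joined <- FALSE
    if (length(centroid_ids)) {
      for (k in seq_along(centroid_ids)) {
        r <- nw_identity_cpp(enc[[centroid_ids[k]]], enc[[id]])
        ident <- if (r$columns == 0) 0 else 100 * r$matches / r$columns
        if (ident > threshold) {
          clusters[[k]]$member_ids <- c(clusters[[k]]$member_ids, id)
          clusters[[k]]$identities_to_centroid[[id]] <- ident
          joined <- TRUE
          break
        }
      }
    }
    if (!joined) {
      centroid_ids <- c(centroid_ids, id)
      clusters[[length(clusters) + 1L]] <- structure(
        list(centroid_id = id, member_ids = id,
             identities_to_centroid = stats::setNames(100, id)),
        class = "identity_cluster")
    }
  }
  audit <- audit_clusters(clusters, records, threshold)
  if (!audit$passed)
    stop("centroid clustering audit failed", call. = FALSE)
  structure(clusters, audit = audit, threshold = threshold)
}

# contract audit: member identities strictly above the threshold,
# centroid pairs at most the threshold
audit_clusters <- function(clusters, records, threshold) {
  member_id <- unlist(lapply(clusters, function(cl)
    cl$identities_to_centroid[setdiff(cl$member_ids, cl$centroid_id)]))
  cents <- vapply(clusters, `[[`, character(1), "centroid_id")
  cent_pairs <- numeric(0)
  if (length(cents) > 1) {
    for (i in seq_along(cents)[-1]) for (j in seq_len(i - 1)) {
      cent_pairs <- c(cent_pairs,
                      pairwise_identity(records[[cents[i]]],
                                        records[[cents[j]]]))
    }
  }
  list(passed = (!length(member_id) || all(member_id > threshold)) &&
         (!length(cent_pairs) || all(cent_pairs <= threshold)),
       min_member_identity = if (length(member_id)) min(member_id) else NA_real_,
       max_centroid_identity = if (length(cent_pairs)) max(cent_pairs)
                               else NA_real_)
}

#' Extract centroid records from identity clusters
#'
#' @param clusters Output of [greedy_cluster()].
#' @param records The clustered sequences.
#' @return Named character vector, one centroid per cluster in cluster
#'   order.
#' @export
extract_centroids <- function(clusters, records) {
  ids <- vapply(clusters, `[[`, character(1), "centroid_id")
  records[ids]
}

#' Write identity clusters as TSV (member, centroid, identity)
#'
#' @param clusters Output of [greedy_cluster()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  rows <- lapply(clusters, function(cl) {
    data.frame(member_id = cl$member_ids, centroid_id = cl$centroid_id,
               identity = unname(cl$identities_to_centroid[cl$member_ids]),
               stringsAsFactors = FALSE)
  })
  write_tsv_report(do.call(rbind, rows), path)
  invisible(path)
}
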