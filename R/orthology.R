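.best_hits <- function(hits) {
  # one row per query: minimal e-value, ties by maximal bitscore,
  # then lexicographically smallest subject id (deterministic)
  o <- order(hits$query_id, hits$e_value, -hits$bitscore, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Reciprocal best hits between two gene sets
#'
#' A pair (a, b) is reported iff b is a's best subject in the forward
#' table and a is b's best subject in the reverse table. "Best" is the
#' minimal e-value, ties broken by maximal bit score, then by
#' lexicographically smallest subject id, so the result is deterministic.
#' The output is symmetric in the two tables up to column naming.
#'
#' @param hits_ab forward hit table ([read_hit_table()] layout).
#' @param hits_ba reverse hit table.
#' @return data.frame with columns `id_a`, `id_b`, `percent_identity`
#'   (from the forward best hit), `e_value_ab`, `e_value_ba`, plus the
#'   forward best hit's subject interval (`s_start`, `s_end`) for
#'   downstream coverage computations.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  if (nrow(hits_ab) == 0 || nrow(hits_ba) == 0)
    stop("both hit tables must be non-empty")
  ba <- .best_hits(hits_ab)
  bb <- .best_hits(hits_ba)
  back <- setNames(bb$subject_id, bb$query_id)
  recip <- !is.na(back[ba$subject_id]) & back[ba$subject_id] == ba$query_id
  res <- ba[recip, , drop = FALSE]
  data.frame(id_a = res$query_id, id_b = res$subject_id,
             percent_identity = res$percent_identity,
             e_value_ab = res$e_value,
             e_value_ba = bb$e_value[match(res$subject_id, bb$query_id)],
             s_start = res$s_start, s_end = res$s_end,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ortholog hit ratio of a single hit
#'
#' Fraction of the orthologous reference gene covered by the hit's subject
#' interval: (s_end - s_start + 1) / ortholog_length, capped at 1. A proxy
#' for assembled-transcript completeness.
#'
#' @param s_start,s_end 1-based inclusive subject coordinates (vectors).
#' @param ortholog_length length of the reference ortholog (recycled).
#' @return numeric vector of ratios in [0, 1].
#' @export
ortholog_hit_ratio <- function(s_start, s_end, ortholog_length) {
  if (any(ortholog_length <= 0))
    stop("ortholog_length must be positive")
  lo <- pmin(s_start, s_end); hi <- pmax(s_start, s_end)
  pmin(1, (hi - lo + 1) / ortholog_length)
}

#' Annotate ortholog pairs with their hit ratio
#'
#' @param pairs output of [reciprocal_best_hits()].
#' @param subject_lengths named vector: reference id -> length.
#' @return `pairs` with an `ohr` column.
#' @export
add_ohr <- function(pairs, subject_lengths) {
  L <- subject_lengths[pairs$id_b]
  if (anyNA(L))
    stop("missing subject length for: ",
         paste(head(pairs$id_b[is.na(L)]), collapse = ", "))
  pairs$ohr <- ortholog_hit_ratio(pairs$s_start, pairs$s_end, as.numeric(L))
  pairs
}

#' Transcriptome-integrity summary over ortholog pairs
#'
#' Restricts to pairs whose percent identity strictly exceeds
#' `identity_min` (completeness estimates are unreliable for divergent
#' pairs) and reports the share of those with an ortholog hit ratio of at
#' least `full_length_min`, along with an OHR histogram.
#'
#' @param pairs ortholog pairs carrying `ohr` and `percent_identity`.
#' @param identity_min strict lower bound on percent identity (default 90).
#' @param full_length_min OHR at or above which a transcript counts as
#'   full-length (default 0.8).
#' @param breaks histogram breaks over [0, 1].
#' @return list with `n_pairs_used`, `fraction_full_length` (NA, flagged,
#'   if no pair passes the identity filter), and `ohr_histogram`.
#' @export
integrity_summary <- function(pairs, identity_min = 90,
                              full_length_min = 0.8,
                              breaks = seq(0, 1, by = 0.1)) {
  stopifnot(!is.null(pairs$ohr), !is.null(pairs$percent_identity))
  used <- pairs[pairs$percent_identity > identity_min, , drop = FALSE]
  n <- nrow(used)
  if (n == 0) {
    return(list(n_pairs_used = 0L, fraction_full_length = NA_real_,
                flagged = TRUE, ohr_histogram = NULL))
  }
  h <- graphics::hist(pmin(used$ohr, 1), breaks = breaks, plot = FALSE)
  list(n_pairs_used = n,
       fraction_full_length = mean(used$ohr >= full_length_min),
       flagged = FALSE,
       ohr_histogram = setNames(h$counts,
                                paste0("(", head(breaks, -1), ",",
                                       breaks[-1], "]")))
}
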