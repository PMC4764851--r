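#' Round half away from zero
#'
#' Fixed-precision rounding with ties going up (0.005 -> 0.01), the
#' convention of repeat-summary tables, rather than R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # nudge compensates binary representation error (1.005 * 100 = 100.49999...)
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Filter a candidate repeat library for false positives
#'
#' Candidate repeats from de novo repeat discovery often capture ordinary
#' protein-coding sequence. A candidate is removed when it matches a
#' reference proteome or carries any annotated protein domain — unless one
#' of its domains is TE-related (reverse transcriptase, integrase,
#' transposase, ...), in which case it is re-included: the re-inclusion
#' rule overrides both removal rules. Candidates not strictly longer than
#' `min_length` are dropped regardless (too short for read mapping).
#'
#' @param candidates data.frame with columns `id`, `length` (or `sequence`,
#'   from which lengths are taken), `proteome_hit` (logical), and `domains`
#'   (list-column of domain ids, or ";"-separated strings).
#' @param te_domain_whitelist character vector of TE-related domain ids;
#'   defaults to the packaged list.
#' @param min_length strict lower length bound in nt (default 100).
#' @return the retained subset of `candidates`, with a `retained_by`
#'   column ("clean" or "te_domain").
#' @export
filter_repeat_library <- function(candidates,
                                  te_domain_whitelist = NULL,
                                  min_length = 100) {
  if (is.null(te_domain_whitelist))
    te_domain_whitelist <- unlist(load_config()$te_domain_whitelist)
  if (is.null(candidates$length)) {
    if (is.null(candidates$sequence))
      stop("candidates need a length or sequence column")
    candidates$length <- nchar(candidates$sequence)
  }
  doms <- candidates$domains
  if (!is.list(doms))
    doms <- strsplit(ifelse(is.na(doms), "", doms), ";", fixed = TRUE)
  doms <- lapply(doms, function(d) d[nzchar(d)])
  has_te_domain <- vapply(doms, function(d)
    length(intersect(d, te_domain_whitelist)) > 0, logical(1))
  has_any_domain <- lengths(doms) > 0
  clean <- !candidates$proteome_hit & !has_any_domain
  keep <- candidates$length > min_length & (clean | has_te_domain)
  out <- candidates[keep, , drop = FALSE]
  out$retained_by <- ifelse(has_te_domain[keep], "te_domain", "clean")
  out
}

.merge_bp <- function(begin, end, by) {
  # total bases covered, merging overlaps within each `by` stratum
  if (!length(begin)) return(0L)
  tot <- 0L
  for (grp in split(seq_along(begin), by)) {
    r <- IRanges::reduce(IRanges::IRanges(begin[grp], end[grp]))
    tot <- tot + sum(IRanges::width(r))
  }
  tot
}

#' Summarize repeat hits into per-class counts and masked bases
#'
#' Element counts are raw hit counts (unmerged). Per class (and per
#' class/subfamily), base-pair totals merge overlapping same-class hit
#' intervals within each transcript, so a twice-hit base counts once for
#' its class. `masked_bp` counts every base at most once across all
#' classes; where hits of different classes overlap, the base is attributed
#' to the class of the higher-scoring hit for the resolved per-class
#' breakdown (`class_bp_resolved`), while the plain per-class totals keep
#' each class's own merged intervals (and so may double-count rare
#' cross-class overlaps, as masking summary tables conventionally do).
#'
#' @param hits repeat-hit data.frame ([parse_repeatmasker_out()] layout).
#' @param scanned_bp total scanned bases (denominator of percentages).
#' @param transcript_lengths optional named vector; when supplied, hits on
#'   unknown transcripts or beyond a transcript's end are an error.
#' @return list with `per_class` (class, subfamily, n_elements, bp,
#'   pct), `class_bp_resolved`, `masked_bp`, `masked_pct`, `scanned_bp`.
#' @export
summarize_repeat_hits <- function(hits, scanned_bp,
                                  transcript_lengths = NULL) {
  stopifnot(scanned_bp > 0)
  if (!is.null(transcript_lengths)) {
    unknown <- setdiff(hits$query_id, names(transcript_lengths))
    if (length(unknown))
      stop("hits on unknown transcript(s): ",
           paste(head(unknown), collapse = ", "))
    if (any(hits$end > transcript_lengths[hits$query_id]))
      stop("hit extends beyond its transcript's length")
  }
  if (nrow(hits) == 0) {
    return(list(per_class = data.frame(class = character(),
                                       subfamily = character(),
                                       n_elements = integer(),
                                       bp = integer(), pct = numeric()),
                class_bp_resolved = numeric(0),
                masked_bp = 0L, masked_pct = 0, scanned_bp = scanned_bp))
  }
  # per class: merged within transcript+class
  cls_rows <- lapply(split(seq_len(nrow(hits)), hits$repeat_class),
                     function(i) {
    h <- hits[i, , drop = FALSE]
    top <- data.frame(class = h$repeat_class[1], subfamily = "",
                      n_elements = nrow(h),
                      bp = .merge_bp(h$begin, h$end, h$query_id),
                      stringsAsFactors = FALSE)
    subs <- NULL
    sf <- unique(h$subfamily[nzchar(h$subfamily)])
    if (length(sf)) {
      subs <- do.call(rbind, lapply(sf, function(s) {
        hs <- h[h$subfamily == s, , drop = FALSE]
        data.frame(class = h$repeat_class[1], subfamily = s,
                   n_elements = nrow(hs),
                   bp = .merge_bp(hs$begin, hs$end, hs$query_id),
                   stringsAsFactors = FALSE)
      }))
    }
    rbind(top, subs)
  })
  per_class <- do.call(rbind, cls_rows)
  rownames(per_class) <- NULL
  per_class$pct <- round_half_up(per_class$bp / scanned_bp * 100, 2)

  # masked bases: each base once; cross-class overlap -> higher score wins
  resolved <- setNames(numeric(length(unique(hits$repeat_class))),
                       sort(unique(hits$repeat_class)))
  masked <- 0L
  for (tx in unique(hits$query_id)) {
    h <- hits[hits$query_id == tx, , drop = FALSE]
    ir <- IRanges::IRanges(h$begin, h$end)
    bins <- IRanges::disjoin(ir)
    ov <- IRanges::findOverlaps(bins, ir)
    best_cls <- vapply(seq_along(bins), function(b) {
      cand <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == b]
      cand <- cand[order(-h$score[cand], h$repeat_class[cand])]
      h$repeat_class[cand[1]]
    }, character(1))
    w <- IRanges::width(bins)
    masked <- masked + sum(w)
    add <- tapply(w, best_cls, sum)
    resolved[names(add)] <- resolved[names(add)] + add
  }
  list(per_class = per_class, class_bp_resolved = resolved,
       masked_bp = masked,
       masked_pct = round_half_up(masked / scanned_bp * 100, 2),
       scanned_bp = scanned_bp)
}

#' Assemble a repeat-summary table with totals and percentages
#'
#' Builds the conventional masking summary layout from class-level (and
#' optional subfamily-level) element counts and base-pair totals: a
#' retroelement total (SINE + LINE + LTR), a total-interspersed row
#' (retroelements + DNA transposons + unclassified), and a percentage for
#' every row computed against the scanned length (rounded half-up to two
#' decimals). The overall masked percentage is computed from `masked_bp`,
#' which is supplied separately because cross-class overlap resolution
#' makes it less than the column sum.
#'
#' @param per_class data.frame with columns `class`, `subfamily` (empty
#'   string for class-level rows), `n_elements`, `bp`.
#' @param scanned_bp total scanned bases.
#' @param masked_bp total distinct masked bases.
#' @return data.frame with columns `row`, `n_elements`, `bp`, `pct`,
#'   including total rows, plus attributes `masked_bp`, `masked_pct`,
#'   `scanned_bp`.
#' @export
repeat_summary_table <- function(per_class, scanned_bp, masked_bp) {
  stopifnot(scanned_bp > 0, masked_bp >= 0, masked_bp <= scanned_bp)
  cls <- per_class[per_class$subfamily == "", , drop = FALSE]
  get <- function(cl, what) {
    i <- match(cl, cls$class)
    if (is.na(i)) 0 else cls[[what]][i]
  }
  pct <- function(bp) round_half_up(bp / scanned_bp * 100, 2)
  rows <- list()
  push <- function(name, n, bp)
    rows[[length(rows) + 1L]] <<- data.frame(
      row = name, n_elements = n, bp = bp, pct = pct(bp),
      stringsAsFactors = FALSE)
  sub_rows <- function(cl) {
    s <- per_class[per_class$class == cl & per_class$subfamily != "", ,
                   drop = FALSE]
    for (i in seq_len(nrow(s)))
      push(paste0("  ", s$subfamily[i]), s$n_elements[i], s$bp[i])
  }
  retro_n <- get("SINE", "n_elements") + get("LINE", "n_elements") +
    get("LTR", "n_elements") + get("Retroelement", "n_elements")
  retro_bp <- get("SINE", "bp") + get("LINE", "bp") + get("LTR", "bp") +
    get("Retroelement", "bp")
  push("Retroelements", retro_n, retro_bp)
  push("SINEs:", get("SINE", "n_elements"), get("SINE", "bp")); sub_rows("SINE")
  push("LINEs:", get("LINE", "n_elements"), get("LINE", "bp")); sub_rows("LINE")
  push("LTR elements:", get("LTR", "n_elements"), get("LTR", "bp")); sub_rows("LTR")
  push("DNA transposons", get("DNA", "n_elements"), get("DNA", "bp")); sub_rows("DNA")
  push("Unclassified:", get("Unclassified", "n_elements"),
       get("Unclassified", "bp"))
  interspersed_bp <- retro_bp + get("DNA", "bp") + get("Unclassified", "bp")
  push("Total interspersed repeats:", NA_integer_, interspersed_bp)
  push("Small RNA:", get("SmallRNA", "n_elements"), get("SmallRNA", "bp"))
  push("Satellites:", get("Satellite", "n_elements"), get("Satellite", "bp"))
  push("Simple repeats:", get("SimpleRepeat", "n_elements"),
       get("SimpleRepeat", "bp"))
  push("Low complexity:", get("LowComplexity", "n_elements"),
       get("LowComplexity", "bp"))
  out <- do.call(rbind, rows)
  attr(out, "scanned_bp") <- scanned_bp
  attr(out, "masked_bp") <- masked_bp
  attr(out, "masked_pct") <- round_half_up(masked_bp / scanned_bp * 100, 2)
  out
}

#' Ortholog-calibrated transposable-element transcription activity
#'
#' Cross-species TE expression cannot be compared on whole-transcriptome
#' TPM because transcriptome size and annotation quality differ. Instead,
#' the per-million scaling factor is computed on a reduced transcriptome of
#' unambiguous orthologs shared by the species compared: per sample,
#' S = sum over calibration genes of count/length, and each TE element's
#' activity is 1e6 * (count/length) / S. Class activity is the sum over
#' the class's elements, so values estimate TE transcription relative to a
#' common conserved gene set and are invariant to library scaling.
#'
#' @param counts transcripts x samples count matrix.
#' @param lengths named effective lengths.
#' @param te_classes named character vector: TE transcript id -> class.
#' @param calibration_ids ids of the calibration ortholog set; must be
#'   present in the matrix and disjoint from the TE ids.
#' @return list with `per_element` (TE x sample activity matrix),
#'   `per_class` (class x sample cumulative activity), and
#'   `calibration_set`.
#' @export
calibrated_te_activity <- function(counts, lengths, te_classes,
                                   calibration_ids) {
  counts <- as.matrix(counts)
  te_ids <- names(te_classes)
  if (length(intersect(te_ids, calibration_ids)))
    stop("calibration set must be disjoint from the TE set")
  missing <- setdiff(c(te_ids, calibration_ids), rownames(counts))
  if (length(missing))
    stop("transcripts absent from the count matrix: ",
         paste(head(missing), collapse = ", "))
  lengths <- lengths[rownames(counts)]
  rate <- counts / as.numeric(lengths)
  S <- colSums(rate[calibration_ids, , drop = FALSE])
  if (any(S == 0))
    stop("no calibration-gene expression in sample(s): ",
         paste(colnames(counts)[S == 0], collapse = ", "))
  per_element <- sweep(rate[te_ids, , drop = FALSE], 2, S, "/") * 1e6
  per_class <- rowsum(per_element, group = te_classes[te_ids])
  list(per_element = per_element, per_class = per_class,
       calibration_set = calibration_ids)
}
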