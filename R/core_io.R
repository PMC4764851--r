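#' @importFrom stats pchisq pnorm pt qt phyper rbinom rbeta rnbinom rlnorm
#'   rmultinom runif sd var cor hclust as.dist setNames
#' @importFrom utils read.table write.table head tail
#' @importFrom graphics hist
#' @importFrom methods is
NULL

# canonical repeat-class vocabulary used in summary tables
REPEAT_CLASSES <- c("SINE", "LINE", "LTR", "DNA", "Retroelement",
                    "Unclassified", "SmallRNA", "Satellite",
                    "SimpleRepeat", "LowComplexity")

#' Map raw RepeatMasker class labels onto the canonical vocabulary
#'
#' RepeatMasker writes class/family strings such as \code{"LINE/L2"} or
#' \code{"Low_complexity"}. This maps the class part (before the first
#' \code{"/"}) onto the fixed vocabulary used by [summarize_repeat_hits()].
#' The mapping is read from a packaged, editable table so that site-specific
#' labels can be added without touching code.
#'
#' @param raw_class character vector of raw class labels.
#' @param map optional data.frame with columns \code{raw} and \code{class}
#'   overriding the packaged table.
#' @return character vector over the canonical vocabulary; unmapped labels
#'   become \code{"Unclassified"}.
#' @export
map_repeat_class <- function(raw_class, map = NULL) {
  if (is.null(map)) {
    path <- system.file("extdata", "repeat_class_map.tsv", package = "transevo")
    map <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  stopifnot(all(c("raw", "class") %in% names(map)))
  idx <- match(raw_class, map$raw)
  out <- map$class[idx]
  out[is.na(out)] <- "Unclassified"
  out
}

#' Parse a RepeatMasker ".out" file
#'
#' Reads the whitespace-delimited RepeatMasker annotation dialect: three
#' header lines followed by one data line per hit. Complement-strand hits
#' ("C") have their query coordinates normalized so that begin <= end;
#' strand is not retained (transcript-level analyses here are strandless).
#' The class/family column is split on its first "/" into a class and a
#' subfamily, and the class is mapped onto the canonical vocabulary.
#'
#' @param lines character vector of file lines, or a file path of length 1
#'   that exists on disk.
#' @param class_map optional mapping table passed to [map_repeat_class()].
#' @return data.frame of repeat hits with columns \code{query_id},
#'   \code{begin}, \code{end}, \code{repeat_name}, \code{repeat_class},
#'   \code{subfamily}, \code{divergence_pct}, \code{score}.
#' @export
parse_repeatmasker_out <- function(lines, class_map = NULL) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  n_header <- min(3L, length(lines))
  out <- vector("list", length(lines))
  keep <- 0L
  rows <- list()
  for (i in seq_along(lines)) {
    if (i <= n_header) next
    ln <- trimws(lines[[i]])
    if (nchar(ln) == 0) next
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) < 14)
      stop(sprintf("malformed RepeatMasker line %d: expected >= 14 columns, got %d",
                   i, length(f)))
    score <- suppressWarnings(as.numeric(f[1]))
    div <- suppressWarnings(as.numeric(f[2]))
    qbeg <- suppressWarnings(as.integer(f[6]))
    qend <- suppressWarnings(as.integer(f[7]))
    if (any(is.na(c(score, div, qbeg, qend))))
      stop(sprintf("malformed RepeatMasker line %d: non-numeric score/divergence/coordinate", i))
    cls <- strsplit(f[11], "/", fixed = TRUE)[[1]]
    keep <- keep + 1L
    rows[[keep]] <- data.frame(
      query_id = f[5],
      begin = min(qbeg, qend), end = max(qbeg, qend),
      repeat_name = f[10],
      raw_class = cls[1],
      subfamily = if (length(cls) > 1) paste(cls[-1], collapse = "/") else "",
      divergence_pct = div,
      score = score,
      stringsAsFactors = FALSE
    )
  }
  if (keep == 0L) {
    res <- data.frame(query_id = character(), begin = integer(), end = integer(),
                      repeat_name = character(), repeat_class = character(),
                      subfamily = character(), divergence_pct = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
    return(res)
  }
  res <- do.call(rbind, rows[seq_len(keep)])
  res$repeat_class <- map_repeat_class(res$raw_class, map = class_map)
  res$raw_class <- NULL
  res[, c("query_id", "begin", "end", "repeat_name", "repeat_class",
          "subfamily", "divergence_pct", "score")]
}

#' Write repeat hits in the RepeatMasker ".out" dialect
#'
#' Emits three header lines and one data line per hit, suitable for
#' re-parsing with [parse_repeatmasker_out()]. Columns not represented in
#' the hit table (deletion/insertion percentages, repeat coordinates, hit
#' id) are written as zeros or dots.
#'
#' @param hits data.frame as returned by [parse_repeatmasker_out()].
#' @param path output file path, or NULL to return the lines.
#' @return invisibly, the character vector of lines written.
#' @export
write_repeatmasker_out <- function(hits, path = NULL) {
  hdr <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "")
  classfam <- ifelse(nchar(hits$subfamily) > 0,
                     paste(hits$repeat_class, hits$subfamily, sep = "/"),
                     hits$repeat_class)
  body <- sprintf("%6.0f %5.1f  0.0  0.0  %s %8d %8d (0) + %s %s 1 100 (0) %d",
                  hits$score, hits$divergence_pct, hits$query_id,
                  hits$begin, hits$end, hits$repeat_name, classfam,
                  seq_len(nrow(hits)))
  lines <- c(hdr, body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a 12-column tabular hit file
#'
#' Reads the standard 12-column tab-separated pairwise-hit format (query,
#' subject, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, e-value, bit score). Lines starting
#' with "#" are skipped.
#'
#' @param lines character vector of file lines, or an existing file path.
#' @return data.frame of hit records in canonical column order.
#' @export
read_hit_table <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  cols <- c("query_id", "subject_id", "percent_identity", "aln_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "e_value", "bitscore")
  data_lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(data_lines) == 0) {
    df <- as.data.frame(setNames(rep(list(character(0)), 12), cols),
                        stringsAsFactors = FALSE)
    num <- cols[c(3:12)]
    for (nm in num) df[[nm]] <- numeric(0)
    return(df)
  }
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12)) {
    bad <- which(nc != 12)[1]
    stop(sprintf("hit table line %d has %d columns, expected 12", bad, nc[bad]))
  }
  m <- do.call(rbind, parts)
  df <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                   stringsAsFactors = FALSE)
  numcols <- as.data.frame(lapply(3:12, function(j) as.numeric(m[, j])))
  names(numcols) <- cols[3:12]
  if (anyNA(numcols))
    stop("hit table contains non-numeric values in numeric columns")
  df <- cbind(df, numcols)
  intcols <- c("aln_length", "mismatches", "gap_opens",
               "q_start", "q_end", "s_start", "s_end")
  for (nm in intcols) df[[nm]] <- as.integer(df[[nm]])
  df
}

#' Write a 12-column tabular hit file
#' @param hits data.frame as returned by [read_hit_table()].
#' @param path output path or NULL to return lines.
#' @return invisibly, the lines written.
#' @export
write_hit_table <- function(hits, path = NULL) {
  lines <- apply(hits, 1, function(r) paste(trimws(r), collapse = "\t"))
  lines <- as.character(lines)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over Biostrings that returns either a nucleotide or
#' amino-acid string set and enforces unique, non-empty ids.
#'
#' @param path FASTA file.
#' @param alphabet "dna" or "aa".
#' @return a \code{DNAStringSet} or \code{AAStringSet}.
#' @export
read_fasta <- function(path, alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  x <- if (alphabet == "dna") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  if (any(!nzchar(ids))) stop("empty sequence id in ", path)
  names(x) <- ids
  x
}

#' Write sequences to a FASTA file
#' @param x an XStringSet or named character vector.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path)
}

#' Default analysis thresholds
#'
#' Loads the packaged declarative configuration holding every tunable
#' threshold of the pipeline (e-value cutoffs, identity filters, fold-change
#' and p-value criteria, repeat-library length minimum, Grubbs alpha, ...).
#' A user file can override any subset of keys.
#'
#' @param path optional YAML file whose keys override the defaults.
#' @return named list of thresholds.
#' @export
load_config <- function(path = NULL) {
  def <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                     package = "transevo"))
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    def[names(user)] <- user
  }
  def
}
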