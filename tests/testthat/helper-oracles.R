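# Independent brute-force oracles used across the suite. These stay
# deliberately naive: enumeration and counting, never calling the package
# code paths they check.

# best subject per query by exhaustive scan (min e-value, max bitscore,
# lexicographic subject)
oracle_best_hit <- function(hits, query) {
  h <- hits[hits$query_id == query, , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(h))) {
    if (is.null(best)) { best <- h[i, ]; next }
    if (h$e_value[i] < best$e_value ||
        (h$e_value[i] == best$e_value && h$bitscore[i] > best$bitscore) ||
        (h$e_value[i] == best$e_value && h$bitscore[i] == best$bitscore &&
         h$subject_id[i] < best$subject_id))
      best <- h[i, ]
  }
  best
}

# upper-tail hypergeometric p by exhaustive enumeration over all C(N, k)
# draws from an urn with m annotated among N
oracle_hyper_upper <- function(q, m, N, k) {
  draws <- utils::combn(N, k)
  ann <- seq_len(m)
  hits <- apply(draws, 2, function(d) sum(d %in% ann))
  mean(hits >= q)
}

# per-site relative-rate classification by explicit case analysis
oracle_rrt_counts <- function(s1, s2, so, resolved) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  o <- strsplit(so, "")[[1]]
  m1 <- 0L; m2 <- 0L; used <- 0L
  for (i in seq_along(a)) {
    if (!(resolved(a[i]) && resolved(b[i]) && resolved(o[i]))) next
    used <- used + 1L
    if (a[i] != b[i] && b[i] == o[i]) m1 <- m1 + 1L
    if (b[i] != a[i] && a[i] == o[i]) m2 <- m2 + 1L
  }
  list(m1 = m1, m2 = m2, n_used = used)
}

aa_resolved <- function(ch) !(ch %in% c("-", ".", "*", "X", "B", "Z",
                                        "J", "U", "O"))

# average synonymous/non-synonymous differences over substitution orders
# between two codons, enumerating orders explicitly
oracle_codon_paths <- function(c1, c2, skip_stops = TRUE) {
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  orders <- if (length(pos) <= 1) list(pos) else
    asplit(do.call(rbind, lapply(
      combinat_perms(length(pos)), function(p) pos[p])), 1)
  res <- NULL
  for (ord in orders) {
    cur <- c1; sdiff <- 0; ndiff <- 0; ok <- TRUE
    for (j in ord) {
      nxt <- cur; substr(nxt, j, j) <- substr(c2, j, j)
      if (gc[[nxt]] == "*" && skip_stops) { ok <- FALSE; break }
      if (gc[[nxt]] == gc[[cur]]) sdiff <- sdiff + 1 else ndiff <- ndiff + 1
      cur <- nxt
    }
    if (ok) res <- rbind(res, c(sdiff, ndiff))
  }
  colMeans(res)
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L)) {
    for (k in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = k)
  }
  out
}

# naive sliding-window motif scan
oracle_motif_count <- function(seq, alts2 = c("N", "D")) {
  # fixed 9-residue window: C [ND] P x x D P x C
  ch <- strsplit(seq, "")[[1]]
  pos <- integer(0)
  for (i in seq_len(max(0, length(ch) - 8))) {
    w <- ch[i:(i + 8)]
    if (w[1] == "C" && w[2] %in% alts2 && w[3] == "P" &&
        w[6] == "D" && w[7] == "P" && w[9] == "C")
      pos <- c(pos, i)
  }
  pos
}

# build a minimal RepeatMasker .out text from a hit spec
rm_out_lines <- function(rows) {
  hdr <- c("   SW  perc perc perc  query  position in query  matching repeat",
           "score  div. del. ins.  sequence begin end (left) repeat class/family begin end (left) ID",
           "")
  c(hdr, rows)
}

# 12-column tab-separated hit line
hit_line <- function(q, s, ident = 95, len = 100, mm = 2, gaps = 0,
                     qs = 1, qe = 100, ss = 1, se = 100,
                     ev = 1e-80, bits = 200) {
  paste(q, s, ident, len, mm, gaps, qs, qe, ss, se,
        format(ev, scientific = TRUE), bits, sep = "\t")
}

make_hits <- function(...) {
  read_hit_table(c(...))
}
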