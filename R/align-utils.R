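## Shared alignment machinery: reverse complement, substitution matrices,
## exact k-mer seed hits with diagonal clustering, and windowed local
## alignment of a query against a large target.

#' Reverse complement of DNA strings
#' @param x character vector of DNA (`A,C,G,T,N`).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Substitution matrix over ACGTN.  N columns are scored neutrally (0
## against everything, including N) so that alignments pass straight
## through masked regions instead of converting them into gaps; this keeps
## N-columns identifiable in downstream SNP/N classification.
sub_matrix <- function(match = 2, mismatch = -2, n_score = 0) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m) <- match
  m["N", ] <- n_score
  m[, "N"] <- n_score
  m
}

## Exact k-mer matches between a query string and a target string.
## Returns data.table(q_start, t_start) of 1-based k-mer start positions.
## K-mers containing N are skipped on both sides.
seed_hits <- function(query, target, k = 16) {
  qn <- nchar(query); tn <- nchar(target)
  if (qn < k || tn < k) {
    return(data.table(q_start = integer(), t_start = integer()))
  }
  qs <- 1:(qn - k + 1L)
  ts <- 1:(tn - k + 1L)
  qk <- substring(query, qs, qs + k - 1L)
  tk <- substring(target, ts, ts + k - 1L)
  qok <- !grepl("N", qk, fixed = TRUE)
  tok <- !grepl("N", tk, fixed = TRUE)
  qdt <- data.table(kmer = qk[qok], q_start = qs[qok])
  tdt <- data.table(kmer = tk[tok], t_start = ts[tok])
  merge(qdt, tdt, by = "kmer", allow.cartesian = TRUE)[, .(q_start, t_start)]
}

## Cluster seed hits lying on nearby diagonals (t_start - q_start) into
## candidate loci.  `band` tolerates small indels; `max_gap` is the largest
## along-diagonal gap bridged within one cluster.  Returns a data.table
## with one row per cluster: q_lo, q_hi, t_lo, t_hi (1-based inclusive,
## k-mer spans included), n_seeds.
cluster_seeds <- function(hits, k, band = 20, max_gap = 2000) {
  if (nrow(hits) == 0) return(hits[, .(q_lo = integer())][0])
  h <- data.table::copy(hits)
  h[, diag_ := t_start - q_start]
  setorder(h, diag_, q_start)
  newgrp <- c(TRUE,
              abs(diff(h$diag_)) > band | diff(h$q_start) > max_gap)
  h[, grp := cumsum(newgrp)]
  h[, .(q_lo = min(q_start), q_hi = max(q_start) + k - 1L,
        t_lo = min(t_start), t_hi = max(t_start) + k - 1L,
        n_seeds = .N), by = grp][, grp := NULL][]
}

## K-mer position index of an assembly's sequences for repeated seeded
## searches: keyed data.table (kmer, seq_name, t_start).
target_kmer_index <- function(assembly, k = 16) {
  tabs <- lapply(names(assembly$seqs), function(nm) {
    s <- assembly$seqs[[nm]]
    L <- nchar(s)
    if (L < k) return(NULL)
    st <- 1:(L - k + 1L)
    km <- substring(s, st, st + k - 1L)
    ok <- !grepl("N", km, fixed = TRUE)
    data.table(kmer = km[ok], seq_name = nm, t_start = st[ok])
  })
  dt <- rbindlist(tabs)
  setkey(dt, kmer)
  structure(list(k = as.integer(k), table = dt), class = "TargetIndex")
}

## Best local alignments of `query` against every sequence of `assembly`,
## on both strands.  Seeds each candidate locus by exact k-mers (via a
## prebuilt or on-the-fly `target_kmer_index`), then runs a Smith-Waterman
## on the padded target window.  Returns a data.table of hits: seq_name,
## start, end (0-based half-open, target), strand, identity (%), coverage
## (% of query aligned to determinate target bases), score; sorted by
## score.  `min_seeds` suppresses spurious windows.
local_hits <- function(query, assembly, k = 16, pad = 100,
                       match = 2, mismatch = -2,
                       gap_open = 10, gap_ext = 0.5,
                       min_seeds = 1, band = 20, max_gap = 2000,
                       index = NULL) {
  if (is.null(index)) index <- target_kmer_index(assembly, k)
  stopifnot(index$k == k)
  mat <- sub_matrix(match, mismatch)
  qlen <- nchar(query)
  strands <- c(`+` = query, `-` = revcomp(query))
  out <- list()
  for (st in names(strands)) {
    q <- strands[[st]]
    qn <- nchar(q)
    if (qn < k) next
    qs <- 1:(qn - k + 1L)
    qk <- substring(q, qs, qs + k - 1L)
    qok <- !grepl("N", qk, fixed = TRUE)
    qdt <- data.table(kmer = qk[qok], q_start = qs[qok])
    hits_all <- index$table[qdt, on = "kmer", nomatch = NULL,
                            allow.cartesian = TRUE]
    if (nrow(hits_all) == 0) next
    ## one candidate window per seed cluster, over all target sequences
    wins <- list()
    for (nm in unique(hits_all$seq_name)) {
      tseq <- assembly$seqs[[nm]]
      cl <- cluster_seeds(hits_all[seq_name == nm, .(q_start, t_start)],
                          k, band, max_gap)
      cl <- cl[cl$n_seeds >= min_seeds, ]
      if (nrow(cl) == 0) next
      cl[, `:=`(seq_name = nm,
                w_lo = pmax(1L, t_lo - pad - q_lo + 1L),
                w_hi = pmin(nchar(tseq), t_hi + pad + (qlen - q_hi)))]
      wins[[length(wins) + 1L]] <- cl
    }
    if (length(wins) == 0) next
    wins <- rbindlist(wins)
    winseq <- vapply(seq_len(nrow(wins)), function(i) {
      substr(assembly$seqs[[wins$seq_name[i]]], wins$w_lo[i], wins$w_hi[i])
    }, character(1))
    ## batched Smith-Waterman: windows as pattern set, query as subject
    al <- Biostrings::pairwiseAlignment(
      Biostrings::BStringSet(winseq), q, type = "local",
      substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_ext)
    nmat <- Biostrings::nmatch(al)
    nmis <- Biostrings::nmismatch(al)
    sc <- Biostrings::score(al)
    pa <- Biostrings::pattern(al)  # window side
    su <- Biostrings::subject(al)  # query side
    tr <- data.frame(start = Biostrings::start(pa), end = Biostrings::end(pa))
    qr <- data.frame(start = Biostrings::start(su), end = Biostrings::end(su))
    ## N columns: with the neutral N scoring, N bases never pair with gaps
    ## (gaps cost, N columns are free), so target Ns inside the aligned
    ## window range are aligned columns.  Queries are assumed N-free.
    n_cols <- vapply(seq_len(nrow(wins)), function(i) {
      w <- substr(winseq[i], tr$start[i], tr$end[i])
      nchar(w) - nchar(gsub("N", "", w, fixed = TRUE))
    }, integer(1))
    det <- nmat + nmis - n_cols
    keep <- which(det > 0)
    for (i in keep) {
      q0 <- qr$start[i]; q1 <- qr$end[i]
      out[[length(out) + 1L]] <- data.table(
        seq_name = wins$seq_name[i],
        start = wins$w_lo[i] + tr$start[i] - 2L,
        end = wins$w_lo[i] + tr$end[i] - 1L,
        strand = st,
        q_start = if (st == "+") q0 - 1L else qlen - q1,
        q_end = if (st == "+") q1 else qlen - q0 + 1L,
        identity = 100 * (nmat[i] - 0) / det[i],
        coverage = 100 * det[i] / qlen,
        score = sc[i])
    }
  }
  if (length(out) == 0) {
    return(data.table(seq_name = character(), start = integer(),
                      end = integer(), strand = character(),
                      q_start = integer(), q_end = integer(),
                      identity = numeric(), coverage = numeric(),
                      score = numeric()))
  }
  res <- rbindlist(out)
  setorder(res, -score)
  res
}

## Column classification of an alignment (equal-length aligned strings):
## matches/mismatches over determinate (non-gap, non-N) columns, N columns
## (either side N), gap columns.
alignment_column_stats <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  gap <- av == "-" | bv == "-"
  nn <- !gap & (av == "N" | bv == "N")
  det <- !gap & !nn
  list(matches = sum(det & av == bv),
       mismatches = sum(det & av != bv),
       n_cols = sum(nn),
       gap_cols = sum(gap),
       length = length(av))
}
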