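## Structural detection of full-length LTR retrotransposons: seeded
## repeat-pair finding with x-drop extension, motif/TSD boundary
## refinement, superfamily classification from internal domain order,
## quality filtering, solo-LTR discovery and size-class selection.

#' Detection parameters
#'
#' Defaults follow the standard structural-annotation parameterization for
#' plant LTR retrotransposons: exact seeds of 30 bp, LTR lengths 100-2000
#' bp, LTR start-to-start distances 3-25 kb, >= 85 % LTR similarity, TSDs
#' of 4-20 bp, `tgca` termini with at most one mismatch over the four
#' motif bases, a 60 bp boundary-adjustment vicinity, x-drop 5 and a
#' +2/-2/-3 match/mismatch/gap scoring scheme.
#'
#' @param seed_len exact seed length.
#' @param min_ltr,max_ltr LTR length bounds.
#' @param min_dist,max_dist bounds on the LTR start-to-start distance.
#' @param min_similarity minimum percent identity between the two LTRs.
#' @param tsd_min,tsd_max TSD length bounds.
#' @param motif terminal motif (element starts with the first two letters
#'   and ends with the last two).
#' @param motif_mismatch_max maximum mismatches over the four motif bases.
#' @param vicinity boundary adjustment radius, bases.
#' @param xdrop x-drop termination threshold for seed extension.
#' @param match,mismatch,gap_open,gap_ext alignment scoring.
#' @return A `DetectionParams` list.
#' @export
detection_params <- function(seed_len = 30, min_ltr = 100, max_ltr = 2000,
                             min_dist = 3000, max_dist = 25000,
                             min_similarity = 85, tsd_min = 4, tsd_max = 20,
                             motif = "tgca", motif_mismatch_max = 1,
                             vicinity = 60, xdrop = 5, match = 2,
                             mismatch = -2, gap_open = -3, gap_ext = -3) {
  stopifnot(min_ltr <= max_ltr, min_dist <= max_dist, nchar(motif) == 4)
  structure(list(seed_len = as.integer(seed_len), min_ltr = as.integer(min_ltr),
                 max_ltr = as.integer(max_ltr), min_dist = as.integer(min_dist),
                 max_dist = as.integer(max_dist),
                 min_similarity = min_similarity, tsd_min = as.integer(tsd_min),
                 tsd_max = as.integer(tsd_max), motif = toupper(motif),
                 motif_mismatch_max = as.integer(motif_mismatch_max),
                 vicinity = as.integer(vicinity), xdrop = xdrop,
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_ext = gap_ext),
            class = "DetectionParams")
}

#' Find candidate LTR pairs
#'
#' Exact seeds of `seed_len` between same-strand positions whose
#' separation is compatible with the inter-LTR distance window are
#' clustered per diagonal and x-drop extended under the scoring scheme
#' (extension stops when the running score falls `xdrop` below its
#' maximum).  A merged repeat pair becomes a candidate when both repeat
#' lengths lie in `[min_ltr, max_ltr]`, the start-to-start distance lies in
#' `[min_dist, max_dist]`, and the global similarity of the two repeats is
#' at least `min_similarity` percent.  Overlapping candidates are resolved
#' greedily by score ("overlaps best"; ties broken leftmost, then by
#' shorter element).
#'
#' @param assembly an [assembly()].
#' @param params a [detection_params()].
#' @return data.frame of candidates: `seq_name`, `start`, `end` (element
#'   span, 0-based half-open), `ltr5_start`, `ltr5_end`, `ltr3_start`,
#'   `ltr3_end`, `similarity` (percent), `score`.
#' @export
find_candidates <- function(assembly, params = detection_params()) {
  stopifnot(inherits(assembly, "Assembly"))
  out <- lapply(names(assembly$seqs), function(nm) {
    find_candidates_seq(nm, assembly$seqs[[nm]], params)
  })
  cands <- rbindlist(out)
  if (nrow(cands) == 0) {
    return(data.frame(seq_name = character(), start = integer(),
                      end = integer(), ltr5_start = integer(),
                      ltr5_end = integer(), ltr3_start = integer(),
                      ltr3_end = integer(), similarity = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  resolve_overlaps(as.data.frame(cands))
}

find_candidates_seq <- function(nm, seq, p) {
  k <- p$seed_len
  L <- nchar(seq)
  lo <- p$min_dist - p$max_ltr
  hi <- p$max_dist + p$max_ltr
  if (L < k + lo) return(NULL)
  starts <- 1:(L - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  dt <- data.table(kmer = kmers[ok], pos = starts[ok])
  rm(kmers)
  dupk <- dt[duplicated(kmer), unique(kmer)]
  if (length(dupk) == 0) return(NULL)
  dup <- dt[kmer %in% dupk]
  setkey(dup, kmer, pos)
  pairs <- dup[, pair_window(pos, lo, hi), by = kmer]
  if (nrow(pairs) == 0) return(NULL)
  pairs[, diag_ := p2 - p1]
  setorder(pairs, diag_, p1)
  ## merge co-diagonal seeds (band 0: substitution-divergent repeats stay
  ## on one diagonal; indel-shifted copies form adjacent clusters that the
  ## x-drop extension reconnects)
  newgrp <- c(TRUE, diff(pairs$diag_) != 0 | diff(pairs$p1) > p$max_ltr)
  pairs[, grp := cumsum(newgrp)]
  cl <- pairs[, .(s = min(p1), e = max(p1) + k - 1L, d = diag_[1]),
              by = grp]
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  res <- list()
  for (i in seq_len(nrow(cl))) {
    cand <- extend_repeat(x, cl$s[i], cl$e[i], cl$d[i], p)
    if (is.null(cand)) next
    ltr1 <- substr(seq, cand$s, cand$e)
    ltr2 <- substr(seq, cand$s + cl$d[i], cand$e + cl$d[i])
    al <- Biostrings::pairwiseAlignment(
      ltr1, ltr2, type = "global",
      substitutionMatrix = sub_matrix(p$match, p$mismatch),
      gapOpening = 0, gapExtension = abs(p$gap_ext))
    st <- alignment_column_stats(as.character(Biostrings::alignedPattern(al)),
                                 as.character(Biostrings::alignedSubject(al)))
    denom <- st$matches + st$mismatches + st$gap_cols
    if (denom == 0) next
    sim <- 100 * st$matches / denom
    if (sim < p$min_similarity) next
    res[[length(res) + 1L]] <- data.frame(
      seq_name = nm,
      start = cand$s - 1L, end = cand$e + cl$d[i],
      ltr5_start = cand$s - 1L, ltr5_end = cand$e,
      ltr3_start = cand$s + cl$d[i] - 1L, ltr3_end = cand$e + cl$d[i],
      similarity = sim, score = Biostrings::score(al),
      stringsAsFactors = FALSE)
  }
  if (length(res)) rbindlist(res) else NULL
}

## all index pairs (i, j>i) of a sorted position vector with separation in
## [lo, hi]
pair_window <- function(pos, lo, hi) {
  n <- length(pos)
  if (n < 2) return(list(p1 = integer(0), p2 = integer(0)))
  j1 <- findInterval(pos + lo - 1L, pos) + 1L
  j2 <- findInterval(pos + hi, pos)
  cnt <- pmax(0L, j2 - j1 + 1L)
  i <- rep.int(seq_len(n), cnt)
  if (length(i) == 0) return(list(p1 = integer(0), p2 = integer(0)))
  j <- j1[i] + (sequence(cnt) - 1L)
  list(p1 = pos[i], p2 = pos[j])
}

## X-drop extension of a co-diagonal seed cluster [s, e] x [s+d, e+d]
## (1-based inclusive) along the diagonal.  Returns refined 1-based repeat
## coordinates or NULL when constraints fail.
extend_repeat <- function(x, s, e, d, p) {
  L <- length(x)
  ## left extension
  max_left <- min(s - 1L, p$max_ltr - (e - s + 1L))
  if (max_left > 0) {
    i1 <- x[(s - 1L):(s - max_left)]
    i2 <- x[(s + d - 1L):(s + d - max_left)]
    s <- s - xdrop_steps(i1, i2, p)
  }
  ## right extension (repeat2 must not run off the sequence)
  max_right <- min(L - (e + d), p$max_ltr - (e - s + 1L))
  if (max_right > 0) {
    i1 <- x[(e + 1L):(e + max_right)]
    i2 <- x[(e + d + 1L):(e + d + max_right)]
    e <- e + xdrop_steps(i1, i2, p)
  }
  len <- e - s + 1L
  if (len < p$min_ltr || len > p$max_ltr) return(NULL)
  if (d < p$min_dist || d > p$max_dist) return(NULL)
  if (e >= s + d) return(NULL)  # repeats must not overlap
  list(s = s, e = e)
}

## number of extension steps before the x-drop rule fires
xdrop_steps <- function(a, b, p) {
  m <- a == b & a != "N"
  sc <- cumsum(ifelse(m, p$match, p$mismatch))
  stop_at <- which(cummax(sc) - sc > p$xdrop)[1]
  lim <- if (is.na(stop_at)) length(sc) else stop_at - 1L
  if (lim == 0) return(0L)
  best <- which.max(sc[1:lim])
  if (sc[best] <= 0) 0L else best
}

## greedy overlap resolution: score desc, then leftmost, then shorter
resolve_overlaps <- function(cands) {
  cands <- cands[order(-cands$score, cands$start, cands$end - cands$start), ]
  keep <- logical(nrow(cands))
  for (nm in unique(cands$seq_name)) {
    idx <- which(cands$seq_name == nm)
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in idx) {
      if (!any(cands$start[i] < taken_e & cands$end[i] > taken_s)) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, cands$start[i])
        taken_e <- c(taken_e, cands$end[i])
      }
    }
  }
  out <- cands[keep, , drop = FALSE]
  out <- out[order(out$seq_name, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Refine candidate boundaries by terminal motif and TSD
#'
#' Element termini are adjusted within `+/- vicinity` to find the position
#' pair with (a) the fewest mismatches to the terminal motif (at most
#' `motif_mismatch_max` over the four motif bases, else the candidate is
#' dropped) and (b) the longest flanking direct repeat (TSD) with length
#' in `[tsd_min, tsd_max]` immediately outside both adjusted termini; ties
#' are broken by the smallest total boundary shift.  Candidates at a
#' sequence edge keep `tsd = NA` and are flagged.
#'
#' @param candidates data.frame from [find_candidates()].
#' @param assembly the [assembly()] the candidates were found in.
#' @param params a [detection_params()].
#' @return The refined candidate data.frame with added columns `motif_ok`,
#'   `motif_mismatches`, `tsd` (NA when absent), `tsd_len`, `edge_flag`.
#' @export
refine_boundaries <- function(candidates, assembly,
                              params = detection_params()) {
  if (nrow(candidates) == 0) {
    candidates$motif_ok <- logical(0)
    candidates$motif_mismatches <- integer(0)
    candidates$tsd <- character(0)
    candidates$tsd_len <- integer(0)
    candidates$edge_flag <- logical(0)
    return(candidates)
  }
  out <- lapply(seq_len(nrow(candidates)), function(i) {
    refine_one(candidates[i, ], assembly, params)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- candidates[0, ]
    res$motif_ok <- logical(0); res$motif_mismatches <- integer(0)
    res$tsd <- character(0); res$tsd_len <- integer(0)
    res$edge_flag <- logical(0)
  }
  rownames(res) <- NULL
  res
}

refine_one <- function(cand, assembly, p) {
  seq <- assembly$seqs[[cand$seq_name]]
  L <- nchar(seq)
  x <- function(pos0) {
    ifelse(pos0 >= 0 & pos0 < L, substring(seq, pos0 + 1, pos0 + 1), "")
  }
  m1 <- substr(p$motif, 1, 1); m2 <- substr(p$motif, 2, 2)
  m3 <- substr(p$motif, 3, 3); m4 <- substr(p$motif, 4, 4)
  s0 <- cand$start; e0 <- cand$end
  a_off <- (-p$vicinity):(p$vicinity)
  b_off <- (-p$vicinity):(p$vicinity)
  sa <- s0 + a_off
  eb <- e0 + b_off
  sa <- sa[sa >= 0 & sa + 1 < L]
  eb <- eb[eb <= L & eb - 2 >= 0]
  if (length(sa) == 0 || length(eb) == 0) return(NULL)
  mm_start <- (x(sa) != m1) + (x(sa + 1) != m2)
  mm_end <- (x(eb - 2) != m3) + (x(eb - 1) != m4)
  grid <- expand.grid(si = seq_along(sa), ei = seq_along(eb))
  grid$mm <- mm_start[grid$si] + mm_end[grid$ei]
  grid <- grid[grid$mm <= p$motif_mismatch_max, , drop = FALSE]
  if (nrow(grid) == 0) return(NULL)  # motif requirement failed: drop
  grid$s <- sa[grid$si]; grid$e <- eb[grid$ei]
  grid <- grid[grid$e > grid$s, , drop = FALSE]
  if (nrow(grid) == 0) return(NULL)
  grid$shift <- abs(grid$s - s0) + abs(grid$e - e0)
  ## only minimal-motif-mismatch rows can win the lexicographic ranking,
  ## so the TSD search is restricted to them
  grid <- grid[grid$mm == min(grid$mm), , drop = FALSE]
  ## longest exact flanking direct repeat per (s, e)
  grid$tsd_len <- vapply(seq_len(nrow(grid)), function(i) {
    best_tsd_len(seq, grid$s[i], grid$e[i], p$tsd_min, p$tsd_max)
  }, integer(1))
  ## rank: motif mismatches, then TSD presence, then minimal shift, then
  ## TSD length -- presence-before-shift keeps a chance long direct repeat
  ## at a shifted position from beating the true boundary
  grid <- grid[order(grid$mm, grid$tsd_len == 0, grid$shift,
                     -grid$tsd_len), , drop = FALSE]
  g <- grid[1, ]
  cand$ltr5_start <- cand$ltr5_start + (g$s - s0)
  cand$ltr3_end <- cand$ltr3_end + (g$e - e0)
  cand$start <- g$s
  cand$end <- g$e
  cand$motif_ok <- g$mm == 0
  cand$motif_mismatches <- g$mm
  edge <- g$s - p$tsd_min < 0 || g$e + p$tsd_min > L
  cand$edge_flag <- edge
  if (g$tsd_len > 0) {
    cand$tsd <- substr(seq, g$s - g$tsd_len + 1, g$s)
    cand$tsd_len <- g$tsd_len
  } else {
    cand$tsd <- NA_character_
    cand$tsd_len <- 0L
  }
  cand
}

## longest exact direct repeat (length in [tmin, tmax]) immediately
## flanking [s, e) (0-based half-open); 0 when none
best_tsd_len <- function(seq, s, e, tmin, tmax) {
  L <- nchar(seq)
  for (t in tmax:tmin) {
    if (s - t < 0 || e + t > L) next
    left <- substr(seq, s - t + 1, s)
    right <- substr(seq, e + 1, e + t)
    if (left == right && !grepl("N", left, fixed = TRUE)) return(t)
  }
  0L
}

#' Classify candidate superfamily from internal domain order
#'
#' The order of `INT`, `RT`, `RH` along the element strand decides Copia
#' (`RLC`: INT-RT-RH) versus Gypsy (`RLG`: RT-RH-INT); with `RH` or `INT`
#' undetected the element stays unassigned (`RLX`).
#'
#' @param candidates candidate data.frame (refined).
#' @param domains data.frame of domain hits: `seq_name`, `start`, `end`,
#'   `strand`, `kind` (`INT`, `RT`, `RH`, `GENE`, `OTHER_TE`).  May be
#'   `NULL`.
#' @return `candidates` with an added `superfamily` column.
#' @export
classify_superfamily <- function(candidates, domains = NULL) {
  if (!is.null(domains)) {
    domains <- domains[!is.na(domains$start) & !is.na(domains$end), ,
                       drop = FALSE]
  }
  candidates$superfamily <- vapply(seq_len(nrow(candidates)), function(i) {
    e <- candidates[i, ]
    if (is.null(domains) || nrow(domains) == 0) return("RLX")
    d <- domains[domains$seq_name == e$seq_name &
                   domains$start >= e$start & domains$end <= e$end &
                   domains$kind %in% c("INT", "RT", "RH"), , drop = FALSE]
    if (nrow(d) == 0) return("RLX")
    strand <- names(sort(table(d$strand), decreasing = TRUE))[1]
    d <- d[order(d$start), ]
    kinds <- if (strand == "-") rev(d$kind) else d$kind
    if (!all(c("INT", "RH") %in% kinds)) return("RLX")
    ord <- paste(kinds[kinds %in% c("INT", "RT", "RH")], collapse = "-")
    if (ord == "INT-RT-RH") "RLC"
    else if (ord == "RT-RH-INT") "RLG"
    else "RLX"
  }, character(1))
  candidates
}

#' Tandem repeat coverage of a sequence
#'
#' Self-comparison dot-strip scan: for each period `p` in
#' `[min_period, max_period]` the sequence is compared to itself shifted by
#' `p`; maximal positive-scoring runs (match +1, mismatch -4, i.e. at
#' least 80 percent local identity) of length >= `max(p, min_run)` mark
#' `run + p` bases as tandem-covered.  `min_run` suppresses the short
#' chance self-matches of random sequence (a 20 bp floor keeps random DNA
#' near 0 percent while real arrays, thousands of bases in the elements
#' this filter targets, are unaffected).  Returns the covered fraction as
#' a percentage.
#'
#' @param seq DNA string.
#' @param min_period,max_period period range scanned (default 2-50).
#' @param min_identity identity threshold; the mismatch score is derived
#'   from it as `-min_identity / (1 - min_identity)`.
#' @param min_run minimum aligned run length, bases (default 20).
#' @return Percent of bases covered by tandem arrays.
#' @export
tandem_fraction <- function(seq, min_period = 2, max_period = 50,
                            min_identity = 0.8, min_run = 20) {
  L <- nchar(seq)
  if (L < 2 * min_period) return(0)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  covered <- logical(L)
  mis_score <- -min_identity / (1 - min_identity)
  for (p in min_period:min(max_period, L %/% 2)) {
    m <- x[1:(L - p)] == x[(p + 1):L] & x[1:(L - p)] != "N"
    sc <- ifelse(m, 1, mis_score)
    cs <- cumsum(sc)
    low <- cummin(c(0, cs[-length(cs)]))
    active <- cs - low > 0
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= max(p, min_run))) {
      covered[starts[j]:min(L, ends[j] + p)] <- TRUE
    }
  }
  100 * mean(covered)
}

#' Quality filter for detected elements
#'
#' An element passes iff all of: no `N` base inside its span; tandem
#' repeat percentage <= `tandem_inner_max` in the internal region and
#' <= `tandem_ltr_max` in each LTR; no `GENE` domain hit inside; no
#' duplicated TE domain kind anywhere in the element; strand consistency
#' between TE domain hits.  The report lists every failure reason per
#' element.
#'
#' @param elements refined candidate data.frame.
#' @param assembly the [assembly()].
#' @param domains optional domain-hit data.frame (see
#'   [classify_superfamily()]).
#' @param tandem_inner_max,tandem_ltr_max tandem coverage limits (percent).
#' @return List with `pass` (passing subset) and `report` (data.frame:
#'   per-element `pass` flag and comma-separated `reasons`).
#' @export
quality_filter <- function(elements, assembly, domains = NULL,
                           tandem_inner_max = 30, tandem_ltr_max = 35) {
  if (!is.null(domains)) {
    domains <- domains[!is.na(domains$start) & !is.na(domains$end), ,
                       drop = FALSE]
  }
  reasons <- vector("list", nrow(elements))
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    r <- character(0)
    span <- subseq0(assembly, e$seq_name, e$start, e$end)
    if (grepl("N", span, fixed = TRUE)) r <- c(r, "gap")
    inner <- subseq0(assembly, e$seq_name, e$ltr5_end, e$ltr3_start)
    if (tandem_fraction(inner) > tandem_inner_max) r <- c(r, "tandem_inner")
    ltr5 <- subseq0(assembly, e$seq_name, e$start, e$ltr5_end)
    ltr3 <- subseq0(assembly, e$seq_name, e$ltr3_start, e$end)
    if (tandem_fraction(ltr5) > tandem_ltr_max ||
        tandem_fraction(ltr3) > tandem_ltr_max) r <- c(r, "tandem_ltr")
    if (!is.null(domains) && nrow(domains) > 0) {
      d <- domains[domains$seq_name == e$seq_name &
                     domains$start >= e$start & domains$end <= e$end, ,
                   drop = FALSE]
      if (any(d$kind == "GENE")) r <- c(r, "gene_domain")
      te <- d[d$kind %in% c("INT", "RT", "RH", "OTHER_TE"), , drop = FALSE]
      if (anyDuplicated(te$kind)) r <- c(r, "duplicated_domain")
      if (length(unique(te$strand)) > 1) r <- c(r, "strand_inconsistent")
    }
    reasons[[i]] <- r
  }
  ok <- lengths(reasons) == 0
  report <- data.frame(
    seq_name = elements$seq_name, start = elements$start,
    end = elements$end, pass = ok,
    reasons = vapply(reasons, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  list(pass = elements[ok, , drop = FALSE], report = report)
}

#' Find solo-LTRs by consensus search
#'
#' Local-alignment hits of an LTR consensus with at least `min_coverage`
#' percent of the consensus aligned at `min_identity` percent identity, on
#' either strand, excluding hits that overlap a full-length element span
#' and hits with a second hit within `max_dist` on the same strand (which
#' would indicate an undetected LTR pair).  A TSD is annotated when a
#' 4-20 bp exact direct repeat flanks the hit.
#'
#' @param assembly an [assembly()].
#' @param ltr_consensus consensus LTR sequence (>= `min_ltr` bases).
#' @param full_length optional data.frame of full-length element spans
#'   (`seq_name`, `start`, `end`) to exclude.
#' @param min_identity,min_coverage acceptance thresholds, percent.
#' @param params a [detection_params()].
#' @return data.frame: `seq_name`, `start`, `end`, `strand`, `identity`,
#'   `coverage`, `tsd` (NA when absent).
#' @export
find_solo_ltrs <- function(assembly, ltr_consensus, full_length = NULL,
                           min_identity = 80, min_coverage = 80,
                           params = detection_params()) {
  if (nchar(ltr_consensus) < params$min_ltr) {
    stop("consensus shorter than min_ltr")
  }
  hits <- local_hits(toupper(ltr_consensus), assembly, k = 16, pad = 100,
                     match = params$match, mismatch = params$mismatch,
                     gap_open = 3, gap_ext = 3, min_seeds = 2)
  hits <- hits[hits$identity >= min_identity &
                 hits$coverage >= min_coverage, , drop = FALSE]
  hits <- as.data.frame(hits)
  if (nrow(hits) == 0) {
    return(data.frame(seq_name = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), coverage = numeric(),
                      tsd = character(), stringsAsFactors = FALSE))
  }
  ## deduplicate overlapping hits (same locus found from several windows)
  hits <- resolve_overlaps(hits)
  ## drop hits overlapping full-length spans
  if (!is.null(full_length) && nrow(full_length) > 0) {
    keep <- vapply(seq_len(nrow(hits)), function(i) {
      !any(full_length$seq_name == hits$seq_name[i] &
             full_length$start < hits$end[i] &
             full_length$end > hits$start[i])
    }, logical(1))
    hits <- hits[keep, , drop = FALSE]
  }
  ## drop hits that pair up within max_dist on the same strand
  if (nrow(hits) > 1) {
    drop <- logical(nrow(hits))
    for (i in seq_len(nrow(hits) - 1)) {
      for (j in (i + 1):nrow(hits)) {
        if (hits$seq_name[i] == hits$seq_name[j] &&
            hits$strand[i] == hits$strand[j] &&
            abs(hits$start[j] - hits$start[i]) <= params$max_dist) {
          drop[i] <- drop[j] <- TRUE
        }
      }
    }
    hits <- hits[!drop, , drop = FALSE]
  }
  hits$tsd <- vapply(seq_len(nrow(hits)), function(i) {
    t <- best_tsd_len(assembly$seqs[[hits$seq_name[i]]], hits$start[i],
                      hits$end[i], params$tsd_min, params$tsd_max)
    if (t > 0) {
      substr(assembly$seqs[[hits$seq_name[i]]],
             hits$start[i] - t + 1, hits$start[i])
    } else NA_character_
  }, character(1))
  rownames(hits) <- NULL
  hits[, c("seq_name", "start", "end", "strand", "identity", "coverage",
           "tsd")]
}

#' Select elements of a family size class
#'
#' @param elements element data.frame with `start`/`end`.
#' @param min_len,max_len length window, bases (defaults 8,500-9,000).
#' @param gappy_max_len relaxed upper bound used in gappy mode (default
#'   9,800, accommodating gap-inflated assemblies).
#' @param gappy use the relaxed upper bound.
#' @return The subset within the window.
#' @export
select_size_class <- function(elements, min_len = 8500, max_len = 9000,
                              gappy_max_len = 9800, gappy = FALSE) {
  len <- elements$end - elements$start
  hi <- if (gappy) gappy_max_len else max_len
  elements[len >= min_len & len <= hi, , drop = FALSE]
}

#' Full structural annotation pipeline
#'
#' [find_candidates()] + [refine_boundaries()] + [classify_superfamily()]
#' + [quality_filter()].
#'
#' @param assembly an [assembly()].
#' @param domains optional domain-hit data.frame.
#' @param params a [detection_params()].
#' @return List with `elements` (refined, classified candidates with a
#'   `quality_pass` column), `pass` (passing subset) and `report`.
#' @export
annotate_ltr <- function(assembly, domains = NULL,
                         params = detection_params()) {
  cands <- find_candidates(assembly, params)
  ref <- refine_boundaries(cands, assembly, params)
  ref <- classify_superfamily(ref, domains)
  qf <- quality_filter(ref, assembly, domains)
  ref$quality_pass <- qf$report$pass
  if (nrow(ref) > 0) ref$id <- sprintf("fl%04d", seq_len(nrow(ref)))
  list(elements = ref, pass = qf$pass, report = qf$report)
}

#' Read domain hits from TSV
#'
#' Expected columns: `seq_name`, `start`, `end`, `strand`, `kind`.
#' @param path TSV path.
#' @return data.frame of domain hits.
#' @export
read_domains_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write detected elements as GFF3
#'
#' @param elements refined element data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_elements_gff3 <- function(elements, path) {
  feats <- list()
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    id <- if (!is.null(e$id)) e$id else sprintf("fl%04d", i)
    sf <- if (!is.null(e$superfamily)) e$superfamily else "RLX"
    attrs <- sprintf("ID=%s;superfamily=%s;ltr_similarity=%.2f", id, sf,
                     e$similarity)
    if (!is.null(e$tsd) && !is.na(e$tsd)) {
      attrs <- paste0(attrs, ";tsd=", e$tsd)
    }
    feats[[length(feats) + 1L]] <- data.frame(
      seq_name = e$seq_name, type = "LTR_retrotransposon",
      start = e$start, end = e$end, strand = ".", attributes = attrs,
      stringsAsFactors = FALSE)
    feats[[length(feats) + 1L]] <- data.frame(
      seq_name = e$seq_name, type = "long_terminal_repeat",
      start = e$ltr5_start, end = e$ltr5_end, strand = ".",
      attributes = paste0("Parent=", id), stringsAsFactors = FALSE)
    feats[[length(feats) + 1L]] <- data.frame(
      seq_name = e$seq_name, type = "long_terminal_repeat",
      start = e$ltr3_start, end = e$ltr3_end, strand = ".",
      attributes = paste0("Parent=", id), stringsAsFactors = FALSE)
  }
  write_gff3(do.call(rbind, feats), path)
}
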