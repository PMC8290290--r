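## Junction-anchored tracking of elements between assembly versions and
## the normalized SNP/N divergence profile.

#' Extract terminal junctions of an element
#'
#' The 5' junction is 100 bp of flanking sequence plus the terminal 100 bp
#' of the element; the 3' junction is the terminal 100 bp of the element
#' plus 100 bp of flank.  Flanks are truncated at sequence edges (flagged).
#'
#' @param element one-row data.frame with `seq_name`, `start`, `end`.
#' @param assembly the source [assembly()].
#' @param flank,term flank and element-terminal lengths (default 100 each).
#' @return List with `five_prime`, `three_prime` (DNA strings),
#'   `five_truncated`, `three_truncated` flags, and the flank lengths used.
#' @export
extract_junctions <- function(element, assembly, flank = 100, term = 100) {
  s <- element$start; e <- element$end
  nm <- element$seq_name
  L <- assembly$lengths[[nm]]
  if (is.null(L)) stop("unknown sequence: ", nm)
  if (e - s < 2 * term) stop("element shorter than ", 2 * term, " bp")
  f5 <- min(flank, s)
  f3 <- min(flank, L - e)
  list(five_prime = subseq0(assembly, nm, s - f5, s + term),
       three_prime = subseq0(assembly, nm, e - term, e + f3),
       five_truncated = f5 < flank, three_truncated = f3 < flank,
       five_flank = f5, three_flank = f3)
}

#' Match element junctions in a target assembly
#'
#' For each element, both junctions are searched in the target with a
#' seeded local aligner; the best hit per junction must reach
#' `min_identity` percent identity over at least `min_coverage` percent of
#' the junction.  An element is accepted iff both junctions hit the same
#' target sequence in the same orientation and the observed span differs
#' from the expected span (element length plus flanks) by at most
#' `tolerance * expected`.  Elements whose best junction hit is tied are
#' reported `ambiguous` and not accepted.
#'
#' @param elements data.frame with `id`, `seq_name`, `start`, `end`.
#' @param source_assembly assembly the elements live in.
#' @param target_assembly assembly to search.
#' @param tolerance relative span tolerance (default 0.10).
#' @param min_identity,min_coverage junction hit thresholds, percent.
#' @param seed_k seed k-mer size of the search operator.
#' @return data.frame per element: `id`, `accepted`, `reason`, `target`,
#'   `strand`, `obs_start`, `obs_end` (matched span including flanks,
#'   0-based half-open), `observed_span`, `expected_span`.
#' @export
match_junctions <- function(elements, source_assembly, target_assembly,
                            tolerance = 0.10, min_identity = 90,
                            min_coverage = 80, seed_k = 16) {
  idx <- target_kmer_index(target_assembly, seed_k)
  out <- lapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    res <- data.frame(id = e$id, accepted = FALSE, reason = "",
                      target = NA_character_, strand = NA_character_,
                      obs_start = NA_integer_, obs_end = NA_integer_,
                      observed_span = NA_integer_,
                      expected_span = NA_integer_, stringsAsFactors = FALSE)
    j <- tryCatch(extract_junctions(e, source_assembly),
                  error = function(err) NULL)
    if (is.null(j)) { res$reason <- "element_too_short"; return(res) }
    h5 <- best_junction_hit(j$five_prime, target_assembly, seed_k,
                            min_identity, min_coverage, idx)
    h3 <- best_junction_hit(j$three_prime, target_assembly, seed_k,
                            min_identity, min_coverage, idx)
    if (is.character(h5)) { res$reason <- paste0("five_", h5); return(res) }
    if (is.character(h3)) { res$reason <- paste0("three_", h3); return(res) }
    if (h5$seq_name != h3$seq_name) { res$reason <- "different_sequence"; return(res) }
    if (h5$strand != h3$strand) { res$reason <- "opposite_orientation"; return(res) }
    expected <- (e$end - e$start) + j$five_flank + j$three_flank
    if (h5$strand == "+") {
      obs_s <- h5$start - h5$q_start
      obs_e <- h3$end + (nchar(j$three_prime) - h3$q_end)
    } else {
      obs_s <- h3$start - (nchar(j$three_prime) - h3$q_end)
      obs_e <- h5$end + h5$q_start
    }
    observed <- obs_e - obs_s
    res$target <- h5$seq_name; res$strand <- h5$strand
    res$obs_start <- as.integer(obs_s); res$obs_end <- as.integer(obs_e)
    res$observed_span <- as.integer(observed)
    res$expected_span <- as.integer(expected)
    if (observed <= 0 || abs(observed - expected) > tolerance * expected) {
      res$reason <- "span_mismatch"
      return(res)
    }
    res$accepted <- TRUE
    res
  })
  do.call(rbind, out)
}

## best local hit of a junction; returns a one-row data.frame, or a
## character reason ("no_hit" / "ambiguous")
best_junction_hit <- function(junction, target_assembly, seed_k,
                              min_identity, min_coverage, index = NULL) {
  h <- local_hits(junction, target_assembly, k = seed_k, pad = 50,
                  min_seeds = 1, index = index)
  h <- h[h$identity >= min_identity & h$coverage >= min_coverage, ,
         drop = FALSE]
  if (nrow(h) == 0) return("no_hit")
  if (nrow(h) > 1 && isTRUE(all.equal(h$score[1], h$score[2])) &&
      !(h$seq_name[1] == h$seq_name[2] && h$start[1] == h$start[2])) {
    return("ambiguous")
  }
  as.data.frame(h[1, ])
}

#' Align two element copies and classify columns
#'
#' Smith-Waterman local alignment with affine gaps.  A SNP is an aligned
#' column with two determinate, unequal bases; an N column is an aligned
#' column whose target base is `N`.  Positions are query-relative 0-based
#' offsets.
#'
#' @param query_elem,target_elem element sequences (non-empty).
#' @param match,mismatch,gap_open,gap_ext scoring (defaults +2/-2/-10/-0.5).
#' @return List: `aligned_query`, `aligned_target`, `snp_positions`,
#'   `n_positions`, `length` (query length).
#' @export
align_elements <- function(query_elem, target_elem, match = 2,
                           mismatch = -2, gap_open = 10, gap_ext = 0.5) {
  if (nchar(query_elem) == 0 || nchar(target_elem) == 0) {
    stop("empty input sequence")
  }
  al <- Biostrings::pairwiseAlignment(
    query_elem, target_elem, type = "local",
    substitutionMatrix = sub_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_ext)
  a <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  qpos <- Biostrings::start(Biostrings::pattern(al)) - 1L  # 0-based
  qcol <- qpos + cumsum(a != "-") - 1L  # query offset of each column
  aligned <- a != "-" & b != "-"
  npos <- qcol[aligned & b == "N"]
  snp <- qcol[aligned & b != "N" & a != "N" & a != b]
  list(aligned_query = paste(a, collapse = ""),
       aligned_target = paste(b, collapse = ""),
       snp_positions = snp, n_positions = npos,
       length = nchar(query_elem))
}

#' Aggregate alignments into a normalized divergence profile
#'
#' Each element's SNP and N positions are mapped to relative coordinates
#' on the query element, binned into 1,000 bins, aggregated over elements,
#' and summed into 10-bin windows (100 windows of 10 bins).
#'
#' @param alignments list of [align_elements()] results.
#' @param n_bins,bins_per_window profile resolution (defaults 1000, 10).
#' @return data.frame with 100 rows: `window` (1-based), `snp_count`,
#'   `n_count`.
#' @export
divergence_profile <- function(alignments, n_bins = 1000,
                               bins_per_window = 10) {
  if (length(alignments) == 0) stop("need at least one alignment")
  n_windows <- n_bins %/% bins_per_window
  snp <- integer(n_windows)
  nn <- integer(n_windows)
  for (al in alignments) {
    len <- al$length
    to_window <- function(pos) {
      bin <- pmin(n_bins - 1L, floor(pos / len * n_bins))
      bin %/% bins_per_window + 1L
    }
    if (length(al$snp_positions)) {
      t <- table(factor(to_window(al$snp_positions), levels = 1:n_windows))
      snp <- snp + as.integer(t)
    }
    if (length(al$n_positions)) {
      t <- table(factor(to_window(al$n_positions), levels = 1:n_windows))
      nn <- nn + as.integer(t)
    }
  }
  data.frame(window = 1:n_windows, snp_count = snp, n_count = nn)
}

#' Track elements from one assembly version to another
#'
#' [match_junctions()] + per-accepted-element local alignment +
#' [divergence_profile()].
#'
#' @param elements data.frame with `id`, `seq_name`, `start`, `end` in
#'   `from_assembly` coordinates.
#' @param from_assembly,to_assembly source and target assemblies.
#' @param tolerance relative span tolerance.
#' @return List: `matches` (per-element status), `alignments` (per
#'   accepted element), `profile` (100-window divergence profile, `NULL`
#'   when nothing was accepted).
#' @export
track_elements <- function(elements, from_assembly, to_assembly,
                           tolerance = 0.10) {
  matches <- match_junctions(elements, from_assembly, to_assembly,
                             tolerance = tolerance)
  alignments <- list()
  for (i in which(matches$accepted)) {
    e <- elements[elements$id == matches$id[i], ]
    q <- subseq0(from_assembly, e$seq_name, e$start, e$end)
    m <- matches[i, ]
    tl <- to_assembly$lengths[[m$target]]
    t0 <- max(0L, m$obs_start); t1 <- min(tl, m$obs_end)
    t <- subseq0(to_assembly, m$target, t0, t1)
    if (m$strand == "-") t <- revcomp(t)
    alignments[[m$id]] <- align_elements(q, t)
  }
  profile <- if (length(alignments)) divergence_profile(alignments) else NULL
  list(matches = matches, alignments = alignments, profile = profile)
}
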