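## Divergence-based insertion dating (Kimura 2-parameter), TSD decay
## arithmetic, and k-mer repetitivity scoring.

#' Kimura 2-parameter distance between aligned sequences
#'
#' Columns containing a gap (`-`) or `N` on either side are excluded.
#' With transition fraction `P` and transversion fraction `Q` over the
#' remaining sites,
#' `d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)`.
#'
#' @param aligned_a,aligned_b equal-length aligned strings.
#' @return List with `P`, `Q`, `d`, `sites_used`.
#' @examples
#' k2p_distance("ACGT", "ACGA")  # one transversion over four sites
#' @export
k2p_distance <- function(aligned_a, aligned_b) {
  a <- strsplit(toupper(aligned_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(aligned_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("aligned strings differ in length")
  det <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[det]; b <- b[det]
  n <- length(a)
  if (n == 0) stop("no usable sites (all columns gapped or ambiguous)")
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("K2P distance undefined: divergence saturated (1-2P-Q or 1-2Q <= 0)")
  }
  list(P = P, Q = Q, d = -0.5 * log(w1) - 0.25 * log(w2), sites_used = n)
}

#' Insertion age from LTR divergence
#'
#' The two LTRs are identical at insertion and diverge at `mu` per site
#' per year each, so a pairwise distance `d` corresponds to an age of
#' `d / (2 * mu)` years.
#'
#' @param d substitutions per site (>= 0).
#' @param mu substitution rate per site per year (default 1.3e-8).
#' @return Age in years.
#' @export
insertion_age <- function(d, mu = 1.3e-8) {
  if (mu <= 0) stop("mu must be positive")
  if (any(d < 0)) stop("d must be non-negative")
  d / (2 * mu)
}

#' Expected TSD mutation load at a given age
#'
#' The fraction of target-site duplications expected to carry at least one
#' mutation after `age_years` of neutral substitution over `tsd_len`
#' sites.  The `expected_count` model returns the expected substitution
#' count as a percentage (`100 * tsd_len * mu * age`); the `poisson` model
#' returns the probability of one or more hits
#' (`100 * (1 - exp(-tsd_len * mu * age))`).
#'
#' @param age_years element age, years.
#' @param mu substitution rate per site per year.
#' @param tsd_len TSD length, bases (default 5; one TSD copy's sites).
#' @param model `"expected_count"` or `"poisson"`.
#' @return Percentage.
#' @examples
#' tsd_decay_fraction(7e5)  # ~4.55, i.e. "approximately 5 %"
#' @export
tsd_decay_fraction <- function(age_years, mu = 1.3e-8, tsd_len = 5,
                               model = c("expected_count", "poisson")) {
  stopifnot(age_years >= 0)
  model <- match.arg(model)
  lambda <- tsd_len * mu * age_years
  switch(model,
         expected_count = 100 * lambda,
         poisson = 100 * (1 - exp(-lambda)))
}

#' Is a TSD pair perfect?
#'
#' @param left_tsd,right_tsd the two TSD copies (either may be `NA`).
#' @param tsd_len expected TSD length (default 5).
#' @return `TRUE` iff both present, byte-identical and of length
#'   `tsd_len`; `NA` (indeterminate) when a side is absent.
#' @export
tsd_perfect <- function(left_tsd, right_tsd, tsd_len = 5) {
  if (is.na(left_tsd) || is.na(right_tsd)) return(NA)
  identical(left_tsd, right_tsd) && nchar(left_tsd) == tsd_len
}

## global alignment of an LTR pair under the detection scoring scheme
align_ltr_pair <- function(ltr5, ltr3, params = detection_params()) {
  al <- Biostrings::pairwiseAlignment(
    ltr5, ltr3, type = "global",
    substitutionMatrix = sub_matrix(params$match, params$mismatch),
    gapOpening = 0, gapExtension = abs(params$gap_ext))
  list(a = as.character(Biostrings::alignedPattern(al)),
       b = as.character(Biostrings::alignedSubject(al)))
}

#' Date detected elements from their LTR divergence
#'
#' Each element's two LTRs are globally aligned and their K2P distance is
#' converted to an age.
#'
#' @param elements refined element data.frame (with LTR coordinates).
#' @param assembly the [assembly()].
#' @param mu substitution rate per site per year.
#' @param params a [detection_params()] (alignment scoring).
#' @return `elements` with added columns `P`, `Q`, `d`, `age_years`
#'   (`NA` on saturation or when no usable sites remain).
#' @export
date_elements <- function(elements, assembly, mu = 1.3e-8,
                          params = detection_params()) {
  n <- nrow(elements)
  P <- Q <- d <- age <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    e <- elements[i, ]
    ltr5 <- subseq0(assembly, e$seq_name, e$start, e$ltr5_end)
    ltr3 <- subseq0(assembly, e$seq_name, e$ltr3_start, e$end)
    al <- align_ltr_pair(ltr5, ltr3, params)
    k <- tryCatch(k2p_distance(al$a, al$b), error = function(err) NULL)
    if (!is.null(k)) {
      P[i] <- k$P; Q[i] <- k$Q; d[i] <- k$d
      age[i] <- insertion_age(k$d, mu)
    }
  }
  elements$P <- P; elements$Q <- Q; elements$d <- d
  elements$age_years <- age
  elements
}

#' Build a canonical k-mer frequency index
#'
#' Counts every k-mer of the assembly in canonical orientation (the
#' lexicographic minimum of the k-mer and its reverse complement); k-mers
#' containing `N` are skipped.
#'
#' @param assembly an [assembly()].
#' @param k k-mer size (default 20).
#' @return A `KmerIndex` list with `k` and a keyed data.table of
#'   `canon`/`freq`.
#' @export
build_kmer_index <- function(assembly, k = 20) {
  tabs <- lapply(assembly$seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(NULL)
    st <- 1:(L - k + 1L)
    km <- substring(s, st, st + k - 1L)
    km[!grepl("N", km, fixed = TRUE)]
  })
  km <- unlist(tabs, use.names = FALSE)
  if (length(km) == 0) stop("no k-mers (assembly shorter than k?)")
  rc <- revcomp(km)
  canon <- pmin(km, rc)
  dt <- data.table(canon = canon)[, .(freq = .N), by = canon]
  setkey(dt, canon)
  structure(list(k = as.integer(k), counts = dt), class = "KmerIndex")
}

#' Median k-mer frequency of an element
#'
#' Repetitivity of an element: the median index frequency over all its
#' k-mers (canonical orientation; k-mers containing `N` skipped).
#'
#' @param element_seq element DNA (length >= k).
#' @param index a [build_kmer_index()].
#' @return Median frequency.
#' @export
element_repetitivity <- function(element_seq, index) {
  stopifnot(inherits(index, "KmerIndex"))
  k <- index$k
  L <- nchar(element_seq)
  if (L < k) stop("element shorter than k = ", k)
  st <- 1:(L - k + 1L)
  km <- substring(toupper(element_seq), st, st + k - 1L)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (length(km) == 0) stop("no usable k-mers in element")
  query <- data.table(canon = pmin(km, revcomp(km)))
  f <- index$counts[query, on = "canon"]$freq
  f[is.na(f)] <- 0L
  median(f)
}

#' Histogram of insertion ages
#'
#' Counts per age bin, overall and per superfamily subset.
#'
#' @param ages numeric vector of ages (years); `NA` dropped.
#' @param superfamily optional parallel vector of `RLC`/`RLG`/`RLX`.
#' @param bin_width bin width in years (default 100,000).
#' @return data.frame: `bin_start`, `bin_end`, `all` and (when superfamily
#'   given) one column per superfamily.
#' @export
age_histogram <- function(ages, superfamily = NULL, bin_width = 1e5) {
  keep <- is.finite(ages)
  ages <- ages[keep]
  if (!is.null(superfamily)) superfamily <- superfamily[keep]
  if (length(ages) == 0) stop("no finite ages")
  bins <- floor(ages / bin_width)
  lev <- seq(0, max(bins))
  out <- data.frame(bin_start = lev * bin_width,
                    bin_end = (lev + 1) * bin_width,
                    all = as.integer(table(factor(bins, levels = lev))))
  if (!is.null(superfamily)) {
    for (sf in c("RLC", "RLG", "RLX")) {
      out[[sf]] <- as.integer(table(factor(bins[superfamily == sf],
                                           levels = lev)))
    }
  }
  out
}
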