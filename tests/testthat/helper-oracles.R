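# Independent brute-force oracles.  These re-derive expected values by
# the most direct method available (character loops, exhaustive
# enumeration, literal rule transcription) and deliberately share no code
# with the implementation under test.

# maximal N runs by a character scan
gaps_bruteforce <- function(seq, min_run = 1) {
  x <- strsplit(seq, "")[[1]]
  runs <- list()
  i <- 1
  while (i <= length(x)) {
    if (x[i] == "N") {
      j <- i
      while (j <= length(x) && x[j] == "N") j <- j + 1
      if (j - i >= min_run) {
        runs[[length(runs) + 1]] <- c(start = i - 1L, end = j - 1L)
      }
      i <- j
    } else i <- i + 1
  }
  runs
}

# Nx by trying every candidate threshold
nx_bruteforce <- function(lengths, x) {
  best <- NA
  for (L in sort(unique(lengths))) {
    if (sum(lengths[lengths >= L]) >= x / 100 * sum(lengths)) best <- L
  }
  best
}

# K2P by a per-column loop with explicit base-pair classification
k2p_bruteforce <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  ts_pairs <- c("AG", "GA", "CT", "TC")
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(av)) {
    if (!av[i] %in% c("A", "C", "G", "T")) next
    if (!bv[i] %in% c("A", "C", "G", "T")) next
    n <- n + 1L
    if (av[i] != bv[i]) {
      if (paste0(av[i], bv[i]) %in% ts_pairs) ts <- ts + 1L else tv <- tv + 1L
    }
  }
  if (n == 0) stop("no sites")
  P <- ts / n; Q <- tv / n
  list(P = P, Q = Q, d = -1 / 2 * log(1 - 2 * P - Q) - 1 / 4 * log(1 - 2 * Q),
       sites_used = n)
}

# exhaustive search over all monotone label matchings, same objective as
# the DP (site bonus 2, skip penalty 1, sizing penalty 1 at rel_err ==
# tol, transitions above tol forbidden)
labelmap_exhaustive <- function(q, r, tol = 0.10, site_bonus = 2,
                                skip_penalty = 1, sizing_penalty = 1) {
  best <- list(score = -Inf, pairs = NULL)
  recurse <- function(qi, ri, chain, score) {
    if (score > best$score && length(chain) > 0) {
      best <<- list(score = score, pairs = chain)
    }
    if (qi > length(q) || ri > length(r)) return()
    for (i in qi:length(q)) {
      for (j in ri:length(r)) {
        add <- site_bonus
        if (length(chain) > 0) {
          prev <- chain[[length(chain)]]
          dq <- q[i] - q[prev[1]]
          dr <- r[j] - r[prev[2]]
          rel <- abs(dq - dr) / max(dq, dr)
          if (rel > tol) next
          add <- add - sizing_penalty * rel / tol -
            skip_penalty * ((i - prev[1] - 1) + (j - prev[2] - 1))
        }
        recurse(i + 1, j + 1, c(chain, list(c(i, j))), score + add)
      }
    }
  }
  recurse(1, 1, list(), 0)
  best
}

# literal transcription of the gene-confidence prose rules
gene_conf_oracle <- function(complete, um_hit, um_cov_ok, up_hit, pt_hit,
                             stars) {
  cls <- if (complete && um_hit && um_cov_ok) "HC"
  else if (complete && !um_hit && up_hit && !pt_hit) "HC"
  else if (!complete && (um_hit || up_hit) && !pt_hit) "LC"
  else if (!um_hit && !up_hit && !pt_hit && complete) "LC"
  else if (!um_hit && complete && pt_hit) "REP"
  else "LC"
  if (cls == "LC" && !is.na(stars) && stars == 3) cls <- "HC"
  else if (cls == "HC" && !is.na(stars) && stars == 1) cls <- "LC"
  cls
}

# literal transcription of the scaffold retention rule
scaffold_oracle <- function(assigned, len, bubble, cov, unique_genes) {
  if (assigned) return(TRUE)
  len >= 50000 && !bubble && (cov >= 10 || unique_genes)
}
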