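## Synthetic genomes with planted LTR retrotransposons, solo-LTRs and
## genes of known truth, plus short-read-style degradation operators.
## Coordinates in all truth tables are 0-based half-open.

#' Define an LTR retrotransposon family model
#'
#' A family fixes the LTR length, internal length (or total element
#' length), TSD length, and the ordered internal protein-domain layout.
#' Element termini always carry the `TG...CA` motif and each LTR starts
#' with `TG` and ends with `CA`.
#'
#' @param name family identifier.
#' @param ltr_len LTR length in bases (100-2000 for detectability).
#' @param total_len total element length; `internal_len` is derived as
#'   `total_len - 2 * ltr_len` when not given directly.
#' @param internal_len internal region length (alternative to `total_len`).
#' @param tsd_len target-site duplication length, bases (default 5).
#' @param domain_order ordered internal domain kinds along the element
#'   strand, a subset/permutation of `INT`, `RT`, `RH`; `character(0)` for
#'   non-autonomous families without coding domains.
#' @param domain_len length of each synthetic domain footprint (default 300).
#' @return A `FamilyModel` list.
#' @export
ltr_family <- function(name, ltr_len, total_len = NULL, internal_len = NULL,
                       tsd_len = 5, domain_order = c("INT", "RT", "RH"),
                       domain_len = 300) {
  if (is.null(internal_len)) {
    if (is.null(total_len)) stop("give total_len or internal_len")
    internal_len <- total_len - 2L * ltr_len
  }
  total_len <- 2L * ltr_len + internal_len
  stopifnot(ltr_len >= 10, internal_len > 0,
            tsd_len >= 4, tsd_len <= 20,
            all(domain_order %in% c("INT", "RT", "RH")),
            !anyDuplicated(domain_order))
  if (length(domain_order) * domain_len > internal_len) {
    stop("internal region too short for the domain layout")
  }
  structure(list(name = name, ltr_len = as.integer(ltr_len),
                 internal_len = as.integer(internal_len),
                 total_len = as.integer(total_len),
                 tsd_len = as.integer(tsd_len),
                 domain_order = domain_order,
                 domain_len = as.integer(domain_len)),
            class = "FamilyModel")
}

#' BARE1-like default family models
#'
#' Two size classes mirroring the autonomous (8,950 bp, Copia domain order
#' `INT-RT-RH`) and non-autonomous (8,600 bp, no coding domains)
#' subfamilies of the most abundant barley retrotransspon family, both
#' with 5-bp TSDs.
#'
#' @return Named list of two [ltr_family()] models.
#' @export
bare1_families <- function() {
  list(
    BARE1_auto = ltr_family("BARE1_auto", ltr_len = 1800, total_len = 8950,
                            domain_order = c("INT", "RT", "RH")),
    BARE1_nonauto = ltr_family("BARE1_nonauto", ltr_len = 1800,
                               total_len = 8600,
                               domain_order = character(0))
  )
}

#' Simulate an i.i.d. background sequence
#'
#' @param length sequence length, bases (> 0).
#' @param gc GC fraction in (0, 1); default 0.44, a cereal-genome value.
#' @param seed RNG seed (reproducible output for a fixed seed).
#' @param name sequence name.
#' @return An [assembly()] with one sequence.
#' @export
simulate_background <- function(length, gc = 0.44, seed = NULL,
                                name = "chr1") {
  if (length <= 0) stop("length must be positive")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    s <- paste(sample(names(p), length, replace = TRUE, prob = p),
               collapse = "")
    assembly(setNames(s, name))
  })
}

## random DNA of given length (uniform base composition)
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Apply `n_sub` random substitution events with transition:transversion
## ratio kappa.  Sites are drawn with replacement and events applied
## sequentially (a site may be hit more than once and may revert), so the
## per-site process is the Markov chain that distance corrections such as
## K2P invert exactly.  `protect` are 1-based positions never mutated.
mutate_seq <- function(seq, n_sub, kappa = 2, protect = integer()) {
  L <- nchar(seq)
  avail <- setdiff(seq_len(L), protect)
  if (n_sub == 0 || length(avail) == 0) return(seq)
  pos <- sample(avail, n_sub, replace = TRUE)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  transit <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"),
             C = c("A", "G"), T = c("A", "G"))
  is_ts <- runif(n_sub) < kappa / (kappa + 1)
  for (i in seq_len(n_sub)) {
    b <- x[pos[i]]
    if (!b %in% c("A", "C", "G", "T")) next
    x[pos[i]] <- if (is_ts[i]) transit[[b]] else sample(tv[[b]], 1)
  }
  paste(x, collapse = "")
}

#' Synthesize a full-length element of a given age
#'
#' Builds an element whose two LTRs are identical copies of a common
#' ancestral LTR at insertion time; each LTR then independently receives
#' `Poisson(ltr_len * mu * age_years)` substitutions (transition to
#' transversion ratio `kappa`), so the expected pairwise LTR divergence is
#' about `2 * mu * age_years`.  The internal region is aged at the same
#' rate.  Both LTRs start with `TG` and end with `CA`; by default the four
#' motif bases are protected from mutation so that motif-based detection
#' tests the detector, not motif decay.
#'
#' @param family an [ltr_family()].
#' @param age_years insertion age, years (>= 0).
#' @param mu substitution rate per site per year (default 1.3e-8).
#' @param kappa transition:transversion ratio (default 2).
#' @param mutate_motif allow substitutions in the terminal TG/CA bases.
#' @param ancestor optional [family_ancestor()] (shared ancestral LTR and
#'   internal sequence); copies of one family must share an ancestor to be
#'   near-identical, as real family members are.  Drawn fresh when `NULL`.
#' @param seed RNG seed.
#' @return List with `seq` (element DNA, 5' LTR + internal + 3' LTR),
#'   `family`, `age_years`, `ltr_len`, `is_solo = FALSE`, `domains`
#'   (data.frame of kind/start/end offsets within the element), and
#'   `base_ltr` (the ancestral LTR, usable as a search consensus).
#' @export
synthesize_element <- function(family, age_years, mu = 1.3e-8, kappa = 2,
                               mutate_motif = FALSE, ancestor = NULL,
                               seed = NULL) {
  stopifnot(inherits(family, "FamilyModel"), age_years >= 0)
  with_seed(seed, {
    if (is.null(ancestor)) ancestor <- family_ancestor(family)
    l <- family$ltr_len
    base_ltr <- ancestor$ltr
    internal <- ancestor$internal
    protect <- if (mutate_motif) integer() else c(1L, 2L, l - 1L, l)
    lambda <- l * mu * age_years
    ltr5 <- mutate_seq(base_ltr, rpois(1, lambda), kappa, protect)
    ltr3 <- mutate_seq(base_ltr, rpois(1, lambda), kappa, protect)
    internal <- mutate_seq(internal,
                           rpois(1, family$internal_len * mu * age_years),
                           kappa)
    nd <- length(family$domain_order)
    domains <- if (nd == 0) {
      data.frame(kind = character(), start = integer(), end = integer())
    } else {
      centers <- l + round(seq_len(nd) / (nd + 1) * family$internal_len)
      data.frame(kind = family$domain_order,
                 start = as.integer(centers - family$domain_len %/% 2),
                 end = as.integer(centers + family$domain_len %/% 2),
                 stringsAsFactors = FALSE)
    }
    list(seq = paste0(ltr5, internal, ltr3), family = family$name,
         age_years = age_years, ltr_len = l, tsd_len = family$tsd_len,
         is_solo = FALSE, domains = domains, base_ltr = base_ltr)
  })
}

#' Ancestral sequence of a family
#'
#' The common ancestor from which all copies of a family descend: one LTR
#' (with `TG`/`CA` termini) and one internal sequence.
#'
#' @param family an [ltr_family()].
#' @param seed RNG seed.
#' @return List with `ltr` and `internal` character strings.
#' @export
family_ancestor <- function(family, seed = NULL) {
  stopifnot(inherits(family, "FamilyModel"))
  with_seed(seed, {
    list(ltr = paste0("TG", random_dna(family$ltr_len - 4L), "CA"),
         internal = random_dna(family$internal_len))
  })
}

#' Synthesize a solo-LTR of a given age
#'
#' A single LTR (the recombination product that removed one LTR and the
#' internal domain), aged by `mu * age_years` substitutions relative to the
#' family's ancestral LTR.
#'
#' @inheritParams synthesize_element
#' @param base_ltr optional ancestral LTR sequence (e.g. from a previously
#'   synthesized element of the same family) so that solos and elements
#'   share a consensus; a fresh one is drawn when `NULL`.
#' @return List as in [synthesize_element()] with `is_solo = TRUE`.
#' @export
synthesize_solo <- function(family, age_years, mu = 1.3e-8, kappa = 2,
                            base_ltr = NULL, mutate_motif = FALSE,
                            seed = NULL) {
  stopifnot(inherits(family, "FamilyModel"), age_years >= 0)
  with_seed(seed, {
    l <- family$ltr_len
    if (is.null(base_ltr)) base_ltr <- paste0("TG", random_dna(l - 4L), "CA")
    protect <- if (mutate_motif) integer() else c(1L, 2L, l - 1L, l)
    ltr <- mutate_seq(base_ltr, rpois(1, l * mu * age_years), kappa, protect)
    list(seq = ltr, family = family$name, age_years = age_years,
         ltr_len = l, tsd_len = family$tsd_len, is_solo = TRUE,
         domains = data.frame(kind = character(), start = integer(),
                              end = integer()),
         base_ltr = base_ltr)
  })
}

#' Plant elements into a genome with target-site duplication
#'
#' At each insertion site the `tsd_len` bases at the site are duplicated so
#' that identical TSD copies immediately flank the inserted element (or the
#' single LTR, for solos).  The genome grows by
#' `sum(element_length + tsd_len)`.
#'
#' @param genome an [assembly()].
#' @param elements list of [synthesize_element()] / [synthesize_solo()]
#'   objects.
#' @param positions optional data.frame with `seq_name` and `pos` (0-based
#'   insertion points in the input genome, one row per element); sampled
#'   uniformly with minimum spacing `min_gap` when `NULL`.
#' @param strands optional vector of `+`/`-` per element; sampled when
#'   `NULL`.
#' @param min_gap minimum spacing between sampled insertion points.
#' @param seed RNG seed (used only for sampling positions/strands).
#' @return List with `genome` (grown assembly) and `truth`, a list holding
#'   `elements` (data.frame: id, family, seq_name, start, end, strand,
#'   age_years, is_solo, tsd_seq, ltr5_start/end, ltr3_start/end) and
#'   `domains` (data.frame: element_id, kind, seq_name, start, end, strand)
#'   in the coordinates of the grown genome.
#' @export
plant_insertions <- function(genome, elements, positions = NULL,
                             strands = NULL, min_gap = 2000, seed = NULL) {
  n <- length(elements)
  if (n == 0) {
    return(list(genome = genome,
                truth = list(elements = empty_truth(), domains = empty_domains())))
  }
  with_seed(seed, {
    if (is.null(positions)) {
      positions <- sample_positions(genome, n, min_gap,
                                    max(vapply(elements, function(e)
                                      e$tsd_len, integer(1))))
    }
    if (is.null(strands)) strands <- sample(c("+", "-"), n, replace = TRUE)
    stopifnot(nrow(positions) == n, length(strands) == n)
    plant_at(genome, elements, positions, strands)
  })
}

empty_truth <- function() {
  data.frame(id = character(), family = character(), seq_name = character(),
             start = integer(), end = integer(), strand = character(),
             age_years = numeric(), is_solo = logical(),
             tsd_seq = character(), ltr5_start = integer(),
             ltr5_end = integer(), ltr3_start = integer(),
             ltr3_end = integer(), stringsAsFactors = FALSE)
}

empty_domains <- function() {
  data.frame(element_id = character(), kind = character(),
             seq_name = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

## Uniform insertion points with pairwise spacing >= min_gap, by the
## standard order-statistics construction (draw in the shrunken interval,
## then add back the mandatory gaps) -- no rejection loop needed.
sample_positions <- function(genome, n, min_gap, tsd_len) {
  lens <- genome$lengths
  nm <- sample(names(lens), n, replace = TRUE,
               prob = as.numeric(lens) / sum(as.numeric(lens)))
  counts <- table(nm)
  out <- list()
  for (s in names(counts)) {
    k <- as.integer(counts[[s]])
    L <- lens[[s]] - tsd_len
    slack <- L - (k - 1) * min_gap - k
    if (slack <= 0) {
      stop("could not place ", k, " insertions with min_gap = ", min_gap,
           " in sequence ", s, " (length ", lens[[s]], ")")
    }
    p <- sort(sample.int(slack, k)) + (0:(k - 1)) * min_gap
    out[[s]] <- data.frame(seq_name = s, pos = as.integer(p),
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

plant_at <- function(genome, elements, positions, strands) {
  seqs <- genome$seqs
  truth <- list()
  domains <- list()
  ord <- order(positions$seq_name, positions$pos)
  for (nm in unique(positions$seq_name[ord])) {
    idx <- ord[positions$seq_name[ord] == nm]
    s <- seqs[[nm]]
    L <- nchar(s)
    pieces <- character(0)
    cursor <- 0L   # 0-based position up to which the original is consumed
    offset <- 0L   # accumulated length added so far
    for (i in idx) {
      p <- positions$pos[i]
      el <- elements[[i]]
      t <- el$tsd_len
      if (p < 0 || p + t > L) stop("insertion position out of bounds: ", p)
      eseq <- if (strands[i] == "-") revcomp(el$seq) else el$seq
      elen <- nchar(eseq)
      tsd <- substr(s, p + 1L, p + t)
      pieces <- c(pieces, substr(s, cursor + 1L, p + t), eseq)
      cursor <- p  # suffix repeats the TSD
      start <- p + t + offset
      end <- start + elen
      if (el$is_solo) {
        l5 <- c(start, end); l3 <- c(NA_integer_, NA_integer_)
      } else if (strands[i] == "+") {
        l5 <- c(start, start + el$ltr_len)
        l3 <- c(end - el$ltr_len, end)
      } else {  # on '-', the element-5' LTR sits at the right end in genome coords
        l5 <- c(end - el$ltr_len, end)
        l3 <- c(start, start + el$ltr_len)
      }
      id <- sprintf("el%03d", i)
      truth[[length(truth) + 1L]] <- data.frame(
        id = id, family = el$family, seq_name = nm,
        start = start, end = end, strand = strands[i],
        age_years = el$age_years, is_solo = el$is_solo, tsd_seq = tsd,
        ltr5_start = l5[1], ltr5_end = l5[2],
        ltr3_start = l3[1], ltr3_end = l3[2], stringsAsFactors = FALSE)
      if (nrow(el$domains) > 0) {
        d <- el$domains
        if (strands[i] == "+") {
          ds <- start + d$start; de <- start + d$end
        } else {
          ds <- end - d$end; de <- end - d$start
        }
        domains[[length(domains) + 1L]] <- data.frame(
          element_id = id, kind = d$kind, seq_name = nm,
          start = as.integer(ds), end = as.integer(de),
          strand = strands[i], stringsAsFactors = FALSE)
      }
      offset <- offset + elen + t
    }
    pieces <- c(pieces, substr(s, cursor + 1L, L))
    seqs[[nm]] <- paste(pieces, collapse = "")
  }
  truth <- if (length(truth)) do.call(rbind, truth) else empty_truth()
  domains <- if (length(domains)) do.call(rbind, domains) else empty_domains()
  rownames(truth) <- rownames(domains) <- NULL
  list(genome = assembly(seqs), truth = list(elements = truth,
                                             domains = domains))
}

#' Designate truth genes in background regions
#'
#' Picks `n` non-overlapping N-free windows outside the planted element
#' spans and records their sequences verbatim as truth genes.  The genome
#' itself is unchanged (genes are background sequence, as in a real genome
#' where genes are part of the assembly, not inserted material).
#'
#' @param genome an [assembly()].
#' @param n number of genes.
#' @param gene_len gene length, bases (default 2000).
#' @param avoid data.frame of intervals (`seq_name`, `start`, `end`) that
#'   genes must not overlap, typically planted element spans.
#' @param seed RNG seed.
#' @return data.frame: id, seq_name, start, end, sequence.
#' @export
plant_genes <- function(genome, n, gene_len = 2000, avoid = NULL,
                        seed = NULL) {
  if (n == 0) {
    return(data.frame(id = character(), seq_name = character(),
                      start = integer(), end = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    placed <- list()
    taken <- if (is.null(avoid)) {
      data.frame(seq_name = character(), start = integer(), end = integer())
    } else {
      avoid[, c("seq_name", "start", "end")]
    }
    lens <- genome$lengths
    tries <- 0L
    while (length(placed) < n) {
      tries <- tries + 1L
      if (tries > 200L * n) {
        stop("insufficient free space to place ", n, " genes")
      }
      nm <- sample(names(lens), 1,
                   prob = as.numeric(lens) / sum(as.numeric(lens)))
      if (lens[[nm]] <= gene_len) next
      st <- sample.int(lens[[nm]] - gene_len, 1)
      en <- st + gene_len
      clash <- taken$seq_name == nm & taken$start < en & taken$end > st
      if (any(clash)) next
      sq <- subseq0(genome, nm, st, en)
      if (grepl("N", sq, fixed = TRUE)) next
      placed[[length(placed) + 1L]] <- data.frame(
        id = sprintf("gene%03d", length(placed) + 1L), seq_name = nm,
        start = st, end = en, sequence = sq, stringsAsFactors = FALSE)
      taken <- rbind(taken, data.frame(seq_name = nm, start = st, end = en))
    }
    out <- do.call(rbind, placed)
    rownames(out) <- NULL
    out
  })
}

#' Degradation profile for short-read-style assembly damage
#'
#' @param ltr_gap_rate probability per LTR of receiving an N run.
#' @param gap_len_mean,gap_len_max geometric mean / hard cap of N-run
#'   lengths, bases.
#' @param collapse_fraction fraction of near-identical copy pairs collapsed
#'   to a single copy.
#' @param collapse_min_identity minimum pairwise identity (fraction) for a
#'   pair to be a collapse candidate (default 0.99).
#' @param base_error_rate substitution probability per base.
#' @param fragment_break_rate contig breaks per Mb.
#' @return A `DegradationProfile` list.
#' @export
degradation_profile <- function(ltr_gap_rate = 0, gap_len_mean = 300,
                                gap_len_max = 2000, collapse_fraction = 0,
                                collapse_min_identity = 0.99,
                                base_error_rate = 0,
                                fragment_break_rate = 0) {
  stopifnot(ltr_gap_rate >= 0, ltr_gap_rate <= 1,
            collapse_fraction >= 0, collapse_fraction <= 1,
            base_error_rate >= 0, base_error_rate <= 1,
            fragment_break_rate >= 0, gap_len_mean >= 1,
            gap_len_max >= gap_len_mean)
  structure(list(ltr_gap_rate = ltr_gap_rate, gap_len_mean = gap_len_mean,
                 gap_len_max = gap_len_max,
                 collapse_fraction = collapse_fraction,
                 collapse_min_identity = collapse_min_identity,
                 base_error_rate = base_error_rate,
                 fragment_break_rate = fragment_break_rate),
            class = "DegradationProfile")
}

#' Degrade a genome into a short-read-style assembly
#'
#' Applies, in order: (1) N-run masking targeted at LTR intervals, (2)
#' collapse of one copy of selected near-identical element pairs, (3)
#' random substitutions, (4) fragmentation into contigs.  Per-LTR gap
#' decisions are driven by fixed uniform draws, so for one seed the set of
#' gapped LTRs at a lower `ltr_gap_rate` is a subset of the set at any
#' higher rate (degradation severity is nested, matching the monotonicity
#' properties tested downstream).
#'
#' @param genome an [assembly()] (the truth genome).
#' @param truth truth list from [plant_insertions()] (optionally with a
#'   `genes` data.frame added).
#' @param profile a [degradation_profile()].
#' @param seed RNG seed.
#' @return List with `assembly` (degraded), `truth` (coordinates lifted to
#'   the degraded assembly; removed or break-spanning features are flagged
#'   via `removed`/`broken` columns) and `edits` (list of the applied edit
#'   tables).
#' @export
degrade_assembly <- function(genome, truth, profile, seed = NULL) {
  stopifnot(inherits(profile, "DegradationProfile"))
  elements <- truth$elements
  with_seed(seed, {
    seqs <- genome$seqs
    edits <- list()

    ## -- 1. N runs in LTRs (nested across rates via fixed draws) ---------
    ltrs <- ltr_interval_table(elements)
    if (nrow(ltrs) > 0) {
      u <- runif(nrow(ltrs))
      glen <- pmin(profile$gap_len_max,
                   1L + rgeom(nrow(ltrs), 1 / profile$gap_len_mean))
      goff <- runif(nrow(ltrs))
      hit <- which(u < profile$ltr_gap_rate)
      gap_edits <- list()
      for (i in hit) {
        L <- ltrs$end[i] - ltrs$start[i]
        len <- min(glen[i], L)
        off <- floor(goff[i] * (L - len + 1))
        s0 <- ltrs$start[i] + off
        nm <- ltrs$seq_name[i]
        substr(seqs[[nm]], s0 + 1L, s0 + len) <-
          paste(rep("N", len), collapse = "")
        gap_edits[[length(gap_edits) + 1L]] <- data.frame(
          type = "ltr_gap", seq_name = nm, start = s0, end = s0 + len,
          element_id = ltrs$element_id[i], stringsAsFactors = FALSE)
      }
      edits$ltr_gaps <- if (length(gap_edits)) do.call(rbind, gap_edits)
    }

    ## -- 2. collapse near-identical copy pairs ---------------------------
    removed_ids <- character(0)
    removals <- data.frame(seq_name = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
    if (profile$collapse_fraction > 0 && nrow(elements) > 1) {
      pairs <- near_identical_pairs(genome, elements,
                                    profile$collapse_min_identity)
      if (nrow(pairs) > 0) {
        n_take <- round(profile$collapse_fraction * nrow(pairs))
        take <- head(seq_len(nrow(pairs)), n_take)
        for (i in take) {
          vic <- pairs$id_b[i]
          e <- elements[elements$id == vic, ]
          removed_ids <- c(removed_ids, vic)
          removals <- rbind(removals, data.frame(
            seq_name = e$seq_name,
            start = e$start - nchar(e$tsd_seq),  # element + one TSD copy
            end = e$end, stringsAsFactors = FALSE))
        }
        removals <- removals[order(removals$seq_name, removals$start), ]
        for (nm in unique(removals$seq_name)) {
          r <- removals[removals$seq_name == nm, ]
          s <- seqs[[nm]]
          keep <- character(0)
          cursor <- 0L
          for (j in seq_len(nrow(r))) {
            keep <- c(keep, substr(s, cursor + 1L, r$start[j]))
            cursor <- r$end[j]
          }
          keep <- c(keep, substr(s, cursor + 1L, nchar(s)))
          seqs[[nm]] <- paste(keep, collapse = "")
        }
        edits$collapsed <- data.frame(type = "collapse",
                                      element_id = removed_ids,
                                      removals, stringsAsFactors = FALSE)
      }
    }

    ## -- 3. random substitutions -----------------------------------------
    if (profile$base_error_rate > 0) {
      for (nm in names(seqs)) {
        L <- nchar(seqs[[nm]])
        nerr <- rbinom(1, L, profile$base_error_rate)
        if (nerr > 0) {
          seqs[[nm]] <- mutate_seq(seqs[[nm]], nerr, kappa = 1)
        }
      }
      edits$substitutions <- data.frame(type = "substitution",
                                        rate = profile$base_error_rate)
    }

    ## -- 4. fragmentation into contigs -----------------------------------
    frag_map <- NULL
    if (profile$fragment_break_rate > 0) {
      newseqs <- list()
      maps <- list()
      for (nm in names(seqs)) {
        L <- nchar(seqs[[nm]])
        nb <- rpois(1, profile$fragment_break_rate * L / 1e6)
        br <- sort(unique(pmin(L - 1L, pmax(1L, sample.int(L - 1L, min(nb, L - 1L))))))
        bounds <- c(0L, br, L)
        for (j in seq_len(length(bounds) - 1L)) {
          cnm <- if (length(bounds) > 2) sprintf("%s_ctg%03d", nm, j) else nm
          newseqs[[cnm]] <- substr(seqs[[nm]], bounds[j] + 1L, bounds[j + 1L])
          maps[[length(maps) + 1L]] <- data.frame(
            seq_name = nm, contig = cnm, start = bounds[j],
            end = bounds[j + 1L], stringsAsFactors = FALSE)
        }
      }
      seqs <- unlist(newseqs)
      frag_map <- do.call(rbind, maps)
      edits$fragmentation <- frag_map
    }

    degraded <- assembly(seqs)
    lifted <- lift_truth(truth, removals, removed_ids, frag_map)
    list(assembly = degraded, truth = lifted, edits = edits)
  })
}

ltr_interval_table <- function(elements) {
  if (nrow(elements) == 0) {
    return(data.frame(element_id = character(), seq_name = character(),
                      start = integer(), end = integer()))
  }
  rows <- list()
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      element_id = e$id, seq_name = e$seq_name,
      start = e$ltr5_start, end = e$ltr5_end, stringsAsFactors = FALSE)
    if (!e$is_solo && !is.na(e$ltr3_start)) {
      rows[[length(rows) + 1L]] <- data.frame(
        element_id = e$id, seq_name = e$seq_name,
        start = e$ltr3_start, end = e$ltr3_end, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## Disjoint near-identical full-length copy pairs of the same family,
## highest identity first.  Identity is computed on strand-normalized
## element sequences (same family implies equal length in this simulator).
near_identical_pairs <- function(genome, elements, min_identity) {
  fl <- elements[!elements$is_solo, ]
  out <- list()
  for (fam in unique(fl$family)) {
    f <- fl[fl$family == fam, ]
    if (nrow(f) < 2) next
    seqsv <- vapply(seq_len(nrow(f)), function(i) {
      s <- subseq0(genome, f$seq_name[i], f$start[i], f$end[i])
      if (f$strand[i] == "-") revcomp(s) else s
    }, character(1))
    for (i in seq_len(nrow(f) - 1)) {
      for (j in (i + 1):nrow(f)) {
        if (nchar(seqsv[i]) != nchar(seqsv[j])) next
        a <- strsplit(seqsv[i], "")[[1]]
        b <- strsplit(seqsv[j], "")[[1]]
        ident <- mean(a == b)
        if (ident >= min_identity) {
          out[[length(out) + 1L]] <- data.frame(
            id_a = f$id[i], id_b = f$id[j], identity = ident,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(id_a = character(), id_b = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  p <- do.call(rbind, out)
  p <- p[order(-p$identity), ]
  used <- character(0)
  keep <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    if (!(p$id_a[i] %in% used) && !(p$id_b[i] %in% used)) {
      keep[i] <- TRUE
      used <- c(used, p$id_a[i], p$id_b[i])
    }
  }
  p[keep, , drop = FALSE]
}

## Lift truth coordinates through collapse removals and fragmentation.
lift_truth <- function(truth, removals, removed_ids, frag_map) {
  shift_point <- function(nm, x) {
    if (nrow(removals) == 0) return(x)
    r <- removals[removals$seq_name == nm, , drop = FALSE]
    x - sum(r$end[r$end <= x] - r$start[r$end <= x])
  }
  lift_df <- function(df, id_col = NULL) {
    if (is.null(df) || nrow(df) == 0) return(df)
    df$removed <- FALSE
    if (!is.null(id_col)) df$removed <- df[[id_col]] %in% removed_ids
    for (col in intersect(c("start", "end", "ltr5_start", "ltr5_end",
                            "ltr3_start", "ltr3_end"), names(df))) {
      df[[col]] <- vapply(seq_len(nrow(df)), function(i) {
        v <- df[[col]][i]
        if (is.na(v) || df$removed[i]) return(NA_integer_)
        as.integer(shift_point(df$seq_name[i], v))
      }, integer(1))
    }
    df$broken <- FALSE
    if (!is.null(frag_map)) {
      for (i in seq_len(nrow(df))) {
        if (df$removed[i]) next
        m <- frag_map[frag_map$seq_name == df$seq_name[i], , drop = FALSE]
        if (nrow(m) == 0) next
        hit <- which(m$start <= df$start[i] & m$end >= df$end[i])
        if (length(hit) == 1) {
          off <- m$start[hit]
          for (col in intersect(c("start", "end", "ltr5_start", "ltr5_end",
                                  "ltr3_start", "ltr3_end"), names(df))) {
            if (!is.na(df[[col]][i])) df[[col]][i] <- df[[col]][i] - off
          }
          df$seq_name[i] <- m$contig[hit]
        } else {
          df$broken[i] <- TRUE
        }
      }
    }
    df
  }
  list(elements = lift_df(truth$elements, "id"),
       domains = lift_df(truth$domains, "element_id"),
       genes = lift_df(truth$genes))
}

#' Simulate a complete synthetic world
#'
#' Background genome + planted full-length elements, solo-LTRs and genes,
#' with ground truth for every feature.
#'
#' @param length background length, bases.
#' @param n_elements number of full-length elements.
#' @param n_solos number of solo-LTRs.
#' @param n_genes number of truth genes.
#' @param families list of [ltr_family()] models (elements drawn uniformly).
#' @param age_range insertion-age range in years, sampled uniformly.
#' @param gc background GC fraction.
#' @param mu substitution rate per site per year.
#' @param kappa transition:transversion ratio.
#' @param min_gap minimum spacing between insertion points; the default of
#'   25 kb (the detector's inter-LTR distance window) plants dispersed,
#'   non-nested insertions so that each element is an isolated test case --
#'   clustered/nested insertion graphs are out of this simulator's scope.
#' @param seed RNG seed; the whole world is reproducible given the seed.
#' @return List: `genome` (truth assembly), `truth` (list with `elements`,
#'   `domains`, `genes`), `consensus` (named list of ancestral LTRs per
#'   family), `families`.
#' @export
simulate_genome <- function(length = 500000, n_elements = 10, n_solos = 0,
                            n_genes = 0, families = bare1_families(),
                            age_range = c(5e5, 2e6), gc = 0.44,
                            mu = 1.3e-8, kappa = 2, min_gap = 25000,
                            seed = 1) {
  with_seed(seed, {
    ancestors <- lapply(families, family_ancestor)
    names(ancestors) <- vapply(families, `[[`, character(1), "name")
    bg <- simulate_background(length, gc)
    fam_idx <- sample(seq_along(families), n_elements + n_solos,
                      replace = TRUE)
    ages <- runif(n_elements + n_solos, age_range[1], age_range[2])
    consensus <- lapply(ancestors, `[[`, "ltr")
    els <- lapply(seq_len(n_elements + n_solos), function(i) {
      f <- families[[fam_idx[i]]]
      if (i <= n_elements) {
        synthesize_element(f, ages[i], mu = mu, kappa = kappa,
                           ancestor = ancestors[[f$name]])
      } else {
        synthesize_solo(f, ages[i], mu = mu, kappa = kappa,
                        base_ltr = consensus[[f$name]])
      }
    })
    planted <- plant_insertions(bg, els, min_gap = min_gap)
    genes <- plant_genes(planted$genome, n_genes,
                         avoid = planted$truth$elements)
    truth <- planted$truth
    truth$genes <- genes
    list(genome = planted$genome, truth = truth,
         consensus = consensus, families = families)
  })
}

#' Write planted truth as GFF3
#'
#' Elements as `LTR_retrotransposon` (or `solo_LTR`) features with
#' `long_terminal_repeat` children; genes as `gene` features.
#'
#' @param truth truth list (from [plant_insertions()] / [simulate_genome()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_truth_gff3 <- function(truth, path) {
  el <- truth$elements
  feats <- list()
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    type <- if (e$is_solo) "solo_LTR" else "LTR_retrotransposon"
    feats[[length(feats) + 1L]] <- data.frame(
      seq_name = e$seq_name, type = type, start = e$start, end = e$end,
      strand = e$strand,
      attributes = sprintf("ID=%s;family=%s;age_years=%.0f;tsd=%s",
                           e$id, e$family, e$age_years, e$tsd_seq),
      stringsAsFactors = FALSE)
    if (!e$is_solo) {
      feats[[length(feats) + 1L]] <- data.frame(
        seq_name = e$seq_name, type = "long_terminal_repeat",
        start = e$ltr5_start, end = e$ltr5_end, strand = e$strand,
        attributes = paste0("Parent=", e$id), stringsAsFactors = FALSE)
      feats[[length(feats) + 1L]] <- data.frame(
        seq_name = e$seq_name, type = "long_terminal_repeat",
        start = e$ltr3_start, end = e$ltr3_end, strand = e$strand,
        attributes = paste0("Parent=", e$id), stringsAsFactors = FALSE)
    }
  }
  g <- truth$genes
  if (!is.null(g) && nrow(g) > 0) {
    feats[[length(feats) + 1L]] <- data.frame(
      seq_name = g$seq_name, type = "gene", start = g$start, end = g$end,
      strand = "+", attributes = paste0("ID=", g$id),
      stringsAsFactors = FALSE)
  }
  write_gff3(do.call(rbind, feats), path)
}
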