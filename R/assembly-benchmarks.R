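## Assembly benchmark panel: stringent transcript completeness, in-silico
## label maps with DP alignment and label-site coverage, the scaffold
## retention filter, the gene-confidence classifier, and the combined
## report.

#' Transcript completeness at stringent thresholds
#'
#' Each transcript is mapped to its best local-alignment hit (k-mer
#' seeding + extension) and counted as aligned iff the hit reaches
#' `min_cov` percent coverage and `min_id` percent identity.  Coverage is
#' the percentage of transcript bases aligned to determinate (non-N)
#' target bases; identity is the percentage of matching columns among
#' determinate aligned columns.  Both standard threshold pairs of the
#' benchmark panel -- (90, 97) for transcript evidence and (99, 100) for
#' base-accuracy-sensitive gene models -- are plain arguments.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param assembly an [assembly()].
#' @param min_cov minimum percent of the transcript aligned.
#' @param min_id minimum percent identity.
#' @return List with `fraction` (aligned / total) and `hits` (per
#'   transcript: best coverage/identity and pass flag).
#' @export
transcript_completeness <- function(transcripts, assembly, min_cov = 99,
                                    min_id = 100) {
  if (length(transcripts) == 0) stop("empty transcript set")
  stopifnot(min_cov > 0, min_cov <= 100, min_id > 0, min_id <= 100)
  ids <- names(transcripts)
  if (is.null(ids)) ids <- sprintf("t%03d", seq_along(transcripts))
  idx <- target_kmer_index(assembly, 16)
  hits <- lapply(seq_along(transcripts), function(i) {
    h <- local_hits(toupper(transcripts[[i]]), assembly, k = 16, pad = 50,
                    min_seeds = 1, index = idx)
    if (nrow(h) == 0) {
      return(data.frame(id = ids[i], coverage = 0, identity = 0,
                        pass = FALSE, stringsAsFactors = FALSE))
    }
    ## best hit = highest coverage * identity product among top scores
    h$pass <- h$coverage >= min_cov & h$identity >= min_id
    b <- h[order(-h$pass, -(h$coverage * h$identity))[1], ]
    data.frame(id = ids[i], coverage = b$coverage, identity = b$identity,
               pass = b$pass, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  list(fraction = mean(hits$pass), hits = hits)
}

#' In-silico digestion: label map of an assembly
#'
#' All occurrence start positions (0-based) of the label motif per
#' sequence.  The default DLE-1 motif `CTTAAG` is its own reverse
#' complement, so single-strand scanning suffices; non-palindromic motifs
#' are scanned on both strands and positions deduplicated.
#'
#' @param assembly an [assembly()].
#' @param motif recognition sequence (default `CTTAAG`).
#' @return A `LabelMap`: list with `sites` (named list of 0-based position
#'   vectors) and `seq_lengths`.
#' @export
insilico_digest <- function(assembly, motif = "CTTAAG") {
  if (nchar(motif) == 0) stop("empty motif")
  motif <- toupper(motif)
  palindromic <- identical(motif, revcomp(motif))
  sites <- lapply(assembly$seqs, function(s) {
    pos <- find_motif(s, motif)
    if (!palindromic) {
      pos <- sort(unique(c(pos, find_motif(s, revcomp(motif)))))
    }
    pos
  })
  structure(list(sites = sites, seq_lengths = assembly$lengths),
            class = "LabelMap")
}

find_motif <- function(seq, motif) {
  m <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' Align two label maps by dynamic programming
#'
#' Finds the best-scoring monotone matching of query sites to reference
#' sites.  Matched pairs earn `site_bonus` each; consecutive matched pairs
#' pay a sizing penalty proportional to the relative discrepancy of their
#' inter-site spacings (pairs with discrepancy above `tol` cannot be
#' chained) and `skip_penalty` per skipped site.  The confidence score is
#' the total score of the best chain; for maps of up to 8 sites the result
#' equals exhaustive search over all monotone matchings.
#'
#' @param query_sites,ref_sites numeric vectors of ordered site positions
#'   (>= 2 each).
#' @param tol relative spacing tolerance (default 0.10).
#' @param site_bonus score per matched site pair (default 2).
#' @param skip_penalty cost per skipped site inside the chain (default 1).
#' @param sizing_penalty cost at discrepancy == tol (default 1).
#' @param max_skip maximum consecutive skipped sites per side (default 10).
#' @return List: `score` (confidence), `pairs` (matrix of matched 1-based
#'   query/ref indices), `n_matched`.
#' @export
align_label_maps <- function(query_sites, ref_sites, tol = 0.10,
                             site_bonus = 2, skip_penalty = 1,
                             sizing_penalty = 1, max_skip = 10) {
  if (length(query_sites) < 2 || length(ref_sites) < 2) {
    stop("need at least 2 labels per map")
  }
  if (is.unsorted(query_sites, strictly = TRUE) ||
      is.unsorted(ref_sites, strictly = TRUE)) {
    stop("site positions must be strictly increasing")
  }
  r <- .labelmap_dp(as.numeric(query_sites), as.numeric(ref_sites), tol,
                    site_bonus, skip_penalty, sizing_penalty,
                    as.integer(max_skip))
  list(score = r$score,
       pairs = cbind(q_idx = r$q_idx, r_idx = r$r_idx),
       n_matched = length(r$q_idx))
}

#' Label-site coverage of an assembly
#'
#' The assembly is digested in silico; every reference-map sequence of
#' length at least `min_contig` is aligned to its best assembly sequence,
#' and alignments with confidence at least `min_confidence` contribute
#' their matched reference sites.  Returns
#' `100 * matched sites / total sites` over the retained reference
#' sequences.
#'
#' @param assembly an [assembly()].
#' @param ref_map a `LabelMap` (e.g. from [insilico_digest()] of a
#'   reference, or [read_label_map()]).
#' @param min_contig minimum reference map length considered (default
#'   100 kb).
#' @param min_confidence minimum alignment confidence (default 20).
#' @param motif label motif used to digest `assembly`.
#' @return Percent of reference label sites aligned.
#' @export
label_site_coverage <- function(assembly, ref_map, min_contig = 100000,
                                min_confidence = 20, motif = "CTTAAG") {
  qmap <- insilico_digest(assembly, motif)
  total <- 0L
  matched <- 0L
  for (nm in names(ref_map$sites)) {
    if (ref_map$seq_lengths[[nm]] < min_contig) next
    rs <- ref_map$sites[[nm]]
    if (length(rs) < 2) next
    total <- total + length(rs)
    best <- NULL
    for (tn in names(qmap$sites)) {
      qs <- qmap$sites[[tn]]
      if (length(qs) < 2) next
      al <- align_label_maps(qs, rs)
      if (is.null(best) || al$score > best$score) best <- al
    }
    if (!is.null(best) && best$score >= min_confidence) {
      matched <- matched + best$n_matched
    }
  }
  if (total == 0) stop("reference map has no sites on retained sequences")
  100 * matched / total
}

#' Read / write a label map as TSV
#'
#' Format: header lines `#seq_name<TAB>length`, then one row
#' `seq_name<TAB>position` per site (0-based).
#'
#' @param path file path.
#' @return [read_label_map()]: a `LabelMap`; [write_label_map()]:
#'   invisibly, `path`.
#' @export
read_label_map <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- do.call(rbind, strsplit(sub("^#", "", lines[hdr]), "\t"))
  seq_lengths <- setNames(as.numeric(meta[, 2]), meta[, 1])
  body <- lines[!hdr & nzchar(lines)]
  sites <- setNames(vector("list", length(seq_lengths)), names(seq_lengths))
  sites[] <- list(integer(0))
  if (length(body)) {
    parts <- do.call(rbind, strsplit(body, "\t"))
    df <- data.frame(seq_name = parts[, 1],
                     pos = as.integer(parts[, 2]),
                     stringsAsFactors = FALSE)
    for (nm in unique(df$seq_name)) {
      sites[[nm]] <- sort(df$pos[df$seq_name == nm])
    }
  }
  structure(list(sites = sites, seq_lengths = seq_lengths),
            class = "LabelMap")
}

#' @rdname read_label_map
#' @param map a `LabelMap`.
#' @export
write_label_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(map$sites)) {
    writeLines(sprintf("#%s\t%d", nm, as.integer(map$seq_lengths[[nm]])),
               con)
  }
  for (nm in names(map$sites)) {
    p <- map$sites[[nm]]
    if (length(p)) writeLines(sprintf("%s\t%d", nm, p), con)
  }
  invisible(path)
}

#' Scaffold retention filter
#'
#' Scaffolds assigned to chromosomes are always kept; unassigned
#' scaffolds are kept iff their length is >= 50 kb AND they are not
#' assembly bubbles AND (their read coverage is >= 10-fold OR they carry
#' genes not present in chromosome-assigned scaffolds).
#'
#' @param metas data.frame with columns `name`, `length`,
#'   `chromosome_assigned`, `bubble`, `read_coverage`, `has_unique_genes`.
#' @param min_len,min_coverage rule thresholds (defaults 50,000 and 10).
#' @return List with `kept` and `discarded` (the latter with a `reason`
#'   column).
#' @export
scaffold_filter <- function(metas, min_len = 50000, min_coverage = 10) {
  reason <- character(nrow(metas))
  keep <- logical(nrow(metas))
  for (i in seq_len(nrow(metas))) {
    m <- metas[i, ]
    if (isTRUE(m$chromosome_assigned)) {
      keep[i] <- TRUE
    } else if (m$length < min_len) {
      reason[i] <- "length"
    } else if (isTRUE(m$bubble)) {
      reason[i] <- "bubble"
    } else if (m$read_coverage < min_coverage && !isTRUE(m$has_unique_genes)) {
      reason[i] <- "coverage_and_no_unique_genes"
    } else {
      keep[i] <- TRUE
    }
  }
  discarded <- metas[!keep, , drop = FALSE]
  if (nrow(discarded)) discarded$reason <- reason[!keep]
  list(kept = metas[keep, , drop = FALSE], discarded = discarded)
}

#' Classify gene confidence (HC / LC / REP)
#'
#' Tiered homology rules against three databases (validated magnoliophyta
#' proteins "UniMag", annotated Poaceae proteins "UniPoa", and the TE
#' hypothetical-protein database "PTREP").  Hits with e-value >=
#' `max_evalue` are treated as no-hit.  Rules, in order:
#' 1. complete AND UniMag query & subject coverage >= 80 -> HC
#' 2. complete AND no UniMag hit AND UniPoa hit AND no PTREP hit -> HC
#'    (completeness distributes over both HC branches: an incomplete
#'    protein with only a UniPoa hit is LC by rule 3)
#' 3. incomplete AND (UniMag or UniPoa hit) AND no PTREP hit -> LC
#' 4. no hit in any database AND complete -> LC
#' 5. no UniMag hit AND complete AND PTREP hit -> REP
#' Unmatched records fall through to LC (rule `default`).  AHRD
#' refinement then promotes 3-star LC to HC and demotes 1-star HC to LC.
#'
#' @param records data.frame with columns `id`, `complete`, `ahrd_stars`,
#'   and per database `<db>_evalue`, `<db>_qcov`, `<db>_scov` for
#'   `db` in `unimag`, `unipoa`, `ptrep` (`NA` = no hit).
#' @param max_evalue e-value cutoff (default 1e-10).
#' @param min_cov coverage threshold, percent (default 80).
#' @return data.frame: `id`, `class`, `rule` (audit trace).
#' @export
classify_gene_confidence <- function(records, max_evalue = 1e-10,
                                     min_cov = 80) {
  has_hit <- function(db, i) {
    e <- records[[paste0(db, "_evalue")]][i]
    !is.na(e) && e < max_evalue
  }
  out <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    if (is.na(r$complete)) stop("record ", r$id, ": complete flag missing")
    um <- has_hit("unimag", i)
    up <- has_hit("unipoa", i)
    pt <- has_hit("ptrep", i)
    cls <- NULL; rule <- NULL
    if (isTRUE(r$complete) && um &&
        !is.na(r$unimag_qcov) && r$unimag_qcov >= min_cov &&
        !is.na(r$unimag_scov) && r$unimag_scov >= min_cov) {
      cls <- "HC"; rule <- "1_complete_unimag"
    } else if (isTRUE(r$complete) && !um && up && !pt) {
      cls <- "HC"; rule <- "2_unipoa_only"
    } else if (!isTRUE(r$complete) && (um || up) && !pt) {
      cls <- "LC"; rule <- "3_incomplete_homology"
    } else if (!um && !up && !pt && isTRUE(r$complete)) {
      cls <- "LC"; rule <- "4_complete_no_hit"
    } else if (!um && isTRUE(r$complete) && pt) {
      cls <- "REP"; rule <- "5_te_hit"
    } else {
      cls <- "LC"; rule <- "default"
    }
    stars <- r$ahrd_stars
    if (!is.na(stars)) {
      if (cls == "LC" && stars == 3) {
        cls <- "HC"; rule <- paste0(rule, "+ahrd_promote")
      } else if (cls == "HC" && stars == 1) {
        cls <- "LC"; rule <- paste0(rule, "+ahrd_demote")
      }
    }
    data.frame(id = r$id, class = cls, rule = rule,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Combined benchmark panel
#'
#' One row of assembly metrics: total size, size in sequences > 1 Mb,
#' contig and scaffold N50, transcript completeness at (90, 97) and
#' (99, 100), label-site coverage, full-length element count and TSD rate.
#'
#' @param assembly an [assembly()].
#' @param transcripts optional named character vector of transcripts.
#' @param ref_map optional reference `LabelMap`.
#' @param elements optional refined element data.frame (with `tsd`
#'   column); when `NULL` the element columns are `NA`.
#' @param min_contig,min_confidence label-map filters.
#' @return One-row data.frame of metrics.
#' @export
benchmark_panel <- function(assembly, transcripts = NULL, ref_map = NULL,
                            elements = NULL, min_contig = 100000,
                            min_confidence = 20) {
  scaf <- as.numeric(assembly$lengths)
  ctg <- as.numeric(contig_lengths(assembly))
  gaps <- gap_segments(assembly)
  res <- data.frame(
    total_size = sum(scaf),
    size_gt_1mb = sum(scaf[scaf > 1e6]),
    contig_n50 = nx_stat(ctg, 50),
    scaffold_n50 = nx_stat(scaf, 50),
    n_gaps = nrow(gaps),
    gap_bases = sum(gaps$n_count),
    completeness_90_97 = NA_real_,
    completeness_99_100 = NA_real_,
    label_site_coverage = NA_real_,
    n_elements = NA_integer_,
    tsd_rate = NA_real_
  )
  if (!is.null(transcripts)) {
    res$completeness_90_97 <-
      transcript_completeness(transcripts, assembly, 90, 97)$fraction
    res$completeness_99_100 <-
      transcript_completeness(transcripts, assembly, 99, 100)$fraction
  }
  if (!is.null(ref_map)) {
    res$label_site_coverage <-
      label_site_coverage(assembly, ref_map, min_contig, min_confidence)
  }
  if (!is.null(elements)) {
    res$n_elements <- nrow(elements)
    if (nrow(elements) > 0 && !is.null(elements$tsd)) {
      res$tsd_rate <- mean(!is.na(elements$tsd))
    }
  }
  res
}
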