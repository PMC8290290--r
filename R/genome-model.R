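## Core sequence/interval model: Assembly container, FASTA/BED/GFF3 IO,
## gap segmentation, Nx statistics.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct an assembly from named DNA sequences
#'
#' An `Assembly` is an ordered collection of named, uppercased DNA sequences
#' over the alphabet `A,C,G,T,N`.  Any other IUPAC ambiguity letter is
#' normalized to `N` (a message reports how many bases were remapped).
#'
#' @param seqs named character vector of DNA sequences.
#' @return An object of class `Assembly` with elements `seqs` (named
#'   character vector) and `lengths` (named integer vector).
#' @examples
#' a <- assembly(c(chr1 = "ACGTNNACGT"))
#' seq_lengths(a)
#' @export
assembly <- function(seqs) {
  if (length(seqs) == 0) stop("assembly must contain at least one sequence")
  nm <- names(seqs)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate sequence names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(seqs))
  bad <- sum(vapply(seqs, function(s) {
    nchar(gsub("[ACGTN]", "", s))
  }, integer(1)))
  if (bad > 0) {
    message("normalized ", bad, " non-ACGTN base(s) to N")
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  names(seqs) <- nm
  structure(
    list(seqs = seqs, lengths = setNames(nchar(seqs), nm)),
    class = "Assembly"
  )
}

#' @export
print.Assembly <- function(x, ...) {
  cat("Assembly with", length(x$seqs), "sequence(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  show <- head(seq_along(x$seqs), 10)
  for (i in show) {
    cat(sprintf("  %-20s %12s bp\n", names(x$seqs)[i],
                format(x$lengths[i], big.mark = ",")))
  }
  if (length(x$seqs) > 10) cat("  ...\n")
  invisible(x)
}

#' Sequence lengths of an assembly
#' @param assembly an [assembly()].
#' @return Named integer vector of sequence lengths.
#' @export
seq_lengths <- function(assembly) assembly$lengths

## 0-based half-open substring accessor (clips are the caller's job).
subseq0 <- function(assembly, seq_name, start, end) {
  s <- assembly$seqs[[seq_name]]
  if (is.null(s)) stop("unknown sequence: ", seq_name)
  if (start < 0 || end > nchar(s) || start >= end) {
    stop(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                 start, end, seq_name, nchar(s)))
  }
  substr(s, start + 1L, end)
}

#' Read a FASTA file into an assembly
#'
#' Sequences are uppercased and IUPAC ambiguity codes other than `N` are
#' mapped to `N`; record order is preserved.  Duplicate record names and
#' empty files are hard errors.
#'
#' @param path path to a FASTA file.
#' @return An [assembly()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  assembly(setNames(as.character(ss), nm))
}

#' Write an assembly to FASTA
#'
#' @param assembly an [assembly()].
#' @param path output path.
#' @param width line wrap width (default 60 columns).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(assembly, path, width = 60) {
  ss <- Biostrings::BStringSet(assembly$seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Maximal N runs (assembly gaps)
#'
#' Finds all maximal runs of `N` of length at least `min_run`, the gap
#' definition used when contigs are delimited by splitting scaffolds at any
#' N run (`min_run = 1`).
#'
#' @param assembly an [assembly()].
#' @param min_run minimum N-run length to report (default 1).
#' @return data.frame with columns `seq_name`, `start`, `end` (0-based
#'   half-open) and `n_count`, sorted by position.
#' @export
gap_segments <- function(assembly, min_run = 1) {
  stopifnot(min_run >= 1)
  out <- lapply(names(assembly$seqs), function(nm) {
    m <- gregexpr("N+", assembly$seqs[[nm]])[[1]]
    if (m[1] == -1) return(NULL)
    len <- attr(m, "match.length")
    keep <- len >= min_run
    if (!any(keep)) return(NULL)
    data.frame(seq_name = nm,
               start = as.integer(m[keep]) - 1L,
               end = as.integer(m[keep]) - 1L + len[keep],
               n_count = len[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(seq_name = character(), start = integer(),
                      end = integer(), n_count = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Contig lengths after splitting at gaps
#'
#' Contigs are the complementary segments of [gap_segments()]: gap-free
#' stretches within each sequence.
#'
#' @inheritParams gap_segments
#' @return Integer vector of contig lengths (zero-length pieces dropped).
#' @export
contig_lengths <- function(assembly, min_run = 1) {
  gaps <- gap_segments(assembly, min_run)
  unlist(lapply(names(assembly$seqs), function(nm) {
    L <- assembly$lengths[[nm]]
    g <- gaps[gaps$seq_name == nm, , drop = FALSE]
    if (nrow(g) == 0) return(L)
    bounds <- c(0L, as.vector(rbind(g$start, g$end)), L)
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    len <- ends - starts
    len[len > 0]
  }), use.names = FALSE)
}

#' Nx statistic of a set of lengths
#'
#' The largest length `L` such that pieces of length `>= L` sum to at least
#' `x` percent of the total (N50 for `x = 50`, N90 for `x = 90`).
#'
#' @param lengths numeric vector of positive lengths.
#' @param x percentage in (0, 100].
#' @return The Nx length.
#' @examples
#' nx_stat(c(5, 4, 3, 2, 1), 50)  # 4
#' @export
nx_stat <- function(lengths, x = 50) {
  if (length(lengths) == 0) stop("empty length list")
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (x <= 0 || x > 100) stop("x must be in (0, 100]")
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(s))
  s[which(cum >= x / 100 * cum[length(cum)])[1]]
}

#' Fraction of genes with gap-free flanking windows
#'
#' For each gene, the window `[start - flank, end + flank)` (clipped to the
#' sequence bounds) is inspected; the gene counts as gap-free when the
#' window contains no `N`.
#'
#' @param assembly an [assembly()].
#' @param genes data.frame with columns `seq_name`, `start`, `end`
#'   (0-based half-open).
#' @param flank flanking window on each side, bases (default 100 kb).
#' @return Fraction of genes whose window is N-free.
#' @export
gene_flank_gap_fraction <- function(assembly, genes, flank = 100000) {
  if (nrow(genes) == 0) stop("empty gene set")
  unknown <- setdiff(unique(genes$seq_name), names(assembly$seqs))
  if (length(unknown) > 0) {
    stop("genes on unknown sequence(s): ", paste(unknown, collapse = ", "))
  }
  ok <- vapply(seq_len(nrow(genes)), function(i) {
    nm <- genes$seq_name[i]
    L <- assembly$lengths[[nm]]
    s <- max(0L, genes$start[i] - flank)
    e <- min(L, genes$end[i] + flank)
    !grepl("N", subseq0(assembly, nm, s, e), fixed = TRUE)
  }, logical(1))
  mean(ok)
}

#' Basic assembly statistics
#'
#' @param assembly an [assembly()].
#' @param min_gap_run minimum N-run length that splits contigs (default 1).
#' @return A one-row data.frame: total size, number of scaffolds and
#'   contigs, scaffold/contig N50 and N90, gap count and total gap bases.
#' @export
assembly_stats <- function(assembly, min_gap_run = 1) {
  scaf <- as.numeric(assembly$lengths)
  ctg <- as.numeric(contig_lengths(assembly, min_gap_run))
  gaps <- gap_segments(assembly, min_gap_run)
  data.frame(
    total_size = sum(scaf),
    n_scaffolds = length(scaf),
    n_contigs = length(ctg),
    scaffold_n50 = nx_stat(scaf, 50),
    scaffold_n90 = nx_stat(scaf, 90),
    contig_n50 = nx_stat(ctg, 50),
    contig_n90 = nx_stat(ctg, 90),
    n_gaps = nrow(gaps),
    gap_bases = sum(gaps$n_count)
  )
}

#' Write intervals as BED
#'
#' @param intervals data.frame with `seq_name`, `start`, `end` (0-based
#'   half-open) and optionally `name`, `score`, `strand`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(intervals$seq_name, intervals$start, intervals$end)
  if (!is.null(intervals$name)) {
    df$name <- intervals$name
    df$score <- if (is.null(intervals$score)) 0 else intervals$score
    df$strand <- if (is.null(intervals$strand)) "." else intervals$strand
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write features as GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive GFF3 convention.
#'
#' @param features data.frame with columns `seq_name`, `source`, `type`,
#'   `start`, `end` (0-based half-open), `score`, `strand`, `attributes`.
#'   Missing optional columns are filled with `.`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(features, path) {
  get_col <- function(col, default) {
    if (is.null(features[[col]])) rep(default, nrow(features))
    else features[[col]]
  }
  df <- data.frame(
    features$seq_name,
    get_col("source", "retrobench"),
    get_col("type", "region"),
    features$start + 1L,
    features$end,
    get_col("score", "."),
    get_col("strand", "."),
    get_col("phase", "."),
    get_col("attributes", ".")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
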