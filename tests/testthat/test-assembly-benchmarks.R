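# Benchmark panel: transcript completeness, label maps, scaffold filter,
# gene confidence classification.

test_that("transcript_completeness applies coverage/identity thresholds", {
  set.seed(91)
  g <- assembly(c(chr = random_dna_str(60000)))
  tx <- setNames(vapply(1:4, function(i) {
    substr(g$seqs[[1]], i * 10000 + 1, i * 10000 + 2000)
  }, ""), paste0("t", 1:4))

  r <- transcript_completeness(tx, g, 99, 100)
  expect_equal(r$fraction, 1.0)

  # 2 % substitutions in one transcript: fails (99,100), passes (90,97)
  tx2 <- tx
  x <- strsplit(tx2[[1]], "")[[1]]
  idx <- seq(10, 1990, length.out = 40)
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  x[idx] <- swap[x[idx]]
  tx2[[1]] <- paste(x, collapse = "")
  expect_equal(transcript_completeness(tx2, g, 99, 100)$fraction, 0.75)
  expect_equal(transcript_completeness(tx2, g, 90, 97)$fraction, 1.0)

  # transcript spanning a 500-bp N gap fails coverage at (99,100)
  g2 <- g
  substr(g2$seqs[[1]], 10800, 11299) <- strrep("N", 500)
  r2 <- transcript_completeness(tx, g2, 99, 100)
  expect_equal(r2$fraction, 0.75)
  expect_lt(r2$hits$coverage[1], 99)

  # monotone non-increasing in both thresholds
  expect_gte(transcript_completeness(tx2, g, 90, 97)$fraction,
             transcript_completeness(tx2, g, 99, 97)$fraction)
  expect_gte(transcript_completeness(tx2, g, 90, 97)$fraction,
             transcript_completeness(tx2, g, 90, 100)$fraction)

  expect_error(transcript_completeness(character(0), g), "empty")
})

test_that("insilico_digest finds motif sites", {
  d <- insilico_digest(assembly(c(s = "AAACTTAAGAAA")))
  expect_equal(d$sites$s, 3L)
  d <- insilico_digest(assembly(c(s = "CTTAAGCTTAAG")))
  expect_equal(d$sites$s, c(0L, 6L))
  d <- insilico_digest(assembly(c(s = "ACACACACAC")))
  expect_length(d$sites$s, 0)
  # non-palindromic motif: both strands, deduplicated
  d <- insilico_digest(assembly(c(s = "GAATTAATTC")), motif = "GAATT")
  expect_equal(d$sites$s, c(0L, 5L))
})

test_that("align_label_maps matches sites and rejects rescaled maps", {
  sites <- cumsum(c(5000, 3000, 8000, 2000, 6000, 4000, 7000, 3500, 5500,
                    4500))
  al <- align_label_maps(sites, sites)
  expect_equal(al$n_matched, 10)
  expect_equal(al$score, 20)  # 10 * site_bonus, zero penalties

  # query missing one interior site: 9 matched, one ref site skipped
  al2 <- align_label_maps(sites[-5], sites)
  expect_equal(al2$n_matched, 9)

  # uniform 3x rescaling: no chainable transition, confidence below 20
  al3 <- align_label_maps(sites * 3, sites)
  expect_lt(al3$score, 20)

  expect_error(align_label_maps(1, sites), "at least 2")
  expect_error(align_label_maps(c(3, 2, 5), sites), "increasing")
})

test_that("label-map DP equals exhaustive enumeration on maps <= 8 sites", {
  set.seed(92)
  for (i in 1:40) {
    nq <- sample(2:8, 1); nr <- sample(2:8, 1)
    q <- cumsum(sample(1000:9000, nq))
    r <- if (runif(1) < 0.3) {
      # related maps: ref = query with jitter and site dropout
      keep <- sort(sample(nq, max(2, nq - 2)))
      round(q[keep] * runif(length(keep), 0.97, 1.03))
    } else {
      cumsum(sample(1000:9000, nr))
    }
    if (is.unsorted(r, strictly = TRUE)) next
    dp <- align_label_maps(q, r)
    ex <- labelmap_exhaustive(q, r)
    expect_equal(dp$score, ex$score, tolerance = 1e-9)
  }
})

test_that("label_site_coverage handles self, damage and short maps", {
  set.seed(93)
  g <- assembly(c(chr = random_dna_str(300000)))
  ref <- insilico_digest(g)
  expect_gte(length(ref$sites$chr), 30)
  expect_equal(label_site_coverage(g, ref), 100)

  # destroy ~10 % of sites with N masking: coverage drops accordingly
  g2 <- g
  kill <- ref$sites$chr[seq(5, length(ref$sites$chr), by = 10)]
  for (p in kill) substr(g2$seqs[[1]], p + 1, p + 6) <- "NNNNNN"
  cov <- label_site_coverage(g2, ref)
  killed_frac <- length(kill) / length(ref$sites$chr)
  expect_lt(cov, 100)
  expect_equal(cov, 100 * (1 - killed_frac), tolerance = 0.05)

  # map sequences below min_contig are excluded from the denominator
  ref_short <- ref
  ref_short$seq_lengths[["chr"]] <- 50000
  expect_error(label_site_coverage(g, ref_short), "no sites")
})

test_that("label map TSV round-trips", {
  m <- insilico_digest(assembly(c(a = "AACTTAAGAA", b = "CTTAAGCTTAAG")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_label_map(m, f)
  m2 <- read_label_map(f)
  expect_equal(m2$sites$a, m$sites$a)
  expect_equal(m2$sites$b, m$sites$b)
  expect_equal(unname(m2$seq_lengths), unname(as.numeric(m$seq_lengths)))
})

test_that("scaffold_filter reproduces its rule table exhaustively", {
  grid <- expand.grid(chromosome_assigned = c(TRUE, FALSE),
                      length = c(40000, 60000),
                      bubble = c(TRUE, FALSE),
                      read_coverage = c(5, 12),
                      has_unique_genes = c(TRUE, FALSE))
  grid$name <- sprintf("s%02d", seq_len(nrow(grid)))
  sf <- scaffold_filter(grid)
  expect_equal(nrow(sf$kept) + nrow(sf$discarded), nrow(grid))
  for (i in seq_len(nrow(grid))) {
    want <- scaffold_oracle(grid$chromosome_assigned[i], grid$length[i],
                            grid$bubble[i], grid$read_coverage[i],
                            grid$has_unique_genes[i])
    expect_equal(grid$name[i] %in% sf$kept$name, want, label = grid$name[i])
  }
  # the three worked examples
  ex <- data.frame(name = c("a", "b", "c"), chromosome_assigned = FALSE,
                   length = c(60000, 40000, 60000),
                   bubble = c(FALSE, FALSE, TRUE),
                   read_coverage = c(12, 12, 12),
                   has_unique_genes = FALSE)
  sfx <- scaffold_filter(ex)
  expect_equal(sfx$kept$name, "a")
  expect_equal(sfx$discarded$reason, c("length", "bubble"))
})

test_that("classify_gene_confidence matches the rule oracle exhaustively", {
  mk_rec <- function(complete, um, um_cov, up, pt, stars, id) {
    data.frame(id = id, complete = complete,
               unimag_evalue = if (um) 1e-30 else NA,
               unimag_qcov = if (um) um_cov else NA,
               unimag_scov = if (um) um_cov else NA,
               unipoa_evalue = if (up) 1e-30 else NA,
               unipoa_qcov = if (up) 90 else NA,
               unipoa_scov = if (up) 90 else NA,
               ptrep_evalue = if (pt) 1e-30 else NA,
               ptrep_qcov = if (pt) 90 else NA,
               ptrep_scov = if (pt) 90 else NA,
               ahrd_stars = stars)
  }
  grid <- expand.grid(complete = c(TRUE, FALSE),
                      um = c(TRUE, FALSE), um_cov = c(85, 60),
                      up = c(TRUE, FALSE), pt = c(TRUE, FALSE),
                      stars = 0:3)
  recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    with(grid[i, ], mk_rec(complete, um, um_cov, up, pt, stars,
                           sprintf("g%03d", i)))
  }))
  dec <- classify_gene_confidence(recs)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    want <- gene_conf_oracle(g$complete, g$um, g$um & g$um_cov >= 80,
                             g$up, g$pt, g$stars)
    expect_equal(dec$class[i], want, label = dec$id[i])
  }
  # every decision carries a rule trace
  expect_true(all(nzchar(dec$rule)))

  # hits at e-value above the cutoff count as no-hit
  weak <- mk_rec(TRUE, TRUE, 85, FALSE, FALSE, 0, "w1")
  weak$unimag_evalue <- 1e-5
  expect_equal(classify_gene_confidence(weak)$class, "LC")  # rule 4
})

test_that("classify_gene_confidence reproduces the worked examples", {
  mk <- function(...) {
    df <- data.frame(id = "x", complete = NA, unimag_evalue = NA,
                     unimag_qcov = NA, unimag_scov = NA,
                     unipoa_evalue = NA, unipoa_qcov = NA,
                     unipoa_scov = NA, ptrep_evalue = NA, ptrep_qcov = NA,
                     ptrep_scov = NA, ahrd_stars = NA)
    args <- list(...)
    df[names(args)] <- args
    df
  }
  # complete, UniMag cov 85/85, 3 stars -> HC
  expect_equal(classify_gene_confidence(
    mk(complete = TRUE, unimag_evalue = 1e-30, unimag_qcov = 85,
       unimag_scov = 85, ahrd_stars = 3))$class, "HC")
  # incomplete, UniPoa hit, no PTREP, 2 stars -> LC
  expect_equal(classify_gene_confidence(
    mk(complete = FALSE, unipoa_evalue = 1e-20, ahrd_stars = 2))$class,
    "LC")
  # complete, no UniMag, PTREP hit -> REP
  expect_equal(classify_gene_confidence(
    mk(complete = TRUE, ptrep_evalue = 1e-20))$class, "REP")
  # LC by rule 4 promoted by 3-star AHRD
  d <- classify_gene_confidence(mk(complete = TRUE, ahrd_stars = 3))
  expect_equal(d$class, "HC")
  expect_match(d$rule, "ahrd_promote")
  # HC demoted by 1-star AHRD
  d2 <- classify_gene_confidence(
    mk(complete = TRUE, unimag_evalue = 1e-30, unimag_qcov = 90,
       unimag_scov = 90, ahrd_stars = 1))
  expect_equal(d2$class, "LC")
  expect_match(d2$rule, "ahrd_demote")
})

test_that("benchmark_panel reports sizes and thresholds", {
  set.seed(94)
  g <- assembly(c(big = random_dna_str(1.2e6), small = random_dna_str(5e5)))
  bp <- benchmark_panel(g)
  expect_equal(bp$total_size, 1.7e6)
  expect_equal(bp$size_gt_1mb, 1.2e6)  # the 0.5 Mb contig is excluded
  expect_equal(bp$gap_bases, 0)
})
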