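# Genome simulator: background, element synthesis, insertion with TSDs,
# gene placement, degradation operators, determinism.

test_that("simulate_background is reproducible and respects GC", {
  a1 <- simulate_background(1000, seed = 1)
  a2 <- simulate_background(1000, seed = 1)
  expect_identical(a1$seqs, a2$seqs)

  a <- simulate_background(1e5, gc = 0.5, seed = 2)
  gc_obs <- nchar(gsub("[AT]", "", a$seqs[[1]])) / 1e5
  # binomial: sd = sqrt(0.25 / n)
  expect_lt(abs(gc_obs - 0.5), 3 * sqrt(0.25 / 1e5))

  expect_error(simulate_background(0), "positive")
})

test_that("synthesize_element builds the stated structure", {
  fam <- test_family()
  e0 <- synthesize_element(fam, age_years = 0, seed = 3)
  expect_equal(nchar(e0$seq), fam$total_len)
  ltr5 <- substr(e0$seq, 1, fam$ltr_len)
  ltr3 <- substr(e0$seq, fam$total_len - fam$ltr_len + 1, fam$total_len)
  expect_identical(ltr5, ltr3)  # age 0: byte-identical LTRs
  # TG...CA termini on both LTRs
  for (l in c(ltr5, ltr3)) {
    expect_equal(substr(l, 1, 2), "TG")
    expect_equal(substr(l, nchar(l) - 1, nchar(l)), "CA")
  }
  # domain layout sits inside the internal region, in order
  expect_equal(e0$domains$kind, c("INT", "RT", "RH"))
  expect_true(all(e0$domains$start >= fam$ltr_len))
  expect_true(all(e0$domains$end <= fam$total_len - fam$ltr_len))
})

test_that("aged LTR pairs carry the expected Poisson mutation load", {
  # LTR 1 kb, age 700 kyr: expected pairwise mismatches ~ 2 * 1.3e-8 *
  # 7e5 * 1000 = 18.2
  fam <- ltr_family("F", ltr_len = 1000, total_len = 3500)
  set.seed(11)
  mm <- vapply(1:60, function(i) {
    e <- synthesize_element(fam, 7e5)
    a <- strsplit(substr(e$seq, 1, 1000), "")[[1]]
    b <- strsplit(substr(e$seq, 2501, 3500), "")[[1]]
    sum(a != b)
  }, numeric(1))
  expect_lt(abs(mean(mm) - 18.2), 2.5)  # ~3 se over 60 replicates
})

test_that("age->divergence regression slope is within 10 % of 1", {
  fam <- ltr_family("F", ltr_len = 1000, total_len = 3500)
  set.seed(12)
  ages <- runif(60, 2e5, 2e6)
  frac <- vapply(ages, function(t) {
    e <- synthesize_element(fam, t)
    a <- strsplit(substr(e$seq, 1, 1000), "")[[1]]
    b <- strsplit(substr(e$seq, 2501, 3500), "")[[1]]
    mean(a != b)
  }, numeric(1))
  fit <- lm(frac ~ 0 + I(2 * 1.3e-8 * ages))
  expect_lt(abs(unname(coef(fit)[1]) - 1), 0.1)
})

test_that("plant_insertions duplicates the target site and is reversible", {
  fam <- test_family()
  bg <- simulate_background(30000, seed = 21)
  orig <- bg$seqs[[1]]
  el <- synthesize_element(fam, 5e5, seed = 22)
  pos <- data.frame(seq_name = "chr1", pos = 12345L)
  pl <- plant_insertions(bg, list(el), positions = pos, strands = "+")
  tr <- pl$truth$elements
  g <- pl$genome$seqs[[1]]

  # length arithmetic: element + one TSD copy
  expect_equal(nchar(g), 30000 + fam$total_len + fam$tsd_len)
  # TSD copies flank the element on both sides
  left <- substr(g, tr$start - fam$tsd_len + 1, tr$start)
  right <- substr(g, tr$end + 1, tr$end + fam$tsd_len)
  expect_identical(left, tr$tsd_seq)
  expect_identical(right, tr$tsd_seq)
  # element is recorded verbatim
  expect_identical(substr(g, tr$start + 1, tr$end), el$seq)
  # reversibility: excising element + one TSD copy restores the genome
  restored <- paste0(substr(g, 1, tr$start - fam$tsd_len),
                     substr(g, tr$end + 1, nchar(g)))
  expect_identical(restored, orig)

  # solo arithmetic
  solo <- synthesize_solo(fam, 5e5, seed = 23)
  pls <- plant_insertions(bg, list(solo), positions = pos, strands = "+")
  expect_equal(nchar(pls$genome$seqs[[1]]), 30000 + fam$ltr_len + fam$tsd_len)

  # no insertions: identity
  pl0 <- plant_insertions(bg, list())
  expect_identical(pl0$genome$seqs, bg$seqs)

  expect_error(plant_insertions(bg, list(el),
                                positions = data.frame(seq_name = "chr1",
                                                       pos = 40000L),
                                strands = "+"),
               "out of bounds")
})

test_that("minus-strand planting reverse-complements and flips LTR roles", {
  fam <- test_family()
  bg <- simulate_background(20000, seed = 31)
  el <- synthesize_element(fam, 3e5, seed = 32)
  pl <- plant_insertions(bg, list(el),
                         positions = data.frame(seq_name = "chr1",
                                                pos = 9000L),
                         strands = "-")
  tr <- pl$truth$elements
  g <- pl$genome$seqs[[1]]
  planted <- substr(g, tr$start + 1, tr$end)
  expect_identical(planted, revcomp(el$seq))
  # 5' LTR of the element sits at the right end in genome coordinates
  expect_equal(tr$ltr5_end, tr$end)
  expect_equal(tr$ltr3_start, tr$start)
})

test_that("plant_genes records verbatim substrings outside elements", {
  w <- small_world()
  g <- w$truth$genes
  expect_equal(nrow(g), 6)
  for (i in seq_len(nrow(g))) {
    expect_identical(subseq0(w$genome, g$seq_name[i], g$start[i], g$end[i]),
                     g$sequence[i])
    overlap <- w$truth$elements$start < g$end[i] &
      w$truth$elements$end > g$start[i]
    expect_false(any(overlap))
  }
  expect_equal(nrow(plant_genes(w$genome, 0)), 0)
  tiny <- assembly(c(t = "ACGTACGT"))
  expect_error(plant_genes(tiny, 3, gene_len = 2000), "insufficient")
})

test_that("degradation with an all-zero profile is the identity", {
  w <- small_world()
  deg <- degrade_assembly(w$genome, w$truth, degradation_profile(),
                          seed = 1)
  expect_identical(deg$assembly$seqs, w$genome$seqs)
  expect_false(any(deg$truth$elements$removed))
})

test_that("ltr_gap_rate = 1 gaps every LTR", {
  w <- small_world()
  deg <- degrade_assembly(w$genome, w$truth,
                          degradation_profile(ltr_gap_rate = 1), seed = 2)
  el <- deg$truth$elements
  for (i in seq_len(nrow(el))) {
    ltr5 <- subseq0(deg$assembly, el$seq_name[i], el$ltr5_start[i],
                    el$ltr5_end[i])
    expect_true(grepl("N", ltr5, fixed = TRUE))
  }
})

test_that("gap sets are nested across rates for one seed", {
  w <- small_world()
  n_gaps <- vapply(c(0.2, 0.5, 0.9), function(r) {
    d <- degrade_assembly(w$genome, w$truth,
                          degradation_profile(ltr_gap_rate = r), seed = 5)
    ids_r <- d$edits$ltr_gaps$element_id
    length(unique(paste(d$edits$ltr_gaps$element_id,
                        d$edits$ltr_gaps$start)))
  }, numeric(1))
  expect_true(all(diff(n_gaps) >= 0))
  # subset relation of gapped loci between two rates
  d1 <- degrade_assembly(w$genome, w$truth,
                         degradation_profile(ltr_gap_rate = 0.3), seed = 5)
  d2 <- degrade_assembly(w$genome, w$truth,
                         degradation_profile(ltr_gap_rate = 0.8), seed = 5)
  key <- function(d) paste(d$edits$ltr_gaps$element_id,
                           d$edits$ltr_gaps$start)
  expect_true(all(key(d1) %in% key(d2)))
})

test_that("fragmentation splits into contigs that concatenate back", {
  w <- small_world()
  deg <- degrade_assembly(w$genome, w$truth,
                          degradation_profile(fragment_break_rate = 20),
                          seed = 3)
  expect_gt(length(deg$assembly$seqs), 1)
  expect_identical(paste(deg$assembly$seqs, collapse = ""),
                   w$genome$seqs[[1]])
  # unbroken lifted elements contain the same sequence as in the truth
  el <- deg$truth$elements
  ok <- !el$removed & !el$broken
  for (i in which(ok)[1:min(3, sum(ok))]) {
    orig <- subseq0(w$genome, w$truth$elements$seq_name[i],
                    w$truth$elements$start[i], w$truth$elements$end[i])
    lifted <- subseq0(deg$assembly, el$seq_name[i], el$start[i], el$end[i])
    expect_identical(lifted, orig)
  }
})

test_that("simulate_genome is byte-identical for a fixed seed", {
  fam <- test_family()
  s1 <- simulate_genome(length = 6e4, n_elements = 2, n_genes = 1,
                        families = list(fam), min_gap = 5000, seed = 77)
  s2 <- simulate_genome(length = 6e4, n_elements = 2, n_genes = 1,
                        families = list(fam), min_gap = 5000, seed = 77)
  expect_identical(s1$genome$seqs, s2$genome$seqs)
  expect_identical(s1$truth$elements, s2$truth$elements)
  s3 <- simulate_genome(length = 6e4, n_elements = 2, n_genes = 1,
                        families = list(fam), min_gap = 5000, seed = 78)
  expect_false(identical(s1$genome$seqs, s3$genome$seqs))
})
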