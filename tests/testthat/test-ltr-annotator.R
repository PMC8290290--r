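# Structural detection: candidates, boundary refinement, superfamily
# classification, quality filter, solo-LTRs, size classes.

test_that("planted elements are recovered with near-exact boundaries", {
  w <- small_world_annotated()
  tr <- w$truth$elements[!w$truth$elements$is_solo, ]
  det <- w$ann$elements
  found <- 0
  for (i in seq_len(nrow(tr))) {
    hit <- det[det$seq_name == tr$seq_name[i] &
                 abs(det$start - tr$start[i]) <= 60 &
                 abs(det$end - tr$end[i]) <= 60, ]
    if (nrow(hit) == 1) found <- found + 1
  }
  expect_equal(found, nrow(tr))
  # no overlapping candidates after "overlaps best" resolution
  det <- det[order(det$seq_name, det$start), ]
  if (nrow(det) > 1) {
    same <- det$seq_name[-1] == det$seq_name[-nrow(det)]
    expect_true(all(!same | det$start[-1] >= det$end[-nrow(det)]))
  }
})

test_that("the distance window excludes distant and dissimilar pairs", {
  set.seed(61)
  ltr <- paste0("TG", random_dna_str(496), "CA")
  # separation 30,000 bp (> max_dist): absent
  g1 <- assembly(c(c1 = paste0(random_dna_str(5000), ltr,
                               random_dna_str(29500), ltr,
                               random_dna_str(5000))))
  expect_equal(nrow(find_candidates(g1)), 0)

  # same pair at separation 8,000: present
  g2 <- assembly(c(c1 = paste0(random_dna_str(5000), ltr,
                               random_dna_str(7500), ltr,
                               random_dna_str(5000))))
  expect_equal(nrow(find_candidates(g2)), 1)

  # 18 % divergent copies (similarity ~82 < 85): absent
  x <- strsplit(ltr, "")[[1]]
  idx <- seq(4, 490, by = 5)[1:90]
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  x[idx] <- swap[x[idx]]
  ltr_div <- paste(x, collapse = "")
  g3 <- assembly(c(c1 = paste0(random_dna_str(5000), ltr,
                               random_dna_str(7500), ltr_div,
                               random_dna_str(5000))))
  expect_equal(nrow(find_candidates(g3)), 0)
})

test_that("refine_boundaries recovers motif and TSD", {
  set.seed(62)
  ltr <- paste0("TG", random_dna_str(396), "CA")
  inner <- random_dna_str(3600)
  tsd <- "ACGTA"
  g <- assembly(c(c1 = paste0(random_dna_str(4000), tsd, ltr, inner, ltr,
                              tsd, random_dna_str(4000))))
  cand <- find_candidates(g)
  ref <- refine_boundaries(cand, g)
  expect_equal(nrow(ref), 1)
  expect_true(ref$motif_ok)
  expect_equal(ref$motif_mismatches, 0L)
  expect_equal(ref$tsd, tsd)
  expect_equal(ref$start, 4005L)
  expect_equal(ref$end, 4005L + 4400L)

  # flanks sharing only a 3-bp repeat: tsd absent (below tsd_min)
  g2 <- assembly(c(c1 = paste0(random_dna_str(4000), "TAAGG", ltr, inner,
                               ltr, "CCAGG", random_dna_str(4000))))
  ref2 <- refine_boundaries(find_candidates(g2), g2)
  expect_equal(nrow(ref2), 1)
  expect_true(is.na(ref2$tsd))
})

test_that("superfamily classification follows internal domain order", {
  cand <- data.frame(seq_name = "c", start = 0L, end = 5000L)
  mk <- function(kinds, strand = "+") {
    data.frame(seq_name = "c", start = c(1000, 2000, 3000),
               end = c(1300, 2300, 3300), strand = strand, kind = kinds)
  }
  expect_equal(classify_superfamily(cand, mk(c("INT", "RT", "RH")))$superfamily,
               "RLC")
  expect_equal(classify_superfamily(cand, mk(c("RT", "RH", "INT")))$superfamily,
               "RLG")
  only_rt <- data.frame(seq_name = "c", start = 2000, end = 2300,
                        strand = "+", kind = "RT")
  expect_equal(classify_superfamily(cand, only_rt)$superfamily, "RLX")
  # minus strand: positional order INT,RT,RH read right-to-left = RH,RT,INT
  expect_equal(classify_superfamily(cand, mk(c("RH", "RT", "INT"),
                                             "-"))$superfamily, "RLC")
  expect_equal(classify_superfamily(cand, NULL)$superfamily, "RLX")
})

test_that("tandem_fraction separates arrays from random sequence", {
  set.seed(63)
  expect_lt(tandem_fraction(random_dna_str(5000)), 5)
  arr <- paste(rep("ACGTGATCGATC", 100), collapse = "")
  expect_gt(tandem_fraction(arr), 95)
  half <- paste0(random_dna_str(1200), arr)
  expect_gt(tandem_fraction(half), 45)
  expect_lt(tandem_fraction(half), 55)
})

test_that("quality_filter flags gaps, tandem arrays and domain anomalies", {
  w <- small_world_annotated()
  clean <- w$ann$elements[1, ]
  qf <- quality_filter(clean, w$genome, w$truth$domains)
  expect_true(qf$report$pass)
  expect_equal(qf$report$reasons, "")

  # inject one N inside the span
  g2 <- w$genome
  mid <- floor((clean$start + clean$end) / 2)
  substr(g2$seqs[[clean$seq_name]], mid, mid) <- "N"
  qf2 <- quality_filter(clean, g2, w$truth$domains)
  expect_false(qf2$report$pass)
  expect_match(qf2$report$reasons, "gap")

  # internal region half-covered by a 12-bp tandem array
  g3 <- w$genome
  arr_len <- floor((clean$ltr3_start - clean$ltr5_end) * 0.5)
  arr <- paste(rep("ACGTGATCGATC", ceiling(arr_len / 12)), collapse = "")
  substr(g3$seqs[[clean$seq_name]], clean$ltr5_end + 1,
         clean$ltr5_end + arr_len) <- substr(arr, 1, arr_len)
  qf3 <- quality_filter(clean, g3, w$truth$domains)
  expect_false(qf3$report$pass)
  expect_match(qf3$report$reasons, "tandem_inner")

  # duplicated TE domain kind
  dup <- rbind(w$truth$domains,
               data.frame(element_id = "x", kind = "RT",
                          seq_name = clean$seq_name,
                          start = clean$start + 500,
                          end = clean$start + 800, strand = "+"))
  qf4 <- quality_filter(clean, w$genome, dup)
  expect_false(qf4$report$pass)
  expect_match(qf4$report$reasons, "duplicated_domain")

  # GENE domain inside the element
  gene_dom <- data.frame(element_id = "y", kind = "GENE",
                         seq_name = clean$seq_name,
                         start = clean$start + 600, end = clean$start + 900,
                         strand = "+")
  qf5 <- quality_filter(clean, w$genome, rbind(w$truth$domains, gene_dom))
  expect_match(qf5$report$reasons, "gene_domain")
})

test_that("find_solo_ltrs recovers planted solos and excludes paired LTRs", {
  w <- small_world_annotated()
  solos_truth <- w$truth$elements[w$truth$elements$is_solo, ]
  fam_name <- w$families[[1]]$name
  solos <- find_solo_ltrs(w$genome, w$consensus[[fam_name]],
                          full_length = w$ann$elements)
  expect_equal(nrow(solos), nrow(solos_truth))
  for (i in seq_len(nrow(solos_truth))) {
    hit <- solos[abs(solos$start - solos_truth$start[i]) <= 20, ]
    expect_equal(nrow(hit), 1)
    expect_false(is.na(hit$tsd))
  }
  # no hit overlaps a full-length element span
  for (i in seq_len(nrow(solos))) {
    fl <- w$ann$elements
    expect_false(any(fl$seq_name == solos$seq_name[i] &
                       fl$start < solos$end[i] & fl$end > solos$start[i]))
  }
  # clean background: empty result
  bg <- simulate_background(50000, seed = 64)
  empty <- find_solo_ltrs(bg, w$consensus[[fam_name]])
  expect_equal(nrow(empty), 0)
  expect_error(find_solo_ltrs(bg, "TGAC"), "min_ltr")
})

test_that("select_size_class applies the BARE1 length windows", {
  el <- data.frame(start = c(0, 0, 0), end = c(8400, 8900, 9500))
  expect_equal(nrow(select_size_class(el)), 1)
  expect_equal(select_size_class(el)$end, 8900)
  expect_equal(nrow(select_size_class(el, gappy = TRUE)), 2)
})

test_that("detection is strand-symmetric", {
  fam <- test_family()
  sim <- simulate_genome(length = 1.2e5, n_elements = 3,
                         families = list(fam), age_range = c(2e5, 8e5),
                         seed = 65)
  fwd <- find_candidates(sim$genome)
  L <- sim$genome$lengths[[1]]
  rc <- assembly(setNames(revcomp(sim$genome$seqs[[1]]), "chr1"))
  rev <- find_candidates(rc)
  expect_equal(nrow(fwd), nrow(rev))
  expect_setequal(L - fwd$end, rev$start)
  expect_setequal(L - fwd$start, rev$end)
})
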