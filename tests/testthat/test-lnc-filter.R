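test_that("coding potential score follows the ORF-fraction formula", {
  # no ATG anywhere: no ORF, score -1
  expect_equal(coding_potential_score("ACCTTTACCTTTACC"), -1)
  # a sequence that is one full-length ORF scores +1 exactly
  full <- seq_with_orf(300, 300)
  expect_equal(coding_potential_score(full), 1)
  # 90 nt ORF in a 300 nt transcript: 2 * 90/300 - 1 = -0.4
  expect_equal(coding_potential_score(seq_with_orf(300, 90)), -0.4)
  expect_error(coding_potential_score(""), "empty")
})

test_that("coding score agrees with a brute-force ORF enumeration", {
  withr::local_seed(17)
  for (i in 1:50) {
    s <- rand_dna(sample(30:400, 1))
    expect_equal(
      coding_potential_score(s),
      2 * oracle_longest_orf(s) / nchar(s) - 1
    )
  }
})

test_that("scores stay in [-1, 1] on both strands", {
  withr::local_seed(23)
  s <- vapply(1:40, function(i) rand_dna(sample(50:500, 1)), "")
  for (x in list(coding_potential_score(s), coding_potential_score(reverse_complement(s)))) {
    expect_true(all(x >= -1 & x <= 1))
  }
})

test_that("the non-coding filter is strict and bidirectional", {
  # both strands negative: kept
  neg <- seq_with_orf(300, 90)
  # forward exactly 0 (ORF covering half): removed by the strict rule
  half <- seq_with_orf(300, 150)
  expect_equal(coding_potential_score(half), 0)
  # forward negative but reverse strand coding: removed
  revcoding <- reverse_complement(seq_with_orf(300, 240))
  ts <- make_ts(
    list(
      keep = list(chrom = "chr1", start = 1, end = 300),
      zero = list(chrom = "chr1", start = 1001, end = 1300),
      revc = list(chrom = "chr1", start = 2001, end = 2300)
    ),
    seqs = c(keep = neg, zero = half, revc = revcoding)
  )
  keep <- filter_noncoding(ts)
  expect_equal(unname(keep), c(TRUE, FALSE, FALSE))
})

test_that("length filter is strictly greater-than 200", {
  ts <- make_ts(list(
    a = list(chrom = "chr1", start = 1, end = 199), # 199 nt
    b = list(chrom = "chr1", start = 1001, end = 1200), # 200 nt
    c = list(chrom = "chr1", start = 2001, end = 2202) # 202 nt
  ))
  expect_equal(unname(filter_length(ts)), c(FALSE, FALSE, TRUE))
})

test_that("intergenic classification uses span overlap and union across annotations", {
  ts <- make_ts(list(
    genic = list(chrom = "chr1", start = 1000, end = 2000),
    inter = list(chrom = "chr1", start = 3000, end = 3500)
  ))
  ann_a <- genomic_intervals("chr1", 1500, 2500)
  expect_equal(
    unname(classify_intergenic(ts, ann_a)),
    c(FALSE, TRUE)
  )
  # genic in B only: union of per-annotation intergenic calls retains it
  ann_b <- genomic_intervals("chr1", c(900, 3100), c(1100, 3400))
  expect_equal(
    unname(classify_intergenic(ts, list(ann_a, ann_b))),
    c(FALSE, TRUE)
  )
  expect_equal(
    unname(classify_intergenic(ts, list(ann_a, ann_b), combine = "intersection")),
    c(FALSE, FALSE)
  )
  expect_warning(
    out <- classify_intergenic(ts, GenomicRanges::GRanges()),
    "empty annotation"
  )
  expect_true(all(out))
})

test_that("domain screen finds planted motifs and nothing in random sequence", {
  withr::local_seed(31)
  motif <- "WWHDKKLW"
  gc <- Biostrings::GENETIC_CODE
  nt <- paste(vapply(strsplit(motif, "")[[1]], function(a) names(gc)[gc == a][1], ""),
    collapse = ""
  )
  # plant in frame +2 of the forward strand
  planted <- paste0("C", nt, rand_dna(50))
  expect_true(scan_protein_domains(planted, motif))
  # plant on the reverse strand
  expect_true(scan_protein_domains(reverse_complement(planted), motif))
  # 100 random 1 kb sequences vs a length-10 motif: expect zero hits
  hits <- scan_protein_domains(
    vapply(1:100, function(i) rand_dna(1000), ""),
    "WWHDKKLWEH"
  )
  expect_equal(sum(hits), 0)
  # too short to translate a 6-mer motif
  expect_false(scan_protein_domains("ATGCC", "MMMMMM"))
})

test_that("homology screen detects embedded sequence and honours its thresholds", {
  withr::local_seed(37)
  gene <- rand_dna(2000)
  known <- Biostrings::DNAStringSet(c(g1 = gene))
  # exact 600 bp substring: identity 1, coverage 1
  q <- substr(gene, 501, 1100)
  expect_true(has_homolog(q, known))
  # reverse-complemented copy is also found
  expect_true(has_homolog(reverse_complement(q), known))
  # sequence sharing no 11-mer: alphabet disjoint from the gene is impossible,
  # so use a short query of repeated dinucleotides absent from the gene index
  noq <- rand_dna(600)
  expect_false(has_homolog(noq, known))
  # ~60% identity over 40% of the transcript: below both thresholds
  frag <- strsplit(substr(gene, 1, 240), "")[[1]]
  mut <- seq(1, 240, by = 3) # mutate every third base, keeping 11-mer seeds away
  frag[mut] <- vapply(frag[mut], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  q2 <- paste0(paste(frag, collapse = ""), rand_dna(360))
  expect_false(has_homolog(q2, known))
  # shorter than the seed length
  expect_warning(out <- has_homolog("ACGTACGT", known), "seed length")
  expect_false(out)
})

test_that("cascade recovers the planted truth exactly, in any input order", {
  gen <- sim_annotation(
    n_genes = 10, n_genic = 15, n_short = 8, n_coding = 15,
    n_domain = 8, n_homolog = 8, n_lncrna = 26, seed = 19
  )
  cs <- run_cascade(gen$transcripts, gen$annotation, gen$motifs, gen$known)
  truth_ids <- gen$truth$id[gen$truth$is_lncrna]
  expect_setequal(names(cs$candidates), truth_ids)
  expect_true(all(diff(cs$report$survivors) <= 0))
  expect_true(all(cs$report$input_count[-1] == cs$report$survivors[-5]))

  # shuffled input gives the same survivor set
  withr::local_seed(4)
  shuffled <- gen$transcripts[sample(length(gen$transcripts))]
  cs2 <- run_cascade(shuffled, gen$annotation, gen$motifs, gen$known)
  expect_setequal(names(cs2$candidates), truth_ids)
  expect_equal(sort(cs2$report$survivors), sort(cs$report$survivors))
})

test_that("cascade merges overlapping survivors and handles empty input", {
  # two overlapping intergenic survivors merge into one candidate interval
  s1 <- seq_with_orf(401, 90)
  s2 <- seq_with_orf(501, 90)
  ts <- make_ts(
    list(
      a = list(chrom = "chr1", start = 5101, end = 5501),
      b = list(chrom = "chr1", start = 5401, end = 5901)
    ),
    condition = "dry",
    seqs = c(a = s1, b = s2)
  )
  cs <- run_cascade(
    ts, genomic_intervals("chr1", 1, 100),
    motifs = default_domain_motifs(),
    known = Biostrings::DNAStringSet(c(k = rand_dna(500)))
  )
  expect_equal(length(cs$merged$dry), 1L)
  expect_equal(BiocGenerics::start(cs$merged$dry), 5101L)
  expect_equal(BiocGenerics::end(cs$merged$dry), 5901L)

  empty <- ts[character(0)]
  cs0 <- run_cascade(
    empty, genomic_intervals("chr1", 1, 100),
    motifs = default_domain_motifs(),
    known = Biostrings::DNAStringSet(c(k = rand_dna(500)))
  )
  expect_null(cs0$candidates)
  expect_true(all(cs0$report$survivors == 0))
})
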