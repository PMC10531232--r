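# Shared fixture builders; everything is generated in code under fixed seeds.

make_ts <- function(exon_list, condition = NULL, seqs = NULL) {
  exl <- GenomicRanges::GRangesList(lapply(exon_list, function(e) {
    GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start, e$end),
      strand = e$strand %||% "*"
    )
  }))
  names(exl) <- names(exon_list)
  if (!is.null(seqs)) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  transcript_set(exl, condition = condition, seqs = seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")

# brute-force longest-ORF scan: every ATG, walk codons to the first stop
oracle_longest_orf <- function(s) {
  s <- toupper(s)
  L <- nchar(s)
  best <- 0L
  for (i in seq_len(max(0L, L - 5L))) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i + 3L
    while (j + 2L <= L) {
      cod <- substr(s, j, j + 2)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, j + 2L - i + 1L)
        break
      }
      j <- j + 3L
    }
  }
  best
}

# an ORF of orf_nt nucleotides (ATG..TAA) padded with stop-rich flanks so no
# longer ORF can arise; total length L
seq_with_orf <- function(L, orf_nt) {
  stopifnot(orf_nt %% 3 == 0, orf_nt >= 6, orf_nt <= L)
  n_mid <- orf_nt / 3 - 2
  orf <- paste0("ATG", paste(rep("GGC", n_mid), collapse = ""), "TAA")
  pad <- L - orf_nt
  left <- floor(pad / 2)
  flank <- function(n) paste(rep_len(strsplit("TAA", "")[[1]], n), collapse = "")
  paste0(flank(left), orf, flank(pad - left))
}
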