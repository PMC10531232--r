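#' Classify transcripts as intergenic
#'
#' A transcript is intergenic with respect to an annotation iff its genomic
#' span overlaps no annotated gene span (the "u" class code of transcript
#' comparison tools; span-level, strand-ignored). When two annotations are
#' supplied the per-annotation intergenic calls are combined by union, i.e.
#' a transcript intergenic in either annotation is retained; set
#' `combine = "intersection"` to require both.
#'
#' @param ts a `TranscriptSet`.
#' @param annotations a `GRanges` of gene spans, or a list of one or two
#'   such objects.
#' @param combine how to combine calls across two annotations.
#' @return named logical vector over transcripts.
#' @export
classify_intergenic <- function(ts, annotations, combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  if (!is.list(annotations)) annotations <- list(annotations)
  spans <- tx_spans(ts)
  calls <- lapply(annotations, function(ann) {
    if (length(ann) == 0L) {
      warnf("empty annotation: all transcripts called intergenic")
      return(rep(TRUE, length(spans)))
    }
    GenomicRanges::countOverlaps(spans, ann, ignore.strand = TRUE) == 0L
  })
  out <- if (length(calls) == 1L) {
    calls[[1]]
  } else if (combine == "union") {
    Reduce(`|`, calls)
  } else {
    Reduce(`&`, calls)
  }
  stats::setNames(out, names(ts))
}

#' Length filter for lncRNA candidates
#'
#' Keeps transcripts strictly longer than `min_len` nucleotides (spliced
#' length). The strict rule follows the standard lncRNA definition
#' ("longer than 200 bp"); a 200 nt transcript is removed.
#'
#' @param ts a `TranscriptSet`.
#' @param min_len length threshold in nucleotides.
#' @return named logical vector (TRUE = keep).
#' @export
filter_length <- function(ts, min_len = 200L) {
  tx_lengths(ts) > min_len
}

#' Coding potential score
#'
#' An ORF-based coding potential scorer mapping a nucleotide sequence to
#' `[-1, 1]`: with `L` the sequence length and `O` the nucleotide length of
#' the longest open reading frame (ATG to the first in-frame stop, stop
#' codon included) in any of the three frames of the given strand,
#' `score = 2 * O / L - 1`. A sequence whose longest ORF covers half its
#' length scores 0; no ORF at all scores -1. Negative scores are read as
#' non-coding. The scorer is deterministic and pluggable: any function with
#' the same signature can replace it in [run_cascade()].
#'
#' @param seqs character vector or [Biostrings::DNAStringSet] (alphabet
#'   ACGTN); only the given strand is scanned.
#' @return numeric vector of scores in `[-1, 1]`.
#' @examples
#' coding_potential_score("ACGTTTACGTTT") # no ATG: -1
#' @export
coding_potential_score <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (any(!nzchar(seqs))) stopf("empty sequence")
  vapply(toupper(seqs), function(s) {
    L <- nchar(s)
    2 * longest_orf(s) / L - 1
  }, 0, USE.NAMES = FALSE)
}

# Longest ORF (nt, stop included) over the three forward frames.
longest_orf <- function(s) {
  L <- nchar(s)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (f in 0:2) {
    n_cod <- (L - f) %/% 3L
    if (n_cod < 2L) next
    first <- seq.int(f + 1L, by = 3L, length.out = n_cod)
    codons <- substring(s, first, first + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% stops)
    if (length(atg) == 0L || length(stp) == 0L) next
    # first stop at or after each start, in codon units
    idx <- findInterval(atg - 1L, stp) + 1L
    ok <- idx <= length(stp)
    if (!any(ok)) next
    len <- (stp[idx[ok]] - atg[ok] + 1L) * 3L
    best <- max(best, len)
  }
  best
}

#' Reverse complement of nucleotide sequences
#'
#' @param seqs character vector or `DNAStringSet`.
#' @return character vector.
#' @export
reverse_complement <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  vapply(seqs, function(s) {
    x <- strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "", fixed = TRUE)[[1]]
    paste(rev(x), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# codon -> amino acid lookup (stops as '*'), built once from the standard code
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

#' Bidirectional non-coding filter
#'
#' A candidate is retained iff its coding potential score is strictly below
#' zero on the forward strand AND on the reverse complement. A score of
#' exactly zero on either strand removes the transcript ("below 0" is
#' strict). Transcripts with no attached sequence are dropped with a
#' warning.
#'
#' @param ts a `TranscriptSet` with sequences.
#' @param scorer a coding-potential scoring function; defaults to
#'   [coding_potential_score()].
#' @return named logical vector (TRUE = keep).
#' @export
filter_noncoding <- function(ts, scorer = coding_potential_score) {
  if (is.null(ts$seqs)) stopf("transcript set has no sequences")
  keep <- rep(FALSE, length(ts))
  names(keep) <- names(ts)
  have <- names(ts)[Biostrings::width(ts$seqs) > 0L]
  if (length(have) < length(ts)) {
    warnf("%d transcripts dropped: missing sequence", length(ts) - length(have))
  }
  s <- as.character(ts$seqs[have])
  keep[have] <- scorer(s) < 0 & scorer(reverse_complement(s)) < 0
  keep
}

#' Protein domain screen
#'
#' Translates all six reading frames (standard genetic code, stops as `*`,
#' ambiguous codons as `X`) and reports whether any supplied amino-acid
#' motif occurs as an exact substring of any frame. This is a motif-set
#' screen with a pluggable interface standing in front of profile-HMM domain
#' databases; transcripts with a hit are treated as harbouring a known
#' protein domain and removed from the candidate list.
#'
#' @param seqs character vector or `DNAStringSet`.
#' @param motifs character vector of amino-acid motifs (length >= 6).
#' @return logical vector: TRUE iff any motif is found.
#' @export
scan_protein_domains <- function(seqs, motifs) {
  if (length(motifs) == 0L) stopf("motif set must be non-empty")
  if (any(nchar(motifs) < 6L)) stopf("motifs must be at least 6 amino acids")
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  vapply(toupper(seqs), function(s) {
    frames <- six_frame_translations(s)
    any(vapply(
      motifs,
      function(m) any(grepl(m, frames, fixed = TRUE)),
      TRUE
    ))
  }, TRUE, USE.NAMES = FALSE)
}

# Translate all six frames of a nucleotide string (standard code, stops as
# '*', codons containing other letters as 'X').
six_frame_translations <- function(s) {
  gc_tab <- codon_table()
  out <- character(0)
  for (seq in c(s, reverse_complement(s))) {
    L <- nchar(seq)
    for (f in 0:2) {
      n_cod <- (L - f) %/% 3L
      if (n_cod < 1L) next
      first <- seq.int(f + 1L, by = 3L, length.out = n_cod)
      aa <- gc_tab[substring(seq, first, first + 2L)]
      aa[is.na(aa)] <- "X"
      out <- c(out, paste(aa, collapse = ""))
    }
  }
  out
}

#' Homology screen against known gene sequences
#'
#' A k-mer-seeded, ungapped identity screen standing in front of full local
#' alignment: exact shared k-mers between the transcript (either strand) and
#' a known gene seed an ungapped extension in both directions (match +1,
#' mismatch -1, abandoning a direction once the running score falls `xdrop`
#' below its best). A transcript "has a homolog" iff some extended segment
#' reaches at least `min_identity` identity while covering at least
#' `min_cov` of the transcript length.
#'
#' @param seqs character vector or `DNAStringSet` of transcripts.
#' @param known a `DNAStringSet` (or named character vector, or FASTA path)
#'   of known gene sequences.
#' @param k seed length.
#' @param min_identity minimum identity of the extended segment.
#' @param min_cov minimum fraction of the transcript covered.
#' @param xdrop score drop tolerated before an extension stops.
#' @return logical vector: TRUE iff a homolog is found.
#' @export
has_homolog <- function(seqs, known, k = 11L, min_identity = 0.9,
                        min_cov = 0.5, xdrop = 5L) {
  idx <- if (inherits(known, "homolog_index")) known else homolog_index(known, k = k)
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  vapply(
    toupper(seqs), query_homolog,
    TRUE,
    index = idx, min_identity = min_identity, min_cov = min_cov, xdrop = xdrop,
    USE.NAMES = FALSE
  )
}

#' Prebuild the k-mer seed index of a known gene set
#'
#' Exposed so the index can be built once and reused across many
#' [has_homolog()] calls.
#'
#' @inheritParams has_homolog
#' @return an object of class `homolog_index`.
#' @export
homolog_index <- function(known, k = 11L) {
  if (is.character(known) && length(known) == 1L && file.exists(known)) {
    known <- Biostrings::readDNAStringSet(known)
  }
  known <- toupper(as.character(known))
  if (length(known) == 0L) stopf("`known` gene set must be non-empty")
  # one combined seed map over all genes: kmer -> (gene, position) pairs
  km_all <- lapply(seq_along(known), function(gi) {
    g <- known[[gi]]
    n <- nchar(g) - k + 1L
    if (n < 1L) {
      return(NULL)
    }
    list(km = substring(g, 1:n, k:nchar(g)), gi = rep(gi, n), pos = seq_len(n))
  })
  km <- unlist(lapply(km_all, `[[`, "km"))
  loc <- cbind(
    gi = unlist(lapply(km_all, `[[`, "gi")),
    pos = unlist(lapply(km_all, `[[`, "pos"))
  )
  structure(
    list(
      chars = lapply(known, function(g) strsplit(g, "", fixed = TRUE)[[1]]),
      idx = split(seq_len(nrow(loc)), km),
      loc = loc,
      k = k
    ),
    class = "homolog_index"
  )
}

query_homolog <- function(q, index, min_identity, min_cov, xdrop) {
  k <- index$k
  if (nchar(q) < k) {
    warnf("transcript shorter than seed length k = %d", k)
    return(FALSE)
  }
  for (qs in c(q, reverse_complement(q))) {
    qc <- strsplit(qs, "", fixed = TRUE)[[1]]
    nq <- length(qc)
    qkm <- substring(qs, 1:(nq - k + 1L), k:nq)
    hits <- index$idx[qkm]
    hit_at <- which(lengths(hits) > 0L)
    if (length(hit_at) == 0L) next
    seen <- character(0) # explored (gene, diagonal) combinations
    for (qi in hit_at) {
      for (row in hits[[qi]]) {
        gi <- index$loc[row, "gi"]
        si <- index$loc[row, "pos"]
        key <- paste0(gi, ":", si - qi)
        if (key %in% seen) next
        seen <- c(seen, key)
        seg <- xdrop_extend(qc, index$chars[[gi]], qi, si, k, xdrop)
        if (seg$identity >= min_identity && seg$len / nq >= min_cov) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

# Ungapped X-drop extension of a seed on one diagonal.
# Returns the best-scoring segment containing the seed.
xdrop_extend <- function(qc, sc, qi, si, k, xdrop) {
  # right of the seed
  best <- 0L
  cur <- 0L
  right <- 0L
  matches_r <- 0L
  best_matches_r <- 0L
  i <- qi + k
  j <- si + k
  while (i <= length(qc) && j <= length(sc)) {
    if (qc[i] == sc[j]) {
      cur <- cur + 1L
      matches_r <- matches_r + 1L
    } else {
      cur <- cur - 1L
    }
    if (cur > best) {
      best <- cur
      right <- i - (qi + k) + 1L
      best_matches_r <- matches_r
    }
    if (best - cur >= xdrop) break
    i <- i + 1L
    j <- j + 1L
  }
  # left of the seed
  best <- 0L
  cur <- 0L
  left <- 0L
  matches_l <- 0L
  best_matches_l <- 0L
  i <- qi - 1L
  j <- si - 1L
  while (i >= 1L && j >= 1L) {
    if (qc[i] == sc[j]) {
      cur <- cur + 1L
      matches_l <- matches_l + 1L
    } else {
      cur <- cur - 1L
    }
    if (cur > best) {
      best <- cur
      left <- qi - i
      best_matches_l <- matches_l
    }
    if (best - cur >= xdrop) break
    i <- i - 1L
    j <- j - 1L
  }
  len <- left + k + right
  list(len = len, identity = (best_matches_l + k + best_matches_r) / len)
}

#' Run the five-criterion lncRNA candidate cascade
#'
#' Applies, in order: intergenic classification, length filter (> 200 nt),
#' bidirectional non-coding filter, protein-domain screen (hits removed) and
#' homology screen (hits removed); survivors are merged by overlap into
#' contiguous candidate intervals per condition. Each stage only sees the
#' survivors of the previous one; a per-stage survivor report and
#' per-transcript provenance are returned alongside the candidates.
#'
#' @param ts a `TranscriptSet` with sequences and (optionally) conditions.
#' @param annotations gene-span annotation(s), see [classify_intergenic()].
#' @param motifs amino-acid motif set for the domain screen.
#' @param known known gene sequences for the homology screen.
#' @param min_len length threshold (strictly greater than).
#' @param combine two-annotation combination rule.
#' @param scorer coding potential scorer.
#' @param k,min_identity,min_cov,xdrop homology screen parameters.
#' @return an object of class `CandidateSet`: list with `candidates` (the
#'   surviving `TranscriptSet`), `merged` (named list of merged candidate
#'   `GRanges`, one per condition), `provenance` (per-transcript stage
#'   pass/fail, `NA` when a stage was not reached) and `report` (stage,
#'   input count, survivors).
#' @export
run_cascade <- function(ts, annotations, motifs, known,
                        min_len = 200L, combine = "union",
                        scorer = coding_potential_score,
                        k = 11L, min_identity = 0.9, min_cov = 0.5, xdrop = 5L) {
  stages <- c("intergenic", "length", "noncoding", "domain", "homology")
  ids <- names(ts)
  prov <- matrix(NA, nrow = length(ids), ncol = length(stages),
    dimnames = list(ids, stages)
  )
  report <- data.frame(
    stage = stages,
    input_count = integer(length(stages)),
    survivors = integer(length(stages))
  )
  alive <- ids
  run_stage <- function(stage, pass) {
    i <- match(stage, stages)
    report$input_count[i] <<- length(alive)
    prov[alive, stage] <<- pass[alive]
    alive <<- alive[pass[alive]]
    report$survivors[i] <<- length(alive)
  }
  if (length(ids) > 0L) {
    run_stage("intergenic", classify_intergenic(ts, annotations, combine = combine))
    if (length(alive)) run_stage("length", filter_length(ts[alive], min_len = min_len))
    if (length(alive)) run_stage("noncoding", filter_noncoding(ts[alive], scorer = scorer))
    if (length(alive)) {
      hit <- scan_protein_domains(ts$seqs[alive], motifs)
      run_stage("domain", stats::setNames(!hit, alive))
    }
    if (length(alive)) {
      hit <- has_homolog(ts$seqs[alive], known,
        k = k, min_identity = min_identity, min_cov = min_cov, xdrop = xdrop
      )
      run_stage("homology", stats::setNames(!hit, alive))
    }
  }
  survivors <- if (length(alive)) ts[alive] else NULL
  merged <- list()
  if (length(alive)) {
    spans <- tx_spans(survivors)
    cond <- survivors$condition %||% stats::setNames(rep("all", length(alive)), alive)
    merged <- lapply(split(seq_along(spans), cond[names(spans)]), function(ix) {
      merge_intervals(spans[ix])
    })
  }
  structure(
    list(candidates = survivors, merged = merged, provenance = prov, report = report),
    class = "CandidateSet"
  )
}

#' @export
print.CandidateSet <- function(x, ...) {
  cat("lncRNA candidate cascade\n")
  print(x$report, row.names = FALSE)
  n_merged <- vapply(x$merged, length, 1L)
  if (length(n_merged)) {
    cat(
      "merged candidates:",
      paste(sprintf("%s=%d", names(n_merged), n_merged), collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' Default amino-acid motif set for the domain screen
#'
#' A small set of synthetic screening motifs used by the generators and as a
#' default for [scan_protein_domains()]. Real screens should supply motifs
#' distilled from curated domain databases.
#'
#' @return character vector of motifs.
#' @export
default_domain_motifs <- function() {
  c("WWHDKKLW", "MHHRRCWE", "DDKYWQNP", "KKLWEEHF")
}
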