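#' Synthetic annotation, transcripts and ground-truth labels
#'
#' Generates a reference gene annotation plus novel transcripts in labelled
#' classes, so that every stage of the candidate cascade has planted
#' positives and negatives:
#'
#' * `genic` - overlapping a reference gene (fails the intergenic test);
#' * `short` - intergenic but at most 200 nt (fails the length filter;
#'   lengths straddle the threshold, including exactly 200);
#' * `coding` - intergenic with a planted ORF covering >50% of its length
#'   (fails the non-coding filter);
#' * `domain` - intergenic, non-coding on both strands, with a screening
#'   motif encoded in one reading frame (fails the domain screen);
#' * `homolog` - intergenic, non-coding, embedded verbatim in a synthetic
#'   known gene (fails the homology screen);
#' * `lncrna` - intergenic, >200 nt, non-coding both strands, no motif, no
#'   homolog: the planted true lncRNAs.
#'
#' Class constraints are enforced by construction plus rejection sampling
#' with the package's own filters, which makes the planted labels exactly
#' separable by the cascade.
#'
#' @param n_genes number of reference genes.
#' @param n_genic,n_short,n_coding,n_domain,n_homolog,n_lncrna class sizes.
#' @param genome named vector of chromosome sizes (default 3 x 1 Mb).
#' @param len_range length range (nt) for regular transcripts.
#' @param gene_len_range length range for reference genes.
#' @param motifs amino-acid motif set planted in the `domain` class.
#' @param n_known number of synthetic known genes for the homology screen.
#' @param condition condition label attached to the transcripts.
#' @param seed RNG seed; identical seeds give identical output.
#' @return list with `annotation` (gene `GRanges`), `transcripts`
#'   (`TranscriptSet` with sequences), `known` (`DNAStringSet`), `motifs`
#'   and `truth` (data.frame of per-transcript labels, one row per
#'   transcript, with the composite `is_lncrna` flag).
#' @export
sim_annotation <- function(n_genes = 15L, n_genic = 20L, n_short = 10L,
                           n_coding = 20L, n_domain = 10L, n_homolog = 10L,
                           n_lncrna = 30L,
                           genome = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
                           len_range = c(250L, 2000L),
                           gene_len_range = c(2000L, 8000L),
                           motifs = default_domain_motifs(),
                           n_known = 8L,
                           condition = "dry",
                           seed = 1L) {
  with_seed(seed, {
    known <- Biostrings::DNAStringSet(vapply(
      seq_len(n_known),
      function(i) random_dna(sample(1500:3000, 1)), ""
    ))
    names(known) <- sprintf("known_gene_%d", seq_len(n_known))
    kidx <- homolog_index(known)

    classes <- rep(
      c("genic", "short", "coding", "domain", "homolog", "lncrna"),
      c(n_genic, n_short, n_coding, n_domain, n_homolog, n_lncrna)
    )
    n_tx <- length(classes)
    lens <- integer(n_tx)
    lens[classes == "short"] <- sample(120:200, sum(classes == "short"), replace = TRUE)
    reg <- classes != "short"
    lens[reg] <- sample(len_range[1]:len_range[2], sum(reg), replace = TRUE)
    if (sum(classes == "short") >= 2L) {
      # pin boundary cases: exactly 200 nt is removed by the strict rule
      lens[which(classes == "short")[1:2]] <- c(200L, 199L)
    }

    seqs <- character(n_tx)
    for (i in seq_len(n_tx)) {
      seqs[i] <- switch(classes[i],
        genic = random_dna(lens[i]),
        short = make_noncoding_seq(lens[i], motifs, kidx),
        coding = make_coding_seq(lens[i]),
        domain = make_domain_seq(lens[i], motifs),
        # homologs are non-coding like true candidates and fail only the
        # homology screen: each is embedded verbatim in a planted known gene
        homolog = make_noncoding_seq(lens[i], motifs, kidx),
        lncrna = make_noncoding_seq(lens[i], motifs, kidx)
      )
    }
    hom <- which(classes == "homolog")
    if (length(hom)) {
      planted <- Biostrings::DNAStringSet(vapply(seqs[hom], function(s) {
        paste0(random_dna(sample(200:500, 1)), s, random_dna(sample(200:500, 1)))
      }, "", USE.NAMES = FALSE))
      names(planted) <- sprintf("known_gene_planted_%d", seq_along(hom))
      known <- c(known, planted)
    }

    # place genes and transcripts without unintended overlap: walk each
    # chromosome advancing by feature span plus a random gap
    placed <- place_features(
      gene_lens = sample(gene_len_range[1]:gene_len_range[2], n_genes, replace = TRUE),
      tx_lens = lens, tx_genic = classes == "genic", genome = genome
    )
    annotation <- placed$genes
    ids <- sprintf("tx_%03d", seq_len(n_tx))
    exl <- placed$exons
    names(exl) <- ids
    seq_set <- Biostrings::DNAStringSet(seqs)
    names(seq_set) <- ids
    ts <- transcript_set(exl, condition = condition, seqs = seq_set)

    truth <- data.frame(
      id = ids,
      class = classes,
      length = lens,
      intergenic = classes != "genic",
      length_ok = lens > 200L,
      noncoding_both = !(classes %in% "coding"),
      has_domain = classes == "domain",
      has_homolog = classes == "homolog",
      stringsAsFactors = FALSE
    )
    truth$is_lncrna <- truth$intergenic & truth$length_ok &
      truth$noncoding_both & !truth$has_domain & !truth$has_homolog
    list(
      annotation = annotation, transcripts = ts, known = known,
      motifs = motifs, truth = truth
    )
  })
}

random_dna <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# Rejection-sample a sequence that is non-coding on both strands, motif-free
# and without homology to the known gene set.
make_noncoding_seq <- function(L, motifs, known, max_tries = 500L) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(L)
    if (coding_potential_score(s) >= 0) next
    if (coding_potential_score(reverse_complement(s)) >= 0) next
    if (scan_protein_domains(s, motifs)) next
    if (suppressWarnings(has_homolog(s, known))) next
    return(s)
  }
  stopf("failed to generate a non-coding sequence of length %d", L)
}

# Plant an ORF covering ~60% of the sequence: score >= +0.2.
make_coding_seq <- function(L) {
  n_cod <- ceiling(0.6 * L / 3) + 1L
  body <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA", "ATG"))
  orf <- paste0("ATG", paste(sample(body, n_cod - 2L, replace = TRUE), collapse = ""), "TAA")
  pad <- L - nchar(orf)
  left <- sample(0:pad, 1)
  paste0(random_dna(left), orf, random_dna(pad - left))
}

# Non-coding background with one motif encoded at a random offset (any
# offset lands the motif in one of the six frames).
make_domain_seq <- function(L, motifs, max_tries = 500L) {
  motif <- sample(motifs, 1)
  gc <- Biostrings::GENETIC_CODE
  nt <- paste(vapply(
    strsplit(motif, "")[[1]],
    function(aa) names(gc)[gc == aa][1], ""
  ), collapse = "")
  if (nchar(nt) + 6L > L) stopf("sequence too short to host motif")
  for (i in seq_len(max_tries)) {
    off <- sample(3:(L - nchar(nt) - 3L), 1)
    s <- paste0(random_dna(off), nt, random_dna(L - off - nchar(nt)))
    if (coding_potential_score(s) < 0 &&
      coding_potential_score(reverse_complement(s)) < 0) {
      return(s)
    }
  }
  stopf("failed to generate a domain-bearing non-coding sequence")
}

# Lay out genes and transcripts along the chromosomes. Genic transcripts
# are nested inside a gene; all other features get disjoint slots.
place_features <- function(gene_lens, tx_lens, tx_genic, genome) {
  chroms <- names(genome)
  ptr <- stats::setNames(rep(1L, length(genome)), chroms)
  ci <- 1L
  next_slot <- function(len) {
    tries <- 0L
    repeat {
      ch <- chroms[ci]
      ci <<- if (ci == length(chroms)) 1L else ci + 1L
      gap <- sample(200:800, 1)
      if (ptr[[ch]] + gap + len <= genome[[ch]]) {
        s <- ptr[[ch]] + gap
        ptr[[ch]] <<- s + len
        return(c(ch = ch, start = s))
      }
      tries <- tries + 1L
      if (tries > length(chroms)) stopf("genome too small for requested features")
    }
  }
  genes <- vector("list", length(gene_lens))
  for (g in seq_along(gene_lens)) {
    slot <- next_slot(gene_lens[g])
    genes[[g]] <- GenomicRanges::GRanges(
      slot[["ch"]],
      IRanges::IRanges(as.integer(slot[["start"]]), width = gene_lens[g])
    )
  }
  genes <- unlist(GenomicRanges::GRangesList(genes))
  genes$gene_id <- sprintf("gene_%03d", seq_along(genes))
  names(genes) <- genes$gene_id

  exons <- vector("list", length(tx_lens))
  for (i in seq_along(tx_lens)) {
    L <- tx_lens[i]
    if (tx_genic[i]) {
      g <- genes[sample(length(genes), 1)]
      off <- sample(max(1L, BiocGenerics::width(g) - L), 1)
      start <- BiocGenerics::start(g) + off - 1L
      exons[[i]] <- GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(g)),
        IRanges::IRanges(start, width = L),
        strand = sample(c("+", "-"), 1)
      )
    } else {
      multi <- L > 400L && stats::runif(1) < 0.3
      span <- if (multi) L + sample(100:500, 1) else L
      slot <- next_slot(span)
      start <- as.integer(slot[["start"]])
      strand <- sample(c("+", "-"), 1)
      if (multi) {
        l1 <- sample(100:(L - 100L), 1)
        intron <- span - L
        exons[[i]] <- GenomicRanges::GRanges(
          slot[["ch"]],
          IRanges::IRanges(
            c(start, start + l1 + intron),
            width = c(l1, L - l1)
          ),
          strand = strand
        )
      } else {
        exons[[i]] <- GenomicRanges::GRanges(
          slot[["ch"]], IRanges::IRanges(start, width = L), strand = strand
        )
      }
    }
  }
  list(genes = genes, exons = GenomicRanges::GRangesList(exons))
}

#' Condition-structured synthetic expression
#'
#' Log-normal baseline expression per transcript with multiplicative
#' log-normal replicate noise, planted fold-changes applied to the dry
#' condition, and planted low-presence rows (non-zero in only a fixed
#' number of samples) to exercise presence filters.
#'
#' @param ids transcript ids (rows).
#' @param design named sample counts, e.g. `c(dry = 60, lactating = 43)`;
#'   at least 2 samples per condition.
#' @param fold optional named vector: multiplicative effect applied to the
#'   dry samples of that transcript (e.g. 4 means four-fold higher in dry).
#' @param nonzero_limit optional named integer vector: the transcript is
#'   zeroed in all but that many randomly chosen samples.
#' @param baseline optional named baseline override (linear scale).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters.
#' @param noise_sdlog replicate noise on the log scale.
#' @param units abundance units tag.
#' @param seed RNG seed.
#' @return list with `expr` (an `ExpressionMatrix`) and `truth` (data.frame
#'   of planted folds and presence limits).
#' @export
sim_expression <- function(ids, design = c(dry = 60L, lactating = 43L),
                           fold = NULL, nonzero_limit = NULL, baseline = NULL,
                           baseline_meanlog = log(5), baseline_sdlog = 1,
                           noise_sdlog = 0.5, units = "FPKM", seed = 1L) {
  if (any(design < 2L)) stopf("need at least 2 samples per condition")
  with_seed(seed, {
    samples <- unlist(lapply(names(design), function(cd) {
      sprintf("%s_%02d", cd, seq_len(design[[cd]]))
    }))
    conditions <- stats::setNames(rep(names(design), design), samples)
    base <- stats::setNames(
      exp(stats::rnorm(length(ids), baseline_meanlog, baseline_sdlog)), ids
    )
    if (!is.null(baseline)) base[names(baseline)] <- baseline
    values <- matrix(
      exp(stats::rnorm(length(ids) * length(samples), 0, noise_sdlog)),
      nrow = length(ids), dimnames = list(ids, samples)
    )
    values <- values * base
    if (!is.null(fold)) {
      dry_cols <- conditions == "dry"
      for (id in names(fold)) {
        values[id, dry_cols] <- values[id, dry_cols] * fold[[id]]
      }
    }
    if (!is.null(nonzero_limit)) {
      for (id in names(nonzero_limit)) {
        keep <- sample(length(samples), nonzero_limit[[id]])
        zero <- setdiff(seq_along(samples), keep)
        values[id, zero] <- 0
      }
    }
    truth <- data.frame(
      id = ids,
      fold = ifelse(ids %in% names(fold), unname(fold[ids]), 1),
      nonzero_limit = ifelse(ids %in% names(nonzero_limit),
        unname(nonzero_limit[ids]), NA_integer_
      ),
      stringsAsFactors = FALSE
    )
    list(
      expr = expression_matrix(values, units = units, conditions = conditions),
      truth = truth
    )
  })
}

#' Piecewise-constant synthetic conservation track
#'
#' Builds a per-base track with a constant low background, per-interval
#' planted mean scores and bounded uniform noise (the planted means stay at
#' least `noise` away from 0, 1 and the 0.5 retention cutoff, so interval
#' means never cross the threshold by noise alone).
#'
#' @param chrom_sizes named chromosome sizes.
#' @param intervals `GRanges` of scored intervals (e.g. lncRNA candidates).
#' @param means optional planted per-interval means; when `NULL`, a
#'   fraction `frac_high` is drawn from U(0.55, 0.95) and the rest from
#'   U(0.05, 0.45).
#' @param frac_high fraction of intervals planted above the 0.5 cutoff.
#' @param noise half-width of the uniform per-base noise (0 for an exact
#'   track).
#' @param background score of unannotated bases.
#' @param seed RNG seed.
#' @return list with `track` (a `ConservationTrack`) and `truth`
#'   (data.frame: `id`, `mean`, `high`).
#' @export
sim_conservation <- function(chrom_sizes, intervals, means = NULL,
                             frac_high = 0.1, noise = 0.02,
                             background = 0.1, seed = 1L) {
  with_seed(seed, {
    n <- length(intervals)
    if (is.null(means)) {
      high <- stats::runif(n) < frac_high
      means <- ifelse(high, stats::runif(n, 0.55, 0.95), stats::runif(n, 0.05, 0.45))
    }
    if (any(means < 0 | means > 1)) stopf("planted means must lie in [0, 1]")
    scores <- lapply(chrom_sizes, function(L) rep(background, L))
    chrom <- as.character(GenomicRanges::seqnames(intervals))
    for (i in seq_len(n)) {
      ix <- BiocGenerics::start(intervals)[i]:BiocGenerics::end(intervals)[i]
      v <- means[i] + if (noise > 0) stats::runif(length(ix), -noise, noise) else 0
      scores[[chrom[i]]][ix] <- pmin(1, pmax(0, v))
    }
    ids <- names(intervals) %||% sprintf("iv_%d", seq_len(n))
    list(
      track = conservation_track(scores),
      truth = data.frame(id = ids, mean = means, high = means > 0.5)
    )
  })
}

#' Synthetic genotypes and phenotypes under the two-component model
#'
#' Simulates unlinked biallelic variants with allele frequencies uniform on
#' `maf_range`, places `m1` of them inside the 10 kb-extended windows of
#' simulated lncRNA intervals and the rest outside, and draws the phenotype
#' from the generating model the enrichment module fits:
#' `y = mu + Z1 u1 + Z2 u2 + e`, with per-variant effects
#' `u_k ~ N(0, sigma2_gk / mk)` on standardized genotypes and residuals
#' inflated by each record's reliability, `e_i ~ N(0, sigma2_e / r_i)`.
#' The true enrichment implied by the planted components,
#' `rho = (s1/m1) / ((s1+s2)/(m1+m2))`, is recorded in the truth.
#'
#' Optionally plants variants that must fail QC: `n_low_maf` single-carrier
#' variants (MAF 1/(2n)) and `n_hwe_viol` variants with only homozygotes
#' (maximal Hardy-Weinberg distortion); both kinds are placed in the `rest`
#' region and flagged in the truth.
#'
#' @param n individuals.
#' @param m informative variants (before any planted QC failures).
#' @param m1 variants placed inside lncRNA windows.
#' @param vc named true variance components `c(g1, g2, e)`.
#' @param n_lnc,lnc_len number and length of simulated lncRNA intervals.
#' @param window partition window (bases).
#' @param genome named chromosome sizes.
#' @param maf_range allele-frequency range of informative variants.
#' @param n_low_maf,n_hwe_viol planted QC failures.
#' @param reliability_range range of per-record reliabilities.
#' @param seed RNG seed.
#' @return list with `geno` (`GenotypeMatrix`), `pheno` (data.frame `id`,
#'   `y`, `reliability`), `lnc` (`GRanges`) and `truth` (list: `vc`, `rho`,
#'   `m1`, `m2`, `g` genetic values, `low_maf_ids`, `hwe_viol_ids`).
#' @export
sim_genetics <- function(n = 800L, m = 4000L, m1 = 200L,
                         vc = c(g1 = 0.1, g2 = 0.4, e = 0.5),
                         n_lnc = 20L, lnc_len = 2000L, window = 10000L,
                         genome = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
                         maf_range = c(0.05, 0.5),
                         n_low_maf = 0L, n_hwe_viol = 0L,
                         reliability_range = c(0.5, 1), seed = 1L) {
  if (any(vc < 0)) stopf("variance components must be non-negative")
  m2 <- m - m1
  if (m1 < 1L || m2 < 1L) stopf("need variants in both partitions")
  with_seed(seed, {
    # spaced lncRNA intervals; windows never overlap
    spacing <- 2L * window + lnc_len + 1000L
    per_chr <- ceiling(n_lnc / length(genome))
    lnc <- list()
    k <- 0L
    for (ch in names(genome)) {
      for (j in seq_len(per_chr)) {
        if (k >= n_lnc) break
        start <- window + 1000L + (j - 1L) * spacing
        if (start + lnc_len + window > genome[[ch]]) break
        k <- k + 1L
        lnc[[k]] <- GenomicRanges::GRanges(ch, IRanges::IRanges(start, width = lnc_len))
      }
    }
    lnc <- unlist(GenomicRanges::GRangesList(lnc))
    names(lnc) <- sprintf("lnc_%02d", seq_along(lnc))
    ext <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(lnc),
      IRanges::IRanges(
        pmax(1L, BiocGenerics::start(lnc) - window),
        BiocGenerics::end(lnc) + window
      )
    )

    # positions: m1 inside windows, the rest (plus QC plants) outside
    pos_in <- sample_positions_in(ext, m1)
    n_out <- m2 + n_low_maf + n_hwe_viol
    pos_out <- sample_positions_out(ext, genome, n_out)
    map <- rbind(pos_in, pos_out)
    mm <- nrow(map)
    map$id <- sprintf("var_%05d", seq_len(mm))

    p <- stats::runif(mm, maf_range[1], maf_range[2])
    d <- matrix(stats::rbinom(n * mm, 2L, rep(p, each = n)), nrow = n)
    low_ids <- hwe_ids <- character(0)
    qc_rows <- mm - n_low_maf - n_hwe_viol + seq_len(n_low_maf + n_hwe_viol)
    if (n_low_maf > 0L) {
      cols <- qc_rows[seq_len(n_low_maf)]
      for (cc in cols) {
        d[, cc] <- 0L
        d[sample(n, 1L), cc] <- 1L
      }
      low_ids <- map$id[cols]
    }
    if (n_hwe_viol > 0L) {
      cols <- qc_rows[n_low_maf + seq_len(n_hwe_viol)]
      for (cc in cols) {
        d[, cc] <- sample(rep(c(0L, 2L), length.out = n))
      }
      hwe_ids <- map$id[cols]
    }

    # phenotype from the informative variants only
    inform <- seq_len(m1 + m2)
    Z <- scale_popvar(d[, inform, drop = FALSE])
    u <- c(
      stats::rnorm(m1, 0, sqrt(vc[["g1"]] / m1)),
      stats::rnorm(m2, 0, sqrt(vc[["g2"]] / m2))
    )
    g <- drop(Z %*% u)
    r <- stats::runif(n, reliability_range[1], reliability_range[2])
    y <- g + stats::rnorm(n, 0, sqrt(vc[["e"]] / r))
    rho <- (vc[["g1"]] / m1) / ((vc[["g1"]] + vc[["g2"]]) / (m1 + m2))
    list(
      geno = genotype_matrix(d, map),
      pheno = data.frame(id = sprintf("ind_%04d", seq_len(n)), y = y, reliability = r),
      lnc = lnc,
      truth = list(
        vc = vc, rho = rho, m1 = m1, m2 = m2, g = g,
        low_maf_ids = low_ids, hwe_viol_ids = hwe_ids
      )
    )
  })
}

#' Redraw phenotypes on fixed genotypes
#'
#' Draws a fresh phenotype replicate from the two-component generating model
#' conditional on an existing genotype sample: new per-variant effects
#' `u_k ~ N(0, sigma2_gk / mk)` on the standardized genotypes of each
#' partition, new residuals inflated by reliability. Useful for replicate
#' studies (e.g. null calibration) where regenerating genotypes and
#' relationship matrices every time adds nothing.
#'
#' @param geno a `GenotypeMatrix`.
#' @param assignment partition factor from [assign_partition()] (levels
#'   `lnc`, `rest`), aligned with the variants of `geno`.
#' @param vc named true variance components `c(g1, g2, e)`.
#' @param reliability per-record reliabilities; default 1.
#' @param seed RNG seed.
#' @return list with `pheno` (data.frame `id`, `y`, `reliability`) and
#'   `truth` (list `vc`, `rho`, `g`).
#' @export
sim_phenotype <- function(geno, assignment, vc, reliability = NULL, seed = 1L) {
  if (any(vc < 0)) stopf("variance components must be non-negative")
  d <- geno$dosages
  n <- nrow(d)
  lnc <- assignment == "lnc"
  m1 <- sum(lnc)
  m2 <- sum(!lnc)
  if (m1 < 1L || m2 < 1L) stopf("need variants in both partitions")
  if (is.null(reliability)) reliability <- rep(1, n)
  Z <- scale_popvar(d)
  with_seed(seed, {
    u <- numeric(ncol(d))
    u[lnc] <- stats::rnorm(m1, 0, sqrt(vc[["g1"]] / m1))
    u[!lnc] <- stats::rnorm(m2, 0, sqrt(vc[["g2"]] / m2))
    g <- drop(Z %*% u)
    y <- g + stats::rnorm(n, 0, sqrt(vc[["e"]] / reliability))
    rho <- (vc[["g1"]] / m1) / ((vc[["g1"]] + vc[["g2"]]) / (m1 + m2))
    list(
      pheno = data.frame(
        id = sprintf("ind_%04d", seq_len(n)), y = y, reliability = reliability
      ),
      truth = list(vc = vc, rho = rho, g = g)
    )
  })
}

scale_popvar <- function(d) {
  n <- nrow(d)
  Z <- d - rep(colMeans(d), each = n)
  Z / rep(sqrt(colMeans(Z^2)), each = n)
}

sample_positions_in <- function(regions, k) {
  w <- BiocGenerics::width(regions)
  pick <- sample(length(regions), k, replace = TRUE, prob = w)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions))[pick],
    pos = BiocGenerics::start(regions)[pick] +
      vapply(w[pick], function(x) sample(x, 1) - 1L, 1L)
  )
}

sample_positions_out <- function(regions, genome, k) {
  out <- data.frame(chrom = character(0), pos = integer(0))
  while (nrow(out) < k) {
    ch <- sample(names(genome), 2L * k, replace = TRUE)
    pos <- vapply(genome[ch], function(L) sample(L, 1), 1)
    pts <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos, pos))
    ok <- GenomicRanges::countOverlaps(pts, regions) == 0L
    out <- rbind(out, data.frame(chrom = ch[ok], pos = as.integer(pos[ok])))
  }
  out[seq_len(k), , drop = FALSE]
}
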