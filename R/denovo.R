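# De novo backsplice discovery from reads that failed every annotated index:
# split-read genome binning, consensus assembly scored by a per-position
# non-consensus statistic S, breakpoint refinement against the local genome,
# splice-signal (U2/U12) annotation, and realignment-based filtering.

#' Find split-read alignments inconsistent with linear splicing
#'
#' Aligns the 5' and 3' segments of each unaligned R1 separately to the
#' genome (unique placement, at most `max_mm` mismatches per segment, both
#' on the same strand) and keeps reads whose segments map in backsplice
#' orientation: the 3' (acceptor-side) segment upstream of the 5'
#' (donor-side) segment on the plus strand, mirrored on the minus strand.
#'
#' @param reads Named character vector of unaligned R1 sequences.
#' @param genome Named character vector / `DNAStringSet` / FASTA path.
#' @param segment_len Segment length (default `read_len - 65`, i.e. 35 for
#'   100-nt reads).
#' @param max_mm Maximum mismatches per segment (default 2).
#' @param max_span Maximum genomic separation of the two segments
#'   (default 1e6).
#' @return A tibble of split alignments: `read_id`, `chrom`, `strand`,
#'   `five_pos`, `three_pos` (segment start coordinates), mismatch counts,
#'   and the read sequence.
#' @export
find_split_alignments <- function(reads, genome, segment_len = NULL,
                                  max_mm = 2, max_span = 1e6) {
  genome <- as_genome(genome)
  if (length(reads) == 0) {
    return(tibble::tibble(read_id = character(), chrom = character(),
                          strand = character(), five_pos = integer(),
                          three_pos = integer(), five_mm = integer(),
                          three_mm = integer(), seq = character()))
  }
  read_len <- nchar(reads[1])
  segment_len <- segment_len %||% max(20L, read_len - 65L)

  match_unique <- function(seg) {
    hits <- list()
    for (str in c("+", "-")) {
      pat <- if (str == "+") seg else revcomp(seg)
      for (ch in names(genome)) {
        m <- Biostrings::matchPattern(pat, genome[[ch]], max.mismatch = max_mm)
        if (length(m) > 0) {
          st <- BiocGenerics::start(m)
          mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pat),
                                            genome[[ch]], starting.at = st,
                                            with.indels = FALSE)
          hits[[length(hits) + 1]] <- tibble::tibble(
            chrom = ch, strand = str, pos = st, mm = as.integer(mm))
        }
      }
    }
    h <- dplyr::bind_rows(hits)
    if (nrow(h) != 1) return(NULL)
    h
  }

  rows <- purrr::imap(reads, function(rd, id) {
    seg5 <- substr(rd, 1L, segment_len)
    seg3 <- substr(rd, nchar(rd) - segment_len + 1L, nchar(rd))
    h5 <- match_unique(seg5)
    h3 <- match_unique(seg3)
    if (is.null(h5) || is.null(h3)) return(NULL)
    if (h5$chrom != h3$chrom || h5$strand != h3$strand) return(NULL)
    backsplice <- if (h5$strand == "+") h3$pos < h5$pos else h3$pos > h5$pos
    if (!backsplice || abs(h5$pos - h3$pos) > max_span) return(NULL)
    tibble::tibble(read_id = id, chrom = h5$chrom, strand = h5$strand,
                   five_pos = h5$pos, three_pos = h3$pos,
                   five_mm = h5$mm, three_mm = h3$mm, seq = rd)
  })
  dplyr::bind_rows(rows)
}

#' Group split reads into candidate genome bin pairs
#'
#' Bins the genome into disjoint `bin_size`-nt bins and groups split reads
#' by the (acceptor bin, donor bin) pair; only groups with at least
#' `min_unique_offsets` reads at distinct offsets (the 5' segment's position
#' within its bin) are candidate junctions.
#'
#' @param splits Tibble from [find_split_alignments()].
#' @param bin_size Bin width in nt (default 50).
#' @param min_unique_offsets Minimum distinct offsets (default 3).
#' @return A nested tibble: `chrom`, `strand`, `bin_acceptor`, `bin_donor`,
#'   `n_reads`, `n_offsets`, and a `reads` list-column.
#' @export
collect_bin_pairs <- function(splits, bin_size = 50, min_unique_offsets = 3) {
  if (nrow(splits) == 0) {
    return(tibble::tibble(chrom = character(), strand = character(),
                          bin_acceptor = integer(), bin_donor = integer(),
                          n_reads = integer(), n_offsets = integer(),
                          reads = list()))
  }
  splits |>
    dplyr::mutate(
      bin_acceptor = (.data$three_pos - 1L) %/% bin_size,
      bin_donor = (.data$five_pos - 1L) %/% bin_size,
      offset = .data$five_pos - .data$bin_donor * bin_size) |>
    tidyr::nest(reads = c("read_id", "five_pos", "three_pos", "offset",
                          "five_mm", "three_mm", "seq")) |>
    dplyr::mutate(n_reads = vapply(.data$reads, nrow, integer(1)),
                  n_offsets = vapply(.data$reads,
                                     function(r) length(unique(r$offset)),
                                     integer(1))) |>
    dplyr::filter(.data$n_offsets >= min_unique_offsets) |>
    dplyr::select("chrom", "strand", "bin_acceptor", "bin_donor",
                  "n_reads", "n_offsets", "reads")
}

#' Consensus assembly and score S for one bin pair
#'
#' Stacks the member reads by their split offsets and, at every position
#' covered by more than one read, adds (reads not matching the consensus
#' base) / (reads overlapping the position) to the score S. S is 0 when the
#' stack is unanimous; under sequencing error alone its expectation is the
#' per-base error rate summed over multiply covered positions (about 1 for
#' 100 such positions at 1% error). Consensus ties are broken
#' lexicographically.
#'
#' @param members Read tibble from one [collect_bin_pairs()] group (needs
#'   `seq` and the stacking anchor `five_pos`).
#' @return A list: `consensus` (over all covered positions), `score`,
#'   `n_multi` (positions with coverage >= 2), `n_conflicts` (positions with
#'   coverage >= 3 whose minority fraction exceeds 1/3, the
#'   multiple-breakpoint signal), and `anchor_col` (column of the smallest
#'   `five_pos`, for breakpoint bookkeeping).
#' @export
consensus_and_score <- function(members) {
  anchor <- if (members$strand[1] %||% "+" == "-") -members$five_pos else
    members$five_pos
  anchor <- anchor - min(anchor)
  lens <- nchar(members$seq)
  width <- max(anchor + lens)
  k <- nrow(members)
  mat <- matrix(NA_character_, nrow = k, ncol = width)
  chars <- strsplit(members$seq, "")
  for (i in seq_len(k)) {
    mat[i, (anchor[i] + 1):(anchor[i] + lens[i])] <- chars[[i]]
  }
  cons <- character(width)
  score <- 0
  n_multi <- 0L
  n_conflicts <- 0L
  letters4 <- c("A", "C", "G", "T", "N")
  for (j in seq_len(width)) {
    col <- mat[, j]
    col <- col[!is.na(col)]
    if (length(col) == 0) next
    tab <- tabulate(match(col, letters4), nbins = 5L)
    cons[j] <- letters4[which.max(tab)]  # ties resolve lexicographically
    if (length(col) >= 2) {
      n_multi <- n_multi + 1L
      nonc <- length(col) - max(tab)
      score <- score + nonc / length(col)
      if (length(col) >= 3 && nonc / length(col) > 1 / 3) {
        n_conflicts <- n_conflicts + 1L
      }
    }
  }
  list(consensus = paste(cons, collapse = ""), score = score,
       n_multi = n_multi, n_conflicts = n_conflicts,
       anchor_offset = min(if (members$strand[1] %||% "+" == "-")
         -members$five_pos else members$five_pos))
}

#' Assemble and screen candidate de novo junctions
#'
#' Runs [consensus_and_score()] over every bin pair and keeps assemblies
#' with `score < s_max` and no evidence of multiple distinct breakpoints
#' (at most one well-supported conflicting consensus column).
#'
#' @param bin_pairs Tibble from [collect_bin_pairs()].
#' @param s_max Score threshold, strict (default 5).
#' @param max_conflict_cols Maximum conflicting columns tolerated
#'   (default 1).
#' @return `bin_pairs` plus `consensus`, `score`, `n_multi`, `n_conflicts`,
#'   filtered to the retained assemblies.
#' @export
screen_candidates <- function(bin_pairs, s_max = 5, max_conflict_cols = 1) {
  if (nrow(bin_pairs) == 0) {
    return(dplyr::mutate(bin_pairs, consensus = character(0), score = numeric(0),
                         n_multi = integer(0), n_conflicts = integer(0)))
  }
  cs <- purrr::map2(bin_pairs$reads, bin_pairs$strand, function(r, st) {
    r$strand <- st
    consensus_and_score(r)
  })
  bin_pairs |>
    dplyr::mutate(consensus = purrr::map_chr(cs, "consensus"),
                  score = purrr::map_dbl(cs, "score"),
                  n_multi = purrr::map_int(cs, "n_multi"),
                  n_conflicts = purrr::map_int(cs, "n_conflicts")) |>
    dplyr::filter(.data$score < s_max,
                  .data$n_conflicts <= max_conflict_cols)
}

#' Refine the breakpoint of a de novo assembly and read its splice signal
#'
#' Splits the consensus at every position leaving at least `min_frag` nt on
#' each side, aligns the donor-side fragment within +/- `flank` nt of the
#' donor bin and the acceptor-side fragment near the acceptor bin (at most
#' one mismatch each), and reads the intronic dinucleotides flanking each
#' mappable breakpoint off the genome. A breakpoint flanked by GT-AG is
#' preferred (canonical U2); otherwise a U12 signature (TATCCT one
#' nucleotide downstream of the donor, or AT-AC termini); otherwise the
#' first mappable breakpoint with signal class `"other"`.
#'
#' @param assembly One row of [screen_candidates()] output.
#' @param genome Genome provider.
#' @param bin_size Bin width used for the candidate (default 50).
#' @param flank Search window around each bin (default 500).
#' @param min_frag Minimum fragment length (default 20).
#' @param max_mm Mismatches allowed per fragment (default 1).
#' @return A one-row tibble (`donor`, `acceptor`, `donor_di`, `acceptor_di`,
#'   `signal_class`, `split_at`), or `NULL` when no breakpoint maps.
#' @export
map_breakpoint <- function(assembly, genome, bin_size = 50, flank = 500,
                           min_frag = 20, max_mm = 1) {
  genome <- as_genome(genome)
  cons <- assembly$consensus
  L <- nchar(cons)
  if (L < 2 * min_frag) return(NULL)
  chrom <- assembly$chrom
  glen <- Biostrings::width(genome[chrom])

  window <- function(bin) {
    lo <- max(1L, bin * bin_size + 1L - flank - L)
    hi <- min(glen, (bin + 1L) * bin_size + flank + L)
    list(seq = Biostrings::subseq(genome[[chrom]], lo, hi), lo = lo)
  }
  win_d <- window(assembly$bin_donor)
  win_a <- window(assembly$bin_acceptor)

  candidates <- list()
  for (k in seq(min_frag, L - min_frag)) {
    f1 <- substr(cons, 1L, k)
    f2 <- substr(cons, k + 1L, L)
    m1 <- Biostrings::matchPattern(f1, win_d$seq, max.mismatch = max_mm)
    if (length(m1) == 0 || length(m1) > 40) next
    m2 <- Biostrings::matchPattern(f2, win_a$seq, max.mismatch = max_mm)
    if (length(m2) == 0 || length(m2) > 40) next
    for (d_end in BiocGenerics::end(m1) + win_d$lo - 1L) {
      for (a_start in BiocGenerics::start(m2) + win_a$lo - 1L) {
        if (d_end + 2L > glen || a_start - 2L < 1L) next
        donor_di <- as.character(
          Biostrings::subseq(genome[[chrom]], d_end + 1L, d_end + 2L))
        acceptor_di <- as.character(
          Biostrings::subseq(genome[[chrom]], a_start - 2L, a_start - 1L))
        u12_sig <- d_end + 7L <= glen && as.character(
          Biostrings::subseq(genome[[chrom]], d_end + 2L, d_end + 7L)) == "TATCCT"
        signal <- if (donor_di == "GT" && acceptor_di == "AG") "U2"
        else if (u12_sig || (donor_di == "AT" && acceptor_di == "AC")) "U12"
        else "other"
        candidates[[length(candidates) + 1]] <- tibble::tibble(
          donor = d_end, acceptor = a_start, donor_di = donor_di,
          acceptor_di = acceptor_di, signal_class = signal, split_at = k)
      }
    }
  }
  if (length(candidates) == 0) return(NULL)
  cand <- dplyr::bind_rows(candidates)
  pick <- which(cand$signal_class == "U2")[1]
  if (is.na(pick)) pick <- which(cand$signal_class == "U12")[1]
  if (is.na(pick)) pick <- 1L
  cand[pick, ]
}

#' Name a de novo junction by its nearest annotated gene
#'
#' Junctions whose breakpoint span lies within `within` nt of an annotated
#' gene span take that gene's name; otherwise `"UNAN"` (un-annotated).
#'
#' @param breakpoint One-row tibble with `donor`, `acceptor` (and the
#'   assembly's `chrom`).
#' @param chrom Chromosome of the junction.
#' @param exons Exon tibble of the annotation.
#' @param within Distance threshold in nt (default 1000).
#' @return The gene id or `"UNAN"`.
#' @export
name_and_classify <- function(breakpoint, chrom, exons, within = 1000) {
  if (is.null(exons) || nrow(exons) == 0) return("UNAN")
  spans <- exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(chrom = .data$chrom[1], lo = min(.data$start),
                     hi = max(.data$end), .groups = "drop") |>
    dplyr::filter(.data$chrom == !!chrom)
  if (nrow(spans) == 0) return("UNAN")
  j_lo <- min(breakpoint$acceptor, breakpoint$donor)
  j_hi <- max(breakpoint$acceptor, breakpoint$donor)
  gap <- pmax(0, pmax(spans$lo - j_hi, j_lo - spans$hi))
  if (min(gap) <= within) spans$gene_id[which.min(gap)] else "UNAN"
}

#' Realign unaligned reads to the de novo index and filter junction calls
#'
#' Builds a junction index from the mapped consensus assemblies, realigns
#' all originally unaligned R1s to it (R2s to the genome), categorizes pairs
#' with a 50-nt circle-region buffer (mates were binned at 50 nt), collapses
#' bins to unique chromosomal breakpoints, and retains junctions passing the
#' naive Poisson test (p > `naive_p_min`), a decoy/circle ratio below
#' `max_decoy_ratio`, and a breakpoint separation above `min_span` nt.
#'
#' @param r1,r2 Named character vectors of the unaligned read pairs.
#' @param assemblies Screened assemblies with breakpoint columns (`donor`,
#'   `acceptor`, `signal_class`, `gene`, `consensus`, `split_at`).
#' @param genome Genome provider.
#' @param buffer Circle-region buffer (default 50).
#' @param min_overlap Minimum junction overlap (default 10).
#' @param naive_p_min Minimum naive p-value (default 0.9).
#' @param max_decoy_ratio Maximum decoy/circle ratio (default 0.1).
#' @param min_span Minimum breakpoint separation in nt (default 200).
#' @param error_rate Per-base error rate for the naive test (default 0.01).
#' @return A call tibble with read support, naive p-value, decoy ratio,
#'   breakpoint, splice signal, and gene name per retained junction.
#' @export
realign_and_filter <- function(r1, r2, assemblies, genome, buffer = 50,
                               min_overlap = 10, naive_p_min = 0.9,
                               max_decoy_ratio = 0.1, min_span = 200,
                               error_rate = 0.01) {
  genome <- as_genome(genome)
  # collapse bins to unique chromosomal breakpoints
  asm <- assemblies |>
    dplyr::group_by(.data$chrom, .data$strand, .data$donor, .data$acceptor) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::mutate(junction_id = paste(.data$chrom, .data$donor,
                                      .data$acceptor, .data$strand, sep = ":"))

  junctions <- tibble::tibble(
    junction_id = asm$junction_id, chrom = asm$chrom, strand = asm$strand,
    cls = "denovo",
    donor_start = asm$donor, donor_end = asm$donor,
    acceptor_start = asm$acceptor, acceptor_end = asm$acceptor,
    donor_gene = asm$gene, acceptor_gene = asm$gene,
    donor_exon = NA_character_, acceptor_exon = NA_character_,
    cross_gene = FALSE, sequence = asm$consensus,
    boundary_index = asm$split_at)

  targets <- c(setNames(asm$consensus, asm$junction_id),
               setNames(as.character(genome), names(genome)))
  kinds <- c(setNames(rep("denovo_junction", nrow(asm)), asm$junction_id),
             setNames(rep("genome", length(genome)), names(genome)))

  a1 <- align_reads(r1, targets[seq_len(nrow(asm))],
                    kinds[seq_len(nrow(asm))])
  a2 <- align_reads(r2, targets, kinds)
  aln <- dplyr::bind_rows(
    if (nrow(a1)) dplyr::mutate(a1, mate = "R1"),
    if (nrow(a2)) dplyr::mutate(a2, mate = "R2"))
  if (is.null(aln) || nrow(aln) == 0) return(empty_denovo_calls())

  feats <- classify_read_pairs(aln, junctions, min_overlap = min_overlap,
                               buffer = buffer)
  if (nrow(feats) == 0) return(empty_denovo_calls())

  calls <- feats |>
    dplyr::group_by(.data$junction_id) |>
    dplyr::summarise(
      n_circular = sum(.data$category == "circular"),
      n_decoy = sum(.data$category == "decoy"),
      naive_p = naive_mismatch_pvalue(
        sum(.data$mismatches[.data$category == "circular"]),
        max(1L, sum(.data$aligned_len[.data$category == "circular"])),
        rate = error_rate),
      .groups = "drop") |>
    dplyr::inner_join(
      asm[, c("junction_id", "chrom", "strand", "donor", "acceptor",
              "donor_di", "acceptor_di", "signal_class", "gene", "score")],
      by = "junction_id") |>
    dplyr::mutate(decoy_ratio = .data$n_decoy / pmax(1L, .data$n_circular),
                  span = abs(.data$donor - .data$acceptor))
  calls |>
    dplyr::filter(.data$n_circular > 0,
                  .data$naive_p > naive_p_min,
                  .data$decoy_ratio < max_decoy_ratio,
                  .data$span > min_span) |>
    dplyr::arrange(dplyr::desc(.data$n_circular))
}

empty_denovo_calls <- function() {
  tibble::tibble(junction_id = character(), n_circular = integer(),
                 n_decoy = integer(), naive_p = numeric(),
                 chrom = character(), strand = character(), donor = integer(),
                 acceptor = integer(), donor_di = character(),
                 acceptor_di = character(), signal_class = character(),
                 gene = character(), score = numeric(),
                 decoy_ratio = numeric(), span = numeric())
}

#' Discover de novo backsplice junctions from unaligned reads
#'
#' End-to-end de novo pipeline: split-read alignment, bin-pair grouping,
#' consensus assembly and screening, breakpoint refinement with splice
#' signal annotation, gene naming, and realignment-based filtering.
#'
#' @param r1,r2 Named character vectors of unaligned read pairs (R1 drives
#'   discovery; R2 is used only for categorization).
#' @param genome Genome provider.
#' @param exons Exon annotation tibble (for naming; may be empty).
#' @param bin_size Genome bin width (default 50).
#' @param segment_len Split segment length (default `read_len - 65`).
#' @param s_max Consensus score threshold (default 5).
#' @param ... Passed to [realign_and_filter()].
#' @return A list with `assemblies` (all screened assemblies with mapped
#'   breakpoints) and `calls` (filtered junction calls).
#' @export
discover_denovo <- function(r1, r2, genome, exons = NULL, bin_size = 50,
                            segment_len = NULL, s_max = 5, ...) {
  splits <- find_split_alignments(r1, genome, segment_len = segment_len)
  pairs <- collect_bin_pairs(splits, bin_size = bin_size)
  screened <- screen_candidates(pairs, s_max = s_max)
  if (nrow(screened) == 0) {
    return(list(assemblies = screened, calls = empty_denovo_calls()))
  }
  bps <- purrr::map(seq_len(nrow(screened)), function(i) {
    bp <- map_breakpoint(screened[i, ], genome, bin_size = bin_size)
    if (is.null(bp)) return(NULL)
    bp$row <- i
    bp
  })
  bps <- dplyr::bind_rows(bps)
  if (nrow(bps) == 0) {
    return(list(assemblies = screened[0, ], calls = empty_denovo_calls()))
  }
  asm <- dplyr::bind_cols(screened[bps$row, ],
                          dplyr::select(bps, -"row"))
  asm$gene <- vapply(seq_len(nrow(asm)), function(i) {
    name_and_classify(asm[i, ], asm$chrom[i], exons)
  }, character(1))
  calls <- realign_and_filter(r1, r2, asm, genome, ...)
  list(assemblies = asm, calls = calls)
}
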