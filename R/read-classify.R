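# Read-pair classification: resolve the R1 junction anchor, resolve the best
# R2 alignment, and categorize each R1-anchored pair as linear, circular, or
# decoy from the mate's genomic position relative to the presumed circle.

KIND_PRIORITY <- c(genome = 1, linear_junction = 2, scrambled_junction = 3,
                   denovo_junction = 4, rRNA = 5)

#' Offset of a junction-spanning alignment over the splice boundary
#'
#' The offset is the number of nucleotides by which the read overlaps the
#' junction boundary, taken as the smaller of the two sides. Reads must
#' overlap by at least a user-chosen minimum (default 10 nt) to count as
#' junctional.
#'
#' @param pos 1-based alignment start on the junction sequence.
#' @param aligned_len Aligned read length.
#' @param boundary_index Position of the last donor-side base (default 150).
#' @return Integer offset; 0 if the read does not span the boundary.
#' @examples
#' compute_offset(61, 100)   # 90 donor-side nt, 10 acceptor-side -> 10
#' compute_offset(101, 100)  # centered -> 50
#' @export
compute_offset <- function(pos, aligned_len, boundary_index = 150) {
  left <- boundary_index - pos + 1L
  right <- pos + aligned_len - 1L - boundary_index
  pmax(0L, pmin(left, right))
}

#' Genomic region of the presumed circle for a scrambled junction
#'
#' The presumed circle may include or exclude any introns and exons between
#' the genomic coordinates of the two junctional exons, so the region spans
#' from the minimum to the maximum coordinate of the pair, expanded by a
#' buffer (15 nt for annotated junctions, absorbing small artifacts
#' introduced during reverse transcription; 50 nt for de novo junctions,
#' matching the bin size).
#'
#' @param junction One-row junction tibble (scrambled or de novo class).
#' @param buffer Expansion in nt on each side (default 15).
#' @return A tibble with `chrom`, `lo`, `hi`, `buffer`.
#' @export
circle_region <- function(junction, buffer = 15) {
  abort_if(any(junction$cls == "linear"),
           "circle regions are defined only for scrambled or de novo junctions")
  tibble::tibble(
    chrom = junction$chrom,
    lo = pmin(junction$donor_start, junction$acceptor_start) - buffer,
    hi = pmax(junction$donor_end, junction$acceptor_end) + buffer,
    buffer = buffer)
}

#' Resolve the R1 junction anchor among a read's alignments
#'
#' R1 must not have a passing alignment to the genome or rRNA (such reads are
#' discarded as non-diagnostic); if it aligns to both a linear and a
#' scrambled junction, the linear junction is the anchor; and the anchor must
#' overlap the splice boundary by at least `min_overlap` nucleotides.
#'
#' @param alignments Alignment tibble for one read's R1 (best alignment per
#'   index kind).
#' @param junctions Junction tibble (for boundary positions).
#' @param min_overlap Minimum boundary overlap in nt (default 10).
#' @return A one-row anchor tibble, or a zero-row tibble with attribute
#'   `reason` (`"genome_hit"`, `"no_junction"`, `"low_overlap"`) when the
#'   read is discarded.
#' @export
resolve_r1 <- function(alignments, junctions, min_overlap = 10) {
  discard <- function(reason) {
    out <- alignments[0, ]
    attr(out, "reason") <- reason
    out
  }
  if (any(alignments$target_kind %in% c("genome", "rRNA"))) {
    return(discard("genome_hit"))
  }
  jal <- alignments[alignments$target_kind %in%
                      c("linear_junction", "scrambled_junction",
                        "denovo_junction"), , drop = FALSE]
  if (nrow(jal) == 0) return(discard("no_junction"))
  jal <- jal[order(KIND_PRIORITY[jal$target_kind]), , drop = FALSE]
  anchor <- jal[1, ]
  b <- junctions$boundary_index[match(anchor$target_id, junctions$junction_id)]
  off <- compute_offset(anchor$pos, anchor$aligned_len, b)
  if (is.na(off) || off < min_overlap) return(discard("low_overlap"))
  anchor$offset <- off
  anchor
}

#' Resolve the best R2 alignment among a read's alignments
#'
#' Picks the alignment with the highest score; ties are broken in favour of
#' the genome, then the linear junction, then the scrambled junction, then
#' de novo junctions.
#'
#' @param alignments Alignment tibble for one read's R2.
#' @return A one-row tibble, or a zero-row tibble when there is no alignment.
#' @export
resolve_r2 <- function(alignments) {
  if (nrow(alignments) == 0) return(alignments)
  ord <- order(-alignments$alignment_score,
               KIND_PRIORITY[alignments$target_kind],
               alignments$target_id, alignments$pos)
  alignments[ord[1], , drop = FALSE]
}

#' Categorize an anchored read pair as linear, circular, or decoy
#'
#' Linear anchors with a concordant mate (opposite orientation, downstream in
#' fragment orientation, within `max_fragment` nt) are linear. For scrambled
#' (or de novo) anchors, the pair is circular when the mate lies entirely
#' within the buffered genomic region of the presumed circle, and decoy when
#' the mate lies outside it, maps to a different chromosome, or has the same
#' orientation as R1.
#'
#' @param anchor One-row anchor from [resolve_r1()].
#' @param r2 One-row resolved mate from [resolve_r2()] (zero rows = missing).
#' @param junctions Junction tibble.
#' @param buffer Circle-region buffer in nt (default 15).
#' @param max_fragment Maximum genomic span of a concordant linear pair
#'   (default 1000).
#' @return `"linear"`, `"circular"`, `"decoy"`, or `NA` (dropped pair).
#' @export
categorize_pair <- function(anchor, r2, junctions, buffer = 15,
                            max_fragment = 1000) {
  pair <- classify_pairs_impl(
    dplyr::mutate(anchor, read_id = anchor$read_id %||% "r"),
    dplyr::mutate(r2, read_id = anchor$read_id %||% "r"),
    junctions, buffer = buffer, max_fragment = max_fragment)
  if (nrow(pair) == 0) NA_character_ else pair$category[1]
}

#' Classify all read pairs into linear, circular, and decoy features
#'
#' Vectorised pipeline step: resolves every R1 anchor and R2 mate from an
#' alignment table (as produced by [align_reads()], [read_alignments_sam()],
#' or [read_alignments_tsv()]) and emits one feature record per retained
#' R1-anchored pair. Only R1's alignment features (offset, alignment score,
#' mapping quality, mismatches) are carried, since R2 is consumed by the
#' categorization itself.
#'
#' @param alignments Alignment tibble with a `mate` column.
#' @param junctions Junction tibble from [build_junction_db()].
#' @param min_overlap Minimum boundary overlap for a junctional R1
#'   (default 10 nt).
#' @param buffer Circle-region buffer (default 15 nt).
#' @param max_fragment Maximum concordant linear span (default 1000 nt).
#' @return A feature tibble: `read_id`, `junction_id`, `cls`, `category`,
#'   `offset`, `alignment_score`, `mapq`, `mismatches`. Dropped reads are
#'   tallied in the `"drops"` attribute (a reason-count tibble).
#' @export
classify_read_pairs <- function(alignments, junctions, min_overlap = 10,
                                buffer = 15, max_fragment = 1000) {
  a1 <- alignments[alignments$mate == "R1", , drop = FALSE]
  a2 <- alignments[alignments$mate == "R2", , drop = FALSE]
  drops <- list()

  # R1: discard reads with genome/rRNA hits
  genome_hit <- unique(a1$read_id[a1$target_kind %in% c("genome", "rRNA")])
  anch <- a1[!(a1$read_id %in% genome_hit) &
               a1$target_kind %in% names(KIND_PRIORITY)[2:4], , drop = FALSE]
  drops$genome_hit <- length(genome_hit)
  # anchor = highest-priority junction kind per read
  anch <- anch[order(anch$read_id, KIND_PRIORITY[anch$target_kind]), ,
               drop = FALSE]
  anch <- anch[!duplicated(anch$read_id), , drop = FALSE]

  j <- match(anch$target_id, junctions$junction_id)
  anch <- dplyr::bind_cols(
    anch,
    junctions[j, c("chrom", "strand", "cls", "donor_start", "donor_end",
                   "acceptor_start", "acceptor_end", "boundary_index")] |>
      stats::setNames(paste0("j_", c("chrom", "strand", "cls", "donor_start",
                                     "donor_end", "acceptor_start",
                                     "acceptor_end", "boundary_index"))))
  anch$offset <- compute_offset(anch$pos, anch$aligned_len, anch$j_boundary_index)
  low <- anch$offset < min_overlap
  drops$low_overlap <- sum(low)
  anch <- anch[!low, , drop = FALSE]

  # R2: best score with genome > linear > scrambled > denovo tie preference
  a2 <- a2[order(a2$read_id, -a2$alignment_score,
                 KIND_PRIORITY[a2$target_kind], a2$target_id, a2$pos), ,
           drop = FALSE]
  a2 <- a2[!duplicated(a2$read_id), , drop = FALSE]

  out <- classify_pairs_impl(anch, a2, junctions, buffer, max_fragment,
                             min_side = min_overlap)
  drops$no_mate <- sum(!(anch$read_id %in% a2$read_id))
  drops$discordant_linear <- nrow(anch) - drops$no_mate - nrow(out)
  attr(out, "drops") <- tibble::tibble(
    reason = names(drops), n = unlist(drops, use.names = FALSE))
  out
}

# Core categorization on resolved anchors + resolved mates (vectorised).
classify_pairs_impl <- function(anch, r2, junctions, buffer, max_fragment,
                                min_side = 10) {
  if (!"j_chrom" %in% names(anch) && nrow(anch) > 0) {
    j <- match(anch$target_id, junctions$junction_id)
    anch <- dplyr::bind_cols(
      anch,
      junctions[j, c("chrom", "strand", "cls", "donor_start", "donor_end",
                     "acceptor_start", "acceptor_end", "boundary_index")] |>
        stats::setNames(paste0("j_", c("chrom", "strand", "cls", "donor_start",
                                       "donor_end", "acceptor_start",
                                       "acceptor_end", "boundary_index"))))
    if (!"offset" %in% names(anch)) {
      anch$offset <- compute_offset(anch$pos, anch$aligned_len,
                                    anch$j_boundary_index)
    }
  }
  m <- match(anch$read_id, r2$read_id)
  keep <- !is.na(m)
  anch <- anch[keep, , drop = FALSE]
  r2 <- r2[m[keep], , drop = FALSE]
  if (nrow(anch) == 0) {
    return(tibble::tibble(read_id = character(), junction_id = character(),
                          cls = character(), category = character(),
                          offset = integer(), alignment_score = numeric(),
                          mapq = numeric(), mismatches = integer(),
                          aligned_len = integer()))
  }

  g1 <- genomic_placement(anch, junctions, min_side)
  g2 <- genomic_placement(r2, junctions, min_side)

  is_lin <- anch$target_kind == "linear_junction"
  lo <- pmin(anch$j_donor_start, anch$j_acceptor_start) - buffer
  hi <- pmax(anch$j_donor_end, anch$j_acceptor_end) + buffer

  same_chrom <- g2$chrom == g1$chrom
  opposite <- g2$orient != g1$orient
  inside <- same_chrom & g2$lo >= lo & g2$hi <= hi

  span <- pmax(g1$hi, g2$hi) - pmin(g1$lo, g2$lo) + 1
  downstream <- ifelse(g1$orient == "+", g2$lo >= g1$lo - 10, g2$hi <= g1$hi + 10)
  concordant <- same_chrom & opposite & downstream & span <= max_fragment

  category <- dplyr::case_when(
    is_lin & concordant ~ "linear",
    is_lin ~ NA_character_,   # discordant linear anchor: dropped
    inside & opposite ~ "circular",
    TRUE ~ "decoy")

  out <- tibble::tibble(
    read_id = anch$read_id, junction_id = anch$target_id,
    cls = anch$j_cls, category = category, offset = anch$offset,
    alignment_score = anch$alignment_score, mapq = anch$mapq,
    mismatches = anch$mismatches, aligned_len = anch$aligned_len)
  out[!is.na(category), , drop = FALSE]
}

# Genomic footprint (chrom, lo, hi, orientation) of an alignment row, mapping
# junction-sequence coordinates back through the junction's two exon sides.
# A side covered by fewer than `min_side` bases is dropped from the
# footprint: like a sub-threshold R1 junction overlap, a few overhanging
# bases carry no usable positional evidence (and routinely tie across
# junction targets sharing the other side).
genomic_placement <- function(tbl, junctions, min_side = 10) {
  n <- nrow(tbl)
  chrom <- character(n); lo <- numeric(n); hi <- numeric(n); orient <- character(n)

  gi <- tbl$target_kind %in% c("genome", "rRNA")
  chrom[gi] <- tbl$target_id[gi]
  lo[gi] <- tbl$pos[gi]
  hi[gi] <- tbl$pos[gi] + tbl$aligned_len[gi] - 1
  orient[gi] <- tbl$strand[gi]

  ji <- which(!gi)
  if (length(ji) > 0) {
    jt <- tbl[ji, , drop = FALSE]
    if (!"j_chrom" %in% names(jt)) {
      j <- match(jt$target_id, junctions$junction_id)
      jt <- dplyr::bind_cols(
        jt,
        junctions[j, c("chrom", "strand", "donor_start", "donor_end",
                       "acceptor_start", "acceptor_end", "boundary_index")] |>
          stats::setNames(paste0("j_", c("chrom", "strand", "donor_start",
                                         "donor_end", "acceptor_start",
                                         "acceptor_end", "boundary_index"))))
    }
    b <- jt$j_boundary_index
    p1 <- jt$pos; p2 <- jt$pos + jt$aligned_len - 1
    plus <- jt$j_strand == "+"
    d_len <- pmin(jt$j_donor_end - jt$j_donor_start + 1, b)
    a_len <- pmin(jt$j_acceptor_end - jt$j_acceptor_start + 1, b)
    # overlap with occupied donor positions [b - d_len + 1, b]
    dp1 <- pmax(p1, b - d_len + 1); dp2 <- pmin(p2, b)
    has_d <- dp2 - dp1 + 1 >= pmin(min_side, p2 - p1 + 1)
    d_g1 <- ifelse(plus, jt$j_donor_end - (b - dp1), jt$j_donor_start + (b - dp1))
    d_g2 <- ifelse(plus, jt$j_donor_end - (b - dp2), jt$j_donor_start + (b - dp2))
    # overlap with occupied acceptor positions [b + 1, b + a_len]
    ap1 <- pmax(p1, b + 1); ap2 <- pmin(p2, b + a_len)
    has_a <- ap2 - ap1 + 1 >= pmin(min_side, p2 - p1 + 1)
    a_g1 <- ifelse(plus, jt$j_acceptor_start + (ap1 - b - 1),
                   jt$j_acceptor_end - (ap1 - b - 1))
    a_g2 <- ifelse(plus, jt$j_acceptor_start + (ap2 - b - 1),
                   jt$j_acceptor_end - (ap2 - b - 1))
    cl <- pmin(ifelse(has_d, pmin(d_g1, d_g2), Inf),
               ifelse(has_a, pmin(a_g1, a_g2), Inf))
    ch <- pmax(ifelse(has_d, pmax(d_g1, d_g2), -Inf),
               ifelse(has_a, pmax(a_g1, a_g2), -Inf))
    chrom[ji] <- jt$j_chrom
    lo[ji] <- cl
    hi[ji] <- ch
    # orientation on the genome composes junction strand with read strand
    orient[ji] <- ifelse((jt$j_strand == "+") == (jt$strand == "+"), "+", "-")
  }
  tibble::tibble(chrom = chrom, lo = lo, hi = hi, orient = orient)
}
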