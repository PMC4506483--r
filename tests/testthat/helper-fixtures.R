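# Shared in-code fixtures for the test suite: tiny genomes, exon tables and
# feature tables built deterministically at test time.

random_genome <- function(len, seed = 1, name = "chr1") {
  set.seed(seed)
  setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = ""), name)
}

toy_exons <- function(starts, lens, strand = "+", chrom = "chr1",
                      gene_id = "g1") {
  tibble::tibble(
    chrom = chrom, start = starts, end = starts + lens - 1L, strand = strand,
    gene_id = gene_id, exon_id = sprintf("%s.e%d", gene_id, seq_along(starts)))
}

# one-row junction tibble in the build_junction_db() layout
toy_junction <- function(cls = "scrambled", donor = c(5000, 5200),
                         acceptor = c(3000, 3200), chrom = "chr1",
                         strand = "+", boundary = 150) {
  tibble::tibble(
    junction_id = paste(chrom, donor[2], acceptor[1], strand, sep = ":"),
    chrom = chrom, strand = strand, cls = cls,
    donor_start = donor[1], donor_end = donor[2],
    acceptor_start = acceptor[1], acceptor_end = acceptor[2],
    donor_gene = "g1", acceptor_gene = "g1",
    donor_exon = "e2", acceptor_exon = "e1", cross_gene = FALSE,
    sequence = strrep("A", 2 * boundary), boundary_index = boundary)
}

alignment_row <- function(read_id = "r1", mate = "R1",
                          target_kind = "scrambled_junction",
                          target_id = "j1", pos = 101L, aligned_len = 100L,
                          strand = "+", alignment_score = 0L, mapq = 42L,
                          mismatches = 0L) {
  tibble::tibble(read_id = read_id, mate = mate, target_kind = target_kind,
                 target_id = target_id, pos = pos, aligned_len = aligned_len,
                 strand = strand, alignment_score = alignment_score,
                 mapq = mapq, mismatches = mismatches, n_best = 1L)
}

# a well-separated little training table for GLM plumbing tests
tiny_training <- function(n = 60, seed = 1) {
  set.seed(seed)
  dplyr::bind_rows(
    tibble::tibble(category = "linear",
                   offset = sample(10:50, n, TRUE),
                   alignment_score = -6 * rpois(n, 0.3),
                   mapq = sample(c(42, 30), n, TRUE, prob = c(.8, .2))),
    tibble::tibble(category = "decoy",
                   offset = pmin(50, 10 + rpois(n, 3)),
                   alignment_score = -6 * rpois(n, 1.5),
                   mapq = sample(c(1, 30), n, TRUE, prob = c(.7, .3)))) |>
    dplyr::mutate(read_id = sprintf("t%04d", dplyr::row_number()),
                  junction_id = "jx", cls = "linear")
}

# run the annotated-index half of the pipeline on a simulation
align_and_classify <- function(sim, rd, min_overlap = 10) {
  jdb <- build_junction_db(sim$exons, sim$genome)
  targets <- c(setNames(jdb$sequence, jdb$junction_id),
               setNames(sim$genome, names(sim$genome)))
  kinds <- c(ifelse(jdb$cls == "linear", "linear_junction",
                    "scrambled_junction"),
             rep("genome", length(sim$genome)))
  names(kinds) <- names(targets)
  aln <- dplyr::bind_rows(
    dplyr::mutate(align_reads(setNames(rd$reads$r1, rd$reads$read_id),
                              targets, kinds), mate = "R1"),
    dplyr::mutate(align_reads(setNames(rd$reads$r2, rd$reads$read_id),
                              targets, kinds), mate = "R2"))
  feats <- classify_read_pairs(aln, jdb, min_overlap = min_overlap)
  list(jdb = jdb, alignments = aln, features = feats)
}
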