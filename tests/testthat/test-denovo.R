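# helpers to build split-read stacks by hand
stack_members <- function(seqs, anchors, strand = "+") {
  tibble::tibble(read_id = sprintf("m%02d", seq_along(seqs)), seq = seqs,
                 five_pos = anchors, three_pos = 1L, offset = anchors,
                 five_mm = 0L, three_mm = 0L, strand = strand)
}

test_that("consensus score S measures disagreement among stacked reads", {
  base <- paste(rep("ACGT", 30), collapse = "")
  # identical reads: unanimous, S = 0
  cs <- consensus_and_score(stack_members(rep(substr(base, 1, 60), 3),
                                          c(10L, 10L, 10L)))
  expect_equal(cs$score, 0)
  expect_equal(cs$consensus, substr(base, 1, 60))

  # two reads overlapping at one position that disagree there: S = 1/2
  s1 <- "AAAAAAAAAT"   # last base conflicts with the next read's first base
  s2 <- "CAAAAAAAAA"
  cs2 <- consensus_and_score(stack_members(c(s1, s2), c(1L, 10L)))
  expect_equal(cs2$score, 0.5)

  # S is invariant to read input order
  set.seed(41)
  seqs <- substring(base, 1:6, 61:66)
  anchors <- 1:6
  ref <- consensus_and_score(stack_members(seqs, as.integer(anchors)))
  perm <- sample(6)
  expect_equal(consensus_and_score(
    stack_members(seqs[perm], as.integer(anchors[perm])))$score, ref$score)
})

test_that("mean S tracks the analytic error expectation on depth-2 stacks", {
  # two reads fully overlapping over 100 positions with i.i.d. errors at 1%:
  # E[S] per position ~ p (tie positions count 1/2), so E[S] ~ 1 over 100
  set.seed(42)
  truth <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  mutate_seq <- function(s, rate) {
    pos <- which(runif(nchar(s)) < rate)
    for (p in pos) {
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
    }
    s
  }
  scores <- vapply(1:400, function(i) {
    consensus_and_score(stack_members(c(mutate_seq(truth, 0.01),
                                        mutate_seq(truth, 0.01)),
                                      c(1L, 1L)))$score
  }, numeric(1))
  # analytic: 100 * (p(1-p) + p^2/3) ~ 0.99, within Monte-Carlo error
  expect_equal(mean(scores), 0.99, tolerance = 0.15)
})

test_that("bin pairs require three reads with unique offsets", {
  mk_splits <- function(five, three = 101L) {
    tibble::tibble(read_id = sprintf("r%02d", seq_along(five)), chrom = "chr1",
                   strand = "+", five_pos = five, three_pos = three,
                   five_mm = 0L, three_mm = 0L, seq = strrep("A", 100))
  }
  # offsets {0, 7, 19} within the donor bin: retained
  expect_equal(nrow(collect_bin_pairs(mk_splits(c(501L, 508L, 520L)))), 1)
  # two reads share an offset: only 2 unique -> dropped
  expect_equal(nrow(collect_bin_pairs(mk_splits(c(501L, 501L, 520L)))), 0)
  # a smaller bin size splits a group that straddles a bin edge
  sp <- mk_splits(c(510L, 520L, 530L))
  expect_equal(nrow(collect_bin_pairs(sp, bin_size = 50)), 1)
  expect_equal(nrow(collect_bin_pairs(sp, bin_size = 25)), 0)
})

test_that("screening drops high scores and multi-breakpoint stacks", {
  pairs <- collect_bin_pairs(tibble::tibble(
    read_id = sprintf("r%02d", 1:3), chrom = "chr1", strand = "+",
    five_pos = c(501L, 508L, 520L), three_pos = 101L,
    five_mm = 0L, three_mm = 0L, seq = strrep("A", 100)))
  scr <- screen_candidates(pairs)
  expect_equal(nrow(scr), 1)
  expect_equal(scr$score, 0)

  # the threshold on S is strict: 4.9 kept, 5.0 dropped
  fake <- dplyr::bind_rows(scr, scr)
  fake$score <- c(4.9, 5.0)
  fake$n_conflicts <- 0L
  kept <- fake[fake$score < 5 & fake$n_conflicts <= 1, ]
  expect_equal(kept$score, 4.9)

  # reads mixing two splices a few nt apart produce conflicting consensus
  # columns and are rejected
  set.seed(43)
  a <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  b <- a
  for (p in 61:75) substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                     substr(b, p, p)), 1)
  mix <- tibble::tibble(
    read_id = sprintf("r%02d", 1:6), chrom = "chr1", strand = "+",
    five_pos = c(501L, 503L, 505L, 501L, 503L, 505L), three_pos = 101L,
    five_mm = 0L, three_mm = 0L,
    seq = c(substring(a, 1:3, 100:102), substring(b, 1:3, 100:102)))
  scr2 <- screen_candidates(collect_bin_pairs(mix))
  expect_equal(nrow(scr2), 0)
})

test_that("breakpoints map exactly at planted GT-AG sites", {
  cfg <- sim_config(seed = 44, n_clean_genes = 0, n_homolog_genes = 0,
                    error_rate = 0, linear_frags_per_gene = 0,
                    n_novel_circles = 1, novel_frags_per_circle = 120)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim)
  splits <- find_split_alignments(setNames(rd$reads$r1, rd$reads$read_id),
                                  sim$genome)
  expect_gt(nrow(splits), 3)
  scr <- screen_candidates(collect_bin_pairs(splits))
  expect_gte(nrow(scr), 1)
  bp <- map_breakpoint(scr[1, ], sim$genome)
  expect_equal(bp$donor, sim$novel_circles$donor)
  expect_equal(bp$acceptor, sim$novel_circles$acceptor)
  expect_equal(bp$donor_di, "GT")
  expect_equal(bp$acceptor_di, "AG")
  expect_equal(bp$signal_class, "U2")

  # a consensus too short to split into two >= 20-nt fragments is dropped
  short <- scr[1, ]
  short$consensus <- substr(short$consensus, 1, 35)
  expect_null(map_breakpoint(short, sim$genome))
})

test_that("split alignments keep only backsplice-orientation reads", {
  set.seed(45)
  g <- setNames(paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                      collapse = ""), "chr1")
  gs <- g[[1]]
  # backsplice read: 5' half from downstream (2001..2050), 3' half upstream
  back <- paste0(substr(gs, 2001, 2050), substr(gs, 501, 550))
  # linear-orientation read: genomic order
  lin <- paste0(substr(gs, 501, 550), substr(gs, 2001, 2050))
  # opposite-strand chimera: 3' half reverse-complemented
  opp <- paste0(substr(gs, 2001, 2050),
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(substr(gs, 501, 550)))))
  sp <- find_split_alignments(c(b = back, l = lin, o = opp), g,
                              segment_len = 35)
  expect_equal(sp$read_id, "b")
  expect_gt(sp$five_pos, sp$three_pos)
})

test_that("junctions are named by nearby genes or UNAN", {
  exons <- toy_exons(c(10000, 12000), c(200, 200), gene_id = "geneA")
  bp <- tibble::tibble(donor = 12700, acceptor = 12500)
  expect_equal(name_and_classify(bp, "chr1", exons), "geneA")  # 500 nt away
  far <- tibble::tibble(donor = 17400, acceptor = 17200)       # 5 kb away
  expect_equal(name_and_classify(far, "chr1", exons), "UNAN")
  inside <- tibble::tibble(donor = 11000, acceptor = 10800)
  expect_equal(name_and_classify(inside, "chr1", exons), "geneA")
  expect_equal(name_and_classify(bp, "chr2", exons), "UNAN")
})

test_that("realignment filters enforce the de novo retention rules", {
  cfg <- sim_config(seed = 46, n_clean_genes = 1, n_homolog_genes = 0,
                    error_rate = 0, circle_frags_clean = 0,
                    linear_frags_per_gene = 40,
                    n_novel_circles = 2, novel_frags_per_circle = 130)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim)
  res <- align_and_classify(sim, rd)
  un <- !(rd$reads$read_id %in%
            unique(res$alignments$read_id[res$alignments$mate == "R1"]))
  dn <- discover_denovo(setNames(rd$reads$r1[un], rd$reads$read_id[un]),
                        setNames(rd$reads$r2[un], rd$reads$read_id[un]),
                        sim$genome, sim$exons)
  expect_equal(nrow(dn$calls), 2)
  expect_setequal(dn$calls$donor, sim$novel_circles$donor)
  expect_setequal(dn$calls$acceptor, sim$novel_circles$acceptor)
  expect_true(all(dn$calls$signal_class == "U2"))
  expect_true(all(dn$calls$naive_p > 0.9))
  expect_true(all(dn$calls$decoy_ratio < 0.1))
  expect_true(all(dn$calls$span > 200))

  # the decoy-ratio and span filters drop failing junctions
  asm <- dn$assemblies
  fake_calls <- realign_and_filter(
    setNames(rd$reads$r1[un], rd$reads$read_id[un]),
    setNames(rd$reads$r2[un], rd$reads$read_id[un]),
    asm, sim$genome, min_span = 1000)
  expect_equal(nrow(fake_calls), 0)  # spans are ~400 nt: all filtered

  # linear-only simulations yield no de novo junctions
  cfg_l <- sim_config(seed = 47, n_clean_genes = 2, n_homolog_genes = 0,
                      circle_frags_clean = 0, linear_frags_per_gene = 80,
                      error_rate = 0.01)
  sim_l <- simulate_genome(cfg_l)
  rd_l <- simulate_reads(sim_l)
  res_l <- align_and_classify(sim_l, rd_l)
  un_l <- !(rd_l$reads$read_id %in%
              unique(res_l$alignments$read_id[res_l$alignments$mate == "R1"]))
  dn_l <- discover_denovo(setNames(rd_l$reads$r1[un_l], rd_l$reads$read_id[un_l]),
                          setNames(rd_l$reads$r2[un_l], rd_l$reads$read_id[un_l]),
                          sim_l$genome, sim_l$exons)
  expect_equal(nrow(dn_l$calls), 0)
})
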