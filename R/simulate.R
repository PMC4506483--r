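# Synthetic-data generator: toy genomes with planted circles and homologous
# exons, paired-end reads with a per-base substitution error model,
# aligner-free feature tables, and multi-timepoint count tables.
#
# The genome layout emulates the two processes the detection problem is
# about: (1) genuine backsplices (a circle over exons e2..e4 of each gene)
# and (2) ALU-like within-gene homology (in "homolog" genes, exon e3 is a
# near-copy of the circle's acceptor exon e2, distinguished by a handful of
# substitutions). Reads from a homolog gene's circle that do not cover the
# diverged positions tie between the true backsplice and the
# homolog-acceptor scrambled junction, producing artifact junctions,
# false-positive circular reads, and decoy reads - the same taxonomy the
# statistical model is built to resolve.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with the default study
#' conditions: 100-nt paired-end reads, a 0.01 per-base substitution error
#' rate (Illumina-like), fragments of 260 +/- 35 nt, and a genome of six
#' five-exon genes on one chromosome - two with clean circles and four
#' whose circle acceptor exon has a near-identical homolog (2 diverged
#' positions) inside the circle.
#'
#' @param seed Integer seed; all generator functions are deterministic given
#'   the seed.
#' @param read_len Read length (nt).
#' @param fragment_mean,fragment_sd Fragment length distribution (nt).
#' @param error_rate Per-base substitution probability.
#' @param n_clean_genes,n_homolog_genes Genes without / with a homologous
#'   exon pair.
#' @param exon_len,acceptor_exon_len Exon lengths (nt); the circle acceptor
#'   exon (e2) and its homolog copy use `acceptor_exon_len`.
#' @param intron_len,gene_gap Intron length and intergenic gap (nt).
#' @param homolog_divergence Substitutions distinguishing a homolog pair
#'   (d <= 2).
#' @param divergence_pos Positions (nt from the exon start) of the diverged
#'   bases, both on the acceptor side of a junction sequence; reads whose
#'   junction overlap stops short of the first one cannot distinguish the
#'   homologs at all and tie between the true and the artifact junction.
#' @param linear_frags_per_gene,circle_frags_clean,circle_frags_homolog
#'   Fragment counts per linear transcript and per circle.
#' @param n_novel_circles,novel_circle_len,novel_frags_per_circle
#'   Un-annotated GT-AG circles planted in intergenic space for de novo
#'   discovery.
#' @param min_overlap Minimum junction overlap used in truth labelling.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, read_len = 100,
                       fragment_mean = 260, fragment_sd = 35,
                       error_rate = 0.01,
                       n_clean_genes = 2, n_homolog_genes = 4,
                       exon_len = 140, acceptor_exon_len = 250,
                       intron_len = 150, gene_gap = 400,
                       homolog_divergence = 2, divergence_pos = c(40, 60),
                       linear_frags_per_gene = 120,
                       circle_frags_clean = 100,
                       circle_frags_homolog = 1000,
                       n_novel_circles = 0, novel_circle_len = 400,
                       novel_frags_per_circle = 150,
                       min_overlap = 10) {
  cfg <- as.list(environment())
  abort_if(error_rate < 0 || error_rate > 1, "error_rate must lie in [0, 1]")
  abort_if(homolog_divergence < 1 || homolog_divergence > 2,
           "homolog_divergence must be 1 or 2")
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each position with a uniformly drawn different base
substitute_base <- function(seq, pos, avoid) {
  for (i in seq_along(pos)) {
    alt <- setdiff(c("A", "C", "G", "T"), avoid[i])
    substr(seq, pos[i], pos[i]) <- sample(alt, 1)
  }
  seq
}

#' Simulate a toy genome with planted circles and homologous exons
#'
#' Lays out `n_clean_genes + n_homolog_genes` five-exon genes (plus strand)
#' on a single random chromosome, each expressing a circle over exons
#' e2..e4. In homolog genes, exon e3 is copied from e2 and then diverged at
#' the `divergence_pos` positions from the exon start, both visible on the
#' acceptor side of a junction sequence. Optionally plants
#' un-annotated circles at GT-AG boundaries in intergenic space for de novo
#' discovery, with breakpoints separated by well over 200 nt.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genome` (named character), `exons` (exon tibble),
#'   `circles` (planted circle tibble with expected `junction_id`),
#'   `artifact_junctions` (the homolog-acceptor scrambled junctions that
#'   reads can be misassigned to), `novel_circles`, and `cfg`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_genes <- cfg$n_clean_genes + cfg$n_homolog_genes
  abort_if(n_genes < 1 && cfg$n_novel_circles < 1, "nothing to simulate")

  exon_rows <- list()
  gene_kind <- rep(c("clean", "homolog"),
                   c(cfg$n_clean_genes, cfg$n_homolog_genes))
  pos <- cfg$gene_gap + 1
  chrom_parts <- list(random_dna(cfg$gene_gap))
  for (gi in seq_len(n_genes)) {
    gene_id <- sprintf("gene%02d", gi)
    homolog <- gene_kind[gi] == "homolog"
    lens <- c(cfg$exon_len, cfg$acceptor_exon_len,
              if (homolog) cfg$acceptor_exon_len else cfg$exon_len,
              cfg$exon_len, cfg$exon_len)
    e2_seq <- random_dna(lens[2])
    seqs <- lapply(seq_along(lens), function(k) {
      if (k == 2) return(e2_seq)
      if (k == 3 && homolog) {
        s <- e2_seq
        dpos <- cfg$divergence_pos[seq_len(cfg$homolog_divergence)]
        s <- substitute_base(s, dpos, substring(s, dpos, dpos))
        return(s)
      }
      random_dna(lens[k])
    })
    for (k in seq_along(lens)) {
      exon_rows[[length(exon_rows) + 1]] <- tibble::tibble(
        chrom = "chr1", start = pos, end = pos + lens[k] - 1L, strand = "+",
        gene_id = gene_id, exon_id = sprintf("%s.e%d", gene_id, k),
        kind = gene_kind[gi])
      chrom_parts[[length(chrom_parts) + 1]] <- seqs[[k]]
      pos <- pos + lens[k]
      filler <- if (k < length(lens)) cfg$intron_len else cfg$gene_gap
      chrom_parts[[length(chrom_parts) + 1]] <- random_dna(filler)
      pos <- pos + filler
    }
  }

  novel <- NULL
  if (cfg$n_novel_circles > 0) {
    rows <- list()
    for (ci in seq_len(cfg$n_novel_circles)) {
      acceptor <- pos + 300L       # leave >200 nt between planted breakpoints
      donor <- acceptor + cfg$novel_circle_len - 1L
      seg <- random_dna(cfg$novel_circle_len + 600L)
      # GT immediately downstream of the donor, AG immediately upstream of
      # the acceptor: a canonical U2 intron context
      substr(seg, 299L, 300L) <- "AG"
      substr(seg, 300L + cfg$novel_circle_len + 1L,
             300L + cfg$novel_circle_len + 2L) <- "GT"
      chrom_parts[[length(chrom_parts) + 1]] <- seg
      rows[[ci]] <- tibble::tibble(
        circle_id = sprintf("novel%02d", ci), chrom = "chr1",
        acceptor = acceptor, donor = donor)
      pos <- pos + nchar(seg)
    }
    novel <- dplyr::bind_rows(rows)
  }

  genome <- c(chr1 = paste(unlist(chrom_parts), collapse = ""))
  exons <- if (length(exon_rows) > 0) dplyr::bind_rows(exon_rows) else
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   strand = character(), gene_id = character(),
                   exon_id = character(), kind = character())

  circles <- artifacts <- NULL
  if (nrow(exons) > 0) {
    by_gene <- split(exons, exons$gene_id)
    circles <- dplyr::bind_rows(lapply(by_gene, function(g) {
      tibble::tibble(
        gene_id = g$gene_id[1], kind = g$kind[1],
        donor_exon = g$exon_id[4], acceptor_exon = g$exon_id[2],
        junction_id = paste("chr1", g$end[4], g$start[2], "+", sep = ":"),
        lo = g$start[2], hi = g$end[4])
    }))
    hom <- dplyr::filter(circles, .data$kind == "homolog")
    if (nrow(hom) > 0) {
      artifacts <- dplyr::bind_rows(lapply(by_gene[hom$gene_id], function(g) {
        tibble::tibble(
          gene_id = g$gene_id[1],
          junction_id = paste("chr1", g$end[4], g$start[3], "+", sep = ":"))
      }))
    }
  }

  list(genome = genome, exons = dplyr::select(exons, -"kind"),
       circles = circles, artifact_junctions = artifacts,
       novel_circles = novel, cfg = cfg)
}

# per-read substitution errors at cfg$error_rate, uniform over the other
# three bases; returns the mutated reads and the per-read error count
add_read_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) {
    return(list(seq = seqs, n_err = integer(length(seqs))))
  }
  len <- nchar(seqs[1])
  n_err <- rbinom(length(seqs), len, rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    pos <- sample.int(len, n_err[i])
    seqs[i] <- substitute_base(seqs[i], pos,
                               substring(seqs[i], pos, pos))
  }
  list(seq = seqs, n_err = n_err)
}

#' Simulate paired-end reads from linear and circular isoforms
#'
#' Draws fragments from every gene's linear transcript, from every planted
#' circle (templates wrap around the backsplice, so circles shorter than a
#' read generate doubly junctional reads), and from un-annotated circles.
#' R1 is the first `read_len` bases of the fragment (sense), R2 the reverse
#' complement of the last `read_len` bases; substitution errors are applied
#' at `error_rate` per base. The truth table records, per read pair, the
#' source isoform and the junction R1 truly spans (with its offset), which
#' downstream classification should recover for error-free reads.
#'
#' @param sim Output of [simulate_genome()].
#' @param seed Optional seed override (default `cfg$seed + 1`).
#' @return A list with `reads` (tibble `read_id`, `r1`, `r2`) and `truth`.
#' @export
simulate_reads <- function(sim, seed = NULL) {
  cfg <- sim$cfg
  set.seed(seed %||% (cfg$seed + 1L))
  exons <- sim$exons
  sources <- list()

  add_source <- function(id, seq, circular, n_frags, boundaries) {
    sources[[length(sources) + 1]] <<- list(
      id = id, seq = seq, circular = circular, n = n_frags,
      boundaries = boundaries)
  }

  if (!is.null(exons) && nrow(exons) > 0) {
    for (g in split(exons, exons$gene_id)) {
      g <- g[order(g$start), ]
      exseq <- substring(sim$genome["chr1"], g$start, g$end)
      lens <- nchar(exseq)
      cum <- cumsum(lens)
      # linear transcript: boundaries after e1..e4, all linear junctions
      lin_b <- tibble::tibble(
        pos = cum[-length(cum)],
        junction_id = paste("chr1", g$end[-nrow(g)], g$start[-1], "+", sep = ":"),
        category = "linear")
      add_source(paste0(g$gene_id[1], ".lin"), paste(exseq, collapse = ""),
                 FALSE, cfg$linear_frags_per_gene, lin_b)
      # circle over e2..e4: interior linear boundaries + the backsplice
      ci <- sim$circles[sim$circles$gene_id == g$gene_id[1], ]
      circ_seq <- paste(exseq[2:4], collapse = "")
      circ_cum <- cumsum(lens[2:4])
      circ_b <- tibble::tibble(
        pos = c(circ_cum[1:2], circ_cum[3]),
        junction_id = c(
          paste("chr1", g$end[2], g$start[3], "+", sep = ":"),
          paste("chr1", g$end[3], g$start[4], "+", sep = ":"),
          ci$junction_id),
        category = c("linear", "linear", "circular"))
      n_circ <- if (ci$kind == "homolog") cfg$circle_frags_homolog else
        cfg$circle_frags_clean
      add_source(paste0(g$gene_id[1], ".circ"), circ_seq, TRUE, n_circ, circ_b)
    }
  }
  if (!is.null(sim$novel_circles) && nrow(sim$novel_circles) > 0) {
    for (i in seq_len(nrow(sim$novel_circles))) {
      nv <- sim$novel_circles[i, ]
      seq <- substr(sim$genome["chr1"], nv$acceptor, nv$donor)
      add_source(nv$circle_id, seq, TRUE, cfg$novel_frags_per_circle,
                 tibble::tibble(pos = nchar(seq), junction_id = nv$circle_id,
                                category = "circular"))
    }
  }
  abort_if(length(sources) == 0, "no read sources: empty simulation")

  reads <- list(); truth <- list(); counter <- 0L
  for (src in sources) {
    if (src$n == 0) next
    slen <- nchar(src$seq)
    flen <- pmax(cfg$read_len + 10L,
                 round(rnorm(src$n, cfg$fragment_mean, cfg$fragment_sd)))
    if (!src$circular) flen <- pmin(flen, slen)
    start <- if (src$circular) sample.int(slen, src$n, replace = TRUE) else
      vapply(flen, function(fl) sample.int(slen - fl + 1L, 1L), integer(1))
    tmpl <- if (src$circular) {
      strrep(src$seq, ceiling((max(start + flen)) / slen))
    } else src$seq
    frag1 <- substring(tmpl, start, start + cfg$read_len - 1L)
    frag2 <- substring(tmpl, start + flen - cfg$read_len, start + flen - 1L)
    ids <- sprintf("rd%07d", counter + seq_len(src$n))
    counter <- counter + src$n

    # which boundary does R1 truly span (offset = smaller side)?
    b_pos <- src$boundaries$pos
    r1_end <- start + cfg$read_len - 1L
    tj <- rep(NA_character_, src$n); tc <- rep(NA_character_, src$n)
    toff <- rep(NA_integer_, src$n)
    for (k in seq_along(b_pos)) {
      # boundary occurs at template positions b, b + slen, ... for circles
      reps <- if (src$circular) 0:ceiling(max(r1_end) / slen) else 0L
      for (rp in reps) {
        b <- b_pos[k] + rp * slen
        left <- b - start + 1L
        right <- r1_end - b
        hit <- left >= cfg$min_overlap & right >= cfg$min_overlap
        off <- pmin(left, right)
        tj[hit] <- src$boundaries$junction_id[k]
        tc[hit] <- src$boundaries$category[k]
        toff[hit] <- off[hit]
      }
    }
    e1 <- add_read_errors(frag1, cfg$error_rate)
    e2 <- add_read_errors(revcomp(frag2), cfg$error_rate)
    reads[[length(reads) + 1]] <- tibble::tibble(
      read_id = ids, r1 = e1$seq, r2 = e2$seq)
    truth[[length(truth) + 1]] <- tibble::tibble(
      read_id = ids, source = src$id,
      origin = if (src$circular) "circular" else "linear",
      true_junction = tj, true_category = tc, true_offset = toff,
      r1_errors = e1$n_err, r2_errors = e2$n_err,
      frag_start = start, frag_len = flen)
  }
  list(reads = dplyr::bind_rows(reads), truth = dplyr::bind_rows(truth))
}

#' Simulate an aligner-free read feature table
#'
#' Draws (offset, alignment score, mapping quality) directly from
#' class-conditional distributions, bypassing sequences entirely - the
#' primary test input for the GLM module. In the `"separable"` scenario the
#' classes follow the pattern seen in real data: linear and true circular
#' reads have offsets spread over the read, near-zero alignment scores and
#' high mapping quality, while decoy and artifact-junction reads have small
#' offsets, depressed scores and low mapping quality. In the `"null"`
#' scenario every class shares the linear distribution (no signal).
#'
#' @param n_linear,n_decoy Training read counts.
#' @param n_true_junctions,n_artifact_junctions Circular junction counts.
#' @param reads_per_junction Mean non-decoy reads per circular junction
#'   (Poisson, min 1).
#' @param scenario `"separable"` or `"null"`.
#' @param read_len Read length (offsets are capped at `read_len / 2`).
#' @param seed Seed.
#' @return A feature tibble with `category`, `junction_id`, the three
#'   predictors, and `true_status` (`"real"`/`"artifact"`/`NA`).
#' @export
simulate_feature_table <- function(n_linear = 2000, n_decoy = 300,
                                   n_true_junctions = 40,
                                   n_artifact_junctions = 40,
                                   reads_per_junction = 5,
                                   scenario = c("separable", "null"),
                                   read_len = 100, seed = 1) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  half <- read_len / 2

  draw_good <- function(n) tibble::tibble(
    offset = pmin(half, sample(10:half, n, replace = TRUE)),
    alignment_score = -6 * rpois(n, 0.4),
    mapq = sample(c(42, 30, 12), n, replace = TRUE, prob = c(0.85, 0.1, 0.05)))
  draw_bad <- function(n) {
    if (scenario == "null") return(draw_good(n))
    tibble::tibble(
      offset = pmin(half, 10 + rpois(n, 4)),
      alignment_score = -6 * rpois(n, 1.5),
      mapq = sample(c(3, 12, 30), n, replace = TRUE, prob = c(0.65, 0.25, 0.1)))
  }

  n_per <- function(k) pmax(1L, rpois(k, reads_per_junction))
  nt <- n_per(n_true_junctions); na <- n_per(n_artifact_junctions)
  dplyr::bind_rows(
    dplyr::mutate(draw_good(n_linear), category = "linear",
                  junction_id = sprintf("lin%05d", seq_len(n_linear)),
                  cls = "linear", true_status = NA_character_),
    dplyr::mutate(draw_bad(n_decoy), category = "decoy",
                  junction_id = sprintf("art%04d",
                                        sample.int(max(1, n_artifact_junctions),
                                                   n_decoy, replace = TRUE)),
                  cls = "scrambled", true_status = NA_character_),
    dplyr::mutate(draw_good(sum(nt)), category = "circular",
                  junction_id = rep(sprintf("true%04d", seq_len(n_true_junctions)), nt),
                  cls = "scrambled", true_status = "real"),
    dplyr::mutate(draw_bad(sum(na)), category = "circular",
                  junction_id = rep(sprintf("art%04d", seq_len(n_artifact_junctions)), na),
                  cls = "scrambled", true_status = "artifact")) |>
    dplyr::mutate(read_id = sprintf("fr%06d", dplyr::row_number()),
                  mismatches = as.integer(-.data$alignment_score / 6),
                  aligned_len = read_len) |>
    dplyr::relocate("read_id", "junction_id", "cls", "category")
}

#' Simulate a multi-timepoint junction count table with planted induction
#'
#' Counts are Poisson with per-junction means
#' `mu_ij = base_j * (1 + slope_j * age_i)`; circular junctions get the
#' planted slope (per week of age), linear junctions slope 0 unless
#' specified. The default ages span 10-21 gestational weeks.
#'
#' @param n_circular,n_linear Junction counts per role.
#' @param ages Sample ages in weeks.
#' @param base_mean Mean of the per-junction baseline expression
#'   (log-normal).
#' @param circular_slope,linear_slope Planted relative increase per week.
#' @param seed Seed.
#' @return A list with `counts` (long tibble `junction_id`, `sample_id`,
#'   `count`), `samples` (sample sheet with `age_weeks`), and `truth`
#'   (per-junction role and slope).
#' @export
simulate_count_table <- function(n_circular = 200, n_linear = 800,
                                 ages = seq(10, 21, length.out = 6),
                                 base_mean = 30, circular_slope = 0.15,
                                 linear_slope = 0, seed = 1) {
  set.seed(seed)
  abort_if(length(ages) < 3, "need at least three samples")
  n <- n_circular + n_linear
  truth <- tibble::tibble(
    junction_id = c(sprintf("circ%05d", seq_len(n_circular)),
                    sprintf("lin%05d", seq_len(n_linear))),
    role = rep(c("circular", "exterior_linear"), c(n_circular, n_linear)),
    slope = rep(c(circular_slope, linear_slope), c(n_circular, n_linear)),
    base = exp(rnorm(n, log(base_mean), 0.5)))
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_along(ages)), age_weeks = ages)
  grid <- tidyr::expand_grid(truth, samples)
  mu <- grid$base * (1 + grid$slope * grid$age_weeks)
  abort_if(any(mu < 0), "negative Poisson mean: slope too negative for ages")
  counts <- grid |>
    dplyr::mutate(count = rpois(dplyr::n(), mu)) |>
    dplyr::select("junction_id", "sample_id", "count")
  list(counts = counts, samples = samples, truth = truth)
}

#' Write simulated reads as FASTQ files
#'
#' @param reads Read tibble from [simulate_reads()].
#' @param dir Output directory; writes `reads_1.fastq` and `reads_2.fastq`.
#' @return Invisibly, the two paths.
#' @export
write_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("reads_1.fastq", "reads_2.fastq"))
  for (k in 1:2) {
    seqs <- if (k == 1) reads$r1 else reads$r2
    writeLines(paste0("@", reads$read_id, "/", k, "\n", seqs, "\n+\n",
                      strrep("I", nchar(seqs))), paths[k])
  }
  invisible(paths)
}

#' Write a simulated genome and annotation to FASTA and GTF
#'
#' @param sim Output of [simulate_genome()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_genome_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  seqs <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(seqs, fa)
  gtf <- file.path(dir, "annotation.gtf")
  ex <- sim$exons
  lines <- sprintf(
    '%s\tcircjunct_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; exon_id "%s";',
    ex$chrom, ex$start, ex$end, ex$strand, ex$gene_id, ex$exon_id)
  writeLines(lines, gtf)
  invisible(c(fa, gtf))
}
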