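#' Build the linear and scrambled junction sequence database
#'
#' Constructs the reference database of exon-exon junction sequences used to
#' detect circular RNA. Every unordered pair of (deduplicated) exons on the
#' same chromosome and strand whose start coordinates lie within `window`
#' bases of each other contributes two junctions: one *linear* junction (the
#' exons joined in canonical transcript order) and one *scrambled* junction
#' (the same exons joined in backsplice order, diagnostic of a circle). Each
#' single exon additionally contributes one scrambled self-junction,
#' representing circularization of that exon alone.
#'
#' Each junction sequence is built from `pad_side` bases of each flanking
#' exon: the last `pad_side` transcript-orientation bases of the donor exon
#' followed by the first `pad_side` bases of the acceptor exon (both reverse
#' complemented for minus-strand genes). Exons shorter than `pad_side` are
#' padded with `N` on the side away from the splice boundary, so every
#' sequence has length exactly `2 * pad_side` and the boundary always sits
#' after position `pad_side`. The padding removes the length bias against
#' circles made of small exons.
#'
#' @param exons A data frame of exons with columns `chrom`, `start`, `end`
#'   (1-based, closed), `strand` (`"+"` or `"-"`), `gene_id`, `exon_id`.
#'   Exons identical on (chrom, start, end, strand) across transcripts are
#'   collapsed before pairing.
#' @param genome A genome sequence provider: a named character vector, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file.
#' @param window Maximum distance (nt) between the start coordinates of two
#'   exons for them to be paired. Default 1e6.
#' @param pad_side Bases contributed by each exon side. Default 150.
#' @return A tibble with one row per junction and columns `junction_id`
#'   (`chrom:pos5:pos3:strand`, 1-based splice-site positions), `chrom`,
#'   `strand`, `cls` (`"linear"` or `"scrambled"`), donor/acceptor exon
#'   coordinates and gene ids, `cross_gene`, `sequence` (length
#'   `2 * pad_side`), and `boundary_index` (`= pad_side`). The `window` and
#'   `pad_side` used are attached as attributes.
#' @examples
#' exons <- tibble::tibble(
#'   chrom = "chr1", start = c(101, 1001), end = c(300, 1300),
#'   strand = "+", gene_id = "g1", exon_id = c("e1", "e2"))
#' genome <- c(chr1 = paste(rep("ACGT", 500), collapse = ""))
#' jdb <- build_junction_db(exons, genome)
#' table(jdb$cls)
#' @export
build_junction_db <- function(exons, genome, window = 1e6, pad_side = 150) {
  genome <- as_genome(genome)
  exons <- validate_exons(exons)
  if (nrow(exons) == 0) {
    warning("empty annotation: returning an empty junction set")
    return(empty_junction_set(window, pad_side))
  }
  check_exon_bounds(exons, genome)

  ex <- dplyr::distinct(exons, .data$chrom, .data$start, .data$end,
                        .data$strand, .keep_all = TRUE)
  ex <- dplyr::arrange(ex, .data$chrom, .data$start, .data$end)

  per_group <- ex |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::group_split()

  rows <- purrr::map(per_group, function(g) {
    n <- nrow(g)
    # self scrambled junction for every exon
    self <- tibble::tibble(d = seq_len(n), a = seq_len(n), cls = "scrambled")
    if (n >= 2) {
      idx <- utils::combn(n, 2)
      keep <- abs(g$start[idx[2, ]] - g$start[idx[1, ]]) <= window
      idx <- idx[, keep, drop = FALSE]
      # g sorted by start: on "+" the transcript-upstream exon is idx[1,];
      # on "-" it is idx[2,]
      if (ncol(idx) > 0) {
        up <- idx[1, ]; dn <- idx[2, ]
        if (g$strand[1] == "-") { tmp <- up; up <- dn; dn <- tmp }
        pairs <- dplyr::bind_rows(
          tibble::tibble(d = up, a = dn, cls = "linear"),
          tibble::tibble(d = dn, a = up, cls = "scrambled"))
      } else pairs <- NULL
    } else pairs <- NULL
    both <- dplyr::bind_rows(self, pairs)
    tibble::tibble(
      chrom = g$chrom[1], strand = g$strand[1], cls = both$cls,
      donor_start = g$start[both$d], donor_end = g$end[both$d],
      acceptor_start = g$start[both$a], acceptor_end = g$end[both$a],
      donor_gene = g$gene_id[both$d], acceptor_gene = g$gene_id[both$a],
      donor_exon = g$exon_id[both$d], acceptor_exon = g$exon_id[both$a])
  })
  jdb <- dplyr::bind_rows(rows)
  if (nrow(jdb) == 0) return(empty_junction_set(window, pad_side))

  minus <- jdb$strand == "-"
  pos5 <- ifelse(minus, jdb$donor_start, jdb$donor_end)
  pos3 <- ifelse(minus, jdb$acceptor_end, jdb$acceptor_start)
  jdb$junction_id <- paste(jdb$chrom, pos5, pos3, jdb$strand, sep = ":")
  jdb$cross_gene <- jdb$donor_gene != jdb$acceptor_gene

  jdb$sequence <- paste0(
    exon_side_seq(genome, jdb$chrom, jdb$donor_start, jdb$donor_end,
                  jdb$strand, pad_side, side = "donor"),
    exon_side_seq(genome, jdb$chrom, jdb$acceptor_start, jdb$acceptor_end,
                  jdb$strand, pad_side, side = "acceptor"))
  jdb$boundary_index <- pad_side

  jdb <- dplyr::select(
    jdb, "junction_id", "chrom", "strand", "cls",
    "donor_start", "donor_end", "acceptor_start", "acceptor_end",
    "donor_gene", "acceptor_gene", "donor_exon", "acceptor_exon",
    "cross_gene", "sequence", "boundary_index")
  attr(jdb, "window") <- window
  attr(jdb, "pad_side") <- pad_side
  jdb
}

empty_junction_set <- function(window, pad_side) {
  out <- tibble::tibble(
    junction_id = character(), chrom = character(), strand = character(),
    cls = character(), donor_start = integer(), donor_end = integer(),
    acceptor_start = integer(), acceptor_end = integer(),
    donor_gene = character(), acceptor_gene = character(),
    donor_exon = character(), acceptor_exon = character(),
    cross_gene = logical(), sequence = character(), boundary_index = integer())
  attr(out, "window") <- window
  attr(out, "pad_side") <- pad_side
  out
}

validate_exons <- function(exons) {
  need <- c("chrom", "start", "end", "strand", "gene_id", "exon_id")
  missing <- setdiff(need, names(exons))
  abort_if(length(missing) > 0,
           paste("exon table is missing columns:", paste(missing, collapse = ", ")))
  exons <- tibble::as_tibble(exons)
  abort_if(any(exons$start > exons$end), "exon start must not exceed end")
  abort_if(!all(exons$strand %in% c("+", "-")), "strand must be '+' or '-'")
  exons
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && is.null(names(genome)) && length(genome) == 1 &&
      file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  abort_if(!is.character(genome) || is.null(names(genome)),
           "genome must be a named character vector, DNAStringSet, or FASTA path")
  Biostrings::DNAStringSet(genome)
}

check_exon_bounds <- function(exons, genome) {
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  bad_chrom <- !(exons$chrom %in% names(lens))
  abort_if(any(bad_chrom),
           paste0("exon ", exons$exon_id[bad_chrom][1], " is on unknown chromosome ",
                  exons$chrom[bad_chrom][1]))
  bad <- exons$start < 1 | exons$end > lens[exons$chrom]
  abort_if(any(bad),
           paste0("exon ", exons$exon_id[bad][1], " (", exons$chrom[bad][1], ":",
                  exons$start[bad][1], "-", exons$end[bad][1],
                  ") lies outside the genome sequence"))
  invisible(TRUE)
}

# Extract one side of a junction sequence in transcript orientation.
# Donor side: last `pad` transcript bases, N-padded on the left (distal).
# Acceptor side: first `pad` transcript bases, N-padded on the right.
exon_side_seq <- function(genome, chrom, start, end, strand, pad, side) {
  len <- pmin(end - start + 1L, pad)
  plus <- strand == "+"
  take_end <- (side == "donor") == plus  # genomic end of the exon?
  g_start <- ifelse(take_end, end - len + 1L, start)
  g_end <- ifelse(take_end, end, start + len - 1L)
  seqs <- as.character(Biostrings::subseq(
    genome[chrom], start = g_start, end = g_end))
  seqs[!plus] <- revcomp(seqs[!plus])
  padding <- strrep("N", pad - len)
  if (side == "donor") paste0(padding, seqs) else paste0(seqs, padding)
}

#' Classify the order of a donor/acceptor exon pair
#'
#' A junction is *linear* when the donor side precedes the acceptor side in
#' transcript orientation (canonical splicing) and *scrambled* otherwise; an
#' exon donating into itself is scrambled (a single-exon circle).
#'
#' @param a Donor exon: a one-row data frame with `chrom`, `start`, `end`,
#'   `strand`.
#' @param b Acceptor exon, same format.
#' @return `"linear"` or `"scrambled"`.
#' @export
classify_pair_order <- function(a, b) {
  abort_if(a$chrom != b$chrom || a$strand != b$strand,
           "exons must be on the same chromosome and strand")
  if (a$start == b$start && a$end == b$end) return("scrambled")
  canonical <- if (a$strand == "+") a$start < b$start else a$start > b$start
  if (canonical) "linear" else "scrambled"
}

#' Write a junction set as FASTA (one file per class)
#'
#' Writes `linear.fa` and `scrambled.fa` under `dir`. Headers carry the
#' junction id plus key=value fields for every annotation column, so
#' [read_junction_fasta()] round-trips the junction set losslessly
#' (N padding included).
#'
#' @param jdb Junction tibble from [build_junction_db()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_junction_fasta <- function(jdb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cl in c("linear", "scrambled")) {
    sub <- dplyr::filter(jdb, .data$cls == cl)
    path <- file.path(dir, paste0(cl, ".fa"))
    hdr <- paste0(
      sub$junction_id,
      " cls=", sub$cls, " chrom=", sub$chrom, " strand=", sub$strand,
      " donor=", sub$donor_start, "-", sub$donor_end,
      " acceptor=", sub$acceptor_start, "-", sub$acceptor_end,
      " donor_gene=", sub$donor_gene, " acceptor_gene=", sub$acceptor_gene,
      " donor_exon=", sub$donor_exon, " acceptor_exon=", sub$acceptor_exon,
      " pad=", attr(jdb, "pad_side") %||% unique(sub$boundary_index),
      " window=", attr(jdb, "window") %||% NA)
    seqs <- Biostrings::DNAStringSet(sub$sequence)
    names(seqs) <- hdr
    Biostrings::writeXStringSet(seqs, filepath = path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a junction set written by [write_junction_fasta()]
#'
#' @param dir Directory containing `linear.fa` and `scrambled.fa`.
#' @return A junction tibble in the same format as [build_junction_db()].
#' @export
read_junction_fasta <- function(dir) {
  files <- file.path(dir, c("linear.fa", "scrambled.fa"))
  files <- files[file.exists(files)]
  abort_if(length(files) == 0, paste("no junction FASTA files under", dir))
  parts <- purrr::map(files, function(path) {
    seqs <- Biostrings::readDNAStringSet(path)
    if (length(seqs) == 0) return(NULL)
    hdr <- names(seqs)
    field <- function(key) stringr::str_match(hdr, paste0(key, "=(\\S+)"))[, 2]
    rng <- function(key) {
      m <- stringr::str_match(hdr, paste0(key, "=(\\d+)-(\\d+)"))
      list(start = as.integer(m[, 2]), end = as.integer(m[, 3]))
    }
    d <- rng("donor"); a <- rng("acceptor")
    tibble::tibble(
      junction_id = stringr::str_split_i(hdr, " ", 1),
      chrom = field("chrom"), strand = field("strand"), cls = field("cls"),
      donor_start = d$start, donor_end = d$end,
      acceptor_start = a$start, acceptor_end = a$end,
      donor_gene = field("donor_gene"), acceptor_gene = field("acceptor_gene"),
      donor_exon = field("donor_exon"), acceptor_exon = field("acceptor_exon"),
      cross_gene = field("donor_gene") != field("acceptor_gene"),
      sequence = unname(as.character(seqs)),
      boundary_index = as.integer(field("pad")),
      window_attr = as.numeric(field("window")))
  })
  out <- dplyr::bind_rows(parts)
  attr(out, "pad_side") <- out$boundary_index[1]
  attr(out, "window") <- out$window_attr[1]
  out$window_attr <- NULL
  out
}

#' Read exon records from a GTF or BED12 annotation file
#'
#' Thin wrapper over [rtracklayer::import()] that flattens exon features into
#' the exon tibble consumed by [build_junction_db()].
#'
#' @param path Path to a GTF (exon features with `gene_id`) or BED12 file.
#' @return An exon tibble (`chrom`, `start`, `end`, `strand`, `gene_id`,
#'   `exon_id`).
#' @export
read_exon_annotation <- function(path) {
  abort_if(!requireNamespace("rtracklayer", quietly = TRUE),
           "rtracklayer is required to read annotation files")
  gr <- rtracklayer::import(path)
  if (grepl("\\.bed(12)?$", path, ignore.case = TRUE)) {
    top <- as.data.frame(gr)
    blocks <- rtracklayer::blocks(gr)
    name <- if (!is.null(top$name)) top$name else paste0("gene", seq_len(nrow(top)))
    rows <- purrr::map(seq_along(blocks), function(i) {
      b <- as.data.frame(blocks[[i]])
      tibble::tibble(
        chrom = as.character(top$seqnames[i]),
        start = b$start, end = b$end,
        strand = as.character(top$strand[i]),
        gene_id = name[i],
        exon_id = paste0(name[i], ".e", seq_len(nrow(b))))
    })
    return(dplyr::bind_rows(rows))
  }
  df <- as.data.frame(gr)
  if ("type" %in% names(df)) df <- df[df$type == "exon", , drop = FALSE]
  exon_id <- if ("exon_id" %in% names(df) && !all(is.na(df$exon_id))) {
    df$exon_id
  } else {
    paste0(df$gene_id, ".e", stats::ave(seq_len(nrow(df)), df$gene_id, FUN = seq_along))
  }
  tibble::tibble(
    chrom = as.character(df$seqnames), start = df$start, end = df$end,
    strand = as.character(df$strand), gene_id = df$gene_id, exon_id = exon_id)
}
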