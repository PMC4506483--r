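# Pipeline surface: configuration, the end-to-end driver tying index
# construction, alignment ingestion, classification, scoring, de novo
# discovery and induction statistics together, and reproducible report I/O.

#' Pipeline configuration
#'
#' Bundles every threshold of the detection pipeline with its default:
#' minimum junction overlap 10 nt, posterior threshold 0.9, minimum read
#' count 2, circle-region buffers 15 nt (annotated) and 50 nt (de novo),
#' pairing window 1 Mb, 150 nt per junction side, 50-nt de novo bins,
#' consensus score cutoff 5, de novo decoy/circle ratio 0.1 and breakpoint
#' span 200 nt, circle-boundary count 10 for exterior assignment, and
#' outlier FDR 0.001. The serialized configuration is embedded in every
#' report header.
#'
#' @param min_overlap,posterior,n_min,buffer,buffer_denovo,window,pad_side
#'   Core detection thresholds (see Details).
#' @param bin_size,s_max,max_decoy_ratio,breakpoint_span De novo thresholds.
#' @param k_min,fdr Induction/outlier thresholds.
#' @param max_fragment Maximum concordant linear pair span (nt).
#' @param mode `"paired"` (GLM scoring) or `"single"` (naive Poisson
#'   scoring).
#' @param seed Integer seed used by any stochastic step.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_overlap = 10, posterior = 0.9, n_min = 2,
                            buffer = 15, buffer_denovo = 50, window = 1e6,
                            pad_side = 150, bin_size = 50, s_max = 5,
                            max_decoy_ratio = 0.1, breakpoint_span = 200,
                            k_min = 10, fdr = 0.001, max_fragment = 1000,
                            mode = c("paired", "single"), seed = 1) {
  mode <- match.arg(mode)
  cfg <- as.list(environment())
  num <- vapply(cfg, is.numeric, logical(1))
  abort_if(any(unlist(cfg[num]) < 0), "thresholds must be non-negative")
  structure(cfg, class = "pipeline_config")
}

#' Serialize or parse a pipeline configuration as YAML
#'
#' `config_to_yaml()` and `config_from_yaml()` round-trip a
#' [pipeline_config()] losslessly.
#'
#' @param cfg A `pipeline_config`.
#' @param path YAML file path.
#' @return The path (writer) or the parsed `pipeline_config` (reader).
#' @export
config_to_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' Run the full detection pipeline on in-memory inputs
#'
#' Executes the pipeline stages in order: junction database construction,
#' read alignment with the built-in matcher, read-pair classification,
#' GLM (or naive) junction scoring, de novo discovery on the unaligned
#' residue, and a machine-readable summary. Rerunning with the same inputs
#' and configuration is deterministic.
#'
#' @param genome Genome provider (named character, `DNAStringSet`, or FASTA
#'   path).
#' @param exons Exon annotation tibble.
#' @param reads Read tibble (`read_id`, `r1`, `r2`), e.g. from
#'   [simulate_reads()].
#' @param cfg A [pipeline_config()].
#' @param denovo Run the de novo stage on unaligned reads (default TRUE).
#' @return A list: `junctions` (the database), `alignments`, `features`,
#'   `calls`, `report` (filtered calls), `denovo` (assemblies and calls or
#'   `NULL`), `fit` (the `circ_glm` or `NULL` in naive mode), and `summary`
#'   (a one-row tibble of stage counts).
#' @export
run_pipeline <- function(genome, exons, reads, cfg = pipeline_config(),
                         denovo = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  genome <- as_genome(genome)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  junctions <- stage("build-index", build_junction_db(
    exons, genome, window = cfg$window, pad_side = cfg$pad_side))

  if (nrow(reads) == 0) {
    empty <- classify_read_pairs(empty_alignments_with_mate(), junctions)
    return(list(junctions = junctions, alignments = empty_alignments_with_mate(),
                features = empty, calls = score_empty(), report = score_empty(),
                denovo = NULL, fit = NULL,
                summary = pipeline_summary(empty, score_empty(), NULL)))
  }

  targets <- c(setNames(junctions$sequence, junctions$junction_id),
               setNames(as.character(genome), names(genome)))
  kinds <- c(ifelse(junctions$cls == "linear", "linear_junction",
                    "scrambled_junction"),
             rep("genome", length(genome)))
  names(kinds) <- names(targets)

  alignments <- stage("align", dplyr::bind_rows(
    dplyr::mutate(align_reads(setNames(reads$r1, reads$read_id), targets, kinds),
                  mate = "R1"),
    dplyr::mutate(align_reads(setNames(reads$r2, reads$read_id), targets, kinds),
                  mate = "R2")))

  features <- stage("classify", classify_read_pairs(
    alignments, junctions, min_overlap = cfg$min_overlap,
    buffer = cfg$buffer, max_fragment = cfg$max_fragment))

  mode <- if (cfg$mode == "single") "naive" else "glm"
  calls <- stage("score", score_junctions(
    features, mode = mode, posterior_threshold = cfg$posterior,
    n_min = cfg$n_min))
  report <- report_calls(calls, posterior_threshold = cfg$posterior,
                         n_min = cfg$n_min)

  dn <- NULL
  if (denovo) {
    aligned_r1 <- unique(alignments$read_id[alignments$mate == "R1"])
    un <- !(reads$read_id %in% aligned_r1)
    if (any(un)) {
      dn <- stage("denovo", discover_denovo(
        setNames(reads$r1[un], reads$read_id[un]),
        setNames(reads$r2[un], reads$read_id[un]),
        genome, exons, bin_size = cfg$bin_size, s_max = cfg$s_max,
        buffer = cfg$buffer_denovo, min_overlap = cfg$min_overlap,
        max_decoy_ratio = cfg$max_decoy_ratio,
        min_span = cfg$breakpoint_span))
    }
  }

  list(junctions = junctions, alignments = alignments, features = features,
       calls = calls, report = report, denovo = dn,
       fit = attr(calls, "fit"),
       summary = pipeline_summary(features, report, dn))
}

empty_alignments_with_mate <- function() {
  dplyr::mutate(empty_alignments(), mate = character(0))
}

score_empty <- function() {
  tibble::tibble(junction_id = character(), cls = character(),
                 n_reads = integer(), decoy_count = integer(),
                 posterior = numeric(), p_value = numeric(), fdr = numeric(),
                 verdict = character())
}

pipeline_summary <- function(features, report, dn) {
  tibble::tibble(
    n_linear_reads = sum(features$category == "linear"),
    n_circular_reads = sum(features$category == "circular"),
    n_decoy_reads = sum(features$category == "decoy"),
    n_junctions_called = nrow(report),
    n_circles_passing = sum(report$cls != "linear", na.rm = TRUE),
    n_denovo_junctions = if (is.null(dn)) 0L else nrow(dn$calls))
}

#' Write a report tibble as TSV with a reproducibility header
#'
#' Reports carry a commented header block with the package version, the
#' serialized configuration, its hash, and the seed, so any report can be
#' traced back to the run that made it.
#'
#' @param x A tibble.
#' @param path Output path.
#' @param cfg Optional `pipeline_config` to embed.
#' @return Invisibly, the path.
#' @export
write_report_tsv <- function(x, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# circjunct ", as.character(utils::packageVersion("circjunct")),
                    " | ", format(Sys.time(), "%Y-%m-%d")), con)
  if (!is.null(cfg)) {
    ser <- paste(names(cfg), unlist(lapply(cfg, format)), sep = "=",
                 collapse = " ")
    writeLines(paste0("# config: ", ser), con)
    writeLines(paste0("# config_hash: ",
                      sum(utf8ToInt(ser) * seq_along(utf8ToInt(ser))) %% 1e9,
                      " | seed: ", cfg$seed), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a report written by [write_report_tsv()]
#'
#' @param path Report path.
#' @return The tibble (header comments skipped).
#' @export
read_report_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      comment.char = "#",
                                      stringsAsFactors = FALSE))
}
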