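#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. `mode = "simulate"` writes a
#' synthetic study to `out_dir`; `"analyze"` runs the analysis stages on
#' existing files; `"full"` does both in one go (passing objects in memory).
#'
#' @param mode One of `"simulate"`, `"analyze"`, `"full"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for all stochastic stages.
#' @param sim A [sim_config()] (simulate/full modes); defaults to
#'   `sim_config(seed = seed)`.
#' @param genome,annotation,insertions,gold,domains,expression Input file
#'   paths (analyze mode). `insertions` may be a vector of per-day tables or a
#'   single table with a `day` column; alternatively give `reads` (FASTQ) to
#'   run insertion calling.
#' @param reads Optional FASTQ path (analyze mode).
#' @param ir_tag,k,max_mismatch Insertion-calling parameters.
#' @param alpha,read_threshold,clr_threshold,min_aa Analysis parameters.
#' @param emit_fastq In simulate/full mode, also write junction reads for the
#'   first day (default FALSE; round-trip exercised through memory).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("full", "simulate", "analyze"),
                            out_dir = tempfile("tnseq_run_"),
                            seed = 1L, sim = NULL,
                            genome = NULL, annotation = NULL, insertions = NULL,
                            gold = NULL, domains = NULL, expression = NULL,
                            reads = NULL, ir_tag = "ACTTGTGGCC", k = 20L,
                            max_mismatch = 1L, alpha = 0.01,
                            read_threshold = "stringent", clr_threshold = 2.5,
                            min_aa = 10L, emit_fastq = FALSE) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
              sim = sim %||% sim_config(seed = seed),
              genome = genome, annotation = annotation, insertions = insertions,
              gold = gold, domains = domains, expression = expression,
              reads = reads, ir_tag = ir_tag, k = as.integer(k),
              max_mismatch = as.integer(max_mismatch), alpha = alpha,
              read_threshold = read_threshold, clr_threshold = clr_threshold,
              min_aa = as.integer(min_aa), emit_fastq = isTRUE(emit_fastq))
  if (mode == "analyze") {
    need <- c("genome", "annotation", "gold")
    missing <- need[vapply(cfg[need], is.null, logical(1))]
    if (is.null(cfg$insertions) && is.null(cfg$reads))
      missing <- c(missing, "insertions (or reads)")
    if (length(missing))
      stop("analyze mode requires paths: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (cfg$clr_threshold < 0) stop("clr_threshold must be >= 0", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Read/write a pipeline configuration as YAML
#' @param path YAML file.
#' @return `read_pipeline_config`: a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- if (!is.null(raw$sim)) do.call(sim_config, raw$sim) else NULL
  raw$sim <- NULL
  do.call(pipeline_config, c(raw, list(sim = sim)))
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  raw <- unclass(config)
  raw$sim <- unclass(raw$sim)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Run the pipeline end to end
#'
#' Executes (simulation, then) insertion calling, timepoint selection,
#' threshold calibration, essentiality scoring and classification, landscape
#' derivation, domain-level scoring, ncRNA co-expression analysis and smORF
#' scanning, writing every output with a manifest of content hashes. The same
#' config and seed produce byte-identical manifest-listed outputs.
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @return Result bundle (list) with the fitted objects and a `manifest`
#'   data.frame (`file`, `md5`, `bytes`); also written to
#'   `out_dir/manifest.tsv` along with `report.txt`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(config = config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (config$mode %in% c("simulate", "full")) {
    sim <- stage("simulate", {
      s <- simulate_genome(config$sim)
      tabs <- simulate_insertions(s)
      expr <- simulate_expression(s)
      write_genome_fasta(s$genome, file.path(config$out_dir, "genome.fasta"), "sim")
      write_annotation_gff3(s$annotation,
                            file.path(config$out_dir, "annotation.gff3"), "sim")
      for (d in names(tabs))
        write_insertion_table(tabs[[d]],
                              file.path(config$out_dir,
                                        sprintf("insertions_day%s.tsv", d)))
      write_domains_tsv(s$domains, file.path(config$out_dir, "domains.tsv"))
      write_expression_tsv(expr, file.path(config$out_dir, "expression.tsv"))
      gold <- make_gold_set(s)
      write_gold_tsv(gold, file.path(config$out_dir, "gold.tsv"))
      if (config$emit_fastq)
        write_fastq(simulate_reads(tabs[[1]], s, ir_tag = config$ir_tag),
                    file.path(config$out_dir, "reads_day1.fastq"))
      list(sim = s, tables = tabs, expr = expr, gold = gold)
    })
    bundle <- c(bundle, sim)
  }

  if (config$mode == "analyze") {
    bundle$sim <- stage("load", {
      g <- read_genome_fasta(config$genome)
      ann <- read_annotation_gff3(config$annotation)
      structure(list(genome = g, annotation = ann), class = "sim_genome")
    })
    bundle$gold <- stage("load", read_gold_tsv(config$gold))
    bundle$tables <- stage("insertion_calling", {
      if (!is.null(config$reads)) {
        tab <- call_insertions(read_fastq(config$reads), bundle$sim$genome,
                               ir_tag = config$ir_tag,
                               max_mismatch = config$max_mismatch, k = config$k)
        attr(tab, "G") <- nchar(bundle$sim$genome)
        as_day_list(tab)
      } else {
        tabs <- lapply(config$insertions, read_insertion_table)
        names(tabs) <- vapply(tabs, function(t) as.character(t$day[1]), character(1))
        tabs
      }
    })
    if (!is.null(config$expression))
      bundle$expr <- stage("load", read_expression_tsv(config$expression))
    if (!is.null(config$domains))
      bundle$domains_tab <- stage("load", read_domains_tsv(config$domains))
  }

  if (config$mode == "simulate") {
    bundle$manifest <- write_manifest(config)
    return(invisible(bundle))
  }

  G <- nchar(bundle$sim$genome)
  bundle$fit <- stage("scoring", fit_essentiality(
    bundle$tables, bundle$sim$annotation, bundle$gold, G = G,
    alpha = config$alpha, read_threshold = config$read_threshold))
  write.table(bundle$fit$calls, file.path(config$out_dir, "calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  bundle$landscape <- stage("landscape", essential_landscape(bundle$fit))
  write_landscape_bed(bundle$landscape, file.path(config$out_dir, "landscape.bed"),
                      genome_id = "sim")

  dom_tab <- bundle$domains_tab %||%
    (if (!is.null(bundle$sim$domains)) bundle$sim$domains else NULL)
  if (!is.null(dom_tab)) {
    bundle$domains_res <- stage("domains", {
      orfs <- bundle$sim$annotation[bundle$sim$annotation$type == "ORF", ]
      res <- lapply(split(dom_tab, dom_tab$orf_id), function(dd) {
        orf <- orfs[orfs$id == dd$orf_id[1], ]
        if (nrow(orf) == 0L) return(NULL)
        r <- score_domains(orf, dd, bundle$fit$table, bundle$fit$model)
        cbind(orf_id = orf$id, r$calls, differential = r$differential)
      })
      do.call(rbind, res)
    })
    write.table(bundle$domains_res, file.path(config$out_dir, "domain_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(bundle$expr)) {
    bundle$ncrna <- stage("ncrna", {
      clr <- clr_matrix(bundle$expr)
      ann <- bundle$sim$annotation
      coding <- ann[ann$type %in% c("ORF", "smORF"), ]
      ncr <- ann[ann$type == "ncRNA", ]
      host <- antisense_host(ncr, coding)
      pairs <- data.frame(ncrna = ncr$id, orf = host,
                          stringsAsFactors = FALSE)
      pairs <- pairs[!is.na(pairs$orf), , drop = FALSE]
      sp <- classify_pairs(clr, pairs, config$clr_threshold)
      enr <- tryCatch(essentiality_enrichment(sp, bundle$fit$calls),
                      error = function(e) NULL)
      list(clr = clr, pairs = sp, enrichment = enr)
    })
    write.table(bundle$ncrna$pairs, file.path(config$out_dir, "ncrna_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(bundle$sim$genome)) {
    bundle$smorfs <- stage("smorf_scan", {
      seqs <- feature_sequences(bundle$sim)
      if (length(seqs) == 0L) data.frame() else
        scan_smorfs(seqs, min_aa = config$min_aa)
    })
    write.table(bundle$smorfs, file.path(config$out_dir, "smorf_candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- render_report(bundle)
  writeLines(report, file.path(config$out_dir, "report.txt"))
  bundle$manifest <- write_manifest(config)
  invisible(bundle)
}

write_manifest <- function(config) {
  files <- setdiff(list.files(config$out_dir), "manifest.tsv")
  paths <- file.path(config$out_dir, files)
  man <- data.frame(file = files,
                    md5 = unname(tools::md5sum(paths)),
                    bytes = file.size(paths), stringsAsFactors = FALSE)
  write.table(man, file.path(config$out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  man
}

#' Render the pipeline summary report
#'
#' One text section per analysis stage: insertion retention at each
#' threshold, the chosen analysis day, calibrated thresholds, E/NE/F counts
#' per feature class, essential genome size, differential-domain protein
#' count, signed ncRNA pair counts with the Welch enrichment test, and the
#' smORF candidate count. Stages not run are marked `not run`.
#'
#' @param bundle A [run_pipeline()] result.
#' @return Character vector of report lines.
#' @export
render_report <- function(bundle) {
  if (is.null(bundle$fit))
    stop("bundle incomplete: missing stage 'scoring'", call. = FALSE)
  fit <- bundle$fit
  lines <- c("== Transposon essentiality screen report ==", "")
  n_all <- nrow(fit$table)
  n_rel <- sum(fit$table$reads >= fit$calibration$relaxed)
  n_str <- sum(fit$table$reads >= fit$calibration$stringent)
  lines <- c(lines, "[insertions]",
             sprintf("unique sites day %g: %d; passing relaxed (%d reads): %d; stringent (%d reads): %d",
                     fit$day, n_all, fit$calibration$relaxed, n_rel,
                     fit$calibration$stringent, n_str), "")
  lines <- c(lines, "[timepoint]",
             sprintf("analysis day: %g%s", fit$day,
                     if (is.null(fit$timepoint)) " (given)" else ""), "")
  lines <- c(lines, "[classification]")
  for (ty in unique(fit$calls$type)) {
    tab <- table(factor(fit$calls$category[fit$calls$type == ty],
                        levels = c("E", "NE", "F")))
    lines <- c(lines, sprintf("%-10s E %3d  NE %3d  F %3d", ty,
                              tab["E"], tab["NE"], tab["F"]))
  }
  lines <- c(lines, "", "[landscape]",
             sprintf("essential genome: %d bp (%.1f%% of %d bp)",
                     fit$landscape$essential_bp,
                     100 * fit$landscape$essential_fraction,
                     as.integer(fit$model$G)),
             sprintf("essential intergenic regions (>100 bp): %d",
                     nrow(fit$landscape$essential_intergenic)), "")
  lines <- c(lines, "[domains]")
  lines <- c(lines, if (!is.null(bundle$domains_res)) {
    diff_n <- length(unique(bundle$domains_res$orf_id[bundle$domains_res$differential]))
    sprintf("proteins with differential domain essentiality: %d", diff_n)
  } else "not run")
  lines <- c(lines, "", "[ncRNA co-expression]")
  lines <- c(lines, if (!is.null(bundle$ncrna)) {
    sp <- bundle$ncrna$pairs
    l <- sprintf("significant antisense pairs: %d (anti-correlated %d, correlated %d)",
                 sum(sp$significant),
                 sum(sp$sign == "anti-correlated", na.rm = TRUE),
                 sum(sp$sign == "correlated", na.rm = TRUE))
    if (!is.null(bundle$ncrna$enrichment)) {
      wl <- bundle$ncrna$enrichment$welch
      c(l, sprintf("Welch t = %.3f, df = %.2f, p = %.3g (mean %%E anti %.1f vs corr %.1f)",
                   wl$t, wl$df, wl$p.value, wl$means[1], wl$means[2]))
    } else l
  } else "not run")
  lines <- c(lines, "", "[smORF scan]")
  lines <- c(lines, if (!is.null(bundle$smorfs)) {
    sprintf("candidate smORFs in ncRNAs: %d", nrow(bundle$smorfs))
  } else "not run")
  lines
}
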