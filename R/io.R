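# File format adapters. Standard formats go through Biostrings (FASTA/FASTQ)
# and rtracklayer (GFF3/BED/WIG); the insertion table is the package's own
# TSV with '#'-prefixed header metadata.

#' Read and write genome FASTA
#' @param path File path.
#' @return `read_genome_fasta`: a single genome sequence as a character string.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  as.character(ss[[1]])
}

#' @rdname read_genome_fasta
#' @param genome Character genome sequence.
#' @param genome_id Sequence name to write.
#' @export
write_genome_fasta <- function(genome, path, genome_id = "genome") {
  ss <- Biostrings::DNAStringSet(setNames(genome, genome_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read and write FASTQ reads
#' @param path File path (plain or gzip).
#' @return `read_fastq`: character vector of read sequences (names = ids).
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(ss), names(ss))
}

#' @rdname read_fastq
#' @param reads data.frame from [simulate_reads()] (`id`, `seq`, `qual`).
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  ss <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read and write the insertion table TSV
#'
#' Tab-separated site table with `#`-prefixed metadata lines (`# genome_id`,
#' `# G`) and columns `position`, `orientation`, `reads`, `sample`, `day`.
#'
#' @param path File path.
#' @return `read_insertion_table`: the table with `genome_id` and `G`
#'   attributes restored.
#' @export
read_insertion_table <- function(path) {
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "#")]
  get <- function(key) {
    ln <- meta[grepl(paste0("^#\\s*", key), meta)]
    if (length(ln)) sub(paste0("^#\\s*", key, "\\s*=?\\s*"), "", ln[1]) else NA
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(tab, "genome_id") <- get("genome_id")
  attr(tab, "G") <- as.integer(get("G"))
  tab
}

#' @rdname read_insertion_table
#' @param table Insertion table.
#' @export
write_insertion_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# genome_id = ", attr(table, "genome_id") %||% "NA"),
               paste0("# G = ", attr(table, "G") %||% "NA")), con)
  suppressWarnings(write.table(table, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read and write annotation GFF3
#'
#' GFF3 (1-based inclusive) with the ground-truth or called essentiality
#' category carried in the `truth` attribute.
#'
#' @param path File path.
#' @return `read_annotation_gff3`: annotation data.frame (`id`, `type`,
#'   `start`, `end`, `strand`, `truth`).
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(id = as.character(gr$ID), type = as.character(gr$type),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             truth = if (!is.null(gr$truth)) as.character(gr$truth) else NA,
             stringsAsFactors = FALSE)
}

#' @rdname read_annotation_gff3
#' @param annotation Annotation data.frame.
#' @param genome_id Sequence name.
#' @export
write_annotation_gff3 <- function(annotation, path, genome_id = "genome") {
  gr <- GenomicRanges::GRanges(
    seqnames = genome_id,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  gr$type <- annotation$type
  gr$ID <- annotation$id
  if (!is.null(annotation$truth)) gr$truth <- annotation$truth
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Export insertion sites as BED and WIG browser tracks
#'
#' BED intervals are 0-based half-open; the WIG track carries per-position
#' read sums (orientations merged).
#'
#' @param table Insertion table.
#' @param path Output file.
#' @param genome_id,G Sequence name and genome length (defaults from the
#'   table's attributes).
#' @export
write_insertion_bed <- function(table, path, genome_id = NULL, G = NULL) {
  genome_id <- genome_id %||% attr(table, "genome_id") %||% "genome"
  gr <- GenomicRanges::GRanges(
    seqnames = genome_id,
    ranges = IRanges::IRanges(table$position, width = 1L),
    strand = table$orientation)
  gr$score <- table$reads
  gr$name <- sprintf("ins_%d%s", table$position, table$orientation)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_insertion_bed
#' @export
write_insertion_wig <- function(table, path, genome_id = NULL, G = NULL) {
  genome_id <- genome_id %||% attr(table, "genome_id") %||% "genome"
  G <- G %||% attr(table, "G")
  sites <- threshold_sites(table, 1L)
  gr <- GenomicRanges::GRanges(
    seqnames = genome_id,
    ranges = IRanges::IRanges(sites$position, width = 1L),
    seqlengths = setNames(as.integer(G), genome_id))
  gr$score <- sites$reads
  rtracklayer::export(gr, path, format = "wig")
  invisible(path)
}

#' Export landscape segments as BED
#' @param landscape A landscape list (from [essential_landscape()] or an
#'   `essfit`'s `$landscape`).
#' @param path Output file.
#' @param genome_id Sequence name.
#' @export
write_landscape_bed <- function(landscape, path, genome_id = "genome") {
  seg <- landscape$essential_segments
  gr <- GenomicRanges::GRanges(
    seqnames = genome_id,
    ranges = IRanges::IRanges(seg$start, seg$end))
  gr$name <- sprintf("essential_%04d", seq_len(nrow(seg)))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read and write two-column gold-set TSV (`id`, `class` in E/NE)
#' @param path File path.
#' @return `read_gold_tsv`: a [gold_set()].
#' @export
read_gold_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  gold_set(tab$id[tab$class == "E"], tab$id[tab$class == "NE"])
}

#' @rdname read_gold_tsv
#' @param gold A [gold_set()].
#' @export
write_gold_tsv <- function(gold, path) {
  tab <- data.frame(id = c(gold$essential_ids, gold$nonessential_ids),
                    class = rep(c("E", "NE"),
                                c(length(gold$essential_ids),
                                  length(gold$nonessential_ids))))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write the expression matrix TSV (rows = features, cols = timepoints)
#' @param path File path.
#' @return `read_expression_tsv`: numeric matrix with feature rownames.
#' @export
read_expression_tsv <- function(path) {
  tab <- read.delim(path, row.names = 1L, check.names = FALSE)
  as.matrix(tab)
}

#' @rdname read_expression_tsv
#' @param expr Numeric matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(feature = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write domain tables (TSV: orf_id, domain_id, aa_start, aa_end, source)
#' @param path File path.
#' @return `read_domains_tsv`: data.frame of domain coordinates.
#' @export
read_domains_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_domains_tsv
#' @param domains Domain data.frame.
#' @export
write_domains_tsv <- function(domains, path) {
  write.table(domains, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
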