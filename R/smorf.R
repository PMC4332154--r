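#' Scan ncRNA sequences for small ORFs under genetic code 4
#'
#' Translates each sequence in its three forward reading frames under genetic
#' code 4 (the mollicute code, in which TGA encodes tryptophan; only TAA and
#' TAG terminate) and reports maximal start-to-stop spans whose encoded
#' peptide is `min_aa` to `max_aa` residues long. Within each stop-delimited
#' segment the first start codon opens the (maximal) candidate. Candidates are
#' emitted without conservation filtering; downstream evidence (homology, MS)
#' is the caller's concern.
#'
#' @param seqs Named character vector of nucleotide sequences (e.g. annotated
#'   ncRNAs, plus strand). Invalid characters raise an error naming the
#'   offending sequence.
#' @param min_aa,max_aa Peptide length bounds in residues (defaults 1 and 99;
#'   by definition a smORF encodes < 100 residues).
#' @param start_codons Permitted start codons (default the common bacterial
#'   starts ATG, GTG, TTG).
#' @param genetic_code NCBI translation table id, `"4"` (default) or `"1"`.
#' @return data.frame `seq_id`, `frame` (1-3), `nt_start`, `nt_end` (1-based
#'   within the sequence, stop codon included), `aa_len`, `peptide`.
#' @examples
#' scan_smorfs(c(x = "ATGAAATGATAA"))  # peptide "MKW": TGA read as Trp
#' @export
scan_smorfs <- function(seqs, min_aa = 1L, max_aa = 99L,
                        start_codons = c("ATG", "GTG", "TTG"),
                        genetic_code = "4") {
  if (length(seqs) == 0L) stop("no sequences given", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop("invalid nucleotide characters in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  code <- Biostrings::getGeneticCode(genetic_code)
  stops <- names(code)[code == "*"]
  out <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    for (frame in 1:3) {
      ncod <- (nchar(s) - frame + 1L) %/% 3L
      if (ncod < 2L) next
      starts_nt <- frame + 3L * (seq_len(ncod) - 1L)
      codons <- substring(s, starts_nt, starts_nt + 2L)
      stop_idx <- which(codons %in% stops)
      seg_start <- 1L
      for (si in stop_idx) {
        cand <- if (si > seg_start)
          seg_start - 1L + which(codons[seg_start:(si - 1L)] %in% start_codons)[1]
        else NA_integer_
        if (!is.na(cand)) {
          aa_len <- si - cand
          if (aa_len >= min_aa && aa_len <= max_aa) {
            pep <- paste(code[codons[cand:(si - 1L)]], collapse = "")
            out[[length(out) + 1L]] <- data.frame(
              seq_id = id, frame = frame,
              nt_start = starts_nt[cand], nt_end = starts_nt[si] + 2L,
              aa_len = aa_len, peptide = pep, stringsAsFactors = FALSE)
          }
        }
        seg_start <- si + 1L
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(seq_id = character(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      aa_len = integer(), peptide = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract annotated ncRNA sequences from a genome
#'
#' Returns the plus-frame sequence of each ncRNA feature on its annotated
#' strand (minus-strand features are reverse-complemented), ready for
#' [scan_smorfs()].
#'
#' @param sim A [simulate_genome()] result, or a list with `genome` and
#'   `annotation`.
#' @param types Feature types to extract (default `"ncRNA"`).
#' @return Named character vector of sequences.
#' @export
feature_sequences <- function(sim, types = "ncRNA") {
  ann <- sim$annotation[sim$annotation$type %in% types, , drop = FALSE]
  if (nrow(ann) == 0L) return(setNames(character(), character()))
  seqs <- vapply(seq_len(nrow(ann)), function(i) {
    s <- substr(sim$genome, ann$start[i], ann$end[i])
    if (ann$strand[i] == "-") revcomp(s) else s
  }, character(1))
  setNames(seqs, ann$id)
}

#' Map smORF candidates back to genome coordinates
#'
#' Converts within-sequence candidate coordinates from [scan_smorfs()] to
#' genomic coordinates using the source feature annotation (strand-aware).
#'
#' @param candidates Output of [scan_smorfs()].
#' @param annotation Feature annotation containing the scanned features.
#' @return `candidates` with added `genome_start`, `genome_end`, `strand`.
#' @export
smorf_genome_coords <- function(candidates, annotation) {
  i <- match(candidates$seq_id, annotation$id)
  if (anyNA(i)) stop("candidate source feature(s) missing from annotation", call. = FALSE)
  plus <- annotation$strand[i] == "+"
  candidates$genome_start <- ifelse(plus,
                                    annotation$start[i] + candidates$nt_start - 1L,
                                    annotation$end[i] - candidates$nt_end + 1L)
  candidates$genome_end <- ifelse(plus,
                                  annotation$start[i] + candidates$nt_end - 1L,
                                  annotation$end[i] - candidates$nt_start + 1L)
  candidates$strand <- annotation$strand[i]
  candidates
}
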