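#' Project protein-domain coordinates onto the genome
#'
#' Converts 1-based inclusive amino-acid coordinates of a domain to the
#' genomic nucleotide interval it occupies within its ORF, respecting strand:
#' on `+`, `nt_start = orf_start + 3 (aa_start - 1)` and
#' `nt_end = orf_start + 3 aa_end - 1`; on `-` the arithmetic mirrors from
#' `orf_end`. The stop codon belongs to no domain.
#'
#' @param domain One-row data.frame (or list) with `aa_start`, `aa_end`.
#' @param orf One-row data.frame with `start`, `end`, `strand`; the ORF span
#'   (including stop codon) must be divisible by 3.
#' @return List with `start` and `end` genomic coordinates.
#' @export
domain_to_genome <- function(domain, orf) {
  len <- orf$end - orf$start + 1L
  if (len %% 3L != 0L) stop("ORF length not divisible by 3", call. = FALSE)
  aa_len <- len %/% 3L - 1L
  if (domain$aa_start < 1L || domain$aa_end > aa_len || domain$aa_start > domain$aa_end)
    stop("domain exceeds protein length (", aa_len, " aa)", call. = FALSE)
  if (orf$strand == "+") {
    list(start = orf$start + 3L * (domain$aa_start - 1L),
         end = orf$start + 3L * domain$aa_end - 1L)
  } else {
    list(start = orf$end - 3L * domain$aa_end + 1L,
         end = orf$end - 3L * (domain$aa_start - 1L))
  }
}

#' Inverse of [domain_to_genome()]
#'
#' Maps a genomic nucleotide interval lying on codon boundaries of an ORF
#' back to 1-based amino-acid coordinates.
#'
#' @param interval List or one-row data.frame with genomic `start`, `end`.
#' @param orf One-row data.frame with `start`, `end`, `strand`.
#' @return List with `aa_start` and `aa_end`.
#' @export
genome_to_domain <- function(interval, orf) {
  if (orf$strand == "+") {
    aa_start <- (interval$start - orf$start) / 3 + 1
    aa_end <- (interval$end - orf$start + 1) / 3
  } else {
    aa_start <- (orf$end - interval$end) / 3 + 1
    aa_end <- (orf$end - interval$start + 1) / 3
  }
  if (aa_start != round(aa_start) || aa_end != round(aa_end))
    stop("interval does not lie on codon boundaries", call. = FALSE)
  list(aa_start = as.integer(aa_start), aa_end = as.integer(aa_end))
}

# Resolve overlapping input domains of one ORF by trimming both at the
# midpoint of the overlap (deterministic and order-independent).
resolve_domain_overlaps <- function(domains) {
  domains <- domains[order(domains$aa_start, domains$aa_end), , drop = FALSE]
  if (nrow(domains) < 2L) return(domains)
  for (i in seq_len(nrow(domains) - 1L)) {
    ov <- domains$aa_end[i] - domains$aa_start[i + 1L] + 1L
    if (ov > 0L) {
      cut <- domains$aa_start[i + 1L] + ov %/% 2L
      domains$aa_end[i] <- cut - 1L
      domains$aa_start[i + 1L] <- cut
    }
  }
  domains[domains$aa_start <= domains$aa_end, , drop = FALSE]
}

#' Score the essentiality of individual protein domains
#'
#' Projects each domain of an ORF onto the genome and scores it independently
#' with the gap-null model, revealing proteins in which the essentiality
#' status of individual structural domains differs -- the signature of
#' multi-domain proteins whose essential function lives in one domain.
#' Inter-domain linkers and termini outside any domain are scored too and
#' reported as `unassigned`, but never drive the differential flag.
#'
#' @param orf One-row annotation data.frame for the ORF (`id`, `start`, `end`,
#'   `strand`).
#' @param domains data.frame of the ORF's domains: `domain_id`, `aa_start`,
#'   `aa_end` (overlaps are trimmed at the overlap midpoint).
#' @param table Insertion table for the analysis day.
#' @param model A [scoring_model()].
#' @return List with `calls` (data.frame: one row per domain and linker with
#'   `domain_id`, `aa_start`, `aa_end`, `assigned`, then the [score_region()]
#'   columns) and `differential` (`TRUE` iff two assigned domains have
#'   different categories).
#' @export
score_domains <- function(orf, domains, table, model) {
  if (nrow(domains) < 1L) stop("need at least one domain", call. = FALSE)
  domains <- resolve_domain_overlaps(domains)
  aa_len <- (orf$end - orf$start + 1L) %/% 3L - 1L
  # add unassigned linkers/termini
  segs <- data.frame(domain_id = domains$domain_id, aa_start = domains$aa_start,
                     aa_end = domains$aa_end, assigned = TRUE,
                     stringsAsFactors = FALSE)
  cov <- IRanges::reduce(IRanges::IRanges(domains$aa_start, domains$aa_end))
  lnk <- IRanges::gaps(cov, start = 1L, end = aa_len)
  if (length(lnk))
    segs <- rbind(segs, data.frame(
      domain_id = sprintf("%s_linker%d", orf$id, seq_along(lnk)),
      aa_start = IRanges::start(lnk), aa_end = IRanges::end(lnk),
      assigned = FALSE, stringsAsFactors = FALSE))
  segs <- segs[order(segs$aa_start), , drop = FALSE]
  sc <- lapply(seq_len(nrow(segs)), function(i) {
    nt <- domain_to_genome(segs[i, ], orf)
    score_region(c(nt$start, nt$end), table, model)
  })
  calls <- cbind(segs, do.call(rbind, sc))
  rownames(calls) <- NULL
  assigned_cats <- unique(calls$category[calls$assigned])
  list(calls = calls, differential = length(assigned_cats) >= 2L)
}
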