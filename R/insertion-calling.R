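#' Filter junction reads by the transposon inverted repeat
#'
#' A genuine transposon-junction read begins with the terminal inverted
#' repeat (IR) of the mini-transposon. Reads whose prefix matches `ir_tag`
#' within `max_mismatch` substitutions are trimmed to their genomic flank;
#' all others are discarded and counted.
#'
#' @param reads Character vector of read sequences (or the data.frame from
#'   [simulate_reads()], or a `DNAStringSet`).
#' @param ir_tag Non-empty IR prefix sequence.
#' @param max_mismatch Allowed substitutions in the prefix (default 0).
#' @return List with `flanks` (character vector of trimmed reads) and
#'   `discarded` (count of reads without a matching IR prefix).
#' @export
filter_by_inverted_repeat <- function(reads, ir_tag, max_mismatch = 0L) {
  if (!nzchar(ir_tag)) stop("ir_tag must be non-empty", call. = FALSE)
  reads <- as_read_seqs(reads)
  n <- nchar(ir_tag)
  mm <- integer(length(reads))
  tag <- strsplit(ir_tag, "")[[1]]
  for (i in seq_len(n))
    mm <- mm + (substr(reads, i, i) != tag[i])
  keep <- nchar(reads) > n & mm <= max_mismatch
  list(flanks = substr(reads[keep], n + 1L, nchar(reads[keep])),
       discarded = sum(!keep))
}

as_read_seqs <- function(reads) {
  if (is.data.frame(reads)) return(as.character(reads$seq))
  if (methods::is(reads, "XStringSet")) return(as.character(reads))
  as.character(reads)
}

#' Map genomic flanks by unique exact k-mer seed
#'
#' Each flank's first `k` bases are matched exactly against the genome on both
#' strands (the genome is treated as circular). A flank matching at exactly
#' one locus yields a raw site call at the junction coordinate -- the genome
#' position of the first flank base -- with the matched orientation. Flanks
#' hitting multiple loci are counted ambiguous; flanks hitting none, unmapped.
#'
#' @param flanks Character vector of trimmed flank sequences.
#' @param genome Genome sequence (character) or [simulate_genome()] result.
#' @param k Seed length in bp (default 20; values below 12 are refused as the
#'   ambiguity floor for sub-megabase genomes).
#' @return List with `calls` (data.frame `position`, `orientation`, one row
#'   per mapped flank), `ambiguous` and `unmapped` counts.
#' @export
map_flanks <- function(flanks, genome, k = 20L) {
  if (inherits(genome, "sim_genome")) genome <- genome$genome
  if (k < 12L) stop("k < 12 is below the ambiguity floor", call. = FALSE)
  if (length(flanks) && any(nchar(flanks) < k))
    stop("k exceeds the length of some flanks", call. = FALSE)
  G <- nchar(genome)
  ext <- paste0(genome, substr(genome, 1L, k - 1L))      # circular index
  fwd <- substring(ext, seq_len(G), seq_len(G) + k - 1L)
  rc <- revcomp(genome)
  ext_rc <- paste0(rc, substr(rc, 1L, k - 1L))
  rev <- substring(ext_rc, seq_len(G), seq_len(G) + k - 1L)
  if (length(flanks) == 0L)
    return(list(calls = data.frame(position = integer(), orientation = character()),
                ambiguous = 0L, unmapped = 0L))
  seeds <- substr(flanks, 1L, k)
  counts <- table(c(fwd, rev))
  nhit <- as.integer(counts[seeds])
  nhit[is.na(nhit)] <- 0L
  fpos <- match(seeds, fwd)
  rpos <- match(seeds, rev)
  # guard against a seed occurring twice on one strand (match() sees only the
  # first): nhit counts all occurrences on both strands
  uniq <- nhit == 1L
  orientation <- ifelse(!is.na(fpos), "+", "-")
  position <- ifelse(!is.na(fpos), fpos, G - rpos + 1L)
  list(calls = data.frame(position = as.integer(position[uniq]),
                          orientation = orientation[uniq],
                          stringsAsFactors = FALSE),
       ambiguous = sum(nhit > 1L),
       unmapped = sum(nhit == 0L))
}

#' Collapse raw site calls into a unique-insertion table
#'
#' Aggregates mapped junction calls by `(position, orientation, sample)`;
#' `reads` is the number of supporting reads. Opposite-orientation sites at
#' the same position are kept distinct here (the mini-transposon carries an
#' internal promoter, so orientation is biologically meaningful); they are
#' merged later for essentiality scoring.
#'
#' @param calls data.frame with `position` and `orientation` (and optionally
#'   `sample`, `day`).
#' @param genome_id Label recorded on the table.
#' @param G Genome length (bp).
#' @param sample,day Labels applied when absent from `calls`.
#' @param provenance Named integer vector of read-accounting counts
#'   (`total`, `no_ir`, `mapped`, `ambiguous`, `unmapped`).
#' @return Insertion table sorted by position, with attributes `genome_id`,
#'   `G`, `provenance`.
#' @export
collapse_sites <- function(calls, genome_id = "genome", G = NA_integer_,
                           sample = "s1", day = 0,
                           provenance = NULL) {
  if (nrow(calls) == 0L) {
    tab <- data.frame(position = integer(), orientation = character(),
                      reads = integer(), sample = character(), day = numeric())
  } else {
    if (is.null(calls$sample)) calls$sample <- sample
    if (is.null(calls$day)) calls$day <- day
    key <- paste(calls$position, calls$orientation, calls$sample, calls$day,
                 sep = "\r")
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
    tab <- data.frame(position = as.integer(parts[, 1]),
                      orientation = parts[, 2],
                      reads = as.integer(agg$Freq),
                      sample = parts[, 3],
                      day = as.numeric(parts[, 4]), stringsAsFactors = FALSE)
    tab <- tab[order(tab$position, tab$orientation), , drop = FALSE]
    rownames(tab) <- NULL
  }
  attr(tab, "genome_id") <- genome_id
  attr(tab, "G") <- as.integer(G)
  attr(tab, "provenance") <- provenance %||%
    c(total = 0L, no_ir = 0L, mapped = 0L, ambiguous = 0L, unmapped = 0L)
  tab
}

#' Call insertion sites from transposon-junction reads
#'
#' End-to-end insertion calling: IR filtering ([filter_by_inverted_repeat()]),
#' unique exact-seed mapping ([map_flanks()]) and deduplication
#' ([collapse_sites()]). Provenance counts satisfy
#' `total = no_ir + mapped + ambiguous + unmapped`.
#'
#' @inheritParams filter_by_inverted_repeat
#' @inheritParams map_flanks
#' @inheritParams collapse_sites
#' @return Insertion table (see [collapse_sites()]).
#' @export
call_insertions <- function(reads, genome, ir_tag, max_mismatch = 0L, k = 20L,
                            genome_id = "genome", sample = "s1", day = 0) {
  if (inherits(genome, "sim_genome")) genome <- genome$genome
  reads <- as_read_seqs(reads)
  filt <- filter_by_inverted_repeat(reads, ir_tag, max_mismatch)
  mapped <- map_flanks(filt$flanks, genome, k)
  prov <- c(total = length(reads), no_ir = filt$discarded,
            mapped = nrow(mapped$calls), ambiguous = mapped$ambiguous,
            unmapped = mapped$unmapped)
  collapse_sites(mapped$calls, genome_id = genome_id, G = nchar(genome),
                 sample = sample, day = day, provenance = prov)
}

#' Insertion bias across junction quadruplets
#'
#' For each of the 256 DNA 4-mers, compares the number of insertions whose
#' junction-centred quadruplet (bases p-1..p+2 around the junction, circular)
#' equals it against the expectation under uniform insertion,
#' `N * occurrences / G`. Reports per-quadruplet observed/expected ratios, a
#' global chi-square test, and the summary ratio for the G/C-rich class
#' (>= 3 G/C bases), where transposition machinery is disfavoured.
#'
#' @param table Non-empty insertion table.
#' @param genome Genome sequence (character) or [simulate_genome()] result.
#' @return List with `per_quadruplet` (data.frame `quadruplet`, `gc`,
#'   `observed`, `expected`, `ratio`), `chisq` (`htest`-like list with
#'   `statistic`, `df`, `p.value`), and `gc_rich_ratio`.
#' @export
quadruplet_bias <- function(table, genome) {
  if (inherits(genome, "sim_genome")) genome <- genome$genome
  assert_insertion_table(table)
  G <- nchar(genome)
  if (G < 4L) stop("genome too short for quadruplet analysis", call. = FALSE)
  if (nrow(table) == 0L) stop("insertion table is empty", call. = FALSE)
  quads_all <- junction_quadruplets(genome, seq_len(G))
  occ <- table(quads_all)
  pos <- unique(table$position)          # unique insertions, orientation-merged
  obs <- table(junction_quadruplets(genome, pos))
  qs <- sort(names(occ))
  observed <- as.integer(obs[qs]); observed[is.na(observed)] <- 0L
  expected <- length(pos) * as.integer(occ[qs]) / G
  gc <- vapply(strsplit(qs, ""), function(b) sum(b %in% c("G", "C")), integer(1))
  per <- data.frame(quadruplet = qs, gc = gc, observed = observed,
                    expected = expected, ratio = observed / expected,
                    stringsAsFactors = FALSE)
  keep <- expected > 0
  stat <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  df <- sum(keep) - 1L
  rich <- gc >= 3L
  list(per_quadruplet = per,
       chisq = list(statistic = stat, df = df,
                    p.value = stats::pchisq(stat, df, lower.tail = FALSE)),
       gc_rich_ratio = sum(observed[rich]) / sum(expected[rich]))
}

junction_quadruplets <- function(genome, pos) {
  G <- nchar(genome)
  ext <- paste0(substr(genome, G, G), genome, substr(genome, 1L, 2L))
  # position p maps to ext index p+1 .. p+4 covering genome bases p-1..p+2
  substring(ext, pos, pos + 3L)
}
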