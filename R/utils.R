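# Shared internal helpers.

# Round-half-up of numer/denom to two decimals using exact integer arithmetic,
# so that a base fraction of exactly 0.005 rounds to 0.01 and 0.004999... to 0.00
# regardless of floating-point representation. numer, denom: non-negative integers.
round2_frac <- function(numer, denom) {
  stopifnot(all(denom > 0), all(numer >= 0))
  ((200 * numer + denom) %/% (2 * denom)) / 100
}

# Normalise a (start, width) circular span on a genome of length G into one or two
# linear IRanges. start may lie outside 1..G; width must be <= G.
circ_ranges <- function(start, width, G) {
  keep <- width > 0
  start <- start[keep]; width <- width[keep]
  if (length(start) == 0L) return(IRanges::IRanges())
  stopifnot(all(width <= G))
  start <- ((start - 1) %% G) + 1
  end <- start + width - 1
  wraps <- end > G
  s1 <- start
  e1 <- ifelse(wraps, G, end)
  parts <- IRanges::IRanges(start = s1, end = e1)
  if (any(wraps)) {
    parts <- c(parts, IRanges::IRanges(start = 1, end = end[wraps] - G))
  }
  IRanges::reduce(parts)
}

# Reverse complement of a plain character DNA string.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Circular substring of a genome string: bases start..start+len-1 with wrap-around.
circ_substr <- function(genome, start, len, G = nchar(genome)) {
  stopifnot(len <= G)
  start <- ((start - 1) %% G) + 1
  if (start + len - 1 <= G) {
    substr(genome, start, start + len - 1)
  } else {
    paste0(substr(genome, start, G), substr(genome, 1, start + len - 1 - G))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stage-specific RNG sub-seed derived from a master seed; kept below 2^31.
sub_seed <- function(seed, offset) {
  (as.numeric(seed) * 97 + offset) %% 2147483647
}

assert_annotation <- function(annotation) {
  need <- c("id", "type", "start", "end", "strand")
  if (!is.data.frame(annotation) || !all(need %in% names(annotation)))
    stop("annotation must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  invisible(annotation)
}

assert_insertion_table <- function(table) {
  need <- c("position", "orientation", "reads")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("insertion table must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  invisible(table)
}
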