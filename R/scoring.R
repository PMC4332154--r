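#' Insertion-free gap null probability
#'
#' Probability that a genomic span of length `L` receives none of `N`
#' transposon insertions placed uniformly at random on a genome of length `G`,
#' i.e. \eqn{P_N(L) = (1 - L/G)^N}. This is the null model against which
#' observed insertion-free gaps are judged: a maximal gap whose probability
#' falls at or below the significance level is evidence that the span is
#' essential (insertions there were lethal), not merely unsampled.
#'
#' Computed in log space (`exp(N * log1p(-L/G))`) for numerical stability at
#' large `N` and small `L/G`.
#'
#' @param L Span length in bp (vectorised). Must satisfy `0 <= L <= G`.
#' @param N Number of insertions genome-wide (`N >= 0`).
#' @param G Genome length in bp.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @examples
#' gap_null_probability(100, 10, 1000)  # 0.9^10 = 0.34868
#' @export
gap_null_probability <- function(L, N, G) {
  if (length(G) != 1L || length(N) != 1L || !is.finite(G) || G <= 0)
    stop("G must be a single positive number", call. = FALSE)
  if (N < 0 || N != round(N)) stop("N must be a non-negative integer count", call. = FALSE)
  if (any(!is.finite(L)) || any(L < 0) || any(L > G))
    stop("L must satisfy 0 <= L <= G", call. = FALSE)
  if (N == 0) return(rep(1, length(L)))
  p <- exp(N * log1p(-L / G))
  p[L == G] <- 0
  p
}

#' Scoring model for essentiality calls
#'
#' Bundles the calibrated parameters of the gap-null scoring system: genome
#' length `G`, the genome-wide count `N` of threshold-passing insertion sites,
#' the significance level `alpha`, the dispensability neighbourhood radius `w`,
#' and the reads-per-insertion threshold actually applied.
#'
#' By default `w = ceiling(G / (2 N))`, half the mean inter-insertion spacing:
#' each observed insertion marks its immediate neighbourhood as dispensable.
#'
#' @param G Genome length (bp).
#' @param N Count of threshold-passing insertion sites genome-wide.
#' @param alpha Significance level for calling an insertion-free gap
#'   essential (default 0.01, i.e. 99% confidence).
#' @param w Neighbourhood radius in bp; default `ceiling(G / (2 * N))`.
#' @param read_threshold Reads-per-insertion threshold the sites were filtered
#'   at (recorded for provenance; default 1).
#' @param circular Treat the genome as circular when computing gaps
#'   (default `TRUE`).
#' @return An object of class `scoring_model`.
#' @export
scoring_model <- function(G, N, alpha = 0.01, w = NULL,
                          read_threshold = 1L, circular = TRUE) {
  if (G < 1) stop("G must be >= 1", call. = FALSE)
  if (N < 0) stop("N must be >= 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (is.null(w)) w <- if (N > 0) ceiling(G / (2 * N)) else G
  if (w < 1 || w > G) stop("w must lie in [1, G]", call. = FALSE)
  structure(list(G = as.numeric(G), N = as.integer(N), alpha = alpha,
                 w = as.integer(w), read_threshold = as.integer(read_threshold),
                 circular = isTRUE(circular)),
            class = "scoring_model")
}

#' @export
print.scoring_model <- function(x, ...) {
  cat("Gap-null scoring model\n")
  cat(sprintf("  genome length G : %d bp\n", as.integer(x$G)))
  cat(sprintf("  insertions N    : %d (reads >= %d, orientations merged)\n",
              x$N, x$read_threshold))
  cat(sprintf("  alpha           : %g\n", x$alpha))
  cat(sprintf("  neighbourhood w : %d bp\n", x$w))
  cat(sprintf("  topology        : %s\n", if (x$circular) "circular" else "linear"))
  invisible(x)
}

# Threshold-passing sites, orientations merged: unique positions with summed
# reads. Essentiality is positional, so opposite-orientation sites at one
# position count once; the threshold is applied per (position, orientation)
# site before merging.
threshold_sites <- function(table, read_threshold = 1L) {
  assert_insertion_table(table)
  keep <- table$reads >= read_threshold
  if (!any(keep)) return(data.frame(position = integer(), reads = integer()))
  agg <- tapply(table$reads[keep], table$position[keep], sum)
  data.frame(position = as.integer(names(agg)), reads = as.integer(agg),
             row.names = NULL)[order(as.integer(names(agg))), , drop = FALSE]
}

# Maximal insertion-free intervals between consecutive sites on a circular
# genome. Returns a data.frame with the interval start (position after the
# bounding site), its length, and significance under the gap null.
insertion_gaps <- function(positions, G, N = length(positions), alpha = 0.01,
                           circular = TRUE) {
  pos <- sort(unique(as.integer(positions)))
  n <- length(pos)
  if (n == 0L) stop("no insertion sites: gap structure undefined (N = 0)", call. = FALSE)
  if (circular) {
    nxt <- c(pos[-1], pos[1] + G)
    start <- pos + 1L
    len <- nxt - pos - 1L
  } else {
    start <- c(1L, pos + 1L)
    len <- c(pos[1] - 1L, c(pos[-1], G + 1L) - pos - 1L)
  }
  keep <- len > 0
  start <- start[keep]; len <- len[keep]
  sig <- if (length(len)) gap_null_probability(len, N, G) <= alpha else logical(0)
  data.frame(start = start, length = len, significant = sig)
}

# Per-base evidence cover. Every base gets at most one label:
#   E-evidence : inside a statistically significant insertion-free interval
#   NE-evidence: within w of a threshold-passing site and not E-evidence
# Returns IRanges covers plus the gap table (for longest_gap reporting).
evidence_cover <- function(positions, G, N, alpha, w, circular = TRUE) {
  gaps <- insertion_gaps(positions, G, N = N, alpha = alpha, circular = circular)
  sig <- gaps[gaps$significant, , drop = FALSE]
  e_cover <- circ_ranges(sig$start, sig$length, G)
  pos <- sort(unique(as.integer(positions)))
  ne_raw <- if (circular) {
    circ_ranges(pos - w, rep(pmin(2 * w + 1, G), length(pos)), G)
  } else {
    IRanges::reduce(IRanges::IRanges(pmax(1L, pos - w), pmin(as.integer(G), pos + w)))
  }
  ne_cover <- IRanges::setdiff(ne_raw, e_cover)
  list(e = e_cover, ne = ne_cover, gaps = gaps, positions = pos)
}

overlap_bp <- function(cover, start, end) {
  if (length(cover) == 0L) return(0L)
  sum(IRanges::width(IRanges::intersect(cover, IRanges::IRanges(start, end))))
}

# Score one region against a precomputed evidence cover.
score_region_core <- function(start, end, cover, G) {
  stopifnot(start >= 1, end <= G, start <= end)
  len <- end - start + 1L
  bp_e <- overlap_bp(cover$e, start, end)
  bp_ne <- overlap_bp(cover$ne, start, end)
  p_e <- round2_frac(bp_e, len)
  p_ne <- round2_frac(bp_ne, len)
  n_ins <- sum(cover$positions >= start & cover$positions <= end)
  longest <- 0L
  if (nrow(cover$gaps)) {
    gs <- ((cover$gaps$start - 1) %% G) + 1
    ge <- gs + cover$gaps$length - 1          # may exceed G (wraps past origin)
    hit <- (gs <= end & pmin(ge, G) >= start) |      # linear part
      (ge > G & ge - G >= start)                     # wrapped part starts at 1
    if (any(hit)) longest <- max(cover$gaps$length[hit])
  }
  list(P_E = p_e, P_NE = p_ne, category = classify_call(p_e, p_ne),
       n_insertions = n_ins, longest_gap = as.integer(longest))
}

#' Score a genomic region for essentiality
#'
#' Computes the essentiality probabilities of a region from the genome-wide
#' insertion pattern. Maximal insertion-free intervals are delimited by
#' threshold-passing, orientation-merged insertion sites on the (circular)
#' genome; an interval of length L is significant when
#' [gap_null_probability]`(L, N, G) <= alpha`. Each base then carries one of
#' three labels: essential evidence (inside a significant interval),
#' non-essential evidence (within `w` bp of a site and not inside a
#' significant interval), or neither. `P_E` and `P_NE` are the fractions of
#' the region carrying each label, rounded half-up to two decimals, and the
#' category follows [classify_call()].
#'
#' @param region Numeric vector `c(start, end)` (1-based inclusive), or a
#'   one-row data.frame with `start` and `end` columns.
#' @param table Insertion table (see [collapse_sites()]).
#' @param model A [scoring_model()]; `model$N` must match the number of
#'   threshold-passing merged sites in `table`.
#' @return A one-row data.frame: `P_E`, `P_NE`, `category`, `n_insertions`,
#'   `longest_gap`.
#' @export
score_region <- function(region, table, model) {
  if (is.data.frame(region)) region <- c(region$start[1], region$end[1])
  sites <- threshold_sites(table, model$read_threshold)
  if (nrow(sites) == 0L || model$N == 0L)
    stop("model has N = 0 threshold-passing insertions; scoring is degenerate ",
         "(every gap is maximally long). See the package vignette.", call. = FALSE)
  cover <- evidence_cover(sites$position, model$G, model$N, model$alpha,
                          model$w, model$circular)
  res <- score_region_core(as.integer(region[1]), as.integer(region[2]), cover, model$G)
  as.data.frame(res)
}

#' Classify a region from its essentiality probabilities
#'
#' Three-way rule at two-decimal resolution: essential (`E`) when `P_E > 0`
#' and `P_NE = 0`; non-essential (`NE`) when `P_E = 0` and `P_NE > 0`;
#' fitness (`F`) otherwise -- both positive (mixed evidence, e.g. a gene with
#' one essential and one dispensable domain) or both zero (no evidence either
#' way, typically short regions below the resolution of the screen).
#'
#' @param P_E,P_NE Two-decimal probabilities in `[0, 1]` (vectorised).
#' @return Character vector with values in `c("E", "NE", "F")`.
#' @export
classify_call <- function(P_E, P_NE) {
  if (any(P_E < 0 | P_E > 1 | P_NE < 0 | P_NE > 1))
    stop("P_E and P_NE must lie in [0, 1]", call. = FALSE)
  ifelse(P_E > 0 & P_NE == 0, "E",
         ifelse(P_E == 0 & P_NE > 0, "NE", "F"))
}

#' Calibrate reads-per-insertion thresholds from gold sets
#'
#' Insertions inside known-essential genes are background noise (dead or dying
#' clones still contributing reads); insertions inside known-dispensable genes
#' are genuine. A reads-per-insertion threshold `t` misclassifies an insertion
#' when it retains one inside an essential gold gene (`reads >= t`) or
#' discards one inside a non-essential gold gene (`reads < t`). The error
#' curve is scanned exhaustively over `t = 1 .. max(reads) + 1`; the relaxed
#' threshold is the smallest minimiser and the stringent threshold the
#' largest, mirroring the relaxed/stringent semantics of the screen.
#'
#' @param table Insertion table for the analysis day.
#' @param gold A [gold_set()].
#' @param annotation Feature annotation containing the gold genes.
#' @return List with `relaxed`, `stringent`, `error_curve` (data.frame
#'   `threshold`, `error`), and `degenerate` (`TRUE` with a warning when the
#'   two gold read distributions are inseparable and relaxed == stringent
#'   minimises at every threshold).
#' @export
calibrate_read_threshold <- function(table, gold, annotation) {
  assert_insertion_table(table)
  assert_annotation(annotation)
  reads_e <- gold_gene_reads(table, gold$essential_ids, annotation)
  reads_ne <- gold_gene_reads(table, gold$nonessential_ids, annotation)
  if (length(reads_e) == 0L)
    stop("no insertions in any essential gold gene: calibration undefined", call. = FALSE)
  if (length(reads_ne) == 0L)
    stop("no insertions in any non-essential gold gene: calibration undefined", call. = FALSE)
  ts <- seq_len(max(c(reads_e, reads_ne)) + 1L)
  err <- vapply(ts, function(t) sum(reads_e >= t) + sum(reads_ne < t), numeric(1))
  best <- which(err == min(err))
  degenerate <- length(best) == length(ts)
  if (degenerate) {
    warning("gold-set read distributions are inseparable; relaxed == stringent")
    best <- best[1]   # no information to separate: collapse both thresholds
  }
  list(relaxed = as.integer(ts[min(best)]),
       stringent = as.integer(ts[max(best)]),
       error_curve = data.frame(threshold = ts, error = err),
       degenerate = degenerate)
}

# Reads of merged-orientation insertion sites falling inside the named genes.
gold_gene_reads <- function(table, ids, annotation) {
  genes <- annotation[annotation$id %in% ids, , drop = FALSE]
  sites <- threshold_sites(table, 1L)
  if (nrow(sites) == 0L || nrow(genes) == 0L) return(integer())
  hits <- lapply(seq_len(nrow(genes)), function(i) {
    sites$reads[sites$position >= genes$start[i] & sites$position <= genes$end[i]]
  })
  unlist(hits)
}

#' Select the analysis timepoint from gold-set insertion dynamics
#'
#' Over serial passages, insertions in essential genes die out of the
#' population while insertions in dispensable genes persist. The analysis day
#' is the earliest day at which the mean number of insertion sites per
#' essential gold gene has fallen to at most `max(e_frac * baseline, e_floor)`
#' (baseline = value on the first day in the series) while the non-essential
#' gold mean remains at least `ne_frac` of its baseline (no population
#' bottleneck).
#'
#' @param tables Named list of insertion tables, one per day; names are day
#'   labels coercible to numbers, or tables carrying a constant `day` column.
#' @param gold A [gold_set()].
#' @param annotation Feature annotation.
#' @param e_frac,e_floor,ne_frac Rule parameters (defaults 0.1, 0.5, 0.8).
#' @return List with `day` (numeric label of the chosen day) and
#'   `diagnostics` (data.frame of both per-day series).
#' @export
select_timepoint <- function(tables, gold, annotation,
                             e_frac = 0.1, e_floor = 0.5, ne_frac = 0.8) {
  tables <- as_day_list(tables)
  days <- as.numeric(names(tables))
  if (length(days) < 1L) stop("need at least one day", call. = FALSE)
  ord <- order(days)
  days <- days[ord]; tables <- tables[ord]
  mean_sites <- function(tab, ids) {
    genes <- annotation[annotation$id %in% ids, , drop = FALSE]
    if (nrow(genes) == 0L) stop("gold genes absent from annotation", call. = FALSE)
    sites <- threshold_sites(tab, 1L)
    n <- vapply(seq_len(nrow(genes)), function(i)
      sum(sites$position >= genes$start[i] & sites$position <= genes$end[i]),
      numeric(1))
    mean(n)
  }
  e_series <- vapply(tables, mean_sites, numeric(1), ids = gold$essential_ids)
  ne_series <- vapply(tables, mean_sites, numeric(1), ids = gold$nonessential_ids)
  diagnostics <- data.frame(day = days, e_mean = e_series, ne_mean = ne_series,
                            row.names = NULL)
  eps <- max(e_frac * e_series[1], e_floor)
  ok <- e_series <= eps & ne_series >= ne_frac * ne_series[1]
  if (!any(ok)) {
    stop("no day satisfies the timepoint rule (possible failed selection or ",
         "bottleneck). Series:\n",
         paste(sprintf("  day %g: E-mean %.3f, NE-mean %.3f", days, e_series,
                       ne_series), collapse = "\n"), call. = FALSE)
  }
  if (length(days) == 1L)
    warning("single timepoint satisfies the rule; no dynamics to confirm it")
  list(day = days[which(ok)[1]], diagnostics = diagnostics)
}

# Accept either a named list of tables or one table with a day column.
as_day_list <- function(tables) {
  if (is.data.frame(tables)) {
    assert_insertion_table(tables)
    if (!"day" %in% names(tables)) return(setNames(list(tables), "0"))
    return(split(tables, tables$day))
  }
  if (!is.list(tables) || is.null(names(tables)))
    stop("tables must be a data.frame or a named list keyed by day", call. = FALSE)
  tables
}

#' Gold-standard gene sets
#'
#' Curated gene identifier lists of known essentiality, used to calibrate the
#' reads-per-insertion threshold and to pick the analysis timepoint.
#'
#' @param essential_ids,nonessential_ids Character vectors of gene ids; must
#'   be disjoint and non-empty.
#' @return An object of class `gold_set`.
#' @export
gold_set <- function(essential_ids, nonessential_ids) {
  essential_ids <- as.character(essential_ids)
  nonessential_ids <- as.character(nonessential_ids)
  if (length(essential_ids) == 0L || length(nonessential_ids) == 0L)
    stop("both gold classes must be non-empty", call. = FALSE)
  if (length(intersect(essential_ids, nonessential_ids)) > 0L)
    stop("gold sets must be disjoint", call. = FALSE)
  structure(list(essential_ids = essential_ids,
                 nonessential_ids = nonessential_ids), class = "gold_set")
}
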