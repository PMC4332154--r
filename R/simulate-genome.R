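# Stop codons under genetic code 4 (mollicute code: TGA encodes tryptophan).
STOPS_CODE4 <- c("TAA", "TAG")
BASES <- c("A", "C", "G", "T")

#' Simulate a genome with ground-truth essentiality
#'
#' Generates a circular bacterial genome of the requested length and base
#' composition and populates it with non-overlapping ORFs, smORFs,
#' conventional RNAs and essential intergenic segments, plus ncRNAs (mostly
#' antisense, placed inside host ORFs on the opposite strand) and 5'-UTRs.
#' Every ORF starts with ATG and ends with a stop codon of genetic code 4
#' (TAA/TAG; TGA is tryptophan and may occur in frame). Each feature carries a
#' ground-truth essentiality category; fitness (F) ORFs are generated as
#' mixed-domain proteins with one essential and one dispensable domain, so
#' that only part of their sequence resists insertion.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_genome`:
#' \describe{
#'   \item{genome}{Plain character genome sequence.}
#'   \item{annotation}{data.frame `id`, `type` (ORF/smORF/ncRNA/UTR5/convRNA/
#'     intergenic), `start`, `end`, `strand`, `truth` (E/NE/F).}
#'   \item{domains}{data.frame `orf_id`, `domain_id`, `aa_start`, `aa_end`,
#'     `truth`, `source` -- per-ORF domain truth (stop codon belongs to no
#'     domain).}
#'   \item{essential_regions}{data.frame `start`, `end` -- the ground-truth
#'     essential base mask as merged intervals.}
#'   \item{config}{The configuration used.}
#' }
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 1))
  G <- config$genome_length
  pr <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
          G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  seq_vec <- sample(BASES, G, replace = TRUE, prob = pr[BASES])

  # -- block layout ----------------------------------------------------------
  orf_nt <- 3L * sample(150:500, config$n_orfs, replace = TRUE)        # 450-1500 nt
  smorf_nt <- 3L * (sample(20:98, config$n_smorfs, replace = TRUE) + 1L) # < 100 aa
  conv_nt <- rep(80L, config$n_convrnas)
  ige_nt <- if (config$n_essential_intergenic > 0)
    sample(150:400, config$n_essential_intergenic, replace = TRUE) else integer()
  blocks <- data.frame(
    id = c(sprintf("ORF_%03d", seq_len(config$n_orfs)),
           sprintf("SMORF_%03d", seq_len(config$n_smorfs)),
           sprintf("CONVRNA_%03d", seq_len(config$n_convrnas)),
           if (length(ige_nt)) sprintf("IGE_%03d", seq_along(ige_nt))),
    type = c(rep("ORF", config$n_orfs), rep("smORF", config$n_smorfs),
             rep("convRNA", config$n_convrnas),
             rep("intergenic", length(ige_nt))),
    nt = c(orf_nt, smorf_nt, conv_nt, ige_nt),
    stringsAsFactors = FALSE)
  min_gap <- 100L   # intergenic spacer floor; keeps neighbouring elements'
                    # insertion-free gaps separated by sampled sequence
  need <- sum(blocks$nt) + min_gap * nrow(blocks)
  if (need > G)
    stop(sprintf("infeasible packing: features need %d bp (incl. %d bp spacers) but genome is %d bp",
                 need, min_gap * nrow(blocks), G), call. = FALSE)
  blocks <- blocks[sample(nrow(blocks)), , drop = FALSE]
  slack <- G - need
  extra <- tabulate(sample.int(nrow(blocks), slack, replace = TRUE), nrow(blocks))
  gaps <- min_gap + extra
  starts <- 1L + cumsum(gaps) + c(0L, cumsum(head(blocks$nt, -1)))
  blocks$start <- starts
  blocks$end <- starts + blocks$nt - 1L
  stopifnot(max(blocks$end) <= G)
  blocks$strand <- sample(c("+", "-"), nrow(blocks), replace = TRUE)
  blocks$strand[blocks$type == "intergenic"] <- "+"

  # -- coding sequence construction -----------------------------------------
  coding <- blocks$type %in% c("ORF", "smORF")
  for (i in which(coding)) {
    cds <- make_cds(blocks$nt[i], pr)
    bases <- strsplit(if (blocks$strand[i] == "+") cds else revcomp(cds), "")[[1]]
    seq_vec[blocks$start[i]:blocks$end[i]] <- bases
  }

  # -- truth categories ------------------------------------------------------
  orf_rows <- which(blocks$type == "ORF")
  n_e <- round(config$frac_essential * length(orf_rows))
  n_f <- round(config$frac_fitness * length(orf_rows))
  # fitness ORFs need room for two decent-sized domains
  f_pool <- orf_rows[blocks$nt[orf_rows] >= 750L]
  f_rows <- if (n_f > 0) sample(f_pool, min(n_f, length(f_pool))) else integer()
  e_rows <- sample(setdiff(orf_rows, f_rows), min(n_e, length(orf_rows) - length(f_rows)))
  blocks$truth <- "NE"
  blocks$truth[e_rows] <- "E"
  blocks$truth[f_rows] <- "F"
  sm_rows <- which(blocks$type == "smORF")
  blocks$truth[sm_rows] <- ifelse(runif(length(sm_rows)) < config$frac_essential, "E", "NE")
  conv_rows <- which(blocks$type == "convRNA")
  blocks$truth[conv_rows] <- ifelse(runif(length(conv_rows)) < 0.8, "E", "NE")
  blocks$truth[blocks$type == "intergenic"] <- "E"

  # -- domain truth ----------------------------------------------------------
  domains <- make_domain_truth(blocks)

  # -- ncRNAs (mostly antisense) and 5'-UTRs --------------------------------
  extras <- place_ncrnas_utrs(blocks, config, G)
  annotation <- rbind(blocks[, c("id", "type", "start", "end", "strand", "truth")],
                      extras)
  annotation <- annotation[order(annotation$start, annotation$end), , drop = FALSE]
  rownames(annotation) <- NULL

  # -- ground-truth essential mask ------------------------------------------
  ess <- essential_truth_ranges(annotation, domains, G)

  structure(list(genome = paste(seq_vec, collapse = ""),
                 annotation = annotation, domains = domains,
                 essential_regions = ess, config = config),
            class = "sim_genome")
}

# One CDS of nt bases: ATG, interior codons free of code-4 stops, final stop.
make_cds <- function(nt, pr) {
  ncod <- nt %/% 3L
  interior <- character(0)
  if (ncod > 2L) {
    b <- sample(BASES, 3L * (ncod - 2L), replace = TRUE, prob = pr[BASES])
    interior <- paste0(b[c(TRUE, FALSE, FALSE)], b[c(FALSE, TRUE, FALSE)],
                       b[c(FALSE, FALSE, TRUE)])
    bad <- interior %in% STOPS_CODE4
    if (any(bad))
      interior[bad] <- paste0("TA", sample(c("T", "C"), sum(bad), replace = TRUE))
  }
  paste0("ATG", paste(interior, collapse = ""),
         sample(STOPS_CODE4, 1L))
}

make_domain_truth <- function(blocks) {
  rows <- which(blocks$type == "ORF")
  out <- lapply(rows, function(i) {
    aa <- blocks$nt[i] %/% 3L - 1L  # stop codon belongs to no domain
    if (blocks$truth[i] == "F") {
      k <- sample(seq(floor(0.4 * aa), ceiling(0.6 * aa)), 1L)
      cats <- sample(c("E", "NE"))
      data.frame(orf_id = blocks$id[i],
                 domain_id = paste0(blocks$id[i], "_d", 1:2),
                 aa_start = c(1L, k + 1L), aa_end = c(k, aa),
                 truth = cats, source = "simulated", stringsAsFactors = FALSE)
    } else if (aa >= 120L && runif(1) < 0.3) {
      k <- sample(seq(floor(0.3 * aa), ceiling(0.7 * aa)), 1L)
      data.frame(orf_id = blocks$id[i],
                 domain_id = paste0(blocks$id[i], "_d", 1:2),
                 aa_start = c(1L, k + 1L), aa_end = c(k, aa),
                 truth = blocks$truth[i], source = "simulated",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(orf_id = blocks$id[i], domain_id = paste0(blocks$id[i], "_d1"),
                 aa_start = 1L, aa_end = aa, truth = blocks$truth[i],
                 source = "simulated", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

place_ncrnas_utrs <- function(blocks, config, G) {
  out <- list()
  orfs <- blocks[blocks$type == "ORF", , drop = FALSE]
  n_anti <- round(0.95 * config$n_ncrnas)
  n_inter <- config$n_ncrnas - n_anti
  hosts <- orfs[sample(nrow(orfs), min(n_anti, nrow(orfs))), , drop = FALSE]
  if (nrow(hosts)) {
    len <- pmin(sample(50:300, nrow(hosts), replace = TRUE),
                hosts$end - hosts$start + 1L)
    off <- vapply(hosts$end - hosts$start + 1L - len,
                  function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
    out$anti <- data.frame(
      id = sprintf("NCRNA_%03d", seq_len(nrow(hosts))),
      type = "ncRNA", start = hosts$start + off, end = hosts$start + off + len - 1L,
      strand = ifelse(hosts$strand == "+", "-", "+"),
      truth = hosts$truth,  # antisense ncRNAs inherit host truth
      stringsAsFactors = FALSE)
  }
  if (n_inter > 0) {
    # free gaps between blocks
    occ <- IRanges::reduce(IRanges::IRanges(blocks$start, blocks$end))
    free <- IRanges::gaps(occ, start = 1L, end = G)
    free <- free[IRanges::width(free) >= 90L]
    k <- min(n_inter, length(free))
    if (k > 0) {
      pick <- sample(length(free), k)
      len <- pmin(sample(50:200, k, replace = TRUE), IRanges::width(free)[pick] - 20L)
      st <- IRanges::start(free)[pick] + 10L
      out$inter <- data.frame(
        id = sprintf("NCRNA_I%02d", seq_len(k)), type = "ncRNA",
        start = st, end = st + len - 1L,
        strand = sample(c("+", "-"), k, replace = TRUE),
        truth = ifelse(runif(k) < 0.3, "E", "NE"), stringsAsFactors = FALSE)
    }
  }
  # 5'-UTRs in the spacer immediately upstream of a subset of ORFs
  occ_all <- IRanges::reduce(IRanges::IRanges(blocks$start, blocks$end))
  utr_hosts <- orfs[runif(nrow(orfs)) < 0.3, , drop = FALSE]
  if (nrow(utr_hosts)) {
    utr <- lapply(seq_len(nrow(utr_hosts)), function(i) {
      h <- utr_hosts[i, ]
      want <- sample(20:60, 1L)
      if (h$strand == "+") {
        lim <- IRanges::end(occ_all)[IRanges::end(occ_all) < h$start]
        room <- h$start - (if (length(lim)) max(lim) else 0L) - 2L
        len <- min(want, room)
        if (len < 10L) return(NULL)
        data.frame(id = paste0("UTR5_", h$id), type = "UTR5",
                   start = h$start - len, end = h$start - 1L, strand = "+",
                   truth = if (h$truth == "E" && runif(1) < 0.26) "E" else "NE",
                   stringsAsFactors = FALSE)
      } else {
        lim <- IRanges::start(occ_all)[IRanges::start(occ_all) > h$end]
        room <- (if (length(lim)) min(lim) else G + 1L) - h$end - 2L
        len <- min(want, room)
        if (len < 10L) return(NULL)
        data.frame(id = paste0("UTR5_", h$id), type = "UTR5",
                   start = h$end + 1L, end = h$end + len, strand = "-",
                   truth = if (h$truth == "E" && runif(1) < 0.26) "E" else "NE",
                   stringsAsFactors = FALSE)
      }
    })
    out$utr <- do.call(rbind, utr)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(id = character(), type = character(),
                                      start = integer(), end = integer(),
                                      strand = character(), truth = character())
  rownames(res) <- NULL
  res
}

# Ground-truth essential base mask as merged intervals: whole spans of E
# features plus the essential domain of mixed-domain (F) ORFs.
essential_truth_ranges <- function(annotation, domains, G) {
  spans <- annotation[annotation$truth == "E", c("start", "end"), drop = FALSE]
  f_orfs <- annotation[annotation$truth == "F" & annotation$type == "ORF", , drop = FALSE]
  if (nrow(f_orfs)) {
    dm <- domains[domains$orf_id %in% f_orfs$id & domains$truth == "E", , drop = FALSE]
    if (nrow(dm)) {
      nt <- t(vapply(seq_len(nrow(dm)), function(i) {
        orf <- f_orfs[f_orfs$id == dm$orf_id[i], ]
        unlist(domain_to_genome(dm[i, ], orf))
      }, numeric(2)))
      spans <- rbind(spans, data.frame(start = nt[, 1], end = nt[, 2]))
    }
  }
  if (nrow(spans) == 0L) return(data.frame(start = integer(), end = integer()))
  r <- IRanges::reduce(IRanges::IRanges(spans$start, spans$end))
  data.frame(start = IRanges::start(r), end = IRanges::end(r))
}

#' @export
print.sim_genome <- function(x, ...) {
  tab <- table(x$annotation$type)
  ess <- sum(x$essential_regions$end - x$essential_regions$start + 1)
  cat(sprintf("Synthetic genome: %d bp, %d features (%s)\n",
              nchar(x$genome), nrow(x$annotation),
              paste(names(tab), tab, sep = ":", collapse = ", ")))
  cat(sprintf("Ground-truth essential: %d bp (%.1f%%)\n", ess,
              100 * ess / nchar(x$genome)))
  invisible(x)
}

#' Deterministic gold sets from simulated truth
#'
#' Picks evenly spaced truth-essential and truth-non-essential ORFs along the
#' genome as gold-standard sets (default sizes 37 and 29, the typical size of
#' manually curated sets for a genome-reduced bacterium).
#'
#' @param sim A [simulate_genome()] result (or its annotation data.frame with
#'   a `truth` column).
#' @param n_essential,n_nonessential Set sizes (capped at availability).
#' @return A [gold_set()].
#' @export
make_gold_set <- function(sim, n_essential = 37L, n_nonessential = 29L) {
  ann <- if (inherits(sim, "sim_genome")) sim$annotation else sim
  pick <- function(cat, n) {
    ids <- ann$id[ann$type == "ORF" & ann$truth == cat]
    if (length(ids) == 0L) stop("no truth-", cat, " ORFs to build a gold set from",
                                call. = FALSE)
    ids[unique(round(seq(1, length(ids), length.out = min(n, length(ids)))))]
  }
  gold_set(pick("E", n_essential), pick("NE", n_nonessential))
}
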