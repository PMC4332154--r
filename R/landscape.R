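# Landscape built from a precomputed evidence cover (used inside the fit).
landscape_from_cover <- function(annotation, calls, cover, G) {
  seg <- cover$e
  segments <- data.frame(start = IRanges::start(seg), end = IRanges::end(seg))
  essential_bp <- sum(IRanges::width(seg))
  inter <- intergenic_regions(annotation, G, min_bp = 100L)
  inter_calls <- if (nrow(inter)) {
    cbind(inter, do.call(rbind, lapply(seq_len(nrow(inter)), function(i)
      as.data.frame(score_region_core(inter$start[i], inter$end[i], cover, G)))))
  } else cbind(inter, data.frame(P_E = numeric(), P_NE = numeric(),
                                 category = character(), n_insertions = integer(),
                                 longest_gap = integer()))
  list(essential_segments = segments, essential_bp = essential_bp,
       essential_fraction = essential_bp / G,
       intergenic = inter_calls,
       essential_intergenic = inter_calls[inter_calls$category == "E", , drop = FALSE])
}

#' Genome-wide essentiality landscape
#'
#' The union of statistically significant insertion-free intervals -- the
#' minimal essential genome implied by the screen -- together with its size,
#' genome fraction, per-feature-class essentiality percentages, and the list
#' of essential intergenic regions longer than `min_bp`.
#'
#' @param fit An [fit_essentiality()] result; or pass `annotation`, `table`
#'   and `model` explicitly.
#' @param annotation,table,model Used when `fit` is missing.
#' @param min_bp Minimum intergenic length reported (default 100).
#' @return List: `essential_segments` (data.frame `start`, `end`, sorted,
#'   non-overlapping), `essential_bp`, `essential_fraction`, `per_class`
#'   summary, `intergenic` calls and `essential_intergenic` subset.
#' @export
essential_landscape <- function(fit = NULL, annotation = NULL, table = NULL,
                                model = NULL, min_bp = 100L) {
  if (is.null(fit)) {
    sites <- threshold_sites(table, model$read_threshold)
    if (nrow(sites) == 0L)
      stop("no insertion passes the read threshold: N = 0 is degenerate", call. = FALSE)
    cover <- evidence_cover(sites$position, model$G, model$N, model$alpha,
                            model$w, model$circular)
    calls <- score_features(annotation, cover, model$G)
    ls <- landscape_from_cover(annotation, calls, cover, model$G)
  } else {
    annotation <- fit$annotation
    calls <- fit$calls
    ls <- fit$landscape
  }
  ls$per_class <- lapply(c("ncRNA", "UTR5", "convRNA"), function(ty)
    assign_feature_essentiality(annotation, calls, ty))
  names(ls$per_class) <- c("ncRNA", "UTR5", "convRNA")
  ls
}

#' Per-class feature essentiality summary
#'
#' Summarises E/NE/F calls for one feature class with the overlap rule for
#' ncRNAs: an ncRNA overlapping an essential ORF on either strand cannot be
#' assigned its own essentiality (an insertion-free stretch there is
#' explained by the host ORF) and is reported `unassignable`; all remaining
#' features keep their gap-null calls.
#'
#' @param annotation Full feature annotation.
#' @param calls Per-feature calls (from [fit_essentiality()]).
#' @param feature_class One of `"ncRNA"`, `"UTR5"`, `"convRNA"`,
#'   `"intergenic"`, `"ORF"`, `"smORF"`.
#' @return List with `calls` (the class's rows, plus `status`), `counts`
#'   (E/NE/F/unassignable) and `percent` (over assignable features).
#' @export
assign_feature_essentiality <- function(annotation, calls, feature_class) {
  known <- c("ORF", "smORF", "ncRNA", "UTR5", "convRNA", "intergenic")
  if (!feature_class %in% known)
    stop("unknown feature class: ", feature_class, call. = FALSE)
  rows <- calls[calls$type == feature_class, , drop = FALSE]
  rows$status <- rows$category
  if (feature_class == "ncRNA" && nrow(rows)) {
    e_orfs <- calls[calls$type == "ORF" & calls$category == "E", , drop = FALSE]
    if (nrow(e_orfs)) {
      ov <- vapply(seq_len(nrow(rows)), function(i)
        any(e_orfs$start <= rows$end[i] & e_orfs$end >= rows$start[i]),
        logical(1))
      rows$status[ov] <- "unassignable"
    }
  }
  counts <- table(factor(rows$status, levels = c("E", "NE", "F", "unassignable")))
  assignable <- sum(counts[c("E", "NE", "F")])
  percent <- if (assignable > 0) 100 * counts[c("E", "NE", "F")] / assignable
             else counts[c("E", "NE", "F")] * NA_real_
  list(calls = rows, counts = counts, percent = percent)
}

#' Intergenic regions of an annotation
#'
#' Complement of all annotated transcribed/coding features (both strands
#' pooled) on the circular genome, filtered to segments longer than `min_bp`.
#' Explicit `intergenic` features in the annotation (planted structural
#' elements) are not subtracted.
#'
#' @param annotation Feature annotation.
#' @param G Genome length.
#' @param min_bp Minimum reported length (default 100; shorter segments are
#'   excluded from intergenic summaries).
#' @return data.frame `id`, `type`, `start`, `end`, `strand`.
#' @export
intergenic_regions <- function(annotation, G, min_bp = 100L) {
  feats <- annotation[annotation$type != "intergenic", , drop = FALSE]
  occ <- if (nrow(feats))
    IRanges::reduce(IRanges::IRanges(feats$start, feats$end))
  else IRanges::IRanges()
  free <- IRanges::gaps(occ, start = 1L, end = as.integer(G))
  free <- free[IRanges::width(free) > min_bp]
  if (length(free) == 0L)
    return(data.frame(id = character(), type = character(), start = integer(),
                      end = integer(), strand = character()))
  data.frame(id = sprintf("IG_%04d", seq_along(free)), type = "intergenic",
             start = IRanges::start(free), end = IRanges::end(free),
             strand = "+", stringsAsFactors = FALSE)
}
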