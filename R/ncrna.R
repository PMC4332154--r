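#' Context likelihood of relatedness (CLR) over an expression matrix
#'
#' Scores every feature pair of an expression time course for co-expression.
#' Pairwise mutual information is estimated with the Gaussian formula
#' `MI = -0.5 * log(1 - r^2)` from the Pearson correlation `r` -- stable at
#' the ~10 timepoints typical of a growth curve, monotone in `|r|`, zero iff
#' `r = 0`. Each MI is then z-scored against the background MI distribution
#' of both partners (`z_i(j) = max(0, (MI_ij - mean_i) / sd_i)` over row `i`,
#' diagonal excluded) and combined as the root mean square
#' `clr_ij = sqrt((z_i(j)^2 + z_j(i)^2) / 2)`, so a pair only scores highly
#' when the association is exceptional for both features, suppressing
#' promiscuous hubs, and the significance threshold reads directly as an
#' average background z-score. Zero-variance features get MI 0 everywhere,
#' with a warning.
#'
#' @param expr Numeric matrix, features x timepoints (>= 3 features, >= 3
#'   timepoints), rownames = feature ids.
#' @return Object of class `clr_result`: list with symmetric matrices `mi`,
#'   `clr`, `r` and the significance `threshold` slot (filled by consumers).
#' @export
clr_matrix <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need >= 3 timepoints", call. = FALSE)
  if (nrow(expr) < 3L)
    stop("need >= 3 features (background distribution undefined)", call. = FALSE)
  if (anyNA(expr)) stop("expression matrix must have no missing values", call. = FALSE)
  if (is.null(rownames(expr))) rownames(expr) <- paste0("f", seq_len(nrow(expr)))
  sds <- apply(expr, 1L, sd)
  if (any(sds == 0))
    warning("zero-variance feature(s): ",
            paste(rownames(expr)[sds == 0], collapse = ", "),
            "; their mutual information is set to 0")
  r <- suppressWarnings(cor(t(expr)))
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  r2 <- pmin(r^2, 1 - 1e-12)            # duplicated features: finite, maximal MI
  mi <- -0.5 * log(1 - r2)
  diag(mi) <- 0
  n <- nrow(mi)
  z <- matrix(0, n, n, dimnames = dimnames(mi))
  for (i in seq_len(n)) {
    row <- mi[i, -i]
    m <- mean(row); s <- sd(row)
    if (s > 0) z[i, -i] <- pmax(0, (mi[i, -i] - m) / s)
  }
  clr <- sqrt((z^2 + t(z)^2) / 2)
  structure(list(mi = mi, clr = clr, r = r, features = rownames(expr)),
            class = "clr_result")
}

#' @export
print.clr_result <- function(x, ...) {
  n <- length(x$features)
  cat(sprintf("CLR result: %d features, %d pairs; max CLR %.2f\n",
              n, n * (n - 1) / 2, max(x$clr)))
  invisible(x)
}

#' Classify antisense ncRNA--ORF pairs by correlation sign
#'
#' Restricted to the pairs of interest (antisense ncRNAs and the ORFs they
#' overlap on the opposite strand), keeps pairs whose CLR score exceeds the
#' significance threshold and labels them by the sign of the Pearson
#' correlation: `anti-correlated` (r < 0, the ncRNA tracks opposite to its
#' host, suggesting repression) or `correlated` (r > 0). A significant pair
#' with r exactly 0 is `undetermined` and excluded from downstream counts.
#'
#' @param clr A [clr_matrix()] result.
#' @param pairs data.frame with columns `ncrna`, `orf` (feature ids present in
#'   the matrix).
#' @param threshold CLR significance threshold (default 2.5).
#' @return `pairs` with added columns `clr`, `r`, `significant`, `sign`.
#' @export
classify_pairs <- function(clr, pairs, threshold = 2.5) {
  stopifnot(inherits(clr, "clr_result"))
  miss <- setdiff(unique(c(pairs$ncrna, pairs$orf)), clr$features)
  if (length(miss))
    stop("pair feature(s) absent from the CLR matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  idx <- cbind(match(pairs$ncrna, clr$features), match(pairs$orf, clr$features))
  pairs$clr <- clr$clr[idx]
  pairs$r <- clr$r[idx]
  pairs$significant <- pairs$clr > threshold
  pairs$sign <- ifelse(!pairs$significant, NA_character_,
                       ifelse(pairs$r < 0, "anti-correlated",
                              ifelse(pairs$r > 0, "correlated", "undetermined")))
  pairs
}

#' Essentiality enrichment of anti-correlated ncRNA partners
#'
#' For each ncRNA with signed significant partners, computes the percentage of
#' its anti-correlated partner ORFs that are essential, and likewise for its
#' correlated partners. The two per-ncRNA percentage samples are compared with
#' Welch's two-sample t-test (unequal variances, Welch--Satterthwaite degrees
#' of freedom, two-sided). A higher anti-correlated mean indicates that
#' essential ORFs are preferentially down-regulated by their antisense ncRNAs.
#'
#' When both groups have zero variance and equal means the test is degenerate
#' and `t = 0`, `p = 1` is returned by convention.
#'
#' @param signed_pairs Output of [classify_pairs()] (undetermined pairs are
#'   dropped).
#' @param calls data.frame mapping `id` to `category` (per-ORF essentiality
#'   calls, e.g. from [fit_essentiality()]).
#' @return List with `welch` (list `t`, `df`, `p.value`, `means`, `n`) and
#'   `per_ncrna` (data.frame `ncrna`, `sign`, `pct_essential`, `n_partners`).
#' @export
essentiality_enrichment <- function(signed_pairs, calls) {
  sp <- signed_pairs[!is.na(signed_pairs$sign) &
                       signed_pairs$sign != "undetermined", , drop = FALSE]
  if (nrow(sp) == 0L) stop("no signed significant pairs", call. = FALSE)
  sp$essential <- calls$category[match(sp$orf, calls$id)] == "E"
  if (anyNA(sp$essential))
    stop("essentiality call missing for ORF(s): ",
         paste(unique(sp$orf[is.na(sp$essential)]), collapse = ", "), call. = FALSE)
  agg <- stats::aggregate(essential ~ ncrna + sign, data = sp,
                          FUN = function(x) 100 * mean(x))
  cnt <- stats::aggregate(essential ~ ncrna + sign, data = sp, FUN = length)
  per <- data.frame(ncrna = agg$ncrna, sign = agg$sign,
                    pct_essential = agg$essential, n_partners = cnt$essential,
                    stringsAsFactors = FALSE)
  g_anti <- per$pct_essential[per$sign == "anti-correlated"]
  g_corr <- per$pct_essential[per$sign == "correlated"]
  list(welch = welch_test(g_anti, g_corr), per_ncrna = per)
}

#' Welch's two-sample t-test
#'
#' Thin wrapper over [stats::t.test()] (`var.equal = FALSE`) returning the
#' statistic, Welch--Satterthwaite degrees of freedom and two-sided p-value,
#' with a convention for the degenerate case: two groups with zero pooled
#' variance and equal means return `t = 0`, `p = 1`.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return List `t`, `df`, `p.value`, `means`, `n`.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs n >= 2 (variance undefined)", call. = FALSE)
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2L, p.value = 1,
                  means = c(mean(x), mean(y)), n = c(length(x), length(y))))
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2L, p.value = 0,
                means = c(mean(x), mean(y)), n = c(length(x), length(y))))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, means = c(mean(x), mean(y)),
       n = c(length(x), length(y)))
}
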