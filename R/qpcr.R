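#' Amplification efficiency from a standard-curve slope
#'
#' `E = 10^(-1/slope)`; a perfect doubling assay has slope about -3.32 and
#' `E = 2`. A warning is raised for implausible efficiencies (outside
#' `(1, 2.5]`), e.g. when the slope has the wrong sign.
#'
#' @param slope Standard-curve slope in cycles per log10(input); non-zero.
#' @return Efficiency (fold amplification per cycle).
#' @examples
#' efficiencyFromSlope(-3.321928)  # 2
#' @export
efficiencyFromSlope <- function(slope) {
  if (!is.numeric(slope) || length(slope) != 1L || is.na(slope) ||
      slope == 0) {
    stop("slope must be a non-zero number")
  }
  e <- 10^(-1 / slope)
  if (e <= 1 || e > 2.5) {
    warning(sprintf("implausible amplification efficiency %.3f", e))
  }
  e
}

#' Efficiency-corrected relative expression ratio
#'
#' `ratio = E_target^dcpTarget / E_ref^dcpRef`, where each delta-CP is the
#' control-minus-treatment difference in crossing points of the target and
#' reference assays.
#'
#' @param eTarget,eRef Amplification efficiencies (> 0).
#' @param dcpTarget,dcpRef Crossing-point differences (control - treatment),
#'   in cycles.
#' @return The expression ratio.
#' @examples
#' pfafflRatio(2, 3, 2, 0)  # 8
#' @export
pfafflRatio <- function(eTarget, dcpTarget, eRef, dcpRef) {
  if (eTarget <= 0 || eRef <= 0) {
    stop("efficiencies must be positive")
  }
  eTarget^dcpTarget / eRef^dcpRef
}

#' Wilcoxon-Mann-Whitney two-sided test
#'
#' Rank-sum test on two samples. When the combined size is at most 12 the
#' p-value is exact, by full enumeration of all group labelings of the
#' ranks (ties handled through mid-ranks); otherwise a normal approximation
#' with tie correction is used (no continuity correction).
#'
#' @param x,y Numeric samples, each non-empty.
#' @return List with `U` (the Mann-Whitney statistic of `x`), `p`
#'   (two-sided) and `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxonMannWhitney(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
#' @export
wilcoxonMannWhitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty")
  }
  nx <- length(x)
  ny <- length(y)
  N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (N <= 12L) {
    subsets <- utils::combn(N, nx)
    Us <- colSums(matrix(r[subsets], nrow = nx)) - nx * (nx + 1) / 2
    pLow <- mean(Us <= U)
    pHigh <- mean(Us >= U)
    p <- min(1, 2 * min(pLow, pHigh))
    method <- "exact"
  } else {
    ties <- table(r)
    sigma <- sqrt(nx * ny / 12 *
                  ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
    z <- (U - nx * ny / 2) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

#' Relative expression of qPCR genes with significance
#'
#' Applies the efficiency-corrected ratio per gene, with the delta-CP of
#' each assay computed from group-mean crossing points, and tests
#' control-vs-treatment separation of the target's replicate crossing
#' points with the Wilcoxon-Mann-Whitney test.
#'
#' @param data Data.frame with columns `gene`, `group` (two levels),
#'   `cp` (crossing point) and `slope` (standard-curve slope, constant per
#'   gene).
#' @param refGene Reference (normalization) gene label, default `"18S"`.
#' @param control,treatment The two group labels; default the first and
#'   second level encountered.
#' @return Data.frame with one row per non-reference gene: `gene`,
#'   `efficiency`, `dcp`, `ratio`, `p_value`.
#' @export
relativeExpression <- function(data, refGene = "18S", control = NULL,
                               treatment = NULL) {
  stopifnot(all(c("gene", "group", "cp", "slope") %in% names(data)))
  groups <- unique(data$group)
  if (is.null(control)) control <- groups[1L]
  if (is.null(treatment)) treatment <- setdiff(groups, control)[1L]
  if (!refGene %in% data$gene) {
    stop(sprintf("reference gene '%s' not present", refGene))
  }
  meanCp <- function(g, grp) mean(data$cp[data$gene == g &
                                          data$group == grp])
  geneSlope <- function(g) data$slope[data$gene == g][1L]
  eRef <- efficiencyFromSlope(geneSlope(refGene))
  dcpRef <- meanCp(refGene, control) - meanCp(refGene, treatment)
  targets <- setdiff(unique(data$gene), refGene)
  rows <- lapply(targets, function(g) {
    e <- efficiencyFromSlope(geneSlope(g))
    dcp <- meanCp(g, control) - meanCp(g, treatment)
    wmw <- wilcoxonMannWhitney(
      data$cp[data$gene == g & data$group == control],
      data$cp[data$gene == g & data$group == treatment])
    data.frame(gene = g, efficiency = e, dcp = dcp,
               ratio = pfafflRatio(e, dcp, eRef, dcpRef),
               p_value = wmw$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
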