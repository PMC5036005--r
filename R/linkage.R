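## Linkage disequilibrium from phased haplotypes.

#' Pairwise linkage disequilibrium r-squared
#'
#' Computes D and r-squared between two SNPs from phased haplotype vectors:
#' with alternate-allele frequencies pA and pB and joint frequency pAB,
#' D = pAB - pA pB and r2 = D^2 / (pA (1-pA) pB (1-pB)). r2 ranges from 0
#' (no correlation) to 1 (perfect correlation: one allele predicts the
#' other every time). Monomorphic input leaves r2 undefined.
#'
#' @param hap_a,hap_b 0/1 vectors over the same phased haplotypes
#'   (length >= 4).
#' @return list with \code{r2}, \code{d}, \code{n_haplotypes} and, when r2
#'   is undefined, a \code{reason}.
#' @examples
#' rSquared(c(1, 1, 0, 0), c(1, 1, 0, 0))$r2  # 1
#' @export
rSquared <- function(hap_a, hap_b) {
  if (length(hap_a) != length(hap_b)) stop("haplotype vectors differ in length")
  if (length(hap_a) < 4) stop("at least 4 haplotypes are required")
  if (!all(hap_a %in% c(0, 1)) || !all(hap_b %in% c(0, 1)))
    stop("allele codes must be 0/1")
  n <- length(hap_a)
  pA <- mean(hap_a); pB <- mean(hap_b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(r2 = NA_real_, d = NA_real_, n_haplotypes = n,
                reason = "monomorphic SNP"))
  pAB <- mean(hap_a == 1 & hap_b == 1)
  d <- pAB - pA * pB
  list(r2 = d^2 / (pA * (1 - pA) * pB * (1 - pB)), d = d, n_haplotypes = n)
}

#' LD r-squared matrix between two SNP sets
#'
#' Computes \code{\link{rSquared}} for every pair of SNPs from two lists
#' drawn from one phased panel (the locus-heatmap layout: rows in input
#' order of \code{snps_a}, columns of \code{snps_b}). SNPs that are
#' monomorphic, or whose minor allele frequency falls below \code{maf_floor},
#' yield NA cells and are reported in the \code{flagged} attribute rather
#' than being silently dropped.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param snps_a,snps_b SNP identifier vectors (default: all SNPs).
#' @param maf_floor minimum minor-allele frequency for a SNP to be
#'   evaluated (default 0.01).
#' @return numeric matrix of r2 values with SNP dimnames; attributes
#'   \code{flagged} (SNPs below the MAF floor or monomorphic) and
#'   \code{maf_floor}.
#' @export
ldMatrix <- function(panel, snps_a = snpIds(panel), snps_b = snpIds(panel),
                     maf_floor = 0.01) {
  h <- haplotypes(panel)
  unknown <- setdiff(c(snps_a, snps_b), snpIds(panel))
  if (length(unknown))
    stop("unknown SNP id(s): ", paste(unknown, collapse = ", "))
  freqs <- colMeans(h)
  maf <- pmin(freqs, 1 - freqs)
  names(maf) <- snpIds(panel)
  flagged <- names(maf)[maf < maf_floor]
  out <- matrix(NA_real_, length(snps_a), length(snps_b),
                dimnames = list(snps_a, snps_b))
  for (i in seq_along(snps_a)) {
    if (snps_a[i] %in% flagged) next
    a <- h[, match(snps_a[i], snpIds(panel))]
    for (j in seq_along(snps_b)) {
      if (snps_b[j] %in% flagged) next
      b <- h[, match(snps_b[j], snpIds(panel))]
      out[i, j] <- rSquared(a, b)$r2
    }
  }
  attr(out, "flagged") <- flagged
  attr(out, "maf_floor") <- maf_floor
  out
}
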