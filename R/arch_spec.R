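#' Specify a multi-trait genetic architecture
#'
#' Defines the generative model used by the simulator: how many traits and
#' variants, what fraction of variants are causal, the genetic correlation
#' between traits (the pleiotropy dial), per-trait liability-scale
#' heritabilities and prevalences, and the allele-frequency range. Binary
#' outcomes arise from a liability-threshold model: each trait's liability is
#' the standardized genetic value scaled to variance `h2_liability` plus
#' independent normal noise with variance `1 - h2_liability`, and a sample is
#' a case when its liability exceeds the standard-normal quantile at
#' `1 - prevalence`.
#'
#' @param n_traits Number of traits (trait 1 is conventionally the target
#'   disease).
#' @param m_variants Number of variants.
#' @param causal_fraction Fraction of variants with nonzero effects, in
#'   `(0, 1]`. Causal variants are shared across traits; pleiotropy comes from
#'   the correlation of their effect sizes.
#' @param genetic_corr `n_traits x n_traits` genetic correlation matrix
#'   (symmetric, unit diagonal, positive semi-definite), or a single scalar
#'   used as the common off-diagonal correlation.
#' @param h2_liability Per-trait liability-scale heritability in `(0, 1)`;
#'   recycled to `n_traits`.
#' @param prevalence Per-trait case prevalence in `(0, 1)`; recycled.
#' @param maf_range Length-2 numeric, minor allele frequency range in
#'   `(0, 0.5]`.
#' @param seed Integer master seed for this architecture.
#' @return An object of class `multipgs_arch_spec` (a validated list).
#' @export
#' @examples
#' arch_spec(n_traits = 3, m_variants = 100, genetic_corr = 0.6)
arch_spec <- function(n_traits = 2L,
                      m_variants = 1000L,
                      causal_fraction = 0.1,
                      genetic_corr = 0,
                      h2_liability = 0.3,
                      prevalence = 0.1,
                      maf_range = c(0.05, 0.5),
                      seed = 1L) {
  n_traits <- as.integer(n_traits)
  m_variants <- as.integer(m_variants)
  stop_if(n_traits < 1L, "`n_traits` must be >= 1.")
  stop_if(m_variants < 1L, "`m_variants` must be >= 1.")
  stop_if(!(causal_fraction > 0 && causal_fraction <= 1),
          "`causal_fraction` must be in (0, 1].")

  if (length(genetic_corr) == 1L && !is.matrix(genetic_corr)) {
    S <- matrix(genetic_corr, n_traits, n_traits)
    diag(S) <- 1
  } else {
    S <- as.matrix(genetic_corr)
  }
  stop_if(nrow(S) != n_traits || ncol(S) != n_traits,
          "`genetic_corr` must be %d x %d.", n_traits, n_traits)
  stop_if(max(abs(S - t(S))) > 1e-8, "`genetic_corr` must be symmetric.")
  stop_if(max(abs(diag(S) - 1)) > 1e-8, "`genetic_corr` must have unit diagonal.")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  stop_if(min(ev) < -1e-8, "`genetic_corr` must be positive semi-definite.")

  h2 <- rep_len(h2_liability, n_traits)
  prev <- rep_len(prevalence, n_traits)
  stop_if(any(h2 <= 0 | h2 >= 1), "`h2_liability` must be in (0, 1) for every trait.")
  stop_if(any(prev <= 0 | prev >= 1), "`prevalence` must be in (0, 1) for every trait.")
  stop_if(length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
            maf_range[1] <= 0 || maf_range[2] > 0.5,
          "`maf_range` must be (low, high) within (0, 0.5].")

  structure(
    list(n_traits = n_traits, m_variants = m_variants,
         causal_fraction = causal_fraction, genetic_corr = S,
         h2_liability = h2, prevalence = prev,
         maf_range = as.numeric(maf_range), seed = as.integer(seed)),
    class = "multipgs_arch_spec"
  )
}

#' @export
print.multipgs_arch_spec <- function(x, ...) {
  cat("<multipgs_arch_spec>\n")
  cat(sprintf("  traits: %d  variants: %d  causal fraction: %.3g\n",
              x$n_traits, x$m_variants, x$causal_fraction))
  off <- x$genetic_corr[upper.tri(x$genetic_corr)]
  cat(sprintf("  genetic correlation (off-diagonal): %s\n",
              if (length(off)) paste(signif(range(off), 3), collapse = " .. ") else "-"))
  cat(sprintf("  h2 (liability): %s   prevalence: %s\n",
              paste(signif(x$h2_liability, 3), collapse = ", "),
              paste(signif(x$prevalence, 3), collapse = ", ")))
  cat(sprintf("  MAF range: [%g, %g]   seed: %d\n",
              x$maf_range[1], x$maf_range[2], x$seed))
  invisible(x)
}
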