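# Bayesian colocalization of two association signals in a region via
# per-variant Wakefield approximate Bayes factors and enumeration of the
# five hypotheses:
#   H0 no causal variant for either trait; H1/H2 one trait only;
#   H3 two distinct causal variants; H4 one shared causal variant.

#' Colocalization priors
#'
#' @param p1 prior probability a variant is causal for trait 1 only
#'   (default 1e-4).
#' @param p2 prior for trait 2 only (default 1e-4).
#' @param p12 prior the variant is causal for both traits (default 1e-5).
#'   `p12 > min(p1, p2)` draws a warning (an implausible prior), not an
#'   error.
#' @return list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 > 0, p12 < 1)
  if (p12 > min(p1, p2))
    warning("p12 exceeds min(p1, p2); check prior specification",
            call. = FALSE)
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Log approximate Bayes factor for one variant
#'
#' Wakefield's closed form: with `V = se^2`, `W = prior_sd^2`, `z = beta/se`
#' and `r = W/(V+W)`, the log-ABF against the null is
#' `0.5*log(1-r) + z^2*r/2`.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), > 0.
#' @param prior_sd prior standard deviation of the true effect (> 0);
#'   conventionally 0.15 for quantitative traits (per-SD scale) and 0.2 for
#'   case-control traits (log-OR scale).
#' @return numeric vector of log Bayes factors.
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stopf("log_abf requires se > 0")
  if (any(prior_sd <= 0)) stopf("log_abf requires prior_sd > 0")
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  z <- beta / se
  0.5 * log1p(-r) + z^2 * r / 2
}

prior_sd_for <- function(trait_type) {
  if (identical(trait_type, "case_control")) 0.2 else 0.15
}

#' Colocalization of two traits over a shared variant set
#'
#' Computes per-variant log-ABFs for both traits on the intersection of
#' variant ids and enumerates the five hypotheses, with all sums in log
#' space (log-sum-exp; no raw Bayes-factor products):
#' `S1 = p1 * sum_i BF1_i`, `S2 = p2 * sum_j BF2_j`,
#' `S3 = p1*p2 * sum_{i != j} BF1_i BF2_j`,
#' `S4 = p12 * sum_i BF1_i BF2_i`, `S0 = 1`; posteriors are the normalized
#' five terms.
#'
#' @param region1,region2 data.frames with `variant_id`, `beta`, `se`
#'   (e.g. [summary_stats] records restricted to the cis window). Variants
#'   missing from either trait are dropped (intersection) with a logged
#'   count.
#' @param priors [coloc_priors].
#' @param sd1,sd2 per-trait effect-size prior scales (see [log_abf]).
#' @param verbose log the intersection size.
#' @return list of class `coloc_result`: `pph0` .. `pph4`, `n_snps`,
#'   `priors`, and the per-variant log-ABF table `labf`.
#' @export
coloc_abf <- function(region1, region2, priors = coloc_priors(),
                      sd1 = 0.15, sd2 = 0.2, verbose = FALSE) {
  stopifnot(is.data.frame(region1), is.data.frame(region2))
  need <- c("variant_id", "beta", "se")
  stopifnot(all(need %in% names(region1)), all(need %in% names(region2)))
  shared <- intersect(region1$variant_id, region2$variant_id)
  dropped <- length(unique(c(region1$variant_id, region2$variant_id))) -
    length(shared)
  if (dropped > 0) log_kv("coloc", dropped_unshared = dropped,
                          verbose = verbose)
  if (length(shared) == 0L)
    stopf("coloc_abf: no shared variants between the two regions")
  r1 <- region1[match(shared, region1$variant_id), ]
  r2 <- region2[match(shared, region2$variant_id), ]
  l1 <- log_abf(r1$beta, r1$se, sd1)
  l2 <- log_abf(r2$beta, r2$se, sd2)

  s1 <- logsumexp(l1)                  # log sum_i BF1_i
  s2 <- logsumexp(l2)                  # log sum_j BF2_j
  s12 <- logsumexp(l1 + l2)            # log sum_i BF1_i BF2_i
  lH0 <- 0
  lH1 <- log(priors$p1) + s1
  lH2 <- log(priors$p2) + s2
  lH3 <- if (length(shared) < 2L) -Inf else
    log(priors$p1) + log(priors$p2) + logdiffexp(s1 + s2, s12)
  lH4 <- log(priors$p12) + s12
  lh <- c(lH0, lH1, lH2, lH3, lH4)
  post <- exp(lh - logsumexp(lh))
  structure(list(pph0 = post[1], pph1 = post[2], pph2 = post[3],
                 pph3 = post[4], pph4 = post[5],
                 n_snps = length(shared), priors = priors,
                 labf = data.frame(variant_id = shared, labf1 = l1,
                                   labf2 = l2, stringsAsFactors = FALSE)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, digits = 3, ...) {
  cat(sprintf("<coloc_result> %d shared variant(s)\n", x$n_snps))
  cat(sprintf("  PPH0 %.3g  PPH1 %.3g  PPH2 %.3g  PPH3 %.3g  PPH4 %.3g\n",
              x$pph0, x$pph1, x$pph2, x$pph3, x$pph4))
  invisible(x)
}

#' Call colocalization from a posterior threshold
#'
#' @param result [coloc_abf] result.
#' @param threshold posterior cutoff in (0, 1), default 0.7; the call is
#'   `colocalized` iff `pph4 > threshold` (strict).
#' @return `"colocalized"` or `"not_colocalized"`.
#' @export
coloc_call <- function(result, threshold = 0.7) {
  stopifnot(inherits(result, "coloc_result"),
            threshold > 0, threshold < 1)
  if (result$pph4 > threshold) "colocalized" else "not_colocalized"
}
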