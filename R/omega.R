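# Decomposition of gene-level selection into passenger and driver components
# (Omega_pass, Omega_dri) and site-specific posterior selection ratios.

#' Passenger-component selection ratio
#'
#' Omega_pass = (S_N / S_S) / (L_N / L_S), built from the numbers of distinct
#' mutated sites: recurrence at driver sites inflates N but not S_N, so the
#' site-based ratio isolates the passenger background.
#'
#' @param S_N,S_S Distinct mutated nonsynonymous / synonymous sites.
#' @param L_N,L_S Site opportunities.
#' @param s_pseudocount Substituted for `S_S` when it is 0 (flagged via
#'   attribute `ss_substituted`).
#' @return Omega_pass, or `NA` (attribute `reason`) when `S_N + S_S == 0`.
#' @export
omega_pass <- function(S_N, S_S, L_N, L_S, s_pseudocount = 0.5) {
  stopifnot(L_N > 0, L_S > 0)
  if (S_N + S_S == 0) {
    return(structure(NA_real_, reason = "no mutated sites"))
  }
  ss_sub <- S_S == 0
  if (ss_sub) S_S <- s_pseudocount
  structure((S_N / S_S) / (L_N / L_S), ss_substituted = ss_sub)
}

#' Driver-component selection ratio
#'
#' The adjusted count ratio [N/S]* = (N/S - (1 - eta) * S_N/S_S) / eta
#' removes the passenger contribution from the mutation-count ratio;
#' Omega_dri = [N/S]* / (L_N / L_S). Together with [omega_pass()] this
#' satisfies the identity (1 - eta) * Omega_pass + eta * Omega_dri = CN/CS.
#'
#' @param N,S Mutation counts.
#' @param S_N,S_S Distinct mutated sites.
#' @param eta Driver-site fraction (> 0).
#' @param L_N,L_S Site opportunities.
#' @param s_pseudocount Substituted for zero `S` or `S_S` (flagged).
#' @return List: `ns_star`, `omega_dri`, `floored` (TRUE when a negative
#'   `ns_star` was floored at 0), `substituted`.
#' @export
omega_dri <- function(N, S, S_N, S_S, eta, L_N, L_S, s_pseudocount = 0.5) {
  stopifnot(L_N > 0, L_S > 0)
  if (eta <= 0) stop("omega_dri is undefined when eta == 0")
  substituted <- FALSE
  if (S == 0) { S <- s_pseudocount; substituted <- TRUE }
  if (S_S == 0) { S_S <- s_pseudocount; substituted <- TRUE }
  ns_star <- (N / S - (1 - eta) * S_N / S_S) / eta
  floored <- ns_star < 0
  if (floored) ns_star <- 0
  list(ns_star = ns_star, omega_dri = ns_star / (L_N / L_S),
       floored = floored, substituted = substituted)
}

#' One-sided test of Omega_pass < 1
#'
#' Two-cell Pearson goodness-of-fit on the distinct-site counts (S_N, S_S)
#' with expected fractions (L_N, L_S) / (L_N + L_S), df = 1, one-sided
#' toward a deficit of mutated nonsynonymous sites. When the deviation runs
#' the other way the reported p is 1 - p/2 (never significant).
#'
#' @param S_N,S_S Distinct mutated sites; `S_N + S_S >= 1`.
#' @param L_N,L_S Site opportunities.
#' @return List: `statistic`, `p.value`, `small_expected`.
#' @export
omega_pass_test <- function(S_N, S_S, L_N, L_S) {
  stopifnot(S_N + S_S >= 1)
  tot <- S_N + S_S
  pN <- L_N / (L_N + L_S)
  expected <- tot * c(pN, 1 - pN)
  x2 <- sum((c(S_N, S_S) - expected)^2 / expected)
  p2 <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  p <- if (S_N <= expected[1L]) p2 / 2 else 1 - p2 / 2
  list(statistic = x2, p.value = p, small_expected = any(expected < 1))
}

#' Posterior probability that a site belongs to the driver component
#'
#' Q_k = eta * NB(z_k; m1, alpha) / f(z_k) by Bayes' rule under the fitted
#' mixture. Nondecreasing in z_k whenever m1 > m0.
#'
#' @param z_k Missense count(s) at the site(s).
#' @param m0,m1,eta,alpha Mixture parameters.
#' @return Q_k in [0, 1] (vectorized over `z_k`).
#' @export
site_posterior <- function(z_k, m0, m1, eta, alpha) {
  if (eta <= 0) return(rep(0, length(z_k)))
  if (eta >= 1) return(rep(1, length(z_k)))
  p1 <- stats::dnbinom(z_k, size = alpha, mu = m1)
  f <- mixture_pmf(z_k, m0, m1, eta, alpha)
  ifelse(f > 0, eta * p1 / f, 0)
}

#' Site-specific selection ratio
#'
#' Omega_k = (1 - Q_k) * Omega_pass +
#'           Q_k * ((z_k + alpha) / (m1 + alpha)) * Omega_dri,
#' the posterior-mean selection ratio at site k; the middle factor shrinks
#' the driver component toward the gene-level driver mean.
#'
#' @param z_k Missense count(s) at the site(s).
#' @param Q_k Posterior driver probability from [site_posterior()].
#' @param alpha,m1 Mixture parameters.
#' @param omega_pass,omega_dri Component ratios.
#' @return Omega_k (vectorized).
#' @export
omega_site <- function(z_k, Q_k, alpha, m1, omega_pass, omega_dri) {
  stopifnot(all(Q_k >= 0 & Q_k <= 1))
  (1 - Q_k) * omega_pass + Q_k * ((z_k + alpha) / (m1 + alpha)) * omega_dri
}

#' Full Omega decomposition for one gene
#'
#' @param counts A `gene_counts` (or list with N, S, S_N, S_S, z).
#' @param fit A `mixture_fit` with eta > 0.
#' @param L_N,L_S Site opportunities.
#' @param s_pseudocount Zero-denominator policy.
#' @return List of class `omega_decomposition`: `omega_pass`, `omega_dri`,
#'   `ns_star`, `p_pass_lt1`, `floored`, and `sites` (data frame
#'   codon_index, z_k, Q_k, omega_k).
#' @export
omega_decompose <- function(counts, fit, L_N, L_S, s_pseudocount = 0.5) {
  op <- omega_pass(counts$S_N, counts$S_S, L_N, L_S, s_pseudocount)
  od <- omega_dri(counts$N, counts$S, counts$S_N, counts$S_S, fit$eta,
                  L_N, L_S, s_pseudocount)
  tst <- omega_pass_test(counts$S_N, counts$S_S, L_N, L_S)
  z <- counts$z
  Q <- site_posterior(z, fit$m0, fit$m1, fit$eta, fit$alpha)
  ok <- omega_site(z, Q, fit$alpha, fit$m1, as.numeric(op), od$omega_dri)
  structure(list(omega_pass = as.numeric(op), omega_dri = od$omega_dri,
                 ns_star = od$ns_star, p_pass_lt1 = tst$p.value,
                 floored = od$floored,
                 sites = data.frame(codon_index = seq_along(z), z_k = z,
                                    Q_k = Q, omega_k = ok)),
            class = "omega_decomposition")
}
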