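## Jones-Taylor-Thornton (1992) empirical amino-acid model, in the classical
## integer digitization distributed with ML phylogenetics software.
## Exchangeabilities fill the lower triangle column-wise in the order
## A R N D C Q E G H I L K M F P S T W Y V.
.JTT_S <- c(
   58,  54,  81,  56,  57, 105, 179,  27,  36,  30,  35,  54,  15, 194, 378,
  475,   9,  11, 298,  45,  16, 113, 310,  29, 137, 328,  22,  38, 646,  44,
    5,  74, 101,  64, 126,  20,  17, 528,  34,  86,  58,  81, 391,  47,  12,
  263,  30,  10,  15, 503, 232,   8,  70,  16,  10,  49, 767, 130, 112,  11,
    7,  26,  15,   4,  15,  59,  38,   4,  46,  31,   9,   5,  59,  69,  17,
   23,   7,  31,  78,  14, 223,  42, 115, 209,  62, 323,  26, 597,   9,  72,
  292,  43,   4, 164,  53,  51,  18,  24,  20, 119,  26,  12,   9, 181,  18,
    5,  18,  30,  32,  10,   7,  45,  23,   6,   6,  27,  14,   5,  24, 201,
   33,  55,   8,  47,  16,  56,  45,  33,  40, 115,  73,  46,   8, 573,  11,
  229,  21, 479,  89,  10,  40, 245,   9,  32, 961,  14, 388, 248, 102,  59,
   25,  52,  24, 180,  65,   4,  21,  47, 103,  10,   8,  14,  43,  16,  29,
  226,  24,  18, 323,  17,  92,  12,  53, 536,  62, 285, 118,   6,  10,  23,
  477,  35,  63,  38,  12,  21, 112,  71,  25,  16)

.JTT_FREQS <- c(
  0.076747923252076758, 0.051690948309051694, 0.042644957355042652,
  0.051543948456051550, 0.019802980197019805, 0.040751959248040752,
  0.061829938170061841, 0.073151926848073159, 0.022943977056022944,
  0.053760946239053767, 0.091903908096091905, 0.058675941324058678,
  0.023825976174023829, 0.040125959874040135, 0.050900949099050907,
  0.068764931235068771, 0.058564941435058568, 0.014260985739014262,
  0.032101967898032102, 0.066004933995066004)

.exchange_matrix <- function(lower) {
  s <- matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  s[lower.tri(s)] <- lower
  s + t(s)
}

#' Amino-acid substitution model (JTT or Poisson) with +I and +G
#'
#' Assembles a reversible amino-acid substitution model: a symmetric
#' exchangeability matrix and equilibrium frequencies, a gamma shape
#' parameter for among-site rate heterogeneity (discretized into `k`
#' equal-probability categories), and a proportion of invariant sites.
#' The instantaneous rate matrix is `Q[i,j] = s[i,j] * pi[j]` (i != j),
#' scaled so the expected substitution rate at equilibrium is 1; the model
#' therefore measures branch lengths in expected substitutions per site.
#'
#' The `"JTT"` model uses the classical Jones-Taylor-Thornton empirical
#' exchangeabilities and frequencies. The `"Poisson"` model (equal rates,
#' equal frequencies) admits closed-form transition probabilities and
#' exists mainly to support exact tests.
#'
#' @param name `"JTT"` or `"Poisson"`.
#' @param alpha gamma shape parameter (> 0). Large values approach
#'   rate homogeneity.
#' @param k number of discrete gamma categories (>= 1); `k = 1` disables
#'   rate heterogeneity regardless of `alpha`.
#' @param p_inv proportion of invariant sites, in `[0, 1)` for inference
#'   (`1` is accepted for simulation of fully invariant data).
#' @param freqs optional length-20 frequency override (must sum to 1).
#' @return an object of class `subst_model` carrying the exchangeabilities,
#'   frequencies, the scaled rate matrix `Q` and its symmetric
#'   eigendecomposition (`eig$lambda`, `eig$U`, `eig$Uinv`).
#' @export
subst_model <- function(name = c("JTT", "Poisson"), alpha = 1, k = 4L,
                        p_inv = 0, freqs = NULL) {
  name <- match.arg(name)
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be finite and > 0")
  if (k < 1L || k != round(k)) stop("'k' must be a positive integer")
  if (!is.finite(p_inv) || p_inv < 0 || p_inv > 1)
    stop("'p_inv' must lie in [0, 1]")
  s <- if (name == "JTT") .exchange_matrix(.JTT_S) else {
    m <- matrix(1, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
    diag(m) <- 0
    m
  }
  pi <- if (!is.null(freqs)) {
    stopifnot(length(freqs) == 20L, all(freqs > 0))
    freqs / sum(freqs)
  } else if (name == "JTT") .JTT_FREQS else rep(1 / 20, 20L)

  Q <- s * rep(pi, each = 20L)            # Q[i,j] = s[i,j] * pi[j]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))                # expected rate at equilibrium
  Q <- Q / mu
  ## symmetric similarity transform: B = D^{1/2} Q D^{-1/2} is symmetric
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2                     # clean residual asymmetry
  e <- eigen(B, symmetric = TRUE)
  structure(list(
    name = name, s = s, freqs = pi, Q = Q,
    alpha = alpha, k = as.integer(k), p_inv = p_inv,
    eig = list(lambda = e$values,
               U = (1 / sq) * e$vectors,        # rows scaled
               Uinv = t(e$vectors) * rep(sq, each = 20L))
  ), class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("%s substitution model: +I (p_inv = %.3g), +G%d (alpha = %.3g)\n",
              x$name, x$p_inv, x$k, x$alpha))
  invisible(x)
}

#' Discrete gamma rate categories (mean of equal-probability bins)
#'
#' Splits the Gamma(alpha, alpha) distribution (mean 1) into `k`
#' equal-probability bins and returns the mean rate of each bin, the
#' standard discretization of among-site rate heterogeneity. The bin mean
#' over (`a`, `b`] is computed in closed form from the incomplete-gamma
#' identity `E[X; X <= q] = P(G(alpha+1, alpha) <= q)` and the rates are
#' renormalized so their mean is exactly 1.
#'
#' @param alpha gamma shape parameter (> 0, finite).
#' @param k number of categories (>= 1).
#' @return numeric vector of `k` increasing rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be finite and > 0")
  if (k < 1L || k != round(k)) stop("'k' must be a positive integer")
  k <- as.integer(k)
  if (k == 1L) return(1)
  q <- stats::qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  cdf1 <- c(0, stats::pgamma(q, shape = alpha + 1, rate = alpha), 1)
  rates <- k * diff(cdf1)
  rates / mean(rates)
}

## Category rates actually used by the +I+G mixture: the gamma rates are
## divided by (1 - p_inv) so that the whole mixture keeps mean rate 1.
mixture_rates <- function(model) {
  r <- discrete_gamma_rates(model$alpha, model$k)
  if (model$p_inv >= 1) return(r)          # degenerate: all-invariant
  r / (1 - model$p_inv)
}

#' Transition probability matrix P(t) of a substitution model
#'
#' @param model a [subst_model].
#' @param t branch length in expected substitutions per site (>= 0).
#' @param rate multiplicative rate factor (e.g. a gamma-category rate).
#' @return 20 x 20 matrix of transition probabilities; rows sum to 1.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  e <- model$eig
  P <- e$U %*% (exp(e$lambda * t * rate) * e$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}
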