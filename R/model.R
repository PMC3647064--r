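# Amino-acid substitution models: LG exchangeabilities as published constants,
# discrete-gamma rate heterogeneity and a proportion of invariant sites.

# canonical state order (PAML convention)
AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# LG exchangeabilities (Le & Gascuel 2008), lower triangle column-wise in
# AA_STATES order, and the accompanying stationary frequencies.
LG_EXCHANGEABILITIES <- c(
  0.425093,
  0.276818, 0.751878,
  0.395144, 0.123954, 5.076149,
  2.489084, 0.534551, 0.528768, 0.062556,
  0.969894, 2.807908, 1.695752, 0.523386, 0.084808,
  1.038545, 0.363970, 0.541712, 5.243870, 0.003499, 4.128591,
  2.066040, 0.390192, 1.437645, 0.844926, 0.569265, 0.267959, 0.348847,
  0.358858, 2.426601, 4.509238, 0.927114, 0.640543, 4.813505, 0.423881,
  0.311484,
  0.149830, 0.126991, 0.191503, 0.010690, 0.320627, 0.072854, 0.044265,
  0.008705, 0.108882,
  0.395337, 0.301848, 0.068427, 0.015076, 0.594007, 0.582457, 0.069673,
  0.044261, 0.366317, 4.145067,
  0.536518, 6.326067, 2.145078, 0.282959, 0.013266, 3.234294, 1.807177,
  0.296636, 0.697264, 0.159069, 0.137500,
  1.124035, 0.484133, 0.371004, 0.025548, 0.893680, 1.672569, 0.173735,
  0.139538, 0.442472, 4.273607, 6.312358, 0.656604,
  0.253701, 0.052722, 0.089525, 0.017416, 1.105251, 0.035855, 0.018811,
  0.089586, 0.682139, 1.112727, 2.592692, 0.023918, 1.798853,
  1.177651, 0.332533, 0.161787, 0.394456, 0.075382, 0.624294, 0.419409,
  0.196961, 0.508851, 0.078281, 0.249060, 0.390322, 0.099849, 0.094464,
  4.727182, 0.858151, 4.008358, 1.240275, 2.784478, 1.223828, 0.611973,
  1.739990, 0.990012, 0.064105, 0.182287, 0.748683, 0.346960, 0.361819,
  1.338132,
  2.139501, 0.578987, 2.000679, 0.425860, 1.143480, 1.080136, 0.604545,
  0.129836, 0.584262, 1.033739, 0.302936, 1.136863, 2.020366, 0.165001,
  0.571468, 6.472279,
  0.180717, 0.593607, 0.045376, 0.029890, 0.670128, 0.236199, 0.077852,
  0.268491, 0.597054, 0.111660, 0.619632, 0.049906, 0.696175, 2.457121,
  0.095131, 0.248862, 0.140825,
  0.218959, 0.314440, 0.612025, 0.135107, 1.165532, 0.257336, 0.120037,
  0.054679, 5.306834, 0.232523, 0.299648, 0.131932, 0.481306, 7.803902,
  0.089613, 0.400547, 0.245841, 3.151815,
  2.547870, 0.170887, 0.083688, 0.037967, 1.959291, 0.210332, 0.245034,
  0.076701, 0.119013, 10.649107, 1.702745, 0.185202, 1.898718, 0.654683,
  0.296501, 0.098369, 2.188158, 0.189510, 0.249313)

LG_FREQUENCIES <- c(
  0.079066, 0.055941, 0.041977, 0.053052, 0.012937, 0.040767, 0.071586,
  0.057337, 0.022355, 0.062157, 0.099081, 0.064600, 0.022951, 0.042302,
  0.044040, 0.061197, 0.053287, 0.012066, 0.034155, 0.069147)

#' Discrete-gamma rate categories
#'
#' Mean-value discretization of the Gamma(alpha, alpha) distribution into
#' `K` equal-probability categories. Each category rate is the conditional
#' mean of the distribution over its quantile band; the returned rates are
#' renormalized so their mean is exactly 1.
#'
#' @param alpha Gamma shape parameter (> 0); small values give strong rate
#'   heterogeneity among sites.
#' @param K Number of rate categories (>= 1).
#' @return Numeric vector of `K` relative rates with mean 1.
#' @examples
#' discrete_gamma_rates(0.5, 4)
#' @export
discrete_gamma_rates <- function(alpha, K) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("`alpha` must be a single positive number", call. = FALSE)
  }
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("`K` must be an integer >= 1", call. = FALSE)
  if (K == 1L) return(1)
  breaks <- stats::qgamma(seq(0, 1, length.out = K + 1L),
                          shape = alpha, rate = alpha)
  # band mean of Gamma(a, a): K * [F_{a+1,a}(hi) - F_{a+1,a}(lo)], where
  # F_{a+1,a} is the cdf of Gamma(a + 1, a) (the size-biased distribution)
  upper <- stats::pgamma(breaks[-1L], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(breaks[-(K + 1L)], shape = alpha + 1, rate = alpha)
  rates <- K * (upper - lower)
  rates / mean(rates)
}

#' Amino-acid substitution model with gamma rates and invariant sites
#'
#' Builds a time-reversible 20-state model from symmetric exchangeabilities
#' `s` and stationary frequencies `pi`: `Q[i,j] = s[i,j] * pi[j]`, the
#' diagonal set so rows sum to zero, and the matrix scaled to one expected
#' substitution per site at stationarity. Site-rate heterogeneity is a
#' discrete-gamma mixture (see [discrete_gamma_rates()]) plus an optional
#' proportion of invariant sites.
#'
#' @param exchangeabilities `"LG"` (bundled published constants) or a
#'   symmetric 20x20 non-negative matrix with zero diagonal in [AA_STATES]
#'   order (a 190-vector of the lower triangle is also accepted).
#' @param frequencies Stationary frequencies summing to 1; defaults to the
#'   frequencies published with the exchangeability matrix.
#' @param alpha Gamma shape for rate heterogeneity.
#' @param pinv Proportion of invariant sites, in `[0, 1)`.
#' @param n_categories Number of discrete-gamma categories.
#' @return Object of class `aa_model` with the scaled rate matrix, its
#'   eigendecomposition, category rates and mixture weights.
#' @seealso [read_paml_matrix()] to load a user matrix (e.g. WAG) from a
#'   PAML-format file.
#' @export
substitution_model <- function(exchangeabilities = "LG", frequencies = NULL,
                               alpha = 1, pinv = 0, n_categories = 4L) {
  if (is.character(exchangeabilities)) {
    if (!identical(toupper(exchangeabilities), "LG")) {
      stop("only the bundled \"LG\" model is named; pass a matrix for others",
           call. = FALSE)
    }
    s <- lower_tri_to_sym(LG_EXCHANGEABILITIES)
    if (is.null(frequencies)) frequencies <- LG_FREQUENCIES
  } else if (is.matrix(exchangeabilities)) {
    s <- exchangeabilities
  } else {
    s <- lower_tri_to_sym(as.numeric(exchangeabilities))
  }
  if (!all(dim(s) == c(20L, 20L)) || any(s < 0) || any(diag(s) != 0) ||
      !isTRUE(all.equal(s, t(s), tolerance = 1e-8))) {
    stop("exchangeabilities must be a symmetric non-negative 20x20 matrix ",
         "with zero diagonal", call. = FALSE)
  }
  if (is.null(frequencies)) {
    stop("`frequencies` must be given with a custom matrix", call. = FALSE)
  }
  pi <- as.numeric(frequencies)
  if (length(pi) != 20L || any(pi <= 0)) {
    stop("`frequencies` must be 20 positive values", call. = FALSE)
  }
  pi <- pi / sum(pi)
  if (!is.numeric(pinv) || pinv < 0 || pinv >= 1) {
    stop("`pinv` must be in [0, 1)", call. = FALSE)
  }

  q <- s %*% diag(pi)
  diag(q) <- -rowSums(q)
  mu <- -sum(pi * diag(q))          # expected rate at stationarity
  q <- q / mu

  # symmetrized eigendecomposition (reversibility): P(t) = U exp(Lt) W
  sp <- sqrt(pi)
  b <- diag(sp) %*% q %*% diag(1 / sp)
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  model <- list(
    exchangeabilities = s,
    frequencies = pi,
    alpha = alpha,
    pinv = pinv,
    n_categories = as.integer(n_categories),
    rates = discrete_gamma_rates(alpha, n_categories),
    Q = q,
    eigenvalues = eig$values,
    U = diag(1 / sp) %*% eig$vectors,
    W = t(eig$vectors) %*% diag(sp)
  )
  dimnames(model$Q) <- list(AA_STATES, AA_STATES)
  class(model) <- "aa_model"
  model
}

#' @export
print.aa_model <- function(x, ...) {
  cat("Amino-acid substitution model (", 20, " states)\n", sep = "")
  cat("  alpha =", x$alpha, " pinv =", x$pinv,
      " categories =", x$n_categories, "\n")
  cat("  category rates:", paste(signif(x$rates, 4), collapse = ", "), "\n")
  invisible(x)
}

# transition probability matrix P(t) for one branch
prob_matrix <- function(model, t) {
  if (t < 0) stop("branch length must be >= 0", call. = FALSE)
  p <- model$U %*% (exp(model$eigenvalues * t) * model$W)
  # clamp tiny numerical negatives
  p[p < 0] <- 0
  p
}

lower_tri_to_sym <- function(x) {
  if (length(x) != 190L) {
    stop("expected 190 lower-triangle exchangeabilities", call. = FALSE)
  }
  # row-wise lower triangle (the published .dat layout)
  m <- matrix(0, 20L, 20L)
  m[upper.tri(m)] <- x
  m <- t(m)
  m + t(m)
}

#' Read a PAML-format amino-acid rate matrix
#'
#' Parses the standard PAML `.dat` layout: 19 lines of the lower triangle of
#' the exchangeability matrix followed by a line (or lines) of 20 stationary
#' frequencies. Whitespace-separated, comments after the numbers ignored.
#'
#' @param path File path.
#' @return List with `exchangeabilities` (20x20 symmetric matrix) and
#'   `frequencies` (length-20 numeric), suitable for [substitution_model()].
#' @export
read_paml_matrix <- function(path) {
  txt <- readLines(path, warn = FALSE)
  nums <- suppressWarnings(as.numeric(unlist(strsplit(trimws(txt), "\\s+"))))
  nums <- nums[!is.na(nums)]
  if (length(nums) < 210L) {
    stop("PAML matrix file must contain 190 exchangeabilities and 20 ",
         "frequencies", call. = FALSE)
  }
  tri <- nums[seq_len(190L)]
  freqs <- nums[191:210]
  list(exchangeabilities = lower_tri_to_sym(tri), frequencies = freqs)
}
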