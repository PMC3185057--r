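.check_incidence <- function(x) {
  stopifnot(is.matrix(x), all(x %in% c(0L, 1L)))
  if (!is.null(rownames(x))) stopifnot(!anyDuplicated(rownames(x)))
  if (!is.null(colnames(x))) stopifnot(!anyDuplicated(colnames(x)))
  invisible(x)
}

#' Sample-based rarefaction (species accumulation) with randomization
#'
#' Estimates the accumulation curve of distinct taxa as sampling units
#' (dung piles or feeding sites) are added in random order. For each
#' number of samples t = 1..m, the mean and standard deviation of the
#' accumulated richness over `R` uniformly random sample orderings
#' (permutations, without replacement) is reported. At t = m every
#' ordering has seen every sample, so the mean equals the observed
#' richness and the SD is zero.
#'
#' @param x binary incidence matrix, samples in rows, taxa in columns.
#' @param R number of randomized orderings (default 500).
#' @param seed integer seed making the curve reproducible.
#' @return data frame of class `accumulation_curve` with columns `t`,
#'   `mean`, `sd`.
#' @seealso [mao_tau()] for the closed-form expectation.
#' @export
rarefy_incidence <- function(x, R = 500L, seed = NULL) {
  .check_incidence(x)
  if (R <= 0L) stop("R must be positive")
  m <- nrow(x)
  stopifnot(m >= 1L)
  if (!is.null(seed)) set.seed(seed)
  # first-detection position of each taxon under a permutation gives the
  # whole accumulation profile in one pass
  acc <- matrix(0L, nrow = R, ncol = m)
  occupied <- x > 0L
  for (r in seq_len(R)) {
    perm <- sample.int(m)
    first <- apply(occupied[perm, , drop = FALSE], 2L, function(col) {
      w <- which(col)
      if (length(w)) w[1L] else NA_integer_
    })
    first <- first[!is.na(first)]
    counts <- tabulate(first, nbins = m)
    acc[r, ] <- cumsum(counts)
  }
  out <- data.frame(t = seq_len(m),
                    mean = colMeans(acc),
                    sd = apply(acc, 2L, stats::sd))
  class(out) <- c("accumulation_curve", class(out))
  out
}

#' Closed-form expected accumulation curve (Mao Tau)
#'
#' The exact expectation of the randomized accumulation curve: with m
#' samples and taxon i present in m_i of them,
#' \deqn{E[S(t)] = S_{obs} - \sum_i \binom{m - m_i}{t} / \binom{m}{t}.}
#' Used as the analytic reference for [rarefy_incidence()].
#'
#' @param x binary incidence matrix.
#' @return numeric vector of length m with the expected richness at
#'   each t.
#' @export
mao_tau <- function(x) {
  .check_incidence(x)
  m <- nrow(x)
  mi <- colSums(x > 0L)
  mi <- mi[mi > 0L]
  s_obs <- length(mi)
  vapply(seq_len(m), function(t) {
    s_obs - sum(exp(lchoose(m - mi, t) - lchoose(m, t)))
  }, numeric(1L))
}

#' Chao2 incidence-based richness estimate with log-normal CI
#'
#' Nonparametric lower-bound estimate of total richness from incidence
#' data, driven by the uniques Q1 (taxa seen in exactly one sample) and
#' duplicates Q2 (exactly two). The classic form
#' \deqn{\hat S = S_{obs} + \frac{m-1}{m}\,\frac{Q_1^2}{2 Q_2}}
#' is used when Q2 > 0 and the bias-corrected form
#' \deqn{\hat S = S_{obs} + \frac{m-1}{m}\,\frac{Q_1 (Q_1 - 1)}{2 (Q_2 + 1)}}
#' when Q2 = 0 (the EstimateS convention); both are exposed explicitly
#' through `variant`. The 95% interval uses the log-normal method on the
#' estimated excess \eqn{\hat S - S_{obs}} (Chao 1987), which keeps the
#' lower bound at or above the observed richness.
#'
#' @param x binary incidence matrix (samples x taxa), or `NULL` when the
#'   summary statistics are supplied directly.
#' @param S_obs,m,Q1,Q2 summary statistics, derived from `x` when given.
#' @param variant `"auto"` (classic unless Q2 = 0), `"classic"` or
#'   `"bias_corrected"`.
#' @param small_sample include the (m-1)/m correction factor (EstimateS
#'   convention); disabling it drops the factor from both forms.
#' @param conf confidence level for the interval.
#' @return list of class `chao2_estimate`: `S_obs`, `m`, `Q1`, `Q2`,
#'   `S_chao2`, `se`, `ci_low`, `ci_high`, `variant`.
#' @export
chao2 <- function(x = NULL, S_obs = NULL, m = NULL, Q1 = NULL, Q2 = NULL,
                  variant = c("auto", "classic", "bias_corrected"),
                  small_sample = TRUE, conf = 0.95) {
  variant <- match.arg(variant)
  if (!is.null(x)) {
    .check_incidence(x)
    m <- nrow(x)
    freq <- colSums(x > 0L)
    S_obs <- sum(freq > 0L)
    Q1 <- sum(freq == 1L)
    Q2 <- sum(freq == 2L)
  }
  stopifnot(!is.null(S_obs), !is.null(m), !is.null(Q1), !is.null(Q2),
            m >= 1L, Q1 >= 0, Q2 >= 0, Q1 + Q2 <= S_obs || S_obs == 0)
  if (S_obs == 0L) {
    return(structure(list(S_obs = 0L, m = m, Q1 = 0L, Q2 = 0L,
                          S_chao2 = 0, se = 0, ci_low = 0, ci_high = 0,
                          variant = "degenerate"),
                     class = "chao2_estimate"))
  }
  A <- if (small_sample) (m - 1) / m else 1
  used <- if (variant == "auto") {
    if (Q2 > 0) "classic" else "bias_corrected"
  } else variant
  if (used == "classic" && Q2 == 0) used <- "bias_corrected"
  if (used == "classic") {
    est <- S_obs + A * Q1^2 / (2 * Q2)
    r <- Q1 / Q2
    v <- Q2 * (A * r^2 / 2 + A^2 * r^3 + A^2 * r^4 / 4)
  } else {
    est <- S_obs + A * Q1 * (Q1 - 1) / (2 * (Q2 + 1))
    v <- A * Q1 * (Q1 - 1) / (2 * (Q2 + 1)) +
      A^2 * Q1 * (2 * Q1 - 1)^2 / (4 * (Q2 + 1)^2) +
      if (est > 0) A^2 * Q1^2 * Q2 * (Q1 - 1)^2 / (4 * (Q2 + 1)^4) else 0
  }
  v <- max(v, 0)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  T_excess <- est - S_obs
  if (T_excess > 0 && v > 0) {
    K <- exp(z * sqrt(log(1 + v / T_excess^2)))
    ci_low <- S_obs + T_excess / K
    ci_high <- S_obs + T_excess * K
  } else {
    ci_low <- ci_high <- est
  }
  structure(list(S_obs = S_obs, m = m, Q1 = Q1, Q2 = Q2,
                 S_chao2 = est, se = sqrt(v),
                 ci_low = ci_low, ci_high = ci_high, variant = used),
            class = "chao2_estimate")
}

#' @export
print.chao2_estimate <- function(x, ...) {
  cat(sprintf(
    "Chao2 (%s): S_obs = %d, S_est = %.1f [%.1f, %.1f]  (m = %d, Q1 = %d, Q2 = %d)\n",
    x$variant, x$S_obs, x$S_chao2, x$ci_low, x$ci_high, x$m, x$Q1, x$Q2))
  invisible(x)
}

#' Read / write incidence matrices as TSV
#'
#' Rows are samples, columns taxa, cells 0/1; the first column holds the
#' sample id.
#'
#' @param path file path.
#' @return [read_incidence()]: binary integer matrix.
#' @export
read_incidence <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  .check_incidence(m)
  m
}

#' @rdname read_incidence
#' @param x binary incidence matrix to write.
#' @export
write_incidence <- function(x, path) {
  .check_incidence(x)
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
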