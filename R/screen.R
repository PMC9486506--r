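#' Normalized drug response of a strain
#'
#' Growth rate in the presence of the drug divided by the strain's own
#' drug-free growth rate. Values above 1 (drug-enhanced growth) are allowed
#' and not clipped. Strains with non-positive drug-free growth have an
#' undefined response and return `NA`.
#'
#' @param g_drug Growth rate under drug, 1/h (vectorized).
#' @param g0 Drug-free growth rate, 1/h.
#' @return Dimensionless response(s); `NA` where `g0 <= 0`.
#' @export
normalized_response <- function(g_drug, g0) {
  stopifnot(is.numeric(g_drug), is.numeric(g0))
  out <- ifelse(g0 > 0, g_drug / g0, NA_real_)
  if (any(g0 <= 0)) {
    warning(sprintf("%d strain(s) with non-positive drug-free growth excluded",
                    sum(g0 <= 0)))
  }
  out
}

#' Spearman correlation with bootstrap standard error
#'
#' Spearman's rank correlation (average ranks for ties) between two paired
#' vectors, with a standard error estimated as the standard deviation of the
#' coefficient over `n_boot` resamples of the pairs with replacement. Pairs
#' with missing values are excluded listwise and counted.
#'
#' @param x,y Paired numeric vectors (e.g. drug-free growth rate and
#'   normalized response per strain).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return An object of class `correlation_result` with `rho_s`,
#'   `bootstrap_se`, `ci95` (percentile bootstrap interval), `n_boot`,
#'   `seed`, `n_strains`, `n_excluded`.
#' @export
#' @examples
#' spearman_bootstrap(1:20, 20:1 + rnorm(20), n_boot = 200, seed = 7)
spearman_bootstrap <- function(x, y, n_boot = 1000, seed) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            n_boot >= 2, !missing(seed))
  ok <- is.finite(x) & is.finite(y)
  n_excluded <- sum(!ok)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("constant vector: Spearman correlation undefined")
  }
  rho <- stats::cor(x, y, method = "spearman")
  boot <- local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(x[i])) < 2L || length(unique(y[i])) < 2L) {
        return(NA_real_)
      }
      stats::cor(x[i], y[i], method = "spearman")
    }, numeric(1))
  })
  boot <- boot[is.finite(boot)]
  structure(
    list(rho_s = rho,
         bootstrap_se = stats::sd(boot),
         ci95 = unname(stats::quantile(boot, c(0.025, 0.975))),
         n_boot = n_boot, seed = seed,
         n_strains = n, n_excluded = n_excluded),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho_s = %.3f +/- %.3f (bootstrap SE, %d resamples)\n",
              x$rho_s, x$bootstrap_se, x$n_boot))
  cat(sprintf("  95%% bootstrap CI [%.3f, %.3f]; n = %d strains (%d excluded); seed %d\n",
              x$ci95[1], x$ci95[2], x$n_strains, x$n_excluded, x$seed))
  invisible(x)
}

#' Screen correlation analysis on a strain table
#'
#' Computes per-strain normalized responses and the Spearman-with-bootstrap
#' correlation between drug-free growth rate and response.
#'
#' @param strains Data frame with columns `g0` and `g_drug` (1/h); an
#'   optional precomputed `response` column is recomputed.
#' @param n_boot,seed Passed to [spearman_bootstrap()].
#' @return A list with `strains` (table with `response` added) and
#'   `correlation` (a `correlation_result`).
#' @export
screen_correlate <- function(strains, n_boot = 1000, seed) {
  stopifnot(is.data.frame(strains), all(c("g0", "g_drug") %in% names(strains)))
  strains$response <- suppressWarnings(
    normalized_response(strains$g_drug, strains$g0)
  )
  list(strains = strains,
       correlation = spearman_bootstrap(strains$g0, strains$response,
                                        n_boot = n_boot, seed = seed))
}
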