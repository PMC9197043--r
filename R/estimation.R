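# Frequency estimation from genotyped samples with percentile-bootstrap
# confidence intervals (default 68% mass, i.e. 16th/84th percentiles, as
# used for cage-trial transgene-frequency trajectories).

new_freq_estimate <- function(point, ci, n, level, reps) {
  structure(list(point = point, ci_low = ci[1L], ci_high = ci[2L],
                 n = n, level = level, bootstrap_reps = reps),
            class = "freq_estimate")
}

#' @export
print.freq_estimate <- function(x, ...) {
  cat(sprintf("%.4f  [%.4f, %.4f]  (%d%% bootstrap CI, n = %d, B = %d)\n",
              x$point, x$ci_low, x$ci_high, round(100 * x$level), x$n,
              x$bootstrap_reps))
  invisible(x)
}

boot_percentile_ci <- function(stats, level) {
  alpha <- (1 - level) / 2
  unname(stats::quantile(stats, c(alpha, 1 - alpha), names = FALSE))
}

#' Carrier frequency of a construct with bootstrap CI
#'
#' Point estimate is carriers / n. The interval is a percentile bootstrap
#' over individuals (rows resampled with replacement; for a 0/1 carrier flag
#' the bootstrap count is drawn directly as Binomial(n, carriers/n), which
#' is the exact resampling distribution).
#'
#' @param sample A genotyping sample: either a data frame with one 0/1
#'   carrier column per construct (rows flagged `is_control == 1` are
#'   excluded from estimation) or a 0/1 vector of carrier flags.
#' @param construct Column name when `sample` is a data frame.
#' @param level Confidence mass (default 0.68, the 16th/84th percentiles).
#' @param B Bootstrap replicates (default 1000).
#' @return A `freq_estimate`.
#' @export
carrier_frequency <- function(sample, construct = NULL, level = 0.68, B = 1000L) {
  flags <- extract_flags(sample, construct)
  n <- length(flags)
  if (!n) stop("empty sample", call. = FALSE)
  p <- mean(flags)
  boot <- stats::rbinom(B, n, p) / n
  new_freq_estimate(p, boot_percentile_ci(boot, level), n, level, B)
}

#' Allele frequency at a locus with bootstrap CI
#'
#' Counts allele copies over 2n chromosomes; the bootstrap resamples
#' individuals (copy counts) with replacement.
#'
#' @param genotypes Either a character matrix/data.frame with two allele
#'   columns (one individual per row), or an integer vector of per-individual
#'   copy counts (0, 1 or 2).
#' @param allele Allele class to count (ignored when `genotypes` is already
#'   a copy-count vector).
#' @inheritParams carrier_frequency
#' @return A `freq_estimate`.
#' @export
allele_frequency <- function(genotypes, allele = NULL, level = 0.68, B = 1000L) {
  if (is.numeric(genotypes)) {
    copies <- as.integer(genotypes)
  } else {
    if (is.null(allele)) stop("`allele` is required for genotype input", call. = FALSE)
    m <- as.matrix(genotypes)
    if (ncol(m) != 2L) stop("genotype input needs exactly two allele columns", call. = FALSE)
    copies <- rowSums(m == allele)
  }
  n <- length(copies)
  if (!n) stop("empty sample", call. = FALSE)
  if (any(copies < 0 | copies > 2)) stop("copy counts must be 0, 1 or 2", call. = FALSE)
  p <- sum(copies) / (2 * n)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  boot <- matrix(copies[idx], nrow = B)
  boot <- rowSums(boot) / (2 * n)
  new_freq_estimate(p, boot_percentile_ci(boot, level), n, level, B)
}

extract_flags <- function(sample, construct) {
  if (is.data.frame(sample)) {
    if ("is_control" %in% names(sample)) {
      sample <- sample[sample$is_control == 0, , drop = FALSE]
    }
    if (is.null(construct)) stop("`construct` is required for data-frame input",
                                 call. = FALSE)
    if (!construct %in% names(sample)) {
      stop("no column for construct ", construct, call. = FALSE)
    }
    flags <- sample[[construct]]
  } else {
    flags <- sample
  }
  flags <- as.integer(flags)
  if (any(is.na(flags)) || any(!flags %in% c(0L, 1L))) {
    stop("carrier flags must be 0/1", call. = FALSE)
  }
  flags
}
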