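# Single-pair cross assays: simulate progeny screens of transgenic parents
# crossed to wild type, and the associated transmission / fertility
# statistics (one-sample t on per-cross proportions, Pearson chi-square on
# insemination contingency tables, Welch t on offspring counts, and
# homing-efficiency estimation from pooled transmission).

#' Clutch-size model for single crosses
#'
#' Truncated-normal larval clutch sizes (default mean 50.9, sd 17.9,
#' minimum 20, matching screened clutches), sampled by inverse-CDF.
#'
#' @param mean,sd Normal parameters before truncation.
#' @param min Lower truncation bound.
#' @return A function `n -> integer vector` of clutch sizes.
#' @export
clutch_model <- function(mean = 50.9, sd = 17.9, min = 20) {
  force(mean); force(sd); force(min)
  function(n) {
    lo <- stats::pnorm((min - mean) / sd)
    u <- stats::runif(n, lo, 1)
    as.integer(round(mean + sd * stats::qnorm(u)))
  }
}

#' Simulate single-pair crosses of a transgenic parent to wild type
#'
#' Each cross draws a clutch size and, per construct, a Binomial(clutch,
#' transmission probability) count of marked progeny, where the transmission
#' probability is the analytic gamete probability of the construct for the
#' transgenic parent (the wild-type mate contributes no constructs). Parents
#' whose driver-locus genotype is sterile (females: fertility predicate;
#' males: zero fecundity weight) yield zero-progeny records flagged sterile.
#'
#' @param sex Sex of the transgenic parent.
#' @param g Parent [genotype()].
#' @param n_crosses Number of independent single crosses.
#' @param model A [drive_model()].
#' @param fertility A [fertility_model()].
#' @param clutch A clutch-size function from [clutch_model()].
#' @return Data frame: cross, parent_sex, parent_genotype (driver-locus
#'   key), total, sterile, and one `marked_<locus>` count column per locus.
#' @export
simulate_crosses <- function(sex = c("female", "male"), g, n_crosses,
                             model = default_drive_model(),
                             fertility = fertility_model(),
                             clutch = clutch_model()) {
  sex <- match.arg(sex)
  validate_genotype(g, model)
  drv <- driver_locus(model)
  key <- pair_key(g[[drv]])
  sterile <- if (sex == "female") {
    !female_is_fertile(g[[drv]], fertility)
  } else {
    male_weights(g[[drv]], fertility)[["fecundity"]] == 0
  }
  loci <- locus_names(model)
  out <- data.frame(cross = seq_len(n_crosses),
                    parent_sex = rep(sex, n_crosses),
                    parent_genotype = rep(key, n_crosses),
                    total = integer(n_crosses),
                    sterile = rep(sterile, n_crosses))
  marked <- matrix(0L, n_crosses, length(loci),
                   dimnames = list(NULL, paste0("marked_", loci)))
  if (!sterile && n_crosses > 0) {
    out$total <- clutch(n_crosses)
    dist <- gamete_distribution(g, model, sex)
    for (i in seq_along(loci)) {
      cons <- construct_class(model$loci[[loci[i]]])
      p <- dist[[loci[i]]][cons]
      if (is.na(p)) p <- 0
      marked[, i] <- stats::rbinom(n_crosses, out$total, p)
    }
  }
  cbind(out, as.data.frame(marked))
}

#' Pooled and per-cross transmission proportions
#'
#' @param records Cross data frame from [simulate_crosses()] (or the same
#'   schema read from CSV).
#' @param construct Locus whose `marked_<locus>` column is scored.
#' @return List with `pooled` (sum marked / sum total), `per_cross`
#'   (proportion per cross with nonzero total), `n_progeny`, `n_crosses`.
#' @export
transmission_rate <- function(records, construct) {
  col <- paste0("marked_", construct)
  if (!col %in% names(records)) stop("no marked column for ", construct, call. = FALSE)
  keep <- records$total > 0
  if (!any(keep)) stop("no crosses with progeny", call. = FALSE)
  total <- sum(records$total[keep])
  marked <- sum(records[[col]][keep])
  list(pooled = marked / total,
       per_cross = records[[col]][keep] / records$total[keep],
       n_progeny = total, n_crosses = sum(keep))
}

#' One-sample t-test on per-cross proportions
#'
#' Two-sided test of the mean per-cross transmission proportion against
#' `mu0` (default 0.5, Mendelian expectation). Crosses are weighted equally.
#' Zero-variance input is flagged degenerate instead of erroring.
#'
#' @param x Per-cross proportions (length >= 2).
#' @param mu0 Null mean.
#' @return List with `t`, `df`, `p`, `mean`, `degenerate`.
#' @export
one_sample_t <- function(x, mu0 = 0.5) {
  if (length(x) < 2L) stop("need at least two crosses", call. = FALSE)
  if (stats::sd(x) == 0) {
    d <- mean(x) - mu0
    return(list(t = if (d == 0) 0 else sign(d) * Inf, df = length(x) - 1L,
                p = if (d == 0) 1 else 0, mean = mean(x), degenerate = TRUE))
  }
  ht <- stats::t.test(x, mu = mu0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = mean(x), degenerate = FALSE)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Without Yates continuity correction by default (the convention used for
#' the insemination-rate comparison); set `continuity_correction = TRUE`
#' for the corrected statistic.
#'
#' @param tab 2x2 matrix of nonnegative counts (group x outcome).
#' @param continuity_correction Apply Yates correction.
#' @return List with `X2`, `df`, `p`.
#' @export
chi_square_2x2 <- function(tab, continuity_correction = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0)) {
    stop("`tab` must be a 2x2 matrix of nonnegative counts", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square statistic undefined: zero margin", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = continuity_correction))
  list(X2 = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t with Satterthwaite degrees of freedom, two-sided.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least two observations", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Estimate homing efficiency from cross records
#'
#' Inverts the transmission closed form for a construct/S heterozygous
#' parent: transmission = (1 + e) / 2, so e_hat = 2 * pooled - 1, clipped to
#' `[0, 1]`. The CI propagates a Wilson score interval on the pooled
#' proportion.
#'
#' @inheritParams transmission_rate
#' @param level Confidence level of the Wilson interval.
#' @return List with `e_hat`, `ci_low`, `ci_high`, `pooled`, `n_progeny`.
#' @export
estimate_homing_efficiency <- function(records, construct, level = 0.95) {
  tr <- transmission_rate(records, construct)
  marked <- round(tr$pooled * tr$n_progeny)
  ci_p <- suppressWarnings(
    stats::prop.test(marked, tr$n_progeny, conf.level = level,
                     correct = FALSE)$conf.int)
  clip01 <- function(x) pmin(1, pmax(0, x))
  if (tr$pooled < 0.5) {
    warning("pooled transmission below 0.5; homing efficiency clipped to 0")
  }
  list(e_hat = clip01(2 * tr$pooled - 1),
       ci_low = clip01(2 * ci_p[1L] - 1), ci_high = clip01(2 * ci_p[2L] - 1),
       pooled = tr$pooled, n_progeny = tr$n_progeny)
}
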