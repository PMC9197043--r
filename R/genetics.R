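# Core genetics: allele classes, germline cut/repair model, fertility.
#
# Alleles at every modelled locus are one of five classes:
#   S  - cleavage-susceptible wild type (the only cuttable class)
#   D  - autonomous driver construct (Cas9 + own gRNA); driver locus only
#   E  - non-autonomous effector/payload construct (gRNA only); payload loci only
#   R1 - cleavage-resistant, host-gene function preserved
#   R2 - cleavage-resistant, host-gene function disrupted

ALLELE_CLASSES <- c("S", "D", "E", "R1", "R2")

#' Germline cut/repair parameters for one locus
#'
#' Parametrises what happens, pre-meiotically, to a cleavage-susceptible (S)
#' allele in the germline of an individual in which the locus is actively
#' targeted. A cut occurs with probability `p_cut`; given a cut,
#' homology-directed repair copies the resident construct with probability
#' `p_hdr` (homing), otherwise end-joining produces a resistant allele which
#' preserves host-gene function (R1) with probability `p_r1` and disrupts it
#' (R2) otherwise. The net construct transmission from a construct/S
#' heterozygote is (1 + p_cut * p_hdr) / 2, so the homing efficiency commonly
#' reported from cross data is e = p_cut * p_hdr.
#'
#' @param p_cut Probability in `[0,1]` that an S allele is cleaved.
#' @param p_hdr Probability in `[0,1]` of homing conversion given a cut.
#' @param p_r1 Probability in `[0,1]` that an end-joined repair yields R1.
#' @return An object of class `germline_params`.
#' @export
germline_params <- function(p_cut = 0.98, p_hdr = 0.92 / 0.98, p_r1 = 1 / 3) {
  for (p in c(p_cut = p_cut, p_hdr = p_hdr, p_r1 = p_r1)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("germline probabilities must be single values in [0, 1]", call. = FALSE)
    }
  }
  structure(list(p_cut = p_cut, p_hdr = p_hdr, p_r1 = p_r1),
            class = "germline_params")
}

#' Construct germline parameters from a net homing efficiency
#'
#' Convenience inverse of the decomposition e = p_cut * p_hdr: fixes `p_cut`
#' and solves for `p_hdr`.
#'
#' @param e Net homing efficiency in `[0,1]` (excess transmission is e/2).
#' @param p_cut Cut probability; must satisfy `p_cut >= e`.
#' @param p_r1 R1 share of end-joined repairs.
#' @return A `germline_params` object with `p_cut * p_hdr == e`.
#' @export
germline_from_efficiency <- function(e, p_cut = 0.98, p_r1 = 1 / 3) {
  if (e > p_cut) stop("homing efficiency cannot exceed p_cut", call. = FALSE)
  germline_params(p_cut = p_cut, p_hdr = if (p_cut > 0) e / p_cut else 0,
                  p_r1 = p_r1)
}

#' Specification of one modelled locus
#'
#' @param name Locus identifier (e.g. `"zpg"`, `"cp"`).
#' @param role `"driver"` (hosts the autonomous Cas9 construct D) or
#'   `"payload"` (hosts a non-autonomous gRNA-only construct E).
#' @param germline Default `germline_params` for both sexes.
#' @param germline_female,germline_male Optional sex-specific overrides; the
#'   default model uses identical parameters in both sexes.
#' @param maternal Optional embryo-stage cutting by maternally deposited
#'   Cas9: a list with `p_cut` and `p_r1` applied to susceptible alleles of
#'   offspring whose mother carried the driver; disabled (`NULL`) by
#'   default.
#' @return An object of class `locus_spec`.
#' @export
locus_spec <- function(name, role = c("driver", "payload"),
                       germline = germline_params(),
                       germline_female = NULL, germline_male = NULL,
                       maternal = NULL) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!inherits(germline, "germline_params")) {
    stop("`germline` must be built with germline_params()", call. = FALSE)
  }
  gl <- list(
    female = if (is.null(germline_female)) germline else germline_female,
    male = if (is.null(germline_male)) germline else germline_male
  )
  if (!is.null(maternal)) {
    maternal <- list(p_cut = maternal$p_cut %||% 0,
                     p_r1 = maternal$p_r1 %||% (1 / 3))
  }
  structure(list(name = name, role = role, germline = gl, maternal = maternal),
            class = "locus_spec")
}

#' Multi-locus drive model
#'
#' Collects the per-locus specifications. Exactly one locus must carry the
#' driver role; any number of payload loci are allowed. The gRNA source rule
#' is implied by the role: the driver construct (D) supplies its own gRNA,
#' while each payload locus is targeted only when a resident payload
#' construct (E) at that same locus supplies the gRNA and a D allele anywhere
#' in the genome supplies Cas9.
#'
#' @param ... `locus_spec` objects.
#' @return An object of class `drive_model`.
#' @export
drive_model <- function(...) {
  loci <- list(...)
  if (length(loci) == 1L && is.list(loci[[1L]]) && !inherits(loci[[1L]], "locus_spec")) {
    loci <- loci[[1L]]
  }
  if (!length(loci) || !all(vapply(loci, inherits, logical(1), "locus_spec"))) {
    stop("drive_model() takes one or more locus_spec objects", call. = FALSE)
  }
  nm <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate locus names", call. = FALSE)
  names(loci) <- nm
  n_driver <- sum(vapply(loci, `[[`, character(1), "role") == "driver")
  if (n_driver != 1L) {
    stop("a drive model requires exactly one driver locus", call. = FALSE)
  }
  structure(list(loci = loci), class = "drive_model")
}

#' @export
print.drive_model <- function(x, ...) {
  cat("<drive_model>", length(x$loci), "loci\n")
  for (l in x$loci) {
    g <- l$germline$male
    cat(sprintf("  %-8s %-7s e(male) = %.3f  p_cut = %.3f  p_r1 = %.3f\n",
                l$name, l$role, g$p_cut * g$p_hdr, g$p_cut, g$p_r1))
  }
  invisible(x)
}

#' @rdname drive_model
#' @export
locus_names <- function(model) names(model$loci)

#' @rdname drive_model
#' @export
driver_locus <- function(model) {
  nm <- locus_names(model)
  nm[vapply(model$loci, `[[`, character(1), "role") == "driver"]
}

#' @rdname drive_model
#' @export
payload_loci <- function(model) setdiff(locus_names(model), driver_locus(model))

construct_class <- function(spec) if (spec$role == "driver") "D" else "E"

#' Default four-locus model
#'
#' One driver locus (`zpg`, homing efficiency 0.92 as measured from male
#' driver/susceptible transmission) and three payload loci (`cp`, `aper1`,
#' `ap2`, homing efficiency 0.98 as measured from female payload
#' transmission with Cas9 supplied in trans). The default decomposition uses
#' p_cut = 0.98 at every locus and p_r1 = 1/3 for end-joined repairs.
#'
#' @param driver_e,payload_e Net homing efficiencies.
#' @param p_cut Cut probability shared by all loci.
#' @param p_r1 R1 share of end-joined repairs.
#' @return A `drive_model` with loci `zpg`, `cp`, `aper1`, `ap2`.
#' @export
default_drive_model <- function(driver_e = 0.92, payload_e = 0.98,
                                p_cut = 0.98, p_r1 = 1 / 3) {
  drive_model(
    locus_spec("zpg", "driver", germline_from_efficiency(driver_e, p_cut, p_r1)),
    locus_spec("cp", "payload", germline_from_efficiency(payload_e, p_cut, p_r1)),
    locus_spec("aper1", "payload", germline_from_efficiency(payload_e, p_cut, p_r1)),
    locus_spec("ap2", "payload", germline_from_efficiency(payload_e, p_cut, p_r1))
  )
}

check_alleles <- function(x) {
  bad <- setdiff(unique(as.character(x)), ALLELE_CLASSES)
  if (length(bad)) {
    stop("unknown allele class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Build a multi-locus diploid genotype
#'
#' @param ... One length-2 character vector of allele classes per locus,
#'   named by locus.
#' @return A named list of unordered allele pairs, class `genotype`.
#' @examples
#' genotype(zpg = c("D", "S"), cp = c("E", "S"))
#' @export
genotype <- function(...) {
  g <- list(...)
  if (is.null(names(g)) || any(!nzchar(names(g)))) {
    stop("every locus in a genotype must be named", call. = FALSE)
  }
  for (pair in g) {
    if (length(pair) != 2L) stop("each locus carries exactly two alleles", call. = FALSE)
    check_alleles(pair)
  }
  structure(g, class = "genotype")
}

validate_genotype <- function(g, model) {
  missing <- setdiff(locus_names(model), names(g))
  if (length(missing)) {
    stop("genotype missing loci: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  drv <- driver_locus(model)
  for (nm in locus_names(model)) {
    pair <- g[[nm]]
    check_alleles(pair)
    if (nm == drv && "E" %in% pair) {
      stop("payload construct (E) cannot occur at the driver locus", call. = FALSE)
    }
    if (nm != drv && "D" %in% pair) {
      stop("driver construct (D) cannot occur at a payload locus", call. = FALSE)
    }
  }
  invisible(g)
}

pair_key <- function(pair) paste(sort(pair), collapse = "/")

#' Genotype-specific fertility model at the driver locus
#'
#' Fitness in the cage model acts through the driver-locus genotype only.
#' Females are fertile or sterile (the driver dominantly sterilises females
#' paired with a susceptible allele, and resistant R2/R2 null homozygotes of
#' either sex are sterile); males carry relative mating-success and
#' offspring-output weights. Defaults:
#'
#' * female fertility: S/S, S/R1, R1/R1, S/R2, R1/R2, D/R1 fertile;
#'   D/S, D/D, D/R2, R2/R2 sterile.
#' * male weights: 1 for every fertile genotype except D/D
#'   (mating 0.20/0.36 ~= 0.556, fecundity 26/74 ~= 0.351) and R2/R2 (0).
#'
#' @param female_fertile Named logical vector keyed by sorted allele pair
#'   (e.g. `"D/S"`); entries override the defaults.
#' @param male_mating,male_fecundity Named nonnegative numeric overrides,
#'   same keying.
#' @return An object of class `fertility_model`.
#' @export
fertility_model <- function(female_fertile = NULL, male_mating = NULL,
                            male_fecundity = NULL) {
  ff <- c("D/D" = FALSE, "D/R1" = TRUE, "D/R2" = FALSE, "D/S" = FALSE,
          "R1/R1" = TRUE, "R1/R2" = TRUE, "R1/S" = TRUE,
          "R2/R2" = FALSE, "R2/S" = TRUE, "S/S" = TRUE)
  mm <- c("D/D" = 0.20 / 0.36, "D/R1" = 1, "D/R2" = 1, "D/S" = 1,
          "R1/R1" = 1, "R1/R2" = 1, "R1/S" = 1,
          "R2/R2" = 0, "R2/S" = 1, "S/S" = 1)
  mf <- c("D/D" = 26 / 74, "D/R1" = 1, "D/R2" = 1, "D/S" = 1,
          "R1/R1" = 1, "R1/R2" = 1, "R1/S" = 1,
          "R2/R2" = 0, "R2/S" = 1, "S/S" = 1)
  override <- function(base, user, what) {
    if (is.null(user)) return(base)
    bad <- setdiff(names(user), names(base))
    if (length(bad)) stop("unknown ", what, " genotype key(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    base[names(user)] <- user
    base
  }
  mm <- override(mm, male_mating, "male_mating")
  mf <- override(mf, male_fecundity, "male_fecundity")
  if (any(mm < 0) || any(mf < 0)) {
    stop("male weights must be nonnegative", call. = FALSE)
  }
  structure(list(female_fertile = override(ff, female_fertile, "female_fertile"),
                 male_mating = mm, male_fecundity = mf),
            class = "fertility_model")
}

fertility_lookup <- function(table, pair) {
  check_alleles(pair)
  key <- pair_key(pair)
  if (!key %in% names(table)) {
    stop("no fertility entry for driver genotype ", key, call. = FALSE)
  }
  unname(table[key])
}

#' Is a female of the given driver-locus genotype fertile?
#'
#' @param pair Character vector of the two driver-locus alleles, or a
#'   `genotype` (in which case `locus` selects the driver locus).
#' @param fertility A `fertility_model`.
#' @param locus Driver locus name, used when `pair` is a full genotype.
#' @return Logical scalar.
#' @examples
#' female_is_fertile(c("D", "S")) # FALSE: dominant sterilisation
#' female_is_fertile(c("D", "R1")) # TRUE: resistant partner restores fertility
#' @export
female_is_fertile <- function(pair, fertility = fertility_model(), locus = "zpg") {
  if (inherits(pair, "genotype")) pair <- pair[[locus]]
  fertility_lookup(fertility$female_fertile, pair)
}

#' @rdname female_is_fertile
#' @export
male_weights <- function(pair, fertility = fertility_model(), locus = "zpg") {
  if (inherits(pair, "genotype")) pair <- pair[[locus]]
  c(mating = fertility_lookup(fertility$male_mating, pair),
    fecundity = fertility_lookup(fertility$male_fecundity, pair))
}

# Which loci of this genotype are actively targeted in the germline?
# Active at L iff: a Cas9 source (D) anywhere in the genome, a gRNA source
# per the locus role (D at the driver locus, E at the payload locus itself),
# and at least one cuttable S allele at L.
locus_active <- function(g, model) {
  has_cas9 <- any(vapply(locus_names(model), function(nm) "D" %in% g[[nm]],
                         logical(1)))
  vapply(locus_names(model), function(nm) {
    spec <- model$loci[[nm]]
    grna <- construct_class(spec) %in% g[[nm]]
    has_cas9 && grna && ("S" %in% g[[nm]])
  }, logical(1))
}

# Pre-meiotic fate distribution of a single allele at one locus.
allele_fate_dist <- function(allele, active, gp, construct) {
  if (!active || allele != "S") {
    out <- 1
    names(out) <- allele
    return(out)
  }
  out <- c(gp$p_cut * gp$p_hdr,
           gp$p_cut * (1 - gp$p_hdr) * gp$p_r1,
           gp$p_cut * (1 - gp$p_hdr) * (1 - gp$p_r1),
           1 - gp$p_cut)
  names(out) <- c(construct, "R1", "R2", "S")
  out[out > 0 | names(out) == "S"]
}

#' Exact gamete distribution of a genotype
#'
#' Analytic per-locus probability of each allele class appearing in a gamete,
#' under the germline model: each S allele at an actively targeted locus is
#' converted to the resident construct with probability p_cut * p_hdr,
#' becomes R1 with p_cut (1-p_hdr) p_r1, R2 with p_cut (1-p_hdr) (1-p_r1),
#' and stays S otherwise; one allele of the (post-modification) pair is then
#' drawn uniformly. Loci segregate independently, so the joint gamete
#' distribution is the product over loci.
#'
#' @param g A `genotype` covering all loci of `model`.
#' @param model A `drive_model`.
#' @param sex `"female"` or `"male"` (selects sex-specific germline
#'   parameters where configured).
#' @return Named list, one named probability vector per locus (each sums
#'   to 1).
#' @examples
#' m <- default_drive_model()
#' g <- genotype(zpg = c("D", "S"), cp = c("S", "S"),
#'               aper1 = c("S", "S"), ap2 = c("S", "S"))
#' gamete_distribution(g, m, "male")$zpg["D"] # 0.96 when e = 0.92
#' @export
gamete_distribution <- function(g, model, sex = c("female", "male")) {
  sex <- match.arg(sex)
  validate_genotype(g, model)
  active <- locus_active(g, model)
  out <- lapply(locus_names(model), function(nm) {
    spec <- model$loci[[nm]]
    gp <- spec$germline[[sex]]
    cons <- construct_class(spec)
    pair <- g[[nm]]
    d1 <- allele_fate_dist(pair[1L], active[[nm]], gp, cons)
    d2 <- allele_fate_dist(pair[2L], active[[nm]], gp, cons)
    classes <- union(names(d1), names(d2))
    p <- 0.5 * (ifelse(classes %in% names(d1), d1[classes], 0) +
                  ifelse(classes %in% names(d2), d2[classes], 0))
    names(p) <- classes
    p[order(match(classes, ALLELE_CLASSES))]
  })
  names(out) <- locus_names(model)
  out
}

#' Draw one gamete from an individual
#'
#' Monte Carlo realisation of [gamete_distribution()]: per locus, one of the
#' two resident alleles is picked uniformly and, if it is a cuttable S allele
#' at an actively targeted locus, its germline fate is sampled. Uses the
#' current R random-number stream.
#'
#' @inheritParams gamete_distribution
#' @return Named character vector, one transmitted allele class per locus.
#' @export
form_gamete <- function(g, model, sex = c("female", "male")) {
  sex <- match.arg(sex)
  validate_genotype(g, model)
  active <- locus_active(g, model)
  vapply(locus_names(model), function(nm) {
    spec <- model$loci[[nm]]
    gp <- spec$germline[[sex]]
    a <- g[[nm]][sample.int(2L, 1L)]
    if (active[[nm]] && a == "S") a <- sample_fate(1L, gp, construct_class(spec))
    a
  }, character(1))
}

# Vectorised germline-fate draw for n S alleles.
sample_fate <- function(n, gp, construct) {
  u <- stats::runif(n)
  conv <- gp$p_cut * gp$p_hdr
  r1 <- conv + gp$p_cut * (1 - gp$p_hdr) * gp$p_r1
  r2 <- gp$p_cut
  out <- rep("S", n)
  out[u < r2] <- "R2"
  out[u < r1] <- "R1"
  out[u < conv] <- construct
  out
}
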