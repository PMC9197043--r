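# Configuration and file-format IO.
#
# Formats: YAML cage/model configuration; CSV genotyping tables (one 0/1
# carrier column per locus, comma-separated, UTF-8, header row); CSV cross
# tables; TSV amplicon allele tables (TSV because aligned sequences follow
# the upstream allele-table convention); FASTA reference windows
# (Biostrings); JSON/YAML target-site annotations; a JSON run manifest.

parse_pair <- function(x) {
  pair <- strsplit(x, "/", fixed = TRUE)[[1L]]
  if (length(pair) != 2L) stop("allele pair must be written 'A/B': ", x, call. = FALSE)
  check_alleles(pair)
}

format_genotype <- function(g) {
  vapply(g, function(p) paste(p, collapse = "/"), character(1))
}

genotype_from_strings <- function(lst, model) {
  loci <- locus_names(model)
  g <- lapply(loci, function(nm) {
    if (!is.null(lst[[nm]])) parse_pair(lst[[nm]]) else c("S", "S")
  })
  names(g) <- loci
  do.call(genotype, g)
}

#' Read / write a cage configuration (YAML)
#'
#' The YAML schema mirrors [cage_config()]: scalar fields
#' `population_size`, `generations`, `sample_size`, `replicates`,
#' `rng_seed`, and a `seed_groups` list whose entries carry `count`, `sex`
#' and a `genotype` map of `locus: "A/B"` pairs (missing loci default to
#' `"S/S"`).
#'
#' @param path File path.
#' @param model A [drive_model()] naming the loci.
#' @return A [cage_config()].
#' @export
read_cage_config <- function(path, model = default_drive_model()) {
  y <- yaml::read_yaml(path)
  need <- c("seed_groups")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("config missing field(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  groups <- lapply(y$seed_groups, function(grp) {
    for (f in c("count", "sex")) {
      if (is.null(grp[[f]])) stop("seed_groups entry missing field: ", f, call. = FALSE)
    }
    seed_group(grp$count, grp$sex,
               genotype_from_strings(grp$genotype %||% list(), model))
  })
  cage_config(groups,
              population_size = y$population_size %||% 600L,
              generations = y$generations %||% 6L,
              sample_size = y$sample_size %||% 47L,
              replicates = y$replicates %||% 25L,
              rng_seed = y$rng_seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_cage_config
#' @param config A [cage_config()] to serialise.
#' @export
write_cage_config <- function(config, path) {
  y <- list(population_size = config$population_size,
            generations = config$generations,
            sample_size = config$sample_size,
            replicates = config$replicates,
            rng_seed = config$rng_seed,
            seed_groups = lapply(config$seed_groups, function(grp) {
              list(count = grp$count, sex = grp$sex,
                   genotype = as.list(format_genotype(grp$genotype)))
            }))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read a drive model from YAML
#'
#' Schema: a `loci` list of maps with `name`, `role`, and either `e` (net
#' homing efficiency; decomposed with `p_cut`, default 0.98) or explicit
#' `p_cut`/`p_hdr`, plus optional `p_r1` and optional `maternal`
#' (`p_cut`/`p_r1`) for embryo-stage cutting by maternally deposited Cas9.
#'
#' @param path YAML file path.
#' @return A [drive_model()].
#' @export
read_drive_model <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$loci)) stop("model config missing 'loci'", call. = FALSE)
  specs <- lapply(y$loci, function(l) {
    if (is.null(l$name) || is.null(l$role)) {
      stop("each locus needs 'name' and 'role'", call. = FALSE)
    }
    gl <- if (!is.null(l$e)) {
      germline_from_efficiency(l$e, l$p_cut %||% 0.98, l$p_r1 %||% (1 / 3))
    } else {
      germline_params(l$p_cut %||% 0.98, l$p_hdr %||% 1, l$p_r1 %||% (1 / 3))
    }
    locus_spec(l$name, l$role, gl, maternal = l$maternal)
  })
  drive_model(specs)
}

#' Built-in cage scenarios
#'
#' * `"paper-cage"`: the cage-trial seeding — 300 wild-type females, 120
#'   wild-type males, and three groups of 60 trans-hemizygous males each
#'   carrying the driver over one payload; the `aper1` payload group carries
#'   the driver over a resistant R1 allele (pre-existing target-site
#'   resistance, 5% starting allele frequency).
#' * `"susceptible-only"`: identical, but every non-driver allele at the
#'   driver locus is susceptible.
#' * `"neutral-null"`: a neutrality control — the driver allele is a passive
#'   marker (cutting disabled, all genotypes fertile with equal weights).
#'
#' @param name Scenario name.
#' @param ... Overrides passed to [cage_config()] (e.g. `replicates`,
#'   `rng_seed`).
#' @return List with `config`, `model`, `fertility`.
#' @export
scenario_config <- function(name = c("paper-cage", "susceptible-only",
                                     "neutral-null"), ...) {
  name <- match.arg(name)
  model <- default_drive_model()
  wt <- genotype(zpg = c("S", "S"), cp = c("S", "S"),
                 aper1 = c("S", "S"), ap2 = c("S", "S"))
  trans_het <- function(zpg_partner, payload) {
    g <- list(zpg = c("D", zpg_partner), cp = c("S", "S"),
              aper1 = c("S", "S"), ap2 = c("S", "S"))
    g[[payload]] <- c("E", "S")
    do.call(genotype, g)
  }
  if (name == "neutral-null") {
    model <- default_drive_model(driver_e = 0, payload_e = 0, p_cut = 0)
    fert <- fertility_model(
      female_fertile = stats::setNames(rep(TRUE, 10), names(fertility_model()$female_fertile)),
      male_mating = stats::setNames(rep(1, 10), names(fertility_model()$male_mating)),
      male_fecundity = stats::setNames(rep(1, 10), names(fertility_model()$male_fecundity)))
    groups <- list(seed_group(300, "female", wt),
                   seed_group(120, "male", wt),
                   seed_group(180, "male", genotype(
                     zpg = c("D", "S"), cp = c("S", "S"),
                     aper1 = c("S", "S"), ap2 = c("S", "S"))))
    return(list(config = cage_config(groups, ...), model = model,
                fertility = fert))
  }
  aper1_partner <- if (name == "paper-cage") "R1" else "S"
  groups <- list(seed_group(300, "female", wt),
                 seed_group(120, "male", wt),
                 seed_group(60, "male", trans_het("S", "cp")),
                 seed_group(60, "male", trans_het("S", "ap2")),
                 seed_group(60, "male", trans_het(aper1_partner, "aper1")))
  list(config = cage_config(groups, ...), model = model,
       fertility = fertility_model())
}

#' Read / write genotyping sample tables (CSV)
#'
#' Schema: `cage`, `generation`, `individual`, `is_control`, then one 0/1
#' carrier column per locus.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_genotype_samples <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_genotype_samples
#' @param x Data frame in the genotyping schema.
#' @export
write_genotype_samples <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write cross tables (CSV)
#'
#' Schema of [simulate_crosses()]: `cross`, `parent_sex`,
#' `parent_genotype`, `total`, `sterile`, `marked_<locus>` columns.
#'
#' @param path CSV path.
#' @export
read_cross_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_cross_table
#' @param x Cross-record data frame.
#' @export
write_cross_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write amplicon allele tables (TSV)
#'
#' Schema: `sample`, `aligned_sequence`, `insertions`, `n_reads` (and any
#' extra columns such as `cage` / `generation`).
#'
#' @param path TSV path.
#' @export
read_allele_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(tab$insertions)) tab$insertions <- ""
  tab$insertions <- as.character(tab$insertions)
  tab$insertions[is.na(tab$insertions)] <- ""
  tab
}

#' @rdname read_allele_table
#' @param x Allele-table data frame.
#' @export
write_allele_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference target-site window from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_reference_window <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}

#' @rdname read_reference_window
#' @param seqs Named character vector of sequences.
#' @export
write_reference_window <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a target-site annotation (JSON or YAML)
#'
#' Fields mirror [target_site()]. Sites annotated on the antisense strand
#' (`strand: "-"`) are reverse-complemented into window coordinates at load
#' time: the reference is reverse-complemented and all intervals, the cut
#' position, the frame offset and the translation direction are flipped.
#'
#' @param path File path (`.json`, `.yml` or `.yaml`).
#' @param reference Optional reference sequence overriding the file's
#'   `reference` field (e.g. read from FASTA).
#' @return A [target_site()].
#' @export
read_target_site <- function(path, reference = NULL) {
  y <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ref <- toupper(reference %||% y$reference)
  if (is.null(ref)) stop("target site needs a reference sequence", call. = FALSE)
  flip <- identical(y$strand, "-")
  L <- nchar(ref)
  if (flip) {
    ref <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref)))
    flip_iv <- function(s, e) c(L - e, L - s)
    sp <- flip_iv(y$spacer_start, y$spacer_end)
    pm <- flip_iv(y$pam_start, y$pam_end)
    cut <- L - y$cut_pos
    fo <- L - 1L - y$frame_offset
    td <- if (identical(y$translation_direction %||% "+", "+")) "-" else "+"
    sc <- if (is.null(y$start_codon_pos) || is.na(y$start_codon_pos)) {
      NA_integer_
    } else L - 3L - y$start_codon_pos
  } else {
    sp <- c(y$spacer_start, y$spacer_end)
    pm <- c(y$pam_start, y$pam_end)
    cut <- y$cut_pos
    fo <- y$frame_offset %||% 0L
    td <- y$translation_direction %||% "+"
    sc <- y$start_codon_pos %||% NA_integer_
  }
  target_site(y$locus, ref, sp[1L], sp[2L], pm[1L], pm[2L], cut,
              strand = y$strand %||% "+", frame_offset = fo,
              translation_direction = td, start_codon_pos = sc)
}

#' @rdname read_target_site
#' @param site A [target_site()] to serialise (JSON).
#' @export
write_target_site <- function(site, path) {
  jsonlite::write_json(unclass(site), path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Records, atomically (temp file + rename), what produced a set of
#' outputs: a hash of the configuration, the master seed, the package
#' version, the output file list and a timestamp.
#'
#' @param path Manifest path (JSON).
#' @param config Any serialisable configuration object.
#' @param seed Master seed of the run.
#' @param outputs Character vector of output file paths.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, config, seed, outputs) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                               digits = NA)
  manifest <- list(
    config_hash = sprintf("%08x", sum(utf8ToInt(as.character(cfg_json)) *
                                        (seq_len(nchar(cfg_json)) %% 97 + 1)) %%
                            .Machine$integer.max),
    master_seed = seed,
    package = "drivecage",
    version = as.character(utils::packageVersion("drivecage")),
    outputs = as.list(outputs),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, path)
  invisible(manifest)
}
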