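# Amplicon resistance-allele analysis.
#
# Alleles arrive post-alignment (CRISPResso-style frequency tables): an
# aligned sequence in the coordinate frame of a reference target-site
# window, "-" for deleted bases, plus insertions annotated against the left
# anchor reference base ("pos:SEQ;pos:SEQ", 0-based). An allele is called
# cleavage-resistant iff at least one edit overlaps the gRNA spacer or the
# PAM; resistant alleles are predicted function-preserving (R1) when the net
# indel length is a multiple of 3, the annotated start codon (if any) is
# untouched and no premature stop codon appears in the annotated frame,
# else function-disrupting (R2).

#' Annotated CRISPR target-site window
#'
#' All coordinates are 0-based, half-open intervals on the reference window.
#' Sites annotated on the antisense strand are expected to be
#' reverse-complemented into window coordinates at load time (see
#' [read_target_site()]); `strand` records the original orientation.
#'
#' @param locus Locus name.
#' @param reference Reference window sequence (character, ACGT).
#' @param spacer_start,spacer_end 20 nt gRNA spacer interval.
#' @param pam_start,pam_end 3 nt PAM (NGG) interval, contiguous with the
#'   spacer.
#' @param cut_pos Between-base cut index, 3 nt inside the spacer from the
#'   PAM-proximal end.
#' @param strand `"+"` or `"-"`.
#' @param frame_offset Window position (0-based) of the first base of a
#'   codon, read in `translation_direction`.
#' @param translation_direction `"+"` (left to right) or `"-"`.
#' @param start_codon_pos Optional 0-based window position of the first base
#'   of the start codon, `NA` when outside the window.
#' @return An object of class `target_site`.
#' @export
target_site <- function(locus, reference, spacer_start, spacer_end,
                        pam_start, pam_end, cut_pos, strand = "+",
                        frame_offset = 0L, translation_direction = "+",
                        start_codon_pos = NA_integer_) {
  reference <- toupper(reference)
  L <- nchar(reference)
  stopifnot(spacer_start >= 0, spacer_end <= L, pam_start >= 0, pam_end <= L)
  if (spacer_end - spacer_start != 20L) {
    stop("spacer must span 20 nt", call. = FALSE)
  }
  if (pam_end - pam_start != 3L) stop("PAM must span 3 nt", call. = FALSE)
  contiguous <- pam_start == spacer_end || pam_end == spacer_start
  if (!contiguous) stop("PAM must be adjacent to the spacer", call. = FALSE)
  if (cut_pos <= spacer_start || cut_pos >= spacer_end) {
    stop("cut position must lie inside the spacer", call. = FALSE)
  }
  if (!strand %in% c("+", "-") || !translation_direction %in% c("+", "-")) {
    stop("strand and translation_direction must be '+' or '-'", call. = FALSE)
  }
  structure(list(locus = locus, reference = reference,
                 spacer_start = as.integer(spacer_start),
                 spacer_end = as.integer(spacer_end),
                 pam_start = as.integer(pam_start),
                 pam_end = as.integer(pam_end),
                 cut_pos = as.integer(cut_pos), strand = strand,
                 frame_offset = as.integer(frame_offset),
                 translation_direction = translation_direction,
                 start_codon_pos = as.integer(start_codon_pos)),
            class = "target_site")
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf("<target_site> %s: %d nt window, spacer [%d,%d), PAM [%d,%d), cut %d (%s)\n",
              x$locus, nchar(x$reference), x$spacer_start, x$spacer_end,
              x$pam_start, x$pam_end, x$cut_pos, x$strand))
  invisible(x)
}

parse_insertions <- function(ins) {
  if (is.null(ins) || is.na(ins) || !nzchar(ins)) {
    return(data.frame(pos = integer(), seq = character()))
  }
  parts <- strsplit(strsplit(ins, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed insertion annotation: ", ins,
                                      call. = FALSE)
  data.frame(pos = as.integer(vapply(parts, `[[`, character(1), 1L)),
             seq = toupper(vapply(parts, `[[`, character(1), 2L)))
}

# Enumerate edits of an aligned allele vs the reference window.
# Returns data.frame(start, end, type, seq): half-open reference intervals;
# insertions have start == end == left anchor base + 1 is NOT used -- the
# anchor base index itself is stored in `start` with end = start + 1 kept
# zero-width via type.
allele_edits <- function(aligned, site, insertions = "") {
  aligned <- toupper(aligned)
  ref <- site$reference
  if (nchar(aligned) != nchar(ref)) {
    stop("misaligned observation: allele length ", nchar(aligned),
         " does not match reference window length ", nchar(ref), call. = FALSE)
  }
  a <- strsplit(aligned, "")[[1L]]
  r <- strsplit(ref, "")[[1L]]
  edits <- list()
  run <- function(mask, type) {
    if (!any(mask)) return(NULL)
    d <- diff(c(0L, as.integer(mask)))
    starts <- which(d == 1L)
    ends <- which(diff(c(as.integer(mask), 0L)) == -1L)
    data.frame(start = starts - 1L, end = ends, type = type,
               seq = vapply(seq_along(starts), function(i) {
                 paste(a[starts[i]:ends[i]], collapse = "")
               }, character(1)))
  }
  edits$del <- run(a == "-", "del")
  edits$sub <- run(a != r & a != "-", "sub")
  ins <- parse_insertions(insertions)
  if (nrow(ins)) {
    if (any(ins$pos < 0 | ins$pos >= nchar(ref))) {
      stop("insertion anchor outside reference window", call. = FALSE)
    }
    edits$ins <- data.frame(start = ins$pos, end = ins$pos, type = "ins",
                            seq = ins$seq)
  }
  out <- do.call(rbind, edits)
  if (is.null(out)) out <- data.frame(start = integer(), end = integer(),
                                      type = character(), seq = character())
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

# Does an edit touch the spacer or PAM? Intervals are half-open; a
# zero-width insertion counts iff its left anchor base lies inside the
# region.
edit_in_region <- function(edits, site) {
  regions <- rbind(c(site$spacer_start, site$spacer_end),
                   c(site$pam_start, site$pam_end))
  vapply(seq_len(nrow(edits)), function(i) {
    s <- edits$start[i]; e <- edits$end[i]
    if (edits$type[i] == "ins") e <- s + 1L
    any(s < regions[, 2L] & e > regions[, 1L])
  }, logical(1))
}

# Reconstruct the edited (gap-free) sequence and map a window position to
# its edited-sequence position.
apply_edits <- function(aligned, insertions) {
  a <- strsplit(toupper(aligned), "")[[1L]]
  ins <- parse_insertions(insertions)
  pieces <- character(length(a))
  pieces[a != "-"] <- a[a != "-"]
  for (i in seq_len(nrow(ins))) {
    p <- ins$pos[i] + 1L
    pieces[p] <- paste0(pieces[p], ins$seq[i])
  }
  paste(pieces, collapse = "")
}

map_position <- function(aligned, insertions, pos) {
  a <- strsplit(toupper(aligned), "")[[1L]]
  ins <- parse_insertions(insertions)
  before <- seq_len(pos)  # window positions 0..pos-1 are 1..pos here
  n_del <- if (pos > 0) sum(a[before] == "-") else 0L
  n_ins <- sum(ins$pos < pos)
  pos - n_del + n_ins
}

translate_window <- function(seq, offset, direction) {
  L <- nchar(seq)
  if (direction == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    offset <- L - 1L - offset
  }
  if (offset < 0 || offset >= L) return("")
  coding <- substr(seq, offset + 1L, L)
  keep <- 3L * (nchar(coding) %/% 3L)
  if (keep < 3L) return("")
  suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(substr(coding, 1L, keep)),
                          if.fuzzy.codon = "X")))
}

#' Classify an amplicon allele against a target site
#'
#' @param aligned Aligned allele sequence (same length as the reference
#'   window; `-` marks deleted bases).
#' @param site A [target_site()].
#' @param insertions Insertion annotation string `"pos:SEQ;..."` (0-based
#'   left anchor base), or `""`.
#' @return An `allele_call`: list with `resistant` (logical), `r_class`
#'   (`"R1"`, `"R2"` or `NA`), and `edits` (data frame of reference-interval
#'   edits).
#' @examples
#' site <- target_site("demo", strrep("ACGT", 15), 10, 30, 30, 33, 27)
#' classify_allele(strrep("ACGT", 15), site) # reference itself: susceptible
#' @export
classify_allele <- function(aligned, site, insertions = "") {
  edits <- allele_edits(aligned, site, insertions)
  resistant <- nrow(edits) > 0 && any(edit_in_region(edits, site))
  r_class <- NA_character_
  if (resistant) {
    n_ins <- sum(nchar(edits$seq[edits$type == "ins"]))
    n_del <- sum(edits$end[edits$type == "del"] - edits$start[edits$type == "del"])
    in_frame <- (n_ins - n_del) %% 3L == 0L
    start_ok <- TRUE
    sc <- site$start_codon_pos
    if (!is.na(sc)) {
      codon_hit <- any(edits$start < sc + 3L &
                         ifelse(edits$type == "ins", edits$start + 1L,
                                edits$end) > sc)
      # an insertion anchored on the last codon base splits the codon only
      # if inside; anchor at sc+2 inserts after the codon's middle boundary
      start_ok <- !codon_hit
    }
    stop_ok <- TRUE
    if (in_frame && start_ok) {
      edited <- apply_edits(aligned, insertions)
      off <- map_position(aligned, insertions, site$frame_offset)
      ref_aa <- translate_window(site$reference, site$frame_offset,
                                 site$translation_direction)
      alt_aa <- translate_window(edited, off, site$translation_direction)
      stop_ok <- !(grepl("*", alt_aa, fixed = TRUE) &&
                     !grepl("*", ref_aa, fixed = TRUE))
    }
    r_class <- if (in_frame && start_ok && stop_ok) "R1" else "R2"
  }
  structure(list(resistant = resistant, r_class = r_class, edits = edits),
            class = "allele_call")
}

#' @export
print.allele_call <- function(x, ...) {
  cat("<allele_call>", if (x$resistant) paste("resistant,", x$r_class)
      else "susceptible", "-", nrow(x$edits), "edit(s)\n")
  invisible(x)
}

classify_table <- function(tab, site) {
  key <- paste(tab$aligned_sequence, tab$insertions, sep = "|")
  uniq <- !duplicated(key)
  calls <- lapply(which(uniq), function(i) {
    classify_allele(tab$aligned_sequence[i], site, tab$insertions[i])
  })
  names(calls) <- key[uniq]
  calls[key]
}

check_allele_table <- function(tab) {
  need <- c("sample", "aligned_sequence", "n_reads")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("allele table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!nrow(tab)) stop("empty allele table", call. = FALSE)
  if (any(tab$n_reads <= 0)) stop("read counts must be positive", call. = FALSE)
  if (is.null(tab$insertions)) tab$insertions <- ""
  tab$insertions[is.na(tab$insertions)] <- ""
  tab
}

#' Percentage of reads carrying a predicted cleavage-resistant allele
#'
#' @param tab Allele table: data frame with columns `sample`,
#'   `aligned_sequence`, optional `insertions`, `n_reads`.
#' @param site A [target_site()].
#' @return Data frame with one row per sample: `sample`, `total_reads`,
#'   `resistant_reads`, `pct_resistant` (0-100).
#' @export
resistant_fraction <- function(tab, site) {
  tab <- check_allele_table(tab)
  calls <- classify_table(tab, site)
  res <- vapply(calls, `[[`, logical(1), "resistant")
  agg <- function(v) tapply(v, tab$sample, sum)
  total <- agg(tab$n_reads)
  resistant <- agg(tab$n_reads * res)
  data.frame(sample = names(total), total_reads = as.numeric(total),
             resistant_reads = as.numeric(resistant),
             pct_resistant = 100 * as.numeric(resistant) / as.numeric(total),
             row.names = NULL)
}

#' Rank the most common resistant alleles across samples
#'
#' Frequencies are per-sample read percentages (denominator: all reads of
#' the sample). Alleles are ranked by their mean frequency across all
#' samples with absent alleles zero-filled; ties break lexicographically on
#' the allele sequence.
#'
#' @inheritParams resistant_fraction
#' @param k Number of top alleles to keep (default 5).
#' @return Data frame: `rank`, `aligned_sequence`, `insertions`, `r_class`,
#'   `mean_pct`, then one `pct_<sample>` column per sample (zero-filled).
#' @export
top_alleles <- function(tab, site, k = 5L) {
  tab <- check_allele_table(tab)
  calls <- classify_table(tab, site)
  res <- vapply(calls, `[[`, logical(1), "resistant")
  samples <- sort(unique(tab$sample))
  totals <- tapply(tab$n_reads, tab$sample, sum)[samples]
  rtab <- tab[res, , drop = FALSE]
  if (!nrow(rtab)) {
    return(data.frame(rank = integer(), aligned_sequence = character(),
                      insertions = character(), r_class = character(),
                      mean_pct = numeric()))
  }
  key <- paste(rtab$aligned_sequence, rtab$insertions, sep = "|")
  freq <- matrix(0, length(unique(key)), length(samples),
                 dimnames = list(unique(key), samples))
  for (i in seq_len(nrow(rtab))) {
    freq[key[i], rtab$sample[i]] <- freq[key[i], rtab$sample[i]] +
      100 * rtab$n_reads[i] / totals[[rtab$sample[i]]]
  }
  first <- match(rownames(freq), key)
  seqs <- rtab$aligned_sequence[first]
  mean_pct <- rowMeans(freq)
  ord <- order(-mean_pct, seqs)
  keep <- utils::head(ord, k)
  out <- data.frame(rank = seq_along(keep),
                    aligned_sequence = seqs[keep],
                    insertions = rtab$insertions[first][keep],
                    r_class = vapply(calls[first][keep], `[[`, character(1),
                                     "r_class"),
                    mean_pct = unname(mean_pct[keep]))
  pct <- as.data.frame(freq[keep, , drop = FALSE])
  names(pct) <- paste0("pct_", samples)
  rownames(pct) <- NULL
  cbind(out, pct)
}

#' Contrast resistant fractions between two generations
#'
#' Paired two-sided t-test over cages plus the fold change of means.
#'
#' @param g1,g6 Equal-length numeric vectors of per-cage resistant
#'   percentages at the early and late generation.
#' @return List with `fold_change` (mean(g6)/mean(g1), `NA` with
#'   `fold_undefined = TRUE` when mean(g1) is 0), `t`, `df`, `p`,
#'   `zero_variance` flag.
#' @export
generation_contrast <- function(g1, g6) {
  if (length(g1) != length(g6)) stop("paired vectors differ in length", call. = FALSE)
  if (length(g1) < 2L) stop("need at least two cages", call. = FALSE)
  fold_undefined <- mean(g1) == 0
  fold <- if (fold_undefined) NA_real_ else mean(g6) / mean(g1)
  d <- g6 - g1
  if (stats::sd(d) == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(fold_change = fold, t = t, df = length(d) - 1L,
                p = if (mean(d) == 0) 1 else 0,
                zero_variance = TRUE, fold_undefined = fold_undefined))
  }
  ht <- stats::t.test(g6, g1, paired = TRUE)
  list(fold_change = fold, t = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value,
       zero_variance = FALSE, fold_undefined = fold_undefined)
}

#' Predict cleavage resistance of a haplotype from sequence alone
#'
#' Mirrors an in-vitro cleavage readout: a haplotype is predicted resistant
#' iff it mismatches the reference in the gRNA spacer or PAM. In
#' `mode = "seed"` only the PAM plus the PAM-proximal 12 nt of the spacer
#' are considered.
#'
#' @param haplotype Ungapped haplotype sequence, same length as the
#'   reference window (substitution-level alignment).
#' @param site A [target_site()].
#' @param mode `"full"` (whole spacer + PAM) or `"seed"`.
#' @return `"resistant"` or `"susceptible"`.
#' @export
predict_haplotype_resistance <- function(haplotype, site,
                                         mode = c("full", "seed")) {
  mode <- match.arg(mode)
  haplotype <- toupper(haplotype)
  if (nchar(haplotype) != nchar(site$reference) || grepl("-", haplotype, fixed = TRUE)) {
    stop("haplotype must be an ungapped sequence matching the window length",
         call. = FALSE)
  }
  h <- strsplit(haplotype, "")[[1L]]
  r <- strsplit(site$reference, "")[[1L]]
  if (mode == "full") {
    spacer <- (site$spacer_start + 1L):site$spacer_end
  } else {
    # PAM-proximal 12 nt of the spacer (the seed region)
    if (site$pam_start == site$spacer_end) {
      spacer <- (site$spacer_end - 11L):site$spacer_end
    } else {
      spacer <- (site$spacer_start + 1L):(site$spacer_start + 12L)
    }
  }
  pam <- (site$pam_start + 1L):site$pam_end
  if (any(h[c(spacer, pam)] != r[c(spacer, pam)])) "resistant" else "susceptible"
}
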