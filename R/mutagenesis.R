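#' Cell density from a colony-count plate record
#'
#' Converts colonies on a plate back to the density of the original
#' suspension: `colonies * dilution_factor / plated_volume`.
#'
#' @param colonies Colony count (>= 0).
#' @param plated_volume Volume plated, in uL (> 0).
#' @param dilution_factor Fold dilution of the suspension before plating
#'   (>= 1).
#' @return Density in cells/uL.
#' @export
density_from_plate <- function(colonies, plated_volume, dilution_factor = 1) {
  if (any(plated_volume <= 0)) stop("plated_volume must be > 0",
                                    call. = FALSE)
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1",
                                     call. = FALSE)
  if (any(colonies < 0)) stop("colonies must be >= 0", call. = FALSE)
  colonies * dilution_factor / plated_volume
}

#' Cell viability
#'
#' Ratio of viable cell density (colony-forming units on a nonselective
#' plate) to total cell density (hemocytometer count).
#'
#' @param viable_density Viable cells/uL.
#' @param total_density Total cells/uL (> 0).
#' @return Viability fraction; values above 1 are kept but flagged with a
#'   warning.
#' @export
viability <- function(viable_density, total_density) {
  if (any(total_density <= 0)) stop("total_density must be > 0",
                                    call. = FALSE)
  v <- viable_density / total_density
  if (any(v > 1)) warning("viability above 1; check plate records",
                          call. = FALSE)
  v
}

#' Canavanine-resistance mutation frequency
#'
#' Frequency of Can-R mutants among viable cells: density of colonies on
#' the selective (canavanine) plate divided by the viable cell density.
#'
#' @param canr_density Can-R cells/uL from the selective plate.
#' @param viable_density Viable cells/uL from the nonselective plate
#'   (> 0).
#' @return Mutation frequency.
#' @export
canr_frequency <- function(canr_density, viable_density) {
  if (any(viable_density <= 0)) stop("viable_density must be > 0",
                                     call. = FALSE)
  canr_density / viable_density
}

#' Normalize a mutation frequency by DSB formation frequency
#'
#' Divides the raw mutation frequency by the strain's DSB formation
#' frequency `f`, removing differences in cutting efficiency between
#' strains.
#'
#' @param freq Raw Can-R mutation frequency.
#' @param f DSB formation frequency (> 0).
#' @return Normalized (per-DSB) mutation frequency.
#' @export
normalize_mutation_frequency <- function(freq, f) {
  if (any(f <= 0)) stop("f must be > 0", call. = FALSE)
  freq / f
}

#' Relative normalized mutation frequency, in percent
#'
#' Expresses a strain's normalized mutation frequency as a percentage of
#' the DSB reference strain's, the scale on which roadblock protection of
#' the reporter is reported.
#'
#' @param test_norm Normalized mutation frequency of the test strain.
#' @param reference_norm Normalized mutation frequency of the reference
#'   strain (> 0).
#' @return Percentage (100 means equal to the reference).
#' @export
relative_normalized_frequency <- function(test_norm, reference_norm) {
  if (any(reference_norm <= 0)) stop("reference_norm must be > 0",
                                     call. = FALSE)
  100 * test_norm / reference_norm
}

#' Fraction of red (ADE2-deleted) colonies on a selective plate
#'
#' Can-R colonies that also lost the DSB-proximal ADE2 reporter turn red
#' on low-adenine canavanine plates, marking on-target deletions that
#' reached the CAN1 reporter rather than point mutations.
#'
#' @param red_colonies Red colonies counted (selective plate only).
#' @param colonies Total colonies on the same plate.
#' @return `red_colonies / colonies`; 0 when `colonies` is 0.
#' @export
red_fraction <- function(red_colonies, colonies) {
  if (any(red_colonies < 0) || any(colonies < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  if (any(red_colonies > colonies)) {
    stop("red_colonies cannot exceed colonies", call. = FALSE)
  }
  ifelse(colonies == 0, 0, red_colonies / colonies)
}

check_pileup <- function(x, arm) {
  need <- c("pos", "ref", "A", "C", "G", "T")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(sprintf("%s pileup missing columns: %s", arm,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!all(x$ref %in% c("A", "C", "G", "T"))) {
    stop(sprintf("%s pileup has unannotated reference bases", arm),
         call. = FALSE)
  }
  x
}

#' Read a per-position pileup table
#'
#' Reads a simple per-position base-count matrix with columns `pos`
#' (0-based), `ref` (sense-strand reference base), and counts `A`, `C`,
#' `G`, `T`.
#'
#' @param path Path to the delimited file (`.csv` comma, otherwise tab).
#' @return Data frame of per-position counts.
#' @export
read_pileup <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  check_pileup(utils::read.table(path, header = TRUE, sep = sep,
                                 stringsAsFactors = FALSE), "input")
}

mutation_freq_per_position <- function(pileup) {
  depth <- pileup$A + pileup$C + pileup$G + pileup$T
  ref_count <- vapply(seq_len(nrow(pileup)), function(i) {
    pileup[[pileup$ref[i]]][i]
  }, numeric(1))
  data.frame(pos = pileup$pos, ref = pileup$ref, depth = depth,
             mutation_frequency = ifelse(depth > 0, 1 - ref_count / depth,
                                         NA_real_))
}

#' Per-position relative mutation frequency
#'
#' Divides the non-reference base frequency at each position of the
#' treated pool by that of the untreated pool. Positions where the
#' untreated frequency is zero are excluded from the ratio table and
#' listed separately (they cannot be normalized without dividing by
#' zero). The ratio is invariant to sequencing depth.
#'
#' @param treated,untreated Pileup data frames (see [read_pileup()])
#'   sharing the same positions and reference bases.
#' @return List with `table` (columns `pos`, `ref`, `treated_freq`,
#'   `untreated_freq`, `relative_frequency`) and `excluded_positions`.
#' @export
per_position_relative_frequency <- function(treated, untreated) {
  treated <- check_pileup(treated, "treated")
  untreated <- check_pileup(untreated, "untreated")
  if (!identical(treated$pos, untreated$pos) ||
      !identical(treated$ref, untreated$ref)) {
    stop("treated and untreated pileups must share positions and reference",
         call. = FALSE)
  }
  ft <- mutation_freq_per_position(treated)
  fu <- mutation_freq_per_position(untreated)
  keep <- fu$mutation_frequency > 0 & !is.na(fu$mutation_frequency) &
    !is.na(ft$mutation_frequency)
  list(
    table = data.frame(
      pos = ft$pos[keep], ref = ft$ref[keep],
      treated_freq = ft$mutation_frequency[keep],
      untreated_freq = fu$mutation_frequency[keep],
      relative_frequency = ft$mutation_frequency[keep] /
        fu$mutation_frequency[keep]
    ),
    excluded_positions = ft$pos[!keep]
  )
}

#' Tally the substitution spectrum of an amplicon pool
#'
#' Counts, on the sense strand, reads supporting each of the 12 base
#' substitution types, reports the dominant type and the G>A / C>T count
#' ratio. In a bisulfite experiment this ratio separates deamination of
#' the resection-exposed non-sense strand (read as sense-strand G>A) from
#' deamination of the transcription-exposed sense strand (sense-strand
#' C>T).
#'
#' @param pileup Pileup data frame (see [read_pileup()]) with sense-strand
#'   reference bases.
#' @return List with `tally` (named counts for all 12 substitution types),
#'   `dominant` (name of the most frequent type, `NA` if no mutations),
#'   and `ga_ct_ratio` (G>A count over C>T count; `Inf` when no C>T).
#' @export
classify_spectrum <- function(pileup) {
  pileup <- check_pileup(pileup, "input")
  bases <- c("A", "C", "G", "T")
  types <- unlist(lapply(bases, function(from) {
    paste0(from, ">", setdiff(bases, from))
  }))
  tally <- stats::setNames(numeric(length(types)), types)
  for (from in bases) {
    sel <- pileup$ref == from
    if (!any(sel)) next
    for (to in setdiff(bases, from)) {
      tally[paste0(from, ">", to)] <- sum(pileup[[to]][sel])
    }
  }
  dominant <- if (sum(tally) == 0) NA_character_ else names(which.max(tally))
  ga <- tally[["G>A"]]; ct <- tally[["C>T"]]
  list(tally = tally, dominant = dominant,
       ga_ct_ratio = if (ct == 0) Inf else ga / ct)
}

#' Pearson correlation between paired condition-level measurements
#'
#' Plain Pearson correlation, used to relate per-condition blocking
#' efficiencies to an orthogonal readout (relative fluorescence intensity
#' or normalized mutation frequency).
#'
#' @param x,y Paired numeric vectors, at least 3 points each.
#' @return Pearson correlation coefficient.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need at least 3 paired points", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for zero-variance input", call. = FALSE)
  }
  stats::cor(x, y)
}
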