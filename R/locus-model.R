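#' Describe the reporter locus geometry
#'
#' Builds a validated description of a linear reporter locus carrying an
#' inducible double-strand-break (DSB) site, SphI sites used by the
#' ssDNA-specific qPCR assay, binding sites for a dead-Cas9 roadblock,
#' restriction sites bracketing the Southern fragment, a strand-specific
#' probe interval, and reporter genes. All coordinates are 0-based bp on a
#' half-open `[0, length)` axis; the telomeric side of the DSB is the side
#' carrying the SphI sites and reporters (increasing coordinates).
#'
#' @param length Locus length in bp.
#' @param dsb_site Position of the inducible DSB.
#' @param sphi_sites Named integer vector of SphI-site positions
#'   (`SphI-1`, `SphI-2`, `SphI-3`), ordered by distance from the DSB, all
#'   on the telomeric side.
#' @param dcas9_sites Named integer vector of roadblock binding sites
#'   (e.g. `sg1`, `sg2`, `sg3`).
#' @param restriction_sites Named integer vector of length 2 with the
#'   restriction sites bounding the Southern fragment (e.g. `MluI`,
#'   `HindIII`).
#' @param probe_interval Length-2 integer `[start, end)` of the Southern
#'   probe; must lie between the DSB and the nearer restriction site and
#'   must not span the DSB.
#' @param reporter_intervals Named list of reporter gene descriptions,
#'   each a list with `start`, `end` (half-open) and `strand`
#'   (`"+"`/`"-"`); typically `ADE2` and `CAN1`.
#' @param amplicons Data frame with columns `amplicon_id`, `start`, `end`
#'   giving the qPCR amplicon intervals; each must contain exactly one
#'   SphI site. Defaults to a 120-bp window centred on each SphI site.
#' @param centromeric_barrier_distance Distance (bp) from the DSB to the
#'   natural resection barrier on the centromeric side (a Ty element).
#'
#' @return An object of class `locus_layout`.
#' @seealso [default_layout()] for the packaged reporter geometry.
#' @export
locus_layout <- function(length,
                         dsb_site,
                         sphi_sites,
                         dcas9_sites,
                         restriction_sites,
                         probe_interval,
                         reporter_intervals = list(),
                         amplicons = NULL,
                         centromeric_barrier_distance = 10000L) {
  length <- as.integer(length)
  dsb_site <- as.integer(dsb_site)
  sphi_sites <- vapply(sphi_sites, as.integer, integer(1))
  dcas9_sites <- vapply(dcas9_sites, as.integer, integer(1))
  restriction_sites <- vapply(restriction_sites, as.integer, integer(1))
  probe_interval <- as.integer(probe_interval)

  inside <- function(p) all(p > 0L & p < length)
  if (!inside(dsb_site) || !inside(sphi_sites) || !inside(dcas9_sites) ||
      !inside(restriction_sites)) {
    stop("all positions must lie strictly inside [0, length)", call. = FALSE)
  }
  d <- abs(sphi_sites - dsb_site)
  if (is.unsorted(d, strictly = TRUE)) {
    stop("sphi_sites must be strictly ordered by distance from the DSB",
         call. = FALSE)
  }
  if (any(sphi_sites <= dsb_site)) {
    stop("sphi_sites must lie on the telomeric side of the DSB",
         call. = FALSE)
  }
  if (is.null(names(sphi_sites)) || anyDuplicated(names(sphi_sites))) {
    stop("sphi_sites must be uniquely named", call. = FALSE)
  }

  if (is.null(amplicons)) {
    amplicons <- data.frame(
      amplicon_id = names(sphi_sites),
      start = sphi_sites - 60L,
      end = sphi_sites + 60L,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(amplicons))) {
    n_in <- sum(sphi_sites >= amplicons$start[i] &
                sphi_sites < amplicons$end[i])
    if (n_in != 1L) {
      stop(sprintf("amplicon '%s' must contain exactly one SphI site",
                   amplicons$amplicon_id[i]), call. = FALSE)
    }
  }

  if (probe_interval[1] <= dsb_site && probe_interval[2] > dsb_site) {
    stop("probe_interval must not span the DSB site", call. = FALSE)
  }

  obj <- structure(list(
    length = length,
    dsb_site = dsb_site,
    sphi_sites = sphi_sites,
    dcas9_sites = dcas9_sites,
    restriction_sites = restriction_sites,
    probe_interval = probe_interval,
    reporter_intervals = reporter_intervals,
    amplicons = amplicons,
    centromeric_barrier_distance = as.integer(centromeric_barrier_distance)
  ), class = "locus_layout")
  obj
}

#' Packaged default reporter locus
#'
#' A compact geometry mirroring the reporter construct used throughout the
#' package: a DSB site 1.4 kb telomeric of an MluI site, three SphI sites at
#' increasing distance from the break, two roadblock sites between SphI-1
#' and SphI-2 plus one between SphI-2 and SphI-3, a HindIII site closing a
#' 4.1-kb Southern fragment, and an ADE2-CAN1 reporter cassette distal to
#' SphI-3. The centromeric side carries a natural barrier 10 kb from the
#' break.
#'
#' @return A `locus_layout`.
#' @export
default_layout <- function() {
  locus_layout(
    length = 12000L,
    dsb_site = 1450L,
    sphi_sites = c("SphI-1" = 1950L, "SphI-2" = 2450L, "SphI-3" = 3150L),
    dcas9_sites = c(sg1 = 2050L, sg2 = 2250L, sg3 = 2800L),
    restriction_sites = c(MluI = 50L, HindIII = 4150L),
    probe_interval = c(3900L, 4080L),
    reporter_intervals = list(
      ADE2 = list(start = 4400L, end = 6100L, strand = "+"),
      CAN1 = list(start = 6500L, end = 8300L, strand = "+")
    ),
    centromeric_barrier_distance = 10000L
  )
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single number in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

#' Forward signal model of the ssDNA-specific qPCR assay
#'
#' Predicts the qPCR yield of an SphI-site amplicon, relative to intact
#' double-stranded DNA, under mock and SphI digestion. A molecule carrying
#' a DSB (probability `f`) whose resection tract has passed the site
#' (probability `r`) is single-stranded there and amplifies at half weight
#' (one surviving strand); double-stranded molecules survive digestion with
#' probability `1 - e`.
#'
#' The design predictions follow directly: full resection (`f = r = 1`)
#' gives 50% under both conditions, while a fully protected amplicon
#' (`r = 0`) with complete cutting and digestion gives 0% digested and
#' 100% mock.
#'
#' @param f DSB formation frequency, in `[0, 1]`.
#' @param r Resection efficiency at the site among DSB-bearing molecules,
#'   in `[0, 1]`.
#' @param e SphI digestion efficiency, in `[0, 1]`.
#'
#' @return Named numeric vector with `mock_yield = 1 - f*r/2` and
#'   `digested_yield = (1 - f*r)*(1 - e) + f*r/2`.
#' @export
#' @examples
#' expected_signal_fractions(f = 1, r = 1, e = 1)  # 0.5, 0.5
#' expected_signal_fractions(f = 1, r = 0, e = 1)  # 1.0, 0.0
expected_signal_fractions <- function(f, r, e) {
  check_fraction(f, "f"); check_fraction(r, "r"); check_fraction(e, "e")
  x <- f * r
  c(mock_yield = 1 - x / 2,
    digested_yield = (1 - x) * (1 - e) + x / 2)
}

#' Expected fold-difference between digested and mock-digested samples
#'
#' The quantity the resection estimator inverts: the ratio `D` of the
#' (ACT1-normalized) amplicon quantity in the SphI-digested sample over the
#' mock-digested sample, as predicted by the forward signal model. `D` is
#' strictly increasing in `r` whenever `e > 0` and `f > 0`.
#'
#' @inheritParams expected_signal_fractions
#' @return The fold-difference `D = digested_yield / mock_yield`.
#' @seealso [estimate_resection()] for the exact inversion.
#' @export
expected_fold_difference <- function(f, r, e) {
  y <- expected_signal_fractions(f, r, e)
  unname(y["digested_yield"] / y["mock_yield"])
}

#' Predict Southern restriction fragment sizes
#'
#' Sizes of the strand-specific Southern bands expected from a locus
#' digested with the two bracketing restriction enzymes: the intact
#' fragment, the DSB-generated fragment detected by the probe, and, when a
#' roadblock stalls resection, the shorter stall band within the resection
#' smear.
#'
#' @param layout A [locus_layout()].
#' @param stall_site Optional bp position where resection stalls; must lie
#'   between the DSB and the probe-side restriction site.
#' @return List with integer `intact`, `cut`, and `stalled` (`NULL` when
#'   no stall site is given) fragment sizes in bp.
#' @export
predict_southern_fragments <- function(layout, stall_site = NULL) {
  stopifnot(inherits(layout, "locus_layout"))
  rs <- sort(layout$restriction_sites)
  probe_mid <- mean(layout$probe_interval)
  # probe-side = restriction site nearer the probe
  probe_side <- rs[which.min(abs(rs - probe_mid))]
  far_side <- rs[which.max(abs(rs - probe_mid))]
  dsb <- layout$dsb_site
  if (!(min(rs) < min(layout$probe_interval) &&
        max(rs) >= max(layout$probe_interval))) {
    stop("probe_interval must lie within the restriction fragment",
         call. = FALSE)
  }
  between <- function(p) p >= min(dsb, probe_side) && p <= max(dsb, probe_side)
  if (!between(probe_mid)) {
    stop("probe must lie between the DSB and the probe-side restriction site",
         call. = FALSE)
  }
  intact <- abs(rs[2] - rs[1])
  cut <- abs(probe_side - dsb)
  stalled <- NULL
  if (!is.null(stall_site)) {
    stall_site <- as.integer(stall_site)
    if (!between(stall_site)) {
      stop("stall_site must lie between the DSB and the probe-side restriction site",
           call. = FALSE)
    }
    stalled <- as.integer(unname(abs(probe_side - stall_site)))
  }
  list(intact = as.integer(unname(intact)), cut = as.integer(unname(cut)),
       stalled = stalled)
}
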