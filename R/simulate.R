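#' Configuration for the forward resection simulator
#'
#' Collects every parameter of the stochastic model of roadblocked end
#' resection. Defaults describe the reference experimental conditions the
#' package's assays assume: half the cells cut after a 4-h induction,
#' resection fast enough to pass all three SphI sites in most cut cells,
#' a roadblock dwell borrowed from the measured residence time of dead
#' Cas9 on matched targets (~206 min), and duplicate qPCR wells with
#' 0.15-cycle Ct noise.
#'
#' @param n_cells Number of simulated cells.
#' @param f_true Per-cell DSB probability during induction.
#' @param induction_hours Duration of DSB induction, h.
#' @param resection_speed Mean resection speed, bp/h per end.
#' @param tract_shape Gamma shape of the per-cell multiplicative speed
#'   dispersion (mean 1); larger is less dispersed.
#' @param block_probs Named numeric vector, probability that the arriving
#'   resection machinery is halted at each bound roadblock site while the
#'   protein is on DNA (names must match `dcas9_sites` of the layout).
#' @param residence_minutes Mean roadblock dwell time (exponential), min.
#' @param centromeric_cap_bp Natural barrier distance on the centromeric
#'   side, bp.
#' @param digestion_efficiency True SphI digestion efficiency `e`.
#' @param ct_noise_sd Gaussian Ct noise per well, cycles.
#' @param n_replicates qPCR wells per (sample, amplicon, condition).
#' @param curve_slope,curve_intercept Standard-curve parameters shared by
#'   all amplicons (slope -3.3219 is perfect doubling).
#' @param standard_quantities Dilution series used for standards.
#' @param fluor_gain Fluorescence proxy units per bp of ssDNA.
#' @param fluor_background Mean background fluorescence per cell.
#' @param fluor_noise_sd SD of per-cell fluorescence noise.
#' @param deamination_rate Per exposed cytosine conversion probability
#'   during one bisulfite treatment.
#' @param canr_fraction Fraction of mutable reporter positions whose
#'   mutation inactivates CAN1 (confers canavanine resistance).
#' @param deletion_prob Probability that a cut cell suffers an on-target
#'   deletion instead of clean resection.
#' @param deletion_mean_bp Mean (exponential) deletion extent from the
#'   break, bp.
#' @param kill_prob_dsb Probability that an induced DSB kills the cell.
#' @param seq_error_rate Per-base background error rate of the amplicon
#'   pool (also the only mutation source in the untreated arm).
#' @param seq_depth Per-position depth of the pooled amplicon counts.
#' @param seed Integer seed making every downstream simulation
#'   reproducible; `NULL` uses the current RNG state.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells = 10000L,
                       f_true = 0.5,
                       induction_hours = 4,
                       resection_speed = 4000,
                       tract_shape = 4,
                       block_probs = numeric(0),
                       residence_minutes = 206,
                       centromeric_cap_bp = 10000L,
                       digestion_efficiency = 0.98,
                       ct_noise_sd = 0.15,
                       n_replicates = 2L,
                       curve_slope = -3.3219,
                       curve_intercept = 25,
                       standard_quantities = 2 * 10^seq(0, -4),
                       fluor_gain = 1,
                       fluor_background = 2000,
                       fluor_noise_sd = 500,
                       deamination_rate = 2e-3,
                       canr_fraction = 0.4,
                       deletion_prob = 0.02,
                       deletion_mean_bp = 2000,
                       kill_prob_dsb = 0.4,
                       seq_error_rate = 1e-4,
                       seq_depth = 50000L,
                       seed = NULL) {
  probs <- c(f_true, block_probs, digestion_efficiency, deamination_rate,
             canr_fraction, deletion_prob, kill_prob_dsb, seq_error_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must be in [0, 1]", call. = FALSE)
  }
  if (n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a population of cells undergoing roadblocked end resection
#'
#' Forward model: each cell is cut with probability `f_true`; both ends of
#' a cut locus are resected at a per-cell Gamma-dispersed speed for the
#' induction time. On the telomeric side the machinery, on reaching a
#' bound roadblock site, is halted with the site's blocking probability
#' for an exponential dwell (the protein's residence time) and then
#' resumes; sites act independently. The centromeric tract is capped at
#' the natural barrier. Per-cell fluorescence is proportional to total
#' ssDNA plus background and noise; induced DSBs kill cells with a fixed
#' probability.
#'
#' @param config A [sim_config()].
#' @param layout A [locus_layout()]; roadblock sites named in
#'   `config$block_probs` must exist in `layout$dcas9_sites`.
#' @return Object of class `sim_population`: data frame with one row per
#'   cell (`dsb`, `tel_extent`, `cen_extent`, `stalled_at`, `viable`,
#'   `fluorescence`), with the config and layout attached as attributes.
#' @export
simulate_population <- function(config, layout = default_layout()) {
  stopifnot(inherits(config, "sim_config"), inherits(layout, "locus_layout"))
  unknown <- setdiff(names(config$block_probs), names(layout$dcas9_sites))
  if (length(unknown)) {
    stop("block_probs name sites absent from the layout: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- as.integer(config$n_cells)
  T_h <- config$induction_hours

  dsb <- stats::runif(n) < config$f_true

  # per-cell, per-direction speed with Gamma(shape, shape) dispersion
  m_tel <- stats::rgamma(n, shape = config$tract_shape,
                         rate = config$tract_shape)
  m_cen <- stats::rgamma(n, shape = config$tract_shape,
                         rate = config$tract_shape)
  v_tel <- config$resection_speed * m_tel
  v_cen <- config$resection_speed * m_cen

  # telomeric walk through roadblock sites in order of distance
  sites <- config$block_probs
  if (length(sites)) {
    site_pos <- layout$dcas9_sites[names(sites)]
    ord <- order(site_pos)
    sites <- sites[ord]
    site_d <- as.numeric(site_pos[ord] - layout$dsb_site)
    if (any(site_d <= 0)) {
      stop("blocked roadblock sites must lie on the telomeric side",
           call. = FALSE)
    }
  } else {
    site_d <- numeric(0)
  }

  t_rem <- ifelse(dsb, T_h, 0)
  pos <- numeric(n)
  stalled_at <- rep(NA_character_, n)
  active <- dsb
  for (k in seq_along(site_d)) {
    d <- site_d[k]
    idx <- which(active)
    if (!length(idx)) break
    dt <- (d - pos[idx]) / v_tel[idx]
    reach <- dt < t_rem[idx]
    # cells that run out of time before the site
    stopnow <- idx[!reach]
    pos[stopnow] <- pos[stopnow] + v_tel[stopnow] * t_rem[stopnow]
    t_rem[stopnow] <- 0
    active[stopnow] <- FALSE
    # cells that reach the site
    go <- idx[reach]
    t_rem[go] <- t_rem[go] - dt[reach]
    pos[go] <- d
    blocked <- go[stats::runif(length(go)) < sites[k]]
    if (length(blocked)) {
      dwell <- stats::rexp(length(blocked),
                           rate = 60 / config$residence_minutes)
      stall <- dwell >= t_rem[blocked]
      hit <- blocked[stall]
      stalled_at[hit] <- names(sites)[k]
      t_rem[hit] <- 0
      active[hit] <- FALSE
      thru <- blocked[!stall]
      t_rem[thru] <- t_rem[thru] - dwell[!stall]
    }
  }
  idx <- which(active)
  pos[idx] <- pos[idx] + v_tel[idx] * t_rem[idx]
  tel_extent <- pmin(pos, layout$length - layout$dsb_site)

  cen_extent <- ifelse(dsb, pmin(v_cen * T_h, config$centromeric_cap_bp), 0)

  fluor <- config$fluor_background +
    config$fluor_gain * (tel_extent + cen_extent) +
    stats::rnorm(n, 0, config$fluor_noise_sd)
  viable <- !(dsb & stats::runif(n) < config$kill_prob_dsb)

  out <- data.frame(dsb = dsb, tel_extent = tel_extent,
                    cen_extent = cen_extent, stalled_at = stalled_at,
                    viable = viable, fluorescence = fluor,
                    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  attr(out, "layout") <- layout
  class(out) <- c("sim_population", "data.frame")
  out
}

#' Fraction of cells single-stranded at a position
#'
#' Fraction of all simulated cells whose resection tract covers the given
#' locus position (on either side of the DSB).
#'
#' @param pop A [simulate_population()] result.
#' @param position Position in bp on the locus.
#' @return Fraction in `[0, 1]`.
#' @export
ssdna_fraction_at <- function(pop, position) {
  layout <- attr(pop, "layout")
  if (position < 0 || position >= layout$length) {
    stop("position outside the locus", call. = FALSE)
  }
  dsb <- layout$dsb_site
  if (position >= dsb) {
    mean(pop$dsb & pop$tel_extent >= (position - dsb))
  } else {
    mean(pop$dsb & pop$cen_extent >= (dsb - position))
  }
}

#' Simulate an ssDNA-specific qPCR plate from populations
#'
#' Maps each population's realized ssDNA fractions through the forward
#' signal model (ssDNA at half template weight, dsDNA destroyed with the
#' digestion efficiency), converts template quantities to Ct through the
#' configured standard curve, adds per-well Gaussian Ct noise, and emits a
#' tidy plate: SphI amplicons under digested/mock conditions, the ACT1
#' normalizer under all conditions, the cleavage-spanning `DSB` amplicon
#' on undigested samples, plus the dilution-series standards.
#'
#' @param samples Named list of [simulate_population()] results; include a
#'   no-DSB control (a population simulated with `f_true = 0`).
#' @param config A [sim_config()] (supplies curve, noise, replicates,
#'   digestion efficiency).
#' @param layout A [locus_layout()].
#' @return List with `plate` and `standards` data frames matching
#'   [read_ct_plate()] / [read_standards()].
#' @export
simulate_ct_plate <- function(samples, config, layout = default_layout()) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  e <- config$digestion_efficiency
  slope <- config$curve_slope
  intercept <- config$curve_intercept
  noisy_ct <- function(q, n_rep) {
    ct <- intercept + slope * log10(q)
    ct + stats::rnorm(n_rep, 0, config$ct_noise_sd)
  }
  sphi <- layout$sphi_sites
  sphi_ids <- layout$amplicons$amplicon_id
  rows <- list()
  add <- function(sample, amplicon, condition, q) {
    cts <- noisy_ct(q, config$n_replicates)
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sample, amplicon_id = amplicon, condition = condition,
      replicate = seq_along(cts), ct = cts, stringsAsFactors = FALSE)
  }
  for (s in names(samples)) {
    pop <- samples[[s]]
    f_realized <- mean(pop$dsb)
    for (i in seq_along(sphi_ids)) {
      a <- ssdna_fraction_at(pop, sphi[[i]])
      add(s, sphi_ids[i], "mock", 1 - a / 2)
      add(s, sphi_ids[i], "digested", (1 - a) * (1 - e) + a / 2)
    }
    for (cond in c("digested", "mock", "undigested")) {
      add(s, "ACT1", cond, 1)
    }
    add(s, "DSB", "undigested", max(1 - f_realized, 1e-12))
  }
  plate <- do.call(rbind, rows)
  amps <- unique(plate$amplicon_id)
  standards <- do.call(rbind, lapply(amps, function(a) {
    q <- config$standard_quantities
    data.frame(amplicon_id = a, known_quantity = q,
               ct = intercept + slope * log10(q) +
                 stats::rnorm(length(q), 0, config$ct_noise_sd),
               stringsAsFactors = FALSE)
  }))
  list(plate = plate, standards = standards)
}

#' Render a fluorescence z-stack for a sample of simulated cells
#'
#' Draws cells as discs at random non-overlapping positions in a square
#' field; each disc's integrated intensity is proportional to the cell's
#' fluorescence proxy. Seven slices are produced with Gaussian defocus
#' blur growing away from the focal slice, plus additive background,
#' Gaussian shot noise, and 16-bit quantization.
#'
#' @param pop A [simulate_population()] result.
#' @param n_cells_field Number of cells drawn into the field (sampled from
#'   the population without replacement).
#' @param field_px Field side length in pixels.
#' @param cell_radius_px Disc radius in pixels.
#' @param focal_slice Index (1-7) of the in-focus slice.
#' @param defocus_sigma Blur sigma added per slice of defocus, px.
#' @param defocus_attenuation Fractional in-plane signal loss per slice of
#'   defocus (light spreading along z); slice signal is scaled by
#'   `1 / (1 + defocus_attenuation * |k - focal_slice|)`.
#' @param background Additive background level (16-bit counts).
#' @param noise_sd Gaussian noise SD (16-bit counts).
#' @param intensity_scale Disc counts per unit of fluorescence proxy.
#' @return `field_px x field_px x 7` integer array of 16-bit intensities.
#' @export
simulate_image_set <- function(pop, n_cells_field = 60L, field_px = 256L,
                               cell_radius_px = 5L, focal_slice = 4L,
                               defocus_sigma = 1.5,
                               defocus_attenuation = 0.25, background = 200,
                               noise_sd = 10, intensity_scale = 5) {
  n <- nrow(pop)
  n_cells_field <- min(n_cells_field, n)
  r <- cell_radius_px
  min_sep <- 2L * r + 3L
  max_fit <- floor((field_px / min_sep))^2
  if (n_cells_field > max_fit) {
    stop("field too small for the requested number of cells", call. = FALSE)
  }
  cells <- pop$fluorescence[sample.int(n, n_cells_field)]

  # rejection-sample non-overlapping centres
  centres <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(centres) < n_cells_field) {
    cand <- stats::runif(2, r + 1, field_px - r)
    ok <- nrow(centres) == 0 ||
      all(sqrt(rowSums(sweep(centres, 2, cand)^2)) >= min_sep)
    if (ok) centres <- rbind(centres, cand)
    tries <- tries + 1L
    if (tries > 200L * n_cells_field) {
      stop("field too small for the requested number of cells",
           call. = FALSE)
    }
  }

  focus <- matrix(0, field_px, field_px)
  disc <- which(outer(-r:r, -r:r, function(i, j) i^2 + j^2 <= r^2),
                arr.ind = TRUE) - (r + 1L)
  for (i in seq_len(n_cells_field)) {
    ci <- round(centres[i, 1]); cj <- round(centres[i, 2])
    per_px <- max(cells[i], 0) * intensity_scale / nrow(disc)
    ii <- ci + disc[, 1]; jj <- cj + disc[, 2]
    focus[cbind(ii, jj)] <- focus[cbind(ii, jj)] + per_px
  }

  stack <- array(0, dim = c(field_px, field_px, 7L))
  for (k in 1:7) {
    dz <- abs(k - focal_slice)
    sl <- if (dz == 0) focus else {
      as.matrix(EBImage::gblur(EBImage::Image(focus),
                               sigma = defocus_sigma * dz)) /
        (1 + defocus_attenuation * dz)
    }
    sl <- sl + background + stats::rnorm(length(sl), 0, noise_sd)
    stack[, , k] <- sl
  }
  stack[stack < 0] <- 0
  stack[stack > 65535] <- 65535
  array(as.integer(round(stack)), dim = dim(stack))
}

# synthetic sense-strand reference for the CAN1 amplicon; a fixed integer
# hash of the position keeps it deterministic (and independent of the RNG
# stream) so treated/untreated arms always share coordinates
can1_reference <- function(layout) {
  iv <- layout$reporter_intervals$CAN1
  if (is.null(iv)) stop("layout has no CAN1 reporter interval",
                        call. = FALSE)
  pos <- seq.int(iv$start, iv$end - 1L)
  idx <- ((pos * 2654435761) %% 89) %% 4 + 1
  data.frame(pos = pos,
             ref = c("A", "C", "G", "T")[idx],
             stringsAsFactors = FALSE)
}

#' Simulate bisulfite mutagenesis of the reporter cassette
#'
#' For every cell whose telomeric resection tract reaches into the CAN1
#' reporter, each deaminatable base on the exposed strand within the
#' exposed interval converts with the configured deamination rate
#' (resection exposes the non-sense strand, read as sense-strand G>A;
#' `exposed_strand = "sense"` models transcription-coupled exposure
#' instead, read as C>T). Cells become canavanine-resistant (Can-R) when
#' they acquire an inactivating substitution or an on-target deletion
#' reaching CAN1 (which also removes the more DSB-proximal ADE2, scoring
#' red). Plating converts per-cell outcomes to Poisson colony counts, and
#' pooled Can-R cells yield per-position base-count matrices for a treated
#' and an untreated arm.
#'
#' @param pop A [simulate_population()] result.
#' @param config A [sim_config()].
#' @param layout A [locus_layout()]; must carry `CAN1` (and `ADE2`)
#'   reporter intervals.
#' @param treated Logical; `FALSE` simulates the water-control arm (no
#'   deamination, background sequencing error only).
#' @param exposed_strand `"nonsense"` (resection bubble; default) or
#'   `"sense"` (transcription exposure).
#' @param suspension_volume,plated_volume_selective,plated_volume_nonselective
#'   Plating volumes in uL.
#' @param dilution_nonselective Fold dilution before the nonselective
#'   plate.
#' @return List with `plates` (one row per plate: colony counts, volumes,
#'   dilution, red colonies), `pileup` (per-position counts for the Can-R
#'   pool), `canr_cells`, `viable_cells`, and the per-cell ground truth
#'   (`canr`, `red`, `n_mutations`).
#' @export
simulate_mutagenesis <- function(pop, config, layout = default_layout(),
                                 treated = TRUE,
                                 exposed_strand = c("nonsense", "sense"),
                                 suspension_volume = 500,
                                 plated_volume_selective = 250,
                                 plated_volume_nonselective = 100,
                                 dilution_nonselective = 1) {
  exposed_strand <- match.arg(exposed_strand)
  can1 <- layout$reporter_intervals$CAN1
  if (is.null(can1)) stop("layout has no CAN1 reporter interval",
                          call. = FALSE)
  ref <- can1_reference(layout)
  # bisulfite deaminates C on the exposed strand: on the non-sense strand
  # the C sits opposite a sense-strand G (read out as G>A); on the sense
  # strand it is a sense C (read out as C>T)
  target_base <- if (exposed_strand == "nonsense") "G" else "C"
  alt_base <- if (exposed_strand == "nonsense") "A" else "T"
  targets <- ref$pos[ref$ref == target_base]
  n_targets <- length(targets)
  canr_cut <- floor(n_targets * config$canr_fraction)
  canr_set <- targets[seq_len(canr_cut)]  # inactivating positions

  n <- nrow(pop)
  dsb_site <- attr(pop, "layout")$dsb_site
  reach <- dsb_site + pop$tel_extent  # telomeric tract end, bp

  mut_pos <- vector("list", n)
  if (treated && config$deamination_rate > 0) {
    n_cov <- findInterval(reach, targets)  # targets covered per cell
    hot <- which(pop$dsb & n_cov > 0)
    for (i in hot) {
      k <- stats::rbinom(1L, n_cov[i], config$deamination_rate)
      if (k > 0) {
        mut_pos[[i]] <- targets[sample.int(n_cov[i], k)]
      }
    }
  }

  deletion <- pop$dsb & stats::runif(n) < config$deletion_prob
  del_len <- ifelse(deletion,
                    stats::rexp(n, rate = 1 / config$deletion_mean_bp), 0)
  del_reaches_can1 <- deletion & (dsb_site + del_len >= can1$start)

  point_canr <- vapply(mut_pos, function(p) any(p %in% canr_set),
                       logical(1))
  canr <- pop$viable & (point_canr | del_reaches_can1)
  red <- canr & del_reaches_can1

  viable_cells <- sum(pop$viable)
  canr_cells <- sum(canr)
  dens_viable <- viable_cells / suspension_volume
  dens_canr <- canr_cells / suspension_volume

  plates <- data.frame(
    plate_type = c("nonselective", "selective"),
    colonies = c(
      stats::rpois(1, dens_viable * plated_volume_nonselective /
                     dilution_nonselective),
      stats::rpois(1, dens_canr * plated_volume_selective)),
    plated_volume = c(plated_volume_nonselective, plated_volume_selective),
    suspension_volume = suspension_volume,
    dilution_factor = c(dilution_nonselective, 1),
    red_colonies = NA_integer_, stringsAsFactors = FALSE)
  sel_col <- plates$colonies[2]
  red_share <- if (canr_cells > 0) sum(red) / canr_cells else 0
  plates$red_colonies[2] <- stats::rbinom(1, sel_col, red_share)

  # pooled amplicon counts over Can-R point-mutant cells (deletions do not
  # amplify); untreated arm carries background error only
  pool <- which(canr & point_canr)
  depth <- as.integer(config$seq_depth)
  alt_frac <- rep(config$seq_error_rate, nrow(ref))
  if (length(pool)) {
    tabulated <- table(factor(unlist(mut_pos[pool]), levels = ref$pos))
    alt_frac <- alt_frac + as.numeric(tabulated) / length(pool)
  }
  alt_counts <- stats::rbinom(nrow(ref), depth, pmin(alt_frac, 1))
  counts <- matrix(0L, nrow(ref), 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  transition <- c(A = "G", C = "T", G = "A", T = "C")
  for (b in c("A", "C", "G", "T")) {
    sel <- ref$ref == b
    counts[sel, b] <- depth - alt_counts[sel]
    # deamination and background errors both land on the transition partner
    counts[sel, transition[[b]]] <- alt_counts[sel]
  }
  pileup <- data.frame(pos = ref$pos, ref = ref$ref, counts,
                       stringsAsFactors = FALSE)

  list(plates = plates, pileup = pileup,
       canr_cells = canr_cells, viable_cells = viable_cells,
       truth = data.frame(canr = canr, red = red,
                          n_mutations = lengths(mut_pos)))
}

#' Run a packaged simulation scenario end to end
#'
#' Generates a complete seeded input bundle for one named strain scenario
#' together with the shared DSB-reference strain and no-DSB control: the
#' Ct plate and standards, per-sample fluorescence summaries, and the
#' mutagenesis outputs (treated and untreated arms) for the scenario
#' strain.
#'
#' @param scenario One of `"reference"` (no roadblock near the break),
#'   `"single-sg"` (sg2), `"double-sg"` (sg1 and sg2), `"distal-sg"`
#'   (sg3), `"no-dsb"` (glucose control).
#' @param config Base [sim_config()]; its `block_probs` are replaced per
#'   scenario using `single_block_probs`.
#' @param layout A [locus_layout()].
#' @param single_block_probs Named per-site blocking probabilities used to
#'   assemble scenarios (defaults sg1 = 0.53, sg2 = 0.47, sg3 = 0.30).
#' @return List with `scenario`, `populations` (test, reference, no-DSB),
#'   `qpcr` (plate + standards), `fluorescence` (per-sample means of the
#'   per-cell proxy), and `mutagenesis` (treated/untreated bundles for the
#'   test strain), or no mutagenesis for the `no-dsb` scenario.
#' @export
run_scenario <- function(scenario, config = sim_config(),
                         layout = default_layout(),
                         single_block_probs = c(sg1 = 0.53, sg2 = 0.47,
                                                sg3 = 0.30)) {
  blocks <- switch(scenario,
    "reference" = numeric(0),
    "single-sg" = single_block_probs["sg2"],
    "double-sg" = single_block_probs[c("sg1", "sg2")],
    "distal-sg" = single_block_probs["sg3"],
    "no-dsb" = numeric(0),
    stop("unknown scenario: ", scenario, call. = FALSE))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg_test <- config
  cfg_test$block_probs <- blocks
  cfg_test$seed <- NULL
  if (identical(scenario, "no-dsb")) cfg_test$f_true <- 0
  cfg_ref <- config; cfg_ref$block_probs <- numeric(0); cfg_ref$seed <- NULL
  cfg_nod <- cfg_ref; cfg_nod$f_true <- 0

  pops <- list(
    test = simulate_population(cfg_test, layout),
    reference = simulate_population(cfg_ref, layout),
    no_dsb = simulate_population(cfg_nod, layout))
  qpcr <- simulate_ct_plate(pops, config, layout)
  fluorescence <- vapply(pops, function(p) mean(p$fluorescence), numeric(1))
  mut <- if (identical(scenario, "no-dsb")) NULL else list(
    treated = simulate_mutagenesis(pops$test, config, layout,
                                   treated = TRUE),
    untreated = simulate_mutagenesis(pops$test, config, layout,
                                     treated = FALSE))
  list(scenario = scenario, populations = pops, qpcr = qpcr,
       fluorescence = fluorescence, mutagenesis = mut)
}
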