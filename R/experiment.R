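#' Read a Ct plate table
#'
#' Reads a tidy delimited plate of replicate Ct measurements with columns
#' `sample_id`, `amplicon_id`, `condition` (`digested`, `mock`,
#' `undigested`), `replicate`, `ct`. The delimiter is taken from the file
#' extension (`.csv` comma, otherwise tab).
#'
#' @param path Path to the delimited file.
#' @return Data frame with the five plate columns.
#' @export
read_ct_plate <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "amplicon_id", "condition", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("plate file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df[need]
}

#' Read a qPCR standards table
#'
#' Reads the dilution-series table with columns `amplicon_id`,
#' `known_quantity`, `ct` used to fit per-amplicon calibration curves.
#'
#' @param path Path to the delimited file (`.csv` comma, otherwise tab).
#' @return Data frame with the three standards columns.
#' @export
read_standards <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("amplicon_id", "known_quantity", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("standards file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df[need]
}

# mean Ct per (sample, amplicon, condition); replicates are averaged on the
# Ct scale before quantification
average_ct <- function(plate) {
  stats::aggregate(ct ~ sample_id + amplicon_id + condition, data = plate,
                   FUN = mean)
}

#' Analyze an ssDNA-specific qPCR experiment
#'
#' Runs the full estimator chain on one plate: fits per-amplicon
#' calibration curves, averages replicate Ct values, quantifies, forms
#' ACT1-normalized fold-differences, estimates digestion efficiency `e`
#' (from the no-DSB control, per SphI amplicon), DSB formation frequency
#' `f` (from the cleavage-spanning amplicon on undigested samples, per
#' strain), the corrected resection efficiency `r` at every SphI site, the
#' two normalizations (to SphI-1 within sample, then to the DSB reference
#' strain), and the blocking efficiency. The function is a pure,
#' deterministic function of the plate.
#'
#' @param plate Data frame as returned by [read_ct_plate()].
#' @param standards Data frame as returned by [read_standards()].
#' @param layout A [locus_layout()]; supplies the SphI amplicon order
#'   (SphI-1 is the DSB-proximal site used for within-sample
#'   normalization).
#' @param reference_sample `sample_id` of the DSB reference strain
#'   (roadblock targeted to an unrelated locus).
#' @param no_dsb_sample `sample_id` of the no-DSB (glucose) control.
#' @param dsb_amplicon `amplicon_id` of the cleavage-spanning amplicon.
#' @param act1_amplicon `amplicon_id` of the normalizer amplicon.
#' @return Object of class `resection_result`: list with `table`
#'   (per sample x site: `raw_r`, `within_sample_norm`, `reference_norm`,
#'   `blocking_efficiency`, plus a clamped `blocking_efficiency_clamped`),
#'   `e` (per SphI amplicon), `f` (per sample), `D` (all intermediate
#'   fold-differences), and `curves`.
#' @export
analyze_experiment <- function(plate, standards, layout = default_layout(),
                               reference_sample, no_dsb_sample,
                               dsb_amplicon = "DSB",
                               act1_amplicon = "ACT1") {
  sphi_ids <- layout$amplicons$amplicon_id
  missing_bits <- character()
  if (!reference_sample %in% plate$sample_id) {
    missing_bits <- c(missing_bits,
                      sprintf("reference sample '%s'", reference_sample))
  }
  if (!no_dsb_sample %in% plate$sample_id) {
    missing_bits <- c(missing_bits,
                      sprintf("no-DSB control '%s'", no_dsb_sample))
  }
  if (!act1_amplicon %in% plate$amplicon_id) {
    missing_bits <- c(missing_bits,
                      sprintf("ACT1 amplicon '%s'", act1_amplicon))
  }
  for (a in sphi_ids) {
    if (!a %in% plate$amplicon_id) {
      missing_bits <- c(missing_bits, sprintf("SphI amplicon '%s'", a))
    }
  }
  if (length(missing_bits)) {
    stop("plate is missing required pieces: ",
         paste(missing_bits, collapse = "; "), call. = FALSE)
  }

  amps <- unique(plate$amplicon_id)
  curves <- lapply(stats::setNames(amps, amps), function(a) {
    s <- standards[standards$amplicon_id == a, ]
    if (nrow(s) < 3L) {
      stop(sprintf("amplicon '%s' has fewer than 3 standard points", a),
           call. = FALSE)
    }
    fit_standard_curve(s$known_quantity, s$ct)
  })

  avg <- average_ct(plate)
  avg$quantity <- vapply(seq_len(nrow(avg)), function(i) {
    as.numeric(quantify(avg$ct[i], curves[[avg$amplicon_id[i]]]))
  }, numeric(1))

  q_of <- function(sample, amplicon, condition) {
    v <- avg$quantity[avg$sample_id == sample &
                      avg$amplicon_id == amplicon &
                      avg$condition == condition]
    if (length(v) != 1L) {
      stop(sprintf("expected one quantity for (%s, %s, %s), found %d",
                   sample, amplicon, condition, length(v)), call. = FALSE)
    }
    v
  }

  # e per SphI amplicon from the no-DSB control (digested vs mock)
  d_records <- list()
  e_by_amp <- vapply(sphi_ids, function(a) {
    D <- fold_difference(q_of(no_dsb_sample, a, "digested"),
                         q_of(no_dsb_sample, a, "mock"),
                         q_of(no_dsb_sample, act1_amplicon, "digested"),
                         q_of(no_dsb_sample, act1_amplicon, "mock"))
    d_records[[length(d_records) + 1L]] <<- data.frame(
      sample_id = no_dsb_sample, amplicon_id = a, kind = "no_dsb", D = D)
    estimate_digestion_efficiency(D)$e
  }, numeric(1))
  if (diff(range(e_by_amp)) > 0.05) {
    warning("per-amplicon digestion efficiencies differ by more than 0.05",
            call. = FALSE)
  }

  test_samples <- setdiff(unique(plate$sample_id), no_dsb_sample)

  # f per strain from the cleavage-spanning amplicon on undigested samples
  f_by_sample <- vapply(stats::setNames(test_samples, test_samples),
                        function(s) {
    D <- fold_difference(q_of(s, dsb_amplicon, "undigested"),
                         q_of(no_dsb_sample, dsb_amplicon, "undigested"),
                         q_of(s, act1_amplicon, "undigested"),
                         q_of(no_dsb_sample, act1_amplicon, "undigested"))
    d_records[[length(d_records) + 1L]] <<- data.frame(
      sample_id = s, amplicon_id = dsb_amplicon, kind = "dsb_frequency",
      D = D)
    estimate_dsb_frequency(D)$f
  }, numeric(1))

  # raw r per sample x site; strains with no detectable cutting cannot
  # carry a resection estimate and are flagged with NA instead
  rows <- list()
  for (s in test_samples) {
    measurable <- f_by_sample[[s]] > 1e-6
    for (a in sphi_ids) {
      D <- fold_difference(q_of(s, a, "digested"), q_of(s, a, "mock"),
                           q_of(s, act1_amplicon, "digested"),
                           q_of(s, act1_amplicon, "mock"))
      d_records[[length(d_records) + 1L]] <- data.frame(
        sample_id = s, amplicon_id = a, kind = "resection", D = D)
      raw_r <- if (measurable) {
        estimate_resection(D, e = e_by_amp[[a]], f = f_by_sample[[s]])$raw
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, site = a, raw_r = raw_r,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)

  proximal <- sphi_ids[1]
  tab$within_sample_norm <- NA_real_
  for (s in test_samples) {
    r1 <- tab$raw_r[tab$sample_id == s & tab$site == proximal]
    if (!is.finite(r1)) next
    idx <- tab$sample_id == s
    tab$within_sample_norm[idx] <-
      normalize_within_sample(tab$raw_r[idx], r1)
  }

  tab$reference_norm <- NA_real_
  for (a in sphi_ids) {
    nr <- tab$within_sample_norm[tab$sample_id == reference_sample &
                                 tab$site == a]
    idx <- tab$site == a
    tab$reference_norm[idx] <-
      normalize_to_reference(tab$within_sample_norm[idx], nr)
  }

  ok <- is.finite(tab$reference_norm)
  tab$blocking_efficiency <- NA_real_
  tab$blocking_efficiency_clamped <- NA_real_
  if (any(ok)) {
    be <- blocking_efficiency(tab$reference_norm[ok])
    tab$blocking_efficiency[ok] <- be$raw
    tab$blocking_efficiency_clamped[ok] <- be$b
  }

  structure(list(
    table = tab,
    e = e_by_amp,
    f = f_by_sample,
    D = do.call(rbind, d_records),
    curves = curves,
    reference_sample = reference_sample,
    no_dsb_sample = no_dsb_sample
  ), class = "resection_result")
}

#' @export
print.resection_result <- function(x, ...) {
  cat("ssDNA-qPCR resection analysis\n")
  cat(sprintf("  digestion efficiency e: %s\n",
              paste(sprintf("%s=%.3f", names(x$e), x$e), collapse = ", ")))
  cat(sprintf("  DSB frequency f: %s\n",
              paste(sprintf("%s=%.3f", names(x$f), x$f), collapse = ", ")))
  print(x$table, digits = 4)
  invisible(x)
}
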