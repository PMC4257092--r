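# Peak-list I/O, two-point recalibration, tolerance matching of measured
# peaks to theoretical fingerprints, coverage scoring and ranked
# identification over a candidate set.

#' Construct a peak list
#'
#' @param spot_id Spot label.
#' @param mz Numeric m/z values (positive, finite); stored sorted ascending.
#'   Near-duplicates (gap < 1e-6 Da) are collapsed keeping the maximum
#'   intensity.
#' @param intensity Optional non-negative intensities, parallel to `mz`.
#' @param calibrated Calibration state flag.
#' @return Object of class `peak_list`.
#' @export
peaklist <- function(spot_id, mz, intensity = NULL, calibrated = FALSE) {
  mz <- as.numeric(mz)
  if (anyNA(mz) || any(!is.finite(mz)) || any(mz <= 0)) {
    stop("peaklist: m/z values must be positive and finite", call. = FALSE)
  }
  if (is.null(intensity)) intensity <- rep(NA_real_, length(mz))
  stopifnot(length(intensity) == length(mz))
  ord <- order(mz)
  mz <- mz[ord]; intensity <- as.numeric(intensity)[ord]
  if (length(mz) > 1L) {
    keep <- rep(TRUE, length(mz))
    for (i in seq_along(mz)[-1]) {
      if (mz[i] - mz[i - 1L] < 1e-6) {
        keep[i] <- FALSE
        pair <- c(intensity[i - 1L], intensity[i])
        intensity[i - 1L] <- if (all(is.na(pair))) NA_real_
        else max(pair, na.rm = TRUE)
      }
    }
    mz <- mz[keep]; intensity <- intensity[keep]
  }
  structure(
    list(spot_id = spot_id, mz = mz, intensity = intensity,
         calibrated = isTRUE(calibrated), calibration_refs = NULL),
    class = "peak_list"
  )
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %s: %d peaks%s\n", x$spot_id, length(x$mz),
              if (x$calibrated) " (calibrated)" else ""))
  invisible(x)
}

#' Read a measured peak list (MGF or two-column text)
#'
#' The MGF dialect parses the first `BEGIN IONS`/`END IONS` block's ion
#' lines as `(m/z, intensity)`; the TSV dialect accepts one or two numeric
#' whitespace/tab-separated columns. `dialect = "auto"` picks MGF when the
#' file contains a `BEGIN IONS` line.
#'
#' @param path File path.
#' @param dialect `"auto"`, `"MGF"` or `"TSV"`.
#' @param spot_id Spot label; defaults to the file name without extension.
#' @return A [peaklist()] (empty, with a warning, when the file holds no ion
#'   lines).
#' @export
read_peaklist <- function(path, dialect = c("auto", "MGF", "TSV"),
                          spot_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak-list file not found: ", path,
                               call. = FALSE)
  if (is.null(spot_id)) spot_id <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") {
    dialect <- if (any(grepl("^BEGIN IONS", lines))) "MGF" else "TSV"
  }
  if (dialect == "MGF") {
    begin <- which(grepl("^BEGIN IONS", lines))
    end <- which(grepl("^END IONS", lines))
    if (!length(begin) || !length(end) || end[1] < begin[1]) {
      stop("malformed MGF (no BEGIN IONS/END IONS block): ", path,
           call. = FALSE)
    }
    body <- lines[seq(begin[1] + 1L, end[1] - 1L)]
    body <- body[!grepl("^[A-Z]+=", body) & nzchar(trimws(body))]
    ion_lines <- body
  } else {
    ion_lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  }
  if (!length(ion_lines)) {
    warning("no peaks in ", path, call. = FALSE)
    return(peaklist(spot_id, numeric(0)))
  }
  fields <- strsplit(trimws(ion_lines), "[\t ]+")
  mz <- suppressWarnings(vapply(fields, function(f) as.numeric(f[1]),
                                numeric(1)))
  if (anyNA(mz)) {
    bad <- which(is.na(mz))[1]
    # report the line number in the original file
    ln <- which(lines == ion_lines[bad])[1]
    stop("non-numeric peak value at line ", ln, " of ", path, call. = FALSE)
  }
  intensity <- suppressWarnings(vapply(fields, function(f) {
    if (length(f) >= 2L) as.numeric(f[2]) else NA_real_
  }, numeric(1)))
  peaklist(spot_id, mz, intensity)
}

#' Write a peak list as MGF or TSV
#' @param pl A [peaklist()].
#' @param path Output path.
#' @param dialect `"MGF"` or `"TSV"`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(pl, path, dialect = c("TSV", "MGF")) {
  dialect <- match.arg(dialect)
  fmt_row <- function(mz, it) {
    if (is.na(it)) sprintf("%.6f", mz) else sprintf("%.6f\t%.4f", mz, it)
  }
  rows <- mapply(fmt_row, pl$mz, pl$intensity)
  lines <- if (dialect == "MGF") {
    c("BEGIN IONS", paste0("TITLE=", pl$spot_id), rows, "END IONS")
  } else {
    rows
  }
  writeLines(as.character(lines), path)
  invisible(path)
}

#' Two-point recalibration
#'
#' Fits the affine map through two `(observed, true)` anchor pairs — in the
#' study, matrix-cluster or trypsin-autolysis ions near m/z 842 and 2211 —
#' and applies it to all peaks. Anchors map exactly onto their true values.
#'
#' @param pl A [peaklist()].
#' @param refs 2x2 numeric matrix (or length-4 vector) of rows
#'   `(observed, true)`.
#' @return Calibrated [peaklist()] (`calibrated = TRUE`).
#' @export
calibrate <- function(pl, refs) {
  stopifnot(inherits(pl, "peak_list"))
  refs <- matrix(as.numeric(refs), ncol = 2L, byrow = FALSE)
  if (nrow(refs) != 2L || anyNA(refs)) {
    stop("calibrate: need exactly two (observed, true) anchors",
         call. = FALSE)
  }
  if (abs(refs[1, 1] - refs[2, 1]) < 1e-9) {
    stop("calibrate: degenerate calibration (identical observed anchors)",
         call. = FALSE)
  }
  slope <- (refs[2, 2] - refs[1, 2]) / (refs[2, 1] - refs[1, 1])
  intercept <- refs[1, 2] - slope * refs[1, 1]
  out <- peaklist(pl$spot_id, slope * pl$mz + intercept, pl$intensity,
                  calibrated = TRUE)
  out$calibration_refs <- refs
  out
}

#' Trypsin autolysis calibration anchors
#'
#' Monoisotopic `[M+H]+` of the two porcine-trypsin autolysis peptides
#' conventionally used as internal calibrants on MALDI-TOF PMF spectra
#' (quoted as m/z 842 and m/z 2211).
#' @return Named numeric vector `c(t842 = 842.5100, t2211 = 2211.1046)`.
#' @export
calibration_ions <- function() {
  c(t842 = 842.5100, t2211 = 2211.1046)
}

#' Match a peak list against a theoretical fingerprint
#'
#' Greedy one-to-one nearest-mass assignment: all (peak, peptide-state)
#' pairs within tolerance are ranked by absolute error and assigned in that
#' order, each peak and each (span, modification-state) row used at most
#' once. Coverage is the percentage of mature-chain residues of the
#' candidate's parent protein covered by the union of matched spans. The
#' score is the matched-peptide count (coverage is tie information), the
#' statistic the study reports as "percentage sequence covered (peptides
#' matched)".
#'
#' @param pl A [peaklist()].
#' @param fp A [digest()] fingerprint.
#' @param tol Tolerance value (> 0); default 50 ppm.
#' @param tol_unit `"PPM"` or `"DA"`.
#' @param accept_uncalibrated Set `TRUE` to match an uncalibrated list.
#' @return Object of class `match_result`: list with `fingerprint`,
#'   `assignments` (data.frame: `peak_index`, `mz`, `start`, `end`,
#'   `sequence`, `mods`, `mh_mono`, `error_da`, `error_ppm`),
#'   `matched_count`, `coverage_pct`, `score`.
#' @export
match_peaks <- function(pl, fp, tol = 50, tol_unit = c("PPM", "DA"),
                        accept_uncalibrated = FALSE) {
  tol_unit <- match.arg(tol_unit)
  stopifnot(inherits(pl, "peak_list"), inherits(fp, "theoretical_fingerprint"))
  if (tol <= 0) stop("match_peaks: tol must be > 0", call. = FALSE)
  if (!pl$calibrated && !accept_uncalibrated) {
    stop("match_peaks: peak list is uncalibrated; calibrate() it or pass ",
         "accept_uncalibrated = TRUE", call. = FALSE)
  }
  pep <- fp$peptides
  pairs <- NULL
  if (length(pl$mz) && nrow(pep)) {
    err_da <- outer(pl$mz, pep$mh_mono, `-`)
    err_ppm <- sweep(err_da, 2L, pep$mh_mono, `/`) * 1e6
    within <- if (tol_unit == "PPM") abs(err_ppm) <= tol else abs(err_da) <= tol
    idx <- which(within, arr.ind = TRUE)
    if (nrow(idx)) {
      pairs <- data.frame(peak = idx[, 1], pep = idx[, 2],
                          error_da = err_da[idx], error_ppm = err_ppm[idx])
      key <- if (tol_unit == "PPM") abs(pairs$error_ppm) else abs(pairs$error_da)
      pairs <- pairs[order(key, pairs$peak, pairs$pep), , drop = FALSE]
    }
  }
  used_peak <- logical(length(pl$mz))
  used_pep <- logical(nrow(pep))
  take <- integer(0)
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$peak[r]; j <- pairs$pep[r]
      if (!used_peak[i] && !used_pep[j]) {
        used_peak[i] <- TRUE; used_pep[j] <- TRUE
        take <- c(take, r)
      }
    }
  }
  if (length(take)) {
    sel <- pairs[take, , drop = FALSE]
    assignments <- data.frame(
      peak_index = sel$peak, mz = pl$mz[sel$peak],
      start = pep$start[sel$pep], end = pep$end[sel$pep],
      sequence = pep$sequence[sel$pep], mods = pep$mods[sel$pep],
      mh_mono = pep$mh_mono[sel$pep],
      error_da = sel$error_da, error_ppm = sel$error_ppm,
      stringsAsFactors = FALSE)
    assignments <- assignments[order(assignments$peak_index), , drop = FALSE]
    rownames(assignments) <- NULL
  } else {
    assignments <- data.frame(
      peak_index = integer(0), mz = numeric(0), start = integer(0),
      end = integer(0), sequence = character(0), mods = character(0),
      mh_mono = numeric(0), error_da = numeric(0), error_ppm = numeric(0),
      stringsAsFactors = FALSE)
  }
  chain_len <- nchar(mature_chain(fp$form$protein))
  covered <- rep(FALSE, chain_len)
  for (r in seq_len(nrow(assignments))) {
    covered[assignments$start[r]:assignments$end[r]] <- TRUE
  }
  coverage <- 100 * sum(covered) / chain_len
  structure(
    list(fingerprint = fp, assignments = assignments,
         matched_count = nrow(assignments), coverage_pct = coverage,
         score = nrow(assignments)),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s: %d matched, %.0f%% coverage\n",
              x$fingerprint$form$protein$id, x$matched_count, x$coverage_pct))
  invisible(x)
}

candidate_key <- function(fp) {
  p <- fp$form$protein
  if (nzchar(p$accession)) p$accession else p$id
}

#' Ranked identification of one spot over a candidate set
#'
#' Runs [match_peaks()] per candidate fingerprint; candidates reaching
#' `min_matched` matched peptides are accepted; the ranking is strictly
#' ordered by (score, coverage, accession/id) and `mixture_flag` is raised
#' when two or more candidates are accepted (the study's two-protein spots).
#'
#' @inheritParams match_peaks
#' @param candidates Non-empty list of [digest()] fingerprints.
#' @param min_matched Acceptance threshold on matched peptides (default 4).
#' @return Object of class `identification`: list with `spot_id`, `ranked`
#'   (list of `list(fingerprint, result, accepted)` in rank order),
#'   `mixture_flag`, `min_matched`.
#' @export
identify_spot <- function(pl, candidates, tol = 50, tol_unit = c("PPM", "DA"),
                          min_matched = 4L, accept_uncalibrated = FALSE) {
  tol_unit <- match.arg(tol_unit)
  if (!length(candidates)) stop("identify_spot: empty candidate set",
                                call. = FALSE)
  results <- lapply(candidates, function(fp) {
    match_peaks(pl, fp, tol, tol_unit, accept_uncalibrated)
  })
  scores <- vapply(results, `[[`, numeric(1), "score")
  cover <- vapply(results, `[[`, numeric(1), "coverage_pct")
  keys <- vapply(candidates, candidate_key, character(1))
  ord <- order(-scores, -cover, keys)
  ranked <- lapply(ord, function(i) {
    list(fingerprint = candidates[[i]], result = results[[i]],
         accepted = results[[i]]$matched_count >= min_matched)
  })
  structure(
    list(spot_id = pl$spot_id, ranked = ranked,
         mixture_flag = sum(vapply(ranked, `[[`, logical(1), "accepted")) >= 2L,
         min_matched = as.integer(min_matched), tol = tol,
         tol_unit = tol_unit),
    class = "identification"
  )
}

#' @export
print.identification <- function(x, ...) {
  cat(sprintf("<identification> %s (mixture: %s)\n", x$spot_id,
              x$mixture_flag))
  for (r in x$ranked) {
    cat(sprintf("  %s%s: %d matched, %.0f%%\n",
                r$fingerprint$form$protein$id,
                if (r$accepted) " [accepted]" else "",
                r$result$matched_count, r$result$coverage_pct))
  }
  invisible(x)
}

#' Summarize an identification as a data.frame
#' @param id An [identify_spot()] result.
#' @return data.frame with one row per candidate in rank order.
#' @export
identification_table <- function(id) {
  stopifnot(inherits(id, "identification"))
  do.call(rbind, lapply(seq_along(id$ranked), function(k) {
    r <- id$ranked[[k]]
    data.frame(spot_id = id$spot_id, rank = k,
               id = r$fingerprint$form$protein$id,
               accession = r$fingerprint$form$protein$accession,
               matched = r$result$matched_count,
               coverage_pct = round(r$result$coverage_pct),
               accepted = r$accepted, mixture_flag = id$mixture_flag,
               stringsAsFactors = FALSE)
  }))
}

#' Scan matched peaks for near-isobaric alternatives
#'
#' For each matched peak of each accepted candidate (all candidates when
#' none is accepted), lists alternative theoretical peptides from ANY
#' candidate whose mass lies within tolerance of the peak — e.g. the
#' near-isobaric splice-variant pair around m/z 1498 that distinguishes the
#' two OBP variants only below ~0.1 Da.
#'
#' @param id An [identify_spot()] result.
#' @param tol Tolerance value; interpreted in `tol_unit`.
#' @param tol_unit `"DA"` or `"PPM"`.
#' @return data.frame of notes: `spot_id`, `mz`, `candidate`, `start`,
#'   `end`, `alt_candidate`, `alt_start`, `alt_end`, `alt_mods`,
#'   `delta_da`.
#' @export
ambiguity_scan <- function(id, tol = 0.15, tol_unit = c("DA", "PPM")) {
  tol_unit <- match.arg(tol_unit)
  stopifnot(inherits(id, "identification"))
  use <- Filter(function(r) r$accepted, id$ranked)
  if (!length(use)) use <- id$ranked
  notes <- list()
  for (r in use) {
    asg <- r$result$assignments
    for (k in seq_len(nrow(asg))) {
      for (alt in id$ranked) {
        pep <- alt$fingerprint$peptides
        d <- abs(pep$mh_mono - asg$mz[k])
        lim <- if (tol_unit == "DA") tol else tol * asg$mz[k] / 1e6
        hit <- which(d <= lim)
        for (j in hit) {
          same_candidate <- identical(alt$fingerprint, r$fingerprint)
          if (same_candidate && pep$start[j] == asg$start[k] &&
              pep$end[j] == asg$end[k] && pep$mods[j] == asg$mods[k]) next
          notes[[length(notes) + 1L]] <- data.frame(
            spot_id = id$spot_id, mz = asg$mz[k],
            candidate = r$fingerprint$form$protein$id,
            start = asg$start[k], end = asg$end[k],
            alt_candidate = alt$fingerprint$form$protein$id,
            alt_start = pep$start[j], alt_end = pep$end[j],
            alt_mods = pep$mods[j], delta_da = d[j],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(notes)) {
    return(data.frame(spot_id = character(0), mz = numeric(0),
                      candidate = character(0), start = integer(0),
                      end = integer(0), alt_candidate = character(0),
                      alt_start = integer(0), alt_end = integer(0),
                      alt_mods = character(0), delta_da = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, notes)
  rownames(out) <- NULL
  out
}
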