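# Proteoform status per spot from the matched-peptide footprint:
# N-terminal truncation, C-terminal residue state (des-Lys), and
# gel-position consistency (dimer / truncation flags).

first_last_fragments <- function(chain, params) {
  sites <- cleavage_sites(chain, params)
  L <- nchar(chain)
  list(first = c(1L, if (length(sites)) sites[1] else L),
       last = c(if (length(sites)) sites[length(sites)] + 1L else 1L, L))
}

span_observable <- function(fp, span) {
  # a fragment is observable when at least one of its modification states
  # survived the fingerprint's length and mass-window filters
  rows <- find_peptide(fp, span)
  nrow(rows) > 0L
}

#' Call terminal status from a full-length match
#'
#' Against the FULL-LENGTH fingerprint of a candidate: the N-terminus is
#' `PRESENT` when a matched peptide starts at mature position 1; `ABSENT`
#' when no matched peptide overlaps the first tryptic fragment AND that
#' fragment was observable (some modification state inside the mass window
#' and length bounds) — absence of evidence only counts when the instrument
#' could have seen the fragment; `UNDETERMINED` otherwise. Symmetric logic
#' for the C-terminus with the last fragment. The inferred span is the
#' evidence hull `[min matched start, max matched end]`: truncation
#' breakpoints are only resolvable to tryptic-fragment granularity, so when
#' a terminus is ABSENT the exact proteoform boundary inside the unmatched
#' terminal region is unknown (`EXACT_BOUNDARY_UNKNOWN` note).
#'
#' @param mr A [match_peaks()] result computed against a full-length
#'   fingerprint.
#' @param params Digestion parameters; defaults to the fingerprint's own.
#' @return Object of class `terminal_call`: `n_status`, `c_status`
#'   (`"PRESENT"`, `"ABSENT"` or `"UNDETERMINED"`), `inferred_span` (NA pair
#'   when nothing matched, with `empty_match` flag), `evidence` (first/last
#'   fragment spans, their observability, matched spans), `notes`.
#' @export
call_terminals <- function(mr, params = NULL) {
  stopifnot(inherits(mr, "match_result"))
  fp <- mr$fingerprint
  if (is.null(params)) params <- fp$params
  chain <- proteoform_chain(fp$form)
  offset <- fp$form$span[1] - 1L
  fl <- first_last_fragments(chain, params)
  first_span <- fl$first + offset
  last_span <- fl$last + offset
  chain_end <- fp$form$span[2]
  asg <- mr$assignments
  if (!nrow(asg)) {
    return(structure(
      list(n_status = "UNDETERMINED", c_status = "UNDETERMINED",
           inferred_span = c(NA_integer_, NA_integer_), empty_match = TRUE,
           evidence = list(first_fragment = first_span,
                           last_fragment = last_span,
                           first_observable = span_observable(fp, first_span),
                           last_observable = span_observable(fp, last_span),
                           matched_spans = asg[, c("start", "end")]),
           notes = "EMPTY_MATCH"),
      class = "terminal_call"))
  }
  overlaps <- function(span) any(asg$start <= span[2] & asg$end >= span[1])
  n_obs <- span_observable(fp, first_span)
  c_obs <- span_observable(fp, last_span)
  n_status <- if (any(asg$start == fp$form$span[1])) "PRESENT"
  else if (!overlaps(first_span) && n_obs) "ABSENT"
  else "UNDETERMINED"
  c_status <- if (any(asg$end == chain_end)) "PRESENT"
  else if (!overlaps(last_span) && c_obs) "ABSENT"
  else "UNDETERMINED"
  notes <- character(0)
  if (n_status == "ABSENT" || c_status == "ABSENT") {
    notes <- c(notes, "EXACT_BOUNDARY_UNKNOWN")
  }
  structure(
    list(n_status = n_status, c_status = c_status,
         inferred_span = c(min(asg$start), max(asg$end)), empty_match = FALSE,
         evidence = list(first_fragment = first_span,
                         last_fragment = last_span,
                         first_observable = n_obs, last_observable = c_obs,
                         matched_spans = asg[, c("start", "end")]),
         notes = notes),
    class = "terminal_call"
  )
}

#' @export
print.terminal_call <- function(x, ...) {
  cat(sprintf("<terminal_call> N:%s C:%s span [%s-%s]\n", x$n_status,
              x$c_status, x$inferred_span[1], x$inferred_span[2]))
  invisible(x)
}

#' Test the C-terminal-residue state (des-Lys) against a peak list
#'
#' Builds the two C-terminal peptide hypotheses of a protein whose mature
#' chain ends in K or R — the zero-missed C-terminal tryptic peptide with
#' the terminal residue, and the one of the chain lacking it (des-Lys
#' style, the study's diagnostic peak at the [138-157] peptide ending in
#' Ala) — and checks which has peak support within tolerance.
#'
#' @param pl A [peaklist()].
#' @param protein A [protein_record()].
#' @param params A [digest_params()].
#' @param tol,tol_unit Matching tolerance (default 50 ppm).
#' @return List of class `cterm_call`: `status` one of `"FULL"`, `"DES_K"`,
#'   `"BOTH"`, `"NEITHER"`, plus the hypothesis spans/masses and which
#'   peaks supported them. For a chain not ending in K/R only the FULL
#'   hypothesis is tested (status `"FULL"` or `"NEITHER"`).
#' @export
call_cterm_variant <- function(pl, protein, params = digest_params(),
                               tol = 50, tol_unit = c("PPM", "DA")) {
  tol_unit <- match.arg(tol_unit)
  stopifnot(inherits(pl, "peak_list"), inherits(protein, "protein_record"))
  chain <- mature_chain(protein)
  L <- nchar(chain)
  supported <- function(fp) {
    fl <- first_last_fragments(proteoform_chain(fp$form), fp$params)
    span <- fl$last + fp$form$span[1] - 1L
    rows <- find_peptide(fp, span)
    rows <- rows[rows$missed == 0L, , drop = FALSE]
    hits <- logical(0)
    for (mh in rows$mh_mono) {
      lim <- if (tol_unit == "DA") tol else tol * mh / 1e6
      hits <- c(hits, any(abs(pl$mz - mh) <= lim))
    }
    list(span = span, mh = rows$mh_mono, supported = any(hits))
  }
  full <- supported(digest(proteoform(protein), params))
  ends_kr <- substr(chain, L, L) %in% c("K", "R")
  if (!ends_kr) {
    status <- if (full$supported) "FULL" else "NEITHER"
    return(structure(list(status = status, full = full, des = NULL),
                     class = "cterm_call"))
  }
  des <- supported(digest(apply_truncation(proteoform(protein), c(1L, L - 1L)),
                          params))
  status <- if (full$supported && des$supported) "BOTH"
  else if (full$supported) "FULL"
  else if (des$supported) "DES_K"
  else "NEITHER"
  structure(list(status = status, full = full, des = des),
            class = "cterm_call")
}

#' Annotate a spot: terminal calls plus gel-position consistency
#'
#' For each accepted candidate of an identification: terminal status from
#' the matched footprint, predicted (pI, MW) from the candidate chain, and
#' one of three mutually exclusive gel flags. `DIMER` when observed MW over
#' predicted monomer MW falls in `dimer_band` (spots near twice the
#' theoretical mass); `TRUNCATED` when the observed MW deficit exceeds
#' `truncation_deficit` AND the N-terminus was called ABSENT (the low-MW
#' N-less isoforms); `CONSISTENT` otherwise.
#'
#' @param id An [identify_spot()] result whose candidates are full-length
#'   fingerprints.
#' @param observed List/`gel_coordinate` with `pi` and `mw_kda` (either may
#'   be `NA`; gel flags then degrade to `"NO_GEL_DATA"`).
#' @param dimer_band Observed/predicted monomer MW ratio band for the dimer
#'   call.
#' @param truncation_deficit Fractional MW deficit required for TRUNCATED.
#' @param pka pKa set for the predicted pI.
#' @return Object of class `spot_annotation`: `spot_id`, `identification`,
#'   `observed`, and `calls` — one entry per accepted candidate with
#'   `candidate`, `terminal`, `predicted`, `gel_flag`, `mw_ratio`.
#' @export
annotate_spot <- function(id, observed = list(pi = NA_real_, mw_kda = NA_real_),
                          dimer_band = c(1.8, 2.2),
                          truncation_deficit = 0.15,
                          pka = pka_bjellqvist()) {
  stopifnot(inherits(id, "identification"))
  accepted <- Filter(function(r) r$accepted, id$ranked)
  calls <- lapply(accepted, function(r) {
    term <- call_terminals(r$result)
    predicted <- predict_spot(r$fingerprint$form, pka)
    monomer_mw <- predicted$mw_kda / r$fingerprint$form$multimer
    if (is.na(observed$mw_kda)) {
      flag <- "NO_GEL_DATA"; ratio <- NA_real_
    } else {
      ratio <- observed$mw_kda / monomer_mw
      flag <- if (ratio >= dimer_band[1] && ratio <= dimer_band[2]) "DIMER"
      else if (observed$mw_kda < (1 - truncation_deficit) * monomer_mw &&
               term$n_status == "ABSENT") "TRUNCATED"
      else "CONSISTENT"
    }
    list(candidate = r$fingerprint$form$protein$id, terminal = term,
         predicted = predicted, gel_flag = flag, mw_ratio = ratio)
  })
  structure(
    list(spot_id = id$spot_id, identification = id, observed = observed,
         calls = calls),
    class = "spot_annotation"
  )
}

#' @export
print.spot_annotation <- function(x, ...) {
  cat(sprintf("<spot_annotation> %s: %d call(s)\n", x$spot_id,
              length(x$calls)))
  for (cl in x$calls) {
    cat(sprintf("  %s: N %s / C %s, %s\n", cl$candidate,
                cl$terminal$n_status, cl$terminal$c_status, cl$gel_flag))
  }
  invisible(x)
}

#' Flatten spot annotations to the report table
#' @param annotations List of [annotate_spot()] results.
#' @return data.frame: `spot_id`, `candidate`, `n_status`, `c_status`,
#'   `inferred_start`, `inferred_end`, `gel_flag`.
#' @export
annotation_table <- function(annotations) {
  if (inherits(annotations, "spot_annotation")) {
    annotations <- list(annotations)
  }
  rows <- list()
  for (ann in annotations) {
    for (cl in ann$calls) {
      rows[[length(rows) + 1L]] <- data.frame(
        spot_id = ann$spot_id, candidate = cl$candidate,
        n_status = cl$terminal$n_status, c_status = cl$terminal$c_status,
        inferred_start = cl$terminal$inferred_span[1],
        inferred_end = cl$terminal$inferred_span[2],
        gel_flag = cl$gel_flag, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(spot_id = character(0), candidate = character(0),
                      n_status = character(0), c_status = character(0),
                      inferred_start = integer(0), inferred_end = integer(0),
                      gel_flag = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
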