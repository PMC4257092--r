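# In-silico trypsin digestion with missed cleavages, variable-modification
# state enumeration, fingerprint construction and splice-variant diagnostic
# peptide discovery.

#' Digestion parameters
#'
#' @param enzyme Rule identifier; only `"TRYPSIN"` (cleave after K or R) is
#'   implemented.
#' @param no_p_rule Suppress cleavage when the next residue is Pro (Keil
#'   convention). Default `TRUE`.
#' @param max_missed Maximum missed cleavages (default 2, the study's PMF
#'   setting).
#' @param min_len,max_len Peptide length bounds.
#' @param mass_window `(min_da, max_da)` window on `[M+H]+` for reporting,
#'   default `c(500, 4000)` (reflector MALDI range).
#' @param var_mods List of VARIABLE [modification()]s to enumerate; default
#'   propionamide on Cys (all-or-none) and up to two Met oxidations.
#' @param max_states Per-peptide cap on enumerated modification states;
#'   exceeding it prunes deterministically (lowest total counts kept) with a
#'   warning.
#' @return Object of class `digest_params`.
#' @export
digest_params <- function(enzyme = "TRYPSIN", no_p_rule = TRUE,
                          max_missed = 2L, min_len = 1L, max_len = 1000L,
                          mass_window = c(500, 4000),
                          var_mods = NULL, max_states = 64L) {
  if (!identical(enzyme, "TRYPSIN")) stop("unsupported enzyme: ", enzyme)
  if (is.null(var_mods)) {
    mods <- builtin_modifications()
    var_mods <- list(mods$propionamide, mods$oxidation)
  }
  stopifnot(min_len >= 1L, max_missed >= 0L,
            length(mass_window) == 2L, mass_window[1] < mass_window[2],
            all(vapply(var_mods, inherits, logical(1), "modification")))
  structure(
    list(enzyme = enzyme, no_p_rule = no_p_rule,
         max_missed = as.integer(max_missed), min_len = as.integer(min_len),
         max_len = as.integer(max_len), mass_window = as.numeric(mass_window),
         var_mods = var_mods, max_states = as.integer(max_states)),
    class = "digest_params"
  )
}

#' Tryptic cleavage sites
#'
#' Positions `i` (1-based, within the given chain) after which trypsin cuts:
#' `chain[i]` is K or R and, under the Keil rule, `chain[i+1]` is not P.
#' The final residue is not a site (cleavage there is just the chain end).
#'
#' @param chain Amino-acid string.
#' @param params A [digest_params()].
#' @return Increasing integer vector of positions (possibly empty).
#' @export
cleavage_sites <- function(chain, params = digest_params()) {
  stopifnot(nzchar(chain))
  aa <- strsplit(chain, "")[[1]]
  n <- length(aa)
  cand <- which(aa %in% c("K", "R"))
  cand <- cand[cand < n]
  if (params$no_p_rule && length(cand)) {
    cand <- cand[aa[cand + 1L] != "P"]
  }
  cand
}

# enumerate variable-mod count vectors for one peptide; returns a list of
# integer vectors (one count per var mod), pruned deterministically at cap
enumerate_mod_states <- function(sequence, var_mods, max_states) {
  if (!length(var_mods)) return(list(integer(0)))
  aa <- strsplit(sequence, "")[[1]]
  per_mod <- lapply(var_mods, function(mod) {
    residue_targets <- setdiff(mod$targets, c("N-TERM", "C-TERM"))
    n_sites <- sum(aa %in% residue_targets) +
      sum(c("N-TERM", "C-TERM") %in% mod$targets)
    n_max <- min(n_sites, mod$max_per_peptide)
    if (isTRUE(mod$all_or_none)) unique(c(0L, n_max)) else 0L:n_max
  })
  grid <- expand.grid(per_mod, KEEP.OUT.ATTRS = FALSE)
  states <- lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
  if (length(states) > max_states) {
    warning("modification-state cap exceeded for '", sequence,
            "'; keeping the ", max_states, " lowest-count states",
            call. = FALSE)
    totals <- vapply(states, sum, integer(1))
    states <- states[order(totals, seq_along(states))][seq_len(max_states)]
  }
  states
}

mod_state_label <- function(var_mods, counts) {
  keep <- counts > 0L
  if (!any(keep)) return("")
  paste(sprintf("%s x%d",
                vapply(var_mods[keep], `[[`, character(1), "name"),
                counts[keep]),
        collapse = ";")
}

#' Theoretical tryptic fingerprint of a proteoform
#'
#' Peptides are all runs of at most `max_missed + 1` consecutive zero-missed
#' fragments of the proteoform chain, filtered by length bounds; every
#' placeable combination of the variable modifications yields one row, and
#' rows are kept when their monoisotopic `[M+H]+` falls inside
#' `mass_window`. Spans are reported in mature coordinates of the PARENT
#' protein, so truncated forms keep the parent numbering.
#'
#' @param form A [proteoform()].
#' @param params A [digest_params()].
#' @return Object of class `theoretical_fingerprint`: list with `form`,
#'   `params` and `peptides`, a data.frame with columns `start`, `end`,
#'   `sequence`, `missed`, `mods`, `mh_mono`, sorted by
#'   `(start, end, mh_mono)`.
#' @export
digest <- function(form, params = digest_params()) {
  if (inherits(form, "protein_record")) form <- proteoform(form)
  stopifnot(inherits(form, "proteoform"), inherits(params, "digest_params"))
  chain <- proteoform_chain(form)
  offset <- form$span[1] - 1L
  sites <- cleavage_sites(chain, params)
  fs <- c(1L, sites + 1L)          # zero-missed fragment starts
  fe <- c(sites, nchar(chain))     # zero-missed fragment ends
  f <- length(fs)
  fixed_pairs_for <- function(seq) {
    lapply(form$fixed_mods, function(mod) {
      residue_targets <- setdiff(mod$targets, c("N-TERM", "C-TERM"))
      list(mod, sum(strsplit(seq, "")[[1]] %in% residue_targets))
    })
  }
  var_deltas <- vapply(params$var_mods, `[[`, numeric(1), "mono_delta")
  col_start <- list(); col_end <- list(); col_seq <- list()
  col_missed <- list(); col_mods <- list(); col_mh <- list()
  for (w in seq_len(params$max_missed + 1L)) {
    if (f - w + 1L < 1L) break
    for (i in seq_len(f - w + 1L)) {
      s <- fs[i]; e <- fe[i + w - 1L]
      len <- e - s + 1L
      if (len < params$min_len || len > params$max_len) next
      seq_i <- substr(chain, s, e)
      base_mass <- peptide_mass(seq_i, fixed_pairs_for(seq_i), "MONO")
      states <- enumerate_mod_states(seq_i, params$var_mods, params$max_states)
      mh <- vapply(states, function(counts) {
        mz_mh(base_mass + sum(counts * var_deltas))
      }, numeric(1))
      keep <- mh >= params$mass_window[1] & mh <= params$mass_window[2]
      if (!any(keep)) next
      n_keep <- sum(keep)
      k <- length(col_start) + 1L
      col_start[[k]] <- rep.int(s + offset, n_keep)
      col_end[[k]] <- rep.int(e + offset, n_keep)
      col_seq[[k]] <- rep.int(seq_i, n_keep)
      col_missed[[k]] <- rep.int(w - 1L, n_keep)
      col_mods[[k]] <- vapply(states[keep], function(counts) {
        mod_state_label(params$var_mods, counts)
      }, character(1))
      col_mh[[k]] <- mh[keep]
    }
  }
  peptides <- data.frame(
    start = as.integer(unlist(col_start)), end = as.integer(unlist(col_end)),
    sequence = as.character(unlist(col_seq)),
    missed = as.integer(unlist(col_missed)),
    mods = as.character(unlist(col_mods)),
    mh_mono = as.numeric(unlist(col_mh)), stringsAsFactors = FALSE)
  peptides <- peptides[order(peptides$start, peptides$end, peptides$mh_mono), ,
                       drop = FALSE]
  rownames(peptides) <- NULL
  structure(list(form = form, peptides = peptides, params = params),
            class = "theoretical_fingerprint")
}

#' @export
print.theoretical_fingerprint <- function(x, ...) {
  cat(sprintf("<theoretical_fingerprint> %s [%d-%d]: %d peptide states\n",
              x$form$protein$id, x$form$span[1], x$form$span[2],
              nrow(x$peptides)))
  invisible(x)
}

#' Look up fingerprint peptides by span
#'
#' @param fp A [digest()] fingerprint.
#' @param span `(start, end)` in parent mature coordinates.
#' @return The data.frame rows (all modification states) whose span equals
#'   the query; zero rows when the span is not a tryptic product.
#' @export
find_peptide <- function(fp, span) {
  stopifnot(inherits(fp, "theoretical_fingerprint"))
  fp$peptides[fp$peptides$start == span[1] & fp$peptides$end == span[2], ,
              drop = FALSE]
}

#' Diagnostic peptides between two fingerprints
#'
#' Lists peptide sequences present in exactly one of two fingerprints (e.g.
#' two splice variants) and pairs each with the nearest-mass peptide of the
#' other fingerprint. A unique peptide is flagged `AMBIGUOUS` when that mass
#' gap is at or below `tolerance_da` (near-isobaric pair a MALDI-TOF survey
#' cannot separate), `RESOLVED` otherwise.
#'
#' @param a,b Fingerprints built with identical parameters.
#' @param tolerance_da Mass-gap threshold in Da.
#' @return data.frame with one row per unique peptide state: `side` ("a" or
#'   "b"), `start`, `end`, `sequence`, `mods`, `mh_mono`, `other_start`,
#'   `other_end`, `other_sequence`, `other_mh`, `delta_da`, `flag`.
#' @export
diagnostic_peptides <- function(a, b, tolerance_da = 0.15) {
  stopifnot(inherits(a, "theoretical_fingerprint"),
            inherits(b, "theoretical_fingerprint"))
  if (!identical(a$params, b$params)) {
    stop("diagnostic_peptides: fingerprints built with different params",
         call. = FALSE)
  }
  one_side <- function(x, y, side) {
    uniq <- x$peptides[!(x$peptides$sequence %in% y$peptides$sequence), ,
                       drop = FALSE]
    if (!nrow(uniq) || !nrow(y$peptides)) {
      uniq$side <- rep(side, nrow(uniq))
      uniq$other_start <- uniq$other_end <- integer(nrow(uniq))
      uniq$other_sequence <- character(nrow(uniq))
      uniq$other_mh <- uniq$delta_da <- numeric(nrow(uniq))
      uniq$flag <- character(nrow(uniq))
      return(uniq)
    }
    nearest <- vapply(uniq$mh_mono, function(m) {
      which.min(abs(y$peptides$mh_mono - m))
    }, integer(1))
    uniq$side <- side
    uniq$other_start <- y$peptides$start[nearest]
    uniq$other_end <- y$peptides$end[nearest]
    uniq$other_sequence <- y$peptides$sequence[nearest]
    uniq$other_mh <- y$peptides$mh_mono[nearest]
    uniq$delta_da <- abs(uniq$mh_mono - uniq$other_mh)
    uniq$flag <- ifelse(uniq$delta_da <= tolerance_da, "AMBIGUOUS", "RESOLVED")
    uniq
  }
  out <- rbind(one_side(a, b, "a"), one_side(b, a, "b"))
  rownames(out) <- NULL
  out
}
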