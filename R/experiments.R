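# Seeded parameter-recovery experiments on synthetic data. These are the
# package's calibration-of-trust runs: they measure how reliably the
# pipeline recovers what the simulator put in, under the stated noise
# model (10 ppm mass error, 20% dropout, 5 decoy candidates).

derive_seed <- function(seed, r) {
  # replicate seeds spread out but kept well below .Machine$integer.max
  (as.integer(seed) %% 10000L) * 100000L + r
}

#' Top-1 identification experiment
#'
#' Per replicate: draw a fresh synthetic proteome of `n_decoys + 1`
#' proteins, emit one spot from the first (true) protein under the noise
#' model, identify it against all candidates, and record whether the true
#' protein ranks first.
#'
#' @param n_reps Number of replicates.
#' @param seed Base seed; replicate `r` uses a seed derived from it.
#' @param error_ppm_sd,dropout,n_noise_peaks Noise model.
#' @param n_decoys Decoy candidates per replicate.
#' @return List: `top1_rate`, `n_reps`, `failures` (replicate indices).
#' @export
experiment_identification <- function(n_reps = 200L, seed = 1L,
                                      error_ppm_sd = 10, dropout = 0.2,
                                      n_noise_peaks = 5L, n_decoys = 5L) {
  hits <- logical(n_reps); failures <- integer(0)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(seed = derive_seed(seed, r),
                      n_proteins = n_decoys + 1L,
                      error_ppm_sd = error_ppm_sd, dropout = dropout,
                      n_noise_peaks = n_noise_peaks)
    sim <- simulate_proteome(cfg)
    cands <- lapply(sim$proteins, function(p) digest(proteoform(p), cfg$digest))
    sp <- simulate_spot(proteoform(sim$proteins[[1]]), cfg, "s")
    id <- identify_spot(sp$peaklist, cands)
    hits[r] <- id$ranked[[1]]$fingerprint$form$protein$id ==
      sim$proteins[[1]]$id
    if (!hits[r]) failures <- c(failures, r)
  }
  list(top1_rate = mean(hits), n_reps = n_reps, failures = failures)
}

#' N-terminal truncation recovery experiment
#'
#' Per replicate: draw one synthetic protein whose first tryptic fragment
#' is observable, truncate it at the first tryptic boundary, emit a spot
#' under the noise model, match against the FULL-LENGTH fingerprint and
#' call terminals. Records the rate of correct ABSENT calls, of exact
#' evidence-hull starts, and any false C-terminal ABSENT call (the
#' C-terminus is always truly present here).
#'
#' @inheritParams experiment_identification
#' @return List: `absent_rate`, `hull_rate`, `absent_and_hull_rate`,
#'   `c_false_absent` (count), `n_reps`.
#' @export
experiment_truncation <- function(n_reps = 200L, seed = 1L,
                                  error_ppm_sd = 10, dropout = 0.2,
                                  n_noise_peaks = 10L) {
  absent <- logical(n_reps); hull <- logical(n_reps)
  c_false <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(seed = derive_seed(seed, r), n_proteins = 1L,
                      length_range = c(100L, 180L),
                      error_ppm_sd = error_ppm_sd, dropout = dropout,
                      n_noise_peaks = n_noise_peaks)
    repeat {
      sim <- simulate_proteome(cfg)
      prot <- sim$proteins[[1]]
      fp <- digest(proteoform(prot), cfg$digest)
      sites <- cleavage_sites(prot$sequence, cfg$digest)
      if (length(sites) &&
          nrow(find_peptide(fp, c(1L, sites[1]))) > 0L) break
      cfg$seed <- cfg$seed + 1L  # redraw until the first fragment is observable
    }
    k <- sites[1] + 1L
    dn <- apply_truncation(proteoform(prot), c(k, nchar(prot$sequence)))
    sp <- simulate_spot(dn, cfg, "s")
    tc <- call_terminals(match_peaks(sp$peaklist, fp, 50, "PPM"))
    absent[r] <- tc$n_status == "ABSENT"
    hull[r] <- isTRUE(tc$inferred_span[1] == k)
    if (tc$c_status == "ABSENT") c_false <- c_false + 1L
  }
  list(absent_rate = mean(absent), hull_rate = mean(hull),
       absent_and_hull_rate = mean(absent & hull),
       c_false_absent = c_false, n_reps = n_reps)
}
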