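# four tryptic fragments of comfortable MALDI mass (all inside 500-4000 Da)
infer_chain <- function(last = "LLLNNNQQK") {
  paste0("AAADDDEEK", "GGGFFFVVK", "HHHWWWTTK", last)
}

noiseless_cfg <- function(seed = 1) {
  sim_config(seed = seed, dropout = 0, error_ppm_sd = 0, n_noise_peaks = 0)
}

full_match <- function(protein, forms, seed = 1) {
  cfg <- noiseless_cfg(seed)
  sp <- simulate_spot(forms, cfg, "s", seed = seed)
  fp <- digest(proteoform(protein), cfg$digest)
  list(mr = match_peaks(sp$peaklist, fp, 50, "PPM"), spot = sp, fp = fp)
}

test_that("call_terminals sees both termini on a full-length noiseless spot", {
  prot <- protein_record("p", infer_chain())
  res <- full_match(prot, proteoform(prot))
  tc <- call_terminals(res$mr)
  expect_equal(tc$n_status, "PRESENT")
  expect_equal(tc$c_status, "PRESENT")
  expect_equal(tc$inferred_span, c(1L, 36L))
})

test_that("call_terminals calls ABSENT only on observable missing termini", {
  prot <- protein_record("p", infer_chain())
  dn <- apply_truncation(proteoform(prot), c(10, 36))
  res <- full_match(prot, dn)
  tc <- call_terminals(res$mr)
  expect_equal(tc$n_status, "ABSENT")
  expect_equal(tc$c_status, "PRESENT")
  expect_equal(tc$inferred_span, c(10L, 36L))
  expect_true("EXACT_BOUNDARY_UNKNOWN" %in% tc$notes)

  # tiny first fragment (AK, ~218 Da) is below the mass window: its absence
  # is unobservable, so the call degrades to UNDETERMINED
  prot2 <- protein_record("q", paste0("AK", infer_chain()))
  dn2 <- apply_truncation(proteoform(prot2), c(3, 38))
  res2 <- full_match(prot2, dn2)
  tc2 <- call_terminals(res2$mr)
  expect_equal(tc2$n_status, "UNDETERMINED")
})

test_that("empty matches yield UNDETERMINED with a flag", {
  prot <- protein_record("p", infer_chain())
  fp <- digest(proteoform(prot))
  mr <- match_peaks(peaklist("s", numeric(0), calibrated = TRUE), fp)
  tc <- call_terminals(mr)
  expect_equal(tc$n_status, "UNDETERMINED")
  expect_equal(tc$c_status, "UNDETERMINED")
  expect_true(tc$empty_match)
  expect_true(all(is.na(tc$inferred_span)))
})

test_that("ABSENT is never called for an unobservable terminal fragment", {
  set.seed(53)
  for (i in 1:30) {
    chain <- random_chain(sample(40:120, 1), p_kr = 0.2)
    prot <- protein_record("r", chain)
    window <- sort(runif(2, 400, 4200))
    if (diff(window) < 300) window[2] <- window[1] + 300
    params <- digest_params(mass_window = window)
    fp <- digest(proteoform(prot), params)
    if (!nrow(fp$peptides)) next
    # random dropout of peaks, including possibly all terminal evidence
    keep <- runif(nrow(fp$peptides)) < 0.5
    pl <- peaklist("s", unique(fp$peptides$mh_mono[keep]), calibrated = TRUE)
    tc <- call_terminals(match_peaks(pl, fp, 50, "PPM"))
    if (!tc$evidence$first_observable) expect_false(tc$n_status == "ABSENT")
    if (!tc$evidence$last_observable) expect_false(tc$c_status == "ABSENT")
  }
})

test_that("noiseless tryptic-boundary truncations are recovered exactly", {
  set.seed(59)
  done <- 0
  while (done < 10) {
    chain <- random_chain(sample(60:150, 1), p_kr = 0.18)
    prot <- protein_record("r", chain)
    params <- digest_params()
    fp <- digest(proteoform(prot), params)
    sites <- cleavage_sites(chain, params)
    if (!length(sites)) next
    k <- sites[1] + 1L  # truncation at the first tryptic boundary
    if (!span_obs_for_test(fp, c(1L, sites[1]))) next  # need observable F1
    dn <- apply_truncation(proteoform(prot), c(k, nchar(chain)))
    sp <- simulate_spot(dn, noiseless_cfg(done), "s", seed = done)
    tc <- call_terminals(match_peaks(sp$peaklist, fp, 50, "PPM"))
    expect_equal(tc$n_status, "ABSENT")
    # the evidence hull starts at the first OBSERVABLE peptide of the
    # truncated chain (a run of single K/R fragments at the breakpoint can
    # push it past k; PMF cannot resolve inside such runs)
    dn_pep <- digest(dn, params)$peptides
    expect_equal(tc$inferred_span[1], min(dn_pep$start))
    expect_false(tc$c_status == "ABSENT")
    done <- done + 1
  }
})

test_that("call_cterm_variant distinguishes full and des-Lys C-termini", {
  prot <- protein_record("p", infer_chain())  # ends ...QQK
  params <- digest_params()
  full_fp <- digest(proteoform(prot), params)
  des_fp <- digest(apply_truncation(proteoform(prot), c(1, 35)), params)
  mh_full <- find_peptide(full_fp, c(28, 36))$mh_mono[1]
  mh_des <- find_peptide(des_fp, c(28, 35))$mh_mono[1]
  expect_equal(mh_full - mh_des, 128.09496, tolerance = 1e-4)

  call_with <- function(mz) {
    call_cterm_variant(peaklist("s", mz, calibrated = TRUE), prot, params)
  }
  expect_equal(call_with(mh_des)$status, "DES_K")
  expect_equal(call_with(mh_full)$status, "FULL")
  expect_equal(call_with(c(mh_des, mh_full))$status, "BOTH")
  expect_equal(call_with(3999)$status, "NEITHER")

  # chain not ending in K/R: only the FULL hypothesis is testable
  prot2 <- protein_record("q", paste0(infer_chain(), "AAA"))
  cc <- call_cterm_variant(peaklist("s", 700, calibrated = TRUE), prot2,
                           params)
  expect_equal(cc$status, "NEITHER")
  expect_null(cc$des)
})

test_that("annotate_spot assigns mutually exclusive gel flags", {
  prot <- protein_record("p", infer_chain())
  pred_mw <- proteoform_mass(proteoform(prot), "AVG") / 1000

  # full-length spot, observed at the predicted position: CONSISTENT
  cfg <- noiseless_cfg()
  sp <- simulate_spot(proteoform(prot), cfg, "s", seed = 3)
  id <- identify_spot(sp$peaklist, list(digest(proteoform(prot), cfg$digest)))
  ann <- annotate_spot(id, list(pi = 4.2, mw_kda = pred_mw))
  expect_length(ann$calls, 1L)
  expect_equal(ann$calls[[1]]$gel_flag, "CONSISTENT")

  # same spot observed at twice the monomer mass: DIMER
  ann2 <- annotate_spot(id, list(pi = 4.2, mw_kda = 2.02 * pred_mw))
  expect_equal(ann2$calls[[1]]$gel_flag, "DIMER")

  # truncated content at clearly lower observed MW: TRUNCATED
  dn <- apply_truncation(proteoform(prot), c(10, 36))
  spt <- simulate_spot(dn, cfg, "t", seed = 4)
  idt <- identify_spot(spt$peaklist,
                       list(digest(proteoform(prot), cfg$digest)))
  annt <- annotate_spot(idt, list(pi = 4.2, mw_kda = 0.7 * pred_mw))
  expect_equal(annt$calls[[1]]$terminal$n_status, "ABSENT")
  expect_equal(annt$calls[[1]]$gel_flag, "TRUNCATED")

  # no gel data degrades gracefully
  ann3 <- annotate_spot(id, list(pi = NA_real_, mw_kda = NA_real_))
  expect_equal(ann3$calls[[1]]$gel_flag, "NO_GEL_DATA")

  tab <- annotation_table(list(ann, annt))
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$gel_flag, c("CONSISTENT", "TRUNCATED"))
})
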