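# Independent oracles and fixture builders used across the suite. These are
# deliberately naive re-implementations kept separate from the package code
# paths they check.

# residue-mass lookup independent of the package's TSV loader
ORACLE_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
ORACLE_WATER <- 18.010565
ORACLE_PROTON <- 1.007276

oracle_mono_mass <- function(seq) {
  sum(ORACLE_MONO[strsplit(seq, "")[[1]]]) + ORACLE_WATER
}

# naive tryptic scan (Keil rule), independent of cleavage_sites()
oracle_fragments <- function(chain, no_p_rule = TRUE) {
  aa <- strsplit(chain, "")[[1]]
  n <- length(aa)
  cut_after <- logical(n)
  for (i in seq_len(n - 1)) {
    if (aa[i] %in% c("K", "R") && (!no_p_rule || aa[i + 1] != "P")) {
      cut_after[i] <- TRUE
    }
  }
  starts <- c(1L, which(cut_after) + 1L)
  ends <- c(which(cut_after), n)
  data.frame(start = starts, end = ends,
             sequence = substring(chain, starts, ends),
             stringsAsFactors = FALSE)
}

# brute-force enumeration of all <= max_missed windows of fragments
oracle_peptides <- function(chain, max_missed, no_p_rule = TRUE) {
  fr <- oracle_fragments(chain, no_p_rule)
  f <- nrow(fr)
  out <- list()
  for (i in seq_len(f)) {
    for (j in i:min(f, i + max_missed)) {
      out[[length(out) + 1L]] <- data.frame(
        start = fr$start[i], end = fr$end[j],
        sequence = substr(chain, fr$start[i], fr$end[j]),
        missed = j - i, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# brute-force maximum one-to-one matching size on the within-tolerance graph
oracle_max_matching <- function(adj) {
  n <- length(adj)
  rec <- function(i, used) {
    if (i > n) return(0L)
    best <- rec(i + 1L, used)
    for (j in adj[[i]]) {
      if (!(j %in% used)) best <- max(best, 1L + rec(i + 1L, c(used, j)))
    }
    best
  }
  rec(1L, integer(0))
}

random_chain <- function(len, p_kr = 0.15) {
  aa <- setdiff(names(ORACLE_MONO), c("K", "R"))
  picks <- ifelse(stats::runif(len) < p_kr,
                  sample(c("K", "R"), len, replace = TRUE),
                  sample(aa, len, replace = TRUE))
  paste(picks, collapse = "")
}

# fingerprint object with hand-set peptide masses, for matcher unit tests
toy_fingerprint <- function(masses, spans = NULL, protein_len = 100L,
                            id = "toy") {
  seq <- paste(rep("A", protein_len), collapse = "")
  prot <- protein_record(id, seq)
  if (is.null(spans)) {
    spans <- cbind(seq_along(masses), seq_along(masses))
  }
  structure(
    list(form = proteoform(prot),
         peptides = data.frame(
           start = as.integer(spans[, 1]), end = as.integer(spans[, 2]),
           sequence = substring(seq, spans[, 1], spans[, 2]),
           missed = 0L, mods = "", mh_mono = as.numeric(masses),
           stringsAsFactors = FALSE),
         params = digest_params()),
    class = "theoretical_fingerprint")
}

# unfiltered digestion parameters: no length/mass/mod-state reduction
raw_params <- function(max_missed = 2L, no_p_rule = TRUE) {
  digest_params(max_missed = max_missed, no_p_rule = no_p_rule,
                min_len = 1L, max_len = 10000L,
                mass_window = c(1e-6, 1e9), var_mods = list())
}

span_obs_for_test <- function(fp, span) {
  nrow(find_peptide(fp, span)) > 0L
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
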