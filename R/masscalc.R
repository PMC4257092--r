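# Monoisotopic/average mass calculus, [M+H]+ conversion, Bjellqvist pI,
# and (pI, MW) gel-coordinate prediction.

# standard physical constants (Da); kept in code for bit-stable tests
PROTON_MASS <- 1.007276
WATER_MONO <- 18.010565
WATER_AVG <- 18.0153

.pmfspot_cache <- new.env(parent = emptyenv())

#' Residue mass tables
#'
#' Monoisotopic and average residue (amino-acid minus water) masses for the
#' 20 canonical letters, loaded from the auditable TSV shipped with the
#' package, plus water and proton constants.
#'
#' @return List with named numeric vectors `mono` and `avg`, and scalars
#'   `water_mono`, `water_avg`, `proton`.
#' @export
mass_tables <- function() {
  if (is.null(.pmfspot_cache$mass_tables)) {
    tab <- read.delim(pkg_table("residue_masses.tsv"), stringsAsFactors = FALSE)
    stopifnot(setequal(tab$residue, AA_ALPHABET), all(tab$mono > 0),
              all(tab$avg > 0))
    .pmfspot_cache$mass_tables <- list(
      mono = stats::setNames(tab$mono, tab$residue),
      avg = stats::setNames(tab$avg, tab$residue),
      water_mono = WATER_MONO, water_avg = WATER_AVG, proton = PROTON_MASS)
  }
  .pmfspot_cache$mass_tables
}

#' Bjellqvist pKa set
#'
#' The pKa values used by the ExPASy ProtParam family of tools: side-chain
#' pKa for D, E, C, Y, H, K, R and residue-dependent terminal pKa with
#' defaults. This is the package default because the study's printed pI
#' values were computed with ProtParam.
#'
#' @return List with named numeric vectors `side_chain`, `n_term`, `c_term`
#'   (terminal vectors carry a `"default"` entry).
#' @export
pka_bjellqvist <- function() {
  if (is.null(.pmfspot_cache$pka)) {
    tab <- read.delim(pkg_table("pka_bjellqvist.tsv"), stringsAsFactors = FALSE)
    stopifnot(all(tab$pka > 0 & tab$pka < 14))
    pick <- function(g) {
      rows <- tab[tab$group == g, ]
      stats::setNames(rows$pka, rows$residue)
    }
    .pmfspot_cache$pka <- list(side_chain = pick("side_chain"),
                               n_term = pick("n_term"), c_term = pick("c_term"))
  }
  .pmfspot_cache$pka
}

mod_counts_valid <- function(sequence, mod, count) {
  residue_targets <- setdiff(mod$targets, c("N-TERM", "C-TERM"))
  n_sites <- sum(strsplit(sequence, "")[[1]] %in% residue_targets) +
    sum(c("N-TERM", "C-TERM") %in% mod$targets)
  count <= n_sites
}

#' Neutral peptide mass
#'
#' Sum of residue masses plus one water, plus the mass deltas of the given
#' modification counts; strictly additive.
#'
#' @param sequence Canonical amino-acid string (non-empty).
#' @param mods List of `list(mod, count)` pairs, `mod` a [modification()].
#' @param kind `"MONO"` or `"AVG"`.
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass("GG") # 132.0535
#' @export
peptide_mass <- function(sequence, mods = list(), kind = c("MONO", "AVG")) {
  kind <- match.arg(kind)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("peptide_mass: empty peptide", call. = FALSE)
  check_canonical(sequence)
  tabs <- mass_tables()
  res <- if (kind == "MONO") tabs$mono else tabs$avg
  water <- if (kind == "MONO") tabs$water_mono else tabs$water_avg
  m <- sum(res[strsplit(sequence, "")[[1]]]) + water
  for (pair in mods) {
    mod <- pair[[1]]; count <- pair[[2]]
    stopifnot(inherits(mod, "modification"), count >= 0)
    if (!mod_counts_valid(sequence, mod, count)) {
      stop("modification '", mod$name, "' x", count,
           " not placeable on '", sequence, "'", call. = FALSE)
    }
    delta <- if (kind == "MONO") mod$mono_delta else mod$avg_delta
    m <- m + count * delta
  }
  unname(m)
}

#' Singly protonated ion mass
#' @param neutral_mass Neutral mass in Da (> 0).
#' @return `[M+H]+` in Da.
#' @export
mz_mh <- function(neutral_mass) {
  stopifnot(all(neutral_mass > 0))
  neutral_mass + PROTON_MASS
}

#' Proteoform mass
#'
#' Chain mass (with fixed modifications applied at all their target sites)
#' times the multimer count. Dimers are modeled as non-covalent: exactly
#' twice the monomer mass.
#'
#' @param form A [proteoform()].
#' @param kind `"MONO"` or `"AVG"`.
#' @return Mass in Da.
#' @export
proteoform_mass <- function(form, kind = c("MONO", "AVG")) {
  kind <- match.arg(kind)
  chain <- proteoform_chain(form)
  mods <- lapply(form$fixed_mods, function(mod) {
    residue_targets <- setdiff(mod$targets, c("N-TERM", "C-TERM"))
    n <- sum(strsplit(chain, "")[[1]] %in% residue_targets) +
      sum(c("N-TERM", "C-TERM") %in% mod$targets)
    list(mod, n)
  })
  form$multimer * peptide_mass(chain, mods, kind)
}

#' Net charge of a polypeptide at a given pH
#'
#' Henderson-Hasselbalch composition model: positive groups (N-terminus,
#' His, Lys, Arg side chains) contribute `1/(1+10^(pH-pKa))`, negative
#' groups (C-terminus, Asp, Glu, Cys, Tyr) contribute
#' `-1/(1+10^(pKa-pH))`. Continuous and strictly decreasing in pH.
#'
#' @param sequence Canonical amino-acid string.
#' @param pH pH value in (0, 14).
#' @param pka A pKa set as from [pka_bjellqvist()].
#' @return Signed net charge.
#' @export
net_charge <- function(sequence, pH, pka = pka_bjellqvist()) {
  stopifnot(nzchar(sequence), all(pH > 0 & pH < 14))
  check_canonical(sequence)
  aa <- strsplit(sequence, "")[[1]]
  counts <- table(factor(aa, levels = AA_ALPHABET))
  term_pka <- function(vec, residue) {
    if (residue %in% names(vec)) vec[[residue]] else vec[["default"]]
  }
  pos_pka <- c(term_pka(pka$n_term, aa[1]),
               rep(pka$side_chain[["H"]], counts[["H"]]),
               rep(pka$side_chain[["K"]], counts[["K"]]),
               rep(pka$side_chain[["R"]], counts[["R"]]))
  neg_pka <- c(term_pka(pka$c_term, aa[length(aa)]),
               rep(pka$side_chain[["D"]], counts[["D"]]),
               rep(pka$side_chain[["E"]], counts[["E"]]),
               rep(pka$side_chain[["C"]], counts[["C"]]),
               rep(pka$side_chain[["Y"]], counts[["Y"]]))
  vapply(pH, function(p) {
    sum(1 / (1 + 10^(p - pos_pka))) - sum(1 / (1 + 10^(neg_pka - p)))
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' Bisection root of [net_charge()] on pH in `[0, 14]`; deterministic, and
#' stable under tolerance refinement beyond the default `1e-3` pH units.
#' The model is composition-only: permuting the sequence (keeping the
#' terminal residues' pKa classes) does not change the result, and
#' modification charge effects are ignored, matching ProtParam behavior.
#'
#' @inheritParams net_charge
#' @param tol Bisection tolerance in pH units (> 0).
#' @return pI value.
#' @export
isoelectric_point <- function(sequence, pka = pka_bjellqvist(), tol = 1e-3) {
  stopifnot(tol > 0)
  lo <- 1e-6; hi <- 14 - 1e-6
  f_lo <- net_charge(sequence, lo, pka)
  if (f_lo <= 0) return(lo)   # degenerate: negative even at pH ~ 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Predicted 2-DE gel coordinate of a proteoform
#'
#' pI is computed on the monomeric chain (multimerization does not change
#' composition); apparent MW is the average proteoform mass in kDa, so a
#' dimer doubles MW and keeps pI.
#'
#' @param form A [proteoform()].
#' @param pka pKa set.
#' @return List of class `gel_coordinate` with fields `pi`, `mw_kda`.
#' @export
predict_spot <- function(form, pka = pka_bjellqvist()) {
  structure(
    list(pi = isoelectric_point(proteoform_chain(form), pka),
         mw_kda = proteoform_mass(form, "AVG") / 1000),
    class = "gel_coordinate"
  )
}

#' @export
print.gel_coordinate <- function(x, ...) {
  cat(sprintf("<gel_coordinate> pI %.2f, %.1f kDa\n", x$pi, x$mw_kda))
  invisible(x)
}
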