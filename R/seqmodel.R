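# Domain types: proteins, modifications, proteoforms; FASTA I/O; accession
# registry. Coordinates are 1-based inclusive and always refer to the MATURE
# chain (the chain left after signal-peptide removal); precursor numbering is
# never exposed.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Protein record
#'
#' A named amino-acid sequence with an optional database accession and a
#' mature-chain annotation. `mature_span` gives the 1-based inclusive
#' positions of the mature chain within `sequence`; it defaults to the whole
#' sequence when no signal peptide is annotated.
#'
#' @param id Short unique label.
#' @param sequence Amino-acid string over the 20 canonical letters
#'   (uppercased; whitespace and `*` stop symbols are stripped).
#' @param accession Free-text database identifier; may be empty.
#' @param mature_span Integer pair `(start, end)`, 1-based inclusive.
#' @param description Free text.
#' @return An object of class `protein_record`.
#' @examples
#' p <- protein_record("p1", "MKGAR", mature_span = c(3, 5))
#' mature_chain(p)
#' @export
protein_record <- function(id, sequence, accession = "",
                           mature_span = NULL, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_sequence(sequence)
  if (!nzchar(sequence)) {
    stop("protein_record: sequence for '", id, "' is empty", call. = FALSE)
  }
  check_canonical(sequence, id)
  n <- nchar(sequence)
  if (is.null(mature_span)) mature_span <- c(1L, n)
  mature_span <- as.integer(mature_span)
  if (length(mature_span) != 2L || anyNA(mature_span) ||
      mature_span[1] < 1L || mature_span[2] > n ||
      mature_span[1] > mature_span[2]) {
    stop("protein_record: invalid mature_span for '", id, "'", call. = FALSE)
  }
  structure(
    list(id = id, accession = accession, sequence = sequence,
         mature_span = mature_span, description = description),
    class = "protein_record"
  )
}

normalize_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  toupper(gsub("[[:space:]*]", "", sequence))
}

check_canonical <- function(sequence, id = "<sequence>") {
  letters_seen <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!(letters_seen %in% AA_ALPHABET))
  if (length(bad)) {
    stop("non-canonical residue '", letters_seen[bad[1]], "' at position ",
         bad[1], " in '", id, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s%s: %d aa, mature [%d-%d]\n", x$id,
              if (nzchar(x$accession)) paste0(" (", x$accession, ")") else "",
              nchar(x$sequence), x$mature_span[1], x$mature_span[2]))
  invisible(x)
}

#' Mature chain of a protein record
#'
#' @param record A [protein_record()].
#' @return The amino-acid string restricted to `mature_span`.
#' @export
mature_chain <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  substr(record$sequence, record$mature_span[1], record$mature_span[2])
}

#' Mass modification
#'
#' A named mass shift targeting a set of residue letters and/or the terminus
#' tokens `"N-TERM"` / `"C-TERM"`.
#'
#' @param name Label, e.g. `"oxidation"`.
#' @param targets Character vector of residue letters or terminus tokens.
#' @param mono_delta,avg_delta Monoisotopic / average mass shift in Da.
#' @param mode `"FIXED"` or `"VARIABLE"`.
#' @param all_or_none For variable modifications: if `TRUE`, enumeration
#'   places the modification on either none or all of its target residues
#'   (used for the acrylamide/propionamide adduct on Cys).
#' @param max_per_peptide Per-peptide cap for variable-state enumeration.
#' @return An object of class `modification`.
#' @export
modification <- function(name, targets, mono_delta, avg_delta = mono_delta,
                         mode = c("VARIABLE", "FIXED"),
                         all_or_none = FALSE, max_per_peptide = 10L) {
  mode <- match.arg(mode)
  targets <- toupper(targets)
  ok <- targets %in% c(AA_ALPHABET, "N-TERM", "C-TERM")
  if (!length(targets) || !all(ok)) {
    stop("modification '", name, "': invalid targets", call. = FALSE)
  }
  stopifnot(is.finite(mono_delta), is.finite(avg_delta))
  structure(
    list(name = name, targets = targets, mono_delta = mono_delta,
         avg_delta = avg_delta, mode = mode, all_or_none = all_or_none,
         max_per_peptide = as.integer(max_per_peptide)),
    class = "modification"
  )
}

#' Built-in modification set
#'
#' Loads the modification table shipped with the package (plain TSV so it is
#' auditable): propionamide (acrylamide adduct) on Cys, oxidation on Met,
#' carbamidomethyl on Cys, and phospho/HexNAc deltas used by the simulator.
#'
#' @param name Optional single modification name to return.
#' @return A named list of [modification()] objects, or one modification.
#' @export
builtin_modifications <- function(name = NULL) {
  tab <- read.delim(pkg_table("modifications.tsv"), stringsAsFactors = FALSE)
  mods <- lapply(seq_len(nrow(tab)), function(i) {
    modification(tab$name[i], strsplit(tab$targets[i], ",", fixed = TRUE)[[1]],
                 tab$mono_delta[i], tab$avg_delta[i], tab$mode[i],
                 tab$all_or_none[i], tab$max_per_peptide[i])
  })
  names(mods) <- tab$name
  if (!is.null(name)) {
    if (!name %in% names(mods)) stop("unknown modification: ", name)
    return(mods[[name]])
  }
  mods
}

pkg_table <- function(file) {
  path <- system.file("extdata", "tables", file, package = "pmfspot")
  if (!nzchar(path)) stop("missing package table: ", file)
  path
}

#' Proteoform
#'
#' A contiguous sub-chain of a protein's mature chain, plus a fixed
#' modification state and a multimer count. This is the unit being
#' identified on a 2-DE gel: full-length monomer, N-terminally truncated
#' form, des-Lys form (C-terminal residue removed), or dimer.
#'
#' @param protein A [protein_record()].
#' @param span Pair `(start, end)` in mature-chain 1-based inclusive
#'   coordinates; defaults to the whole mature chain.
#' @param fixed_mods List of [modification()] applied as fixed.
#' @param multimer Positive integer; 1 = monomer, 2 = dimer.
#' @param label Free-text label (auto-filled by [apply_truncation()]).
#' @return An object of class `proteoform`.
#' @export
proteoform <- function(protein, span = NULL, fixed_mods = list(),
                       multimer = 1L, label = "") {
  stopifnot(inherits(protein, "protein_record"))
  mlen <- protein$mature_span[2] - protein$mature_span[1] + 1L
  if (is.null(span)) span <- c(1L, mlen)
  span <- as.integer(span)
  if (length(span) != 2L || span[1] < 1L || span[2] > mlen ||
      span[1] > span[2]) {
    stop("proteoform: span must lie within the mature chain (1..", mlen, ")",
         call. = FALSE)
  }
  multimer <- as.integer(multimer)
  stopifnot(multimer >= 1L)
  stopifnot(all(vapply(fixed_mods, inherits, logical(1), "modification")))
  structure(
    list(protein = protein, span = span, fixed_mods = fixed_mods,
         multimer = multimer, label = label),
    class = "proteoform"
  )
}

#' @export
print.proteoform <- function(x, ...) {
  cat(sprintf("<proteoform> %s [%d-%d] x%d%s\n", x$protein$id,
              x$span[1], x$span[2], x$multimer,
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  invisible(x)
}

#' Chain sequence of a proteoform (one protomer)
#' @param form A [proteoform()].
#' @return Amino-acid string of the (monomeric) chain over `span`.
#' @export
proteoform_chain <- function(form) {
  stopifnot(inherits(form, "proteoform"))
  substr(mature_chain(form$protein), form$span[1], form$span[2])
}

#' Truncate a proteoform
#'
#' Returns a new proteoform with the narrowed span; the label records the
#' removed intervals in mature coordinates, e.g. `"ΔN1-15"` for loss of
#' the first 15 residues and `"ΔC158"` for loss of the terminal residue
#' (des-Lys style). The parent proteoform and protein are unchanged.
#'
#' @param form A [proteoform()].
#' @param new_span Pair `(start, end)` within `form$span`.
#' @return A new [proteoform()].
#' @export
apply_truncation <- function(form, new_span) {
  stopifnot(inherits(form, "proteoform"))
  new_span <- as.integer(new_span)
  if (length(new_span) != 2L || new_span[1] < form$span[1] ||
      new_span[2] > form$span[2] || new_span[1] > new_span[2]) {
    stop("apply_truncation: new_span escapes the parent span", call. = FALSE)
  }
  removed <- character(0)
  if (new_span[1] > form$span[1]) {
    a <- form$span[1]; b <- new_span[1] - 1L
    removed <- c(removed,
                 if (a == b) sprintf("ΔN%d", a) else sprintf("ΔN%d-%d", a, b))
  }
  if (new_span[2] < form$span[2]) {
    a <- new_span[2] + 1L; b <- form$span[2]
    removed <- c(removed,
                 if (a == b) sprintf("ΔC%d", a) else sprintf("ΔC%d-%d", a, b))
  }
  proteoform(form$protein, new_span, form$fixed_mods, form$multimer,
             label = paste(removed, collapse = ","))
}

#' Read a FASTA file of protein sequences
#'
#' The header token before the first whitespace becomes the record id, the
#' remainder the description. Sequences are uppercased, whitespace and `*`
#' stop symbols removed, and `mature_span` defaults to the full length.
#'
#' @param path FASTA file path.
#' @param skip_ambiguous If `TRUE`, records containing non-canonical letters
#'   (B, J, O, U, X, Z) are collected on a skip list (attribute `"skipped"`)
#'   instead of raising an error.
#' @return List of [protein_record()]; empty (with a warning) for an empty
#'   file.
#' @export
read_fasta <- function(path, skip_ambiguous = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(list())
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  records <- list()
  skipped <- character(0)
  for (i in seq_along(set)) {
    seq_i <- normalize_sequence(as.character(set[[i]]))
    if (!nzchar(ids[i]) || !nzchar(seq_i)) {
      stop("malformed FASTA entry ", i, " ('", headers[i], "') in ", path,
           call. = FALSE)
    }
    rec <- tryCatch(protein_record(ids[i], seq_i, description = descs[i]),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      if (skip_ambiguous) { skipped <- c(skipped, ids[i]); next }
      stop(conditionMessage(rec), call. = FALSE)
    }
    records[[length(records) + 1L]] <- rec
  }
  attr(records, "skipped") <- skipped
  records
}

#' Write protein records to FASTA (wrapped at 60 columns)
#' @param records List of [protein_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(vapply(records, inherits, logical(1), "protein_record")))
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(records, function(r) {
    trimws(paste(r$id, r$description))
  }, character(1))
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Translate a coding sequence (standard genetic code)
#'
#' Helper for cDNA inputs such as the EOGT transcript: translates the first
#' ORF starting at the first ATG, stopping at the first stop codon.
#'
#' @param dna Nucleotide string (A/C/G/T/U, case-insensitive).
#' @return Amino-acid string (stop symbol removed).
#' @export
translate_cds <- function(dna) {
  dna <- toupper(gsub("[[:space:]]", "", dna))
  dna <- chartr("U", "T", dna)
  start <- regexpr("ATG", dna, fixed = TRUE)
  if (start < 0) stop("translate_cds: no ATG start codon found", call. = FALSE)
  orf <- substr(dna, start, nchar(dna))
  orf <- substr(orf, 1L, 3L * (nchar(orf) %/% 3L))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(orf)))
  sub("\\*.*$", "", aa)
}

#' Reference accession registry
#'
#' Maps the study proteins to their public database accessions and to local
#' FASTA files under `dir`. The FASTA files are not shipped: fetch them once
#' with `scripts/fetch_references.sh` (network required) or drop files named
#' `<id>.fasta` into `dir`. All unit tests run on synthetic sequences; only
#' the acceptance checks against published theoretical values need these.
#'
#' @param dir Directory holding `<id>.fasta` files; defaults to the
#'   `pmfspot.reference_dir` option, falling back to the packaged
#'   `extdata/reference` directory.
#' @return data.frame with columns `id`, `accession`, `signal_peptide_len`,
#'   `fasta_path`, `available`.
#' @export
reference_registry <- function(dir = getOption("pmfspot.reference_dir",
                                               system.file("extdata", "reference",
                                                           package = "pmfspot"))) {
  reg <- data.frame(
    id = c("OBP1", "OBP2", "VEG_RM", "VEG_VNO", "SAL", "EOGT"),
    accession = c("NP_998961 / NM_213796 / ENSSSCT00000013229",
                  "ENSSSCP00000028674 / ENSSSCT00000033772",
                  "AAO18367.1 (Leu141) / S77587",
                  "AAB34720.1 (Pro141)",
                  "P81608 / NM_213814",
                  "JX546149 / ENSSSCT00000012589"),
    signal_peptide_len = c(NA, NA, NA, NA, NA, 18L),
    stringsAsFactors = FALSE
  )
  reg$fasta_path <- file.path(dir, paste0(reg$id, ".fasta"))
  reg$available <- file.exists(reg$fasta_path)
  reg
}

#' Load one reference protein by registry id
#'
#' @inheritParams reference_registry
#' @param id Registry id (e.g. `"OBP1"`, `"SAL"`).
#' @return A [protein_record()] with the mature-chain annotation applied
#'   (for EOGT, the 18-residue signal peptide is removed; the lipocalin
#'   reference entries are mature sequences as deposited).
#' @export
load_reference <- function(id, dir = getOption("pmfspot.reference_dir",
                                               system.file("extdata", "reference",
                                                           package = "pmfspot"))) {
  reg <- reference_registry(dir)
  row <- reg[reg$id == id, ]
  if (nrow(row) != 1L) stop("unknown reference id: ", id, call. = FALSE)
  if (!row$available) {
    stop("reference sequence '", id, "' (", row$accession, ") not available: ",
         "expected ", row$fasta_path,
         "; fetch it with scripts/fetch_references.sh (network required)",
         call. = FALSE)
  }
  recs <- read_fasta(row$fasta_path)
  rec <- recs[[1]]
  rec$id <- id
  rec$accession <- row$accession
  if (!is.na(row$signal_peptide_len)) {
    rec$mature_span <- c(row$signal_peptide_len + 1L, nchar(rec$sequence))
  }
  rec
}
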