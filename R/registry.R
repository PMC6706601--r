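# Compound registry: molecular formulas, mass arithmetic and ion channels
# for the nitroaromatic target panel, the internal standard and the matrix.

# Supported element set. Nominal = integer mass number of the lightest
# isotope; monoisotopic = exact mass of the lightest isotope (12C = 12 by
# definition).
.ELEMENTS <- c("C", "H", "N", "O", "Cl")
.NOMINAL_MASS <- c(C = 12, H = 1, N = 14, O = 16, Cl = 35)
.MONO_MASS <- c(C = 12,
                H = 1.0078250319,
                N = 14.0030740052,
                O = 15.9949146221,
                Cl = 34.96885271)

.ION_KINDS <- c("radical_anion", "deprotonated", "oxygen_loss",
                "deprotonated_oxygen_loss", "observed_fixed")

#' Parse a Hill-notation molecular formula
#'
#' Accepts formulas over the element set C, H, N, O, Cl (sufficient for the
#' nitroaromatic panel, the chlorinated internal standard and the calibrant
#' acids). Each element symbol may be followed by an optional positive
#' integer count.
#'
#' @param text Formula string, e.g. `"C7H5N3O6"` or `"C7H5ClN2O4"`.
#' @return A `chem_formula`: a named integer vector with one entry per
#'   supported element.
#' @examples
#' parse_formula("C7H5N3O6")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  if (!nzchar(s)) stop("empty formula string")
  counts <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  # tokenize: element symbol (one upper + optional lower letters) + digits
  pos <- 1L
  while (pos <= nchar(s)) {
    rest <- substr(s, pos, nchar(s))
    m <- regmatches(rest, regexec("^([A-Z][a-z]*)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[2]))
      stop(sprintf("malformed formula near '%s'", rest))
    sym <- m[2]
    if (!sym %in% .ELEMENTS)
      stop(sprintf("unsupported element symbol '%s' in formula '%s'",
                   sym, text))
    n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    if (is.na(n) || n < 1L)
      stop(sprintf("malformed count '%s' for element '%s'", m[3], sym))
    counts[sym] <- counts[sym] + n
    pos <- pos + nchar(m[1])
  }
  structure(counts, class = "chem_formula")
}

#' Canonical Hill-notation string for a formula
#' @param x A `chem_formula`.
#' @param ... Ignored.
#' @export
format.chem_formula <- function(x, ...) {
  # Hill order: C, H, then remaining elements alphabetically
  ord <- c("C", "H", sort(setdiff(.ELEMENTS, c("C", "H"))))
  parts <- vapply(ord, function(el) {
    n <- x[[el]]
    if (n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }, character(1))
  paste0(parts, collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula>", format(x), "\n")
  invisible(x)
}

#' Nominal (integer) mass of a formula
#'
#' Sum of element counts times integer mass numbers (C=12, H=1, N=14, O=16,
#' Cl=35). This is the mass scale on which the unit-resolution ion channels
#' (m/z 227, 211, 216, ...) are defined.
#'
#' @param f A `chem_formula` (or formula string).
#' @return Integer mass in Da.
#' @examples
#' nominal_mass("C7H5N3O6") # TNT, 227
#' @export
nominal_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "chem_formula"))
  as.integer(sum(unclass(f) * .NOMINAL_MASS[names(f)]))
}

#' Monoisotopic (exact) mass of a formula
#'
#' Sum of element counts times the exact mass of the lightest isotope.
#' Additive over formula union by construction.
#'
#' @inheritParams nominal_mass
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "chem_formula"))
  sum(unclass(f) * .MONO_MASS[names(f)])
}

#' m/z of an ion species of a registered compound
#'
#' Negative-mode species at charge -1. The electron mass (~0.00055 Da) is
#' ignored; it is negligible at the 0.5 Da extraction tolerance used
#' throughout. Offsets on the nominal scale: radical anion \[M\]^.- = M;
#' deprotonated \[M-H\]^- = M-1; oxygen loss \[M-O\]^.- = M-16 (in-source
#' nitro-to-nitroso reduction); deprotonated oxygen loss = M-17. On the
#' monoisotopic scale the exact H and O masses are subtracted.
#'
#' @param compound Compound abbreviation (looked up in `registry`) or a
#'   `chem_formula`.
#' @param kind One of `"radical_anion"`, `"deprotonated"`, `"oxygen_loss"`,
#'   `"deprotonated_oxygen_loss"`, `"observed_fixed"`.
#' @param resolution `"nominal"` (integer Da) or `"monoisotopic"`.
#' @param registry A `compound_registry`; defaults to [builtin_registry()].
#' @return m/z value. For `observed_fixed` the literal m/z values stored in
#'   the registry are returned (may be length > 1, e.g. the DAN matrix ions
#'   156 and 157).
#' @examples
#' ion_mz("CDNT", "oxygen_loss") # 200
#' @export
ion_mz <- function(compound, kind, resolution = c("nominal", "monoisotopic"),
                   registry = builtin_registry()) {
  resolution <- match.arg(resolution)
  kind <- match.arg(kind, .ION_KINDS)
  if (kind == "observed_fixed") {
    if (!is.character(compound))
      stop("observed_fixed m/z values require a registered compound")
    ch <- registry$channels
    hit <- ch[ch$abbreviation == compound & ch$kind == "observed_fixed", ]
    if (nrow(hit) == 0L)
      stop(sprintf("compound '%s' has no observed_fixed m/z in the registry",
                   compound))
    return(hit$nominal_mz)
  }
  f <- if (inherits(compound, "chem_formula")) compound else {
    cmp <- registry$compounds
    row <- cmp[cmp$abbreviation == compound, ]
    if (nrow(row) != 1L)
      stop(sprintf("compound '%s' not found in registry", compound))
    parse_formula(row$formula)
  }
  if (resolution == "nominal") {
    m <- nominal_mass(f)
    switch(kind,
           radical_anion = m,
           deprotonated = m - 1L,
           oxygen_loss = m - 16L,
           deprotonated_oxygen_loss = m - 17L)
  } else {
    m <- monoisotopic_mass(f)
    h <- .MONO_MASS[["H"]]; o <- .MONO_MASS[["O"]]
    switch(kind,
           radical_anion = m,
           deprotonated = m - h,
           oxygen_loss = m - o,
           deprotonated_oxygen_loss = m - h - o)
  }
}

.registry_compound <- function(abbreviation, name, formula, role,
                               isomer_group = NA_character_) {
  data.frame(abbreviation = abbreviation, name = name, formula = formula,
             role = role, isomer_group = isomer_group,
             stringsAsFactors = FALSE)
}

#' Built-in compound registry for the nitroaromatic panel
#'
#' Contains the eight analytes (TNT, 2-ADNT, 4-ADNT, 2,4-DNT, 2,6-DNT, TNB,
#' DNB, NT), the internal standard CDNT (5-chloro-2,4-dinitrotoluene), the
#' MALDI matrices DAN (active), CHCA and AA (reference metadata only), and
#' the mass calibrants mefenamic, citric and chlorogenic acid. Positional
#' isomers that the method cannot distinguish share an `isomer_group`
#' ("ADNT", "DNT"); quantification always reports isomer-group sums.
#'
#' Each analyte and the internal standard expose a radical-anion channel
#' and an oxygen-loss fragment channel (16 Da below the parent). The DAN
#' matrix ions are stored as observed literals m/z 156/157 (attributed to
#' reduction chemistry, not computed from the C10H10N2 formula). Calibrants
#' expose deprotonated channels.
#'
#' @return A `compound_registry`: list with data frames `compounds`
#'   (abbreviation, name, formula, role, isomer_group) and `channels`
#'   (abbreviation, kind, nominal_mz, monoisotopic_mz, label).
#' @examples
#' reg <- builtin_registry()
#' subset(reg$compounds, role == "internal_standard")
#' @export
builtin_registry <- function() {
  compounds <- rbind(
    .registry_compound("TNT", "2,4,6-trinitrotoluene", "C7H5N3O6", "analyte"),
    .registry_compound("2-ADNT", "2-amino-4,6-dinitrotoluene", "C7H7N3O4",
                       "analyte", "ADNT"),
    .registry_compound("4-ADNT", "4-amino-2,6-dinitrotoluene", "C7H7N3O4",
                       "analyte", "ADNT"),
    .registry_compound("2,4-DNT", "2,4-dinitrotoluene", "C7H6N2O4",
                       "analyte", "DNT"),
    .registry_compound("2,6-DNT", "2,6-dinitrotoluene", "C7H6N2O4",
                       "analyte", "DNT"),
    .registry_compound("TNB", "1,3,5-trinitrobenzene", "C6H3N3O6", "analyte"),
    .registry_compound("DNB", "1,3-dinitrobenzene", "C6H4N2O4", "analyte"),
    .registry_compound("NT", "2-nitrotoluene", "C7H7NO2", "analyte"),
    .registry_compound("CDNT", "5-chloro-2,4-dinitrotoluene", "C7H5ClN2O4",
                       "internal_standard"),
    .registry_compound("DAN", "1,5-diaminonaphthalene", "C10H10N2", "matrix"),
    # CHCA's often-quoted molar mass (188) disagrees with the computed 189
    # for C10H7NO3; the computed value is stored.
    .registry_compound("CHCA", "alpha-cyano-4-hydroxycinnamic acid",
                       "C10H7NO3", "matrix"),
    .registry_compound("AA", "9-aminoacridine", "C13H10N2", "matrix"),
    .registry_compound("MEF", "mefenamic acid", "C15H15NO2", "mass_calibrant"),
    .registry_compound("CIT", "citric acid", "C6H8O7", "mass_calibrant"),
    .registry_compound("CGA", "chlorogenic acid", "C16H18O9", "mass_calibrant")
  )
  channel_row <- function(abbr, kind, nominal, mono) {
    data.frame(abbreviation = abbr, kind = kind, nominal_mz = nominal,
               monoisotopic_mz = mono,
               label = sprintf("%s_%d", abbr, as.integer(round(nominal))),
               stringsAsFactors = FALSE)
  }
  chans <- list()
  for (i in seq_len(nrow(compounds))) {
    abbr <- compounds$abbreviation[i]
    role <- compounds$role[i]
    f <- parse_formula(compounds$formula[i])
    if (role %in% c("analyte", "internal_standard")) {
      for (k in c("radical_anion", "oxygen_loss")) {
        chans[[length(chans) + 1L]] <- channel_row(
          abbr, k, ion_mz(f, k, "nominal"), ion_mz(f, k, "monoisotopic"))
      }
    } else if (abbr == "DAN") {
      # observed reduction products, not computable from the formula
      for (mzv in c(156, 157)) {
        chans[[length(chans) + 1L]] <- channel_row(
          abbr, "observed_fixed", mzv, mzv)
      }
    } else if (role == "mass_calibrant") {
      chans[[length(chans) + 1L]] <- channel_row(
        abbr, "deprotonated",
        ion_mz(f, "deprotonated", "nominal"),
        ion_mz(f, "deprotonated", "monoisotopic"))
    }
  }
  reg <- list(compounds = compounds, channels = do.call(rbind, chans))
  class(reg) <- "compound_registry"
  validate_registry(reg)
  reg
}

#' Validate registry invariants
#'
#' Checks abbreviation uniqueness, the single-internal-standard rule, and
#' the 16 Da relation between radical-anion and oxygen-loss channels.
#'
#' @param registry A `compound_registry`.
#' @return The registry, invisibly; errors on violation.
#' @export
validate_registry <- function(registry) {
  cmp <- registry$compounds
  if (anyDuplicated(cmp$abbreviation))
    stop("duplicate compound abbreviations in registry")
  n_is <- sum(cmp$role == "internal_standard")
  if (n_is != 1L)
    stop(sprintf("registry must contain exactly one internal standard, found %d",
                 n_is))
  ch <- registry$channels
  for (abbr in unique(ch$abbreviation)) {
    sub <- ch[ch$abbreviation == abbr, ]
    if (all(c("radical_anion", "oxygen_loss") %in% sub$kind)) {
      ra <- sub$nominal_mz[sub$kind == "radical_anion"]
      ox <- sub$nominal_mz[sub$kind == "oxygen_loss"]
      if (ra - ox != 16)
        stop(sprintf("oxygen-loss channel of %s is not 16 Da below the parent",
                     abbr))
    }
  }
  invisible(registry)
}

#' @export
print.compound_registry <- function(x, ...) {
  cat(sprintf("<compound_registry> %d compounds, %d ion channels\n",
              nrow(x$compounds), nrow(x$channels)))
  print(x$compounds, row.names = FALSE)
  invisible(x)
}

#' Isomer group of a compound abbreviation
#'
#' Maps an abbreviation to the label under which it is quantified: its
#' `isomer_group` if set (2-ADNT and 4-ADNT -> "ADNT"), otherwise the
#' abbreviation itself. Group labels pass through unchanged.
#'
#' @param abbr Character vector of abbreviations or group labels.
#' @param registry A `compound_registry`.
#' @return Character vector of group labels.
#' @export
isomer_group_of <- function(abbr, registry = builtin_registry()) {
  cmp <- registry$compounds
  vapply(abbr, function(a) {
    i <- match(a, cmp$abbreviation)
    if (!is.na(i)) {
      g <- cmp$isomer_group[i]
      if (is.na(g)) a else g
    } else if (a %in% cmp$isomer_group) {
      a
    } else {
      stop(sprintf("unknown compound or isomer group '%s'", a))
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Write a compound registry to CSV
#'
#' One row per compound; ion channels serialized as semicolon-separated
#' `kind:mz` pairs in a `channels` column.
#'
#' @param registry A `compound_registry`.
#' @param path Output CSV path.
#' @export
write_registry <- function(registry, path) {
  cmp <- registry$compounds
  ch <- registry$channels
  cmp$channels <- vapply(cmp$abbreviation, function(a) {
    sub <- ch[ch$abbreviation == a, ]
    paste(sprintf("%s:%g", sub$kind, sub$nominal_mz), collapse = ";")
  }, character(1))
  utils::write.csv(cmp, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a compound registry from CSV
#'
#' Inverse of [write_registry()]. Monoisotopic channel m/z values are
#' recomputed from the formulas (observed_fixed channels keep their literal
#' value).
#'
#' @param path CSV path written by [write_registry()].
#' @return A `compound_registry`.
#' @export
read_registry <- function(path) {
  cmp <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("abbreviation", "name", "formula", "role", "isomer_group",
            "channels")
  if (!all(need %in% names(cmp)))
    stop("registry CSV is missing required columns")
  chans <- list()
  for (i in seq_len(nrow(cmp))) {
    spec_str <- cmp$channels[i]
    if (is.na(spec_str) || !nzchar(spec_str)) next
    for (pair in strsplit(spec_str, ";", fixed = TRUE)[[1]]) {
      kv <- strsplit(pair, ":", fixed = TRUE)[[1]]
      kind <- kv[1]
      mzv <- as.numeric(kv[2])
      mono <- if (kind == "observed_fixed") mzv else
        ion_mz(parse_formula(cmp$formula[i]), kind, "monoisotopic")
      chans[[length(chans) + 1L]] <- data.frame(
        abbreviation = cmp$abbreviation[i], kind = kind, nominal_mz = mzv,
        monoisotopic_mz = mono,
        label = sprintf("%s_%d", cmp$abbreviation[i], as.integer(round(mzv))),
        stringsAsFactors = FALSE)
    }
  }
  reg <- list(compounds = cmp[setdiff(names(cmp), "channels")],
              channels = do.call(rbind, chans))
  class(reg) <- "compound_registry"
  validate_registry(reg)
  reg
}
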